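test_that("penalty arithmetic matches hand computation", {
  expect_equal(aen_penalty(c(0, 0, 0), 0.3), 0)
  expect_equal(aen_penalty(c(1, -2), 0.3, c(1, 1)), 0.35 * 5 + 0.3 * 3)
  expect_equal(aen_penalty(c(1, -2), 1, c(2, 1)), 4)
})

test_that("objective is the stable average log-likelihood minus the penalty", {
  x <- matrix(rnorm(20), 10, 2)
  y <- rep(c(0, 1), 5)
  expect_equal(aen_objective(0, c(0, 0), x, y, 0.1, 0.3), -log(2))
  # saturation: with all-one labels the objective rises toward 0 in beta0
  y1 <- rep(1, 10)
  objs <- sapply(c(0, 2, 5, 10, 30), function(b0)
    aen_objective(b0, c(0, 0), x, y1, 0.1, 0.3))
  expect_true(all(diff(objs) > 0))
  expect_gt(objs[length(objs)], -1e-4)
  # no overflow at extreme linear predictors
  expect_true(is.finite(aen_objective(1000, c(0, 0), x, y, 0.1, 0.3)))
})

test_that("a fitted model beats the optimal-intercept null model", {
  set.seed(21)
  net <- random_test_net(10, 0.3)
  ef <- random_instance(80, net, effect = 1.5, seed = 1)
  lam <- 0.3 * aen_lambda_max(ef, alpha = 0.3)
  fit <- aen_fit(ef, lambda = lam, alpha = 0.3)
  null_obj <- aen_objective(qlogis(mean(ef$y)), rep(0, ncol(ef$x)), ef$x, ef$y,
                            lam, 0.3)
  expect_gte(fit$objective, null_obj)
})

test_that("lambda_max thresholds the path exactly", {
  set.seed(22)
  net <- random_test_net(10, 0.3)
  ef <- random_instance(60, net, effect = 1.5, seed = 2)
  lmax <- aen_lambda_max(ef, alpha = 0.3)
  # doubling alpha halves lambda_max
  expect_equal(aen_lambda_max(ef, alpha = 0.6), lmax / 2)
  expect_error(aen_lambda_max(ef, alpha = 0), "ridge")
  # fitting just above lambda_max yields an empty active set
  fit_above <- aen_fit(ef, lambda = 1.01 * lmax, alpha = 0.3)
  expect_length(fit_above$active, 0)
  # fitting at lambda_max itself is exactly null with the closed-form intercept
  fit_at <- aen_fit(ef, lambda = lmax, alpha = 0.3)
  expect_true(all(fit_at$beta == 0))
  expect_equal(fit_at$beta0, qlogis(mean(ef$y)), tolerance = 1e-8)
  # just below, something activates
  fit_below <- aen_fit(ef, lambda = 0.95 * lmax, alpha = 0.3)
  expect_gt(length(fit_below$active), 0)
})

test_that("an all-zero design yields the null model", {
  x <- matrix(0, 40, 5)
  colnames(x) <- paste0("f", 1:5)
  y <- rep(c(0, 1, 1, 1), 10)
  suppressWarnings(path <- aen_path(x, y, alpha = 0.3, lambda = 0.1))
  expect_true(all(path$beta == 0))
  expect_equal(path$beta0[1], qlogis(0.75), tolerance = 1e-8)
})

test_that("solver errors on degenerate inputs", {
  x <- matrix(rnorm(20), 10, 2)
  expect_error(aen_path(x, rep(1, 10), alpha = 0.3), "both classes")
  expect_error(aen_path(x, rep(c(0, 1), 5), alpha = 1.5), "alpha")
  x[1, 1] <- NA
  expect_error(aen_path(x, rep(c(0, 1), 5), alpha = 0.3), "non-finite")
})

test_that("the r=0 path matches a reference elastic-net solver", {
  skip_if_not_installed("glmnet")
  set.seed(23)
  net <- random_test_net(12, 0.35)
  ef <- random_instance(100, net, effect = 1.5, seed = 3)
  path <- aen_path(ef, alpha = 0.3, nlambda = 50)
  g <- glmnet::glmnet(ef$x, ef$y, family = "binomial", alpha = 0.3,
                      lambda = path$lambda, standardize = FALSE,
                      thresh = 1e-14, maxit = 1e6)
  expect_lt(max(abs(as.matrix(g$beta) - path$beta)), 1e-4)
  expect_lt(max(abs(g$a0 - path$beta0)), 1e-4)
})

test_that("weighted fits satisfy the weighted stationarity conditions", {
  # no drop-in reference exists for L1-only weights (penalty factors in the
  # usual solvers scale the ridge term too), so the certificate is the KKT
  # system of the weighted objective itself, recomputed in R
  set.seed(24)
  net <- random_test_net(12, 0.35)
  ef <- random_instance(90, net, effect = 1.5, seed = 4)
  w <- adaptive_weights(line_graph(net), 0.5)
  wv <- unname(w$normalized[colnames(ef$x)])
  path <- aen_path(ef, alpha = 0.3, weights = wv, nlambda = 40)
  expect_true(all(path$converged))
  for (j in c(1L, 10L, 25L, 40L)) {
    expect_lt(kkt_residual(path$beta0[j], path$beta[, j], ef$x, ef$y,
                           path$lambda[j], 0.3, wv), 1e-4)
  }
  # and the weighted objective at the solution beats nearby perturbations
  j <- 25L
  obj <- aen_objective(path$beta0[j], path$beta[, j], ef$x, ef$y,
                       path$lambda[j], 0.3, wv)
  set.seed(1)
  for (t in 1:10) {
    d <- rnorm(ncol(ef$x), sd = 0.01)
    expect_lt(aen_objective(path$beta0[j], path$beta[, j] + d, ef$x, ef$y,
                            path$lambda[j], 0.3, wv), obj + 1e-12)
  }
})

test_that("KKT residuals reported by the solver agree with an independent check", {
  set.seed(25)
  for (i in 1:5) {
    net <- random_test_net(10, 0.3)
    ef <- random_instance(60, net, effect = 1, seed = 30 + i)
    path <- aen_path(ef, alpha = 0.3, nlambda = 20)
    j <- sample(length(path$lambda), 1)
    resid_r <- kkt_residual(path$beta0[j], path$beta[, j], ef$x, ef$y,
                            path$lambda[j], 0.3)
    expect_lt(resid_r, 1e-4)
    expect_lt(abs(resid_r - path$kkt[j]), 1e-6)
  }
})

test_that("doubling one penalty weight weakly shrinks that coefficient", {
  set.seed(26)
  shrunk <- 0; total <- 0
  for (i in 1:20) {
    net <- random_test_net(8, 0.4)
    ef <- random_instance(60, net, effect = 1.5, seed = 50 + i)
    M <- ncol(ef$x)
    lam <- 0.3 * aen_lambda_max(ef, alpha = 0.3)
    base <- aen_fit(ef, lambda = lam, alpha = 0.3)
    act <- which(base$beta != 0)
    if (!length(act)) next
    m <- act[1]
    w2 <- rep(1, M); w2[m] <- 2
    mod <- aen_fit(ef, lambda = lam, alpha = 0.3, weights = w2)
    total <- total + 1
    if (abs(mod$beta[m]) <= abs(base$beta[m]) + 1e-10) shrunk <- shrunk + 1
  }
  expect_gt(total, 10)
  expect_equal(shrunk, total)
})

test_that("paths are finite, start empty, and count selections consistently", {
  set.seed(27)
  net <- random_test_net(10, 0.3)
  ef <- random_instance(80, net, effect = 2, seed = 6)
  path <- aen_path(ef, alpha = 0.3)
  expect_false(any(!is.finite(path$beta)))
  expect_false(any(!is.finite(path$beta0)))
  expect_equal(path$df[1], 0L)
  expect_true(all(diff(path$lambda) < 0))
  expect_equal(unname(path$selection_count),
               unname(rowSums(path$beta != 0)))
  expect_true(all(path$converged))
})

test_that("probability predictions follow the logistic link", {
  fit <- structure(list(beta0 = 0, beta = c(f1 = 0, f2 = 0)), class = "aen_fit")
  x <- matrix(rnorm(20), 10, 2, dimnames = list(NULL, c("f1", "f2")))
  expect_equal(predict(fit, x), rep(0.5, 10))
  set.seed(28)
  net <- random_test_net(8, 0.4)
  ef <- random_instance(60, net, effect = 1.5, seed = 7)
  lam <- 0.2 * aen_lambda_max(ef, alpha = 0.3)
  f <- aen_fit(ef, lambda = lam, alpha = 0.3)
  pr <- predict(f, ef)
  eta <- predict(f, ef, type = "link")
  expect_true(all(pr > 0 & pr < 1))
  expect_equal(pr > 0.5, eta > 0)
  # null fit predicts the calibrated base rate everywhere
  fnull <- aen_fit(ef, lambda = 2 * aen_lambda_max(ef, alpha = 0.3), alpha = 0.3)
  expect_equal(unname(predict(fnull, ef)), rep(mean(ef$y), nrow(ef$x)),
               tolerance = 1e-6)
  expect_error(predict(f, ef$x[, 1:3]), "mismatch")
})

test_that("solution paths serialize to TSV + JSON", {
  set.seed(29)
  net <- random_test_net(8, 0.4)
  ef <- random_instance(40, net, effect = 1, seed = 8)
  path <- aen_path(ef, alpha = 0.3, nlambda = 10)
  pre <- file.path(withr::local_tempdir(), "run")
  files <- write_solution_path(path, pre)
  expect_true(all(file.exists(files)))
  sel <- read.delim(files[2])
  expect_equal(sort(sel$feature), sort(rownames(path$beta)))
  meta <- jsonlite::read_json(files[3])
  expect_length(meta$lambda, 10)
})
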