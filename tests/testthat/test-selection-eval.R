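test_that("AUC matches pairwise enumeration, with half credit for ties", {
  expect_equal(auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(auc(rep(0.4, 6), c(1, 0, 1, 0, 1, 0)), 0.5)
  # classes interleaved: 2 of 4 pairs concordant
  expect_equal(auc(c(0.9, 0.1, 0.8, 0.2), c(1, 1, 0, 0)), 0.5)
  expect_error(auc(c(0.1, 0.2), c(1, 1)), "both classes")
})

test_that("edge-to-gene transfer deduplicates endpoints", {
  expect_equal(edges_to_genes(c("A|B", "B|C")), c("A", "B", "C"))
  expect_equal(edges_to_genes(character(0)), character(0))
  expect_equal(edges_to_genes("A|B"), c("A", "B"))
  expect_equal(edges_to_genes(data.frame(a = c("X", "Y"), b = c("Y", "Z"))),
               c("X", "Y", "Z"))
})

test_that("Jaccard coefficient handles the boundary cases", {
  expect_equal(jaccard(c("A", "B"), c("A", "B")), 1)
  expect_equal(jaccard(c("A", "B"), c("C", "D")), 0)
  expect_equal(jaccard(c("A", "B"), c("B", "C")), 1 / 3)
  expect_message(j0 <- jaccard(character(0), character(0)), "empty")
  expect_equal(j0, 1)
})

test_that("fold assignment is stratified, seeded, and reproducible", {
  y <- rep(c(0, 1), c(30, 20))
  f1 <- edgemarker:::make_folds(y, 10, seed = 1)
  f2 <- edgemarker:::make_folds(y, 10, seed = 1)
  f3 <- edgemarker:::make_folds(y, 10, seed = 2)
  expect_identical(f1, f2)
  expect_false(identical(f1, f3))
  for (k in 1:10) {
    expect_equal(sum(f1 == k & y == 0), 3)
    expect_equal(sum(f1 == k & y == 1), 2)
  }
})

test_that("cross-validation is deterministic given a seed and prefers sparser ties", {
  net <- simulate_network(30, "scale_free", 2, seed = 91)
  sim <- simulate_dataset(net, n = 80, n_informative = 5, effect = 2, seed = 92)
  cv1 <- cv_lambda(sim$ds, net, k = 5, nlambda = 30, seed = 7)
  cv2 <- cv_lambda(sim$ds, net, k = 5, nlambda = 30, seed = 7)
  expect_identical(cv1$cvm, cv2$cvm)
  expect_identical(cv1$lambda_opt, cv2$lambda_opt)
  # the chosen index is the first (largest lambda) attaining the maximum
  expect_equal(cv1$index_opt, which(cv1$cvm >= max(cv1$cvm) - 1e-12)[1])
  # strong planted signal selects a nonempty model
  expect_gt(length(cv1$selected_edges), 0)
  expect_equal(cv1$selected_genes, edges_to_genes(cv1$selected_edges))
})

test_that("leave-one-out folds pool held-out scores before the AUC", {
  net <- simulate_network(12, "scale_free", 1, seed = 93)
  sim <- simulate_dataset(net, n = 14, n_informative = 2, effect = 2, seed = 94)
  cv <- cv_lambda(sim$ds, net, k = 14, nlambda = 10, seed = 8)
  expect_true(cv$pooled)
  expect_true(all(cv$cvm >= 0 & cv$cvm <= 1))
})

test_that("a flat AUC surface makes the grid search pick the largest r then largest lambda", {
  # constant expression: every edge feature has zero variance, every model
  # is the null model, and the whole (lambda, r) surface ties at AUC 0.5
  net <- simulate_network(10, "scale_free", 2, seed = 95)
  x <- matrix(1, 40, 10, dimnames = list(NULL, net$nodes))
  ds <- expr_dataset(x, rep(c(0, 1), 20))
  gs <- grid_search_r(ds, net, r_grid = c(0.01, 0.2, 0.8), k = 4,
                      nlambda = 8, seed = 9)
  expect_equal(gs$r, 0.8)
  expect_equal(gs$index_opt, 1L)
  expect_true(all(abs(gs$auc_by_r - 0.5) < 1e-12))
})

test_that("a singleton r grid reduces to plain lambda CV", {
  net <- simulate_network(20, "scale_free", 2, seed = 96)
  sim <- simulate_dataset(net, n = 60, n_informative = 3, effect = 2, seed = 97)
  lg <- line_graph(net)
  gs <- grid_search_r(sim$ds, net, r_grid = 0.2, lg = lg, k = 5,
                      nlambda = 20, seed = 10)
  cv <- cv_lambda(sim$ds, net, r = 0.2, lg = lg, k = 5, nlambda = 20, seed = 10)
  expect_equal(gs$cvm, cv$cvm)
  expect_equal(gs$lambda_opt, cv$lambda_opt)
})

test_that("selection ranking recounts nonzero path points and breaks ties deterministically", {
  net <- simulate_network(25, "scale_free", 2, seed = 98)
  sim <- simulate_dataset(net, n = 80, n_informative = 4, effect = 2, seed = 99)
  ef <- edge_features(sim$ds, net)
  path <- aen_path(ef, alpha = 0.3, nlambda = 40)
  rk <- rank_by_selection(path)
  expect_equal(sort(rk$id), sort(rownames(path$beta)))
  for (i in sample(nrow(rk), 5)) {
    expect_equal(rk$count[i], sum(path$beta[rk$id[i], ] != 0))
  }
  expect_true(all(diff(rk$count) <= 0))
  # gene level: a gene inherits the max count over incident edges
  rg <- rank_by_selection(path, level = "gene")
  g <- rg$id[1]
  inc <- path$features$edges$a == g | path$features$edges$b == g
  expect_equal(rg$count[1], max(path$selection_count[inc]))
  expect_true(all(diff(rg$count) <= 0))
})

test_that("an all-zero path yields an empty positive-count ranking", {
  net <- simulate_network(10, "scale_free", 1, seed = 90)
  sim <- simulate_dataset(net, n = 30, n_informative = 2, effect = 1, seed = 89)
  ef <- edge_features(sim$ds, net)
  lmax <- aen_lambda_max(ef, alpha = 0.3)
  path <- aen_path(ef, alpha = 0.3, lambda = c(2 * lmax, 1.5 * lmax))
  rk <- rank_by_selection(path)
  expect_true(all(rk$count == 0))
  expect_length(edgemarker:::top_ranked(rk, 10), 0)
})

test_that("perturbation protocols honour stub selectors", {
  net <- simulate_network(15, "scale_free", 2, seed = 88)
  sim <- simulate_dataset(net, n = 60, n_informative = 3, effect = 1, seed = 87)
  fixed <- function(ds_sub, seed = NULL) c("G1", "G2", "G3")
  soft <- soft_perturbation_stability(sim$ds, net, repeats = 5, seed = 1,
                                      selector = fixed)
  expect_equal(soft$median, 1)
  expect_equal(soft$setting, "soft")

  flip <- local({
    state <- 0L
    function(ds_sub, seed = NULL) {
      state <<- state + 1L
      if (state %% 2L == 1L) c("A1", "A2") else c("B1", "B2")
    }
  })
  hard <- hard_perturbation_stability(sim$ds, net, repeats = 5, seed = 2,
                                      selector = flip)
  expect_equal(hard$median, 0)
  expect_equal(hard$values, rep(0, 5))
})

test_that("soft perturbation rejects infeasible constructions", {
  net <- simulate_network(10, "scale_free", 1, seed = 86)
  sim <- simulate_dataset(net, n = 10, n_informative = 2, effect = 1, seed = 85)
  expect_error(
    soft_perturbation_stability(sim$ds, net, repeats = 2, frac = 0.95,
                                overlap = 0.5, seed = 3,
                                selector = function(ds_sub, seed = NULL) "G"),
    "infeasible")
})

test_that("hard perturbation needs both classes twice", {
  x <- matrix(rnorm(9), 3, 3, dimnames = list(NULL, c("A", "B", "C")))
  ds <- expr_dataset(x, c(0, 1, 1))
  net <- ppi_network(data.frame(a = "A", b = "B"))
  expect_error(hard_perturbation_stability(ds, net, repeats = 2, seed = 1,
                                           selector = function(d, s) "A"),
               "infeasible")
})

test_that("between-dataset overlap behaves at the extremes", {
  mk <- function(ids, counts) {
    df <- data.frame(id = ids, count = counts, max_abs_beta = counts)
    class(df) <- c("gene_ranking", "data.frame")
    df
  }
  r1 <- mk(paste0("g", 1:10), 10:1)
  expect_equal(between_dataset_stability(list(r1, r1), k = 5)$median, 1)
  r2 <- mk(paste0("h", 1:10), 10:1)
  expect_equal(between_dataset_stability(list(r1, r2), k = 5)$median, 0)
  # at k = total genes the overlap is 1 by construction
  r3 <- mk(paste0("g", sample(1:10)), sample(1:10))
  expect_equal(between_dataset_stability(list(r1, r3), k = 10)$median, 1)
  expect_error(between_dataset_stability(list(r1)), "at least two")
})

test_that("stability reports serialize to JSON and TSV", {
  rep <- edgemarker:::stability_report("hard", c(0.2, 0.4, 0.6))
  expect_equal(rep$median, 0.4)
  files <- write_stability_report(rep, file.path(withr::local_tempdir(), "x"))
  expect_true(all(file.exists(files)))
  j <- jsonlite::read_json(files[1])
  expect_equal(j$median, 0.4)
})
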