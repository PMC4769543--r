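#' Simulate an interaction network
#'
#' Scale-free networks are grown by preferential attachment: the first
#' `param` nodes start unconnected, and each subsequent node attaches to
#' `param` distinct existing nodes with probability proportional to degree
#' plus one (the smoothing lets isolated seed nodes acquire edges). The edge
#' count is therefore exactly `param * (p - param)`. Erdos-Renyi networks
#' draw each pair independently with probability `param`.
#'
#' @param p number of genes (>= 3)
#' @param model `"scale_free"` or `"erdos_renyi"`
#' @param param edges per new node (scale-free) or edge probability (ER)
#' @param seed RNG seed
#' @return a [ppi_network()] over genes `g001`, `g002`, ...
#' @export
simulate_network <- function(p, model = c("scale_free", "erdos_renyi"),
                             param = 2, seed = NULL) {
  model <- match.arg(model)
  if (p < 3L) stop("p must be at least 3")
  genes <- sprintf("g%03d", seq_len(p))
  with_seed(seed, {
    if (model == "scale_free") {
      m <- as.integer(param)
      if (m < 1L || m >= p) stop("scale-free param must be in [1, p)")
      deg <- numeric(p)
      a <- character(0); b <- character(0)
      for (v in seq(m + 1L, p)) {
        existing <- seq_len(v - 1L)
        targets <- sample(existing, m, prob = deg[existing] + 1)
        deg[targets] <- deg[targets] + 1
        deg[v] <- deg[v] + m
        a <- c(a, rep(genes[v], m)); b <- c(b, genes[targets])
      }
      ppi_network(data.frame(a = a, b = b, stringsAsFactors = FALSE),
                  nodes = genes)
    } else {
      if (param < 0 || param > 1) stop("edge probability must be in [0, 1]")
      g <- igraph::sample_gnp(p, param)
      el <- igraph::as_edgelist(g)
      if (nrow(el) == 0L) {
        structure(list(nodes = genes,
                       edges = data.frame(a = character(), b = character(),
                                          weight = numeric(), id = character(),
                                          stringsAsFactors = FALSE),
                       adj = lapply(stats::setNames(genes, genes),
                                    function(x) character())),
                  class = "ppi_network")
      } else {
        ppi_network(data.frame(a = genes[el[, 1L]], b = genes[el[, 2L]],
                               stringsAsFactors = FALSE), nodes = genes)
      }
    }
  })
}

# Find the intercept for which the mean class probability hits the target
# prevalence, by bisection on the (monotone) mean of plogis(b0 + eta).
calibrate_intercept <- function(eta, prevalence, lo = -40, hi = 40) {
  if (prevalence <= 0 || prevalence >= 1) stop("prevalence must be in (0, 1)")
  f <- function(b0) mean(plogis(b0 + eta)) - prevalence
  if (f(lo) > 0 || f(hi) < 0) stop("target prevalence unreachable for this signal")
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) < 0) lo <- mid else hi <- mid
    if (hi - lo < 1e-12) break
  }
  (lo + hi) / 2
}

#' Simulate expression and labels from the edge-interaction logistic model
#'
#' Draws i.i.d. Gaussian expression (identity covariance, or the
#' network-smoothed covariance obtained by rescaling `(I + tau L)^-1` to
#' unit diagonal, with L the graph Laplacian), plants `n_informative`
#' informative edges with coefficients `+-effect` (random signs), calibrates
#' the intercept by bisection so the mean class-1 probability matches
#' `prevalence`, and draws labels Bernoulli from the logistic model on the
#' planted edge products. Planted edges are sampled uniformly, or with
#' probability proportional to line-graph degree when `bias_high_degree`.
#'
#' @param net a `ppi_network` whose nodes are the genes
#' @param n number of samples (default 300)
#' @param n_informative number of planted edges (default 10)
#' @param effect absolute effect size per planted edge (default 1.5)
#' @param prevalence target class-1 fraction (default 0.5)
#' @param correlated use the network-smoothed covariance
#' @param tau smoothing strength for the correlated option (default 1)
#' @param bias_high_degree plant edges preferentially on high line-graph
#'   degrees
#' @param seed RNG seed
#' @return object of class `synthetic_dataset`: `ds` (an `expr_dataset`),
#'   `net`, `planted` (data.frame `id`, `beta`), `beta0_true`, `eta_true`
#'   (the generative linear predictor per sample), and `config`.
#' @export
simulate_dataset <- function(net, n = 300L, n_informative = 10L, effect = 1.5,
                             prevalence = 0.5, correlated = FALSE, tau = 1,
                             bias_high_degree = FALSE, seed = NULL) {
  M <- n_edges(net)
  if (n_informative > M) stop("cannot plant more informative edges than network edges")
  p <- length(net$nodes)
  with_seed(seed, {
    if (correlated) {
      A <- matrix(0, p, p, dimnames = list(net$nodes, net$nodes))
      for (i in seq_len(M)) {
        A[net$edges$a[i], net$edges$b[i]] <- net$edges$weight[i]
        A[net$edges$b[i], net$edges$a[i]] <- net$edges$weight[i]
      }
      L <- diag(rowSums(A)) - A
      S <- solve(diag(p) + tau * L)
      D <- 1 / sqrt(diag(S))
      S <- S * tcrossprod(D)          # unit-diagonal rescaling
      X <- matrix(rnorm(n * p), n, p) %*% chol(S)
    } else {
      X <- matrix(rnorm(n * p), n, p)
    }
    dimnames(X) <- list(sprintf("s%04d", seq_len(n)), net$nodes)

    prob <- if (bias_high_degree) {
      d <- line_graph(net)$degree
      d + max(d) * 1e-6                # keep isolated edges samplable
    } else rep(1, M)
    planted_idx <- sort(sample(M, n_informative, prob = prob))
    signs <- sample(c(-1, 1), n_informative, replace = TRUE)
    beta_star <- effect * signs

    prods <- X[, net$edges$a[planted_idx], drop = FALSE] *
      X[, net$edges$b[planted_idx], drop = FALSE]
    eta <- as.vector(prods %*% beta_star)
    beta0 <- calibrate_intercept(eta, prevalence)
    y <- rbinom(n, 1L, plogis(beta0 + eta))
    names(y) <- rownames(X)

    structure(list(ds = expr_dataset(X, y), net = net,
                   planted = data.frame(id = net$edges$id[planted_idx],
                                        beta = beta_star,
                                        stringsAsFactors = FALSE),
                   beta0_true = beta0, eta_true = beta0 + eta,
                   config = list(p = p, n = n, n_informative = n_informative,
                                 effect = effect, prevalence = prevalence,
                                 correlated = correlated, tau = tau,
                                 bias_high_degree = bias_high_degree,
                                 seed = seed)),
              class = "synthetic_dataset")
  })
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf("synthetic_dataset: %d samples, %d genes, %d edges (%d planted), prevalence %.2f\n",
              length(x$ds$y), ncol(x$ds$x), n_edges(x$net),
              nrow(x$planted), mean(x$ds$y)))
  invisible(x)
}

#' Precision and recall of planted edges in a ranking
#'
#' @param ranking an edge-level `gene_ranking`
#' @param planted character vector of planted edge ids (or the `planted`
#'   data.frame of a `synthetic_dataset`)
#' @param k ranking depth (>= 1)
#' @return list with `precision` (`|top-k n planted| / k`) and `recall`
#'   (`|top-k n planted| / |planted|`)
#' @export
recovery_metrics <- function(ranking, planted, k) {
  stopifnot(k >= 1L)
  if (is.data.frame(planted)) planted <- planted$id
  topk <- top_ranked(ranking, k)
  hits <- length(intersect(topk, planted))
  list(precision = hits / k, recall = hits / length(planted))
}

#' Write a synthetic dataset bundle to disk
#'
#' Emits the same plain-text formats the loaders read: `expression.tsv`
#' (genes x samples), `labels.tsv`, `network.tsv`, plus `truth.json`
#' (planted edges, coefficients, intercept, generator config).
#'
#' @param sim a `synthetic_dataset`
#' @param dir output directory (created if needed)
#' @return invisibly, the written file names
#' @export
write_dataset <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ex <- file.path(dir, "expression.tsv")
  lb <- file.path(dir, "labels.tsv")
  nw <- file.path(dir, "network.tsv")
  tr <- file.path(dir, "truth.json")
  em <- t(sim$ds$x)  # genes-in-rows, GEO style
  write.table(data.frame(gene = rownames(em), em, check.names = FALSE),
              ex, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(sample = names(sim$ds$y), label = unname(sim$ds$y)),
              lb, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  write.table(sim$net$edges[, c("a", "b", "weight")], nw, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(list(planted = sim$planted, beta0_true = sim$beta0_true,
                            config = sim$config),
                       tr, auto_unbox = TRUE, digits = NA)
  invisible(c(ex, lb, nw, tr))
}
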