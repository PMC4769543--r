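#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUC; tied scores contribute one half.
#'
#' @param scores numeric prediction scores
#' @param labels 0/1 class labels
#' @return AUC in \[0, 1\]
#' @examples
#' auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))  # 1
#' @export
auc <- function(scores, labels) {
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels), all(labels %in% c(0L, 1L)))
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) stop("both classes are required to compute AUC")
  r <- rank(scores)  # average ranks handle ties
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Genes spanned by a set of edges
#'
#' Union of edge endpoints, each gene counted once — the transfer from a
#' selected interaction set to the gene set used by the stability metrics.
#'
#' @param edges character vector of `"A|B"` edge ids, or a data.frame with
#'   columns `a` and `b`
#' @return sorted character vector of gene identifiers
#' @export
edges_to_genes <- function(edges) {
  if (is.data.frame(edges)) return(sort(unique(c(edges$a, edges$b))))
  edges <- as.character(edges)
  if (!length(edges)) return(character(0))
  sort(unique(unlist(strsplit(edges, "|", fixed = TRUE))))
}

#' Jaccard coefficient of two gene sets
#'
#' `|G1 n G2| / |G1 u G2|`. Two empty selections are defined as identical
#' (coefficient 1); this case is reported via message.
#'
#' @param g1,g2 character vectors
#' @return value in \[0, 1\]
#' @export
jaccard <- function(g1, g2) {
  g1 <- unique(as.character(g1)); g2 <- unique(as.character(g2))
  if (!length(g1) && !length(g2)) {
    message("jaccard: both selections empty; returning 1")
    return(1)
  }
  length(intersect(g1, g2)) / length(union(g1, g2))
}

#' Keep a subset of samples
#' @param ds an `expr_dataset`
#' @param idx integer or logical sample index
#' @return an `expr_dataset`
#' @export
subset_samples <- function(ds, idx) {
  structure(list(x = ds$x[idx, , drop = FALSE], y = ds$y[idx]),
            class = "expr_dataset")
}

# Stratified fold assignment: within each class, samples are shuffled and
# dealt round-robin, so every fold holds >= 1 member of each class whenever
# the class counts allow it.
make_folds <- function(y, k, seed = NULL) {
  with_seed(seed, {
    fold <- integer(length(y))
    start <- 0L
    for (cls in sort(unique(y))) {
      idx <- sample(which(y == cls))
      fold[idx] <- ((start + seq_along(idx) - 1L) %% k) + 1L
      start <- start + length(idx)
    }
    fold
  })
}

#' Cross-validated choice of the penalty level
#'
#' Stratified k-fold cross-validation for lambda at fixed alpha and r. On
#' each training fold the feature standardization and the lambda grid are
#' recomputed from that fold alone; fold paths are aligned by grid index,
#' the index with the largest mean held-out AUC wins, and ties go to the
#' largest lambda (the sparser model). When the smaller class has fewer
#' members than folds, held-out scores are pooled across folds before a
#' single AUC is taken per index. The reported `lambda_opt` is the chosen
#' index on the full-data grid, and the selected edge set is the active set
#' of the full-data path at that index.
#'
#' @param ds an `expr_dataset` (intersected with `net`)
#' @param net a `ppi_network`
#' @param alpha elastic-net mixing parameter (default 0.3)
#' @param r degree exponent for the adaptive weights (default 0, plain
#'   elastic net)
#' @param weights optional precomputed `penalty_weights` (overrides `r`)
#' @param lg optional precomputed `line_graph` (avoids recomputation in
#'   resampling loops)
#' @param level `"edge"` or `"gene"` feature map
#' @param k number of folds (default 10)
#' @param nlambda,lambda_min_ratio path geometry
#' @param pre_z z-score genes before products
#' @param seed RNG seed for the fold assignment
#' @return object of class `cv_aen`: `lambda` (full-data grid), `cvm` (mean
#'   held-out AUC per index), `index_opt`, `lambda_opt`, `auc`
#'   (`cvm[index_opt]`), `folds`, `fit` (full-data `aen_path`),
#'   `selected_edges`, `selected_genes`, `r`, `alpha`.
#' @export
cv_lambda <- function(ds, net, alpha = 0.3, r = 0, weights = NULL, lg = NULL,
                      level = c("edge", "gene"), k = 10L, nlambda = 100L,
                      lambda_min_ratio = 0.01, pre_z = FALSE, seed = NULL) {
  level <- match.arg(level)
  y <- ds$y
  if (length(unique(y)) < 2L) stop("both classes must be present")
  if (is.null(weights)) {
    weights <- if (level == "edge") {
      adaptive_weights(lg %||% line_graph(net), r)
    } else {
      adaptive_weights(net, r)
    }
  }
  fold <- make_folds(y, k, seed)
  if (any(tabulate(fold, k) == 0L)) stop("fold assignment infeasible: too few samples")

  ef_full <- edge_features(ds, net, pre_z = pre_z, level = level)
  fit_full <- aen_path(ef_full, alpha = alpha, weights = weights,
                       nlambda = nlambda, lambda_min_ratio = lambda_min_ratio)

  pooled <- min(table(y)) < k
  aucs <- matrix(NA_real_, nlambda, k)
  pooled_scores <- vector("list", k)
  for (f in seq_len(k)) {
    tr <- fold != f; te <- !tr
    if (length(unique(y[tr])) < 2L) stop("training fold lost a class; reduce k")
    ef_tr <- edge_features(subset_samples(ds, tr), net, pre_z = pre_z, level = level)
    p_tr <- aen_path(ef_tr, alpha = alpha, weights = weights,
                     nlambda = nlambda, lambda_min_ratio = lambda_min_ratio)
    xte <- apply_feature_record(ef_tr, subset_samples(ds, te))
    eta <- sweep(xte %*% p_tr$beta, 2L, p_tr$beta0, "+")
    if (pooled) {
      pooled_scores[[f]] <- list(eta = eta, y = y[te])
    } else {
      aucs[, f] <- vapply(seq_len(nlambda), function(j) auc(eta[, j], y[te]),
                          numeric(1))
    }
  }
  if (pooled) {
    all_y <- unlist(lapply(pooled_scores, `[[`, "y"))
    cvm <- vapply(seq_len(nlambda), function(j) {
      auc(unlist(lapply(pooled_scores, function(s) s$eta[, j])), all_y)
    }, numeric(1))
    cvsd <- rep(NA_real_, nlambda)
  } else {
    cvm <- rowMeans(aucs)
    cvsd <- apply(aucs, 1L, sd)
  }
  index_opt <- which(cvm >= max(cvm) - 1e-12)[1L]  # tie -> largest lambda
  sel_edges <- rownames(fit_full$beta)[fit_full$beta[, index_opt] != 0]
  sel_genes <- if (level == "edge") edges_to_genes(sel_edges) else sort(sel_edges)
  structure(list(lambda = fit_full$lambda, cvm = cvm, cvsd = cvsd,
                 index_opt = index_opt, lambda_opt = fit_full$lambda[index_opt],
                 auc = cvm[index_opt], folds = fold, fit = fit_full,
                 selected_edges = sel_edges, selected_genes = sel_genes,
                 r = r, alpha = alpha, level = level, pooled = pooled),
            class = "cv_aen")
}

#' @export
print.cv_aen <- function(x, ...) {
  cat(sprintf("cv_aen: lambda_opt = %.4g (index %d), CV AUC = %.3f, %d edges selected\n",
              x$lambda_opt, x$index_opt, x$auc, length(x$selected_edges)))
  invisible(x)
}

#' Grid search over the degree exponent and the penalty level
#'
#' Runs [cv_lambda()] for every value of `r_grid` on a shared fold
#' assignment and picks the pair (lambda, r) with the largest mean held-out
#' AUC. Ties are broken first by the largest r, then by the largest lambda.
#'
#' @inheritParams cv_lambda
#' @param r_grid candidate degree exponents (default the eight-point grid
#'   0.001-0.8)
#' @return a `cv_aen` for the winning r, with extra fields `r_grid`,
#'   `auc_by_r` (best CV AUC per r) and `surface` (nlambda x |r_grid| AUC
#'   matrix).
#' @export
grid_search_r <- function(ds, net, alpha = 0.3,
                          r_grid = c(0.001, 0.01, 0.05, 0.1, 0.2, 0.4, 0.6, 0.8),
                          lg = NULL, level = c("edge", "gene"), k = 10L,
                          nlambda = 100L, lambda_min_ratio = 0.01,
                          pre_z = FALSE, seed = NULL) {
  level <- match.arg(level)
  if (level == "edge" && is.null(lg)) lg <- line_graph(net)
  cvs <- vector("list", length(r_grid))
  for (i in seq_along(r_grid)) {
    w <- if (level == "edge") adaptive_weights(lg, r_grid[i]) else adaptive_weights(net, r_grid[i])
    cvs[[i]] <- cv_lambda(ds, net, alpha = alpha, r = r_grid[i], weights = w,
                          lg = lg, level = level, k = k, nlambda = nlambda,
                          lambda_min_ratio = lambda_min_ratio, pre_z = pre_z,
                          seed = seed)
  }
  best_auc <- vapply(cvs, `[[`, numeric(1), "auc")
  cand <- which(best_auc >= max(best_auc) - 1e-12)
  winner <- cand[which.max(r_grid[cand])]  # tie on AUC -> largest r
  out <- cvs[[winner]]
  out$r_grid <- r_grid
  out$auc_by_r <- best_auc
  out$surface <- vapply(cvs, `[[`, numeric(nlambda), "cvm")
  out
}

#' Repeated k-fold cross-validation of predictive performance
#'
#' The outer protocol: `repeats` independent stratified k-fold partitions;
#' on each training portion an inner k-fold [cv_lambda()] picks lambda, the
#' training-portion model at that index is applied to the held-out fold, and
#' the fold AUCs of one partition are averaged. The reported summary is the
#' median over the repeats.
#'
#' @inheritParams cv_lambda
#' @param repeats number of outer partitions (default 10)
#' @param inner_k inner folds for the lambda choice (default `k`)
#' @return list with `median_auc`, `repeat_auc` (one value per repeat) and
#'   `fold_auc` (repeats x k matrix)
#' @export
repeated_cv_auc <- function(ds, net, alpha = 0.3, r = 0, weights = NULL,
                            lg = NULL, level = c("edge", "gene"), k = 10L,
                            repeats = 10L, inner_k = k, nlambda = 100L,
                            lambda_min_ratio = 0.01, seed = NULL) {
  level <- match.arg(level)
  if (level == "edge" && is.null(lg)) lg <- line_graph(net)
  if (is.null(weights)) {
    weights <- if (level == "edge") adaptive_weights(lg, r) else adaptive_weights(net, r)
  }
  sub_seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1L, repeats * 2L))
  fold_auc <- matrix(NA_real_, repeats, k)
  for (t in seq_len(repeats)) {
    fold <- make_folds(ds$y, k, sub_seeds[t])
    for (f in seq_len(k)) {
      tr <- fold != f
      ds_tr <- subset_samples(ds, tr)
      cv <- cv_lambda(ds_tr, net, alpha = alpha, r = r, weights = weights,
                      lg = lg, level = level, k = inner_k, nlambda = nlambda,
                      lambda_min_ratio = lambda_min_ratio,
                      seed = sub_seeds[repeats + t])
      xte <- apply_feature_record(cv$fit$features, subset_samples(ds, !tr))
      eta <- as.vector(cv$fit$beta0[cv$index_opt] +
                         xte %*% cv$fit$beta[, cv$index_opt])
      fold_auc[t, f] <- auc(eta, ds$y[!tr])
    }
  }
  repeat_auc <- rowMeans(fold_auc)
  list(median_auc = median(repeat_auc), repeat_auc = repeat_auc,
       fold_auc = fold_auc)
}

#' Held-out AUC of the cross-validation-selected model
#'
#' One outer train/test split (stratified, 90/10 by default): an inner
#' k-fold [cv_lambda()] on the training portion chooses lambda, and the
#' training-portion model at that index is scored on the untouched test
#' portion. Unlike the in-CV estimate `cv$auc`, this is free of the
#' optimism from picking the best point of a noisy AUC curve.
#'
#' @inheritParams cv_lambda
#' @param test_frac held-out fraction (default 0.1)
#' @return list with `auc` (test AUC), `cv` (the inner `cv_aen`) and
#'   `test_idx`
#' @export
holdout_cv_auc <- function(ds, net, alpha = 0.3, r = 0, weights = NULL,
                           lg = NULL, level = c("edge", "gene"), k = 10L,
                           nlambda = 100L, lambda_min_ratio = 0.01,
                           test_frac = 0.1, seed = NULL) {
  level <- match.arg(level)
  kk <- max(2L, round(1 / test_frac))
  seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1L, 2L))
  fold <- make_folds(ds$y, kk, seeds[1L])
  te <- fold == 1L
  cv <- cv_lambda(subset_samples(ds, !te), net, alpha = alpha, r = r,
                  weights = weights, lg = lg, level = level, k = k,
                  nlambda = nlambda, lambda_min_ratio = lambda_min_ratio,
                  seed = seeds[2L])
  xte <- apply_feature_record(cv$fit$features, subset_samples(ds, te))
  eta <- as.vector(cv$fit$beta0[cv$index_opt] + xte %*% cv$fit$beta[, cv$index_opt])
  list(auc = auc(eta, ds$y[te]), cv = cv, test_idx = which(te))
}

#' Rank features by how often the path selects them
#'
#' Counts, for every edge (or gene), the number of lambda grid points at
#' which its coefficient is nonzero. At gene level a gene inherits the
#' largest count among its incident edges. Ties are broken by the larger
#' maximum absolute coefficient along the path, then lexicographically.
#'
#' @param path an `aen_path`
#' @param level `"edge"` or `"gene"`
#' @return data.frame of class `gene_ranking` with columns `id`, `count`,
#'   `max_abs_beta`, ordered by the ranking
#' @export
rank_by_selection <- function(path, level = c("edge", "gene")) {
  level <- match.arg(level)
  counts <- path$selection_count
  max_abs <- apply(abs(path$beta), 1L, max)
  if (level == "gene") {
    if (is.null(path$features)) stop("path carries no edge table; gene-level ranking unavailable")
    ed <- path$features$edges
    if (path$features$level == "gene") {
      df <- data.frame(id = ed$id, count = unname(counts),
                       max_abs_beta = unname(max_abs), stringsAsFactors = FALSE)
    } else {
      genes <- sort(unique(c(ed$a, ed$b)))
      cnt <- vapply(genes, function(g) {
        inc <- ed$a == g | ed$b == g
        max(counts[inc])
      }, numeric(1))
      mab <- vapply(genes, function(g) {
        inc <- ed$a == g | ed$b == g
        max(max_abs[inc])
      }, numeric(1))
      df <- data.frame(id = genes, count = unname(cnt),
                       max_abs_beta = unname(mab), stringsAsFactors = FALSE)
    }
  } else {
    df <- data.frame(id = names(counts), count = unname(counts),
                     max_abs_beta = unname(max_abs), stringsAsFactors = FALSE)
  }
  df <- df[order(-df$count, -df$max_abs_beta, df$id), ]
  rownames(df) <- NULL
  class(df) <- c("gene_ranking", "data.frame")
  attr(df, "level") <- level
  df
}

# Top-k identifiers with a positive selection count.
top_ranked <- function(ranking, k) {
  pos <- ranking$id[ranking$count > 0]
  head(pos, k)
}

stability_report <- function(setting, values) {
  structure(list(setting = setting, repeats = length(values), values = values,
                 median = median(values),
                 iqr = unname(diff(quantile(values, c(0.25, 0.75))))),
            class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  cat(sprintf("stability_report (%s): median = %.3f over %d repeats (IQR %.3f)\n",
              x$setting, x$median, x$repeats, x$iqr))
  invisible(x)
}

# Default gene selector for the perturbation protocols: cross-validate
# lambda on the subset and transfer the selected edges to genes.
cv_gene_selector <- function(net, alpha, r, weights, lg, level, k, nlambda,
                             lambda_min_ratio) {
  function(ds_sub, seed = NULL) {
    cv <- cv_lambda(ds_sub, net, alpha = alpha, r = r, weights = weights,
                    lg = lg, level = level, k = k, nlambda = nlambda,
                    lambda_min_ratio = lambda_min_ratio, seed = seed)
    cv$selected_genes
  }
}

#' Gene-selection stability under soft sample perturbation
#'
#' Each repeat draws two training sets of size `ceiling(frac * n)` sharing a
#' common core of `ceiling(overlap * s)` samples, with disjoint remainders;
#' the selector (by default cross-validated edge selection transferred to
#' genes) runs on both and the Jaccard coefficient of the two gene sets is
#' recorded. The summary is the median over repeats.
#'
#' @inheritParams cv_lambda
#' @param repeats number of sampled pairs (default 20)
#' @param frac training-set size as a fraction of n (default 0.8; the
#'   construction requires `frac <= 1 / (2 - overlap)`, so 5/6 is the
#'   ceiling at the default overlap)
#' @param overlap shared-core fraction of the training-set size (default 0.8)
#' @param selector optional function(ds_sub, seed) returning a character
#'   vector of genes; overrides the default CV-based selector
#' @return a `stability_report` with setting `"soft"`
#' @export
soft_perturbation_stability <- function(ds, net, alpha = 0.3, r = 0,
                                        weights = NULL, lg = NULL,
                                        level = c("edge", "gene"),
                                        repeats = 20L, frac = 0.8, overlap = 0.8,
                                        k = 10L, nlambda = 100L,
                                        lambda_min_ratio = 0.01, seed = NULL,
                                        selector = NULL) {
  level <- match.arg(level)
  n <- length(ds$y)
  s <- ceiling(frac * n)
  core <- ceiling(overlap * s)
  if (2L * (s - core) > n - core) {
    stop(sprintf("soft-perturbation construction infeasible for n = %d: need 2*(s - core) <= n - core; use a smaller training fraction", n))
  }
  if (is.null(selector)) {
    if (level == "edge" && is.null(lg)) lg <- line_graph(net)
    if (is.null(weights)) {
      weights <- if (level == "edge") adaptive_weights(lg, r) else adaptive_weights(net, r)
    }
    selector <- cv_gene_selector(net, alpha, r, weights, lg, level, k,
                                 nlambda, lambda_min_ratio)
  }
  sub_seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1L, repeats * 3L))
  values <- numeric(repeats)
  for (t in seq_len(repeats)) {
    pair <- with_seed(sub_seeds[t], {
      core_idx <- sample(n, core)
      rest <- setdiff(seq_len(n), core_idx)
      extra <- sample(rest, 2L * (s - core))
      list(i1 = c(core_idx, extra[seq_len(s - core)]),
           i2 = c(core_idx, extra[seq(s - core + 1L, 2L * (s - core))]))
    })
    g1 <- selector(subset_samples(ds, pair$i1), sub_seeds[repeats + t])
    g2 <- selector(subset_samples(ds, pair$i2), sub_seeds[2L * repeats + t])
    values[t] <- jaccard(g1, g2)
  }
  stability_report("soft", values)
}

#' Gene-selection stability under hard sample perturbation
#'
#' Each repeat splits the samples into two disjoint stratified halves and
#' compares the gene sets the selector picks on each, by Jaccard
#' coefficient; the summary is the median over repeats.
#'
#' @inheritParams soft_perturbation_stability
#' @return a `stability_report` with setting `"hard"`
#' @export
hard_perturbation_stability <- function(ds, net, alpha = 0.3, r = 0,
                                        weights = NULL, lg = NULL,
                                        level = c("edge", "gene"),
                                        repeats = 20L, k = 10L, nlambda = 100L,
                                        lambda_min_ratio = 0.01, seed = NULL,
                                        selector = NULL) {
  level <- match.arg(level)
  y <- ds$y
  if (length(y) < 4L || any(table(y) < 2L)) {
    stop("hard-perturbation split infeasible: need >= 2 samples per class")
  }
  if (is.null(selector)) {
    if (level == "edge" && is.null(lg)) lg <- line_graph(net)
    if (is.null(weights)) {
      weights <- if (level == "edge") adaptive_weights(lg, r) else adaptive_weights(net, r)
    }
    selector <- cv_gene_selector(net, alpha, r, weights, lg, level, k,
                                 nlambda, lambda_min_ratio)
  }
  sub_seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1L, repeats * 3L))
  values <- numeric(repeats)
  for (t in seq_len(repeats)) {
    halves <- with_seed(sub_seeds[t], {
      i1 <- integer(); i2 <- integer()
      for (cls in unique(y)) {
        idx <- sample(which(y == cls))
        h <- floor(length(idx) / 2)
        i1 <- c(i1, idx[seq_len(h)])
        i2 <- c(i2, idx[seq(h + 1L, 2L * h)])
      }
      list(i1 = i1, i2 = i2)
    })
    g1 <- selector(subset_samples(ds, halves$i1), sub_seeds[repeats + t])
    g2 <- selector(subset_samples(ds, halves$i2), sub_seeds[2L * repeats + t])
    values[t] <- jaccard(g1, g2)
  }
  stability_report("hard", values)
}

#' Between-dataset stability of top-ranked genes
#'
#' For every pair of rankings, the fraction of shared identifiers among the
#' top k (by selection count); the summary is the median over pairs.
#'
#' @param rankings list of at least two `gene_ranking` objects
#' @param k number of top genes compared (default 100)
#' @return a `stability_report` with setting `"between"`
#' @export
between_dataset_stability <- function(rankings, k = 100L) {
  if (length(rankings) < 2L) stop("need at least two rankings")
  pairs <- utils::combn(length(rankings), 2L)
  values <- apply(pairs, 2L, function(pr) {
    t1 <- top_ranked(rankings[[pr[1L]]], k)
    t2 <- top_ranked(rankings[[pr[2L]]], k)
    length(intersect(t1, t2)) / k
  })
  stability_report("between", as.numeric(values))
}

#' Write a stability report as JSON and TSV
#' @param report a `stability_report`
#' @param prefix output path prefix
#' @return invisibly, the written file names
#' @export
write_stability_report <- function(report, prefix) {
  jf <- paste0(prefix, "_stability.json")
  tf <- paste0(prefix, "_stability.tsv")
  jsonlite::write_json(list(setting = report$setting, repeats = report$repeats,
                            median = report$median, iqr = report$iqr,
                            values = report$values),
                       jf, auto_unbox = TRUE, digits = NA)
  write.table(data.frame(repeat_index = seq_along(report$values),
                         value = report$values),
              tf, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(jf, tf))
}
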