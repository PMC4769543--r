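#' Construct an expression dataset with binary labels
#'
#' @param values numeric matrix, samples in rows and genes in columns, with
#'   sample and gene identifiers as dimnames
#' @param labels 0/1 vector (or named vector matched to rownames)
#' @return object of class `expr_dataset` with elements `x` (n x p matrix)
#'   and `y` (named 0/1 integer vector)
#' @export
expr_dataset <- function(values, labels) {
  values <- as.matrix(values)
  if (is.null(rownames(values))) rownames(values) <- paste0("s", seq_len(nrow(values)))
  if (is.null(colnames(values))) stop("expression matrix needs gene names")
  if (anyDuplicated(colnames(values))) stop("duplicate gene identifiers")
  if (anyNA(values)) stop("missing values in expression matrix")
  if (!is.null(names(labels))) {
    common <- intersect(rownames(values), names(labels))
    if (!length(common)) stop("no overlap between labelled samples and expression samples")
    if (length(common) < nrow(values)) {
      warning(sprintf("dropping %d unlabelled sample(s)", nrow(values) - length(common)))
      values <- values[common, , drop = FALSE]
    }
    labels <- labels[rownames(values)]
  }
  if (length(labels) != nrow(values)) stop("label length does not match sample count")
  y <- as.integer(labels)
  if (anyNA(y) || !all(y %in% c(0L, 1L))) stop("labels must be 0/1")
  names(y) <- rownames(values)
  structure(list(x = values, y = y), class = "expr_dataset")
}

#' @export
print.expr_dataset <- function(x, ...) {
  cat(sprintf("expr_dataset: %d samples x %d genes (%d cases / %d controls)\n",
              nrow(x$x), ncol(x$x), sum(x$y == 1L), sum(x$y == 0L)))
  invisible(x)
}

#' Read expression values and sample labels from delimited text
#'
#' The matrix file has a header of sample (or gene) names and an identifier
#' first column; GEO-style genes-in-rows layout is the default and is
#' transposed to the internal samples-by-genes convention. Rows mapping to a
#' duplicated gene identifier are averaged when `aggregate_duplicates` is
#' set. The label file has two columns, sample identifier and 0/1 class;
#' samples missing from it are dropped with a warning.
#'
#' @param matrix_path delimited expression file (TSV or CSV by extension)
#' @param labels_path two-column label file
#' @param genes_in_rows is the matrix genes x samples? (default TRUE)
#' @param aggregate_duplicates average rows sharing a gene identifier
#' @return an [expr_dataset()]
#' @export
read_expression <- function(matrix_path, labels_path, genes_in_rows = TRUE,
                            aggregate_duplicates = TRUE) {
  sep <- if (grepl("\\.csv$", matrix_path, ignore.case = TRUE)) "," else ""
  tab <- read.table(matrix_path, header = TRUE, sep = sep, check.names = FALSE,
                    stringsAsFactors = FALSE, comment.char = "#")
  ids <- as.character(tab[[1L]])
  m <- as.matrix(tab[, -1L, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(!vapply(as.data.frame(m), is.numeric, logical(1)))[1L]
    badrow <- which(is.na(suppressWarnings(as.numeric(m[, bad]))))[1L]
    stop(sprintf("non-numeric value at row %d, column '%s' of %s",
                 badrow, colnames(m)[bad], matrix_path))
  }
  rownames(m) <- ids
  if (anyDuplicated(ids)) {
    if (!aggregate_duplicates) stop("duplicate identifiers in ", matrix_path)
    counts <- table(ids)
    m <- rowsum(m, group = ids) / as.vector(counts[sort(unique(ids))])
  }
  if (genes_in_rows) m <- t(m)

  lab <- read.table(labels_path, header = FALSE, stringsAsFactors = FALSE,
                    comment.char = "#")
  if (nrow(lab) && (lab[1, 1] %in% c("sample", "sample_id")
                    || is.na(suppressWarnings(as.numeric(lab[1, 2]))))) {
    lab <- lab[-1L, , drop = FALSE]  # tolerate a header row
  }
  labels <- stats::setNames(as.integer(lab[[2L]]), as.character(lab[[1L]]))
  expr_dataset(m, labels)
}

#' Restrict an expression dataset and a network to their common genes
#'
#' Genes absent from either source are dropped, as are network edges losing
#' an endpoint. Counts are reported via message.
#'
#' @param ds an `expr_dataset`
#' @param net a `ppi_network`
#' @param keep_unused keep expression genes not present in the network
#' @return list with elements `ds` and `net`, both restricted
#' @export
intersect_network <- function(ds, net, keep_unused = FALSE) {
  common <- intersect(colnames(ds$x), net$nodes)
  if (!length(common)) stop("no genes shared between expression data and network")
  keep <- net$edges$a %in% common & net$edges$b %in% common
  if (!any(keep)) stop("no network edge has both endpoints in the expression data")
  net2 <- ppi_network(net$edges[keep, c("a", "b", "weight")])
  genes <- if (keep_unused) colnames(ds$x) else intersect(colnames(ds$x), net2$nodes)
  ds2 <- ds
  ds2$x <- ds$x[, genes, drop = FALSE]
  message(sprintf("intersection: %d genes, %d edges retained (from %d genes, %d edges)",
                  ncol(ds2$x), n_edges(net2), ncol(ds$x), n_edges(net)))
  list(ds = ds2, net = net2)
}

# Raw n x M product matrix over the network edges (no standardization).
raw_edge_products <- function(x, edges) {
  xm <- x[, edges$a, drop = FALSE] * x[, edges$b, drop = FALSE]
  colnames(xm) <- edges$id
  xm
}

# Center/scale columns to mean 0, population variance 1; zero-variance
# columns are left centered only and flagged.
standardize_cols <- function(xm) {
  n <- nrow(xm)
  ctr <- colMeans(xm)
  xc <- sweep(xm, 2L, ctr)
  scl <- sqrt(colSums(xc^2) / n)
  zero <- scl < 1e-12
  scl[zero] <- 1
  list(x = sweep(xc, 2L, scl, "/"), center = ctr, scale = scl, zero_var = zero)
}

#' Build the edge-product design matrix
#'
#' Maps expression onto network edges: column m for edge (j, k) holds the
#' per-sample product `x_ij * x_ik`. Columns follow the network's canonical
#' edge order. With `pre_z` the per-gene values are z-scored before taking
#' products (a documented variant; the default multiplies values as given).
#' With `standardize` (the default, matching the convention of penalized
#' GLM solvers) each product column is then centered and scaled to unit
#' population variance; zero-variance columns are flagged and excluded from
#' penalized fitting. `level = "gene"` instead returns the identity feature
#' map (columns are the genes themselves), the degenerate configuration
#' under which the solver fits ordinary gene-level models.
#'
#' @param ds an `expr_dataset` (already intersected with `net`)
#' @param net a `ppi_network`
#' @param standardize center/scale feature columns
#' @param pre_z z-score genes before taking products
#' @param level `"edge"` (products over network edges) or `"gene"`
#' @return object of class `edge_features`: `x` (n x M matrix), `edges`
#'   (edge table, or gene ids for gene level), `center`, `scale`,
#'   `zero_var`, plus the options used.
#' @export
edge_features <- function(ds, net, standardize = TRUE, pre_z = FALSE,
                          level = c("edge", "gene")) {
  level <- match.arg(level)
  x <- ds$x
  gene_center <- NULL; gene_scale <- NULL
  if (pre_z) {
    gs <- standardize_cols(x)
    x <- gs$x; gene_center <- gs$center; gene_scale <- gs$scale
  }
  if (level == "edge") {
    miss <- setdiff(unique(c(net$edges$a, net$edges$b)), colnames(x))
    if (length(miss)) stop("network genes absent from expression data: run intersect_network first")
    xm <- raw_edge_products(x, net$edges)
    edges <- net$edges
  } else {
    xm <- x
    edges <- data.frame(a = colnames(x), b = colnames(x), weight = 1,
                        id = colnames(x), stringsAsFactors = FALSE)
  }
  if (standardize) {
    st <- standardize_cols(xm)
  } else {
    st <- list(x = xm, center = rep(0, ncol(xm)), scale = rep(1, ncol(xm)),
               zero_var = apply(xm, 2L, function(v) var(v) * (nrow(xm) - 1) / nrow(xm)) < 1e-24)
    names(st$center) <- names(st$scale) <- colnames(xm)
  }
  structure(list(x = st$x, edges = edges, y = ds$y,
                 center = st$center, scale = st$scale, zero_var = st$zero_var,
                 standardize = standardize, pre_z = pre_z, level = level,
                 gene_center = gene_center, gene_scale = gene_scale),
            class = "edge_features")
}

#' @export
print.edge_features <- function(x, ...) {
  cat(sprintf("edge_features (%s level): %d samples x %d features (%d zero-variance)\n",
              x$level, nrow(x$x), ncol(x$x), sum(x$zero_var)))
  invisible(x)
}

# Apply a fitted feature record (pre-z, products, standardization) to new
# raw expression; used for held-out folds.
apply_feature_record <- function(ef, ds) {
  x <- ds$x
  if (ef$pre_z) x <- sweep(sweep(x, 2L, ef$gene_center), 2L, ef$gene_scale, "/")
  xm <- if (ef$level == "edge") raw_edge_products(x, ef$edges) else x[, ef$edges$id, drop = FALSE]
  sweep(sweep(xm, 2L, ef$center), 2L, ef$scale, "/")
}

#' Export an edge-feature matrix as TSV
#' @param ef an `edge_features` object
#' @param path output file
#' @return invisibly, the path
#' @export
write_edge_features <- function(ef, path) {
  out <- data.frame(sample = rownames(ef$x), ef$x, check.names = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
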