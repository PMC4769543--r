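#' Construct an undirected interaction network
#'
#' Builds the network container used throughout the package from an edge
#' table. Gene identifiers are opaque, case-sensitive strings. Self loops are
#' dropped, duplicate unordered pairs are collapsed (the first weight wins),
#' and missing weights default to 1. Edges are stored canonically with the
#' lexicographically smaller endpoint first, sorted by (a, b), so that edge
#' ordering — and hence feature-column ordering downstream — is stable across
#' runs and input permutations.
#'
#' @param edges data.frame (or matrix) whose first two columns are gene
#'   identifiers; an optional third column gives positive edge weights.
#' @param nodes optional character vector of additional (possibly isolated)
#'   nodes to carry along.
#' @return An object of class `ppi_network` with elements `nodes` (sorted
#'   character vector), `edges` (data.frame with columns `a`, `b`, `weight`,
#'   `id`), and `adj` (named adjacency list of neighbor identifiers).
#' @examples
#' net <- ppi_network(data.frame(a = c("A", "B"), b = c("B", "C")))
#' net$edges$id
#' @export
ppi_network <- function(edges, nodes = NULL) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (ncol(edges) < 2L) stop("edge table needs at least two columns")
  a <- as.character(edges[[1L]])
  b <- as.character(edges[[2L]])
  if (any(!nzchar(a)) || any(!nzchar(b))) stop("empty gene identifier in edge table")
  w <- if (ncol(edges) >= 3L) as.numeric(edges[[3L]]) else rep(1, length(a))
  w[is.na(w)] <- 1
  if (any(w <= 0)) stop("edge weights must be positive")

  keep <- a != b                       # self loops removed
  a <- a[keep]; b <- b[keep]; w <- w[keep]
  swap <- a > b
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  key <- paste(a, b, sep = "|")
  first <- !duplicated(key)            # keep first weight for duplicates
  a <- a[first]; b <- b[first]; w <- w[first]; key <- key[first]
  o <- order(a, b)
  ed <- data.frame(a = a[o], b = b[o], weight = w[o], id = key[o],
                   stringsAsFactors = FALSE)

  nd <- sort(unique(c(ed$a, ed$b, as.character(nodes %||% character()))))
  adj <- lapply(stats::setNames(nd, nd), function(x) character())
  for (i in seq_len(nrow(ed))) {
    adj[[ed$a[i]]] <- c(adj[[ed$a[i]]], ed$b[i])
    adj[[ed$b[i]]] <- c(adj[[ed$b[i]]], ed$a[i])
  }
  structure(list(nodes = nd, edges = ed, adj = adj), class = "ppi_network")
}

#' @export
print.ppi_network <- function(x, ...) {
  cat(sprintf("ppi_network: %d nodes, %d edges\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Number of edges of a network
#' @param net a `ppi_network`
#' @return integer edge count
#' @export
n_edges <- function(net) nrow(net$edges)

#' Read an interaction network from an edge-list file
#'
#' Accepts whitespace/tab-delimited records `gene_a gene_b [weight]` with
#' `#` comment lines, or the SIF dialect `gene_a relation gene_b` when
#' `sif = TRUE`. Parsing errors name the offending line.
#'
#' @param path file path
#' @param sif treat the middle of three fields as a relation label rather
#'   than a weight
#' @return a [ppi_network()]
#' @export
read_network <- function(path, sif = FALSE) {
  lines <- readLines(path)
  a <- character(); b <- character(); w <- numeric()
  for (ln in seq_along(lines)) {
    raw <- sub("#.*$", "", lines[ln])
    if (!nzchar(trimws(raw))) next
    f <- strsplit(trimws(raw), "[ \t,]+")[[1L]]
    if (length(f) < 2L || length(f) > 3L) {
      stop(sprintf("malformed edge record at line %d: expected 2-3 fields, got %d",
                   ln, length(f)))
    }
    if (sif && length(f) == 3L) {
      a <- c(a, f[1L]); b <- c(b, f[3L]); w <- c(w, 1)
    } else if (length(f) == 3L) {
      wt <- suppressWarnings(as.numeric(f[3L]))
      if (is.na(wt)) stop(sprintf("non-numeric weight at line %d: '%s'", ln, f[3L]))
      if (wt <= 0) stop(sprintf("non-positive weight at line %d", ln))
      a <- c(a, f[1L]); b <- c(b, f[2L]); w <- c(w, wt)
    } else {
      a <- c(a, f[1L]); b <- c(b, f[2L]); w <- c(w, 1)
    }
  }
  if (!length(a)) stop("no edges found in ", path)
  ppi_network(data.frame(a = a, b = b, weight = w, stringsAsFactors = FALSE))
}

#' Closed neighborhood of a node
#'
#' Returns the node together with its network neighbors; this is the set on
#' which the edge-similarity measure is defined.
#'
#' @param net a `ppi_network`
#' @param i node identifier
#' @return sorted character vector containing `i` and its neighbors
#' @export
neighborhood <- function(net, i) {
  if (!i %in% net$nodes) stop("unknown node: ", i)
  sort(unique(c(i, net$adj[[i]])))
}

canonical_edge_id <- function(e) {
  if (length(e) == 1L) return(e)
  e <- as.character(e)
  paste(min(e), max(e), sep = "|")
}

edge_index <- function(net, e) {
  id <- canonical_edge_id(e)
  idx <- match(id, net$edges$id)
  if (is.na(idx)) stop("not an edge of the network: ", id)
  idx
}

#' Topological similarity between two adjacent edges
#'
#' For edges e = (i, k) and f = (j, k) sharing node k, the similarity is the
#' Jaccard index of the closed neighborhoods of the two unshared endpoints,
#' `|n+(i) intersect n+(j)| / |n+(i) union n+(j)|`; the shared node carries no
#' information and enters only through the neighborhoods. Edges with no
#' common node have similarity zero. Set membership is binary: input edge
#' weights are ignored.
#'
#' @param net a `ppi_network`
#' @param e,f edges, each as a length-2 character vector or an `"A|B"` id
#' @return similarity in \[0, 1\]
#' @examples
#' tri <- ppi_network(data.frame(a = c("A", "B", "A"), b = c("B", "C", "C")))
#' edge_similarity(tri, c("A", "B"), c("A", "C"))  # 1
#' @export
edge_similarity <- function(net, e, f) {
  ie <- edge_index(net, e); jf <- edge_index(net, f)
  ea <- c(net$edges$a[ie], net$edges$b[ie])
  fb <- c(net$edges$a[jf], net$edges$b[jf])
  shared <- intersect(ea, fb)
  if (length(shared) == 0L) return(0)
  if (length(shared) == 2L) stop("identical edges have no defined similarity")
  i <- setdiff(ea, shared); j <- setdiff(fb, shared)
  ni <- neighborhood(net, i); nj <- neighborhood(net, j)
  length(intersect(ni, nj)) / length(union(ni, nj))
}

#' Line graph of an interaction network
#'
#' The line graph has one node per network edge; two line-graph nodes are
#' joined exactly when the underlying edges share a network node, with edge
#' weight given by [edge_similarity()]. The weighted degree of an edge in
#' this graph drives the adaptive penalty: interactions touching
#' high-degree genes overlap many other interactions and so acquire large
#' line-graph degrees.
#'
#' @param net a nonempty `ppi_network`
#' @return object of class `line_graph`: `edges` (the network edge table),
#'   `pairs` (data.frame `e1`, `e2`, `sim` of adjacent edge index pairs with
#'   their similarities), and `degree` (named vector of weighted line-graph
#'   degrees, one per network edge).
#' @export
line_graph <- function(net) {
  M <- n_edges(net)
  if (M == 0L) stop("network has no edges")
  # closed neighborhoods once per node
  nbr <- lapply(stats::setNames(net$nodes, net$nodes),
                function(v) sort(unique(c(v, net$adj[[v]]))))
  incident <- lapply(stats::setNames(net$nodes, net$nodes), function(v) integer())
  for (m in seq_len(M)) {
    incident[[net$edges$a[m]]] <- c(incident[[net$edges$a[m]]], m)
    incident[[net$edges$b[m]]] <- c(incident[[net$edges$b[m]]], m)
  }
  e1 <- integer(); e2 <- integer(); sim <- numeric()
  ends <- cbind(net$edges$a, net$edges$b)
  for (k in net$nodes) {
    inc <- incident[[k]]
    if (length(inc) < 2L) next
    for (u in seq_len(length(inc) - 1L)) {
      for (v in seq(u + 1L, length(inc))) {
        m1 <- inc[u]; m2 <- inc[v]
        i <- setdiff(ends[m1, ], k); j <- setdiff(ends[m2, ], k)
        ni <- nbr[[i]]; nj <- nbr[[j]]
        s <- length(intersect(ni, nj)) / length(union(ni, nj))
        e1 <- c(e1, m1); e2 <- c(e2, m2); sim <- c(sim, s)
      }
    }
  }
  deg <- numeric(M)
  if (length(e1)) {
    for (t in seq_along(e1)) {
      deg[e1[t]] <- deg[e1[t]] + sim[t]
      deg[e2[t]] <- deg[e2[t]] + sim[t]
    }
  }
  names(deg) <- net$edges$id
  structure(list(edges = net$edges,
                 pairs = data.frame(e1 = e1, e2 = e2, sim = sim),
                 degree = deg),
            class = "line_graph")
}

#' @export
print.line_graph <- function(x, ...) {
  cat(sprintf("line_graph: %d edge-nodes, %d adjacent pairs\n",
              nrow(x$edges), nrow(x$pairs)))
  invisible(x)
}

#' Adaptive elastic-net penalty weights from graph degrees
#'
#' Computes per-feature L1 penalty multipliers `w_j = d_j^(-r)` where `d_j`
#' is the weighted degree — the line-graph degree of an edge for edge-level
#' models, or the node degree for the gene-level configuration. Larger `r`
#' penalizes poorly connected features more heavily, steering selection
#' toward hubs. Degrees of zero are floored at the smallest positive degree
#' (1e-8 if none) before exponentiation, and the weights are rescaled to sum
#' to the number of features so that the lambda scale is comparable across
#' `r` (the usual penalty-factor convention). `r = 0` yields all-ones
#' weights, i.e. the plain elastic net.
#'
#' @param x a `line_graph` (edge-level) or `ppi_network` (gene-level)
#' @param r nonnegative degree exponent
#' @param ... unused
#' @return object of class `penalty_weights`: `r`, `degree`, `raw`,
#'   `normalized` (named, summing to the number of features).
#' @export
adaptive_weights <- function(x, r, ...) UseMethod("adaptive_weights")

make_penalty_weights <- function(deg, r) {
  if (!is.numeric(r) || length(r) != 1L || r < 0) stop("r must be a nonnegative scalar")
  pos <- deg[deg > 0]
  floor_at <- if (length(pos)) min(pos) else 1e-8
  d <- pmax(deg, floor_at)
  raw <- d^(-r)
  normalized <- raw * length(raw) / sum(raw)
  structure(list(r = r, degree = deg, raw = raw, normalized = normalized),
            class = "penalty_weights")
}

#' @rdname adaptive_weights
#' @export
adaptive_weights.line_graph <- function(x, r, ...) make_penalty_weights(x$degree, r)

#' @rdname adaptive_weights
#' @export
adaptive_weights.ppi_network <- function(x, r, ...) {
  deg <- vapply(stats::setNames(x$nodes, x$nodes), function(v) {
    sum(x$edges$weight[x$edges$a == v | x$edges$b == v])
  }, numeric(1))
  make_penalty_weights(deg, r)
}

#' Export a line graph and its penalty weights as TSV
#'
#' Writes one row per network edge: edge id, endpoints, weighted line-graph
#' degree, and (if `weights` is given) the normalized penalty weight.
#'
#' @param lg a `line_graph`
#' @param path output file
#' @param weights optional `penalty_weights`
#' @return the written data.frame, invisibly
#' @export
write_line_graph <- function(lg, path, weights = NULL) {
  out <- data.frame(edge_id = lg$edges$id, endpoint_a = lg$edges$a,
                    endpoint_b = lg$edges$b, line_degree = unname(lg$degree),
                    stringsAsFactors = FALSE)
  if (!is.null(weights)) out$weight <- unname(weights$normalized)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out)
}
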