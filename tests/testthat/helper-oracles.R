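# Shared fixtures and independent brute-force oracles. The oracles work from
# an explicit adjacency matrix and plain set enumeration, deliberately
# avoiding the package's neighborhood/line-graph code paths.

path_net <- function() ppi_network(data.frame(a = c("A", "B"), b = c("B", "C")))
triangle_net <- function() ppi_network(data.frame(a = c("A", "B", "A"),
                                                  b = c("B", "C", "C")))
star_net <- function(leaves = 4) {
  ppi_network(data.frame(a = rep("H", leaves), b = paste0("L", seq_len(leaves))))
}

# Dense binary adjacency matrix over net$nodes.
adjacency_of <- function(net) {
  p <- length(net$nodes)
  A <- matrix(0L, p, p, dimnames = list(net$nodes, net$nodes))
  for (i in seq_len(nrow(net$edges))) {
    A[net$edges$a[i], net$edges$b[i]] <- 1L
    A[net$edges$b[i], net$edges$a[i]] <- 1L
  }
  A
}

# Closed neighborhood as a character set, straight from the adjacency matrix.
closed_nbhd <- function(A, v) sort(unique(c(v, colnames(A)[A[v, ] > 0])))

# Brute-force similarity between two edges given as endpoint pairs.
oracle_similarity <- function(A, e, f) {
  shared <- intersect(e, f)
  if (length(shared) != 1L) return(0)
  i <- setdiff(e, shared); j <- setdiff(f, shared)
  ni <- closed_nbhd(A, i); nj <- closed_nbhd(A, j)
  length(intersect(ni, nj)) / length(union(ni, nj))
}

# Brute-force line-graph degrees: sum similarity over all other edges.
oracle_line_degrees <- function(net) {
  A <- adjacency_of(net)
  M <- nrow(net$edges)
  ends <- lapply(seq_len(M), function(m) c(net$edges$a[m], net$edges$b[m]))
  d <- numeric(M)
  if (M >= 2L) {
    for (m1 in seq_len(M - 1L)) {
      for (m2 in seq(m1 + 1L, M)) {
        s <- oracle_similarity(A, ends[[m1]], ends[[m2]])
        d[m1] <- d[m1] + s
        d[m2] <- d[m2] + s
      }
    }
  }
  stats::setNames(d, net$edges$id)
}

# Random Erdos-Renyi network over at most `p` labelled nodes; guaranteed to
# have at least one edge.
random_test_net <- function(p, prob = 0.2) {
  repeat {
    pairs <- t(combn(sprintf("n%02d", seq_len(p)), 2))
    keep <- runif(nrow(pairs)) < prob
    if (any(keep)) {
      return(ppi_network(data.frame(a = pairs[keep, 1], b = pairs[keep, 2],
                                    stringsAsFactors = FALSE)))
    }
  }
}

# Small labelled Gaussian design for solver tests.
random_instance <- function(n, net, effect = 1, seed = NULL) {
  sim <- simulate_dataset(net, n = n,
                          n_informative = min(3L, n_edges(net)),
                          effect = effect, seed = seed)
  suppressMessages(edge_features(sim$ds, net))
}

default_truth <- function(seed_net, seed_data, effect = 1.5, n = 300L) {
  net <- simulate_network(200, "scale_free", 2, seed = seed_net)
  list(net = net,
       sim = simulate_dataset(net, n = n, n_informative = 10L,
                              effect = effect, prevalence = 0.5,
                              seed = seed_data))
}
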