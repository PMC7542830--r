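# Independent oracles and shared fixtures for the test suite.

# Brute-force phylogenetic covariance: root-to-tip node paths with
# cumulative edge lengths; C[i,j] = depth of the deepest shared node.
# Independent of ape::vcv.phylo.
brute_force_cov <- function(tree) {
  n <- ape::Ntip(tree)
  root <- n + 1L
  parent <- integer(max(tree$edge))
  plen <- numeric(max(tree$edge))
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  plen[tree$edge[, 2]] <- tree$edge.length
  path_of <- function(tip) {
    nodes <- tip
    while (nodes[length(nodes)] != root) {
      nodes <- c(nodes, parent[nodes[length(nodes)]])
    }
    rev(nodes)  # root ... tip
  }
  paths <- lapply(seq_len(n), path_of)
  depth_along <- function(path) cumsum(c(0, plen[path[-1]]))
  C <- matrix(0, n, n, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(n)) {
    di <- depth_along(paths[[i]])
    for (j in i:n) {
      shared <- max(which(paths[[i]][seq_len(min(length(paths[[i]]),
                                                 length(paths[[j]])))] ==
                            paths[[j]][seq_len(min(length(paths[[i]]),
                                                   length(paths[[j]])))]))
      C[i, j] <- C[j, i] <- di[shared]
    }
  }
  C
}

# Dense-matrix GLS oracle: beta = (X' C^-1 X)^-1 X' C^-1 y via solve().
dense_gls <- function(X, y, C) {
  Ci <- solve(C)
  as.numeric(solve(t(X) %*% Ci %*% X, t(X) %*% Ci %*% y))
}

# A small random bifurcating tree with positive branch lengths.
random_tree <- function(n, seed) {
  simulate_yule_tree(n, birth_rate = 1, seed = seed)
}

# Small shared synthetic dataset (kept modest so the suite stays fast).
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_dataset(sim_config(n_species = 64, seed = 42))
    }
    cache
  }
})

quiet_pgls <- function(...) suppressMessages(pgls_fit(...))
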