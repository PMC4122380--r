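# Independent brute-force oracles. These deliberately avoid the package's
# matrix algebra: reachability is depth-first search, reductions are subset
# enumeration, component structure is pairwise reachability.

# depth-first reachability from one vertex (path length >= 1)
dfs_reachable <- function(m, start) {
  n <- nrow(m)
  seen <- rep(FALSE, n)
  stack <- which(m[start, ] != 0)
  while (length(stack)) {
    v <- stack[[1L]]
    stack <- stack[-1L]
    if (!seen[v]) {
      seen[v] <- TRUE
      stack <- c(stack, which(m[v, ] != 0))
    }
  }
  seen
}

# closure oracle: DFS from every vertex, diagonal cleared
closure_oracle <- function(m) {
  n <- nrow(m)
  out <- matrix(0L, n, n)
  for (i in seq_len(n)) out[i, dfs_reachable(m, i)] <- 1L
  diag(out) <- 0L
  out
}

# minimum equivalent graph oracle: enumerate subsets of the edge set in
# increasing size and return the first whose closure matches. Only for
# small edge counts.
min_equiv_oracle <- function(m) {
  target <- closure_oracle(m)
  edges <- which(m != 0)
  for (k in 0:length(edges)) {
    subsets <- utils::combn(length(edges), k, simplify = FALSE)
    for (s in subsets) {
      cand <- matrix(0L, nrow(m), ncol(m))
      cand[edges[s]] <- 1L
      if (identical(closure_oracle(cand), target)) return(cand)
    }
  }
}

# mutual-reachability classes oracle
scc_oracle <- function(m) {
  n <- nrow(m)
  reach <- matrix(FALSE, n, n)
  for (i in seq_len(n)) reach[i, ] <- dfs_reachable(m, i)
  mutual <- reach & t(reach)
  diag(mutual) <- TRUE
  comp <- integer(n)
  k <- 0L
  for (i in seq_len(n)) {
    if (comp[i] == 0L) {
      k <- k + 1L
      comp[mutual[i, ]] <- k
    }
  }
  comp
}

# testable-edge oracle: edge (u,v) of the closure with a path u -> v
# passing through a gene of sigma (DFS in two halves)
testability_oracle <- function(g, sigma_idx) {
  m <- tracegrn:::strip_attrs(g)
  cl <- closure_oracle(m)
  n <- nrow(m)
  out <- matrix(0L, n, n)
  for (u in seq_len(n)) {
    for (v in seq_len(n)) {
      if (u == v || cl[u, v] == 0L) next
      if (u %in% sigma_idx || v %in% sigma_idx) next
      for (s in sigma_idx) {
        if (cl[u, s] == 1L && cl[s, v] == 1L) {
          out[u, v] <- 1L
          break
        }
      }
    }
  }
  out
}

strip <- tracegrn:::strip_attrs

# full single+double knock-out design: A_0 plus every single-gene-removal
# background
full_design_spec <- function(g) {
  a0 <- true_accessibility(g, character())
  extras <- lapply(gene_labels(g), function(s) true_accessibility(g, s))
  ensemble_spec(a0, extras)
}

# sparse DAG inside the z-score operating regime: every gene accessible
# from fewer than `max_frac` of the knock-outs (see the methods vignette);
# deterministically retries sub-seeds until the constraint holds.
regime_dag <- function(n, size_range, seed, max_frac = 0.16) {
  for (k in 0:100) {
    g <- random_dag(n, size_range, seed = seed + 1000L * k)
    acc <- true_accessibility(g, character())
    if (max(colSums(strip(acc))) < max_frac * n) return(g)
  }
  stop("no in-regime DAG found")
}
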