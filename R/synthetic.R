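#' Simulation configuration
#'
#' Collects the tunable parameters of the synthetic-data generators. The
#' defaults describe the simulation world used throughout the package's
#' tests: random digraphs with 1 to `3 * n_genes` edges (the upper limit
#' mirrors the edge-to-node ratio of curated E. coli / yeast regulatory
#' networks), scale-free growth with 1--5 edges per added node, five
#' technical replicates of log-10 scale expression with Gaussian noise, a
#' ten-fold knock-down effect for accessible genes, and a 50% chance that a
#' fan-in target with surviving regulators compensates (yielding the
#' false-negative mechanism seen in real knock-out screens).
#'
#' @param n_genes number of genes
#' @param size_range integer range the edge count is drawn from (uniformly)
#' @param ba_edges_range edges attached per new node in scale-free growth
#' @param fpr,fnr error rates for [inject_errors()], relative to the edge
#'   count of the generating network
#' @param noise_sd standard deviation of measurement noise (log-10 units)
#' @param effect_size expression shift of accessible genes (log-10 units)
#' @param replicates number of technical replicates
#' @param fan_in_compensation probability in `[0, 1]` that a gene with
#'   several regulators is buffered against the knock-out of one of them
#' @param seed integer seed making every generator reproducible
#' @return a list of class `sim_config`
#' @export
sim_config <- function(n_genes = 10L,
                       size_range = c(1L, 3L * n_genes),
                       ba_edges_range = c(1L, 5L),
                       fpr = 0, fnr = 0,
                       noise_sd = 0.1,
                       effect_size = 1,
                       replicates = 5L,
                       fan_in_compensation = 0.5,
                       seed = NULL) {
  stopifnot(fpr >= 0, fnr >= 0, noise_sd >= 0, replicates >= 1,
            fan_in_compensation >= 0, fan_in_compensation <= 1)
  structure(list(n_genes = as.integer(n_genes),
                 size_range = as.integer(size_range),
                 ba_edges_range = as.integer(ba_edges_range),
                 fpr = fpr, fnr = fnr, noise_sd = noise_sd,
                 effect_size = effect_size,
                 replicates = as.integer(replicates),
                 fan_in_compensation = fan_in_compensation,
                 seed = seed),
            class = "sim_config")
}

# internal: run `expr` under a locally-seeded RNG without disturbing the
# caller's RNG state (when seed is NULL the global stream is used).
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Random digraph with uniformly drawn size
#'
#' Draws the edge count uniformly from `size_range` and then places that
#' many distinct ordered non-self pairs uniformly at random (no structural
#' preference).
#'
#' @param n number of genes
#' @param size_range inclusive edge-count range, within `[0, n * (n - 1)]`
#' @param seed optional integer seed
#' @return a `grn_adjacency`
#' @export
random_grn <- function(n, size_range = c(1L, 3L * n), seed = NULL) {
  n <- as.integer(n)
  size_range <- as.integer(size_range)
  if (size_range[1L] < 0L || size_range[2L] > n * (n - 1L) ||
      size_range[1L] > size_range[2L]) {
    stop("infeasible size range for a simple digraph of order ", n,
         call. = FALSE)
  }
  with_seed(seed, {
    size <- if (size_range[1L] == size_range[2L]) size_range[1L] else
      sample(size_range[1L]:size_range[2L], 1L)
    m <- matrix(0L, n, n)
    offdiag <- which(row(m) != col(m))
    m[sample(offdiag, size)] <- 1L
    grn_adjacency(m)
  })
}

#' Random directed acyclic graph
#'
#' Like [random_grn()] but edges are only placed forward along a random
#' topological order, so the result is acyclic. Used for fixtures where the
#' DAG-only guarantees (unique transitive reduction, ensemble enumeration)
#' apply.
#'
#' @inheritParams random_grn
#' @return an acyclic `grn_adjacency`
#' @export
random_dag <- function(n, size_range = c(1L, 3L * n), seed = NULL) {
  n <- as.integer(n)
  size_range <- as.integer(size_range)
  max_edges <- n * (n - 1L) %/% 2L
  if (size_range[1L] < 0L || size_range[2L] > max_edges ||
      size_range[1L] > size_range[2L]) {
    stop("infeasible size range for a DAG of order ", n, call. = FALSE)
  }
  with_seed(seed, {
    size <- if (size_range[1L] == size_range[2L]) size_range[1L] else
      sample(size_range[1L]:size_range[2L], 1L)
    ord <- sample.int(n)
    m <- matrix(0L, n, n)
    forward <- which(outer(ord, ord, `<`))
    m[sample(forward, size)] <- 1L
    grn_adjacency(m)
  })
}

#' Scale-free digraph by preferential attachment
#'
#' Barabasi-Albert growth: starting from a random weakly connected seed of
#' 3 vertices (a randomly oriented 2-edge path), each new node attaches `m`
#' edges (capped at the number of existing nodes) to distinct existing
#' nodes chosen with probability proportional to their total degree, where
#' `m` is drawn uniformly from `edges_per_node_range` once per graph. Each
#' attachment is oriented new-to-existing or existing-to-new with equal
#' probability.
#'
#' @param n number of genes (at least 3)
#' @param edges_per_node_range inclusive range of edges per added node
#' @param seed optional integer seed
#' @return a weakly connected `grn_adjacency`
#' @export
scale_free_grn <- function(n, edges_per_node_range = c(1L, 5L), seed = NULL) {
  n <- as.integer(n)
  stopifnot(n >= 3L)
  r <- as.integer(edges_per_node_range)
  with_seed(seed, {
    m <- matrix(0L, n, n)
    path <- sample.int(3L)
    for (k in 1:2) {
      if (stats::runif(1) < 0.5) m[path[k], path[k + 1L]] <- 1L
      else m[path[k + 1L], path[k]] <- 1L
    }
    if (n > 3L) {
      m_per_node <- if (r[1L] == r[2L]) r[1L] else sample(r[1L]:r[2L], 1L)
      for (v in 4:n) {
        existing <- seq_len(v - 1L)
        deg <- rowSums(m[existing, existing, drop = FALSE]) +
          colSums(m[existing, existing, drop = FALSE])
        k <- min(m_per_node, v - 1L)
        targets <- sample(existing, k, prob = deg + (sum(deg) == 0))
        for (u in targets) {
          if (stats::runif(1) < 0.5) m[v, u] <- 1L else m[u, v] <- 1L
        }
      }
    }
    grn_adjacency(m)
  })
}

#' Inject false-positive and false-negative errors
#'
#' Contaminates accessibility matrices with errors at rates defined relative
#' to a reference edge count (the size of the generating network):
#' `round(fpr * ref)` zero entries at unmasked off-diagonal positions are
#' flipped to 1 and `round(fnr * ref)` one entries flipped to 0 in each
#' matrix, positions drawn uniformly and independently per matrix.
#'
#' @param matrices list of `grn_accessibility`
#' @param fpr,fnr error rates (fractions of `ref_edge_count`)
#' @param ref_edge_count reference edge count `|E(G)|`
#' @param seed optional integer seed
#' @return list of contaminated matrices
#' @export
inject_errors <- function(matrices, fpr, fnr, ref_edge_count, seed = NULL) {
  stopifnot(fpr >= 0, fnr >= 0, ref_edge_count >= 0)
  n_fp <- round(fpr * ref_edge_count)
  n_fn <- round(fnr * ref_edge_count)
  with_seed(seed, lapply(matrices, function(a) {
    m <- strip_attrs(a)
    sigma <- ko_background(a)
    labels <- rownames(m)
    allowed <- matrix(TRUE, nrow(m), ncol(m))
    diag(allowed) <- FALSE
    allowed[match(sigma, labels), ] <- FALSE
    allowed[, match(sigma, labels)] <- FALSE
    zeros <- which(allowed & m == 0L)
    ones <- which(allowed & m == 1L)
    if (n_fp > length(zeros) || n_fn > length(ones)) {
      stop("more error flips requested than available positions", call. = FALSE)
    }
    if (n_fp > 0L) m[sample(zeros, n_fp)] <- 1L
    if (n_fn > 0L) m[sample(ones, n_fn)] <- 0L
    grn_accessibility(m, sigma = sigma)
  }))
}

#' Simulate steady-state knock-out expression data
#'
#' Deliberately simple stand-in for kinetic expression simulators: the
#' framework consumes only differential-expression calls, so the fixture
#' needs correct accessibility semantics and a tunable false-negative
#' mechanism rather than kinetics. Each experiment knocking out
#' `sigma + {i}` is modeled as a single-gene knock-out of `i` on the
#' background-reduced network: every gene gets a fixed baseline (drawn once
#' per dataset, uniform on 2--3 log-10 units); genes downstream of the
#' background `sigma` carry a constant shift shared by all experiments of
#' the dataset (absorbed by the per-column statistics); genes accessible
#' from `i` after removal of the edges incident to `sigma` are additionally
#' shifted down by `effect_size` -- except that, with probability
#' `fan_in_compensation`, a gene with two or more regulators of which at
#' least one remains unperturbed is buffered and not shifted (the fan-in
#' compensation mechanism behind false negatives). Compensation draws are
#' made once per (knock-out, gene) pair and shared across technical
#' replicates, as the mechanism is biological, not technical. Knocked-out
#' genes are floored at 0, and a background experiment (knocking out
#' `sigma` alone) is included. Per-replicate Gaussian noise (`noise_sd`) is
#' added on top.
#'
#' @param g the generating `grn_adjacency`
#' @param sigma background knock-out set
#' @param config a [sim_config()]
#' @return a [ko_dataset()]
#' @export
simulate_ko_expression <- function(g, sigma = character(), config = sim_config()) {
  g <- as_grn(g)
  labels <- gene_labels(g)
  n <- length(labels)
  sigma <- as.character(sigma)
  stopifnot(all(sigma %in% labels))
  with_seed(config$seed, {
    baseline <- stats::runif(n, 2, 3)
    names(baseline) <- labels
    targets <- setdiff(labels, sigma)
    exp_labels <- c(lapply(targets, function(i) c(sigma, i)), list(sigma))
    n_exp <- length(exp_labels)
    regulators <- lapply(seq_len(n), function(j) labels[g[, j] != 0L])
    # constant background component: genes downstream of sigma
    bg_shift <- rep(0, n)
    names(bg_shift) <- labels
    if (length(sigma)) {
      full_acc <- strip_attrs(true_accessibility(g, character()))
      downstream <- labels[colSums(full_acc[sigma, , drop = FALSE]) > 0L]
      bg_shift[downstream] <- config$effect_size
    }
    acc_sigma <- strip_attrs(true_accessibility(g, sigma))
    template <- matrix(rep(baseline - bg_shift, each = n_exp), n_exp, n,
                       dimnames = list(NULL, labels))
    for (r in seq_along(targets)) {
      i <- targets[r]
      reach <- labels[acc_sigma[i, ] != 0L]
      for (j in setdiff(reach, c(sigma, i))) {
        compensated <- FALSE
        regs <- regulators[[match(j, labels)]]
        active <- setdiff(regs, c(sigma, i, reach))
        if (length(regs) >= 2L && length(active) >= 1L &&
            config$fan_in_compensation > 0) {
          compensated <- stats::runif(1) < config$fan_in_compensation
        }
        if (!compensated) {
          template[r, j] <- template[r, j] - config$effect_size
        }
      }
    }
    # knocked-out genes are floored
    for (r in seq_len(n_exp)) {
      template[r, exp_labels[[r]]] <- 0
    }
    reps <- lapply(seq_len(config$replicates), function(k) {
      template + matrix(stats::rnorm(n_exp * n, sd = config$noise_sd), n_exp, n)
    })
    ko_dataset(reps, exp_labels, sigma = sigma, gene_labels = labels)
  })
}
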