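#' Ensemble specification: the accessibility matrices given to inference
#'
#' Bundles the empty-background accessibility matrix `A_0` with any number
#' of extra matrices `A_sigma` from multi-gene knock-out designs. The
#' ensemble of interest is the set of all digraphs consistent with every
#' matrix in the specification.
#'
#' @param a0 `grn_accessibility` with empty background
#' @param extras list of `grn_accessibility` with distinct non-empty
#'   backgrounds
#' @return object of class `ensemble_spec`
#' @export
ensemble_spec <- function(a0, extras = list()) {
  stopifnot(inherits(a0, "grn_accessibility"))
  if (length(ko_background(a0))) {
    stop("a0 must have an empty knock-out background", call. = FALSE)
  }
  labels <- gene_labels(a0)
  keys <- character(0)
  for (a in extras) {
    stopifnot(inherits(a, "grn_accessibility"))
    if (!identical(gene_labels(a), labels)) {
      stop("gene labels of all matrices must agree", call. = FALSE)
    }
    sig <- ko_background(a)
    if (!length(sig)) stop("extras must have non-empty backgrounds", call. = FALSE)
    keys <- c(keys, paste(sort(sig), collapse = ","))
  }
  if (anyDuplicated(keys)) {
    stop("extras must have distinct knock-out backgrounds", call. = FALSE)
  }
  structure(list(a0 = a0, extras = extras), class = "ensemble_spec")
}

#' @export
print.ensemble_spec <- function(x, ...) {
  cat(sprintf("ensemble spec: %d genes, A_0 plus %d extra matrices\n",
              nrow(x$a0), length(x$extras)))
  invisible(x)
}

#' Upper bound of the network ensemble
#'
#' Starts from `A_0` and intersects entrywise with each extra matrix
#' `A_sigma`, except that entries incident to the background genes of that
#' matrix (row or column in `sigma`) are left unaltered -- a knock-out
#' background carries no information about edges touching its own genes.
#' With no extras, the upper bound is `A_0` itself.
#'
#' @param spec an [ensemble_spec()]
#' @return `grn_adjacency` upper bound
#' @export
upper_bound <- function(spec) {
  stopifnot(inherits(spec, "ensemble_spec"))
  u <- strip_attrs(spec$a0)
  labels <- gene_labels(spec$a0)
  for (a in spec$extras) {
    free <- setdiff(labels, ko_background(a))
    u[free, free] <- u[free, free] * strip_attrs(a)[free, free]
  }
  grn_adjacency(u)
}

#' Lower bound of the network ensemble
#'
#' Union of the ConTREx reductions of `A_0` and of every extra matrix
#' (plain transitive reduction when the matrix is acyclic). For acyclic
#' inputs every lower-bound edge is certain -- it appears in each consistent
#' network; edges expanded from 2-node cycle components are only certain up
#' to the choice of member (see [contrex()]).
#'
#' @param spec an [ensemble_spec()]
#' @return `grn_adjacency` lower bound
#' @export
lower_bound <- function(spec) {
  stopifnot(inherits(spec, "ensemble_spec"))
  l <- strip_attrs(contrex(spec$a0))
  for (a in spec$extras) {
    l <- l | strip_attrs(contrex(a))
  }
  grn_adjacency(l * 1L)
}

# internal constructor for a bounds pair
new_bounds <- function(lower, upper) {
  gap <- strip_attrs(upper) & !strip_attrs(lower)
  structure(list(lower = lower, upper = upper,
                 gap = which_edges(gap),
                 gap_size = sum(gap),
                 inferable = sum(gap) == 0L),
            class = "grn_bounds")
}

# internal: integer index matrix (row, col) of nonzero entries,
# deterministic row-major order
which_edges <- function(m) {
  idx <- which(t(m != 0L))
  n <- nrow(m)
  cbind(row = (idx - 1L) %/% n + 1L, col = (idx - 1L) %% n + 1L)
}

#' @export
print.grn_bounds <- function(x, ...) {
  cat(sprintf("ensemble bounds: lower %d edges, upper %d edges, gap %d (%s)\n",
              n_edges(x$lower), n_edges(x$upper), x$gap_size,
              if (x$inferable) "inferable" else "not inferable"))
  invisible(x)
}

#' Infer ensemble bounds without error correction
#'
#' Core bound construction for error-free (or accepted-as-is) accessibility
#' matrices: the lower bound is the union of the ConTREx reductions and the
#' upper bound the masked intersection of the accessibility matrices. The
#' network is inferable exactly when the two bounds coincide. If the lower
#' bound is not contained in the upper bound the inputs are inconsistent
#' (noisy); a warning reports the inconsistent edges and the error-corrected
#' path ([infer_bounds_corrected()]) should be used instead.
#'
#' @param spec an [ensemble_spec()]
#' @return object of class `grn_bounds`: list with `lower`, `upper`, `gap`
#'   (index matrix of upper-minus-lower edges), `gap_size`, `inferable`
#' @export
infer_bounds <- function(spec) {
  lower <- lower_bound(spec)
  upper <- upper_bound(spec)
  bad <- strip_attrs(lower) & !strip_attrs(upper)
  if (any(bad)) {
    labs <- gene_labels(lower)
    e <- which_edges(bad)
    warning("inconsistent bounds: lower-bound edge(s) missing from upper bound (",
            paste(sprintf("%s->%s", labs[e[, 1L]], labs[e[, 2L]]),
                  collapse = ", "),
            "); caused by noisy inputs (consider infer_bounds_corrected()) or ",
            "by 2-node cycles, whose expanded reduction edges need not all be ",
            "consistent",
            call. = FALSE)
  }
  new_bounds(lower, upper)
}

#' Ensemble size for acyclic upper bounds
#'
#' For a DAG upper bound, the consistent networks are obtained by
#' combinatorially adding gap edges to the lower bound, so the ensemble has
#' at most `2^d` members where `d` is the gap size.
#'
#' @param b a `grn_bounds`
#' @return numeric `2^d`
#' @export
ensemble_size_dag <- function(b) {
  stopifnot(inherits(b, "grn_bounds"))
  if (!is_acyclic(b$upper)) {
    stop("ensemble size formula requires an acyclic upper bound", call. = FALSE)
  }
  2^b$gap_size
}

#' Enumerate the ensemble for acyclic upper bounds
#'
#' Generates every candidate `lower + S` for subsets `S` of the gap edges
#' and keeps those whose regenerated accessibility matrices reproduce every
#' matrix of the specification exactly. Inconsistent combinations are
#' excluded and counted in the `n_inconsistent` attribute.
#'
#' @param b a `grn_bounds` with acyclic upper bound
#' @param spec the [ensemble_spec()] the bounds were built from
#' @param max_size refuse enumeration when `2^d` exceeds this (default 1024)
#' @return list of `grn_adjacency` members
#' @export
enumerate_ensemble_dag <- function(b, spec, max_size = 1024) {
  stopifnot(inherits(b, "grn_bounds"), inherits(spec, "ensemble_spec"))
  if (!is_acyclic(b$upper)) {
    stop("ensemble enumeration supported only for acyclic upper bounds",
         call. = FALSE)
  }
  d <- b$gap_size
  if (2^d > max_size) {
    stop(sprintf("ensemble too large to enumerate: 2^%d > max_size", d),
         call. = FALSE)
  }
  base <- strip_attrs(b$lower)
  sigmas <- c(list(character()), lapply(spec$extras, ko_background))
  targets <- c(list(spec$a0), spec$extras)
  members <- list()
  n_bad <- 0L
  for (mask in 0:(2^d - 1)) {
    m <- base
    if (d > 0L) {
      on <- which(bitwAnd(mask, 2^(seq_len(d) - 1L)) != 0L)
      if (length(on)) m[b$gap[on, , drop = FALSE]] <- 1L
    }
    cand <- grn_adjacency(m, gene_labels(b$lower))
    ok <- TRUE
    for (k in seq_along(sigmas)) {
      acc <- true_accessibility(cand, sigmas[[k]])
      if (!identical(strip_attrs(acc), strip_attrs(targets[[k]]))) {
        ok <- FALSE
        break
      }
    }
    if (ok) members[[length(members) + 1L]] <- cand else n_bad <- n_bad + 1L
  }
  attr(members, "n_inconsistent") <- n_bad
  members
}

#' Distances between bounds and a reference network
#'
#' Reports `lower_dist = |E(g) - E(lower)|` (true edges missed by the lower
#' bound), `upper_dist = |E(upper) - E(g)|` (upper-bound edges absent from
#' the reference) and the gap size -- the quantities plotted in inferability
#' analyses.
#'
#' @param b a `grn_bounds`
#' @param g reference `grn_adjacency` (e.g. the generating network)
#' @return named numeric vector
#' @export
bound_distances <- function(b, g) {
  g <- as_grn(g)
  stopifnot(identical(gene_labels(g), gene_labels(b$lower)))
  gm <- strip_attrs(g)
  c(lower_dist = sum(gm & !strip_attrs(b$lower)),
    upper_dist = sum(strip_attrs(b$upper) & !gm),
    gap_size = b$gap_size)
}

#' Rank candidate knock-out backgrounds by informativeness
#'
#' Backgrounds with more testable edges are more informative: their
#' accessibility matrices can verify more edges of `A_0`. Ties are broken
#' lexicographically by the sorted gene labels of the background, so the
#' ordering is deterministic.
#'
#' @param a0 `grn_accessibility` with empty background
#' @param candidate_sigmas list of character vectors (candidate backgrounds)
#' @return the candidates reordered by decreasing testable-edge count; the
#'   counts are attached as attribute `"n_testable"`.
#' @export
rank_sigma_informativeness <- function(a0, candidate_sigmas) {
  counts <- vapply(candidate_sigmas,
                   function(s) sum(testability_matrix(a0, s)),
                   numeric(1))
  keys <- vapply(candidate_sigmas,
                 function(s) paste(sort(as.character(s)), collapse = ","),
                 character(1))
  ord <- order(-counts, keys)
  out <- candidate_sigmas[ord]
  attr(out, "n_testable") <- counts[ord]
  out
}

#' Structural Hamming distance between two digraphs
#'
#' Utility metric: the number of gene pairs on which the two edge sets
#' disagree (an edge reversal counts as two disagreements).
#'
#' @param g1,g2 `grn_adjacency` objects on the same genes
#' @return integer distance
#' @export
structural_hamming_distance <- function(g1, g2) {
  g1 <- as_grn(g1); g2 <- as_grn(g2)
  stopifnot(identical(gene_labels(g1), gene_labels(g2)))
  sum(strip_attrs(g1) != strip_attrs(g2))
}
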