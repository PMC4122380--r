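#' Majority-vote pre-processing of accessibility matrices
#'
#' Noise hits different matrices at different positions, while a real edge
#' of `A_0` reappears in most backgrounds. For every off-diagonal position,
#' the fraction of matrices containing the edge is computed among the
#' matrices where the position is eligible to vote; positions at or above
#' `threshold` are kept wherever they appeared, positions below are removed
#' from all matrices. By default only matrices whose background does not
#' touch the position are eligible (`eligibility = "unmasked"`); the
#' all-matrices variant is kept behind a switch.
#'
#' @param matrices list of `grn_accessibility` (any mix of backgrounds)
#' @param threshold majority fraction, validated range `[0.5, 0.8]`
#'   (default 0.65); comparison is inclusive (`>=`).
#' @param eligibility `"unmasked"` (default) or `"all"`
#' @return list of cleaned matrices (same order/backgrounds)
#' @export
preprocess_majority <- function(matrices, threshold = 0.65,
                                eligibility = c("unmasked", "all")) {
  eligibility <- match.arg(eligibility)
  if (threshold < 0.5 || threshold > 0.8) {
    stop("threshold outside validated range [0.5, 0.8]", call. = FALSE)
  }
  if (length(matrices) < 2L) {
    warning("fewer than 2 matrices: pre-processing is a pass-through",
            call. = FALSE)
    return(matrices)
  }
  n <- nrow(matrices[[1L]])
  labels <- gene_labels(matrices[[1L]])
  present <- matrix(0, n, n)
  eligible <- matrix(0, n, n)
  for (a in matrices) {
    mask <- unmasked_positions(a)
    if (eligibility == "all") mask[] <- TRUE
    diag(mask) <- FALSE
    present <- present + (strip_attrs(a) != 0L) * mask
    eligible <- eligible + mask
  }
  frac <- ifelse(eligible > 0, present / pmax(eligible, 1), 1)
  drop <- eligible > 0 & present > 0 & frac < threshold
  lapply(matrices, function(a) {
    m <- strip_attrs(a)
    m[drop] <- 0L
    grn_accessibility(m, sigma = ko_background(a))
  })
}

# internal: logical matrix TRUE at positions not incident to the background
unmasked_positions <- function(a) {
  labels <- gene_labels(a)
  free <- !(labels %in% ko_background(a))
  outer(free, free)
}

#' Inconsistent (Type C) edges between candidate bounds
#'
#' Errors that leave an edge in the lower bound while removing it from the
#' upper bound make the bounds contradict each other; those edges are
#' detectable (unlike Type A) and are handed to the voting correction.
#' Type B patterns (edge in the upper bound only) are *not* returned --
#' they widen the ensemble but keep the bounds consistent.
#'
#' @param lower_cand,upper_cand `grn_adjacency` candidates
#' @return integer index matrix (row, col) of edges in lower but not upper
#' @export
detect_inconsistent_edges <- function(lower_cand, upper_cand) {
  which_edges(strip_attrs(lower_cand) & !strip_attrs(upper_cand))
}

#' Filtered bound construction (error-corrected path)
#'
#' Builds candidate bounds in which each extra matrix only updates the
#' entries flagged testable for its background (testability computed from
#' the pre-processed closed `A_0`): a false call at a non-testable position
#' of some `A_sigma` then cannot propagate into the bounds. Two upper
#' candidates are produced -- one from the raw (possibly non-transitive)
#' matrices, one from their transitive closures -- together with a lower
#' candidate from the ConTREx reductions of the closed set, and an evidence
#' ledger of per-edge presence votes for the consistency check.
#'
#' @param raw [ensemble_spec()] of pre-processed raw matrices
#' @param closed [ensemble_spec()] of pre-processed transitive closures
#' @return list with `lower_cand`, `upper_cand_raw`, `upper_cand_closed`,
#'   `ledger` (list of `present` and `eligible` count matrices) and
#'   `testability` (list of testability matrices per extra)
#' @export
filtered_bounds <- function(raw, closed) {
  stopifnot(inherits(raw, "ensemble_spec"), inherits(closed, "ensemble_spec"))
  labels <- gene_labels(closed$a0)
  n <- length(labels)
  test_mats <- lapply(closed$extras, function(a) {
    strip_attrs(testability_matrix(closed$a0, ko_background(a))) != 0L
  })
  masked_intersect <- function(spec) {
    u <- strip_attrs(spec$a0)
    for (k in seq_along(spec$extras)) {
      pos <- test_mats[[k]]
      u[pos] <- u[pos] * strip_attrs(spec$extras[[k]])[pos]
    }
    grn_adjacency(u, labels)
  }
  upper_raw <- masked_intersect(raw)
  upper_closed <- masked_intersect(closed)
  # lower: ConTREx of the closed set; pre-processing may have broken
  # transitivity, so each matrix is re-closed first. Extras contribute only
  # at their testable positions.
  reduce <- function(a) strip_attrs(contrex(transitive_closure(a)))
  lower <- reduce(closed$a0)
  contrex_mats <- list(reduce(closed$a0))
  for (k in seq_along(closed$extras)) {
    cx <- reduce(closed$extras[[k]])
    contrex_mats[[k + 1L]] <- cx
    lower <- lower | (cx & test_mats[[k]])
  }
  lower_cand <- grn_adjacency(lower * 1L, labels)
  # evidence ledger: votes from the raw accessibility matrices and the
  # ConTREx matrices; a matrix votes on a position only where unmasked and
  # (for non-empty backgrounds) testable.
  present <- matrix(0, n, n)
  eligible <- matrix(0, n, n)
  vote <- function(entries, sigma_mask, testable) {
    mask <- sigma_mask
    if (!is.null(testable)) mask <- mask & testable
    diag(mask) <- FALSE
    present <<- present + (entries != 0L) * mask
    eligible <<- eligible + mask
  }
  all_sources <- c(list(raw$a0), raw$extras)
  for (k in seq_along(all_sources)) {
    a <- all_sources[[k]]
    vote(strip_attrs(a), unmasked_positions(a),
         if (k > 1L) test_mats[[k - 1L]] else NULL)
  }
  specs_closed <- c(list(closed$a0), closed$extras)
  for (k in seq_along(specs_closed)) {
    vote(contrex_mats[[k]], unmasked_positions(specs_closed[[k]]),
         if (k > 1L) test_mats[[k - 1L]] else NULL)
  }
  list(lower_cand = lower_cand,
       upper_cand_raw = upper_raw,
       upper_cand_closed = upper_closed,
       ledger = list(present = present, eligible = eligible),
       testability = test_mats)
}

#' Consistency check: correct inconsistent edges by voting
#'
#' For each inconsistent edge (in the lower candidate but not the upper),
#' presence and absence votes from the evidence ledger decide the fix: a
#' strict majority for presence adds the edge to the upper bound, a strict
#' majority for absence removes it from the lower bound, and a tie does
#' both (the edge becomes non-inferable). The result always satisfies
#' lower within upper.
#'
#' @param lower_cand,upper_cand candidate bounds
#' @param ledger evidence ledger from [filtered_bounds()]
#' @return a `grn_bounds`
#' @export
consistency_check <- function(lower_cand, upper_cand, ledger) {
  lo <- strip_attrs(lower_cand)
  up <- strip_attrs(upper_cand)
  bad <- detect_inconsistent_edges(lower_cand, upper_cand)
  for (r in seq_len(nrow(bad))) {
    e <- bad[r, , drop = FALSE]
    p <- ledger$present[e]
    a <- ledger$eligible[e] - p
    if (p > a) {
      up[e] <- 1L
    } else if (a > p) {
      lo[e] <- 0L
    } else {
      up[e] <- 1L
      lo[e] <- 0L
    }
  }
  labels <- gene_labels(lower_cand)
  new_bounds(grn_adjacency(lo, labels), grn_adjacency(up, labels))
}

#' Infer ensemble bounds with error correction
#'
#' Full corrected pipeline for noisy accessibility matrices: close each raw
#' matrix, pre-process the raw and closed sets by majority voting, build
#' filtered bounds, then run the consistency check twice -- first against
#' the closed-set upper candidate (producing the corrected lower bound),
#' then against the raw-set upper candidate (producing the final bounds).
#' On error-free inputs the result coincides exactly with [infer_bounds()].
#'
#' @param raw_matrices list of `grn_accessibility` from
#'   [build_accessibility()] (must include exactly one empty-background
#'   matrix)
#' @param threshold pre-processing majority threshold (default 0.65)
#' @param eligibility see [preprocess_majority()]
#' @return a `grn_bounds`
#' @export
infer_bounds_corrected <- function(raw_matrices, threshold = 0.65,
                                   eligibility = "unmasked") {
  sig_len <- vapply(raw_matrices, function(a) length(ko_background(a)),
                    integer(1))
  if (sum(sig_len == 0L) != 1L) {
    stop("raw_matrices must contain exactly one empty-background matrix",
         call. = FALSE)
  }
  ord <- order(sig_len)  # A_0 first
  raw_matrices <- raw_matrices[ord]
  closed <- lapply(raw_matrices, transitive_closure)
  pre_raw <- preprocess_majority(raw_matrices, threshold, eligibility)
  pre_closed <- preprocess_majority(closed, threshold, eligibility)
  raw_spec <- ensemble_spec(pre_raw[[1L]], pre_raw[-1L])
  closed_spec <- ensemble_spec(pre_closed[[1L]], pre_closed[-1L])
  fb <- filtered_bounds(raw_spec, closed_spec)
  cc1 <- consistency_check(fb$lower_cand, fb$upper_cand_closed, fb$ledger)
  consistency_check(cc1$lower, fb$upper_cand_raw, fb$ledger)
}

#' Classify bound errors against a known truth
#'
#' Simulation-side audit of a bounds pair: counts the three error patterns
#' (Type A: the same error in both bounds, undetectable; Type B: edge in
#' the upper bound only, a consistent widening; Type C: edge in the lower
#' bound only, an inconsistency) plus the headline error counts
#' `|L - G|`, `|G - U|` and the gap size.
#'
#' @param truth the generating `grn_adjacency`
#' @param b a `grn_bounds`
#' @return named list of counts and FP/FN edge index matrices
#' @export
classify_errors <- function(truth, b) {
  truth <- as_grn(truth)
  g <- strip_attrs(truth) != 0L
  lo <- strip_attrs(b$lower) != 0L
  up <- strip_attrs(b$upper) != 0L
  list(type_a = sum((lo & up & !g) | (g & !lo & !up)),
       type_b = sum(up & !lo),
       type_c = sum(lo & !up),
       lower_fp = sum(lo & !g),
       upper_fn = sum(g & !up),
       gap_size = sum(up & !lo),
       lower_fp_edges = which_edges(lo & !g),
       upper_fn_edges = which_edges(g & !up))
}
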