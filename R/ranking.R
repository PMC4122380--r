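#' Two-phase ranked edge list with confidence scores
#'
#' Phase 1 assigns every ordered gene pair (self-pairs excluded) to one of
#' five confidence subsets, from most to least confident:
#' \enumerate{
#'   \item edges of the lower bound (certain),
#'   \item edges of the upper bound outside the lower bound (non-inferable),
#'   \item edges of the accessibility matrix outside the upper bound
#'     (indirect regulations),
#'   \item edges of the transitive closure of the accessibility matrix not
#'     in any of the above (implied reachability the raw matrix missed),
#'   \item all remaining pairs (certain non-edges).
#' }
#' Phase 2 orders pairs within each subset by decreasing average absolute
#' z-score, combining both into an overall score
#' `s_ij = (5 - subset) + |zbar_ij| / (max |zbar| + 1)` so that subset
#' membership always dominates. Phase 3 maps the overall rank `r` linearly
#' onto confidence `c_ij = 1 - (r - 1) / (N - 1)`, so the top pair scores 1
#' (certain presence) and the bottom pair 0 (certain absence). Ties in
#' `|zbar|` are broken by source/target label order, making output files
#' bit-reproducible.
#'
#' @param b a `grn_bounds`
#' @param a0 empty-background `grn_accessibility`
#' @param zbar averaged z-score matrix from the empty-background dataset
#'   (e.g. `attr(build_accessibility(...), "zbar")`); pass `NULL` to rank on
#'   subsets alone.
#' @return a `data.frame` of class `grn_ranked_edges` with columns `from`,
#'   `to`, `confidence`, `subset`, sorted by decreasing confidence.
#' @export
rank_edges <- function(b, a0, zbar = NULL) {
  stopifnot(inherits(b, "grn_bounds"))
  labels <- gene_labels(b$lower)
  n <- length(labels)
  lo <- strip_attrs(b$lower) != 0L
  up <- strip_attrs(b$upper) != 0L
  am <- strip_attrs(a0) != 0L
  acl <- strip_attrs(transitive_closure(a0)) != 0L
  if (is.null(zbar)) zbar <- matrix(0, n, n)
  subset <- matrix(5L, n, n)
  subset[acl & !am & !up] <- 4L
  subset[am & !up] <- 3L
  subset[up & !lo] <- 2L
  subset[lo] <- 1L
  pair <- which(row(subset) != col(subset))
  from <- row(subset)[pair]
  to <- col(subset)[pair]
  absz <- abs(zbar)[pair]
  sub <- subset[pair]
  ord <- order(sub, -absz, labels[from], labels[to], method = "radix")
  N <- length(ord)
  score <- (5L - sub[ord]) + absz[ord] / (max(absz) + 1)
  conf <- if (N > 1L) 1 - (seq_len(N) - 1) / (N - 1) else 1
  out <- data.frame(from = labels[from][ord], to = labels[to][ord],
                    confidence = conf, subset = sub[ord],
                    score = score, stringsAsFactors = FALSE)
  class(out) <- c("grn_ranked_edges", class(out))
  out
}

#' Confusion-curve points with non-inferable edges masked
#'
#' Sweeps the ranked list from most to least confident and tallies true and
#' false positives against a gold-standard network, excluding gene pairs in
#' the non-inferable set from all tallies: prediction errors that no method
#' could resolve from the data are not penalized. The non-inferable set is
#' normally the gap of the error-free bounds of the gold standard.
#'
#' @param ranked a `grn_ranked_edges`
#' @param gold gold-standard `grn_adjacency`
#' @param noninferable data.frame with `from`/`to` columns, or an index or
#'   logical matrix of pairs to exclude; `NULL` for no masking
#' @return list with `roc` (`fpr`, `tpr`) and `pr` (`recall`, `precision`)
#'   data.frames of curve points
#' @export
masked_confusion <- function(ranked, gold, noninferable = NULL) {
  gold <- as_grn(gold)
  labels <- gene_labels(gold)
  if (!all(ranked$from %in% labels) || !all(ranked$to %in% labels)) {
    stop("ranked list contains genes absent from the gold standard",
         call. = FALSE)
  }
  excl <- matrix(FALSE, nrow(gold), ncol(gold), dimnames = dimnames(gold))
  if (!is.null(noninferable)) {
    if (is.data.frame(noninferable)) {
      excl[cbind(match(noninferable$from, labels),
                 match(noninferable$to, labels))] <- TRUE
    } else if (is.matrix(noninferable) && ncol(noninferable) == 2L) {
      excl[noninferable] <- TRUE
    } else {
      excl <- noninferable != 0
    }
  }
  idx <- cbind(match(ranked$from, labels), match(ranked$to, labels))
  keep <- !excl[idx]
  lab <- (strip_attrs(gold) != 0L)[idx][keep]
  pos <- sum(lab)
  neg <- sum(!lab)
  if (pos == 0L) {
    stop("undefined metric: gold standard has no positive pairs after masking",
         call. = FALSE)
  }
  tp <- cumsum(lab)
  fp <- cumsum(!lab)
  roc <- data.frame(fpr = c(0, fp / max(neg, 1L)), tpr = c(0, tp / pos))
  pr <- data.frame(recall = tp / pos, precision = tp / seq_along(lab))
  list(roc = roc, pr = pr, n_positive = pos, n_negative = neg)
}

#' Areas under ROC and precision-recall curves
#'
#' Trapezoidal integration of the curve points from [masked_confusion()].
#'
#' @param curves list with `roc` and `pr` data.frames
#' @return named numeric vector `c(auroc =, aupr =)`, both in `[0, 1]`
#' @export
auroc_aupr <- function(curves) {
  trapz <- function(x, y) {
    if (length(x) < 2L) stop("need at least 2 curve points", call. = FALSE)
    sum(diff(x) * (utils::head(y, -1L) + utils::tail(y, -1L)) / 2)
  }
  roc <- curves$roc
  pr <- curves$pr
  # anchor the PR curve at recall 0 with its first precision value
  prx <- c(0, pr$recall)
  pry <- c(pr$precision[1L], pr$precision)
  c(auroc = trapz(roc$fpr, roc$tpr), aupr = trapz(prx, pry))
}

#' @export
print.grn_ranked_edges <- function(x, ...) {
  cat(sprintf("ranked edge list: %d pairs (top confidence %.3f)\n",
              nrow(x), x$confidence[1L]))
  NextMethod()
}
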