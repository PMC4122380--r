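#' Error-free accessibility matrix of a known network
#'
#' Oracle used for inferability analysis: for a known GRN `g` and knock-out
#' background `sigma`, the accessibility matrix is the transitive closure of
#' the knock-out subgraph, with the background rows/columns zero. This is
#' what an ideal (noise-free, unbiased) differential-expression experiment
#' would measure.
#'
#' @param g a `grn_adjacency`
#' @param sigma character vector of background knock-out genes
#' @return a `grn_accessibility`
#' @export
true_accessibility <- function(g, sigma = character()) {
  g <- as_grn(g)
  cl <- transitive_closure(knockout_subgraph(g, sigma))
  out <- grn_accessibility(strip_attrs(cl), sigma = as.character(sigma))
  attr(out, "transitive") <- TRUE
  out
}

#' Trimmed sample mean and standard deviation
#'
#' Two-pass outlier-resistant location/scale estimate used for the z-score
#' normalization of knock-out expression columns: compute the mean and
#' (population) standard deviation, exclude values whose distance from the
#' mean reaches `k_sigma` standard deviations (inclusive comparison, like
#' the other thresholds of the pipeline; the boundary has measure zero for
#' noisy data), and recompute once on the kept values. If fewer than two
#' values survive the trim, the untrimmed pair is returned. Trimming is a
#' single pass -- it is not iterated to convergence.
#'
#' @param values numeric vector (at least 2 values)
#' @param k_sigma positive trimming multiple (default 2)
#' @return named numeric vector `c(mean =, sd =)`
#' @export
trimmed_mean_std <- function(values, k_sigma = 2) {
  values <- as.numeric(values)
  if (length(values) < 2L) {
    stop("insufficient data: need at least 2 values", call. = FALSE)
  }
  stopifnot(k_sigma > 0)
  sd_pop <- function(v) sqrt(mean((v - mean(v))^2))
  m <- mean(values)
  s <- sd_pop(values)
  keep <- if (s > 0) abs(values - m) < k_sigma * s else rep(TRUE, length(values))
  if (sum(keep) >= 2L) {
    m <- mean(values[keep])
    s <- sd_pop(values[keep])
  }
  c(mean = m, sd = s)
}

#' Knock-out expression dataset
#'
#' Container for steady-state knock-out expression data on the log-10
#' intensity scale. Each technical replicate is an experiments x genes
#' matrix; every experiment is labeled by the full set of knocked-out genes
#' (the shared background `sigma` plus one additional gene). A background
#' experiment knocking out `sigma` alone (labeled `"WT"` when `sigma` is
#' empty) may be included and is then used for mean/sd estimation.
#'
#' @param replicates list of numeric matrices (experiments x genes), equal
#'   shapes
#' @param experiment_labels list of character vectors: the knocked-out gene
#'   set of each experiment row (must contain `sigma`); `character(0)` marks
#'   the background/wild-type row
#' @param sigma shared background knock-out set
#' @param gene_labels column gene labels
#' @param complete_design logical; when TRUE (default), [build_accessibility()]
#'   requires one experiment per non-background gene
#' @return object of class `ko_dataset`
#' @export
ko_dataset <- function(replicates, experiment_labels, sigma = character(),
                       gene_labels = NULL, complete_design = TRUE) {
  stopifnot(is.list(replicates), length(replicates) >= 1L)
  replicates <- lapply(replicates, as.matrix)
  dims <- unique(lapply(replicates, dim))
  if (length(dims) != 1L) stop("replicate matrices must share shape", call. = FALSE)
  if (is.null(gene_labels)) {
    gene_labels <- colnames(replicates[[1L]]) %||%
      paste0("G", seq_len(ncol(replicates[[1L]])))
  }
  sigma <- as.character(sigma)
  experiment_labels <- lapply(experiment_labels, as.character)
  if (length(experiment_labels) != nrow(replicates[[1L]])) {
    stop("one experiment label per data row is required", call. = FALSE)
  }
  for (lab in experiment_labels) {
    if (length(unknown <- setdiff(lab, gene_labels))) {
      stop("unknown gene label(s) in experiments: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    if (length(lab) && !all(sigma %in% lab) && !setequal(lab, sigma)) {
      stop("every experiment label must contain the background sigma",
           call. = FALSE)
    }
  }
  replicates <- lapply(replicates, function(m) {
    colnames(m) <- gene_labels
    m
  })
  structure(list(replicates = replicates,
                 experiment_labels = experiment_labels,
                 sigma = sigma, gene_labels = gene_labels,
                 complete_design = complete_design),
            class = "ko_dataset")
}

#' @export
print.ko_dataset <- function(x, ...) {
  cat(sprintf("knock-out expression dataset: %d experiments x %d genes, %d replicate(s)\n",
              nrow(x$replicates[[1L]]), length(x$gene_labels),
              length(x$replicates)))
  cat("background sigma: {", paste(x$sigma, collapse = ", "), "}\n")
  invisible(x)
}

# internal: the single gene added on top of sigma for each experiment row,
# or NA for the background row.
added_gene <- function(dataset) {
  vapply(dataset$experiment_labels, function(lab) {
    extra <- setdiff(lab, dataset$sigma)
    if (length(extra) == 0L) NA_character_
    else if (length(extra) == 1L) extra
    else stop("experiment knocks out more than one gene beyond sigma: ",
              paste(lab, collapse = ","), call. = FALSE)
  }, character(1))
}

#' Z-score matrix of one technical replicate
#'
#' For the experiment knocking out background `sigma` plus gene `i`, the
#' z-score of gene `j` is `(x_ij - mu_j) / sd_j` where `mu_j`, `sd_j` are the
#' per-column trimmed statistics. Columns with zero spread use a small
#' positive floor (the smallest positive sd across genes, or machine epsilon)
#' so that noise-free fixtures do not divide by zero; entries exactly at the
#' mean stay 0. Rows/columns of background genes and the diagonal are zero.
#'
#' @param data experiments x genes matrix of one replicate
#' @param means,stds per-gene statistics from [trimmed_mean_std()]
#' @param dataset the `ko_dataset` the replicate belongs to (provides row ->
#'   knocked-out-gene mapping and `sigma`)
#' @return n x n numeric z-score matrix (knock-out gene x measured gene)
#' @export
zscore_replicate <- function(data, means, stds, dataset) {
  genes <- dataset$gene_labels
  n <- length(genes)
  if (ncol(data) != n || length(means) != n || length(stds) != n) {
    stop("shape mismatch between data and column statistics", call. = FALSE)
  }
  floor_sd <- min(stds[stds > 0], .Machine$double.eps^0.5)
  denom <- ifelse(stds > 0, stds, floor_sd)
  z <- matrix(0, n, n, dimnames = list(genes, genes))
  ko <- added_gene(dataset)
  for (r in seq_len(nrow(data))) {
    if (is.na(ko[r])) next  # background row is used only for mu/sd
    diff <- data[r, ] - means
    z[ko[r], ] <- ifelse(diff == 0, 0, diff / denom)
  }
  z[dataset$sigma, ] <- 0
  z[, dataset$sigma] <- 0
  diag(z) <- 0
  z
}

#' Average z-score matrices over technical replicates
#' @param zs non-empty list of equal-shape z-score matrices
#' @return entrywise mean matrix
#' @export
average_zscores <- function(zs) {
  if (!length(zs)) stop("need at least one replicate z-score matrix", call. = FALSE)
  Reduce(`+`, zs) / length(zs)
}

#' Threshold an averaged z-score matrix into an accessibility matrix
#'
#' Entry `(i, j)` is set to 1 iff `|zbar_ij| >= k_z` (inclusive comparison;
#' boundary ties have measure zero for noisy data). Background rows/columns
#' and the diagonal are forced to zero.
#'
#' @param zbar averaged z-score matrix (genes x genes)
#' @param k_z positive threshold (default 3)
#' @param sigma knock-out background of the dataset
#' @return a `grn_accessibility`
#' @export
accessibility_from_zscores <- function(zbar, k_z = 3, sigma = character()) {
  stopifnot(k_z > 0)
  a <- (abs(zbar) >= k_z) * 1L
  diag(a) <- 0L
  if (length(sigma)) {
    a[sigma, ] <- 0L
    a[, sigma] <- 0L
  }
  grn_accessibility(a, sigma = sigma)
}

#' Build an accessibility matrix from knock-out expression data
#'
#' Full differential-expression pipeline: per replicate, trimmed mean/sd per
#' gene column (using all experiment rows, including the background
#' experiment when present), z-score matrix, average over replicates, then
#' thresholding. Row `i` of the result corresponds to the experiment
#' knocking out `sigma + {i}`.
#'
#' @param dataset a [ko_dataset()]
#' @param k_sigma trimming multiple, validated range 1.5--2.5 (default 2)
#' @param k_z z-score threshold, validated range 2--3 (default 3)
#' @param force allow parameter values outside the validated ranges
#' @return a `grn_accessibility`; the averaged z-score matrix is attached as
#'   attribute `"zbar"` for edge ranking.
#' @export
build_accessibility <- function(dataset, k_sigma = 2, k_z = 3, force = FALSE) {
  stopifnot(inherits(dataset, "ko_dataset"))
  if (!force && (k_sigma < 1.5 || k_sigma > 2.5)) {
    stop("k_sigma outside validated range [1.5, 2.5]; use force = TRUE",
         call. = FALSE)
  }
  if (!force && (k_z < 2 || k_z > 3)) {
    stop("k_z outside validated range [2, 3]; use force = TRUE", call. = FALSE)
  }
  ko <- added_gene(dataset)
  expected <- setdiff(dataset$gene_labels, dataset$sigma)
  missing <- setdiff(expected, ko[!is.na(ko)])
  if (length(missing) && dataset$complete_design) {
    stop("incomplete design: no experiment knocks out ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  # Column statistics exclude the experiments that knock out the column's
  # own gene: a knocked-out gene's reading is residual background, and
  # keeping it would inflate the first-pass spread and shield genuine
  # differential-expression outliers from the trim.
  ko_contains <- vapply(dataset$gene_labels, function(j) {
    vapply(dataset$experiment_labels, function(lab) j %in% lab, logical(1))
  }, logical(length(dataset$experiment_labels)))
  zs <- lapply(dataset$replicates, function(rep) {
    stats <- vapply(seq_along(dataset$gene_labels), function(j) {
      keep <- !ko_contains[, j]
      if (sum(keep) < 2L) keep <- rep(TRUE, nrow(rep))  # background columns
      trimmed_mean_std(rep[keep, j], k_sigma = k_sigma)
    }, numeric(2))
    zscore_replicate(rep, stats["mean", ], stats["sd", ], dataset)
  })
  zbar <- average_zscores(zs)
  a <- accessibility_from_zscores(zbar, k_z = k_z, sigma = dataset$sigma)
  attr(a, "zbar") <- zbar
  if (length(missing)) attr(a, "missing_experiments") <- missing
  a
}

#' Testability matrix of a knock-out background
#'
#' The testable edges of background `sigma` are the edges `(u, v)` of the
#' empty-background accessibility matrix `a0` for which some directed path
#' from `u` to `v` passes through a gene of `sigma`: exactly these entries
#' can change between `a0` and `A_sigma`, so only they carry information in
#' the masked intersection/union steps. Computed as the union over
#' `i in sigma` of the outer product of column `i` and row `i` of `a0`,
#' masked to the edges of `a0` and to endpoints outside `sigma`.
#'
#' @param a0 a `grn_accessibility` with empty background
#' @param sigma candidate knock-out background
#' @return a `grn_accessibility` (binary testability matrix carrying `sigma`)
#' @export
testability_matrix <- function(a0, sigma) {
  stopifnot(inherits(a0, "grn_accessibility"))
  if (length(ko_background(a0))) {
    stop("a0 must have an empty knock-out background", call. = FALSE)
  }
  sigma <- as.character(sigma)
  n <- nrow(a0)
  tmat <- matrix(0L, n, n, dimnames = dimnames(a0))
  m <- strip_attrs(a0)
  for (i in sigma) {
    tmat <- tmat | outer(m[, i], m[i, ])
  }
  tmat <- tmat & m
  tmat[sigma, ] <- FALSE
  tmat[, sigma] <- FALSE
  grn_accessibility(tmat * 1L, sigma = sigma)
}
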