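#' Read a directed network from a DREAM-style edge list
#'
#' Tab-separated `source<TAB>target<TAB>1` lines (the third column is
#' optional and implies 1; a 0 marks an explicit non-edge and is ignored).
#' Lines starting with `#` are comments. Malformed lines are reported with
#' their line numbers.
#'
#' @param path file path
#' @param gene_labels optional full gene universe; defaults to the sorted
#'   genes seen in the file (natural "G<number>" ordering when applicable)
#' @return a `grn_adjacency`
#' @export
read_network <- function(path, gene_labels = NULL) {
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  rows <- strsplit(lines[keep], "\t", fixed = TRUE)
  lineno <- which(keep)
  bad <- which(vapply(rows, length, integer(1)) < 2L)
  if (length(bad)) {
    stop("malformed edge-list line(s): ",
         paste(lineno[bad], collapse = ", "), call. = FALSE)
  }
  from <- vapply(rows, `[[`, character(1), 1L)
  to <- vapply(rows, `[[`, character(1), 2L)
  val <- vapply(rows, function(r) if (length(r) >= 3L) as.numeric(r[[3L]]) else 1,
                numeric(1))
  if (is.null(gene_labels)) {
    gene_labels <- sort_gene_labels(unique(c(from, to)))
  }
  m <- matrix(0L, length(gene_labels), length(gene_labels),
              dimnames = list(gene_labels, gene_labels))
  sel <- val != 0
  m[cbind(match(from[sel], gene_labels), match(to[sel], gene_labels))] <- 1L
  grn_adjacency(m)
}

# internal: "G2" < "G10" natural ordering when all labels are G<number>
sort_gene_labels <- function(labels) {
  nums <- suppressWarnings(as.integer(sub("^G", "", labels)))
  if (!anyNA(nums)) labels[order(nums)] else sort(labels)
}

#' Write a network as a DREAM-style edge list
#'
#' @param g a `grn_adjacency`
#' @param path output file
#' @param header logical: write a comment header with the edge count
#' @export
write_network <- function(g, path, header = TRUE) {
  g <- as_grn(g)
  e <- edge_list(g)
  con <- file(path, "w")
  on.exit(close(con))
  if (header) {
    writeLines(sprintf("# directed network: %d genes, %d edges",
                       nrow(g), nrow(e)), con)
  }
  if (nrow(e)) {
    writeLines(sprintf("%s\t%s\t1", e$from, e$to), con)
  }
  invisible(path)
}

#' Write an accessibility matrix as adjacency CSV
#'
#' The header comments record the knock-out background and, when known, the
#' `k_sigma`/`k_z` thresholds the matrix was built with.
#'
#' @param a a `grn_accessibility`
#' @param path output file
#' @param k_sigma,k_z optional thresholds to record
#' @export
write_accessibility_csv <- function(a, path, k_sigma = NULL, k_z = NULL) {
  stopifnot(inherits(a, "grn_accessibility"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# sigma: %s",
                     paste(ko_background(a), collapse = ",")), con)
  if (!is.null(k_sigma)) writeLines(sprintf("# k_sigma: %g", k_sigma), con)
  if (!is.null(k_z)) writeLines(sprintf("# k_z: %g", k_z), con)
  utils::write.csv(as.data.frame(strip_attrs(a)), con, row.names = TRUE)
  invisible(path)
}

#' Read an accessibility matrix from adjacency CSV
#' @param path file written by [write_accessibility_csv()]
#' @return a `grn_accessibility`
#' @export
read_accessibility_csv <- function(path) {
  lines <- readLines(path)
  meta <- grep("^#", lines, value = TRUE)
  sigma <- character()
  sig_line <- grep("^# sigma:", meta, value = TRUE)
  if (length(sig_line)) {
    raw <- trimws(sub("^# sigma:", "", sig_line[1L]))
    if (nzchar(raw)) sigma <- strsplit(raw, ",", fixed = TRUE)[[1L]]
  }
  body <- lines[!grepl("^#", lines)]
  df <- utils::read.csv(text = body, row.names = 1L, check.names = FALSE)
  grn_accessibility(as.matrix(df), sigma = sigma)
}

#' Read knock-out expression replicates
#'
#' Each replicate file is a TSV whose first column holds the comma-joined
#' knocked-out gene labels of the experiment (`"G3"` or `"G3,G7"`; `"WT"`
#' marks the unperturbed background) and whose remaining columns are gene
#' expression on the log-10 scale. All replicate files must share header
#' and experiment labels.
#'
#' @param paths character vector of replicate file paths
#' @param sigma background knock-out set shared by all experiments
#' @param complete_design see [ko_dataset()]
#' @return a [ko_dataset()]
#' @export
read_expression <- function(paths, sigma = character(), complete_design = TRUE) {
  stopifnot(length(paths) >= 1L)
  parse_one <- function(path) {
    df <- utils::read.delim(path, check.names = FALSE,
                            stringsAsFactors = FALSE, comment.char = "#")
    labels_raw <- as.character(df[[1L]])
    m <- as.matrix(df[, -1L, drop = FALSE])
    storage.mode(m) <- "double"
    list(labels = labels_raw, data = m, genes = colnames(m))
  }
  parsed <- lapply(paths, parse_one)
  genes <- parsed[[1L]]$genes
  labels_raw <- parsed[[1L]]$labels
  for (p in parsed[-1L]) {
    if (!identical(p$genes, genes)) {
      stop("replicate files disagree on gene columns", call. = FALSE)
    }
    if (!identical(p$labels, labels_raw)) {
      stop("replicate files disagree on experiment labels", call. = FALSE)
    }
  }
  if (anyDuplicated(labels_raw)) {
    stop("duplicate experiment label(s): ",
         paste(unique(labels_raw[duplicated(labels_raw)]), collapse = ", "),
         call. = FALSE)
  }
  exp_labels <- lapply(labels_raw, function(s) {
    if (toupper(s) == "WT") character() else strsplit(s, ",", fixed = TRUE)[[1L]]
  })
  ko_dataset(lapply(parsed, `[[`, "data"), exp_labels, sigma = sigma,
             gene_labels = genes, complete_design = complete_design)
}

#' Write a knock-out expression dataset
#'
#' One TSV per technical replicate in the dialect of [read_expression()].
#'
#' @param dataset a [ko_dataset()]
#' @param paths one output path per replicate
#' @export
write_expression <- function(dataset, paths) {
  stopifnot(length(paths) == length(dataset$replicates))
  labels <- vapply(dataset$experiment_labels, function(lab) {
    if (!length(lab)) "WT" else paste(lab, collapse = ",")
  }, character(1))
  for (k in seq_along(paths)) {
    df <- data.frame(knockout = labels,
                     dataset$replicates[[k]], check.names = FALSE)
    utils::write.table(df, paths[k], sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(paths)
}

#' Split pooled multi-gene knock-out experiments by background
#'
#' Experiments knocking out gene sets of size `k` serve the backgrounds of
#' size `k - 1` they contain: a `{G1,G2}` knock-out contributes row `G2` to
#' the `{G1}` background and row `G1` to the `{G2}` background, while
#' single knock-outs form the empty-background dataset and double as
#' background rows. Returns one (possibly partial) [ko_dataset()] per
#' background encountered.
#'
#' @param dataset a pooled [ko_dataset()] with `sigma = character()` whose
#'   experiment labels may contain multiple genes
#' @return named list of `ko_dataset` objects, keyed by comma-joined sorted
#'   background (`""` for the empty background)
#' @export
split_by_background <- function(dataset) {
  stopifnot(inherits(dataset, "ko_dataset"))
  sizes <- lengths(dataset$experiment_labels)
  backgrounds <- list(character())
  keys <- ""
  for (lab in dataset$experiment_labels[sizes >= 2L]) {
    for (drop in seq_along(lab)) {
      sig <- sort(lab[-drop])
      key <- paste(sig, collapse = ",")
      if (!key %in% keys) {
        keys <- c(keys, key)
        backgrounds <- c(backgrounds, list(sig))
      }
    }
  }
  out <- lapply(backgrounds, function(sig) {
    rows <- which(vapply(dataset$experiment_labels, function(lab) {
      all(sig %in% lab) && length(lab) <= length(sig) + 1L
    }, logical(1)))
    if (!length(sig)) {
      rows <- which(sizes <= 1L)
    }
    ko_dataset(lapply(dataset$replicates, function(m) m[rows, , drop = FALSE]),
               dataset$experiment_labels[rows], sigma = sig,
               gene_labels = dataset$gene_labels, complete_design = FALSE)
  })
  names(out) <- keys
  out
}

#' Write ranked edge predictions in DREAM format
#'
#' Tab-separated `source<TAB>target<TAB>confidence`, strictly ordered by
#' decreasing confidence (ties already broken deterministically upstream).
#'
#' @param ranked a `grn_ranked_edges`
#' @param path output file
#' @param top optionally truncate to the `top` most confident pairs
#' @export
write_predictions <- function(ranked, path, top = NULL) {
  df <- ranked
  if (!is.null(top)) df <- utils::head(df, top)
  writeLines(sprintf("%s\t%s\t%.10f", df$from, df$to, df$confidence), path)
  invisible(path)
}

#' Read ranked edge predictions in DREAM format
#' @param path file path
#' @return data.frame with `from`, `to`, `confidence`
#' @export
read_predictions <- function(path) {
  df <- utils::read.delim(path, header = FALSE,
                          col.names = c("from", "to", "confidence"),
                          stringsAsFactors = FALSE)
  df
}
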