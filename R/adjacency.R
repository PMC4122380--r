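#' Directed-graph containers for gene regulatory networks
#'
#' A gene regulatory network (GRN) is represented by its binary adjacency
#' matrix: entry `(i, j) = 1` means a directed regulatory edge from gene `i`
#' to gene `j`. No self-loops are modeled, so the diagonal is always zero.
#'
#' @param entries an `n x n` matrix containing only 0/1 values with a zero
#'   diagonal. Dimnames, if present, must agree with `gene_labels`.
#' @param gene_labels character vector of unique gene identifiers; defaults
#'   to `"G1".."Gn"` (DREAM convention) or the existing row names.
#' @return an object of class `grn_adjacency`: an integer 0/1 matrix with
#'   gene labels as dimnames.
#' @examples
#' g <- grn_adjacency(rbind(c(0, 1, 0), c(0, 0, 1), c(0, 0, 0)))
#' n_edges(g)
#' @export
grn_adjacency <- function(entries, gene_labels = NULL) {
  entries <- as.matrix(entries)
  if (nrow(entries) != ncol(entries)) {
    stop("invalid adjacency matrix: must be square", call. = FALSE)
  }
  if (!all(entries %in% c(0, 1))) {
    stop("invalid adjacency matrix: entries must be 0/1", call. = FALSE)
  }
  if (any(diag(entries) != 0)) {
    stop("invalid adjacency matrix: diagonal must be zero (no self-loops)",
         call. = FALSE)
  }
  if (is.null(gene_labels)) {
    gene_labels <- rownames(entries)
    if (is.null(gene_labels)) gene_labels <- paste0("G", seq_len(nrow(entries)))
  }
  if (length(gene_labels) != nrow(entries) || anyDuplicated(gene_labels)) {
    stop("gene_labels must be unique and match the matrix dimension",
         call. = FALSE)
  }
  storage.mode(entries) <- "integer"
  dimnames(entries) <- list(gene_labels, gene_labels)
  structure(entries, class = c("grn_adjacency", "matrix", "array"))
}

#' Accessibility matrix of a knock-out background
#'
#' The accessibility matrix `A_sigma` records reachability in the GRN after
#' all edges incident to the knock-out background set `sigma` have been
#' removed: entry `(i, j) = 1` means gene `j` is reachable from gene `i` in
#' that subgraph. Rows and columns of the background genes are all zero.
#'
#' @inheritParams grn_adjacency
#' @param sigma character vector of background knock-out gene labels
#'   (possibly empty).
#' @return an object of class `grn_accessibility` (also a `grn_adjacency`).
#' @export
grn_accessibility <- function(entries, sigma = character(), gene_labels = NULL) {
  g <- grn_adjacency(entries, gene_labels)
  sigma <- as.character(sigma)
  labels <- rownames(g)
  unknown <- setdiff(sigma, labels)
  if (length(unknown)) {
    stop("unknown gene(s) in sigma: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (length(sigma) && (any(g[sigma, , drop = FALSE] != 0L) ||
                        any(g[, sigma, drop = FALSE] != 0L))) {
    stop("rows and columns of background genes must be zero", call. = FALSE)
  }
  attr(g, "sigma") <- sigma
  class(g) <- c("grn_accessibility", class(g))
  g
}

#' @export
print.grn_adjacency <- function(x, ...) {
  n <- nrow(x)
  kind <- if (inherits(x, "grn_accessibility")) "accessibility" else "adjacency"
  cat(sprintf("%s matrix: %d genes, %d edges\n", kind, n, sum(x)))
  sig <- attr(x, "sigma")
  if (!is.null(sig)) {
    cat("background sigma: {", paste(sig, collapse = ", "), "}\n")
  }
  if (n <= 12L) print(unclass(strip_attrs(x)))
  invisible(x)
}

#' Gene labels of a network object
#' @param g a `grn_adjacency`
#' @return character vector of gene labels
#' @export
gene_labels <- function(g) rownames(g)

#' Knock-out background of an accessibility matrix
#' @param a a `grn_accessibility`
#' @return character vector (possibly empty)
#' @export
ko_background <- function(a) attr(a, "sigma") %||% character()

#' Number of directed edges
#' @param g a `grn_adjacency`
#' @export
n_edges <- function(g) sum(g != 0L)

#' Edge list of a network
#'
#' @param g a `grn_adjacency`
#' @return a data.frame with columns `from`, `to`, ordered by row-major
#'   position (deterministic).
#' @export
edge_list <- function(g) {
  idx <- which(t(unclass(g)) != 0L)  # transpose => source-major ordering
  n <- nrow(g)
  from <- (idx - 1L) %/% n + 1L
  to <- (idx - 1L) %% n + 1L
  labels <- rownames(g)
  data.frame(from = labels[from], to = labels[to], stringsAsFactors = FALSE)
}

# internal: keep only dim/dimnames
strip_attrs <- function(x) {
  y <- unclass(x)
  attributes(y) <- attributes(y)[c("dim", "dimnames")]
  y
}

# internal: rebuild an object like `template` from new entries
rewrap <- function(entries, template, transitive = NA) {
  entries <- matrix(as.integer(entries != 0L), nrow(template),
                    dimnames = dimnames(template))
  out <- if (inherits(template, "grn_accessibility")) {
    grn_accessibility(entries, sigma = ko_background(template))
  } else {
    grn_adjacency(entries)
  }
  if (isTRUE(transitive)) attr(out, "transitive") <- TRUE
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# internal validation used by algorithms accepting plain matrices too
as_grn <- function(g) {
  if (inherits(g, "grn_adjacency")) g else grn_adjacency(g)
}
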