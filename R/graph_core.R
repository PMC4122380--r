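#' Transitive closure of a digraph
#'
#' Computes reachability: the closure `C` has `C[i, j] = 1` iff a directed
#' path of length >= 1 from `i` to `j` exists. Self-reachability on cycles is
#' not recorded: the diagonal of the result is always zero, because a gene's
#' differential expression upon its own knock-out carries no regulatory
#' information.
#'
#' Implemented as boolean repeated squaring of the adjacency matrix, which
#' converges in O(log n) matrix products.
#'
#' @param g a `grn_adjacency` (or 0/1 matrix)
#' @return closure with the same class as `g`; carries an internal
#'   `transitive` flag so downstream checks can be skipped.
#' @export
transitive_closure <- function(g) {
  g <- as_grn(g)
  reach <- reachability(strip_attrs(g))
  diag(reach) <- 0L
  rewrap(reach, g, transitive = TRUE)
}

# internal: reachability by paths of length >= 1; diagonal entries are 1
# exactly for vertices lying on a directed cycle.
reachability <- function(m) {
  m <- m != 0L
  storage.mode(m) <- "double"
  repeat {
    m2 <- (m + m %*% m) != 0L
    storage.mode(m2) <- "double"
    if (identical(m2, m)) break
    m <- m2
  }
  m != 0
}

#' Test whether a digraph is acyclic
#' @param g a `grn_adjacency`
#' @return TRUE iff `g` has no directed cycle
#' @export
is_acyclic <- function(g) {
  g <- as_grn(g)
  !any(diag(reachability(strip_attrs(g))))
}

# internal: transitivity check; a digraph is transitive iff it equals its
# own closure (under the zero-diagonal convention).
is_transitive <- function(g) {
  if (isTRUE(attr(g, "transitive"))) return(TRUE)
  cl <- reachability(strip_attrs(g))
  diag(cl) <- 0
  identical(unname(strip_attrs(g) != 0L), unname(cl != 0))
}

#' Transitive reduction of a DAG
#'
#' Returns the unique minimal digraph with the same transitive closure as
#' `g`: an edge `(u, v)` is pruned whenever an alternative directed path
#' from `u` to `v` exists. Only defined (uniquely) for acyclic graphs; cyclic
#' inputs raise an error directing the caller to [contrex()].
#'
#' @param g an acyclic `grn_adjacency`
#' @return the transitive reduction, same class as `g`
#' @export
transitive_reduction_dag <- function(g) {
  g <- as_grn(g)
  m <- strip_attrs(g)
  reach <- reachability(m)
  if (any(diag(reach))) {
    stop("cycle detected: transitive reduction of cyclic digraphs is not ",
         "unique; use contrex()", call. = FALSE)
  }
  # paths of length >= 2 from u to v: an edge followed by a path. In a DAG
  # such a path can never use the edge (u, v) itself.
  storage.mode(reach) <- "double"
  long <- (m %*% reach) > 0
  rewrap(m & !long, g)
}

#' Condensation of a digraph by strong components
#'
#' Collapses every strongly connected component (maximal set of mutually
#' accessible genes) into one node, yielding a DAG over components.
#'
#' @param g a `grn_adjacency`
#' @return an object of class `grn_condensation`: a list with `dag`
#'   (`grn_adjacency` over components, labels `"c1"..`), `component_map`
#'   (named integer vector gene -> component id) and `sizes` (component
#'   sizes).
#' @export
scc_condensation <- function(g) {
  g <- as_grn(g)
  m <- strip_attrs(g)
  n <- nrow(m)
  reach <- reachability(m)
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
  names(comp) <- rownames(g)
  dag <- matrix(0L, k, k)
  edges <- which(m != 0L, arr.ind = TRUE)
  if (nrow(edges)) {
    cu <- comp[edges[, 1L]]
    cv <- comp[edges[, 2L]]
    keep <- cu != cv
    dag[cbind(cu[keep], cv[keep])] <- 1L
  }
  structure(
    list(dag = grn_adjacency(dag, paste0("c", seq_len(k))),
         component_map = comp,
         sizes = tabulate(comp, k)),
    class = "grn_condensation")
}

#' @export
print.grn_condensation <- function(x, ...) {
  cat(sprintf("condensation: %d genes -> %d strong components\n",
              length(x$component_map), nrow(x$dag)))
  invisible(x)
}

#' ConTREx: condensation, transitive reduction, expansion
#'
#' Reduction step for accessibility matrices that may contain cycles. The
#' transitive input is condensed into a DAG of strong components, the DAG is
#' transitively reduced, and the result is expanded back to genes. Both edges
#' of every 2-node cycle are retained (their direction is unambiguous); all
#' edges among -- and incident to -- members of strong components with 3 or
#' more genes are pruned, because individual cycle edges cannot be uniquely
#' prescribed from reachability alone. Edges incident to a 2-node component
#' survive the reduction: on expansion they are attached to both members
#' wherever the input matrix contains them. This keeps the reduction of a
#' 2-cycle's neighborhood non-empty at the price of possibly retaining an
#' edge for the wrong member -- the reduced graph is a reduction heuristic,
#' not necessarily a member of the consistent ensemble (see the methods
#' vignette).
#'
#' @param a a transitive `grn_adjacency`/`grn_accessibility` (i.e. the
#'   closure of some digraph); non-transitive inputs raise an error -- close
#'   them first with [transitive_closure()].
#' @return reduced digraph, same class as `a`
#' @export
contrex <- function(a) {
  a <- as_grn(a)
  if (!is_transitive(a)) {
    stop("input is not transitive; apply transitive_closure() first",
         call. = FALSE)
  }
  cond <- scc_condensation(a)
  k <- nrow(cond$dag)
  comp <- cond$component_map
  sizes <- cond$sizes
  trd <- transitive_reduction_dag(cond$dag)
  out <- matrix(0L, nrow(a), nrow(a), dimnames = dimnames(a))
  # retained 2-node cycles
  for (cc in which(sizes == 2L)) {
    mem <- which(comp == cc)
    out[mem[1L], mem[2L]] <- 1L
    out[mem[2L], mem[1L]] <- 1L
  }
  # surviving reduced edges between components of size <= 2 are expanded to
  # every member pair backed by the input matrix; anything incident to a
  # component of 3 or more genes is pruned
  m <- strip_attrs(a)
  tedges <- which(strip_attrs(trd) != 0L, arr.ind = TRUE)
  for (r in seq_len(nrow(tedges))) {
    cu <- tedges[r, 1L]
    cv <- tedges[r, 2L]
    if (sizes[cu] <= 2L && sizes[cv] <= 2L) {
      for (u in which(comp == cu)) {
        for (v in which(comp == cv)) {
          if (m[u, v] == 1L) out[u, v] <- 1L
        }
      }
    }
  }
  rewrap(out, a)
}

#' Knock-out subgraph
#'
#' Removes all edges incident (either endpoint) to the genes in `sigma`,
#' modeling the regulatory wiring that remains after those genes are knocked
#' out. The vertex set is unchanged.
#'
#' @param g a `grn_adjacency`
#' @param sigma character vector of knocked-out gene labels
#' @return subgraph, same class as `g`
#' @export
knockout_subgraph <- function(g, sigma) {
  g <- as_grn(g)
  sigma <- as.character(sigma)
  unknown <- setdiff(sigma, rownames(g))
  if (length(unknown)) {
    stop("unknown gene(s) in sigma: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  m <- strip_attrs(g)
  m[sigma, ] <- 0L
  m[, sigma] <- 0L
  rewrap(m, g)
}
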