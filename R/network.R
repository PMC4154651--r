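#' Directed weighted functional networks
#'
#' A `functional_network` is a node set plus a nonnegative weight matrix
#' `w[i, j]` giving the accumulated weight of the directed link i -> j.
#' The diagonal is zero: self-links carry no causal information here.
#'
#' @param w square numeric matrix of nonnegative link weights; dimnames give
#'   the node ids (assigned `"1"..."n"` if missing).
#' @return An object of class `functional_network`: a list with elements
#'   `nodes` (character) and `w` (named matrix).
#' @export
functional_network <- function(w) {
  w <- as.matrix(w)
  if (nrow(w) != ncol(w)) stop("weight matrix must be square", call. = FALSE)
  if (any(w < 0)) stop("link weights must be nonnegative", call. = FALSE)
  if (is.null(rownames(w))) {
    ids <- as.character(seq_len(nrow(w)))
    dimnames(w) <- list(ids, ids)
  }
  if (!identical(rownames(w), colnames(w))) {
    stop("row and column node ids must agree", call. = FALSE)
  }
  diag(w) <- 0
  structure(list(nodes = rownames(w), w = w), class = "functional_network")
}

#' @export
print.functional_network <- function(x, ...) {
  cat(sprintf("Directed weighted functional network: %d nodes, %d links, total weight %.4g\n",
              length(x$nodes), sum(x$w > 0), sum(x$w)))
  invisible(x)
}

#' Node degrees and strengths
#'
#' Degrees count nonzero links; strengths sum link weights. `out` follows
#' rows of the weight matrix (i -> j), `in` follows columns.
#'
#' @param net a `functional_network`.
#' @return Named numeric vector over the network's nodes.
#' @name node-measures
NULL

#' @rdname node-measures
#' @export
out_degree <- function(net) rowSums(net$w > 0)

#' @rdname node-measures
#' @export
in_degree <- function(net) colSums(net$w > 0)

#' @rdname node-measures
#' @export
out_strength <- function(net) rowSums(net$w)

#' @rdname node-measures
#' @export
in_strength <- function(net) colSums(net$w)

#' @rdname node-measures
#' @export
total_strength <- function(net) sum(net$w)

#' Number of directed links with nonzero weight
#' @param net a `functional_network`.
#' @return Integer count of nonzero off-diagonal entries.
#' @export
n_links <- function(net) sum(net$w > 0)
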