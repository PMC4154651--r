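#' Activation event trains
#'
#' An `event_train` holds the time-ordered ignition events of one recording:
#' one row per event with the node (cluster) identifier and the onset time in
#' seconds. The declared node set may be larger than the set of nodes that
#' actually fire; network construction only ever uses active nodes.
#'
#' @param node character or coercible vector of node identifiers.
#' @param time numeric vector of onset times, seconds.
#' @param nodes optional character vector declaring the full node set;
#'   defaults to the sorted unique ids present in `node`.
#' @return A data frame of class `event_train` with columns `node` and
#'   `time`, sorted by time (ties broken by node id), with attribute
#'   `nodes`.
#' @export
event_train <- function(node, time, nodes = NULL) {
  node <- as.character(node)
  time <- as.numeric(time)
  if (length(node) != length(time)) {
    stop("`node` and `time` must have the same length", call. = FALSE)
  }
  if (any(is.na(time))) stop("onset times contain NA", call. = FALSE)
  if (is.null(nodes)) {
    nodes <- sort(unique(node))
  } else {
    nodes <- sort(unique(as.character(nodes)))
    if (!all(node %in% nodes)) {
      stop("events reference nodes outside the declared node set", call. = FALSE)
    }
  }
  ord <- order(time, node)
  out <- data.frame(node = node[ord], time = time[ord],
                    stringsAsFactors = FALSE)
  attr(out, "nodes") <- nodes
  class(out) <- c("event_train", "data.frame")
  out
}

#' @export
print.event_train <- function(x, ...) {
  cat(sprintf("Event train: %d events, %d declared nodes (%d active), %s\n",
              nrow(x), length(attr(x, "nodes")),
              length(unique(x$node)),
              if (nrow(x)) sprintf("span %.2f s", diff(range(x$time))) else "empty"))
  if (nrow(x)) print(utils::head(as.data.frame(x), 10))
  invisible(x)
}

#' Node set of an event train
#' @param train an `event_train`.
#' @return Character vector of declared node ids.
#' @export
train_nodes <- function(train) attr(train, "nodes")

#' Nodes with at least one event
#' @inheritParams train_nodes
#' @return Character vector of node ids that fire at least once, sorted.
#' @export
active_nodes <- function(train) sort(unique(train$node))
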