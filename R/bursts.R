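#' Segment an event train into bursts
#'
#' A burst is a maximal run of events whose consecutive inter-event gaps do
#' not exceed the cut-off. Two activations separated by more than the
#' cut-off cannot influence one another causally, so the cut-off both
#' terminates bursts and bounds the lags that enter the network weights.
#' Gaps exactly equal to the cut-off stay within the burst.
#'
#' @param train an [event_train()].
#' @param cutoff burst-separation cut-off in seconds (default 0.2, the value
#'   appropriate for clustered-culture recordings; homogeneous-style data
#'   call for a smaller cut-off, e.g. 0.05).
#' @return A list of bursts, each an `event_train` subset (plain data frame
#'   with `node`, `time`) with attributes `start` and `end`.
#' @export
segment_bursts <- function(train, cutoff = 0.2) {
  if (!is.numeric(cutoff) || cutoff <= 0) stop("`cutoff` must be > 0", call. = FALSE)
  n <- nrow(train)
  if (n == 0L) return(list())
  gaps <- diff(train$time)
  # new burst starts wherever the gap to the previous event exceeds cutoff
  burst_id <- cumsum(c(1, as.integer(gaps > cutoff)))
  lapply(split(seq_len(n), burst_id), function(idx) {
    ev <- as.data.frame(train)[idx, , drop = FALSE]
    rownames(ev) <- NULL
    attr(ev, "start") <- ev$time[1L]
    attr(ev, "end") <- ev$time[nrow(ev)]
    ev
  })
}

#' Fit the within-burst lag distribution
#'
#' Collects the time lags between pairs of consecutive firings inside each
#' burst and fits the Gaussian-decaying lag frequency
#' G(dt) = exp(-dt^2 / (2 sigma^2)). The width sigma is culture-specific and
#' defines the weight function used in network construction.
#'
#' Two estimators are available. `"mle"` (default) is the half-normal
#' maximum-likelihood estimate sigma = sqrt(mean(dt^2)), which is
#' binning-free. `"hist"` performs a least-squares fit of
#' A * exp(-dt^2/(2 sigma^2)) to the lag frequency histogram, closer to a
#' graphical fit of the lag distribution.
#'
#' @param bursts list of bursts from [segment_bursts()].
#' @param method `"mle"` or `"hist"`.
#' @param n_bins histogram bin count for `method = "hist"`.
#' @return A `lag_model`: list with `lags`, `sigma` (seconds), `fit_method`,
#'   and `cutoff` (largest observed lag bound, carried for reference).
#' @export
fit_lag_model <- function(bursts, method = c("mle", "hist"), n_bins = 20) {
  method <- match.arg(method)
  lags <- unlist(lapply(bursts, function(b) diff(b$time)), use.names = FALSE)
  if (is.null(lags)) lags <- numeric(0)
  pos <- lags[lags > 0]
  if (length(pos) < 10L) {
    stop(sprintf("too few nonzero within-burst lags to fit (%d, need >= 10)",
                 length(pos)), call. = FALSE)
  }
  sigma <- switch(method,
    mle = sqrt(mean(pos^2)),
    hist = {
      h <- graphics::hist(pos, breaks = n_bins, plot = FALSE)
      mids <- h$mids
      cnt <- h$counts
      sse <- function(s) {
        b <- exp(-mids^2 / (2 * s^2))
        a <- sum(cnt * b) / sum(b^2)  # profiled amplitude
        sum((cnt - a * b)^2)
      }
      stats::optimize(sse, interval = c(min(pos) / 10, max(pos)))$minimum
    })
  structure(list(lags = lags, sigma = sigma, fit_method = method,
                 cutoff = max(lags)), class = "lag_model")
}

#' @export
print.lag_model <- function(x, ...) {
  cat(sprintf("Lag model: %d lags, sigma = %.4g s (%s fit)\n",
              length(x$lags), x$sigma, x$fit_method))
  invisible(x)
}

#' Gaussian delay weight
#'
#' The causal weight assigned to an activation pair with delay `dt`,
#' g(dt) = exp(-dt^2 / (2 sigma^2)): influence fades with the time elapsed
#' since the upstream node fired, on the scale sigma fitted from the
#' culture's own lag distribution.
#'
#' @param dt nonnegative delay(s), seconds.
#' @param sigma positive Gaussian width, seconds.
#' @return Weight(s) in (0, 1]; g(0) = 1.
#' @export
gaussian_weight <- function(dt, sigma) {
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma <= 0) {
    stop("`sigma` must be a positive scalar", call. = FALSE)
  }
  if (any(dt < 0)) stop("delays must be nonnegative", call. = FALSE)
  exp(-dt^2 / (2 * sigma^2))
}

#' Build the delay-weighted directed functional network
#'
#' Within each burst, every ordered pair of active nodes (a, b) with
#' 0 < t_b - t_a <= cutoff contributes g(t_b - t_a) to the weight of the
#' link a -> b: a node is assumed to influence every node that ignites
#' after it within the causal window, not only the next one. Pairs igniting
#' at exactly the same time are treated as a bi-directional link and
#' contribute weight 1 to both directions, since no causal order can be
#' inferred. Weights accumulate (are reinforced) across bursts. If a node
#' fires more than once inside one burst, only its first onset is used.
#' Only nodes with at least one event appear in the network.
#'
#' Beyond a few lag widths the Gaussian influence is negligible and two
#' clusters separated by such a delay are functionally disconnected, so by
#' default pairs with lag above `influence_horizon * sigma` contribute no
#' link at all; set `influence_horizon = Inf` to let every pair up to the
#' cut-off contribute its (possibly vanishing) weight.
#'
#' @param bursts list of bursts from [segment_bursts()].
#' @param lag_model a [fit_lag_model()] result (or any list with a positive
#'   `sigma`).
#' @param cutoff causal window in seconds; pairs with larger lags are not
#'   linked (default 0.2).
#' @param influence_horizon causal-influence horizon in units of sigma
#'   (default 2.5); the effective window is
#'   `min(cutoff, influence_horizon * sigma)`.
#' @return A [functional_network()] over the active nodes.
#' @export
build_functional_network <- function(bursts, lag_model, cutoff = 0.2,
                                     influence_horizon = 2.5) {
  sigma <- lag_model$sigma
  if (is.null(sigma) || sigma <= 0) stop("lag model must carry sigma > 0", call. = FALSE)
  window <- min(cutoff, influence_horizon * sigma)
  ids <- sort(unique(unlist(lapply(bursts, function(b) b$node), use.names = FALSE)))
  n <- length(ids)
  w <- matrix(0, n, n, dimnames = list(ids, ids))
  for (b in bursts) {
    # first onset per node within the burst
    first <- !duplicated(b$node)
    nd <- b$node[first]
    tt <- b$time[first]
    if (length(nd) < 2L) next
    for (a in seq_along(nd)) {
      dt <- tt - tt[a]
      sel <- which(dt >= 0 & dt <= window)
      sel <- sel[sel != a]
      for (k in sel) {
        if (tt[k] > tt[a]) {
          w[nd[a], nd[k]] <- w[nd[a], nd[k]] + exp(-dt[k]^2 / (2 * sigma^2))
        } else if (nd[a] < nd[k]) {
          # simultaneous pair, counted once: unit weight both ways
          w[nd[a], nd[k]] <- w[nd[a], nd[k]] + 1
          w[nd[k], nd[a]] <- w[nd[k], nd[a]] + 1
        }
      }
    }
  }
  functional_network(w)
}

#' Variation of information between two partitions
#'
#' VI(A, B) = H(A) + H(B) - 2 I(A, B) in nats, a metric distance between
#' two partitions of the same items. Used here to compare the burst
#' groupings induced by neighbouring cut-off values.
#'
#' @param partition_a,partition_b membership vectors of equal length:
#'   element i gives the group of item i.
#' @return Nonnegative VI in nats; 0 iff the partitions coincide.
#' @export
variation_of_information <- function(partition_a, partition_b) {
  if (length(partition_a) != length(partition_b)) {
    stop("partitions must cover the same items", call. = FALSE)
  }
  n <- length(partition_a)
  if (n == 0L) return(0)
  joint <- table(partition_a, partition_b) / n
  pa <- rowSums(joint)
  pb <- colSums(joint)
  ent <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
  mi <- sum(ifelse(joint > 0, joint * log(joint / outer(pa, pb)), 0))
  vi <- ent(pa) + ent(pb) - 2 * mi
  if (abs(vi) < 1e-12) 0 else max(0, vi)
}

#' Burst-partition sensitivity to the cut-off
#'
#' Screens a grid of cut-off values: for each consecutive pair of cut-offs
#' the events are segmented into bursts and the variation of information
#' between the two burst partitions is computed. A stable plateau (VI
#' staying below `threshold` for all subsequent steps) indicates that the
#' inferred grouping -- and hence the functional network -- no longer
#' depends on the precise cut-off.
#'
#' @param train an [event_train()].
#' @param cutoff_grid increasing numeric vector of cut-offs (>= 2 values),
#'   seconds.
#' @param threshold VI level (nats) below which the partition is considered
#'   stable (default 1e-9, i.e. identical partitions).
#' @return Data frame with `cutoff`, `vi` (VI against the previous grid
#'   value; first row refers to the second grid point), and attribute
#'   `plateau_start`: the smallest cut-off from which all following VI
#'   values stay below `threshold` (NA if never).
#' @export
cutoff_sensitivity <- function(train, cutoff_grid, threshold = 1e-9) {
  if (length(cutoff_grid) < 2L || is.unsorted(cutoff_grid, strictly = TRUE)) {
    stop("`cutoff_grid` must be increasing with >= 2 values", call. = FALSE)
  }
  membership <- function(cutoff) {
    if (nrow(train) == 0L) return(integer(0))
    cumsum(c(1, as.integer(diff(train$time) > cutoff)))
  }
  parts <- lapply(cutoff_grid, membership)
  vi <- vapply(seq_len(length(parts) - 1L), function(k) {
    variation_of_information(parts[[k]], parts[[k + 1L]])
  }, numeric(1))
  out <- data.frame(cutoff = cutoff_grid[-1L], vi = vi)
  stable <- vi <= threshold
  plateau <- NA_real_
  for (k in seq_along(stable)) {
    if (all(stable[k:length(stable)])) { plateau <- cutoff_grid[k]; break }
  }
  attr(out, "plateau_start") <- plateau
  out
}
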