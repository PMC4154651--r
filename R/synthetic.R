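#' Parameters of the burst-cascade generator
#'
#' The generator emulates the spontaneous dynamics of clustered cultures:
#' bursts in which a group of nodes ignites sequentially within a short
#' window, separated by quiescent intervals of tens of seconds.
#' Activation propagates along the ground-truth links as a sequential
#' ignition wave (see [simulate_bursts()]): successive ignitions are
#' separated by lags drawn from a Gaussian truncated to (0, delay_max] --
#' so consecutive activation lags sit well below the 200 ms burst cut-off
#' and their frequency distribution has the Gaussian-decay shape the
#' network construction fits.
#'
#' @param delay_mean mean parent-to-child activation delay, seconds
#'   (default 0.030).
#' @param delay_sd delay standard deviation, seconds (default 0.015).
#' @param delay_max upper truncation of the delay, seconds (default 0.100,
#'   half the burst cut-off).
#' @param transmission_scale maps link weight to recruitment probability
#'   p = 1 - exp(-transmission_scale * w) (default 0.2: at unit weights
#'   and mean out-degree around 6 the ignition wave typically engages a
#'   handful of nodes before stalling, matching the conditional,
#'   subset-wise bursts of clustered cultures).
#' @param inter_burst_interval_mean mean quiescent gap between bursts,
#'   seconds (default 30).
#' @param n_bursts number of bursts to simulate (default 100).
#' @param refractory if TRUE (default) a node fires at most once per burst.
#' @param initiator_probs optional probability per node of seeding a burst
#'   (default uniform).
#' @param snap_fraction fraction of event times snapped to the acquisition
#'   frame grid, to inject simultaneous activations (default 0).
#' @param frame_rate acquisition frame rate used for snapping, frames/s
#'   (default 33).
#' @return A validated `cascade_params` list.
#' @export
cascade_params <- function(delay_mean = 0.030, delay_sd = 0.015,
                           delay_max = 0.100, transmission_scale = 0.2,
                           inter_burst_interval_mean = 30, n_bursts = 100,
                           refractory = TRUE, initiator_probs = NULL,
                           snap_fraction = 0, frame_rate = 33) {
  stopifnot(delay_mean > 0, delay_mean <= delay_max, delay_sd > 0,
            transmission_scale > 0, inter_burst_interval_mean > 0,
            n_bursts >= 1, snap_fraction >= 0, snap_fraction <= 1,
            frame_rate > 0)
  structure(list(delay_mean = delay_mean, delay_sd = delay_sd,
                 delay_max = delay_max,
                 transmission_scale = transmission_scale,
                 inter_burst_interval_mean = inter_burst_interval_mean,
                 n_bursts = n_bursts, refractory = refractory,
                 initiator_probs = initiator_probs,
                 snap_fraction = snap_fraction, frame_rate = frame_rate),
            class = "cascade_params")
}

# truncated-Gaussian delays on (0, delay_max]
rtrunc_delay <- function(n, mean, sd, max) {
  out <- numeric(0)
  while (length(out) < n) {
    d <- stats::rnorm(n, mean, sd)
    out <- c(out, d[d > 0 & d <= max])
  }
  out[seq_len(n)]
}

directed_degree_assortativity <- function(src, dst, kout, kin) {
  stats::cor(kout[src], kin[dst])
}

#' Generate a ground-truth network with planted assortativity
#'
#' Draws heterogeneous out-degrees from a log-normal law (producing the
#' strength heterogeneity rich-club analysis needs), wires each node to
#' random targets, assigns log-normal link weights, and then applies
#' degree-preserving double-edge swaps, accepting only swaps that move the
#' unweighted directed degree assortativity (source out-degree vs target
#' in-degree over edges) toward the target value.
#'
#' @param n_nodes number of nodes (>= 3).
#' @param mean_out_degree mean number of outgoing links per node
#'   (< n_nodes).
#' @param weight_scale median link weight (default 1).
#' @param target_assortativity desired unweighted directed assortativity in
#'   `[-1, 1]` (default 0).
#' @param seed integer seed.
#' @param swap_budget maximum swap proposals (default 20000).
#' @param tol stop once the realized assortativity is within `tol` of the
#'   target (default 0.02).
#' @return A `ground_truth_network`: list with `n_nodes`, `nodes`,
#'   `weights` (matrix), `planted_assortativity` (the target),
#'   `realized_assortativity`, `converged` (FALSE flags an unreachable
#'   target within the swap budget), `seed`.
#' @export
generate_planted_network <- function(n_nodes, mean_out_degree,
                                     weight_scale = 1,
                                     target_assortativity = 0, seed = 1L,
                                     swap_budget = 20000, tol = 0.02) {
  if (n_nodes < 3L) stop("need at least 3 nodes", call. = FALSE)
  if (mean_out_degree >= n_nodes) stop("mean_out_degree must be < n_nodes", call. = FALSE)
  if (abs(target_assortativity) > 1) stop("target must lie in [-1, 1]", call. = FALSE)
  res <- withr::with_seed(seed, {
    sdlog <- 0.5
    raw <- stats::rlnorm(n_nodes, log(mean_out_degree) - sdlog^2 / 2, sdlog)
    # rescale so the realized mean degree hits the target despite the
    # truncation at n - 1
    k <- pmin(pmax(round(raw * mean_out_degree / mean(raw)), 1L), n_nodes - 1L)
    for (adj in 1:3) {
      deficit <- round(n_nodes * mean_out_degree) - sum(k)
      if (deficit == 0) break
      room <- if (deficit > 0) which(k < n_nodes - 1L) else which(k > 1L)
      if (!length(room)) break
      bump <- sample(room, min(abs(deficit), length(room)))
      k[bump] <- k[bump] + sign(deficit)
    }
    src <- rep(seq_len(n_nodes), k)
    dst <- unlist(lapply(seq_len(n_nodes), function(i) {
      sample(setdiff(seq_len(n_nodes), i), k[i])
    }), use.names = FALSE)
    m <- length(src)
    w <- stats::rlnorm(m, log(weight_scale) - 0.125, 0.5)
    kout <- tabulate(src, n_nodes)
    kin <- tabulate(dst, n_nodes)
    key <- function(s, d) (s - 1) * n_nodes + d
    present <- new.env(hash = TRUE)
    for (e in seq_len(m)) assign(as.character(key(src[e], dst[e])), TRUE, present)
    r <- directed_degree_assortativity(src, dst, kout, kin)
    converged <- is.finite(r) && abs(r - target_assortativity) <= tol
    tries <- 0L
    while (!converged && tries < swap_budget) {
      tries <- tries + 1L
      e <- sample.int(m, 2L)
      i <- src[e[1L]]; j <- dst[e[1L]]
      kk <- src[e[2L]]; l <- dst[e[2L]]
      if (i == l || kk == j || i == kk || j == l) next
      if (exists(as.character(key(i, l)), present) ||
          exists(as.character(key(kk, j)), present)) next
      src2 <- src; dst2 <- dst
      dst2[e[1L]] <- l; dst2[e[2L]] <- j
      r2 <- directed_degree_assortativity(src2, dst2, kout, kin)
      if (is.finite(r2) &&
          abs(r2 - target_assortativity) < abs(r - target_assortativity)) {
        rm(list = c(as.character(key(i, j)), as.character(key(kk, l))),
           envir = present)
        assign(as.character(key(i, l)), TRUE, present)
        assign(as.character(key(kk, j)), TRUE, present)
        src <- src2; dst <- dst2
        r <- r2
        converged <- abs(r - target_assortativity) <= tol
      }
    }
    ids <- sprintf("n%02d", seq_len(n_nodes))
    wm <- matrix(0, n_nodes, n_nodes, dimnames = list(ids, ids))
    wm[cbind(src, dst)] <- w
    list(weights = wm, realized = r, converged = converged)
  })
  if (!res$converged) {
    warning(sprintf("target assortativity %.3f not reached (realized %.3f)",
                    target_assortativity, res$realized), call. = FALSE)
  }
  structure(list(n_nodes = n_nodes, nodes = rownames(res$weights),
                 weights = res$weights,
                 planted_assortativity = target_assortativity,
                 realized_assortativity = res$realized,
                 converged = res$converged, seed = seed),
            class = "ground_truth_network")
}

#' @export
print.ground_truth_network <- function(x, ...) {
  cat(sprintf("Ground-truth network: %d nodes, %d links, assortativity %.3f (target %.3f%s)\n",
              x$n_nodes, sum(x$weights > 0), x$realized_assortativity,
              x$planted_assortativity,
              if (x$converged) "" else ", NOT reached"))
  invisible(x)
}

#' Simulate burst cascades on a ground-truth network
#'
#' Each burst is seeded by one initiator and unfolds as a sequential
#' ignition wave, the dynamical signature of clustered cultures: one node
#' ignites at a time, each ignition following the previous one after a
#' truncated-Gaussian lag. When a node fires, each of its not-yet-fired
#' out-neighbours is recruited with probability
#' 1 - exp(-transmission_scale * w) (one trial per link per burst);
#' recruited candidates ignite one by one, preferring children of the most
#' recently fired node (the advancing wavefront), and a candidate whose
#' recruiting parent fired more than `delay_max` ago lapses -- the
#' subthreshold drive has faded. The burst ends when no viable candidate
#' remains. Bursts are separated by quiescent gaps drawn around
#' `inter_burst_interval_mean`, far above the delay scale. Realized
#' parent-to-child transmissions are recorded for ground-truth
#' comparisons.
#'
#' @param net a `ground_truth_network` (or any list with a square
#'   `weights` matrix with node ids as dimnames).
#' @param params a [cascade_params()].
#' @param seed integer seed.
#' @return An [event_train()] over the network's nodes, with attributes
#'   `transmissions` (data frame `src`, `dst` of realized activations),
#'   `burst_id` (integer per event, in time order), and `singleton_only`
#'   (TRUE when the network has no links, so every burst is just its
#'   initiator).
#' @export
simulate_bursts <- function(net, params = cascade_params(), seed = 1L) {
  w <- net$weights
  ids <- rownames(w)
  n <- length(ids)
  if (n == 0L) stop("network is empty", call. = FALSE)
  p_edge <- 1 - exp(-params$transmission_scale * w)
  has_edges <- any(w > 0)
  withr::with_seed(seed, {
    ibi <- params$inter_burst_interval_mean
    gaps <- pmax(ibi / 3, stats::rnorm(params$n_bursts, ibi, 0.15 * ibi))
    starts <- cumsum(gaps)
    ev_node <- integer(0); ev_time <- numeric(0); ev_burst <- integer(0)
    tr_src <- integer(0); tr_dst <- integer(0)
    probs <- params$initiator_probs
    for (b in seq_len(params$n_bursts)) {
      init <- sample.int(n, 1L, prob = probs)
      fired <- rep(FALSE, n)
      t_fire <- rep(NA_real_, n)
      fired[init] <- TRUE
      t_fire[init] <- starts[b]
      ev_node <- c(ev_node, init); ev_time <- c(ev_time, starts[b])
      ev_burst <- c(ev_burst, b)
      pool_p <- integer(0); pool_c <- integer(0)
      recruit <- function(i) {
        nb <- which(w[i, ] > 0)
        if (params$refractory) nb <- nb[!fired[nb]]
        ok <- nb[stats::runif(length(nb)) < p_edge[i, nb]]
        pool_p <<- c(pool_p, rep(i, length(ok)))
        pool_c <<- c(pool_c, ok)
      }
      recruit(init)
      t_last <- starts[b]
      n_fired <- 1L
      while (length(pool_p) && n_fired < 10L * n) {
        keep <- (t_last - t_fire[pool_p]) < params$delay_max
        if (params$refractory) keep <- keep & !fired[pool_c]
        pool_p <- pool_p[keep]; pool_c <- pool_c[keep]
        if (!length(pool_p)) break
        # wavefront: prefer candidates recruited by the most recent igniter
        front <- which(t_fire[pool_p] == max(t_fire[pool_p]))
        k <- front[sample.int(length(front), 1L)]
        par <- pool_p[k]; ch <- pool_c[k]
        lo <- t_last - t_fire[par]
        d <- NA_real_
        for (try in 1:50) {
          dd <- rtrunc_delay(1L, params$delay_mean, params$delay_sd,
                             params$delay_max)
          if (dd > lo) { d <- dd; break }
        }
        if (is.na(d)) { pool_p <- pool_p[-k]; pool_c <- pool_c[-k]; next }
        t_ch <- t_fire[par] + d
        fired[ch] <- TRUE
        t_fire[ch] <- t_ch
        n_fired <- n_fired + 1L
        ev_node <- c(ev_node, ch); ev_time <- c(ev_time, t_ch)
        ev_burst <- c(ev_burst, b)
        tr_src <- c(tr_src, par); tr_dst <- c(tr_dst, ch)
        t_last <- t_ch
        recruit(ch)
      }
    }
    if (params$snap_fraction > 0 && length(ev_time)) {
      snap <- stats::runif(length(ev_time)) < params$snap_fraction
      ev_time[snap] <- round(ev_time[snap] * params$frame_rate) / params$frame_rate
    }
    train <- event_train(ids[ev_node], ev_time, nodes = ids)
    attr(train, "burst_id") <- ev_burst[order(ev_time, ids[ev_node])]
    attr(train, "transmissions") <- data.frame(src = ids[tr_src],
                                               dst = ids[tr_dst],
                                               stringsAsFactors = FALSE)
    attr(train, "singleton_only") <- !has_edges
    train
  })
}

#' Parameters of the fluorescence synthesizer
#'
#' Emulates calcium-fluorescence transients: at each ignition the signal
#' rises sharply (linearly over a few frames) and then decays exponentially
#' back to the baseline over seconds, on top of an optional linear drift
#' and white acquisition noise.
#'
#' @param frame_rate acquisition rate, frames/s (default 33).
#' @param rise_frames frames of linear rise to the transient peak
#'   (default 3).
#' @param decay_tau exponential decay time constant, seconds (default 2).
#' @param amplitude transient peak amplitude, fluorescence units
#'   (default 20).
#' @param noise_sd white-noise standard deviation, fluorescence units
#'   (default 1).
#' @param drift_slope linear drift, fluorescence units per second
#'   (default 0).
#' @param baseline resting fluorescence level, units (default 100).
#' @return A validated `trace_params` list.
#' @export
trace_params <- function(frame_rate = 33, rise_frames = 3, decay_tau = 2,
                         amplitude = 20, noise_sd = 1, drift_slope = 0,
                         baseline = 100) {
  stopifnot(frame_rate > 0, rise_frames >= 1, decay_tau > 0,
            decay_tau > rise_frames / frame_rate, amplitude > 0,
            noise_sd >= 0, baseline > 0)
  structure(list(frame_rate = frame_rate, rise_frames = rise_frames,
                 decay_tau = decay_tau, amplitude = amplitude,
                 noise_sd = noise_sd, drift_slope = drift_slope,
                 baseline = baseline), class = "trace_params")
}

#' Synthesize fluorescence traces from an event train
#'
#' Renders each activation as a transient (linear rise over `rise_frames`
#' frames starting at the onset frame, exponential decay with
#' `decay_tau`); overlapping transients sum. Baseline, linear drift and
#' white noise are added.
#'
#' @param train an [event_train()].
#' @param tp a [trace_params()].
#' @param seed integer seed for the noise.
#' @param duration recording length in seconds; default covers the last
#'   event plus `5 * decay_tau`.
#' @return Numeric matrix (frames x nodes), column names the node ids,
#'   with attributes `frame_rate` and `crowded` (TRUE if some node has two
#'   events closer than the transient rise, i.e. the frame rate cannot
#'   separate them).
#' @export
synthesize_fluorescence <- function(train, tp = trace_params(), seed = 1L,
                                    duration = NULL) {
  fr <- tp$frame_rate
  if (is.null(duration)) {
    if (nrow(train) == 0L) stop("empty train needs an explicit `duration`", call. = FALSE)
    duration <- max(train$time) + 5 * tp$decay_tau
  }
  n_frames <- max(20L, ceiling(duration * fr))
  ids <- train_nodes(train)
  crowded <- FALSE
  if (nrow(train)) {
    gaps <- unlist(lapply(split(train$time, train$node),
                          function(tt) diff(sort(tt))), use.names = FALSE)
    if (length(gaps) && any(gaps < (tp$rise_frames + 1) / fr)) {
      crowded <- TRUE
      warning("frame rate too low to separate some same-node events", call. = FALSE)
    }
  }
  # transient template: 0 at the onset frame, linear rise, exp decay
  n_tail <- ceiling(5 * tp$decay_tau * fr)
  template <- c(seq_len(tp$rise_frames) / tp$rise_frames,
                exp(-(seq_len(n_tail)) / (tp$decay_tau * fr))) * tp$amplitude
  tvec <- (seq_len(n_frames) - 1L) / fr
  out <- withr::with_seed(seed, {
    base <- tp$baseline + tp$drift_slope * tvec
    m <- matrix(stats::rnorm(n_frames * length(ids), 0, tp$noise_sd),
                n_frames, length(ids))
    m <- m + base
    colnames(m) <- ids
    for (e in seq_len(nrow(train))) {
      f0 <- floor(train$time[e] * fr) + 1L  # 1-based frame of the onset
      idx <- f0 + seq_along(template)
      keep <- idx <= n_frames
      m[idx[keep], train$node[e]] <- m[idx[keep], train$node[e]] + template[keep]
    }
    m
  })
  attr(out, "frame_rate") <- fr
  attr(out, "crowded") <- crowded
  out
}

#' Synthetic study scenarios: clustered vs homogeneous dynamics
#'
#' Generates the two dynamical regimes contrasted in clustered-culture
#' work. `"clustered"` plants a modular ground truth (dense, strong
#' within-module links with module-specific weight scales; sparse weak
#' cross-links) and simulates bursts that ignite essentially one module at
#' a time -- the conditional, subset-wise activity of clustered cultures.
#' `"homogeneous"` plants a dense uniform network with strong links, so
#' every burst recruits (nearly) the whole population coherently.
#'
#' @param type `"clustered"` or `"homogeneous"`.
#' @param n_nodes number of nodes (default 25).
#' @param n_bursts number of bursts (default 150).
#' @param seed integer seed.
#' @return List with `type`, `net` (ground-truth weight matrix wrapper)
#'   and `train` (the simulated [event_train()]).
#' @export
simulate_scenario <- function(type = c("clustered", "homogeneous"),
                              n_nodes = 25, n_bursts = 150, seed = 1L) {
  type <- match.arg(type)
  ids <- sprintf("n%02d", seq_len(n_nodes))
  w <- withr::with_seed(seed, {
    w <- matrix(0, n_nodes, n_nodes, dimnames = list(ids, ids))
    if (type == "clustered") {
      sizes <- integer(0)
      while (sum(sizes) < n_nodes) {
        sizes <- c(sizes, sample(4:8, 1L))
      }
      sizes[length(sizes)] <- sizes[length(sizes)] - (sum(sizes) - n_nodes)
      if (sizes[length(sizes)] < 2L) {
        sizes[length(sizes) - 1L] <- sizes[length(sizes) - 1L] + sizes[length(sizes)]
        sizes <- sizes[-length(sizes)]
      }
      module <- rep(seq_along(sizes), sizes)
      scale_m <- stats::rlnorm(length(sizes), 0, 0.6)
      for (i in seq_len(n_nodes)) for (j in seq_len(n_nodes)) {
        if (i == j) next
        if (module[i] == module[j]) {
          if (stats::runif(1) < 0.8) {
            w[i, j] <- stats::rlnorm(1, log(2 * scale_m[module[i]]), 0.3)
          }
        } else if (stats::runif(1) < 0.02) {
          w[i, j] <- 0.05
        }
      }
    } else {
      mask <- matrix(stats::runif(n_nodes^2) < 0.5, n_nodes)
      diag(mask) <- FALSE
      w[mask] <- stats::rlnorm(sum(mask), log(2), 0.2)
    }
    w
  })
  net <- list(n_nodes = n_nodes, nodes = ids, weights = w)
  params <- cascade_params(transmission_scale = if (type == "clustered") 1.5 else 1.5,
                           n_bursts = n_bursts)
  train <- simulate_bursts(net, params, seed = seed + 1L)
  list(type = type, net = net, train = train)
}

#' Random unit-weight digraph
#'
#' Uniformly samples `n_edges` distinct directed links (no self-links)
#' among `n_nodes` nodes, all with unit weight. Used as a reference
#' topology for consistency checks of the summary statistics.
#'
#' @param n_nodes,n_edges node and directed-link counts;
#'   `n_edges <= n_nodes * (n_nodes - 1)`.
#' @param seed integer seed.
#' @return A [functional_network()].
#' @export
random_network <- function(n_nodes, n_edges, seed = 1L) {
  stopifnot(n_edges <= n_nodes * (n_nodes - 1))
  withr::with_seed(seed, {
    # sample ordered pairs by linear index, skipping the diagonal
    all_pairs <- n_nodes * (n_nodes - 1L)
    pick <- sample.int(all_pairs, n_edges)
    src <- (pick - 1L) %/% (n_nodes - 1L) + 1L
    off <- (pick - 1L) %% (n_nodes - 1L) + 1L
    dst <- ifelse(off >= src, off + 1L, off)
    ids <- sprintf("n%04d", seq_len(n_nodes))
    w <- matrix(0, n_nodes, n_nodes, dimnames = list(ids, ids))
    w[cbind(src, dst)] <- 1
    functional_network(w)
  })
}
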