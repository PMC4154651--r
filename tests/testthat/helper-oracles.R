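# Independent oracles used across the suite. These deliberately share no
# code with the package: plain-loop implementations of the statistics, for
# dual-route checks.

# naive weighted Pearson correlation via explicit sums
oracle_weighted_pearson <- function(x, y, w) {
  h <- 0; sx <- 0; sy <- 0
  for (e in seq_along(x)) { h <- h + w[e]; sx <- sx + w[e] * x[e]; sy <- sy + w[e] * y[e] }
  xb <- sx / h; yb <- sy / h
  cxy <- cxx <- cyy <- 0
  for (e in seq_along(x)) {
    cxy <- cxy + w[e] * (x[e] - xb) * (y[e] - yb)
    cxx <- cxx + w[e] * (x[e] - xb)^2
    cyy <- cyy + w[e] * (y[e] - yb)^2
  }
  cxy / sqrt(cxx * cyy)
}

# assortativity of an edge table, computed independently of the package
oracle_assortativity <- function(rec, variant) {
  weighted <- grepl("strength-weighted", variant)
  x <- if (weighted) rec$src_out_strength else rec$src_out_degree
  y <- if (weighted) rec$dst_in_strength else rec$dst_in_degree
  if (grepl("spearman", variant)) {
    rank_by_node <- function(node, val) {
      tab <- unique(data.frame(node = node, val = val))
      r <- rank(tab$val, ties.method = "average")
      r[match(node, tab$node)]
    }
    x <- rank_by_node(rec$src, x)
    y <- rank_by_node(rec$dst, y)
  }
  w <- if (weighted) rec$weight else rep(1, nrow(rec))
  oracle_weighted_pearson(x, y, w)
}

# random weighted digraph with n_edges links among n nodes
random_digraph_net <- function(n, n_edges, seed) {
  withr::with_seed(seed, {
    pairs <- expand.grid(src = seq_len(n), dst = seq_len(n))
    pairs <- pairs[pairs$src != pairs$dst, ]
    pick <- pairs[sample.int(nrow(pairs), n_edges), ]
    ids <- sprintf("v%02d", seq_len(n))
    w <- matrix(0, n, n, dimnames = list(ids, ids))
    w[cbind(pick$src, pick$dst)] <- stats::rlnorm(n_edges, 0, 0.7)
    functional_network(w)
  })
}

# brute-force delay-network accumulation for tiny trains (all ordered
# pairs enumerated explicitly, mirroring the construction contract)
oracle_build_network <- function(bursts, sigma, cutoff, horizon = 2.5) {
  ids <- sort(unique(unlist(lapply(bursts, function(b) b$node))))
  w <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  win <- min(cutoff, horizon * sigma)
  for (b in bursts) {
    keep <- !duplicated(b$node)
    nd <- b$node[keep]; tt <- b$time[keep]
    for (i in seq_along(nd)) for (j in seq_along(nd)) {
      if (i == j) next
      dt <- tt[j] - tt[i]
      if (dt > 0 && dt <= win) {
        w[nd[i], nd[j]] <- w[nd[i], nd[j]] + exp(-dt^2 / (2 * sigma^2))
      } else if (dt == 0 && i < j) {
        w[nd[i], nd[j]] <- w[nd[i], nd[j]] + 1
        w[nd[j], nd[i]] <- w[nd[j], nd[i]] + 1
      }
    }
  }
  w
}

# shared fixture: a small planted system simulated once per session
fixture_small_system <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      gt <- suppressWarnings(
        generate_planted_network(10, 3, target_assortativity = 0, seed = 71))
      tr <- simulate_bursts(
        gt, cascade_params(n_bursts = 200, inter_burst_interval_mean = 10,
                           transmission_scale = 0.5), seed = 81)
      bursts <- segment_bursts(tr, 0.2)
      lagm <- fit_lag_model(bursts)
      cache <<- list(gt = gt, train = tr, bursts = bursts, lag = lagm,
                     net = build_functional_network(bursts, lagm, 0.2))
    }
    cache
  }
})
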