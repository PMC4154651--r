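#' Edge table of a functional network
#'
#' One record per nonzero directed link, carrying the endpoint properties
#' the assortativity measures correlate: the source's out-degree and
#' out-strength and the target's in-degree and in-strength. Reciprocal
#' links yield two records.
#'
#' @param net a [functional_network()].
#' @return Data frame with columns `src`, `dst`, `weight`,
#'   `src_out_degree`, `dst_in_degree`, `src_out_strength`,
#'   `dst_in_strength`.
#' @export
edge_table <- function(net) {
  if (length(net$nodes) == 0L) stop("network is empty", call. = FALSE)
  idx <- which(net$w > 0, arr.ind = TRUE)
  kout <- out_degree(net); kin <- in_degree(net)
  sout <- out_strength(net); sin <- in_strength(net)
  data.frame(
    src = net$nodes[idx[, 1L]],
    dst = net$nodes[idx[, 2L]],
    weight = net$w[idx],
    src_out_degree = kout[idx[, 1L]],
    dst_in_degree = kin[idx[, 2L]],
    src_out_strength = sout[idx[, 1L]],
    dst_in_strength = sin[idx[, 2L]],
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Weighted Pearson correlation over edges
#'
#' Correlation of endpoint properties (x_e, y_e) across edges e, with each
#' edge contributing proportionally to its weight w_e: means are weighted
#' means over the total weight H = sum(w_e), and
#' r = sum(w_e (x - xbar)(y - ybar)) /
#'     sqrt(sum(w_e (x - xbar)^2) * sum(w_e (y - ybar)^2)).
#' With all w_e equal this reduces to the plain Pearson correlation.
#'
#' @param x,y numeric vectors over edges.
#' @param w nonnegative edge weights.
#' @return Correlation in `[-1, 1]`, or NA if either series has zero
#'   weighted variance.
#' @keywords internal
weighted_pearson <- function(x, y, w) {
  h <- sum(w)
  xb <- sum(w * x) / h
  yb <- sum(w * y) / h
  vx <- sum(w * (x - xb)^2)
  vy <- sum(w * (y - yb)^2)
  if (vx <= 0 || vy <= 0) return(NA_real_)
  sum(w * (x - xb) * (y - yb)) / sqrt(vx * vy)
}

# ranks endpoint values by their node-level position (mid-ranks for ties):
# every distinct node's value enters the ranking once, then each edge
# endpoint is replaced by its node's rank
node_level_ranks <- function(node, value) {
  first <- !duplicated(node)
  rk <- rank(value[first], ties.method = "average")
  names(rk) <- node[first]
  unname(rk[node])
}

#' Directed (weighted) assortativity over an edge table
#'
#' Four variants of the assortativity coefficient for directed networks.
#' All correlate a property of the link source with a property of the link
#' target across edges: `pearson-degree` is Newman's coefficient, the plain
#' Pearson correlation of (source out-degree, target in-degree);
#' `pearson-strength-weighted` correlates (source out-strength, target
#' in-strength) with every edge weighted by its link weight, so that
#' strong links dominate the correlation; the `spearman` variants replace
#' each endpoint value by its rank among the node-level out-strengths
#' (sources) resp. in-strengths (targets) -- mid-ranks for ties -- before
#' applying the same (weighted) correlation. Positive values mean nodes
#' preferentially link to nodes of similar degree/strength.
#'
#' @param records edge table from [edge_table()] (or a resample of it).
#' @param variant one of `"pearson-degree"`, `"spearman-degree"`,
#'   `"pearson-strength-weighted"`, `"spearman-strength-weighted"`.
#' @return List with `variant`, `value`, `n_edges`.
#' @export
assortativity <- function(records,
                          variant = c("pearson-degree", "spearman-degree",
                                      "pearson-strength-weighted",
                                      "spearman-strength-weighted")) {
  variant <- match.arg(variant)
  if (nrow(records) < 3L) stop("need >= 3 edges", call. = FALSE)
  weighted <- grepl("strength-weighted", variant)
  x <- if (weighted) records$src_out_strength else records$src_out_degree
  y <- if (weighted) records$dst_in_strength else records$dst_in_degree
  if (grepl("spearman", variant)) {
    x <- node_level_ranks(records$src, x)
    y <- node_level_ranks(records$dst, y)
  }
  w <- if (weighted) records$weight else rep(1, nrow(records))
  value <- weighted_pearson(x, y, w)
  if (is.na(value)) {
    stop("assortativity undefined: zero variance of endpoint values", call. = FALSE)
  }
  list(variant = variant, value = value, n_edges = nrow(records))
}

#' Bootstrap standard error of an assortativity value
#'
#' Resamples edge records with replacement, recomputes the coefficient, and
#' reports the standard deviation of the resampled values. Resamples with
#' zero endpoint variance (undefined coefficient) are discarded and
#' counted; if more than half are degenerate, or fewer than 2 valid
#' resamples remain, the error is flagged unreliable.
#'
#' @inheritParams assortativity
#' @param n_boot number of bootstrap resamples (default 1000).
#' @param seed integer seed for the resampling.
#' @return List with `stderr`, `n_boot`, `n_degenerate`, `unreliable`.
#' @export
bootstrap_error <- function(records, variant, n_boot = 1000, seed = 1L) {
  if (nrow(records) < 3L) stop("need >= 3 edges", call. = FALSE)
  vals <- withr::with_seed(seed, {
    replicate(n_boot, {
      idx <- sample.int(nrow(records), replace = TRUE)
      tryCatch(assortativity(records[idx, , drop = FALSE], variant)$value,
               error = function(e) NA_real_)
    })
  })
  n_deg <- sum(is.na(vals))
  ok <- vals[!is.na(vals)]
  unreliable <- n_deg > n_boot / 2 || length(ok) < 2L
  list(stderr = if (length(ok) >= 2L) stats::sd(ok) else 0,
       n_boot = n_boot, n_degenerate = n_deg, unreliable = unreliable)
}

#' Assortativity with bootstrap error
#'
#' Convenience wrapper computing one variant's value and its bootstrap
#' standard error from a network.
#'
#' @param net a [functional_network()].
#' @inheritParams assortativity
#' @inheritParams bootstrap_error
#' @return List with `variant`, `value`, `stderr`, `n_edges`, `n_boot`,
#'   `unreliable`.
#' @export
assortativity_with_error <- function(net, variant, n_boot = 1000, seed = 1L) {
  rec <- edge_table(net)
  a <- assortativity(rec, variant)
  b <- bootstrap_error(rec, variant, n_boot = n_boot, seed = seed)
  c(a, b[c("stderr", "n_boot", "unreliable")])
}
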