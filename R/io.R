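#' Read an activation event table
#'
#' Reads a delimited text file with columns (node_id, onset_seconds);
#' a header line is detected automatically. Rows are sorted by time;
#' duplicated (node, time) rows are collapsed with a warning.
#'
#' @param path file path.
#' @param sep field separator (default any whitespace / tab).
#' @return An [event_train()]; empty file gives an empty train with a
#'   warning.
#' @export
read_events <- function(path, sep = "") {
  raw <- tryCatch(
    utils::read.table(path, header = FALSE, sep = sep,
                      colClasses = "character", fill = FALSE,
                      stringsAsFactors = FALSE),
    error = function(e) {
      if (grepl("no lines available", conditionMessage(e))) return(NULL)
      stop(sprintf("cannot parse '%s': %s", path, conditionMessage(e)),
           call. = FALSE)
    })
  if (is.null(raw) || nrow(raw) == 0L) {
    warning(sprintf("'%s' contains no events", path), call. = FALSE)
    return(event_train(character(0), numeric(0)))
  }
  if (ncol(raw) < 2L) stop("expected >= 2 columns (node_id, onset_seconds)", call. = FALSE)
  # drop a header line if the time column is not numeric there
  first_time <- suppressWarnings(as.numeric(raw[1L, 2L]))
  if (is.na(first_time)) raw <- raw[-1L, , drop = FALSE]
  times <- suppressWarnings(as.numeric(raw[[2L]]))
  if (any(is.na(times))) {
    bad <- which(is.na(times))[1L]
    stop(sprintf("unparseable onset time at data row %d of '%s'", bad, path),
         call. = FALSE)
  }
  dup <- duplicated(paste(raw[[1L]], times))
  if (any(dup)) {
    warning(sprintf("collapsed %d duplicated (node, time) rows", sum(dup)),
            call. = FALSE)
  }
  event_train(raw[[1L]][!dup], times[!dup])
}

#' Write an activation event table
#'
#' @param train an [event_train()].
#' @param path output path; tab-separated columns node_id, onset_seconds
#'   (12 significant digits), with a header line.
#' @return `path`, invisibly.
#' @export
write_events <- function(train, path) {
  df <- data.frame(node_id = train$node,
                   onset_seconds = format(train$time, digits = 12,
                                          scientific = FALSE, trim = TRUE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a network as a weighted directed edge list
#'
#' Three tab-separated columns (src, dst, weight) with a header line;
#' weights printed with 12 significant digits so a write/read round-trip
#' reproduces the matrix. Zero-weight pairs are not written.
#'
#' @param net a [functional_network()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path) {
  idx <- which(net$w > 0, arr.ind = TRUE)
  idx <- idx[order(net$nodes[idx[, 1L]], net$nodes[idx[, 2L]]), , drop = FALSE]
  df <- data.frame(src = net$nodes[idx[, 1L]], dst = net$nodes[idx[, 2L]],
                   weight = format(net$w[idx], digits = 12, trim = TRUE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a weighted directed edge list
#'
#' @param path file with >= 3 delimited columns (src, dst, weight); header
#'   detected automatically. Negative weights are an error.
#' @return A [functional_network()].
#' @export
read_network <- function(path) {
  raw <- utils::read.table(path, header = FALSE, colClasses = "character",
                           stringsAsFactors = FALSE)
  if (ncol(raw) < 3L) stop("expected >= 3 columns (src, dst, weight)", call. = FALSE)
  if (is.na(suppressWarnings(as.numeric(raw[1L, 3L])))) raw <- raw[-1L, , drop = FALSE]
  wts <- as.numeric(raw[[3L]])
  if (any(is.na(wts))) stop("unparseable weight", call. = FALSE)
  if (any(wts < 0)) stop("negative weight in edge list", call. = FALSE)
  ids <- sort(unique(c(raw[[1L]], raw[[2L]])))
  w <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  w[cbind(match(raw[[1L]], ids), match(raw[[2L]], ids))] <- wts
  functional_network(w)
}

#' Write / read a fluorescence trace matrix
#'
#' Tab-separated frames x nodes matrix; the first line is a comment header
#' `# frame_rate <fps>`, the second the node ids.
#'
#' @param traces numeric matrix with `frame_rate` attribute.
#' @param path file path.
#' @return `path` (write) or the matrix with `frame_rate` attribute
#'   (read).
#' @export
write_traces <- function(traces, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# frame_rate %.10g", attr(traces, "frame_rate")), con)
  utils::write.table(as.data.frame(traces), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_traces
#' @export
read_traces <- function(path) {
  hdr <- readLines(path, n = 1L)
  if (!grepl("^# frame_rate ", hdr)) stop("missing frame_rate header", call. = FALSE)
  fr <- as.numeric(sub("^# frame_rate ", "", hdr))
  m <- as.matrix(utils::read.table(path, header = TRUE, sep = "\t", skip = 1L,
                                   check.names = FALSE))
  attr(m, "frame_rate") <- fr
  m
}

#' Jaccard overlap of two networks' strongest links
#'
#' Compares the top-`k` links (by weight) of two networks over the same
#' node set; used to cross-validate the delay-based construction against
#' the mutual-information one.
#'
#' @param net_a,net_b [functional_network()] objects.
#' @param k number of top links from each (default: the smaller link
#'   count).
#' @return Jaccard index in `[0, 1]` of the two directed edge sets.
#' @export
top_edge_jaccard <- function(net_a, net_b, k = NULL) {
  top <- function(net, k) {
    idx <- which(net$w > 0, arr.ind = TRUE)
    wts <- net$w[idx]
    ord <- order(wts, decreasing = TRUE)
    idx <- idx[ord[seq_len(min(k, length(wts)))], , drop = FALSE]
    paste(net$nodes[idx[, 1L]], net$nodes[idx[, 2L]], sep = "->")
  }
  if (is.null(k)) k <- min(n_links(net_a), n_links(net_b))
  a <- top(net_a, k); b <- top(net_b, k)
  length(intersect(a, b)) / length(union(a, b))
}

#' Pipeline configuration
#'
#' Collects every tunable parameter of the end-to-end pipeline with its
#' default; the full configuration is embedded in the pipeline report for
#' provenance.
#'
#' @param cutoff burst cut-off, seconds (default 0.2).
#' @param influence_horizon causal-influence horizon in sigma units
#'   (default 2.5), see [build_functional_network()].
#' @param sigma_method lag-fit estimator, `"mle"` or `"hist"`.
#' @param sd_factor,min_frames,smooth_window onset-detection parameters.
#' @param n_background,n_rise sub-frame refinement window sizes.
#' @param n_boot bootstrap resamples for assortativity errors.
#' @param n_thresholds rich-club thresholds.
#' @param run_mi logical: also build the MI network and the overlap score
#'   (default FALSE; it is the expensive cross-check).
#' @param mi_frame_rate,tau_max,n_bins,alpha,n_surrogates MI parameters.
#' @param seed integer master seed.
#' @return A `run_config` list.
#' @export
run_config <- function(cutoff = 0.2, influence_horizon = 2.5,
                       sigma_method = "mle", sd_factor = 2,
                       min_frames = 5, smooth_window = 3, n_background = 10,
                       n_rise = 5, n_boot = 1000, n_thresholds = 50,
                       run_mi = FALSE, mi_frame_rate = 5, tau_max = 3,
                       n_bins = 8, alpha = 0.01, n_surrogates = 200,
                       seed = 1L) {
  structure(as.list(environment()), class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Composes the stages end-to-end: fluorescence traces to onsets (when
#' traces are supplied), burst segmentation, lag-model fit, delay-weighted
#' network construction, topological summary, and (optionally) the
#' MI-based network with its overlap score. Every randomized stage
#' consumes a seed derived from the config's master seed, and the full
#' configuration is embedded in the report.
#'
#' @param config a [run_config()].
#' @param events an [event_train()], or NULL to derive events from
#'   `traces`.
#' @param traces frames x nodes matrix with `frame_rate` attribute
#'   (optional when `events` is given; ignored, with a log message, when
#'   both are given).
#' @return A list report: `provenance` (config, seed, package version),
#'   `stages` (character log), `burst_count`, `burst_sizes`, `sigma`,
#'   `network` (the [functional_network()]), `summary`
#'   ([summarize_network()] block), and optionally `mi` (network +
#'   `jaccard_top_links`).
#' @export
run_pipeline <- function(config = run_config(), events = NULL, traces = NULL) {
  stages <- character(0)
  log_stage <- function(msg) stages <<- c(stages, msg)
  if (is.null(events)) {
    if (is.null(traces)) stop("need `events` or `traces`", call. = FALSE)
    log_stage("traces: onset detection")
    events <- detect_events(traces, sd_factor = config$sd_factor,
                            min_frames = config$min_frames,
                            smooth_window = config$smooth_window,
                            n_background = config$n_background,
                            n_rise = config$n_rise)
  } else if (!is.null(traces)) {
    log_stage("traces ignored: events supplied directly")
  } else {
    log_stage("trace stage skipped: events supplied")
  }
  log_stage(sprintf("segmentation at cutoff %g s", config$cutoff))
  bursts <- segment_bursts(events, config$cutoff)
  lm <- fit_lag_model(bursts, method = config$sigma_method)
  log_stage(sprintf("lag fit (%s): sigma = %.5g s", lm$fit_method, lm$sigma))
  net <- build_functional_network(bursts, lm, config$cutoff,
                                  influence_horizon = config$influence_horizon)
  log_stage(sprintf("network: %d nodes, %d links", length(net$nodes), n_links(net)))
  summ <- summarize_network(net, n_boot = config$n_boot,
                            n_thresholds = config$n_thresholds,
                            seed = config$seed)
  report <- list(
    provenance = list(config = unclass(config), seed = config$seed,
                      package_version = as.character(utils::packageVersion("burstnet"))),
    stages = stages,
    burst_count = length(bursts),
    burst_sizes = vapply(bursts, nrow, integer(1)),
    sigma = lm$sigma,
    network = net,
    summary = summ
  )
  class(report) <- "burstnet_report"
  if (isTRUE(config$run_mi)) {
    mi <- mi_network(events, frame_rate = config$mi_frame_rate,
                     tau_max = config$tau_max, n_bins = config$n_bins,
                     alpha = config$alpha,
                     n_surrogates = config$n_surrogates,
                     seed = config$seed + 1000L)
    report$mi <- list(network = mi,
                      jaccard_top_links = top_edge_jaccard(net, mi))
    report$stages <- c(report$stages,
                       sprintf("MI network: %d significant links", n_links(mi)))
  }
  report
}

#' Serialize a pipeline report to JSON
#'
#' Writes the provenance block, stage log, burst statistics, the network
#' as an edge list, and the topological summary (weight matrices are
#' flattened to edge lists for portability).
#'
#' @param report a [run_pipeline()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  as_edges <- function(net) {
    idx <- which(net$w > 0, arr.ind = TRUE)
    data.frame(src = net$nodes[idx[, 1L]], dst = net$nodes[idx[, 2L]],
               weight = net$w[idx])
  }
  out <- list(
    provenance = report$provenance,
    stages = report$stages,
    burst_count = report$burst_count,
    burst_sizes = report$burst_sizes,
    sigma = report$sigma,
    network = as_edges(report$network),
    summary = report$summary
  )
  if (!is.null(report$mi)) {
    out$mi <- list(network = as_edges(report$mi$network),
                   jaccard_top_links = report$mi$jaccard_top_links)
  }
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}
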