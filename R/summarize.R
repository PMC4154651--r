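#' Topological summary of a functional network
#'
#' The standard per-culture summary block: number of active nodes N, number
#' of directed links E, average degree E/N (mean number of connections per
#' node), average strength S/N (mean weight per node), the four directed
#' assortativity variants with bootstrap errors, and the rich-club curve.
#'
#' @param net a [functional_network()].
#' @param n_boot bootstrap resamples for the assortativity errors
#'   (default 1000).
#' @param n_thresholds rich-club thresholds (default 50).
#' @param seed integer seed for the bootstrap.
#' @param rich_club set `FALSE` to skip the rich-club curve (it needs
#'   >= 5 nodes).
#' @return List with `n_nodes`, `n_edges`, `average_degree`,
#'   `average_strength`, `assortativity` (named list over the four
#'   variants), and `rich_club` (data frame or NULL).
#' @export
summarize_network <- function(net, n_boot = 1000, n_thresholds = 50,
                              seed = 1L, rich_club = TRUE) {
  n <- length(net$nodes)
  if (n == 0L) stop("network is empty", call. = FALSE)
  e <- n_links(net)
  variants <- c("pearson-degree", "spearman-degree",
                "pearson-strength-weighted", "spearman-strength-weighted")
  assort <- lapply(variants, function(v) {
    tryCatch(assortativity_with_error(net, v, n_boot = n_boot, seed = seed),
             error = function(err) list(variant = v, value = NA_real_,
                                        stderr = NA_real_,
                                        note = conditionMessage(err)))
  })
  names(assort) <- variants
  rc <- if (rich_club && n >= 5L) rich_club_curve(net, n_thresholds) else NULL
  list(
    n_nodes = n,
    n_edges = e,
    average_degree = e / n,
    average_strength = total_strength(net) / n,
    assortativity = assort,
    rich_club = rc
  )
}
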