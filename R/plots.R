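#' Bar chart of normalized comparison metrics per subtype
#'
#' Mirrors the usual presentation of moiety rankings: one bar per subtype for
#' each normalized metric, negative bars flagging candidate malicious
#' subtypes.
#'
#' @param object A `subtype_ranking`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.subtype_ranking <- function(object, ...) {
  df <- tidy(object)
  long <- rbind(
    data.frame(subtype_id = df$subtype_id, metric = "nCosSim", value = df$n_cos_sim),
    data.frame(subtype_id = df$subtype_id, metric = "nAvgDiff", value = df$n_avg_diff)
  )
  long$subtype_id <- factor(long$subtype_id, levels = df$subtype_id)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$subtype_id, y = .data$value,
                                     fill = .data$value > 0)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#2166ac", `FALSE` = "#b2182b")) +
    ggplot2::labs(x = "atom subtype (ranked, most malicious first)",
                  y = "normalized metric") +
    ggplot2::theme_minimal()
}

#' Heat-strip of cluster sizes along the trajectory
#'
#' One horizontal strip per series, colored by per-frame cluster size: stable
#' series show long dark-red stretches, unstable ones fragment into small
#' blue clusters.
#'
#' @param series Named list of `cluster_size_series` (or numeric vectors); the
#'   first is conventionally the whole-molecule reference.
#' @return A ggplot object.
#' @export
plot_size_series <- function(series) {
  stopifnot(length(series) >= 1L)
  nm <- names(series) %||% paste0("series_", seq_along(series))
  df <- do.call(rbind, lapply(seq_along(series), function(i) {
    s <- as_sizes(series[[i]])
    data.frame(series = nm[i], frame = seq_along(s), size = s)
  }))
  df$series <- factor(df$series, levels = rev(nm))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$frame, y = .data$series,
                                   fill = .data$size)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "#2166ac", high = "#b2182b") +
    ggplot2::labs(x = "frame", y = NULL, fill = "cluster size") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom rlang .data
NULL
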