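#' Heatmap of a splicing-ratio matrix
#'
#' Rows (events) are ordered by Ward clustering of the log-transformed
#' ratios, the standard display for tissue/stage splicing profiles.
#'
#' @param object A `ratio_matrix` from [build_ratio_matrix()].
#' @param log_transform,eps Passed to [ward_order()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ratio_matrix <- function(object, log_transform = TRUE, eps = 1e-6,
                                  ...) {
  ord <- if (nrow(object) >= 2) {
    ward_order(object, log_transform = log_transform, eps = eps)$order
  } else {
    seq_len(nrow(object))
  }
  long <- object %>%
    mutate(event_id = factor(.data$event_id,
                             levels = .data$event_id[ord])) %>%
    tidyr::pivot_longer(-c("event_id", "event_type", "gene_id"),
                        names_to = "sample_id", values_to = "ratio")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$sample_id, y = .data$event_id,
                                     fill = .data$ratio)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1), name = "IRR / PSI") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Splicing-ratio trajectories across stages
#'
#' @param ratios Ratio-record tibble from [event_ratios()] joined with a
#'   numeric `stage` column (e.g. via the sample sheet from
#'   [simulate_expression()]).
#' @return A ggplot object: one line per event over stages.
#' @export
plot_ratio_trajectories <- function(ratios) {
  assert_cols(ratios, c("event_id", "stage", "ratio"))
  avg <- ratios %>%
    group_by(.data$event_id, .data$stage) %>%
    summarise(ratio = mean(.data$ratio), .groups = "drop")
  ggplot2::ggplot(avg, ggplot2::aes(x = .data$stage, y = .data$ratio,
                                    group = .data$event_id)) +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "stage", y = "IRR / PSI") +
    ggplot2::theme_minimal()
}

#' Volcano-style view of a cis-sQTL scan
#'
#' @param object An `sqtl_scan` from [cis_scan()].
#' @param ... Unused.
#' @return A ggplot object of splicing-odds log fold change versus
#'   -log10 q, colored by significance.
#' @export
autoplot.sqtl_scan <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$beta,
                               y = -log10(pmax(.data$q_value, 1e-300)),
                               color = .data$significant)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = -log10(0.05), linetype = 2) +
    ggplot2::labs(x = "log odds difference (M - B)", y = "-log10 q") +
    ggplot2::theme_minimal()
}

#' Conservation summary barplot
#'
#' @param summary_tbl Output of [summarize_conservation()].
#' @return A ggplot object: cluster counts per category, faceted by event
#'   type.
#' @export
plot_conservation_summary <- function(summary_tbl) {
  assert_cols(summary_tbl, c("event_type", "category", "clusters"))
  ggplot2::ggplot(summary_tbl,
                  ggplot2::aes(x = factor(.data$category),
                               y = .data$clusters)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~event_type) +
    ggplot2::labs(x = "conservation category", y = "clusters") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
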