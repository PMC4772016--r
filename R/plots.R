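#' Diagnostic plot: separation histogram versus fitted model
#'
#' Overlays the edge-corrected separation histogram (an estimate of
#' `N f(x)`) with the fitted mixture density scaled by the fitted pair
#' count, on log-log axes.
#'
#' @param hist a [separation_histogram()] tibble.
#' @param model a [link_model()].
#' @return a ggplot object.
#' @export
plot_separation_fit <- function(hist, model) {
  h <- hist[hist$usable & hist$count > 0, , drop = FALSE]
  curve <- tibble(
    mid = exp(seq(log(min(h$mid)), log(max(h$mid)), length.out = 300))
  )
  curve$fit <- model$N * pair_density(curve$mid, model)
  ggplot2::ggplot(h, ggplot2::aes(x = .data$mid, y = .data$corrected)) +
    ggplot2::geom_point(size = 0.8, colour = "grey30") +
    ggplot2::geom_line(data = curve,
                       ggplot2::aes(y = .data$fit), colour = "firebrick") +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "pair separation (bp)",
                  y = "edge-corrected count density (~ N f(x))",
                  title = "Chicago separation model fit") +
    ggplot2::theme_minimal()
}

#' Plot a per-position support profile
#'
#' Raw (and, when present, robust) break-support LLR along a contig, with
#' optional break positions marked.
#'
#' @param profile a [support_profile()] or [robust_support_profile()] tibble.
#' @param breaks optional numeric vector of break positions (bp).
#' @return a ggplot object.
#' @export
plot_support_profile <- function(profile, breaks = NULL) {
  long <- tidyr::pivot_longer(
    profile, dplyr::any_of(c("llr", "robust_llr")),
    names_to = "score", values_to = "value")
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$pos, y = .data$value,
                                          colour = .data$score)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::labs(x = "position (bp)", y = "support LLR (nats)",
                  colour = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(breaks) && length(breaks) > 0) {
    p <- p + ggplot2::geom_vline(xintercept = breaks, colour = "firebrick",
                                 linetype = 3)
  }
  p
}

#' Plot scaffold sizes of a pipeline result
#'
#' Span-ordered scaffold sizes with cumulative assembly fraction; the N50 is
#' marked.
#'
#' @param result a `hirise_result`.
#' @return a ggplot object.
#' @export
plot_scaffold_sizes <- function(result) {
  spans <- result$layout %>%
    left_join(result$contigs, by = "contig") %>%
    group_by(.data$scaffold) %>%
    summarise(span = sum(.data$length) + sum(.data$gap_before),
              .groups = "drop") %>%
    arrange(desc(.data$span)) %>%
    mutate(rank = row_number(), cum = cumsum(.data$span) / sum(.data$span))
  n50v <- n50(spans$span)
  ggplot2::ggplot(spans, ggplot2::aes(x = .data$rank, y = .data$span)) +
    ggplot2::geom_step() +
    ggplot2::geom_hline(yintercept = n50v, colour = "firebrick",
                        linetype = 2) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "scaffold rank", y = "scaffold span (bp)",
                  subtitle = sprintf("N50 = %.3g bp", n50v)) +
    ggplot2::theme_minimal()
}
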