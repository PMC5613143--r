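#' @export
autoplot.positional_profile <- function(object, ...) {
  anchor <- attr(object, "anchor") %||% "anchor"
  label <- attr(object, "set_label")
  ggplot2::ggplot(object, ggplot2::aes(x = .data$offset)) +
    ggplot2::geom_col(ggplot2::aes(y = .data$raw), width = 1,
                      fill = "grey80") +
    ggplot2::geom_line(ggplot2::aes(y = .data$smoothed),
                       colour = "firebrick", linewidth = 0.8) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::labs(
      x = sprintf("position relative to %s (nt)", gsub("_", " ", anchor)),
      y = "motif occurrences (column sum)",
      title = if (is.null(label)) NULL else paste(label, "set")
    ) +
    ggplot2::theme_minimal()
}

#' Overlay smoothed positional profiles of several transcript sets
#'
#' @param profiles Named list of [positional_profile()] results (names used
#'   when a profile carries no set label).
#' @return A ggplot object.
#' @export
plot_profiles <- function(profiles) {
  stopifnot(is.list(profiles), length(profiles) > 0)
  df <- dplyr::bind_rows(purrr::imap(profiles, function(p, nm) {
    tibble::tibble(set_label = attr(p, "set_label") %||% nm,
                   offset = p$offset, smoothed = p$smoothed)
  }))
  anchor <- attr(profiles[[1]], "anchor") %||% "anchor"
  ggplot2::ggplot(df, ggplot2::aes(x = .data$offset, y = .data$smoothed,
                                   colour = .data$set_label)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::labs(
      x = sprintf("position relative to %s (nt)", gsub("_", " ", anchor)),
      y = "smoothed motif occurrences", colour = NULL
    ) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.metagene_profiles <- function(object, ...) {
  n_flank <- attr(object, "n_flank_bins")
  body_bins <- attr(object, "body_bins")
  ggplot2::ggplot(object, ggplot2::aes(x = .data$bin, y = .data$mean,
                                       colour = .data$set_label)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::geom_vline(xintercept = c(n_flank + 0.5,
                                       n_flank + body_bins + 0.5),
                        linetype = "dashed") +
    ggplot2::annotate("text", x = n_flank + body_bins / 2, y = Inf,
                      label = "gene body (scaled)", vjust = 1.5, size = 3) +
    ggplot2::labs(x = "bin (5' flank | scaled body | 3' flank)",
                  y = sprintf("mean peak %s",
                              if (identical(attr(object, "mode"), "score"))
                                "score density" else "prevalence"),
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.gate_table <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$maturation, y = .data$ko_call,
                                   fill = .data$n)) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::geom_text(ggplot2::aes(label = .data$n)) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::labs(x = "maturation class (GV to MII)",
                  y = "knockout dosage call (MII)", fill = "genes") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.group_comparison <- function(object, ...,
                                      fc_min = 2, p_max = 0.05) {
  sig <- abs(object$log2_fc) >= log2(fc_min) & object$p_value < p_max
  df <- tibble::tibble(mean_a = object$mean_a, mean_b = object$mean_b,
                       significant = sig)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mean_a, y = .data$mean_b,
                                   colour = .data$significant)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.6) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "red")) +
    ggplot2::labs(x = "mean log2 expression (group A)",
                  y = "mean log2 expression (group B)",
                  colour = sprintf("FC >= %g & p < %g", fc_min, p_max)) +
    ggplot2::theme_minimal()
}
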