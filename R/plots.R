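# ggplot2 quick-look plots for each result type

#' Plot a sampled waveform
#'
#' @param object a `vest_waveform`.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot vest_waveform
#' @export
autoplot.vest_waveform <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$t_us, y = .data$i_uA)) +
    ggplot2::geom_step() +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.2, colour = "grey50") +
    ggplot2::labs(x = "time (µs)", y = "current (µA)") +
    ggplot2::theme_minimal()
}

#' Plot recruitment curves per branch
#'
#' @param object a `vest_recruitment`.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot vest_recruitment
#' @export
autoplot.vest_recruitment <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$amp_uA, y = .data$fraction_active,
                               colour = .data$branch)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "stimulus amplitude (µA)",
                  y = "fraction of fibers active", colour = "branch") +
    ggplot2::theme_minimal()
}

#' Plot an eCAP trace
#'
#' @param object a `vest_ecap`.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot vest_ecap
#' @export
autoplot.vest_ecap <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$t_ms, y = .data$v_uV)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (ms)", y = "recorded potential (µV)") +
    ggplot2::theme_minimal()
}

#' Plot an eCAP growth function
#'
#' @param object a `vest_growth`.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot vest_growth
#' @export
autoplot.vest_growth <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$level_uA,
                                   y = .data$ecap_amp_uV)) +
    ggplot2::geom_point(ggplot2::aes(shape = .data$in_segment)) +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::labs(x = "stimulus level (µA)", y = "eCAP amplitude (µV)",
                  shape = "in slope fit") +
    ggplot2::theme_minimal()
}

#' Plot eVOR velocity components
#'
#' @param object a `vest_evor`.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot vest_evor
#' @export
autoplot.vest_evor <- function(object, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object),
                              c("horizontal", "LARP", "RALP"),
                              names_to = "component", values_to = "velocity")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$t_s, y = .data$velocity,
                                     colour = .data$component)) +
    ggplot2::geom_line() +
    ggplot2::scale_colour_manual(
      values = c(horizontal = "red", LARP = "green3", RALP = "blue")) +
    ggplot2::labs(x = "time (s)", y = "eye velocity (a.u.)") +
    ggplot2::theme_minimal()
}

#' Plot a pulse-shape sweep
#'
#' @param object a `vest_sweep`.
#' @param ... unused.
#' @return a ggplot of charge at threshold per shape/slope.
#' @method autoplot vest_sweep
#' @export
autoplot.vest_sweep <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$label <- ifelse(is.na(df$slope_deg), df$shape,
                     paste0(df$shape, " ", df$slope_deg, "°"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$label,
                                   y = .data$charge_at_threshold_nC)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "charge at eCAP threshold (nC)") +
    ggplot2::theme_minimal()
}
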