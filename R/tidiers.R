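# broom-style tidiers for fitted/derived result objects

#' Tidy a recruitment curve
#'
#' @param x a `vest_recruitment`.
#' @param ... unused.
#' @return tibble with `amp_uA`, `branch`, `fraction_active`.
#' @method tidy vest_recruitment
#' @export
tidy.vest_recruitment <- function(x, ...) {
  tibble::as_tibble(as.data.frame(x))
}

#' One-row summary of a recruitment curve
#'
#' Sensory/discomfort thresholds and the top-of-grid fraction for the target
#' branch.
#'
#' @param x a `vest_recruitment`.
#' @param frac ST activation fraction (default 0.10).
#' @param ... unused.
#' @method glance vest_recruitment
#' @export
glance.vest_recruitment <- function(x, frac = 0.10, ...) {
  thr <- sensory_threshold(x, frac = frac)
  tgt <- attr(x, "target_branch")
  top <- x$fraction_active[x$branch == tgt & x$amp_uA == max(x$amp_uA)]
  tibble::tibble(
    target_branch = tgt, ST_uA = as.numeric(thr$ST_uA), DT_uA = thr$DT_uA,
    UL_uA = thr$UL_uA, max_fraction = top
  )
}

#' Tidy a growth function
#'
#' @param x a `vest_growth`.
#' @param ... unused.
#' @return tibble with `level_uA`, `ecap_amp_uV`, and `in_segment` marking
#'   the points used in the slope fit.
#' @method tidy vest_growth
#' @export
tidy.vest_growth <- function(x, ...) {
  tibble::tibble(level_uA = x$level_uA, ecap_amp_uV = x$ecap_amp_uV,
                 in_segment = attr(x, "segment"))
}

#' One-row summary of a growth function
#'
#' @param x a `vest_growth`.
#' @param ... unused.
#' @return tibble with the fitted slope, its R-squared (NA when no fit), and
#'   the segment size.
#' @method glance vest_growth
#' @export
glance.vest_growth <- function(x, ...) {
  fit <- attr(x, "fit")
  tibble::tibble(
    slope_uV_per_uA = as.numeric(attr(x, "slope_uV_per_uA")),
    r_squared = if (is.null(fit)) NA_real_ else summary(fit)$r.squared,
    n_segment = sum(attr(x, "segment"))
  )
}

#' Tidy a VOR prediction
#'
#' @param x a `vest_vor`.
#' @param ... unused.
#' @return tibble with one row per frame component.
#' @method tidy vest_vor
#' @export
tidy.vest_vor <- function(x, ...) {
  tibble::tibble(component = names(x$components),
                 projection = unname(x$components),
                 magnitude = x$magnitude)
}

#' Tidy a thresholds object
#'
#' @param x a `vest_thresholds`.
#' @param ... unused.
#' @method tidy vest_thresholds
#' @export
tidy.vest_thresholds <- function(x, ...) {
  tibble::tibble(
    ST_uA = as.numeric(x$ST_uA), DT_uA = x$DT_uA, UL_uA = x$UL_uA,
    dyn_range_lo_uA = x$dynamic_range_uA[1],
    dyn_range_hi_uA = x$dynamic_range_uA[2]
  )
}
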