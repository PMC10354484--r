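#' Standardize a body width by total length
#'
#' Width divided by total length gives the scale-invariant, unitless
#' metric used throughout (W50 is the value at 50% of TL).
#'
#' @param width_m Width in metres.
#' @param tl_m Total body length in metres.
#' @return The unitless ratio (vectorized).
#' @export
standardize_width <- function(width_m, tl_m) {
  if (any(width_m <= 0 | tl_m <= 0, na.rm = TRUE)) {
    stop("widths and lengths must be positive")
  }
  if (any(width_m >= tl_m, na.rm = TRUE)) {
    stop("width >= total length: implausible measurement")
  }
  width_m / tl_m
}

#' Late-season filter for photogrammetry measurements
#'
#' Keeps only measurements taken strictly after 26 August of their year.
#' Early-season measurements reflect whales that recently arrived from the
#' fasting season, while the late-season cut-off captures pregnant females
#' nearer late gestation; 26 August itself is excluded.
#'
#' @param date Date vector (or ISO-8601 strings).
#' @param cutoff_month,cutoff_day Month-day boundary (exclusive).
#' @return Logical vector, `TRUE` = keep.
#' @examples
#' late_season_filter(as.Date(c("2021-07-07", "2021-08-26", "2021-08-27")))
#' @export
late_season_filter <- function(date, cutoff_month = 8, cutoff_day = 26) {
  date <- as.Date(date)
  m <- as.integer(format(date, "%m"))
  d <- as.integer(format(date, "%d"))
  m > cutoff_month | (m == cutoff_month & d > cutoff_day)
}

#' Aggregate width measurements into one annual W50
#'
#' Selects, among a whale-year's late-season measurements, the one with
#' the maximal W50 posterior mean (pregnant females grow wider over the
#' season, so the annual maximum is the most informative summary) and
#' carries its posterior sd. Ties break toward the most recent
#' measurement, the one closest to putative late gestation.
#'
#' @param measurements Data frame for one whale-year with columns
#'   `w50_mean`, and optionally `w50_sd`, `date`, `tl_mean`, `tl_sd`.
#' @return A single-row tibble (the selected measurement) with
#'   `n_measurements` appended, or `NULL` for empty input.
#' @export
aggregate_annual_w50 <- function(measurements) {
  if (is.null(measurements) || nrow(measurements) == 0) return(NULL)
  best <- which(measurements$w50_mean == max(measurements$w50_mean))
  if (length(best) > 1 && !is.null(measurements$date)) {
    best <- best[order(as.Date(measurements$date[best]),
                       decreasing = TRUE)]
  }
  out <- measurements[best[1], , drop = FALSE]
  out$n_measurements <- nrow(measurements)
  tibble::as_tibble(out)
}

#' Prepare annual W50 values from per-measurement morphometrics
#'
#' Applies the late-season filter and the annual maximum rule to a table
#' of per-measurement standardized widths, returning one W50 (with its
#' posterior sd and the length posterior) per whale-year. The number of
#' measurements removed by the late-season filter is reported.
#'
#' @param morph Data frame with one row per measurement: `whale_id`,
#'   `date`, `tl_mean`, `tl_sd`, `w50_mean`, and optionally `w50_sd` plus
#'   further `w<pos>_mean`/`w<pos>_sd` columns for other body positions
#'   (kept for width-profile plots, not used by the models).
#' @param late_season_only Apply the after-26-August filter.
#' @return A tibble with one row per whale-year: `whale_id`, `year`,
#'   `w50`, `w50_sd`, `tl_mean`, `tl_sd`, `n_measurements`.
#' @export
prep_morphometrics <- function(morph, late_season_only = TRUE) {
  stopifnot(all(c("whale_id", "date", "w50_mean") %in% names(morph)))
  morph$date <- as.Date(morph$date)
  if (late_season_only) {
    keep <- late_season_filter(morph$date)
    if (any(!keep)) {
      message(sum(!keep),
              " measurement(s) excluded by the late-season filter")
    }
    morph <- morph[keep, , drop = FALSE]
  }
  if (!"w50_sd" %in% names(morph)) morph$w50_sd <- NA_real_

  morph |>
    dplyr::mutate(year = as.integer(format(.data$date, "%Y"))) |>
    dplyr::group_by(.data$whale_id, .data$year) |>
    dplyr::group_modify(~aggregate_annual_w50(.x)) |>
    dplyr::ungroup() |>
    dplyr::transmute(
      whale_id = .data$whale_id, year = .data$year,
      w50 = .data$w50_mean, w50_sd = .data$w50_sd,
      tl_mean = if ("tl_mean" %in% names(morph)) .data$tl_mean else NA_real_,
      tl_sd = if ("tl_sd" %in% names(morph)) .data$tl_sd else NA_real_,
      n_measurements = .data$n_measurements
    )
}

#' Per-whale total-length posteriors from raw measurements
#'
#' Total body length is a property of the whale, not of the season, so
#' the length posterior used for maturity classification may come from
#' any measurement, including early-season flights excluded from W50
#' aggregation. Returns the most recent measurement's posterior per
#' whale.
#'
#' @param morph Data frame with `whale_id`, `date`, `tl_mean`, `tl_sd`.
#' @return A tibble with one row per whale.
#' @export
whale_lengths <- function(morph) {
  stopifnot(all(c("whale_id", "date", "tl_mean") %in% names(morph)))
  morph |>
    dplyr::filter(!is.na(.data$tl_mean)) |>
    dplyr::group_by(.data$whale_id) |>
    dplyr::arrange(dplyr::desc(as.Date(.data$date)), .by_group = TRUE) |>
    dplyr::slice(1) |>
    dplyr::ungroup() |>
    dplyr::select("whale_id", "tl_mean", "tl_sd")
}

#' Read a morphometrics CSV
#'
#' @param path Path to a CSV with the columns described in
#'   [prep_morphometrics()].
#' @return A tibble.
#' @export
read_morph <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    whale_id = readr::col_character(),
    date = readr::col_date(),
    .default = readr::col_double()
  ))
}

#' Plot standardized width profiles by reproductive class
#'
#' Width against body-axis position (20-70% of TL) per measurement,
#' coloured by reproductive class; the plot that motivates using W50 as
#' the diagnostic variable.
#'
#' @param morph Data frame with `w<pos>_mean` columns (one per body
#'   position) and a `group` column.
#' @return A ggplot object.
#' @export
plot_width_profile <- function(morph) {
  stopifnot("group" %in% names(morph))
  long <- morph |>
    tidyr::pivot_longer(dplyr::matches("^w[0-9]+_mean$"),
                        names_to = "position", values_to = "width",
                        names_pattern = "w([0-9]+)_mean") |>
    dplyr::mutate(position = as.numeric(.data$position))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$position, y = .data$width,
                                     colour = .data$group,
                                     group = interaction(.data$group,
                                                         .data$position))) +
    ggplot2::geom_boxplot(position = "identity", alpha = 0.4,
                          outlier.size = 0.5) +
    ggplot2::labs(x = "% of total length", y = "standardized width",
                  colour = "class") +
    ggplot2::theme_minimal()
}
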