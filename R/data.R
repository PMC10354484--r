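#' Gray whale whale-year analysis records
#'
#' Loads the packaged six-year (2016-2021) individual-based dataset of
#' female Pacific Coast Feeding Group gray whales sampled off Newport,
#' Oregon. Each row is one whale in one year, carrying the annual
#' aggregates the diagnosis models consume: the natural log of the median
#' faecal progesterone metabolite concentration (`fp4m`, log ng per g dry
#' faeces) and the late-season maximum standardized body width at 50% of
#' total length (`w50`, unitless width/TL ratio). 76 records have fP4m, 77
#' have W50, and 42 have both.
#'
#' Reproductive class (`group`) comes from sighting histories: `PF`
#' (presumed pregnant, seen with a calf the year after sampling), `LF`
#' (lactating, seen with a calf in the sampling year), `JF` (juvenile,
#' immature female) and `MF` (mature female of unknown pregnancy status).
#' `lsh` is the length of the sighting history in years and `age_type`
#' records whether it is a `known` age (first seen as a calf) or a
#' `minimum` age. `tl_mean` and `tl_sd` summarise the photogrammetric
#' posterior for total body length in metres (`NA` where no usable
#' measurement exists).
#'
#' Columns `p1`..`p3` (with `_lq`/`_uq` quartiles) are the reference
#' per-record pregnancy probabilities from the original bootstrap analysis
#' of this dataset (Model 1 = bivariate fP4m + W50, Model 2 = fP4m only,
#' Model 3 = W50 only), retained so that reimplementations of the models
#' can be compared against them.
#'
#' @return A tibble with 111 rows.
#' @examples
#' recs <- gray_whale_records()
#' dplyr::count(recs, group)
#' @export
gray_whale_records <- function() {
  path <- system.file("extdata", "gray_whale_table.csv", package = "pregmix",
                      mustWork = TRUE)
  readr::read_csv(path, col_types = readr::cols(
    whale_id = readr::col_character(),
    year = readr::col_integer(),
    group = readr::col_character(),
    lsh = readr::col_integer(),
    age_type = readr::col_character(),
    .default = readr::col_double()
  )) |>
    dplyr::mutate(
      group = factor(.data$group, levels = c("PF", "LF", "JF", "MF")),
      record_id = paste(.data$whale_id, .data$year, sep = ":"),
      .before = 1
    ) |>
    dplyr::relocate("whale_id", "year", .before = 1)
}

#' Group summary statistics of the pregnancy indicators
#'
#' Mean and range of log-fP4m and W50 by reproductive class, the standard
#' descriptive summary of the two candidate pregnancy indicators.
#'
#' @param records A data frame with columns `group`, `fp4m`, `w50`, such
#'   as [gray_whale_records()] or the output of [build_dataset()].
#' @return A tibble with one row per reproductive class and columns
#'   `n_fp4m`, `mean_fp4m`, `min_fp4m`, `max_fp4m`, `n_w50`, `mean_w50`,
#'   `min_w50`, `max_w50`.
#' @export
indicator_summary <- function(records) {
  records |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(
      n_fp4m = sum(!is.na(.data$fp4m)),
      mean_fp4m = mean(.data$fp4m, na.rm = TRUE),
      min_fp4m = suppressWarnings(min(.data$fp4m, na.rm = TRUE)),
      max_fp4m = suppressWarnings(max(.data$fp4m, na.rm = TRUE)),
      n_w50 = sum(!is.na(.data$w50)),
      mean_w50 = mean(.data$w50, na.rm = TRUE),
      min_w50 = suppressWarnings(min(.data$w50, na.rm = TRUE)),
      max_w50 = suppressWarnings(max(.data$w50, na.rm = TRUE)),
      .groups = "drop"
    )
}
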