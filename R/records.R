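#' Classify a female as mature or juvenile
#'
#' Maturity is decided from the sighting history first: a known or minimum
#' age of at least 8 years (the mean age of sexual maturity for gray
#' whales) classifies the whale as mature, and a *known* age below 8 years
#' as juvenile. When age is uninformative (no sighting history, or only a
#' minimum age below 8), the total body length posterior decides: mature
#' when more than half the posterior mass, taken as Normal(`tl_mean`,
#' `tl_sd`^2), lies above 11.7 m, the average female length at maturity.
#' The boundary case P(TL > 11.7) = 0.5 classifies as juvenile
#' (conservative).
#'
#' All arguments are vectorized and recycled to a common length.
#'
#' @param age_type `"known"`, `"minimum"`, or `"unknown"` per whale-year.
#' @param lsh Length of sighting history in whole years (ignored when
#'   `age_type = "unknown"`).
#' @param tl_mean,tl_sd Total-length posterior mean and sd in metres; may
#'   be `NA` when age alone decides.
#' @param maturity_age Age threshold in years.
#' @param maturity_length Length threshold in metres.
#' @return A character vector of `"mature"` / `"juvenile"`.
#' @examples
#' classify_maturity("known", 5)                      # juvenile
#' classify_maturity("minimum", 23)                   # mature
#' classify_maturity("unknown", NA, 12.4, 0.2)        # mature by length
#' @export
classify_maturity <- function(age_type, lsh, tl_mean = NA_real_,
                              tl_sd = NA_real_, maturity_age = 8,
                              maturity_length = 11.7) {
  n <- max(length(age_type), length(lsh), length(tl_mean), length(tl_sd))
  age_type <- rep_len(as.character(age_type), n)
  lsh <- rep_len(lsh, n)
  tl_mean <- rep_len(tl_mean, n)
  tl_sd <- rep_len(tl_sd, n)

  bad <- !age_type %in% c("known", "minimum", "unknown")
  if (any(bad)) {
    stop("age_type must be 'known', 'minimum' or 'unknown'; got: ",
         paste(unique(age_type[bad]), collapse = ", "))
  }
  by_age <- (age_type %in% c("known", "minimum")) & !is.na(lsh) &
    lsh >= maturity_age
  known_juv <- age_type == "known" & !is.na(lsh) & lsh < maturity_age
  needs_length <- !by_age & !known_juv
  if (any(needs_length & (is.na(tl_mean) | is.na(tl_sd)))) {
    offenders <- which(needs_length & (is.na(tl_mean) | is.na(tl_sd)))
    stop("maturity indeterminate for record(s) ",
         paste(offenders, collapse = ", "),
         ": age is uninformative and no length posterior is available")
  }
  out <- rep("juvenile", n)
  out[by_age] <- "mature"
  p_long <- stats::pnorm(maturity_length, tl_mean, pmax(tl_sd, 1e-12),
                         lower.tail = FALSE)
  out[needs_length & p_long > 0.5] <- "mature"
  out
}

#' Assign the reproductive class for a whale-year
#'
#' A mature female seen with a calf the year *after* sampling was pregnant
#' at sampling (`PF`); one seen with a calf *in* the sampling year is
#' lactating (`LF`); a juvenile is `JF`; any other mature female is `MF`
#' (unknown status, a mixture of pregnant and non-pregnant whales).
#' Lactation lasts about seven months and gray whales have a two-year
#' breeding cycle, so a calf in both the sampling year and the next is
#' biologically excluded and raises an error.
#'
#' @param maturity `"mature"` or `"juvenile"` (e.g. from
#'   [classify_maturity()]).
#' @param year Sampling year.
#' @param calf_years List of integer vectors (one per whale-year) of years
#'   the female was seen with a calf; a single vector is accepted for one
#'   record.
#' @return A character vector of `"PF"`, `"LF"`, `"JF"`, `"MF"`.
#' @examples
#' assign_repro_class("mature", 2019, list(2020))   # PF
#' assign_repro_class("mature", 2018, list(2018))   # LF
#' assign_repro_class("mature", 2017, list(integer()))  # MF
#' @export
assign_repro_class <- function(maturity, year, calf_years) {
  if (!is.list(calf_years)) calf_years <- list(calf_years)
  n <- max(length(maturity), length(year), length(calf_years))
  maturity <- rep_len(maturity, n)
  year <- rep_len(year, n)
  calf_years <- rep_len(calf_years, n)
  stopifnot(all(maturity %in% c("mature", "juvenile")))

  calf_now <- mapply(function(y, cy) y %in% cy, year, calf_years)
  calf_next <- mapply(function(y, cy) (y + 1) %in% cy, year, calf_years)
  if (any(calf_now & calf_next)) {
    stop("calf observed in both the sampling year and the next for ",
         "record(s) ", paste(which(calf_now & calf_next), collapse = ", "),
         ": lactating gray whales do not produce a calf the following year")
  }
  dplyr::case_when(
    calf_next ~ "PF",
    calf_now ~ "LF",
    maturity == "juvenile" ~ "JF",
    .default = "MF"
  )
}

#' Assemble whale-year records from sightings and annual aggregates
#'
#' Joins the annual hormone and morphometric aggregates onto the sighting
#' histories, computes maturity and reproductive class for every
#' whale-year with at least one measurement, and returns one tidy record
#' per whale-year. Records lacking both measurements are dropped with a
#' message reporting the count.
#'
#' @param sightings Data frame with columns `whale_id`, `first_year`,
#'   `first_seen_as_calf` (logical), and `calf_years` (list-column of
#'   integer vectors, or a semicolon-separated string as produced by
#'   [read_sightings()]).
#' @param hormone_annual Data frame with `whale_id`, `year`, `log_fp4m`
#'   (e.g. from [prep_hormones()]).
#' @param morph_annual Data frame with `whale_id`, `year`, `w50`,
#'   `w50_sd`, `tl_mean`, `tl_sd` (e.g. from [prep_morphometrics()]).
#' @param lengths Optional per-whale length posteriors (`whale_id`,
#'   `tl_mean`, `tl_sd`, e.g. from [whale_lengths()]) used to fill
#'   records whose own year lacks a usable measurement; total length is a
#'   whale-level quantity, so any year's measurement informs maturity.
#' @return A tibble with one row per whale-year: `record_id`, `whale_id`,
#'   `year`, `group`, `lsh`, `age_type`, `tl_mean`, `tl_sd`, `fp4m`,
#'   `w50`, `w50_sd`.
#' @export
build_dataset <- function(sightings, hormone_annual = NULL,
                          morph_annual = NULL, lengths = NULL) {
  stopifnot(all(c("whale_id", "first_year", "first_seen_as_calf",
                  "calf_years") %in% names(sightings)))
  if (!is.list(sightings$calf_years)) {
    sightings$calf_years <- parse_year_list(sightings$calf_years)
  }
  if (anyDuplicated(sightings$whale_id)) {
    stop("duplicate whale_id in sightings: ",
         paste(unique(sightings$whale_id[duplicated(sightings$whale_id)]),
               collapse = ", "))
  }

  empty_h <- tibble::tibble(whale_id = character(), year = integer(),
                            log_fp4m = double())
  empty_m <- tibble::tibble(whale_id = character(), year = integer(),
                            w50 = double(), w50_sd = double(),
                            tl_mean = double(), tl_sd = double())
  h <- if (is.null(hormone_annual)) empty_h else hormone_annual
  m <- if (is.null(morph_annual)) empty_m else morph_annual
  for (df in list(h, m)) {
    dup <- duplicated(df[, c("whale_id", "year")])
    if (any(dup)) {
      stop("conflicting duplicate whale-year keys in aggregates: ",
           paste(unique(paste(df$whale_id[dup], df$year[dup])),
                 collapse = ", "))
    }
  }

  keys <- dplyr::bind_rows(h[, c("whale_id", "year")],
                           m[, c("whale_id", "year")]) |>
    dplyr::distinct()
  n_dropped <- 0L

  out <- keys |>
    dplyr::left_join(dplyr::rename(h, fp4m = "log_fp4m"),
                     by = c("whale_id", "year")) |>
    dplyr::left_join(m, by = c("whale_id", "year")) |>
    dplyr::inner_join(sightings, by = "whale_id")
  missing_sight <- dplyr::anti_join(keys, sightings, by = "whale_id")
  if (nrow(missing_sight) > 0) {
    stop("no sighting history for whale(s): ",
         paste(unique(missing_sight$whale_id), collapse = ", "))
  }

  if (!"tl_mean" %in% names(out)) out$tl_mean <- NA_real_
  if (!"tl_sd" %in% names(out)) out$tl_sd <- NA_real_
  if (!is.null(lengths)) {
    i <- match(out$whale_id, lengths$whale_id)
    fill <- is.na(out$tl_mean) & !is.na(i)
    out$tl_mean[fill] <- lengths$tl_mean[i[fill]]
    out$tl_sd[fill] <- lengths$tl_sd[i[fill]]
  }

  both_absent <- is.na(out$fp4m) & is.na(out$w50)
  n_dropped <- sum(both_absent)
  if (n_dropped > 0) {
    message("dropping ", n_dropped,
            " whale-year record(s) lacking both fP4m and W50")
    out <- out[!both_absent, , drop = FALSE]
  }

  out <- out |>
    dplyr::mutate(
      lsh = .data$year - .data$first_year,
      age_type = dplyr::case_when(
        is.na(.data$first_year) ~ "unknown",
        .data$first_seen_as_calf ~ "known",
        .default = "minimum"
      ),
      maturity = classify_maturity(.data$age_type, .data$lsh,
                                   .data$tl_mean, .data$tl_sd),
      group = factor(assign_repro_class(.data$maturity, .data$year,
                                        .data$calf_years),
                     levels = c("PF", "LF", "JF", "MF")),
      record_id = paste(.data$whale_id, .data$year, sep = ":")
    ) |>
    dplyr::select("record_id", "whale_id", "year", "group", "lsh",
                  "age_type", "tl_mean", "tl_sd", "fp4m", "w50",
                  dplyr::any_of("w50_sd")) |>
    dplyr::arrange(.data$whale_id, .data$year)
  out
}

#' Read a sightings CSV
#'
#' Expected columns: `whale_id`, `first_year`, `first_seen_as_calf`
#' (TRUE/FALSE), `calf_years` (semicolon-separated years, may be empty),
#' and optionally `sex_source`. Validation failures report the offending
#' line numbers.
#'
#' @param path Path to the CSV file.
#' @return A tibble with `calf_years` parsed into a list-column.
#' @export
read_sightings <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(
    whale_id = readr::col_character(),
    first_year = readr::col_integer(),
    first_seen_as_calf = readr::col_logical(),
    calf_years = readr::col_character(),
    .default = readr::col_character()
  ))
  df$calf_years <- parse_year_list(df$calf_years)
  bad <- vapply(seq_len(nrow(df)), function(i) {
    cy <- df$calf_years[[i]]
    length(cy) > 0 && !is.na(df$first_year[i]) && any(cy < df$first_year[i])
  }, logical(1))
  if (any(bad)) {
    stop("calf_years precede first_year at data line(s): ",
         paste(which(bad), collapse = ", "))
  }
  df
}

parse_year_list <- function(x) {
  lapply(x, function(s) {
    if (is.na(s) || !nzchar(trimws(s))) return(integer())
    as.integer(strsplit(trimws(s), ";")[[1]])
  })
}
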