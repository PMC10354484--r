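#' Coefficient of variation between assay replicates
#'
#' Percent CV (100 x sample sd / mean) of the raw replicate readings of
#' one well pair. Values above `threshold` flag the sample for a rerun.
#'
#' @param replicates Numeric vector of at least two raw readings
#'   (pg ml^-1).
#' @param threshold Rerun threshold in percent.
#' @return A list with `cv_pct` and `rerun_required`.
#' @examples
#' replicate_cv(c(80, 120))  # 28.28, rerun flagged
#' @export
replicate_cv <- function(replicates, threshold = 15) {
  replicates <- replicates[!is.na(replicates)]
  if (length(replicates) < 2) {
    stop("need at least two replicates to compute a CV")
  }
  m <- mean(replicates)
  if (m <= 0) stop("replicate mean must be positive, got ", m)
  cv <- 100 * stats::sd(replicates) / m
  list(cv_pct = cv, rerun_required = cv > threshold)
}

#' Substitute values below the assay limit of detection
#'
#' Raw readings strictly below the limit of detection are replaced by half
#' the LOD, the standard convention for left-censored immunoassay data.
#' The default LOD of 8.57 pg ml^-1 is the manufacturer's value for the
#' progesterone kit.
#'
#' @param raw_pgml Numeric vector of raw readings (pg ml^-1).
#' @param lod_pgml Limit of detection (pg ml^-1).
#' @return A tibble with columns `value` and `below_lod`.
#' @examples
#' substitute_lod(c(3, 8.57, 100))
#' @export
substitute_lod <- function(raw_pgml, lod_pgml = 8.57) {
  stopifnot(lod_pgml > 0)
  if (any(raw_pgml < 0, na.rm = TRUE)) {
    stop("negative raw assay reading")
  }
  below <- !is.na(raw_pgml) & raw_pgml < lod_pgml
  tibble::tibble(value = ifelse(below, lod_pgml / 2, raw_pgml),
                 below_lod = below)
}

#' Convert a raw assay reading to ng per g of dry faeces
#'
#' `ng g^-1 = pg ml^-1 x dilution x extract volume (ml) / (1000 x dry
#' mass (g))`: the reading is scaled back through the dilution, multiplied
#' by the extract volume to give total hormone, and divided by the dried
#' faecal mass, with pg-to-ng conversion.
#'
#' @param mean_pgml Mean raw reading across replicates (pg ml^-1).
#' @param dilution_factor Dilution factor (>= 1).
#' @param extract_volume_ml Extraction volume in ml.
#' @param dry_mass_g Dried faecal mass in grams.
#' @return Concentration in ng per g (vectorized).
#' @examples
#' convert_to_ngg(500, 2, 10, 0.5)  # 20
#' @export
convert_to_ngg <- function(mean_pgml, dilution_factor, extract_volume_ml,
                           dry_mass_g) {
  if (any(c(mean_pgml, dilution_factor, extract_volume_ml, dry_mass_g) <= 0,
          na.rm = TRUE)) {
    stop("all conversion inputs must be positive")
  }
  mean_pgml * dilution_factor * extract_volume_ml / (1000 * dry_mass_g)
}

#' Mass filter for faecal samples
#'
#' Samples with dried mass strictly below 0.02 g are excluded to avoid the
#' small-sample effect (spuriously inflated concentrations).
#'
#' @param dry_mass_g Dried mass in grams (vectorized).
#' @param min_mass_g Exclusion threshold in grams.
#' @return Logical vector, `TRUE` = keep.
#' @export
filter_mass <- function(dry_mass_g, min_mass_g = 0.02) {
  !is.na(dry_mass_g) & dry_mass_g >= min_mass_g
}

#' Resolve duplicate same-day samples for one whale
#'
#' When one whale yields several samples on the same day they are normally
#' pooled into a single jar before assay; the few analysed separately are
#' resolved by keeping only the sample with the greater dried mass. Mass
#' ties break deterministically on the sample identifier (lowest first),
#' with a message.
#'
#' @param results Data frame of same-day results for one whale with
#'   columns `dry_mass_g`, optionally `pooled` (logical) and `sample_id`.
#' @return A single-row data frame.
#' @export
resolve_same_day <- function(results) {
  if (nrow(results) == 1) return(results)
  if (!is.null(results$pooled) && any(results$pooled)) {
    return(results[which(results$pooled)[1], , drop = FALSE])
  }
  best <- which(results$dry_mass_g == max(results$dry_mass_g))
  if (length(best) > 1) {
    ids <- if (!is.null(results$sample_id)) results$sample_id[best] else best
    keep <- best[order(ids)[1]]
    message("same-day mass tie resolved toward sample ",
            if (!is.null(results$sample_id)) results$sample_id[keep] else keep)
    best <- keep
  }
  results[best[1], , drop = FALSE]
}

#' Aggregate faecal results into one annual log-fP4m value
#'
#' The annual summary is the natural log of the *median* concentration on
#' the natural (ng g^-1) scale: the median is taken first, then
#' log-transformed. For odd counts the order is immaterial; for even
#' counts the midpoint mean is taken on the natural scale before the log,
#' so `aggregate_annual_fp4m(c(exp(3), exp(5)))` is
#' `log((exp(3) + exp(5)) / 2)`, not 4.
#'
#' @param fp4m_ngg Numeric vector of QC-passed concentrations (ng g^-1).
#' @return The annual log-fP4m, or `NA` for empty input.
#' @export
aggregate_annual_fp4m <- function(fp4m_ngg) {
  fp4m_ngg <- fp4m_ngg[!is.na(fp4m_ngg)]
  if (length(fp4m_ngg) == 0) return(NA_real_)
  log(stats::median(fp4m_ngg))
}

#' Quality-control and aggregate assay data into annual log-fP4m values
#'
#' Full hormone preparation pipeline: replicate CV flags, mass filter,
#' LOD substitution on the raw scale, unit conversion to ng g^-1,
#' same-day duplicate resolution, and annual aggregation (log of the
#' median). Counts removed at each filter are reported with messages.
#'
#' @param assays Data frame with one row per assayed sample: `whale_id`,
#'   `date` (Date or ISO-8601 string), replicate columns `rep1_pgml`,
#'   `rep2_pgml` (additional `rep<k>_pgml` columns are used if present),
#'   `dilution`, `extract_volume_ml`, `dry_mass_g`, and optionally
#'   `pooled` and `sample_id`.
#' @param lod_pgml Assay limit of detection (pg ml^-1).
#' @param cv_threshold Replicate-CV rerun threshold in percent.
#' @param drop_high_cv Drop samples whose replicate CV exceeds the
#'   threshold instead of keeping them flagged. Default `FALSE`: the
#'   laboratory protocol reruns such samples, so surviving values are
#'   usable.
#' @return A tibble with one row per whale-year: `whale_id`, `year`,
#'   `log_fp4m`, `n_samples`, `any_below_lod`, `max_cv_pct`.
#' @export
prep_hormones <- function(assays, lod_pgml = 8.57, cv_threshold = 15,
                          drop_high_cv = FALSE) {
  stopifnot(all(c("whale_id", "date", "rep1_pgml", "rep2_pgml", "dilution",
                  "extract_volume_ml", "dry_mass_g") %in% names(assays)))
  assays$date <- as.Date(assays$date)
  rep_cols <- grep("^rep[0-9]+_pgml$", names(assays), value = TRUE)

  reps <- as.matrix(assays[, rep_cols])
  cv <- apply(reps, 1, function(r) replicate_cv(r, cv_threshold)$cv_pct)
  rerun <- cv > cv_threshold
  if (any(rerun)) {
    message(sum(rerun), " sample(s) exceed ", cv_threshold,
            "% replicate CV", if (drop_high_cv) " and are dropped" else
              " (flagged, kept)")
  }

  keep_mass <- filter_mass(assays$dry_mass_g)
  if (any(!keep_mass)) {
    message(sum(!keep_mass), " sample(s) excluded by the 0.02 g mass filter")
  }
  keep <- keep_mass & (!drop_high_cv | !rerun)

  df <- assays[keep, , drop = FALSE]
  reps <- reps[keep, , drop = FALSE]
  sub <- apply(reps, 2, function(r) substitute_lod(r, lod_pgml)$value)
  below <- rowSums(matrix(reps < lod_pgml, nrow = nrow(df))) > 0
  mean_pgml <- rowMeans(sub)
  df$fp4m_ngg <- convert_to_ngg(mean_pgml, df$dilution,
                                df$extract_volume_ml, df$dry_mass_g)
  df$below_lod <- below
  df$cv_pct <- cv[keep]

  before <- nrow(df)
  df <- df |>
    dplyr::group_by(.data$whale_id, .data$date) |>
    dplyr::group_modify(~resolve_same_day(.x)) |>
    dplyr::ungroup()
  if (nrow(df) < before) {
    message(before - nrow(df), " duplicate same-day sample(s) resolved")
  }

  df |>
    dplyr::mutate(year = as.integer(format(.data$date, "%Y"))) |>
    dplyr::group_by(.data$whale_id, .data$year) |>
    dplyr::summarise(
      log_fp4m = aggregate_annual_fp4m(.data$fp4m_ngg),
      n_samples = dplyr::n(),
      any_below_lod = any(.data$below_lod),
      max_cv_pct = max(.data$cv_pct),
      .groups = "drop"
    )
}

#' Read an assay CSV
#'
#' @param path Path to a CSV with the columns described in
#'   [prep_hormones()].
#' @return A tibble.
#' @export
read_assays <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    whale_id = readr::col_character(),
    date = readr::col_date(),
    .default = readr::col_guess()
  ))
}
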