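#' Configuration for the synthetic gray whale dataset generator
#'
#' Defaults emulate the study population: five presumed-pregnant females
#' among ~76 whale-years, log-fP4m components that *overlap heavily*
#' (pregnant N(4.60, 1.15^2) vs non-pregnant N(4.10, 0.77^2), means half a
#' log-unit apart with large spread — the generator reproduces the
#' indicator's real failure mode, not an idealized separation) and W50
#' components that separate well (pregnant N(0.178, 0.01^2) vs
#' non-pregnant N(0.150, 0.01^2)) with small per-measurement
#' photogrammetric noise.
#'
#' `mf_pregnant_fraction` is the fraction of mature females of unknown
#' status that are truly pregnant; it is also the calf-loss / missed-calf
#' channel, since a truly pregnant whale whose calf is never sighted stays
#' in the MF class rather than being recognized as PF.
#'
#' @param n_per_class Named integer vector of whale-years per reproductive
#'   class.
#' @param fp4m_pregnant,fp4m_nonpregnant Mean and sd of log-fP4m
#'   (log ng g^-1) per pregnancy state.
#' @param w50_pregnant,w50_nonpregnant Mean and sd of the annual true W50
#'   per pregnancy state.
#' @param w50_measurement_sd Photogrammetric sd of one W50 measurement.
#' @param within_year_log_sd Sd of per-sample log concentrations around
#'   the whale-year's true log-fP4m (faecal sampling noise).
#' @param replicate_cv_frac Assay replicate noise as a fraction of the
#'   mean reading.
#' @param mf_pregnant_fraction Fraction of MF whale-years truly pregnant.
#' @param lod_pgml Assay limit of detection.
#' @param p_below_lod Probability a sample's raw readings fall below the
#'   LOD.
#' @param p_duplicate_day Probability a whale-year contributes a
#'   separately-assayed duplicate same-day sample.
#' @param p_small_mass Probability of a sample below the 0.02 g mass
#'   filter.
#' @param samples_per_whale_year Range (min, max) of faecal samples per
#'   whale-year.
#' @param measurements_per_whale_year Range of drone measurements per
#'   whale-year.
#' @param p_early_measurement Probability a drone measurement falls
#'   before the 26 August cut-off (exercising the late-season filter).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_per_class = c(PF = 5, LF = 4, JF = 19, MF = 48),
                       fp4m_pregnant = c(mean = 4.60, sd = 1.15),
                       fp4m_nonpregnant = c(mean = 4.10, sd = 0.77),
                       w50_pregnant = c(mean = 0.178, sd = 0.01),
                       w50_nonpregnant = c(mean = 0.150, sd = 0.01),
                       w50_measurement_sd = 0.005,
                       within_year_log_sd = 0.30,
                       replicate_cv_frac = 0.06,
                       mf_pregnant_fraction = 0.15,
                       lod_pgml = 8.57,
                       p_below_lod = 0.03,
                       p_duplicate_day = 0.08,
                       p_small_mass = 0.03,
                       samples_per_whale_year = c(1, 3),
                       measurements_per_whale_year = c(1, 3),
                       p_early_measurement = 0.25) {
  cfg <- as.list(environment())
  stopifnot(all(cfg$n_per_class >= 0),
            all(names(cfg$n_per_class) %in% c("PF", "LF", "JF", "MF")),
            cfg$mf_pregnant_fraction >= 0, cfg$mf_pregnant_fraction <= 1,
            cfg$w50_measurement_sd >= 0, cfg$lod_pgml > 0)
  structure(cfg, class = "sim_config")
}

#' Simulate a full synthetic dataset
#'
#' Generates the three raw input tables the pipeline ingests (assays,
#' morphometrics, sightings) plus per-whale-year ground truth, with the
#' class-conditional distributions of [sim_config()]. Every QC path is
#' exercised: multiple samples per whale-year (median aggregation),
#' duplicate same-day samples, below-LOD readings, sub-threshold faecal
#' masses, and early-season drone measurements.
#'
#' @param config A [sim_config()].
#' @param seed Optional integer seed; a fixed seed gives byte-identical
#'   output.
#' @return A list of class `sim_dataset` with tibbles `assays`, `morph`,
#'   `sightings`, `truth`, and the `config`.
#' @examples
#' sim <- simulate_dataset(seed = 1)
#' head(sim$truth)
#' @export
simulate_dataset <- function(config = sim_config(), seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(seed)) set.seed(seed)
  cfg <- config

  classes <- rep(names(cfg$n_per_class), cfg$n_per_class)
  n <- length(classes)
  whale_id <- sprintf("Sw-%04d", seq_len(n))
  year <- sample(2016:2021, n, replace = TRUE)

  pregnant <- dplyr::case_when(
    classes == "PF" ~ TRUE,
    classes == "MF" ~ stats::runif(n) < cfg$mf_pregnant_fraction,
    .default = FALSE
  )

  draw2 <- function(p, par_t, par_f) {
    stats::rnorm(length(p), ifelse(p, par_t["mean"], par_f["mean"]),
                 ifelse(p, par_t["sd"], par_f["sd"]))
  }
  true_fp4m <- draw2(pregnant, cfg$fp4m_pregnant, cfg$fp4m_nonpregnant)
  true_w50 <- pmin(pmax(draw2(pregnant, cfg$w50_pregnant,
                              cfg$w50_nonpregnant), 0.08), 0.30)

  # sighting histories: juveniles young, matures at least 8 years
  lsh <- ifelse(classes == "JF", sample(1:7, n, replace = TRUE),
                sample(8:30, n, replace = TRUE))
  first_seen_as_calf <- stats::runif(n) < 0.4
  calf_years <- lapply(seq_len(n), function(i) {
    switch(classes[i], PF = year[i] + 1L, LF = year[i], integer())
  })
  sightings <- tibble::tibble(
    whale_id = whale_id,
    first_year = as.integer(year - lsh),
    first_seen_as_calf = first_seen_as_calf,
    calf_years = calf_years,
    sex_source = sample(c("observation", "tissue-genetics",
                          "faecal-genetics"), n, replace = TRUE)
  )

  # faecal assay samples
  assays <- purrr::map_dfr(seq_len(n), function(i) {
    k <- sample(seq(cfg$samples_per_whale_year[1],
                    cfg$samples_per_whale_year[2]), 1)
    days <- sort(sample(152:290, k))        # June-mid October
    rows <- purrr::map_dfr(seq_len(k), function(j) {
      dup <- stats::runif(1) < cfg$p_duplicate_day
      nsub <- if (dup) 2L else 1L
      purrr::map_dfr(seq_len(nsub), function(s) {
        conc <- exp(true_fp4m[i] +
                      stats::rnorm(1, 0, cfg$within_year_log_sd))
        mass <- if (stats::runif(1) < cfg$p_small_mass)
          stats::runif(1, 0.005, 0.019) else stats::runif(1, 0.03, 1.2)
        vol <- stats::runif(1, 5, 15)
        dil <- sample(c(1, 2), 1)
        mean_pgml <- conc * 1000 * mass / (dil * vol)
        if (stats::runif(1) < cfg$p_below_lod) {
          mean_pgml <- stats::runif(1, 0.2, 0.9) * cfg$lod_pgml
        }
        reps <- abs(stats::rnorm(2, mean_pgml,
                                 cfg$replicate_cv_frac * mean_pgml))
        tibble::tibble(
          whale_id = whale_id[i],
          sample_id = sprintf("%s-%03d-%d", whale_id[i], days[j], s),
          date = as.Date(days[j] - 1, origin = paste0(year[i], "-01-01")),
          rep1_pgml = reps[1], rep2_pgml = reps[2],
          dilution = dil, extract_volume_ml = vol, dry_mass_g = mass,
          pooled = FALSE)
      })
    })
    rows
  })

  # drone photogrammetry measurements
  profile <- function(w50) {
    pos <- seq(20, 70, 5)
    w50 * (1 - 0.55 * ((pos - 47.5) / 27.5)^2)
  }
  morph <- purrr::map_dfr(seq_len(n), function(i) {
    k <- sample(seq(cfg$measurements_per_whale_year[1],
                    cfg$measurements_per_whale_year[2]), 1)
    early <- stats::runif(k) < cfg$p_early_measurement
    days <- ifelse(early, sample(150:238, k, replace = TRUE),
                   sample(239:290, k, replace = TRUE))
    tl <- stats::rnorm(1, ifelse(classes[i] == "JF", 10.2, 12.3), 0.5)
    purrr::map_dfr(seq_len(k), function(j) {
      prof <- profile(true_w50[i])
      meas <- prof + stats::rnorm(length(prof), 0, cfg$w50_measurement_sd)
      row <- tibble::tibble(
        whale_id = whale_id[i],
        date = as.Date(days[j] - 1, origin = paste0(year[i], "-01-01")),
        tl_mean = round(tl, 2), tl_sd = round(stats::runif(1, 0.1, 0.5), 2))
      pos <- seq(20, 70, 5)
      for (p in seq_along(pos)) {
        row[[paste0("w", pos[p], "_mean")]] <- meas[p]
        row[[paste0("w", pos[p], "_sd")]] <- cfg$w50_measurement_sd
      }
      row
    })
  })

  truth <- tibble::tibble(
    whale_id = whale_id, year = as.integer(year),
    group = factor(classes, levels = c("PF", "LF", "JF", "MF")),
    pregnant = pregnant,
    true_fp4m = true_fp4m, true_w50 = true_w50
  )

  structure(list(assays = assays, morph = morph, sightings = sightings,
                 truth = truth, config = cfg),
            class = "sim_dataset")
}

#' Ground-truth labels of a simulated dataset
#'
#' @param sim A [simulate_dataset()] result.
#' @return A tibble with `record_id`, `whale_id`, `year`, `group`, and the
#'   latent `pregnant` state, for oracle evaluation of the pipeline.
#' @export
truth_table <- function(sim) {
  stopifnot(inherits(sim, "sim_dataset"))
  sim$truth |>
    dplyr::mutate(record_id = paste(.data$whale_id, .data$year, sep = ":"),
                  .before = 1) |>
    dplyr::select("record_id", "whale_id", "year", "group", "pregnant")
}

#' Write a simulated dataset to CSV files
#'
#' Emits `assays.csv`, `morph.csv`, `sightings.csv` (calf years
#' semicolon-separated) and `truth.csv` into a directory, in the schemas
#' the preparation functions read back.
#'
#' @param sim A [simulate_dataset()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_sim_dataset <- function(sim, dir) {
  stopifnot(inherits(sim, "sim_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  s <- sim$sightings
  s$calf_years <- vapply(s$calf_years, paste, character(1), collapse = ";")
  readr::write_csv(sim$assays, file.path(dir, "assays.csv"))
  readr::write_csv(sim$morph, file.path(dir, "morph.csv"))
  readr::write_csv(s, file.path(dir, "sightings.csv"))
  readr::write_csv(sim$truth, file.path(dir, "truth.csv"))
  invisible(dir)
}
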