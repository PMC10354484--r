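#' Draw one constrained bootstrap sample
#'
#' Resamples whale-year records with replacement while forcing a set of
#' records (normally the few presumed-pregnant females) into every sample,
#' because a two-component fit is meaningless when a bootstrap draw loses
#' the entire high-mean group.
#'
#' Two schemes are available. `"hold_forced"` (default) keeps each forced
#' record exactly once and fills the remaining `n - n_forced` slots by
#' resampling the non-forced records; the sample size always equals the
#' original `n`. `"resample_all"` resamples all `n` records and then
#' appends any forced record the draw missed, so the sample can be
#' slightly larger than `n`.
#'
#' @param records A data frame of records.
#' @param forced_ids Values of `id_col` to include in every sample.
#' @param id_col Name of the identifier column (default `"record_id"`).
#' @param scheme `"hold_forced"` or `"resample_all"`.
#' @return A data frame of resampled rows (a record multiset).
#' @export
draw_bootstrap_sample <- function(records, forced_ids,
                                  id_col = "record_id",
                                  scheme = c("hold_forced", "resample_all")) {
  scheme <- match.arg(scheme)
  ids <- records[[id_col]]
  if (!all(forced_ids %in% ids)) {
    stop("forced_ids not present in records: ",
         paste(setdiff(forced_ids, ids), collapse = ", "))
  }
  records[boot_indices(ids, forced_ids, scheme), , drop = FALSE]
}

# index-level resampling shared by draw_bootstrap_sample() and the
# bootstrap loop; consumes the RNG stream
boot_indices <- function(ids, forced_ids, scheme) {
  n <- length(ids)
  forced_idx <- which(ids %in% forced_ids)
  if (scheme == "hold_forced") {
    free <- setdiff(seq_len(n), forced_idx)
    n_draw <- n - length(forced_idx)
    if (n_draw > 0 && length(free) == 0) {
      stop("no non-forced records to resample")
    }
    drawn <- if (n_draw > 0) sample(free, n_draw, replace = TRUE) else integer()
    c(forced_idx, drawn)
  } else {
    drawn <- sample.int(n, n, replace = TRUE)
    c(drawn, setdiff(forced_idx, drawn))
  }
}

#' Bootstrap pregnancy probabilities from a normal mixture model
#'
#' Runs the full constrained non-parametric bootstrap: resample the
#' records `n_boot` times (with the presumed-pregnant records forced into
#' every sample), fit the two-component normal mixture to each bootstrap
#' sample, keep only replicates whose fit converged *and* produced a valid
#' component labelling (one component's mean strictly higher in every
#' modelled variable), and evaluate the posterior probability of pregnancy
#' at every original record under every retained fit. Per-record
#' probabilities are then summarised across retained replicates.
#'
#' Three models are supported: `"joint"` (bivariate log-fP4m + W50,
#' Model 1), `"fp4m"` (Model 2) and `"w50"` (Model 3). The point estimate
#' is the across-replicate mean for the bivariate model and the median for
#' the univariate models (`point_rule` overrides this default); quartiles
#' and the 2.5/97.5 percentile confidence limits are always reported.
#'
#' @param records Data frame with columns `record_id`, `group`, and the
#'   modelled variable(s) `fp4m` and/or `w50`. Records missing a modelled
#'   variable are dropped for fitting but also excluded from evaluation.
#' @param model `"joint"`, `"fp4m"`, or `"w50"` (or 1, 2, 3).
#' @param n_boot Number of bootstrap replicates.
#' @param seed Optional integer seed set before resampling begins.
#' @param weighting Posterior weighting passed to [posterior_pregnancy()]:
#'   `"responsibility"` (mixing-weighted EM posterior) or `"literal"`
#'   (plain density ratio). The default is per model: `"responsibility"`
#'   for the fP4m model and `"literal"` for the W50 and joint models, the
#'   combination that reproduces the reference per-record probabilities
#'   shipped with [gray_whale_records()] (see the package vignette for the
#'   calibration evidence).
#' @param point_rule `"mean"` or `"median"`; defaults by model as above.
#' @param forced_ids Record ids forced into every sample; defaults to the
#'   `PF` records present in the model's subset.
#' @param scheme Resampling scheme, see [draw_bootstrap_sample()].
#' @param init EM initialization protocol per replicate fit, see
#'   [mix_fit()]. The default `"partition"` (one random-partition start,
#'   retried only on failure) matters for the bivariate model: its
#'   likelihood surface typically carries both a dominance-valid local
#'   optimum and a dominance-invalid optimum with higher likelihood, so a
#'   best-of-many-starts protocol would systematically select the invalid
#'   one and cut the retained fraction far below what a standard
#'   single-start EM yields on the same replicates.
#' @param n_restarts Restart budget per replicate fit.
#' @return An object of class `preg_boot` with elements `summary` (tibble:
#'   one row per record with `point`, `lq`, `uq`, `ci_low`, `ci_high`,
#'   plus `point_mean`/`point_median` under both rules), `retention`
#'   (fraction of replicates retained), `n_boot`, `n_retained`, `model`,
#'   `vars`, `weighting`, `point_rule`, and `seed`.
#' @examples
#' recs <- gray_whale_records()
#' bb <- boot_pregnancy(recs, model = "w50", n_boot = 50, seed = 1)
#' glance(bb)
#' @export
boot_pregnancy <- function(records,
                           model = c("joint", "fp4m", "w50"),
                           n_boot = 10000,
                           seed = NULL,
                           weighting = NULL,
                           point_rule = NULL,
                           forced_ids = NULL,
                           scheme = c("hold_forced", "resample_all"),
                           init = c("partition", "best"),
                           n_restarts = 5) {
  if (is.numeric(model)) model <- c("joint", "fp4m", "w50")[model]
  model <- match.arg(model)
  weighting <- weighting %||%
    switch(model, fp4m = "responsibility", "literal")
  weighting <- match.arg(weighting, c("responsibility", "literal"))
  scheme <- match.arg(scheme)
  init <- match.arg(init)
  vars <- switch(model, joint = c("fp4m", "w50"), fp4m = "fp4m", w50 = "w50")
  point_rule <- point_rule %||% if (model == "joint") "mean" else "median"
  stopifnot(point_rule %in% c("mean", "median"), n_boot >= 1)

  sub <- records[stats::complete.cases(records[, vars, drop = FALSE]), ,
                 drop = FALSE]
  if (nrow(sub) < 4) stop("fewer than 4 records with ",
                          paste(vars, collapse = "+"), " present")
  ids <- sub$record_id
  if (is.null(forced_ids)) forced_ids <- ids[sub$group == "PF"]
  X <- as.matrix(sub[, vars, drop = FALSE])

  if (!is.null(seed)) set.seed(seed)

  probs <- matrix(NA_real_, nrow(sub), n_boot)
  retained <- 0L
  for (b in seq_len(n_boot)) {
    idx <- boot_indices(ids, forced_ids, scheme)
    fit <- mix_fit(X[idx, , drop = FALSE], init = init,
                   n_restarts = n_restarts)
    if (!fit$converged) next
    lab <- label_components(fit)
    if (!lab$valid) next
    retained <- retained + 1L
    probs[, retained] <- posterior_pregnancy(fit, X, weighting = weighting,
                                             labels = lab)
  }
  if (retained == 0L) {
    stop("no bootstrap replicate was retained for model '", model,
         "' (n_boot = ", n_boot, "); the mixture may be degenerate on ",
         "these records")
  }
  probs <- probs[, seq_len(retained), drop = FALSE]

  qs <- t(apply(probs, 1, quantile, probs = c(0.025, 0.25, 0.75, 0.975),
                names = FALSE, type = 7))
  summary <- tibble::tibble(
    record_id = ids,
    group = sub$group,
    point_mean = rowMeans(probs),
    point_median = apply(probs, 1, median),
    ci_low = qs[, 1], lq = qs[, 2], uq = qs[, 3], ci_high = qs[, 4],
    n_retained = retained
  )
  summary$point <- if (point_rule == "mean") summary$point_mean else
    summary$point_median
  summary <- dplyr::relocate(summary, "point", .after = "group")

  structure(
    list(summary = summary,
         retention = retained / n_boot,
         n_boot = n_boot,
         n_retained = retained,
         model = model,
         vars = vars,
         weighting = weighting,
         point_rule = point_rule,
         scheme = scheme,
         init = init,
         forced_ids = forced_ids,
         seed = seed),
    class = "preg_boot")
}

#' @export
print.preg_boot <- function(x, ...) {
  cat("Constrained bootstrap pregnancy probabilities\n")
  cat("  model:     ", x$model, " (", paste(x$vars, collapse = " + "),
      ")\n", sep = "")
  cat("  replicates:", x$n_boot, "retained:", x$n_retained,
      sprintf("(%.1f%%)", 100 * x$retention), "\n")
  cat("  point rule:", x$point_rule, " weighting:", x$weighting, "\n")
  print(x$summary, n = 10)
  invisible(x)
}

#' Tidy bootstrap pregnancy summaries
#'
#' @param x A [boot_pregnancy()] object.
#' @param ... Unused.
#' @return The per-record summary tibble.
#' @export
tidy.preg_boot <- function(x, ...) x$summary

#' One-row summary of a bootstrap run
#'
#' @param x A [boot_pregnancy()] object.
#' @param ... Unused.
#' @return A one-row tibble with the model, replicate counts and the
#'   retained fraction.
#' @export
glance.preg_boot <- function(x, ...) {
  tibble::tibble(model = x$model, n_records = nrow(x$summary),
                 n_boot = x$n_boot, n_retained = x$n_retained,
                 retention = x$retention, point_rule = x$point_rule,
                 weighting = x$weighting)
}

#' Plot bootstrap pregnancy probabilities by reproductive class
#'
#' Point estimates with 95% bootstrap confidence intervals for every
#' record, grouped by reproductive class, with the classification
#' threshold drawn as a horizontal line.
#'
#' @param object A [boot_pregnancy()] object.
#' @param threshold Classification threshold drawn as a reference line.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.preg_boot <- function(object, threshold = 0.75, ...) {
  df <- object$summary |>
    dplyr::arrange(.data$group, dplyr::desc(.data$point)) |>
    dplyr::mutate(record_id = factor(.data$record_id,
                                     levels = .data$record_id))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$record_id, y = .data$point)) +
    ggplot2::geom_linerange(ggplot2::aes(ymin = .data$ci_low,
                                         ymax = .data$ci_high),
                            linetype = "dashed", linewidth = 0.3) +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_hline(yintercept = threshold, colour = "grey40",
                        linetype = "dotted") +
    ggplot2::facet_grid(~group, scales = "free_x", space = "free_x") +
    ggplot2::labs(x = NULL, y = "P(pregnant)",
                  title = paste0("Bootstrap pregnancy probability (",
                                 object$model, " model)")) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       size = 5,
                                                       vjust = 0.5))
}
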