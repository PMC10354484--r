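#' Highest posterior density interval of a sample
#'
#' The shortest contiguous interval of the sorted sample containing
#' `ceiling(level * n)` points; ties between equally short windows break
#' toward the lowest start. For symmetric unimodal samples this coincides
#' with the equal-tailed interval; for skewed samples it is shorter.
#'
#' @param samples Numeric vector.
#' @param level Coverage level in (0, 1).
#' @return Named numeric vector `c(low, high)`.
#' @examples
#' hpdi(1:100, 0.95)  # c(1, 95): all windows tie, lowest start wins
#' @export
hpdi <- function(samples, level = 0.95) {
  if (!is.numeric(level) || length(level) != 1 || level <= 0 || level >= 1) {
    stop("level must be a single number in (0, 1)")
  }
  samples <- samples[!is.na(samples)]
  n <- length(samples)
  if (n >= 1 && min(samples) == max(samples)) {
    # a point mass is exact at any sample size
    return(c(low = samples[1], high = samples[1]))
  }
  m <- ceiling(level * n)
  if (n < ceiling(1 / (1 - level)) || m < 1) {
    stop("need at least ", ceiling(1 / (1 - level)),
         " samples for level ", level)
  }
  if (m >= n) {
    return(c(low = min(samples), high = max(samples)))
  }
  s <- sort(samples)
  widths <- s[m:n] - s[1:(n - m + 1)]
  i <- which.min(widths)  # which.min returns the first (lowest-start) tie
  c(low = s[i], high = s[i + m - 1])
}

#' Monte Carlo ANOVA of W50 by demographic unit
#'
#' Propagates per-measurement photogrammetric uncertainty into the group
#' comparison of W50: in each of `n_rep` replicates every record's W50 is
#' drawn from Normal(`w50`, `w50_sd`^2) (its photogrammetric posterior),
#' the per-group means (the cell-means coding of a one-way ANOVA) and all
#' pairwise differences are computed, and the replicate results are
#' summarised as means with 95% highest posterior density intervals.
#'
#' @param records Data frame with columns `group`, `w50`, and `w50_sd`
#'   (all sds > 0; supply or simulate measurement sds if your source lacks
#'   them).
#' @param n_rep Number of Monte Carlo replicates.
#' @param level HPDI coverage level.
#' @param seed Optional integer seed.
#' @return An object of class `mc_anova`: list with `groups` (tibble of
#'   per-group mean and HPDI), `differences` (tibble of pairwise mean
#'   differences with HPDIs), `n_rep`, `level`, and `seed`.
#' @examples
#' df <- data.frame(group = rep(c("JF", "PF"), each = 5),
#'                  w50 = rep(c(0.15, 0.18), each = 5), w50_sd = 0.005)
#' mc_anova(df, n_rep = 2000, seed = 1)
#' @export
mc_anova <- function(records, n_rep = 80000, level = 0.95, seed = NULL) {
  stopifnot(all(c("group", "w50", "w50_sd") %in% names(records)))
  records <- records[!is.na(records$w50), , drop = FALSE]
  if (any(is.na(records$w50_sd) | records$w50_sd <= 0)) {
    stop("every record needs a positive w50_sd; supply measurement sds ",
         "or simulate them before calling mc_anova()")
  }
  grp <- droplevels(factor(records$group))
  counts <- table(grp)
  if (length(counts) < 2 || any(counts < 2)) {
    stop("need at least two groups with at least two records each")
  }

  if (!is.null(seed)) set.seed(seed)
  n <- nrow(records)
  # one draw matrix per replicate column; group means via the indicator map
  G <- stats::model.matrix(~grp - 1)
  G <- sweep(G, 2, colSums(G), "/")              # n x k averaging weights
  draws <- matrix(stats::rnorm(n * n_rep, records$w50, records$w50_sd),
                  nrow = n, ncol = n_rep)
  means <- crossprod(G, draws)                   # k x n_rep group means
  rownames(means) <- levels(grp)

  groups <- tibble::tibble(
    group = levels(grp),
    n = as.integer(counts),
    mean = rowMeans(means),
    hpdi_low = apply(means, 1, function(z) unname(hpdi(z, level)[1])),
    hpdi_high = apply(means, 1, function(z) unname(hpdi(z, level)[2]))
  )

  pairs <- utils::combn(levels(grp), 2, simplify = FALSE)
  differences <- purrr::map_dfr(pairs, function(p) {
    d <- means[p[2], ] - means[p[1], ]
    h <- hpdi(d, level)
    tibble::tibble(contrast = paste(p[2], "-", p[1]),
                   mean = mean(d), hpdi_low = unname(h[1]),
                   hpdi_high = unname(h[2]),
                   excludes_zero = unname(h[1] > 0 | h[2] < 0))
  })

  structure(list(groups = groups, differences = differences,
                 n_rep = n_rep, level = level, seed = seed),
            class = "mc_anova")
}

#' @export
print.mc_anova <- function(x, ...) {
  cat("Monte Carlo ANOVA (", x$n_rep, " replicates, ",
      100 * x$level, "% HPDI)\n", sep = "")
  print(x$groups)
  print(x$differences)
  invisible(x)
}

#' Tidy Monte Carlo ANOVA pairwise differences
#'
#' @param x An [mc_anova()] object.
#' @param ... Unused.
#' @return The pairwise-differences tibble.
#' @export
tidy.mc_anova <- function(x, ...) x$differences

#' One-row summary of a Monte Carlo ANOVA
#'
#' @param x An [mc_anova()] object.
#' @param ... Unused.
#' @return A one-row tibble.
#' @export
glance.mc_anova <- function(x, ...) {
  tibble::tibble(n_rep = x$n_rep, level = x$level,
                 n_groups = nrow(x$groups),
                 n_contrasts = nrow(x$differences))
}

#' One-way ANOVA with Tukey HSD on an indicator variable
#'
#' Convenience wrapper around [stats::aov()] and [stats::TukeyHSD()] for
#' the exploratory group comparison of an indicator (e.g. log-fP4m) by
#' reproductive class, ignoring measurement uncertainty.
#'
#' @param records Data frame with a `group` column.
#' @param var Name of the response column.
#' @return A list with the `aov` fit and the `TukeyHSD` table.
#' @export
anova_tukey <- function(records, var = "fp4m") {
  df <- records[!is.na(records[[var]]), , drop = FALSE]
  df$group <- droplevels(factor(df$group))
  fit <- stats::aov(stats::reformulate("group", var), data = df)
  list(aov = fit, tukey = stats::TukeyHSD(fit))
}
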