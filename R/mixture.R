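#' Fit a two-component normal mixture by EM
#'
#' Fits a two-component Gaussian mixture to one or two variables of a data
#' frame using the EM algorithm with full (unconstrained) covariance
#' matrices. This is the model underlying pregnancy diagnosis: one component
#' is interpreted as the presumed non-pregnant group (low fP4m and/or low
#' W50) and the other, with higher means, as the pregnant group.
#'
#' Two initialization protocols are available. `init = "best"` (the
#' default for one-off fits) runs EM from a deterministic rank-based split
#' (records below / above the median of the first variable seed the two
#' components) plus `n_restarts` runs seeded at random pairs of
#' distinct-valued data points, and the converged, non-degenerate fit with
#' the highest log-likelihood wins. `init = "partition"` runs EM from a
#' single random hard partition of the records into two halves, retrying
#' (up to `n_restarts` times) only when the run fails; the fit is whichever
#' local optimum that start reaches. The bootstrap uses `"partition"`: see
#' [boot_pregnancy()] for why.
#'
#' A fit is flagged degenerate when any covariance eigenvalue falls below
#' `var_floor`, which guards against component collapse onto tied values
#' (the width data are reported to two decimals, so exact ties are common).
#'
#' @param data A data frame, numeric vector, or numeric matrix with one or
#'   two columns.
#' @param vars Character vector naming the one or two columns to model when
#'   `data` is a data frame. Defaults to all columns.
#' @param init `"best"` or `"partition"`, see Details.
#' @param n_restarts Number of additional random starts (`"best"`) or
#'   failure retries (`"partition"`).
#' @param tol Relative log-likelihood convergence tolerance.
#' @param max_iter Maximum EM iterations per start. The default is generous
#'   because heavily overlapping components separate slowly, and width
#'   data reported to two decimals produce ties that slow the E-step
#'   geometry further.
#' @param var_floor Minimum admissible covariance eigenvalue.
#' @return An object of class `mix_fit`: a list with elements `lambda`
#'   (mixing weights), `mu` (2 x d matrix of component means), `sigma`
#'   (list of two covariance matrices), `loglik`, `trace` (log-likelihood
#'   at every EM iteration of the winning start), `n_iter`, `converged`,
#'   `degenerate`, `dim`, and `vars`.
#' @examples
#' set.seed(1)
#' x <- c(rnorm(50, 0, 1), rnorm(50, 5, 1))
#' fit <- mix_fit(x)
#' tidy(fit)
#' @export
mix_fit <- function(data, vars = NULL,
                    init = c("best", "partition"),
                    n_restarts = 10, tol = 1e-8,
                    max_iter = 2000, var_floor = 1e-10) {
  init <- match.arg(init)
  X <- as_model_matrix(data, vars)
  n <- nrow(X)
  d <- ncol(X)
  if (d > 2) stop("mix_fit() models one or two variables, got ", d)
  if (n < 4) stop("need at least 4 complete observations, got ", n)
  if (anyNA(X)) stop("missing values in the modelled variables")

  if (init == "best") {
    inits <- c(list(init_split(X)), replicate(n_restarts, init_random(X),
                                              simplify = FALSE))
    fits <- lapply(inits, function(ini) {
      em_gauss2_cpp(X, ini$lambda, ini$mu, ini$sigma, tol, max_iter,
                    var_floor)
    })
    ok <- vapply(fits, function(f) f$converged && !f$degenerate, logical(1))
    if (any(ok)) {
      lls <- vapply(fits, function(f) if (f$converged && !f$degenerate)
        f$loglik else -Inf, numeric(1))
      best <- fits[[which.max(lls)]]
    } else {
      # no usable start: return the split-init fit, flagged non-convergent
      best <- fits[[1]]
      best$converged <- FALSE
    }
  } else {
    # one random-partition start, retried on failure: the fit is whichever
    # local optimum that start reaches, not the best of many.  This is the
    # protocol classic mixture-EM implementations use by default, and the
    # one the bootstrap relies on (see boot_pregnancy)
    best <- NULL
    for (r in seq_len(n_restarts + 1L)) {
      ini <- init_partition(X)
      f <- em_gauss2_cpp(X, ini$lambda, ini$mu, ini$sigma, tol, max_iter,
                         var_floor)
      if (f$converged && !f$degenerate) { best <- f; break }
      if (is.null(best)) best <- f
    }
    if (best$degenerate) best$converged <- FALSE
  }

  structure(
    list(lambda = as.numeric(best$lambda),
         mu = unname(best$mu),
         sigma = lapply(best$sigma, unname),
         loglik = best$loglik,
         trace = as.numeric(best$trace),
         n_iter = best$n_iter,
         converged = isTRUE(best$converged) && !isTRUE(best$degenerate),
         degenerate = isTRUE(best$degenerate),
         dim = d,
         n = n,
         vars = colnames(X)),
    class = "mix_fit")
}

# coerce the accepted input shapes to an n x d numeric matrix
as_model_matrix <- function(data, vars = NULL) {
  if (is.data.frame(data)) {
    if (is.null(vars)) vars <- names(data)
    X <- as.matrix(data[, vars, drop = FALSE])
  } else if (is.numeric(data) && is.null(dim(data))) {
    X <- matrix(data, ncol = 1, dimnames = list(NULL, vars %||% "x"))
  } else {
    X <- as.matrix(data)
    if (is.null(colnames(X))) {
      colnames(X) <- vars %||% paste0("x", seq_len(ncol(X)))
    }
  }
  storage.mode(X) <- "double"
  X
}

# random hard partition into two halves (consumes the RNG stream)
init_partition <- function(X) {
  n <- nrow(X)
  perm <- sample.int(n)
  k <- floor(n / 2)
  moments_init(X, list(perm[seq_len(k)], perm[(k + 1):n]))
}

# deterministic initialization: split on the rank of the first variable
init_split <- function(X) {
  ord <- order(X[, 1])
  n <- nrow(X)
  lo <- ord[seq_len(ceiling(n / 2))]
  hi <- setdiff(ord, lo)
  moments_init(X, list(lo, hi))
}

# random restart: component means seeded at two distinct random data
# points with the pooled covariance; gives diverse basins of attraction,
# unlike random responsibilities which concentrate both components on the
# global moments (consumes the RNG stream)
init_random <- function(X) {
  n <- nrow(X)
  i1 <- sample.int(n, 1)
  # the second seed must differ in value, not merely in index: seeding both
  # components at the same tied value puts EM on an exactly symmetric
  # manifold it can never leave (a saddle with equal means)
  differs <- which(rowSums(abs(sweep(X, 2, X[i1, ])) > 0) > 0)
  i2 <- if (length(differs)) differs[sample.int(length(differs), 1)] else
    sample.int(n, 1)
  mu <- X[c(i1, i2), , drop = FALSE]
  S <- regularize_cov(stats::cov(X) * (n - 1) / n, X)
  list(lambda = c(0.5, 0.5), mu = unname(mu), sigma = list(S, S))
}

moments_init <- function(X, idx) {
  d <- ncol(X)
  mu <- matrix(0, 2, d)
  sigma <- vector("list", 2)
  for (k in 1:2) {
    Xi <- X[idx[[k]], , drop = FALSE]
    mu[k, ] <- colMeans(Xi)
    S <- stats::cov(Xi) * (nrow(Xi) - 1) / nrow(Xi)
    sigma[[k]] <- regularize_cov(S, X)
  }
  list(lambda = c(0.5, 0.5), mu = mu, sigma = sigma)
}

moments_from_resp <- function(X, resp) {
  d <- ncol(X)
  nk <- colSums(resp)
  mu <- matrix(0, 2, d)
  sigma <- vector("list", 2)
  for (k in 1:2) {
    mu[k, ] <- colSums(X * resp[, k]) / nk[k]
    centred <- sweep(X, 2, mu[k, ])
    S <- crossprod(centred, centred * resp[, k]) / nk[k]
    sigma[[k]] <- regularize_cov(S, X)
  }
  list(lambda = nk / nrow(X), mu = mu, sigma = sigma)
}

# keep starting covariances positive definite even for constant halves
regularize_cov <- function(S, X) {
  S <- (S + t(S)) / 2
  floor_var <- 1e-6 * max(apply(X, 2, stats::var), 1e-12)
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < floor_var) S <- S + diag(floor_var, ncol(S))
  S
}

#' Identify the pregnant (higher-mean) mixture component
#'
#' Labels the component whose mean strictly exceeds the other component's
#' mean in *every* modelled dimension as the pregnant component. When
#' neither component dominates (e.g. one component has higher fP4m but
#' lower W50), the labelling is invalid; the bootstrap retention rules
#' discard such replicates rather than raising an error.
#'
#' @param fit A [mix_fit()] object.
#' @return A list with elements `high`, `low` (component indices) and
#'   `valid` (logical).
#' @export
label_components <- function(fit) {
  stopifnot(inherits(fit, "mix_fit"))
  d1 <- all(fit$mu[1, ] > fit$mu[2, ])
  d2 <- all(fit$mu[2, ] > fit$mu[1, ])
  if (d2) {
    list(high = 2L, low = 1L, valid = TRUE)
  } else if (d1) {
    list(high = 1L, low = 2L, valid = TRUE)
  } else {
    list(high = NA_integer_, low = NA_integer_, valid = FALSE)
  }
}

#' Posterior probability of pregnancy under a fitted mixture
#'
#' Evaluates, for each observation, the probability of belonging to the
#' pregnant (higher-mean) component. Two weightings are available:
#' `"responsibility"` (the default) is the standard EM posterior
#' \eqn{\lambda_H \phi_H(x) / (\lambda_H \phi_H(x) + \lambda_L \phi_L(x))}
#' including the mixing weights; `"literal"` is the plain density ratio
#' \eqn{\phi_H(x) / (\phi_H(x) + \phi_L(x))}. Both are computed in log
#' space so extreme observations never produce NaN.
#'
#' @param fit A converged [mix_fit()] object.
#' @param newdata A data frame containing the fitted variables, a numeric
#'   vector (univariate fits), or a matrix.
#' @param weighting `"responsibility"` or `"literal"`.
#' @param labels Component labelling, normally from [label_components()].
#' @return A numeric vector of probabilities in `[0, 1]`.
#' @export
posterior_pregnancy <- function(fit, newdata,
                                weighting = c("responsibility", "literal"),
                                labels = label_components(fit)) {
  stopifnot(inherits(fit, "mix_fit"))
  weighting <- match.arg(weighting)
  if (!isTRUE(labels$valid)) {
    stop("component labelling is invalid: neither component's mean ",
         "dominates in every dimension")
  }
  X <- as_model_matrix(newdata, if (is.data.frame(newdata)) fit$vars else NULL)
  if (ncol(X) != fit$dim) {
    stop("newdata has ", ncol(X), " columns but the fit has dimension ",
         fit$dim)
  }
  hi <- labels$high
  lo <- labels$low
  lh <- mvn_logdens(X, fit$mu[hi, ], fit$sigma[[hi]])
  ll <- mvn_logdens(X, fit$mu[lo, ], fit$sigma[[lo]])
  if (weighting == "responsibility") {
    lh <- lh + log(fit$lambda[hi])
    ll <- ll + log(fit$lambda[lo])
  }
  unname(stats::plogis(lh - ll))
}

# log multivariate normal density, d = 1 or 2, vectorized over rows
mvn_logdens <- function(X, mu, Sigma) {
  d <- ncol(X)
  if (d == 1) {
    return(stats::dnorm(X[, 1], mu, sqrt(Sigma[1, 1]), log = TRUE))
  }
  L <- chol(Sigma)
  centred <- sweep(X, 2, mu)
  z <- backsolve(L, t(centred), transpose = TRUE)
  -0.5 * (d * log(2 * pi) + 2 * sum(log(diag(L))) + colSums(z^2))
}

#' @export
print.mix_fit <- function(x, ...) {
  cat("Two-component normal mixture (", x$dim, "-dimensional, n = ", x$n,
      ")\n", sep = "")
  cat("  variables:", paste(x$vars, collapse = ", "), "\n")
  cat("  weights:  ", sprintf("%.3f", x$lambda), "\n")
  for (k in 1:2) {
    cat("  mean ", k, ":   ", paste(sprintf("%.4f", x$mu[k, ]),
                                    collapse = ", "), "\n", sep = "")
  }
  cat("  loglik:   ", sprintf("%.4f", x$loglik),
      if (x$converged) " (converged in" else " (NOT converged after",
      x$n_iter, "iterations)\n")
  invisible(x)
}

#' Tidy a mixture fit into one row per component
#'
#' @param x A [mix_fit()] object.
#' @param ... Unused.
#' @return A tibble with columns `component`, `weight`, one `mean_*` and
#'   one `var_*` column per modelled variable, and `cov` (the off-diagonal
#'   covariance, `NA` for univariate fits).
#' @export
tidy.mix_fit <- function(x, ...) {
  vars <- x$vars
  out <- tibble::tibble(component = 1:2, weight = x$lambda)
  for (j in seq_along(vars)) {
    out[[paste0("mean_", vars[j])]] <- x$mu[, j]
    out[[paste0("var_", vars[j])]] <-
      vapply(x$sigma, function(S) S[j, j], numeric(1))
  }
  out$cov <- if (x$dim == 2) {
    vapply(x$sigma, function(S) S[1, 2], numeric(1))
  } else {
    NA_real_
  }
  out
}

#' One-row summary of a mixture fit
#'
#' @param x A [mix_fit()] object.
#' @param ... Unused.
#' @return A one-row tibble with `loglik`, `n_iter`, `converged`,
#'   `degenerate`, `dim`, `n`, and `labels_valid`.
#' @export
glance.mix_fit <- function(x, ...) {
  tibble::tibble(loglik = x$loglik, n_iter = x$n_iter,
                 converged = x$converged, degenerate = x$degenerate,
                 dim = x$dim, n = x$n,
                 labels_valid = label_components(x)$valid)
}
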