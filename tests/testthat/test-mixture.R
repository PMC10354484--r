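test_that("EM recovers well-separated clusters exactly", {
  x <- sep_clusters()
  withr::local_seed(1)
  for (init in c("best", "partition")) {
    fit <- mix_fit(x, init = init)
    expect_true(fit$converged)
    expect_equal(sort(fit$mu[, 1]), c(0, 5), tolerance = 1e-6)
    expect_equal(fit$lambda, c(0.5, 0.5), tolerance = 1e-6)
    # at the fixed point each component carries its cluster's moments
    expect_equal(sort(sapply(fit$sigma, function(S) S[1, 1])),
                 rep(var(c(-0.1, 0, 0.1)) * 2 / 3, 2), tolerance = 1e-6)
  }
})

test_that("degenerate data is flagged, not silently fitted", {
  withr::local_seed(1)
  fit <- mix_fit(rep(1, 10))
  expect_false(fit$converged)
  expect_error(mix_fit(c(1, 2, 3)), "at least 4")
})

test_that("log-likelihood is non-decreasing on every EM trace", {
  withr::local_seed(42)
  for (i in 1:20) {
    x <- rmix2(40, c(0.5, 0.5), c(0, runif(1, 1, 6)), c(1, runif(1, 0.5, 2)))
    fit <- mix_fit(x, init = sample(c("best", "partition"), 1))
    expect_true(all(diff(fit$trace) >= -1e-8), info = paste("dataset", i))
  }
  # bivariate as well
  for (i in 1:5) {
    X <- cbind(rnorm(40, rep(c(0, 3), each = 20)),
               rnorm(40, rep(c(0, 2), each = 20), 0.7))
    fit <- mix_fit(X)
    expect_true(all(diff(fit$trace) >= -1e-8))
  }
})

test_that("component labelling requires dominance in every dimension", {
  fake <- function(mu) {
    structure(list(lambda = c(0.5, 0.5), mu = mu,
                   sigma = list(diag(ncol(mu)), diag(ncol(mu))),
                   dim = ncol(mu), converged = TRUE),
              class = "mix_fit")
  }
  expect_equal(label_components(fake(rbind(c(0, 0), c(5, 5))))$high, 2L)
  expect_true(label_components(fake(rbind(c(0, 0), c(5, 5))))$valid)
  expect_false(label_components(fake(rbind(c(0, 5), c(5, 0))))$valid)
  lab <- label_components(fake(matrix(c(3, 4), 2, 1)))
  expect_equal(lab$high, 2L)
})

test_that("posterior pregnancy probability matches closed forms", {
  fake <- structure(
    list(lambda = c(0.5, 0.5), mu = matrix(c(0, 5), 2, 1),
         sigma = list(matrix(1), matrix(1)), dim = 1, converged = TRUE,
         vars = "x"),
    class = "mix_fit")
  # midpoint of the means: exactly 1/2 under both weightings
  expect_equal(posterior_pregnancy(fake, 2.5), 0.5)
  expect_equal(posterior_pregnancy(fake, 2.5, weighting = "literal"), 0.5)
  # literal closed form: logit = (d/sd^2) * (x - midpoint)
  expect_equal(posterior_pregnancy(fake, 2, weighting = "literal"),
               plogis(5 * (2 - 2.5)))
  expect_equal(round(posterior_pregnancy(fake, 2, weighting = "literal"), 4),
               0.0759)
  # far beyond the high mean: probability 1 without NaN (log-space)
  expect_equal(posterior_pregnancy(fake, c(5, 500, -500)), c(1, 1, 0),
               tolerance = 1e-5)
  # unequal weights shift the responsibility but not the literal mode
  fake$lambda <- c(0.9, 0.1)
  expect_equal(posterior_pregnancy(fake, 2.5, weighting = "literal"), 0.5)
  expect_equal(posterior_pregnancy(fake, 2.5),
               plogis(log(0.1 / 0.9)))
})

test_that("posteriors are monotone in x under equal covariances", {
  fake <- structure(
    list(lambda = c(0.3, 0.7), mu = matrix(c(1, 3), 2, 1),
         sigma = list(matrix(0.5), matrix(0.5)), dim = 1,
         converged = TRUE, vars = "x"),
    class = "mix_fit")
  g <- seq(-3, 8, length.out = 60)
  for (w in c("responsibility", "literal")) {
    p <- posterior_pregnancy(fake, g, weighting = w)
    expect_true(all(diff(p) >= 0))
  }
})

test_that("label order is irrelevant: swapped components give identical
           probabilities bit for bit", {
  withr::local_seed(3)
  x <- rmix2(60, c(0.6, 0.4), c(1, 4), c(0.8, 1.2))
  fit <- mix_fit(x)
  swapped <- fit
  swapped$lambda <- rev(fit$lambda)
  swapped$mu <- fit$mu[2:1, , drop = FALSE]
  swapped$sigma <- fit$sigma[2:1]
  grid <- seq(-2, 7, length.out = 41)
  for (w in c("responsibility", "literal")) {
    expect_identical(posterior_pregnancy(fit, grid, weighting = w),
                     posterior_pregnancy(swapped, grid, weighting = w))
  }
})

test_that("EM log-likelihood beats a random-parameter search oracle", {
  withr::local_seed(7)
  x <- c(-0.4, 0.1, 0.3, 2.8, 3.1, 3.3, 3.6, 3.9)
  fit <- mix_fit(x)
  expect_true(fit$converged)
  # brute-force lower bound: 1000 random parameter draws over the same
  # non-degenerate model class EM searches (component sds bounded away
  # from the collapse region the variance floor excludes)
  ll_mix <- function(lambda, mu, sd) {
    sum(log(lambda * dnorm(x, mu[1], sd[1]) +
              (1 - lambda) * dnorm(x, mu[2], sd[2])))
  }
  best <- max(replicate(1000, {
    ll_mix(runif(1, 0.05, 0.95), runif(2, min(x), max(x)),
           runif(2, 0.25 * sd(x), 2 * sd(x)))
  }))
  expect_gte(fit$loglik, best)
})

test_that("EM agrees with an independent mixture implementation", {
  skip_if_not_installed("mclust")
  withr::local_package("mclust")
  withr::local_seed(11)
  x <- rmix2(300, c(0.6, 0.4), c(0, 3.5), c(1, 0.8))
  fit <- mix_fit(x)
  mc <- mclust::Mclust(x, G = 2, modelNames = "V", verbose = FALSE)
  expect_true(fit$converged)
  expect_gte(fit$loglik, mc$loglik - 1e-4)
  expect_equal(sort(fit$mu[, 1]), sort(as.numeric(mc$parameters$mean)),
               tolerance = 0.05)
  expect_equal(sort(fit$lambda), sort(mc$parameters$pro), tolerance = 0.05)
})

test_that("parameters of a known mixture are recovered at n = 500", {
  withr::local_seed(5)
  lambda <- c(0.5, 0.5)
  mu <- c(0.150, 0.178)
  sdv <- c(0.01, 0.01)
  x <- rmix2(500, lambda, mu, sdv)
  fit <- mix_fit(x)
  lab <- label_components(fit)
  expect_true(fit$converged && lab$valid)
  # 3 x Monte-Carlo SE of a component mean at n ~ 250
  tol <- 3 * 0.01 / sqrt(250)
  expect_equal(fit$mu[lab$low, 1], mu[1], tolerance = tol / mu[1])
  expect_equal(fit$mu[lab$high, 1], mu[2], tolerance = tol / mu[2])
})

test_that("tidy and glance summarise fits in broom style", {
  withr::local_seed(2)
  X <- cbind(a = rnorm(40, rep(c(0, 4), each = 20)),
             b = rnorm(40, rep(c(0, 3), each = 20)))
  fit <- mix_fit(X)
  td <- tidy(fit)
  expect_equal(nrow(td), 2)
  expect_true(all(c("component", "weight", "mean_a", "mean_b", "var_a",
                    "var_b", "cov") %in% names(td)))
  gl <- glance(fit)
  expect_equal(nrow(gl), 1)
  expect_true(gl$converged)
  expect_true(gl$labels_valid)
})
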