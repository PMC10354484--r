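# small in-code fixtures shared across test files

# two clearly separated univariate clusters
sep_clusters <- function(n_per = 3, gap = 5) {
  c(seq(-0.1, 0.1, length.out = n_per),
    gap + seq(-0.1, 0.1, length.out = n_per))
}

# minimal whale-year record table for bootstrap tests: two separated
# groups in both variables, PF on the high side
toy_records <- function(n_low = 12, n_high = 5) {
  tibble::tibble(
    record_id = sprintf("w%02d:2020", seq_len(n_low + n_high)),
    group = factor(c(rep("JF", n_low), rep("PF", n_high)),
                   levels = c("PF", "LF", "JF", "MF")),
    fp4m = c(rnorm(n_low, 3, 0.2), rnorm(n_high, 6, 0.2)),
    w50 = c(rnorm(n_low, 0.14, 0.004), rnorm(n_high, 0.19, 0.004))
  )
}

# draw from a known two-component univariate mixture
rmix2 <- function(n, lambda, mu, sd) {
  z <- stats::rbinom(n, 1, lambda[2]) + 1
  stats::rnorm(n, mu[z], sd[z])
}
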