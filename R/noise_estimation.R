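#' Moment-based recovery of the bundle noise parameters
#'
#' Validates the noise injection of the forward simulator by recovering its
#' parameters from simulated clean/noisy fibre-signal pairs. For
#' `nfs = (1 + m) * fs + a` the conditional second moment of the residual
#' is `E[(nfs - fs)^2 | fs] = sigma_m^2 * fs^2 + sigma_a^2`, so regressing
#' the squared residuals on the squared clean signals recovers
#' `sigma_m^2` as the slope and `sigma_a^2` as the intercept. Each
#' replicate draws `n` clean signals uniform on `[lo, hi]`, applies
#' [apply_noise()] and fits the regression; slope and intercept are
#' averaged over `n_reps` independent replicates because the intercept of
#' a single replicate is dominated by the multiplicative term's sampling
#' noise (the squared residuals are heteroskedastic with variance
#' proportional to `(sigma_m^2 fs^2 + sigma_a^2)^2`, and the clean signals
#' never approach zero). The additive coefficient is reported relative to
#' the clean-signal range, matching its parameterization.
#'
#' @param params a [noise_params()] to recover (its seed is ignored; the
#'   experiment derives per-replicate seeds from `seed`).
#' @param n clean/noisy pairs per replicate.
#' @param n_reps independent replicates averaged.
#' @param range_fs clean-signal range `c(lo, hi)` sampled uniformly.
#' @param seed experiment seed.
#' @return list with `sigma_m` (recovered multiplicative sd), and
#'   `sigma_a_coeff` (recovered additive sd divided by the clean-signal
#'   range `hi - lo`).
#' @export
estimate_noise_moments <- function(params = noise_params(), n = 1e5,
                                   n_reps = 100L, range_fs = c(0.5, 1.0),
                                   seed = 1L) {
  stopifnot(n >= 10, n_reps >= 1, range_fs[2] > range_fs[1])
  slopes <- numeric(n_reps); intercepts <- numeric(n_reps)
  for (r in seq_len(n_reps)) {
    fs_vals <- with_seed(derive_seed(seed, 2L * r), {
      v <- runif(n, range_fs[1], range_fs[2])
      # pin the extremes so the realized range equals the nominal range
      v[1] <- range_fs[1]; v[2] <- range_fs[2]
      v
    })
    fs <- fibre_signals(fs_vals)
    np <- noise_params(params$sigma_m, params$sigma_a_coeff,
                       seed = derive_seed(seed, 2L * r + 1L))
    nfs <- apply_noise(fs, np)
    d2 <- (nfs$values - fs$values)^2
    x2 <- fs$values^2
    fit <- lm(d2 ~ x2)
    slopes[r] <- coef(fit)[2]
    intercepts[r] <- coef(fit)[1]
  }
  rng <- range_fs[2] - range_fs[1]
  list(sigma_m = sqrt(max(mean(slopes), 0)),
       sigma_a_coeff = sqrt(max(mean(intercepts), 0)) / rng,
       n = n, n_reps = n_reps)
}
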