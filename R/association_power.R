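#' Quantitative trait model for a single CNV locus
#'
#' The phenotype follows `Y = X * beta + eps` with `X` the carrier
#' indicator and `eps ~ N(0, sigma^2)`. The residual variance is derived
#' per carrier frequency `p` so the total phenotype variance stays fixed:
#' `sigma^2 = var_y - beta^2 p (1 - p)`. With the defaults (beta 2.5,
#' var_y 100) a CNV carried by 20% of the population explains exactly 1%
#' of the trait variance.
#'
#' @param beta trait shift per carrier (trait units); default 2.5.
#' @param var_y total phenotype variance; default 100.
#' @return An object of class `"trait_model"`.
#' @export
trait_model <- function(beta = 2.5, var_y = 100) {
  stopifnot(is.numeric(beta), length(beta) == 1L,
            is.numeric(var_y), length(var_y) == 1L, var_y > 0)
  structure(list(beta = beta, var_y = var_y), class = "trait_model")
}

#' Residual standard deviation at a given carrier frequency
#'
#' @param trait a [trait_model()].
#' @param freq carrier frequency in (0, 1).
#' @return `sqrt(var_y - beta^2 * freq * (1 - freq))`; errors if the
#'   implied residual variance is not positive.
#' @export
residual_sd <- function(trait, freq) {
  stopifnot(inherits(trait, "trait_model"), freq >= 0, freq <= 1)
  s2 <- trait$var_y - trait$beta^2 * freq * (1 - freq)
  if (s2 <= 0) stop("residual variance <= 0: effect too large for var_y")
  sqrt(s2)
}

#' Fraction of trait variance explained by the carrier indicator
#' @inheritParams residual_sd
#' @return `beta^2 * freq * (1 - freq) / var_y`.
#' @export
explained_r2 <- function(trait, freq) {
  trait$beta^2 * freq * (1 - freq) / trait$var_y
}

#' Simulate phenotypes for carrier indicators
#'
#' @param carriers binary vector of carrier indicators.
#' @inheritParams residual_sd
#' @param freq carrier frequency used to derive the residual variance
#'   (defaults to the declared frequency `mean(carriers)`).
#' @return Numeric phenotype vector with expected variance `trait$var_y`.
#' @export
simulate_phenotype <- function(carriers, trait = trait_model(),
                               freq = mean(carriers)) {
  x <- as.numeric(carriers)
  if (any(!x %in% c(0, 1))) stop("carrier indicators must be binary")
  x * trait$beta + rnorm(length(x), 0, residual_sd(trait, freq))
}

#' Monte-Carlo power simulation settings
#'
#' @param n_subjects cohort size per replicate (default 1000).
#' @param n_replicates number of Monte-Carlo replicates (default 10000).
#' @param alpha significance level of the association test (default 0.05).
#' @param seed optional integer seed applied before simulation.
#' @return An object of class `"power_config"`.
#' @export
power_config <- function(n_subjects = 1000, n_replicates = 10000,
                         alpha = 0.05, seed = NULL) {
  stopifnot(n_subjects >= 3, n_replicates >= 1, alpha > 0, alpha < 1)
  structure(list(n_subjects = as.integer(n_subjects),
                 n_replicates = as.integer(n_replicates),
                 alpha = alpha, seed = seed),
            class = "power_config")
}

power_estimate <- function(n_significant, n_replicates) {
  p <- n_significant / n_replicates
  structure(list(power = p,
                 mc_se = sqrt(p * (1 - p) / n_replicates),
                 n_replicates = n_replicates),
            class = "power_estimate")
}

#' @export
print.power_estimate <- function(x, ...) {
  cat(sprintf("power %.4f (MC se %.4f, %d replicates)\n",
              x$power, x$mc_se, x$n_replicates))
  invisible(x)
}

#' Two-sided OLS slope test
#'
#' Ordinary least-squares regression of `y` on a single predictor with a
#' two-sided t-test of the slope. A zero-variance predictor (e.g. no
#' called carriers at all) is flagged degenerate and counted
#' non-significant, so power is 0 rather than undefined at a
#' false-negative rate of 1.
#'
#' @param y numeric response.
#' @param predictor numeric predictor of the same length (>= 3).
#' @param alpha significance level.
#' @return List with `p_value`, `significant` and `degenerate`.
#' @export
slope_test <- function(y, predictor, alpha = 0.05) {
  n <- length(y)
  stopifnot(n >= 3, length(predictor) == n)
  vx <- sum((predictor - mean(predictor))^2)
  if (vx <= 0)
    return(list(p_value = NA_real_, significant = FALSE, degenerate = TRUE))
  vy <- sum((y - mean(y))^2)
  if (vy <= 0)
    return(list(p_value = NA_real_, significant = FALSE, degenerate = TRUE))
  r <- sum((predictor - mean(predictor)) * (y - mean(y))) / sqrt(vx * vy)
  r2 <- min(r^2, 1)
  tstat <- sqrt(r2 * (n - 2) / max(1 - r2, .Machine$double.xmin))
  p <- 2 * pt(tstat, df = n - 2, lower.tail = FALSE)
  list(p_value = p, significant = isTRUE(p < alpha), degenerate = FALSE)
}

# Column-wise slope-test decisions for replicate matrices (n x m).
# Identical statistic to slope_test(), vectorised across replicates.
.col_slope_significant <- function(xo, y, alpha) {
  n <- nrow(xo)
  sx <- colSums(xo); sy <- colSums(y)
  vxx <- colSums(xo^2) - sx^2 / n
  vyy <- colSums(y^2) - sy^2 / n
  cxy <- colSums(xo * y) - sx * sy / n
  ok <- vxx > 0 & vyy > 0
  r2 <- numeric(ncol(xo))
  r2[ok] <- pmin(cxy[ok]^2 / (vxx[ok] * vyy[ok]), 1)
  tstat <- sqrt(r2 * (n - 2) / pmax(1 - r2, .Machine$double.xmin))
  p <- 2 * pt(tstat, df = n - 2, lower.tail = FALSE)
  ok & p < alpha
}

.mc_chunks <- function(n_replicates, chunk = 250L) {
  sizes <- rep(chunk, n_replicates %/% chunk)
  if (n_replicates %% chunk) sizes <- c(sizes, n_replicates %% chunk)
  sizes
}

#' Power of association testing on error-prone CNV calls
#'
#' Per replicate, carrier status is drawn Bernoulli(`freq`) per subject,
#' the phenotype is simulated from the trait model, and the observed
#' indicator is the true one degraded by the call-error process: carriers
#' are missed with probability `nu_n`, non-carriers called with
#' probability `nu_p`. Power is the fraction of replicates in which the
#' OLS slope test on the observed indicator is significant.
#'
#' @param freq true carrier frequency in (0, 1).
#' @param rates an [error_rates()] object (or numeric `c(nu_n, nu_p)`).
#' @param trait a [trait_model()].
#' @param config a [power_config()].
#' @return A `"power_estimate"`: list with `power`, `mc_se`,
#'   `n_replicates`.
#' @export
estimate_power_calls <- function(freq, rates, trait = trait_model(),
                                 config = power_config()) {
  stopifnot(freq > 0, freq < 1)
  rates <- as_error_rates(rates)
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n_subjects
  sigma <- residual_sd(trait, freq)
  hits <- 0L
  for (m in .mc_chunks(config$n_replicates)) {
    x <- matrix(rbinom(n * m, 1L, freq), n, m)
    y <- x * trait$beta + matrix(rnorm(n * m, 0, sigma), n, m)
    u <- matrix(runif(n * m), n, m)
    xo <- x * (u >= rates$nu_n) + (1 - x) * (u < rates$nu_p)
    hits <- hits + sum(.col_slope_significant(xo, y, config$alpha))
  }
  power_estimate(hits, config$n_replicates)
}

#' Power of association testing on raw LRR intensities
#'
#' Per replicate, carriers are drawn Bernoulli(`freq`), the phenotype is
#' simulated, and the predictor is a single noisy LRR measurement per
#' subject: carriers at the damped one-copy (deletion) or three-copy
#' (duplication) mean, non-carriers at 0, noise sd from the model. Because
#' a single locus is tested, the result does not depend on CNV size.
#'
#' @inheritParams estimate_power_calls
#' @param cnv_type `"deletion"` or `"duplication"`.
#' @param model an [lrr_model()]; the `"array"` preset reproduces the
#'   reference numbers (power ~0.71 for deletions, ~0.49 for duplications
#'   at freq 0.2).
#' @return A `"power_estimate"`.
#' @export
estimate_power_lrr <- function(freq, cnv_type = c("deletion", "duplication"),
                               model = lrr_model("array"),
                               trait = trait_model(),
                               config = power_config()) {
  stopifnot(freq > 0, freq < 1)
  cnv_type <- match.arg(cnv_type)
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n_subjects
  sigma <- residual_sd(trait, freq)
  shift <- theoretical_lrr(if (cnv_type == "deletion") 1L else 3L, model)
  hits <- 0L
  for (m in .mc_chunks(config$n_replicates)) {
    x <- matrix(rbinom(n * m, 1L, freq), n, m)
    y <- x * trait$beta + matrix(rnorm(n * m, 0, sigma), n, m)
    z <- x * shift + matrix(rnorm(n * m, 0, model$noise_sd), n, m)
    hits <- hits + sum(.col_slope_significant(z, y, config$alpha))
  }
  power_estimate(hits, config$n_replicates)
}

#' Analytic power of the slope test (noncentral-F oracle)
#'
#' Closed-form power of the two-sided OLS slope test when the predictor
#' captures a fraction `rho_sq` of the signal: with effective
#' \eqn{R^2 = \rho^2 R^2_{base}}, the test statistic is noncentral
#' F(1, n-2) with noncentrality \eqn{\lambda = n R^2 / (1 - R^2)}.
#' Measurement error in the predictor only attenuates `rho_sq` (the
#' squared correlation between true and observed predictor), e.g.
#' \eqn{\rho^2 = (1-\nu_n)(1-p)/(1 - p(1-\nu_n))} for a carrier indicator
#' degraded by false negatives alone.
#'
#' @param rho_sq squared correlation between true and observed predictor,
#'   in \[0, 1\].
#' @param base_r2 trait variance fraction explained by the true predictor,
#'   in \[0, 1).
#' @param n number of subjects.
#' @param alpha significance level.
#' @return Power in \[`alpha`, 1\].
#' @export
analytic_power <- function(rho_sq, base_r2, n, alpha = 0.05) {
  stopifnot(rho_sq >= 0, rho_sq <= 1, base_r2 >= 0, base_r2 < 1,
            n >= 3, alpha > 0, alpha < 1)
  r2 <- rho_sq * base_r2
  lambda <- n * r2 / (1 - r2)
  fcrit <- qf(1 - alpha, 1, n - 2)
  pf(fcrit, 1, n - 2, ncp = lambda, lower.tail = FALSE)
}

#' Squared correlation between true and error-degraded carrier indicator
#'
#' @param freq true carrier frequency.
#' @param nu_n false-negative rate; `nu_p` is taken as 0.
#' @return Attenuation factor \eqn{(1-\nu_n)(1-p)/(1 - p(1-\nu_n))}.
#' @export
call_attenuation <- function(freq, nu_n) {
  a <- 1 - nu_n
  a * (1 - freq) / (1 - freq * a)
}

#' False-negative rate at which power halves
#'
#' Simulates the power curve over a grid of false-negative rates (with
#' `nu_p = 0`), applies monotone (non-increasing) smoothing by isotonic
#' regression, and reports the smallest grid rate at which smoothed power
#' drops to half its error-free value. When the baseline power is at or
#' below twice the significance level the ratio is dominated by the null
#' floor and the crossing is flagged unreliable.
#'
#' @inheritParams estimate_power_calls
#' @param grid false-negative rates to evaluate; must cover \[0, 1\].
#' @return List of class `"half_power_crossing"` with `nu_n` (the crossing,
#'   or `NA` if the curve never halves), `baseline`, `reliable`, and the
#'   evaluated `grid`, `power` and `smoothed` vectors.
#' @export
half_power_crossing <- function(freq, trait = trait_model(),
                                config = power_config(),
                                grid = seq(0, 1, by = 0.01)) {
  stopifnot(min(grid) == 0, max(grid) == 1, !is.unsorted(grid))
  if (!is.null(config$seed)) set.seed(config$seed)
  cfg <- config
  cfg$seed <- NULL
  pw <- vapply(grid, function(nn) {
    estimate_power_calls(freq, error_rates(nn, 0), trait, cfg)$power
  }, numeric(1))
  sm <- -isoreg(grid, -pw)$yf
  baseline <- sm[1L]
  reliable <- baseline > 2 * config$alpha
  idx <- which(sm <= baseline / 2)
  structure(list(
    nu_n = if (length(idx)) grid[idx[1L]] else NA_real_,
    baseline = baseline, reliable = reliable,
    grid = grid, power = pw, smoothed = sm
  ), class = "half_power_crossing")
}

#' Analytic half-power crossing (deterministic oracle)
#'
#' Same quantity as [half_power_crossing()] but computed from
#' [analytic_power()] with the carrier-indicator attenuation formula, on a
#' fine grid, with no Monte-Carlo noise.
#'
#' @inheritParams half_power_crossing
#' @param n,alpha test dimensions.
#' @return The smallest grid `nu_n` with analytic power <= half baseline.
#' @export
analytic_half_power_crossing <- function(freq, trait = trait_model(),
                                         n = 1000, alpha = 0.05,
                                         grid = seq(0, 1, by = 0.001)) {
  base_r2 <- explained_r2(trait, freq)
  pw <- vapply(grid, function(nn) {
    analytic_power(call_attenuation(freq, nn), base_r2, n, alpha)
  }, numeric(1))
  grid[which(pw <= pw[1L] / 2)[1L]]
}

#' Compose a recovery curve with a power curve
#'
#' Converts recovery rates by CNV size into association power by size via
#' the identity `nu_n = 1 - recovery`, interpolating the power-vs-nu_n
#' curve linearly between grid points.
#'
#' @param recovery_by_size data frame with columns `size` and `recovery`
#'   (rates in \[0, 1\]).
#' @param power_by_nu_n data frame with columns `nu_n` and `power`,
#'   covering \[0, 1\].
#' @return Data frame with columns `size` and `power`.
#' @export
compose_power_vs_size <- function(recovery_by_size, power_by_nu_n) {
  stopifnot(all(c("size", "recovery") %in% names(recovery_by_size)),
            all(c("nu_n", "power") %in% names(power_by_nu_n)),
            all(recovery_by_size$recovery >= 0),
            all(recovery_by_size$recovery <= 1))
  f <- approxfun(power_by_nu_n$nu_n, power_by_nu_n$power, rule = 2)
  data.frame(size = recovery_by_size$size,
             power = f(1 - recovery_by_size$recovery))
}
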