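#' Log R ratio intensity model
#'
#' The log R ratio (LRR) is the base-2 log of total allelic intensity
#' relative to a two-copy reference, so without noise a one-copy segment
#' sits at -1, a two-copy segment at 0 and a three-copy segment at
#' log2(3/2). The zero-copy mean tends to minus infinity in theory but is
#' kept finite in practice by background intensity; it is represented here
#' by a configurable floor. On real arrays the observed means are damped
#' towards zero; the `"array"` preset uses the commonly observed damping of
#' one half and a noise sd of 0.15.
#'
#' @param preset `"array"` (damping 0.5, noise sd 0.15 — used for every
#'   reproduced simulation) or `"theoretical"` (damping 1, no noise).
#' @param state_means theoretical LRR means for copy states 0..4; the first
#'   entry is the zero-copy floor. Default `c(floor, -1, 0, log2(3/2), 1)`.
#' @param damping multiplicative shrinkage of the means, in (0, 1\].
#' @param noise_sd standard deviation of the additive Gaussian measurement
#'   noise (log2 units), >= 0.
#' @param floor finite stand-in mean for the zero-copy state (default -2).
#' @return An object of class `"lrr_model"`.
#' @export
lrr_model <- function(preset = c("array", "theoretical"),
                      state_means = NULL, damping = NULL, noise_sd = NULL,
                      floor = -2) {
  preset <- match.arg(preset)
  damping <- damping %||% switch(preset, array = 0.5, theoretical = 1)
  noise_sd <- noise_sd %||% switch(preset, array = 0.15, theoretical = 0)
  state_means <- state_means %||% c(floor, -1, 0, log2(3 / 2), 1)
  stopifnot(
    length(state_means) == 5L, is.numeric(state_means),
    damping > 0, damping <= 1, noise_sd >= 0,
    state_means[3L] == 0,
    diff(state_means[2:5]) > 0,
    state_means[1L] <= state_means[2L]
  )
  structure(
    list(state_means = state_means, damping = damping, noise_sd = noise_sd),
    class = "lrr_model"
  )
}

#' Expected (damped) LRR for a copy state
#'
#' @param state integer copy state(s) in 0..4.
#' @param model an [lrr_model()].
#' @return `model$damping * model$state_means[state + 1]`.
#' @examples
#' theoretical_lrr(3, lrr_model("theoretical"))  # log2(3/2) ~ 0.585
#' theoretical_lrr(1, lrr_model("array"))        # -0.5
#' @export
theoretical_lrr <- function(state, model = lrr_model("theoretical")) {
  stopifnot(inherits(model, "lrr_model"))
  s <- as.integer(state)
  if (any(is.na(s)) || any(s < 0L | s > 4L))
    stop("copy state must be an integer in 0..4")
  model$damping * model$state_means[s + 1L]
}

#' Simulate noisy LRR values for copy states
#'
#' Independent Gaussian draws centred at the damped state means with sd
#' `model$noise_sd`. Uses R's global RNG.
#'
#' @param states integer copy states in 0..4.
#' @inheritParams theoretical_lrr
#' @return Numeric vector of observed LRR values.
#' @export
simulate_lrr <- function(states, model = lrr_model("array")) {
  mu <- theoretical_lrr(states, model)
  rnorm(length(mu), mean = mu, sd = model$noise_sd)
}
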