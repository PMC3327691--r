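#' Hardy-Weinberg CNV locus model
#'
#' Builds the population distribution of the true integer copy number
#' \eqn{X \in \{0,...,4\}} at a single CNV locus. Each parental chromosome
#' carries a deletion allele (0 copies), the normal allele (1 copy) or a
#' duplication allele (2 copies); under Hardy-Weinberg equilibrium the
#' genotype frequencies are the trinomial expansion of the allele
#' frequencies and \eqn{X} is the sum of the two parental copy counts. At a
#' multiallelic locus the deletion/duplication heterozygote contributes to
#' the two-copy class (0 + 2 copies), so with both alleles at frequency 0.1
#' the frequencies are (0.01, 0.16, 0.66, 0.16, 0.01).
#'
#' @param kind locus type: `"deletion"` and `"duplication"` loci segregate a
#'   single variant allele; a `"multiallelic"` locus segregates both.
#' @param q variant allele frequency in \[0, 0.5\]; for a multiallelic locus
#'   this is the deletion-allele frequency. Default 0.1.
#' @param q_dup duplication-allele frequency for a multiallelic locus
#'   (defaults to `q`); must be `NULL` for single-variant loci.
#' @return An object of class `"locus_model"`: a list with elements `kind`
#'   and `freqs` (named numeric vector `g0`..`g4` summing to 1).
#' @examples
#' locus_model("deletion", q = 0.1)$freqs   # 0.01 0.18 0.81 0 0
#' locus_model("multiallelic", q = 0.1)$freqs
#' @export
locus_model <- function(kind = c("deletion", "duplication", "multiallelic"),
                        q = 0.1, q_dup = NULL) {
  kind <- match.arg(kind)
  if (!is.numeric(q) || length(q) != 1L || q < 0 || q > 0.5)
    stop("variant allele frequency `q` must be a single value in [0, 0.5]")
  if (kind != "multiallelic" && !is.null(q_dup))
    stop("only multiallelic loci take two allele frequencies")
  qd <- qu <- 0
  if (kind == "deletion") qd <- q
  if (kind == "duplication") qu <- q
  if (kind == "multiallelic") {
    qu <- q_dup %||% q
    if (!is.numeric(qu) || length(qu) != 1L || qu < 0 || qu > 0.5)
      stop("duplication allele frequency must be a single value in [0, 0.5]")
    qd <- q
  }
  p <- 1 - qd - qu # normal allele
  g <- c(
    g0 = qd^2,
    g1 = 2 * qd * p,
    g2 = p^2 + 2 * qd * qu, # del/dup heterozygote has copy number 0 + 2 = 2
    g3 = 2 * qu * p,
    g4 = qu^2
  )
  stopifnot(abs(sum(g) - 1) < 1e-12, all(g >= 0), g[["g2"]] > 0)
  structure(list(kind = kind, freqs = g), class = "locus_model")
}

#' @export
print.locus_model <- function(x, ...) {
  cat(sprintf("<locus_model> %s locus\n", x$kind))
  print(round(x$freqs, 6))
  invisible(x)
}

#' False-positive / false-negative call error rates
#'
#' @param nu_n false-negative rate: probability that a true non-reference
#'   copy state (0, 1, 3 or 4) is called as the reference state 2. The
#'   complement `1 - nu_n` is the recovery rate.
#' @param nu_p false-positive rate: probability that a true two-copy state
#'   is called as some non-reference state.
#' @return An object of class `"error_rates"`.
#' @export
error_rates <- function(nu_n, nu_p) {
  stopifnot(
    is.numeric(nu_n), length(nu_n) == 1L, nu_n >= 0, nu_n <= 1,
    is.numeric(nu_p), length(nu_p) == 1L, nu_p >= 0, nu_p <= 1
  )
  structure(list(nu_n = nu_n, nu_p = nu_p), class = "error_rates")
}

as_error_rates <- function(rates) {
  if (inherits(rates, "error_rates")) return(rates)
  if (is.numeric(rates) && length(rates) == 2L)
    return(error_rates(rates[[1L]], rates[[2L]]))
  stop("`rates` must be an error_rates object or a numeric (nu_n, nu_p) pair")
}

#' Joint distribution of true and called copy number
#'
#' The 5x5 joint law of the true state \eqn{X} and the called state
#' \eqn{X_o} under the two-error model. A true non-reference state `j` is
#' either called correctly (probability \eqn{1-\nu_n}) or collapsed to the
#' reference state 2 (probability \eqn{\nu_n}). A true two-copy state is
#' either called correctly (probability \eqn{1-\nu_p}) or assigned a
#' non-reference state `k` with probability proportional to that state's
#' population frequency, \eqn{\nu_p g_k / (1 - g_2)}. Mis-assignment among
#' non-reference states (e.g. a deletion called as a duplication) is not
#' modelled.
#'
#' @param locus a [locus_model()].
#' @param rates an [error_rates()] object (or numeric `c(nu_n, nu_p)`).
#' @return A 5x5 matrix of probabilities with rows `X = 0..4` and columns
#'   `X_o = 0..4`, summing to 1; row sums equal the locus genotype
#'   frequencies.
#' @export
joint_call_distribution <- function(locus, rates) {
  stopifnot(inherits(locus, "locus_model"))
  rates <- as_error_rates(rates)
  g <- unname(locus$freqs)
  g2 <- g[3L]
  if (rates$nu_p > 0 && g2 >= 1)
    stop("nu_p > 0 requires non-reference mass: false positives have no ",
         "destination distribution when g2 = 1")
  P <- matrix(0, 5L, 5L, dimnames = list(X = 0:4, X_o = 0:4))
  for (j in c(1L, 2L, 4L, 5L)) { # true states 0, 1, 3, 4
    P[j, 3L] <- P[j, 3L] + g[j] * rates$nu_n
    P[j, j] <- P[j, j] + g[j] * (1 - rates$nu_n)
  }
  if (g2 < 1) {
    for (k in c(1L, 2L, 4L, 5L))
      P[3L, k] <- g2 * rates$nu_p * g[k] / (1 - g2)
  }
  P[3L, 3L] <- g2 * (1 - rates$nu_p)
  P
}

#' Moments of the call error
#'
#' The called copy number decomposes as \eqn{X_o = X + \Delta}. With
#' \eqn{S_1 = \sum_{k \ne 2} g_k (2-k)}, \eqn{S_2 = \sum_{k \ne 2} g_k
#' (2-k)^2} and \eqn{r = g_2 / (1-g_2)}, the error moments have the closed
#' forms \eqn{E[\Delta] = (\nu_n - \nu_p r) S_1} and \eqn{E[\Delta^2] =
#' (\nu_n + \nu_p r) S_2}. The variance of \eqn{\Delta} is the variance a
#' calling algorithm adds purely through its errors, on the copy-number
#' scale, and is the quantity compared against the LRR noise floor.
#'
#' @inheritParams joint_call_distribution
#' @return A list of class `"delta_moments"` with elements `mean`,
#'   `variance` and `sd`.
#' @examples
#' # deletion locus, half of variants missed:
#' delta_moments(locus_model("deletion"), error_rates(0.5, 0))$sd  # 0.316...
#' @export
delta_moments <- function(locus, rates) {
  stopifnot(inherits(locus, "locus_model"))
  rates <- as_error_rates(rates)
  g <- unname(locus$freqs)
  g2 <- g[3L]
  if (rates$nu_p > 0 && g2 >= 1)
    stop("nu_p > 0 requires non-reference mass at the locus")
  k <- 0:4
  off <- k != 2L
  s1 <- sum(g[off] * (2 - k[off]))
  s2 <- sum(g[off] * (2 - k[off])^2)
  r <- if (g2 < 1) g2 / (1 - g2) else 0
  m1 <- (rates$nu_n - rates$nu_p * r) * s1
  m2 <- (rates$nu_n + rates$nu_p * r) * s2
  v <- m2 - m1^2
  v <- max(v, 0)
  structure(list(mean = m1, variance = v, sd = sqrt(v)),
            class = "delta_moments")
}

#' Table of sd(Delta) over a grid of error rates
#'
#' @inheritParams joint_call_distribution
#' @param nu_n,nu_p numeric vectors of false-negative (rows) and
#'   false-positive (columns) rates in \[0, 1\].
#' @param digits decimals for display rounding (default 3, as printed in the
#'   reference tables); use `NULL` for full precision.
#' @return A `length(nu_n)` x `length(nu_p)` matrix of `sqrt(Var(Delta))`.
#' @export
sd_delta_table <- function(locus, nu_n = c(0, 0.2, 0.5, 0.7, 0.9),
                           nu_p = c(0, 0.05, 0.10), digits = 3) {
  stopifnot(all(nu_n >= 0 & nu_n <= 1), all(nu_p >= 0 & nu_p <= 1))
  out <- outer(nu_n, nu_p, Vectorize(function(nn, np) {
    delta_moments(locus, error_rates(nn, np))$sd
  }))
  dimnames(out) <- list(nu_n = format(nu_n), nu_p = format(nu_p))
  if (!is.null(digits)) out <- round(out, digits)
  out
}

#' Error-rate contour of constant call-error variance
#'
#' For each false-negative rate on a grid, solves for the false-positive
#' rate at which \eqn{Var(\Delta)} equals `target_sd^2`. The variance is
#' quadratic in \eqn{\nu_p}; the smaller non-negative root is the physically
#' meaningful rate. Rates strictly inside the returned contour inject less
#' variance than the target — e.g. with `target_sd = 0.15` they beat the
#' typical noise level of raw LRR intensities.
#'
#' @inheritParams joint_call_distribution
#' @param target_sd target standard deviation of the call error (default
#'   0.15, the typical LRR noise sd on high-quality arrays).
#' @param nu_n_grid grid of false-negative rates to solve at.
#' @return A data frame with columns `nu_n` and `nu_p`; grid points with no
#'   solution in \[0, 1\] are omitted (empty data frame if the contour is
#'   unreachable).
#' @export
equivalence_contour <- function(locus, target_sd = 0.15,
                                nu_n_grid = seq(0, 1, by = 0.001)) {
  stopifnot(inherits(locus, "locus_model"), target_sd >= 0)
  g <- unname(locus$freqs)
  g2 <- g[3L]
  k <- 0:4
  off <- k != 2L
  s1 <- sum(g[off] * (2 - k[off]))
  s2 <- sum(g[off] * (2 - k[off])^2)
  r <- g2 / (1 - g2)
  tt <- target_sd^2
  # Var(nu_p) = (nu_n + r nu_p) s2 - ((nu_n - r nu_p) s1)^2
  #           = -r^2 s1^2 nu_p^2 + (r s2 + 2 nu_n r s1^2) nu_p
  #             + nu_n s2 - nu_n^2 s1^2
  sols <- lapply(nu_n_grid, function(nn) {
    a <- r^2 * s1^2
    b <- r * s2 + 2 * nn * r * s1^2
    cc <- tt - nn * s2 + nn^2 * s1^2 # a x^2 - b x + cc = 0
    if (a < 1e-14) {
      if (b < 1e-14) return(NULL)
      np <- cc / b
    } else {
      disc <- b^2 - 4 * a * cc
      if (disc < 0) return(NULL)
      np <- (b - sqrt(disc)) / (2 * a) # smaller root
    }
    if (!is.finite(np) || np < -1e-12 || np > 1) return(NULL)
    data.frame(nu_n = nn, nu_p = max(np, 0))
  })
  out <- do.call(rbind, sols)
  if (is.null(out)) out <- data.frame(nu_n = numeric(0), nu_p = numeric(0))
  rownames(out) <- NULL
  out
}

#' Sample called copy numbers given true states
#'
#' Monte-Carlo twin of [joint_call_distribution()]: perturbs each true state
#' independently under the two-error model. Uses R's global RNG; seed with
#' `set.seed()` for reproducibility.
#'
#' @param true_states integer vector of true copy states in 0..4.
#' @inheritParams joint_call_distribution
#' @return Integer vector of called states, same length as `true_states`.
#' @export
sample_observed_calls <- function(true_states, locus, rates) {
  stopifnot(inherits(locus, "locus_model"))
  rates <- as_error_rates(rates)
  x <- as.integer(true_states)
  if (any(is.na(x)) || any(x < 0L | x > 4L))
    stop("true states must be integers in 0..4")
  g <- unname(locus$freqs)
  g2 <- g[3L]
  if (rates$nu_p > 0 && g2 >= 1)
    stop("nu_p > 0 requires non-reference mass at the locus")
  out <- x
  u <- runif(length(x))
  miss <- x != 2L & u < rates$nu_n
  out[miss] <- 2L
  fp <- x == 2L & u < rates$nu_p
  if (any(fp)) {
    dest <- c(0L, 1L, 3L, 4L)
    w <- g[dest + 1L] / (1 - g2)
    out[fp] <- sample(dest, sum(fp), replace = TRUE, prob = w)
  }
  out
}
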