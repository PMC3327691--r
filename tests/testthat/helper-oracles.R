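# Independent oracles and fixture builders shared across the suite.

# Moments of Delta = X_o - X by direct summation over the 5x5 joint table.
moments_from_table <- function(P) {
  d <- outer(0:4, 0:4, function(j, k) k - j)
  m1 <- sum(P * d)
  m2 <- sum(P * d^2)
  list(mean = m1, variance = m2 - m1^2)
}

# Exhaustive-enumeration Viterbi: scores all 5^L state paths directly from
# the hmm_params fields (no shared code with the package decoder).
brute_viterbi <- function(obs, params) {
  L <- length(obs)
  grid <- as.matrix(expand.grid(rep(list(0:4), L)))
  off <- (1 - params$stay_prob) / 4
  A <- matrix(off, 5, 5)
  diag(A) <- params$stay_prob
  logA <- log(A)
  init <- rep(params$cnv_prior, 5)
  init[3] <- 1 - 4 * params$cnv_prior
  emis <- vapply(1:5, function(s) {
    dnorm(obs, params$state_means[s], params$state_sds[s], log = TRUE)
  }, numeric(L))
  emis <- matrix(emis, nrow = L)
  sc <- log(init)[grid[, 1] + 1]
  for (t in seq_len(L)) sc <- sc + emis[t, ][grid[, t] + 1]
  if (L > 1) {
    for (t in 2:L) sc <- sc + logA[cbind(grid[, t - 1] + 1, grid[, t] + 1)]
  }
  unname(grid[which.max(sc), ])
}

# Viterbi path recovered from the package's segment output.
path_from_segments <- function(segs, L) {
  p <- rep(2L, L)
  for (i in seq_len(nrow(segs))) p[segs$start[i]:segs$end[i]] <- segs$state[i]
  p
}

random_locus <- function() {
  kind <- sample(c("deletion", "duplication", "multiallelic"), 1)
  if (kind == "multiallelic") {
    locus_model(kind, q = runif(1, 0.01, 0.4), q_dup = runif(1, 0.01, 0.4))
  } else {
    locus_model(kind, q = runif(1, 0.01, 0.5))
  }
}

paper_table_deletion <- matrix(
  c(0.000, 0.212, 0.294,
    0.206, 0.301, 0.368,
    0.316, 0.392, 0.451,
    0.367, 0.438, 0.495,
    0.407, 0.475, 0.532),
  nrow = 5, byrow = TRUE,
  dimnames = list(nu_n = c("0.0", "0.2", "0.5", "0.7", "0.9"),
                  nu_p = c("0.00", "0.05", "0.10"))
)

paper_table_multiallelic <- matrix(
  c(0.000, 0.197, 0.279,
    0.283, 0.345, 0.397,
    0.447, 0.489, 0.527,
    0.529, 0.565, 0.598,
    0.600, 0.632, 0.662),
  nrow = 5, byrow = TRUE,
  dimnames = list(nu_n = c("0.0", "0.2", "0.5", "0.7", "0.9"),
                  nu_p = c("0.00", "0.05", "0.10"))
)
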