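test_that("a flat LRR vector yields no calls", {
  segs <- viterbi_segment(rep(0, 200))
  expect_equal(nrow(segs), 0L)
  expect_error(viterbi_segment(numeric(0)), "empty")
})

test_that("Viterbi equals exhaustive path enumeration on short instances", {
  set.seed(61)
  params_list <- list(
    hmm_params(),
    hmm_params(stay_prob = 0.9, cnv_prior = 0.05),
    hmm_params(state_sds = rep(0.3, 5), stay_prob = 0.99)
  )
  for (i in 1:12) {
    params <- params_list[[1 + (i %% 3)]]
    L <- sample(2:6, 1)
    obs <- rnorm(L, sample(params$state_means, 1), 0.3)
    segs <- viterbi_segment(obs, params)
    expect_identical(path_from_segments(segs, L),
                     as.integer(brute_viterbi(obs, params)))
  }
})

test_that("calls are deterministic given the input", {
  set.seed(62)
  lrr <- matrix(rnorm(5 * 300, 0, 0.15), 5, 300,
                dimnames = list(paste0("s", 1:5), NULL))
  lrr[2, 100:110] <- lrr[2, 100:110] - 0.5
  expect_identical(call_cnvs(lrr), call_cnvs(lrr))
})

test_that("an embedded 8-probe deletion is recovered in >90% of replicates", {
  set.seed(63)
  hits <- 0L
  for (i in 1:60) {
    obs <- rnorm(120, 0, 0.15)
    obs[57:64] <- obs[57:64] - 0.5
    segs <- viterbi_segment(obs)
    ok <- any(segs$state < 2 & segs$start <= 64 & segs$end >= 57)
    hits <- hits + ok
  }
  expect_gt(hits / 60, 0.9)
})

test_that("recovery scoring enforces overlap and direction", {
  region <- list(start = 10, end = 14, state = 1,
                 carriers = c("a", "b", "c", "d"))
  perfect <- data.frame(subject = c("a", "b", "c", "d"),
                        start = 10, end = 14, state = 1)
  expect_equal(recovery_rate(perfect, region), 1)
  none <- perfect[0, ]
  expect_equal(recovery_rate(none, region), 0)
  # duplication calls cannot recover a deletion truth
  wrong_dir <- transform(perfect, state = 3)
  expect_equal(recovery_rate(wrong_dir, region), 0)
  # one-probe overlap counts; disjoint does not; non-carriers do not
  partial <- data.frame(subject = c("a", "b", "z"),
                        start = c(14, 20, 10), end = c(30, 30, 14),
                        state = 1)
  expect_equal(recovery_rate(partial, region), 0.25)
})

test_that("recovery increases with CNV size and deletions dominate duplications", {
  set.seed(64)
  sizes <- c(2, 5, 8, 14)
  del <- recovery_curve(sizes, "deletion", n_subjects = 150,
                        n_probes = 400, n_carriers = 150)
  dup <- recovery_curve(sizes, "duplication", n_subjects = 150,
                        n_probes = 400, n_carriers = 150)
  mc <- 3 * sqrt(0.25 / 150)
  expect_true(all(diff(del$recovery) >= -mc))
  expect_true(all(diff(dup$recovery) >= -mc))
  expect_true(all(del$recovery >= dup$recovery - mc))
})

test_that("end-to-end power matches the composed recovery/power curve", {
  set.seed(65)
  sizes <- c(3, 8, 14)
  e2e <- end_to_end_power(sizes, "deletion",
                          config = power_config(n_replicates = 250),
                          n_subjects = 400, n_probes = 250, n_carriers = 80)
  rec <- recovery_curve(sizes, "deletion", n_subjects = 400,
                        n_probes = 250, n_carriers = 80, n_cohorts = 3)
  grid <- seq(0, 1, by = 0.02)
  base_r2 <- explained_r2(trait_model(), 0.2)
  pw <- data.frame(nu_n = grid,
                   power = vapply(grid, function(nn) {
                     analytic_power(call_attenuation(0.2, nn), base_r2, 400)
                   }, numeric(1)))
  comp <- compose_power_vs_size(rec, pw)
  for (i in seq_along(sizes)) {
    tol <- 3 * (e2e$mc_se[i] + sqrt(0.25 / (3 * 80)))
    expect_lt(abs(e2e$power[i] - comp$power[i]), tol + 0.02)
  }
  # large sizes approach the error-free analytic power
  expect_lt(abs(e2e$power[3] - analytic_power(1, base_r2, 400)),
            3 * e2e$mc_se[3] + 0.02)
})
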