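test_that("HWE expansion gives the expected genotype frequencies", {
  expect_equal(unname(locus_model("deletion", q = 0.1)$freqs),
               c(0.01, 0.18, 0.81, 0, 0))
  expect_equal(unname(locus_model("duplication", q = 0.1)$freqs),
               c(0, 0, 0.81, 0.18, 0.01))
  expect_equal(unname(locus_model("multiallelic", q = 0.1)$freqs),
               c(0.01, 0.16, 0.66, 0.16, 0.01))
  expect_equal(unname(locus_model("deletion", q = 0)$freqs),
               c(0, 0, 1, 0, 0))
})

test_that("locus construction rejects invalid frequencies", {
  expect_error(locus_model("deletion", q = 0.6), "0, 0.5")
  expect_error(locus_model("deletion", q = -0.1), "0, 0.5")
  expect_error(locus_model("deletion", q = 0.1, q_dup = 0.1),
               "multiallelic")
})

test_that("joint call distribution follows the two-error rule", {
  del <- locus_model("deletion", q = 0.1)
  # no errors: diagonal table of genotype frequencies
  P0 <- joint_call_distribution(del, error_rates(0, 0))
  expect_equal(unname(diag(P0)), unname(del$freqs))
  expect_equal(sum(P0), 1)
  # missed one-copy deletions land at X_o = 2
  P <- joint_call_distribution(del, error_rates(0.5, 0))
  expect_equal(P["1", "2"], 0.18 * 0.5)
  # false positives redistribute over non-reference states by frequency
  mul <- locus_model("multiallelic", q = 0.1)
  Pm <- joint_call_distribution(mul, error_rates(0, 0.05))
  expect_equal(Pm["2", "1"], 0.66 * 0.05 * 0.16 / 0.34)
  # degenerate: nowhere to send false positives
  mono <- locus_model("deletion", q = 0)
  expect_error(joint_call_distribution(mono, error_rates(0, 0.05)),
               "destination")
})

test_that("joint distribution normalizes with locus marginals (property sweep)", {
  set.seed(42)
  for (i in 1:25) {
    locus <- random_locus()
    rates <- error_rates(runif(1), runif(1))
    P <- joint_call_distribution(locus, rates)
    expect_true(all(P >= 0))
    expect_equal(sum(P), 1, tolerance = 1e-12)
    expect_equal(unname(rowSums(P)), unname(locus$freqs), tolerance = 1e-12)
  }
})

test_that("closed-form moments equal direct summation over the joint table", {
  set.seed(43)
  for (i in 1:25) {
    locus <- random_locus()
    rates <- error_rates(runif(1), runif(1))
    dm <- delta_moments(locus, rates)
    oracle <- moments_from_table(joint_call_distribution(locus, rates))
    expect_equal(dm$mean, oracle$mean, tolerance = 1e-12)
    expect_equal(dm$variance, oracle$variance, tolerance = 1e-12)
    expect_equal(dm$sd, sqrt(max(oracle$variance, 0)), tolerance = 1e-12)
  }
})

test_that("sd(Delta) reproduces the reference values and limiting cases", {
  del <- locus_model("deletion", q = 0.1)
  mul <- locus_model("multiallelic", q = 0.1)
  expect_equal(round(delta_moments(del, error_rates(0.5, 0))$sd, 3), 0.316)
  expect_equal(round(delta_moments(del, error_rates(0.5, 0.05))$sd, 3), 0.392)
  expect_equal(round(delta_moments(mul, error_rates(0.2, 0.05))$sd, 3), 0.345)
  # error-free calls add no variance
  dm0 <- delta_moments(del, error_rates(0, 0))
  expect_equal(dm0$mean, 0)
  expect_equal(dm0$sd, 0)
  # symmetric multiallelic locus: errors cancel in expectation
  expect_equal(delta_moments(mul, error_rates(0.3, 0.07))$mean, 0)
})

test_that("sd(Delta) is monotone in each rate and symmetric in CNV direction", {
  nn <- seq(0, 1, by = 0.1)
  np <- seq(0, 0.2, by = 0.05)
  for (locus in list(locus_model("deletion", q = 0.1),
                     locus_model("multiallelic", q = 0.1))) {
    tab <- sd_delta_table(locus, nn, np, digits = NULL)
    expect_true(all(apply(tab, 2, diff) >= -1e-12))
    expect_true(all(apply(tab, 1, diff) >= -1e-12))
  }
  # deletion and duplication loci at equal allele frequency share Var(Delta)
  del <- locus_model("deletion", q = 0.17)
  dup <- locus_model("duplication", q = 0.17)
  r <- error_rates(0.3, 0.08)
  expect_equal(delta_moments(del, r)$variance, delta_moments(dup, r)$variance)
  expect_equal(delta_moments(del, r)$mean, -delta_moments(dup, r)$mean)
})

test_that("equivalence contour solves Var(Delta) = target^2", {
  del <- locus_model("deletion", q = 0.1)
  mul <- locus_model("multiallelic", q = 0.1)
  cc <- equivalence_contour(del, 0.15, nu_n_grid = c(0, 0.02, 0.05))
  expect_equal(cc$nu_p[cc$nu_n == 0], 0.0244534, tolerance = 1e-5)
  # multiallelic: Var = nu_n * S2 at nu_p = 0, so the contour hits the
  # nu_n axis at 0.0225 / 0.4
  cm <- equivalence_contour(mul, 0.15,
                            nu_n_grid = c(0, 0.0225 / 0.4, 0.2))
  expect_equal(cm$nu_p[abs(cm$nu_n - 0.05625) < 1e-9], 0, tolerance = 1e-12)
  # every returned pair satisfies the defining equation
  for (i in seq_len(nrow(cc))) {
    v <- delta_moments(del, error_rates(cc$nu_n[i], cc$nu_p[i]))$variance
    expect_equal(v, 0.15^2, tolerance = 1e-9)
  }
  # target 0 is only reachable with no errors
  c0 <- equivalence_contour(del, 0, nu_n_grid = seq(0, 1, by = 0.25))
  expect_equal(nrow(c0), 1L)
  expect_equal(c(c0$nu_n, c0$nu_p), c(0, 0))
})

test_that("sampled calls follow the joint law", {
  del <- locus_model("deletion", q = 0.1)
  set.seed(101)
  x <- sample(0:4, 500, replace = TRUE, prob = del$freqs)
  expect_identical(sample_observed_calls(x, del, error_rates(0, 0)), x)
  all2 <- sample_observed_calls(x, del, error_rates(1, 0))
  expect_true(all(all2[x != 2] == 2L))
  expect_true(all(all2[x == 2] == 2L))
  expect_error(sample_observed_calls(c(1, 5), del, error_rates(0, 0)),
               "0..4")
})
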