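test_that("Wald statistics follow the chi-squared(1) reference", {
  w <- wald_test(0, 1)
  expect_equal(w$W, 0)
  expect_equal(w$p, 1)
  # chi2(1) upper tail equals the two-sided normal tail
  w <- wald_test(sqrt(3.841459), 1)
  expect_equal(w$p, 0.05, tolerance = 1e-6)
  expect_equal(w$p, 2 * pnorm(sqrt(w$W), lower.tail = FALSE),
               tolerance = 1e-12)
  # sign symmetry
  expect_identical(wald_test(1.3, 0.4), wald_test(-1.3, 0.4))
  # invalid SEs give NA with no error
  expect_true(is.na(wald_test(1, 0)$p))
  expect_true(is.na(wald_test(1, NA)$p))
})

test_that("Cauchy combination matches its closed form", {
  cc <- cauchy_combine(0.5, 0.5)
  expect_equal(cc$T, 0)
  expect_equal(cc$p_joint, 0.5)
  # equal inputs are a fixed point
  p <- c(0.001, 0.01, 0.2, 0.5, 0.77, 0.99)
  cc <- cauchy_combine(p, p)
  expect_equal(cc$p_joint, p, tolerance = 1e-12)
  # direct high-precision evaluation of the tangent form
  cc <- cauchy_combine(0.01, 0.04)
  T_direct <- (tan((0.5 - 0.01) * pi) + tan((0.5 - 0.04) * pi)) / 2
  expect_equal(cc$T, T_direct, tolerance = 1e-10)
  expect_equal(cc$T, 19.86817, tolerance = 1e-5)
  expect_equal(cc$p_joint, 0.5 - atan(T_direct) / pi, tolerance = 1e-12)
  expect_equal(cc$p_joint, 0.0160076, tolerance = 1e-6)
})

test_that("Cauchy combination is symmetric, monotone and stable", {
  set.seed(61)
  a <- runif(50); b <- runif(50)
  expect_equal(cauchy_combine(a, b)$p_joint, cauchy_combine(b, a)$p_joint)
  # monotone in each argument
  grid <- seq(0.01, 0.99, by = 0.07)
  pj <- cauchy_combine(grid, rep(0.3, length(grid)))$p_joint
  expect_true(all(diff(pj) > 0))
  # extreme inputs stay finite and ordered
  tiny <- cauchy_combine(c(1e-15, 1e-300, 0), c(0.5, 0.5, 0.5))$p_joint
  expect_true(all(is.finite(tiny)))
  expect_true(all(tiny >= 0 & tiny <= 1))
  expect_lt(tiny[1], 1e-12)
  expect_true(is.na(cauchy_combine(NA_real_, 0.5)$p_joint))
})

test_that("BH adjustment equals the step-up definition", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(67)
  for (i in 1:1000) {
    p <- runif(sample(1:30, 1))^sample(1:3, 1)
    expect_equal(bh_adjust(p), bh_bruteforce(p), tolerance = 1e-12)
  }
  # q >= p and rank order preserved
  p <- runif(100)
  q <- bh_adjust(p)
  expect_true(all(q >= p))
  expect_true(all(diff(q[order(p)]) >= -1e-12))
  # NA passthrough excluded from the family size
  q <- bh_adjust(c(0.01, NA, 0.02))
  expect_true(is.na(q[2]))
  expect_equal(q[c(1, 3)], bh_adjust(c(0.01, 0.02)))
})

test_that("classification applies DVMR > DMR > VMR precedence", {
  res <- data.frame(fdr_mean = c(0.01, 0.5, 0.04, NA),
                    fdr_var = c(0.9, 0.5, 0.9, NA),
                    fdr_joint = c(0.2, 0.5, 0.04, NA))
  out <- classify_regions(res, alpha = 0.05)
  expect_identical(out$call, c("DMR", "none", "DVMR", NA))
  expect_identical(out$is_dmr, c(TRUE, FALSE, TRUE, FALSE))
  expect_identical(out$is_vmr, rep(FALSE, 4))
  expect_identical(out$is_dvmr, c(FALSE, FALSE, TRUE, FALSE))
})

test_that("end-to-end analysis is deterministic and FDR-consistent", {
  sim <- simulate_study(scenario_config(n_regions = 10, N = 24,
                                        scenario = "null", seed = 71))
  res <- methdys(sim$mvalues, sim$regions, sim$design)
  expect_identical(nrow(res), 10L)
  expect_true(all(res$fdr_mean >= res$p_mean))
  expect_true(all(res$fdr_var >= res$p_var))
  expect_true(all(res$fdr_joint >= res$p_joint))
  # joint p consistent with the combination statistic
  expect_equal(res$p_joint, 0.5 - atan(res$T_cauchy) / pi,
               tolerance = 1e-12)
  # serial and parallel execution give identical tables
  res2 <- methdys(sim$mvalues, sim$regions, sim$design, threads = 2)
  expect_identical(res, res2)
})

test_that("planted mean shifts are recovered with clean calls", {
  sim <- simulate_study(scenario_config(n_regions = 100, prop_signal = 0.1,
                                        N = 150, scenario = "DMR",
                                        mean_effect = 1.0, var_fold = 1,
                                        seed = 73))
  res <- methdys(sim$mvalues, sim$regions, sim$design)
  cc <- confusion(res$is_dmr, sim$truth$is_signal)
  expect_gte(cc$TP, 5)
  expect_lte(cc$FP, 1)
})

test_that("null p-values are uniform for all three tests", {
  # pooled Kolmogorov-Smirnov check at N = 150
  sim <- simulate_study(scenario_config(n_regions = 2000, N = 150,
                                        scenario = "null", seed = 79))
  res <- methdys(sim$mvalues, sim$regions, sim$design)
  expect_gt(ks.test(res$p_mean, "punif")$p.value, 0.001)
  expect_gt(ks.test(res$p_var, "punif")$p.value, 0.001)
  expect_gt(ks.test(res$p_joint, "punif")$p.value, 0.001)
})
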