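test_that("replicate aggregation averages detected wells only", {
  expect_equal(aggregate_replicates(c(25.1, 25.0, 24.9))$mean_ct, 25.0)
  expect_equal(aggregate_replicates(30.0),
               list(mean_ct = 30.0, n_detected = 1L))
  res <- aggregate_replicates(c(24.8, 25.3, NA))
  expect_equal(res$mean_ct, 25.05)
  expect_equal(res$n_detected, 2L)
  all_na <- aggregate_replicates(c(NA_real_, NA_real_))
  expect_true(is.na(all_na$mean_ct))
  expect_equal(all_na$n_detected, 0L)
  expect_error(aggregate_replicates(numeric(0)), "at least one")
  expect_error(aggregate_replicates(c(25, -1)), "positive")
})

test_that("delta-Ct and relative expression follow the comparative-Ct identities", {
  expect_equal(delta_ct(25, 25), 0)
  expect_equal(delta_ct(27, 25), 2)
  expect_equal(delta_ct(23.5, 25.0), -1.5)
  expect_error(delta_ct(25, NA), "normalizer undetected")
  expect_equal(relative_expression(0), 1)
  expect_equal(relative_expression(2), 0.25)
  expect_equal(relative_expression(-1), 2)
  # strictly decreasing in delta-Ct
  dct <- sort(runif(50, -5, 5))
  expect_true(all(diff(relative_expression(dct)) < 0))
  # round-trip to machine precision
  expect_equal(-log2(relative_expression(dct)), dct)
})

test_that("composite score sums the panel and respects the missing-target policy", {
  expect_equal(composite_score(rep(1, 7)), 7)
  expect_equal(composite_score(c(1, 0.25, 2, 1, 1, 0.5, 0.25)), 6.0)
  # order invariance
  v <- c(1, 0.25, 2, 1, 1, 0.5, 0.25)
  for (i in 1:5) expect_equal(composite_score(sample(v)), 6.0)
  # strict policy: any undetected target voids the score
  expect_true(is.na(composite_score(c(v[-7], NA))))
  expect_true(is.na(composite_score(rep(NA_real_, 7))))
  # rescale policy scales the partial sum up by panel/detected
  expect_equal(composite_score(c(1, 1, NA, NA), policy = "rescale"), 4)
  expect_error(composite_score(numeric(0)), "empty")
})

test_that("noise-free pipeline recovers 2^-mu exactly for healthy subjects", {
  mu <- c(HNRNPA1 = 2.5, HNRNPA2B1 = 3.0, HNRNPA3 = 4.0, HNRNPK = 3.5,
          HNRNPK_ex8 = 6.0, PTBP1 = 4.5, SRSF6 = 5.0)
  cfg <- ct_sim_config(n_healthy = 4, n_patients = 0, mu_g = mu,
                       sigma_between = 0, sigma_within = 0,
                       sigma_replicate = 0)
  prof <- quantify_profiles(simulate_ct_dataset(cfg, seed = 1))
  for (tg in SF_PANEL) {
    expect_equal(prof[[tg]], rep(2^(-mu[[tg]]), 4))
  }
  expect_equal(prof$composite_score, rep(sum(2^(-mu)), 4))
  # with a disease effect, patients sit at 2^-(mu + beta) exactly
  cfg2 <- ct_sim_config(n_healthy = 0, n_patients = 3, mu_g = mu,
                        sigma_between = 0, sigma_within = 0,
                        sigma_replicate = 0)
  prof2 <- quantify_profiles(simulate_ct_dataset(cfg2, seed = 1))
  beta <- cfg2$beta_g
  for (tg in SF_PANEL) {
    expect_equal(prof2[[tg]], rep(2^(-(mu[[tg]] + beta[[tg]])), 3))
  }
})

test_that("quantify_profiles flags dropout and supports the delta-Ct-sum score", {
  ct <- make_ct_table(c(HNRNPA1 = 1, HNRNPA2B1 = 2, HNRNPA3 = 0,
                        HNRNPK = 1, HNRNPK_ex8 = 2, PTBP1 = 1, SRSF6 = 2))
  # knock out one target entirely
  ct$ct[ct$target == "SRSF6"] <- NA
  prof <- quantify_profiles(ct)
  expect_equal(prof$n_targets_detected, 6L)
  expect_true(is.na(prof$composite_score))
  # undetected normalizer drops the sample with a warning
  ct2 <- make_ct_table(c(HNRNPA1 = 1), sample_id = "S9")
  ct2$ct[ct2$target == SF_NORMALIZER] <- NA
  expect_warning(out <- quantify_profiles(
    dplyr::bind_rows(make_ct_table(c(HNRNPA1 = 1)), ct2),
    targets = "HNRNPA1"), "undetected normalizer")
  expect_equal(out$sample_id, "S1")
  # delta-Ct-sum alternative
  ct3 <- make_ct_table(c(A = 1, B = 2))
  prof3 <- quantify_profiles(ct3, targets = c("A", "B"),
                             score = "sum_delta_ct")
  expect_equal(prof3$composite_score, 3)
})
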