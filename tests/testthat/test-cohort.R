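test_that("permutation mean test matches brute-force enumeration", {
  # separated constants: only the 2 all-or-nothing assignments reach |10|
  res <- permutation_mean_test(c(0, 0, 0), c(10, 10, 10))
  expect_equal(res$method, "exhaustive")
  expect_equal(res$p_value, 2 / 20)
  expect_equal(res$p_value,
               enumerate_mean_perm_p(c(0, 0, 0), c(10, 10, 10)))
  # random small instances against the independent oracle
  for (i in 1:5) {
    withr::with_seed(100 + i, {
      x <- sample(0:9, 4, replace = TRUE)
      y <- sample(0:9, 5, replace = TRUE)
    })
    got <- permutation_mean_test(x, y)
    expect_equal(got$method, "exhaustive")
    expect_equal(got$p_value, enumerate_mean_perm_p(x, y))
  }
  # identical groups are fully exchangeable
  expect_equal(permutation_mean_test(1:3, 1:3)$p_value, 1)
})

test_that("Monte-Carlo path is seeded, bounded and approaches enumeration", {
  x <- c(1, 5, 2, 8, 3); y <- c(4, 9, 7, 6, 2)
  exact <- enumerate_mean_perm_p(x, y)
  mc1 <- permutation_mean_test(x, y, B = 4000, seed = 1,
                               exhaustive_limit = 1)
  mc2 <- permutation_mean_test(x, y, B = 4000, seed = 1,
                               exhaustive_limit = 1)
  expect_equal(mc1$method, "monte_carlo")
  expect_identical(mc1$p_value, mc2$p_value)
  expect_gte(mc1$p_value, 1 / 4001)
  expect_lte(mc1$p_value, 1)
  expect_lt(abs(mc1$p_value - exact), 0.05)
})

test_that("compare_groups reports direction and survives relabeling", {
  prof <- quantify_profiles(simulate_ct_dataset(
    ct_sim_config(n_healthy = 6, n_patients = 6), seed = 41))
  res <- compare_groups(prof, "composite_score")
  # swapping the labels flips the direction, p unchanged
  flipped <- prof
  flipped$group <- ifelse(prof$group == "healthy", "patient", "healthy")
  res_f <- compare_groups(flipped, "composite_score")
  expect_equal(res_f$p_value, res$p_value)
  expect_true(res$direction != res_f$direction ||
                res$direction == "equal")
  # sample order is irrelevant
  shuffled <- prof[sample(nrow(prof)), ]
  expect_equal(compare_groups(shuffled, "composite_score")$p_value,
               res$p_value)
  # degenerate inputs fail loudly
  expect_error(compare_groups(prof[prof$group == "healthy", ],
                              "composite_score"), ">= 2 samples")
  expect_error(compare_groups(prof, "no_such_column"), "not found")
  # Welch alternative agrees with stats::t.test
  w <- compare_groups(prof, "composite_score", method = "welch")
  tt <- stats::t.test(prof$composite_score[prof$group == "patient"],
                      prof$composite_score[prof$group == "healthy"])
  expect_equal(w$p_value, tt$p.value)
})

test_that("age stratification partitions at the cut", {
  prof <- tibble::tibble(sample_id = letters[1:4], group = "healthy",
                         age = c(30, 40, 60, 70), composite_score = 1:4)
  s <- stratify_by_age(prof, cut = 50)
  expect_equal(s$young$age, c(30, 40))
  expect_equal(s$old$age, c(60, 70))
  # all below the cut: old stratum empty, downstream errors cleanly
  s2 <- stratify_by_age(prof, cut = 100)
  expect_equal(nrow(s2$old), 0)
  expect_error(compare_groups(s2$old, "composite_score"))
  # median split balances strata to within one sample
  prof3 <- quantify_profiles(simulate_ct_dataset(ct_sim_config(),
                                                 seed = 13))
  s3 <- stratify_by_age(prof3)
  expect_lte(abs(nrow(s3$young) - nrow(s3$old)), 1)
  expect_equal(attr(s3, "age_cut"), stats::median(prof3$age))
  # missing ages are excluded with a message
  prof$age[1] <- NA
  expect_message(s4 <- stratify_by_age(prof, cut = 50), "missing age")
  expect_equal(nrow(s4$young) + nrow(s4$old), 3)
})

test_that("per-target summary reproduces the panel sign pattern with Holm p", {
  prof <- quantify_profiles(simulate_ct_dataset(ct_sim_config(),
                                                seed = 11))
  res <- per_target_summary(prof, B = 500, seed = 3)
  expect_equal(nrow(res), 8)
  tg <- res[res$endpoint != "composite_score", ]
  expect_equal(tg$direction[tg$endpoint == "HNRNPA2B1"],
               "lower_in_patient")
  expect_true(all(tg$direction[tg$endpoint != "HNRNPA2B1"] ==
                    "higher_in_patient"))
  expect_true(all(tg$p_holm >= tg$p_value))
  expect_true(is.na(res$p_holm[res$endpoint == "composite_score"]))
})

test_that("power of the composite comparison grows with the effect size", {
  rejections <- vapply(c(0, 1, 2), function(mult) {
    hits <- 0
    for (i in 1:12) {
      beta <- c(HNRNPA1 = -0.4, HNRNPA2B1 = 0.3, HNRNPA3 = -0.5,
                HNRNPK = -0.4, HNRNPK_ex8 = -0.6, PTBP1 = -0.7,
                SRSF6 = -0.8) * mult
      cfg <- ct_sim_config(n_healthy = 14, n_patients = 14, beta_g = beta)
      prof <- quantify_profiles(simulate_ct_dataset(cfg, seed = 700 + i))
      p <- compare_groups(prof, "composite_score", B = 200,
                          seed = i)$p_value
      hits <- hits + (p <= 0.05)
    }
    hits
  }, numeric(1))
  expect_true(all(diff(rejections) >= 0))
  expect_gt(rejections[3], rejections[1])
})
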