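test_that("Delta has the documented endpoints and symmetry", {
  expect_equal(pair_delta(0.5, 0.5), 0.5)
  expect_equal(pair_delta(1, 0), 1)
  expect_equal(pair_delta(0, 0), 0)
  expect_equal(pair_delta(1, 1), 0)
  expect_equal(pair_delta(0.8, 0.3), 0.62)
  expect_error(pair_delta(1.1, 0), "\\[0, 1\\]")
  set.seed(2)
  p <- runif(50); q <- runif(50)
  expect_equal(pair_delta(p, q), pair_delta(q, p))
  expect_true(all(pair_delta(p, p) <= 0.5 + 1e-12))
  expect_equal(pair_delta(p, p), 2 * p * (1 - p))
})

test_that("pair enumeration yields C(n, 2) shells with pooled rates", {
  s36 <- summary_from_rates(seq(0, 1, length.out = 36))
  expect_equal(nrow(enumerate_pairs(s36)), 630)
  expect_equal(nrow(enumerate_pairs(summary_from_rates(c(0.2, 0.8)))), 1)
  for (n in c(3, 7, 10, 25, 50))
    expect_equal(nrow(enumerate_pairs(summary_from_rates(seq(0.05, 0.95, length.out = n)))),
                 choose(n, 2))
  expect_error(enumerate_pairs(summary_from_rates(0.5)), "at least two")
  pr <- enumerate_pairs(s36)
  expect_true(all(pr$delta >= 0 & pr$delta <= 1))
  # pooled rates of a pure heterospecific pair equal the generative rates
  pure <- enumerate_pairs(summary_from_rates(c(0, 1), n = 500))
  expect_equal(pure$p_t_tros, 0.8)
  expect_equal(pure$p_t_edu, 0.05)
})

test_that("goodness is the reciprocal grid MSS with sentinel and failure cases", {
  ref <- function(pt) as.numeric(prevalence_from_pt(calc_params(0.8, 0.05), pt))
  good <- pair_goodness(calc_params(0.8, 0.05), ref, target = "prevalence")
  expect_equal(good$mss, 0)
  expect_identical(good$goodness, Inf)
  expect_false(good$failed)
  # a constant offset of 0.1 gives MSS 0.01 and goodness 100
  off <- pair_goodness(calc_params(0.8, 0.05),
                       function(pt) ref(pt) + 0.1,
                       target = "prevalence")
  expect_equal(off$mss, 0.01, tolerance = 1e-9)
  expect_equal(off$goodness, 100, tolerance = 1e-6)
  # non-informative parameters: recorded as failed, not dropped
  bad <- pair_goodness(calc_params(0.1, 0.4), ref, target = "prevalence")
  expect_true(bad$failed)
  expect_true(is.na(bad$goodness))
})

test_that("goodness ranking is stable under grid-step halving", {
  s <- summary_from_rates(seq(0.02, 0.98, length.out = 12), n = 150)
  ref <- "WSBL"
  g1 <- evaluate_pairs(s, ref, grid_step = 0.01)
  g2 <- evaluate_pairs(s, ref, grid_step = 0.005)
  ok <- is.finite(g1$goodness_prevalence) & is.finite(g2$goodness_prevalence)
  expect_gt(cor(rank(g1$goodness_prevalence[ok]),
                rank(g2$goodness_prevalence[ok])), 0.999)
})

test_that("LOESS summary smooths goodness and ignores sentinels", {
  pairs <- data.frame(delta = seq(0.05, 0.95, length.out = 40),
                      goodness_prevalence = 50)
  sm <- loess_summary(pairs, "prevalence")
  expect_true(all(abs(sm$goodness - 50) < 1e-6))
  # permutation invariance
  perm <- pairs[sample(nrow(pairs)), ]
  expect_equal(loess_summary(perm, "prevalence"), sm)
  # sentinels excluded, insufficient data rejected
  pairs$goodness_prevalence[1] <- Inf
  expect_silent(loess_summary(pairs, "prevalence"))
  expect_error(loess_summary(pairs[1:8, ], "prevalence"), "at least 10")
})

test_that("calibrator selection pools the required prevalence strata", {
  s <- summary_from_rates(c(0.05, 0.5, 0.9), n = 400)
  sel <- select_calibrators(s, "prevalence")
  expect_match(sel$provenance, "S01")
  expect_match(sel$provenance, "S03")
  expect_false(grepl("S02", sel$provenance))
  mid <- select_calibrators(s, "predictive")
  expect_match(mid$provenance, "S02")
  all_mixed <- summary_from_rates(c(0.5, 0.55, 0.5), n = 200)
  expect_error(select_calibrators(all_mixed, "prevalence"), "empty stratum")
  all_pure <- summary_from_rates(c(0.02, 0.05, 0.95), n = 200)
  expect_error(select_calibrators(all_pure, "predictive"), "empty stratum")

  # on a large study the prevalence-purpose rates approach the generative ones
  cfg <- sim_config(prevalence_grid = c(0.02, 0.05, 0.5, 0.9, 0.95),
                    sample_size_range = c(5000, 5000),
                    morph_model = list(
                      intercept = c(edulis = qlogis(0.04), trossulus = qlogis(0.74)),
                      slope = c(edulis = 0, trossulus = 0)),
                    intermediate_fraction = 0, seed = 77)
  big <- select_calibrators(summarize_study(generate_study(cfg)$individuals),
                            "prevalence")
  expect_equal(big$p_t_tros, 0.74, tolerance = 0.02)
  expect_equal(big$p_t_edu, 0.04, tolerance = 0.15)
})
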