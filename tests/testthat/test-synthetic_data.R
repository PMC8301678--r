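test_that("configuration validates its inputs", {
  expect_s3_class(sim_config(), "sim_config")
  expect_error(sim_config(intermediate_fraction = 1.2), "\\[0, 1\\]")
  expect_error(sim_config(prevalence_grid = c(0.2, 1.4)), "\\[0, 1\\]")
  expect_error(sim_config(sample_size_range = c(50, 10)), "increasing pair")
  expect_error(sim_config(morph_model = list(intercept = c(a = 1),
                                             slope = c(edulis = 0, trossulus = 0))),
               "edulis")
})

test_that("seeded generation is deterministic", {
  cfg <- sim_config(n_samples = 4, sample_size_range = c(20, 40), seed = 0)
  expect_identical(generate_individual("hybrid", 0.5, cfg),
                   generate_individual("hybrid", 0.5, cfg))
  expect_identical(generate_sample(0.5, 25, cfg), generate_sample(0.5, 25, cfg))
  expect_identical(generate_study(cfg), generate_study(cfg))
})

test_that("unknown species labels and bad sizes are rejected", {
  cfg <- sim_config(seed = 1)
  expect_error(generate_individual("gallus", 0.5, cfg), "unknown species")
  expect_error(generate_sample(0.5, 0, cfg), ">= 1")
  expect_error(generate_study(sim_config(prevalence_grid = numeric(0))),
               "non-empty")
})

test_that("morphotype law follows the configured logit model", {
  # saturated logit: certain T-morphotype
  cfg_sat <- sim_config(morph_model = list(
    intercept = c(edulis = -Inf, trossulus = Inf),
    slope = c(edulis = 0, trossulus = 0)), seed = 5)
  s <- generate_sample(1, 200, cfg_sat, stream = NULL)
  expect_true(all(s$morphotype == "T"))

  # law of large numbers against the Bernoulli parameter
  cfg_e <- sim_config(morph_model = list(
    intercept = c(edulis = qlogis(0.04), trossulus = qlogis(0.74)),
    slope = c(edulis = 0, trossulus = 0)),
    intermediate_fraction = 0, seed = 11)
  s_e <- generate_sample(0, 1e5, cfg_e)
  expect_equal(mean(s_e$morphotype == "T"), 0.04, tolerance = 0.1)
  expect_lt(abs(mean(s_e$morphotype == "T") - 0.04), 3 * sqrt(0.04 * 0.96 / 1e5))

  # pure trossulus population: PT approaches the configured sensitivity
  s_t <- generate_sample(1, 1e5, cfg_e)
  expect_lt(abs(mean(s_t$morphotype == "T") - 0.74), 3 * sqrt(0.74 * 0.26 / 1e5))
})

test_that("q mixture respects the regime and the prevalence target", {
  cfg <- sim_config(intermediate_fraction = 0.10, hybrid_profile = "constant",
                    seed = 21)
  s <- generate_sample(0.5, 1e4, cfg)
  expect_equal(mean(s$q > 0.2 & s$q < 0.8), 0.10, tolerance = 0.1)
  expect_equal(mean(s$q > 0.5), 0.5, tolerance = 0.03)

  # pure population with no hybrids: every q at the edulis end
  cfg0 <- sim_config(intermediate_fraction = 0, seed = 3)
  s0 <- generate_sample(0, 2000, cfg0)
  expect_true(all(s0$q <= 0.2))

  # zero intermediate fraction is strictly bimodal at any prevalence
  s_mix <- generate_sample(0.5, 5000, cfg0)
  expect_false(any(s_mix$q > 0.2 & s_mix$q < 0.8))

  # unimodal hybrid profile: no hybrids at the extremes
  cfg_u <- sim_config(intermediate_fraction = 0.3, hybrid_profile = "unimodal",
                      seed = 9)
  expect_false(any({s <- generate_sample(1, 2000, cfg_u); s$q < 0.8}))
})

test_that("a study spans the grid with sizes in range", {
  grid <- seq(0, 1, length.out = 36)
  cfg <- sim_config(prevalence_grid = grid, sample_size_range = c(18, 173),
                    seed = 2)
  st <- generate_study(cfg)
  expect_equal(nrow(st$samples), 36)
  expect_true(all(st$samples$n >= 18 & st$samples$n <= 173))
  expect_equal(st$samples$true_ptros, grid)
  # empirical prevalence ordering preserved in expectation at large n
  cfg_big <- sim_config(prevalence_grid = c(0, 0.5, 1),
                        sample_size_range = c(3000, 3000), seed = 4)
  s <- summarize_study(generate_study(cfg_big)$individuals)
  expect_true(all(diff(s$ptros) > 0))
})

test_that("pooled class rates converge to the configured logit model", {
  # with zero slopes the class-conditional rates are prevalence-independent:
  # a Model-2-style refit finds no drift
  cfg <- sim_config(prevalence_grid = seq(0.1, 0.9, length.out = 8),
                    sample_size_range = c(2000, 2000),
                    morph_model = list(
                      intercept = c(edulis = qlogis(0.04), trossulus = qlogis(0.74)),
                      slope = c(edulis = 0, trossulus = 0)),
                    intermediate_fraction = 0, seed = 13)
  ind <- generate_study(cfg)$individuals
  frame <- prepare_model_frame(ind)
  for (sp in c("edulis", "trossulus")) {
    sub <- frame[frame$species == sp, ]
    fit <- stats::glm(morph01 ~ ptros, binomial(), sub)
    ci <- suppressMessages(confint.default(fit))["ptros", ]
    expect_true(ci[1] < 0 && ci[2] > 0)
  }
  # and the pooled rates match the inverse-logit of the intercepts
  idx <- diagnostic_indices(pool_summaries(summarize_study(ind)))
  expect_equal(idx$sens, 0.74, tolerance = 0.02)
  expect_equal(idx$fpr, 0.04, tolerance = 0.25)
})
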