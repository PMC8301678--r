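# Simulate one study from a logistic law on a design prevalence grid,
# returning an individual-level table carrying the design ptros/pt columns.
sim_from_logit <- function(intercept, slope, n_samples = 36, n = 100,
                           predictor = c("ptros", "pt"), seed = 1) {
  predictor <- match.arg(predictor)
  set.seed(seed)
  x <- seq(0, 1, length.out = n_samples)
  rows <- lapply(seq_len(n_samples), function(i) {
    pr <- plogis(intercept + slope * x[i])
    if (predictor == "ptros") {
      # response is the morphotype; genotype tracks the design prevalence
      morph <- ifelse(runif(n) < pr, "T", "E")
      q <- ifelse(runif(n) < x[i], 0.9, 0.1)
    } else {
      # response is the genotype; morphotype frequency is the design value
      morph <- ifelse(runif(n) < x[i], "T", "E")
      q <- ifelse(runif(n) < pr, 0.9, 0.1)
    }
    out <- data.frame(sample_id = sprintf("S%02d", i), set = "SIM",
                      q = q, morphotype = morph, stringsAsFactors = FALSE)
    out$ptros <- x[i]; out$pt <- x[i]
    out
  })
  do.call(rbind, rows)
}

test_that("model specifications carry the published random-effect structure", {
  expect_false(model_spec("M1")$random)
  expect_false(model_spec("M4")$random)
  for (id in c("M2", "M3", "M5", "M6")) expect_true(model_spec(id)$random)
  expect_equal(model_spec("M3")$response, "correct")
  expect_equal(model_spec("M4")$response, "tros01")
  expect_error(model_spec("M9"))
})

test_that("degenerate and rank-deficient designs are rejected with reasons", {
  ind <- individuals_from_counts(20, 0, 20, 0)  # all T-morphotypes
  expect_error(fit_model("M1", ind), "constant")
  # set perfectly confounded with prevalence: aliased interaction
  a <- individuals_from_counts(8, 2, 1, 9, sample_id = "A")
  b <- individuals_from_counts(9, 1, 2, 8, sample_id = "B")
  a$set <- "S1"; b$set <- "S2"
  expect_error(fit_model("M1", rbind(a, b)), "aliased")
})

test_that("M1 recovers generative coefficients from simulated data", {
  ind <- sim_from_logit(-2.4, 5.4, predictor = "ptros", seed = 101)
  fit <- fit_model("M1", ind)
  expect_true(fit$converged)
  est <- fit$coefficients
  for (k in 1:2) {
    ci <- est$estimate[k] + c(-1.96, 1.96) * est$se[k]
    expect_gt(c(-2.4, 5.4)[k], ci[1])
    expect_lt(c(-2.4, 5.4)[k], ci[2])
  }
  # logistic score equation: mean fitted probability equals response mean
  expect_equal(mean(fitted(fit$model)), mean(fit$frame$morph01))
})

test_that("separation triggers the flagged bias-reduced fallback", {
  # perfectly separated: all T above prevalence 0.5, all E below
  ind <- do.call(rbind, lapply(1:10, function(i) {
    p <- (i - 0.5) / 10
    out <- individuals_from_counts(ifelse(p > 0.5, 20, 0), 0,
                                   0, ifelse(p > 0.5, 0, 20),
                                   sample_id = sprintf("S%02d", i))
    out$ptros <- p; out$pt <- p
    out
  }))
  fit <- fit_model("M1", ind)
  expect_true(fit$separation)
  expect_equal(fit$method, "firth")
  expect_true(all(is.finite(fit$coefficients$estimate)))
  expect_true(all(is.finite(fit$coefficients$se)))
  # far smaller than the unbounded ML divergence an ordinary glm would show
  expect_true(all(abs(fit$coefficients$estimate) < 200))
})

test_that("pseudo-R2 follows the Nakagawa-Schielzeth arithmetic", {
  r2 <- morphotest:::r2_from_variances(1, 0.5)
  expect_equal(unname(r2["marginal"]), 1 / (1.5 + pi^2 / 3), tolerance = 1e-10)
  expect_equal(round(unname(r2["marginal"]), 3), 0.209)
  expect_equal(round(unname(r2["conditional"]), 3), 0.313)
  expect_equal(unname(morphotest:::r2_from_variances(0, 0.5)["marginal"]), 0)
  r0 <- morphotest:::r2_from_variances(2, 0)
  expect_equal(r0[["marginal"]], r0[["conditional"]])
})

test_that("zero sample-level variance makes marginal and conditional R2 agree", {
  set.seed(31)
  # M6-type data with no sample heterogeneity beyond the fixed effects
  ind <- do.call(rbind, lapply(1:12, function(i) {
    p <- (i - 1) / 11
    n <- 80
    morph <- rep(c("T", "E"), n / 2)
    pc <- plogis(ifelse(morph == "T", 0.2 + 3.2 * p, 3.7 - 4.9 * p))
    corr <- runif(n) < pc
    tros <- (morph == "T") == corr
    out <- data.frame(sample_id = sprintf("S%02d", i), set = "SIM",
                      q = ifelse(tros, 0.9, 0.1), morphotype = morph,
                      stringsAsFactors = FALSE)
    out$ptros <- p; out$pt <- p
    out
  }))
  fit <- fit_model("M6", ind)
  r2 <- pseudo_r2(fit)
  expect_lte(r2[["marginal"]], r2[["conditional"]])
  expect_equal(r2[["marginal"]], r2[["conditional"]], tolerance = 0.05)
  expect_lt(fit$random_variance, 0.2)
})

test_that("prediction intervals behave like Wald intervals on the logit scale", {
  ind <- sim_from_logit(-2.4, 5.4, n_samples = 12, n = 200, seed = 7)
  fit <- fit_model("M1", ind)
  nd <- data.frame(ptros = c(0.25, 0.5))
  pr <- predict_with_ci(fit, nd)
  expect_true(all(pr$lwr >= 0 & pr$upr <= 1))
  expect_true(all(pr$lwr <= pr$fit & pr$fit <= pr$upr))
  # at a fitted design point the prediction equals the fitted probability
  row <- fit$frame[1, ]
  expect_equal(predict_with_ci(fit, row)$fit, unname(fitted(fit$model)[1]))
  # degenerate interval at level zero
  p0 <- predict_with_ci(fit, nd, level = 0)
  expect_equal(p0$lwr, p0$fit)
  expect_equal(p0$upr, p0$fit)
  # interval width shrinks as per-sample n grows
  widths <- vapply(c(50, 500, 5000), function(n) {
    f <- fit_model("M1", sim_from_logit(-2.4, 5.4, n_samples = 12, n = n,
                                        seed = 7))
    p <- predict_with_ci(f, data.frame(ptros = 0.5))
    p$upr - p$lwr
  }, numeric(1))
  expect_true(all(diff(widths) < 0))
  expect_warning(predict_with_ci(fit, data.frame(ptros = 1.5)),
                 "outside \\[0, 1\\]")
})

test_that("AIC pooling selects the generative grouping of sets", {
  one_set <- function(set, b_e, b_t, seed) {
    cfg <- sim_config(prevalence_grid = seq(0.05, 0.95, length.out = 10),
                      sample_size_range = c(80, 80),
                      morph_model = list(
                        intercept = c(edulis = qlogis(0.05), trossulus = qlogis(0.7)),
                        slope = c(edulis = b_e, trossulus = b_t)),
                      intermediate_fraction = 0, seed = seed)
    st <- generate_study(cfg, set = set)
    ind <- st$individuals
    ind$sample_id <- paste0(set, "_", ind$sample_id)
    ind
  }
  # WS and BL share one generative law; BH differs sharply
  ind <- rbind(one_set("WS", 0, 0, 51), one_set("BL", 0, 0, 52),
               one_set("BH", 4, -3, 53))
  parts <- list("WSBL+BH" = list(c("WS", "BL"), "BH"),
                "WSBH+BL" = list(c("WS", "BH"), "BL"),
                "BLBH+WS" = list(c("BL", "BH"), "WS"))
  res <- pooling_test(ind, parts)
  expect_equal(res$best, "WSBL+BH")
  expect_equal(nrow(res$table), 3)
  # a single candidate partition is returned as-is
  solo <- pooling_test(ind, parts["WSBL+BH"])
  expect_equal(solo$best, "WSBL+BH")
  expect_error(pooling_test(ind, list(bad = list("WS", "BL"))), "cover")
})
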