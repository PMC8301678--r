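#' Pair-dissimilarity index Delta
#'
#' Taxonomic dissimilarity of two samples with prevalences `p1` and `p2`:
#' \deqn{\Delta = p_1 (1 - p_2) + p_2 (1 - p_1).}
#' Delta is 0 for two pure conspecific samples, 0.5 for two equal mixtures
#' and 1 for a pure trossulus sample paired with a pure edulis sample. It is
#' symmetric in the pair, and `pair_delta(p, p) = 2 p (1 - p) <= 0.5`.
#'
#' @param p1,p2 prevalences in \[0, 1\] (vectorized).
#' @return Numeric vector of Delta values in \[0, 1\].
#' @export
#' @examples
#' pair_delta(0.5, 0.5)  # 0.5
#' pair_delta(1, 0)      # 1
pair_delta <- function(p1, p2) {
  check_fraction(p1, "p1")
  check_fraction(p2, "p2")
  p1 * (1 - p2) + p2 * (1 - p1)
}

#' Enumerate all candidate calibration pairs of a study
#'
#' Builds the shell of the calibration-pair experiment: every unordered pair
#' of samples (`C(n, 2)` rows), its Delta index, and the calculator
#' parameters pooled from the pair's 2x2 counts. Pairs whose pooled counts
#' leave the sensitivity or false-positive rate undefined, or give
#' `P(T|tros) <= P(T|edu)` (a non-informative marker), are kept with
#' `params_ok = FALSE` rather than dropped.
#'
#' @param samples data frame of `sample_summary` rows (>= 2 samples).
#' @return Data frame with columns `id1`, `id2`, `ptros1`, `ptros2`,
#'   `delta`, `p_t_tros`, `p_t_edu`, `params_ok`.
#' @export
enumerate_pairs <- function(samples) {
  n <- nrow(samples %||% data.frame())
  if (n < 2L) stopf("pair enumeration needs at least two samples")
  idx <- utils::combn(n, 2)
  i <- idx[1, ]; j <- idx[2, ]
  cnt <- function(k) samples[[k]][i] + samples[[k]][j]
  n_tros <- cnt("n_T_tros") + cnt("n_E_tros")
  n_edu <- cnt("n_T_edu") + cnt("n_E_edu")
  sens <- ifelse(n_tros > 0, cnt("n_T_tros") / n_tros, NA_real_)
  fpr <- ifelse(n_edu > 0, cnt("n_T_edu") / n_edu, NA_real_)
  data.frame(id1 = samples$sample_id[i], id2 = samples$sample_id[j],
             ptros1 = samples$ptros[i], ptros2 = samples$ptros[j],
             delta = pair_delta(samples$ptros[i], samples$ptros[j]),
             p_t_tros = sens, p_t_edu = fpr,
             params_ok = !is.na(sens) & !is.na(fpr) & sens > fpr,
             stringsAsFactors = FALSE)
}

# Normalise a reference into prediction functions over the evaluation grid.
# Accepts a fitted morphotest_fit, a published set name, or a function.
as_prevalence_reference <- function(reference) {
  if (is.function(reference)) return(reference)
  if (inherits(reference, "morphotest_fit")) {
    fit <- reference
    return(function(pt) {
      nd <- data.frame(pt = pt)
      for (v in names(fit$xlevels)) nd[[v]] <- fit$xlevels[[v]][1]
      predict_with_ci(fit, nd)$fit
    })
  }
  if (is.character(reference) && length(reference) == 1L)
    return(function(pt) published_predict(reference, "Ptros_from_PT", pt))
  stopf("unsupported prevalence reference")
}

as_predictive_reference <- function(reference) {
  if (is.function(reference)) return(reference)
  if (inherits(reference, "morphotest_fit")) {
    fit <- reference
    return(function(ptros, morphotype) {
      nd <- data.frame(ptros = ptros, morphotype = morphotype)
      for (v in setdiff(names(fit$xlevels), "morphotype"))
        nd[[v]] <- fit$xlevels[[v]][1]
      predict_with_ci(fit, nd)$fit
    })
  }
  if (is.character(reference) && length(reference) == 1L)
    return(function(ptros, morphotype)
      published_predict(reference,
                        if (morphotype[1] == "T") "PPV_from_Ptros" else "NPV_from_Ptros",
                        ptros))
  stopf("unsupported predictive reference")
}

#' Goodness of a calibration pair against a regression reference
#'
#' Measures how closely the calculators parameterized by one candidate pair
#' reproduce the study-wide regression reference over a fixed grid (\[0, 1\]
#' in steps of `grid_step`, endpoints included). For the `"prevalence"`
#' target, the "Ptros by PT calculator" curve is compared with the Model-4
#' reference over the `PT` grid. For the `"predictive"` target, the
#' `P(tros|T)` and `P(edu|E)` calculator curves are compared with the
#' Model-6 reference over the `Ptros` grid, the two species' curves pooled
#' with equal weight. `Goodness = 1/MSS`, reported as `Inf` (a sentinel) on
#' perfect agreement. Degenerate parameters (sensitivity not exceeding the
#' false-positive rate) are recorded as a failed evaluation, not dropped.
#'
#' @param params a [calc_params()] object.
#' @param reference a converged [fit_model()] result (M4-type for the
#'   prevalence target, M6-type for the predictive target), a published set
#'   name, or a prediction function.
#' @param grid_step grid step on the frequency axis (default 0.01).
#' @param target `"prevalence"` or `"predictive"`.
#' @return List with `mss`, `goodness` and `failed`.
#' @export
pair_goodness <- function(params, reference, grid_step = 0.01,
                          target = c("prevalence", "predictive")) {
  target <- match.arg(target)
  if (!is.numeric(grid_step) || grid_step <= 0 || grid_step > 1)
    stopf("`grid_step` must be in (0, 1]")
  grid <- seq(0, 1, by = grid_step)
  if (!inherits(params, "calc_params") ||
      !(params$p_t_tros > params$p_t_edu))
    return(list(mss = NA_real_, goodness = NA_real_, failed = TRUE))
  if (target == "prevalence") {
    ref <- as_prevalence_reference(reference)
    pred <- as.numeric(prevalence_from_pt(params, grid))
    mss <- mean((pred - ref(grid))^2)
  } else {
    ref <- as_predictive_reference(reference)
    d2 <- c((ppv(params, grid) - ref(grid, rep("T", length(grid))))^2,
            (npv(params, grid) - ref(grid, rep("E", length(grid))))^2)
    mss <- mean(d2, na.rm = TRUE)
  }
  list(mss = mss, goodness = if (mss == 0) Inf else 1 / mss, failed = FALSE)
}

#' Evaluate every calibration pair of a study
#'
#' Runs [pair_goodness()] for both targets over all pairs from
#' [enumerate_pairs()].
#'
#' @param samples data frame of `sample_summary` rows.
#' @param reference_prevalence reference for the prevalence target (M4-type).
#' @param reference_predictive reference for the predictive target (M6-type);
#'   `NULL` skips that target.
#' @inheritParams pair_goodness
#' @return The pair data frame extended with `mss_prevalence`,
#'   `goodness_prevalence`, `mss_predictive`, `goodness_predictive`,
#'   `failed`.
#' @export
evaluate_pairs <- function(samples, reference_prevalence,
                           reference_predictive = NULL, grid_step = 0.01) {
  pairs <- enumerate_pairs(samples)
  grid <- seq(0, 1, by = grid_step)
  ref_prev <- as_prevalence_reference(reference_prevalence)
  ref_prev_vals <- ref_prev(grid)
  have_pred <- !is.null(reference_predictive)
  if (have_pred) {
    ref_pred <- as_predictive_reference(reference_predictive)
    ref_T <- ref_pred(grid, rep("T", length(grid)))
    ref_E <- ref_pred(grid, rep("E", length(grid)))
  }
  m_prev <- m_pred <- rep(NA_real_, nrow(pairs))
  for (k in seq_len(nrow(pairs))) {
    if (!pairs$params_ok[k]) next
    par <- calc_params(pairs$p_t_tros[k], pairs$p_t_edu[k])
    m_prev[k] <- mean((as.numeric(prevalence_from_pt(par, grid)) - ref_prev_vals)^2)
    if (have_pred)
      m_pred[k] <- mean(c((ppv(par, grid) - ref_T)^2,
                          (npv(par, grid) - ref_E)^2), na.rm = TRUE)
  }
  pairs$mss_prevalence <- m_prev
  pairs$goodness_prevalence <- ifelse(m_prev == 0, Inf, 1 / m_prev)
  pairs$mss_predictive <- m_pred
  pairs$goodness_predictive <- ifelse(m_pred == 0, Inf, 1 / m_pred)
  pairs$failed <- !pairs$params_ok
  pairs
}

#' LOESS summary of goodness against Delta
#'
#' Locally weighted regression of a goodness column on the Delta index,
#' evaluated over a Delta grid. Infinite (sentinel) and failed evaluations
#' are excluded before smoothing.
#'
#' @param pairs output of [evaluate_pairs()].
#' @param target `"prevalence"` or `"predictive"`.
#' @param span LOESS span (default 0.75).
#' @param degree local polynomial degree (default 2).
#' @param delta_grid grid on which the smoothed curve is returned; defaults
#'   to 50 points spanning the observed Delta range.
#' @return Data frame with columns `delta` and `goodness`.
#' @export
loess_summary <- function(pairs, target = c("prevalence", "predictive"),
                          span = 0.75, degree = 2, delta_grid = NULL) {
  target <- match.arg(target)
  g <- pairs[[paste0("goodness_", target)]]
  ok <- is.finite(g) & is.finite(pairs$delta)
  if (sum(ok) < 10L)
    stopf("need at least 10 finite pair evaluations for LOESS (have %d)", sum(ok))
  d <- pairs$delta[ok]; g <- g[ok]
  if (is.null(delta_grid))
    delta_grid <- seq(min(d), max(d), length.out = 50L)
  sm <- stats::loess(g ~ d, span = span, degree = degree,
                     family = "gaussian",
                     control = stats::loess.control(surface = "direct"))
  data.frame(delta = delta_grid,
             goodness = stats::predict(sm, data.frame(d = delta_grid)))
}

#' Select calibration samples by prevalence strata
#'
#' Applies the selection rules derived from the calibration-pair experiment:
#' to calibrate the "Ptros by PT calculator" (`purpose = "prevalence"`),
#' pool the most dissimilar samples -- those with `ptros` below `bounds[1]`
#' or above `bounds[2]`; to calibrate the "genotype by morphotype
#' calculator" (`purpose = "predictive"`), pool the most mixed samples --
#' `ptros` strictly between `bounds[3]` and `bounds[4]`. Pooling raw counts
#' avoids the noise of small individual samples. An empty required stratum
#' is an error naming the stratum (in that situation practitioners pool all
#' available samples instead).
#'
#' @param samples data frame of `sample_summary` rows.
#' @param purpose `"prevalence"` or `"predictive"`.
#' @param bounds numeric vector `c(low, high, mid_lo, mid_hi)`, default
#'   `c(0.1, 0.8, 0.45, 0.65)`.
#' @return A [calc_params()] object with the pooled rates; the provenance
#'   records the stratum rule and sample ids.
#' @export
select_calibrators <- function(samples, purpose = c("prevalence", "predictive"),
                               bounds = c(0.1, 0.8, 0.45, 0.65)) {
  purpose <- match.arg(purpose)
  check_fraction(bounds, "bounds")
  if (length(bounds) != 4L) stopf("`bounds` must have four elements")
  if (purpose == "prevalence") {
    low <- samples$ptros < bounds[1]
    high <- samples$ptros > bounds[2]
    if (!any(low)) stopf("empty stratum: no samples with Ptros < %.2f", bounds[1])
    if (!any(high)) stopf("empty stratum: no samples with Ptros > %.2f", bounds[2])
    pick <- low | high
    rule <- sprintf("Ptros < %.2f or > %.2f", bounds[1], bounds[2])
  } else {
    pick <- samples$ptros > bounds[3] & samples$ptros < bounds[4]
    if (!any(pick))
      stopf("empty stratum: no samples with %.2f < Ptros < %.2f",
            bounds[3], bounds[4])
    rule <- sprintf("%.2f < Ptros < %.2f", bounds[3], bounds[4])
  }
  params_from_counts(samples[pick, , drop = FALSE],
                     provenance = sprintf("%s calibration (%s): %s", purpose, rule,
                                          paste(samples$sample_id[pick],
                                                collapse = ", ")))
}
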