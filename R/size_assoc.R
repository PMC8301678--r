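#' Hochberg step-up adjustment of p-values
#'
#' Step-up multiple-testing correction: with the p-values sorted ascending,
#' `adjusted(i) = min(adjusted(i+1), (m - i + 1) * p(i))`, capped at 1, and
#' returned in the input order.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values in input order.
#' @export
#' @examples
#' hochberg_adjust(c(0.01, 0.03, 0.04))
hochberg_adjust <- function(p) {
  if (!is.numeric(p) || any(!is.finite(p)) || any(p < 0 | p > 1))
    stopf("p-values must be numeric in [0, 1]")
  stats::p.adjust(p, method = "hochberg")
}

#' Morphotype-size screen within species-specific genotypes
#'
#' For every (sample x species) cell, fits a logistic regression of the
#' T-morphotype indicator on shell length. A cell is *informative* when both
#' morphotypes occur in it; non-informative cells are flagged and excluded
#' from testing. Slope p-values are Hochberg-adjusted within each species'
#' family of informative cells (species corrected separately).
#'
#' @param data individual-level data frame with `sample_id`, `q`,
#'   `morphotype` and `length_mm`.
#' @param threshold q-value classification threshold.
#' @return Data frame with one row per (sample x species) cell: `sample_id`,
#'   `species`, `n`, `slope` (logit per mm), `p_raw`, `p_adjusted`,
#'   `informative`.
#' @export
size_screen <- function(data, threshold = 0.5) {
  if (!"length_mm" %in% names(data) || all(is.na(data$length_mm)))
    stopf("size screen requires a `length_mm` column with data")
  frame <- prepare_model_frame(data, threshold)
  frame <- frame[!is.na(frame$length_mm), , drop = FALSE]
  cells <- unique(frame[, c("sample_id", "species")])
  cells <- cells[order(cells$sample_id, cells$species), , drop = FALSE]
  res <- lapply(seq_len(nrow(cells)), function(k) {
    sub <- frame[frame$sample_id == cells$sample_id[k] &
                   frame$species == cells$species[k], , drop = FALSE]
    informative <- length(unique(sub$morph01)) == 2L
    slope <- p_raw <- NA_real_
    if (informative) {
      fit <- suppressWarnings(
        stats::glm(morph01 ~ length_mm, family = stats::binomial(), data = sub))
      cf <- summary(fit)$coefficients
      if ("length_mm" %in% rownames(cf)) {
        slope <- cf["length_mm", "Estimate"]
        p_raw <- cf["length_mm", "Pr(>|z|)"]
      } else informative <- FALSE
    }
    data.frame(sample_id = as.character(cells$sample_id[k]),
               species = as.character(cells$species[k]),
               n = nrow(sub), slope = slope, p_raw = p_raw,
               informative = informative, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_adjusted <- NA_real_
  for (sp in unique(out$species)) {
    sel <- out$species == sp & out$informative & !is.na(out$p_raw)
    if (any(sel)) out$p_adjusted[sel] <- hochberg_adjust(out$p_raw[sel])
  }
  if (!any(out$informative))
    warnf("no informative (morphotype-polymorphic) cells found")
  rownames(out) <- NULL
  out
}

#' Residual check of the correctness model against shell size
#'
#' Regresses the deviance residuals of a fitted correctness model (M6-type)
#' on shell length and reports the slope test: a non-significant slope is
#' taken as absence of a size pattern in the residuals, i.e. evidence that
#' the morphotype test's error structure does not depend on size.
#'
#' @param fit converged [fit_model()] result for an M3/M6-type model.
#' @param data the individual-level data the model was fitted to, carrying
#'   `length_mm`.
#' @param alpha significance level for the no-pattern flag.
#' @return List with `slope`, `p_value` and `no_pattern` (logical).
#' @export
residual_size_check <- function(fit, data, alpha = 0.05) {
  stopifnot(inherits(fit, "morphotest_fit"))
  if (!fit$converged) stopf("residual check requires a converged fit")
  if (!"length_mm" %in% names(data) || all(is.na(data$length_mm)))
    stopf("residual check requires a `length_mm` column with data")
  len <- data$length_mm
  if (length(len) != nrow(fit$frame))
    stopf("`data` must be the table the model was fitted to (%d rows, got %d)",
          nrow(fit$frame), length(len))
  if (stats::sd(len, na.rm = TRUE) == 0)
    stopf("degenerate predictor: shell length is constant")
  r <- if (inherits(fit$model, c("glm", "glmerMod")))
    stats::residuals(fit$model, type = "deviance")
  else {  # firth fallback: deviance residuals from fitted probabilities
    y <- fit$frame[[fit$spec$response]]
    mu <- fit$model$fitted
    sign(y - mu) * sqrt(-2 * (y * log(pmax(mu, 1e-12)) +
                                (1 - y) * log(pmax(1 - mu, 1e-12))))
  }
  ok <- !is.na(len)
  lm_fit <- stats::lm(r[ok] ~ len[ok])
  cf <- summary(lm_fit)$coefficients
  list(slope = cf[2, "Estimate"], p_value = cf[2, "Pr(>|t|)"],
       no_pattern = cf[2, "Pr(>|t|)"] >= alpha)
}
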