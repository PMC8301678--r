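#' Calculator parameters: sensitivity and false-positive rate
#'
#' Bundles the two rates that parameterize the predictive-value and
#' prevalence calculators: `p_t_tros`, the sensitivity `P(T|tros)` (fraction
#' of trossulus genotypes showing the T-morphotype), and `p_t_edu`, the
#' false-positive rate `P(T|edu)`. In practice these come from pooled counts
#' of genotyped "calibration" samples (see [select_calibrators()] and
#' [lazy_params()]).
#'
#' @param p_t_tros sensitivity, in \[0, 1\].
#' @param p_t_edu false-positive rate, in \[0, 1\].
#' @param provenance free-text label recording where the rates came from.
#' @return Object of class `"calc_params"`.
#' @export
calc_params <- function(p_t_tros, p_t_edu, provenance = "") {
  check_fraction(p_t_tros, "p_t_tros")
  check_fraction(p_t_edu, "p_t_edu")
  if (length(p_t_tros) != 1L || length(p_t_edu) != 1L)
    stopf("calculator parameters must be scalars")
  structure(list(p_t_tros = p_t_tros, p_t_edu = p_t_edu,
                 provenance = provenance),
            class = "calc_params")
}

#' @export
print.calc_params <- function(x, ...) {
  cat(sprintf("Morphotype-test parameters: P(T|tros) = %.4f, P(T|edu) = %.4f\n",
              x$p_t_tros, x$p_t_edu))
  if (nzchar(x$provenance)) cat("  provenance:", x$provenance, "\n")
  invisible(x)
}

as_calc_params <- function(params) {
  if (inherits(params, "calc_params")) return(params)
  stopf("`params` must be a calc_params object (see calc_params())")
}

#' Positive predictive value of the morphotype test
#'
#' Probability that a T-morphotype individual is *M. trossulus* in a
#' population of prevalence `ptros`, assuming prevalence-independent rates:
#' \deqn{P(tros|T) = \frac{Ptros \, P(T|tros)}{Ptros \, P(T|tros) +
#'   (1-Ptros) \, P(T|edu)}.}
#' Undefined (0/0, only possible when `ptros = 0` with a zero false-positive
#' rate, or `ptros = 1` with zero sensitivity) values are returned as `NA`.
#'
#' @param params a [calc_params()] object.
#' @param ptros prevalence value(s) in \[0, 1\].
#' @return Numeric vector of the same length as `ptros`.
#' @export
#' @examples
#' ppv(calc_params(0.74, 0.04), 0.5)  # 0.949
ppv <- function(params, ptros) {
  params <- as_calc_params(params)
  check_fraction(ptros, "ptros")
  num <- ptros * params$p_t_tros
  den <- num + (1 - ptros) * params$p_t_edu
  ifelse(den > 0, num / den, NA_real_)
}

#' Negative predictive value of the morphotype test
#'
#' Probability that an E-morphotype individual is *M. edulis*, in the
#' Bayes-consistent form
#' \deqn{P(edu|E) = \frac{(1-Ptros)(1-P(T|edu))}{(1-Ptros)(1-P(T|edu)) +
#'   Ptros \, (1-P(T|tros))}.}
#'
#' @inheritParams ppv
#' @return Numeric vector of the same length as `ptros`.
#' @export
#' @examples
#' npv(calc_params(0.74, 0.04), 0.5)  # 0.787
npv <- function(params, ptros) {
  params <- as_calc_params(params)
  check_fraction(ptros, "ptros")
  num <- (1 - ptros) * (1 - params$p_t_edu)
  den <- num + ptros * (1 - params$p_t_tros)
  ifelse(den > 0, num / den, NA_real_)
}

#' Prevalence from the observed T-morphotype frequency
#'
#' Inverts the mixture identity `PT = Ptros * P(T|tros) + (1 - Ptros) *
#' P(T|edu)`:
#' \deqn{Ptros = \frac{PT - P(T|edu)}{P(T|tros) - P(T|edu)},}
#' the "Ptros by PT calculator". Requires an informative marker
#' (`p_t_tros > p_t_edu`). Values of `PT` outside the interval
#' \[`p_t_edu`, `p_t_tros`\] yield estimates outside \[0, 1\]; these are
#' clamped and flagged in the `"clamped"` attribute.
#'
#' @param params a [calc_params()] object with `p_t_tros > p_t_edu`.
#' @param pt observed T-morphotype frequency value(s) in \[0, 1\].
#' @return Numeric vector of prevalence estimates in \[0, 1\] with a logical
#'   attribute `"clamped"` marking out-of-range inputs.
#' @export
#' @examples
#' prevalence_from_pt(calc_params(0.74, 0.04), 0.39)  # 0.5
prevalence_from_pt <- function(params, pt) {
  params <- as_calc_params(params)
  check_fraction(pt, "pt")
  if (!(params$p_t_tros > params$p_t_edu))
    stopf("non-informative marker: P(T|tros) = %.4f <= P(T|edu) = %.4f",
          params$p_t_tros, params$p_t_edu)
  raw <- (pt - params$p_t_edu) / (params$p_t_tros - params$p_t_edu)
  out <- clamp01(raw)
  attr(out, "clamped") <- raw < 0 | raw > 1
  out
}

#' "Lazy" calculator parameters from extreme samples
#'
#' The lazy calibration assumes that the samples with the highest and lowest
#' T-morphotype frequency represent pure *M. trossulus* and pure *M. edulis*
#' respectively, and uses their `PT` values directly as `P(T|tros)` and
#' `P(T|edu)`. No genotyping of the calibration samples is needed, at the
#' cost of bias whenever the extreme samples are not actually pure.
#'
#' @param samples data frame of `sample_summary` rows with columns
#'   `sample_id` and `pt` (at least two samples with distinct `pt`).
#' @return A [calc_params()] object; `provenance` records both sample ids.
#' @export
lazy_params <- function(samples) {
  if (is.null(samples) || nrow(samples) < 2L)
    stopf("lazy calibration needs at least two samples")
  pt <- samples$pt
  if (diff(range(pt)) == 0)
    stopf("all samples have identical PT; lazy calibration is impossible")
  hi <- which.max(pt); lo <- which.min(pt)
  calc_params(pt[hi], pt[lo],
              provenance = sprintf("lazy: max PT %s (%.3f), min PT %s (%.3f)",
                                   samples$sample_id[hi], pt[hi],
                                   samples$sample_id[lo], pt[lo]))
}

#' Calculator parameters from pooled sample counts
#'
#' @param summaries `sample_summary` rows to pool (see [pool_summaries()]).
#' @param provenance provenance label.
#' @return A [calc_params()] object.
#' @export
params_from_counts <- function(summaries, provenance = "pooled counts") {
  pooled <- pool_summaries(summaries)
  idx <- diagnostic_indices(pooled)
  if (!idx$sens_defined || !idx$fpr_defined)
    stopf("pooled calibration samples lack %s genotypes",
          if (!idx$sens_defined) "trossulus" else "edulis")
  calc_params(idx$sens, idx$fpr, provenance = provenance)
}
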