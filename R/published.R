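#' Published assignment formulas for the five regional sample sets
#'
#' Logistic-scale coefficients of the regional assignment formulas reported
#' for the morphotype test: for each of five sample sets (`WSBL` White Sea +
#' brackish Barents Sea, `BH` saline Barents Sea, `GOM` Gulf of Maine,
#' `BALT` Baltic Sea, `NORW` western Norway) a formula predicting the
#' taxonomic structure from the T-morphotype frequency (`Ptros_from_PT`) and
#' two formulas predicting the probability of correct identification of an
#' individual from the prevalence (`NPV_from_Ptros` for E-morphotypes,
#' `PPV_from_Ptros` for T-morphotypes). Coefficients are stored to the
#' published precision (one decimal), shipped as a versioned CSV under
#' `extdata`.
#'
#' @return Data frame with columns `set`, `target`, `intercept`, `slope`.
#' @export
#' @examples
#' published_models()
published_models <- function() {
  path <- system.file("extdata", "published_models.csv",
                      package = "morphotest", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Evaluate a published assignment formula
#'
#' Computes `inverse-logit(intercept + slope * x)` for one of the published
#' regional formulas (see [published_models()]).
#'
#' @param set one of `"WSBL"`, `"BH"`, `"GOM"`, `"BALT"`, `"NORW"`.
#' @param target `"Ptros_from_PT"`, `"NPV_from_Ptros"` or `"PPV_from_Ptros"`.
#' @param x predictor value(s) in \[0, 1\]: `PT` for `Ptros_from_PT`, `Ptros`
#'   otherwise.
#' @return Numeric vector of predicted probabilities.
#' @export
#' @examples
#' published_predict("GOM", "PPV_from_Ptros", 0.5)  # about 0.86
published_predict <- function(set, target, x) {
  check_fraction(x, "x")
  tab <- published_models()
  row <- tab[tab$set == set & tab$target == target, , drop = FALSE]
  if (nrow(row) != 1L)
    stopf("no published formula for set '%s', target '%s'", set, target)
  stats::plogis(row$intercept + row$slope * x)
}
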