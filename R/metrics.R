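#' Classify a genotype by its admixture proportion
#'
#' Individuals with a q-value (estimated proportion of *M. trossulus* genes)
#' above the threshold are classed as `"trossulus"`, all others (boundary
#' included) as `"edulis"`. Both classes contain purebreds and hybrids
#' dominated by the respective species' genes.
#'
#' @param q numeric vector of admixture proportions in \[0, 1\].
#' @param threshold classification threshold (default 0.5, boundary assigned
#'   to edulis).
#' @return Character vector of `"edulis"` / `"trossulus"`.
#' @export
#' @examples
#' classify_genotype(c(0, 0.5, 0.51, 1))
classify_genotype <- function(q, threshold = 0.5) {
  check_fraction(q, "q")
  ifelse(q > threshold, "trossulus", "edulis")
}

check_morphotype <- function(m) {
  m <- toupper(as.character(m))
  bad <- !m %in% c("T", "E")
  if (any(bad))
    stopf("unknown morphotype code(s): %s",
          paste(unique(m[bad]), collapse = ", "))
  m
}

#' Summarize one sample into genotype-by-morphotype counts
#'
#' Cross-tabulates genotype class (by q-value) against morphotype and derives
#' the sample prevalence `ptros` (fraction of trossulus genotypes) and the
#' T-morphotype frequency `pt`.
#'
#' @param individuals data frame with columns `sample_id`, `q`, `morphotype`
#'   (and optionally `set`), all rows from a single sample.
#' @param threshold q-value classification threshold passed to
#'   [classify_genotype()].
#' @return One-row data frame of class `"sample_summary"` with columns
#'   `sample_id`, `set`, `n`, the 2x2 counts `n_T_tros`, `n_E_tros`,
#'   `n_T_edu`, `n_E_edu`, and the frequencies `ptros` and `pt`.
#' @export
#' @examples
#' x <- data.frame(sample_id = "A", q = c(0.9, 0.9, 0.1, 0.1),
#'                 morphotype = c("T", "E", "T", "E"))
#' summarize_sample(x)
summarize_sample <- function(individuals, threshold = 0.5) {
  if (is.null(individuals) || nrow(individuals) == 0L)
    stopf("cannot summarize an empty sample")
  ids <- unique(as.character(individuals$sample_id))
  if (length(ids) != 1L)
    stopf("individuals span multiple sample_ids: %s", paste(ids, collapse = ", "))
  m <- check_morphotype(individuals$morphotype)
  g <- classify_genotype(individuals$q, threshold)
  n <- nrow(individuals)
  out <- data.frame(
    sample_id = ids,
    set = if ("set" %in% names(individuals))
      as.character(individuals$set[1]) else NA_character_,
    n = n,
    n_T_tros = sum(m == "T" & g == "trossulus"),
    n_E_tros = sum(m == "E" & g == "trossulus"),
    n_T_edu  = sum(m == "T" & g == "edulis"),
    n_E_edu  = sum(m == "E" & g == "edulis"),
    stringsAsFactors = FALSE)
  out$ptros <- (out$n_T_tros + out$n_E_tros) / n
  out$pt <- (out$n_T_tros + out$n_T_edu) / n
  class(out) <- c("sample_summary", "data.frame")
  out
}

#' Summarize every sample of a study
#'
#' @param individuals individual-level data frame (multiple samples).
#' @inheritParams summarize_sample
#' @return Data frame with one `sample_summary` row per sample, in order of
#'   first appearance.
#' @export
summarize_study <- function(individuals, threshold = 0.5) {
  if (is.null(individuals) || nrow(individuals) == 0L)
    stopf("no individuals to summarize")
  ids <- unique(as.character(individuals$sample_id))
  rows <- lapply(ids, function(id)
    summarize_sample(individuals[individuals$sample_id == id, , drop = FALSE],
                     threshold))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Pool sample summaries by summing their 2x2 counts
#'
#' Pooling across samples is done on raw counts (a direct count over the
#' combined individuals), not by averaging frequencies.
#'
#' @param summaries data frame of `sample_summary` rows.
#' @param sample_id label for the pooled row.
#' @return One-row `sample_summary`.
#' @export
pool_summaries <- function(summaries, sample_id = "pooled") {
  if (nrow(summaries) == 0L) stopf("no summaries to pool")
  cnt <- c("n_T_tros", "n_E_tros", "n_T_edu", "n_E_edu")
  out <- data.frame(sample_id = sample_id,
                    set = paste(unique(summaries$set), collapse = "+"),
                    n = sum(summaries$n),
                    stringsAsFactors = FALSE)
  for (k in cnt) out[[k]] <- sum(summaries[[k]])
  out$ptros <- (out$n_T_tros + out$n_E_tros) / out$n
  out$pt <- (out$n_T_tros + out$n_T_edu) / out$n
  class(out) <- c("sample_summary", "data.frame")
  out
}

#' Diagnostic indices of the morphotype test for a sample
#'
#' Computes the four indices describing how well the morphotype tracks the
#' genotype in a sample, in the vocabulary of clinical test evaluation:
#' sensitivity `P(T|tros)`, false-positive rate `P(T|edu)` (one minus the
#' specificity), positive predictive value `P(tros|T)` and negative
#' predictive value `P(edu|E)`. Indices with a zero denominator (e.g. PPV in
#' a sample without T-morphotypes) are returned as `NA` with the matching
#' `*_defined` flag set to `FALSE`; degenerate samples are legal data and are
#' never dropped here.
#'
#' @param s one or more `sample_summary` rows (see [summarize_sample()]).
#' @return Data frame with columns `sample_id`, `sens`, `fpr`, `ppv`, `npv`
#'   and logical flags `sens_defined`, `fpr_defined`, `ppv_defined`,
#'   `npv_defined`.
#' @export
#' @examples
#' x <- data.frame(sample_id = "A", q = rep(c(0.9, 0.1), c(50, 50)),
#'                 morphotype = rep(c("T", "E", "T", "E"), c(40, 10, 5, 45)))
#' diagnostic_indices(summarize_sample(x))
diagnostic_indices <- function(s) {
  need <- c("n_T_tros", "n_E_tros", "n_T_edu", "n_E_edu")
  if (!all(need %in% names(s)))
    stopf("`s` must carry the 2x2 counts %s", paste(need, collapse = ", "))
  ratio <- function(num, den) ifelse(den > 0, num / den, NA_real_)
  n_tros <- s$n_T_tros + s$n_E_tros
  n_edu <- s$n_T_edu + s$n_E_edu
  n_T <- s$n_T_tros + s$n_T_edu
  n_E <- s$n_E_tros + s$n_E_edu
  data.frame(
    sample_id = if ("sample_id" %in% names(s)) s$sample_id else NA_character_,
    sens = ratio(s$n_T_tros, n_tros),
    fpr  = ratio(s$n_T_edu, n_edu),
    ppv  = ratio(s$n_T_tros, n_T),
    npv  = ratio(s$n_E_edu, n_E),
    sens_defined = n_tros > 0,
    fpr_defined  = n_edu > 0,
    ppv_defined  = n_T > 0,
    npv_defined  = n_E > 0,
    stringsAsFactors = FALSE)
}
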