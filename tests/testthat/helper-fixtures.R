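# Shared fixtures and independent oracles used across the suite.

# Build a one-sample individual table from explicit 2x2 counts.
individuals_from_counts <- function(n_T_tros, n_E_tros, n_T_edu, n_E_edu,
                                    sample_id = "S1", set = "SIM") {
  data.frame(
    sample_id = sample_id, set = set,
    q = rep(c(0.9, 0.9, 0.1, 0.1), c(n_T_tros, n_E_tros, n_T_edu, n_E_edu)),
    morphotype = rep(c("T", "E", "T", "E"),
                     c(n_T_tros, n_E_tros, n_T_edu, n_E_edu)),
    stringsAsFactors = FALSE)
}

# A summary table with given prevalences and exact per-class morphotype
# counts implied by (sens, fpr), for deterministic calibration tests.
summary_from_rates <- function(ptros, n = 200, sens = 0.8, fpr = 0.05) {
  rows <- lapply(seq_along(ptros), function(i) {
    n_tros <- round(n * ptros[i]); n_edu <- n - n_tros
    ind <- individuals_from_counts(round(n_tros * sens),
                                   n_tros - round(n_tros * sens),
                                   round(n_edu * fpr),
                                   n_edu - round(n_edu * fpr),
                                   sample_id = sprintf("S%02d", i))
    summarize_sample(ind)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Independent brute-force Hochberg oracle: the step-up bound written as the
# direct definition min over j >= i (in the sorted order) of (m-j+1) p_(j),
# capped at 1 -- no recursion shared with the implementation path.
hochberg_brute <- function(p) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  adj <- vapply(seq_len(m), function(i)
    min(1, min((m - seq(i, m) + 1) * ps[seq(i, m)])), numeric(1))
  out <- numeric(m)
  out[ord] <- adj
  out
}
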