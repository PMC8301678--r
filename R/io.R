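#' Read and validate an individual-level CSV
#'
#' Expects one row per mussel with columns `sample_id`, `q`, `morphotype`
#' and optionally `set`, `length_mm` and `id`. Morphotype codes are
#' normalized to upper case `T`/`E`; `q` must lie in \[0, 1\]. Schema
#' violations are rejected with the offending row numbers.
#'
#' @param path path to a CSV file.
#' @return Validated data frame.
#' @export
read_individuals <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "q", "morphotype")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stopf("%s: missing required column(s): %s", path, paste(miss, collapse = ", "))
  q <- suppressWarnings(as.numeric(x$q))
  bad <- which(is.na(q) | q < 0 | q > 1)
  if (length(bad))
    stopf("%s: q outside [0, 1] or non-numeric at row(s) %s", path,
          paste(utils::head(bad, 5), collapse = ", "))
  x$q <- q
  m <- toupper(trimws(as.character(x$morphotype)))
  bad <- which(!m %in% c("T", "E"))
  if (length(bad))
    stopf("%s: unknown morphotype code at row(s) %s", path,
          paste(utils::head(bad, 5), collapse = ", "))
  x$morphotype <- m
  if ("id" %in% names(x)) {
    dup <- which(duplicated(x$id))
    if (length(dup))
      stopf("%s: duplicate individual id at row(s) %s", path,
            paste(utils::head(dup, 5), collapse = ", "))
  }
  if ("length_mm" %in% names(x)) {
    len <- suppressWarnings(as.numeric(x$length_mm))
    bad <- which(!is.na(x$length_mm) & (is.na(len) | len <= 0))
    if (length(bad))
      stopf("%s: non-positive or non-numeric length_mm at row(s) %s", path,
            paste(utils::head(bad, 5), collapse = ", "))
    x$length_mm <- len
  }
  x
}

#' Write an individual-level table to CSV
#'
#' Round-trips through [read_individuals()] without loss.
#'
#' @param x individual-level data frame.
#' @param path output path.
#' @export
write_individuals <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' Read a simulation configuration from a YAML file
#'
#' Keys mirror the arguments of [sim_config()]; `morph_model` and
#' `size_model` are nested mappings.
#'
#' @param path path to a YAML file.
#' @return A [sim_config()] object.
#' @export
read_sim_config <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  raw <- yaml::read_yaml(path)
  args <- raw[intersect(names(raw),
                        c("n_samples", "sample_size_range", "prevalence_grid",
                          "q_regime", "intermediate_fraction",
                          "purebred_concentration", "seed"))]
  if (!is.null(raw$morph_model))
    args$morph_model <- list(intercept = unlist(raw$morph_model$intercept),
                             slope = unlist(raw$morph_model$slope))
  if (!is.null(raw$size_model)) args$size_model <- raw$size_model
  do.call(sim_config, args)
}

#' Pipeline configuration
#'
#' Collects the knobs of the end-to-end analysis: where the data come from
#' (a CSV or the synthetic generator), the q-value classification threshold,
#' the calibration strata bounds, the evaluation grid step, the LOESS span,
#' the seed and the output directory.
#'
#' @param input path to an individual-level CSV, or `NULL` to simulate.
#' @param sim a [sim_config()] used when `input` is `NULL`.
#' @param out_dir output directory.
#' @param q_threshold genotype classification threshold (default 0.5).
#' @param strata calibration strata bounds `c(low, high, mid_lo, mid_hi)`.
#' @param grid_step evaluation grid step for the pair experiment.
#' @param loess_span LOESS span for the goodness-vs-Delta summary.
#' @param seed integer seed for every random draw of the run.
#' @return Object of class `"pipeline_config"`.
#' @export
pipeline_config <- function(input = NULL, sim = sim_config(),
                            out_dir = tempfile("morphotest_run_"),
                            q_threshold = 0.5,
                            strata = c(0.1, 0.8, 0.45, 0.65),
                            grid_step = 0.01, loess_span = 0.75, seed = 1L) {
  check_fraction(q_threshold, "q_threshold")
  check_fraction(strata, "strata")
  if (length(strata) != 4L || strata[1] >= strata[2] || strata[3] >= strata[4])
    stopf("`strata` must be c(low, high, mid_lo, mid_hi) with low < high and mid_lo < mid_hi")
  if (!is.numeric(grid_step) || grid_step <= 0 || grid_step > 1)
    stopf("`grid_step` must be in (0, 1]")
  structure(list(input = input, sim = sim, out_dir = out_dir,
                 q_threshold = q_threshold, strata = strata,
                 grid_step = grid_step, loess_span = loess_span,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}
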