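#' Run the full morphotype-test analysis pipeline
#'
#' Executes the whole analysis on one study: per-sample summaries and
#' diagnostic indices; regression models M1 (morphotype frequency vs
#' prevalence), M4 (prevalence vs morphotype frequency) and M6
#' (identification correctness vs prevalence); the calibration-pair
#' experiment with LOESS summaries and stratum-based calibrator selection;
#' and, when shell lengths are present, the morphotype-size screen and the
#' Model-6 residual-size check. All outputs are written as CSV plus a JSON
#' summary and a run log; numeric outputs are byte-identical across runs
#' with the same configuration and seed. On failure, partially written
#' outputs are removed.
#'
#' @param cfg a [pipeline_config()].
#' @return Invisibly, a list with the output paths and the in-memory
#'   results (`summaries`, `fits`, `pairs`, `calibrators`, ...).
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()
  written <- character()
  out <- function(name) file.path(cfg$out_dir, name)
  emit <- function(obj, name) {
    p <- out(name)
    utils::write.csv(obj, p, row.names = FALSE)
    written <<- c(written, p)
    paths[[sub("\\.csv$", "", name)]] <<- p
    p
  }
  log_lines <- c(sprintf("morphotest %s on %s",
                         as.character(utils::packageVersion("morphotest")),
                         R.version.string),
                 sprintf("started: %s", format(Sys.time(), usetz = TRUE)),
                 sprintf("seed: %d", cfg$seed),
                 "config:",
                 paste0("  ", strsplit(yaml::as.yaml(
                   lapply(unclass(cfg)[setdiff(names(unclass(cfg)), "sim")],
                          function(x) x)), "\n")[[1]]))

  result <- tryCatch({
    if (!is.null(cfg$input)) {
      individuals <- read_individuals(cfg$input)
      meta <- NULL
      log_lines <- c(log_lines, sprintf("input: %s (%d rows)", cfg$input,
                                        nrow(individuals)))
    } else {
      sim <- cfg$sim
      sim$seed <- cfg$seed
      study <- generate_study(sim)
      individuals <- study$individuals
      meta <- study$samples
      emit(individuals, "individuals.csv")
      emit(meta, "samples.csv")
      log_lines <- c(log_lines,
                     sprintf("simulated study: %d samples, %d individuals",
                             nrow(meta), nrow(individuals)))
    }

    summaries <- summarize_study(individuals, cfg$q_threshold)
    indices <- diagnostic_indices(summaries)
    summary_tab <- cbind(summaries, indices[, setdiff(names(indices), "sample_id")])
    emit(summary_tab, "sample_summaries.csv")

    fits <- list()
    for (id in c("M1", "M4", "M6")) {
      fits[[id]] <- tryCatch(fit_model(model_spec(id), individuals, cfg$q_threshold),
                             error = function(e) e)
      log_lines <- c(log_lines, sprintf(
        "model %s: %s", id,
        if (inherits(fits[[id]], "error")) paste("skipped -", conditionMessage(fits[[id]]))
        else sprintf("%s, AIC %.1f", fits[[id]]$method, fits[[id]]$aic)))
    }
    ok <- !vapply(fits, inherits, TRUE, "error")
    coef_tab <- do.call(rbind, lapply(names(fits)[ok], function(id)
      cbind(model = id, fits[[id]]$coefficients)))
    if (!is.null(coef_tab)) emit(coef_tab, "model_coefficients.csv")

    grid <- seq(0, 1, by = cfg$grid_step)
    preds <- list()
    if (ok[["M4"]])
      preds$M4 <- cbind(model = "M4", pt = grid,
                        predict_with_ci(fits$M4, data.frame(pt = grid)))
    if (ok[["M6"]]) {
      for (m in c("E", "T"))
        preds[[paste0("M6", m)]] <- cbind(model = paste0("M6_", m), pt = NA,
          ptros = grid,
          predict_with_ci(fits$M6, data.frame(ptros = grid, morphotype = m)))
    }
    if (length(preds)) {
      ptab <- do.call(rbind, lapply(preds, function(p) {
        if (!"ptros" %in% names(p)) p$ptros <- NA
        p[, c("model", "pt", "ptros", "fit", "lwr", "upr")]
      }))
      emit(ptab, "model_predictions.csv")
    }

    pairs <- loess_tab <- NULL
    if (ok[["M4"]] && nrow(summaries) >= 2L) {
      pairs <- evaluate_pairs(summaries, fits$M4,
                              if (ok[["M6"]]) fits$M6 else NULL,
                              grid_step = cfg$grid_step)
      emit(pairs, "pair_evaluations.csv")
      curves <- list()
      for (tg in c("prevalence", "predictive")) {
        cv <- tryCatch(loess_summary(pairs, tg, span = cfg$loess_span),
                       error = function(e) NULL)
        if (!is.null(cv)) curves[[tg]] <- cbind(target = tg, cv)
      }
      if (length(curves)) {
        loess_tab <- do.call(rbind, curves)
        emit(loess_tab, "loess_curves.csv")
      }
    }

    calibrators <- lapply(
      stats::setNames(c("prevalence", "predictive"), c("prevalence", "predictive")),
      function(purpose) tryCatch(
        select_calibrators(summaries, purpose, cfg$strata),
        error = function(e) conditionMessage(e)))

    sizes <- "length_mm" %in% names(individuals) &&
      !all(is.na(individuals$length_mm))
    screen <- resid_check <- NULL
    if (sizes) {
      screen <- tryCatch(size_screen(individuals, cfg$q_threshold),
                         error = function(e) NULL)
      if (!is.null(screen)) emit(screen, "size_screen.csv")
      if (ok[["M6"]])
        resid_check <- tryCatch(residual_size_check(fits$M6, individuals),
                                error = function(e) NULL)
    }

    summary_json <- list(
      seed = cfg$seed,
      n_samples = nrow(summaries),
      n_individuals = nrow(individuals),
      models = lapply(fits[ok], function(f) list(
        method = f$method, aic = f$aic, converged = f$converged,
        separation = f$separation,
        r2 = tryCatch(as.list(pseudo_r2(f)), error = function(e) NULL))),
      calibrators = lapply(calibrators, function(p)
        if (inherits(p, "calc_params"))
          list(p_t_tros = p$p_t_tros, p_t_edu = p$p_t_edu,
               provenance = p$provenance)
        else list(error = p)),
      n_pairs = if (is.null(pairs)) 0L else nrow(pairs),
      residual_size_check = resid_check)
    pj <- out("summary.json")
    jsonlite::write_json(summary_json, pj, auto_unbox = TRUE, digits = NA,
                         null = "null", pretty = TRUE)
    written <- c(written, pj)
    paths$summary <- pj

    log_lines <- c(log_lines, sprintf("finished: %s", format(Sys.time(), usetz = TRUE)))
    pl <- out("pipeline.log")
    writeLines(log_lines, pl)
    paths$log <- pl

    list(paths = paths, individuals = individuals, samples = meta,
         summaries = summary_tab, fits = fits[ok], pairs = pairs,
         loess = loess_tab, calibrators = calibrators,
         size_screen = screen, residual_size_check = resid_check)
  }, error = function(e) {
    unlink(written)
    stopf("pipeline failed (partial outputs removed): %s", conditionMessage(e))
  })
  invisible(result)
}
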