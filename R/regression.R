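#' Specification of the six morphotype-test regression models
#'
#' The six binomial logit models linking morphotype frequencies to the
#' taxonomic structure of samples. Models 1--3 were formulated for comparing
#' geographic sets within one region, models 4--6 for the between-zone
#' analysis; structurally they form three pairs:
#'
#' * `M1` (and its between-zone twin) -- T-morphotype indicator regressed on
#'   sample prevalence `ptros`, `set` and their interaction; no random term.
#' * `M4` -- trossulus-genotype indicator regressed on the sample T-morphotype
#'   frequency `pt`, `set` and interaction; no random term. This is the
#'   reference for the "Ptros by PT calculator".
#' * `M2` / `M5` -- T-morphotype indicator regressed on `ptros`, `set`,
#'   `species` and all interactions, with a sample-level random intercept;
#'   captures prevalence drift of the within-species morphotype rates.
#' * `M3` / `M6` -- correct-identification indicator (trossulus shown as T or
#'   edulis shown as E) regressed on `ptros`, `set`, `morphotype` and all
#'   interactions, with a sample-level random intercept; the reference for
#'   the "genotype by morphotype calculator".
#'
#' Factors with fewer than two levels in the data (e.g. `set` in a
#' single-region study) are dropped from the fixed part at fitting time.
#'
#' @param id one of `"M1"` ... `"M6"`.
#' @return Object of class `"model_spec"`.
#' @export
model_spec <- function(id = c("M1", "M2", "M3", "M4", "M5", "M6")) {
  id <- match.arg(id)
  def <- switch(id,
    M1 = list(response = "morph01", fixed = c("ptros", "set"), random = FALSE),
    M2 = list(response = "morph01", fixed = c("ptros", "set", "species"), random = TRUE),
    M3 = list(response = "correct", fixed = c("ptros", "set", "morphotype"), random = TRUE),
    M4 = list(response = "tros01", fixed = c("pt", "set"), random = FALSE),
    M5 = list(response = "morph01", fixed = c("ptros", "set", "species"), random = TRUE),
    M6 = list(response = "correct", fixed = c("ptros", "set", "morphotype"), random = TRUE))
  structure(c(list(id = id), def), class = "model_spec")
}

#' Derive the model frame used by the regression models
#'
#' Adds to the individual-level table the derived columns the models need:
#' the genotype class and indicators (`species`, `tros01`), the morphotype
#' indicator `morph01`, the correctness indicator `correct`, and the
#' per-sample frequencies `ptros` and `pt`. The frequencies are derived
#' empirically from the table itself; when the table already carries a
#' `ptros` or `pt` column (e.g. design values of a simulation), the existing
#' column is kept.
#'
#' @param data individual-level data frame (`sample_id`, `set`, `q`,
#'   `morphotype`).
#' @param threshold q-value classification threshold.
#' @return Data frame with the derived columns appended.
#' @export
prepare_model_frame <- function(data, threshold = 0.5) {
  need <- c("sample_id", "q", "morphotype")
  miss <- setdiff(need, names(data))
  if (length(miss)) stopf("missing column(s): %s", paste(miss, collapse = ", "))
  out <- data
  out$morphotype <- factor(check_morphotype(data$morphotype), levels = c("E", "T"))
  out$species <- factor(classify_genotype(data$q, threshold),
                        levels = c("edulis", "trossulus"))
  out$morph01 <- as.integer(out$morphotype == "T")
  out$tros01 <- as.integer(out$species == "trossulus")
  out$correct <- as.integer(out$tros01 == out$morph01)
  out$sample_id <- factor(out$sample_id)
  if (!"set" %in% names(out)) out$set <- "SIM"
  out$set <- factor(out$set)
  if (!all(c("ptros", "pt") %in% names(out))) {
    freq <- summarize_study(data, threshold)
    if (!"ptros" %in% names(out))
      out$ptros <- freq$ptros[match(as.character(out$sample_id), freq$sample_id)]
    if (!"pt" %in% names(out))
      out$pt <- freq$pt[match(as.character(out$sample_id), freq$sample_id)]
  }
  out
}

fixed_formula_terms <- function(spec, frame) {
  keep <- vapply(spec$fixed, function(v) {
    x <- frame[[v]]
    !is.factor(x) || nlevels(droplevels(x)) > 1L
  }, logical(1))
  terms <- spec$fixed[keep]
  if (!length(terms)) terms <- "1"
  paste(terms, collapse = " * ")
}

#' Fit one of the morphotype-test regression models
#'
#' Fits the binomial logit model described by a [model_spec()] by maximum
#' likelihood: [stats::glm()] for the fixed-effects models, [lme4::glmer()]
#' (Laplace approximation) when a sample-level random intercept is present.
#' Complete separation in a fixed-effects fit triggers a flagged
#' bias-reduced (Firth) refit. A non-converged mixed fit falls back to a
#' fixed-effects fit, with cluster-robust standard errors by sample when the
#' `sandwich` package is available; the `converged` and `method` fields
#' report what happened.
#'
#' @param spec a [model_spec()] or a model id string.
#' @param data individual-level data frame (see [prepare_model_frame()]).
#' @param threshold q-value classification threshold.
#' @return Object of class `"morphotest_fit"` with elements `spec`, `model`,
#'   `coefficients` (term/estimate/se/z/p table), `aic`, `random_variance`,
#'   `converged`, `separation`, `method`, plus the design bookkeeping used by
#'   [predict_with_ci()].
#' @export
fit_model <- function(spec, data, threshold = 0.5) {
  if (is.character(spec)) spec <- model_spec(spec)
  stopifnot(inherits(spec, "model_spec"))
  frame <- prepare_model_frame(data, threshold)
  y <- frame[[spec$response]]
  if (length(unique(y)) < 2L)
    stopf("degenerate response: `%s` is constant in the data", spec$response)
  rhs <- fixed_formula_terms(spec, frame)
  fixed_formula <- stats::as.formula(paste(spec$response, "~", rhs))

  # reject rank-deficient fixed designs up front, naming the aliased columns
  X <- stats::model.matrix(fixed_formula, frame)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stopf("rank-deficient design: aliased term(s) %s",
          paste(aliased, collapse = ", "))
  }

  separation <- FALSE
  method <- if (spec$random) "glmer" else "glm"
  converged <- TRUE
  notes <- character()

  if (!spec$random) {
    sep_warn <- FALSE
    model <- withCallingHandlers(
      stats::glm(fixed_formula, family = stats::binomial(), data = frame),
      warning = function(w) {
        if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
          sep_warn <<- TRUE
        invokeRestart("muffleWarning")
      })
    if (sep_warn && max(abs(stats::coef(model))) > 10) {
      separation <- TRUE
      method <- "firth"
      fr <- firth_glm(X, y)
      beta <- fr$coefficients; vc <- fr$vcov
      aic <- -2 * fr$logLik + 2 * fr$df
      converged <- fr$converged
      model <- fr
    } else {
      beta <- stats::coef(model); vc <- stats::vcov(model)
      aic <- stats::AIC(model)
      converged <- model$converged
    }
    rand_var <- 0
  } else {
    mixed_formula <- stats::as.formula(
      paste(spec$response, "~", rhs, "+ (1 | sample_id)"))
    fit_ok <- TRUE
    model <- withCallingHandlers(
      tryCatch(lme4::glmer(mixed_formula, family = stats::binomial(), data = frame),
               error = function(e) { fit_ok <<- FALSE; e }),
      warning = function(w) {
        msg <- conditionMessage(w)
        if (grepl("failed to converge|Model failed", msg)) fit_ok <<- FALSE
        notes <<- c(notes, msg)
        invokeRestart("muffleWarning")
      },
      message = function(m) invokeRestart("muffleMessage"))
    if (fit_ok && !inherits(model, "error") &&
        length(model@optinfo$conv$lme4) &&
        any(grepl("failed to converge", unlist(model@optinfo$conv$lme4))))
      fit_ok <- FALSE
    if (fit_ok && !inherits(model, "error")) {
      beta <- lme4::fixef(model)
      vc <- as.matrix(stats::vcov(model))
      aic <- stats::AIC(model)
      vcmp <- lme4::VarCorr(model)
      rand_var <- sum(vapply(vcmp, function(m) sum(diag(m)), numeric(1)))
    } else {
      # documented fallback: the random factor was found weak in this system,
      # so a fixed-effects fit with cluster-robust errors stands in
      converged <- FALSE
      method <- "glm_robust"
      model <- suppressWarnings(
        stats::glm(fixed_formula, family = stats::binomial(), data = frame))
      beta <- stats::coef(model)
      vc <- if (requireNamespace("sandwich", quietly = TRUE))
        sandwich::vcovCL(model, cluster = frame$sample_id)
      else stats::vcov(model)
      aic <- stats::AIC(model)
      rand_var <- 0
    }
  }

  se <- sqrt(diag(vc))
  z <- beta / se
  coefs <- data.frame(term = names(beta), estimate = unname(beta),
                      se = unname(se), z = unname(z),
                      p = unname(2 * stats::pnorm(-abs(z))),
                      stringsAsFactors = FALSE)
  mf <- stats::model.frame(fixed_formula, frame)
  trm <- attr(mf, "terms")
  structure(list(spec = spec, model = model, formula = fixed_formula,
                 coefficients = coefs, beta = beta, vcov_fixed = vc,
                 aic = aic, random_variance = rand_var,
                 converged = converged, separation = separation,
                 method = method, notes = notes,
                 fixed_terms = trm,
                 xlevels = stats::.getXlevels(trm, mf),
                 frame = frame),
            class = "morphotest_fit")
}

#' @export
print.morphotest_fit <- function(x, ...) {
  cat(sprintf("Morphotype-test model %s (%s%s), AIC = %.1f\n", x$spec$id,
              x$method,
              if (x$separation) ", separation: bias-reduced" else "", x$aic))
  print(x$coefficients, row.names = FALSE, digits = 3)
  if (x$spec$random)
    cat(sprintf("Sample-level intercept variance: %.4f\n", x$random_variance))
  if (!x$converged) cat("NOTE: primary fit did not converge; see $method\n")
  invisible(x)
}

# Nakagawa-Schielzeth pseudo-R2 pieces, theoretical logit variance pi^2/3.
r2_from_variances <- function(var_fixed, var_random) {
  tot <- var_fixed + var_random + pi^2 / 3
  c(marginal = var_fixed / tot, conditional = (var_fixed + var_random) / tot)
}

#' Marginal and conditional pseudo-R-squared
#'
#' Nakagawa--Schielzeth pseudo-R2 for binomial logit models: the marginal
#' value is the variance of the fixed-effect linear predictor over the total
#' latent variance (fixed + random + the logistic distribution-specific
#' variance \eqn{\pi^2/3}); the conditional value adds the random-intercept
#' variance to the numerator. For fixed-effects models the two coincide.
#'
#' @param fit a converged [fit_model()] result.
#' @return Named numeric vector `c(marginal, conditional)`.
#' @export
pseudo_r2 <- function(fit) {
  stopifnot(inherits(fit, "morphotest_fit"))
  if (!fit$converged)
    stopf("pseudo-R2 requires a converged fit (method was '%s')", fit$method)
  X <- stats::model.matrix(stats::delete.response(fit$fixed_terms), fit$frame,
                           xlev = fit$xlevels)
  var_fixed <- stats::var(drop(X %*% fit$beta))
  r2_from_variances(var_fixed, fit$random_variance)
}

#' Predicted probabilities with Wald confidence intervals
#'
#' Fixed-effects predictions on the probability scale with a Wald interval
#' computed on the linear predictor and transformed by the inverse logit, so
#' the bounds always lie in \[0, 1\]. Numeric predictors outside \[0, 1\]
#' draw a warning (the frequencies the models use are proportions), not a
#' rejection.
#'
#' @param fit a converged [fit_model()] result.
#' @param newdata data frame with the predictor columns of the model.
#' @param level confidence level in \[0, 1\]; `level = 0` degenerates to the
#'   point estimate.
#' @return Data frame `fit`, `lwr`, `upr` (probabilities), plus `eta` and
#'   `se` on the logit scale.
#' @export
predict_with_ci <- function(fit, newdata, level = 0.95) {
  stopifnot(inherits(fit, "morphotest_fit"))
  if (!fit$converged)
    stopf("prediction requires a converged fit (method was '%s')", fit$method)
  check_fraction(level, "level")
  trm <- stats::delete.response(fit$fixed_terms)
  for (v in names(fit$xlevels))
    if (v %in% names(newdata) && !is.factor(newdata[[v]]))
      newdata[[v]] <- factor(newdata[[v]], levels = fit$xlevels[[v]])
  num_vars <- setdiff(all.vars(trm), names(fit$xlevels))
  for (v in intersect(num_vars, names(newdata)))
    if (is.numeric(newdata[[v]]) && any(newdata[[v]] < 0 | newdata[[v]] > 1))
      warnf("predictor `%s` outside [0, 1]: extrapolating beyond the frequency scale", v)
  X <- stats::model.matrix(trm, newdata, xlev = fit$xlevels)
  eta <- drop(X %*% fit$beta)
  se <- sqrt(rowSums((X %*% fit$vcov_fixed) * X))
  zq <- stats::qnorm(1 - (1 - level) / 2)
  data.frame(fit = stats::plogis(eta),
             lwr = stats::plogis(eta - zq * se),
             upr = stats::plogis(eta + zq * se),
             eta = eta, se = se)
}

#' AIC-based test of pooling geographic sets
#'
#' Refits the correctness model (M3 structure) after relabelling the `set`
#' factor according to each candidate partition and compares the fits by
#' AIC; all candidates are fit to the identical response vector, so the AICs
#' are directly comparable. The minimum-AIC partition is selected.
#'
#' @param data individual-level data frame covering at least two sets.
#' @param partitions named list of candidate partitions; each partition is a
#'   list of character vectors of set labels that jointly cover every set in
#'   the data exactly once (e.g. `list("WSBL+BH" = list(c("WS","BL"), "BH"))`).
#' @param threshold q-value classification threshold.
#' @return List with `table` (partition, n_groups, aic), `best` (name of the
#'   minimum-AIC partition) and `best_partition` (its grouping).
#' @export
pooling_test <- function(data, partitions, threshold = 0.5) {
  if (!length(partitions)) stopf("no candidate partitions supplied")
  sets <- unique(as.character(data$set))
  if (is.null(names(partitions)))
    names(partitions) <- vapply(partitions, function(p)
      paste(vapply(p, paste, "", collapse = ""), collapse = "+"), "")
  aics <- numeric(length(partitions))
  for (i in seq_along(partitions)) {
    part <- partitions[[i]]
    members <- unlist(part)
    if (!setequal(members, sets) || anyDuplicated(members))
      stopf("partition '%s' does not cover every set exactly once (sets: %s)",
            names(partitions)[i], paste(sets, collapse = ", "))
    relabel <- data
    map <- unlist(lapply(part, function(g)
      stats::setNames(rep(paste(g, collapse = ""), length(g)), g)))
    relabel$set <- unname(map[as.character(data$set)])
    fit <- fit_model(model_spec("M3"), relabel, threshold)
    aics[i] <- fit$aic
  }
  tab <- data.frame(partition = names(partitions),
                    n_groups = vapply(partitions, length, 0L),
                    aic = aics, stringsAsFactors = FALSE)
  best <- which.min(aics)
  list(table = tab, best = names(partitions)[best],
       best_partition = partitions[[best]])
}
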