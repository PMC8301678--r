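#' Configuration for a synthetic hybrid-zone study
#'
#' Builds the configuration object consumed by [generate_individual()],
#' [generate_sample()] and [generate_study()]. The generator emulates the
#' statistical structure of genotyped mussel samples from a contact zone
#' between *Mytilus edulis* and *M. trossulus*: per-individual admixture
#' proportions `q` (the estimated fraction of *trossulus* genes), a binary
#' shell morphotype (T = uninterrupted prismatic strip present, E = absent)
#' whose probability depends on the species and, optionally, on the sample
#' prevalence, and a log-normal shell length.
#'
#' @details
#' The `q` distribution is a three-component mixture. Purebred *edulis* draw
#' `q = 0.2 * Beta(1, purebred_concentration)` (all mass below 0.2), purebred
#' *trossulus* the mirror image above 0.8, and putative hybrids draw
#' `q = 0.2 + 0.6 * Beta(1.2, 1.2)` (a flat-ish spread across (0.2, 0.8)).
#' Two named regimes set the hybrid (intermediate) fraction: `"bimodal"`
#' (10\% intermediates, as in most contact zones) and `"flattened"` (35\%,
#' as in zones with extensive hybridization); `intermediate_fraction`
#' overrides the regime value.
#'
#' The morphotype model gives each species a logit-scale intercept and an
#' optional logit-scale slope on the sample prevalence `Ptros`, so that
#' \eqn{P(T) = \mathrm{logit}^{-1}(a_{sp} + b_{sp} \cdot Ptros)}. Hybrids use
#' the midpoint of the two species' intercepts and slopes. The defaults place
#' the test's sensitivity `P(T|tros)` at 0.74 and false-positive rate
#' `P(T|edu)` at 0.04 for an equal mixture (`Ptros = 0.5`), with a moderate
#' positive drift of both rates with prevalence on the logit scale.
#'
#' @param n_samples number of samples in a study.
#' @param sample_size_range integer pair; per-sample sizes are drawn uniformly
#'   within it (default 18--173 individuals).
#' @param prevalence_grid vector of true prevalences (`Ptros` values) in
#'   \[0, 1\], one sample per grid point.
#' @param q_regime `"bimodal"` or `"flattened"`; sets the default
#'   intermediate (hybrid) fraction.
#' @param intermediate_fraction fraction of individuals drawn from the hybrid
#'   `q` component in an equal species mixture; overrides `q_regime` when
#'   supplied.
#' @param hybrid_profile `"unimodal"` (default) scales the hybrid fraction of
#'   a sample as `4 * p * (1 - p)` of `intermediate_fraction`, so hybrids
#'   concentrate where the species co-occur and vanish in pure populations;
#'   `"constant"` applies `intermediate_fraction` at every prevalence.
#' @param purebred_concentration second shape parameter of the scaled Beta
#'   component for purebreds; larger values concentrate `q` nearer 0 (or 1).
#' @param morph_model list with numeric vectors `intercept` and `slope`, each
#'   named `edulis` and `trossulus`, on the logit scale.
#' @param size_model list with `meanlog` and `sdlog` of the log-normal shell
#'   length (mm) and `morph_effect`, a logit-per-mm shift of the T-morphotype
#'   probability per mm of length above the median length (default 0: no
#'   systematic morphotype--size association).
#' @param seed integer; single global seed governing all draws through
#'   per-sample substreams.
#'
#' @return An object of class `"sim_config"`.
#' @seealso [generate_study()]
#' @export
#' @examples
#' cfg <- sim_config(n_samples = 6, seed = 42)
#' study <- generate_study(cfg)
#' head(study$individuals)
sim_config <- function(n_samples = 36L,
                       sample_size_range = c(18L, 173L),
                       prevalence_grid = seq(0, 1, length.out = n_samples),
                       q_regime = c("bimodal", "flattened"),
                       intermediate_fraction = NULL,
                       hybrid_profile = c("unimodal", "constant"),
                       purebred_concentration = 4,
                       morph_model = list(
                         intercept = c(edulis = stats::qlogis(0.04) - 0.75,
                                       trossulus = stats::qlogis(0.74) - 0.75),
                         slope = c(edulis = 1.5, trossulus = 1.5)),
                       size_model = list(meanlog = log(40), sdlog = 0.25,
                                         morph_effect = 0),
                       seed = 1L) {
  q_regime <- match.arg(q_regime)
  hybrid_profile <- match.arg(hybrid_profile)
  if (is.null(intermediate_fraction))
    intermediate_fraction <- switch(q_regime, bimodal = 0.10, flattened = 0.35)
  check_fraction(intermediate_fraction, "intermediate_fraction")
  check_fraction(prevalence_grid, "prevalence_grid")
  if (length(prevalence_grid) < 1L) stopf("`prevalence_grid` must be non-empty")
  if (length(sample_size_range) != 2L || any(sample_size_range < 1) ||
      sample_size_range[1] > sample_size_range[2])
    stopf("`sample_size_range` must be an increasing pair of counts >= 1")
  for (part in c("intercept", "slope")) {
    v <- morph_model[[part]]
    if (!is.numeric(v) || !all(c("edulis", "trossulus") %in% names(v)))
      stopf("`morph_model$%s` needs named entries 'edulis' and 'trossulus'", part)
  }
  if (!is.numeric(size_model$sdlog) || size_model$sdlog < 0)
    stopf("`size_model$sdlog` must be non-negative")
  structure(list(n_samples = as.integer(length(prevalence_grid)),
                 sample_size_range = as.integer(sample_size_range),
                 prevalence_grid = as.numeric(prevalence_grid),
                 q_regime = q_regime,
                 intermediate_fraction = intermediate_fraction,
                 hybrid_profile = hybrid_profile,
                 purebred_concentration = purebred_concentration,
                 morph_model = morph_model,
                 size_model = size_model,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic hybrid-zone study configuration\n")
  cat(sprintf("  samples: %d, sizes %d-%d, q regime '%s' (%.0f%% intermediates)\n",
              x$n_samples, x$sample_size_range[1], x$sample_size_range[2],
              x$q_regime, 100 * x$intermediate_fraction))
  cat(sprintf("  morphotype logits: edulis %.2f + %.2f Ptros, trossulus %.2f + %.2f Ptros\n",
              x$morph_model$intercept[["edulis"]], x$morph_model$slope[["edulis"]],
              x$morph_model$intercept[["trossulus"]], x$morph_model$slope[["trossulus"]]))
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}

# Species mixture weights for a target prevalence. Hybrids sit symmetrically
# around q = 0.5, so they contribute half their mass to the q > 0.5 class.
species_weights <- function(ptros, h) {
  if (h >= 1) return(c(edulis = 0, trossulus = 0, hybrid = 1))
  pi_t <- clamp01((ptros - 0.5 * h) / (1 - h))
  c(edulis = (1 - h) * (1 - pi_t), trossulus = (1 - h) * pi_t, hybrid = h)
}

draw_q <- function(species, cfg) {
  conc <- cfg$purebred_concentration
  n <- length(species)
  q <- numeric(n)
  ed <- species == "edulis"; tr <- species == "trossulus"; hy <- species == "hybrid"
  q[ed] <- 0.2 * stats::rbeta(sum(ed), 1, conc)
  q[tr] <- 1 - 0.2 * stats::rbeta(sum(tr), 1, conc)
  q[hy] <- 0.2 + 0.6 * stats::rbeta(sum(hy), 1.2, 1.2)
  q
}

morph_linpred <- function(species, ptros, cfg) {
  a <- cfg$morph_model$intercept
  b <- cfg$morph_model$slope
  # hybrids: logistic midpoint between the species' coefficients
  a <- c(a, hybrid = unname(mean(a[c("edulis", "trossulus")])))
  b <- c(b, hybrid = unname(mean(b[c("edulis", "trossulus")])))
  a[species] + b[species] * ptros
}

draw_individuals <- function(species, ptros, cfg, sample_id, set) {
  n <- length(species)
  q <- draw_q(species, cfg)
  len <- stats::rlnorm(n, cfg$size_model$meanlog, cfg$size_model$sdlog)
  eta <- morph_linpred(species, ptros, cfg) +
    (cfg$size_model$morph_effect %||% 0) * (len - exp(cfg$size_model$meanlog))
  morph <- ifelse(stats::runif(n) < stats::plogis(eta), "T", "E")
  data.frame(sample_id = sample_id, set = set, q = q,
             morphotype = morph, length_mm = len,
             stringsAsFactors = FALSE)
}

#' Generate one synthetic individual
#'
#' Draws a single mussel of a given species class from the configured
#' mixture: its admixture proportion `q`, morphotype and shell length.
#'
#' @param species one of `"edulis"`, `"trossulus"`, `"hybrid"`.
#' @param ptros prevalence of the population the individual is imagined to
#'   come from (enters the morphotype model when slopes are non-zero).
#' @param cfg a [sim_config()].
#' @param stream optional RNG stream (class `morphotest_stream`); when `NULL`
#'   a fresh stream is derived from `cfg$seed`.
#' @param sample_id,set labels stored on the returned row.
#' @return One-row data frame with columns `sample_id`, `set`, `q`,
#'   `morphotype`, `length_mm`.
#' @export
generate_individual <- function(species, ptros, cfg, stream = NULL,
                                sample_id = "S1", set = "SIM") {
  if (!is.character(species) || length(species) != 1L ||
      !species %in% c("edulis", "trossulus", "hybrid"))
    stopf("unknown species label '%s' (expected edulis, trossulus or hybrid)",
          as.character(species)[1])
  check_fraction(ptros, "ptros")
  stopifnot(inherits(cfg, "sim_config"))
  if (is.null(stream)) stream <- new_stream(cfg$seed)
  stream_eval(stream, draw_individuals(species, ptros, cfg, sample_id, set))
}

#' Generate one synthetic sample
#'
#' Draws `n` individuals whose species classes follow the mixture implied by
#' the target prevalence `ptros` and the configured intermediate fraction;
#' the expected fraction of individuals with `q > 0.5` equals `ptros` (up to
#' the hybrid-mass correction at extreme prevalences, see [sim_config()]).
#'
#' @inheritParams generate_individual
#' @param ptros target prevalence in \[0, 1\].
#' @param n number of individuals (>= 1).
#' @return Data frame of `n` individuals with attribute `true_ptros`.
#' @export
generate_sample <- function(ptros, n, cfg, stream = NULL,
                            sample_id = "S1", set = "SIM") {
  check_fraction(ptros, "ptros")
  if (!is.numeric(n) || length(n) != 1L || n < 1) stopf("`n` must be >= 1")
  stopifnot(inherits(cfg, "sim_config"))
  if (is.null(stream)) stream <- new_stream(cfg$seed)
  h <- cfg$intermediate_fraction
  if ((cfg$hybrid_profile %||% "constant") == "unimodal")
    h <- h * 4 * ptros * (1 - ptros)
  w <- species_weights(ptros, h)
  out <- stream_eval(stream, {
    species <- sample(names(w), size = n, replace = TRUE, prob = w)
    draw_individuals(species, ptros, cfg, sample_id, set)
  })
  attr(out, "true_ptros") <- ptros
  out
}

#' Generate a synthetic study spanning the prevalence grid
#'
#' Produces one sample per value of `cfg$prevalence_grid`, with sizes drawn
#' uniformly within `cfg$sample_size_range`. Sample `i` draws from RNG
#' substream `i` of the global seed, so the study is reproducible as a whole
#' and any sample can be regenerated individually.
#'
#' @param cfg a [sim_config()].
#' @param set label recorded for all samples.
#' @return Object of class `"sim_study"`: a list with `individuals` (one row
#'   per mussel), `samples` (per-sample metadata: `sample_id`, `set`,
#'   `salinity_class`, `true_ptros`, `n`) and `config`.
#' @export
generate_study <- function(cfg, set = "SIM") {
  stopifnot(inherits(cfg, "sim_config"))
  grid <- cfg$prevalence_grid
  if (length(grid) < 1L) stopf("prevalence grid is empty")
  ids <- sprintf("S%03d", seq_along(grid))
  pieces <- vector("list", length(grid))
  sizes <- integer(length(grid))
  for (i in seq_along(grid)) {
    stream <- new_stream(cfg$seed, substream = i)
    rng <- cfg$sample_size_range
    sizes[i] <- stream_eval(stream,
      rng[1] + sample.int(rng[2] - rng[1] + 1L, 1L) - 1L)
    pieces[[i]] <- generate_sample(grid[i], sizes[i], cfg, stream = stream,
                                   sample_id = ids[i], set = set)
  }
  individuals <- do.call(rbind, pieces)
  rownames(individuals) <- NULL
  samples <- data.frame(sample_id = ids, set = set,
                        salinity_class = NA_character_,
                        true_ptros = grid, n = sizes,
                        stringsAsFactors = FALSE)
  structure(list(individuals = individuals, samples = samples, config = cfg),
            class = "sim_study")
}

#' Study conditions emulating the White Sea / brackish Barents Sea system
#'
#' A [sim_config()] preset reproducing the salient features of the reference
#' contact zone on which the calibration-pair experiment was developed:
#' 36 samples; an *edulis*-dominated, right-skewed distribution of sample
#' prevalences (trossulus-dominated samples scarce, with representatives at
#' both extremes); a pronouncedly bimodal q distribution (about 13\% pooled
#' intermediates, concentrated in mixed samples); a morphotype test with
#' sensitivity 0.74 and false-positive rate 0.04 at an equal mixture; and a
#' positive prevalence drift of both within-class T-frequencies, steeper in
#' the *edulis* class -- where elevated T-frequencies, partly carried by
#' introgressed genotypes, are what degrades the test.
#'
#' @param seed integer seed.
#' @param n_samples number of samples (default 36).
#' @param ... further arguments passed to [sim_config()].
#' @return A `"sim_config"` object.
#' @export
wsbl_config <- function(seed = 1L, n_samples = 36L, ...) {
  sim_config(
    n_samples = n_samples,
    prevalence_grid = stats::qbeta(stats::ppoints(n_samples), 0.8, 1.6),
    intermediate_fraction = 0.2,
    hybrid_profile = "unimodal",
    morph_model = list(
      intercept = c(edulis = stats::qlogis(0.04) - 1.5,
                    trossulus = stats::qlogis(0.74) - 0.5),
      slope = c(edulis = 3, trossulus = 1)),
    seed = seed, ...)
}

#' @export
print.sim_study <- function(x, ...) {
  cat(sprintf("Synthetic hybrid-zone study: %d samples, %d individuals\n",
              nrow(x$samples), nrow(x$individuals)))
  invisible(x)
}
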