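#' The packaged 20-sample rheology + sensory dataset
#'
#' Returns the calibration dataset shipped with the package: 20 liquid
#' samples -- 8 custom-made bouillons (set1), 6 commercial bouillons
#' (set2) and 6 xanthan-gum solutions spanning higher stresses (set3) --
#' each with fitted power-law parameters `(kappa, n)` and the panel
#' thickness score (mean, SEM) on the 0-15 category scale. Set-3 scores
#' are shipped already converted to that scale.
#'
#' @return A [as_sensory_samples()] data frame with 20 rows.
#' @export
#' @examples
#' tab <- table1_samples()
#' table(tab$set_label)
table1_samples <- function() {
  path <- system.file("extdata", "table1_sensory_rheology.csv",
                      package = "mouthfeel", mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  as_sensory_samples(df)
}

#' Specification for synthetic test data
#'
#' One object collects everything the synthetic generators need; a fixed
#' `seed` makes every generated artefact byte-identical across runs. All
#' randomness flows from `seed` through a documented splitting rule: the
#' flow-curve generator seeds the RNG with `seed`, the panel generator
#' with `seed + 1`, so the two streams never alias for consecutive seeds
#' used in a loop of replicates spaced >= 2 apart (tests use stride 10).
#'
#' @param seed Integer RNG seed.
#' @param rates Shear-rate grid for flow curves, 1/s (default 30
#'   log-spaced points over 0.1-1000, a typical rheometer sweep).
#' @param noise_sd_rel Relative (lognormal sdlog) noise on stresses; >= 0.
#' @param n_panelists Panelists per product (default 12, the size of a
#'   trained descriptive panel).
#' @param panel_noise_sd Additive score noise per panelist, score units
#'   (default 0.8, matching the shipped SEM * sqrt(n) magnitudes).
#' @param true_law Named list describing the ground-truth psychophysical
#'   law: `list(law = "weber_fechner", a =, b =)` or
#'   `list(law = "stevens", c =, k =, m =)`.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(seed = 1L,
                           rates = 10^seq(-1, 3, length.out = 30),
                           noise_sd_rel = 0.05,
                           n_panelists = 12L,
                           panel_noise_sd = 0.8,
                           true_law = list(law = "weber_fechner",
                                           a = 1, b = 4)) {
  stopifnot(is.numeric(seed), length(seed) == 1,
            is.numeric(rates), all(rates > 0), !is.unsorted(rates),
            noise_sd_rel >= 0, n_panelists >= 1, panel_noise_sd >= 0,
            is.list(true_law),
            true_law$law %in% c("weber_fechner", "stevens"))
  structure(list(seed = as.integer(seed), rates = rates,
                 noise_sd_rel = noise_sd_rel,
                 n_panelists = as.integer(n_panelists),
                 panel_noise_sd = panel_noise_sd, true_law = true_law),
            class = "synthetic_spec")
}

#' Generate a synthetic flow curve with known ground truth
#'
#' Evaluates the exact power law of `fluid` on `spec$rates` and applies
#' multiplicative lognormal noise with sdlog `spec$noise_sd_rel`
#' (relative error is the natural rheometer error model; zero noise gives
#' the exact curve). Deterministic under a fixed `spec$seed`.
#'
#' @param fluid A [power_law_fluid()] (the ground truth).
#' @param spec A [synthetic_spec()].
#' @return A [flow_curve()].
#' @export
generate_flow_curve <- function(fluid, spec) {
  stopifnot(inherits(fluid, "power_law_fluid"),
            inherits(spec, "synthetic_spec"))
  sigma <- stress_at_rate(fluid, spec$rates)
  if (spec$noise_sd_rel > 0) {
    old <- .save_rng()
    on.exit(.restore_rng(old))
    set.seed(spec$seed)
    sigma <- sigma * exp(stats::rnorm(length(sigma), 0,
                                      spec$noise_sd_rel))
  }
  flow_curve(spec$rates, sigma, label = fluid$label)
}

#' Generate synthetic raw panel scores with known ground truth
#'
#' For each fluid, computes the model tongue stress at the assessment
#' time, applies the ground-truth psychophysical law of `spec$true_law`,
#' adds independent normal panelist noise of sd `spec$panel_noise_sd`,
#' and clamps every score to the 0-15 category scale. Deterministic under
#' a fixed `spec$seed` (panel stream = `seed + 1`).
#'
#' @param fluids A list of [power_law_fluid()] objects (the products).
#' @param params An [oral_parameters()] object.
#' @param spec A [synthetic_spec()].
#' @param variant Equation variant passed to [tongue_stress()].
#' @return A data frame with one row per (product, panelist):
#'   columns `product` (index), `panelist`, `stress`, `true_score`,
#'   `score`.
#' @export
generate_panel_scores <- function(fluids, params, spec,
                                  variant = c("main_text", "derivation")) {
  variant <- match.arg(variant)
  stopifnot(is.list(fluids), length(fluids) >= 1,
            inherits(spec, "synthetic_spec"))
  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(spec$seed + 1L)
  law <- spec$true_law
  out <- lapply(seq_along(fluids), function(i) {
    fl <- fluids[[i]]
    stopifnot(inherits(fl, "power_law_fluid"))
    sigma <- tongue_stress(fl, params, params$t_assess, variant)
    truth <- .eval_law(law$law,
                       unlist(law[setdiff(names(law), "law")]), sigma)
    noise <- if (spec$panel_noise_sd > 0)
      stats::rnorm(spec$n_panelists, 0, spec$panel_noise_sd) else
        numeric(spec$n_panelists)
    data.frame(product = i, panelist = seq_len(spec$n_panelists),
               stress = sigma, true_score = truth,
               score = pmin(pmax(truth + noise, 0), 15))
  })
  do.call(rbind, out)
}

.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
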