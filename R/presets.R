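# Named serum population presets that parameterize the synthetic-data
# generators. Observed-mode presets carry the published peak means/SDs and
# component weights directly; the mechanistic preset carries latent chain
# masses plus the two population parameters f7 (fraction of beta-containing
# complexes with 7 alpha chains) and q (ProS occupancy).

#' Construct a serum population preset
#'
#' @param mode `"observed"` (components given directly as means/SDs/weights)
#'   or `"mechanistic"` (components derived from chain masses, `f7` and `q`).
#' @param components In observed mode, a data.frame with columns `species`,
#'   `mean` (kDa), `sd` (kDa), `weight` (summing to 1).
#' @param f7 Fraction of beta-containing complexes carrying 7 alpha chains.
#' @param q ProS occupancy of beta-containing complexes.
#' @param chain_masses Named chain masses (kDa), mechanistic mode.
#' @param sd_complex Per-species mass heterogeneity SD for complexes (kDa).
#' @param sd_pros Mass SD of free ProS (kDa).
#' @param n_events Default number of events to generate.
#' @param seed Default random seed.
#' @param name Optional preset name.
#' @return An object of class `serum_preset`.
#' @export
serum_preset <- function(mode = c("observed", "mechanistic"),
                         components = NULL, f7 = 0.55, q = 0.68,
                         chain_masses = mechanistic_chain_masses(),
                         sd_complex = 20, sd_pros = 6,
                         n_events = 5000L, seed = 42L, name = NULL) {
  mode <- match.arg(mode)
  stopifnot(f7 >= 0, f7 <= 1, q >= 0, q <= 1, n_events >= 1,
            sd_complex > 0, sd_pros > 0)
  if (mode == "observed") {
    stopifnot(is.data.frame(components),
              all(c("species", "mean", "sd", "weight") %in% names(components)))
    if (any(components$mean <= 0) || any(components$sd <= 0))
      stop("component means and SDs must be positive")
    if (abs(sum(components$weight) - 1) > 1e-8)
      stop("observed-mode component weights must sum to 1")
  } else {
    stopifnot(all(c("alpha", "beta", "pros") %in% names(chain_masses)),
              all(chain_masses > 0))
    components <- mechanistic_components(f7, q, chain_masses, sd_complex)
  }
  structure(list(mode = mode, components = components, f7 = f7, q = q,
                 chain_masses = chain_masses, sd_complex = sd_complex,
                 sd_pros = sd_pros, n_events = as.integer(n_events),
                 seed = as.integer(seed), name = name),
            class = "serum_preset")
}

# Latent native species table under the mechanistic model.
mechanistic_components <- function(f7, q, cm, sd_complex) {
  species <- data.frame(
    species = c("a7b1+ProS", "a6b1+ProS", "a7b1", "a6b1"),
    n_alpha = c(7L, 6L, 7L, 6L),
    has_pros = c(TRUE, TRUE, FALSE, FALSE),
    weight = c(f7 * q, (1 - f7) * q, f7 * (1 - q), (1 - f7) * (1 - q)))
  species$mean <- species$n_alpha * cm[["alpha"]] + cm[["beta"]] +
    ifelse(species$has_pros, cm[["pros"]], 0)
  species$sd <- sd_complex
  species[species$weight > 0, , drop = FALSE]
}

#' Named presets for the serum C4BP populations
#'
#' * `SERUM-CDMS-NATIVE`: observed mode; three native complex populations at
#'   633/553/481 kDa (SD 22/20/20) with weights 0.374/0.482/0.144 (the
#'   weights implied by f7 = 0.55, q = 0.68 under the occupancy algebra).
#' * `SERUM-CDMS-ACID`: observed mode; acid-dissociated populations at
#'   551/478 kDa complexes (55:45 among complexes) plus free ProS at
#'   80 kDa (SD 6); event weights follow from every ProS-bound particle
#'   splitting into one complex and one free-ProS event at q = 0.68.
#' * `SERUM-MP-NATIVE`: observed mode; MP masses 630/553/487 kDa plus a
#'   small (5%) free-ProS population at 68 kDa (SD 9).
#' * `MECHANISTIC`: latent particle population from chain masses
#'   (alpha 72.9, beta 40.7, ProS 79.8 kDa), f7 = 0.55, q = 0.68,
#'   per-species SD 20 kDa.
#'
#' @param name Preset name (see above).
#' @param n_events,seed Defaults stored on the preset.
#' @param ... Passed on to [serum_preset()] (e.g. `f7`, `q` for
#'   `MECHANISTIC`).
#' @return A [serum_preset()].
#' @export
named_preset <- function(name = c("SERUM-CDMS-NATIVE", "SERUM-CDMS-ACID",
                                  "SERUM-MP-NATIVE", "MECHANISTIC"),
                         n_events = 5000L, seed = 42L, ...) {
  name <- match.arg(name)
  if (name == "SERUM-CDMS-NATIVE") {
    comp <- data.frame(
      species = c("a7b1+ProS", "a7b1|a6b1+ProS", "a6b1"),
      mean = c(633, 553, 481), sd = c(22, 20, 20),
      weight = c(0.374, 0.482, 0.144))
    serum_preset("observed", comp, n_events = n_events, seed = seed,
                 name = name, ...)
  } else if (name == "SERUM-CDMS-ACID") {
    q <- 0.68
    w_complex <- c(0.55, 0.45) / (1 + q)
    comp <- data.frame(
      species = c("a7b1", "a6b1", "ProS"),
      mean = c(551, 478, 80), sd = c(22, 23, 6),
      weight = c(w_complex, q / (1 + q)))
    serum_preset("observed", comp, q = q, n_events = n_events, seed = seed,
                 name = name, ...)
  } else if (name == "SERUM-MP-NATIVE") {
    w_pros <- 0.05
    comp <- data.frame(
      species = c("a7b1+ProS", "a7b1|a6b1+ProS", "a6b1", "ProS"),
      mean = c(630, 553, 487, 68), sd = c(29, 22, 22, 9),
      weight = c((1 - w_pros) * c(0.374, 0.482, 0.144), w_pros))
    serum_preset("observed", comp, n_events = n_events, seed = seed,
                 name = name, ...)
  } else {
    serum_preset("mechanistic", n_events = n_events, seed = seed,
                 name = name, ...)
  }
}

#' @export
print.serum_preset <- function(x, ...) {
  cat(sprintf("<serum preset%s> mode=%s, n_events=%d, seed=%d\n",
              if (!is.null(x$name)) paste0(" ", x$name) else "",
              x$mode, x$n_events, x$seed))
  if (x$mode == "mechanistic")
    cat(sprintf("  f7=%.2f q=%.2f chains: alpha=%.1f beta=%.1f ProS=%.1f kDa\n",
                x$f7, x$q, x$chain_masses[["alpha"]],
                x$chain_masses[["beta"]], x$chain_masses[["pros"]]))
  print(x$components, row.names = FALSE)
  invisible(x)
}
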