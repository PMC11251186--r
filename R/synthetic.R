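# Synthetic-data generators: every input the pipeline consumes, generated
# with the statistical structure the analysis assumes (ion-level CDMS
# events, MP contrasts with calibrant block, glycopeptide PSM tables,
# cross-link fixtures with a coordinate model, longitudinal plasma LFQ
# cohorts with a reference panel, and SEC elution profiles).

#' CDMS charge model parameters
#'
#' Mean charge scales with the square root of mass (Rayleigh-limit-like),
#' z-bar = c * sqrt(mass in Da), with Gaussian charge spread `sd_z` and
#' Gaussian noise `sd_I` on the normalized single-ion intensity
#' (intensity = z / factor_k + noise).
#'
#' @param c Charge-scaling coefficient (charges per sqrt(Da)).
#' @param sd_z Charge SD (charges).
#' @param factor_k Charges per unit normalized intensity.
#' @param sd_I Intensity noise SD (normalized-intensity units).
#' @return A list of class `charge_model`.
#' @export
charge_model <- function(c = 0.1, sd_z = 2, factor_k = 14.713, sd_I = 0.05) {
  stopifnot(c > 0, sd_z >= 0, factor_k > 0, sd_I >= 0)
  structure(list(c = c, sd_z = sd_z, factor_k = factor_k, sd_I = sd_I),
            class = "charge_model")
}

.PROTON_DA <- 1.007276

# Draw latent particles (species + true mass, kDa) from a preset.
# Assumes the RNG state has been set by the caller.
draw_particles <- function(preset, n) {
  stopifnot(inherits(preset, "serum_preset"), n >= 1)
  comp <- preset$components
  idx <- sample.int(nrow(comp), n, replace = TRUE, prob = comp$weight)
  mass <- stats::rnorm(n, comp$mean[idx], comp$sd[idx])
  # truncate > 0 (redraw; means are tens of SDs above zero)
  while (any(bad <- mass <= 0))
    mass[bad] <- stats::rnorm(sum(bad), comp$mean[idx][bad], comp$sd[idx][bad])
  out <- data.frame(species = comp$species[idx], mass = mass)
  out$has_pros <- if (preset$mode == "mechanistic")
    comp$has_pros[idx] else grepl("ProS", comp$species[idx], fixed = TRUE)
  out
}

# Turn true particle masses into ion events under a charge model.
ionize <- function(particles, charge) {
  n <- nrow(particles)
  mass_da <- particles$mass * 1000
  zbar <- charge$c * sqrt(mass_da)
  z <- pmax(1L, as.integer(floor(zbar + stats::rnorm(n, 0, charge$sd_z) + 0.5)))
  mz <- (mass_da + z * .PROTON_DA) / z
  intensity <- z / charge$factor_k + stats::rnorm(n, 0, charge$sd_I)
  data.frame(mz = mz, intensity_norm = pmax(intensity, 1e-9),
             true_mass = particles$mass, true_charge = z,
             true_species = particles$species,
             true_has_pros = particles$has_pros)
}

#' Generate synthetic CDMS single-ion events
#'
#' Draws particles from the preset population, assigns each an integer
#' charge from the charge model, and emits (m/z, normalized intensity)
#' pairs: m/z = (mass_Da + z * 1.007276) / z, intensity = z / factor_k +
#' noise. Deterministic given `seed`.
#'
#' @param preset A [serum_preset()] or preset name for [named_preset()].
#' @param n_events Number of ion events.
#' @param seed Random seed.
#' @param charge A [charge_model()].
#' @return data.frame with columns `mz`, `intensity_norm` plus ground-truth
#'   columns `true_mass` (kDa), `true_charge`, `true_species`,
#'   `true_has_pros`.
#' @export
gen_cdms_events <- function(preset, n_events = preset$n_events,
                            seed = preset$seed, charge = charge_model()) {
  if (is.character(preset)) preset <- named_preset(preset)
  stopifnot(inherits(preset, "serum_preset"))
  if (n_events < 1) stop("n_events must be >= 1")
  set.seed(seed)
  ionize(draw_particles(preset, n_events), charge)
}

#' Generate acid-dissociated CDMS events from a mechanistic preset
#'
#' Draws the same latent native particle population as [gen_cdms_events()],
#' then dissociates: every ProS-bound particle is split into its complex
#' (particle mass minus the ProS chain mass) and one free-ProS event drawn
#' around the ProS chain mass. A detection-efficiency parameter thins the
#' low-mass free-ProS events (default 1, all detected).
#'
#' @inheritParams gen_cdms_events
#' @param pros_detect Detection efficiency for free-ProS events in (0, 1].
#' @return data.frame as in [gen_cdms_events()]; one row per detected event
#'   (more rows than `n_events` when particles dissociate).
#' @export
gen_acidified <- function(preset, n_events = preset$n_events,
                          seed = preset$seed, charge = charge_model(),
                          pros_detect = 1.0) {
  if (is.character(preset)) preset <- named_preset(preset)
  stopifnot(inherits(preset, "serum_preset"))
  if (preset$mode != "mechanistic")
    stop("gen_acidified requires a mechanistic preset (latent composition)")
  stopifnot(pros_detect > 0, pros_detect <= 1)
  set.seed(seed)
  part <- draw_particles(preset, n_events)
  m_pros <- preset$chain_masses[["pros"]]
  bound <- part$has_pros
  complexes <- part
  complexes$mass[bound] <- complexes$mass[bound] - m_pros
  complexes$species[bound] <- sub("\\+ProS$", "", complexes$species[bound])
  complexes$has_pros <- FALSE
  n_free <- sum(bound)
  free <- data.frame(species = character(0), mass = numeric(0),
                     has_pros = logical(0))
  if (n_free > 0) {
    fm <- stats::rnorm(n_free, m_pros, preset$sd_pros)
    while (any(bad <- fm <= 0))
      fm[bad] <- stats::rnorm(sum(bad), m_pros, preset$sd_pros)
    keep <- stats::runif(n_free) <= pros_detect
    free <- data.frame(species = "ProS", mass = fm,
                       has_pros = FALSE)[keep, , drop = FALSE]
  }
  ionize(rbind(complexes, free), charge)
}

#' Generate synthetic mass photometry events
#'
#' Ratiometric contrast is linear in mass: contrast = slope * mass +
#' intercept + noise. A calibrant block holds replicate landing events at
#' exactly the calibrant masses (default standard mixture 73/149/483/800
#' kDa).
#'
#' @inheritParams gen_cdms_events
#' @param slope Contrast per kDa (must be > 0).
#' @param intercept Contrast offset.
#' @param noise_kda Optical measurement noise expressed in kDa (converted
#'   to contrast units via the slope).
#' @param include_calibrants Emit the calibrant block?
#' @param calibrant_masses Calibrant masses (kDa).
#' @param n_per_calibrant Landing events per calibrant.
#' @return List with `events` (data.frame: `contrast`, `true_mass`,
#'   `true_species`) and `calibrants` (data.frame: `calibrant_mass`,
#'   `contrast`; empty when `include_calibrants = FALSE`).
#' @export
gen_mp_events <- function(preset, n_events = preset$n_events,
                          seed = preset$seed, slope = 2e-5,
                          intercept = 1e-4, noise_kda = 5,
                          include_calibrants = TRUE,
                          calibrant_masses = c(73, 149, 483, 800),
                          n_per_calibrant = 200L) {
  if (is.character(preset)) preset <- named_preset(preset)
  stopifnot(inherits(preset, "serum_preset"))
  if (slope <= 0) stop("slope must be positive")
  set.seed(seed)
  part <- draw_particles(preset, n_events)
  contrast <- slope * part$mass + intercept +
    stats::rnorm(n_events, 0, slope * noise_kda)
  events <- data.frame(contrast = contrast, true_mass = part$mass,
                       true_species = part$species)
  calibrants <- data.frame(calibrant_mass = numeric(0), contrast = numeric(0))
  if (include_calibrants) {
    cm <- rep(calibrant_masses, each = n_per_calibrant)
    calibrants <- data.frame(
      calibrant_mass = cm,
      contrast = slope * cm + intercept +
        stats::rnorm(length(cm), 0, slope * noise_kda))
  }
  list(events = events, calibrants = calibrants,
       truth = list(slope = slope, intercept = intercept))
}

#' Default N-glycosylation site table
#'
#' The eleven serum C4BP/ProS N-sites (three C4BPa: N221/N506/N528; five
#' C4BPb: N64/N71/N98/N117/N154; three ProS: N499/N509/N530) with a
#' categorical glycoform distribution per site. Complex biantennary
#' mono-/di-sialylated compositions dominate everywhere except ProS N509,
#' which carries mostly triantennary di-/tri-sialylated glycans. Sites
#' C4BPa N221/N528 and C4BPb N71 have elevated unoccupied probability.
#'
#' @return data.frame with columns `protein`, `site`, `p_unoccupied`, and a
#'   list-column `glycoforms` (named probability vectors over composition
#'   labels, conditional on occupancy).
#' @export
default_glyco_sites <- function() {
  bi <- c("HexNAc4Hex5NeuAc2" = 0.45, "HexNAc4Hex5NeuAc1" = 0.30,
          "HexNAc4Hex5" = 0.08, "HexNAc5Hex6NeuAc2" = 0.07,
          "HexNAc4Hex5dHex1NeuAc1" = 0.10)
  tri <- c("HexNAc5Hex6NeuAc3" = 0.40, "HexNAc5Hex6NeuAc2" = 0.33,
           "HexNAc4Hex5NeuAc2" = 0.15, "HexNAc5Hex6NeuAc1" = 0.12)
  tab <- data.frame(
    protein = c(rep("C4BPa", 3), rep("C4BPb", 5), rep("ProS", 3)),
    site = c(221L, 506L, 528L, 64L, 71L, 98L, 117L, 154L,
             499L, 509L, 530L))
  tab$p_unoccupied <- ifelse(
    (tab$protein == "C4BPa" & tab$site %in% c(221L, 528L)) |
      (tab$protein == "C4BPb" & tab$site == 71L), 0.25, 0.05)
  tab$glycoforms <- rep(list(bi), nrow(tab))
  tab$glycoforms[tab$protein == "ProS" & tab$site == 509L] <- list(tri)
  tab
}

#' Generate a synthetic glycopeptide PSM table
#'
#' Per site, draws `n_psm_per_site` PSMs: unoccupied with the site's
#' probability, otherwise a composition from the site's categorical
#' distribution; search scores ~ Uniform(100, 400) and |log prob| ~
#' Uniform(0.5, 4), so a realistic fraction of rows fails the downstream
#' confidence filters.
#'
#' @param site_table Site table as from [default_glyco_sites()].
#' @param n_psm_per_site PSMs per site (0 gives an empty table).
#' @param seed Random seed.
#' @return data.frame with columns `protein`, `site`, `composition`
#'   (label or `"unoccupied"`), `score`, `log_prob`.
#' @export
gen_glyco_psms <- function(site_table = default_glyco_sites(),
                           n_psm_per_site = 200L, seed = 1L) {
  stopifnot(n_psm_per_site >= 0)
  empty <- data.frame(protein = character(0), site = integer(0),
                      composition = character(0), score = numeric(0),
                      log_prob = numeric(0))
  if (n_psm_per_site == 0 || nrow(site_table) == 0) return(empty)
  set.seed(seed)
  rows <- lapply(seq_len(nrow(site_table)), function(i) {
    st <- site_table[i, ]
    probs <- st$glycoforms[[1]]
    unocc <- stats::runif(n_psm_per_site) < st$p_unoccupied
    comp <- character(n_psm_per_site)
    comp[unocc] <- "unoccupied"
    n_occ <- sum(!unocc)
    if (n_occ > 0)
      comp[!unocc] <- sample(names(probs), n_occ, replace = TRUE,
                             prob = probs)
    data.frame(protein = st$protein, site = st$site, composition = comp,
               score = stats::runif(n_psm_per_site, 100, 400),
               log_prob = stats::runif(n_psm_per_site, 0.5, 4))
  })
  do.call(rbind, rows)
}

#' Generate a cross-link validation fixture
#'
#' Builds a toy multi-chain coordinate model — two copies (chains A, B) of
#' protein `C4BPa` and one copy (chain C) of protein `C4BPb`, with CA atoms
#' on a known grid and one CYS SG pair — together with a cross-link table
#' (scores and replicate structure spanning kept/dropped cases and one
#' deliberately overlength link) and a manifest recording the ground-truth
#' minimum CA-CA distance of every link, computed directly from the placed
#' coordinates.
#'
#' @param seed Random seed (jitters scores only; geometry is fixed).
#' @param dir Optional directory; when given, `model.pdb`,
#'   `crosslinks.tsv` and `manifest.tsv` are written there.
#' @return List with `links` (data.frame), `model` (coordinates, see
#'   [read_model()] for the structure), `chain_map`, `manifest`
#'   (data.frame `link_id`, `true_min_dist`), and `paths` when `dir` is
#'   given.
#' @export
gen_xl_fixture <- function(seed = 1L, dir = NULL) {
  set.seed(seed)
  mk_chain <- function(resnos, offset) {
    data.frame(resno = resnos,
               x = 4 * resnos + offset[1], y = offset[2], z = offset[3])
  }
  chains <- list(A = mk_chain(1:30, c(0, 0, 0)),
                 B = mk_chain(1:30, c(0, 30, 0)),
                 C = mk_chain(1:20, c(0, 0, 12)))
  # one disulfide pair: SG on A/Cys25 and C/Cys18, 2.03 A apart
  sg <- data.frame(chain = c("A", "C"), resno = c(25L, 18L),
                   x = c(100, 102.03), y = c(0, 0), z = c(6, 6))
  model <- list(chains = chains, sg = sg)
  chain_map <- list(C4BPa = c("A", "B"), C4BPb = "C")

  links <- data.frame(
    link_id = c("L1", "L1", "L2", "L2", "L3", "L3", "L3",
                "L4", "L4", "L5", "L6", "L6", "L7", "L7"),
    protein_a = c("C4BPa", "C4BPa", "C4BPa", "C4BPa", "C4BPa", "C4BPa",
                  "C4BPa", "C4BPa", "C4BPa", "C4BPa", "C4BPa", "C4BPa",
                  "C4BPa", "C4BPa"),
    site_a = c(5L, 5L, 12L, 12L, 8L, 8L, 8L, 2L, 2L, 20L, 15L, 15L,
               3L, 3L),
    protein_b = c("C4BPa", "C4BPa", "C4BPa", "C4BPa", "C4BPb", "C4BPb",
                  "C4BPb", "C4BPb", "C4BPb", "C4BPa", "C4BPb", "C4BPb",
                  "C4BPa", "C4BPa"),
    site_b = c(10L, 10L, 12L, 12L, 8L, 8L, 8L, 11L, 11L, 25L, 99L, 99L,
               7L, 7L),
    linker = c("DSS", "DSS", "DSS", "DSS", "DMTMM", "DMTMM", "DMTMM",
               "DSS", "DSS", "DSS", "DMTMM", "DMTMM", "DSS", "DSS"),
    replicate = c(1L, 3L, 1L, 2L, 1L, 2L, 3L, 2L, 3L, 2L, 1L, 3L, 1L, 2L))
  base_score <- c(L1 = 75, L2 = 55, L3 = 120, L4 = 60, L5 = 90, L6 = 50,
                  L7 = 35)
  links$score <- round(base_score[links$link_id] +
                         stats::runif(nrow(links), -5, 5), 2)
  # L7 must stay at/below the score threshold; L5 single-replicate
  links$score[links$link_id == "L7"] <- c(38, 40)

  ca <- function(chain, resno) {
    r <- chains[[chain]]
    unlist(r[r$resno == resno, c("x", "y", "z")], use.names = FALSE)
  }
  min_dist <- function(pa, sa, pb, sb, self) {
    best <- Inf
    for (cha in chain_map[[pa]]) for (chb in chain_map[[pb]]) {
      if (self && cha == chb) next
      ra <- chains[[cha]]; rb <- chains[[chb]]
      if (!sa %in% ra$resno || !sb %in% rb$resno) next
      d <- sqrt(sum((ca(cha, sa) - ca(chb, sb))^2))
      best <- min(best, d)
    }
    best
  }
  uniq <- unique(links[, c("link_id", "protein_a", "site_a", "protein_b",
                           "site_b")])
  uniq$true_min_dist <- mapply(function(pa, sa, pb, sb) {
    self <- pa == pb && sa == sb
    d <- min_dist(pa, sa, pb, sb, self)
    if (is.finite(d)) d else NA_real_
  }, uniq$protein_a, uniq$site_a, uniq$protein_b, uniq$site_b)
  manifest <- uniq[, c("link_id", "true_min_dist")]
  rownames(manifest) <- NULL

  out <- list(links = links, model = model, chain_map = chain_map,
              manifest = manifest)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    paths <- list(model = file.path(dir, "model.pdb"),
                  links = file.path(dir, "crosslinks.tsv"),
                  manifest = file.path(dir, "manifest.tsv"))
    write_model_pdb(model, paths$model)
    utils::write.table(links, paths$links, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    utils::write.table(manifest, paths$manifest, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    out$paths <- paths
  }
  out
}

# Write the toy model as a minimal PDB (CA trace + CYS SG atoms).
write_model_pdb <- function(model, path) {
  lines <- character(0)
  serial <- 0L
  for (ch in names(model$chains)) {
    r <- model$chains[[ch]]
    for (i in seq_len(nrow(r))) {
      serial <- serial + 1L
      is_cys <- !is.null(model$sg) &&
        any(model$sg$chain == ch & model$sg$resno == r$resno[i])
      lines <- c(lines, sprintf(
        "ATOM  %5d  CA  %3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
        serial, if (is_cys) "CYS" else "ALA", ch, r$resno[i],
        r$x[i], r$y[i], r$z[i]))
    }
  }
  if (!is.null(model$sg)) for (i in seq_len(nrow(model$sg))) {
    serial <- serial + 1L
    s <- model$sg[i, ]
    lines <- c(lines, sprintf(
      "ATOM  %5d  SG  CYS %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00           S",
      serial, s$chain, s$resno, s$x, s$y, s$z))
  }
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Built-in synthetic reference-panel concentrations
#'
#' Plasma concentrations (g/L) for the 22 reference proteins used to anchor
#' the LFQ-to-concentration regression. The values are literature-plausible
#' averages spanning about 4.5 orders of magnitude; they are synthetic
#' stand-ins, since real reported averages must be user-supplied for real
#' data.
#'
#' @return Named numeric vector (g/L), 22 entries.
#' @export
reference_panel <- function() {
  c(A2M = 1.5, B2M = 0.002, C1R = 0.05, C2 = 0.025, C6 = 0.045,
    C9 = 0.06, CFP = 0.025, CP = 0.35, F10 = 0.01, F12 = 0.03,
    F2 = 0.1, F7 = 5e-4, F8 = 2e-4, F9 = 0.005, HP = 1.0,
    KLKB1 = 0.05, MB = 5e-5, MBL2 = 0.002, SERPINA1 = 1.5,
    TFRC = 0.001, TTR = 0.25, VWF = 0.01)
}

#' Generate a longitudinal plasma LFQ cohort
#'
#' Simulates per-sample molar complex concentrations (healthy: equimolar
#' alpha6 beta1 + ProS and alpha7 beta1 + ProS; acute timepoints add a
#' beta-free 7-alpha species and a CRP spike), derives chain
#' concentrations, and maps every protein to a MaxLFQ intensity via the
#' log-linear response log10(LFQ) = a * log10(conc g/L) + b + N(0, sigma).
#' The 22-protein reference panel is included at its fixed concentrations.
#'
#' @param n_donors Number of donors.
#' @param timepoints Number of timepoints per donor.
#' @param scenario `"healthy"` or `"acute"`. In the acute scenario,
#'   timepoints `acute_timepoints` of every donor carry the 7-alpha
#'   species and elevated CRP.
#' @param seed Random seed.
#' @param sigma LFQ log10 noise SD (0 gives exact log-linear response).
#' @param a,b Response slope and intercept of the log-linear LFQ model.
#' @param c_complex Molar concentration (mol/L) of each of the two healthy
#'   complexes.
#' @param free_pros Molar concentration of circulating free ProS.
#' @param frac_7a Fraction of complexes that are the 7-alpha species at
#'   acute timepoints.
#' @param crp_healthy,crp_acute CRP concentrations (g/L).
#' @param acute_timepoints Integer indices of acute timepoints (acute
#'   scenario only).
#' @param mw_map Chain molecular weights (Da) used to convert molar chain
#'   concentrations to mass concentrations.
#' @return List with `lfq` (samples x proteins matrix), `panel` (named g/L
#'   vector), `truth` (per-sample data.frame with true ratio, unbound ProS
#'   (mol/L), CRP, acute flag), `mw_map`, and `sec` (SEC fraction profiles
#'   from [gen_sec_profiles()]).
#' @export
gen_plasma_cohort <- function(n_donors = 2L, timepoints = 5L,
                              scenario = c("healthy", "acute"), seed = 1L,
                              sigma = 0.05, a = 1, b = 6,
                              c_complex = 1.75e-7, free_pros = 1.0e-7,
                              frac_7a = 0.5, crp_healthy = 0.002,
                              crp_acute = 0.15,
                              acute_timepoints = NULL,
                              mw_map = mechanistic_chain_masses() * 1000) {
  scenario <- match.arg(scenario)
  stopifnot(n_donors >= 1, timepoints >= 1, sigma >= 0, a != 0)
  set.seed(seed)
  if (is.null(acute_timepoints))
    acute_timepoints <- if (scenario == "acute")
      unique(pmin(timepoints, c(2L, timepoints))) else integer(0)
  panel <- reference_panel()
  mw <- c(C4BPA = unname(mw_map[["alpha"]]), C4BPB = unname(mw_map[["beta"]]),
          PROS1 = unname(mw_map[["pros"]]), CRP = 25000)
  samples <- expand.grid(timepoint = seq_len(timepoints),
                         donor = seq_len(n_donors))[, c("donor", "timepoint")]
  n <- nrow(samples)
  truth <- data.frame(sample = sprintf("D%d_T%d", samples$donor,
                                       samples$timepoint),
                      donor = samples$donor, timepoint = samples$timepoint)
  truth$acute <- scenario == "acute" & truth$timepoint %in% acute_timepoints
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    total_c <- 2 * c_complex
    if (truth$acute[i]) {
      c7a <- frac_7a * total_c
      c6 <- c7 <- (1 - frac_7a) * total_c / 2
      crp <- crp_acute
    } else {
      c7a <- 0
      c6 <- c7 <- c_complex
      crp <- crp_healthy
    }
    conc_alpha <- 6 * c6 + 7 * c7 + 7 * c7a   # mol/L
    conc_beta <- c6 + c7
    conc_pros <- c6 + c7 + free_pros
    conc_gL <- c(C4BPA = conc_alpha * mw[["C4BPA"]],
                 C4BPB = conc_beta * mw[["C4BPB"]],
                 PROS1 = conc_pros * mw[["PROS1"]],
                 CRP = crp, panel)
    rows[[i]] <- conc_gL
    truth$ratio_true[i] <- conc_alpha / conc_beta
    truth$unbound_pros_true[i] <- free_pros
    truth$crp_gL[i] <- crp
  }
  conc <- do.call(rbind, rows)
  rownames(conc) <- truth$sample
  lfq <- 10^(a * log10(conc) + b +
               matrix(stats::rnorm(length(conc), 0, sigma), nrow(conc)))
  list(lfq = lfq, panel = panel, truth = truth,
       mw_map = mw, sec = gen_sec_profiles(seed = seed + 1L))
}

#' Generate synthetic SEC co-elution profiles
#'
#' Gaussian elution peaks over fractions, in triplicate: C4BPa, C4BPb and
#' ProS share one high-molecular-weight complex peak; ProS carries an
#' additional late free-monomer peak.
#'
#' @param seed Random seed.
#' @param n_fractions Number of SEC fractions.
#' @param peak_complex,peak_free Peak centers (fraction index).
#' @param width Gaussian peak SD in fractions.
#' @param noise_sd Additive intensity noise SD.
#' @return Long data.frame: `protein`, `replicate`, `fraction`,
#'   `intensity`.
#' @export
gen_sec_profiles <- function(seed = 1L, n_fractions = 40L,
                             peak_complex = 12, peak_free = 28,
                             width = 2.5, noise_sd = 0.01) {
  set.seed(seed)
  fr <- seq_len(n_fractions)
  shape <- function(centers, heights) {
    rowSums(vapply(seq_along(centers), function(j)
      heights[j] * exp(-0.5 * ((fr - centers[j]) / width)^2),
      numeric(n_fractions)))
  }
  spec <- list(C4BPa = shape(peak_complex, 1.0),
               C4BPb = shape(peak_complex, 0.35),
               ProS = shape(c(peak_complex, peak_free), c(0.5, 0.6)))
  rows <- lapply(names(spec), function(p) {
    do.call(rbind, lapply(1:3, function(r) {
      data.frame(protein = p, replicate = r, fraction = fr,
                 intensity = pmax(0, spec[[p]] +
                                    stats::rnorm(n_fractions, 0, noise_sd)))
    }))
  })
  do.call(rbind, rows)
}
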