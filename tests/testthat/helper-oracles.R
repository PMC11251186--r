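# Independent oracles used across the suite. These deliberately re-derive
# results by brute force, never by calling the implementation under test.

# Brute-force stoichiometry enumeration: triple loop over the lattice.
oracle_enumerate_stoich <- function(observed, sd, chain_masses, bounds,
                                    k_sigma = 2,
                                    require_beta_for_pros = TRUE) {
  rows <- list()
  for (na in 0:bounds[["alpha"]]) for (nb in 0:bounds[["beta"]])
    for (np in 0:bounds[["pros"]]) {
      if (na + nb + np == 0) next
      if (require_beta_for_pros && np > 0 && nb == 0 && na > 0) next
      m <- na * chain_masses[["alpha"]] + nb * chain_masses[["beta"]] +
        np * chain_masses[["pros"]]
      if (abs(m - observed) <= k_sigma * sd)
        rows[[length(rows) + 1L]] <- data.frame(
          n_alpha = na, n_beta = nb, n_pros = np, mass = m,
          error = m - observed)
    }
  if (!length(rows))
    return(data.frame(n_alpha = integer(0), n_beta = integer(0),
                      n_pros = integer(0), mass = numeric(0),
                      error = numeric(0)))
  out <- do.call(rbind, rows)
  out[order(abs(out$error), out$n_alpha + out$n_beta + out$n_pros), ]
}

# Grid search over the middle-population split x minimizing |(a1+x) - f7|.
oracle_overlap_grid <- function(a1, a2, f7, step = 1e-4) {
  xs <- seq(0, a2, by = step)
  xs[which.min(abs((a1 + xs) - f7))]
}

# Monoisotopic elemental-composition glycan-mass oracle (atom counts per
# dehydrated residue, summed from atomic masses).
oracle_glycan_mono <- function(nHexNAc = 0, nHex = 0, ndHex = 0, nNeuAc = 0) {
  am <- c(C = 12, H = 1.0078250319, N = 14.0030740052, O = 15.9949146221)
  formula <- function(C, H, N, O) C * am["C"] + H * am["H"] +
    N * am["N"] + O * am["O"]
  unname(nHexNAc * formula(8, 13, 1, 5) + nHex * formula(6, 10, 0, 5) +
           ndHex * formula(6, 10, 0, 4) + nNeuAc * formula(11, 17, 1, 8))
}

mech_native_masses <- function(seed, n = 5000) {
  cdms_event_to_mass(gen_cdms_events("MECHANISTIC", n, seed = seed))$mass
}

mech_acid_masses <- function(seed, n = 5000) {
  cdms_event_to_mass(gen_acidified(named_preset("MECHANISTIC"), n,
                                   seed = seed))$mass
}
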