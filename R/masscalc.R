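# Mass arithmetic for chains, glycans and complexes, and combinatorial
# stoichiometry assignment of an observed particle mass.

# Dehydrated monosaccharide residue masses (Da), glycosidic-bond convention.
.GLYCAN_MONO <- c(HexNAc = 203.079373, Hex = 162.052824,
                  dHex = 146.057909, NeuAc = 291.095417)
.GLYCAN_AVG <- c(HexNAc = 203.195, Hex = 162.141,
                 dHex = 146.141, NeuAc = 291.255)

.WATER_MONO <- 18.010565
.WATER_AVG <- 18.01528

# Expasy amino-acid residue masses (Da).
.AA_AVG <- c(A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886,
             C = 103.1388, E = 129.1155, Q = 128.1307, G = 57.0519,
             H = 137.1411, I = 113.1594, L = 113.1594, K = 128.1741,
             M = 131.1926, F = 147.1766, P = 97.1167, S = 87.0782,
             T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326)
.AA_MONO <- c(A = 71.03711, R = 156.10111, N = 114.04293, D = 115.02694,
              C = 103.00919, E = 129.04259, Q = 128.05858, G = 57.02146,
              H = 137.05891, I = 113.08406, L = 113.08406, K = 128.09496,
              M = 131.04049, F = 147.06841, P = 97.05276, S = 87.03203,
              T = 101.04768, W = 186.07931, Y = 163.06333, V = 99.06841)

#' N-glycan composition
#'
#' Construct a composition of the four monosaccharide classes observed on
#' serum N-glycans: N-acetylhexosamine (HexNAc), hexose (Hex), deoxyhexose
#' (dHex, fucose) and N-acetylneuraminic acid (NeuAc, sialic acid).
#'
#' @param HexNAc,Hex,dHex,NeuAc Non-negative integer residue counts.
#' @return An object of class `glycan_comp` (named integer vector).
#' @examples
#' glycan_comp(HexNAc = 4, Hex = 5, NeuAc = 2)
#' @export
glycan_comp <- function(HexNAc = 0L, Hex = 0L, dHex = 0L, NeuAc = 0L) {
  counts <- c(HexNAc = HexNAc, Hex = Hex, dHex = dHex, NeuAc = NeuAc)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("glycan residue counts must be non-negative integers")
  structure(as.integer(counts),
            names = names(counts), class = "glycan_comp")
}

#' Parse a glycan composition string
#'
#' Accepts the long form (`"HexNAc4Hex5NeuAc2"`, `Neu5Ac` tolerated as an
#' alias, `Fuc` as an alias of `dHex`) and the single-letter shorthand used
#' in site-specific bar charts (`N`-HexNAc, `H`-Hex, `F`-dHex, `S`-NeuAc;
#' e.g. `"N4H5S2"`).
#'
#' @param x Composition string, or `"unoccupied"`/`""`/`"-"` for an
#'   unoccupied site (returns `NULL`).
#' @return A [glycan_comp()] or `NULL` for unoccupied.
#' @export
parse_glycan <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  x <- trimws(x)
  if (x %in% c("", "-", "(-)", "unoccupied", "Unoccupied")) return(NULL)
  xx <- gsub("Neu5Ac", "NeuAc", x, fixed = TRUE)
  xx <- gsub("Fuc", "dHex", xx, fixed = TRUE)
  counts <- c(HexNAc = 0L, Hex = 0L, dHex = 0L, NeuAc = 0L)
  long <- gregexpr("(HexNAc|Hex|dHex|NeuAc)([0-9]+)", xx)[[1]]
  is_long <- grepl("HexNAc|NeuAc|dHex|Hex", xx)
  if (is_long) {
    m <- regmatches(xx, gregexpr("(HexNAc|dHex|Hex(?!NAc)|NeuAc)([0-9]+)",
                                 xx, perl = TRUE))[[1]]
    if (!length(m) || nchar(paste(m, collapse = "")) != nchar(xx))
      stop("cannot parse glycan composition: ", x)
    for (piece in m) {
      unit <- sub("[0-9]+$", "", piece)
      n <- as.integer(sub("^[A-Za-z]+", "", piece))
      counts[unit] <- counts[unit] + n
    }
  } else {
    m <- regmatches(xx, gregexpr("([NHFS])([0-9]+)", xx))[[1]]
    if (!length(m) || nchar(paste(m, collapse = "")) != nchar(xx))
      stop("cannot parse glycan composition: ", x)
    map <- c(N = "HexNAc", H = "Hex", F = "dHex", S = "NeuAc")
    for (piece in m) {
      unit <- map[[substr(piece, 1L, 1L)]]
      counts[unit] <- counts[unit] + as.integer(substring(piece, 2L))
    }
  }
  do.call(glycan_comp, as.list(counts))
}

#' Canonical composition label
#'
#' @param comp A [glycan_comp()].
#' @return Serialized label such as `"HexNAc4Hex5NeuAc2"` (zero counts
#'   omitted); `"unoccupied"` for `NULL`.
#' @export
glycan_label <- function(comp) {
  if (is.null(comp)) return("unoccupied")
  comp <- as_glycan(comp)
  nz <- comp[comp > 0]
  if (!length(nz)) return("Hex0")
  paste0(names(nz), unclass(nz), collapse = "")
}

as_glycan <- function(x) {
  if (is.null(x)) return(NULL)
  if (inherits(x, "glycan_comp")) return(x)
  if (is.character(x)) return(parse_glycan(x))
  if (is.numeric(x) && !is.null(names(x)))
    return(do.call(glycan_comp, as.list(x)))
  stop("cannot interpret object as a glycan composition")
}

#' @export
print.glycan_comp <- function(x, ...) {
  cat("<glycan>", glycan_label(x), "\n")
  invisible(x)
}

#' @export
`+.glycan_comp` <- function(e1, e2) {
  do.call(glycan_comp, as.list(unclass(e1) + unclass(e2)))
}

#' Glycan mass
#'
#' Mass of an N-glycan composition as the sum of dehydrated residue masses
#' (the glycan as attached, glycosidic-bond convention).
#'
#' @param comp A [glycan_comp()], composition string, or `NULL` (mass 0).
#' @param mode `"average"` or `"monoisotopic"`.
#' @return Mass in Da.
#' @examples
#' glycan_mass(glycan_comp(HexNAc = 4, Hex = 5, NeuAc = 2), "monoisotopic")
#' @export
glycan_mass <- function(comp, mode = c("average", "monoisotopic")) {
  mode <- match.arg(mode)
  comp <- as_glycan(comp)
  if (is.null(comp)) return(0)
  tab <- if (mode == "average") .GLYCAN_AVG else .GLYCAN_MONO
  sum(unclass(comp) * tab[names(comp)])
}

#' Chain specification
#'
#' A protein chain defined either by its mature amino-acid sequence or by a
#' fixed mass, optionally decorated with site-specific glycoforms.
#'
#' @param chain_id Chain identifier, e.g. `"C4BPa"`, `"C4BPb"`, `"ProS"`.
#' @param sequence Mature-chain amino-acid string (one-letter codes), or
#'   `NULL` when `fixed_mass` is given.
#' @param fixed_mass Fixed chain mass in kDa, or `NULL` when `sequence` is
#'   given. Exactly one of the two must be set.
#' @param glycoforms Named list mapping site number (as character) to a
#'   glycan composition (object or string).
#' @return An object of class `chain_spec`.
#' @export
chain_spec <- function(chain_id, sequence = NULL, fixed_mass = NULL,
                       glycoforms = list()) {
  if (is.null(sequence) == is.null(fixed_mass))
    stop("exactly one of `sequence` or `fixed_mass` must be given")
  if (!is.null(sequence)) {
    sequence <- toupper(gsub("[[:space:]*]", "", sequence))
    if (!nchar(sequence)) stop("empty sequence")
    bad <- setdiff(strsplit(sequence, "")[[1]], names(.AA_AVG))
    if (length(bad))
      stop("unknown residue letter(s): ", paste(unique(bad), collapse = ", "))
  } else {
    stopifnot(is.numeric(fixed_mass), fixed_mass > 0)
  }
  if (length(glycoforms)) {
    sites <- suppressWarnings(as.integer(names(glycoforms)))
    if (anyNA(sites) || any(sites < 1))
      stop("glycoform sites must be positive integers")
    if (!is.null(sequence) && any(sites > nchar(sequence)))
      stop("glycoform site beyond sequence length")
    glycoforms <- lapply(glycoforms, as_glycan)
  }
  structure(list(chain_id = chain_id, sequence = sequence,
                 fixed_mass = fixed_mass, glycoforms = glycoforms),
            class = "chain_spec")
}

#' Chain mass
#'
#' Sequence mode: sum of residue masses plus one water, plus the mass of all
#' attached glycoforms. Fixed-mass mode: the fixed mass plus glycoforms.
#'
#' @param spec A [chain_spec()].
#' @param mode `"average"` or `"monoisotopic"`.
#' @return Mass in kDa.
#' @export
chain_mass <- function(spec, mode = c("average", "monoisotopic")) {
  mode <- match.arg(mode)
  stopifnot(inherits(spec, "chain_spec"))
  gly <- sum(vapply(spec$glycoforms, glycan_mass, numeric(1), mode = mode))
  if (!is.null(spec$sequence)) {
    tab <- if (mode == "average") .AA_AVG else .AA_MONO
    water <- if (mode == "average") .WATER_AVG else .WATER_MONO
    res <- strsplit(spec$sequence, "")[[1]]
    (sum(tab[res]) + water + gly) / 1000
  } else {
    spec$fixed_mass + gly / 1000
  }
}

#' Default mechanistic chain masses
#'
#' Glycosylated mature-chain masses (kDa) consistent with the four resolved
#' complex peak masses: M(alpha) = 72.9, M(beta) = 40.7, M(ProS) = 79.8.
#'
#' @return Named numeric vector `c(alpha=, beta=, pros=)` in kDa.
#' @export
mechanistic_chain_masses <- function() {
  c(alpha = 72.9, beta = 40.7, pros = 79.8)
}

#' Species label for a stoichiometry
#'
#' `"a7b1+ProS"` for (7,1,1); the beta/ProS parts are omitted when absent,
#' so (7,0,0) is labelled `"a7"`.
#'
#' @param n_alpha,n_beta,n_pros Non-negative integer copy numbers.
#' @return Character label.
#' @export
species_label <- function(n_alpha, n_beta, n_pros) {
  stopifnot(n_alpha >= 0, n_beta >= 0, n_pros >= 0)
  lab <- ""
  if (n_alpha > 0) lab <- paste0("a", n_alpha)
  if (n_beta > 0) lab <- paste0(lab, "b", n_beta)
  if (n_pros > 0) lab <- paste0(lab, if (nzchar(lab)) "+" else "", "ProS")
  if (!nzchar(lab)) stop("all-zero stoichiometry has no label")
  lab
}

#' Parse a species label back to its stoichiometry
#'
#' @param label Label as produced by [species_label()].
#' @return Named integer vector `c(n_alpha=, n_beta=, n_pros=)`.
#' @export
parse_species_label <- function(label) {
  na <- if (grepl("a[0-9]+", label))
    as.integer(sub(".*?a([0-9]+).*", "\\1", label)) else 0L
  nb <- if (grepl("b[0-9]+", label))
    as.integer(sub(".*b([0-9]+).*", "\\1", label)) else 0L
  np <- if (grepl("ProS", label, fixed = TRUE)) 1L else 0L
  c(n_alpha = na, n_beta = nb, n_pros = np)
}

#' Complex mass from stoichiometry
#'
#' @param n_alpha,n_beta,n_pros Non-negative integer copy numbers (not all
#'   zero).
#' @param chain_masses Named vector `c(alpha=, beta=, pros=)` in kDa.
#' @return A one-row data.frame with the stoichiometry, `label` and `mass`
#'   (kDa).
#' @examples
#' complex_mass(7, 1, 1) # alpha7 beta1 + ProS
#' @export
complex_mass <- function(n_alpha, n_beta, n_pros = 0L,
                         chain_masses = mechanistic_chain_masses()) {
  stopifnot(all(c("alpha", "beta", "pros") %in% names(chain_masses)))
  if (n_alpha + n_beta + n_pros == 0) stop("all-zero stoichiometry")
  mass <- n_alpha * chain_masses[["alpha"]] +
    n_beta * chain_masses[["beta"]] + n_pros * chain_masses[["pros"]]
  data.frame(n_alpha = as.integer(n_alpha), n_beta = as.integer(n_beta),
             n_pros = as.integer(n_pros),
             label = species_label(n_alpha, n_beta, n_pros),
             mass = unname(mass))
}

#' Assign subunit stoichiometries to an observed mass
#'
#' Exhaustively enumerates complexes over a bounded copy-number lattice and
#' returns every candidate whose theoretical mass falls within
#' `k_sigma * sd` of the observed mass, ranked by absolute error. The
#' assignment is flagged ambiguous when two or more candidates survive —
#' the situation encountered at ~553 kDa where alpha7 beta1 and
#' alpha6 beta1 + ProS differ by less than the peak width.
#'
#' @param observed Observed mass (kDa).
#' @param sd Mass standard deviation of the observed population (kDa).
#' @param chain_masses Named vector `c(alpha=, beta=, pros=)` in kDa.
#' @param bounds Named vector of maximum copies per chain; default allows up
#'   to 8 alpha (historical 8-arm hypothesis), 1 beta, 1 ProS.
#' @param k_sigma Tolerance multiplier; candidates within `k_sigma * sd`.
#' @param require_beta_for_pros When TRUE (default), ProS may only appear in
#'   complexes containing a beta chain (its binding partner); a free ProS
#'   monomer (no alpha, no beta) remains assignable.
#' @return An object of class `mass_assignment`: list with `observed`, `sd`,
#'   `candidates` (data.frame with `label`, `mass`, `error`, sorted by
#'   `abs(error)`) and `ambiguous`.
#' @export
assign_stoichiometry <- function(observed, sd,
                                 chain_masses = mechanistic_chain_masses(),
                                 bounds = c(alpha = 8L, beta = 1L, pros = 1L),
                                 k_sigma = 2, require_beta_for_pros = TRUE) {
  stopifnot(observed > 0, sd > 0, k_sigma > 0)
  if (!length(chain_masses)) stop("empty chain-mass map")
  stopifnot(all(c("alpha", "beta", "pros") %in% names(chain_masses)),
            all(bounds >= 0))
  grid <- expand.grid(n_alpha = 0:bounds[["alpha"]],
                      n_beta = 0:bounds[["beta"]],
                      n_pros = 0:bounds[["pros"]])
  grid <- grid[rowSums(grid) > 0L, , drop = FALSE]
  if (require_beta_for_pros) {
    drop <- grid$n_pros > 0L & grid$n_beta == 0L & grid$n_alpha > 0L
    grid <- grid[!drop, , drop = FALSE]
  }
  mass <- grid$n_alpha * chain_masses[["alpha"]] +
    grid$n_beta * chain_masses[["beta"]] +
    grid$n_pros * chain_masses[["pros"]]
  err <- mass - observed
  keep <- abs(err) <= k_sigma * sd
  cand <- grid[keep, , drop = FALSE]
  cand$mass <- mass[keep]
  cand$error <- err[keep]
  cand$label <- vapply(seq_len(nrow(cand)), function(i)
    species_label(cand$n_alpha[i], cand$n_beta[i], cand$n_pros[i]),
    character(1))
  n_subunits <- cand$n_alpha + cand$n_beta + cand$n_pros
  ord <- order(abs(cand$error), n_subunits, cand$label)
  cand <- cand[ord, c("label", "n_alpha", "n_beta", "n_pros",
                      "mass", "error")]
  rownames(cand) <- NULL
  structure(list(observed = observed, sd = sd, candidates = cand,
                 ambiguous = nrow(cand) >= 2L,
                 k_sigma = k_sigma, chain_masses = chain_masses),
            class = "mass_assignment")
}

#' @export
print.mass_assignment <- function(x, ...) {
  cat(sprintf("<mass assignment> observed %.1f kDa (sd %.1f), %d candidate(s)%s\n",
              x$observed, x$sd, nrow(x$candidates),
              if (x$ambiguous) " [ambiguous]" else ""))
  if (nrow(x$candidates)) print(x$candidates)
  invisible(x)
}
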