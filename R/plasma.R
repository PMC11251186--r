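# Plasma subunit-stoichiometry monitoring: reference-protein regression
# from MaxLFQ intensities to absolute concentrations, C4BP alpha/beta
# molar ratios, unbound ProS, iBAQ purity profiles, and SEC co-elution.

#' Fit the per-sample reference-protein concentration regression
#'
#' For every sample, fits log10(LFQ) = a * log10(conc) + b over the
#' reference-panel proteins with quantified (finite, positive) LFQ
#' values. Panel proteins missing from a sample are excluded and
#' reported.
#'
#' @param matrix Samples x proteins numeric matrix of MaxLFQ intensities
#'   (missing values allowed as NA).
#' @param panel Named vector of known concentrations (g/L), e.g.
#'   [reference_panel()].
#' @return data.frame, one row per sample: `sample`, `a`, `b`, `r2`,
#'   `n_used`.
#' @export
fit_concentration_regression <- function(matrix, panel) {
  stopifnot(is.matrix(matrix), !is.null(colnames(matrix)),
            !is.null(names(panel)), all(panel > 0))
  if (length(panel) < 3) stop("reference panel needs at least 3 proteins")
  common <- intersect(colnames(matrix), names(panel))
  rows <- lapply(seq_len(nrow(matrix)), function(i) {
    lfq <- matrix[i, common]
    use <- is.finite(lfq) & lfq > 0
    if (sum(use) < 3)
      stop("sample ", rownames(matrix)[i],
           ": fewer than 3 usable panel proteins")
    dropped <- common[!use]
    if (length(dropped))
      message("sample ", rownames(matrix)[i], ": excluded panel protein(s) ",
              paste(dropped, collapse = ", "))
    x <- log10(panel[common[use]])
    y <- log10(lfq[use])
    fit <- stats::lm(y ~ x)
    # summary() warns on exact (noise-free) fits; r2 = 1 is then correct
    r2 <- suppressWarnings(summary(fit)$r.squared)
    data.frame(sample = rownames(matrix)[i],
               a = unname(stats::coef(fit)[2]),
               b = unname(stats::coef(fit)[1]),
               r2 = r2,
               n_used = sum(use))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Convert LFQ intensities to concentrations
#'
#' Inverts the per-sample regression: conc (g/L) = 10^((log10(LFQ) - b)/a).
#' Missing LFQ stays missing (never zero). With a chain molecular-weight
#' map, molar concentrations (mol/L) are computed as mass concentration
#' divided by the molecular weight in g/mol (= Da).
#'
#' @param matrix Samples x proteins LFQ matrix.
#' @param fits Output of [fit_concentration_regression()].
#' @param mw_map Optional named vector of molecular weights (Da) for the
#'   proteins to be expressed in molar units.
#' @return List with `conc_gL` (samples x proteins) and, when `mw_map`
#'   is given, `conc_molar` (samples x proteins of the mapped subset).
#' @export
to_concentration <- function(matrix, fits, mw_map = NULL) {
  stopifnot(is.matrix(matrix), nrow(matrix) == nrow(fits))
  conc <- matrix * NA_real_
  for (i in seq_len(nrow(matrix))) {
    lfq <- matrix[i, ]
    ok <- is.finite(lfq) & lfq > 0
    conc[i, ok] <- 10^((log10(lfq[ok]) - fits$b[i]) / fits$a[i])
  }
  out <- list(conc_gL = conc)
  if (!is.null(mw_map)) {
    prot <- intersect(colnames(matrix), names(mw_map))
    out$conc_molar <- sweep(conc[, prot, drop = FALSE], 2,
                            mw_map[prot], "/")
  }
  out
}

#' Per-sample C4BP alpha/beta molar subunit ratio
#'
#' ratio = [C4BPalpha] / [C4BPbeta] on molar concentrations. The ratio is
#' expected in the 6-7 band when only alpha6 beta1(+ProS) and
#' alpha7 beta1(+ProS) complexes co-occur; values above 7 flag isoform
#' variation (e.g. an acute-phase beta-free 7-alpha species).
#'
#' @param conc_molar Samples x proteins molar concentration matrix.
#' @param alpha,beta Column names of the two chains.
#' @param expected_range The expected ratio band.
#' @return data.frame: `sample`, `ratio_alpha_beta`, `in_expected_range`
#'   (band inclusive), `variation_flag` (ratio above the band).
#' @export
subunit_ratio <- function(conc_molar, alpha = "C4BPA", beta = "C4BPB",
                          expected_range = c(6, 7)) {
  stopifnot(all(c(alpha, beta) %in% colnames(conc_molar)))
  a <- conc_molar[, alpha]
  b <- conc_molar[, beta]
  ratio <- ifelse(is.finite(b) & b > 0, a / b, NA_real_)
  if (any(!is.finite(b) | b == 0))
    warning("undefined ratio (missing or zero beta) reported as NA")
  data.frame(sample = rownames(conc_molar),
             ratio_alpha_beta = unname(ratio),
             in_expected_range = !is.na(ratio) &
               ratio >= expected_range[1] & ratio <= expected_range[2],
             variation_flag = !is.na(ratio) & ratio > expected_range[2])
}

#' Unbound protein S concentration
#'
#' max(0, [ProS] - [C4BPbeta]) molar, assuming saturating high-affinity
#' binding of ProS to every beta chain; negative intermediates are
#' clamped to 0 with a warning.
#'
#' @param conc_molar Samples x proteins molar concentration matrix.
#' @param pros,beta Column names.
#' @return data.frame: `sample`, `unbound_pros` (mol/L).
#' @export
unbound_pros <- function(conc_molar, pros = "PROS1", beta = "C4BPB") {
  stopifnot(all(c(pros, beta) %in% colnames(conc_molar)))
  diffc <- conc_molar[, pros] - conc_molar[, beta]
  if (any(diffc < 0, na.rm = TRUE))
    warning(sum(diffc < 0, na.rm = TRUE),
            " sample(s) with ProS below C4BPbeta; clamped to 0")
  data.frame(sample = rownames(conc_molar),
             unbound_pros = unname(pmax(0, diffc)))
}

#' Sample purity profile from iBAQ intensities
#'
#' Drops contaminant-flagged protein groups, merges the C4A and C4B
#' isotypes into a single `C4b` group, normalizes iBAQ to 100%, and
#' reports groups strictly above `threshold_pct` plus an `other`
#' remainder.
#'
#' @param ibaq Named numeric vector of iBAQ intensities, or a data.frame
#'   with columns `protein`, `ibaq` and optional logical `contaminant`.
#' @param threshold_pct Strict visibility threshold (percent).
#' @return data.frame: `protein`, `percent`, sorted decreasing with
#'   `other` last (if nonzero).
#' @export
purity_profile <- function(ibaq, threshold_pct = 1) {
  if (is.data.frame(ibaq)) {
    if ("contaminant" %in% names(ibaq))
      ibaq <- ibaq[!ibaq$contaminant, , drop = FALSE]
    vals <- stats::setNames(ibaq$ibaq, ibaq$protein)
  } else vals <- ibaq
  stopifnot(!is.null(names(vals)), all(vals >= 0))
  is_c4 <- names(vals) %in% c("C4A", "C4B")
  if (any(is_c4)) {
    vals <- c(vals[!is_c4], C4b = sum(vals[is_c4]))
  }
  pct <- 100 * vals / sum(vals)
  shown <- pct[pct > threshold_pct]
  shown <- shown[order(-shown)]
  other <- sum(pct[pct <= threshold_pct])
  out <- data.frame(protein = names(shown), percent = unname(shown))
  if (other > 0)
    out <- rbind(out, data.frame(protein = "other", percent = other))
  rownames(out) <- NULL
  out
}

#' Centered rolling mean with shrinking edge windows
#'
#' @param x Numeric vector.
#' @param window Odd window width (default 3).
#' @return Smoothed vector of the same length.
#' @export
rolling_mean <- function(x, window = 3L) {
  stopifnot(window >= 1, window %% 2 == 1)
  half <- (window - 1L) %/% 2L
  n <- length(x)
  vapply(seq_len(n), function(i) {
    lo <- max(1L, i - half)
    hi <- min(n, i + half)
    mean(x[lo:hi])
  }, numeric(1))
}

#' SEC co-elution profiles and pairwise scores
#'
#' Per protein, sums the triplicate intensities per fraction, applies a
#' centered window-3 rolling mean (edges use the available fractions),
#' smooths the across-replicate SD the same way, and computes the
#' pairwise co-elution score as the Pearson correlation of smoothed
#' profiles over fractions.
#'
#' @param profiles Long data.frame: `protein`, `replicate`, `fraction`,
#'   `intensity` (as from [gen_sec_profiles()]).
#' @param window Rolling-mean window.
#' @return List with `smoothed` (fractions x proteins matrix of smoothed
#'   summed intensity), `sd_smoothed` (same shape, across-replicate SD),
#'   and `coelution` (proteins x proteins correlation matrix).
#' @export
sec_coelution <- function(profiles, window = 3L) {
  req <- c("protein", "replicate", "fraction", "intensity")
  stopifnot(all(req %in% names(profiles)))
  prots <- unique(profiles$protein)
  fracs <- sort(unique(profiles$fraction))
  smoothed <- matrix(NA_real_, length(fracs), length(prots),
                     dimnames = list(fracs, prots))
  sd_sm <- smoothed
  for (p in prots) {
    sub <- profiles[profiles$protein == p, ]
    summed <- vapply(fracs, function(f)
      sum(sub$intensity[sub$fraction == f]), numeric(1))
    sds <- vapply(fracs, function(f)
      stats::sd(sub$intensity[sub$fraction == f]), numeric(1))
    smoothed[, p] <- rolling_mean(summed, window)
    sd_sm[, p] <- rolling_mean(sds, window)
  }
  list(smoothed = smoothed, sd_smoothed = sd_sm,
       coelution = stats::cor(smoothed))
}
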