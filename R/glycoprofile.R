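# Site-specific N-glycosylation profiling from glycopeptide PSM tables:
# confidence filtering, per-site composition proportions, unoccupied-site
# flagging, and export of dominant glycoforms for mass prediction.

#' Filter glycopeptide PSMs by search confidence
#'
#' Keeps rows with score strictly greater than `min_score` and absolute
#' log probability strictly greater than `min_log_prob` (defaults: the
#' score > 150, |log prob| > 1.5 confidence rule).
#'
#' @param table data.frame with at least `score` and `log_prob` columns.
#' @param min_score,min_log_prob Strict lower thresholds.
#' @return The filtered data.frame.
#' @export
filter_psms <- function(table, min_score = 150, min_log_prob = 1.5) {
  req <- c("protein", "site", "composition", "score", "log_prob")
  missing_cols <- setdiff(req, names(table))
  if (length(missing_cols))
    stop("missing column(s): ", paste(missing_cols, collapse = ", "))
  keep <- table$score > min_score & abs(table$log_prob) > min_log_prob
  table[keep, , drop = FALSE]
}

#' Per-site glycoform profiles
#'
#' Groups filtered PSMs by (protein, site) and computes composition
#' proportions (PSM counts over the site total, unoccupied included), the
#' unoccupied fraction, the dominant occupied composition (ties broken
#' toward the higher NeuAc count, then lexicographically), and a flag for
#' sites with more than 20% unoccupied PSMs.
#'
#' @param table Filtered PSM data.frame (see [filter_psms()]).
#' @param unoccupied_threshold Strict threshold for the high-unoccupied
#'   flag.
#' @return data.frame with one row per site: `protein`, `site`, `n_psm`,
#'   `unoccupied_fraction`, `dominant` (NA when no occupied PSM),
#'   `high_unoccupied_flag`, and list-column `proportions` (named
#'   fractions over compositions including `"unoccupied"`).
#' @export
site_profiles <- function(table, unoccupied_threshold = 0.20) {
  req <- c("protein", "site", "composition")
  stopifnot(all(req %in% names(table)))
  if (!nrow(table)) {
    out <- data.frame(protein = character(0), site = integer(0),
                      n_psm = integer(0), unoccupied_fraction = numeric(0),
                      dominant = character(0),
                      high_unoccupied_flag = logical(0))
    out$proportions <- list()
    return(out)
  }
  comp <- vapply(as.character(table$composition),
                 function(x) glycan_label(parse_glycan(x)), character(1),
                 USE.NAMES = FALSE)
  key <- interaction(table$protein, table$site, drop = TRUE, lex.order = TRUE)
  groups <- split(seq_len(nrow(table)), key)
  rows <- lapply(groups, function(idx) {
    cc <- comp[idx]
    tab <- table(cc)
    props <- as.numeric(tab) / length(cc)
    names(props) <- names(tab)
    unocc <- if ("unoccupied" %in% names(props)) props[["unoccupied"]] else 0
    occ <- props[names(props) != "unoccupied"]
    dominant <- NA_character_
    if (length(occ)) {
      top <- names(occ)[occ == max(occ)]
      if (length(top) > 1L) {
        neuac <- vapply(top, function(lab)
          as.integer(parse_glycan(lab)[["NeuAc"]]), integer(1))
        top <- top[order(-neuac, top)]
      }
      dominant <- top[1L]
    }
    data.frame(protein = table$protein[idx[1]],
               site = table$site[idx[1]],
               n_psm = length(idx),
               unoccupied_fraction = unname(unocc),
               dominant = dominant,
               high_unoccupied_flag = unocc > unoccupied_threshold)
  })
  out <- do.call(rbind, rows)
  out$proportions <- lapply(groups, function(idx) {
    cc <- comp[idx]
    tab <- table(cc)
    stats::setNames(as.numeric(tab) / length(cc), names(tab))
  })
  out <- out[order(out$protein, out$site), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-protein counts of occupied glycosylation sites
#'
#' Counts distinct sites with at least one occupied PSM for each protein.
#'
#' @param profiles Output of [site_profiles()].
#' @return Named integer vector of site counts per protein.
#' @export
sites_summary <- function(profiles) {
  if (!nrow(profiles)) return(stats::setNames(integer(0), character(0)))
  occupied <- profiles[!is.na(profiles$dominant), , drop = FALSE]
  counts <- tapply(occupied$site, occupied$protein,
                   function(s) length(unique(s)))
  all_prot <- unique(profiles$protein)
  out <- stats::setNames(integer(length(all_prot)), all_prot)
  out[names(counts)] <- as.integer(counts)
  out
}

#' Export dominant glycoforms per chain
#'
#' Builds, per protein, the site-to-dominant-composition map consumed by
#' [chain_spec()]/[chain_mass()] glycoform decoration. Sites without a
#' dominant occupied composition are omitted with a message.
#'
#' @param profiles Output of [site_profiles()].
#' @return Named list: protein -> named list (site as character ->
#'   composition label).
#' @export
export_glycoforms <- function(profiles) {
  out <- list()
  for (p in unique(profiles$protein)) {
    sub <- profiles[profiles$protein == p, , drop = FALSE]
    skipped <- sub$site[is.na(sub$dominant)]
    if (length(skipped))
      message("omitting site(s) without dominant glycoform for ", p, ": ",
              paste(skipped, collapse = ", "))
    sub <- sub[!is.na(sub$dominant), , drop = FALSE]
    out[[p]] <- stats::setNames(as.list(sub$dominant),
                                as.character(sub$site))
  }
  out
}
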