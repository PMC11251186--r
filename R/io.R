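# Readers for the plain-text interchange formats the pipeline consumes.

#' Read protein chain sequences from FASTA
#'
#' @param path FASTA file of mature chain sequences.
#' @return Named character vector of sequences (names from FASTA headers,
#'   first whitespace-delimited token).
#' @export
read_chain_fasta <- function(path) {
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    aa <- Biostrings::readAAStringSet(path)
    seqs <- as.character(aa)
    names(seqs) <- sub("\\s.*$", "", names(aa))
    return(seqs)
  }
  lines <- readLines(path)
  hdr <- grep("^>", lines)
  if (!length(hdr)) stop("no FASTA records in ", path)
  ends <- c(hdr[-1] - 1L, length(lines))
  seqs <- vapply(seq_along(hdr), function(i)
    paste(lines[(hdr[i] + 1L):ends[i]], collapse = ""), character(1))
  names(seqs) <- sub("\\s.*$", "", sub("^>", "", lines[hdr]))
  seqs
}

#' Read CDMS ion events from TSV
#'
#' Expects header columns `mz` and `intensity_norm`.
#'
#' @param path TSV path.
#' @return data.frame of ion events.
#' @export
read_ion_events <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  if (!all(c("mz", "intensity_norm") %in% names(df)))
    stop("ion-event TSV must have columns mz, intensity_norm")
  df
}

#' Read MP contrast events from TSV
#'
#' Expects a header column `contrast`.
#'
#' @param path TSV path.
#' @return data.frame of contrast events.
#' @export
read_mp_events <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  if (!"contrast" %in% names(df))
    stop("MP-event TSV must have a contrast column")
  df
}

#' Read a chain-mass / bounds configuration from YAML
#'
#' Expected top-level keys: `chain_masses` (named kDa values with keys
#' alpha, beta, pros) and optionally `bounds` and `k_sigma` for
#' [assign_stoichiometry()].
#'
#' @param path YAML path.
#' @return Named list with `chain_masses` (numeric), and `bounds` /
#'   `k_sigma` when present.
#' @export
read_chain_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$chain_masses))
    stop("config must define chain_masses")
  cfg$chain_masses <- unlist(cfg$chain_masses)
  if (!is.null(cfg$bounds)) cfg$bounds <- unlist(cfg$bounds)
  cfg
}

#' Write mass assignments as TSV
#'
#' One row per candidate: observed, sd, label, error, ambiguous.
#'
#' @param assignments A single [assign_stoichiometry()] result or a list
#'   of them.
#' @param path Output TSV path.
#' @return The path, invisibly.
#' @export
write_assignments <- function(assignments, path) {
  if (inherits(assignments, "mass_assignment"))
    assignments <- list(assignments)
  rows <- lapply(assignments, function(a) {
    if (!nrow(a$candidates))
      return(data.frame(observed = a$observed, sd = a$sd,
                        label = NA_character_, error = NA_real_,
                        ambiguous = FALSE))
    data.frame(observed = a$observed, sd = a$sd,
               label = a$candidates$label, error = a$candidates$error,
               ambiguous = a$ambiguous)
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
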