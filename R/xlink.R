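# Cross-link confidence filtering and validation of distance restraints
# against multi-chain coordinate models, plus disulfide geometry checks.

#' Classify a cross-link by its endpoints
#'
#' `self` = identical protein and site on both ends (only resolvable
#' between two physical copies), `intra` = same protein, `inter` =
#' different proteins.
#'
#' @param protein_a,site_a,protein_b,site_b Link endpoints (vectorized).
#' @return Character vector in `{"self", "intra", "inter"}`.
#' @export
link_class <- function(protein_a, site_a, protein_b, site_b) {
  ifelse(protein_a == protein_b & site_a == site_b, "self",
         ifelse(protein_a == protein_b, "intra", "inter"))
}

#' Filter cross-links by score and replicate support
#'
#' Deduplicates by (unordered endpoints, linker) and keeps links whose
#' best score is strictly greater than `min_score` and which were
#' identified in at least `min_replicates` distinct replicates (defaults:
#' score > 40 in at least two of three replicates).
#'
#' @param table data.frame with columns `protein_a`, `site_a`,
#'   `protein_b`, `site_b`, `linker`, `score`, `replicate`.
#' @param min_score Strict score threshold.
#' @param min_replicates Minimum number of distinct replicates.
#' @param n_replicates Total replicates in the design (sanity bound).
#' @return One row per surviving unique link: endpoint columns, `linker`,
#'   `score` (best), `n_replicates_seen`, `link_class`.
#' @export
filter_links <- function(table, min_score = 40, min_replicates = 2L,
                         n_replicates = 3L) {
  req <- c("protein_a", "site_a", "protein_b", "site_b", "linker",
           "score", "replicate")
  missing_cols <- setdiff(req, names(table))
  if (length(missing_cols))
    stop("missing column(s): ", paste(missing_cols, collapse = ", "))
  if (min_replicates > n_replicates)
    stop("min_replicates cannot exceed n_replicates")
  if (!nrow(table)) return(table[0, req[1:6]])
  # canonical endpoint order so A-B and B-A collapse
  flip <- table$protein_b < table$protein_a |
    (table$protein_b == table$protein_a & table$site_b < table$site_a)
  tab <- table
  tab[flip, c("protein_a", "site_a", "protein_b", "site_b")] <-
    table[flip, c("protein_b", "site_b", "protein_a", "site_a")]
  key <- paste(tab$protein_a, tab$site_a, tab$protein_b, tab$site_b,
               tab$linker, sep = "\r")
  groups <- split(seq_len(nrow(tab)), key)
  rows <- lapply(groups, function(idx) {
    g <- tab[idx, , drop = FALSE]
    data.frame(protein_a = g$protein_a[1], site_a = g$site_a[1],
               protein_b = g$protein_b[1], site_b = g$site_b[1],
               linker = g$linker[1], score = max(g$score),
               n_replicates_seen = length(unique(g$replicate)))
  })
  out <- do.call(rbind, rows)
  out <- out[out$score > min_score & out$n_replicates_seen >= min_replicates,
             , drop = FALSE]
  out$link_class <- link_class(out$protein_a, out$site_a,
                               out$protein_b, out$site_b)
  rownames(out) <- NULL
  out
}

#' Read a coordinate model from PDB or mmCIF
#'
#' Extracts the CA trace per chain plus any cysteine SG atoms, the
#' representation used for cross-link and disulfide validation.
#'
#' @param path Path to a `.pdb` or `.cif` file.
#' @return List with `chains` (chain id -> data.frame `resno`, `x`, `y`,
#'   `z`) and `sg` (data.frame `chain`, `resno`, `x`, `y`, `z`).
#' @export
read_model <- function(path) {
  pdb <- if (grepl("\\.cif$", path, ignore.case = TRUE))
    bio3d::read.cif(path) else bio3d::read.pdb(path)
  atoms <- pdb$atom
  ca <- atoms[atoms$elety == "CA", , drop = FALSE]
  chains <- lapply(split(ca, ca$chain), function(d) {
    d <- d[!duplicated(d$resno), , drop = FALSE]
    data.frame(resno = d$resno, x = d$x, y = d$y, z = d$z)
  })
  sgrows <- atoms[atoms$elety == "SG", , drop = FALSE]
  sg <- data.frame(chain = sgrows$chain, resno = sgrows$resno,
                   x = sgrows$x, y = sgrows$y, z = sgrows$z)
  list(chains = chains, sg = sg)
}

.model_ca <- function(model, chain, resno) {
  r <- model$chains[[chain]]
  if (is.null(r)) return(NULL)
  hit <- which(r$resno == resno)
  if (!length(hit)) return(NULL)
  c(r$x[hit[1]], r$y[hit[1]], r$z[hit[1]])
}

#' Validate cross-links against a coordinate model
#'
#' For each link, enumerates all admissible chain-copy pairings (for
#' self-links the two ends must lie on different physical copies), records
#' the minimum CA-CA distance and all alternate pairings within
#' `alt_window` of it, and flags links whose minimum distance exceeds the
#' linker-specific cap (defaults DSS 30 A, DMTMM 25 A CA-CA). Endpoints
#' absent from the model make a link unmappable.
#'
#' @param links Filtered link data.frame (see [filter_links()]).
#' @param model Coordinate model from [read_model()] (or the equivalent
#'   in-memory structure).
#' @param chain_map Named list: protein name -> chain id(s) in the model.
#' @param max_len Named vector of per-linker distance caps (Angstrom).
#' @param alt_window Width (Angstrom) of the alternate-pairing window
#'   around the minimum distance.
#' @return data.frame, one row per link: endpoints, `linker`,
#'   `min_dist`, `n_alternates`, `alternates` (collapsed "chainA-chainB"
#'   strings), `overlength`, `unmappable`.
#' @export
validate_links <- function(links, model, chain_map,
                           max_len = c(DSS = 30, DMTMM = 25),
                           alt_window = 2) {
  if (!length(chain_map)) stop("empty chain_map")
  rows <- lapply(seq_len(nrow(links)), function(i) {
    l <- links[i, ]
    is_self <- l$protein_a == l$protein_b && l$site_a == l$site_b
    cha <- chain_map[[l$protein_a]]
    chb <- chain_map[[l$protein_b]]
    dists <- c()
    pair_lab <- c()
    if (!is.null(cha) && !is.null(chb)) {
      for (ca_id in cha) for (cb_id in chb) {
        if (is_self && ca_id == cb_id) next
        pa <- .model_ca(model, ca_id, l$site_a)
        pb <- .model_ca(model, cb_id, l$site_b)
        if (is.null(pa) || is.null(pb)) next
        dists <- c(dists, sqrt(sum((pa - pb)^2)))
        pair_lab <- c(pair_lab, paste0(ca_id, "-", cb_id))
      }
    }
    if (!length(dists)) {
      return(data.frame(protein_a = l$protein_a, site_a = l$site_a,
                        protein_b = l$protein_b, site_b = l$site_b,
                        linker = l$linker, min_dist = NA_real_,
                        n_alternates = 0L, alternates = "",
                        overlength = NA, unmappable = TRUE))
    }
    dmin <- min(dists)
    alt <- dists <= dmin + alt_window & dists > dmin
    cap <- max_len[[l$linker]]
    if (is.null(cap)) stop("no distance cap for linker ", l$linker)
    data.frame(protein_a = l$protein_a, site_a = l$site_a,
               protein_b = l$protein_b, site_b = l$site_b,
               linker = l$linker, min_dist = dmin,
               n_alternates = sum(alt),
               alternates = paste(pair_lab[alt], collapse = ","),
               overlength = dmin > cap, unmappable = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Check disulfide-bond geometry
#'
#' SG-SG distance per cysteine pair; a pair is plausible when the distance
#' is strictly below the threshold (default 2.05 A).
#'
#' @param model Coordinate model (see [read_model()]) with SG atoms.
#' @param cys_pairs data.frame with columns `chain_a`, `res_a`,
#'   `chain_b`, `res_b`.
#' @param threshold Plausibility threshold (Angstrom).
#' @return data.frame: the pair columns plus `distance` and `plausible`.
#' @export
disulfide_check <- function(model, cys_pairs, threshold = 2.05) {
  stopifnot(all(c("chain_a", "res_a", "chain_b", "res_b") %in%
                  names(cys_pairs)))
  sg_xyz <- function(chain, resno) {
    hit <- which(model$sg$chain == chain & model$sg$resno == resno)
    if (!length(hit))
      stop("no SG coordinate for Cys ", chain, "/", resno)
    c(model$sg$x[hit[1]], model$sg$y[hit[1]], model$sg$z[hit[1]])
  }
  d <- vapply(seq_len(nrow(cys_pairs)), function(i) {
    p <- cys_pairs[i, ]
    sqrt(sum((sg_xyz(p$chain_a, p$res_a) - sg_xyz(p$chain_b, p$res_b))^2))
  }, numeric(1))
  out <- cys_pairs
  out$distance <- d
  out$plausible <- d < threshold
  out
}
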