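#' decoyFLR: decoy amino acid post-processing for PTM site localization
#'
#' Tools for estimating global false localization rates (FLR) of
#' post-translational modification sites from searches that include a decoy
#' amino acid (a residue that cannot carry the modification, alanine by
#' default for phosphorylation). The package adjusts per-PSM site scores by
#' how often each protein site is observed phosphorylated relative to its
#' coverage (a binomial penalty), collapses redundant PSM-site records to the
#' peptidoform-site and protein-site level, ranks sites and converts
#' cumulative decoy counts into a monotone FLR, and combines several
#' independent datasets into a Gold/Silver/Bronze site catalogue.
#'
#' The main entry point is [ptm_flr()]; [simulate_psm_dataset()] generates
#' seeded synthetic PSM-site tables with ground-truth localization labels.
#'
#' @keywords internal
"_PACKAGE"

# Canonical column set for a PSM-site table. One row = one candidate modified
# residue on one PSM. Derived columns (final_score, is_decoy_site,
# psm_has_decoy, peptidoform_key) are recomputed by as_psm_sites().
PSM_SITE_COLUMNS <- c(
  "dataset_id", "spectrum_id", "psm_id", "peptide", "mods",
  "site_pos", "site_residue", "protein", "protein_pos",
  "peptide_prob", "site_prob"
)

#' Validate and complete a PSM-site table
#'
#' Checks the canonical PSM-site columns, validates probabilities and site
#' positions, and computes the derived columns: `final_score`
#' (peptide_prob * site_prob), `is_decoy_site` (the site residue equals the
#' decoy residue), `psm_has_decoy` (any site on the same PSM is a decoy
#' site), and `peptidoform_key` (peptide sequence plus its sorted
#' modification set).
#'
#' @param x data.frame with at least the columns `dataset_id`, `spectrum_id`,
#'   `psm_id`, `peptide`, `mods`, `site_pos`, `site_residue`, `protein`,
#'   `protein_pos`, `peptide_prob`, `site_prob`. `mods` is a
#'   semicolon-separated list of `pos:name` tokens in peptide coordinates.
#' @param targets character vector of target residues (default S, T, Y).
#' @param decoy single decoy residue (default "A").
#' @return the input data.frame with derived columns filled in.
#' @export
as_psm_sites <- function(x, targets = c("S", "T", "Y"), decoy = "A") {
  stopifnot(is.data.frame(x))
  missing_cols <- setdiff(PSM_SITE_COLUMNS, names(x))
  if (length(missing_cols) > 0L) {
    stop("PSM-site table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  x$site_pos <- as.integer(x$site_pos)
  x$protein_pos <- as.integer(x$protein_pos)
  x$peptide_prob <- as.numeric(x$peptide_prob)
  x$site_prob <- as.numeric(x$site_prob)

  if (nrow(x) == 0L) {
    x$final_score <- numeric(0)
    x$is_decoy_site <- logical(0)
    x$psm_has_decoy <- logical(0)
    x$peptidoform_key <- character(0)
    return(x)
  }

  for (col in c("peptide_prob", "site_prob")) {
    bad <- which(is.na(x[[col]]) | x[[col]] < 0 | x[[col]] > 1)
    if (length(bad) > 0L) {
      stop(sprintf("%s outside [0,1] (or unparseable) at row %d", col, bad[1L]),
           call. = FALSE)
    }
  }
  bad_pos <- which(is.na(x$site_pos) | x$site_pos < 1L |
                     x$site_pos > nchar(x$peptide))
  if (length(bad_pos) > 0L) {
    stop("site_pos outside the peptide at row ", bad_pos[1L], call. = FALSE)
  }
  seen <- substring(x$peptide, x$site_pos, x$site_pos)
  bad_res <- which(seen != x$site_residue)
  if (length(bad_res) > 0L) {
    stop(sprintf("site_residue disagrees with the peptide sequence at row %d ('%s' vs '%s')",
                 bad_res[1L], x$site_residue[bad_res[1L]], seen[bad_res[1L]]),
         call. = FALSE)
  }
  known <- c(targets, decoy)
  bad_known <- which(!(x$site_residue %in% known))
  if (length(bad_known) > 0L) {
    stop(sprintf("site_residue '%s' at row %d is neither a target (%s) nor the decoy (%s)",
                 x$site_residue[bad_known[1L]], bad_known[1L],
                 paste(targets, collapse = ""), decoy), call. = FALSE)
  }

  # multi-mapping peptides: keep the lexicographically smallest accession
  x$protein <- vapply(strsplit(x$protein, ";", fixed = TRUE),
                      function(a) sort(a)[1L], character(1))

  x$final_score <- compute_final_score(x$peptide_prob, x$site_prob)
  x$is_decoy_site <- x$site_residue == decoy
  grp <- paste(x$dataset_id, x$psm_id, sep = "\r")
  x$psm_has_decoy <- as.logical(ave(x$is_decoy_site, grp, FUN = any))
  x$peptidoform_key <- peptidoform_key(x$peptide, x$mods)
  x
}

#' Combined site score
#'
#' The per-site score used throughout the pipeline is the product of the PSM
#' identification probability (e.g. an iProphet probability, or 1 - PEP) and
#' the site localization probability.
#'
#' @param peptide_prob,site_prob numeric vectors in \[0, 1\].
#' @return `peptide_prob * site_prob`.
#' @export
compute_final_score <- function(peptide_prob, site_prob) {
  if (any(is.na(peptide_prob)) || any(peptide_prob < 0) || any(peptide_prob > 1)) {
    stop("peptide_prob must be in [0,1]", call. = FALSE)
  }
  if (any(is.na(site_prob)) || any(site_prob < 0) || any(site_prob > 1)) {
    stop("site_prob must be in [0,1]", call. = FALSE)
  }
  peptide_prob * site_prob
}

#' Canonical peptidoform key
#'
#' A peptidoform is a peptide sequence together with the number and exact
#' positions of its modifications. The key is the sequence followed by the
#' modification tokens sorted by position, so it does not depend on the
#' order the tokens were written in.
#'
#' @param peptide character vector of peptide sequences.
#' @param mods character vector of semicolon-separated `pos:name` tokens.
#' @return character vector of canonical keys.
#' @export
peptidoform_key <- function(peptide, mods) {
  canon <- vapply(strsplit(mods, ";", fixed = TRUE), function(tok) {
    tok <- tok[nzchar(tok)]
    if (length(tok) == 0L) return("")
    pos <- as.integer(sub(":.*$", "", tok))
    paste(tok[order(pos)], collapse = ";")
  }, character(1))
  paste0(peptide, "|", canon)
}
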