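# Collapsing PSM-site records to the peptidoform-site level. A peptidoform
# (peptide sequence + exact modification set) sampled many times yields
# redundant PSM-site rows; four strategies reduce each
# (peptidoform, site) group to one score.

#' Collapse PSM-site records to peptidoform-site level
#'
#' Groups records by (dataset, peptidoform, site position) and reduces each
#' group to a single score:
#' \describe{
#'   \item{max}{the maximum member score; chosen scores for one peptidoform
#'     may come from different PSMs.}
#'   \item{mean}{the arithmetic mean of member scores.}
#'   \item{mm}{each PSM gets the mean of its site scores; the peptidoform's
#'     representative PSM is the one with the largest mean (ties broken by
#'     psm_id), and by default every site of the peptidoform receives that
#'     PSM's mean (`mm_assign = "psm_mean"`). With
#'     `mm_assign = "site_score"` each site instead keeps its own score from
#'     the representative PSM.}
#'   \item{product}{one minus the product of (1 - score) over members,
#'     treating observations as independent accumulating evidence. By
#'     default members are the PSM-sites of the peptidoform-site group;
#'     `product_group = "protein_site"` pools all PSM-sites of the same
#'     protein site instead.}
#' }
#' The conservative decoy flag of a collapsed record is the union of its
#' members' flags, and `psm_support` counts the member PSM-sites.
#'
#' @param records a validated PSM-site data.frame.
#' @param method one of `"max"`, `"mean"`, `"mm"`, `"product"`.
#' @param score_col score column to collapse (`"final_score"` or
#'   `"score_adj"`).
#' @param mm_assign see above; only used by `method = "mm"`.
#' @param product_group see above; only used by `method = "product"`.
#' @return data.frame with one row per (dataset, peptidoform, site),
#'   carrying `collapsed_score`, `psm_support`, `method`, `is_decoy_site`
#'   and `decoy_flag`.
#' @export
collapse_psm_sites <- function(records,
                               method = c("max", "mean", "mm", "product"),
                               score_col = "final_score",
                               mm_assign = c("psm_mean", "site_score"),
                               product_group = c("peptidoform_site", "protein_site")) {
  method <- match.arg(method)
  mm_assign <- match.arg(mm_assign)
  product_group <- match.arg(product_group)
  stopifnot(score_col %in% names(records))
  if (!"decoy_flag" %in% names(records)) {
    records <- mark_conservative_decoys(records)
  }
  score <- records[[score_col]]

  gkey <- if (method == "product" && product_group == "protein_site") {
    paste(records$dataset_id, records$protein, records$protein_pos, sep = "\r")
  } else {
    paste(records$dataset_id, records$peptidoform_key, records$site_pos, sep = "\r")
  }

  collapsed <- switch(method,
    max = ave(score, gkey, FUN = max),
    mean = ave(score, gkey, FUN = mean),
    product = ave(score, gkey, FUN = function(v) 1 - prod(1 - v)),
    mm = {
      psm_key <- paste(records$dataset_id, records$psm_id, sep = "\r")
      psm_mean <- ave(score, psm_key, FUN = mean)
      pform_key <- paste(records$dataset_id, records$peptidoform_key, sep = "\r")
      # representative PSM per peptidoform: max psm_mean, ties by psm_id
      ord <- order(pform_key, -psm_mean, records$psm_id, method = "radix")
      rep_psm <- ave(records$psm_id[ord], pform_key[ord], FUN = function(v) v[1L])
      rep_psm <- rep_psm[order(ord)]         # back to input order
      if (mm_assign == "psm_mean") {
        rep_mean <- psm_mean
        rep_mean[records$psm_id != rep_psm] <- NA_real_
        ave(rep_mean, gkey, FUN = function(v) v[!is.na(v)][1L])
      } else {
        own <- score
        own[records$psm_id != rep_psm] <- NA_real_
        ave(own, gkey, FUN = function(v) v[!is.na(v)][1L])
      }
    }
  )

  support <- ave(rep(1L, nrow(records)), gkey, FUN = length)
  dflag <- as.logical(ave(records$decoy_flag, gkey, FUN = any))

  keep <- !duplicated(gkey)
  out <- records[keep, intersect(
    c("dataset_id", "peptidoform_key", "peptide", "mods", "site_pos",
      "site_residue", "protein", "protein_pos", "is_decoy_site"),
    names(records)), drop = FALSE]
  out$collapsed_score <- collapsed[keep]
  out$psm_support <- support[keep]
  out$decoy_flag <- dflag[keep]
  out$method <- method
  rownames(out) <- NULL
  out
}

#' Collapse peptidoform-sites to unique protein sites
#'
#' One record per (dataset, protein accession, protein position, residue);
#' the score is the maximum over contributing peptidoform-sites and
#' `pform_support` counts them. The conservative decoy flag is again the
#' union over members.
#'
#' @param pform_sites output of [collapse_psm_sites()].
#' @param score_col column holding the collapsed score.
#' @return data.frame of unique protein sites.
#' @export
collapse_protein_sites <- function(pform_sites, score_col = "collapsed_score") {
  stopifnot(score_col %in% names(pform_sites))
  gkey <- paste(pform_sites$dataset_id, pform_sites$protein,
                pform_sites$protein_pos, pform_sites$site_residue, sep = "\r")
  score <- ave(pform_sites[[score_col]], gkey, FUN = max)
  support <- ave(rep(1L, nrow(pform_sites)), gkey, FUN = length)
  dflag <- if ("decoy_flag" %in% names(pform_sites)) {
    as.logical(ave(pform_sites$decoy_flag, gkey, FUN = any))
  } else {
    pform_sites$is_decoy_site
  }
  keep <- !duplicated(gkey)
  out <- pform_sites[keep, intersect(
    c("dataset_id", "protein", "protein_pos", "site_residue", "peptide",
      "site_pos", "is_decoy_site"), names(pform_sites)), drop = FALSE]
  out$collapsed_score <- score[keep]
  out$pform_support <- support[keep]
  out$decoy_flag <- dflag[keep]
  rownames(out) <- NULL
  out
}
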