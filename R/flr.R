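# Decoy-based global FLR. Sites are ranked by score; cumulative
# conservative decoy counts D_n are scaled by the target:decoy residue
# ratio T/A and divided by the number of reported (non-decoy) sites,
# FLR(n) = (D_n * T/A) / (n - D_n), then monotonised bottom-up into a
# q-value for thresholding.

#' Flag every site of a decoy-containing PSM
#'
#' Conservative decoy counting: when any site of a PSM matches the decoy
#' residue, all sites of that PSM count toward the decoy tally used for FLR
#' estimation. The flag (`decoy_flag`) is distinct from `is_decoy_site`,
#' which marks only the decoy-residue row itself and governs removal from
#' reported output.
#'
#' @param records a PSM-site data.frame.
#' @return records with a logical `decoy_flag` column.
#' @export
mark_conservative_decoys <- function(records) {
  if ("psm_has_decoy" %in% names(records)) {
    records$decoy_flag <- records$psm_has_decoy
  } else {
    grp <- paste(records$dataset_id, records$psm_id, sep = "\r")
    records$decoy_flag <- as.logical(ave(records$is_decoy_site, grp, FUN = any))
  }
  records
}

#' Rank sites by score with residue-blind tie-breaking
#'
#' Stable sort by score descending. Ties are ordered alphabetically by
#' peptide sequence, then by site position — never by the modified residue,
#' since any residue-aware ordering would push decoys systematically up or
#' down within a tie and bias the FLR.
#'
#' @param records data.frame with a score column and `peptide` plus a site
#'   position column (`site_pos` or `protein_pos`).
#' @param score_col name of the score column.
#' @return records reordered; row names reset.
#' @export
rank_sites <- function(records, score_col = "final_score") {
  stopifnot(score_col %in% names(records))
  pos_col <- if ("site_pos" %in% names(records)) "site_pos" else "protein_pos"
  ord <- order(-records[[score_col]], records$peptide, records[[pos_col]],
               method = "radix")
  out <- records[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Count target and decoy residues
#'
#' Returns T (total target-residue occurrences), A (decoy-residue
#' occurrences) and their ratio, counted either over the observed unique
#' peptides of a PSM-site table, over an explicit character vector of
#' sequences, or over a FASTA database. The scope matters: the ratio scales
#' decoy counts onto the target scale in the FLR formula.
#'
#' @param x a PSM-site data.frame (unique peptides are counted), a character
#'   vector of sequences, or a FASTA file path.
#' @param targets target residues.
#' @param decoy decoy residue.
#' @return list with elements `T`, `A`, `ratio`.
#' @export
count_residues <- function(x, targets = c("S", "T", "Y"), decoy = "A") {
  seqs <- if (is.data.frame(x)) {
    unique(x$peptide)
  } else if (is.character(x) && length(x) == 1L && file.exists(x)) {
    read_fasta(x)
  } else if (is.character(x)) {
    x
  } else {
    stop("x must be a PSM-site table, sequences, or a FASTA path", call. = FALSE)
  }
  if (length(seqs) == 0L) stop("no sequences to count", call. = FALSE)
  count_char <- function(res) sum(nchar(seqs) - nchar(gsub(res, "", seqs, fixed = TRUE)))
  T_count <- sum(vapply(targets, count_char, numeric(1)))
  A_count <- count_char(decoy)
  if (A_count == 0L) {
    stop("no decoy residues ('", decoy, "') in the counting scope; FLR is undefined",
         call. = FALSE)
  }
  list(T = T_count, A = A_count, ratio = T_count / A_count)
}

#' Decoy-estimated FLR along the ranked list
#'
#' For each rank n with cumulative conservative decoy count D_n:
#' `running_flr = (D_n * T/A) / (n - D_n)`, reflecting that decoy rows are
#' removed from the reported list (hence the subtraction in the
#' denominator) and that decoy counts are normalised to the target scale by
#' T/A. The running FLR is 0 while D_n = 0, set to 1 on an all-decoy
#' prefix, and clipped to \[0, 1\]. `q_flr` is the running minimum taken
#' from the bottom of the list upward, the monotone quantity used for
#' thresholding.
#'
#' @param ranked output of [rank_sites()], with `decoy_flag` set.
#' @param T,A target and decoy residue counts (see [count_residues()]).
#' @return `ranked` with columns `rank`, `cum_decoy`, `running_flr`,
#'   `q_flr` added; `T`, `A` and `ratio` stored as attributes.
#' @export
compute_decoy_flr <- function(ranked, T, A) {
  stopifnot(T > 0, A > 0)
  if (!"decoy_flag" %in% names(ranked)) {
    stop("ranked records lack 'decoy_flag'; run mark_conservative_decoys() first",
         call. = FALSE)
  }
  n <- seq_len(nrow(ranked))
  D <- cumsum(ranked$decoy_flag)
  running <- ifelse(D == 0L, 0,
                    ifelse(n - D == 0L, 1, pmin(1, (D * (T / A)) / (n - D))))
  ranked$rank <- n
  ranked$cum_decoy <- D
  ranked$running_flr <- running
  ranked$q_flr <- rev(cummin(rev(running)))
  attr(ranked, "T") <- T
  attr(ranked, "A") <- A
  attr(ranked, "ratio") <- T / A
  ranked
}

#' Sites passing an FLR threshold
#'
#' Returns the rows whose monotone FLR (`q_flr`) is at or below `alpha`,
#' with decoy-residue rows removed — decoys estimate the error but are
#' known false positives and never reported.
#'
#' @param x an FLR-annotated data.frame (from [compute_decoy_flr()]) or a
#'   fitted [ptm_flr()] object.
#' @param alpha FLR threshold in (0, 1\].
#' @param ... unused.
#' @return data.frame of reported sites.
#' @export
threshold_at <- function(x, alpha, ...) UseMethod("threshold_at")

#' @export
threshold_at.data.frame <- function(x, alpha, ...) {
  stopifnot(alpha > 0, alpha <= 1, "q_flr" %in% names(x))
  keep <- x$q_flr <= alpha
  if ("is_decoy_site" %in% names(x)) keep <- keep & !x$is_decoy_site
  out <- x[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Ground-truth FLR along a ranked list
#'
#' For data with known localization labels, the real FLR at rank n is the
#' proportion of incorrect localizations among the reported (non-decoy)
#' sites in the top n.
#'
#' @param ranked ranked data.frame.
#' @param truth logical vector aligned with `ranked` (TRUE = correctly
#'   localized), or a data.frame with columns `psm_id`, `site_pos`,
#'   `correct` to be joined on.
#' @return numeric vector of real FLR per rank.
#' @export
compute_real_flr <- function(ranked, truth) {
  if (is.data.frame(truth)) {
    key <- paste(ranked$psm_id, ranked$site_pos, sep = "\r")
    tkey <- paste(truth$psm_id, truth$site_pos, sep = "\r")
    idx <- match(key, tkey)
    if (anyNA(idx)) {
      stop("truth labels missing for ", sum(is.na(idx)), " ranked record(s)",
           call. = FALSE)
    }
    correct <- truth$correct[idx]
  } else {
    correct <- truth
    if (length(correct) != nrow(ranked) || anyNA(correct)) {
      stop("truth must label every ranked record", call. = FALSE)
    }
  }
  reported <- if ("is_decoy_site" %in% names(ranked)) !ranked$is_decoy_site
              else rep(TRUE, nrow(ranked))
  cum_rep <- cumsum(reported)
  cum_bad <- cumsum(reported & !correct)
  ifelse(cum_rep == 0L, 0, cum_bad / cum_rep)
}
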