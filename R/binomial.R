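# Binomial score adjustment: penalise sites observed phosphorylated rarely
# relative to how often their protein position is covered, using the chance
# decoy-match probability estimated from the dataset itself.

#' Probability of a chance decoy match per spectrum
#'
#' Estimated as the number of unique decoy (pAla) PSM-site matches divided
#' by the number of unique spectra in the dataset. A decoy PSM-site match is
#' counted once per distinct (spectrum, peptide, site position).
#'
#' @param records a validated PSM-site data.frame.
#' @return a single probability; 0 when there are no decoy matches.
#' @export
estimate_random_match_prob <- function(records) {
  if (nrow(records) == 0L) stop("empty PSM-site table", call. = FALSE)
  dec <- records[records$is_decoy_site, , drop = FALSE]
  n_dec <- nrow(unique(dec[, c("spectrum_id", "peptide", "site_pos")]))
  n_spec <- length(unique(records$spectrum_id))
  n_dec / n_spec
}

#' Per-protein-site observation counts
#'
#' For every protein position carrying at least one phospho observation,
#' counts `s` = the number of PSMs in which the position is observed
#' phosphorylated, and `n` = the number of PSMs whose peptide covers the
#' position at all (phosphorylated or not). Coverage comes from
#' `coverage`, a PSM-level peptide table, when supplied; otherwise it is
#' inferred from the peptide spans of the phospho PSMs themselves, a
#' documented approximation (PSMs of never-phosphorylated peptides covering
#' the position are then invisible).
#'
#' @param records a validated PSM-site data.frame.
#' @param coverage optional data.frame with columns `psm_id`, `peptide`,
#'   `protein`, `protein_start` (1-based position of the peptide's first
#'   residue), one row per PSM.
#' @return data.frame with columns protein, protein_pos, s, n.
#' @export
site_observation_counts <- function(records, coverage = NULL) {
  if (nrow(records) == 0L) {
    return(data.frame(protein = character(0), protein_pos = integer(0),
                      s = integer(0), n = integer(0)))
  }
  sites <- unique(records[, c("protein", "protein_pos")])

  # s: distinct PSMs observing the site phosphorylated
  obs <- unique(records[, c("protein", "protein_pos", "psm_id")])
  s_tab <- table(paste(obs$protein, obs$protein_pos, sep = "\r"))
  sites$s <- as.integer(s_tab[paste(sites$protein, sites$protein_pos, sep = "\r")])

  # covering spans, one per PSM
  if (is.null(coverage)) {
    spans <- unique(data.frame(
      psm_id = records$psm_id,
      protein = records$protein,
      start = records$protein_pos - records$site_pos + 1L,
      len = nchar(records$peptide),
      stringsAsFactors = FALSE
    ))
    spans <- unique(spans[, c("psm_id", "protein", "start", "len")])
  } else {
    stopifnot(all(c("psm_id", "peptide", "protein", "protein_start") %in% names(coverage)))
    spans <- data.frame(
      psm_id = coverage$psm_id,
      protein = coverage$protein,
      start = as.integer(coverage$protein_start),
      len = nchar(coverage$peptide),
      stringsAsFactors = FALSE
    )
    spans <- unique(spans)
  }
  spans$end <- spans$start + spans$len - 1L

  # n = #spans covering the position = #(start <= pos) - #(end < pos),
  # per protein, via sorted start/end vectors
  sites$n <- 0L
  for (prot in unique(sites$protein)) {
    qi <- which(sites$protein == prot)
    sp <- spans[spans$protein == prot, , drop = FALSE]
    starts <- sort(sp$start)
    ends <- sort(sp$end)
    pos <- sites$protein_pos[qi]
    sites$n[qi] <- findInterval(pos, starts) - findInterval(pos - 1L, ends)
  }
  bad <- which(sites$n < sites$s)
  if (length(bad) > 0L) {
    stop(sprintf("site %s:%d is phosphorylated in more PSMs (%d) than cover it (%d); coverage table inconsistent",
                 sites$protein[bad[1L]], sites$protein_pos[bad[1L]],
                 sites$s[bad[1L]], sites$n[bad[1L]]), call. = FALSE)
  }
  rownames(sites) <- NULL
  sites
}

#' Binomial penalty P_s
#'
#' Probability that a site observed phosphorylated `s` times out of `n`
#' covering PSMs would do at least as well by chance, X ~ Binomial(n, p):
#' the upper tail Pr(X >= s), computed through the survival function so it
#' stays accurate for large n. `mode = "pmf"` returns Pr(X = s) instead, a
#' sensitivity-analysis variant.
#'
#' @param s,n integer vectors, 0 <= s <= n.
#' @param p chance match probability in \[0, 1\] (scalar or vector).
#' @param mode `"tail"` (default) or `"pmf"`.
#' @return numeric vector of probabilities.
#' @export
binomial_penalty <- function(s, n, p, mode = c("tail", "pmf")) {
  mode <- match.arg(mode)
  if (any(is.na(s)) || any(is.na(n)) || any(s < 0) || any(n < 0) || any(s > n)) {
    stop("require 0 <= s <= n", call. = FALSE)
  }
  if (any(is.na(p)) || any(p < 0) || any(p > 1)) {
    stop("p must be in [0,1]", call. = FALSE)
  }
  if (mode == "pmf") return(stats::dbinom(s, n, p))
  ifelse(s == 0L, 1, stats::pbinom(s - 1L, n, p, lower.tail = FALSE))
}

#' Build the binomial adjustment context for one dataset
#'
#' @param records a validated PSM-site data.frame (one dataset).
#' @param coverage optional PSM-level coverage table, see
#'   [site_observation_counts()].
#' @param mode penalty mode, see [binomial_penalty()].
#' @return list with elements `p`, `q` = 1 - p, `counts` (per-site s, n) and
#'   `mode`.
#' @export
build_binomial_context <- function(records, coverage = NULL,
                                   mode = c("tail", "pmf")) {
  mode <- match.arg(mode)
  p <- estimate_random_match_prob(records)
  counts <- site_observation_counts(records, coverage = coverage)
  counts$p_s <- binomial_penalty(counts$s, counts$n, p, mode = mode)
  list(p = p, q = 1 - p, counts = counts, mode = mode)
}

#' Adjust site scores by the binomial penalty
#'
#' Multiplies every record's combined score by (1 - P_s) for its protein
#' site, so sites observed phosphorylated rarely relative to their coverage
#' are pushed down the ranked list. The unadjusted score is retained in
#' `final_score`; the adjusted one is added as `score_adj`.
#'
#' @param records a validated PSM-site data.frame.
#' @param context result of [build_binomial_context()] on the same dataset.
#' @return records with columns `p_s` and `score_adj` added.
#' @export
adjust_scores <- function(records, context) {
  key <- paste(records$protein, records$protein_pos, sep = "\r")
  ckey <- paste(context$counts$protein, context$counts$protein_pos, sep = "\r")
  idx <- match(key, ckey)
  if (anyNA(idx)) {
    miss <- which(is.na(idx))[1L]
    stop(sprintf("site %s:%d not present in the binomial context",
                 records$protein[miss], records$protein_pos[miss]),
         call. = FALSE)
  }
  records$p_s <- context$counts$p_s[idx]
  records$score_adj <- records$final_score * (1 - records$p_s)
  records
}
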