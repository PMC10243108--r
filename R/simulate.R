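# Seeded synthetic PSM-site tables with known localization truth. The
# generator works at the score-table level the post-processing consumes:
# no spectra are simulated. Proteins are drawn with a realistic residue
# composition, digested tryptically, and PSMs sample planted phosphosites
# with lognormal abundance; mislocalizations land uniformly on the other
# S/T/Y/A positions of the peptide, which makes the decoy residue a fair
# sample of the error process — the core assumption of decoy-based FLR —
# and makes T/A normalisation exact by construction.

# average amino-acid composition (fractions, UniProt-like)
.aa_freqs <- c(
  A = 0.083, R = 0.056, N = 0.041, D = 0.055, C = 0.014, Q = 0.039,
  E = 0.067, G = 0.071, H = 0.023, I = 0.057, L = 0.097, K = 0.058,
  M = 0.024, F = 0.039, P = 0.047, S = 0.067, T = 0.054, W = 0.011,
  Y = 0.029, V = 0.069
)

#' Synthetic dataset configuration
#'
#' Defaults describe a well-behaved phosphoproteomics run: 20,000 PSMs over
#' 300 proteins, 90% of reported sites correctly localized, clearly
#' separated score distributions for correct and incorrect localizations,
#' and site abundances spread over a lognormal so that true sites are
#' sampled repeatedly while errors scatter.
#'
#' @param n_proteins,protein_length proteome size.
#' @param residue_freqs named residue frequency vector (must include the
#'   decoy residue with non-zero frequency).
#' @param n_psms number of PSMs to draw.
#' @param planted_rate fraction of proteome S/T/Y positions that are
#'   genuinely phosphorylated.
#' @param true_localization_rate probability that a PSM localizes its sites
#'   correctly; a bad PSM mislocalizes every site it carries, so the
#'   expected fraction of incorrect reported sites equals
#'   `1 - true_localization_rate`.
#' @param extra_site_rate probability a PSM carries a second phosphosite
#'   (when its peptide contains another planted site).
#' @param correct_shape,incorrect_shape Beta shape pairs for the per-PSM
#'   score base of correctly and incorrectly localized PSMs. The incorrect
#'   distribution keeps a small right tail: a minority of random matches
#'   score high, which is what frequency-based adjustment exists to demote.
#' @param psm_score_concentration concentration of per-site scores around
#'   their PSM's score base; large values mean site scores within a PSM are
#'   strongly correlated, as observed for probabilistic localization
#'   pipelines.
#' @param peptide_prob_shape Beta shape pair for the PSM identification
#'   probability.
#' @param abundance_sdlog lognormal sd of per-site abundance.
#' @param targets,decoy residue configuration.
#' @param n_datasets number of independent datasets sharing one proteome
#'   and one set of planted sites (abundances and PSMs are redrawn).
#' @param dataset_prefix prefix for dataset ids.
#' @param seed integer seed fixing every draw.
#' @return a config list.
#' @export
synthetic_config <- function(n_proteins = 300, protein_length = 350,
                             residue_freqs = NULL, n_psms = 20000,
                             planted_rate = 0.15,
                             true_localization_rate = 0.9,
                             extra_site_rate = 0.2,
                             correct_shape = c(3.5, 0.9),
                             incorrect_shape = c(0.8, 2.2),
                             psm_score_concentration = 400,
                             peptide_prob_shape = c(40, 1.5),
                             abundance_sdlog = 1,
                             targets = c("S", "T", "Y"), decoy = "A",
                             n_datasets = 1L, dataset_prefix = "synth",
                             seed = 1L) {
  if (is.null(residue_freqs)) residue_freqs <- .aa_freqs
  stopifnot(true_localization_rate >= 0, true_localization_rate <= 1,
            planted_rate > 0, planted_rate <= 1, n_psms >= 1)
  if (!decoy %in% names(residue_freqs) || residue_freqs[[decoy]] <= 0) {
    stop("decoy residue frequency must be positive, otherwise FLR cannot be estimated",
         call. = FALSE)
  }
  list(n_proteins = n_proteins, protein_length = protein_length,
       residue_freqs = residue_freqs / sum(residue_freqs), n_psms = n_psms,
       planted_rate = planted_rate,
       true_localization_rate = true_localization_rate,
       extra_site_rate = extra_site_rate,
       correct_shape = correct_shape, incorrect_shape = incorrect_shape,
       psm_score_concentration = psm_score_concentration,
       peptide_prob_shape = peptide_prob_shape,
       abundance_sdlog = abundance_sdlog,
       targets = targets, decoy = decoy,
       n_datasets = as.integer(n_datasets), dataset_prefix = dataset_prefix,
       seed = as.integer(seed))
}

#' Preset configurations
#'
#' `"separated"` emulates a dataset whose target and decoy score
#' distributions are well separated (high localization specificity);
#' `"overlapping"` emulates one where correct and incorrect localizations
#' score similarly, so few sites survive stringent FLR thresholds.
#'
#' @param name preset name.
#' @param ... overrides passed on to [synthetic_config()].
#' @return a config list.
#' @export
synthetic_preset <- function(name = c("separated", "overlapping"), ...) {
  name <- match.arg(name)
  if (name == "separated") {
    synthetic_config(...)
  } else {
    synthetic_config(true_localization_rate = 0.65,
                     correct_shape = c(2.2, 1.4), incorrect_shape = c(1.8, 1.6),
                     ...)
  }
}

# tryptic peptides (cleave after K/R, 0-1 missed cleavages) containing a
# given position; returns list(start, end) vectors
.tryptic_windows <- function(seq_chars, min_len = 7L, max_len = 35L) {
  n <- length(seq_chars)
  cut_after <- which(seq_chars %in% c("K", "R"))
  bounds <- unique(c(0L, cut_after, n))
  starts <- bounds[-length(bounds)] + 1L
  ends <- bounds[-1L]
  k <- length(starts)
  # 0 and 1 missed cleavages
  st <- c(starts, if (k > 1L) starts[-k])
  en <- c(ends, if (k > 1L) ends[-1L])
  len <- en - st + 1L
  ok <- len >= min_len & len <= max_len
  list(start = st[ok], end = en[ok])
}

#' Generate a synthetic PSM-site table with ground truth
#'
#' Draws a proteome, plants true phosphosites on target residues, then
#' samples PSMs: each PSM picks a planted site (probability proportional to
#' a lognormal abundance) and a tryptic peptide containing it. With
#' probability `true_localization_rate` the PSM is well localized and
#' reports true positions with scores from the "correct" Beta; otherwise
#' the whole PSM is corrupted and each of its sites lands on another
#' S/T/Y/A position of the peptide — decoy in proportion to its sequence
#' frequency — with scores from the "incorrect" Beta. Mislocalization being
#' a PSM-level event is the regime in which conservative decoy flagging
#' (all sites of a decoy-containing PSM count as decoys) is justified. A
#' second planted site in the same peptide is included with probability
#' `extra_site_rate`. Fully reproducible under the config seed.
#'
#' @param config from [synthetic_config()] or [synthetic_preset()].
#' @return list with `records` (validated PSM-site data.frame over all
#'   datasets), `truth` (per record: dataset_id, psm_id, site_pos, correct,
#'   true_protein_pos), `proteome` (named character) and `planted`
#'   (data.frame of true sites).
#' @export
simulate_psm_dataset <- function(config = synthetic_config()) {
  set.seed(config$seed)
  aa <- names(config$residue_freqs)
  proteome_chars <- lapply(seq_len(config$n_proteins), function(i) {
    sample(aa, config$protein_length, replace = TRUE,
           prob = config$residue_freqs)
  })
  proteome <- vapply(proteome_chars, paste, character(1), collapse = "")
  names(proteome) <- sprintf("P%04d", seq_len(config$n_proteins))
  names(proteome_chars) <- names(proteome)

  cand_res <- c(config$targets, config$decoy)

  # planted sites: a fraction of target-residue positions, restricted to
  # those reachable by an acceptable tryptic peptide
  planted <- list()
  windows <- list()
  for (acc in names(proteome)) {
    ch <- proteome_chars[[acc]]
    w <- .tryptic_windows(ch)
    windows[[acc]] <- w
    sty <- which(ch %in% config$targets)
    sty <- sty[stats::runif(length(sty)) < config$planted_rate]
    covered <- vapply(sty, function(pos) any(w$start <= pos & w$end >= pos),
                      logical(1))
    sty <- sty[covered]
    if (length(sty) > 0L) {
      planted[[acc]] <- data.frame(protein = acc, protein_pos = sty,
                                   residue = ch[sty], stringsAsFactors = FALSE)
    }
  }
  planted <- do.call(rbind, planted)
  rownames(planted) <- NULL
  if (is.null(planted) || nrow(planted) < 2L) {
    stop("configuration produced fewer than two plantable sites", call. = FALSE)
  }

  datasets <- lapply(seq_len(config$n_datasets), function(d) {
    .simulate_one_dataset(config, proteome, proteome_chars, windows, planted,
                          dataset_id = paste0(config$dataset_prefix, d))
  })
  records <- do.call(rbind, lapply(datasets, `[[`, "records"))
  truth <- do.call(rbind, lapply(datasets, `[[`, "truth"))
  records <- as_psm_sites(records, targets = config$targets,
                          decoy = config$decoy)
  list(records = records, truth = truth, proteome = proteome,
       planted = planted)
}

.simulate_one_dataset <- function(config, proteome, proteome_chars, windows,
                                  planted, dataset_id) {
  n_sites <- nrow(planted)
  abundance <- stats::rlnorm(n_sites, sdlog = config$abundance_sdlog)
  pick <- sample.int(n_sites, config$n_psms, replace = TRUE,
                     prob = abundance)

  rec <- vector("list", config$n_psms)
  tru <- vector("list", config$n_psms)
  cand_res <- c(config$targets, config$decoy)

  kappa <- config$psm_score_concentration
  site_score <- function(base) {
    # per-site score concentrated around the PSM's score base, so scores
    # within a PSM are strongly correlated
    stats::rbeta(1, kappa * base + 0.5, kappa * (1 - base) + 0.5)
  }

  draw_site <- function(psm_bad, base, true_pep_pos, cand_pos, cand_is_decoy,
                        taken) {
    # localization draw for one modification; returns pos/correct/prob.
    # Mislocalization is a property of the PSM (a bad match corrupts every
    # site it carries — the premise behind conservative decoy flagging).
    # An incorrect localization first picks the residue class (decoy vs
    # target) by the peptide's full S/T/Y/A composition, then a position
    # of that class other than the true site — so errors sample the decoy
    # residue in proportion to its sequence frequency.
    alt <- setdiff(cand_pos, c(true_pep_pos, taken))
    if (!psm_bad || length(alt) == 0L) {
      if (true_pep_pos %in% taken) return(NULL)
      return(list(pos = true_pep_pos, correct = TRUE, prob = site_score(base)))
    }
    p_decoy <- mean(cand_is_decoy)
    alt_dec <- alt[alt %in% cand_pos[cand_is_decoy]]
    alt_tgt <- setdiff(alt, alt_dec)
    pool <- if (stats::runif(1) < p_decoy) {
      if (length(alt_dec) > 0L) alt_dec else alt_tgt
    } else {
      if (length(alt_tgt) > 0L) alt_tgt else alt_dec
    }
    list(pos = pool[sample.int(length(pool), 1L)], correct = FALSE,
         prob = site_score(base))
  }

  for (i in seq_len(config$n_psms)) {
    site <- planted[pick[i], ]
    acc <- site$protein
    w <- windows[[acc]]
    hit <- which(w$start <= site$protein_pos & w$end >= site$protein_pos)
    j <- if (length(hit) > 1L) sample(hit, 1L) else hit
    pstart <- w$start[j]; pend <- w$end[j]
    ch <- proteome_chars[[acc]][pstart:pend]
    peptide <- paste(ch, collapse = "")
    cand_pos <- which(ch %in% cand_res)
    cand_is_decoy <- ch[cand_pos] == config$decoy
    true_pep_pos <- site$protein_pos - pstart + 1L
    psm_bad <- stats::runif(1) >= config$true_localization_rate
    shape <- if (psm_bad) config$incorrect_shape else config$correct_shape
    base <- stats::rbeta(1, shape[1], shape[2])

    sites_i <- list(draw_site(psm_bad, base, true_pep_pos, cand_pos,
                              cand_is_decoy, integer(0)))
    true_pos_i <- site$protein_pos

    # optional second planted site in the same peptide
    if (stats::runif(1) < config$extra_site_rate) {
      others <- planted$protein == acc &
        planted$protein_pos >= pstart & planted$protein_pos <= pend &
        planted$protein_pos != site$protein_pos
      if (any(others)) {
        o <- which(others)
        o <- if (length(o) > 1L) sample(o, 1L) else o
        second <- draw_site(psm_bad, base, planted$protein_pos[o] - pstart + 1L,
                            cand_pos, cand_is_decoy, sites_i[[1L]]$pos)
        if (!is.null(second)) {
          sites_i <- c(sites_i, list(second))
          true_pos_i <- c(true_pos_i, planted$protein_pos[o])
        }
      }
    }

    spec <- sprintf("%s.sp%06d", dataset_id, i)
    pos <- vapply(sites_i, `[[`, integer(1), "pos")
    ord <- order(pos)
    sites_i <- sites_i[ord]
    true_pos_i <- true_pos_i[ord]
    pos <- pos[ord]
    mods <- paste(sprintf("%d:Phospho", pos), collapse = ";")
    pprob <- stats::rbeta(1, config$peptide_prob_shape[1],
                          config$peptide_prob_shape[2])
    rec[[i]] <- data.frame(
      dataset_id = dataset_id, spectrum_id = spec, psm_id = spec,
      peptide = peptide, mods = mods, site_pos = pos,
      site_residue = ch[pos], protein = acc,
      protein_pos = pstart + pos - 1L,
      peptide_prob = pprob,
      site_prob = vapply(sites_i, `[[`, numeric(1), "prob"),
      stringsAsFactors = FALSE
    )
    tru[[i]] <- data.frame(
      dataset_id = dataset_id, psm_id = spec, site_pos = pos,
      correct = vapply(sites_i, `[[`, logical(1), "correct"),
      true_protein_pos = true_pos_i, stringsAsFactors = FALSE
    )
  }
  list(records = do.call(rbind, rec), truth = do.call(rbind, tru))
}

#' Compare decoy-estimated and ground-truth FLR at thresholds
#'
#' Runs the estimation path (conservative decoy flagging, ranking,
#' decoy-based FLR with the observed-peptide residue ratio) and, for each
#' threshold, reports the estimated FLR at the cutoff rank alongside the
#' real FLR computed from the truth labels.
#'
#' @param records a validated PSM-site data.frame (one or more datasets;
#'   evaluated pooled).
#' @param truth truth table as returned by [simulate_psm_dataset()].
#' @param alphas FLR thresholds to evaluate.
#' @param score_col score column to rank by.
#' @return data.frame with one row per alpha: number of reported sites,
#'   cumulative decoy-flag count, estimated and real FLR at the cutoff.
#' @export
evaluate_recovery <- function(records, truth, alphas = c(0.01, 0.05),
                              score_col = "final_score") {
  records <- mark_conservative_decoys(records)
  ranked <- rank_sites(records, score_col)
  cnt <- count_residues(ranked)
  ranked <- compute_decoy_flr(ranked, cnt$T, cnt$A)
  tkey <- paste(truth$dataset_id, truth$psm_id, truth$site_pos, sep = "\r")
  rkey <- paste(ranked$dataset_id, ranked$psm_id, ranked$site_pos, sep = "\r")
  correct <- truth$correct[match(rkey, tkey)]
  if (anyNA(correct)) stop("truth labels missing for ranked records", call. = FALSE)
  real <- compute_real_flr(ranked, correct)

  res <- lapply(alphas, function(a) {
    pass <- which(ranked$q_flr <= a)
    if (length(pass) == 0L) {
      return(data.frame(alpha = a, n_reported = 0L, cum_decoy = 0L,
                        est_flr = NA_real_, real_flr = NA_real_))
    }
    cut <- max(pass)
    reported <- !ranked$is_decoy_site[seq_len(cut)]
    data.frame(alpha = a, n_reported = sum(reported),
               cum_decoy = ranked$cum_decoy[cut],
               est_flr = ranked$q_flr[cut], real_flr = real[cut])
  })
  do.call(rbind, res)
}
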