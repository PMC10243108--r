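# The main entry point: run the post-processing chain on one dataset's
# PSM-site table and return a classed object holding the FLR-annotated
# ranked site list.

#' Fit the decoy-FLR post-processing model to a PSM-site table
#'
#' Runs the full chain on one dataset: optional binomial score adjustment,
#' collapsing to the requested reporting level, conservative decoy
#' flagging, residue-blind ranking, and decoy-based FLR estimation with
#' q-value style monotonisation.
#'
#' @param records a validated PSM-site data.frame ([as_psm_sites()] or
#'   [read_psm_table()]); a single dataset.
#' @param adjust apply the binomial frequency adjustment before collapsing.
#' @param collapse collapsing strategy (`"max"`, `"mm"`, `"mean"`,
#'   `"product"`) or `"none"` to stay at PSM-site level.
#' @param level reporting level: `"peptidoform"` (default) or `"protein"`
#'   (peptidoform-sites uniquified per protein position). Ignored when
#'   `collapse = "none"`.
#' @param targets,decoy residue configuration.
#' @param binomial_mode penalty mode, see [binomial_penalty()].
#' @param coverage optional PSM-level coverage table, see
#'   [site_observation_counts()].
#' @param ratio_source where T/A comes from: `"observed"` (unique observed
#'   peptides), `"fixed"` (supply `ratio`), `"fasta"` (supply `fasta`).
#' @param ratio fixed T/A ratio when `ratio_source = "fixed"`.
#' @param fasta FASTA path when `ratio_source = "fasta"`.
#' @param alphas FLR thresholds reported by `summary()`.
#' @return an object of class `"ptm_flr"` with the FLR table in `$table`.
#' @seealso [threshold_at()], [plot.ptm_flr()], [simulate_psm_dataset()]
#' @examples
#' sim <- simulate_psm_dataset(synthetic_config(n_proteins = 40, n_psms = 800))
#' fit <- ptm_flr(sim$records)
#' summary(fit)
#' head(threshold_at(fit, 0.05))
#' @export
ptm_flr <- function(records, adjust = TRUE,
                    collapse = c("max", "mm", "mean", "product", "none"),
                    level = c("peptidoform", "protein"),
                    targets = c("S", "T", "Y"), decoy = "A",
                    binomial_mode = c("tail", "pmf"),
                    coverage = NULL,
                    ratio_source = c("observed", "fixed", "fasta"),
                    ratio = NULL, fasta = NULL,
                    alphas = c(0.01, 0.05)) {
  collapse <- match.arg(collapse)
  level <- match.arg(level)
  binomial_mode <- match.arg(binomial_mode)
  ratio_source <- match.arg(ratio_source)
  if (nrow(records) == 0L) stop("empty PSM-site table", call. = FALSE)
  if (length(unique(records$dataset_id)) > 1L) {
    stop("ptm_flr() fits one dataset at a time; see combine_datasets() for meta-analysis",
         call. = FALSE)
  }
  cl <- match.call()

  context <- NULL
  if (adjust) {
    context <- build_binomial_context(records, coverage = coverage,
                                      mode = binomial_mode)
    records <- adjust_scores(records, context)
    score_col <- "score_adj"
  } else {
    score_col <- "final_score"
  }
  records <- mark_conservative_decoys(records)

  tab <- if (collapse == "none") {
    records
  } else {
    pf <- collapse_psm_sites(records, method = collapse, score_col = score_col)
    if (level == "protein") collapse_protein_sites(pf) else pf
  }
  rank_col <- if (collapse == "none") score_col else "collapsed_score"

  counts <- switch(ratio_source,
    observed = count_residues(records, targets = targets, decoy = decoy),
    fixed = {
      stopifnot(is.numeric(ratio), ratio > 0)
      list(T = ratio, A = 1, ratio = ratio)
    },
    fasta = count_residues(fasta, targets = targets, decoy = decoy)
  )

  ranked <- rank_sites(tab, rank_col)
  ranked <- compute_decoy_flr(ranked, counts$T, counts$A)

  structure(list(
    table = ranked, score_col = rank_col, context = context,
    n_psm_sites = nrow(records), T = counts$T, A = counts$A,
    ratio = counts$ratio, adjust = adjust, collapse = collapse,
    level = level, targets = targets, decoy = decoy, alphas = alphas,
    call = cl
  ), class = "ptm_flr")
}

#' @export
print.ptm_flr <- function(x, ...) {
  cat("Decoy-based FLR fit\n")
  cat(sprintf("  input: %d PSM-site records; reporting level: %s (collapse: %s)\n",
              x$n_psm_sites, if (x$collapse == "none") "psm-site" else x$level,
              x$collapse))
  cat(sprintf("  binomial adjustment: %s\n", if (x$adjust) "yes" else "no"))
  cat(sprintf("  T = %d, A = %d target/decoy residues (ratio %.3f)\n",
              round(x$T), round(x$A), x$ratio))
  cat(sprintf("  %d ranked sites, %d decoy-flagged\n",
              nrow(x$table), sum(x$table$decoy_flag)))
  invisible(x)
}

#' @export
summary.ptm_flr <- function(object, alphas = object$alphas, ...) {
  counts <- vapply(alphas, function(a) nrow(threshold_at(object, a)),
                   numeric(1))
  out <- list(
    fit = object,
    thresholds = data.frame(alpha = alphas, n_sites = as.integer(counts))
  )
  class(out) <- "summary.ptm_flr"
  out
}

#' @export
print.summary.ptm_flr <- function(x, ...) {
  print(x$fit)
  cat("  sites reported at FLR thresholds (decoys removed):\n")
  for (i in seq_len(nrow(x$thresholds))) {
    cat(sprintf("    %4.1f%% FLR: %d sites\n",
                100 * x$thresholds$alpha[i], x$thresholds$n_sites[i]))
  }
  invisible(x)
}

#' @export
threshold_at.ptm_flr <- function(x, alpha, ...) {
  threshold_at(x$table, alpha)
}

#' FLR curve of a fitted object
#'
#' Plots the running FLR (grey) and its monotonised q-value (solid) against
#' rank in the score-ordered site list, with the requested thresholds as
#' horizontal guides.
#'
#' @param x a `ptm_flr` fit.
#' @param alphas thresholds to mark.
#' @param ... passed to [plot()].
#' @export
plot.ptm_flr <- function(x, alphas = x$alphas, ...) {
  tab <- x$table
  graphics::plot(tab$rank, tab$running_flr, type = "l", col = "grey60",
       xlab = "rank (score-ordered sites)", ylab = "pAla FLR", ...)
  graphics::lines(tab$rank, tab$q_flr, col = "black", lwd = 2)
  graphics::abline(h = alphas, lty = 3, col = "red3")
  graphics::legend("topleft", c("running FLR", "monotone (q)"),
                   col = c("grey60", "black"), lwd = c(1, 2), bty = "n")
  invisible(x)
}
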