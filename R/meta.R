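# Cross-study meta-analysis. Scores are never compared across datasets —
# only per-dataset FLR status crosses the dataset boundary. Decoy-residue
# sites are carried through the catalogue (class-labelled by the same
# rules) so that a class-level FLR can be computed, and dropped only at
# final reporting.

#' Combine per-dataset FLR-annotated protein-site lists
#'
#' Builds one row per (protein, position, residue) across datasets,
#' recording in which datasets the site passes the strict (default 1%) and
#' loose (default 5%) FLR thresholds, and keeping the best (lowest)
#' per-dataset q-value as the site's provenance. Decoy-residue rows are
#' retained for class-level FLR accounting.
#'
#' @param per_dataset named list, dataset id -> FLR-annotated protein-site
#'   data.frame (columns `protein`, `protein_pos`, `site_residue`, `q_flr`,
#'   `is_decoy_site`).
#' @param strict_alpha,loose_alpha the two FLR thresholds.
#' @return data.frame of meta sites with columns `protein`, `protein_pos`,
#'   `site_residue`, `is_decoy_site`, `n_strict`, `n_loose`,
#'   `datasets_strict`, `datasets_loose`, `best_q`.
#' @export
combine_datasets <- function(per_dataset, strict_alpha = 0.01,
                             loose_alpha = 0.05) {
  stopifnot(is.list(per_dataset), length(per_dataset) > 0L)
  ids <- names(per_dataset)
  if (is.null(ids) || any(!nzchar(ids))) {
    stop("per_dataset must be a named list keyed by dataset id", call. = FALSE)
  }
  if (anyDuplicated(ids)) stop("duplicate dataset id in input", call. = FALSE)

  rows <- lapply(ids, function(id) {
    df <- per_dataset[[id]]
    need <- c("protein", "protein_pos", "site_residue", "q_flr", "is_decoy_site")
    miss <- setdiff(need, names(df))
    if (length(miss) > 0L) {
      stop("dataset '", id, "' lacks column(s): ", paste(miss, collapse = ", "),
           call. = FALSE)
    }
    # best q per site within the dataset
    key <- paste(df$protein, df$protein_pos, df$site_residue, sep = "\r")
    best <- ave(df$q_flr, key, FUN = min)
    keep <- !duplicated(key)
    data.frame(dataset_id = id,
               protein = df$protein[keep], protein_pos = df$protein_pos[keep],
               site_residue = df$site_residue[keep],
               is_decoy_site = df$is_decoy_site[keep],
               q_flr = best[keep], stringsAsFactors = FALSE)
  })
  long <- do.call(rbind, rows)

  key <- paste(long$protein, long$protein_pos, long$site_residue, sep = "\r")
  strict <- long$q_flr <= strict_alpha
  loose <- long$q_flr <= loose_alpha
  agg <- function(v, f) ave(v, key, FUN = f)
  n_strict <- as.integer(agg(as.integer(strict), sum))
  n_loose <- as.integer(agg(as.integer(loose), sum))
  best_q <- agg(long$q_flr, min)
  ds_sets <- function(flag) {
    ids_in <- long$dataset_id
    ids_in[!flag] <- NA_character_
    vapply(split(ids_in, key), function(v) {
      paste(sort(v[!is.na(v)]), collapse = ",")
    }, character(1))[key]
  }
  datasets_strict <- ds_sets(strict)
  datasets_loose <- ds_sets(loose)

  keep <- !duplicated(key)
  out <- data.frame(
    protein = long$protein[keep], protein_pos = long$protein_pos[keep],
    site_residue = long$site_residue[keep],
    is_decoy_site = long$is_decoy_site[keep],
    n_strict = n_strict[keep], n_loose = n_loose[keep],
    datasets_strict = datasets_strict[keep],
    datasets_loose = datasets_loose[keep],
    best_q = best_q[keep], stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Assign Gold/Silver/Bronze confidence classes
#'
#' Gold: the site passes the strict FLR threshold in at least `gold_min`
#' datasets. Silver: in at least one but fewer than `gold_min`. Bronze: any
#' other site passing the loose threshold in at least one dataset. All
#' remaining sites are classed `"none"`.
#'
#' @param meta_sites output of [combine_datasets()].
#' @param gold_min minimum number of strict-threshold datasets for Gold.
#' @return `meta_sites` with a `confidence_class` column.
#' @export
classify_gsb <- function(meta_sites, gold_min = 2L) {
  stopifnot(gold_min >= 1L)
  cls <- rep("none", nrow(meta_sites))
  cls[meta_sites$n_loose >= 1L] <- "Bronze"
  cls[meta_sites$n_strict >= 1L & meta_sites$n_strict < gold_min] <- "Silver"
  cls[meta_sites$n_strict >= gold_min] <- "Gold"
  meta_sites$confidence_class <- cls
  meta_sites
}

#' Class-level FLR from retained decoy sites
#'
#' For each confidence class, the decoy-residue meta-site count is scaled
#' by the target:decoy ratio and divided by the target meta-site count:
#' `FLR(class) = (#decoy sites in class * ratio) / (#target sites in class)`.
#'
#' @param meta_sites class-labelled output of [classify_gsb()].
#' @param ratio target:decoy residue ratio (T/A) used for normalisation.
#' @return named numeric vector over classes present (NA when a class has
#'   no target sites).
#' @export
class_flr <- function(meta_sites, ratio) {
  stopifnot(is.numeric(ratio), ratio > 0)
  classes <- c("Gold", "Silver", "Bronze")
  out <- vapply(classes, function(cl) {
    in_cl <- meta_sites$confidence_class == cl
    n_dec <- sum(in_cl & meta_sites$is_decoy_site)
    n_tgt <- sum(in_cl & !meta_sites$is_decoy_site)
    if (n_tgt == 0L) NA_real_ else (n_dec * ratio) / n_tgt
  }, numeric(1))
  names(out) <- classes
  out
}

#' Unique protein sites above a fixed score cut
#'
#' The traditional alternative to FLR thresholding: the union across
#' datasets of target protein sites whose collapsed score reaches
#' `score_cut` in at least one dataset.
#'
#' @param per_dataset named list of protein-site data.frames with columns
#'   `protein`, `protein_pos`, `site_residue`, `collapsed_score` and
#'   optionally `is_decoy_site`.
#' @param score_cut score threshold in \[0, 1\].
#' @return data.frame of unique target protein sites passing the cut.
#' @export
score_threshold_catalogue <- function(per_dataset, score_cut) {
  stopifnot(is.list(per_dataset), score_cut >= 0, score_cut <= 1)
  rows <- lapply(per_dataset, function(df) {
    keep <- df$collapsed_score >= score_cut
    if ("is_decoy_site" %in% names(df)) keep <- keep & !df$is_decoy_site
    df[keep, c("protein", "protein_pos", "site_residue"), drop = FALSE]
  })
  long <- do.call(rbind, rows)
  out <- unique(long)
  rownames(out) <- NULL
  out
}
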