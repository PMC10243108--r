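# End-to-end runner: adjust -> collapse -> FLR -> (optional) meta over one
# or more input tables, with versioned TSV outputs and a JSON manifest of
# parameters and row counts at every stage.

#' Run the full post-processing pipeline
#'
#' Executes the chain for each input table and, when more than one dataset
#' is given, the cross-dataset meta-analysis. Outputs are written as TSV
#' under `out_dir` together with `manifest.json` recording the parameters
#' (including the exact T, A and ratio used for FLR) and the row counts at
#' each stage.
#'
#' @param config a named list (or path to a YAML file) with entries:
#'   `inputs` (character vector of TSV paths, or a named list dataset id ->
#'   path), `dialect`, `targets`, `decoy`, `adjust` (logical),
#'   `binomial_mode`, `collapse`, `level`, `alphas`, `ratio_source`,
#'   `ratio`, `fasta`, `meta` (logical; default TRUE when >1 input),
#'   `gold_min`, `strict_alpha`, `loose_alpha`, `meta_ratio`. Missing
#'   entries take the defaults of [ptm_flr()] / [classify_gsb()].
#' @param out_dir output directory, created if needed.
#' @return the manifest list, invisibly.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config) && length(config) == 1L) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("reading a YAML config requires the yaml package", call. = FALSE)
    }
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config), !is.null(config$inputs))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  cfg <- function(key, default) if (is.null(config[[key]])) default else config[[key]]
  dialect <- cfg("dialect", "generic")
  targets <- cfg("targets", c("S", "T", "Y"))
  decoy <- cfg("decoy", "A")
  adjust <- isTRUE(cfg("adjust", TRUE))
  binomial_mode <- cfg("binomial_mode", "tail")
  collapse <- cfg("collapse", "max")
  level <- cfg("level", "peptidoform")
  alphas <- cfg("alphas", c(0.01, 0.05))
  ratio_source <- cfg("ratio_source", "observed")

  inputs <- config$inputs
  if (is.null(names(inputs))) {
    names(inputs) <- sub("\\.[^.]*$", "", basename(unlist(inputs)))
  }

  stage <- "read"
  manifest <- list(parameters = list(
    dialect = dialect, targets = targets, decoy = decoy, adjust = adjust,
    binomial_mode = binomial_mode, collapse = collapse, level = level,
    alphas = alphas, ratio_source = ratio_source
  ), datasets = list())

  per_dataset <- list()
  fits <- list()
  for (id in names(inputs)) {
    res <- tryCatch({
      stage <- "read"
      recs <- read_psm_table(inputs[[id]], dialect = dialect,
                             targets = targets, decoy = decoy)
      stage <- "flr"
      fit <- ptm_flr(recs, adjust = adjust, collapse = collapse,
                     level = if (length(inputs) > 1L) "protein" else level,
                     targets = targets, decoy = decoy,
                     binomial_mode = binomial_mode,
                     ratio_source = ratio_source,
                     ratio = config$ratio, fasta = config$fasta,
                     alphas = alphas)
      stage <- "write"
      write_site_table(fit$table, file.path(out_dir, paste0(id, "_sites.tsv")),
                       include_decoys = TRUE)
      for (a in alphas) {
        write_site_table(threshold_at(fit, a),
                         file.path(out_dir, sprintf("%s_sites_flr%g.tsv", id, a)))
      }
      fit
    }, error = function(e) {
      stop(sprintf("pipeline failed for dataset '%s' at stage '%s': %s",
                   id, stage, conditionMessage(e)), call. = FALSE)
    })
    fits[[id]] <- res
    per_dataset[[id]] <- res$table
    manifest$datasets[[id]] <- list(
      input = unname(inputs[[id]]),
      n_psm_sites = res$n_psm_sites,
      n_ranked_sites = nrow(res$table),
      T = res$T, A = res$A, ratio = res$ratio,
      n_at_alpha = stats::setNames(
        lapply(alphas, function(a) nrow(threshold_at(res, a))),
        paste0("alpha_", alphas))
    )
  }

  do_meta <- isTRUE(cfg("meta", length(inputs) > 1L))
  if (do_meta) {
    stage <- "meta"
    strict_alpha <- cfg("strict_alpha", 0.01)
    loose_alpha <- cfg("loose_alpha", 0.05)
    gold_min <- cfg("gold_min", 2L)
    meta_ratio <- cfg("meta_ratio",
                      mean(vapply(fits, `[[`, numeric(1), "ratio")))
    meta <- combine_datasets(per_dataset, strict_alpha = strict_alpha,
                             loose_alpha = loose_alpha)
    meta <- classify_gsb(meta, gold_min = gold_min)
    flr_by_class <- class_flr(meta, ratio = meta_ratio)
    write_site_table(meta, file.path(out_dir, "meta_sites.tsv"),
                     include_decoys = TRUE)
    manifest$meta <- list(
      gold_min = gold_min, strict_alpha = strict_alpha,
      loose_alpha = loose_alpha, ratio = meta_ratio,
      n_sites = nrow(meta),
      class_counts = as.list(table(meta$confidence_class[!meta$is_decoy_site])),
      class_decoys = as.list(table(meta$confidence_class[meta$is_decoy_site])),
      class_flr = as.list(flr_by_class)
    )
  }

  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
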