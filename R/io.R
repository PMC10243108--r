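# Tabular input/output. The canonical exchange format is a TSV with the
# columns in PSM_SITE_COLUMNS; "tpp" and "pd" dialects rename pipeline-
# specific headers onto it.

# dialect -> canonical-name = source-column map. psm_id falls back to the
# spectrum id when the source has no separate PSM key (one accepted PSM per
# spectrum in these pipelines).
.dialect_maps <- list(
  generic = c(
    dataset_id = "dataset_id", spectrum_id = "spectrum_id", psm_id = "psm_id",
    peptide = "peptide", mods = "mods", site_pos = "site_pos",
    site_residue = "site_residue", protein = "protein",
    protein_pos = "protein_pos", peptide_prob = "peptide_prob",
    site_prob = "site_prob"
  ),
  tpp = c(
    dataset_id = "dataset", spectrum_id = "spectrum", psm_id = "spectrum",
    peptide = "peptide", mods = "modifications", site_pos = "site",
    site_residue = "residue", protein = "protein",
    protein_pos = "protein_position", peptide_prob = "iprophet_probability",
    site_prob = "ptmprophet_probability"
  ),
  pd = c(
    dataset_id = "dataset", spectrum_id = "spectrum", psm_id = "spectrum",
    peptide = "sequence", mods = "modifications", site_pos = "site",
    site_residue = "residue", protein = "protein",
    protein_pos = "protein_position", peptide_prob = "PEP",
    site_prob = "ptmRS_probability"
  )
)

#' Read a PSM-site table
#'
#' Reads a tab-separated PSM-site export and returns a validated PSM-site
#' data.frame (see [as_psm_sites()]). The `tpp` dialect expects
#' PTMProphet-style per-site probabilities with an iProphet peptide
#' probability; the `pd` dialect expects ptmRS site probabilities (on a
#' 0-100 scale) with the peptide probability computed as 1 - PEP; `generic`
#' is the package's canonical column set.
#'
#' @param path path to a TSV file.
#' @param dialect one of `"generic"`, `"tpp"`, `"pd"`.
#' @param targets,decoy residue configuration passed to [as_psm_sites()].
#' @return a validated PSM-site data.frame (possibly with zero rows).
#' @export
read_psm_table <- function(path, dialect = c("generic", "tpp", "pd"),
                           targets = c("S", "T", "Y"), decoy = "A") {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE,
                           stringsAsFactors = FALSE)
  map <- .dialect_maps[[dialect]]
  missing_cols <- setdiff(unname(map), names(raw))
  if (length(missing_cols) > 0L) {
    stop(sprintf("input lacks required column(s) for dialect '%s': %s",
                 dialect, paste(unique(missing_cols), collapse = ", ")),
         call. = FALSE)
  }
  out <- as.data.frame(lapply(map, function(src) raw[[src]]),
                       stringsAsFactors = FALSE)
  names(out) <- names(map)
  for (col in c("peptide_prob", "site_prob")) {
    val <- suppressWarnings(as.numeric(out[[col]]))
    bad <- which(is.na(val) & nzchar(out[[col]]))
    if (length(bad) > 0L) {
      stop(sprintf("cannot parse %s at row %d: '%s'", col, bad[1L],
                   out[[col]][bad[1L]]), call. = FALSE)
    }
    out[[col]] <- val
  }
  if (dialect == "pd" && nrow(out) > 0L) {
    out$peptide_prob <- 1 - out$peptide_prob       # column held PEP
    out$site_prob <- out$site_prob / 100           # ptmRS reports percent
  }
  as_psm_sites(out, targets = targets, decoy = decoy)
}

#' Write a site table
#'
#' Writes records as TSV with a deterministic column order. At reporting
#' level decoy-residue rows are removed by default, matching the convention
#' that decoy matches are known false positives dropped from final outputs;
#' set `include_decoys = TRUE` to keep them (e.g. for meta-analysis input,
#' which needs decoys for class-level FLR). Numeric columns are written with
#' enough digits to round-trip exactly.
#'
#' @param records a data.frame at any reporting level.
#' @param path output path.
#' @param level one of `"psm_site"`, `"peptidoform_site"`, `"protein_site"`;
#'   recorded for the reader, not used to reshape.
#' @param include_decoys keep rows whose own residue is the decoy.
#' @return the path, invisibly.
#' @export
write_site_table <- function(records, path,
                             level = c("psm_site", "peptidoform_site", "protein_site"),
                             include_decoys = FALSE) {
  level <- match.arg(level)
  if (!include_decoys && "is_decoy_site" %in% names(records)) {
    records <- records[!records$is_decoy_site, , drop = FALSE]
  }
  out <- records
  for (col in names(out)) {
    if (is.double(out[[col]])) out[[col]] <- sprintf("%.17g", out[[col]])
  }
  ok <- tryCatch({
    utils::write.table(out, file = path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("cannot write ", path, ": ", conditionMessage(ok),
                        call. = FALSE)
  invisible(path)
}

#' Map peptides onto protein positions by exact substring search
#'
#' Optional helper for inputs lacking protein coordinates. Each peptide is
#' located in the supplied protein sequences; if it occurs in several
#' proteins the lexicographically smallest accession is the representative,
#' and if it occurs several times within one protein the first occurrence is
#' used. Both choices are deterministic, not biological claims.
#'
#' @param peptides character vector.
#' @param proteins named character vector of protein sequences, or a FASTA
#'   path (read with Biostrings).
#' @return data.frame with columns peptide, protein, start (1-based).
#' @export
map_peptides_to_proteins <- function(peptides, proteins) {
  if (is.character(proteins) && length(proteins) == 1L && file.exists(proteins)) {
    proteins <- read_fasta(proteins)
  }
  stopifnot(is.character(proteins), !is.null(names(proteins)))
  acc <- sort(names(proteins))
  res <- lapply(unique(peptides), function(pep) {
    for (a in acc) {
      hit <- regexpr(pep, proteins[[a]], fixed = TRUE)
      if (hit > 0L) {
        return(data.frame(peptide = pep, protein = a, start = as.integer(hit),
                          stringsAsFactors = FALSE))
      }
    }
    data.frame(peptide = pep, protein = NA_character_, start = NA_integer_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

# FASTA input for count_residues()/map_peptides_to_proteins(); accession is
# the first whitespace-delimited token of the header.
read_fasta <- function(path) {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    stop("reading FASTA requires the Biostrings package", call. = FALSE)
  }
  seqs <- Biostrings::readAAStringSet(path)
  out <- as.character(seqs)
  names(out) <- sub("\\s.*$", "", names(seqs))
  out
}
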