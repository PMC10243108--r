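# Builders for small in-code fixtures.

# One PSM-site row per element of site_pos; peptide positions are 1-based.
psm_rows <- function(psm_id, peptide, site_pos, site_prob,
                     peptide_prob = 1, protein = "P1", protein_start = 11,
                     dataset_id = "d1", spectrum_id = psm_id) {
  data.frame(
    dataset_id = dataset_id, spectrum_id = spectrum_id, psm_id = psm_id,
    peptide = peptide,
    mods = paste(sprintf("%d:Phospho", site_pos), collapse = ";"),
    site_pos = as.integer(site_pos),
    site_residue = substring(peptide, site_pos, site_pos),
    protein = protein,
    protein_pos = protein_start + as.integer(site_pos) - 1L,
    peptide_prob = peptide_prob, site_prob = site_prob,
    stringsAsFactors = FALSE
  )
}

make_records <- function(..., targets = c("S", "T", "Y"), decoy = "A") {
  as_psm_sites(do.call(rbind, list(...)), targets = targets, decoy = decoy)
}

# a small validated table: three PSMs on one peptide, one carrying a decoy
tiny_records <- function() {
  make_records(
    psm_rows("ps1", "SSTAYK", c(1, 3), c(0.9, 0.8)),
    psm_rows("ps2", "SSTAYK", c(1, 4), c(0.7, 0.6)),   # position 4 is A
    psm_rows("ps3", "SSTAYK", 5, 0.95)
  )
}

# write a canonical TSV and return its path
write_generic_tsv <- function(df, path = tempfile(fileext = ".tsv")) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# small simulated fixture shared across tests (cached per session)
default_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_psm_dataset(
        synthetic_config(n_proteins = 80, n_psms = 4000, seed = 1))
    }
    cache
  }
})
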