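# In-code fixtures shared across test files.

# Minimal contact table builder: one row per residue.
contact_rows <- function(structure_id, ligand_instance, chain, domain_id,
                         residues, n_contacts, domain_db = "CATH",
                         domain_family = domain_id) {
  tibble::tibble(
    structure_id = structure_id, ligand_instance = ligand_instance,
    chain = chain, residue = residues, domain_id = domain_id,
    domain_db = domain_db, n_contacts = n_contacts,
    domain_family = domain_family)
}

# A contact table realizing given contact fractions (scaled to 300 total
# contacts so even a 1% domain supports 3 residues), each domain touching
# via `n_res` residues.
contacts_for_fractions <- function(ligand_instance, fractions,
                                   n_res = 3, structure_id = "STRX",
                                   chain = "A") {
  counts <- round(fractions * 300)
  counts[1] <- 300 - sum(counts[-1])
  out <- list()
  base <- 0L
  for (d in seq_along(fractions)) {
    per <- rep(counts[d] %/% n_res, n_res)
    per[1] <- per[1] + counts[d] %% n_res
    out[[d]] <- contact_rows(structure_id, ligand_instance, chain,
                             paste0("D", d), base + seq_len(n_res), per)
    base <- base + n_res
  }
  dplyr::bind_rows(out)
}

# Small cognate table; ec entries given as comma strings.
make_cognates <- function(ids, smiles, ecs, cofactor = FALSE) {
  tibble::tibble(cognate_id = ids, name = ids, smiles = smiles,
                 ec_ids = strsplit(ecs, ","), is_cofactor = cofactor)
}

withr_local_tsv <- function(df) {
  path <- tempfile(fileext = ".tsv")
  readr::write_tsv(df, path)
  path
}

required_cols_present <- function(df) {
  c("structure_id", "ligand_instance", "chain", "residue", "domain_id",
    "domain_db", "n_contacts") %in% names(df)
}

# Independent mode rules, written directly from the printed inequalities.
expected_mode <- function(f, all_f) {
  if (length(all_f) == 1) return("exclusive")
  if (f < 0.10) return("minor")
  nonminor <- all_f[all_f >= 0.10]
  if (length(nonminor) == 1) {
    if (f >= 0.90) "dominant" else "major"
  } else {
    if (f >= 0.50) "major_partner" else "partner"
  }
}
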