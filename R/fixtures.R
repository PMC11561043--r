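#' The worked-example molecule set
#'
#' Four small molecules used throughout the documentation and acceptance
#' checks: catechol and its cognate 3-chlorocatechol (an exclusive
#' beta-barrel binding site), and S-hexylglutathione with its cognate
#' (R)-S-lactoylglutathione (a dimer-interface binding site). Their PARITY
#' similarities have closed forms under the Jaccard normalization:
#' 8/9 = 0.89 for the catechol pair and 23/28 = 0.82 for the glutathione
#' pair.
#'
#' @return A named list of `molecule` objects: `catechol`,
#'   `chlorocatechol`, `hexylglutathione`, `lactoylglutathione`.
#' @export
worked_example_molecules <- function() {
  smiles <- c(
    catechol = "Oc1ccccc1O",
    chlorocatechol = "Oc1cccc(Cl)c1O",
    hexylglutathione =
      "CCCCCCSC[C@@H](C(=O)NCC(=O)O)NC(=O)CC[C@@H](C(=O)O)N",
    lactoylglutathione =
      "C[C@@H](O)C(=O)SC[C@@H](C(=O)NCC(=O)O)NC(=O)CC[C@@H](C(=O)O)N")
  mapply(parse_smiles, smiles, names(smiles), SIMPLIFY = FALSE)
}

#' A deterministic synthetic ligand library
#'
#' Builds a diverse small-molecule SMILES library from homologous series
#' (alkanes, alkanols, amines, thiols, acids, amides, ethers,
#' chloroalkanes, terminal alkenes), mono- and di-substituted benzenes,
#' and cycloalkanes. Members of a homologous series have closed-form
#' pairwise PARITY scores (for two chain molecules with n < m heavy atoms
#' sharing the smaller as a substructure, n/m), which gives analytic
#' expectations in tests. Duplicated structures are removed on canonical
#' SMILES.
#'
#' @param n_min Minimum library size to guarantee (default 200).
#' @return A tibble with columns `id`, `smiles`.
#' @export
fixture_ligand_library <- function(n_min = 200) {
  smiles <- character(0)
  groups <- c("", "O", "N", "S", "Cl", "C(=O)O", "C(=O)N", "OC")
  for (k in 1:15) {
    for (g in groups) smiles <- c(smiles, paste0(strrep("C", k), g))
  }
  for (k in 2:13) smiles <- c(smiles, paste0(strrep("C", k), "C=C"))
  for (k in 1:10) {
    smiles <- c(smiles,
                paste0("OC(=O)", strrep("C", k), "C(=O)O"),  # diacids
                paste0("CC(C)", strrep("C", k)),             # branched alkanes
                paste0("OC", strrep("C", k), "CO"))          # diols
  }
  subst <- c("O", "N", "Cl", "C", "CO")
  smiles <- c(smiles, paste0(subst, "c1ccccc1"))
  for (x in subst) {
    for (y in subst) {
      smiles <- c(smiles, paste0(x, "c1ccccc1", y))         # ortho
      smiles <- c(smiles, paste0(x, "c1cccc(", y, ")c1"))   # meta
    }
  }
  for (k in 3:8) {
    ring <- paste0("C1", strrep("C", k - 1), "1")
    smiles <- c(smiles, ring, paste0("O", ring))
  }
  can <- vapply(smiles, canonical_smiles, character(1), USE.NAMES = FALSE)
  keep <- !duplicated(can)
  lib <- tibble::tibble(
    id = sprintf("LIG%03d", seq_len(sum(keep))),
    smiles = can[keep])
  if (nrow(lib) < n_min) {
    stop(sprintf("library has %d molecules, below the guaranteed %d",
                 nrow(lib), n_min))
  }
  lib
}

#' Specification for a synthetic fixture with planted ground truth
#'
#' Defines a set of synthetic structures, each with one protein chain
#' carrying a partial EC annotation and bound ligands with planted
#' interaction-mode vectors and planted true ECs, such that the full
#' pipeline recovers the planted truth exactly.
#'
#' @param seed Integer seed (byte-identical outputs under a fixed seed).
#' @param n_structures Number of synthetic structures/chains.
#' @param planted_modes List of fraction vectors cycled over structures;
#'   each must sum to 1 with all entries > 0 (defaults cover exclusive,
#'   dominant/minor, major-partner/partner, major/minor/minor and the
#'   50/50 tie).
#' @param n_chains_with_specific How many chains additionally carry a
#'   specific EC (and must be excluded from EC completion), default 2.
#' @param include_noise Plant a 2-residue spurious domain contact per
#'   structure that the minimum-residue filter must remove, default TRUE.
#' @param domain_db Domain database label stamped on contacts.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(seed = 42L, n_structures = 12L,
                         planted_modes = list(
                           c(1.0), c(0.93, 0.07), c(0.6, 0.4),
                           c(0.85, 0.08, 0.07), c(0.5, 0.5)),
                         n_chains_with_specific = 2L,
                         include_noise = TRUE,
                         domain_db = "CATH") {
  for (v in planted_modes) {
    if (any(v < 0.03) || abs(sum(v) - 1) > 1e-9 || length(v) > 4) {
      stop("invalid planted mode vector: fractions must be positive ",
           "(>= 0.03, so every domain can clear the 3-residue filter), ",
           "sum to 1, and use at most 4 domains: ",
           paste(v, collapse = ", "))
    }
  }
  if (n_structures < 1) stop("n_structures must be >= 1")
  if (n_chains_with_specific > n_structures) {
    stop("n_chains_with_specific exceeds n_structures")
  }
  structure(list(seed = as.integer(seed),
                 n_structures = as.integer(n_structures),
                 planted_modes = planted_modes,
                 n_chains_with_specific = as.integer(n_chains_with_specific),
                 include_noise = isTRUE(include_noise),
                 domain_db = domain_db),
            class = "fixture_spec")
}

#' Generate the synthetic fixture tables in memory
#'
#' Produces the four pipeline inputs (bound entities, cognates, contacts,
#' chain annotations) plus the planted truth. Each structure `i` carries:
#' an "evidence" ligand identical to its true cognate (a small chain
#' molecule unique to EC `1.1.1.i` inside partial class `1.1.1.-`), bound
#' exclusively by domain family FAM1; and a "mode" ligand (catechol,
#' matching an aromatic
#' cognate in a different EC class so it cannot perturb EC completion)
#' whose contact counts realize the structure's planted mode vector over
#' domain families FAM1..FAM3.
#'
#' The mode ligand sits on chain B, which carries no EC annotation, so the
#' mode plants can never perturb EC completion on chain A.
#'
#' @param spec A [fixture_spec()].
#' @return A list: `bound`, `cognates`, `contacts`, `chains`, `truth`
#'   (with `planted_ec` and `planted_modes` tibbles).
#' @export
generate_fixture_tables <- function(spec = fixture_spec()) {
  stopifnot(inherits(spec, "fixture_spec"))
  n <- spec$n_structures
  sid <- sprintf("STR%03d", seq_len(n))
  true_ec <- sprintf("1.1.1.%d", seq_len(n))
  # unique (terminal group, chain length) per structure: no two cognates
  # are isomorphic, so the identical bound entity is always the unique
  # best match, while homologues still score above threshold as decoys
  groups <- c("O", "N", "S", "Cl")
  chain_mol <- function(i) {
    paste0(strrep("C", 2 + (i - 1) %/% 4), groups[(i - 1) %% 4 + 1])
  }
  evidence_smiles <- vapply(seq_len(n), chain_mol, character(1))

  cognates <- tibble::tibble(
    cognate_id = sprintf("COG%03d", seq_len(n)),
    name = sprintf("chain-%s-C%d", groups[(seq_len(n) - 1) %% 4 + 1],
                   2 + (seq_len(n) - 1) %/% 4),
    smiles = evidence_smiles,
    ec_ids = as.list(true_ec),
    is_cofactor = seq_len(n) %% 5 == 0)
  cognates <- dplyr::bind_rows(cognates, tibble::tibble(
    cognate_id = "COGAROM", name = "phenol", smiles = "Oc1ccccc1",
    ec_ids = list("2.7.1.1"), is_cofactor = FALSE))

  bound <- dplyr::bind_rows(
    tibble::tibble(structure_id = sid, chain = "A",
                   ligand_instance = sprintf("%s_A_EVD_1", sid),
                   ccd_code = "EVD",
                   smiles = evidence_smiles),
    tibble::tibble(structure_id = sid, chain = "B",
                   ligand_instance = sprintf("%s_B_MOD_1", sid),
                   ccd_code = "MOD", smiles = "Oc1ccccc1O")) |>
    dplyr::arrange(.data$structure_id, .data$ligand_instance)

  contacts <- list()
  planted <- list()
  add_contacts <- function(structure, instance, chain, fractions, families) {
    counts <- round(fractions * 100)
    counts[1] <- 100 - sum(counts[-1])
    rows <- list()
    res_base <- 0L
    for (d in seq_along(fractions)) {
      n_res <- min(4L, counts[d])
      per <- rep(counts[d] %/% n_res, n_res)
      per[1] <- per[1] + counts[d] %% n_res
      rows[[d]] <- tibble::tibble(
        structure_id = structure, ligand_instance = instance, chain = chain,
        residue = res_base + seq_len(n_res),
        domain_id = paste0("D", d), domain_db = spec$domain_db,
        n_contacts = per, domain_family = families[d])
      res_base <- res_base + n_res
    }
    dplyr::bind_rows(rows)
  }
  for (i in seq_len(n)) {
    ev <- sprintf("%s_A_EVD_1", sid[i])
    md <- sprintf("%s_B_MOD_1", sid[i])
    contacts[[length(contacts) + 1]] <-
      add_contacts(sid[i], ev, "A", c(1.0), "FAM1")
    frac <- spec$planted_modes[[(i - 1) %% length(spec$planted_modes) + 1]]
    contacts[[length(contacts) + 1]] <-
      add_contacts(sid[i], md, "B", frac, paste0("FAM", seq_along(frac)))
    planted[[length(planted) + 1]] <- tibble::tibble(
      ligand_instance = md, domain_id = paste0("D", seq_along(frac)),
      fraction = frac, mode = classify_modes(frac))
    if (spec$include_noise) {
      contacts[[length(contacts) + 1]] <- tibble::tibble(
        structure_id = sid[i], ligand_instance = ev, chain = "A",
        residue = 900:901, domain_id = "DNOISE",
        domain_db = spec$domain_db, n_contacts = 1L,
        domain_family = "FAMNOISE")
    }
  }
  contacts <- dplyr::bind_rows(contacts)

  with_specific <- seq_len(spec$n_chains_with_specific)
  chains <- tibble::tibble(
    structure_id = sid, chain = "A",
    ec_ids = lapply(seq_len(n), function(i) {
      if (i %in% with_specific) c("1.1.1.-", true_ec[i]) else "1.1.1.-"
    }))

  list(bound = bound, cognates = cognates, contacts = contacts,
       chains = chains,
       truth = list(
         planted_ec = tibble::tibble(
           structure_id = sid, chain = "A", partial_ec = "1.1.1.-",
           true_ec = true_ec,
           excluded = seq_len(n) %in% with_specific),
         planted_modes = dplyr::bind_rows(planted)))
}

#' Write a synthetic fixture to disk as TSVs
#'
#' @param spec A [fixture_spec()].
#' @param outdir Output directory (created if needed).
#' @return Invisibly, a named character vector of written files
#'   (also recorded in `manifest.json`).
#' @export
generate_fixture <- function(spec = fixture_spec(), outdir) {
  tabs <- generate_fixture_tables(spec)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    bound = file.path(outdir, "bound_entities.tsv"),
    cognates = file.path(outdir, "cognate_ligands.tsv"),
    contacts = file.path(outdir, "contacts.tsv"),
    chains = file.path(outdir, "chain_annotations.tsv"))
  readr::write_tsv(tabs$bound, paths[["bound"]])
  cog <- tabs$cognates
  cog$ec_ids <- vapply(cog$ec_ids, paste, character(1), collapse = ",")
  readr::write_tsv(cog, paths[["cognates"]])
  readr::write_tsv(tabs$contacts, paths[["contacts"]])
  ch <- tabs$chains
  ch$ec_ids <- vapply(ch$ec_ids, paste, character(1), collapse = ",")
  readr::write_tsv(ch, paths[["chains"]])
  jsonlite::write_json(as.list(basename(paths)),
                       file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(paths)
}
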