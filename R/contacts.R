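#' Load a per-residue domain-ligand contact table
#'
#' Reads a TSV with one row per contacting residue: which domain of which
#' chain touches which bound-ligand instance, and with how many atomic
#' contacts (as produced upstream by a contact-detection tool such as
#' arpeggio). Duplicate (instance, domain, chain, residue) rows are merged
#' by summing their contact counts, with a warning.
#'
#' @param path TSV path with header columns `structure_id`,
#'   `ligand_instance`, `chain`, `residue`, `domain_id`, `domain_db`,
#'   `n_contacts` (an optional `domain_family` column is passed through).
#' @return A tibble of validated contact records.
#' @export
load_contacts <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  validate_contacts(df)
}

required_contact_cols <- c("structure_id", "ligand_instance", "chain",
                           "residue", "domain_id", "domain_db", "n_contacts")

validate_contacts <- function(df) {
  missing <- setdiff(required_contact_cols, names(df))
  if (length(missing)) {
    stop("contact table lacks required column(s): ",
         paste(missing, collapse = ", "))
  }
  if (nrow(df) == 0) {
    warning("contact table is empty")
    return(tibble::as_tibble(df))
  }
  if (any(df$n_contacts < 1)) stop("n_contacts must be >= 1")
  if (!"domain_family" %in% names(df)) df$domain_family <- df$domain_id
  key <- c("ligand_instance", "domain_db", "domain_id", "chain", "residue")
  if (anyDuplicated(df[key])) {
    warning("duplicate residue rows merged by summing n_contacts")
    df <- df |>
      dplyr::group_by(dplyr::across(dplyr::all_of(
        c("structure_id", key, "domain_family")))) |>
      dplyr::summarise(n_contacts = sum(.data$n_contacts), .groups = "drop")
  }
  tibble::as_tibble(df)
}

#' Filter sparse domain-ligand contacts
#'
#' Removes every (domain, ligand-instance) pair supported by fewer than
#' `min_residues` distinct contacting residues — spurious touches between a
#' domain and a peripheral ligand. A ligand instance whose every domain
#' partner is removed disappears from the output entirely.
#'
#' @param contacts Contact tibble ([load_contacts()]).
#' @param min_residues Minimum distinct residues per domain-ligand pair,
#'   default 3.
#' @return The filtered contact tibble.
#' @export
filter_min_residues <- function(contacts, min_residues = 3) {
  contacts <- validate_contacts(contacts)
  if (nrow(contacts) == 0) return(contacts)
  contacts |>
    dplyr::group_by(.data$domain_db, .data$ligand_instance,
                    .data$domain_id, .data$chain) |>
    dplyr::filter(dplyr::n_distinct(.data$residue) >= min_residues) |>
    dplyr::ungroup()
}

#' Gini index of a set of non-negative contributions
#'
#' Mean-absolute-difference form: sum_ij |x_i - x_j| / (2 n^2 mu).
#' 0 for perfect equality; bounded above by (n-1)/n < 1. Used to quantify
#' how unequally the contacts to one ligand are shared between domains.
#'
#' @param values Non-negative numeric vector, not all zero.
#' @return Gini index in \[0, 1).
#' @examples
#' gini(c(5, 5, 5))   # 0
#' gini(c(1, 0, 0, 0)) # 0.75
#' @export
gini <- function(values) {
  if (length(values) == 0) stop("gini of empty input is undefined")
  if (any(values < 0)) stop("gini requires non-negative values")
  mu <- mean(values)
  if (mu == 0) stop("gini of an all-zero vector is undefined")
  n <- length(values)
  sum(abs(outer(values, values, "-"))) / (2 * n^2 * mu)
}

#' Per-ligand Gini report over domain contact fractions
#'
#' @param interactions Classified interactions
#'   ([assign_interaction_modes()]).
#' @return A tibble with `domain_db`, `ligand_instance`, `n_domains`,
#'   `gini`.
#' @export
gini_report <- function(interactions) {
  interactions |>
    dplyr::group_by(.data$domain_db, .data$ligand_instance) |>
    dplyr::summarise(n_domains = dplyr::n(),
                     gini = gini(.data$n_contacts), .groups = "drop")
}

#' Classify domain-ligand interaction modes from contact shares
#'
#' Aggregates filtered per-residue contacts to one record per
#' (domain, chain, ligand instance) and assigns an interaction mode from
#' each domain's share of the ligand's contacts (contact counts, not
#' residue counts), independently within each domain database:
#'
#' * single contacting domain: `exclusive`;
#' * share < 10%: `minor`;
#' * exactly one nonminor domain: `dominant` (>= 90%) or `major`
#'   (10-90%);
#' * two or more nonminor domains: `major_partner` (>= 50%) or `partner`
#'   (10 to < 50%).
#'
#' @param contacts Contact tibble, normally already passed through
#'   [filter_min_residues()].
#' @param prefilter_contacts Optional unfiltered contact tibble. By default
#'   fractions are renormalized over the domains surviving filtering; pass
#'   the pre-filter table here to use the original per-ligand totals as
#'   denominators instead.
#' @return A tibble with one row per domain-ligand pair: `structure_id`,
#'   `ligand_instance`, `domain_db`, `domain_id`, `domain_family`, `chain`,
#'   `n_residues`, `n_contacts`, `fraction`, `mode`.
#' @export
assign_interaction_modes <- function(contacts, prefilter_contacts = NULL) {
  contacts <- validate_contacts(contacts)
  totals <- NULL
  if (!is.null(prefilter_contacts)) {
    totals <- validate_contacts(prefilter_contacts) |>
      dplyr::group_by(.data$domain_db, .data$ligand_instance) |>
      dplyr::summarise(total_contacts = sum(.data$n_contacts),
                       .groups = "drop")
  }
  per_domain <- contacts |>
    dplyr::group_by(.data$structure_id, .data$ligand_instance,
                    .data$domain_db, .data$domain_id, .data$domain_family,
                    .data$chain) |>
    dplyr::summarise(n_residues = dplyr::n_distinct(.data$residue),
                     n_contacts = sum(.data$n_contacts), .groups = "drop") |>
    dplyr::group_by(.data$domain_db, .data$ligand_instance)
  if (is.null(totals)) {
    per_domain <- dplyr::mutate(per_domain,
      fraction = .data$n_contacts / sum(.data$n_contacts))
  } else {
    per_domain <- per_domain |>
      dplyr::left_join(totals, by = c("domain_db", "ligand_instance")) |>
      dplyr::mutate(fraction = .data$n_contacts / .data$total_contacts,
                    total_contacts = NULL)
  }
  per_domain <- per_domain |>
    dplyr::mutate(mode = classify_modes(.data$fraction)) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$domain_db, .data$ligand_instance,
                   dplyr::desc(.data$fraction), .data$domain_id, .data$chain)
  per_domain
}

interaction_mode_levels <- c("exclusive", "dominant", "major",
                             "major_partner", "partner", "minor")

# fractions of one (domain_db, ligand_instance) group -> mode labels
classify_modes <- function(fraction) {
  k <- length(fraction)
  if (k == 1) return("exclusive")
  mode <- rep(NA_character_, k)
  minor <- fraction < 0.10
  mode[minor] <- "minor"
  nonminor <- which(!minor)
  if (length(nonminor) == 1) {
    mode[nonminor] <- if (fraction[nonminor] >= 0.90) "dominant" else "major"
  } else if (length(nonminor) >= 2) {
    mode[nonminor] <- ifelse(fraction[nonminor] >= 0.50,
                             "major_partner", "partner")
  }
  mode
}

#' Extract combinatorial (multi-domain) interactions with cognate support
#'
#' A combinatorial interaction is a ligand instance bound in a nonminor
#' manner by more than one domain, where the ligand also has at least one
#' retained cognate match. The combination key is the sorted multiset of
#' domain family identifiers — the same family contributed by two chains
#' appears twice.
#'
#' @param interactions Classified interactions.
#' @param matches Retained similarity matches ([match_bound_to_cognates()]).
#' @return A tibble with `domain_db`, `ligand_instance`, `combination`,
#'   `n_domains`, `best_score`.
#' @export
combinatorial_interactions <- function(interactions, matches) {
  matched <- unique(matches$bound_id)
  if (length(matched) == 0) {
    return(tibble::tibble(domain_db = character(),
                          ligand_instance = character(),
                          combination = character(),
                          n_domains = integer(), best_score = numeric()))
  }
  interactions |>
    dplyr::filter(.data$mode != "minor",
                  .data$ligand_instance %in% matched) |>
    dplyr::group_by(.data$domain_db, .data$ligand_instance) |>
    dplyr::filter(dplyr::n() >= 2) |>
    dplyr::summarise(
      combination = paste(sort(.data$domain_family), collapse = "+"),
      n_domains = dplyr::n(), .groups = "drop") |>
    dplyr::left_join(
      matches |>
        dplyr::group_by(bound_id = .data$bound_id) |>
        dplyr::summarise(best_score = max(.data$score), .groups = "drop"),
      by = c(ligand_instance = "bound_id"))
}

#' Write classified interactions as a distribution TSV
#'
#' One file per domain database, mirroring a domain/bound-entity mapping
#' flat file.
#'
#' @param interactions Classified interactions.
#' @param dir Output directory.
#' @return Invisibly, the written paths.
#' @export
write_interaction_tables <- function(interactions, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (db in sort(unique(interactions$domain_db))) {
    p <- file.path(dir, sprintf("domain_bound_entity_%s.tsv", db))
    readr::write_tsv(dplyr::filter(interactions, .data$domain_db == db), p)
    paths <- c(paths, p)
  }
  invisible(paths)
}
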