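#' Read a cognate-ligand TSV
#'
#' Expected columns: `cognate_id`, `name`, `smiles`, `ec_ids`
#' (comma-separated complete EC numbers), `is_cofactor` (logical or 0/1).
#' An optional `roles` column is passed through.
#'
#' @param path TSV path.
#' @return A tibble with `ec_ids` as a list-column of character vectors.
#' @export
read_cognate_table <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(c("cognate_id", "name", "smiles", "ec_ids",
                       "is_cofactor"), names(df))
  if (length(missing)) {
    stop("cognate table lacks required column(s): ",
         paste(missing, collapse = ", "))
  }
  df$ec_ids <- split_ec_ids(df$ec_ids)
  df$is_cofactor <- as.logical(df$is_cofactor)
  validate_cognates(tibble::as_tibble(df))
}

split_ec_ids <- function(x) {
  if (is.list(x)) return(lapply(x, as.character))
  lapply(strsplit(as.character(x), "[,;]\\s*"), function(v) v[nzchar(v)])
}

validate_cognates <- function(cognates) {
  if (!is.list(cognates$ec_ids)) cognates$ec_ids <- split_ec_ids(cognates$ec_ids)
  n_ec <- lengths(cognates$ec_ids)
  if (any(n_ec == 0)) {
    stop("cognate(s) without EC membership: ",
         paste(utils::head(cognates$cognate_id[n_ec == 0], 5), collapse = ", "))
  }
  bad <- !vapply(cognates$ec_ids,
                 function(v) all(grepl("^\\d+\\.\\d+\\.\\d+\\.\\d+$", v)),
                 logical(1))
  if (any(bad)) {
    stop("cognate EC ids must be complete 4-field numbers; offending: ",
         paste(utils::head(cognates$cognate_id[bad], 5), collapse = ", "))
  }
  cognates
}

#' Deduplicate cognate ligands on canonical SMILES
#'
#' Cognates aggregated from several source databases often repeat the same
#' chemical structure under different identifiers. Records sharing a
#' canonical SMILES are merged: the first id (sorted) is kept, EC
#' memberships are unioned, the cofactor flag is OR-ed, and all
#' contributing ids are retained in `source_ids`.
#'
#' @param cognates Cognate tibble.
#' @return Deduplicated tibble with an added `source_ids` column.
#' @export
dedupe_cognates <- function(cognates) {
  cognates <- validate_cognates(cognates)
  can <- vapply(cognates$smiles, function(s) {
    tryCatch(canonical_smiles(s), error = function(e) NA_character_)
  }, character(1), USE.NAMES = FALSE)
  cognates$.canonical <- ifelse(is.na(can), cognates$smiles, can)
  cognates |>
    dplyr::arrange(.data$cognate_id) |>
    dplyr::group_by(.data$.canonical) |>
    dplyr::summarise(
      source_ids = list(.data$cognate_id),
      cognate_id = dplyr::first(.data$cognate_id),
      name = dplyr::first(.data$name),
      smiles = dplyr::first(.data$smiles),
      ec_ids = list(sort(unique(unlist(.data$ec_ids)))),
      is_cofactor = any(.data$is_cofactor),
      .groups = "drop") |>
    dplyr::select(-".canonical") |>
    dplyr::arrange(.data$cognate_id)
}

#' Match bound entities to cognate ligands by PARITY similarity
#'
#' Scores every bound entity against every cognate ligand and retains the
#' matches at or above the similarity threshold. All valid matches per
#' bound entity are kept; the highest-scoring match(es) are flagged
#' `is_best` (ties all flagged). Cognates whose SMILES cannot be parsed are
#' skipped with a warning; pairs that hit the search timeout are flagged
#' and excluded from best-match competition.
#'
#' @param bound A list of `molecule` objects (bound entities); ids are
#'   taken from each molecule's `id`.
#' @param cognates Cognate tibble (`cognate_id`, `smiles`, ...).
#' @param threshold Minimum retained similarity, default 0.4.
#' @param timeout_s Per-pair search budget, seconds.
#' @param strict_inequality If `TRUE`, retain only scores strictly above
#'   the threshold (default keeps `score >= threshold`).
#' @return A tibble: `bound_id`, `cognate_id`, `score`, `timed_out`,
#'   `passed_threshold`, `is_best`.
#' @export
match_bound_to_cognates <- function(bound, cognates, threshold = 0.4,
                                    timeout_s = 10,
                                    strict_inequality = FALSE) {
  cognates <- validate_cognates(cognates)
  cog_mols <- list()
  for (i in seq_len(nrow(cognates))) {
    m <- tryCatch(parse_smiles(cognates$smiles[i], cognates$cognate_id[i]),
                  cogmap_parse_error = function(e) NULL)
    if (!is.null(m)) cog_mols[[cognates$cognate_id[i]]] <- m
  }
  n_skip <- nrow(cognates) - length(cog_mols)
  if (n_skip > 0) {
    warning(sprintf("skipped %d cognate(s) with unparseable SMILES", n_skip))
  }
  rows <- list()
  for (bm in bound) {
    for (cid in names(cog_mols)) {
      pr <- parity_score(bm, cog_mols[[cid]], timeout_s = timeout_s)
      keep <- if (strict_inequality) pr$score > threshold
              else pr$score >= threshold
      if (keep) {
        rows[[length(rows) + 1]] <- tibble::tibble(
          bound_id = bm$id, cognate_id = cid, score = pr$score,
          timed_out = pr$timed_out)
      }
    }
  }
  if (length(rows) == 0) {
    return(tibble::tibble(bound_id = character(), cognate_id = character(),
                          score = numeric(), timed_out = logical(),
                          passed_threshold = logical(), is_best = logical()))
  }
  dplyr::bind_rows(rows) |>
    dplyr::mutate(passed_threshold = TRUE) |>
    dplyr::group_by(.data$bound_id) |>
    dplyr::mutate(is_best = !.data$timed_out &
                    .data$score == max(.data$score[!.data$timed_out],
                                       -Inf)) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$bound_id, dplyr::desc(.data$score),
                   .data$cognate_id)
}

#' Summarize a match table
#'
#' @param matches Match tibble ([match_bound_to_cognates()]).
#' @param cognates Cognate tibble (for cofactor flags).
#' @return A list: `n_bound_matched`, `n_matches`, `n_perfect` (score
#'   exactly 1), `n_cofactor_matches`, `cofactor_fraction`.
#' @export
summarize_matches <- function(matches, cognates) {
  cof <- cognates$cognate_id[as.logical(cognates$is_cofactor)]
  n_matches <- nrow(matches)
  list(
    n_bound_matched = dplyr::n_distinct(matches$bound_id),
    n_matches = n_matches,
    n_perfect = sum(matches$score == 1.0),
    n_cofactor_matches = sum(matches$cognate_id %in% cof),
    cofactor_fraction = if (n_matches == 0) 0
                        else sum(matches$cognate_id %in% cof) / n_matches
  )
}

#' Write the bound-entity/cognate similarity mapping TSV
#'
#' @param matches Match tibble.
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_match_table <- function(matches, path) {
  readr::write_tsv(
    dplyr::select(matches, "bound_id", "cognate_id", "score", "is_best"),
    path)
  invisible(path)
}
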