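#' Expand a partial EC number over a universe of complete ECs
#'
#' A partial EC such as `3.2.1.-` (or the bare prefix `3.2.1`) denotes
#' every complete four-field EC sharing its specified leading fields.
#'
#' @param partial EC string with 1-4 specified fields; unspecified fields
#'   may be written as a trailing `-` (or `.-.-` etc.) or simply omitted.
#' @param ec_universe Character vector of complete four-field ECs.
#' @return The complete ECs of the universe lying in the partial class.
#' @examples
#' expand_partial_ec("1.1.1.-", c("1.1.1.1", "1.1.1.2", "1.2.1.1"))
#' @export
expand_partial_ec <- function(partial, ec_universe) {
  if (length(ec_universe) == 0) stop("empty EC universe")
  fields <- parse_ec(partial)
  spec <- fields[fields != "-"]
  uni <- strsplit(ec_universe, ".", fixed = TRUE)
  hit <- vapply(uni, function(u) {
    length(u) == 4L && all(u[seq_along(spec)] == spec)
  }, logical(1))
  ec_universe[hit]
}

# Split an EC string into 4 fields, validating shape; wildcard only as a
# suffix. Returns c(f1,f2,f3,f4) with "-" for unspecified trailing fields.
parse_ec <- function(ec) {
  if (!is.character(ec) || length(ec) != 1L || !nzchar(ec)) {
    stop("malformed EC string: ", deparse(ec))
  }
  f <- strsplit(sub("\\.+$", "", ec), ".", fixed = TRUE)[[1]]
  if (length(f) < 1L || length(f) > 4L) stop("malformed EC string: ", ec)
  f <- c(f, rep("-", 4L - length(f)))
  specified <- f != "-"
  if (any(!specified) &&
      any(specified[cumsum(!specified) > 0])) {
    stop("EC wildcard must be a suffix: ", ec)
  }
  if (!all(grepl("^\\d+$", f[specified]))) {
    stop("malformed EC string: ", ec)
  }
  f
}

is_partial_ec <- function(ec) {
  vapply(ec, function(e) any(parse_ec(e) == "-"), logical(1),
         USE.NAMES = FALSE)
}

#' Complete partial EC annotations of protein chains via cognate ligands
#'
#' For each chain annotated with a partial EC, candidate activities are the
#' complete ECs (within the partial class) of cognate ligands matched at or
#' above the similarity threshold to bound entities the chain's domains
#' contact in a nonminor manner. Per bound entity only the best-scoring
#' in-class cognates contribute. The chain is `assigned` when the candidate
#' EC sets of all contributing bound entities intersect in exactly one EC;
#' conflicting or multiple survivors give `ambiguous`, no evidence gives
#' `no_candidates`, and chains that already carry a specific EC alongside
#' the partial are `excluded_has_specific`.
#'
#' @param chains Chain-annotation tibble: `structure_id`, `chain`,
#'   `ec_ids` (comma-separated string or list-column; entries may be
#'   partial).
#' @param interactions Classified interactions
#'   ([assign_interaction_modes()]).
#' @param matches Retained similarity matches
#'   ([match_bound_to_cognates()]).
#' @param cognates Cognate tibble.
#' @param threshold Minimum similarity for supporting evidence,
#'   default 0.4.
#' @param strict_inequality If `TRUE`, require score strictly above the
#'   threshold.
#' @param best_within_class If `TRUE` (default) best cognates are selected
#'   among in-class candidates; if `FALSE`, a bound entity's global best
#'   cognates are selected first and then filtered to the class.
#' @return A tibble with one row per (chain, partial EC): `structure_id`,
#'   `chain`, `partial_ec`, `assigned_ec`, `status`, `perfect_support`,
#'   `supporting` (list-column of bound_id/cognate_id/score tibbles).
#' @export
assign_specific_ec <- function(chains, interactions, matches, cognates,
                               threshold = 0.4, strict_inequality = FALSE,
                               best_within_class = TRUE) {
  chains <- normalize_chain_annotations(chains)
  cognates <- validate_cognates(cognates)
  ec_universe <- sort(unique(unlist(cognates$ec_ids)))
  ec_by_cognate <- stats::setNames(cognates$ec_ids, cognates$cognate_id)

  keep <- if (strict_inequality) matches$score > threshold
          else matches$score >= threshold
  matches <- matches[keep & !matches$timed_out, , drop = FALSE]

  nonminor <- dplyr::filter(interactions, .data$mode != "minor")

  out <- vector("list", nrow(chains))
  for (i in seq_len(nrow(chains))) {
    ecs <- chains$ec_ids[[i]]
    partials <- ecs[is_partial_ec(ecs)]
    has_specific <- any(!is_partial_ec(ecs))
    if (length(partials) == 0) next
    rows <- lapply(partials, function(pec) {
      if (has_specific) {
        return(ec_assignment_row(chains$structure_id[i], chains$chain[i],
                                 pec, NA_character_,
                                 "excluded_has_specific", FALSE, NULL))
      }
      class_ecs <- expand_partial_ec(pec, ec_universe)
      ents <- nonminor$ligand_instance[
        nonminor$structure_id == chains$structure_id[i] &
          nonminor$chain == chains$chain[i]]
      ev <- matches[matches$bound_id %in% ents, , drop = FALSE]
      if (nrow(ev) == 0 || length(class_ecs) == 0) {
        return(ec_assignment_row(chains$structure_id[i], chains$chain[i],
                                 pec, NA_character_, "no_candidates",
                                 FALSE, NULL))
      }
      per_entity <- split(ev, ev$bound_id)
      cand_sets <- list(); supp <- list()
      for (be in names(per_entity)) {
        tab <- per_entity[[be]]
        in_class <- vapply(tab$cognate_id, function(cid) {
          length(intersect(ec_by_cognate[[cid]], class_ecs)) > 0
        }, logical(1))
        if (best_within_class) {
          tab <- tab[in_class, , drop = FALSE]
          if (nrow(tab) == 0) next
          tab <- tab[tab$score == max(tab$score), , drop = FALSE]
        } else {
          tab <- tab[tab$score == max(tab$score), , drop = FALSE]
          tab <- tab[vapply(tab$cognate_id, function(cid) {
            length(intersect(ec_by_cognate[[cid]], class_ecs)) > 0
          }, logical(1)), , drop = FALSE]
          if (nrow(tab) == 0) next
        }
        cand <- sort(unique(unlist(lapply(tab$cognate_id, function(cid) {
          intersect(ec_by_cognate[[cid]], class_ecs)
        }))))
        cand_sets[[be]] <- cand
        supp[[be]] <- tab[, c("bound_id", "cognate_id", "score")]
      }
      if (length(cand_sets) == 0) {
        return(ec_assignment_row(chains$structure_id[i], chains$chain[i],
                                 pec, NA_character_, "no_candidates",
                                 FALSE, NULL))
      }
      final <- Reduce(intersect, cand_sets)
      supp_tab <- dplyr::bind_rows(supp)
      if (length(final) == 1) {
        perfect <- all(supp_tab$score == 1.0)
        ec_assignment_row(chains$structure_id[i], chains$chain[i], pec,
                          final, "assigned", perfect, supp_tab)
      } else {
        # conflicting nonempty candidate sets or several survivors
        ec_assignment_row(chains$structure_id[i], chains$chain[i], pec,
                          NA_character_, "ambiguous", FALSE, supp_tab)
      }
    })
    out[[i]] <- dplyr::bind_rows(rows)
  }
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0) {
    res <- tibble::tibble(structure_id = character(), chain = character(),
                          partial_ec = character(),
                          assigned_ec = character(), status = character(),
                          perfect_support = logical(), supporting = list())
  }
  res
}

ec_assignment_row <- function(structure_id, chain, partial_ec, assigned_ec,
                              status, perfect_support, supporting) {
  tibble::tibble(structure_id = structure_id, chain = chain,
                 partial_ec = partial_ec, assigned_ec = assigned_ec,
                 status = status, perfect_support = perfect_support,
                 supporting = list(supporting))
}

normalize_chain_annotations <- function(chains) {
  missing <- setdiff(c("structure_id", "chain", "ec_ids"), names(chains))
  if (length(missing)) {
    stop("chain annotation table lacks column(s): ",
         paste(missing, collapse = ", "))
  }
  if (!is.list(chains$ec_ids)) {
    chains$ec_ids <- lapply(strsplit(as.character(chains$ec_ids),
                                     "[,;]\\s*"),
                            function(v) v[nzchar(v)])
  }
  tibble::as_tibble(chains)
}

#' Read a chain-annotation TSV (structure_id, chain, ec_ids)
#'
#' @param path TSV path; `ec_ids` is a comma-separated list that may mix
#'   complete and partial EC numbers.
#' @return A tibble with `ec_ids` as a list-column.
#' @export
read_chain_annotations <- function(path) {
  normalize_chain_annotations(
    readr::read_tsv(path, show_col_types = FALSE, progress = FALSE))
}

#' Write EC assignments as TSV (list-columns collapsed)
#'
#' @param assignments Output of [assign_specific_ec()].
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_ec_assignments <- function(assignments, path) {
  flat <- assignments |>
    dplyr::mutate(supporting = vapply(.data$supporting, function(s) {
      if (is.null(s) || nrow(s) == 0) return("")
      paste(sprintf("%s:%s:%.4f", s$bound_id, s$cognate_id, s$score),
            collapse = ";")
    }, character(1)))
  readr::write_tsv(flat, path)
  invisible(path)
}
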