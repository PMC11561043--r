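#' Profile domain families by their cognate ligand repertoire
#'
#' Aggregates, per domain family (within each domain database), the set of
#' distinct cognate ligands reached through nonminor interactions and
#' retained similarity matches. A family with four or more cognate ligands
#' is promiscuous — a cutoff that avoids flagging a domain that merely
#' binds the cofactor, substrate and product of a single reaction.
#' Promiscuous families are split by the chemical coherence of their
#' cognate set: `specialized` when the mean pairwise MACCS Tanimoto
#' similarity is at or above the strict threshold (0.575), `generalized`
#' otherwise.
#'
#' @param interactions Classified interactions
#'   ([assign_interaction_modes()]).
#' @param matches Retained similarity matches.
#' @param cognates Cognate tibble.
#' @param similarity_threshold Tanimoto boundary between specialized and
#'   generalized, default 0.575 (the strict random-pair threshold; 0.431
#'   is the permissive alternative).
#' @param promiscuity_min Minimum distinct cognates for promiscuity,
#'   default 4.
#' @return A tibble: `domain_db`, `domain_family`, `cognate_ids`
#'   (list-column), `n_cognates`, `is_promiscuous`,
#'   `mean_pairwise_tanimoto` (NA when fewer than 2 cognates), `class`.
#' @export
build_domain_profiles <- function(interactions, matches, cognates,
                                  similarity_threshold = 0.575,
                                  promiscuity_min = 4) {
  cognates <- validate_cognates(cognates)
  links <- interactions |>
    dplyr::filter(.data$mode != "minor") |>
    dplyr::inner_join(matches, by = c(ligand_instance = "bound_id"),
                      relationship = "many-to-many")
  prof <- links |>
    dplyr::group_by(.data$domain_db, .data$domain_family) |>
    dplyr::summarise(cognate_ids = list(sort(unique(.data$cognate_id))),
                     .groups = "drop") |>
    dplyr::mutate(n_cognates = lengths(.data$cognate_ids),
                  is_promiscuous = .data$n_cognates >= promiscuity_min)
  fps <- cognate_fingerprints(cognates)
  prof$mean_pairwise_tanimoto <- vapply(prof$cognate_ids, function(ids) {
    ids <- intersect(ids, names(fps))
    if (length(ids) < 2) return(NA_real_)
    mean_pairwise_tanimoto(fps[ids])
  }, numeric(1))
  prof$class <- ifelse(
    !prof$is_promiscuous, "not_promiscuous",
    ifelse(!is.na(prof$mean_pairwise_tanimoto) &
             prof$mean_pairwise_tanimoto >= similarity_threshold,
           "specialized", "generalized"))
  dplyr::arrange(prof, .data$domain_db, .data$domain_family)
}

# named list of maccs_fp, one per parseable cognate
cognate_fingerprints <- function(cognates) {
  fps <- list()
  for (i in seq_len(nrow(cognates))) {
    m <- tryCatch(parse_smiles(cognates$smiles[i], cognates$cognate_id[i]),
                  cogmap_parse_error = function(e) NULL)
    if (!is.null(m)) fps[[cognates$cognate_id[i]]] <- maccs_fingerprint(m)
  }
  fps
}

mean_pairwise_tanimoto <- function(fps) {
  n <- length(fps)
  vals <- numeric(0)
  for (i in seq_len(n - 1)) {
    for (j in seq((i + 1), n)) {
      vals <- c(vals, tanimoto(fps[[i]], fps[[j]]))
    }
  }
  mean(vals)
}

#' EC diversity of a domain family
#'
#' Counts the distinct complete ECs annotated on chains where the family
#' has a nonminor, cognate-matched interaction. Specialized families tend
#' to show far lower EC diversity than generalized ones.
#'
#' @param profiles Output of [build_domain_profiles()].
#' @param interactions Classified interactions.
#' @param matches Retained matches.
#' @param chains Chain-annotation tibble.
#' @return `profiles` with an added integer `ec_diversity` column.
#' @export
ec_diversity <- function(profiles, interactions, matches, chains) {
  chains <- normalize_chain_annotations(chains)
  chain_ecs <- chains |>
    dplyr::mutate(ec = lapply(.data$ec_ids,
                              function(v) v[!is_partial_ec(v)])) |>
    dplyr::select("structure_id", "chain", "ec") |>
    tidyr::unnest("ec")
  links <- interactions |>
    dplyr::filter(.data$mode != "minor") |>
    dplyr::semi_join(matches, by = c(ligand_instance = "bound_id")) |>
    dplyr::inner_join(chain_ecs, by = c("structure_id", "chain"),
                      relationship = "many-to-many")
  div <- links |>
    dplyr::group_by(.data$domain_db, .data$domain_family) |>
    dplyr::summarise(ec_diversity = dplyr::n_distinct(.data$ec),
                     .groups = "drop")
  profiles |>
    dplyr::left_join(div, by = c("domain_db", "domain_family")) |>
    dplyr::mutate(ec_diversity = dplyr::coalesce(.data$ec_diversity, 0L))
}

#' Cluster cognate ligands in chemical space
#'
#' Embeds MACCS fingerprints by classical multidimensional scaling of
#' Tanimoto (Jaccard) distances, then k-means clusters the embedding,
#' selecting k by maximal mean silhouette width over a range. Clustering
#' runs on an `embed_dim`-dimensional embedding (two dimensions cannot
#' hold more than three mutually equidistant clusters apart, so the
#' clustering space is higher-dimensional by default), while the first
#' two coordinates are returned for plotting. Set
#' `space = "fingerprint"` to cluster the raw 166-bit fingerprints
#' instead of the embedding.
#'
#' @param cognates Cognate tibble; ignored when `fingerprints` is given.
#' @param k_range Candidate cluster counts, default `2:20` (capped at
#'   n - 1).
#' @param seed Integer seed controlling k-means initialization.
#' @param space `"embedding"` (default) or `"fingerprint"`.
#' @param embed_dim Dimensionality of the clustering embedding, default
#'   10 (capped at n - 1); the reported coordinates are always 2D.
#' @param fingerprints Optional named list of precomputed binary
#'   fingerprints, bypassing SMILES parsing.
#' @return A list: `assignments` (tibble `cognate_id`, `cluster`, `dim1`,
#'   `dim2`), `k`, `mean_silhouette`, `silhouette_by_k`, `degenerate`
#'   (TRUE when all fingerprints are identical, in which case no
#'   clustering is performed).
#' @export
cluster_cognate_space <- function(cognates, k_range = 2:20, seed = 1L,
                                  space = c("embedding", "fingerprint"),
                                  embed_dim = 10L, fingerprints = NULL) {
  space <- match.arg(space)
  fps <- if (is.null(fingerprints)) {
    cognate_fingerprints(validate_cognates(cognates))
  } else fingerprints
  n <- length(fps)
  if (n < min(k_range)) {
    stop(sprintf("need at least %d cognates with fingerprints, have %d",
                 min(k_range), n))
  }
  mat <- do.call(rbind, lapply(fps, as.integer))
  rownames(mat) <- names(fps)
  if (all(apply(mat, 2, function(col) length(unique(col)) == 1))) {
    return(list(assignments = tibble::tibble(
      cognate_id = names(fps), cluster = NA_integer_,
      dim1 = NA_real_, dim2 = NA_real_),
      k = NA_integer_, mean_silhouette = NA_real_,
      silhouette_by_k = NULL, degenerate = TRUE))
  }
  d <- stats::dist(mat, method = "binary")  # 1 - Tanimoto
  emb <- stats::cmdscale(d, k = min(max(2L, embed_dim), n - 1))
  feat <- if (space == "embedding") emb else mat
  k_range <- k_range[k_range <= n - 1 & k_range >= 2]
  if (length(k_range) == 0) stop("no feasible k in k_range")
  old <- .Random.seed_exists()
  set.seed(seed)
  on.exit(.restore_seed(old), add = TRUE)
  feat_d <- stats::dist(feat)
  sil <- vapply(k_range, function(k) {
    km <- stats::kmeans(feat, centers = k, nstart = 10, iter.max = 200)
    mean(cluster::silhouette(km$cluster, feat_d)[, "sil_width"])
  }, numeric(1))
  k_best <- k_range[which.max(sil)]
  km <- stats::kmeans(feat, centers = k_best, nstart = 10, iter.max = 200)
  # relabel clusters contiguously from 0, by order of first appearance
  lab <- as.integer(factor(km$cluster, levels = unique(km$cluster))) - 1L
  list(assignments = tibble::tibble(
    cognate_id = names(fps), cluster = lab,
    dim1 = emb[, 1], dim2 = emb[, 2]),
    k = k_best, mean_silhouette = max(sil),
    silhouette_by_k = stats::setNames(sil, k_range), degenerate = FALSE)
}
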