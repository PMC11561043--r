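#' Assemble pipeline products into a property graph
#'
#' Builds node and edge tables over six node labels (Structure,
#' ProteinChain, Domain, BoundEntity, CognateLigand, EC) and five edge
#' types: `CONTAINS` (structure to chain), `HAS_DOMAIN` (chain to domain),
#' `INTERACTS_WITH` (domain to bound entity, carrying mode, fraction and
#' the residue-level interface), `MAPS_TO` (bound entity to cognate,
#' carrying score and best flag), `IN_EC_CLASS` (chain or cognate to EC).
#' Node ids are namespaced (`structure:...`, `domain:db:id:chain`, ...) so
#' they are globally unique. All property values are stored as character
#' strings so that flat-file round trips are exact.
#'
#' @param structures Character vector of structure ids (may be derived
#'   from the other tables when `NULL`).
#' @param chains Chain-annotation tibble (`structure_id`, `chain`,
#'   `ec_ids`), or `NULL`.
#' @param interactions Classified interactions, or `NULL`.
#' @param matches Retained similarity matches, or `NULL`.
#' @param cognates Cognate tibble, or `NULL`.
#' @param bound Optional bound-entity tibble (`structure_id`, `chain`,
#'   `ligand_instance`, `ccd_code`, `smiles`) used to place BoundEntity
#'   nodes even when they have no interactions.
#' @return A `cogmap_graph`: list with `nodes` (tibble `node_id`, `label`,
#'   `properties` list-column of named character vectors) and `edges`
#'   (tibble `start_id`, `end_id`, `type`, `properties`).
#' @export
build_graph <- function(structures = NULL, chains = NULL,
                        interactions = NULL, matches = NULL,
                        cognates = NULL, bound = NULL) {
  nodes <- list(); edges <- list()
  add_node <- function(id, label, ...) {
    props <- prop_chr(list(...))
    nodes[[length(nodes) + 1]] <<- tibble::tibble(
      node_id = id, label = label, properties = list(props))
  }
  add_edge <- function(start, end, type, ...) {
    props <- prop_chr(list(...))
    edges[[length(edges) + 1]] <<- tibble::tibble(
      start_id = start, end_id = end, type = type,
      properties = list(props))
  }

  structures <- sort(unique(c(
    structures,
    if (!is.null(chains)) chains$structure_id,
    if (!is.null(interactions)) interactions$structure_id,
    if (!is.null(bound)) bound$structure_id)))
  for (s in structures) add_node(paste0("structure:", s), "Structure",
                                 structure_id = s)

  if (!is.null(chains)) {
    chains <- normalize_chain_annotations(chains)
    for (i in seq_len(nrow(chains))) {
      sid <- chains$structure_id[i]; ch <- chains$chain[i]
      cid <- paste0("chain:", sid, ":", ch)
      add_node(cid, "ProteinChain", structure_id = sid, chain = ch)
      add_edge(paste0("structure:", sid), cid, "CONTAINS")
      for (ec in chains$ec_ids[[i]]) {
        add_node(paste0("ec:", ec), "EC", ec = ec,
                 is_partial = any(parse_ec(ec) == "-"))
        add_edge(cid, paste0("ec:", ec), "IN_EC_CLASS")
      }
    }
  }

  if (!is.null(bound)) {
    for (i in seq_len(nrow(bound))) {
      bid <- paste0("bound:", bound$ligand_instance[i])
      add_node(bid, "BoundEntity",
               ligand_instance = bound$ligand_instance[i],
               structure_id = bound$structure_id[i],
               ccd_code = if ("ccd_code" %in% names(bound))
                 bound$ccd_code[i] else "",
               smiles = if ("smiles" %in% names(bound))
                 bound$smiles[i] else "")
    }
  }

  if (!is.null(interactions)) {
    for (i in seq_len(nrow(interactions))) {
      r <- interactions[i, ]
      did <- paste0("domain:", r$domain_db, ":", r$domain_id, ":", r$chain)
      add_node(did, "Domain", domain_db = r$domain_db,
               domain_id = r$domain_id, domain_family = r$domain_family,
               chain = r$chain)
      chain_id <- paste0("chain:", r$structure_id, ":", r$chain)
      if (!is.null(chains) &&
          any(chains$structure_id == r$structure_id &
                chains$chain == r$chain)) {
        add_edge(chain_id, did, "HAS_DOMAIN")
      }
      bid <- paste0("bound:", r$ligand_instance)
      if (is.null(bound) ||
          !r$ligand_instance %in% bound$ligand_instance) {
        add_node(bid, "BoundEntity", ligand_instance = r$ligand_instance,
                 structure_id = r$structure_id, ccd_code = "", smiles = "")
      }
      add_edge(did, bid, "INTERACTS_WITH", mode = r$mode,
               fraction = r$fraction, n_contacts = r$n_contacts,
               n_residues = r$n_residues)
    }
  }

  if (!is.null(cognates)) {
    cognates <- validate_cognates(cognates)
    for (i in seq_len(nrow(cognates))) {
      cid <- paste0("cognate:", cognates$cognate_id[i])
      add_node(cid, "CognateLigand", cognate_id = cognates$cognate_id[i],
               name = cognates$name[i], smiles = cognates$smiles[i],
               is_cofactor = cognates$is_cofactor[i])
      for (ec in cognates$ec_ids[[i]]) {
        add_node(paste0("ec:", ec), "EC", ec = ec, is_partial = FALSE)
        add_edge(cid, paste0("ec:", ec), "IN_EC_CLASS")
      }
    }
  }

  if (!is.null(matches) && nrow(matches) > 0) {
    if (is.null(cognates)) {
      stop("graph build error: matches supplied without cognates")
    }
    unknown <- setdiff(matches$cognate_id, cognates$cognate_id)
    if (length(unknown)) {
      stop("graph build error: match references unknown cognate(s): ",
           paste(utils::head(unknown, 5), collapse = ", "))
    }
    for (i in seq_len(nrow(matches))) {
      bid <- paste0("bound:", matches$bound_id[i])
      add_edge(bid, paste0("cognate:", matches$cognate_id[i]), "MAPS_TO",
               score = matches$score[i], is_best = matches$is_best[i])
    }
  }

  nodes <- if (length(nodes)) dplyr::bind_rows(nodes) else empty_nodes()
  edges <- if (length(edges)) dplyr::bind_rows(edges) else empty_edges()
  nodes <- nodes[!duplicated(nodes$node_id), , drop = FALSE]
  nodes <- dplyr::arrange(nodes, .data$node_id)
  edges <- dplyr::arrange(edges, .data$type, .data$start_id, .data$end_id)
  dangling <- setdiff(c(edges$start_id, edges$end_id), nodes$node_id)
  if (length(dangling)) {
    stop("graph build error: dangling node reference(s): ",
         paste(utils::head(dangling, 5), collapse = ", "))
  }
  structure(list(nodes = nodes, edges = edges), class = "cogmap_graph")
}

prop_chr <- function(x) {
  p <- vapply(x, function(v) {
    if (is.numeric(v)) format(v, digits = 15, trim = TRUE, scientific = FALSE)
    else if (is.logical(v)) ifelse(v, "true", "false")
    else as.character(v)
  }, character(1))
  p <- p[nzchar(p)]  # empty-string properties are not stored (round-trip exactness)
  p <- p[sort(names(p))]  # canonical key order, matching the flat-file headers
  if (length(p) == 0) p <- stats::setNames(character(0), character(0))
  p
}

empty_nodes <- function() {
  tibble::tibble(node_id = character(), label = character(),
                 properties = list())
}

empty_edges <- function() {
  tibble::tibble(start_id = character(), end_id = character(),
                 type = character(), properties = list())
}

#' @export
print.cogmap_graph <- function(x, ...) {
  cat(sprintf("<cogmap_graph> %d nodes (%s), %d edges (%s)\n",
              nrow(x$nodes),
              paste(sort(unique(x$nodes$label)), collapse = ", "),
              nrow(x$edges),
              paste(sort(unique(x$edges$type)), collapse = ", ")))
  invisible(x)
}

#' Write a graph as bulk-import flat files
#'
#' Emits one RFC 4180 CSV per node label under `nodes/` (header
#' `node_id:ID,...,:LABEL`) and one per edge type under `relationships/`
#' (header `:START_ID,...,:END_ID,:TYPE`), the convention of Neo4j's
#' admin-import tool, plus distribution TSVs under `distribution/`
#' (domain to cognate mapping and domain to bound-entity mapping per
#' domain database, and the ligand to cognate similarity mapping) and a
#' `manifest.json`. Row order is deterministic (sorted ids).
#'
#' @param graph A `cogmap_graph`.
#' @param outdir Output directory (created if needed).
#' @param interactions,matches Optional tibbles used to produce the
#'   distribution TSVs; omitted files are skipped.
#' @return Invisibly, the manifest (named list of written files).
#' @export
write_flatfiles <- function(graph, outdir, interactions = NULL,
                            matches = NULL) {
  stopifnot(inherits(graph, "cogmap_graph"))
  for (d in c("nodes", "relationships", "distribution")) {
    dir.create(file.path(outdir, d), showWarnings = FALSE, recursive = TRUE)
  }
  manifest <- list(nodes = list(), relationships = list(),
                   distribution = list())

  for (lab in sort(unique(graph$nodes$label))) {
    sub <- graph$nodes[graph$nodes$label == lab, , drop = FALSE]
    keys <- sort(unique(unlist(lapply(sub$properties, names))))
    df <- data.frame(`node_id:ID` = sub$node_id, check.names = FALSE,
                     stringsAsFactors = FALSE)
    for (k in keys) {
      df[[k]] <- vapply(sub$properties, function(p) {
        if (k %in% names(p)) p[[k]] else ""
      }, character(1))
    }
    df[[":LABEL"]] <- lab
    path <- file.path(outdir, "nodes", paste0(tolower(lab), ".csv"))
    utils::write.csv(df[order(df[["node_id:ID"]]), , drop = FALSE], path,
                     row.names = FALSE, quote = TRUE, fileEncoding = "UTF-8")
    manifest$nodes[[lab]] <- path
  }

  for (ty in sort(unique(graph$edges$type))) {
    sub <- graph$edges[graph$edges$type == ty, , drop = FALSE]
    keys <- sort(unique(unlist(lapply(sub$properties, names))))
    df <- data.frame(`:START_ID` = sub$start_id, check.names = FALSE,
                     stringsAsFactors = FALSE)
    for (k in keys) {
      df[[k]] <- vapply(sub$properties, function(p) {
        if (k %in% names(p)) p[[k]] else ""
      }, character(1))
    }
    df[[":END_ID"]] <- sub$end_id
    df[[":TYPE"]] <- ty
    path <- file.path(outdir, "relationships", paste0(tolower(ty), ".csv"))
    ord <- order(df[[":START_ID"]], df[[":END_ID"]])
    utils::write.csv(df[ord, , drop = FALSE], path, row.names = FALSE,
                     quote = TRUE, fileEncoding = "UTF-8")
    manifest$relationships[[ty]] <- path
  }

  if (!is.null(interactions)) {
    for (db in sort(unique(interactions$domain_db))) {
      p <- file.path(outdir, "distribution",
                     sprintf("domain_bound_entity_%s.tsv", db))
      readr::write_tsv(
        dplyr::filter(interactions, .data$domain_db == db), p)
      manifest$distribution[[paste0("domain_bound_entity_", db)]] <- p
    }
    if (!is.null(matches)) {
      dc <- interactions |>
        dplyr::filter(.data$mode != "minor") |>
        dplyr::inner_join(matches, by = c(ligand_instance = "bound_id"),
                          relationship = "many-to-many") |>
        dplyr::distinct(.data$domain_db, .data$domain_family,
                        .data$cognate_id, .data$score, .data$is_best)
      for (db in sort(unique(dc$domain_db))) {
        p <- file.path(outdir, "distribution",
                       sprintf("domain_cognate_%s.tsv", db))
        readr::write_tsv(dplyr::filter(dc, .data$domain_db == db), p)
        manifest$distribution[[paste0("domain_cognate_", db)]] <- p
      }
    }
  }
  if (!is.null(matches)) {
    p <- file.path(outdir, "distribution", "ligand_cognate_similarity.tsv")
    readr::write_tsv(
      dplyr::select(matches, "bound_id", "cognate_id", "score", "is_best"),
      p)
    manifest$distribution[["ligand_cognate_similarity"]] <- p
  }

  jsonlite::write_json(
    rapply(manifest, function(p) basename(p), how = "replace"),
    file.path(outdir, "manifest.json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Load a graph back from bulk-import flat files
#'
#' Inverse of [write_flatfiles()]: reading what was written reproduces the
#' node and edge multisets exactly.
#'
#' @param outdir Directory previously written by [write_flatfiles()].
#' @return A `cogmap_graph`.
#' @export
load_graph <- function(outdir) {
  node_files <- list.files(file.path(outdir, "nodes"), "\\.csv$",
                           full.names = TRUE)
  edge_files <- list.files(file.path(outdir, "relationships"), "\\.csv$",
                           full.names = TRUE)
  nodes <- lapply(node_files, function(f) {
    df <- utils::read.csv(f, check.names = FALSE, colClasses = "character")
    keys <- setdiff(names(df), c("node_id:ID", ":LABEL"))
    tibble::tibble(
      node_id = df[["node_id:ID"]], label = df[[":LABEL"]],
      properties = lapply(seq_len(nrow(df)), function(i) {
        p <- vapply(keys, function(k) df[[k]][i], character(1))
        p <- p[nzchar(p)]
        if (length(p) == 0) p <- stats::setNames(character(0), character(0))
        p
      }))
  })
  edges <- lapply(edge_files, function(f) {
    df <- utils::read.csv(f, check.names = FALSE, colClasses = "character")
    keys <- setdiff(names(df), c(":START_ID", ":END_ID", ":TYPE"))
    tibble::tibble(
      start_id = df[[":START_ID"]], end_id = df[[":END_ID"]],
      type = df[[":TYPE"]],
      properties = lapply(seq_len(nrow(df)), function(i) {
        p <- vapply(keys, function(k) df[[k]][i], character(1))
        p <- p[nzchar(p)]
        if (length(p) == 0) p <- stats::setNames(character(0), character(0))
        p
      }))
  })
  nodes <- if (length(nodes)) dplyr::bind_rows(nodes) else empty_nodes()
  edges <- if (length(edges)) dplyr::bind_rows(edges) else empty_edges()
  nodes <- dplyr::arrange(nodes, .data$node_id)
  edges <- dplyr::arrange(edges, .data$type, .data$start_id, .data$end_id)
  structure(list(nodes = nodes, edges = edges), class = "cogmap_graph")
}
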