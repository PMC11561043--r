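#' @useDynLib cogmap, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Parse a SMILES string into a heavy-atom molecular graph
#'
#' Sanitizes and canonicalizes a SMILES string (OpenBabel backend via
#' ChemmineR/ChemmineOB), strips hydrogens, and for multi-fragment input
#' (salts) keeps the largest fragment by heavy-atom count, breaking ties by
#' the lexicographically smallest canonical SMILES.
#'
#' @param smiles A single SMILES string.
#' @param id Identifier carried on the molecule (defaults to the SMILES).
#' @return An object of class `molecule`: a list with `id`, `smiles`
#'   (canonical, kept fragment), `elements` (character vector of element
#'   symbols, heavy atoms only), `bonds` (integer matrix with columns
#'   `a`, `b`, `order`, `ring`), and `n_heavy`.
#' @examples
#' \dontrun{
#' m <- parse_smiles("Oc1ccccc1O", "catechol")
#' m$n_heavy  # 8
#' }
#' @export
parse_smiles <- function(smiles, id = smiles) {
  if (!is.character(smiles) || length(smiles) != 1L || is.na(smiles) ||
      !nzchar(trimws(smiles))) {
    stop(parse_error("empty or non-string SMILES", smiles, id))
  }
  smiles <- trimws(smiles)
  can <- tryCatch(canonical_smiles(smiles),
                  error = function(e) {
                    stop(parse_error(conditionMessage(e), smiles, id))
                  })
  frags <- strsplit(can, ".", fixed = TRUE)[[1]]
  frags <- frags[nzchar(frags)]
  if (length(frags) == 0L) stop(parse_error("no atoms", smiles, id))
  if (length(frags) > 1L) {
    parsed <- lapply(frags, ob_atoms_bonds)
    sizes <- vapply(parsed, function(p) length(p$elements), integer(1))
    cand <- which(sizes == max(sizes))
    keep <- cand[order(frags[cand])][1L]
    frag_smiles <- canonical_smiles(frags[keep])
    ab <- ob_atoms_bonds(frag_smiles)
  } else {
    frag_smiles <- can
    ab <- ob_atoms_bonds(can)
  }
  if (length(ab$elements) < 1L) {
    stop(parse_error("no heavy atoms after hydrogen removal", smiles, id))
  }
  structure(
    list(id = id, smiles = frag_smiles, elements = ab$elements,
         bonds = ab$bonds, n_heavy = length(ab$elements)),
    class = "molecule"
  )
}

parse_error <- function(msg, smiles, id) {
  structure(
    class = c("cogmap_parse_error", "error", "condition"),
    list(message = sprintf("cannot parse SMILES for '%s': %s [%s]",
                           id, msg, smiles),
         call = NULL, smiles = smiles, id = id)
  )
}

canonical_smiles <- function(smiles) {
  out <- suppressWarnings(
    ChemmineOB::convertFormat("SMI", "CAN", source = smiles)
  )
  out <- trimws(sub("\t.*$", "", out))
  if (!nzchar(out)) stop("OpenBabel produced no canonical SMILES")
  out
}

# Atom elements and heavy-atom bond table from a single-fragment SMILES.
# Hydrogens (including explicit [H]) are dropped; bond indices re-based.
ob_atoms_bonds <- function(smiles) {
  sdfset <- suppressWarnings(ChemmineR::smiles2sdf(stats::setNames(smiles, "m")))
  if (!ChemmineR::validSDF(sdfset)[1]) {
    # bond-free molecules (single heavy atom) trip ChemmineR's SDF reader
    return(molfile_atoms_bonds(smiles))
  }
  sdf <- sdfset[[1]]
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  elements <- sub("_.*$", "", rownames(ab))
  heavy <- which(elements != "H")
  idx_map <- integer(length(elements))
  idx_map[heavy] <- seq_along(heavy)
  bonds <- matrix(integer(0), ncol = 4,
                  dimnames = list(NULL, c("a", "b", "order", "ring")))
  if (!is.null(bb) && nrow(bb) > 0) {
    b1 <- as.integer(bb[, 1]); b2 <- as.integer(bb[, 2])
    ord <- as.integer(bb[, 3])
    keep <- elements[b1] != "H" & elements[b2] != "H"
    if (any(keep)) {
      bonds <- cbind(a = idx_map[b1[keep]], b = idx_map[b2[keep]],
                     order = ord[keep], ring = 0L)
      bonds[, "ring"] <- ring_bond_flags(bonds, length(heavy))
    }
  }
  list(elements = elements[heavy], bonds = bonds)
}

# Fixed-width V2000 fallback used when the SDF has no bond block.
molfile_atoms_bonds <- function(smiles) {
  txt <- suppressWarnings(
    ChemmineOB::convertFormat("SMI", "SDF", source = smiles))
  lines <- strsplit(txt, "\n", fixed = TRUE)[[1]]
  if (length(lines) < 4) stop("OpenBabel produced no molfile")
  natoms <- as.integer(substr(lines[4], 1, 3))
  nbonds <- as.integer(substr(lines[4], 4, 6))
  if (is.na(natoms) || natoms < 1) stop("molfile reports no atoms")
  atom_lines <- lines[4 + seq_len(natoms)]
  elements <- trimws(substr(atom_lines, 32, 34))
  heavy <- which(elements != "H")
  idx_map <- integer(length(elements))
  idx_map[heavy] <- seq_along(heavy)
  bonds <- matrix(integer(0), ncol = 4,
                  dimnames = list(NULL, c("a", "b", "order", "ring")))
  if (!is.na(nbonds) && nbonds > 0) {
    bl <- lines[4 + natoms + seq_len(nbonds)]
    b1 <- as.integer(substr(bl, 1, 3)); b2 <- as.integer(substr(bl, 4, 6))
    ord <- as.integer(substr(bl, 7, 9))
    keep <- elements[b1] != "H" & elements[b2] != "H"
    if (any(keep)) {
      bonds <- cbind(a = idx_map[b1[keep]], b = idx_map[b2[keep]],
                     order = ord[keep], ring = 0L)
      bonds[, "ring"] <- ring_bond_flags(bonds, length(heavy))
    }
  }
  list(elements = elements[heavy], bonds = bonds)
}

# A bond lies in a ring iff its endpoints stay connected when it is removed.
ring_bond_flags <- function(bonds, n_atoms) {
  nb <- nrow(bonds)
  flags <- integer(nb)
  adj <- vector("list", n_atoms)
  for (k in seq_len(nb)) {
    adj[[bonds[k, "a"]]] <- c(adj[[bonds[k, "a"]]], k)
    adj[[bonds[k, "b"]]] <- c(adj[[bonds[k, "b"]]], k)
  }
  for (k in seq_len(nb)) {
    src <- bonds[k, "a"]; dst <- bonds[k, "b"]
    seen <- logical(n_atoms); seen[src] <- TRUE
    queue <- src
    while (length(queue) && !seen[dst]) {
      v <- queue[1]; queue <- queue[-1]
      for (e in adj[[v]]) {
        if (e == k) next
        w <- if (bonds[e, "a"] == v) bonds[e, "b"] else bonds[e, "a"]
        if (!seen[w]) { seen[w] <- TRUE; queue <- c(queue, w) }
      }
    }
    flags[k] <- as.integer(seen[dst])
  }
  flags
}

#' @export
print.molecule <- function(x, ...) {
  cat(sprintf("<molecule> %s: %s (%d heavy atoms)\n",
              x$id, x$smiles, x$n_heavy))
  invisible(x)
}

#' Parse a table of ligands, skipping unparseable entries
#'
#' Molecules that fail sanitation are excluded with a warning rather than
#' aborting the batch.
#'
#' @param ligands A data frame with columns `id` and `smiles` (other columns
#'   ignored), or a character vector of SMILES (optionally named by id).
#' @return A named list of `molecule` objects; ids of failed entries are
#'   attached as attribute `failed`.
#' @export
parse_ligands <- function(ligands) {
  if (is.character(ligands)) {
    ids <- if (is.null(names(ligands))) ligands else names(ligands)
    ligands <- tibble::tibble(id = ids, smiles = unname(ligands))
  }
  stopifnot(all(c("id", "smiles") %in% names(ligands)))
  out <- vector("list", nrow(ligands))
  ok <- logical(nrow(ligands))
  for (i in seq_len(nrow(ligands))) {
    m <- tryCatch(parse_smiles(ligands$smiles[i], ligands$id[i]),
                  cogmap_parse_error = function(e) e)
    if (inherits(m, "molecule")) {
      out[[i]] <- m; ok[i] <- TRUE
    }
  }
  if (any(!ok)) {
    warning(sprintf("excluded %d unparseable ligand(s): %s", sum(!ok),
                    paste(utils::head(ligands$id[!ok], 5), collapse = ", ")))
  }
  res <- out[ok]
  names(res) <- ligands$id[ok]
  attr(res, "failed") <- ligands$id[!ok]
  res
}

#' Read a ligand TSV (columns id, name, smiles)
#'
#' @param path Path to a tab-separated file with a header; columns `id` and
#'   `smiles` are required, others are passed through.
#' @return A tibble.
#' @export
read_ligand_table <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(c("id", "smiles"), names(df))
  if (length(missing)) {
    stop(sprintf("ligand table %s lacks required column(s): %s",
                 path, paste(missing, collapse = ", ")))
  }
  df
}

#' PARITY similarity between two molecules
#'
#' The Proportion of Atoms Residing in Identical Topology: the size of the
#' connected maximum common substructure (atoms matched on element identity;
#' bond order, aromaticity and formal charge ignored) normalized as a Jaccard
#' index over heavy atoms, |MCS| / (N_a + N_b - |MCS|). 1 means the
#' heavy-atom graphs are isomorphic, 0 means no shared connected fragment.
#'
#' @param a,b `molecule` objects.
#' @param timeout_s Wall-clock budget for the substructure search, seconds.
#'   On timeout the best score found so far is returned with `timed_out`
#'   set, never silently reported as exact.
#' @param match_rings If `TRUE`, a ring bond may only match a ring bond.
#'   Off by default.
#' @return An object of class `parity_result`: list with `score` in
#'   \[0, 1\], `mcs_atom_count`, and `timed_out`.
#' @examples
#' \dontrun{
#' a <- parse_smiles("Oc1ccccc1O", "catechol")
#' b <- parse_smiles("Oc1cccc(Cl)c1O", "3-chlorocatechol")
#' parity_score(a, b)$score  # 8/9 = 0.889
#' }
#' @export
parity_score <- function(a, b, timeout_s = 10, match_rings = FALSE) {
  stopifnot(inherits(a, "molecule"), inherits(b, "molecule"),
            timeout_s > 0)
  labs <- union(a$elements, b$elements)
  la <- match(a$elements, labs) - 1L
  lb <- match(b$elements, labs) - 1L
  res <- mccs_search(la, adjacency_matrix(a), lb, adjacency_matrix(b),
                     as.numeric(timeout_s), isTRUE(match_rings))
  m <- res$mcs_atom_count
  score <- if (m == 0) 0 else m / (a$n_heavy + b$n_heavy - m)
  structure(list(score = score, mcs_atom_count = m,
                 timed_out = isTRUE(res$timed_out)),
            class = "parity_result")
}

#' @export
print.parity_result <- function(x, ...) {
  cat(sprintf("<parity> score = %.4f (|MCS| = %d%s)\n", x$score,
              x$mcs_atom_count, if (x$timed_out) ", TIMED OUT" else ""))
  invisible(x)
}

# 0 = no bond, 1 = chain bond, 2 = ring bond
adjacency_matrix <- function(m) {
  n <- m$n_heavy
  adj <- matrix(0L, n, n)
  if (nrow(m$bonds)) {
    val <- 1L + m$bonds[, "ring"]
    adj[cbind(m$bonds[, "a"], m$bonds[, "b"])] <- val
    adj[cbind(m$bonds[, "b"], m$bonds[, "a"])] <- val
  }
  adj
}

#' MACCS 166-key structural fingerprint
#'
#' Computed with OpenBabel's MACCS SMARTS key set on the molecule's
#' canonical SMILES; deterministic for a given molecule.
#'
#' @param m A `molecule`.
#' @return A `maccs_fp`: integer 0/1 vector of length 166 with a
#'   `key_version` attribute.
#' @export
maccs_fingerprint <- function(m) {
  stopifnot(inherits(m, "molecule"))
  fp <- ChemmineOB::fingerprint_OB(
    ChemmineOB::forEachMol("SMILES", m$smiles, identity), "MACCS")
  bits <- as.integer(fp[seq_len(166)])
  structure(bits, class = "maccs_fp", key_version = "openbabel-MACCS-166")
}

#' Tanimoto similarity of two fingerprints
#'
#' |a AND b| / |a OR b|; defined as 1 when both fingerprints are empty.
#'
#' @param a,b Binary fingerprint vectors of equal length (166 for MACCS).
#' @return Similarity in \[0, 1\].
#' @export
tanimoto <- function(a, b) {
  a <- as.integer(unclass(a)); b <- as.integer(unclass(b))
  if (length(a) != length(b)) {
    stop("fingerprint length mismatch: ", length(a), " vs ", length(b))
  }
  union_ct <- sum(a | b)
  if (union_ct == 0) return(1.0)
  sum(a & b) / union_ct
}
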