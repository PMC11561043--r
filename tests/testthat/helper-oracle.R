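# Independent brute-force oracles used to pin expected values.
# These deliberately share no code with the package's search engine.

# All connected common subgraphs of two molecules, enumerated over the
# pair-compatibility (product) graph: vertices are element-matched atom
# pairs, edges join pairs whose atoms are bonded in both molecules.  A
# common connected subgraph is a connected, pairwise non-conflicting
# vertex set of that graph.  Returns the maximum atom count.  Exponential;
# intended for molecules of <= 8 heavy atoms.
oracle_mccs <- function(a, b) {
  na <- a$n_heavy; nb <- b$n_heavy
  adj_a <- matrix(FALSE, na, na); adj_b <- matrix(FALSE, nb, nb)
  if (nrow(a$bonds)) {
    adj_a[a$bonds[, c("a", "b")]] <- TRUE
    adj_a[a$bonds[, c("b", "a")]] <- TRUE
  }
  if (nrow(b$bonds)) {
    adj_b[b$bonds[, c("a", "b")]] <- TRUE
    adj_b[b$bonds[, c("b", "a")]] <- TRUE
  }
  verts <- which(outer(a$elements, b$elements, "=="), arr.ind = TRUE)
  nv <- nrow(verts)
  if (nv == 0) return(0L)
  # product-graph connection and conflict relations
  conn <- matrix(FALSE, nv, nv); conflict <- matrix(FALSE, nv, nv)
  for (u in seq_len(nv)) {
    for (v in seq_len(nv)) {
      if (u == v) next
      iu <- verts[u, 1]; ju <- verts[u, 2]
      iv <- verts[v, 1]; jv <- verts[v, 2]
      if (iu == iv || ju == jv) { conflict[u, v] <- TRUE; next }
      if (adj_a[iu, iv] && adj_b[ju, jv]) conn[u, v] <- TRUE
    }
  }
  best <- 1L
  seen <- new.env(hash = TRUE, parent = emptyenv())
  grow <- function(set) {
    key <- paste(set, collapse = ",")
    if (!is.null(seen[[key]])) return(invisible())
    assign(key, TRUE, envir = seen)
    if (length(set) > best) best <<- length(set)
    reach <- which(apply(conn[set, , drop = FALSE], 2, any))
    ok <- setdiff(reach, set)
    ok <- ok[!apply(conflict[set, ok, drop = FALSE], 2, any)]
    for (w in ok) grow(sort(c(set, w)))
  }
  for (v in seq_len(nv)) grow(v)
  best
}

# Is molecule `small` embeddable whole into `big` (element-matched,
# any-bond)?  Plain backtracking over injective mappings.  When TRUE and
# small is connected, |MCS| = small$n_heavy exactly.
oracle_embeds <- function(small, big) {
  ns <- small$n_heavy; nbg <- big$n_heavy
  if (ns > nbg) return(FALSE)
  adj_s <- matrix(FALSE, ns, ns); adj_b <- matrix(FALSE, nbg, nbg)
  if (nrow(small$bonds)) {
    adj_s[small$bonds[, c("a", "b")]] <- TRUE
    adj_s[small$bonds[, c("b", "a")]] <- TRUE
  }
  if (nrow(big$bonds)) {
    adj_b[big$bonds[, c("a", "b")]] <- TRUE
    adj_b[big$bonds[, c("b", "a")]] <- TRUE
  }
  assign_next <- function(mapping) {
    i <- length(mapping) + 1L
    if (i > ns) return(TRUE)
    for (j in setdiff(seq_len(nbg), mapping)) {
      if (small$elements[i] != big$elements[j]) next
      ok <- TRUE
      for (p in seq_len(i - 1L)) {
        if (adj_s[i, p] && !adj_b[j, mapping[p]]) { ok <- FALSE; break }
      }
      if (ok && assign_next(c(mapping, j))) return(TRUE)
    }
    FALSE
  }
  assign_next(integer(0))
}

# Tanimoto by explicit popcount arithmetic (independent of tanimoto()).
oracle_tanimoto <- function(a, b) {
  a <- as.integer(unclass(a)); b <- as.integer(unclass(b))
  inter <- sum(a == 1L & b == 1L)
  uni <- sum(a == 1L) + sum(b == 1L) - inter
  if (uni == 0) 1.0 else inter / uni
}
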