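test_that("parse_smiles builds sanitized heavy-atom graphs", {
  m <- parse_smiles("Oc1ccccc1O", "catechol")
  expect_s3_class(m, "molecule")
  expect_equal(m$n_heavy, 8)
  expect_equal(sum(m$elements == "C"), 6)
  expect_equal(sum(m$elements == "O"), 2)
  expect_equal(length(m$elements), m$n_heavy)

  expect_equal(parse_smiles("C", "methane")$n_heavy, 1)
  expect_error(parse_smiles("not_a_smiles", "junk"),
               class = "cogmap_parse_error")
  expect_error(parse_smiles("", "empty"), class = "cogmap_parse_error")

  # hydrogens never enter the graph, explicit or implicit
  m2 <- parse_smiles("[H]OC([H])([H])O[H]", "methanediol")
  expect_equal(m2$n_heavy, 3)
  expect_false(any(m2$elements == "H"))

  # re-parsing the canonical SMILES gives the same graph size and formula
  m3 <- parse_smiles(m$smiles, "reparsed")
  expect_equal(m3$n_heavy, m$n_heavy)
  expect_equal(sort(m3$elements), sort(m$elements))
})

test_that("multi-fragment SMILES keep the largest fragment", {
  m <- parse_smiles("CCO.[Na+]", "salt")
  expect_equal(m$n_heavy, 3)
  expect_false("Na" %in% m$elements)
  # tie on size: lexicographically smallest canonical SMILES wins
  tie <- parse_smiles("O.C", "tie")
  expect_equal(tie$n_heavy, 1)
  expect_equal(tie$elements, "C")
})

test_that("parse_ligands skips failures with a warning instead of aborting", {
  tab <- tibble::tibble(id = c("ok1", "bad", "ok2"),
                        smiles = c("CCO", "xyz(((", "c1ccccc1"))
  expect_warning(mols <- parse_ligands(tab), "excluded 1")
  expect_named(mols, c("ok1", "ok2"))
  expect_equal(attr(mols, "failed"), "bad")
})

test_that("PARITY reproduces the two published worked examples", {
  cat_ <- parse_smiles("Oc1ccccc1O", "catechol")
  ccat <- parse_smiles("Oc1cccc(Cl)c1O", "3-chlorocatechol")
  r1 <- parity_score(cat_, ccat)
  expect_equal(r1$mcs_atom_count, 8)
  expect_equal(r1$score, 8 / 9)
  expect_equal(round(r1$score, 2), 0.89)
  expect_false(r1$timed_out)

  wm <- worked_example_molecules()
  r2 <- parity_score(wm$hexylglutathione, wm$lactoylglutathione)
  expect_equal(r2$mcs_atom_count, 23)  # frozen from independent MCS oracle
  expect_equal(r2$score, 23 / 28)
  expect_equal(round(r2$score, 2), 0.82)
})

test_that("PARITY identity, disjointness and append monotonicity", {
  mols <- lapply(c("C", "CCO", "Oc1ccccc1O", "CC(C)CC", "OC(=O)CC(=O)O"),
                 parse_smiles)
  for (m in mols) {
    r <- parity_score(m, m)
    expect_equal(r$score, 1.0)
    expect_equal(r$mcs_atom_count, m$n_heavy)
  }
  expect_equal(parity_score(parse_smiles("C"), parse_smiles("O"))$score, 0)

  # appending an atom to one molecule of an identical pair: n/(n+1)
  for (n in c(3, 6, 10)) {
    a <- parse_smiles(strrep("C", n))
    b <- parse_smiles(strrep("C", n + 1))
    expect_equal(parity_score(a, b)$score, n / (n + 1))
  }
})

test_that("PARITY is symmetric across random fixture pairs", {
  lib <- fixture_ligand_library()
  set.seed(11)
  idx <- matrix(sample.int(nrow(lib), 40, replace = TRUE), ncol = 2)
  for (k in seq_len(nrow(idx))) {
    a <- parse_smiles(lib$smiles[idx[k, 1]])
    b <- parse_smiles(lib$smiles[idx[k, 2]])
    sab <- parity_score(a, b)$score
    sba <- parity_score(b, a)$score
    expect_equal(sab, sba)
    expect_gte(sab, 0); expect_lte(sab, 1)
  }
})

test_that("MCS equals the brute-force oracle on small molecules", {
  smiles <- c("CCO", "CCCO", "CC(C)O", "OCC(N)C", "C1CC1C", "Oc1ccccc1O",
              "CC=O", "NCCS")
  mols <- lapply(smiles, parse_smiles)
  stopifnot(all(vapply(mols, function(m) m$n_heavy, integer(1)) <= 8))
  for (i in seq_along(mols)) {
    for (j in seq(i, length(mols))) {
      got <- parity_score(mols[[i]], mols[[j]])$mcs_atom_count
      expect_equal(got, oracle_mccs(mols[[i]], mols[[j]]),
                   info = paste(smiles[i], "vs", smiles[j]))
    }
  }
})

test_that("ring-bond matching constraint is available and off by default", {
  hexane <- parse_smiles("CCCCCC")
  cyclohexane <- parse_smiles("C1CCCCC1")
  # default: a chain may trace through the ring
  expect_equal(parity_score(hexane, cyclohexane)$mcs_atom_count, 6)
  # with ring matching, chain bonds cannot match ring bonds
  strict <- parity_score(hexane, cyclohexane, match_rings = TRUE)
  expect_lt(strict$mcs_atom_count, 6)
})

test_that("MACCS fingerprints are 166-bit, deterministic and structure-rich", {
  cat_ <- parse_smiles("Oc1ccccc1O", "catechol")
  fp <- maccs_fingerprint(cat_)
  expect_length(unclass(fp), 166)
  expect_true(all(unclass(fp) %in% c(0L, 1L)))
  expect_gt(sum(unclass(fp)), 0)
  expect_identical(unclass(maccs_fingerprint(parse_smiles("Oc1ccccc1O"))),
                   unclass(fp))
  # methane triggers almost no structural keys
  expect_lte(sum(unclass(maccs_fingerprint(parse_smiles("C")))), 3)
})

test_that("tanimoto matches popcount arithmetic", {
  mk <- function(bits) { v <- integer(166); v[bits] <- 1L; v }
  expect_equal(tanimoto(mk(c(1, 2, 3)), mk(c(2, 3, 4))), 0.5)
  expect_equal(tanimoto(mk(1:10), mk(1:10)), 1.0)
  expect_equal(tanimoto(mk(1:5), mk(6:10)), 0.0)
  expect_equal(tanimoto(mk(integer(0)), mk(integer(0))), 1.0)
  expect_error(tanimoto(mk(1), integer(10)), "mismatch")
  set.seed(42)
  for (k in 1:20) {
    a <- rbinom(166, 1, 0.3); b <- rbinom(166, 1, 0.3)
    expect_equal(tanimoto(a, b), oracle_tanimoto(a, b))
  }
})
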