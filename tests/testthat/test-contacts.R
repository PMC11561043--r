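test_that("contact tables load, validate and merge duplicates", {
  tab <- contacts_for_fractions("LIG1", c(0.6, 0.4), n_res = 6)
  expect_equal(nrow(tab), 12)
  path <- withr_local_tsv(tab)
  rec <- load_contacts(path)
  expect_equal(nrow(rec), 12)
  expect_true(all(required_cols_present(rec)))

  dup <- dplyr::bind_rows(tab, tab[1, ])
  expect_warning(merged <- validate_contacts(dup), "merged")
  expect_equal(nrow(merged), 12)
  expect_equal(sum(merged$n_contacts), sum(tab$n_contacts) + tab$n_contacts[1])

  expect_error(load_contacts(withr_local_tsv(tab[, -4])), "residue")

  empty <- tab[0, ]
  expect_warning(out <- load_contacts(withr_local_tsv(empty)), "empty")
  expect_equal(nrow(out), 0)
})

test_that("minimum-residue filter drops sparse pairs and orphan ligands", {
  tab <- dplyr::bind_rows(
    contact_rows("S1", "LIG1", "A", "DOM_OK", 1:3, 5),
    contact_rows("S1", "LIG1", "A", "DOM_SPARSE", 10:11, 50),
    contact_rows("S1", "LIG2", "A", "DOM_ONLY2RES", 1:2, 9))
  filt <- filter_min_residues(tab)
  expect_setequal(unique(filt$domain_id), "DOM_OK")      # 2-residue pair gone
  expect_false("LIG2" %in% filt$ligand_instance)         # orphan ligand gone
  # boundary: exactly 3 residues retained
  expect_equal(sum(filt$domain_id == "DOM_OK"), 3)
})

test_that("gini closed forms and scale invariance are exact", {
  expect_equal(gini(c(5, 5, 5)), 0)
  expect_equal(gini(c(0, 1)), 0.5)
  expect_equal(gini(c(1, 0, 0, 0)), 0.75)   # (n-1)/n for one non-zero, n = 4
  for (n in 2:6) {
    expect_equal(gini(c(1, rep(0, n - 1))), (n - 1) / n)
  }
  x <- c(2, 3, 7, 11)
  expect_equal(gini(17 * x), gini(x))
  expect_error(gini(numeric(0)))
  expect_error(gini(c(0, 0)))
  expect_error(gini(c(-1, 2)))
})

test_that("interaction modes match the printed inequalities exhaustively", {
  # all fraction vectors on a 0.01 grid, 1 to 4 domains
  check_vec <- function(frac) {
    tab <- contacts_for_fractions("L", frac)
    got <- assign_interaction_modes(tab)
    got <- got[order(got$domain_id), ]
    want <- vapply(frac, expected_mode, character(1), all_f = frac)
    expect_identical(got$mode, want)
  }
  # k = 1
  check_vec(1)
  # k = 2: full grid
  for (a in seq(1, 99)) check_vec(c(a, 100 - a) / 100)
  # k = 3 and 4: coarser sweep plus all printed boundary cases
  for (a in seq(5, 90, by = 5)) {
    for (b in seq(5, 95 - a, by = 5)) {
      check_vec(c(a, b, 100 - a - b) / 100)
    }
  }
  for (a in seq(10, 70, by = 10)) {
    for (b in seq(10, 80 - a, by = 10)) {
      check_vec(c(a, b, 10, 90 - a - b) / 100)
    }
  }
  check_vec(c(0.93, 0.07)); check_vec(c(0.9, 0.1)); check_vec(c(0.5, 0.5))
  check_vec(c(0.6, 0.4)); check_vec(c(0.85, 0.08, 0.07))
  check_vec(c(0.89, 0.11)); check_vec(c(0.1, 0.9)); check_vec(c(0.91, 0.09))
})

test_that("fractions sum to one per ligand after filtering", {
  fx <- generate_fixture_tables(fixture_spec(n_structures = 8))
  ia <- assign_interaction_modes(filter_min_residues(fx$contacts))
  sums <- tapply(ia$fraction, paste(ia$domain_db, ia$ligand_instance), sum)
  expect_true(all(abs(sums - 1) < 1e-9))
})

test_that("classification is invariant to input row order", {
  fx <- generate_fixture_tables(fixture_spec(n_structures = 5))
  set.seed(2)
  shuffled <- fx$contacts[sample.int(nrow(fx$contacts)), ]
  a <- assign_interaction_modes(filter_min_residues(fx$contacts))
  b <- assign_interaction_modes(filter_min_residues(shuffled))
  expect_identical(a, b)
})

test_that("pre-filter denominators are available as the alternative", {
  tab <- dplyr::bind_rows(
    contact_rows("S1", "L1", "A", "DBIG", 1:4, 24),   # 96 contacts
    contact_rows("S1", "L1", "A", "DTINY", 10:11, 2)) # 4 contacts, filtered
  filt <- filter_min_residues(tab)
  renorm <- assign_interaction_modes(filt)
  prefil <- assign_interaction_modes(filt, prefilter_contacts = tab)
  expect_equal(renorm$fraction, 1.0)
  expect_equal(prefil$fraction, 0.96)
})

test_that("gini_report flags unequal multi-domain interactions", {
  tab <- dplyr::bind_rows(
    contacts_for_fractions("EQ", c(0.5, 0.5)),
    contacts_for_fractions("UNEQ", c(0.9, 0.1)))
  rep_ <- gini_report(assign_interaction_modes(tab))
  expect_equal(rep_$gini[rep_$ligand_instance == "EQ"], 0, tolerance = 1e-3)
  expect_gt(rep_$gini[rep_$ligand_instance == "UNEQ"], 0.3)
  expect_true(all(rep_$gini >= 0 & rep_$gini < 1))
})

test_that("combinatorial interactions require >= 2 nonminor domains and a match", {
  ia <- assign_interaction_modes(dplyr::bind_rows(
    contacts_for_fractions("PAIR", c(0.6, 0.4)),
    contacts_for_fractions("SOLO", 1),
    contacts_for_fractions("DOM", c(0.93, 0.07))))
  matches <- tibble::tibble(bound_id = c("PAIR", "SOLO", "DOM"),
                            cognate_id = "COGX", score = 0.82,
                            timed_out = FALSE, passed_threshold = TRUE,
                            is_best = TRUE)
  cc <- combinatorial_interactions(ia, matches)
  expect_equal(cc$ligand_instance, "PAIR")
  expect_equal(cc$combination, "D1+D2")
  expect_equal(cc$best_score, 0.82)

  # unmatched ligands yield no record
  expect_equal(nrow(combinatorial_interactions(ia, matches[0, ])), 0)

  # duplicated family (two chains) keeps the duplicate in the key
  dup <- dplyr::bind_rows(
    contact_rows("S1", "DIMER", "A", "D1", 1:3, 10, domain_family = "SF1"),
    contact_rows("S1", "DIMER", "B", "D1", 1:3, 10, domain_family = "SF1"))
  iad <- assign_interaction_modes(dup)
  ccd <- combinatorial_interactions(
    iad, dplyr::mutate(matches[1, ], bound_id = "DIMER"))
  expect_equal(ccd$combination, "SF1+SF1")
})
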