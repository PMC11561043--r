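test_that("promiscuity is a >=4 distinct-cognate property of the family", {
  # family FPROM reaches 4 cognates through 2 ligand instances;
  # family FTHREE reaches only 3.
  ia <- assign_interaction_modes(dplyr::bind_rows(
    contact_rows("S1", "L1", "A", "d1", 1:3, 5, domain_family = "FPROM"),
    contact_rows("S2", "L2", "A", "d2", 1:3, 5, domain_family = "FPROM"),
    contact_rows("S3", "L3", "A", "d3", 1:3, 5, domain_family = "FTHREE")))
  mt <- tibble::tibble(
    bound_id = c("L1", "L1", "L2", "L2", "L3", "L3", "L3"),
    cognate_id = c("c1", "c2", "c3", "c4", "c1", "c2", "c3"),
    score = 0.8, timed_out = FALSE, passed_threshold = TRUE,
    is_best = TRUE)
  cogs <- make_cognates(paste0("c", 1:4),
                        c("CCO", "CCCO", "CCCCO", "CCCCCO"),
                        sprintf("1.1.1.%d", 1:4))
  prof <- build_domain_profiles(ia, mt, cogs)
  expect_equal(prof$n_cognates[prof$domain_family == "FPROM"], 4)
  expect_true(prof$is_promiscuous[prof$domain_family == "FPROM"])
  expect_equal(prof$n_cognates[prof$domain_family == "FTHREE"], 3)
  expect_false(prof$is_promiscuous[prof$domain_family == "FTHREE"])
  expect_equal(prof$class[prof$domain_family == "FTHREE"],
               "not_promiscuous")

  # brute-force recount of (family, cognate) pairs agrees
  recount <- unique(merge(
    as.data.frame(ia[ia$mode != "minor",
                     c("ligand_instance", "domain_family")]),
    data.frame(ligand_instance = mt$bound_id, cognate_id = mt$cognate_id))
    [, c("domain_family", "cognate_id")])
  expect_equal(prof$n_cognates,
               as.vector(table(recount$domain_family)[prof$domain_family]))
})

test_that("duplicate structures do not inflate the cognate count", {
  ia <- assign_interaction_modes(dplyr::bind_rows(
    contact_rows("S1", "L1", "A", "d1", 1:3, 5, domain_family = "F"),
    contact_rows("S2", "L2", "A", "d1", 1:3, 5, domain_family = "F")))
  mt <- tibble::tibble(bound_id = c("L1", "L2"), cognate_id = "cSAME",
                       score = 1, timed_out = FALSE,
                       passed_threshold = TRUE, is_best = TRUE)
  cogs <- make_cognates("cSAME", "CCO", "1.1.1.1")
  prof <- build_domain_profiles(ia, mt, cogs)
  expect_equal(prof$n_cognates, 1)
})

test_that("specialized and generalized split promiscuous families exhaustively", {
  ia <- assign_interaction_modes(dplyr::bind_rows(
    contact_rows("S1", "L1", "A", "d1", 1:3, 5, domain_family = "FSPEC"),
    contact_rows("S2", "L2", "A", "d2", 1:3, 5, domain_family = "FGEN")))
  # FSPEC: four long-chain alcohols, nearly identical key sets
  # FGEN: four chemically disjoint scaffolds
  cogs <- make_cognates(
    c(paste0("spec", 1:4), paste0("gen", 1:4)),
    c("CCCCCCCCCCO", "CCCCCCCCCCCO", "CCCCCCCCCO", "CCCCCCCCCCCCO",
      "CCCCCCCC", "Oc1ccc(Cl)cc1O", "NC(CCSC)C(=O)O", "OCC1OC(O)C(O)C1O"),
    sprintf("1.1.1.%d", 1:8))
  mt <- tibble::tibble(
    bound_id = c(rep("L1", 4), rep("L2", 4)),
    cognate_id = c(paste0("spec", 1:4), paste0("gen", 1:4)),
    score = 0.9, timed_out = FALSE, passed_threshold = TRUE, is_best = TRUE)
  prof <- build_domain_profiles(ia, mt, cogs)
  expect_true(all(prof$is_promiscuous))
  expect_equal(prof$class[prof$domain_family == "FSPEC"], "specialized")
  expect_gte(prof$mean_pairwise_tanimoto[prof$domain_family == "FSPEC"],
             0.575)
  expect_equal(prof$class[prof$domain_family == "FGEN"], "generalized")
  expect_lt(prof$mean_pairwise_tanimoto[prof$domain_family == "FGEN"],
            0.575)
  expect_true(all(prof$class %in% c("specialized", "generalized")))
})

test_that("fewer than two cognates leave the similarity undefined", {
  ia <- assign_interaction_modes(
    contact_rows("S1", "L1", "A", "d1", 1:3, 5, domain_family = "F"))
  mt <- tibble::tibble(bound_id = "L1", cognate_id = "c1", score = 1,
                       timed_out = FALSE, passed_threshold = TRUE,
                       is_best = TRUE)
  prof <- build_domain_profiles(ia, mt, make_cognates("c1", "CCO", "1.1.1.1"))
  expect_true(is.na(prof$mean_pairwise_tanimoto))
})

test_that("EC diversity counts distinct complete ECs over matched chains", {
  ia <- assign_interaction_modes(dplyr::bind_rows(
    contact_rows("S1", "L1", "A", "d1", 1:3, 5, domain_family = "F1"),
    contact_rows("S2", "L2", "A", "d2", 1:3, 5, domain_family = "F1"),
    contact_rows("S3", "L3", "A", "d3", 1:3, 5, domain_family = "F2")))
  mt <- tibble::tibble(bound_id = c("L1", "L2", "L3"), cognate_id = "c1",
                       score = 1, timed_out = FALSE,
                       passed_threshold = TRUE, is_best = TRUE)
  cogs <- make_cognates("c1", "CCO", "1.1.1.1")
  # S3 carries only a partial EC: matched evidence but no complete EC
  chains <- tibble::tibble(
    structure_id = c("S1", "S2", "S3"), chain = "A",
    ec_ids = list(c("1.1.1.1", "2.2.2.2"), "3.3.3.3", "4.4.4.-"))
  prof <- ec_diversity(build_domain_profiles(ia, mt, cogs),
                       ia, mt, chains)
  expect_equal(prof$ec_diversity[prof$domain_family == "F1"], 3)
  expect_equal(prof$ec_diversity[prof$domain_family == "F2"], 0)
})

test_that("silhouette-selected k recovers planted fingerprint blobs", {
  for (k in c(2, 3)) {
    fps <- blob_fingerprints(n_per = 8, k = k, seed = 100 + k)
    res <- cluster_cognate_space(NULL, k_range = 2:6, seed = 1,
                                 fingerprints = fps)
    expect_false(res$degenerate)
    expect_equal(res$k, k)
    expect_gt(res$mean_silhouette, 0.5)
    # planted labels agree with recovered partition
    planted <- sub("_.*$", "", res$assignments$cognate_id)
    tab <- table(planted, res$assignments$cluster)
    expect_true(all(rowSums(tab > 0) == 1))
  }
})

test_that("clustering is deterministic and degenerate inputs are reported", {
  fps <- blob_fingerprints(n_per = 6, k = 3, seed = 4)
  a <- cluster_cognate_space(NULL, k_range = 2:5, seed = 7,
                             fingerprints = fps)
  b <- cluster_cognate_space(NULL, k_range = 2:5, seed = 7,
                             fingerprints = fps)
  expect_identical(a$assignments, b$assignments)

  same <- make_cognates(paste0("c", 1:5), rep("CCO", 5),
                        sprintf("1.1.1.%d", 1:5))
  res <- cluster_cognate_space(same, k_range = 2:4, seed = 1)
  expect_true(res$degenerate)
  expect_true(is.na(res$k))

  expect_error(cluster_cognate_space(same[1, ], k_range = 2:4, seed = 1),
               "at least")
})
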