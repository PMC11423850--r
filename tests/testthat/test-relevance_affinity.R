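# relevance_affinity: relevance hierarchy, affinity normalization, consensus
# regression, bootstrap comparison

fake_ligand <- function(kind = "small_molecule", id = "XYZ") {
  structure(list(kind = kind, ligand_id = id, chains = "L"),
            class = "qs_ligand")
}
fake_site <- function(n) {
  structure(list(residues = data.frame(chain_id = rep("A", n),
                                       seq_id = seq_len(n), comp_id = "ALA",
                                       min_dist = 3.0),
                 n_chains_involved = 1L), class = "qs_site")
}

test_that("relevance hierarchy fires the expected rules", {
  ex <- read_exclusion_list()
  # unconditional branches
  v <- assess_relevance(fake_ligand("peptide", "peptide"))
  expect_equal(c(v$status, v$rule_fired), c("relevant", "peptide_or_nucleic"))
  v <- assess_relevance(fake_ligand("nucleic", "dna"))
  expect_equal(v$status, "relevant")
  # off-list default
  v <- assess_relevance(fake_ligand(id = "XYZ"), fake_site(1), ex)
  expect_equal(c(v$status, v$rule_fired), c("relevant", "not_in_list"))
  # listed, small site -> irrelevant
  v <- assess_relevance(fake_ligand(id = "GOL"), fake_site(2), ex,
                        min_site_residues = 6L)
  expect_equal(c(v$status, v$rule_fired), c("irrelevant", "site_size_rule"))
  # listed, large site, no abstract -> needs_review
  v <- assess_relevance(fake_ligand(id = "GOL"), fake_site(8), ex)
  expect_equal(c(v$status, v$rule_fired), c("needs_review", "listed_default"))
  # keyword rule, positive and negative
  v <- assess_relevance(fake_ligand(id = "GOL"), fake_site(8), ex,
                        abstract_text = "Glycerol GOL binds the active site.")
  expect_equal(c(v$status, v$rule_fired), c("relevant", "keyword_rule"))
  v <- assess_relevance(fake_ligand(id = "GOL"), fake_site(8), ex,
                        abstract_text = "Crystals were cryoprotected in glycerol.")
  expect_equal(v$status, "needs_review")
  # site required for listed molecules
  expect_error(assess_relevance(fake_ligand(id = "GOL"), NULL, ex), "site")
})

test_that("quaternary sites never shrink relative to single chains", {
  # mechanism behind keeping multi-chain pockets: residues only accumulate
  asm <- fx_assembly("ion_in_pocket", seed = 3,
                     params = list(n_chains = 4, ion = "K"))
  part <- partition_assembly(asm)
  rec <- quatsite:::receptor_atoms(asm, part$receptor)
  la <- quatsite:::ligand_atoms(asm, part$ligands[[1]])
  full <- nrow(find_binding_residues(rec, la)$residues)
  for (ch in names(part$receptor$chains)) {
    single <- nrow(find_binding_residues(rec[rec$chain_id == ch, ], la)$residues)
    expect_lte(single, full)
  }
})

test_that("affinity values normalize to the pKd scale; bad rows quarantined", {
  p <- tempfile(fileext = ".tsv")
  writeLines(c("pdb_id\tligand_id\tchain\tmeasure\tvalue\tunit\tsource",
               "1abc\tLIG\tA\tKd\t2\tnM\tmoad",
               "1abd\tLIG\tA\tKd\t1\tM\tpdbbind",
               "1abe\tLIG\tA\tIC50\t5\tuM\tbindingdb",
               "1abf\tLIG\tA\tKd\t3\tfurlongs\tmoad"), p)
  out <- read_affinity_table(p)
  expect_equal(nrow(out$records), 3L)
  expect_equal(out$records$pkd[1], -log10(2e-9), tolerance = 1e-9)  # 8.70
  expect_equal(out$records$pkd[2], 0.0)
  expect_equal(out$records$pkd[3], -log10(5e-6), tolerance = 1e-9)
  expect_equal(nrow(out$rejects), 1L)
  expect_match(out$rejects$reason, "furlongs")
  bad <- tempfile(fileext = ".tsv")
  writeLines(c("a\tb", "1\t2"), bad)
  expect_error(read_affinity_table(bad), "header")
})

test_that("consensus OLS: exact recovery, preconditions, nesting property", {
  ds0 <- make_affinity_dataset(n = 40, weights = c(0.5, 0.3, -0.2),
                               intercept = 1, noise_sigma = 0, seed = 9)
  m0 <- fit_consensus(ds0$data)
  expect_equal(unname(m0$weights), c(0.5, 0.3, -0.2), tolerance = 1e-8)
  expect_equal(m0$intercept, 1, tolerance = 1e-8)
  # noise-free fit reproduces training targets exactly
  pred <- predict_consensus(m0, ds0$data)
  expect_equal(pred, ds0$data$pkd, tolerance = 1e-8)

  expect_error(fit_consensus(ds0$data[1:5, ]), "at least 10")
  dup <- ds0$data; dup$x_itscore <- dup$x_xscore
  expect_error(fit_consensus(dup), "rank-deficient")

  ds <- make_affinity_dataset(n = 285, seed = 1)
  m <- fit_consensus(ds$data)
  expect_true(all(m$pcc_consensus >= m$pcc_single))
})

test_that("predict_consensus equals the dot-product oracle; errors on gaps", {
  m <- structure(list(intercept = 6, weights = c(x_xscore = 0, x_itscore = 0,
                                                 x_vina = 0)),
                 class = "qs_affinity_model")
  expect_equal(predict_consensus(m, c(x_xscore = 9, x_itscore = -4, x_vina = 2)), 6)
  m$weights <- c(x_xscore = 0.4, x_itscore = -0.7, x_vina = 1.1)
  set.seed(5)
  for (k in 1:20) {
    v <- stats::rnorm(3)
    names(v) <- names(m$weights)
    expect_equal(predict_consensus(m, v), 6 + sum(m$weights * v),
                 tolerance = 1e-12)
  }
  expect_error(predict_consensus(m, c(x_xscore = 1, x_itscore = 2)), "missing")
})

test_that("bootstrap PCC comparison: null gives no signal, planted effect does", {
  ds <- make_affinity_dataset(n = 285, seed = 1)
  m <- fit_consensus(ds$data)
  cons <- predict_consensus(m, ds$data)
  singles <- list(x_xscore = ds$data$x_xscore)
  # consensus vs itself: zero improvement, not significant
  null <- bootstrap_pcc_compare(cons, list(self = cons), ds$data$pkd,
                                n_boot = 200L, seed = 1)
  expect_equal(null$delta_pcc_mean, 0)
  expect_false(null$significant)
  # planted: consensus beats the single strongest score
  res <- bootstrap_pcc_compare(cons, singles, ds$data$pkd,
                               n_boot = 1000L, seed = 1)
  expect_gt(res$delta_pcc_mean, 0)
  expect_true(res$significant)
  # determinism given the seed; CI stability across seeds
  res2 <- bootstrap_pcc_compare(cons, singles, ds$data$pkd,
                                n_boot = 1000L, seed = 1)
  expect_identical(res, res2)
  res3 <- bootstrap_pcc_compare(cons, singles, ds$data$pkd,
                                n_boot = 1000L, seed = 2)
  expect_lt(abs(res3$delta_pcc_mean - res$delta_pcc_mean), 0.05)
  expect_error(bootstrap_pcc_compare(cons[1:10], singles, ds$data$pkd[1:10]),
               "n >= 30")
})
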