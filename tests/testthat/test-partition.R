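# partition: chain classification, receptor/ligand split, stoichiometry,
# pairwise identity

test_that("classify_chain follows the 80% dictionary rule", {
  expect_equal(classify_chain(rep("ALA", 50)), "protein")
  expect_equal(classify_chain(rep(c("DA", "DT"), 4)), "dna")
  expect_equal(classify_chain(rep(c("A", "U"), 4)), "rna")
  expect_equal(classify_chain(c(rep("DA", 4), rep("A", 4))), "na_hybrid")
  # 50% standard amino acids is below the 80% protein threshold
  expect_equal(classify_chain(c(rep("ALA", 10), rep("XXX", 10))), "other")
  expect_error(classify_chain(character(0)), "empty")
})

test_that("partition splits receptor, metal ion and peptides correctly", {
  asm <- fx_assembly("ion_in_pocket", seed = 3)
  part <- partition_assembly(asm)
  expect_equal(part$receptor$oligomeric_state, 2L)
  expect_length(part$ligands, 1L)
  expect_equal(part$ligands[[1]]$kind, "metal_ion")
  expect_equal(part$ligands[[1]]$ligand_id, "ZN")
  expect_false(part$structure_only)
})

test_that("the 30-residue bound is inclusive for receptors", {
  st30 <- fx_structure("protein_monomer", seed = 7, params = list(len = 30L))
  p30 <- partition_assembly(build_assemblies(st30)[[1]])
  expect_equal(p30$receptor$oligomeric_state, 1L)
  expect_length(p30$ligands, 0L)

  st29 <- fx_structure("protein_monomer", seed = 7, params = list(len = 29L))
  p29 <- partition_assembly(build_assemblies(st29)[[1]])
  expect_null(p29$receptor)
  expect_equal(p29$ligands[[1]]$kind, "peptide")
  expect_true(p29$structure_only)  # no receptor
})

test_that("every polymer chain lands in exactly one bucket (conservation)", {
  for (kind in c("ion_in_pocket", "protein_dna_complex", "dimer_interface_ligand")) {
    asm <- fx_assembly(kind, seed = 3)
    part <- partition_assembly(asm)
    ct <- asm$chain_types
    assigned <- c(if (!is.null(part$receptor)) names(part$receptor$chains),
                  unlist(lapply(part$ligands, function(l)
                    if (l$kind %in% c("peptide", "nucleic")) l$chains)),
                  part$unassigned)
    expect_setequal(assigned, ct$chain_id)
    expect_false(anyDuplicated(assigned) > 0)
  }
})

test_that("partition is invariant to atom input order", {
  asm <- fx_assembly("protein_dna_complex", seed = 5)
  part1 <- partition_assembly(asm)
  set.seed(42)
  asm2 <- asm
  asm2$atoms <- asm$atoms[sample(nrow(asm$atoms)), ]
  part2 <- partition_assembly(asm2)
  expect_equal(names(part1$receptor$chains), names(part2$receptor$chains))
  expect_setequal(vapply(part1$ligands, `[[`, character(1), "ligand_id"),
                  vapply(part2$ligands, `[[`, character(1), "ligand_id"))
  expect_equal(sort(part1$ligands[[1]]$chains), sort(part2$ligands[[1]]$chains))
})

test_that("stoichiometry: homo-n-mers give A<n>, heterodimer gives AB", {
  st <- fx_structure("protein_monomer")
  p <- partition_assembly(build_assemblies(st)[[1]])
  expect_equal(stoichiometry(p$receptor), "A")
  for (n in 2:8) {
    stn <- fx_structure("hetero_oligomer", seed = n,
                        params = list(identical = TRUE, n_chains = n))
    pn <- partition_assembly(build_assemblies(stn)[[1]])
    expect_equal(stoichiometry(pn$receptor), paste0("A", n))
  }
  het <- fx_structure("hetero_oligomer", seed = 1)  # ~50% identity pair
  ph <- partition_assembly(build_assemblies(het)[[1]])
  expect_equal(stoichiometry(ph$receptor), "AB")
})

test_that("pairwise_identity matches a reference aligner on random pairs", {
  expect_equal(pairwise_identity("PEPTIDE", "PEPTIDE"), 1.0)
  expect_equal(pairwise_identity("AAAA", "TTTT"), 0.0)
  expect_equal(pairwise_identity("PEPTIDE", "PEPTIDEXX"), 7 / 9)
  expect_error(pairwise_identity("", "AA"), "empty")
  # independent oracle: Biostrings global alignment with the same scoring
  library(Biostrings)
  mat <- nucleotideSubstitutionMatrix(match = 1, mismatch = 0)
  set.seed(11)
  for (k in 1:8) {
    a <- rand_seq(sample(5:25, 1), alphabet = c("A", "C", "G", "T"))
    b <- rand_seq(sample(5:25, 1), alphabet = c("A", "C", "G", "T"))
    al <- pairwiseAlignment(a, b, substitutionMatrix = mat,
                            gapOpening = 0, gapExtension = 0.5,
                            type = "global")
    oracle <- nmatch(al) / nchar(as.character(alignedPattern(al)))
    expect_equal(pairwise_identity(a, b), oracle, tolerance = 1e-9,
                 info = paste(a, b))
    expect_equal(pairwise_identity(a, b), pairwise_identity(b, a))
  }
})
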