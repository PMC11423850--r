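# site_annotation: binding residues, SASA, interface area

mk_atoms <- function(x, y = 0, z = 0, element = "C", chain = "A",
                     seq = seq_along(x), comp = "ALA", name = "CA") {
  data.frame(chain_id = chain, seq_id = as.integer(seq), ins_code = "",
             comp_id = comp, name = name, element = element,
             x = x, y = y, z = z, is_h = element %in% c("H", "D"),
             stringsAsFactors = FALSE)
}

test_that("binding threshold is strict vdW sum + margin", {
  r <- default_radii()
  lig <- mk_atoms(0, chain = "L", comp = "LIG")
  # carbon-carbon threshold = 1.70 + 1.70 + 0.5 = 3.90
  near <- find_binding_residues(mk_atoms(3.89), lig, r)
  expect_equal(nrow(near$residues), 1L)
  expect_equal(near$residues$min_dist, 3.89)
  far <- find_binding_residues(mk_atoms(3.91), lig, r)
  expect_equal(nrow(far$residues), 0L)
  exact <- find_binding_residues(mk_atoms(3.90), lig, r)  # strict "less than"
  expect_equal(nrow(exact$residues), 0L)
})

test_that("distant ligands give empty sites; empty inputs error", {
  rec <- mk_atoms(c(0, 3.8, 7.6))
  lig <- mk_atoms(100, chain = "L")
  expect_equal(nrow(find_binding_residues(rec, lig)$residues), 0L)
  expect_error(find_binding_residues(rec[0, ], lig), "empty atom set")
  expect_error(find_binding_residues(rec, lig[0, ]), "empty atom set")
})

test_that("grid search equals the all-pairs oracle on every fixture", {
  for (kind in c("ion_in_pocket", "dimer_interface_ligand",
                 "protein_dna_complex")) {
    asm <- fx_assembly(kind, seed = 3)
    part <- partition_assembly(asm)
    rec <- quatsite:::receptor_atoms(asm, part$receptor)
    for (lig in part$ligands) {
      la <- quatsite:::ligand_atoms(asm, lig)
      a <- find_binding_residues(rec, la)
      b <- binding_residues_bruteforce(rec, la)
      expect_equal(a$residues, b$residues, info = kind)
      expect_equal(a$n_chains_involved, b$n_chains_involved)
    }
  }
})

test_that("SASA: analytic sphere, additivity, spherical-cap oracle", {
  r <- default_radii()
  single <- compute_sasa(mk_atoms(0), r)
  expect_lt(abs(single$total - 4 * pi * 3.1^2) / (4 * pi * 3.1^2), 0.01)
  sep <- compute_sasa(mk_atoms(c(0, 100)), r)
  expect_equal(sep$total, 2 * single$total, tolerance = 1e-6)
  # two overlapping spheres: closed-form lost spherical caps
  d <- 2.0
  R1 <- 1.70 + 1.4; R2 <- 1.52 + 1.4
  pair <- compute_sasa(data.frame(x = c(0, d), y = 0, z = 0,
                                  element = c("C", "O")), r)
  cap1 <- 2 * pi * R1 * (R1 - (d^2 - R2^2 + R1^2) / (2 * d))
  cap2 <- 2 * pi * R2 * (R2 - (d^2 - R1^2 + R2^2) / (2 * d))
  analytic <- 4 * pi * R1^2 - cap1 + 4 * pi * R2^2 - cap2
  expect_lt(abs(pair$total - analytic) / analytic, 0.015)
})

test_that("SASA decreases monotonically on approach; converges in n_points", {
  r <- default_radii()
  a <- mk_atoms(c(0, 3.8, 7.6))
  totals <- vapply(c(50, 20, 10, 6, 4), function(d) {
    b <- mk_atoms(c(0, 3.8, 7.6) + d, chain = "B")
    compute_sasa(rbind(a, b), r)$total
  }, numeric(1))
  expect_true(all(diff(totals) < 1e-9))
  s1 <- compute_sasa(a, r, n_points = 960L)$total
  s2 <- compute_sasa(a, r, n_points = 1920L)$total
  expect_lt(abs(s1 - s2) / s2, 0.005)
})

test_that("interface area: zero at separation, symmetric, bounded, rigid-invariant", {
  r <- default_radii()
  rec <- mk_atoms(c(0, 3.8))
  far <- mk_atoms(100, chain = "L")
  ifc <- interface_area(rec, far, r)
  expect_lt(abs(ifc$S), 1e-6 * ifc$S_com)
  expect_equal(ifc$S, (ifc$S_prot + ifc$S_lig - ifc$S_com) / 2)

  asm <- fx_assembly("ion_in_pocket", seed = 3)
  part <- partition_assembly(asm)
  reca <- quatsite:::receptor_atoms(asm, part$receptor)
  liga <- quatsite:::ligand_atoms(asm, part$ligands[[1]])
  i1 <- interface_area(reca, liga, r)
  expect_gt(i1$S, 0)
  expect_lte(i1$S, min(i1$S_prot, i1$S_lig))
  # role swap leaves S unchanged
  i2 <- interface_area(liga, reca, r)
  expect_equal(i1$S, i2$S, tolerance = 1e-9)
  # rigid-body transformation of the whole complex (rotation + translation);
  # checked at a denser sampling so discretization noise sits below the bound
  rot <- quatsite:::rot_z(37)
  move <- function(df) {
    m <- as.matrix(df[, c("x", "y", "z")]) %*% t(rot)
    df$x <- m[, 1] + 5; df$y <- m[, 2] - 3; df$z <- m[, 3] + 11
    df
  }
  i1d <- interface_area(reca, liga, r, n_points = 3840L)
  i3 <- interface_area(move(reca), move(liga), r, n_points = 3840L)
  expect_lt(abs(i3$S - i1d$S) / max(i1d$S, 1), 0.005)
})

test_that("multi-chain pocket: ion contacts all chains of the tetramer", {
  f <- fx("ion_in_pocket", seed = 3, params = list(n_chains = 4, ion = "K"))
  asm <- build_assemblies(parse_structure(f$path))[[1]]
  part <- partition_assembly(asm)
  site <- find_binding_residues(quatsite:::receptor_atoms(asm, part$receptor),
                                quatsite:::ligand_atoms(asm, part$ligands[[1]]))
  expect_equal(site$n_chains_involved, 4L)
  expect_equal(nrow(site$residues), f$manifest$expected_site_residues)
})
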