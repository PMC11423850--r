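# structure_io: parsing, assembly generation, writing, oversized splitting

test_that("fixture dimer mmCIF parses with assembly records", {
  st <- fx_structure("protein_dimer_via_operator", seed = 2)
  expect_s3_class(st, "qs_structure")
  expect_equal(length(st$assembly_defs), 1L)
  expect_equal(length(st$operators), 2L)
  expect_equal(unique(st$atoms$chain_id), "A")
  expect_true(all(st$atoms$is_polymer))
  # identity operator present
  expect_equal(st$operators[["1"]]$R, diag(3))
})

test_that("malformed input raises a parse error, no partial result", {
  bad <- tempfile(fileext = ".cif")
  writeLines(c("data_X", "loop_", "_atom_site.id", "_atom_site.Cartn_x", "1"),
             bad)
  expect_error(parse_structure(bad), "parse error")
  junk <- tempfile(fileext = ".xyz")
  writeLines(c("%%%% not a structure", "12345"), junk)
  expect_error(parse_structure(junk), "format")
})

test_that("PDB round trip preserves composition and coordinates to 1e-3", {
  st <- fx_structure("hetero_oligomer")
  p <- tempfile(fileext = ".pdb")
  write_structure(st, p, "pdb")
  st2 <- parse_structure(p)
  expect_equal(nrow(st2$atoms), nrow(st$atoms))
  expect_equal(st2$atoms$comp_id, st$atoms$comp_id)
  expect_equal(st2$atoms$chain_id, st$atoms$chain_id)
  expect_lt(max(abs(st2$atoms$x - st$atoms$x)), 1e-3)
  expect_lt(max(abs(st2$atoms$z - st$atoms$z)), 1e-3)
})

test_that("mmCIF write -> read round trip preserves atoms exactly", {
  st <- fx_structure("bdna_duplex")
  p <- tempfile(fileext = ".cif")
  write_structure(st, p, "mmcif")
  st2 <- parse_structure(p)
  expect_equal(nrow(st2$atoms), nrow(st$atoms))
  expect_equal(st2$atoms$name, st$atoms$name)
  expect_lt(max(abs(st2$atoms$y - st$atoms$y)), 1e-9)
})

test_that("identity-operator assembly reproduces the asymmetric unit", {
  st <- fx_structure("hetero_oligomer")   # no stored assembly: identity fallback
  asm <- build_assemblies(st)[[1]]
  expect_identical(asm$atoms$x, st$atoms$x)
  expect_identical(asm$atoms$chain_id, st$atoms$chain_id)
})

test_that("operator application matches an independent matrix oracle", {
  st <- fx_structure("protein_dimer_via_operator", seed = 2)
  asm <- build_assemblies(st)[[1]]
  expect_setequal(unique(asm$atoms$chain_id), c("A-1", "A-2"))
  # oracle: apply the stored rotation directly to the asymmetric unit
  op <- st$operators[["2"]]
  xyz0 <- as.matrix(st$atoms[, c("x", "y", "z")])
  oracle <- xyz0 %*% t(op$R) + matrix(op$t, nrow(xyz0), 3, byrow = TRUE)
  got <- as.matrix(asm$atoms[asm$atoms$chain_id == "A-2", c("x", "y", "z")])
  expect_lt(max(abs(got - oracle)), 1e-9)
})

test_that("assembly atom count obeys the conservation law and rigid bodies stay rigid", {
  for (kind in c("protein_dimer_via_operator", "hetero_oligomer", "bdna_duplex")) {
    st <- fx_structure(kind, seed = 2)
    asm <- build_assemblies(st)[[1]]
    expected <- if (length(st$assembly_defs)) {
      sum(vapply(st$assembly_defs[[1]]$generators, function(g)
        length(quatsite:::parse_oper_expression(g$oper_expression)) *
          nrow(st$atoms[st$atoms$chain_id %in% g$asym_ids, ]), numeric(1)))
    } else nrow(st$atoms)
    expect_equal(nrow(asm$atoms), expected, info = kind)
    # rigid-body property: intra-chain pairwise distances preserved to 1e-6
    src <- st$atoms[st$atoms$chain_id == st$atoms$chain_id[1], ]
    for (ch in unique(asm$provenance$chain_id[asm$provenance$source_asym == src$chain_id[1]])) {
      moved <- asm$atoms[asm$atoms$chain_id == ch, ]
      if (nrow(moved) != nrow(src)) next
      i <- seq_len(min(20L, nrow(src)))
      d0 <- dist(as.matrix(src[i, c("x", "y", "z")]))
      d1 <- dist(as.matrix(moved[i, c("x", "y", "z")]))
      expect_lt(max(abs(d0 - d1)), 1e-6)
    }
  }
})

test_that("build_assemblies is deterministic", {
  p <- fx("protein_dimer_via_operator", seed = 2)$path
  a1 <- build_assemblies(parse_structure(p))[[1]]
  a2 <- build_assemblies(parse_structure(p))[[1]]
  expect_identical(a1$provenance, a2$provenance)
  expect_identical(a1$atoms, a2$atoms)
})

test_that("oper_expression grammar: lists, ranges, two factors; errors otherwise", {
  pe <- quatsite:::parse_oper_expression
  expect_equal(pe("1,2"), list("1", "2"))
  expect_equal(pe("1-3"), list("1", "2", "3"))
  expect_equal(pe("(1-2)(3)"), list(c("1", "3"), c("2", "3")))
  expect_equal(length(pe("(1-10)(11-12)")), 20L)
  expect_error(pe("(1)(2)(3)"), "two parenthesized factors")
  # composition is the left-to-right matrix product
  ops <- list(`1` = list(R = quatsite:::rot_z(90), t = c(1, 0, 0)),
              `2` = list(R = diag(3), t = c(0, 2, 0)))
  M <- quatsite:::compose_opers(c("1", "2"), ops)
  # x' = R1 (x + t2) + t1 for x = (1,0,0)
  x <- c(1, 0, 0, 1)
  expect_equal(as.numeric(M %*% x)[1:3],
               as.numeric(quatsite:::rot_z(90) %*% (c(1, 0, 0) + c(0, 2, 0)) + c(1, 0, 0)))
})

test_that("unknown operator ids and improper rotations are rejected", {
  expect_error(quatsite:::compose_opers("9", list(`1` = list(R = diag(3), t = rep(0, 3)))),
               "unknown oper_id '9'")
  expect_error(quatsite:::validate_operator(diag(c(1, 1, -1)), "m"), "improper")
})

test_that("PDB capacity: 62-chain boundary and >62-chain splitting", {
  stg <- fx_structure("many_chain_giant")   # 100 chains
  expect_error(write_structure(stg, tempfile(fileext = ".pdb"), "pdb"),
               "at most 62 chains")
  res <- split_for_pdb(stg, dir = tempdir(), base = "giant")
  expect_length(res$files, 2L)
  expect_equal(nrow(res$map), 100L)
  expect_equal(as.integer(table(res$map$file_index)), c(62L, 38L))
  # bijection: no (file, new id) pair repeats; union of chains is the input
  expect_false(anyDuplicated(paste(res$map$file_index, res$map$new_chain)) > 0)
  expect_setequal(res$map$orig_chain, unique(stg$atoms$chain_id))
  # files parse back with the stated chain counts
  n_back <- vapply(res$files, function(f)
    length(unique(parse_structure(f)$atoms$chain_id)), integer(1))
  expect_equal(unname(n_back), c(62L, 38L))
})

test_that("altloc reduction keeps the highest-occupancy conformer", {
  p <- tempfile(fileext = ".cif")
  writeLines(c(
    "data_ALT", "loop_", "_atom_site.group_PDB", "_atom_site.id",
    "_atom_site.type_symbol", "_atom_site.label_atom_id",
    "_atom_site.label_alt_id", "_atom_site.label_comp_id",
    "_atom_site.label_asym_id", "_atom_site.label_seq_id",
    "_atom_site.Cartn_x", "_atom_site.Cartn_y", "_atom_site.Cartn_z",
    "_atom_site.occupancy", "_atom_site.auth_seq_id",
    "ATOM 1 C CA A ALA A 1 0.0 0.0 0.0 0.40 1",
    "ATOM 2 C CA B ALA A 1 1.0 0.0 0.0 0.60 1",
    "ATOM 3 C CA A ALA A 2 2.0 0.0 0.0 0.50 2",
    "ATOM 4 C CA B ALA A 2 3.0 0.0 0.0 0.50 2"), p)
  st <- parse_structure(p)
  expect_equal(nrow(st$atoms), 2L)
  expect_equal(st$atoms$x[st$atoms$seq_id == 1], 1.0)  # occupancy 0.6 wins
  expect_equal(st$atoms$x[st$atoms$seq_id == 2], 2.0)  # tie -> altloc 'A'
})

test_that("modified residues map to their standard parents after assembly", {
  st <- fx_structure("protein_monomer", params = list(with_modres = TRUE))
  expect_equal(nrow(st$mod_residues), 1L)
  asm <- build_assemblies(st)[[1]]
  mod <- asm$atoms[asm$atoms$seq_id == 5L, ]
  expect_true(all(mod$comp_id == "MET"))
  expect_true(all(mod$orig_comp_id == "MSE"))
  # coordinates untouched by the renaming
  expect_identical(mod$x, st$atoms$x[st$atoms$seq_id == 5L])
})
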