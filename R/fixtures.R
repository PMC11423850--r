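## Synthetic structure and affinity fixtures.
##
## Every fixture is written to disk as a real mmCIF file (so the parsers are
## always on the tested path) together with a ground-truth manifest (JSON).
## Geometry is idealized, not physical: protein chains are extended backbone
## traces, B-DNA duplexes use ideal helical parameters (rise 3.38 A, twist
## 36 deg) with a known base-pair registry, and the accession analogues
## (dimer_interface_ligand, protein_dna_complex, ion_in_pocket) are synthetic
## stand-ins for worked examples that would otherwise need downloads.

FIXTURE_KINDS <- c("protein_monomer", "protein_dimer_via_operator",
                   "hetero_oligomer", "bdna_duplex",
                   "rna_hairpin_plus_dinucleotide", "ion_in_pocket",
                   "many_chain_giant", "dimer_interface_ligand",
                   "protein_dna_complex")

#' Generate a synthetic structure fixture
#'
#' @param kind one of \code{protein_monomer}, \code{protein_dimer_via_operator},
#'   \code{hetero_oligomer}, \code{bdna_duplex},
#'   \code{rna_hairpin_plus_dinucleotide}, \code{ion_in_pocket},
#'   \code{many_chain_giant}, \code{dimer_interface_ligand},
#'   \code{protein_dna_complex}.
#' @param seed RNG seed; the same (kind, seed, params) always produces a
#'   byte-identical file.
#' @param dir output directory.
#' @param params named list of size parameters (see Details of each kind in
#'   the package vignette); invalid combinations raise an error.
#' @return list: \code{path} (mmCIF file), \code{manifest_path},
#'   \code{manifest} (ground-truth list).
#' @export
make_structure_fixture <- function(kind, seed = 1L, dir = tempdir(),
                                   params = list()) {
  kind <- match.arg(kind, FIXTURE_KINDS)
  set.seed(seed)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fx <- switch(kind,
               protein_monomer = fx_protein_monomer(params),
               protein_dimer_via_operator = fx_protein_dimer(params),
               hetero_oligomer = fx_hetero_oligomer(params),
               bdna_duplex = fx_bdna_duplex(params),
               rna_hairpin_plus_dinucleotide = fx_rna_hairpin(params),
               ion_in_pocket = fx_ion_in_pocket(params),
               many_chain_giant = fx_many_chain_giant(params),
               dimer_interface_ligand = fx_dimer_interface_ligand(params),
               protein_dna_complex = fx_protein_dna_complex(params))
  suffix <- if (length(params))
    paste0("_", gsub("[^A-Za-z0-9]", "", paste(names(params),
                                               unlist(params), collapse = "")))
  else ""
  stem <- sprintf("%s_seed%d%s", kind, seed, suffix)
  path <- file.path(dir, paste0(stem, ".cif"))
  fixture_write_cif(fx, path, block = toupper(gsub("[^A-Za-z0-9]", "", stem)))
  fx$manifest$kind <- kind
  fx$manifest$seed <- seed
  mpath <- file.path(dir, paste0(stem, "_manifest.json"))
  jsonlite::write_json(fx$manifest, mpath, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  list(path = path, manifest_path = mpath, manifest = fx$manifest)
}

## atom-row helpers ----------------------------------------------------------

fx_row <- function(chain, seq, comp, name, element, x, y, z,
                   entity, het = FALSE) {
  data.frame(group_PDB = if (het) "HETATM" else "ATOM", name = name,
             element = element, comp_id = comp, chain_id = chain,
             seq_id = as.integer(seq), x = x, y = y, z = z,
             entity_id = as.character(entity), stringsAsFactors = FALSE)
}

random_aa_seq <- function(n) sample(STANDARD_AA, n, replace = TRUE)

# Extended backbone trace: N, CA, C, O per residue, 3.8 A rise along `dir`.
fx_protein_chain <- function(chain, comps, origin = c(0, 0, 0),
                             dir = c(1, 0, 0), entity = "1", seq_start = 1L) {
  dir <- dir / sqrt(sum(dir^2))
  perp <- if (abs(dir[3]) < 0.9) {
    v <- c(-dir[2], dir[1], 0); v / sqrt(sum(v^2))
  } else c(1, 0, 0)
  rows <- list()
  for (i in seq_along(comps)) {
    base <- origin + dir * 3.8 * (i - 1)
    s <- seq_start + i - 1L
    rows[[length(rows) + 1L]] <- rbind(
      fx_row(chain, s, comps[i], "N", "N", base[1] - 1.2 * dir[1] + 0.5 * perp[1],
             base[2] - 1.2 * dir[2] + 0.5 * perp[2], base[3] - 1.2 * dir[3] + 0.5 * perp[3],
             entity),
      fx_row(chain, s, comps[i], "CA", "C", base[1], base[2], base[3], entity),
      fx_row(chain, s, comps[i], "C", "C", base[1] + 1.2 * dir[1] + 0.5 * perp[1],
             base[2] + 1.2 * dir[2] + 0.5 * perp[2], base[3] + 1.2 * dir[3] + 0.5 * perp[3],
             entity),
      fx_row(chain, s, comps[i], "O", "O", base[1] + 1.6 * dir[1] + 1.6 * perp[1],
             base[2] + 1.6 * dir[2] + 1.6 * perp[2], base[3] + 1.6 * dir[3] + 1.6 * perp[3],
             entity))
  }
  do.call(rbind, rows)
}

rot_z <- function(deg) {
  th <- deg * pi / 180
  matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3, byrow = TRUE)
}

# Ideal duplex level: returns atoms for one base pair at helical level k.
# strand1/strand2: list(chain, seq, comp) with comp in {DA, DT, A, U}.
fx_bp_level <- function(k, strand1, strand2, ent1, ent2, rise = 3.38, twist = 36) {
  R <- rot_z(twist * k)
  z <- rise * k
  at <- function(local, dz = 0) {
    p <- R %*% c(local, 0)
    c(p[1], p[2], z + dz)
  }
  base_atoms <- function(chain, seq, comp, side, entity) {
    # side -1 = strand1 (left), +1 = strand2 (right)
    purine <- comp %in% c("DA", "A", "DG", "G")
    c1 <- at(c(5.2 * side, 0))   # -5.2 for strand1, +5.2 for strand2
    inner <- at(c(1.45 * side, -0.55))
    outer <- at(c(1.45 * side, 1.55))
    rbind(
      fx_row(chain, seq, comp, "C1'", "C", c1[1], c1[2], c1[3], entity),
      if (purine) rbind(
        fx_row(chain, seq, comp, "N1", "N", inner[1], inner[2], inner[3], entity),
        fx_row(chain, seq, comp, "N6", "N", outer[1], outer[2], outer[3], entity))
      else rbind(
        fx_row(chain, seq, comp, "N3", "N", inner[1], inner[2], inner[3], entity),
        fx_row(chain, seq, comp, "O4", "O", outer[1], outer[2], outer[3], entity)))
  }
  rbind(base_atoms(strand1$chain, strand1$seq, strand1$comp, -1, ent1),
        base_atoms(strand2$chain, strand2$seq, strand2$comp, +1, ent2))
}

# Groove anchor position contacting both chains at helical level k
fx_groove_anchor <- function(k, rise = 3.38, twist = 36) {
  p <- rot_z(twist * k) %*% c(0, -3.5, 0)
  c(p[1], p[2], rise * k)
}

## fixture kinds -------------------------------------------------------------

fx_protein_monomer <- function(params) {
  len <- params$len %||% 50L
  if (len < 1L) stopf("protein_monomer: len must be >= 1")
  comps <- params$comps %||% random_aa_seq(len)
  atoms <- fx_protein_chain("A", comps, entity = "1")
  mod <- NULL
  if (isTRUE(params$with_modres)) {
    atoms$comp_id[atoms$seq_id == 5L & atoms$chain_id == "A"] <- "MSE"
    mod <- data.frame(label_asym_id = "A", auth_seq_id = 5L,
                      label_comp_id = "MSE", parent_comp_id = "MET",
                      stringsAsFactors = FALSE)
    comps[5] <- "MET"
  }
  list(atoms = atoms,
       entities = data.frame(id = "1", type = "polymer",
                             poly_type = "polypeptide(L)", stringsAsFactors = FALSE),
       assembly = NULL, mod_residues = mod,
       manifest = list(chains = list(A = len), polymer_types = list(A = "protein"),
                       sequence = seq3_to_1(comps),
                       expected_category = "structure_only"))
}

fx_protein_dimer <- function(params) {
  len <- params$len %||% 100L
  comps <- params$comps %||% random_aa_seq(len)
  atoms <- fx_protein_chain("A", comps, origin = c(5, 3, 0), entity = "1")
  ops <- list(
    data.frame(id = "1", R = I(list(diag(3))), t = I(list(c(0, 0, 0)))),
    data.frame(id = "2", R = I(list(rot_z(180))), t = I(list(c(0, 0, 0)))))
  assembly <- list(assembly_id = "1",
                   generators = list(list(oper_expression = "1,2",
                                          asym_ids = "A")),
                   operators = ops)
  list(atoms = atoms,
       entities = data.frame(id = "1", type = "polymer",
                             poly_type = "polypeptide(L)", stringsAsFactors = FALSE),
       assembly = assembly, mod_residues = NULL,
       manifest = list(chains = list("A-1" = len, "A-2" = len),
                       n_assembly_chains = 2, chain_len = len,
                       operator_expression = "1,2"))
}

fx_hetero_oligomer <- function(params) {
  n_chains <- params$n_chains %||% 2L
  len <- params$len %||% 40L
  identical_seqs <- params$identical %||% FALSE
  if (n_chains < 2L) stopf("hetero_oligomer: n_chains must be >= 2")
  base <- random_aa_seq(len)
  atoms <- list(); ents <- list(); manifest_chains <- list()
  for (k in seq_len(n_chains)) {
    comps <- base
    if (!identical_seqs && k > 1L) {
      # mutate every other position deterministically (~50% identity)
      pos <- seq(1L, len, by = 2L)
      comps[pos] <- STANDARD_AA[(match(comps[pos], STANDARD_AA) + k) %% 20L + 1L]
    }
    ch <- LETTERS[k]
    atoms[[k]] <- fx_protein_chain(ch, comps, origin = c(0, 10 * (k - 1), 0),
                                   entity = as.character(k))
    ents[[k]] <- data.frame(id = as.character(k), type = "polymer",
                            poly_type = "polypeptide(L)", stringsAsFactors = FALSE)
    manifest_chains[[ch]] <- len
  }
  list(atoms = do.call(rbind, atoms), entities = do.call(rbind, ents),
       assembly = NULL, mod_residues = NULL,
       manifest = list(chains = manifest_chains,
                       identical = identical_seqs,
                       expected_stoichiometry = if (identical_seqs)
                         paste0("A", n_chains) else
                           paste0(LETTERS[seq_len(n_chains)], collapse = "")))
}

fx_bdna_duplex <- function(params) {
  n_bp <- params$n_bp %||% 8L
  if (n_bp < 1L) stopf("bdna_duplex: n_bp must be >= 1")
  rows <- list()
  registry <- list()
  for (k in seq_len(n_bp) - 1L) {
    comp1 <- if (k %% 2 == 0) "DA" else "DT"
    comp2 <- if (comp1 == "DA") "DT" else "DA"
    rows[[k + 1L]] <- fx_bp_level(k,
                                  list(chain = "C", seq = k + 1L, comp = comp1),
                                  list(chain = "D", seq = k + 1L, comp = comp2),
                                  "1", "2")
    registry[[k + 1L]] <- list(chain_a = "C", seq_a = k + 1L,
                               chain_b = "D", seq_b = k + 1L)
  }
  ents <- data.frame(id = c("1", "2"), type = "polymer",
                     poly_type = "polydeoxyribonucleotide",
                     stringsAsFactors = FALSE)
  list(atoms = do.call(rbind, rows), entities = ents, assembly = NULL,
       mod_residues = NULL,
       manifest = list(chains = list(C = n_bp, D = n_bp),
                       n_inter_chain_pairs = n_bp,
                       pair_registry = registry,
                       expected_groups = list(c("C", "D"))))
}

fx_rna_hairpin <- function(params) {
  n_stem <- params$n_stem %||% 4L   # intra-chain stem pairs in the long chain
  n_di <- 2L                        # dinucleotide partner
  rows <- list()
  # levels 0..1: long chain G (strand1) paired with dinucleotide H (strand2)
  # levels 2..(1+n_stem): G paired with itself (fold-back)
  total_levels <- n_di + n_stem
  g_seq <- 0L
  for (k in 0:(n_di - 1L)) {
    g_seq <- g_seq + 1L
    rows[[length(rows) + 1L]] <- fx_bp_level(
      k, list(chain = "G", seq = g_seq, comp = if (k %% 2 == 0) "A" else "U"),
      list(chain = "H", seq = k + 1L, comp = if (k %% 2 == 0) "U" else "A"),
      "1", "2")
  }
  for (k in n_di:(total_levels - 1L)) {
    g_seq <- g_seq + 1L
    back_seq <- n_di + n_stem + (total_levels - k)  # fold-back numbering
    rows[[length(rows) + 1L]] <- fx_bp_level(
      k, list(chain = "G", seq = g_seq, comp = if (k %% 2 == 0) "A" else "U"),
      list(chain = "G", seq = back_seq, comp = if (k %% 2 == 0) "U" else "A"),
      "1", "1")
  }
  ents <- data.frame(id = c("1", "2"), type = "polymer",
                     poly_type = "polyribonucleotide", stringsAsFactors = FALSE)
  list(atoms = do.call(rbind, rows), entities = ents, assembly = NULL,
       mod_residues = NULL,
       manifest = list(chains = list(G = n_di + 2L * n_stem, H = n_di),
                       n_inter_chain_pairs = n_di,
                       n_intra_chain_pairs = n_stem,
                       expected_groups = list(c("G", "H")),
                       special_case = "1-2-nt chain fully paired"))
}

fx_ion_in_pocket <- function(params) {
  n_chains <- params$n_chains %||% 2L
  len <- params$len %||% 32L
  ion <- toupper(params$ion %||% "ZN")
  contact_res <- params$contact_res %||% 2L
  if (len < 30L) stopf("ion_in_pocket: chains must be receptors (len >= 30)")
  if (!ion %in% METAL_ELEMENTS) stopf("ion_in_pocket: '%s' is not a metal element", ion)
  atoms <- list(); ents <- list()
  shared <- random_aa_seq(len)   # homo-oligomeric channel-like receptor
  for (k in seq_len(n_chains)) {
    phi <- 2 * pi * (k - 1) / n_chains
    dirv <- c(cos(phi), sin(phi), 0)
    ch <- LETTERS[k]
    comps <- shared
    # backbone marches away from the ion at the origin
    chain_atoms <- fx_protein_chain(ch, comps, origin = dirv * 3.2, dir = dirv,
                                    entity = as.character(k))
    # pull CB atoms of the first contact_res residues back toward the ion
    extra <- lapply(seq_len(contact_res), function(i) {
      d <- 3.2 + 1.5 * (i - 1)          # 3.2, 4.7, ... all under vdW+0.5 for K/ZN
      p <- dirv * d + c(0, 0, 0.4)
      fx_row(ch, i, comps[i], "CB", "C", p[1], p[2], p[3], as.character(k))
    })
    atoms[[k]] <- rbind(chain_atoms, do.call(rbind, extra))
    ents[[k]] <- data.frame(id = as.character(k), type = "polymer",
                            poly_type = "polypeptide(L)", stringsAsFactors = FALSE)
  }
  ion_ent <- as.character(n_chains + 1L)
  atoms[[n_chains + 1L]] <- fx_row("Z", 1L, ion, ion, ion, 0, 0, 0, ion_ent,
                                   het = TRUE)
  ents[[n_chains + 1L]] <- data.frame(id = ion_ent, type = "non-polymer",
                                      poly_type = NA_character_,
                                      stringsAsFactors = FALSE)
  list(atoms = do.call(rbind, atoms), entities = do.call(rbind, ents),
       assembly = NULL, mod_residues = NULL,
       manifest = list(n_chains = n_chains, ion = ion,
                       expected_site_residues = n_chains * contact_res,
                       expected_n_chains_involved = n_chains,
                       ligand_kind = "metal_ion"))
}

fx_many_chain_giant <- function(params) {
  n_chains <- params$n_chains %||% 100L
  if (n_chains < 2L) stopf("many_chain_giant: n_chains must be >= 2")
  atoms <- list()
  ids <- sprintf("C%03d", seq_len(n_chains))
  for (k in seq_len(n_chains)) {
    gx <- (k - 1) %% 10; gy <- (k - 1) %/% 10
    atoms[[k]] <- rbind(
      fx_row(ids[k], 1L, "GLY", "CA", "C", 20 * gx, 20 * gy, 0, "1"),
      fx_row(ids[k], 2L, "GLY", "CA", "C", 20 * gx + 3.8, 20 * gy, 0, "1"))
  }
  ents <- data.frame(id = "1", type = "polymer", poly_type = "polypeptide(L)",
                     stringsAsFactors = FALSE)
  list(atoms = do.call(rbind, atoms), entities = ents, assembly = NULL,
       mod_residues = NULL,
       manifest = list(n_chains = n_chains, chain_ids = ids))
}

# Synthetic analogue of a C2-symmetric homodimeric enzyme with one inhibitor
# bound across the two-fold interface (cf. an HIV-protease-like topology).
fx_dimer_interface_ligand <- function(params) {
  len <- params$len %||% 40L
  comps <- random_aa_seq(len)
  a <- fx_protein_chain("A", comps, origin = c(0, 5, 0), dir = c(1, 0, 0),
                        entity = "1")
  b <- fx_protein_chain("B", comps, origin = c(0, -5, 0), dir = c(1, 0, 0),
                        entity = "1")
  xc <- 3.8 * floor(len / 2)   # mid-chain CA x position
  lig <- rbind(
    fx_row("L", 1L, "INH", "C1", "C", xc, 1.6, 0, "2", het = TRUE),
    fx_row("L", 1L, "INH", "C2", "C", xc, 0.0, 0, "2", het = TRUE),
    fx_row("L", 1L, "INH", "C3", "C", xc, -1.6, 0, "2", het = TRUE),
    fx_row("L", 1L, "INH", "O1", "O", xc + 1.4, 0.0, 0, "2", het = TRUE))
  ents <- data.frame(id = c("1", "2"), type = c("polymer", "non-polymer"),
                     poly_type = c("polypeptide(L)", NA), stringsAsFactors = FALSE)
  list(atoms = rbind(a, b, lig), entities = ents, assembly = NULL,
       mod_residues = NULL,
       manifest = list(chains = list(A = len, B = len),
                       ligand = "INH", expected_stoichiometry = "A2",
                       expected_entries = 1, expected_single_chain_entries = 2,
                       synthetic_analogue_of = "C2 homodimer + interface inhibitor"))
}

# Synthetic analogue of an endonuclease homodimer bound to a DNA ligand made
# of four paired chains; each receptor chain contacts only three of them.
fx_protein_dna_complex <- function(params) {
  n_bp <- 16L
  # strand1: chain C levels 0-7, chain E levels 8-15
  # strand2: chain D levels 0-11, chain F levels 12-15
  rows <- list()
  seqs <- list(C = 0L, D = 0L, E = 0L, F = 0L)
  for (k in 0:(n_bp - 1L)) {
    ch1 <- if (k < 8L) "C" else "E"
    ch2 <- if (k < 12L) "D" else "F"
    seqs[[ch1]] <- seqs[[ch1]] + 1L
    seqs[[ch2]] <- seqs[[ch2]] + 1L
    comp1 <- if (k %% 2 == 0) "DA" else "DT"
    rows[[length(rows) + 1L]] <- fx_bp_level(
      k, list(chain = ch1, seq = seqs[[ch1]], comp = comp1),
      list(chain = ch2, seq = seqs[[ch2]], comp = if (comp1 == "DA") "DT" else "DA"),
      ent_of_dna(ch1), ent_of_dna(ch2))
  }
  len <- 32L
  prot <- list()
  for (spec in list(list(chain = "A", anchors = c(2L, 10L), park_y = 60),
                    list(chain = "B", anchors = c(11L, 13L), park_y = -60))) {
    comps <- random_aa_seq(len)
    anchor_rows <- lapply(seq_along(spec$anchors), function(i) {
      p <- fx_groove_anchor(spec$anchors[i])
      fx_row(spec$chain, i, comps[i], "CA", "C", p[1], p[2], p[3],
             ent_of_prot(spec$chain))
    })
    rest <- fx_protein_chain(spec$chain, comps[3:len],
                             origin = c(30, spec$park_y, 0),
                             entity = ent_of_prot(spec$chain), seq_start = 3L)
    prot[[length(prot) + 1L]] <- rbind(do.call(rbind, anchor_rows), rest)
  }
  ents <- data.frame(
    id = c("1", "2", "3", "4", "5", "6"),
    type = "polymer",
    poly_type = c("polypeptide(L)", "polypeptide(L)",
                  rep("polydeoxyribonucleotide", 4)),
    stringsAsFactors = FALSE)
  list(atoms = rbind(do.call(rbind, prot), do.call(rbind, rows)),
       entities = ents, assembly = NULL, mod_residues = NULL,
       manifest = list(
         receptor_chains = c("A", "B"), dna_chains = c("C", "D", "E", "F"),
         expected_nucleic_group = c("C", "D", "E", "F"),
         contacts = list(A = c("C", "D", "E"), B = c("D", "E", "F")),
         expected_single_chain_entries = 6,
         synthetic_analogue_of = "homodimer + 4-chain paired DNA ligand"))
}

ent_of_prot <- function(ch) c(A = "1", B = "2")[[ch]]
ent_of_dna <- function(ch) c(C = "3", D = "4", E = "5", F = "6")[[ch]]

## mmCIF assembly of fixture parts -------------------------------------------

fixture_write_cif <- function(fx, path, block = "FIX") {
  atoms <- fx$atoms
  n <- nrow(atoms)
  as <- data.frame(
    group_PDB = atoms$group_PDB,
    id = seq_len(n),
    type_symbol = atoms$element,
    label_atom_id = atoms$name,
    label_alt_id = ".",
    label_comp_id = atoms$comp_id,
    label_asym_id = atoms$chain_id,
    label_entity_id = atoms$entity_id,
    label_seq_id = atoms$seq_id,
    pdbx_PDB_ins_code = "?",
    Cartn_x = formatC(atoms$x, format = "f", digits = 4),
    Cartn_y = formatC(atoms$y, format = "f", digits = 4),
    Cartn_z = formatC(atoms$z, format = "f", digits = 4),
    occupancy = "1.00", B_iso_or_equiv = "0.00",
    auth_seq_id = atoms$seq_id,
    auth_comp_id = atoms$comp_id,
    auth_asym_id = atoms$chain_id,
    auth_atom_id = atoms$name,
    pdbx_PDB_model_num = 1L,
    stringsAsFactors = FALSE)
  cats <- list(entry = data.frame(id = block, stringsAsFactors = FALSE))
  ent <- fx$entities
  cats$entity <- data.frame(id = ent$id, type = ent$type, stringsAsFactors = FALSE)
  poly <- ent[!is.na(ent$poly_type) & ent$type == "polymer", , drop = FALSE]
  if (nrow(poly))
    cats$entity_poly <- data.frame(entity_id = poly$id, type = poly$poly_type,
                                   stringsAsFactors = FALSE)
  if (!is.null(fx$assembly)) {
    asm <- fx$assembly
    cats$pdbx_struct_assembly <- data.frame(id = asm$assembly_id,
                                            details = "synthetic assembly",
                                            stringsAsFactors = FALSE)
    gens <- asm$generators
    cats$pdbx_struct_assembly_gen <- do.call(rbind, lapply(gens, function(g)
      data.frame(assembly_id = asm$assembly_id,
                 oper_expression = g$oper_expression,
                 asym_id_list = paste(g$asym_ids, collapse = ","),
                 stringsAsFactors = FALSE)))
    op_rows <- lapply(asm$operators, function(o) {
      R <- o$R[[1]]; t <- o$t[[1]]
      row <- data.frame(id = o$id, type = "point symmetry operation",
                        stringsAsFactors = FALSE)
      for (r in 1:3) for (c in 1:3)
        row[[sprintf("matrix[%d][%d]", r, c)]] <- formatC(R[r, c], format = "f", digits = 10)
      for (r in 1:3) row[[sprintf("vector[%d]", r)]] <- formatC(t[r], format = "f", digits = 10)
      row
    })
    cats$pdbx_struct_oper_list <- do.call(rbind, op_rows)
  }
  if (!is.null(fx$mod_residues))
    cats$pdbx_struct_mod_residue <- fx$mod_residues
  cats$atom_site <- as
  write_cif(cats, path, block = block)
  invisible(path)
}

## affinity fixture ----------------------------------------------------------

#' Generate a synthetic score/affinity dataset
#'
#' Score triples are drawn iid standard normal; the observed affinity is
#' \code{intercept + weights . x + N(0, noise_sigma)} on the pKd scale. The
#' default \code{noise_sigma = 0.56} puts the strongest single-score
#' correlation near 0.6 at n = 285 (the benchmark regime the consensus model
#' targets). Writes the score TSV and the experimental-affinity TSV in the
#' adapter formats.
#'
#' @param n rows (>= 10).
#' @param weights 3-vector over (x_xscore, x_itscore, x_vina).
#' @param intercept intercept on the pKd scale.
#' @param noise_sigma Gaussian noise sd.
#' @param seed RNG seed.
#' @param dir output directory.
#' @return list: \code{score_file}, \code{affinity_file}, \code{data}
#'   (data.frame incl. pkd), \code{params}.
#' @export
make_affinity_dataset <- function(n = 285L, weights = c(0.5, 0.3, -0.2),
                                  intercept = 6, noise_sigma = 0.56,
                                  seed = 1L, dir = tempdir()) {
  if (n < 10L) stopf("need n >= 10")
  set.seed(seed)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  X <- matrix(stats::rnorm(3 * n), ncol = 3,
              dimnames = list(NULL, c("x_xscore", "x_itscore", "x_vina")))
  y <- intercept + as.numeric(X %*% weights) + stats::rnorm(n, sd = noise_sigma)
  dat <- data.frame(pdb_id = sprintf("s%04d", seq_len(n)), ligand_id = "SYN",
                    X, pkd = y, stringsAsFactors = FALSE)
  sf <- file.path(dir, sprintf("scores_seed%d.tsv", seed))
  utils::write.table(dat[, c("pdb_id", "ligand_id", "x_xscore", "x_itscore", "x_vina")],
                     sf, sep = "\t", quote = FALSE, row.names = FALSE)
  af <- file.path(dir, sprintf("affinity_seed%d.tsv", seed))
  aff <- data.frame(pdb_id = dat$pdb_id, ligand_id = dat$ligand_id, chain = "A",
                    measure = "Kd",
                    value = formatC(10^(-dat$pkd), format = "e", digits = 10),
                    unit = "M", source = "synthetic", stringsAsFactors = FALSE)
  utils::write.table(aff, af, sep = "\t", quote = FALSE, row.names = FALSE)
  list(score_file = sf, affinity_file = af, data = dat,
       params = list(n = n, weights = weights, intercept = intercept,
                     noise_sigma = noise_sigma, seed = seed))
}
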