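## Receptor/ligand partitioning of an assembly, chain classification,
## stoichiometry and pairwise sequence identity.
##
## The receptor is the set of protein chains with >= 30 observed residues;
## everything else (small molecules, metal ions, peptides < 30 AA, paired
## DNA/RNA chain groups) becomes a ligand candidate. Waters are never ligands.

MIN_RECEPTOR_LENGTH <- 30L

classify_residues <- function(comp_ids) {
  n <- length(comp_ids)
  if (!n) stopf("cannot classify an empty chain")
  aa <- mean(comp_ids %in% STANDARD_AA)
  if (aa >= 0.8) return("protein")
  dna <- comp_ids %in% STANDARD_DNA
  rna <- comp_ids %in% STANDARD_RNA
  if (mean(dna | rna) >= 0.8) {
    if (any(dna) && any(rna)) return("na_hybrid")
    if (any(dna)) return("dna")
    return("rna")
  }
  "other"
}

#' Classify a polymer chain as protein, DNA, RNA, hybrid or other
#'
#' A chain is protein when at least 80\% of its residues are standard (or
#' mapped) amino acids; DNA/RNA by nucleotide dictionary membership, with
#' mixed deoxy/ribo chains labelled \code{na_hybrid}; anything else is
#' \code{other}.
#'
#' @param chain a \code{qs_chain} (from \code{\link{assembly_chains}}) or a
#'   character vector of residue comp_ids.
#' @return one of \code{"protein"}, \code{"dna"}, \code{"rna"},
#'   \code{"na_hybrid"}, \code{"other"}.
#' @export
classify_chain <- function(chain) {
  comp <- if (is.character(chain)) chain else chain$residues$comp_id
  if (!length(comp)) stopf("cannot classify an empty chain")
  classify_residues(comp)
}

#' List polymer chains of an assembly as residue tables
#'
#' Residues are counted only when they have at least one resolved
#' non-hydrogen atom (observed length, not the full entity sequence).
#'
#' @param asm a \code{qs_assembly} (or \code{qs_structure}).
#' @return named list of \code{qs_chain} objects: \code{chain_id},
#'   \code{polymer_type}, \code{residues} (seq_id, ins_code, comp_id),
#'   \code{length}.
#' @export
assembly_chains <- function(asm) {
  atoms <- qs_atoms(asm)
  a <- atoms[atoms$is_polymer & !atoms$is_h & !atoms$is_water, , drop = FALSE]
  chains <- unique(a$chain_id)
  out <- lapply(chains, function(ch) {
    ac <- a[a$chain_id == ch, , drop = FALSE]
    res <- unique(ac[, c("seq_id", "ins_code", "comp_id")])
    res <- res[order(res$seq_id, res$ins_code), , drop = FALSE]
    rownames(res) <- NULL
    structure(list(chain_id = ch, polymer_type = classify_residues(res$comp_id),
                   residues = res, length = nrow(res)), class = "qs_chain")
  })
  stats::setNames(out, chains)
}

chain_sequence <- function(chain) {
  if (chain$polymer_type == "protein") seq3_to_1(chain$residues$comp_id)
  else paste0(ifelse(is.na(NT1[chain$residues$comp_id]), "n",
                     NT1[chain$residues$comp_id]), collapse = "")
}

#' Partition an assembly into a receptor and ligand candidates
#'
#' Protein chains with >= 30 observed residues form the receptor (the bound
#' "30" is inclusive); shorter protein chains become peptide ligands; paired
#' nucleic chain groups become one ligand each; every non-water non-polymer
#' residue group becomes a small-molecule or metal-ion ligand (single-atom
#' groups whose element is in the packaged metal list are metal ions).
#'
#' @param asm a \code{qs_assembly}.
#' @param pairing optional \code{qs_pairing} from \code{\link{pair_chains}}
#'   computed on the assembly's nucleic chains; if NULL it is computed here
#'   with default parameters.
#' @return list with \code{receptor} (a \code{qs_receptor} or NULL),
#'   \code{ligands} (list of \code{qs_ligand}), \code{unassigned}
#'   (chain ids of "other" polymers routed as residue-group ligands),
#'   \code{structure_only} flag.
#' @export
partition_assembly <- function(asm, pairing = NULL) {
  atoms <- qs_atoms(asm)
  chains <- assembly_chains(asm)
  types <- vapply(chains, `[[`, character(1), "polymer_type")
  lens  <- vapply(chains, `[[`, integer(1), "length")

  prot <- names(chains)[types == "protein"]
  receptor_ids <- prot[lens[prot] >= MIN_RECEPTOR_LENGTH]
  peptide_ids  <- prot[lens[prot] <  MIN_RECEPTOR_LENGTH]
  nuc_ids <- names(chains)[types %in% c("dna", "rna", "na_hybrid")]
  other_ids <- names(chains)[types == "other"]

  receptor <- NULL
  if (length(receptor_ids)) {
    rchains <- chains[sort(receptor_ids)]
    receptor <- structure(list(
      chains = rchains,
      oligomeric_state = length(rchains),
      stoichiometry = stoichiometry_chains(rchains)
    ), class = "qs_receptor")
  }

  ligands <- list()
  add_lig <- function(lig) ligands[[length(ligands) + 1L]] <<- lig

  for (pid in sort(peptide_ids)) {
    add_lig(structure(list(kind = "peptide", ligand_id = "peptide",
                           chains = pid, comp_id = NA_character_,
                           chain = chains[[pid]]), class = "qs_ligand"))
  }

  if (length(nuc_ids)) {
    if (is.null(pairing)) {
      bps <- detect_base_pairs(atoms, nuc_ids)
      pairing <- pair_chains(bps, chains[nuc_ids])
    }
    for (grp in pairing$groups) {
      grp <- sort(grp)
      gt <- unique(types[grp])
      tag <- if (all(gt %in% c("dna"))) "dna"
      else if (all(gt %in% c("rna"))) "rna"
      else "dna-rna"
      add_lig(structure(list(kind = "nucleic", ligand_id = tag, chains = grp,
                             comp_id = NA_character_), class = "qs_ligand"))
    }
  }

  # "other" polymers (e.g., polysaccharides): residue-group ligands, flagged
  for (oid in sort(other_ids)) {
    add_lig(structure(list(kind = "small_molecule", ligand_id = "polymer-other",
                           chains = oid, comp_id = NA_character_,
                           flagged = TRUE), class = "qs_ligand"))
  }

  np <- atoms[!atoms$is_polymer & !atoms$is_water & !atoms$is_h, , drop = FALSE]
  if (nrow(np)) {
    key <- paste(np$chain_id, np$seq_id, np$ins_code, np$comp_id, sep = "\r")
    for (k in unique(key[order(np$chain_id, np$seq_id)])) {
      grp <- np[key == k, , drop = FALSE]
      kind <- if (nrow(grp) == 1L && grp$element[1] %in% METAL_ELEMENTS)
        "metal_ion" else "small_molecule"
      add_lig(structure(list(kind = kind, ligand_id = grp$comp_id[1],
                             chains = grp$chain_id[1], comp_id = grp$comp_id[1],
                             seq_id = grp$seq_id[1], ins_code = grp$ins_code[1]),
                        class = "qs_ligand"))
    }
  }

  list(receptor = receptor, ligands = ligands,
       unassigned = other_ids,
       structure_only = is.null(receptor) || !length(ligands))
}

# Atom subset belonging to a ligand (excluding hydrogens)
ligand_atoms <- function(asm, lig) {
  atoms <- qs_atoms(asm)
  atoms <- atoms[!atoms$is_h, , drop = FALSE]
  if (lig$kind %in% c("peptide", "nucleic") ||
      identical(lig$ligand_id, "polymer-other")) {
    atoms[atoms$chain_id %in% lig$chains & atoms$is_polymer, , drop = FALSE]
  } else {
    atoms[atoms$chain_id == lig$chains & atoms$seq_id == lig$seq_id &
            atoms$ins_code == lig$ins_code & atoms$comp_id == lig$comp_id &
            !atoms$is_polymer, , drop = FALSE]
  }
}

receptor_atoms <- function(asm, receptor) {
  atoms <- qs_atoms(asm)
  atoms[atoms$chain_id %in% names(receptor$chains) & atoms$is_polymer &
          !atoms$is_h, , drop = FALSE]
}

## Sequence identity and stoichiometry ---------------------------------------

#' Global-alignment sequence identity
#'
#' Needleman-Wunsch global alignment with match +1, mismatch 0 and linear
#' gap penalty -0.5 (open = extend). Identity is the number of identical
#' aligned positions divided by the alignment length; symmetric in its
#' arguments.
#'
#' @param seq_a,seq_b non-empty sequence strings.
#' @return identity fraction in [0, 1].
#' @export
pairwise_identity <- function(seq_a, seq_b) {
  if (!nzchar(seq_a) || !nzchar(seq_b)) stopf("empty sequence")
  # canonical argument order: ties between co-optimal alignments are broken
  # identically whichever way the pair is passed, keeping the measure symmetric
  if (seq_a > seq_b) { tmp <- seq_a; seq_a <- seq_b; seq_b <- tmp }
  a <- strsplit(seq_a, "")[[1]]
  b <- strsplit(seq_b, "")[[1]]
  n <- length(a); m <- length(b)
  gap <- -0.5
  S <- matrix(0, n + 1L, m + 1L)
  S[, 1] <- gap * (0:n)
  S[1, ] <- gap * (0:m)
  for (i in seq_len(n)) {
    match_row <- (a[i] == b) * 1
    prev <- S[i, ]
    cur <- numeric(m + 1L)
    cur[1] <- gap * i
    for (j in seq_len(m)) {
      cur[j + 1L] <- max(prev[j] + match_row[j], prev[j + 1L] + gap, cur[j] + gap)
    }
    S[i + 1L, ] <- cur
  }
  # traceback (prefer diagonal, then up, then left — deterministic)
  i <- n; j <- m
  matches <- 0L; alen <- 0L
  while (i > 0L || j > 0L) {
    alen <- alen + 1L
    if (i > 0L && j > 0L &&
        abs(S[i + 1L, j + 1L] - (S[i, j] + (a[i] == b[j]))) < 1e-9) {
      matches <- matches + (a[i] == b[j])
      i <- i - 1L; j <- j - 1L
    } else if (i > 0L && abs(S[i + 1L, j + 1L] - (S[i, j + 1L] + gap)) < 1e-9) {
      i <- i - 1L
    } else {
      j <- j - 1L
    }
  }
  matches / alen
}

stoichiometry_chains <- function(chains, identity_threshold = 0.95) {
  ids <- names(chains)
  seqs <- vapply(chains, chain_sequence, character(1))
  uf <- uf_new(ids)
  if (length(ids) > 1L) {
    for (i in seq_len(length(ids) - 1L)) {
      for (j in seq((i + 1L), length(ids))) {
        if (pairwise_identity(seqs[i], seqs[j]) > identity_threshold)
          uf <- uf_union(uf, ids[i], ids[j])
      }
    }
  }
  comps <- uf_components(uf)
  sizes <- vapply(comps, length, integer(1))
  mins  <- vapply(comps, function(g) min(g), character(1))
  ord <- order(-sizes, mins)
  letters_ <- LETTERS[seq_along(ord)]
  paste0(vapply(seq_along(ord), function(k) {
    cnt <- sizes[ord[k]]
    if (cnt == 1L) letters_[k] else paste0(letters_[k], cnt)
  }, character(1)), collapse = "")
}

#' Stoichiometry string of a receptor
#'
#' Chains are grouped by single-linkage clustering on pairwise global
#' sequence identity above \code{identity_threshold} (the PDB convention:
#' chains with > 95\% identity are equivalent). Groups are lettered A, B, ...
#' by descending size (ties by smallest chain id) and counts of 1 omitted,
#' e.g. \code{"A2"}, \code{"AB"}.
#'
#' @param receptor a \code{qs_receptor}.
#' @param identity_threshold equivalence threshold (default 0.95).
#' @return stoichiometry string.
#' @export
stoichiometry <- function(receptor, identity_threshold = 0.95) {
  stopifnot(inherits(receptor, "qs_receptor"))
  if (!length(receptor$chains)) stopf("receptor has no chains")
  stoichiometry_chains(receptor$chains, identity_threshold)
}

# homo-oligomer test: all chains in one equivalence group
is_homo_oligomer <- function(stoich_string) {
  grepl("^A[0-9]*$", stoich_string)
}
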