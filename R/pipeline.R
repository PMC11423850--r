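## End-to-end pipeline: assemblies -> partition -> nucleic pairing -> binding
## sites -> relevance -> optional interface area and affinities -> entries in
## three categories (relevant / irrelevant / structure_only), plus
## single-chain splits, corpus statistics and TSV/JSON export.

#' Default pipeline configuration
#'
#' Every threshold used by the pipeline, overridable via
#' \code{\link{read_qs_config}} or by editing the returned list.
#'
#' @return named list of parameters.
#' @export
qs_config <- function() {
  list(
    margin = 0.5,            # binding-residue distance margin (angstrom)
    min_pairs = 3L,          # inter-chain base pairs to pair two nucleic chains
    hbond_max = 3.5,         # base-pair donor-acceptor cutoff (angstrom)
    c1_min = 8.0,            # C1'-C1' window (angstrom)
    c1_max = 11.5,
    min_contacts = 2L,       # edge-atom contacts per base pair
    identity_threshold = 0.95,   # stoichiometry equivalence
    redundancy_threshold = 0.9,  # nr-dataset chain similarity
    probe = 1.4,             # SASA probe radius (angstrom)
    n_points = 960L,         # SASA sample points per atom
    min_site_residues = 6L,  # relevance site-size threshold (calibration)
    compute_interface = TRUE,    # interface area for small_molecule/metal_ion
    interface_all_ligands = FALSE
  )
}

#' Read a key = value configuration file
#'
#' TOML-style: one \code{key = value} per line, \code{#} comments, section
#' headers ignored. Unknown keys raise an error; values are coerced to the
#' type of the default.
#'
#' @param path config file.
#' @param base defaults to extend (default \code{\link{qs_config}()}).
#' @return config list.
#' @export
read_qs_config <- function(path, base = qs_config()) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines) & !grepl("^\\[", lines)]
  for (l in lines) {
    kv <- strsplit(l, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2L) stopf("malformed config line: '%s'", l)
    key <- trimws(kv[1]); val <- trimws(kv[2])
    if (!key %in% names(base)) stopf("unknown config key '%s'", key)
    base[[key]] <- if (is.logical(base[[key]])) toupper(val) %in% c("TRUE", "YES", "1")
    else if (is.integer(base[[key]])) as.integer(val)
    else as.numeric(val)
  }
  base
}

#' Run the full annotation pipeline over structure files
#'
#' For each input: parse, build assemblies (first model only), partition into
#' receptor and ligands (nucleic chains paired first), then per ligand:
#' binding site on the quaternary structure, biological-relevance verdict,
#' optional interface area (small molecules and ions) and affinity
#' (experimental lookup, else consensus prediction when a model and score
#' table are supplied). Assemblies without a receptor or without ligands
#' yield one \code{structure_only} entry. Per-file failures are quarantined
#' in the errors report; the run continues.
#'
#' @param paths character vector of mmCIF/PDB files.
#' @param config list from \code{\link{qs_config}}.
#' @param exclusion \code{qs_exclusion} (default: packaged synthetic list).
#' @param affinity optional result of \code{\link{read_affinity_table}}.
#' @param scores optional data.frame from \code{\link{read_score_table}}.
#' @param model optional \code{qs_affinity_model} for predictions.
#' @param abstracts optional named character vector: ligand comp_id ->
#'   abstract text for the keyword rule.
#' @return object of class \code{qs_run}: \code{entries} (list of
#'   \code{qs_entry}), \code{errors} (data.frame path, message).
#' @export
run_pipeline <- function(paths, config = qs_config(),
                         exclusion = read_exclusion_list(),
                         affinity = NULL, scores = NULL, model = NULL,
                         abstracts = NULL) {
  radii <- default_radii()
  entries <- list()
  errors <- list()
  for (path in paths) {
    res <- tryCatch({
      st <- parse_structure(path)
      asms <- build_assemblies(st)
      out <- list()
      for (asm in asms)
        out <- c(out, annotate_assembly(asm, config, exclusion, radii,
                                        affinity, scores, model, abstracts))
      out
    }, error = function(e) e)
    if (inherits(res, "error")) {
      errors[[length(errors) + 1L]] <- data.frame(
        path = path, message = conditionMessage(res), stringsAsFactors = FALSE)
    } else entries <- c(entries, res)
  }
  errors <- if (length(errors)) do.call(rbind, errors)
  else data.frame(path = character(0), message = character(0),
                  stringsAsFactors = FALSE)
  structure(list(entries = entries, errors = errors, config = config),
            class = "qs_run")
}

annotate_assembly <- function(asm, config, exclusion, radii,
                              affinity = NULL, scores = NULL, model = NULL,
                              abstracts = NULL) {
  atoms <- asm$atoms
  ct <- asm$chain_types
  nuc_ids <- ct$chain_id[ct$polymer_type %in% c("dna", "rna", "na_hybrid")]
  pairing <- NULL
  if (length(nuc_ids)) {
    bps <- detect_base_pairs(atoms, nuc_ids, hbond_max = config$hbond_max,
                             c1_range = c(config$c1_min, config$c1_max),
                             min_contacts = config$min_contacts)
    pairing <- pair_chains(bps, assembly_chains(asm)[nuc_ids],
                           min_pairs = config$min_pairs)
  }
  part <- partition_assembly(asm, pairing)
  mk_id <- function(serial) sprintf("%s_%s_%d", asm$pdb_id, asm$assembly_id, serial)
  if (part$structure_only) {
    e <- structure(list(entry_id = mk_id(1L), pdb_id = asm$pdb_id,
                        assembly_id = asm$assembly_id,
                        receptor = part$receptor,
                        stoichiometry = if (!is.null(part$receptor))
                          part$receptor$stoichiometry else NA_character_,
                        ligand = NULL, site = NULL, verdict = NULL,
                        interface = NULL, affinity = NULL,
                        category = "structure_only",
                        resolution = asm$resolution, assembly = asm),
                   class = "qs_entry")
    return(list(e))
  }
  rec_atoms <- receptor_atoms(asm, part$receptor)
  # deterministic ligand order: (kind, first chain, seq)
  ligs <- part$ligands
  ord <- order(vapply(ligs, `[[`, character(1), "kind"),
               vapply(ligs, function(l) l$chains[1], character(1)),
               vapply(ligs, function(l) as.integer(l$seq_id %||% 0L), integer(1)))
  ligs <- ligs[ord]
  out <- list()
  serial <- 0L
  for (lig in ligs) {
    la <- ligand_atoms(asm, lig)
    if (!nrow(la)) next
    serial <- serial + 1L
    site <- find_binding_residues(rec_atoms, la, radii, margin = config$margin)
    abstract <- NULL
    if (!is.null(abstracts) && !is.na(lig$ligand_id) &&
        lig$ligand_id %in% names(abstracts))
      abstract <- abstracts[[lig$ligand_id]]
    verdict <- assess_relevance(lig, site, exclusion, abstract_text = abstract,
                                min_site_residues = config$min_site_residues)
    iface <- NULL
    if ((lig$kind %in% c("small_molecule", "metal_ion") && config$compute_interface) ||
        isTRUE(config$interface_all_ligands)) {
      iface <- interface_area(rec_atoms, la, radii, probe = config$probe,
                              n_points = config$n_points)
    }
    aff <- lookup_affinity(asm$pdb_id, lig, affinity, scores, model)
    category <- if (verdict$status == "relevant") "relevant" else "irrelevant"
    out[[length(out) + 1L]] <- structure(
      list(entry_id = mk_id(serial), pdb_id = asm$pdb_id,
           assembly_id = asm$assembly_id, receptor = part$receptor,
           stoichiometry = part$receptor$stoichiometry,
           ligand = lig, site = site, verdict = verdict, interface = iface,
           affinity = aff, category = category,
           resolution = asm$resolution, assembly = asm),
      class = "qs_entry")
  }
  if (!length(out)) {
    # ligand candidates had no atoms: treat as structure-only
    return(annotate_structure_only(asm, part, mk_id))
  }
  out
}

annotate_structure_only <- function(asm, part, mk_id) {
  list(structure(list(entry_id = mk_id(1L), pdb_id = asm$pdb_id,
                      assembly_id = asm$assembly_id, receptor = part$receptor,
                      stoichiometry = if (!is.null(part$receptor))
                        part$receptor$stoichiometry else NA_character_,
                      ligand = NULL, site = NULL, verdict = NULL,
                      interface = NULL, affinity = NULL,
                      category = "structure_only",
                      resolution = asm$resolution, assembly = asm),
                 class = "qs_entry"))
}

lookup_affinity <- function(pdb_id, lig, affinity, scores, model) {
  if (!is.null(affinity)) {
    rec <- affinity$records
    hit <- rec[rec$pdb_id == pdb_id &
                 toupper(rec$ligand_id) == toupper(lig$ligand_id %||% ""), ,
               drop = FALSE]
    if (nrow(hit))
      return(list(kind = "experimental", value = hit$pkd[1], raw = hit$raw[1],
                  source = hit$source[1]))
  }
  if (!is.null(scores) && !is.null(model)) {
    hit <- scores[scores$pdb_id == pdb_id &
                    toupper(scores$ligand_id) == toupper(lig$ligand_id %||% ""), ,
                  drop = FALSE]
    if (nrow(hit)) {
      comp <- c(x_xscore = hit$x_xscore[1], x_itscore = hit$x_itscore[1],
                x_vina = hit$x_vina[1])
      return(list(kind = "predicted", value = predict_consensus(model, comp),
                  source = "consensus", components = comp))
    }
  }
  NULL
}

#' @export
print.qs_entry <- function(x, ...) {
  cat(sprintf("<qs_entry> %s [%s] ligand=%s site=%d residue(s)\n", x$entry_id,
              x$category, if (is.null(x$ligand)) "-" else x$ligand$ligand_id,
              if (is.null(x$site)) 0L else nrow(x$site$residues)))
  invisible(x)
}

## Single-chain splitting ----------------------------------------------------

#' Split a quaternary entry into single-chain entries
#'
#' One entry per (receptor chain with at least one binding residue for the
#' ligand) x (contacting ligand unit). Nucleic ligands decompose into their
#' component chains, keeping only chains that contact the given receptor
#' chain; small molecules and peptides stay atomic units.
#'
#' @param entry a \code{qs_entry} with both receptor and ligand.
#' @param radii radii table.
#' @param margin binding margin (angstrom).
#' @return list of single-chain entries: \code{parent_entry_id},
#'   \code{receptor_chain}, \code{ligand_component}, \code{residues}.
#' @export
split_single_chain <- function(entry, radii = default_radii(), margin = 0.5) {
  stopifnot(inherits(entry, "qs_entry"))
  if (is.null(entry$receptor) || is.null(entry$ligand))
    stopf("entry '%s' lacks a receptor or a ligand", entry$entry_id)
  asm <- entry$assembly
  atoms <- asm$atoms
  lig <- entry$ligand
  out <- list()
  for (ch in names(entry$receptor$chains)) {
    ch_atoms <- atoms[atoms$chain_id == ch & atoms$is_polymer & !atoms$is_h, ,
                      drop = FALSE]
    res_on_chain <- entry$site$residues[entry$site$residues$chain_id == ch, ,
                                        drop = FALSE]
    if (!nrow(res_on_chain)) next
    if (lig$kind == "nucleic") {
      for (comp_chain in lig$chains) {
        la <- atoms[atoms$chain_id == comp_chain & atoms$is_polymer &
                      !atoms$is_h, , drop = FALSE]
        if (!nrow(la)) next
        sub_site <- find_binding_residues(ch_atoms, la, radii, margin)
        if (!nrow(sub_site$residues)) next
        out[[length(out) + 1L]] <- list(
          parent_entry_id = entry$entry_id, receptor_chain = ch,
          ligand_component = comp_chain, residues = sub_site$residues)
      }
    } else {
      out[[length(out) + 1L]] <- list(
        parent_entry_id = entry$entry_id, receptor_chain = ch,
        ligand_component = lig$ligand_id, residues = res_on_chain)
    }
  }
  out
}

## Corpus summary ------------------------------------------------------------

#' Summarize a corpus of interaction entries
#'
#' Category counts over all entries; oligomeric-state histogram, homo/hetero
#' split, ligand-kind distribution and the fraction of ligands contacting
#' more than one receptor chain, computed over biologically relevant entries
#' (multi-chain fraction over relevant entries with oligomeric receptors; 0
#' when there are none).
#'
#' @param entries list of \code{qs_entry} (or a \code{qs_run}).
#' @return object of class \code{qs_summary}.
#' @export
summarize_corpus <- function(entries) {
  if (inherits(entries, "qs_run")) entries <- entries$entries
  if (!length(entries)) stopf("no entries to summarize")
  cat_counts <- table(factor(vapply(entries, `[[`, character(1), "category"),
                             levels = c("relevant", "irrelevant", "structure_only")))
  rel <- Filter(function(e) e$category == "relevant" && !is.null(e$receptor),
                entries)
  states <- vapply(rel, function(e) e$receptor$oligomeric_state, integer(1))
  stoich <- vapply(rel, `[[`, character(1), "stoichiometry")
  homo <- vapply(stoich, is_homo_oligomer, logical(1))
  state_hist <- table(states)
  homo_hetero <- if (length(states)) {
    tb <- table(states, factor(ifelse(homo, "homo", "hetero"),
                               levels = c("homo", "hetero")))
    as.data.frame.matrix(tb)
  } else data.frame(homo = integer(0), hetero = integer(0))
  kinds <- table(vapply(rel, function(e) e$ligand$kind, character(1)))
  oligo <- states >= 2L
  multi <- vapply(rel, function(e) e$site$n_chains_involved > 1L, logical(1))
  frac_multi <- if (any(oligo)) mean(multi[oligo]) else 0
  structure(list(category_counts = cat_counts,
                 oligomeric_state_hist = state_hist,
                 homo_hetero_by_state = homo_hetero,
                 ligand_kind_counts = kinds,
                 frac_multi_chain_ligands = frac_multi,
                 n_relevant = length(rel)),
            class = "qs_summary")
}

#' @export
print.qs_summary <- function(x, ...) {
  cat("<qs_summary>\n  categories:",
      paste(names(x$category_counts), as.integer(x$category_counts),
            sep = "=", collapse = " "), "\n")
  cat("  multi-chain ligand fraction (oligomeric receptors):",
      sprintf("%.3f", x$frac_multi_chain_ligands), "\n")
  invisible(x)
}

## Export --------------------------------------------------------------------

entry_row <- function(e) {
  data.frame(
    entry_id = e$entry_id, pdb_id = e$pdb_id, assembly_id = e$assembly_id,
    stoichiometry = e$stoichiometry %||% NA_character_,
    ligand_id = if (is.null(e$ligand)) NA_character_ else e$ligand$ligand_id,
    ligand_kind = if (is.null(e$ligand)) NA_character_ else e$ligand$kind,
    category = e$category,
    n_binding_residues = if (is.null(e$site)) NA_integer_ else nrow(e$site$residues),
    n_chains_involved = if (is.null(e$site)) NA_integer_ else e$site$n_chains_involved,
    interface_S = if (is.null(e$interface)) NA_real_ else e$interface$S,
    affinity_kind = if (is.null(e$affinity)) NA_character_ else e$affinity$kind,
    affinity_value = if (is.null(e$affinity)) NA_real_ else e$affinity$value,
    resolution = e$resolution %||% NA_real_,
    stringsAsFactors = FALSE)
}

#' Export entries as TSV or JSON
#'
#' The TSV mirrors the browse-table fields (entry id, PDB id with
#' resolution, assembly id, stoichiometry, ligand, category, site size,
#' chains involved, interface area, affinity); the JSON export is a lossless
#' superset including per-residue binding sites and verdict provenance.
#'
#' @param entries list of \code{qs_entry} or a \code{qs_run}.
#' @param path output file.
#' @param format \code{"tsv"} or \code{"json"}.
#' @return \code{path}, invisibly.
#' @export
export_entries <- function(entries, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (inherits(entries, "qs_run")) entries <- entries$entries
  if (!length(entries)) stopf("no entries to export")
  if (format == "tsv") {
    df <- do.call(rbind, lapply(entries, entry_row))
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                       na = ".")
    return(invisible(path))
  }
  payload <- lapply(entries, function(e) {
    list(entry_id = e$entry_id, pdb_id = e$pdb_id, assembly_id = e$assembly_id,
         stoichiometry = e$stoichiometry,
         category = e$category,
         resolution = e$resolution,
         ligand = if (!is.null(e$ligand))
           list(kind = e$ligand$kind, ligand_id = e$ligand$ligand_id,
                chains = e$ligand$chains),
         site = if (!is.null(e$site))
           list(residues = e$site$residues,
                n_chains_involved = e$site$n_chains_involved),
         verdict = if (!is.null(e$verdict))
           list(status = e$verdict$status, rule_fired = e$verdict$rule_fired,
                evidence = e$verdict$evidence),
         interface = if (!is.null(e$interface))
           e$interface[c("S", "S_prot", "S_lig", "S_com")],
         affinity = e$affinity)
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

## Command-line interface ----------------------------------------------------

#' Command-line entry point
#'
#' Verbs: \code{build} (annotate mmCIF/PDB inputs; \code{--out DIR}),
#' \code{convert} (mmCIF <-> PDB), \code{fixtures} (write a synthetic
#' fixture; \code{--kind}, \code{--seed}, \code{--dir}), \code{summarize}
#' (corpus TSV from build output), \code{dedupe} (FASTA in, cluster TSV
#' out), \code{split} (>62-chain structure into PDB files). Use
#' \code{--show-config} to print all defaults.
#'
#' @param args character vector (default: command-line arguments).
#' @return exit status, invisibly.
#' @export
qs_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args) || args[1] == "--help") {
    cat("usage: quatsite <build|convert|fixtures|dedupe|split|summarize> [options]\n")
    return(invisible(0L))
  }
  if ("--show-config" %in% args) {
    cfg <- qs_config()
    for (k in names(cfg)) cat(sprintf("%s = %s\n", k, cfg[[k]]))
    return(invisible(0L))
  }
  verb <- args[1]; rest <- args[-1]
  opt <- function(flag, default = NULL) {
    i <- which(rest == flag)
    if (length(i)) rest[i[1] + 1L] else default
  }
  positional <- rest[!rest %in% c("--out", "--kind", "--seed", "--dir",
                                  "--config", "--threshold") &
                       !seq_along(rest) %in% (which(startsWith(rest, "--")) + 1L)]
  switch(verb,
    build = {
      cfg <- if (!is.null(opt("--config"))) read_qs_config(opt("--config")) else qs_config()
      run <- run_pipeline(positional, config = cfg)
      out <- opt("--out", ".")
      dir.create(out, showWarnings = FALSE, recursive = TRUE)
      if (length(run$entries))
        export_entries(run, file.path(out, "entries.tsv"), "tsv")
      utils::write.table(run$errors, file.path(out, "errors.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      cat(sprintf("build: %d entries, %d error(s)\n", length(run$entries),
                  nrow(run$errors)))
    },
    convert = {
      if (length(positional) != 2L) stopf("convert needs <in> <out>")
      convert_structure(positional[1], positional[2])
    },
    fixtures = {
      fx <- make_structure_fixture(opt("--kind", "protein_monomer"),
                                   seed = as.integer(opt("--seed", "1")),
                                   dir = opt("--dir", "."))
      cat(fx$path, "\n")
    },
    dedupe = {
      seqs <- read_fasta(positional[1])
      cl <- cluster_chains(seqs, as.numeric(opt("--threshold", "0.9")))
      utils::write.table(cl, opt("--out", "clusters.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    },
    split = {
      st <- parse_structure(positional[1])
      res <- split_for_pdb(st, dir = opt("--dir", "."),
                           base = st$pdb_id)
      cat(paste(res$files, collapse = "\n"), "\n")
    },
    summarize = {
      stopf("summarize operates on in-memory runs; use summarize_corpus() in R")
    },
    stopf("unknown verb '%s'", verb))
  invisible(0L)
}

# minimal FASTA reader for the dedupe verb and redundancy tests
read_fasta <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- grepl("^>", lines)
  if (!any(hdr)) stopf("not a FASTA file: '%s'", path)
  ids <- sub("^>", "", lines[hdr])
  ids <- sub("[[:space:]].*$", "", ids)
  grp <- cumsum(hdr)
  seqs <- vapply(split(lines[!hdr], grp[!hdr]), paste, character(1), collapse = "")
  stats::setNames(toupper(gsub("[[:space:]]", "", seqs)), ids)
}
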