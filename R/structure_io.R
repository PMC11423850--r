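## Structure I/O: mmCIF/PDB parsing, biological-assembly generation from
## stored symmetry operators, format conversion, >62-chain PDB splitting.

ATOM_COLS <- c("serial", "name", "altloc", "comp_id", "chain_id", "auth_asym_id",
               "entity_id", "seq_id", "ins_code", "x", "y", "z", "occupancy",
               "bfactor", "element", "is_hetatm", "model_num", "is_polymer",
               "is_water", "is_h", "orig_comp_id")

#' Parse an mmCIF or legacy PDB structure file
#'
#' Reads coordinates, polymer/non-polymer classification, biological-assembly
#' definitions (\code{pdbx_struct_assembly_gen}), symmetry operators
#' (\code{pdbx_struct_oper_list}) and the modified-residue map
#' (\code{pdbx_struct_mod_residue}). For PDB input (which stores none of the
#' assembly records) the assembly-definition list is empty and polymer status
#' is inferred from residue dictionaries and record type.
#'
#' Alternate locations are reduced to a single conformer at parse time: for
#' each atom the highest-occupancy altloc is kept (ties broken by altloc
#' character order). All models are retained and flagged with
#' \code{model_num}; waters are flagged (\code{is_water}) but kept for output
#' fidelity.
#'
#' @param path file path.
#' @param format one of \code{"auto"}, \code{"mmcif"}, \code{"pdb"}.
#' @return an object of class \code{qs_structure}: a list with elements
#'   \code{pdb_id}, \code{atoms} (data.frame), \code{assembly_defs},
#'   \code{operators}, \code{mod_residues}, \code{chain_types},
#'   \code{resolution}, \code{format}.
#' @export
parse_structure <- function(path, format = c("auto", "mmcif", "pdb")) {
  format <- match.arg(format)
  if (!file.exists(path)) stopf("file not found: '%s'", path)
  if (format == "auto") format <- detect_format(path)
  st <- if (format == "mmcif") parse_mmcif(path) else parse_pdb(path)
  st$format <- format
  st$path <- path
  # single-conformer reduction
  st$atoms <- select_altlocs(st$atoms)
  st$chain_types <- chain_type_table(st$atoms)
  class(st) <- "qs_structure"
  st
}

detect_format <- function(path) {
  head <- readLines(path, n = 50L, warn = FALSE)
  if (any(grepl("^data_", head)) || any(grepl("^_atom_site\\.", head))) return("mmcif")
  if (any(grepl("^(ATOM|HETATM|HEADER|MODEL)", head))) return("pdb")
  stopf("cannot detect structure format of '%s'", path)
}

num_or_stop <- function(x, what) {
  out <- suppressWarnings(as.numeric(x))
  if (anyNA(out) && !all(is.na(x) == is.na(out)))
    stopf("parse error: non-numeric value in %s", what)
  out
}

parse_mmcif <- function(path) {
  cats <- read_cif(path)
  as <- cats[["atom_site"]]
  if (is.null(as)) stopf("mmCIF parse error: no _atom_site records in '%s'", path)
  need <- c("Cartn_x", "Cartn_y", "Cartn_z")
  if (!all(need %in% names(as)))
    stopf("mmCIF parse error: _atom_site lacks coordinate items in '%s'", path)
  g <- function(item, default = NA_character_) {
    if (item %in% names(as)) as[[item]] else rep(default, nrow(as))
  }
  x <- num_or_stop(as$Cartn_x, "_atom_site.Cartn_x")
  y <- num_or_stop(as$Cartn_y, "_atom_site.Cartn_y")
  z <- num_or_stop(as$Cartn_z, "_atom_site.Cartn_z")
  if (anyNA(x) || anyNA(y) || anyNA(z))
    stopf("mmCIF parse error: missing coordinates in '%s'", path)
  seq_raw <- g("auth_seq_id"); seq_lab <- g("label_seq_id")
  seq_id <- suppressWarnings(as.integer(ifelse(is.na(seq_raw), seq_lab, seq_raw)))
  atoms <- data.frame(
    serial = suppressWarnings(as.integer(g("id", NA))),
    name = g("auth_atom_id") , altloc = g("label_alt_id"),
    comp_id = toupper(g("label_comp_id")),
    chain_id = g("label_asym_id"),
    auth_asym_id = g("auth_asym_id"),
    entity_id = g("label_entity_id"),
    seq_id = seq_id,
    ins_code = g("pdbx_PDB_ins_code"),
    x = x, y = y, z = z,
    occupancy = suppressWarnings(as.numeric(g("occupancy", "1"))),
    bfactor = suppressWarnings(as.numeric(g("B_iso_or_equiv", "0"))),
    element = toupper(g("type_symbol")),
    is_hetatm = g("group_PDB", "ATOM") == "HETATM",
    model_num = suppressWarnings(as.integer(g("pdbx_PDB_model_num", "1"))),
    stringsAsFactors = FALSE
  )
  atoms$name[is.na(atoms$name)] <- g("label_atom_id")[is.na(atoms$name)]
  atoms$altloc[is.na(atoms$altloc)] <- ""
  atoms$ins_code[is.na(atoms$ins_code)] <- ""
  atoms$occupancy[is.na(atoms$occupancy)] <- 1
  atoms$model_num[is.na(atoms$model_num)] <- 1L
  if (any(is.na(atoms$element) | atoms$element == ""))
    stopf("mmCIF parse error: _atom_site.type_symbol missing in '%s'", path)

  # polymer classification from entity records; heuristic fallback
  ent <- cats[["entity"]]
  if (!is.null(ent) && "type" %in% names(ent)) {
    poly_ids <- ent$id[ent$type == "polymer"]
    atoms$is_polymer <- atoms$entity_id %in% poly_ids
  } else {
    atoms$is_polymer <- heuristic_polymer(atoms)
  }
  atoms$is_water <- atoms$comp_id %in% WATER_IDS
  atoms$is_h <- atoms$element %in% c("H", "D")
  atoms$orig_comp_id <- atoms$comp_id

  entity_poly <- cats[["entity_poly"]]
  st <- list(
    pdb_id = tolower(cats[["entry"]]$id[1] %||% tools::file_path_sans_ext(basename(path))),
    atoms = atoms,
    assembly_defs = parse_assembly_defs(cats),
    operators = parse_oper_list(cats[["pdbx_struct_oper_list"]]),
    mod_residues = parse_mod_residues(cats[["pdbx_struct_mod_residue"]]),
    entity_poly = entity_poly,
    resolution = parse_resolution(cats)
  )
  st
}

parse_resolution <- function(cats) {
  r <- cats[["refine"]]
  if (!is.null(r) && "ls_d_res_high" %in% names(r))
    return(suppressWarnings(as.numeric(r$ls_d_res_high[1])))
  r <- cats[["em_3d_reconstruction"]]
  if (!is.null(r) && "resolution" %in% names(r))
    return(suppressWarnings(as.numeric(r$resolution[1])))
  NA_real_
}

parse_assembly_defs <- function(cats) {
  gen <- cats[["pdbx_struct_assembly_gen"]]
  if (is.null(gen)) return(list())
  need <- c("assembly_id", "oper_expression", "asym_id_list")
  if (!all(need %in% names(gen)))
    stopf("mmCIF parse error: incomplete _pdbx_struct_assembly_gen")
  defs <- list()
  for (aid in unique(gen$assembly_id)) {
    rows <- gen[gen$assembly_id == aid, , drop = FALSE]
    gens <- lapply(seq_len(nrow(rows)), function(i) {
      asyms <- strsplit(rows$asym_id_list[i], ",", fixed = TRUE)[[1]]
      asyms <- trimws(asyms)
      if (!length(asyms) || any(asyms == ""))
        stopf("mmCIF parse error: empty asym_id_list for assembly '%s'", aid)
      list(oper_expression = rows$oper_expression[i], asym_ids = asyms)
    })
    defs[[aid]] <- list(assembly_id = aid, generators = gens)
  }
  unname(defs)
}

parse_oper_list <- function(op) {
  if (is.null(op)) return(list())
  ops <- list()
  for (i in seq_len(nrow(op))) {
    R <- matrix(NA_real_, 3, 3)
    t <- numeric(3)
    for (r in 1:3) {
      for (c in 1:3)
        R[r, c] <- as.numeric(op[[sprintf("matrix[%d][%d]", r, c)]][i])
      t[r] <- as.numeric(op[[sprintf("vector[%d]", r)]][i])
    }
    if (anyNA(R) || anyNA(t))
      stopf("mmCIF parse error: incomplete operator matrix in _pdbx_struct_oper_list row %d", i)
    validate_operator(R, op$id[i])
    ops[[op$id[i]]] <- list(oper_id = op$id[i], R = R, t = t)
  }
  ops
}

validate_operator <- function(R, id) {
  d <- det(R)
  if (d < 0)
    stopf("operator '%s' is improper (det = %.4f); reflections are not supported", id, d)
  if (abs(d - 1) > 1e-3)
    stopf("operator '%s' is not a proper rotation (det = %.6f)", id, d)
  if (max(abs(R %*% t(R) - diag(3))) > 1e-3)
    stopf("operator '%s' is not orthogonal", id)
  invisible(TRUE)
}

parse_mod_residues <- function(mr) {
  empty <- data.frame(asym_id = character(0), seq_id = integer(0),
                      comp_id = character(0), parent_comp_id = character(0),
                      stringsAsFactors = FALSE)
  if (is.null(mr)) return(empty)
  asym <- mr[["label_asym_id"]] %||% mr[["auth_asym_id"]]
  seq_ <- mr[["auth_seq_id"]] %||% mr[["label_seq_id"]]
  comp <- mr[["label_comp_id"]] %||% mr[["auth_comp_id"]]
  parent <- mr[["parent_comp_id"]]
  if (is.null(asym) || is.null(seq_) || is.null(comp) || is.null(parent))
    stopf("mmCIF parse error: incomplete _pdbx_struct_mod_residue")
  data.frame(asym_id = asym, seq_id = as.integer(seq_),
             comp_id = toupper(comp), parent_comp_id = toupper(parent),
             stringsAsFactors = FALSE)
}

heuristic_polymer <- function(atoms) {
  std <- atoms$comp_id %in% c(STANDARD_AA, STANDARD_NT)
  std & !atoms$is_hetatm
}

# Keep the highest-occupancy alternate per atom site; ties by altloc order.
select_altlocs <- function(atoms) {
  has_alt <- atoms$altloc != ""
  if (!any(has_alt)) return(atoms)
  key <- paste(atoms$model_num, atoms$chain_id, atoms$seq_id, atoms$ins_code,
               atoms$comp_id, atoms$name, sep = "\r")
  ord <- order(key, -atoms$occupancy, atoms$altloc)
  at2 <- atoms[ord, , drop = FALSE]
  keep <- !duplicated(key[ord])
  at2 <- at2[keep, , drop = FALSE]
  at2[order(at2$model_num, match(at2$chain_id, unique(atoms$chain_id)), at2$serial), ,
      drop = FALSE]
}

chain_type_table <- function(atoms) {
  a1 <- atoms[atoms$model_num == min(atoms$model_num) & atoms$is_polymer & !atoms$is_h, ,
              drop = FALSE]
  chains <- unique(a1$chain_id)
  if (!length(chains))
    return(data.frame(chain_id = character(0), polymer_type = character(0),
                      length = integer(0), stringsAsFactors = FALSE))
  rows <- lapply(chains, function(ch) {
    res <- unique(a1[a1$chain_id == ch, c("seq_id", "ins_code", "comp_id")])
    data.frame(chain_id = ch,
               polymer_type = classify_residues(res$comp_id),
               length = nrow(res), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

## Operator expressions ------------------------------------------------------

# Parse an mmCIF oper_expression into a list of operator-id chains.
# Supported grammar: "1" | "1,2,5" | "1-60" | "(1-60)(61)" (max two factors).
parse_oper_expression <- function(expr) {
  expr <- gsub("[[:space:]]", "", expr)
  if (grepl("^\\(", expr)) {
    m <- gregexpr("\\(([^()]*)\\)", expr)[[1]]
    factors <- regmatches(expr, list(m))[[1]]
    if (paste(factors, collapse = "") != expr)
      stopf("unsupported oper_expression grammar: '%s'", expr)
    if (length(factors) > 2L)
      stopf("unsupported oper_expression: more than two parenthesized factors in '%s'", expr)
    factors <- lapply(factors, function(f) parse_oper_factor(substr(f, 2, nchar(f) - 1L)))
    if (length(factors) == 1L) return(as.list(factors[[1]]))
    out <- list()
    for (f1 in factors[[1]]) for (f2 in factors[[2]]) out[[length(out) + 1L]] <- c(f1, f2)
    return(out)
  }
  as.list(parse_oper_factor(expr))
}

parse_oper_factor <- function(f) {
  if (f == "") stopf("empty operator selection in oper_expression")
  parts <- strsplit(f, ",", fixed = TRUE)[[1]]
  out <- character(0)
  for (p in parts) {
    if (grepl("^[0-9]+-[0-9]+$", p)) {
      ab <- as.integer(strsplit(p, "-", fixed = TRUE)[[1]])
      out <- c(out, as.character(seq(ab[1], ab[2])))
    } else if (nzchar(p)) {
      out <- c(out, p)
    } else stopf("empty operator id in oper_expression factor '%s'", f)
  }
  out
}

oper_homogeneous <- function(op) {
  M <- diag(4)
  M[1:3, 1:3] <- op$R
  M[1:3, 4] <- op$t
  M
}

# Compose an operator chain (ids, applied as the left-to-right matrix product)
compose_opers <- function(ids, operators) {
  M <- diag(4)
  for (id in ids) {
    op <- operators[[id]]
    if (is.null(op)) stopf("unknown oper_id '%s' referenced by assembly generator", id)
    M <- M %*% oper_homogeneous(op)
  }
  M
}

## Assembly construction -----------------------------------------------------

#' Generate biological assemblies from stored symmetry operators
#'
#' Applies each assembly definition's operator expressions (x' = R x + t;
#' parenthesized factors compose as matrix products) to the selected asym
#' units. Only the first model is used when several are present (NMR).
#' Modified residues are renamed to their standard parents for downstream
#' sequence/typing (coordinates untouched; the original \code{comp_id} is kept
#' in \code{orig_comp_id}). Chains duplicated by operators are renamed
#' deterministically as \code{<asym_id>-<oper chain>} and recorded in the
#' provenance table.
#'
#' @param st a \code{qs_structure} from \code{\link{parse_structure}}.
#' @param model_policy only \code{"first_model"} is supported.
#' @param fallback_identity if the file stores no assembly definitions,
#'   build one identity assembly (id \code{"1"}) over all chains.
#' @return list of \code{qs_assembly} objects with elements \code{pdb_id},
#'   \code{assembly_id}, \code{atoms}, \code{provenance}, \code{chain_types},
#'   \code{resolution}.
#' @export
build_assemblies <- function(st, model_policy = "first_model",
                             fallback_identity = TRUE) {
  stopifnot(inherits(st, "qs_structure"))
  model_policy <- match.arg(model_policy, "first_model")
  defs <- st$assembly_defs
  operators <- st$operators
  if (!length(defs)) {
    if (!fallback_identity) return(list())
    asyms <- unique(st$atoms$chain_id)
    defs <- list(list(assembly_id = "1",
                      generators = list(list(oper_expression = "1", asym_ids = asyms))))
    operators <- list(`1` = list(oper_id = "1", R = diag(3), t = numeric(3)))
  }
  atoms0 <- st$atoms[st$atoms$model_num == min(st$atoms$model_num), , drop = FALSE]
  lapply(defs, function(def) {
    gens <- def$generators
    # operator chains per asym, for duplication-aware renaming
    chains_per_asym <- list()
    parts <- list()
    for (gen in gens) {
      op_chains <- parse_oper_expression(gen$oper_expression)
      if (!length(gen$asym_ids)) stopf("empty generator selection in assembly '%s'", def$assembly_id)
      for (asym in gen$asym_ids)
        chains_per_asym[[asym]] <- c(chains_per_asym[[asym]] %||% character(0),
                                     vapply(op_chains, paste, character(1), collapse = "x"))
      parts[[length(parts) + 1L]] <- list(gen = gen, op_chains = op_chains)
    }
    out <- list(); prov <- list()
    for (part in parts) {
      sel <- atoms0[atoms0$chain_id %in% part$gen$asym_ids, , drop = FALSE]
      missing <- setdiff(part$gen$asym_ids, unique(atoms0$chain_id))
      if (length(missing))
        warnf("assembly '%s': asym id(s) %s have no atoms", def$assembly_id,
              paste(missing, collapse = ","))
      for (op_ids in part$op_chains) {
        key <- paste(op_ids, collapse = "x")
        M <- compose_opers(op_ids, operators)
        xyz <- cbind(sel$x, sel$y, sel$z, 1) %*% t(M)
        blk <- sel
        blk$x <- xyz[, 1]; blk$y <- xyz[, 2]; blk$z <- xyz[, 3]
        for (asym in intersect(part$gen$asym_ids, unique(sel$chain_id))) {
          dup <- length(chains_per_asym[[asym]]) > 1L
          new_id <- if (dup) paste0(asym, "-", key) else asym
          blk$chain_id[blk$chain_id == asym] <- new_id
          prov[[length(prov) + 1L]] <- data.frame(
            chain_id = new_id, source_asym = asym, oper_chain = key,
            stringsAsFactors = FALSE)
        }
        out[[length(out) + 1L]] <- blk
      }
    }
    atoms <- do.call(rbind, out)
    rownames(atoms) <- NULL
    atoms <- apply_mod_residues(atoms, st$mod_residues)
    prov <- do.call(rbind, prov)
    if (anyDuplicated(prov$chain_id))
      stopf("internal error: duplicate chain ids in assembly '%s'", def$assembly_id)
    asm <- list(pdb_id = st$pdb_id, assembly_id = def$assembly_id,
                atoms = atoms, provenance = prov,
                chain_types = chain_type_table(atoms),
                resolution = st$resolution)
    class(asm) <- "qs_assembly"
    asm
  })
}

apply_mod_residues <- function(atoms, mod) {
  if (is.null(mod) || !nrow(mod)) return(atoms)
  for (i in seq_len(nrow(mod))) {
    hit <- (atoms$auth_asym_id == mod$asym_id[i] |
              sub("-.*$", "", atoms$chain_id) == mod$asym_id[i]) &
      atoms$seq_id == mod$seq_id[i] & atoms$comp_id == mod$comp_id[i]
    if (any(hit)) {
      atoms$comp_id[hit] <- mod$parent_comp_id[i]
      atoms$is_polymer[hit] <- TRUE
    }
  }
  atoms
}

qs_atoms <- function(x) {
  if (inherits(x, "qs_structure") || inherits(x, "qs_assembly")) return(x$atoms)
  if (is.data.frame(x)) return(x)
  stopf("cannot extract atoms from object of class '%s'", class(x)[1])
}

#' @export
print.qs_assembly <- function(x, ...) {
  cat(sprintf("<qs_assembly> %s assembly %s: %d chains, %d atoms\n",
              x$pdb_id, x$assembly_id, length(unique(x$atoms$chain_id)),
              nrow(x$atoms)))
  invisible(x)
}

#' @export
print.qs_structure <- function(x, ...) {
  cat(sprintf("<qs_structure> %s (%s): %d atoms, %d chains, %d assembly definition(s)\n",
              x$pdb_id, x$format, nrow(x$atoms), length(unique(x$atoms$chain_id)),
              length(x$assembly_defs)))
  invisible(x)
}

## Writing -------------------------------------------------------------------

#' Write a structure or assembly to mmCIF or PDB
#'
#' PDB output refuses more than 62 chains (use \code{\link{split_for_pdb}});
#' chain identifiers longer than one character are remapped deterministically
#' to \code{[A-Za-z0-9]} in order of appearance (mapping returned as the
#' \code{chain_map} attribute).
#'
#' @param x a \code{qs_structure}, \code{qs_assembly} or atom data.frame.
#' @param path output path.
#' @param format \code{"mmcif"} or \code{"pdb"}.
#' @return \code{path}, invisibly.
#' @export
write_structure <- function(x, path, format = c("mmcif", "pdb")) {
  format <- match.arg(format)
  atoms <- qs_atoms(x)
  if (!nrow(atoms)) stopf("no atoms to write")
  if (format == "mmcif") return(write_mmcif_atoms(atoms, path,
                                                  block = toupper(if (is.list(x) && !is.null(x$pdb_id)) x$pdb_id else "QS")))
  chains <- unique(atoms$chain_id)
  if (length(chains) > 62L)
    stopf("PDB format supports at most 62 chains; got %d. Use split_for_pdb().",
          length(chains))
  write_pdb_atoms(atoms, path)
}

write_mmcif_atoms <- function(atoms, path, block = "QS") {
  n <- nrow(atoms)
  fmt <- function(v) formatC(v, format = "f", digits = 4)
  as <- data.frame(
    group_PDB = ifelse(atoms$is_hetatm, "HETATM", "ATOM"),
    id = if (all(!is.na(atoms$serial))) atoms$serial else seq_len(n),
    type_symbol = atoms$element,
    label_atom_id = atoms$name,
    label_alt_id = ifelse(atoms$altloc == "", ".", atoms$altloc),
    label_comp_id = atoms$comp_id,
    label_asym_id = atoms$chain_id,
    label_entity_id = ifelse(is.na(atoms$entity_id), ".", atoms$entity_id),
    label_seq_id = atoms$seq_id,
    pdbx_PDB_ins_code = ifelse(atoms$ins_code == "", "?", atoms$ins_code),
    Cartn_x = fmt(atoms$x), Cartn_y = fmt(atoms$y), Cartn_z = fmt(atoms$z),
    occupancy = formatC(atoms$occupancy, format = "f", digits = 2),
    B_iso_or_equiv = formatC(atoms$bfactor, format = "f", digits = 2),
    auth_seq_id = atoms$seq_id,
    auth_comp_id = atoms$comp_id,
    auth_asym_id = atoms$chain_id,
    auth_atom_id = atoms$name,
    pdbx_PDB_model_num = atoms$model_num,
    stringsAsFactors = FALSE
  )
  cats <- list(entry = data.frame(id = block, stringsAsFactors = FALSE),
               atom_site = as)
  write_cif(cats, path, block = block)
  invisible(path)
}

pdb_atom_name <- function(name, element) {
  # standard alignment: 1-char elements indent one column
  ifelse(nchar(name) >= 4L, substr(name, 1, 4),
         ifelse(nchar(element) == 1L, sprintf(" %-3s", name), sprintf("%-4s", name)))
}

write_pdb_atoms <- function(atoms, path) {
  chains <- unique(atoms$chain_id)
  map <- stats::setNames(chains, chains)
  if (any(nchar(chains) > 1L)) map[] <- PDB_CHAIN_IDS[seq_along(chains)]
  con <- file(path, "w")
  on.exit(close(con))
  models <- sort(unique(atoms$model_num))
  serial <- 0L
  for (m in models) {
    if (length(models) > 1L) writeLines(sprintf("MODEL     %4d", m), con)
    am <- atoms[atoms$model_num == m, , drop = FALSE]
    for (ch in intersect(chains, unique(am$chain_id))) {
      ac <- am[am$chain_id == ch, , drop = FALSE]
      for (i in seq_len(nrow(ac))) {
        serial <- serial + 1L
        writeLines(sprintf("%-6s%5d %s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                           ifelse(ac$is_hetatm[i], "HETATM", "ATOM"),
                           serial %% 100000L,
                           pdb_atom_name(ac$name[i], ac$element[i]),
                           substr(ac$altloc[i], 1, 1),
                           substr(ac$comp_id[i], 1, 3), map[[ch]],
                           ac$seq_id[i] %% 10000L, substr(ac$ins_code[i], 1, 1),
                           ac$x[i], ac$y[i], ac$z[i],
                           ac$occupancy[i], ac$bfactor[i], ac$element[i]), con)
      }
      serial <- serial + 1L
      writeLines(sprintf("TER   %5d      %3s %1s", serial %% 100000L,
                         ac$comp_id[nrow(ac)], map[[ch]]), con)
    }
    if (length(models) > 1L) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  out <- path
  attr(out, "chain_map") <- map
  invisible(out)
}

parse_pdb <- function(path) {
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  is_atom <- rec %in% c("ATOM  ", "HETATM")
  model_of <- rep(1L, length(lines))
  is_model <- startsWith(lines, "MODEL")
  if (any(is_model)) {
    cur_model <- 1L
    for (i in seq_along(lines)) {
      if (is_model[i]) {
        m <- suppressWarnings(as.integer(substr(lines[i], 11, 14)))
        cur_model <- if (is.na(m)) cur_model + 1L else m
      }
      model_of[i] <- cur_model
    }
  }
  al <- lines[is_atom]
  if (!length(al)) stopf("PDB parse error: no ATOM/HETATM records in '%s'", path)
  f <- function(a, b) trimws(substr(al, a, b))
  x <- suppressWarnings(as.numeric(f(31, 38)))
  y <- suppressWarnings(as.numeric(f(39, 46)))
  z <- suppressWarnings(as.numeric(f(47, 54)))
  if (anyNA(x) || anyNA(y) || anyNA(z))
    stopf("PDB parse error: missing or malformed coordinates in '%s'", path)
  element <- toupper(f(77, 78))
  name <- f(13, 16)
  noel <- element == ""
  element[noel] <- substr(gsub("[^A-Za-z].*$", "", name[noel]), 1, 1)
  occ <- suppressWarnings(as.numeric(f(55, 60))); occ[is.na(occ)] <- 1
  bf <- suppressWarnings(as.numeric(f(61, 66))); bf[is.na(bf)] <- 0
  atoms <- data.frame(
    serial = suppressWarnings(as.integer(f(7, 11))),
    name = name, altloc = f(17, 17),
    comp_id = toupper(f(18, 20)),
    chain_id = f(22, 22), auth_asym_id = f(22, 22),
    entity_id = NA_character_,
    seq_id = suppressWarnings(as.integer(f(23, 26))),
    ins_code = f(27, 27),
    x = x, y = y, z = z, occupancy = occ, bfactor = bf,
    element = element,
    is_hetatm = substr(al, 1, 6) == "HETATM",
    model_num = model_of[is_atom],
    stringsAsFactors = FALSE
  )
  atoms$is_polymer <- heuristic_polymer(atoms)
  atoms$is_water <- atoms$comp_id %in% WATER_IDS
  atoms$is_h <- atoms$element %in% c("H", "D")
  atoms$orig_comp_id <- atoms$comp_id
  list(pdb_id = tolower(tools::file_path_sans_ext(basename(path))),
       atoms = atoms, assembly_defs = list(), operators = list(),
       mod_residues = parse_mod_residues(NULL), resolution = NA_real_)
}

## Oversized-structure splitting ---------------------------------------------

#' Split a >62-chain assembly into multiple PDB files with a chain-ID map
#'
#' Chains (in order of first appearance) are chunked into groups of at most
#' 62; each file renames its chains to single characters drawn from
#' \code{[A-Z a-z 0-9]} in deterministic order. The mapping table has one row
#' per chain: original ID, file index (1-based) and new ID.
#'
#' @param x assembly (or atom data.frame).
#' @param dir output directory (created if needed).
#' @param base file-name stem.
#' @param max_chains capacity per file (62 for legacy PDB).
#' @return list with \code{files} (paths) and \code{map} (data.frame
#'   \code{orig_chain}, \code{file_index}, \code{new_chain}); the map is also
#'   written as \code{<base>_chain_map.tsv}.
#' @export
split_for_pdb <- function(x, dir = tempdir(), base = "structure", max_chains = 62L) {
  atoms <- qs_atoms(x)
  chains <- unique(atoms$chain_id)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  idx <- split(seq_along(chains), ceiling(seq_along(chains) / max_chains))
  files <- character(0)
  map <- list()
  for (k in seq_along(idx)) {
    sel_chains <- chains[idx[[k]]]
    new_ids <- PDB_CHAIN_IDS[seq_along(sel_chains)]
    sub <- atoms[atoms$chain_id %in% sel_chains, , drop = FALSE]
    sub$chain_id <- new_ids[match(sub$chain_id, sel_chains)]
    f <- file.path(dir, sprintf("%s_part%d.pdb", base, k))
    write_pdb_atoms(sub, f)
    files <- c(files, f)
    map[[k]] <- data.frame(orig_chain = sel_chains, file_index = k,
                           new_chain = new_ids, stringsAsFactors = FALSE)
  }
  map <- do.call(rbind, map)
  mf <- file.path(dir, sprintf("%s_chain_map.tsv", base))
  utils::write.table(map, mf, sep = "\t", quote = FALSE, row.names = FALSE)
  list(files = files, map = map, map_file = mf)
}

#' Convert between mmCIF and PDB formats
#'
#' Detects the input format and writes the other one. Structures with more
#' than 62 chains are split into multiple PDB files with a chain-ID map.
#'
#' @param path_in input structure file.
#' @param path_out output file (for the split case, treated as a stem).
#' @return output path(s), invisibly.
#' @export
convert_structure <- function(path_in, path_out) {
  st <- parse_structure(path_in)
  to <- if (st$format == "mmcif") "pdb" else "mmcif"
  if (to == "pdb" && length(unique(st$atoms$chain_id)) > 62L) {
    res <- split_for_pdb(st, dir = dirname(path_out),
                         base = tools::file_path_sans_ext(basename(path_out)))
    return(invisible(res$files))
  }
  write_structure(st, path_out, format = to)
  invisible(path_out)
}
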