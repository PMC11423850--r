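## Binding residues, solvent-accessible surface area and buried interface
## area. All geometry ignores hydrogens; distances are in angstrom, areas in
## square angstrom.

.qs_cache <- new.env(parent = emptyenv())

#' Van der Waals radii table
#'
#' Bondi (1964) radii shipped with the package; elements not in the table
#' fall back to \code{default} (1.70, the carbon radius) with a one-time
#' message per call.
#'
#' @param path optional replacement TSV with columns \code{element},
#'   \code{radius}.
#' @param default radius for unknown elements (angstrom).
#' @return named numeric vector with attribute \code{default}.
#' @export
default_radii <- function(path = NULL, default = 1.70) {
  if (is.null(path)) {
    if (is.null(.qs_cache$radii)) {
      f <- system.file("extdata", "vdw_radii_bondi.tsv", package = "quatsite")
      tb <- utils::read.table(f, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
      .qs_cache$radii <- stats::setNames(tb$radius, toupper(tb$element))
    }
    r <- .qs_cache$radii
  } else {
    tb <- utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
    r <- stats::setNames(tb$radius, toupper(tb$element))
  }
  if (any(r <= 0.5 | r >= 3.0)) stopf("van der Waals radii must lie in (0.5, 3.0) angstrom")
  attr(r, "default") <- default
  r
}

atom_radii <- function(elements, radii) {
  out <- unname(radii[toupper(elements)])
  miss <- is.na(out)
  if (any(miss)) out[miss] <- attr(radii, "default") %||% 1.70
  out
}

strip_h <- function(atoms) {
  if ("is_h" %in% names(atoms)) atoms[!atoms$is_h, , drop = FALSE]
  else atoms[!toupper(atoms$element) %in% c("H", "D"), , drop = FALSE]
}

## Spatial grid --------------------------------------------------------------

grid_build <- function(xyz, cell) {
  keys <- paste(floor(xyz[, 1] / cell), floor(xyz[, 2] / cell),
                floor(xyz[, 3] / cell), sep = "_")
  split(seq_len(nrow(xyz)), keys)
}

grid_neighbors <- function(grid, p, cell) {
  i0 <- floor(p[1] / cell); j0 <- floor(p[2] / cell); k0 <- floor(p[3] / cell)
  out <- integer(0)
  for (di in -1:1) for (dj in -1:1) for (dk in -1:1) {
    key <- paste(i0 + di, j0 + dj, k0 + dk, sep = "_")
    idx <- grid[[key]]
    if (!is.null(idx)) out <- c(out, idx)
  }
  out
}

## Binding residues ----------------------------------------------------------

#' Find receptor residues binding a ligand
#'
#' A residue binds when any of its atoms lies strictly closer to any ligand
#' atom than the sum of the two van der Waals radii plus \code{margin}
#' (default 0.5 angstrom). Uses a spatial grid; equals the all-pairs
#' computation (\code{\link{binding_residues_bruteforce}}) by construction.
#' Hydrogens are excluded.
#'
#' @param receptor_atoms,ligand_atoms atom data.frames (non-empty).
#' @param radii radii table from \code{\link{default_radii}}.
#' @param margin additive distance margin in angstrom.
#' @return object of class \code{qs_site}: \code{residues} data.frame
#'   (chain_id, seq_id, comp_id, min_dist) sorted by (chain_id, seq_id), and
#'   \code{n_chains_involved}.
#' @export
find_binding_residues <- function(receptor_atoms, ligand_atoms,
                                  radii = default_radii(), margin = 0.5) {
  ra <- strip_h(receptor_atoms); la <- strip_h(ligand_atoms)
  if (!nrow(ra) || !nrow(la)) stopf("empty atom set in binding-residue search")
  r_rec <- atom_radii(ra$element, radii)
  r_lig <- atom_radii(la$element, radii)
  cell <- 2 * max(c(r_rec, r_lig)) + margin
  lig_xyz <- cbind(la$x, la$y, la$z)
  grid <- grid_build(lig_xyz, cell)
  n <- nrow(ra)
  hit <- logical(n)
  mind <- rep(Inf, n)
  rec_xyz <- cbind(ra$x, ra$y, ra$z)
  for (i in seq_len(n)) {
    idx <- grid_neighbors(grid, rec_xyz[i, ], cell)
    if (!length(idx)) next
    d <- sqrt(colSums((t(lig_xyz[idx, , drop = FALSE]) - rec_xyz[i, ])^2))
    thr <- r_rec[i] + r_lig[idx] + margin
    if (any(d < thr)) hit[i] <- TRUE
    mind[i] <- min(mind[i], min(d))
  }
  site_from_hits(ra, hit, mind)
}

site_from_hits <- function(ra, hit, mind) {
  if (!any(hit)) {
    res <- data.frame(chain_id = character(0), seq_id = integer(0),
                      comp_id = character(0), min_dist = numeric(0),
                      stringsAsFactors = FALSE)
    return(structure(list(residues = res, n_chains_involved = 0L),
                     class = "qs_site"))
  }
  key <- paste(ra$chain_id, ra$seq_id, ra$ins_code, sep = "\r")
  hit_keys <- unique(key[hit])
  rows <- lapply(hit_keys, function(k) {
    sel <- key == k
    data.frame(chain_id = ra$chain_id[sel][1], seq_id = ra$seq_id[sel][1],
               comp_id = ra$comp_id[sel][1],
               min_dist = min(mind[sel]), stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res <- res[order(res$chain_id, res$seq_id), , drop = FALSE]
  rownames(res) <- NULL
  structure(list(residues = res,
                 n_chains_involved = length(unique(res$chain_id))),
            class = "qs_site")
}

#' All-pairs reference implementation of binding-residue detection
#'
#' Independent of the grid path; used as the equivalence oracle in tests.
#' @inheritParams find_binding_residues
#' @return a \code{qs_site} (same contract as
#'   \code{\link{find_binding_residues}}).
#' @export
binding_residues_bruteforce <- function(receptor_atoms, ligand_atoms,
                                        radii = default_radii(), margin = 0.5) {
  ra <- strip_h(receptor_atoms); la <- strip_h(ligand_atoms)
  if (!nrow(ra) || !nrow(la)) stopf("empty atom set in binding-residue search")
  r_rec <- atom_radii(ra$element, radii)
  r_lig <- atom_radii(la$element, radii)
  rec <- cbind(ra$x, ra$y, ra$z); lig <- cbind(la$x, la$y, la$z)
  d2 <- outer(rowSums(rec^2), rowSums(lig^2), `+`) - 2 * rec %*% t(lig)
  d <- sqrt(pmax(d2, 0))
  thr <- outer(r_rec, r_lig, `+`) + margin
  hit <- apply(d < thr, 1, any)
  mind <- apply(d, 1, min)
  site_from_hits(ra, hit, mind)
}

#' @export
print.qs_site <- function(x, ...) {
  cat(sprintf("<qs_site> %d binding residue(s) on %d chain(s)\n",
              nrow(x$residues), x$n_chains_involved))
  invisible(x)
}

## SASA ----------------------------------------------------------------------

golden_spiral <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- (seq_len(n) - 1) * pi * (3 - sqrt(5))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Deterministic golden-spiral point sampling on each solvent-extended
#' sphere (radius + probe); a point is accessible when it lies outside every
#' neighbouring extended sphere. Hydrogens are excluded.
#'
#' @param atoms atom data.frame with at least x, y, z, element.
#' @param radii radii table (\code{\link{default_radii}}).
#' @param probe probe radius in angstrom (default 1.4, water).
#' @param n_points sample points per atom (default 960).
#' @return list: \code{total} (square angstrom) and \code{per_atom} vector.
#' @export
compute_sasa <- function(atoms, radii = default_radii(), probe = 1.4,
                         n_points = 960L) {
  a <- strip_h(atoms)
  if (!nrow(a)) stopf("no non-hydrogen atoms for SASA")
  r <- atom_radii(a$element, radii) + probe
  xyz <- cbind(a$x, a$y, a$z)
  n <- nrow(a)
  pts <- golden_spiral(n_points)
  cell <- 2 * max(r)
  grid <- grid_build(xyz, cell)
  per_atom <- numeric(n)
  for (i in seq_len(n)) {
    cand <- grid_neighbors(grid, xyz[i, ], cell)
    cand <- cand[cand != i]
    if (length(cand)) {
      d <- sqrt(colSums((t(xyz[cand, , drop = FALSE]) - xyz[i, ])^2))
      cand <- cand[d < r[i] + r[cand]]
    }
    P <- pts * r[i]
    P <- sweep(P, 2, xyz[i, ], `+`)
    acc <- rep(TRUE, n_points)
    for (j in cand) {
      if (!any(acc)) break
      dj2 <- (P[, 1] - xyz[j, 1])^2 + (P[, 2] - xyz[j, 2])^2 +
        (P[, 3] - xyz[j, 3])^2
      acc <- acc & (dj2 >= r[j]^2)
    }
    per_atom[i] <- 4 * pi * r[i]^2 * sum(acc) / n_points
  }
  list(total = sum(per_atom), per_atom = per_atom)
}

#' Buried interface area between receptor and ligand
#'
#' S = (S_prot + S_lig - S_com) / 2, where the three terms are the
#' solvent-accessible surface areas of the receptor alone, the ligand alone
#' and the complex, computed with identical parameters. Symmetric in the two
#' roles.
#'
#' @inheritParams find_binding_residues
#' @inheritParams compute_sasa
#' @return object of class \code{qs_interface}: \code{S}, \code{S_prot},
#'   \code{S_lig}, \code{S_com} (square angstrom).
#' @export
interface_area <- function(receptor_atoms, ligand_atoms,
                           radii = default_radii(), probe = 1.4,
                           n_points = 960L) {
  ra <- strip_h(receptor_atoms); la <- strip_h(ligand_atoms)
  cols <- intersect(names(ra), names(la))
  s_prot <- compute_sasa(ra, radii, probe, n_points)$total
  s_lig <- compute_sasa(la, radii, probe, n_points)$total
  s_com <- compute_sasa(rbind(ra[, cols, drop = FALSE], la[, cols, drop = FALSE]),
                        radii, probe, n_points)$total
  structure(list(S = (s_prot + s_lig - s_com) / 2,
                 S_prot = s_prot, S_lig = s_lig, S_com = s_com,
                 probe = probe, n_points = n_points,
                 backend = "builtin_shrake_rupley"),
            class = "qs_interface")
}

#' @export
print.qs_interface <- function(x, ...) {
  cat(sprintf("<qs_interface> S = %.2f A^2 (S_prot %.2f, S_lig %.2f, S_com %.2f)\n",
              x$S, x$S_prot, x$S_lig, x$S_com))
  invisible(x)
}
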