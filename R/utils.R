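#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

## Residue dictionaries ------------------------------------------------------

# 20 standard amino acids, three-letter -> one-letter
AA3TO1 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
  GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
  LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
  SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V"
)

STANDARD_AA  <- names(AA3TO1)
STANDARD_DNA <- c("DA", "DC", "DG", "DT", "DI", "DU")
STANDARD_RNA <- c("A", "C", "G", "U", "I")
STANDARD_NT  <- c(STANDARD_DNA, STANDARD_RNA)
WATER_IDS    <- c("HOH", "DOD", "WAT")

NT1 <- c(DA = "a", DC = "c", DG = "g", DT = "t", DI = "i", DU = "u",
         A = "a", C = "c", G = "g", U = "u", I = "i")

# Elements counted as metal/ion species when a non-polymer group has one atom.
# Alkali + alkaline earth + transition metals + common post-transition ions.
METAL_ELEMENTS <- c(
  "LI", "NA", "K", "RB", "CS",
  "BE", "MG", "CA", "SR", "BA",
  "SC", "TI", "V", "CR", "MN", "FE", "CO", "NI", "CU", "ZN",
  "Y", "ZR", "MO", "RU", "RH", "PD", "AG", "CD",
  "W", "RE", "OS", "IR", "PT", "AU", "HG",
  "AL", "GA", "IN", "TL", "SN", "PB", "BI"
)

seq3_to_1 <- function(comp_ids) {
  out <- AA3TO1[comp_ids]
  out[is.na(out)] <- "X"
  paste0(out, collapse = "")
}

## Union-find (path compression) for connected components --------------------

uf_new <- function(ids) {
  structure(list(parent = stats::setNames(ids, ids)), class = "qs_uf")
}

uf_find <- function(uf, x) {
  p <- uf$parent
  root <- x
  while (p[[root]] != root) root <- p[[root]]
  root
}

uf_union <- function(uf, a, b) {
  ra <- uf_find(uf, a); rb <- uf_find(uf, b)
  # deterministic: smaller id becomes the root
  if (ra == rb) return(uf)
  lo <- min(ra, rb); hi <- max(ra, rb)
  uf$parent[[hi]] <- lo
  uf
}

uf_components <- function(uf) {
  ids <- names(uf$parent)
  roots <- vapply(ids, function(i) uf_find(uf, i), character(1))
  split(ids, roots)
}

## Small numeric helpers -----------------------------------------------------

fmt_num <- function(x, digits = 3) formatC(x, format = "f", digits = digits)

# Pearson correlation without stats::cor NA fuss
pcc <- function(x, y) {
  sx <- stats::sd(x); sy <- stats::sd(y)
  if (sx == 0 || sy == 0) return(NA_real_)
  stats::cor(x, y)
}

# 62 legal single-character PDB chain identifiers, deterministic order
PDB_CHAIN_IDS <- c(LETTERS, letters, as.character(0:9))
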