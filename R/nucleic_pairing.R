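## Base-pair detection and DNA/RNA chain pairing.
##
## Chains are paired when they share at least `min_pairs` (default 3)
## inter-chain base pairs; a chain of 1-2 nucleotides keeps its pairing when
## all of its nucleotides are base-paired with the partner chain. Multi-chain
## nucleic ligands are the connected components of the accepted-edge graph.

WC_EDGE_ATOMS <- c("N1", "N3", "N6", "N4", "O6", "O4", "O2", "N2")

#' Detect base pairs geometrically
#'
#' Built-in detector (substituting for an external secondary-structure
#' program): a residue pair is accepted as a base pair when (a) at least
#' \code{min_contacts} atom pairs among the standard Watson-Crick edge atoms
#' (N1, N3, N6, N4, O6, O4, O2, N2) are within \code{hbond_max} angstrom,
#' (b) the C1'-C1' distance lies in \code{c1_range}, and (c) each nucleotide
#' joins at most one accepted pair (greedy by smallest mean contact
#' distance). Residues lacking base atoms are skipped with a warning.
#'
#' @param atoms atom data.frame (or \code{qs_assembly}/\code{qs_structure}).
#' @param chain_ids nucleic chain ids to consider (default: all chains
#'   classified dna/rna/na_hybrid).
#' @param hbond_max H-bond donor-acceptor cutoff in angstrom (default 3.5).
#' @param c1_range C1'-C1' distance window in angstrom (default c(8, 11.5)).
#' @param min_contacts minimum edge-atom contacts (default 2).
#' @return data.frame of class \code{qs_base_pairs}: chain_a, seq_a, comp_a,
#'   chain_b, seq_b, comp_b, inter_chain, n_contacts, mean_dist, source.
#' @export
detect_base_pairs <- function(atoms, chain_ids = NULL, hbond_max = 3.5,
                              c1_range = c(8.0, 11.5), min_contacts = 2L) {
  atoms <- qs_atoms(atoms)
  if (is.null(chain_ids)) {
    ct <- chain_type_table(atoms)
    chain_ids <- ct$chain_id[ct$polymer_type %in% c("dna", "rna", "na_hybrid")]
  }
  empty <- empty_base_pairs()
  a <- atoms[atoms$chain_id %in% chain_ids & atoms$is_polymer & !atoms$is_h, ,
             drop = FALSE]
  if (!nrow(a)) return(empty)
  key <- paste(a$chain_id, a$seq_id, a$ins_code, sep = "\r")
  res_keys <- unique(key)
  info <- list()
  for (k in res_keys) {
    ra <- a[key == k, , drop = FALSE]
    c1 <- ra[ra$name %in% c("C1'", "C1*"), c("x", "y", "z"), drop = FALSE]
    wc <- ra[ra$name %in% WC_EDGE_ATOMS, c("x", "y", "z"), drop = FALSE]
    if (nrow(c1) != 1L || !nrow(wc)) {
      warnf("residue %s %d of chain %s lacks base atoms; skipped for base pairing",
            ra$comp_id[1], ra$seq_id[1], ra$chain_id[1])
      next
    }
    info[[k]] <- list(chain = ra$chain_id[1], seq = ra$seq_id[1],
                      comp = ra$comp_id[1], c1 = as.numeric(c1[1, ]),
                      wc = as.matrix(wc))
  }
  if (length(info) < 2L) return(empty)
  ks <- names(info)
  cand <- list()
  for (i in seq_len(length(ks) - 1L)) {
    ri <- info[[ks[i]]]
    for (j in seq((i + 1L), length(ks))) {
      rj <- info[[ks[j]]]
      d_c1 <- sqrt(sum((ri$c1 - rj$c1)^2))
      if (d_c1 < c1_range[1] || d_c1 > c1_range[2]) next
      dd <- sqrt(outer(rowSums(ri$wc^2), rowSums(rj$wc^2), `+`) -
                   2 * ri$wc %*% t(rj$wc))
      contacts <- dd[dd < hbond_max]
      if (length(contacts) < min_contacts) next
      cand[[length(cand) + 1L]] <- data.frame(
        i = i, j = j, mean_dist = mean(contacts), n_contacts = length(contacts),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(cand)) return(empty)
  cand <- do.call(rbind, cand)
  cand <- cand[order(cand$mean_dist, cand$i, cand$j), , drop = FALSE]
  used <- logical(length(ks))
  rows <- list()
  for (r in seq_len(nrow(cand))) {
    i <- cand$i[r]; j <- cand$j[r]
    if (used[i] || used[j]) next
    used[i] <- used[j] <- TRUE
    ri <- info[[ks[i]]]; rj <- info[[ks[j]]]
    # canonical orientation: partner_a sorts first by (chain, seq), so the
    # pair set is invariant to atom input order
    if (rj$chain < ri$chain || (rj$chain == ri$chain && rj$seq < ri$seq)) {
      tmp <- ri; ri <- rj; rj <- tmp
    }
    rows[[length(rows) + 1L]] <- data.frame(
      chain_a = ri$chain, seq_a = ri$seq, comp_a = ri$comp,
      chain_b = rj$chain, seq_b = rj$seq, comp_b = rj$comp,
      inter_chain = ri$chain != rj$chain,
      n_contacts = cand$n_contacts[r], mean_dist = cand$mean_dist[r],
      source = "builtin_geometric", stringsAsFactors = FALSE)
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out <- out[order(out$chain_a, out$seq_a, out$chain_b, out$seq_b), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("qs_base_pairs", "data.frame")
  out
}

empty_base_pairs <- function() {
  out <- data.frame(chain_a = character(0), seq_a = integer(0),
                    comp_a = character(0), chain_b = character(0),
                    seq_b = integer(0), comp_b = character(0),
                    inter_chain = logical(0), n_contacts = integer(0),
                    mean_dist = numeric(0), source = character(0),
                    stringsAsFactors = FALSE)
  class(out) <- c("qs_base_pairs", "data.frame")
  out
}

#' Parse base pairs from DSSR output
#'
#' Accepts DSSR JSON (object with a \code{pairs} array whose elements carry
#' \code{nt1}/\code{nt2} ids like \code{"A.DT5"} or \code{"1:A.DT5"}) or a
#' plain-text listing with six whitespace-separated columns: chain_a seq_a
#' comp_a chain_b seq_b comp_b.
#'
#' @param path DSSR output file.
#' @param chain_ids optional chain inventory; pairs naming unknown chains
#'   raise an error.
#' @return \code{qs_base_pairs} data.frame with source \code{"dssr_parsed"}.
#' @export
parse_dssr_pairs <- function(path, chain_ids = NULL) {
  if (!file.exists(path)) stopf("file not found: '%s'", path)
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  rows <- NULL
  if (grepl("^[[:space:]]*\\{", txt)) {
    js <- tryCatch(jsonlite::fromJSON(txt, simplifyVector = FALSE),
                   error = function(e) stopf("unrecognized DSSR output: %s", conditionMessage(e)))
    pairs <- js$pairs %||% list()
    rows <- lapply(pairs, function(p) {
      a <- parse_dssr_nt(p$nt1); b <- parse_dssr_nt(p$nt2)
      data.frame(chain_a = a$chain, seq_a = a$seq, comp_a = a$comp,
                 chain_b = b$chain, seq_b = b$seq, comp_b = b$comp,
                 stringsAsFactors = FALSE)
    })
  } else {
    lines <- strsplit(txt, "\n")[[1]]
    lines <- trimws(lines)
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    rows <- lapply(lines, function(l) {
      f <- strsplit(l, "[[:space:]]+")[[1]]
      if (length(f) < 6L) stopf("unrecognized DSSR pair line: '%s'", l)
      data.frame(chain_a = f[1], seq_a = as.integer(f[2]), comp_a = f[3],
                 chain_b = f[4], seq_b = as.integer(f[5]), comp_b = f[6],
                 stringsAsFactors = FALSE)
    })
  }
  if (!length(rows)) {
    out <- empty_base_pairs()
    out$source <- character(0)
    return(out)
  }
  out <- do.call(rbind, rows)
  if (!is.null(chain_ids)) {
    bad <- setdiff(unique(c(out$chain_a, out$chain_b)), chain_ids)
    if (length(bad))
      stopf("DSSR pairs reference unknown chain id(s): %s", paste(bad, collapse = ", "))
  }
  out$inter_chain <- out$chain_a != out$chain_b
  out$n_contacts <- NA_integer_
  out$mean_dist <- NA_real_
  out$source <- "dssr_parsed"
  class(out) <- c("qs_base_pairs", "data.frame")
  out
}

parse_dssr_nt <- function(id) {
  id <- sub("^[^:]*:", "", id)  # drop model prefix "1:"
  m <- regmatches(id, regexec("^([^.]+)\\.([A-Za-z]+)(-?[0-9]+)$", id))[[1]]
  if (length(m) != 4L) stopf("cannot parse DSSR nucleotide id '%s'", id)
  list(chain = m[2], comp = toupper(m[3]), seq = as.integer(m[4]))
}

#' Group DNA/RNA chains into paired units
#'
#' An edge links chains i and j when they share at least \code{min_pairs}
#' inter-chain base pairs, or when one chain has at most two nucleotides all
#' of which are base-paired with nucleotides of the other chain. Groups are
#' the connected components of the accepted-edge graph; unpaired chains form
#' singleton groups.
#'
#' @param base_pairs a \code{qs_base_pairs} data.frame.
#' @param chains nucleic-chain inventory: list of \code{qs_chain} (named by
#'   chain id) or a named integer vector of chain lengths.
#' @param min_pairs minimum inter-chain base pairs (default 3).
#' @return object of class \code{qs_pairing}: \code{groups} (list of chain-id
#'   vectors, a partition), \code{edge_evidence} (data.frame chain_a,
#'   chain_b, n_pairs, accepted, rule).
#' @export
pair_chains <- function(base_pairs, chains, min_pairs = 3L) {
  lens <- if (is.list(chains)) vapply(chains, `[[`, integer(1), "length")
  else chains
  ids <- names(lens)
  if (is.null(ids)) stopf("chain inventory must be named")
  bad <- setdiff(unique(c(base_pairs$chain_a, base_pairs$chain_b)), ids)
  if (length(bad))
    stopf("base pairs reference chain(s) not in the inventory: %s",
          paste(bad, collapse = ", "))
  inter <- base_pairs[base_pairs$inter_chain, , drop = FALSE]
  # inter-chain pair counts per unordered chain pair
  if (nrow(inter)) {
    ca <- pmin(inter$chain_a, inter$chain_b)
    cb <- pmax(inter$chain_a, inter$chain_b)
    cnt <- table(paste(ca, cb, sep = "\r"))
  } else cnt <- table(character(0))
  evidence <- list()
  uf <- uf_new(ids)
  for (k in names(cnt)) {
    p <- strsplit(k, "\r", fixed = TRUE)[[1]]
    n <- as.integer(cnt[[k]])
    accepted <- n >= min_pairs
    rule <- if (accepted) sprintf(">=%d inter-chain pairs", min_pairs) else ""
    if (!accepted) {
      # 1-2-nt special case, either direction
      for (ord in list(c(p[1], p[2]), c(p[2], p[1]))) {
        short <- ord[1]; long <- ord[2]
        if (lens[[short]] <= 2L && all_nt_paired_with(base_pairs, short, long, lens[[short]])) {
          accepted <- TRUE
          rule <- "1-2-nt chain fully paired"
          break
        }
      }
    }
    if (accepted) uf <- uf_union(uf, p[1], p[2])
    evidence[[length(evidence) + 1L]] <- data.frame(
      chain_a = p[1], chain_b = p[2], n_pairs = n, accepted = accepted,
      rule = rule, stringsAsFactors = FALSE)
  }
  groups <- unname(uf_components(uf))
  groups <- groups[order(vapply(groups, min, character(1)))]
  ev <- if (length(evidence)) do.call(rbind, evidence)
  else data.frame(chain_a = character(0), chain_b = character(0),
                  n_pairs = integer(0), accepted = logical(0),
                  rule = character(0), stringsAsFactors = FALSE)
  structure(list(groups = groups, edge_evidence = ev, min_pairs = min_pairs),
            class = "qs_pairing")
}

# TRUE when every nucleotide of `short` appears in a base pair whose partner
# belongs to `long`.
all_nt_paired_with <- function(base_pairs, short, long, short_len) {
  pa <- base_pairs[base_pairs$chain_a == short & base_pairs$chain_b == long,
                   "seq_a"]
  pb <- base_pairs[base_pairs$chain_b == short & base_pairs$chain_a == long,
                   "seq_b"]
  length(unique(c(pa, pb))) >= short_len
}

#' @export
print.qs_pairing <- function(x, ...) {
  cat(sprintf("<qs_pairing> %d group(s): %s\n", length(x$groups),
              paste(vapply(x$groups, paste, character(1), collapse = "+"),
                    collapse = " | ")))
  invisible(x)
}

# Export the pairing report as TSV
write_pairing_report <- function(pairing, path) {
  utils::write.table(pairing$edge_evidence, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
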