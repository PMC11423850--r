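# Shared fixture helpers. Fixtures are generated into a per-session temp dir
# and cached by (kind, seed, params) so repeated tests reuse the same files.

.fx_cache <- new.env(parent = emptyenv())

fx <- function(kind, seed = 1L, params = list()) {
  key <- paste(kind, seed, paste(deparse(params), collapse = ""), sep = "|")
  if (is.null(.fx_cache[[key]])) {
    dir <- file.path(tempdir(), "quatsite-fixtures")
    .fx_cache[[key]] <- make_structure_fixture(kind, seed = seed, dir = dir,
                                               params = params)
  }
  .fx_cache[[key]]
}

fx_structure <- function(kind, seed = 1L, params = list()) {
  parse_structure(fx(kind, seed, params)$path)
}

fx_assembly <- function(kind, seed = 1L, params = list()) {
  build_assemblies(fx_structure(kind, seed, params))[[1]]
}

# Minimal synthetic entry for corpus-summary tests (planted counts)
make_fake_entry <- function(id, category = "relevant", state = 1L,
                            stoich = "A", n_chains_involved = 1L,
                            kind = "small_molecule") {
  receptor <- structure(list(chains = vector("list", state),
                             oligomeric_state = state,
                             stoichiometry = stoich), class = "qs_receptor")
  structure(list(entry_id = id, pdb_id = "fake", assembly_id = "1",
                 receptor = receptor, stoichiometry = stoich,
                 ligand = structure(list(kind = kind, ligand_id = "FAK",
                                         chains = "L"), class = "qs_ligand"),
                 site = structure(list(residues = data.frame(),
                                       n_chains_involved = n_chains_involved),
                                  class = "qs_site"),
                 verdict = NULL, interface = NULL, affinity = NULL,
                 category = category, resolution = NA_real_, assembly = NULL),
            class = "qs_entry")
}

# Independent connected-components oracle: boolean reachability by repeated
# squaring of the adjacency matrix.
components_oracle <- function(ids, edges) {
  n <- length(ids)
  A <- diag(n) > 0
  rownames(A) <- colnames(A) <- ids
  for (k in seq_len(nrow(edges))) {
    A[edges$chain_a[k], edges$chain_b[k]] <- TRUE
    A[edges$chain_b[k], edges$chain_a[k]] <- TRUE
  }
  repeat {
    A2 <- (A %*% A) > 0
    if (identical(A2, A)) break
    A <- A2
  }
  groups <- unique(apply(A, 1, function(r) paste(sort(ids[r]), collapse = "+")))
  sort(groups)
}

groups_as_strings <- function(groups) {
  sort(vapply(groups, function(g) paste(sort(g), collapse = "+"), character(1)))
}

# random protein-like sequence
rand_seq <- function(n, alphabet = c("A", "C", "D", "E", "F", "G", "H", "I")) {
  paste0(sample(alphabet, n, replace = TRUE), collapse = "")
}
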