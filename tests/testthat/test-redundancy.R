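# redundancy: greedy chain clustering and oligomer-aware deduplication

# independent exhaustive re-implementation of the greedy rule (plain loops,
# no shared code with cluster_chains)
greedy_oracle <- function(seqs, thr) {
  ord <- order(-nchar(seqs), names(seqs))
  reps <- character(0)
  out <- character(length(seqs))
  names(out) <- names(seqs)
  for (k in ord) {
    hit <- NA_character_
    for (r in reps) {
      if (pairwise_identity(seqs[[k]], seqs[[r]]) > thr) { hit <- r; break }
    }
    if (is.na(hit)) { reps <- c(reps, names(seqs)[k]); hit <- names(seqs)[k] }
    out[[names(seqs)[k]]] <- hit
  }
  out
}

test_that("clustering degenerate cases", {
  s <- c(a = "MKVLAT", b = "MKVLAT", c = "MKVLAT")
  cl <- cluster_chains(s)
  expect_equal(length(unique(cl$cluster)), 1L)
  far <- c(a = "AAAAAAAA", b = "CCCCCCCC", c = "DDDDDDDD")
  expect_equal(length(unique(cluster_chains(far)$cluster)), 3L)
  expect_error(cluster_chains(character(0)), "at least one")
})

test_that("20-sequence clustering equals the exhaustive oracle", {
  set.seed(21)
  base <- rand_seq(40)
  seqs <- character(20)
  for (i in 1:20) {
    s <- strsplit(base, "")[[1]]
    nmut <- sample(0:12, 1)
    pos <- sample(40, nmut)
    s[pos] <- sample(c("K", "L", "M", "N"), nmut, replace = TRUE)
    seqs[i] <- paste0(s, collapse = "")
  }
  names(seqs) <- sprintf("s%02d", 1:20)
  cl <- cluster_chains(seqs, 0.9)
  oracle <- greedy_oracle(seqs, 0.9)
  expect_equal(stats::setNames(cl$representative, cl$id), oracle[cl$id])
})

mk_struct <- function(id, chains, resolution = NA_real_) {
  list(id = id, chains = chains, resolution = resolution)
}

test_that("identical structures collapse; oligomeric states never merge", {
  set.seed(4)
  sq <- rand_seq(50)
  dimer1 <- mk_struct("d1", c(A = sq, B = sq), resolution = 2.0)
  dimer2 <- mk_struct("d2", c(A = sq, B = sq), resolution = 1.5)
  res <- deduplicate_structures(list(dimer1, dimer2))
  expect_equal(res$retained, "d2")   # better resolution wins
  mono <- mk_struct("m1", c(A = sq))
  res2 <- deduplicate_structures(list(dimer1, mono))
  expect_setequal(res2$retained, c("d1", "m1"))
  expect_equal(sort(unique(res2$clusters$oligomeric_state)), c(1L, 2L))
})

test_that("planted similarity graph equals the transitive-closure oracle", {
  set.seed(7)
  # 10 monomers built from 3 sequence families (within-family identity 1,
  # across-family identity << 0.9)
  fams <- c(rand_seq(40, LETTERS[1:6]), rand_seq(40, LETTERS[7:12]),
            rand_seq(40, LETTERS[13:18]))
  fam_of <- c(1, 1, 1, 2, 2, 3, 3, 3, 3, 2)
  structs <- lapply(1:10, function(i)
    mk_struct(sprintf("s%02d", i), c(A = fams[fam_of[i]])))
  res <- deduplicate_structures(structs)
  ids <- vapply(structs, `[[`, character(1), "id")
  edges <- do.call(rbind, lapply(1:9, function(i) do.call(rbind, lapply((i + 1):10, function(j)
    if (pairwise_identity(fams[fam_of[i]], fams[fam_of[j]]) > 0.9)
      data.frame(chain_a = ids[i], chain_b = ids[j])))))
  oracle <- components_oracle(ids, edges)
  got <- sort(vapply(split(res$clusters$structure_id, res$clusters$representative),
                     function(g) paste(sort(g), collapse = "+"), character(1)))
  expect_equal(unname(got), oracle)
  # exactly one representative per family
  expect_equal(length(res$retained), 3L)
  # no retained pair is redundant under the rule
  for (i in seq_along(res$retained)) for (j in seq_along(res$retained)) {
    if (i >= j) next
    a <- structs[[which(ids == res$retained[i])]]
    b <- structs[[which(ids == res$retained[j])]]
    expect_lte(pairwise_identity(a$chains[[1]], b$chains[[1]]), 0.9)
  }
})

test_that("dedup is order-invariant and monotone in the threshold", {
  set.seed(8)
  sq1 <- rand_seq(30); sq2 <- rand_seq(30)
  structs <- list(mk_struct("a", c(X = sq1)), mk_struct("b", c(X = sq1)),
                  mk_struct("c", c(X = sq2)))
  r1 <- deduplicate_structures(structs)
  r2 <- deduplicate_structures(rev(structs))
  expect_equal(r1$retained, r2$retained)
  expect_lte(length(r1$retained), length(structs))
  lo <- deduplicate_structures(structs, threshold = 0.5)
  expect_lte(length(lo$retained), length(r1$retained))
})

test_that("structure mode requires an adapter; uses it when given", {
  s <- list(mk_struct("a", c(X = "AAAA")), mk_struct("b", c(X = "CCCC")))
  expect_error(deduplicate_structures(s, mode = "structure"),
               "similarity table")
  sim <- data.frame(chain_a = "a:X", chain_b = "b:X", score = 0.95)
  res <- deduplicate_structures(s, mode = "structure", similarity = sim)
  expect_length(res$retained, 1L)   # merged by adapter score despite 0 identity
})
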