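## Non-redundant dataset construction: greedy chain-level sequence clustering
## and oligomer-aware structure deduplication (structures compared only within
## the same oligomeric state; any chain pair above the similarity threshold
## makes two structures redundant).

#' Greedy incremental chain clustering by sequence identity
#'
#' Sequences are sorted by descending length (ties by name); each joins the
#' first existing cluster whose representative it matches with identity
#' above \code{identity_threshold} (via \code{\link{pairwise_identity}}),
#' otherwise it founds a new cluster. Deterministic.
#'
#' @param sequences named character vector of sequences.
#' @param identity_threshold default 0.9.
#' @return data.frame: \code{id}, \code{representative}, \code{cluster}
#'   (integer index in founding order).
#' @export
cluster_chains <- function(sequences, identity_threshold = 0.9) {
  if (!length(sequences)) stopf("need at least one sequence")
  ids <- names(sequences)
  if (is.null(ids)) ids <- as.character(seq_along(sequences))
  ord <- order(-nchar(sequences), ids)
  reps <- character(0)
  assign <- integer(length(sequences))
  names(assign) <- ids
  for (k in ord) {
    placed <- FALSE
    for (ci in seq_along(reps)) {
      if (pairwise_identity(sequences[[k]], sequences[[reps[ci]]]) > identity_threshold) {
        assign[[ids[k]]] <- ci
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      reps <- c(reps, ids[k])
      assign[[ids[k]]] <- length(reps)
    }
  }
  data.frame(id = ids, representative = reps[assign[ids]],
             cluster = assign[ids], row.names = NULL, stringsAsFactors = FALSE)
}

#' Deduplicate oligomeric structures by chain similarity
#'
#' Structures are grouped by oligomeric state (chain count); within a group,
#' two structures are redundant when any pair of chains (one from each)
#' exceeds the similarity threshold. The redundancy relation is made
#' transitive by connected components; one representative is retained per
#' component (best resolution when known, ties/unknowns by lowest id).
#'
#' @param structures list of entries, each a list with \code{id},
#'   \code{chains} (named character vector of chain sequences), optional
#'   \code{resolution}.
#' @param threshold similarity threshold (default 0.9), in (0, 1].
#' @param mode \code{"sequence"} (built-in identity) or \code{"structure"}
#'   (requires \code{similarity}).
#' @param similarity optional data.frame \code{chain_a}, \code{chain_b},
#'   \code{score} (chain keys \code{"<structure id>:<chain id>"}) from an
#'   external structure-alignment adapter; required for mode "structure".
#' @return list: \code{clusters} (data.frame structure_id, representative,
#'   oligomeric_state), \code{retained} (character vector of ids).
#' @export
deduplicate_structures <- function(structures, threshold = 0.9,
                                   mode = c("sequence", "structure"),
                                   similarity = NULL) {
  mode <- match.arg(mode)
  if (threshold <= 0 || threshold > 1) stopf("threshold must lie in (0, 1]")
  if (mode == "structure" && is.null(similarity))
    stopf("mode='structure' requires an external similarity table (structure_backend)")
  ids <- vapply(structures, `[[`, character(1), "id")
  if (anyDuplicated(ids)) stopf("duplicate structure ids")
  names(structures) <- ids
  states <- vapply(structures, function(s) length(s$chains), integer(1))
  sim_lookup <- NULL
  if (!is.null(similarity)) {
    sim_lookup <- stats::setNames(
      as.numeric(similarity$score),
      paste(similarity$chain_a, similarity$chain_b, sep = "\r"))
  }
  chain_sim <- function(sid_a, ka, seq_a, sid_b, kb, seq_b) {
    if (mode == "structure") {
      keys <- c(paste(paste0(sid_a, ":", ka), paste0(sid_b, ":", kb), sep = "\r"),
                paste(paste0(sid_b, ":", kb), paste0(sid_a, ":", ka), sep = "\r"))
      hit <- sim_lookup[keys]
      hit <- hit[!is.na(hit)]
      if (!length(hit)) return(0)
      return(max(hit))
    }
    pairwise_identity(seq_a, seq_b)
  }
  uf <- uf_new(ids)
  for (state in unique(states)) {
    grp <- ids[states == state]
    if (length(grp) < 2L) next
    for (i in seq_len(length(grp) - 1L)) {
      for (j in seq((i + 1L), length(grp))) {
        si <- structures[[grp[i]]]; sj <- structures[[grp[j]]]
        redundant <- FALSE
        for (ka in names(si$chains)) {
          for (kb in names(sj$chains)) {
            if (chain_sim(si$id, ka, si$chains[[ka]],
                          sj$id, kb, sj$chains[[kb]]) > threshold) {
              redundant <- TRUE; break
            }
          }
          if (redundant) break
        }
        if (redundant) uf <- uf_union(uf, grp[i], grp[j])
      }
    }
  }
  comps <- uf_components(uf)
  rows <- lapply(comps, function(members) {
    res <- vapply(members, function(m) structures[[m]]$resolution %||% NA_real_,
                  numeric(1))
    ord <- order(ifelse(is.na(res), Inf, res), members)
    rep_ <- members[ord[1]]
    data.frame(structure_id = sort(members), representative = rep_,
               oligomeric_state = states[[members[1]]],
               stringsAsFactors = FALSE)
  })
  clusters <- do.call(rbind, rows)
  rownames(clusters) <- NULL
  clusters <- clusters[order(clusters$representative, clusters$structure_id), ,
                       drop = FALSE]
  list(clusters = clusters, retained = sort(unique(clusters$representative)))
}
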