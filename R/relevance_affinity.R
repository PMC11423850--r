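## Biological-relevance assessment of ligands and binding-affinity handling
## (experimental-table ingestion, consensus OLS over three physics scores,
## bootstrap significance of the consensus improvement).

#' Read a crystallization-additive exclusion list
#'
#' Plain text, one chemical component ID per line, \code{#} comments. The
#' packaged default is a small synthetic stand-in for the full manually
#' curated additive list and can be replaced by any file in the same format.
#'
#' @param path list file; default: packaged synthetic list.
#' @return object of class \code{qs_exclusion}: \code{comp_ids} (uppercase),
#'   \code{source}, \code{checksum}.
#' @export
read_exclusion_list <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "exclusion_synthetic.txt", package = "quatsite")
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  ids <- toupper(lines[nzchar(lines)])
  bad <- ids[nchar(ids) > 5L]
  if (length(bad)) stopf("invalid component id(s) in exclusion list: %s",
                         paste(bad, collapse = ", "))
  structure(list(comp_ids = unique(ids), source = path,
                 checksum = unname(tools::md5sum(path))),
            class = "qs_exclusion")
}

#' Assess the biological relevance of a ligand
#'
#' Hierarchy: peptides and nucleic acids are relevant without assessment;
#' small molecules (and ions) outside the exclusion list are relevant by
#' default; listed molecules are judged by the size of their binding site on
#' the quaternary structure — fewer than \code{min_site_residues} binding
#' residues means irrelevant, otherwise the verdict is escalated to a
#' keyword check on caller-supplied abstract text (ligand name near binding
#' vocabulary in one sentence => relevant) or left as \code{needs_review}.
#' The single-chain-era occurrence-number and binding-residue-continuity
#' criteria are deliberately not applied.
#'
#' @param ligand a \code{qs_ligand}.
#' @param site the ligand's \code{qs_site} on the quaternary structure
#'   (required for small molecules / ions).
#' @param exclusion a \code{qs_exclusion}.
#' @param abstract_text optional abstract text for the keyword rule.
#' @param min_site_residues site-size threshold (default 6; a calibration
#'   choice, not a literature constant).
#' @param synonyms optional extra names for the ligand in the abstract.
#' @return object of class \code{qs_verdict}: \code{status} (relevant /
#'   irrelevant / needs_review), \code{rule_fired}, \code{evidence}.
#' @export
assess_relevance <- function(ligand, site = NULL,
                             exclusion = read_exclusion_list(),
                             abstract_text = NULL, min_site_residues = 6L,
                             synonyms = character(0)) {
  verdict <- function(status, rule, evidence)
    structure(list(status = status, rule_fired = rule, evidence = evidence),
              class = "qs_verdict")
  if (ligand$kind %in% c("peptide", "nucleic"))
    return(verdict("relevant", "peptide_or_nucleic",
                   "peptides and nucleic acids are relevant without assessment"))
  comp <- toupper(ligand$ligand_id)
  if (!comp %in% exclusion$comp_ids)
    return(verdict("relevant", "not_in_list",
                   sprintf("'%s' not in the additive exclusion list", comp)))
  if (is.null(site))
    stopf("binding site required to assess listed ligand '%s'", comp)
  n_res <- nrow(site$residues)
  if (n_res < min_site_residues)
    return(verdict("irrelevant", "site_size_rule",
                   sprintf("listed ligand with %d binding residue(s) < %d",
                           n_res, min_site_residues)))
  if (!is.null(abstract_text)) {
    if (keyword_match(abstract_text, c(comp, synonyms)))
      return(verdict("relevant", "keyword_rule",
                     sprintf("abstract links '%s' to binding vocabulary", comp)))
    return(verdict("needs_review", "keyword_rule",
                   sprintf("abstract given but no binding-vocabulary link for '%s'", comp)))
  }
  verdict("needs_review", "listed_default",
          sprintf("listed ligand with %d binding residue(s) >= %d; no abstract supplied",
                  n_res, min_site_residues))
}

BINDING_VOCAB <- c("bind", "binds", "binding", "bound", "inhibit", "inhibits",
                   "inhibitor", "inhibition", "substrate", "cofactor",
                   "co-factor", "activate", "activates", "activator",
                   "coordination", "coordinates")

# ligand name and binding vocabulary within the same sentence
keyword_match <- function(text, names) {
  sentences <- strsplit(tolower(text), "[.!?]")[[1]]
  names <- tolower(names[nzchar(names)])
  vocab_re <- paste0("\\b(", paste(BINDING_VOCAB, collapse = "|"), ")\\b")
  for (s in sentences) {
    if (!grepl(vocab_re, s)) next
    for (nm in names) {
      if (grepl(nm, s, fixed = TRUE)) return(TRUE)
    }
  }
  FALSE
}

#' @export
print.qs_verdict <- function(x, ...) {
  cat(sprintf("<qs_verdict> %s (%s): %s\n", x$status, x$rule_fired, x$evidence))
  invisible(x)
}

## Experimental affinities ---------------------------------------------------

UNIT_FACTORS <- c(M = 1, MM = 1e-3, UM = 1e-6, "µM" = 1e-6, NM = 1e-9,
                  PM = 1e-12, FM = 1e-15)

#' Read an experimental-affinity table
#'
#' TSV with header \code{pdb_id ligand_id chain measure value unit source}.
#' Kd/Ki/IC50 measurements in M, mM, uM, nM, pM or fM are normalized to the
#' pKd scale (-log10 of the molar value). Unparseable rows are collected in
#' a rejects report rather than failing the load.
#'
#' @param path TSV path.
#' @return list: \code{records} (data.frame with added \code{pkd} column),
#'   \code{rejects} (offending rows + reason).
#' @export
read_affinity_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, quote = "")
  need <- c("pdb_id", "ligand_id", "chain", "measure", "value", "unit", "source")
  if (!all(need %in% names(df)))
    stopf("affinity table must have header: %s", paste(need, collapse = "\t"))
  ok <- rep(TRUE, nrow(df)); why <- character(nrow(df)); pkd <- rep(NA_real_, nrow(df))
  for (i in seq_len(nrow(df))) {
    meas <- toupper(df$measure[i])
    unit <- toupper(df$unit[i])
    unit <- if (unit %in% c("µM", "µm")) "UM" else unit
    val <- suppressWarnings(as.numeric(df$value[i]))
    if (!meas %in% c("KD", "KI", "IC50")) { ok[i] <- FALSE; why[i] <- sprintf("unknown measure '%s'", df$measure[i]); next }
    if (!unit %in% names(UNIT_FACTORS)) { ok[i] <- FALSE; why[i] <- sprintf("unknown unit '%s'", df$unit[i]); next }
    if (is.na(val) || val <= 0) { ok[i] <- FALSE; why[i] <- sprintf("bad value '%s'", df$value[i]); next }
    pkd[i] <- -log10(val * UNIT_FACTORS[[unit]])
  }
  records <- df[ok, , drop = FALSE]
  records$pkd <- pkd[ok]
  records$raw <- sprintf("%s=%s%s", df$measure[ok], df$value[ok], df$unit[ok])
  rejects <- df[!ok, , drop = FALSE]
  if (nrow(rejects)) rejects$reason <- why[!ok]
  list(records = records, rejects = rejects)
}

#' Read a docking-score table
#'
#' TSV with header \code{pdb_id ligand_id x_xscore x_itscore x_vina}.
#' @param path TSV path.
#' @return data.frame.
#' @export
read_score_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("pdb_id", "ligand_id", "x_xscore", "x_itscore", "x_vina")
  if (!all(need %in% names(df)))
    stopf("score table must have header: %s", paste(need, collapse = "\t"))
  df
}

## Consensus affinity model --------------------------------------------------

#' Fit the consensus affinity regression
#'
#' Ordinary least squares with intercept over the three physics-based scores
#' (x_xscore, x_itscore, x_vina) against experimental pKd. Also reports the
#' in-sample Pearson correlation of the consensus fit and of each univariate
#' single-score fit.
#'
#' @param training data.frame with columns \code{x_xscore}, \code{x_itscore},
#'   \code{x_vina}, \code{pkd}; at least 10 complete rows.
#' @return object of class \code{qs_affinity_model}: \code{intercept},
#'   \code{weights} (named 3-vector), \code{n}, \code{pcc_consensus},
#'   \code{pcc_single} (named), \code{target_scale = "pKd"}.
#' @export
fit_consensus <- function(training) {
  feats <- c("x_xscore", "x_itscore", "x_vina")
  if (!all(c(feats, "pkd") %in% names(training)))
    stopf("training data needs columns %s", paste(c(feats, "pkd"), collapse = ", "))
  tr <- training[stats::complete.cases(training[, c(feats, "pkd")]), , drop = FALSE]
  if (nrow(tr) < 10L)
    stopf("need at least 10 complete training rows, got %d", nrow(tr))
  fit <- stats::lm(pkd ~ x_xscore + x_itscore + x_vina, data = tr)
  if (anyNA(stats::coef(fit)))
    stopf("rank-deficient design: drop a collinear score column and refit")
  co <- stats::coef(fit)
  pred <- stats::fitted(fit)
  pcc_single <- vapply(feats, function(f) {
    uni <- stats::lm(stats::reformulate(f, "pkd"), data = tr)
    pcc(stats::fitted(uni), tr$pkd)
  }, numeric(1))
  structure(list(intercept = unname(co[1]),
                 weights = co[feats],
                 n = nrow(tr),
                 pcc_consensus = pcc(pred, tr$pkd),
                 pcc_single = pcc_single,
                 target_scale = "pKd"),
            class = "qs_affinity_model")
}

#' Predict consensus affinity
#'
#' @param model a \code{qs_affinity_model}.
#' @param components named list/vector (or data.frame) with x_xscore,
#'   x_itscore, x_vina; all three required.
#' @return predicted pKd (numeric vector).
#' @export
predict_consensus <- function(model, components) {
  stopifnot(inherits(model, "qs_affinity_model"))
  feats <- names(model$weights)
  if (is.data.frame(components)) {
    if (!all(feats %in% names(components)))
      stopf("missing score component(s): %s",
            paste(setdiff(feats, names(components)), collapse = ", "))
    X <- as.matrix(components[, feats, drop = FALSE])
  } else {
    components <- unlist(components)
    if (!all(feats %in% names(components)) || anyNA(components[feats]))
      stopf("missing score component(s): %s",
            paste(setdiff(feats, names(components[!is.na(components)])), collapse = ", "))
    X <- matrix(components[feats], nrow = 1, dimnames = list(NULL, feats))
  }
  if (anyNA(X)) stopf("missing score component value(s)")
  as.numeric(model$intercept + X %*% model$weights)
}

#' @export
print.qs_affinity_model <- function(x, ...) {
  cat(sprintf("<qs_affinity_model> pKd ~ %.3f + %.3f*xscore + %.3f*itscore + %.3f*vina (n=%d, PCC=%.3f)\n",
              x$intercept, x$weights[1], x$weights[2], x$weights[3], x$n,
              x$pcc_consensus))
  invisible(x)
}

#' Bootstrap comparison of consensus vs single-score correlation
#'
#' Resamples rows with replacement \code{n_boot} times; for each single-score
#' prediction vector reports the mean PCC improvement of the consensus, the
#' 95 percent percentile confidence interval of the improvement, and whether
#' it is significant (CI excluding 0). Deterministic given \code{seed}.
#'
#' @param consensus_pred consensus predictions.
#' @param single_preds named list of single-score prediction vectors.
#' @param observed observed affinities (same length, n >= 30).
#' @param n_boot bootstrap replicates (default 1000).
#' @param seed RNG seed.
#' @return data.frame: comparison, delta_pcc_mean, ci_lo, ci_hi, significant.
#' @export
bootstrap_pcc_compare <- function(consensus_pred, single_preds, observed,
                                  n_boot = 1000L, seed = 1L) {
  n <- length(observed)
  if (n < 30L) stopf("need n >= 30 observations, got %d", n)
  for (nm in names(single_preds))
    if (length(single_preds[[nm]]) != n || length(consensus_pred) != n)
      stopf("prediction vector length mismatch for '%s'", nm)
  set.seed(seed)
  idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), nrow = n_boot)
  rows <- lapply(names(single_preds), function(nm) {
    sp <- single_preds[[nm]]
    delta <- vapply(seq_len(n_boot), function(b) {
      ii <- idx[b, ]
      pcc(consensus_pred[ii], observed[ii]) - pcc(sp[ii], observed[ii])
    }, numeric(1))
    delta <- delta[!is.na(delta)]
    ci <- stats::quantile(delta, c(0.025, 0.975), names = FALSE)
    data.frame(comparison = nm, delta_pcc_mean = mean(delta),
               ci_lo = ci[1], ci_hi = ci[2],
               significant = ci[1] > 0 || ci[2] < 0,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
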