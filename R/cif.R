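## Minimal PDBx/mmCIF (STAR) reader and writer.
##
## Scope: the categories this pipeline consumes (atom_site, entity,
## entity_poly, pdbx_struct_assembly*, pdbx_struct_oper_list,
## pdbx_struct_mod_residue, refine/exptl). Handles loop_ tables, quoted
## tokens and semicolon-delimited text blocks; one data block per file.

# Tokenize one physical line into CIF tokens (quoted strings kept intact,
# surrounding quotes stripped). '#' starts a comment at a token boundary.
cif_tokenize_line <- function(line) {
  m <- gregexpr("'[^']*'|\"[^\"]*\"|[^[:space:]]+", line)[[1]]
  if (m[1] == -1L) return(character(0))
  toks <- regmatches(line, list(m))[[1]]
  # comment: drop from the first unquoted token beginning with '#'
  cm <- which(substr(toks, 1, 1) == "#")
  if (length(cm)) toks <- toks[seq_len(cm[1] - 1L)]
  q <- substr(toks, 1, 1) %in% c("'", "\"")
  toks[q] <- substr(toks[q], 2, nchar(toks[q]) - 1L)
  toks
}

# Read a CIF file into a token stream. Semicolon text blocks collapse to one
# token. Returns character vector.
cif_token_stream <- function(lines) {
  out <- vector("list", length(lines))
  i <- 1L; k <- 1L; n <- length(lines)
  while (i <= n) {
    line <- lines[[i]]
    if (startsWith(line, ";")) {
      block <- sub("^;", "", line)
      i <- i + 1L
      body <- character(0)
      while (i <= n && !startsWith(lines[[i]], ";")) {
        body <- c(body, lines[[i]]); i <- i + 1L
      }
      if (i > n) stopf("mmCIF parse error: unterminated ';' text block")
      out[[k]] <- paste(c(block, body), collapse = "\n"); k <- k + 1L
      i <- i + 1L
    } else {
      toks <- cif_tokenize_line(line)
      if (length(toks)) { out[[k]] <- toks; k <- k + 1L }
      i <- i + 1L
    }
  }
  unlist(out[seq_len(k - 1L)], use.names = FALSE)
}

cif_na <- function(x) {
  x[x %in% c(".", "?")] <- NA_character_
  x
}

#' Read an mmCIF file into per-category tables
#'
#' @param path path to an mmCIF file (single data block).
#' @return named list: category name (without leading underscore) ->
#'   data.frame of items (loop categories may have many rows; key-value
#'   categories have one row).
#' @keywords internal
read_cif <- function(path) {
  lines <- readLines(path, warn = FALSE)
  toks <- cif_token_stream(lines)
  if (!length(toks)) stopf("mmCIF parse error: empty file '%s'", path)
  cats <- list()
  i <- 1L; n <- length(toks)
  is_name <- function(t) startsWith(t, "_")
  add_kv <- function(cats, name, value) {
    parts <- strsplit(sub("^_", "", name), ".", fixed = TRUE)[[1]]
    if (length(parts) < 2L) stopf("mmCIF parse error: malformed item name '%s'", name)
    cat <- parts[1]; item <- paste(parts[-1], collapse = ".")
    row <- cats[[cat]] %||% data.frame(row.names = 1)
    row[[item]] <- cif_na(value)
    cats[[cat]] <- row
    cats
  }
  while (i <= n) {
    t <- toks[[i]]
    if (startsWith(t, "data_") || startsWith(t, "#")) { i <- i + 1L; next }
    if (identical(t, "loop_")) {
      i <- i + 1L
      names_ <- character(0)
      while (i <= n && is_name(toks[[i]])) { names_ <- c(names_, toks[[i]]); i <- i + 1L }
      if (!length(names_)) stopf("mmCIF parse error: loop_ without item names")
      vals <- character(0)
      while (i <= n && !is_name(toks[[i]]) && !identical(toks[[i]], "loop_") &&
             !startsWith(toks[[i]], "data_")) {
        vals <- c(vals, toks[[i]]); i <- i + 1L
      }
      ncol <- length(names_)
      if (length(vals) %% ncol != 0L)
        stopf("mmCIF parse error: loop for '%s' has %d values, not a multiple of %d columns",
              names_[1], length(vals), ncol)
      m <- matrix(cif_na(vals), ncol = ncol, byrow = TRUE)
      cat <- strsplit(sub("^_", "", names_[1]), ".", fixed = TRUE)[[1]][1]
      items <- vapply(names_, function(nm) {
        p <- strsplit(sub("^_", "", nm), ".", fixed = TRUE)[[1]]
        if (!identical(p[1], cat))
          stopf("mmCIF parse error: loop mixes categories '%s' and '%s'", cat, p[1])
        paste(p[-1], collapse = ".")
      }, character(1))
      df <- as.data.frame(m, stringsAsFactors = FALSE)
      names(df) <- items
      cats[[cat]] <- df
      next
    }
    if (is_name(t)) {
      if (i + 1L > n) stopf("mmCIF parse error: item '%s' has no value", t)
      cats <- add_kv(cats, t, toks[[i + 1L]])
      i <- i + 2L
      next
    }
    stopf("mmCIF parse error: unexpected token '%s'", t)
  }
  cats
}

cif_quote <- function(x) {
  x <- as.character(x)
  x[is.na(x)] <- "?"
  bad <- grepl("[[:space:]]", x) | x == "" |
    substr(x, 1, 1) %in% c("_", "'", "\"", "#", "$", "[", "]")
  x[bad] <- paste0("'", x[bad], "'")
  x
}

#' Write per-category tables as an mmCIF file
#' @keywords internal
write_cif <- function(cats, path, block = "QS") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("data_", block), con)
  for (cat in names(cats)) {
    df <- cats[[cat]]
    writeLines("#", con)
    if (nrow(df) == 1L) {
      for (item in names(df))
        writeLines(sprintf("_%s.%s %s", cat, item, cif_quote(df[[item]][1])), con)
    } else {
      writeLines("loop_", con)
      writeLines(sprintf("_%s.%s", cat, names(df)), con)
      cols <- lapply(df, cif_quote)
      writeLines(do.call(paste, cols), con)
    }
  }
  writeLines("#", con)
  invisible(path)
}
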