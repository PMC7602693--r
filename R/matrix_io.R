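# Discrete morphological character matrices.
#
# Cells carry state-set semantics: a determinate cell holds one state code, a
# polymorphic cell ("[01]") two or more, missing ("?") and inapplicable
# ("-"/Unicode en dash) are empty sentinels expanded to the column's observed
# state set at scoring time. States are restricted to the codes 0-9.
#
# Internal storage: `states` is an n_taxa x n_char integer matrix of bitmasks
# (bit k set = state k present; 0 for the empty sentinels) and `kind` a
# parallel character matrix in {"det","poly","missing","inapp"}.

MISSING_TOKENS <- c("?")
INAPP_TOKENS <- c("-", "–", "−")

mask_of <- function(states) {
  if (!length(states)) return(0L)
  sum(bitwShiftL(1L, as.integer(states)))
}

states_of <- function(mask) {
  which(bitwAnd(mask, bitwShiftL(1L, 0:9)) > 0L) - 1L
}

#' Construct a morphological character matrix
#'
#' @param taxa Character vector of unique taxon names.
#' @param cells List (or matrix) of cell tokens, by row: each token one of a
#'   digit `"0"`-`"9"`, `"?"` (missing), `"-"` (inapplicable), or a bracketed
#'   polymorphism such as `"[01]"`.
#' @param ordered Logical vector: is each character additive (ordered)?
#' @param active Logical vector: is each character included in scoring?
#' @param labels Optional character labels.
#' @return An object of class `"morph_matrix"`.
#' @export
morph_matrix <- function(taxa, cells, ordered = NULL, active = NULL,
                         labels = NULL) {
  taxa <- gsub("[[:space:]]+", "_", trimws(taxa))
  if (anyDuplicated(taxa)) stop("duplicate taxon name: ",
                                taxa[duplicated(taxa)][1L])
  if (is.matrix(cells)) cells <- apply(cells, 1L, identity, simplify = FALSE)
  nch <- unique(lengths(cells))
  if (length(nch) != 1L) stop("rows differ in character count")
  if (length(cells) != length(taxa)) stop("row count != taxon count")
  states <- matrix(0L, length(taxa), nch)
  kind <- matrix("det", length(taxa), nch)
  for (i in seq_along(taxa)) for (j in seq_len(nch)) {
    cs <- parse_cell_token(cells[[i]][[j]], where = paste0("taxon ", taxa[i],
                                                           ", character ", j))
    states[i, j] <- cs$mask
    kind[i, j] <- cs$kind
  }
  if (is.null(ordered)) ordered <- rep(FALSE, nch)
  if (is.null(active)) active <- rep(TRUE, nch)
  if (is.null(labels)) labels <- rep("", nch)
  stopifnot(length(ordered) == nch, length(active) == nch,
            length(labels) == nch)
  structure(list(taxa = taxa, nchar = as.integer(nch), states = states,
                 kind = kind, ordered = as.logical(ordered),
                 active = as.logical(active), labels = as.character(labels)),
            class = "morph_matrix")
}

parse_cell_token <- function(tok, where = "") {
  tok <- trimws(tok)
  if (tok %in% MISSING_TOKENS) return(list(mask = 0L, kind = "missing"))
  if (tok %in% INAPP_TOKENS) return(list(mask = 0L, kind = "inapp"))
  if (grepl("^[0-9]$", tok))
    return(list(mask = mask_of(as.integer(tok)), kind = "det"))
  if (grepl("^[\\[(][0-9]+[])]$", tok)) {
    st <- unique(as.integer(strsplit(gsub("[][()]", "", tok), "")[[1L]]))
    if (length(st) < 2L) stop("polymorphism with fewer than 2 states at ", where)
    return(list(mask = mask_of(st), kind = "poly"))
  }
  stop("invalid cell token '", tok, "' at ", where,
       " (state codes must be 0-9)")
}

format_cell_token <- function(mask, kind) {
  switch(kind,
         missing = "?",
         inapp = "-",
         det = as.character(states_of(mask)),
         poly = paste0("[", paste(states_of(mask), collapse = ""), "]"))
}

#' @export
print.morph_matrix <- function(x, ...) {
  cat("morph_matrix: ", length(x$taxa), " taxa x ", x$nchar, " characters (",
      sum(x$ordered), " ordered, ", sum(!x$active), " inactive)\n", sep = "")
  invisible(x)
}

#' @export
dim.morph_matrix <- function(x) c(length(x$taxa), x$nchar)

#' Extract one character column as a list of cell descriptors
#'
#' @param matrix A [morph_matrix].
#' @param char 1-based character index.
#' @return List with one element per taxon: `list(kind=, states=)`.
#' @export
matrix_column <- function(matrix, char) {
  lapply(seq_along(matrix$taxa), function(i)
    list(kind = matrix$kind[i, char], states = states_of(matrix$states[i, char])))
}

#' Read a NEXUS or TNT morphological matrix
#'
#' Supports the subset of the two dialects needed for discrete morphological
#' matrices: NEXUS `DATA`/`CHARACTERS` blocks with `DIMENSIONS`, `FORMAT`,
#' `CHARLABELS` and `MATRIX` commands plus an `ASSUMPTIONS` block with
#' `TYPESET` (`ord:`/`unord:`) and `EXSET` (excluded characters), and TNT
#' `xread` (or a bare name-plus-row matrix) with `ccode` additivity and
#' activity toggles (`+ - [ ]`, 0-based indices, `a.b` ranges). Characters
#' without a declaration default to non-additive and active.
#'
#' @param text Matrix file content, as a single string or character vector of
#'   lines. A path to an existing file is also accepted.
#' @param dialect `"nexus"`, `"tnt"` or `"auto"` (detect from content).
#' @return A [morph_matrix].
#' @export
parse_matrix <- function(text, dialect = c("auto", "nexus", "tnt")) {
  dialect <- match.arg(dialect)
  if (length(text) == 1L && !grepl("\n", text) && file.exists(text))
    text <- readLines(text, warn = FALSE)
  lines <- if (length(text) == 1L) strsplit(text, "\n")[[1L]] else text
  if (dialect == "auto") {
    dialect <- if (any(grepl("^\\s*#nexus", lines, ignore.case = TRUE)))
      "nexus" else "tnt"
  }
  if (dialect == "nexus") parse_nexus_lines(lines) else parse_tnt_lines(lines)
}

split_row_tokens <- function(row_text, line_no) {
  chars <- strsplit(row_text, "")[[1L]]
  toks <- character(0)
  i <- 1L
  while (i <= length(chars)) {
    ch <- chars[[i]]
    if (grepl("[[:space:]]", ch)) { i <- i + 1L; next }
    if (ch %in% c("[", "(")) {
      close <- if (ch == "[") "]" else ")"
      j <- i + 1L
      while (j <= length(chars) && chars[[j]] != close) j <- j + 1L
      if (j > length(chars))
        stop("line ", line_no, ": unterminated polymorphism bracket")
      toks <- c(toks, paste(chars[i:j], collapse = ""))
      i <- j + 1L
    } else {
      toks <- c(toks, ch)
      i <- i + 1L
    }
  }
  toks
}

# Split "Taxon_name 0101[01]?-" (name may be quoted) into name + tokens.
parse_matrix_row <- function(ln, line_no) {
  ln <- trimws(ln)
  if (startsWith(ln, "'") || startsWith(ln, "\"")) {
    q <- substr(ln, 1L, 1L)
    end <- regexpr(q, substring(ln, 2L), fixed = TRUE)
    if (end < 0L) stop("line ", line_no, ": unterminated quoted taxon name")
    name <- substr(ln, 2L, end)
    rest <- substring(ln, end + 2L)
  } else {
    sp <- regexpr("[[:space:]]", ln)
    if (sp < 0L) stop("line ", line_no, ": row has no character data")
    name <- substr(ln, 1L, sp - 1L)
    rest <- substring(ln, sp + 1L)
  }
  list(name = name, tokens = split_row_tokens(rest, line_no))
}

parse_index_list <- function(tokens, n, base) {
  idx <- integer(0)
  for (tk in tokens) {
    if (grepl("^\\d+$", tk)) idx <- c(idx, as.integer(tk))
    else if (grepl("^\\d+[.-]\\d+$", tk)) {
      ab <- as.integer(strsplit(tk, "[.-]")[[1L]])
      idx <- c(idx, seq(ab[1L], ab[2L]))
    } else if (tk == ".") idx <- c(idx, if (base == 0L) n - 1L else n)
    else stop("cannot parse character index '", tk, "'")
  }
  idx <- idx + (1L - base)
  if (any(idx < 1L | idx > n)) stop("character index out of range")
  idx
}

parse_nexus_lines <- function(lines) {
  txt <- paste(lines, collapse = "\n")
  # names of matrix rows may contain dots etc; work command-wise outside the
  # matrix, line-wise inside it
  low <- tolower(lines)
  ntax <- nchar_ <- NA_integer_
  dims <- grep("\\bdimensions\\b", low)
  for (i in dims) {
    m1 <- regmatches(low[i], regexpr("ntax\\s*=\\s*\\d+", low[i]))
    m2 <- regmatches(low[i], regexpr("nchar\\s*=\\s*\\d+", low[i]))
    if (length(m1)) ntax <- as.integer(gsub("\\D", "", m1))
    if (length(m2)) nchar_ <- as.integer(gsub("\\D", "", m2))
  }
  if (is.na(ntax) || is.na(nchar_))
    stop("malformed NEXUS: DIMENSIONS with NTAX and NCHAR required")
  mstart <- grep("^\\s*matrix\\s*$", low)
  if (!length(mstart)) stop("malformed NEXUS: no MATRIX command")
  taxa <- character(0); rows <- list()
  i <- mstart[1L] + 1L
  while (i <= length(lines)) {
    ln <- trimws(lines[i])
    if (ln == ";" || grepl("^;", ln)) break
    if (nzchar(ln) && !startsWith(ln, "[")) {
      pr <- parse_matrix_row(sub(";\\s*$", "", ln), i)
      if (pr$name %in% taxa) stop("line ", i, ": duplicate taxon ", pr$name)
      if (length(pr$tokens) != nchar_)
        stop("line ", i, ": row for ", pr$name, " has ", length(pr$tokens),
             " characters, expected ", nchar_)
      taxa <- c(taxa, pr$name)
      rows[[length(rows) + 1L]] <- pr$tokens
      if (grepl(";\\s*$", lines[i])) { i <- i + 1L; break }
    }
    i <- i + 1L
  }
  if (length(taxa) != ntax)
    stop("matrix has ", length(taxa), " rows, DIMENSIONS declared ", ntax)
  ordered <- rep(FALSE, nchar_)
  active <- rep(TRUE, nchar_)
  labels <- rep("", nchar_)
  # ASSUMPTIONS: typeset / exset, single-line commands
  for (i in grep("\\btypeset\\b", low)) {
    body <- sub(".*=", "", sub(";\\s*$", "", lines[i]))
    for (grp in strsplit(body, ",")[[1L]]) {
      kv <- strsplit(grp, ":")[[1L]]
      if (length(kv) != 2L) next
      type <- tolower(trimws(kv[1L]))
      idx <- parse_index_list(strsplit(trimws(kv[2L]), "\\s+")[[1L]], nchar_, 1L)
      if (type %in% c("ord", "o")) ordered[idx] <- TRUE
      if (type %in% c("unord", "u")) ordered[idx] <- FALSE
    }
  }
  for (i in grep("\\bexset\\b", low)) {
    body <- trimws(sub(".*=", "", sub(";\\s*$", "", lines[i])))
    if (nzchar(body))
      active[parse_index_list(strsplit(body, "\\s+")[[1L]], nchar_, 1L)] <- FALSE
  }
  cl <- grep("^\\s*charlabels\\b", low)
  if (length(cl)) {
    # labels until ';', quoted or bare, whitespace separated
    j <- cl[1L]
    buf <- sub("^\\s*charlabels", "", lines[j], ignore.case = TRUE)
    while (!grepl(";", buf) && j < length(lines)) {
      j <- j + 1L
      buf <- paste(buf, lines[j])
    }
    buf <- sub(";.*$", "", buf)
    labs <- regmatches(buf, gregexpr("'[^']*'|\\S+", buf))[[1L]]
    labs <- gsub("^'|'$", "", labs)
    if (length(labs)) labels[seq_along(labs)] <- labs
  }
  morph_matrix(taxa, rows, ordered, active, labels)
}

parse_tnt_lines <- function(lines) {
  low <- tolower(lines)
  xr <- grep("^\\s*xread\\b", low)
  taxa <- character(0); rows <- list()
  nchar_ <- NA_integer_; ntax <- NA_integer_
  if (length(xr)) {
    i <- xr[1L]
    rest <- trimws(sub("^\\s*xread", "", lines[i], ignore.case = TRUE))
    # optional quoted title, possibly spanning lines
    buf <- rest
    repeat {
      nq <- lengths(regmatches(buf, gregexpr("'", buf)))
      if (nq %% 2L == 0L) break
      i <- i + 1L
      buf <- paste(buf, lines[i])
    }
    buf <- gsub("'[^']*'", "", buf)
    nums <- regmatches(buf, gregexpr("\\d+", buf))[[1L]]
    while (length(nums) < 2L && i < length(lines)) {
      i <- i + 1L
      nums <- c(nums, regmatches(lines[i], gregexpr("\\d+", lines[i]))[[1L]])
    }
    nchar_ <- as.integer(nums[1L]); ntax <- as.integer(nums[2L])
    i <- i + 1L
    while (i <= length(lines) && length(taxa) < ntax) {
      ln <- trimws(lines[i])
      if (ln == ";") break
      if (nzchar(ln)) {
        pr <- parse_matrix_row(sub(";\\s*$", "", ln), i)
        if (pr$name %in% taxa) stop("line ", i, ": duplicate taxon ", pr$name)
        if (length(pr$tokens) != nchar_)
          stop("line ", i, ": row for ", pr$name, " has ", length(pr$tokens),
               " characters, expected ", nchar_)
        taxa <- c(taxa, pr$name)
        rows[[length(rows) + 1L]] <- pr$tokens
      }
      i <- i + 1L
    }
    if (length(taxa) != ntax)
      stop("xread declared ", ntax, " taxa but matrix has ", length(taxa))
  } else {
    # bare matrix: every non-empty, non-command line is "name row"
    for (i in seq_along(lines)) {
      ln <- trimws(lines[i])
      if (!nzchar(ln) || grepl("^(ccode|proc|;)", tolower(ln))) next
      pr <- parse_matrix_row(sub(";\\s*$", "", ln), i)
      if (pr$name %in% taxa) stop("line ", i, ": duplicate taxon ", pr$name)
      taxa <- c(taxa, pr$name)
      rows[[length(rows) + 1L]] <- pr$tokens
    }
    if (!length(taxa)) stop("no matrix rows found")
    nchar_ <- length(rows[[1L]])
    for (k in seq_along(rows))
      if (length(rows[[k]]) != nchar_)
        stop("row for ", taxa[k], " has ", length(rows[[k]]),
             " characters, expected ", nchar_)
  }
  ordered <- rep(FALSE, nchar_)
  active <- rep(TRUE, nchar_)
  for (i in grep("^\\s*ccode\\b", low)) {
    body <- trimws(sub(";.*$", "", sub("^\\s*ccode", "", lines[i],
                                       ignore.case = TRUE)))
    toks <- strsplit(body, "\\s+")[[1L]]
    mode <- NULL
    pend <- character(0)
    flush <- function(mode, pend) {
      if (is.null(mode) || !length(pend)) return(invisible())
      idx <- parse_index_list(pend, nchar_, 0L)   # TNT indices are 0-based
      switch(mode,
             "+" = ordered[idx] <<- TRUE,
             "-" = ordered[idx] <<- FALSE,
             "[" = active[idx] <<- TRUE,
             "]" = active[idx] <<- FALSE)
      invisible()
    }
    for (tk in toks) {
      if (tk %in% c("+", "-", "[", "]")) {
        flush(mode, pend); mode <- tk; pend <- character(0)
      } else pend <- c(pend, tk)
    }
    flush(mode, pend)
  }
  morph_matrix(taxa, rows, ordered, active)
}

#' Write a matrix in NEXUS or TNT dialect
#'
#' The output is round-trip stable: `parse_matrix(write_matrix(m, d), d)`
#' reproduces `m` including cell kinds (`?` vs `-` vs `[..]`), additivity and
#' activity flags. Taxon-name whitespace is normalized to underscores.
#'
#' @param matrix A [morph_matrix].
#' @param dialect `"nexus"` or `"tnt"`.
#' @return A single string of file text.
#' @export
write_matrix <- function(matrix, dialect = c("nexus", "tnt")) {
  dialect <- match.arg(dialect)
  m <- matrix
  rows <- vapply(seq_along(m$taxa), function(i)
    paste(vapply(seq_len(m$nchar), function(j)
      format_cell_token(m$states[i, j], m$kind[i, j]), ""), collapse = ""), "")
  namew <- max(nchar(m$taxa)) + 2L
  body <- paste0(formatC(m$taxa, width = -namew), rows)
  if (dialect == "nexus") {
    out <- c("#NEXUS", "", "BEGIN DATA;",
             paste0("  DIMENSIONS NTAX=", length(m$taxa), " NCHAR=", m$nchar, ";"),
             "  FORMAT DATATYPE=STANDARD SYMBOLS=\"0123456789\" MISSING=? GAP=-;")
    if (any(nzchar(m$labels)))
      out <- c(out, paste0("  CHARLABELS ",
                           paste(ifelse(nzchar(m$labels),
                                        paste0("'", m$labels, "'"), "_"),
                                 collapse = " "), ";"))
    out <- c(out, "  MATRIX", paste0("    ", body), "  ;", "END;")
    asmp <- character(0)
    if (any(m$ordered))
      asmp <- c(asmp, paste0("  TYPESET * default = ord: ",
                             paste(which(m$ordered), collapse = " "), ";"))
    if (any(!m$active))
      asmp <- c(asmp, paste0("  EXSET * excluded = ",
                             paste(which(!m$active), collapse = " "), ";"))
    if (length(asmp))
      out <- c(out, "", "BEGIN ASSUMPTIONS;", asmp, "END;")
  } else {
    out <- c(paste0("xread 'mpclad export' ", m$nchar, " ", length(m$taxa)),
             body, ";")
    if (any(m$ordered))
      out <- c(out, paste0("ccode + ", paste(which(m$ordered) - 1L,
                                             collapse = " "), ";"))
    if (any(!m$active))
      out <- c(out, paste0("ccode ] ", paste(which(!m$active) - 1L,
                                             collapse = " "), ";"))
    out <- c(out, "proc /;")
  }
  paste0(paste(out, collapse = "\n"), "\n")
}

#' Built-in example matrices
#'
#' * `"table2_cols1_18"`: the published 43-taxon x 18-character block of the
#'   *Isodacrys* data matrix (characters 1-18 of 72), verbatim, with
#'   characters 3 and 15 additive. It contains one polymorphic cell
#'   (*I. brevirostre*, character 1) and missing cells only in the
#'   *I. schwarzi* row.
#' * `"toy4x2"`: 4 taxa x 2 binary characters, all determinate.
#' * `"toy6"`: 6 taxa x 5 binary characters with one clean clade signal.
#' * `"supplementary_full"`: placeholder for the complete deposited 43 x 72
#'   matrix; not shipped (the full matrix is only available from the data
#'   archive), so requesting it raises an error explaining this.
#'
#' @param name Fixture id.
#' @return A [morph_matrix].
#' @export
builtin_fixture <- function(name) {
  known <- c("table2_cols1_18", "toy4x2", "toy6", "supplementary_full")
  if (!name %in% known)
    stop("unknown fixture '", name, "'; available: ",
         paste(known, collapse = ", "))
  if (name == "supplementary_full")
    stop("fixture 'supplementary_full' (the complete 43x72 deposited matrix) ",
         "is not shipped with the package: only characters 1-18 are published ",
         "in print (see fixture 'table2_cols1_18'). Obtain the deposited ",
         "Nexus file and load it with parse_matrix().")
  if (name == "table2_cols1_18") {
    path <- system.file("extdata", "table2_cols1_18.nex", package = "mpclad",
                        mustWork = TRUE)
    return(parse_matrix(readLines(path, warn = FALSE), "nexus"))
  }
  if (name == "toy4x2")
    return(morph_matrix(c("A", "B", "C", "D"),
                        list(c("0", "0"), c("0", "1"), c("1", "0"), c("1", "1"))))
  morph_matrix(c("A", "B", "C", "D", "E", "F"),
               list(c("1", "1", "0", "0", "0"),
                    c("1", "1", "1", "0", "0"),
                    c("1", "1", "1", "0", "1"),
                    c("0", "0", "1", "1", "0"),
                    c("0", "0", "0", "1", "1"),
                    c("0", "0", "0", "0", "0")))
}
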