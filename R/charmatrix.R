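# Discrete morphological character matrices.
#
# States are the digits 0..9; "?" and "-" are both treated as missing data
# (the full state set in scoring) — the standard morphology convention, since
# the matrix dialect does not give the gap symbol its own semantics.
# Polymorphic codings like "(01)" or "[01]" are parsed but treated as
# missing, with a warning.

#' Construct a character matrix
#'
#' @param states Integer matrix (taxa x characters) with values 0..9 and
#'   `NA` for missing; rownames are taxon labels.
#' @param ordered Logical vector, one flag per character (`TRUE` = scored
#'   with linear order costs), or an integer vector of 1-based ordered
#'   character indices.
#' @param outgroup Outgroup taxon label (or `NA`).
#' @return An object of class `character_matrix`.
#' @export
character_matrix <- function(states, ordered = FALSE, outgroup = NA_character_) {
  states <- as.matrix(states)
  storage.mode(states) <- "integer"
  if (is.null(rownames(states))) {
    stop_input("`states` must have taxon rownames", "validation_error")
  }
  if (anyDuplicated(rownames(states))) {
    stop_input("taxon labels must be unique", "validation_error")
  }
  if (any(!is.na(states))) {
    rng <- range(states, na.rm = TRUE)
    if (rng[1] < 0 || rng[2] > 9) {
      stop_input("states must be in 0..9 (NA for missing)", "validation_error")
    }
  }
  nchar_ <- ncol(states)
  if (is.logical(ordered)) {
    ordered <- if (length(ordered) == 1) rep(ordered, nchar_) else ordered
  } else {
    idx <- as.integer(ordered)
    if (length(idx) && (any(idx < 1) || any(idx > nchar_))) {
      stop_input("ordered character indices outside 1..n_characters",
                 "validation_error")
    }
    ordered <- seq_len(nchar_) %in% idx
  }
  if (length(ordered) != nchar_) {
    stop_input("`ordered` must have one flag per character", "validation_error")
  }
  if (!is.na(outgroup) && !outgroup %in% rownames(states)) {
    stop_input(paste0("outgroup ", outgroup, " not among taxa"), "validation_error")
  }
  structure(
    list(states = states, taxa = rownames(states),
         ordered = ordered, outgroup = outgroup),
    class = "character_matrix"
  )
}

#' @export
print.character_matrix <- function(x, ...) {
  cat(sprintf("<character_matrix> %d taxa x %d characters (%d ordered, %.1f%% missing)\n",
              nrow(x$states), ncol(x$states), sum(x$ordered),
              100 * mean(is.na(x$states))))
  if (!is.na(x$outgroup)) cat("  outgroup:", x$outgroup, "\n")
  invisible(x)
}

#' @export
dim.character_matrix <- function(x) dim(x$states)

#' Tidy a character matrix into long form
#'
#' @param x A `character_matrix`.
#' @param ... Unused.
#' @return A tibble with columns `taxon`, `character` (1-based index),
#'   `state` (integer or NA), `ordered`.
#' @exportS3Method generics::tidy
tidy.character_matrix <- function(x, ...) {
  tibble::tibble(
    taxon = rep(x$taxa, times = ncol(x$states)),
    character = rep(seq_len(ncol(x$states)), each = nrow(x$states)),
    state = as.integer(x$states),
    ordered = rep(x$ordered, each = nrow(x$states))
  )
}

# ---- parsing ---------------------------------------------------------------

# Tokenize one row of state symbols into integers (NA = missing), collapsing
# polymorphisms to missing with a warning.
parse_state_row <- function(symbols, taxon, missing_chars = c("?", "-")) {
  chars <- strsplit(symbols, "")[[1]]
  out <- integer(0)
  i <- 1
  poly <- FALSE
  while (i <= length(chars)) {
    ch <- chars[i]
    if (ch %in% c("(", "[", "{")) {
      close <- c("(" = ")", "[" = "]", "{" = "}")[[ch]]
      j <- i + 1
      while (j <= length(chars) && chars[j] != close) j <- j + 1
      if (j > length(chars)) {
        stop_input(paste0("unclosed polymorphism in row for taxon ", taxon),
                   "format_error")
      }
      out <- c(out, NA_integer_)
      poly <- TRUE
      i <- j + 1
    } else if (ch %in% missing_chars) {
      out <- c(out, NA_integer_)
      i <- i + 1
    } else if (grepl("[0-9]", ch)) {
      out <- c(out, as.integer(ch))
      i <- i + 1
    } else if (grepl("\\s", ch)) {
      i <- i + 1
    } else {
      stop_input(paste0("state symbol '", ch, "' outside alphabet for taxon ",
                        taxon), "format_error")
    }
  }
  if (poly) {
    warn(paste0("polymorphic coding(s) for taxon ", taxon,
                " treated as missing data"))
  }
  out
}

#' Read a morphological character matrix (NEXUS or TNT)
#'
#' Parses a NEXUS DATA/CHARACTERS block (SYMBOLS 0-9, MISSING `?`, GAP `-`)
#' or a TNT `xread` block into a [character_matrix()]. Both `?` and `-` map
#' to missing data; polymorphic codings are accepted but treated as missing,
#' with a warning. Declared dimensions are enforced.
#'
#' @param path Path to the matrix file.
#' @param dialect `"nexus"` or `"tnt"`; `"auto"` (default) detects from the
#'   file header.
#' @param ordered Ordered-character specification passed to
#'   [character_matrix()] (logical vector or 1-based indices).
#' @param outgroup Outgroup taxon label.
#' @return A `character_matrix`.
#' @export
read_character_matrix <- function(path, dialect = c("auto", "nexus", "tnt"),
                                  ordered = FALSE, outgroup = NA_character_) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop_input(paste0("matrix file not found: ", path), "io_error")
  lines <- readLines(path, warn = FALSE)
  if (dialect == "auto") {
    dialect <- if (any(grepl("^\\s*#NEXUS", lines, ignore.case = TRUE))) {
      "nexus"
    } else if (any(grepl("^\\s*xread", lines, ignore.case = TRUE))) {
      "tnt"
    } else {
      stop_input("cannot detect matrix dialect (no #NEXUS or xread header)",
                 "format_error")
    }
  }
  parsed <- if (dialect == "nexus") parse_nexus_matrix(lines) else parse_tnt_matrix(lines)
  states <- parsed$states
  if (nrow(states) != parsed$ntax || ncol(states) != parsed$nchar) {
    stop_input(sprintf("matrix dimensions %dx%d do not match declared %dx%d",
                       nrow(states), ncol(states), parsed$ntax, parsed$nchar),
               "format_error")
  }
  character_matrix(states, ordered = ordered, outgroup = outgroup)
}

parse_nexus_matrix <- function(lines) {
  txt <- paste(lines, collapse = "\n")
  txt <- gsub("\\[[^][]*\\](?![0-9])", "", txt, perl = TRUE) # strip [comments] not followed by digits
  dims <- regmatches(txt, regexpr("DIMENSIONS[^;]*;", txt, ignore.case = TRUE))
  if (!length(dims)) stop_input("no DIMENSIONS statement", "format_error")
  ntax <- as.integer(sub(".*NTAX\\s*=\\s*([0-9]+).*", "\\1", dims, ignore.case = TRUE))
  nchar_ <- as.integer(sub(".*NCHAR\\s*=\\s*([0-9]+).*", "\\1", dims, ignore.case = TRUE))
  if (is.na(ntax) || is.na(nchar_)) stop_input("bad DIMENSIONS statement", "format_error")
  mat <- regmatches(txt, regexpr("MATRIX\\s*\\n(.|\\n)*?;", txt, ignore.case = TRUE))
  if (!length(mat)) stop_input("no MATRIX block", "format_error")
  body <- sub("^MATRIX\\s*\\n", "", mat, ignore.case = TRUE)
  body <- sub(";\\s*$", "", body)
  rows <- strsplit(body, "\n")[[1]]
  rows <- trimws(rows)
  rows <- rows[nzchar(rows)]
  parse_matrix_rows(rows, ntax, nchar_)
}

parse_tnt_matrix <- function(lines) {
  txt <- paste(lines, collapse = "\n")
  txt <- gsub("'[^']*'", "", txt) # strip quoted title
  m <- regexpr("xread\\s*([0-9]+)\\s+([0-9]+)", txt, ignore.case = TRUE)
  if (m == -1) stop_input("no xread header", "format_error")
  hdr <- regmatches(txt, m)
  nums <- as.integer(strsplit(trimws(sub("xread", "", hdr, ignore.case = TRUE)),
                              "\\s+")[[1]])
  nchar_ <- nums[1] # TNT order: nchar then ntax
  ntax <- nums[2]
  body <- substr(txt, m + attr(m, "match.length"), nchar(txt))
  body <- sub(";(.|\\n)*$", "", body)
  rows <- trimws(strsplit(body, "\n")[[1]])
  rows <- rows[nzchar(rows)]
  parse_matrix_rows(rows, ntax, nchar_)
}

parse_matrix_rows <- function(rows, ntax, nchar_) {
  labels <- character(0)
  states_list <- list()
  for (row in rows) {
    # taxon label = first whitespace-delimited token (quoted labels supported)
    if (startsWith(row, "'")) {
      end <- regexpr("'", substring(row, 2), fixed = TRUE)
      label <- substr(row, 2, end)
      rest <- trimws(substring(row, end + 2))
    } else {
      sp <- regexpr("\\s", row)
      if (sp == -1) stop_input(paste0("matrix row without states: ", row), "format_error")
      label <- substr(row, 1, sp - 1)
      rest <- trimws(substring(row, sp + 1))
    }
    st <- parse_state_row(gsub("\\s", "", rest), label)
    if (label %in% labels) { # interleaved continuation
      idx <- match(label, labels)
      states_list[[idx]] <- c(states_list[[idx]], st)
    } else {
      labels <- c(labels, label)
      states_list[[length(labels)]] <- st
    }
  }
  lens <- lengths(states_list)
  if (length(unique(lens)) > 1 || (length(lens) && lens[1] != nchar_)) {
    bad <- labels[which(lens != nchar_)[1]]
    stop_input(sprintf("row for taxon %s has %d states, expected %d",
                       bad, lens[match(bad, labels)], nchar_), "format_error")
  }
  states <- do.call(rbind, states_list)
  rownames(states) <- labels
  list(states = states, ntax = ntax, nchar = nchar_)
}

# ---- writing ---------------------------------------------------------------

#' Write a character matrix to NEXUS or TNT format
#'
#' @param x A `character_matrix`.
#' @param path Output path.
#' @param dialect `"nexus"` (default) or `"tnt"`.
#' @return `path`, invisibly.
#' @export
write_character_matrix <- function(x, path, dialect = c("nexus", "tnt")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(x, "character_matrix"))
  sym <- x$states
  rows <- apply(sym, 1, function(r) {
    paste(ifelse(is.na(r), "?", as.character(r)), collapse = "")
  })
  lab <- gsub("\\s", "_", x$taxa)
  if (dialect == "nexus") {
    out <- c(
      "#NEXUS",
      "BEGIN DATA;",
      sprintf("DIMENSIONS NTAX=%d NCHAR=%d;", nrow(sym), ncol(sym)),
      "FORMAT SYMBOLS=\"0123456789\" MISSING=? GAP=-;",
      "MATRIX",
      paste(formatC(lab, width = max(nchar(lab)) + 2, flag = "-"), rows),
      ";",
      "END;"
    )
  } else {
    out <- c(
      "xread",
      "'exported matrix'",
      sprintf("%d %d", ncol(sym), nrow(sym)),
      paste(formatC(lab, width = max(nchar(lab)) + 2, flag = "-"), rows),
      ";"
    )
  }
  writeLines(out, path)
  invisible(path)
}

#' Published ordered-character indices
#'
#' The 40 1-based character indices scored as ordered (transformational
#' sequences) in the ordered variant of the phylogenetic analysis, shipped
#' as a plain-text fixture.
#'
#' @return An integer vector of length 40.
#' @export
ordered_character_indices <- function() {
  path <- system.file("extdata", "ordered_characters.txt",
                      package = "metriomorph", mustWork = TRUE)
  as.integer(readLines(path, warn = FALSE))
}
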