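# Cytological notation: normalize, split, parse, and evaluate raw
# chromosome-count record strings as exported from the CCDB.
#
# The grammar covers the documented pattern families: plain integers
# ("42"), meiotic configurations with roman-numeral valences
# ("40II+44I" = 40 bivalents + 44 univalents), B-chromosome terms that
# never enter the total ("11II+1BI", "62+2BS"), supernumerary ranges
# as additive terms ("34+0-13"), standalone endpoint ranges ("40-44"),
# fragment suffixes ("30f"), approximate prefixes ("c.24"), comma/
# semicolon alternatives, parenthetical record-multiplicity metadata
# ("64(1, 1, 1, 4, 1, 1)") and literal "etc" tokens.

# Unicode dash variants seen in CCDB exports: hyphen, non-breaking
# hyphen, figure/en/em dash, horizontal bar, minus sign.
.dash_class <- "[‐‑‒–—―−]"

#' Normalize a raw count-record string to canonical form
#'
#' Maps every unicode dash variant (hyphen, en/em dash, minus sign, ...)
#' to ASCII `-`, collapses runs of whitespace to single spaces, trims,
#' and upper-cases valence markers (`I`, `II`, ..., roman numerals),
#' B-chromosome markers (`B`, `Bs`, `BI`), fragment suffixes (`f`) and
#' approximate prefixes (`c.`, `ca.`). Everything else is left
#' unchanged, so the canonical string stays recognizably close to the
#' original record.
#'
#' @param raw Character vector of raw record strings. Each element must
#'   be non-empty after whitespace trimming.
#' @return Character vector of canonical strings, same length as `raw`.
#' @examples
#' normalize_record("40‐44")   # unicode hyphen -> "40-44"
#' normalize_record(" 11ii + 1bi ") # -> "11II + 1BI"
#' @export
normalize_record <- function(raw) {
  stopifnot(is.character(raw))
  if (any(is.na(raw)) || any(!nzchar(trimws(raw)))) {
    rlang::abort("every record string must be non-empty",
                 class = "chromcurate_empty_record")
  }
  x <- gsub(.dash_class, "-", raw, perl = TRUE)
  x <- gsub("\\s+", " ", trimws(x))
  # markers directly following a digit: valences, B terms, fragment "f"
  x <- gsub("(?<=[0-9])((?i:B[IVXS]*|[IVX]+|F))(?![[:alnum:]])",
            "\\U\\1", x, perl = TRUE)
  # approximate prefixes at a word boundary ("etc." is not affected:
  # its "c." is not preceded by a boundary)
  x <- gsub("(?i)\\bca\\.", "CA.", x, perl = TRUE)
  x <- gsub("(?i)\\bc\\.", "C.", x, perl = TRUE)
  x
}

#' Split a canonical record into its alternative count expressions
#'
#' Records often list several independent observations in one string,
#' separated by `;` or by `,` (Table-style records such as
#' `"62+1B, 62+2Bs, 63"`). Commas inside parentheses do not split.
#' A parenthetical group immediately following a count is
#' record-multiplicity metadata and is deleted before splitting;
#' literal `etc`/`etc.` tokens are dropped.
#'
#' @param canonical A single canonical string (see [normalize_record()]).
#' @return Character vector of expression strings, in input order.
#'   Attribute `"dropped"` lists tokens that were discarded (`etc`).
#' @export
split_alternatives <- function(canonical) {
  stopifnot(is.character(canonical), length(canonical) == 1L)
  chars <- strsplit(canonical, "", fixed = TRUE)[[1]]
  depth <- 0L
  cut <- logical(length(chars))
  for (i in seq_along(chars)) {
    ch <- chars[i]
    if (ch == "(") depth <- depth + 1L
    else if (ch == ")") {
      depth <- depth - 1L
      if (depth < 0L) {
        rlang::abort("unbalanced parentheses in record",
                     class = "chromcurate_unbalanced_parens")
      }
    } else if ((ch == ";" || ch == ",") && depth == 0L) cut[i] <- TRUE
  }
  if (depth != 0L) {
    rlang::abort("unbalanced parentheses in record",
                 class = "chromcurate_unbalanced_parens")
  }
  grp <- cumsum(cut)
  parts <- vapply(split(chars[!cut], grp[!cut]), paste, "", collapse = "")
  # delete parenthetical metadata directly after a count/term
  parts <- gsub("(?<=[0-9IVXBSF])\\s*\\([^()]*\\)", "", parts, perl = TRUE)
  parts <- trimws(parts)
  is_etc <- grepl("^(?i)etc\\.?$", parts, perl = TRUE)
  dropped <- parts[is_etc]
  parts <- unname(parts[!is_etc & nzchar(parts)])
  attr(parts, "dropped") <- unname(dropped)
  parts
}

.roman_value <- function(s) {
  v <- suppressWarnings(as.integer(utils::as.roman(s)))
  if (is.na(v) || v < 1L) NULL else v
}

#' Parse one count expression into its additive terms
#'
#' Decomposes a `+`-joined expression into terms. Each term is one of:
#' a plain integer (an already-summed count), an integer with a roman
#' valence marker (`40II` = 40 bivalents, contributing
#' multiplicity x valence chromosomes), a B-chromosome term
#' (`1B`, `2BS`, `1BI`; contributes 0), or a non-leading range `a-b`
#' (a supernumerary series; contributes 0). A trailing `F` marks a
#' fragment (flagged, number kept); a leading `C.`/`CA.` marks an
#' approximate count (flagged, stripped).
#'
#' A standalone leading range is *not* handled here; [translate_record()]
#' expands it into its two endpoint counts upstream.
#'
#' @param expr A single expression string (no `;` or top-level `,`).
#' @return An object of class `parsed_expression`: a list with `terms`
#'   (a tibble with columns `multiplicity`, `valence`, `kind`,
#'   `range_hi`) and `flags` (character vector).
#' @examples
#' parse_expression("40II+44I")
#' parse_expression("11II+1BI")
#' @export
parse_expression <- function(expr) {
  stopifnot(is.character(expr), length(expr) == 1L)
  x <- gsub(" ", "", expr, fixed = TRUE)
  flags <- character()
  if (grepl("^CA?\\.", x)) {
    flags <- "approximate"
    x <- sub("^CA?\\.", "", x)
  }
  tokens <- strsplit(x, "+", fixed = TRUE)[[1]]
  if (length(tokens) == 0L || any(!nzchar(tokens))) {
    .abort_unparseable(expr, "empty term")
  }
  terms <- vector("list", length(tokens))
  for (i in seq_along(tokens)) {
    tok <- tokens[i]
    if (grepl("^[0-9]+$", tok)) {
      terms[[i]] <- list(as.integer(tok), 1L, "chromosomal", NA_integer_)
    } else if (grepl("^[0-9]+F$", tok)) {
      flags <- union(flags, "fragment")
      terms[[i]] <- list(as.integer(sub("F$", "", tok)), 1L, "chromosomal",
                         NA_integer_)
    } else if (grepl("^[0-9]+B[IVX]*S?$", tok)) {
      flags <- union(flags, "has_b_chromosomes")
      m <- as.integer(sub("^([0-9]+)B.*$", "\\1", tok))
      terms[[i]] <- list(m, NA_integer_, "b_chromosome", NA_integer_)
    } else if (grepl("^[0-9]+[IVX]+$", tok)) {
      mult <- as.integer(sub("^([0-9]+).*$", "\\1", tok))
      val <- .roman_value(sub("^[0-9]+", "", tok))
      if (is.null(val)) .abort_unparseable(expr, tok)
      terms[[i]] <- list(mult, val, "chromosomal", NA_integer_)
    } else if (grepl("^[0-9]+-[0-9]+$", tok)) {
      if (i == 1L) .abort_unparseable(expr, tok) # leading range: upstream
      flags <- union(flags, "has_supernumerary_range")
      lo <- as.integer(sub("^([0-9]+)-.*$", "\\1", tok))
      hi <- as.integer(sub("^[0-9]+-", "", tok))
      terms[[i]] <- list(lo, NA_integer_, "supernumerary_range", hi)
    } else {
      .abort_unparseable(expr, tok)
    }
  }
  terms <- tibble::tibble(
    multiplicity = vapply(terms, function(t) t[[1]], integer(1)),
    valence      = vapply(terms, function(t) t[[2]], integer(1)),
    kind         = vapply(terms, function(t) t[[3]], character(1)),
    range_hi     = vapply(terms, function(t) t[[4]], integer(1))
  )
  if (!any(terms$kind == "chromosomal")) {
    .abort_unparseable(expr, "no chromosomal term")
  }
  structure(list(terms = terms, flags = flags),
            class = "parsed_expression")
}

.abort_unparseable <- function(expr, token) {
  rlang::abort(
    sprintf("unparseable expression '%s' (token '%s')", expr, token),
    class = "chromcurate_unparseable", token = token
  )
}

#' Evaluate a parsed expression to its total chromosome count
#'
#' Sums multiplicity x valence over the chromosomal terms; B-chromosome
#' and supernumerary-range terms contribute nothing to the standard
#' complement. `40II+44I` therefore evaluates to 40 + 40 + 44 = 124.
#'
#' @param parsed A `parsed_expression` from [parse_expression()].
#' @return A single non-negative integer count.
#' @export
evaluate_expression <- function(parsed) {
  stopifnot(inherits(parsed, "parsed_expression"))
  tt <- parsed$terms[parsed$terms$kind == "chromosomal", ]
  as.integer(sum(tt$multiplicity * tt$valence))
}

.standalone_range_re <- "^(CA?\\.)?([0-9]+) ?- ?([0-9]+)$"

.translate_one <- function(raw) {
  unparsed <- function(notes) {
    list(counts = integer(0), flags = character(0),
         status = "unparsed",
         notes = if (length(notes)) notes else "unrecognized record")
  }
  if (is.na(raw) || !nzchar(trimws(raw))) {
    return(unparsed("empty record"))
  }
  canon <- normalize_record(raw)
  alts <- tryCatch(split_alternatives(canon), error = function(e) e)
  if (inherits(alts, "error")) {
    return(unparsed(conditionMessage(alts)))
  }
  notes <- if (length(attr(alts, "dropped"))) {
    sprintf("dropped token '%s'", attr(alts, "dropped"))
  } else character(0)
  counts <- integer(0)
  flags <- character(0)
  for (alt in alts) {
    m <- regmatches(alt, regexec(.standalone_range_re, alt))[[1]]
    if (length(m)) {
      # standalone range: emit the two endpoints only ("40-44" -> 40 44)
      if (nzchar(m[2])) flags <- union(flags, "approximate")
      counts <- c(counts, as.integer(m[3]), as.integer(m[4]))
      next
    }
    p <- tryCatch(parse_expression(alt), error = function(e) e)
    if (inherits(p, "error")) {
      notes <- c(notes, conditionMessage(p))
    } else {
      counts <- c(counts, evaluate_expression(p))
      flags <- union(flags, p$flags)
    }
  }
  if (length(counts) == 0L) return(unparsed(notes))
  if (all(counts == 0L)) flags <- union(flags, "suspicious_zero")
  list(counts = counts, flags = flags, status = "parsed", notes = notes)
}

#' Translate raw count records into lists of integer counts
#'
#' The full record translation: normalize, split into alternatives,
#' then per alternative either expand a standalone range `a-b` into its
#' two endpoints or parse-and-evaluate the expression. Counts are
#' concatenated in input order with duplicates preserved (a record such
#' as `"11II+16I;19II"` yields 38 twice, one per observation).
#' Translation never throws: records the grammar does not recognize get
#' `status = "unparsed"` with diagnostic notes, so curation is total
#' over a table.
#'
#' @param record Character vector of raw record strings.
#' @return A tibble with one row per input record: `original` (the raw
#'   string, byte-for-byte), `counts` (list of integer vectors),
#'   `translation` (counts space-joined, for display), `n_counts`,
#'   `status` (`"parsed"`/`"unparsed"`), `flags` and `notes`
#'   (list columns of character vectors).
#' @examples
#' translate_record(c("40II+44I", "40-44", "11II+16I;19II"))
#' @export
translate_record <- function(record) {
  stopifnot(is.character(record))
  out <- lapply(record, .translate_one)
  tibble::tibble(
    original    = record,
    counts      = lapply(out, `[[`, "counts"),
    translation = vapply(out, function(o) paste(o$counts, collapse = " "),
                         character(1)),
    n_counts    = vapply(out, function(o) length(o$counts), integer(1)),
    status      = vapply(out, `[[`, character(1), "status"),
    flags       = lapply(out, `[[`, "flags"),
    notes       = lapply(out, `[[`, "notes")
  )
}

#' Lossy leading-integer baseline parse
#'
#' Returns the first maximal digit run of the normalized record as an
#' integer, or `NA` when the record contains no digits. This reproduces
#' the behavior of the CCDB CSV export's parsed-value column, which
#' reduces `"40II+44I"` to 40 and thereby loses the univalent and
#' bivalent structure; it is provided only for side-by-side comparison
#' with the full translation.
#'
#' @param record Character vector of raw record strings.
#' @return Integer vector, `NA` where no digits occur.
#' @examples
#' naive_leading_integer("40II+44I") # 40, not 124
#' @export
naive_leading_integer <- function(record) {
  stopifnot(is.character(record))
  vapply(record, function(r) {
    if (is.na(r) || !nzchar(trimws(r))) return(NA_integer_)
    x <- normalize_record(r)
    m <- regmatches(x, regexpr("[0-9]+", x))
    if (length(m)) as.integer(m) else NA_integer_
  }, integer(1), USE.NAMES = FALSE)
}
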