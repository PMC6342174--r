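# Ingest raw record tables (CCDB-style CSV exports), translate them,
# and build the integer-only long-format curated table with provenance.

.count_type_levels <- c("gametophytic", "sporophytic")

.map_count_type <- function(x) {
  x <- tolower(trimws(as.character(x)))
  dplyr::case_match(
    x,
    c("gametophytic", "n", "gametophyte", "haploid") ~ "gametophytic",
    c("sporophytic", "2n", "sporophyte", "diploid") ~ "sporophytic",
    .default = NA_character_
  )
}

#' Read raw chromosome-count records from a CSV export
#'
#' Supports the two common export dialects. *Long*: one record per row
#' with columns mapping to `taxon`, `count_type`, `record`. *Wide*: one
#' species per row with separate gametophytic (`n`) and sporophytic
#' (`2n`) record columns, which are melted to long form. `count_type`
#' cells accept `n`/`2n` as well as the full words. Empty or missing
#' record cells are skipped (tallied in the `"skipped"` attribute), as
#' are rows whose count type cannot be mapped.
#'
#' @param path Path to a UTF-8 CSV file with a header row.
#' @param dialect `"auto"` (default; inferred from the headers),
#'   `"long"` or `"wide"`.
#' @param col_map Optional named list overriding header names, e.g.
#'   `list(taxon = "resolved_name", record = "raw_count")`. Recognized
#'   keys: `taxon`, `count_type`, `record`, `gametophytic`,
#'   `sporophytic`.
#' @return A tibble of raw records with columns `taxon`, `count_type`,
#'   `record`, `source_id` (file row provenance), carrying attributes
#'   `"skipped"` (empty record cells) and `"bad_count_type"` (rows
#'   dropped for an unmappable count type).
#' @export
read_records <- function(path, dialect = c("auto", "long", "wide"),
                         col_map = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) {
    rlang::abort(sprintf("file not found: %s", path),
                 class = "chromcurate_io_error")
  }
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE, show_col_types = FALSE)
  hdr <- names(raw)
  pick <- function(key, candidates) {
    if (!is.null(col_map[[key]])) {
      if (!col_map[[key]] %in% hdr) {
        rlang::abort(sprintf("mapped column '%s' (%s) not in header",
                             col_map[[key]], key),
                     class = "chromcurate_config_error")
      }
      return(col_map[[key]])
    }
    hit <- hdr[tolower(hdr) %in% candidates]
    if (length(hit)) hit[1] else NA_character_
  }
  taxon_col <- pick("taxon", c("taxon", "species", "resolved_name", "name"))
  rec_col <- pick("record", c("record", "original", "count", "raw"))
  type_col <- pick("count_type", c("count_type", "type"))
  gam_col <- pick("gametophytic", c("gametophytic", "n"))
  spo_col <- pick("sporophytic", c("sporophytic", "2n"))
  if (dialect == "auto") {
    dialect <- if (!is.na(rec_col) && !is.na(type_col)) "long"
               else if (!is.na(gam_col) || !is.na(spo_col)) "wide"
               else rlang::abort(
                 "cannot infer dialect: need either {count_type, record} or {gametophytic, sporophytic} columns",
                 class = "chromcurate_config_error")
  }
  if (is.na(taxon_col)) {
    rlang::abort("missing taxon/species column",
                 class = "chromcurate_config_error")
  }
  if (dialect == "long") {
    for (nm in c(rec_col, type_col)) {
      if (is.na(nm)) rlang::abort("long dialect needs count_type and record columns",
                                  class = "chromcurate_config_error")
    }
    out <- tibble::tibble(
      taxon = raw[[taxon_col]],
      count_type = .map_count_type(raw[[type_col]]),
      record = raw[[rec_col]],
      source_id = sprintf("%s:%d", basename(path), seq_len(nrow(raw)) + 1L)
    )
  } else {
    present <- c(gametophytic = gam_col, sporophytic = spo_col)
    present <- present[!is.na(present)]
    if (!length(present)) {
      rlang::abort("wide dialect needs a gametophytic and/or sporophytic column",
                   class = "chromcurate_config_error")
    }
    out <- purrr::imap_dfr(present, function(col, type) {
      tibble::tibble(
        taxon = raw[[taxon_col]],
        count_type = type,
        record = raw[[col]],
        source_id = sprintf("%s:%d:%s", basename(path),
                            seq_len(nrow(raw)) + 1L, type)
      )
    })
  }
  empty <- is.na(out$record) | !nzchar(trimws(out$record))
  bad_type <- !empty & is.na(out$count_type)
  res <- out[!empty & !bad_type, ]
  attr(res, "skipped") <- sum(empty)
  attr(res, "bad_count_type") <- sum(bad_type)
  res
}

#' Curate raw records into an integer-only long table
#'
#' Translates every record with [translate_record()] and *explodes*
#' parsed records into one row per integer count, so a record like
#' `"11II+16I;19II"` (two observations of 38) becomes two rows sharing
#' one `record_index`. Records the grammar cannot read land in a
#' `rejects` table with their diagnostic notes; nothing ever crashes
#' curation. Translated counts of zero are excluded from the curated
#' rows (the curated table holds positive integers only) and tallied.
#'
#' @param records A tibble of raw records with columns `taxon`,
#'   `count_type`, `record` (as from [read_records()] or [messify()]);
#'   `source_id` is optional.
#' @return An object of class `curated_records`: a list with
#'   - `rows`: tibble `taxon`, `count_type`, `count`, `translation`,
#'     `original`, `flags` (list column), `record_index`;
#'   - `rejects`: tibble `taxon`, `count_type`, `original`, `reason`,
#'     `record_index`;
#'   - `n_records`, `n_zero_dropped`.
#' @examples
#' recs <- tibble::tibble(taxon = "Gentiana terglouensis",
#'                        count_type = "sporophytic",
#'                        record = "11II+16I;19II")
#' curate_records(recs)
#' @export
curate_records <- function(records) {
  records <- tibble::as_tibble(records)
  need <- c("taxon", "count_type", "record")
  if (!all(need %in% names(records))) {
    rlang::abort(sprintf("records must have columns: %s",
                         paste(need, collapse = ", ")),
                 class = "chromcurate_config_error")
  }
  n <- nrow(records)
  tr <- translate_record(if (n) as.character(records$record) else character(0))
  parsed <- tr$status == "parsed"
  n_zero <- 0L
  if (n) {
    rows <- tibble::tibble(
      taxon = records$taxon,
      count_type = records$count_type,
      translation = tr$translation,
      original = tr$original,
      counts = tr$counts,
      flags = tr$flags,
      record_index = seq_len(n)
    )[parsed, ]
    rows <- tidyr::unnest(rows, "counts")
    names(rows)[names(rows) == "counts"] <- "count"
    n_zero <- sum(rows$count == 0L)
    rows <- rows[rows$count > 0L,
                 c("taxon", "count_type", "count", "translation",
                   "original", "flags", "record_index")]
    rejects <- tibble::tibble(
      taxon = records$taxon[!parsed],
      count_type = records$count_type[!parsed],
      original = tr$original[!parsed],
      reason = vapply(tr$notes[!parsed], paste, character(1),
                      collapse = "; "),
      record_index = which(!parsed)
    )
  } else {
    rows <- tibble::tibble(taxon = character(), count_type = character(),
                           count = integer(), translation = character(),
                           original = character(), flags = list(),
                           record_index = integer())
    rejects <- tibble::tibble(taxon = character(), count_type = character(),
                              original = character(), reason = character(),
                              record_index = integer())
  }
  structure(list(rows = rows, rejects = rejects, n_records = n,
                 n_zero_dropped = n_zero),
            class = "curated_records")
}

#' @export
print.curated_records <- function(x, ...) {
  cat(sprintf(
    "<curated_records> %d source records -> %d curated rows (%d rejected)\n",
    x$n_records, nrow(x$rows), nrow(x$rejects)))
  print(x$rows, ...)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a curated table into its long row tibble
#'
#' @param x A `curated_records` object.
#' @param ... Unused.
#' @return The curated rows tibble (one row per taxon/count-type/count).
#' @method tidy curated_records
#' @export
tidy.curated_records <- function(x, ...) x$rows

#' One-row summary of a curation run
#'
#' @param x A `curated_records` object.
#' @param ... Unused.
#' @return A one-row tibble: records in, records parsed/rejected, rows
#'   out, distinct taxa, and the proportion parsed.
#' @method glance curated_records
#' @export
glance.curated_records <- function(x, ...) {
  n_rej <- nrow(x$rejects)
  tibble::tibble(
    n_records = x$n_records,
    n_parsed = x$n_records - n_rej,
    n_rejected = n_rej,
    n_rows = nrow(x$rows),
    n_taxa = dplyr::n_distinct(x$rows$taxon),
    parse_rate = if (x$n_records) (x$n_records - n_rej) / x$n_records else NA_real_
  )
}

.genus_of <- function(taxon) {
  tolower(vapply(strsplit(trimws(taxon), "\\s+"),
                 function(w) if (length(w)) w[1] else "", character(1)))
}

#' Filter a curated table by taxa and count type
#'
#' Restricts the curated rows to a genus (prefix match on the first
#' word of the binomial, case-insensitive) or an explicit species list
#' (exact, case-insensitive match on the full name), and to a count
#' type: `"gametophytic"` (n), `"sporophytic"` (2n), or `"combined"`
#' (both, untransformed). With `haploid_double = TRUE`, gametophytic
#' counts are doubled onto the 2n scale for a common axis; the default
#' keeps every row at its reported scale.
#'
#' @param x A `curated_records` object.
#' @param genus Genus name (single string), or `NULL`.
#' @param species Character vector of species binomials, or `NULL`.
#'   At least one of `genus`/`species` must be given.
#' @param count_type `"combined"` (default), `"gametophytic"` or
#'   `"sporophytic"`.
#' @param haploid_double Double gametophytic counts to the 2n scale?
#' @return A `curated_records` object with the restricted rows; rejects
#'   are carried through unchanged for reporting.
#' @export
filter_curated <- function(x, genus = NULL, species = NULL,
                           count_type = c("combined", .count_type_levels),
                           haploid_double = FALSE) {
  stopifnot(inherits(x, "curated_records"))
  count_type <- match.arg(count_type)
  if (is.null(genus) && is.null(species)) {
    rlang::abort("give a genus or a species list to filter on",
                 class = "chromcurate_validation_error")
  }
  rows <- x$rows
  keep <- rep(FALSE, nrow(rows))
  if (!is.null(genus)) {
    if (!nzchar(trimws(genus[1]))) {
      rlang::abort("empty genus selection",
                   class = "chromcurate_validation_error")
    }
    keep <- keep | .genus_of(rows$taxon) == tolower(trimws(genus[1]))
  }
  if (!is.null(species)) {
    if (!length(species)) {
      rlang::abort("empty species selection",
                   class = "chromcurate_validation_error")
    }
    keep <- keep | tolower(trimws(rows$taxon)) %in% tolower(trimws(species))
  }
  rows <- rows[keep, ]
  if (count_type != "combined") rows <- rows[rows$count_type == count_type, ]
  if (haploid_double) {
    gam <- rows$count_type == "gametophytic"
    rows$count[gam] <- rows$count[gam] * 2L
    rows$count_type[gam] <- "sporophytic"
  }
  out <- x
  out$rows <- rows
  out
}

.flags_chr <- function(flags) {
  vapply(flags, paste, character(1), collapse = ";")
}

#' Write a curated table (and optionally its rejects) to CSV
#'
#' The curated CSV keeps full provenance per row: the integer count,
#' the whole translation of its source record, the original record
#' string byte-for-byte, the flags, and `naive_parse` — the lossy
#' leading-integer value a CCDB CSV export would have shown — for
#' side-by-side comparison. Round-trips through [read_curated_csv()].
#'
#' @param x A `curated_records` object.
#' @param path Output CSV path (UTF-8).
#' @param rejects_path Optional path for a rejects CSV
#'   (`taxon`, `count_type`, `original`, `reason`).
#' @return `x`, invisibly.
#' @export
write_curated_csv <- function(x, path, rejects_path = NULL) {
  stopifnot(inherits(x, "curated_records"))
  out <- tibble::tibble(
    taxon = x$rows$taxon,
    count_type = x$rows$count_type,
    count = x$rows$count,
    translation = x$rows$translation,
    original = x$rows$original,
    flags = .flags_chr(x$rows$flags),
    naive_parse = if (nrow(x$rows)) naive_leading_integer(x$rows$original)
                  else integer(0),
    record_index = x$rows$record_index
  )
  readr::write_csv(out, path, progress = FALSE)
  if (!is.null(rejects_path)) {
    readr::write_csv(x$rejects[, c("taxon", "count_type", "original",
                                   "reason")],
                     rejects_path, progress = FALSE)
  }
  invisible(x)
}

#' Read a curated CSV back into a `curated_records` object
#'
#' @param path A CSV written by [write_curated_csv()].
#' @return A `curated_records` object (with an empty rejects table).
#' @export
read_curated_csv <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(
    taxon = "c", count_type = "c", count = "i", translation = "c",
    original = "c", flags = "c", naive_parse = "i", record_index = "i"
  ), progress = FALSE, show_col_types = FALSE)
  rows <- tibble::tibble(
    taxon = df$taxon, count_type = df$count_type, count = df$count,
    translation = df$translation, original = df$original,
    flags = strsplit(ifelse(is.na(df$flags), "", df$flags), ";",
                     fixed = TRUE),
    record_index = df$record_index
  )
  structure(list(rows = rows,
                 rejects = tibble::tibble(taxon = character(),
                                          count_type = character(),
                                          original = character(),
                                          reason = character(),
                                          record_index = integer()),
                 n_records = dplyr::n_distinct(rows$record_index),
                 n_zero_dropped = 0L),
            class = "curated_records")
}
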