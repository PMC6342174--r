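# Seeded synthetic data: ground-truth count tables with known base
# numbers and ploidy levels, plus a "messifier" that renders each true
# record into one of the raw notation pattern families the parser
# documents. Generator and grammar share this registry by construction,
# so a family the messifier emits is always one the translator can
# invert — the round-trip property tested end-to-end.

# sample() treats a length-1 vector as 1:n; .resample never does
.resample <- function(x, ...) x[sample.int(length(x), ...)]

.render_bivalent <- function(count) {
  # split 2n into k bivalents + r univalents, 2k + r = count; k drawn
  # so both configurations are usually present
  k <- .resample(seq.int(ceiling(count / 4), floor(count / 2)), 1)
  r <- count - 2L * k
  if (r > 0) sprintf("%dII+%dI", k, r) else sprintf("%dII", k)
}

.pattern_families <- list(
  plain = list(
    applicable = function(counts) length(counts) == 1L,
    render = function(counts) as.character(counts)
  ),
  bivalent = list(
    applicable = function(counts) length(counts) == 1L && counts >= 2L,
    render = function(counts) .render_bivalent(counts)
  ),
  b_chromosome = list(
    applicable = function(counts) length(counts) == 1L,
    render = function(counts) {
      base <- if (counts >= 2L && stats::runif(1) < 0.5) {
        .render_bivalent(counts)
      } else {
        as.character(counts)
      }
      m <- sample(1:3, 1)
      sprintf("%s+%d%s", base, m, sample(c("B", "Bs", "BI"), 1))
    }
  ),
  fragment = list(
    applicable = function(counts) length(counts) == 1L,
    render = function(counts) sprintf("%df", counts)
  ),
  approximate = list(
    applicable = function(counts) length(counts) == 1L,
    render = function(counts) sprintf("%s%d", sample(c("c.", "ca."), 1),
                                      counts)
  ),
  list = list(
    applicable = function(counts) length(counts) >= 2L,
    render = function(counts) {
      s <- as.character(counts)
      if (stats::runif(1) < 0.5) { # record-multiplicity metadata
        k <- length(counts)
        s[k] <- sprintf("%s(%s)", s[k],
                        paste(sample(1:4, k, replace = TRUE),
                              collapse = ", "))
      }
      paste(s, collapse = ", ")
    }
  ),
  alternatives = list(
    applicable = function(counts) length(counts) >= 2L,
    render = function(counts) {
      paste(vapply(counts, function(ci) {
        if (ci >= 2L) .render_bivalent(ci) else as.character(ci)
      }, character(1)), collapse = ";")
    }
  ),
  range = list(
    applicable = function(counts) length(counts) == 2L &&
      counts[1] != counts[2],
    render = function(counts) sprintf("%d-%d", min(counts), max(counts))
  ),
  etc = list(
    applicable = function(counts) length(counts) >= 2L,
    render = function(counts) {
      sprintf("%s,%s", paste(counts, collapse = ","),
              sample(c("etc", "etc."), 1))
    }
  )
)

#' Names of the raw-notation pattern families
#'
#' The families the synthetic messifier can emit; every one of them is
#' invertible by [translate_record()].
#' @return Character vector of family names.
#' @export
pattern_family_names <- function() names(.pattern_families)

.syllables <- c("an", "bel", "cra", "del", "eri", "fil", "gen", "hel",
                "ix", "lon", "mer", "not", "oph", "pter", "ris", "sel",
                "thy", "ul", "ven", "zon")

.make_genus <- function(taken = character()) {
  repeat {
    s <- sample(.syllables, 3)
    g <- paste0(toupper(substr(s[1], 1, 1)), substr(s[1], 2, nchar(s[1])),
                s[2], s[3], "ia")
    if (!g %in% taken) return(g)
  }
}

.make_epithet <- function() paste0(paste(sample(.syllables, 2), collapse = ""),
                                   sample(c("a", "um", "is", "ense"), 1))

#' Generate a seeded ground-truth chromosome-count table
#'
#' Emulates the statistical structure a genus search displays: per
#' genus a base number x, per species a small set of even ploidy levels
#' (a polyploid series 2x, 4x, ...), several records per species, a
#' stated fraction of aneuploid records deviating from p * x by 1-2
#' chromosomes, and a mix of sporophytic (2n) and gametophytic
#' (n = 2n/2) observations. All randomness is fixed by `seed`.
#'
#' @param n_genera,species_per_genus Table dimensions.
#' @param x_range Integer interval for the genus base numbers
#'   (default 7-21, the common range for flowering plants; ferns run
#'   higher).
#' @param max_ploidy Highest euploid level (even, >= 2).
#' @param aneuploid_fraction Fraction of drawn counts perturbed by a
#'   +/-1 or +/-2 aneuploid offset.
#' @param gametophytic_prob Probability that a record with even counts
#'   is reported as gametophytic (n) rather than sporophytic (2n).
#' @param two_count_prob Probability that a record reports two counts
#'   (a multi-observation record).
#' @param records_per_species Integer vector to draw each species'
#'   record number from (default 1-5).
#' @param seed Integer seed fixing all randomness.
#' @return An object of class `chrom_truth`: list with `records` (a
#'   tibble: `record_id`, `taxon`, `genus`, `base_x`, `count_type`,
#'   `counts` (list, on the reported scale), `ploidies` (list),
#'   `euploid` (list)), and `params`.
#' @export
generate_ground_truth <- function(n_genera = 3, species_per_genus = 4,
                                  x_range = c(7, 21), max_ploidy = 8,
                                  aneuploid_fraction = 0.1,
                                  gametophytic_prob = 0.3,
                                  two_count_prob = 0.25,
                                  records_per_species = 1:5,
                                  seed = 1L) {
  if (n_genera < 1 || species_per_genus < 1 ||
      length(x_range) != 2 || x_range[1] < 1 || x_range[2] < x_range[1] ||
      max_ploidy < 2 || max_ploidy %% 2 != 0 ||
      aneuploid_fraction < 0 || aneuploid_fraction > 1) {
    rlang::abort("invalid generator parameters",
                 class = "chromcurate_validation_error")
  }
  set.seed(seed)
  levels_all <- seq(2L, as.integer(max_ploidy), by = 2L)
  recs <- list()
  rid <- 0L
  genera <- character(0)
  for (g in seq_len(n_genera)) {
    genus <- .make_genus(genera)
    genera <- c(genera, genus)
    base_x <- .resample(seq.int(x_range[1], x_range[2]), 1)
    for (s in seq_len(species_per_genus)) {
      taxon <- paste(genus, .make_epithet())
      n_lev <- .resample(seq_len(min(3, length(levels_all))), 1)
      lev <- sort(.resample(levels_all, n_lev))
      n_rec <- .resample(records_per_species, 1)
      for (r in seq_len(n_rec)) {
        k <- if (stats::runif(1) < two_count_prob) 2L else 1L
        p <- .resample(lev, k, replace = TRUE)
        cnt <- p * base_x
        anu <- stats::runif(k) < aneuploid_fraction
        cnt[anu] <- cnt[anu] +
          sample(c(-2L, -1L, 1L, 2L), sum(anu), replace = TRUE)
        cnt <- pmax(cnt, 1L)
        type <- if (all(cnt %% 2L == 0L) &&
                    stats::runif(1) < gametophytic_prob) {
          "gametophytic"
        } else {
          "sporophytic"
        }
        reported <- if (type == "gametophytic") cnt %/% 2L else cnt
        rid <- rid + 1L
        recs[[rid]] <- tibble::tibble(
          record_id = rid, taxon = taxon, genus = genus,
          base_x = as.integer(base_x), count_type = type,
          counts = list(as.integer(reported)),
          ploidies = list(as.integer(p)),
          euploid = list(!anu)
        )
      }
    }
  }
  structure(
    list(records = dplyr::bind_rows(recs),
         params = list(n_genera = n_genera,
                       species_per_genus = species_per_genus,
                       x_range = x_range, max_ploidy = max_ploidy,
                       aneuploid_fraction = aneuploid_fraction,
                       gametophytic_prob = gametophytic_prob,
                       two_count_prob = two_count_prob, seed = seed)),
    class = "chrom_truth")
}

#' @export
print.chrom_truth <- function(x, ...) {
  cat(sprintf("<chrom_truth> %d records, %d taxa, seed %d\n",
              nrow(x$records), dplyr::n_distinct(x$records$taxon),
              x$params$seed))
  print(x$records, ...)
  invisible(x)
}

#' Flatten a ground truth into one row per true count
#'
#' @param truth A `chrom_truth` object.
#' @return A tibble `taxon`, `count_type`, `count` (reported scale).
#' @export
truth_counts <- function(truth) {
  stopifnot(inherits(truth, "chrom_truth"))
  truth$records |>
    dplyr::select("taxon", "count_type", count = "counts") |>
    tidyr::unnest("count")
}

#' Render true counts into raw notation record strings
#'
#' Each ground-truth record is written as exactly one raw string, using
#' a pattern family sampled from `style_weights`: plain integers,
#' bivalent/univalent splits (`40II+44I`), B-chromosome additions
#' (total unchanged), comma lists with optional parenthetical metadata,
#' semicolon alternatives, `f` suffixes, approximate prefixes,
#' standalone endpoint ranges, and `etc` injection. A family that
#' cannot represent a record (e.g. the range family for a single-count
#' record) is never sampled for it.
#'
#' @param truth A `chrom_truth` object.
#' @param style_weights Named numeric vector of sampling weights over
#'   [pattern_family_names()]; missing families get weight 0. Defaults
#'   to a mix favoring plain integers and meiotic configurations.
#' @param seed Integer seed for the family sampling.
#' @return A raw-record tibble (`taxon`, `count_type`, `record`,
#'   `source_id`) suitable for [curate_records()] or
#'   [write_records_csv()].
#' @export
messify <- function(truth, style_weights = NULL, seed = 1L) {
  stopifnot(inherits(truth, "chrom_truth"))
  default_w <- c(plain = 0.25, bivalent = 0.20, b_chromosome = 0.12,
                 fragment = 0.06, approximate = 0.07, list = 0.10,
                 alternatives = 0.10, range = 0.05, etc = 0.05)
  w <- if (is.null(style_weights)) default_w else {
    if (is.null(names(style_weights)) ||
        !all(names(style_weights) %in% names(.pattern_families))) {
      rlang::abort("style_weights must be named after pattern families",
                   class = "chromcurate_validation_error")
    }
    out <- stats::setNames(numeric(length(.pattern_families)),
                           names(.pattern_families))
    out[names(style_weights)] <- style_weights
    out
  }
  if (abs(sum(w) - 1) > 1e-8) {
    rlang::abort("style weights must sum to 1",
                 class = "chromcurate_validation_error")
  }
  set.seed(seed)
  rec <- truth$records
  out <- character(nrow(rec))
  for (i in seq_len(nrow(rec))) {
    counts <- rec$counts[[i]]
    ok <- vapply(.pattern_families, function(f) f$applicable(counts),
                 logical(1)) & w > 0
    if (!any(ok)) ok <- vapply(.pattern_families,
                               function(f) f$applicable(counts), logical(1))
    fam <- sample(names(.pattern_families)[ok], 1,
                  prob = if (sum(w[ok]) > 0) w[ok] else NULL)
    out[i] <- .pattern_families[[fam]]$render(counts)
  }
  tibble::tibble(
    taxon = rec$taxon,
    count_type = rec$count_type,
    record = out,
    source_id = sprintf("sim:%d", rec$record_id)
  )
}

#' Write a raw-record table in the long CSV dialect
#'
#' @param records A raw-record tibble (`taxon`, `count_type`, `record`).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_records_csv <- function(records, path) {
  readr::write_csv(
    tibble::as_tibble(records)[, c("taxon", "count_type", "record")],
    path, progress = FALSE)
  invisible(path)
}
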