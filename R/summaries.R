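# Quantitative summaries of a curated table: per-species record
# frequencies, percentage matrices, modal counts, intraspecific
# variation, and ploidy levels against a base chromosome number x.

.freq_input <- function(x) {
  rows <- if (inherits(x, "curated_records")) x$rows else tibble::as_tibble(x)
  if (!all(c("taxon", "count") %in% names(rows))) {
    rlang::abort("need a curated table with 'taxon' and 'count' columns",
                 class = "chromcurate_config_error")
  }
  rows
}

#' Tally record frequencies per (species, count)
#'
#' An exact multiset tally: the frequency of a (species, count) pair is
#' the number of curated records carrying that count — duplicate
#' records are never collapsed, since each is an independent
#' observation in the database. Ordered species-lexicographic, count
#' ascending.
#'
#' @param x A `curated_records` object, or any data frame with `taxon`
#'   and `count` columns.
#' @return A tibble of class `chrom_freq` with columns `species`,
#'   `count`, `n_records`.
#' @export
count_frequencies <- function(x) {
  rows <- .freq_input(x)
  out <- rows |>
    dplyr::count(species = .data$taxon, count = .data$count,
                 name = "n_records") |>
    dplyr::arrange(.data$species, .data$count)
  class(out) <- c("chrom_freq", class(out))
  out
}

#' Percentage-of-records matrix for a heatmap
#'
#' Each cell is 100 x (records of that species at that count) /
#' (total records for that species), so every species row sums to 100
#' and species with few records are directly comparable to well-sampled
#' ones. `normalize = "global"` divides by the grand total instead.
#' Absent (species, count) combinations are 0.
#'
#' @param freq A `chrom_freq` tibble from [count_frequencies()].
#' @param normalize `"species"` (default) or `"global"`.
#' @return A numeric matrix, rows = species (lexicographic), columns =
#'   counts (ascending, as character names).
#' @export
heatmap_percentages <- function(freq, normalize = c("species", "global")) {
  normalize <- match.arg(normalize)
  stopifnot(is.data.frame(freq), nrow(freq) > 0)
  wide <- freq |>
    dplyr::arrange(.data$species, .data$count) |>
    tidyr::pivot_wider(names_from = "count", values_from = "n_records",
                       values_fill = 0L, names_sort = TRUE)
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- wide$species
  denom <- if (normalize == "species") rowSums(m) else sum(m)
  100 * sweep(m, 1, if (normalize == "species") denom else rep(denom, nrow(m)),
              "/")
}

#' Modal chromosome count(s) of a species
#'
#' All counts achieving the species' maximum record frequency,
#' ascending; ties are reported in full, never broken.
#'
#' @param freq A `chrom_freq` tibble.
#' @param species A species name present in `freq`.
#' @return Integer vector of modal counts.
#' @export
species_mode <- function(freq, species) {
  f <- freq[freq$species == species, ]
  if (!nrow(f)) {
    rlang::abort(sprintf("species '%s' not in frequency table", species),
                 class = "chromcurate_lookup_error")
  }
  sort(f$count[f$n_records == max(f$n_records)])
}

#' Species with records at more than one chromosome number
#'
#' Intraspecific count variation — a species recorded at several
#' distinct numbers — often signals a polyploid series or unrecognized
#' autopolyploidy (e.g. *Anemia adiantifolia* recorded at both 76 and
#' 152).
#'
#' @param freq A `chrom_freq` tibble.
#' @return A tibble `species`, `n_distinct_counts`, `counts` (list
#'   column of ascending distinct counts), only species with >= 2
#'   distinct counts.
#' @export
detect_intraspecific_variation <- function(freq) {
  freq |>
    dplyr::group_by(.data$species) |>
    dplyr::summarise(
      n_distinct_counts = dplyr::n_distinct(.data$count),
      counts = list(sort(unique(.data$count)))) |>
    dplyr::filter(.data$n_distinct_counts >= 2L) |>
    dplyr::arrange(.data$species)
}

#' Infer ploidy level against a base chromosome number
#'
#' With base number x, a sporophytic count 2n near p * x indicates
#' ploidy level p: the Blechnum count 124 with x = 31 gives p = 4, a
#' tetraploid. Gametophytic counts are doubled onto the 2n scale first.
#' p is the nearest positive integer to count/x (exact halves round
#' up); the residual count - p*x measures aneuploidy, and a count is
#' euploid only when that residual is exactly 0 — near-misses are
#' reported, never snapped.
#'
#' @param count Integer vector of chromosome counts (>= 1).
#' @param count_type `"gametophytic"` or `"sporophytic"`; recycled.
#' @param base_x The base chromosome number x (single positive integer).
#' @return A tibble of class `chrom_ploidy`: `count`, `count_type`,
#'   `scaled_2n`, `base_x`, `ploidy`, `residual`, `euploid`.
#' @examples
#' infer_ploidy(124, "sporophytic", base_x = 31) # tetraploid
#' infer_ploidy(c(76, 228, 304), "sporophytic", base_x = 38)
#' @export
infer_ploidy <- function(count, count_type = "sporophytic", base_x) {
  if (length(base_x) != 1L || is.na(base_x) || base_x < 1 ||
      base_x != as.integer(base_x)) {
    rlang::abort("base_x must be a single positive integer",
                 class = "chromcurate_validation_error")
  }
  if (any(is.na(count)) || any(count < 1)) {
    rlang::abort("counts must be positive integers",
                 class = "chromcurate_validation_error")
  }
  count_type <- rep_len(count_type, length(count))
  if (!all(count_type %in% .count_type_levels)) {
    rlang::abort("count_type must be 'gametophytic' or 'sporophytic'",
                 class = "chromcurate_validation_error")
  }
  scaled <- as.integer(ifelse(count_type == "gametophytic", 2L * count, count))
  p <- pmax(1L, as.integer(floor(scaled / base_x + 0.5)))
  out <- tibble::tibble(
    count = as.integer(count),
    count_type = count_type,
    scaled_2n = scaled,
    base_x = as.integer(base_x),
    ploidy = p,
    residual = scaled - p * as.integer(base_x),
    euploid = scaled %% as.integer(base_x) == 0L
  )
  class(out) <- c("chrom_ploidy", class(out))
  out
}

#' Ploidy assignments for every row of a curated table
#'
#' @param x A `curated_records` object or data frame with `taxon`,
#'   `count_type`, `count`.
#' @param base_x Base chromosome number x.
#' @return A `chrom_ploidy` tibble with a leading `taxon` column.
#' @export
ploidy_table <- function(x, base_x) {
  rows <- .freq_input(x)
  pl <- infer_ploidy(rows$count, rows$count_type, base_x)
  out <- dplyr::bind_cols(tibble::tibble(taxon = rows$taxon), pl)
  class(out) <- c("chrom_ploidy", class(tibble::tibble()))
  out
}

#' Suggest candidate base numbers (heuristic)
#'
#' Proposes x as the greatest common divisor of the counts after
#' halving (2n = p * x with p even implies x divides count/2 for
#' euploid series). This is a rough screening heuristic only: the base
#' number of a lineage is cytological knowledge and should be supplied
#' by the user whenever known.
#'
#' @param counts Integer vector of sporophytic (2n) counts.
#' @param min_x Smallest x worth reporting (default 2).
#' @return Integer vector of candidate base numbers, largest first
#'   (the GCD and its divisors >= `min_x`).
#' @export
suggest_base_number <- function(counts, min_x = 2L) {
  stopifnot(length(counts) >= 1, all(counts >= 1))
  gcd2 <- function(a, b) if (b == 0) a else gcd2(b, a %% b)
  g <- Reduce(gcd2, as.integer(counts))
  divs <- which(g %% seq_len(g) == 0L)
  sort(divs[divs >= min_x & divs <= max(counts)], decreasing = TRUE)
}
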