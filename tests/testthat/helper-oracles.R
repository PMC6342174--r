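# Shared fixtures and independent oracles for the test suite.

# The documented example records and their expected clean translations
# (standalone range, supernumerary range + fragment + etc, semicolon
# alternatives of meiotic configurations, comma list with B chromosomes
# and parenthetical metadata, bivalents + one B chromosome).
example_records <- tibble::tribble(
  ~taxon, ~record, ~translation,
  "Gomphrena globosa", "40‐44", "40 44",
  "Barnardia japonica", "34+0‐13,16,27,30f,etc", "34 16 27 30",
  "Gentiana terglouensis", "11II+16I;19II", "38 38",
  "Chrysanthemum morifolium",
  "62+1B, 62+2Bs, 63, 63+1B, 64(1, 1, 1, 4, 1, 1)", "62 62 63 63 64",
  "Heracleum sphondylium", "11II+1BI", "22"
)

# Brute-force valence oracle: replace each chromosomal term by
# `multiplicity` copies of `valence` and sum the expanded list.
brute_force_total <- function(terms) {
  chrom <- terms[terms$kind == "chromosomal", ]
  sum(unlist(Map(function(m, v) rep(v, m), chrom$multiplicity,
                 chrom$valence)))
}

# Random additive expression with its independently computed total:
# builds the term list first, computes the expected value by expansion,
# then renders the string the parser will see.
random_expression <- function() {
  n_extra <- sample(0:3, 1)
  kinds <- c("chromosomal",
             sample(c("chromosomal", "b_chromosome", "range"), n_extra,
                    replace = TRUE, prob = c(0.6, 0.25, 0.15)))
  toks <- character(length(kinds))
  terms <- list()
  for (i in seq_along(kinds)) {
    if (kinds[i] == "chromosomal") {
      m <- sample(0:60, 1)
      v <- sample(1:8, 1)
      terms[[i]] <- list(multiplicity = m, valence = v, kind = "chromosomal")
      toks[i] <- if (v == 1 && runif(1) < 0.5) as.character(m) else {
        paste0(m, as.character(utils::as.roman(v)))
      }
    } else if (kinds[i] == "b_chromosome") {
      m <- sample(1:3, 1)
      terms[[i]] <- list(multiplicity = m, valence = NA, kind = "b_chromosome")
      toks[i] <- paste0(m, sample(c("B", "BS", "BI"), 1))
    } else {
      lo <- sample(0:10, 1)
      terms[[i]] <- list(multiplicity = lo, valence = NA, kind = "range")
      toks[i] <- paste0(lo, "-", lo + sample(1:13, 1))
    }
  }
  expected <- sum(vapply(terms, function(t) {
    if (t$kind == "chromosomal") sum(rep(t$valence, t$multiplicity)) else 0
  }, numeric(1)))
  list(expr = paste(toks, collapse = "+"), expected = as.integer(expected),
       terms = terms)
}

# A small polyploid-series table in the style of a fern genus search:
# diploid through octoploid on base number x = 38, with one species
# recorded at two counts.
anemia_style_rows <- function() {
  tibble::tibble(
    taxon = c("Anemia adiantifolia", "Anemia adiantifolia",
              "Anemia adiantifolia", "Anemia phyllitidis",
              "Anemia tomentosa", "Anemia mexicana"),
    count_type = "sporophytic",
    record = c("76", "38II", "152", "228", "304", "76")
  )
}

curate_fixture <- function(rows = anemia_style_rows()) {
  curate_records(rows)
}
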