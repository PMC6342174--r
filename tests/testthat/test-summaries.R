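test_that("frequency tallies match a brute-force multiset count", {
  cur <- curate_records(tibble::tibble(
    taxon = "Gentiana terglouensis", count_type = "sporophytic",
    record = "11II+16I;19II"))
  freq <- count_frequencies(cur)
  expect_equal(freq$n_records, 2L) # two observations of 38
  expect_equal(freq$count, 38L)

  set.seed(3)
  for (i in 1:10) {
    rows <- tibble::tibble(
      taxon = sample(paste("Sp", letters[1:4]), 30, replace = TRUE),
      count_type = "sporophytic",
      count = sample(c(14L, 28L, 42L), 30, replace = TRUE))
    freq <- count_frequencies(rows)
    # independent oracle: nested table() tally
    tab <- table(rows$taxon, rows$count)
    for (j in seq_len(nrow(freq))) {
      expect_equal(freq$n_records[j],
                   unname(tab[freq$species[j], as.character(freq$count[j])]))
    }
    # conservation: frequencies sum to the row count
    expect_equal(sum(freq$n_records), nrow(rows))
    # ordering: species lexicographic, count ascending within species
    expect_false(is.unsorted(freq$species))
  }
})

test_that("heatmap percentages normalize per species", {
  freq <- count_frequencies(tibble::tibble(
    taxon = c(rep("Anemia adiantifolia", 4), "Anemia phyllitidis"),
    count = c(76L, 76L, 76L, 152L, 228L)))
  m <- heatmap_percentages(freq)
  expect_equal(m["Anemia adiantifolia", "76"], 75)
  expect_equal(m["Anemia adiantifolia", "152"], 25)
  expect_equal(m["Anemia phyllitidis", "228"], 100)
  expect_equal(m["Anemia phyllitidis", "76"], 0) # absent pair is 0
  expect_equal(unname(rowSums(m)), c(100, 100), tolerance = 1e-9)

  g <- heatmap_percentages(freq, normalize = "global")
  expect_equal(sum(g), 100, tolerance = 1e-9)
})

test_that("modal counts report ties in full", {
  freq <- count_frequencies(tibble::tibble(
    taxon = c("A x", "A x", "A x", "B y", "B y"),
    count = c(38L, 38L, 19L, 76L, 152L)))
  expect_equal(species_mode(freq, "A x"), 38L)
  expect_equal(species_mode(freq, "B y"), c(76L, 152L)) # tie, ascending
  expect_error(species_mode(freq, "C z"),
               class = "chromcurate_lookup_error")

  set.seed(5)
  for (i in 1:10) {
    counts <- sample(10:15, 20, replace = TRUE)
    freq <- count_frequencies(tibble::tibble(taxon = "S p",
                                             count = counts))
    tab <- table(counts)
    expect_equal(species_mode(freq, "S p"),
                 sort(as.integer(names(tab)[tab == max(tab)])))
  }
})

test_that("intraspecific variation lists species with multiple counts", {
  freq <- count_frequencies(tibble::tibble(
    taxon = c("Anemia adiantifolia", "Anemia adiantifolia",
              "Anemia mexicana"),
    count = c(76L, 152L, 76L)))
  v <- detect_intraspecific_variation(freq)
  expect_equal(v$species, "Anemia adiantifolia")
  expect_equal(v$counts[[1]], c(76L, 152L))

  set.seed(8)
  rows <- tibble::tibble(
    taxon = sample(paste("Sp", letters[1:6]), 60, replace = TRUE),
    count = sample(c(20L, 40L, 60L), 60, replace = TRUE))
  v <- detect_intraspecific_variation(count_frequencies(rows))
  oracle <- names(which(tapply(rows$count, rows$taxon,
                               dplyr::n_distinct) >= 2))
  expect_setequal(v$species, oracle)
})

test_that("ploidy inference reproduces the worked polyploid series", {
  # tetraploid fern count: 124 on base number x = 31
  expect_equal(infer_ploidy(124, "sporophytic", 31)$ploidy, 4L)
  expect_true(infer_ploidy(124, "sporophytic", 31)$euploid)
  # diploid/hexaploid/octoploid series on x = 38
  pl <- infer_ploidy(c(76L, 228L, 304L), "sporophytic", 38)
  expect_equal(pl$ploidy, c(2L, 6L, 8L))
  expect_true(all(pl$euploid))
  expect_equal(pl$residual, c(0L, 0L, 0L))
  # gametophytic counts are doubled onto the 2n scale
  pl <- infer_ploidy(38, "gametophytic", 38)
  expect_equal(pl$scaled_2n, 76L)
  expect_equal(pl$ploidy, 2L)
  # aneuploid near-miss keeps its residual, never snapped
  pl <- infer_ploidy(77, "sporophytic", 38)
  expect_equal(pl$ploidy, 2L)
  expect_equal(pl$residual, 1L)
  expect_false(pl$euploid)

  expect_error(infer_ploidy(76, "sporophytic", 0),
               class = "chromcurate_validation_error")
  expect_error(infer_ploidy(0, "sporophytic", 7),
               class = "chromcurate_validation_error")
})

test_that("ploidy inference is consistent for any base number", {
  set.seed(13)
  for (i in 1:25) {
    x <- sample(4:40, 1)
    # euploid series 2x..8x maps to levels 2,4,6,8 with zero residual
    pl <- infer_ploidy(x * c(2L, 4L, 6L, 8L), "sporophytic", x)
    expect_equal(pl$ploidy, c(2L, 4L, 6L, 8L))
    expect_true(all(pl$euploid))
    # doubling consistency between the two count scales
    n <- sample(5:200, 10)
    expect_equal(infer_ploidy(n, "gametophytic", x)$ploidy,
                 infer_ploidy(2L * n, "sporophytic", x)$ploidy)
    # exact-half ties round up
    if (x %% 2 == 0) {
      expect_equal(infer_ploidy(x + x %/% 2L, "sporophytic", x)$ploidy, 2L)
    }
  }
})

test_that("base-number suggestion recovers x from a euploid series", {
  cand <- suggest_base_number(c(76L, 152L, 228L, 304L))
  expect_equal(cand[1], 76L) # GCD first; x itself among the divisors
  expect_true(38L %in% cand)
  expect_true(19L %in% cand)
})

test_that("ploidy_table annotates every curated row", {
  cur <- curate_fixture()
  pt <- ploidy_table(cur, base_x = 38)
  expect_equal(nrow(pt), nrow(cur$rows))
  expect_setequal(unique(pt$ploidy), c(2L, 4L, 6L, 8L))
  expect_true(all(pt$euploid))
})
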