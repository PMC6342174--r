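test_that("long and wide CSV dialects are read and melted correctly", {
  long <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("taxon,count_type,record",
               "Gentiana terglouensis,2n,11II+16I;19II",
               "Blechnum occidentale,sporophytic,40II+44I",
               "Some species,n,17",
               "Empty cell,2n,"), long)
  recs <- read_records(long)
  expect_equal(nrow(recs), 3L)
  expect_equal(attr(recs, "skipped"), 1L)
  expect_equal(recs$count_type, c("sporophytic", "sporophytic",
                                  "gametophytic"))

  wide <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("species,gametophytic,sporophytic",
               "Anemia adiantifolia,76,152",
               "Anemia phyllitidis,,228"), wide)
  recs <- read_records(wide)
  expect_equal(nrow(recs), 3L) # one empty cell melted away
  expect_setequal(unique(recs$count_type),
                  c("gametophytic", "sporophytic"))

  expect_error(read_records(long, col_map = list(record = "nope")),
               class = "chromcurate_config_error")
  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("a,b", "1,2"), bad)
  expect_error(read_records(bad), class = "chromcurate_config_error")
  expect_error(read_records("no/such/file.csv"),
               class = "chromcurate_io_error")
})

test_that("curation explodes multi-count records and isolates rejects", {
  cur <- curate_records(tibble::tibble(
    taxon = c("Gentiana terglouensis", "X y", "A b"),
    count_type = "sporophytic",
    record = c("11II+16I;19II", "???", "17")))
  expect_s3_class(cur, "curated_records")
  expect_equal(cur$rows$count, c(38L, 38L, 17L))
  expect_equal(cur$rows$record_index, c(1L, 1L, 3L))
  expect_equal(nrow(cur$rejects), 1L)
  expect_match(cur$rejects$reason, "unparseable")

  # conservation: every parsed count becomes exactly one row, and
  # source records partition into exploded rows plus rejects
  g <- glance(cur)
  expect_equal(g$n_records,
               dplyr::n_distinct(cur$rows$record_index) + g$n_rejected)
  tr <- translate_record(c("11II+16I;19II", "17"))
  expect_equal(sum(lengths(tr$counts)), nrow(cur$rows))
})

test_that("explosion conservation holds on randomized record tables", {
  set.seed(11)
  for (i in 1:10) {
    truth <- generate_ground_truth(n_genera = 2, species_per_genus = 3,
                                   seed = i)
    raw <- messify(truth, seed = i)
    cur <- curate_records(raw)
    expect_equal(nrow(cur$rejects), 0L)
    tr <- translate_record(raw$record)
    expect_equal(nrow(cur$rows), sum(lengths(tr$counts)))
  }
})

test_that("filtering selects by genus, species list, and count type", {
  cur <- curate_fixture(tibble::tibble(
    taxon = c("Anemia adiantifolia", "Anemia adiantifolia",
              "Anemia phyllitidis", "Blechnum occidentale",
              "Blechnum occidentale"),
    count_type = c("sporophytic", "sporophytic", "gametophytic",
                   "sporophytic", "sporophytic"),
    record = c("76", "152", "76", "40II+44I", "124")))
  expect_equal(nrow(filter_curated(cur, genus = "Anemia")$rows), 3L)
  expect_equal(nrow(filter_curated(cur, genus = "anemia")$rows), 3L)
  expect_equal(nrow(filter_curated(cur, species = "Anemia adiantifolia")$rows),
               2L)
  expect_equal(nrow(filter_curated(cur, genus = "Anemia",
                                   count_type = "gametophytic")$rows), 1L)
  expect_equal(nrow(filter_curated(cur, genus = "Blechnum",
                                   count_type = "gametophytic")$rows), 0L)

  # optional common-scale view doubles n onto 2n
  doubled <- filter_curated(cur, genus = "Anemia", haploid_double = TRUE)
  expect_equal(sort(doubled$rows$count), c(76L, 152L, 152L))
  expect_true(all(doubled$rows$count_type == "sporophytic"))

  expect_error(filter_curated(cur), class = "chromcurate_validation_error")
  expect_error(filter_curated(cur, genus = " "),
               class = "chromcurate_validation_error")
})

test_that("curated CSV round-trips, keeps provenance, and stays integer-only", {
  cur <- curate_records(tibble::tibble(
    taxon = example_records$taxon,
    count_type = "sporophytic",
    record = example_records$record))
  path <- withr::local_tempfile(fileext = ".csv")
  rej <- withr::local_tempfile(fileext = ".csv")
  write_curated_csv(cur, path, rejects_path = rej)

  # the B-chromosome record keeps its original and naive parse side by side
  lines <- readLines(path, encoding = "UTF-8")
  expect_true(any(grepl("Heracleum sphondylium,sporophytic,22,22,11II\\+1BI",
                        lines)))
  # count column is strictly positive integers
  counts <- readr::read_csv(path, show_col_types = FALSE)$count
  expect_true(all(grepl("^[0-9]+$", as.character(counts))))
  expect_true(all(counts > 0))

  back <- read_curated_csv(path)
  expect_equal(back$rows$count, cur$rows$count)
  expect_equal(back$rows$taxon, cur$rows$taxon)
  expect_equal(back$rows$original, cur$rows$original)

  # curation is idempotent: re-curating the written counts changes nothing
  again <- curate_records(tibble::tibble(
    taxon = back$rows$taxon, count_type = back$rows$count_type,
    record = as.character(back$rows$count)))
  expect_equal(again$rows$count, back$rows$count)

  # empty table writes a header-only file
  empty <- curate_records(tibble::tibble(taxon = character(),
                                         count_type = character(),
                                         record = character()))
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_curated_csv(empty, p2)
  expect_equal(length(readLines(p2)), 1L)
})

test_that("tidy and glance expose the curated table broom-style", {
  cur <- curate_fixture()
  expect_identical(tidy(cur), cur$rows)
  g <- glance(cur)
  expect_equal(g$n_records, 6L)
  expect_equal(g$n_rejected, 0L)
  expect_equal(g$parse_rate, 1)
})
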