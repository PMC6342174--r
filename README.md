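# chromcurate

Curation and visualization of plant chromosome-count records.

## The problem

Chromosome counts are the primary evidence for ploidy in plants, and the
largest public collection of them — the Chromosome Counts Database
(CCDB, http://ccdb.tau.ac.il) — stores records exactly as they were
published. That means heterogeneous cytological notation rather than
clean integers: a count observed at meiosis as 40 bivalents plus 44
univalents is stored as `40II+44I`, which is 40 × 2 + 44 = **124**
chromosomes. The CSV export's own parsed-value column reduces that
record to `40`, silently discarding most of the complement. Other
records mix comma- or semicolon-separated alternatives, B-chromosome
terms (`62+2Bs`) that do not belong in the standard complement,
supernumerary ranges (`34+0-13`), endpoint ranges (`40-44`, often with
a unicode hyphen), fragment suffixes (`30f`), parenthetical
record-multiplicity metadata (`64(1, 1, 1, 4, 1, 1)`) and stray `etc`
tokens.

`chromcurate` is for anyone who needs those records as data: it parses
the notation into lists of integer counts with full provenance,
tabulates intra- and interspecific variation, infers ploidy levels
against a base chromosome number, and builds the standard stacked-bar
and heatmap summaries. A seeded synthetic-record generator lets the
whole pipeline be tested end-to-end with no database download.

## The model

A record is a set of alternatives (split on `;` and top-level `,`);
each alternative is a sum of terms; each **chromosomal** term with
multiplicity *m* and valence *v* (univalent I, bivalent II,
multivalents III, IV, ...) contributes *m·v* chromosomes, while
B-chromosome and supernumerary-range terms contribute 0. A standalone
range `a-b` reports its two endpoint counts. Ploidy is inferred from a
user-supplied base number *x*: a count 2*n* (gametophytic *n* doubled
first) has level *p* = round(2*n*/*x*), residual 2*n* − *p·x*, and is
euploid only when the residual is exactly 0.

## Worked example

```r
library(chromcurate)

recs <- tibble::tibble(
  taxon = c("Blechnum occidentale", "Gentiana terglouensis",
            "Heracleum sphondylium"),
  count_type = "sporophytic",
  record = c("40II+44I", "11II+16I;19II", "11II+1BI"))

cur <- curate_records(recs)
tidy(cur)[, c("taxon", "count", "translation", "original")]
#> # A tibble: 4 × 4
#>   taxon                 count translation original
#>   <chr>                 <int> <chr>       <chr>
#> 1 Blechnum occidentale    124 124         40II+44I
#> 2 Gentiana terglouensis    38 38 38       11II+16I;19II
#> 3 Gentiana terglouensis    38 38 38       11II+16I;19II
#> 4 Heracleum sphondylium    22 22          11II+1BI
```

The Blechnum record becomes one row of 124 chromosomes (compare
`naive_leading_integer("40II+44I")`, which returns the lossy `40`); the
Gentiana record, two independent observations of 38, becomes two rows;
the Heracleum B chromosome is excluded from the total of 22. With the
base number *x* = 31 known for *Blechnum*:

```r
infer_ploidy(124, "sporophytic", base_x = 31)
#> # A tibble: 1 × 7
#>   count count_type  scaled_2n base_x ploidy residual euploid
#>   <int> <chr>           <int>  <int>  <int>    <int> <lgl>
#> 1   124 sporophytic       124     31      4        0 TRUE
```

— a tetraploid. `count_frequencies()`, `heatmap_percentages()`,
`stacked_bar_data()` and the `plot_*()`/`render_*()` functions build
the summary tables and figures; `generate_ground_truth()` + `messify()`
produce seeded synthetic raw tables whose curation recovers the truth
exactly. A command-line wrapper lives at
`inst/scripts/chromcurate` (subcommands `curate`, `summarize`, `plot`,
`ploidy`, `simulate`).

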