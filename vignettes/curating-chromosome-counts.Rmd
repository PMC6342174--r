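---
title: "Curating and summarizing plant chromosome-count records"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Curating and summarizing plant chromosome-count records}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chromcurate)
```

## The curation model

Chromosome-count repositories store records as published, and
cytologists have published them in many notations. `chromcurate`
treats a raw record as a small formal language:

1. **Normalization.** All unicode dash variants become ASCII `-`,
   whitespace collapses, and valence (`I`, `II`, ...), B-chromosome
   (`B`, `Bs`, `BI`), fragment (`f`) and approximate (`c.`, `ca.`)
   markers are upper-cased. Nothing else changes, so the canonical
   string stays comparable to the original, which is preserved
   byte-for-byte in every output for side-by-side display.
2. **Alternatives.** A record may list several independent
   observations, split on `;` and on `,` outside parentheses. A
   parenthetical group directly after a count is record-multiplicity
   metadata and is deleted, not expanded — so
   `64(1, 1, 1, 4, 1, 1)` contributes a single 64. Literal
   `etc` tokens are dropped with a note.
3. **Terms.** Each alternative is a `+`-joined sum. A chromosomal term
   of multiplicity $m$ and valence $v$ contributes $m \cdot v$
   chromosomes (a bivalent is two chromosomes, a trivalent three, and
   so on; plain integers are already-summed counts with $v = 1$).
   B-chromosome terms and supernumerary ranges (`34+0-13`) contribute
   zero: B chromosomes are dispensable supernumeraries excluded from
   the standard complement, and an additive range describes variable
   supernumeraries rather than the complement itself.
4. **Standalone ranges.** A record that *is* a range, like `40-44`,
   reports its two endpoint counts only — not the intermediate
   integers, which were never observed.

So `40II+44I` translates to $40 \times 2 + 44 = 124$, and
`11II+16I;19II` to two observations of 38. Unrecognized tokens never
stop a run: the record is routed to a rejects table with its offending
token named, mirroring the report-and-extend workflow that raw
count databases require (their pattern inventory is open-ended; this
package implements the documented families and keeps the grammar and
the synthetic generator on one shared registry so new families are
added in one place).

Two judgment calls deserve explanation. The `f` suffix (most likely
"fragment") has no defined arithmetic, so the digits are kept and the
record is flagged rather than altered. A translation consisting only
of zero (e.g. `0II`) is arithmetically valid but biologically
suspicious; it is kept and flagged at the notation layer, while the
curated table — whose contract is strictly positive integer counts —
excludes zero rows and tallies them.

## Ploidy inference

Ploidy is always inferred against a **user-supplied** base number $x$
(chromosomes per monoploid set): base numbers are lineage knowledge,
and silently inferring them would launder a guess into a result.
Gametophytic counts $n$ are doubled onto the sporophytic scale first;
then $p = \mathrm{round}(2n/x)$ (exact halves round up, clamped to
$\ge 1$), the aneuploidy residual is $2n - p x$, and a count is
euploid only at residual zero — near-misses keep their residual rather
than being snapped to the nearest level. `suggest_base_number()`
offers a GCD-based candidate screen, clearly labelled a heuristic.

## Summaries and plot data

Frequencies are exact multiset tallies of (species, count) pairs; one
database record is one unit of evidence, and duplicates are never
collapsed. Heatmap cells are percentages normalized **per species**
(each species row sums to 100, within 1e-9), so sparsely sampled
species remain readable next to well-sampled ones; a `normalize =
"global"` switch is available when the grand-total share is wanted.
Modal counts report ties in full. The stacked-bar structure —
one bar per count, one segment per species, heights equal to record
frequencies — is a first-class data object (exportable as JSON for
interactive front ends); renderers are a thin deterministic ggplot2
layer with a fixed qualitative palette cycled in species sort order.

## What the synthetic generator emulates

`generate_ground_truth()` draws, per genus, a base number $x$
(default range 7–21, the common span for flowering plants; pin
`x_range` higher for fern-like karyotypes), per species a small set of
even ploidy levels up to `max_ploidy = 8` (an octoploid series is the
deep end of what genus summaries usually show), 1–5 records per
species, a 10% default aneuploid fraction with ±1–2 chromosome
offsets, and a 30% chance that an even-count record is reported on the
gametophytic scale. `messify()` then renders every true record in one
sampled notation family; the bivalent split draws the bivalent number
uniformly in $[\lceil c/4 \rceil, \lfloor c/2 \rfloor]$ so both
bivalents and univalents usually appear.

What passing the round-trip property shows is that curation inverts
**every documented notation family exactly, at any mix**. What it does
not show: real exports contain undocumented pattern families, OCR
noise, and taxonomic synonymy — none of which the generator imitates,
and the last of which (name resolution) is explicitly out of scope.

## Numerical choices and degenerate inputs

* Ploidy ties ($2n/x$ at an exact half) round up; `infer_ploidy`
  requires $x \ge 1$ and counts $\ge 1$.
* Heatmap row-sum validation uses a 1e-6 tolerance on rendering input;
  the computation itself is exact rational arithmetic in doubles.
* Empty record cells are skipped at ingest with a tally; empty curated
  tables write header-only CSVs; an empty frequency table is a valid
  empty result, but plot builders refuse it.
* Zero multiplicities parse (`0II` evaluates to 0); see the
  suspicious-zero handling above.
* Roman valences are accepted through `VIII`; higher multivalents are
  vanishingly rare in print and would extend the same arithmetic.

## Test problem sizes

The suite exercises the valence oracle (brute-force expansion of each
term into `multiplicity` copies of `valence`) on 10,000 random
expressions, the synthetic round trip on a table of over 1,000 records
spanning all pattern families, frequency/heatmap invariants on 20
randomized tables of 200 rows, and ploidy recovery on six genera at
`aneuploid_fraction = 0` — sizes chosen to give the property tests
broad coverage of the grammar while the suite stays fast to run often.

## Limitations

The package reads offline CSV exports only (no live database or API
queries), performs no taxonomic name resolution, does not weight
frequencies by parenthetical record-multiplicity metadata (an open
question; the documented translations drop it), and prepares — but
does not fit — models of chromosome-number evolution.
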