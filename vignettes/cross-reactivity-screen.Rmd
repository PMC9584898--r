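---
title: "Screening phosphosites for antibody cross-reactivity candidates"
author: "CrossPhos authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening phosphosites for antibody cross-reactivity candidates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(CrossPhos)
```

## The problem

Antibodies raised against short phosphopeptides — most prominently the
anti-pS129 antibodies used throughout the alpha-synuclein field — recognize a
linear epitope of roughly a dozen residues around the phosphosite. Any other
phosphoprotein whose local sequence around one of its *own* annotated
phosphosites resembles that epitope is a candidate for cross-reaction: an
off-target band on a blot, a spurious inclusion in tissue staining, or an
inflated biomarker signal in plasma or CSF. CrossPhos implements a
proteome-wide screen for such candidates and a synthetic-proteome generator
that makes every stage of the screen testable without any database download.

## The comparison model

Every comparison in the screen is between two 13-mer windows, each centered
on a phosphosite, aligned center-to-center with no gaps:

* **Seed fragment** — a window around a phosphosite of the immunogen. The
  default seed set is the six windows of canonical human alpha-synuclein
  centered on Y39, S87, Y125, S129, Y133 and Y136. The Y136 window runs two
  positions past the C-terminus (the protein has 140 residues); truncated
  positions are tracked explicitly and rendered as `*`/`-` padding, and they
  never participate in scoring.
* **Candidate window** — the analogous window around any annotated
  phosphoserine or phosphotyrosine of any entry in the scanned proteome.

A candidate is retained iff the residues **immediately preceding and
following** the phosphosite are perfect matches to the seed (the anchor
filter, `anchorsMatch()`). The center residue itself is *not* required to
match: the only stated hard constraint of the procedure is the flank match.
Because this is a genuinely open reading of the procedure, a
`strictCenter` switch is provided that additionally requires center
identity; it is off by default.

Retained candidates are scored (`compareWindows()`) with four statistics:

* `nExact` — aligned positions with identical residues;
* `nSimilar` — aligned, non-identical positions whose PAM120 score is
  **strictly greater than 1**. The two tallies are disjoint: an identical
  pair counts once, as exact. Under this rule Glu/Gln (score 2) and Tyr/Phe
  (4) are similar while Ile/Leu (1) and Ile/Phe (0) are not;
* `exactStretch` — the length of the longest run of consecutive exact
  matches that contains the central position (0 when the centers differ);
* `exactOrSimilarStretch` — the same under the exact-or-similar predicate.

A position where either window is truncated fails both predicates and
breaks both stretches: a residue that does not exist cannot be conserved.

The PAM120 matrix is taken from Biostrings, which distributes the standard
published table; codes outside the table (`X`, `U`, `O`, padding) score a
sentinel far below any threshold, so unknown residues can never count as
similar. The threshold is configurable (`similarityRule()`), and raising it
can only shrink `nSimilar` and `exactOrSimilarStretch` — a property the test
suite checks explicitly.

## Ranking

Within each (seed, organism) group, hits are ordered by five keys:
`exactStretch` (descending), `exactOrSimilarStretch` (descending), `nExact`
(descending), `nSimilar` (descending), then molecular weight. The procedure
names molecular weight as the final key without a direction; CrossPhos sorts
it **ascending** by default — among metric ties the candidate most plausibly
co-migrating with a small protein like alpha-synuclein (14.5 kDa) on a blot
ranks first — and exposes the choice as `mwDirection`. A final tie-break on
accession and site position makes the order total, so reports are
byte-identical across runs and platforms.

## Cross-organism commonality and biofluid overlap

The screen reports, per seed, which candidate proteins appear in both the
human and mouse scans. "Common" is not defined by the screening procedure
itself; CrossPhos uses a case-insensitive gene-symbol match (`SNCA`/`Snca`),
falling back to the entry-name stem before the `_HUMAN`/`_MOUSE` suffix when
an entry has no gene name. This is the lightest assumption that makes
orthologous pairs common without an orthology database, which is out of
scope. Commonality is reported both per seed and over the union of seeds,
since either aggregation is defensible.

Biofluid overlap (`annotateBiofluids()`) takes a user-supplied plain-text
presence list (plasma or CSF proteins, one accession or gene symbol per
line) and reports how many distinct candidate proteins — deduplicated by
accession across seeds — appear in it, as a percentage to two decimals.
Live queries to expression/proteomics databases are deliberately not
performed; presence lists are inputs.

## Input handling

The flat-text parser accepts UniProtKB-style records. Decisions worth
stating:

* Residue numbering is 1-based everywhere, matching `FT` coordinates.
* `MOD_RES` descriptions are matched on the leading token, so
  `"Phosphoserine; by PLK3"` still counts; only phosphoserine and
  phosphotyrosine become sites (phosphothreonine is outside the screen).
* Isoform-scoped features are skipped; only canonical-sequence sites are
  scanned, since molecular weight and the sequence come from the canonical
  record. Duplicate annotations at one position collapse to a single site.
* The first accession of the `AC` line is primary; secondary accessions are
  retained for presence-list matching. Deduplication of obsolete or merged
  entries is left to the caller.
* Malformed records (missing `ID`/`SQ`, length disagreeing with the `SQ`
  header, a feature beyond the sequence) are rejected per record into a
  parse report — never silently truncated. A site annotated on the wrong
  residue is dropped with a warning.
* A FASTA + TSV site-table route (`readFastaSites()`) serves users without
  flat files; molecular weights are then computed from the sequence with
  standard average residue masses (the computed weight of canonical human
  alpha-synuclein is 14460 Da, matching its database record).

## The synthetic proteome generator

`generateSyntheticProteome()` exists so that the scan's correctness is a
*constructive* fact, not a statistical one:

* **Planted candidates** are written into random sequences by
  `plantCandidate()`, which realizes a requested metric triple
  (`exactStretch`, `nExact`, `nSimilar`) exactly: anchors and center copied
  from the seed, a central exact run of exactly the requested length,
  isolated exact matches elsewhere, similar slots filled from residues
  scoring above the threshold, and all remaining positions drawn from the
  similarity complement so they contribute to neither tally. Since several
  residues (Ala, Gly, Cys, Pro, Trp) have no PAM120 partner above 1,
  similarity slots are the scarce resource: they are assigned before the
  isolated exact matches, and run placement is retried across all feasible
  intervals before an infeasible request fails with a diagnostic.
  Requested triples are validated against the metric inequalities at
  config time (`generatorConfig()`); note a planted stretch is always at
  least 3, because anchors and center are exact by construction.
* **Decoys** fail the anchor filter *by construction* — their −1 flank is
  set to tryptophan, which no default seed carries there — so "no false
  positives" is a hard assertion.
* Human- and mouse-tagged entries with optionally paired gene symbols make
  the commonality computation testable with planted truth.
* Generation is a pure function of the config, including its RNG seed, and
  restores the caller's RNG state; identical configs give byte-identical
  flat text.

The generator emulates annotation structure, not biology: residue
composition is uniform (or user-supplied frequencies) with no domain
structure, no homology between entries, no realistic phosphosite density,
and no annotation biases. Passing the recovery tests therefore demonstrates
the *mechanics* of the screen — parsing, anchoring, scoring, ranking — not
performance on real proteomes, where hit counts depend entirely on the
annotation snapshot scanned.

## Numerical and testing choices

There is no floating-point arithmetic in the core: all scores and metrics
are integers, so no tolerances are involved. Percentages are rounded to two
decimals at the reporting boundary only. An empty candidate set makes an
overlap percentage undefined; it is reported as 0 with a warning.

The test suite cross-checks `compareWindows()` against an independent
brute-force oracle (`oracleCompare()`, exhaustive interval enumeration with
no shared code) on 10,000 randomized window pairs, and verifies planted-hit
recovery with precision and recall 1.0 on a generated proteome of 500
entries carrying 24 planted hits across four seeds plus one anchor-failing
decoy per entry — sizes chosen so the whole suite runs in about a minute on
one CPU while still exercising every code path at scale.

## Known limitations

* Strictly ungapped, center-anchored comparison: no alignment statistics,
  no E-values, and no attempt to model conformational epitopes — candidates
  are sequence-level hypotheses to be tested experimentally.
* Hit counts against a real database are snapshot-dependent; the package
  ships no database and performs no network retrieval.
* Cross-organism commonality by gene symbol is a heuristic, not orthology.
* Only phosphoserine and phosphotyrosine sites are scanned, mirroring the
  seed sites; phosphothreonine epitopes would need their own seed set and
  an extension of the site filter.
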