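---
title: "Methods: exon-boundary alignment with domain and disorder boundaries"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: exon-boundary alignment with domain and disorder boundaries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The question and the model

Eukaryotic genes are split into exons, and one long-standing hypothesis is
that exons act as shuffling units in protein evolution. If so, the
positions where exons meet (splice junctions), projected into protein
coordinates, should fall near the boundaries of protein domains more often
than a random placement would produce — and the excess should be larger in
proteins whose domain architecture was assembled recently. `boundalign`
quantifies this as an observed/expected ratio per genome, with a chi-square
test per genome and a cross-genome bootstrap for the new-vs-old contrast.
The same machinery runs on boundaries of intrinsically disordered regions,
where the alignment question is open rather than expected.

The null model is deliberately simple: conditional on a protein's length
`L`, its number of internal junctions `n`, and its boundary-window set `W`,
junctions are placed independently and uniformly over residues `1..L`, so
the expected number in `W` is `n·|W|/L`. Everything about gene structure
except junction *position* is taken as given, which makes the expectation
exact rather than model-fitted. Terminal residues are not excluded from the
null: internal-boundary filtering has already happened upstream, and the
uniform-over-`1..L` reading is the simplest consistent one.

Genome-level counts are sums over eligible proteins — multi-exon proteins
carrying at least one assignment of the class being scored. For the
disorder class, eligibility mirrors the domain rule (at least one disorder
region); `summarize_genome_alignment(eligibility = "domain")` instead sums
both classes over domain-containing proteins as a sensitivity analysis.

## Coordinate conventions

- Genomic coordinates are 1-based inclusive (GTF/GFF3); protein residues
  are 1-based inclusive (matching SUPERFAMILY-style domain tables).
- A junction is addressed by the last coding nucleotide of the upstream
  exon, position `c` along the spliced CDS, and maps to residue `⌈c/3⌉`:
  the residue whose codon contains that nucleotide. A phase-0 junction
  (between codons) belongs to the residue completed by the upstream exon; a
  phase-1/2 junction to the residue encoded by the split codon, which is
  the physical splice position in protein coordinates. This rounding
  convention is a package decision — annotation sources do not fix one.
- Counting mode: by default each splice junction is **one** boundary event
  (`boundary_mode = "junction"`). The alternative reading — each exon end
  and the next exon's start counted separately, `2(n−1)` events — is
  available as `boundary_mode = "both_ends"`. The default avoids counting a
  single splice event twice, and the expected-count formula treats
  boundaries as exchangeable point events either way; the choice is
  exposed, not hidden.

## Stop codons and malformed CDS

Whether an annotation's CDS features include the stop codon varies by
source and is often undocumented. The package makes the policy explicit:
with `stop_included = TRUE` (default) a CDS totalling `3k` nucleotides
encodes `k − 1` residues and a junction mapping into the stop codon
(residue `> L`) is discarded with a warning; `stop_included = FALSE`
treats all `k` codons as coding. Transcripts whose CDS length is not a
multiple of three (annotated frameshifts, partial models) are dropped with
a warning — codon-phase bookkeeping is undefined for them. The synthetic
generator emits CDS *with* the stop codon so the default policy
round-trips exactly.

## Windows, overlaps, degenerate inputs

A boundary window is `{s−1, s, s+1, e−1, e, e+1}` per assignment — six
residues for an interior assignment — unioned across assignments and
clipped to `[1, L]`. Overlapping windows count once because the statistic
uses the proportion of residues inside *any* window. Degenerate cases are
defined, not special-cased: a protein whose windows cover every residue has
`E = n` and an undefined chi-square (flagged `NA` with a warning, as is a
genome with `E = 0`); junctions are kept as a multiset, so two junctions
mapping to the same residue both count.

Disorder consensus: a residue is disordered when at least 75% of predictor
tracks call it (`consensus_call`, threshold inclusive — 6 of 8 predictors
qualify — with a `1e-9` slack so exact fractions survive floating-point
comparison). Consensus tracks are run-length encoded into maximal regions.

## Statistical tests

- **Chi-square**: two cells (inside/outside windows), 1 df, on
  genome-level pooled counts — matching per-genome significance calls —
  with `χ² = (O−E)²/E + (O−E)²/(N−E)` and the upper tail of χ²(1). The
  number of cells is a package decision; the test suite pins the
  implementation against `stats::chisq.test` on the two-cell table.
- **Bootstrap partition test**: 50,000 trials by default; per trial each
  genome's eligible proteins are repartitioned uniformly into pseudo-new /
  pseudo-old sets of the original sizes, and the trial statistic is the
  number of genomes with pseudo-new ratio strictly greater than
  pseudo-old. The p-value is the plain proportion of trials at or above
  the actual count — the estimator stated by the test's definition — with
  the Davison–Hinkley add-one correction available via `add_one = TRUE`.
  Ties count as *not* greater: a strict reading of "larger", and the
  deterministic choice (ties are measure-zero in practice). The trial loop
  is compiled (Rcpp) but draws from R's RNG, so runs are bit-reproducible
  under `set.seed()`. Genomes lacking either class are excluded with a
  warning.
- **Pearson correlation** between per-genome domain and disorder ratios
  uses the standard product-moment estimate with a two-sided t test.

## Novelty classification

With an external label table (e.g. derived from ancestral reconstructions
of domain content), labels win verbatim. The built-in rule is strict
presence/absence: a protein is 'new' when its domain architecture — the
N→C comma-joined domain ids, with overlapping assignments resolved by
keeping the longer (ties: smaller start) — occurs in exactly one genome of
the clade. This is intentionally *not* a reconstruction over a species
tree, which would require phylogenetic machinery outside this package's
scope; the label-file path exists precisely so reconstruction-derived
labels can be injected. Proteins without domains are unlabelled and
excluded. Genomes with fewer than `min_new_proteins = 10` new proteins are
excluded from the contrast — too few novel architectures to estimate a
stable ratio; the threshold is explicit and configurable because no
canonical value exists. Likewise the genome-level filter
`min_multiexon_proteins = 200` drops genomes with too few multi-exon,
domain-containing proteins (overwhelmingly intronless genomes) — again an
explicit, reportable choice where no standard number exists.

## The synthetic generator

The generator emulates what the pipeline consumes, not genome biology:

| parameter | default | rationale |
|---|---|---|
| protein length | log-normal, median 350, σ = 0.5, min 30 | typical eukaryotic protein length scale |
| exons per transcript | 1 + Poisson(6) | several junctions per protein, single-exon proteins present |
| domains per protein | 0–3 with probs 0.15/0.45/0.30/0.10 | most proteins carry 1–2 assignments, some none |
| domain length | uniform 50–150 residues | SUPERFAMILY-scale domains; shrunk proportionally when they would not fit |
| disorder regions | per inter-domain segment, prob 0.6, length 10–40 | short disordered linkers outside domains |
| predictors | 8, flip error 0.05 | consensus recoverable but noisy |
| introns | uniform 50–2000 nt | irrelevant to the statistics, required for valid GTF |

Planted enrichment θ draws a junction uniformly over the *window residue
set* (not over windows, then residues) with probability θ — this makes the
closed-form ratio `(θ + (1−θ)·w̄)/w̄` exact, with `w̄` the
boundary-weighted mean window fraction; `expected_planted_ratio()` and
`planted_ratio_se()` compute the prediction and its Monte-Carlo standard
error from the per-protein counts. Junction residues then receive a random
codon phase each and are realized as genomic CDS coordinates on a toy
chromosome, strand drawn uniformly. At most three junctions (one per
phase) can share a residue; overflow junctions are redrawn from the same
source distribution they came from, so enrichment is preserved. When a
protein has no windows but θ > 0, the junction falls back to uniform and
is counted in the truth table.

Architectures come from a bundle-level pool shared across genomes, and
each genome carries every pool architecture at least once (sizes
permitting), so the presence/absence classifier recovers planted new/old
labels exactly — the recovery property tested in the suite. Disorder is
carved outside domains by default so the two window classes are
distinguishable in truth; `allow_overlap = TRUE` relaxes this. What the
generator does **not** emulate: nucleotide sequence content, realistic
domain-family frequencies, alternative splicing sharing loci between
transcripts, and inter-protein length/exon correlations. Passing
calibration on synthetic data therefore validates the *machinery* — the
counting, mapping and tests — not claims about any real genome.

## Problem sizes in the test suite

Calibration tests run at sizes chosen to keep Monte-Carlo error well below
the tested tolerances: the null ratio check uses one genome of 5,000
proteins; the false-positive-rate check uses 500 independent null genomes
of 150 proteins at α = 0.01 with a 99% binomial acceptance band;
enrichment recovery uses 3,000 proteins per θ with a 3-standard-error
band; bootstrap null uniformity pools 200 replicate datasets of 84 genomes
× 50 proteins (84 matching the scale of a broad eukaryote panel after
exclusions) at 2,000 trials each, checked by a Kolmogorov–Smirnov test;
bootstrap power uses 20 replicate runs of 20 genomes with θ_new = 0.5
vs θ_old = 0. Exhaustive-enumeration checks of the expectation run on
proteins of length ≤ 30 with ≤ 3 junctions, where all placements can be
enumerated.

## Known limitations

- The expectation conditions on the annotated gene structure; biases that
  correlate junction position with window position for reasons other than
  boundary alignment (e.g. length-dependent annotation quality) are not
  modelled.
- The built-in novelty rule is sensitive to clade composition: an
  architecture lost in all relatives looks 'new'. Use label files from
  proper ancestral reconstruction when available.
- Disorder windows frequently abut domain windows, so the domain and
  disorder ratios are correlated by construction in both real and
  synthetic data; the package reports the correlation rather than
  attempting to deconvolve it.
- Selenocysteine recoding, ribosomal frameshifts and trans-splicing are
  out of scope; affected transcripts are dropped by the mod-3 filter.
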