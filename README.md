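# boundalign

Do the boundaries of exons line up with the boundaries of protein domains —
and with the boundaries of intrinsically disordered regions — more often
than chance would allow? If exon shuffling contributed to the evolution of
new proteins, splice junctions should fall near domain boundaries more
often than a uniform-placement null predicts, and the effect should be
stronger in proteins whose domain architecture arose recently. `boundalign`
implements that analysis end to end for anyone working with genome
annotations and per-protein domain/disorder assignments: it maps splice
junctions from genomic CDS coordinates into protein residue coordinates,
scores their co-occurrence with boundary windows, and tests the new-protein
vs old-protein contrast.

## The statistic

For each domain (or disordered-region) assignment with residue coordinates
`(s, e)`, a **boundary window** is the residue set
`{s−1, s, s+1, e−1, e, e+1}` — six residues per interior assignment —
unioned over all assignments of the protein and clipped to `[1, L]`. Each
internal splice junction (there are `n_exons − 1`) is mapped to the residue
whose codon contains the last nucleotide of the upstream exon,
`r = ⌈c/3⌉` for spliced-CDS position `c`, so phase-1/2 junctions land on
the residue encoded by the split codon.

Per genome, over all multi-exon proteins carrying at least one assignment:

- **O** = number of junctions falling inside any boundary window;
- **E** = Σ over proteins of `n_junctions × |window| / L`, the expectation
  when junctions are placed uniformly over the protein;
- the **observed/expected ratio** `O/E`, with a two-cell chi-square
  goodness-of-fit test (1 df) for its difference from 1.

Proteins are classified **new** (domain architecture unique to their genome
within the clade — or labels supplied externally) or **old**, and the
cross-genome contrast in `O/E` between new and old proteins is tested with
a bootstrap partition test: each genome's proteins are repartitioned at
random into pseudo-new/pseudo-old sets of the original sizes (50,000
trials), and the p-value is the proportion of trials in which at least as
many genomes show pseudo-new ratio > pseudo-old ratio as actually do.

A built-in generator produces complete multi-genome inputs (GTF plus
domain, per-predictor disorder, and label tables) with a planted enrichment
θ: a junction is drawn from the domain boundary-window set with probability
θ and uniformly otherwise, giving the closed-form genome ratio
`(θ + (1−θ)·w̄)/w̄` (w̄ = boundary-weighted mean window fraction) against
which recovery is checked.

## Worked example

Generate eight synthetic genomes with strong planted enrichment
(θ = 0.4 overall, θ = 0.7 for the 10% of proteins with planted-novel
architectures), write them to disk, and run the full pipeline on the files:

```r
library(boundalign)

cfg <- synthetic_config(seed = 42, n_genomes = 8, n_proteins = 500,
                        theta_domain = 0.4, frac_new = 0.1, theta_new = 0.7)
dir <- tempfile("bundle")
write_bundle(generate_bundle(cfg), dir)

res <- run_pipeline(bundle_file_table(dir),
                    min_multiexon_proteins = 100, min_new_proteins = 5,
                    n_trials = 10000, seed = 1)
res$summary
#> # A tibble: 16 × 10
#>    genome_id class    n_proteins n_boundaries observed expected  ratio     chi2  p_value significant
#>  1 G01       disorder        415         2488      107     79.2  1.35     10.1  0.00150  TRUE
#>  2 G01       domain          439         2604     1196     84.0 14.2   15204.   0        TRUE
#>  3 G02       disorder        394         2382      107     72.5  1.48     17.0  0.0000380 TRUE
#>  4 G02       domain          421         2518     1136     80.4 14.1   14320.  0        TRUE
#>  ...
```

Every genome's domain-class ratio sits near the closed-form prediction
(θ = 0.4 with w̄ ≈ 0.032 gives ≈ 13–14×), and the chi-square flags them all
at `p < 0.01`; the disorder-class ratios hover nearer 1 because only
spillover from adjacent domain windows is planted. The new/old contrast:

```r
res$bootstrap
#> Bootstrap partition test (new vs old proteins)
#>   genomes: 8 (new ratio > old ratio in 8)
#>   trials:  10000
#>   p-value: 0.0041
```

All eight genomes show stronger alignment in planted-new proteins, which
random partitions reproduce in only 0.4% of trials. `tidy(res$bootstrap)`
returns the per-genome ratio pairs, `glance()` the one-row test summary,
and `plot_genome_ratios(res$summary)` / `plot_new_old_ratios(res$new_old)` /
`autoplot(res$bootstrap)` draw the standard figures.

Real annotations work the same way: point `run_pipeline()` at a table of
per-genome GTF/GFF3, domain TSV (`protein_id, domain_id, start, end`),
disorder TSV (consensus regions, or per-predictor 0/1 tracks collapsed at
a 75% consensus), and optional new/old label files.

A thin command-line wrapper (`inst/cli/boundalign.R`) exposes
`generate`, `run` and `report` subcommands over the same functions.

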