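# mcmbench

Benchmarking quantitative microbial profiling against a synthetic
metagenomic control material, entirely in silico.

## The problem

Microbiome studies quantify community composition either by 16S rRNA
amplicon sequencing or by whole-genome shotgun (WGS) sequencing. Both are
long measurement chains — PCR or library preparation, sequencing, read
filtering, taxonomic assignment, normalisation — and each step contributes
random error (imprecision) and systematic error (bias). With real samples
of unknown composition the two cannot be separated. A *metagenomic control
material* (MCM) — a defined mix of genomic DNAs from known species at
known genome-copy concentrations, independently quantified by fluorometry
and digital PCR (dPCR) — makes both measurable.

`mcmbench` is for method developers and bioinformaticians who want that
benchmarking framework as executable, testable code: a ten-species
MCM-like community (5 Gram-negative + 5 Gram-positive; genomes
1.85–6.26 Mb; 16S rRNA gene copy numbers 4–8; abundances ~100 to >50,000
copies/µL), simulators for every measurement of it, and the downstream
informatics and statistics.

## What it implements

* **Community model** — species with genome length `g_i`, rrn copy number
  `r_i`, true abundance `a_i`; dsDNA mass↔copy conversion
  (`copies = m·1e-9·N_A/(g·650)`).
* **Synthetic references** — per-species 16S-like genes (conserved regions
  flanking divergent variable blocks; 337 bp and 564 bp amplicons) and
  genomes embedding the gene `r_i` times; a rooted rank taxonomy; database
  corruption (drop / mislabel taxa) for studying reference effects.
* **Amplicon simulation with PCR bias** — reads drawn with weights
  `w_i = a_i · r_i · (1 + E_i · δ^{m_i})^C` (35 cycles; `m_i` primer
  mismatches; run-level and species-level efficiency jitter), four primer
  strategies (`alpha`: Gram-negative-specific, 2 mismatches on
  Gram-positives; `beta`/`gamma`/`delta`: matched mixes), bimera
  formation, 454-like substitution + homopolymer-indel errors with
  decaying qualities.
* **WGS simulation** — paired-end 2×100 bp reads with weights `a_i · g_i`,
  Illumina-like errors.
* **Filters** — the high-stringency amplicon filter (≤2 primer
  mismatches, bimera removal, 50 bp/Q35 sliding-window trim, 200 b minimum
  and 1.1× maximum length, no ambiguous bases, no homopolymer >8) with
  one-reason-per-read attrition accounting, and the WGS filter (end-trim,
  ≥30 bases, ≥90% of bases Q30+, mate-aware pair bookkeeping).
* **Assignment** — shared-k-mer scoring, retention of hits within 1% of
  the top score, lowest-common-ancestor (LCA) placement on the taxonomy,
  minimum support of 5 reads per called taxon.
* **Quantification** — rrn-copy-number (amplicon) or genome-size (WGS)
  normalisation to percent profiles; plasmid-hit exclusion; dPCR Poisson
  estimator `λ = −ln(1 − k/N)`, `M = Nλ`, with delta-method 95% CIs and
  triplicate aggregation.
* **Statistics** — per-species %CV precision matrices, bootstrap
  subsampling precision curves (sizes 500–30,000, B = 1000), Welch
  t-tests with Bonferroni correction and OLS slope tests (vs 0 and vs 1)
  for fluorometry-vs-dPCR comparison.

See `vignettes/mcmbench-methods.Rmd` for models, parameter choices and
limitations.

## Worked example

```r
library(mcmbench)

community <- mcm_community(genome_scale = 0.01)  # desk-scale genomes
ref <- build_reference(community, seed = 1)
strategy <- primer_strategy("beta", ref)          # mixed specific primers

run <- run_amplicon_pipeline(ref, strategy, n_reads = 5000, seed = 1)
run$report
#> <filter_report> 5000 reads in, 4075 surviving (81.5%)
#>   removed: primer=181, chimera=15, too_short=728, homopolymer=1
print(run$profile, digits = 3)
#>                     species raw_count normalized percent
#> 1    Neisseria meningitidis      1618     404.50  50.152
#> 2     Klebsiella pneumoniae      1041     130.12  16.134
#> 3          Escherichia coli       554      79.14   9.813
#> 4    Pseudomonas aeruginosa        94      23.50   2.914
#> 5   Acinetobacter baumannii         0       0.00   0.000
#> 6  Streptococcus pneumoniae       414     103.50  12.833
#> 7     Staphylococcus aureus       215      43.00   5.331
#> 8    Streptococcus pyogenes        91      15.17   1.880
#> 9  Streptococcus agalactiae        41       5.86   0.726
#> 10    Enterococcus faecalis         7       1.75   0.217
```

Reading this: 5000 simulated reads passed the high-stringency filter at
81.5% (primer failures are mostly homopolymer indels inside the priming
region; `too_short` are reads quality-trimmed below 200 bases). Surviving
reads were assigned by k-mer/LCA, counts divided by each species' rrn
copy number and rescaled to percent. The estimates track the true
composition (51.6%, 18.2%, 7.6%, 2.5%, 0.10%, 12.1%, 5.1%, 1.8%, 0.71%,
0.25%); Acinetobacter baumannii (~5 expected reads at this depth) fell
below the 5-read minimum support and is reported as an explicit zero —
exactly the rare-species detection limit the control material is designed
to expose.

Absolute quantification by digital PCR:

```r
panel <- simulate_dpcr_panel(500, seed = 1)   # 500 molecules on the chip
panel
#> <dpcr_panel> 367/770 positive partitions (0.84 nL each)
dpcr_estimate(panel)
#> <dpcr_result> k=367/770, lambda=0.6475, molecules=498.5 [446.6, 550.4],
#>               2569.3 copies/uL
```

The full experiment (all four primer strategies + WGS, triplicate runs,
fluorometry-vs-dPCR comparison, bootstrap depth study) is one call:

```r
exp <- run_experiment(experiment_config(seed = 7), out_dir = "run1")
make_report(exp)    # %CV matrix, abundance-vs-truth, method comparison
```

or from a shell, `Rscript inst/scripts/run_experiment.R --seed 7 --out run1`.

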