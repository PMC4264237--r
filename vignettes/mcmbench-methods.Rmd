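---
title: "Benchmarking quantitative microbial profiling in silico: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking quantitative microbial profiling in silico: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mcmbench)
```

# The measurement problem

Microbial profiling experiments report which organisms are in a sample and
at what relative abundance. Two sequencing routes dominate: amplicon
sequencing of a marker gene (usually 16S rRNA variable regions, after PCR)
and whole-genome shotgun (WGS) sequencing. Both are multi-step measurement
chains — extraction, amplification or library preparation, sequencing, read
filtering, taxonomic assignment, normalisation — and every step can add
random error (limiting precision) or systematic error (bias). Because each
taxon is quantified through a different sequence, the two error types are
hard to separate on real samples of unknown composition.

A *metagenomic control material* (MCM) breaks this circularity: a defined
mixture of genomic DNAs from known species at known genome-copy
concentrations, quantified independently by fluorometry and by digital PCR
(dPCR). Against such a material one can measure the precision (replicate
coefficient of variation, %CV) and bias (deviation from truth) of each
profiling strategy.

`mcmbench` rebuilds that benchmarking framework entirely in silico. It
models a ten-species control material (five Gram-negative, five
Gram-positive members, genome sizes 1.85–6.26 Mb, 16S rRNA gene ("rrn")
copy numbers 4–8, GC contents 33%–67%, abundances from ~100 to >50,000
genome copies/µL), simulates its measurement by four 16S primer
strategies, by paired-end WGS, by partition-based dPCR and by fluorometry,
and implements the downstream informatics: high-stringency read filters,
k-mer/LCA taxonomic assignment, copy-number and genome-size normalisation,
and the precision and method-comparison statistics.

Everything is seeded and reproducible: each stage derives its own RNG seed
from a master seed through `derive_seed()`, so reruns are byte-identical.

# The synthetic community and reference

`mcm_community()` returns the bundled ten-species definition. Per-species
genome sizes, rrn copies, GC fractions and abundances are representative
values inside the published ranges, with the abundance rank order
preserved within each Gram subgroup; they are labelled "MCM-like", not
authoritative, because the exact per-species loadings are not published in
the sources available to the package.

`build_reference()` generates, deterministically per seed, one 16S-like
gene per species with the layout

```
C1 | V12 | C2 | linker | C3 | V456 | C4
```

where the conserved regions C1–C4 (64 bp each) are identical within a Gram
subgroup and differ between subgroups at 2 sites, and the variable blocks
V12 (209 bp) and V456 (436 bp) are drawn independently per species
(re-drawn until all pairs differ by at least `d_min = 10` substitutions;
in practice random draws differ at ~70% of sites). The two amplicon blocks
C1+V12+C2 and C3+V456+C4 are 337 bp and 564 bp, matching the two amplicon
sizes of the emulated assays. Each genome embeds the gene `rrn_copies`
times, evenly spaced in random background of the species' GC composition,
and has exactly the community's stated length. Gene regions are generated
with single-base runs capped at 4 (so no true sequence can contain a
homopolymer longer than 8, even across region boundaries): the filter's
homopolymer rule targets sequencing artifacts, and a reference whose
*true* sequence tripped it would silently delete a species from every
profile — real 16S sequences do not carry such runs either.

Two deliberate simplifications follow from this design. First, real 16S
variable regions are far more conserved across taxa than independent random
draws, so species discrimination is *easier* here than in nature: the
assignment accuracy the tests demonstrate is a property of the pipeline on
well-separated references, not a claim about closely related taxa. Second,
primer strategies are modelled by their *mismatch structure*, not by
literal primer sequences (which are not available as text): what is
preserved is the testable mechanism — a single primer that matches one
subgroup perfectly and the other with 2 mismatches (alpha), versus
mixed/degenerate/cross-priming strategies with no mismatches (beta, gamma,
delta).

## Genome scaling

Simulation studies use `mcm_community(genome_scale = 0.01)`: genome
lengths at 1% of full size (18.5–62.6 kb). Every relative quantity is
invariant to uniform genome scaling — WGS read sampling weights are
$a_i g_i$ and the genome-size normalisation divides by the same $g_i$ —
so this changes nothing in the statistics while keeping reference
construction and k-mer indexing light. The package's tests and acceptance
script use this scale; the full-size community is the default for
`mcm_community()` itself.

# Measurement models

## PCR amplification bias (amplicon strategies)

Species $i$ with abundance $a_i$ (genome copies/µL) and $r_i$ rrn copies
enters PCR with template weight $a_i r_i$. Amplification over $C = 35$
cycles is modelled deterministically: with per-cycle efficiency $E$ and a
per-mismatch efficiency penalty $\delta \in (0, 1]$, a species facing
$m_i$ primer mismatches is amplified by $(1 + E\,\delta^{m_i})^{C}$, so
reads are drawn multinomially with weights

$$ w_i = a_i\, r_i\, (1 + E_i\, \delta^{m_i})^{C}. $$

Replicate-to-replicate PCR variability enters through the efficiency:
$E_i = E_{\mathrm{run}} + \varepsilon_i$, where $E_{\mathrm{run}} \sim
N(E_{\max}, \sigma_{\mathrm{run}})$ is shared by all species in a run and
$\varepsilon_i \sim N(0, \sigma_{\mathrm{sp}})$ is independent per
species. For strategies with $m_i = 0$ everywhere (beta, gamma, delta) the
shared term cancels in the read *proportions*, leaving only the
species-level jitter; for alpha ($m_i = 2$ on Gram-positives) the shared
term does **not** cancel, because matched and mismatched species respond
to $E_{\mathrm{run}}$ with different exponents. That is the package's
mechanism for the alpha strategy's excess run-to-run variance on the
subgroup its primer does not match.

Defaults (all exposed in `primer_strategy()`): $E_{\max} = 0.12$,
$\delta = 0.7$, $C = 35$, $\sigma_{\mathrm{run}} = 0.03$,
$\sigma_{\mathrm{sp}} = 0.005$, chimera probability 0.01. Two notes on
these choices:

* Because the weight applies one fixed efficiency across all 35 cycles,
  $E$ is an *effective whole-reaction average* — including the plateau
  phase where amplification stalls — not an early-cycle efficiency (which
  would be near 0.9). The product $C \cdot E$ is what matters. With
  $E_{\max} = 0.12$ and $\delta = 0.7$, two mismatches depress a species
  about 7-fold: strongly biased but still detected, which is the regime
  the benchmark needs — a strategy whose mismatched species vanished
  entirely could not exhibit *imprecision* on them. With these values the
  log-share of a mismatched species responds to $E_{\mathrm{run}}$ with
  sensitivity $\approx -15$, so $\sigma_{\mathrm{run}} = 0.03$ yields
  ~35–50 %CV on mismatched species while matched species sit at ~15–20
  %CV from the species-level jitter alone.
* These are *study conditions*, set once: the %CV ordering checks in the
  test suite are statements about the model under these conditions, and
  the per-cell %CV magnitudes are not calibrated to any published table
  (the published values derive from real instrument runs that are not
  reproducible at desk scale).

Chimeras (bimeras) are formed, with the configured probability, by joining
the prefix of one parent amplicon to the suffix of another at a uniform
interior breakpoint; both parents are drawn from the pre-error amplicon
pool, and chimeric reads are recorded as such in the truth table.

PCR products carry the *primer's* bases at their ends (as real products
do): under alpha every product carries the Gram-negative conserved
variant; under beta/gamma each carries its own subgroup's variant.

## Sequencing error and quality model

Amplicon reads use a pyrosequencing-like model: constant per-base
substitution rate (default 0.004) plus homopolymer indels — for a run of
length $L$ the per-run indel probability is
$\min(0.003\,(L - 1),\ 0.03)$, insertion or deletion with equal
probability. Per-base Phred qualities decay linearly along the read
(40 → 36 by default) with a per-read offset (SD 2) and per-base noise
(SD 3), so the sliding-window trim and the length/quality rules are
genuinely exercised. WGS reads use an Illumina-like substitution-only
model (rate 0.001) with a flatter profile (38 → 34, read offset SD 2.5);
under these defaults a few percent of WGS reads fail the 90%-Q30 rule,
producing realistic attrition. No flowgram simulation, quality
recalibration or instrument-trained profile is attempted.

## Digital PCR

A panel loads $M$ molecules into $N = 770$ partitions of 0.84 nL
uniformly and independently; $k$ partitions are positive. The estimator
inverts the Poisson occupancy:

$$ \hat\lambda = -\ln(1 - k/N), \qquad \hat M = N \hat\lambda, $$

with sample concentration $\hat M / (N V_p) \cdot D$ for partition volume
$V_p$ and dilution factor $D = 4/1.2$ (1.2 µL of material in a 4 µL
reaction). The 95% CI propagates the binomial standard error of $k/N$
through the log transform (delta method), truncated at zero; the method is
a documented choice, since only the existence of the intervals is
published, not their construction. A saturated panel ($k = N$) is an
error, as $\hat\lambda$ is unbounded. In `dpcr_quantify_community()` each
species is pre-diluted so the expected load is ~385 molecules (occupancy
~0.5), the load itself is Poisson-distributed around that expectation, and
triplicate panels are combined with a t-based interval — mirroring how the
instrument workflow dilutes "to the appropriate concentration". The
volume/dilution bookkeeping ($N V_p$ = 646.8 nL per panel, $D = 4/1.2$)
is a stated assumption, exposed as parameters.

## Fluorometry

Each species' true mass concentration (from its copy number via the
standard dsDNA conversion, below) is observed through a multiplicative
species bias and mean-one lognormal noise (CV 0.05), in triplicate with
the mean reported. The default experiment gives Pseudomonas aeruginosa a
3-fold bias, reproducing the one known fluorometry/dPCR discordance in
the material; all other species are unbiased.

Mass-to-copies uses $\mathrm{copies} = m_{\mathrm{ng}} \times 10^{-9}
N_A / (g \times 650)$ with $650\ \mathrm{g\,mol^{-1}\,bp^{-1}}$ as the
average double-stranded base-pair molar mass. The source material never
states its conversion; 650 is the field-standard constant and is
prominently documented here because every fluorometry-derived copy number
depends on it.

# Read filtering

The amplicon filter applies the published high-stringency rules in a fixed
order, so each removed read has exactly one (first-failing) reason and the
per-rule counts always sum to the input count:

1. **primer** — read prefix within 2 mismatches of a forward primer
   variant (ungapped, N counts as mismatch);
2. **chimera** — bimera detector (below), run on the quality-trimmed
   sequence;
3. **too_long** — raw (pre-trim) length > 1.10 × expected amplicon
   length;
4. **too_short** — quality trimming truncates before the first 50 bp
   window whose mean Phred quality is strictly below 35 (windows advance
   one base; sub-window reads are one full-read window); drop if fewer
   than 200 bases remain;
5. **ambiguous** — any N;
6. **homopolymer** — any single-base run strictly longer than 8.

The quality trim is computed before the chimera test even though
removals are attributed in the order above: trimming is idempotent, and
judging chimerism on the trimmed sequence is what makes the whole filter
idempotent (filtering survivors removes nothing) — a raw-sequence chimera
test can change its verdict after trimming.

Choices the published text leaves open, fixed here: the rule order is the
sentence order of the source protocol; "average quality" is the
arithmetic mean of Phred scores; "below 35" is strict; the 10%
over-length test uses the raw (pre-trim) length; primer matching in the
bulk filter uses the forward primer only (the reverse primer may be
removed by quality trimming, and one-reason-per-read accounting plus
idempotence — filtering survivors must remove nothing — requires rules
that act on what trimming preserves). `match_primer()` itself supports
either orientation.

The bimera detector replaces a full chimera-search tool with the minimal
two-parent test: a read is flagged when some split point gives left- and
right-segment identities ≥ 0.9 to two *different* parent amplicons while
its full-length identity to every single parent is < 0.9. Identities are
ungapped and position-aligned from the read start, split points keep at
least 20 bases on each side, and a read identical to any parent is never
flagged. Ungapped comparison means reads carrying early indels drift out
of register and are judged by their (low) downstream identity — such reads
are typically not flagged and fall through to the later rules instead,
which is acceptable for the error rates simulated here.

The WGS filter end-trims bases below Q20 from both read ends (the trim
threshold is not parameterised in the source text; Q20 is this package's
default), then drops reads shorter than 30 bases or with fewer than 90%
of bases at Q30+. A surviving read whose mate was dropped is rerouted to
the unpaired stream, keeping pair files synchronised.

# Taxonomic assignment

`assign_reads()` replaces the BLAST + LCA-classifier pair with a
deterministic, dependency-free equivalent:

* **Scoring**: the score of read vs reference is the number of the read's
  distinct 12-mers present in the reference, taking the better of the two
  orientations. On these references (variable regions ~70% divergent) a
  read scores near its maximum against its source and near the shared
  conserved-region floor against everything else.
* **Top-score retention**: keep hits with score ≥ 0.99 × top score — ties
  for the top all qualify, so no arbitrary first-hit choice exists.
  Because k-mer scores are integers, a 1% window narrower than one score
  unit would reduce to "exactly the top score" and make assignment
  sensitive to single chance k-mer collisions; the reference design
  avoids this by keeping the conserved-region score floor above 99
  (64 bp conserved regions give 2 × 53 = 106 shared k-mers), so ties
  across same-subgroup references survive a one-unit perturbation.
* **LCA**: the read is assigned to the deepest taxonomy node that is an
  ancestor-or-self of every qualifying record's node. Reads from a
  species absent from the reference tie across the remaining
  same-subgroup references on conserved-region k-mers and resolve to a
  shallow node — the missing-genus phenomenon the database-corruption
  tools exist to study.
* **Minimum support**: at the reporting rank, taxa with fewer than 5
  supporting reads are suppressed and their reads counted as
  unassigned-at-rank. The threshold applies at whatever rank is reported;
  the WGS pipeline (raw alignment counting) uses `min_support = 1`.

`corrupt_reference()` emulates imperfect public databases: dropping taxa
(sequences and taxonomy nodes disappear, with internal nodes pruned) and
mislabelling (bases kept, taxonomy path swapped), with a provenance log.

# Quantification and statistics

Species-level counts are normalised by rrn copy number (amplicon) or
genome size (WGS), then rescaled to percentages summing to 100; absent
species get explicit zeros so replicate profiles are comparable. Plasmid
hits can be excluded before normalisation (copy number unknown);
unlabelled references count as chromosome with a warning.

Precision is the per-species %CV across replicate profiles, with the
sample (n−1) standard deviation — with triplicates this choice matters.
Strategy averages are arithmetic means over species; species with
all-zero replicates have undefined CV and are dropped from averages
(`NA`), which is reported rather than imputed.

Method comparison uses Welch's unequal-variance two-sample t-test on
replicate log10 copy numbers (the source says only "t-test"; Welch is the
robust default), Bonferroni-corrected with divisor = number of species
tested (10). The slope of log10 method A vs method B means is tested
against 0 and against 1 by t-tests on n−2 degrees of freedom; agreement
between methods shows as a slope distinguishable from 0 but not from 1.
These standard fits are delegated to `stats::t.test()` and `stats::lm()`;
the test suite pins them to hand-computed closed-form values at 1e-10.

The bootstrap depth study draws, for each subsample size (default ladder
500–30,000) and B replicates (default 1000), reads with replacement from
the filtered set — streams are sampled in proportion by construction —
and recomputes the profile. Since per-read assignment is deterministic,
the implementation assigns the full read set once and resamples the
per-read labels; this is exactly equivalent to re-running assignment per
subsample and is what makes B = 1000 tractable. Per-(size, replicate)
seeds derive from the master seed by a counter scheme.

# Problem sizes and numerical tolerances in the test suite

The suite checks properties at these sizes, chosen as the package's own
balance of statistical power against turnaround: dPCR recovery on 1000
panels per load at loads 100–2000 (median recovery within 2%, delta CI
coverage ≥ 93%); LCA vs a brute-force oracle on 1000 random node sets;
end-to-end error-free recovery at 10,000 reads within 3 multinomial
standard errors; the strategy %CV ordering over 20 replicate triplets at
depth 3000; the bootstrap study on one 50,000-pair WGS replicate with
B = 200; stochastic comparisons generally use 3–4σ bands. Monte-Carlo
monotonicity checks on CV-vs-depth allow a 25% tolerance per step, and
CV-vs-multinomial agreement is asserted within a factor of 2.

# What passing tests do and do not show

The generator emulates: compositional truth with realistic spans of
abundance, genome size and rrn copy number; mismatch-driven PCR bias with
run-level and species-level efficiency variation; chimera formation;
454-like homopolymer errors and quality decay; Illumina-like WGS errors;
Poisson partition statistics; fluorometric bias and noise. It does not
emulate: real 16S conservation structure (assignment here is easier),
extraction and library-preparation chemistry, instrument-specific error
profiles, strain-level variation (one strain per species), plasmid
sequences (plasmid exclusion is exercised via labels), or human gDNA
background (available as an option, default off). Conclusions from green
tests are therefore about the correctness and internal consistency of the
measurement chain and its statistics — not about the wet-lab performance
of any real assay.

# Known limitations

* The exponential PCR-bias model couples suppression strength to
  jitter sensitivity; regimes with strong bias but low run-to-run
  variance (or vice versa) need `e_max`/`mismatch_penalty` chosen
  jointly. A per-cycle stochastic duplication mode would decouple them at
  simulation cost.
* Integer k-mer scores quantise the 1% top-hit window; the reference
  design keeps the window wider than one score unit (see above), but
  references with very short conserved stretches would reintroduce
  sensitivity to single chance k-mer collisions.
* The bimera detector is ungapped and two-parent only; multi-parent
  chimeras or indel-shifted chimeras may evade it (and then usually fail
  later rules).
* dPCR confidence intervals are delta-method approximations; at very low
  occupancy they are conservative.
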