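---
title: "Profiling bacterial methylomes and modelling cell-cycle-gated CcrM methylation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling bacterial methylomes and modelling cell-cycle-gated CcrM methylation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methylcycle)
```

## The biology in brief

Most Alphaproteobacteria carry CcrM, an orphan adenine methyltransferase
that methylates the A of GANTC on both strands. In dividing cells CcrM is
present only in a short window at the end of the cell cycle. Passage of the
replication fork therefore converts each fully methylated GANTC duplex into
two hemimethylated duplexes, which stay hemimethylated until CcrM fires. In
an asynchronous culture, loci replicated early (near the origin, *ori*)
spend a large share of the cell cycle hemimethylated, while loci replicated
just before CcrM fires (near the terminus, *ter*) spend almost none. The
population-averaged "extent of methylation" — the fraction of sequenced
strands at a site that carry the mark — consequently rises from *ori* to
*ter*, producing the "frowning" profile of a replicon linearised at its
origin. Arrested cells that have completed replication and methylation show
a flat profile near 1; in terminally differentiating rhizobial bacteroids,
which endoreduplicate their genomes without dividing, a late loss of CcrM
activity produces the opposite, "smiling" profile. `methylcycle` implements
this entire chain: motif statistics, extent profiling, the population
model, motif discovery, copy-number inference from depth, promoter
enrichment, and a generator for every input.

## The population model

All timing is expressed in units of the doubling time $T$. A replicon
initiates bidirectional replication at $t_{\mathrm{init}}$ and completes it
at $t_{\mathrm{init}} + C$; a locus at arm fraction $f$ (0 at *ori*, 1 at
the antipode, `arm_fraction()`) is replicated at
$t_r = t_{\mathrm{init}} + C f$. An asynchronous exponential culture has
steady-state age density

$$f(a) = \frac{2\ln 2}{T}\, 2^{-a/T}, \qquad 0 \le a < T,$$

young cells being twice as frequent as cells about to divide. Weighting
every cell by its strand count (a sequencer samples strands, not cells), a
locus whose delay between replication and CcrM firing is
$\Delta = t_{\mathrm{ccrm}} - t_r$ has population extent

$$E(\Delta) = 2^{-\Delta/T},$$

which is `closed_form_extent()`. Its endpoints are the two biological
limits: $\Delta = 0$ gives 1 (methylated the moment it is replicated) and
$\Delta = T$ gives $1/2$ (hemimethylated throughout). At $\Delta = T/2$ the
model gives $2^{-1/2} \approx 0.71$, matching the extent observed at
origin-proximal chromosomal loci in exponentially growing cells. The same
age integral gives the expected copies of a locus per cell,
$2^{1 - t_r/T}$ (`copy_number_expectation()`), whose *ori*:*ter* ratio
$2^{C/T}$ links replication timing to sequencing-depth gradients.

We do not take the closed form on faith: `simulate_population()` is an
agent-based implementation that draws cell ages, tracks per-locus strand
counts per cell, and reports read-weighted extents. The test suite holds
the two routes to within 0.01 of each other at $10^4$ cells across a grid
of delays; `analysis/04_population_model.R` reports the realised maximum
error (0.005 at the shipped seed).

### Differentiation regimes

`differentiation_presets()` encodes five canonical stages:

| stage | CcrM mode | rounds | profile |
|---|---|---|---|
| `exponential` | pulse at `t_ccrm` | 1 | ascending to *ter* ("frown") |
| `stationary` | completed, arrested | — | flat at 1 |
| `early_bacteroid` | constitutive, lag 0.05 T | 1 | flat near 1 |
| `endoreduplicating` | constitutive, lag 0.25 T | 4 | flat, intermediate |
| `late_bacteroid` | constitutive, shutoff at 0.5 T in the final round | 4 | descending to *ter* ("smile") |

Choices that the data do not pin down, made once here: endoreduplicating
populations are simulated asynchronous across rounds (elapsed time uniform
over `rounds`·T), since no synchronisation mechanism is known for
bacteroid endoreduplication; each round lasts one $T$; and the bacteroid
presets use a short replication period (C = 0.1 T), consistent with genome
replication being fast relative to the round period — this is also what
makes the constitutive regime's profile flat rather than weakly sloped,
since the per-locus hemimethylated interval (the lag δ) is then nearly
independent of arm position. The late-bacteroid shutoff at 0.5 T bisects
the re-methylation window `[t_r + δ]` of the chromosome so that
origin-proximal loci are re-methylated in the final round and
terminus-proximal loci are not, which is what produces the smile. The
exponential-phase chromosome preset (`t_init` 0.2, `C` 0.5, `t_ccrm` 0.7)
puts $\Delta$ at 0.5 T at *ori* and 0 at *ter*, spanning extents 0.71–1.0;
secondary replicons initiate later and replicate faster (`t_init` 0.4,
`C` 0.25), reproducing their higher *ori*-proximal extents.

In the `off` mode (no re-methylation at all) the two originally methylated
strands are diluted $2^{-r}$ per round; the late-shutoff regime therefore
sits strictly between the constitutive and off regimes in mean extent, and
the simulated series arrested > endoreduplicating > late-shutoff mirrors
the ordering of mean chromosome extents observed along the bacteroid
differentiation series.

## Extent profiles and their classification

`window_extent()` averages per-strand-site fractions in sliding windows
(default 10 kb window, 1 kb step; the window size is the conventional
choice for such profiles, the step is ours). Every strand of a duplex site
is an independent observation — a hemimethylated duplex contributes
fractions {1, 0} — and window means are unweighted by coverage because the
fraction is already a per-site estimate. Replicates are averaged per
strand-site before windowing. Windows wrap across the origin junction of
circular replicons; empty windows carry `n_sites = 0` and no extent.

`fit_trend()` fits the windowed means with a degree-2 polynomial by
iteratively reweighted least squares with Huber weights (tuning constant
1.345, at most 50 iterations, tolerance $10^{-8}$) on an orthogonalised
predictor — the `rlm(y ~ poly(x, 2))` fit conventionally drawn over such
profiles — using the genome coordinate rotated so *ori* maps to 0. On
(near-)exact polynomial data the robust scale vanishes and IRLS cannot
iterate; the least-squares fit, which is then identical, is used directly.
`classify_pattern()` compares the fitted extent at the profile ends (*ori*)
with the midpoint (*ter*): a difference above θ = 0.02 in either direction
labels the profile `ascending_to_ter` or `descending_to_ter`, otherwise
`flat`. θ is ours to choose; 0.02 is comfortably above the window noise of
the shipped generator settings and far below the regime signals (≥ 0.1).

`persistent_hypomethylated()` flags strand-sites whose fraction stays
below τ = 0.2 (or which are absent) in **every** replicate. No published
threshold exists for this; 0.2 sits well below the minima observed in any
simulated regime, and the planted-truth test recovers exactly the sites the
generator forced to zero.

## Motif statistics and discovery

`scan_motif()` matches IUPAC motifs via `Biostrings`; palindromic motifs
(equal to their reverse complement, like GANTC and TCGA(N8)TCGA) are
scanned on the plus strand only, one site per duplex position, and
`expected_density()` counts them the same way, so observed and expected
densities are commensurable. Recognition pairs are stored 5'→3' and paired
through true reverse complements (not the unreversed base-wise complements
sometimes printed in inventory tables). The methylated base of the
opposite strand, where present, is carried as `partner_offset`;
`motif_strand_sites()` expands each duplex occurrence into its methylated
strand-sites. One caveat: ambiguous (N) bases in a genome are never
matched by any motif column, including motif N — a deliberate
simplification; the generators emit no Ns.

Density expectations divide by total sequence length (not non-N length),
and `region_density()` classifies a site by its methylated-base position:
inside any annotated gene interval (either strand) is coding, else
intergenic. Site counts in coding plus intergenic always reconstruct the
genome-wide count. Group comparisons use Welch's t test by default (the
pooled form is a switch) for two groups and one-way ANOVA with Tukey's HSD
beyond that.

`discover_motifs()` recovers motifs from catalogues of methylated
positions by iterative greedy column consensus: ±12 bp context windows
oriented 5'→3' on the methylated strand; per column a base at ≥ 0.9
frequency, a 2-fold IUPAC code when the top two bases reach 0.95 (3-fold
codes collapse to N, since real inventories rarely need them); flanking Ns
trimmed; candidates accepted when ≥ 50% of their genome occurrences are
marked and they explain ≥ 1% of the remaining marks; explained marks
removed and the loop repeated. Two refinements make this work on real
mixtures. First, when a candidate fails validation, windows that mismatch
its specified columns are dropped and the consensus re-derived — this
evicts spurious marks that would otherwise dilute degenerate columns
below threshold. Second, non-palindromic motifs methylated on both strands
split their marks into two reverse-complement context families whose 50/50
mixture keeps every discriminating column below the majority threshold;
when match-filtering stalls, the round splits on the single most
concentrated sub-threshold column, which separates the families within a
few iterations. After acceptance, a consistent opposite-strand mark offset
inside the occurrence footprint is detected and recorded as the partner
offset, so both families of a bipartite motif are explained by one
discovered motif. The ±12 flank spans the longest bipartite motif in the
inventories (16 bp, methylated base at offset 3); detection rates are
computed against the full mark catalogue so that sites shared with a
previously accepted motif (e.g. a methylated A inside both a GANTC and a
bipartite site) do not count against a later motif. The acceptance
thresholds are not published for the reference implementation this stage
emulates; the defaults here are validated by planted-truth recovery and
documented as this package's own.

## Copy number from depth

`relative_depth()` reduces windowed depth tables to per-replicon means
(unweighted over 10-kb window means, edge windows shorter than half a
window dropped) and divides by the chromosome of the same sample — per
window rather than per base, a documented choice that makes the statistic
robust to length non-multiples. `percent_reduction()` is the Table-style
`100 (1 − ratio)`; at per-cell copies 3:2:2 the secondary replicons sit
~33% below the chromosome. Ratios are invariant to uniform depth scaling,
and on simulator output the within-replicon gradient reproduces
$2^{C/T}$.

## Promoters and candidate regulons

Promoters are the 125 bp immediately upstream of a transcript (plus
strand: `[start−125, start−1]`; minus strand: `[end+1, end+125]`), wrapped
across circular origins and **not** clipped at upstream gene boundaries —
whether the original analysis clipped is unstated, so the simpler
convention is used and documented. Genes inherit their transcript's
promoter, so operon members share one. `enrichment_test()` is the
upper-tail hypergeometric $P(X \ge k)$ with fold $(k/n)/(K/N)$, verified
against exhaustive enumeration for every universe up to $N = 12$;
`group_balance_test()` (chi-square goodness of fit across expression
groups) backs statements that an overlap is "unbiased" across groups. Both
test choices are pragmatic conventions of this package, not uniquely
implied by the analysis design.

## The synthetic-data generator, and what passing tests mean

`random_genome()` draws i.i.d. bases at GC 0.619 — the average GC content
of the genus the fixtures emulate. `build_strain_fixtures()` produces four
~1 Mb annotated genomes carrying the four strains' motif inventories
(GANTC shared; RCGCCTC, CGCA(N5)GTG, TCGA(N8)TCGA, CAGA(N7)GTTG, WNCCGATG
strain-specific); motifs whose natural occurrence falls below 200 copies
(the long bipartite ones, ~24 expected per Mb) are spiked as concrete
realisations at recorded random positions. `generate_methylome()` assigns
every GANTC strand-site its analytic extent under a mixture of stage
presets, other motifs a constitutively high extent (0.98), then emulates
detection with Poisson coverage (mean 60) and Binomial sampling with a 5%
per-strand false-negative rate and 1% false-positive rate; the 5% miss
rate reproduces the ~0.95 genome-wide extent characteristic of
stationary-phase calls. `generate_depth()` draws per-10-kb-window Poisson
depth proportional to copy ratios, optionally shaped by the replication
gradient.

Fixtures are ~1 Mb rather than full rhizobial size so the complete
analysis runs in minutes; densities, not absolute counts, are the
cross-checked quantities at that scale (the test suite uses genomes from
0.1 to 5 Mb, and the acceptance script simulates depth on
3.6/1.4/1.7 Mb replicons with ~670 windows). What the generator does *not*
emulate: sequence composition beyond i.i.d. bases (no dinucleotide bias,
no GANTC depletion — depletion in real genomes is detected *relative to*
the random expectation), kinetic artifacts of base-modification calling,
coverage dips near repeats, or the read-level structure of alignments.
Passing tests therefore demonstrate that the statistics and the model are
implemented correctly and recover planted truths under realistic sampling
noise — not that any particular biological genome satisfies the model.

## Numerical and degenerate-input conventions

Coordinates are 1-based inclusive throughout; circular arithmetic is
modulo length. *ter* is modelled as the antipode of *ori* for timing even
when a skew-derived terminus differs (that estimate is reported
separately as `skew_ter_pos`), because the fork model assumes symmetric
bidirectional replication. Skew-based origin inference (`ori_spec =
"infer"`, minimum of the cumulative GC skew) is offered for
chromosome-like replicons but repABC replicons' weak skew makes it
provisional there. Empty windows, empty mark sets, zero-coverage sites
(absent from call tables, as in real output) and annotation-free genomes
all degrade gracefully; degenerate statistics (zero reference depth,
groups of size one, fewer than six windows for a trend) raise errors
rather than guessing. All stochastic functions take an explicit seed and
restore the RNG state.

## Known limitations

The model has no D-period beyond `t_ccrm ≤ T`, no fork-speed variation,
and no per-cell variability in timing parameters; bacteroid rounds are
equal-length and age-asynchronous by assumption. Motif discovery assigns
only 2-fold degenerate codes and will split a genuinely 3-fold degenerate
column into separate motifs. Depth inference does not correct GC bias or
mappability. The promoter analysis takes transcript structure from the
annotation as given and does not predict transcription start sites.
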