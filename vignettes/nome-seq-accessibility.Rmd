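---
title: "Modelling chromatin accessibility from NOMe-seq GpC footprints"
author: "nomefoot"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling chromatin accessibility from NOMe-seq GpC footprints}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nomefoot)
```

## The assay and the model

NOMe-seq treats nuclei with the M.CviPI GpC methyltransferase before
bisulfite conversion.  The enzyme methylates cytosines in GpC context only
where the DNA is not wrapped around a nucleosome or bound by protein, so a
single bisulfite library reads out two signals at once: endogenous CpG
methylation at `HCG` trinucleotides and chromatin accessibility at `GCH`
trinucleotides (H = A, C or T).  `GCG` sites are ambiguous between the two
signals and are excluded everywhere.

The central object of this package is the ordered series of GCH
observations along a chromosome, one pair (methylated count, total count)
per site.  We model it with a two-state hidden Markov model:

* **protected** state (MPR, methyltransferase-protected region) —
  nucleosome-occupied DNA, low labeling probability;
* **accessible** state (MAR, methyltransferase-accessible region) — linker
  or nucleosome-depleted DNA, high labeling probability.

Emissions are beta-binomial: at a site with $n$ reads in state $s$,

$$k \mid n, s \sim \mathrm{BetaBin}(n, \alpha_s, \beta_s),$$

which absorbs the site-to-site overdispersion (enzyme efficiency,
conversion and mapping variability) that a plain binomial would
misattribute to state switching.  The parameterization exposed to users is
the emission mean $\mu_s = \alpha_s/(\alpha_s+\beta_s)$ and intra-site
correlation $\rho_s = 1/(\alpha_s+\beta_s+1)$; $\rho \to 0$ recovers the
binomial.  Identifiability is fixed by ordering: the accessible mean is
always the larger one.

Transitions between consecutive GCH sites are homogeneous
(distance-independent).  Because GCH sites are irregularly spaced, long
site deserts would otherwise couple unrelated regions, so the series is
broken into independent chains wherever the gap between consecutive sites
exceeds `max_gap` (default 500 bp, exposed as a flag; the choice is a
documented design decision, not an estimate).

## Fitting, decoding, segmentation

`fit_nome_hmm()` runs EM with the forward-backward recursions in log
space (compiled code; the sums over sites are exact, not subsampled).
The emission M-step is method-of-moments on responsibility-weighted
counts.  Moment updates alone do not guarantee the EM ascent property, so
the update is *guarded*: the previous parameters are always kept as a
candidate and the best candidate under the expected complete-data
log-likelihood wins, making the step a generalized EM step with a
provably non-decreasing log-likelihood.  `emission_update = "exact"` adds
a quasi-Newton refinement of $(\log\alpha, \log\beta)$ to the candidate
set for validation; at realistic depths it changes estimates negligibly.
Training is performed independently per biological replicate, and each
replicate is decoded with its own parameters.

`predict(fit, calls)` returns the Viterbi path (maximum a posteriori
joint path; ties resolve deterministically toward the protected state, so
uninformative stretches default to "closed" rather than inventing open
chromatin).  `assemble_segments()` collapses the path into maximal
same-state runs and enforces the evidence rule that a segment must
contain at least three contiguous GCH sites.  Sub-minimal runs are
absorbed into a flanking run rather than deleted, so segments tile each
chain; because states alternate, both flanks of an interior short run
carry the same state and the absorption target is immaterial to the
result (the tie resolves to the preceding run).  A segment's end
coordinate extends 2 bp past its last GCH so the final dinucleotide is
covered, clipped where the next segment starts sooner.  MPRs of
100-200 bp flanked by MARs on both sides are flagged as candidate
mononucleosomes.

## NDR calling

A MAR is evidence of accessibility; a *nucleosome-depleted region* is a
MAR that is both statistically open relative to its neighbourhood and
long enough to be more than a linker:

1. **Local background** — pool the counts of all MPRs within ±100 kb of
   the MAR (falling back, flagged, to the chromosome-wide MPR pool when
   the window is empty).
2. **Exact one-tailed binomial test** — $P[X \ge k]$ for
   $X \sim \mathrm{Bin}(n, p_0)$ with $p_0$ the pooled background rate.
   Counts are pooled (`sum(meth)/sum(total)`), not averaged per site,
   precisely because this test operates on pooled counts.
3. **Benjamini-Hochberg** correction across all MARs of a replicate;
   calls require $q < 0.01$.
4. **Length rule** — NDRs must be strictly longer than 100 bp.
5. **Replicate support** — only NDRs overlapping (≥ 1 bp) between the two
   biological replicates are kept; the reported interval is the union of
   the overlapping calls, with transitive chains merged.  Each replicate
   is tested on its own and intersected afterwards rather than pooled
   before testing.

## Promoter methylation classes and phasing

Promoters are summarized over a transcription-oriented window from 300 bp
upstream to 500 bp downstream of the TSS.  A promoter is classifiable
only with at least 3 covered HCG sites and 10 reads in the window in
*both* samples.  With pooled window levels $\ell_A$ (parental) and
$\ell_B$ (demethylated):

| class | rule |
|-------|------|
| UU    | $\ell_A < 5\%$ and $\ell_B < 5\%$ |
| MU    | $\ell_A \ge 60\%$ and $\ell_B < 5\%$ |
| MM    | $\ell_A \ge 60\%$ and $\ell_B \ge 25\%$ |

Levels between the unmethylated and methylated cutoffs fall in a gap zone
and are reported `unclassified` — the only reading under which the class
totals can be smaller than the promoter universe.  Promoters
unmethylated in A but methylated in B are not a class of this system;
they are counted with a warning and sunk into `unclassified`.

**Phasing autocorrelation.**  For a promoter class, every pair of GCH
sites lying 0-700 bp downstream of the same TSS is collected, the pair
distance binned at 10 bp, and the Pearson correlation of the two sites'
methylation ratios computed per bin over all pairs pooled across the
class (per-site ratios here, since correlation is across pairs; sites
with fewer than 3 reads are dropped, and bins with fewer than 30 pairs
are undefined).  Regularly phased nucleosomes produce a damped
oscillation of $r$ with its positive peak at the nucleosome repeat
length; unphased chromatin stays inside the $3/\sqrt{n}$ sampling band.
Pooling across promoters (rather than averaging per-promoter curves) is
a documented choice: irregular GCH spacing makes per-promoter curves at
10-bp resolution mostly undefined.

**NP vs NDR subclusters.**  MU promoters are clustered (average linkage,
Euclidean) on their anchor-aligned accessibility profiles in the
demethylated sample and the tree is cut at $k = 2$.  The cluster whose
members more often contain a called NDR overlapping the promoter window
is labelled **NDR** (depletion gained), the other **NP** (positioning
only).  Two numerical choices matter here and were made after explicit
comparison:

* *No row normalization by default.*  The two configurations differ in
  absolute central accessibility; standardizing each row removes exactly
  that signal, and average-linkage cuts then split off single outliers
  instead of the NDR group.  A `normalize` flag restores standardization
  for sensitivity checks.
* *50-bp profile bins for clustering.*  At a mean GCH spacing of ~15 bp,
  10-bp bins are mostly empty or single-site and half the matrix is
  missing; 50-bp bins give near-complete rows.  Heatmap rendering can
  still use 10-bp bins.

## Tracks and domains

Binned signal tracks (10-bp bedGraph, the contract of an upstream signal
pipeline) are z-scored against the genome-wide mean and standard
deviation; the population (1/n) form of the standard deviation is used so
that a two-point track (0, 2, 0, 2, ...) standardizes exactly to
(−1, +1, ...).  `window_summarize()` tiles the genome with 1-Mb windows
and reports pooled GCH accessibility, pooled HCG methylation and mean
track z-scores (track bins inside CpG islands excluded), ranked by
accessibility.  Megabase-scale low-accessibility domains — the analogue
of partially methylated, H3K9me3-marked heterochromatin — surface as the
bottom-ranked windows.  Windows or rows with under 10% coverage are
reported missing; the data never state a coverage floor, so 10% is a
package default.

## The synthetic data generator

Every stage is exercised end to end on synthetic data built by
`build_landscape()` / `simulate_nome_experiment()`.  The generator
emulates:

* irregular GCH/HCG site spacing (geometric gaps; defaults 15 bp and
  50 bp — roughly genomic GpC/CpG density — simulated as position lists
  directly, avoiding a reference FASTA);
* a latent nucleosome occupancy function per sample: truth NDRs
  (occupancy 0), phased arrays, constant unphased background, and
  low-accessibility domains that scale the labeling ceiling;
* enzyme chemistry: labeling probability
  `leak + (efficiency − leak) · (1 − occupancy) · domain_scale`, with
  defaults efficiency 0.8 and leak 0.05 (the data give no quantitative
  efficiency; these are stated defaults chosen to produce realistic
  dynamic range);
* overdispersed depth: negative-binomial reads per site (mean 30,
  dispersion 0.1; dispersion 0 degenerates to Poisson);
* two biological replicates as independent resamplings of the same
  landscape at the same genomic site positions.

**Phased arrays are density conserving.**  The k-th nucleosome away from
the anchor occupies a 147-bp core whose center is positioned with
Gaussian uncertainty growing as `nuc_sd / decay^(k−1)`; its occupancy
contribution is the probability that the core covers a position.  Tight
positioning near the anchor gives deep occupancy oscillation; growing
fuzziness decays the oscillation geometrically while the mean occupancy
per repeat stays near the core-to-repeat ratio (147/190 ≈ 0.77, hence
the default background occupancy 0.75).  An earlier amplitude-blended
bump model was rejected because it leaked net accessibility across whole
arrays and produced spurious NDR calls with no counterpart in the truth.
The default repeat length is 190 bp — the canonical human value, chosen
because the observed periodicity is shown but never stated — and is
configurable; nothing outside the generator hard-codes it.

Promoter ground truth ties the two samples together: UU promoters are
open (NDR + flanking arrays) in both samples; MU promoters are closed in
the parental sample and reorganized in the demethylated one, 80%
gaining positioning alone (an array with a nucleosome *on* the TSS,
`center_bump`) and 20% also gaining a central NDR — the
majority/minority balance of the study system.  For the phasing
statistic the phased class is simulated in the positioning-only
configuration: a central open plateau makes adjacent same-plateau site
pairs trivially correlated and moves the global lag maximum into the
first bin, which is a property of the statistic worth knowing when
interpreting real data.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: sequence-dependent site composition and
bisulfite conversion failure; fragment-level correlation between
neighbouring sites on the same read; copy-number and mappability
artefacts; cell-to-cell heterogeneity of nucleosome positioning beyond
the Gaussian fuzziness; and any coupling between endogenous methylation
and accessibility other than the promoter classes built in by
construction.

## Problem sizes and reproducibility

The bundled checks run the full chain at desk scale: a 10-Mb chromosome
(~670k GCH sites per replicate) for NDR recovery, 500-600 promoters for
classification, phasing and subclustering, and a 10-Mb genome with a
3-Mb scale-0.4 domain for the window ranking — sizes chosen so the whole
suite completes in minutes on one core while every stage still operates
in its intended regime.  All simulations are seeded; identical
configurations give byte-identical outputs, and the pipeline writes a
JSON manifest (package version, configuration hash, input checksums,
seed) alongside each stage's artifacts.

## A worked example

```{r example, eval = FALSE}
library(nomefoot)

sim <- simulate_nome_experiment(chrom_length = 1e6, n_ndr = 20,
                                config = sim_config(seed = 1))

# fit and decode each replicate of the demethylated sample
ndr_reps <- lapply(sim$gch_b, function(calls) {
  fit <- fit_nome_hmm(calls)
  call_ndrs(segment_calls(fit, calls))
})
ndrs <- intersect_replicates(ndr_reps[[1]], ndr_reps[[2]])

# promoter classes, with NP/NDR subclusters for the MU class
prom <- data.frame(gene = sim$tss$name, chrom = sim$tss$chrom,
                   tss = sim$tss$start, strand = sim$tss$strand,
                   is_cgi = TRUE)
tab <- promoter_chromatin_table(prom, sim$hcg_a, sim$hcg_b,
                                gch_b = do.call(rbind, sim$gch_b),
                                ndrs = ndrs)
table(tab$class_label, tab$mu_subclass)
```

## Known limitations

* Transitions are distance-independent between consecutive sites; some
  footprinting HMMs scale transition probabilities with genomic distance,
  and whether the original approach did is not determinable from its
  description.  The chain-break flag bounds the damage from site deserts.
* The two-state model cannot represent partially accessible states
  (e.g. fragile nucleosomes); such sites land on whichever side the
  likelihood favours.
* The binomial background test treats reads as independent; residual
  within-fragment correlation makes the test slightly anticonservative
  at very high depth, mitigated by the exact test's discreteness and the
  strict FDR cutoff.
* GCH strands are kept separate and never merged; strand-merged callers
  will produce slightly different site series.
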