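---
title: "Chromatin-accessibility stratification of GSC cultures: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Chromatin-accessibility stratification of GSC cultures: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`gscatac` implements an analysis pipeline for stratifying bulk ATAC-seq
cohorts of glioblastoma stem-cell (GSC) cultures and for mapping mouse
chromatin-accessibility programs onto human cohorts. The pipeline covers:
saturation modelling of cumulative peak discovery; non-smooth NMF (nsNMF)
consensus clustering with cophenetic model selection; negative-binomial
differential accessibility with cluster-unique peak filters;
correlation-based peak-to-gene linkage against an empirical null;
chromVAR-style transcription-factor motif deviations; and a
homolog-mediated mouse-to-human peak conversion with random-peak null
controls. A synthetic-cohort generator with planted ground truth makes
every stage testable end to end without external data; the numbered
scripts under `analysis/` run the whole workflow on such a cohort.

# The synthetic cohort generator

The generator emulates the structure of a patient-derived GSC ATAC-seq
cohort, not its sequence content.

**Toy genome.** Genes sit on a grid: 200 genes per chromosome, one TSS
every 2 Mb, alternating strand, 50 kb gene bodies. The 2 Mb spacing keeps
every gene's promoter window (−1,000..+100 bp), distal window (3 kb–500 kb)
and far "other" positions (600 kb–1.35 Mb) unambiguous — a peak can fall in
exactly one gene's regulatory neighbourhood. Coordinates are BED-style,
0-based and half-open, and distances are measured from the peak midpoint
`floor((start+end)/2)`, signed along the gene's transcriptional
orientation.

**Counts.** Each peak has an expected count at average depth: `open_mean`
(default 50) where it is open, `closed_mean` (default 5) where closed, and
a per-peak constant drawn log-uniformly between the two for
non-cluster-specific peaks. Per-sample depths are drawn uniformly from
`library_size_range` and enter as relative factors. Counts are negative
binomial with a single global dispersion (default 0.1, i.e. a within-group
CV of ≈0.35 for an open peak) — enough structure to exercise every
downstream contract without modelling fragment-level realism. Cluster
structure is planted by making each cluster's specific peaks (default 1%
of peaks per cluster, all at DRE coordinates) open exactly in that
cluster's samples. Defaults follow the cohort the pipeline targets: 60
human samples in three clusters of 20, 20,000 peaks, 70% at DRE
coordinates, 50 specific peaks per cluster; the mouse configuration
scales to 9 samples in three groups, 6,000 peaks and 48 specific peaks
per group.

The program sizes are a deliberate regime choice. Planted markers are
individually strong (a 10:1 open/closed ratio at dispersion 0.1), and a
random draw of a few hundred peaks that happens to contain ten or more
markers already reproduces the clustering. Keeping each program a ~1%
minority of the distal-peak universe is what makes the cross-species
random-peak control meaningful: the full top-variance selection and the
program-enriched mapped sets recover the clusters, while size-matched
random draws from the peaks-to-genes universe rarely contain enough
markers to do so — the regime the real cohorts' controls exhibit. At
several percent, the control is structurally impossible: essentially
every random draw reproduces the clustering.

**Expression and links.** Each linked gene's expression equals the
standardised log2(CPM+1) accessibility of its linked DRE peak plus
Gaussian noise with SD `link_noise_sd`, so the population
accessibility–expression correlation is exactly `1/sqrt(1 +
link_noise_sd^2)` (the default 0.75 gives r = 0.8, and 0 gives r = 1
exactly — which is what makes correlation-recovery tests analytic). Linked
genes are the cluster-program genes plus a configurable extra pool
(default 200). Keeping planted links a small minority (~2.5%) of the
candidate pairs is deliberate: the linkage stage standardises every
pair's correlation against the empirical mean and SD of *all* candidate
correlations, and that null is only meaningful when nonspecific pairs
dominate. If most candidates were true links the null SD would absorb the
signal and Benjamini–Hochberg would reject nothing — a regime real
cohorts are not in.

**Motifs.** A shared motif namespace (default 100 motifs) carries one
program of 10 motifs per cluster: program motifs mark their cluster's
specific peaks with probability 0.9 and any peak with the base rate 0.05.
Because mouse and human cohorts use the same namespace and program
indices, a paired simulation automatically shares its motif programs.

**Pairing and homologs.** `generate_paired_species()` generates the two
cohorts independently and then *constructs* the one-to-one homolog map:
a fraction `shared_program_frac` of each mouse cluster's program genes is
paired with program genes of the corresponding human cluster; remaining
mouse program genes pair with random non-program linked human genes; all
other genes pair at random. The fraction of chained human peaks that are
truly cluster-specific therefore equals `shared_program_frac` by
construction, which is what the cross-species tests verify.

**What the generator does not emulate.** Reads, fragment sizes, GC and
Tn5 bias, overlapping regulatory neighbourhoods, correlated peaks within
topological domains, many-to-many homology, and sequence-based motif
occurrence. Passing tests therefore demonstrate the pipeline's contracts
(recovery of planted structure, error control, invariances), not
performance on real chromatin.

# Normalisation, QC and annotation

Counts are CPM-normalised per sample (each column scaled to one million;
`log2(CPM+1)` is the working scale everywhere downstream). Technical
replicates are QC'd by the Pearson correlation of their log-CPM profiles,
flagged below 0.8. Peak merging uses bedtools semantics — intervals
overlapping by one base or bookended are merged — via `IRanges::reduce`.
Peaks are annotated to their nearest gene by absolute midpoint-to-TSS
distance (ties to the lexicographically smaller gene id), classed as
promoter (−1,000..+100 bp, strand-aware on both strands), DRE (3 kb–500 kb
absolute), or other. The seven-feature classification (TSS, TTS, 5'UTR,
3'UTR, exon, intron, intergenic) resolves overlaps in that fixed priority
order; the order is configurable because no single convention exists.

# Saturation modelling

The discovery curve averages, over random sample orderings, the
cumulative number of distinct peaks present in the first x samples. The
model `P(x) = a + b·e^(cx+d)` is over-parameterised — only `b·e^d` is
identifiable — so the fit estimates the amplitude `B = b·e^d` and reports
`d = 0`. For fixed rate `c` the model is linear in `(a, B)`, so the fit
profiles them out by linear least squares and minimises the residual sum
of squares over `c` alone, bracketing from a log-linearised self-start.
This is deterministic, has no convergence failures, and recovers noiseless
parameters to <1e-6 relative error. The "saturation point" is the smallest
integer n with `P(n) ≥ fraction·a`; the fraction defaults to 0.99 and is
exposed as a parameter because "all predicted regions detected" has no
unique algebraic reading (the asymptote is attained only in the limit).

# nsNMF consensus clustering

The input is the log-CPM matrix restricted to the top 20% most variable
peaks (ties broken by peak id). nsNMF factorises `V ≈ W S H` with
`S = (1−θ)I + (θ/k)11ᵀ`; θ defaults to 0.5 (the common choice for the
method; exposed as a parameter). Updates are KL-divergence multiplicative
rules with `SH` substituted for `H` in the W step and `WS` for `W` in the
H step, so each half-step is a standard KL-NMF update and the objective
`D(V‖WSH)` is non-increasing; entries are floored at 1e-12. The inner
loop is compiled (RcppArmadillo) with preallocated workspaces;
initialisation is uniform (0,1] from R's RNG, so a seed fixes the run.

Consensus clustering runs `n_runs` restarts per candidate k (2–8);
each run's connectivity matrix marks sample pairs sharing the argmax
factor of H, and the consensus is the mean connectivity. Because only the
argmax pattern enters the consensus, consensus runs stop early once that
pattern has been stable for several checks, and run in single precision;
the default factorisation path is double precision with an objective
tolerance. The cophenetic correlation ρ_k compares the condensed
distances `1 − consensus` with the cophenetic distances of their
average-linkage tree.

**Model selection.** ρ_k is maximised over the ranks whose consensus
resolves k majority co-clustering blocks (connected components of
consensus ≥ 0.5), and numerical ties at the maximum go to the *largest*
such k. Both guards matter on separable data. A coarser rank can be
perfectly stable — at k = 2 every run may merge the same two of three
true clusters, giving a binary consensus and ρ₂ = 1 — so "smallest k at
the maximum" would systematically under-select; the stability literature's
reading is to take the last k *before* stability begins to fall. A finer
rank, conversely, can look stable while leaving a factor effectively
unused, or can drop marginally below smaller ranks only because one
restart wandered; requiring k majority blocks discards ranks that are
merely re-finding a smaller model. Samples are assigned by the argmax of
H from the best (lowest-objective) run at the chosen k, ties to the
lowest factor index.

Agreement between labelings is reported as the adjusted Rand index and as
matched agreement — the maximal diagonal fraction of the contingency
table over one-to-one label matchings, found by exact permutation
enumeration (k ≤ 8 throughout).

# Differential accessibility and unique peaks

The two-group test is a documented NB-Wald approximation, not a DESeq2
re-implementation: median-of-ratios size factors; per-peak
method-of-moments NB dispersion (floored at 1e-8, reported); log2 fold
change of size-factor-normalised group means with pseudocount 1. The
Wald statistic is computed on the per-sample log2(normalised +
pseudocount) values — the log transform stabilises the NB variance —
with the per-peak residual variance squeezed toward a cohort-wide prior
by empirical Bayes (scaled-F model, prior df and scale estimated from
the log-variance moments), and p referred to a t distribution at
residual-plus-prior degrees of freedom. The alternatives fail at one end
or the other: the NB plug-in variance with a normal reference is visibly
anti-conservative at n = 10 per group (null p<0.05 rates near 0.065,
empirical FDR several-fold above nominal), while an unmoderated t has
essentially no power at the mouse design's n = 3 per group. The
moderated log-scale form is calibrated (null rate ≈0.050, observed FDR
under half the nominal level at the 4-fold planted benchmark) and
retains full power in both regimes — the same reason the field reaches
for shrinkage-based tests on small-n count designs.

Unique-peak filters are applied verbatim, with strict inequalities:
human clusters keep p<0.01, FDR<0.01, log2FC>1, mean CPM intensity>30 and
CV<0.2; mouse groups keep log2FC>1 and FDR<0.05, a peak being
group-unique when it passes against *every* other group (the intersection
reading of "comparing each group with each other" — the union reading
would call a peak unique on the evidence of a single contrast). The CV is
computed across the *target cluster's* samples, i.e. as a within-cluster
consistency filter. The across-all-samples alternative is incompatible
with the fold-change filter it accompanies: any peak with a 2-fold
one-vs-rest difference already has an across-all CV above ~0.35, so that
reading would leave every unique set empty. Human one-vs-rest sets from
different clusters may overlap; overlaps are flagged, never silently
removed.

# Peak-to-gene linkage

Candidate pairs are all peak–gene combinations with midpoint-to-TSS
distance in (3 kb, 500 kb]. Each pair's Pearson correlation r between
log2(CPM+1) accessibility and expression is standardised against the mean
and SD of all candidate correlations ("nonspecific correlation"), giving
z, a two-sided normal p, and BH FDR across pairs; links are significant
at FDR < 0.05. Two-sided p values retain negative-r links with their sign
reported (the sidedness is not dictated by the method's description;
the cross-species stage uses significant links of either sign unless
configured positive-only). Constant profiles are dropped with a message;
a degenerate null (zero SD) is an error. The reverse lookup
`genes_to_peaks()` returns the deduplicated union of (by default
significant) linked peaks for a gene set.

# Motif deviations

For motif m and sample j, the raw deviation is
`Y[m,j] = (obs[m,j] − E[m,j]) / E[m,j]` with `E[m,j] = (Σ_i M[i,m] f_i)·T_j`.
The expected fraction `f_i` is the mean over samples of the per-sample
count fractions `X[i,j]/T_j`. This composition-based expectation keeps two
properties exact rather than approximate: a motif covering all peaks has
deviation identically zero, and rescaling any sample's column (library
size) leaves Y unchanged. Bias correction follows the chromVAR scheme
with `n_background` (default 50) random peak sets per motif, matched per
member peak within deciles of `f`; the z score standardises Y by the
background mean and SD. Synthetic peaks carry no sequence, so GC matching
is not applicable. Variability is the SD of a motif's z scores across
samples — a simplified form of the chromVAR statistic, used only for
ranking and the >1.5 cut-off. Cluster-enriched motifs require positive
correlation with the cluster indicator, BH q < 0.05 and variability >
1.5; the deviation/TF-expression filter retains positive correlations at
p < 0.05. Motif enrichment *rankings* for peak sets (used by the
cross-species comparison) come from one-sided hypergeometric tests of
membership counts — a rank-generating surrogate for sequence-based motif
enrichment, which is out of scope.

# Cross-species conversion and controls

Mouse cluster-unique peaks are converted to human peaks by the chain:
nearest mouse genes (deduplicated) → one-to-one homologs → intersection
with significantly linked human genes → union of their linked human
peaks, with every step's retention count recorded; an empty step yields
an empty result with diagnostics. Guided clustering re-runs consensus
nsNMF at fixed k on the mapped peaks and scores matched agreement and ARI
against reference labels. The random-peak control repeats this on sets of
the same size drawn without replacement from the peaks-to-genes universe
(n_iter configurable; reduced counts report their Monte-Carlo SE), and
the motif-overlap control compares top-10 hypergeometric enrichment
rankings of the mouse set and its chained human set against size-matched
random mouse sets with their own chained mappings.

# Numerical choices and degenerate inputs

Zero-total CPM columns warn and stay zero. Constant columns make Pearson
correlations undefined; they are reported as missing (QC) or dropped with
a message (linkage). All-zero peaks get p = 1. nsNMF floors all factors at
1e-12; degenerate (all-zero-column) runs are discarded from the consensus
and fewer than two valid runs is an error. Saturation fitting flags flat
curves as degenerate (B = 0) and non-saturating fits (c ≥ 0); the
saturation point is undefined for them. Ties are always broken
deterministically (peak id, gene id, lowest factor index, motif id), so
every stage is reproducible bitwise under a seed.

# Problem sizes

The test-suite and acceptance runs use the defaults above: 60-sample,
20,000-peak human cohorts (50 seeds for clustering recovery, with 10
consensus restarts per k — the block-count guard makes model selection
robust at modest restart counts), 25 paired-cohort seeds for the
cross-species property, 100-seed saturation recovery, 10,000-peak
differential simulations, and 200-draw random-peak nulls where a full
analysis would use 1,000 (the Monte-Carlo SE of the null mean is reported
alongside). The `analysis/` scripts use the same sizes and finish in a
few minutes each on a single core.

# Known limitations

The NB-Wald test is an approximation; exact DESeq2 behaviour (dispersion
shrinkage, Cook's filtering) is out of scope, and the filter thresholds
carry more of the selection burden than the test internals. The
hypergeometric motif enrichment is a membership-count surrogate for
sequence-based enrichment. The chromVAR variability statistic is
simplified. Real-genome annotation (overlapping genes, alternative TSSs)
is reduced to a one-TSS-per-gene model; genes with multiple TSS records
would need a nearest-TSS-per-gene reduction before use.
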