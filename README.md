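# gscatac

Chromatin-accessibility stratification of glioblastoma stem-cell (GSC)
cultures, and mouse-to-human mapping of regulatory programs, from bulk
ATAC-seq peak count matrices.

Glioblastoma cell cultures differ strongly between patients, and their
open-chromatin landscapes carry that heterogeneity: most ATAC peaks are
private to a few cultures, and the peaks that vary most across a cohort
separate the cultures into epigenetic subtypes enriched in distal
regulatory elements. `gscatac` implements, as tested and reusable R
functions, the analysis chain such a study needs:

- **Peak handling and QC** — bedtools-style merging of per-sample peak
  calls, CPM/log2 normalisation, technical-replicate Pearson QC,
  peak-sharing histograms, nearest-gene annotation with promoter
  (−1,000..+100 bp) and DRE (3 kb–500 kb) classes, and a seven-feature
  genomic classification.
- **Saturation modelling** — random-subsampling discovery curves fitted
  with the exponential model `P(x) = a + b·e^(cx+d)` (estimated through
  the identifiable amplitude `B = b·e^d`), predicting the total number of
  accessible regions (`a`) and the number of cultures needed to reach a
  chosen fraction of it.
- **nsNMF consensus clustering** — variance-ranked peak selection (top
  20%), non-smooth NMF `V ≈ W S H` with `S = (1−θ)I + (θ/k)11ᵀ` under KL
  multiplicative updates (compiled inner loop), consensus matrices over
  restarts, cophenetic model selection over k = 2..8, and
  Hungarian-matched agreement / adjusted Rand index between clusterings.
- **Differential accessibility** — an NB-Wald approximation
  (median-of-ratios size factors, method-of-moments dispersion,
  Welch-Satterthwaite t reference) with the cluster-unique filter sets
  applied verbatim: human `p<0.01, FDR<0.01, log2FC>1, mean CPM>30,
  CV<0.2`; mouse `log2FC>1, FDR<0.05` in every pairwise comparison.
- **Peak-to-gene linkage** — candidate pairs within ±0.5 Mbp but beyond
  ±3 kbp of the TSS; each Pearson correlation standardised against the
  empirical mean/SD of all candidate correlations, BH-corrected, kept at
  FDR < 0.05; plus the reverse genes-to-peaks lookup.
- **TF motif deviations** — chromVAR-style deviation z-scores with
  accessibility-matched background sets, per-motif variability,
  cluster-enriched motif selection (positive correlation, q<0.05,
  variability>1.5), TF-expression correlation filtering, and top-k
  ranking overlap.
- **Cross-species conversion** — mouse unique peaks → nearest genes →
  one-to-one homologs → significant human links → human peaks; guided
  re-clustering of the human cohort on the mapped peaks; random-peak and
  motif-overlap null controls.
- **Synthetic cohorts** — a generator that plants cluster structure,
  peak-gene links, motif programs and power-law peak sharing with full
  ground truth, so every stage above is testable without external data.

## Worked example

The numbered scripts under `analysis/` run the whole workflow on a
simulated 60-sample human / 9-sample mouse paired cohort with an 80%
shared regulatory program (`Rscript analysis/01_simulate.R` … `07_crossspecies.R`).
Highlights of what they print:

```
$ Rscript analysis/02_saturation.R
42.3% of peaks are private to a single culture; 0.1% are in all 60.
Fitted asymptote 55731 predicted accessible regions (observed 50000);
99% of the asymptote is reached with 137 cultures.

$ Rscript analysis/03_cluster.R
Cophenetic correlation by k:
     2      3      4      5      6      7      8
0.9524 0.9962 0.9972 0.9974 0.9930 0.9907 0.9913
Chosen k = 3; ARI vs planted labels = 1.000; matched agreement = 1.000
Cluster sizes: 20/20/20

$ Rscript analysis/05_linkage.R
14000 candidate pairs; 350 significant links at FDR<0.05.
Recall of the 350 planted links: 1.000; precision 1.000.

$ Rscript analysis/06_motifs.R
Cluster 1: 10 enriched motifs; 10/10 of the planted program recovered
Cluster 2: 10 enriched motifs; 10/10 of the planted program recovered
Cluster 3: 10 enriched motifs; 10/10 of the planted program recovered

$ Rscript analysis/07_crossspecies.R
Conversion chain: mouse_peaks=144 -> mouse_genes=144 -> homolog_genes=144 -> linked_genes=144 -> human_peaks=144
Mouse-guided human clustering: matched agreement 1.000, ARI 1.000 on 144 peaks
Random-peak null (200 draws): mean 0.585 +/- 0.150; observed sits at the 100th percentile
Top-10 enriched-motif overlap: observed 4/10 (40%); random control 10.5% +/- 9.1%
```

The saturation asymptote `a` estimates the total accessible-region pool
(with heavy-tailed peak sharing, well beyond what 60 cultures observe —
the fitted curve says 137 cultures would be needed to see 99% of it).
The cophenetic curve peaks into a plateau whose largest
capacity-respecting rank is k = 3, recovering the three planted culture
subtypes exactly. The linkage stage recalls all planted distal peak-gene
couplings while keeping the 14,000-pair nonspecific background out. The
cross-species chain, seeded only with the mouse group-unique peaks,
selects 144 human peaks that reproduce the human clustering perfectly
while 200 size-matched random peak sets average 0.59 agreement; the
top-10 enriched-motif overlap between the mouse set and its mapped human
set (4/10) sits far above the size-matched random control (1.05/10),
reflecting the shared cross-species motif programs.

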