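---
title: "Methods: cfDNA fragmentomics with MERGE-guided feature restriction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cfDNA fragmentomics with MERGE-guided feature restriction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem this package addresses

Plasma cell-free DNA (cfDNA) is fragmented by nucleases acting on
chromatin, so fragment sizes, genomic coverage, and the sequence around
fragment ends all carry an imprint of the chromatin state of the cells
the DNA came from. Tumour-derived cfDNA therefore perturbs these
*fragmentomic* features — but diffusely, across the whole genome, which
limits the sensitivity of genome-wide classifiers in early-stage disease.

`cfmerge` implements a feature-restriction strategy: use three cell-free
*epigenomic* assays (cfChIP-seq H3K4me3, cfRRBS promoter methylation, and
nucleosome-depleted-region scores from low-pass WGS coverage) to find the
genes whose regulatory state differs between cancer and non-cancer
plasma, and then compute fragmentomic classifier features only over those
genes. The selected genes are called MERGEs (multi-epigenetically
regulated genes). The hypothesis encoded in the pipeline is that
cancer-specific fragmentation changes concentrate at epigenetically
dysregulated loci, so restricting motif and size features to MERGE
intervals raises the signal-to-background ratio of the classifier.

## Feature definitions

All coordinates are 0-based half-open (BED convention); upstream/downstream
are strand-aware in gene orientation.

* **End motif (EDM)** — the k-mer (k = 6 for the classifier, k = 4 for
  entropy/deconvolution) read 5'→3' from each fragment terminus on the
  terminus's own strand; both termini of every fragment contribute, and
  k-mers containing N are discarded. Frequencies are normalised to sum
  to 1 per sample.
* **Breakpoint motif (BPM)** — the reference k-mer spanning each 5'
  breakpoint: 2 bp outside plus 4 bp inside the fragment, read on the
  breakpoint's strand.
* **FSR** — per 1 Mb window, the fraction of fragments of 151–220 bp
  (mononucleosomal) among all fragments whose midpoint falls in the
  window. The MERGE-scope variant uses each selected gene's capture
  interval (gene body + 1500 bp upstream) as the window.
* **FSD** — per chromosome arm, the proportions of fragment lengths in
  67 half-open 5 bp bins covering [65, 400).
* **Motif entropy** — Shannon entropy (bits) of the 4-mer end-motif
  profile; 0 for a one-hot profile, 8 for the uniform one.
* **F-profile contributions** — the dot product of the 4-mer end-motif
  frequency vector with six basis profiles attributed to nuclease
  activities (DNASE1L3, DNASE1, DFFB, non-DNase C-end, non-DNase G-end,
  non-specific). The bundled basis (`fprofile_matrix()`) is synthetic —
  a deterministic stand-in with the documented row labels and plausible
  end-base preferences — because the fitted basis published for these
  components is external; `read_fprofile()` accepts a user-supplied one.
* **H3K4me3 RPKM** — promoter read count / (promoter kb × library-size
  millions), where the library size is the sample's deduplicated mapped
  read total. Samples with fewer than 100,000 on-target reads or an
  on-target rate below 30% are excluded from this layer. Plain RPKM is
  used; the external cfChIP background-correction step is not
  reimplemented, which is a documented deviation.
* **Methylation** — unweighted mean of per-CpG methylation ratios inside
  the promoter interval; missing when no CpG is covered.
* **NDR score** — mean coverage over [−150, +50) around the TSS divided
  by the mean over the pooled [−2000, −1000) and [+1000, +2000) flanks.
  Lower scores mean deeper promoter nucleosome depletion. Both flanks
  are pooled into one 2 kb region before averaging; for complete tracks
  this coincides with the mean of the two flank means, and it degrades
  more gracefully on partial tracks.

## Differential statistics and MERGE selection

Each layer is compared between cancer and control samples per gene with
the Mann–Whitney U test, summarised by the normal-approximation Z:

    Z = (U − n1·n2/2) / sqrt(n1·n2·(n1+n2+1)/12)

with mid-ranks and, deliberately, *no tie correction* in the default
variance (the tie-corrected variance is available behind a flag). Genes
with detectable (non-missing, nonzero) signal in fewer than 10 samples
are dropped before testing. P-values are Benjamini–Hochberg adjusted
within each (layer, comparison) batch; BH is used because the adjustment
method is otherwise unspecified and it is the field default. The
H3K4me3 RPKM matrix is median-of-ratios normalised across samples before
testing, replacing an external count-model differential with a
self-contained rank test on normalised abundances; methylation ratios
and NDR scores are already scale-free.

Three comparison designs are run: cancer vs benign, cancer vs healthy,
and cancer vs both pooled. A gene becomes a MERGE when it has at least
two significant results — across layers, comparisons, or both — whose
implied regulatory states agree. The state map is: H3K4me3 up,
methylation down, or NDR down ⇒ *activated*; the mirrors ⇒ *repressed*.
Two readings of "two analyses" are possible; this package counts any two
significant (layer, comparison) cells, including one layer significant
in two comparisons, and excludes genes with conflicting significant
states outright rather than arbitrating by p-value — the conservative
resolution of an ambiguity. Genes measurable in fewer than three layers
remain eligible through the layers they have.

## Classifier

Seven candidate feature tables are assembled (BPM, EDM, FSR genome-wide
and MERGE-restricted, plus arm-level FSD), with missing values imputed
by training-column medians (schema frozen for held-out data) and one
shared stratified 10-fold assignment. The base learner is L2-regularised
logistic regression on standardised features — the base algorithm is not
pinned down by the source description, and ridge logistic regression is
transparent, deterministic, and adequate for producing probabilities to
stack. Out-of-fold probabilities from the shared folds give each
candidate's training AUC; for each of BPM/EDM/FSR the better-scoring
scope is kept (ties break toward MERGE scope, matching the stated
preference for MERGE variants), the EDM survivor is dropped unless it
beats the BPM survivor, and FSD is always retained.

The stacker is an extremely-randomised-trees classifier (1000 trees,
depth 5, minimum node size 5, no bootstrap resampling) fitted on the
out-of-fold base probabilities — not refit-on-full probabilities, the
standard guard against stacking leakage. Its output is the MERGE score
in [0, 1]; a score at or above 0.5 calls cancer (the boundary calls
cancer because a screening context favours sensitivity). Cross-validated
training scores come from refitting the stacker over the shared folds.
Evaluation reports the confusion counts at the cutoff, Wilson 95%
intervals for sensitivity/specificity/PPV/NPV, a 2000-replicate
stratified-bootstrap AUC interval, and optionally a DeLong comparison
(via pROC) against a second score vector.

## The synthetic cohort

`simulate_cohort()` generates the study conditions used throughout the
tests: per cohort, 60 cancer, 30 benign and 30 healthy samples; a toy
genome of 2 × 2 Mb carrying 1000 genes in 4 kb slots (bodies of 1–2 kb
with the TSS fixed at slot offset 2000 so that per-gene coverage tracks
tile the genome without overlap); 5% of genes planted as activated;
15,000 fragments per sample. Fragment lengths follow a mono/di-
nucleosome Gaussian mixture (80% N(167, 10), 20% N(330, 25)); planted
genes in cancer samples get a −20 bp shift and a 0.15 probability of an
extra short fragment (N(110, 15)). Motif signal is planted by snapping
fragment starts to nearby CC dinucleotides (probability 0.4 at planted
genes in cancer, plus a 0.02 global cancer tilt over a 0.01 baseline),
so end and breakpoint motifs remain genuinely read from the emitted
FASTA. Methylation is beta-distributed (concentration 50) around 0.6,
shifted by −0.3 at planted genes in cancer; H3K4me3 counts are
negative-binomial (dispersion 0.2) around lognormal gene baselines with
a +1 log2 fold-change; coverage tracks are Poisson around depth 30 with
a promoter dip of 0.4 deepening by 0.3. Gene bodies are capped at 2 kb
(rather than 3 kb) so that a body plus its 1.5 kb upstream capture
region and the ±2 kb NDR span fit inside one 4 kb slot. Per-sample
nuisance variation — length jitter (sd 2 bp), motif-tilt jitter
(sd 0.02), depth jitter — keeps samples from being trivially separable
at genome scale while planted loci stay strongly informative, which is
what makes the genome-vs-MERGE base-model comparison meaningful.

These sizes were chosen so a full two-cohort study (240 samples) runs in
about three minutes on one CPU. What the generator does *not* emulate:
read-level sequences and sequencing error, GC and mappability bias,
copy-number structure, realistic promoter CpG density variation,
cell-type deconvolution structure in end motifs, and batch effects.
Passing the recovery tests therefore demonstrates internal correctness
of the pipeline — that planted cross-layer signal of the stated sizes is
recovered with the stated error control — not clinical performance on
real plasma.

## Numerical and degenerate-input conventions

* Motif profiles are normalised only when at least one motif was
  counted; windows running off a chromosome are skipped and counted.
* Empty windows/arms/genes yield missing values, never zeros; FSD rows
  and motif profiles sum to 1 (tolerance 1e−12) whenever non-missing.
* An NDR score with zero pooled flank coverage is missing; the score is
  invariant under scaling the whole track.
* Fragment→interval assignment is by midpoint, giving each fragment one
  window/arm assignment; overlapping genes may each receive a copy of a
  shared fragment (documented behaviour of `gene_fragment_features()`).
* The default ingest length window is [65, 1000) bp — a package
  convention, since no global pre-analysis ceiling is prescribed by the
  method description; analyses apply their own tighter windows.
* All randomness (fold assignment, bootstrap, trees, simulation) derives
  from one seed through a rolling-hash sub-seed scheme, so identical
  configs reproduce bit-identical scores and files.

## Known limitations

* The bundled F-profile basis is synthetic; deconvolution contributions
  are only meaningful relative to a user-supplied fitted basis.
* The rank-based H3K4me3 differential on normalised RPKM is a
  self-contained replacement for a count-model (edgeR-style) analysis;
  on low counts a count model has more power.
* Base-model selection happens once on the full training set rather
  than nested within each fold; with seven candidates compared on
  out-of-fold AUC the optimistic bias is small, but held-out evaluation
  remains the arbiter.
* The null-cohort cross-validated ensemble AUC is a noisy quantity
  (n = 120 gives a sampling sd of about 0.05, and a flexible stacker on
  pure noise is mildly pessimistic under cross-validation), so its
  calibration band check is inherently stochastic.
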