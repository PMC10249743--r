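---
title: "srnafrag: models, parameters and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{srnafrag: models, parameters and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(srnafrag)
```

This vignette documents the statistical model behind the synthetic data
generator, the analysis conventions of each stage, and the numerical
decisions that are the package's own (i.e., not forced by the data
formats), with their rationale.

## 1. The synthetic library model

`synthetic_config()` describes a sperm-like small RNA experiment. The
defaults — all of them overridable — are:

- **Composition** (expected read mass): rRNA 70%, nuclear tsRNA 15%,
  miRNA 5%, mitochondrial tsRNA 3%, other biotypes (lncRNA, piRNA,
  protein-coding fragments) 7% together. Sperm libraries are
  rsRNA-dominated with tsRNA second and miRNA minor; the mitochondrial
  share is small but biologically central, so it gets its own knob.
- **Gene complement**: 20 nuclear tRNA genes (73 nt), 5 mitochondrial
  tRNA genes (69 nt), 20 miRNA (21–23 nt), 5 rRNA (120–200 nt), and 10
  genes each of lncRNA, piRNA and protein-coding. These sizes are a desk-
  scale choice: large enough that every hierarchy level, both genomes and
  all five tsRNA subtypes are exercised, small enough that the full
  pipeline runs in seconds to minutes.
- **Cut-site models**: nuclear tRNA fragments are mostly 5'-halves
  (50%), mitochondrial tRNA fragments mostly internal (60%), reflecting
  the qualitatively different cleavage profiles of the two compartments.
  Two distinct fragments are drawn per subtype per tRNA.
- **Design**: two diet groups ("sugar30", "sugar300") of five samples;
  sample *j* of each group shares subject *j*, giving the paired design
  that repeated-measures correlation needs.
- **Planted effects** (`default_effects()`): +1 log2 on every
  mitochondrial transcript and +1.5 log2 on `miRNA-01`, both in the
  second group — a global compartment shift plus a single responsive
  miRNA.
- **Phenotypes**: per-sample `motility` and `sperm_count` are linear in
  the *realized* mitochondrial read fraction plus a subject intercept and
  small noise, so their association with mito sRNA levels is true by
  construction and estimable within subjects.

### Sequence generation

Transcript sequences are rejection-sampled to be **pairwise
non-substring** (no transcript contains another, in either direction), so
biotype assignment of any fragment is unambiguous on synthetic data. Each
genome is its genes concatenated with random spacers (default 50 nt) on
random strands. tRNA genes are embedded **without** the 3' CCA; the
mature reference sequence carries it, making mature 3' fragments
biotype-mappable but genome-absent — exactly the situation the CCA rescue
(section 3) addresses. Generated secondary structures follow the
canonical cloverleaf with the anticodon at mature positions 34–36 and a
7-nt anticodon loop at 32–38.

### Read counts

For sample *s* in group *g*, fragment *i* receives weight
$w_{ig} = \text{catalogue weight}_i \times \text{effect multiplier}_{ig}
\times \gamma_{is}$ with $\gamma_{is} \sim \Gamma(\theta, \theta)$
(default $\theta = 10$), and the per-sample read total $N$ (default
50,000) is split into a Binomial($N$, 0.1) share of adapter-free reads
plus one multinomial draw over fragments. Marginally each fragment count
is negative-binomial with size $\theta$, while per-sample totals are
*exactly* $N$ — which keeps the adapter-free discard rate an honest
binomial proportion. Each informative read is the fragment followed by
the full NEB 3' adapter, truncated at the 75-nt sequencing window;
adapter-free reads are rejection-sampled so that trimming must discard
them (no full adapter and no adapter prefix ≥ 3 nt at the read end).

## 2. Ingest conventions

Trimming keeps the leftmost full-adapter match; failing that, the longest
adapter *prefix* (≥ `min_overlap` = 3) that is a read *suffix* — the read
window ended inside the adapter. Reads with neither are discarded and
counted, as are zero-length inserts. Collapsing drops N-containing reads,
then requires ≥ 1 count in ≥ 2 separate samples. Rows are ordered by
descending total count with lexicographic ties, so tables are
byte-reproducible.

## 3. Annotation

Mapping is exact substring search (both strands against the genomes,
sense only against biotype references). With unique sequences after
collapsing, non-repetitive references and a no-mismatch policy, an
in-package scan replaces an external aligner; a position-by-position
oracle in the test suite guards it. Biotype is the **first** hierarchy
level (rRNA, mt-tRNA, tRNA, miRNA, lncRNA, piRNA, protein coding) with a
sense hit; all hits at that level are kept for multimapping diagnostics.
rRNA-assigned sequences are flagged `excluded` — excluded from displays
and summaries, never deleted, and still counted in CPM depth.

Genome origin is nuclear / mito / both / unmapped. A sequence that hits a
tRNA biotype reference but no genome is almost always a mature 3'
fragment carrying the non-templated CCA; it is rescued to the origin its
biotype implies (mt-tRNA → mito, tRNA → nuclear) and flagged `rescued`.
The rescue is applied to both compartments because nuclear tRNA 3'
fragments are genome-absent for exactly the same reason as mitochondrial
ones.

## 4. tsRNA subtypes

With mature length $L$ and anticodon loop $[a, b]$ (the maximal unpaired
run containing the anticodon):

| touches 5' end | touches 3' end | condition       | subtype     |
|---------------|----------------|-----------------|-------------|
| yes           | no             | end ≥ a         | five_half   |
| yes           | no             | end < a         | five_tsRNA  |
| no            | yes            | start ≤ b       | three_half  |
| no            | yes            | start > b       | three_tsRNA |
| no            | no             | —               | i_tsRNA     |
| yes           | yes            | —               | whole_tRNA  |

Two edge conventions are the package's own: a 5'-anchored fragment ending
*past* the loop still counts as a 5'-half (the cut is 3' of the loop, the
fragment still contains it), mirrored at the 3' end; and full-length
fragments are labelled `whole_tRNA` and excluded from five-subtype
tallies rather than being forced into a half class. `end_tolerance`
(default 0) relaxes end contact by a few nucleotides for data with ragged
termini.

## 5. Quantification

CPM depth is computed over stage-1 survivors *including* rRNA, so the
display exclusion does not distort normalisation. The two-stage filter is
18–50 nt, ≥ 10 counts in ≥ ceiling(0.60 · n) samples and a genome match
(stage 1), then ≥ 20 CPM in ≥ ceiling(0.25 · n) samples (stage 2); all
thresholds inclusive. Fold changes use
$\log_2((\bar{x}_A + 1)/(\bar{x}_B + 1))$; the SEM is taken over group-A
samples of the per-individual ratios
$\log_2((x_{Ai} + 1)/(\bar{x}_B + 1))$, i.e. denominator-mean fixed —
the convention that matches per-individual fold-change plots.

Note one consequence of CPM's compositional nature: a planted +1 log2
shift on a 3% mitochondrial share inflates total depth slightly, biasing
every *nuclear* log2fc by about $-\log_2(1.03) \approx -0.04$. Nuclear
%up therefore sits a point or two below 50 even under a purely
compartment-specific effect — visible in the origin summaries and worth
remembering when reading them.

## 6. Statistics

**NB-GLM.** Each feature is fit as
$\log \mu = \beta_0 + \beta_1 \cdot \mathbb{1}[\text{group A}] +
\log(\text{library size})$ with NB variance $\mu + \mu^2/\theta$, by
alternating IRLS for $\beta$ with a dispersion update. Two dispersion
estimators are provided: maximum likelihood (safeguarded Newton on
$\log \theta$) and Cox–Reid adjusted profile likelihood (the profile
likelihood minus $\tfrac12 \log\det X^\top W X$, maximised by golden
section on $\log\theta$). The default is **Cox–Reid plus a t reference
with df = N − p** for the Wald statistic. The reason is empirical and
decisive: at the package's own calibration point (θ = 10, mean 200,
n = 5 + 5), plain ML dispersion with a normal reference — the
`MASS::glm.nb` summary convention — rejects ~12% of true nulls at
α = 0.05, while the default rejects ~5% with power ≈ 0.85 against a
2-fold effect. `theta_method = "ml", p_reference = "normal"` reproduces
`MASS::glm.nb` to numerical precision and serves as the test-suite
oracle. θ is capped at 10⁶; hitting the cap triggers a Poisson fallback
flagged `converged = FALSE`. No multiple-testing correction is applied by
default; BH is optional.

**Repeated-measures correlation** is the common-slope ANCOVA:
$y \sim$ subject intercepts $+ \beta x$;
$r = \operatorname{sign}(\beta)\sqrt{SS_x/(SS_x + SS_{res})}$ with
df = N − k − 1 and an F test on the slope.

**Clustering** is complete-linkage on Euclidean or Pearson distance
(1 − r); the pipeline clusters row-standardised mature-tRNA CPM into
k = 4 groups. Zero-variance rows get Pearson distance 1 with a warning.

## 7. Pipeline and reproducibility

`run_pipeline()` chains all stages and emits a bundle of plain TSV tables
plus a provenance JSON (package version, seed, contrast list, filter
parameters, sequence counts, input MD5 hashes — deliberately no
timestamps). With a fixed config and seed, two runs produce byte-identical
bundles. Any stage failure aborts with the stage name and a
machine-readable `E_<STAGE>` code.

## 8. Scope and limitations

The generator is a validation instrument, not a biological simulator: it
has no sequencing errors, no quality-score variation, no expression-
dependent GC effects, and its genomes are non-repetitive by construction,
so multimapping arises only between deliberately duplicated references.
Exact-match mapping is likewise only appropriate for collapsed unique
sequences against references where a single mismatch should genuinely
disqualify a hit. The NB-GLM deliberately omits empirical-Bayes
dispersion shrinkage and mixed models; at the target sample sizes the
Cox–Reid/t correction is the simplest adequate fix. Proteomics support is
limited to column normalisation and clustering.
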