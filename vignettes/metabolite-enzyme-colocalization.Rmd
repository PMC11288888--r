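---
title: "Mapping enzyme-metabolite colocalization across tissue microhabitats"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping enzyme-metabolite colocalization across tissue microhabitats}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Microbial communities organize chemistry at the scale of tens of microns.
Mass spectrometry imaging (MSI) can map metabolites across a tissue section
at that scale, and microscale proteomics of laser- or manually dissected
regions can tell which enzymes each micro-region expresses -- but neither
modality alone says whether an enzyme and the chemistry it catalyzes occupy
the same place. `metacoloc` implements the computational half of a
metabolome-informed proteome imaging analysis: starting from negative-mode
ion images with region-of-interest (ROI) masks and replicate metaproteomic
peptide tables, it asks, for every detected enzyme and every reaction that
enzyme can catalyze, whether the enzyme's peptides spatially co-vary with
the reaction's substrate and product across the microhabitats.

The running example mirrors a fungus-farming ant garden: three lignin-rich
microhabitats (LM1-LM3) and one primary-metabolite microhabitat (PMM),
profiled as serial 12-um cryosections at 50-um pixel pitch over an m/z
92-700 acquisition window, with 3/3/6/3 replicate sections per ROI.

## The statistic

For an analyte (a peptide or an ion image) with within-ROI mean intensities
$m_1, \dots, m_p$ over $p$ ROIs, the spatial signature is the vector of
log~2~ fold changes over all ordered ROI pairs $(i<j)$ in a canonical label
order, $d_{ij} = \log_2 (m_i / m_j)$. Colocalization of a peptide and an
ion image is the Pearson correlation of their pair profiles after centering
and scaling each to unit variance, computed over the pairs where both are
defined, with Benjamini-Hochberg adjustment over all tests emitted in a run.

Three rules handle partial data:

* An ROI mean for a peptide is computable only from **at least two observed
  intensities** among that ROI's section replicates.
* When exactly one side of a pair lacks a computable mean, a **G-test**
  ($G = 2\sum O \ln(O/E)$, df = 1) on the 2x2 observed/missing x ROI
  detection table decides whether absence itself is informative. If
  $p < \alpha_G$ (default 0.05) the pair receives a signed **sentinel**
  pointing toward the side with data; otherwise the pair is missing.
  Sentinel magnitude is (max |log~2~FC| in the run) + 1, so a flag is
  numeric, outranks every real fold change, and carries direction into the
  correlation. A zero ROI mean on either side likewise marks the pair
  missing rather than infinite.
* A peptide profile is emitted only when at least three ROIs are usable
  (computable, or non-computable but flagged against a computable ROI);
  a correlation requires at least three shared non-missing pairs.

### Why the p-value uses df = n~ROI~ - 2

The pair profile of $p$ ROI means is a linear image of a $p$-vector: its
$\binom{p}{2}$ entries span only $p-1$ dimensions. Treating the 6 pairs of
4 ROIs as 6 observations (df = 4) is badly anticonservative -- on
simulated independent pairs the nominal 5% level rejects several times
too often (the test suite reproduces this inflation). For
complete profiles the *uncentered* cosine of two pair profiles equals the
Pearson correlation of the underlying centered ROI mean vectors exactly
($\sum_{i<j}(x_i-x_j)(y_i-y_j) = p\,\widehat{\mathrm{cov}}(x,y)$), and
under an isotropic null that statistic follows the textbook correlation
law with an effective sample size of $p$ ROIs. `metacoloc` therefore
reports `r` as the classic centered/scaled profile correlation but derives
the p-value from the cosine statistic with
$t = r_0\sqrt{\mathrm{df}/(1-r_0^2)}$, df = (distinct ROIs spanned by the
shared pairs) - 2 (`p_method = "roi"`, the default; simulated null
rejection consistent with the nominal 5% level under the default
conditions, as the calibration check in the test suite verifies). The
literal df = n~pairs~ - 2 remains available as `p_method = "pairs"` for
comparison. A consequence worth knowing: with 4 ROIs, df = 2, even a
correlation of 0.99 yields p ~ 0.01 -- single-peptide significance is
intentionally hard to reach, and profiles that lose an ROI to missingness
drop to df = 1, where only near-perfect correlations are detectable.
Published analyses of this kind print far smaller p-values than 6 pairwise
observations can support, which suggests a pair-level or pixel-level
df; we treat the calibrated ROI-level df as the defensible choice and per
enzyme read colocalization from its best-supported peptide, the way such
results are reported with one representative peptide.

## The qualification cascade

Upstream of the statistic, the metaproteomic evidence passes the fixed
acceptance rules: PSMs must be fully tryptic (NTT = 2) with at most two
missed cleavages; spectral-probability and absolute mass-error thresholds
are grid-optimized over the observed score values to maximize distinct
accepted target peptides subject to target-decoy FDR <= 5% at both the
spectrum and the peptide level (a peptide is a decoy only if all its
accepted PSMs are); qualified peptides need >= 2 accepted PSMs; identified
clusters need >= 2 qualified peptides; and an analyte is called present in
an ROI only when observed in >= 2 of that ROI's section replicates, with a
cluster present only where >= 2 of its peptides individually are. The FDR
estimator is the plain decoys/targets ratio; ties in the optimization
prefer the stricter spectral-probability cap, then the stricter mass-error
cap; for large PSM sets each grid axis is thinned to at most 60 observed
quantile values.

Peptide intensities are normalized per replicate column (ROI x section) by
median scaling to the global median (`"total"` and `"none"` are selectable).
Median scaling presumes most peptides are stable across columns -- true of
real tables with thousands of background peptides, and emulated in the
synthetic tables by a block of uniformly expressed background clusters.

## Annotation and the reaction graph

MS1 annotation matches detected channels against a formula database under
negative-mode adduct rules -- deprotonation ([M-H]^-^) and chloride
attachment ([M+Cl]^-^) -- within a symmetric, boundary-inclusive ppm
tolerance (default 3 ppm). Confidence control uses a deliberately simple
decoy-adduct FDR: implausible adduct shifts ([M+Br]^-^, [M+Na-2H]^-^,
[M+K-2H]^-^) act as decoys, matches are ranked by |ppm error|, and the
q-value-style FDR at a cut is the decoy fraction at or below it, kept
monotone in the cut. This is a stand-in for image-aware annotation engines
that score isotope patterns and spatial structure; it controls formula-level
false matching only. Theoretical m/z includes the electron mass -- at FTICR
accuracy the ~0.55 mDa electron term matters. Mass isomers (one formula,
two compounds) are resolved by ionization preference: annotation keeps all
candidates per adduct, and the pipeline selects each compound's image under
its preferred adduct, which is knowledge supplied as an input column, the
way fuconate (readily deprotonated) and glucose (chloride-attaching) are
distinguished.

Enzymes link to chemistry through a local KEGG-style reaction graph
(KO -> reaction -> substrate/product, with pathway labels), loaded from a
validated file so analyses are hermetic. Triplet enumeration emits each
(substrate, KO, product) whose enzyme is detected and whose substrate
*or* product is annotated (`"either"`, the default -- a product may remain
observable after its substrate is consumed below detection; `"both"` is
stricter), optionally mirrored when reactions are treated as reversible.

Consensus taxonomy and function per cluster protein follow the hit-table
rules: top 10 hits by bit score, floors at bit score > 50 and
e-value < 1e-5; the maximum-bit-score set assigns its unanimous lineage,
else its lowest common ancestor (longest shared rank prefix, with unknown
intermediate ranks matching nothing); a unanimous KO, else unclassified.
Independent methods (workflow, protein-LCA, contig) cross-check by LCA of
their classified results.

## What the synthetic generator emulates

The generator reproduces the structure of the study design so every stage
is exercisable at desk scale, with planted ground truth:

* 4 disc ROIs on a 100x100 grid (50-um pitch metadata), replicates 3/3/6/3.
* Three planted substrate-enzyme-product triplets spanning both
  microhabitat archetypes, including the isomer pair (fuconate as [M-H]^-^
  in the LMs; glucose as [M+Cl]^-^ in the PMM). Within a triplet the
  substrate image, enzyme peptides and product image share one per-ROI mean
  profile exactly, with on/off contrasts of ~16-25 fold -- typical of
  spatially structured analytes.
* Multiplicative lognormal noise (log-scale sd 0.1 by default): intensities
  stay positive and errors scale with abundance, as in MS data.
* Missingness completely at random per cell at rate 0.1 (the low end of
  label-free practice), plus an optional intensity-dependent mode (dropout
  odds doubling per 4-fold intensity decrease below the median) to exercise
  the G-test branch.
* Scored PSM tables with decoys stochastically worse by `score_sep` orders
  of magnitude in spectral probability, wider decoy mass errors, and a
  fraction of structurally invalid rows; 1500 target + 1500 decoy PSMs by
  default, with the quantified table's peptides sampled at 6-fold weight so
  abundant peptides accumulate the multiple PSMs they would in a real
  search.
* Flat background clusters (the normalization anchor) and distractor
  enzymes/metabolites with no planted relationship, one of which is wired
  into the reaction graph so every default run also emits genuine null
  tests.
* One global seed fans out to per-generator subseeds by stable name
  hashing; regeneration is bit-identical.

What it does **not** emulate: spatial autocorrelation within ROIs (pixels
are independent draws), isotope envelopes, peak shapes, chromatography,
chimeric spectra, or structured (batch- or sequence-driven) missingness.
Passing the planted-recovery and calibration checks therefore demonstrates
the correctness of the rules and statistics, not robustness to every
pathology of real data.

## Numerical and design choices

* ppm matching is symmetric and boundary-inclusive; coordinates are
  0-based row-major internally, shifted to imzML's 1-based convention on
  write and back on read.
* imzML support is a purpose-built reader/writer (continuous and processed
  binary modes, uncompressed 32/64-bit floats, UUID and MD5 integrity,
  truncation reported with the offending byte offset); an independent
  Python imzML parser is used as a round-trip oracle in the tests.
* The exact-recovery property (noiseless planted r = 1) is defined on
  unnormalized intensities: median scaling at desk-scale table sizes
  shifts columns by composition, so the validation arm runs
  `normalization = "none"`.
* Peptide/protein matching collapses I and L (isobaric) by default.
* `bh_adjust` delegates to `stats::p.adjust(method = "BH")` behind input
  validation; the test suite checks it against an independently written
  step-up pass.
* The BH family is all peptide-metabolite tests emitted in one run -- the
  most conservative reading -- and results are ranked by adjusted p.
* Default problem sizes (100x100 grid, 3000 PSMs, 400 null pairs in the
  calibration experiment) keep a full run under ~10 s on one CPU while
  leaving every rule with enough data to bind.

## Limitations

With four ROIs the correlation test has 2 degrees of freedom; power comes
from profile contrast, not sample size, and losing one ROI to missingness
nearly extinguishes single-test power. The decoy-adduct FDR does not model
spatial plausibility of annotations. The reaction graph is consumed as
given -- no directionality inference or pathway enrichment. Contig-level
taxonomy is an input, not recomputed. Printed p-values from pair profiles
should be read as rank evidence within a run rather than literal error
probabilities across studies.
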