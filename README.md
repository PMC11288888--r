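# metacoloc

Spatial colocalization of metabolite ion images and metaproteomic enzymes
across tissue microhabitats.

Microbial ecosystems such as fungus-farming ant gardens organize their
chemistry at micrometer scale. Mass spectrometry imaging (MSI) maps
metabolites across a section; microscale metaproteomics of dissected
regions of interest (ROIs) reveals which enzymes each microhabitat
expresses. `metacoloc` integrates the two: it reads imzML, annotates ion
images by molecular formula and negative-mode adduct under a decoy-adduct
FDR, applies target-decoy PSM filtering with threshold optimization and
the peptide/cluster/replicate qualification rules, derives consensus
taxonomy and KEGG Orthology function from homology hit tables, links
detected enzymes to substrates and products through a local reaction
graph, and scores spatial colocalization of each enzyme's peptides with
its substrate and product images.

## The statistic

For an analyte with within-ROI means $m_1,\dots,m_p$, its spatial
signature is the vector of $\log_2(m_i/m_j)$ over all ordered ROI pairs
$(i<j)$. When a peptide lacks a computable mean on one side of a pair
(fewer than two observed replicate intensities), a G-test
($G = 2\sum O\ln(O/E)$) on the 2x2 detection table can convert informative
absence into a signed sentinel that dominates every real fold change.
Colocalization of a peptide and an ion image is the Pearson correlation of
their centered, unit-variance pair profiles over shared non-missing pairs;
significance uses the equivalent ROI-level statistic with
df = n_ROI - 2 (calibrated: pair profiles of $p$ ROI means span only
$p-1$ dimensions), and Benjamini-Hochberg adjustment runs over all tests
emitted in a run. Substrate-enzyme-product triplets come from a validated
KO-reaction-compound graph; mass isomers separate by ionization
preference (e.g. one C6H12O6 compound as [M-H]-, its isomer as [M+Cl]-).

A synthetic-data module generates every pipeline input -- ROI layouts
(default 4 microhabitats with 3/3/6/3 section replicates at 50-um pitch),
ion images in the m/z 92-700 window, peptide tables with missingness,
scored decoy-containing PSM tables, hit tables and the reaction graph --
with planted colocalization as recoverable ground truth.

## Worked example

```r
library(metacoloc)
run <- run_pipeline(default_config(seed = 1, out_dir = "coloc_run"))
print(run$fit)
```

```
Enzyme-metabolite colocalization: 4 triplets, 24 tests, 16 significant (BH <= 0.05)
Top associations:
         peptide     ko compound      role      r n_pairs         p    p_adj
1      HKHYVWGVK K00844   C00031 substrate 0.9992       6 0.0004340 0.003555
2      HKHYVWGVK K00844   C00092   product 0.9990       6 0.0005730 0.003555
3     TWRYCGLVGR K00844   C00031 substrate 0.9987       6 0.0007139 0.003555
4 DVWLKHEDRGVGNR K00844   C00031 substrate 0.9991       6 0.0007970 0.003555
5 DVWLKHEDRGVGNR K00844   C00092   product 0.9989       6 0.0008646 0.003555
6     TWRYCGLVGR K00844   C00092   product 0.9984       6 0.0008887 0.003555
```

Each row is one test: a peptide of a detected enzyme (here hexokinase,
K00844) against the fold-change profile of its substrate (glucose,
C00031) or product (glucose 6-phosphate, C00092) ion image; `r` is the
profile correlation over `n_pairs` ROI pairs and `p_adj` the BH-adjusted
significance -- the planted glucose triplet localizes to the
primary-metabolite microhabitat and is recovered at r > 0.998. The run
directory holds the Table-style O/X detection matrix
(`detection_matrix.tsv`, column headers carrying replicate counts such as
`LM3 (n = 6)`), `correlations.tsv`, `annotations.tsv`, the imzML pair,
ROI masks and a JSON manifest with counts at every filter stage. The
methods vignette (`vignettes/metabolite-enzyme-colocalization.Rmd`)
documents the model, the defaults and their rationale.

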