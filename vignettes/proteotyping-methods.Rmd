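---
title: "Metaproteome proteotyping: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Metaproteome proteotyping: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette explains the scientific model behind `proteotypeR`, the
parameters that matter, what the synthetic-study generator does and does
not emulate, and the design decisions taken where the methodology was
genuinely open. It states no empirical result that the test suite and
`scripts/acceptance.R` do not themselves compute.

## The problem

Metaproteomics characterizes a microbial community by the proteins it
actually expresses. For engineered ecosystems such as anaerobic
digesters (biogas plants), surveys of many plants ask: which taxa and
functions are always present (a core community), how do communities
cluster by reactor type, substrate and temperature regime, which taxa
track process parameters such as total ammonia nitrogen (TAN) or
organic loading rate (OLR), and can single metaproteins serve as markers
for process conditions?

The quantitative unit throughout is the **spectral count**: the number
of identified MS/MS spectra (peptide-spectrum matches, PSMs) attributed
to a feature. Spectral counting is semi-quantitative — it saturates for
abundant proteins and undersamples rare ones — but it is robust,
additive, and well suited to the compositional analyses used here.

## From PSMs to metaproteins

1. **Identification filter.** PSMs below a search-engine score of 40
   (the default; a stand-in for 1% FDR control, which is assumed to have
   happened upstream) are discarded. FDR estimation itself is out of
   scope: the pipeline starts from an identified PSM table.
2. **Homology transfer.** Metagenome-predicted proteins usually lack
   annotation. Each unannotated accession with a BLAST-style hit at
   e-value ≤ 10⁻⁴ inherits the UniRef50 cluster, taxon and function sets
   of its best (lowest-e) annotated hit. "Better than 10⁻⁴" is read
   inclusively (≤), the standard BLAST idiom; the cutoff is a parameter.
3. **Exclusion.** Contaminant keratins and accessions still unannotated
   after transfer carry no community signal and are removed; the counts
   of excluded spectra are kept in provenance.
4. **UniRef50 grouping.** Protein inference in a community sample is
   ill-posed (homologous proteins from related species share peptides),
   so redundant identifications are grouped into **metaproteins** by
   their UniRef50 cluster (UniProt sequences clustered at ≥50%
   identity). Accessions without UniRef50 membership are kept as
   singleton metaproteins (`ACC:<accession>`) rather than discarded —
   they still carry taxonomy and function.
5. **LCA taxonomy.** A metaprotein's taxonomy is redefined as the lowest
   common ancestor (LCA) of the taxa of all member accessions its
   peptides matched. Members without a taxon are ignored; a metaprotein
   with none maps to the root. This is deliberately conservative: a
   metaprotein spanning two orders of one class is reported at class
   level and later binned as `unassigned_order` in order profiles —
   mirroring the large unassignable fraction seen in real surveys.
6. **Shared spectra.** A spectrum whose accessions fall into two or more
   UniRef50 clusters must not be counted twice. The default rule assigns
   the whole spectrum to the cluster with the larger study-wide spectrum
   count (ties broken lexicographically by cluster id), a parsimony-style
   choice that keeps the **spectrum conservation** invariant: per
   sample, metaprotein counts sum exactly to the retained spectra.
   Fractional splitting (1/k to each of k clusters) is available as an
   option; it conserves totals but produces non-integer counts.

## Abundance profiles

Counts are rolled up to four levels: metaprotein, taxonomic order
(via the LCA's order-rank ancestor), biological process (UniProt
keyword) and pathway (a user-supplied KO → pathway map). Process-level
counting duplicates a spectrum across all keywords of its metaprotein
and then renormalizes — the deterministic choice when a multi-keyword
rule is not specified; the duplication is recorded in provenance.

Each sample's column is normalized to 100% of its retained spectra.
The **1% filter** then keeps features reaching ≥1% in ≥1 sample.
Filtering deliberately does **not** renormalize: retained values remain
percentages of total sample spectra, so a core feature's "minimum
abundance" reads as percent of all spectra of the weakest sample.

**Core features** are those strictly above zero in every sample
(`floor = 0` by default; a configurable detection floor is available
because presence at 0.001% is operationally indistinguishable from
absence — the strict reading was chosen as the default since filtered
profiles already impose a 1% detection standard).

## Community statistics

* **Richness** is the number of order-level features detected (>0) in a
  sample, computed on the 1%-filtered matrix — a *filtered* richness by
  design (set `min_pct = 0` for the unfiltered variant).
* **Evenness** is Gini-based. The Gini coefficient
  $G = \sum_{ij} |x_i - x_j| / (2 n \sum_i x_i)$
  is 0 for a perfectly even vector and approaches 1 under extreme
  dominance. Because the field reports *evenness* on a 0–100 scale where
  equality scores high, the package defines
  `evenness_pct = 100 (1 − G)` and always reports the raw Gini
  alongside; both orientations circulate in the literature, and the
  explicit pairing avoids ambiguity. Zero entries of the filtered
  profile count as real zeros in the Gini vector by default. The
  production implementation uses the $O(n \log n)$ sorted identity and
  is tested against the $O(n^2)$ pairwise oracle at 10⁻¹⁰.
* **Clustering** of samples uses euclidean distance with average linkage
  over feature-wise z-scored profiles (population standard deviation, as
  clustergram-style heat maps use; a sample-sd switch exists). The
  original workflow's tool call lists "distance 'average', linkage
  'euclidian'" — almost surely transposed; euclidean distance with
  average linkage is implemented as the default and both knobs are
  exposed. Group separation is assessed by a **permutation test**:
  statistic T = mean between-group distance − mean within-group
  distance, p = (1 + #{T\* ≥ T}) / (1 + n\_perm) over label
  permutations (default 1000). Permutation rather than bootstrap
  resampling is used although the source workflow says "bootstrapping":
  the hypothesis is exchangeability of fixed group labels, for which
  label permutation is the exact scheme.
* **PCA** is computed on the centred samples × features matrix (no
  scaling); variance explained comes from squared singular values and
  sums to 100% over all components; loadings are exposed for
  inspecting which features drive each component.

## Associations and markers

* **Spearman correlations** (Pearson on midranks, so ties are exact) of
  every feature against every numeric process parameter, with the
  t-approximation p-value on n−2 df; an exact permutation p is
  available for n ≤ 8 (full enumeration; beyond that the factorial
  blow-up buys nothing over the approximation). Significance is
  reported at both 0.05 and 0.01 without multiplicity correction — the
  screen is descriptive, matching the dual-alpha reporting convention
  of such surveys; a Benjamini–Hochberg option exists but is off by
  default, and both raw and adjusted p are returned.
* The **correlation network** has taxa/functions and parameters as
  nodes and significant correlations as signed edges; node degree is
  recorded. Export is GEXF 1.2 (readable by Gephi, where such networks
  are conventionally laid out) plus a plain edge-list TSV; layout
  itself is not computed.
* **Marker discovery** binarizes a parameter at a literature threshold
  where one exists (TAN 4200 mg/L, with 3000 mg/L as the common
  alternative; 40 °C as the thermophile boundary) and at the median
  otherwise; values exactly at the threshold are "low". A **CART**
  tree (exhaustive binary splits maximizing Gini-impurity decrease over
  midpoints of sorted distinct values, max depth 3, min leaf 2, ties
  broken toward the lower feature index then lower cut — fully
  deterministic) is fit on a stratified random 60/40 train/test split;
  the proposed marker is the root-split feature and both errors are
  reported. CART was chosen over ensembles because the claim is
  interpretable single-marker discovery. Depth/pruning settings of the
  original analysis are not documented; the defaults above are this
  package's choice, exposed as parameters.

## The synthetic-study generator

`simulate_study()` defines the study conditions the pipeline is tested
under; its defaults are fixed and are not tuning knobs:

* **4 plant groups** (mesophile, thermophile, UASB, sewage sludge) × 10
  samples, reflecting the four community clusters such surveys resolve.
* **4000 identified spectra per sample** — the depth at which order
  richness saturates in real data — drawn multinomially over metaprotein
  probabilities at fixed depth (per-sample depth variance is
  undocumented in real studies; a uniform jitter option exists, default
  off, and a Dirichlet overdispersion option likewise).
* **300 UniRef50 metaproteins** over **40 orders** in two superkingdoms
  (~25% archaeal), with log-normal base abundances (σ = 1.2 on the log
  scale), 1–10 member accessions per cluster mostly within one order,
  30% unannotated metagenome accessions (20% of their homology hits
  failing the e-value cutoff), a few keratin-like contaminants, ~5%
  sub-threshold PSM scores, and 2% of peptides shared between two
  clusters to exercise the shared-spectrum rule.
* **Group structure**: each group owns three signature orders whose
  metaproteins are enriched `exp(2)` ≈ 7.4-fold in that group's
  samples. Temperature separates thermophile (40–54 °C) from mesophile
  (33–35 °C) groups; OLR spans 1.5–11 kg_COD/(m³ d), pH 7.1–8.6.
* **Planted associations**: one metaprotein is rank-coupled to TAN
  (positively) and one to OLR (negatively) at target Spearman 0.7 via a
  Gaussian copula — both the parameter and the feature's probability
  share are monotone functions of a shared latent variate plus
  independent noise whose variance is set from the target
  (σ² = 1/r − 1 per side with r = 2 sin(πρ/6)). The planted features'
  probability *shares* are set directly and the community background is
  scaled into the complement, so the target correlation is attained in
  expectation instead of being attenuated by denominator drift of the
  compositional normalization.
* **Planted marker**: one metaprotein is enriched `exp(2)`-fold exactly
  in samples with TAN > 4200 mg/L.
* Ground truth (group labels, signature orders/features, planted
  associations and signs, the marker, and the true per-sample
  probability matrix) is returned for recovery tests, and everything is
  byte-reproducible from (config, seed).

**What passing tests do and do not show.** The generator emulates the
statistical skeleton of a multi-plant survey: multinomial spectral
counting, compositional normalization, group-structured communities,
monotone parameter couplings. It does not emulate mass spectra,
peptide physicochemistry, FDR estimation, depth variation between
plants, phylogenetic correlation of abundances, or the heavy-tailed
cluster-size distribution of real UniRef50. Recovery results therefore
validate the *procedures* (that the pipeline finds what was planted at
realistic effect sizes and depths), not the biological conclusions of
any real survey, whose headline numbers require the original LC–MS/MS
data.

## Numerical choices and degenerate inputs

* Column sums after normalization are exact to 10⁻⁹; matrix IO
  round-trips at 12 significant digits.
* Constant feature rows are dropped (with a warning) before z-scoring;
  all-zero sample columns are an error naming the sample.
* The permutation p uses the add-one form, so the smallest attainable p
  is 1/(1 + n_perm); permutations are seeded and reproducible.
* `lca()` of an empty or all-missing taxon set is the root; unknown
  taxon ids are an error naming the id.
* Single-class label vectors give a single-leaf CART tree, not an
  error; a class absent from a train split triggers a redraw with the
  next seed (logged in the result).
* Problem sizes in the test suite: exact, size-independent properties
  (spectrum conservation, IO round-trips, Gini/LCA oracles) run on
  reduced studies (8 samples, 400 spectra); statistical recovery
  properties (cluster ARI, planted correlations, marker root-splits)
  run at the full default conditions over 20 seeds, the replication
  level at which the expected pass rates are comfortably resolved.

## Known limitations

* With 40 samples and dozens of retained features, several features can
  separate a binarized parameter perfectly on a 24-sample training set;
  CART then returns whichever wins the deterministic tie-break, which
  occasionally is not the planted marker even when the planted marker
  also separates perfectly (observed as the rare misses in the
  20-seed marker-recovery rate). This is a property of small-n marker
  discovery, not of the implementation.
* Fixed per-sample depth makes filtered richness nearly constant across
  synthetic samples; the richness-vs-depth saturation behaviour is
  exercised by varying depth across configurations instead.
* Evenness orientation follows the 100 × (1 − Gini) convention; when
  comparing against numbers from sources using raw Gini on 0–100,
  subtract from 100.
* The spectral-count unit ignores protein length and detectability;
  no NSAF-style correction is applied, matching the source methodology.
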