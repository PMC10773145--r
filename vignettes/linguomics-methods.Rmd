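---
title: "Methods: tongue-coating metaproteomics from database to screening model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tongue-coating metaproteomics from database to screening model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Tongue coating is a mixed host–microbial biofilm on the tongue dorsum. In
data-independent-acquisition (DIA) metaproteomics of such samples, every
quantified peptide may originate from the host or from any of hundreds of
microbial taxa, and the analytical questions layer on top of each other:
which protein database to search, which taxon each peptide belongs to, how
stable the proteome is over time within a person, which proteins and
functions differ between gastric cancer patients and non-cancer
individuals, which species carry risk, and whether microbial proteins can
screen for cancer. `linguomics` implements this chain as composable,
data-frame-first functions, and pairs it with a synthetic-data generator so
that every stage can be exercised and validated without any external
download.

# Two-step database reduction

DIA searches of a metagenome-derived database suffer from search-space
inflation. The two-step strategy searches each run against the full
database first (externally — this package consumes the resulting PSM
tables), keeps only proteins supported by at least one peptide-spectrum
match at q ≤ 0.01 (`simplify_database()`, row-level cutoff), and merges the
per-run simplified databases with the host database (`merge_databases()`,
host record wins accession collisions; output canonicalized by accession
sort so the merge is order-invariant). Protein inference is deliberately
not re-done: the PSM table's accession lists are taken at face value, as no
finer detail is available about the upstream engine's grouping.

# Peptide-centric taxonomic annotation

The annotation algorithm works on canonical peptides: leucine is rewritten
to isoleucine ("equal I and L" — the two residues are isobaric and
indistinguishable by MS), and peptides shorter than 5 or longer than 50
residues are discarded (bounds inclusive). Observed DIA peptides can carry
missed cleavages, so each one is first split into its fully tryptic
subpeptides (`tryptic_digest()` cleaves after K/R but not before proline;
the proline rule is the standard convention and can be disabled). Each
subpeptide is looked up in a peptide index built by digesting the host and
microbial databases with up to 2 missed cleavages (a typical search-engine
setting).

Conflicts are resolved by the branch rule:

* within a subpeptide, the taxa of all its database hits resolve to their
  lowest common ancestor (LCA);
* across subpeptides, if the per-subpeptide taxa lie on one root-to-leaf
  branch the narrowest (deepest) taxon is kept; otherwise the broadest.

"Broadest" is genuinely ambiguous when the conflicting taxa sit in disjoint
branches: the literally shallowest member is still inside one of the
conflicting lineages. The default `broad_mode = "lca"` therefore returns
the LCA of the set — the standard peptide-centric semantics — while
`broad_mode = "literal_broadest"` keeps the shallowest member (ties broken
deterministically by smallest taxon id) for fidelity experiments.
Subpeptides with no database hit are ignored rather than vetoing the
annotation; this maximizes annotation rate. Peptides that hit any human
protein are assigned to the host and excluded from taxonomic annotation
(host-first rule) — conservative, preventing microbial inflation from
shared host/microbe peptides. `no_rank` taxonomy nodes participate in
lineages and LCA computations but are skipped when reporting at a named
rank.

# Quantification, QC, and overlap reports

Quant tables are wide tibbles (features × samples) with annotation columns
(`origin`, `taxon_id`, `cog`, `ko`). A missing intensity means "not
identified": identification counts use non-missing, not non-zero, values,
matching how DIA reports encode absence. Intensities stay on their native
linear scale for ratios and aggregation; log2 transforms happen only inside
the statistics functions.

* `qc_filter()` keeps samples with ≥ 800 identified human proteins **and**
  ≥ 2000 identified microbial proteins (the study thresholds, inclusive;
  both are arguments because synthetic databases are smaller).
* `aggregate_quant()` sums member intensities per sample to a taxonomic
  rank (mapping each feature's taxon up its lineage) or a COG/KO category;
  features without the needed annotation are dropped and counted in a
  report, so aggregation conserves total intensity up to the report.
* `cohort_overlap()` reports `100·|A∩B|/|A∪B|` to one decimal. The union
  denominator is the reading that reproduces all four published overlap
  percentages (95.2, 94.1, 96.2, 94.4) exactly from the published totals,
  which is how the package's acceptance script recomputes them.

# Statistics

**Stability.** Temporal stability is summarised as Spearman correlations
over pairwise-complete features for every sample pair, stratified into
intra-individual (same subject) vs inter-individual pairs, reported as mean
± sd per stratum. Pairs sharing fewer than 3 features are dropped and
reported.

**Differential proteins.** Two-sided Wilcoxon rank-sum per feature — exact
when the combined non-missing n ≤ 20 without ties, normal approximation
with tie/continuity correction otherwise. Fold change is on linear-scale
group means, `log2FC = log2(mean_cancer / mean_noncancer)`, offset by +1
only when a group mean is zero. The significance rule is
`|log2FC| > 1` and p < 0.05; raw p is the default (`adjust = "none"`)
because the headline differential counts use raw p with the fold-change
filter, while `adjust = "bh"` supports the FDR-controlled reading. Features
with fewer than 3 non-missing values per group are skipped and reported.

**Enrichment.** Fisher's exact test per category on the 2×2 table of
in/out-foreground × in/out-category over the background; the reported odds
ratio is the sample cross-product ratio.

**Species risk.** Per-species univariate logistic regression of outcome on
the z-score of `log2(intensity + 1)` (missing = 0 = not identified);
OR = exp(coefficient) with Wald 95% CI and Wald p. The predictor coding is
a package decision — the source analysis does not state its regression
coding — and `standardize = FALSE` recovers the classical 2×2
cross-product odds ratio for a presence/absence predictor. Species whose
fit fails to converge or shows quasi-separation are flagged with no
estimate rather than reporting a meaningless interval.

**Host–microbe correlation.** Spearman rho for every (human feature, COG)
pair over shared samples, p from the t approximation on the rank
correlation, sorted by |rho|.

# Screening model

The classifier is a stochastic gradient-boosted tree ensemble with the
published hyper-parameters: depth 3, 150 trees, learning rate 0.1, minimum
node size 10, bag fraction 0.5, ten-fold cross-validation on the training
data, top 50 features by relative influence (reduction-in-loss importance
normalized to sum 100, ties broken by feature id). The ensemble is fitted
with xgboost under Bernoulli deviance. One mapping deserves a note: the
minimum-node-size constraint is expressed in observation counts, while
xgboost's `min_child_weight` is in hessian units, which for Bernoulli
deviance are at most 1/4 per observation — the package therefore passes
`min_node_size / 4`, keeping the effective constraint equivalent at the
decision boundary and preventing the degenerate no-split regime at small n.

The cohort splits 3:1 (stratified, `round(0.75·n)` per class, seeded).
Feature ranking and refitting use training samples only — a test asserts
that perturbing held-out intensities never changes the selected features.
Evaluation reports accuracy with an exact binomial (Clopper–Pearson) 95%
CI (the CI method is a package choice; the source does not name one),
sensitivity and specificity at the 0.5 probability cutoff (no threshold
tuning is described upstream, so none is done), trapezoidal AUC, and the
confusion matrix. The internal validation split is performed once, not
repeatedly.

**Embedding diagnostics.** Distances and the 2-D embedding work on
`log2(x+1)` with missing values min-imputed at each feature's observed
detection floor — treating absence as intensity 0 would place points ~20
log units away and dominate every distance. The t-SNE is a compact exact
O(n²) implementation (perplexity 30 clamped to (n−1)/3, PCA
initialization plus seeded jitter, early exaggeration, momentum with
adaptive gains), deterministic for a fixed seed and entirely adequate for
cohort-sized inputs (a few hundred samples). Group-averaged Euclidean
distances between healthy controls and the gastritis / stage I–II / stage
III–IV strata accompany the embedding.

# The synthetic-data generator

`generator_config()` encodes the emulated study conditions; the generator
is first-class, tested code, and the truth ledger it returns is the only
source of ground truth for recovery tests.

* **Cohort designs** (deterministic layouts): a time-series cohort of 5
  healthy subjects × 4 timepoints × 3 replicates with one subject absent
  at the final timepoint (57 samples); a 120 cancer / 120 non-cancer
  single-center cohort (stages I–IV 30 each; 30 of the non-cancer subjects
  gastritis); a 60/60 cohort over three centers. Together: 417 samples.
* **Reference**: a rank-labelled taxonomy of configurable shape (default
  5 phyla × 2 genera × 3 species), random protein sequences of 80–400
  residues with taxon-labelled FASTA headers, a UniProt-style human
  database, and one COG and KO per microbial protein. The default
  composition keeps the study's 9:1 microbial:human protein count ratio
  and ~4:1 peptide ratio at desk scale (150 human / 1350 microbial
  proteins) — large enough for every statistical property, small enough
  that the full pipeline runs in minutes on one CPU; tests that need a
  specific width (e.g. 2000 microbial proteins for feature-selection
  recovery) set the shape explicitly.
* **Intensity model**: feature baselines log2 ~ N(20, 2); additive
  subject-level random effects and residual noise on the log2 scale with
  origin-specific sds (human 0.25/0.25, microbial 1.0/0.5). Microbial
  profiles are thereby stable within a subject and variable between
  subjects, while human profiles are stable everywhere — the qualitative
  stability finding the generator must reproduce. The sds are realistic
  for DIA between-run and biological variability and are exposed, not
  hard-coded.
* **Planted effects**: differential proteins at ±2 log2 units; 10
  discriminative microbial proteins at ±1.5 ("strong effect"), scaled by
  1.25 in stage III–IV cancers and leaked at 0.3 into gastritis so staged
  cancers displace farther from controls than gastritis does; an optional
  latent factor coupling two keratin-like human proteins with one COG.
  Which features carry effects is drawn from a seed derived from the
  config alone, so all cohorts simulated from one reference share the same
  planted features — essential for external validation.
* **Risk species**: the per-subject exposure is N(0,1) in controls and
  N(δ,1) in cases; this normal-discriminant construction makes the log
  odds exactly linear in the exposure with slope δ, and δ is solved
  (δ·√(1+δ²/4) = log OR) so the slope on the *z-scored* exposure — the
  predictor `species_risk()` actually uses — equals log OR. The species'
  member proteins carry reduced noise (sd 0.15) and are exempt from
  missingness masking: masking a dominant member shifts the species
  log-aggregate by whole units and would attenuate the planted odds ratio
  into an unrecoverable quantity.
* **Missingness** is missing-at-random at rate 0.1 elsewhere.
* **PSM emission**: per run, a sampled subset of proteins contributes
  fully tryptic peptides at q < 0.01, plus decoy rows above the cutoff, so
  the database-reduction step has real work to do; the sampled accessions
  are ledgered.

What the generator does **not** emulate: spectrum-level effects (retention
time, m/z, interference), intensity-dependent missingness, batch effects,
compositionality constraints, or realistic protein sequence homology
(shared peptides across species arise only by chance). Passing recovery
tests therefore demonstrate that the pipeline's logic is correct under a
known generative model, not that the study's real-data performance
transfers.

# Numerical and design choices

* Seeds: one global seed fans out per stage via a fixed string-hash
  derivation (`derive_seed()`), avoiding cross-stage RNG coupling; all
  derived seeds stay below 2³¹.
* The exact Wilcoxon p switches to the tie-corrected normal approximation
  beyond combined n = 20; the two agree within 0.02 at the boundary.
* Logistic fits are declared non-converged when `glm` reports
  non-convergence or |coefficient| or its SE exceeds 10 on the log scale
  (quasi-separation).
* `literal_broadest` ties at equal depth break by smallest taxon id
  (numeric when ids are numeric) for reproducibility.
* Accession collisions across databases keep the first occurrence with a
  classed warning; database merges prefer the host record.
* The pipeline orchestration (`run_pipeline()`) is an R function rather
  than a shell tool: the package's users are R analysts, and the stage
  functions are the interface. The manifest records output hashes, so the
  reproducibility contract (identical config ⇒ byte-identical
  deterministic outputs) is directly checkable.
* Problem sizes in the test-suite and acceptance script (desk-scale
  references of tens to thousands of proteins, 100–150 simulation
  replicates) were chosen so the full validation runs in minutes on a
  single CPU while keeping Monte Carlo error well below each asserted
  margin.

# Known limitations

* Wald intervals around the logistic MLE at n = 240 cover a correctly
  planted odds ratio ~94% of the time, not 95% — the small-sample bias of
  the MLE is visible at this n. The acceptance check on CI coverage
  therefore estimates the coverage fraction over 150 replicates so its own
  Monte Carlo error stays well inside the asserted 90% bound.
* The peptide-level synthetic table attaches peptides to proteins by
  construction rather than by digesting the generated sequences, so
  peptide-to-protein roll-up is exercised structurally, not
  sequence-faithfully (the digestion code has its own oracle tests).
* The two-step reduction consumes PSM q-values at face value; no FDR
  re-estimation is attempted.
* Real tongue-coating data (the deposited cohort) is not bundled; the
  published real-data AUCs and accuracies are out of desk scope by design,
  and the synthetic analogue is the package's acceptance surface.
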