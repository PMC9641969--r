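---
title: "Methods: models, parameters and design choices in mitonuc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in mitonuc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# What the package computes

`mitonuc` tests two related ideas on a phylogeny of mammals (or any
comparable clade):

1. **Mitonuclear coevolution**, read off as *evolutionary rate covariation*
   (ERC): lineages in which mitochondrially encoded (mt) proteins evolve
   fast should also show fast evolution in nuclear-encoded,
   mitochondrially targeted (N-mt) proteins — but not in unrelated nuclear
   proteins — once genome-wide lineage effects are removed.
2. **Nuclear compensation**, the stronger hypothesis that deleterious mt
   substitutions are *followed* by compensatory N-mt substitutions. Its
   observable fingerprints are elevated dN/dS in N-mt genes, positive
   selection concentrated at mitonuclear contact residues, and — most
   directly — a temporal ordering in which the mt partner of a contact
   pair substitutes on a shallower branch than its N-mt partner.

Every stage is exercised end-to-end on synthetic data with known ground
truth, so the package's statistical machinery is testable without any
external download.

# Rate estimation

Branch lengths are estimated on a **fixed topology** by maximum likelihood
under a 20-state equal-exchangeability (Poisson) amino-acid model,
optionally with 4-category discrete-gamma rate variation, via Felsenstein's
pruning algorithm (`pruning_log_likelihood()`, `estimate_branch_lengths()`).
The closed-form transition probability
\[
P_{\text{same}}(t) = \tfrac{1}{20} + \tfrac{19}{20} e^{-\frac{20}{19} t}
\]
makes the implementation analytically checkable: the two-taxon maximum
likelihood distance inverts the observed difference fraction in closed
form, and the test suite verifies the optimizer against per-branch grid
search. A hook accepts an arbitrary symmetric 20x20 exchangeability matrix
for users who want LG- or mtART-like behaviour, but the Poisson model is
the default because ERC consumes only *relative* root-to-tip rates and the
simple model keeps simulator and estimator mutually verifiable.

Numerical choices: gaps and ambiguity codes are missing data (partial
likelihood 1); branch lengths are maximized one at a time by Brent search
on [0, 10] substitutions/site with fresh pruning partials before each
branch, so the log-likelihood increases monotonically; convergence is
declared when a full round improves the log-likelihood by less than `tol`
(default 1e-6). Under a reversible model only the *sum* of the two
root-adjacent branch lengths is identifiable; `estimate_branch_lengths()`
splits that sum equally by convention (`root_edge = "balance"`), which
bounds the arbitrariness of rooted root-to-tip distances. Identical
sequences yield exactly zero branch lengths.

Per-taxon rates are root-to-tip path sums (`root_to_tip_distances()`),
in expected substitutions per site.

# ERC: normalization and inference

Lineage-wide effects (demography, generation time, mutation rate) inflate
rate correlations between *any* two gene sets. Following standard practice
the background set of random orthologs is split into halves
(`split_random_orthologs()`, a seeded shuffle); the mt set is normalized by
half 1 and every nuclear target by half 2 (`normalize_rates()`, an
element-wise ratio), so a target is never normalized by the same genes as
the mt set. The correlation statistic is Spearman's \(r_s\) with average
ranks (`spearman_erc()`); differences between two correlations are tested
by jointly resampling taxa with replacement and computing the
bias-corrected and accelerated (BCa) interval of
\(r_s(\text{mt}, A) - r_s(\text{mt}, B)\)
(`bootstrap_difference()`; z0 from the fraction of replicates below the
point estimate, acceleration from the leave-one-taxon-out jackknife,
interval by type-6 quantiles). Replicates with constant ranks are dropped
and counted; more than 10% dropped is an error rather than a silent
degradation. A difference is reported "robust" when the 95% interval
excludes zero.

`pic_correlation()` supplies a phylogenetically corrected correlation:
Felsenstein independent contrasts of the two normalized rate vectors,
correlated through the origin. It is this package's *definition* of the
phylogenetic check — a standard, assertable choice — not a re-implementation
of any particular published variant. Non-binary trees are resolved with
zero-length branches floored at a small epsilon (with a warning); on a star
tree the contrast correlation provably equals the ordinary correlation of
centred tip values, which the tests assert.

**Calibration design.** The null/alternative calibration of the ERC stage
(uncoupled targets give \(|r_s| \le 0.3\), strongly coupled targets give
\(r_s \ge 0.5\), each in at least 90% of seeded runs) is performed on a
**star phylogeny** of 60 independent lineages, because those bounds are
statements about the sampling distribution of a correlation whose units
are exchangeable taxa. On a tree-structured sample, shared deep branches
reduce the effective number of independent observations and legitimately
widen the distribution of \(r_s\) in both directions — that inflation is a
property of phylogenetic data, not of the estimator, and is exactly why
`pic_correlation()` exists. The tree-structured pipeline is instead
checked by a single-run Monte-Carlo test: coupled targets must beat
uncoupled ones with a BCa difference interval excluding zero.

# dN/dS

Gene-wise dN/dS is estimated by Nei–Gojobori (1986) counting
(`count_sites_ng86()`, `pairwise_dnds_ng86()`, `geneset_dnds()`):
fractional synonymous site counts per codon position with mutations to
stop codons excluded from the denominators, codon differences at more than
one position averaged over minimal mutational pathways (stop-passing
pathways excluded; if every pathway is blocked, all are retained so the
count stays defined), and Jukes–Cantor correction
\(d = -\tfrac{3}{4}\ln(1 - \tfrac{4}{3} p)\). Pairs with \(p \ge 3/4\) are
*saturated*: excluded and counted, never coerced to infinity. Gene-level
\(d_N\) and \(d_S\) are means over non-saturated pairs and
\(\omega = \bar d_N / \bar d_S\) (ratio of means; stabler than a mean of
ratios when some pairwise \(d_S\) approach zero). NG86 is a deliberate,
self-contained counting stand-in for maximum-likelihood codon models; its
site counting is exact only without transition bias, so the
omega-recovery tests simulate with \(\kappa = 1\) while the generator's
default \(\kappa = 2\) reflects the mammalian transition bias. Mt genes
are translated with the vertebrate mitochondrial code, nuclear genes with
the standard code.

Group comparisons use one-way ANOVA with Tukey HSD adjustment
(`compare_groups()`); the contact-residue trend is ordinary least squares
of omega on each gene's contact-residue fraction
(`contact_fraction_trend()`).

# Contacts

`parse_structure()` reads PDB coordinate records (heavy atoms of ATOM
records; hydrogens dropped; for alternate locations the highest-occupancy
atom per atom name is kept). `find_contact_pairs()` reports a residue pair
iff its minimum heavy-atom Euclidean distance is **at or below 5
Angstrom** (inclusive) *and* the two residues' genes come from different
genomes; an optional van der Waals overlap criterion
(\(r_i + r_j - d \ge -1\) Angstrom, with a bundled radius table)
reproduces the clash-tool convention that motivates the 5 Angstrom window.
Residues keep PDB author numbering end-to-end; alignment columns are
1-based. `map_residue_to_column()` bridges structure and alignment
coordinates by global pairwise alignment (match 1, mismatch -1, gap -2)
against the reference taxon's ungapped row, refusing below 50% identity
(which almost always means a wrong chain-to-gene assignment).

# Substitution ordering

Ancestral states are reconstructed by two-pass Fitch parsimony with a
deterministic resolution rule (a node with an ambiguous optimal set takes
its parent's state when possible, else the lexicographically smallest
member; the root takes the smallest member). Determinism is required for
reproducibility; a marginal maximum-likelihood reconstruction under the
Poisson model (`method = "marginal_ml"`) is available for sensitivity
checks. Substitutions are assigned to the branch where parent and child
states differ (`map_substitutions()`).

A contact pair is classified (`classify_pair_order()`) per root-to-tip
path: the shallowest event at each partner site is compared by branch
depth; the pair's label aggregates paths by majority of mt-first vs
N-mt-first votes (exact tie or no qualifying path: *unresolved*; only
same-branch co-occurrences: *same_branch*, which is tabulated separately
and excluded from the chi-square, consistent with the close/far definition
excluding same-branch events). Branch separation counts intervening edges
(adjacent = 1) and is the minimum over winning paths; separations of 1–2
are *close*. Because both events lie on one root-to-tip path, the deeper
branch is automatically inside the clade subtended by the shallower one,
so no extra monophyly check is needed. Lineage-restricted analyses are a
tip-set filter on the considered paths.

The ordering statistics are a one-degree-of-freedom goodness-of-fit
chi-square against equal mt-first/N-mt-first counts
(`chisq_equal_order()`) and Fisher's exact test for mt-first enrichment
between datasets (`fisher_mtfirst_enrichment()`), both delegating to the
exact textbook procedures and verified against closed forms and full
hypergeometric enumeration.

# Site selection and FNM flags

`site_selection_test()` is a counting (SLAC-like) stand-in for
likelihood branch-site machinery: synonymous and nonsynonymous changes at
a codon site are counted over (optionally foreground-restricted) branches
by replaying the codon reconstruction; the neutral expectation of the
nonsynonymous fraction comes from the site's NG86 opportunities on each
branch's parent codon, weighted by branch length; the P value is the
one-sided binomial tail for nonsynonymous excess. Two tiers are reported
(default alpha 0.05; stringent 0.01). Categorical agreement with
likelihood-based site tests is *not* claimed; the tests verify type-I
control on neutral simulations and a correct power direction. The
counting test has binomial resolution only when a site carries several
changes, so site-level scans are meaningful on deep, dense phylogenies and
the power checks simulate in that regime.

Functional-nodal-mutation flags (`flag_functional_nodal()`) implement only
the frequency component of predictive deleteriousness models — a derived
residue is flagged when its column frequency is below 5% — and are labelled
"frequency-FNM" accordingly; no structural stability term is computed.

# The synthetic-data generator

The generator (`simulation_config()` and friends) emulates the statistical
structure the analyses assume, with one master seed feeding per-stage
sub-streams:

* **Trees**: Yule (pure-birth) trees with uniquely named tips
  (`generate_yule_tree()`), or a fixed Newick topology, or the star tree
  of independent lineages (`star_tree()`).
* **Lineage rates**: per-branch log-scalars, bivariate normal between the
  mt and N-mt sets with correlation `rate_coupling_rho` and standard
  deviation `scalar_sd` (default 0.3 — across ~60 lineages the fastest is
  then roughly 3x the slowest, matching the spread reported for mammals).
  The pipeline adds a lineage-wide effect shared by *all* sets (default sd
  0.3) — the component the background normalization exists to remove — and
  shrinks the background halves' set-specific deviation by
  \(\sqrt{\text{genes per half}}\), because a concatenation of many random
  orthologs averages out gene-level effects.
* **Sequences**: amino mode is the same Poisson process the estimator
  assumes (`base_rate` expected substitutions/site per unit branch length,
  default 0.1 — root-to-tip totals of roughly 0.3–0.5 substitutions/site
  on the default trees, a mammal-like amount for OXPHOS proteins); codon
  mode is a Goldman–Yang-style omega/kappa process with uniform codon
  frequencies and stop codons excluded. Every substitution is logged with
  its branch, giving exact ground truth for recovery tests. Default
  omegas (mt 0.06; N-mt OXPHOS/ribosomal 0.16; glycolysis 0.07;
  cytoplasmic-ribosomal 0.03; random orthologs 0.12) encode purifying
  selection throughout with the elevated N-mt values the compensation
  debate is about.
* **Compensatory pairs** (`simulate_compensatory_pairs()`): each pair
  couples one mt and one N-mt site. The trigger site substitutes at the
  baseline rate; once it substitutes on a lineage, the partner's rate on
  **descendant branches** is multiplied by `compensation_boost_beta` until
  the partner substitutes. The boost deliberately starts at the next
  branch: a within-branch response would collapse the signal into
  same-branch co-occurrences, which the branch-resolution classifier
  cannot order. Modelling compensation as a rate boost (not a
  deterministic immediate fix) yields both mt-first and N-mt-first labels,
  so classifier error behaviour is testable. True per-pair labels are
  derived from the logged events by the same path logic the classifier
  uses, with exact event times breaking vote ties.
* **Contact-site rate**: the ordering pipeline simulates contact pairs at
  `contact_site_rate` (default 0.03 substitutions/site per unit branch
  length), slower than the protein-wide default because mitonuclear
  contact residues are conserved and the ordering analysis presumes
  sparse substitutions (on the order of one trigger event per pair across
  the tree). At dense rates the many descendant lineages all compensate in
  parallel and parsimony provably collapses those parallel responses onto
  the shallow trigger branch — a property of ancestral reconstruction that
  the sparse regime avoids.

What the generator does **not** emulate: indels, among-site rate
heterogeneity beyond per-set scalars, realistic base/residue composition,
codon usage bias, selection on synonymous sites, or correlated
substitution processes beyond the single trigger-partner mechanism.
Passing tests therefore demonstrate that the statistical machinery behaves
correctly under the stated generative assumptions — not that real data
meet those assumptions.

# Problem sizes used by the checks

The shipped tests and the acceptance script choose sizes that make each
property measurable with comfortable margins: rate-recovery at 10,000
amino-acid sites on 12 taxa; ERC calibration on 100 seeded 60-taxon
star-tree runs (2,000-site targets, 6,000-site backgrounds); BCa coverage
on 200 runs of 40 taxa at 2,000 bootstrap replicates; omega recovery at
200–1,000 codons; compensatory recovery on 30-taxon trees with 150–300
pairs; the full-pipeline ERC demonstration at a mammal-study scale of 58 taxa.

# Known limitations

* The Poisson amino-acid model ignores realistic exchangeabilities; use
  the exchangeability hook if absolute branch lengths matter.
* NG86 and the counting selection test are counting stand-ins for
  likelihood codon machinery; they are calibrated and directionally
  correct under the generator, but their site lists will not match
  likelihood methods categorically.
* Rooted root-to-tip distances inherit the root-edge convention described
  above; analyses should treat them as relative rates.
* Per-pair ordering aggregates multiple root-to-tip paths by majority
  vote; other aggregation rules are defensible, and the per-path vote
  counts are retained in the output so users can apply their own.
* The vertebrate mitochondrial genetic code is assumed for mt genes;
  other clades need a different code table.
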