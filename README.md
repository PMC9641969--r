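# mitonuc

Tools for testing **mitonuclear coevolution** and the **nuclear
compensation hypothesis** on a phylogeny.

Mitochondrially encoded (mt) proteins and nuclear-encoded,
mitochondrially targeted (N-mt) proteins must co-function inside the
OXPHOS complexes, yet they are inherited and mutate very differently. If
the two genomes coevolve, lineages with fast mt protein evolution should
also show fast N-mt evolution — *evolutionary rate covariation* (ERC) —
while unrelated nuclear genes should not. If the specific mechanism is
nuclear compensation, N-mt genes should additionally carry elevated
dN/dS, positive selection at mitonuclear contact residues, and a temporal
signature: within an mt/N-mt contact pair, the mt substitution should
appear on a shallower branch than the compensating N-mt substitution.

`mitonuc` implements the full analysis chain for these predictions:

| Stage | Functions | Method |
|---|---|---|
| Rates | `estimate_branch_lengths`, `root_to_tip_distances` | ML branch lengths on a fixed topology under a Poisson amino-acid model (+gamma option), pruning algorithm |
| ERC | `split_random_orthologs`, `normalize_rates`, `spearman_erc`, `bootstrap_difference`, `pic_correlation` | background-normalized Spearman r_s; bootstrap BCa difference intervals; independent-contrasts check |
| dN/dS | `count_sites_ng86`, `pairwise_dnds_ng86`, `geneset_dnds`, `compare_groups` | Nei–Gojobori (1986) counting with Jukes–Cantor correction; ANOVA + Tukey HSD |
| Contacts | `parse_structure`, `find_contact_pairs`, `map_residue_to_column` | minimum heavy-atom distance ≤ 5 Å between residues of different genomes (PDB input) |
| Ordering | `reconstruct_ancestral`, `map_substitutions`, `classify_pair_order`, `chisq_equal_order`, `fisher_mtfirst_enrichment` | Fitch parsimony; mt-first / N-mt-first classification along root-to-tip paths; exact tests |
| Selection | `site_selection_test`, `contact_enrichment`, `flag_functional_nodal` | counting-based (SLAC-like) binomial site test; frequency-FNM flags |
| Synthetic data | `simulation_config`, `generate_yule_tree`, `simulate_alignment`, `simulate_compensatory_pairs` | seeded generator with logged ground truth for every stage |
| Pipeline | `validate_config`, `run_erc_pipeline`, `run_ordering_pipeline`, `run_full_analysis` | YAML-configured end-to-end runs, TSV outputs |

The methods vignette (`vignettes/mitonuc-methods.Rmd`) documents every
model, default and deliberate simplification (e.g. NG86 and the counting
selection test as self-contained stand-ins for likelihood codon
machinery).

## Worked example

The temporal ordering test on the published contact-pair counts — 74
pairs in which the mt partner substituted first versus 323 in which the
N-mt partner did:

```r
library(mitonuc)
res <- chisq_equal_order(74, 323)
res
#> chi-square = 156.17, df = 1, P = 7.76e-36 (mt_first = 74, nmt_first = 323)
round(100 * 74 / 397, 1)   # 18.6  (% mt-first)
round(100 * 323 / 397, 1)  # 81.4  (% N-mt-first)
```

N-mt substitutions precede mt substitutions far more often than chance —
the opposite of the nuclear-compensation prediction.

A synthetic end-to-end ERC run (strong mt/N-mt coupling, rho = 0.9,
against an uncoupled control set) on a 58-taxon tree:

```r
cfg <- validate_config(list(
  seed = 1,
  synthetic = list(n_taxa = 58, seq_length = 600,
                   rho_target = 0.9, rho_control = 0),
  erc = list(rate_method = "ml", n_boot = 2000)))
erc <- run_erc_pipeline(cfg)
erc$erc_table
#>    target        r_s       ci_lo     ci_hi  n
#> 1     nmt 0.69687219  0.51239817 0.8261918 58
#> 2 control 0.01677114 -0.27687086 0.3174685 58
erc$difference
#> delta r_s = 0.680, 95% BCa CI = 0.402..1.003 (n_boot = 2000)
```

The coupled target shows a strong normalized rate correlation, the
control none, and the bootstrap BCa interval of the difference excludes
zero — the ERC signature of mitonuclear coevolution, recovered from
simulated sequences by the full estimation chain (ML branch lengths →
root-to-tip rates → background normalization → correlation → bootstrap).

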