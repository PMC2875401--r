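---
title: "Detecting lateral gene transfer with bootstrap-gated tree walks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting lateral gene transfer with bootstrap-gated tree walks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lgtree)
```

## The model and its assumptions

`lgtree` detects lateral gene transfer (LGT) by topological conflict: a
gene whose phylogenetic placement contradicts the placement of its host
lineage (established by rRNA markers) is a transfer candidate. The unit of
analysis is one query gene on a genomic fragment whose host has been
assigned to a *focal group* — by default *Clostridium* cluster IV, the
recipient lineage in the fosmid study this pipeline operationalizes — and a
gene tree relating the query to homologs from species with known group
membership (cluster IV, cluster XIVa, other clusters, outgroups).

The method makes three assumptions worth keeping in mind:

- **The group map is correct.** Cluster membership of reference species is
  an input, not an inference. Misassigned references propagate directly
  into calls.
- **Support values calibrate trust.** A clade is only allowed to influence
  a call if its support exceeds the gate. NJ bootstrap percentages and
  approximately-ML local supports are both accepted as values in [0, 100];
  the gate is applied uniformly, and calibrating one scale against the
  other is left to the user.
- **Transfers involve the query lineage.** The walk starts at the query;
  transfers elsewhere in the tree are out of scope.

## The classifier, step by step

For a query gene with best reference e-value *e* and a rooted, supported
gene tree:

1. If *e* > 10⁻⁶ (strictly), the gene is `novel`: too divergent for
   placement to mean anything. The tree is not consulted, and no
   tree-derived fields are reported.
2. Otherwise walk from the query leaf's parent toward the root. The
   *decision node* is the first node whose support is strictly greater
   than 60 **and** whose leaf descendants include a species different from
   the query's. Unsupported nodes are walked past even if they contain
   other species — the walk continues rather than aborting, which is the
   natural reading of "step back until a supported node".
3. The groups of the decision node's descendants — excluding the query
   itself, which would otherwise always inject the focal group — decide:
   only focal → `no_lgt`; focal and non-focal → `unresolved`; only
   non-focal → `lgt`.
4. If no node on the root path passes the gate, the gene is `unresolved`
   with decision fields absent. This is a recorded outcome, not an error.

### Direction inference

For `lgt` calls, the donor is reconstructed by two-pass Fitch parsimony
over the group alphabet. The reconstruction runs on the tree with the
query leaf *removed*: the query is the putative transferred copy, and its
own (focal) label must not vote on the ancestral state of the clade it
inserted into. A direction "from donor to focal" is reported only when two
independent singletons agree — the Fitch state set of the decision node
and the decision node's descendant group set. Any ambiguity (multi-state
Fitch set, multiple non-focal descendant groups) leaves the direction
`unresolved`; ambiguity sets are retained in full rather than resolved by
sampling, so a direction is only ever reported when it is forced.

### Reconciliation of NJ and ML calls

When both NJ- and ML-based calls exist, the default policy is
conservative: `lgt` requires both methods to call `lgt`; a `no_lgt` from
either method overrules; every other disagreement reconciles to
`unresolved`. A stricter reading than "unresolved does not veto" is used
deliberately: in the motivating dataset, a gene with an unresolved NJ call
and an ML transfer call was *not* counted among the transfers, and the
conservative headline count (10 of 44) is only reproducible if one-method
support is insufficient. Discordant genes are flagged and both per-method
calls are kept. Calls whose decision support falls below a report-only
threshold (default 70) carry a `low_support` flag; the gate itself stays
at the literal "> 60", since that is the operating point the analysis
defines, but the flag lets users apply the stricter tier the low-support
(61) counter-example in the source data suggests.

## Tunable parameters

| Parameter | Default | Units | Why this default |
|---|---|---|---|
| `evalue_threshold` | 1e-6 | e-value | novelty gate, strict `>`; standard homology-screen cutoff |
| `support_threshold` | 60 | bootstrap % | strict `>`, taken literally from the defining analysis |
| `focal_group` | `cluster_IV` | label | recipient lineage of the motivating dataset |
| `rooting` | `midpoint` | — | the source analysis does not state its rooting; midpoint needs no outgroup and minimizes the maximum root-to-leaf distance |
| `low_support_flag` | 70 | bootstrap % | report-only stricter tier |
| bootstrap `replicates` | 100 | count | unstated in the source; the field's customary floor |

Distance/gap handling: K2P distances exclude gap/ambiguity sites pairwise
(the MEGA-style default implied by the original workflow); complete
deletion is available by flag. Saturation (1 − 2P − Q ≤ 0 or 1 − 2Q ≤ 0)
raises an explicit error rather than returning infinity, so saturated
pairs surface instead of silently distorting trees.

## Numerical and determinism choices

- **NJ tie-breaks.** Equal Q-criterion values are resolved toward the
  lexicographically smallest cluster-name pair, making output independent
  of taxon input order.
- **Negative NJ branches** are clamped to zero with the deficit moved to
  the sister edge (preserving the pair's path length); raw values are
  available by flag.
- **Supports travel with edges.** Rerooting re-attaches each support to
  the same bipartition, not the same node index — the property that makes
  a walk over a rerooted tree meaningful.
- **Bootstrap replicates that fail** (a saturated resample) contribute no
  bipartitions but stay in the denominator, so supports cannot be inflated
  by discarding awkward replicates.
- **Fitch on multifurcations** folds children left-to-right
  (intersection-else-union); the change count is the exact parsimony
  minimum on binary trees, which is what the pipeline produces and what
  the brute-force oracle checks.
- **Profile bins** are one-decade half-open intervals from 1e0 down to
  1e-180, plus a most-significant bin that also receives e-value 0; 1e-80
  (the conserved-sequence landmark) is always an edge. The exact bin edges
  of the original heat-map figure are not recoverable from its text, so
  the defaults encode the structural procedure, configurable by argument.
- Percentages in recount reports are rounded half-up to whole percent,
  matching how such tables are printed; raw fractions are emitted too.

## What the synthetic generator emulates — and what it does not

`sim_scenario()` + `simulate_gene_tree()` produce clade-labelled rooted
trees with a planted event: the query grafted innermost in a pure
donor-group clade (`transfer`) or inside its own focal clade (`none`).
Supports on the nodes the classifier will walk are drawn from truncated
uniform regimes — gate-passing U(80, 100), gate-failing U(0, 60) — rather
than computed by bootstrap. That choice keeps classifier tests independent
of tree construction: a planted-recovery failure indicts the classifier,
not the tree builder. Default clade sizes (6 focal, 5 donor, 4 other)
mirror the modest reference sets of single-copy bacterial gene trees;
branch lengths are U(0.02, 0.2) substitutions/site, comfortably below K2P
saturation.

`evolve_alignment()` evolves sites i.i.d. under the two-parameter
transition/transversion process (default κ = 2) — no rate heterogeneity,
no indels, no compositional drift. Consequently a green planted-recovery
test establishes that the classifier implements its specification, and
that the estimator chain (K2P → NJ → bootstrap) is consistent on data
generated by its own model. It does **not** establish robustness to model
violation, alignment error, or incomplete taxon sampling, all of which
real fosmid data contain.

All generators are pure functions of (parameters, seed) and restore the
caller's RNG state.

## Degenerate inputs

Two-taxon "trees", zero-column alignments, empty hit lists, empty group
maps, all-gap pairs, and zero-variance codon vectors all have defined
behaviour (closed form, empty result, or a classed error — never a silent
`NaN`). The gene-table fixture loader enforces frozen totals (62 rows, 44
protein-coding, 18 RNA features) and vocabulary membership, so a corrupted
fixture fails loudly before any count is computed.

## Known limitations

- The accession-dependent validation tier — 16S/23S percent identity
  between the two deposited fosmid sequences (99.8% / 99.9%), codon-usage
  r ≈ 0.70, per-CDS GC against the printed table — requires the GenBank
  records (FJ625861, FJ625862) and cannot run offline. The machinery
  (`percent_identity()`, `codon_usage()`, `usage_correlation()`,
  `gc_content()`) is exercised on synthetic data instead, and the CLI can
  run the real comparison when the sequences are supplied as FASTA.
- Probabilistic transfer reconciliation (duplication-transfer-loss
  models), transfers not involving the query lineage, and likelihood tree
  inference are out of scope; externally built ML trees are consumed as
  Newick.
- Fitch parsimony treats groups as unordered states; it cannot distinguish
  a transfer from donor paraphyly when reference sampling is thin.
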