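# lgtree

Tree-based detection of lateral gene transfer (LGT) in microbial genomes.

## The problem

Gut-microbiome surveys keep turning up genomic fragments whose housekeeping
markers say one thing and whose protein-coding genes say another. The
motivating case for this package is a pair of fosmid inserts recovered from
an agar-degrading enrichment of marine iguana feces: their 16S/23S rRNA
operons place the source organism firmly inside *Clostridium* cluster IV,
yet over half of the coding genes hit species outside that cluster,
suggesting lateral acquisition — mostly from the neighbouring *Clostridium*
cluster XIVa. `lgtree` packages the analysis needed to make that claim
rigorously and repeatably: per-gene phylogenies, a bootstrap-gated
tree-walk classifier, and Fitch-parsimony donor/direction inference, plus
the supporting compositional statistics and BLAST e-value profiles.

## The method

For each gene a phylogeny is built (or supplied): pairwise distances under
the Kimura two-parameter model,

d = −½ ln[(1 − 2P − Q) √(1 − 2Q)],

with P and Q the transition and transversion difference proportions, a
neighbor-joining tree, and nonparametric bootstrap supports (percentage of
column-resampled replicate trees containing each bipartition).

The classifier then works per query gene:

1. **Novelty gate.** Best reference-database e-value > 10⁻⁶ → `novel`
   (too divergent to place); the tree is not consulted.
2. **Tree walk.** Starting at the query leaf, step back toward the root
   until the first node with bootstrap support strictly > 60 that contains
   a sequence from a species other than the query's — the *decision node*.
3. **Call.** Let G be the clade groups of the decision node's non-query
   descendants. G ⊆ {cluster IV} → `no_lgt`; G mixed → `unresolved`;
   G ∩ {cluster IV} = ∅ → `lgt`.
4. **Direction.** For `lgt` calls, Fitch parsimony on the query-dropped
   tree reconstructs the decision node's ancestral group; a singleton
   non-focal state with a singleton descendant group set yields
   "from *donor* to *recipient*", anything ambiguous stays `unresolved`.
5. **Reconciliation.** NJ- and ML-based calls for the same gene are merged
   conservatively: `lgt` only when both methods agree; `no_lgt` from
   either wins; other mixtures reconcile to `unresolved`.

Compositional evidence (GC content, codon-usage correlation across the 61
sense codons, rRNA percent identity) and per-genus BLAST e-value profile
matrices ("heat maps") round out the analysis. Seeded simulators generate
gene trees with planted transfer events, alignments evolved under the
two-parameter process, and controlled BLAST hit sets, so every stage is
testable offline with known truth.

## Worked example

```r
library(lgtree)

# recount the packaged fosmid gene table (fosmids 7-14 and 7-25)
rec <- recount_fixture(load_table1_fixture())
str(rec[1:4])
#> List of 4
#>  $ coding_total     : int 44
#>  $ lgt_count        : int 10
#>  $ donor_xiva_count : int 7
#>  $ nonfocal_tophit_count: int 23
```

Of the 44 protein-coding genes on the two fosmids, 10 are called
laterally transferred after conservative NJ/ML reconciliation, 7 of them
with a resolved donor (*Clostridium* cluster XIVa), and 23 (52%) have top
BLASTX hits outside the focal cluster IV.

```r
# classify one gene tree: query nested inside a supported cluster-XIVa clade
gm <- taxon_group_map(
  c("Q", "X1", "X2", "IV1", "IV2"),
  group = c("cluster_IV", "cluster_XIVa", "cluster_XIVa",
            "cluster_IV", "cluster_IV"))
tr <- read_newick("(((Q:1,X1:1)95:1,X2:1)90:1,(IV1:1,IV2:1)99:1);")
classify_and_infer(tr, "Q", gm, top_evalue = 1e-20)
#> lgt_call [nj] Q: lgt (decision support 95, groups {cluster_XIVa}),
#>   direction from_cluster_XIVa_to_cluster_IV
```

The decision node is the query's parent (support 95 > 60); its only
descendant group is cluster XIVa, so the gene is called `lgt`, and the
Fitch reconstruction resolves the donor, giving a cluster XIVa → cluster IV
transfer.

A command-line front end covers scripted use (`inst/cli/lgtree`):

```sh
lgtree build-tree --alignment aln.fasta --bootstrap 100 --seed 42 --root midpoint --o tree.nwk
lgtree classify --manifest genes.tsv --groups groups.tsv --o out/
lgtree recount
lgtree profile --hits hits.tsv --min-hits 10 --o profile.tsv
```

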