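# noveltynet

Compare three de novo amplicon clustering approaches — greedy centroid
clustering, sequence similarity networks, and swarm-style iterative
single linkage — and audit how each delineates *novel diversity* in
environmental metabarcoding data (e.g. protist 18S V4 amplicons
clustered together with a curated reference database).

## The problem

Environmental surveys call an amplicon *novel* when it clusters into an
OTU (operational taxonomic unit) containing no reference sequence. The
clustering algorithm therefore decides what counts as novel:

* **Greedy centroid clustering** processes amplicons by decreasing
  abundance; an amplicon joins the existing centroid of maximal global
  identity when that identity reaches a threshold *t* (here the
  all-columns definition: matching columns / total alignment columns,
  terminal gaps included), otherwise it founds a new OTU. Every OTU has
  radius ≤ 1 − *t* around its centroid — the *radius cap* — so members
  similar to a reference can be stranded in an OTU without it.
* **Sequence similarity networks** join every pair with identity ≥ *t*
  by an edge and take connected components as OTUs. Components grow
  transitively, so their radius is unbounded; an amplicon within *t* of
  a reference is, by construction, in the same OTU as that reference.
* **Swarm** links amplicons iteratively at a small local threshold *d*
  (maximum differences per link, default 1), growing from
  abundance-ranked seeds, with abundance-aware chain breaking and
  optional "fastidious" grafting of low-abundance OTUs.

Per environmental amplicon the package reports the OTU composition
class (`mixed` / `ref_only` / `env_only`), the shortest-path distance to
the nearest reference inside its OTU (network and swarm OTUs carry an
internal edge topology), the best-hit identity to the reference set,
and a novelty class: `covered` (distance 1), `novel_variant` (finite
distance ≥ 2) and `novel` (no path to any reference). Cross-approach
comparison includes a composition summary table, the 7-region overlap
of the three novel amplicon sets, divergence profiles, and a
*misclassification audit*: amplicons called novel despite a best hit
≥ *t* — provably zero for the network approach, and structurally
nonzero for radius-capped clustering on communities whose intraspecific
variation exceeds 1 − *t* while remaining connected through
intermediates.

A synthetic community generator with known ground truth (reference
"species", 1%-divergence amplicon clouds with stepping-stone chains and
distance-1 satellite variants, truly novel lineages above 5%
divergence, Zipf-like abundances) makes the whole pipeline testable
without downloads; see the methods vignette
(`vignettes/clustering-comparison.Rmd`) for the generator's assumptions
and every numerical design choice.

## Worked example

```r
library(noveltynet)

refs <- generateReferences(seed = 1)          # 20 references, 380 bp
com  <- generateCommunity(refs, seed = 2)     # 440 environmental amplicons
paths <- writeSyntheticDataset(com, refs, "dataset")

res <- runPipeline(runConfig("dataset/environmental.fasta",
                             "dataset/references.fasta", "results"))
res$summary
```

```
Clustering comparison
 approach otus mixed_otus mixed_env_amplicons mixed_ref_amplicons ref_only_otus
   greedy   45         20                 295                  20             0
  network   25         20                 400                  20             0
    swarm   34         12                  38                  12             0
 ref_only_ref_amplicons env_only_otus env_only_env_amplicons
                      0            25                    135
                      0             5                     39
                      0            22                    110
 misclassified_novel retained_amplicons
                  42                450
                   0                459
                  85                160

Overlap of novel amplicon sets:
   greedy_only   network_only     swarm_only greedy_network   greedy_swarm
            86              0             75             14             10
 network_swarm      all_three
             0             25
```

Reading the table: the network approach produces the fewest OTUs (25)
and the smallest novel set (39 amplicons — exactly the five planted
novel lineages, after dereplication), with 0 misclassified. Greedy
clustering over-splits (45 OTUs) and calls 135 amplicons novel, 42 of
which are ≥ 97% identical to a reference (radius-cap
misclassifications). Swarm reports 110 novel amplicons, of which 85 are
within 97% of a reference, because distance-1 linkage cannot bridge
1%-diverged clouds without intermediate sequences. `res$reports` holds
the per-amplicon records;
`plotDivergence()` and `plotPathDistances()` draw the corresponding
diagnostics.

All result files (membership, novelty, edge lists, summary, Venn
counts, audit, manifest, log) are written as TSV under the configured
output directory. A thin command-line front end with `simulate`,
`cluster`, `analyze`, `compare` and `run-all` subcommands is installed
at `inst/scripts/noveltynet-cli.R`.

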