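# pbpclust

Subquadratic agglomerative clustering of marker-gene amplicon reads
(16S rRNA and similar) into operational taxonomic units (OTUs), for
microbiome researchers who want *hierarchical* clustering — the reference
method for de novo OTU binning — at dataset sizes where the textbook
algorithm's quadratic pairwise matrix is out of reach.

## What it does

Given reads $x_1,\dots,x_N$, a stop distance $d_{up}$ (e.g. 0.15 for the
usual 85% similarity termination) and the normalized global-alignment
distance $D(\cdot,\cdot) \in [0,1]$ between cluster consensus profiles,
sequential hierarchical clustering repeatedly merges
$\{a,b\} = \arg\min_{i \ne j} D(S_i, S_j)$ until every inter-cluster
distance reaches $d_{up}$.  `pbpclust` computes exactly that merge
sequence, but organizes the work differently:

* active clusters live in a **PBP tree** (pseudo-metric based partitioning
  tree): an ordered, equal-depth hierarchy of hyper-spheres with a halving
  radius schedule, frozen centers, near-constant insert/delete and
  branch-and-bound nearest-neighbour search;
* all **mutual nearest-neighbour pairs** ($NN(a)=b$, $NN(b)=a$,
  $D(a,b) < d_{up}$) are independent merges, discoverable together and,
  with a tie-breaking pass for equal-distance cycles, guaranteed to exist;
* **delayed NN updating** keeps, for each cluster whose neighbour was
  consumed by a merge, a certified lower bound on its new NN distance
  (one evaluation against the merged cluster often restores the record
  outright); a candidate pair merges only when its distance beats every
  such bound (making it the global minimum), and otherwise a batch of
  stale records is re-searched — on replicated worker trees when
  `workers > 1`.

Merge decisions are bit-identical to the sequential reference (`hc_oracle()`)
at every threshold, for any worker count.  Around the engine: FASTA
dereplication and length/primer filters, flat partition cutting, tetrad and
OTU file writers, Chao1 / ACE / rarefaction estimators, a synthetic read
simulator with ground-truth labels, and NMI-based evaluation.

## Worked example

```r
library(pbpclust)

ds  <- make_dataset(synthetic_spec(n_templates = 4, template_length = 150,
                                   reads_per_template = 30,
                                   sub_rate = 0.01, seed = 42))
res <- otu_pipeline(ds$reads[, c("id", "seq")], d_up = 0.15,
                    thresholds = c(0.03, 0.05, 0.10))
#> reads in: 120
#> after filters: 120 kept, 0 rejected
#> dereplicated: 101 unique records
#> merges: 97 (8,854 distance evaluations)

res
#> <pbp_otu> 101 records, 97 merges
#>   t = 0.03 : 13 OTUs
#>   t = 0.05 : 4 OTUs
#>   t = 0.1  : 4 OTUs

diversity_table(res)
#> # A tibble: 3 x 5
#>   threshold n_reads s_obs chao1   ace
#>       <dbl>   <int> <int> <dbl> <dbl>
#> 1      0.03     120    13    49    49
#> 2      0.05     120     4     4     4
#> 3      0.1      120     4     4     4
```

Reading it: 120 reads from 4 source templates dereplicate to 101 records;
97 merges happen below `d_up`, using under 9k alignment evaluations rather
than a full pairwise matrix plus its per-merge updates.  At the 0.03 cutoff
sequencing errors still split singleton OTUs off (13 observed, Chao1
extrapolates richness upward from those singletons); by 0.05 the partition
collapses onto the 4 true templates and the richness estimators agree with
the observed count.  Scoring against the simulator's labels:

```r
truth <- setNames(ds$reads$template, ds$reads$id)
peak_nmi(truth, res$fit, thresholds = c(0.03, 0.05, 0.10),
         members = res$records$members)$scores
#> # A tibble: 3 x 2
#>   threshold   nmi
#>       <dbl> <dbl>
#> 1      0.03 0.900
#> 2      0.05 1
#> 3      0.1  1
```

The same workflow is scriptable: `inst/cli/pbpclust` provides `simulate`,
`preproc`, `cluster` and `stats` subcommands over the exported functions.

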