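# graphbwt

Run-length encoded FM-index of haplotype paths over variation graphs, in R.

A variation graph represents a population's genetic variation as a labelled
bidirected graph; every haplotype is a path, but almost all graph paths are
*recombinations* no genome contains. `graphbwt` implements the **Graph BWT
(GBWT)**: an FM-index of a path collection, sorted by reverse-prefix keys
and partitioned into per-node records with run-length encoded bodies, so
that large repetitive haplotype collections compress well and all the
standard FM-index machinery applies. On top of the index it implements
**haplotype-aware graph simplification**: pruned regions of the graph are
restored by *unfolding* the haplotype-supported paths through them, with
node duplication and an id translation map, so that aggressive pruning
loses no haplotype k-mer.

The package is for people building or analysing pangenome/variation-graph
references: it provides the index (construction, merging, removal,
`find`/`locate`/`extract`, bidirectional search), haplotype path generation
from a reference FASTA plus a phased VCF (with overlap resolution and phase
breaks), GFA1 input/output, the unfolding algorithm, a synthetic fixture
generator and a brute-force oracle used as ground truth in the tests.

## The core structure

Paths are strings over oriented nodes (forward node *n* encodes to 2*n*,
reverse to 2*n*+1, 0 is the end-marker `$`). The occurrence of node *v* at
offset *i* of path *j* sorts by its reversed prefix
`(v, P[i-1], ..., P[0], $_j)` with distinct end-markers `$_0 < $_1 < ...`.
The BWT — the successor of each occurrence in sorted order — is stored per
node as a record:

* header: the local alphabet (successors in use) with cumulative ranks
  `rank(v, w)` = occurrences of *w* in all records before *v*;
* body: run-length encoded successor sequence.

The positional LF-mapping
`LF((v, i), w) = (w, rank(v, w) + rank_body(i, w))` drives `find` (pattern
counting), `locate` (path identifiers, via sampled positions every *d*
on-path offsets, default 1024, plus path ends), `extract` (path recovery
from the end-marker record) and FMD-style bidirectional search (both path
orientations are indexed by default).

## Worked example

The five-node exemplar graph (labels G, A, T, GGG, C; a bubble 2/3 between
nodes 1 and 4) carries three haplotype paths: `1 2 4 5`, `1 3 4 5`,
`1 2 4 5`.

```r
library(graphbwt)
f1  <- fixture_f1()
idx <- gbwt_build(f1$paths)
idx
#> GBWT index: 6 sequence(s) (both orientations), 10 node record(s), 20 run(s), total length 30
#> sample interval d = 1024 (12 sampled position(s))

s <- gbwt_find(idx, node_encode(c(1, 2, 4)))   # subpath 1 -> 2 -> 4
state_size(s)
#> [1] 2                     # two haplotypes take the '2' allele
gbwt_locate(idx, s)
#> [1] 0 4                   # sequences 0 and 4 = paths 0 and 2 (forward)
write_paths(list(gbwt_extract(idx, 2)))
#> [1] "1 3 4 5"             # sequence 2 is path 1, recovered exactly

gbwt_record(idx, node_encode(1))$runs
#>   code successor length
#> 1    0         4      1  # successors of node 1 in sorted occurrence
#> 2    1         6      1  # order: nodes 2, 3, 2 (run-length encoded)
#> 3    0         4      1
```

Sequence ids double-count orientations: sequence `2j` is path `j`, `2j+1`
its reverse. Deleting the bubble (nodes 2 and 3) and simplifying restores
both alleles as duplicated nodes, never the unobserved recombinations:

```r
pruned <- bd_graph(f1$graph$labels[c("1", "4", "5")],
                   rbind(node_encode(c(4, 5))))
sim <- simplify(f1$graph, idx, pruned = pruned)
sim$mapping$map
#> 6 7
#> 2 3                       # new nodes 6 and 7 duplicate originals 2 and 3
path_embeddable(sim$graph, sim$mapping, f1$paths[[2]])
#> [1] TRUE
```

A phased cohort is indexed end to end with
`gbwt_index_vcf(ref.fa, cohort.vcf)`; see the methods vignette
(`vignettes/graphbwt-methods.Rmd`) for the model, the overlap-resolution
policies and all parameter defaults.

## Command line

A thin CLI over the same functions is installed as `exec/graphbwt`:

```sh
Rscript exec/graphbwt simulate --seed 7 --out-gfa sim.gfa --out-paths sim.txt
Rscript exec/graphbwt build --paths sim.txt --out sim.gbwt
Rscript exec/graphbwt stats --index sim.gbwt
Rscript exec/graphbwt query --index sim.gbwt find 1 2
```

Subcommands: `build`, `query`, `stats`, `merge [--fast]`, `remove`,
`gfa-validate`, `gfa-convert`, `construct`, `index-vcf`, `simplify`,
`simulate`.

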