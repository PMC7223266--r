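---
title: "The Graph BWT: indexing haplotype paths in variation graphs"
author: "graphbwt"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The Graph BWT: indexing haplotype paths in variation graphs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(graphbwt)
```

## The problem

A variation graph collapses a population of haplotypes into nodes (labelled
with DNA) and edges. Every haplotype is a path in the graph, but almost all
paths are *recombinations* — switches between haplotypes that no sampled
genome contains. Two consequences follow. First, to use haplotype
information (for read mapping, imputation or population queries) one needs a
compressed, searchable index of the haplotype paths themselves. Second, when
a graph is simplified for k-mer indexing by pruning complex regions, the
pruning should preserve the k-mers of real haplotypes while discarding
recombinant ones.

`graphbwt` addresses both: the **Graph BWT (GBWT)**, a run-length encoded
FM-index of paths over a bidirected graph, and a **haplotype-aware
unfolding** algorithm that restores pruned haplotype paths by duplicating
nodes.

## The index

### Oriented nodes and the sort order

A bidirected graph is simulated as a directed graph over *oriented nodes*:
the forward orientation of graph id $n$ is the integer $2n$, the reverse is
$2n + 1$, and $0$ is the end-marker \$. This keeps node values a dense
integer range, gives a total order with \$ smallest, and makes
`reverse(v) = v xor 1` an involution. Edge sets are closed under the
bidirected symmetry $(u, v) \Leftrightarrow (\bar v, \bar u)$.

Paths $P_0, \dots, P_{m-1}$ are treated as strings over the node alphabet.
The index is an FM-index of the *reverse* strings: each occurrence of node
$v$ at offset $i$ of path $j$ is sorted by its reversed prefix key

$$(v,\; P_j[i-1],\; \dots,\; P_j[0],\; \$_j),$$

with distinct end-markers $\$_j < \$_{j+1}$, so equal reverse prefixes of
different paths break ties by path id. Sorting reverse prefixes (rather
than suffixes) makes the LF-mapping traverse edges in path direction, and
makes the end-marker record ordered by path id — which is what lets
`gbwt_extract(index, j)` start at offset $j$ of the end-marker record and
walk forward.

### Records

Rather than one global BWT string, the BWT is partitioned into one *record*
per node. The record of $v$ has

* a **header**: the local alphabet $\Sigma_v$ (successors of $v$ used by at
  least one indexed path, plus \$ when a path ends at $v$), each with its
  cumulative rank — the number of occurrences of that successor in all
  records of smaller node value; the classical C array is recoverable from
  these ranks;
* a **body**: the successor sequence of $v$'s occurrences in sorted order,
  run-length encoded as (local code, length) pairs.

Positions are (node, offset) pairs and the positional LF-mapping is

$$\mathrm{LF}((v, i), w) = (w,\; \mathrm{rank}(v, w) + \mathrm{rank}_{B_v}(i, w)),$$

with the first term read from the header and the second by scanning runs.
`find` extends patterns with LF on range endpoints; `locate` walks LF until
a sampled position; `extract` walks from the end-marker record. Because
haplotype collections are repetitive, run-length encoding keeps record
bodies small: indexing $m$ copies of the same path yields bodies whose run
counts do not depend on $m$.

Correctness does **not** depend on the graph being acyclic, topologically
sorted, or densely numbered — those are only performance assumptions, and
the test fixtures deliberately violate them (cyclic graphs, sparse ids,
paths revisiting nodes).

### Bidirectional search

By default every path is indexed together with its reverse path (sequence
$2j$ is $P_j$, $2j+1$ is $\bar P_j$), which turns the GBWT into an
FMD-style index. A bidirectional state keeps the range of the pattern and
the range of its reverse path; extending on one side updates the other
side's range by partitioning the extending record's range by successor —
occurrences followed by \$ first, then by the reverse of the successor.
Both ranges always have the same size.

### Identifier sampling

`locate` needs path identifiers. Storing one per position is wasteful, so
the index samples: every on-path offset divisible by the interval $d$, plus
every final position, maps to its path id. A locate walk therefore
terminates within the path's remainder and needs at most $d$ steps to hit a
sample once past the last sampled offset. The default $d = 1024$ follows
the configuration used for thousand-genome-scale cohorts; small fixtures
simply sample each path's endpoints. The direct algorithm advances one
position at a time; the fast algorithm advances whole ranges one run per
step — both return the same multiset, and locate deliberately returns a
*multiset* (one id per occurrence); de-duplication is the caller's concern.

### Construction, merging, removal

Construction inserts paths incrementally into a dynamic index (the BCR
family of multi-string BWT algorithms): the new path's end-marker appends
to the end-marker record, and each following symbol is inserted at the
LF-image of the previous insertion point, rebuilding the touched record.
Records are small (local alphabets are small, bodies bounded by the
haplotype count), so per-update rebuilds are cheap. Paths inside a batch
are inserted one at a time; only the post-state is contracted, and the
result is structurally identical for any batch partition. A construction
buffer (default capacity $10^8$ nodes) groups paths before insertion.

`gbwt_merge(a, b)` re-inserts `b`'s paths after `a`'s — the contract is
structural equality with a single build over the concatenated path list,
and the implementation is free to achieve it either by rank interleaving or
re-insertion. `gbwt_merge_fast` handles the disjoint-node case (different
chromosomes) structurally: records are reused as-is, end-marker bodies
concatenated, cumulative ranks and samples recomputed. `gbwt_remove`
rebuilds over the surviving paths, renumbering them consecutively in their
original order (the renumbering convention is ours; nothing downstream
depends on retired ids).

### Serialization

The on-disk format is a little-endian binary container: magic `GBWTR`, a
format version byte, the orientation encoding tag, flags, the sample
interval, length-prefixed integer vectors for records and samples, the
metadata table, and a trailing checksum. Writing is byte-deterministic;
reading verifies magic, version and checksum and rejects truncation.
Bit-compressed layouts (wavelet trees, memory-mapped structures) are out of
scope: the portable container favours transparency over final size.

## From phased VCF to haplotype paths

`construct_graph` splits each reference contig into backbone nodes at every
variant boundary and at `max_node_len` (default 32 bp, the current default
for graph construction at scale), strips the shared VCF anchor base, builds
one node chain per alternate allele, and turns pure deletions into bypass
edges. Symbolic and breakend alleles are skipped and counted.

`generate_haplotype_paths` threads a phased sample: reference nodes are
appended up to each site carrying an alternate allele, then the allele
path. When a site's reference interval overlaps what was already generated
(overlapping deletions are the common cause), resolution is attempted in a
fixed order: (1) skip allele-path nodes already emitted, (2) truncate
emitted *reference* trailing nodes back to the site start. If neither
applies, the policy decides: **phase-break** closes the fragment and starts
a new one with the allele path; **force-ref** keeps the reference allele.
An unphased heterozygous site is treated as a phase break on both
haplotypes (the assignment is ambiguous on both sides) under phase-break,
and as reference under force-ref; missing genotypes are reference. The
package also computes the expected haplotype *sequence* by direct string
substitution with the same policy (`haplotype_sequence`), giving an
independent check that concatenated node labels spell the intended
haplotype.

Parsed information can be written to a plain-text *staging bundle*
(reference layout, per-site allele paths, and per-batch run-length encoded
phasing, default 200 samples per batch) so that index construction can be
repeated or distributed without re-reading the VCF; any subset of batch
files is independently readable.

## Haplotype-aware simplification

### Pruning

`prune` makes the usual k-mer pruning heuristic precise: an edge is removed
when the *best* window through it still makes more than `max_choices` edge
choices (default 3 choices in a `k` = 24-base window). Traversing an edge
counts as a choice when its source has out-degree ≥ 2 or its target
in-degree ≥ 2; forced edges (sole outgoing and sole incoming) are never
removed. A window is a walk of at least `k` bases through the edge, or an
inextensible walk when the graph ends earlier — so short linear chains are
never pruned. The minimum is computed by dynamic programming over
(oriented node, remaining bases); dead-ended walk enumeration restricts to
node-simple continuations in cyclic regions, a deterministic
under-approximation that can only keep more edges. Afterwards, weakly
connected components with less than `min_component_bp` (default 33) bases
of sequence are deleted, and reference paths optionally restored. The
unfolding below works with *any* pruning that removes nodes or edges, not
just this heuristic, and the tests exercise it with random removals.

### Complement components and maximal paths

Let $G_i$ be the graph induced by the indexed paths and $G_p$ the pruned
graph. The complement edge set $E_i \setminus E_p$ decomposes into weakly
connected components; each component's *border* consists of its nodes that
still exist in $G_p$, the rest are *internal*. Within a component, the
GBWT is searched for every haplotype-supported *maximal path*: searches
start from each oriented border node with the full record range, and from
each oriented internal node with the start-of-path range; a path of length
≥ 2 stops when it reaches the border (and is output when it also started
there) or when no extension is supported (a dead end, always output). A
haplotype fragment that starts inside a component and runs to the border is
captured as the dead end of its reverse orientation, which is why both
orientations must be indexed here. Dead-end paths are extended along the
smallest-named reference path carrying their endpoint, within the
component, until a border node is met; every output is canonicalized to the
lexicographically smaller of itself and its reverse path and de-duplicated.

### Unfolding

Re-inserting each maximal path with entirely fresh duplicates would create
many indistinguishable same-label predecessors, which k-mer index
construction handles badly. Instead each path is split into a prefix of
length $\lceil |P|/2 \rceil$ and the remaining suffix; a trie of prefixes
and a trie of reversed suffixes are built, and every trie edge becomes one
node of the unfolded component: border nodes at trie depth 1 are reused
from the pruned graph, all other trie edges become fresh duplicate ids
(allocated from max original id + 1, deterministically by component order
and trie preorder) whose forward orientation spells what the oriented
original spelled. Trie adjacency becomes edges in path direction, and one
cross edge per maximal path joins its prefix end to its suffix start. A
border-to-border path of length 2 degenerates to restoring the edge, with
no duplicates.

The translation map sends duplicate ids back to signed original ids;
`translate` composes orientations and is a graph homomorphism onto the
original graph that commutes with path reversal. Two guarantees are tested
throughout: **completeness** — every indexed haplotype path embeds in the
simplified graph under translation (hence every haplotype k-mer is
spelled), and **tightness** — the translated border-to-border routes of an
unfolded component are exactly its maximal path set, so no recombinant is
created *inside* a component. Recombinations that switch at border nodes,
or span several components, remain representable; that is inherent to any
graph model and out of the method's scope.

## The synthetic fixture generator

`gen_fixture` emulates the features that matter for index correctness:
bubble-chain graphs (biallelic sites), short random labels, optional
cycles, founder haplotypes with recombination switches, duplicate paths,
sub-walks and single-node paths, and optionally sparse ids. With
recombination rate 0 every generated path is an exact founder copy. What it
does **not** emulate: realistic coalescent genealogies, mutation spectra,
linkage structure, or genome-scale coordinates — so passing tests show
structural correctness of the index and algorithms on small graphs, not
biological realism or performance at cohort scale. The fixed exemplar
(`fixture_f1`) is a five-node bubble with three paths whose records are
small enough to verify by hand.

The companion brute-force oracle (`naive_gbwt`) re-derives every structure
from first principles: it enumerates all occurrences, sorts them by the
reversed-prefix key with a padded key matrix and radix order, and partitions
them into record views. The test suite compares the compiled index against
the oracle record-by-record on hundreds of seeded fixtures, and all query
results against direct subpath scans.

## Numerical and design choices

* **Tie-breaks.** All order decisions reduce to the distinct end-markers;
  there are no floating-point comparisons anywhere in the index.
* **Degenerate inputs.** Empty path lists build a valid empty index (all
  queries empty); empty patterns and empty paths are rejected as errors;
  single-node paths get an end-marker successor; empty search states
  propagate (empty in, empty out).
* **Problem sizes.** The suite runs 200 seeded fixtures (≤ 40 graph ids,
  ≤ 30 paths, path length ≤ 60) for record/query equivalence, 50 each for
  merge, batching and unfolding, 100 for serialization, a 1 kb / 20-variant
  / 10-sample synthetic cohort for haplotype threading, and m up to 1000
  identical copies for the compression property.
* **Known limitations.** Single-threaded construction only (the contract is
  the post-state, so parallel batch building can be layered on later);
  merge and removal are implemented by re-insertion/rebuild rather than
  rank-array interleaving — equivalent output, different constants; no
  bit-compressed serialization; the VCF parser supports 1–2 phases per
  sample (diploid with haploid regions), not arbitrary ploidy; reference
  extension of dead-end paths is skipped when the endpoint lies on no
  reference path.
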