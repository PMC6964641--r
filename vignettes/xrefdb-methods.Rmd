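---
title: "Building and querying a cross-reference database: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building and querying a cross-reference database: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xrefdb)
```

## The problem

Genomic analyses constantly hop between identifier namespaces: a microarray
probe set id must become a transcript, the transcript a gene, the gene a set
of GO annotations; a species name must become a taxonomy id whose genome's
genes link to curated protein records. `xrefdb` builds a single uniform
key-value database over heterogeneous dataset files (taxonomy XML, GFF3
genomes, UniProt-style XML, HGNC-style JSON, GO/probe-set TSV, literature
CSV) and answers *chain mapping queries* over it: expressions like

```
map(transcript).map(ensembl).map(go).filter(go.type=="molecular_function")
```

that walk the cross-reference graph dataset to dataset, pruning with
attribute filters at any hop. Search keys are identifiers *and* special
keywords — gene symbols and species names — so `"homo sapiens"` resolves to
the taxonomy entry `9606` just as the id itself would.

## The build model: a single-node map/reduce

Dataset files are large and periodically replaced, and after a build the
workload is read-only. The build is therefore organized as a two-phase
external sort:

* **Map phase.** Each file is read as a stream (gzip detected by magic
  bytes and decompressed on the fly), with bounded memory: delimited and
  JSON-lines formats are processed in line blocks, XML record-element by
  record-element, single-document JSON through an event scanner that
  decodes one record object at a time. Every entry record expands into
  (canonical key, payload) pairs — the entry itself keyed by `(dataset,
  identifier)`, plus one reference payload per search term (identifier and
  keywords). Pairs accumulate in a buffer; when the buffer fills, it is
  sorted, same-key payloads are pre-merged, and the result is spilled as a
  sorted chunk file. Whenever `fan_in` chunks of the same merge generation
  exist, they are merged into one chunk of the next generation; with
  `workers > 1`, ready merge groups run on forked workers. Output never
  depends on scheduling: group membership is fixed by spill order, and the
  merge itself is order-canonical (below).

* **Reduce phase.** The surviving sorted runs are globally merged by a
  patience-style k-way tournament: a binary min-heap over the run heads,
  O(log k) per record, with a linear scan-minimum implementation kept as an
  internal cross-check (the two must produce identical streams; ties
  between runs break on run index so they do). The strictly ascending
  (key, value) stream is batch-inserted into the store in one sequential
  pass, which is the access pattern ordered page-structured stores ingest
  fastest.

### Determinism and merge semantics

Builds are reproducible to the byte: the same registry and inputs give an
identical store data file for *any* buffer size, fan-in or worker count.
That property dictates the merge semantics:

* Cross-reference sets merge as a **set union stored in canonical
  (target, id) order**. A first-seen order would leak the partition into
  the output, so it was rejected.
* **List attributes** (e.g. protein `names`) keep first-seen element order
  — `names[1]` must remain the primary name — and union away duplicates.
  List attributes come from a single source record in practice, so this
  never conflicts with reproducibility.
* **Scalar attribute conflicts** resolve last-writer-wins in stream order.
  A real entry's scalar attributes are a function of the entry, so
  conflicts indicate dirty inputs; resolution is deterministic for a fixed
  partition, and the reproducibility guarantee is stated for conflict-free
  inputs.
* Payload lists under one key are sorted by (dataset id, identifier);
  attribute names are sorted in the encoding. The wire encoding itself is a
  self-describing escaped text format in which the same payload always
  yields the same bytes.

## The store

The store is an embedded ordered key-value engine of the package's own: a
single sorted plain-text data file (one `key TAB value` line per key, in
C-locale byte order, which for UTF-8 equals code-point order) plus a JSON
metadata file carrying the format version, entry count and a snapshot of
the dataset registry. Reads load a sorted key table with a hash index:
exact lookup is O(1), prefix search an ordered scan, iteration ascending.
The engine sits behind the same narrow surface (`batch_insert`, `lookup`,
`prefix_search`, `store_dump`) that any ordered B+-tree engine would
implement, so a memory-mapped engine can be slotted in without touching the
pipeline; the flat-file engine keeps the package dependency-free and its
dumps trivially diffable.

Two keyspaces share the file, multiplexed by a one-byte prefix: term keys
(`T`) map a normalized search term to the list of `(dataset, identifier)`
references it indexes; entry keys (`E`) map `(dataset id, identifier)` to
the merged full payload. The term index stays small and an entry fetch is a
single exact lookup.

**Key normalization.** Search keys are case-insensitive: uppercased,
trimmed, internal whitespace collapsed. The original identifier case is
preserved inside payloads and in all results. Normalization is idempotent,
and the one-byte keyspace prefix plus the 0x1f separator cannot collide
with user terms because normalization never emits control characters.

## The query language

A query is a chain of steps: `map(target)` follows cross-references whose
label equals `target` (a dataset name, or a relation label such as
`taxchild`, which resolves in the taxonomy dataset) and replaces the
frontier with the referenced entries, deduplicated and ordered by
identifier; `filter(expr)` prunes the frontier with a boolean expression
over the *active* dataset's attributes. The grammar permits a filter only
immediately after a map, and a filter's attribute prefixes must name that
map's active dataset — source-side filtering is expressible by first
mapping to the source dataset itself.

Filter semantics, fixed points worth stating:

* `ds.within(a, b)` is shorthand for `ds.start > a && ds.end < b` — strict
  at **both** ends. Coordinates are 1-based inclusive, the GFF3 convention
  of the genome files ingested.
* `contains` is a case-sensitive substring match; `==`/`!=` on strings are
  exact and case-sensitive.
* A bare attribute (`uniprot.reviewed`) is true iff present and true.
* A missing attribute makes any comparison false — never an error — so
  heterogeneous frontiers filter cleanly. An *ordered* comparison against a
  quoted string literal is a type error and reported as such.
* Numeric literals compare numerically, coercing character attributes when
  possible; multi-valued attributes match if any element does.

`taxchild` maps to **direct** children per hop; consecutive `map(taxchild)`
steps compose, and a transitive-closure flag (`taxchild_transitive`,
default off, cycle-safe) covers the "all descendants" reading. Result rows
are grouped by input term with mapped identifiers ascending; attribute
selectors (`attrs = "strand,start,end"`, `names[1]` with 1-based indexing)
append columns, with `-`/`NA` marking misses. Paging uses an opaque
continuation token; concatenated pages equal the unpaged result exactly.

The same functionality is exposed as a CLI (`build` / `query` / `web`
verbs, exit codes 0/1/2) and a minimal JSON web service (`GET /ws/search`,
`GET /ws/map?i=<terms>&m=<query>&s=<source>`). The HTTP layer is a
deliberately small single-threaded server over a socket connection; the
request handler is transport-agnostic and is what the test suite exercises,
asserting that CLI, HTTP and library calls return identical rows.

## The synthetic universe and the oracle

No fixed external release can back a test suite, so the package generates
its own universe: a taxonomy tree of configurable depth and branching;
species with genes (coordinates uniform over synthetic chromosomes `1`,
`2`, `X`; descriptions drawn from a small vocabulary that includes
filterable tokens), transcripts, probe sets, proteins with Bernoulli
reviewed flags, GO terms typed uniformly over the three namespaces,
nomenclature symbols and literature ids. Defaults (6 species × 30 genes ×
2 transcripts, 60 GO terms, reviewed probability 0.7) give a ~1,400-node,
~4,300-edge graph — large enough to exercise every dataset format, edge
label and filter type, small enough that a full build-and-query round trip
takes seconds. Generation is seed-deterministic to the byte and leaves the
session RNG untouched.

The generator returns both the emitted files and the ground-truth graph;
ingesting the files reproduces the graph exactly (a test asserts node,
edge and keyword equality). Queries are validated against a brute-force
oracle that walks the graph's adjacency lists with an independently written
filter evaluator — it shares the parser (the grammar is the public
contract) but none of the chunk, store or execution code.

What the universe does *not* emulate: ontology DAG structure (GO terms are
flat), sequence content, realistic genome sizes or coordinate clustering,
multi-mapping probes across genes, or dirty real-world records (malformed
lines are tested separately and synthetically). Passing the oracle
therefore certifies the mapping machinery, not robustness to every
real-world file quirk.

A second, hand-written fixture encodes three end-to-end worked examples —
probe→transcript→gene→GO with a namespace filter; species keyword→genes in
an X-chromosome window→reviewed proteins; taxon→children→genes near the
origin with a description word — together with decoy records sitting
exactly on each filter boundary (a gene starting at the window edge, an
unreviewed protein, an off-chromosome gene, a grandchild taxon). The
expected identifier sets are fixed constants of the fixture; every decoy
must be excluded.

## Parameters, defaults, and numerical choices

| parameter | default | why |
|---|---|---|
| `buffer_size` | 100,000 records | ~tens of MB of buffered pairs; spill cost amortized |
| `fan_in` | 8 | merge depth log₈(runs); higher costs open files, lower costs passes |
| `workers` | 1 | merging parallelizes per group; output independent of the count |
| malformed-record threshold | 1% | skip-and-count, fail loudly on systematic breakage |
| `page_size` | 200 | interactive-scale pages |
| reviewed probability | 0.7 | curated fraction of a mixed protein set |
| value size cap | 16 MiB | a larger single key almost always means a mis-specified ingest |

Degenerate inputs are first-class: empty buffers refuse to spill, an empty
chunk list merges to an empty stream, a zero-gene universe builds a valid
store, unknown terms return zero rows rather than errors, and out-of-order
batch inserts abort the build with an ordering error naming the keys.

## Problem sizes used by the test suite

The suite validates the pipeline at the largest sizes that keep a full run
comfortable on a single core: 10,000-payload encode/decode round trips;
50,000-record spills against an in-memory reference; a 100,000-record
multiset built under buffer sizes {10, 10³, 10⁵}, fan-in {2, 8} and worker
counts {1, 4} with byte-identical stores required; a 1,000,000-record
delimited stream ingested under a 10,000-record buffer with the peak
buffer counter asserted; and 500 random chain queries checked against the
brute-force oracle. `scripts/acceptance.R` re-runs the same computations at
script scale and reports the resulting numbers.

## Known limitations

* The store engine loads its key table into memory on open; it is sized
  for the fixture-scale universes this package targets, not for full
  public releases. The interface, not the engine, is the contract.
* Rebuilds replace the store; there are no in-place incremental updates,
  matching the periodic-release model of the upstream resources.
* XML streaming assumes record elements start on a new line, which holds
  for the major public XML dumps and for all fixtures.
* The query language offers no joins across independent term lists and no
  projection beyond attribute selectors.
* `within` binds to the entry's `start`/`end` attributes only; there is no
  general interval algebra over arbitrary attribute pairs.
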