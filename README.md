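# xrefdb

Build and query a uniform cross-reference database of bioinformatics
identifiers and special keywords.

Genomic pipelines constantly translate between identifier namespaces —
microarray probe ids to transcripts, transcripts to genes, genes to GO
annotations, species names to taxonomy ids to genomes to curated protein
records. `xrefdb` turns heterogeneous dataset files (taxonomy XML, Ensembl-
style GFF3, UniProt-style XML, HGNC-style JSON, GO and probe-set TSV,
literature CSV, each optionally gzip-compressed) into one embedded ordered
key-value store, then answers *chain mapping queries* that hop the
cross-reference graph with filters at any step:

```
map(ds1).filter(ds1.attr == value).map(ds2).filter(ds2.within(a,b)). ...
```

Keys are identifiers **and** special keywords (gene symbols, species
names), case-insensitive: `"homo sapiens"` finds taxonomy entry `9606`.

## How it works

The build is a single-node map/reduce over streams:

* **map** — every file is ingested as a stream with bounded memory; each
  record expands into (canonical key, payload) pairs which are buffered,
  sorted, and spilled as sorted chunk files; chunks merge recursively
  (fan-in configurable, optionally on forked workers) while ingestion
  continues;
* **reduce** — the sorted runs are globally merged with a patience-style
  k-way tournament (min-heap over run heads) into a strictly ascending
  stream that is batch-inserted into the store in one sequential pass.

Builds are byte-reproducible: the same inputs give an identical store data
file for any buffer size, fan-in or worker count. Filters support
`== != < <= > >= && ||`, case-sensitive `contains("...")`, boolean
attributes, and the genomic-range shorthand `within(a,b)` ≡
`start > a && end < b` (strict at both ends; coordinates 1-based
inclusive). Results come back as paged tables of
`input, input_dataset, mapping_id` plus any selected attributes
(`attrs = "strand,start,end"`, `names[1]`).

The package also ships a deterministic synthetic-universe generator with a
ground-truth graph and a brute-force query oracle (the test suite's
independent reference), a CLI (`inst/cli/xrefdb` with `build`, `query` and
`web` verbs), and a minimal JSON web service (`GET /ws/search`,
`GET /ws/map?i=<terms>&m=<query>`).

## Worked example

The bundled worked-example fixture encodes, among others, this mapping: all
taxonomic children of taxon `59201`, mapped to genes near the start of
their genomes whose description mentions the secreted effector SopD —
with decoy records (a gene starting exactly at position 10000, a gene
without the word, a grandchild taxon) that the filters must exclude.

```r
library(xrefdb)

pc <- worked_example_fixture()                                    # writes the fixture files
st <- build_db(build_config(pc$sources, out_dir = tempfile()))

execute_mapping(st, "59201",
  'map(taxchild).map(ensembl).filter(ensembl.start<10000&&ensembl.description.contains("SopD"))',
  attrs = "strand,start,end")
#>   input input_dataset    mapping_id strand start   end
#> 1 59201      taxonomy   ACH54_23895      +  2525  3484
#> 2     -             -   ACH56_04205      -    27   986
#> 3     -             -   AEW14_05145      -  3410  4369
#> 4     -             -   AEW14_15935      -     1    89
#> 5     -             -    DE27_21250      +  8885  9967
#> 6     -             -    DE87_06330      +  7839  8921
#> 7     -             - LPMST02_21800      +  8983 10065
```

Each row is one mapped gene: its identifier, then the selected `strand`,
`start`, `end` attributes; the input term prints once per group. One
`map(taxchild)` hop reaches *direct* children only (the grandchild decoy's
genes are absent); `start<10000` is strict, so the boundary decoy at 10000
is excluded too. The same fixture answers a probe→transcript→gene→GO chain
(14 and 7 molecular-function GO terms for its two probe ids) and a
species-keyword→X-window→reviewed-protein chain (9 accessions with their
primary protein names).

For synthetic data at scale:

```r
u  <- generate_universe(universe_params(seed = 1))   # files + ground-truth graph
st <- build_db(build_config(u$sources, out_dir = tempfile()))
execute_mapping(st, "ENSG00000001", "map(transcript).map(affy_hg_u133_plus_2)")
oracle_map(u$graph, "ENSG00000001", "map(transcript).map(affy_hg_u133_plus_2)")  # brute-force reference
```

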