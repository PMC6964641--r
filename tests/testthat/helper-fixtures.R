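# Shared test fixtures: built once per test run and reused across files.

.fixture_cache <- new.env(parent = emptyenv())

# A compact synthetic universe plus its built store.
test_universe <- function() {
  if (is.null(.fixture_cache$universe)) {
    u <- generate_universe(
      universe_params(seed = 101L, species_count = 3L, genes_per_species = 8L),
      dir = file.path(tempdir(), "xr-test-universe"))
    store <- build_db(build_config(u$sources,
                                   out_dir = file.path(tempdir(), "xr-test-store"),
                                   buffer_size = 500L, fan_in = 4L))
    .fixture_cache$universe <- list(u = u, store = store)
  }
  .fixture_cache$universe
}

# The worked-example fixture plus its built store.
test_worked_examples <- function() {
  if (is.null(.fixture_cache$workedex)) {
    pc <- worked_example_fixture(dir = file.path(tempdir(), "xr-test-workedex"))
    store <- build_db(build_config(pc$sources,
                                   out_dir = file.path(tempdir(), "xr-test-workedex-store")))
    .fixture_cache$workedex <- list(pc = pc, store = store)
  }
  .fixture_cache$workedex
}

# Minimal two-dataset registry for delimited-format unit tests.
tiny_registry <- function() {
  xr_registry(list(
    list(name = "chebi", format = "tsv", spec = list(
      header = FALSE, id_col = 1L,
      attrs = list(name = list(col = 2L, type = "s")),
      xrefs = list(list(col = 3L, target = "kegg", forward = TRUE,
                        strip_prefix = "^KEGG:")),
      keywords = integer())),
    list(name = "kegg", format = "tsv", spec = NULL),
    list(name = "taxonomy", format = "xml", spec = NULL)
  ), relations = c(taxchild = "taxonomy"))
}

# Random payloads for round-trip and merge tests. Strings draw from a pool
# that includes every reserved wire character.
random_string <- function(n_chars = 8L) {
  pool <- c(letters, LETTERS, 0:9, ":", "_", "-", " ", "\\", "\t", "\x1c",
            "\x1d", "\x1e", "\x1f", "=", ",", ";")
  paste(sample(pool, n_chars, replace = TRUE), collapse = "")
}

random_payload <- function() {
  attrs <- list()
  if (runif(1) < 0.8) attrs$name <- random_string()
  if (runif(1) < 0.5) attrs$start <- sample.int(1e6, 1) + 0
  if (runif(1) < 0.3) attrs$reviewed <- runif(1) < 0.5
  if (runif(1) < 0.3) attrs$names <- replicate(sample(2:4, 1), random_string())
  nx <- sample(0:3, 1)
  xrefs <- list(target = sample(c("go", "kegg", "ensembl"), nx, replace = TRUE),
                id = replicate(nx, random_string()))
  if (nx == 0L) xrefs <- list(target = character(), id = character())
  new_payload(sample.int(50L, 1L), gsub("^\\s+|\\s+$", "x", random_string()),
              attrs, xrefs)
}

# In-memory reference for sorted-chunk and merge behaviour: sort all keys,
# merge payload groups per key — no chunk, heap or store code involved.
reference_merge <- function(keys, payloads) {
  o <- order(keys, method = "radix")
  keys <- keys[o]; payloads <- payloads[o]
  groups <- split(seq_along(keys), factor(keys, levels = unique(keys)))
  list(keys = unique(keys),
       values = vapply(groups, function(idx)
         encode_payload_list(merge_payloads(payloads[idx])), "", USE.NAMES = FALSE))
}

stream_table <- function(stream) {
  items <- collect_stream(stream, decode = FALSE)
  list(keys = vapply(items, `[[`, "", "key"),
       values = vapply(items, `[[`, "", "value"))
}

term_key_vec <- function(ids) paste0("T\x1f", toupper(ids))

# Random multiset of records over a bounded key space. Scalar attributes
# are a pure function of the identifier (as a real entry's attributes are),
# so merges are conflict-free; cross-references vary per record and merge
# as a set union.
random_kv <- function(n, key_space = n %/% 2L) {
  nums <- sample.int(key_space, n, replace = TRUE)
  ids <- sprintf("ID%06d", nums)
  ds <- (nums %% 5L) + 1L
  payloads <- lapply(seq_len(n), function(i)
    new_payload(ds[i], ids[i],
                attrs = list(v = (nums[i] * 7L) %% 1000L + 0),
                xrefs = list(target = "go", id = sprintf("GO:%07d", sample.int(50L, 1L)))))
  list(keys = term_key_vec(ids), payloads = payloads)
}

# Canonical (input, mapping_id) row-set signature for result comparison.
row_set <- function(df) sort(paste(df$input, df$mapping_id, sep = "\x01"))

# Random valid chain queries over the synthetic universe's schema.
random_query_text <- function(registry) {
  datasets <- c(registry$datasets$name, names(registry$relations))
  n_steps <- sample(1:4, 1L)
  steps <- character()
  for (s in seq_len(n_steps)) {
    target <- sample(datasets, 1L)
    active <- resolve_map_target(registry, target)
    steps <- c(steps, sprintf("map(%s)", target))
    if (runif(1) < 0.5) {
      f <- random_filter_text(active)
      if (!is.null(f)) steps <- c(steps, sprintf("filter(%s)", f))
    }
  }
  paste(steps, collapse = ".")
}

random_filter_text <- function(active) {
  preds <- switch(active,
    ensembl = c(
      sprintf("ensembl.start%s%d", sample(c("<", "<=", ">", ">="), 1L),
              sample.int(1e6, 1L)),
      sprintf('ensembl.seq_region=="%s"', sample(c("1", "2", "X"), 1L)),
      sprintf('ensembl.description.contains("%s")',
              sample(c("Sop", "kinase", "membrane", "putative"), 1L)),
      sprintf("ensembl.within(%d,%d)", sample.int(5e5, 1L),
              5e5 + sample.int(5e5, 1L))),
    transcript = sprintf("transcript.end%s%d", sample(c("<", ">"), 1L),
                         sample.int(1e6, 1L)),
    uniprot = c("uniprot.reviewed",
                'uniprot.names.contains("Protein")'),
    go = c(sprintf('go.type=="%s"',
                   sample(c("molecular_function", "biological_process",
                            "cellular_component"), 1L)),
           'go.name.contains("activity")'),
    taxonomy = c(sprintf('taxonomy.rank!="%s"', sample(c("clade", "species"), 1L)),
                 'taxonomy.scientific_name.contains("Genus")'),
    hgnc = 'hgnc.symbol.contains("GN")',
    literature = 'literature.doi.contains("10.")',
    NULL)
  if (is.null(preds)) return(NULL)
  p1 <- sample(preds, 1L)
  if (length(preds) > 1L && runif(1) < 0.3) {
    p2 <- sample(preds, 1L)
    op <- sample(c(" && ", " || "), 1L)
    paste0(p1, op, p2)
  } else p1
}

# Terms worth querying: identifiers, keywords, and guaranteed misses.
random_terms <- function(graph, n = 2L) {
  ids <- vapply(graph$nodes, `[[`, "", "identifier", USE.NAMES = FALSE)
  kws <- unlist(lapply(graph$nodes, `[[`, "keywords"), use.names = FALSE)
  pool <- c(ids, kws, "NOPE12345", "missing term")
  paste(sample(pool, n), collapse = ",")
}
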