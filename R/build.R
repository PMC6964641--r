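# The end-to-end build: ingest every selected dataset as a stream, expand
# records into (key, payload) pairs, spill sorted chunks as the buffer
# fills, merge chunks recursively while ingestion continues, then globally
# merge and batch-insert into a fresh store.

#' Expand an entry record into its (canonical key, payload) pairs
#'
#' One record contributes: its merged full payload under its entry key, and
#' a reference payload under the term key of its identifier and of each of
#' its keywords — identifiers and special keywords such as gene names or
#' species names all become search keys.
#'
#' @param record An `xref_record`.
#' @param registry An `xref_registry`.
#' @return List of `list(key =, payload =)` pairs.
#' @export
record_kv_pairs <- function(record, registry) {
  dsid <- registry_id(registry, record$dataset)
  norm_id <- normalize_keys(record$identifier)
  full <- new_payload(dsid, record$identifier, record$attrs, record$xrefs)
  ref <- ref_payload(dsid, record$identifier)
  pairs <- list(
    list(key = entry_key(dsid, norm_id), payload = full),
    list(key = term_key(norm_id), payload = ref)
  )
  for (kw in unique(record$keywords)) {
    nk <- normalize_keys(kw)
    if (!nzchar(nk)) next
    pairs[[length(pairs) + 1L]] <- list(key = term_key(nk), payload = ref)
  }
  pairs
}

#' Build configuration
#'
#' @param sources Named list: dataset name -> character vector of input
#'   file paths (plain or gzip). Every named dataset must be registered.
#' @param out_dir Output directory for the store.
#' @param registry Dataset registry.
#' @param taxonomy_ids Optional character vector of taxonomy identifiers;
#'   when given, only entries belonging to (or cross-reference-linked to)
#'   those taxa are ingested.
#' @param buffer_size Records buffered before a chunk spill.
#' @param fan_in Chunks per recursive merge (>= 2).
#' @param workers Worker processes for concurrent chunk merges.
#' @param verbose Log per-stage counters.
#' @return A `build_config` list.
#' @export
build_config <- function(sources, out_dir, registry = default_registry(),
                         taxonomy_ids = NULL, buffer_size = 100000L,
                         fan_in = 8L, workers = 1L, verbose = FALSE) {
  if (length(sources) == 0L || is.null(names(sources)) || any(!nzchar(names(sources)))) {
    xr_abort("xrefdb_config_error", "sources must be a non-empty named list of dataset paths")
  }
  for (ds in names(sources)) registry_id(registry, ds)
  if (fan_in < 2L) xr_abort("xrefdb_config_error", "fan_in must be >= 2")
  if (buffer_size < 1L) xr_abort("xrefdb_config_error", "buffer_size must be >= 1")
  structure(list(sources = sources, out_dir = out_dir, registry = registry,
                 taxonomy_ids = as.character(taxonomy_ids),
                 buffer_size = as.integer(buffer_size),
                 fan_in = as.integer(fan_in), workers = as.integer(workers),
                 verbose = isTRUE(verbose)),
            class = "build_config")
}

# Taxon-restricted builds keep records that carry evidence of membership:
# the taxon itself, a parent with a child edge into the restriction set, or
# any record cross-referencing one of the restricted taxa.
keep_under_taxa <- function(record, taxa) {
  if (length(taxa) == 0L) return(TRUE)
  if (record$dataset == "taxonomy") {
    return(record$identifier %in% taxa ||
             any(record$xrefs$target == "taxchild" & record$xrefs$id %in% taxa))
  }
  any(record$xrefs$target == "taxonomy" & record$xrefs$id %in% taxa)
}

#' Build a store from dataset files
#'
#' Runs the full pipeline: streaming ingest of every configured dataset,
#' spill of sorted chunk files whenever the record buffer fills, recursive
#' background-style chunk merging, a global k-way merge, and ordered batch
#' insert into the store. Deterministic: the same registry and inputs give
#' a byte-identical store data file for any buffer size, fan-in or worker
#' count.
#'
#' @param config A [build_config()].
#' @return A read-mode `xref_store`; build counters are attached as
#'   `attr(store, "build_stats")` (wrapped in the handle environment).
#' @export
build_db <- function(config) {
  if (!inherits(config, "build_config")) xr_abort("xrefdb_config_error", "not a build_config")
  registry <- config$registry
  chunk_dir <- tempfile("xrchunks-")
  dir.create(chunk_dir)
  on.exit(unlink(chunk_dir, recursive = TRUE), add = TRUE)
  pool <- chunk_pool(chunk_dir, fan_in = config$fan_in, workers = config$workers)

  cap <- max(1024L, min(config$buffer_size, 1000000L))
  buf_keys <- character(cap)
  buf_payloads <- vector("list", cap)
  bn <- 0L
  spills <- 0L
  flush <- function() {
    if (bn == 0L) return(invisible())
    pool$add(spill_chunk(list(keys = buf_keys[seq_len(bn)],
                              payloads = buf_payloads[seq_len(bn)]),
                         dir = chunk_dir))
    spills <<- spills + 1L
    bn <<- 0L
  }
  add_pair <- function(key, payload) {
    bn <<- bn + 1L
    if (bn > length(buf_keys)) {
      buf_keys <<- c(buf_keys, character(length(buf_keys)))
      buf_payloads <<- c(buf_payloads, vector("list", length(buf_payloads)))
    }
    buf_keys[bn] <<- key
    buf_payloads[[bn]] <<- payload
    if (bn >= config$buffer_size) flush()
  }

  stage_stats <- list()
  kept <- 0L; dropped_taxa <- 0L
  for (ds in names(config$sources)) {
    for (path in config$sources[[ds]]) {
      res <- ingest_dataset(path, ds, registry, emit = function(rec) {
        if (!keep_under_taxa(rec, config$taxonomy_ids)) {
          dropped_taxa <<- dropped_taxa + 1L
          return(invisible())
        }
        kept <<- kept + 1L
        for (pair in record_kv_pairs(rec, registry)) add_pair(pair$key, pair$payload)
      })
      stage_stats[[paste(ds, basename(path), sep = ":")]] <- res$stats
      if (config$verbose) {
        message(sprintf("[ingest] %s %s: %d records (%d skipped, %d derived)",
                        ds, basename(path), res$stats$records_emitted,
                        res$stats$records_skipped, res$stats$derived_records))
      }
    }
  }
  flush()
  chunks <- pool$finish()
  if (config$verbose) {
    message(sprintf("[map] %d spills, %d merges, %d final runs",
                    spills, pool$merges, length(chunks)))
  }
  store <- store_create(config$out_dir, registry)
  batch_insert(store, global_merge(chunks))
  store <- store_finalize(store)
  if (config$verbose) {
    message(sprintf("[reduce] %d keys inserted", store$entry_count))
  }
  store$build_stats <- list(ingest = stage_stats, records_kept = kept,
                            records_dropped_by_taxa = dropped_taxa,
                            chunks_spilled = spills, chunk_merges = pool$merges,
                            keys_inserted = store$entry_count)
  store
}
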