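# The reduce-phase sink and query-time source: an embedded ordered
# key-value store. Data live in a single sorted plain-text data file
# (key <TAB> canonical encoded value, ascending C-locale key order) plus a
# JSON metadata file; reads go through an in-memory sorted key table with a
# hash index for exact lookup and ordered scans for prefix search. Build
# mode is append-only and strictly ordered, which is what makes batch
# insert of the globally merged stream a single sequential pass.

STORE_DATA <- "data.xr"
STORE_META <- "meta.json"
STORE_VERSION <- 1L

#' Create a store in build mode
#'
#' @param dir Directory for the store files (created if missing).
#' @param registry The dataset registry; a snapshot is persisted in the
#'   store metadata so a reader never needs the build-side config.
#' @return An `xref_store` handle in build mode.
#' @export
store_create <- function(dir, registry = default_registry()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) xr_abort("xrefdb_io_error", sprintf("cannot create %s", dir))
  store <- new.env(parent = emptyenv())
  store$dir <- dir
  store$mode <- "build"
  store$registry <- registry
  store$entry_count <- 0L
  store$prev_key <- NULL
  store$con <- file(file.path(dir, STORE_DATA), "wt")
  store$buf <- character(8192L)
  store$bn <- 0L
  class(store) <- "xref_store"
  store
}

#' @export
print.xref_store <- function(x, ...) {
  cat(sprintf("<xref_store %s: %s mode, %d keys>\n", x$dir, x$mode, x$entry_count))
  invisible(x)
}

stopifnot_mode <- function(store, mode) {
  if (!inherits(store, "xref_store")) xr_abort("xrefdb_state_error", "not a store handle")
  if (!identical(store$mode, mode)) {
    xr_abort("xrefdb_state_error",
             sprintf("store is in %s mode; %s mode required", store$mode, mode))
  }
}

flush_store_buf <- function(store) {
  if (store$bn > 0L) {
    writeLines(store$buf[seq_len(store$bn)], store$con)
    store$bn <- 0L
  }
}

#' Batch-insert a strictly ascending (key, value) stream
#'
#' The stream is the [global_merge()] iterator (or anything with the same
#' `nxt()` contract). Keys must arrive in strictly ascending canonical
#' order; a violation aborts the build with an ordering error, mirroring
#' how an ordered tree ingests pre-sorted runs as sequential page appends.
#'
#' @param store A build-mode `xref_store`.
#' @param stream Iterator yielding `list(key, value)` or `NULL`.
#' @return The store handle, invisibly.
#' @export
batch_insert <- function(store, stream) {
  stopifnot_mode(store, "build")
  repeat {
    item <- stream$nxt()
    if (is.null(item)) break
    if (!is.null(store$prev_key) && !key_lt(store$prev_key, item$key)) {
      close(store$con); store$mode <- "aborted"
      xr_abort("xrefdb_ordering",
               sprintf("batch insert key out of order: %s after %s",
                       item$key, store$prev_key))
    }
    store$prev_key <- item$key
    store$entry_count <- store$entry_count + 1L
    store$bn <- store$bn + 1L
    store$buf[store$bn] <- paste0(item$key, "\t", item$value)
    if (store$bn == length(store$buf)) flush_store_buf(store)
  }
  if (!is.null(stream$close)) stream$close()
  invisible(store)
}

#' Finalize a build-mode store and switch it to read mode
#'
#' Writes the metadata file (format version, entry count, dataset registry
#' snapshot, build timestamp) and reopens the store for reading.
#'
#' @param store A build-mode `xref_store`.
#' @return A read-mode `xref_store` handle.
#' @export
store_finalize <- function(store) {
  stopifnot_mode(store, "build")
  flush_store_buf(store)
  close(store$con)
  reg <- store$registry
  meta <- list(
    format_version = STORE_VERSION,
    entry_count = store$entry_count,
    datasets = reg$datasets,
    relations = as.list(reg$relations),
    built = format(Sys.time(), tz = "UTC", usetz = TRUE)
  )
  jsonlite::write_json(meta, file.path(store$dir, STORE_META),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  store$mode <- "closed"
  store_open(store$dir)
}

#' Open a store for reading
#'
#' @param dir Store directory produced by [store_finalize()].
#' @return A read-mode `xref_store` handle.
#' @export
store_open <- function(dir) {
  meta_path <- file.path(dir, STORE_META)
  data_path <- file.path(dir, STORE_DATA)
  if (!file.exists(meta_path) || !file.exists(data_path)) {
    xr_abort("xrefdb_state_error", sprintf("%s is not a finalized store", dir))
  }
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  lines <- readLines(data_path)
  tabs <- regexpr("\t", lines, fixed = TRUE)
  store <- new.env(parent = emptyenv())
  store$dir <- dir
  store$mode <- "read"
  store$keys <- substr(lines, 1L, tabs - 1L)
  store$values <- substring(lines, tabs + 1L)
  store$entry_count <- length(store$keys)
  store$index <- if (length(store$keys)) {
    list2env(stats::setNames(as.list(seq_along(store$keys)), store$keys),
             hash = TRUE, size = max(29L, length(store$keys)))
  } else new.env(parent = emptyenv())
  store$datasets <- as.data.frame(meta$datasets, stringsAsFactors = FALSE)
  store$relations <- unlist(meta$relations)
  store$registry <- structure(
    list(datasets = store$datasets, specs = list(), relations = store$relations),
    class = "xref_registry")
  class(store) <- "xref_store"
  store
}

store_get <- function(store, key) {
  i <- store$index[[key]]
  if (is.null(i)) NULL else store$values[i]
}

# Fetch the merged full payload of one entry by (dataset id, identifier).
fetch_entry <- function(store, dataset_id, identifier) {
  v <- store_get(store, entry_key(dataset_id, normalize_keys(identifier)))
  if (is.null(v)) NULL else decode_payload_list(v)[[1L]]
}

#' Look up a term (identifier or special keyword)
#'
#' The term is normalized and resolved through the term keyspace to the
#' entries it indexes; each reference is then fetched from the entry
#' keyspace. A species name like `"homo sapiens"` therefore resolves to its
#' taxonomy record exactly as the numeric identifier does.
#'
#' @param store A read-mode `xref_store`.
#' @param term Identifier or keyword (case-insensitive).
#' @param source Optional dataset name restricting the hits.
#' @return List of `xref_payload` (empty if the term is unknown).
#' @export
store_lookup <- function(store, term, source = NULL) {
  stopifnot_mode(store, "read")
  key <- term_key(normalize_key(term))
  v <- store_get(store, key)
  if (is.null(v)) return(list())
  refs <- decode_payload_list(v)
  if (!is.null(source)) {
    sid <- registry_id(store$registry, source)
    refs <- Filter(function(p) p$dataset_id == sid, refs)
  }
  out <- lapply(refs, function(p) fetch_entry(store, p$dataset_id, p$identifier))
  out[!vapply(out, is.null, TRUE)]
}

encode_page_token <- function(key, offset) {
  jsonlite::base64_enc(charToRaw(paste0(key, "\x1f", offset)))
}

decode_page_token <- function(token) {
  parts <- tryCatch(
    strsplit(rawToChar(jsonlite::base64_dec(token)), "\x1f", fixed = TRUE)[[1L]],
    error = function(e) NULL)
  if (is.null(parts) || length(parts) != 2L ||
      is.na(suppressWarnings(as.integer(parts[2L])))) {
    xr_abort("xrefdb_token_error", "invalid continuation token")
  }
  list(key = parts[1L], offset = as.integer(parts[2L]))
}

#' Prefix search over the term keyspace
#'
#' Returns `(key, dataset, identifier)` hits for every term key starting
#' with the normalized prefix, in ascending key order, paged. Concatenating
#' pages until the token is absent yields the full result exactly once.
#'
#' @param store A read-mode `xref_store`.
#' @param prefix Search prefix (normalized like any term).
#' @param page_size Maximum hits per page (>= 1).
#' @param token Continuation token from a previous page, or `NULL`.
#' @return `list(items = data.frame(key, dataset, identifier), next_token)`;
#'   `next_token` is `NULL` on the last page.
#' @export
prefix_search <- function(store, prefix, page_size = 200L, token = NULL) {
  stopifnot_mode(store, "read")
  if (page_size < 1L) xr_abort("xrefdb_config_error", "page_size must be >= 1")
  p <- term_key(normalize_key(prefix))
  hit <- startsWith(store$keys, p)
  idx <- which(hit)
  items <- list()
  after <- NULL
  if (!is.null(token)) after <- decode_page_token(token)
  rows_key <- character(); rows_ds <- character(); rows_id <- character(); rows_off <- integer()
  for (i in idx) {
    k <- strip_term_key(store$keys[i])
    refs <- decode_payload_list(store$values[i])
    for (j in seq_along(refs)) {
      rows_key <- c(rows_key, k)
      rows_ds <- c(rows_ds, registry_name(store$registry, refs[[j]]$dataset_id))
      rows_id <- c(rows_id, refs[[j]]$identifier)
      rows_off <- c(rows_off, j)
    }
  }
  if (!is.null(after)) {
    keep <- mapply(function(k, o) key_lt(after$key, k) ||
                     (k == after$key && o > after$offset),
                   rows_key, rows_off)
    keep <- as.logical(keep)
    rows_key <- rows_key[keep]; rows_ds <- rows_ds[keep]
    rows_id <- rows_id[keep]; rows_off <- rows_off[keep]
  }
  n <- length(rows_key)
  take <- min(page_size, n)
  sel <- seq_len(take)
  next_token <- if (n > take) {
    encode_page_token(rows_key[take], rows_off[take])
  } else NULL
  list(
    items = data.frame(key = rows_key[sel], dataset = rows_ds[sel],
                       identifier = rows_id[sel], stringsAsFactors = FALSE),
    next_token = next_token
  )
}

#' Dump every (key, value) line of a store's data file
#'
#' Primarily for reproducibility checks: two builds from the same registry
#' and inputs must dump byte-identically.
#' @param store A read-mode `xref_store`.
#' @return Character vector of `key<TAB>value` lines in ascending key order.
#' @export
store_dump <- function(store) {
  stopifnot_mode(store, "read")
  readLines(file.path(store$dir, STORE_DATA))
}
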