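# Streaming format adapters. Each adapter reads a (possibly gzip-compressed)
# file as a stream of line blocks, emits one EntryRecord per data record via
# a sink callback, and never materializes the whole input. Malformed records
# are skipped and counted; a build fails only when the malformed fraction
# exceeds the configured threshold.

XR_INGEST_BLOCK <- 10000L
XR_MAX_BAD_FRAC <- 0.01

#' Construct an entry record
#'
#' The atom of ingestion: one dataset entry with its original-case
#' identifier, attributes, cross-references and any extra keywords (gene
#' symbols, species names) that should also index it. Genomic coordinates,
#' when present, are 1-based inclusive and must satisfy `1 <= start <= end`;
#' strand must be `"+"` or `"-"`.
#'
#' @param identifier Non-empty original-case identifier.
#' @param dataset Registered dataset name.
#' @param attrs Named list of atomic attribute vectors.
#' @param xrefs `list(target =, id =)` parallel character vectors.
#' @param keywords Character vector of additional index terms.
#' @return An object of class `xref_record`.
#' @export
new_record <- function(identifier, dataset, attrs = list(), xrefs = NULL,
                       keywords = character()) {
  if (!is.character(identifier) || length(identifier) != 1L || !nzchar(identifier)) {
    xr_abort("xrefdb_invalid_record", "identifier must be a non-empty string")
  }
  if (!is.null(attrs$start) || !is.null(attrs$end)) {
    s <- attrs$start; e <- attrs$end
    if (is.null(s) || is.null(e) || !is.numeric(s) || !is.numeric(e) ||
        s < 1 || s > e) {
      xr_abort("xrefdb_invalid_record",
               sprintf("entry %s: coordinates must satisfy 1 <= start <= end", identifier))
    }
  }
  if (!is.null(attrs$strand) && !attrs$strand %in% c("+", "-")) {
    xr_abort("xrefdb_invalid_record", sprintf("entry %s: strand must be + or -", identifier))
  }
  if (is.null(xrefs)) xrefs <- list(target = character(), id = character())
  structure(list(identifier = identifier, dataset = dataset, attrs = attrs,
                 xrefs = xrefs, keywords = keywords),
            class = "xref_record")
}

#' @export
print.xref_record <- function(x, ...) {
  cat(sprintf("<record %s/%s; %d attrs, %d xrefs, %d keywords>\n",
              x$dataset, x$identifier, length(x$attrs),
              length(x$xrefs$target), length(x$keywords)))
  invisible(x)
}

# Open a path as a text-mode connection, transparently decompressing gzip
# (detected by the 1f 8b magic bytes, not the file extension).
open_stream <- function(path) {
  if (!file.exists(path)) xr_abort("xrefdb_io_error", sprintf("cannot read %s", path))
  con <- file(path, "rb")
  magic <- readBin(con, "raw", n = 2L)
  close(con)
  gz <- length(magic) == 2L && magic[1L] == as.raw(0x1f) && magic[2L] == as.raw(0x8b)
  if (gz) gzfile(path, "rt") else file(path, "rt")
}

# Collect-or-forward sink shared by the adapters.
make_sink <- function(emit) {
  records <- NULL
  n <- 0L
  if (is.null(emit)) {
    records <- vector("list", 256L)
    emit_fn <- function(rec) {
      n <<- n + 1L
      if (n > length(records)) length(records) <<- 2L * n
      records[[n]] <<- rec
    }
  } else {
    emit_fn <- function(rec) { n <<- n + 1L; emit(rec) }
  }
  list(emit = emit_fn,
       result = function() if (is.null(emit)) records[seq_len(n)] else NULL,
       count = function() n)
}

new_stats <- function() {
  list(records_emitted = 0L, records_skipped = 0L, derived_records = 0L,
       bytes_consumed = 0, peak_buffered_records = 0L)
}

check_bad_fraction <- function(stats, max_bad_frac, what) {
  total <- stats$records_emitted + stats$records_skipped
  if (total > 0L && stats$records_skipped / total > max_bad_frac) {
    xr_abort("xrefdb_format_error",
             sprintf("%s: %d of %d records malformed (threshold %.2f%%)",
                     what, stats$records_skipped, total, 100 * max_bad_frac))
  }
  stats
}

ingest_result <- function(sink, stats) {
  list(records = sink$result(), stats = stats)
}

typed_value <- function(raw, type) {
  switch(type,
    s = raw,
    n = { v <- suppressWarnings(as.numeric(raw)); if (any(is.na(v))) NULL else v },
    b = { v <- tolower(raw) %in% c("true", "1", "yes", "t")
          w <- tolower(raw) %in% c("true", "1", "yes", "t", "false", "0", "no", "f")
          if (!all(w)) NULL else v },
    raw
  )
}

# Derived reverse records: the captured value is the *target* of a forward
# edge; a reverse record re-keys it as an entry in the target's dataset with
# a cross-reference pointing back to the source record.
reverse_record <- function(target_id, target_dataset, back_label, source_id) {
  new_record(target_id, target_dataset,
             xrefs = list(target = back_label, id = source_id))
}

emit_with_reverses <- function(rec, reverses, sink, stats) {
  sink$emit(rec)
  stats$records_emitted <- stats$records_emitted + 1L
  for (rv in reverses) {
    sink$emit(rv)
    stats$derived_records <- stats$derived_records + 1L
  }
  stats
}

#' Ingest a delimited (TSV/CSV) stream
#'
#' Reads the stream in bounded blocks of lines and emits one record per data
#' line according to the column spec: `id_col` supplies the identifier,
#' `attrs` maps attribute names to `{col, type}` (types `s`/`n`/`b`),
#' `xrefs` maps columns to cross-reference targets (optionally `split` on a
#' separator, optionally emitting `reverse` records for the target dataset),
#' and `keywords` lists extra index columns. Gzip input is auto-detected.
#'
#' @param path File path (plain or gzip).
#' @param spec Column spec (see [default_registry()] for examples).
#' @param dataset Dataset name the records belong to.
#' @param registry An `xref_registry`.
#' @param emit Optional callback taking each `xref_record`; when `NULL`,
#'   records are collected and returned.
#' @param delim Field delimiter (tab for TSV; `","` for CSV).
#' @param block_size Lines per buffered block (the memory bound).
#' @param max_bad_frac Maximum tolerated fraction of malformed lines.
#' @return `list(records, stats)`; `stats` counts emitted, skipped and
#'   derived records, bytes consumed and the peak number of records buffered.
#' @export
ingest_tsv <- function(path, spec, dataset, registry = default_registry(),
                       emit = NULL, delim = "\t", block_size = XR_INGEST_BLOCK,
                       max_bad_frac = XR_MAX_BAD_FRAC) {
  con <- open_stream(path)
  on.exit(close(con), add = TRUE)
  sink <- make_sink(emit)
  stats <- new_stats()
  header_pending <- isTRUE(spec$header)
  xref_specs <- spec$xrefs
  for (xs in xref_specs) resolve_map_target(registry, xs$target)   # validate
  repeat {
    lines <- readLines(con, n = block_size)
    if (length(lines) == 0L) break
    stats$bytes_consumed <- stats$bytes_consumed + sum(nchar(lines, type = "bytes")) + length(lines)
    if (header_pending) { lines <- lines[-1L]; header_pending <- FALSE }
    lines <- lines[nzchar(lines)]
    if (length(lines) == 0L) next
    stats$peak_buffered_records <- max(stats$peak_buffered_records, length(lines))
    fields <- strsplit(lines, delim, fixed = TRUE)
    for (f in fields) {
      rec <- tsv_line_record(f, spec, dataset, registry)
      if (is.null(rec)) { stats$records_skipped <- stats$records_skipped + 1L; next }
      stats <- emit_with_reverses(rec$record, rec$reverses, sink, stats)
    }
  }
  stats <- check_bad_fraction(stats, max_bad_frac, path)
  ingest_result(sink, stats)
}

tsv_line_record <- function(f, spec, dataset, registry) {
  id <- if (spec$id_col <= length(f)) f[[spec$id_col]] else ""
  if (!nzchar(id)) return(NULL)
  attrs <- list()
  for (nm in names(spec$attrs)) {
    a <- spec$attrs[[nm]]
    if (a$col > length(f) || !nzchar(f[[a$col]])) next
    v <- typed_value(f[[a$col]], a$type %||% "s")
    if (is.null(v)) return(NULL)
    attrs[[nm]] <- v
  }
  xt <- character(); xi <- character(); reverses <- list()
  for (xs in spec$xrefs) {
    if (xs$col > length(f) || !nzchar(f[[xs$col]])) next
    vals <- f[[xs$col]]
    if (!is.null(xs$split)) vals <- strsplit(vals, xs$split, fixed = TRUE)[[1L]]
    vals <- vals[nzchar(vals)]
    if (!is.null(xs$strip_prefix)) vals <- sub(xs$strip_prefix, "", vals)
    if (isTRUE(xs$forward) || is.null(xs$forward)) {
      xt <- c(xt, rep(xs$target, length(vals))); xi <- c(xi, vals)
    }
    if (isTRUE(xs$reverse)) {
      rd <- resolve_map_target(registry, xs$target)
      lb <- xs$reverse_label %||% dataset
      for (v in vals) reverses[[length(reverses) + 1L]] <- reverse_record(v, rd, lb, id)
    }
  }
  keywords <- character()
  for (kc in spec$keywords) if (kc <= length(f) && nzchar(f[[kc]])) keywords <- c(keywords, f[[kc]])
  rec <- tryCatch(
    new_record(id, dataset, attrs, list(target = xt, id = xi), keywords),
    xrefdb_invalid_record = function(e) NULL
  )
  if (is.null(rec)) return(NULL)
  list(record = rec, reverses = reverses)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---------------------------------------------------------------------------

#' Ingest a JSON or JSON-lines stream
#'
#' JSON-lines input (`spec$lines = TRUE`) is parsed one record per line with
#' bounded memory. A single-document input is scanned incrementally with an
#' event state machine that locates the record array named by `spec$path`
#' (dotted key path) and decodes one record object at a time, so the whole
#' document is never held in memory. Record fields are addressed by dotted
#' paths; a record missing its identifier field is skipped and counted.
#'
#' @inheritParams ingest_tsv
#' @return `list(records, stats)` as for [ingest_tsv()].
#' @export
ingest_json <- function(path, spec, dataset, registry = default_registry(),
                        emit = NULL, block_size = XR_INGEST_BLOCK,
                        max_bad_frac = XR_MAX_BAD_FRAC) {
  con <- open_stream(path)
  on.exit(close(con), add = TRUE)
  sink <- make_sink(emit)
  stats <- new_stats()
  handle <- function(obj) {
    rec <- json_object_record(obj, spec, dataset, registry)
    if (is.null(rec)) stats$records_skipped <<- stats$records_skipped + 1L
    else stats <<- emit_with_reverses(rec$record, rec$reverses, sink, stats)
  }
  if (isTRUE(spec$lines)) {
    repeat {
      lines <- readLines(con, n = block_size)
      if (length(lines) == 0L) break
      stats$bytes_consumed <- stats$bytes_consumed + sum(nchar(lines, type = "bytes")) + length(lines)
      lines <- lines[nzchar(trimws(lines))]
      stats$peak_buffered_records <- max(stats$peak_buffered_records, length(lines))
      for (ln in lines) {
        obj <- tryCatch(jsonlite::fromJSON(ln, simplifyVector = TRUE),
                        error = function(e) NULL)
        if (is.null(obj)) stats$records_skipped <- stats$records_skipped + 1L
        else handle(obj)
      }
    }
  } else {
    stats$bytes_consumed <- json_scan_array(con, spec$path, handle)
    stats$peak_buffered_records <- max(stats$peak_buffered_records, 1L)
  }
  stats <- check_bad_fraction(stats, max_bad_frac, path)
  ingest_result(sink, stats)
}

json_field <- function(obj, path) {
  for (p in strsplit(path, ".", fixed = TRUE)[[1L]]) {
    if (!is.list(obj) || is.null(obj[[p]])) return(NULL)
    obj <- obj[[p]]
  }
  obj
}

json_object_record <- function(obj, spec, dataset, registry) {
  id <- json_field(obj, spec$id_field)
  if (is.null(id) || !nzchar(as.character(id)[1L])) return(NULL)
  id <- as.character(id)[1L]
  attrs <- list()
  for (nm in names(spec$attrs)) {
    a <- spec$attrs[[nm]]
    v <- json_field(obj, a$field)
    if (is.null(v)) next
    v <- typed_value(as.character(v), a$type %||% "s")
    if (is.null(v)) return(NULL)
    attrs[[nm]] <- v
  }
  xt <- character(); xi <- character(); reverses <- list()
  for (xs in spec$xrefs) {
    vals <- json_field(obj, xs$field)
    if (is.null(vals)) next
    vals <- as.character(unlist(vals))
    vals <- vals[nzchar(vals)]
    if (isTRUE(xs$forward) || is.null(xs$forward)) {
      xt <- c(xt, rep(xs$target, length(vals))); xi <- c(xi, vals)
    }
    if (isTRUE(xs$reverse)) {
      rd <- resolve_map_target(registry, xs$target)
      for (v in vals) reverses[[length(reverses) + 1L]] <- reverse_record(v, rd, xs$reverse_label %||% dataset, id)
    }
  }
  keywords <- character()
  for (kf in spec$keywords) {
    v <- json_field(obj, kf)
    if (!is.null(v)) keywords <- c(keywords, as.character(unlist(v)))
  }
  rec <- tryCatch(new_record(id, dataset, attrs, list(target = xt, id = xi), keywords),
                  xrefdb_invalid_record = function(e) NULL)
  if (is.null(rec)) return(NULL)
  list(record = rec, reverses = reverses)
}

# Incremental scan of a JSON document for the record array at `path`
# (dotted keys; NULL means the first array in the document). A small state
# machine tracks strings, escapes and the object-key stack; each element
# object of the target array is captured and decoded on its own, so memory
# is bounded by one record regardless of document size. Errors carry the
# byte offset of the offending character.
json_scan_array <- function(con, path, handle, chunk_bytes = 65536L) {
  want <- if (is.null(path)) NULL else strsplit(path, ".", fixed = TRUE)[[1L]]
  kinds <- character()           # "{" or "[" per open container
  stack <- character()           # object key under which each container opened
  in_string <- FALSE; escaped <- FALSE
  cur_string <- character(); capturing_key <- TRUE
  last_key <- NA_character_
  target_level <- NA_integer_    # container depth of the record array
  in_record <- FALSE; rec_depth <- 0L
  rec_chars <- character(4096L); rec_n <- 0L
  offset <- 0
  push_rec <- function(ch) {
    rec_n <<- rec_n + 1L
    if (rec_n > length(rec_chars)) rec_chars <<- c(rec_chars, character(length(rec_chars)))
    rec_chars[rec_n] <<- ch
  }
  repeat {
    lines <- readLines(con, n = max(1L, chunk_bytes %/% 256L))
    if (length(lines) == 0L) break
    chunk <- paste(lines, collapse = "\n")
    if (!nzchar(chunk)) { offset <- offset + length(lines); next }
    chars <- strsplit(chunk, "", fixed = TRUE)[[1L]]
    n <- length(chars)
    for (i in seq_len(n)) {
      ch <- chars[[i]]
      if (in_record) {
        push_rec(ch)
        if (in_string) {
          if (escaped) escaped <- FALSE
          else if (ch == "\\") escaped <- TRUE
          else if (ch == "\"") in_string <- FALSE
        } else if (ch == "\"") in_string <- TRUE
        else if (ch == "{" || ch == "[") rec_depth <- rec_depth + 1L
        else if (ch == "}" || ch == "]") {
          rec_depth <- rec_depth - 1L
          if (rec_depth == 0L) {
            txt <- paste(rec_chars[seq_len(rec_n)], collapse = "")
            obj <- tryCatch(jsonlite::fromJSON(txt, simplifyVector = TRUE),
                            error = function(e)
                              xr_abort("xrefdb_format_error",
                                       sprintf("invalid JSON record near byte %d: %s",
                                               offset + i, conditionMessage(e))))
            handle(obj)
            in_record <- FALSE; rec_n <- 0L
          }
        }
        next
      }
      if (in_string) {
        if (escaped) { cur_string <- c(cur_string, ch); escaped <- FALSE }
        else if (ch == "\\") escaped <- TRUE
        else if (ch == "\"") {
          in_string <- FALSE
          if (capturing_key) last_key <- paste(cur_string, collapse = "")
        } else cur_string <- c(cur_string, ch)
        next
      }
      if (ch == "\"") { in_string <- TRUE; cur_string <- character() }
      else if (ch == "{") {
        if (!is.na(target_level) && length(kinds) == target_level) {
          # element object directly inside the record array
          in_record <- TRUE; rec_depth <- 1L; rec_n <- 0L
          push_rec(ch)
        } else {
          kinds <- c(kinds, "{"); stack <- c(stack, last_key)
          last_key <- NA_character_; capturing_key <- TRUE
        }
      } else if (ch == "[") {
        kinds <- c(kinds, "["); stack <- c(stack, last_key)
        keys <- stack[!is.na(stack)]
        hit <- if (is.null(want)) TRUE else identical(unname(keys), want)
        if (is.na(target_level) && hit) target_level <- length(kinds)
        last_key <- NA_character_; capturing_key <- FALSE
      } else if (ch == "}" || ch == "]") {
        if (length(kinds) == 0L) {
          xr_abort("xrefdb_format_error",
                   sprintf("invalid JSON: unbalanced '%s' at byte %d", ch, offset + i))
        }
        if (!is.na(target_level) && length(kinds) == target_level) target_level <- NA_integer_
        kinds <- kinds[-length(kinds)]; stack <- stack[-length(stack)]
        capturing_key <- length(kinds) > 0L && kinds[length(kinds)] == "{"
      } else if (ch == ":") capturing_key <- FALSE
      else if (ch == ",") capturing_key <- length(kinds) > 0L && kinds[length(kinds)] == "{"
    }
    offset <- offset + n
  }
  if (length(kinds) != 0L || in_string || in_record) {
    xr_abort("xrefdb_format_error",
             sprintf("invalid JSON: unterminated document at byte %d", offset))
  }
  offset
}
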