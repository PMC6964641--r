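# The map phase: buffered (key, payload) pairs spill to sorted chunk files;
# chunk files merge recursively while ingestion continues; a final global
# patience merge (k-way tournament over sorted run heads) yields every key
# exactly once in ascending order.
#
# Chunk files are self-describing plain text:
#   line 1:  #xrchunk <TAB> 1 <TAB> record_count <TAB> min_key <TAB> max_key
#   then:    key <TAB> encoded-payload-list
# Keys never contain tabs or newlines (normalization collapses whitespace),
# and payload encodings escape them.

CHUNK_MAGIC <- "#xrchunk"

# Canonical key order is C-locale byte order, which for UTF-8 equals code
# point order. R's `<` on character follows the session collation locale,
# so ordered comparisons go through this instead.
key_lt <- function(a, b) {
  if (a == b) return(FALSE)
  ai <- utf8ToInt(a); bi <- utf8ToInt(b)
  n <- min(length(ai), length(bi))
  if (n > 0L) {
    d <- ai[seq_len(n)] != bi[seq_len(n)]
    w <- which.max(d)
    if (d[w]) return(ai[w] < bi[w])
  }
  length(ai) < length(bi)
}

chunk_file <- function(path, record_count, min_key, max_key, generation = 0L) {
  structure(list(path = path, record_count = record_count, min_key = min_key,
                 max_key = max_key, generation = generation),
            class = "xref_chunk")
}

#' @export
print.xref_chunk <- function(x, ...) {
  cat(sprintf("<chunk %s: %d records, gen %d, [%s .. %s]>\n",
              basename(x$path), x$record_count, x$generation, x$min_key, x$max_key))
  invisible(x)
}

write_chunk_file <- function(path, keys, values, generation) {
  n <- length(keys)
  header <- paste(CHUNK_MAGIC, "1", n, keys[1L], keys[n], sep = "\t")
  con <- file(path, "wt")
  ok <- FALSE
  on.exit({ close(con); if (!ok) unlink(path) }, add = TRUE)
  writeLines(c(header, paste(keys, values, sep = "\t")), con, sep = "\n")
  ok <- TRUE
  chunk_file(path, n, keys[1L], keys[n], generation)
}

read_chunk_meta <- function(path) {
  h <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1L]]
  if (length(h) < 5L || h[1L] != CHUNK_MAGIC || h[2L] != "1") {
    xr_abort("xrefdb_corruption", sprintf("%s is not a chunk file", path))
  }
  chunk_file(path, as.integer(h[3L]), h[4L], h[5L])
}

#' Sort and spill a buffer of (key, payload) pairs to a chunk file
#'
#' Pairs are sorted by canonical key; same-key payloads within the buffer
#' are pre-merged ([merge_payloads()]) so a chunk holds each key once, in
#' strictly ascending order. On write failure the partial file is removed.
#'
#' @param buffer A list of `list(key =, payload =)` pairs, or
#'   `list(keys = <character>, payloads = <list>)` parallel vectors.
#' @param dir Directory for the chunk file.
#' @param generation Merge depth recorded in the chunk (0 = fresh spill).
#' @return An `xref_chunk` descriptor.
#' @export
spill_chunk <- function(buffer, dir, generation = 0L) {
  if (is.list(buffer) && !is.null(buffer$keys)) {
    keys <- buffer$keys; payloads <- buffer$payloads
  } else {
    keys <- vapply(buffer, `[[`, "", "key")
    payloads <- lapply(buffer, `[[`, "payload")
  }
  if (length(keys) == 0L) xr_abort("xrefdb_empty_buffer", "cannot spill an empty buffer")
  o <- order(keys, method = "radix")
  keys <- keys[o]; payloads <- payloads[o]
  dup <- anyDuplicated(keys) > 0L
  if (dup) {
    groups <- split(seq_along(keys), factor(keys, levels = unique(keys)))
    keys <- unique(keys)
    values <- vapply(groups, function(idx)
      encode_payload_list(merge_payloads(payloads[idx])), "", USE.NAMES = FALSE)
  } else {
    values <- vapply(payloads, function(p)
      encode_payload_list(canonical_payloads(list(p))), "", USE.NAMES = FALSE)
  }
  path <- tempfile("chunk-", tmpdir = dir, fileext = ".xrc")
  write_chunk_file(path, keys, values, generation)
}

# Buffered sequential reader over a chunk file; verifies ascending key order
# as it goes and raises a corruption error naming the chunk otherwise.
chunk_reader <- function(chunk, block = 4096L) {
  con <- file(chunk$path, "rt")
  open_flag <- TRUE
  readLines(con, n = 1L)   # header
  keys <- character(); values <- character(); i <- 0L; nbuf <- 0L
  prev <- NULL
  fill <- function() {
    lines <- readLines(con, n = block)
    if (length(lines) == 0L) { keys <<- character(); nbuf <<- 0L; return(FALSE) }
    tabs <- regexpr("\t", lines, fixed = TRUE)
    keys <<- substr(lines, 1L, tabs - 1L)
    values <<- substring(lines, tabs + 1L)
    i <<- 0L; nbuf <<- length(lines)
    TRUE
  }
  list(
    nxt = function() {
      if (i >= nbuf && !fill()) return(NULL)
      i <<- i + 1L
      k <- keys[i]
      if (!is.null(prev) && !key_lt(prev, k)) {
        close(con); open_flag <<- FALSE
        xr_abort("xrefdb_corruption",
                 sprintf("chunk %s is not strictly sorted at key %s", chunk$path, k))
      }
      prev <<- k
      list(key = k, value = values[i])
    },
    close = function() {
      if (open_flag) { close(con); open_flag <<- FALSE }
    }
  )
}

# Tournament (binary min-heap) merge over the head records of k sorted runs:
# the merge stage of patience sort. method = "scan" uses a linear minimum
# scan instead; both must produce identical streams.
make_merge_stream <- function(chunks, method = c("heap", "scan")) {
  method <- match.arg(method)
  readers <- lapply(chunks, chunk_reader)
  k <- length(readers)
  hk <- character(k); hi <- integer(k); hn <- 0L
  # heap order: (key, run index) — the run-index tie-break makes equal keys
  # pop in run order, so merge output is identical to the scan method
  lt2 <- function(ka, ia, kb, ib) {
    if (ka == kb) ia < ib else key_lt(ka, kb)
  }
  heap_push <- function(key, idx) {
    hn <<- hn + 1L
    j <- hn; hk[j] <<- key; hi[j] <<- idx
    while (j > 1L) {
      p <- j %/% 2L
      if (lt2(hk[j], hi[j], hk[p], hi[p])) {
        tk <- hk[p]; hk[p] <<- hk[j]; hk[j] <<- tk
        ti <- hi[p]; hi[p] <<- hi[j]; hi[j] <<- ti
        j <- p
      } else break
    }
  }
  heap_pop <- function() {
    top <- list(key = hk[1L], idx = hi[1L])
    hk[1L] <<- hk[hn]; hi[1L] <<- hi[hn]; hn <<- hn - 1L
    j <- 1L
    repeat {
      l <- 2L * j; r <- l + 1L
      s <- j
      if (l <= hn && lt2(hk[l], hi[l], hk[s], hi[s])) s <- l
      if (r <= hn && lt2(hk[r], hi[r], hk[s], hi[s])) s <- r
      if (s == j) break
      tk <- hk[s]; hk[s] <<- hk[j]; hk[j] <<- tk
      ti <- hi[s]; hi[s] <<- hi[j]; hi[j] <<- ti
      j <- s
    }
    top
  }
  heads <- vector("list", k)
  for (j in seq_len(k)) {
    h <- readers[[j]]$nxt()
    if (!is.null(h)) { heads[[j]] <- h; if (method == "heap") heap_push(h$key, j) }
  }
  advance <- function(j) {
    h <- readers[[j]]$nxt()
    heads[j] <<- list(h)   # [[<-]] with NULL would delete the slot
    if (!is.null(h) && method == "heap") heap_push(h$key, j)
  }
  pick_min <- function() {
    # scan method: linear minimum over run heads
    best <- 0L
    for (j in seq_len(k)) {
      h <- heads[[j]]
      if (is.null(h)) next
      if (best == 0L || key_lt(h$key, heads[[best]]$key)) best <- j
    }
    best
  }
  nxt <- function() {
    if (method == "heap") {
      if (hn == 0L) return(NULL)
      top <- heap_pop()
      key <- top$key
      vals <- heads[[top$idx]]$value
      advance(top$idx)
      while (hn > 0L && hk[1L] == key) {
        t2 <- heap_pop()
        vals <- c(vals, heads[[t2$idx]]$value)
        advance(t2$idx)
      }
    } else {
      j <- pick_min()
      if (j == 0L) return(NULL)
      key <- heads[[j]]$key
      vals <- heads[[j]]$value
      advance(j)
      repeat {
        j <- 0L
        for (jj in seq_len(k)) {
          if (!is.null(heads[[jj]]) && heads[[jj]]$key == key) { j <- jj; break }
        }
        if (j == 0L) break
        vals <- c(vals, heads[[j]]$value)
        advance(j)
      }
    }
    if (length(vals) == 1L) {
      list(key = key, value = vals)   # already canonical from its chunk
    } else {
      merged <- merge_payloads(unlist(lapply(vals, decode_payload_list),
                                      recursive = FALSE))
      list(key = key, value = encode_payload_list(merged))
    }
  }
  list(nxt = nxt, close = function() for (r in readers) r$close())
}

#' Merge sorted chunk files into one
#'
#' Streaming k-way merge: memory is bounded by one buffered block per input
#' chunk. Keys appearing in several chunks have their payload lists merged
#' and deduplicated. Input chunk files are deleted on success.
#'
#' @param chunks List of `xref_chunk`.
#' @param dir Output directory (defaults to the first chunk's directory).
#' @param method `"heap"` (tournament merge) or `"scan"` (linear minimum
#'   scan); both give identical output.
#' @param delete_inputs Remove the merged input files.
#' @return An `xref_chunk` for the merged file.
#' @export
merge_chunks <- function(chunks, dir = dirname(chunks[[1L]]$path),
                         method = "heap", delete_inputs = TRUE) {
  if (length(chunks) == 0L) xr_abort("xrefdb_empty_buffer", "no chunks to merge")
  gen <- max(vapply(chunks, `[[`, 0L, "generation")) + 1L
  stream <- make_merge_stream(chunks, method)
  on.exit(stream$close(), add = TRUE)
  path <- tempfile("chunk-", tmpdir = dir, fileext = ".xrc")
  con <- file(path, "wt")
  ok <- FALSE
  on.exit({ close(con); if (!ok) unlink(path) }, add = TRUE)
  # header written last (record count unknown until done): buffer to temp body
  keys_min <- NULL; keys_max <- NULL; n <- 0L
  buf <- character(8192L); bn <- 0L
  body <- tempfile("chunkbody-", tmpdir = dir)
  bcon <- file(body, "wt")
  repeat {
    item <- stream$nxt()
    if (is.null(item)) break
    n <- n + 1L
    if (is.null(keys_min)) keys_min <- item$key
    keys_max <- item$key
    bn <- bn + 1L
    buf[bn] <- paste0(item$key, "\t", item$value)
    if (bn == length(buf)) { writeLines(buf, bcon); bn <- 0L }
  }
  if (bn > 0L) writeLines(buf[seq_len(bn)], bcon)
  close(bcon)
  if (n == 0L) {
    unlink(body)
    xr_abort("xrefdb_empty_buffer", "merge produced no records")
  }
  writeLines(paste(CHUNK_MAGIC, "1", n, keys_min, keys_max, sep = "\t"), con)
  bcon <- file(body, "rt")
  repeat {
    lines <- readLines(bcon, n = 8192L)
    if (length(lines) == 0L) break
    writeLines(lines, con)
  }
  close(bcon)
  unlink(body)
  ok <- TRUE
  if (delete_inputs) for (ch in chunks) unlink(ch$path)
  chunk_file(path, n, keys_min, keys_max, gen)
}

#' Globally merge sorted chunks into an ascending (key, payloads) stream
#'
#' The reduce-phase source: yields every distinct key exactly once, in
#' strictly ascending canonical order, with payload lists merged and
#' deduplicated across all chunks. Memory is proportional to the number of
#' chunks, not the number of records.
#'
#' @param chunks List of `xref_chunk`.
#' @param method Merge strategy, as in [merge_chunks()].
#' @return An iterator: `list(nxt = function(), close = function())` where
#'   `nxt()` returns `list(key, value)` (`value` is the canonical encoded
#'   payload list; [decode_payload_list()] recovers the payload objects) or
#'   `NULL` at end of stream.
#' @export
global_merge <- function(chunks, method = "heap") {
  if (length(chunks) == 0L) {
    return(list(nxt = function() NULL, close = function() invisible()))
  }
  make_merge_stream(chunks, method)
}

#' Drain a (key, value) iterator into a list (testing/inspection helper)
#' @param stream An iterator from [global_merge()].
#' @param decode Decode values into payload lists.
#' @export
collect_stream <- function(stream, decode = TRUE) {
  out <- list(); n <- 0L
  repeat {
    item <- stream$nxt()
    if (is.null(item)) break
    n <- n + 1L
    if (decode) item <- list(key = item$key, payloads = decode_payload_list(item$value))
    out[[n]] <- item
  }
  stream$close()
  out
}

# -- recursive background-style merge pool -----------------------------------

#' Create a chunk pool that merges spilled chunks recursively
#'
#' Freshly spilled chunks accumulate per generation; whenever `fan_in`
#' chunks share a generation they are merged into one chunk of the next
#' generation, bounding the fan-in of the final global merge. With
#' `workers > 1` ready merge groups run on forked workers; output is
#' identical for any worker count because group membership and order are
#' determined purely by spill order.
#'
#' @param dir Chunk directory.
#' @param fan_in Chunks per merge (>= 2).
#' @param workers Worker processes for concurrent merges.
#' @return An environment with `add(chunk)` and `finish()`.
#' @export
chunk_pool <- function(dir, fan_in = 8L, workers = 1L) {
  if (fan_in < 2L) xr_abort("xrefdb_config_error", "fan_in must be >= 2")
  pool <- new.env(parent = emptyenv())
  pool$gens <- list()   # generation (as character) -> list of chunks
  pool$merges <- 0L
  take_ready <- function() {
    ready <- list()
    repeat {
      found <- FALSE
      for (g in names(pool$gens)) {
        if (length(pool$gens[[g]]) >= fan_in) {
          grp <- pool$gens[[g]][seq_len(fan_in)]
          pool$gens[[g]] <- pool$gens[[g]][-seq_len(fan_in)]
          ready[[length(ready) + 1L]] <- grp
          found <- TRUE
        }
      }
      if (!found) break
    }
    ready
  }
  run_groups <- function(groups) {
    if (length(groups) == 0L) return(invisible())
    merged <- if (workers > 1L && length(groups) > 1L) {
      parallel::mclapply(groups, function(grp) merge_chunks(grp, dir = dir),
                         mc.cores = workers)
    } else {
      lapply(groups, function(grp) merge_chunks(grp, dir = dir))
    }
    for (m in merged) {
      if (inherits(m, "try-error")) {
        xr_abort("xrefdb_io_error", sprintf("chunk merge failed: %s", as.character(m)))
      }
    }
    pool$merges <- pool$merges + length(groups)
    for (ch in merged) add_chunk(ch)
  }
  add_chunk <- function(ch) {
    g <- as.character(ch$generation)
    pool$gens[[g]] <- c(pool$gens[[g]], list(ch))
  }
  pool$add <- function(ch) {
    add_chunk(ch)
    run_groups(take_ready())
    invisible()
  }
  pool$finish <- function() {
    # merge any leftover same-generation groups down to a single run list
    repeat {
      run_groups(take_ready())
      all_chunks <- unlist(pool$gens, recursive = FALSE, use.names = FALSE)
      if (length(all_chunks) <= fan_in) break
      # group leftovers across generations, oldest first, deterministically
      o <- order(vapply(all_chunks, `[[`, 0L, "generation"),
                 vapply(all_chunks, `[[`, "", "path"), method = "radix")
      all_chunks <- all_chunks[o]
      pool$gens <- list()
      groups <- split(all_chunks, (seq_along(all_chunks) - 1L) %/% fan_in)
      run_groups(unname(groups))
    }
    all_chunks <- unlist(pool$gens, recursive = FALSE, use.names = FALSE)
    o <- order(vapply(all_chunks, `[[`, 0L, "generation"),
               vapply(all_chunks, `[[`, "", "path"), method = "radix")
    all_chunks[o]
  }
  pool
}
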