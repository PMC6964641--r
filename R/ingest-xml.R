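# XML and GFF3 adapters. XML is processed record-at-a-time: the stream is
# scanned for the repeating record element, each element's text is parsed as
# a standalone document and released, so memory is bounded by one record.

#' Ingest an XML stream
#'
#' The spec names the repeating `record_element` and how to pull the
#' identifier, attributes, keywords and cross-references out of each record:
#' values come from child-element text (`path`, an XPath relative to the
#' record) or from attributes (`from = "attr"`). Cross-reference specs
#' support UniProt-style `<dbReference type="..." id="..."/>` elements
#' (`target_attr`/`id_attr`, with reverse records emitted for targets listed
#' in `reverse_targets`) and captured-attribute edges such as a taxonomy
#' node's `parent`, which emits only the reverse `taxchild` edge.
#' Records must start on a new line, as UniProt and NCBI dumps do.
#'
#' @inheritParams ingest_tsv
#' @return `list(records, stats)` as for [ingest_tsv()].
#' @export
ingest_xml <- function(path, spec, dataset, registry = default_registry(),
                       emit = NULL, block_size = XR_INGEST_BLOCK,
                       max_bad_frac = XR_MAX_BAD_FRAC) {
  con <- open_stream(path)
  on.exit(close(con), add = TRUE)
  sink <- make_sink(emit)
  stats <- new_stats()
  el <- spec$record_element
  open_re <- paste0("<", el, "([ \t>/]|$)")
  close_tag <- paste0("</", el, ">")
  acc <- character(); in_rec <- FALSE
  lineno <- 0L; rec_line <- 0L
  parse_one <- function(txt, at_line) {
    node <- tryCatch(xml2::read_xml(txt),
                     error = function(e)
                       xr_abort("xrefdb_format_error",
                                sprintf("%s: malformed XML near line %d: %s",
                                        path, at_line, conditionMessage(e))))
    rec <- xml_node_record(node, spec, dataset, registry)
    if (is.null(rec)) stats$records_skipped <<- stats$records_skipped + 1L
    else stats <<- emit_with_reverses(rec$record, rec$reverses, sink, stats)
  }
  repeat {
    lines <- readLines(con, n = block_size)
    if (length(lines) == 0L) break
    stats$bytes_consumed <- stats$bytes_consumed + sum(nchar(lines, type = "bytes")) + length(lines)
    for (ln in lines) {
      lineno <- lineno + 1L
      if (!in_rec) {
        if (grepl(open_re, ln)) {
          rec_line <- lineno
          if (grepl("/>[[:space:]]*$", ln) && !grepl(close_tag, ln, fixed = TRUE)) {
            parse_one(ln, lineno)
          } else if (grepl(close_tag, ln, fixed = TRUE)) {
            parse_one(ln, lineno)
          } else {
            acc <- ln; in_rec <- TRUE
          }
        }
      } else {
        acc <- c(acc, ln)
        if (grepl(close_tag, ln, fixed = TRUE)) {
          parse_one(paste(acc, collapse = "\n"), rec_line)
          acc <- character(); in_rec <- FALSE
        }
      }
    }
    stats$peak_buffered_records <- max(stats$peak_buffered_records, 1L)
  }
  if (in_rec) {
    xr_abort("xrefdb_format_error",
             sprintf("%s: unterminated <%s> element starting at line %d", path, el, rec_line))
  }
  stats <- check_bad_fraction(stats, max_bad_frac, path)
  ingest_result(sink, stats)
}

xml_value <- function(node, sp) {
  if (identical(sp$from, "attr") && is.null(sp$path)) {
    v <- xml2::xml_attr(node, sp$attr)
    if (is.na(v)) character() else v
  } else {
    found <- xml2::xml_find_all(node, sp$path)
    if (identical(sp$from, "attr")) {
      v <- xml2::xml_attr(found, sp$attr)
      v[!is.na(v)]
    } else {
      xml2::xml_text(found)
    }
  }
}

xml_node_record <- function(node, spec, dataset, registry) {
  id <- xml_value(node, spec$id)
  if (length(id) == 0L || !nzchar(id[1L])) return(NULL)
  id <- id[1L]
  attrs <- list()
  for (nm in names(spec$attrs)) {
    a <- spec$attrs[[nm]]
    v <- xml_value(node, a)
    if (length(v) == 0L) next
    if (!isTRUE(a$many)) v <- v[1L]
    v <- typed_value(v, a$type %||% "s")
    if (is.null(v)) return(NULL)
    attrs[[nm]] <- v
  }
  xt <- character(); xi <- character(); reverses <- list()
  for (xs in spec$xrefs) {
    if (!is.null(xs$target_attr)) {
      refs <- xml2::xml_find_all(node, xs$path)
      tg <- xml2::xml_attr(refs, xs$target_attr)
      ti <- xml2::xml_attr(refs, xs$id_attr)
      ok <- !is.na(tg) & !is.na(ti) & nzchar(ti)
      tg <- tg[ok]; ti <- ti[ok]
      if (!is.null(xs$target_map)) {
        mapped <- xs$target_map[tg]
        keep <- !is.na(mapped)
        tg <- unname(mapped[keep]); ti <- ti[keep]
      }
      known <- vapply(tg, function(t)
        !inherits(tryCatch(resolve_map_target(registry, t), error = identity), "error"),
        logical(1L))
      tg <- tg[known]; ti <- ti[known]
      xt <- c(xt, tg); xi <- c(xi, ti)
      rev_t <- intersect(unique(tg), xs$reverse_targets %||% character())
      for (t in rev_t) {
        rd <- resolve_map_target(registry, t)
        for (v in ti[tg == t]) {
          reverses[[length(reverses) + 1L]] <- reverse_record(v, rd, dataset, id)
        }
      }
    } else {
      vals <- xml_value(node, xs)
      vals <- vals[nzchar(vals)]
      if (length(vals) == 0L) next
      if (isTRUE(xs$forward)) {
        xt <- c(xt, rep(xs$target, length(vals))); xi <- c(xi, vals)
      }
      if (isTRUE(xs$reverse)) {
        rd <- resolve_map_target(registry, xs$target)
        lb <- xs$reverse_label %||% dataset
        for (v in vals) reverses[[length(reverses) + 1L]] <- reverse_record(v, rd, lb, id)
      }
    }
  }
  keywords <- character()
  for (ks in spec$keywords) keywords <- c(keywords, xml_value(node, ks))
  rec <- tryCatch(new_record(id, dataset, attrs, list(target = xt, id = xi),
                             keywords[nzchar(keywords)]),
                  xrefdb_invalid_record = function(e) NULL)
  if (is.null(rec)) return(NULL)
  list(record = rec, reverses = reverses)
}

# ---------------------------------------------------------------------------

gff3_attrs <- function(col9) {
  out <- list()
  for (kv in strsplit(col9, ";", fixed = TRUE)[[1L]]) {
    eq <- regexpr("=", kv, fixed = TRUE)
    if (eq < 0L) next
    key <- substr(kv, 1L, eq - 1L)
    val <- substring(kv, eq + 1L)
    if (grepl("%", val, fixed = TRUE)) {
      val <- tryCatch(utils::URLdecode(val), error = function(e) val)
    }
    out[[key]] <- val
  }
  out
}

#' Ingest a GFF3 stream (genes and transcripts)
#'
#' Gene features become entries of the gene dataset with attributes
#' `seq_region` (column 1), `start`/`end` (columns 4-5, 1-based inclusive),
#' `strand` (column 7) and `name`/`description` from column 9; `Name` also
#' indexes the gene as a keyword and `Ontology_term` values become GO
#' cross-references. Transcript features (`mRNA`/`transcript`/`*RNA`) become
#' entries of the transcript dataset; `Parent` links gene and transcript in
#' both directions. A `##species taxon:<id>` directive attaches a taxonomy
#' cross-reference to every feature and a reverse edge from the taxon to its
#' genes. Lines with non-numeric coordinates are skipped and counted.
#'
#' @inheritParams ingest_tsv
#' @param gene_dataset,transcript_dataset Dataset names for gene and
#'   transcript entries.
#' @return `list(records, stats)` as for [ingest_tsv()].
#' @export
ingest_gff3 <- function(path, registry = default_registry(), emit = NULL,
                        gene_dataset = "ensembl", transcript_dataset = "transcript",
                        block_size = XR_INGEST_BLOCK, max_bad_frac = XR_MAX_BAD_FRAC) {
  con <- open_stream(path)
  on.exit(close(con), add = TRUE)
  sink <- make_sink(emit)
  stats <- new_stats()
  taxid <- NA_character_
  tx_types <- c("mRNA", "transcript", "ncRNA", "tRNA", "rRNA")
  repeat {
    lines <- readLines(con, n = block_size)
    if (length(lines) == 0L) break
    stats$bytes_consumed <- stats$bytes_consumed + sum(nchar(lines, type = "bytes")) + length(lines)
    sp <- grep("^##species ", lines, value = TRUE)
    if (length(sp)) taxid <- sub("^##species +(taxon:)?", "", sp[length(sp)])
    lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
    if (length(lines) == 0L) next
    stats$peak_buffered_records <- max(stats$peak_buffered_records, length(lines))
    for (f in strsplit(lines, "\t", fixed = TRUE)) {
      if (length(f) < 9L) { stats$records_skipped <- stats$records_skipped + 1L; next }
      type <- f[[3L]]
      is_gene <- type == "gene"
      is_tx <- type %in% tx_types
      if (!is_gene && !is_tx) next    # other feature types are not ingested
      start <- suppressWarnings(as.numeric(f[[4L]]))
      end <- suppressWarnings(as.numeric(f[[5L]]))
      if (is.na(start) || is.na(end)) { stats$records_skipped <- stats$records_skipped + 1L; next }
      a9 <- gff3_attrs(f[[9L]])
      reverses <- list()
      if (is_gene) {
        id <- sub("^gene:", "", a9$ID %||% "")
        if (!nzchar(id)) { stats$records_skipped <- stats$records_skipped + 1L; next }
        attrs <- list(seq_region = f[[1L]], start = start, end = end)
        if (f[[7L]] %in% c("+", "-")) attrs$strand <- f[[7L]]
        if (!is.null(a9$Name)) attrs$name <- a9$Name
        if (!is.null(a9$description)) attrs$description <- a9$description
        xt <- character(); xi <- character()
        if (!is.null(a9$Ontology_term)) {
          go <- strsplit(a9$Ontology_term, ",", fixed = TRUE)[[1L]]
          xt <- c(xt, rep("go", length(go))); xi <- c(xi, go)
        }
        if (!is.na(taxid)) {
          xt <- c(xt, "taxonomy"); xi <- c(xi, taxid)
          reverses[[1L]] <- reverse_record(taxid, "taxonomy", gene_dataset, id)
        }
        rec <- tryCatch(
          new_record(id, gene_dataset, attrs, list(target = xt, id = xi),
                     keywords = if (is.null(a9$Name)) character() else a9$Name),
          xrefdb_invalid_record = function(e) NULL)
      } else {
        id <- sub("^transcript:", "", a9$ID %||% "")
        parent <- sub("^gene:", "", a9$Parent %||% "")
        if (!nzchar(id)) { stats$records_skipped <- stats$records_skipped + 1L; next }
        attrs <- list(seq_region = f[[1L]], start = start, end = end)
        if (f[[7L]] %in% c("+", "-")) attrs$strand <- f[[7L]]
        xt <- character(); xi <- character()
        if (nzchar(parent)) {
          xt <- c(xt, gene_dataset); xi <- c(xi, parent)
          reverses[[length(reverses) + 1L]] <-
            reverse_record(parent, gene_dataset, transcript_dataset, id)
        }
        if (!is.na(taxid)) { xt <- c(xt, "taxonomy"); xi <- c(xi, taxid) }
        rec <- tryCatch(
          new_record(id, transcript_dataset, attrs, list(target = xt, id = xi)),
          xrefdb_invalid_record = function(e) NULL)
      }
      if (is.null(rec)) { stats$records_skipped <- stats$records_skipped + 1L; next }
      stats <- emit_with_reverses(rec, reverses, sink, stats)
    }
  }
  stats <- check_bad_fraction(stats, max_bad_frac, path)
  ingest_result(sink, stats)
}

#' Ingest one dataset file, dispatching on its registered format
#'
#' @param path File path (plain or gzip).
#' @param dataset Registered dataset name.
#' @param registry An `xref_registry`.
#' @param emit Optional per-record callback.
#' @param ... Passed to the format adapter.
#' @return `list(records, stats)`.
#' @export
ingest_dataset <- function(path, dataset, registry = default_registry(),
                           emit = NULL, ...) {
  i <- match(dataset, registry$datasets$name)
  if (is.na(i)) registry_id(registry, dataset)  # raises unknown-dataset
  fmt <- registry$datasets$format[i]
  spec <- registry$specs[[dataset]]
  switch(fmt,
    tsv = ingest_tsv(path, spec, dataset, registry, emit, delim = "\t", ...),
    csv = ingest_tsv(path, spec, dataset, registry, emit, delim = ",", ...),
    json = ingest_json(path, spec, dataset, registry, emit, ...),
    xml = ingest_xml(path, spec, dataset, registry, emit, ...),
    gff3 = ingest_gff3(path, registry, emit, gene_dataset = dataset, ...)
  )
}
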