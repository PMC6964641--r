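# Query execution: filter evaluation against entry attributes and the
# mapping executor that walks cross-references dataset to dataset.

#' Evaluate a filter expression against one entry payload
#'
#' Semantics: `within(a,b)` is the genomic-range shorthand for
#' `start > a && end < b` (strict at both ends); `contains` is
#' case-sensitive substring match; a bare attribute is true iff present and
#' true; comparisons against numeric literals coerce character attributes
#' to numbers when possible. A missing attribute makes any comparison
#' false, never an error; an ordered comparison (`<`, `<=`, `>`, `>=`)
#' against a quoted string literal is an evaluation error. Multi-valued
#' attributes match if any element does.
#'
#' @param expr A filter expression node from [parse_query()].
#' @param entry An `xref_payload`.
#' @return `TRUE` or `FALSE`.
#' @export
eval_filter <- function(expr, entry) {
  switch(expr$type,
    and = eval_filter(expr$left, entry) && eval_filter(expr$right, entry),
    or = eval_filter(expr$left, entry) || eval_filter(expr$right, entry),
    within = {
      s <- entry$attrs$start; e <- entry$attrs$end
      !is.null(s) && !is.null(e) && s[1L] > expr$low && e[1L] < expr$high
    },
    contains = {
      v <- entry$attrs[[expr$path[2L]]]
      !is.null(v) && any(grepl(expr$needle, as.character(v), fixed = TRUE))
    },
    bool = {
      v <- entry$attrs[[expr$path[2L]]]
      is.logical(v) && isTRUE(any(v))
    },
    cmp = eval_compare(expr, entry),
    xr_abort("xrefdb_eval_error", sprintf("unknown filter node type '%s'", expr$type))
  )
}

eval_compare <- function(expr, entry) {
  v <- entry$attrs[[expr$path[2L]]]
  lit <- expr$literal
  op <- expr$op
  ordered <- op %in% c("<", "<=", ">", ">=")
  if (ordered && is.character(lit)) {
    xr_abort("xrefdb_eval_error",
             sprintf("ordered comparison '%s' requires a numeric literal, got a string", op))
  }
  if (is.null(v)) return(FALSE)
  if (is.numeric(lit)) {
    if (!is.numeric(v)) {
      v <- suppressWarnings(as.numeric(as.character(v)))
      if (all(is.na(v))) return(FALSE)
      v <- v[!is.na(v)]
    }
  } else if (is.logical(lit)) {
    if (!is.logical(v)) return(FALSE)
  } else {
    if (ordered) return(FALSE)
    v <- as.character(v)
  }
  res <- switch(op,
    "==" = v == lit, "!=" = v != lit,
    "<" = v < lit, "<=" = v <= lit,
    ">" = v > lit, ">=" = v >= lit)
  isTRUE(any(res))
}

#' Follow one mapping hop from a set of entries
#'
#' For a dataset target, returns the entries reachable through one
#' cross-reference whose target dataset equals it; for a relation label
#' (`taxchild`), the entries reachable through edges with that label,
#' resolved in the relation's dataset (direct children per hop;
#' `transitive = TRUE` takes the closure, cycle-safe). The result is
#' deduplicated and ordered by ascending identifier; cross-references whose
#' target id is absent from the store are dropped and counted.
#'
#' @param store A read-mode `xref_store`.
#' @param entries List of `xref_payload`.
#' @param target Dataset name or relation label.
#' @param transitive Transitive closure for relation targets.
#' @return List of `xref_payload` with attribute `dropped` counting
#'   unresolvable cross-references.
#' @export
map_step <- function(store, entries, target, transitive = FALSE) {
  registry <- store$registry
  target_ds <- resolve_map_target(registry, target)
  target_id <- registry_id(registry, target_ds)
  dropped <- 0L
  out <- list(); seen <- character()
  frontier <- entries
  visited <- character()
  repeat {
    ids <- character()
    for (p in frontier) {
      sel <- p$xrefs$target == target
      ids <- c(ids, p$xrefs$id[sel])
    }
    ids <- unique(ids)
    next_frontier <- list()
    for (id in ids) {
      nk <- normalize_keys(id)
      if (nk %in% seen) next
      hit <- fetch_entry(store, target_id, id)
      if (is.null(hit)) { dropped <- dropped + 1L; next }
      seen <- c(seen, nk)
      out[[length(out) + 1L]] <- hit
      next_frontier[[length(next_frontier) + 1L]] <- hit
    }
    if (!transitive || length(next_frontier) == 0L) break
    frontier <- next_frontier
  }
  if (length(out) > 1L) {
    o <- order(normalize_keys(vapply(out, `[[`, "", "identifier")), method = "radix")
    out <- out[o]
  }
  attr(out, "dropped") <- dropped
  out
}

#' Parse an attribute selector
#'
#' A comma-separated list of attribute names, each optionally indexed
#' `name[i]` with 1-based `i` picking one element of a list attribute.
#' @param selector Selector text, e.g. `"names[1]"` or `"strand,start,end"`.
#' @return List of `list(name, index)` (index `NA` when unindexed).
#' @export
parse_attr_selector <- function(selector) {
  parts <- trimws(strsplit(selector, ",", fixed = TRUE)[[1L]])
  lapply(parts, function(p) {
    m <- regmatches(p, regexec("^([A-Za-z_][A-Za-z0-9_]*)(\\[([0-9]+)\\])?$", p))[[1L]]
    if (length(m) == 0L) {
      xr_abort("xrefdb_selector_error", sprintf("malformed attribute selector '%s'", p))
    }
    idx <- if (nzchar(m[4L])) as.integer(m[4L]) else NA_integer_
    if (!is.na(idx) && idx < 1L) {
      xr_abort("xrefdb_selector_error", sprintf("selector index must be >= 1 in '%s'", p))
    }
    list(name = m[2L], index = idx)
  })
}

#' Select attribute values from an entry
#'
#' Values come back in selector order; `name[i]` picks the i-th element of
#' a list attribute; a missing attribute or out-of-range index yields `NA`
#' (rendered as `-` in tabular output).
#'
#' @param entry An `xref_payload`.
#' @param selector Selector text or the result of [parse_attr_selector()].
#' @return Unnamed list of scalar values (`NA` for misses).
#' @export
select_attrs <- function(entry, selector) {
  if (is.character(selector)) selector <- parse_attr_selector(selector)
  lapply(selector, function(s) {
    v <- entry$attrs[[s$name]]
    if (is.null(v)) return(NA)
    if (is.na(s$index)) {
      if (length(v) == 1L) v else paste(as.character(v), collapse = ";")
    } else if (s$index <= length(v)) {
      v[s$index]
    } else NA
  })
}

attr_col_string <- function(vals) {
  vapply(vals, function(v) {
    if (length(v) == 1L && is.na(v)) return(NA_character_)
    if (is.numeric(v)) num_repr(v) else as.character(v)
  }, NA_character_)
}

#' Execute a chain mapping query
#'
#' Each comma-separated input term is resolved through the term index
#' (identifier or special keyword, case-insensitive; restricted to `source`
#' when given), the query steps are applied left to right (map expands the
#' frontier one cross-reference hop, filter prunes it), and the final
#' frontier becomes one row per (input term, mapped identifier) with any
#' selected attribute values. A term resolving to nothing simply
#' contributes no rows.
#'
#' @param store A read-mode `xref_store`.
#' @param terms Comma-separated input terms.
#' @param query_text Query text (see [parse_query()]).
#' @param source Optional dataset name restricting term resolution.
#' @param attrs Optional attribute selector for the mapped entries.
#' @param page_size Rows per page.
#' @param token Continuation token from a previous page.
#' @param taxchild_transitive Treat relation hops as transitive closure.
#' @return An `xref_mapping_result`: `list(rows = data.frame(input,
#'   input_dataset, mapping_id, ...), next_token)`.
#' @export
execute_mapping <- function(store, terms, query_text, source = NULL,
                            attrs = NULL, page_size = 200L, token = NULL,
                            taxchild_transitive = FALSE) {
  stopifnot_mode(store, "read")
  query <- parse_query(query_text, registry = store$registry)
  if (!is.null(source)) registry_id(store$registry, source)
  term_list <- trimws(strsplit(terms, ",", fixed = TRUE)[[1L]])
  term_list <- term_list[nzchar(term_list)]
  selector <- if (!is.null(attrs)) parse_attr_selector(attrs) else NULL
  sel_names <- if (!is.null(selector)) {
    vapply(selector, function(s)
      if (is.na(s$index)) s$name else sprintf("%s[%d]", s$name, s$index), "")
  } else character()

  all_rows <- list()
  for (term in term_list) {
    start <- store_lookup(store, term, source = source)
    if (length(start) == 0L) next
    input_ds <- paste(sort(unique(vapply(start, function(p)
      registry_name(store$registry, p$dataset_id), ""))), collapse = ",")
    frontier <- start
    for (step in query) {
      if (length(frontier) == 0L) break
      if (step$type == "map") {
        frontier <- map_step(store, frontier, step$target,
                             transitive = taxchild_transitive &&
                               step$target %in% names(store$registry$relations))
      } else {
        frontier <- Filter(function(p) eval_filter(step$expr, p), frontier)
      }
    }
    if (length(frontier) == 0L) next
    ids <- vapply(frontier, `[[`, "", "identifier")
    row <- data.frame(input = normalize_key(term), input_dataset = input_ds,
                      mapping_id = ids, stringsAsFactors = FALSE)
    if (!is.null(selector)) {
      cols <- lapply(seq_along(selector), function(j)
        attr_col_string(lapply(frontier, function(p) select_attrs(p, selector)[[j]])))
      names(cols) <- sel_names
      for (nm in names(cols)) row[[nm]] <- cols[[nm]]
    }
    all_rows[[length(all_rows) + 1L]] <- row
  }
  rows <- if (length(all_rows)) do.call(rbind, all_rows) else {
    df <- data.frame(input = character(), input_dataset = character(),
                     mapping_id = character(), stringsAsFactors = FALSE)
    for (nm in sel_names) df[[nm]] <- character()
    df
  }
  rownames(rows) <- NULL
  offset <- 0L
  if (!is.null(token)) {
    tk <- decode_page_token(token)
    if (tk$key != "rows") xr_abort("xrefdb_token_error", "invalid continuation token")
    offset <- tk$offset
  }
  n <- nrow(rows)
  take <- seq_len(min(page_size, max(0L, n - offset))) + offset
  page <- rows[take, , drop = FALSE]
  rownames(page) <- NULL
  next_token <- if (offset + length(take) < n) {
    encode_page_token("rows", offset + length(take))
  } else NULL
  structure(list(rows = page, next_token = next_token),
            class = "xref_mapping_result")
}

#' Drain every page of a mapping query into one row table
#' @inheritParams execute_mapping
#' @return A data.frame of all result rows.
#' @export
execute_mapping_all <- function(store, terms, query_text, source = NULL,
                                attrs = NULL, page_size = 200L,
                                taxchild_transitive = FALSE) {
  token <- NULL
  out <- list()
  repeat {
    page <- execute_mapping(store, terms, query_text, source = source,
                            attrs = attrs, page_size = page_size,
                            token = token,
                            taxchild_transitive = taxchild_transitive)
    out[[length(out) + 1L]] <- page$rows
    token <- page$next_token
    if (is.null(token)) break
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' @export
print.xref_mapping_result <- function(x, ...) {
  df <- x$rows
  if (nrow(df) == 0L) {
    cat("<no mapping results>\n")
    return(invisible(x))
  }
  # repeat input columns only on the first row of each input group
  rep_rows <- c(FALSE, df$input[-1L] == df$input[-nrow(df)])
  df$input[rep_rows] <- "-"
  df$input_dataset[rep_rows] <- "-"
  df[is.na(df)] <- "-"
  print(df, row.names = TRUE)
  if (!is.null(x$next_token)) cat("... more rows; pass the continuation token\n")
  invisible(x)
}
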