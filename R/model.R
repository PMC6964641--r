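# Core domain types and the on-disk key/value encoding.
#
# Every search term (identifier, gene symbol, species name, ...) is stored
# under a canonical key: uppercased, trimmed, internal whitespace collapsed.
# Two keyspaces are multiplexed by a one-character prefix:
#   "T" <US> <TERM>                 -> list of reference payloads (dataset, id)
#   "E" <US> <dsid> <US> <ID>       -> the merged full payload of one entry
# so the term index stays small and entry fetch is a single exact lookup.
# <US> is the ASCII unit separator (0x1f), which never survives key
# normalization and therefore cannot collide with user terms.

KEY_SEP <- "\x1f"
PAYLOAD_SEP <- "\x1d"
FIELD_SEP <- "\x1e"
ELEM_SEP <- "\x1c"

#' Raise a classed xrefdb error
#' @noRd
xr_abort <- function(class, msg, ...) {
  cond <- structure(
    class = c(class, "xrefdb_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  )
  stop(cond)
}

#' Normalize a search term to its canonical key form
#'
#' Search keys are case-insensitive: terms are uppercased, outer whitespace
#' is trimmed and internal whitespace runs collapse to a single space, so
#' `"202763_at"` and `"202763_AT"` address the same entries while the
#' original identifier case is preserved inside the stored payload.
#' Normalization is idempotent.
#'
#' @param term A character scalar (an identifier or special keyword).
#' @return The canonical key, a character scalar.
#' @examples
#' normalize_key("202763_at")
#' normalize_key("  homo   sapiens ")
#' @export
normalize_key <- function(term) {
  if (!is.character(term) || length(term) != 1L || is.na(term)) {
    xr_abort("xrefdb_invalid_term", "term must be a single character string")
  }
  key <- toupper(gsub("[[:space:]]+", " ", trimws(term)))
  if (!nzchar(key)) {
    xr_abort("xrefdb_invalid_term", "term is empty or whitespace-only")
  }
  key
}

# Vectorized variant used on hot paths (no error on empties; caller filters).
normalize_keys <- function(terms) {
  toupper(gsub("[[:space:]]+", " ", trimws(terms)))
}

# -- string escaping for the payload wire format ------------------------------
# Reserved bytes: backslash, tab, newline, CR and the 0x1c-0x1f separators.
# Escapes: \\ \t \n \r and \a \b \c \d for 0x1c..0x1f.

esc <- function(x) {
  needs <- grepl("[\\\\\t\n\r\x1c\x1d\x1e\x1f]", x, useBytes = TRUE, perl = TRUE)
  if (!any(needs)) return(x)
  y <- x[needs]
  y <- gsub("\\", "\\\\", y, fixed = TRUE, useBytes = TRUE)
  y <- gsub("\t", "\\t", y, fixed = TRUE, useBytes = TRUE)
  y <- gsub("\n", "\\n", y, fixed = TRUE, useBytes = TRUE)
  y <- gsub("\r", "\\r", y, fixed = TRUE, useBytes = TRUE)
  y <- gsub("\x1c", "\\a", y, fixed = TRUE, useBytes = TRUE)
  y <- gsub("\x1d", "\\b", y, fixed = TRUE, useBytes = TRUE)
  y <- gsub("\x1e", "\\c", y, fixed = TRUE, useBytes = TRUE)
  y <- gsub("\x1f", "\\d", y, fixed = TRUE, useBytes = TRUE)
  x[needs] <- y
  x
}

unesc <- function(x) {
  needs <- grepl("\\", x, fixed = TRUE, useBytes = TRUE)
  if (!any(needs)) return(x)
  # Split on escaped backslashes first so the remaining single backslashes
  # unambiguously start a two-character escape code.
  unesc1 <- function(s) {
    parts <- strsplit(paste0(s, "\x02"), "\\\\", fixed = TRUE)[[1L]]
    parts <- gsub("\\t", "\t", parts, fixed = TRUE, useBytes = TRUE)
    parts <- gsub("\\n", "\n", parts, fixed = TRUE, useBytes = TRUE)
    parts <- gsub("\\r", "\r", parts, fixed = TRUE, useBytes = TRUE)
    parts <- gsub("\\a", "\x1c", parts, fixed = TRUE, useBytes = TRUE)
    parts <- gsub("\\b", "\x1d", parts, fixed = TRUE, useBytes = TRUE)
    parts <- gsub("\\c", "\x1e", parts, fixed = TRUE, useBytes = TRUE)
    parts <- gsub("\\d", "\x1f", parts, fixed = TRUE, useBytes = TRUE)
    out <- paste(parts, collapse = "\\")
    substr(out, 1L, nchar(out) - 1L)
  }
  x[needs] <- vapply(x[needs], unesc1, character(1L), USE.NAMES = FALSE)
  x
}

# Deterministic decimal representation of a double; round-trips exactly
# through as.numeric for all finite values.
num_repr <- function(d) {
  ifelse(d == floor(d) & abs(d) < 2^53, sprintf("%.0f", d), sprintf("%.17g", d))
}

# -- payloads -----------------------------------------------------------------

#' Construct an entry payload
#'
#' A payload is the value stored under a canonical key: the owning dataset's
#' numeric id, the original-case identifier, a named attribute list and a
#' cross-reference set. Attribute values are atomic vectors of one type
#' (character, numeric or logical); multi-element vectors are ordered list
#' attributes (e.g. protein `names`). Cross-references are parallel
#' `target`/`id` character vectors where `target` is a dataset name or a
#' relation label such as `taxchild`.
#'
#' @param dataset_id Integer dataset id from the registry.
#' @param identifier Original-case identifier, non-empty.
#' @param attrs Named list of atomic vectors.
#' @param xrefs `list(target = character(), id = character())` or `NULL`.
#' @return An object of class `xref_payload`.
#' @export
new_payload <- function(dataset_id, identifier, attrs = list(), xrefs = NULL) {
  if (!is.character(identifier) || length(identifier) != 1L || !nzchar(identifier)) {
    xr_abort("xrefdb_invalid_term", "identifier must be a non-empty string")
  }
  if (is.null(xrefs)) xrefs <- list(target = character(), id = character())
  an <- names(attrs)
  if (length(attrs) && (is.null(an) || any(!nzchar(an)) ||
      any(!grepl("^[A-Za-z_][A-Za-z0-9_]*$", an)))) {
    xr_abort("xrefdb_invalid_attr", "attribute names must be valid identifiers")
  }
  attrs <- lapply(attrs, function(v) {
    if (is.numeric(v)) {
      v <- as.double(v)
      if (any(!is.finite(v))) xr_abort("xrefdb_invalid_attr", "non-finite numeric attribute")
    } else if (!is.character(v) && !is.logical(v)) {
      xr_abort("xrefdb_invalid_attr", "attribute values must be character, numeric or logical")
    }
    if (length(v) == 0L) xr_abort("xrefdb_invalid_attr", "empty attribute value")
    unname(v)
  })
  structure(
    list(dataset_id = as.integer(dataset_id), identifier = identifier,
         attrs = attrs, xrefs = list(target = as.character(xrefs$target),
                                     id = as.character(xrefs$id))),
    class = "xref_payload"
  )
}

#' @export
print.xref_payload <- function(x, ...) {
  cat(sprintf("<entry ds=%d id=%s; %d attrs, %d xrefs>\n",
              x$dataset_id, x$identifier, length(x$attrs), length(x$xrefs$target)))
  invisible(x)
}

# A reference payload carries no attributes or xrefs: it points from a term
# to an entry in the entry keyspace.
ref_payload <- function(dataset_id, identifier) {
  new_payload(dataset_id, identifier)
}

xref_key <- function(xr) paste0(xr$target, "\x01", xr$id)

# Canonical xref order (C-locale byte order on target, then id) so that
# merged payloads are identical no matter how the inputs were partitioned.
sort_xrefs <- function(xrefs) {
  if (length(xrefs$target) <= 1L) return(xrefs)
  o <- order(xrefs$target, xrefs$id, method = "radix")
  list(target = xrefs$target[o], id = xrefs$id[o])
}

dedup_xrefs <- function(xrefs) {
  if (length(xrefs$target) <= 1L) return(xrefs)
  keep <- !duplicated(paste0(xrefs$target, "\x01", xrefs$id))
  list(target = xrefs$target[keep], id = xrefs$id[keep])
}

#' Merge two payloads of the same (dataset, identifier)
#'
#' List attributes take the set union preserving first-seen element order
#' (so a primary name stays first); scalar attribute conflicts resolve
#' last-writer-wins. Cross-references are deduplicated and kept in canonical
#' (target, id) order so the merge result is independent of how the inputs
#' were split into chunks.
#' @noRd
merge_two_payloads <- function(a, b) {
  for (nm in names(b$attrs)) {
    bv <- b$attrs[[nm]]
    av <- a$attrs[[nm]]
    if (is.null(av)) {
      a$attrs[[nm]] <- bv
    } else if (length(av) > 1L || length(bv) > 1L) {
      a$attrs[[nm]] <- c(av, bv[!(bv %in% av)])
    } else if (!identical(av, bv)) {
      a$attrs[[nm]] <- bv   # last writer wins on scalar conflict
    }
  }
  a$xrefs <- sort_xrefs(dedup_xrefs(list(
    target = c(a$xrefs$target, b$xrefs$target),
    id = c(a$xrefs$id, b$xrefs$id)
  )))
  a
}

#' Merge a list of payloads into one deduplicated, canonically ordered list
#'
#' Payloads sharing a (dataset, identifier) pair are folded together with
#' [merge_two_payloads()] semantics; the result is sorted by (dataset id,
#' identifier) in C-locale order.
#' @param payloads List of `xref_payload`.
#' @return List of `xref_payload`, unique per (dataset, identifier).
#' @export
merge_payloads <- function(payloads) {
  if (length(payloads) <= 1L) return(canonical_payloads(payloads))
  ids <- paste0(vapply(payloads, function(p) p$dataset_id, 1L), "\x01",
                vapply(payloads, function(p) p$identifier, ""))
  groups <- split(seq_along(payloads), ids)
  out <- lapply(groups, function(idx) {
    p <- payloads[[idx[1L]]]
    for (i in idx[-1L]) p <- merge_two_payloads(p, payloads[[i]])
    p
  })
  canonical_payloads(unname(out))
}

#' Put a payload list in canonical form
#'
#' Deduplicates and sorts each payload's cross-references, orders attribute
#' names, and sorts the payload list by (dataset id, identifier); the form
#' [encode_payload_list()] serializes deterministically.
#' @param payloads List of `xref_payload`.
#' @export
canonical_payloads <- function(payloads) {
  payloads <- lapply(payloads, function(p) {
    p$xrefs <- sort_xrefs(dedup_xrefs(p$xrefs))
    if (length(p$attrs) > 1L) p$attrs <- p$attrs[order(names(p$attrs), method = "radix")]
    p
  })
  if (length(payloads) > 1L) {
    o <- order(vapply(payloads, function(p) p$dataset_id, 1L),
               vapply(payloads, function(p) p$identifier, ""),
               method = "radix")
    payloads <- payloads[o]
  }
  payloads
}

# -- wire encoding ------------------------------------------------------------

encode_attr_value <- function(v) {
  if (is.character(v)) {
    paste0("s", paste(esc(v), collapse = ELEM_SEP))
  } else if (is.logical(v)) {
    paste0("b", paste(as.integer(v), collapse = ELEM_SEP))
  } else {
    paste0("n", paste(num_repr(v), collapse = ELEM_SEP))
  }
}

decode_attr_value <- function(s) {
  type <- substr(s, 1L, 1L)
  body <- substr(s, 2L, nchar(s))
  elems <- strsplit(body, ELEM_SEP, fixed = TRUE)[[1L]]
  switch(type,
    s = unesc(elems),
    b = as.logical(as.integer(elems)),
    n = as.numeric(elems),
    xr_abort("xrefdb_decode_error", sprintf("unknown attribute type tag '%s'", type))
  )
}

encode_payload <- function(p) {
  attrs <- p$attrs
  a <- if (length(attrs)) {
    if (length(attrs) > 1L) attrs <- attrs[order(names(attrs), method = "radix")]
    paste(paste0(esc(names(attrs)), "=",
                 vapply(attrs, encode_attr_value, "", USE.NAMES = FALSE)),
          collapse = KEY_SEP)
  } else ""
  x <- if (length(p$xrefs$target)) {
    paste(paste0(esc(p$xrefs$target), ELEM_SEP, esc(p$xrefs$id)), collapse = KEY_SEP)
  } else ""
  paste(p$dataset_id, esc(p$identifier), a, x, sep = FIELD_SEP)
}

decode_payload <- function(s) {
  f <- strsplit(s, FIELD_SEP, fixed = TRUE)[[1L]]
  if (length(f) < 4L) f <- c(f, rep("", 4L - length(f)))   # trailing empties
  if (length(f) != 4L) xr_abort("xrefdb_decode_error", "malformed payload record")
  attrs <- list()
  if (nzchar(f[3L])) {
    pairs <- strsplit(f[3L], KEY_SEP, fixed = TRUE)[[1L]]
    eq <- regexpr("=", pairs, fixed = TRUE)
    nms <- unesc(substr(pairs, 1L, eq - 1L))
    vals <- substring(pairs, eq + 1L)
    attrs <- lapply(vals, decode_attr_value)
    names(attrs) <- nms
  }
  xrefs <- list(target = character(), id = character())
  if (nzchar(f[4L])) {
    prs <- strsplit(strsplit(f[4L], KEY_SEP, fixed = TRUE)[[1L]], ELEM_SEP, fixed = TRUE)
    xrefs <- list(target = unesc(vapply(prs, `[`, "", 1L)),
                  id = unesc(vapply(prs, `[`, "", 2L)))
  }
  new_payload(as.integer(f[1L]), unesc(f[2L]), attrs, xrefs)
}

#' Encode / decode a payload list to its canonical wire string
#'
#' The deterministic value encoding used in chunk files and the store data
#' file; `decode_payload_list(encode_payload_list(x))` is the identity on
#' canonical payload lists.
#' @param payloads List of `xref_payload`.
#' @return A single encoded string.
#' @export
encode_payload_list <- function(payloads) {
  paste(vapply(payloads, encode_payload, "", USE.NAMES = FALSE),
        collapse = PAYLOAD_SEP)
}

#' @rdname encode_payload_list
#' @param s An encoded payload-list string.
#' @export
decode_payload_list <- function(s) {
  lapply(strsplit(s, PAYLOAD_SEP, fixed = TRUE)[[1L]], decode_payload)
}

# Default cap on one encoded value; a single key holding more than this is
# almost certainly an ingest spec error (e.g. everything keyed by one term).
XR_MAX_VALUE_BYTES <- 16L * 1024L * 1024L

#' Encode a canonical key and its payload list as a byte pair
#'
#' The byte key preserves C-locale lexicographic order of the canonical key
#' text, and the value is a deterministic self-describing encoding: the same
#' payload list always yields the same bytes, which is what makes whole-store
#' builds byte-reproducible. `decode_kv()` inverts it exactly.
#'
#' @param key Canonical key string (already normalized).
#' @param payloads Non-empty list of `xref_payload`.
#' @param max_bytes Size cap for the encoded value.
#' @return `list(key = raw, value = raw)`.
#' @export
encode_kv <- function(key, payloads, max_bytes = XR_MAX_VALUE_BYTES) {
  if (length(payloads) == 0L) xr_abort("xrefdb_encode_error", "empty payload list")
  val <- encode_payload_list(payloads)
  if (nchar(val, type = "bytes") > max_bytes) {
    xr_abort("xrefdb_oversize", sprintf("encoded value for key %s exceeds %d bytes", key, max_bytes))
  }
  list(key = charToRaw(key), value = charToRaw(val))
}

#' Decode a byte pair produced by [encode_kv()]
#' @param key Raw byte key.
#' @param value Raw encoded value.
#' @return `list(key = character, payloads = list of xref_payload)`.
#' @export
decode_kv <- function(key, value) {
  list(key = rawToChar(key), payloads = decode_payload_list(rawToChar(value)))
}

# -- key construction ---------------------------------------------------------

term_key <- function(norm_term) paste0("T", KEY_SEP, norm_term)
entry_key <- function(dataset_id, norm_id) {
  paste0("E", KEY_SEP, sprintf("%04d", dataset_id), KEY_SEP, norm_id)
}
is_term_key <- function(key) startsWith(key, paste0("T", KEY_SEP))
strip_term_key <- function(key) substring(key, 3L)
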