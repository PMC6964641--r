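# The chain mapping query language:
#   map(target).filter(expr).map(target2)...
# with filter expressions over the active dataset's attributes:
#   ==  !=  <  <=  >  >=  &&  ||  dataset.attr.contains("s")
#   dataset.within(a,b)   dataset.attr          (boolean attribute)
# String literals are double-quoted; a filter may only appear immediately
# after a map, and its attribute prefixes must name that map's active
# dataset.

# -- tokenizer ---------------------------------------------------------------

TOKEN_PATTERNS <- list(
  c("ws",     "^[ \t\r\n]+"),
  c("number", "^-?[0-9]+(\\.[0-9]+)?([eE][+-]?[0-9]+)?"),
  c("ident",  "^[A-Za-z_][A-Za-z0-9_]*"),
  c("string", '^"[^"]*"'),
  c("op",     "^(==|!=|<=|>=|&&|\\|\\||[<>.(),])")
)

tokenize_query <- function(text) {
  tokens <- list(); pos <- 1L
  n <- nchar(text)
  while (pos <= n) {
    rest <- substring(text, pos)
    matched <- FALSE
    for (tp in TOKEN_PATTERNS) {
      m <- regexpr(tp[2L], rest, perl = TRUE)
      if (m == 1L) {
        len <- attr(m, "match.length")
        if (tp[1L] != "ws") {
          tokens[[length(tokens) + 1L]] <-
            list(type = tp[1L], text = substr(rest, 1L, len), pos = pos)
        }
        pos <- pos + len
        matched <- TRUE
        break
      }
    }
    if (!matched) {
      xr_abort("xrefdb_syntax_error",
               sprintf("unexpected character '%s' at position %d",
                       substr(rest, 1L, 1L), pos),
               position = pos)
    }
  }
  tokens
}

# Cursor over the token list with one-token lookahead.
token_cursor <- function(tokens, text) {
  i <- 0L
  end_pos <- nchar(text) + 1L
  peek <- function() if (i < length(tokens)) tokens[[i + 1L]] else NULL
  advance <- function() { i <<- i + 1L; tokens[[i]] }
  expect <- function(type, text_val = NULL) {
    tk <- peek()
    want <- text_val %||% type
    if (is.null(tk)) {
      xr_abort("xrefdb_syntax_error",
               sprintf("expected %s at position %d (end of query)", want, end_pos),
               position = end_pos)
    }
    if (tk$type != type || (!is.null(text_val) && tk$text != text_val)) {
      xr_abort("xrefdb_syntax_error",
               sprintf("expected %s but found '%s' at position %d", want, tk$text, tk$pos),
               position = tk$pos)
    }
    advance()
  }
  list(peek = peek, advance = advance, expect = expect)
}

# -- parser ------------------------------------------------------------------

#' Parse a chain mapping query
#'
#' Produces the step AST: `map` steps carry their target (a dataset name or
#' relation label), `filter` steps carry a boolean expression tree over the
#' active dataset of the preceding map. Structural rules enforced here: at
#' least one map step; every filter immediately follows a map; filter
#' attribute prefixes name that map's active dataset. Map targets are
#' validated against the registry when one is supplied (execution always
#' validates them).
#'
#' @param text Query text, e.g.
#'   `'map(transcript).map(ensembl).map(go).filter(go.type=="molecular_function")'`.
#' @param registry Optional `xref_registry` for target validation.
#' @return An object of class `xref_query` (list of steps).
#' @export
parse_query <- function(text, registry = NULL) {
  if (!is.character(text) || length(text) != 1L || !nzchar(trimws(text))) {
    xr_abort("xrefdb_syntax_error", "query text must be a non-empty string", position = 1L)
  }
  cur <- token_cursor(tokenize_query(text), text)
  steps <- list()
  active <- NULL
  repeat {
    verb <- cur$expect("ident")
    if (verb$text == "map") {
      cur$expect("op", "(")
      tgt <- cur$peek()
      if (is.null(tgt) || tgt$type != "ident") {
        p <- if (is.null(tgt)) nchar(text) + 1L else tgt$pos
        xr_abort("xrefdb_syntax_error",
                 sprintf("map() needs a dataset or relation target at position %d", p),
                 position = p)
      }
      cur$advance()
      cur$expect("op", ")")
      if (!is.null(registry)) {
        active <- resolve_map_target(registry, tgt$text)
      } else {
        active <- tgt$text
      }
      steps[[length(steps) + 1L]] <- list(type = "map", target = tgt$text)
    } else if (verb$text == "filter") {
      if (length(steps) == 0L || steps[[length(steps)]]$type != "map") {
        xr_abort("xrefdb_semantic_error",
                 sprintf("filter at position %d must immediately follow a map step", verb$pos),
                 position = verb$pos)
      }
      cur$expect("op", "(")
      expr <- parse_or(cur, text)
      cur$expect("op", ")")
      check_filter_prefixes(expr, active, verb$pos)
      steps[[length(steps) + 1L]] <- list(type = "filter", expr = expr, dataset = active)
    } else {
      xr_abort("xrefdb_syntax_error",
               sprintf("expected 'map' or 'filter' but found '%s' at position %d",
                       verb$text, verb$pos),
               position = verb$pos)
    }
    nx <- cur$peek()
    if (is.null(nx)) break
    if (nx$type == "op" && nx$text == ".") { cur$advance(); next }
    xr_abort("xrefdb_syntax_error",
             sprintf("expected '.' or end of query but found '%s' at position %d",
                     nx$text, nx$pos),
             position = nx$pos)
  }
  if (!any(vapply(steps, function(s) s$type == "map", TRUE))) {
    xr_abort("xrefdb_semantic_error", "query must contain at least one map step")
  }
  structure(steps, class = "xref_query")
}

parse_or <- function(cur, text) {
  left <- parse_and(cur, text)
  repeat {
    tk <- cur$peek()
    if (is.null(tk) || tk$type != "op" || tk$text != "||") return(left)
    cur$advance()
    left <- list(type = "or", left = left, right = parse_and(cur, text))
  }
}

parse_and <- function(cur, text) {
  left <- parse_primary(cur, text)
  repeat {
    tk <- cur$peek()
    if (is.null(tk) || tk$type != "op" || tk$text != "&&") return(left)
    cur$advance()
    left <- list(type = "and", left = left, right = parse_primary(cur, text))
  }
}

parse_primary <- function(cur, text) {
  tk <- cur$peek()
  if (!is.null(tk) && tk$type == "op" && tk$text == "(") {
    cur$advance()
    expr <- parse_or(cur, text)
    cur$expect("op", ")")
    return(expr)
  }
  parse_predicate(cur, text)
}

parse_predicate <- function(cur, text) {
  first <- cur$expect("ident")
  path <- first$text
  repeat {
    tk <- cur$peek()
    if (is.null(tk) || tk$type != "op" || tk$text != ".") break
    cur$advance()
    seg <- cur$expect("ident")
    nx <- cur$peek()
    if (!is.null(nx) && nx$type == "op" && nx$text == "(") {
      # built-in call: dataset.within(a,b) or path.contains("s")
      cur$advance()
      if (seg$text == "within") {
        lo <- parse_number(cur)
        cur$expect("op", ",")
        hi <- parse_number(cur)
        cur$expect("op", ")")
        return(list(type = "within", dataset = path, low = lo, high = hi))
      }
      if (seg$text == "contains") {
        s <- cur$expect("string")
        cur$expect("op", ")")
        return(list(type = "contains", path = strsplit(path, ".", fixed = TRUE)[[1L]],
                    needle = unquote_string(s$text)))
      }
      xr_abort("xrefdb_syntax_error",
               sprintf("unknown filter function '%s' at position %d", seg$text, seg$pos),
               position = seg$pos)
    }
    path <- paste0(path, ".", seg$text)
  }
  segs <- strsplit(path, ".", fixed = TRUE)[[1L]]
  if (length(segs) < 2L) {
    xr_abort("xrefdb_semantic_error",
             sprintf("attribute reference '%s' at position %d must be dataset.attribute",
                     path, first$pos),
             position = first$pos)
  }
  tk <- cur$peek()
  if (!is.null(tk) && tk$type == "op" &&
      tk$text %in% c("==", "!=", "<", "<=", ">", ">=")) {
    cur$advance()
    lit <- parse_literal(cur)
    return(list(type = "cmp", path = segs, op = tk$text, literal = lit))
  }
  list(type = "bool", path = segs)
}

parse_number <- function(cur) {
  tk <- cur$expect("number")
  as.numeric(tk$text)
}

parse_literal <- function(cur) {
  tk <- cur$peek()
  if (is.null(tk)) xr_abort("xrefdb_syntax_error", "expected a literal at end of query")
  if (tk$type == "number") { cur$advance(); return(as.numeric(tk$text)) }
  if (tk$type == "string") { cur$advance(); return(unquote_string(tk$text)) }
  if (tk$type == "ident" && tk$text %in% c("true", "false")) {
    cur$advance(); return(tk$text == "true")
  }
  xr_abort("xrefdb_syntax_error",
           sprintf("expected a number, string or boolean literal at position %d", tk$pos),
           position = tk$pos)
}

unquote_string <- function(s) substr(s, 2L, nchar(s) - 1L)

filter_prefixes <- function(expr) {
  switch(expr$type,
    and = , or = c(filter_prefixes(expr$left), filter_prefixes(expr$right)),
    within = expr$dataset,
    contains = , cmp = , bool = expr$path[1L]
  )
}

check_filter_prefixes <- function(expr, active, pos) {
  if (is.null(active)) return(invisible())
  bad <- setdiff(unique(filter_prefixes(expr)), active)
  if (length(bad)) {
    xr_abort("xrefdb_semantic_error",
             sprintf("filter at position %d references dataset '%s' but the active dataset is '%s'",
                     pos, bad[1L], active),
             position = pos)
  }
  invisible()
}

# -- canonical re-serialization ---------------------------------------------

format_filter <- function(expr) {
  switch(expr$type,
    and = paste0(format_filter(expr$left), " && ", format_filter(expr$right)),
    or = paste0("(", format_filter(expr$left), " || ", format_filter(expr$right), ")"),
    within = sprintf("%s.within(%s,%s)", expr$dataset,
                     num_repr(expr$low), num_repr(expr$high)),
    contains = sprintf('%s.contains("%s")', paste(expr$path, collapse = "."), expr$needle),
    cmp = {
      lit <- expr$literal
      lit_s <- if (is.character(lit)) sprintf('"%s"', lit)
               else if (is.logical(lit)) tolower(as.character(lit))
               else num_repr(lit)
      sprintf("%s%s%s", paste(expr$path, collapse = "."), expr$op, lit_s)
    },
    bool = paste(expr$path, collapse = ".")
  )
}

#' Serialize a parsed query back to canonical query text
#'
#' The canonical form re-parses to an equal AST.
#' @param query An `xref_query` from [parse_query()].
#' @return Query text.
#' @export
format_query <- function(query) {
  paste(vapply(query, function(s) {
    if (s$type == "map") sprintf("map(%s)", s$target)
    else sprintf("filter(%s)", format_filter(s$expr))
  }, ""), collapse = ".")
}

#' @export
print.xref_query <- function(x, ...) {
  cat(format_query(x), "\n")
  invisible(x)
}
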