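# Command-line and web-service surface. The CLI verbs (build, query, web)
# are thin wrappers over build_db() / execute_mapping(); the web layer is a
# transport-agnostic request handler (http_handle) plus a minimal blocking
# HTTP server over a socket connection, so the handler can be exercised and
# tested independently of any socket.

#' Render a mapping result as an aligned text table
#'
#' Mirrors the tabular layout of the interactive wrappers: columns `input`,
#' `input_dataset`, `mapping_id`, then any selected attribute columns;
#' repeated input cells print as `-`.
#' @param rows Mapping result rows (data.frame).
#' @param format `"table"`, `"tsv"` or `"json"`.
#' @return Character vector of output lines.
#' @export
format_mapping_rows <- function(rows, format = c("table", "tsv", "json")) {
  format <- match.arg(format)
  if (format == "json") {
    return(jsonlite::toJSON(rows, dataframe = "rows", na = "null",
                            auto_unbox = TRUE, digits = NA, pretty = TRUE))
  }
  out <- rows
  for (j in seq_along(out)) out[[j]][is.na(out[[j]])] <- "-"
  if (format == "tsv") {
    header <- paste(names(out), collapse = "\t")
    body <- apply(out, 1L, paste, collapse = "\t")
    return(c(header, body))
  }
  if (nrow(out) > 0L) {
    rep_rows <- c(FALSE, out$input[-1L] == out$input[-nrow(out)])
    out$input[rep_rows] <- "-"
    out$input_dataset[rep_rows] <- "-"
  }
  widths <- vapply(seq_along(out), function(j)
    max(nchar(c(names(out)[j], out[[j]]), type = "width")), 0L)
  fmt_row <- function(cells) {
    paste(mapply(formatC, cells, width = widths, MoreArgs = list(flag = "-")),
          collapse = "  ")
  }
  c(fmt_row(names(out)), if (nrow(out)) apply(out, 1L, fmt_row))
}

cli_usage <- function() {
  c("usage: xrefdb <verb> [options]",
    "",
    "verbs:",
    "  build  --config <build.yml> --out <dir> [--taxa id,id,...]",
    "         [--buffer N] [--fan-in N] [--workers N] [--verbose]",
    "  query  --store <dir> --terms <t1,t2> --query <text>",
    "         [--source <dataset>] [--attrs <selector>] [--format table|tsv|json]",
    "  web    --store <dir> [--port N] [--max-requests N]",
    "",
    "exit codes: 0 ok, 1 user error, 2 internal error")
}

parse_cli_flags <- function(args) {
  flags <- list(); positional <- character()
  i <- 1L
  while (i <= length(args)) {
    a <- args[[i]]
    if (startsWith(a, "--")) {
      key <- substring(a, 3L)
      if (key %in% c("verbose")) {
        flags[[key]] <- TRUE
        i <- i + 1L
      } else {
        if (i == length(args)) xr_abort("xrefdb_config_error", sprintf("flag --%s needs a value", key))
        flags[[key]] <- args[[i + 1L]]
        i <- i + 2L
      }
    } else {
      positional <- c(positional, a)
      i <- i + 1L
    }
  }
  list(flags = flags, positional = positional)
}

# Build config YAML: registry: <path or "default">; sources: {dataset: [paths]}.
read_build_yaml <- function(path, base_dir = dirname(path)) {
  if (!file.exists(path)) xr_abort("xrefdb_config_error", sprintf("config not found: %s", path))
  cfg <- yaml::read_yaml(path)
  registry <- if (is.null(cfg$registry) || identical(cfg$registry, "default")) {
    default_registry()
  } else {
    rp <- cfg$registry
    if (!file.exists(rp)) rp <- file.path(base_dir, cfg$registry)
    load_registry(rp)
  }
  sources <- lapply(cfg$sources, function(paths) {
    paths <- unlist(paths)
    vapply(paths, function(p) if (file.exists(p)) p else file.path(base_dir, p), "")
  })
  list(registry = registry, sources = sources)
}

#' Command-line entry point
#'
#' @param args Character vector of command-line arguments (after the
#'   program name).
#' @param out Connection or `""` for result output.
#' @return Integer exit status: 0 ok, 1 user error, 2 internal error.
#' @export
cli_main <- function(args = commandArgs(trailingOnly = TRUE), out = stdout()) {
  emit <- function(lines) writeLines(lines, con = out)
  if (length(args) == 0L) { emit(cli_usage()); return(1L) }
  verb <- args[[1L]]
  tryCatch({
    parsed <- parse_cli_flags(args[-1L])
    flags <- parsed$flags
    if (verb == "build") {
      if (is.null(flags$config) || is.null(flags$out)) {
        xr_abort("xrefdb_config_error", "build needs --config and --out")
      }
      cfg <- read_build_yaml(flags$config)
      taxa <- if (is.null(flags$taxa)) NULL else trimws(strsplit(flags$taxa, ",")[[1L]])
      store <- build_db(build_config(
        sources = cfg$sources, out_dir = flags$out, registry = cfg$registry,
        taxonomy_ids = taxa,
        buffer_size = as.integer(flags$buffer %||% 100000L),
        fan_in = as.integer(flags$`fan-in` %||% 8L),
        workers = as.integer(flags$workers %||% 1L),
        verbose = isTRUE(flags$verbose)))
      emit(sprintf("built store at %s: %d keys", store$dir, store$entry_count))
      0L
    } else if (verb == "query") {
      if (is.null(flags$store) || is.null(flags$terms) || is.null(flags$query)) {
        xr_abort("xrefdb_config_error", "query needs --store, --terms and --query")
      }
      store <- store_open(flags$store)
      rows <- execute_mapping_all(store, flags$terms, flags$query,
                                  source = flags$source, attrs = flags$attrs)
      emit(format_mapping_rows(rows, format = flags$format %||% "table"))
      0L
    } else if (verb == "web") {
      if (is.null(flags$store)) xr_abort("xrefdb_config_error", "web needs --store")
      store <- store_open(flags$store)
      serve_db(store, port = as.integer(flags$port %||% 8765L),
               max_requests = as.numeric(flags$`max-requests` %||% Inf))
      0L
    } else {
      emit(cli_usage())
      1L
    }
  },
  xrefdb_error = function(e) { message("error: ", conditionMessage(e)); 1L },
  error = function(e) { message("internal error: ", conditionMessage(e)); 2L })
}

# -- web service --------------------------------------------------------------

ws_response <- function(status, body) list(status = status, body = body)

ws_error_body <- function(e) {
  body <- list(error = conditionMessage(e))
  if (!is.null(e$position)) body$position <- e$position
  body
}

#' Handle a web-service request against a read-mode store
#'
#' Endpoints: `GET /ws/search?term=...&page=<token>` (exact lookup plus
#' prefix hits) and `GET /ws/map?i=<terms>&m=<query>[&s=<source>]
#' [&attrs=<selector>][&page=<token>]`. Stateless between requests;
#' responses are JSON-ready lists. Malformed queries give 400 with the
#' syntax position; unknown endpoints 404; unmatched terms 200 with empty
#' rows.
#'
#' @param store A read-mode `xref_store`.
#' @param path Request path, e.g. `"/ws/map"`.
#' @param params Named list of decoded query parameters.
#' @return `list(status, body)` where `body` is a JSON-serializable list.
#' @export
http_handle <- function(store, path, params = list()) {
  tryCatch({
    if (path == "/ws/search") {
      term <- params$term
      if (is.null(term)) xr_abort("xrefdb_syntax_error", "missing 'term' parameter", position = 1L)
      hits <- tryCatch(store_lookup(store, term), xrefdb_invalid_term = function(e) list())
      exact <- lapply(hits, function(p) list(
        dataset = registry_name(store$registry, p$dataset_id),
        identifier = p$identifier, attrs = p$attrs,
        xrefs = data.frame(target = p$xrefs$target, id = p$xrefs$id,
                           stringsAsFactors = FALSE)))
      pg <- prefix_search(store, term,
                          page_size = as.integer(params$page_size %||% 200L),
                          token = params$page)
      ws_response(200L, list(term = term, results = exact,
                             prefix = pg$items, next_page = pg$next_token))
    } else if (path == "/ws/map") {
      if (is.null(params$i) || is.null(params$m)) {
        xr_abort("xrefdb_syntax_error", "map needs 'i' (terms) and 'm' (query)", position = 1L)
      }
      res <- execute_mapping(store, params$i, params$m, source = params$s,
                             attrs = params$attrs,
                             page_size = as.integer(params$page_size %||% 200L),
                             token = params$page)
      ws_response(200L, list(rows = res$rows, next_page = res$next_token))
    } else {
      ws_response(404L, list(error = sprintf("unknown endpoint %s", path)))
    }
  },
  xrefdb_syntax_error = function(e) ws_response(400L, ws_error_body(e)),
  xrefdb_semantic_error = function(e) ws_response(400L, ws_error_body(e)),
  xrefdb_selector_error = function(e) ws_response(400L, ws_error_body(e)),
  xrefdb_token_error = function(e) ws_response(400L, ws_error_body(e)),
  xrefdb_error = function(e) ws_response(400L, ws_error_body(e)))
}

parse_query_string <- function(qs) {
  if (is.null(qs) || !nzchar(qs)) return(list())
  out <- list()
  for (kv in strsplit(qs, "&", fixed = TRUE)[[1L]]) {
    eq <- regexpr("=", kv, fixed = TRUE)
    if (eq < 0L) next
    key <- utils::URLdecode(substr(kv, 1L, eq - 1L))
    val <- utils::URLdecode(chartr("+", " ", substring(kv, eq + 1L)))
    out[[key]] <- val
  }
  out
}

#' Serve a store over HTTP (blocking)
#'
#' A deliberately small single-threaded HTTP/1.0 server: one request per
#' connection, JSON responses, endpoints as in [http_handle()]. Intended
#' for local pipeline use, mirroring a start-server-then-query workflow.
#'
#' @param store A read-mode `xref_store`.
#' @param port TCP port.
#' @param max_requests Stop after this many requests (for scripted use).
#' @export
serve_db <- function(store, port = 8765L, max_requests = Inf) {
  stopifnot_mode(store, "read")
  served <- 0
  while (served < max_requests) {
    con <- suppressWarnings(socketConnection(
      host = "127.0.0.1", port = port, server = TRUE, blocking = TRUE,
      open = "r+b", timeout = 30))
    req <- tryCatch(readLines(con, n = 1L), error = function(e) character())
    if (length(req) == 1L && nzchar(req)) {
      parts <- strsplit(req, " ", fixed = TRUE)[[1L]]
      target <- if (length(parts) >= 2L) parts[2L] else "/"
      q <- regexpr("?", target, fixed = TRUE)
      path <- if (q > 0L) substr(target, 1L, q - 1L) else target
      params <- if (q > 0L) parse_query_string(substring(target, q + 1L)) else list()
      resp <- http_handle(store, path, params)
      body <- jsonlite::toJSON(resp$body, auto_unbox = TRUE, digits = NA,
                               na = "null", dataframe = "rows")
      payload <- charToRaw(paste0(
        sprintf("HTTP/1.0 %d %s\r\n", resp$status,
                c(`200` = "OK", `400` = "Bad Request", `404` = "Not Found")[as.character(resp$status)]),
        "Content-Type: application/json\r\n",
        sprintf("Content-Length: %d\r\n\r\n", nchar(body, type = "bytes")),
        body))
      writeBin(payload, con)
      served <- served + 1
    }
    close(con)
  }
  invisible(served)
}
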