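list_stream <- function(pairs) {
  i <- 0L
  list(nxt = function() {
    i <<- i + 1L
    if (i > length(pairs)) NULL else pairs[[i]]
  }, close = function() invisible())
}

kv_pair <- function(key, id = tolower(key)) {
  list(key = key, value = encode_payload_list(list(new_payload(1L, id))))
}

test_that("batch insert preserves stream order and rejects out-of-order keys", {
  st <- store_create(tempfile("st-"))
  st <- store_finalize(batch_insert(st, list_stream(list(
    kv_pair("A"), kv_pair("B"), kv_pair("C")))))
  expect_identical(st$keys, c("A", "B", "C"))
  expect_identical(st$entry_count, 3L)

  st2 <- store_create(tempfile("st-"))
  expect_error(batch_insert(st2, list_stream(list(kv_pair("B"), kv_pair("A")))),
               class = "xrefdb_ordering")
  expect_error(store_lookup(st2, "B"), class = "xrefdb_state_error")
  expect_error(store_open(tempfile("missing-")), class = "xrefdb_state_error")
})

test_that("every fixture identifier and keyword resolves to its ground-truth entry", {
  tu <- test_universe()
  st <- tu$store
  reg <- default_registry()
  nodes <- tu$u$graph$nodes
  for (node in nodes) {
    hits <- store_lookup(st, node$identifier, source = node$dataset)
    expect_length(hits, 1L)
    hit <- hits[[1]]
    want <- merge_payloads(list(new_payload(registry_id(reg, node$dataset),
                                            node$identifier, node$attrs, node$xrefs)))[[1]]
    expect_identical(hit, want)
  }
  # species names and gene symbols are search keys too
  sp <- Filter(function(n) n$dataset == "taxonomy" && identical(n$attrs$rank, "species"),
               nodes)[[1]]
  by_name <- store_lookup(st, tolower(sp$attrs$scientific_name))
  expect_true(sp$identifier %in% vapply(by_name, `[[`, "", "identifier"))
  expect_identical(store_lookup(st, "never ingested term"), list())
})

test_that("prefix search agrees with a linear scan and pages without loss", {
  tu <- test_universe()
  st <- tu$store
  all_term_keys <- st$keys[startsWith(st$keys, "T\x1f")]
  scan_oracle <- function(prefix) {
    norm <- normalize_key(prefix)
    sort(xrefdb:::strip_term_key(
      all_term_keys[startsWith(xrefdb:::strip_term_key(all_term_keys), norm)]),
      method = "radix")
  }
  collect_pages <- function(prefix, page_size) {
    token <- NULL; items <- list()
    repeat {
      pg <- prefix_search(st, prefix, page_size = page_size, token = token)
      items[[length(items) + 1L]] <- pg$items
      token <- pg$next_token
      if (is.null(token)) break
    }
    do.call(rbind, items)
  }
  set.seed(9)
  prefixes <- c("GO:00", "ensg", "GN", "ENST", "hgnc:", "genus", "P0", "ZZZ")
  for (p in prefixes) {
    got <- collect_pages(p, page_size = 7L)
    expect_identical(sort(unique(got$key), method = "radix"), scan_oracle(p))
    expect_false(any(duplicated(paste(got$key, got$dataset, got$identifier))))
    # page size must not change the result
    expect_identical(collect_pages(p, page_size = 200L), got)
  }
  pg <- prefix_search(st, "GO:00", page_size = 2L)
  expect_identical(nrow(pg$items), 2L)
  expect_error(prefix_search(st, "GO", token = "not a token"),
               class = "xrefdb_token_error")
  expect_error(prefix_search(st, "GO", page_size = 0L), class = "xrefdb_config_error")
})

test_that("identical inputs build byte-identical stores", {
  u <- test_universe()$u
  md5 <- function(store) unname(tools::md5sum(file.path(store$dir, "data.xr")))
  s1 <- build_db(build_config(u$sources, out_dir = tempfile("det1-"),
                              buffer_size = 777L, fan_in = 3L))
  s2 <- build_db(build_config(u$sources, out_dir = tempfile("det2-"),
                              buffer_size = 50L, fan_in = 8L, workers = 2L))
  expect_identical(md5(s1), md5(s2))
  expect_identical(md5(s1), md5(test_universe()$store))
})

test_that("every pair emitted by the global merge is retrievable after insert", {
  dir <- withr::local_tempdir()
  set.seed(77)
  ids <- sprintf("K%04d", sample.int(500L, 1000L, replace = TRUE))
  keys <- paste0("T\x1f", ids)
  payloads <- lapply(ids, function(i) new_payload(1L, i))
  chunks <- lapply(split(seq_along(keys), (seq_along(keys) - 1L) %/% 100L),
                   function(idx) spill_chunk(list(keys = keys[idx],
                                                  payloads = payloads[idx]), dir))
  merged <- collect_stream(global_merge(unname(chunks)), decode = FALSE)
  st <- store_create(tempfile("st-"))
  batch_insert(st, list_stream(merged))
  st <- store_finalize(st)
  for (item in merged[seq(1L, length(merged), by = 7L)]) {
    expect_identical(xrefdb:::store_get(st, item$key), item$value)
  }
  expect_identical(st$entry_count, length(merged))
})
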