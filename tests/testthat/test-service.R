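test_that("a full build passes the store oracles and logs stage counters", {
  tu <- test_universe()
  st <- tu$store
  expect_identical(st$mode, "read")
  expect_identical(st$entry_count, length(st$keys))
  expect_gt(st$build_stats$chunks_spilled, 0L)
  expect_identical(st$build_stats$records_dropped_by_taxa, 0L)
  expect_error(build_config(list(), out_dir = tempfile()), class = "xrefdb_config_error")
  expect_error(build_config(list(nosuch = "x.tsv"), out_dir = tempfile()),
               class = "xrefdb_unknown_dataset")
})

test_that("a taxon-restricted build contains exactly that taxon's genome", {
  u <- test_universe()$u
  graph <- u$graph
  species <- unique(vapply(Filter(function(n)
    n$dataset == "taxonomy" && identical(n$attrs$rank, "species"), graph$nodes),
    `[[`, "", "identifier", USE.NAMES = FALSE))
  keep <- species[1L]
  st <- build_db(build_config(u$sources, out_dir = tempfile("taxa-"),
                              taxonomy_ids = keep))
  in_taxon <- function(node) {
    any(node$xrefs$target == "taxonomy" & node$xrefs$id == keep)
  }
  for (node in graph$nodes) {
    if (!node$dataset %in% c("ensembl", "transcript", "uniprot")) next
    hits <- store_lookup(st, node$identifier, source = node$dataset)
    if (in_taxon(node)) {
      expect_length(hits, 1L)
    } else {
      expect_length(hits, 0L)
    }
  }
  # the restricted taxon itself resolves; unrelated species do not
  expect_length(store_lookup(st, keep, source = "taxonomy"), 1L)
  expect_length(store_lookup(st, species[2L], source = "taxonomy"), 0L)
})

test_that("the CLI builds, queries, and its TSV output round-trips the API rows", {
  u <- test_universe()$u
  cfg <- tempfile(fileext = ".yml")
  yaml::write_yaml(list(registry = "default",
                        sources = lapply(u$sources, as.list)), cfg)
  out_dir <- tempfile("cli-store-")
  log1 <- tempfile()
  status <- withr::with_output_sink(log1, cli_main(c(
    "build", "--config", cfg, "--out", out_dir, "--buffer", "400")))
  expect_identical(status, 0L)

  gene <- "ENSG00000001"
  qtext <- "map(transcript).map(affy_hg_u133_plus_2)"
  tsv_file <- tempfile()
  status <- withr::with_output_sink(tsv_file, cli_main(c(
    "query", "--store", out_dir, "--terms", gene, "--query", qtext,
    "--attrs", "seq_region,start", "--format", "tsv")))
  expect_identical(status, 0L)
  got <- utils::read.delim(tsv_file, stringsAsFactors = FALSE, check.names = FALSE)
  api <- execute_mapping_all(store_open(out_dir), gene, qtext,
                             attrs = "seq_region,start")
  api$start <- as.character(NA)
  got$start <- as.character(NA)   # probes carry no coordinates: both columns empty
  expect_identical(got$mapping_id, api$mapping_id)
  expect_identical(names(got), names(api))

  # aligned table output puts mapping_id before the selected attributes
  tab <- format_mapping_rows(execute_mapping_all(
    test_worked_examples()$store, "59201",
    'map(taxchild).map(ensembl).filter(ensembl.start<10000&&ensembl.description.contains("SopD"))',
    attrs = "strand,start,end"))
  expect_match(tab[1], "mapping_id\\s+strand\\s+start\\s+end")

  expect_identical(suppressMessages(cli_main(c("query", "--store", tempfile(),
                                               "--terms", "x", "--query", "map(go)"))), 1L)
  expect_identical(withr::with_output_sink(tempfile(), cli_main(c("frobnicate"))), 1L)
  expect_identical(withr::with_output_sink(tempfile(), cli_main(character())), 1L)
})

test_that("web handlers mirror library results and report errors by status", {
  tp <- test_worked_examples()
  st <- tp$store
  q <- tp$pc$queries$uc1
  resp <- http_handle(st, "/ws/map", list(i = q$terms, m = q$query,
                                          s = q$source, attrs = q$attrs))
  expect_identical(resp$status, 200L)
  api <- execute_mapping(st, q$terms, q$query, source = q$source, attrs = q$attrs)
  expect_identical(resp$body$rows, api$rows)

  bad <- http_handle(st, "/ws/map", list(i = "x", m = "map()"))
  expect_identical(bad$status, 400L)
  expect_identical(bad$body$position, 5L)
  expect_identical(http_handle(st, "/ws/nope")$status, 404L)
  empty <- http_handle(st, "/ws/map", list(i = "UNKNOWN_TERM", m = "map(go)"))
  expect_identical(empty$status, 200L)
  expect_identical(nrow(empty$body$rows), 0L)

  sr <- http_handle(st, "/ws/search", list(term = "homo sapiens"))
  expect_identical(sr$status, 200L)
  expect_identical(sr$body$results[[1]]$identifier, "9606")

  # token walk over map pages: complete and duplicate-free
  token <- NULL; seen <- character()
  repeat {
    pg <- http_handle(st, "/ws/map", list(i = q$terms, m = q$query, s = q$source,
                                          page_size = "4", page = token))
    seen <- c(seen, paste(pg$body$rows$input, pg$body$rows$mapping_id))
    token <- pg$body$next_page
    if (is.null(token)) break
  }
  full <- execute_mapping_all(st, q$terms, q$query, source = q$source)
  expect_identical(sort(seen), sort(paste(full$input, full$mapping_id)))
  expect_false(any(duplicated(seen)))
})

test_that("CLI, web and library routes return identical row multisets", {
  tp <- test_worked_examples()
  st <- tp$store
  q <- tp$pc$queries$uc3
  lib <- execute_mapping_all(st, q$terms, q$query, attrs = q$attrs)
  web <- http_handle(st, "/ws/map", list(i = q$terms, m = q$query, attrs = q$attrs))
  tsv_file <- tempfile()
  withr::with_output_sink(tsv_file, cli_main(c(
    "query", "--store", st$dir, "--terms", q$terms, "--query", q$query,
    "--attrs", q$attrs, "--format", "tsv")))
  cli <- utils::read.delim(tsv_file, stringsAsFactors = FALSE, check.names = FALSE,
                           colClasses = "character")
  expect_identical(web$body$rows, lib)
  expect_identical(cli$mapping_id, lib$mapping_id)
  expect_identical(cli$start, as.character(lib$start))
})

test_that("the shipped registry file reproduces the built-in registry", {
  path <- system.file("extdata", "registry.yml", package = "xrefdb")
  reg <- load_registry(path)
  def <- default_registry()
  expect_identical(reg$datasets, def$datasets)
  expect_identical(sort(names(reg$specs)), sort(names(def$specs)))
  expect_identical(unname(reg$relations["taxchild"]), "taxonomy")
  expect_error(load_registry(tempfile()), class = "xrefdb_config_error")
})
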