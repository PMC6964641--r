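write_tmp <- function(lines, ext = ".txt", gz = FALSE) {
  path <- tempfile(fileext = if (gz) paste0(ext, ".gz") else ext)
  if (gz) {
    con <- gzfile(path, "wt")
    writeLines(lines, con)
    close(con)
  } else writeLines(lines, path)
  path
}

test_that("TSV lines map to records per the column spec", {
  reg <- tiny_registry()
  path <- write_tmp("CHEBI:15377\twater\tKEGG:C00001")
  res <- ingest_tsv(path, reg$specs[["chebi"]], "chebi", reg)
  expect_length(res$records, 1L)
  rec <- res$records[[1]]
  expect_identical(rec$identifier, "CHEBI:15377")
  expect_identical(rec$attrs$name, "water")
  expect_identical(rec$xrefs, list(target = "kegg", id = "C00001"))
})

test_that("empty streams yield empty iterators", {
  reg <- tiny_registry()
  path <- write_tmp(character())
  res <- ingest_tsv(path, reg$specs[["chebi"]], "chebi", reg)
  expect_length(res$records, 0L)
  expect_identical(res$stats$records_emitted, 0L)
})

test_that("record counts equal lines minus malformed, and the bad-line threshold trips", {
  reg <- tiny_registry()
  set.seed(5)
  n <- 10000L
  lines <- sprintf("CHEBI:%05d\tname %d\tKEGG:C%05d", 1:n, 1:n, 1:n)
  bad <- sample(n, 30L)            # 0.3% malformed: missing identifier
  lines[bad] <- sprintf("\tname %d\t", bad)
  path <- write_tmp(lines)
  res <- ingest_tsv(path, reg$specs[["chebi"]], "chebi", reg)
  expect_identical(res$stats$records_emitted, n - 30L)
  expect_identical(res$stats$records_skipped, 30L)
  expect_identical(res$stats$records_emitted + res$stats$records_skipped, n)

  lines[sample(n, 500L)] <- ""      # blank lines are dropped, not malformed
  lines[1:200] <- "\tonly-name\t"   # push past the 1% threshold
  expect_error(ingest_tsv(write_tmp(lines), reg$specs[["chebi"]], "chebi", reg),
               class = "xrefdb_format_error")
})

test_that("ingest memory is bounded by the configured block size", {
  reg <- tiny_registry()
  lines <- sprintf("CHEBI:%05d\tn%d\tKEGG:C%05d", 1:5000, 1:5000, 1:5000)
  res <- ingest_tsv(write_tmp(lines), reg$specs[["chebi"]], "chebi", reg,
                    block_size = 128L, emit = function(rec) NULL)
  expect_lte(res$stats$peak_buffered_records, 128L)
  expect_identical(res$stats$records_emitted, 5000L)
})

test_that("gzip-compressed streams are detected by magic bytes and match their plain twin", {
  reg <- tiny_registry()
  lines <- sprintf("CHEBI:%05d\tname %d\tKEGG:C%05d", 1:50, 1:50, 1:50)
  plain <- ingest_tsv(write_tmp(lines), reg$specs[["chebi"]], "chebi", reg)
  gz <- ingest_tsv(write_tmp(lines, gz = TRUE), reg$specs[["chebi"]], "chebi", reg)
  expect_identical(plain$records, gz$records)
})

test_that("JSON documents stream record objects from the configured array path", {
  reg <- default_registry()
  doc <- c('{"meta":{"note":"docs [ {bracket} in a string"},"response":{"docs":[',
           '{"hgnc_id":"HGNC:1509","symbol":"CASP8","ensembl_gene_id":"ENSG00000064012"},',
           '{"symbol":"NOID"},',
           '{"hgnc_id":"HGNC:2","symbol":"TWO","ensembl_gene_id":"ENSG00000000002"}',
           ']}}')
  res <- ingest_json(write_tmp(doc), reg$specs[["hgnc"]], "hgnc", reg,
                     max_bad_frac = 0.5)
  emitted <- Filter(function(r) r$dataset == "hgnc", res$records)
  expect_length(emitted, 2L)
  expect_identical(emitted[[1]]$keywords, "CASP8")
  expect_identical(emitted[[1]]$xrefs, list(target = "ensembl", id = "ENSG00000064012"))
  expect_identical(res$stats$records_skipped, 1L)     # record without identifier
  # derived reverse records re-key the gene with an hgnc cross-reference
  rev <- Filter(function(r) r$dataset == "ensembl", res$records)
  expect_identical(rev[[1]]$xrefs, list(target = "hgnc", id = "HGNC:1509"))
})

test_that("JSON-lines input streams line by line and invalid documents error with offset", {
  reg <- default_registry()
  spec <- reg$specs[["hgnc"]]
  spec$lines <- TRUE
  nd <- c('{"hgnc_id":"HGNC:10","symbol":"A","ensembl_gene_id":"ENSG1"}',
          '{"hgnc_id":"HGNC:11","symbol":"B","ensembl_gene_id":"ENSG2"}')
  res <- ingest_json(write_tmp(nd), spec, "hgnc", reg)
  expect_length(Filter(function(r) r$dataset == "hgnc", res$records), 2L)
  expect_error(ingest_json(write_tmp('{"response":{"docs":[{"hgnc_id":'),
                           reg$specs[["hgnc"]], "hgnc", reg),
               class = "xrefdb_format_error")
})

test_that("XML entries stream one record element at a time", {
  reg <- default_registry()
  xml <- c("<uniprot>",
           '  <entry reviewed="true">',
           "    <accession>P12345</accession>",
           "    <protein>",
           "      <name>Tetraspanin-6</name>",
           "      <name>TSPAN6</name>",
           "    </protein>",
           '    <dbReference type="ensembl" id="ENSG000TEST"/>',
           '    <dbReference type="go" id="GO:0005515"/>',
           '    <dbReference type="go" id="GO:0005515"/>',
           '    <dbReference type="taxonomy" id="9606"/>',
           "  </entry>",
           '  <entry reviewed="false">',
           "    <accession>Q00001</accession>",
           "    <protein><name>Other</name></protein>",
           "  </entry>",
           "</uniprot>")
  res <- ingest_xml(write_tmp(xml), reg$specs[["uniprot"]], "uniprot", reg)
  ups <- Filter(function(r) r$dataset == "uniprot", res$records)
  expect_length(ups, 2L)
  expect_identical(ups[[1]]$attrs$names, c("Tetraspanin-6", "TSPAN6"))
  expect_true(ups[[1]]$attrs$reviewed)
  expect_false(ups[[2]]$attrs$reviewed)
  # duplicate dbReference is emitted twice here; deduplication is the merge stage's job
  expect_identical(sum(ups[[1]]$xrefs$id == "GO:0005515"), 2L)
  merged <- merge_payloads(list(new_payload(1L, "P12345", xrefs = ups[[1]]$xrefs)))
  expect_identical(sum(merged[[1]]$xrefs$id == "GO:0005515"), 1L)
  # reverse record: the gene gains a uniprot cross-reference
  rev <- Filter(function(r) r$dataset == "ensembl", res$records)
  expect_identical(rev[[1]]$xrefs, list(target = "uniprot", id = "P12345"))
  expect_error(ingest_xml(write_tmp(c("<uniprot>", "<entry>", "<accession>X</accession>")),
                          reg$specs[["uniprot"]], "uniprot", reg),
               class = "xrefdb_format_error")
})

test_that("GFF3 genes carry coordinates, strand and description; transcripts link both ways", {
  reg <- default_registry()
  gff <- c("##gff-version 3",
           "##species taxon:9606",
           paste("X", "src", "gene", "100500000", "100501000", ".", "+", ".",
                 "ID=gene:ENSGTEST1;Name=SOPD1;description=test SopD protein",
                 sep = "\t"),
           paste("X", "src", "mRNA", "100500010", "100501000", ".", "+", ".",
                 "ID=transcript:ENSTTEST1;Parent=gene:ENSGTEST1", sep = "\t"),
           paste("X", "src", "gene", "bad", "100", ".", "+", ".", "ID=gene:BROKEN",
                 sep = "\t"))
  res <- ingest_gff3(write_tmp(gff), reg, max_bad_frac = 0.5)
  genes <- Filter(function(r) r$dataset == "ensembl" && length(r$attrs), res$records)
  expect_length(genes, 1L)
  g <- genes[[1]]
  expect_identical(g$identifier, "ENSGTEST1")
  expect_identical(g$attrs$seq_region, "X")
  expect_identical(g$attrs$start, 100500000)
  expect_identical(g$attrs$end, 100501000)
  expect_identical(g$attrs$strand, "+")
  expect_match(g$attrs$description, "SopD")
  expect_identical(g$keywords, "SOPD1")
  expect_true(any(g$xrefs$target == "taxonomy" & g$xrefs$id == "9606"))
  expect_identical(res$stats$records_skipped, 1L)   # non-numeric coordinates
  # gene gains its transcript edge through the derived reverse record
  rev <- Filter(function(r) r$dataset == "ensembl" && length(r$attrs) == 0L, res$records)
  expect_true(any(vapply(rev, function(r)
    any(r$xrefs$target == "transcript" & r$xrefs$id == "ENSTTEST1"), TRUE)))
  tx <- Filter(function(r) r$dataset == "transcript", res$records)
  expect_identical(tx[[1]]$xrefs$id[tx[[1]]$xrefs$target == "ensembl"], "ENSGTEST1")
})

test_that("fixture files round-trip the ground-truth graph exactly", {
  u <- test_universe()$u
  reg <- default_registry()
  collected <- list()
  for (ds in names(u$sources)) {
    if (ds == "transcript") next
    for (path in u$sources[[ds]]) {
      res <- ingest_dataset(path, ds, reg)
      collected <- c(collected, res$records)
    }
  }
  to_nodes <- function(records) {
    pay <- lapply(records, function(r)
      new_payload(registry_id(reg, r$dataset), r$identifier, r$attrs, r$xrefs))
    merged <- merge_payloads(pay)
    kw <- list()
    for (r in records) {
      if (length(r$keywords)) {
        k <- paste(r$dataset, r$identifier, sep = "\x01")
        kw[[k]] <- sort(unique(c(kw[[k]], r$keywords)))
      }
    }
    list(payloads = merged, keywords = kw)
  }
  got <- to_nodes(collected)
  want <- to_nodes(unname(u$graph$nodes))
  expect_identical(length(got$payloads), length(want$payloads))
  expect_identical(got$payloads, want$payloads)
  expect_identical(got$keywords[order(names(got$keywords), method = "radix")],
                   want$keywords[order(names(want$keywords), method = "radix")])
})
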