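# A hand-written fixture whose cross-reference graph encodes three classic
# worked examples end to end, plus decoy records that each filter must
# exclude:
#   1. microarray probe -> transcript -> gene -> molecular_function GO terms
#   2. species keyword -> genes in an X-chromosome window -> reviewed proteins
#   3. taxon -> direct taxonomic children -> genes near the origin whose
#      description mentions SopD
# Identifiers not asserted by the examples (transcripts, gene ids) are
# plausible synthetic intermediates.

uc1_go_p1 <- c(
  "GO:0002020" = "protease binding",
  "GO:0004190" = "aspartic-type endopeptidase activity",
  "GO:0004197" = "cysteine-type endopeptidase activity",
  "GO:0004861" = "cyclin-dependent protein serine/threonine kinase inhibitor activity",
  "GO:0005123" = "death receptor binding",
  "GO:0005515" = "protein binding",
  "GO:0008233" = "peptidase activity",
  "GO:0008234" = "cysteine-type peptidase activity",
  "GO:0016005" = "phospholipase A2 activator activity",
  "GO:0016787" = "hydrolase activity",
  "GO:0044877" = "protein-containing complex binding",
  "GO:0097153" = "cysteine-type endopeptidase activity involved in apoptotic process",
  "GO:0097199" = "cysteine-type endopeptidase activity involved in apoptotic signaling pathway",
  "GO:0097200" = "cysteine-type endopeptidase activity involved in execution phase of apoptosis")

uc1_go_p2 <- c(
  "GO:0004197" = "cysteine-type endopeptidase activity",
  "GO:0005515" = "protein binding",
  "GO:0008233" = "peptidase activity",
  "GO:0008234" = "cysteine-type peptidase activity",
  "GO:0016787" = "hydrolase activity",
  "GO:0050700" = "CARD domain binding",
  "GO:0097199" = "cysteine-type endopeptidase activity involved in apoptotic signaling pathway")

uc1_go_decoys <- c(
  "GO:0006915" = "apoptotic process",          # biological_process
  "GO:0005737" = "cytoplasm")                  # cellular_component

uc2_proteins <- c(
  O43657 = "Tetraspanin-6",
  Q9H2S6 = "Tenomodulin",
  Q9Y5S8 = "NADPH oxidase 1",
  P33240 = "Cleavage stimulation factor subunit 2",
  O60687 = "Sushi repeat-containing protein SRPX2",
  Q96C24 = "Synaptotagmin-like protein 4",
  Q8TAB3 = "Protocadherin-19",
  Q5H913 = "ADP-ribosylation factor-like protein 13A",
  Q6PP77 = "XK-related protein 2")

uc2_symbols <- c("TSPAN6", "TNMD", "NOX1", "CSTF2", "SRPX2", "SYTL4",
                 "PCDH19", "ARL13A", "XKR2")

uc3_genes <- data.frame(
  id = c("ACH54_23895", "ACH56_04205", "AEW14_05145", "AEW14_15935",
         "DE27_21250", "DE87_06330", "LPMST02_21800"),
  strand = c("+", "-", "-", "-", "+", "+", "+"),
  start = c(2525, 27, 3410, 1, 8885, 7839, 8983),
  end = c(3484, 986, 4369, 89, 9967, 8921, 10065),
  taxon = c("595", "595", "984254", "984254", "465517", "465517", "1249525"),
  stringsAsFactors = FALSE)

#' The worked-example fixture
#'
#' Emits the fixture's dataset files (same formats as
#' [generate_universe()]) and the ground-truth graph encoding the three
#' worked examples, including the decoy records every filter must exclude:
#' GO terms outside molecular_function, genes at or beyond each window
#' boundary, an unreviewed protein, an off-chromosome gene, a gene whose
#' description lacks the searched word, and a grandchild taxon whose genes
#' a single direct-children hop must not reach.
#'
#' @param dir Output directory.
#' @return `list(sources, graph, expected, queries)`: `expected` holds the
#'   mapping-id sets each example query must return; `queries` the query
#'   strings, input terms, sources and attribute selectors.
#' @export
worked_example_fixture <- function(dir = tempfile("workedex-")) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  registry <- default_registry()
  graph <- new_graph(registry)

  # ---- taxonomy ----
  tax <- rbind(
    data.frame(id = "1", parent = NA, rank = "root", name = "root clade"),
    data.frame(id = "9605", parent = "1", rank = "genus", name = "Homo"),
    data.frame(id = "9606", parent = "9605", rank = "species", name = "Homo sapiens"),
    data.frame(id = "28901", parent = "1", rank = "species", name = "Salmonella enterica"),
    data.frame(id = "59201", parent = "28901", rank = "subspecies",
               name = "Salmonella enterica subsp. enterica"),
    data.frame(id = "595", parent = "59201", rank = "serovar", name = "Salmonella serovar A"),
    data.frame(id = "984254", parent = "59201", rank = "serovar", name = "Salmonella serovar B"),
    data.frame(id = "465517", parent = "59201", rank = "serovar", name = "Salmonella serovar C"),
    data.frame(id = "1249525", parent = "59201", rank = "serovar", name = "Salmonella serovar D"),
    data.frame(id = "595001", parent = "595", rank = "strain", name = "Salmonella strain decoy"))
  for (i in seq_len(nrow(tax))) {
    graph <- graph_add(graph, "taxonomy", tax$id[i],
                       attrs = list(scientific_name = tax$name[i], rank = tax$rank[i]),
                       keywords = tax$name[i])
  }
  for (i in seq_len(nrow(tax))) if (!is.na(tax$parent[i])) {
    graph <- graph_add_edge(graph, "taxonomy", tax$parent[i], "taxchild", tax$id[i])
  }

  # ---- GO terms ----
  go_all <- c(uc1_go_p1, uc1_go_p2[setdiff(names(uc1_go_p2), names(uc1_go_p1))])
  go_tab <- data.frame(id = names(go_all), name = unname(go_all),
                       type = "molecular_function", stringsAsFactors = FALSE)
  go_tab <- rbind(go_tab, data.frame(id = names(uc1_go_decoys),
                                     name = unname(uc1_go_decoys),
                                     type = c("biological_process", "cellular_component")))
  for (i in seq_len(nrow(go_tab))) {
    graph <- graph_add(graph, "go", go_tab$id[i],
                       attrs = list(name = go_tab$name[i], type = go_tab$type[i]))
  }

  # ---- human genes ----
  # Two probe-bearing genes for example 1 (off the X window), nine window
  # genes for example 2, and the boundary/reviewed/chromosome decoys.
  hum <- list()
  add_hum <- function(id, name, chrom, start, end, strand, desc, acc = NA,
                      reviewed = NA, gos = character(), tids = character(),
                      probes = list()) {
    hum[[length(hum) + 1L]] <<- list(
      id = id, name = name, chrom = chrom, start = start, end = end,
      strand = strand, desc = desc, acc = acc, reviewed = reviewed,
      gos = gos, tids = tids, probes = probes)
  }
  add_hum("ENSG00000064012", "CASP8", "2", 201233443, 201287711, "+",
          "caspase 8", gos = c(names(uc1_go_p1), names(uc1_go_decoys)),
          tids = "ENST00000323492", probes = list(ENST00000323492 = "202763_at"))
  add_hum("ENSG00000003400", "CASP10", "2", 201182900, 201229406, "+",
          "caspase 10", gos = c(names(uc1_go_p2), names(uc1_go_decoys)),
          tids = "ENST00000286186", probes = list(ENST00000286186 = "209310_s_at"))
  uc2_acc <- names(uc2_proteins)
  for (i in seq_along(uc2_acc)) {
    start <- 100050000 + (i - 1L) * 90000
    add_hum(sprintf("ENSG0000000%04d", i), uc2_symbols[i], "X",
            start, start + 30000, if (i %% 2L) "+" else "-",
            sprintf("%s gene", uc2_symbols[i]),
            acc = uc2_acc[i], reviewed = TRUE)
  }
  add_hum("ENSG00000900001", "DECOYB1", "X", 100000000, 100030000, "+",
          "window start boundary decoy", acc = "P99901", reviewed = TRUE)
  add_hum("ENSG00000900002", "DECOYU1", "X", 100500001, 100530001, "-",
          "unreviewed protein decoy", acc = "Q99902", reviewed = FALSE)
  add_hum("ENSG00000900003", "DECOYC7", "7", 100400000, 100430000, "+",
          "off-chromosome decoy", acc = "P99903", reviewed = TRUE)
  add_hum("ENSG00000900004", "DECOYO1", "X", 101200000, 101230000, "-",
          "out-of-window decoy", acc = "P99904", reviewed = TRUE)
  add_hum("ENSG00000900005", "DECOYE1", "X", 100900000, 101000000, "+",
          "window end boundary decoy", acc = "P99905", reviewed = TRUE)

  for (g in hum) {
    xt <- c(rep("go", length(g$gos)), "taxonomy", rep("transcript", length(g$tids)))
    xi <- c(g$gos, "9606", g$tids)
    if (!is.na(g$acc)) { xt <- c(xt, "uniprot"); xi <- c(xi, g$acc) }
    graph <- graph_add(graph, "ensembl", g$id,
                       attrs = list(seq_region = g$chrom, start = as.double(g$start),
                                    end = as.double(g$end), strand = g$strand,
                                    name = g$name, description = g$desc),
                       xrefs = list(target = xt, id = xi), keywords = g$name)
    graph <- graph_add_edge(graph, "taxonomy", "9606", "ensembl", g$id)
    for (tid in g$tids) {
      graph <- graph_add(graph, "transcript", tid,
                         attrs = list(seq_region = g$chrom, start = as.double(g$start + 10),
                                      end = as.double(g$end), strand = g$strand),
                         xrefs = list(
                           target = c("ensembl", "taxonomy",
                                      rep("affy_hg_u133_plus_2", length(g$probes[[tid]]))),
                           id = c(g$id, "9606", g$probes[[tid]])))
      for (pr in g$probes[[tid]]) {
        graph <- graph_add(graph, "affy_hg_u133_plus_2", pr,
                           xrefs = list(target = "transcript", id = tid))
      }
    }
    if (!is.na(g$acc)) {
      pname <- if (g$acc %in% uc2_acc) unname(uc2_proteins[g$acc])
               else sprintf("Decoy protein %s", g$name)
      graph <- graph_add(graph, "uniprot", g$acc,
                         attrs = list(reviewed = g$reviewed,
                                      names = c(pname, g$name)),
                         xrefs = list(target = c("ensembl", "taxonomy"),
                                      id = c(g$id, "9606")))
    }
  }

  # ---- bacterial genes ----
  bac <- uc3_genes
  bac_extra <- data.frame(
    id = c("ACH54_99999", "ACH56_88888", "GRAND_00001"),
    strand = c("+", "-", "+"),
    start = c(10000, 500, 100),
    end = c(10959, 1400, 999),
    taxon = c("595", "595", "595001"),
    stringsAsFactors = FALSE)
  bac_desc <- c(rep("Secreted effector protein SopD", nrow(bac)),
                "Secreted effector protein SopD boundary decoy",
                "Secreted effector protein SopE2",
                "Secreted effector protein SopD grandchild decoy")
  bac <- rbind(bac, bac_extra)
  for (i in seq_len(nrow(bac))) {
    graph <- graph_add(graph, "ensembl", bac$id[i],
                       attrs = list(seq_region = "Chromosome",
                                    start = as.double(bac$start[i]),
                                    end = as.double(bac$end[i]),
                                    strand = bac$strand[i],
                                    name = bac$id[i], description = bac_desc[i]),
                       xrefs = list(target = "taxonomy", id = bac$taxon[i]),
                       keywords = bac$id[i])
    graph <- graph_add_edge(graph, "taxonomy", bac$taxon[i], "ensembl", bac$id[i])
  }

  files <- write_worked_example_files(dir, tax, go_tab, hum, bac, bac_desc, uc2_acc)

  expected <- list(
    uc1 = list(`202763_AT` = names(uc1_go_p1), `209310_S_AT` = names(uc1_go_p2)),
    uc2 = list(accessions = names(uc2_proteins), names1 = unname(uc2_proteins)),
    uc3 = uc3_genes)
  queries <- list(
    uc1 = list(terms = "202763_at,209310_s_at",
               query = 'map(transcript).map(ensembl).map(go).filter(go.type=="molecular_function")',
               source = "affy_hg_u133_plus_2", attrs = "name"),
    uc2 = list(terms = "homo sapiens",
               query = 'map(ensembl).filter(ensembl.within(100000000,101000000) && ensembl.seq_region=="X").map(uniprot).filter(uniprot.reviewed)',
               source = NULL, attrs = "names[1]"),
    uc3 = list(terms = "59201",
               query = 'map(taxchild).map(ensembl).filter(ensembl.start<10000&&ensembl.description.contains("SopD"))',
               source = NULL, attrs = "strand,start,end"))
  list(sources = files, graph = graph, expected = expected, queries = queries)
}

write_worked_example_files <- function(dir, tax, go_tab, hum, bac, bac_desc, uc2_acc) {
  wl <- function(lines, name) {
    path <- file.path(dir, name)
    writeLines(lines, path)
    path
  }
  tax_lines <- c("<taxonomy>", vapply(seq_len(nrow(tax)), function(i) {
    pa <- if (is.na(tax$parent[i])) "" else sprintf(' parent="%s"', tax$parent[i])
    sprintf('  <taxon id="%s"%s rank="%s"><name>%s</name></taxon>',
            tax$id[i], pa, tax$rank[i], xml_escape(tax$name[i]))
  }, ""), "</taxonomy>")
  taxonomy <- wl(tax_lines, "taxonomy.xml")

  go <- wl(c("id\tname\ttype",
             sprintf("%s\t%s\t%s", go_tab$id, go_tab$name, go_tab$type)), "go.tsv")

  hum_lines <- c("##gff-version 3", "##species taxon:9606")
  for (g in hum) {
    a9 <- sprintf("ID=gene:%s;Name=%s;description=%s", g$id, g$name, g$desc)
    if (length(g$gos)) a9 <- paste0(a9, ";Ontology_term=", paste(g$gos, collapse = ","))
    hum_lines <- c(hum_lines, sprintf("%s\tsynthetic\tgene\t%d\t%d\t.\t%s\t.\t%s",
                                      g$chrom, g$start, g$end, g$strand, a9))
    for (tid in g$tids) {
      hum_lines <- c(hum_lines,
        sprintf("%s\tsynthetic\tmRNA\t%d\t%d\t.\t%s\t.\tID=transcript:%s;Parent=gene:%s",
                g$chrom, g$start + 10, g$end, g$strand, tid, g$id))
    }
  }
  gff_h <- wl(hum_lines, "ensembl_9606.gff3")

  gff_b <- character()
  for (tx in unique(bac$taxon)) {
    lines <- c("##gff-version 3", sprintf("##species taxon:%s", tx))
    sel <- which(bac$taxon == tx)
    for (i in sel) {
      lines <- c(lines,
        sprintf("Chromosome\tsynthetic\tgene\t%d\t%d\t.\t%s\t.\tID=gene:%s;Name=%s;description=%s",
                bac$start[i], bac$end[i], bac$strand[i], bac$id[i], bac$id[i], bac_desc[i]))
    }
    gff_b <- c(gff_b, wl(lines, sprintf("ensembl_%s.gff3", tx)))
  }

  uni_lines <- "<uniprot>"
  for (g in hum) {
    if (is.na(g$acc)) next
    pname <- if (g$acc %in% uc2_acc) unname(uc2_proteins[g$acc])
             else sprintf("Decoy protein %s", g$name)
    uni_lines <- c(uni_lines,
      sprintf('  <entry reviewed="%s">', tolower(as.character(g$reviewed))),
      sprintf('    <accession>%s</accession>', g$acc),
      "    <protein>",
      sprintf('      <name>%s</name>', xml_escape(c(pname, g$name))),
      "    </protein>",
      sprintf('    <dbReference type="ensembl" id="%s"/>', g$id),
      sprintf('    <dbReference type="taxonomy" id="9606"/>'),
      "  </entry>")
  }
  uniprot <- wl(c(uni_lines, "</uniprot>"), "uniprot.xml")

  probe_lines <- character()
  for (g in hum) for (tid in g$tids) for (pr in g$probes[[tid]]) {
    probe_lines <- c(probe_lines, sprintf("%s\t%s", pr, tid))
  }
  affy <- wl(probe_lines, "probes.tsv")

  list(taxonomy = taxonomy, go = go,
       ensembl = c(gff_h, gff_b), uniprot = uniprot,
       affy_hg_u133_plus_2 = affy)
}
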