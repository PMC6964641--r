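# Deterministic synthetic universe: a taxonomy subtree, species with genes,
# transcripts, proteins (with reviewed flags), GO terms, probe sets,
# nomenclature and literature ids, emitted both as dataset files in every
# supported ingest format and as an in-memory ground-truth graph, plus a
# brute-force mapping oracle over that graph that shares no code with the
# chunk/store pipeline.

#' Parameters of the synthetic universe
#'
#' Defaults describe a small multi-species universe (a few thousand
#' entries) that exercises every dataset format and edge type while keeping
#' a full build-and-query round trip fast on one CPU.
#'
#' @param seed RNG seed; the same seed gives byte-identical files.
#' @param taxonomy_depth,branching Shape of the taxonomy tree below the root.
#' @param species_count Leaves that become species with genomes.
#' @param genes_per_species,transcripts_per_gene,probes_per_transcript Counts.
#' @param reviewed_prob Probability a protein is curated (reviewed).
#' @param go_terms GO term pool size; types are drawn uniformly from the
#'   three ontology namespaces.
#' @param go_per_protein GO cross-references per protein.
#' @param literature_prob Probability a protein has a literature id.
#' @param chrom_length Chromosome length range (bp).
#' @return A `universe_params` list.
#' @export
universe_params <- function(seed = 1L, taxonomy_depth = 3L, branching = 2L,
                            species_count = 6L, genes_per_species = 30L,
                            transcripts_per_gene = 2L, probes_per_transcript = 1L,
                            reviewed_prob = 0.7, go_terms = 60L,
                            go_per_protein = 3L, literature_prob = 0.3,
                            chrom_length = c(1e5, 1e6)) {
  p <- list(seed = as.integer(seed), taxonomy_depth = as.integer(taxonomy_depth),
            branching = as.integer(branching), species_count = as.integer(species_count),
            genes_per_species = as.integer(genes_per_species),
            transcripts_per_gene = as.integer(transcripts_per_gene),
            probes_per_transcript = as.integer(probes_per_transcript),
            reviewed_prob = reviewed_prob, go_terms = as.integer(go_terms),
            go_per_protein = as.integer(go_per_protein),
            literature_prob = literature_prob, chrom_length = chrom_length)
  counts <- unlist(p[c("taxonomy_depth", "branching", "species_count",
                       "genes_per_species", "transcripts_per_gene",
                       "probes_per_transcript", "go_terms", "go_per_protein")])
  if (any(counts < 0L)) xr_abort("xrefdb_config_error", "universe counts must be >= 0")
  probs <- c(p$reviewed_prob, p$literature_prob)
  if (any(probs < 0 | probs > 1)) xr_abort("xrefdb_config_error", "probabilities must be in [0,1]")
  leaves <- p$branching^p$taxonomy_depth
  if (p$species_count > leaves) {
    xr_abort("xrefdb_config_error",
             sprintf("species_count %d exceeds the %d taxonomy leaves", p$species_count, leaves))
  }
  structure(p, class = "universe_params")
}

with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# -- ground-truth graph -------------------------------------------------------

new_graph <- function(registry = default_registry()) {
  structure(list(nodes = list(), registry = registry), class = "xref_graph")
}

node_key <- function(dataset, id) paste(dataset, id, sep = "\x01")

graph_add <- function(graph, dataset, id, attrs = list(),
                      xrefs = list(target = character(), id = character()),
                      keywords = character()) {
  graph$nodes[[node_key(dataset, id)]] <-
    new_record(id, dataset, attrs, xrefs, keywords)
  graph
}

graph_add_edge <- function(graph, dataset, id, label, to_id) {
  k <- node_key(dataset, id)
  node <- graph$nodes[[k]]
  node$xrefs$target <- c(node$xrefs$target, label)
  node$xrefs$id <- c(node$xrefs$id, to_id)
  graph$nodes[[k]] <- node
  graph
}

#' @export
print.xref_graph <- function(x, ...) {
  ds <- vapply(x$nodes, `[[`, "", "dataset")
  cat(sprintf("<xref_graph: %d nodes>\n", length(x$nodes)))
  print(table(ds))
  invisible(x)
}

#' Node and edge counts of a ground-truth graph
#' @param graph An `xref_graph`.
#' @export
graph_counts <- function(graph) {
  list(nodes = length(graph$nodes),
       edges = sum(vapply(graph$nodes, function(n) length(n$xrefs$target), 0L)))
}

# -- generator ----------------------------------------------------------------

word_pool <- c("secreted", "effector", "kinase", "transporter", "membrane",
               "putative", "hydrolase", "binding", "SopD", "SopE")
go_types <- c("molecular_function", "biological_process", "cellular_component")

#' Generate the synthetic universe
#'
#' Writes one file per dataset — taxonomy XML, GO TSV, HGNC-style JSON,
#' UniProt-style XML, one Ensembl-style GFF3 per species, probe-set TSV and
#' literature CSV — and returns the ground-truth graph those files encode.
#' Output is deterministic for a seed and byte-identical across runs; file
#' content and graph agree exactly (ingesting the files reproduces the
#' graph's nodes, edges and keywords).
#'
#' @param params A [universe_params()].
#' @param dir Output directory (created if needed).
#' @param compress Write gzip-compressed variants of the flat files too.
#' @return `list(sources, graph, params)`; `sources` is the named
#'   dataset-to-paths list accepted by [build_config()].
#' @export
generate_universe <- function(params = universe_params(), dir = tempfile("universe-"),
                              compress = FALSE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  registry <- default_registry()
  with_local_seed(params$seed, {
    graph <- new_graph(registry)

    # taxonomy tree
    tax <- data.frame(id = "1", parent = NA_character_, rank = "root",
                      name = "root clade", stringsAsFactors = FALSE)
    level <- "1"; next_id <- 2L
    for (d in seq_len(params$taxonomy_depth)) {
      children <- character()
      for (p in level) {
        for (b in seq_len(params$branching)) {
          id <- as.character(next_id); next_id <- next_id + 1L
          rank <- if (d == params$taxonomy_depth) "species" else "clade"
          nm <- if (rank == "species") sprintf("Genus%02d species%02d", next_id %% 89L, next_id)
                else sprintf("Clade %d", next_id)
          tax <- rbind(tax, data.frame(id = id, parent = p, rank = rank, name = nm,
                                       stringsAsFactors = FALSE))
          children <- c(children, id)
        }
      }
      level <- children
    }
    leaves <- tax$id[tax$rank == "species"]
    species <- utils::head(leaves, params$species_count)
    for (i in seq_len(nrow(tax))) {
      graph <- graph_add(graph, "taxonomy", tax$id[i],
                         attrs = list(scientific_name = tax$name[i], rank = tax$rank[i]),
                         keywords = tax$name[i])
    }
    for (i in seq_len(nrow(tax))) {
      if (!is.na(tax$parent[i])) {
        graph <- graph_add_edge(graph, "taxonomy", tax$parent[i], "taxchild", tax$id[i])
      }
    }

    # GO pool
    go_ids <- sprintf("GO:%07d", seq_len(params$go_terms))
    go_names <- if (params$go_terms)
      paste(sample(word_pool, params$go_terms, replace = TRUE), "activity",
            seq_len(params$go_terms)) else character()
    go_type <- sample(go_types, params$go_terms, replace = TRUE)
    for (i in seq_len(params$go_terms)) {
      graph <- graph_add(graph, "go", go_ids[i],
                         attrs = list(name = go_names[i], type = go_type[i]))
    }

    chroms <- c("1", "2", "X")
    genes <- list()
    gcount <- 0L; tcount <- 0L; pcount <- 0L; lcount <- 0L
    for (sp in species) {
      for (j in seq_len(params$genes_per_species)) {
        gcount <- gcount + 1L
        gid <- sprintf("ENSG%08d", gcount)
        gname <- sprintf("GN%05d", gcount)
        chrom <- sample(chroms, 1L)
        start <- sample.int(as.integer(params$chrom_length[2L] - 6000L), 1L)
        end <- start + sample(500:5000, 1L)
        strand <- sample(c("+", "-"), 1L)
        desc <- paste(sample(word_pool, 3L, replace = TRUE), collapse = " ")
        acc <- sprintf("P%05d", gcount)
        reviewed <- stats::runif(1L) < params$reviewed_prob
        gos <- if (params$go_terms && params$go_per_protein)
          sort(sample(go_ids, min(params$go_per_protein, params$go_terms))) else character()
        tids <- character()
        for (t in seq_len(params$transcripts_per_gene)) {
          tcount <- tcount + 1L
          tids <- c(tids, sprintf("ENST%08d", tcount))
        }
        probes <- list()
        for (tid in tids) {
          pr <- character()
          for (q in seq_len(params$probes_per_transcript)) {
            pcount <- pcount + 1L
            pr <- c(pr, sprintf("%06d_at", 200000L + pcount))
          }
          probes[[tid]] <- pr
        }
        pmid <- if (stats::runif(1L) < params$literature_prob) {
          lcount <- lcount + 1L
          sprintf("%08d", 30000000L + lcount)
        } else NA_character_
        genes[[gcount]] <- list(id = gid, name = gname, species = sp,
                                chrom = chrom, start = start, end = end,
                                strand = strand, desc = desc, acc = acc,
                                reviewed = reviewed, gos = gos, tids = tids,
                                probes = probes, hgnc = sprintf("HGNC:%05d", gcount),
                                pmid = pmid)
      }
    }

    for (g in genes) {
      graph <- graph_add(graph, "ensembl", g$id,
                         attrs = list(seq_region = g$chrom, start = as.double(g$start),
                                      end = as.double(g$end), strand = g$strand,
                                      name = g$name, description = g$desc),
                         xrefs = list(
                           target = c(rep("go", length(g$gos)), "taxonomy",
                                      rep("transcript", length(g$tids)),
                                      "hgnc", "uniprot"),
                           id = c(g$gos, g$species, g$tids, g$hgnc, g$acc)),
                         keywords = g$name)
      graph <- graph_add_edge(graph, "taxonomy", g$species, "ensembl", g$id)
      for (tid in g$tids) {
        toff <- match(tid, g$tids) * 10L
        graph <- graph_add(graph, "transcript", tid,
                           attrs = list(seq_region = g$chrom,
                                        start = as.double(g$start + toff),
                                        end = as.double(g$end), strand = g$strand),
                           xrefs = list(
                             target = c("ensembl", "taxonomy",
                                        rep("affy_hg_u133_plus_2", length(g$probes[[tid]]))),
                             id = c(g$id, g$species, g$probes[[tid]])))
        for (pr in g$probes[[tid]]) {
          graph <- graph_add(graph, "affy_hg_u133_plus_2", pr,
                             xrefs = list(target = "transcript", id = tid))
        }
      }
      prot_names <- c(sprintf("Protein %s", g$name), g$name)
      ux <- list(target = c("ensembl", rep("go", length(g$gos)), "taxonomy"),
                 id = c(g$id, g$gos, g$species))
      if (!is.na(g$pmid)) {
        ux$target <- c(ux$target, "literature"); ux$id <- c(ux$id, g$pmid)
        graph <- graph_add(graph, "literature", g$pmid,
                           attrs = list(pmcid = sprintf("PMC%s", substr(g$pmid, 4L, 8L)),
                                        doi = sprintf("10.1000/j.%s", g$pmid)),
                           xrefs = list(target = "uniprot", id = g$acc))
      }
      graph <- graph_add(graph, "uniprot", g$acc,
                         attrs = list(reviewed = g$reviewed, names = prot_names),
                         xrefs = ux)
      graph <- graph_add(graph, "hgnc", g$hgnc,
                         attrs = list(symbol = g$name),
                         xrefs = list(target = "ensembl", id = g$id),
                         keywords = g$name)
    }

    files <- write_universe_files(dir, tax, species, go_ids, go_names, go_type,
                                  genes, compress)
    list(sources = files, graph = graph, params = params)
  })
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

write_universe_files <- function(dir, tax, species, go_ids, go_names, go_type,
                                 genes, compress = FALSE) {
  wl <- function(lines, name) {
    path <- file.path(dir, name)
    writeLines(lines, path)
    if (compress) {
      gz <- gzfile(paste0(path, ".gz"), "wt")
      writeLines(lines, gz)
      close(gz)
    }
    path
  }
  tax_lines <- c("<taxonomy>", vapply(seq_len(nrow(tax)), function(i) {
    pa <- if (is.na(tax$parent[i])) "" else sprintf(' parent="%s"', tax$parent[i])
    sprintf('  <taxon id="%s"%s rank="%s"><name>%s</name></taxon>',
            tax$id[i], pa, tax$rank[i], xml_escape(tax$name[i]))
  }, ""), "</taxonomy>")
  taxonomy <- wl(tax_lines, "taxonomy.xml")

  go <- wl(c("id\tname\ttype",
             sprintf("%s\t%s\t%s", go_ids, go_names, go_type)), "go.tsv")

  gene_sp <- vapply(genes, `[[`, "", "species")
  gff <- character(0)
  for (sp in species) {
    lines <- c("##gff-version 3", sprintf("##species taxon:%s", sp))
    for (g in genes[gene_sp == sp]) {
      a9 <- sprintf("ID=gene:%s;Name=%s;description=%s", g$id, g$name, g$desc)
      if (length(g$gos)) a9 <- paste0(a9, ";Ontology_term=", paste(g$gos, collapse = ","))
      lines <- c(lines, sprintf("%s\tsynthetic\tgene\t%d\t%d\t.\t%s\t.\t%s",
                                g$chrom, g$start, g$end, g$strand, a9))
      for (tid in g$tids) {
        toff <- match(tid, g$tids) * 10L
        lines <- c(lines, sprintf("%s\tsynthetic\tmRNA\t%d\t%d\t.\t%s\t.\tID=transcript:%s;Parent=gene:%s",
                                  g$chrom, g$start + toff, g$end, g$strand, tid, g$id))
      }
    }
    gff <- c(gff, wl(lines, sprintf("ensembl_%s.gff3", sp)))
  }

  uni_lines <- c("<uniprot>")
  for (g in genes) {
    refs <- c(sprintf('    <dbReference type="ensembl" id="%s"/>', g$id),
              sprintf('    <dbReference type="go" id="%s"/>', g$gos),
              sprintf('    <dbReference type="taxonomy" id="%s"/>', g$species))
    if (!is.na(g$pmid)) {
      # literature link arrives via the literature CSV (reverse edge)
    }
    uni_lines <- c(uni_lines,
      sprintf('  <entry reviewed="%s">', tolower(as.character(g$reviewed))),
      sprintf('    <accession>%s</accession>', g$acc),
      "    <protein>",
      sprintf('      <name>%s</name>', xml_escape(c(sprintf("Protein %s", g$name), g$name))),
      "    </protein>",
      refs,
      "  </entry>")
  }
  uniprot <- wl(c(uni_lines, "</uniprot>"), "uniprot.xml")

  hg <- vapply(genes, function(g)
    sprintf('{"hgnc_id":"%s","symbol":"%s","ensembl_gene_id":"%s"}',
            g$hgnc, g$name, g$id), "")
  hgnc <- wl(c('{"response":{"docs":[', paste0(hg, c(rep(",", max(0L, length(hg) - 1L)), "")),
               "]}}"), "hgnc.json")

  probe_lines <- character()
  for (g in genes) for (tid in g$tids) for (pr in g$probes[[tid]]) {
    probe_lines <- c(probe_lines, sprintf("%s\t%s", pr, tid))
  }
  affy <- wl(probe_lines, "probes.tsv")

  lit <- Filter(function(g) !is.na(g$pmid), genes)
  lit_lines <- c("pmid,pmcid,doi,uniprot", vapply(lit, function(g)
    sprintf("%s,PMC%s,10.1000/j.%s,%s", g$pmid, substr(g$pmid, 4L, 8L), g$pmid, g$acc), ""))
  literature <- wl(lit_lines, "literature.csv")

  list(taxonomy = taxonomy, go = go, ensembl = gff, uniprot = uniprot,
       hgnc = hgnc, affy_hg_u133_plus_2 = affy, literature = literature)
}

# -- brute-force oracle -------------------------------------------------------

# Independent filter evaluation used only by the oracle: a literal
# transcription of the filter semantics, sharing no code with eval_filter.
oracle_eval <- function(expr, attrs) {
  if (expr$type == "and") return(oracle_eval(expr$left, attrs) && oracle_eval(expr$right, attrs))
  if (expr$type == "or") return(oracle_eval(expr$left, attrs) || oracle_eval(expr$right, attrs))
  if (expr$type == "within") {
    if (is.null(attrs$start) || is.null(attrs$end)) return(FALSE)
    return(attrs$start[1L] > expr$low && attrs$end[1L] < expr$high)
  }
  if (expr$type == "contains") {
    v <- attrs[[expr$path[2L]]]
    if (is.null(v)) return(FALSE)
    for (el in as.character(v)) {
      if (grepl(expr$needle, el, fixed = TRUE)) return(TRUE)
    }
    return(FALSE)
  }
  if (expr$type == "bool") {
    v <- attrs[[expr$path[2L]]]
    return(is.logical(v) && any(v == TRUE))
  }
  v <- attrs[[expr$path[2L]]]
  lit <- expr$literal
  if (expr$op %in% c("<", "<=", ">", ">=") && is.character(lit)) {
    xr_abort("xrefdb_eval_error", "ordered comparison against a string literal")
  }
  if (is.null(v)) return(FALSE)
  if (is.numeric(lit) && !is.numeric(v)) {
    v <- suppressWarnings(as.numeric(as.character(v)))
    v <- v[!is.na(v)]
    if (length(v) == 0L) return(FALSE)
  }
  if (is.logical(lit) && !is.logical(v)) return(FALSE)
  if (is.character(lit)) {
    if (expr$op %in% c("<", "<=", ">", ">=")) return(FALSE)
    v <- as.character(v)
  }
  for (el in v) {
    hit <- switch(expr$op,
      "==" = el == lit, "!=" = el != lit, "<" = el < lit,
      "<=" = el <= lit, ">" = el > lit, ">=" = el >= lit)
    if (isTRUE(hit)) return(TRUE)
  }
  FALSE
}

#' Brute-force mapping oracle over the ground-truth graph
#'
#' A literal breadth-wise walk of the graph's adjacency lists with inline
#' filter evaluation — deliberately simple and independent of the
#' chunk/store/query execution paths, used as the reference for
#' equivalence testing. Cycle-safe: each node is visited once per hop (and
#' once overall under transitive relation hops).
#'
#' @param graph An `xref_graph`.
#' @param terms Comma-separated input terms.
#' @param query_text Query text.
#' @param source Optional dataset restriction for term resolution.
#' @param taxchild_transitive Transitive closure on relation hops.
#' @return data.frame(input, mapping_id), one row per final mapped entry.
#' @export
oracle_map <- function(graph, terms, query_text, source = NULL,
                       taxchild_transitive = FALSE) {
  registry <- graph$registry
  query <- parse_query(query_text, registry = registry)
  nodes <- graph$nodes
  norm_ids <- normalize_keys(vapply(nodes, `[[`, "", "identifier"))
  node_ds <- vapply(nodes, `[[`, "", "dataset")
  term_list <- trimws(strsplit(terms, ",", fixed = TRUE)[[1L]])
  term_list <- term_list[nzchar(term_list)]
  out_input <- character(); out_id <- character()
  for (term in term_list) {
    nt <- normalize_keys(term)
    hit <- norm_ids == nt
    for (i in seq_along(nodes)) {
      if (!hit[i] && length(nodes[[i]]$keywords) &&
          nt %in% normalize_keys(nodes[[i]]$keywords)) hit[i] <- TRUE
    }
    if (!is.null(source)) hit <- hit & node_ds == source
    frontier <- which(hit)
    for (step in query) {
      if (length(frontier) == 0L) break
      if (step$type == "map") {
        tds <- resolve_map_target(registry, step$target)
        seen <- character(); nxt <- integer()
        wave <- frontier
        repeat {
          newly <- integer()
          for (i in wave) {
            xr <- nodes[[i]]$xrefs
            for (j in which(xr$target == step$target)) {
              k <- node_key(tds, xr$id[j])
              tk <- normalize_keys(xr$id[j])
              if (tk %in% seen) next
              pos <- match(k, names(nodes))
              if (is.na(pos)) next
              seen <- c(seen, tk)
              newly <- c(newly, pos)
            }
          }
          nxt <- c(nxt, newly)
          transitive_hop <- taxchild_transitive &&
            step$target %in% names(registry$relations)
          if (!transitive_hop || length(newly) == 0L) break
          wave <- newly
        }
        frontier <- nxt[order(normalize_keys(vapply(nodes[nxt], `[[`, "", "identifier")),
                              method = "radix")]
      } else {
        keep <- vapply(frontier, function(i) oracle_eval(step$expr, nodes[[i]]$attrs), TRUE)
        frontier <- frontier[keep]
      }
    }
    if (length(frontier)) {
      out_input <- c(out_input, rep(normalize_keys(term), length(frontier)))
      out_id <- c(out_id, vapply(nodes[frontier], `[[`, "", "identifier",
                                 USE.NAMES = FALSE))
    }
  }
  data.frame(input = unname(out_input), mapping_id = unname(out_id),
             stringsAsFactors = FALSE)
}
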