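# Dataset registry: which datasets exist, their stable numeric ids, their
# file formats and their per-format ingest column specs. Numeric ids are
# assigned in registry order, so a fixed registry file gives reproducible
# builds.

#' Create a dataset registry
#'
#' @param datasets A list of dataset descriptors, each
#'   `list(name =, format =, spec = <column spec or NULL>)`. `format` is one
#'   of `"tsv"`, `"csv"`, `"json"`, `"xml"`, `"gff3"`.
#' @param relations Named character vector mapping relation labels (edge
#'   labels usable as `map()` targets that are not datasets themselves) to
#'   the dataset in which their target identifiers resolve.
#' @return An object of class `xref_registry`.
#' @export
xr_registry <- function(datasets, relations = c(taxchild = "taxonomy")) {
  nms <- vapply(datasets, `[[`, "", "name")
  fmts <- vapply(datasets, `[[`, "", "format")
  if (anyDuplicated(nms)) xr_abort("xrefdb_config_error", "duplicate dataset names in registry")
  bad <- !fmts %in% c("tsv", "csv", "json", "xml", "gff3")
  if (any(bad)) {
    xr_abort("xrefdb_config_error",
             sprintf("unknown format(s): %s", paste(fmts[bad], collapse = ", ")))
  }
  if (!all(relations %in% nms)) {
    xr_abort("xrefdb_config_error", "relation labels must resolve to registered datasets")
  }
  specs <- lapply(datasets, function(d) d$spec)
  names(specs) <- nms
  structure(
    list(
      datasets = data.frame(name = nms, numeric_id = seq_along(nms),
                            format = fmts, stringsAsFactors = FALSE),
      specs = specs,
      relations = relations
    ),
    class = "xref_registry"
  )
}

#' @export
print.xref_registry <- function(x, ...) {
  cat(sprintf("<xref_registry: %d datasets, %d relation labels>\n",
              nrow(x$datasets), length(x$relations)))
  print(x$datasets, row.names = FALSE)
  invisible(x)
}

#' Numeric id of a registered dataset
#' @param registry An `xref_registry`.
#' @param name Dataset name.
#' @export
registry_id <- function(registry, name) {
  i <- match(name, registry$datasets$name)
  if (is.na(i)) {
    xr_abort("xrefdb_unknown_dataset",
             sprintf("unknown dataset '%s'; valid: %s", name,
                     paste(registry$datasets$name, collapse = ", ")))
  }
  registry$datasets$numeric_id[i]
}

#' Dataset name for a numeric id
#' @param registry An `xref_registry`.
#' @param id Numeric dataset id.
#' @export
registry_name <- function(registry, id) {
  i <- match(as.integer(id), registry$datasets$numeric_id)
  if (is.na(i)) xr_abort("xrefdb_unknown_dataset", sprintf("unknown dataset id %s", id))
  registry$datasets$name[i]
}

#' Resolve a map() target to the dataset its identifiers live in
#'
#' A target is valid if it is a dataset name (resolving to itself) or a
#' relation label such as `taxchild` (resolving to the relation's dataset).
#' @param registry An `xref_registry`.
#' @param target Dataset name or relation label.
#' @return The dataset name the target's identifiers resolve in.
#' @export
resolve_map_target <- function(registry, target) {
  if (target %in% names(registry$relations)) {
    unname(registry$relations[[target]])
  } else if (target %in% registry$datasets$name) {
    target
  } else {
    xr_abort("xrefdb_unknown_dataset",
             sprintf("unknown map target '%s'; valid targets: %s", target,
                     paste(c(registry$datasets$name, names(registry$relations)),
                           collapse = ", ")))
  }
}

#' The built-in dataset registry
#'
#' Registers the dataset universe the synthetic fixtures emulate: an NCBI-style
#' taxonomy (XML), Ensembl-style genes and transcripts (GFF3), UniProt-style
#' proteins (XML), GO terms (TSV), HGNC-style gene nomenclature (JSON), an
#' Affymetrix probe-set platform (TSV) and literature id mappings (CSV).
#' The relation label `taxchild` resolves in `taxonomy`.
#'
#' @return An `xref_registry`.
#' @export
default_registry <- function() {
  xr_registry(list(
    list(name = "taxonomy", format = "xml", spec = list(
      record_element = "taxon",
      id = list(from = "attr", attr = "id"),
      attrs = list(
        scientific_name = list(path = "name", from = "text", type = "s"),
        rank = list(from = "attr", attr = "rank", type = "s")
      ),
      keywords = list(list(path = "name", from = "text")),
      xrefs = list(
        # parent attribute: emit the reverse edge parent --taxchild--> child
        list(from = "attr", attr = "parent", target = "taxonomy",
             forward = FALSE, reverse = TRUE, reverse_label = "taxchild")
      )
    )),
    list(name = "ensembl", format = "gff3", spec = NULL),
    list(name = "transcript", format = "gff3", spec = NULL),
    list(name = "uniprot", format = "xml", spec = list(
      record_element = "entry",
      id = list(path = "accession", from = "text"),
      attrs = list(
        reviewed = list(from = "attr", attr = "reviewed", type = "b"),
        names = list(path = "protein/name", from = "text", many = TRUE, type = "s")
      ),
      keywords = list(),
      xrefs = list(
        list(path = "dbReference", target_attr = "type", id_attr = "id",
             forward = TRUE, reverse_targets = "ensembl")
      )
    )),
    list(name = "go", format = "tsv", spec = list(
      header = TRUE, id_col = 1L,
      attrs = list(name = list(col = 2L, type = "s"),
                   type = list(col = 3L, type = "s")),
      xrefs = list(), keywords = integer()
    )),
    list(name = "hgnc", format = "json", spec = list(
      path = "response.docs", id_field = "hgnc_id",
      attrs = list(symbol = list(field = "symbol", type = "s")),
      keywords = c("symbol"),
      xrefs = list(
        list(field = "ensembl_gene_id", target = "ensembl",
             forward = TRUE, reverse = TRUE)
      )
    )),
    list(name = "affy_hg_u133_plus_2", format = "tsv", spec = list(
      header = FALSE, id_col = 1L,
      attrs = list(),
      xrefs = list(
        list(col = 2L, target = "transcript", forward = TRUE, reverse = TRUE,
             split = ",")
      ),
      keywords = integer()
    )),
    list(name = "literature", format = "csv", spec = list(
      header = TRUE, id_col = 1L,
      attrs = list(pmcid = list(col = 2L, type = "s"),
                   doi = list(col = 3L, type = "s")),
      xrefs = list(
        list(col = 4L, target = "uniprot", forward = TRUE, reverse = TRUE)
      ),
      keywords = integer()
    ))
  ))
}

#' Load a dataset registry from a YAML config file
#'
#' The file holds `relations:` (label -> dataset) and `datasets:`, a list of
#' `{name, format, spec}` entries in id-assignment order; `spec` uses the
#' same shape as the column specs of [default_registry()].
#'
#' @param path Path to the YAML registry file.
#' @return An `xref_registry`.
#' @export
load_registry <- function(path) {
  if (!file.exists(path)) xr_abort("xrefdb_config_error", sprintf("registry file not found: %s", path))
  cfg <- yaml::read_yaml(path)
  relations <- if (is.null(cfg$relations)) c(taxchild = "taxonomy") else unlist(cfg$relations)
  xr_registry(cfg$datasets, relations = relations)
}
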