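test_that("the probe-to-GO chain query parses to the expected steps", {
  q <- parse_query('map(transcript).map(ensembl).map(go).filter(go.type=="molecular_function")',
                   registry = default_registry())
  expect_length(q, 4L)
  expect_identical(vapply(q, `[[`, "", "type"), c("map", "map", "map", "filter"))
  expect_identical(q[[2]]$target, "ensembl")
  f <- q[[4]]$expr
  expect_identical(f$type, "cmp")
  expect_identical(f$path, c("go", "type"))
  expect_identical(f$op, "==")
  expect_identical(f$literal, "molecular_function")
})

test_that("range, boolean and conjunction filters parse with map-bound datasets", {
  q <- parse_query(paste0('map(ensembl).filter(ensembl.within(100000000,101000000)',
                          ' && ensembl.seq_region=="X").map(uniprot).filter(uniprot.reviewed)'),
                   registry = default_registry())
  expect_identical(vapply(q, `[[`, "", "type"), c("map", "filter", "map", "filter"))
  f1 <- q[[2]]$expr
  expect_identical(f1$type, "and")
  expect_identical(f1$left$type, "within")
  expect_identical(f1$left$low, 1e8)
  expect_identical(f1$right$type, "cmp")
  expect_identical(q[[4]]$expr$type, "bool")
  expect_identical(q[[4]]$expr$path, c("uniprot", "reviewed"))
})

test_that("syntax and semantic errors carry positions and classes", {
  err <- tryCatch(parse_query("map()"), condition = identity)
  expect_s3_class(err, "xrefdb_syntax_error")
  expect_identical(err$position, 5L)
  expect_error(parse_query("filter(a.b==1).map(x)"), class = "xrefdb_semantic_error")
  expect_error(parse_query("map(x).filter(a.b==1).filter(a.c==2)"),
               class = "xrefdb_semantic_error")
  expect_error(parse_query('map(go).filter(ensembl.start<5)', registry = default_registry()),
               class = "xrefdb_semantic_error")
  expect_error(parse_query('map(nosuch)', registry = default_registry()),
               class = "xrefdb_unknown_dataset")
  expect_error(parse_query("map(x)."), class = "xrefdb_syntax_error")
  expect_error(parse_query('map(x).filter(a.b=="unterminated)'),
               class = "xrefdb_syntax_error")
})

test_that("canonical re-serialization re-parses to an equal AST", {
  texts <- c(
    'map(transcript).map(ensembl).map(go).filter(go.type=="molecular_function")',
    'map(ensembl).filter(ensembl.within(100000000,101000000) && ensembl.seq_region=="X").map(uniprot).filter(uniprot.reviewed)',
    'map(taxchild).map(ensembl).filter(ensembl.start<10000&&ensembl.description.contains("SopD"))',
    'map(x).filter(x.a==1 || x.b!=2 && x.c.contains("w"))',
    'map(x).filter((x.a<=5||x.b>=7)&&x.flag)')
  for (tx in texts) {
    ast <- parse_query(tx)
    expect_identical(parse_query(format_query(ast)), ast, info = tx)
  }
})

test_that("within is strict at both boundaries and matches its expanded form", {
  a <- 100000000; b <- 101000000
  entry <- function(s, e) new_payload(1L, "G", list(start = s, end = e))
  w <- parse_query(sprintf("map(x).filter(x.within(%d,%d))", a, b))[[2]]$expr
  expect_true(eval_filter(w, entry(100500000, 100600000)))
  expect_false(eval_filter(w, entry(100000000, 100600000)))
  for (s in c(a - 1, a, a + 1)) for (e in c(b - 1, b, b + 1)) {
    expect_identical(eval_filter(w, entry(s, e)), s > a && e < b,
                     info = sprintf("start=%s end=%s", s, e))
  }
})

test_that("comparison, contains and boolean predicates follow the filter semantics", {
  e <- new_payload(1L, "G", list(description = "Secreted effector protein SopD",
                                 start = 10000, reviewed = TRUE,
                                 names = c("Alpha", "Beta")))
  f <- function(txt) parse_query(paste0("map(x).filter(", txt, ")"))[[2]]$expr
  expect_true(eval_filter(f('x.description.contains("SopD")'), e))
  expect_false(eval_filter(f('x.description.contains("sopd")'), e))  # case-sensitive
  expect_false(eval_filter(f("x.start<10000"), e))                    # strict boundary
  expect_true(eval_filter(f("x.start<=10000"), e))
  expect_true(eval_filter(f("x.reviewed"), e))
  expect_false(eval_filter(f("x.missing_flag"), e))
  expect_false(eval_filter(f("x.nosuch==5"), e))                      # missing: false, no error
  expect_true(eval_filter(f('x.names=="Beta"'), e))                   # any element matches
  expect_error(eval_filter(f('x.start<"ten"'), e), class = "xrefdb_eval_error")
  # filter algebra on random operands
  set.seed(3)
  for (i in 1:50) {
    s <- sample.int(20000L, 1L); r <- runif(1) < 0.5
    ee <- new_payload(1L, "G", list(start = s + 0, reviewed = r))
    p <- f(sprintf("x.start<%d && x.reviewed", 10000L))
    q <- f(sprintf("x.start<%d || x.reviewed", 10000L))
    expect_identical(eval_filter(p, ee), s < 10000L && r)
    expect_identical(eval_filter(q, ee), s < 10000L || r)
  }
})

test_that("attribute selectors pick and index values in order", {
  e <- new_payload(1L, "P", list(names = c("Tetraspanin-6", "TSPAN6"),
                                 strand = "+", start = 2525, end = 3484))
  expect_identical(select_attrs(e, "names[1]"), list("Tetraspanin-6"))
  expect_identical(select_attrs(e, "strand,start,end"), list("+", 2525, 3484))
  expect_true(is.na(select_attrs(e, "names[9]")[[1]]))
  expect_true(is.na(select_attrs(e, "absent")[[1]]))
  expect_identical(select_attrs(e, "names")[[1]], "Tetraspanin-6;TSPAN6")
  expect_error(parse_attr_selector("bad-name!"), class = "xrefdb_selector_error")
  expect_error(parse_attr_selector("names[0]"), class = "xrefdb_selector_error")
})

test_that("one mapping hop returns exactly the cross-referenced entries, ordered", {
  tp <- test_worked_examples()
  st <- tp$store
  root <- store_lookup(st, "59201", source = "taxonomy")
  expect_length(root, 1L)
  kids <- map_step(st, root, "taxchild")
  expect_identical(vapply(kids, `[[`, "", "identifier"),
                   sort(c("595", "984254", "465517", "1249525"), method = "radix"))
  expect_identical(map_step(st, kids, "uniprot"), structure(list(), dropped = 0L))
  expect_error(map_step(st, root, "nosuch"), class = "xrefdb_unknown_dataset")
  # transitive closure reaches the grandchild, the single hop does not
  trans <- map_step(st, root, "taxchild", transitive = TRUE)
  expect_true("595001" %in% vapply(trans, `[[`, "", "identifier"))
  expect_false("595001" %in% vapply(kids, `[[`, "", "identifier"))
})

test_that("mapping rows page completely, dedupe, and vanish for unknown terms", {
  tp <- test_worked_examples()
  st <- tp$store
  q <- tp$pc$queries$uc1
  full <- execute_mapping_all(st, q$terms, q$query, source = q$source, attrs = q$attrs)
  for (ps in c(1L, 2L, 7L, 200L)) {
    paged <- execute_mapping_all(st, q$terms, q$query, source = q$source,
                                 attrs = q$attrs, page_size = ps)
    expect_identical(paged, full, info = sprintf("page_size=%d", ps))
  }
  expect_false(any(duplicated(paste(full$input, full$mapping_id))))
  none <- execute_mapping(st, "UTTERLY_UNKNOWN", "map(go)")
  expect_identical(nrow(none$rows), 0L)
  expect_null(none$next_token)
  expect_error(execute_mapping(st, "x", "map(go)", source = "nosuch"),
               class = "xrefdb_unknown_dataset")
})

test_that("appending a filter never enlarges the mapped row set", {
  tu <- test_universe()
  st <- tu$store
  set.seed(123)
  reg <- default_registry()
  for (i in 1:40) {
    base <- random_query_text(reg)
    ast <- parse_query(base, registry = reg)
    last <- ast[[length(ast)]]
    if (last$type != "map") next
    active <- resolve_map_target(reg, last$target)
    filt <- random_filter_text(active)
    if (is.null(filt)) next
    terms <- random_terms(tu$u$graph, n = 2L)
    rows_base <- row_set(execute_mapping_all(st, terms, base))
    rows_filt <- row_set(execute_mapping_all(
      st, terms, paste0(base, sprintf(".filter(%s)", filt))))
    expect_true(all(rows_filt %in% rows_base), info = paste(terms, base, filt))
  }
})
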