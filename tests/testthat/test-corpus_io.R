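test_that("the relation schema is the 8-label, 3-level forest with 12 entity types", {
  sch <- relation_schema()
  expect_length(sch$relation_labels, 8)
  expect_setequal(sch$relation_labels, c(
    "undirected_link", "directed_link", "positive_cause", "negative_cause",
    "positive_increase", "negative_decrease", "positive_decrease",
    "negative_increase"))
  expect_length(sch$entity_types, 12)
  expect_identical(sch$negative_labels, "undirected_link")
  # parent mapping
  expect_identical(label_parent("positive_increase"), "positive_cause")
  expect_identical(label_parent("negative_decrease"), "positive_cause")
  expect_identical(label_parent("positive_decrease"), "negative_cause")
  expect_identical(label_parent("negative_increase"), "negative_cause")
  expect_identical(label_parent("positive_cause"), "directed_link")
  expect_true(is.na(label_parent("directed_link")))
  expect_true(is.na(label_parent("undirected_link")))
  expect_error(label_parent("increase"), "unknown relation label")
  # every label reaches a root within 2 steps
  for (lb in sch$relation_labels) {
    steps <- 0
    while (!is.na(label_parent(lb)) && steps <= 2) {
      lb <- label_parent(lb)
      steps <- steps + 1
    }
    expect_lte(steps, 2)
  }
})

test_that("binary collapse maps exactly undirected_link to negative", {
  sch <- relation_schema()
  bin <- vapply(sch$relation_labels, collapse_to_binary, character(1))
  expect_identical(sum(bin == "negative"), 1L)
  expect_identical(unname(bin[["undirected_link"]]), "negative")
  expect_identical(collapse_to_binary("positive_increase"), "positive")
  # display forms normalize case-insensitively
  expect_identical(collapse_to_binary("Positive Cause"), "positive")
  expect_identical(normalize_label("BIOLOGICAL PROCESS"),
                   "biological_process")
  expect_error(collapse_to_binary("no_such_label"), "unknown")
})

test_that("TextAE JSON documents map relations to instances", {
  doc <- '{"text": "A binds B",
           "denotations": [
             {"id": "T1", "span": {"begin": 0, "end": 1}, "obj": "gene"},
             {"id": "T2", "span": {"begin": 8, "end": 9}, "obj": "protein"}],
           "relations": [
             {"id": "R1", "pred": "Undirected Link", "subj": "T1", "obj": "T2"}]}'
  corpus <- read_textae_json(doc)
  expect_identical(nrow(corpus), 1L)
  expect_identical(corpus$label, "undirected_link")
  expect_identical(corpus$e1_text, "A")
  expect_identical(corpus$e2_text, "B")
  expect_identical(corpus$e2_start, 8L)
  # empty relation list -> zero instances
  empty <- sub('"relations": \\[[^]]*\\]', '"relations": []', doc)
  expect_identical(nrow(read_textae_json(empty)), 0L)
  # dangling denotation reference is a structural error naming the id
  dangling <- sub('"subj": "T1"', '"subj": "T9"', doc)
  expect_error(read_textae_json(dangling), "T9")
  # span outside text
  badspan <- sub('"begin": 8, "end": 9', '"begin": 8, "end": 99', doc)
  expect_error(read_textae_json(badspan), "span")
  # unknown entity type / relation label
  expect_error(read_textae_json(sub('"obj": "gene"', '"obj": "widget"', doc)),
               "entity type")
  expect_error(read_textae_json(sub("Undirected Link", "friendship", doc)),
               "relation label")
})

test_that("relation table read/write round-trips and rejects malformed rows", {
  syn <- small_synthetic(25, seed = 31)$corpus
  syn$split <- rep(c("train", "validate", "test"), length.out = 25)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_relation_table(syn, path)
  back <- read_relation_table(path)
  expect_identical(back, syn)
  # write-read-write is byte-identical
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write_relation_table(back, path2)
  expect_identical(readLines(path), readLines(path2))
  # header-only file -> empty corpus
  path3 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(readLines(path)[1], path3)
  expect_identical(nrow(read_relation_table(path3)), 0L)
  # missing column
  writeLines(sub("\\<label\\>", "lab", readLines(path)), path3)
  expect_error(read_relation_table(path3), "missing column")
  # non-integer offset
  lns <- readLines(path)
  f <- strsplit(lns[2], "\t")[[1]]; f[5] <- "zero"
  lns[2] <- paste(f, collapse = "\t")
  writeLines(lns, path3)
  expect_error(read_relation_table(path3), "integer")
  # surface/slice mismatch
  lns <- readLines(path)
  f <- strsplit(lns[2], "\t")[[1]]; f[4] <- "WRONG"
  lns[2] <- paste(f, collapse = "\t")
  writeLines(lns, path3)
  expect_error(read_relation_table(path3), "slice")
  # fields with embedded tabs are rejected, not escaped
  bad <- syn[1, ]
  bad$sentence <- paste0(bad$sentence, "\tx")
  expect_error(write_relation_table(bad, path3), "tab")
})

test_that("validate_instance reports violations as data", {
  good <- worked_instance()
  expect_length(validate_instance(good), 0)
  inverted <- good; inverted$e1_start <- 5L; inverted$e1_end <- 3L
  expect_match(validate_instance(inverted), "start < end", all = FALSE)
  overlap <- relation_instance("d", 0, "A activates B C",
                               "A activates", 0, 11, "gene",
                               "activates B", 2, 13, "protein",
                               "positive_cause")
  expect_match(validate_instance(overlap), "overlap", all = FALSE)
  badlab <- good; badlab$label <- "friendship"
  expect_match(validate_instance(badlab), "label", all = FALSE)
  outside <- good; outside$e2_end <- 99L
  expect_true(length(validate_instance(outside)) > 0)
})

test_that("corpus statistics count relations, mentions, documents and splits", {
  two <- rbind(
    relation_instance("p1", 0, "A activates B", "A", 0, 1, "gene",
                      "B", 12, 13, "protein", "positive_cause"),
    relation_instance("p2", 0, "A binds B", "A", 0, 1, "gene",
                      "B", 8, 9, "protein", "undirected_link"))
  st <- corpus_stats(two)
  expect_identical(st$n_relations, 2L)
  expect_identical(st$n_entity_mentions, 4L)
  expect_identical(st$n_documents, 2L)
  expect_identical(unname(st$per_label_counts["positive_cause", "total"]), 1L)
  expect_error(corpus_stats(transform(two, split = "dev")), "unknown split")

  # mentions = 2 x relations across corpus sizes; split sums equal totals
  for (n in c(1, 17, 100)) {
    syn <- small_synthetic(n, seed = n)$corpus
    syn$split <- rep(c("train", "validate", "test"), length.out = n)
    st <- corpus_stats(syn)
    expect_identical(st$n_entity_mentions, 2L * st$n_relations)
    expect_equal(rowSums(st$per_label_counts[, c("train", "validate", "test")]),
                 st$per_label_counts[, "total"], ignore_attr = TRUE)
    expect_identical(sum(st$per_entity_type_counts[, "total"]),
                     st$n_entity_mentions)
  }
})
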