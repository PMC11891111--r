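test_that("parse_rrf drops suppressed atoms and joins types/definitions", {
  d <- withr::local_tempdir()
  conso <- write_mrconso(file.path(d, "MRCONSO.RRF"), list(
    list(cui = "C0007097", lat = "ENG", sab = "NCI", str = "carcinoma"),
    list(cui = "C0007097", lat = "SPA", sab = "MSH", str = "carcinoma"),
    list(cui = "C0006141", lat = "SPA", sab = "MSH", str = "mama derecha",
         suppress = "O")
  ))
  sty <- write_mrsty(file.path(d, "MRSTY.RRF"), list(
    list(cui = "C0007097", sty = "Neoplastic Process")
  ))
  def <- write_mrdef(file.path(d, "MRDEF.RRF"), list(
    list(cui = "C0007097", sab = "NCI", def = "A malignant neoplasm.")
  ))
  recs <- parse_rrf(conso, sty, def)
  expect_equal(nrow(recs), 2L)
  expect_setequal(recs$cui, "C0007097")
  expect_true(all(recs$label == "carcinoma"))
  expect_true(all(recs$sty == "Neoplastic Process"))
  defs <- attr(recs, "definitions")
  expect_equal(defs$definition, "A malignant neoplasm.")
  expect_equal(defs$def_source, "NCI")
})

test_that("parse_rrf skips malformed rows with a warning and errors on empty files", {
  d <- withr::local_tempdir()
  conso <- file.path(d, "MRCONSO.RRF")
  writeLines(c(
    paste0(paste(c("C0000001", "ENG", rep("", 9), "NCI", "PT", "",
                   "tumor", "", "N", ""), collapse = "|"), "|"),
    "garbled|row"
  ), conso)
  expect_warning(recs <- parse_rrf(conso), "malformed")
  expect_equal(nrow(recs), 1L)
  expect_equal(attr(recs, "skipped"), 1L)

  empty <- file.path(d, "empty.RRF")
  writeLines(character(), empty)
  expect_error(parse_rrf(empty), "unusable")
})

test_that("parse_rrf matches a brute-force join on a generated RRF triple", {
  d <- withr::local_tempdir()
  set.seed(3)
  n <- 100
  cuis <- sprintf("C%07d", sample(1:40, n, replace = TRUE))
  labels <- paste0("term", seq_len(n))
  lats <- sample(c("ENG", "SPA", "FRE"), n, replace = TRUE)
  supp <- sample(c("N", "O"), n, replace = TRUE, prob = c(0.8, 0.2))
  conso <- write_mrconso(file.path(d, "MRCONSO.RRF"),
    lapply(seq_len(n), function(i)
      list(cui = cuis[i], lat = lats[i], sab = "SRC", str = labels[i],
           suppress = supp[i])))
  ucui <- unique(cuis)
  sty <- write_mrsty(file.path(d, "MRSTY.RRF"),
    lapply(ucui[1:20], function(cc) list(cui = cc, sty = "Finding")))
  recs <- parse_rrf(conso, sty, NULL, lang_filter = c("ENG", "SPA"))

  keep <- supp == "N" & lats %in% c("ENG", "SPA")
  expect_equal(nrow(recs), sum(keep))
  expect_equal(recs$label, labels[keep])
  # brute-force join: sty present iff the CUI is among the first 20
  expect_equal(recs$sty,
               ifelse(cuis[keep] %in% ucui[1:20], "Finding", ""))
})

test_that("load_simple_vocab reads JSON-lines and tolerates an empty file", {
  d <- withr::local_tempdir()
  p <- file.path(d, "vocab.jsonl")
  writeLines(c(
    '{"cui":"C0006142","label":"cáncer de mama","lang":"SPA","source":"MSH"}',
    '{"cui":"","label":"orphan"}'
  ), p, useBytes = TRUE)
  expect_warning(recs <- load_simple_vocab(p), "rejected")
  expect_equal(nrow(recs), 1L)
  expect_equal(recs$cui, "C0006142")
  expect_equal(recs$label, "cáncer de mama")
  expect_equal(recs$lang, "SPA")

  empty <- file.path(d, "empty.jsonl")
  writeLines(character(), empty)
  expect_equal(nrow(load_simple_vocab(empty)), 0L)
})

test_that("a generated 50-concept vocabulary aggregates to 50 distinct CUIs", {
  v <- gen_vocab(synth_spec(seed = 5, n_concepts = 50, homonym_rate = 0))
  tab <- aggregate_concepts(v$records)
  expect_length(tab, 50L)
  expect_setequal(names(tab), unique(v$records$cui))
})

test_that("linking scores count duplicate labels across sources", {
  recs <- simple_vocab_df(list(
    list(cui = "C0007097", label = "carcinoma", lang = "ENG", source = "NCI"),
    list(cui = "C0007097", label = "Carcinoma", lang = "ENG", source = "MSH"),
    list(cui = "C0007097", label = "carcinoma", lang = "ENG",
         source = "SNOMEDCT_US"),
    list(cui = "C0007097", label = "epithelial cancer", lang = "ENG",
         source = "MDR")
  ))
  tab <- aggregate_concepts(recs)
  labs <- tab[["C0007097"]]$labels
  expect_equal(labs$linking_score[labs$label_norm == "carcinoma"], 3L)
  expect_equal(labs$linking_score[labs$label_norm == "epithelial cancer"], 1L)
  # ranked by descending linking score
  expect_equal(labs$label_norm[1], "carcinoma")

  single <- aggregate_concepts(simple_vocab_df(list(
    list(cui = "C1", label = "solo", lang = "ENG", source = "NCI"))))
  expect_equal(single[["C1"]]$labels$linking_score, 1L)
})

test_that("homonym surfaces are preserved under every CUI", {
  tab <- fixture_concepts()
  expect_true("boost" %in% tab[["C0183683"]]$labels$label_norm)
  expect_true("boost" %in% tab[["C1282911"]]$labels$label_norm)
})

test_that("linking scores conserve record counts and aggregation is order-invariant", {
  set.seed(9)
  for (rep in 1:5) {
    v <- gen_vocab(synth_spec(seed = rep, n_concepts = 30,
                              synonym_rate = 0.5, homonym_rate = 0.2))
    tab <- aggregate_concepts(v$records)
    for (cui in names(tab)) {
      n_recs <- sum(v$records$cui == cui)
      labs <- tab[[cui]]$labels
      per_norm <- labs$linking_score[!duplicated(labs$label_norm)]
      expect_equal(sum(per_norm), n_recs)
    }
    shuffled <- v$records[sample.int(nrow(v$records)), , drop = FALSE]
    attr(shuffled, "definitions") <- attr(v$records, "definitions")
    class(shuffled) <- class(v$records)
    tab2 <- aggregate_concepts(shuffled)
    expect_identical(tab, tab2)
  }
})

test_that("the index retrieves its own labels at rank 1", {
  tab <- aggregate_concepts(simple_vocab_df(list(
    list(cui = "C0007097", label = "carcinoma", lang = "ENG", source = "NCI"))))
  idx <- build_index(tab)
  expect_gte(nrow(idx$docs), 1L)
  q <- build_query("carcinoma", pipeline_config(q_type = "Exact"))
  hits <- search_index(idx, q)
  expect_equal(hits$cui[1], "C0007097")
  expect_error(build_index(structure(list(), class = "concept_table")),
               "empty")
})

test_that("indexed BM25 scores equal the closed-form brute-force formula", {
  v <- gen_vocab(synth_spec(seed = 21, n_concepts = 50, homonym_rate = 0.1))
  tab <- aggregate_concepts(v$records)
  idx <- build_index(tab)
  set.seed(33)
  queries <- sample(v$truth$surface[v$truth$spa_in_vocab], 10)
  for (qt in c("Exact", "Multi_match")) {
    for (qs in queries) {
      got <- search_index(idx, build_query(qs, pipeline_config(
        q_type = qt, k = 1000L)))
      want <- ref_search(tab, qs, qt)
      expect_equal(got$cui, want$cui, info = paste(qt, qs))
      expect_equal(got$retrieval_score, want$retrieval_score,
                   tolerance = 1e-12, info = paste(qt, qs))
    }
  }
})

test_that("an index round-trips through serialization with identical scores", {
  v <- gen_vocab(synth_spec(seed = 2, n_concepts = 30))
  idx <- build_index(aggregate_concepts(v$records))
  d <- withr::local_tempdir()
  save_index(idx, d)
  idx2 <- load_index(d)
  expect_identical(idx2$build_hash, idx$build_hash)
  set.seed(4)
  queries <- sample(v$truth$surface, 20, replace = TRUE)
  for (qs in queries) {
    q <- build_query(qs, pipeline_config(q_type = "Multi_match", k = 100L))
    expect_identical(search_index(idx, q), search_index(idx2, q))
  }
})
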