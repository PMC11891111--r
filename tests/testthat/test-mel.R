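make_idx <- function() build_index(fixture_concepts())

test_that("build_query derives language constraints and validates q_type", {
  cfg <- pipeline_config(q_type = "Exact", lang = "SPA")
  q <- build_query("carcinoma", cfg)
  expect_equal(q$lang, "SPA")
  expect_equal(q$text_norm, "carcinoma")

  q2 <- build_query("carcinoma", pipeline_config(q_type = "Multi_match_SPA"))
  expect_equal(q2$lang, "SPA")
  q3 <- build_query("carcinoma", pipeline_config(q_type = "Multi_match"))
  expect_equal(q3$lang, "any")
  q4 <- build_query("x", pipeline_config(q_type = "Multi_match_boosted"))
  expect_true(length(q4$boost_words) > 0)

  bad <- pipeline_config(); bad$q_type <- "Nope"
  expect_error(build_query("x", bad), "unknown q_type")
})

test_that("exact search retrieves a verbatim label at rank 1 and nothing else", {
  idx <- make_idx()
  hits <- search_index(idx, build_query("carcinoma",
                                        pipeline_config(q_type = "Exact")))
  expect_equal(hits$cui[1], "C0007097")
  expect_true(all(hits$label_norm == "carcinoma"))
  miss <- search_index(idx, build_query("inexistente",
                                        pipeline_config(q_type = "Exact")))
  expect_equal(nrow(miss), 0L)
})

test_that("basic fuzzy search tolerates a one-character variation", {
  tab <- aggregate_concepts(simple_vocab_df(list(
    list(cui = "C0006141", label = "mama derechas", lang = "SPA",
         source = "MSH"))))
  idx <- build_index(tab)
  hits <- search_index(idx, build_query(
    "mama derecha", pipeline_config(q_type = "Basic_Fuzzy")))
  expect_equal(hits$cui, "C0006141")
  # but exact does not
  expect_equal(nrow(search_index(idx, build_query(
    "mama derecha", pipeline_config(q_type = "Exact")))), 0L)
})

test_that("boosted multi-match multiplies scores of boost-word labels", {
  tab <- aggregate_concepts(simple_vocab_df(list(
    list(cui = "C1", label = "carcinoma de mama", lang = "SPA",
         source = "A"),
    list(cui = "C2", label = "lesión de mama", lang = "SPA", source = "A")
  )))
  idx <- build_index(tab)
  plain <- search_index(idx, build_query(
    "de mama", pipeline_config(q_type = "Multi_match")))
  boosted <- search_index(idx, build_query(
    "de mama", pipeline_config(q_type = "Multi_match_boosted",
                               boost_factor = 2.0)))
  s_plain <- plain$retrieval_score[match("C1", plain$cui)]
  s_boost <- boosted$retrieval_score[match("C1", boosted$cui)]
  expect_equal(s_boost, 2.0 * s_plain)
  # the non-boost-word label is unchanged
  expect_equal(boosted$retrieval_score[match("C2", boosted$cui)],
               plain$retrieval_score[match("C2", plain$cui)])
  expect_equal(boosted$cui[1], "C1")
})

test_that("search rankings equal the exhaustive brute-force oracle", {
  v <- gen_vocab(synth_spec(seed = 31, n_concepts = 40, homonym_rate = 0.15,
                            synonym_rate = 0.4))
  tab <- aggregate_concepts(v$records)
  idx <- build_index(tab)
  expect_lte(nrow(idx$docs), 100L)
  set.seed(55)
  pool <- c(v$truth$surface, v$truth$eng)
  mutate <- function(s) {
    if (runif(1) < 0.5) s else apply_typo_for_test(s)
  }
  queries <- vapply(sample(pool, 25, replace = TRUE), mutate, "")
  for (qt in c("Exact", "Basic_Fuzzy", "Multi_match_SPA", "Multi_match",
               "Multi_match_boosted")) {
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

test_that("hit sets grow with query fuzziness and with k", {
  v <- gen_vocab(synth_spec(seed = 37, n_concepts = 35, homonym_rate = 0.1))
  idx <- build_index(aggregate_concepts(v$records))
  set.seed(7)
  queries <- sample(c(v$truth$surface, v$truth$eng), 30, replace = TRUE)
  big <- function(qt, qs, k = 1000L) {
    search_index(idx, build_query(qs, pipeline_config(q_type = qt, k = k)))
  }
  for (qs in queries) {
    h_exact <- big("Exact", qs)$cui
    h_fuzzy <- big("Basic_Fuzzy", qs)$cui
    h_spa <- big("Multi_match_SPA", qs)$cui
    h_multi <- big("Multi_match", qs)$cui
    expect_true(all(h_exact %in% h_fuzzy), info = qs)
    expect_true(all(h_fuzzy %in% h_multi), info = qs)
    expect_true(all(h_spa %in% h_multi), info = qs)
    # hit count is non-decreasing in k
    expect_lte(nrow(big("Multi_match", qs, k = 5L)),
               nrow(big("Multi_match", qs, k = 50L)))
  }
})

test_that("filtering annotates similarity and applies the threshold rules", {
  idx <- make_idx()
  cands <- search_index(idx, build_query(
    "mama derecha", pipeline_config(q_type = "Multi_match")))
  f0 <- filter_candidates(cands, "mama derecha", 0)
  expect_equal(nrow(f0$confident), nrow(cands))
  expect_false(f0$low_confidence)
  f1 <- filter_candidates(cands, "mama derecha", 1)
  expect_true(all(f1$confident$label_norm == "mama derecha"))
  expect_error(filter_candidates(cands, "x", 1.5), "theta_sim")

  # survivors at theta = 0.96 equal a direct recomputation
  f96 <- filter_candidates(cands, "mama derecha", 0.96)
  want <- cands$label_norm[vapply(cands$label_norm, function(l)
    ref_similarity("mama derecha", l), 0) >= 0.96]
  expect_setequal(f96$confident$label_norm, want)
})

test_that("confident sets shrink as the threshold rises", {
  v <- gen_vocab(synth_spec(seed = 43, n_concepts = 30, homonym_rate = 0.1))
  idx <- build_index(aggregate_concepts(v$records))
  set.seed(8)
  for (qs in sample(v$truth$surface, 10)) {
    cands <- search_index(idx, build_query(qs, pipeline_config(
      q_type = "Multi_match", k = 100L)))
    sizes <- vapply(c(0.5, 0.7, 0.9, 0.96, 0.98), function(th)
      nrow(filter_candidates(cands, qs, th)$confident), 0L)
    expect_true(all(diff(sizes) <= 0), info = qs)
  }
})

test_that("the decision rule partitions filter outputs into three branches", {
  idx <- make_idx()
  # no candidates
  f_none <- filter_candidates(search_index(idx, build_query(
    "zzz", pipeline_config(q_type = "Exact"))), "zzz", 0.96)
  expect_equal(decide(f_none)$branch, "NO_CANDIDATE")
  # one confident CUI -> direct link
  f_one <- filter_candidates(search_index(idx, build_query(
    "carcinoma", pipeline_config(q_type = "Exact"))), "carcinoma", 0.96)
  d_one <- decide(f_one)
  expect_equal(d_one$branch, "DIRECT_LINK")
  expect_equal(d_one$cui, "C0007097")
  # two confident CUIs -> ambiguous (the homonym surface)
  f_two <- filter_candidates(search_index(idx, build_query(
    "boost", pipeline_config(q_type = "Exact"))), "boost", 0.96)
  d_two <- decide(f_two)
  expect_equal(d_two$branch, "AMBIGUOUS")
  expect_setequal(d_two$candidates$cui, c("C0183683", "C1282911"))
  expect_false(d_two$low_confidence)
  # nothing confident -> ambiguous, flagged low-confidence, full set kept
  cands <- search_index(idx, build_query(
    "mastectomia radical", pipeline_config(q_type = "Multi_match")))
  f_low <- filter_candidates(cands, "mastectomia radical", 0.96)
  d_low <- decide(f_low)
  expect_equal(d_low$branch, "AMBIGUOUS")
  expect_true(d_low$low_confidence)
  expect_equal(sort(d_low$candidates$cui), sort(unique(cands$cui)))
})

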