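test_that("definition selection prefers NCI, then the priority list", {
  entry <- list(cui = "C1", definitions = data.frame(
    definition = c("from MSH", "from NCI"),
    def_source = c("MSH", "NCI"), stringsAsFactors = FALSE))
  sel <- select_definition(entry)
  expect_equal(sel$source, "NCI")
  expect_equal(sel$definition, "from NCI")

  none <- select_definition(list(cui = "C2", definitions = NULL))
  expect_equal(none$definition, "no definition available")

  # random multi-source entries equal a brute-force priority scan
  prio <- c("NCI", "MSH", "SNOMEDCT_US", "SNOMEDCT", "ICD10CM", "HPO")
  set.seed(61)
  for (i in 1:20) {
    srcs <- sample(c(prio, "MDR", "CSP"), sample(1:5, 1))
    defs <- data.frame(definition = paste("def", srcs), def_source = srcs,
                       stringsAsFactors = FALSE)
    got <- select_definition(list(cui = "C3", definitions = defs))
    in_prio <- prio[prio %in% srcs]
    want_src <- if (length(in_prio)) in_prio[1] else srcs[1]
    expect_equal(got$source, want_src)
  }
})

test_that("prompts contain every candidate's CUI and definition exactly once", {
  idx <- build_index(fixture_concepts())
  cands <- decide(filter_candidates(search_index(idx, build_query(
    "boost", pipeline_config(q_type = "Exact"))), "boost", 0.96))$candidates
  for (style in c("CoT", "FewShot", "ZeroShot")) {
    p <- build_prompt("boost", "Treatment name", cands,
                      prompt_spec(style), idx)
    expect_equal(stringi::stri_count_fixed(p, "Entity: boost"), 1L)
    expect_equal(stringi::stri_count_fixed(p, "Treatment name"), 1L)
    for (i in seq_len(nrow(cands))) {
      expect_equal(stringi::stri_count_fixed(p, cands$cui[i]), 1L)
      entry <- idx$concepts[[cands$cui[i]]]
      expect_equal(stringi::stri_count_fixed(
        p, select_definition(entry)$definition), 1L)
      expect_true(grepl(cands$semantic_type[i], p, fixed = TRUE))
    }
  }
  # deterministic rendering
  p1 <- build_prompt("boost", "Treatment name", cands, prompt_spec(), idx)
  p2 <- build_prompt("boost", "Treatment name", cands, prompt_spec(), idx)
  expect_identical(p1, p2)
  # single candidate still renders
  expect_silent(build_prompt("boost", "Treatment name",
                             cands[1, , drop = FALSE], prompt_spec(), idx))
  bad <- cands; bad$cui[1] <- ""
  expect_error(build_prompt("boost", "Treatment name", bad,
                            prompt_spec(), idx), "CUI")
})

test_that("prompt token accounting matches an independent tokenizer", {
  idx <- build_index(fixture_concepts())
  cands <- decide(filter_candidates(search_index(idx, build_query(
    "boost", pipeline_config(q_type = "Exact"))), "boost", 0.96))$candidates
  p <- build_prompt("boost", "Treatment name", cands, prompt_spec(), idx)
  ref_count <- length(scan(text = p, what = "", quiet = TRUE,
                           quote = NULL))
  expect_equal(count_tokens(p), ref_count)
})

test_that("response parsing follows the answer grammar", {
  offered <- c("C0007097", "C0006141")
  r1 <- parse_response("Step by step... the best CUI is C0007097.", offered)
  expect_equal(r1$outcome, "SELECTED")
  expect_equal(r1$selected_cuis, "C0007097")

  r2 <- parse_response("No suitable CUI. TRANSLATION: right breast", offered)
  expect_equal(r2$outcome, "INADEQUATE")
  expect_equal(r2$translation, "right breast")

  # a non-offered CUI is discarded
  r3 <- parse_response("ANSWER: C9999999", offered)
  expect_equal(r3$outcome, "INADEQUATE")
  expect_length(r3$selected_cuis, 0L)

  r4 <- parse_response("ANSWER: C0007097 C0006141", offered)
  expect_setequal(r4$selected_cuis, offered)

  r5 <- parse_response("ANSWER: NONE | TRANSLATION: breast tumor", offered)
  expect_equal(r5$outcome, "INADEQUATE")
  expect_equal(r5$translation, "breast tumor")

  r6 <- parse_response("complete gibberish", offered)
  expect_equal(r6$outcome, "INADEQUATE")
  expect_null(r6$translation)
})

test_that("disambiguation keeps selections inside the offered set", {
  idx <- build_index(fixture_concepts())
  cands <- decide(filter_candidates(search_index(idx, build_query(
    "boost", pipeline_config(q_type = "Exact"))), "boost", 0.96))$candidates
  truth <- data.frame(surface = "boost", context = "Treatment name",
                      cui = "C0183683", stringsAsFactors = FALSE)
  oracle <- mock_llm("oracle", truth = truth)
  res <- disambiguate(oracle, "boost", "Treatment name", cands,
                      prompt_spec(), idx)
  expect_equal(res$outcome, "SELECTED")
  expect_equal(res$selected_cuis, "C0183683")
  expect_gt(res$token_usage$prompt_tokens, 0)

  adv <- mock_llm("adversarial", translations = c("boost" = "boost"))
  res2 <- disambiguate(adv, "boost", "Treatment name", cands,
                       prompt_spec(), idx)
  expect_equal(res2$outcome, "INADEQUATE")

  # transport failure: bounded retries, then INADEQUATE without translation
  calls <- 0L
  failing <- llm_client(function(prompt) {
    calls <<- calls + 1L
    stop("boom")
  })
  res3 <- disambiguate(failing, "boost", "Treatment name", cands,
                       prompt_spec(), idx, max_retries = 3L)
  expect_equal(res3$outcome, "INADEQUATE")
  expect_null(res3$translation)
  expect_equal(calls, 3L)
})

test_that("oracle disambiguation recovers the gold CUI on synthetic homonyms", {
  v <- gen_vocab(synth_spec(seed = 71, n_concepts = 60, homonym_rate = 0.3))
  idx <- build_index(aggregate_concepts(v$records))
  oracle <- mock_llm("oracle", truth = v$truth,
                     translations = v$translations)
  hom_surf <- names(which(table(v$truth$surface[v$truth$spa_in_vocab]) >= 2))
  cases <- v$truth[v$truth$surface %in% hom_surf & v$truth$spa_in_vocab, ]
  expect_gte(nrow(cases), 2L)
  ok <- vapply(seq_len(nrow(cases)), function(i) {
    cands <- decide(filter_candidates(search_index(idx, build_query(
      cases$surface[i], pipeline_config(q_type = "Exact"))),
      cases$surface[i], 0.96))$candidates
    res <- disambiguate(oracle, cases$surface[i], cases$context[i], cands,
                        prompt_spec(), idx)
    identical(res$selected_cuis, cases$cui[i])
  }, TRUE)
  expect_true(all(ok))
})

test_that("translation goes through the fixture dictionary", {
  dict <- c("mama derecha" = "right breast", "pulmón" = "lung")
  cli <- mock_llm("adversarial", translations = dict)
  expect_equal(translate_term(cli, "mama derecha")$translation,
               "right breast")
  # a term already in English comes back unchanged
  expect_equal(translate_term(cli, "right breast")$translation,
               "right breast")
  # round-trip 20 fixture pairs through the oracle mock
  v <- gen_vocab(synth_spec(seed = 73, n_concepts = 25))
  cli2 <- mock_llm("oracle", truth = v$truth,
                   translations = v$translations)
  pairs <- utils::head(v$translations, 20)
  for (i in seq_along(pairs)) {
    expect_equal(translate_term(cli2, names(pairs)[i])$translation,
                 unname(pairs[i]))
  }
})

test_that("scripted clients replay responses and error when exhausted", {
  cli <- mock_llm("scripted", script = c("ANSWER: C1", "ANSWER: NONE"))
  expect_equal(cli$complete("p")$text, "ANSWER: C1")
  expect_equal(cli$complete("p")$text, "ANSWER: NONE")
  expect_error(cli$complete("p"), "exhausted")
})
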