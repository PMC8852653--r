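small_spec <- function(seed = 1L, msgs = 80L, n_chats = 2L, ...) {
  synthetic_spec(
    groups = tibble::tibble(
      label = c("opposition", "control"),
      n_chats = c(n_chats, n_chats),
      messages_per_chat = c(msgs, msgs)
    ),
    seed = seed, ...
  )
}

test_that("generation produces one structurally valid export per chat", {
  g <- generate_corpus(small_spec(seed = 3))
  expect_equal(length(g$exports), 4)
  for (e in g$exports) {
    chat <- parse_export(e)
    expect_equal(sum(chat$kind == "message"), 80)
    expect_gt(sum(chat$kind == "service"), 0)
    expect_false(any(is.na(chat$timestamp)))
  }
  expect_equal(sort(unname(g$labels)), rep(c("control", "opposition"), each = 2))
  # member counts reported for the eligibility screen
  expect_true(all(g$members == 20))
})

test_that("the default spec mirrors the study design in miniature", {
  spec <- synthetic_spec()
  expect_equal(spec$groups$n_chats, c(4L, 4L))
  expect_equal(spec$groups$messages_per_chat, c(500L, 500L))
  rates <- spec$phrase_rates
  expect_equal(
    rates$rate[rates$label == "opposition" & rates$code == "green_pass"], 0.30
  )
  expect_equal(
    rates$rate[rates$label == "control" & rates$code == "green_pass"], 0.05
  )
  expect_equal(unname(spec$neg_word_rate[c("opposition", "control")]), c(0.6, 0.2))
  # the opposition chats carry the university/generic naming
  g <- generate_corpus(small_spec())
  plan_names <- purrr::map_chr(generate_corpus(synthetic_spec(
    groups = tibble::tibble(
      label = c("opposition", "control"), n_chats = c(4L, 4L),
      messages_per_chat = c(5L, 5L)
    )
  ))$exports, "name")
  expect_true(all(c(
    "university_north", "university_center", "university_south", "generic"
  ) %in% plan_names))
})

test_that("generation is byte-identical under a fixed seed", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  f1 <- generate_corpus(small_spec(seed = 9), dir = d1)$files
  f2 <- generate_corpus(small_spec(seed = 9), dir = d2)$files
  for (i in seq_along(f1)) {
    expect_identical(
      readBin(f1[i], "raw", file.size(f1[i])),
      readBin(f2[i], "raw", file.size(f2[i]))
    )
  }
  # and a different seed changes the content
  d3 <- withr::local_tempdir()
  f3 <- generate_corpus(small_spec(seed = 10), dir = d3)$files
  expect_false(identical(
    readBin(f1[1], "raw", file.size(f1[1])),
    readBin(f3[1], "raw", file.size(f3[1]))
  ))
})

test_that("a zero phrase rate plants nothing for that code", {
  spec <- small_spec(seed = 5)
  spec$phrase_rates$rate[spec$phrase_rates$code == "vaccine"] <- 0
  g <- generate_corpus(spec)
  corpus <- build_corpus(purrr::map(g$exports, parse_export), g$labels)
  codes <- code_corpus(corpus, example_dictionaries())
  expect_false("vaccine" %in% codes$code)
  expect_true("green_pass" %in% codes$code)
})

test_that("invalid specs are rejected before generation", {
  expect_error(small_spec(mention_rate = 1.5), "\\[0, 1\\]")
  bad <- small_spec()
  bad$phrase_rates$code[1] <- "inesistente"
  expect_error(generate_corpus(bad), "without a dictionary")
  bad2 <- small_spec()
  bad2$neg_word_rate <- c(opposition = 0.9, control = 0.9)
  bad2$pos_word_rate <- 0.2
  expect_error(generate_corpus(bad2), "exceed 1")
})

test_that("every pipeline stage runs clean on generated corpora", {
  for (seed in c(21, 22)) {
    g <- generate_corpus(small_spec(seed = seed, msgs = 40L))
    expect_no_error({
      corpus <- build_corpus(purrr::map(g$exports, parse_export), g$labels)
      anon <- anonymize_corpus(corpus, default_scrub_lexicons(), seed = seed)
      codes <- code_corpus(anon, example_dictionaries())
      freq <- rule_frequency(anon, codes)
      toks <- lemmatize_corpus(anon, default_lemmatizer())
      lemma_table(toks, by = "group")
      s <- score_corpus(anon, stub_scorer())
      compare_groups(
        dplyr::filter(freq, code == "green_pass"),
        statistic_name = "gp"
      )
      sub <- subcorpus_by_code(anon, codes, "green_pass")
      export_annotated(sub, codes, "green_pass")
    })
  }
})

test_that("a planted rule rate is recovered within its exact binomial CI", {
  spec <- synthetic_spec(
    groups = tibble::tibble(
      label = c("opposition", "control"), n_chats = c(1L, 1L),
      messages_per_chat = c(500L, 100L)
    ),
    seed = 31L
  )
  g <- generate_corpus(spec)
  corpus <- build_corpus(purrr::map(g$exports, parse_export), g$labels)
  codes <- code_corpus(corpus, example_dictionaries())
  freq <- rule_frequency(corpus, codes)
  rec <- recovery_report(g$truth, rule_freq = freq)
  rr <- rec[rec$quantity == "rule_rate" &
    rec$label == "opposition" & rec$item == "green_pass", ]
  expect_true(rr$covered)
  expect_equal(rr$planted, 0.30)
  # untested quantities are marked, not guessed
  expect_true(all(is.na(rec$covered[rec$quantity == "sentiment_mean"])))
})

test_that("joint recovery coverage stays near nominal across seeds", {
  # 10 generated corpora; each quantity is checked against an exact 95%
  # CI, so the pooled coverage fraction should stay well above 0.9
  covered <- integer(0)
  for (seed in 101:110) {
    g <- generate_corpus(small_spec(seed = seed, msgs = 100L))
    corpus <- build_corpus(purrr::map(g$exports, parse_export), g$labels)
    anon <- anonymize_corpus(corpus, default_scrub_lexicons(), seed = seed)
    codes <- code_corpus(anon, example_dictionaries())
    rec <- recovery_report(
      g$truth,
      rule_freq = rule_frequency(anon, codes),
      lemma_tokens = lemmatize_corpus(anon, default_lemmatizer()),
      sentiment = score_corpus(anon, stub_scorer())
    )
    covered <- c(covered, rec$covered[!is.na(rec$covered)])
  }
  expect_gt(mean(covered), 0.93)
})

test_that("equal planted groups rarely reach significance", {
  # null calibration at the corpus level: identical parameters in both
  # groups, Welch test on per-chat mean sentiment across 30 seeds
  n_sig <- 0
  for (seed in 201:230) {
    spec <- synthetic_spec(
      groups = tibble::tibble(
        label = c("opposition", "control"), n_chats = c(4L, 4L),
        messages_per_chat = c(40L, 40L)
      ),
      neg_word_rate = c(opposition = 0.3, control = 0.3),
      seed = seed
    )
    g <- generate_corpus(spec)
    corpus <- build_corpus(purrr::map(g$exports, parse_export), g$labels)
    s <- score_corpus(corpus, stub_scorer())
    cmp <- compare_groups(s$per_chat, value = "mean_p_neg")
    if (!is.na(cmp$p) && cmp$p < 0.05) n_sig <- n_sig + 1
  }
  expect_lte(n_sig, 3) # >= 90% non-significant
})
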