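test_that("the lexicon scorer implements the hit-ratio contract", {
  sc <- lexicon_scorer(neg = c("paura", "rabbia"), pos = c("felice", "ottimo"))
  expect_equal(sc("paura e rabbia ovunque"), 1.0)
  expect_equal(sc("niente di rilevante"), 0.5)
  expect_equal(sc("paura ma felice"), 0.5)
  expect_equal(sc("paura paura felice"), 2 / 3)
  # vectorized and deterministic
  expect_equal(sc(c("paura", "felice")), c(1, 0))
  # configuration errors
  expect_error(lexicon_scorer(c("x"), c("x", "y")), "overlap")
  expect_error(lexicon_scorer(character(), "y"), "non-empty")
})

test_that("per-chat means average messages; group means average chats", {
  # chat 11: scores 0.2 and 0.8 -> mean 0.5
  sc <- lexicon_scorer(neg = "paura", pos = "ottimo")
  corpus <- tiny_corpus(
    texts_a = c(
      "paura ottimo ottimo ottimo ottimo", # 1/5
      "paura paura paura paura ottimo" # 4/5
    ),
    texts_b = "neutro"
  )
  s <- score_corpus(corpus, sc)
  expect_equal(s$per_chat$mean_p_neg[s$per_chat$chat_id == "11"], 0.5)
  expect_equal(s$per_chat$mean_p_neg[s$per_chat$chat_id == "22"], 0.5)
  expect_equal(sort(s$per_message$p_neg[s$per_message$chat_id == "11"]), c(0.2, 0.8))
})

test_that("group aggregation is two-stage, not pooled", {
  sc <- lexicon_scorer(neg = "paura", pos = "ottimo")
  # one group, two chats of very different size:
  #   chat A: 1 message at p_neg 1      -> chat mean 1
  #   chat B: 9 messages at p_neg 0     -> chat mean 0
  # two-stage mean = 0.5; pooled mean would be 0.1
  doc_a <- make_doc("a", 1, list(msg_entry(1, "paura")))
  doc_b <- make_doc("b", 2, purrr::map(1:9, function(i) msg_entry(i, "ottimo")))
  corpus <- build_corpus(
    list(parse_export(doc_a), parse_export(doc_b)),
    c("1" = "g", "2" = "g")
  )
  s <- score_corpus(corpus, sc)
  expect_equal(s$per_group$mean_p_neg, 0.5)
  # and the group mean does not depend on chat ordering
  s2 <- score_corpus(dplyr::arrange(corpus, dplyr::desc(chat_id)), sc)
  expect_equal(s2$per_group$mean_p_neg, s$per_group$mean_p_neg)
})

test_that("a single-chat group reports SEM as missing, not zero", {
  sc <- stub_scorer()
  corpus <- tiny_corpus()
  s <- score_corpus(corpus, sc)
  expect_true(all(is.na(s$per_group$sem)))
  expect_equal(nrow(s$per_group), 2)
})

test_that("empty messages are skipped and counted, never scored 0.5", {
  sc <- lexicon_scorer(neg = "paura", pos = "ottimo")
  corpus <- tiny_corpus(texts_a = c("paura", "", "   "), texts_b = "ottimo")
  s <- score_corpus(corpus, sc)
  expect_equal(s$n_skipped, 2)
  expect_equal(nrow(s$per_message), 2)
  expect_equal(s$per_chat$mean_p_neg[s$per_chat$chat_id == "11"], 1.0)
})

test_that("probabilities always lie in [0, 1]", {
  s <- score_corpus(small_gen()$anon, stub_scorer())
  expect_true(all(s$per_message$p_neg >= 0 & s$per_message$p_neg <= 1))
  expect_true(all(s$per_chat$mean_p_neg >= 0 & s$per_chat$mean_p_neg <= 1))
  expect_true(all(s$per_group$mean_p_neg >= 0 & s$per_group$mean_p_neg <= 1))
})

test_that("sentiment by code restricts to fired messages", {
  sc <- lexicon_scorer(neg = "paura", pos = "ottimo")
  corpus <- tiny_corpus(
    texts_a = c(
      "tessera verde paura paura", # fires, p_neg 1
      "ottimo ottimo", # does not fire
      "pass verde ottimo" # fires, p_neg 0
    ),
    texts_b = "paura" # control chat: no firing message
  )
  codes <- code_corpus(corpus, green_pass_dict())
  s <- sentiment_by_code(corpus, codes, "green_pass", sc)
  expect_equal(nrow(s$per_message), 2)
  expect_equal(s$per_chat$mean_p_neg, 0.5)
  # chats where the code never fired are absent from the group layer
  expect_false("control" %in% s$per_group$group)
  # a code firing everywhere reproduces the full-corpus summary
  all_dict <- dictionary("tutto", "\\w")
  codes_all <- code_corpus(corpus, all_dict)
  s_all <- sentiment_by_code(corpus, codes_all, "tutto", sc)
  expect_equal(s_all$per_chat, score_corpus(corpus, sc)$per_chat)
  # a code firing nowhere warns and yields an empty summary
  expect_warning(
    s_none <- sentiment_by_code(corpus, codes, "assente", sc),
    "empty"
  )
  expect_equal(nrow(s_none$per_message), 0)
})

test_that("tidy/glance expose per-chat and whole-run views", {
  s <- score_corpus(small_gen()$anon, stub_scorer())
  td <- tidy(s)
  expect_s3_class(td, "tbl_df")
  expect_true(all(c("chat_id", "group", "mean_p_neg") %in% names(td)))
  gl <- glance(s)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$n_chats, 4)
  p <- autoplot(s)
  expect_s3_class(p, "ggplot")
})

test_that("a higher planted negative-word rate raises the group mean", {
  spec <- synthetic_spec(
    groups = tibble::tibble(
      label = c("opposition", "control"), n_chats = c(2L, 2L),
      messages_per_chat = c(100L, 100L)
    ),
    seed = 11L
  )
  g <- generate_corpus(spec)
  corpus <- build_corpus(purrr::map(g$exports, parse_export), g$labels)
  anon <- anonymize_corpus(corpus, default_scrub_lexicons(), seed = 11)
  s <- score_corpus(anon, stub_scorer())
  m <- setNames(s$per_group$mean_p_neg, s$per_group$group)
  expect_gt(m["opposition"], m["control"])
})
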