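test_that("a plain single-entry document parses to one message", {
  doc <- make_doc(entries = list(msg_entry(1, "ciao")))
  chat <- parse_export(doc)
  expect_equal(nrow(chat), 1)
  expect_equal(chat$text, "ciao")
  expect_equal(chat$kind, "message")
  expect_equal(chat$chat_id, "1")
  expect_s3_class(chat$timestamp, "POSIXct")
})

test_that("entity arrays are flattened by in-order concatenation", {
  e <- msg_entry(1, list("ciao ", list(type = "mention", text = "@thisuser")))
  chat <- parse_export(make_doc(entries = list(e)))
  expect_equal(chat$text, "ciao @thisuser")

  # attachments without text contribute empty text
  e2 <- msg_entry(2, NULL)
  e2$text <- NULL
  e2$photo <- "photo.jpg"
  chat2 <- parse_export(make_doc(entries = list(e2)))
  expect_equal(chat2$text, "")
})

test_that("text_entities wins over the legacy text field when both exist", {
  e <- msg_entry(1, "legacy text")
  e$text_entities <- list(
    list(type = "plain", text = "nuovo "),
    list(type = "mention", text = "@qualcuno")
  )
  chat <- parse_export(make_doc(entries = list(e)))
  expect_equal(chat$text, "nuovo @qualcuno")
})

test_that("flattening an already-plain string is idempotent", {
  strings <- c("", "ciao", "testo con @menzione e url http://x", "a b  c")
  for (s in strings) {
    expect_identical(flatten_text(s), s)
    expect_identical(flatten_text(flatten_text(s)), flatten_text(s))
  }
})

test_that("service entries are retained but excluded from textual analysis", {
  doc <- make_doc(entries = list(
    msg_entry(1, "ciao"),
    list(id = 2, type = "service", date = "2021-09-05T10:01:00",
         actor = "x", action = "pin_message", text = "")
  ))
  chat <- parse_export(doc)
  expect_equal(nrow(chat), 2)
  expect_equal(chat$kind, c("message", "service"))
  corpus <- build_corpus(list(chat), c("1" = "a"))
  codes <- code_corpus(corpus, green_pass_dict())
  freq <- rule_frequency(corpus, codes, "green_pass")
  expect_equal(freq$n_messages, 1) # the service row is not a denominator
})

test_that("malformed documents raise errors naming the problem", {
  expect_error(parse_export(list(name = "x", id = 1)), "messages")
  bad <- make_doc(entries = list(msg_entry(1, "ok"), list(type = "message")))
  expect_error(parse_export(bad), "index 2")
  expect_error(parse_export("no/such/file.json"), "not found")
})

test_that("eligibility applies both criteria with inclusive boundaries", {
  mk <- function(n, date) {
    parse_export(make_doc(entries = purrr::map(
      seq_len(n), function(i) msg_entry(i, "x", date = date)
    )))
  }
  ref <- as.Date("2021-09-09")
  # exactly 10 recent messages and exactly 200 members -> eligible
  chat <- mk(10, "2021-09-02T00:00:00") # ref - 7 days, inclusive
  expect_true(filter_eligible(chat, ref, member_count = 200))
  # fails the activity criterion despite many members
  expect_false(filter_eligible(mk(9, "2021-09-08T12:00:00"), ref, 10000))
  # fails the size criterion despite heavy activity
  expect_false(filter_eligible(mk(500, "2021-09-08T12:00:00"), ref, 199))
  # stale messages don't count
  expect_false(filter_eligible(mk(50, "2021-08-01T12:00:00"), ref, 1000))
  # empty chat is ineligible
  empty <- parse_export(make_doc(entries = list()))
  expect_false(filter_eligible(empty, ref, 1000))
})

test_that("eligibility is monotone in members and in recent activity", {
  ref <- as.Date("2021-09-09")
  mk <- function(n) {
    parse_export(make_doc(entries = purrr::map(
      seq_len(n), function(i) msg_entry(i, "x", date = "2021-09-08T12:00:00")
    )))
  }
  for (n in c(5, 10, 15)) {
    for (m in c(150, 200, 300)) {
      ok <- filter_eligible(mk(n), ref, m)
      # increasing either argument can never turn TRUE into FALSE
      expect_true(!ok || filter_eligible(mk(n + 5), ref, m))
      expect_true(!ok || filter_eligible(mk(n), ref, m + 100))
    }
  }
})

test_that("build_corpus enforces the labelling invariant", {
  a <- parse_export(make_doc("a", 1, list(msg_entry(1, "x"))))
  b <- parse_export(make_doc("b", 2, list(msg_entry(1, "y"))))
  corpus <- build_corpus(list(a, b), c("1" = "opposition", "2" = "control"))
  expect_equal(sort(unique(corpus$group)), c("control", "opposition"))
  expect_equal(nrow(corpus), 2)

  expect_error(build_corpus(list(a), c("99" = "x")), "Unlabeled chat.*1")
  expect_warning(empty <- build_corpus(list(), c()), "empty")
  expect_equal(nrow(empty), 0)
  # duplicated chat ids across exports are rejected
  expect_error(
    build_corpus(list(a, a), c("1" = "x")),
    "Duplicate chat_id"
  )
})

test_that("parsing a written synthetic export recovers the document exactly", {
  g <- small_gen()$gen
  dir <- withr::local_tempdir()
  spec <- synthetic_spec(
    groups = tibble::tibble(
      label = c("opposition", "control"), n_chats = c(2L, 2L),
      messages_per_chat = c(120L, 120L)
    ),
    seed = 42L
  )
  files <- generate_corpus(spec, dir = dir)$files
  from_file <- purrr::map(files, parse_export)
  from_memory <- purrr::map(g$exports, parse_export)
  for (i in seq_along(from_file)) {
    expect_equal(from_file[[i]]$msg_id, from_memory[[i]]$msg_id)
    expect_equal(from_file[[i]]$text, from_memory[[i]]$text)
    expect_equal(from_file[[i]]$timestamp, from_memory[[i]]$timestamp)
    expect_equal(from_file[[i]]$kind, from_memory[[i]]$kind)
  }
})
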