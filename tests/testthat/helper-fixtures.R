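# Fixture builders shared across test files. Everything is constructed in
# code; no fixture files.

# A minimal raw export document in the Telegram result.json dialect.
make_doc <- function(name = "chat", id = 1, entries = list()) {
  list(name = name, type = "private_supergroup", id = id, messages = entries)
}

msg_entry <- function(id, text, date = "2021-09-05T10:00:00",
                      from_id = "user111", from = "Utente 111",
                      type = "message") {
  list(id = id, type = type, date = date, from = from, from_id = from_id,
       text = text)
}

# A tiny two-chat labelled corpus built directly from documents.
tiny_corpus <- function(texts_a = c("ciao a tutti", "ho la tessera verde"),
                        texts_b = c("parliamo di musica")) {
  doc_a <- make_doc("alpha", 11, purrr::imap(
    texts_a, function(t, i) msg_entry(i, t, from_id = sprintf("user%d", i))
  ))
  doc_b <- make_doc("beta", 22, purrr::imap(
    texts_b, function(t, i) msg_entry(i, t, from_id = "user999")
  ))
  build_corpus(
    list(parse_export(doc_a), parse_export(doc_b)),
    c("11" = "opposition", "22" = "control")
  )
}

# A small synthetic generation shared by several files (cached per session).
small_gen <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      spec <- synthetic_spec(
        groups = tibble::tibble(
          label = c("opposition", "control"),
          n_chats = c(2L, 2L),
          messages_per_chat = c(120L, 120L)
        ),
        seed = 42L
      )
      g <- generate_corpus(spec)
      corpus <- build_corpus(purrr::map(g$exports, parse_export), g$labels)
      cache <<- list(
        gen = g,
        corpus = corpus,
        anon = anonymize_corpus(corpus, default_scrub_lexicons(), seed = 42L)
      )
    }
    cache
  }
})

stub_scorer <- function() {
  do.call(lexicon_scorer, default_sentiment_lexicons())
}

# The worked green-pass dictionary (single printed rule).
green_pass_dict <- function() {
  dictionary(
    "green_pass",
    "(tesser.\\sverd.?|pass\\sverd.?|certifica\\w*\\sverd.?)"
  )
}
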