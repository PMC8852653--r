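#' Build a lookup-table lemmatizer
#'
#' The lemmatizer contract is a function mapping a character vector of
#' texts to one tibble with columns `doc` (index into the input vector),
#' `token`, `lemma`, `pos` — deterministic for a fixed input, rows in
#' surface order within each document. This constructor builds one from a
#' lookup table: tokens are lowercased, matched against the table, and
#' fall back to themselves (identity lemma) when absent. A morphological
#' model for Italian can be wrapped behind the same contract; the lookup
#' form keeps every analysis reproducible with no external model
#' artifact.
#'
#' @param mapping Named character vector: `surface = lemma` (surfaces
#'   matched case-insensitively).
#' @param pos Optional named character vector: `surface = tag` (any
#'   tagset; tags listed in `drop_pos` of [lemmatize_corpus()] are
#'   removed). Tokens without a tag get `"X"`.
#' @return A function of class `lemmatizer`.
#' @examples
#' lem <- lookup_lemmatizer(c(tessere = "tessera", verdi = "verde"))
#' lem("Tessere verdi")
#' @export
lookup_lemmatizer <- function(mapping = character(), pos = character()) {
  mapping <- setNames(as.character(mapping), tolower(names(mapping)))
  pos <- setNames(as.character(pos), tolower(names(pos)))
  f <- function(text) {
    toks <- tokenize(text)
    n <- lengths(toks)
    tk <- unlist(toks, use.names = FALSE)
    if (is.null(tk)) tk <- character()
    low <- tolower(tk)
    lemma <- unname(mapping[low])
    lemma[is.na(lemma)] <- low[is.na(lemma)]
    tag <- unname(pos[low])
    tag[is.na(tag)] <- "X"
    tibble(
      doc = rep(seq_along(text), n),
      token = tk, lemma = lemma, pos = tag
    )
  }
  structure(f, class = c("lemmatizer", "function"))
}

# Tokenizer: placeholders are kept as single tokens so they can be
# dropped downstream; everything else splits on Unicode word characters.
tokenize <- function(text) {
  text <- as.character(text)
  text[is.na(text)] <- ""
  stringr::str_extract_all(
    text,
    stringr::regex("\\[(?:name|place|username)\\]|[\\p{L}\\p{N}_@]+")
  )
}

#' Default Italian function-word stoplist
#'
#' Articles, prepositions, conjunctions, pronouns and common auxiliaries.
#' Frequency tables of content words presuppose removing these; the list
#' is deliberately small and transparent, and fully replaceable via the
#' `stoplist` argument of [lemmatize_corpus()].
#'
#' @return Character vector of lowercase stop lemmas.
#' @export
italian_stopwords <- function() {
  c(
    "il", "lo", "la", "i", "gli", "le", "un", "uno", "una", "l",
    "di", "a", "da", "in", "con", "su", "per", "tra", "fra",
    "al", "allo", "alla", "ai", "agli", "alle", "del", "dello", "della",
    "dei", "degli", "delle", "dal", "dallo", "dalla", "dai", "dagli",
    "dalle", "nel", "nello", "nella", "nei", "negli", "nelle",
    "sul", "sullo", "sulla", "sui", "sugli", "sulle",
    "e", "ed", "o", "od", "ma", "se", "che", "chi", "cui", "non",
    "come", "dove", "quando", "quindi", "anche", "ancora", "gia",
    "io", "tu", "lui", "lei", "noi", "voi", "loro", "mi", "ti", "si",
    "ci", "vi", "ne", "questo", "questa", "questi", "queste", "quello",
    "quella", "quelli", "quelle", "mio", "tuo", "suo", "nostro", "vostro",
    "essere", "avere", "sono", "sei", "siamo", "siete", "ho", "hai",
    "ha", "abbiamo", "avete", "hanno", "piu", "meno", "molto", "poco",
    "tutto", "tutti", "cosa", "cose", "perche", "pero", "cioe"
  )
}

#' Lemmatize a corpus into a token stream
#'
#' Runs the lemmatizer over every textual message of the (sub)corpus and
#' returns the retained lemma stream: stoplist lemmas, dropped
#' part-of-speech tags, privacy placeholders (`[name]`, `[place]`,
#' `[username]`), purely numeric tokens and residual handles are removed.
#' Lemmas are case-folded and NFC-normalized before counting.
#'
#' @param corpus A corpus tibble (or subset, e.g. from
#'   [subcorpus_by_code()]).
#' @param lemmatizer A function honouring the lemmatizer contract (see
#'   [lookup_lemmatizer()]).
#' @param stoplist Character vector of lemmas to drop; default
#'   [italian_stopwords()].
#' @param drop_pos Part-of-speech tags to drop (default punctuation,
#'   numeral and symbol tags).
#' @return A tibble with columns `chat_id`, `group` (if present),
#'   `msg_id`, `lemma` — one row per retained token, in surface order.
#' @export
lemmatize_corpus <- function(corpus, lemmatizer,
                             stoplist = italian_stopwords(),
                             drop_pos = c("PUNCT", "NUM", "SYM")) {
  assert_corpus(corpus)
  msgs <- textual(corpus)
  if (nrow(msgs) == 0) {
    warn("Lemmatizing an empty corpus subset: returning an empty stream.")
    return(tibble(
      chat_id = character(), msg_id = integer(), lemma = character()
    ))
  }
  stream <- lemmatizer(msgs$text)
  out <- tibble(
    chat_id = msgs$chat_id[stream$doc],
    msg_id = msgs$msg_id[stream$doc],
    lemma = stringr::str_to_lower(stream$lemma),
    pos = stream$pos
  )
  if ("group" %in% names(msgs)) {
    out <- dplyr::mutate(out,
      group = msgs$group[stream$doc], .after = "chat_id"
    )
  }
  placeholders <- c("[name]", "[place]", "[username]")
  out <- out |>
    dplyr::mutate(lemma = stringi_nfc(.data$lemma)) |>
    dplyr::filter(
      !.data$pos %in% drop_pos,
      !.data$lemma %in% placeholders,
      !.data$lemma %in% stoplist,
      !stringr::str_detect(.data$lemma, "^[\\p{N}_]+$"),
      !stringr::str_starts(.data$lemma, stringr::fixed("@"))
    ) |>
    dplyr::select(-"pos")
  out
}

# NFC normalization; stringr/stringi ships with the tidyverse.
stringi_nfc <- function(x) {
  stringi::stri_trans_nfc(x)
}

#' Lemma counts and percentage frequencies
#'
#' @param tokens A token stream from [lemmatize_corpus()].
#' @param by Optional grouping column of the stream (`"chat_id"` or
#'   `"group"`); default `NULL` pools the whole stream. Percentages are
#'   computed within each group so each group's `freq_pct` sums to 100.
#' @return A tibble with (optional grouping column,) `lemma`, `n`,
#'   `freq_pct`, sorted by descending `freq_pct`, ties broken
#'   lexicographically by lemma.
#' @examples
#' toks <- tibble::tibble(
#'   chat_id = "c1", msg_id = 1L,
#'   lemma = c("verde", "verde", rep("pass", 8))
#' )
#' lemma_table(toks)
#' @export
lemma_table <- function(tokens, by = NULL) {
  if (nrow(tokens) == 0) {
    out <- tibble(lemma = character(), n = integer(), freq_pct = numeric())
    if (!is.null(by)) {
      out <- dplyr::mutate(out, "{by}" := character(), .before = 1)
    }
    return(out)
  }
  grp <- if (is.null(by)) character() else by
  tokens |>
    dplyr::count(dplyr::across(dplyr::all_of(grp)), .data$lemma, name = "n") |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
    dplyr::mutate(freq_pct = 100 * .data$n / sum(.data$n)) |>
    dplyr::ungroup() |>
    dplyr::arrange(
      dplyr::across(dplyr::all_of(grp)),
      dplyr::desc(.data$freq_pct), .data$lemma
    )
}

#' Per-chat frequency of a lemma set
#'
#' For each chat, the summed percentage frequency of the given lemmas on
#' that chat's own token stream — the per-chat statistic behind
#' group-level lemma comparisons (e.g. the combined frequency of the
#' lemmas "green" and "pass").
#'
#' @param corpus A corpus tibble.
#' @param lemmatizer Lemmatizer function.
#' @param lemmas Character vector of lemmas (non-empty).
#' @param ... Passed to [lemmatize_corpus()].
#' @return A tibble `chat_id`, `group` (if present), `pct`. Chats with an
#'   empty retained stream are excluded with a warning.
#' @export
per_chat_lemma_frequency <- function(corpus, lemmatizer, lemmas, ...) {
  if (length(lemmas) == 0) {
    abort("`lemmas` must name at least one lemma.")
  }
  lemmas <- stringr::str_to_lower(lemmas)
  toks <- lemmatize_corpus(corpus, lemmatizer, ...)
  chats_in <- unique(textual(corpus)$chat_id)
  chats_with <- unique(toks$chat_id)
  dropped <- setdiff(chats_in, chats_with)
  if (length(dropped) > 0) {
    warn(sprintf(
      "Excluding chat(s) with empty token stream: %s",
      paste(dropped, collapse = ", ")
    ))
  }
  out <- toks |>
    dplyr::group_by(.data$chat_id) |>
    dplyr::summarise(
      pct = 100 * sum(.data$lemma %in% lemmas) / dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$chat_id)
  if ("group" %in% names(corpus)) {
    key <- dplyr::distinct(corpus, .data$chat_id, .data$group)
    out <- dplyr::left_join(out, key, by = "chat_id") |>
      dplyr::relocate("group", .after = "chat_id")
  }
  out
}

#' Subset a corpus to the messages a code fired on
#'
#' @param corpus A corpus tibble.
#' @param codes Code matrix from [code_corpus()].
#' @param code A single code label.
#' @return The corpus rows whose (chat_id, msg_id) carry weight >= 1 for
#'   `code`, in original order; chat structure (columns) preserved. An
#'   absent code yields an empty subset with a warning.
#' @export
subcorpus_by_code <- function(corpus, codes, code) {
  assert_corpus(corpus)
  hit <- codes |>
    dplyr::filter(.data$code == !!code, .data$weight >= 1) |>
    dplyr::distinct(.data$chat_id, .data$msg_id)
  if (nrow(hit) == 0) {
    warn(sprintf("Code '%s' fired on no message: empty subcorpus.", code))
    return(corpus[0, ])
  }
  dplyr::semi_join(textual(corpus), hit, by = c("chat_id", "msg_id"))
}

#' Top lemmas of a frequency table
#'
#' @param table A lemma table from [lemma_table()] (ungrouped form).
#' @param n Number of lemmas (default 20). `n = 0` gives an empty list;
#'   `n` beyond the vocabulary returns the full list.
#' @return Character vector of lemmas by descending `freq_pct`, ties
#'   broken lexicographically.
#' @export
top_lemmas <- function(table, n = 20) {
  ord <- dplyr::arrange(table, dplyr::desc(.data$freq_pct), .data$lemma)
  head(ord$lemma, n)
}
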