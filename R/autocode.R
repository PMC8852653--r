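#' Define a regex dictionary for one concept
#'
#' A dictionary gathers the regular expressions that express a single
#' concept (a "code"), e.g. a `green_pass` code whose one rule
#' `(tesser.\sverd.?|pass\sverd.?|certifica\w*\sverd.?)` fires on
#' "tessera verde", "tessere verdi", "pass verde" or "certificato verde",
#' but not on "casa verde", "verderame" or "tessera del cinema". Patterns
#' are interpreted in the ICU regex dialect (PCRE-compatible for the
#' constructs used here: alternation, `\s`, `\w` with Unicode word
#' characters including Italian diacritics, `.`/`?` quantifiers), and are
#' matched case-insensitively by default — chat text is casually cased.
#'
#' @param code Unique label for the concept (e.g. `"green_pass"`).
#' @param patterns Character vector of one or more regular expressions;
#'   every pattern must compile.
#' @param description Free-text description of the concept.
#' @param case_insensitive Match case-insensitively (default `TRUE`).
#' @return An object of class `dictionary` with compiled matchers in
#'   pattern order.
#' @examples
#' dictionary("green_pass",
#'   patterns = "(tesser.\\sverd.?|pass\\sverd.?|certifica\\w*\\sverd.?)"
#' )
#' @export
dictionary <- function(code, patterns, description = "",
                       case_insensitive = TRUE) {
  if (length(code) != 1 || !nzchar(code)) {
    abort("`code` must be a single non-empty label.")
  }
  patterns <- as.character(patterns)
  if (length(patterns) < 1) {
    abort(sprintf("Dictionary '%s' needs at least one pattern.", code))
  }
  compiled <- vector("list", length(patterns))
  for (i in seq_along(patterns)) {
    rx <- stringr::regex(patterns[i], ignore_case = case_insensitive)
    ok <- tryCatch(
      {
        stringr::str_detect("", rx)
        TRUE
      },
      error = function(e) FALSE
    )
    if (!ok) {
      abort(sprintf(
        "Dictionary '%s': pattern %d does not compile: %s",
        code, i, patterns[i]
      ))
    }
    compiled[[i]] <- rx
  }
  structure(
    list(
      code = code, patterns = patterns, description = description,
      case_insensitive = case_insensitive, compiled = compiled
    ),
    class = "dictionary"
  )
}

#' @export
print.dictionary <- function(x, ...) {
  cat(sprintf(
    "<dictionary '%s': %d pattern(s)%s>\n", x$code, length(x$patterns),
    if (nzchar(x$description)) paste0(" - ", x$description) else ""
  ))
  invisible(x)
}

#' Read a dictionary set from YAML
#'
#' The file holds a list of entries with fields `code`, `description`
#' (optional) and `patterns`. Code labels must be unique within the set.
#' An example file reproducing the worked green-pass rule ships with the
#' package: `system.file("extdata", "dictionaries.yaml",
#' package = "socioscope")`.
#'
#' @param path Path to a YAML dictionary file.
#' @param case_insensitive Passed to [dictionary()].
#' @return A named list of `dictionary` objects.
#' @export
read_dictionaries <- function(path, case_insensitive = TRUE) {
  raw <- yaml::read_yaml(path)
  dicts <- purrr::map(raw, function(d) {
    dictionary(
      code = d$code,
      patterns = unlist(d$patterns),
      description = d$description %||% "",
      case_insensitive = case_insensitive
    )
  })
  as_dictionary_set(dicts)
}

#' Validate a list of dictionaries as a set
#'
#' @param dicts A list of `dictionary` objects.
#' @return The same list, named by code, after checking label uniqueness.
#' @export
as_dictionary_set <- function(dicts) {
  if (inherits(dicts, "dictionary")) {
    dicts <- list(dicts)
  }
  ok <- purrr::map_lgl(dicts, inherits, "dictionary")
  if (!all(ok)) {
    abort("All elements must be dictionary() objects.")
  }
  codes <- purrr::map_chr(dicts, "code")
  dup <- unique(codes[duplicated(codes)])
  if (length(dup) > 0) {
    abort(sprintf("Duplicate code label(s): %s.", paste(dup, collapse = ", ")))
  }
  setNames(dicts, codes)
}

#' Weight of a dictionary on each message
#'
#' The autocoding weight system: the weight of a code on a message is the
#' number of *distinct* rules of its dictionary that fire — one rule
#' firing gives weight 1, two rules firing give weight 2, and so on.
#' Repeated matches of the same rule within one message still count once.
#' Counting every match occurrence instead is available via
#' `count_occurrences = TRUE` for diagnostic use.
#'
#' @param text Character vector of (privacy-transformed) message texts.
#' @param dict A `dictionary` object.
#' @param count_occurrences If `TRUE`, sum match occurrences over patterns
#'   instead of counting distinct firing patterns.
#' @return Integer vector of weights, one per message.
#' @examples
#' gp <- dictionary("green_pass",
#'   "(tesser.\\sverd.?|pass\\sverd.?|certifica\\w*\\sverd.?)"
#' )
#' code_message(c("ho la tessera verde", "casa verde"), gp)
#' @export
code_message <- function(text, dict, count_occurrences = FALSE) {
  if (!inherits(dict, "dictionary")) {
    abort("`dict` must be a dictionary() object.")
  }
  text <- as.character(text)
  w <- integer(length(text))
  for (rx in dict$compiled) {
    if (count_occurrences) {
      w <- w + stringr::str_count(text, rx)
    } else {
      w <- w + as.integer(stringr::str_detect(text, rx))
    }
  }
  w[is.na(text)] <- 0L
  w
}

#' Autocode a corpus against a dictionary set
#'
#' Runs every dictionary over every textual message and records the firing
#' weights. The result — the code matrix — is the backbone of all
#' prevalence, subcorpus and per-code sentiment analyses.
#'
#' @param corpus An anonymized corpus tibble.
#' @param dicts A `dictionary` object, a list of them, or the result of
#'   [as_dictionary_set()].
#' @return A tibble with columns `chat_id`, `msg_id`, `code`, `weight`,
#'   one row per (message, code) with weight > 0. Absent pairs have
#'   weight 0.
#' @export
code_corpus <- function(corpus, dicts) {
  assert_corpus(corpus)
  dicts <- as_dictionary_set(dicts)
  msgs <- textual(corpus)
  out <- purrr::map(dicts, function(d) {
    w <- code_message(msgs$text, d)
    hit <- w > 0L
    tibble(
      chat_id = msgs$chat_id[hit],
      msg_id = msgs$msg_id[hit],
      code = d$code,
      weight = w[hit]
    )
  })
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0) {
    res <- tibble(
      chat_id = character(), msg_id = integer(),
      code = character(), weight = integer()
    )
  }
  res
}

#' Per-chat rule frequency (percentage of messages firing)
#'
#' The prevalence of a code in a chat: 100 times the number of textual
#' messages on which the code fired (weight >= 1) over the number of
#' textual messages of the chat. Message-level prevalence matches the
#' message-level weight system; the per-chat values are the unit on which
#' group comparisons and SEM error bars are computed.
#'
#' @param corpus The corpus the code matrix was computed on.
#' @param codes Code matrix from [code_corpus()].
#' @param code Code label(s) to report; default all codes in `codes`.
#' @return A tibble with columns `chat_id`, `group` (if labelled), `code`,
#'   `n_messages`, `n_fired`, `pct`, ordered by `chat_id`. Chats with zero
#'   textual messages are excluded with a warning.
#' @export
rule_frequency <- function(corpus, codes, code = NULL) {
  assert_corpus(corpus)
  if (is.null(code)) {
    code <- unique(codes$code)
  }
  msgs <- textual(corpus)
  has_group <- "group" %in% names(corpus)
  denom <- msgs |>
    dplyr::group_by(.data$chat_id) |>
    dplyr::summarise(n_messages = dplyr::n(), .groups = "drop")
  all_chats <- unique(corpus$chat_id)
  empty <- setdiff(all_chats, denom$chat_id[denom$n_messages > 0])
  if (length(empty) > 0) {
    warn(sprintf(
      "Excluding chat(s) with no textual messages: %s",
      paste(empty, collapse = ", ")
    ))
  }
  fired <- codes |>
    dplyr::filter(.data$code %in% !!code, .data$weight >= 1) |>
    dplyr::distinct(.data$chat_id, .data$msg_id, .data$code) |>
    dplyr::count(.data$chat_id, .data$code, name = "n_fired")
  grid <- tidyr::expand_grid(
    chat_id = sort(denom$chat_id),
    code = sort(unique(code))
  )
  out <- grid |>
    dplyr::left_join(denom, by = "chat_id") |>
    dplyr::left_join(fired, by = c("chat_id", "code")) |>
    dplyr::mutate(
      n_fired = dplyr::coalesce(.data$n_fired, 0L),
      pct = 100 * .data$n_fired / .data$n_messages
    ) |>
    dplyr::arrange(.data$chat_id, .data$code)
  if (has_group) {
    key <- dplyr::distinct(corpus, .data$chat_id, .data$group)
    out <- dplyr::left_join(out, key, by = "chat_id") |>
      dplyr::relocate("group", .after = "chat_id")
  }
  out
}

#' Per-pattern firing report for dictionary development
#'
#' Dictionary writing is iterative: run the rules, inspect what fired and
#' what slipped through, refine. This report gives, per pattern, the
#' number of messages it fires on, plus a sample of messages no pattern of
#' the dictionary matched.
#'
#' @param corpus An anonymized corpus tibble.
#' @param dict A `dictionary` object.
#' @param n_sample Number of unmatched messages to sample (deterministic:
#'   the first `n_sample` in corpus order).
#' @return A list with `per_pattern` (tibble: pattern index, pattern,
#'   n_messages fired) and `unmatched_sample` (character vector).
#' @export
pattern_report <- function(corpus, dict, n_sample = 10) {
  assert_corpus(corpus)
  msgs <- textual(corpus)
  per <- purrr::imap(dict$compiled, function(rx, i) {
    tibble(
      pattern_index = i,
      pattern = dict$patterns[i],
      n_messages = sum(stringr::str_detect(msgs$text, rx), na.rm = TRUE)
    )
  }) |> dplyr::bind_rows()
  w <- code_message(msgs$text, dict)
  unmatched <- msgs$text[w == 0 & nzchar(msgs$text)]
  list(
    per_pattern = per,
    unmatched_sample = head(unmatched, n_sample)
  )
}
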