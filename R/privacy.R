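#' Scrub lexicons for anonymization
#'
#' Bundles the word lists driving name and toponym scrubbing. Matching is
#' case-insensitive on whole words, so `"marco"` covers `"Marco"` but not
#' `"marcolino"`. Detection is lexicon-driven by design: no named-entity
#' model is required and the transformation stays deterministic; a
#' model-based recognizer can be substituted simply by materialising its
#' vocabulary into these lists.
#'
#' @param names Character vector of personal (first) names to replace with
#'   `[name]`. Surnames are deliberately not scrubbed: in informal chat
#'   they refer to public figures, not to chat members, and carry analytic
#'   value.
#' @param toponyms Character vector of place names to replace with
#'   `[place]`.
#' @return An object of class `scrub_lexicons`.
#' @seealso [read_scrub_lexicons()] to load the lists from plain-text
#'   files, [default_scrub_lexicons()] for the built-in Italian lists used
#'   by the synthetic generator.
#' @export
scrub_lexicons <- function(names, toponyms) {
  names <- unique(tolower(as.character(names)))
  toponyms <- unique(tolower(as.character(toponyms)))
  if (length(names) == 0 && length(toponyms) == 0) {
    abort("Scrub lexicons are empty: supply at least one name or toponym.")
  }
  structure(list(names = names, toponyms = toponyms), class = "scrub_lexicons")
}

#' @export
print.scrub_lexicons <- function(x, ...) {
  cat(sprintf(
    "<scrub_lexicons: %d names, %d toponyms>\n",
    length(x$names), length(x$toponyms)
  ))
  invisible(x)
}

#' Load scrub lexicons from plain-text word lists
#'
#' @param names_file,toponyms_file UTF-8 text files, one entry per line;
#'   blank lines and lines starting with `#` are ignored.
#' @return A `scrub_lexicons` object.
#' @export
read_scrub_lexicons <- function(names_file, toponyms_file) {
  read_list <- function(path) {
    x <- trimws(readLines(path, encoding = "UTF-8"))
    x[nzchar(x) & !startsWith(x, "#")]
  }
  scrub_lexicons(read_list(names_file), read_list(toponyms_file))
}

#' Replace user mentions with a placeholder
#'
#' Every `@handle` token (an `@` preceded by a word boundary and followed
#' by one or more word characters) becomes the literal placeholder
#' `[username]`. An `@` embedded inside a word — as in an e-mail address
#' fragment like `a@b` — is left untouched: the handle pattern requires
#' that the `@` not be preceded by a word character.
#'
#' @param text Character vector of message texts.
#' @return Character vector with mentions replaced.
#' @examples
#' scrub_mentions("chiedi a @thisuser")
#' scrub_mentions("email me at a@b") # unchanged
#' @export
scrub_mentions <- function(text) {
  stringr::str_replace_all(text, stringr::regex("(?<!\\w)@\\w+"), "[username]")
}

#' Replace names and toponyms with placeholders
#'
#' Whole-word, case-insensitive occurrences of lexicon entries are
#' replaced: personal names by `[name]`, toponyms by `[place]`. Surnames
#' are not in scope (see [scrub_lexicons()]).
#'
#' @param text Character vector of message texts.
#' @param lexicons A `scrub_lexicons` object.
#' @return Character vector with names and toponyms replaced.
#' @examples
#' lex <- scrub_lexicons(names = "marco", toponyms = "milano")
#' scrub_entities("Marco vive a Milano", lex)
#' @export
scrub_entities <- function(text, lexicons) {
  if (!inherits(lexicons, "scrub_lexicons")) {
    abort("`lexicons` must be built with scrub_lexicons().")
  }
  text <- scrub_wordlist(text, lexicons$names, "[name]")
  scrub_wordlist(text, lexicons$toponyms, "[place]")
}

scrub_wordlist <- function(text, words, placeholder) {
  if (length(words) == 0) {
    return(text)
  }
  pat <- paste0("\\b(", paste(stringr::str_escape(words), collapse = "|"), ")\\b")
  stringr::str_replace_all(
    text, stringr::regex(pat, ignore_case = TRUE),
    stringr::fixed(placeholder)
  )
}

#' Build a deterministic pseudonym map
#'
#' Assigns each sender identifier a pseudonym token `user_0001`,
#' `user_0002`, ... The assignment is a seeded random permutation of the
#' sorted identifier set, so it is deterministic given (identifiers, seed),
#' bijective, and unlinkable to first-appearance order in the chat.
#'
#' @param sender_ids Character vector of sender identifiers (duplicates
#'   allowed; `NA` entries, typical of service messages, are ignored).
#' @param seed Integer seed.
#' @return A tibble with columns `sender_id` and `pseudonym`.
#' @export
pseudonym_map <- function(sender_ids, seed = 1L) {
  ids <- sort(unique(as.character(sender_ids[!is.na(sender_ids)])))
  if (length(ids) == 0) {
    return(tibble(sender_id = character(), pseudonym = character()))
  }
  shuffled <- withr::with_seed(as.integer(seed), sample(ids))
  tibble(
    sender_id = shuffled,
    pseudonym = sprintf("user_%04d", seq_along(shuffled))
  )
}

#' Anonymize and pseudonymize a corpus
#'
#' Applies the full privacy transformation downstream analysis is required
#' to run on: every message text is passed through [scrub_mentions()] and
#' then [scrub_entities()]; sender identifiers are replaced by pseudonyms
#' from a seeded [pseudonym_map()]; sender display names are dropped. The
#' input corpus is left untouched, and the transformation is idempotent —
#' placeholders contain no scrubbable tokens.
#'
#' The pseudonym map is attached to the returned corpus as an attribute
#' (retrieve it with [get_pseudonym_map()]); store it separately from the
#' anonymized corpus if conversations must remain re-traceable, or discard
#' it for irreversible anonymization.
#'
#' @param corpus A corpus tibble from [build_corpus()].
#' @param lexicons A `scrub_lexicons` object.
#' @param seed Integer seed for the pseudonym assignment.
#' @return The anonymized corpus tibble, with attribute `pseudonym_map`.
#' @export
anonymize_corpus <- function(corpus, lexicons, seed = 1L) {
  assert_corpus(corpus)
  if (missing(lexicons) || !inherits(lexicons, "scrub_lexicons")) {
    abort("Scrubbing requires `lexicons` built with scrub_lexicons().")
  }
  pmap <- pseudonym_map(corpus$sender_id, seed = seed)
  lookup <- setNames(pmap$pseudonym, pmap$sender_id)
  out <- corpus |>
    dplyr::mutate(
      text = scrub_entities(scrub_mentions(.data$text), lexicons),
      sender_id = dplyr::if_else(
        is.na(.data$sender_id), NA_character_,
        unname(lookup[.data$sender_id])
      ),
      sender_name = NA_character_
    )
  attr(out, "pseudonym_map") <- pmap
  attr(out, "anonymized") <- TRUE
  out
}

#' Retrieve the pseudonym map attached by [anonymize_corpus()]
#'
#' @param corpus An anonymized corpus tibble.
#' @return A tibble with columns `sender_id` (original) and `pseudonym`,
#'   or `NULL` if the corpus carries no map.
#' @export
get_pseudonym_map <- function(corpus) {
  attr(corpus, "pseudonym_map", exact = TRUE)
}
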