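#' Parse a Telegram Desktop chat export
#'
#' Reads one `result.json` document produced by the "export chat history"
#' function of Telegram's desktop client and returns its messages as a tidy
#' tibble, one row per exported entry. Only textual content is retained:
#' the polymorphic `text` field (a plain string, or an array mixing strings
#' and typed entity objects such as mentions and links) is flattened by
#' concatenating the textual content of each element in order, and the
#' newer `text_entities` array takes precedence over `text` when both are
#' present. Non-textual attachments contribute empty text. Service entries
#' (joins, pins, calls, ...) are parsed and kept with `kind = "service"` so
#' that counts are faithful, but every analysis function in the package
#' excludes them.
#'
#' @param doc Path to an export JSON file, or an already-parsed list with
#'   elements `name`, `type`, `id` and `messages`.
#' @return A tibble with columns `chat_id`, `chat_name`, `chat_type`,
#'   `msg_id`, `timestamp` (POSIXct, kept timezone-naive as exported and
#'   represented in UTC), `sender_id`, `sender_name`, `kind`
#'   (`"message"` or `"service"`) and `text`.
#' @examples
#' doc <- list(
#'   name = "esempio", type = "private_supergroup", id = 42,
#'   messages = list(list(
#'     id = 1, type = "message", date = "2021-09-01T10:00:00",
#'     from = "A", from_id = "user1", text = "ciao"
#'   ))
#' )
#' parse_export(doc)
#' @export
parse_export <- function(doc) {
  if (is.character(doc)) {
    if (length(doc) != 1 || !file.exists(doc)) {
      abort(sprintf("Export file not found: %s", paste(doc, collapse = ", ")))
    }
    doc <- jsonlite::read_json(doc)
  }
  if (!is.list(doc)) {
    abort("`doc` must be a file path or a parsed export list.")
  }
  if (is.null(doc$messages)) {
    abort("Malformed export: no `messages` list found.")
  }
  msgs <- doc$messages
  chat_id <- as.character(doc$id %||% NA_character_)
  chat_name <- as.character(doc$name %||% NA_character_)
  chat_type <- normalize_chat_type(doc$type %||% "other")

  n <- length(msgs)
  msg_id <- integer(n)
  timestamp <- character(n)
  sender_id <- character(n)
  sender_name <- character(n)
  kind <- character(n)
  text <- character(n)
  for (i in seq_len(n)) {
    m <- msgs[[i]]
    if (!is.list(m) || is.null(m$id) || is.null(m$date)) {
      abort(sprintf("Malformed export entry at index %d: missing id or date.", i))
    }
    msg_id[i] <- as.integer(m$id)
    timestamp[i] <- as.character(m$date)
    sender_id[i] <- as.character(m$from_id %||% NA_character_)
    sender_name[i] <- as.character(m$from %||% NA_character_)
    kind[i] <- if (identical(m$type, "service")) "service" else "message"
    text[i] <- tryCatch(
      flatten_text(m),
      error = function(e) {
        abort(sprintf("Malformed export entry at index %d: %s", i, conditionMessage(e)))
      }
    )
  }
  out <- tibble(
    msg_id = msg_id, timestamp = timestamp,
    sender_id = sender_id, sender_name = sender_name,
    kind = kind, text = text
  )
  out <- dplyr::mutate(
    out,
    chat_id = chat_id, chat_name = chat_name, chat_type = chat_type,
    timestamp = as.POSIXct(.data$timestamp, format = "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
    .before = 1
  )
  out
}

normalize_chat_type <- function(type) {
  type <- as.character(type)
  if (grepl("supergroup", type)) "supergroup"
  else if (grepl("channel", type)) "channel"
  else if (grepl("group", type)) "group"
  else "other"
}

#' Flatten the polymorphic text of one export entry
#'
#' Telegram exports carry message text either as a plain string, as an
#' array whose elements are strings or typed objects (`{type, text}`), or —
#' in newer client versions — additionally as a `text_entities` array.
#' Flattening concatenates the textual content of each element in order;
#' `text_entities` wins when both forms are present. Flattening a plain
#' string returns it unchanged (idempotence).
#'
#' @param entry A single parsed export entry (list), or a plain text value.
#' @return A single character string (possibly empty).
#' @export
flatten_text <- function(entry) {
  if (is.character(entry)) {
    return(paste(entry, collapse = ""))
  }
  if (!is.list(entry)) {
    return(if (is.null(entry)) "" else as.character(entry))
  }
  field <- if (!is.null(entry$text_entities)) entry$text_entities else entry$text
  flatten_text_field(field)
}

flatten_text_field <- function(field) {
  if (is.null(field)) {
    return("")
  }
  if (is.character(field)) {
    return(paste(field, collapse = ""))
  }
  if (is.list(field)) {
    parts <- purrr::map_chr(field, function(el) {
      if (is.character(el)) {
        paste(el, collapse = "")
      } else if (is.list(el)) {
        if (is.null(el$text)) "" else as.character(el$text)
      } else {
        as.character(el)
      }
    })
    return(paste(parts, collapse = ""))
  }
  as.character(field)
}

#' Screen a chat for eligibility
#'
#' Applies the activity and size screen used to select control chats: the
#' chat must be active — at least `min_recent` textual messages sent within
#' the `window_days` days up to `reference_date` (inclusive at both ends) —
#' and must count at least `min_members` users. Exports do not record the
#' member count, so it is supplied externally (read it off the client when
#' exporting).
#'
#' @param chat A chat tibble from [parse_export()].
#' @param reference_date A `Date` (or string) marking the end of the
#'   activity window.
#' @param member_count Number of users in the chat, supplied externally.
#' @param min_recent Minimum number of recent textual messages (default 10).
#' @param window_days Length of the activity window in days (default 7).
#' @param min_members Minimum member count (default 200).
#' @return `TRUE` if the chat passes both criteria, else `FALSE`. An empty
#'   chat is ineligible.
#' @export
filter_eligible <- function(chat, reference_date, member_count,
                            min_recent = 10, window_days = 7,
                            min_members = 200) {
  assert_corpus(chat, "chat")
  if (missing(reference_date) || is.null(reference_date)) {
    abort("`reference_date` must be supplied.")
  }
  if (missing(member_count) || is.null(member_count)) {
    abort("`member_count` must be supplied (exports do not record it).")
  }
  reference_date <- as.Date(reference_date)
  if (nrow(chat) == 0) {
    return(FALSE)
  }
  dates <- as.Date(chat$timestamp)
  recent <- chat$kind == "message" &
    !is.na(dates) &
    dates >= reference_date - window_days &
    dates <= reference_date
  sum(recent) >= min_recent && member_count >= min_members
}

#' Assemble a labelled corpus from parsed exports
#'
#' Binds chat exports into a single corpus tibble and attaches a group
#' label (e.g. `"opposition"` / `"control"`) to every chat. Every chat must
#' be labelled; the label column is the unit over which all group-level
#' statistics in the package are aggregated.
#'
#' @param exports A list of chat tibbles from [parse_export()].
#' @param labels A named character vector (`chat_id = label`) or a data
#'   frame with columns `chat_id` and `group`.
#' @return A corpus tibble: one row per message, with a `group` column.
#' @export
build_corpus <- function(exports, labels) {
  if (is.data.frame(exports)) {
    exports <- list(exports)
  }
  if (length(exports) == 0) {
    warn("Building an empty corpus: no exports supplied.")
    return(tibble(
      chat_id = character(), chat_name = character(), chat_type = character(),
      group = character(), msg_id = integer(),
      timestamp = as.POSIXct(character(), tz = "UTC"),
      sender_id = character(), sender_name = character(),
      kind = character(), text = character()
    ))
  }
  if (is.data.frame(labels)) {
    lab <- setNames(as.character(labels$group), as.character(labels$chat_id))
  } else {
    lab <- setNames(as.character(labels), names(labels))
  }
  export_ids <- purrr::map_chr(exports, function(e) {
    if (nrow(e) > 0) e$chat_id[1] else NA_character_
  })
  export_ids <- export_ids[!is.na(export_ids)]
  if (anyDuplicated(export_ids) > 0) {
    abort("Duplicate chat_id across exports; chat_id must be unique in a corpus.")
  }
  corpus <- dplyr::bind_rows(exports)
  ids <- unique(corpus$chat_id)
  unlabeled <- setdiff(ids, names(lab))
  if (length(unlabeled) > 0) {
    abort(sprintf(
      "Unlabeled chat(s): %s. Every chat_id needs a group label.",
      paste(unlabeled, collapse = ", ")
    ))
  }
  dplyr::mutate(corpus, group = unname(lab[.data$chat_id]), .after = "chat_type")
}
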