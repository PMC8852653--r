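#' Export a subcorpus as an annotated document for qualitative coding
#'
#' Renders a (sub)corpus as a structured plain-text document: each message
#' gets a header line `«<pseudonym>» [code:weight, ...]` followed by its
#' text split on newlines. Positions count *text lines only* — headers are
#' excluded from the numbering — so a quote cited as "position 14716-14718"
#' refers to text lines 14716 through 14718 of the subcorpus, matching
#' how positions are reported alongside quotes in thematic analysis. The
#' rendering is deterministic: re-exporting the same inputs is
#' byte-identical.
#'
#' @param corpus An anonymized (sub)corpus tibble, e.g. from
#'   [subcorpus_by_code()].
#' @param codes Code matrix from [code_corpus()] (may cover a larger
#'   corpus; only rows for messages present in `corpus` are used). `NULL`
#'   for an export without code annotations.
#' @param label Subcorpus label (used in the header and default file
#'   name).
#' @return An object of class `annotated_document`: a list with `label`,
#'   `lines` (the full rendered lines, headers included), and `index` (a
#'   tibble `chat_id`, `msg_id`, `start`, `end` of 1-based text-line
#'   positions, contiguous and non-overlapping).
#' @export
export_annotated <- function(corpus, codes = NULL, label = "subcorpus") {
  assert_corpus(corpus)
  msgs <- textual(corpus)
  if (!is.null(codes) && nrow(codes) > 0) {
    ann <- codes |>
      dplyr::filter(.data$weight >= 1) |>
      dplyr::arrange(.data$chat_id, .data$msg_id, .data$code) |>
      dplyr::group_by(.data$chat_id, .data$msg_id) |>
      dplyr::summarise(
        ann = paste(sprintf("%s:%d", .data$code, .data$weight), collapse = ", "),
        .groups = "drop"
      )
    msgs <- dplyr::left_join(msgs, ann, by = c("chat_id", "msg_id"))
  } else {
    msgs <- dplyr::mutate(msgs, ann = NA_character_)
  }
  lines <- character()
  idx <- vector("list", nrow(msgs))
  pos <- 0L
  for (i in seq_len(nrow(msgs))) {
    speaker <- msgs$sender_id[i]
    if (is.na(speaker)) speaker <- "unknown"
    codes_part <- if (is.na(msgs$ann[i])) "" else sprintf(" [%s]", msgs$ann[i])
    header <- sprintf("«%s»%s", speaker, codes_part)
    txt <- msgs$text[i]
    if (is.na(txt)) txt <- ""
    body <- strsplit(txt, "\n", fixed = TRUE)[[1]]
    if (length(body) == 0) body <- ""
    lines <- c(lines, header, body)
    idx[[i]] <- tibble(
      chat_id = msgs$chat_id[i],
      msg_id = msgs$msg_id[i],
      start = pos + 1L,
      end = pos + length(body)
    )
    pos <- pos + length(body)
  }
  index <- if (nrow(msgs) > 0) dplyr::bind_rows(idx) else
    tibble(chat_id = character(), msg_id = integer(),
           start = integer(), end = integer())
  structure(
    list(label = label, lines = lines, index = index),
    class = "annotated_document"
  )
}

#' @export
print.annotated_document <- function(x, ...) {
  cat(sprintf(
    "<annotated_document '%s': %d messages, %d text lines>\n",
    x$label, nrow(x$index),
    if (nrow(x$index) > 0) max(x$index$end) else 0L
  ))
  invisible(x)
}

#' Write an annotated document and its sidecar index
#'
#' @param doc An `annotated_document`.
#' @param path Output `.txt` path; defaults to `<label>.txt` in the
#'   current directory.
#' @param index_path Sidecar JSON index path; default `<path>.index.json`.
#' @return Invisibly, the paths written.
#' @export
write_annotated <- function(doc, path = paste0(doc$label, ".txt"),
                            index_path = paste0(path, ".index.json")) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(doc$lines, con, useBytes = TRUE)
  jsonlite::write_json(
    list(label = doc$label, index = doc$index),
    index_path,
    dataframe = "rows", auto_unbox = TRUE, digits = NA
  )
  invisible(c(path, index_path))
}

#' Locate the message containing a text-line position
#'
#' Reverse lookup for quote auditing: given a position (or range) cited
#' with a quote, return the message whose text-line range contains it.
#'
#' @param doc An `annotated_document`.
#' @param position 1-based text-line position, or a length-2 range
#'   `c(start, end)` (resolved by its start).
#' @return One row of the document index (`chat_id`, `msg_id`, `start`,
#'   `end`).
#' @export
locate <- function(doc, position) {
  if (!inherits(doc, "annotated_document")) {
    abort("`doc` must be an annotated_document.")
  }
  pos <- as.integer(position[1])
  top <- if (nrow(doc$index) > 0) max(doc$index$end) else 0L
  if (is.na(pos) || pos < 1 || pos > top) {
    abort(sprintf(
      "Position %s is outside the document (text lines 1..%d).",
      as.character(position[1]), top
    ))
  }
  hit <- dplyr::filter(doc$index, .data$start <= pos, pos <= .data$end)
  hit[1, ]
}
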