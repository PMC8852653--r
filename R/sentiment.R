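#' Build a lexicon-based binary sentiment scorer
#'
#' The scorer contract is a deterministic function mapping a character
#' vector of texts to per-message probabilities of negative sentiment
#' `p_neg` in [0, 1], with `p_pos = 1 - p_neg` (binary polarity). This
#' constructor builds the lexicon scorer: `p_neg = n_neg / (n_neg +
#' n_pos)` over whole-word, case-insensitive lexicon hits, and 0.5 when
#' no lexicon word occurs. A transformer-based Italian polarity model can
#' be wrapped behind the same contract; the lexicon form is deterministic
#' and needs no model artifact, which is what every test and synthetic
#' analysis in the package uses.
#'
#' @param neg,pos Disjoint, non-empty character vectors of negative and
#'   positive words.
#' @return A function of class `sentiment_scorer`.
#' @examples
#' sc <- lexicon_scorer(neg = c("paura", "rabbia"), pos = "felice")
#' sc(c("che paura e che rabbia", "sono felice", "boh"))
#' @export
lexicon_scorer <- function(neg, pos) {
  neg <- unique(tolower(as.character(neg)))
  pos <- unique(tolower(as.character(pos)))
  if (length(neg) == 0 || length(pos) == 0) {
    abort("Both lexicons must be non-empty.")
  }
  overlap <- intersect(neg, pos)
  if (length(overlap) > 0) {
    abort(sprintf(
      "Sentiment lexicons overlap: %s.", paste(overlap, collapse = ", ")
    ))
  }
  word_rx <- function(words) {
    stringr::regex(
      paste0("\\b(", paste(stringr::str_escape(words), collapse = "|"), ")\\b"),
      ignore_case = TRUE
    )
  }
  rx_neg <- word_rx(neg)
  rx_pos <- word_rx(pos)
  f <- function(text) {
    n_neg <- stringr::str_count(text, rx_neg)
    n_pos <- stringr::str_count(text, rx_pos)
    p <- ifelse(n_neg + n_pos == 0, 0.5, n_neg / (n_neg + n_pos))
    as.numeric(p)
  }
  structure(f, class = c("sentiment_scorer", "function"))
}

#' Score a corpus and aggregate sentiment chat-then-group
#'
#' Every textual, non-empty message is scored for its probability of
#' negative sentiment; scores are then averaged per chat, and group means
#' are the *unweighted* means of the per-chat means (two-stage
#' aggregation: the chat, not the message, is the statistical unit, so a
#' very large chat does not dominate its group). SEM is computed across
#' chats within a group and reported as missing for single-chat groups.
#' Messages left empty after privacy transformation, and messages the
#' scorer fails on, are skipped — not scored 0.5 — and counted.
#'
#' @param corpus An anonymized corpus tibble with a `group` column.
#' @param scorer A scorer honouring the contract (see [lexicon_scorer()]).
#' @return An object of class `sentiment_summary`: a list with tibbles
#'   `per_message` (`chat_id`, `msg_id`, `p_neg`), `per_chat` (`chat_id`,
#'   `group`, `n_messages`, `mean_p_neg`) and `per_group` (`group`,
#'   `n_chats`, `mean_p_neg`, `sem`), plus `n_skipped`.
#' @export
score_corpus <- function(corpus, scorer) {
  assert_corpus(corpus)
  msgs <- textual(corpus)
  scorable <- !is.na(msgs$text) & nzchar(trimws(msgs$text))
  n_skipped <- sum(!scorable)
  msgs <- msgs[scorable, ]
  p <- rep(NA_real_, nrow(msgs))
  if (nrow(msgs) > 0) {
    p <- tryCatch(scorer(msgs$text), error = function(e) {
      # score one-by-one so a single failing message is skipped, not fatal
      purrr::map_dbl(msgs$text, function(t) {
        tryCatch(scorer(t), error = function(e) NA_real_)
      })
    })
  }
  failed <- is.na(p)
  if (any(failed)) {
    n_skipped <- n_skipped + sum(failed)
    inform(sprintf("Scorer failed on %d message(s); skipped.", sum(failed)))
    msgs <- msgs[!failed, ]
    p <- p[!failed]
  }
  per_message <- tibble(
    chat_id = msgs$chat_id, msg_id = msgs$msg_id, p_neg = p
  )
  has_group <- "group" %in% names(msgs)
  per_chat <- per_message |>
    dplyr::group_by(.data$chat_id) |>
    dplyr::summarise(
      n_messages = dplyr::n(),
      mean_p_neg = mean(.data$p_neg),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$chat_id)
  if (has_group) {
    key <- dplyr::distinct(corpus, .data$chat_id, .data$group)
    per_chat <- dplyr::left_join(per_chat, key, by = "chat_id") |>
      dplyr::relocate("group", .after = "chat_id")
    per_group <- per_chat |>
      dplyr::group_by(.data$group) |>
      dplyr::summarise(
        n_chats = dplyr::n(),
        sem = sem(.data$mean_p_neg),
        mean_p_neg = mean(.data$mean_p_neg),
        .groups = "drop"
      ) |>
      dplyr::relocate("sem", .after = "mean_p_neg")
  } else {
    per_group <- tibble(
      group = character(), n_chats = integer(),
      mean_p_neg = numeric(), sem = numeric()
    )
  }
  structure(
    list(
      per_message = per_message, per_chat = per_chat,
      per_group = per_group, n_skipped = n_skipped
    ),
    class = "sentiment_summary"
  )
}

#' Sentiment restricted to the messages a code fired on
#'
#' Same two-stage aggregation as [score_corpus()], but over the subcorpus
#' of messages with weight >= 1 for `code`. Chats where the code never
#' fired contribute no per-chat mean and are excluded from the group mean.
#'
#' @param corpus An anonymized corpus tibble.
#' @param codes Code matrix from [code_corpus()].
#' @param code A single code label.
#' @param scorer A sentiment scorer.
#' @return A `sentiment_summary` over the fired messages; empty (with a
#'   warning) if the code fired nowhere.
#' @export
sentiment_by_code <- function(corpus, codes, code, scorer) {
  sub <- withCallingHandlers(
    subcorpus_by_code(corpus, codes, code),
    warning = function(w) invokeRestart("muffleWarning")
  )
  if (nrow(sub) == 0) {
    warn(sprintf("Code '%s' fired on no message: empty sentiment summary.", code))
  }
  score_corpus(sub, scorer)
}

#' @export
print.sentiment_summary <- function(x, ...) {
  cat(sprintf(
    "<sentiment_summary: %d messages scored, %d skipped, %d chats>\n",
    nrow(x$per_message), x$n_skipped, nrow(x$per_chat)
  ))
  if (nrow(x$per_group) > 0) {
    print(x$per_group)
  }
  invisible(x)
}

#' @describeIn score_corpus `tidy()` returns the per-chat means.
#' @param x A `sentiment_summary`.
#' @param ... Unused.
#' @export
tidy.sentiment_summary <- function(x, ...) {
  x$per_chat
}

#' @describeIn score_corpus `glance()` returns one row: messages scored,
#'   skipped, chats, and the grand mean of per-chat means.
#' @export
glance.sentiment_summary <- function(x, ...) {
  tibble(
    n_messages = nrow(x$per_message),
    n_skipped = x$n_skipped,
    n_chats = nrow(x$per_chat),
    mean_p_neg = if (nrow(x$per_chat) > 0) mean(x$per_chat$mean_p_neg) else NA_real_
  )
}

#' @describeIn score_corpus `autoplot()` draws the group means of
#'   negative-sentiment probability with SEM error bars.
#' @param object A `sentiment_summary`.
#' @export
autoplot.sentiment_summary <- function(object, ...) {
  dat <- object$per_group
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$group, y = .data$mean_p_neg)) +
    ggplot2::geom_col(fill = "grey35", width = 0.6) +
    ggplot2::geom_errorbar(
      ggplot2::aes(
        ymin = .data$mean_p_neg - .data$sem,
        ymax = .data$mean_p_neg + .data$sem
      ),
      width = 0.15, na.rm = TRUE
    ) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(
      x = NULL, y = "Mean probability of negative sentiment",
      caption = "Error bars: SEM across chats"
    ) +
    ggplot2::theme_minimal()
}
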