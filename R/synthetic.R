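#' Specify a synthetic chat corpus with planted structure
#'
#' Defines the parameters of a generated Telegram-export-style corpus
#' whose statistical structure is known in closed form, so every pipeline
#' stage can be validated without access to real chat data. The defaults
#' mirror the study design in miniature: 4 green-pass-opposition chats
#' (three university groups and one generic group) versus 4 control
#' chats, 500 textual messages each; the opposition group carries a
#' planted per-message rate of 0.30 for dictionary-matching green-pass
#' phrases against 0.05 in controls, and a negative-lexicon token rate of
#' 0.6 against 0.2 (positive rate 0.2 in both groups, so the control
#' group centres at a negative-sentiment probability of 0.5).
#'
#' @param groups Tibble with columns `label`, `n_chats`,
#'   `messages_per_chat`.
#' @param phrase_rates Tibble with columns `label`, `code`, `rate`:
#'   per-message probability of inserting one phrase matching that code's
#'   dictionary.
#' @param neg_word_rate Named numeric: per-label probability that a
#'   filler token is drawn from the negative lexicon.
#' @param pos_word_rate Single probability (shared by all groups) that a
#'   filler token is drawn from the positive lexicon.
#' @param tokens_per_message Number of filler tokens per message.
#' @param n_users_per_chat Users per chat (also the member count reported
#'   for eligibility screening).
#' @param mention_rate,name_rate,toponym_rate Per-message probabilities
#'   of planting an `@`-mention, a lexicon first name, a lexicon toponym.
#' @param newline_rate Per-message probability of an embedded newline
#'   (exercises multi-line positions in the qualitative export).
#' @param n_service Service entries inserted per chat (excluded from all
#'   analytics).
#' @param seed Integer seed; generation is fully deterministic given the
#'   spec.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(groups = NULL,
                           phrase_rates = NULL,
                           neg_word_rate = c(opposition = 0.6, control = 0.2),
                           pos_word_rate = 0.2,
                           tokens_per_message = 8,
                           n_users_per_chat = 20,
                           mention_rate = 0.05,
                           name_rate = 0.05,
                           toponym_rate = 0.05,
                           newline_rate = 0.05,
                           n_service = 3,
                           seed = 1L) {
  if (is.null(groups)) {
    groups <- tibble(
      label = c("opposition", "control"),
      n_chats = c(4L, 4L),
      messages_per_chat = c(500L, 500L)
    )
  }
  if (is.null(phrase_rates)) {
    phrase_rates <- tibble(
      label = rep(c("opposition", "control"), each = 2),
      code = rep(c("green_pass", "vaccine"), times = 2),
      rate = c(0.30, 0.15, 0.05, 0.03)
    )
  }
  spec <- structure(
    list(
      groups = groups, phrase_rates = phrase_rates,
      neg_word_rate = neg_word_rate, pos_word_rate = pos_word_rate,
      tokens_per_message = as.integer(tokens_per_message),
      n_users_per_chat = as.integer(n_users_per_chat),
      mention_rate = mention_rate, name_rate = name_rate,
      toponym_rate = toponym_rate, newline_rate = newline_rate,
      n_service = as.integer(n_service),
      seed = as.integer(seed)
    ),
    class = "synthetic_spec"
  )
  validate_synthetic_spec(spec)
  spec
}

#' @export
print.synthetic_spec <- function(x, ...) {
  cat("<synthetic_spec>\n")
  print(x$groups)
  print(x$phrase_rates)
  cat(sprintf(
    "neg_word_rate: %s; pos_word_rate: %.2f; seed %d\n",
    paste(sprintf("%s=%.2f", names(x$neg_word_rate), x$neg_word_rate),
      collapse = ", "
    ),
    x$pos_word_rate, x$seed
  ))
  invisible(x)
}

# Validates probability ranges and the mutual consistency of vocabulary,
# lexicons and dictionary phrases: each planted phrase must match exactly
# one pattern of its own code's dictionary and no pattern of any other,
# and no filler / sentiment-lexicon word may fire any dictionary.
validate_synthetic_spec <- function(spec, dicts = example_dictionaries(),
                                    voc = synthetic_vocabulary()) {
  probs <- c(
    spec$phrase_rates$rate, spec$neg_word_rate, spec$pos_word_rate,
    spec$mention_rate, spec$name_rate, spec$toponym_rate, spec$newline_rate
  )
  if (any(probs < 0 | probs > 1)) {
    abort("All synthetic_spec probabilities must lie in [0, 1].")
  }
  if (any(spec$neg_word_rate + spec$pos_word_rate > 1)) {
    abort("neg_word_rate + pos_word_rate must not exceed 1.")
  }
  missing_lab <- setdiff(spec$groups$label, names(spec$neg_word_rate))
  if (length(missing_lab) > 0) {
    abort(sprintf(
      "neg_word_rate missing for group(s): %s.",
      paste(missing_lab, collapse = ", ")
    ))
  }
  bad_code <- setdiff(unique(spec$phrase_rates$code), names(dicts))
  if (length(bad_code) > 0) {
    abort(sprintf(
      "phrase_rates references code(s) without a dictionary: %s.",
      paste(bad_code, collapse = ", ")
    ))
  }
  for (code in names(voc$phrases)) {
    for (ph in voc$phrases[[code]]) {
      own <- sum(purrr::map_lgl(
        dicts[[code]]$compiled,
        ~ stringr::str_detect(ph, .x)
      ))
      if (own != 1) {
        abort(sprintf(
          "Planted phrase '%s' matches %d patterns of its dictionary '%s' (need exactly 1).",
          ph, own, code
        ))
      }
      others <- setdiff(names(dicts), code)
      for (oc in others) {
        if (code_message(ph, dicts[[oc]]) > 0) {
          abort(sprintf(
            "Planted phrase '%s' also fires dictionary '%s'.", ph, oc
          ))
        }
      }
    }
  }
  neutral <- c(voc$fillers$surface, voc$neg, voc$pos)
  for (d in dicts) {
    if (any(code_message(neutral, d) > 0)) {
      abort(sprintf("A filler/lexicon word fires dictionary '%s'.", d$code))
    }
  }
  invisible(spec)
}

#' Generate a synthetic corpus of Telegram-style exports
#'
#' Produces one export document per chat — structurally valid input for
#' [parse_export()], including a fraction of entity-array texts (every
#' planted mention is exported through `text_entities`) and service
#' entries — together with the planted truth the pipeline should recover.
#' Generation is fully deterministic given the spec's seed: the same spec
#' yields byte-identical documents.
#'
#' @param spec A [synthetic_spec()].
#' @param dir Optional directory; when given, each export is also written
#'   as `<chat_name>.json`.
#' @return A list with elements `exports` (list of export documents,
#'   parseable lists), `labels` (named character vector `chat_id` ->
#'   group label), `members` (named integer vector of member counts),
#'   `truth` (a `planted_truth` object, see [recovery_report()]) and
#'   `files` (paths written, if `dir` was given).
#' @export
generate_corpus <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  voc <- synthetic_vocabulary()
  dicts <- example_dictionaries()
  validate_synthetic_spec(spec, dicts, voc)

  chat_plan <- chat_plan(spec)
  exports <- withr::with_seed(spec$seed, {
    purrr::pmap(chat_plan, function(label, chat_id, chat_name, n_msg) {
      generate_chat(spec, voc, label, chat_id, chat_name, n_msg)
    })
  })
  labels <- setNames(chat_plan$label, chat_plan$chat_id)
  members <- setNames(
    rep(spec$n_users_per_chat, nrow(chat_plan)), chat_plan$chat_id
  )
  files <- NULL
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    files <- purrr::map2_chr(exports, chat_plan$chat_name, function(e, nm) {
      path <- file.path(dir, paste0(nm, ".json"))
      jsonlite::write_json(e, path, auto_unbox = TRUE, digits = NA)
      path
    })
  }
  list(
    exports = exports, labels = labels, members = members,
    truth = planted_truth(spec, voc), files = files
  )
}

chat_plan <- function(spec) {
  rows <- purrr::pmap(spec$groups, function(label, n_chats, messages_per_chat) {
    nm <- if (label == "opposition" && n_chats == 4) {
      c("university_north", "university_center", "university_south", "generic")
    } else {
      sprintf("%s_%02d", label, seq_len(n_chats))
    }
    tibble(label = label, chat_name = nm, n_msg = messages_per_chat)
  })
  plan <- dplyr::bind_rows(rows)
  dplyr::mutate(plan, chat_id = as.character(1000 + dplyr::row_number()),
    .after = "label"
  )
}

generate_chat <- function(spec, voc, label, chat_id, chat_name, n_msg) {
  q_neg <- unname(spec$neg_word_rate[label])
  q_pos <- spec$pos_word_rate
  users <- sprintf("user%06d", sample(100000:999999, spec$n_users_per_chat))
  rates <- spec$phrase_rates[spec$phrase_rates$label == label, ]
  t0 <- as.POSIXct("2021-09-01 00:00:00", tz = "UTC")
  dt <- (8 * 86400) / max(n_msg, 1)

  entries <- vector("list", n_msg)
  for (i in seq_len(n_msg)) {
    u <- runif(spec$tokens_per_message)
    tok <- character(spec$tokens_per_message)
    is_neg <- u < q_neg
    is_pos <- !is_neg & u < q_neg + q_pos
    n_fill <- sum(!is_neg & !is_pos)
    tok[is_neg] <- sample(voc$neg, sum(is_neg), replace = TRUE)
    tok[is_pos] <- sample(voc$pos, sum(is_pos), replace = TRUE)
    tok[!is_neg & !is_pos] <- sample(
      voc$fillers$surface, n_fill,
      replace = TRUE, prob = voc$fillers$prob
    )
    # planted dictionary phrases, one Bernoulli per code
    for (j in seq_len(nrow(rates))) {
      if (runif(1) < rates$rate[j]) {
        ph <- sample(voc$phrases[[rates$code[j]]], 1)
        slot <- sample(length(tok) + 1, 1)
        tok <- append(tok, ph, after = slot - 1)
      }
    }
    if (runif(1) < spec$name_rate) {
      nm <- stringr::str_to_title(sample(voc$names, 1))
      tok <- append(tok, nm, after = sample(length(tok) + 1, 1) - 1)
    }
    if (runif(1) < spec$toponym_rate) {
      tp <- stringr::str_to_title(sample(voc$toponyms, 1))
      tok <- append(tok, tp, after = sample(length(tok) + 1, 1) - 1)
    }
    mention <- runif(1) < spec$mention_rate
    handle <- if (mention) sprintf("@utente%03d", sample(999, 1)) else NULL
    text <- paste(tok, collapse = " ")
    if (runif(1) < 0.3) {
      text <- paste0(toupper(substr(text, 1, 1)), substring(text, 2))
    }
    if (runif(1) < spec$newline_rate) {
      sp <- stringr::str_locate_all(text, stringr::fixed(" "))[[1]]
      if (nrow(sp) > 0) {
        cut <- sp[sample(nrow(sp), 1), 1]
        substr(text, cut, cut) <- "\n"
      }
    }
    sender <- sample(users, 1)
    entry <- list(
      id = i, # placeholder; renumbered after service insertion
      type = "message",
      date = format(t0 + (i - 1) * dt, "%Y-%m-%dT%H:%M:%S"),
      from = paste("Utente", sub("^user", "", sender)),
      from_id = sender
    )
    if (mention) {
      entry$text <- list(paste0(text, " "), list(type = "mention", text = handle))
      entry$text_entities <- list(
        list(type = "plain", text = paste0(text, " ")),
        list(type = "mention", text = handle)
      )
    } else if (i %% 7 == 0) {
      # a fraction of plain messages exported through text_entities
      entry$text_entities <- list(list(type = "plain", text = text))
      entry$text <- text
    } else {
      entry$text <- text
    }
    entries[[i]] <- entry
  }
  # interleave service entries at deterministic positions
  if (spec$n_service > 0 && n_msg > 0) {
    at <- unique(pmin(
      n_msg,
      floor(seq(1, n_msg, length.out = spec$n_service))
    ))
    svc <- purrr::map(seq_along(at), function(k) {
      list(
        id = 0L, type = "service",
        date = entries[[at[k]]]$date,
        actor = "group", action = "pin_message", text = ""
      )
    })
    merged <- list()
    si <- 1L
    for (i in seq_len(n_msg)) {
      merged <- c(merged, list(entries[[i]]))
      if (si <= length(at) && at[si] == i) {
        merged <- c(merged, list(svc[[si]]))
        si <- si + 1L
      }
    }
    entries <- merged
  }
  for (i in seq_along(entries)) {
    entries[[i]]$id <- i
  }
  list(
    name = chat_name,
    type = "private_supergroup",
    id = as.integer(chat_id),
    messages = entries
  )
}

# Closed-form planted truth derived from the spec.
planted_truth <- function(spec, voc = synthetic_vocabulary()) {
  groups <- spec$groups
  n_msgs <- setNames(
    groups$n_chats * groups$messages_per_chat, groups$label
  )

  rule_rates <- spec$phrase_rates |>
    dplyr::mutate(n_messages = unname(n_msgs[.data$label]))

  lemma_rows <- purrr::pmap(groups, function(label, n_chats, messages_per_chat) {
    q_neg <- unname(spec$neg_word_rate[label])
    q_pos <- spec$pos_word_rate
    q_fill <- 1 - q_neg - q_pos
    filler <- voc$fillers |>
      dplyr::group_by(.data$lemma) |>
      dplyr::summarise(p = sum(.data$prob), .groups = "drop") |>
      dplyr::mutate(prob = q_fill * .data$p) |>
      dplyr::select("lemma", "prob")
    lex <- tibble(
      lemma = c(voc$neg, voc$pos),
      prob = c(
        rep(q_neg / length(voc$neg), length(voc$neg)),
        rep(q_pos / length(voc$pos), length(voc$pos))
      )
    )
    n_tok <- n_chats * messages_per_chat * spec$tokens_per_message
    dplyr::bind_rows(filler, lex) |>
      dplyr::mutate(
        label = label, basis = "filler_token", n_basis = n_tok,
        .before = 1
      )
  })
  # phrase lemmas: at most one phrase per code per message, so the count
  # of a phrase lemma is Bernoulli per message
  phrase_rows <- purrr::pmap(
    spec$phrase_rates,
    function(label, code, rate) {
      phr <- voc$phrases[[code]]
      lem <- purrr::map(phr, function(p) {
        unique(unname(voc$lemma_map[tokenize_words(p)]))
      })
      all_lem <- unique(unlist(lem))
      tibble(
        label = label, basis = "message",
        n_basis = unname(n_msgs[label]),
        lemma = all_lem,
        prob = purrr::map_dbl(all_lem, function(l) {
          rate * mean(purrr::map_lgl(lem, ~ l %in% .x))
        })
      )
    }
  )
  lemma_probs <- dplyr::bind_rows(lemma_rows, phrase_rows) |>
    dplyr::relocate("label", "lemma", "prob", "basis", "n_basis")

  sent <- purrr::pmap(groups, function(label, n_chats, messages_per_chat) {
    mom <- p_neg_moments(
      spec$tokens_per_message,
      unname(spec$neg_word_rate[label]), spec$pos_word_rate
    )
    tibble(
      label = label,
      mean_p_neg = mom$mean, var_p_neg = mom$var,
      n_messages = n_chats * messages_per_chat
    )
  }) |> dplyr::bind_rows()

  structure(
    list(
      rule_rates = rule_rates,
      lemma_probs = lemma_probs,
      sentiment = sent,
      spec = spec
    ),
    class = "planted_truth"
  )
}

tokenize_words <- function(x) {
  unlist(stringr::str_extract_all(tolower(x), "[\\p{L}]+"))
}

# Exact moments of p_neg = n_neg / (n_neg + n_pos) (0.5 when no lexicon
# hit) with (n_neg, n_pos) multinomial over k filler tokens.
p_neg_moments <- function(k, q_neg, q_pos) {
  m1 <- 0
  m2 <- 0
  for (a in 0:k) {
    for (b in 0:(k - a)) {
      pr <- dmultinom(
        c(a, b, k - a - b),
        prob = c(q_neg, q_pos, 1 - q_neg - q_pos)
      )
      v <- if (a + b == 0) 0.5 else a / (a + b)
      m1 <- m1 + pr * v
      m2 <- m2 + pr * v^2
    }
  }
  list(mean = m1, var = m2 - m1^2)
}

#' @export
print.planted_truth <- function(x, ...) {
  cat("<planted_truth>\n")
  print(x$rule_rates)
  print(x$sentiment)
  cat(sprintf("lemma quantities: %d\n", nrow(x$lemma_probs)))
  invisible(x)
}

#' Check pipeline outputs against the planted truth
#'
#' For every planted quantity of a generated corpus, reports the
#' recovered estimate and whether the planted value lies inside an exact
#' 95% confidence interval computed from the recovered counts
#' ([stats::binom.test()] for rule and lemma rates; a normal interval
#' from the planted per-message variance for the sentiment means, plus a
#' group-ordering check). Quantities whose pipeline output was not
#' supplied are marked untested (`covered = NA`).
#'
#' @param truth A `planted_truth` object from [generate_corpus()].
#' @param rule_freq Output of [rule_frequency()] on the processed corpus
#'   (all codes), or `NULL`.
#' @param lemma_tokens Output of [lemmatize_corpus()] on the anonymized
#'   corpus (with a `group` column), or `NULL`.
#' @param sentiment A `sentiment_summary` from [score_corpus()], or
#'   `NULL`.
#' @return A tibble with columns `quantity`, `label`, `item`, `planted`,
#'   `recovered`, `lower`, `upper`, `covered`.
#' @export
recovery_report <- function(truth, rule_freq = NULL, lemma_tokens = NULL,
                            sentiment = NULL) {
  stopifnot(inherits(truth, "planted_truth"))
  out <- list()

  rr <- truth$rule_rates
  if (!is.null(rule_freq)) {
    obs <- rule_freq |>
      dplyr::group_by(.data$group, .data$code) |>
      dplyr::summarise(
        fired = sum(.data$n_fired), n = sum(.data$n_messages),
        .groups = "drop"
      )
    rows <- purrr::pmap(rr, function(label, code, rate, n_messages) {
      o <- obs[obs$group == label & obs$code == code, ]
      if (nrow(o) == 0) {
        return(untested_row("rule_rate", label, code, rate))
      }
      ci <- stats::binom.test(o$fired, o$n)$conf.int
      tibble(
        quantity = "rule_rate", label = label, item = code,
        planted = rate, recovered = o$fired / o$n,
        lower = ci[1], upper = ci[2],
        covered = rate >= ci[1] & rate <= ci[2]
      )
    })
  } else {
    rows <- purrr::pmap(rr, function(label, code, rate, n_messages) {
      untested_row("rule_rate", label, code, rate)
    })
  }
  out <- c(out, rows)

  lp <- truth$lemma_probs
  if (!is.null(lemma_tokens)) {
    if (!"group" %in% names(lemma_tokens)) {
      abort("`lemma_tokens` must carry a `group` column.")
    }
    counts <- lemma_tokens |>
      dplyr::count(.data$group, .data$lemma, name = "k")
    rows <- purrr::pmap(lp, function(label, lemma, prob, basis, n_basis) {
      k <- counts$k[counts$group == label & counts$lemma == lemma]
      k <- if (length(k) == 0) 0L else k
      ci <- stats::binom.test(k, n_basis)$conf.int
      tibble(
        quantity = paste0("lemma_", basis), label = label, item = lemma,
        planted = prob, recovered = k / n_basis,
        lower = ci[1], upper = ci[2],
        covered = prob >= ci[1] & prob <= ci[2]
      )
    })
  } else {
    rows <- purrr::pmap(lp, function(label, lemma, prob, basis, n_basis) {
      untested_row(paste0("lemma_", basis), label, lemma, prob)
    })
  }
  out <- c(out, rows)

  st <- truth$sentiment
  if (!is.null(sentiment)) {
    rows <- purrr::pmap(st, function(label, mean_p_neg, var_p_neg, n_messages) {
      g <- sentiment$per_group[sentiment$per_group$group == label, ]
      if (nrow(g) == 0) {
        return(untested_row("sentiment_mean", label, NA_character_, mean_p_neg))
      }
      half <- 1.96 * sqrt(var_p_neg / n_messages)
      tibble(
        quantity = "sentiment_mean", label = label, item = NA_character_,
        planted = mean_p_neg, recovered = g$mean_p_neg,
        lower = g$mean_p_neg - half, upper = g$mean_p_neg + half,
        covered = mean_p_neg >= g$mean_p_neg - half &
          mean_p_neg <= g$mean_p_neg + half
      )
    })
    out <- c(out, rows)
    ord <- st |> dplyr::arrange(dplyr::desc(.data$mean_p_neg))
    if (nrow(ord) >= 2 && ord$mean_p_neg[1] > ord$mean_p_neg[2]) {
      g <- sentiment$per_group
      rec <- g$mean_p_neg[match(ord$label[1], g$group)] >
        g$mean_p_neg[match(ord$label[2], g$group)]
      out <- c(out, list(tibble(
        quantity = "sentiment_ordering",
        label = paste(ord$label[1], ">", ord$label[2]),
        item = NA_character_,
        planted = 1, recovered = as.numeric(rec),
        lower = NA_real_, upper = NA_real_, covered = rec
      )))
    }
  } else {
    rows <- purrr::pmap(st, function(label, mean_p_neg, var_p_neg, n_messages) {
      untested_row("sentiment_mean", label, NA_character_, mean_p_neg)
    })
    out <- c(out, rows)
  }
  dplyr::bind_rows(out)
}

untested_row <- function(quantity, label, item, planted) {
  tibble(
    quantity = quantity, label = label, item = item,
    planted = planted, recovered = NA_real_,
    lower = NA_real_, upper = NA_real_, covered = NA
  )
}

#' @importFrom stats dmultinom runif
NULL
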