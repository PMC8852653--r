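#' Validate a run configuration
#'
#' A run configuration drives [run_pipeline()]. It is a named list (or a
#' YAML file read with [read_run_config()]) with the keys below; unknown
#' keys are rejected before any stage runs.
#'
#' Keys: `exports` (character vector of export JSON paths, or `NULL` to
#' generate the default synthetic corpus), `labels` (named list/vector
#' `chat_id` -> group label; unused when synthetic), `dictionaries`
#' (YAML path; default the shipped example set), `names_file` /
#' `places_file` (scrub word lists; default built-in), `out_dir`
#' (output directory), `seed` (integer), `top_n` (top-lemma list size,
#' default 20), `var_equal` (Student instead of Welch, default FALSE),
#' `focus_code` (code for the subcorpus/sentiment-by-code stage, default
#' `"green_pass"`).
#'
#' @param config A named list.
#' @return The validated config with defaults filled in.
#' @export
validate_run_config <- function(config) {
  known <- c(
    "exports", "labels", "dictionaries", "names_file", "places_file",
    "out_dir", "seed", "top_n", "var_equal", "focus_code",
    "synth_chats_per_group", "synth_messages_per_chat"
  )
  unknown <- setdiff(names(config), known)
  if (length(unknown) > 0) {
    abort(sprintf(
      "Unknown config key(s): %s. Known keys: %s.",
      paste(unknown, collapse = ", "), paste(known, collapse = ", ")
    ))
  }
  defaults <- list(
    exports = NULL, labels = NULL, dictionaries = NULL,
    names_file = NULL, places_file = NULL,
    out_dir = "socioscope_out", seed = 1L, top_n = 20L,
    var_equal = FALSE, focus_code = "green_pass",
    synth_chats_per_group = 4L, synth_messages_per_chat = 500L
  )
  cfg <- utils::modifyList(defaults, config)
  cfg$seed <- as.integer(cfg$seed)
  cfg$top_n <- as.integer(cfg$top_n)
  if (!is.logical(cfg$var_equal)) {
    abort("`var_equal` must be TRUE or FALSE.")
  }
  cfg
}

#' Read a run configuration from YAML
#'
#' @param path YAML file path.
#' @return A validated config list.
#' @export
read_run_config <- function(path) {
  validate_run_config(yaml::read_yaml(path))
}

#' Run the full analysis pipeline
#'
#' Executes the stages in order — ingest, anonymize, autocode, lemma
#' analytics, sentiment, group comparison, annotated export — writing
#' every artifact under `out_dir` together with a manifest (file name and
#' content hash per output) and a frozen copy of the effective
#' configuration. With no `exports` configured, the default synthetic
#' corpus is generated first and a planted-truth recovery report is
#' included among the outputs. Logs report counts and hashes, never
#' message text. The whole run is deterministic given the seed.
#'
#' @param config A named list (see [validate_run_config()]) or a path to
#'   a YAML config file.
#' @return Invisibly, a list with `manifest` (tibble: file, bytes,
#'   sha-like hash) and the in-memory stage results.
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) {
    config <- read_run_config(config)
  } else {
    config <- validate_run_config(config)
  }
  out_dir <- config$out_dir
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)

  synthetic <- is.null(config$exports)
  truth <- NULL
  if (synthetic) {
    inform("No exports configured: generating the default synthetic corpus.")
    spec <- synthetic_spec(
      groups = tibble(
        label = c("opposition", "control"),
        n_chats = rep(as.integer(config$synth_chats_per_group), 2),
        messages_per_chat = rep(as.integer(config$synth_messages_per_chat), 2)
      ),
      seed = config$seed
    )
    gen <- generate_corpus(spec)
    exports <- purrr::map(gen$exports, parse_export)
    labels <- gen$labels
    truth <- gen$truth
  } else {
    exports <- purrr::map(config$exports, parse_export)
    labels <- unlist(config$labels)
  }
  corpus <- build_corpus(exports, labels)
  inform(sprintf(
    "Ingested %d chats, %d entries (%d textual).",
    length(unique(corpus$chat_id)), nrow(corpus), nrow(textual(corpus))
  ))

  lexicons <- if (!is.null(config$names_file)) {
    read_scrub_lexicons(config$names_file, config$places_file)
  } else {
    default_scrub_lexicons()
  }
  anon <- anonymize_corpus(corpus, lexicons, seed = config$seed)

  dicts <- if (!is.null(config$dictionaries)) {
    read_dictionaries(config$dictionaries)
  } else {
    example_dictionaries()
  }
  codes <- code_corpus(anon, dicts)
  freq <- rule_frequency(anon, codes, code = names(dicts))

  lemmatizer <- default_lemmatizer()
  tokens <- lemmatize_corpus(anon, lemmatizer)
  tab_group <- lemma_table(tokens, by = "group")
  tab_all <- lemma_table(tokens)

  scorer <- do.call(lexicon_scorer, default_sentiment_lexicons())
  sent <- score_corpus(anon, scorer)
  sent_code <- sentiment_by_code(anon, codes, config$focus_code, scorer)

  comparisons <- purrr::map(names(dicts), function(cd) {
    compare_groups(
      dplyr::filter(freq, .data$code == cd),
      value = "pct",
      statistic_name = sprintf("rule frequency (%%): %s", cd),
      var_equal = config$var_equal
    )
  })
  names(comparisons) <- names(dicts)
  sent_cmp <- compare_groups(
    sent$per_chat,
    value = "mean_p_neg",
    statistic_name = "mean probability of negative sentiment",
    var_equal = config$var_equal
  )

  sub <- subcorpus_by_code(anon, codes, config$focus_code)
  doc <- export_annotated(sub, codes, label = config$focus_code)

  # ---- write artifacts ------------------------------------------------
  tsv <- function(df, name) {
    path <- file.path(out_dir, name)
    utils::write.table(df, path,
      sep = "\t", quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8"
    )
    path
  }
  files <- c(
    write_corpus_json(anon, file.path(out_dir, "corpus_anonymized.json")),
    tsv(codes, "codes.tsv"),
    tsv(freq, "rule_frequency.tsv"),
    tsv(tab_group, "lemmas_by_group.tsv"),
    tsv(utils::head(tab_all, config$top_n), sprintf("top%d_lemmas.tsv", config$top_n)),
    tsv(sent$per_chat, "sentiment_per_chat.tsv"),
    tsv(sent$per_group, "sentiment_per_group.tsv"),
    tsv(
      dplyr::bind_rows(c(
        purrr::map(comparisons, glance),
        list(glance(sent_cmp))
      )),
      "comparisons.tsv"
    )
  )
  ann_path <- file.path(out_dir, sprintf("%s.txt", config$focus_code))
  write_annotated(doc, ann_path)
  files <- c(files, ann_path, paste0(ann_path, ".index.json"))
  if (!is.null(truth)) {
    rec <- recovery_report(truth,
      rule_freq = freq, lemma_tokens = tokens, sentiment = sent
    )
    files <- c(files, tsv(rec, "recovery_report.tsv"))
  }
  cfg_path <- file.path(out_dir, "config_used.yaml")
  yaml::write_yaml(config[!purrr::map_lgl(config, is.null)], cfg_path)
  files <- c(files, cfg_path)

  manifest <- tibble(
    file = basename(files),
    bytes = file.size(files),
    hash = purrr::map_chr(files, file_hash)
  )
  utils::write.table(manifest, file.path(out_dir, "manifest.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  inform(sprintf("Wrote %d artifacts to %s.", nrow(manifest), out_dir))
  invisible(list(
    manifest = manifest, corpus = anon, codes = codes, rule_freq = freq,
    lemma_tokens = tokens, sentiment = sent, sentiment_by_code = sent_code,
    comparisons = comparisons, sentiment_comparison = sent_cmp,
    annotated = doc,
    recovery = if (!is.null(truth)) rec else NULL
  ))
}

#' Write / read the internal corpus JSON
#'
#' The corpus interchange format between pipeline stages (and CLI
#' subcommands): a JSON array of message records with the corpus columns,
#' timestamps in ISO-8601.
#'
#' @param corpus A corpus tibble.
#' @param path Output path.
#' @return `write_corpus_json()` returns the path invisibly;
#'   `read_corpus_json()` returns the corpus tibble.
#' @export
write_corpus_json <- function(corpus, path) {
  jsonlite::write_json(
    corpus_public(corpus), path,
    dataframe = "rows", auto_unbox = TRUE, digits = NA, na = "null"
  )
  invisible(path)
}

#' @rdname write_corpus_json
#' @export
read_corpus_json <- function(path) {
  df <- jsonlite::fromJSON(path)
  out <- as_tibble(df)
  if (!"text" %in% names(out)) {
    abort("Not a corpus JSON: missing `text` column.")
  }
  dplyr::mutate(
    out,
    msg_id = as.integer(.data$msg_id),
    timestamp = as.POSIXct(.data$timestamp,
      format = "%Y-%m-%dT%H:%M:%S", tz = "UTC"
    )
  )
}

# Drop non-serializable POSIXct and keep a stable column set for the
# exported anonymized corpus JSON.
corpus_public <- function(corpus) {
  dplyr::mutate(
    corpus,
    timestamp = format(.data$timestamp, "%Y-%m-%dT%H:%M:%S")
  )
}

# Content hash without extra dependencies: serialize-and-sum. Stable
# across runs for identical bytes.
file_hash <- function(path) {
  bytes <- as.double(readBin(path, "raw", n = file.size(path)))
  if (length(bytes) == 0) {
    return("00000000-0")
  }
  h <- sum(bytes * (seq_along(bytes) %% 9973 + 1)) %% 2^31
  sprintf("%08x-%d", as.integer(h), length(bytes))
}
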