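# Built-in closed vocabulary and word lists.
#
# The synthetic generator draws from a closed vocabulary with a known
# surface -> lemma map, so the lookup-table lemmatizer is exact on
# generated corpora and every planted frequency is recoverable. The
# lists double as defaults for the scrub lexicons and the lexicon
# sentiment scorer. None of these words collide with each other, with
# the stoplist, or with the shipped dictionary patterns — generation
# validates that invariant (see `validate_synthetic_spec()`).

#' Built-in synthetic vocabulary and word lists
#'
#' Returns the closed vocabulary the synthetic generator draws from:
#' neutral filler surfaces with a Zipf-shaped sampling distribution and
#' their lemma map, the negative/positive sentiment lexicons, the
#' personal-name and toponym lists, and the per-code planted phrase sets
#' (each phrase matches exactly one pattern of the shipped
#' dictionaries).
#'
#' @return A list with elements `fillers` (tibble: `surface`, `lemma`,
#'   `prob`), `lemma_map` (named character vector over all known
#'   surfaces), `neg`, `pos`, `names`, `toponyms` (character vectors) and
#'   `phrases` (named list of character vectors, one per code).
#' @export
synthetic_vocabulary <- function() {
  surfaces <- c(
    "legge", "leggi", "articolo", "articoli", "potere", "chiedere",
    "parlare", "prendere", "mettere", "usare", "andare", "venire",
    "scrivere", "sapere", "dire", "volere", "dovere", "casa",
    "scuola", "libro", "libri", "gioco", "musica", "lavoro",
    "tempo", "giorno", "giorni", "settimana", "domanda", "risposta",
    "idea", "problema", "studente", "studenti", "universita", "citta"
  )
  lemmas <- c(
    "legge", "legge", "articolo", "articolo", "potere", "chiedere",
    "parlare", "prendere", "mettere", "usare", "andare", "venire",
    "scrivere", "sapere", "dire", "volere", "dovere", "casa",
    "scuola", "libro", "libro", "gioco", "musica", "lavoro",
    "tempo", "giorno", "giorno", "settimana", "domanda", "risposta",
    "idea", "problema", "studente", "studente", "universita", "citta"
  )
  prob <- 1 / seq_along(surfaces)
  prob <- prob / sum(prob)
  fillers <- tibble(surface = surfaces, lemma = lemmas, prob = prob)

  neg <- c(
    "paura", "rabbia", "vergogna", "assurdo", "pericoloso",
    "terribile", "schifo", "dannoso", "follia", "inaccettabile"
  )
  pos <- c(
    "ottimo", "felice", "bello", "sicuro",
    "tranquillo", "perfetto", "grazie", "splendido"
  )
  nm <- c(
    "marco", "giulia", "paolo", "francesca",
    "luca", "anna", "davide", "elena"
  )
  topo <- c("milano", "roma", "napoli", "torino", "bologna", "firenze")

  phrases <- list(
    green_pass = c(
      "tessera verde", "tessere verdi", "pass verde", "certificato verde"
    ),
    vaccine = c("vaccino", "vaccini", "vaccinazione")
  )
  phrase_lemma_map <- c(
    tessera = "tessera", tessere = "tessera", verde = "verde",
    verdi = "verde", pass = "pass", certificato = "certificato",
    vaccino = "vaccino", vaccini = "vaccino", vaccinazione = "vaccinazione"
  )
  lemma_map <- c(
    setNames(fillers$lemma, fillers$surface),
    phrase_lemma_map,
    setNames(neg, neg),
    setNames(pos, pos)
  )
  list(
    fillers = fillers, lemma_map = lemma_map,
    neg = neg, pos = pos, names = nm, toponyms = topo,
    phrases = phrases
  )
}

#' Default lemmatizer over the built-in closed vocabulary
#'
#' A [lookup_lemmatizer()] built from the lemma map of
#' [synthetic_vocabulary()]. Exact on synthetic corpora; on real Italian
#' text, substitute a morphological model wrapped behind the same
#' contract.
#'
#' @return A `lemmatizer` function.
#' @export
default_lemmatizer <- function() {
  lookup_lemmatizer(synthetic_vocabulary()$lemma_map)
}

#' Default scrub lexicons (built-in Italian name and toponym lists)
#'
#' The same lists the synthetic generator plants, so the privacy sweep on
#' generated corpora is exact. For real data, supply your own lists via
#' [read_scrub_lexicons()].
#'
#' @return A `scrub_lexicons` object.
#' @export
default_scrub_lexicons <- function() {
  voc <- synthetic_vocabulary()
  scrub_lexicons(names = voc$names, toponyms = voc$toponyms)
}

#' Default sentiment lexicons
#'
#' The built-in disjoint negative/positive word lists used by the lexicon
#' scorer and planted by the synthetic generator.
#'
#' @return A list with character vectors `neg` and `pos`.
#' @export
default_sentiment_lexicons <- function() {
  voc <- synthetic_vocabulary()
  list(neg = voc$neg, pos = voc$pos)
}

#' The shipped example dictionaries
#'
#' Reads the example dictionary YAML installed with the package, whose
#' `green_pass` entry is the worked single-rule dictionary
#' `(tesser.\sverd.?|pass\sverd.?|certifica\w*\sverd.?)` together with a
#' simple `vaccine` dictionary.
#'
#' @return A named list of `dictionary` objects.
#' @export
example_dictionaries <- function() {
  read_dictionaries(
    system.file("extdata", "dictionaries.yaml", package = "socioscope")
  )
}
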