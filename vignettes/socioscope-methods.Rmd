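---
title: "Methods: weighted dictionary coding, privacy transformation and chat-level inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: weighted dictionary coding, privacy transformation and chat-level inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(socioscope)
```

`socioscope` analyses Telegram group-chat exports for public-health
social listening. This vignette is the package's account of its methods:
the models and procedures, the tunable parameters and their defaults,
what the synthetic generator does and does not emulate, and the
numerical and design choices a maintainer should know about.

## The data model

A corpus is a tidy tibble, one row per exported entry, with chat
metadata (`chat_id`, `chat_name`, `chat_type`, `group`), message
metadata (`msg_id`, `timestamp`, `sender_id`, `sender_name`, `kind`) and
the flattened `text`. Two facts about Telegram exports shape the
ingest stage:

* The `text` field is polymorphic: a plain string, or an array mixing
  strings with typed entity objects (mentions, links, formatting).
  Newer client versions add a `text_entities` array. We flatten by
  concatenating the textual content of the elements in order, and
  `text_entities` wins when both are present, since it is the
  better-specified dialect. Non-textual attachments contribute empty
  text; only textual data is analysed.
* Service entries (joins, pins, calls) are parsed — so entry counts are
  faithful — but carry `kind = "service"` and are excluded from every
  denominator downstream.

Timestamps are kept timezone-naive as exported (represented in UTC);
the eligibility screen (`filter_eligible()`: at least 10 textual
messages within the 7 days up to a reference date, inclusive at both
ends, and at least 200 members) therefore uses date arithmetic on the
naive values. Exports do not record the member count, so it is an
explicit external argument — read it off the client when exporting.

## Privacy transformation

All analysis runs on the anonymized corpus. The transformation is, in
order: `@`-mentions → `[username]` (structurally identifiable, so they
go first — `@marco` becomes `[username]`, not `[name]`); lexicon first
names → `[name]`; lexicon toponyms → `[place]`. Matching is whole-word
and case-insensitive; an `@` embedded inside a word (an e-mail fragment
like `a@b`) is not a mention, which the handle pattern enforces with a
preceding non-word-character requirement. Surnames are deliberately
retained: in casual group chat they refer to public figures and are
analytically valuable, while first names refer to participants.

Name and toponym detection is lexicon-driven by default. A named-entity
model can stand behind the same contract, but a lexicon keeps the
transformation deterministic and auditable; the package ships Italian
demonstration lists and reads user lists from plain text files.

Sender identifiers are replaced through a pseudonym map: a seeded random
permutation of the sorted identifier set mapped to `user_0001`,
`user_0002`, ... The map is bijective and deterministic given
(identifiers, seed), and the shuffle prevents the pseudonym index from
encoding the identifier's sort rank. The map is returned alongside the
corpus: keep it (separately secured) if conversations must remain
traceable, or discard it for irreversible anonymization. The
`anonymize` CLI subcommand offers `--shred` to delete its input after
success; it is never on by default.

Because placeholders contain no scrubbable tokens, the transformation is
idempotent, and a regex sweep after anonymization must find no lexicon
name, no toponym and no handle — that sweep is asserted in the test
suite on generated corpora whose planted names come from the same
lists.

## Weighted dictionary autocoding

The quantitative backbone is top-down content coding with regex
dictionaries. A dictionary gathers the expressions of one concept; the
weight of a code on a message counts the *distinct* rules that fire —
one rule firing gives weight 1, two rules give 2, and repeated matches
of one rule still count once. We read the weight system this way because
it is defined over rules, not occurrences; occurrence counting is
available as an explicit option (`count_occurrences = TRUE`) for
diagnostics. The shipped example dictionary carries the worked
green-pass rule `(tesser.\sverd.?|pass\sverd.?|certifica\w*\sverd.?)`,
which fires on "tessera verde", "tessere verdi", "pass verde" and
"certificato verde" but not on "casa verde", "verderame" or "tessera del
cinema".

Patterns are interpreted by the ICU regex engine (stringr). For the
constructs dictionary authors use — alternation, `\s`, `\w`, `.`, `?`,
`*` — ICU agrees with PCRE, and `\w` covers Unicode word characters, so
Italian diacritics match; the test suite cross-checks weights against an
independent PCRE evaluation. Matching is case-insensitive by default
because chat text is casually cased and dictionary rules are
conventionally written in lowercase.

*Rule frequency* is reported per chat as 100 × (messages with weight
≥ 1) / (textual messages of the chat). The denominator is all textual
messages; since the weight system is message-level, message-level
prevalence is the coherent frequency notion, and the per-chat values
are the inputs to every group comparison. Dictionary development is
iterative, so `pattern_report()` returns per-pattern firing counts and a
sample of unmatched messages to support the write–run–inspect–refine
loop.

## Lemma analytics

Lemmatization is a contract: a deterministic function from texts to an
ordered token table (token, lemma, part-of-speech). The default
implementation is a lookup table over a closed vocabulary — exact on
synthetic corpora and dependency-free; a pretrained morphological model
for Italian can be wrapped behind the same contract for real data.
Before counting, the stream drops: the three privacy placeholders,
stoplist lemmas (default: a transparent Italian function-word list,
fully replaceable), numerals, residual handles, and configurable
part-of-speech tags (punctuation/number/symbol by default). Content-word
frequency tables presuppose function-word removal; the default stoplist
is deliberately small and visible rather than comprehensive. Lemmas are
case-folded and NFC-normalized, so diacritic encodings compare equal.

Frequencies are percentages of retained tokens; every non-empty table
sums to 100 within 1e-9 and corpus counts decompose exactly over chats.
Group-level lemma statistics are computed per chat and averaged across
chats (matching SEM-across-chats error bars); pooled-corpus tables are
also available and labelled as such. Ties in `top_lemmas()` break
lexicographically, making top-n lists deterministic.

## Sentiment

The scorer contract is binary polarity: text → probability of negative
sentiment in [0, 1], with p(pos) = 1 − p(neg). The shipped lexicon
scorer returns the negative hit ratio n_neg/(n_neg + n_pos) over
whole-word lexicon matches and 0.5 when no lexicon word occurs; a
transformer-based Italian polarity model maps onto the same contract
through its two-class softmax. Messages that are empty after privacy
transformation (pure attachments, pure mentions) are *skipped and
counted*, not scored 0.5: a default score would dilute group contrasts
with fabricated neutrality.

Aggregation is two-stage: average messages within a chat, then chats
within a group, unweighted. With unequal chat sizes the two-stage and
pooled means differ; the package deliberately uses the two-stage rule
everywhere (a dedicated test constructs a corpus where the two
disagree), because the chat is the sampling unit and a single huge chat
must not dominate its group. A group with one chat reports its mean
with a missing SEM rather than 0.

## Group comparison

Every comparison reports per-group means, SEM = s/√n with the sample
standard deviation (n − 1), a t-test, and stars (* p<.05, ** p<.01,
*** p<.001; two-sided). The default test is Welch's unequal-variance
test with Welch–Satterthwaite degrees of freedom: chat groups here are
small and their variances have no reason to be equal. Student's pooled
test is available via `var_equal = TRUE`. The t statistic, df and
p-value come from `stats::t.test()`; the test suite validates them
against an independently coded textbook formula and an exhaustive
permutation reference, and checks the type-I error rate on null
simulations. No multiple-testing correction is applied by default —
comparisons are reported one per statistic, as in the figures this
machinery reproduces — but `adjust_comparisons()` offers Holm
correction across a family. Degenerate inputs are handled explicitly:
groups under 2 chats yield missing t/p with means still reported, and
two zero-variance samples with equal means give t = 0, p = 1.

## The synthetic generator

Real chat corpora of this kind cannot be shared, so validation runs on
generated corpora with planted, closed-form-recoverable structure. Per
message, the generator draws 8 filler tokens from a mixture: negative
lexicon with probability q_neg (group-dependent), positive lexicon with
probability q_pos (shared), otherwise a closed neutral vocabulary with a
Zipf-shaped surface distribution and known lemma map. Each dictionary
code independently inserts, with its planted per-message rate, one
phrase matching exactly one pattern of that code's dictionary. Names,
toponyms and `@`-mentions are planted at 5% per message from the same
lists the scrubber uses, so the privacy sweep is exact; mentions are
exported through `text_entities` arrays, exercising both export
dialects. Service entries are interleaved; 5% of messages carry an
embedded newline to exercise multi-line positions in the qualitative
export.

The defaults are the study design in miniature: 4 opposition chats
(three university, one generic) versus 4 control chats, 500 textual
messages each; green-pass phrase rates 0.30 versus 0.05; negative-word
rates 0.6 versus 0.2. The positive-word rate is fixed at 0.2 in both
groups, chosen so the control group's expected negative-sentiment
probability is exactly 0.5 (the neutral point of the hit-ratio scorer)
and the planted group ordering follows from q_neg alone.

Planted truth is derived in closed form. Rule firing is Bernoulli per
message, so recovered group rates are checked against exact binomial
CIs. Filler-lemma counts are marginally binomial in the total filler
draws; phrase-lemma counts are Bernoulli per message. The expected
per-message negative-sentiment probability E[n_neg/(n_neg + n_pos)],
with the hit counts multinomial over 8 tokens, is computed by exact
enumeration, giving mean and variance for a normal check on group
means. `recovery_report()` tabulates planted value, recovered estimate,
CI and coverage for every quantity, and marks quantities whose pipeline
output was not supplied as untested.

What the generator does **not** emulate: real Italian morphology (the
closed vocabulary trades realism for exact recoverability), reply
structure, temporal bursts, topic drift, or messages whose dictionary
phrases arise from natural text rather than insertion. Passing recovery
tests therefore demonstrates that the pipeline measures what it claims
on data with known truth — not that any particular dictionary is a good
measure of a real-world concept, which remains the analyst's iterative
responsibility.

## Problem sizes and numerical choices

The validation suite runs the full default study (4 + 4 × 500 messages)
once end-to-end, checks sentiment-ordering reproducibility across 50
generated replicates at 150 messages per chat (separation 0.6 vs 0.2
dominates sampling noise at that size), pools recovery coverage over 10
seeds of 2 + 2 × 100 corpora against a 0.93 joint-coverage bound (each
quantity has exactly 95% nominal coverage), and calibrates the null
rejection rate over 30 corpus replicates plus 200 direct t-test
simulations — sizes chosen to exercise every statistical claim at
desk-scale runtimes. Other numerical choices: percentages conserve mass
to 1e-9; pseudonym and generation determinism come from isolated seeded
RNG scopes (`withr::with_seed`), so library calls elsewhere cannot
perturb them; annotated re-export is byte-stable (no timestamps in the
body, `\n` line endings, UTF-8).

## Known limitations

* The lexicon scorer is a validation instrument, not a competitive
  sentiment model; real analyses should wrap a trained Italian polarity
  model behind the scorer contract.
* Lexicon-driven scrubbing only removes what its lists contain;
  out-of-lexicon names survive. For real deployments, combine a
  comprehensive name/toponym list or an NER model with a manual audit
  sample.
* Eligibility screening depends on an externally supplied member count,
  which exports omit.
* Chat-level inference with few chats has low power, and the t-test
  rests on approximate normality of per-chat means; with very few,
  very heterogeneous chats, permutation inference is the safer check
  (the test suite includes one).
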