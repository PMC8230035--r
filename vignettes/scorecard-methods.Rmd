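---
title: "Methods: the media reporting scorecard and its detectors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the media reporting scorecard and its detectors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The instrument

`mrscore` implements a 20-item scorecard for rating how responsibly a
newspaper article reports on a suicide or suicide attempt. Ten *positive*
criteria (P1–P10) are protective practices associated with the Papageno
effect — printing operational helpline information, linking the death to
mental-illness or substance-use struggles, quoting prevention experts,
citing credible statistics, challenging myths, attributing facts to an
official source. Ten *negative* criteria (N1–N10) are harmful practices
associated with the Werther (imitative-suicide) effect — criminalizing
language such as "committed suicide", attention-grabbing headlines, naming
or detailing the method, identifying the site, reducing the death to a
single cause, photographs, coverage of grieving relatives, publishing the
suicide note, front-page placement.

Each criterion is coded 1 (present) or 0 (absent) with equal weight, so an
article receives a pair of integer scores on 0–10 scales: on the positive
scale 10 is best, on the negative scale 0 is best. A newspaper's score for
a period is the arithmetic mean over its rated articles. This deliberate
simplicity — binary codes, unweighted sums — is what makes the instrument
usable for quarterly monitoring and for self-audit by journalists; it is
not a psychometrically weighted risk scale.

Two constraints are structural rather than empirical. First, **P2 ≤ P1**:
help-seeking information cannot be verified operational (P2) unless it is
present at all (P1). The package enforces this coupling in every pathway —
auto-coding, manual-sheet ingestion, reconciliation — and the generator
draws P2 conditionally on P1. Second, criteria N7 (photos) and N10 (front
page) are read from article *metadata* (photo flags, page number), never
from text.

## Screening

Before coding, a corpus is screened to specific case reports:

1. **Period and language.** Articles dated outside the configured window
   or tagged with another language are dropped first.
2. **Keyword prefilter.** An article must contain one of the phrases
   *suicide*, *kills self*, *ends life* (configurable) in headline or
   body. Matching is case-insensitive and token-boundary anchored, so
   "suicidal" does not satisfy the keyword "suicide".
3. **Category exclusions.** General commentary, ideation-only pieces,
   suicide bombings, and deaths of undetermined cause are excluded. These
   are judgment calls; the package takes a human screener's per-article
   category tag when one is present and otherwise falls back to heuristic
   lexicon cues, and every decision records whether it came from a tag or
   a cue (`category_source`), because the cue fallback is explicitly a
   heuristic.
4. **Half-content rule.** Articles devoting less than 50% of their content
   to the case are excluded. The original rule does not say how content is
   measured; this package's operational proxy is the *fraction of body
   sentences containing at least one suicide-case term*, with a
   deterministic rule-based sentence splitter. Exactly 50% is included
   (the rule excludes only *less than* half). Reports state this proxy
   explicitly. This is the one screening rule where a different
   operationalization (words, column inches) could plausibly move
   individual decisions.

The first failing rule determines the recorded exclusion reason, so
decisions are reproducible and the PRISMA-style report (scanned,
identified, per-reason exclusions, included) always conserves counts.

## Automatic detection

Every auto-capable criterion has a deterministic rule over versioned
lexicon term lists. Matching is span-based on case-folded text with token
boundaries; every positive code carries evidence spans (field, character
offsets, matched text), and overlapping spans are merged for reporting.
Design choices worth knowing:

* **Accept/reject precedence (P3, P4, P10).** Mood qualifiers
  ("stressed", "unhappy") and slurs ("crazy", "mental") never fire the
  mental-health link; an accept term ("depressed", "anxiety", names of
  disorders) fires it. A reject entry that sits *inside* an accept phrase
  ("mental" within "mental illness") does not veto it. Intoxication at
  the time of death does not fire the substance-link criterion; an
  ongoing-struggle phrase does. A bare "sources" attribution never fires
  the official-source criterion.
* **Same-sentence co-occurrence (P5, P7, P8, P10, N5, N9).** Rules whose
  description pairs two things — an expert and a quote, a number and a
  statistic marker, a myth and its refutation, an official and an
  attribution verb, a site and a locating preposition, a note and quoted
  text — are operationalized as co-occurrence within one sentence. This is
  the package's reading of rules the instrument states but does not
  operationalize.
* **Single factor (N6).** Fires only when a single-cause cue is present,
  no speculation marker appears anywhere in the body, and at most one
  distinct stressor noun occurs in the cue-bearing sentences; speculation
  or multiple distinct causes suppress it. N6 (with the reject rules
  above) is therefore deliberately non-monotone: appending text can turn
  it off. All other text criteria are monotone in added text.
* **Helpline verification (P2).** Auto mode checks P1's evidence against
  a local helpline registry file (names and phone numbers with an
  operational flag) — never a live lookup, which would break determinism.
  Without a registry, P2 defers to manual coding and the record is
  flagged.

The packaged default lexicon is this package's own resource: each list is
seeded from the worked phrases in the rubric's item descriptions and
expanded conservatively with common Indian-English news phrasing. It is
versioned, and every report and manifest records the version used, so
replacing it wholesale is supported and auditable.

## Dual coding, reconciliation, agreement

The instrument's protocol is dual independent coding with discrepancy
resolution. `reconcile_codings()` copies agreements and resolves
disagreements by strategy: `flag` (leave unresolved for a human; such
records refuse scoring unless explicitly scored permissively, in which
case unresolved criteria contribute 0 and are listed), `prefer_A`/
`prefer_B`, or `conservative` — the stricter reading, 0 for a disputed
protective practice and 1 for a disputed harmful one, so reconciliation
never flatters the newspaper. `interrater_agreement()` reports percent
agreement and Cohen's kappa per criterion from the 2×2 confusion counts;
kappa is reported as `NA` when chance agreement is 1 (both coders
constant), where the statistic is undefined.

## Aggregation

Scores aggregate to per-newspaper mean (SD) pairs using the sample (n−1)
standard deviation, reported as absent for single-article newspapers. The
pooled `Total` row is computed over all articles — i.e. article-weighted,
not an unweighted mean of newspaper means; with unequal article counts
the two differ, and the article-weighted form is the one consistent with
"average score across all reports". Criterion frequency tables report
counts and percentages of the included total, rounded **half-up** to two
decimals (base R's half-even rounding would print 0.125 → 0.12; published
tables of this kind round half up), ordered by descending count within
polarity. `compare_periods()` takes two period outputs and reports signed
deltas in newspaper means and criterion prevalences, flagging newspapers
present in only one period — the quarter-over-quarter tracking use case.

## The synthetic corpus generator

Real suicide-reporting corpora are proprietary and sensitive, so the
package ships a generator that emulates the *statistical shape* of a
screened quarterly corpus, with ground truth for every stage:

* **Criterion prevalences** default to the frequency profile of a
  1318-article quarterly corpus of English-language Indian newspapers
  (e.g. official-source attribution 82.25%, method mention 86.49%,
  criminalizing language 65.17%, helpline information 10.55%). One
  published cell is internally inconsistent — a site-disclosure count of
  228/1318 printed next to 17.05% — and the generator follows the count
  (228/1318 = 17.30%), treating the percent column as derived.
* **P2** defaults to conditional probability 1 given P1, the coupling
  implied by identical published counts (139/139) for the two criteria.
* **Screening mix** defaults to 57% includable case reports, 10%
  commentary, 7% ideation-only, 4% bombing, 7% undetermined cause, 10%
  below-half-content, 5% not matching the prefilter. The source reports
  identified and included totals (2326 → 1318, a 43% post-identification
  exclusion rate) but not per-reason counts; this mix matches that overall
  rate with the remainder spread over the stated reasons, chosen once as
  a plausible newsroom mixture.
* **Criteria are drawn independently** (except P2 | P1). Real criteria are
  surely correlated (method mention and method detail, for instance), but
  no correlation structure is published, and independence is sufficient
  for what the generator is for: testing detectors and aggregation, where
  only marginal prevalences matter, with a null model whose expected
  scores are analyzable — E[positive score] is the sum of the positive
  prevalences (~1.32) and E[negative score] the sum of the negative ones
  (~3.31).
* **Templates are decidable.** Positive sentences use lexicon trigger
  phrases; criteria coded 0 receive curated near-miss distractors
  ("stressed" where an accept term would fire, "according to sources",
  intoxication-only wording, an unquoted "no suicide note was found").
  Sentence-level bookkeeping steers the case-sentence fraction above or
  below the 50% screening threshold to realize the planted screening
  category. All randomness flows from a single integer seed, and
  generation is byte-identical on rerun.

What passing tests on this corpus shows: the detectors recover exactly the
constructions the lexicons define, the screening rules tally exactly, and
the aggregation arithmetic is correct. What it does not show: performance
on natural newsroom prose — paraphrase, regional idiom, sarcasm, OCR noise
— where rule-based detection will miss reformulations the lexicon lacks.
The generator tests the machinery, not natural-language robustness; for
production monitoring the auto-coder is a first pass whose evidence spans
make human verification fast, not a replacement for the dual-coding
protocol.

## Numerical and procedural choices

* Sentence splitting: terminal `.`/`!`/`?` runs followed by whitespace or
  end of text; no abbreviation list. Simple, deterministic, documented.
* Percentages: half-up at two decimals, applied at the final reporting
  step only.
* Problem sizes: the shipped tests exercise a 1000-article synthetic
  corpus for recovery and aggregation checks and a 400-article corpus for
  screening properties — large enough that three-standard-error bands on
  the binomial checks are tight, small enough to run routinely.
* Degenerate inputs: empty bodies code 0 everywhere and screen as
  non-matching; empty corpora produce zero-count reports; single-article
  newspapers report `NA` SD; kappa is `NA` under degenerate marginals;
  unresolved reconciliations refuse scoring by default.
* Workflow artifacts embed package/lexicon versions and input digests in
  per-command manifests, and timestamps are confined to logs and
  manifests so data artifacts are digest-comparable across reruns.

## Limitations

The detectors are lexicon-bound and English-only; sensational or
glamourizing *tone* is out of scope (deliberately, as in the source
instrument, because it is subjective); N7 trusts photo metadata rather
than analyzing images; the half-content rule is a sentence-level proxy;
and the cue-based screening fallback is a convenience for triage, not a
substitute for a human screener's category tags.
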