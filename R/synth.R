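#' Synthetic corpus generation
#'
#' Generates newspaper-article corpora with per-criterion ground truth so
#' the screening, coding and aggregation stages are testable without any
#' real news data. Criterion presence is drawn independently per criterion
#' at configurable prevalences (defaults: the frequency profile of a
#' quarterly all-newspaper corpus of 1318 suicide reports), except that
#' operational-helpline verification (P2) is drawn conditionally on
#' help-seeking information being present (P1). Article text is composed
#' from templates that use lexicon trigger phrases for planted criteria and
#' curated near-miss distractors (e.g. "stressed" where a mental-health
#' accept term would fire, bare "sources" where an official source would)
#' for absent ones, so detector recovery is decidable by construction.
#'
#' @name synthetic
NULL

#' Default per-criterion prevalences
#'
#' Presence probabilities per criterion; `P2` is the *conditional*
#' probability of verified-operational given helpline information present.
#'
#' @return Named numeric vector over [criterion_codes()].
#' @export
default_prevalence <- function() {
  n <- 1318
  counts <- c(P1 = 139, P2 = NA, P3 = 286, P4 = 61, P5 = 13, P6 = 4, P7 = 6,
              P8 = 2, P9 = 0, P10 = 1084,
              N1 = 859, N2 = 992, N3 = 1140, N4 = 194, N5 = 228, N6 = 541,
              N7 = 148, N8 = 126, N9 = 61, N10 = 79)
  p <- counts / n
  p[["P2"]] <- 1  # operational-verification rate among helpline-bearing articles
  p[criterion_codes()]
}

#' Default screening-category mix
#'
#' @return Named probability vector over planted screening categories.
#' @export
default_screening_mix <- function() c(
  included = 0.57, general_commentary = 0.10, ideation_only = 0.07,
  bombing_intent = 0.04, undetermined_cause = 0.07, below_half_content = 0.10,
  not_matching_prefilter = 0.05)

default_newspapers <- function() {
  nm <- c("The Times of India", "Hindustan Times", "The New Indian Express",
          "The Telegraph", "The Hindu", "The Indian Express", "Mirror",
          "The Tribune", "The Economic Times")
  tibble::tibble(name = nm, weight = rep(1 / length(nm), length(nm)))
}

#' Build a generator configuration
#'
#' @param n_articles Number of articles to generate.
#' @param newspapers Tibble `name, weight` (weights sum to 1).
#' @param period Length-2 `Date` vector; publication dates are uniform on
#'   it.
#' @param prevalence Named per-criterion presence probabilities
#'   ([default_prevalence()]); `P2` is conditional on `P1 = 1`.
#' @param screening_mix Named category probabilities
#'   ([default_screening_mix()]).
#' @param seed Integer seed; all generation randomness flows from it.
#' @return An `mrs_generator_config` list.
#' @export
generator_config <- function(n_articles = 1000,
                             newspapers = default_newspapers(),
                             period = as.Date(c("2020-04-01", "2020-06-30")),
                             prevalence = default_prevalence(),
                             screening_mix = default_screening_mix(),
                             seed = 1L) {
  prevalence <- prevalence[criterion_codes()]
  if (anyNA(prevalence) || any(prevalence < 0 | prevalence > 1))
    stop_mrscore("prevalence must define probabilities in [0,1] for all 20 criteria",
                 "mrscore_config_error")
  if (abs(sum(screening_mix) - 1) > 1e-8 || any(screening_mix < 0))
    stop_mrscore("screening_mix must be a probability vector summing to 1",
                 "mrscore_config_error")
  if (abs(sum(newspapers$weight) - 1) > 1e-8)
    stop_mrscore("newspaper weights must sum to 1", "mrscore_config_error")
  structure(list(n_articles = n_articles, newspapers = newspapers, period = period,
                 prevalence = prevalence, screening_mix = screening_mix,
                 seed = as.integer(seed)),
            class = "mrs_generator_config")
}

#' Read a generator configuration from YAML
#'
#' Keys mirror [generator_config()] arguments; `newspapers` is a mapping
#' of name to weight, `prevalence` and `screening_mix` are mappings.
#'
#' @param path YAML file.
#' @return An `mrs_generator_config`.
#' @export
read_generator_config <- function(path) {
  y <- yaml::read_yaml(path)
  prev <- default_prevalence()
  if (!is.null(y$prevalence)) prev[names(y$prevalence)] <- unlist(y$prevalence)
  mix <- default_screening_mix()
  if (!is.null(y$screening_mix)) mix[names(y$screening_mix)] <- unlist(y$screening_mix)
  papers <- if (is.null(y$newspapers)) default_newspapers() else
    tibble::tibble(name = names(y$newspapers), weight = unlist(y$newspapers))
  generator_config(
    n_articles = y$n_articles %||% 1000,
    newspapers = papers,
    period = if (!is.null(y$period)) as.Date(unlist(y$period)) else
      as.Date(c("2020-04-01", "2020-06-30")),
    prevalence = prev, screening_mix = mix, seed = y$seed %||% 1L)
}

#' Draw one ground-truth record
#'
#' Independent Bernoulli draws per criterion at the configured prevalence,
#' with P2 drawn conditionally on P1 = 1, and a screening category drawn
#' from the screening mix. Uses the current RNG state; seed via
#' [generate_corpus()] or `set.seed()`.
#'
#' @param config An [generator_config()].
#' @param article_id Identifier to stamp on the record.
#' @return A list `article_id, true_codes` (named 0/1 integer vector),
#'   `screening_category`.
#' @export
sample_truth <- function(config, article_id = NA_character_) {
  category <- sample(names(config$screening_mix), 1L, prob = config$screening_mix)
  codes <- setNames(integer(20), criterion_codes())
  if (category %in% c("included", "below_half_content")) {
    p <- config$prevalence
    for (cr in setdiff(criterion_codes(), "P2"))
      codes[[cr]] <- stats::rbinom(1L, 1L, p[[cr]])
    codes[["P2"]] <- if (codes[["P1"]] == 1L) stats::rbinom(1L, 1L, p[["P2"]]) else 0L
  }
  list(article_id = article_id, true_codes = codes, screening_category = category)
}

# template text ---------------------------------------------------------
# Every sentence is annotated is_case = does it contain a suicide-case term
# (drives the relevance fraction). Positive templates use lexicon trigger
# phrases; distractors are near-misses that must NOT fire the detector.

synth_cities <- function() c("Pune", "Nagpur", "Indore", "Kochi", "Jaipur", "Patna")
synth_days <- function() c("Monday", "Tuesday", "Wednesday", "Thursday",
                           "Friday", "Saturday", "Sunday")

synth_openers <- function(city, day, age) c(
  paste0("A ", age, "-year-old resident of ", city, " died by suicide on ", day, "."),
  paste0("The ", age, "-year-old had attempted suicide once before, the report said."),
  paste0("Family members learnt of the suicide on ", day, " morning."))

synth_case_fillers <- function() c(
  "The suicide stunned the neighbourhood.",
  "News of the suicide spread quickly through the locality.",
  "It was the second suicide reported from the area this month.")

synth_noncase_fillers <- function() c(
  "The locality has seen rapid construction in recent years.",
  "Residents have long complained about erratic power supply.",
  "The weather that week was unusually warm.",
  "Local schools remained shut for the summer break.")

# trigger sentence per criterion; is_case flags below
synth_trigger <- function(cr, p2 = 0L) {
  switch(cr,
    P1 = if (p2 == 1L)
      "Those in distress can call the Sneha helpline at 044-24640050 for support."
    else
      "Those in distress can call the local helpline at 1800-000-1111 for support.",
    P3 = "She had been battling depression for several months.",
    P4 = "He had struggled with alcohol addiction for years.",
    P5 = "\"Timely support saves lives,\" said a senior psychiatrist in the city.",
    P6 = "Such deaths are preventable when warning signs are recognised early.",
    P7 = "India recorded a suicide rate of 10.4 per 100,000 people in 2019.",
    P8 = "The common belief that talking about suicide encourages it is simply not true.",
    P9 = "She later shared a hopeful story of how she rebuilt her life.",
    P10 = "Police officers confirmed the sequence of events to reporters.",
    N1 = "Neighbours said he committed suicide at his home late that night.",
    N3 = "He was found hanging at his home that evening.",
    N4 = "A rope and a can of kerosene were found at the spot.",
    N5 = "The spot, a bridge near the old station, remains accessible to the public.",
    N6 = "He took the extreme step after being unable to repay his debt.",
    N8 = "His grieving widow spoke to reporters about what the family has lost.",
    N9 = "The suicide note read, \"I alone am responsible for my decision,\" the report noted.",
    NULL)
}

synth_trigger_is_case <- function(cr) cr %in% c("P7", "P8", "N1", "N9")

synth_distractor <- function(cr) {
  switch(cr,
    P1 = "Neighbours offered what help they could.",
    P3 = "He had been stressed and unhappy about work in recent weeks.",
    P4 = "He was drunk at the time of the incident.",
    P10 = "According to sources, the family had recently moved to the area.",
    N6 = "The reason may be related to a financial dispute, and the matter remains under investigation.",
    N9 = "No suicide note was found at the spot.",
    NULL)
}

synth_distractor_is_case <- function(cr) cr %in% "N9"

synth_headline <- function(codes, city) {
  if (codes[["N2"]] == 1L) {
    if (codes[["N3"]] == 1L && stats::runif(1) < 0.5)
      return(paste0("Man ends life by hanging in ", city))
    if (stats::runif(1) < 0.3)
      return("Student ends life after exam failure")
    return(paste0(sample(c("Man", "Woman"), 1L), " dies by suicide in ", city))
  }
  sample(c(paste0("Young man found dead in ", city), "Tragedy strikes local family"), 1L)
}

#' Render one article from a truth record
#'
#' Composes headline, body and metadata such that, for every auto-capable
#' criterion, a lexicon-matching construction appears iff its true code is
#' 1; criteria coded 0 receive (with probability 0.35) a near-miss
#' distractor that must not fire. Body composition also realizes the
#' planted screening category: case articles keep at least half their
#' sentences on the case, `below_half_content` plants are padded with
#' off-case filler below the 50% threshold, and category plants carry their
#' screener tag.
#'
#' @param truth A [sample_truth()] record.
#' @param lexicon Lexicon (present for interface symmetry; templates are
#'   aligned with the packaged default lists).
#' @param city,day,age Surface details; sampled by [generate_corpus()].
#' @return Named list of article fields (see [corpus()]), including a
#'   `category` tag column.
#' @export
render_article <- function(truth, lexicon = read_lexicon(),
                           city = "Pune", day = "Monday", age = 34L) {
  codes <- truth$true_codes
  cat <- truth$screening_category
  if (cat == "not_matching_prefilter") {
    body <- paste(sample(synth_noncase_fillers(), 3L), collapse = " ")
    return(list(headline = "Local market reopens after renovation", body = body,
                page_number = sample(2:12, 1L), continues_from_front_page = FALSE,
                has_photo = FALSE, photo_kinds = character(), category = NA_character_))
  }
  if (cat %in% c("general_commentary", "ideation_only", "undetermined_cause",
                 "bombing_intent")) {
    body <- switch(cat,
      general_commentary = paste("Suicide prevention needs sustained public attention.",
                                 "This editorial examines what newspapers owe their readers."),
      ideation_only = paste("He told friends he had considered suicide many times.",
                            "Counselling helped him manage the suicidal thoughts."),
      bombing_intent = paste("A suicide bomber struck the convoy on", day, "morning.",
                             "Several vehicles were damaged in the blast."),
      undetermined_cause = paste("The cause of death was undetermined, and suicide was",
                                 "not ruled out. An inquiry is expected to take weeks."))
    return(list(headline = paste0("News from ", city), body = body,
                page_number = sample(2:12, 1L), continues_from_front_page = FALSE,
                has_photo = FALSE, photo_kinds = character(), category = cat))
  }
  # case article (included or below_half_content plant)
  sentences <- character(); is_case <- logical()
  add <- function(s, case) { sentences <<- c(sentences, s); is_case <<- c(is_case, case) }
  add(sample(synth_openers(city, day, age), 1L), TRUE)
  auto_text <- c("P1", "P3", "P4", "P5", "P6", "P7", "P8", "P9", "P10",
                 "N1", "N3", "N4", "N5", "N6", "N8", "N9")
  for (cr in auto_text) {
    if (codes[[cr]] == 1L)
      add(synth_trigger(cr, p2 = codes[["P2"]]), synth_trigger_is_case(cr))
    else if (codes[[cr]] == 0L && cr == "N6" && codes[["N6"]] == 0L &&
             stats::runif(1) < 0.35)
      add(synth_distractor("N6"), FALSE)
    else if (!is.null(synth_distractor(cr)) && cr != "N6" && stats::runif(1) < 0.35)
      add(synth_distractor(cr), synth_distractor_is_case(cr))
  }
  # steer the sentence-level case fraction to realize the screening plant
  target_below <- cat == "below_half_content"
  fillers_case <- sample(synth_case_fillers())
  fillers_off <- sample(synth_noncase_fillers())
  i_case <- 1L; i_off <- 1L
  repeat {
    frac <- sum(is_case) / length(is_case)
    if (!target_below && frac >= 0.5) break
    if (target_below && frac < 0.5) break
    if (!target_below) {
      add(fillers_case[(i_case - 1L) %% length(fillers_case) + 1L], TRUE)
      i_case <- i_case + 1L
    } else {
      add(fillers_off[(i_off - 1L) %% length(fillers_off) + 1L], FALSE)
      i_off <- i_off + 1L
    }
  }
  front <- codes[["N10"]] == 1L
  continues <- front && stats::runif(1) < 0.3
  kinds <- if (codes[["N7"]] == 1L)
    sample(photo_kind_levels(), sample(1:2, 1L)) else character()
  list(headline = synth_headline(codes, city),
       body = paste(sentences, collapse = " "),
       page_number = if (front && !continues) 1L else sample(2:12, 1L),
       continues_from_front_page = continues,
       has_photo = codes[["N7"]] == 1L,
       photo_kinds = kinds,
       category = "case_report")
}

#' Generate a corpus with ground truth
#'
#' Deterministic for a fixed seed: identical configuration yields
#' byte-identical corpora on rerun. Articles are assigned to newspapers by
#' weight and dated uniformly within the period.
#'
#' @param config An [generator_config()].
#' @param lexicon Lexicon passed through to [render_article()].
#' @return List with `corpus` (an `mrs_corpus`; includes a `category`
#'   screener-tag column) and `truth` (tibble `article_id,
#'   screening_category, P1..N10`).
#' @export
generate_corpus <- function(config = generator_config(), lexicon = read_lexicon()) {
  stopifnot(inherits(config, "mrs_generator_config"))
  set.seed(config$seed)
  n <- config$n_articles
  if (n == 0L) {
    return(list(corpus = corpus(empty_article_table(), source_label = "synthetic",
                                period = config$period),
                truth = tibble::tibble(article_id = character(),
                                       screening_category = character())))
  }
  ids <- sprintf("syn-%05d", seq_len(n))
  papers <- sample(config$newspapers$name, n, replace = TRUE,
                   prob = config$newspapers$weight)
  dates <- config$period[1] +
    floor(stats::runif(n) * (as.integer(config$period[2] - config$period[1]) + 1L))
  rows <- vector("list", n)
  truths <- vector("list", n)
  for (i in seq_len(n)) {
    tr <- sample_truth(config, article_id = ids[i])
    art <- render_article(tr, lexicon,
                          city = sample(synth_cities(), 1L),
                          day = sample(synth_days(), 1L),
                          age = sample(19:70, 1L))
    rows[[i]] <- tibble::tibble(
      article_id = ids[i], newspaper = papers[i], publication_date = dates[i],
      edition = NA_character_, page_number = art$page_number,
      continues_from_front_page = art$continues_from_front_page,
      headline = art$headline, body = art$body, has_photo = art$has_photo,
      photo_kinds = list(art$photo_kinds), url = NA_character_,
      category = art$category)
    truths[[i]] <- tibble::as_tibble(c(
      list(article_id = ids[i], screening_category = tr$screening_category),
      as.list(tr$true_codes)))
  }
  list(corpus = corpus(dplyr::bind_rows(rows), source_label = "synthetic",
                       period = config$period),
       truth = dplyr::bind_rows(truths))
}
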