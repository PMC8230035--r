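lex <- NULL
setup_lex <- function() test_lexicon()

test_that("worked rubric phrases code as the item descriptions dictate", {
  lex <- setup_lex()
  d <- function(body, code) detect_criterion(list(headline = "", body = body),
                                             code, lex)$code
  # criminalizing language
  expect_equal(d("He committed suicide on Monday", "N1"), 1L)
  expect_equal(d("He died by suicide on Monday", "N1"), 0L)
  # mental-health link: accept terms fire, mood qualifiers and slurs do not
  expect_equal(d("she had been depressed for months", "P3"), 1L)
  expect_equal(d("he was stressed", "P3"), 0L)
  expect_equal(d("people called him crazy", "P3"), 0L)
  expect_equal(d("he lived with a mental illness", "P3"), 1L)
  # substance link: ongoing struggle fires, intoxication at the time does not
  expect_equal(d("struggled with alcohol addiction for years", "P4"), 1L)
  expect_equal(d("he was drunk at the time", "P4"), 0L)
  # official source: a bare "sources" attribution does not qualify
  expect_equal(d("according to sources", "P10"), 0L)
  expect_equal(d("police officers confirmed the events", "P10"), 1L)
})

test_that("N1 evidence span covers the criminalizing phrase", {
  res <- detect_criterion(list(headline = "", body = "He committed suicide on Monday"),
                          "N1", setup_lex())
  expect_equal(res$code, 1L)
  expect_equal(tolower(res$evidence$text), "committed suicide")
  expect_equal(res$evidence$field, "body")
})

test_that("headline rule fires on the word, the method, or the reason", {
  lex <- setup_lex()
  h <- function(headline) detect_criterion(list(headline = headline, body = ""),
                                           "N2", lex)$code
  expect_equal(h("Man ends life by hanging"), 1L)        # method term
  expect_equal(h("City suicide shocks residents"), 1L)   # the word itself
  expect_equal(h("Student dies after exam failure"), 1L) # reason cue + stressor
  expect_equal(h("Helpline calls rise in city"), 0L)
  expect_equal(h("Young man found dead in Pune"), 0L)
  # body text never triggers the headline criterion
  expect_equal(detect_criterion(list(headline = "Quiet day in the city",
                                     body = "He died by hanging."), "N2", lex)$code, 0L)
})

test_that("method-detail needs two distinct details; site needs a locatable pattern", {
  lex <- setup_lex()
  d <- function(body, code) detect_criterion(list(headline = "", body = body),
                                             code, lex)$code
  expect_equal(d("A rope was found at the spot.", "N4"), 0L)
  expect_equal(d("A rope and a can of kerosene were found.", "N4"), 1L)
  expect_equal(d("A rope and another rope were found.", "N4"), 0L)
  expect_equal(d("The spot, a bridge near the old station, is accessible.", "N5"), 1L)
  expect_equal(d("Many consider that bridge scenic.", "N5"), 0L)  # no locating cue
  expect_equal(d("He admired every lake painting that hung elsewhere.", "N5"), 0L)
})

test_that("single-factor attribution is suppressed by speculation or multiple causes", {
  lex <- setup_lex()
  d <- function(body) detect_criterion(list(headline = "", body = body), "N6", lex)$code
  expect_equal(d("He took the extreme step after being unable to repay his debt."), 1L)
  expect_equal(d(paste("He took the extreme step after being unable to repay his debt.",
                       "However, the reason may be something else entirely.")), 0L)
  expect_equal(d("The suicide was blamed on his debt and a property dispute."), 0L)
  expect_equal(d("The family described a calm week."), 0L)
})

test_that("metadata criteria read flags, not text", {
  lex <- setup_lex()
  a <- list(headline = "", body = "", page_number = 3L,
            continues_from_front_page = FALSE, has_photo = FALSE,
            photo_kinds = character())
  expect_equal(detect_criterion(a, "N10", lex)$code, 0L)
  a$page_number <- 1L
  expect_equal(detect_criterion(a, "N10", lex)$code, 1L)
  a$page_number <- 5L; a$continues_from_front_page <- TRUE
  expect_equal(detect_criterion(a, "N10", lex)$code, 1L)
  expect_equal(detect_criterion(a, "N7", lex)$code, 0L)
  a$has_photo <- TRUE; a$photo_kinds <- c("method", "location")
  res <- detect_criterion(a, "N7", lex)
  expect_equal(res$code, 1L)
  expect_match(res$evidence$text, "method")
})

test_that("helpline detection and registry verification couple P2 to P1", {
  lex <- setup_lex()
  reg <- test_registry()
  art <- function(body) list(article_id = "x", headline = "", body = body)
  # registry-backed operational helpline: both fire
  r <- code_article_auto(art("Those in distress can call the Sneha helpline at 044-24640050."),
                         lex, reg)
  expect_equal(unname(r$codes[c("P1", "P2")]), c(1L, 1L))
  # helpline present but unknown number: P1 only
  r <- code_article_auto(art("Those in distress can call the local helpline at 1800-000-1111."),
                         lex, reg)
  expect_equal(unname(r$codes[c("P1", "P2")]), c(1L, 0L))
  # registry entry flagged non-operational does not verify
  r <- code_article_auto(art("Call 044-00000000 for support."), lex, reg)
  expect_equal(unname(r$codes[c("P1", "P2")]), c(1L, 0L))
  # no registry at all: P2 deferred to manual, flagged
  r <- code_article_auto(art("Call the Sneha helpline at 044-24640050."), lex, NULL)
  expect_equal(unname(r$codes[["P2"]]), 0L)
  expect_match(r$notes, "needs_manual:.*P2")
  # no helpline: neither fires
  r <- code_article_auto(art("No support information was printed."), lex, reg)
  expect_equal(unname(r$codes[c("P1", "P2")]), c(0L, 0L))
})

test_that("sentence co-occurrence rules need their cue in the same sentence", {
  lex <- setup_lex()
  d <- function(body, code) detect_criterion(list(headline = "", body = body),
                                             code, lex)$code
  expect_equal(d("\"Support saves lives,\" said a senior psychiatrist.", "P5"), 1L)
  expect_equal(d("A psychiatrist lives nearby. Neighbours said little.", "P5"), 0L)
  expect_equal(d("India recorded a suicide rate of 10.4 per 100,000 people.", "P7"), 1L)
  expect_equal(d("The suicide rate is a concern. About 30 cars passed.", "P7"), 0L)
  expect_equal(d("The belief that talking about suicide causes it is a myth and is not true.",
                 "P8"), 1L)
  expect_equal(d("Myths persist in the town. The claim is not true, people say.", "P8"), 0L)
  expect_equal(d("The suicide note read, \"I am responsible.\"", "N9"), 1L)
  expect_equal(d("No suicide note was found at the spot.", "N9"), 0L)
})

test_that("detection is deterministic and empty articles code to zero", {
  lex <- setup_lex()
  a <- list(article_id = "e", headline = "", body = "")
  r <- code_article_auto(a, lex, test_registry())
  expect_true(all(r$codes == 0L))
  body <- "Neighbours said he committed suicide. He was found hanging at home."
  r1 <- detect_criterion(list(headline = "", body = body), "N3", lex)
  r2 <- detect_criterion(list(headline = "", body = body), "N3", lex)
  expect_identical(r1, r2)
})

test_that("evidence spans index into their field and contain a lexicon match", {
  lex <- setup_lex()
  run <- synthetic_run(400, seed = 31)
  recs <- run$records[1:40]
  arts <- run$case_corpus[1:40, , drop = FALSE]
  for (i in seq_along(recs)) {
    e <- recs[[i]]$evidence
    e <- e[e$field != "metadata", , drop = FALSE]
    if (nrow(e) == 0L) next
    for (j in seq_len(nrow(e))) {
      fld <- arts[[e$field[j]]][i]
      expect_equal(substr(fld, e$start[j], e$end[j]), e$text[j])
    }
  }
  # soundness: every span's text, lowercased, contains a relevant lexicon entry
  r <- code_article_auto(list(article_id = "s", headline = "",
                              body = "Neighbours said he committed suicide."),
                         lex, test_registry())
  ev <- r$evidence[r$evidence$criterion == "N1", ]
  expect_true(grepl("committed suicide", tolower(ev$text[1]), fixed = TRUE))
})

test_that("adding a trigger flips monotone criteria 0 to 1 and never 1 to 0", {
  lex <- setup_lex()
  reg <- test_registry()
  monotone <- setdiff(criterion_codes(), c("P2", "P3", "P4", "P10", "N6", "N2", "N7", "N10"))
  base <- "The family described a quiet week. Nothing unusual was reported."
  triggers <- list(
    P1 = "Call the Sneha helpline at 044-24640050.",
    P5 = "\"Support saves lives,\" said a senior psychiatrist.",
    P6 = "Such deaths are preventable when warning signs are recognised.",
    P7 = "India recorded a suicide rate of 10.4 per 100,000 people.",
    P8 = "The common belief that talking about suicide causes it is not true.",
    P9 = "She shared a hopeful story of recovery.",
    N1 = "Neighbours said he committed suicide that night.",
    N3 = "He was found hanging at home.",
    N4 = "A rope and a can of kerosene were found.",
    N5 = "The spot, a bridge near the station, is accessible.",
    N8 = "His grieving widow spoke to reporters.",
    N9 = "The suicide note read, \"I am responsible.\"")
  r0 <- code_article_auto(list(article_id = "m", headline = "", body = base), lex, reg)
  for (cr in intersect(monotone, names(triggers))) {
    expect_equal(unname(r0$codes[[cr]]), 0L, label = paste("base", cr))
    r1 <- code_article_auto(list(article_id = "m", headline = "",
                                 body = paste(base, triggers[[cr]])), lex, reg)
    expect_equal(unname(r1$codes[[cr]]), 1L, label = paste("flip", cr))
    # codes already 1 stay 1 under further appends
    r2 <- code_article_auto(list(article_id = "m", headline = "",
                                 body = paste(base, triggers[[cr]],
                                              "An unrelated festival took place.")),
                            lex, reg)
    expect_equal(unname(r2$codes[[cr]]), 1L, label = paste("stable", cr))
  }
})

test_that("non-monotone sub-rules: reject-only, intoxication-only, bare sources, speculation", {
  lex <- setup_lex()
  d <- function(body, code) detect_criterion(list(headline = "", body = body),
                                             code, lex)$code
  # appending reject-only text never creates P3; appending accept text does
  expect_equal(d("He was stressed. He was unhappy.", "P3"), 0L)
  expect_equal(d("He was stressed. He had battled depression.", "P3"), 1L)
  expect_equal(d("He was drunk. He was inebriated.", "P4"), 0L)
  expect_equal(d("According to sources, little is known. Sources said more.", "P10"), 0L)
  # N6 is non-monotone: appending speculation turns it off
  on <- "The suicide was blamed on his debt."
  expect_equal(d(on, "N6"), 1L)
  expect_equal(d(paste(on, "The matter remains under investigation."), "N6"), 0L)
})
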