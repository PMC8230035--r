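test_that("coding records enforce binary codes and the P2-P1 coupling", {
  expect_s3_class(coding_record("a1", "c1", codes_with(c("P1", "P2"))), "mrs_coding")
  expect_error(coding_record("a1", "c1", codes_with("P2")), "P2 = 1 requires",
               class = "mrscore_coding_error")
  bad <- codes_with(); bad[["N1"]] <- 2L
  expect_error(coding_record("a1", "c1", bad), "0/1", class = "mrscore_coding_error")
  expect_error(coding_record("a1", "c1", codes_with()[1:19]), "0/1",
               class = "mrscore_coding_error")
  # evidence only for codes = 1
  expect_error(coding_record("a1", "c1", codes_with("P1"),
                             evidence = tibble::tibble(criterion = "N1", field = "body",
                                                       start = 1L, end = 2L, text = "xx")),
               "coded 0", class = "mrscore_coding_error")
})

test_that("manual sheets are validated cell by cell", {
  sheet <- function(rows) {
    p <- tempfile(fileext = ".csv")
    header <- paste(c("article_id", "coder_id", criterion_codes(), "notes"),
                    collapse = ",")
    writeLines(c(header, rows), p)
    p
  }
  ok <- sheet(paste(c("a1", "coderA", rep("0", 20), "fine"), collapse = ","))
  recs <- ingest_manual_codes(ok)
  expect_length(recs, 1L)
  expect_equal(recs[[1]]$coder_id, "coderA")
  expect_true(all(recs[[1]]$codes == 0L))
  bad_cell <- sheet(paste(c("a1", "coderA", "2", rep("0", 19), ""), collapse = ","))
  expect_error(ingest_manual_codes(bad_cell), "non-binary.*P1",
               class = "mrscore_coding_error")
  # P1=0 with P2=1 is inconsistent (operational implies present)
  codes <- rep("0", 20); codes[2] <- "1"
  incons <- sheet(paste(c("a1", "coderA", codes, ""), collapse = ","))
  expect_error(ingest_manual_codes(incons), "P2", class = "mrscore_coding_error")
  p <- sheet(paste(c("a1", "coderA", rep("0", 20), ""), collapse = ","))
  df <- readr::read_csv(p, show_col_types = FALSE)
  df$X21 <- 1
  readr::write_csv(df, p)
  expect_error(ingest_manual_codes(p), "unknown criterion",
               class = "mrscore_coding_error")
})

test_that("coding JSONL round-trips records with evidence", {
  r <- code_article_auto(list(article_id = "a1", headline = "",
                              body = "Neighbours said he committed suicide."),
                         test_lexicon(), test_registry())
  p <- tempfile(fileext = ".jsonl")
  write_codings(list(r), p)
  back <- read_codings(p)
  expect_equal(back[[1]]$codes, r$codes)
  expect_equal(back[[1]]$evidence$text, r$evidence$text)
  expect_equal(back[[1]]$lexicon_version, r$lexicon_version)
  unlink(p)
})

test_that("reconciliation copies agreements and resolves by strategy", {
  a <- coding_record("a1", "coderA", codes_with(c("P1", "P2", "N1")))
  b <- coding_record("a1", "coderB", codes_with(c("P1", "P2", "N1")))
  r <- reconcile_codings(a, b, "flag")
  expect_equal(nrow(r$discrepancies), 0L)
  expect_equal(r$final_codes, a$codes)
  # single disagreement, flagged
  b2 <- coding_record("a1", "coderB", codes_with(c("P1", "P2")))
  r <- reconcile_codings(a, b2, "flag")
  expect_equal(r$discrepancies$criterion, "N1")
  expect_equal(r$discrepancies$resolution, "unresolved")
  expect_true(is.na(r$final_codes[["N1"]]))
  expect_error(reconcile_codings(a, coding_record("zz", "coderB", codes_with())),
               "mismatch", class = "mrscore_coding_error")
  expect_error(reconcile_codings(a, coding_record("a1", "coderA", codes_with())),
               "distinct coders", class = "mrscore_coding_error")
})

test_that("conservative resolution takes the stricter reading in all 2x2 cases", {
  # enumerate every disagreement direction for one positive and one negative
  for (a_val in 0:1) {
    b_val <- 1L - a_val
    pa <- codes_with(if (a_val == 1L) "P5" else character())
    pb <- codes_with(if (b_val == 1L) "P5" else character())
    r <- reconcile_codings(coding_record("a1", "A", pa),
                           coding_record("a1", "B", pb), "conservative")
    expect_equal(unname(r$final_codes[["P5"]]), 0L)  # disputed protective -> 0
    na_ <- codes_with(if (a_val == 1L) "N4" else character())
    nb_ <- codes_with(if (b_val == 1L) "N4" else character())
    r <- reconcile_codings(coding_record("a1", "A", na_),
                           coding_record("a1", "B", nb_), "conservative")
    expect_equal(unname(r$final_codes[["N4"]]), 1L)  # disputed harmful -> 1
  }
  # prefer_A / prefer_B
  a <- coding_record("a1", "A", codes_with("N1"))
  b <- coding_record("a1", "B", codes_with())
  expect_equal(unname(reconcile_codings(a, b, "prefer_A")$final_codes[["N1"]]), 1L)
  expect_equal(unname(reconcile_codings(a, b, "prefer_B")$final_codes[["N1"]]), 0L)
})

test_that("flagged discrepancies can be resolved to a scoreable record", {
  a <- coding_record("a1", "A", codes_with("N1"))
  b <- coding_record("a1", "B", codes_with())
  r <- reconcile_codings(a, b, "flag")
  expect_error(score_article(r), "unresolved", class = "mrscore_scoring_error")
  r2 <- resolve_discrepancies(r, c(N1 = 1L), resolved_by = "consensus")
  expect_equal(score_article(r2)$negative_score, 1L)
  expect_equal(r2$discrepancies$resolution, "consensus_value")
  expect_error(resolve_discrepancies(r, c(P5 = 1L)), "not in dispute",
               class = "mrscore_coding_error")
})

test_that("reconciliation preserves P2 <= P1 under any strategy", {
  a <- coding_record("a1", "A", codes_with(c("P1", "P2")))
  b <- coding_record("a1", "B", codes_with())
  for (s in c("prefer_A", "prefer_B", "conservative")) {
    f <- reconcile_codings(a, b, s)$final_codes
    expect_true(is.na(f[["P2"]]) || is.na(f[["P1"]]) || f[["P2"]] <= f[["P1"]],
                label = s)
  }
})

test_that("percent agreement and kappa match the 2x2 closed form", {
  # constructed confusion counts (both1, A-only, B-only, both0) = (40,5,5,50)
  mk <- function(i, on) coding_record(paste0("a", i), "X", codes_with(on))
  mkb <- function(i, on) coding_record(paste0("a", i), "Y", codes_with(on))
  a_on <- c(rep(TRUE, 40), rep(TRUE, 5), rep(FALSE, 5), rep(FALSE, 50))
  b_on <- c(rep(TRUE, 40), rep(FALSE, 5), rep(TRUE, 5), rep(FALSE, 50))
  ra <- lapply(1:100, function(i) mk(i, if (a_on[i]) "N3" else character()))
  rb <- lapply(1:100, function(i) mkb(i, if (b_on[i]) "N3" else character()))
  tab <- interrater_agreement(ra, rb)
  row <- tab[tab$criterion == "N3", ]
  expect_equal(row$percent_agreement, 0.90)
  # hand-computed kappa: po=.9, pe=(45*45+55*55)/100^2=.505 -> (.9-.505)/.495
  expect_equal(row$kappa, (0.9 - 0.505) / 0.495, tolerance = 1e-12)
  # criteria where both coders were constant: perfect agreement, kappa undefined
  row0 <- tab[tab$criterion == "P1", ]
  expect_equal(row0$percent_agreement, 1)
  expect_true(is.na(row0$kappa))
  # independent cross-check of the kappa value
  skip_if_not_installed("e1071")
  cm <- table(factor(a_on, c(FALSE, TRUE)), factor(b_on, c(FALSE, TRUE)))
  expect_equal(row$kappa, e1071::classAgreement(cm)$kappa, tolerance = 1e-12)
})

test_that("identical coders agree perfectly on every criterion", {
  set.seed(5)
  recs <- lapply(1:20, function(i)
    coding_record(paste0("a", i), "X",
                  codes_with(sample(setdiff(criterion_codes(), "P2"), 4))))
  recs_b <- lapply(recs, function(r) coding_record(r$article_id, "Y", r$codes))
  tab <- interrater_agreement(recs, recs_b)
  expect_true(all(tab$percent_agreement == 1))
  expect_error(interrater_agreement(list()), "at least one",
               class = "mrscore_coding_error")
})
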