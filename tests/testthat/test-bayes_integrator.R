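# build a component score frame and matching gold with known structure
make_calibration <- function(n, rates, method = "Str", aspect = "MF",
                             seed = 1L) {
  set.seed(seed)
  sim <- simulate_binned_scores(n, rates)
  scores <- data.frame(method = method,
                       domain_id = sprintf("d%06d", seq_len(n)),
                       term = "GO:0000002", aspect = aspect,
                       score = sim$score)
  gold <- as_annotation_set(scores$domain_id[sim$label], "GO:0000002",
                            aspect)
  list(scores = scores, gold = gold, sim = sim)
}

test_that("per-bin LRs follow the odds-ratio definition by hand", {
  # one bin holding 8 pos / 2 neg against 100 pos / 900 neg overall -> LR 36
  # constructed with smoothing 0 and 10 equal-width bins
  set.seed(61)
  n_pos <- 100; n_neg <- 900
  score_pos <- c(runif(8, 0.9, 0.9999), runif(92, 0, 0.1))
  score_neg <- c(runif(2, 0.9, 0.9999), runif(898, 0, 0.1))
  scores <- data.frame(method = "Str",
                       domain_id = sprintf("d%04d", 1:1000),
                       term = "GO:0000002", aspect = "MF",
                       score = c(score_pos, score_neg))
  gold <- as_annotation_set(scores$domain_id[1:100], "GO:0000002", "MF")
  tab <- fit_lr_table(scores, gold, onto = NULL, bins = 10L, smoothing = 0)
  top <- tab$table[tab$table$bin == 10L, ]
  expect_equal(top$pos, 8); expect_equal(top$neg, 2)
  expect_equal(top$lr, 36, tolerance = 1e-12)
  expect_equal(tab$prior$prior_odds, 1 / 9, tolerance = 1e-12)
})

test_that("shuffled labels drive every bin LR to 1 within sampling error", {
  cal <- make_calibration(1e4, rates = rep(0.3, 10), seed = 62)
  tab <- fit_lr_table(cal$scores, cal$gold, onto = NULL)
  lrs <- tab$table$lr[tab$table$bin > 0]
  expect_true(all(abs(log(lrs)) < log(1.35)))
})

test_that("fitted LRs recover analytic LRs from known per-bin rates", {
  rates <- seq(0.08, 0.85, length.out = 10)
  cal <- make_calibration(1e5, rates, seed = 63)
  tab <- fit_lr_table(cal$scores, cal$gold, onto = NULL)
  p <- mean(rates)
  analytic <- (rates / (1 - rates)) / (p / (1 - p))
  fitted <- tab$table$lr[order(tab$table$bin)][-1]   # drop absent bin
  expect_equal(fitted, analytic, tolerance = 0.1)
})

test_that("combine multiplies LRs and converts through prior odds exactly", {
  # hand-built table: method LRs {36, 1, 1, 1}, prior odds 1/9 -> 0.8
  mk <- function(m, lr_hi) {
    data.frame(method = m, aspect = "MF", bin = c(0L, 1L, 2L),
               bin_lo = c(NA, 0, 0.5), bin_hi = c(NA, 0.5, 1),
               pos = 0, neg = 0, lr = c(1, 1, lr_hi))
  }
  tables <- structure(list(
    table = rbind(mk("Str", 36), mk("IPR", 1), mk("PSSM", 1), mk("Seq", 1)),
    prior = data.frame(aspect = "MF", pos = 100, neg = 900,
                       prior_odds = 1 / 9),
    bins = 2L, smoothing = 0, methods = c("Str", "IPR", "PSSM", "Seq"),
    universe = "scored"), class = "lr_table")
  scores <- data.frame(method = c("Str", "IPR", "PSSM", "Seq"),
                       domain_id = "d1", term = "GO:0000002",
                       aspect = "MF", score = c(0.9, 0.9, 0.9, 0.9))
  res <- combine(scores, tables)
  expect_equal(res$combined_lr, 36, tolerance = 1e-12)
  expect_equal(res$posterior, 0.8, tolerance = 1e-12)

  # no evidence at all with absent-LR 1 -> posterior equals the prior
  only_str <- scores[1, ]; only_str$score <- 0.1   # bin LR 1
  res2 <- combine(only_str, tables)
  expect_equal(res2$posterior, (1 / 9) / (1 + 1 / 9), tolerance = 1e-12)
})

test_that("fused posteriors equal the direct odds-form oracle on random instances", {
  set.seed(64)
  aspects <- c("MF", "BP")
  scores <- NULL; gold_e <- character(0); gold_t <- character(0)
  for (a in aspects) {
    trm <- if (a == "MF") "GO:0000002" else "GO:0000012"
    for (m in c("Str", "IPR", "Seq")) {
      n <- 400
      dom <- sprintf("%s_d%03d", a, sample(300, n, TRUE))
      df <- unique(data.frame(method = m, domain_id = dom, term = trm,
                              aspect = a, score = round(runif(n), 3)))
      scores <- rbind(scores, df)
    }
    doms <- unique(scores$domain_id[scores$aspect == a])
    pos <- sample(doms, length(doms) %/% 3)
    gold_e <- c(gold_e, pos); gold_t <- c(gold_t, rep(trm, length(pos)))
  }
  gold <- as_annotation_set(gold_e, gold_t,
                            ifelse(grepl("^MF", gold_e), "MF", "BP"))
  tab <- fit_lr_table(scores, gold, onto = NULL, bins = 5L, smoothing = 1)
  res <- combine(scores, tab)
  want <- oracle_posterior(tab, res)
  expect_equal(res$posterior, want, tolerance = 1e-12)
})

test_that("method order does not change the combined LR", {
  set.seed(65)
  scores <- data.frame(method = rep(c("Str", "IPR", "Seq"), each = 50),
                       domain_id = sprintf("d%03d", rep(1:50, 3)),
                       term = "GO:0000002", aspect = "MF",
                       score = runif(150))
  gold <- as_annotation_set(sprintf("d%03d", sample(50, 20)),
                            "GO:0000002", "MF")
  tab <- fit_lr_table(scores, gold, onto = NULL, bins = 4L)
  perm <- scores[sample(nrow(scores)), ]
  expect_equal(combine(scores, tab)$combined_lr,
               combine(perm, tab)$combined_lr, tolerance = 1e-12)
})

test_that("posterior is monotone in a component score under a monotone LR table", {
  rates <- seq(0.05, 0.95, length.out = 10)
  cal <- make_calibration(2e4, rates, seed = 66)
  tab <- fit_lr_table(cal$scores, cal$gold, onto = NULL)
  probe <- data.frame(method = "Str",
                      domain_id = sprintf("q%02d", 1:10),
                      term = "GO:0000002", aspect = "MF",
                      score = seq(0.05, 0.95, length.out = 10))
  res <- combine(probe, tab)
  res <- res[order(res$score_Str), ]
  expect_true(all(diff(res$posterior) > 0))
})

test_that("thresholding is inclusive at the cutoff and monotone in it", {
  res <- data.frame(domain_id = "d1", term = sprintf("GO:%07d", 1:3),
                    aspect = "MF", combined_lr = 1,
                    posterior = c(0.4, 0.5, 0.9))
  expect_equal(nrow(threshold_annotations(res, 0.5)), 2L)
  expect_equal(nrow(threshold_annotations(res, 0)), 3L)
  counts <- vapply(seq(0, 1, 0.05),
                   function(ct) nrow(threshold_annotations(res, ct)), 0L)
  expect_true(all(diff(counts) <= 0))
})

test_that("fitting fails cleanly with no positives and LR tables round-trip TSV", {
  scores <- data.frame(method = "Str", domain_id = c("d1", "d2"),
                       term = "GO:0000002", aspect = "MF",
                       score = c(0.2, 0.7))
  empty_gold <- as_annotation_set(character(0), character(0), character(0))
  expect_error(fit_lr_table(scores, empty_gold, onto = NULL),
               "no positive")

  cal <- make_calibration(500, seq(0.1, 0.9, length.out = 10), seed = 67)
  tab <- fit_lr_table(cal$scores, cal$gold, onto = NULL)
  f <- tempfile(fileext = ".tsv")
  write_lr_table(tab, f)
  back <- read_lr_table(f)
  expect_equal(back$bins, tab$bins)
  expect_equal(back$prior$prior_odds, tab$prior$prior_odds)
  expect_equal(back$table$lr, tab$table$lr, tolerance = 1e-12)
  probe <- cal$scores[1:20, ]
  expect_equal(combine(probe, back)$posterior,
               combine(probe, tab)$posterior, tolerance = 1e-12)
})
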