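# a 3-term flat MF ontology for evaluation tests (root + children)
eval_ontology <- function(n_children = 8L) {
  obo <- c("[Term]", "id: GO:0000001", "namespace: molecular_function", "")
  for (i in seq_len(n_children)) {
    obo <- c(obo, "[Term]", sprintf("id: GO:%07d", i + 1),
             "namespace: molecular_function", "is_a: GO:0000001", "")
  }
  parse_obo(obo)
}

test_that("the three-threshold worked example yields Fmax 0.8", {
  onto <- eval_ontology()
  gold <- as_annotation_set(c("d1", "d1"), c("GO:0000002", "GO:0000003"),
                            "MF")
  preds <- data.frame(domain_id = "d1",
                      term = c("GO:0000002", "GO:0000004", "GO:0000003"),
                      aspect = "MF", score = c(0.9, 0.8, 0.4))
  rep <- evaluate_fmax(preds, gold, onto, universe = "d1", aspect = "MF")
  expect_equal(sort(rep$thresholds, decreasing = TRUE), c(0.9, 0.8, 0.4))
  f <- 2 * rep$precision * rep$recall / (rep$precision + rep$recall)
  expect_equal(f, c(2 / 3, 1 / 2, 4 / 5), tolerance = 1e-12)
  expect_equal(rep$fmax, 0.8, tolerance = 1e-12)
  expect_equal(rep$fmax_threshold, 0.4)
  expect_equal(rep$coverage, 1)
})

test_that("a perfect predictor reaches Fmax 1 and full coverage", {
  onto <- eval_ontology()
  set.seed(71)
  doms <- sprintf("d%02d", 1:10)
  gold <- as_annotation_set(rep(doms, each = 2),
                            sample(sprintf("GO:%07d", 2:9), 20, TRUE), "MF")
  preds <- data.frame(domain_id = gold$entity, term = gold$term,
                      aspect = "MF", score = 1.0)
  rep <- evaluate_fmax(preds, gold, onto, universe = doms, aspect = "MF")
  expect_equal(rep$fmax, 1.0)
  expect_equal(rep$coverage, 1.0)
})

test_that("Fmax matches the exhaustive-threshold oracle on random instances", {
  onto <- eval_ontology(20L)
  terms <- sprintf("GO:%07d", 2:21)
  for (seed in 72:74) {
    set.seed(seed)
    doms <- sprintf("d%02d", 1:25)
    gold <- as_annotation_set(rep(doms, each = 3),
                              sample(terms, 75, TRUE), "MF")
    preds <- unique(data.frame(domain_id = sample(doms, 150, TRUE),
                               term = sample(terms, 150, TRUE),
                               aspect = "MF",
                               score = round(runif(150), 2)))
    preds <- preds[!duplicated(preds[c("domain_id", "term")]), ]
    rep <- evaluate_fmax(preds, gold, onto, universe = doms, aspect = "MF")
    expect_equal(rep$fmax,
                 oracle_fmax(preds, as.data.frame(gold), doms),
                 tolerance = 1e-12)
  }
})

test_that("Fmax is invariant to monotone score rescaling", {
  onto <- eval_ontology(10L)
  set.seed(75)
  doms <- sprintf("d%02d", 1:15)
  terms <- sprintf("GO:%07d", 2:11)
  gold <- as_annotation_set(rep(doms, each = 2), sample(terms, 30, TRUE),
                            "MF")
  preds <- unique(data.frame(domain_id = sample(doms, 80, TRUE),
                             term = sample(terms, 80, TRUE),
                             aspect = "MF", score = runif(80)))
  preds <- preds[!duplicated(preds[c("domain_id", "term")]), ]
  base <- evaluate_fmax(preds, gold, onto, doms, "MF")$fmax
  for (f in list(function(x) x^3, function(x) plogis(5 * x),
                 function(x) 0.1 + 0.8 * x)) {
    resc <- preds; resc$score <- f(preds$score)
    expect_equal(evaluate_fmax(resc, gold, onto, doms, "MF")$fmax, base,
                 tolerance = 1e-12)
  }
})

test_that("aspect roots are excluded and empty gold raises an error", {
  onto <- eval_ontology()
  gold <- as_annotation_set("d1", "GO:0000002", "MF")
  preds <- data.frame(domain_id = "d1",
                      term = c("GO:0000001", "GO:0000002"),
                      aspect = "MF", score = c(1, 0.5))
  rep <- evaluate_fmax(preds, gold, onto, "d1", "MF")
  expect_equal(rep$fmax, 1.0)      # the root prediction is ignored
  expect_error(evaluate_fmax(preds, gold, onto, "d1", "BP"), "no gold")
})

test_that("coverage counts domains with any prediction over the universe", {
  onto <- eval_ontology()
  gold <- as_annotation_set(c("d1", "d2", "d3"), "GO:0000002", "MF")
  preds <- data.frame(domain_id = c("d1", "d2"), term = "GO:0000002",
                      aspect = "MF", score = c(0.9, 0.2))
  rep <- evaluate_fmax(preds, gold, onto,
                       universe = c("d1", "d2", "d3", "d4"), aspect = "MF")
  expect_equal(rep$coverage, 0.5)
})

test_that("decontamination removes test entries strictly above the identity cutoff", {
  idt <- data.frame(query_id = c("t1", "t2", "t3"),
                    subject_id = c("r1", "r1", "r2"),
                    pident = c(91, 90, 45))
  kept <- decontaminate(c("t1", "t2", "t3"), c("r1", "r2"), idt)
  expect_setequal(kept, c("t2", "t3"))   # 0.90 is not > 0.90
  expect_equal(decontaminate(c("t1", "t2"), character(0), idt),
               c("t1", "t2"))
})

test_that("decontamination matches a nested-loop oracle on random tables", {
  set.seed(76)
  test_d <- sprintf("t%02d", 1:20)
  train_d <- sprintf("r%02d", 1:15)
  idt <- data.frame(query_id = sample(test_d, 100, TRUE),
                    subject_id = sample(train_d, 100, TRUE),
                    pident = round(runif(100, 30, 100), 1))
  got <- decontaminate(test_d, train_d, idt, 0.9)
  bad <- character(0)
  for (td in test_d) {
    for (rd in train_d) {
      hit <- idt[(idt$query_id == td & idt$subject_id == rd) |
                   (idt$query_id == rd & idt$subject_id == td), ]
      if (nrow(hit) && any(hit$pident / 100 > 0.9)) bad <- c(bad, td)
    }
  }
  expect_setequal(got, setdiff(test_d, bad))
})

test_that("evaluation reports round-trip through their TSV form", {
  onto <- eval_ontology()
  gold <- as_annotation_set(c("d1", "d1"), c("GO:0000002", "GO:0000003"),
                            "MF")
  preds <- data.frame(domain_id = "d1",
                      term = c("GO:0000002", "GO:0000004"),
                      aspect = "MF", score = c(0.9, 0.4))
  rep <- evaluate_fmax(preds, gold, onto, "d1", "MF")
  f <- tempfile(fileext = ".tsv")
  write_eval_report(rep, f)
  hdr <- readLines(f, n = 1)
  expect_match(hdr, sprintf("fmax=%.6f", rep$fmax), fixed = TRUE)
  df <- read.delim(f, skip = 1)
  expect_equal(df$precision, rep$precision, tolerance = 1e-9)
  expect_equal(df$recall, rep$recall, tolerance = 1e-9)
})
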