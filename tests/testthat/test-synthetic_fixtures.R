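test_that("fixture generation is deterministic under a fixed seed", {
  d1 <- file.path(tempdir(), "fxdet1"); d2 <- file.path(tempdir(), "fxdet2")
  cfg <- fixture_config(seed = 101, n_domains = 12L, n_proteins = 40L,
                        n_terms = 24L)
  generate_fixtures(cfg, d1)
  generate_fixtures(cfg, d2)
  f1 <- sort(list.files(d1, recursive = TRUE))
  expect_equal(f1, sort(list.files(d2, recursive = TRUE)))
  for (f in f1) {
    expect_identical(readLines(file.path(d1, f), warn = FALSE),
                     readLines(file.path(d2, f), warn = FALSE),
                     label = f)
  }
})

test_that("all emitted files round-trip through the package readers", {
  d <- file.path(tempdir(), "fxround")
  cfg <- fixture_config(seed = 102, n_domains = 10L, n_proteins = 30L,
                        n_terms = 21L)
  fx <- generate_fixtures(cfg, d)
  onto <- parse_obo(fx$paths$obo)
  expect_s3_class(onto, "go_ontology")
  expect_gt(nrow(read_neighbor_table(fx$paths$neighbors)), 0L)
  expect_gt(nrow(read_blast_tab(fx$paths$blast)), 0L)
  expect_gt(nrow(read_interproscan(fx$paths$interproscan)), 0L)
  expect_gt(length(read_interpro2go(fx$paths$interpro2go)), 0L)
  expect_length(read_domain_fasta(fx$paths$fasta), cfg$n_domains)
  gold <- read_gaf(fx$paths$gold_gaf, onto)
  expect_length(attr(gold, "rejects"), 0L)
  for (p in fx$paths$pssm[1]) {
    prof <- read_pssm_ascii(p)
    expect_equal(ncol(prof$matrix), 20L)
    expect_equal(nrow(prof$matrix), cfg$pssm_length)
  }
})

test_that("generated gold annotations are true-path closed", {
  d <- file.path(tempdir(), "fxclosed")
  fx <- generate_fixtures(fixture_config(seed = 103, n_domains = 8L,
                                         n_terms = 18L), d)
  prop <- propagate(fx$gold, fx$ontology)
  expect_setequal(paste(prop$entity, prop$term),
                  paste(fx$gold$entity, fx$gold$term))
})

test_that("in the noiseless limit every counting scorer is certain on covered gold pairs", {
  d <- file.path(tempdir(), "fxnoiseless")
  cfg <- fixture_config(seed = 104, n_domains = 10L, n_proteins = 200L,
                        n_terms = 18L,
                        signal = c(str = 1, ipr = 1, pssm = 1, seq = 1),
                        noise = 0, channel_coverage = 1)
  fx <- generate_fixtures(cfg, d)
  onto <- fx$ontology
  scores <- suppressMessages(
    compute_component_scores(d, onto, run_config()))
  gold_key <- paste(fx$gold$entity, fx$gold$term)
  for (m in c("Str", "IPR", "Seq")) {
    sm <- scores[scores$method == m, ]
    on_gold <- sm[paste(sm$domain_id, sm$term) %in% gold_key, ]
    expect_gt(nrow(on_gold), 0)
    expect_true(all(abs(on_gold$score - 1) < 1e-12), label = m)
  }
})

test_that("structural scores concentrate at the signal rate (binomial expectation)", {
  d <- file.path(tempdir(), "fxbinom")
  cfg <- fixture_config(seed = 105, n_domains = 5L, n_proteins = 5000L,
                        n_terms = 27L,
                        signal = c(str = 0.5, ipr = 0.9, pssm = 0.9,
                                   seq = 0.9),
                        noise = 0, channel_coverage = 1,
                        neighbors_per_domain = 200L)
  fx <- generate_fixtures(cfg, d)
  nb <- read_neighbor_table(file.path(d, "neighbors.tsv"))
  mapping <- filter_neighbors(nb, 0.1, collapse_chains = FALSE)
  pa <- propagate(read_gaf(file.path(d, "protein_annotations.gaf"),
                           fx$ontology), fx$ontology)
  s <- score_structural(mapping, pa)
  # measure only gold draws that are not ancestors of a sibling gold draw
  # (an ancestral term also collects carriers through propagation of the
  # sibling, pushing its fraction above the per-term inheritance rate)
  gd <- fx$gold_direct
  indep <- vapply(seq_len(nrow(gd)), function(i) {
    sibs <- gd$term[gd$entity == gd$entity[i] & gd$term != gd$term[i]]
    !any(vapply(sibs, function(s2) {
      gd$term[i] %in% ancestors(fx$ontology, s2)
    }, TRUE))
  }, TRUE)
  leaf_key <- paste(gd$entity[indep], gd$term[indep])
  on_leaf <- s[paste(s$domain_id, s$term) %in% leaf_key, ]
  expect_gt(nrow(on_leaf), 10)
  expect_equal(mean(on_leaf$score), 0.5, tolerance = 0.05)
})

test_that("raising a channel's signal weakly raises its mean score on gold pairs", {
  means <- vapply(c(0.3, 0.6, 0.9), function(sig) {
    d <- file.path(tempdir(), sprintf("fxmono%d", round(100 * sig)))
    cfg <- fixture_config(seed = 106, n_domains = 10L, n_proteins = 60L,
                          n_terms = 18L,
                          signal = c(str = sig, ipr = 0.5, pssm = 0.5,
                                     seq = 0.5),
                          noise = 0.05, channel_coverage = 1)
    fx <- generate_fixtures(cfg, d)
    scores <- suppressMessages(
      compute_component_scores(d, fx$ontology, run_config()))
    sm <- scores[scores$method == "Str", ]
    gold_key <- paste(fx$gold$entity, fx$gold$term)
    mean(sm$score[paste(sm$domain_id, sm$term) %in% gold_key])
  }, 0)
  expect_true(all(diff(means) > 0))
})

test_that("infeasible configurations are rejected", {
  expect_error(fixture_config(n_terms = 6L), "at least 9")
  expect_error(fixture_config(signal = c(str = 1.2, ipr = 1, pssm = 1,
                                         seq = 1)))
  expect_error(fixture_config(signal = c(a = 0.5)), "names")
})

test_that("simulate_binned_scores hits the requested per-bin rates", {
  set.seed(107)
  rates <- c(0.1, 0.5, 0.9)
  sim <- simulate_binned_scores(3e4, rates)
  got <- tapply(sim$label, sim$bin, mean)
  expect_equal(as.numeric(got), rates, tolerance = 0.03)
  expect_true(all(sim$score >= 0 & sim$score < 1))
  expect_equal(floor(sim$score * 3) + 1, sim$bin)
})
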