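#' Pipeline run configuration
#'
#' Collects the tunable constants of the annotation pipeline with their
#' default values: PSD neighbor cutoff 0.1 (strict `<`), homolog
#' alignment-coverage cutoff 0.6 (strict `>`), auto-covariance lag 10,
#' 10 LR bins with additive smoothing 1, posterior reporting cutoff 0.5
#' (inclusive `>=`), and decontamination identity cutoff 0.9 (strict `>`).
#'
#' @param psd_threshold PSD below which a protein is a structural
#'   neighbor.
#' @param coverage_threshold Homolog query-coverage floor.
#' @param acc_lag Auto-covariance maximum lag.
#' @param bins LR bins over \[0,1\].
#' @param smoothing Additive LR smoothing per cell.
#' @param score_cutoff Posterior cutoff for reported annotations.
#' @param max_identity Train/test decontamination identity cutoff.
#' @param min_support Minimum structural neighbors per scored domain.
#' @param min_pos,min_neg Class floors for PSSM term classifiers.
#' @param seed RNG seed for stochastic training steps.
#' @return List of class `run_config`.
#' @export
run_config <- function(psd_threshold = 0.1, coverage_threshold = 0.6,
                       acc_lag = 10L, bins = 10L, smoothing = 1,
                       score_cutoff = 0.5, max_identity = 0.9,
                       min_support = 1L, min_pos = 10L, min_neg = 10L,
                       seed = 1L) {
  structure(list(psd_threshold = psd_threshold,
                 coverage_threshold = coverage_threshold,
                 acc_lag = as.integer(acc_lag), bins = as.integer(bins),
                 smoothing = smoothing, score_cutoff = score_cutoff,
                 max_identity = max_identity,
                 min_support = as.integer(min_support),
                 min_pos = as.integer(min_pos),
                 min_neg = as.integer(min_neg),
                 seed = as.integer(seed)),
            class = "run_config")
}

.stage <- function(name, n) {
  message(sprintf("stage %s: n=%d", name, n))
}

#' Auto-covariance feature matrix for a directory of PSSM files
#'
#' @param pssm_dir Directory of `*.pssm` ASCII profiles.
#' @param lag Auto-covariance lag.
#' @return Numeric matrix, one row per domain (rownames = domain ids).
#' @export
pssm_feature_matrix <- function(pssm_dir, lag = 10L) {
  files <- sort(list.files(pssm_dir, pattern = "\\.pssm$",
                           full.names = TRUE))
  if (!length(files)) {
    return(matrix(numeric(0), nrow = 0, ncol = 20L * lag))
  }
  feats <- lapply(files, function(f) {
    acc_transform(read_pssm_ascii(f), l = lag)
  })
  mat <- do.call(rbind, feats)
  rownames(mat) <- vapply(feats, attr, "", "domain_id")
  mat
}

#' Compute all component scores for a fixture-layout input directory
#'
#' Runs the four scorers over the standard input layout (as produced by
#' [generate_fixtures()]): `neighbors.tsv` + `protein_annotations.gaf`
#' (Str), `interproscan.tsv` + `interpro2go.txt` (IPR), `pssm/` (PSSM,
#' when trained models are supplied), `blast.tsv` +
#' `homolog_annotations.gaf` (Seq). Protein and homolog annotations are
#' true-path propagated before counting.
#'
#' @param input_dir Input directory.
#' @param onto A `go_ontology`.
#' @param config A [run_config()].
#' @param pssm_models Optional `pssm_model_set`; the PSSM channel is
#'   skipped when NULL.
#' @param features Optional precomputed feature matrix (else read from
#'   `pssm/`).
#' @return Component score data.frame (columns `method`, `domain_id`,
#'   `term`, `aspect`, `score`).
#' @export
compute_component_scores <- function(input_dir, onto, config = run_config(),
                                     pssm_models = NULL, features = NULL) {
  common <- c("method", "domain_id", "term", "aspect", "score")
  parts <- list()

  nb_path <- file.path(input_dir, "neighbors.tsv")
  if (file.exists(nb_path)) {
    nb <- read_neighbor_table(nb_path)
    .stage("neighbors_read", nrow(nb))
    mapping <- filter_neighbors(nb, config$psd_threshold)
    .stage("neighbors_retained", nrow(mapping))
    pa <- propagate(read_gaf(file.path(input_dir, "protein_annotations.gaf"),
                             onto), onto)
    s <- score_structural(mapping, pa, config$min_support)
    .stage("scores_str", nrow(s))
    parts$str <- s[common]
  }

  ips_path <- file.path(input_dir, "interproscan.tsv")
  if (file.exists(ips_path)) {
    hits <- read_interproscan(ips_path)
    .stage("interpro_hits", nrow(hits))
    i2g <- read_interpro2go(file.path(input_dir, "interpro2go.txt"))
    s <- score_interpro(hits, i2g, onto)
    .stage("scores_ipr", nrow(s))
    parts$ipr <- s[common]
  }

  if (!is.null(pssm_models)) {
    if (is.null(features)) {
      features <- pssm_feature_matrix(file.path(input_dir, "pssm"),
                                      config$acc_lag)
    }
    s <- score_pssm(features, pssm_models, onto)
    .stage("scores_pssm", nrow(s))
    parts$pssm <- s[common]
  }

  bl_path <- file.path(input_dir, "blast.tsv")
  if (file.exists(bl_path)) {
    bl <- read_blast_tab(bl_path)
    .stage("blast_read", nrow(bl))
    bl <- filter_homologs(bl, config$coverage_threshold)
    .stage("blast_retained", nrow(bl))
    ha <- propagate(read_gaf(file.path(input_dir, "homolog_annotations.gaf"),
                             onto), onto)
    s <- score_homolog(bl, ha)
    .stage("scores_seq", nrow(s))
    parts$seq <- s[common]
  }
  out <- do.call(rbind, unname(parts))
  rownames(out) <- NULL
  out
}

#' Train the annotation model on a fixture-layout directory
#'
#' Parses the ontology and gold GAF, trains per-term PSSM classifiers,
#' computes component scores for all training domains, and fits the
#' binned likelihood-ratio tables. Artifacts (LR table TSV, PSSM model
#' store) are written to `out_dir`.
#'
#' @param input_dir Directory in the [generate_fixtures()] layout.
#' @param out_dir Output directory for trained artifacts.
#' @param config A [run_config()].
#' @return Invisibly: list with `tables` (`lr_table`), `models`
#'   (`pssm_model_set` or NULL), `scores`, `onto`, `gold`.
#' @export
run_train <- function(input_dir, out_dir, config = run_config()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  onto <- parse_obo(file.path(input_dir, "ontology.obo"))
  gold <- propagate(read_gaf(file.path(input_dir, "gold.gaf"), onto), onto)
  .stage("gold_pairs", nrow(gold))

  models <- NULL; features <- NULL
  pssm_dir <- file.path(input_dir, "pssm")
  if (dir.exists(pssm_dir) &&
        length(list.files(pssm_dir, pattern = "\\.pssm$"))) {
    features <- pssm_feature_matrix(pssm_dir, config$acc_lag)
    .stage("pssm_profiles", nrow(features))
    models <- train_pssm_models(features, gold, onto,
                                min_pos = config$min_pos,
                                min_neg = config$min_neg,
                                seed = config$seed)
    .stage("pssm_models", length(models$models))
  }
  scores <- compute_component_scores(input_dir, onto, config,
                                     pssm_models = models,
                                     features = features)
  .stage("component_scores", nrow(scores))
  tables <- fit_lr_table(scores, gold, onto, bins = config$bins,
                         smoothing = config$smoothing)
  write_lr_table(tables, file.path(out_dir, "lr_table.tsv"))
  if (!is.null(models)) {
    saveRDS(models, file.path(out_dir, "pssm_models.rds"))
  }
  invisible(list(tables = tables, models = models, scores = scores,
                 onto = onto, gold = gold))
}

#' Annotate domains with trained artifacts
#'
#' Computes component scores for the input directory's domains, fuses
#' them through the fitted LR tables, applies the posterior cutoff and
#' writes the annotation table plus a sidecar report of domains with no
#' evidence on any channel.
#'
#' @param input_dir Directory in the [generate_fixtures()] layout.
#' @param model_dir Directory written by [run_train()].
#' @param out_path Output annotation TSV path.
#' @param config A [run_config()].
#' @param cutoff Posterior cutoff (default `config$score_cutoff`).
#' @return Invisibly: the thresholded annotation data.frame (attribute
#'   `unannotated` lists evidence-less domains).
#' @export
run_annotate <- function(input_dir, model_dir, out_path,
                         config = run_config(),
                         cutoff = config$score_cutoff) {
  onto <- parse_obo(file.path(input_dir, "ontology.obo"))
  tables <- read_lr_table(file.path(model_dir, "lr_table.tsv"))
  models_path <- file.path(model_dir, "pssm_models.rds")
  models <- if (file.exists(models_path)) readRDS(models_path) else NULL
  scores <- compute_component_scores(input_dir, onto, config,
                                     pssm_models = models)
  results <- combine(scores, tables)
  .stage("fused_pairs", nrow(results))
  kept <- threshold_annotations(results, cutoff)
  .stage("reported_annotations", nrow(kept))
  write_annotations(kept, out_path)

  universe <- .domain_universe(input_dir)
  unannotated <- setdiff(universe, unique(results$domain_id))
  writeLines(unannotated, paste0(out_path, ".unannotated"))
  attr(kept, "unannotated") <- unannotated
  invisible(kept)
}

.domain_universe <- function(input_dir) {
  fa <- file.path(input_dir, "domains.fasta")
  if (file.exists(fa)) return(names(read_domain_fasta(fa)))
  character(0)
}

#' Evaluate a written annotation table against gold
#'
#' @param pred_path Annotation TSV written by [run_annotate()] (or any
#'   table [read_annotations()] accepts).
#' @param input_dir Directory holding `ontology.obo` and `gold.gaf`.
#' @param out_dir Directory for per-aspect report TSVs (NULL to skip
#'   writing).
#' @param universe Optional domain universe (default: domains in the
#'   input directory's FASTA, else the gold domains).
#' @return Named list of `eval_report`s (aspects with gold only).
#' @export
run_evaluate <- function(pred_path, input_dir, out_dir = NULL,
                         universe = NULL) {
  onto <- parse_obo(file.path(input_dir, "ontology.obo"))
  gold <- propagate(read_gaf(file.path(input_dir, "gold.gaf"), onto), onto)
  preds <- read_annotations(pred_path)
  if (is.null(universe)) {
    universe <- .domain_universe(input_dir)
    if (!length(universe)) universe <- unique(gold$entity)
  }
  reports <- list()
  for (a in c("MF", "BP", "CC")) {
    if (!any(gold$aspect == a)) {
      warning(sprintf("aspect %s has no gold annotations; skipped", a))
      next
    }
    rep_a <- evaluate_fmax(preds, gold, onto, universe = universe,
                           aspect = a)
    print(rep_a)
    reports[[a]] <- rep_a
    if (!is.null(out_dir)) {
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      write_eval_report(rep_a, file.path(out_dir,
                                         sprintf("eval_%s.tsv", a)))
    }
  }
  invisible(reports)
}
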