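#' Precision-recall / Fmax evaluation of domain GO predictions
#'
#' Domain-centric (CAFA-1 style) protocol within one aspect. At each score
#' threshold t (the sorted distinct prediction scores — exact maximisation,
#' no grid): precision is averaged over domains with at least one
#' prediction >= t, recall over all gold-annotated domains in the universe
#' (domains with no prediction contribute recall 0). The F-measure is the
#' harmonic mean `2PR/(P+R)`, Fmax its maximum over thresholds, and
#' coverage the fraction of the universe with at least one prediction at
#' any score. Aspect-root terms are excluded from gold and predictions
#' before scoring (they are trivially true).
#'
#' @param predictions data.frame with columns `domain_id`, `term`,
#'   `aspect`, and a score column (`posterior` or `score`); assumed
#'   true-path propagated.
#' @param gold True-path-propagated `annotation_set` over the test
#'   domains.
#' @param onto A `go_ontology` (supplies the aspect roots to drop).
#' @param universe Character vector of domain ids defining the evaluation
#'   universe; defaults to the gold-annotated domains.
#' @param aspect Aspect to evaluate (`"MF"`, `"BP"`, `"CC"`).
#' @return Object of class `eval_report`: list with `aspect`,
#'   `thresholds` (descending), `precision`, `recall`, `fmax`,
#'   `fmax_threshold`, `coverage`, `n_domains`.
#' @export
evaluate_fmax <- function(predictions, gold, onto, universe = NULL,
                          aspect = c("MF", "BP", "CC")) {
  aspect <- match.arg(aspect)
  score_col <- if ("posterior" %in% names(predictions)) "posterior" else "score"
  gold_df <- as.data.frame(gold)
  roots <- unname(onto$roots)
  gold_df <- gold_df[gold_df$aspect == aspect & !gold_df$term %in% roots, ,
                     drop = FALSE]
  if (nrow(gold_df) == 0L) {
    stop(sprintf("no gold annotations for aspect %s", aspect))
  }
  if (is.null(universe)) universe <- unique(gold_df$entity)
  gold_df <- gold_df[gold_df$entity %in% universe, , drop = FALSE]

  pred <- predictions[predictions$aspect == aspect &
                        !predictions$term %in% roots &
                        predictions$domain_id %in% universe, , drop = FALSE]
  pred_score <- pred[[score_col]]

  gold_by_dom <- split(gold_df$term, gold_df$entity)
  gold_doms <- names(gold_by_dom)
  n_gold_dom <- length(gold_doms)

  coverage <- length(unique(pred$domain_id)) / length(universe)

  if (nrow(pred) == 0L) {
    return(structure(list(aspect = aspect, thresholds = numeric(0),
                          precision = numeric(0), recall = numeric(0),
                          fmax = 0, fmax_threshold = NA_real_,
                          coverage = coverage,
                          n_domains = length(universe)),
                     class = "eval_report"))
  }

  thresholds <- sort(unique(pred_score), decreasing = TRUE)
  P <- R <- numeric(length(thresholds))
  pred_by_dom <- split(seq_len(nrow(pred)), pred$domain_id)
  gold_of <- gold_by_dom[names(pred_by_dom)]

  for (ti in seq_along(thresholds)) {
    t <- thresholds[ti]
    prec <- c(); rec_sum <- 0
    for (di in seq_along(pred_by_dom)) {
      idx <- pred_by_dom[[di]]
      sel <- idx[pred_score[idx] >= t]
      if (!length(sel)) next
      terms_t <- pred$term[sel]
      gset <- gold_of[[di]]
      tp <- sum(terms_t %in% gset)
      prec <- c(prec, tp / length(terms_t))
      if (!is.null(gset)) rec_sum <- rec_sum + tp / length(gset)
    }
    P[ti] <- if (length(prec)) mean(prec) else 0
    R[ti] <- rec_sum / n_gold_dom
  }
  F <- ifelse(P + R > 0, 2 * P * R / (P + R), 0)
  best <- which.max(F)
  structure(list(aspect = aspect, thresholds = thresholds,
                 precision = P, recall = R,
                 fmax = F[best], fmax_threshold = thresholds[best],
                 coverage = coverage, n_domains = length(universe)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("%s: Fmax = %.4f at t = %.4f; coverage = %.4f (%d domains, %d thresholds)\n",
              x$aspect, x$fmax, x$fmax_threshold, x$coverage,
              x$n_domains, length(x$thresholds)))
  invisible(x)
}

#' Write an evaluation report as TSV
#'
#' One (threshold, precision, recall) row per threshold plus a trailing
#' summary block of comment lines.
#' @param report An `eval_report`.
#' @param path Output path.
#' @export
write_eval_report <- function(report, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("# aspect=%s fmax=%.6f fmax_threshold=%.6f coverage=%.6f",
                     report$aspect, report$fmax, report$fmax_threshold,
                     report$coverage), con)
  df <- data.frame(threshold = report$thresholds,
                   precision = report$precision, recall = report$recall)
  utils::write.table(format(df, digits = 10), con, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Remove test domains too similar to the training set
#'
#' Drops test entries whose sequence identity to any training entry is
#' strictly greater than `max_identity` (default 0.9), the standard
#' decontamination step before measuring generalisation. Pairs missing
#' from the identity table are treated as identity 0.
#'
#' @param test_domains,train_domains Character vectors of domain ids.
#' @param identity data.frame with columns `query_id`, `subject_id`,
#'   `pident` (percent, 0-100, as in BLAST tabular) or `identity`
#'   (fraction).
#' @param max_identity Fractional identity cutoff; strict `>` removal.
#' @return Filtered test domain vector.
#' @export
decontaminate <- function(test_domains, train_domains, identity,
                          max_identity = 0.9) {
  if (!length(train_domains) || is.null(identity) || nrow(identity) == 0L) {
    return(test_domains)
  }
  frac <- if ("identity" %in% names(identity)) identity$identity
          else identity$pident / 100
  cross <- (identity$query_id %in% test_domains &
              identity$subject_id %in% train_domains) |
           (identity$subject_id %in% test_domains &
              identity$query_id %in% train_domains)
  hot <- cross & frac > max_identity
  contaminated <- unique(c(identity$query_id[hot], identity$subject_id[hot]))
  setdiff(test_domains, contaminated)
}
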