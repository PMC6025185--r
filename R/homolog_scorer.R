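#' Filter sequence homologs by alignment coverage
#'
#' Retains BLAST hits with query coverage strictly greater than the
#' threshold (default 0.6), then keeps one hit per (query, subject) pair at
#' the minimum E-value.
#'
#' @param hits data.frame from [read_blast_tab()].
#' @param min_coverage Coverage threshold in (0, 1\]; strict `>`.
#' @return Filtered, deduplicated data.frame.
#' @export
filter_homologs <- function(hits, min_coverage = 0.6) {
  stopifnot(min_coverage > 0, min_coverage <= 1)
  df <- hits[hits$coverage > min_coverage, , drop = FALSE]
  o <- order(df$query_id, df$subject_id, df$evalue)
  df <- df[o, , drop = FALSE]
  df <- df[!duplicated(df[c("query_id", "subject_id")]), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Homology-transfer GO score P4(g)
#'
#' Each retained homolog i of a query domain votes with weight
#' `w_i = (-log E_i + b) / sum_j (-log E_j + b)` and
#' `P4(g) = sum_i w_i I_i(g)`, where I_i(g) is 1 when homolog i carries g.
#' b = log(10) in the same base as the log, which makes P4 invariant to the
#' choice of log base (natural log used here). Hits with E > 10, whose
#' weight would be negative, are dropped with a warning.
#'
#' @param hits Filtered data.frame from [filter_homologs()].
#' @param homolog_annotations True-path-propagated `annotation_set` over
#'   the subject (homolog) ids.
#' @return data.frame with columns `method` ("Seq"), `domain_id`, `term`,
#'   `aspect`, `score`, `n` (retained homolog count for the domain).
#' @export
score_homolog <- function(hits, homolog_annotations) {
  empty <- data.frame(method = character(0), domain_id = character(0),
                      term = character(0), aspect = character(0),
                      score = numeric(0), n = integer(0))
  if (nrow(hits) == 0L) return(empty)
  stopifnot(all(hits$evalue > 0))
  w_raw <- -log(hits$evalue) + log(10)
  if (any(w_raw <= 0)) {
    warning(sprintf("dropping %d hit(s) with E-value > 10 (non-positive weight)",
                    sum(w_raw <= 0)))
    hits <- hits[w_raw > 0, , drop = FALSE]
    w_raw <- w_raw[w_raw > 0]
    if (nrow(hits) == 0L) return(empty)
  }
  wsum <- tapply(w_raw, hits$query_id, sum)
  n_by_q <- table(hits$query_id)
  hits$weight <- w_raw / as.numeric(wsum[hits$query_id])

  ann <- as.data.frame(homolog_annotations)
  m <- merge(hits[c("query_id", "subject_id", "weight")], ann,
             by.x = "subject_id", by.y = "entity")
  if (nrow(m) == 0L) return(empty)
  agg <- stats::aggregate(list(score = m$weight),
                          by = list(domain_id = m$query_id, term = m$term,
                                    aspect = m$aspect),
                          FUN = sum)
  out <- data.frame(method = "Seq", domain_id = agg$domain_id,
                    term = agg$term, aspect = agg$aspect,
                    score = pmin(agg$score, 1),
                    n = as.integer(n_by_q[agg$domain_id]),
                    stringsAsFactors = FALSE)
  out <- out[order(out$domain_id, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out
}
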