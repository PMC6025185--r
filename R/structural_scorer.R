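#' Filter structural neighbors by PSD
#'
#' A protein counts as a structural neighbor of a domain when its protein
#' structure distance (PSD) is strictly below the threshold (default 0.1).
#' Retained pairs are deduplicated to unique (domain, protein) pairs; by
#' default chains are collapsed so proteins are counted at PDB-entry
#' granularity.
#'
#' @param hits data.frame from [read_neighbor_table()].
#' @param psd_threshold Positive PSD cutoff; strict `<` (default 0.1).
#' @param collapse_chains Strip a trailing chain suffix (`_A` or `:A`)
#'   from protein ids before deduplication (default TRUE).
#' @return data.frame of unique (`domain_id`, `protein_id`) pairs.
#' @export
filter_neighbors <- function(hits, psd_threshold = 0.1,
                             collapse_chains = TRUE) {
  stopifnot(psd_threshold > 0)
  keep <- hits$psd < psd_threshold
  df <- hits[keep, c("domain_id", "protein_id"), drop = FALSE]
  if (collapse_chains) {
    df$protein_id <- sub("[_:][A-Za-z0-9]$", "", df$protein_id)
  }
  df <- unique(df)
  rownames(df) <- NULL
  df
}

#' Structural-neighbor GO score P1(g|d)
#'
#' For each domain d with neighbor proteins, the probability of term g is
#' the fraction of d's neighbor proteins annotated with g:
#' `P1(g|d) = P(d,g) / P(d)`, where `P(d,g)` counts neighbor proteins of d
#' carrying g and `P(d)` counts all neighbor proteins of d. Terms with no
#' annotated neighbor are omitted rather than emitted as zero.
#'
#' @param mapping data.frame of (`domain_id`, `protein_id`) pairs from
#'   [filter_neighbors()].
#' @param protein_annotations A true-path-propagated `annotation_set` over
#'   the neighbor proteins.
#' @param min_support Minimum neighbor count for a domain to be scored
#'   (default 1).
#' @return data.frame with columns `method` ("Str"), `domain_id`, `term`,
#'   `aspect`, `score`, `support` (P(d)), `hits` (P(d,g)).
#' @export
score_structural <- function(mapping, protein_annotations, min_support = 1L) {
  stopifnot(min_support >= 1L)
  empty <- data.frame(method = character(0), domain_id = character(0),
                      term = character(0), aspect = character(0),
                      score = numeric(0), support = integer(0),
                      hits = integer(0))
  if (nrow(mapping) == 0L) return(empty)
  support <- table(mapping$domain_id)
  keep_dom <- names(support)[support >= min_support]
  mapping <- mapping[mapping$domain_id %in% keep_dom, , drop = FALSE]
  if (nrow(mapping) == 0L) return(empty)

  ann <- as.data.frame(protein_annotations)
  m <- merge(mapping, ann, by.x = "protein_id", by.y = "entity")
  if (nrow(m) == 0L) return(empty)
  agg <- stats::aggregate(cbind(hits = m$protein_id),
                          by = list(domain_id = m$domain_id, term = m$term,
                                    aspect = m$aspect),
                          FUN = length)
  agg$support <- as.integer(support[agg$domain_id])
  agg$hits <- as.integer(agg$hits)
  agg$score <- agg$hits / agg$support
  out <- data.frame(method = "Str", domain_id = agg$domain_id,
                    term = agg$term, aspect = agg$aspect,
                    score = agg$score, support = agg$support,
                    hits = agg$hits, stringsAsFactors = FALSE)
  out <- out[order(out$domain_id, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out
}
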