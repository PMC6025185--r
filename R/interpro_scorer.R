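#' InterPro-mapping GO score P2(g)
#'
#' For a domain with n distinct InterPro hits, the probability of term g is
#' the fraction of those hits whose (true-path-propagated) InterPro2GO term
#' set contains g: `P2(g) = (1/n) sum_i I_i(g)`. InterPro accessions absent
#' from the mapping still count in n (they are hits carrying no terms);
#' domains with no hits emit nothing.
#'
#' @param hits data.frame from [read_interproscan()] (`domain_id`,
#'   `interpro_acc`), deduplicated internally by accession.
#' @param mapping Named list IPR -> GO accessions from
#'   [read_interpro2go()].
#' @param onto A `go_ontology`; each IPR's GO set is propagated by the
#'   true-path rule before counting.
#' @return data.frame with columns `method` ("IPR"), `domain_id`, `term`,
#'   `aspect`, `score`, `n` (distinct InterPro hits of the domain).
#' @export
score_interpro <- function(hits, mapping, onto) {
  empty <- data.frame(method = character(0), domain_id = character(0),
                      term = character(0), aspect = character(0),
                      score = numeric(0), n = integer(0))
  if (nrow(hits) == 0L) return(empty)
  hits <- unique(hits[c("domain_id", "interpro_acc")])
  n_by_dom <- table(hits$domain_id)

  # propagated GO set per distinct IPR accession appearing in the hits
  iprs <- unique(hits$interpro_acc)
  unmapped <- setdiff(iprs, names(mapping))
  if (length(unmapped)) {
    message(sprintf("%d InterPro accession(s) absent from InterPro2GO; counted in n only",
                    length(unmapped)))
  }
  ipr_terms <- lapply(iprs, function(ip) {
    gos <- mapping[[ip]]
    if (is.null(gos) || !length(gos)) return(character(0))
    anno <- annotation_set(rep(ip, length(gos)), gos, onto)
    prop <- propagate(anno, onto)
    prop$term
  })
  names(ipr_terms) <- iprs

  per_hit_terms <- ipr_terms[hits$interpro_acc]
  dom <- rep(hits$domain_id, times = lengths(per_hit_terms))
  trm <- unlist(per_hit_terms, use.names = FALSE)
  if (!length(trm)) return(empty)
  counts <- stats::aggregate(cbind(k = dom),
                             by = list(domain_id = dom, term = trm),
                             FUN = length)
  counts$n <- as.integer(n_by_dom[counts$domain_id])
  out <- data.frame(method = "IPR", domain_id = counts$domain_id,
                    term = counts$term,
                    aspect = onto$terms[counts$term, "aspect"],
                    score = as.integer(counts$k) / counts$n,
                    n = counts$n, stringsAsFactors = FALSE)
  out <- out[order(out$domain_id, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out
}
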