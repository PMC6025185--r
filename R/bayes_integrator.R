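.bin_index <- function(score, bins) {
  # equal-width bins over [0,1], convention [lo, hi) with the last bin
  # closed; findInterval on the shared edge vector keeps boundary scores
  # consistent with the serialized bin_lo/bin_hi columns
  edges <- seq(0, 1, length.out = bins + 1L)
  findInterval(score, edges, rightmost.closed = TRUE)
}

#' Fit binned likelihood-ratio tables from labelled calibration scores
#'
#' For each component method and GO aspect, component scores on calibration
#' (domain, term) pairs are split into equal-width bins over \[0, 1\] and a
#' likelihood ratio is estimated per bin: the odds of a pair being a true
#' annotation given its score falls in the bin, over the prior odds,
#'
#' `LR_b = ((pos_b + s) / (neg_b + s)) / ((pos_tot + s) / (neg_tot + s))`
#'
#' with additive smoothing `s`. Pairs the method produced no score for are
#' pooled into an "absent" pseudo-bin so that missing evidence is itself
#' informative. Positive pairs are those present in the propagated gold
#' annotation set; negatives are candidate pairs (scored by at least one
#' method, or all domain x term pairs with `universe = "all"`) not in gold.
#' Prior odds are estimated per aspect as `pos_tot / neg_tot`.
#'
#' @param scores Component score set: data.frame with columns `method`,
#'   `domain_id`, `term`, `aspect`, `score` (in \[0,1\]); typically
#'   `rbind()` of the four scorers' outputs.
#' @param gold True-path-propagated `annotation_set` over the calibration
#'   domains.
#' @param onto A `go_ontology` (used with `universe = "all"`).
#' @param bins Number of equal-width bins (default 10, >= 2).
#' @param smoothing Additive smoothing per cell (default 1).
#' @param universe `"scored"` (default): candidate negatives are pairs
#'   some method scored; `"all"`: the full domain x term cross product.
#' @return Object of class `lr_table` with `print`, `summary` and
#'   `predict` methods; `predict` fuses new component scores into
#'   posterior probabilities (see [combine()]).
#' @export
fit_lr_table <- function(scores, gold, onto, bins = 10L, smoothing = 1,
                         universe = c("scored", "all")) {
  universe <- match.arg(universe)
  stopifnot(bins >= 2L, smoothing >= 0)
  if (any(scores$score < 0 | scores$score > 1)) {
    stop("component scores must lie in [0, 1]")
  }
  gold_df <- as.data.frame(gold)
  gold_key <- paste(gold_df$entity, gold_df$term)

  if (universe == "scored") {
    cand <- unique(scores[c("domain_id", "term", "aspect")])
  } else {
    doms <- unique(scores$domain_id)
    live <- onto$terms[!onto$terms$obsolete, , drop = FALSE]
    cand <- expand.grid(domain_id = doms, term = live$id,
                        stringsAsFactors = FALSE)
    cand$aspect <- live[cand$term, "aspect"]
  }
  cand$label <- paste(cand$domain_id, cand$term) %in% gold_key

  aspects <- sort(unique(cand$aspect))
  methods <- sort(unique(scores$method))
  prior <- data.frame(aspect = aspects, pos = NA_real_, neg = NA_real_,
                      prior_odds = NA_real_)
  rows <- list()
  edges <- seq(0, 1, length.out = bins + 1L)

  for (a in aspects) {
    ca <- cand[cand$aspect == a, , drop = FALSE]
    pos_tot <- sum(ca$label); neg_tot <- sum(!ca$label)
    if (pos_tot == 0) {
      stop(sprintf("no positive calibration pairs for aspect %s", a))
    }
    prior[prior$aspect == a, c("pos", "neg")] <- c(pos_tot, neg_tot)
    prior[prior$aspect == a, "prior_odds"] <- pos_tot / neg_tot
    prior_term <- (pos_tot + smoothing) / (neg_tot + smoothing)
    ca_key <- paste(ca$domain_id, ca$term)

    for (m in methods) {
      sm <- scores[scores$method == m & scores$aspect == a, , drop = FALSE]
      sm_key <- paste(sm$domain_id, sm$term)
      lab <- ca$label[match(sm_key, ca_key)]
      b <- .bin_index(sm$score, bins)
      pos_b <- tabulate(b[lab], nbins = bins)
      neg_b <- tabulate(b[!lab], nbins = bins)
      lr <- ((pos_b + smoothing) / (neg_b + smoothing)) / prior_term
      absent <- !(ca_key %in% sm_key)
      pos_abs <- sum(ca$label[absent]); neg_abs <- sum(!ca$label[absent])
      lr_abs <- ((pos_abs + smoothing) / (neg_abs + smoothing)) / prior_term
      rows[[length(rows) + 1L]] <- data.frame(
        method = m, aspect = a,
        bin = c(seq_len(bins), 0L),
        bin_lo = c(edges[-length(edges)], NA_real_),
        bin_hi = c(edges[-1L], NA_real_),
        pos = c(pos_b, pos_abs), neg = c(neg_b, neg_abs),
        lr = c(lr, lr_abs), stringsAsFactors = FALSE)
    }
  }
  structure(list(table = do.call(rbind, rows), prior = prior,
                 bins = bins, smoothing = smoothing, methods = methods,
                 universe = universe),
            class = "lr_table")
}

.lr_lookup <- function(object, method, aspect, score) {
  # score NA -> absent pseudo-bin
  tb <- object$table
  sel <- tb$method == method & tb$aspect == aspect
  if (!any(sel)) {
    stop(sprintf("no fitted LR table for method %s, aspect %s",
                 method, aspect))
  }
  lr_bins <- tb$lr[sel][order(tb$bin[sel])]       # bin 0 (absent) first
  idx <- ifelse(is.na(score), 1L, .bin_index(score, object$bins) + 1L)
  lr_bins[idx]
}

#' Fuse component scores into posterior annotation probabilities
#'
#' For each (domain, term) pair, the combined likelihood ratio is the
#' product over methods of the LR of the bin containing that method's
#' score (the absent-bin LR when the method produced none):
#' `LR = prod_i LR_{f_i}`. The posterior is then
#' `prior_odds * LR / (1 + prior_odds * LR)` with the aspect's prior odds.
#'
#' @param scores Component score set (as in [fit_lr_table()]) for the
#'   domains to annotate.
#' @param tables A fitted `lr_table`.
#' @return data.frame with columns `domain_id`, `term`, `aspect`,
#'   `combined_lr`, `posterior`, and one `score_<method>` column per
#'   method (NA where the method produced no score).
#' @export
combine <- function(scores, tables) {
  stopifnot(inherits(tables, "lr_table"))
  if (any(scores$score < 0 | scores$score > 1)) {
    stop("component scores must lie in [0, 1]")
  }
  known <- scores$aspect %in% tables$prior$aspect
  scores <- scores[known, , drop = FALSE]
  pairs <- unique(scores[c("domain_id", "term", "aspect")])
  pair_key <- paste(pairs$domain_id, pairs$term)
  lr <- rep(1, nrow(pairs))
  for (m in tables$methods) {
    sm <- scores[scores$method == m, , drop = FALSE]
    sc <- sm$score[match(pair_key, paste(sm$domain_id, sm$term))]
    pairs[[paste0("score_", m)]] <- sc
    for (a in unique(pairs$aspect)) {
      sel <- pairs$aspect == a
      lr[sel] <- lr[sel] * .lr_lookup(tables, m, a, sc[sel])
    }
  }
  prior_odds <- tables$prior$prior_odds[match(pairs$aspect,
                                              tables$prior$aspect)]
  post_odds <- prior_odds * lr
  out <- data.frame(domain_id = pairs$domain_id, term = pairs$term,
                    aspect = pairs$aspect, combined_lr = lr,
                    posterior = post_odds / (1 + post_odds),
                    stringsAsFactors = FALSE)
  out <- cbind(out, pairs[grep("^score_", names(pairs))])
  out <- out[order(out$domain_id, -out$posterior), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @rdname combine
#' @param object A fitted `lr_table`.
#' @param newdata Component score set to fuse.
#' @param ... Unused.
#' @export
predict.lr_table <- function(object, newdata, ...) {
  combine(newdata, object)
}

#' Keep annotations above a posterior cutoff
#'
#' Retains rows with posterior greater than or equal to the cutoff
#' (default 0.5, the conventional confidence threshold for reporting).
#'
#' @param results data.frame from [combine()].
#' @param cutoff Posterior cutoff in \[0,1\]; inclusive `>=`.
#' @return Filtered data.frame.
#' @export
threshold_annotations <- function(results, cutoff = 0.5) {
  stopifnot(cutoff >= 0, cutoff <= 1)
  out <- results[results$posterior >= cutoff, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @export
print.lr_table <- function(x, ...) {
  cat(sprintf("Binned likelihood-ratio table: %d methods x %d aspects, %d bins (+absent), smoothing %g\n",
              length(x$methods), nrow(x$prior), x$bins, x$smoothing))
  cat(sprintf("  methods: %s\n", paste(x$methods, collapse = ", ")))
  for (i in seq_len(nrow(x$prior))) {
    cat(sprintf("  %s: prior odds %.4g (%d pos / %d neg)\n",
                x$prior$aspect[i], x$prior$prior_odds[i],
                x$prior$pos[i], x$prior$neg[i]))
  }
  invisible(x)
}

#' @export
summary.lr_table <- function(object, ...) {
  print(object)
  tb <- object$table
  for (m in object$methods) {
    rng <- range(tb$lr[tb$method == m & tb$bin > 0])
    cat(sprintf("  %s: LR range %.3g - %.3g across scored bins\n",
                m, rng[1], rng[2]))
  }
  invisible(object)
}

#' Serialize a fitted LR table to a self-describing TSV
#' @param object An `lr_table`.
#' @param path Output path.
#' @export
write_lr_table <- function(object, path) {
  tb <- object$table
  pr <- data.frame(method = "_prior", aspect = object$prior$aspect,
                   bin = NA_integer_, bin_lo = NA_real_, bin_hi = NA_real_,
                   pos = object$prior$pos, neg = object$prior$neg,
                   lr = object$prior$prior_odds, stringsAsFactors = FALSE)
  out <- rbind(tb[names(pr)], pr)
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("# lr_table bins=%d smoothing=%g universe=%s",
                     object$bins, object$smoothing, object$universe), con)
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read back an LR table written by [write_lr_table()]
#' @param path Path to the TSV.
#' @return An `lr_table`.
#' @export
read_lr_table <- function(path) {
  hdr <- readLines(path, n = 1L)
  m <- regmatches(hdr, regexec(
    "bins=(\\d+) smoothing=([0-9.eE+-]+) universe=(\\w+)", hdr))[[1]]
  if (length(m) != 4L) stop("not an lr_table file (missing header)")
  df <- utils::read.delim(path, skip = 1L, stringsAsFactors = FALSE)
  pr <- df[df$method == "_prior", , drop = FALSE]
  tb <- df[df$method != "_prior", , drop = FALSE]
  rownames(tb) <- rownames(pr) <- NULL
  structure(list(table = tb,
                 prior = data.frame(aspect = pr$aspect, pos = pr$pos,
                                    neg = pr$neg, prior_odds = pr$lr,
                                    stringsAsFactors = FALSE),
                 bins = as.integer(m[2]), smoothing = as.numeric(m[3]),
                 methods = sort(unique(tb$method)), universe = m[4]),
            class = "lr_table")
}
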