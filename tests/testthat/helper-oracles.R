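# Independent brute-force oracles used across the suite. These are written
# against the definitions directly (explicit nested loops, exhaustive path
# enumeration) and share no code with the package implementations.

# all ancestors of `term` by exhaustive path enumeration over parent lists
oracle_ancestors <- function(parents, term) {
  out <- character(0)
  walk <- function(t) {
    for (p in parents[[t]]) {
      out <<- c(out, p)
      walk(p)
    }
  }
  walk(term)
  unique(out)
}

# per-entity closure by the same enumeration
oracle_propagate <- function(entity, term, parents) {
  res_e <- character(0); res_t <- character(0)
  for (e in unique(entity)) {
    terms <- term[entity == e]
    closed <- unique(c(terms, unlist(lapply(terms, oracle_ancestors,
                                            parents = parents))))
    res_e <- c(res_e, rep(e, length(closed)))
    res_t <- c(res_t, closed)
  }
  df <- data.frame(entity = res_e, term = res_t, stringsAsFactors = FALSE)
  df[order(df$entity, df$term), ]
}

# P1 by explicit nested counting loops
oracle_p1 <- function(mapping, anno_df) {
  out <- NULL
  for (d in unique(mapping$domain_id)) {
    nbrs <- unique(mapping$protein_id[mapping$domain_id == d])
    terms <- unique(anno_df$term[anno_df$entity %in% nbrs])
    for (g in terms) {
      hits <- 0L
      for (p in nbrs) {
        if (any(anno_df$entity == p & anno_df$term == g)) hits <- hits + 1L
      }
      out <- rbind(out, data.frame(domain_id = d, term = g,
                                   score = hits / length(nbrs)))
    }
  }
  out[order(out$domain_id, out$term), ]
}

# P2 by explicit loops over a domain's distinct InterPro hits
oracle_p2 <- function(hits, ipr2go_closed) {
  out <- NULL
  for (d in unique(hits$domain_id)) {
    iprs <- unique(hits$interpro_acc[hits$domain_id == d])
    n <- length(iprs)
    terms <- unique(unlist(ipr2go_closed[iprs]))
    for (g in terms) {
      k <- 0L
      for (ip in iprs) if (g %in% ipr2go_closed[[ip]]) k <- k + 1L
      out <- rbind(out, data.frame(domain_id = d, term = g, score = k / n))
    }
  }
  out[order(out$domain_id, out$term), ]
}

# P4 by explicit weighted loops; log base selectable to check invariance
oracle_p4 <- function(hits, anno_df, logfun = log, b = log(10)) {
  out <- NULL
  for (q in unique(hits$query_id)) {
    h <- hits[hits$query_id == q, ]
    w <- -logfun(h$evalue) + b
    terms <- unique(anno_df$term[anno_df$entity %in% h$subject_id])
    for (g in terms) {
      num <- 0
      for (i in seq_len(nrow(h))) {
        if (any(anno_df$entity == h$subject_id[i] & anno_df$term == g)) {
          num <- num + w[i]
        }
      }
      out <- rbind(out, data.frame(domain_id = q, term = g,
                                   score = num / sum(w)))
    }
  }
  out[order(out$domain_id, out$term), ]
}

# auto-covariance by a naive double loop straight from the formula
oracle_ac <- function(X, l) {
  DL <- nrow(X)
  vals <- numeric(0)
  for (j in seq_len(ncol(X))) {
    xbar <- mean(X[, j])
    for (lag in seq_len(l)) {
      s <- 0
      for (i in seq_len(DL - lag)) {
        s <- s + (X[i, j] - xbar) * (X[i + lag, j] - xbar)
      }
      vals <- c(vals, s / (DL - lag))
    }
  }
  vals
}

# Fmax by exhaustive threshold enumeration with explicit per-domain loops
oracle_fmax <- function(pred, gold, universe) {
  gold_by <- split(gold$term, gold$entity)
  thr <- sort(unique(pred$score), decreasing = TRUE)
  best <- 0
  for (t in thr) {
    precs <- c(); recs <- numeric(0)
    for (d in universe) {
      pd <- pred$term[pred$domain_id == d & pred$score >= t]
      gd <- gold_by[[d]]
      if (length(pd)) precs <- c(precs, sum(pd %in% gd) / length(pd))
      if (!is.null(gd)) recs <- c(recs, sum(pd %in% gd) / length(gd))
    }
    P <- if (length(precs)) mean(precs) else 0
    R <- if (length(recs)) mean(recs) else 0
    f <- if (P + R > 0) 2 * P * R / (P + R) else 0
    if (f > best) best <- f
  }
  best
}

# direct odds-form naive-Bayes posterior: recompute per-bin LRs from the
# stored counts and bin each score by scanning the edges
oracle_posterior <- function(tables, scores_wide) {
  s <- tables$smoothing
  post <- numeric(nrow(scores_wide))
  for (r in seq_len(nrow(scores_wide))) {
    a <- scores_wide$aspect[r]
    pr <- tables$prior[tables$prior$aspect == a, ]
    odds <- pr$pos / pr$neg
    denom <- (pr$pos + s) / (pr$neg + s)
    lr <- 1
    for (m in tables$methods) {
      sc <- scores_wide[[paste0("score_", m)]][r]
      tb <- tables$table[tables$table$method == m & tables$table$aspect == a, ]
      if (is.na(sc)) {
        row <- tb[tb$bin == 0L, ]
      } else {
        hit <- NA
        for (i in which(tb$bin > 0L)) {
          lo <- tb$bin_lo[i]; hi <- tb$bin_hi[i]
          if ((sc >= lo && sc < hi) || (hi == 1 && sc == 1)) { hit <- i; break }
        }
        row <- tb[hit, ]
      }
      lr <- lr * ((row$pos + s) / (row$neg + s)) / denom
    }
    post[r] <- odds * lr / (1 + odds * lr)
  }
  post
}

# small random ontology helpers ------------------------------------------

random_obo_lines <- function(n_per_aspect = 10L, seed = 1L) {
  set.seed(seed)
  ns <- c(MF = "molecular_function", BP = "biological_process",
          CC = "cellular_component")
  lines <- c("format-version: 1.2", "")
  parents <- list()
  k <- 0L
  for (a in names(ns)) {
    ids <- sprintf("GO:%07d", k + seq_len(n_per_aspect))
    k <- k + n_per_aspect
    for (i in seq_along(ids)) {
      par <- if (i == 1L) character(0) else {
        ids[sample(i - 1L, min(i - 1L, sample(1:2, 1L)))]
      }
      parents[[ids[i]]] <- par
      lines <- c(lines, "[Term]", sprintf("id: %s", ids[i]),
                 sprintf("name: t%d", i), sprintf("namespace: %s", ns[a]),
                 sprintf("is_a: %s", par), "")
    }
  }
  list(lines = lines, parents = parents)
}

tiny_ontology <- function(n_per_aspect = 10L, seed = 1L) {
  ro <- random_obo_lines(n_per_aspect, seed)
  list(onto = parse_obo(ro$lines), parents = ro$parents)
}

as_annotation_set <- function(entity, term, aspect) {
  structure(unique(data.frame(entity = entity, term = term, aspect = aspect,
                              stringsAsFactors = FALSE)),
            class = c("annotation_set", "data.frame"))
}
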