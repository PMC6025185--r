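#' Auto-covariance transform of a PSSM profile
#'
#' Compresses a variable-length L x 20 PSSM into a fixed-length vector of
#' lag auto-covariances. For descriptor column X (one of the 20 residue
#' types) and lag `lag` in 1..l:
#' `AC = 1/(DL - lag) * sum_{i=1}^{DL-lag} (X_i - Xbar)(X_{i+lag} - Xbar)`,
#' with Xbar the column mean over the whole sequence and DL the sequence
#' length. Output is ordered descriptor-major, lag-minor (20 * l values).
#'
#' Cross-covariance terms between distinct descriptor columns (the "CC"
#' half of the ACC family, same normalisation) can be appended with
#' `cross = TRUE`; the default is auto-covariance only.
#'
#' @param profile A `pssm_profile` (or list with a numeric `matrix` of 20
#'   columns).
#' @param l Maximum lag (default 10); must satisfy `DL > l >= 1`.
#' @param cross Append cross-covariance features (default FALSE).
#' @return Named numeric vector of length `20 * l` (plus `20*19*l` when
#'   `cross = TRUE`), with an attribute `domain_id`.
#' @export
acc_transform <- function(profile, l = 10L, cross = FALSE) {
  X <- profile$matrix
  DL <- nrow(X)
  stopifnot(ncol(X) == 20L, l >= 1L)
  if (DL <= l) {
    stop(sprintf("profile '%s' has length %d <= lag %d",
                 profile$domain_id %||% "?", DL, l))
  }
  Xc <- sweep(X, 2L, colMeans(X))
  ac <- matrix(0, nrow = 20L, ncol = l)
  for (lag in seq_len(l)) {
    ac[, lag] <- colSums(Xc[seq_len(DL - lag), , drop = FALSE] *
                           Xc[(lag + 1L):DL, , drop = FALSE]) / (DL - lag)
  }
  vals <- as.numeric(t(ac))                    # descriptor-major, lag-minor
  names(vals) <- paste0("AC_", rep(seq_len(20L), each = l), "_lag",
                        rep(seq_len(l), times = 20L))
  if (cross) {
    cc <- numeric(0)
    idx <- expand.grid(j = 1:20, k = 1:20)
    idx <- idx[idx$j != idx$k, ]
    ccv <- matrix(0, nrow = nrow(idx), ncol = l)
    for (lag in seq_len(l)) {
      a <- Xc[seq_len(DL - lag), , drop = FALSE]
      b <- Xc[(lag + 1L):DL, , drop = FALSE]
      ccv[, lag] <- vapply(seq_len(nrow(idx)), function(r) {
        sum(a[, idx$j[r]] * b[, idx$k[r]]) / (DL - lag)
      }, 0)
    }
    cc <- as.numeric(t(ccv))
    names(cc) <- paste0("CC_", rep(idx$j, each = l), "_",
                        rep(idx$k, each = l), "_lag",
                        rep(seq_len(l), times = nrow(idx)))
    vals <- c(vals, cc)
  }
  attr(vals, "domain_id") <- profile$domain_id
  vals
}

#' Fit a probability-calibration sigmoid (Platt scaling, robust variant)
#'
#' Fits A and B in `p(y=1 | f) = 1 / (1 + exp(A f + B))` by regularised
#' maximum likelihood with the prior-smoothed targets
#' `t+ = (n+ + 1)/(n+ + 2)`, `t- = 1/(n- + 2)` and a backtracking Newton
#' iteration, the numerically robust formulation of Lin, Lin & Weng.
#'
#' @param margins Numeric vector of decision values f.
#' @param labels Logical (or 0/1) vector, TRUE = positive.
#' @param max_iter,min_step,sigma Newton controls.
#' @return List with elements `A`, `B`, `converged`, `iterations`.
#' @export
fit_sigmoid <- function(margins, labels, max_iter = 100L,
                        min_step = 1e-10, sigma = 1e-12) {
  labels <- as.logical(labels)
  stopifnot(length(margins) == length(labels), any(labels), any(!labels))
  n_pos <- sum(labels); n_neg <- sum(!labels)
  hi <- (n_pos + 1) / (n_pos + 2)
  lo <- 1 / (n_neg + 2)
  t <- ifelse(labels, hi, lo)
  f <- margins

  fval_of <- function(A, B) {
    fApB <- f * A + B
    # stable cross-entropy: t*log(p) + (1-t)*log(1-p)
    sum(ifelse(fApB >= 0,
               t * fApB + log1p(exp(-fApB)),
               (t - 1) * fApB + log1p(exp(fApB))))
  }

  A <- 0
  B <- log((n_neg + 1) / (n_pos + 1))
  fval <- fval_of(A, B)
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    fApB <- f * A + B
    p <- ifelse(fApB >= 0, exp(-fApB) / (1 + exp(-fApB)),
                1 / (1 + exp(fApB)))
    q <- 1 - p
    d2 <- p * q
    h11 <- sigma + sum(f * f * d2)
    h22 <- sigma + sum(d2)
    h21 <- sum(f * d2)
    d1 <- t - p
    g1 <- sum(f * d1)
    g2 <- sum(d1)
    if (abs(g1) < 1e-5 && abs(g2) < 1e-5) { converged <- TRUE; break }
    det <- h11 * h22 - h21 * h21
    dA <- -(h22 * g1 - h21 * g2) / det
    dB <- -(-h21 * g1 + h11 * g2) / det
    gd <- g1 * dA + g2 * dB
    stepsize <- 1
    ok <- FALSE
    while (stepsize >= min_step) {
      newA <- A + stepsize * dA
      newB <- B + stepsize * dB
      newf <- fval_of(newA, newB)
      if (newf < fval + 1e-4 * stepsize * gd) {
        A <- newA; B <- newB; fval <- newf; ok <- TRUE; break
      }
      stepsize <- stepsize / 2
    }
    if (!ok) break                       # line search failed
  }
  list(A = A, B = B, converged = converged || it < max_iter,
       iterations = it)
}

#' Evaluate the calibrated sigmoid
#' @param margin Numeric decision values.
#' @param params List with `A`, `B` (from [fit_sigmoid()]).
#' @return Probabilities in (0, 1).
#' @export
sigmoid_probability <- function(margin, params) {
  fApB <- params$A * margin + params$B
  ifelse(fApB >= 0, exp(-fApB) / (1 + exp(-fApB)), 1 / (1 + exp(fApB)))
}

#' Train a calibrated per-term classifier
#'
#' Fits a binary SVM for one GO term over auto-covariance feature vectors,
#' then calibrates raw margins to probabilities with [fit_sigmoid()] fitted
#' on out-of-fold margins (stratified k-fold) to avoid optimistic
#' calibration. Features are standardised by training-set mean/sd.
#'
#' @param features Numeric matrix, one row per domain (rownames = domain
#'   ids), columns = AC features.
#' @param labels Logical vector (length nrow(features)), TRUE where the
#'   domain carries the term.
#' @param term GO accession being modelled (stored on the result).
#' @param min_pos,min_neg Class floors (default 10/10); below either the
#'   term is skipped and `NULL` returned with a message.
#' @param kernel SVM kernel, `"linear"` (default) or `"radial"`.
#' @param folds Calibration folds (default 5).
#' @param cost SVM cost parameter (default 1).
#' @param seed RNG seed for fold assignment.
#' @return List of class `term_classifier` (svm fit, standardisation,
#'   sigmoid params, term), or NULL when the class floor is unmet.
#' @export
train_term_classifier <- function(features, labels, term = NA_character_,
                                  min_pos = 10L, min_neg = 10L,
                                  kernel = "linear", folds = 5L,
                                  cost = 1, seed = 1L) {
  labels <- as.logical(labels)
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos < min_pos || n_neg < min_neg) {
    message(sprintf("term %s skipped: %d positives / %d negatives (floor %d/%d)",
                    term, n_pos, n_neg, min_pos, min_neg))
    return(NULL)
  }
  ctr <- colMeans(features)
  scl <- apply(features, 2L, stats::sd)
  scl[scl == 0 | !is.finite(scl)] <- 1
  xs <- sweep(sweep(features, 2L, ctr), 2L, scl, "/")
  y <- factor(ifelse(labels, "pos", "neg"), levels = c("neg", "pos"))

  fit_svm <- function(x, yy) {
    e1071::svm(x, yy, kernel = kernel, cost = cost, scale = FALSE,
               probability = FALSE)
  }
  margin_of <- function(model, x, ytrain, xtrain) {
    dec <- attr(stats::predict(model, x, decision.values = TRUE),
                "decision.values")[, 1]
    dtr <- attr(stats::predict(model, xtrain, decision.values = TRUE),
                "decision.values")[, 1]
    if (mean(dtr[ytrain == "pos"]) < mean(dtr[ytrain == "neg"])) dec <- -dec
    dec
  }

  # stratified out-of-fold margins for calibration
  set.seed(seed)
  fold <- integer(length(y))
  fold[labels] <- sample(rep_len(seq_len(folds), n_pos))
  fold[!labels] <- sample(rep_len(seq_len(folds), n_neg))
  oof <- numeric(length(y))
  for (k in seq_len(folds)) {
    tr <- fold != k
    if (length(unique(y[tr])) < 2L) next
    mk <- fit_svm(xs[tr, , drop = FALSE], y[tr])
    oof[!tr] <- margin_of(mk, xs[!tr, , drop = FALSE], y[tr],
                          xs[tr, , drop = FALSE])
  }
  sig <- fit_sigmoid(oof, labels)

  model <- fit_svm(xs, y)
  dtr <- attr(stats::predict(model, xs, decision.values = TRUE),
              "decision.values")[, 1]
  flip <- mean(dtr[labels]) < mean(dtr[!labels])
  structure(list(term = term, model = model, center = ctr, scale = scl,
                 flip = flip, sigmoid = sig,
                 train_accuracy = mean(((if (flip) -dtr else dtr) > 0) == labels)),
            class = "term_classifier")
}

#' Margin of a trained term classifier on new feature rows
#' @param object A `term_classifier`.
#' @param features Numeric matrix of AC features (rows = domains).
#' @return Numeric margins, oriented so higher = more likely positive.
#' @export
classifier_margin <- function(object, features) {
  xs <- sweep(sweep(features, 2L, object$center), 2L, object$scale, "/")
  dec <- attr(stats::predict(object$model, xs, decision.values = TRUE),
              "decision.values")[, 1]
  if (object$flip) -dec else dec
}

#' Train PSSM-channel classifiers for a set of GO terms
#'
#' @param features Numeric matrix (rows = domain ids) of AC vectors.
#' @param gold True-path-propagated `annotation_set` over the same domains.
#' @param onto A `go_ontology`.
#' @param terms Terms to model; default: every term with enough positives
#'   and negatives among the feature domains.
#' @param min_pos,min_neg,kernel,folds,cost,seed Passed to
#'   [train_term_classifier()].
#' @return Object of class `pssm_model_set`: named list of
#'   `term_classifier`s plus the skipped-term log.
#' @export
train_pssm_models <- function(features, gold, onto, terms = NULL,
                              min_pos = 10L, min_neg = 10L,
                              kernel = "linear", folds = 5L, cost = 1,
                              seed = 1L) {
  doms <- rownames(features)
  stopifnot(!is.null(doms))
  gold_df <- as.data.frame(gold)
  gold_df <- gold_df[gold_df$entity %in% doms, , drop = FALSE]
  if (is.null(terms)) {
    cnt <- table(gold_df$term)
    terms <- names(cnt)[cnt >= min_pos & (length(doms) - cnt) >= min_neg]
    terms <- setdiff(terms, unname(onto$roots))
  }
  models <- list(); skipped <- character(0)
  for (g in terms) {
    lab <- doms %in% gold_df$entity[gold_df$term == g]
    cl <- train_term_classifier(features, lab, term = g,
                                min_pos = min_pos, min_neg = min_neg,
                                kernel = kernel, folds = folds,
                                cost = cost, seed = seed)
    if (is.null(cl)) skipped <- c(skipped, g) else models[[g]] <- cl
  }
  structure(list(models = models, skipped = skipped,
                 config = list(min_pos = min_pos, min_neg = min_neg,
                               kernel = kernel, folds = folds, cost = cost,
                               seed = seed)),
            class = "pssm_model_set")
}

#' PSSM-channel GO scores P3(g)
#'
#' Applies every calibrated term classifier to the feature rows and maps
#' margins through the fitted sigmoid:
#' `P3(g) = 1 / (1 + exp(A f(g) + B))`.
#'
#' @param features Numeric matrix of AC vectors (rownames = domain ids).
#' @param models A `pssm_model_set`.
#' @param onto A `go_ontology` (for aspect lookup).
#' @return data.frame with columns `method` ("PSSM"), `domain_id`, `term`,
#'   `aspect`, `score`.
#' @export
score_pssm <- function(features, models, onto) {
  empty <- data.frame(method = character(0), domain_id = character(0),
                      term = character(0), aspect = character(0),
                      score = numeric(0))
  if (!length(models$models) || nrow(features) == 0L) return(empty)
  out <- lapply(models$models, function(cl) {
    if (ncol(features) != length(cl$center)) {
      stop(sprintf("feature length %d does not match model dimension %d",
                   ncol(features), length(cl$center)))
    }
    f <- classifier_margin(cl, features)
    data.frame(method = "PSSM", domain_id = rownames(features),
               term = cl$term, aspect = onto$terms[cl$term, "aspect"],
               score = sigmoid_probability(f, cl$sigmoid),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out <- out[order(out$domain_id, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out
}
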