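# Canonical k-mer spectrum SVM: training, scoring, calibration, evaluation.

#' Train a k-mer spectrum SVM classifier
#'
#' Fits a linear soft-margin SVM on canonical k-mer count features
#' (positives vs negatives), using a precomputed linear kernel and the
#' kernlab C-SVC solver, then extracts the per-k-mer weight vector
#' \eqn{w} and bias \eqn{b} so that a sequence's score is
#' \eqn{s = b + \sum_i w(\mathrm{kmer}_i)} over all positions. A sigmoid
#' (Platt) calibration is fitted on the training scores so raw scores can be
#' reported as posterior probabilities.
#'
#' @param positives,negatives Character vectors of training sequences.
#' @param k Even k-mer length (default 8).
#' @param C Soft-margin cost (default 1).
#' @param seed Integer seed recorded in the model and used for any
#'   stochastic step.
#' @param calibrate Fit Platt scalars on training scores (default TRUE).
#' @return An object of class \code{kmer_model}: list with \code{k},
#'   \code{weights} (numeric, one per canonical k-mer, index column order),
#'   \code{bias}, \code{platt_a}, \code{platt_b} and \code{meta}.
#' @export
train_kmer_svm <- function(positives, negatives, k = 8L, C = 1.0, seed = 1L,
                           calibrate = TRUE) {
  if (length(positives) < 1L || length(negatives) < 1L) {
    stop("both classes must be non-empty")
  }
  index <- kmer_index(k)
  X <- feature_matrix(c(positives, negatives), index)
  y <- c(rep(1, length(positives)), rep(-1, length(negatives)))
  train_on_features(X, y, k = k, C = C, seed = seed, calibrate = calibrate)
}

# core fit on a precomputed feature matrix (rows = sequences)
train_on_features <- function(X, y, k = 8L, C = 1.0, seed = 1L,
                              calibrate = TRUE) {
  if (length(unique(sign(y))) < 2L) stop("both classes must be non-empty")
  set.seed(seed)
  K <- as.matrix(Matrix::tcrossprod(X))
  fit <- kernlab::ksvm(kernlab::as.kernelMatrix(K), factor(y, levels = c(1, -1)),
                       type = "C-svc", C = C)
  sv <- kernlab::SVindex(fit)
  alpha_y <- kernlab::coef(fit)[[1]]
  w <- as.numeric(Matrix::crossprod(X[sv, , drop = FALSE], alpha_y))
  b <- -kernlab::b(fit)
  # orient the decision function so positives score high
  s_train <- as.numeric(X %*% w) + b
  if (mean(s_train[y > 0]) < mean(s_train[y < 0])) {
    w <- -w; b <- -b; s_train <- -s_train
  }
  model <- structure(list(
    k = as.integer(k), weights = w, bias = b,
    platt_a = NA_real_, platt_b = NA_real_,
    meta = list(C = C, seed = as.integer(seed),
                n_pos = sum(y > 0), n_neg = sum(y < 0))),
    class = "kmer_model")
  if (calibrate) {
    ab <- platt_fit(s_train, y)
    model$platt_a <- ab[["A"]]
    model$platt_b <- ab[["B"]]
  }
  model
}

#' @export
print.kmer_model <- function(x, ...) {
  cat(sprintf("kmer_model: k=%d, %d canonical k-mer weights, bias=%.4g\n",
              x$k, length(x$weights), x$bias))
  cat(sprintf("  trained on %d positives / %d negatives (C=%g, seed=%d)\n",
              x$meta$n_pos, x$meta$n_neg, x$meta$C, x$meta$seed))
  if (!is.na(x$platt_a)) {
    cat(sprintf("  Platt calibration: A=%.4g, B=%.4g\n", x$platt_a, x$platt_b))
  }
  invisible(x)
}

# Platt (1999) sigmoid fit with the Lin-Weng-Hsu Newton iteration and the
# standard smoothed +1/-1 targets; returns c(A, B) for
# p = 1 / (1 + exp(A*s + B)).
platt_fit <- function(scores, labels) {
  y <- labels > 0
  n1 <- sum(y); n0 <- sum(!y)
  if (n1 == 0 || n0 == 0) stop("platt_fit needs both classes")
  hi <- (n1 + 1) / (n1 + 2)
  lo <- 1 / (n0 + 2)
  t <- ifelse(y, hi, lo)
  A <- 0; B <- log((n0 + 1) / (n1 + 1))
  fval <- function(A, B) {
    z <- A * scores + B
    # stable -sum(t*log(p) + (1-t)*log(1-p)) with p = 1/(1+exp(z))
    sum(ifelse(z >= 0, t * z + log1p(exp(-z)), (t - 1) * z + log1p(exp(z))))
  }
  f <- fval(A, B)
  for (it in 1:100) {
    z <- A * scores + B
    p <- 1 / (1 + exp(z))
    d1 <- t - p                       # dF/dz per point
    d2 <- p * (1 - p)
    g1 <- sum(scores * d1); g2 <- sum(d1)
    if (abs(g1) < 1e-10 && abs(g2) < 1e-10) break
    h11 <- sum(scores^2 * d2) + 1e-12
    h22 <- sum(d2) + 1e-12
    h21 <- sum(scores * d2)
    det <- h11 * h22 - h21^2
    dA <- -(h22 * g1 - h21 * g2) / det
    dB <- -(-h21 * g1 + h11 * g2) / det
    gd <- g1 * dA + g2 * dB
    step <- 1
    repeat {
      A2 <- A + step * dA; B2 <- B + step * dB
      f2 <- fval(A2, B2)
      if (f2 < f + 1e-4 * step * gd) { A <- A2; B <- B2; f <- f2; break }
      step <- step / 2
      if (step < 1e-10) break
    }
    if (step < 1e-10) break
  }
  c(A = A, B = B)
}

#' Score sequences with a trained model
#'
#' The score of a sequence is the bias plus the sum of the weights of the
#' canonical k-mers at every position (N-containing windows skipped); the
#' sign of the score is the predicted class.
#'
#' @param model A \code{kmer_model}.
#' @param seqs Character vector of sequences (each of length >= k).
#' @return Numeric vector of raw scores.
#' @export
score_sequences <- function(model, seqs) {
  index <- kmer_index(model$k)
  X <- feature_matrix(seqs, index)
  as.numeric(X %*% model$weights) + model$bias
}

#' Posterior probability of the positive class
#'
#' Sigmoid-calibrated probability \eqn{1 / (1 + \exp(A s + B))} for a raw
#' score \eqn{s}; requires a calibrated model.
#'
#' @param model A calibrated \code{kmer_model}.
#' @param s Numeric vector of raw scores.
#' @return Probabilities in \code{[0, 1]}.
#' @export
posterior_prob <- function(model, s) {
  if (is.na(model$platt_a) || is.na(model$platt_b)) {
    stop("model is not calibrated (platt_a/platt_b missing)")
  }
  1 / (1 + exp(model$platt_a * s + model$platt_b))
}

#' Per-k-mer weight table
#'
#' @param model A \code{kmer_model}.
#' @param top Optionally keep only the \code{top} k-mers by |weight|.
#' @return Tibble with columns \code{kmer}, \code{weight}, sorted by
#'   decreasing weight.
#' @export
weight_table <- function(model, top = NULL) {
  index <- kmer_index(model$k)
  tb <- tibble(kmer = index$kmers, weight = model$weights)
  tb <- tb[order(-tb$weight), , drop = FALSE]
  if (!is.null(top)) {
    tb <- tb[order(-abs(tb$weight)), , drop = FALSE][seq_len(top), , drop = FALSE]
  }
  tb
}

#' Write / read a k-mer model as a weight TSV
#'
#' Header comment lines carry k, bias, Platt scalars and training metadata;
#' the body is one canonical k-mer and weight per line.
#'
#' @param model A \code{kmer_model}.
#' @param path File path.
#' @return \code{path} (write) or a \code{kmer_model} (read).
#' @export
write_kmer_model <- function(model, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#k=%d\n#bias=%.17g\n#platt_a=%.17g\n#platt_b=%.17g\n#C=%g\n#seed=%d\n#n_pos=%d\n#n_neg=%d",
                     model$k, model$bias, model$platt_a, model$platt_b,
                     model$meta$C, model$meta$seed,
                     model$meta$n_pos, model$meta$n_neg), con)
  index <- kmer_index(model$k)
  utils::write.table(data.frame(kmer = index$kmers, weight = model$weights),
                     con, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_kmer_model
#' @export
read_kmer_model <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  getv <- function(key) {
    ln <- grep(paste0("^#", key, "="), hdr, value = TRUE)
    as.numeric(sub(paste0("^#", key, "="), "", ln))
  }
  body <- utils::read.table(text = lines[!grepl("^#", lines)], sep = "\t",
                            col.names = c("kmer", "weight"),
                            colClasses = c("character", "numeric"))
  k <- as.integer(getv("k"))
  index <- kmer_index(k)
  w <- body$weight[match(index$kmers, body$kmer)]
  if (anyNA(w)) stop("model file does not cover the canonical k-mer space")
  structure(list(k = k, weights = w, bias = getv("bias"),
                 platt_a = getv("platt_a"), platt_b = getv("platt_b"),
                 meta = list(C = getv("C"), seed = as.integer(getv("seed")),
                             n_pos = as.integer(getv("n_pos")),
                             n_neg = as.integer(getv("n_neg")))),
            class = "kmer_model")
}

#' ROC area under the curve
#'
#' Rank-based (Mann-Whitney) AUC: the probability that a random positive
#' outscores a random negative, with tied pairs credited one half.
#'
#' @param scores Numeric scores.
#' @param labels Logical (or 0/1) positive-class labels.
#' @return AUC in \code{[0, 1]}.
#' @export
roc_auc <- function(scores, labels) {
  y <- as.logical(labels)
  n1 <- sum(y); n0 <- sum(!y)
  if (n1 == 0 || n0 == 0) stop("need both classes for ROC AUC")
  r <- rank(scores)                    # average ranks handle ties as half-credit
  (sum(r[y]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC curve points
#'
#' FPR/TPR at every distinct score threshold (descending sweep), starting at
#' (0,0) and ending at (1,1).
#'
#' @inheritParams roc_auc
#' @return Tibble with columns \code{fpr}, \code{tpr}.
#' @export
roc_curve <- function(scores, labels) {
  y <- as.logical(labels)
  o <- order(scores, decreasing = TRUE)
  ys <- y[o]; ss <- scores[o]
  grp_end <- cumsum(rle(ss)$lengths)
  tp <- cumsum(ys)[grp_end]; fp <- cumsum(!ys)[grp_end]
  tibble(fpr = c(0, fp / sum(!y)), tpr = c(0, tp / sum(y)))
}

#' Precision-recall curve and area
#'
#' Curve points at every distinct threshold; area by right-step
#' interpolation, \eqn{\sum_j (R_j - R_{j-1}) P_j}.
#'
#' @inheritParams roc_auc
#' @return \code{prc_curve}: tibble with \code{tpr} (recall), \code{ppv}
#'   (precision); \code{prc_auc}: scalar area.
#' @export
prc_curve <- function(scores, labels) {
  y <- as.logical(labels)
  if (sum(y) == 0) stop("need positives for PRC")
  o <- order(scores, decreasing = TRUE)
  ys <- y[o]; ss <- scores[o]
  grp_end <- cumsum(rle(ss)$lengths)
  tp <- cumsum(ys)[grp_end]; fp <- cumsum(!ys)[grp_end]
  tibble(tpr = tp / sum(y), ppv = tp / (tp + fp))
}

#' @rdname prc_curve
#' @export
prc_auc <- function(scores, labels) {
  cv <- prc_curve(scores, labels)
  sum(diff(c(0, cv$tpr)) * cv$ppv)
}

#' Repeated stratified holdout evaluation
#'
#' Repeats a stratified random 80/20 split \code{n_repeats} times; trains on
#' the 80 percent, scores the held-out 20 percent, and accumulates per-repeat
#' ROC and PRC curves and areas.
#'
#' @param positives,negatives Training sequences per class.
#' @param n_repeats Number of random splits (default 5).
#' @param train_frac Training fraction (default 0.8).
#' @param k,C Passed to \code{\link{train_kmer_svm}}.
#' @param seed Integer seed; repeat r uses \code{seed + r}.
#' @return List of class \code{eval_curves} with \code{per_repeat} (tibble:
#'   repeat, roc_auc, prc_auc), \code{roc_curves}, \code{prc_curves},
#'   \code{mean_roc_auc}, \code{mean_prc_auc}.
#' @export
evaluate_repeated_holdout <- function(positives, negatives, n_repeats = 5L,
                                      train_frac = 0.8, k = 8L, C = 1.0,
                                      seed = 1L) {
  stopifnot(length(positives) >= 10L, length(negatives) >= 10L)
  index <- kmer_index(k)
  X <- rbind(feature_matrix(positives, index), feature_matrix(negatives, index))
  np <- length(positives); nn <- length(negatives)
  res <- vector("list", n_repeats)
  rocs <- vector("list", n_repeats)
  prcs <- vector("list", n_repeats)
  for (r in seq_len(n_repeats)) {
    set.seed(seed + r)
    tr_p <- sample(np, round(train_frac * np))
    tr_n <- sample(nn, round(train_frac * nn))
    tr <- c(tr_p, np + tr_n)
    model <- train_on_features(X[tr, , drop = FALSE],
                               c(rep(1, length(tr_p)), rep(-1, length(tr_n))),
                               k = k, C = C, seed = seed + r, calibrate = FALSE)
    te <- c(setdiff(seq_len(np), tr_p), np + setdiff(seq_len(nn), tr_n))
    lab <- te <= np
    s <- as.numeric(X[te, , drop = FALSE] %*% model$weights) + model$bias
    res[[r]] <- tibble(repeat_id = r, roc_auc = roc_auc(s, lab),
                       prc_auc = prc_auc(s, lab))
    rocs[[r]] <- roc_curve(s, lab)
    prcs[[r]] <- prc_curve(s, lab)
  }
  per <- do.call(rbind, res)
  structure(list(per_repeat = per, roc_curves = rocs, prc_curves = prcs,
                 mean_roc_auc = mean(per$roc_auc),
                 mean_prc_auc = mean(per$prc_auc)),
            class = "eval_curves")
}

#' @export
print.eval_curves <- function(x, ...) {
  cat(sprintf("repeated holdout over %d splits: mean ROC AUC %.3f, mean PRC AUC %.3f\n",
              nrow(x$per_repeat), x$mean_roc_auc, x$mean_prc_auc))
  print(x$per_repeat)
  invisible(x)
}
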