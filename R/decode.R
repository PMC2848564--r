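#' Decimated ERP feature vectors
#'
#' For each selected channel the 80 post-baseline samples (100 Hz) are
#' decimated by taking the mean of five consecutive samples, leaving 16
#' values per channel; channels are concatenated channel-major. With the
#' standard 20 selected channels this yields the 320-dimensional feature
#' vector. Baseline samples are excluded.
#'
#' @param epochs `bci_epochs` at 100 Hz.
#' @param channels character vector of channel labels (order preserved;
#'   duplicates allowed, a channel qualifying for both selection lists
#'   contributes its features twice).
#' @param block decimation block length.
#' @return matrix (epochs x features); attribute `feature_channels` maps
#'   columns to channel labels.
#' @export
extract_features <- function(epochs, channels, block = 5) {
  ch_idx <- match(channels, epochs$channels$label)
  if (anyNA(ch_idx)) stop("unknown channel label(s): ",
                          paste(channels[is.na(ch_idx)], collapse = ", "))
  nt <- dim(epochs$data)[3]
  post <- (epochs$n_baseline + 1L):nt
  if (length(post) %% block != 0L) {
    stop("post-baseline length (", length(post),
         ") is not divisible by the decimation block (", block, ")")
  }
  n_dec <- length(post) %/% block
  grp <- rep(seq_len(n_dec), each = block)
  n_ep <- dim(epochs$data)[1]
  out <- matrix(NA_real_, n_ep, length(ch_idx) * n_dec)
  for (j in seq_along(ch_idx)) {
    m <- epochs$data[, ch_idx[j], post, drop = FALSE]
    dim(m) <- c(n_ep, length(post))
    dec <- sapply(seq_len(n_dec), function(g) {
      rowMeans(m[, grp == g, drop = FALSE])
    })
    if (n_ep == 1L) dec <- matrix(dec, nrow = 1L)
    out[, (j - 1L) * n_dec + seq_len(n_dec)] <- dec
  }
  attr(out, "feature_channels") <- rep(channels, each = n_dec)
  out
}

#' Per-dimension standardization fitted on the training set
#'
#' Estimates mean and standard deviation of every feature dimension on the
#' training subtrials; the stored vector is later applied unchanged to test
#' subtrials. Degenerate (zero-variance) dimensions get SD 1 and are
#' flagged with a warning.
#'
#' @param train_features matrix (subtrials x dims), at least two rows.
#' @return list of class `norm_vector` with `mean`, `sd`, `degenerate`.
#' @export
fit_normalization <- function(train_features) {
  if (nrow(train_features) < 2L) stop("need at least 2 training subtrials")
  mu <- colMeans(train_features)
  # population (1/n) standard deviation: two training points map to -1/+1
  sd <- sqrt(colMeans(sweep(train_features, 2, mu)^2))
  degenerate <- sd == 0 | !is.finite(sd)
  if (any(degenerate)) {
    warning(sum(degenerate), " zero-variance feature dimension(s); SD set to 1")
    sd[degenerate] <- 1
  }
  structure(list(mean = mu, sd = sd, degenerate = degenerate),
            class = "norm_vector")
}

#' @rdname fit_normalization
#' @param features matrix to transform.
#' @param nv a stored `norm_vector`.
#' @export
apply_normalization <- function(features, nv) {
  sweep(sweep(features, 2, nv$mean), 2, nv$sd, "/")
}

#' Shrinkage covariance estimate (Ledoit-Wolf, scaled-identity target)
#'
#' Counterbalances the systematic error of the empirical covariance in the
#' small-sample / high-dimension regime by shrinking towards `nu * I` with
#' `nu = trace(S)/d`: `Sigma = (1 - gamma) S + gamma nu I`. The intensity
#' `gamma` is the analytic optimum (ratio of the estimated dispersion of the
#' sample covariance entries to the squared distance between `S` and the
#' target), clipped to `[0, 1]`. `S` is the unbiased (`n - 1`) empirical
#' covariance.
#'
#' @param X data matrix (rows = observations), `n >= 2`.
#' @param gamma fixed intensity in `[0, 1]`, or `NULL` for the analytic
#'   optimum.
#' @return list: `sigma`, `gamma`, `nu`, `S`.
#' @export
shrinkage_covariance <- function(X, gamma = NULL) {
  if (nrow(X) < 2L) stop("need at least 2 rows")
  if (!is.null(gamma)) stopifnot(gamma >= 0, gamma <= 1)
  Xc <- sweep(X, 2, colMeans(X))
  out <- shrinkage_covariance_centered(Xc, gamma)
  out$S <- crossprod(Xc) / (nrow(X) - 1)
  out
}

#' Train a shrinkage-regularized Fisher Discriminant
#'
#' Binary linear discriminant on normalized features with the pooled
#' within-class covariance replaced by its shrinkage estimate:
#' `w = Sigma^-1 (mu_nontarget - mu_target)`, so that target subtrials
#' project to negative scores. The bias places the decision threshold midway
#' between the projected class means, `b = -w . (mu_t + mu_nt) / 2`; it
#' affects only the binary classification score, not the multi-class argmin.
#'
#' @param train_features matrix (subtrials x dims).
#' @param is_target logical vector, both classes present.
#' @param gamma shrinkage intensity; `NULL` (default) for analytic.
#' @return list of class `fd_model`: `w`, `b`, `gamma`, plus `channels` and
#'   `normalization` slots filled by [crossvalidate()].
#' @export
train_fd <- function(train_features, is_target, gamma = NULL) {
  stopifnot(length(is_target) == nrow(train_features))
  if (!any(is_target) || all(is_target)) stop("both classes must be present")
  mu_t <- colMeans(train_features[is_target, , drop = FALSE])
  mu_n <- colMeans(train_features[!is_target, , drop = FALSE])
  Xw <- rbind(
    sweep(train_features[is_target, , drop = FALSE], 2, mu_t),
    sweep(train_features[!is_target, , drop = FALSE], 2, mu_n)
  )
  cov <- shrinkage_covariance_centered(Xw, gamma)
  w <- solve(cov$sigma, mu_n - mu_t)
  b <- -sum(w * (mu_t + mu_n)) / 2
  structure(list(w = w, b = b, gamma = cov$gamma, nu = cov$nu,
                 mu_target = mu_t, mu_nontarget = mu_n,
                 channels = NULL, normalization = NULL),
            class = "fd_model")
}

# Shrinkage estimate for data already centered per class (rows have mean
# ~0 by construction; no further centering so the pooled scatter is kept).
shrinkage_covariance_centered <- function(Xc, gamma = NULL) {
  n <- nrow(Xc)
  d <- ncol(Xc)
  S_mle <- crossprod(Xc) / n
  nu_mle <- mean(diag(S_mle))
  if (is.null(gamma)) {
    d2 <- sum((S_mle - diag(nu_mle, d))^2)
    if (d2 <= .Machine$double.eps) {
      gamma <- 0
    } else {
      sq <- rowSums(Xc^2)
      quad <- rowSums((Xc %*% S_mle) * Xc)
      b2 <- (sum(sq^2) - 2 * sum(quad) + n * sum(S_mle^2)) / n^2
      gamma <- min(b2 / d2, 1)
    }
  }
  S <- crossprod(Xc) / (n - 1)
  nu <- mean(diag(S))
  list(sigma = (1 - gamma) * S + diag(gamma * nu, d), gamma = gamma, nu = nu)
}

#' @rdname train_fd
#' @param object an `fd_model`.
#' @param features matrix of (normalized) feature vectors.
#' @param ... unused.
#' @return numeric scores; negative favours the target class.
#' @export
predict.fd_model <- function(object, features, ...) {
  drop(features %*% object$w + object$b)
}

#' Binary classification summary
#'
#' A subtrial is predicted target iff its classifier score is negative.
#' Because non-targets outnumber targets 4:1 in the 5-class conditions, the
#' all-non-target predictor already scores 80%; the target-only score
#' exposes such degenerate behaviour.
#'
#' @param scores classifier outputs.
#' @param is_target true labels.
#' @return list: `classification_pct` (all subtrials), `target_pct`
#'   (target subtrials only), `n`.
#' @export
classification_summary <- function(scores, is_target) {
  pred_target <- scores < 0
  list(
    classification_pct = 100 * mean(pred_target == is_target),
    target_pct = if (any(is_target)) 100 * mean(pred_target[is_target]) else NA_real_,
    n = length(scores)
  )
}

#' Chronological k-fold cross-validation of the decoding chain
#'
#' Splits the trials into `k` contiguous chronological blocks (fold
#' boundaries never cut inside a trial, so a trial's subtrials cannot
#' straddle train and test). Within each fold, channel selection (via the
#' training-set ROC map), feature normalization and FD training use the
#' k - 1 training blocks only; every unmasked subtrial is scored exactly
#' once, by the fold in which it is test data. Masked (artifact) subtrials
#' are excluded from training and scoring but retain their timeline slot.
#'
#' @param epochs a `bci_epochs` object at 100 Hz with rejection applied.
#' @param k number of folds.
#' @param n_pos,n_neg channel-selection counts.
#' @param gamma shrinkage intensity (`NULL` = analytic).
#' @return list of class `cv_result`: `scores` (data.frame with one row per
#'   subtrial: trial/iteration/direction labels, `fold`, `score`, `masked`),
#'   `summary` (from [classification_summary()]), `models`, `channels`
#'   (per-fold selections), `skipped_folds`.
#' @export
crossvalidate <- function(epochs, k = 10, n_pos = 10, n_neg = 10, gamma = NULL) {
  info <- epochs$info
  trials <- unique(info$trial_id)  # chronological order of appearance
  k <- min(k, length(trials))
  trial_fold <- setNames(ceiling(seq_along(trials) * k / length(trials)), trials)
  fold <- trial_fold[as.character(info$trial_id)]

  scores <- rep(NA_real_, nrow(info))
  models <- vector("list", k)
  chans <- vector("list", k)
  skipped <- integer(0)
  for (f in seq_len(k)) {
    tr <- !epochs$artifact & fold != f
    te <- !epochs$artifact & fold == f
    if (!any(te)) next
    if (length(unique(info$is_target[tr])) < 2L) {
      warning("fold ", f, " skipped: a class is absent from its training set")
      skipped <- c(skipped, f)
      next
    }
    rmap <- channelwise_roc(epochs, use = tr)
    sel <- select_channels(rmap, n_pos = n_pos, n_neg = n_neg)
    Xtr <- extract_features(epochs, sel$channels)[tr, , drop = FALSE]
    nv <- fit_normalization(Xtr)
    model <- train_fd(apply_normalization(Xtr, nv), info$is_target[tr],
                      gamma = gamma)
    model$channels <- sel$channels
    model$normalization <- nv
    Xte <- extract_features(epochs, sel$channels)[te, , drop = FALSE]
    scores[te] <- predict(model, apply_normalization(Xte, nv))
    models[[f]] <- model
    chans[[f]] <- sel
  }
  res <- data.frame(info, fold = unname(fold), score = scores,
                    masked = epochs$artifact)
  ok <- !res$masked & !is.na(res$score)
  structure(list(
    scores = res,
    summary = classification_summary(res$score[ok], res$is_target[ok]),
    models = models,
    channels = chans,
    skipped_folds = skipped,
    k = k
  ), class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %d folds, %d subtrials (%d masked); classification %.2f%%, target score %.2f%%\n",
              x$k, nrow(x$scores), sum(x$scores$masked),
              x$summary$classification_pct, x$summary$target_pct))
  invisible(x)
}

#' Dump a trained FD model as structured text (YAML)
#'
#' Serializes the selected channels, normalization vector, weights, bias
#' and shrinkage intensity so a fitted fold can be inspected or re-applied.
#'
#' @param model an `fd_model`.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_fd_model <- function(model, path) {
  yaml::write_yaml(list(
    channels = model$channels,
    gamma = model$gamma,
    bias = model$b,
    weights = as.numeric(model$w),
    normalization = list(mean = as.numeric(model$normalization$mean),
                         sd = as.numeric(model$normalization$sd))
  ), path)
  invisible(path)
}
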