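test_that("feature decimation takes means of five consecutive samples", {
  ep <- make_epochs(n_trials = 1, n_directions = 2, n_iterations = 1,
                    noise_sd = 0)
  # plant a known ramp 1..80 on channel C1 of epoch 1, constants elsewhere
  ep$data[1, , ] <- 5
  ep$data[1, 3, 16:95] <- 1:80
  X <- extract_features(ep, c("C1", "P1"))
  expect_equal(ncol(X), 32)
  expect_equal(X[1, 1:16], seq(3, 78, by = 5))   # means of 1:5, 6:10, ...
  expect_equal(X[1, 17:32], rep(5, 16))          # constant channel
  expect_equal(attr(X, "feature_channels"),
               rep(c("C1", "P1"), each = 16))
  # 20 channels -> 320 dimensions
  mont <- data.frame(label = sprintf("c%d", 1:20), role = "central")
  ep20 <- make_epochs(n_trials = 1, n_directions = 2, n_iterations = 1,
                      montage = mont)
  expect_equal(ncol(extract_features(ep20, mont$label)), 320)
  expect_error(extract_features(ep, "nope"), "unknown channel")
  expect_error(extract_features(ep, "C1", block = 7), "divisible")
})

test_that("normalization standardizes training data and transfers to test", {
  X <- rbind(c(0, 10), c(2, 14))
  nv <- fit_normalization(X)
  expect_equal(apply_normalization(X, nv),
               rbind(c(-1, -1), c(1, 1)), ignore_attr = TRUE)
  # the stored vector (not a re-estimate) transforms the test set
  expect_equal(apply_normalization(rbind(c(1, 12)), nv),
               rbind(c(0, 0)), ignore_attr = TRUE)
  expect_warning(nv0 <- fit_normalization(rbind(c(1, 5), c(1, 7))),
                 "zero-variance")
  expect_equal(nv0$sd[1], 1)
  expect_error(fit_normalization(rbind(c(1, 2))), "at least 2")
})

test_that("shrinkage intensity shrinks to zero with growing sample size", {
  set.seed(7)
  d <- 12
  A <- matrix(rnorm(d * d), d)
  sigma_true <- crossprod(A) / d
  draw <- function(n) matrix(rnorm(n * d), n) %*% chol(sigma_true)
  g_small <- shrinkage_covariance(draw(max(2, d / 2)))$gamma
  g_large <- shrinkage_covariance(draw(10 * d))$gamma
  expect_lt(g_large, g_small)
  expect_true(g_small >= 0 && g_small <= 1)
})

test_that("shrinkage limits behave: gamma=1 gives nu*I, d=1 is untouched", {
  set.seed(8)
  X <- matrix(rnorm(60), 20, 3)
  cv1 <- shrinkage_covariance(X, gamma = 1)
  expect_equal(cv1$sigma, diag(cv1$nu, 3))
  x1 <- matrix(rnorm(20), 20, 1)
  for (g in c(0, 0.3, 1)) {
    expect_equal(shrinkage_covariance(x1, gamma = g)$sigma[1, 1], var(drop(x1)))
  }
  expect_error(shrinkage_covariance(X[1, , drop = FALSE]), "at least 2")
})

test_that("FD separates well-separated clouds and matches the classical rule", {
  set.seed(9)
  n <- 120; d <- 6
  Xt <- matrix(rnorm(n * d), n) + matrix(rep(c(8, rep(0, d - 1)), each = n), n)
  Xn <- matrix(rnorm(n * d), n)
  X <- rbind(Xt, Xn)
  y <- rep(c(TRUE, FALSE), each = n)
  model <- train_fd(X, y)
  # held-out points from the same clouds are classified perfectly
  Xte <- rbind(matrix(rnorm(40 * d), 40) + 8 * diag(d)[rep(1, 40), ],
               matrix(rnorm(40 * d), 40))
  sc <- predict(model, Xte)
  expect_true(all(sc[1:40] < 0))   # targets negative by convention
  expect_true(all(sc[41:80] > 0))
  # gamma = 0 reproduces the classical Fisher direction
  m0 <- train_fd(X, y, gamma = 0)
  mu_t <- colMeans(Xt); mu_n <- colMeans(Xn)
  Sw <- (crossprod(sweep(Xt, 2, mu_t)) + crossprod(sweep(Xn, 2, mu_n))) / (2 * n - 1)
  w_ref <- solve(Sw, mu_n - mu_t)
  cosine <- sum(m0$w * w_ref) / sqrt(sum(m0$w^2) * sum(w_ref^2))
  expect_gte(cosine, 0.999)
})

test_that("swapping the class means negates the weight vector", {
  set.seed(10)
  X <- matrix(rnorm(200), 50, 4)
  y <- rep(c(TRUE, FALSE), 25)
  m1 <- train_fd(X, y, gamma = 0.2)
  m2 <- train_fd(X, !y, gamma = 0.2)
  expect_equal(m2$w, -m1$w)
  expect_error(train_fd(X, rep(TRUE, 50)), "both classes")
})

test_that("the all-non-target predictor scores 80% on a 1:4 class ratio", {
  is_target <- rep(c(TRUE, FALSE, FALSE, FALSE, FALSE), 40)
  scores <- rep(1, 200)  # positive scores = non-target predictions
  s <- classification_summary(scores, is_target)
  expect_equal(s$classification_pct, 80)
  expect_equal(s$target_pct, 0)
})

test_that("chronological folds are contiguous trial blocks, each tested once", {
  ep <- make_epochs(n_trials = 10, n_directions = 5, n_iterations = 2,
                    noise_sd = 1)
  cv <- suppressWarnings(crossvalidate(ep, k = 10, n_pos = 3, n_neg = 3))
  df <- cv$scores
  expect_equal(sort(unique(df$fold)), 1:10)
  # folds are contiguous in time and never split a trial
  expect_true(all(diff(df$fold[order(df$onset_ms)]) >= 0))
  expect_true(all(vapply(split(df$fold, df$trial_id),
                         function(f) length(unique(f)) == 1L, TRUE)))
  # every unmasked subtrial scored exactly once
  expect_true(all(!is.na(df$score[!df$masked])))
})

test_that("masked subtrials are excluded from scoring but keep their slot", {
  ep <- make_epochs(n_trials = 6, n_directions = 5, n_iterations = 2)
  ep$artifact[c(3, 17, 40)] <- TRUE
  cv <- suppressWarnings(crossvalidate(ep, k = 3, n_pos = 3, n_neg = 3))
  expect_true(all(is.na(cv$scores$score[c(3, 17, 40)])))
  expect_equal(nrow(cv$scores), 60)
})

test_that("no training leakage: a fold's model ignores its own test block", {
  sig <- function(is_target) {
    m <- matrix(0, 7, 95)
    if (is_target) m[5, 40:60] <- -3
    m
  }
  ep <- make_epochs(n_trials = 8, n_directions = 4, n_iterations = 2,
                    noise_sd = 1, signal_fun = sig)
  cv1 <- suppressWarnings(crossvalidate(ep, k = 4, n_pos = 3, n_neg = 3))
  # corrupt the data of fold 2's trials only
  fold_of <- vapply(split(cv1$scores$fold, cv1$scores$trial_id), unique, 1)
  ep2 <- ep
  idx <- cv1$scores$fold == 2
  set.seed(99)
  ep2$data[idx, , ] <- rnorm(sum(idx) * 7 * 95, 0, 5)
  cv2 <- suppressWarnings(crossvalidate(ep2, k = 4, n_pos = 3, n_neg = 3))
  # fold 2's model was trained on folds 1,3,4 and is unchanged ...
  expect_equal(cv2$models[[2]]$w, cv1$models[[2]]$w)
  expect_equal(cv2$models[[2]]$normalization$mean,
               cv1$models[[2]]$normalization$mean)
  # ... whereas models trained on data including fold 2 differ
  expect_false(isTRUE(all.equal(cv2$models[[1]]$w, cv1$models[[1]]$w)))
})

test_that("decoding accuracy rises with template amplitude", {
  run_at <- function(amp) {
    s <- generate_sequence("C300", n_trials = 4, seed = 41)
    rec <- simulate_recording(
      s, erp_templates(p300_amplitude = amp, n2_amplitude = -amp / 2),
      noise_spec(background_sd = 12, blink_rate = 0),
      montage = default_montage(), seed = 42)
    cv <- crossvalidate(preprocess(rec), k = 4)
    cv$summary$classification_pct
  }
  acc <- vapply(c(0, 4, 10, 18), run_at, 1)
  # monotone within a 2-point tolerance
  expect_true(all(diff(acc) > -2))
  expect_gt(acc[4], acc[1] + 5)
})

test_that("high-SNR synthetic decoding beats the 80% chance level", {
  s <- generate_sequence("C300", n_trials = 5, seed = 51)
  rec <- simulate_recording(s, erp_templates(),
                            noise_spec(background_sd = 10, blink_rate = 0),
                            montage = default_montage(), seed = 52)
  cv <- crossvalidate(preprocess(rec), k = 5)
  expect_gt(cv$summary$classification_pct, 80)
  expect_gt(cv$summary$target_pct, 50)
})
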