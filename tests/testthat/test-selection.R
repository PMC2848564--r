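test_that("target selection takes the argmin of averaged scores", {
  m <- matrix(c(-2, 1, 0, 3, 2), 5, 1)
  expect_equal(select_target(m, 1), 1)
  # missing subtrials: averaging over the available entries only
  m2 <- matrix(0.5, 5, 3)
  m2[2, ] <- c(-5, NA, -4)
  expect_equal(mean(m2[2, 1:3], na.rm = TRUE), -4.5)
  expect_equal(select_target(m2, 3), 2)
  # ties resolve to the lowest direction index
  m3 <- matrix(c(-1, -1, 0, 0, 0), 5, 1)
  expect_equal(select_target(m3, 1), 1)
  # directions with no valid score are excluded from the argmin
  m4 <- matrix(c(NA, NA, 1, 2, 3), 5, 1)
  expect_equal(select_target(m4, 1), 3)
  # fully empty trial is unselectable
  expect_true(is.na(select_target(matrix(NA_real_, 5, 2), 2)))
})

test_that("selection curve counts correct trials per iteration number", {
  # target always strictly minimal -> P(k) = 1 everywhere
  trials <- lapply(1:10, function(i) {
    m <- matrix(1, 5, 15); m[3, ] <- -1
    list(scores = m, target = 3)
  })
  cv <- selection_curve(trials)
  expect_equal(cv$accuracy, rep(1, 15))
  # 36 of 40 correct at k = 11 -> 90%
  trials2 <- lapply(1:40, function(i) {
    m <- matrix(1, 5, 11)
    m[if (i <= 36) 2 else 4, ] <- -1
    list(scores = m, target = 2)
  })
  expect_equal(selection_curve(trials2)$accuracy[11], 0.9)
})

test_that("selection under permuted scores converges to chance 1/N", {
  set.seed(104)
  trials <- lapply(1:2000, function(i) {
    list(scores = matrix(rnorm(5 * 15), 5, 15), target = sample(5, 1))
  })
  cv <- selection_curve(trials)
  expect_true(all(abs(cv$accuracy - 0.2) < 0.03))
})

test_that("bits/selection follows the Wolpaw formula", {
  expect_equal(itr_bits_per_selection(5, 1), log2(5))
  expect_equal(itr_bits_per_selection(5, 0.2), 0)
  expect_equal(itr_bits_per_selection(5, 0.9), 1.652932, tolerance = 1e-6)
  expect_equal(itr_bits_per_selection(2, 0.5), 0)
  expect_error(itr_bits_per_selection(1, 0.5), "at least 2")
  # strictly increasing in P above chance, zero at chance
  P <- seq(0.2, 1, by = 0.01)
  R <- itr_bits_per_selection(5, P)
  expect_true(all(diff(R) > 0))
  expect_equal(R[1], 0)
})

test_that("bits/minute uses the k*N*ISI timing model", {
  B <- itr_bits_per_minute(itr_bits_per_selection(5, 0.9), 15, 5, 300)
  expect_equal(round_half_up(B, 2), 4.41)
  B2 <- itr_bits_per_minute(itr_bits_per_selection(5, 0.94), 11, 5, 300)
  expect_equal(B2, 6.8163, tolerance = 1e-4)
  expect_equal(itr_bits_per_minute(0, 5, 5, 300), 0)
  # B scales as 1/k and 1/ISI at fixed accuracy
  R <- itr_bits_per_selection(5, 0.9)
  k <- 1:15
  Bk <- itr_bits_per_minute(R, k, 5, 300)
  expect_equal(Bk, Bk[1] / k)
  expect_equal(itr_bits_per_minute(R, 5, 5, 600),
               itr_bits_per_minute(R, 5, 5, 300) / 2)
})

test_that("thresholded maximum ITR honours constraint, ties and absence", {
  # hand-computed: R(.85)/4 = 0.353 beats every other eligible k under the
  # 70% constraint; R(.95)/7 = 0.277 wins under the 90% constraint
  curve <- structure(data.frame(k = 1:15,
                                accuracy = c(0.5, 0.6, 0.6, 0.85, 0.85, 0.88,
                                             rep(0.95, 9)),
                                n_trials = 20),
                     class = c("selection_curve", "data.frame"))
  m70 <- max_itr_thresholded(curve, 0.70, N = 5, isi_ms = 300)
  expect_equal(m70$k, 4)
  m90 <- max_itr_thresholded(curve, 0.90, N = 5, isi_ms = 300)
  expect_equal(m90$k, 7)
  # constraint never met -> absent
  low <- curve; low$accuracy <- rep(0.5, 15)
  m <- max_itr_thresholded(low, 0.70, N = 5, isi_ms = 300)
  expect_true(is.na(m$bits_per_minute) && is.na(m$k))
  # perfect curve: k = 1 wins since B decreases in k at fixed P
  perfect <- curve; perfect$accuracy <- rep(1, 15)
  expect_equal(max_itr_thresholded(perfect, 0.9, 5, 300)$k, 1)
})

test_that("key-response error excludes true negatives", {
  expect_equal(round_half_up(key_response_error(72, 3, 0), 1), 4)
  expect_equal(round_half_up(key_response_error(88, 17, 8), 1), 22.1)
  expect_equal(key_response_error(0, 0, 10), 100)
})

test_that("key presses are scored into hits, false alarms and misses", {
  s <- generate_sequence("Cr", n_trials = 2, seed = 21)
  # perfect subject
  r <- simulate_key_responses(s, key_response_model(p_hit = 1, p_neighbor = 0,
                                                    p_other = 0), seed = 22)
  sc <- score_key_responses(s, r)
  expect_equal(sc$counts$hits, sum(s$is_target))
  expect_equal(sc$counts$false_alarms, 0)
  expect_equal(sc$counts$misses, 0)
  expect_equal(sc$counts$error_pct, 0)
  expect_equal(sum(sc$per_direction$hits), sc$counts$hits)
  # silent subject: all targets missed, error 100%
  sc0 <- score_key_responses(s, r[0, ])
  expect_equal(sc0$counts$misses, sum(s$is_target))
  expect_equal(sc0$counts$error_pct, 100)
  # a press on a non-target becomes a false alarm on that direction
  nt <- which(!s$is_target)[1]
  r1 <- data.frame(time_ms = s$onset_ms[nt] + 400, stimulus_index = nt,
                   direction = s$direction[nt])
  sc1 <- score_key_responses(s, r1)
  expect_equal(sc1$counts$false_alarms, 1)
  expect_equal(sc1$confusions$response_direction, s$direction[nt])
  # reaction times of hits are recovered
  expect_equal(sc$counts$rt_mean_ms, mean(r$time_ms - s$onset_ms[r$stimulus_index]),
               tolerance = 1e-9)
})

test_that("neighbour false-alarm normalization divides by opportunity counts", {
  r <- neighbor_fa_rates(n_neighbor = 14, n_other = 19, n_directions = 8,
                         n_targets = 576)
  expect_equal(round_half_up(r$p_neighbor_pct, 2), 1.22)
  expect_equal(round_half_up(r$p_other_pct, 2), 0.66)
  z <- neighbor_fa_rates(n_neighbor = 0, n_other = 0, n_directions = 8,
                         n_targets = 100)
  expect_equal(z$p_neighbor_pct, 0)
  expect_equal(z$p_other_pct, 0)
  # counts derived from a confusion table on the circular layout
  conf <- data.frame(target_direction = c(1, 1, 4), response_direction = c(8, 2, 6))
  rc <- neighbor_fa_rates(conf, n_directions = 8, n_targets = 50)
  expect_equal(rc$n_neighbor, 2)  # 8 and 2 are direct neighbours of 1
  expect_equal(rc$n_other, 1)
})

test_that("trial score matrices carry masked subtrials as missing", {
  ep <- make_epochs(n_trials = 4, n_directions = 5, n_iterations = 3)
  ep$artifact[5] <- TRUE
  cv <- suppressWarnings(crossvalidate(ep, k = 2, n_pos = 3, n_neg = 3))
  tsc <- trial_scores(cv, n_directions = 5)
  expect_length(tsc, 4)
  expect_equal(dim(tsc[[1]]$scores), c(5, 3))
  d5 <- cv$scores$direction[5]; i5 <- cv$scores$iteration_id[5]
  expect_true(is.na(tsc[[1]]$scores[d5, i5]))
  expect_equal(sum(is.na(tsc[[1]]$scores)), 1)
})
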