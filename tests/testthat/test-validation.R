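# small fitted-model stand-in with known weights over 20 items
fake_model <- function(n = 20, k = 2, seed = 40) {
  withr::with_seed(seed, {
    H <- matrix(runif(k * n), k, n,
                dimnames = list(NULL, sprintf("v%02d", seq_len(n))))
    structure(list(W = t(H), H = H, k = k, s_w = 0, s_h = 0,
                   items = colnames(H)), class = "nmf_model")
  })
}

test_that("extreme_videos returns disjoint deterministic top/bottom sets", {
  H <- matrix(1:16, 1, 16, dimnames = list(NULL, sprintf("v%02d", 1:16)))
  ext <- extreme_videos(H, 1)
  expect_setequal(ext$bottom, sprintf("v%02d", 1:8))
  expect_setequal(ext$top, sprintf("v%02d", 9:16))
  expect_length(intersect(ext$top, ext$bottom), 0)
  # all-equal weights: deterministic id-order split with a warning
  Hc <- matrix(1, 1, 16, dimnames = dimnames(H))
  expect_warning(extc <- extreme_videos(Hc, 1), "tied")
  expect_setequal(extc$bottom, sprintf("v%02d", 1:8))
  expect_error(extreme_videos(H[, 1:10, drop = FALSE], 1), "at least 16")
})

test_that("build_trials resamples 7 high + 1 low per trial, reproducibly", {
  model <- fake_model()
  tr <- build_trials(model, 1, n_trials = 20, seed = 41)
  expect_equal(nrow(tr), 20)
  ext <- extreme_videos(model, 1)
  pres <- as.matrix(tr[paste0("item_", 1:8)])
  for (i in 1:20) {
    expect_true(tr$low_item[i] %in% ext$bottom)
    expect_setequal(setdiff(pres[i, ], tr$low_item[i]),
                    intersect(pres[i, ], ext$top))
    expect_length(unique(pres[i, ]), 8)
  }
  expect_identical(build_trials(model, 1, n_trials = 20, seed = 41), tr)
})

make_responses <- function(trials, participants, chooser) {
  do.call(rbind, lapply(participants, function(p)
    data.frame(participant_id = p,
               dimension_id = trials$dimension_id,
               trial_idx = trials$trial_idx,
               chosen_item = vapply(seq_len(nrow(trials)), function(i)
                 chooser(trials[i, ], p), character(1)))))
}

test_that("score_responses scores the odd-one-out and applies strict exclusion", {
  model <- fake_model()
  trials <- rbind(build_trials(model, 1, n_trials = 5, seed = 42),
                  build_trials(model, 2, n_trials = 5, seed = 43))
  # dimension 2 trials double as catch trials for the exclusion rule
  trials$is_catch[trials$dimension_id == 2] <- TRUE
  always_right <- function(t, p) t$low_item
  # p_bad answers catch trials at exactly 12.5% (0 of 5 < 1/8... use 0 correct)
  wrong <- function(t, p) setdiff(unlist(t[paste0("item_", 1:8)]), t$low_item)[1]
  resp <- rbind(make_responses(trials, c("good1", "good2"), always_right),
                make_responses(trials[trials$is_catch, ], "bad", wrong),
                make_responses(trials[!trials$is_catch, ], "bad", always_right))
  sc <- score_responses(trials, resp)
  expect_identical(sc$excluded_participants, "bad")
  expect_equal(unname(sc$accuracy_per_dimension["1"]), 1)
  # chance responder sits near 12.5%
  withr::with_seed(44, {
    rand <- function(t, p) sample(unlist(t[paste0("item_", 1:8)]), 1)
    big <- build_trials(model, 1, n_trials = 20, seed = 45)
    racc <- mean(replicate(40, {
      r <- make_responses(big, "r1", rand)
      score_responses(big, r)$accuracy_per_dimension[["1"]]
    }))
    expect_lt(abs(racc - 0.125), 0.04)
  })
  # invariance to presentation order
  trials_shuf <- trials
  trials_shuf[paste0("item_", 1:8)] <- trials[paste0("item_", c(3, 1, 2, 8, 5, 4, 7, 6))]
  sc2 <- score_responses(trials_shuf, resp)
  expect_equal(sc2$accuracy_per_dimension, sc$accuracy_per_dimension)
  # participant at exactly the chance bound is excluded (strict inequality)
  catch <- build_trials(model, 2, n_trials = 8, seed = 90)
  catch$is_catch <- TRUE
  one_of_eight <- function(t, p)
    if (t$trial_idx == 1) t$low_item else wrong(t, p)
  resp3 <- make_responses(catch, "edge", one_of_eight)
  sc3 <- score_responses(catch, resp3)
  expect_identical(sc3$excluded_participants, "edge")
  bad_resp <- data.frame(participant_id = "x", dimension_id = 9,
                         trial_idx = 99, chosen_item = "v01")
  expect_error(score_responses(trials, bad_resp), "unknown trials")
})

test_that("sign permutation test controls the omnibus null", {
  # all participants exactly at chance: p must be far from significant
  A <- matrix(0.125, 10, 4)
  p <- sign_permutation_test(A, n_iter = 1000, seed = 46)
  expect_true(all(p > 0.4))
  # a ceiling dimension among 20 participants hits the permutation floor
  withr::with_seed(47, {
    B <- matrix(0.125 + rnorm(20 * 4, 0, 0.01), 20, 4)
    B[, 2] <- 1
    p2 <- sign_permutation_test(B, n_iter = 5000, seed = 48)
    expect_equal(unname(p2[2]), 1 / 5001)
  })
  # invariant to dimension ordering
  p3 <- suppressWarnings(
    sign_permutation_test(B[, c(3, 1, 4, 2)], n_iter = 500, seed = 49))
  p4 <- suppressWarnings(sign_permutation_test(B, n_iter = 500, seed = 49))
  expect_equal(unname(p3), unname(p4[c(3, 1, 4, 2)]))
  expect_error(sign_permutation_test(B[1, , drop = FALSE]), "two participants")
  expect_warning(sign_permutation_test(B, n_iter = 100, seed = 1), "coarse")
})

test_that("sign permutation test keeps familywise error near nominal", {
  withr::with_seed(50, {
    any_sig <- replicate(200, {
      A <- matrix(0.125 + rnorm(16 * 8, 0, 0.1), 16, 8)
      min(suppressWarnings(sign_permutation_test(A, n_iter = 500))) < 0.05
    })
    expect_lte(mean(any_sig), 0.07)
  })
})

test_that("welch_t matches a hand-computed statistic and its symmetries", {
  a <- c(1, 2, 3); b <- c(1, 2, 3, 100)
  out <- welch_t(a, b)
  # independent formula evaluation
  se2 <- var(a) / 3 + var(b) / 4
  t_hand <- (mean(a) - mean(b)) / sqrt(se2)
  df_hand <- se2^2 / ((var(a) / 3)^2 / 2 + (var(b) / 4)^2 / 3)
  expect_equal(out$t, t_hand)
  expect_equal(out$df, df_hand)
  expect_equal(out$p, 2 * pt(-abs(t_hand), df_hand))
  # identical samples: t = 0, p = 1
  same <- welch_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  # swapping flips the sign, p unchanged
  sw <- welch_t(b, a)
  expect_equal(sw$t, -out$t)
  expect_equal(sw$p, out$p)
  expect_error(welch_t(c(1, 1), c(2, 2)), "zero variance")
})
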