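test_that("participant hold-out takes whole participants reproducibly", {
  ds <- complete_dataset(n_items = 5, n_units = 53, seed = 2)
  sp <- split_holdout(ds, seed = 1, n_holdout_units = 5)
  expect_equal(sp$holdout_fraction, 5 / 53)
  expect_length(dataset_units(sp$holdout), 5)
  expect_length(intersect(dataset_units(sp$holdout),
                          dataset_units(sp$training)), 0)
  sp2 <- split_holdout(ds, seed = 1, n_holdout_units = 5)
  expect_identical(dataset_units(sp2$holdout), dataset_units(sp$holdout))
})

test_that("rating-level hold-out takes one rating per coverable pair", {
  m <- make_planted_model(12, 3, 0.5, seed = 3)
  ds <- simulate_dataset(m, 20, mode = "exp1_subsets", subset_size = 8,
                         rating_noise_sd = 0.05, seed = 4)
  sp <- split_holdout(ds, seed = 5)
  hold <- sp$holdout$ratings
  expect_true(all(table(paste(hold$item_a, hold$item_b)) == 1))
  # training and hold-out partition the rating ids
  expect_length(intersect(hold$rating_id, sp$training$ratings$rating_id), 0)
  expect_equal(nrow(hold) + nrow(sp$training$ratings), nrow(ds$ratings))
  # a pair with a single rating stays in training with a warning
  one <- tiny_dataset()
  expect_warning(sp1 <- split_holdout(one, seed = 1), "single rating")
  expect_true(all(c("a c", "c d") %in%
    paste(sp1$training$ratings$item_a, sp1$training$ratings$item_b)))
})

test_that("cross-validation plans partition training units 1/3-2/3", {
  ds <- complete_dataset(n_items = 4, n_units = 48, seed = 6)
  plan <- make_cv_plan(ds, reps = 5, seed = 7)
  expect_length(plan$reps, 5)
  for (p in plan$reps) {
    expect_equal(unname(sort(lengths(p))), c(16L, 16L, 16L))
    expect_setequal(unlist(p), dataset_units(ds))
    expect_length(intersect(p$fold1, p$fold2), 0)
    expect_length(intersect(p$fold1, p$ksel), 0)
  }
  # repetitions differ under one seed stream
  expect_false(identical(sort(plan$reps[[1]]$fold1),
                         sort(plan$reps[[2]]$fold1)))
  expect_error(make_cv_plan(complete_dataset(3, 2), reps = 2), "at least three")
})

test_that("rating-level plans stratify folds across pairs", {
  m <- make_planted_model(10, 2, 0.5, seed = 8)
  ds <- simulate_dataset(m, 30, mode = "exp2_complete", seed = 9)
  ds$mode <- "rating_sampled" # treat each rating as a unit
  plan <- make_cv_plan(ds, reps = 2, seed = 10)
  p <- plan$reps[[1]]
  expect_setequal(unlist(p), dataset_units(ds))
  # with 30 ratings per pair every fold covers every pair
  for (part in p) {
    sub <- subset_units(ds, part)
    expect_true(all(aggregate_ratings(sub)$observed))
  }
  # inner folds together hold about two thirds of the ratings
  frac <- (length(p$fold1) + length(p$fold2)) / length(dataset_units(ds))
  expect_equal(frac, 2 / 3, tolerance = 0.05)
})

test_that("sparsity_search scans the full grid and scores noiseless data", {
  S <- similarity_matrix(planted_similarity(12, 3, seed = 11),
                         items = sprintf("i%02d", 1:12))
  ss <- sparsity_search(S, S, 3)
  expect_equal(nrow(ss$scores), 81)
  expect_gte(ss$mean_tau, 0.95)
  expect_true(ss$s_w %in% seq(0, 0.8, 0.1) && ss$s_h %in% seq(0, 0.8, 0.1))
  expect_equal(max(ss$scores$tau), ss$mean_tau)
})

test_that("k_curve rises to the planted rank and averages repetitions", {
  m <- make_planted_model(24, 4, 0.5, seed = 12)
  ds <- simulate_dataset(m, 18, mode = "exp2_complete", seed = 13)
  plan <- make_cv_plan(ds, reps = 2, seed = 14)
  curve <- k_curve(ds, plan, k_range = 1:8, grid = c(0, 0.4))
  expect_identical(curve$k_values, 1:8)
  expect_equal(dim(curve$per_rep_tau), c(2L, 8L))
  expect_equal(unname(curve$mean_tau), unname(colMeans(curve$per_rep_tau)))
  # noiseless planted k* = 4: steep rise then plateau
  expect_gt(curve$mean_tau[4] - curve$mean_tau[1], 0.1)
  expect_lt(abs(curve$mean_tau[8] - curve$mean_tau[5]), 0.1)
  expect_equal(nrow(curve$best_sparsity_per_k), 8)
})

test_that("find_elbow picks the max-chord-distance point", {
  expect_equal(find_elbow(c(1, 2, 3, 4), c(0, 0.5, 0.6, 0.62)), 2)
  # invariant under positive rescaling of tau
  expect_equal(find_elbow(c(1, 2, 3, 4), 7 * c(0, 0.5, 0.6, 0.62)), 2)
  expect_warning(k <- find_elbow(1:5, seq(0, 1, length.out = 5)), "linear")
  expect_equal(k, 2)
  expect_error(find_elbow(1:2, c(0, 1)), "three points")
})

test_that("find_elbow matches a brute-force oracle on random curves", {
  withr::with_seed(15, {
    for (i in 1:100) {
      npt <- sample(4:30, 1)
      k <- sort(sample(1:60, npt))
      tau <- cumsum(abs(rnorm(npt))) # increasing, concave-ish after norming
      tau <- tau + rnorm(npt, 0, 0.05 * max(tau))
      expect_equal(find_elbow(k, tau), elbow_oracle(k, tau))
    }
  })
})

test_that("finalize reports train, hold-out and reliability-ceiling taus", {
  m <- make_planted_model(20, 3, 0.5, seed = 16)
  ds <- simulate_dataset(m, 16, mode = "exp2_complete", seed = 17)
  sp <- split_holdout(ds, seed = 18, n_holdout_units = 2)
  plan <- make_cv_plan(sp$training, reps = 2, seed = 19)
  fin <- finalize_nmf(sp$training, sp$holdout, k = 3, s_w = 0, s_h = 0,
                      plan = plan)
  # tau_true is the plain correlation between the two matrices
  expect_equal(fin$tau_true,
               kendall_tau_a(lower_triangle(fold_matrix(sp$training)),
                             lower_triangle(fold_matrix(sp$holdout))))
  # noiseless data: hold-out tracks training performance
  expect_equal(fin$tau_holdout, fin$tau_train, tolerance = 0.05)
  expect_warning(finalize_nmf(sp$training, sp$holdout, 3, 0, 0), "NNDSVD")
})

test_that("selection never sees hold-out units", {
  m <- make_planted_model(16, 3, 0.5, seed = 20)
  ds <- simulate_dataset(m, 14, mode = "exp2_complete",
                         rating_noise_sd = 0.05, seed = 21)
  res <- select_dimensions(ds, k_range = 1:6, grid = c(0, 0.4), reps = 2,
                           seed = 22, n_holdout_units = 2)
  plan_units <- unlist(lapply(res$plan$reps, unlist))
  expect_length(intersect(plan_units, dataset_units(res$split$holdout)), 0)
  expect_setequal(unique(plan_units), dataset_units(res$split$training))
  expect_true(res$k_selected %in% 1:6)
  expect_true(all(abs(c(res$tau_train, res$tau_holdout, res$tau_true)) <= 1))
})

test_that("PCA reconstruction is exact at full rank", {
  S <- planted_similarity(10, 9, seed = 23)
  recon <- simdims:::pca_reconstruct(S, 10)
  expect_equal(recon, S, tolerance = 1e-8)
  expect_equal(kendall_tau_a(lower_triangle(recon), lower_triangle(S)), 1)
})

test_that("cross-validated PCA plateaus at the planted rank and shares folds", {
  m <- make_planted_model(20, 3, 0.5, seed = 24)
  ds <- simulate_dataset(m, 16, mode = "exp2_complete", seed = 25)
  res_nmf <- select_dimensions(ds, k_range = 1:8, grid = c(0, 0.4), reps = 2,
                               seed = 26, n_holdout_units = 2)
  res_pca <- cross_validated_pca(ds, k_range = 1:8,
                                 split = res_nmf$split, plan = res_nmf$plan)
  # identical fold partitions under the shared plan
  expect_identical(res_pca$plan, res_nmf$plan)
  expect_identical(res_pca$tau_true, res_nmf$tau_true)
  # rank-3 planted matrix (+ rank-1 similarity rescaling): early plateau
  mt <- res_pca$curve$mean_tau
  expect_lt(abs(mt[8] - mt[5]), 0.1)
  expect_gt(mt[4], mt[1])
  expect_true(res_pca$k_selected %in% 1:8)
})

test_that("selection reports serialize to JSON and TSV", {
  m <- make_planted_model(14, 3, 0.5, seed = 27)
  ds <- simulate_dataset(m, 12, mode = "exp2_complete", seed = 28)
  res <- select_dimensions(ds, k_range = 1:5, grid = c(0, 0.4), reps = 2,
                           seed = 29, n_holdout_units = 2)
  d <- withr::local_tempdir()
  write_selection_report(res, d)
  rep <- jsonlite::read_json(file.path(d, "selection_report.json"),
                             simplifyVector = TRUE)
  expect_equal(rep$k_selected, res$k_selected)
  expect_equal(rep$tau_holdout, res$tau_holdout)
  curve <- read.delim(file.path(d, "curve.tsv"))
  expect_equal(curve$k, res$curve$k_values)
  expect_equal(curve$mean_tau, unname(res$curve$mean_tau))
})
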