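#' Split a dataset into training and hold-out portions
#'
#' In \code{rating_sampled} mode, one randomly selected rating per item pair
#' forms the hold-out, yielding a complete test matrix with a single rating
#' per pair; pairs with only one rating keep it in training (with a warning)
#' and are unobserved in the hold-out. In \code{participant_complete} mode a
#' fixed number of whole participants is held out (default 5, i.e. 5/53 =
#' 9.43\% at the 53-participant design scale).
#'
#' @param dataset a [similarity_dataset()].
#' @param seed integer seed for reproducible splits.
#' @param n_holdout_units participants to hold out in
#'   \code{participant_complete} mode.
#' @return list with elements \code{training} and \code{holdout}, both
#'   [similarity_dataset()]s, plus \code{holdout_fraction} (held-out units /
#'   total units).
#' @export
split_holdout <- function(dataset, seed = NULL, n_holdout_units = 5) {
  with_seed(seed, {
    if (dataset$mode == "rating_sampled") {
      r <- dataset$ratings
      pair_key <- paste(r$item_a, r$item_b, sep = "\r")
      ids_by_pair <- split(r$rating_id, pair_key)
      singles <- sum(lengths(ids_by_pair) < 2L)
      if (singles > 0)
        warning(singles, " pair(s) have a single rating; kept in training, ",
                "unobserved in the hold-out")
      hold_ids <- unlist(lapply(ids_by_pair, function(ids) {
        if (length(ids) < 2L) return(integer(0))
        ids[sample.int(length(ids), 1L)]
      }), use.names = FALSE)
      all_ids <- r$rating_id
      train_ids <- setdiff(all_ids, hold_ids)
      list(training = subset_units(dataset, train_ids),
           holdout = subset_units(dataset, hold_ids),
           holdout_fraction = length(hold_ids) / length(all_ids))
    } else {
      units <- dataset_units(dataset)
      if (n_holdout_units < 1 || n_holdout_units >= length(units))
        stop_input("n_holdout_units must leave at least one training unit")
      hold <- sample(units, n_holdout_units)
      list(training = subset_units(dataset, setdiff(units, hold)),
           holdout = subset_units(dataset, hold),
           holdout_fraction = n_holdout_units / length(units))
    }
  })
}

#' Build a nested cross-validation plan
#'
#' Per repetition, the training units are partitioned into two equal inner
#' folds (together about two thirds, used for the two-fold sparsity search)
#' and a k-selection set (about one third). In \code{rating_sampled} mode
#' the assignment is stratified per item pair so every fold covers every
#' pair whose rating count permits it.
#'
#' @param training a training [similarity_dataset()] (from [split_holdout()]).
#' @param reps number of repetitions (default 5).
#' @param seed integer seed.
#' @return an object of class \code{cv_plan}: per repetition the unit-id
#'   vectors \code{fold1}, \code{fold2}, \code{ksel}.
#' @export
make_cv_plan <- function(training, reps = 5, seed = NULL) {
  units <- dataset_units(training)
  if (length(units) < 3L)
    stop_input("need at least three units to form two folds and a selection set")
  plan <- with_seed(seed, {
    lapply(seq_len(reps), function(r) {
      if (training$mode == "participant_complete") {
        u <- sample(units)
        n <- length(u)
        n_sel <- max(1L, round(n / 3))
        rem <- n - n_sel
        n_f1 <- ceiling(rem / 2)
        list(fold1 = u[seq_len(n_f1)],
             fold2 = u[n_f1 + seq_len(rem - n_f1)],
             ksel = u[(rem + 1):n])
      } else {
        rt <- training$ratings
        pair_key <- paste(rt$item_a, rt$item_b, sep = "\r")
        ids_by_pair <- split(as.character(rt$rating_id), pair_key)
        part <- lapply(ids_by_pair, function(ids) {
          ids <- if (length(ids) > 1L) sample(ids) else ids
          # deal ratings cyclically over (fold1, fold2, ksel) with a random
          # starting phase, so proportions approach 1/3 each per pair
          lab <- (sample.int(3L, 1L) + seq_along(ids) - 2L) %% 3L + 1L
          split(ids, factor(lab, levels = 1:3))
        })
        f <- function(i) unlist(lapply(part, `[[`, i), use.names = FALSE)
        list(fold1 = f(1L), fold2 = f(2L), ksel = f(3L))
      }
    })
  })
  if (any(vapply(plan, function(p) any(lengths(p) == 0L), logical(1))))
    stop_input("too few units: a fold came out empty")
  structure(list(mode = training$mode, reps = plan, seed = seed),
            class = "cv_plan")
}

#' @export
print.cv_plan <- function(x, ...) {
  sizes <- vapply(x$reps[[1]], length, integer(1))
  cat("<cv_plan> ", length(x$reps), " repetitions (", x$mode, "); rep-1 sizes ",
      paste(sizes, collapse = "/"), "\n", sep = "")
  invisible(x)
}

#' Aggregate a unit subset into a complete similarity matrix
#'
#' Averages the selected units' ratings, converts to similarity and imputes
#' any missing pairs — always within the given fold only, never across
#' folds.
#'
#' @param dataset a [similarity_dataset()].
#' @param units unit ids; default all.
#' @return a fully observed [similarity_matrix()].
#' @export
fold_matrix <- function(dataset, units = NULL) {
  impute_missing(to_similarity(aggregate_ratings(dataset, units)))
}

# default sparsity grid: 0 (no sparsity) to 0.8 in steps of 0.1
default_sparsity_grid <- function() seq(0, 0.8, by = 0.1)

#' Two-fold search over the sparsity-parameter grid
#'
#' For every \code{(s_w, s_h)} combination, fits on fold 1 and scores the
#' reconstruction against fold 2 with Kendall tau-a (off-diagonal pairs
#' only), and vice versa; returns the combination maximizing the two-fold
#' mean. Ties break toward smaller \code{s_w + s_h}, then smaller
#' \code{s_w}. Non-convergent (diverging) fits are recorded with tau = -1
#' rather than aborting the search.
#'
#' @param V1,V2 fully observed fold [similarity_matrix()]es.
#' @param k number of dimensions.
#' @param grid sparsity values to cross (default 0 to 0.8 by 0.1, a 9 x 9
#'   grid).
#' @param max_iter,tol passed to [nmf_fit()].
#' @return list: \code{s_w}, \code{s_h}, \code{mean_tau}, and \code{scores},
#'   a data frame of all combinations with their two-fold mean tau.
#' @export
sparsity_search <- function(V1, V2, k, grid = default_sparsity_grid(),
                            max_iter = 500, tol = 1e-5) {
  combos <- expand.grid(s_w = grid, s_h = grid, KEEP.OUT.ATTRS = FALSE)
  init1 <- nndsvd_init(V1$values, k)
  init2 <- nndsvd_init(V2$values, k)
  lt1 <- lower_triangle(V1)
  lt2 <- lower_triangle(V2)
  one_way <- function(V, init, lt_other, s_w, s_h) {
    fit <- tryCatch(nmf_fit(V, k, s_w, s_h, init = init,
                            max_iter = max_iter, tol = tol),
                    nmf_divergence = function(e) NULL)
    if (is.null(fit)) return(-1)
    kendall_tau_a(lower_triangle(reconstruct(fit)), lt_other)
  }
  combos$tau <- vapply(seq_len(nrow(combos)), function(i) {
    sw <- combos$s_w[i]; sh <- combos$s_h[i]
    mean(c(one_way(V1, init1, lt2, sw, sh),
           one_way(V2, init2, lt1, sw, sh)))
  }, numeric(1))
  ord <- order(-combos$tau, combos$s_w + combos$s_h, combos$s_w)
  best <- combos[ord[1L], ]
  list(s_w = best$s_w, s_h = best$s_h, mean_tau = best$tau, scores = combos)
}

#' Cross-validated performance curve over the number of dimensions
#'
#' For every repetition of the plan and every \code{k}: the sparsity grid is
#' searched on the two inner folds, the winning combination is refit on the
#' combined inner folds, and the reconstruction is scored against that
#' repetition's k-selection matrix. The mean over repetitions forms the
#' performance curve used for elbow-based selection. The reported best
#' sparsity per \code{k} maximizes the grid scores averaged over
#' repetitions.
#'
#' @param training a training [similarity_dataset()].
#' @param plan a [make_cv_plan()] object.
#' @param k_range integer vector of dimensionalities; default
#'   \code{1:(n_items - 2)} capped at \code{k_cap}.
#' @param grid sparsity grid, see [sparsity_search()].
#' @param k_cap upper cap on the default k range.
#' @param max_iter,tol passed to [nmf_fit()].
#' @param verbose print progress.
#' @return an object of class \code{performance_curve}: \code{k_values},
#'   \code{mean_tau}, \code{per_rep_tau} (reps x k), and
#'   \code{best_sparsity_per_k} (data frame k, s_w, s_h).
#' @export
k_curve <- function(training, plan, k_range = NULL,
                    grid = default_sparsity_grid(), k_cap = Inf,
                    max_iter = 500, tol = 1e-5, verbose = FALSE) {
  stopifnot(inherits(plan, "cv_plan"))
  n_items <- length(training$stimuli$item_ids)
  if (is.null(k_range)) k_range <- seq_len(min(n_items - 2L, k_cap))
  k_range <- sort(unique(as.integer(k_range)))
  if (any(k_range < 1L) || any(k_range > n_items - 1L))
    stop_input("k_range must lie within [1, n_items - 1]")
  reps <- length(plan$reps)
  mats <- lapply(plan$reps, function(p) {
    list(V1 = fold_matrix(training, p$fold1),
         V2 = fold_matrix(training, p$fold2),
         V12 = fold_matrix(training, c(p$fold1, p$fold2)),
         Vsel = fold_matrix(training, p$ksel))
  })
  per_rep <- matrix(NA_real_, reps, length(k_range),
                    dimnames = list(NULL, paste0("k", k_range)))
  grid_sums <- vector("list", length(k_range))
  for (r in seq_len(reps)) {
    m <- mats[[r]]
    lt_sel <- lower_triangle(m$Vsel)
    init12 <- NULL
    for (ki in seq_along(k_range)) {
      k <- k_range[ki]
      ss <- sparsity_search(m$V1, m$V2, k, grid = grid,
                            max_iter = max_iter, tol = tol)
      refit <- tryCatch(
        nmf_fit(m$V12, k, ss$s_w, ss$s_h, max_iter = max_iter, tol = tol),
        nmf_divergence = function(e) NULL)
      per_rep[r, ki] <- if (is.null(refit)) -1 else
        kendall_tau_a(lower_triangle(reconstruct(refit)), lt_sel)
      if (is.null(grid_sums[[ki]])) grid_sums[[ki]] <- ss$scores
      else grid_sums[[ki]]$tau <- grid_sums[[ki]]$tau + ss$scores$tau
      if (verbose)
        message(sprintf("rep %d k %d: s=(%.1f, %.1f) tau_sel=%.3f",
                        r, k, ss$s_w, ss$s_h, per_rep[r, ki]))
    }
  }
  best_s <- do.call(rbind, lapply(seq_along(k_range), function(ki) {
    g <- grid_sums[[ki]]
    ord <- order(-g$tau, g$s_w + g$s_h, g$s_w)
    data.frame(k = k_range[ki], s_w = g$s_w[ord[1]], s_h = g$s_h[ord[1]])
  }))
  structure(list(k_values = k_range,
                 mean_tau = colMeans(per_rep),
                 per_rep_tau = per_rep,
                 best_sparsity_per_k = best_s),
            class = "performance_curve")
}

#' @export
print.performance_curve <- function(x, ...) {
  cat("<performance_curve> k in [", min(x$k_values), ", ", max(x$k_values),
      "], ", nrow(x$per_rep_tau), " repetitions; peak mean tau ",
      round(max(x$mean_tau), 3), " at k = ",
      x$k_values[which.max(x$mean_tau)], "\n", sep = "")
  invisible(x)
}

#' Elbow point of a performance curve
#'
#' Both axes are min-max normalized to \[0, 1\]; the elbow is the point
#' maximally distant from the chord joining the first and last points (ties
#' break toward the smallest k). A degenerate, effectively linear curve
#' returns the smallest interior k with a warning.
#'
#' @param curve a \code{performance_curve}, or a numeric vector of k values.
#' @param tau mean performance per k (only when \code{curve} is a vector).
#' @return the selected k.
#' @export
find_elbow <- function(curve, tau = NULL) {
  if (inherits(curve, "performance_curve")) {
    k <- curve$k_values; y <- curve$mean_tau
  } else {
    k <- curve; y <- tau
  }
  if (length(k) < 3L) stop_input("need at least three points")
  norm01 <- function(v) {
    r <- range(v)
    if (diff(r) == 0) rep(0, length(v)) else (v - r[1]) / diff(r)
  }
  x <- norm01(k); z <- norm01(y)
  x1 <- x[1]; z1 <- z[1]; x2 <- x[length(x)]; z2 <- z[length(z)]
  len <- sqrt((x2 - x1)^2 + (z2 - z1)^2)
  d <- if (len == 0) rep(0, length(x)) else
    abs((z2 - z1) * x - (x2 - x1) * z + x2 * z1 - z2 * x1) / len
  interior <- seq(2L, length(k) - 1L)
  di <- d[interior]
  if (all(di < 1e-12)) {
    warning("performance curve is effectively linear; returning smallest interior k")
    return(k[interior[1L]])
  }
  k[interior[which.max(di)]]
}

#' Final refit and hold-out evaluation
#'
#' Refits on the full averaged training matrix at the selected parameters,
#' initialized from the first cross-validation fold of repetition 1 (refit
#' at the selected \code{(k, s)}), and reports tau-a of the reconstruction
#' against the training and hold-out matrices plus the "true" tau-a between
#' the training and hold-out matrices themselves (the reliability ceiling).
#' All correlations use off-diagonal pairs only. No hold-out information is
#' used in any selection step.
#'
#' @param training,holdout the two datasets from [split_holdout()].
#' @param k,s_w,s_h selected parameters.
#' @param plan the [make_cv_plan()] used during selection (for the
#'   fold-1 re-initialization); when \code{NULL} falls back to
#'   [nndsvd_init()] with a warning.
#' @param init_model optional explicit \code{nmf_model} to initialize from.
#' @param max_iter,tol passed to [nmf_fit()].
#' @return list: \code{model}, \code{tau_train}, \code{tau_holdout},
#'   \code{tau_true}.
#' @export
finalize_nmf <- function(training, holdout, k, s_w, s_h, plan = NULL,
                         init_model = NULL, max_iter = 500, tol = 1e-5) {
  if (is.null(init_model)) {
    if (!is.null(plan)) {
      V1 <- fold_matrix(training, plan$reps[[1]]$fold1)
      init_model <- tryCatch(
        nmf_fit(V1, k, s_w, s_h, max_iter = max_iter, tol = tol),
        nmf_divergence = function(e) NULL)
    }
    if (is.null(init_model))
      warning("no stored fold-1 model available; initializing with NNDSVD")
  }
  V_train <- fold_matrix(training)
  V_hold <- fold_matrix(holdout)
  init <- if (is.null(init_model)) NULL else
    list(W = init_model$W, H = init_model$H)
  model <- nmf_fit(V_train, k, s_w, s_h, init = init,
                   max_iter = max_iter, tol = tol)
  model$items <- V_train$items
  recon <- reconstruct(model)
  list(model = model,
       tau_train = kendall_tau_a(lower_triangle(recon), lower_triangle(V_train)),
       tau_holdout = kendall_tau_a(lower_triangle(recon), lower_triangle(V_hold)),
       tau_true = tau_between(V_train, V_hold))
}

#' Run the full nested cross-validated sparse-NMF selection
#'
#' Orchestrates [split_holdout()], [make_cv_plan()], [k_curve()],
#' [find_elbow()] and [finalize_nmf()]: the two-fold sparsity search runs on
#' about 60\% of the data, k selection on a separate ~30\%, and ~10\% is
#' held out for final evaluation only.
#'
#' @inheritParams k_curve
#' @param dataset a [similarity_dataset()].
#' @param reps plan repetitions (default 5).
#' @param seed integer seed controlling the hold-out split and the plan.
#' @param n_holdout_units see [split_holdout()].
#' @return object of class \code{selection_result}: \code{k_selected},
#'   \code{s_selected} (named vector s_w, s_h), \code{model}, \code{curve},
#'   \code{plan}, \code{tau_train}, \code{tau_holdout}, \code{tau_true},
#'   \code{method = "nmf"}.
#' @export
select_dimensions <- function(dataset, k_range = NULL,
                              grid = default_sparsity_grid(), reps = 5,
                              seed = NULL, n_holdout_units = 5, k_cap = Inf,
                              max_iter = 500, tol = 1e-5, verbose = FALSE) {
  seeds <- derive_seeds(seed, 2)
  split <- split_holdout(dataset, seed = seeds[[1]],
                         n_holdout_units = n_holdout_units)
  plan <- make_cv_plan(split$training, reps = reps, seed = seeds[[2]])
  curve <- k_curve(split$training, plan, k_range = k_range, grid = grid,
                   k_cap = k_cap, max_iter = max_iter, tol = tol,
                   verbose = verbose)
  k_sel <- find_elbow(curve)
  s_row <- curve$best_sparsity_per_k[curve$best_sparsity_per_k$k == k_sel, ]
  fin <- finalize_nmf(split$training, split$holdout, k_sel,
                      s_row$s_w, s_row$s_h, plan = plan,
                      max_iter = max_iter, tol = tol)
  structure(c(list(k_selected = k_sel,
                   s_selected = c(s_w = s_row$s_w, s_h = s_row$s_h),
                   curve = curve, plan = plan, split = split,
                   method = "nmf"),
              fin),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat("<selection_result> (", x$method, ") k = ", x$k_selected,
      if (x$method == "nmf")
        paste0(", s = (", x$s_selected[["s_w"]], ", ", x$s_selected[["s_h"]], ")"),
      "\n  tau_train = ", round(x$tau_train, 3),
      ", tau_holdout = ", round(x$tau_holdout, 3),
      ", tau_true = ", round(x$tau_true, 3), "\n", sep = "")
  invisible(x)
}

# rank-k PCA reconstruction: column-mean-center, project on the top-k
# principal axes, reconstruct, add the means back
pca_reconstruct <- function(V, k) {
  V <- if (inherits(V, "similarity_matrix")) V$values else as.matrix(V)
  ctr <- colMeans(V)
  Vc <- sweep(V, 2, ctr)
  sv <- svd(Vc, nu = k, nv = k)
  recon <- sv$u %*% (t(sv$v) * sv$d[seq_len(k)])
  sweep(recon, 2, ctr, `+`)
}

#' Cross-validated PCA baseline
#'
#' Identical nested scheme to the sparse-NMF path — same splits, same
#' elbow rule — except no sparsity search is performed: per repetition and
#' k, the combined inner-fold matrix is reconstructed from its top-k
#' principal axes (column-mean-centered, means restored) and scored with
#' tau-a against the k-selection matrix.
#'
#' @inheritParams select_dimensions
#' @param split optional precomputed [split_holdout()] result; when paired
#'   with \code{plan}, the PCA path consumes the exact fold partitions of an
#'   NMF run.
#' @param plan optional precomputed [make_cv_plan()].
#' @return a \code{selection_result} with \code{method = "pca"} and a
#'   \code{reconstruction} matrix in place of an NMF model.
#' @export
cross_validated_pca <- function(dataset, k_range = NULL, reps = 5,
                                seed = NULL, n_holdout_units = 5, k_cap = Inf,
                                split = NULL, plan = NULL, verbose = FALSE) {
  seeds <- derive_seeds(seed, 2)
  if (is.null(split))
    split <- split_holdout(dataset, seed = seeds[[1]],
                           n_holdout_units = n_holdout_units)
  if (is.null(plan))
    plan <- make_cv_plan(split$training, reps = reps, seed = seeds[[2]])
  n_items <- length(dataset$stimuli$item_ids)
  if (is.null(k_range)) k_range <- seq_len(min(n_items - 2L, k_cap))
  k_range <- sort(unique(as.integer(k_range)))
  reps_n <- length(plan$reps)
  per_rep <- matrix(NA_real_, reps_n, length(k_range),
                    dimnames = list(NULL, paste0("k", k_range)))
  for (r in seq_len(reps_n)) {
    p <- plan$reps[[r]]
    V12 <- fold_matrix(split$training, c(p$fold1, p$fold2))
    lt_sel <- lower_triangle(fold_matrix(split$training, p$ksel))
    for (ki in seq_along(k_range)) {
      recon <- pca_reconstruct(V12, k_range[ki])
      per_rep[r, ki] <- kendall_tau_a(lower_triangle(recon), lt_sel)
    }
  }
  curve <- structure(list(k_values = k_range, mean_tau = colMeans(per_rep),
                          per_rep_tau = per_rep, best_sparsity_per_k = NULL),
                     class = "performance_curve")
  k_sel <- find_elbow(curve)
  V_train <- fold_matrix(split$training)
  V_hold <- fold_matrix(split$holdout)
  recon <- pca_reconstruct(V_train, k_sel)
  structure(list(k_selected = k_sel, s_selected = NULL, curve = curve,
                 plan = plan, split = split, method = "pca",
                 reconstruction = recon,
                 tau_train = kendall_tau_a(lower_triangle(recon),
                                           lower_triangle(V_train)),
                 tau_holdout = kendall_tau_a(lower_triangle(recon),
                                             lower_triangle(V_hold)),
                 tau_true = tau_between(V_train, V_hold)),
            class = "selection_result")
}

#' Write a selection report
#'
#' \code{selection_report.json} holds the chosen parameters and all tau
#' values; \code{curve.tsv} holds the performance curve with per-repetition
#' traces.
#'
#' @param result a \code{selection_result}.
#' @param dir output directory (created if needed).
#' @return invisibly, the two file paths.
#' @export
write_selection_report <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rep_json <- file.path(dir, "selection_report.json")
  jsonlite::write_json(
    list(method = result$method,
         k_selected = result$k_selected,
         s_selected = as.list(result$s_selected),
         tau_train = result$tau_train,
         tau_holdout = result$tau_holdout,
         tau_true = result$tau_true,
         holdout_fraction = result$split$holdout_fraction,
         seed = result$plan$seed),
    rep_json, auto_unbox = TRUE, digits = NA, null = "null")
  curve_tsv <- file.path(dir, "curve.tsv")
  cv <- data.frame(k = result$curve$k_values,
                   mean_tau = result$curve$mean_tau)
  cv <- cbind(cv, t(result$curve$per_rep_tau))
  names(cv)[-(1:2)] <- paste0("rep", seq_len(nrow(result$curve$per_rep_tau)))
  utils::write.table(cv, curve_tsv, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(c(rep_json, curve_tsv))
}
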