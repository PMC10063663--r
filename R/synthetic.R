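#' Plant a ground-truth non-negative embedding
#'
#' Draws an item x dimension weight matrix with each dimension projected to
#' a target Hoyer sparseness and rescaled so the implied similarities
#' \code{W W'} stay within \[0, 1\]. Item categories are planted by
#' assigning each item the dimension it loads most on (so category removal
#' can be aligned, or not, with planted dimensions).
#'
#' @param n_items number of stimuli.
#' @param k_true number of planted dimensions (between 2 and
#'   \code{n_items / 4}).
#' @param sparseness target Hoyer sparseness per dimension (scalar or
#'   length-k vector; values in (0, 1)).
#' @param seed integer seed.
#' @return object of class \code{planted_model}: \code{W_true} (n x k,
#'   rows named item001...), \code{similarity} (the implied item x item
#'   similarity matrix), \code{categories}, \code{k_true}, \code{seed}.
#' @export
make_planted_model <- function(n_items, k_true, sparseness = 0.5, seed = NULL) {
  if (k_true < 2 || k_true > n_items / 4)
    stop_input("k_true must lie in [2, n_items / 4]")
  sparseness <- rep_len(sparseness, k_true)
  with_seed(seed, {
    W <- matrix(abs(rnorm(n_items * k_true)), n_items, k_true)
    for (j in seq_len(k_true))
      W[, j] <- project_sparseness(W[, j], sparseness[j])
    S <- W %*% t(W)
    scale <- sqrt(max(S))
    W <- W / scale
    S <- S / scale^2
    items <- sprintf("item%03d", seq_len(n_items))
    rownames(W) <- items
    dimnames(S) <- list(items, items)
    cats <- paste0("cat", max.col(W, ties.method = "first"))
    names(cats) <- items
    structure(list(W_true = W, similarity = S, k_true = as.integer(k_true),
                   target_sparseness = sparseness,
                   categories = cats, seed = seed),
              class = "planted_model")
  })
}

#' @export
print.planted_model <- function(x, ...) {
  cat("<planted_model> ", nrow(x$W_true), " items, k_true = ", x$k_true,
      ", sparseness ", paste(round(x$target_sparseness, 2), collapse = "/"),
      "\n", sep = "")
  invisible(x)
}

#' Simulate a similarity-judgment dataset from a planted model
#'
#' True similarities are \code{W W'}; each participant contributes
#' dissimilarities \code{1 - clip(bias * S + noise, 0, 1)} for every pair
#' within their item subset. \code{exp1_subsets} mode assigns each
#' participant a random item subset (the 300-participants-rate-30-of-152
#' regime, variable ratings per pair); \code{exp2_complete} mode has every
#' participant rate all pairs (the 53-participants-rate-65 regime).
#'
#' @param model a [make_planted_model()] object.
#' @param n_participants number of raters.
#' @param mode \code{"exp1_subsets"} or \code{"exp2_complete"}.
#' @param subset_size items per participant in \code{exp1_subsets} mode.
#' @param rating_noise_sd sd of additive Gaussian noise per rating on the
#'   unit similarity scale.
#' @param participant_bias_sd sd of the per-participant multiplicative
#'   scaling jitter (bias = 1 + N(0, sd)).
#' @param seed integer seed.
#' @param max_attempts subset redraws attempted before accepting uncovered
#'   pairs with a warning.
#' @return a [similarity_dataset()] with the planted categories attached to
#'   its stimulus set.
#' @export
simulate_dataset <- function(model, n_participants,
                             mode = c("exp2_complete", "exp1_subsets"),
                             subset_size = 30, rating_noise_sd = 0,
                             participant_bias_sd = 0, seed = NULL,
                             max_attempts = 100) {
  mode <- match.arg(mode)
  S <- model$similarity
  items <- rownames(model$W_true)
  n <- length(items)
  ut <- which(upper.tri(S), arr.ind = TRUE)
  with_seed(seed, {
    if (mode == "exp1_subsets") {
      if (subset_size > n) stop_input("subset_size exceeds n_items")
      for (attempt in seq_len(max_attempts)) {
        subsets <- replicate(n_participants,
                             sort(sample.int(n, subset_size)),
                             simplify = FALSE)
        covered <- matrix(FALSE, n, n)
        for (s in subsets) covered[s, s] <- TRUE
        if (all(covered[upper.tri(covered)])) break
      }
      if (!all(covered[upper.tri(covered)]))
        warning("some pairs remain uncovered after ", max_attempts, " attempts")
    } else {
      subsets <- replicate(n_participants, seq_len(n), simplify = FALSE)
    }
    rows <- lapply(seq_len(n_participants), function(p) {
      s <- subsets[[p]]
      keep <- ut[, 1] %in% s & ut[, 2] %in% s
      i <- ut[keep, 1]; j <- ut[keep, 2]
      bias <- 1 + rnorm(1, 0, participant_bias_sd)
      sim <- bias * S[cbind(i, j)] + rnorm(length(i), 0, rating_noise_sd)
      data.frame(unit_id = sprintf("p%03d", p),
                 item_a = items[i], item_b = items[j],
                 dissimilarity = 1 - pmin(pmax(sim, 0), 1))
    })
    st <- stimulus_set(items, categories = model$categories)
    similarity_dataset(do.call(rbind, rows), st,
                       mode = if (mode == "exp1_subsets") "rating_sampled"
                              else "participant_complete")
  })
}

#' Simulate clustered label embeddings
#'
#' One center per dimension, mutually separated by \code{between_sep} in
#' Euclidean distance; each labeler's label is drawn isotropically around
#' its dimension's center with sd \code{within_sd}. A fixture for the
#' label-agreement analytics.
#'
#' @param k number of dimensions.
#' @param n_labelers labelers per dimension (one rank-1 label each).
#' @param within_sd within-dimension isotropic sd.
#' @param between_sep pairwise distance between dimension centers (> 0).
#' @param vec_len embedding length (default 300).
#' @param seed integer seed.
#' @return a [label_embedding_table()].
#' @export
simulate_label_embeddings <- function(k, n_labelers, within_sd, between_sep,
                                      vec_len = 300, seed = NULL) {
  if (between_sep <= 0) stop_input("between_sep must be positive")
  if (k > vec_len) stop_input("k must not exceed vec_len")
  with_seed(seed, {
    # centers on scaled coordinate axes: mutual distance exactly between_sep
    centers <- diag(between_sep / sqrt(2), k)
    centers <- cbind(centers, matrix(0, k, vec_len - k))
    rows <- expand.grid(participant_id = sprintf("lab%02d", seq_len(n_labelers)),
                        dimension_id = seq_len(k),
                        KEEP.OUT.ATTRS = FALSE,
                        stringsAsFactors = FALSE)
    vecs <- centers[rows$dimension_id, , drop = FALSE] +
      matrix(rnorm(nrow(rows) * vec_len, 0, within_sd), nrow(rows), vec_len)
    labels <- data.frame(participant_id = rows$participant_id,
                         dimension_id = rows$dimension_id,
                         rank = 1L,
                         label = sprintf("label_d%d_%s", rows$dimension_id,
                                         rows$participant_id))
    label_embedding_table(labels, vecs)
  })
}

#' Summarize how well a selection run recovered the planted structure
#'
#' @param model the [make_planted_model()] ground truth.
#' @param result a \code{selection_result} fitted on data simulated from
#'   \code{model}.
#' @return list: \code{k_error} (|k_selected - k_true|), \code{match_r}
#'   (per planted dimension, best absolute Pearson r against the recovered
#'   dimension weights), \code{mean_match_r}, \code{tau_holdout}.
#' @export
recovery_report <- function(model, result) {
  H <- dimension_weights(result$model)
  items <- rownames(model$W_true)
  if (is.null(colnames(H)) || !all(items %in% colnames(H)))
    stop_input("result items do not match the planted model")
  H <- H[, items, drop = FALSE]
  match_r <- vapply(seq_len(model$k_true), function(j) {
    v <- model$W_true[, j]
    max(abs(vapply(seq_len(nrow(H)), function(i) {
      w <- as.numeric(H[i, ])
      if (sd(w) == 0 || sd(v) == 0) 0 else cor(v, w)
    }, numeric(1))))
  }, numeric(1))
  list(k_error = abs(result$k_selected - model$k_true),
       match_r = match_r,
       mean_match_r = mean(match_r),
       tau_holdout = result$tau_holdout)
}

#' Write a simulated dataset plus its ground truth
#'
#' Writes the ratings file consumed by [read_ratings()] and a
#' \code{ground_truth/} directory with the planted weights and a config
#' echo.
#'
#' @param dataset a simulated [similarity_dataset()].
#' @param model the [make_planted_model()] that generated it.
#' @param dir output directory.
#' @return invisibly, \code{dir}.
#' @export
write_simulation <- function(dataset, model, dir) {
  dir.create(file.path(dir, "ground_truth"), recursive = TRUE,
             showWarnings = FALSE)
  write_ratings(dataset, file.path(dir, "ratings.csv"))
  utils::write.table(model$W_true, file.path(dir, "ground_truth", "W_true.tsv"),
                     sep = "\t", quote = FALSE, col.names = FALSE)
  jsonlite::write_json(list(n_items = nrow(model$W_true),
                            k_true = model$k_true,
                            target_sparseness = model$target_sparseness,
                            seed = model$seed),
                       file.path(dir, "ground_truth", "config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}
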