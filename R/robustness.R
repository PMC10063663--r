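#' Remove a stimulus category or setting from a dataset
#'
#' Drops every item matching the selector (an action-category label or a
#' scene-setting label such as \code{"indoors"}) together with all ratings
#' touching those items.
#'
#' @param dataset a [similarity_dataset()].
#' @param selector a category or setting label.
#' @param min_remaining minimum surviving items (default 10).
#' @return a [similarity_dataset()] over the surviving items; the removed
#'   ids are recorded in attribute \code{"removed_items"}.
#' @export
remove_stimuli <- function(dataset, selector, min_remaining = 10) {
  st <- dataset$stimuli
  hit <- character(0)
  if (!is.null(st$categories))
    hit <- c(hit, names(st$categories)[st$categories == selector])
  if (!is.null(st$setting))
    hit <- c(hit, names(st$setting)[st$setting == selector])
  hit <- unique(hit)
  if (length(hit) == 0L)
    stop_input("selector '", selector, "' matches no items")
  keep <- setdiff(st$item_ids, hit)
  if (length(keep) < min_remaining)
    stop_input("fewer than ", min_remaining, " items would remain")
  new_st <- stimulus_set(keep,
                         categories = st$categories[names(st$categories) %in% keep],
                         setting = st$setting[names(st$setting) %in% keep])
  r <- dataset$ratings
  r <- r[r$item_a %in% keep & r$item_b %in% keep, , drop = FALSE]
  out <- similarity_dataset(r[c("unit_id", "item_a", "item_b", "dissimilarity")],
                            new_st, mode = "rating_sampled")
  out$mode <- dataset$mode # completeness re-check not meaningful after removal
  attr(out, "removed_items") <- hit
  attr(out, "removed_selector") <- selector
  out
}

#' Match new dimensions to the original ones
#'
#' For each dimension recovered after a stimulus perturbation, the maximum
#' Pearson correlation with any of the original dimensions restricted to
#' the surviving items (repeats allowed — one original dimension may match
#' several new ones).
#'
#' @param H_new k_new x n weight matrix over the surviving items (columns
#'   named by item id, or aligned with \code{surviving_items}).
#' @param H_orig k_orig x n_orig weight matrix over the original items
#'   (columns named by item id).
#' @param surviving_items item ids to restrict \code{H_orig} to; default the
#'   column names of \code{H_new}.
#' @return numeric vector of per-new-dimension maximal correlations; a
#'   constant dimension yields \code{NA}.
#' @export
match_dimensions <- function(H_new, H_orig, surviving_items = colnames(H_new)) {
  if (is.null(surviving_items))
    stop_input("surviving_items required when H_new has no column names")
  if (is.null(colnames(H_orig)))
    stop_input("H_orig must have item ids as column names")
  missing <- setdiff(surviving_items, colnames(H_orig))
  if (length(missing))
    stop_input("items absent from H_orig: ", paste(missing, collapse = ", "))
  Ho <- H_orig[, surviving_items, drop = FALSE]
  vapply(seq_len(nrow(H_new)), function(i) {
    v <- as.numeric(H_new[i, ])
    if (sd(v) == 0) return(NA_real_)
    max(vapply(seq_len(nrow(Ho)), function(j) {
      w <- as.numeric(Ho[j, ])
      if (sd(w) == 0) NA_real_ else cor(v, w)
    }, numeric(1)), na.rm = TRUE)
  }, numeric(1))
}

#' Shuffle null for dimension matching
#'
#' One-tailed randomization test: each iteration independently permutes the
#' item order of every original dimension and recomputes the maximal match
#' correlations, destroying item alignment while preserving each dimension's
#' weight distribution. Per-dimension p-values are
#' \code{(1 + #(null >= observed)) / (n_iter + 1)}; the null range is the
#' (min, max) over all null match values (the plotted chance band).
#'
#' @inheritParams match_dimensions
#' @param n_iter shuffle iterations (default 1000; below 100 warns).
#' @param seed integer seed.
#' @return list: \code{observed}, \code{p_values}, \code{null_range}.
#' @export
shuffle_null <- function(H_new, H_orig, surviving_items = colnames(H_new),
                         n_iter = 1000, seed = NULL) {
  if (n_iter < 100) warning("n_iter < 100 gives a coarse null")
  observed <- match_dimensions(H_new, H_orig, surviving_items)
  Ho <- H_orig[, surviving_items, drop = FALSE]
  n <- ncol(Ho)
  null_mat <- with_seed(seed, {
    vapply(seq_len(n_iter), function(i) {
      Hp <- t(apply(Ho, 1, function(row) row[sample.int(n)]))
      colnames(Hp) <- surviving_items
      match_dimensions(H_new, Hp, surviving_items)
    }, numeric(nrow(H_new)))
  })
  null_mat <- matrix(null_mat, nrow = nrow(H_new))
  p <- vapply(seq_len(nrow(H_new)), function(d) {
    if (is.na(observed[d])) return(NA_real_)
    (1 + sum(null_mat[d, ] >= observed[d])) / (n_iter + 1)
  }, numeric(1))
  list(observed = observed, p_values = p,
       null_range = range(null_mat, na.rm = TRUE))
}

#' Correlate dimensions with stimulus features
#'
#' @param H k x n dimension-weight matrix (columns named by item id).
#' @param feature_table item x feature numeric data frame or matrix, rows
#'   aligned to (or named by) the items of \code{H}.
#' @return k x n_features matrix of Pearson correlations; constant feature
#'   columns or dimensions yield \code{NA}.
#' @export
feature_correlations <- function(H, feature_table) {
  F <- as.matrix(feature_table)
  if (!is.null(rownames(F)) && !is.null(colnames(H))) {
    missing <- setdiff(colnames(H), rownames(F))
    if (length(missing))
      stop_input("feature table lacks items: ", paste(missing, collapse = ", "))
    F <- F[colnames(H), , drop = FALSE]
  } else if (nrow(F) != ncol(H)) {
    stop_input("feature table rows must align with the items of H")
  }
  out <- suppressWarnings(cor(t(H), F))
  rownames(out) <- rownames(H)
  out
}

#' Stimulus-perturbation robustness analysis
#'
#' For each selector (category or setting label), removes the matching
#' stimuli, reruns the full selection pipeline (sparsity search and k
#' selection, per the original procedure) on the reduced dataset, matches
#' the new dimensions against the original ones restricted to the surviving
#' items, and tests the matches against a shuffle null.
#'
#' @param dataset the full [similarity_dataset()].
#' @param original a \code{selection_result} from [select_dimensions()] on
#'   the full dataset.
#' @param selectors character vector of category/setting labels to remove,
#'   one analysis per label.
#' @param n_iter shuffle iterations per analysis.
#' @param seed integer seed.
#' @param ... passed on to [select_dimensions()] (grid, k_range, reps, ...).
#' @return object of class \code{robustness_result}: a list with one entry
#'   per selector, each holding \code{removed_category}, \code{k_new},
#'   \code{match_r}, \code{p_values}, \code{null_range}, \code{result}.
#' @export
run_robustness <- function(dataset, original, selectors, n_iter = 1000,
                           seed = NULL, ...) {
  H_orig <- dimension_weights(original$model)
  seeds <- derive_seeds(seed, 2 * length(selectors))
  out <- lapply(seq_along(selectors), function(i) {
    sel <- selectors[i]
    reduced <- remove_stimuli(dataset, sel)
    res <- select_dimensions(reduced, seed = seeds[[2 * i - 1]], ...)
    H_new <- dimension_weights(res$model)
    nl <- shuffle_null(H_new, H_orig, surviving_items = colnames(H_new),
                       n_iter = n_iter, seed = seeds[[2 * i]])
    list(removed_category = sel,
         removed_items = attr(reduced, "removed_items"),
         k_new = res$k_selected,
         match_r = nl$observed,
         p_values = nl$p_values,
         null_range = nl$null_range,
         result = res)
  })
  names(out) <- selectors
  structure(out, class = "robustness_result")
}

#' @export
print.robustness_result <- function(x, ...) {
  for (r in x)
    cat(sprintf("- removed %-12s k = %d, mean match r = %.2f, min p = %.3g\n",
                r$removed_category, r$k_new, mean(r$match_r, na.rm = TRUE),
                min(r$p_values, na.rm = TRUE)))
  invisible(x)
}

#' Write a robustness report
#'
#' One row per (removed category, new dimension) with the match
#' correlation, its permutation p-value and the null range.
#'
#' @param robustness a \code{robustness_result}.
#' @param path output TSV path.
#' @return invisibly, \code{path}.
#' @export
write_robustness_report <- function(robustness, path) {
  rows <- do.call(rbind, lapply(robustness, function(r) {
    data.frame(removed_category = r$removed_category,
               new_dimension = seq_along(r$match_r),
               k_new = r$k_new,
               match_r = r$match_r,
               p = r$p_values,
               null_min = r$null_range[1],
               null_max = r$null_range[2])
  }))
  utils::write.table(rows, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
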