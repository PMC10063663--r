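#' Highest- and lowest-weighted videos along a dimension
#'
#' Items are ranked by the dimension's weights; ties break deterministically
#' by item order. Used to build odd-one-out trials from the top and bottom
#' eight.
#'
#' @param model an \code{nmf_model} (or a weight matrix from
#'   [dimension_weights()]).
#' @param dimension_id row index of the dimension.
#' @param n extreme-set size (default 8); requires at least \code{2 n}
#'   items.
#' @return list with character vectors \code{top} and \code{bottom}.
#' @export
extreme_videos <- function(model, dimension_id, n = 8) {
  H <- if (inherits(model, "nmf_model")) dimension_weights(model) else model
  w <- as.numeric(H[dimension_id, ])
  items <- colnames(H)
  if (is.null(items)) items <- as.character(seq_along(w))
  if (length(w) < 2 * n)
    stop_input("need at least ", 2 * n, " items")
  ord <- order(w, seq_along(w)) # ties resolved by item position
  bottom <- items[ord[seq_len(n)]]
  top <- items[rev(ord)[seq_len(n)]]
  if (w[ord[n]] == w[ord[n + 1L]] ||
      w[rev(ord)[n]] == w[rev(ord)[n + 1L]])
    warning("tied weights at an extreme-set boundary; split by item order")
  list(top = top, bottom = bottom)
}

#' Build odd-one-out trials for a dimension
#'
#' Each trial presents seven videos resampled from the dimension's top
#' eight and one from its bottom eight, in random order; the correct
#' response is the low-weighted odd one out.
#'
#' @inheritParams extreme_videos
#' @param n_trials trials per dimension (default 20).
#' @param seed integer seed.
#' @return data frame with columns \code{dimension_id}, \code{trial_idx},
#'   \code{low_item}, \code{is_catch} and the presented order
#'   \code{item_1 ... item_8}.
#' @export
build_trials <- function(model, dimension_id, n_trials = 20, seed = NULL) {
  ext <- extreme_videos(model, dimension_id)
  with_seed(seed, {
    rows <- lapply(seq_len(n_trials), function(t) {
      high <- sample(ext$top, 7)
      low <- sample(ext$bottom, 1)
      pres <- sample(c(high, low))
      c(list(dimension_id = dimension_id, trial_idx = t,
             low_item = low, is_catch = FALSE),
        setNames(as.list(pres), paste0("item_", 1:8)))
    })
    do.call(rbind, lapply(rows, as.data.frame))
  })
}

#' Score odd-one-out responses
#'
#' A response is correct iff the chosen item is the trial's low-weighted
#' item. Participants whose catch-trial accuracy is not strictly above
#' chance (12.5\%) are excluded before aggregation; accuracy is therefore
#' invariant to presentation order.
#'
#' @param trials trial table as from [build_trials()] (catch trials carry
#'   \code{is_catch = TRUE}), rows unique in
#'   \code{(dimension_id, trial_idx)}.
#' @param responses data frame with columns \code{participant_id},
#'   \code{dimension_id}, \code{trial_idx}, \code{chosen_item}.
#' @param catch_threshold exclusion bound on catch accuracy (strict;
#'   default 0.125).
#' @return object of class \code{validation_scores}: per-dimension accuracy,
#'   the participant x dimension accuracy matrix, and excluded participant
#'   ids.
#' @export
score_responses <- function(trials, responses, catch_threshold = 0.125) {
  key <- function(d, t) paste(d, t, sep = "\r")
  tk <- key(trials$dimension_id, trials$trial_idx)
  if (anyDuplicated(tk)) stop_input("duplicate (dimension_id, trial_idx) in trials")
  idx <- match(key(responses$dimension_id, responses$trial_idx), tk)
  if (anyNA(idx)) stop_input("responses reference unknown trials")
  pres <- as.matrix(trials[paste0("item_", 1:8)])
  ok <- vapply(seq_len(nrow(responses)), function(i)
    responses$chosen_item[i] %in% pres[idx[i], ], logical(1))
  if (!all(ok)) stop_input("responses reference items not presented in their trial")
  correct <- responses$chosen_item == trials$low_item[idx]
  is_catch <- trials$is_catch[idx]

  excluded <- character(0)
  if (any(is_catch)) {
    catch_acc <- tapply(correct[is_catch], responses$participant_id[is_catch], mean)
    excluded <- names(catch_acc)[catch_acc <= catch_threshold]
  }
  keep <- !(responses$participant_id %in% excluded) & !is_catch
  r <- responses[keep, , drop = FALSE]
  rc <- correct[keep]
  if (nrow(r) == 0L) {
    acc_mat <- matrix(numeric(0), 0, 0)
    dim_acc <- numeric(0)
  } else {
    acc_mat <- tapply(rc, list(r$participant_id, trials$dimension_id[idx[keep]]),
                      mean)
    dim_acc <- tapply(rc, trials$dimension_id[idx[keep]], mean)
  }
  structure(list(accuracy_per_dimension = dim_acc,
                 accuracy_matrix = acc_mat,
                 excluded_participants = excluded),
            class = "validation_scores")
}

#' Omnibus sign-permutation test of above-chance accuracy
#'
#' Each iteration flips the sign of every participant's accuracy deviation
#' from chance (one random sign per participant, shared across dimensions)
#' and records the maximum across dimensions of the mean deviation. The
#' max-statistic null provides familywise-error (omnibus) corrected
#' one-tailed p-values: \code{(1 + #(null_max >= observed)) / (n_iter + 1)}.
#'
#' @param accuracies participant x dimension accuracy matrix (NAs allowed;
#'   at least two participants).
#' @param chance chance level (default 0.125, one of eight).
#' @param n_iter permutation iterations (default 5000; below 1000 warns).
#' @param seed integer seed.
#' @return named vector of per-dimension corrected p-values.
#' @export
sign_permutation_test <- function(accuracies, chance = 0.125, n_iter = 5000,
                                  seed = NULL) {
  A <- as.matrix(accuracies) - chance
  if (nrow(A) < 2L) stop_input("need at least two participants")
  if (n_iter < 1000) warning("n_iter < 1000 gives a coarse null")
  observed <- colMeans(A, na.rm = TRUE)
  null_max <- with_seed(seed, {
    signs <- matrix(sample(c(-1, 1), n_iter * nrow(A), replace = TRUE),
                    n_iter, nrow(A))
    # per-column counts handle NAs in the accuracy matrix
    apply(signs, 1, function(s) {
      max(colMeans(A * s, na.rm = TRUE))
    })
  })
  p <- vapply(observed, function(o) (1 + sum(null_max >= o)) / (n_iter + 1),
              numeric(1))
  names(p) <- colnames(accuracies)
  p
}

#' Welch's unequal-variance t-test
#'
#' Two-sided t-test with Welch-Satterthwaite degrees of freedom, used to
#' compare per-dimension statistics between experiments.
#'
#' @param a,b numeric vectors (length at least 2 each).
#' @return list with \code{t}, \code{df}, \code{p}.
#' @export
welch_t <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L) stop_input("need at least two values per group")
  if (sd(a) == 0 && sd(b) == 0) stop_input("test undefined: zero variance in both groups")
  ht <- t.test(a, b, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value))
}

#' Read odd-one-out response and label files
#'
#' Responses: delimited text with header
#' \code{participant_id,dimension_id,trial_idx,chosen_item,is_catch}.
#' Labels: \code{participant_id,dimension_id,rank,label}.
#'
#' @param path file path.
#' @return a data frame.
#' @export
read_responses <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("participant_id", "dimension_id", "trial_idx", "chosen_item")
  if (!all(need %in% names(df)))
    stop_input("responses file must have columns ", paste(need, collapse = ", "))
  df
}

#' @rdname read_responses
#' @export
read_labels <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("participant_id", "dimension_id", "rank", "label")
  if (!all(need %in% names(df)))
    stop_input("labels file must have columns ", paste(need, collapse = ", "))
  df
}
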