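#' Define a stimulus set
#'
#' A stimulus set is an ordered collection of unique item identifiers,
#' optionally annotated with an action-category label and a scene setting
#' (\code{"indoors"} / \code{"outdoors"}) per item. Categories typically come
#' from the 18 everyday action categories of the American Time Use Survey
#' plus a \code{"control"} category.
#'
#' @param item_ids character vector of unique stimulus identifiers; their
#'   order fixes the item indexing used throughout the package.
#' @param categories optional named character vector mapping item ids to
#'   category labels.
#' @param setting optional named character vector mapping item ids to
#'   \code{"indoors"} or \code{"outdoors"}.
#' @return An object of class \code{stimulus_set}.
#' @export
#' @examples
#' stimulus_set(c("a", "b", "c"), categories = c(a = "eating", b = "eating"))
stimulus_set <- function(item_ids, categories = NULL, setting = NULL) {
  item_ids <- as.character(item_ids)
  if (length(item_ids) < 1L) stop_input("item_ids must be non-empty")
  if (anyDuplicated(item_ids)) stop_input("item_ids must be unique")
  check_map <- function(m, what) {
    if (is.null(m)) return(NULL)
    m <- vapply(m, as.character, character(1))
    if (is.null(names(m)) || any(!nzchar(names(m))))
      stop_input(what, " must be a named vector keyed by item id")
    bad <- setdiff(names(m), item_ids)
    if (length(bad))
      stop_input(what, " refers to unknown item ids: ", paste(bad, collapse = ", "))
    m
  }
  structure(list(item_ids = item_ids,
                 categories = check_map(categories, "categories"),
                 setting = check_map(setting, "setting")),
            class = "stimulus_set")
}

#' @export
print.stimulus_set <- function(x, ...) {
  cat("<stimulus_set> ", length(x$item_ids), " items",
      if (!is.null(x$categories))
        paste0("; ", length(unique(x$categories)), " categories"),
      "\n", sep = "")
  invisible(x)
}

#' Number of unordered item pairs
#'
#' @param n_items number of stimuli (at least 2).
#' @return \code{n_items * (n_items - 1) / 2}.
#' @export
#' @examples
#' pair_count(152) # 11476
#' pair_count(65)  # 2080
pair_count <- function(n_items) {
  if (!is.numeric(n_items) || length(n_items) != 1L || n_items < 2 ||
      n_items != round(n_items))
    stop_input("n_items must be a single integer >= 2")
  as.integer(n_items * (n_items - 1) / 2)
}

#' Assemble a similarity-judgment dataset
#'
#' Holds long-format pairwise dissimilarity ratings over a stimulus set.
#' Two sampling designs are supported: \code{"rating_sampled"}, where
#' different raters judged different item subsets so per-pair rating counts
#' vary (the 152-video design with 30-item subsets), and
#' \code{"participant_complete"}, where every participant rated every pair
#' (the 65-video design).
#'
#' @param ratings data frame with columns \code{unit_id} (participant or
#'   rating-occasion id), \code{item_a}, \code{item_b} (item ids) and
#'   \code{dissimilarity} (non-negative).
#' @param stimuli a [stimulus_set()].
#' @param mode \code{"rating_sampled"} or \code{"participant_complete"}.
#' @return An object of class \code{similarity_dataset}. Item pairs are
#'   stored in canonical order (first item earlier in the stimulus set) and a
#'   \code{rating_id} column indexes individual ratings.
#' @export
similarity_dataset <- function(ratings, stimuli,
                               mode = c("rating_sampled", "participant_complete")) {
  mode <- match.arg(mode)
  if (!inherits(stimuli, "stimulus_set")) stop_input("stimuli must be a stimulus_set")
  need <- c("unit_id", "item_a", "item_b", "dissimilarity")
  if (!all(need %in% names(ratings)))
    stop_input("ratings must have columns ", paste(need, collapse = ", "))
  ratings <- as.data.frame(ratings)[need]
  ratings$unit_id <- as.character(ratings$unit_id)
  ratings$item_a <- as.character(ratings$item_a)
  ratings$item_b <- as.character(ratings$item_b)
  ia <- match(ratings$item_a, stimuli$item_ids)
  ib <- match(ratings$item_b, stimuli$item_ids)
  if (anyNA(ia) || anyNA(ib)) stop_input("ratings reference unknown item ids")
  if (any(ia == ib)) stop_input("item_a and item_b must differ")
  if (any(!is.finite(ratings$dissimilarity)) || any(ratings$dissimilarity < 0))
    stop_input("dissimilarities must be finite and non-negative")
  # canonical pair order: first item earlier in the stimulus ordering
  swap <- ia > ib
  if (any(swap)) {
    tmp <- ratings$item_a[swap]
    ratings$item_a[swap] <- ratings$item_b[swap]
    ratings$item_b[swap] <- tmp
    t2 <- ia[swap]; ia[swap] <- ib[swap]; ib[swap] <- t2
  }
  ratings$rating_id <- seq_len(nrow(ratings))
  if (mode == "participant_complete") {
    n <- length(stimuli$item_ids)
    counts <- table(ratings$unit_id)
    if (any(counts != pair_count(n)))
      stop_input("participant_complete mode requires every unit to rate every pair")
  }
  structure(list(stimuli = stimuli, ratings = ratings, mode = mode),
            class = "similarity_dataset")
}

#' @export
print.similarity_dataset <- function(x, ...) {
  cat("<similarity_dataset> ", length(x$stimuli$item_ids), " items, ",
      length(unique(x$ratings$unit_id)), " units, ",
      nrow(x$ratings), " ratings (", x$mode, ")\n", sep = "")
  invisible(x)
}

#' Units of a dataset
#'
#' The sampling units a cross-validation plan partitions: individual rating
#' ids in \code{rating_sampled} mode, participant ids in
#' \code{participant_complete} mode.
#' @param dataset a [similarity_dataset()].
#' @return character vector of unit identifiers.
#' @export
dataset_units <- function(dataset) {
  if (dataset$mode == "rating_sampled") as.character(dataset$ratings$rating_id)
  else unique(dataset$ratings$unit_id)
}

#' Restrict a dataset to a subset of units
#'
#' @param dataset a [similarity_dataset()].
#' @param units unit ids as returned by [dataset_units()].
#' @return a \code{similarity_dataset} containing only the selected units'
#'   ratings (mode is kept; completeness is not re-enforced).
#' @export
subset_units <- function(dataset, units) {
  units <- as.character(units)
  if (length(units) == 0L) stop_input("empty unit selection")
  keep <- if (dataset$mode == "rating_sampled")
    as.character(dataset$ratings$rating_id) %in% units
  else dataset$ratings$unit_id %in% units
  if (!any(keep)) stop_input("no ratings match the selected units")
  out <- dataset
  out$ratings <- dataset$ratings[keep, , drop = FALSE]
  out
}

#' Average ratings into a dissimilarity matrix
#'
#' Each pair's value is the arithmetic mean of that pair's individual ratings
#' among the selected units (ratings are pooled, not averaged per unit
#' first). Pairs with no rating are marked unobserved; the diagonal is zero
#' dissimilarity and always observed.
#'
#' @param dataset a [similarity_dataset()].
#' @param units unit ids to include; default all units.
#' @return a [similarity_matrix()] of dissimilarities.
#' @export
aggregate_ratings <- function(dataset, units = NULL) {
  if (is.null(units)) units <- dataset_units(dataset)
  ds <- subset_units(dataset, units)
  ids <- ds$stimuli$item_ids
  n <- length(ids)
  ia <- match(ds$ratings$item_a, ids)
  ib <- match(ds$ratings$item_b, ids)
  key <- (ia - 1L) * n + ib
  sums <- rowsum(ds$ratings$dissimilarity, key)
  counts <- rowsum(rep(1, length(key)), key)
  vals <- matrix(0, n, n, dimnames = list(ids, ids))
  obs <- matrix(FALSE, n, n, dimnames = list(ids, ids))
  k <- as.integer(rownames(sums))
  i <- (k - 1L) %/% n + 1L
  j <- (k - 1L) %% n + 1L
  m <- sums[, 1] / counts[, 1]
  vals[cbind(i, j)] <- m; vals[cbind(j, i)] <- m
  obs[cbind(i, j)] <- TRUE; obs[cbind(j, i)] <- TRUE
  diag(obs) <- TRUE
  similarity_matrix(vals, observed = obs, items = ids)
}

#' Read / write long-format ratings files
#'
#' The ratings file is delimited text with header
#' \code{unit_id,item_a,item_b,dissimilarity}.
#'
#' @param path file path.
#' @param stimuli optional [stimulus_set()]; inferred from the file when
#'   omitted (items ordered by first appearance).
#' @param mode dataset mode, see [similarity_dataset()].
#' @return \code{read_ratings} returns a [similarity_dataset()];
#'   \code{write_ratings} invisibly returns \code{path}.
#' @export
read_ratings <- function(path, stimuli = NULL,
                         mode = c("rating_sampled", "participant_complete")) {
  mode <- match.arg(mode)
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (is.null(stimuli))
    stimuli <- stimulus_set(unique(c(df$item_a, df$item_b)))
  similarity_dataset(df, stimuli, mode)
}

#' @rdname read_ratings
#' @param dataset a [similarity_dataset()] to write.
#' @export
write_ratings <- function(dataset, path) {
  write.csv(dataset$ratings[c("unit_id", "item_a", "item_b", "dissimilarity")],
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
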