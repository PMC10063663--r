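#' Square symmetric similarity/dissimilarity matrix with missingness mask
#'
#' @param values n x n symmetric non-negative numeric matrix.
#' @param observed n x n logical mask of observed entries (symmetric; the
#'   diagonal is observed by convention). Default: everything observed.
#' @param items item ids; default the row names of \code{values}.
#' @return An object of class \code{similarity_matrix} with fields
#'   \code{items}, \code{values}, \code{observed}.
#' @export
similarity_matrix <- function(values, observed = NULL, items = rownames(values)) {
  values <- as.matrix(values)
  n <- nrow(values)
  if (ncol(values) != n) stop_input("values must be square")
  if (is.null(items)) items <- as.character(seq_len(n))
  items <- as.character(items)
  if (length(items) != n || anyDuplicated(items))
    stop_input("items must be n unique ids")
  if (is.null(observed)) observed <- matrix(TRUE, n, n)
  observed <- as.matrix(observed)
  storage.mode(observed) <- "logical"
  if (!identical(dim(observed), dim(values)))
    stop_input("observed mask must match values in shape")
  diag(observed) <- TRUE
  if (!isTRUE(all.equal(values, t(values), tolerance = 1e-8)) ||
      !identical(observed, t(observed)))
    stop_input("values and mask must be symmetric")
  if (any(!is.finite(values[observed])) || any(values[observed] < 0))
    stop_input("observed values must be finite and non-negative")
  dimnames(values) <- dimnames(observed) <- list(items, items)
  structure(list(items = items, values = values, observed = observed),
            class = "similarity_matrix")
}

#' @export
print.similarity_matrix <- function(x, ...) {
  n <- length(x$items)
  off <- upper.tri(x$observed)
  cat("<similarity_matrix> ", n, " x ", n, "; ",
      sum(x$observed[off]), "/", sum(off), " pairs observed\n", sep = "")
  invisible(x)
}

#' Convert a dissimilarity matrix to a bounded similarity matrix
#'
#' Applies \code{S = 1 - D / max(D)} over observed off-diagonal entries and
#' sets the diagonal to 1, so observed similarities lie in \[0, 1\]. The
#' missingness mask is preserved.
#'
#' @param D a [similarity_matrix()] holding dissimilarities.
#' @return a [similarity_matrix()] of similarities.
#' @export
to_similarity <- function(D) {
  stopifnot(inherits(D, "similarity_matrix"))
  off <- D$observed & !diag(TRUE, length(D$items))
  if (!any(off)) stop_input("no observed off-diagonal entries")
  mx <- max(D$values[off])
  if (mx <= 0) stop_input("degenerate input: all observed dissimilarities are zero")
  S <- 1 - D$values / mx
  S[!D$observed] <- 0
  diag(S) <- 1
  similarity_matrix(S, observed = D$observed, items = D$items)
}

#' Impute missing similarities from row minima
#'
#' Each missing entry \code{S[a, b]} is replaced by
#' \code{max(min_c S[a, c], min_c S[b, c])}, the minima running over each
#' item's \emph{observed} off-diagonal similarities. All missing entries are
#' imputed simultaneously from the observed data, so the operation is
#' idempotent and never alters observed entries.
#'
#' @param S a [similarity_matrix()] of similarities.
#' @return a fully observed [similarity_matrix()].
#' @export
impute_missing <- function(S) {
  stopifnot(inherits(S, "similarity_matrix"))
  n <- length(S$items)
  off_obs <- S$observed & !diag(TRUE, n)
  row_min <- vapply(seq_len(n), function(i) {
    v <- S$values[i, off_obs[i, ]]
    if (length(v) == 0L) NA_real_ else min(v)
  }, numeric(1))
  if (anyNA(row_min)) {
    bad <- S$items[is.na(row_min)]
    stop_input("items with no observed off-diagonal entry: ",
               paste(bad, collapse = ", "))
  }
  vals <- S$values
  miss <- which(!S$observed & upper.tri(S$observed), arr.ind = TRUE)
  if (nrow(miss)) {
    imp <- pmax(row_min[miss[, 1]], row_min[miss[, 2]])
    vals[miss] <- imp
    vals[miss[, c(2, 1), drop = FALSE]] <- imp
  }
  similarity_matrix(vals, observed = matrix(TRUE, n, n), items = S$items)
}

#' Vectorize the unique pairs of a symmetric matrix
#'
#' Off-diagonal lower-triangle entries in a fixed column-major pair order
#' (item pairs (2,1), (3,1), ..., (n, n-1)); length \code{pair_count(n)}.
#' All rank-correlation evaluations in the package operate on this vector,
#' excluding the diagonal.
#'
#' @param S a [similarity_matrix()] or square symmetric matrix.
#' @return numeric vector of the unique off-diagonal entries.
#' @export
lower_triangle <- function(S) {
  v <- if (inherits(S, "similarity_matrix")) S$values else as.matrix(S)
  if (nrow(v) != ncol(v)) stop_input("matrix must be square")
  v[lower.tri(v)]
}

#' Kendall tau-a rank correlation
#'
#' \eqn{\tau_A = (n_c - n_d) / (n(n-1)/2)}: pairs tied in either vector
#' count as neither concordant nor discordant, and the denominator is the
#' total number of pairs (the tau-a variant, not the tie-corrected tau-b).
#'
#' @param x,y numeric vectors of equal length (at least 2).
#' @return correlation in \[-1, 1\].
#' @export
#' @examples
#' kendall_tau_a(c(1, 2, 3), c(1, 3, 2)) # 1/3
kendall_tau_a <- function(x, y) {
  if (length(x) != length(y)) stop_input("x and y must have equal length")
  if (length(x) < 2L) stop_input("need at least two observations")
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop_input("inputs must be finite")
  cpp_kendall_tau_a(as.numeric(x), as.numeric(y))
}

# tau-a between the unique pairs of two similarity matrices
tau_between <- function(A, B) {
  kendall_tau_a(lower_triangle(A), lower_triangle(B))
}

#' Read / write a similarity matrix as delimited text
#'
#' First row and column carry item ids; empty cells are unobserved entries.
#'
#' @param path file path.
#' @return \code{read_matrix} returns a [similarity_matrix()];
#'   \code{write_matrix} invisibly returns \code{path}.
#' @export
read_matrix <- function(path) {
  df <- read.csv(path, row.names = 1, check.names = FALSE)
  m <- as.matrix(df)
  storage.mode(m) <- "double"
  obs <- !is.na(m)
  m[is.na(m)] <- 0
  similarity_matrix(m, observed = obs, items = rownames(m))
}

#' @rdname read_matrix
#' @param S a [similarity_matrix()] to write.
#' @export
write_matrix <- function(S, path) {
  m <- S$values
  m[!S$observed] <- NA
  write.csv(m, path, row.names = TRUE, na = "")
  invisible(path)
}
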