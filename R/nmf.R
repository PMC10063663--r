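#' Hoyer sparseness of a non-negative vector
#'
#' \eqn{(\sqrt{n} - \|v\|_1/\|v\|_2) / (\sqrt{n} - 1)}: 0 for a constant
#' vector, 1 for a one-hot vector.
#'
#' @param v non-negative numeric vector with at least two entries.
#' @return sparseness in \[0, 1\].
#' @export
hoyer_sparseness <- function(v) {
  if (length(v) < 2L) stop_input("need at least two entries")
  if (any(v < 0)) stop_input("v must be non-negative")
  l2 <- sqrt(sum(v^2))
  if (l2 == 0) stop_input("sparseness undefined for an all-zero vector")
  n <- length(v)
  (sqrt(n) - sum(v) / l2) / (sqrt(n) - 1)
}

#' Project a vector to a target Hoyer sparseness
#'
#' Returns the closest (Euclidean) non-negative vector with the same L2 norm
#' as \code{v} and L1 norm chosen so its Hoyer sparseness equals \code{s}.
#'
#' @param v non-negative numeric vector.
#' @param s target sparseness, strictly between 0 and 1.
#' @return projected vector; its sparseness matches \code{s} to within 1e-6.
#' @export
project_sparseness <- function(v, s) {
  if (!is.numeric(s) || length(s) != 1L || s <= 0 || s >= 1)
    stop_input("s must lie strictly between 0 and 1")
  if (any(v < 0)) stop_input("v must be non-negative")
  n <- length(v)
  if (n < 2L) stop_input("need at least two entries")
  l2 <- sqrt(sum(v^2))
  if (l2 == 0) stop_input("cannot project an all-zero vector")
  l1 <- l2 * (sqrt(n) - s * (sqrt(n) - 1))
  out <- cpp_hoyer_project(as.numeric(v), l1, l2)
  if (abs(hoyer_sparseness(out) - s) > 1e-6)
    stop_input("projection failed to reach the target sparseness")
  out
}

#' Non-negative double SVD initialization (NNDSVD)
#'
#' Deterministic NMF initialization built from the leading k singular
#' triplets with negative parts zeroed (the standard positive/negative
#' section choice per component).
#'
#' @param V non-negative numeric matrix.
#' @param k rank, at most \code{min(dim(V))}.
#' @return list with non-negative matrices \code{W} (n x k) and \code{H}
#'   (k x m).
#' @export
nndsvd_init <- function(V, k) {
  V <- as.matrix(V)
  if (any(V < 0)) stop_input("V must be non-negative")
  if (k < 1 || k > min(dim(V))) stop_input("invalid rank k")
  sv <- svd(V, nu = k, nv = k)
  n <- nrow(V); m <- ncol(V)
  W <- matrix(0, n, k); H <- matrix(0, k, m)
  u1 <- sv$u[, 1]
  if (sum(u1) < 0) u1 <- -u1
  v1 <- sv$v[, 1]
  if (sum(v1) < 0) v1 <- -v1
  W[, 1] <- sqrt(sv$d[1]) * abs(u1)
  H[1, ] <- sqrt(sv$d[1]) * abs(v1)
  if (k > 1) {
    for (j in 2:k) {
      x <- sv$u[, j]; y <- sv$v[, j]
      xp <- pmax(x, 0); xn <- pmax(-x, 0)
      yp <- pmax(y, 0); yn <- pmax(-y, 0)
      nxp <- sqrt(sum(xp^2)); nxn <- sqrt(sum(xn^2))
      nyp <- sqrt(sum(yp^2)); nyn <- sqrt(sum(yn^2))
      mp <- nxp * nyp; mn <- nxn * nyn
      if (mp >= mn) {
        if (mp > 0) {
          W[, j] <- sqrt(sv$d[j] * mp) * xp / nxp
          H[j, ] <- sqrt(sv$d[j] * mp) * yp / nyp
        }
      } else {
        W[, j] <- sqrt(sv$d[j] * mn) * xn / nxn
        H[j, ] <- sqrt(sv$d[j] * mn) * yn / nyn
      }
    }
  }
  list(W = W, H = H)
}

#' Fit a sparse non-negative matrix factorization
#'
#' Factorizes a fully observed non-negative matrix \code{V} as \code{W H}
#' with \code{k} dimensions. An unconstrained factor (\code{s = 0}) follows
#' multiplicative updates; a constrained factor takes a gradient step with an
#' adaptive step size followed by a Hoyer sparseness projection
#' (\code{s_w} applies to columns of \code{W}, \code{s_h} to rows of
#' \code{H}). Initialization defaults to [nndsvd_init()], making fits fully
#' deterministic. Standard (non-symmetric) NMF is run even on symmetric
#' input; for similarity matrices the two factors end up highly correlated,
#' so rows of \code{H} are used as the dimension weights downstream.
#'
#' @param V a [similarity_matrix()] (fully observed; impute first) or a
#'   plain non-negative matrix.
#' @param k number of dimensions.
#' @param s_w,s_h sparsity parameters in \[0, 0.8\]; 0 means unconstrained.
#' @param init optional initialization: an \code{nmf_model} or a
#'   \code{list(W, H)}; zeros in multiplicative-path factors are filled
#'   with \code{mean(V) / 100} so multiplicative updates cannot lock on
#'   exact zeros.
#' @param max_iter,tol stopping rule: stop when the relative loss change
#'   falls below \code{tol} or after \code{max_iter} iterations.
#' @return an object of class \code{nmf_model}: fields \code{W}, \code{H},
#'   \code{k}, \code{s_w}, \code{s_h}, \code{loss_trace}, \code{converged},
#'   \code{iterations}, \code{items}.
#' @export
nmf_fit <- function(V, k, s_w = 0, s_h = 0, init = NULL,
                    max_iter = 500, tol = 1e-5) {
  items <- NULL
  if (inherits(V, "similarity_matrix")) {
    if (!all(V$observed)) stop_input("V must be fully observed; impute first")
    items <- V$items
    V <- V$values
  }
  V <- as.matrix(V)
  if (any(!is.finite(V))) stop_input("V contains non-finite entries")
  if (any(V < 0)) stop_input("V must be non-negative")
  if (k < 1 || k > min(dim(V))) stop_input("invalid rank k")
  for (s in c(s_w, s_h))
    if (s < 0 || s >= 1) stop_input("sparsity parameters must lie in [0, 1)")
  if (is.null(init)) init <- nndsvd_init(V, k)
  W0 <- as.matrix(init$W); H0 <- as.matrix(init$H)
  if (!identical(dim(W0), c(nrow(V), as.integer(k))) ||
      !identical(dim(H0), c(as.integer(k), ncol(V))))
    stop_input("init factors have wrong shape for this V and k")
  eps0 <- max(mean(V) / 100, 1e-12)
  if (s_w == 0) W0[W0 <= 0] <- eps0
  if (s_h == 0) H0[H0 <= 0] <- eps0
  fit <- cpp_nmf_fit(V, W0, H0, s_w, s_h, as.integer(max_iter), tol)
  if (isTRUE(fit$diverged))
    stop(structure(class = c("nmf_divergence", "error", "condition"),
                   list(message = "NMF loss diverged", call = NULL)))
  structure(list(W = fit$W, H = fit$H, k = as.integer(k),
                 s_w = s_w, s_h = s_h,
                 loss_trace = fit$loss_trace,
                 converged = isTRUE(fit$converged),
                 iterations = fit$iterations,
                 items = items),
            class = "nmf_model")
}

#' @export
print.nmf_model <- function(x, ...) {
  cat("<nmf_model> k = ", x$k, ", s_w = ", x$s_w, ", s_h = ", x$s_h,
      "; ", x$iterations, " iterations (",
      if (x$converged) "converged" else "max_iter reached", ")\n", sep = "")
  invisible(x)
}

#' Reconstruct the approximated matrix W H
#'
#' @param model an \code{nmf_model}.
#' @return numeric matrix \code{W \%*\% H}.
#' @export
reconstruct <- function(model) {
  stopifnot(inherits(model, "nmf_model"))
  model$W %*% model$H
}

#' Correlation between the two factors of a fit
#'
#' Pearson correlation between vectorized \code{W} and \code{t(H)}; close to
#' 1 for fits to symmetric matrices, where standard NMF behaves like
#' symmetric NMF.
#'
#' @param model an \code{nmf_model}.
#' @return Pearson r.
#' @export
factor_symmetry <- function(model) {
  stopifnot(inherits(model, "nmf_model"))
  a <- as.numeric(model$W)
  b <- as.numeric(t(model$H))
  if (sd(a) == 0 || sd(b) == 0)
    stop_input("correlation undefined for constant factor matrices")
  cor(a, b)
}

#' Dimension weights of a fitted model
#'
#' Rows of \code{H}, the package-wide convention for per-item dimension
#' weights (equivalently columns of \code{W} given factor symmetry on
#' similarity matrices).
#'
#' @param model an \code{nmf_model}.
#' @return k x n matrix, columns named by item ids when known.
#' @export
dimension_weights <- function(model) {
  H <- model$H
  if (!is.null(model$items)) colnames(H) <- model$items
  rownames(H) <- paste0("dim", seq_len(nrow(H)))
  H
}

#' Serialize / load a fitted model
#'
#' Writes a directory with delimited-text \code{W.tsv}, \code{H.tsv} and a
#' \code{model.json} sidecar (k, sparsity parameters, final loss,
#' convergence, iteration count).
#'
#' @param model an \code{nmf_model}.
#' @param dir directory to create/fill.
#' @return \code{write_nmf_model} invisibly returns \code{dir};
#'   \code{read_nmf_model} returns the \code{nmf_model}.
#' @export
write_nmf_model <- function(model, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(model$W, file.path(dir, "W.tsv"), sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(model$H, file.path(dir, "H.tsv"), sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  meta <- list(k = model$k, s_w = model$s_w, s_h = model$s_h,
               loss = model$loss_trace[length(model$loss_trace)],
               converged = model$converged, iterations = model$iterations,
               items = model$items)
  jsonlite::write_json(meta, file.path(dir, "model.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(dir)
}

#' @rdname write_nmf_model
#' @export
read_nmf_model <- function(dir) {
  W <- as.matrix(utils::read.table(file.path(dir, "W.tsv"), sep = "\t"))
  H <- as.matrix(utils::read.table(file.path(dir, "H.tsv"), sep = "\t"))
  dimnames(W) <- dimnames(H) <- NULL
  meta <- jsonlite::read_json(file.path(dir, "model.json"), simplifyVector = TRUE)
  structure(list(W = W, H = H, k = as.integer(meta$k),
                 s_w = meta$s_w, s_h = meta$s_h,
                 loss_trace = meta$loss, converged = meta$converged,
                 iterations = meta$iterations,
                 items = if (is.null(meta$items)) NULL else as.character(meta$items)),
            class = "nmf_model")
}
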