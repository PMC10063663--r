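#' Read word vectors in the standard text format
#'
#' First line \code{"vocab_size dim"}, then one token followed by its
#' floating-point coordinates per line (the word2vec/fastText text layout).
#'
#' @param path file path.
#' @param vocab optional character vector: read only these tokens.
#' @return numeric matrix, one row per token, row names = tokens.
#' @export
read_word_vectors <- function(path, vocab = NULL) {
  lines <- readLines(path)
  hdr <- as.integer(strsplit(trimws(lines[1]), "\\s+")[[1]])
  if (length(hdr) != 2L || anyNA(hdr))
    stop_input("first line must be 'vocab_size dim'")
  dim_len <- hdr[2]
  body <- lines[-1]
  toks <- sub("\\s.*$", "", body)
  if (!is.null(vocab)) body <- body[toks %in% vocab]
  if (length(body) == 0L) return(matrix(numeric(0), 0, dim_len))
  parts <- strsplit(trimws(body), "\\s+")
  bad <- lengths(parts) != dim_len + 1L
  if (any(bad)) stop_input("malformed vector line(s): ", which(bad)[1])
  m <- t(vapply(parts, function(p) as.numeric(p[-1]), numeric(dim_len)))
  rownames(m) <- vapply(parts, `[[`, character(1), 1L)
  m
}

#' Attach embeddings to participant labels
#'
#' Single-word labels take their token's vector; multi-word labels average
#' the vectors of their in-vocabulary tokens. Labels with no in-vocabulary
#' token are dropped with a message reporting the count.
#'
#' @param labels data frame with columns \code{participant_id},
#'   \code{dimension_id}, \code{rank}, \code{label} (see [read_labels()]).
#' @param vectors word-vector matrix from [read_word_vectors()].
#' @return object of class \code{label_embedding_table}: the label data
#'   frame plus a \code{vectors} matrix (one row per retained label).
#' @export
embed_labels <- function(labels, vectors) {
  if (any(!nzchar(labels$label))) stop_input("labels must be non-empty")
  emb <- lapply(tolower(labels$label), function(lab) {
    toks <- strsplit(lab, "[^a-z0-9']+")[[1]]
    toks <- toks[toks %in% rownames(vectors)]
    if (length(toks) == 0L) return(NULL)
    colMeans(vectors[toks, , drop = FALSE])
  })
  oov <- vapply(emb, is.null, logical(1))
  if (any(oov))
    message(sum(oov), " label(s) dropped as out-of-vocabulary")
  label_embedding_table(labels[!oov, , drop = FALSE],
                        do.call(rbind, emb[!oov]))
}

#' Construct a label-embedding table directly
#'
#' @param labels label data frame (\code{participant_id},
#'   \code{dimension_id}, \code{rank}, \code{label}).
#' @param vectors numeric matrix, one row per label row, all rows the same
#'   length (default 300 in the pretrained-embedding use case).
#' @return object of class \code{label_embedding_table}.
#' @export
label_embedding_table <- function(labels, vectors) {
  vectors <- as.matrix(vectors)
  if (nrow(vectors) != nrow(labels))
    stop_input("one vector row per label row required")
  need <- c("participant_id", "dimension_id", "rank", "label")
  if (!all(need %in% names(labels)))
    stop_input("labels must have columns ", paste(need, collapse = ", "))
  structure(list(labels = as.data.frame(labels), vectors = vectors),
            class = "label_embedding_table")
}

#' Apply declarative label-cleanup rules
#'
#' Supports the antonym-pair rule used during label curation: for rows
#' listed in the rules table (columns \code{participant_id},
#' \code{dimension_id}), only the first-listed (lowest rank) label is kept.
#'
#' @param labels label data frame.
#' @param rules data frame with columns \code{participant_id},
#'   \code{dimension_id}.
#' @return filtered label data frame.
#' @export
apply_label_rules <- function(labels, rules) {
  key <- function(p, d) paste(p, d, sep = "\r")
  flagged <- key(labels$participant_id, labels$dimension_id) %in%
    key(rules$participant_id, rules$dimension_id)
  keep_first <- !flagged
  for (k in unique(key(labels$participant_id, labels$dimension_id)[flagged])) {
    idx <- which(key(labels$participant_id, labels$dimension_id) == k)
    keep_first[idx[which.min(labels$rank[idx])]] <- TRUE
  }
  labels[keep_first, , drop = FALSE]
}

# all pairwise Euclidean distances between rows of two matrices
euclidean_cross <- function(A, B) {
  sq <- outer(rowSums(A^2), rowSums(B^2), `+`) - 2 * A %*% t(B)
  sqrt(pmax(sq, 0))
}

# pooled within-dimension pairwise distances across a list of tables
pooled_within_distances <- function(tables) {
  unlist(lapply(tables, function(tb) {
    unlist(lapply(split(seq_len(nrow(tb$labels)), tb$labels$dimension_id),
                  function(idx) {
                    if (length(idx) < 2L) return(numeric(0))
                    as.numeric(dist(tb$vectors[idx, , drop = FALSE]))
                  }))
  }), use.names = FALSE)
}

#' Label agreement via embedding distances
#'
#' Within-dimension pairwise Euclidean distances are pooled across all
#' supplied tables (all dimensions, all experiments) and the relatedness
#' threshold is their 10th percentile. A participant counts as agreeing on
#' a dimension if their first-listed label lies strictly below the
#' threshold from some other participant's label for that dimension; the
#' chance level is the proportion of across-dimension label pairs below the
#' same threshold.
#'
#' @param tables a \code{label_embedding_table} or list of them (e.g. one
#'   per experiment; the pooled percentile then spans both).
#' @param threshold override the pooled-percentile threshold (e.g. a
#'   pre-registered value such as 1.2).
#' @param probs percentile for the threshold (default 0.1).
#' @return list: \code{agreement} (per table, named per-dimension
#'   proportions), \code{threshold}, \code{chance}.
#' @export
label_agreement <- function(tables, threshold = NULL, probs = 0.1) {
  if (inherits(tables, "label_embedding_table")) tables <- list(tables)
  lens <- unique(vapply(tables, function(tb) ncol(tb$vectors), integer(1)))
  if (length(lens) != 1L) stop_input("all tables must share one vector length")
  counts <- unlist(lapply(tables, function(tb)
    table(tb$labels$dimension_id)))
  if (any(counts < 2L)) stop_input("every dimension needs at least two labels")
  if (is.null(threshold))
    threshold <- unname(quantile(pooled_within_distances(tables), probs,
                                 type = 7))
  agreement <- lapply(tables, function(tb) {
    dims <- unique(tb$labels$dimension_id)
    vapply(setNames(dims, dims), function(d) {
      idx <- which(tb$labels$dimension_id == d)
      lab <- tb$labels[idx, , drop = FALSE]
      V <- tb$vectors[idx, , drop = FALSE]
      participants <- unique(lab$participant_id)
      agree <- vapply(participants, function(p) {
        own <- which(lab$participant_id == p)
        top <- own[which.min(lab$rank[own])]
        others <- which(lab$participant_id != p)
        if (length(others) == 0L) return(FALSE)
        dmin <- min(euclidean_cross(V[top, , drop = FALSE],
                                    V[others, , drop = FALSE]))
        dmin < threshold
      }, logical(1))
      mean(agree)
    }, numeric(1))
  })
  # chance: across-dimension label pairs (pooled over tables) below threshold
  all_vec <- do.call(rbind, lapply(tables, `[[`, "vectors"))
  all_dim <- unlist(lapply(seq_along(tables), function(i)
    paste(i, tables[[i]]$labels$dimension_id, sep = "\r")))
  D <- euclidean_cross(all_vec, all_vec)
  cross <- outer(all_dim, all_dim, `!=`) & upper.tri(D)
  chance <- mean(D[cross] < threshold)
  if (length(agreement) == 1L) agreement <- agreement[[1]]
  list(agreement = agreement, threshold = threshold, chance = chance)
}

#' Cross-experiment distances between dimension embeddings
#'
#' Embeddings are averaged across labels within each dimension; the output
#' is the Euclidean distance between every pair of averaged dimension
#' vectors across the two tables.
#'
#' @param table1,table2 \code{label_embedding_table}s with equal vector
#'   length (e.g. the two experiments).
#' @return k1 x k2 distance matrix with dimension ids as dimnames; empty
#'   dimensions are excluded with a warning.
#' @export
dimension_distances <- function(table1, table2) {
  if (ncol(table1$vectors) != ncol(table2$vectors))
    stop_input("tables must share one vector length")
  mean_by_dim <- function(tb) {
    groups <- split(seq_len(nrow(tb$labels)), tb$labels$dimension_id)
    empty <- names(groups)[lengths(groups) == 0L]
    if (length(empty)) {
      warning("excluding empty dimension(s): ", paste(empty, collapse = ", "))
      groups <- groups[lengths(groups) > 0L]
    }
    t(vapply(groups, function(idx)
      colMeans(tb$vectors[idx, , drop = FALSE]), numeric(ncol(tb$vectors))))
  }
  euclidean_cross(mean_by_dim(table1), mean_by_dim(table2))
}
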