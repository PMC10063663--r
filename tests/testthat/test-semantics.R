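write_vec_file <- function(path, tokens, vectors) {
  lines <- c(paste(length(tokens), ncol(vectors)),
             vapply(seq_along(tokens), function(i)
               paste(tokens[i], paste(format(vectors[i, ], scientific = FALSE),
                                      collapse = " ")),
               character(1)))
  writeLines(lines, path)
}

test_that("word-vector files parse in the standard text layout", {
  withr::with_seed(51, {
    toks <- c("eating", "nature", "work", "children")
    V <- matrix(round(rnorm(4 * 5), 4), 4, 5)
    f <- withr::local_tempfile(fileext = ".vec")
    write_vec_file(f, toks, V)
    m <- read_word_vectors(f)
    expect_identical(rownames(m), toks)
    expect_equal(unname(m), V, tolerance = 1e-8)
    m2 <- read_word_vectors(f, vocab = c("work", "nature"))
    expect_setequal(rownames(m2), c("work", "nature"))
    writeLines(c("2 3", "a 1 2"), f)
    expect_error(read_word_vectors(f), "malformed")
  })
})

test_that("labels embed by token averaging and drop out-of-vocabulary", {
  withr::with_seed(52, {
    vocab <- matrix(rnorm(3 * 4), 3, 4,
                    dimnames = list(c("washing", "dishes", "nature"), NULL))
    labels <- data.frame(participant_id = c("p1", "p1", "p2"),
                         dimension_id = 1, rank = c(1, 2, 1),
                         label = c("washing dishes", "nature", "zzzz"))
    expect_message(tb <- embed_labels(labels, vocab), "1 label")
    expect_equal(nrow(tb$labels), 2)
    expect_equal(tb$vectors[1, ], colMeans(vocab[c("washing", "dishes"), ]))
    expect_equal(tb$vectors[2, ], vocab["nature", ])
  })
})

test_that("antonym rule keeps only the first-listed label", {
  labels <- data.frame(participant_id = c("p1", "p1", "p2"),
                       dimension_id = 1, rank = c(1, 2, 1),
                       label = c("nature", "home", "nature"))
  rules <- data.frame(participant_id = "p1", dimension_id = 1)
  out <- apply_label_rules(labels, rules)
  expect_equal(out$label, c("nature", "nature"))
})

test_that("pooled threshold equals a sort-based percentile oracle", {
  withr::with_seed(53, {
    tb1 <- simulate_label_embeddings(3, 6, within_sd = 0.3, between_sep = 2,
                                     vec_len = 20, seed = 54)
    tb2 <- simulate_label_embeddings(4, 5, within_sd = 0.3, between_sep = 2,
                                     vec_len = 20, seed = 55)
    ag <- label_agreement(list(tb1, tb2))
    # oracle: pool within-dimension pairwise distances, sort, interpolate
    pool <- c()
    for (tb in list(tb1, tb2)) {
      for (d in unique(tb$labels$dimension_id)) {
        V <- tb$vectors[tb$labels$dimension_id == d, , drop = FALSE]
        for (i in seq_len(nrow(V) - 1))
          for (j in (i + 1):nrow(V))
            pool <- c(pool, sqrt(sum((V[i, ] - V[j, ])^2)))
      }
    }
    srt <- sort(pool)
    h <- (length(srt) - 1) * 0.1 + 1
    oracle <- srt[floor(h)] + (h - floor(h)) * (srt[ceiling(h)] - srt[floor(h)])
    expect_equal(ag$threshold, oracle, tolerance = 1e-12)
    expect_lte(ag$chance, 1)
  })
})

test_that("clustered embeddings drive agreement up and chance down", {
  # chance (across-dimension relatedness) falls as cluster separation grows
  near <- label_agreement(simulate_label_embeddings(
    5, 40, within_sd = 0.05, between_sep = 0.3, vec_len = 50, seed = 56))
  far <- label_agreement(simulate_label_embeddings(
    5, 40, within_sd = 0.05, between_sep = 10, vec_len = 50, seed = 56))
  expect_lt(far$chance, 0.01)
  expect_gt(near$chance, far$chance)
  # a dimension much tighter than the pooled threshold reaches full
  # agreement; dimensions looser than the threshold get none
  withr::with_seed(90, {
    k <- 5; n <- 40; d <- 50
    centers <- cbind(diag(10 / sqrt(2), k), matrix(0, k, d - k))
    sds <- c(0.05, rep(1, k - 1))
    rows <- expand.grid(participant_id = sprintf("lab%02d", seq_len(n)),
                        dimension_id = seq_len(k), stringsAsFactors = FALSE)
    vecs <- centers[rows$dimension_id, , drop = FALSE] +
      matrix(rnorm(nrow(rows) * d), nrow(rows), d) * sds[rows$dimension_id]
    mixed <- label_embedding_table(
      data.frame(rows, rank = 1L,
                 label = paste0("l", seq_len(nrow(rows)))), vecs)
    ag <- label_agreement(mixed)
    expect_gte(ag$agreement[["1"]], 0.9)
    expect_true(all(ag$agreement[as.character(2:5)] < ag$agreement[["1"]]))
  })
  # identical labels (distance zero) always count as related
  tb <- label_embedding_table(
    data.frame(participant_id = c("p1", "p2", "p3"), dimension_id = 1,
               rank = 1, label = "same"),
    matrix(1, 3, 4))
  ag <- label_agreement(tb, threshold = 1.2)
  expect_equal(unname(ag$agreement["1"]), 1)
})

test_that("dimension distances average labels then compare across experiments", {
  tb1 <- simulate_label_embeddings(10, 4, within_sd = 0.1, between_sep = 3,
                                   vec_len = 30, seed = 57)
  tb2 <- simulate_label_embeddings(9, 4, within_sd = 0.1, between_sep = 3,
                                   vec_len = 30, seed = 58)
  D <- dimension_distances(tb1, tb2)
  expect_equal(dim(D), c(10L, 9L))
  expect_true(all(D >= 0))
  # a table against itself: zero diagonal, symmetric
  Dself <- dimension_distances(tb1, tb1)
  expect_lt(max(abs(diag(Dself))), 1e-6)
  expect_equal(Dself, t(Dself))
  bad <- simulate_label_embeddings(3, 3, within_sd = 0.1, between_sep = 1,
                                   vec_len = 10, seed = 59)
  expect_error(dimension_distances(tb1, bad), "vector length")
})
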