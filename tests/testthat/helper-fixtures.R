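# Shared fixtures and independent oracles used across the suite.

# tiny long-format dataset over items a..d with hand-set ratings
tiny_dataset <- function() {
  st <- stimulus_set(c("a", "b", "c", "d"),
                     categories = c(a = "eating", b = "eating",
                                    c = "driving", d = "control"))
  ratings <- data.frame(
    unit_id = c("u1", "u1", "u1", "u2", "u2", "u2"),
    item_a = c("a", "a", "b", "a", "c", "b"),
    item_b = c("b", "c", "c", "b", "d", "d"),
    dissimilarity = c(0.2, 0.6, 0.3, 0.4, 0.8, 0.5))
  similarity_dataset(ratings, st, mode = "rating_sampled")
}

# complete-design dataset: every unit rates every pair of n items
complete_dataset <- function(n_items = 4, n_units = 6, seed = 1) {
  withr::with_seed(seed, {
    items <- letters[seq_len(n_items)]
    pairs <- t(combn(items, 2))
    ratings <- do.call(rbind, lapply(seq_len(n_units), function(u)
      data.frame(unit_id = paste0("u", u),
                 item_a = pairs[, 1], item_b = pairs[, 2],
                 dissimilarity = runif(nrow(pairs)))))
    similarity_dataset(ratings, stimulus_set(items),
                       mode = "participant_complete")
  })
}

# brute-force Kendall tau-a oracle: explicit pair enumeration
tau_a_oracle <- function(x, y) {
  n <- length(x)
  conc <- 0L; disc <- 0L
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      s <- sign(x[i] - x[j]) * sign(y[i] - y[j])
      if (s > 0) conc <- conc + 1L
      if (s < 0) disc <- disc + 1L
    }
  }
  (conc - disc) / (n * (n - 1) / 2)
}

# brute-force elbow oracle: vector rejection from the normalized chord
elbow_oracle <- function(k, tau) {
  norm01 <- function(v) if (diff(range(v)) == 0) rep(0, length(v))
                        else (v - min(v)) / diff(range(v))
  p <- cbind(norm01(k), norm01(tau))
  a <- p[1, ]; b <- p[nrow(p), ]
  u <- (b - a) / sqrt(sum((b - a)^2))
  d <- apply(p, 1, function(q) {
    v <- q - a
    sqrt(sum((v - sum(v * u) * u)^2))
  })
  interior <- 2:(length(k) - 1)
  k[interior[which.max(d[interior])]]
}

# symmetric non-negative low-rank fixture W W' with planted rank
planted_similarity <- function(n, k, seed = 1) {
  withr::with_seed(seed, {
    W <- matrix(abs(rnorm(n * k)), n, k)
    S <- W %*% t(W)
    S / max(S)
  })
}
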