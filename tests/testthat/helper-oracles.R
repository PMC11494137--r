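# Independent brute-force oracles used to cross-check the vectorized
# implementations. These deliberately use naive enumeration and nothing from
# the implementation paths they verify.

random_sequence <- function(len) {
  paste(sample(AA_ALPHABET, len, replace = TRUE), collapse = "")
}

# AAPIV by direct position enumeration
aapiv_oracle <- function(seq) {
  chars <- strsplit(seq, "")[[1]]
  out <- stats::setNames(numeric(20), AA_ALPHABET)
  for (p in seq_along(chars)) {
    out[chars[p]] <- out[chars[p]] + p
  }
  out
}

# PRIM by direct double enumeration over residue types and occurrences
prim_oracle <- function(seq) {
  chars <- strsplit(seq, "")[[1]]
  R <- matrix(0, 20, 20, dimnames = list(AA_ALPHABET, AA_ALPHABET))
  for (x in AA_ALPHABET) {
    first_x <- match(x, chars)
    if (is.na(first_x)) next
    for (y in AA_ALPHABET) {
      pos_y <- which(chars == y)
      R[x, y] <- sum(pos_y - first_x)
    }
  }
  R
}

# raw and central moments by explicit double loops
raw_moments_oracle <- function(m, a, b) {
  acc <- 0
  for (e in seq_len(nrow(m))) {
    for (f in seq_len(ncol(m))) {
      acc <- acc + e^a * f^b * m[e, f]
    }
  }
  acc
}

central_moments_oracle <- function(m, a, b) {
  u00 <- raw_moments_oracle(m, 0, 0)
  xb <- raw_moments_oracle(m, 1, 0) / u00
  yb <- raw_moments_oracle(m, 0, 1) / u00
  acc <- 0
  for (e in seq_len(nrow(m))) {
    for (f in seq_len(ncol(m))) {
      acc <- acc + (e - xb)^a * (f - yb)^b * m[e, f]
    }
  }
  acc
}

# the fixed order-pair set shared by all moment families
moment_order_pairs <- function() {
  list(
    c(0, 0), c(0, 1), c(1, 0), c(1, 1), c(0, 2),
    c(2, 0), c(1, 2), c(2, 1), c(0, 3), c(3, 0)
  )
}

# two separable Gaussian blobs in d dimensions, as a feature table
blob_features <- function(n_per_class, d = 4, sep = 4, seed = 1) {
  set.seed(seed)
  X <- rbind(
    matrix(stats::rnorm(n_per_class * d, mean = 0), ncol = d),
    matrix(stats::rnorm(n_per_class * d, mean = sep / sqrt(d)), ncol = d)
  )
  colnames(X) <- sprintf("f%03d", seq_len(d) - 1)
  dplyr::bind_cols(
    tibble::tibble(
      id = sprintf("s%04d", seq_len(2 * n_per_class)),
      label = rep(c(0L, 1L), each = n_per_class)
    ),
    tibble::as_tibble(X)
  )
}

# quick training configuration used where convergence speed is not the point
fast_config <- function(kind = "MLP", seed = 1, ...) {
  model_config(kind, max_epochs = 30L, patience = 8L, seed = seed, ...)
}
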