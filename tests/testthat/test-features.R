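test_that("frequency vector counts residues", {
  all20 <- paste(AA_ALPHABET, collapse = "")
  expect_equal(unname(frequency_vector(all20)), rep(1L, 20))
  fv <- frequency_vector("AAAA")
  expect_equal(fv[["A"]], 4L)
  expect_equal(sum(fv), 4L)
  set.seed(21)
  s <- random_sequence(200)
  expect_equal(sum(frequency_vector(s)), 200L)
  expect_equal(unname(frequency_vector(s)[AA_ALPHABET]),
    unname(vapply(AA_ALPHABET, function(a) {
      sum(strsplit(s, "")[[1]] == a)
    }, 1L))
  )
})

test_that("aapiv matches position enumeration and sums to n(n+1)/2", {
  expect_equal(aapiv("A")[["A"]], 1)
  expect_equal(aapiv("ACA")[["A"]], 4)
  expect_equal(aapiv("ACA")[["C"]], 2)
  set.seed(7)
  for (len in c(1, 2, 17, 211)) {
    s <- random_sequence(len)
    expect_equal(aapiv(s), aapiv_oracle(s))
    expect_equal(sum(aapiv(s)), len * (len + 1) / 2)
  }
})

test_that("raapiv equals aapiv of the reversed sequence", {
  expect_equal(raapiv("AC")[["A"]], 2)
  expect_equal(raapiv("AC")[["C"]], 1)
  expect_equal(raapiv("ACA"), aapiv("ACA")) # palindrome
  set.seed(8)
  for (len in c(3, 40, 150)) {
    s <- random_sequence(len)
    rev_s <- paste(rev(strsplit(s, "")[[1]]), collapse = "")
    expect_equal(raapiv(s), aapiv(rev_s))
    expect_equal(sum(raapiv(s)), len * (len + 1) / 2)
  }
})

test_that("prim matches the brute-force incidence oracle", {
  R <- prim("A")
  expect_equal(dim(R), c(20L, 20L))
  expect_equal(sum(R != 0), 0L) # single residue at its own first position
  expect_equal(prim("AAAA")[["A", "A"]], 6)
  R <- prim("AC")
  expect_equal(R[["A", "A"]], 0)
  expect_equal(R[["A", "C"]], 1)
  expect_equal(R[["C", "A"]], -1)
  expect_equal(R[["C", "C"]], 0)
  set.seed(9)
  for (len in c(2, 25, 180)) {
    s <- random_sequence(len)
    expect_equal(prim(s), prim_oracle(s))
  }
})

test_that("prim rows of absent residues are identically zero", {
  s <- "ACACACAC" # only A and C present
  R <- prim(s)
  absent <- setdiff(AA_ALPHABET, c("A", "C"))
  expect_true(all(R[absent, ] == 0))
  expect_equal(length(R), 400L)
})

test_that("rprim equals prim of the reversed sequence", {
  expect_equal(rprim("ACA"), prim("ACA")) # palindrome
  Q <- rprim("AC")
  expect_equal(Q[["C", "A"]], 1)
  expect_equal(Q[["A", "C"]], -1)
  set.seed(10)
  for (len in c(5, 60, 240)) {
    s <- random_sequence(len)
    rev_s <- paste(rev(strsplit(s, "")[[1]]), collapse = "")
    expect_equal(rprim(s), prim(rev_s))
  }
})

test_that("sequence matrix is the ceil-sqrt row-major rank grid", {
  expect_equal(
    sequence_matrix("ACDEF"),
    matrix(c(1L, 2L, 3L, 4L, 5L, 0L, 0L, 0L, 0L), 3, byrow = TRUE)
  )
  expect_equal(sequence_matrix("A"), matrix(1L, 1, 1))
  s9 <- random_sequence(9)
  g <- sequence_matrix(s9)
  expect_equal(dim(g), c(3L, 3L))
  expect_true(all(g > 0)) # perfect square, no padding
  set.seed(11)
  for (len in c(2, 7, 50, 145)) {
    g <- sequence_matrix(random_sequence(len))
    k <- ceiling(sqrt(len))
    expect_equal(dim(g), c(k, k))
    expect_equal(sum(g == 0), k^2 - len)
    expect_true(all(g %in% 0:20))
  }
})

test_that("extract_features assembles the documented 150-value layout", {
  s <- paste(AA_ALPHABET, collapse = "")
  fv <- extract_features(s)
  expect_length(fv, 150L)
  expect_true(all(is.finite(fv)))
  expect_equal(unname(fv[1:20]), rep(1, 20)) # FV block
  expect_equal(unname(fv[111:130]), unname(as.numeric(aapiv(s)))) # AAPIV block
  expect_equal(unname(fv[131:150]), unname(as.numeric(raapiv(s)))) # RAAPIV block
  expect_equal(unname(fv[21:50]), unname(moment_descriptor(prim(s))))
  expect_equal(unname(fv[51:80]), unname(moment_descriptor(rprim(s))))
  expect_equal(unname(fv[81:110]), unname(moment_descriptor(sequence_matrix(s))))
})

test_that("extract_features is deterministic and layout metadata is consistent", {
  set.seed(12)
  s <- random_sequence(77)
  expect_identical(extract_features(s), extract_features(s))
  layout <- feature_layout()
  expect_equal(layout$length, 150L)
  widths <- vapply(layout$blocks, `[[`, 1L, "width")
  offsets <- vapply(layout$blocks, `[[`, 1L, "offset")
  expect_equal(sum(widths), 150L)
  expect_equal(offsets, cumsum(c(0L, utils::head(widths, -1))))
})

test_that("feature_table maps over a dataset with ids and labels", {
  ds <- tibble::tibble(
    id = c("a", "b"), residues = c("MKVL", "AAAA"), label = c(1L, 0L)
  )
  ft <- feature_table(ds)
  expect_equal(dim(ft), c(2L, 152L))
  expect_equal(ft$label, c(1L, 0L))
  expect_equal(unname(unlist(ft[2, sprintf("f%03d", 0:19)])),
    unname(as.numeric(frequency_vector("AAAA"))))
})
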