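test_that("raw moments match the double-loop oracle", {
  m <- matrix(1:4, 2, byrow = TRUE)
  u <- raw_moments(m)
  expect_equal(u[["U00"]], 10)
  expect_equal(u[["U10"]], 17)
  expect_equal(u[["U01"]], 16)
  expect_equal(unname(raw_moments(matrix(0, 5, 5))), rep(0, 10))
  set.seed(31)
  for (n in c(1, 3, 8, 20)) {
    m <- matrix(stats::rnorm(n * n), n)
    u <- raw_moments(m)
    for (pair in moment_order_pairs()) {
      expected <- raw_moments_oracle(m, pair[1], pair[2])
      got <- u[[paste0("U", pair[1], pair[2])]]
      expect_equal(got, expected, tolerance = 1e-9)
    }
  }
})

test_that("centroid is the mass-weighted mean index", {
  expect_equal(centroid(matrix(1:4, 2, byrow = TRUE)), c(x = 1.7, y = 1.6))
  expect_equal(centroid(matrix(3, 2, 2)), c(x = 1.5, y = 1.5))
  expect_error(centroid(matrix(0, 3, 3)), "degenerate")
})

test_that("central moments match the oracle with v10 = v01 = 0", {
  m <- matrix(1:4, 2, byrow = TRUE)
  expect_equal(central_moments(m)[["V11"]], -0.2, tolerance = 1e-12)
  set.seed(32)
  for (n in c(2, 6, 20)) {
    m <- matrix(stats::runif(n * n), n)
    v <- central_moments(m)
    expect_equal(v[["V10"]], 0, tolerance = 1e-10)
    expect_equal(v[["V01"]], 0, tolerance = 1e-10)
    expect_equal(v[["V00"]], raw_moments(m)[["U00"]])
    for (pair in moment_order_pairs()) {
      expect_equal(
        v[[paste0("V", pair[1], pair[2])]],
        central_moments_oracle(m, pair[1], pair[2]),
        tolerance = 1e-9
      )
    }
  }
})

test_that("central moments are invariant to translation inside zero padding", {
  set.seed(33)
  core <- matrix(stats::runif(9), 3)
  big1 <- matrix(0, 8, 8)
  big1[1:3, 1:3] <- core
  big2 <- matrix(0, 8, 8)
  big2[4:6, 3:5] <- core # shifted content, same mass
  expect_equal(central_moments(big1), central_moments(big2), tolerance = 1e-9)
})

test_that("hahn basis is orthonormal on dyadic supports", {
  for (Q in c(2, 4, 8, 16)) {
    B <- hahn_basis(Q - 1, Q)
    expect_equal(B %*% t(B), diag(Q), tolerance = 1e-8)
  }
  # order 0 before normalization is constant: normalized it is 1/sqrt(Q)
  expect_equal(unname(hahn_basis(0, 8)[1, ]), rep(1 / sqrt(8), 8))
  expect_error(hahn_basis(8, 8), "order")
  expect_error(hahn_polynomial(1, 9, 8), "0 <= p < Q")
})

test_that("full Hahn transform reconstructs random matrices", {
  set.seed(34)
  for (Q in c(4, 8)) {
    m <- matrix(stats::rnorm(Q * Q), Q)
    B <- hahn_basis(Q - 1, Q)
    H <- B %*% t(m) %*% t(B) # full coefficient matrix
    rec <- t(t(B) %*% H %*% B) # inverse transform
    expect_equal(rec, m, tolerance = 1e-6)
  }
})

test_that("hahn_moments agree with the basis-sandwich oracle", {
  set.seed(35)
  m <- matrix(stats::rnorm(36), 6)
  B <- hahn_basis(5, 6)
  full <- B %*% t(m) %*% t(B)
  h <- hahn_moments(m)
  for (pair in moment_order_pairs()) {
    expect_equal(
      h[[paste0("H", pair[1], pair[2])]],
      full[pair[1] + 1, pair[2] + 1],
      tolerance = 1e-9
    )
  }
  expect_equal(unname(hahn_moments(matrix(0, 6, 6))), rep(0, 10))
})

test_that("hahn moments handle tiny grids by zeroing missing orders", {
  h1 <- hahn_moments(matrix(2.5, 1, 1))
  expect_equal(h1[["H00"]], 2.5) # h0 at Q=1 is the unit basis vector
  expect_true(all(h1[names(h1) != "H00"] == 0))
  h2 <- hahn_moments(matrix(1:4, 2))
  expect_true(all(h2[c("H02", "H20", "H12", "H21", "H03", "H30")] == 0))
})

test_that("moment descriptor is the 30-value concatenation, zero matrix safe", {
  m <- matrix(stats::runif(400), 20)
  d <- moment_descriptor(m)
  expect_length(d, 30L)
  expect_equal(names(d)[c(1, 11, 21)], c("U00", "V00", "H00"))
  expect_true(all(is.finite(d)))
  expect_equal(unname(moment_descriptor(matrix(0, 4, 4))), rep(0, 30))
  expect_identical(moment_descriptor(m), moment_descriptor(m))
  expect_error(raw_moments(matrix(1:6, 2, 3)), "square")
})
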