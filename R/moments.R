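# The ten (a, b) order pairs used for every moment family: all pairs with
# total order a + b <= 3, in a fixed documented sequence. The same set indexes
# raw moments U_ab, central moments V_ab, and Hahn moments H_pq.
.moment_orders <- cbind(
  a = c(0L, 0L, 1L, 1L, 0L, 2L, 1L, 2L, 0L, 3L),
  b = c(0L, 1L, 0L, 1L, 2L, 0L, 2L, 1L, 3L, 0L)
)

.moment_names <- function(prefix) {
  paste0(prefix, .moment_orders[, "a"], .moment_orders[, "b"])
}

.check_square <- function(m) {
  if (!is.matrix(m) || nrow(m) == 0L) {
    stop("input must be a non-empty matrix", call. = FALSE)
  }
  if (nrow(m) != ncol(m)) {
    stop("input matrix must be square, got ", nrow(m), "x", ncol(m), call. = FALSE)
  }
  if (any(!is.finite(m))) {
    stop("input matrix contains non-finite values", call. = FALSE)
  }
  invisible(m)
}

#' Raw moments of a square matrix
#'
#' Computes the ten raw moments \eqn{U_{ab} = \sum_e \sum_f e^a f^b m_{ef}}
#' of total order \eqn{a + b \le 3}, with 1-based row index \eqn{e} and
#' column index \eqn{f}.
#'
#' @param m A non-empty square numeric matrix.
#' @return A named numeric vector of length 10 (`U00`, `U01`, `U10`, `U11`,
#'   `U02`, `U20`, `U12`, `U21`, `U03`, `U30`).
#' @examples
#' raw_moments(matrix(1:4, 2, byrow = TRUE))
#' @export
raw_moments <- function(m) {
  .check_square(m)
  n <- nrow(m)
  idx <- seq_len(n)
  # row sums weighted by e^a, column sums weighted by f^b
  vals <- vapply(seq_len(nrow(.moment_orders)), function(k) {
    a <- .moment_orders[k, "a"]
    b <- .moment_orders[k, "b"]
    as.numeric(crossprod(idx^a, m %*% (idx^b)))
  }, numeric(1))
  stats::setNames(vals, .moment_names("U"))
}

#' Centroid of a square matrix
#'
#' The centroid is the mass-weighted mean index pair
#' \eqn{(\bar x, \bar y) = (U_{10}/U_{00},\; U_{01}/U_{00})}, treating the
#' matrix entries as masses on the 1-based index grid.
#'
#' @param m A non-empty square numeric matrix with nonzero total mass.
#' @return A named numeric vector `c(x = ..., y = ...)`, where `x` is the
#'   row coordinate and `y` the column coordinate.
#' @examples
#' centroid(matrix(1:4, 2, byrow = TRUE))
#' @export
centroid <- function(m) {
  u <- raw_moments(m)
  if (u[["U00"]] == 0) {
    stop("degenerate matrix: total mass U00 is zero, centroid undefined", call. = FALSE)
  }
  c(x = u[["U10"]] / u[["U00"]], y = u[["U01"]] / u[["U00"]])
}

#' Central moments of a square matrix
#'
#' Computes the ten centroid-centred moments
#' \eqn{V_{ab} = \sum_e \sum_f (e - \bar x)^a (f - \bar y)^b m_{ef}} on the
#' same order set as [raw_moments()]. By construction `V00 == U00` and
#' `V10 == V01 == 0`. For an all-zero matrix (undefined centroid) the grid
#' centre is substituted, which yields all-zero central moments rather than
#' NaNs.
#'
#' @inheritParams raw_moments
#' @return A named numeric vector of length 10 (`V00` ... `V30`).
#' @export
central_moments <- function(m) {
  .check_square(m)
  n <- nrow(m)
  ctr <- tryCatch(centroid(m), error = function(e) c(x = (n + 1) / 2, y = (n + 1) / 2))
  dx <- seq_len(n) - ctr[["x"]]
  dy <- seq_len(n) - ctr[["y"]]
  vals <- vapply(seq_len(nrow(.moment_orders)), function(k) {
    a <- .moment_orders[k, "a"]
    b <- .moment_orders[k, "b"]
    as.numeric(crossprod(dx^a, m %*% (dy^b)))
  }, numeric(1))
  stats::setNames(vals, .moment_names("V"))
}

# --- discrete Hahn basis -----------------------------------------------------

# Unnormalized Hahn polynomial values Q_n(x; a, b, N) for n = 0..nmax on the
# support x = 0..N-1, by the standard three-term recurrence
#   -x Q_n = A_n Q_{n+1} - (A_n + C_n) Q_n + C_n Q_{n-1}.
# With a = b = 0 these reduce to the discrete Chebyshev (Gram) polynomials.
.hahn_raw <- function(nmax, N, a = 0, b = 0) {
  x <- 0:(N - 1)
  out <- matrix(0, nrow = nmax + 1L, ncol = N)
  out[1L, ] <- 1
  if (nmax >= 1L) {
    for (n in 0:(nmax - 1L)) {
      A <- (n + a + b + 1) * (n + a + 1) * (N - 1 - n) /
        ((2 * n + a + b + 1) * (2 * n + a + b + 2))
      C <- if (n == 0L) 0 else {
        n * (n + a + b + N) * (n + b) / ((2 * n + a + b) * (2 * n + a + b + 1))
      }
      prev <- if (n == 0L) rep(0, N) else out[n, ]
      out[n + 2L, ] <- ((A + C - x) * out[n + 1L, ] - C * prev) / A
    }
  }
  out
}

# Hahn weight w(x; a, b, N) on 0..N-1 (uniform when a = b = 0)
.hahn_weight <- function(N, a = 0, b = 0) {
  x <- 0:(N - 1)
  choose(a + x, x) * choose(b + N - 1 - x, N - 1 - x)
}

#' Weight-normalized Hahn polynomial basis
#'
#' Builds the orthonormal discrete Hahn basis
#' \eqn{\tilde h_n(x) = Q_n(x)\sqrt{w(x)}/d_n} on the support
#' \eqn{x \in \{0, ..., Q-1\}}, rows indexed by order `n = 0..nmax`. With the
#' default parameters `a = b = 0` the weight is uniform and the basis is the
#' orthonormal discrete Chebyshev system. Rows satisfy
#' \eqn{\sum_x \tilde h_m(x) \tilde h_n(x) = \delta_{mn}}.
#'
#' @param nmax Highest polynomial order (must satisfy `nmax < Q`).
#' @param Q Support size (grid side length).
#' @param a,b Hahn shape parameters (non-negative reals); default 0.
#' @return A `(nmax + 1) x Q` numeric matrix; row `n + 1` holds
#'   \eqn{\tilde h_n} evaluated on `0:(Q-1)`.
#' @examples
#' B <- hahn_basis(3, 8)
#' round(B %*% t(B), 12)  # identity
#' @export
hahn_basis <- function(nmax, Q, a = 0, b = 0) {
  if (Q < 1L) stop("support size Q must be >= 1", call. = FALSE)
  if (nmax < 0L || nmax >= Q) {
    stop("polynomial order must satisfy 0 <= n < Q (got n = ", nmax, ", Q = ", Q, ")",
      call. = FALSE
    )
  }
  raw <- .hahn_raw(nmax, Q, a, b)
  sw <- sqrt(.hahn_weight(Q, a, b))
  weighted <- sweep(raw, 2L, sw, `*`)
  norms <- sqrt(rowSums(weighted^2))
  weighted / norms
}

#' Evaluate one weight-normalized Hahn polynomial
#'
#' @param n Polynomial order, `0 <= n < Q`.
#' @param p Evaluation point on the discrete support, `0 <= p < Q`.
#' @param Q Support size.
#' @param a,b Hahn shape parameters; default 0 (uniform weight).
#' @return The scalar value \eqn{\tilde h_n(p)}.
#' @export
hahn_polynomial <- function(n, p, Q, a = 0, b = 0) {
  if (p < 0L || p >= Q) {
    stop("evaluation point must satisfy 0 <= p < Q (got p = ", p, ", Q = ", Q, ")",
      call. = FALSE
    )
  }
  hahn_basis(n, Q, a, b)[n + 1L, p + 1L]
}

# cache of orthonormal full bases keyed by Q (a = b = 0), reused across the
# thousands of matrices summarized in a dataset
.hahn_cache <- new.env(parent = emptyenv())

.hahn_full_basis <- function(Q) {
  key <- as.character(Q)
  got <- .hahn_cache[[key]]
  if (is.null(got)) {
    got <- hahn_basis(Q - 1L, Q)
    .hahn_cache[[key]] <- got
  }
  got
}

#' Hahn moments of a square matrix
#'
#' Projects the matrix onto the orthonormal discrete Hahn basis:
#' \eqn{H_{pq} = \sum_j \sum_i m_{ij}\, \tilde h_p(j-1)\, \tilde h_q(i-1)},
#' i.e. order `p` runs along columns and order `q` along rows, and returns
#' the ten coefficients on the same order set as [raw_moments()]. For grids
#' smaller than 4x4 the basis has fewer than four orders; coefficients whose
#' order does not exist on that support are 0.
#'
#' @inheritParams raw_moments
#' @return A named numeric vector of length 10 (`H00` ... `H30`).
#' @export
hahn_moments <- function(m) {
  .check_square(m)
  Q <- nrow(m)
  B <- .hahn_full_basis(Q)     # Q x Q orthonormal, rows = orders
  H <- B %*% t(m) %*% t(B)     # H[p+1, q+1] = sum_ij m_ij h_p(j-1) h_q(i-1)
  vals <- vapply(seq_len(nrow(.moment_orders)), function(k) {
    p <- .moment_orders[k, "a"]
    q <- .moment_orders[k, "b"]
    if (p >= Q || q >= Q) 0 else H[p + 1L, q + 1L]
  }, numeric(1))
  stats::setNames(vals, .moment_names("H"))
}

#' Full 30-value moment descriptor of a square matrix
#'
#' Concatenates the ten raw, ten central, and ten Hahn moments of `m`, in
#' that order, giving the fixed 30-value summary used for each incidence
#' matrix and sequence grid.
#'
#' @inheritParams raw_moments
#' @return A named numeric vector of length 30:
#'   `U00..U30`, `V00..V30`, `H00..H30`.
#' @examples
#' length(moment_descriptor(matrix(runif(400), 20)))
#' @export
moment_descriptor <- function(m) {
  c(raw_moments(m), central_moments(m), hahn_moments(m))
}
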