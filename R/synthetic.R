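# Default biased transition matrix for the disordered-like class: strong
# self-transitions for the hydrophobic residues I, L, V, F, remaining mass
# uniform. With effect = 0 both classes emit from the uniform chain; the
# mixing weight interpolates the class-1 chain toward the biased one.
.biased_transition <- function(self_mass = 0.6) {
  P <- matrix(1 / 20, 20L, 20L, dimnames = list(AA_ALPHABET, AA_ALPHABET))
  sticky <- c("I", "L", "V", "F")
  for (r in sticky) {
    row <- rep((1 - self_mass) / 19, 20L)
    row[match(r, AA_ALPHABET)] <- self_mass
    P[r, ] <- row
  }
  P
}

.uniform_transition <- function() {
  matrix(1 / 20, 20L, 20L, dimnames = list(AA_ALPHABET, AA_ALPHABET))
}

.check_stochastic <- function(P, what) {
  if (!is.matrix(P) || !all(dim(P) == c(20L, 20L))) {
    stop(what, " must be a 20x20 matrix", call. = FALSE)
  }
  if (any(P < 0) || any(abs(rowSums(P) - 1) > 1e-8)) {
    stop(what, " rows must be probability vectors (non-negative, summing to 1)",
      call. = FALSE
    )
  }
  invisible(P)
}

#' Specification of the synthetic sequence generator
#'
#' Defines two class emission models — first-order Markov chains over the
#' 20-residue alphabet — and how far apart they are. Class 0 ("ordered")
#' emits from `transition0`; class 1 ("disordered") emits from the mixture
#' `(1 - effect) * transition0 + effect * transition1`. With `effect = 0`
#' the classes are identically distributed (a null dataset); with
#' `effect = 1` class 1 uses `transition1` unmixed. First-order emission
#' (rather than i.i.d. draws) lets the generator plant signal that only the
#' positional descriptors can detect — equal stationary composition but
#' different transition structure.
#'
#' @param n_per_class Sequences per class (default 500).
#' @param length_range Two-element integer range of sequence lengths,
#'   sampled uniformly (default `c(50, 400)`, the span typical of curated
#'   disorder benchmarks).
#' @param effect Mixing weight in `[0, 1]` between the class chains
#'   (default 0.5).
#' @param transition0,transition1 20 x 20 row-stochastic transition matrices
#'   for the two class models. Defaults: uniform for class 0, and for class 1
#'   a chain with self-transition mass 0.6 on the hydrophobic residues
#'   I, L, V, F.
#' @param init0,init1 Initial residue distributions (default uniform).
#' @param seed Integer RNG seed.
#' @return An object of class `idp_generator_spec`.
#' @seealso [generate_dataset()], [separable_spec()], [benchmark_like()]
#' @export
generator_spec <- function(n_per_class = 500L, length_range = c(50L, 400L),
                           effect = 0.5,
                           transition0 = .uniform_transition(),
                           transition1 = .biased_transition(),
                           init0 = rep(1 / 20, 20L), init1 = rep(1 / 20, 20L),
                           seed = 1L) {
  stopifnot(
    n_per_class >= 1, length(length_range) == 2L,
    length_range[1] >= 1, length_range[2] >= length_range[1],
    effect >= 0, effect <= 1
  )
  .check_stochastic(transition0, "transition0")
  .check_stochastic(transition1, "transition1")
  stopifnot(
    length(init0) == 20L, length(init1) == 20L,
    all(init0 >= 0), all(init1 >= 0),
    abs(sum(init0) - 1) < 1e-8, abs(sum(init1) - 1) < 1e-8
  )
  structure(
    list(
      n_per_class = as.integer(n_per_class),
      length_range = as.integer(length_range),
      effect = effect,
      transition0 = transition0, transition1 = transition1,
      init0 = init0, init1 = init1,
      seed = as.integer(seed)
    ),
    class = "idp_generator_spec"
  )
}

#' A maximally separable generator specification
#'
#' Classes emit from disjoint residue alphabets (class 0 from the first ten
#' residues `A..L`, class 1 from the last ten `M..Y`), so the frequency-vector
#' block alone separates them perfectly. Used to verify that every classifier
#' head can recover a clean signal end to end.
#'
#' @inheritParams generator_spec
#' @return An `idp_generator_spec` with `effect = 1`.
#' @export
separable_spec <- function(n_per_class = 200L, length_range = c(50L, 400L),
                           seed = 1L) {
  half0 <- c(rep(1 / 10, 10L), rep(0, 10L))
  half1 <- c(rep(0, 10L), rep(1 / 10, 10L))
  t0 <- matrix(half0, 20L, 20L, byrow = TRUE, dimnames = list(AA_ALPHABET, AA_ALPHABET))
  t1 <- matrix(half1, 20L, 20L, byrow = TRUE, dimnames = list(AA_ALPHABET, AA_ALPHABET))
  generator_spec(
    n_per_class = n_per_class, length_range = length_range, effect = 1,
    transition0 = t0, transition1 = t1, init0 = half0, init1 = half1,
    seed = seed
  )
}

# sample one Markov sequence of given length from init/transition cumsums
.markov_sequence <- function(len, cum_init, cum_trans) {
  ranks <- integer(len)
  ranks[1] <- findInterval(stats::runif(1), cum_init) + 1L
  if (len > 1L) {
    u <- stats::runif(len - 1L)
    for (i in 2:len) {
      ranks[i] <- findInterval(u[i - 1L], cum_trans[ranks[i - 1L], ]) + 1L
    }
  }
  intToUtf8(utf8ToInt(paste(AA_ALPHABET, collapse = ""))[ranks])
}

#' Generate a labeled synthetic sequence dataset
#'
#' Draws `2 * n_per_class` sequences from the two class Markov models of a
#' [generator_spec()], balanced, with lengths uniform in `length_range`.
#' Deterministic given the spec's seed.
#'
#' @param spec An [generator_spec()] object.
#' @return A tibble with `id` (`pos_0001` ... / `neg_0001` ...), `residues`,
#'   and `label` (1 for the disordered-like class, positives first).
#' @examples
#' ds <- generate_dataset(generator_spec(n_per_class = 5, seed = 42))
#' table(ds$label)
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "idp_generator_spec"))
  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(spec$seed)
  n <- spec$n_per_class
  P1 <- (1 - spec$effect) * spec$transition0 + spec$effect * spec$transition1
  i1 <- (1 - spec$effect) * spec$init0 + spec$effect * spec$init1
  draw_class <- function(trans, init, n_seq) {
    cum_trans <- t(apply(trans, 1L, cumsum))
    cum_init <- cumsum(init)
    lens <- sample(spec$length_range[1]:spec$length_range[2], n_seq, replace = TRUE)
    vapply(lens, .markov_sequence, character(1), cum_init = cum_init, cum_trans = cum_trans)
  }
  pos <- draw_class(P1, i1, n)
  neg <- draw_class(spec$transition0, spec$init0, n)
  width <- max(4L, nchar(as.character(n)))
  tibble::tibble(
    id = c(sprintf("pos_%0*d", width, seq_len(n)), sprintf("neg_%0*d", width, seq_len(n))),
    residues = c(pos, neg),
    label = rep(c(1L, 0L), each = n)
  )
}

#' Benchmark-shaped synthetic dataset
#'
#' A drop-in stand-in matching the shape of the curated disorder benchmark
#' this package targets: 1446 sequences, 723 per class, lengths 50-400, with
#' a moderate class separation (`effect = 0.3`). Intended for exercising the
#' cross-validation protocols at realistic scale without any download; it is
#' synthetic and carries none of the biology of the real data.
#'
#' @param seed Integer RNG seed.
#' @return A labeled tibble of 1446 sequences (723 positive, 723 negative).
#' @export
benchmark_like <- function(seed = 1L) {
  generate_dataset(generator_spec(
    n_per_class = 723L, length_range = c(50L, 400L), effect = 0.3, seed = seed
  ))
}

#' Stationary distribution of a transition matrix
#'
#' Left eigenvector of the chain, used by tests to verify that generated
#' residue frequencies converge to the emission model's stationary law.
#'
#' @param P A 20 x 20 row-stochastic matrix.
#' @return A probability vector of length 20 named by residue.
#' @export
stationary_distribution <- function(P) {
  .check_stochastic(P, "P")
  e <- eigen(t(P))
  k <- which.min(abs(e$values - 1))
  v <- Re(e$vectors[, k])
  stats::setNames(v / sum(v), AA_ALPHABET)
}
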