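#' Amino-acid frequency vector
#'
#' Counts the occurrences of each of the 20 canonical residues, indexed by
#' [AA_ALPHABET] rank. Raw counts, not normalized: the counts sum to the
#' sequence length.
#'
#' @param residues A validated residue string over the canonical alphabet.
#' @return A named integer vector of length 20.
#' @examples
#' frequency_vector("ACAAY")
#' @export
frequency_vector <- function(residues) {
  ranks <- .seq_ranks(residues)
  counts <- tabulate(ranks, nbins = 20L)
  stats::setNames(counts, AA_ALPHABET)
}

# residue string -> integer ranks, erroring on non-canonical characters
.seq_ranks <- function(residues) {
  stopifnot(is.character(residues), length(residues) == 1L, nzchar(residues))
  ranks <- .aa_rank_lut[utf8ToInt(residues) + 1L]
  if (anyNA(ranks)) {
    bad <- which(is.na(ranks))[1]
    stop(
      "non-canonical residue '", substr(residues, bad, bad), "' at position ", bad,
      "; validate the sequence first",
      call. = FALSE
    )
  }
  ranks
}

#' Accumulative absolute position incidence vector (AAPIV)
#'
#' For each of the 20 residue types, sums the 1-based positions at which it
#' occurs in the sequence. A residue absent from the sequence contributes 0,
#' and the 20 entries always total \eqn{n(n+1)/2} for a length-\eqn{n}
#' sequence, since every position is counted exactly once.
#'
#' @inheritParams frequency_vector
#' @return A named numeric vector of length 20.
#' @examples
#' aapiv("ACA")  # A at 1 and 3 -> 4; C at 2 -> 2
#' @export
aapiv <- function(residues) {
  ranks <- .seq_ranks(residues)
  sums <- vapply(
    split(seq_along(ranks), factor(ranks, levels = 1:20)),
    sum, numeric(1)
  )
  stats::setNames(as.numeric(sums), AA_ALPHABET)
}

#' Reverse accumulative absolute position incidence vector (RAAPIV)
#'
#' [aapiv()] applied to the reversed residue string, exposing positional
#' structure measured from the C-terminal end.
#'
#' @inheritParams frequency_vector
#' @return A named numeric vector of length 20.
#' @export
raapiv <- function(residues) {
  aapiv(.str_rev(residues))
}

#' Position relative incidence matrix (PRIM)
#'
#' A 20 x 20 matrix accumulating the positions of each residue type relative
#' to the first occurrence of every other residue type:
#' \deqn{R[x, y] = \sum_{p : s_p = y} (p - \mathrm{firstpos}(x))}
#' where positions are 1-based and `firstpos(x)` is the position of the first
#' occurrence of residue `x`. Rows for residue types absent from the sequence
#' are identically zero; entries may be negative. Rows index the reference
#' residue `x`, columns the occurring residue `y`, both in [AA_ALPHABET]
#' order.
#'
#' @inheritParams frequency_vector
#' @return A 20 x 20 numeric matrix with dimnames `AA_ALPHABET`.
#' @examples
#' prim("AC")["A", "C"]  # C occurs at 2, first A at 1 -> 1
#' @export
prim <- function(residues) {
  ranks <- .seq_ranks(residues)
  n <- length(ranks)
  pos_sum <- vapply(
    split(seq_len(n), factor(ranks, levels = 1:20)),
    sum, numeric(1)
  )
  counts <- tabulate(ranks, nbins = 20L)
  firstpos <- rep(NA_real_, 20L)
  firstpos[ranks[!duplicated(ranks)]] <- which(!duplicated(ranks))
  # R[x, y] = sum_p(y) - count(y) * firstpos(x), zero when x absent
  R <- outer(firstpos, counts, function(fp, ct) -fp * ct)
  R <- sweep(R, 2L, as.numeric(pos_sum), `+`)
  R[is.na(R)] <- 0
  dimnames(R) <- list(AA_ALPHABET, AA_ALPHABET)
  R
}

#' Reverse position relative incidence matrix (RPRIM)
#'
#' [prim()] applied to the reversed residue string.
#'
#' @inheritParams frequency_vector
#' @return A 20 x 20 numeric matrix with dimnames `AA_ALPHABET`.
#' @export
rprim <- function(residues) {
  prim(.str_rev(residues))
}

#' Square sequence grid
#'
#' Encodes the sequence as alphabet ranks (`A` = 1 ... `Y` = 20) laid out
#' row-major in the smallest square grid that holds it:
#' \eqn{k = \lceil\sqrt n\rceil}, with the \eqn{k^2 - n} trailing cells
#' zero-padded. Rank encoding keeps cell values small and distinct from the
#' padding value 0. This grid is the two-dimensional carrier the Hahn
#' transform needs.
#'
#' @inheritParams frequency_vector
#' @return A `k x k` integer matrix.
#' @examples
#' sequence_matrix("ACDEF")
#' @export
sequence_matrix <- function(residues) {
  ranks <- .seq_ranks(residues)
  n <- length(ranks)
  k <- ceiling(sqrt(n))
  matrix(c(ranks, rep(0L, k * k - n)), nrow = k, ncol = k, byrow = TRUE)
}

#' Layout of the assembled feature vector
#'
#' The fixed 150-value descriptor concatenates six blocks. This helper
#' returns the block names with their zero-based offsets and widths, and is
#' the layout serialized as the JSON sidecar of a feature CSV.
#'
#' @return A list of blocks, each with `name`, `offset`, `width`.
#' @export
feature_layout <- function() {
  list(
    version = 1L,
    length = 150L,
    alphabet = paste(AA_ALPHABET, collapse = ""),
    blocks = list(
      list(name = "frequency_vector", offset = 0L, width = 20L),
      list(name = "prim_moments", offset = 20L, width = 30L),
      list(name = "rprim_moments", offset = 50L, width = 30L),
      list(name = "sequence_matrix_moments", offset = 80L, width = 30L),
      list(name = "aapiv", offset = 110L, width = 20L),
      list(name = "raapiv", offset = 130L, width = 20L)
    )
  )
}

#' Extract the 150-value feature vector of one sequence
#'
#' Assembles the full descriptor of a validated sequence: residue frequency
#' vector (20), moment descriptors of the PRIM, RPRIM and square sequence
#' grid (30 each), and the AAPIV and RAAPIV position vectors (20 each) — a
#' deterministic, purely compositional/positional function of the residue
#' string.
#'
#' @inheritParams frequency_vector
#' @return A named numeric vector of length 150; names are `f000` ... `f149`.
#' @examples
#' fv <- extract_features("MKVLINGKTLKGEITVDGAKNAVLPIL")
#' length(fv)
#' @export
extract_features <- function(residues) {
  v <- c(
    frequency_vector(residues),
    moment_descriptor(prim(residues)),
    moment_descriptor(rprim(residues)),
    moment_descriptor(sequence_matrix(residues)),
    aapiv(residues),
    raapiv(residues)
  )
  if (any(!is.finite(v))) {
    stop("non-finite feature value computed; this indicates an internal error",
      call. = FALSE
    )
  }
  stats::setNames(as.numeric(v), sprintf("f%03d", 0:149))
}

#' Feature table of a sequence dataset
#'
#' Maps [extract_features()] over a tibble of sequences (as returned by
#' [read_fasta()], [load_dataset()] or [generate_dataset()]), yielding the
#' samples-by-features table the classifiers consume.
#'
#' @param sequences A data frame with columns `id`, `residues`, and
#'   optionally `label`.
#' @return A tibble with columns `id`, `label`, `f000` ... `f149`.
#' @examples
#' ds <- tibble::tibble(id = c("a", "b"), residues = c("MKVL", "AAAA"))
#' feature_table(ds)
#' @export
feature_table <- function(sequences) {
  stopifnot(all(c("id", "residues") %in% names(sequences)))
  label <- if ("label" %in% names(sequences)) {
    as.integer(sequences$label)
  } else {
    rep(NA_integer_, nrow(sequences))
  }
  mat <- t(vapply(sequences$residues, extract_features, numeric(150), USE.NAMES = FALSE))
  colnames(mat) <- sprintf("f%03d", 0:149)
  dplyr::bind_cols(
    tibble::tibble(id = sequences$id, label = label),
    tibble::as_tibble(mat)
  )
}
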