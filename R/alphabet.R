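#' The canonical amino-acid alphabet
#'
#' All positional descriptors in this package index residues by their rank in
#' the fixed alphabetical ordering of the 20 canonical single-letter codes,
#' `"ACDEFGHIKLMNPQRSTVWY"`. The ordering itself is a convention: any fixed
#' bijection between residues and ranks 1..20 yields an equivalent feature
#' space, but models and feature tables are only interoperable when all were
#' produced under the same ordering, so it is pinned here.
#'
#' @format A length-20 character vector, `A` first, `Y` last.
#' @export
AA_ALPHABET <- c(
  "A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"
)

# fast residue -> rank lookup over raw char codes; non-canonical chars map to NA
.aa_rank_lut <- local({
  lut <- rep(NA_integer_, 256L)
  lut[utf8ToInt(paste(AA_ALPHABET, collapse = "")) + 1L] <- seq_len(20L)
  lut
})

#' Rank of residues in the canonical alphabet
#'
#' @param residues A character vector of single residues, or a single string
#'   (which is split into characters).
#' @return Integer ranks in 1..20 (`A` = 1, ..., `Y` = 20); `NA` for
#'   characters outside the canonical alphabet.
#' @examples
#' aa_rank("ACDY")
#' @export
aa_rank <- function(residues) {
  if (length(residues) == 1L && nchar(residues) > 1L) {
    return(.aa_rank_lut[utf8ToInt(residues) + 1L])
  }
  .aa_rank_lut[vapply(residues, function(ch) utf8ToInt(ch)[1], 1L) + 1L]
}

# reverse a single residue string
.str_rev <- function(s) {
  intToUtf8(rev(utf8ToInt(s)))
}
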