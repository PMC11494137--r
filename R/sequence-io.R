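#' Read protein sequences from a FASTA file
#'
#' Parses a FASTA file into a tibble of sequences. The id of each record is
#' the first whitespace-delimited token of its header; the remainder of the
#' header is discarded. Multi-line records are concatenated, residues are
#' uppercased, and trailing `'*'` stop characters are stripped. No residue
#' validation is applied here — see [validate_sequence()] and the
#' `policy` argument of [load_dataset()].
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `id` (character), `residues` (character,
#'   uppercased), and `label` (integer, all `NA`), one row per record, in
#'   file order.
#' @seealso [load_dataset()] to read and label a positive/negative FASTA
#'   pair, [write_fasta()] for the inverse operation.
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">p1 some description", "acd", "ef"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) {
    stop("FASTA file does not exist: ", path, call. = FALSE)
  }
  set <- Biostrings::readBStringSet(path)
  ids <- vapply(
    strsplit(names(set), "[ \t]+"),
    function(x) if (length(x)) x[[1]] else "",
    character(1)
  )
  residues <- toupper(as.character(set))
  residues <- gsub("\\*+$", "", residues)
  if (any(!nzchar(residues))) {
    bad <- ids[!nzchar(residues)][1]
    stop("FASTA record with empty sequence: '", bad, "'", call. = FALSE)
  }
  dup <- ids[duplicated(ids)]
  if (length(dup)) {
    stop(
      "duplicate sequence id(s) in '", path, "': ",
      paste(unique(dup), collapse = ", "),
      call. = FALSE
    )
  }
  tibble::tibble(id = unname(ids), residues = unname(residues), label = NA_integer_)
}

#' Write sequences to a FASTA file
#'
#' @param sequences A data frame with columns `id` and `residues`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(sequences, path) {
  stopifnot(all(c("id", "residues") %in% names(sequences)))
  set <- Biostrings::BStringSet(sequences$residues)
  names(set) <- sequences$id
  Biostrings::writeXStringSet(set, path, width = 70L)
  invisible(path)
}

#' Validate a residue string against the canonical alphabet
#'
#' Uppercases `raw` and resolves characters outside the 20-letter canonical
#' alphabet according to `policy`:
#' \describe{
#'   \item{`"strict"`}{(default) any non-canonical character is an error
#'     naming the character and its 1-based position. The benchmark data this
#'     package targets are curated, and silently mutating residues would
#'     corrupt every positional descriptor downstream, so strict is the
#'     default.}
#'   \item{`"drop"`}{non-canonical characters are removed.}
#'   \item{`"map"`}{the common ambiguity codes are resolved to a canonical
#'     representative — `B` (Asx) to `D`, `Z` (Glx) to `E`, `U`
#'     (selenocysteine) to `C` — and everything else (`X`, `J`, `O`, gaps,
#'     ...) is dropped.}
#' }
#'
#' @param raw A non-empty residue string.
#' @param policy One of `"strict"`, `"drop"`, `"map"`.
#' @return The validated, uppercased residue string over the canonical
#'   alphabet.
#' @examples
#' validate_sequence("mkacd")
#' validate_sequence("MKX", policy = "drop")
#' validate_sequence("MKB", policy = "map")
#' @export
validate_sequence <- function(raw, policy = c("strict", "drop", "map")) {
  policy <- match.arg(policy)
  if (!is.character(raw) || length(raw) != 1L || !nzchar(raw)) {
    stop("sequence must be a single non-empty string", call. = FALSE)
  }
  s <- toupper(raw)
  codes <- utf8ToInt(s)
  ranks <- .aa_rank_lut[codes + 1L]
  bad <- which(is.na(ranks))
  if (!length(bad)) {
    return(s)
  }
  if (policy == "strict") {
    stop(
      "illegal residue '", intToUtf8(codes[bad[1]]), "' at position ", bad[1],
      " (policy = \"strict\")",
      call. = FALSE
    )
  }
  if (policy == "map") {
    map_from <- utf8ToInt("BZU")
    map_to <- utf8ToInt("DEC")
    for (k in seq_along(map_from)) {
      codes[codes == map_from[k]] <- map_to[k]
    }
    ranks <- .aa_rank_lut[codes + 1L]
  }
  codes <- codes[!is.na(ranks)]
  if (!length(codes)) {
    stop("sequence empty after applying policy \"", policy, "\"", call. = FALSE)
  }
  intToUtf8(codes)
}

#' Load a labeled two-class sequence dataset from a FASTA pair
#'
#' Reads a positive-class and a negative-class FASTA file and returns the
#' labeled union. The positive class is the disordered (lipid-binding) class
#' and is labeled `1`; the ordered class is labeled `0`. Sequences are
#' validated with [validate_sequence()] under `policy`.
#'
#' @param positives Path to the FASTA file of disordered (positive, label 1)
#'   sequences.
#' @param negatives Path to the FASTA file of ordered (negative, label 0)
#'   sequences.
#' @param policy Ambiguity policy passed to [validate_sequence()].
#' @return A tibble with columns `id`, `residues`, `label`, positives first,
#'   with attribute `provenance` recording the source paths and per-class
#'   counts.
#' @examples
#' pos <- tempfile(fileext = ".fa"); neg <- tempfile(fileext = ".fa")
#' writeLines(c(">d1", "MKLVIF"), pos)
#' writeLines(c(">o1", "AAAGGG"), neg)
#' load_dataset(pos, neg)
#' @export
load_dataset <- function(positives, negatives, policy = "strict") {
  pos <- read_fasta(positives)
  neg <- read_fasta(negatives)
  if (nrow(pos) == 0L) stop("positive class has no sequences: ", positives, call. = FALSE)
  if (nrow(neg) == 0L) stop("negative class has no sequences: ", negatives, call. = FALSE)
  clash <- intersect(pos$id, neg$id)
  if (length(clash)) {
    stop(
      "sequence id(s) present in both classes: ",
      paste(utils::head(clash, 5), collapse = ", "),
      call. = FALSE
    )
  }
  pos$label <- 1L
  neg$label <- 0L
  ds <- dplyr::bind_rows(pos, neg)
  ds$residues <- vapply(ds$residues, validate_sequence, character(1),
    policy = policy, USE.NAMES = FALSE
  )
  attr(ds, "provenance") <- sprintf(
    "positives=%s (n=%d), negatives=%s (n=%d)",
    positives, nrow(pos), negatives, nrow(neg)
  )
  ds
}

#' Write a feature table to CSV
#'
#' Persists a feature table (as produced by [feature_table()]) as a CSV with
#' header `id, label, f000..f149`, readable back losslessly to within 1e-9.
#' A machine-readable JSON sidecar describing the feature-block layout is
#' written next to it.
#'
#' @param features A data frame with columns `id`, `label`, and the numeric
#'   feature columns, all rows the same width.
#' @param path Output CSV path.
#' @param sidecar Write the `<path>.layout.json` sidecar describing block
#'   names and offsets? Default `TRUE`.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(features, path, sidecar = TRUE) {
  stopifnot(all(c("id", "label") %in% names(features)))
  feat_cols <- setdiff(names(features), c("id", "label"))
  if (length(feat_cols) && any(vapply(features[feat_cols], function(col) any(is.na(col)), NA))) {
    stop("ragged feature rows: NA entries found in feature columns", call. = FALSE)
  }
  readr::write_csv(features, path)
  if (sidecar) {
    jsonlite::write_json(
      feature_layout(),
      paste0(path, ".layout.json"),
      auto_unbox = TRUE, pretty = TRUE
    )
  }
  invisible(path)
}

#' Read a feature table written by [write_feature_table()]
#'
#' @param path CSV path.
#' @return A tibble with `id` (character), `label` (integer), and numeric
#'   feature columns.
#' @export
read_feature_table <- function(path) {
  readr::read_csv(
    path,
    col_types = readr::cols(
      id = readr::col_character(),
      label = readr::col_integer(),
      .default = readr::col_double()
    ),
    progress = FALSE
  )
}
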