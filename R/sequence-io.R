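# Sequence collections and FASTA I/O.
#
# Collections are Biostrings AAStringSet / DNAStringSet objects whose
# names are unique identifier tokens; free-text descriptions live in
# mcols(x)$description. All residues are stored uppercase and must
# conform to the declared alphabet: the 20 standard amino acids plus X
# for proteins, ACGTN for nucleotides.

PROTEIN_LETTERS <- c("A","C","D","E","F","G","H","I","K","L",
                     "M","N","P","Q","R","S","T","V","W","Y")
PROTEIN_ALPHABET <- c(PROTEIN_LETTERS, "X")
NUCLEOTIDE_ALPHABET <- c("A","C","G","T","N")

#' Build a validated sequence collection
#'
#' @param residues named character vector of sequences (names are ids).
#' @param alphabet `"protein"` or `"nucleotide"`.
#' @param descriptions optional character vector of free-text
#'   descriptions, recycled to length of `residues`.
#' @return An [Biostrings::AAStringSet] or [Biostrings::DNAStringSet]
#'   with unique names and a `description` metadata column.
#' @export
seq_set <- function(residues, alphabet = c("protein", "nucleotide"),
                    descriptions = "") {
  alphabet <- match.arg(alphabet)
  ids <- names(residues)
  if (is.null(ids) || any(!nzchar(ids)))
    stopf("every sequence must have a nonempty id")
  residues <- toupper(as.character(residues))
  validate_ids(ids)
  validate_residues(residues, ids, alphabet)
  x <- if (alphabet == "protein") Biostrings::AAStringSet(residues)
       else Biostrings::DNAStringSet(residues)
  names(x) <- ids
  S4Vectors::mcols(x) <- S4Vectors::DataFrame(
    description = rep_len(as.character(descriptions), length(x)))
  x
}

validate_ids <- function(ids) {
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stopf("duplicate sequence ids: %s", paste(dup, collapse = ", "))
  invisible(ids)
}

validate_residues <- function(residues, ids, alphabet) {
  allowed <- if (alphabet == "protein") PROTEIN_ALPHABET else NUCLEOTIDE_ALPHABET
  pat <- paste0("[^", paste(allowed, collapse = ""), "]")
  for (i in seq_along(residues)) {
    if (!nzchar(residues[[i]]))
      stopf("sequence '%s' is empty", ids[[i]])
    m <- regexpr(pat, residues[[i]])
    if (m > 0L)
      stopf("illegal %s residue '%s' in record '%s' at position %d",
            alphabet, substr(residues[[i]], m, m), ids[[i]], m)
  }
  invisible(residues)
}

seq_alphabet <- function(x) {
  if (is(x, "AAStringSet") || is(x, "AAString")) "protein"
  else if (is(x, "DNAStringSet") || is(x, "DNAString")) "nucleotide"
  else stopf("unsupported sequence class: %s", class(x)[[1]])
}

#' Read a FASTA file into a validated sequence collection
#'
#' Headers are split at the first whitespace: the first token becomes the
#' record id, the remainder its description. Wrapped sequence lines are
#' concatenated; residues are uppercased and validated against the
#' declared alphabet. Duplicate ids and illegal residues are errors; an
#' empty file yields an empty collection with a warning.
#'
#' @param path path to a FASTA file.
#' @inheritParams seq_set
#' @return see [seq_set()].
#' @export
read_fasta <- function(path, alphabet = c("protein", "nucleotide")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stopf("no such file: %s", path)
  raw <- if (alphabet == "protein")
    Biostrings::readAAStringSet(path) else
    Biostrings::readDNAStringSet(path)
  if (length(raw) == 0L) {
    warning(sprintf("empty FASTA file: %s", path))
    return(seq_set_empty(alphabet))
  }
  headers <- names(raw)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  seq_set(setNames(as.character(raw), ids), alphabet, desc)
}

seq_set_empty <- function(alphabet) {
  x <- if (alphabet == "protein") Biostrings::AAStringSet()
       else Biostrings::DNAStringSet()
  S4Vectors::mcols(x) <- S4Vectors::DataFrame(description = character(0))
  x
}

#' Write a sequence collection to FASTA
#'
#' Output is byte-stable for a given `line_width` and round-trips through
#' [read_fasta()].
#'
#' @param x an `XStringSet` as returned by [seq_set()] / [read_fasta()].
#' @param path output path.
#' @param line_width residues per sequence line.
#' @export
write_fasta <- function(x, path, line_width = 60L) {
  stopifnot(line_width >= 1L)
  desc <- descriptions(x)
  out <- x
  names(out) <- ifelse(nzchar(desc), paste(names(x), desc), names(x))
  Biostrings::writeXStringSet(out, filepath = path, width = line_width)
  invisible(path)
}

#' Per-record descriptions of a collection
#' @param x an `XStringSet`.
#' @return character vector (empty strings where absent).
#' @export
descriptions <- function(x) {
  mc <- S4Vectors::mcols(x)
  if (!is.null(mc) && "description" %in% colnames(mc))
    as.character(mc$description)
  else rep("", length(x))
}

# Extract one record as a length-1 set, preserving its id.
seq_get <- function(x, id) {
  if (!id %in% names(x)) stopf("no sequence with id '%s'", id)
  x[id]
}
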