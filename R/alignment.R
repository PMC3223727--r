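# Local alignment primitive.
#
# Smith-Waterman with affine gaps (Biostrings' dynamic program) plays
# the role BLASTP / a read mapper would play at database scale: all
# comparisons here are exhaustive. E-values use the Karlin-Altschul form
# E = K * m * n * exp(-lambda * S); lambda and K are fixed per scoring
# scheme (an ungapped-style approximation -- thresholds, not absolute
# E-values, drive every downstream decision).

#' Scoring scheme for local alignment
#'
#' Defaults mirror the classic BLAST parameterizations: protein scoring
#' is BLOSUM62 with gap open -11 / extend -1 (lambda = 0.267,
#' K = 0.041); nucleotide scoring is match +1 / mismatch -2 with gap
#' open -5 / extend -2 (lambda = 1.28, K = 0.46). A gap of length L
#' costs |gap_open| + L * |gap_extend|.
#'
#' @param type `"protein"` or `"nucleotide"`.
#' @param substitution_matrix symmetric integer scoring matrix; default
#'   BLOSUM62 (protein) or a match/mismatch matrix over ACGTN
#'   (nucleotide, N treated as mismatch).
#' @param gap_open,gap_extend negative gap penalties,
#'   `gap_open <= gap_extend < 0`.
#' @param lambda,karlin_k Karlin-Altschul parameters for the E-value.
#' @param match,mismatch scores used to build the default nucleotide
#'   matrix (ignored when `substitution_matrix` is supplied).
#' @return An object of class `scoring_scheme`.
#' @export
scoring_scheme <- function(type = c("protein", "nucleotide"),
                           substitution_matrix = NULL,
                           gap_open = NULL, gap_extend = NULL,
                           lambda = NULL, karlin_k = NULL,
                           match = 1L, mismatch = -2L) {
  type <- match.arg(type)
  if (type == "protein") {
    substitution_matrix <- substitution_matrix %||% blosum62_matrix()
    gap_open <- gap_open %||% -11L
    gap_extend <- gap_extend %||% -1L
    lambda <- lambda %||% 0.267
    karlin_k <- karlin_k %||% 0.041
  } else {
    substitution_matrix <- substitution_matrix %||%
      nucleotide_matrix(match, mismatch)
    gap_open <- gap_open %||% -5L
    gap_extend <- gap_extend %||% -2L
    lambda <- lambda %||% 1.28
    karlin_k <- karlin_k %||% 0.46
  }
  if (!(gap_open <= gap_extend && gap_extend < 0))
    stopf("gap penalties must satisfy gap_open <= gap_extend < 0")
  if (!isTRUE(all.equal(substitution_matrix, t(substitution_matrix))))
    stopf("substitution matrix must be symmetric")
  if (lambda <= 0 || karlin_k <= 0)
    stopf("lambda and karlin_k must be positive")
  structure(list(type = type,
                 substitution_matrix = substitution_matrix,
                 gap_open = gap_open, gap_extend = gap_extend,
                 lambda = lambda, karlin_k = karlin_k),
            class = "scoring_scheme")
}

blosum62_cache <- new.env(parent = emptyenv())

blosum62_matrix <- function() {
  if (is.null(blosum62_cache$m)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    blosum62_cache$m <- e$BLOSUM62
  }
  blosum62_cache$m
}

nucleotide_matrix <- function(match = 1L, mismatch = -2L) {
  letters <- c("A", "C", "G", "T", "N")
  m <- matrix(as.numeric(mismatch), 5, 5, dimnames = list(letters, letters))
  diag(m) <- match
  m["N", "N"] <- mismatch   # N never counts as a match
  m
}

#' @export
print.scoring_scheme <- function(x, ...) {
  cat(sprintf(
    "<scoring_scheme> %s; gap open %d / extend %d; lambda=%.3f K=%.3f\n",
    x$type, x$gap_open, x$gap_extend, x$lambda, x$karlin_k))
  invisible(x)
}

karlin_evalue <- function(score, m, n, scheme) {
  scheme$karlin_k * as.numeric(m) * as.numeric(n) *
    exp(-scheme$lambda * score)
}

bit_score <- function(score, scheme) {
  (scheme$lambda * score - log(scheme$karlin_k)) / log(2)
}

# Align each sequence of `queries` against the single sequence
# `subject`; returns one row per query. Spans are 0-based half-open on
# the ungapped sequences. A query with no positive-scoring local
# alignment gets score 0 and an empty span.
align_many <- function(queries, subject, scheme) {
  stopifnot(length(subject) == 1L)
  S4Vectors::mcols(queries) <- NULL   # silence mcols-drop warning
  pa <- Biostrings::pairwiseAlignment(
    pattern = queries, subject = subject[[1L]], type = "local",
    substitutionMatrix = scheme$substitution_matrix,
    gapOpening = abs(scheme$gap_open), gapExtension = abs(scheme$gap_extend))
  aln_length <- Biostrings::nchar(pa)
  identities <- Biostrings::nmatch(pa)
  sc <- Biostrings::score(pa)
  empty <- aln_length == 0L | sc <= 0
  qs <- ifelse(empty, 0L, S4Vectors::start(Biostrings::pattern(pa)) - 1L)
  qe <- ifelse(empty, 0L, S4Vectors::end(Biostrings::pattern(pa)))
  ss <- ifelse(empty, 0L, S4Vectors::start(Biostrings::subject(pa)) - 1L)
  se <- ifelse(empty, 0L, S4Vectors::end(Biostrings::subject(pa)))
  data.frame(
    query_id = names(queries),
    subject_id = names(subject),
    score = ifelse(empty, 0, sc),
    evalue = karlin_evalue(ifelse(empty, 0, sc),
                           Biostrings::width(queries),
                           Biostrings::width(subject), scheme),
    aln_length = ifelse(empty, 0L, aln_length),
    identities = ifelse(empty, 0L, identities),
    mismatches = ifelse(empty, 0L, Biostrings::nmismatch(pa)),
    gap_opens = ifelse(empty, 0L, rowSums(Biostrings::nindel(pa)@insertion[, 1, drop = FALSE]) +
                                  rowSums(Biostrings::nindel(pa)@deletion[, 1, drop = FALSE])),
    pident = ifelse(empty, 0, identities / pmax(aln_length, 1L)),
    q_start = qs, q_end = qe, s_start = ss, s_end = se,
    strand = "+",
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Optimal local alignment of two sequences
#'
#' Smith-Waterman local alignment under affine gap penalties. For
#' nucleotide sequences both strands are scored by default and the
#' better hit is kept, with reverse-strand hits reported on forward
#' query coordinates and `strand == "-"`. Percent identity is
#' identities / alignment columns (gap columns included).
#'
#' @param query,subject length-1 sequence collections (see [seq_set()])
#'   sharing one alphabet.
#' @param scheme a [scoring_scheme()] matching the alphabet.
#' @param both_strands for nucleotide input, also score the reverse
#'   complement of the query.
#' @return A one-row data.frame: ids, raw `score`, Karlin-Altschul
#'   `evalue`, `aln_length`, `identities`, `pident`, 0-based half-open
#'   `q_start`/`q_end`/`s_start`/`s_end`, and `strand`.
#' @export
local_align <- function(query, subject, scheme = NULL, both_strands = TRUE) {
  alpha <- seq_alphabet(query)
  if (alpha != seq_alphabet(subject))
    stopf("query and subject must share one alphabet")
  stopifnot(length(query) == 1L, length(subject) == 1L)
  if (Biostrings::width(query)[1] == 0L || Biostrings::width(subject)[1] == 0L)
    stopf("cannot align empty sequences")
  scheme <- scheme %||% scoring_scheme(alpha)
  if (scheme$type != alpha)
    stopf("scoring scheme type '%s' does not match alphabet '%s'",
          scheme$type, alpha)
  fwd <- align_many(query, subject, scheme)
  if (alpha == "nucleotide" && both_strands) {
    rcq <- Biostrings::reverseComplement(query)
    names(rcq) <- names(query)
    rev <- align_many(rcq, subject, scheme)
    if (rev$score > fwd$score) {     # tie prefers the forward strand
      w <- Biostrings::width(query)[1]
      qs <- w - rev$q_end
      rev$q_end <- w - rev$q_start
      rev$q_start <- qs
      rev$strand <- "-"
      return(rev)
    }
  }
  fwd
}

#' Aligned-span coverage of a sequence
#'
#' Fraction of a sequence's length covered by the aligned span of an
#' alignment result, the quantity thresholded by the paralog-clustering
#' length cutoff.
#'
#' @param aln a one-row alignment data.frame from [local_align()].
#' @param seq the length-1 collection holding the sequence referred to.
#' @param which `"query"` or `"subject"`.
#' @return Numeric fraction in \[0, 1\].
#' @export
length_coverage <- function(aln, seq, which = c("query", "subject")) {
  which <- match.arg(which)
  id <- if (which == "query") aln$query_id else aln$subject_id
  if (!identical(id, names(seq)[[1]]))
    stopf("alignment %s id '%s' does not match sequence id '%s'",
          which, id, names(seq)[[1]])
  span <- if (which == "query") aln$q_end - aln$q_start
          else aln$s_end - aln$s_start
  span / Biostrings::width(seq)[[1]]
}

#' Export alignments as BLAST outfmt-6 rows
#'
#' Tab-separated qseqid, sseqid, pident (percent), length, mismatch,
#' gapopen, qstart, qend, sstart, send, evalue, bitscore. Coordinates in
#' this export only are 1-based inclusive, for ecosystem compatibility.
#'
#' @param alignments data.frame of alignment rows (rbind of
#'   [local_align()] results).
#' @param path output path.
#' @param scheme the [scoring_scheme()] used (for the bit score).
#' @export
write_blast6 <- function(alignments, path, scheme) {
  out <- data.frame(
    qseqid = alignments$query_id,
    sseqid = alignments$subject_id,
    pident = sprintf("%.2f", 100 * alignments$pident),
    length = alignments$aln_length,
    mismatch = alignments$mismatches,
    gapopen = alignments$gap_opens,
    qstart = alignments$q_start + 1L, qend = alignments$q_end,
    sstart = alignments$s_start + 1L, send = alignments$s_end,
    evalue = format(alignments$evalue, digits = 3, scientific = TRUE),
    bitscore = sprintf("%.1f", bit_score(alignments$score, scheme)))
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
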