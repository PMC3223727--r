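# ORF sequence tags (OSTs): paired Sanger-style end reads of cloned
# ORFs. The forward and reverse reads are clipped of vector/tail
# contamination upstream (see trim_reads), merged into a contig when
# their overlap supports it, and used to verify the predicted CDS at
# both ends.

#' Merge paired end reads into a contig
#'
#' The reverse read is reverse-complemented; if a suffix of the forward
#' read overlaps a prefix of the reverse-complemented reverse read with
#' at least `min_overlap` aligned columns at `min_identity` or better
#' (overlap ends anchored within `end_slack` nt), the two are merged,
#' the forward read's bases winning at disagreements. Returns NULL when
#' no qualifying overlap exists (the reads stay singlets).
#'
#' @param fwd,rev length-1 nucleotide collections (raw orientation:
#'   `rev` reads the opposite strand).
#' @param min_overlap minimum overlap columns (default 20).
#' @param min_identity minimum overlap identity (default 0.95).
#' @param end_slack tolerated unaligned terminal bases at the junction.
#' @param scheme nucleotide [scoring_scheme()].
#' @return Length-1 `DNAStringSet` named `<fwd_id>_contig`, or NULL.
#' @export
assemble_ends <- function(fwd, rev, min_overlap = 20L, min_identity = 0.95,
                          end_slack = 5L,
                          scheme = scoring_scheme("nucleotide")) {
  stopifnot(length(fwd) == 1L, length(rev) == 1L)
  rcr <- Biostrings::reverseComplement(rev)
  names(rcr) <- names(rev)
  aln <- local_align(fwd, rcr, scheme, both_strands = FALSE)
  if (aln$score <= 0 || aln$aln_length < min_overlap ||
      aln$pident < min_identity)
    return(NULL)
  wf <- Biostrings::width(fwd)[[1]]
  wr <- Biostrings::width(rcr)[[1]]
  # suffix-of-forward / prefix-of-reverse geometry, up to end_slack
  if ((wf - aln$q_end) > end_slack || aln$s_start > end_slack)
    return(NULL)
  merged <- paste0(substr(as.character(fwd[[1]]), 1L, aln$q_end),
                   substr(as.character(rcr[[1]]), aln$s_end + 1L, wr))
  seq_set(setNames(merged, paste0(names(fwd), "_contig")), "nucleotide")
}

#' Verify a predicted CDS from its end reads
#'
#' The 5' end is verified when the forward read (or the contig) aligns
#' to the reference covering its first base at `min_identity` or
#' better; the 3' end analogously for the last base using the reverse
#' read (or contig). `full_length_contig` additionally requires an
#' assembled contig aligning at >= `full_identity` identity over
#' >= `full_coverage` of the reference length.
#'
#' @param fwd,rev length-1 nucleotide collections (trimmed end reads).
#' @param contig result of [assemble_ends()] (may be NULL).
#' @param reference_cds length-1 nucleotide collection (predicted CDS).
#' @param min_identity identity required of an end-covering alignment.
#' @param full_identity,full_coverage contig requirements for a
#'   full-length call.
#' @param scheme nucleotide [scoring_scheme()].
#' @return list: `reference_id`, `five_prime_ok`, `three_prime_ok`,
#'   `both_ends_ok`, `full_length_contig`.
#' @export
verify_ost <- function(fwd, rev, contig, reference_cds,
                       min_identity = 0.95, full_identity = 0.98,
                       full_coverage = 0.98,
                       scheme = scoring_scheme("nucleotide")) {
  len <- Biostrings::width(reference_cds)[[1]]
  covers <- function(x, want_start, want_end) {
    if (is.null(x)) return(FALSE)
    aln <- local_align(x, reference_cds, scheme, both_strands = TRUE)
    if (aln$score <= 0 || aln$pident < min_identity) return(FALSE)
    (!want_start || aln$s_start == 0L) && (!want_end || aln$s_end == len)
  }
  five <- covers(fwd, TRUE, FALSE) || covers(contig, TRUE, FALSE)
  three <- covers(rev, FALSE, TRUE) || covers(contig, FALSE, TRUE)
  full <- FALSE
  if (!is.null(contig) && five && three) {
    aln <- local_align(contig, reference_cds, scheme, both_strands = TRUE)
    full <- aln$score > 0 && aln$pident >= full_identity &&
      (aln$s_end - aln$s_start) / len >= full_coverage
  }
  list(reference_id = names(reference_cds),
       five_prime_ok = five, three_prime_ok = three,
       both_ends_ok = five && three, full_length_contig = full)
}

#' Verify a set of clones from paired end reads
#'
#' For each reference CDS with a matching pair of trimmed end reads,
#' attempts contig assembly and end verification.
#'
#' @param fwd_reads,rev_reads nucleotide collections whose names carry
#'   the target ORF id (see `orf_of`).
#' @param references nucleotide collection of predicted CDSs.
#' @param orf_of function mapping a read id to its ORF id (default
#'   strips a trailing `_5` / `_3` suffix).
#' @param ... passed to [verify_ost()].
#' @return data.frame with one row per reference that has both reads:
#'   the [verify_ost()] fields plus `contig_assembled`.
#' @export
verify_ost_set <- function(fwd_reads, rev_reads, references,
                           orf_of = function(id) sub("_[53]$", "", id),
                           ...) {
  fmap <- setNames(names(fwd_reads), vapply(names(fwd_reads), orf_of, ""))
  rmap <- setNames(names(rev_reads), vapply(names(rev_reads), orf_of, ""))
  orfs <- intersect(names(references), intersect(names(fmap), names(rmap)))
  rows <- lapply(orfs, function(o) {
    fwd <- fwd_reads[fmap[[o]]]
    rev <- rev_reads[rmap[[o]]]
    contig <- assemble_ends(fwd, rev)
    v <- verify_ost(fwd, rev, contig, references[o], ...)
    data.frame(reference_id = o,
               five_prime_ok = v$five_prime_ok,
               three_prime_ok = v$three_prime_ok,
               both_ends_ok = v$both_ends_ok,
               contig_assembled = !is.null(contig),
               full_length_contig = v$full_length_contig,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(reference_id = character(),
                      five_prime_ok = logical(), three_prime_ok = logical(),
                      both_ends_ok = logical(), contig_assembled = logical(),
                      full_length_contig = logical(),
                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
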