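# Structural verification of ORF models from sequencing reads:
# trim contaminants -> drop short reads -> map against references
# (minimum 40 nt aligned overlap, 90% identity) -> per-base coverage ->
# classify (verified when more than 98% of the reference length is
# covered) -> histogram bins.

#' Trim vector / adapter contamination and drop short reads
#'
#' For each read, any contaminant matched by local alignment at
#' identity >= `min_identity` over >= `min_match` nt (and alignment
#' score >= `min_match`), with the matched read span starting (ending)
#' within `end_slack` nt of the read start (end), is clipped off
#' together with everything outside it. Matches are anchored the way
#' adapter trimmers anchor them: the matched span must include the
#' contaminant terminus that faces the read interior, which rejects
#' chance internal look-alikes. Both contaminant strands are searched,
#' the best-scoring qualifying match clips first, and clipping repeats
#' until stable.
#' Reads shorter than `min_len` after trimming are dropped; the number
#' dropped is available as `attr(result, "n_dropped")`.
#'
#' @param reads nucleotide collection.
#' @param contaminants nucleotide collection of vector / tail
#'   sequences.
#' @param min_len minimum surviving read length (default 20 nt).
#' @param min_identity,min_match,end_slack contamination-match rules.
#' @param scheme nucleotide [scoring_scheme()].
#' @return Trimmed `DNAStringSet` (empty descriptions preserved), with
#'   attribute `n_dropped`.
#' @export
trim_reads <- function(reads, contaminants, min_len = 20L,
                       min_identity = 0.90, min_match = 10L,
                       end_slack = 5L, scheme = scoring_scheme("nucleotide")) {
  cont <- as.character(contaminants)
  cont <- c(cont, vapply(cont, function(s)
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s))),
    character(1)))
  cur <- as.character(reads)
  ids <- names(reads)
  # each pass aligns every still-active read against every contaminant
  # strand in one vectorized call per strand, clips each read with its
  # best-scoring qualifying match, and repeats on the clipped reads
  # until stable
  active <- rep(TRUE, length(cur))
  repeat {
    idx <- which(active & nchar(cur) >= min_match)
    if (length(idx) == 0L) break
    sub <- seq_set(setNames(cur[idx], ids[idx]), "nucleotide")
    read_len <- nchar(cur[idx])
    n <- length(idx)
    best_score <- rep(-Inf, n)
    best_start <- integer(n)
    best_end <- integer(n)
    best_at_start <- logical(n)
    for (cs in cont) {
      a <- align_many(sub, seq_set(setNames(cs, "cont"), "nucleotide"),
                      scheme)
      # the read plays the query role here, so q_* is the read span and
      # s_* the contaminant span. Anchored-adapter geometry: a genuine
      # contaminant run at a read end always includes the contaminant
      # terminus that faces the read interior (tail 3' end before the
      # insert, 5' end after it). Tails can be near-duplicates of each
      # other; the best-scoring match identifies the true contaminant.
      at_start <- a$q_start <= end_slack & nchar(cs) - a$s_end <= end_slack
      at_end <- read_len - a$q_end <= end_slack & a$s_start <= end_slack
      upd <- a$score >= min_match & a$pident >= min_identity &
        (a$q_end - a$q_start) >= min_match &
        (at_start | at_end) & a$score > best_score
      best_score[upd] <- a$score[upd]
      best_start[upd] <- a$q_start[upd]
      best_end[upd] <- a$q_end[upd]
      best_at_start[upd] <- at_start[upd]
    }
    hit <- best_score > -Inf
    active[] <- FALSE
    if (!any(hit)) break
    ih <- idx[hit]
    cur[ih] <- ifelse(best_at_start[hit],
                      substr(cur[ih], best_end[hit] + 1L, nchar(cur[ih])),
                      substr(cur[ih], 1L, best_start[hit]))
    active[ih] <- nchar(cur[ih]) > 0L
  }
  keep <- nchar(cur) >= min_len
  res <- seq_set(setNames(cur[keep], ids[keep]), "nucleotide")
  attr(res, "n_dropped") <- sum(!keep)
  res
}

# Shared k-mer prescreen: candidate references for each read. Exact
# k-mer sharing on either strand; NULL index means all references are
# candidates.
kmer_index <- function(references, k = 12L) {
  idx <- new.env(parent = emptyenv())
  for (id in names(references)) {
    s <- as.character(references[[id]])
    n <- nchar(s)
    if (n < k) next
    kms <- unique(substring(s, 1:(n - k + 1L), k:n))
    for (km in kms) assign(km, c(idx[[km]], id), envir = idx)
  }
  attr(idx, "k") <- k
  idx
}

kmer_candidates <- function(read_seq, idx) {
  k <- attr(idx, "k")
  hits <- character(0)
  for (s in c(read_seq,
              as.character(Biostrings::reverseComplement(
                Biostrings::DNAString(read_seq))))) {
    n <- nchar(s)
    if (n < k) next
    for (km in unique(substring(s, 1:(n - k + 1L), k:n))) {
      v <- idx[[km]]
      if (!is.null(v)) hits <- c(hits, v)
    }
  }
  unique(hits)
}

# Align a set of reads against one reference on both strands, keeping
# the better strand per read (ties prefer the forward strand);
# reverse-strand spans are reported on forward read coordinates, as in
# local_align().
align_reads_to_ref <- function(reads_sub, ref, scheme) {
  fwd <- align_many(reads_sub, ref, scheme)
  rcq <- Biostrings::reverseComplement(reads_sub)
  names(rcq) <- names(reads_sub)
  rev <- align_many(rcq, ref, scheme)
  take <- rev$score > fwd$score
  out <- fwd
  if (any(take)) {
    w <- Biostrings::width(reads_sub)
    qs <- w - rev$q_end
    qe <- w - rev$q_start
    out[take, ] <- rev[take, , drop = FALSE]
    out$q_start[take] <- qs[take]
    out$q_end[take] <- qe[take]
    out$strand[take] <- "-"
  }
  out
}

#' Map reads against reference sequences
#'
#' Every read is aligned (both strands) against each reference by
#' Smith-Waterman; hits are kept when the aligned span on the read is
#' at least `min_overlap` nt and percent identity is at least
#' `min_identity`. A read may map to several paralogous references
#' (`mode = "all"`); `mode = "best"` keeps only its highest-scoring
#' reference. With `prefilter_k` set (the default), references sharing
#' no exact k-mer with the read on either strand are skipped before
#' alignment -- a seeding shortcut that does not change which hits pass
#' the thresholds in practice and can be disabled with
#' `prefilter_k = NULL`.
#'
#' @param reads,references nucleotide collections.
#' @param scheme nucleotide [scoring_scheme()].
#' @param min_overlap minimum aligned span on the read (nt).
#' @param min_identity minimum percent identity (fraction).
#' @param mode `"all"` or `"best"`.
#' @param prefilter_k k-mer length for the candidate prescreen, or
#'   NULL for exhaustive alignment.
#' @return data.frame: `read_id`, `reference_id`, `ref_start`,
#'   `ref_end` (0-based half-open), `read_start`, `read_end`,
#'   `identity`, `score`, `strand`.
#' @export
map_reads <- function(reads, references, scheme = scoring_scheme("nucleotide"),
                      min_overlap = 40L, min_identity = 0.90,
                      mode = c("all", "best"), prefilter_k = 12L) {
  mode <- match.arg(mode)
  if (length(references) == 0L) stopf("empty reference set")
  idx <- if (!is.null(prefilter_k)) kmer_index(references, prefilter_k)
  ref_ids <- names(references)
  # invert the candidate relation so each reference is aligned against
  # all of its candidate reads in one vectorized call per strand
  cand_reads <- vector("list", length(ref_ids))
  names(cand_reads) <- ref_ids
  for (i in seq_along(reads)) {
    cand <- if (is.null(idx)) ref_ids
            else kmer_candidates(as.character(reads[[i]]), idx)
    for (rid in cand) cand_reads[[rid]] <- c(cand_reads[[rid]], i)
  }
  chunks <- vector("list", length(ref_ids))
  for (r in seq_along(ref_ids)) {
    ri <- cand_reads[[r]]
    if (is.null(ri)) next
    hits <- align_reads_to_ref(reads[ri], references[r], scheme)
    keep <- hits$score > 0 &
      (hits$q_end - hits$q_start) >= min_overlap &
      hits$pident >= min_identity
    if (!any(keep)) next
    hits <- hits[keep, , drop = FALSE]
    chunks[[r]] <- data.frame(
      read_idx = ri[keep],
      read_id = hits$query_id, reference_id = hits$subject_id,
      ref_start = hits$s_start, ref_end = hits$s_end,
      read_start = hits$q_start, read_end = hits$q_end,
      identity = hits$pident, score = hits$score, strand = hits$strand,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, chunks)
  if (is.null(out))
    return(data.frame(read_id = character(), reference_id = character(),
                      ref_start = integer(), ref_end = integer(),
                      read_start = integer(), read_end = integer(),
                      identity = numeric(), score = numeric(),
                      strand = character(), stringsAsFactors = FALSE))
  # canonical row order -- by read, then reference input position -- so
  # the output does not depend on the prescreen's candidate ordering
  out <- out[order(out$read_idx, match(out$reference_id, ref_ids)), ,
             drop = FALSE]
  if (mode == "best") {
    o <- order(out$read_idx, -out$score, out$reference_id)
    out <- out[o, , drop = FALSE]
    out <- out[!duplicated(out$read_idx), , drop = FALSE]
  }
  out$read_idx <- NULL
  rownames(out) <- NULL
  out
}

#' Per-base coverage of one reference
#'
#' @param mappings data.frame from [map_reads()] (rows for other
#'   references are ignored).
#' @param reference length-1 nucleotide collection.
#' @return list of class `coverage_profile`: `reference_id`, integer
#'   `depth` of reference length, and `percent_covered` in \[0, 100\].
#' @export
coverage_profile <- function(mappings, reference) {
  stopifnot(length(reference) == 1L)
  rid <- names(reference)
  len <- Biostrings::width(reference)[[1]]
  depth <- integer(len)
  m <- mappings[mappings$reference_id == rid, , drop = FALSE]
  for (j in seq_len(nrow(m))) {
    a <- max(m$ref_start[j] + 1L, 1L)
    b <- min(m$ref_end[j], len)
    if (b >= a) depth[a:b] <- depth[a:b] + 1L
  }
  structure(list(reference_id = rid, depth = depth,
                 percent_covered = 100 * sum(depth > 0) / len),
            class = "coverage_profile")
}

COVERAGE_BINS <- c("95-100", "50-95", "20-50", "<20")

coverage_bin <- function(percent) {
  if (percent >= 95) "95-100"
  else if (percent >= 50) "50-95"
  else if (percent >= 20) "20-50"
  else "<20"
}

#' Classify a reference from its coverage profile
#'
#' A reference is `verified` when strictly more than 98% of its length
#' is covered by at least one mapped read; references below 20%
#' coverage are `unsupported`; everything between is `partial`.
#' Coverage bins are half-open on the left except the top bin:
#' \[95,100\], \[50,95), \[20,50), \[0,20).
#'
#' @param profile a [coverage_profile()].
#' @return list: `reference_id`, `status`, `coverage_bin`,
#'   `percent_covered`.
#' @export
classify_verification <- function(profile) {
  p <- profile$percent_covered
  status <- if (p > 98) "verified" else if (p < 20) "unsupported" else "partial"
  list(reference_id = profile$reference_id, status = status,
       coverage_bin = coverage_bin(p), percent_covered = p)
}

#' Verify a reference set from reads
#'
#' Convenience wrapper: maps reads, computes coverage per reference and
#' classifies each.
#'
#' @inheritParams map_reads
#' @return list with `mappings`, `report` (data.frame: reference_id,
#'   percent_covered, status, coverage_bin) and `histogram` (bin
#'   counts).
#' @export
verify_references <- function(reads, references,
                              scheme = scoring_scheme("nucleotide"),
                              min_overlap = 40L, min_identity = 0.90,
                              mode = c("all", "best"), prefilter_k = 12L) {
  mode <- match.arg(mode)
  mappings <- map_reads(reads, references, scheme, min_overlap,
                        min_identity, mode, prefilter_k)
  rows <- lapply(names(references), function(rid)
    classify_verification(coverage_profile(mappings, references[rid])))
  report <- data.frame(
    reference_id = vapply(rows, `[[`, character(1), "reference_id"),
    percent_covered = vapply(rows, `[[`, numeric(1), "percent_covered"),
    status = vapply(rows, `[[`, character(1), "status"),
    coverage_bin = vapply(rows, `[[`, character(1), "coverage_bin"),
    stringsAsFactors = FALSE)
  hist <- table(factor(report$coverage_bin, levels = COVERAGE_BINS))
  list(mappings = mappings, report = report,
       histogram = data.frame(bin = COVERAGE_BINS, n = as.integer(hist),
                              stringsAsFactors = FALSE))
}

#' Export mappings as a minimal SAM file
#'
#' Header plus one line per mapping: QNAME, FLAG (0 or 16 for strand),
#' RNAME, 1-based POS, MAPQ 255, a fully-aligned-span CIGAR
#' (`<span>M`), and `*` placeholders.
#'
#' @param mappings data.frame from [map_reads()].
#' @param references the reference collection (for `@SQ` header lines).
#' @param path output path.
#' @export
write_sam <- function(mappings, references, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unknown", con)
  for (id in names(references))
    writeLines(sprintf("@SQ\tSN:%s\tLN:%d", id,
                       Biostrings::width(references[id])[[1]]), con)
  if (nrow(mappings))
    writeLines(sprintf("%s\t%d\t%s\t%d\t255\t%dM\t*\t0\t0\t*\t*",
                       mappings$read_id,
                       ifelse(mappings$strand == "-", 16L, 0L),
                       mappings$reference_id,
                       mappings$ref_start + 1L,
                       mappings$ref_end - mappings$ref_start), con)
  invisible(path)
}
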