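# Shared fixture builders. Everything is generated in code, under
# explicit seeds, so the suite ships no data files.

AA20 <- c("A","C","D","E","F","G","H","I","K","L",
          "M","N","P","Q","R","S","T","V","W","Y")

rand_protein <- function(len) paste(sample(AA20, len, TRUE), collapse = "")

rand_dna <- function(len) paste(sample(c("A","C","G","T"), len, TRUE),
                                collapse = "")

rand_protein_set <- function(n, len_range = c(30, 60), prefix = "p") {
  lens <- sample(len_range[1]:len_range[2], n, replace = TRUE)
  seqs <- vapply(lens, rand_protein, character(1))
  seq_set(setNames(seqs, sprintf("%s%03d", prefix, seq_len(n))), "protein")
}

# Brute-force optimal local alignment score by recursive enumeration of
# every alignment path over every pair of substrings, with affine gap
# costs (a gap of length L costs |open| + L * |ext|, charged as
# open + ext on the first gap column and ext on each continuation).
# Exponential; only for tiny sequences.
brute_force_local_score <- function(a, b, scheme) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  open <- scheme$gap_open; ext <- scheme$gap_extend
  m <- scheme$substitution_matrix
  # Best score over alignments consuming A[i+1..i1] and B[j+1..j1]
  # completely, given the state of the previous alignment column.
  rec <- function(i, j, i1, j1, state) {
    if (i == i1 && j == j1) return(0)
    best <- -Inf
    if (i < i1 && j < j1)
      best <- max(best, m[A[i + 1], B[j + 1]] + rec(i + 1, j + 1, i1, j1, "d"))
    if (i < i1)
      best <- max(best, (if (state == "u") ext else open + ext) +
                    rec(i + 1, j, i1, j1, "u"))
    if (j < j1)
      best <- max(best, (if (state == "l") ext else open + ext) +
                    rec(i, j + 1, i1, j1, "l"))
    best
  }
  best <- 0  # the empty local alignment scores 0
  for (i0 in 0:(length(A) - 1)) for (j0 in 0:(length(B) - 1))
    for (i1 in (i0 + 1):length(A)) for (j1 in (j0 + 1):length(B))
      best <- max(best, rec(i0, j0, i1, j1, "s"))
  best
}

# Independent connected-components by depth-first search on an explicit
# edge list (ids as vertices).
brute_force_components <- function(ids, edges) {
  adj <- setNames(vector("list", length(ids)), ids)
  for (r in seq_len(nrow(edges))) {
    a <- edges$from[r]; b <- edges$to[r]
    adj[[a]] <- c(adj[[a]], b); adj[[b]] <- c(adj[[b]], a)
  }
  comp <- setNames(rep(NA_integer_, length(ids)), ids)
  cid <- 0L
  for (v in ids) {
    if (!is.na(comp[[v]])) next
    cid <- cid + 1L
    stack <- v
    while (length(stack)) {
      u <- stack[[1]]; stack <- stack[-1]
      if (!is.na(comp[[u]])) next
      comp[[u]] <- cid
      stack <- c(stack, adj[[u]])
    }
  }
  comp
}

# The explicit 35%/70% similarity edge list, built independently of
# cluster_paralogs (pairwise local_align calls, no shared code path
# beyond the alignment primitive itself).
explicit_edges <- function(proteome, scheme, identity_min = 0.35,
                           coverage_min = 0.70) {
  ids <- names(proteome)
  from <- character(0); to <- character(0)
  n <- length(ids)
  if (n >= 2) for (i in 1:(n - 1)) for (j in (i + 1):n) {
    a <- local_align(proteome[i], proteome[j], scheme)
    if (a$score <= 0) next
    covq <- length_coverage(a, proteome[i], "query")
    covs <- length_coverage(a, proteome[j], "subject")
    if (a$pident >= identity_min && covq >= coverage_min &&
        covs >= coverage_min) {
      from <- c(from, ids[i]); to <- c(to, ids[j])
    }
  }
  data.frame(from = from, to = to, stringsAsFactors = FALSE)
}

make_reads_tiling <- function(cds, step = 80L, read_len = 120L) {
  s <- as.character(cds[[1]])
  L <- nchar(s)
  starts <- unique(c(seq(1L, max(L - read_len + 1L, 1L), by = step),
                     max(L - read_len + 1L, 1L)))
  seqs <- vapply(starts, function(a)
    substr(s, a, min(a + read_len - 1L, L)), character(1))
  seq_set(setNames(seqs, sprintf("%s_t%03d", names(cds), seq_along(seqs))),
          "nucleotide")
}
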