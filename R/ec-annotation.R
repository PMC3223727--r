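# EC annotation: reciprocal-best-hit transfer plus paralog propagation.
#
# Stage (1): every translated ORF is searched against an EC-labelled
# enzyme database; reciprocal best hits (each sequence the other's
# highest-scoring match at E <= 1e-3) carry the database entry's EC
# numbers onto the ORF. Stage (2): the full proteome is clustered by
# single linkage (edges at >= 35% identity and >= 70% length coverage),
# and direct assignments are propagated to unannotated cluster members.

EC_PATTERN <- "^[0-9]+\\.[0-9]+\\.[0-9]+\\.([0-9]+|-)$"

#' Read an enzyme reference database
#'
#' The database is a protein FASTA plus a tab-separated annotation table
#' with columns `accession`, `ec_numbers` (semicolon-joined EC strings;
#' may be empty for entries annotated only with a free-text enzyme
#' name), and optionally `function_name` and `source`.
#'
#' @param fasta_path protein FASTA of database sequences.
#' @param tsv_path annotation table path.
#' @return A list with elements `sequences` (an `AAStringSet`) and
#'   `annotations` (data.frame with list-column `ec_numbers`).
#' @export
read_enzyme_db <- function(fasta_path, tsv_path) {
  seqs <- read_fasta(fasta_path, "protein")
  ann <- read.delim(tsv_path, stringsAsFactors = FALSE,
                    colClasses = "character")
  if (!all(c("accession", "ec_numbers") %in% names(ann)))
    stopf("enzyme db table needs 'accession' and 'ec_numbers' columns")
  enzyme_db(seqs, ann$accession, strsplit(ann$ec_numbers, ";", fixed = TRUE),
            function_name = ann$function_name %||% rep("", nrow(ann)),
            source = ann$source %||% rep("uniprot_like", nrow(ann)))
}

#' Construct an enzyme database object
#'
#' @param sequences `AAStringSet` of database proteins.
#' @param accession character vector matching `names(sequences)`.
#' @param ec_numbers list of character vectors of EC strings
#'   (`a.b.c.d`, last field may be `-`); an element may be empty when
#'   the entry carries only a free-text function.
#' @param function_name,source optional per-entry metadata.
#' @return list with `sequences` and `annotations`.
#' @export
enzyme_db <- function(sequences, accession = names(sequences),
                      ec_numbers, function_name = "",
                      source = "uniprot_like") {
  validate_ids(accession)
  if (!setequal(accession, names(sequences)))
    stopf("accessions must match the FASTA ids")
  ec_numbers <- lapply(ec_numbers, function(e) e[nzchar(e)])
  bad <- vapply(ec_numbers,
                function(e) any(!grepl(EC_PATTERN, e)), logical(1))
  if (any(bad))
    stopf("malformed EC numbers for: %s",
          paste(accession[bad], collapse = ", "))
  none <- lengths(ec_numbers) == 0 & !nzchar(rep_len(function_name,
                                                     length(accession)))
  if (any(none))
    stopf("entries with neither EC nor function name: %s",
          paste(accession[none], collapse = ", "))
  list(sequences = sequences[accession],
       annotations = data.frame(
         accession = accession,
         ec_numbers = I(ec_numbers),
         function_name = rep_len(as.character(function_name),
                                 length(accession)),
         source = rep_len(as.character(source), length(accession)),
         stringsAsFactors = FALSE))
}

#' Best database hit per query
#'
#' For each query, the single target with the highest raw alignment
#' score among hits with E-value at or below `evalue_max`. Score ties
#' are broken toward the lexicographically smallest target id so the
#' result is deterministic. Queries with no qualifying hit are absent.
#'
#' @param queries,targets protein collections (see [seq_set()]).
#' @param scheme protein [scoring_scheme()].
#' @param evalue_max E-value threshold.
#' @return data.frame with columns `query_id`, `target_id`, `score`,
#'   `evalue`, `pident`.
#' @export
best_hits <- function(queries, targets, scheme = scoring_scheme("protein"),
                      evalue_max = 1e-3) {
  if (length(targets) == 0L) stopf("empty target set")
  rows <- lapply(seq_along(queries), function(i) {
    hits <- align_many(targets, queries[i], scheme)
    # align_many treats `queries[i]` as the single subject; relabel so
    # the ORF is the query
    hits <- data.frame(query_id = hits$subject_id, target_id = hits$query_id,
                       score = hits$score, evalue = hits$evalue,
                       pident = hits$pident, stringsAsFactors = FALSE)
    hits <- hits[hits$score > 0 & hits$evalue <= evalue_max, , drop = FALSE]
    if (nrow(hits) == 0L) return(NULL)
    hits[order(-hits$score, hits$target_id), , drop = FALSE][1L, , drop = FALSE]
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(query_id = character(), target_id = character(),
                      score = numeric(), evalue = numeric(),
                      pident = numeric(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Reciprocal best hits between a proteome and an enzyme database
#'
#' Pairs (orf, accession) such that the accession is the orf's best hit
#' and the orf is the accession's best hit, both directions passing the
#' E-value threshold.
#'
#' @param proteome protein collection of translated ORFs.
#' @param db_sequences `AAStringSet` of database proteins (e.g.
#'   `enzyme_db(...)$sequences`).
#' @inheritParams best_hits
#' @return data.frame with columns `orf_id`, `accession`, `score`,
#'   `evalue`, `pident` (from the ORF-to-database direction).
#' @export
reciprocal_best_hits <- function(proteome, db_sequences,
                                 scheme = scoring_scheme("protein"),
                                 evalue_max = 1e-3) {
  fwd <- best_hits(proteome, db_sequences, scheme, evalue_max)
  if (nrow(fwd) == 0L)
    return(data.frame(orf_id = character(), accession = character(),
                      score = numeric(), evalue = numeric(),
                      pident = numeric(), stringsAsFactors = FALSE))
  rev <- best_hits(db_sequences, proteome, scheme, evalue_max)
  rev_map <- setNames(rev$target_id, rev$query_id)
  keep <- !is.na(rev_map[fwd$target_id]) &
    rev_map[fwd$target_id] == fwd$query_id
  out <- fwd[keep, , drop = FALSE]
  data.frame(orf_id = out$query_id, accession = out$target_id,
             score = out$score, evalue = out$evalue, pident = out$pident,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Transfer EC numbers across reciprocal best hits
#'
#' One assignment per RBH pair, carrying all EC numbers (and any
#' free-text function) of the matched database entry, with provenance
#' `rbh_direct`.
#'
#' @param rbh_pairs data.frame from [reciprocal_best_hits()].
#' @param db an enzyme database from [enzyme_db()] / [read_enzyme_db()].
#' @return data.frame of assignments: `orf_id`, list-column
#'   `ec_numbers`, `function_name`, `provenance`, `best_hit_accession`,
#'   `cluster_id` (NA until clustering).
#' @export
transfer_ec <- function(rbh_pairs, db) {
  ann <- db$annotations
  idx <- match(rbh_pairs$accession, ann$accession)
  if (anyNA(idx))
    stopf("RBH accession not in database: %s",
          paste(rbh_pairs$accession[is.na(idx)], collapse = ", "))
  data.frame(
    orf_id = rbh_pairs$orf_id,
    ec_numbers = I(unname(ann$ec_numbers[idx])),
    function_name = ann$function_name[idx],
    provenance = rep("rbh_direct", nrow(rbh_pairs)),
    best_hit_accession = rbh_pairs$accession,
    cluster_id = rep(NA_integer_, nrow(rbh_pairs)),
    stringsAsFactors = FALSE)
}

# Build the similarity edge list thresholded at identity and coverage.
# coverage_mode "both" requires the aligned span to cover >= coverage_min
# of each sequence; "shorter" only of the shorter one.
paralog_edges <- function(proteome, scheme, identity_min, coverage_min,
                          coverage_mode = c("both", "shorter")) {
  coverage_mode <- match.arg(coverage_mode)
  n <- length(proteome)
  widths <- Biostrings::width(proteome)
  from <- character(0); to <- character(0)
  if (n < 2L) return(data.frame(from = from, to = to))
  for (i in seq_len(n - 1L)) {
    rest <- (i + 1L):n
    hits <- align_many(proteome[rest], proteome[i], scheme)
    cov_q <- (hits$q_end - hits$q_start) / widths[rest]   # the later seqs
    cov_s <- (hits$s_end - hits$s_start) / widths[i]
    cov_ok <- if (coverage_mode == "both")
      cov_q >= coverage_min & cov_s >= coverage_min
    else  # coverage of the shorter sequence only
      ifelse(widths[rest] <= widths[i], cov_q, cov_s) >= coverage_min
    keep <- hits$score > 0 & hits$pident >= identity_min & cov_ok
    from <- c(from, rep(names(proteome)[i], sum(keep)))
    to <- c(to, names(proteome)[rest][keep])
  }
  data.frame(from = from, to = to, stringsAsFactors = FALSE)
}

#' Single-linkage paralog clustering
#'
#' Builds an undirected similarity graph with an edge between two
#' proteins when their optimal local alignment reaches both the
#' identity cutoff (default 35%) and the length-coverage cutoff
#' (default 70%, applied to both sequences), then takes connected
#' components. Single linkage deliberately chains: two sequences below
#' threshold between themselves still cluster together when linked
#' through an above-threshold intermediate. Every protein belongs to
#' exactly one cluster; unlinked proteins are singleton clusters.
#' Cluster ids are assigned by the lexicographically smallest member so
#' the result is invariant to input order.
#'
#' @param proteome protein collection.
#' @param scheme protein [scoring_scheme()].
#' @param identity_min minimum percent identity (fraction).
#' @param coverage_min minimum aligned-length coverage (fraction).
#' @param coverage_mode apply the coverage cutoff to `"both"` sequences
#'   or only to the `"shorter"` one.
#' @return data.frame with columns `orf_id`, `cluster_id` (integer).
#' @export
cluster_paralogs <- function(proteome, scheme = scoring_scheme("protein"),
                             identity_min = 0.35, coverage_min = 0.70,
                             coverage_mode = c("both", "shorter")) {
  edges <- paralog_edges(proteome, scheme, identity_min, coverage_min,
                         coverage_mode)
  ids <- names(proteome)
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = data.frame(name = ids))
  comp <- igraph::components(g)$membership[ids]
  # relabel components by smallest member id for order invariance
  anchor <- vapply(split(ids, comp), min, character(1))
  rank <- match(anchor[as.character(comp)], sort(anchor))
  data.frame(orf_id = ids, cluster_id = as.integer(rank),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Propagate EC assignments to paralogs
#'
#' Every unannotated member of a cluster containing at least one direct
#' (RBH) assignment receives the union of the cluster's direct EC sets
#' with provenance `paralog_propagated`. Direct assignments are passed
#' through unchanged (annotated with their cluster id); clusters with
#' no direct member contribute nothing. Clusters whose direct members
#' disagree on ECs are flagged (`ambiguous_cluster`), and the union is
#' propagated rather than suppressed.
#'
#' @param clusters data.frame from [cluster_paralogs()].
#' @param direct_assignments data.frame from [transfer_ec()].
#' @return data.frame of assignments (direct rows first), with an extra
#'   logical column `ambiguous_cluster`.
#' @export
propagate_ec <- function(clusters, direct_assignments) {
  cl <- setNames(clusters$cluster_id, clusters$orf_id)
  direct <- direct_assignments
  direct$cluster_id <- as.integer(cl[direct$orf_id])
  by_cluster <- split(seq_len(nrow(direct)), direct$cluster_id)
  union_ec <- lapply(by_cluster, function(ix)
    sort(unique(unlist(direct$ec_numbers[ix]))))
  union_fn <- lapply(by_cluster, function(ix)
    paste(sort(unique(direct$function_name[ix][nzchar(direct$function_name[ix])])),
          collapse = ";"))
  ambiguous <- vapply(by_cluster, function(ix) {
    sets <- unique(lapply(direct$ec_numbers[ix], sort))
    length(sets) > 1L
  }, logical(1))
  direct$ambiguous_cluster <-
    unname(ambiguous[as.character(direct$cluster_id)])
  todo <- clusters[clusters$cluster_id %in% names(by_cluster) &
                   !(clusters$orf_id %in% direct$orf_id), , drop = FALSE]
  prop <- data.frame(
    orf_id = todo$orf_id,
    ec_numbers = I(unname(union_ec[as.character(todo$cluster_id)])),
    function_name = unlist(union_fn[as.character(todo$cluster_id)],
                           use.names = FALSE) %||% character(0),
    provenance = rep("paralog_propagated", nrow(todo)),
    best_hit_accession = rep(NA_character_, nrow(todo)),
    cluster_id = todo$cluster_id,
    ambiguous_cluster = unname(ambiguous[as.character(todo$cluster_id)]),
    stringsAsFactors = FALSE)
  out <- rbind(direct, prop)
  rownames(out) <- NULL
  out
}

#' End-to-end enzyme annotation of a proteome
#'
#' Runs reciprocal best hits against the enzyme database, transfers EC
#' numbers, clusters the full input proteome by single linkage, and
#' propagates direct assignments to paralogs.
#'
#' @inheritParams reciprocal_best_hits
#' @param db enzyme database from [enzyme_db()].
#' @inheritParams cluster_paralogs
#' @return list with `assignments` (see [propagate_ec()]), `clusters`,
#'   and `rbh` (the reciprocal pairs).
#' @export
annotate_enzymes <- function(proteome, db,
                             scheme = scoring_scheme("protein"),
                             evalue_max = 1e-3,
                             identity_min = 0.35, coverage_min = 0.70) {
  rbh <- reciprocal_best_hits(proteome, db$sequences, scheme, evalue_max)
  direct <- transfer_ec(rbh, db)
  clusters <- cluster_paralogs(proteome, scheme, identity_min, coverage_min)
  list(assignments = propagate_ec(clusters, direct),
       clusters = clusters, rbh = rbh)
}

#' Write EC assignments as a tab-separated table
#'
#' @param assignments data.frame from [propagate_ec()] /
#'   [annotate_enzymes()].
#' @param path output path.
#' @export
write_ec_assignments <- function(assignments, path) {
  out <- assignments
  out$ec_numbers <- vapply(assignments$ec_numbers, paste,
                           character(1), collapse = ";")
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
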