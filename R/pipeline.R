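# End-to-end orchestration: simulate -> annotate -> localize ->
# design primers -> verify (shotgun reads) -> OST end reads -> summary.
#
# Every threshold defaults to the pipeline's canonical constant
# (E-value 1e-3; clustering 35% identity / 70% coverage; k = 32;
# primary bin 50%; consolidation 85%; mapping 40 nt / 90%; verified
# > 98% coverage; 20 nt read minimum; Tm 55-65 degC); any override is
# echoed in the run log and the summary records the configuration
# fingerprint.

#' Pipeline configuration
#'
#' Stage toggles plus every module threshold, the output seed and the
#' simulation configuration. Threshold defaults are the pipeline's
#' canonical constants (see module docs).
#'
#' @param seed global seed; forwarded into [simulation_config()] unless
#'   an explicit `sim` is given.
#' @param sim a [simulation_config()] (default: one built from `seed`
#'   with generator defaults).
#' @param stages named logical vector toggling `annotate`, `localize`,
#'   `primers`, `verify`, `ost`.
#' @param evalue_max,identity_min,coverage_min EC-annotation thresholds.
#' @param k,bin_threshold,consolidation_cutoff localization parameters.
#' @param min_overlap,map_identity_min,verified_min_coverage,trim_min_len
#'   verification parameters (`verified_min_coverage` in percent,
#'   strictly exceeded).
#' @param tm_min,tm_max primer melting-temperature window (degC).
#' @param prefilter_k read-mapping k-mer prescreen (NULL disables).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, sim = NULL,
                            stages = c(annotate = TRUE, localize = TRUE,
                                       primers = TRUE, verify = TRUE,
                                       ost = TRUE),
                            evalue_max = 1e-3,
                            identity_min = 0.35, coverage_min = 0.70,
                            k = 32L, bin_threshold = 0.5,
                            consolidation_cutoff = 0.85,
                            min_overlap = 40L, map_identity_min = 0.90,
                            verified_min_coverage = 98,
                            trim_min_len = 20L,
                            tm_min = 55, tm_max = 65,
                            prefilter_k = 12L) {
  sim <- sim %||% simulation_config(seed = seed)
  defaults <- c(annotate = TRUE, localize = TRUE, primers = TRUE,
                verify = TRUE, ost = TRUE)
  defaults[names(stages)] <- stages
  structure(list(seed = seed, sim = sim, stages = defaults,
                 evalue_max = evalue_max, identity_min = identity_min,
                 coverage_min = coverage_min, k = k,
                 bin_threshold = bin_threshold,
                 consolidation_cutoff = consolidation_cutoff,
                 min_overlap = min_overlap,
                 map_identity_min = map_identity_min,
                 verified_min_coverage = verified_min_coverage,
                 trim_min_len = trim_min_len,
                 tm_min = tm_min, tm_max = tm_max,
                 prefilter_k = prefilter_k),
            class = "pipeline_config")
}

#' Load a pipeline configuration from YAML
#'
#' Top-level keys override [pipeline_config()] arguments; a `sim` block
#' overrides [simulation_config()] arguments.
#'
#' @param path YAML file.
#' @param seed optional seed overriding the file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path, seed = NULL) {
  y <- yaml::read_yaml(path) %||% list()
  if (!is.null(seed)) y$seed <- seed
  sim_args <- y$sim %||% list()
  y$sim <- NULL
  if (!is.null(y$seed) && is.null(sim_args$seed)) sim_args$seed <- y$seed
  bad <- setdiff(names(y), names(formals(pipeline_config)))
  if (length(bad)) stopf("unknown config keys: %s", paste(bad, collapse = ", "))
  bad <- setdiff(names(sim_args), names(formals(simulation_config)))
  if (length(bad)) stopf("unknown sim config keys: %s",
                         paste(bad, collapse = ", "))
  y$sim <- do.call(simulation_config, sim_args)
  do.call(pipeline_config, y)
}

config_fingerprint <- function(config) {
  flat <- unlist(list(core = config[setdiff(names(config), "sim")],
                      sim = unclass(config$sim)))
  fnv1a32(paste(names(flat), vapply(flat, format, character(1)),
                sep = "=", collapse = ";"))
}

log_line <- function(con, fmt, ...) writeLines(sprintf(fmt, ...), con)

#' Run the full pipeline into a directory
#'
#' Executes the enabled stages in dependency order against a freshly
#' simulated input set, writing per-stage tab-separated outputs, a run
#' log (tool version, configuration fingerprint, seed, per-stage
#' timings) and a `summary.json` of headline counts. Re-running with
#' the same configuration reproduces the outputs byte for byte.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created; simulated inputs go under
#'   `out_dir/inputs`).
#' @return Invisibly, the summary list.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(is(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(out_dir, f)
  log_con <- file(p("run.log"), "w")
  on.exit(close(log_con))
  log_line(log_con, "orfpipe %s", as.character(packageVersion("orfpipe")))
  log_line(log_con, "config_hash %s", config_fingerprint(config))
  log_line(log_con, "seed %d", config$seed)
  defaults <- pipeline_config(seed = config$seed, sim = config$sim)
  for (key in setdiff(names(defaults), c("seed", "sim", "stages")))
    if (!identical(defaults[[key]], config[[key]]))
      log_line(log_con, "override %s = %s (default %s)", key,
               format(config[[key]]), format(defaults[[key]]))

  summary <- list(seed = config$seed,
                  config_hash = config_fingerprint(config))

  sim <- simulate_all(config$sim, p("inputs"))
  log_line(log_con, "stage simulate: %d ORFs, %d db entries, %d reads",
           length(sim$proteome$proteome), length(sim$db$db$sequences),
           length(sim$reads$reads))
  summary$n_orfs <- length(sim$proteome$proteome)

  prot_scheme <- scoring_scheme("protein")
  nt_scheme <- scoring_scheme("nucleotide")

  if (config$stages[["annotate"]]) {
    ann <- annotate_enzymes(sim$proteome$proteome, sim$db$db,
                            prot_scheme, config$evalue_max,
                            config$identity_min, config$coverage_min)
    write_ec_assignments(ann$assignments, p("ec_assignments.tsv"))
    write.table(ann$clusters, p("clusters.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    summary$n_orfs_annotated <- nrow(ann$assignments)
    summary$n_rbh_direct <-
      sum(ann$assignments$provenance == "rbh_direct")
    summary$n_ec_distinct <-
      length(unique(unlist(ann$assignments$ec_numbers)))
    summary$n_clusters <- length(unique(ann$clusters$cluster_id))
    log_line(log_con,
             "stage annotate: %d assignments (%d direct), %d distinct ECs",
             summary$n_orfs_annotated, summary$n_rbh_direct,
             summary$n_ec_distinct)
  }

  if (config$stages[["localize"]]) {
    loc <- predict_localization(sim$compartments$queries,
                                sim$compartments$plant,
                                sim$compartments$animal,
                                k = config$k,
                                bin_threshold = config$bin_threshold,
                                consolidation_cutoff =
                                  config$consolidation_cutoff)
    write_loc_predictions(loc$plant, p("localization_plant.tsv"))
    write_loc_predictions(loc$animal, p("localization_animal.tsv"))
    write.table(loc$consolidated, p("localization_consolidated.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    cs <- compartment_summary(loc$consolidated)
    write.table(cs, p("compartment_summary.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    summary$localization_bins <- setNames(as.list(cs$n), cs$compartment)
    log_line(log_con, "stage localize: %d queries, %d assigned",
             nrow(loc$consolidated),
             sum(loc$consolidated$assignment != OTHER))
  }

  if (config$stages[["primers"]]) {
    primers <- design_primer_set(sim$cds,
                                 b1_tail = config$sim$b1_tail,
                                 b2_tail = config$sim$b2_tail,
                                 tm_min = config$tm_min,
                                 tm_max = config$tm_max)
    write.table(primers, p("primers.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    summary$n_primer_ok <- sum(primers$status == "ok")
    summary$n_primer_failed <- sum(primers$status == "failed")
    log_line(log_con, "stage primers: %d designed, %d failed",
             summary$n_primer_ok, summary$n_primer_failed)
  }

  if (config$stages[["verify"]]) {
    contaminants <- seq_set(
      c(vector = config$sim$vector_seq, b1 = config$sim$b1_tail,
        b2 = config$sim$b2_tail), "nucleotide")
    trimmed <- trim_reads(sim$reads$reads, contaminants,
                          min_len = config$trim_min_len)
    ver <- verify_references(trimmed, sim$cds, nt_scheme,
                             config$min_overlap, config$map_identity_min,
                             prefilter_k = config$prefilter_k)
    write.table(ver$report, p("verification.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(ver$histogram, p("coverage_histogram.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write_sam(ver$mappings, sim$cds, p("mappings.sam"))
    summary$n_reads_dropped <- attr(trimmed, "n_dropped")
    summary$verification_status <- as.list(table(
      factor(ver$report$status,
             levels = c("verified", "partial", "unsupported"))))
    summary$coverage_bins <-
      setNames(as.list(ver$histogram$n), ver$histogram$bin)
    log_line(log_con, "stage verify: %d/%d references verified",
             summary$verification_status$verified, length(sim$cds))
  }

  if (config$stages[["ost"]]) {
    contaminants <- seq_set(
      c(vector = config$sim$vector_seq, b1 = config$sim$b1_tail,
        b2 = config$sim$b2_tail), "nucleotide")
    fwd <- trim_reads(sim$ends$fwd, contaminants,
                      min_len = config$trim_min_len)
    rev <- trim_reads(sim$ends$rev, contaminants,
                      min_len = config$trim_min_len)
    ost <- verify_ost_set(fwd, rev, sim$cds)
    write.table(ost, p("ost.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    summary$n_ost_both_ends <- sum(ost$both_ends_ok)
    summary$n_ost_full_length <- sum(ost$full_length_contig)
    log_line(log_con, "stage ost: %d/%d clones verified at both ends",
             summary$n_ost_both_ends, nrow(ost))
  }

  jsonlite::write_json(summary, p("summary.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(summary)
}

#' Score a pipeline run against its simulated ground truth
#'
#' Reads the truth tables and per-stage outputs of a [run_pipeline()]
#' directory and computes recovery statistics: EC recovery (fraction of
#' family members carrying their family's true EC), decoy
#' false-annotation count, held-out localization accuracy, verification
#' rates, and OST end-verification agreement with the simulated clone
#' truncations.
#'
#' @param out_dir a [run_pipeline()] output directory.
#' @return list of named statistics.
#' @export
score_run <- function(out_dir) {
  p <- function(f) file.path(out_dir, f)
  inp <- function(f) file.path(out_dir, "inputs", f)
  out <- list()
  prot_truth <- read.delim(inp("truth_proteome.tsv"),
                           stringsAsFactors = FALSE)
  if (file.exists(p("ec_assignments.tsv"))) {
    asg <- read.delim(p("ec_assignments.tsv"), stringsAsFactors = FALSE)
    ecs <- strsplit(as.character(asg$ec_numbers), ";", fixed = TRUE)
    fam <- prot_truth[!is.na(prot_truth$family_id), , drop = FALSE]
    hit <- vapply(seq_len(nrow(fam)), function(i) {
      j <- match(fam$orf_id[i], asg$orf_id)
      !is.na(j) && fam$true_ec[i] %in% ecs[[j]]
    }, logical(1))
    out$ec_recovery <- mean(hit)
    decoys <- prot_truth$orf_id[is.na(prot_truth$family_id)]
    out$n_decoys_annotated <- sum(decoys %in% asg$orf_id)
  }
  if (file.exists(p("localization_consolidated.tsv"))) {
    cons <- read.delim(p("localization_consolidated.tsv"),
                       stringsAsFactors = FALSE)
    ct <- read.delim(inp("truth_compartments.tsv"),
                     stringsAsFactors = FALSE)
    m <- match(cons$orf_id, ct$orf_id)
    assigned <- cons$assignment != OTHER
    out$localization_accuracy_assigned <-
      mean(cons$assignment[assigned] == ct$compartment[m][assigned])
    out$localization_assigned_fraction <- mean(assigned)
  }
  if (file.exists(p("verification.tsv"))) {
    ver <- read.delim(p("verification.tsv"), stringsAsFactors = FALSE)
    rt <- read.delim(inp("truth_reads.tsv"), stringsAsFactors = FALSE)
    out$verified_fraction <- mean(ver$status == "verified")
    expressed <- rt$orf_id[rt$expressed]
    out$verified_fraction_expressed <-
      mean(ver$status[ver$reference_id %in% expressed] == "verified")
    unexpr <- ver$reference_id[!ver$reference_id %in% expressed]
    out$unsupported_zero_read <- all(
      ver$status[ver$reference_id %in% unexpr] == "unsupported")
  }
  if (file.exists(p("ost.tsv"))) {
    ost <- read.delim(p("ost.tsv"), stringsAsFactors = FALSE)
    et <- read.delim(inp("truth_ends.tsv"), stringsAsFactors = FALSE)
    m <- match(ost$reference_id, et$orf_id)
    full <- !et$truncated[m]
    out$ost_both_ends_rate_full_clones <- mean(ost$both_ends_ok[full])
    if (any(et$truncated_side[m] == "5"))
      out$ost_five_prime_fail_rate_truncated5 <-
        mean(!ost$five_prime_ok[et$truncated_side[m] == "5"])
  }
  out
}
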