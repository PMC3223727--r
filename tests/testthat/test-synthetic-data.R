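# The synthetic-data generator: determinism, ground-truth fidelity and
# statistical targets.

test_that("the enzyme database has distinct, well-formed EC numbers", {
  cfg <- simulation_config(seed = 5, n_families = 12L)
  db <- simulate_enzyme_db(cfg)
  expect_length(db$db$sequences, 12L)
  ecs <- unlist(db$db$annotations$ec_numbers)
  expect_length(unique(ecs), 12L)
  expect_true(all(grepl(orfpipe:::EC_PATTERN, ecs)))
  expect_identical(db$truth$ec, ecs)
})

test_that("generators are deterministic and leave the RNG untouched", {
  cfg <- simulation_config(seed = 9, n_families = 3L,
                           members_per_family = 2L, n_decoys = 2L,
                           ancestor_length = c(80L, 120L))
  set.seed(123); before <- runif(1)
  a <- simulate_proteome(simulate_enzyme_db(cfg), cfg)
  b <- simulate_proteome(simulate_enzyme_db(cfg), cfg)
  expect_identical(as.character(a$proteome), as.character(b$proteome))
  expect_identical(a$truth, b$truth)
  # with_seed restores the caller's stream
  set.seed(123); mid <- runif(1)
  expect_identical(before, mid)
  # a different seed gives different sequences
  cfg2 <- simulation_config(seed = 10, n_families = 3L,
                            members_per_family = 2L, n_decoys = 2L,
                            ancestor_length = c(80L, 120L))
  c2 <- simulate_proteome(simulate_enzyme_db(cfg2), cfg2)
  expect_false(identical(as.character(a$proteome),
                         as.character(c2$proteome)))
})

test_that("family members hit their identity target; decoys have none", {
  cfg <- simulation_config(seed = 2, n_families = 10L,
                           members_per_family = 3L, n_decoys = 5L,
                           ancestor_length = c(300L, 400L),
                           within_family_identity = 0.8)
  prot <- simulate_proteome(simulate_enzyme_db(cfg), cfg)
  fam <- prot$truth[!is.na(prot$truth$family_id), ]
  expect_true(all(abs(fam$realized_identity - 0.8) < 0.08))
  expect_lt(abs(mean(fam$realized_identity) - 0.8), 0.02)
  dec <- prot$truth[is.na(prot$truth$family_id), ]
  expect_identical(nrow(dec), 5L)
  expect_true(all(is.na(dec$true_ec)))
  # identity 1 reproduces the ancestor exactly
  cfg1 <- simulation_config(seed = 2, n_families = 2L,
                            members_per_family = 2L, n_decoys = 1L,
                            within_family_identity = 1)
  db1 <- simulate_enzyme_db(cfg1)
  p1 <- simulate_proteome(db1, cfg1)
  expect_identical(as.character(p1$proteome[["orf001_1"]]),
                   as.character(db1$db$sequences[["ENZ0001"]]))
})

test_that("reverse translation is exact, GC-targeted and invertible", {
  set.seed(77)
  prots <- seq_set(setNames(vapply(1:4, function(i)
    random_protein(sample(300:330, 1)), character(1)),
    sprintf("p%d", 1:4)), "protein")
  for (gc in c(0.45, 0.64)) {
    for (i in seq_along(prots)) {
      cds <- reverse_translate(prots[i], gc_content = gc, seed = 50 + i)
      s <- as.character(cds[[1]])
      expect_identical(substr(s, 1, 3), "ATG")
      expect_true(substr(s, nchar(s) - 2, nchar(s)) %in%
                    c("TAA", "TAG", "TGA"))
      expect_identical(nchar(s) %% 3L, 0L)
      # translation inverts it (the generator's own proteins start with M)
      expect_identical(translate_cds(cds), as.character(prots[[i]]))
      # realized GC within 3 points of target at ~900 nt
      gc_obs <- sum(strsplit(s, "")[[1]] %in% c("G", "C")) / nchar(s)
      expect_lt(abs(gc_obs - gc), 0.03)
    }
  }
  # deterministic per seed
  c1 <- reverse_translate(prots[1], 0.64, seed = 99)
  c2 <- reverse_translate(prots[1], 0.64, seed = 99)
  expect_identical(as.character(c1), as.character(c2))
})

test_that("simulated reads cover expressed ORFs and respect zero-read truth", {
  cfg <- simulation_config(seed = 13, n_families = 3L,
                           members_per_family = 2L, n_decoys = 0L,
                           ancestor_length = c(150L, 250L),
                           per_base_error = 0,
                           zero_read_fraction = 0.3, depth_mean = 8)
  prot <- simulate_proteome(simulate_enzyme_db(cfg), cfg)
  cds <- reverse_translate_set(prot$proteome, cfg)
  reads <- simulate_reads(cds, cfg)
  expect_identical(sum(reads$truth$n_reads), length(reads$reads))
  expect_true(any(!reads$truth$expressed))   # the point of the seed choice
  for (orf in reads$truth$orf_id) {
    n_from <- sum(grepl(paste0("^", orf, "_r"), names(reads$reads)))
    expect_identical(n_from,
                     reads$truth$n_reads[reads$truth$orf_id == orf])
  }
})

test_that("end reads carry vector+tail and truncate per truth", {
  cfg <- simulation_config(seed = 4, n_families = 3L,
                           members_per_family = 2L, n_decoys = 0L,
                           ancestor_length = c(200L, 300L),
                           truncated_fraction = 0.5)
  prot <- simulate_proteome(simulate_enzyme_db(cfg), cfg)
  cds <- reverse_translate_set(prot$proteome, cfg)
  ends <- simulate_end_reads(cds, cfg)
  expect_identical(names(ends$fwd), paste0(names(cds), "_5"))
  expect_identical(names(ends$rev), paste0(names(cds), "_3"))
  expect_true(all(startsWith(as.character(ends$fwd),
                             paste0(cfg$vector_seq, cfg$b1_tail))))
  # after the contaminants, an untruncated forward read is the CDS 5' end
  full <- ends$truth$orf_id[!ends$truth$truncated]
  expect_gt(length(full), 0)
  pre <- nchar(cfg$vector_seq) + nchar(cfg$b1_tail)
  for (orf in full) {
    r <- as.character(ends$fwd[[paste0(orf, "_5")]])
    ins <- substr(r, pre + 1L, nchar(r))
    expect_identical(ins, substr(as.character(cds[[orf]]), 1, nchar(ins)))
  }
  # a 5'-truncated clone is missing its first truncation_offset bases
  t5 <- ends$truth[ends$truth$truncated_side == "5", ]
  for (i in seq_len(nrow(t5))) {
    r <- as.character(ends$fwd[[paste0(t5$orf_id[i], "_5")]])
    ins <- substr(r, pre + 1L, nchar(r))
    s <- as.character(cds[[t5$orf_id[i]]])
    expect_identical(ins, substr(s, t5$truncation_offset[i] + 1L,
                                 t5$truncation_offset[i] + nchar(ins)))
  }
})

test_that("simulate_all writes a complete, reproducible file layout", {
  cfg <- simulation_config(seed = 6, n_families = 2L,
                           members_per_family = 2L, n_decoys = 1L,
                           ancestor_length = c(80L, 120L),
                           n_ref_per_compartment = 3L,
                           n_query_per_compartment = 1L,
                           depth_mean = 2)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  sim <- simulate_all(cfg, d1)
  simulate_all(cfg, d2)
  expected <- c("enzymes.faa", "enzymes.tsv", "proteome.faa",
                "refs_plant.faa", "refs_plant.tsv", "refs_animal.faa",
                "refs_animal.tsv", "queries.faa", "orfs.fna",
                "reads.fasta", "ends_5.fasta", "ends_3.fasta",
                "truth_proteome.tsv", "truth_compartments.tsv",
                "truth_reads.tsv", "truth_ends.tsv", "manifest.json")
  expect_true(all(expected %in% list.files(d1)))
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), info = f)
  }
  # files round-trip through the package's own readers
  prot <- read_fasta(file.path(d1, "proteome.faa"), "protein")
  expect_identical(as.character(prot), as.character(sim$proteome$proteome))
  orfs <- read_fasta(file.path(d1, "orfs.fna"), "nucleotide")
  expect_identical(names(orfs), names(prot))
  # the manifest checksums match the files on disk
  man <- jsonlite::read_json(file.path(d1, "manifest.json"))
  for (f in setdiff(names(man$files), "manifest.json")) {
    fp <- file.path(d1, f)
    expect_identical(
      orfpipe:::fnv1a32(readChar(fp, file.info(fp)$size, useBytes = TRUE)),
      man$files[[f]], info = f)
  }
})
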