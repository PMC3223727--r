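# Read trimming, mapping, per-base coverage and verification calculus.

test_that("adapter tails are clipped exactly and short reads dropped", {
  set.seed(21)
  insert <- rand_dna(180)
  contaminants <- seq_set(c(vector = orfpipe:::SYNTHETIC_VECTOR,
                            b1 = GATEWAY_B1_1, b2 = GATEWAY_B2_1),
                          "nucleotide")
  reads <- seq_set(c(
    tailed = paste0(GATEWAY_B1_1, insert),
    both = paste0(orfpipe:::SYNTHETIC_VECTOR, GATEWAY_B1_1, insert),
    clean = insert,
    short_after = paste0(GATEWAY_B2_1, rand_dna(10)),
    rc_tail = paste0(insert, as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(GATEWAY_B2_1))))), "nucleotide")
  out <- trim_reads(reads, contaminants)
  expect_identical(as.character(out[["tailed"]]), insert)
  expect_identical(as.character(out[["both"]]), insert)
  expect_identical(as.character(out[["clean"]]), insert)
  expect_identical(as.character(out[["rc_tail"]]), insert)
  expect_false("short_after" %in% names(out))
  expect_identical(attr(out, "n_dropped"), 1L)
})

test_that("a 19 nt survivor is dropped, a 20 nt survivor kept", {
  contaminants <- seq_set(c(b1 = GATEWAY_B1_1), "nucleotide")
  set.seed(3)
  keep20 <- rand_dna(20); drop19 <- rand_dna(19)
  reads <- seq_set(c(keep = paste0(GATEWAY_B1_1, keep20),
                     drop = paste0(GATEWAY_B1_1, drop19)), "nucleotide")
  out <- trim_reads(reads, contaminants, min_len = 20L)
  expect_identical(names(out), "keep")
  expect_identical(as.character(out[["keep"]]), keep20)
  expect_identical(attr(out, "n_dropped"), 1L)
})

test_that("mapping honors the 40 nt overlap and 90% identity floors", {
  set.seed(33)
  ref <- seq_set(c(cds1 = rand_dna(500)), "nucleotide")
  s <- as.character(ref[[1]])
  sub_at <- function(a, len) substr(s, a, a + len - 1L)
  reads <- seq_set(c(r100 = sub_at(101, 100),
                     r41 = sub_at(301, 41),
                     r39 = sub_at(201, 39)), "nucleotide")
  m <- map_reads(reads, ref, min_overlap = 40L)
  expect_setequal(m$read_id, c("r100", "r41"))
  r <- m[m$read_id == "r100", ]
  expect_identical(c(r$ref_start, r$ref_end), c(100L, 200L))
  expect_equal(r$identity, 1)
  # identity floor: ~13% mismatches disqualify a 100-mer
  noisy <- orfpipe:::apply_substitutions(sub_at(101, 100), 0)  # start exact
  b <- strsplit(noisy, "")[[1]]
  for (i in seq(4, 100, by = 8)) b[i] <- setdiff(c("A","C","G","T"), b[i])[1]
  reads2 <- seq_set(c(noisy = paste(b, collapse = "")), "nucleotide")
  expect_identical(nrow(map_reads(reads2, ref, min_identity = 0.90)), 0L)
  # reverse-strand reads map with strand "-"
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(sub_at(51, 80))))
  m3 <- map_reads(seq_set(c(rcread = rc), "nucleotide"), ref)
  expect_identical(m3$strand, "-")
  expect_identical(c(m3$ref_start, m3$ref_end), c(50L, 130L))
  expect_error(map_reads(reads, ref[0]), "empty reference")
})

test_that("the k-mer prescreen does not change mapping results", {
  set.seed(44)
  refs <- seq_set(setNames(vapply(1:4, function(i) rand_dna(400),
                                  character(1)),
                           sprintf("c%d", 1:4)), "nucleotide")
  reads <- seq_set(setNames(c(
    vapply(1:6, function(i) {
      src <- sample(4, 1)
      a <- sample(300, 1)
      substr(as.character(refs[[src]]), a, a + 99)
    }, character(1)),
    rand_dna(100)), sprintf("r%d", 1:7)), "nucleotide")
  with_pf <- map_reads(reads, refs, prefilter_k = 12L)
  without <- map_reads(reads, refs, prefilter_k = NULL)
  expect_identical(with_pf, without)
})

test_that("coverage arithmetic follows directly from the spans", {
  ref <- seq_set(c(cds = paste(rep("ACGT", 50), collapse = "")),
                 "nucleotide")   # 200 nt
  maps <- data.frame(read_id = c("a", "b"), reference_id = "cds",
                     ref_start = c(0L, 90L), ref_end = c(100L, 200L),
                     read_start = 0L, read_end = 100L,
                     identity = 1, score = 100, strand = "+")
  prof <- coverage_profile(maps, ref)
  expect_equal(prof$percent_covered, 100)
  expect_identical(prof$depth[95], 2L)   # the overlap is double-covered
  expect_identical(prof$depth[50], 1L)
  half <- coverage_profile(maps[1, ], ref)
  expect_equal(half$percent_covered, 50)
  none <- coverage_profile(maps[0, ], ref)
  expect_equal(none$percent_covered, 0)
  expect_identical(sum(none$depth), 0L)
})

test_that("adding mappings never decreases coverage", {
  set.seed(87)
  ref <- seq_set(c(cds = rand_dna(300)), "nucleotide")
  for (rep in 1:20) {
    n <- sample(1:8, 1)
    a <- sample(0:250, n, TRUE)
    maps <- data.frame(read_id = sprintf("r%d", seq_len(n)),
                       reference_id = "cds",
                       ref_start = a, ref_end = pmin(a + sample(20:120, n, TRUE), 300L),
                       read_start = 0L, read_end = 50L,
                       identity = 1, score = 50, strand = "+")
    cum <- vapply(seq_len(n), function(k)
      coverage_profile(maps[seq_len(k), ], ref)$percent_covered, numeric(1))
    expect_true(all(diff(cum) >= -1e-12))
    # permutation invariance
    perm <- coverage_profile(maps[sample(n), ], ref)
    expect_equal(perm$percent_covered, cum[n])
  }
})

test_that("verification thresholds are strict at their boundaries", {
  mk <- function(pct) structure(list(reference_id = "x",
                                     depth = integer(0),
                                     percent_covered = pct),
                                class = "coverage_profile")
  expect_identical(classify_verification(mk(98.5))$status, "verified")
  expect_identical(classify_verification(mk(98))$status, "partial")
  expect_identical(classify_verification(mk(100))$status, "verified")
  expect_identical(classify_verification(mk(20))$status, "partial")
  expect_identical(classify_verification(mk(19.9))$status, "unsupported")
  expect_identical(classify_verification(mk(0))$status, "unsupported")
  # bin edges: [95,100], [50,95), [20,50), [0,20)
  expect_identical(classify_verification(mk(95))$coverage_bin, "95-100")
  expect_identical(classify_verification(mk(94.99))$coverage_bin, "50-95")
  expect_identical(classify_verification(mk(50))$coverage_bin, "50-95")
  expect_identical(classify_verification(mk(49.9))$coverage_bin, "20-50")
  expect_identical(classify_verification(mk(20))$coverage_bin, "20-50")
  expect_identical(classify_verification(mk(19.9))$coverage_bin, "<20")
})

test_that("tiled reads verify a reference; a withheld window blocks it", {
  set.seed(99)
  refs <- seq_set(c(covered = rand_dna(600), gapped = rand_dna(600)),
                  "nucleotide")
  full <- make_reads_tiling(refs["covered"])
  gappy <- make_reads_tiling(refs["gapped"])
  # withhold every read overlapping a central window of the second ref
  win <- c(280L, 320L)
  keep <- vapply(seq_along(gappy), function(i) {
    m <- map_reads(gappy[i], refs["gapped"])
    nrow(m) == 1L && (m$ref_end <= win[1] || m$ref_start >= win[2])
  }, logical(1))
  reads <- c(full, gappy[keep])
  res <- verify_references(reads, refs)
  rep_tab <- res$report
  expect_identical(rep_tab$status[rep_tab$reference_id == "covered"],
                   "verified")
  expect_identical(rep_tab$status[rep_tab$reference_id == "gapped"],
                   "partial")
  expect_equal(sum(res$histogram$n), 2L)
  expect_identical(res$histogram$bin, c("95-100", "50-95", "20-50", "<20"))
  # SAM export: one header line per reference plus one row per mapping
  sam <- withr::local_tempfile(fileext = ".sam")
  write_sam(res$mappings, refs, sam)
  lines <- readLines(sam)
  expect_identical(sum(grepl("^@SQ", lines)), 2L)
  expect_identical(sum(!grepl("^@", lines)), nrow(res$mappings))
  body <- strsplit(lines[!grepl("^@", lines)][1], "\t")[[1]]
  expect_length(body, 11L)
})
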