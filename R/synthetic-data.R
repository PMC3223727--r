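# Ground-truthed synthetic inputs for every pipeline stage.
#
# The generator emulates the statistical structure the pipeline
# assumes: a proteome organized into paralog families that share EC
# numbers; compartment-dependent amino-acid composition biases (two
# independently perturbed lineages); high-GC coding sequences (default
# 64% G+C, the regime of the green-algal transcriptome that motivates
# GC-aware reverse translation); error-bearing shotgun-style reads of
# variable depth with a low-expression tail; and vector/tail
# contaminated paired end reads with a configurable fraction of
# truncated clones. One global seed expands into fixed per-stage child
# seeds, so any stage regenerates identically on its own.

SEED_OFFSETS <- c(db = 1L, proteome = 2L, compartments = 3L,
                  cds = 4L, reads = 5L, ends = 6L)

stage_seed <- function(cfg, stage) cfg$seed + SEED_OFFSETS[[stage]]

# A synthetic cloning-vector flank used to contaminate raw end reads.
SYNTHETIC_VECTOR <- "TCGCGCGTTTCGGTGATGACGGTGAAAACCTCTGACACAT"

#' Simulation configuration
#'
#' All knobs of the synthetic-data generator, with defaults chosen to
#' exercise every stage under realistic conditions: 20 paralog families
#' of 5 members mutated to 80% target identity plus 20 random decoys;
#' ten compartments with Dirichlet-skewed compositions; 64% GC coding
#' sequences; shotgun reads of mean length 250 nt at 1% per-base error
#' with a low-expression depth tail and a 2% zero-read fraction; 600 nt
#' error-free Sanger-style end reads with 5% truncated clones.
#'
#' @param seed global integer seed; identical config + seed gives
#'   byte-identical outputs.
#' @param n_families,members_per_family,within_family_identity,n_decoys
#'   paralog-family structure of the proteome.
#' @param ancestor_length length range (aa) of family ancestors and
#'   decoys.
#' @param n_ref_per_compartment,n_query_per_compartment,dirichlet_alpha,composition_bias,lineage_perturbation,compartment_length
#'   localization reference/query generator: per-compartment Dirichlet
#'   concentration, bias strength in \[0,1\] (0 = uniform composition,
#'   compartments indistinguishable), and the lineage mixing rate.
#' @param gc_content target G+C fraction of reverse-translated CDSs.
#' @param read_length_mean,read_length_sd,fragment_length_mean,depth_mean,low_depth_fraction,zero_read_fraction,per_base_error
#'   shotgun read generator: reads are taken from random fragmentations
#'   of the tailed amplicon, `depth_mean` fragmentation rounds per ORF
#'   on average, with a low-expression tail (`low_depth_fraction` of
#'   ORFs get a single round, `zero_read_fraction` none).
#' @param end_read_length,end_read_error,truncated_fraction,truncation_range
#'   paired end-read generator; truncated clones lose 20-100 nt from
#'   one end.
#' @param vector_seq,b1_tail,b2_tail contaminating vector flank and
#'   Gateway adapter sequences.
#' @return list of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L,
                              n_families = 20L, members_per_family = 5L,
                              within_family_identity = 0.80,
                              n_decoys = 20L,
                              ancestor_length = c(150L, 600L),
                              n_ref_per_compartment = 50L,
                              n_query_per_compartment = 10L,
                              dirichlet_alpha = 0.5,
                              composition_bias = 1.0,
                              lineage_perturbation = 0.1,
                              compartment_length = c(100L, 400L),
                              gc_content = 0.64,
                              read_length_mean = 250, read_length_sd = 40,
                              fragment_length_mean = 350,
                              depth_mean = 6, low_depth_fraction = 0.05,
                              zero_read_fraction = 0.02,
                              per_base_error = 0.01,
                              end_read_length = 600L, end_read_error = 0,
                              truncated_fraction = 0.05,
                              truncation_range = c(20L, 100L),
                              vector_seq = SYNTHETIC_VECTOR,
                              b1_tail = GATEWAY_B1_1,
                              b2_tail = GATEWAY_B2_1) {
  cfg <- as.list(environment())
  probs <- c(within_family_identity, composition_bias,
             lineage_perturbation, gc_content, low_depth_fraction,
             zero_read_fraction, per_base_error, truncated_fraction)
  if (any(probs < 0 | probs > 1)) stopf("probabilities must lie in [0, 1]")
  if (within_family_identity <= 0) stopf("within_family_identity must be > 0")
  counts <- c(n_families, members_per_family, n_decoys + 1L,
              n_ref_per_compartment, n_query_per_compartment,
              end_read_length, depth_mean)
  if (any(counts <= 0)) stopf("counts and sizes must be positive")
  structure(cfg, class = "simulation_config")
}

#' Random protein sequence
#'
#' Residues drawn i.i.d. from `probs` over the 20 standard amino acids;
#' with `start_met` the first residue is forced to methionine. Uses the
#' current RNG state.
#'
#' @param len sequence length.
#' @param start_met force a leading M.
#' @param probs per-residue sampling weights (order of
#'   `PROTEIN_LETTERS`: alphabetical one-letter codes).
#' @return character scalar.
#' @export
random_protein <- function(len, start_met = TRUE,
                           probs = rep(1 / 20, 20)) {
  r <- sample(PROTEIN_LETTERS, len, replace = TRUE, prob = probs)
  if (start_met) r[1] <- "M"
  paste(r, collapse = "")
}

#' Point-mutate a protein towards a target identity
#'
#' Each site independently substitutes (to a different residue) with
#' probability `1 - identity`; no indels, so the realized identity is
#' the fraction of unmutated sites and concentrates on the target for
#' long sequences. Uses the current RNG state.
#'
#' @param seq character protein sequence.
#' @param identity target fractional identity in (0, 1].
#' @return character scalar.
#' @export
mutate_protein <- function(seq, identity) {
  b <- strsplit(seq, "")[[1]]
  hit <- which(runif(length(b)) < (1 - identity))
  for (i in hit) b[i] <- sample(setdiff(PROTEIN_LETTERS, b[i]), 1L)
  paste(b, collapse = "")
}

#' Simulate an EC-labelled enzyme database
#'
#' Random ancestor proteins (one per family) with distinct synthetic EC
#' numbers, mimicking a curated enzyme reference database.
#'
#' @param cfg a [simulation_config()].
#' @return list with `db` (see [enzyme_db()]) and `truth` (data.frame:
#'   accession, family_id, ec).
#' @export
simulate_enzyme_db <- function(cfg) {
  with_seed(stage_seed(cfg, "db"), {
    n <- cfg$n_families
    lens <- sample(cfg$ancestor_length[1]:cfg$ancestor_length[2], n,
                   replace = TRUE)
    seqs <- vapply(lens, random_protein, character(1))
    acc <- sprintf("ENZ%04d", seq_len(n))
    ecs <- sprintf("%d.%d.%d.%d",
                   1L + (seq_len(n) - 1L) %% 6L,
                   1L + (seq_len(n) - 1L) %% 9L,
                   1L + (seq_len(n) - 1L) %% 4L,
                   seq_len(n))
    src <- rep(c("uniprot_like", "aracyc_like"), length.out = n)
    db <- enzyme_db(seq_set(setNames(seqs, acc), "protein"),
                    accession = acc, ec_numbers = as.list(ecs),
                    function_name = sprintf("synthetic enzyme %d", seq_len(n)),
                    source = src)
    list(db = db,
         truth = data.frame(accession = acc, family_id = seq_len(n),
                            ec = ecs, stringsAsFactors = FALSE))
  })
}

#' Simulate a paralog-structured proteome
#'
#' Each family member is the family ancestor point-mutated to the
#' target within-family identity; decoys are i.i.d. random proteins
#' belonging to no family.
#'
#' @param db result of [simulate_enzyme_db()].
#' @param cfg a [simulation_config()].
#' @return list with `proteome` (`AAStringSet`) and `truth`
#'   (data.frame: orf_id, family_id (NA for decoys), true_ec,
#'   ancestor_accession, realized_identity).
#' @export
simulate_proteome <- function(db, cfg) {
  with_seed(stage_seed(cfg, "proteome"), {
    anc <- as.character(db$db$sequences)
    rows <- list(); seqs <- character(0)
    for (f in seq_len(cfg$n_families)) {
      for (m in seq_len(cfg$members_per_family)) {
        id <- sprintf("orf%03d_%d", f, m)
        s <- mutate_protein(anc[[f]], cfg$within_family_identity)
        seqs[[id]] <- s
        a <- strsplit(anc[[f]], "")[[1]]; b <- strsplit(s, "")[[1]]
        rows[[id]] <- data.frame(
          orf_id = id, family_id = f, true_ec = db$truth$ec[f],
          ancestor_accession = db$truth$accession[f],
          realized_identity = mean(a == b), stringsAsFactors = FALSE)
      }
    }
    for (d in seq_len(cfg$n_decoys)) {
      id <- sprintf("decoy%03d", d)
      len <- sample(cfg$ancestor_length[1]:cfg$ancestor_length[2], 1L)
      seqs[[id]] <- random_protein(len)
      rows[[id]] <- data.frame(orf_id = id, family_id = NA_integer_,
                               true_ec = NA_character_,
                               ancestor_accession = NA_character_,
                               realized_identity = NA_real_,
                               stringsAsFactors = FALSE)
    }
    list(proteome = seq_set(seqs, "protein"),
         truth = do.call(rbind, c(rows, list(make.row.names = FALSE))))
  })
}

rdirichlet1 <- function(alpha) {
  g <- rgamma(length(alpha), shape = alpha, rate = 1)
  g / sum(g)
}

#' Simulate labelled compartment reference and query sets
#'
#' Each compartment gets a Dirichlet-sampled amino-acid composition,
#' blended towards uniform by `1 - composition_bias`; the plant and
#' animal lineages each mix in an independent perturbation. Reference
#' proteins are drawn residue-wise from the lineage compositions;
#' held-out query proteins from the unperturbed compartment
#' compositions.
#'
#' @param cfg a [simulation_config()].
#' @return list: `plant` and `animal` ([loc_reference()] objects),
#'   `queries` (`AAStringSet`), `query_truth` (data.frame: orf_id,
#'   compartment), and `compositions` (20 x n matrix of base
#'   compartment compositions).
#' @export
simulate_compartment_refs <- function(cfg) {
  with_seed(stage_seed(cfg, "compartments"), {
    ncomp <- length(COMPARTMENTS)
    unif <- rep(1 / 20, 20)
    base <- vapply(seq_len(ncomp), function(i)
      cfg$composition_bias * rdirichlet1(rep(cfg$dirichlet_alpha, 20)) +
        (1 - cfg$composition_bias) * unif, numeric(20))
    rownames(base) <- PROTEIN_LETTERS
    colnames(base) <- COMPARTMENTS
    lineage_comp <- function() {
      pert <- vapply(seq_len(ncomp), function(i)
        rdirichlet1(rep(cfg$dirichlet_alpha, 20)), numeric(20))
      (1 - cfg$lineage_perturbation) * base +
        cfg$lineage_perturbation * pert
    }
    draw_set <- function(comp, n_per, prefix) {
      seqs <- character(0); labels <- character(0)
      for (ci in seq_len(ncomp)) {
        for (j in seq_len(n_per)) {
          id <- sprintf("%s_%s_%03d", prefix, COMPARTMENTS[ci], j)
          len <- sample(cfg$compartment_length[1]:cfg$compartment_length[2], 1L)
          seqs[[id]] <- random_protein(len, start_met = FALSE,
                                       probs = comp[, ci])
          labels[[id]] <- COMPARTMENTS[ci]
        }
      }
      list(seqs = seq_set(seqs, "protein"), labels = unname(labels))
    }
    plant <- draw_set(lineage_comp(), cfg$n_ref_per_compartment, "pref")
    animal <- draw_set(lineage_comp(), cfg$n_ref_per_compartment, "aref")
    qry <- draw_set(base, cfg$n_query_per_compartment, "query")
    list(plant = loc_reference(plant$seqs, plant$labels, "plant"),
         animal = loc_reference(animal$seqs, animal$labels, "animal"),
         queries = qry$seqs,
         query_truth = data.frame(orf_id = names(qry$seqs),
                                  compartment = qry$labels,
                                  stringsAsFactors = FALSE),
         compositions = base)
  })
}

# aa -> codon lookup from the standard genetic code, plus per-codon GC
# counts, cached at first use.
codon_table_cache <- new.env(parent = emptyenv())

codon_table <- function() {
  if (is.null(codon_table_cache$tab)) {
    gc <- Biostrings::GENETIC_CODE
    codons <- names(gc)
    tab <- split(codons, gc)
    codon_table_cache$tab <- tab
    codon_table_cache$gc_count <- vapply(
      codons, function(c) sum(strsplit(c, "")[[1]] %in% c("G", "C")),
      integer(1))
  }
  list(tab = codon_table_cache$tab, gc_count = codon_table_cache$gc_count)
}

#' Reverse-translate a protein with a target GC content
#'
#' Codons are sampled with weights exp(theta * gc(codon)) among each
#' residue's synonymous codons, with theta calibrated per protein so
#' the expected G+C fraction of the CDS equals `gc_content` (clamped to
#' the achievable range of the genetic code for that residue
#' composition). An ATG is the first codon (prepended when the protein
#' does not start with M) and a stop codon is appended.
#'
#' @param protein length-1 protein collection (no X residues).
#' @param gc_content target G+C fraction.
#' @param seed integer seed (deterministic output).
#' @return length-1 `DNAStringSet` with the same id.
#' @export
reverse_translate <- function(protein, gc_content = 0.64, seed = 1L) {
  stopifnot(length(protein) == 1L)
  s <- as.character(protein[[1]])
  if (grepl("X", s)) stopf("cannot reverse-translate X residues")
  ct <- codon_table()
  aa <- strsplit(s, "")[[1]]
  if (aa[1] == "M") aa <- aa[-1]          # first codon is ATG either way
  groups <- c(ct$tab[aa], list(c("TAA", "TAG", "TGA")))
  exp_gc <- function(theta) {
    e <- vapply(groups, function(cs) {
      g <- ct$gc_count[cs]
      w <- exp(theta * g)
      sum(g * w) / sum(w)
    }, numeric(1))
    (1 + sum(e)) / (3 * (length(groups) + 1))   # +1 GC and +1 codon: ATG
  }
  lo <- exp_gc(-30); hi <- exp_gc(30)
  theta <- if (gc_content <= lo) -30
           else if (gc_content >= hi) 30
           else uniroot(function(t) exp_gc(t) - gc_content,
                        c(-30, 30), tol = 1e-7)$root
  with_seed(seed, {
    codons <- vapply(groups, function(cs) {
      w <- exp(theta * ct$gc_count[cs])
      sample(cs, 1L, prob = w / sum(w))
    }, character(1))
    cds <- paste0("ATG", paste(codons, collapse = ""))
    seq_set(setNames(cds, names(protein)), "nucleotide")
  })
}

#' Translate a CDS back to its protein
#'
#' Inverse of [reverse_translate()] (modulo the initiator methionine):
#' standard-code translation with the trailing stop removed.
#'
#' @param cds length-1 nucleotide collection.
#' @return character protein sequence.
#' @export
translate_cds <- function(cds) {
  p <- as.character(Biostrings::translate(
    Biostrings::DNAString(as.character(cds[[1]]))))
  sub("\\*$", "", p)
}

#' Reverse-translate a whole proteome
#'
#' @param proteome protein collection.
#' @param cfg a [simulation_config()] (uses `gc_content` and the CDS
#'   child seed; per-record seeds are offsets of it).
#' @return `DNAStringSet` of CDSs, ids preserved.
#' @export
reverse_translate_set <- function(proteome, cfg) {
  base <- stage_seed(cfg, "cds")
  out <- lapply(seq_along(proteome), function(i)
    as.character(reverse_translate(proteome[i], cfg$gc_content,
                                   base + i)[[1]]))
  seq_set(setNames(unlist(out), names(proteome)), "nucleotide")
}

apply_substitutions <- function(seq, rate) {
  if (rate <= 0) return(seq)
  b <- strsplit(seq, "")[[1]]
  hit <- which(runif(length(b)) < rate)
  for (i in hit) b[i] <- sample(setdiff(c("A", "C", "G", "T"), b[i]), 1L)
  paste(b, collapse = "")
}

#' Simulate shotgun-style amplicon reads
#'
#' Each CDS becomes a Gateway-tailed amplicon (b1 tail + CDS + reverse
#' complement of the b2 tail). Sequencing is emulated as repeated
#' random fragmentation rounds of the amplicon (mean fragment
#' `fragment_length_mean` nt); each fragment yields one read of up to
#' `read_length_mean` +/- `read_length_sd` nt from a random end/strand,
#' with substitution errors at `per_base_error`. Depth has a
#' low-expression tail and a configurable zero-read fraction.
#'
#' @param cds_set nucleotide collection of CDSs.
#' @param cfg a [simulation_config()].
#' @return list with `reads` (`DNAStringSet`) and `truth` (data.frame:
#'   orf_id, n_rounds, n_reads, expressed).
#' @export
simulate_reads <- function(cds_set, cfg) {
  with_seed(stage_seed(cfg, "reads"), {
    reads <- character(0)
    truth <- vector("list", length(cds_set))
    counter <- 0L
    for (i in seq_along(cds_set)) {
      orf <- names(cds_set)[i]
      amp <- paste0(cfg$b1_tail, as.character(cds_set[[i]]),
                    as.character(Biostrings::reverseComplement(
                      Biostrings::DNAString(cfg$b2_tail))))
      u <- runif(1)
      rounds <- if (u < cfg$zero_read_fraction) 0L
                else if (u < cfg$zero_read_fraction + cfg$low_depth_fraction) 1L
                else 1L + rpois(1, max(cfg$depth_mean - 1, 0))
      n_reads_orf <- 0L
      L <- nchar(amp)
      for (r in seq_len(rounds)) {
        cuts <- which(runif(L - 1L) < 1 / cfg$fragment_length_mean)
        bounds <- c(0L, cuts, L)
        for (f in seq_len(length(bounds) - 1L)) {
          a <- bounds[f] + 1L; b <- bounds[f + 1L]
          frag <- substr(amp, a, b)
          fl <- nchar(frag)
          rl <- min(fl, max(30L, round(rnorm(1, cfg$read_length_mean,
                                             cfg$read_length_sd))))
          rs <- if (runif(1) < 0.5) substr(frag, 1L, rl)
                else as.character(Biostrings::reverseComplement(
                  Biostrings::DNAString(substr(frag, fl - rl + 1L, fl))))
          rs <- apply_substitutions(rs, cfg$per_base_error)
          counter <- counter + 1L
          n_reads_orf <- n_reads_orf + 1L
          reads[[sprintf("%s_r%05d", orf, counter)]] <- rs
        }
      }
      truth[[i]] <- data.frame(orf_id = orf, n_rounds = rounds,
                               n_reads = n_reads_orf,
                               expressed = rounds > 0L,
                               stringsAsFactors = FALSE)
    }
    list(reads = seq_set(reads, "nucleotide"),
         truth = do.call(rbind, truth))
  })
}

#' Simulate paired, contaminated end reads of cloned ORFs
#'
#' The forward read starts at the CDS 5' end behind a synthetic vector
#' flank and the B1 tail; the reverse read reads the 3' end on the
#' opposite strand behind vector + B2 tail. A configurable fraction of
#' clones is truncated at one end (missing `truncation_range` nt),
#' which makes the corresponding end unverifiable downstream.
#'
#' @param cds_set nucleotide collection of CDSs.
#' @param cfg a [simulation_config()].
#' @return list with `fwd`, `rev` (`DNAStringSet`, ids `<orf>_5` /
#'   `<orf>_3`) and `truth` (data.frame: orf_id, truncated,
#'   truncated_side, truncation_offset, clone_full_length).
#' @export
simulate_end_reads <- function(cds_set, cfg) {
  with_seed(stage_seed(cfg, "ends"), {
    fwd <- character(0); rev <- character(0)
    truth <- vector("list", length(cds_set))
    for (i in seq_along(cds_set)) {
      orf <- names(cds_set)[i]
      s <- as.character(cds_set[[i]])
      L <- nchar(s)
      truncated <- runif(1) < cfg$truncated_fraction
      side <- if (truncated) sample(c("5", "3"), 1L) else "none"
      off <- if (truncated)
        sample(cfg$truncation_range[1]:cfg$truncation_range[2], 1L) else 0L
      ins5 <- if (side == "5") substr(s, off + 1L, L) else s
      ins3 <- if (side == "3") substr(s, 1L, L - off) else s
      fraw <- paste0(cfg$vector_seq, cfg$b1_tail, ins5)
      rraw <- paste0(cfg$vector_seq, cfg$b2_tail,
                     as.character(Biostrings::reverseComplement(
                       Biostrings::DNAString(ins3))))
      fwd[[paste0(orf, "_5")]] <- apply_substitutions(
        substr(fraw, 1L, cfg$end_read_length), cfg$end_read_error)
      rev[[paste0(orf, "_3")]] <- apply_substitutions(
        substr(rraw, 1L, cfg$end_read_length), cfg$end_read_error)
      truth[[i]] <- data.frame(orf_id = orf, truncated = truncated,
                               truncated_side = side,
                               truncation_offset = off,
                               clone_full_length = !truncated,
                               stringsAsFactors = FALSE)
    }
    list(fwd = seq_set(fwd, "nucleotide"),
         rev = seq_set(rev, "nucleotide"),
         truth = do.call(rbind, truth))
  })
}

#' Generate the complete synthetic input set on disk
#'
#' Runs every generator and writes the full file layout: proteome.faa,
#' enzymes.faa + enzymes.tsv, refs_plant/animal.faa + .tsv,
#' queries.faa, orfs.fna, reads.fasta, ends_5/3.fasta, truth tables,
#' and a manifest JSON recording the configuration and a checksum per
#' file. Identical config + seed reproduces the file set byte for
#' byte.
#'
#' @param cfg a [simulation_config()].
#' @param dir output directory (created if needed).
#' @return Invisibly, a list with all in-memory objects and `paths`.
#' @export
simulate_all <- function(cfg, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  db <- simulate_enzyme_db(cfg)
  prot <- simulate_proteome(db, cfg)
  comp <- simulate_compartment_refs(cfg)
  cds <- reverse_translate_set(prot$proteome, cfg)
  reads <- simulate_reads(cds, cfg)
  ends <- simulate_end_reads(cds, cfg)

  write_fasta(db$db$sequences, p("enzymes.faa"))
  ann <- db$db$annotations
  ann$ec_numbers <- vapply(ann$ec_numbers, paste, character(1),
                           collapse = ";")
  write.table(ann, p("enzymes.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write_fasta(prot$proteome, p("proteome.faa"))
  for (lin in c("plant", "animal")) {
    ref <- comp[[lin]]
    write_fasta(ref$sequences, p(sprintf("refs_%s.faa", lin)))
    write.table(data.frame(id = ref$ids, compartment = ref$compartments,
                           lineage = lin),
                p(sprintf("refs_%s.tsv", lin)), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  write_fasta(comp$queries, p("queries.faa"))
  write.table(comp$query_truth, p("truth_compartments.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write_fasta(cds, p("orfs.fna"))
  write_fasta(reads$reads, p("reads.fasta"))
  write_fasta(ends$fwd, p("ends_5.fasta"))
  write_fasta(ends$rev, p("ends_3.fasta"))
  write.table(prot$truth, p("truth_proteome.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(reads$truth, p("truth_reads.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(ends$truth, p("truth_ends.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  files <- list.files(dir, full.names = FALSE)
  checksums <- vapply(files, function(f)
    fnv1a32(readChar(p(f), file.info(p(f))$size, useBytes = TRUE)),
    character(1))
  manifest <- list(config = unclass(cfg),
                   files = as.list(checksums))
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(list(db = db, proteome = prot, compartments = comp,
                 cds = cds, reads = reads, ends = ends,
                 dir = dir, paths = setNames(file.path(dir, files), files)))
}
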