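# Gateway-tailed ORF-specific primer design.
#
# The forward primer's gene-specific part starts exactly at the A of
# the ATG start codon and carries the Gateway B1.1 adapter at its 5'
# end; the reverse primer starts from the codon immediately before the
# termination codon (i.e. it is the reverse complement of a CDS suffix
# that excludes the stop codon) and carries the B2.1 adapter. The
# gene-specific part is grown from the minimum length until its
# melting temperature falls inside the 55-65 degC window.

# Standard attB1.1 / attB2.1 adapter sequences, supplied as defaults
# only -- override via the b1_tail / b2_tail arguments (or the pipeline
# config) to match the clone collection actually in use.
GATEWAY_B1_1 <- "GGGGACAACTTTGTACAAAAAAGTTGGC"
GATEWAY_B2_1 <- "GGGGACAACTTTGTACAAGAAAGTTGG"

# Unified nearest-neighbor parameters (Allawi & SantaLucia 1997 /
# SantaLucia 1998): dH kcal/mol, dS cal/(mol K), per 5'->3' dinucleotide.
NN_DH <- c(AA = -7.9, TT = -7.9, AT = -7.2, TA = -7.2,
           CA = -8.5, TG = -8.5, GT = -8.4, AC = -8.4,
           CT = -7.8, AG = -7.8, GA = -8.2, TC = -8.2,
           CG = -10.6, GC = -9.8, GG = -8.0, CC = -8.0)
NN_DS <- c(AA = -22.2, TT = -22.2, AT = -20.4, TA = -21.3,
           CA = -22.7, TG = -22.7, GT = -22.4, AC = -22.4,
           CT = -21.0, AG = -21.0, GA = -22.2, TC = -22.2,
           CG = -27.2, GC = -24.4, GG = -19.9, CC = -19.9)

#' Primer melting temperature
#'
#' `method = "nn"` (default) uses the unified nearest-neighbor
#' thermodynamic model: Tm = 1000 dH / (dS + R ln CT) - 273.15 with
#' R = 1.987 cal/(mol K), duplex initiation terms per terminal base,
#' total strand concentration `conc` (mol/L, default 500 nM primer in
#' excess over template) and the entropy salt correction
#' 0.368 (N - 1) ln\[Na+\] at `na` mol/L (default 50 mM).
#' `method = "wallace"` is the 2(A+T) + 4(G+C) rule.
#'
#' @param seq primer sequence, 5' to 3' (character, ACGT only).
#' @param method `"nn"` or `"wallace"`.
#' @param conc total single-strand concentration, mol/L.
#' @param na monovalent cation concentration, mol/L.
#' @return Tm in degrees Celsius.
#' @export
primer_tm <- function(seq, method = c("nn", "wallace"),
                      conc = 500e-9, na = 0.05) {
  method <- match.arg(method)
  seq <- toupper(seq)
  if (grepl("[^ACGT]", seq)) stopf("primer contains non-ACGT characters")
  b <- strsplit(seq, "")[[1]]
  n <- length(b)
  if (n < 2L) stopf("primer too short for a Tm")
  if (method == "wallace")
    return(2 * sum(b %in% c("A", "T")) + 4 * sum(b %in% c("G", "C")))
  steps <- paste0(b[-n], b[-1L])
  dh <- sum(NN_DH[steps])
  ds <- sum(NN_DS[steps])
  for (terminal in b[c(1L, n)]) {
    if (terminal %in% c("A", "T")) { dh <- dh + 2.3; ds <- ds + 4.1 }
    else                           { dh <- dh + 0.1; ds <- ds - 2.8 }
  }
  ds <- ds + 0.368 * (n - 1) * log(na)
  1000 * dh / (ds + 1.987 * log(conc)) - 273.15
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

validate_cds <- function(cds_seq, id) {
  n <- nchar(cds_seq)
  if (n < 60L) stopf("CDS '%s' shorter than 60 nt", id)
  if (n %% 3L != 0L) stopf("CDS '%s' length not divisible by 3", id)
  if (substr(cds_seq, 1L, 3L) != "ATG")
    stopf("CDS '%s' does not start with ATG", id)
  if (!substr(cds_seq, n - 2L, n) %in% STOP_CODONS)
    stopf("CDS '%s' does not end with a stop codon", id)
  invisible(cds_seq)
}

#' Design a Gateway-tailed primer pair for one CDS
#'
#' The gene-specific forward part is the shortest CDS prefix (within
#' `len_range`) whose Tm lies in \[`tm_min`, `tm_max`\]; the
#' gene-specific reverse part is the reverse complement of the shortest
#' CDS suffix ending at the codon immediately before the stop codon
#' whose Tm lies in the window. Full primers are tail + gene-specific
#' part. Deterministic; fails with an informative error when no length
#' in range reaches the Tm window.
#'
#' @param cds length-1 nucleotide collection: an ATG-initiated,
#'   stop-terminated CDS of length >= 60 divisible by 3.
#' @param b1_tail,b2_tail Gateway adapter sequences prepended to the
#'   forward / reverse primer (defaults: standard attB1.1 / attB2.1).
#' @param tm_min,tm_max melting-temperature window (degC).
#' @param len_range allowed gene-specific lengths (nt).
#' @param tm_method passed to [primer_tm()].
#' @return list: `orf_id`, `forward_full`, `reverse_full`,
#'   `forward_gs`, `reverse_gs`, `forward_gs_len`, `reverse_gs_len`,
#'   `forward_tm`, `reverse_tm`, `tm_method`.
#' @export
design_orf_primers <- function(cds, b1_tail = GATEWAY_B1_1,
                               b2_tail = GATEWAY_B2_1,
                               tm_min = 55, tm_max = 65,
                               len_range = c(18L, 30L),
                               tm_method = c("nn", "wallace")) {
  tm_method <- match.arg(tm_method)
  stopifnot(length(cds) == 1L)
  id <- names(cds)
  s <- as.character(cds[[1]])
  validate_cds(s, id)
  n <- nchar(s)
  pick <- function(candidate) {  # candidate(len) -> primer string
    for (len in seq(len_range[1], len_range[2])) {
      p <- candidate(len)
      tm <- primer_tm(p, tm_method)
      if (tm >= tm_min && tm <= tm_max)
        return(list(seq = p, len = len, tm = tm))
    }
    NULL
  }
  fwd <- pick(function(len) substr(s, 1L, len))
  core_end <- n - 3L  # last base before the stop codon
  rev <- pick(function(len)
    as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(substr(s, core_end - len + 1L, core_end)))))
  if (is.null(fwd) || is.null(rev))
    stopf("primer design failed for '%s': no gene-specific length in [%d,%d] reaches Tm [%g,%g] (%s)",
          id, len_range[1], len_range[2], tm_min, tm_max,
          paste(c("forward", "reverse")[c(is.null(fwd), is.null(rev))],
                collapse = " and "))
  list(orf_id = id,
       forward_full = paste0(b1_tail, fwd$seq),
       reverse_full = paste0(b2_tail, rev$seq),
       forward_gs = fwd$seq, reverse_gs = rev$seq,
       forward_gs_len = fwd$len, reverse_gs_len = rev$len,
       forward_tm = fwd$tm, reverse_tm = rev$tm,
       tm_method = tm_method)
}

#' Design primers for a CDS collection
#'
#' Per-CDS design with failures collected instead of raised.
#'
#' @param cds_set nucleotide collection of CDSs.
#' @param ... passed to [design_orf_primers()].
#' @return data.frame with one row per CDS: the primer fields, a
#'   `status` column (`ok` / `failed`) and the failure `message`.
#' @export
design_primer_set <- function(cds_set, ...) {
  rows <- lapply(seq_along(cds_set), function(i) {
    res <- tryCatch(design_orf_primers(cds_set[i], ...),
                    error = function(e) conditionMessage(e))
    if (is.character(res))
      data.frame(orf_id = names(cds_set)[i], forward_full = NA_character_,
                 reverse_full = NA_character_, forward_gs_len = NA_integer_,
                 reverse_gs_len = NA_integer_, forward_tm = NA_real_,
                 reverse_tm = NA_real_, tm_method = NA_character_,
                 status = "failed", message = res,
                 stringsAsFactors = FALSE)
    else
      data.frame(orf_id = res$orf_id, forward_full = res$forward_full,
                 reverse_full = res$reverse_full,
                 forward_gs_len = res$forward_gs_len,
                 reverse_gs_len = res$reverse_gs_len,
                 forward_tm = res$forward_tm, reverse_tm = res$reverse_tm,
                 tm_method = res$tm_method, status = "ok", message = "",
                 stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
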