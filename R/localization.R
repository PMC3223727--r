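# Subcellular localization by k-nearest neighbors on amino-acid
# composition.
#
# For each protein the k nearest labelled reference proteins (default
# k = 32) are tallied per compartment; the counts N(c_i) convert to a
# probability model P(c_i) = N(c_i) / k. A protein is binned to a
# single compartment when more than 50% of its neighbors share it,
# otherwise to "other". Predictions are made twice -- against a plant
# and an animal reference set -- and consolidated at an 85% cutoff by
# keeping the higher-confidence lineage (ties go to plant, the closer
# lineage for a green alga).

#' Composition features of protein sequences
#'
#' The 20 amino-acid frequencies (X ignored, frequencies over the
#' standard residues sum to 1) plus the natural log of sequence length.
#' This composition-based feature set stands in for the richer sorting
#' signal features of trained localization predictors; the module's
#' contract is the neighbor-count probability arithmetic, not any
#' specific feature engineering.
#'
#' @param x a protein collection (see [seq_set()]).
#' @return Numeric matrix, one row per sequence, columns the 20 amino
#'   acids plus `log_length`.
#' @export
composition_features <- function(x) {
  if (seq_alphabet(x) != "protein") stopf("protein sequences required")
  freq <- Biostrings::letterFrequency(x, letters = PROTEIN_LETTERS)
  tot <- rowSums(freq)
  if (any(tot == 0)) stopf("sequence of only X residues has no composition")
  m <- cbind(freq / tot, log_length = log(Biostrings::width(x)))
  rownames(m) <- names(x)
  m
}

#' Build a labelled localization reference set
#'
#' @param sequences protein collection of reference proteins.
#' @param compartments character vector of [COMPARTMENTS] labels, one
#'   per reference protein (dual labels are not allowed).
#' @param lineage `"plant"` or `"animal"`.
#' @return list of class `loc_reference` with precomputed features.
#' @export
loc_reference <- function(sequences, compartments,
                          lineage = c("plant", "animal")) {
  lineage <- match.arg(lineage)
  if (length(compartments) != length(sequences))
    stopf("one compartment label per reference protein required")
  bad <- setdiff(unique(compartments), COMPARTMENTS)
  if (length(bad))
    stopf("unknown compartment labels: %s", paste(bad, collapse = ", "))
  structure(list(ids = names(sequences),
                 sequences = sequences,
                 features = composition_features(sequences),
                 compartments = as.character(compartments),
                 lineage = lineage),
            class = "loc_reference")
}

#' k-nearest-neighbor localization prediction
#'
#' Finds the `k` references nearest to the query in Euclidean feature
#' distance (ties at the k-th neighbor broken by reference id) and
#' tallies their compartments. With `weighting = "uniform"` the counts
#' are plain neighbor counts; with `"inverse_distance"` each neighbor
#' contributes weight 1/(d + 1e-9), renormalized so the weights sum to
#' k. Probabilities are N(c_i) / k and always sum to 1.
#'
#' @param query a length-1 protein collection.
#' @param reference a [loc_reference()].
#' @param k number of nearest neighbors (default 32).
#' @param weighting `"uniform"` or `"inverse_distance"`.
#' @return A `loc_prediction`: list with `orf_id`, `lineage`, `k`,
#'   `neighbor_counts` and `probabilities` (named over [COMPARTMENTS]).
#' @export
knn_predict <- function(query, reference, k = 32L,
                        weighting = c("uniform", "inverse_distance")) {
  weighting <- match.arg(weighting)
  if (length(reference$ids) < k)
    stopf("reference set (%d) smaller than k = %d",
          length(reference$ids), k)
  f <- composition_features(query)
  d <- sqrt(colSums((t(reference$features) - as.numeric(f))^2))
  ord <- order(d, reference$ids)[seq_len(k)]
  labels <- reference$compartments[ord]
  w <- if (weighting == "uniform") rep(1, k) else {
    raw <- 1 / (d[ord] + 1e-9)
    raw * (k / sum(raw))
  }
  counts <- setNames(numeric(length(COMPARTMENTS)), COMPARTMENTS)
  for (i in seq_len(k)) counts[labels[i]] <- counts[labels[i]] + w[i]
  loc_prediction(names(query), reference$lineage, counts, k)
}

#' Construct a localization prediction from neighbor counts
#'
#' @param orf_id protein id.
#' @param lineage `"plant"` or `"animal"`.
#' @param neighbor_counts nonnegative numeric named by [COMPARTMENTS]
#'   (missing compartments are zero), summing to `k`.
#' @param k total number of neighbors.
#' @return A `loc_prediction` object.
#' @export
loc_prediction <- function(orf_id, lineage, neighbor_counts, k = 32L) {
  counts <- setNames(numeric(length(COMPARTMENTS)), COMPARTMENTS)
  counts[names(neighbor_counts)] <- neighbor_counts
  if (any(counts < 0)) stopf("negative neighbor counts")
  if (abs(sum(counts) - k) > 1e-8)
    stopf("neighbor counts must sum to k = %s", format(k))
  structure(list(orf_id = orf_id, lineage = lineage, k = k,
                 neighbor_counts = counts, probabilities = counts / k),
            class = "loc_prediction")
}

#' @export
print.loc_prediction <- function(x, ...) {
  cat(sprintf("<loc_prediction> %s (%s, k=%s)\n", x$orf_id, x$lineage,
              format(x$k)))
  p <- sort(x$probabilities[x$probabilities > 0], decreasing = TRUE)
  cat(paste(sprintf("%s=%.3f", names(p), p), collapse = " "), "\n")
  invisible(x)
}

#' Bin a prediction to its primary compartment
#'
#' Returns the unique compartment whose probability strictly exceeds
#' the threshold (default 0.5, i.e. more than half of the nearest
#' neighbors), otherwise [OTHER] -- the bucket for multi-compartment or
#' ambiguous predictions. A probability of exactly 0.5 does not
#' qualify.
#'
#' @param pred a `loc_prediction`.
#' @param threshold probability that must be strictly exceeded.
#' @return A compartment label or [OTHER].
#' @export
bin_primary <- function(pred, threshold = 0.5) {
  over <- names(pred$probabilities)[pred$probabilities > threshold]
  if (length(over) == 1L) over else OTHER
}

#' Consolidate plant and animal predictions
#'
#' Each lineage contributes its top compartment probability p*. If both
#' lineages reach the cutoff (default 0.85), the higher p* wins, a tie
#' going to the plant lineage; if exactly one reaches it, that lineage
#' is used; if neither does, the protein is reported as [OTHER] with
#' `lineage_used = "none"` and confidence equal to the better p*.
#'
#' @param plant,animal `loc_prediction` objects for the same protein.
#' @param cutoff consolidation cutoff on the top probability.
#' @return list with `orf_id`, `assignment`, `confidence`,
#'   `lineage_used`.
#' @export
consolidate <- function(plant, animal, cutoff = 0.85) {
  if (!identical(plant$orf_id, animal$orf_id))
    stopf("plant and animal predictions are for different proteins")
  top <- function(pred) {
    i <- which.max(pred$probabilities)   # first compartment on ties
    list(label = names(pred$probabilities)[i],
         p = unname(pred$probabilities[i]))
  }
  tp <- top(plant); ta <- top(animal)
  if (tp$p >= cutoff && ta$p >= cutoff) {
    pick <- if (ta$p > tp$p) list(ta, "animal") else list(tp, "plant")
  } else if (tp$p >= cutoff) {
    pick <- list(tp, "plant")
  } else if (ta$p >= cutoff) {
    pick <- list(ta, "animal")
  } else {
    return(list(orf_id = plant$orf_id, assignment = OTHER,
                confidence = max(tp$p, ta$p), lineage_used = "none"))
  }
  list(orf_id = plant$orf_id, assignment = pick[[1]]$label,
       confidence = pick[[1]]$p, lineage_used = pick[[2]])
}

#' Predict localization for a whole collection
#'
#' Runs [knn_predict()] per protein against both lineage references,
#' bins each lineage at `bin_threshold` and consolidates at
#' `consolidation_cutoff`.
#'
#' @param queries protein collection.
#' @param ref_plant,ref_animal [loc_reference()] objects.
#' @inheritParams knn_predict
#' @param bin_threshold see [bin_primary()].
#' @param consolidation_cutoff see [consolidate()].
#' @return list with `plant` and `animal` (lists of `loc_prediction`),
#'   and `consolidated` (data.frame: orf_id, plant_bin, animal_bin,
#'   assignment, confidence, lineage_used).
#' @export
predict_localization <- function(queries, ref_plant, ref_animal, k = 32L,
                                 weighting = c("uniform", "inverse_distance"),
                                 bin_threshold = 0.5,
                                 consolidation_cutoff = 0.85) {
  weighting <- match.arg(weighting)
  plant <- lapply(seq_along(queries), function(i)
    knn_predict(queries[i], ref_plant, k, weighting))
  animal <- lapply(seq_along(queries), function(i)
    knn_predict(queries[i], ref_animal, k, weighting))
  cons <- lapply(seq_along(queries), function(i)
    consolidate(plant[[i]], animal[[i]], consolidation_cutoff))
  tab <- data.frame(
    orf_id = names(queries),
    plant_bin = vapply(plant, bin_primary, character(1),
                       threshold = bin_threshold),
    animal_bin = vapply(animal, bin_primary, character(1),
                        threshold = bin_threshold),
    assignment = vapply(cons, `[[`, character(1), "assignment"),
    confidence = vapply(cons, `[[`, numeric(1), "confidence"),
    lineage_used = vapply(cons, `[[`, character(1), "lineage_used"),
    stringsAsFactors = FALSE)
  list(plant = plant, animal = animal, consolidated = tab)
}

#' Write per-lineage neighbor counts as a table
#'
#' @param predictions list of `loc_prediction` (one lineage).
#' @param path output path.
#' @export
write_loc_predictions <- function(predictions, path) {
  counts <- do.call(rbind, lapply(predictions, `[[`, "neighbor_counts"))
  out <- data.frame(
    orf_id = vapply(predictions, `[[`, character(1), "orf_id"),
    lineage = vapply(predictions, `[[`, character(1), "lineage"),
    k = vapply(predictions, function(p) as.numeric(p$k), numeric(1)),
    counts, stringsAsFactors = FALSE, check.names = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Compartment frequency summary of consolidated assignments
#'
#' @param consolidated data.frame from [predict_localization()].
#' @return data.frame of assignment counts over [COMPARTMENTS] plus
#'   [OTHER].
#' @export
compartment_summary <- function(consolidated) {
  lv <- c(COMPARTMENTS, OTHER)
  tab <- table(factor(consolidated$assignment, levels = lv))
  data.frame(compartment = lv, n = as.integer(tab),
             stringsAsFactors = FALSE)
}
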