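#' Sample decoy protein pairs
#'
#' Decoys represent the null of random co-elution: unordered protein pairs
#' drawn uniformly without replacement from the pairs that did NOT pass the
#' candidate co-elution screen. They are subsequently featurized and scored
#' with the same trained classifier as the targets.
#'
#' @param candidates Candidate pair tibble (`protein_a`, `protein_b`).
#' @param proteins Character vector of all protein ids in the experiment
#'   (or a `cf_profiles` tibble, from which ids are taken).
#' @param n Number of decoys (default: one per candidate).
#' @param seed Integer seed for reproducible sampling.
#' @return Tibble `protein_a`, `protein_b`, `is_decoy = TRUE`.
#' @export
generate_decoys <- function(candidates, proteins, n = nrow(candidates),
                            seed = 1L) {
  if (is.data.frame(proteins)) proteins <- unique(proteins$protein_id)
  proteins <- sort(unique(proteins))
  if (length(proteins) < 2) stop("need at least two proteins", call. = FALSE)
  cmb <- utils::combn(proteins, 2)
  all_keys <- pair_key(cmb[1, ], cmb[2, ])
  cand_keys <- pair_key(candidates$protein_a, candidates$protein_b)
  pool <- which(!all_keys %in% cand_keys)
  if (length(pool) < n) {
    stop("decoy pool too small: ", length(pool), " non-candidate pairs, ",
         n, " requested", call. = FALSE)
  }
  set.seed(seed)
  take <- pool[sample.int(length(pool), n)]
  tibble::tibble(protein_a = cmb[1, take], protein_b = cmb[2, take],
                 is_decoy = TRUE)
}

#' Target-decoy q-values
#'
#' The estimated FDR at score threshold t is
#' `#(decoys >= t) / max(1, #(targets >= t))`; the q-value of a target is
#' the minimum estimated FDR over all thresholds at or below its score
#' (monotone step-down), so q-values never increase with the score. Tied
#' scores share the worse q-value.
#'
#' @param target_scores Classifier probabilities of the target pairs.
#' @param decoy_scores Classifier probabilities of the decoy pairs.
#' @return Numeric q-value per target, in input order.
#' @export
target_decoy_qvalues <- function(target_scores, decoy_scores) {
  if (length(target_scores) == 0) return(numeric(0))
  if (length(decoy_scores) == 0) {
    stop("decoy score set is empty", call. = FALSE)
  }
  thresholds <- sort(unique(target_scores), decreasing = TRUE)
  n_target_ge <- vapply(thresholds, function(t) sum(target_scores >= t), 0)
  n_decoy_ge <- vapply(thresholds, function(t) sum(decoy_scores >= t), 0)
  fdr <- n_decoy_ge / pmax(1, n_target_ge)
  q_at_threshold <- rev(cummin(rev(fdr)))  # min FDR over thresholds <= score
  q_at_threshold[match(target_scores, thresholds)]
}

#' Filter scored pairs into the final interaction set
#'
#' Applies the two confidence filters to the scored target pairs: the
#' target-decoy q-value must not exceed `fdr` and the classifier
#' probability must reach `min_probability`. Decoys are dropped. When an
#' organism map is given, each retained interaction is typed as
#' `host-host`, `host-phage` or `phage-phage`.
#'
#' @param scored Tibble of scored pairs with columns `protein_a`,
#'   `protein_b`, `probability`, and `q_value`; rows with `is_decoy = TRUE`
#'   are removed first.
#' @param fdr Maximum q-value (default 0.05).
#' @param min_probability Minimum classifier probability (default 0.75).
#' @param organisms Optional named character vector protein id -> organism
#'   (`"host"`/`"phage"`).
#' @return The retained interactions, sorted by descending probability,
#'   with an `interaction_type` column when `organisms` is supplied.
#' @export
filter_interactions <- function(scored, fdr = 0.05, min_probability = 0.75,
                                organisms = NULL) {
  out <- tibble::as_tibble(scored)
  if ("is_decoy" %in% names(out)) out <- out[!out$is_decoy, , drop = FALSE]
  keep <- out$q_value <= fdr & out$probability >= min_probability
  out <- out[keep, , drop = FALSE]
  if (!is.null(organisms)) {
    oa <- organisms[out$protein_a]
    ob <- organisms[out$protein_b]
    out$interaction_type <- dplyr::case_when(
      oa == "host" & ob == "host" ~ "host-host",
      oa == "phage" & ob == "phage" ~ "phage-phage",
      TRUE ~ "host-phage"
    )
  }
  out[order(-out$probability, out$protein_a, out$protein_b), , drop = FALSE]
}
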