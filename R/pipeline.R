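#' Train a co-elution classifier on simulated data
#'
#' Builds processed profiles from one or several simulations, selects
#' candidate pairs in every condition, featurizes them, labels them
#' against the planted complexes and trains the classifier. Training on
#' several independently laid-out datasets (different seeds) is strongly
#' recommended: the per-fraction feature blocks are positional, and a
#' single elution layout lets the network memorize *where* the training
#' complexes eluted instead of learning what co-elution looks like -
#' published co-fractionation classifiers train across many experiments
#' for the same reason.
#'
#' @param sims A [simulate_dataset()] result, or a list of them.
#' @param spec A [classifier_spec()]; the input size must be `2 * F + 3`.
#' @param candidate_threshold Candidate r-squared cut (default 0.3).
#' @param q Sliding-window width for featurization.
#' @param holdout_sims How many of the supplied simulations (taken from the
#'   end of the list) form the early-stopping validation set. Holding out
#'   whole datasets, not a random pair split, is what lets early stopping
#'   catch layout memorization; 0 falls back to the spec's random split.
#' @param augment_shifts Number of additional, elution-shifted copies of
#'   every training pair (both traces rolled by one common random offset,
#'   so co-elution structure is preserved while absolute peak positions
#'   are scrambled). Per-fraction features are positional, and shift
#'   augmentation is what forces the network to score elution *shape*
#'   agreement rather than memorizing where the training complexes eluted.
#'   0 disables augmentation; validation pairs are never augmented.
#' @param augment_max_shift Largest absolute offset (fractions) used for
#'   augmentation.
#' @return A trained `cf_classifier`.
#' @export
train_on_simulation <- function(sims, spec = classifier_spec(),
                                candidate_threshold = 0.3, q = 6L,
                                holdout_sims = 0L, augment_shifts = 0L,
                                augment_max_shift = 20L) {
  if (inherits(sims, "cf_simulation")) sims <- list(sims)
  stopifnot(holdout_sims >= 0, holdout_sims < length(sims))
  parts <- lapply(sims, function(sim) {
    profiles <- process_profiles(sim$peptides)
    feats <- dplyr::bind_rows(lapply(unique(profiles$condition),
                                     function(cond) {
      candidate_pairs(profiles, cond, threshold = candidate_threshold)
    }))
    feats$label <- planted_pair_labels(sim$truth, feats)
    list(feats = feats, profiles = profiles)
  })
  n_train_sims <- length(parts) - holdout_sims
  set.seed(spec$seed + 2L)
  feat_parts <- lapply(seq_along(parts), function(i) {
    p <- parts[[i]]
    fe <- featurize(p$feats, p$profiles, q = q)
    if (i <= n_train_sims && augment_shifts > 0) {
      aug <- augment_pair_features(p$feats, p$profiles, augment_shifts,
                                   augment_max_shift, q = q)
      fe <- dplyr::bind_rows(fe, aug)
    }
    fe
  })
  feats <- dplyr::bind_rows(feat_parts)
  val_idx <- NULL
  if (holdout_sims > 0) {
    n_per <- vapply(feat_parts, nrow, 0L)
    first_val <- sum(n_per[seq_len(n_train_sims)])
    val_idx <- seq(first_val + 1L, nrow(feats))
  }
  model <- build_classifier(spec)
  train_classifier(model, feats, feats$label, spec, validation_idx = val_idx)
}

# featurize shift-augmented copies of labelled pairs: both traces of a pair
# are circularly rolled by the same offset, keeping their relative geometry
augment_pair_features <- function(pairs, profiles, n_shifts, max_shift,
                                  q = 6L) {
  key <- paste(profiles$protein_id, profiles$condition, sep = "\r")
  ia <- match(paste(pairs$protein_a, pairs$condition, sep = "\r"), key)
  ib <- match(paste(pairs$protein_b, pairs$condition, sep = "\r"), key)
  roll <- function(x, s) {
    n <- length(x)
    s <- ((s %% n) + n) %% n
    if (s == 0) x else c(x[(n - s + 1):n], x[1:(n - s)])
  }
  out <- vector("list", n_shifts)
  for (k in seq_len(n_shifts)) {
    offs <- sample(c(-max_shift:-1, 1:max_shift), nrow(pairs), replace = TRUE)
    cp <- pairs
    cp$features <- lapply(seq_len(nrow(pairs)), function(i) {
      featurize_pair(roll(profiles$intensity[[ia[i]]], offs[i]),
                     roll(profiles$intensity[[ib[i]]], offs[i]), q = q)
    })
    out[[k]] <- cp
  }
  dplyr::bind_rows(out)
}

#' Score and filter protein-protein interactions end to end
#'
#' Runs the full interaction-mapping pipeline on a peptide table: profile
#' inference, smoothing and replicate averaging; candidate selection
#' (r-squared threshold) per condition; featurization and neural scoring;
#' decoy generation and target-decoy q-values per condition; and the final
#' q-value plus probability filter. Results from several conditions are
#' combined by keeping, for each pair retained anywhere, the row with the
#' highest probability.
#'
#' @param records Peptide record tibble (see [read_peptide_table()]), or a
#'   `cf_simulation` (its peptide table is used).
#' @param model A trained `cf_classifier`.
#' @param candidate_threshold Candidate r-squared cut (default 0.3).
#' @param fdr Target-decoy q-value cut (default 0.05).
#' @param min_probability Probability cut (default 0.75).
#' @param q Sliding-window width for featurization (default 6).
#' @param decoy_seed Seed for decoy sampling (default 1).
#' @param organisms Optional named organism map for interaction typing.
#' @return A `cf_interactions` list: `network` (the combined retained
#'   interaction tibble), `per_condition` (all scored targets and decoys
#'   with probabilities and q-values), and `profiles` (the processed
#'   per-condition profiles).
#' @export
score_interactions <- function(records, model, candidate_threshold = 0.3,
                               fdr = 0.05, min_probability = 0.75, q = 6L,
                               decoy_seed = 1L, organisms = NULL) {
  if (inherits(records, "cf_simulation")) records <- records$peptides
  profiles <- process_profiles(records)
  all_proteins <- unique(profiles$protein_id)

  per_condition <- lapply(unique(profiles$condition), function(cond) {
    cand <- candidate_pairs(profiles, cond, threshold = candidate_threshold)
    if (nrow(cand) == 0) return(NULL)
    cand$is_decoy <- FALSE
    dec <- generate_decoys(cand, all_proteins, seed = decoy_seed)
    dec$condition <- cond
    dec$r_squared <- NA_real_
    scored <- dplyr::bind_rows(cand, dec)
    scored <- featurize(scored, profiles, q = q)
    scored$probability <- predict_probability(model, scored)
    scored$q_value <- NA_real_
    scored$q_value[!scored$is_decoy] <- target_decoy_qvalues(
      scored$probability[!scored$is_decoy],
      scored$probability[scored$is_decoy]
    )
    scored$features <- NULL
    scored
  })
  per_condition <- dplyr::bind_rows(per_condition)

  retained <- filter_interactions(per_condition, fdr = fdr,
                                  min_probability = min_probability,
                                  organisms = organisms)
  # combine conditions: best-probability row per unordered pair
  if (nrow(retained) > 0) {
    retained <- retained[order(-retained$probability), , drop = FALSE]
    retained <- retained[!duplicated(pair_key(retained$protein_a,
                                              retained$protein_b)), ,
                         drop = FALSE]
  }
  structure(list(network = tibble::as_tibble(retained),
                 per_condition = per_condition,
                 profiles = profiles),
            class = "cf_interactions")
}

#' @export
print.cf_interactions <- function(x, ...) {
  n_t <- sum(!x$per_condition$is_decoy)
  cat("Scored", n_t, "candidate pairs (",
      sum(x$per_condition$is_decoy), "decoys );",
      nrow(x$network), "interactions retained\n")
  invisible(x)
}
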