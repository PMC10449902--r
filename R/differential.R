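#' Bayesian differential SEC score for one profile pair
#'
#' Posterior probability that two processed elution profiles of the same
#' protein (one per condition) arise from *different* underlying elution
#' behaviours. Two generative hypotheses are compared fraction-wise under
#' Gaussian observation noise of scale `noise_sd` and a shared Gaussian
#' latent prior: H0 - both observations are noisy copies of one latent
#' profile value; H1 - each condition has its own independent latent value.
#' With equal prior odds, the score is the marginal likelihood of H1
#' divided by the sum of both marginals. Both marginals are available in
#' closed form (the fraction-wise observation pair is bivariate normal
#' under H0, independent normal under H1), which keeps the score exact and
#' fast. Scores above 0.5 favour a real change - of peak position
#' (assembly state) or of relative peak intensity (stoichiometry); both
#' move fraction-wise values and so both move the score. Identical
#' profiles always score below 0.5.
#'
#' @param x,y Processed \[0, 1\] traces of equal length.
#' @param noise_sd Fraction-wise observation noise SD on the \[0, 1\]
#'   scale. Estimate from replicates with [estimate_noise_sd()]
#'   (default 0.05).
#' @param prior_sd SD of the latent-profile prior; defaults to the SD of
#'   the pooled trace values (floored at 0.05) so the prior spans the
#'   dynamic range actually used.
#' @return Score in (0, 1); symmetric in `x` and `y`.
#' @export
sec_differential_score <- function(x, y, noise_sd = 0.05, prior_sd = NULL) {
  n <- length(x)
  if (n == 0 || length(y) != n) {
    stop("profiles must be non-empty and of equal length", call. = FALSE)
  }
  stopifnot(noise_sd > 0)
  pooled <- c(x, y)
  m0 <- mean(pooled)
  tau <- prior_sd %||% max(stats::sd(pooled), 0.05)
  v <- noise_sd^2 + tau^2   # marginal variance of one observation
  cv <- tau^2               # H0 covariance between the paired observations
  da <- x - m0
  db <- y - m0
  det0 <- v^2 - cv^2
  loglik0 <- sum(-log(2 * pi) - 0.5 * log(det0) -
                   (v * (da^2 + db^2) - 2 * cv * da * db) / (2 * det0))
  loglik1 <- sum(-log(2 * pi) - log(v) - (da^2 + db^2) / (2 * v))
  1 / (1 + exp(loglik0 - loglik1))
}

#' Estimate fraction-wise profile noise from replicates
#'
#' Median absolute fraction-wise difference between the first two
#' replicate profiles (processed scale), computed over *active* fractions
#' - those where either replicate exceeds 10% of the peak height. The
#' restriction matters: most of a 72-fraction trace is flat baseline
#' where replicates agree trivially, and a baseline-dominated median
#' would understate the real null variation (peptide noise plus the
#' sub-fraction elution jitter of unchanged proteins) that the
#' differential score must tolerate.
#'
#' @param profiles Processed `cf_profiles` tibble with a `replicate`
#'   column.
#' @param active_min Activity cutoff on the \[0, 1\] scale (default 0.1).
#' @return A single noise SD (floored at 0.01).
#' @export
estimate_noise_sd <- function(profiles, active_min = 0.1) {
  reps <- sort(unique(profiles$replicate))
  if (length(reps) < 2) return(0.05)
  a <- profiles[profiles$replicate == reps[1], ]
  b <- profiles[profiles$replicate == reps[2], ]
  key <- function(d) paste(d$protein_id, d$condition, sep = "\r")
  shared <- intersect(key(a), key(b))
  xa <- unlist(a$intensity[match(shared, key(a))], use.names = FALSE)
  xb <- unlist(b$intensity[match(shared, key(b))], use.names = FALSE)
  active <- pmax(xa, xb) >= active_min
  if (!any(active)) return(0.05)
  max(stats::median(abs(xa - xb)[active]), 0.01)
}

#' Differential SEC scores between two conditions
#'
#' Applies [sec_differential_score()] to every protein present in both
#' conditions, and reports a signed apex-shift diagnostic (positive =
#' later elution, i.e. apparent disassembly, in `condition_b`).
#'
#' @param profiles Processed per-condition `cf_profiles` tibble.
#' @param condition_a,condition_b The two conditions to compare
#'   (`condition_a` is the reference).
#' @param noise_sd Observation noise SD; see [sec_differential_score()].
#' @param min_prominence,min_width Peak settings for the apex diagnostic.
#' @return Tibble: `protein_id`, `sec_score`, `apex_shift`.
#' @export
sec_differential <- function(profiles, condition_a, condition_b,
                             noise_sd = 0.05, min_prominence = 0.1,
                             min_width = 2) {
  a <- profiles[profiles$condition == condition_a, ]
  b <- profiles[profiles$condition == condition_b, ]
  shared <- intersect(a$protein_id, b$protein_id)
  rows <- lapply(shared, function(pid) {
    xa <- a$intensity[[match(pid, a$protein_id)]]
    xb <- b$intensity[[match(pid, b$protein_id)]]
    primary <- function(v) {
      pk <- detect_peaks_trace(v, min_prominence, min_width)
      if (is.null(pk) || nrow(pk) == 0) return(NA_real_)
      pk$apex_fraction[order(-pk$prominence, pk$apex_fraction)][1]
    }
    tibble::tibble(
      protein_id = pid,
      sec_score = sec_differential_score(xa, xb, noise_sd = noise_sd),
      apex_shift = primary(xb) - primary(xa)
    )
  })
  dplyr::bind_rows(rows)
}

#' Per-protein abundance from peptide records
#'
#' Total intensity per protein, condition and replicate (summed over
#' peptides and fractions) - the whole-proteome abundance view that
#' complements the SEC profile shape.
#'
#' @param records Peptide record tibble.
#' @return Tibble: `protein_id`, `condition`, `replicate`, `intensity`.
#' @export
protein_abundances <- function(records) {
  dplyr::summarise(
    dplyr::group_by(records, .data$protein_id, .data$condition,
                    .data$replicate),
    intensity = sum(.data$intensity), .groups = "drop"
  )
}

#' Differential protein abundance between two conditions
#'
#' Log2 fold change of mean intensities plus a two-sided t-test on log2
#' intensities across replicates, Benjamini-Hochberg adjusted over
#' proteins. A protein absent (zero or missing) in one condition gets an
#' infinite fold change and no q-value.
#'
#' @param abundances Tibble from [protein_abundances()].
#' @param condition_a,condition_b Reference and test condition.
#' @return Tibble: `protein_id`, `log2fc` (`condition_b` over
#'   `condition_a`), `p_value`, `abundance_q`.
#' @export
abundance_differential <- function(abundances, condition_a, condition_b) {
  ab <- abundances[abundances$condition %in% c(condition_a, condition_b), ]
  rows <- lapply(sort(unique(ab$protein_id)), function(pid) {
    xa <- ab$intensity[ab$protein_id == pid & ab$condition == condition_a]
    xb <- ab$intensity[ab$protein_id == pid & ab$condition == condition_b]
    if (length(xa) == 0 || all(xa == 0) || length(xb) == 0 || all(xb == 0)) {
      lfc <- if (length(xb) > 0 && any(xb > 0)) Inf else
        if (length(xa) > 0 && any(xa > 0)) -Inf else NA_real_
      return(tibble::tibble(protein_id = pid, log2fc = lfc,
                            p_value = NA_real_))
    }
    p <- if (length(xa) >= 2 && length(xb) >= 2) {
      stats::t.test(log2(xb), log2(xa))$p.value
    } else NA_real_
    tibble::tibble(protein_id = pid, log2fc = log2(mean(xb) / mean(xa)),
                   p_value = p)
  })
  out <- dplyr::bind_rows(rows)
  out$abundance_q <- stats::p.adjust(out$p_value, method = "BH")
  out
}

#' Classify per-protein regulation
#'
#' Combines the differential SEC score with the whole-proteome abundance
#' change into four regulation classes: `assembly_only` (SEC score at or
#' above `sec_threshold`), `abundance_only` (absolute log2 fold change at
#' least `fc_threshold` with q at most `q_threshold`), `both`, or `none`.
#'
#' @param results Tibble carrying `sec_score`, `log2fc` and `abundance_q`
#'   columns (join of [sec_differential()] and [abundance_differential()]).
#' @param sec_threshold SEC-score cut (default 0.5).
#' @param fc_threshold Absolute log2 fold-change cut (default 2).
#' @param q_threshold Abundance q-value cut (default 0.01).
#' @return `results` with a `regulation` factor column.
#' @export
classify_regulation <- function(results, sec_threshold = 0.5,
                                fc_threshold = 2, q_threshold = 0.01) {
  sec <- !is.na(results$sec_score) & results$sec_score >= sec_threshold
  ab <- !is.na(results$log2fc) & abs(results$log2fc) >= fc_threshold &
    !is.na(results$abundance_q) & results$abundance_q <= q_threshold
  results$regulation <- dplyr::case_when(
    sec & ab ~ "both",
    sec ~ "assembly_only",
    ab ~ "abundance_only",
    TRUE ~ "none"
  )
  results
}
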