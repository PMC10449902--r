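#' Simulation configuration for synthetic co-fractionation data
#'
#' Bundles every knob of the synthetic SEC-MS generator. The defaults
#' emulate a 72-fraction, 2-replicate, two-condition experiment: planted
#' protein complexes whose members share a Gaussian elution apex, free
#' monomers eluting at their monomeric molecular weight, peptide-level
#' multiplicative log-normal noise, between-replicate apex jitter well
#' within 1-2 fractions, and condition-specific peak shifts and abundance
#' changes in the non-control condition.
#'
#' @param n_fractions Number of SEC fractions (default 72).
#' @param n_replicates Biological replicates per condition (default 2).
#' @param conditions Condition names; the first is the unperturbed control.
#' @param n_complexes Number of planted complexes.
#' @param complex_size_range Integer pair: min/max members per complex.
#' @param n_monomers Number of free (never complexed) proteins.
#' @param peptides_per_protein_range Integer pair: peptides simulated per
#'   protein.
#' @param peak_sigma_range Real pair: Gaussian elution peak standard
#'   deviation, in fractions.
#' @param apex_jitter_sd Between-replicate apex jitter SD in fractions
#'   (complexes jitter as a unit, so co-elution of members is preserved).
#' @param noise_cv Coefficient of variation of the multiplicative
#'   log-normal intensity noise (unit mean).
#' @param perturbed_fraction Share of proteins perturbed in each
#'   non-control condition.
#' @param shift_magnitude Elution shift applied to shift-perturbed proteins,
#'   in fractions (sign drawn at random per protein).
#' @param abundance_log2fc Log2 fold change applied to abundance-perturbed
#'   proteins.
#' @param monomer_peak_prob Probability that a complex member also shows a
#'   secondary peak at its monomeric weight.
#' @param monomer_peak_scale Relative amplitude of that secondary monomeric
#'   peak.
#' @param mw_range_monomer_da Log-uniform sampling range for monomeric
#'   molecular weights, Da.
#' @param complex_mw_range_da Log-uniform sampling range for the target
#'   total mass of a planted complex, Da. Subunit copy numbers are chosen
#'   so the stoichiometric sum of member masses approximates the target,
#'   letting planted complexes span the column's resolving range the way
#'   real assemblies (0.1 to several MDa) do.
#' @param calibration_slope,calibration_intercept The log-linear SEC
#'   column law used by the generator: log10(MW in Da) =
#'   intercept + slope * fraction. Apex fractions of complexes and monomers
#'   are placed by inverting this law, so a calibration fitted downstream
#'   can be checked against planted masses.
#' @param n_standards Calibration standards emitted (noiseless, on the
#'   column law, spanning the fraction range).
#' @param standard_apex_sd SD of optional Gaussian noise on standard apexes
#'   (0 = noiseless default; a toggle for robustness tests).
#' @param phage_fraction Share of proteins tagged as phage (the rest are
#'   host); drives interaction-type annotation and virion labels.
#' @param virion_fraction Share of phage proteins labelled as packaged in
#'   the virion (ground truth for ROC-style tests).
#' @param abundance_range Log-uniform range for total protein abundance
#'   (arbitrary MS intensity units).
#' @param seed Integer seed; identical seeds give identical datasets.
#' @return A `cf_sim_config` list.
#' @export
sim_config <- function(n_fractions = 72L,
                       n_replicates = 2L,
                       conditions = c("control", "infected"),
                       n_complexes = 10L,
                       complex_size_range = c(3L, 5L),
                       n_monomers = 30L,
                       peptides_per_protein_range = c(3L, 6L),
                       peak_sigma_range = c(1.0, 2.5),
                       apex_jitter_sd = 0.5,
                       noise_cv = 0.1,
                       perturbed_fraction = 0.2,
                       shift_magnitude = 10,
                       abundance_log2fc = 2,
                       monomer_peak_prob = 0.3,
                       monomer_peak_scale = 0.4,
                       mw_range_monomer_da = c(1.5e4, 3e5),
                       complex_mw_range_da = c(1.5e5, 3e6),
                       calibration_slope = -0.05,
                       calibration_intercept = 7.7,
                       n_standards = 6L,
                       standard_apex_sd = 0,
                       phage_fraction = 0.4,
                       virion_fraction = 0.5,
                       abundance_range = c(1e5, 1e7),
                       seed = 1L) {
  cfg <- list(
    n_fractions = as.integer(n_fractions), n_replicates = as.integer(n_replicates),
    conditions = conditions, n_complexes = as.integer(n_complexes),
    complex_size_range = as.integer(complex_size_range),
    n_monomers = as.integer(n_monomers),
    peptides_per_protein_range = as.integer(peptides_per_protein_range),
    peak_sigma_range = peak_sigma_range, apex_jitter_sd = apex_jitter_sd,
    noise_cv = noise_cv, perturbed_fraction = perturbed_fraction,
    shift_magnitude = shift_magnitude, abundance_log2fc = abundance_log2fc,
    monomer_peak_prob = monomer_peak_prob,
    monomer_peak_scale = monomer_peak_scale,
    mw_range_monomer_da = mw_range_monomer_da,
    complex_mw_range_da = complex_mw_range_da,
    calibration_slope = calibration_slope,
    calibration_intercept = calibration_intercept,
    n_standards = as.integer(n_standards), standard_apex_sd = standard_apex_sd,
    phage_fraction = phage_fraction, virion_fraction = virion_fraction,
    abundance_range = abundance_range, seed = as.integer(seed)
  )
  stopifnot(cfg$n_fractions > 0, cfg$n_replicates > 0,
            length(cfg$conditions) >= 1, cfg$n_complexes >= 0,
            cfg$n_monomers >= 0, cfg$apex_jitter_sd >= 0, cfg$noise_cv >= 0,
            cfg$perturbed_fraction >= 0, cfg$perturbed_fraction <= 1)
  class(cfg) <- "cf_sim_config"
  cfg
}

# fraction index at which a species of mass mw_da elutes under the column law
mw_to_fraction <- function(mw_da, cfg) {
  (log10(mw_da) - cfg$calibration_intercept) / cfg$calibration_slope
}

fraction_to_mw <- function(fraction, cfg) {
  10^(cfg$calibration_intercept + cfg$calibration_slope * fraction)
}

runif_log <- function(n, range) {
  exp(stats::runif(n, log(range[1]), log(range[2])))
}

# multiplicative log-normal noise with unit mean and coefficient of
# variation cv: sdlog^2 = log(1 + cv^2), meanlog = -sdlog^2 / 2
lognormal_noise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

gaussian_peak <- function(fractions, apex, sigma) {
  exp(-0.5 * ((fractions - apex) / sigma)^2)
}

#' Simulate a co-fractionation dataset with planted ground truth
#'
#' Generates peptide-level SEC-MS intensities for a set of planted protein
#' complexes and free monomers. Each complex elutes as one shared Gaussian
#' peak per condition, placed so that its apparent molecular weight under
#' the generator's column law equals the sum of the members' monomeric
#' masses; members may additionally show a smaller monomeric peak. Monomers
#' elute at their monomeric mass. Replicate apexes are jittered
#' (complexes as a unit), peptide intensities carry per-peptide response
#' factors (log-uniform in 0.2-1, so top-2 peptide selection is
#' non-trivial) and multiplicative log-normal noise. In non-control
#' conditions a configured share of proteins is perturbed: elution shift,
#' abundance change, or both.
#'
#' @param config A [sim_config()].
#' @return A list of class `cf_simulation` with elements
#'   \describe{
#'     \item{peptides}{long peptide record tibble (the [read_peptide_table()]
#'       contract), `n_fractions` attribute set}
#'     \item{standards}{calibration standards tibble (`name`, `mw_da`,
#'       `apex_fraction`)}
#'     \item{truth}{ground-truth list: `proteins` (per-protein tibble with
#'       organism, monomer MW, abundance, complex membership, perturbation,
#'       virion flag), `complexes` (per complex and condition: apex fraction
#'       and total MW), `true_pairs` (all within-complex unordered pairs),
#'       `differential_proteins`, `virion_proteins`, `monomer_mw`,
#'       `organisms`}
#'     \item{config}{the config used}
#'   }
#' @examples
#' sim <- simulate_dataset(sim_config(n_complexes = 2, n_monomers = 5,
#'                                    complex_size_range = c(3, 3), seed = 7))
#' nrow(sim$truth$true_pairs)  # 2 * choose(3, 2) = 6
#' @export
simulate_dataset <- function(config = sim_config()) {
  cfg <- config
  stopifnot(inherits(cfg, "cf_sim_config"))
  set.seed(cfg$seed)

  sample_range <- function(range, n) {
    vals <- seq(range[1], range[2])
    vals[sample.int(length(vals), n, replace = TRUE)]
  }
  sizes <- if (cfg$n_complexes > 0) {
    sample_range(cfg$complex_size_range, cfg$n_complexes)
  } else integer(0)
  n_complex_members <- sum(sizes)
  n_proteins <- n_complex_members + cfg$n_monomers
  if (n_proteins < 1) stop("config error: no proteins to simulate", call. = FALSE)
  if (cfg$n_complexes > 0 && max(sizes) > n_proteins) {
    stop("config error: complex size exceeds protein count", call. = FALSE)
  }

  protein_id <- sprintf("P%03d", seq_len(n_proteins))
  complex_id <- c(rep(sprintf("CPX%02d", seq_along(sizes)), sizes),
                  rep(NA_character_, cfg$n_monomers))
  monomer_mw <- runif_log(n_proteins, cfg$mw_range_monomer_da)
  abundance <- runif_log(n_proteins, cfg$abundance_range)
  organism <- ifelse(stats::runif(n_proteins) < cfg$phage_fraction,
                     "phage", "host")
  virion <- organism == "phage" & stats::runif(n_proteins) < cfg$virion_fraction
  has_monomer_peak <- !is.na(complex_id) &
    stats::runif(n_proteins) < cfg$monomer_peak_prob

  # perturbations in non-control conditions (assigned per protein; a
  # perturbed complex member detaches from its complex peak, emulating
  # assembly-state change)
  n_pert <- round(cfg$perturbed_fraction * n_proteins)
  perturbed_ids <- sample(protein_id, n_pert)
  pert_type <- sample(c("shift", "abundance", "both"), n_pert, replace = TRUE)
  names(pert_type) <- perturbed_ids
  shift_sign <- sample(c(-1, 1), n_pert, replace = TRUE)
  names(shift_sign) <- perturbed_ids

  # per-complex elution parameters: a target total mass spanning the
  # column range is realized with integer subunit copy numbers, and the
  # apex comes from the realized stoichiometric mass
  cpx_ids <- unique(complex_id[!is.na(complex_id)])
  target_mw <- runif_log(length(cpx_ids), cfg$complex_mw_range_da)
  copies <- stats::setNames(rep(1, n_proteins), protein_id)
  total_mw <- vapply(seq_along(cpx_ids), function(ci) {
    members <- which(complex_id %in% cpx_ids[ci])
    shares <- stats::runif(length(members), 0.5, 1.5)
    shares <- shares / sum(shares)
    cp <- pmax(1, round(target_mw[ci] * shares / monomer_mw[members]))
    copies[protein_id[members]] <<- cp
    sum(cp * monomer_mw[members])
  }, 0)
  cpx <- tibble::tibble(
    complex_id = cpx_ids,
    total_mw_da = total_mw,
    sigma = stats::runif(length(cpx_ids), cfg$peak_sigma_range[1],
                         cfg$peak_sigma_range[2])
  )
  cpx$apex_fraction <- mw_to_fraction(cpx$total_mw_da, cfg)

  # per-protein monomeric peak parameters
  mono_apex <- pmin(mw_to_fraction(monomer_mw, cfg), cfg$n_fractions - 1)
  mono_sigma <- stats::runif(n_proteins, cfg$peak_sigma_range[1],
                             cfg$peak_sigma_range[2])

  # peptides
  n_pep <- sample_range(cfg$peptides_per_protein_range, n_proteins)
  peptide_tbl <- tibble::tibble(
    protein_id = rep(protein_id, n_pep),
    peptide = unlist(lapply(n_pep, function(k)
      vapply(seq_len(k), function(i)
        paste0(paste(sample(setdiff(LETTERS, c("B", "J", "O", "U", "X", "Z")),
                            8, replace = TRUE), collapse = ""), "K"), "")),
      use.names = FALSE),
    response = exp(stats::runif(sum(n_pep), log(0.2), log(1)))
  )

  fr <- seq_len(cfg$n_fractions)
  # replicate jitter: one draw per complex x condition x replicate (shared by
  # members) and one per monomeric peak x condition x replicate
  records <- vector("list", length(cfg$conditions) * cfg$n_replicates)
  k <- 0L
  # a shift that would push a peak off the column is applied in the opposite
  # direction instead, so perturbed proteins stay observable
  safe_shift <- function(apex, sh) {
    out <- apex + sh
    flip <- out > cfg$n_fractions - 2 | out < 3
    sh[flip] <- -sh[flip]
    sh
  }
  for (cond_i in seq_along(cfg$conditions)) {
    cond <- cfg$conditions[cond_i]
    is_control <- cond_i == 1L
    # condition-level perturbation per protein
    shift <- stats::setNames(rep(0, n_proteins), protein_id)
    scale <- stats::setNames(rep(1, n_proteins), protein_id)
    if (!is_control && n_pert > 0) {
      for (pid in perturbed_ids) {
        ty <- pert_type[[pid]]
        if (ty %in% c("shift", "both")) {
          shift[pid] <- shift_sign[[pid]] * cfg$shift_magnitude
        }
        if (ty %in% c("abundance", "both")) {
          scale[pid] <- 2^cfg$abundance_log2fc
        }
      }
    }
    for (rep_i in seq_len(cfg$n_replicates)) {
      cpx_jit <- stats::rnorm(nrow(cpx), 0, cfg$apex_jitter_sd)
      names(cpx_jit) <- cpx$complex_id
      mono_jit <- stats::rnorm(n_proteins, 0, cfg$apex_jitter_sd)

      prof <- matrix(0, n_proteins, cfg$n_fractions)
      for (p in seq_len(n_proteins)) {
        pid <- protein_id[p]
        sh <- shift[[pid]]
        if (!is.na(complex_id[p])) {
          ci <- match(complex_id[p], cpx$complex_id)
          base_apex <- cpx$apex_fraction[ci]
          apex <- base_apex + cpx_jit[[complex_id[p]]] + safe_shift(base_apex, sh)
          prof[p, ] <- gaussian_peak(fr, apex, cpx$sigma[ci])
          if (has_monomer_peak[p]) {
            prof[p, ] <- prof[p, ] + cfg$monomer_peak_scale *
              gaussian_peak(fr, mono_apex[p] + mono_jit[p] +
                              safe_shift(mono_apex[p], sh), mono_sigma[p])
          }
        } else {
          prof[p, ] <- gaussian_peak(fr, mono_apex[p] + mono_jit[p] +
                                       safe_shift(mono_apex[p], sh),
                                     mono_sigma[p])
        }
        prof[p, ] <- prof[p, ] * abundance[p] * scale[[pid]] /
          sum(prof[p, ])
      }

      pep_int <- prof[match(peptide_tbl$protein_id, protein_id), , drop = FALSE] *
        peptide_tbl$response
      noise <- matrix(lognormal_noise(length(pep_int), cfg$noise_cv),
                      nrow(pep_int), ncol(pep_int))
      pep_int <- pep_int * noise
      k <- k + 1L
      records[[k]] <- tibble::tibble(
        protein_id = rep(peptide_tbl$protein_id, cfg$n_fractions),
        peptide = rep(peptide_tbl$peptide, cfg$n_fractions),
        condition = cond,
        replicate = rep_i,
        fraction = rep(fr, each = nrow(peptide_tbl)),
        intensity = as.vector(pep_int)
      )
    }
  }
  peptides <- dplyr::bind_rows(records)
  peptides <- peptides[order(peptides$protein_id, peptides$peptide,
                             peptides$condition, peptides$replicate,
                             peptides$fraction), ]
  attr(peptides, "n_fractions") <- cfg$n_fractions

  # calibration standards on the column law, spanning the fraction range
  std_fr <- seq(4, cfg$n_fractions - 4, length.out = cfg$n_standards)
  std_fr <- std_fr + stats::rnorm(cfg$n_standards, 0, cfg$standard_apex_sd)
  standards <- tibble::tibble(
    name = sprintf("STD%02d", seq_len(cfg$n_standards)),
    mw_da = fraction_to_mw(std_fr, cfg),
    apex_fraction = std_fr
  )

  # ground truth
  proteins <- tibble::tibble(
    protein_id = protein_id, complex_id = complex_id,
    organism = organism, monomer_mw_da = monomer_mw,
    copies_in_complex = ifelse(is.na(complex_id), NA_real_,
                               unname(copies[protein_id])),
    abundance = abundance,
    has_monomer_peak = has_monomer_peak,
    perturbation = ifelse(protein_id %in% perturbed_ids,
                          pert_type[protein_id], "none"),
    virion = virion
  )
  complexes <- tidyr::crossing(cpx, condition = cfg$conditions)
  true_pairs <- dplyr::bind_rows(lapply(cpx_ids, function(cid) {
    members <- sort(protein_id[complex_id %in% cid])
    if (length(members) < 2) return(NULL)
    cmb <- utils::combn(members, 2)
    tibble::tibble(protein_a = cmb[1, ], protein_b = cmb[2, ],
                   complex_id = cid)
  }))
  truth <- list(
    proteins = proteins,
    complexes = complexes,
    true_pairs = true_pairs,
    differential_proteins = perturbed_ids,
    virion_proteins = protein_id[virion],
    monomer_mw = stats::setNames(monomer_mw, protein_id),
    organisms = stats::setNames(organism, protein_id)
  )
  structure(list(peptides = peptides, standards = standards, truth = truth,
                 config = cfg),
            class = "cf_simulation")
}

#' Label candidate pairs against planted ground truth
#'
#' @param truth The `truth` element of a [simulate_dataset()] result.
#' @param pairs Tibble with `protein_a`, `protein_b` columns (unordered).
#' @return Integer vector, 1 for planted within-complex pairs, 0 otherwise.
#' @export
planted_pair_labels <- function(truth, pairs) {
  known <- truth$proteins$protein_id
  unknown <- setdiff(unique(c(pairs$protein_a, pairs$protein_b)), known)
  if (length(unknown) > 0) {
    stop("unknown protein(s): ", paste(utils::head(unknown, 3), collapse = ", "),
         call. = FALSE)
  }
  true_keys <- pair_key(truth$true_pairs$protein_a, truth$true_pairs$protein_b)
  as.integer(pair_key(pairs$protein_a, pairs$protein_b) %in% true_keys)
}

#' Simulate a virion-enrichment MS experiment
#'
#' Emulates comparing a purified-virion sample against a whole-proteome
#' reference: virion proteins are enriched by a log-normal factor, the rest
#' fluctuate around parity. Used to exercise ROC threshold selection and
#' enrichment fold-change analysis against known virion labels.
#'
#' @param truth Ground truth from [simulate_dataset()].
#' @param enrichment_log2 Mean log2 enrichment of virion proteins (default 3).
#' @param noise_sd SD of the per-protein log2 fluctuation (default 1).
#' @param seed Integer seed.
#' @return Tibble: `protein_id`, `enriched_intensity`, `reference_intensity`,
#'   `is_virion`.
#' @export
simulate_virion_intensities <- function(truth, enrichment_log2 = 3,
                                        noise_sd = 1, seed = 1L) {
  set.seed(seed)
  pr <- truth$proteins
  lfc <- stats::rnorm(nrow(pr), mean = ifelse(pr$virion, enrichment_log2, 0),
                      sd = noise_sd)
  tibble::tibble(
    protein_id = pr$protein_id,
    enriched_intensity = pr$abundance * 2^lfc,
    reference_intensity = pr$abundance,
    is_virion = pr$virion
  )
}
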