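# numeric-integration oracle for the two-hypothesis marginal likelihoods:
# integrates the latent profile value out fraction by fraction
oracle_sec_score <- function(x, y, noise_sd, prior_sd = NULL) {
  pooled <- c(x, y)
  m0 <- mean(pooled)
  tau <- if (is.null(prior_sd)) max(sd(pooled), 0.05) else prior_sd
  marg1 <- function(obs) {
    stats::integrate(function(mu)
      dnorm(obs, mu, noise_sd) * dnorm(mu, m0, tau),
      lower = m0 - 12 * tau, upper = m0 + 12 * tau,
      rel.tol = 1e-10)$value
  }
  marg2 <- function(a, b) {
    stats::integrate(function(mu)
      dnorm(a, mu, noise_sd) * dnorm(b, mu, noise_sd) * dnorm(mu, m0, tau),
      lower = m0 - 12 * tau, upper = m0 + 12 * tau,
      rel.tol = 1e-10)$value
  }
  l0 <- sum(log(mapply(marg2, x, y)))
  l1 <- sum(log(vapply(x, marg1, 0))) + sum(log(vapply(y, marg1, 0)))
  1 / (1 + exp(l0 - l1))
}

test_that("identical profiles never look differential", {
  g <- cofrac:::rescale01(gauss_trace(72, 30, 2))
  expect_lte(sec_differential_score(g, g), 0.5)
  flatish <- rep(0.5, 20)
  expect_lte(sec_differential_score(flatish, flatish), 0.5)
  expect_error(sec_differential_score(numeric(0), numeric(0)), "non-empty")
})

test_that("a large apex shift is confidently called differential", {
  a <- cofrac:::rescale01(gauss_trace(72, 30, 2))
  b <- cofrac:::rescale01(gauss_trace(72, 45, 2))
  expect_gt(sec_differential_score(a, b, noise_sd = 0.05), 0.5)
  # symmetry
  expect_equal(sec_differential_score(a, b, noise_sd = 0.05),
               sec_differential_score(b, a, noise_sd = 0.05),
               tolerance = 1e-12)
})

test_that("the closed-form marginals match numeric integration", {
  set.seed(23)
  n <- 24
  a <- cofrac:::rescale01(gauss_trace(n, 8, 2) + 0.05 * runif(n))
  b <- cofrac:::rescale01(gauss_trace(n, 14, 2) + 0.05 * runif(n))
  for (ns in c(0.03, 0.1)) {
    expect_equal(sec_differential_score(a, b, noise_sd = ns),
                 oracle_sec_score(a, b, noise_sd = ns), tolerance = 1e-6)
  }
  # identical input too
  expect_equal(sec_differential_score(a, a, noise_sd = 0.05),
               oracle_sec_score(a, a, noise_sd = 0.05), tolerance = 1e-6)
})

test_that("noise estimation reflects replicate disagreement", {
  sim <- default_sim()
  prof <- infer_protein_profiles(sim$peptides) |> smooth_and_rescale()
  ns <- estimate_noise_sd(prof)
  expect_gt(ns, 0.005)
  expect_lt(ns, 0.3)
})

test_that("shift-perturbed proteins score high, unperturbed score low", {
  sim <- default_sim()
  prof <- process_profiles(sim$peptides)
  raw <- infer_protein_profiles(sim$peptides) |> smooth_and_rescale()
  ns <- estimate_noise_sd(raw)
  diffs <- sec_differential(prof, "control", "infected", noise_sd = ns)
  truth <- sim$truth$proteins
  shifted <- truth$protein_id[truth$perturbation %in% c("shift", "both")]
  unchanged <- truth$protein_id[truth$perturbation == "none"]
  s_shift <- diffs$sec_score[diffs$protein_id %in% shifted]
  s_none <- diffs$sec_score[diffs$protein_id %in% unchanged]
  expect_gt(mean(s_shift), mean(s_none))
  # unperturbed proteins concentrate below the 0.5 decision line
  expect_lt(median(s_none), 0.5)
})

test_that("abundance differential recovers fold changes and flags absences", {
  ab <- tibble::tibble(
    protein_id = rep(c("P1", "P2", "P3"), each = 4),
    condition = rep(rep(c("a", "b"), each = 2), 3),
    replicate = rep(1:2, 6),
    intensity = c(100, 110, 101, 109,     # P1: unchanged
                  50, 52, 199, 201,       # P2: ratio ~4
                  80, 82, 0, 0)           # P3: absent in b
  )
  out <- abundance_differential(ab, "a", "b")
  expect_equal(out$log2fc[out$protein_id == "P1"], 0, tolerance = 0.1)
  expect_equal(out$log2fc[out$protein_id == "P2"],
               log2(mean(c(199, 201)) / mean(c(50, 52))), tolerance = 1e-12)
  expect_true(is.infinite(out$log2fc[out$protein_id == "P3"]))
  expect_true(is.na(out$abundance_q[out$protein_id == "P3"]))
  # q-values are the BH adjustment of the t-test p-values
  expect_equal(out$abundance_q[!is.na(out$p_value)],
               p.adjust(out$p_value[!is.na(out$p_value)], "BH"))
})

test_that("regulation classes follow the three thresholds", {
  res <- tibble::tibble(
    protein_id = c("a", "b", "c", "d"),
    sec_score = c(0.9, 0.1, 0.6, 0.2),
    log2fc = c(0.1, 3, 2.5, 0.5),
    abundance_q = c(0.5, 0.001, 0.005, 0.5)
  )
  out <- classify_regulation(res)
  expect_equal(out$regulation, c("assembly_only", "abundance_only",
                                 "both", "none"))
  # boundary: sec exactly 0.5 counts; |log2fc| exactly 2 with q exactly 0.01
  res2 <- tibble::tibble(protein_id = "x", sec_score = 0.5,
                         log2fc = -2, abundance_q = 0.01)
  expect_equal(classify_regulation(res2)$regulation, "both")
})
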