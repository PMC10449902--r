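test_that("sibling-peptide inference selects the most correlated pair", {
  tri <- c(0, 1, 4, 1, 0, 0)
  # single peptide: pass-through
  rec <- tibble::tibble(protein_id = "P1", peptide = "AAK", condition = "c1",
                        replicate = 1L, fraction = 1:6, intensity = tri)
  prof <- infer_protein_profiles(rec)
  expect_equal(prof$intensity[[1]], tri)

  # two peptides that are scalar multiples average elementwise
  rec2 <- dplyr::bind_rows(
    tibble::tibble(protein_id = "P1", peptide = "AAK", condition = "c1",
                   replicate = 1L, fraction = 1:5,
                   intensity = c(0, 1, 2, 1, 0)),
    tibble::tibble(protein_id = "P1", peptide = "CCK", condition = "c1",
                   replicate = 1L, fraction = 1:5,
                   intensity = 3 * c(0, 1, 2, 1, 0))
  )
  prof2 <- infer_protein_profiles(rec2)
  expect_equal(prof2$intensity[[1]], c(0, 2, 4, 2, 0))

  # three peptides: the two identical triangles win over flat noise
  set.seed(1)
  rec3 <- dplyr::bind_rows(
    rec2,
    tibble::tibble(protein_id = "P1", peptide = "GGK", condition = "c1",
                   replicate = 1L, fraction = 1:5,
                   intensity = runif(5, 0.9, 1.1))
  )
  prof3 <- infer_protein_profiles(rec3)
  expect_setequal(prof3$peptides[[1]], c("AAK", "CCK"))
  expect_equal(prof3$intensity[[1]], c(0, 2, 4, 2, 0))
})

test_that("peptide selection is shared across conditions and row-order invariant", {
  set.seed(2)
  base <- c(0, 2, 5, 2, 0, 0)
  rec <- dplyr::bind_rows(lapply(c("c1", "c2"), function(cond) {
    dplyr::bind_rows(
      tibble::tibble(protein_id = "P1", peptide = "AAK", condition = cond,
                     replicate = 1L, fraction = 1:6, intensity = base),
      tibble::tibble(protein_id = "P1", peptide = "CCK", condition = cond,
                     replicate = 1L, fraction = 1:6, intensity = base * 2),
      tibble::tibble(protein_id = "P1", peptide = "GGK", condition = cond,
                     replicate = 1L, fraction = 1:6,
                     intensity = runif(6))
    )
  }))
  prof <- infer_protein_profiles(rec)
  expect_equal(nrow(prof), 2)
  expect_equal(prof$peptides[[1]], prof$peptides[[2]])

  shuf <- rec[sample(nrow(rec)), ]
  prof_shuf <- infer_protein_profiles(shuf)
  expect_equal(prof_shuf$intensity, prof$intensity)
  expect_equal(prof_shuf$peptides, prof$peptides)
})

test_that("zero-intensity proteins are dropped with a warning", {
  rec <- dplyr::bind_rows(
    tibble::tibble(protein_id = "P1", peptide = "AAK", condition = "c1",
                   replicate = 1L, fraction = 1:4, intensity = c(1, 2, 1, 0)),
    tibble::tibble(protein_id = "P2", peptide = "CCK", condition = "c1",
                   replicate = 1L, fraction = 1:4, intensity = rep(0, 4))
  )
  expect_warning(prof <- infer_protein_profiles(rec), "P2")
  expect_equal(prof$protein_id, "P1")
})

test_that("smoothing and rescaling obey the min-max contract", {
  traces <- list(P1 = c(0, 1, 5, 9, 5, 1, 0, 0, 0, 0),
                 P2 = rep(0, 10))
  prof <- profiles_from_traces(traces)
  out <- smooth_and_rescale(prof)
  expect_equal(max(out$intensity[[1]]), 1)
  expect_equal(min(out$intensity[[1]]), 0)
  expect_equal(out$intensity[[2]], rep(0, 10))  # all-zero stays all-zero
  # idempotent in range: processing the processed profiles changes nothing
  twice <- smooth_and_rescale(out)
  expect_equal(cofrac:::rescale01(out$intensity[[1]]), out$intensity[[1]])
  expect_error(smooth_and_rescale(prof, sg_window = 11), "config error")
})

test_that("the Savitzky-Golay impulse response matches closed-form coefficients", {
  skip_if_not_installed("pracma")
  n <- 21
  x <- rep(0, n); x[11] <- 1
  prof <- profiles_from_traces(list(P1 = x))
  out <- smooth_and_rescale(prof, sg_window = 5, sg_order = 2)$intensity[[1]]
  # independent oracle: pracma's Savitzky-Golay implementation on the
  # interior (edge handling differs by construction), clipped and rescaled
  oracle <- pracma::savgol(x, fl = 5, forder = 2)
  oracle[oracle < 0] <- 0
  oracle <- (oracle - min(oracle)) / (max(oracle) - min(oracle))
  expect_equal(out[4:18], oracle[4:18], tolerance = 1e-10)
  # the central coefficients of the window-5 order-2 filter are
  # (-3, 12, 17, 12, -3)/35; the impulse reproduces them around fraction 11
  coefs <- c(-3, 12, 17, 12, -3) / 35
  raw <- as.numeric(signal::sgolayfilt(x, p = 2, n = 5))
  expect_equal(raw[9:13], rev(coefs), tolerance = 1e-12)
})

test_that("peak detection counts well-separated peaks and merges close ones", {
  n <- 72
  one <- cofrac:::rescale01(gauss_trace(n, 30, 2))
  two <- cofrac:::rescale01(gauss_trace(n, 20, 2) + gauss_trace(n, 40, 2))
  merged <- cofrac:::rescale01(gauss_trace(n, 30, 2) + gauss_trace(n, 31, 2))
  prof <- profiles_from_traces(list(P1 = one, P2 = two, P3 = merged),
                               processed = TRUE)
  pk <- detect_peaks(prof)
  expect_equal(sum(pk$protein_id == "P1"), 1)
  expect_equal(pk$apex_fraction[pk$protein_id == "P1"], 30)
  expect_equal(sum(pk$protein_id == "P2"), 2)
  expect_equal(sum(pk$protein_id == "P3"), 1)  # prominence rule merges
  # the minor bump of two Gaussians 1 fraction apart has near-zero
  # prominence: compute it explicitly
  x <- gauss_trace(n, 30, 2) + gauss_trace(n, 31, 2)
  x <- cofrac:::rescale01(x)
  apexes <- which(diff(sign(diff(x))) == -2) + 1
  proms <- vapply(apexes, function(a) cofrac:::peak_prominence(x, a), 0)
  expect_true(all(proms[-which.max(proms)] < 0.1))
})

test_that("peaks per protein equal planted assembly counts on noiseless data", {
  sim <- simulate_dataset(sim_config(
    n_complexes = 2, complex_size_range = c(3, 3), n_monomers = 4,
    noise_cv = 0, apex_jitter_sd = 0, perturbed_fraction = 0,
    monomer_peak_prob = 1, seed = 11
  ))
  prof <- process_profiles(sim$peptides)
  pk <- detect_peaks(prof, min_prominence = 0.1)
  counts <- table(pk$protein_id[pk$condition == "control"])
  truth <- sim$truth$proteins
  for (i in seq_len(nrow(truth))) {
    expected <- if (is.na(truth$complex_id[i])) 1 else 2  # complex + monomer
    # a complex whose apex lands within ~2 fractions of the member monomer
    # apex merges into one peak; require at least the complex peak then
    observed <- as.integer(counts[truth$protein_id[i]])
    expect_gte(observed, 1)
    expect_lte(observed, expected)
  }
})

test_that("replicate correlation is scale-invariant and matches pooled oracle", {
  n <- 24
  set.seed(3)
  traces <- list(P1 = gauss_trace(n, 8, 2), P2 = gauss_trace(n, 15, 3))
  p1 <- profiles_from_traces(traces, replicate = 1L)
  p2 <- profiles_from_traces(lapply(traces, function(x) 5 * x),
                             replicate = 2L)
  rc <- replicate_correlation(dplyr::bind_rows(p1, p2))
  expect_equal(rc$per_protein$r, rep(1, 2))
  expect_equal(rc$global_r2,
               cor(c(traces$P1, traces$P2), 5 * c(traces$P1, traces$P2))^2)

  # noisy simulator output against a brute-force pooled computation
  sim <- default_sim()
  raw <- infer_protein_profiles(sim$peptides)
  rc2 <- replicate_correlation(raw)
  a <- raw[raw$replicate == 1, ]; b <- raw[raw$replicate == 2, ]
  key <- function(d) paste(d$protein_id, d$condition)
  ord <- order(key(a)); a <- a[ord, ]
  b <- b[match(key(a), key(b)), ]
  pooled <- cor(unlist(a$intensity), unlist(b$intensity))^2
  expect_equal(rc2$global_r2, pooled, tolerance = 1e-12)
})
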