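test_that("candidate selection keeps exactly the pairs above the r2 cut", {
  n <- 72
  traces <- list(
    A = cofrac:::rescale01(gauss_trace(n, 30, 2)),
    B = cofrac:::rescale01(gauss_trace(n, 30, 2)),   # identical to A
    C = cofrac:::rescale01(gauss_trace(n, 60, 2))    # far away
  )
  prof <- profiles_from_traces(traces, processed = TRUE)
  cand <- candidate_pairs(prof)
  expect_true("A" %in% cand$protein_a & "B" %in% cand$protein_b)
  expect_equal(cand$r_squared[cand$protein_a == "A" & cand$protein_b == "B"],
               1, tolerance = 1e-12)
  # disjoint impulses are anti-correlated only through the flat baseline:
  # r2 far below 0.3, excluded
  imp1 <- rep(0, n); imp1[10] <- 1
  imp2 <- rep(0, n); imp2[50] <- 1
  expect_lt(cor(imp1, imp2)^2, 0.3)
  prof2 <- profiles_from_traces(list(X = imp1, Y = imp2), processed = TRUE)
  expect_equal(nrow(candidate_pairs(prof2)), 0)
  # threshold 0 keeps all C(n,2) pairs; higher thresholds nest
  all_pairs <- candidate_pairs(prof, threshold = 0)
  expect_equal(nrow(all_pairs), choose(3, 2))
  k <- function(d) paste(d$protein_a, d$protein_b)
  t03 <- candidate_pairs(prof, threshold = 0.3)
  t08 <- candidate_pairs(prof, threshold = 0.8)
  expect_true(all(k(t08) %in% k(t03)))
  expect_true(all(k(t03) %in% k(all_pairs)))
})

test_that("sliding-window correlation matches the brute-force windowed oracle", {
  set.seed(4)
  for (rep in 1:5) {
    x <- runif(72); y <- runif(72)
    expect_equal(sliding_window_correlation(x, y, 6),
                 brute_window_cor(x, y, 6), tolerance = 1e-10)
  }
  # odd window too
  x <- runif(30); y <- runif(30)
  expect_equal(sliding_window_correlation(x, y, 5),
               brute_window_cor(x, y, 5), tolerance = 1e-10)
  # identical traces give 1 wherever variance is positive
  g <- gauss_trace(72, 30, 3)
  swc <- sliding_window_correlation(g, g, 6)
  pos_var <- brute_window_cor(g, g, 6)
  expect_true(all(swc[pos_var != 0] == 1))
  # anti-correlated traces give -1 in windows whose variance is not
  # dominated by floating-point cancellation in the deep Gaussian tails
  y2 <- -g + 1
  swc2 <- sliding_window_correlation(g, y2, 6)
  well_posed <- vapply(seq_len(72), function(i) {
    lo <- max(1, i - 2); hi <- min(72, i + 3)
    stats::sd(g[lo:hi]) > 1e-6
  }, TRUE)
  expect_true(all(abs(swc2[well_posed] + 1) < 1e-10))
  expect_error(sliding_window_correlation(runif(5), runif(5), 6),
               "config error")
})

test_that("intensity difference is the elementwise L1 contribution", {
  x <- c(0, 0.5, 1, 0.5, 0); y <- c(0, 0, 1, 1, 0)
  expect_equal(intensity_difference(x, x), rep(0, 5))
  expect_equal(intensity_difference(rep(1, 5), rep(0, 5)), rep(1, 5))
  expect_equal(sum(intensity_difference(x, y)), sum(abs(x - y)))
})

test_that("pair scalars: identity, orthogonality, and constructed shift", {
  g <- cofrac:::rescale01(gauss_trace(72, 20, 2))
  sc <- pair_scalars(g, g)
  expect_equal(as.numeric(sc), c(0, 0, 0), tolerance = 1e-12)
  # orthogonal nonzero vectors
  a <- c(1, 0, 0, 0); b <- c(0, 1, 0, 0)
  expect_equal(unname(pair_scalars(a, b)["contrast_angle"]), pi / 2)
  # zero-norm input also maps to pi/2
  expect_equal(unname(pair_scalars(rep(0, 4), b)["contrast_angle"]), pi / 2)
  # Gaussians at apexes 20 and 30
  h <- cofrac:::rescale01(gauss_trace(72, 30, 2))
  sc2 <- pair_scalars(g, h)
  expect_equal(unname(sc2["peak_shift"]), 10)
  expect_equal(unname(sc2["euclidean"]), sqrt(sum((g - h)^2)),
               tolerance = 1e-12)
  expect_equal(unname(sc2["contrast_angle"]),
               acos(sum(g * h) / sqrt(sum(g^2) * sum(h^2))),
               tolerance = 1e-12)
})

test_that("featurize assembles the documented 147-value layout", {
  n <- 72
  g1 <- cofrac:::rescale01(gauss_trace(n, 25, 2))
  g2 <- cofrac:::rescale01(gauss_trace(n, 40, 3))
  prof <- profiles_from_traces(list(A = g1, B = g2), processed = TRUE)
  pairs <- tibble::tibble(protein_a = "A", protein_b = "B")
  fv <- featurize(pairs, prof)$features[[1]]
  expect_length(fv, 147)
  # compositional oracle: each block equals its standalone operation
  expect_equal(fv[1:72], sliding_window_correlation(g1, g2, 6))
  expect_equal(fv[73:144], intensity_difference(g1, g2))
  expect_equal(fv[145:147], as.numeric(pair_scalars(g1, g2)))
  # identical profiles: correlations in {0,1}, zero differences and scalars
  fv2 <- featurize(tibble::tibble(protein_a = "A", protein_b = "A2"),
                   profiles_from_traces(list(A = g1, A2 = g1),
                                        processed = TRUE))$features[[1]]
  expect_true(all(fv2[1:72] %in% c(0, 1)))
  expect_equal(fv2[73:147], rep(0, 75))
})

test_that("featurize is symmetric in the two proteins and sizes as 2F + 3", {
  set.seed(5)
  n <- 40
  x <- cofrac:::rescale01(gauss_trace(n, 10, 2) + 0.05 * runif(n))
  y <- cofrac:::rescale01(gauss_trace(n, 18, 3) + 0.05 * runif(n))
  prof <- profiles_from_traces(list(A = x, B = y), processed = TRUE)
  fab <- featurize(tibble::tibble(protein_a = "A", protein_b = "B"),
                   prof)$features[[1]]
  fba <- featurize(tibble::tibble(protein_a = "B", protein_b = "A"),
                   prof)$features[[1]]
  expect_equal(fab, fba, tolerance = 1e-12)
  expect_length(fab, 2 * n + 3)
  expect_error(featurize(tibble::tibble(protein_a = "A", protein_b = "ZZ"),
                         prof), "missing profile")
})
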