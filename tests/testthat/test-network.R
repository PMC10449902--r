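toy_edges <- function() {
  tibble::tibble(
    protein_a = c("h1", "h1", "h2", "p1"),
    protein_b = c("h2", "p1", "p2", "p2"),
    probability = c(0.9, 0.8, 0.85, 0.95),
    q_value = c(0, 0.01, 0.02, 0)
  )
}

toy_orgs <- c(h1 = "host", h2 = "host", p1 = "phage", p2 = "phage")

test_that("networks are simple and edge counts partition by type", {
  net <- build_network(toy_edges(), toy_orgs)
  expect_equal(nrow(net$degrees), 4)
  counts <- interaction_counts(net)
  expect_equal(sum(counts$n), nrow(net$edges))
  expect_equal(counts$n[counts$interaction_type == "host-host"], 1)
  expect_equal(counts$n[counts$interaction_type == "host-phage"], 2)
  expect_equal(counts$n[counts$interaction_type == "phage-phage"], 1)
  bad <- toy_edges(); bad$protein_b[1] <- "h1"
  expect_error(build_network(bad), "self-loops")
  dup <- rbind(toy_edges(), toy_edges()[1, ])
  expect_error(build_network(dup), "duplicate")
})

test_that("a frequency table proportional to k^-2 fits exactly", {
  # build an edge-free degree vector directly: frequencies 2^... not needed,
  # feed degrees to the fitter
  k <- 1:8
  freq <- round(10000 / k^2)
  deg <- rep(k, freq)
  fit <- degree_powerlaw_fit(deg)
  expect_equal(fit$exponent, 2, tolerance = 0.01)
  expect_gt(fit$fit_r2, 0.999)
  # star graph: two degree values, fit runs with a warning
  star <- tibble::tibble(protein_a = "hub", protein_b = paste0("n", 1:5),
                         probability = 0.9, q_value = 0)
  net <- build_network(star)
  expect_warning(fit2 <- degree_powerlaw_fit(net), "small support")
  expect_equal(fit2$n_degrees, 2)
  # complete graph: one degree value, error
  cg <- t(combn(paste0("v", 1:4), 2))
  cge <- tibble::tibble(protein_a = cg[, 1], protein_b = cg[, 2],
                        probability = 0.9, q_value = 0)
  expect_error(degree_powerlaw_fit(build_network(cge)), "degenerate")
})

test_that("a planted scale-free degree sequence recovers its exponent", {
  # configuration-model graph whose degree frequencies follow k^-gamma;
  # the log-log frequency regression must recover gamma within +-0.3
  set.seed(7)
  for (gamma in c(2.0, 2.5)) {
    k <- 1:30
    f <- round(3000 * k^-gamma)
    f <- f[f > 0]
    degs <- rep(seq_along(f), f)
    if (sum(degs) %% 2 == 1) degs[1] <- degs[1] + 1
    g <- igraph::sample_degseq(degs, method = "fast.heur.simple")
    fit <- degree_powerlaw_fit(igraph::degree(g))
    expect_lt(abs(fit$exponent - gamma), 0.3)
    expect_gt(fit$fit_r2, 0.9)
  }
})

test_that("genomic distances are start-to-start in kb with skips counted", {
  ann <- tibble::tibble(
    gene_id = c("g1", "g2", "g3"), start = c(1000L, 5000L, 120000L),
    end = c(1900L, 5900L, 121000L), strand = c("+", "-", "+"),
    genome_id = c("chr", "chr", "chr"), genome_length = NA_integer_
  )
  pairs <- tibble::tibble(protein_a = c("g1", "g1", "g2"),
                          protein_b = c("g2", "g3", "gX"))
  expect_warning(gd <- genomic_distance(pairs, ann), "skipped")
  expect_equal(gd$distances$distance_kb, c(4, 119))
  expect_equal(gd$n_skipped, 1)
  expect_equal(gd$summary$mean_kb, mean(c(4, 119)))
  expect_equal(gd$summary$max_kb, 119)
})

test_that("ROC sweep, AUC and Youden threshold match the hand example", {
  scores <- c(0.9, 0.8, 0.3, 0.2)
  labels <- c(TRUE, TRUE, FALSE, FALSE)
  roc <- roc_threshold(scores, labels)
  expect_equal(roc$auc, 1)
  expect_equal(roc$selected_threshold, 0.8)
  expect_equal(roc$selected_tpr, 1)
  expect_equal(roc$selected_fpr, 0)
  # inverted labels complement the AUC
  expect_equal(roc_threshold(scores, !labels)$auc, 0)
  expect_error(roc_threshold(scores, c(TRUE, TRUE, TRUE, TRUE)), "negative")
})

test_that("ROC AUC matches an independent implementation and is rank-invariant", {
  skip_if_not_installed("pROC")
  set.seed(29)
  scores <- rnorm(300)
  labels <- runif(300) < plogis(scores)
  roc <- roc_threshold(scores, labels)
  oracle <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                           direction = "<")))
  expect_equal(roc$auc, oracle, tolerance = 1e-10)
  # strictly monotone transform leaves the AUC unchanged
  roc2 <- roc_threshold(exp(3 * scores), labels)
  expect_equal(roc2$auc, roc$auc, tolerance = 1e-12)
  # random scores vs random labels sit near 0.5
  set.seed(31)
  rnd <- roc_threshold(runif(1000), runif(1000) < 0.5)
  expect_lt(abs(rnd$auc - 0.5), 0.05)
})

test_that("enrichment fold changes use the half-minimum pseudocount", {
  enriched <- c(100, 800, 50, 0, 1)
  reference <- c(100, 100, 0, 40, 1)
  lfc <- enrichment_log2fc(enriched, reference)
  expect_equal(lfc[1], 0)
  # 8x enrichment, pseudocount half the smallest nonzero value (0.5)
  expect_equal(lfc[2], 3, tolerance = 0.01)
  c0 <- min(c(enriched, reference)[c(enriched, reference) > 0]) / 2
  expect_equal(lfc[3], log2((50 + c0) / c0))
  expect_true(is.finite(lfc[3]) && lfc[3] > 0)
})

test_that("neighbourhood queries nest as the probability cut rises", {
  net <- build_network(toy_edges(), toy_orgs)
  star <- neighborhood_query(net, "h1", 0)
  expect_equal(nrow(star), 2)
  hi <- neighborhood_query(net, "h1", 0.85)
  lo <- neighborhood_query(net, "h1", 0.5)
  expect_true(all(paste(hi$protein_a, hi$protein_b) %in%
                    paste(lo$protein_a, lo$protein_b)))
  expect_warning(out <- neighborhood_query(net, "absent"), "not in network")
  expect_equal(nrow(out), 0)
})

test_that("virion ROC on simulated enrichment picks a sensible threshold", {
  sim <- default_sim()
  vir <- simulate_virion_intensities(sim$truth, seed = 41)
  lfc <- enrichment_log2fc(vir$enriched_intensity, vir$reference_intensity)
  roc <- roc_threshold(lfc, vir$is_virion)
  expect_gt(roc$auc, 0.8)
  expect_gt(roc$selected_tpr - roc$selected_fpr, 0.4)
})
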