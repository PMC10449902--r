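# Shared fixtures, built in code at test time.

# tiny noiseless simulation used by several suites (cached per session)
tiny_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_dataset(sim_config(
        n_complexes = 2, complex_size_range = c(3, 3), n_monomers = 5,
        noise_cv = 0, apex_jitter_sd = 0, perturbed_fraction = 0,
        monomer_peak_prob = 0, seed = 42
      ))
    }
    cache
  }
})

# default-config simulation shared across suites
default_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- simulate_dataset(sim_config(seed = 101))
    cache
  }
})

# a raw cf_profiles tibble built directly from traces (bypassing peptides)
profiles_from_traces <- function(traces, condition = "c1", replicate = NULL,
                                 processed = FALSE) {
  tbl <- tibble::tibble(
    protein_id = names(traces),
    condition = condition,
    n_peptides = 1L,
    peptides = lapply(names(traces), identity),
    intensity = unname(traces)
  )
  if (!is.null(replicate)) tbl$replicate <- replicate
  tbl <- tbl[, intersect(c("protein_id", "condition", "replicate",
                           "n_peptides", "peptides", "intensity"),
                         names(tbl))]
  cofrac:::new_profiles(tbl, length(traces[[1]]), processed)
}

gauss_trace <- function(n, apex, sigma = 2) {
  exp(-0.5 * ((seq_len(n) - apex) / sigma)^2)
}

# brute-force windowed Pearson correlation oracle (independent of the
# cumulative-sum implementation)
brute_window_cor <- function(x, y, q) {
  n <- length(x)
  vapply(seq_len(n), function(i) {
    lo <- max(1, i - floor((q - 1) / 2))
    hi <- min(n, i + ceiling((q - 1) / 2))
    xs <- x[lo:hi]; ys <- y[lo:hi]
    if (stats::sd(xs) == 0 || stats::sd(ys) == 0) 0 else stats::cor(xs, ys)
  }, 0)
}

# brute-force target-decoy q-values oracle
brute_qvalues <- function(targets, decoys) {
  vapply(targets, function(s) {
    ts <- sort(unique(targets[targets <= s]), decreasing = TRUE)
    min(vapply(ts, function(t)
      sum(decoys >= t) / max(1, sum(targets >= t)), 0))
  }, 0)
}
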