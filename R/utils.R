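# Internal helpers shared across the pipeline.

# Canonical unordered pair key: lexicographically smaller id first.
pair_key <- function(a, b) {
  swap <- a > b
  tmp <- a[swap]
  a[swap] <- b[swap]
  b[swap] <- tmp
  paste(a, b, sep = "\r")
}

order_pair <- function(a, b) {
  swap <- a > b
  tmp <- a[swap]
  a[swap] <- b[swap]
  b[swap] <- tmp
  list(a = a, b = b)
}

# Pearson correlation that returns 0 when either vector has zero variance
# (no evidence of co-movement, rather than NA).
safe_cor <- function(x, y) {
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(0)
  stats::cor(x, y)
}

n_fractions_of <- function(profiles) {
  nf <- attr(profiles, "n_fractions")
  if (is.null(nf)) nf <- length(profiles$intensity[[1]])
  nf
}

# Wide intensity matrix (proteins x fractions) for one condition.
profile_matrix <- function(profiles, condition = NULL) {
  if (!is.null(condition)) {
    profiles <- profiles[profiles$condition == condition, , drop = FALSE]
  }
  m <- do.call(rbind, profiles$intensity)
  rownames(m) <- profiles$protein_id
  m
}

new_profiles <- function(tbl, n_fractions, processed) {
  tbl <- tibble::as_tibble(tbl)
  attr(tbl, "n_fractions") <- n_fractions
  attr(tbl, "processed") <- processed
  class(tbl) <- c("cf_profiles", class(tbl))
  tbl
}

is_processed <- function(profiles) isTRUE(attr(profiles, "processed"))

`%||%` <- function(x, y) if (is.null(x)) y else x
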