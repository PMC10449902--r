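#' Select candidate protein pairs by profile correlation
#'
#' All unordered protein pairs within one condition whose squared Pearson
#' correlation of processed elution profiles reaches the threshold are
#' retained as putative interactors; everything below is never scored.
#'
#' @param profiles Processed per-condition `cf_profiles` tibble.
#' @param condition Condition to pair within (default: the only condition
#'   present; required when there are several).
#' @param threshold Minimum r-squared (default 0.3).
#' @return Tibble of candidate pairs: `protein_a`, `protein_b` (sorted so
#'   `protein_a < protein_b`), `condition`, `r_squared`.
#' @export
candidate_pairs <- function(profiles, condition = NULL, threshold = 0.3) {
  if (is.null(condition)) {
    conds <- unique(profiles$condition)
    if (length(conds) != 1) {
      stop("profiles contain several conditions; pick one", call. = FALSE)
    }
    condition <- conds
  }
  m <- profile_matrix(profiles, condition)
  if (nrow(m) < 2) {
    return(tibble::tibble(protein_a = character(), protein_b = character(),
                          condition = character(), r_squared = double()))
  }
  sds <- apply(m, 1, stats::sd)
  cm <- suppressWarnings(stats::cor(t(m)))
  cm[sds == 0, ] <- 0  # zero-variance traces carry no co-movement evidence
  cm[, sds == 0] <- 0
  r2 <- cm^2
  idx <- which(upper.tri(r2) & r2 >= threshold, arr.ind = TRUE)
  ids <- rownames(m)
  ord <- order_pair(ids[idx[, 1]], ids[idx[, 2]])
  out <- tibble::tibble(protein_a = ord$a, protein_b = ord$b,
                        condition = condition,
                        r_squared = r2[idx])
  out[order(out$protein_a, out$protein_b), ]
}

#' Sliding-window correlation of two elution profiles
#'
#' For each fraction i, the Pearson correlation of the two traces over a
#' window of width `q` centred at i (indices i - floor((q-1)/2) ...
#' i + ceiling((q-1)/2)), truncated at the profile edges. Windows in which
#' either trace has zero variance contribute 0.
#'
#' @param x,y Numeric traces of equal length.
#' @param q Window width in fractions (default 6).
#' @return Numeric vector of per-fraction correlations, same length as `x`.
#' @export
sliding_window_correlation <- function(x, y, q = 6L) {
  n <- length(x)
  stopifnot(length(y) == n)
  if (q > n) stop("config error: window q exceeds profile length", call. = FALSE)
  lo <- pmax(1L, seq_len(n) - floor((q - 1) / 2))
  hi <- pmin(n, seq_len(n) + ceiling((q - 1) / 2))
  r <- numeric(n)
  for (i in seq_len(n)) {
    xs <- x[lo[i]:hi[i]]
    ys <- y[lo[i]:hi[i]]
    dx <- xs - sum(xs) / length(xs)
    dy <- ys - sum(ys) / length(ys)
    vx <- sum(dx * dx)
    vy <- sum(dy * dy)
    # centred two-pass sums keep tiny but genuine window variances exact;
    # only truly constant windows carry no co-movement evidence, and an
    # identical window pair is exactly 1 by definition
    r[i] <- if (vx == 0 || vy == 0) 0 else if (all(xs == ys)) 1 else
      sum(dx * dy) / sqrt(vx) / sqrt(vy)  # sequential roots avoid underflow
  }
  pmin(1, pmax(-1, r))
}

#' Per-fraction intensity difference of two processed profiles
#'
#' @param x,y Numeric \[0, 1\] traces of equal length.
#' @return `abs(x - y)`, one value per fraction.
#' @export
intensity_difference <- function(x, y) {
  stopifnot(length(x) == length(y))
  abs(x - y)
}

#' Scalar co-elution descriptors of a profile pair
#'
#' Three global descriptors: the absolute apex shift between the primary
#' (highest-prominence) peaks, the Euclidean distance between the traces,
#' and the contrast angle `acos(<x,y> / (|x| |y|))` in radians (0 for
#' identical directions, pi/2 for orthogonal or zero-norm input).
#'
#' @param x,y Processed traces of equal length.
#' @param min_prominence,min_width Peak-detection settings for the apex
#'   shift (see [detect_peaks()]).
#' @return Named numeric vector `peak_shift`, `euclidean`, `contrast_angle`;
#'   the `no_peak` attribute flags pairs where either trace had no
#'   qualifying peak (shift reported as 0).
#' @export
pair_scalars <- function(x, y, min_prominence = 0.1, min_width = 2) {
  stopifnot(length(x) == length(y))
  # primary = highest prominence, ties towards the earlier fraction
  ax <- primary_apex_of(x, min_prominence, min_width)
  ay <- primary_apex_of(y, min_prominence, min_width)
  no_peak <- is.na(ax) || is.na(ay)
  shift <- if (no_peak) 0 else abs(ax - ay)
  euclid <- sqrt(sum((x - y)^2))
  nx <- sqrt(sum(x^2)); ny <- sqrt(sum(y^2))
  angle <- if (nx == 0 || ny == 0) pi / 2 else
    acos(pmin(1, pmax(-1, sum(x * y) / (nx * ny))))
  out <- c(peak_shift = shift, euclidean = euclid, contrast_angle = angle)
  attr(out, "no_peak") <- no_peak
  out
}

primary_apex_of <- function(v, min_prominence = 0.1, min_width = 2) {
  pk <- detect_peaks_trace(v, min_prominence, min_width)
  if (is.null(pk) || nrow(pk) == 0) return(NA_real_)
  pk$apex_fraction[order(-pk$prominence, pk$apex_fraction)][1]
}

featurize_pair <- function(x, y, q = 6L, min_prominence = 0.1, min_width = 2,
                           apex_x = NULL, apex_y = NULL) {
  if (is.null(apex_x)) apex_x <- primary_apex_of(x, min_prominence, min_width)
  if (is.null(apex_y)) apex_y <- primary_apex_of(y, min_prominence, min_width)
  shift <- if (is.na(apex_x) || is.na(apex_y)) 0 else abs(apex_x - apex_y)
  nx <- sqrt(sum(x^2)); ny <- sqrt(sum(y^2))
  angle <- if (nx == 0 || ny == 0) pi / 2 else
    acos(pmin(1, pmax(-1, sum(x * y) / (nx * ny))))
  c(sliding_window_correlation(x, y, q),
    abs(x - y),
    shift, sqrt(sum((x - y)^2)), angle)
}

#' Assemble the co-elution feature vector for candidate pairs
#'
#' Concatenates the five co-elution feature families into one descriptor
#' per pair: per-fraction sliding-window (q = 6) correlation (F values),
#' per-fraction intensity difference (F values), then the peak shift,
#' Euclidean distance and contrast angle scalars. With the standard F = 72
#' fractions this is the 147-value layout (72 + 72 + 3) the classifier's
#' input layer expects; for other F the vector is 2F + 3 and the classifier
#' input resizes accordingly.
#'
#' @param pairs Tibble with `protein_a`, `protein_b` and (if `profiles`
#'   spans several conditions) `condition` columns, e.g. from
#'   [candidate_pairs()].
#' @param profiles Processed per-condition `cf_profiles` tibble.
#' @param q Sliding-window width (default 6).
#' @param min_prominence,min_width Peak-detection settings for the
#'   peak-shift scalar.
#' @return The `pairs` tibble with a `features` list-column of numeric
#'   vectors of length `2 * F + 3`. Use [feature_matrix()] to stack them.
#' @export
featurize <- function(pairs, profiles, q = 6L, min_prominence = 0.1,
                      min_width = 2) {
  if (!is_processed(profiles)) {
    stop("featurize expects processed profiles", call. = FALSE)
  }
  conds <- unique(profiles$condition)
  if (!"condition" %in% names(pairs)) {
    if (length(conds) != 1) {
      stop("pairs need a condition column when profiles span several ",
           "conditions", call. = FALSE)
    }
    pairs$condition <- conds
  }
  key <- paste(profiles$protein_id, profiles$condition, sep = "\r")
  ia <- match(paste(pairs$protein_a, pairs$condition, sep = "\r"), key)
  ib <- match(paste(pairs$protein_b, pairs$condition, sep = "\r"), key)
  if (anyNA(ia) || anyNA(ib)) {
    miss <- unique(c(pairs$protein_a[is.na(ia)], pairs$protein_b[is.na(ib)]))
    stop("missing profile for: ", paste(utils::head(miss, 3), collapse = ", "),
         call. = FALSE)
  }
  # the primary apex of each profile is pair-independent: detect once
  need <- sort(unique(c(ia, ib)))
  apex_cache <- rep(NA_real_, nrow(profiles))
  apex_cache[need] <- vapply(need, function(i)
    primary_apex_of(profiles$intensity[[i]], min_prominence, min_width), 0)
  pairs$features <- lapply(seq_len(nrow(pairs)), function(i) {
    featurize_pair(profiles$intensity[[ia[i]]], profiles$intensity[[ib[i]]],
                   q = q, min_prominence = min_prominence,
                   min_width = min_width,
                   apex_x = apex_cache[ia[i]], apex_y = apex_cache[ib[i]])
  })
  pairs
}

#' Stack a `features` list-column into a matrix
#'
#' @param pairs Tibble with a `features` list-column (see [featurize()]).
#' @return Numeric matrix, one row per pair.
#' @export
feature_matrix <- function(pairs) {
  do.call(rbind, pairs$features)
}
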