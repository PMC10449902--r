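#' Infer protein elution profiles from peptide records
#'
#' Implements the sibling-peptide correlation strategy: for a protein with
#' one peptide the trace is used as is; with two, their mean; with three or
#' more, the unordered peptide pair with the highest Pearson correlation —
#' computed on traces concatenated across *all* conditions and replicates,
#' so the same two peptides represent the protein everywhere — is averaged.
#' Undetected (peptide, fraction) cells count as intensity 0.
#'
#' @param records Peptide record tibble (see [read_peptide_table()]).
#' @param n_fractions Total fraction count; defaults to the table's
#'   `n_fractions` attribute or the maximum observed index.
#' @return A `cf_profiles` tibble with one row per protein, condition and
#'   replicate: columns `protein_id`, `condition`, `replicate`,
#'   `n_peptides`, `peptides` (list of the selected peptide sequences, at
#'   most two) and `intensity` (list of numeric traces of length
#'   `n_fractions`). Proteins whose total intensity is zero are dropped
#'   with a warning.
#' @export
infer_protein_profiles <- function(records, n_fractions = NULL) {
  nf <- n_fractions %||% attr(records, "n_fractions") %||% max(records$fraction)
  conds <- sort(unique(records$condition))
  reps <- sort(unique(records$replicate))
  n_cells <- length(conds) * length(reps)

  out <- vector("list", 0L)
  dropped <- character(0)
  for (pid in sort(unique(records$protein_id))) {
    rec <- records[records$protein_id == pid, , drop = FALSE]
    peps <- sort(unique(rec$peptide))
    # dense trace per peptide x condition x replicate
    traces <- array(0, dim = c(length(peps), length(conds), length(reps), nf),
                    dimnames = list(peps, conds, NULL, NULL))
    idx <- cbind(match(rec$peptide, peps), match(rec$condition, conds),
                 match(rec$replicate, reps), rec$fraction)
    traces[idx] <- rec$intensity
    if (sum(traces) == 0) {
      dropped <- c(dropped, pid)
      next
    }
    # select peptides on traces concatenated across all samples
    flat <- matrix(aperm(traces, c(2, 3, 4, 1)), ncol = length(peps))
    colnames(flat) <- peps
    if (length(peps) <= 2) {
      selected <- peps
    } else {
      best <- c(NA_character_, NA_character_)
      best_r <- -Inf
      for (i in seq_len(length(peps) - 1)) {
        for (j in seq(i + 1, length(peps))) {
          r <- safe_cor(flat[, i], flat[, j])
          if (r > best_r) {  # ties keep the lexicographically first pair
            best_r <- r
            best <- c(peps[i], peps[j])
          }
        }
      }
      selected <- best
    }
    sel_idx <- match(selected, peps)
    for (ci in seq_along(conds)) {
      for (ri in seq_along(reps)) {
        tr <- traces[sel_idx, ci, ri, , drop = FALSE]
        prof <- colMeans(matrix(tr, nrow = length(sel_idx)))
        out[[length(out) + 1L]] <- tibble::tibble(
          protein_id = pid, condition = conds[ci], replicate = reps[ri],
          n_peptides = length(peps), peptides = list(selected),
          intensity = list(prof)
        )
      }
    }
  }
  if (length(dropped) > 0) {
    warning("dropped ", length(dropped),
            " protein(s) with zero total intensity: ",
            paste(utils::head(dropped, 5), collapse = ", "), call. = FALSE)
  }
  new_profiles(dplyr::bind_rows(out), nf, processed = FALSE)
}

# Savitzky-Golay smoothing of one trace, negatives clipped, then min-max
# rescaling into [0, 1]; all-zero traces stay all-zero.
process_trace <- function(x, sg_window, sg_order) {
  if (all(x == 0)) return(x)
  sm <- as.numeric(signal::sgolayfilt(x, p = sg_order, n = sg_window))
  sm[sm < 0] <- 0
  rescale01(sm)
}

rescale01 <- function(x) {
  rng <- range(x)
  if (rng[2] == rng[1]) return(rep(0, length(x)))
  (x - rng[1]) / (rng[2] - rng[1])
}

#' Smooth and rescale elution profiles
#'
#' Savitzky-Golay smoothing followed by 0-1 min-max rescaling of every
#' trace. Negative filter output is clipped to zero before rescaling;
#' all-zero traces map to all-zero. The default window of 5 and polynomial
#' order 2 is the smallest quadratic-preserving filter, which avoids
#' distorting peak shapes at 72-fraction resolution.
#'
#' @param profiles A `cf_profiles` tibble (raw or already processed;
#'   rescaling is idempotent).
#' @param sg_window Odd filter window length in fractions (default 5).
#' @param sg_order Polynomial order (default 2, must be < `sg_window`).
#' @return The profiles with each trace replaced by its processed version
#'   and the `processed` attribute set.
#' @export
smooth_and_rescale <- function(profiles, sg_window = 5L, sg_order = 2L) {
  nf <- n_fractions_of(profiles)
  if (sg_window > nf) {
    stop("config error: sg_window (", sg_window, ") exceeds the number of ",
         "fractions (", nf, ")", call. = FALSE)
  }
  if (sg_order >= sg_window) {
    stop("config error: sg_order must be smaller than sg_window", call. = FALSE)
  }
  profiles$intensity <- lapply(profiles$intensity, process_trace,
                               sg_window = sg_window, sg_order = sg_order)
  attr(profiles, "processed") <- TRUE
  profiles
}

#' Average replicate profiles into one profile per condition
#'
#' Arithmetic mean of the replicate traces for each protein and condition,
#' rescaled back to \[0, 1\] when the inputs were processed. Smoothing per
#' replicate followed by averaging (rather than averaging first) keeps
#' replicate-specific peak positions visible to the mean.
#'
#' @param profiles A `cf_profiles` tibble with a `replicate` column.
#' @return `cf_profiles` tibble with one row per protein and condition
#'   (`replicate` column dropped).
#' @export
average_replicates <- function(profiles) {
  nf <- n_fractions_of(profiles)
  proc <- is_processed(profiles)
  grp <- dplyr::group_by(profiles, .data$protein_id, .data$condition)
  out <- dplyr::summarise(
    grp,
    n_peptides = .data$n_peptides[1],
    peptides = list(.data$peptides[[1]]),
    intensity = {
      m <- colMeans(do.call(rbind, .data$intensity))
      list(if (proc) rescale01(m) else m)
    },
    .groups = "drop"
  )
  new_profiles(out, nf, processed = proc)
}

#' Build processed per-condition profiles from peptide records
#'
#' Convenience wrapper chaining [infer_protein_profiles()],
#' [smooth_and_rescale()] (per replicate) and [average_replicates()].
#'
#' @inheritParams infer_protein_profiles
#' @inheritParams smooth_and_rescale
#' @return Processed `cf_profiles` tibble, one row per protein and condition.
#' @export
process_profiles <- function(records, n_fractions = NULL, sg_window = 5L,
                             sg_order = 2L) {
  records |>
    infer_protein_profiles(n_fractions = n_fractions) |>
    smooth_and_rescale(sg_window = sg_window, sg_order = sg_order) |>
    average_replicates()
}

# Peak prominence: height above the higher of the two base levels, where
# each base is the minimum between the peak and the nearest higher point
# (or the trace end) on that side.
peak_prominence <- function(x, apex) {
  h <- x[apex]
  left <- if (apex > 1) {
    higher <- which(x[seq_len(apex - 1)] > h)
    lo <- if (length(higher) > 0) max(higher) + 1L else 1L
    min(x[lo:apex])
  } else h
  right <- if (apex < length(x)) {
    higher <- which(x[seq(apex + 1, length(x))] > h) + apex
    hi <- if (length(higher) > 0) min(higher) - 1L else length(x)
    min(x[apex:hi])
  } else h
  h - max(left, right)
}

# width (in fractions) at half prominence, linearly interpolated
peak_width <- function(x, apex, prominence) {
  level <- x[apex] - prominence / 2
  l <- apex
  while (l > 1 && x[l - 1] >= level) l <- l - 1
  left <- if (l == 1 || x[l] == level) as.numeric(l) else
    l - (x[l] - level) / (x[l] - x[l - 1])
  r <- apex
  n <- length(x)
  while (r < n && x[r + 1] >= level) r <- r + 1
  right <- if (r == n || x[r] == level) as.numeric(r) else
    r + (x[r] - level) / (x[r] - x[r + 1])
  c(left = left, right = right, width = right - left)
}

detect_peaks_trace <- function(x, min_prominence, min_width) {
  n <- length(x)
  if (n < 3) return(NULL)
  # local maxima; plateaus contribute their (rounded-down) centre
  apexes <- integer(0)
  i <- 2L
  while (i <= n - 1L) {
    if (x[i] > x[i - 1]) {
      j <- i
      while (j < n && x[j + 1] == x[j]) j <- j + 1L
      if (j == n || x[j + 1] < x[j]) apexes <- c(apexes, (i + j) %/% 2L)
      i <- j + 1L
    } else i <- i + 1L
  }
  if (length(apexes) == 0) return(NULL)
  rows <- lapply(apexes, function(a) {
    prom <- peak_prominence(x, a)
    if (prom < min_prominence) return(NULL)
    w <- peak_width(x, a, prom)
    if (w[["width"]] < min_width) return(NULL)
    tibble::tibble(apex_fraction = a, prominence = prom,
                   left = w[["left"]], right = w[["right"]],
                   width = w[["width"]])
  })
  dplyr::bind_rows(rows)
}

#' Detect elution peaks in processed profiles
#'
#' Local maxima on the \[0, 1\] profile with a prominence and a
#' half-prominence width filter. The number of SEC peaks per protein is a
#' direct proxy for how many distinct assemblies the protein participates
#' in.
#'
#' @param profiles Processed `cf_profiles` tibble.
#' @param min_prominence Minimum topographic prominence on the \[0, 1\]
#'   scale (default 0.1).
#' @param min_width Minimum width at half prominence, in fractions
#'   (default 2).
#' @return Tibble with one row per peak: `protein_id`, `condition`
#'   (and `replicate` if present), `apex_fraction`, `prominence`, `left`,
#'   `right`, `width`, sorted by apex within each profile. Profiles with no
#'   qualifying peak contribute no rows.
#' @export
detect_peaks <- function(profiles, min_prominence = 0.1, min_width = 2) {
  if (!is_processed(profiles)) {
    stop("detect_peaks expects processed profiles; run smooth_and_rescale()",
         call. = FALSE)
  }
  keys <- profiles[intersect(c("protein_id", "condition", "replicate"),
                             names(profiles))]
  rows <- lapply(seq_len(nrow(profiles)), function(i) {
    pk <- detect_peaks_trace(profiles$intensity[[i]], min_prominence, min_width)
    if (is.null(pk) || nrow(pk) == 0) return(NULL)
    dplyr::bind_cols(keys[rep(i, nrow(pk)), , drop = FALSE], pk)
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    out <- dplyr::bind_cols(keys[0, , drop = FALSE],
                            tibble::tibble(apex_fraction = integer(),
                                           prominence = double(),
                                           left = double(), right = double(),
                                           width = double()))
  }
  out
}

#' Between-replicate reproducibility of protein profiles
#'
#' Pearson correlation per protein between two replicates (raw traces,
#' concatenated across conditions unless one is selected) plus the global
#' r-squared of all paired intensities pooled.
#'
#' @param profiles Raw `cf_profiles` tibble with a `replicate` column.
#' @param replicates Length-2 vector naming the two replicates to compare
#'   (default: the two smallest present).
#' @param condition Optional single condition to restrict to.
#' @return List with `per_protein` (tibble `protein_id`, `r`), `global_r2`
#'   (pooled), and `n_excluded` (proteins present in only one replicate).
#' @export
replicate_correlation <- function(profiles, replicates = NULL,
                                  condition = NULL) {
  if (!is.null(condition)) {
    profiles <- profiles[profiles$condition %in% condition, , drop = FALSE]
  }
  reps <- replicates %||% utils::head(sort(unique(profiles$replicate)), 2)
  if (length(reps) != 2) stop("need exactly two replicates", call. = FALSE)
  a <- profiles[profiles$replicate == reps[1], , drop = FALSE]
  b <- profiles[profiles$replicate == reps[2], , drop = FALSE]
  shared <- intersect(a$protein_id, b$protein_id)
  n_excluded <- length(union(a$protein_id, b$protein_id)) - length(shared)
  per <- lapply(shared, function(pid) {
    xa <- unlist(a$intensity[a$protein_id == pid], use.names = FALSE)
    xb <- unlist(b$intensity[b$protein_id == pid], use.names = FALSE)
    tibble::tibble(protein_id = pid, r = safe_cor(xa, xb),
                   x = list(xa), y = list(xb))
  })
  per <- dplyr::bind_rows(per)
  pooled_x <- unlist(per$x, use.names = FALSE)
  pooled_y <- unlist(per$y, use.names = FALSE)
  global_r2 <- safe_cor(pooled_x, pooled_y)^2
  list(per_protein = per[c("protein_id", "r")], global_r2 = global_r2,
       n_excluded = n_excluded)
}
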