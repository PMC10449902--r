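#' Build an interactome graph from retained interactions
#'
#' Simple undirected graph (self-loops and duplicate edges rejected) with
#' organism tags on nodes and probability/q-value on edges.
#'
#' @param edges Tibble with `protein_a`, `protein_b`, `probability`,
#'   `q_value` (e.g. from [filter_interactions()]).
#' @param organisms Optional named vector protein id -> `"host"`/`"phage"`.
#' @return A `cf_network`: list with the `igraph` graph, the edge tibble
#'   (typed), and a per-node degree tibble.
#' @export
build_network <- function(edges, organisms = NULL) {
  if (any(edges$protein_a == edges$protein_b)) {
    stop("self-loops are not allowed", call. = FALSE)
  }
  keys <- pair_key(edges$protein_a, edges$protein_b)
  if (anyDuplicated(keys)) {
    stop("duplicate edges are not allowed", call. = FALSE)
  }
  nodes <- sort(unique(c(edges$protein_a, edges$protein_b)))
  g <- igraph::graph_from_data_frame(
    edges[c("protein_a", "protein_b", "probability", "q_value")],
    directed = FALSE,
    vertices = data.frame(name = nodes)
  )
  if (!is.null(organisms)) {
    igraph::V(g)$organism <- unname(organisms[nodes])
    oa <- organisms[edges$protein_a]
    ob <- organisms[edges$protein_b]
    edges$interaction_type <- dplyr::case_when(
      oa == "host" & ob == "host" ~ "host-host",
      oa == "phage" & ob == "phage" ~ "phage-phage",
      TRUE ~ "host-phage"
    )
  }
  deg <- igraph::degree(g)
  structure(list(
    graph = g,
    edges = tibble::as_tibble(edges),
    degrees = tibble::tibble(protein_id = names(deg), degree = unname(deg))
  ), class = "cf_network")
}

#' @export
print.cf_network <- function(x, ...) {
  cat("Interaction network:", nrow(x$degrees), "proteins,",
      nrow(x$edges), "interactions\n")
  if ("interaction_type" %in% names(x$edges)) {
    print(table(x$edges$interaction_type))
  }
  invisible(x)
}

#' Count interactions by type
#'
#' @param network A `cf_network` built with organism annotations.
#' @return Tibble `interaction_type`, `n`; the counts partition the edge
#'   set exactly.
#' @export
interaction_counts <- function(network) {
  if (!"interaction_type" %in% names(network$edges)) {
    stop("network was built without organism annotations", call. = FALSE)
  }
  dplyr::count(network$edges, .data$interaction_type, name = "n")
}

#' Power-law fit of the degree distribution
#'
#' Least-squares line of log10(frequency) on log10(degree) over observed
#' degrees - the log-log regression commonly drawn through degree
#' histograms of scale-free networks. (A maximum-likelihood power-law fit
#' is statistically preferable but is not what this summary reports.)
#'
#' @param network A `cf_network`, or a numeric degree vector.
#' @return List: `exponent` (the negated slope), `fit_r2`, `n_degrees`
#'   (distinct degree values; a warning is raised below 3).
#' @export
degree_powerlaw_fit <- function(network) {
  deg <- if (inherits(network, "cf_network")) network$degrees$degree else network
  deg <- deg[deg > 0]
  tab <- table(deg)
  k <- as.numeric(names(tab))
  freq <- as.numeric(tab)
  if (length(k) < 2) {
    stop("degenerate degree distribution: fewer than 2 distinct degrees",
         call. = FALSE)
  }
  if (length(k) < 3) {
    warning("only ", length(k), " distinct degrees: power-law fit has very ",
            "small support", call. = FALSE)
  }
  fit <- stats::lm(log10(freq) ~ log10(k))
  r2 <- if (length(k) == 2) 1 else summary(fit)$r.squared
  list(exponent = -unname(stats::coef(fit)[2]), fit_r2 = r2,
       n_degrees = length(k))
}

#' Genomic distances of interacting gene pairs
#'
#' Start-to-start distance in kb on a linear genome for each interaction
#' whose two genes are annotated on the same genome; other pairs are
#' skipped and counted.
#'
#' @param pairs Tibble with `protein_a`, `protein_b` (gene ids must match
#'   the annotation's `gene_id`).
#' @param annotation Tibble from [read_annotation()].
#' @return List: `distances` (tibble `protein_a`, `protein_b`,
#'   `distance_kb`), `summary` (n, mean, median, max kb), `n_skipped`.
#' @export
genomic_distance <- function(pairs, annotation) {
  ia <- match(pairs$protein_a, annotation$gene_id)
  ib <- match(pairs$protein_b, annotation$gene_id)
  same_genome <- !is.na(ia) & !is.na(ib) &
    (is.na(annotation$genome_id[ia]) | is.na(annotation$genome_id[ib]) |
       annotation$genome_id[ia] == annotation$genome_id[ib])
  n_skipped <- sum(!same_genome)
  if (n_skipped > 0) {
    warning(n_skipped, " pair(s) skipped (unannotated or cross-genome)",
            call. = FALSE)
  }
  d <- abs(annotation$start[ia[same_genome]] -
             annotation$start[ib[same_genome]]) / 1000
  distances <- tibble::tibble(protein_a = pairs$protein_a[same_genome],
                              protein_b = pairs$protein_b[same_genome],
                              distance_kb = d)
  list(
    distances = distances,
    summary = tibble::tibble(n = length(d), mean_kb = mean(d),
                             median_kb = stats::median(d),
                             max_kb = if (length(d)) max(d) else NA_real_),
    n_skipped = n_skipped
  )
}

#' ROC sweep and threshold selection
#'
#' Full ROC curve of a per-protein score against a known-positive label
#' set, swept over every observed score value; AUC by the trapezoid rule.
#' The operating threshold maximizes Youden's J = TPR - FPR (maximum
#' sensitivity at the lowest false-positive rate), ties resolved towards
#' the higher (stricter) threshold.
#'
#' @param scores Numeric score per item (e.g. virion MS intensity).
#' @param labels Logical/0-1 vector: known positives.
#' @return A `cf_roc` list: `curve` (tibble `threshold`, `tpr`, `fpr`),
#'   `auc`, `selected_threshold`, and the TPR/FPR at the selection.
#' @export
roc_threshold <- function(scores, labels) {
  labels <- as.logical(labels)
  if (!any(labels) || all(labels)) {
    stop("need at least one positive and one negative label", call. = FALSE)
  }
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  tpr <- vapply(thr, function(t) sum(scores >= t & labels) / n_pos, 0)
  fpr <- vapply(thr, function(t) sum(scores >= t & !labels) / n_neg, 0)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  j <- tpr - fpr
  best <- which(j == max(j))[1]  # thresholds descend, so the first tie wins
  out <- list(
    curve = tibble::tibble(threshold = thr, tpr = tpr, fpr = fpr),
    auc = auc,
    selected_threshold = thr[best],
    selected_tpr = tpr[best],
    selected_fpr = fpr[best]
  )
  class(out) <- "cf_roc"
  out
}

#' @export
print.cf_roc <- function(x, ...) {
  cat(sprintf("ROC: AUC = %.3f; threshold %.4g (TPR %.3f, FPR %.3f)\n",
              x$auc, x$selected_threshold, x$selected_tpr, x$selected_fpr))
  invisible(x)
}

#' Enrichment log2 fold change with a pseudocount
#'
#' `log2((enriched + c) / (reference + c))` with `c` equal to half the
#' smallest nonzero intensity across both samples, so proteins absent from
#' one sample get large but finite fold changes.
#'
#' @param enriched,reference Non-negative intensity vectors over a shared
#'   protein universe.
#' @return Numeric log2 fold change per protein.
#' @export
enrichment_log2fc <- function(enriched, reference) {
  stopifnot(length(enriched) == length(reference))
  pool <- c(enriched, reference)
  nz <- pool[pool > 0]
  if (length(nz) == 0) return(rep(0, length(enriched)))
  c0 <- min(nz) / 2
  log2((enriched + c0) / (reference + c0))
}

#' Direct neighbourhood of a protein in the network
#'
#' The induced star of edges touching the query protein with probability
#' at or above the cut; lowering the cut (e.g. 0.5 instead of 0.75)
#' surfaces positive but lower-confidence interactors.
#'
#' @param network A `cf_network`.
#' @param protein_id Query protein.
#' @param min_probability Probability cut (default 0).
#' @return Tibble of the retained edges (possibly empty; an unknown
#'   protein warns and returns an empty result).
#' @export
neighborhood_query <- function(network, protein_id, min_probability = 0) {
  ed <- network$edges
  if (!protein_id %in% c(ed$protein_a, ed$protein_b)) {
    warning("protein '", protein_id, "' not in network", call. = FALSE)
    return(ed[0, , drop = FALSE])
  }
  hit <- (ed$protein_a == protein_id | ed$protein_b == protein_id) &
    ed$probability >= min_probability
  ed[hit, , drop = FALSE]
}
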