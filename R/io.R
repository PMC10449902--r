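#' Read a peptide-level quantification table
#'
#' Reads the long-format peptide report produced by DIA quantification
#' software (one row per protein, peptide, condition, replicate and SEC
#' fraction) and validates it against the schema the pipeline expects.
#' Undetected (protein, fraction) cells are implicitly zero: DIA reports
#' omit precursors that were not detected, and the downstream correlation
#' machinery needs dense traces, so missing cells are filled with 0 at
#' profile-building time rather than stored.
#'
#' @param path Path to a tab- or comma-separated file with a header row.
#'   The delimiter is inferred from the file extension (".csv" means comma,
#'   anything else tab).
#' @param schema Optional named character vector mapping the required column
#'   names (`protein_id`, `peptide`, `condition`, `replicate`, `fraction`,
#'   `intensity`) to the names used in the file, e.g.
#'   `c(protein_id = "Protein.Group")`. Columns not mentioned are assumed to
#'   already carry the canonical name.
#' @return A tibble of validated peptide records with the canonical columns,
#'   plus an `n_fractions` attribute holding the inferred fraction count
#'   (the maximum fraction index seen).
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' df <- data.frame(protein_id = "P1", peptide = "AAK", condition = "ctrl",
#'                  replicate = 1L, fraction = 1:6, intensity = c(0, 1, 4, 1, 0, 0))
#' write.table(df, tf, sep = "\t", row.names = FALSE, quote = FALSE)
#' pep <- read_peptide_table(tf)
#' attr(pep, "n_fractions")
#' @export
read_peptide_table <- function(path, schema = NULL) {
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  required <- c("protein_id", "peptide", "condition", "replicate",
                "fraction", "intensity")
  if (!is.null(schema)) {
    for (canon in names(schema)) {
      if (!schema[[canon]] %in% names(raw)) {
        stop("schema error: column '", schema[[canon]], "' (mapped to '",
             canon, "') not found in ", path, call. = FALSE)
      }
      names(raw)[names(raw) == schema[[canon]]] <- canon
    }
  }
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0) {
    stop("schema error: missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  rec <- tibble::as_tibble(raw[required])
  rec$replicate <- as.integer(rec$replicate)
  rec$fraction <- as.integer(rec$fraction)
  validate_peptide_records(rec)
}

#' @rdname read_peptide_table
#' @param records A data frame of peptide records to validate in memory
#'   (same columns as the file contract).
#' @export
validate_peptide_records <- function(records) {
  rec <- tibble::as_tibble(records)
  bad <- which(rec$intensity < 0)
  if (length(bad) > 0) {
    stop("validation error: negative intensity at row ", bad[1], call. = FALSE)
  }
  if (any(rec$fraction < 1)) {
    stop("validation error: fraction indices must be >= 1", call. = FALSE)
  }
  if (any(rec$replicate < 1)) {
    stop("validation error: replicate must be a positive integer", call. = FALSE)
  }
  key <- paste(rec$protein_id, rec$peptide, rec$condition, rec$replicate,
               rec$fraction, sep = "|")
  dup <- duplicated(key)
  if (any(dup)) {
    stop("validation error: duplicated (protein, peptide, condition, ",
         "replicate, fraction) key(s): ",
         paste(utils::head(unique(key[dup]), 3), collapse = "; "),
         call. = FALSE)
  }
  attr(rec, "n_fractions") <- max(rec$fraction)
  rec
}

#' Write a peptide table to disk
#'
#' Inverse of [read_peptide_table()]; full float precision so that a
#' write/read round trip is lossless.
#'
#' @param records Peptide record tibble.
#' @param path Output path (".csv" writes comma-separated, otherwise tab).
#' @return `path`, invisibly.
#' @export
write_peptide_table <- function(records, path) {
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  readr::write_delim(records, path, delim = delim)
  invisible(path)
}

#' Read gene annotations for genomic-distance analysis
#'
#' Accepts either a GFF3 file (only `gene` feature rows are used; `ID=` or
#' `gene_id=` attributes name the gene) or a plain 4+ column TSV with a
#' header (`gene_id`, `start`, `end`, `strand`, optionally `genome_id` and
#' `genome_length`). Coordinates are 1-based inclusive throughout, the GFF3
#' convention.
#'
#' @param path Path to the annotation file.
#' @return Tibble with columns `gene_id`, `start`, `end`, `strand`,
#'   `genome_id`, `genome_length` (the last two may be `NA` for TSV input
#'   that omits them).
#' @export
read_annotation <- function(path) {
  head_lines <- readLines(path, n = 5L)
  body <- head_lines[!startsWith(head_lines, "#")]
  gff <- grepl("^##gff", head_lines[1]) ||
    (length(body) > 0 && length(strsplit(body[1], "\t", fixed = TRUE)[[1]]) == 9)
  ann <- if (gff) read_annotation_gff3(path) else read_annotation_tsv(path)
  bad <- which(ann$start >= ann$end)
  if (length(bad) > 0) {
    stop("validation error: start >= end for gene '", ann$gene_id[bad[1]], "'",
         call. = FALSE)
  }
  if (any(!is.na(ann$genome_length) & ann$end > ann$genome_length)) {
    stop("validation error: gene coordinates exceed genome_length", call. = FALSE)
  }
  ann
}

read_annotation_gff3 <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  fields <- fields[vapply(fields, length, 1L) == 9]
  keep <- vapply(fields, function(f) identical(f[3], "gene"), TRUE)
  fields <- fields[keep]
  if (length(fields) == 0) {
    return(tibble::tibble(gene_id = character(), start = integer(),
                          end = integer(), strand = character(),
                          genome_id = character(), genome_length = integer()))
  }
  get_id <- function(attr) {
    m <- regmatches(attr, regexec("(?:^|;)(?:ID|gene_id)=([^;]+)", attr))[[1]]
    if (length(m) == 2) m[2] else NA_character_
  }
  tibble::tibble(
    gene_id = vapply(fields, function(f) get_id(f[9]), ""),
    start = vapply(fields, function(f) as.integer(f[4]), 1L),
    end = vapply(fields, function(f) as.integer(f[5]), 1L),
    strand = vapply(fields, function(f) f[7], ""),
    genome_id = vapply(fields, function(f) f[1], ""),
    genome_length = NA_integer_
  )
}

read_annotation_tsv <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("gene_id", "start", "end", "strand")
  missing <- setdiff(required, names(tab))
  if (length(missing) > 0) {
    stop("schema error: missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  tibble::tibble(
    gene_id = as.character(tab$gene_id),
    start = as.integer(tab$start),
    end = as.integer(tab$end),
    strand = as.character(tab$strand),
    genome_id = if ("genome_id" %in% names(tab)) as.character(tab$genome_id) else NA_character_,
    genome_length = if ("genome_length" %in% names(tab)) as.integer(tab$genome_length) else NA_integer_
  )
}

#' Read protein sequences from a FASTA file
#'
#' Thin wrapper around `Biostrings::readAAStringSet()` returning a plain
#' named character vector suitable for [monomeric_mass()]. Sequence names
#' are truncated at the first whitespace (the usual FASTA id convention).
#'
#' @param path FASTA file of amino-acid sequences.
#' @return Named character vector of sequences.
#' @export
read_protein_sequences <- function(path) {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    stop("reading FASTA requires the Biostrings package", call. = FALSE)
  }
  aa <- Biostrings::readAAStringSet(path)
  out <- as.character(aa)
  names(out) <- sub("\\s.*$", "", names(aa))
  out
}

#' Read a calibration-standards table
#'
#' @param path CSV/TSV with columns `name`, `mw_da`, `apex_fraction`.
#' @return Tibble of standards.
#' @export
read_calibration_standards <- function(path) {
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  tab <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  missing <- setdiff(c("name", "mw_da", "apex_fraction"), names(tab))
  if (length(missing) > 0) {
    stop("schema error: missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (any(tab$mw_da <= 0)) stop("validation error: mw_da must be > 0", call. = FALSE)
  tibble::as_tibble(tab[c("name", "mw_da", "apex_fraction")])
}

#' Write / read a scored interaction network as a plain-text edge list
#'
#' The edge list carries one row per retained interaction, sorted by
#' descending classifier probability, with the interaction type
#' (`host-host`, `host-phage`, `phage-phage`) when organism annotations are
#' available.
#'
#' @param edges Tibble of scored pairs with columns `protein_a`, `protein_b`,
#'   `probability`, `q_value` and optionally `interaction_type`.
#' @param path Output TSV path.
#' @return `path` invisibly (`write_network`); tibble of edges
#'   (`read_network`).
#' @export
write_network <- function(edges, path) {
  cols <- c("protein_a", "protein_b", "probability", "q_value")
  missing <- setdiff(cols, names(edges))
  if (length(missing) > 0) {
    stop("edges must carry column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  out <- tibble::as_tibble(edges)
  if (!"interaction_type" %in% names(out)) out$interaction_type <- NA_character_
  out <- out[order(-out$probability, out$protein_a, out$protein_b),
             c(cols, "interaction_type")]
  readr::write_tsv(out, path)
  invisible(path)
}

#' @rdname write_network
#' @export
read_network <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                  col_types = readr::cols(
                    protein_a = readr::col_character(),
                    protein_b = readr::col_character(),
                    probability = readr::col_double(),
                    q_value = readr::col_double(),
                    interaction_type = readr::col_character()
                  ))
}
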