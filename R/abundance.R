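#' Construct an abundance table
#'
#' The universal input container of the package: a samples x taxa matrix of
#' relative abundances in percent, with rank-aware taxon labels (MetaPhlAn-style
#' clade strings such as `k__Bacteria|...|g__Bacteroides`). Taxonomic tables are
#' expected to sum to ~100 per sample; functional-profile tables (`rank =
#' "functional"`) are exempt from the closure check.
#'
#' @param values numeric matrix, samples in rows, taxa in columns; rownames are
#'   sample ids, colnames are taxon labels. Both must be unique and non-empty.
#' @param rank character scalar: the taxonomic level of the columns
#'   (`"kingdom"`, `"phylum"`, ..., `"species"`) or `"functional"`.
#' @param check logical; validate invariants (non-negativity, closure).
#' @return an object of class `abundance_table` (a matrix with a `rank`
#'   attribute).
#' @export
abundance_table <- function(values, rank, check = TRUE) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("abundance_table requires sample ids (rownames) and taxon labels (colnames)")
  if (anyDuplicated(rownames(values)))
    stop("duplicate sample ids: ", paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate taxon labels")
  if (check) {
    if (any(values < 0)) stop("abundance values must be non-negative")
    if (!identical(rank, "functional")) {
      s <- rowSums(values)
      bad <- which(s < 99 | s > 101)
      if (length(bad))
        stop("per-sample abundance sums outside [99, 101] for: ",
             paste(utils::head(rownames(values)[bad], 5), collapse = ", "))
    }
  }
  structure(values, rank = rank, class = c("abundance_table", "matrix", "array"))
}

#' @export
print.abundance_table <- function(x, ...) {
  cat(sprintf("<abundance_table> %d samples x %d taxa (rank: %s)\n",
              nrow(x), ncol(x), attr(x, "rank")))
  invisible(x)
}

sample_ids <- function(x) rownames(x)
taxon_labels <- function(x) colnames(x)

#' Renormalize abundance rows to proportions
#'
#' @param x an `abundance_table` or numeric matrix.
#' @return matrix of per-sample proportions (rows sum to 1).
#' @export
as_proportions <- function(x) {
  m <- unclass(x)
  attr(m, "rank") <- NULL
  sweep(m, 1, rowSums(m), "/")
}

rank_prefixes <- c(kingdom = "k__", phylum = "p__", class = "c__",
                   order = "o__", family = "f__", genus = "g__",
                   species = "s__", strain = "t__")

#' Read a MetaPhlAn-style merged abundance table
#'
#' Reads a merged profiler TSV (rows are clade strings like
#' `k__Bacteria|p__...|g__...|s__...`, columns are samples, values are
#' relative abundances in percent) and extracts the rows terminating at a
#' single taxonomic rank. At species level, strain-level (`t__`, SGB) rows
#' are treated as sub-species and dropped. Both the plain dialect and the
#' two-column-header dialect (`clade_name`, `NCBI_tax_id`) are accepted;
#' the header is sniffed.
#'
#' @param path TSV file path; comment lines start with `#` (the last such
#'   line may carry the column header).
#' @param rank taxonomic level to extract: one of `"kingdom"`, `"phylum"`,
#'   `"class"`, `"order"`, `"family"`, `"genus"`, `"species"`.
#' @return an [abundance_table] (samples x taxa).
#' @export
read_metaphlan_table <- function(path, rank = "species") {
  rank <- match.arg(rank, names(rank_prefixes)[1:7])
  lines <- readLines(path)
  if (!length(lines)) stop("empty file: ", path)
  hdr_idx <- which(!startsWith(lines, "#"))[1]
  # header may be the last comment line (classic MetaPhlAn) or the first
  # non-comment line
  header <- NULL
  if (!is.na(hdr_idx) && hdr_idx > 1 && grepl("clade_name|#SampleID", lines[hdr_idx - 1])) {
    header <- sub("^#", "", lines[hdr_idx - 1])
  } else if (!is.na(hdr_idx)) {
    header <- lines[hdr_idx]
    hdr_idx <- hdr_idx + 1
  }
  if (is.null(header)) stop("no header line found in ", path)
  cols <- strsplit(header, "\t", fixed = TRUE)[[1]]
  body <- lines[seq(hdr_idx, length(lines))]
  body <- body[!startsWith(body, "#") & nzchar(body)]
  fields <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != length(cols)))
    stop("ragged TSV: row ", which(nf != length(cols))[1], " has ", nf[nf != length(cols)][1],
         " fields, header has ", length(cols))
  clade <- vapply(fields, `[[`, "", 1L)
  drop_cols <- 1L
  if (length(cols) >= 2 && cols[2] %in% c("NCBI_tax_id", "clade_taxid")) drop_cols <- 2L
  samples <- cols[-seq_len(drop_cols)]
  if (!length(samples)) stop("no sample columns in ", path)

  pref <- rank_prefixes[[rank]]
  deeper <- rank_prefixes[seq(match(rank, names(rank_prefixes)) + 1, length(rank_prefixes))]
  keep <- grepl(pref, clade, fixed = TRUE)
  for (d in deeper) keep <- keep & !grepl(d, clade, fixed = TRUE)
  if (!any(keep))
    stop("no rows at rank '", rank, "' in ", path)

  vals <- matrix(NA_real_, sum(keep), length(samples))
  krows <- which(keep)
  for (i in seq_along(krows)) {
    v <- suppressWarnings(as.numeric(fields[[krows[i]]][-seq_len(drop_cols)]))
    if (anyNA(v)) {
      j <- which(is.na(v))[1]
      stop("non-numeric value in row '", clade[krows[i]], "', sample '", samples[j], "'")
    }
    vals[i, ] <- v
  }
  m <- t(vals)
  rownames(m) <- samples
  colnames(m) <- clade[keep]
  abundance_table(m, rank = rank)
}

#' Write an abundance table as a MetaPhlAn-style merged TSV
#'
#' @param table an [abundance_table].
#' @param path output path.
#' @param digits significant digits to print (default 12, lossless round-trip
#'   at the package's declared precision).
#' @export
write_metaphlan_table <- function(table, path, digits = 12) {
  m <- t(unclass(table))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("clade_name", sample_ids(table)), collapse = "\t"), con)
  body <- vapply(seq_len(nrow(m)), function(i)
    paste(c(rownames(m)[i], formatC(m[i, ], digits = digits, format = "g")), collapse = "\t"),
    character(1))
  writeLines(body, con)
  invisible(path)
}

#' Read a sample metadata table
#'
#' Reads a TSV with one row per sample. Required columns: `sample_id`,
#' `cohort`, `age`, `sex`. Medication exposure flags (0/1 at ATC 3rd level,
#' e.g. exposure registered 30 days prior to sampling) are auto-detected by a
#' column-name prefix; `any_medication` is derived as the union of the flags
#' when absent. Unknown extra columns are preserved as passthrough.
#'
#' @param path TSV file path with header.
#' @param medication_prefix prefix identifying medication flag columns.
#' @return a `data.frame` of class `sample_metadata` with attribute
#'   `medication_cols`.
#' @export
read_metadata <- function(path, medication_prefix = "med_") {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  required <- c("sample_id", "cohort", "age", "sex")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("metadata is missing required column(s): ", paste(missing, collapse = ", "))
  if (anyDuplicated(df$sample_id))
    stop("duplicated sample_id in metadata: ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  med_cols <- grep(paste0("^", medication_prefix), names(df), value = TRUE)
  for (mc in med_cols) {
    if (!all(df[[mc]] %in% c(0, 1)))
      stop("medication flag column '", mc, "' must be 0/1")
  }
  if (!"any_medication" %in% names(df)) {
    df$any_medication <- if (length(med_cols))
      as.integer(rowSums(df[, med_cols, drop = FALSE]) > 0) else 0L
  }
  if (length(med_cols)) {
    derived <- as.integer(rowSums(df[, med_cols, drop = FALSE]) > 0)
    if (!all(df$any_medication == derived))
      stop("any_medication inconsistent with medication flags")
  }
  structure(df, medication_cols = med_cols,
            class = c("sample_metadata", "data.frame"))
}

#' Write sample metadata as TSV
#' @param metadata a `sample_metadata` data frame.
#' @param path output path.
#' @export
write_metadata <- function(metadata, path) {
  utils::write.table(as.data.frame(metadata), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Inner-join an abundance table with metadata
#'
#' Restricts both to the common sample set, warning loudly about dropped ids.
#'
#' @param table an [abundance_table].
#' @param metadata a `sample_metadata` data frame.
#' @return list with elements `table` and `metadata`, row-aligned.
#' @export
align_samples <- function(table, metadata) {
  common <- intersect(sample_ids(table), metadata$sample_id)
  if (!length(common)) stop("no samples shared between abundance table and metadata")
  drop_t <- setdiff(sample_ids(table), common)
  drop_m <- setdiff(metadata$sample_id, common)
  if (length(drop_t))
    warning("dropping ", length(drop_t), " abundance sample(s) without metadata: ",
            paste(utils::head(drop_t, 10), collapse = ", "))
  if (length(drop_m))
    warning("dropping ", length(drop_m), " metadata row(s) without abundance: ",
            paste(utils::head(drop_m, 10), collapse = ", "))
  tab <- abundance_table(unclass(table)[common, , drop = FALSE],
                         rank = attr(table, "rank"), check = FALSE)
  md <- metadata[match(common, metadata$sample_id), , drop = FALSE]
  rownames(md) <- NULL
  list(table = tab, metadata = md)
}
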