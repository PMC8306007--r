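#' Construct an OTU count table
#'
#' An `otu_table` is the pipeline's universal currency: a non-negative
#' integer matrix of read counts with OTUs as rows and samples as columns,
#' both carrying unique identifiers.
#'
#' @param counts numeric matrix of read counts, OTUs in rows, samples in
#'   columns. All entries must be finite, non-negative integers.
#' @param otu_ids,sample_ids character vectors of row/column identifiers;
#'   default to the dimnames of `counts`.
#' @return An integer matrix of class `otu_table` with `otu_ids` as rownames
#'   and `sample_ids` as colnames.
#' @export
otu_table <- function(counts, otu_ids = rownames(counts),
                      sample_ids = colnames(counts)) {
  counts <- as.matrix(counts)
  if (is.null(otu_ids)) otu_ids <- paste0("OTU", seq_len(nrow(counts)))
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(ncol(counts)))
  otu_ids <- as.character(otu_ids)
  sample_ids <- as.character(sample_ids)
  if (length(otu_ids) != nrow(counts))
    stop("length of otu_ids (", length(otu_ids),
         ") does not match number of rows (", nrow(counts), ")")
  if (length(sample_ids) != ncol(counts))
    stop("length of sample_ids (", length(sample_ids),
         ") does not match number of columns (", ncol(counts), ")")
  if (anyDuplicated(otu_ids))
    stop("duplicate OTU ids: ",
         paste(unique(otu_ids[duplicated(otu_ids)]), collapse = ", "))
  if (anyDuplicated(sample_ids))
    stop("duplicate sample ids: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  bad <- which(!is.finite(counts) | counts < 0 | counts != round(counts))
  if (length(bad)) {
    i <- ((bad[1] - 1) %% nrow(counts)) + 1
    j <- ((bad[1] - 1) %/% nrow(counts)) + 1
    stop("counts must be finite non-negative integers; offending cell: OTU '",
         otu_ids[i], "', sample '", sample_ids[j], "' (value ",
         counts[bad[1]], ")")
  }
  storage.mode(counts) <- "integer"
  dimnames(counts) <- list(otu_ids, sample_ids)
  class(counts) <- c("otu_table", class(matrix()))
  counts
}

#' @export
print.otu_table <- function(x, ...) {
  cat("OTU table: ", nrow(x), " OTUs x ", ncol(x), " samples, ",
      format(sum(as.numeric(x)), big.mark = ","), " reads total\n", sep = "")
  invisible(x)
}

#' Test for otu_table
#' @param x object
#' @return logical
#' @export
is_otu_table <- function(x) inherits(x, "otu_table")

otu_ids <- function(x) rownames(x)
sample_ids <- function(x) colnames(x)

as_counts <- function(x) {
  y <- unclass(x)
  attr(y, "class") <- NULL
  y
}

#' Read an OTU table from file
#'
#' Reads a tab-delimited OTU table (one header row of sample IDs, one leading
#' column of OTU IDs; a leading `#OTU ID` header cell is tolerated) or a
#' BIOM-format JSON file (requires the \pkg{biomformat} package).
#'
#' Orientation is fixed as OTUs-as-rows; a transposed file is accepted only
#' via `orientation = "samples_as_rows"`, never guessed from shape.
#'
#' @param path file path.
#' @param orientation `"otus_as_rows"` (default) or `"samples_as_rows"`.
#' @param format `"auto"` (by extension), `"tsv"` or `"biom"`.
#' @return validated [otu_table].
#' @export
read_otu_table <- function(path,
                           orientation = c("otus_as_rows", "samples_as_rows"),
                           format = c("auto", "tsv", "biom")) {
  orientation <- match.arg(orientation)
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.(biom|json)$", path, ignore.case = TRUE))
      "biom" else "tsv"
  if (format == "biom") {
    if (!requireNamespace("biomformat", quietly = TRUE))
      stop("reading BIOM files requires the 'biomformat' package")
    b <- biomformat::read_biom(path)
    m <- as.matrix(biomformat::biom_data(b))
  } else {
    first <- readLines(path, n = 1L)
    if (length(first) == 0L) stop("no data rows in '", path, "'")
    df <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                            comment.char = "", stringsAsFactors = FALSE)
    if (nrow(df) == 0L) stop("no data rows in '", path, "'")
    ids <- as.character(df[[1]])
    m <- as.matrix(df[, -1, drop = FALSE])
    if (!is.numeric(m)) stop("non-numeric counts in '", path, "'")
    rownames(m) <- ids
  }
  if (orientation == "samples_as_rows") m <- t(m)
  otu_table(m)
}

#' Write an OTU table to a TSV file
#'
#' @param table [otu_table].
#' @param path output path; tab-delimited, header cell `#OTU ID`.
#' @return `path`, invisibly.
#' @export
write_otu_table <- function(table, path) {
  stopifnot(is_otu_table(table))
  df <- data.frame(`#OTU ID` = rownames(table), as_counts(table),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample metadata table
#'
#' Tab-delimited with columns `sample_id`, `host`, `organ`, `plot`.
#'
#' @param path file path.
#' @return data.frame with character columns.
#' @export
read_sample_meta <- function(path) {
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                          check.names = FALSE)
  need <- c("sample_id", "host", "organ", "plot")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("metadata is missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample_id in metadata")
  df[need]
}

#' Read a taxonomy table
#'
#' Tab-delimited with columns `otu_id` and `taxonomy` (semicolon-joined
#' ranks, `k__`/`p__`/... prefixes tolerated and stripped), or already-split
#' rank columns kingdom...species. An optional `confidence` column in
#' \eqn{[0,1]} is carried through.
#'
#' @param path file path.
#' @return data.frame with columns otu_id, kingdom, phylum, class, order,
#'   family, genus, species, confidence.
#' @export
read_taxonomy <- function(path) {
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                          check.names = FALSE)
  ranks <- c("kingdom", "phylum", "class", "order", "family", "genus",
             "species")
  if (!"otu_id" %in% names(df)) stop("taxonomy is missing column otu_id")
  if ("taxonomy" %in% names(df)) {
    parts <- strsplit(df$taxonomy, ";", fixed = TRUE)
    m <- t(vapply(parts, function(p) {
      p <- trimws(p)
      p <- sub("^[kpcofgs]__", "", p)
      length(p) <- 7L
      p
    }, character(7)))
    colnames(m) <- ranks
    tax <- data.frame(otu_id = df$otu_id, m, stringsAsFactors = FALSE)
  } else {
    miss <- setdiff(ranks, names(df))
    for (r in miss) df[[r]] <- NA_character_
    tax <- df[c("otu_id", ranks)]
  }
  for (r in ranks) {
    v <- tax[[r]]
    v[is.na(v) | v == ""] <- "unclassified"
    tax[[r]] <- v
  }
  tax$confidence <- if ("confidence" %in% names(df))
    as.numeric(df$confidence) else NA_real_
  tax
}

#' Remove OTUs with low total read counts
#'
#' Retains exactly the OTUs whose total reads summed across all samples are
#' at least `min_total`; the sample set is unchanged. The boundary is
#' inclusive, so the common "fewer than 10 reads" filter corresponds to
#' `min_total = 10`.
#'
#' @param table [otu_table].
#' @param min_total non-negative integer, default 10.
#' @return filtered [otu_table] (possibly with zero rows).
#' @export
filter_low_count_otus <- function(table, min_total = 10) {
  stopifnot(is_otu_table(table), min_total >= 0)
  keep <- rowSums(as_counts(table)) >= min_total
  table[keep, , drop = FALSE]
}

#' Select abundant OTUs
#'
#' Retains OTUs whose total reads across all samples are strictly greater
#' than `min_reads` (an OTU with exactly `min_reads` reads is removed).
#'
#' @param table [otu_table].
#' @param min_reads integer threshold, default 1000.
#' @return filtered [otu_table].
#' @export
select_abundant_otus <- function(table, min_reads = 1000) {
  stopifnot(is_otu_table(table))
  keep <- rowSums(as_counts(table)) > min_reads
  table[keep, , drop = FALSE]
}

#' Retain fungal OTUs
#'
#' Keeps OTUs whose taxonomy kingdom is `Fungi`. OTUs absent from the
#' taxonomy table are conservatively treated as non-fungal, dropped, and
#' reported in a message.
#'
#' @param table [otu_table].
#' @param tax taxonomy data.frame as returned by [read_taxonomy()].
#' @return filtered [otu_table].
#' @export
filter_fungal_otus <- function(table, tax) {
  stopifnot(is_otu_table(table))
  kingdom <- tax$kingdom[match(rownames(table), tax$otu_id)]
  missing <- is.na(kingdom)
  if (any(missing))
    message(sum(missing), " OTU(s) missing from taxonomy; treated as ",
            "non-fungal and dropped")
  keep <- !missing & kingdom == "Fungi"
  table[keep, , drop = FALSE]
}

#' Subset samples by metadata predicate
#'
#' Selects the samples matching every supplied value of host/organ/plot.
#'
#' @param table [otu_table].
#' @param meta metadata data.frame (`sample_id`, `host`, `organ`, `plot`).
#' @param host,organ,plot optional character vectors of levels to keep.
#' @param drop_empty_otus if TRUE, OTUs whose counts are all zero in the
#'   subset are removed.
#' @return column-subset [otu_table].
#' @export
subset_samples <- function(table, meta, host = NULL, organ = NULL,
                           plot = NULL, drop_empty_otus = FALSE) {
  stopifnot(is_otu_table(table))
  m <- meta[match(colnames(table), meta$sample_id), , drop = FALSE]
  if (anyNA(m$sample_id))
    stop("samples missing from metadata: ",
         paste(colnames(table)[is.na(m$sample_id)], collapse = ", "))
  keep <- rep(TRUE, ncol(table))
  if (!is.null(host)) keep <- keep & m$host %in% host
  if (!is.null(organ)) keep <- keep & m$organ %in% organ
  if (!is.null(plot)) keep <- keep & m$plot %in% plot
  if (!any(keep)) stop("no samples match the requested predicate")
  out <- table[, keep, drop = FALSE]
  if (drop_empty_otus)
    out <- out[rowSums(as_counts(out)) > 0, , drop = FALSE]
  out
}

# keep otu_table class through [ subsetting (dimnames preserved by matrix)
#' @export
`[.otu_table` <- function(x, i, j, ..., drop = FALSE) {
  y <- NextMethod(drop = FALSE)
  class(y) <- c("otu_table", class(matrix()))
  y
}
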