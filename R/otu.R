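#' Construct an OTU count table
#'
#' An `otu_table` is an integer matrix of read counts with samples in rows
#' and OTUs in columns. Counts must be non-negative integers and sample ids
#' unique.
#'
#' @param counts numeric matrix of non-negative integer counts,
#'   samples x OTUs.
#' @param sample_ids,otu_ids optional character labels; taken from the
#'   dimnames of `counts` when omitted.
#' @return an object of class `otu_table`.
#' @export
otu_table <- function(counts, sample_ids = rownames(counts),
                      otu_ids = colnames(counts)) {
  counts <- as.matrix(counts)
  if (is.null(sample_ids)) sample_ids <- paste0("sample_", seq_len(nrow(counts)))
  if (is.null(otu_ids)) otu_ids <- paste0("OTU_", seq_len(ncol(counts)))
  if (length(sample_ids) != nrow(counts))
    stop_input("sample_ids length (%d) does not match number of rows (%d)",
               length(sample_ids), nrow(counts))
  if (length(otu_ids) != ncol(counts))
    stop_input("otu_ids length (%d) does not match number of columns (%d)",
               length(otu_ids), ncol(counts))
  if (anyDuplicated(sample_ids))
    stop_input("duplicate sample ids: %s",
               paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  bad <- which(!is.finite(counts) | counts < 0 | counts != round(counts))
  if (length(bad)) {
    i <- ((bad[1] - 1) %% nrow(counts)) + 1
    j <- ((bad[1] - 1) %/% nrow(counts)) + 1
    stop_input("invalid count %s at sample '%s', OTU '%s' (must be a non-negative integer)",
               format(counts[bad[1]]), sample_ids[i], otu_ids[j])
  }
  storage.mode(counts) <- "integer"
  dimnames(counts) <- list(sample_ids, otu_ids)
  structure(list(counts = counts,
                 sample_ids = sample_ids,
                 otu_ids = otu_ids),
            class = "otu_table")
}

#' @export
print.otu_table <- function(x, ...) {
  cat(sprintf("otu_table: %d samples x %d OTUs, %s total reads\n",
              nrow(x$counts), ncol(x$counts),
              format(sum(as.numeric(x$counts)), big.mark = ",")))
  invisible(x)
}

#' Read an OTU count table from a delimited text file
#'
#' Reads a TSV/CSV matrix with a header row and row labels in the first
#' column, and normalizes it to samples-in-rows. Orientation `"auto"` is
#' resolved only when labels disambiguate: one axis (and only one) must have
#' labels starting with "OTU", "otu" or "sp"; otherwise the orientation must
#' be given explicitly.
#'
#' @param path file path.
#' @param orientation `"samples-in-rows"`, `"samples-in-columns"` or
#'   `"auto"`.
#' @param sep field separator; tab by default, use `","` for CSV.
#' @return an [otu_table].
#' @export
load_otu_table <- function(path,
                           orientation = c("samples-in-rows",
                                           "samples-in-columns", "auto"),
                           sep = "\t") {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop_input("file not found: %s", path)
  df <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1,
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df)
  if (!is.numeric(m)) {
    bad <- which(is.na(suppressWarnings(as.numeric(m))) & !is.na(m))
    stop_input("non-numeric entry in %s%s", path,
               if (length(bad)) sprintf(" (first at matrix position %d)", bad[1]) else "")
  }
  if (orientation == "auto") {
    looks_otu <- function(v) mean(grepl("^(OTU|otu|Otu|sp)", v)) > 0.5
    row_otu <- looks_otu(rownames(m))
    col_otu <- looks_otu(colnames(m))
    if (row_otu && !col_otu) orientation <- "samples-in-columns"
    else if (col_otu && !row_otu) orientation <- "samples-in-rows"
    else stop_input(
      "cannot auto-detect orientation of %s: labels do not disambiguate; pass orientation explicitly",
      path)
  }
  if (orientation == "samples-in-columns") m <- t(m)
  otu_table(m)
}

#' Write an OTU count table to a delimited text file
#'
#' Inverse of [load_otu_table]: writes samples in rows with a header of OTU
#' ids, so that a write-then-read round trip preserves counts and labels.
#'
#' @param table an [otu_table].
#' @param path output path.
#' @param sep field separator.
#' @return `path`, invisibly.
#' @export
write_otu_table <- function(table, path, sep = "\t") {
  stopifnot(inherits(table, "otu_table"))
  df <- data.frame(sample_id = table$sample_ids, table$counts,
                   check.names = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a BIOM-format OTU table
#'
#' Thin wrapper over the biomformat package mapping a BIOM file (where
#' observations are OTUs and columns are samples) onto the same [otu_table]
#' container used throughout the package.
#'
#' @param path path to a BIOM file.
#' @return an [otu_table] with samples in rows.
#' @export
load_biom_table <- function(path) {
  if (!requireNamespace("biomformat", quietly = TRUE))
    stop_input("the biomformat package is required to read BIOM files")
  b <- biomformat::read_biom(path)
  m <- as(biomformat::biom_data(b), "matrix")  # OTUs x samples
  otu_table(t(m))
}

#' Extract the positive abundance vector of one sample
#'
#' Drops zero-count OTUs and returns the per-OTU read counts of a single
#' sample, the unit the RSA model is fitted to. Count order follows the
#' table's OTU order.
#'
#' @param table an [otu_table], or a bare numeric vector of counts.
#' @param sample_id sample label (ignored for bare vectors).
#' @return an object of class `abundance_vector` with elements `counts`
#'   (named positive integers), `n_obs` (observed richness) and
#'   `total_reads`.
#' @export
abundance_vector <- function(table, sample_id = NULL) {
  if (inherits(table, "otu_table")) {
    if (is.null(sample_id)) stop_input("sample_id is required")
    if (!sample_id %in% table$sample_ids)
      stop_input("unknown sample_id '%s'", sample_id)
    row <- table$counts[sample_id, ]
  } else {
    row <- as.numeric(table)
    if (any(!is.finite(row) | row < 0 | row != round(row)))
      stop_input("counts must be non-negative integers")
    names(row) <- names(table) %||% paste0("OTU_", seq_along(row))
    sample_id <- sample_id %||% "sample_1"
  }
  keep <- row > 0
  if (!any(keep))
    stop_input("sample '%s' has no observed species (all counts zero)", sample_id)
  counts <- row[keep]
  structure(list(sample_id = sample_id,
                 counts = counts,
                 n_obs = length(counts),
                 total_reads = sum(as.numeric(counts))),
            class = "abundance_vector")
}

#' @export
print.abundance_vector <- function(x, ...) {
  cat(sprintf("abundance_vector '%s': %d OTUs, %s reads\n",
              x$sample_id, x$n_obs, format(x$total_reads, big.mark = ",")))
  invisible(x)
}
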