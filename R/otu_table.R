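#' Construct an OTU count table
#'
#' Container for a marker-gene (16S or ITS) OTU count matrix together with its
#' per-OTU taxonomy lineage. Counts are stored samples x OTUs; files on disk
#' use the conventional OTUs x samples orientation.
#'
#' @param counts integer matrix, samples in rows, OTUs in columns; must carry
#'   dimnames (sample ids, OTU ids).
#' @param taxonomy character vector of semicolon-delimited lineages
#'   (`kingdom;phylum;class;order;family;genus;species`, ranks may be empty),
#'   one per OTU, named or in column order.
#' @param marker `"16S"` or `"ITS"`.
#' @return An object of class `otu_table`: list with elements `counts`,
#'   `taxonomy`, `marker`.
#' @export
otu_table <- function(counts, taxonomy = NULL, marker = c("16S", "ITS")) {
  marker <- match.arg(marker)
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have sample ids as rownames and OTU ids as colnames")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate sample id: ",
         rownames(counts)[duplicated(rownames(counts))][1L])
  if (anyDuplicated(colnames(counts)))
    stop("duplicate OTU id: ",
         colnames(counts)[duplicated(colnames(counts))][1L])
  bad <- which(!is.finite(counts) | counts < 0 | counts != round(counts))
  if (length(bad)) {
    i <- arrayInd(bad[1L], dim(counts))
    stop(sprintf(
      "counts must be non-negative integers; offending cell sample '%s', OTU '%s'",
      rownames(counts)[i[1L]], colnames(counts)[i[2L]]))
  }
  storage.mode(counts) <- "integer"
  if (is.null(taxonomy)) taxonomy <- rep("", ncol(counts))
  if (length(taxonomy) != ncol(counts))
    stop("taxonomy length (", length(taxonomy),
         ") must equal number of OTUs (", ncol(counts), ")")
  names(taxonomy) <- colnames(counts)
  structure(list(counts = counts, taxonomy = taxonomy, marker = marker),
            class = "otu_table")
}

#' @export
print.otu_table <- function(x, ...) {
  cat(sprintf("otu_table [%s]: %d samples x %d OTUs, total count %.0f\n",
              x$marker, nrow(x$counts), ncol(x$counts), sum(x$counts)))
  invisible(x)
}

#' @export
dim.otu_table <- function(x) dim(x$counts)

n_samples <- function(x) nrow(x$counts)
n_otus    <- function(x) ncol(x$counts)

#' Read an OTU table from TSV
#'
#' Expects a tab-separated file with OTU ids in the first column, one column
#' per sample, and an optional final `taxonomy` column. The BIOM dense-TSV
#' convention (first header cell `#OTU ID`) is detected and accepted.
#'
#' @param path file path.
#' @param marker `"16S"` or `"ITS"`.
#' @return An [otu_table].
#' @export
read_otu_table <- function(path, marker = c("16S", "ITS")) {
  marker <- match.arg(marker)
  lines <- readLines(path, encoding = "UTF-8")
  if (!length(lines)) stop("empty file: ", path)
  header <- strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]]
  body <- strsplit(lines[-1L], "\t", fixed = TRUE)
  has_tax <- length(header) > 1L &&
    tolower(header[length(header)]) == "taxonomy"
  sample_ids <- header[-1L]
  if (has_tax) sample_ids <- sample_ids[-length(sample_ids)]
  if (anyDuplicated(sample_ids))
    stop("duplicate sample column: ", sample_ids[duplicated(sample_ids)][1L])
  ncol_expect <- 1L + length(sample_ids) + as.integer(has_tax)
  otu_ids <- character(length(body))
  taxonomy <- character(length(body))
  counts <- matrix(0L, nrow = length(sample_ids), ncol = length(body))
  for (r in seq_along(body)) {
    f <- body[[r]]
    # strsplit drops a trailing empty taxonomy field
    if (has_tax && length(f) == ncol_expect - 1L) f <- c(f, "")
    if (length(f) != ncol_expect)
      stop(sprintf("row %d has %d fields, expected %d", r + 1L, length(f),
                   ncol_expect))
    otu_ids[r] <- f[1L]
    if (has_tax) taxonomy[r] <- f[length(f)]
    vals <- f[1L + seq_along(sample_ids)]
    ok <- grepl("^[0-9]+$", vals)
    if (!all(ok)) {
      j <- which(!ok)[1L]
      stop(sprintf(
        "negative or non-integer count '%s' at OTU '%s', sample '%s'",
        vals[j], f[1L], sample_ids[j]))
    }
    counts[, r] <- as.integer(vals)
  }
  if (anyDuplicated(otu_ids))
    stop("duplicate OTU id: ", otu_ids[duplicated(otu_ids)][1L])
  dimnames(counts) <- list(sample_ids, otu_ids)
  otu_table(counts, taxonomy, marker)
}

#' Write an OTU table to TSV
#'
#' Inverse of [read_otu_table()]: OTUs in rows, samples in columns, trailing
#' `taxonomy` column. UTF-8, tab-delimited, `.` decimal separator.
#'
#' @param table an [otu_table].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_otu_table <- function(table, path) {
  stopifnot(inherits(table, "otu_table"))
  con <- file(path, open = "wb")
  on.exit(close(con))
  header <- paste(c("otu_id", rownames(table$counts), "taxonomy"),
                  collapse = "\t")
  rows <- vapply(seq_len(ncol(table$counts)), function(j) {
    paste(c(colnames(table$counts)[j],
            format(table$counts[, j], scientific = FALSE, trim = TRUE),
            table$taxonomy[j]), collapse = "\t")
  }, character(1))
  writeLines(c(header, rows), con, sep = "\n", useBytes = TRUE)
  invisible(path)
}
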