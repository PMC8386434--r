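#' Validate a sample metadata table
#'
#' Checks the study design invariants: known time-point labels, the bulk vs
#' rhizosphere convention (T0/T3 are bulk soil, T1/T2 rhizosphere), and yield
#' constancy within a block (yield is measured per block, so every sample of a
#' block must carry the same value; missing yield is `NA`).
#'
#' @param meta data.frame with columns `sample_id`, `location`, `time_point`,
#'   `treatment`, `block_id`, `soil_type`, `variety`, `yield_t_ha`.
#' @return `meta` (with `yield_t_ha` numeric), invisibly usable downstream.
#' @export
validate_metadata <- function(meta) {
  req <- c("sample_id", "location", "time_point", "treatment", "block_id",
           "soil_type", "variety", "yield_t_ha")
  miss <- setdiff(req, names(meta))
  if (length(miss)) stop("metadata missing column(s): ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(meta$sample_id))
    stop("duplicate sample_id: ",
         meta$sample_id[duplicated(meta$sample_id)][1L])
  bad_tp <- setdiff(unique(meta$time_point), c("T0", "T1", "T2", "T3"))
  if (length(bad_tp)) stop("unknown time_point label: ", bad_tp[1L])
  bad_tr <- setdiff(unique(meta$treatment), c("control", "treated"))
  if (length(bad_tr)) stop("unknown treatment label: ", bad_tr[1L])
  bad_st <- setdiff(unique(meta$soil_type), c("bulk", "rhizosphere"))
  if (length(bad_st)) stop("unknown soil_type label: ", bad_st[1L])
  expected_soil <- ifelse(meta$time_point %in% c("T0", "T3"),
                          "bulk", "rhizosphere")
  off <- which(meta$soil_type != expected_soil)
  if (length(off))
    stop(sprintf(
      "sample '%s': soil_type '%s' inconsistent with time_point '%s' (T0/T3 are bulk, T1/T2 rhizosphere)",
      meta$sample_id[off[1L]], meta$soil_type[off[1L]],
      meta$time_point[off[1L]]))
  y <- suppressWarnings(as.numeric(meta$yield_t_ha))
  not_na_in <- !is.na(meta$yield_t_ha) & !(meta$yield_t_ha %in% c("", "NA"))
  if (any(is.na(y) & not_na_in))
    stop("non-numeric yield_t_ha: ",
         meta$yield_t_ha[which(is.na(y) & not_na_in)][1L])
  if (any(!is.na(y) & y < 0)) stop("negative yield_t_ha")
  meta$yield_t_ha <- y
  for (b in unique(meta$block_id)) {
    yv <- unique(y[meta$block_id == b & !is.na(y)])
    if (length(yv) > 1L)
      stop(sprintf("block '%s' has %d distinct yields (%s); yield must be constant within block",
                   b, length(yv), paste(format(yv), collapse = ", ")))
  }
  meta
}

#' Read sample metadata from TSV
#'
#' @param path TSV with the columns documented in [validate_metadata()];
#'   missing yield encoded as an empty field and read as `NA` (never as 0).
#' @return validated data.frame of per-sample records.
#' @export
read_metadata <- function(path) {
  meta <- utils::read.delim(path, sep = "\t", header = TRUE,
                            colClasses = "character", check.names = FALSE,
                            na.strings = c("", "NA"))
  validate_metadata(meta)
}

#' Write sample metadata to TSV
#'
#' @param meta validated metadata data.frame.
#' @param path output path. Missing yield is written as an empty field.
#' @return `path`, invisibly.
#' @export
write_metadata <- function(meta, path) {
  out <- meta
  out$yield_t_ha <- ifelse(is.na(meta$yield_t_ha), "",
                           sprintf("%.4f", as.numeric(meta$yield_t_ha)))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(names(out), collapse = "\t"), con, useBytes = TRUE)
  lines <- do.call(paste, c(lapply(out, as.character), sep = "\t"))
  writeLines(lines, con, useBytes = TRUE)
  invisible(path)
}
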