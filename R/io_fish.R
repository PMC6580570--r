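#' Read a FISH count table
#'
#' One row per cell, first column the cell identifier, one integer column per
#' probed chromosome. The delimiter is auto-detected among comma, tab and
#' semicolon; a header row is mandatory (`cell_id,<chrom>,...`). Empty
#' fields and the spellings `NA`, `na`, `NaN` become missing entries; any
#' other non-numeric field is an error naming the row and column.
#'
#' @param path path to the count table
#' @param key_path optional path to a group key file (see [read_group_key()])
#' @return a [cnv_matrix()] with `source = "FISH"`; if `key_path` is given, a
#'   list with elements `matrix` and `key`.
#' @export
read_fish_table <- function(path, key_path = NULL) {
  df <- read_delim_auto(path)
  if (ncol(df) < 2L)
    stop("FISH table needs a cell_id column plus at least one chromosome: ", path)
  ids <- df[[1L]]
  if (anyDuplicated(ids))
    stop("duplicate cell_id in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  chroms <- colnames(df)[-1L]
  counts <- matrix(NA_integer_, nrow(df), length(chroms))
  for (j in seq_along(chroms)) {
    raw <- trimws(df[[j + 1L]])
    missing <- raw %in% c("", "NA", "na", "NaN")
    num <- suppressWarnings(as.numeric(raw))
    bad <- which(!missing & (is.na(num) | num < 0 | num != round(num)))
    if (length(bad))
      stop(sprintf("non-integer count '%s' at row %d (cell '%s'), column '%s' in %s",
                   raw[bad[1L]], bad[1L], ids[bad[1L]], chroms[j], path))
    counts[, j] <- ifelse(missing, NA_integer_, as.integer(round(num)))
  }
  m <- cnv_matrix(counts, cell_ids = ids, chromosomes = chroms, source = "FISH")
  if (is.null(key_path)) return(m)
  list(matrix = m, key = read_group_key(key_path))
}

#' Write a copy-number matrix as a FISH-style count table
#'
#' Inverse of [read_fish_table()]: header `cell_id,<chrom>,...`, one row per
#' cell, missing entries written as empty fields. Round-trips counts, the
#' missing mask, and row/column order exactly.
#'
#' @param x a [cnv_matrix()]
#' @param path output path
#' @param sep field delimiter
#' @return `path`, invisibly
#' @export
write_fish_table <- function(x, path, sep = ",") {
  stopifnot(inherits(x, "cnv_matrix"))
  m <- unclass(x)
  df <- data.frame(cell_id = rownames(m), stringsAsFactors = FALSE)
  for (ch in colnames(m)) df[[ch]] <- ifelse(is.na(m[, ch]), "", m[, ch])
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}
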