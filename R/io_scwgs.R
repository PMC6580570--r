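#' Read a binned copy-number state table
#'
#' Consumes the integer copy-number state matrix produced by an upstream
#' single-cell WGS caller (e.g. the downloadable "copy number" file of a
#' binning/segmentation pipeline): a delimited file whose first three columns
#' are `CHR`, `START`, `END` (BED convention, 0-based half-open) followed by
#' one integer column per cell. A leading `#` on the header (`#CHR`) is
#' accepted. This package does not call copy number from reads; alignment,
#' binning and segmentation happen upstream.
#'
#' @param path path to the table
#' @return list of class `binned_table`: `bins` (data frame `chrom`, `start`,
#'   `end`) and `states` (bins x cells integer matrix, `NA` for missing).
#' @export
read_binned_table <- function(path) {
  df <- read_delim_auto(path)
  colnames(df)[1L] <- sub("^#", "", colnames(df)[1L])
  cn <- toupper(colnames(df)[1:3])
  if (ncol(df) < 4L || cn[1L] != "CHR" || cn[2L] != "START" || cn[3L] != "END")
    stop("binned table needs CHR, START, END columns then one column per cell: ",
         path)
  chrom <- normalize_chrom(df[[1L]])
  start <- as.numeric(df[[2L]]); end <- as.numeric(df[[3L]])
  if (anyNA(start) || anyNA(end))
    stop("non-numeric bin coordinates in ", path)
  bad <- which(end <= start)
  if (length(bad))
    stop(sprintf("bin with end <= start at %s:%s-%s in %s",
                 chrom[bad[1L]], start[bad[1L]], end[bad[1L]], path))
  for (ch in unique(chrom)) {
    i <- which(chrom == ch)
    o <- i[order(start[i])]
    if (any(start[o][-1L] < end[o][-length(o)]))
      stop("overlapping bins on chromosome ", ch, " in ", path)
  }
  cells <- colnames(df)[-(1:3)]
  states <- matrix(NA_integer_, nrow(df), length(cells),
                   dimnames = list(NULL, cells))
  for (j in seq_along(cells)) {
    raw <- trimws(df[[j + 3L]])
    missing <- raw %in% c("", "NA", "na", "NaN")
    num <- suppressWarnings(as.numeric(raw))
    badj <- which(!missing & (is.na(num) | num < 0 | num != round(num)))
    if (length(badj))
      stop(sprintf("non-integer copy state '%s' at bin %s:%s-%s, cell '%s' in %s",
                   raw[badj[1L]], chrom[badj[1L]], start[badj[1L]],
                   end[badj[1L]], cells[j], path))
    states[, j] <- ifelse(missing, NA_integer_, as.integer(round(num)))
  }
  structure(list(bins = data.frame(chrom = chrom, start = start, end = end,
                                   stringsAsFactors = FALSE),
                 states = states),
            class = "binned_table")
}

#' @export
print.binned_table <- function(x, ...) {
  cat(sprintf("<binned_table> %d bins on %d chromosome(s), %d cell(s)\n",
              nrow(x$bins), length(unique(x$bins$chrom)), ncol(x$states)))
  invisible(x)
}

#' Collapse binned copy-number states to whole-chromosome counts
#'
#' For each cell and chromosome the bin states are combined by a weighted
#' average in which each bin contributes proportionally to its length in
#' base pairs, and the average is rounded to the nearest integer (halves
#' round away from zero, so 2.5 -> 3). Bins with a missing state for a cell
#' are excluded from that cell's average (weights renormalized); a cell with
#' no observed bin on a chromosome gets a missing entry.
#'
#' @param table a `binned_table` from [read_binned_table()]
#' @return a [cnv_matrix()] with `source = "scWGS"`, one column per
#'   chromosome in genomic order
#' @examples
#' tb <- structure(list(
#'   bins = data.frame(chrom = "1", start = c(0, 1e6), end = c(1e6, 4e6)),
#'   states = cbind(cellA = c(2L, 3L))), class = "binned_table")
#' collapse_to_chromosomes(tb)  # (2*1 + 3*3)/4 = 2.75 -> 3
#' @export
collapse_to_chromosomes <- function(table) {
  stopifnot(inherits(table, "binned_table"))
  chroms <- order_chromosomes(unique(table$bins$chrom))
  len <- table$bins$end - table$bins$start
  cells <- colnames(table$states)
  counts <- matrix(NA_integer_, length(cells), length(chroms),
                   dimnames = list(cells, chroms))
  for (ch in chroms) {
    i <- which(table$bins$chrom == ch)
    for (j in seq_along(cells)) {
      st <- table$states[i, j]
      ok <- !is.na(st)
      w <- len[i][ok]
      if (!any(ok) || sum(w) == 0) next  # stays missing
      counts[j, ch] <- round_half_away(sum(st[ok] * w) / sum(w))
    }
  }
  cnv_matrix(counts, cell_ids = cells, chromosomes = chroms, source = "scWGS")
}

# round to nearest integer, halves away from zero (states are >= 0, so this
# is floor(x + 0.5)); base round() would go to even
round_half_away <- function(x) as.integer(floor(x + 0.5))

#' Read and reduce an sc-WGS state matrix in one step
#'
#' @param path path to the binned state table
#' @param key_path optional group key path
#' @return a [cnv_matrix()], or a list `(matrix, key)` when `key_path` is
#'   given
#' @export
read_scwgs_table <- function(path, key_path = NULL) {
  m <- collapse_to_chromosomes(read_binned_table(path))
  if (is.null(key_path)) return(m)
  list(matrix = m, key = read_group_key(key_path))
}

#' Write a binned state table
#'
#' Serializes a `binned_table` as tab-delimited text with `CHR`, `START`,
#' `END` leading columns; the format accepted by [read_binned_table()].
#'
#' @param table a `binned_table`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_binned_table <- function(table, path) {
  stopifnot(inherits(table, "binned_table"))
  df <- data.frame(CHR = table$bins$chrom,
                   START = format(table$bins$start, scientific = FALSE, trim = TRUE),
                   END = format(table$bins$end, scientific = FALSE, trim = TRUE),
                   stringsAsFactors = FALSE)
  for (j in colnames(table$states))
    df[[j]] <- ifelse(is.na(table$states[, j]), "", table$states[, j])
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
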