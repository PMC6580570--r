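#' Construct a cell-by-chromosome copy-number matrix
#'
#' The canonical exchange object of the package: one row per cell, one column
#' per chromosome (or FISH probe), integer copy numbers, with `NA` marking
#' entries that were not observed. All readers produce this object and all
#' statistics consume it.
#'
#' @param counts numeric matrix or data frame of non-negative integer copy
#'   numbers; rows are cells, columns are chromosomes. `NA` marks missing
#'   (unobserved) entries.
#' @param cell_ids character vector of unique cell identifiers; defaults to
#'   `rownames(counts)` or `cell_1 ... cell_N`.
#' @param chromosomes character vector of unique chromosome labels; defaults
#'   to `colnames(counts)`. Labels are normalized with [normalize_chrom()].
#' @param source data-source tag, one of `"FISH"`, `"SKY"`, `"scWGS"`.
#' @return An object of class `cnv_matrix`: an integer matrix with dimnames
#'   `(cell_ids, chromosomes)` and attribute `source`.
#' @examples
#' m <- cnv_matrix(rbind(c(2, 2), c(2, 3)), chromosomes = c("9", "12"))
#' m
#' @export
cnv_matrix <- function(counts, cell_ids = NULL, chromosomes = NULL,
                       source = c("FISH", "SKY", "scWGS")) {
  source <- match.arg(source)
  counts <- as.matrix(counts)
  if (nrow(counts) < 1L || ncol(counts) < 1L)
    stop("a copy-number matrix needs at least one cell and one chromosome")
  if (is.null(cell_ids)) cell_ids <- rownames(counts)
  if (is.null(cell_ids)) cell_ids <- paste0("cell_", seq_len(nrow(counts)))
  if (is.null(chromosomes)) chromosomes <- colnames(counts)
  if (is.null(chromosomes)) chromosomes <- as.character(seq_len(ncol(counts)))
  cell_ids <- as.character(cell_ids)
  chromosomes <- normalize_chrom(as.character(chromosomes))
  if (anyDuplicated(cell_ids))
    stop("duplicate cell identifiers: ",
         paste(unique(cell_ids[duplicated(cell_ids)]), collapse = ", "))
  if (anyDuplicated(chromosomes))
    stop("duplicate chromosome labels: ",
         paste(unique(chromosomes[duplicated(chromosomes)]), collapse = ", "))
  if (length(cell_ids) != nrow(counts) || length(chromosomes) != ncol(counts))
    stop("dimnames do not match matrix dimensions")
  storage <- suppressWarnings(as.numeric(counts))
  bad <- which(!is.na(storage) & (storage < 0 | storage != round(storage)))
  if (length(bad)) {
    rc <- arrayInd(bad[1L], dim(counts))
    stop(sprintf("non-integer or negative copy number at cell '%s', chromosome '%s'",
                 cell_ids[rc[1L]], chromosomes[rc[2L]]))
  }
  m <- matrix(as.integer(round(storage)), nrow = nrow(counts),
              dimnames = list(cell_ids, chromosomes))
  structure(m, source = source, class = c("cnv_matrix", "matrix", "array"))
}

#' @export
print.cnv_matrix <- function(x, ...) {
  cat(sprintf("<cnv_matrix> %d cells x %d chromosomes, source = %s\n",
              nrow(x), ncol(x), cnv_source(x)))
  n_mis <- sum(is.na(x))
  if (n_mis > 0L) cat(sprintf("  %d missing entr%s\n", n_mis,
                              if (n_mis == 1L) "y" else "ies"))
  show <- utils::head(unclass(x)[, , drop = FALSE], 6L)
  attr(show, "source") <- NULL
  print(show)
  if (nrow(x) > 6L) cat(sprintf("  ... and %d more cells\n", nrow(x) - 6L))
  invisible(x)
}

#' @rdname cnv_matrix
#' @param x a `cnv_matrix`
#' @export
cnv_source <- function(x) attr(x, "source", exact = TRUE)

#' @rdname cnv_matrix
#' @export
missing_mask <- function(x) is.na(unclass(x))

# subsetting keeps class and source; drop is forced off for rows
#' @export
`[.cnv_matrix` <- function(x, i, j, ...) {
  out <- NextMethod(drop = FALSE)
  structure(out, source = cnv_source(x),
            class = c("cnv_matrix", "matrix", "array"))
}

#' Normalize chromosome labels
#'
#' Strips a leading `"chr"` prefix (any case) and upper-cases `x`/`y` so that
#' labels from different platforms ("chr1" vs "1", "chrX" vs "x") unify in a
#' shared label space, as cross-platform comparison requires.
#'
#' @param x character vector of chromosome labels
#' @return normalized character vector
#' @examples
#' normalize_chrom(c("chr1", "1", "chrX", "y"))
#' @export
normalize_chrom <- function(x) {
  x <- trimws(as.character(x))
  x <- sub("^[Cc][Hh][Rr]", "", x)
  sexy <- x %in% c("x", "y")
  x[sexy] <- toupper(x[sexy])
  x
}

#' Sort chromosome labels in genomic order
#'
#' Numeric labels first in numeric order, then X, then Y, then anything else
#' alphabetically (probe names).
#' @param x character vector of (normalized) chromosome labels
#' @return `x` sorted
#' @export
order_chromosomes <- function(x) {
  num <- suppressWarnings(as.numeric(x))
  key1 <- ifelse(!is.na(num), 0L, ifelse(x == "X", 1L, ifelse(x == "Y", 2L, 3L)))
  x[order(key1, num, x)]
}

#' Group assignment of cells to experimental groups
#'
#' @param cell_id character vector of cell identifiers
#' @param group character vector of group labels, recycled if length 1
#' @return a data frame of class `group_key` with columns `cell_id`, `group`
#' @examples
#' group_key(c("c1", "c2", "c3", "c4"), c("A", "A", "B", "B"))
#' @export
group_key <- function(cell_id, group) {
  cell_id <- as.character(cell_id)
  group <- as.character(group)
  if (length(group) == 1L) group <- rep(group, length(cell_id))
  if (length(cell_id) != length(group))
    stop("cell_id and group must have the same length")
  if (anyDuplicated(cell_id))
    stop("duplicate cell identifiers in group key: ",
         paste(unique(cell_id[duplicated(cell_id)]), collapse = ", "))
  structure(data.frame(cell_id = cell_id, group = group,
                       stringsAsFactors = FALSE),
            class = c("group_key", "data.frame"))
}

#' Read a group key file
#'
#' Two-column delimited text with header `cell_id,group`; the delimiter is
#' auto-detected among comma, tab and semicolon.
#'
#' @param path path to the key file
#' @return a `group_key`
#' @export
read_group_key <- function(path) {
  df <- read_delim_auto(path)
  if (ncol(df) < 2L)
    stop("group key must have two columns (cell_id, group): ", path)
  group_key(df[[1L]], df[[2L]])
}

#' Write a group key file
#' @param key a `group_key`
#' @param path output path
#' @param sep field delimiter
#' @return `path`, invisibly
#' @export
write_group_key <- function(key, path, sep = ",") {
  utils::write.table(as.data.frame(key)[, c("cell_id", "group")], path,
                     sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Delimiter auto-detection: pick the candidate that splits the header into
# the most fields, ties broken in the order comma, tab, semicolon.
read_delim_auto <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  header <- readLines(path, n = 1L)
  if (length(header) == 0L) stop("empty file: ", path)
  cands <- c(",", "\t", ";")
  nf <- vapply(cands, function(s) length(strsplit(header, s, fixed = TRUE)[[1L]]),
               integer(1))
  sep <- cands[which.max(nf)]
  utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                    check.names = FALSE, comment.char = "",
                    colClasses = "character", na.strings = NULL)
}

#' Euploid reference copy numbers
#'
#' Expected euploid copy number per chromosome, the baseline against which
#' ANCA, the aneuploidy score and ploidy classes are computed. The default is
#' 2 for every chromosome (diploid autosomes). A sex-aware reference sets the
#' sex chromosomes from the complement: `"XY"` gives X = 1, Y = 1; `"XX"`
#' gives X = 2, Y = 0.
#'
#' @param chromosomes character vector of chromosome labels in scope
#' @param default default euploid copy number (2)
#' @param sex `NULL` for `default` everywhere, or `"XX"`/`"XY"` to set the
#'   sex-chromosome expectations
#' @return named integer vector, one entry per chromosome
#' @examples
#' euploid_reference(c("7", "8", "X", "Y"), sex = "XY")
#' @export
euploid_reference <- function(chromosomes, default = 2L, sex = NULL) {
  chromosomes <- normalize_chrom(chromosomes)
  e <- stats::setNames(rep(as.integer(default), length(chromosomes)), chromosomes)
  if (!is.null(sex)) {
    sex <- toupper(sex)
    if (!sex %in% c("XX", "XY")) stop("sex must be \"XX\" or \"XY\"")
    nx <- sum(strsplit(sex, "")[[1L]] == "X")
    ny <- sum(strsplit(sex, "")[[1L]] == "Y")
    if ("X" %in% chromosomes) e[["X"]] <- nx
    if ("Y" %in% chromosomes) e[["Y"]] <- ny
  }
  if (any(e < 0L)) stop("euploid copy numbers must be >= 0")
  if (all(e == 0L)) stop("at least one chromosome must have euploid copy > 0")
  e
}

# Resolve a reference argument against a matrix: NULL -> default 2; a single
# number -> that value everywhere; a named vector -> matched by label.
resolve_reference <- function(x, ref = NULL) {
  chroms <- colnames(x)
  if (is.null(ref)) return(euploid_reference(chroms))
  if (is.null(names(ref))) {
    if (length(ref) == 1L) return(euploid_reference(chroms, default = ref))
    if (length(ref) == length(chroms))
      return(stats::setNames(as.integer(ref), chroms))
    stop("unnamed euploid reference must have length 1 or ncol(x)")
  }
  names(ref) <- normalize_chrom(names(ref))
  miss <- setdiff(chroms, names(ref))
  if (length(miss))
    stop("euploid reference missing chromosomes: ", paste(miss, collapse = ", "))
  as.integer(ref[chroms]) -> out
  stats::setNames(out, chroms)
}

#' Validate a copy-number matrix against a group key
#'
#' Side-effect-free consistency check run before any analysis. Reports cells
#' without a group label, group labels with no cells in the matrix, key
#' entries absent from the matrix, and cells with no observed entries at all.
#'
#' @param x a [cnv_matrix()]
#' @param key a [group_key()]
#' @return a list of class `validation_report` with character-vector fields
#'   `unlabeled_cells`, `empty_groups`, `key_only_cells`, `all_missing_cells`
#'   and logical `clean`.
#' @export
validate_matrix <- function(x, key) {
  stopifnot(inherits(x, "cnv_matrix"), inherits(key, "group_key"))
  usable <- key$cell_id[!is.na(key$group) & nzchar(trimws(key$group))]
  unlabeled <- setdiff(rownames(x), usable)
  key_only <- setdiff(usable, rownames(x))
  labeled_groups <- unique(key$group[key$cell_id %in% rownames(x) &
                                       nzchar(trimws(key$group))])
  empty_groups <- setdiff(unique(key$group[nzchar(trimws(key$group))]),
                          labeled_groups)
  all_missing <- rownames(x)[rowSums(!is.na(x)) == 0L]
  if (length(setdiff(rownames(x), unlabeled)) == 0L)
    stop("no cells remain after removing cells without a group label")
  structure(list(unlabeled_cells = unlabeled,
                 empty_groups = empty_groups,
                 key_only_cells = key_only,
                 all_missing_cells = all_missing,
                 clean = !length(unlabeled) && !length(empty_groups) &&
                   !length(key_only) && !length(all_missing)),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  if (x$clean) {
    cat("validation: clean\n")
  } else {
    for (f in c("unlabeled_cells", "empty_groups", "key_only_cells",
                "all_missing_cells"))
      if (length(x[[f]]))
        cat(sprintf("%s: %s\n", gsub("_", " ", f),
                    paste(x[[f]], collapse = ", ")))
  }
  invisible(x)
}

#' Split a matrix into per-group strata
#'
#' Partitions the cells of `x` by group label. Cells without a usable label
#' (absent from the key, or with an empty label) are excluded with a warning;
#' key entries for cells not in `x` are ignored with a warning.
#'
#' @inheritParams validate_matrix
#' @return named list of `cnv_matrix` objects, one per group, in order of
#'   first appearance in the key; chromosome order is preserved.
#' @examples
#' m <- cnv_matrix(rbind(c(2, 2), c(2, 3), c(4, 4), c(2, 2)))
#' stratify(m, group_key(rownames(m), c("A", "A", "B", "B")))
#' @export
stratify <- function(x, key) {
  stopifnot(inherits(x, "cnv_matrix"), inherits(key, "group_key"))
  key2 <- key[nzchar(trimws(key$group)) & !is.na(key$group), , drop = FALSE]
  if (nrow(key2) < nrow(key))
    warning(sprintf("%d key entr%s with an empty group label excluded",
                    nrow(key) - nrow(key2),
                    if (nrow(key) - nrow(key2) == 1L) "y" else "ies"))
  extra <- setdiff(key2$cell_id, rownames(x))
  if (length(extra))
    warning(sprintf("%d key cell%s not present in the matrix ignored",
                    length(extra), if (length(extra) == 1L) "" else "s"))
  key2 <- key2[key2$cell_id %in% rownames(x), , drop = FALSE]
  drop <- setdiff(rownames(x), key2$cell_id)
  if (length(drop))
    warning(sprintf("%d cell%s without a group label excluded",
                    length(drop), if (length(drop) == 1L) "" else "s"))
  if (nrow(key2) == 0L)
    stop("no cells remain after removing cells without a group label")
  groups <- unique(key2$group)
  out <- lapply(groups, function(g) x[key2$cell_id[key2$group == g], , drop = FALSE])
  stats::setNames(out, groups)
}
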