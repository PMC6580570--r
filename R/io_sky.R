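#' Parse an ISCN karyotype string into whole-chromosome copy counts
#'
#' Extracts the numerical content of a karyotype string such as
#' `"47,XY,+8"`: the leading modal chromosome number fixes the baseline
#' ploidy (nearest multiple of 23: 46 -> 2 copies per autosome, 69 -> 3,
#' 92 -> 4), the sex complement gives the X and Y counts, and `+`/`-` tokens
#' add or remove whole chromosomes. Structural tokens (translocations,
#' deletions, inversions, markers, ...) carry no whole-chromosome change;
#' they are collected in `unparsed_tokens`, never silently dropped.
#'
#' Conventions for messy strings: a modal-number range (`"44~47"`) uses its
#' first number; mosaic karyotypes separated by `/` use the first clone with
#' a warning; clone sizes in brackets (`"[12]"`) are stripped. Chromosome
#' tokens are case-insensitive.
#'
#' @param iscn a single ISCN karyotype string
#' @return list of class `karyotype_record`: `iscn` (raw string),
#'   `modal_total` (reported leading number), `sex_complement`, `baseline`
#'   (per-autosome copies), `counts` (named integer vector over 1-22, X, Y),
#'   `unparsed_tokens`, and `consistent` — whether baseline, sex complement
#'   and gains/losses reproduce the reported modal total (mismatches are
#'   flagged, never corrected).
#' @examples
#' parse_iscn("47,XY,+8")
#' parse_iscn("46,XX,t(9;22)")
#' @export
parse_iscn <- function(iscn) {
  stopifnot(is.character(iscn), length(iscn) == 1L)
  raw <- iscn
  s <- trimws(iscn)
  if (!nzchar(s)) stop("empty karyotype string")
  clones <- strsplit(s, "/", fixed = TRUE)[[1L]]
  if (length(clones) > 1L)
    warning("composite karyotype: using first clone of ", raw)
  s <- gsub("\\[[^]]*\\]", "", clones[[1L]])  # strip clone sizes "[12]"
  tokens <- trimws(strsplit(s, ",", fixed = TRUE)[[1L]])
  tokens <- tokens[nzchar(tokens)]
  if (!length(tokens)) stop("no tokens in karyotype string: ", raw)

  modal_match <- regmatches(tokens[1L], regexpr("^[0-9]+", tokens[1L]))
  if (!length(modal_match))
    stop("unparseable modal chromosome number in karyotype: ", raw)
  modal_total <- as.integer(modal_match)
  baseline <- max(1L, as.integer(round(modal_total / 23)))

  sex <- ""
  rest <- tokens[-1L]
  if (length(rest) && grepl("^[XxYy]+$", rest[1L])) {
    sex <- toupper(rest[1L])
    rest <- rest[-1L]
  }
  letters_sex <- strsplit(sex, "")[[1L]]
  nx <- sum(letters_sex == "X")
  ny <- sum(letters_sex == "Y")

  chroms <- c(as.character(1:22), "X", "Y")
  counts <- stats::setNames(c(rep(baseline, 22L), nx, ny), chroms)

  unparsed <- character(0)
  for (tok in rest) {
    m <- regmatches(tok, regexec("^([+-])(([0-9]+)|[XxYy])$", tok))[[1L]]
    if (length(m)) {
      ch <- normalize_chrom(m[2L + 1L])
      if (ch %in% chroms) {
        delta <- if (m[2L] == "+") 1L else -1L
        counts[[ch]] <- counts[[ch]] + delta
        next
      }
    }
    unparsed <- c(unparsed, tok)
  }
  if (any(counts < 0L)) {
    bad <- names(counts)[counts < 0L]
    stop("negative chromosome count for ", paste(bad, collapse = ", "),
         " in karyotype: ", raw)
  }
  structure(list(iscn = raw, modal_total = modal_total,
                 sex_complement = sex, baseline = baseline,
                 counts = counts, unparsed_tokens = unparsed,
                 consistent = sum(counts) == modal_total),
            class = "karyotype_record")
}

#' @export
print.karyotype_record <- function(x, ...) {
  cat(sprintf("<karyotype> %s\n  modal %d, sex '%s', baseline %d%s\n",
              x$iscn, x$modal_total, x$sex_complement, x$baseline,
              if (x$consistent) "" else "  [modal-total mismatch]"))
  if (length(x$unparsed_tokens))
    cat("  unparsed tokens:", paste(x$unparsed_tokens, collapse = ", "), "\n")
  invisible(x)
}

#' Build a copy-number matrix from karyotype records
#'
#' @param records list of `karyotype_record` (from [parse_iscn()]), named by
#'   cell identifier, or a character vector of ISCN strings (names used as
#'   cell identifiers).
#' @return a [cnv_matrix()] with `source = "SKY"` over chromosomes 1-22, X, Y.
#'   Cells whose reported modal total disagrees with the reconstructed count
#'   sum are flagged in a warning.
#' @examples
#' karyotypes_to_matrix(c(c1 = "46,XY", c2 = "47,XY,+8"))
#' @export
karyotypes_to_matrix <- function(records) {
  if (is.character(records)) {
    ids <- names(records)
    if (is.null(ids)) ids <- paste0("cell_", seq_along(records))
    records <- stats::setNames(lapply(records, parse_iscn), ids)
  }
  if (!length(records)) stop("no karyotype records")
  ids <- names(records)
  if (is.null(ids)) ids <- paste0("cell_", seq_along(records))
  counts <- do.call(rbind, lapply(records, function(r) r$counts))
  inconsistent <- ids[!vapply(records, `[[`, logical(1), "consistent")]
  if (length(inconsistent))
    warning("modal-total mismatch for cell(s): ",
            paste(inconsistent, collapse = ", "))
  cnv_matrix(counts, cell_ids = ids, source = "SKY")
}

#' Read a SKY karyotype table
#'
#' Accepts a delimited text file or an Excel spreadsheet (`.xlsx`/`.xls`,
#' read via the readxl package) with columns `cell_id, karyotype`; each
#' karyotype is parsed with [parse_iscn()].
#'
#' @param path path to the table
#' @param key_path optional group key path
#' @return a [cnv_matrix()] with `source = "SKY"`, or a list
#'   `(matrix, key)` when `key_path` is given.
#' @export
read_sky_table <- function(path, key_path = NULL) {
  if (grepl("\\.xlsx?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("readxl", quietly = TRUE))
      stop("reading Excel files requires the readxl package")
    df <- as.data.frame(readxl::read_excel(path, col_types = "text"))
  } else {
    df <- read_delim_auto(path)
  }
  if (ncol(df) < 2L)
    stop("SKY table needs columns cell_id, karyotype: ", path)
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids))
    stop("duplicate cell_id in ", path)
  records <- stats::setNames(lapply(as.character(df[[2L]]), parse_iscn), ids)
  m <- karyotypes_to_matrix(records)
  if (is.null(key_path)) return(m)
  list(matrix = m, key = read_group_key(key_path))
}

#' Render whole-chromosome counts as an ISCN karyotype string
#'
#' Inverse of [parse_iscn()] for purely numerical karyotypes: autosome
#' deviations from the baseline ploidy become `+`/`-` tokens (repeated for
#' multi-copy deviations) and the sex chromosomes are written into the
#' complement. Useful for generating synthetic SKY inputs.
#'
#' @param counts named integer vector over chromosomes `1`-`22`, `X`, `Y`
#' @param baseline per-autosome baseline ploidy (2 for a near-diploid clone)
#' @return a single ISCN string whose [parse_iscn()] counts equal `counts`
#' @examples
#' e <- euploid_reference(c(1:22, "X", "Y"), sex = "XY")
#' counts <- e; counts[["8"]] <- 3
#' counts_to_iscn(counts)
#' @export
counts_to_iscn <- function(counts, baseline = 2L) {
  chroms <- c(as.character(1:22), "X", "Y")
  if (!all(chroms %in% names(counts)))
    stop("counts must be named over chromosomes 1-22, X, Y")
  counts <- counts[chroms]
  sex <- paste0(strrep("X", counts[["X"]]), strrep("Y", counts[["Y"]]))
  toks <- character(0)
  for (ch in as.character(1:22)) {
    d <- counts[[ch]] - baseline
    if (d != 0L)
      toks <- c(toks, rep(paste0(if (d > 0L) "+" else "-", ch), abs(d)))
  }
  paste(c(sum(counts), sex, toks), collapse = ",")
}
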