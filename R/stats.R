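#' Tally copy-number states of one chromosome
#'
#' Counts how many cells carry each copy-number state of one chromosome,
#' over non-missing entries only. This tally backs the instability index
#' (through the fraction of cells away from the modal state) and the
#' heterogeneity score (through the ranked state counts).
#'
#' When two states tie for modal, the reported modal state is the one closest
#' to the euploid copy number, then the smaller state. Only the modal cell
#' count enters any statistic, so the tie rule affects labels only.
#'
#' @param x a [cnv_matrix()]
#' @param chromosome chromosome label present in `x`
#' @param ref euploid reference (see [euploid_reference()]); `NULL` for 2
#' @return list of class `chrom_tally`: `chromosome`, `state_counts` (named
#'   by state), `n_cells`, `modal_state`, `modal_count`, `nonmodal_fraction`,
#'   `n_states`.
#' @examples
#' m <- cnv_matrix(cbind(`1` = c(2, 2, 2, 3)))
#' tally_chromosome(m, "1")
#' @export
tally_chromosome <- function(x, chromosome, ref = NULL) {
  stopifnot(inherits(x, "cnv_matrix"))
  chromosome <- normalize_chrom(chromosome)
  if (!chromosome %in% colnames(x))
    stop("chromosome not in matrix: ", chromosome)
  e <- resolve_reference(x, ref)[[chromosome]]
  v <- unclass(x)[, chromosome]
  v <- v[!is.na(v)]
  if (length(v) == 0L)
    stop("all entries missing for chromosome ", chromosome)
  tab <- table(v)
  states <- as.integer(names(tab))
  counts <- as.integer(tab)
  top <- which(counts == max(counts))
  modal_state <- states[top][order(abs(states[top] - e), states[top])][1L]
  structure(list(chromosome = chromosome,
                 state_counts = stats::setNames(counts, states),
                 n_cells = length(v),
                 modal_state = modal_state,
                 modal_count = max(counts),
                 nonmodal_fraction = 1 - max(counts) / length(v),
                 n_states = length(counts)),
            class = "chrom_tally")
}

#' @export
print.chrom_tally <- function(x, ...) {
  cat(sprintf("chromosome %s: %d cells, %d state%s, modal %d (%d cells), %.1f%% non-modal\n",
              x$chromosome, x$n_cells, x$n_states,
              if (x$n_states == 1L) "" else "s",
              x$modal_state, x$modal_count, 100 * x$nonmodal_fraction))
  invisible(x)
}

#' Instability index
#'
#' Mean, across chromosomes, of the percentage of cells whose copy number
#' deviates from the modal (most frequent) state of that chromosome:
#' `I = 100 * sum_t(k_t) / T` with `k_t = 1 - modal_count_t / N_t`. It is a
#' population-level measure: a lone cell is always at its own modal state,
#' so `I = 0` for a single cell.
#'
#' @inheritParams tally_chromosome
#' @return non-negative scalar, in percent; bounded above by
#'   `100 * (1 - 1/N)`.
#' @examples
#' m <- cnv_matrix(cbind(a = c(2, 2, 2, 3), b = c(2, 2, 2, 2)))
#' instability_index(m)  # (0.25 + 0) / 2 * 100 = 12.5
#' @export
instability_index <- function(x, ref = NULL) {
  stopifnot(inherits(x, "cnv_matrix"))
  k <- vapply(colnames(x),
              function(ch) tally_chromosome(x, ch, ref)$nonmodal_fraction,
              numeric(1))
  100 * mean(k)
}

#' ANCA: average number of copy-number alterations per cell
#'
#' `A = sum_n(q_n) / N`, where `q_n` is the number of observed chromosomes of
#' cell `n` whose copy number differs from the euploid reference. Cells with
#' no observed entries are dropped with a warning.
#'
#' @inheritParams tally_chromosome
#' @return non-negative scalar in `[0, T]`
#' @export
anca <- function(x, ref = NULL) {
  stopifnot(inherits(x, "cnv_matrix"))
  e <- resolve_reference(x, ref)
  m <- unclass(x)
  q <- rowSums(sweep(m, 2L, e, `!=`), na.rm = TRUE)
  obs <- rowSums(!is.na(m))
  if (any(obs == 0L)) {
    warning(sprintf("%d cell(s) with no observed entries dropped", sum(obs == 0L)))
    q <- q[obs > 0L]
  }
  mean(q)
}

#' Normalized ANCA
#'
#' [anca()] divided by the number of chromosomes measured, `AN = A / T`,
#' so panels with different probe counts (e.g. 2-probe FISH vs genome-wide
#' sc-WGS) are comparable; `AN` lies in `[0, 1]`.
#'
#' @inheritParams tally_chromosome
#' @export
normalized_anca <- function(x, ref = NULL) {
  anca(x, ref) / ncol(x)
}

#' Aneuploidy score
#'
#' Mean absolute deviation of observed copy numbers from the euploid
#' reference, over all observed (cell, chromosome) entries:
#' `D = sum |c_nt - e_t| / n_observed` (equal to `(1/(T N)) sum_n sum_t |...|`
#' when no entries are missing). The only statistic here sensitive to the
#' magnitude of copy-number change.
#'
#' @inheritParams tally_chromosome
#' @return non-negative scalar
#' @export
aneuploidy_score <- function(x, ref = NULL) {
  stopifnot(inherits(x, "cnv_matrix"))
  e <- resolve_reference(x, ref)
  dev <- abs(sweep(unclass(x), 2L, e, `-`))
  sum(dev, na.rm = TRUE) / sum(!is.na(dev))
}

#' Heterogeneity score
#'
#' Rank-weighted spread of copy-number states. Per chromosome the state
#' counts are sorted descending, `m_0 >= m_1 >= ... >= m_{S-1}`, and weighted
#' by their rank: `H_t = sum_f f * m_{f,t} / N_t`; the score is the mean of
#' `H_t` over chromosomes (equal to `(1/(T N)) sum_t sum_f f * m_{f,t}` on a
#' complete matrix). `H = 0` when all cells agree on every chromosome and is
#' maximal, `(N - 1) / 2`, when every cell carries a distinct state. Unlike
#' the aneuploidy score it ignores the identity of the states, only their
#' frequency spectrum matters.
#'
#' @inheritParams tally_chromosome
#' @export
heterogeneity_score <- function(x, ref = NULL) {
  stopifnot(inherits(x, "cnv_matrix"))
  h <- vapply(colnames(x), function(ch) {
    tl <- tally_chromosome(x, ch, ref)
    m <- sort(tl$state_counts, decreasing = TRUE)
    sum((seq_along(m) - 1L) * m) / tl$n_cells
  }, numeric(1))
  mean(h)
}

#' Classify single cells as diploid, polyploid, or aneuploid
#'
#' A cell is *euploid-diploid* when every observed count equals its euploid
#' reference; *polyploid* when the counts are a uniform integer multiple
#' (>= 2) of the reference across all observed chromosomes (whole-genome
#' duplication: e.g. uniform 4 against reference 2); *aneuploid* otherwise.
#' Uniform counts below the reference (e.g. an all-1 haploid cell against
#' reference 2) are aneuploid: polyploidy denotes an integer-valued increase.
#'
#' @inheritParams tally_chromosome
#' @return character vector of length `nrow(x)` with values `"diploid"`,
#'   `"polyploid"`, `"aneuploid"`, or `NA` for cells with no observed entry.
#' @examples
#' m <- cnv_matrix(rbind(c(2, 2), c(4, 4), c(2, 3)))
#' classify_cells(m)
#' @export
classify_cells <- function(x, ref = NULL) {
  stopifnot(inherits(x, "cnv_matrix"))
  e <- resolve_reference(x, ref)
  m <- unclass(x)
  vapply(seq_len(nrow(m)), function(i) {
    v <- m[i, ]
    obs <- which(!is.na(v))
    if (!length(obs)) return(NA_character_)
    v <- v[obs]; ei <- e[obs]
    if (all(v == ei)) return("diploid")
    # uniform integer multiple k >= 2 of the reference; chromosomes with
    # reference 0 must stay 0 under any whole-genome multiplication
    pos <- ei > 0L
    if (any(pos) && all(v[!pos] == 0L)) {
      k <- v[pos] / ei[pos]
      if (all(k == k[1L]) && k[1L] >= 2 && k[1L] == round(k[1L]))
        return("polyploid")
    }
    "aneuploid"
  }, character(1))
}

#' Ploidy-class proportions
#'
#' Proportions of cells classified diploid, polyploid and aneuploid by
#' [classify_cells()]; the three components sum to one.
#'
#' @inheritParams tally_chromosome
#' @return named numeric vector `c(P_A, P_D, P_P)`
#' @examples
#' m <- cnv_matrix(rbind(c(2, 2), c(4, 4), c(2, 3)))
#' ploidy_proportions(m)
#' @export
ploidy_proportions <- function(x, ref = NULL) {
  cls <- classify_cells(x, ref)
  cls <- cls[!is.na(cls)]
  if (!length(cls)) stop("no classifiable cells")
  n <- length(cls)
  c(P_A = sum(cls == "aneuploid") / n,
    P_D = sum(cls == "diploid") / n,
    P_P = sum(cls == "polyploid") / n)
}

#' Summarize one group of cells
#'
#' Computes all six population statistics for one stratum: instability index
#' `I`, ANCA `A`, normalized ANCA `AN`, aneuploidy score `D`, heterogeneity
#' score `H`, and the ploidy proportions `(P_A, P_D, P_P)`.
#'
#' @inheritParams tally_chromosome
#' @param group group label to record
#' @return list of class `group_stats` with fields `group`, `source`,
#'   `n_cells`, `n_chromosomes`, `I`, `ANCA`, `normANCA`, `D`, `H`, `P_A`,
#'   `P_D`, `P_P`.
#' @export
summarize_group <- function(x, ref = NULL, group = "all") {
  stopifnot(inherits(x, "cnv_matrix"))
  p <- ploidy_proportions(x, ref)
  a <- anca(x, ref)
  structure(list(group = group, source = cnv_source(x),
                 n_cells = nrow(x), n_chromosomes = ncol(x),
                 I = instability_index(x, ref),
                 ANCA = a, normANCA = a / ncol(x),
                 D = aneuploidy_score(x, ref),
                 H = heterogeneity_score(x, ref),
                 P_A = p[["P_A"]], P_D = p[["P_D"]], P_P = p[["P_P"]]),
            class = "group_stats")
}

#' @export
print.group_stats <- function(x, digits = 4, ...) {
  cat(sprintf("Group '%s' (%s): %d cells, %d chromosomes\n",
              x$group, x$source, x$n_cells, x$n_chromosomes))
  vals <- unlist(x[c("I", "ANCA", "normANCA", "D", "H", "P_A", "P_D", "P_P")])
  print(round(vals, digits))
  invisible(x)
}

#' @export
as.data.frame.group_stats <- function(x, ...) {
  data.frame(group = x$group, source = x$source, n_cells = x$n_cells,
             n_chromosomes = x$n_chromosomes, I = x$I, ANCA = x$ANCA,
             normANCA = x$normANCA, D = x$D, H = x$H,
             P_A = x$P_A, P_D = x$P_D, P_P = x$P_P,
             stringsAsFactors = FALSE)
}

#' Per-chromosome statistics for one group
#'
#' The per-cell statistics (ANCA, normalized ANCA, aneuploidy score,
#' heterogeneity score) recomputed chromosome by chromosome (T = 1), to
#' identify the chromosomes most perturbed within a group. The instability
#' index and ploidy proportions are population-of-cells features and are not
#' defined per chromosome. On a complete matrix the mean over chromosomes of
#' the per-chromosome `D` (or `H`) equals the group aggregate.
#'
#' @inheritParams summarize_group
#' @return data frame with one row per chromosome: `group`, `source`,
#'   `chromosome`, `n_cells`, `ANCA`, `normANCA`, `D`, `H`.
#' @export
summarize_chromosomes <- function(x, ref = NULL, group = "all") {
  stopifnot(inherits(x, "cnv_matrix"))
  rows <- lapply(colnames(x), function(ch) {
    sub <- x[, ch, drop = FALSE]
    obs <- rowSums(!is.na(sub)) > 0L
    sub <- sub[obs, , drop = FALSE]
    a <- suppressWarnings(anca(sub, resolve_reference(x, ref)[ch]))
    data.frame(group = group, source = cnv_source(x), chromosome = ch,
               n_cells = nrow(sub), ANCA = a, normANCA = a,
               D = aneuploidy_score(sub, resolve_reference(x, ref)[ch]),
               H = heterogeneity_score(sub),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Summarize a full study: all groups, group and chromosome level
#'
#' Stratifies the matrix by the group key and computes the group-level and
#' chromosome-level summary tables that head the analysis workflow.
#'
#' @inheritParams validate_matrix
#' @param ref euploid reference (see [euploid_reference()]); `NULL` for 2
#' @return list of class `study_summary` with data frames `groups` (one row
#'   per group) and `chromosomes` (one row per group x chromosome).
#' @examples
#' m <- cnv_matrix(rbind(c(2, 2), c(2, 3), c(4, 4), c(2, 2)))
#' summarize_study(m, group_key(rownames(m), c("A", "A", "B", "B")))
#' @export
summarize_study <- function(x, key, ref = NULL) {
  strata <- stratify(x, key)
  g <- do.call(rbind, lapply(names(strata), function(gname)
    as.data.frame(summarize_group(strata[[gname]], ref, group = gname))))
  ch <- do.call(rbind, lapply(names(strata), function(gname)
    summarize_chromosomes(strata[[gname]], ref, group = gname)))
  rownames(g) <- rownames(ch) <- NULL
  structure(list(groups = g, chromosomes = ch), class = "study_summary")
}

#' @export
print.study_summary <- function(x, digits = 4, ...) {
  cat("Group-level summary:\n")
  print(format(x$groups, digits = digits), row.names = FALSE)
  cat("\nChromosome-level summary:\n")
  print(format(x$chromosomes, digits = digits), row.names = FALSE)
  invisible(x)
}

#' Write study summary tables as delimited text
#' @param x a `study_summary`
#' @param group_path,chromosome_path output paths (`NULL` to skip one)
#' @param sep field delimiter
#' @return invisibly, the paths written
#' @export
write_summary <- function(x, group_path, chromosome_path = NULL, sep = ",") {
  stopifnot(inherits(x, "study_summary"))
  utils::write.table(full_precision(x$groups), group_path, sep = sep,
                     row.names = FALSE, quote = FALSE)
  if (!is.null(chromosome_path))
    utils::write.table(full_precision(x$chromosomes), chromosome_path,
                       sep = sep, row.names = FALSE, quote = FALSE)
  invisible(c(group_path, chromosome_path))
}

# serialize doubles with 17 significant digits so that reading the table back
# reproduces every statistic bit-for-bit
full_precision <- function(df) {
  for (j in seq_along(df))
    if (is.double(df[[j]])) df[[j]] <- sprintf("%.17g", df[[j]])
  df
}
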