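# Precompute everything the permutation kernel needs so that evaluating a
# group statistic on an index subset is cheap: per-cell deviation sums for D
# and ANCA, and a global integer coding of (chromosome, state) pairs so that
# one tabulate() per group yields every per-chromosome state tally.
perm_precompute <- function(x, ref = NULL) {
  m <- unclass(x)
  e <- resolve_reference(x, ref)
  dev <- abs(sweep(m, 2L, e, `-`))
  ncol_t <- ncol(m)
  states <- lapply(seq_len(ncol_t), function(t) sort(unique(m[!is.na(m[, t]), t])))
  sizes <- lengths(states)
  offsets <- cumsum(c(0L, sizes[-ncol_t]))
  codes <- matrix(0L, nrow(m), ncol_t)
  for (t in seq_len(ncol_t)) {
    idx <- match(m[, t], states[[t]])
    idx[is.na(idx)] <- -offsets[t]  # NA -> code 0, ignored by tabulate
    codes[, t] <- offsets[t] + idx
  }
  list(n = nrow(m), T = ncol_t,
       dev_row = rowSums(dev, na.rm = TRUE),
       nobs_row = rowSums(!is.na(m)),
       q_row = rowSums(sweep(m, 2L, e, `!=`), na.rm = TRUE),
       codes = codes, nbins = sum(sizes),
       bin_lo = offsets + 1L, bin_hi = offsets + sizes)
}

# Group statistic on a row-index subset. `stat` is one of
# I, ANCA, normANCA, D, H. Chromosomes with no observed entry in the subset
# are excluded from the I/H means.
perm_group_stat <- function(pc, idx, stat) {
  if (stat == "D") {
    return(sum(pc$dev_row[idx]) / sum(pc$nobs_row[idx]))
  }
  if (stat == "ANCA" || stat == "normANCA") {
    a <- sum(pc$q_row[idx]) / sum(pc$nobs_row[idx] > 0L)
    return(if (stat == "ANCA") a else a / pc$T)
  }
  tb <- tabulate(pc$codes[idx, ], nbins = pc$nbins)
  acc <- 0
  used <- 0L
  for (t in seq_len(pc$T)) {
    m <- tb[pc$bin_lo[t]:pc$bin_hi[t]]
    nt <- sum(m)
    if (nt == 0L) next
    used <- used + 1L
    acc <- acc + if (stat == "I") {
      1 - max(m) / nt
    } else {  # H
      ms <- sort.int(m, decreasing = TRUE)
      sum((seq_along(ms) - 1L) * ms) / nt
    }
  }
  if (used == 0L) return(NA_real_)
  out <- acc / used
  if (stat == "I") 100 * out else out
}

#' Permutation test of group differences in an aneuploidy statistic
#'
#' Tests, for every unordered pair of groups, the null hypothesis that the
#' groups share the same value of the chosen statistic. Under the null the
#' group labels are exchangeable, so cell labels are shuffled jointly across
#' all groups (group sizes preserved), the statistic is recomputed per group
#' after each shuffle, and each pair's permuted absolute difference is
#' compared with the observed one. P-values use the add-one convention
#' `p = (1 + #\{permuted >= observed\}) / (1 + B)`, so the smallest
#' attainable p with the default `B = 500` is `1/501` (about 0.002); they
#' are corrected across pairs by [bh_adjust()].
#'
#' @inheritParams summarize_study
#' @param statistic which statistic to permute: `"D"` (aneuploidy score),
#'   `"H"` (heterogeneity score), `"I"` (instability index), `"ANCA"`, or
#'   `"normANCA"`
#' @param n_perm number of permutations `B` (default 500)
#' @param seed integer seed for the permutation stream; identical seed and
#'   inputs give identical p-values
#' @return object of class `perm_test`: data frame `table` with columns
#'   `group_a`, `group_b`, `statistic`, `observed_diff`, `p`, `q`, plus
#'   fields `statistic`, `n_perm`, `seed`, `group_values` (observed per-group
#'   statistics), and `alpha` (0.05 reporting threshold).
#' @examples
#' set.seed(1)
#' pop <- generate_group_study(list(
#'   A = population_spec(n_cells = 20, missegregation_rate = 0),
#'   B = population_spec(n_cells = 20, missegregation_rate = 0.4)), seed = 1)
#' permutation_test(pop$matrix, pop$key, "D", n_perm = 99, seed = 7)
#' @export
permutation_test <- function(x, key, statistic = c("D", "H", "I", "ANCA",
                                                   "normANCA"),
                             n_perm = 500L, seed = NULL, ref = NULL) {
  statistic <- match.arg(statistic)
  stopifnot(n_perm >= 1L)
  strata <- stratify(x, key)
  if (length(strata) < 2L)
    stop("permutation testing needs at least 2 groups")
  labels <- rep(names(strata), vapply(strata, nrow, integer(1)))
  cells <- unlist(lapply(strata, rownames), use.names = FALSE)
  sub <- x[cells, , drop = FALSE]
  pc <- perm_precompute(sub, ref)
  grp <- factor(labels, levels = names(strata))
  idx_by_group <- split(seq_along(labels), grp)

  observed <- vapply(idx_by_group, function(i) perm_group_stat(pc, i, statistic),
                     numeric(1))
  pairs <- utils::combn(names(strata), 2L)
  obs_diff <- apply(pairs, 2L, function(p) abs(observed[[p[1L]]] - observed[[p[2L]]]))

  if (!is.null(seed)) set.seed(seed)
  n <- pc$n
  sizes <- lengths(idx_by_group)
  bounds <- cumsum(sizes)
  starts <- c(1L, bounds[-length(bounds)] + 1L)
  exceed <- numeric(ncol(pairs))
  for (b in seq_len(n_perm)) {
    perm <- sample.int(n)
    stats_b <- vapply(seq_along(sizes), function(g)
      perm_group_stat(pc, perm[starts[g]:bounds[g]], statistic), numeric(1))
    diffs_b <- apply(pairs, 2L, function(p)
      abs(stats_b[match(p[1L], names(strata))] -
            stats_b[match(p[2L], names(strata))]))
    exceed <- exceed + (diffs_b >= obs_diff - 1e-12)
  }
  p <- (1 + exceed) / (1 + n_perm)
  q <- bh_adjust(p)
  tab <- data.frame(group_a = pairs[1L, ], group_b = pairs[2L, ],
                    statistic = statistic, observed_diff = obs_diff,
                    p = p, q = q, n_perm = n_perm,
                    stringsAsFactors = FALSE)
  structure(list(table = tab, statistic = statistic, n_perm = n_perm,
                 seed = seed, group_values = observed, alpha = 0.05),
            class = "perm_test")
}

#' @export
print.perm_test <- function(x, digits = 4, ...) {
  cat(sprintf("Permutation test of %s (%d permutations%s)\n", x$statistic,
              x$n_perm,
              if (is.null(x$seed)) "" else paste0(", seed ", x$seed)))
  cat("Observed group values:\n")
  print(round(x$group_values, digits))
  tab <- x$table
  tab$signif <- ifelse(tab$q <= x$alpha, "*", "")
  print(format(tab, digits = digits), row.names = FALSE)
  cat(sprintf("Significance threshold: q <= %.2f\n", x$alpha))
  invisible(x)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate correction: with p-values sorted ascending,
#' `q_(i) = min_(j >= i) (m / j) p_(j)`, capped at 1 and mapped back to the
#' input order. Wraps [stats::p.adjust()] after validating that each p lies
#' in (0, 1].
#'
#' @param p numeric vector of p-values in (0, 1]
#' @return q-values in the input order
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03))
#' bh_adjust(c(0.04, 0.9))
#' @export
bh_adjust <- function(p) {
  if (!length(p)) return(numeric(0))
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1))
    stop("p-values must lie in (0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Pairwise significance table
#'
#' Arranges the pairwise permutation results as a square symmetric matrix of
#' p- (or q-) values, the tabular form behind the pairwise heatmap; the
#' diagonal is `NA`.
#'
#' @param result a [permutation_test()] result
#' @param value `"p"` or `"q"`
#' @return square numeric matrix with class `pairwise_table`; attribute
#'   `significant` is the logical matrix `value <= 0.05`, attribute `value`
#'   records which column was used.
#' @export
pairwise_heatmap_table <- function(result, value = c("p", "q")) {
  stopifnot(inherits(result, "perm_test"))
  value <- match.arg(value)
  groups <- names(result$group_values)
  m <- matrix(NA_real_, length(groups), length(groups),
              dimnames = list(groups, groups))
  for (i in seq_len(nrow(result$table))) {
    a <- result$table$group_a[i]; b <- result$table$group_b[i]
    m[a, b] <- m[b, a] <- result$table[[value]][i]
  }
  structure(m, significant = !is.na(m) & m <= result$alpha, value = value,
            class = c("pairwise_table", "matrix", "array"))
}

#' Write a permutation result table as delimited text
#' @param result a [permutation_test()] result
#' @param path output path
#' @param sep field delimiter
#' @return `path`, invisibly
#' @export
write_perm_table <- function(result, path, sep = ",") {
  stopifnot(inherits(result, "perm_test"))
  tab <- result$table
  tab$seed <- if (is.null(result$seed)) NA_integer_ else result$seed
  tab$alpha <- result$alpha
  utils::write.table(tab, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}
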