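#' Bivariate percentage grid for two chromosomes
#'
#' Tabulates the joint copy-number distribution of two chromosomes across the
#' population: each grid square holds the percentage of cells observed with
#' that pair of counts (the display published as the bivariate percentage
#' heatmap for FISH data). Cells missing either count are excluded
#' (pairwise-complete); the axes cover the observed states of each
#' chromosome plus its euploid state, so the euploid gridline always exists
#' and can be drawn bold.
#'
#' @inheritParams tally_chromosome
#' @param chrom_x,chrom_y chromosome labels present in `x`
#' @return list of class `bivariate_grid`: `chrom_x`, `chrom_y`, `states_x`,
#'   `states_y` (sorted axis states), `percent` (matrix, rows = states_x,
#'   columns = states_y, summing to 100), `n_cells` (jointly observed), and
#'   `euploid` (`c(e_x, e_y)`).
#' @examples
#' m <- cnv_matrix(rbind(c(2, 2), c(2, 2), c(2, 3), c(3, 3)),
#'                 chromosomes = c("9", "12"))
#' bivariate_grid(m, "9", "12")
#' @export
bivariate_grid <- function(x, chrom_x, chrom_y, ref = NULL) {
  stopifnot(inherits(x, "cnv_matrix"))
  chrom_x <- normalize_chrom(chrom_x); chrom_y <- normalize_chrom(chrom_y)
  for (ch in c(chrom_x, chrom_y))
    if (!ch %in% colnames(x)) stop("chromosome not in matrix: ", ch)
  e <- resolve_reference(x, ref)
  vx <- unclass(x)[, chrom_x]; vy <- unclass(x)[, chrom_y]
  ok <- !is.na(vx) & !is.na(vy)
  if (!any(ok))
    stop("no cells jointly observed for chromosomes ", chrom_x, " and ", chrom_y)
  vx <- vx[ok]; vy <- vy[ok]
  states_x <- sort(unique(c(vx, e[[chrom_x]])))
  states_y <- sort(unique(c(vy, e[[chrom_y]])))
  tab <- table(factor(vx, levels = states_x), factor(vy, levels = states_y))
  percent <- 100 * unclass(tab) / sum(tab)
  dimnames(percent) <- list(states_x, states_y)
  structure(list(chrom_x = chrom_x, chrom_y = chrom_y,
                 states_x = states_x, states_y = states_y,
                 percent = percent, n_cells = sum(ok),
                 euploid = c(e[[chrom_x]], e[[chrom_y]])),
            class = "bivariate_grid")
}

#' @export
print.bivariate_grid <- function(x, digits = 1, ...) {
  cat(sprintf("Bivariate percentage grid: chr%s vs chr%s, %d cells\n",
              x$chrom_x, x$chrom_y, x$n_cells))
  print(round(x$percent, digits))
  invisible(x)
}

#' All pairwise bivariate grids
#'
#' One [bivariate_grid()] per unordered chromosome pair, `choose(T, 2)` grids
#' in total (a 4-chromosome panel yields 6), each pair once with the
#' lower-ordered chromosome on the x axis.
#'
#' @inheritParams tally_chromosome
#' @return named list of `bivariate_grid` objects (`"x:y"` names)
#' @export
all_pairwise_grids <- function(x, ref = NULL) {
  stopifnot(inherits(x, "cnv_matrix"))
  if (ncol(x) < 2L)
    stop("pairwise grids need at least 2 chromosomes")
  chroms <- order_chromosomes(colnames(x))
  pairs <- utils::combn(chroms, 2L)
  out <- lapply(seq_len(ncol(pairs)), function(i)
    bivariate_grid(x, pairs[1L, i], pairs[2L, i], ref))
  stats::setNames(out, paste(pairs[1L, ], pairs[2L, ], sep = ":"))
}

#' @export
plot.bivariate_grid <- function(x, col = NULL, main = NULL, ...) {
  sx <- (min(x$states_x) - 1L):(max(x$states_x) + 1L)
  sy <- (min(x$states_y) - 1L):(max(x$states_y) + 1L)
  z <- matrix(0, length(sx), length(sy))
  z[match(x$states_x, sx), match(x$states_y, sy)] <- x$percent
  if (is.null(col))
    col <- grDevices::colorRampPalette(c("white", "#fee0d2", "#de2d26"))(64)
  if (is.null(main))
    main <- sprintf("chr%s vs chr%s (n = %d)", x$chrom_x, x$chrom_y, x$n_cells)
  graphics::image(sx, sy, z, col = col, zlim = c(0, max(z, 1)),
                  xlab = paste("chromosome", x$chrom_x, "copies"),
                  ylab = paste("chromosome", x$chrom_y, "copies"),
                  main = main, axes = FALSE, ...)
  graphics::axis(1, at = setdiff(sx, x$euploid[1L]))
  graphics::axis(1, at = x$euploid[1L], font.axis = 2)
  graphics::axis(2, at = setdiff(sy, x$euploid[2L]))
  graphics::axis(2, at = x$euploid[2L], font.axis = 2)
  graphics::abline(v = x$euploid[1L] + c(-0.5, 0.5),
                   h = x$euploid[2L] + c(-0.5, 0.5), lwd = 2)
  nz <- which(z > 0, arr.ind = TRUE)
  if (nrow(nz))
    graphics::text(sx[nz[, 1L]], sy[nz[, 2L]],
                   sprintf("%.1f", z[nz]), cex = 0.8)
  graphics::box()
  invisible(x)
}

#' Scatter-plot data: aneuploidy vs heterogeneity score
#'
#' One point per (group, source) stratum with the aneuploidy score on the x
#' axis and the heterogeneity score on the y axis; groups are encoded by
#' color and data sources by plotting symbol, so FISH and sc-WGS strata of
#' the same treatment can be compared on one panel.
#'
#' @param group_stats a `study_summary` (see [summarize_study()]) or its
#'   `groups` data frame; data frames from several studies may be
#'   `rbind`-ed first to pool sources.
#' @return data frame of class `dh_scatter`: `group`, `source`, `x` (D),
#'   `y` (H)
#' @export
scatter_dh <- function(group_stats) {
  df <- if (inherits(group_stats, "study_summary")) group_stats$groups
        else as.data.frame(group_stats)
  stopifnot(all(c("group", "source", "D", "H") %in% colnames(df)))
  structure(data.frame(group = df$group, source = df$source,
                       x = df$D, y = df$H, stringsAsFactors = FALSE),
            class = c("dh_scatter", "data.frame"))
}

#' @export
plot.dh_scatter <- function(x, main = "Aneuploidy vs heterogeneity", ...) {
  groups <- unique(x$group); sources <- unique(x$source)
  cols <- stats::setNames(grDevices::hcl.colors(max(3L, length(groups)),
                                                "Dark 3")[seq_along(groups)],
                          groups)
  pchs <- stats::setNames(c(16, 17, 15, 18)[seq_along(sources)], sources)
  graphics::plot(x$x, x$y, col = cols[x$group], pch = pchs[x$source],
                 cex = 1.6, xlab = "aneuploidy score (D)",
                 ylab = "heterogeneity score (H)", main = main, ...)
  graphics::legend("topleft", bty = "n",
                   legend = c(groups, sources),
                   col = c(cols, rep("black", length(sources))),
                   pch = c(rep(16, length(groups)), pchs))
  invisible(x)
}

#' Ternary-plot data: ploidy-class composition per stratum
#'
#' Barycentric coordinates are the ploidy proportions themselves, one point
#' per (group, source) stratum in the diploid / polyploid / aneuploid
#' simplex; cartesian projections (`px`, `py`) place the diploid vertex at
#' the origin, polyploid at (1, 0) and aneuploid at the apex.
#'
#' @inheritParams scatter_dh
#' @param tol tolerance on `P_A + P_D + P_P = 1`
#' @return data frame of class `ternary_coords`: `group`, `source`, `P_D`,
#'   `P_P`, `P_A`, `px`, `py`
#' @export
ternary_coordinates <- function(group_stats, tol = 1e-6) {
  df <- if (inherits(group_stats, "study_summary")) group_stats$groups
        else as.data.frame(group_stats)
  stopifnot(all(c("group", "source", "P_A", "P_D", "P_P") %in% colnames(df)))
  s <- df$P_A + df$P_D + df$P_P
  if (any(abs(s - 1) > tol))
    stop("ploidy proportions do not sum to 1 (max deviation ",
         format(max(abs(s - 1))), ")")
  structure(data.frame(group = df$group, source = df$source,
                       P_D = df$P_D, P_P = df$P_P, P_A = df$P_A,
                       px = df$P_P + df$P_A / 2,
                       py = df$P_A * sqrt(3) / 2,
                       stringsAsFactors = FALSE),
            class = c("ternary_coords", "data.frame"))
}

#' @export
plot.ternary_coords <- function(x, main = "Ploidy composition", ...) {
  graphics::plot(NA, xlim = c(-0.08, 1.08), ylim = c(-0.1, sqrt(3) / 2 + 0.08),
                 axes = FALSE, xlab = "", ylab = "", main = main, asp = 1, ...)
  graphics::polygon(c(0, 1, 0.5), c(0, 0, sqrt(3) / 2))
  graphics::text(c(0, 1, 0.5), c(-0.05, -0.05, sqrt(3) / 2 + 0.05),
                 c("diploid", "polyploid", "aneuploid"))
  groups <- unique(x$group); sources <- unique(x$source)
  cols <- stats::setNames(grDevices::hcl.colors(max(3L, length(groups)),
                                                "Dark 3")[seq_along(groups)],
                          groups)
  pchs <- stats::setNames(c(16, 17, 15, 18)[seq_along(sources)], sources)
  graphics::points(x$px, x$py, col = cols[x$group], pch = pchs[x$source],
                   cex = 1.6)
  invisible(x)
}

#' Copy-number heatmap data
#'
#' Orders cells into contiguous per-group row blocks over the original
#' counts, the layout used for SKY and sc-WGS copy-number heatmaps. Values
#' are identical to the matrix counts; missing entries stay `NA` and are
#' rendered as their own category.
#'
#' @inheritParams validate_matrix
#' @return list of class `cn_heatmap`: `counts` (reordered matrix), `group`
#'   (per-row labels), `source`
#' @export
copy_number_heatmap_data <- function(x, key) {
  strata <- stratify(x, key)
  counts <- do.call(rbind, lapply(strata, unclass))
  structure(list(counts = counts,
                 group = rep(names(strata), vapply(strata, nrow, integer(1))),
                 source = cnv_source(x)),
            class = "cn_heatmap")
}

#' @export
plot.cn_heatmap <- function(x, main = NULL, ...) {
  m <- x$counts
  if (is.null(main)) main <- sprintf("Copy-number heatmap (%s)", x$source)
  states <- 0:max(m, 2, na.rm = TRUE)
  pal <- grDevices::hcl.colors(length(states), "Blue-Red 2")
  z <- t(m)[, rev(seq_len(nrow(m))), drop = FALSE]
  graphics::image(seq_len(ncol(m)), seq_len(nrow(m)), z,
                  col = pal, zlim = range(states), axes = FALSE,
                  xlab = "chromosome", ylab = "cells (grouped)", main = main, ...)
  graphics::axis(1, at = seq_len(ncol(m)), labels = colnames(m), las = 2,
                 cex.axis = 0.7)
  blocks <- rev(cumsum(rev(table(factor(x$group, levels = unique(x$group))))))
  graphics::abline(h = nrow(m) - cumsum(table(factor(x$group,
                                                     levels = unique(x$group)))) +
                     0.5, lwd = 2)
  mids <- tapply(rev(seq_len(nrow(m))), x$group, mean)
  graphics::axis(4, at = mids[unique(x$group)], labels = unique(x$group),
                 tick = FALSE, las = 2, cex.axis = 0.8)
  graphics::box()
  invisible(x)
}

#' @export
plot.pairwise_table <- function(x, main = NULL, ...) {
  v <- attr(x, "value", exact = TRUE)
  if (is.null(main)) main <- sprintf("Pairwise permutation %s-values", v)
  n <- nrow(x)
  z <- unclass(x); attributes(z) <- attributes(z)["dim"]
  graphics::image(seq_len(n), seq_len(n), z[, rev(seq_len(n)), drop = FALSE],
                  col = grDevices::colorRampPalette(c("#de2d26", "white"))(64),
                  zlim = c(0, 1), axes = FALSE, xlab = "", ylab = "",
                  main = main, ...)
  graphics::axis(1, at = seq_len(n), labels = rownames(x), las = 2)
  graphics::axis(2, at = seq_len(n), labels = rev(colnames(x)), las = 2)
  for (i in seq_len(n)) for (j in seq_len(n)) if (!is.na(x[i, j]))
    graphics::text(i, n - j + 1L, sprintf("%.3f", x[i, j]), cex = 0.9)
  graphics::box()
  invisible(x)
}

#' Build the standard figure set for a study
#'
#' Assembles, in deterministic order, the figures of the analysis report:
#' the D-vs-H scatter, the ternary ploidy-composition plot, all pairwise
#' bivariate percentage grids, and the copy-number heatmap.
#'
#' @inheritParams summarize_study
#' @return named, ordered list of plottable objects for [export_pdf()]
#' @export
build_figures <- function(x, key, ref = NULL) {
  summ <- summarize_study(x, key, ref)
  figs <- list(scatter = scatter_dh(summ),
               ternary = ternary_coordinates(summ))
  if (ncol(x) >= 2L) {
    grids <- all_pairwise_grids(x, ref)
    names(grids) <- paste0("grid_", gsub(":", "_", names(grids)))
    figs <- c(figs, grids)
  }
  figs$heatmap <- copy_number_heatmap_data(x, key)
  figs
}

#' Export figures to a multi-page PDF
#'
#' Renders each figure on its own page, in list order; rendering is
#' deterministic for identical inputs.
#'
#' @param figures non-empty list of objects with `plot` methods (as returned
#'   by [build_figures()]), or zero-argument functions
#' @param path output PDF path
#' @param width,height page size in inches
#' @return `path`, invisibly
#' @export
export_pdf <- function(figures, path, width = 7, height = 7) {
  if (!is.list(figures) || length(figures) == 0L)
    stop("figures must be a non-empty list")
  grDevices::pdf(path, width = width, height = height, onefile = TRUE)
  on.exit(grDevices::dev.off(), add = TRUE)
  for (f in figures) {
    if (is.function(f)) f() else graphics::plot(f)
  }
  invisible(path)
}
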