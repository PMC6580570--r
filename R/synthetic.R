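#' Specification of a synthetic cell population
#'
#' Describes a population of single cells with controllable ploidy structure,
#' used to exercise every statistic, test and plot without external data.
#' Each cell starts at the euploid reference, is whole-genome doubled with
#' probability `polyploid_fraction`, and then each (cell, chromosome) entry
#' independently gains or loses one copy with probability
#' `missegregation_rate` (direction equiprobable). Counts are clipped to
#' `[0, max_state]`.
#'
#' The defaults emulate a four-probe interphase FISH experiment on a
#' moderately unstable near-diploid population: 50 cells, 4 chromosomes,
#' euploid copy 2, a 10% per-chromosome missegregation probability and a 5%
#' whole-genome-doubling fraction.
#'
#' @param n_cells number of cells
#' @param chromosomes chromosome labels
#' @param euploid euploid copy number per chromosome (scalar or named vector)
#' @param missegregation_rate per-(cell, chromosome) probability of a one-copy
#'   gain or loss, in `[0, 1]`
#' @param polyploid_fraction probability a cell is whole-genome doubled
#'   before missegregation, in `[0, 1]`
#' @param max_state upper clip for copy numbers
#' @return list of class `population_spec`
#' @export
population_spec <- function(n_cells = 50L,
                            chromosomes = c("1", "2", "3", "4"),
                            euploid = 2L,
                            missegregation_rate = 0.1,
                            polyploid_fraction = 0.05,
                            max_state = 8L) {
  stopifnot(n_cells >= 1L,
            missegregation_rate >= 0, missegregation_rate <= 1,
            polyploid_fraction >= 0, polyploid_fraction <= 1,
            max_state >= 1L)
  chromosomes <- normalize_chrom(as.character(chromosomes))
  e <- if (length(euploid) == 1L)
    stats::setNames(rep(as.integer(euploid), length(chromosomes)), chromosomes)
  else stats::setNames(as.integer(euploid[chromosomes]), chromosomes)
  structure(list(n_cells = as.integer(n_cells), chromosomes = chromosomes,
                 euploid = e,
                 missegregation_rate = missegregation_rate,
                 polyploid_fraction = polyploid_fraction,
                 max_state = as.integer(max_state)),
            class = "population_spec")
}

#' Generate a synthetic cell population
#'
#' Draws a population from a [population_spec()]; deterministic under `seed`.
#'
#' @param spec a `population_spec`
#' @param seed integer seed (`NULL` to use the current random state)
#' @param source source tag for the resulting matrix
#' @param cell_prefix prefix for generated cell identifiers
#' @return a [cnv_matrix()] of `n_cells` x `length(chromosomes)` counts
#' @examples
#' generate_population(population_spec(n_cells = 5), seed = 1)
#' @export
generate_population <- function(spec, seed = NULL, source = "FISH",
                                cell_prefix = "cell") {
  stopifnot(inherits(spec, "population_spec"))
  if (!is.null(seed)) set.seed(seed)
  n <- spec$n_cells; t_ <- length(spec$chromosomes)
  base <- matrix(rep(spec$euploid, each = n), n, t_)
  doubled <- stats::runif(n) < spec$polyploid_fraction
  base[doubled, ] <- 2L * base[doubled, ]
  hit <- matrix(stats::runif(n * t_) < spec$missegregation_rate, n, t_)
  dir <- matrix(ifelse(stats::runif(n * t_) < 0.5, -1L, 1L), n, t_)
  counts <- base + hit * dir
  counts <- pmin(pmax(counts, 0L), spec$max_state)
  cnv_matrix(counts,
             cell_ids = sprintf("%s_%0*d", cell_prefix, nchar(n), seq_len(n)),
             chromosomes = spec$chromosomes, source = source)
}

#' Generate a multi-group synthetic study
#'
#' Concatenates one generated population per group, mirroring an experiment
#' with treatments of varying severity (e.g. Control / TreatmentA /
#' TreatmentB with increasing missegregation rates).
#'
#' @param specs named list of [population_spec()], one per group
#' @param seed integer seed; per-group draws use sub-seeds derived from it
#' @param source source tag for the combined matrix
#' @return list with elements `matrix` (a [cnv_matrix()]) and `key` (a
#'   [group_key()])
#' @examples
#' generate_group_study(list(
#'   Control = population_spec(missegregation_rate = 0),
#'   TreatmentA = population_spec(missegregation_rate = 0.1)), seed = 1)$key[1:3, ]
#' @export
generate_group_study <- function(specs, seed = NULL, source = "FISH") {
  stopifnot(is.list(specs), length(specs) >= 1L)
  if (is.null(names(specs)) || any(!nzchar(names(specs))))
    stop("specs must be a named list (names are the group labels)")
  if (!is.null(seed)) set.seed(seed)
  mats <- lapply(names(specs), function(g)
    generate_population(specs[[g]], seed = NULL, source = source,
                        cell_prefix = g))
  chroms <- unique(unlist(lapply(mats, colnames)))
  if (!all(vapply(mats, function(m) identical(colnames(m), chroms), logical(1))))
    stop("all group specs must share the same chromosome set")
  counts <- do.call(rbind, lapply(mats, unclass))
  ids <- rownames(counts)
  if (anyDuplicated(ids)) stop("duplicate cell ids across groups")
  m <- cnv_matrix(counts, cell_ids = ids, chromosomes = chroms, source = source)
  key <- group_key(ids, rep(names(specs), vapply(mats, nrow, integer(1))))
  list(matrix = m, key = key)
}

#' Write a synthetic population as a binned sc-WGS state table
#'
#' Expands whole-chromosome counts into a synthetic binned copy-number state
#' matrix: each chromosome is tiled with `n_bins` bins of `bin_size` base
#' pairs carrying that cell's uniform state, so that
#' [collapse_to_chromosomes()] recovers the input counts exactly. Together
#' with [write_fish_table()] and [counts_to_iscn()] this lets all three
#' readers be tested end-to-end on generated data.
#'
#' @param x a [cnv_matrix()]
#' @param path output path
#' @param n_bins bins per chromosome
#' @param bin_size bin width in base pairs
#' @return `path`, invisibly
#' @export
write_scwgs_fixture <- function(x, path, n_bins = 3L, bin_size = 1e6) {
  stopifnot(inherits(x, "cnv_matrix"))
  m <- unclass(x)
  bins <- do.call(rbind, lapply(colnames(m), function(ch)
    data.frame(chrom = ch, start = (seq_len(n_bins) - 1L) * bin_size,
               end = seq_len(n_bins) * bin_size, stringsAsFactors = FALSE)))
  states <- matrix(NA_integer_, nrow(bins), nrow(m),
                   dimnames = list(NULL, rownames(m)))
  for (j in seq_len(nrow(m)))
    states[, j] <- rep(m[j, ], each = n_bins)
  write_binned_table(structure(list(bins = bins, states = states),
                               class = "binned_table"), path)
}
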