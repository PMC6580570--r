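test_that("chromosome tallies count states, modal cells and spread", {
  m <- cnv_matrix(cbind(`1` = c(2, 2, 2, 3)))
  tl <- tally_chromosome(m, "1")
  expect_equal(tl$modal_count, 3L)
  expect_equal(tl$modal_state, 2L)
  expect_equal(tl$nonmodal_fraction, 0.25)
  expect_equal(tl$n_states, 2L)
  expect_equal(sum(tl$state_counts), tl$n_cells)

  uniform <- tally_chromosome(cnv_matrix(cbind(a = rep(2, 4))), "a")
  expect_equal(uniform$nonmodal_fraction, 0)
  expect_equal(uniform$n_states, 1L)

  distinct <- tally_chromosome(cnv_matrix(cbind(a = 1:4)), "a")
  expect_equal(distinct$modal_count, 1L)
  expect_equal(distinct$nonmodal_fraction, 0.75)
  expect_equal(distinct$n_states, 4L)
  # tie rule: modal state is the one closest to euploid, then smaller
  expect_equal(distinct$modal_state, 2L)
  tie <- tally_chromosome(cnv_matrix(cbind(a = c(1, 3, 1, 3))), "a")
  expect_equal(tie$modal_state, 1L)

  expect_error(tally_chromosome(cnv_matrix(cbind(a = c(NA, NA), b = c(2, 2))),
                                "a"), "all entries missing")
})

test_that("instability index is the mean percent of non-modal cells", {
  expect_equal(instability_index(
    cnv_matrix(cbind(a = c(2, 2, 2, 3), b = c(2, 2, 2, 2)))), 12.5)
  expect_equal(instability_index(cnv_matrix(matrix(2, 5, 3))), 0)
  # modal tie on a single chromosome: half the cells are non-modal
  expect_equal(instability_index(cnv_matrix(cbind(a = c(2, 3)))), 50)
})

test_that("ANCA counts altered chromosomes per cell", {
  expect_equal(anca(cnv_matrix(matrix(2, 3, 4))), 0)
  m <- cnv_matrix(rbind(c(2, 3), c(2, 2)))
  expect_equal(anca(m), 0.5)
  expect_equal(normalized_anca(m), 0.25)
  expect_equal(anca(cnv_matrix(rbind(c(4, 4)))), 2)
  # upper bound: every chromosome of every cell altered
  expect_equal(normalized_anca(cnv_matrix(matrix(3, 4, 5))), 1)
})

test_that("aneuploidy score is the mean absolute deviation from euploid", {
  expect_equal(aneuploidy_score(cnv_matrix(matrix(2, 3, 2))), 0)
  expect_equal(aneuploidy_score(cnv_matrix(rbind(c(2, 3), c(2, 2)))), 0.25)
  expect_equal(aneuploidy_score(cnv_matrix(rbind(c(4, 4), c(4, 4)))), 2)
})

test_that("heterogeneity score weights ranked state counts", {
  expect_equal(heterogeneity_score(cnv_matrix(cbind(a = c(2, 2, 3, 3)))), 0.5)
  expect_equal(heterogeneity_score(cnv_matrix(cbind(a = c(5, 1, 9, 3)))), 1.5)
  expect_equal(heterogeneity_score(cnv_matrix(matrix(2, 4, 3))), 0)
  # label invariance: depends only on the multiset of state counts
  expect_equal(heterogeneity_score(cnv_matrix(cbind(a = c(0, 0, 7, 7)))),
               heterogeneity_score(cnv_matrix(cbind(a = c(2, 2, 3, 3)))))
})

test_that("ploidy classification distinguishes diploid, polyploid, aneuploid", {
  m <- cnv_matrix(rbind(c(2, 2, 2, 2), c(4, 4, 4, 4), c(2, 3, 2, 2),
                        c(6, 6, 6, 6), c(1, 1, 1, 1), c(3, 3, 3, 3)))
  expect_identical(classify_cells(m),
                   c("diploid", "polyploid", "aneuploid", "polyploid",
                     "aneuploid", "aneuploid"))
  expect_equal(ploidy_proportions(cnv_matrix(rbind(c(2, 2), c(4, 4), c(2, 3)))),
               c(P_A = 1 / 3, P_D = 1 / 3, P_P = 1 / 3))
  expect_equal(ploidy_proportions(cnv_matrix(matrix(2, 5, 2))),
               c(P_A = 0, P_D = 1, P_P = 0))
  # sex-aware reference: 46,XX female cells are diploid with e_Y = 0
  f <- cnv_matrix(rbind(c(2, 2, 2, 0)), chromosomes = c("1", "2", "X", "Y"))
  e <- euploid_reference(colnames(f), sex = "XX")
  expect_identical(classify_cells(f, e), "diploid")
  # and its whole-genome doubling is polyploid
  f2 <- cnv_matrix(rbind(c(4, 4, 4, 0)), chromosomes = c("1", "2", "X", "Y"))
  expect_identical(classify_cells(f2, e), "polyploid")
})

test_that("group summary composes the individual statistics", {
  m <- cnv_matrix(rbind(c(2, 3), c(2, 2), c(4, 4)))
  gs <- summarize_group(m, group = "g1")
  expect_equal(gs$I, instability_index(m))
  expect_equal(gs$ANCA, anca(m))
  expect_equal(gs$normANCA, normalized_anca(m))
  expect_equal(gs$D, aneuploidy_score(m))
  expect_equal(gs$H, heterogeneity_score(m))
  expect_equal(gs$P_A + gs$P_D + gs$P_P, 1, tolerance = 1e-12)

  euploid <- summarize_group(cnv_matrix(matrix(2, 4, 3)))
  expect_equal(unlist(euploid[c("I", "ANCA", "normANCA", "D", "H")]),
               c(I = 0, ANCA = 0, normANCA = 0, D = 0, H = 0))
  expect_equal(euploid$P_D, 1)

  # one cell is always modal and single-state
  single <- summarize_group(cnv_matrix(rbind(c(5, 1, 7))))
  expect_equal(single$I, 0)
  expect_equal(single$H, 0)
})

test_that("per-chromosome summaries average back to the aggregate", {
  m <- cnv_matrix(rbind(c(2, 3), c(2, 2)))
  ch <- summarize_chromosomes(m)
  expect_equal(nrow(ch), 2L)
  # the all-euploid column scores zero everywhere
  row1 <- ch[ch$chromosome == colnames(m)[1L], ]
  expect_equal(row1$ANCA, 0)
  expect_equal(row1$D, 0)
  expect_equal(row1$H, 0)
  # the column with one gained copy in one of two cells
  row2 <- ch[ch$chromosome == colnames(m)[2L], ]
  expect_equal(row2$D, 0.5)
  expect_equal(row2$H, 0.5)

  set.seed(42)
  for (i in 1:20) {
    x <- random_matrix(sample(2:8, 1), sample(2:5, 1))
    chs <- summarize_chromosomes(x)
    expect_equal(mean(chs$D), aneuploidy_score(x), tolerance = 1e-12)
    expect_equal(mean(chs$H), heterogeneity_score(x), tolerance = 1e-12)
  }

  # single chromosome: per-chromosome row equals the aggregate
  one <- cnv_matrix(cbind(a = c(2, 3, 4)))
  expect_equal(summarize_chromosomes(one)$D, aneuploidy_score(one))
})

test_that("statistics match the brute-force oracle on random matrices", {
  set.seed(7)
  for (i in 1:60) {
    x <- random_matrix(sample(1:5, 1), sample(1:3, 1))
    o <- oracle_stats(unclass(x))
    expect_equal(instability_index(x), o$I, tolerance = 1e-12)
    expect_equal(anca(x), o$A, tolerance = 1e-12)
    expect_equal(normalized_anca(x), o$AN, tolerance = 1e-12)
    expect_equal(aneuploidy_score(x), o$D, tolerance = 1e-12)
    expect_equal(heterogeneity_score(x), o$H, tolerance = 1e-12)
  }
})

test_that("statistics are invariant under cell permutation and duplication", {
  set.seed(11)
  for (i in 1:15) {
    x <- random_matrix(sample(2:6, 1), sample(2:4, 1))
    stats_of <- function(m) c(instability_index(m), anca(m),
                              normalized_anca(m), aneuploidy_score(m),
                              heterogeneity_score(m), ploidy_proportions(m))
    perm <- x[sample(nrow(x)), , drop = FALSE]
    expect_equal(stats_of(perm), stats_of(x), tolerance = 1e-12)
    # D and A also invariant under chromosome permutation
    cperm <- x[, sample(ncol(x)), drop = FALSE]
    expect_equal(aneuploidy_score(cperm), aneuploidy_score(x))
    expect_equal(anca(cperm), anca(x))
    # duplicating every cell changes nothing
    dup <- cnv_matrix(rbind(unclass(x), unclass(x)),
                      cell_ids = c(rownames(x), paste0(rownames(x), "_b")),
                      chromosomes = colnames(x))
    expect_equal(stats_of(dup), stats_of(x), tolerance = 1e-12)
  }
})

test_that("statistic bounds hold and zero iff homogeneous-euploid", {
  set.seed(13)
  for (i in 1:40) {
    n <- sample(1:6, 1); t_ <- sample(1:4, 1)
    x <- random_matrix(n, t_)
    expect_gte(instability_index(x), 0)
    expect_lte(instability_index(x), 100 * (1 - 1 / n) + 1e-12)
    expect_true(anca(x) >= 0 && anca(x) <= t_)
    expect_true(normalized_anca(x) >= 0 && normalized_anca(x) <= 1)
    expect_gte(aneuploidy_score(x), 0)
    expect_lte(heterogeneity_score(x), (n - 1) / 2 + 1e-12)
    p <- ploidy_proportions(x)
    expect_equal(sum(p), 1, tolerance = 1e-12)
    all_euploid <- all(unclass(x) == 2)
    zeroes <- instability_index(x) == 0 && anca(x) == 0 &&
      aneuploidy_score(x) == 0 && heterogeneity_score(x) == 0 &&
      p[["P_D"]] == 1
    expect_identical(zeroes, all_euploid)
  }
})

test_that("missing entries are excluded with observed-entry denominators", {
  m <- cnv_matrix(rbind(c(2, 3), c(2, NA), c(NA, 2)))
  # D over the 4 observed entries: |2-2|+|3-2|+|2-2|+|2-2| = 1/4
  expect_equal(aneuploidy_score(m), 0.25)
  # chromosome tallies over observed cells only
  expect_equal(tally_chromosome(m, colnames(m)[2L])$n_cells, 2L)
  # ANCA: q = (1, 0, 0) over the three cells (all have >= 1 observation)
  expect_equal(anca(m), 1 / 3)
  # a fully missing cell is dropped with a warning
  m2 <- cnv_matrix(rbind(c(2, 3), c(NA, NA)))
  expect_warning(a2 <- anca(m2), "dropped")
  expect_equal(a2, 1)
})

test_that("study summary stratifies and serializes the six statistics", {
  m <- cnv_matrix(rbind(c(2, 2), c(2, 3), c(4, 4), c(2, 2)),
                  cell_ids = paste0("c", 1:4))
  key <- group_key(paste0("c", 1:4), c("A", "A", "B", "B"))
  s <- summarize_study(m, key)
  expect_equal(nrow(s$groups), 2L)
  expect_equal(nrow(s$chromosomes), 4L)
  expect_identical(colnames(s$groups),
                   c("group", "source", "n_cells", "n_chromosomes", "I",
                     "ANCA", "normANCA", "D", "H", "P_A", "P_D", "P_P"))
  path <- withr::local_tempfile(fileext = ".csv")
  cpath <- withr::local_tempfile(fileext = ".csv")
  write_summary(s, path, cpath)
  back <- utils::read.csv(path, colClasses = c(group = "character"))
  expect_equal(back$D, s$groups$D)
  expect_equal(nrow(utils::read.csv(cpath)), 4L)
})
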