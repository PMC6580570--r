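test_that("bivariate grids tally joint states as percentages", {
  m <- cnv_matrix(rbind(c(2, 2), c(2, 2), c(2, 3), c(3, 3)),
                  chromosomes = c("9", "12"))
  g <- bivariate_grid(m, "9", "12")
  expect_equal(g$n_cells, 4L)
  expect_equal(g$percent["2", "2"], 50)
  expect_equal(g$percent["2", "3"], 25)
  expect_equal(g$percent["3", "3"], 25)
  expect_equal(g$percent["3", "2"], 0)
  expect_equal(sum(g$percent), 100, tolerance = 1e-9)

  # degenerate population: everything in one square
  u <- cnv_matrix(matrix(2, 5, 2))
  uni <- bivariate_grid(u, colnames(u)[1], colnames(u)[2])
  expect_equal(max(uni$percent), 100)

  # axes always include the euploid state for the bold gridline
  m2 <- cnv_matrix(rbind(c(4, 5), c(4, 5)), chromosomes = c("9", "12"))
  g2 <- bivariate_grid(m2, "9", "12")
  expect_true(2 %in% g2$states_x && 2 %in% g2$states_y)
  expect_equal(sum(g2$percent), 100)

  # pairwise-complete: cells missing either count are excluded
  m3 <- cnv_matrix(rbind(c(2, 2), c(2, NA), c(NA, 3)),
                   chromosomes = c("9", "12"))
  expect_equal(bivariate_grid(m3, "9", "12")$n_cells, 1L)
  m4 <- cnv_matrix(rbind(c(NA, 2), c(2, NA)))
  expect_error(bivariate_grid(m4, colnames(m4)[1], colnames(m4)[2]),
               "jointly observed")
})

test_that("grid percentages sum to 100 on random populations", {
  set.seed(31)
  for (i in 1:20) {
    x <- random_matrix(sample(2:30, 1), 2)
    g <- bivariate_grid(x, colnames(x)[1], colnames(x)[2])
    expect_equal(sum(g$percent), 100, tolerance = 1e-9)
    expect_true(all(g$percent >= 0))
  }
})

test_that("all_pairwise_grids enumerates each unordered pair once", {
  for (t_ in 2:8) {
    x <- random_matrix(5, t_)
    g <- all_pairwise_grids(x)
    expect_length(g, choose(t_, 2))
    pairs <- t(vapply(g, function(gr) c(gr$chrom_x, gr$chrom_y), character(2)))
    expect_false(any(duplicated(pairs)))
    ord <- order_chromosomes(colnames(x))
    expect_true(all(match(pairs[, 1], ord) < match(pairs[, 2], ord)))
  }
  expect_error(all_pairwise_grids(random_matrix(3, 1)), "at least 2")
})

test_that("scatter coordinates equal the group statistics exactly", {
  study <- generate_group_study(list(
    A = population_spec(n_cells = 15, missegregation_rate = 0),
    B = population_spec(n_cells = 15, missegregation_rate = 0.3)), seed = 2)
  summ <- summarize_study(study$matrix, study$key)
  sc <- scatter_dh(summ)
  expect_equal(sc$x, summ$groups$D)
  expect_equal(sc$y, summ$groups$H)
  expect_equal(sc$x[sc$group == "A"], 0)

  # coordinates round-trip through the serialized summary table
  path <- withr::local_tempfile(fileext = ".csv")
  write_summary(summ, path)
  back <- utils::read.csv(path, colClasses = c(group = "character"))
  sc2 <- scatter_dh(back)
  expect_identical(sc2$x, sc$x)
  expect_identical(sc2$y, sc$y)
})

test_that("ternary coordinates are the ploidy proportions", {
  df <- data.frame(group = c("a", "b", "c"), source = "FISH",
                   P_D = c(1, 0, 1 / 3), P_P = c(0, 0, 1 / 3),
                   P_A = c(0, 1, 1 / 3))
  tc <- ternary_coordinates(df)
  expect_equal(tc$px[1], 0)  # pure-diploid vertex at the origin
  expect_equal(tc$py[1], 0)
  expect_equal(tc$px[3], 0.5)  # centroid
  expect_equal(tc$py[3], sqrt(3) / 6, tolerance = 1e-12)
  expect_equal(tc$P_D, df$P_D)

  bad <- df; bad$P_A <- bad$P_A + 0.2
  expect_error(ternary_coordinates(bad), "sum to 1")
})

test_that("heatmap data keeps values and contiguous group blocks", {
  m <- cnv_matrix(rbind(c(2, 2), c(2, 3), c(4, 4), c(2, 2)),
                  cell_ids = paste0("c", 1:4))
  key <- group_key(paste0("c", 1:4), c("B", "A", "B", "A"))
  hm <- copy_number_heatmap_data(m, key)
  expect_equal(hm$group, c("B", "B", "A", "A"))
  expect_identical(rownames(hm$counts), c("c1", "c3", "c2", "c4"))
  for (cell in paste0("c", 1:4))
    expect_equal(hm$counts[cell, ], unclass(m)[cell, ])
})

test_that("PDF export writes one page per figure deterministically", {
  study <- generate_group_study(list(
    A = population_spec(n_cells = 10), B = population_spec(n_cells = 10)),
    seed = 4)
  figs <- build_figures(study$matrix, study$key)
  expect_identical(names(figs)[1:2], c("scatter", "ternary"))
  expect_length(figs, 2 + choose(4, 2) + 1)

  count_pages <- function(path) {
    raw <- readBin(path, "raw", file.info(path)$size)
    all_page <- length(grepRaw("/Type /Page", raw, fixed = TRUE, all = TRUE))
    pages_obj <- length(grepRaw("/Type /Pages", raw, fixed = TRUE, all = TRUE))
    all_page - pages_obj
  }
  pdf1 <- withr::local_tempfile(fileext = ".pdf")
  export_pdf(figs, pdf1)
  expect_equal(count_pages(pdf1), length(figs))

  pdf2 <- withr::local_tempfile(fileext = ".pdf")
  export_pdf(figs[1:3], pdf2)
  expect_equal(count_pages(pdf2), 3L)

  expect_error(export_pdf(list(), withr::local_tempfile(fileext = ".pdf")),
               "non-empty")

  # re-export gives the same page count
  pdf3 <- withr::local_tempfile(fileext = ".pdf")
  export_pdf(figs, pdf3)
  expect_equal(count_pages(pdf3), count_pages(pdf1))
})
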