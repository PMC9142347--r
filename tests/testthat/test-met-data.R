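test_that("plot CSV round trip is value identical and preserves missingness", {
  csv <- tempfile(fileext = ".csv")
  writeLines(c("genotype,location,year,block,row,column,yield_kg_ha",
               "g01,locA,2020,b1,1,1,2510.25",
               "g02,locA,2020,b1,1,2,2719.5",
               "g01,locA,2020,b2,2,1,2630",
               "g02,locA,2020,b2,2,2,2805.125"), csv)
  p <- read_plot_csv(csv)
  expect_s3_class(p, "met_plots")
  expect_equal(nrow(p), 4L)
  expect_equal(sum(is.na(p$value)), 0L)
  expect_equal(p$row, c(1L, 1L, 2L, 2L))

  out <- tempfile(fileext = ".csv")
  write_plot_csv(p, out)
  p2 <- read_plot_csv(out)
  o1 <- p[order(p$genotype, p$block), ]
  o2 <- p2[order(p2$genotype, p2$block), ]
  rownames(o1) <- rownames(o2) <- NULL
  expect_identical(o1[c("genotype", "location", "block")],
                   o2[c("genotype", "location", "block")])
  expect_equal(o1$value, o2$value, tolerance = 1e-12)

  # empty cell -> missing value, never zero
  writeLines(c("genotype,location,year,block,row,column,yield_kg_ha",
               "g01,locA,2020,b1,1,1,2510",
               "g02,locA,2020,b1,1,2,",
               "g01,locA,2020,b2,2,1,NA",
               "g02,locA,2020,b2,2,2,2805"), csv)
  pm <- read_plot_csv(csv)
  expect_equal(nrow(pm), 4L)
  expect_equal(sum(is.na(pm$value)), 2L)
  expect_false(any(pm$value == 0, na.rm = TRUE))
})

test_that("malformed cells and duplicate plot positions are rejected with locations", {
  csv <- tempfile(fileext = ".csv")
  writeLines(c("genotype,location,year,block,row,column,yield_kg_ha",
               "g01,locA,2020,b1,1,1,2510",
               "g02,locA,2020,b1,1,2,oops"), csv)
  expect_error(read_plot_csv(csv), "malformed numeric.*yield_kg_ha.*3")

  writeLines(c("genotype,location,year,block,row,column,yield_kg_ha",
               "g01,locA,2020,b1,1,1,2510",
               "g02,locA,2020,b1,1,1,2700"), csv)
  expect_error(read_plot_csv(csv), "duplicate.*1, 2")
})

test_that("trait-range validation enforces percentage and positivity rules", {
  base <- data.frame(genotype = "g01", location = "locA", year = 2020L,
                     block = "b1", row = 1L, column = 1L,
                     stringsAsFactors = FALSE)
  expect_error(met_plots(cbind(base, trait = "protein_pct", value = 104)),
               "outside")
  expect_error(met_plots(cbind(base, trait = "falling_number_s", value = 0)),
               "outside")
  expect_silent(met_plots(cbind(base, trait = "protein_pct", value = 12.5)))
})

test_that("two_way_table orders deterministically and reports completeness", {
  rec <- expand.grid(genotype = c("gB", "gA", "gC"),
                     location = "locA", year = c(2021L, 2020L),
                     stringsAsFactors = FALSE)
  rec$value <- seq_len(nrow(rec))
  b <- two_way_table(rec)
  expect_equal(rownames(b), c("gA", "gB", "gC"))
  expect_equal(colnames(b), c("locA:2020", "locA:2021"))
  expect_equal(completeness(b)$overall, 1)

  # permutation invariance
  set.seed(7)
  b2 <- two_way_table(rec[sample(nrow(rec)), ])
  expect_identical(unclass(b), unclass(b2))

  # one absent combination -> missing cell and per-row completeness report
  rec3 <- rec[-4, ]
  b3 <- two_way_table(rec3)
  expect_equal(sum(is.na(b3)), 1L)
  expect_equal(unname(completeness(b3)$by_genotype[rownames(b3) == "gB"]),
               0.5)

  # conflicting duplicates are an error; exact duplicates collapse
  expect_error(two_way_table(rbind(rec, data.frame(
    genotype = "gA", location = "locA", year = 2020L, value = 99))),
    "conflicting duplicate")
  expect_silent(two_way_table(rbind(rec, rec[1, ])))
})

test_that("BLUE matrix CSV round trip preserves values and SEs", {
  b <- random_blue_table(4, 3, seed = 11)
  se <- matrix(0.5, 4, 3, dimnames = dimnames(b))
  b <- blue_matrix(unclass(b), se = se)
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_blues_csv(b, f1, f2)
  b2 <- read_blues_csv(f1, f2)
  expect_equal(unclass(b2), unclass(b), tolerance = 1e-12)
  expect_equal(attr(b2, "se"), attr(b, "se"), tolerance = 1e-12)
})

test_that("score records validate their scale", {
  df <- data.frame(evaluator = "ev1", genotype = "g01", stage = NA,
                   score = 11, scale_min = 1, scale_max = 10)
  expect_error(score_records(df), "outside its scale")
  df$score <- 7
  expect_s3_class(score_records(df), "score_records")
})
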