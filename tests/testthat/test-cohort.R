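test_that("HVPG grading uses inclusive >= 10 and >= 12 thresholds", {
  cls <- classify_hvpg(c(9.9, 10, 12))
  expect_equal(cls$csph, c(FALSE, TRUE, TRUE))
  expect_equal(cls$sph, c(FALSE, FALSE, TRUE))
  expect_equal(cls$grade, c(1L, 2L, 3L))
  expect_equal(classify_hvpg(11.99)$grade, 2L)
  expect_error(classify_hvpg(-1), "finite")
  expect_error(classify_hvpg(Inf), "finite")
  expect_error(classify_hvpg(NA_real_), "finite")
})

test_that("exactly one grade, non-decreasing in HVPG, and SPH implies CSPH", {
  hv <- sort(c(seq(0, 35, by = 0.25), 9.999, 10, 11.999, 12))
  cls <- classify_hvpg(hv)
  expect_true(all(cls$grade %in% 1:3))
  expect_true(all(diff(cls$grade) >= 0))
  expect_true(all(cls$csph[cls$sph]))
  expect_equal(cls$grade == 1L, !cls$csph)
  expect_equal(cls$grade == 3L, cls$sph)
})

test_that("cohort CSV round-trip is the identity on canonical fields", {
  co <- generate_cohort(generator_config(n = 25, seed = 42))
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(co, path)
  back <- read_cohort(path)
  expect_s3_class(back, "ph_cohort")
  expect_equal(nrow(back), 25)
  for (col in c("id", "sex", "etiology", "child_pugh", "ascites"))
    expect_equal(back[[col]], co[[col]])
  for (col in c("age", "ast", "alt", "ggt", "albumin", "cholesterol",
                "plt", "inr", "hvpg"))
    expect_equal(back[[col]], co[[col]], tolerance = 1e-12)
})

test_that("row-level validation reports row and field, never drops silently", {
  df <- data.frame(id = c("a", "b", "c"), age = c(50, 60, 70),
                   sex = c("male", "female", "male"),
                   ast = c(40, 50, 60), alt = c(30, 35, 40),
                   albumin = c(33, 34, 35), plt = c("120", "abc", "90"),
                   inr = c(1.1, 1.2, 1.3), stringsAsFactors = FALSE)
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(df, path, row.names = FALSE)
  co <- read_cohort(path)
  expect_equal(nrow(co), 2)
  report <- attr(co, "validation")
  expect_equal(report$row, 2L)
  expect_equal(report$field, "plt")
  expect_match(report$reason, "numeric")
})

test_that("missing required columns and unknown ids fail loudly", {
  df <- data.frame(id = "a", age = 50, sex = "male", ast = 40,
                   stringsAsFactors = FALSE)
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(df, path, row.names = FALSE)
  expect_error(read_cohort(path), "missing required column")
  expect_error(
    as_cohort(data.frame(id = c("a", "a"), age = 50, sex = "male",
                         ast = 40, alt = 30, albumin = 33, plt = 100,
                         inr = 1.1)),
    "duplicate")
})

test_that("g/dL-scale albumin triggers a unit warning, and the flag rescales", {
  df <- data.frame(id = c("a", "b"), age = 50, sex = "male", ast = 40,
                   alt = 30, albumin = c(3.6, 4.1), plt = 100, inr = 1.1)
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(df, path, row.names = FALSE)
  expect_warning(read_cohort(path), "g/dL")
  co <- read_cohort(path, albumin_gdl_to_gl = TRUE)
  expect_equal(co$albumin, c(36, 41))
})

test_that("column mapping renames file columns to the canonical schema", {
  df <- data.frame(patient = "a", years = 50, gender = "M", AST = 40,
                   ALT = 30, ALB = 33, platelets = 100, INR = 1.1)
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(df, path, row.names = FALSE)
  cmap <- c(id = "patient", age = "years", sex = "gender", ast = "AST",
            alt = "ALT", albumin = "ALB", plt = "platelets", inr = "INR")
  co <- read_cohort(path, col_map = cmap)
  expect_equal(co$sex, "male")
  expect_equal(co$plt, 100)
  # same mapping through a YAML config file
  cfg <- withr::local_tempfile(fileext = ".yaml")
  writeLines(paste0(names(cmap), ": ", cmap), cfg)
  co2 <- read_cohort(path, col_map = cfg)
  expect_equal(as.data.frame(co2), as.data.frame(co))
})

test_that("subgroup splits are exhaustive, disjoint, and correctly defined", {
  co <- generate_cohort(generator_config(n = 200, seed = 3))
  for (axis in c("child_pugh_AB_C", "etiology_viral_nonviral", "sex")) {
    groups <- split_subgroups(co, axis)
    expect_equal(sum(vapply(groups, nrow, 0L)), nrow(co))
    ids <- unlist(lapply(groups, function(g) g$id))
    expect_setequal(ids, co$id)
  }
  viral <- split_subgroups(co, "etiology_viral_nonviral")
  expect_true(all(viral$viral$etiology %in% c("HBV", "HCV")))
  expect_true(all(!viral$nonviral$etiology %in% c("HBV", "HCV")))
  cp <- split_subgroups(co, "child_pugh_AB_C")
  expect_true(all(cp$child_pugh_A$child_pugh == "A"))
  expect_true(all(cp$child_pugh_BC$child_pugh %in% c("B", "C")))
})

test_that("an empty subgroup is kept with size zero and a warning", {
  df <- random_records(6)
  df$sex <- "male"
  df$etiology <- "HBV"
  df$child_pugh <- c("A", "A", "B", "C", "B", "A")
  co <- as_cohort(df)
  expect_warning(groups <- split_subgroups(co, "sex"), "empty subgroup")
  expect_equal(nrow(groups$female), 0L)
  expect_equal(nrow(groups$male), 6L)
  cp <- split_subgroups(co, "child_pugh_AB_C")
  expect_equal(vapply(cp, nrow, 0L),
               c(child_pugh_A = 3L, child_pugh_BC = 3L))
  expect_error(split_subgroups(co, "nonsense"))
})
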