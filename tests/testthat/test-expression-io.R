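test_that("a small TSV parses with order preserved", {
  df <- data.frame(ID = c("hsa-miR-16", "hsa-miR-21", "hsa-miR-425"),
                   a = c(1.5, 2, 3), b = c(4, 5, 6),
                   c = c(7, 8, 9), d = c(10, 11, 12))
  path <- writeTsv(df, tempfile(fileext = ".tsv"))
  me <- readExpressionTable(path, labels = c(a = 0, b = 0, c = 1, d = 1))
  expect_s4_class(me, "MirnaExperiment")
  expect_equal(dim(me), c(3L, 4L))
  expect_identical(rownames(me), df$ID)
  expect_identical(colnames(me), c("a", "b", "c", "d"))
  expect_equal(unname(exprsValues(me)[1, ]), c(1.5, 4, 7, 10))
  expect_equal(as.integer(sampleLabels(me)) - 1L, c(0L, 0L, 1L, 1L))
})

test_that("malformed tables are rejected with informative errors", {
  df <- data.frame(ID = c("hsa-miR-16", "hsa-miR-16", "hsa-miR-21"),
                   a = 1:3, b = 4:6, c = 7:9, d = 10:12)
  path <- writeTsv(df, tempfile(fileext = ".tsv"))
  expect_error(readExpressionTable(path, c(a = 0, b = 0, c = 1, d = 1)),
               "hsa-miR-16")

  df2 <- data.frame(ID = c("m1", "m2"), a = c("1", "oops"), b = c("3", "4"),
                    c = c("5", "6"), d = c("7", "8"))
  path2 <- writeTsv(df2, tempfile(fileext = ".tsv"))
  expect_error(readExpressionTable(path2, c(a = 0, b = 0, c = 1, d = 1)),
               "row 2.*'m2'.*column 'a'")

  df3 <- data.frame(ID = c("m1", "m2"), a = 1:2, b = 3:4, c = 5:6, d = 7:8)
  path3 <- writeTsv(df3, tempfile(fileext = ".tsv"))
  expect_error(readExpressionTable(path3, c(a = 0, b = 0, c = 1)),
               "no label.*d")
})

test_that("write/read round trip reproduces values to full precision", {
  me <- makeMe(20L, 10L, seed = 99L)
  path <- writeExpressionTable(me, tempfile(fileext = ".tsv"))
  back <- readExpressionTable(path, labels = setNames(
    as.integer(sampleLabels(me)) - 1L, colnames(me)))
  expect_identical(exprsValues(back), exprsValues(me))
})

test_that("per-sample z-scoring matches its definition and is idempotent", {
  v <- cbind(s1 = c(1, 2, 3), s2 = c(10, 30, 20),
             s3 = c(0, 5, 1), s4 = c(2, 2, 9))
  rownames(v) <- paste0("m", 1:3)
  me <- MirnaExperiment(v, labels = c(0, 0, 1, 1))
  nz <- normalizeSamples(me)
  expect_equal(unname(exprsValues(nz)[, "s1"]), c(-1, 0, 1))

  twice <- normalizeSamples(nz)
  expect_lt(max(abs(exprsValues(twice) - exprsValues(nz))), 1e-10)

  big <- normalizeSamples(makeMe(50L, 8L, seed = 3L))
  v2 <- exprsValues(big)
  # recompute moments from sums, independently of scale()/sd()
  mu <- colSums(v2) / nrow(v2)
  s2 <- (colSums(v2^2) - nrow(v2) * mu^2) / (nrow(v2) - 1)
  expect_true(all(abs(mu) < 1e-10))
  expect_equal(unname(s2), rep(1, 8), tolerance = 1e-10)
})

test_that("a constant sample is refused by name", {
  v <- cbind(s1 = c(2, 2, 2), s2 = c(1, 2, 3),
             s3 = c(4, 5, 6), s4 = c(7, 8, 10))
  rownames(v) <- paste0("m", 1:3)
  me <- MirnaExperiment(v, labels = c(0, 0, 1, 1))
  expect_error(normalizeSamples(me), "s1")
})

test_that("feature exclusion drops named rows and guards degeneracy", {
  me <- makeMe(5L, 6L, seed = 2L,
               labels = rep(c("control", "patient"), each = 3))
  v <- exprsValues(me)
  rownames(v)[1] <- "hsa-miR-486-5p"
  me <- MirnaExperiment(v, labels = sampleLabels(me))

  out <- excludeFeatures(me, "hsa-miR-486-5p")
  expect_equal(nrow(out), nrow(me) - 1L)
  expect_false("hsa-miR-486-5p" %in% rownames(out))

  expect_identical(excludeFeatures(me, character()), me)
  expect_warning(unch <- excludeFeatures(me, "hsa-miR-absent"), "absent")
  expect_identical(exprsValues(unch), exprsValues(me))
  expect_error(excludeFeatures(me, rownames(me)[1:4]), "fewer than 2")
})

test_that("panel subsetting keeps present members in panel order", {
  ids <- c(udbPanel()[1:10], "hsa-miR-9999", "hsa-miR-8888")
  v <- matrix(rnorm(12 * 6), 12, 6,
              dimnames = list(ids, paste0("s", 1:6)))
  me <- MirnaExperiment(v, labels = rep(c(0, 1), each = 3))

  sub <- subsetToPanel(me)
  expect_identical(rownames(sub), udbPanel()[1:10])
  expect_identical(metadata(sub)$missingPanelMembers, udbPanel()[11:12])

  full <- MirnaExperiment(
    matrix(rnorm(12 * 6), 12, 6,
           dimnames = list(udbPanel(), paste0("s", 1:6))),
    labels = rep(c(0, 1), each = 3))
  allIn <- subsetToPanel(full)
  expect_equal(nrow(allIn), 12L)
  expect_length(metadata(allIn)$missingPanelMembers, 0L)

  none <- makeMe(5L, 6L, labels = rep(c(0, 1), each = 3))
  expect_error(subsetToPanel(none), "no panel member")
})

test_that("exclusion and panel subsetting commute", {
  v <- matrix(rnorm(14 * 6), 14, 6,
              dimnames = list(c(udbPanel(), "x1", "x2"), paste0("s", 1:6)))
  me <- MirnaExperiment(v, labels = rep(c(0, 1), each = 3))
  drop <- c("hsa-miR-16", "x1")
  suppressWarnings({
    a <- subsetToPanel(excludeFeatures(me, drop))
    b <- excludeFeatures(subsetToPanel(me), drop)
  })
  expect_identical(exprsValues(a), exprsValues(b))
})

test_that("the shipped example cohort loads through the config path", {
  tsv <- system.file("extdata", "example_cohort.tsv", package = "mirUDB")
  cfg <- readDatasetConfig(
    system.file("extdata", "example_cohort.yaml", package = "mirUDB"))
  me <- readExpressionTable(tsv, labels = cfg$labels)
  expect_equal(dim(me), c(25L, 10L))
  expect_equal(sum(udbPanel() %in% rownames(me)), 12L)
  expect_equal(cfg$config$timing, "before_fe")
})

test_that("dataset configs round-trip through YAML", {
  cfg <- tempfile(fileext = ".yaml")
  writeLines(c("label_map:", "  s1: control", "  s2: control",
               "  s3: patient", "  s4: patient",
               "normalization:", "  timing: after_fe",
               "excluded_features: [hsa-miR-451]"), cfg)
  got <- readDatasetConfig(cfg)
  expect_equal(got$labels, c(s1 = "control", s2 = "control",
                             s3 = "patient", s4 = "patient"))
  expect_equal(got$config$timing, "after_fe")
  expect_equal(got$config$excludedFeatures, "hsa-miR-451")
})

test_that("invalid experiments are refused", {
  v <- matrix(rnorm(8), 2, 4, dimnames = list(c("a", "b"), NULL))
  expect_error(MirnaExperiment(v, labels = c(0, 0, 0, 0)), "both")
  v2 <- matrix(c(rnorm(7), NA), 2, 4,
               dimnames = list(c("a", "b"), paste0("s", 1:4)))
  expect_error(MirnaExperiment(v2, labels = c(0, 0, 1, 1)), "finite")
})
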