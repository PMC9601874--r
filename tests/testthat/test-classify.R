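test_that("worked dispersion points map to the expected diagnoses", {
  expect_equal(classify_point(c(50, 10))$coarse, "normal")
  expect_equal(classify_point(c(50, 10))$fine, "N")
  d <- classify_point(c(15, 65))          # ventricular subdomain overlap
  expect_equal(d$coarse, "ventricular_abnormal")
  expect_equal(d$fine, "none")
  d <- classify_point(c(5, 120))          # bundle-branch subdomain overlap
  expect_equal(d$coarse, "bundle_branch_block")
  expect_equal(d$fine, "none")
  expect_equal(classify_point(c(95, 50))$coarse, "unclassified")
})

test_that("unique subdomain membership yields fine labels", {
  expect_equal(classify_point(c(60, 40))$fine, "A.P.")
  expect_equal(classify_point(c(15, 20))$fine, "V.F.")
  expect_equal(classify_point(c(15, 55))$fine, "F.V.N.")
  expect_equal(classify_point(c(15, 80))$fine, "P.V.C.")
  expect_equal(classify_point(c(5, 50))$fine, "L.B.B.B.")
  expect_equal(classify_point(c(5, 150))$fine, "R.B.B.B.")
})

test_that("printed endpoints honour their open/closed flags", {
  # cur1 = 25 closes D2 and opens D0/D1
  expect_equal(classify_point(c(25, 10))$coarse, "ventricular_abnormal")
  # cur1 = 10 is excluded by both (10, 25] and [0, 10)
  expect_equal(classify_point(c(10, 10))$coarse, "unclassified")
  # cur1 = 90 still atrial; beyond 90 falls out
  expect_equal(classify_point(c(90, 30))$coarse, "atrial_abnormal")
  expect_equal(classify_point(c(90.5, 30))$coarse, "unclassified")
  # cur2 = 25 closes D0; above it the atrial box opens
  expect_equal(classify_point(c(50, 25))$coarse, "normal")
  expect_equal(classify_point(c(50, 25.5))$coarse, "atrial_abnormal")
  # ventricular subdomain edges 40, 50, 60, 70 (closed on both sides)
  expect_equal(classify_point(c(15, 39.9))$fine, "V.F.")
  expect_equal(classify_point(c(15, 40))$fine, "none")     # D21 & D22
  expect_equal(classify_point(c(15, 50))$fine, "none")     # D21 & D22
  expect_equal(classify_point(c(15, 50.5))$fine, "F.V.N.")
  expect_equal(classify_point(c(15, 60))$fine, "none")     # D22 & D23
  expect_equal(classify_point(c(15, 70))$fine, "none")     # D22 & D23
  expect_equal(classify_point(c(15, 70.5))$fine, "P.V.C.")
  # bundle-branch edges 100 and 140
  expect_equal(classify_point(c(5, 99.9))$fine, "L.B.B.B.")
  expect_equal(classify_point(c(5, 100))$fine, "none")     # D31 & D32
  expect_equal(classify_point(c(5, 140))$fine, "none")     # D31 & D32
  expect_equal(classify_point(c(5, 140.5))$fine, "R.B.B.B.")
  # D0's cur1 ceiling is literal: beyond 200 is unclassified
  expect_equal(classify_point(c(200, 10))$coarse, "normal")
  expect_equal(classify_point(c(200.5, 10))$coarse, "unclassified")
})

test_that("every finite point receives exactly one coarse outcome", {
  grid1 <- seq(0, 210, by = 2.5)
  grid2 <- seq(0, 160, by = 2.5)
  part <- default_partition()
  for (x in grid1) for (y in grid2) {
    d <- classify_point(c(x, y), part)
    expect_true(d$coarse %in% c("normal", "atrial_abnormal",
                                "ventricular_abnormal", "bundle_branch_block",
                                "unclassified"))
  }
  expect_equal(classify_point(c(NA_real_, 5))$coarse, "unclassified")
})

test_that("partition JSON round-trips through read/write", {
  path <- tempfile(fileext = ".json")
  write_partition(default_partition(), path)
  back <- read_partition(path)
  expect_equal(back, default_partition(), ignore_attr = FALSE)
  expect_equal(classify_point(c(15, 65), back)$coarse, "ventricular_abnormal")
})

test_that("classification metrics follow the set-cardinality definitions", {
  truth <- rep(c("normal", "atrial_abnormal"), c(4, 2))
  rep1 <- evaluate_classification(truth, truth)
  m <- rep1$metrics
  for (cl in c("normal", "atrial_abnormal")) {
    row <- m[m$class == cl, ]
    expect_equal(row$tpr, 100)
    expect_equal(row$nrr, 100)
    expect_equal(row$ppv, 100)
    expect_equal(row$f1, 100)
  }
  # single sample, wrong
  r2 <- evaluate_classification("normal", "atrial_abnormal")
  expect_equal(r2$metrics$tpr[r2$metrics$class == "normal"], 0)
  expect_equal(r2$metrics$f1[r2$metrics$class == "normal"], 0)
  # empty classes are undefined, not zero
  expect_true(is.na(r2$metrics$tpr[r2$metrics$class == "ventricular_abnormal"]))
})

test_that("metrics reconstructed from cohort counts match the known report", {
  # 5000 beats: 2500 normal; predictions catch 2499 normals plus 14 others
  truth <- rep(c("normal", "ventricular_abnormal"), c(2500, 2500))
  predicted <- truth
  predicted[1] <- "ventricular_abnormal"             # one missed normal
  predicted[2501:2514] <- "normal"                   # 14 false normals
  rep1 <- evaluate_classification(truth, predicted)
  row <- rep1$metrics[rep1$metrics$class == "normal", ]
  expect_equal(row$classified_size, 2513)
  expect_equal(round(row$tpr, 2), 99.96)
  expect_equal(round(row$nrr, 2), 99.44)
  expect_equal(round(row$ppv, 2), 99.44)
  expect_equal(round(row$f1, 2), 99.70)
})

test_that("the two F1 forms agree: 2 I / (|Q| + |Qhat|) == harmonic mean of PPV and TPR", {
  set.seed(33)
  classes <- c("normal", "atrial_abnormal", "ventricular_abnormal")
  for (rep in 1:10) {
    truth <- sample(classes, 200, replace = TRUE)
    predicted <- sample(classes, 200, replace = TRUE)
    m <- evaluate_classification(truth, predicted)$metrics
    m <- m[m$original_size > 0 & m$classified_size > 0, ]
    harm <- 2 * m$ppv * m$tpr / (m$ppv + m$tpr)
    harm[m$ppv + m$tpr == 0] <- 0
    expect_equal(m$f1, harm, tolerance = 1e-10)
  }
})
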