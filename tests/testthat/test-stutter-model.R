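test_that("step distribution follows the linear forms and conserves mass", {
  # no-mutation limit
  p0 <- stutter_params("AC")
  s0 <- step_distribution(p0, 20)
  expect_equal(unname(s0["0"]), 1)
  expect_equal(sum(s0), 1)

  # direct arithmetic from the linear forms
  p <- stutter_params("AC", up_slope = 2e-4, down_slope_1 = 1e-3,
                      down_slope_2 = 2e-4, down_slope_3 = 5e-5)
  s <- step_distribution(p, 20)
  expect_equal(unname(s[c("+1", "-1", "-2", "-3", "0")]),
               c(0.004, 0.02, 0.004, 0.001, 0.971), tolerance = 1e-12)
  expect_equal(sum(s), 1, tolerance = 1e-12)

  # support is exactly {+1, 0, -1, -2, -3}
  expect_named(s, c("+1", "0", "-1", "-2", "-3"))
  expect_true(all(s[c("+1", "-1", "-2", "-3")] > 0))

  expect_error(step_distribution(p, 0), "integer >= 1")
})

test_that("oversized mutation probabilities rescale to sum 1 with zero stay", {
  p <- stutter_params("A", up_slope = 0.008, down_slope_1 = 0.012,
                      down_slope_2 = 0.006, down_slope_3 = 0.004)
  s <- step_distribution(p, 40)  # raw sum = 0.03*40 = 1.2 > 1, none clamped
  expect_equal(unname(s["0"]), 0)
  expect_equal(sum(s), 1, tolerance = 1e-12)
  # relative composition preserved by the rescale
  expect_equal(unname(s["-1"] / s["+1"]), 0.012 / 0.008, tolerance = 1e-12)
  # an individually oversized probability is clamped to 1 before rescaling
  p2 <- stutter_params("A", up_slope = 0.02, down_slope_1 = 0.05)
  s2 <- step_distribution(p2, 40)  # raw: up 0.8, down1 2 -> clamp -> 0.8, 1
  expect_equal(unname(s2["-1"] / s2["+1"]), 1 / 0.8, tolerance = 1e-12)
})

test_that("contractions below one repeat are redirected feasibly", {
  p <- stutter_params("A", up_intercept = 0.01, down_intercept_1 = 0.1,
                      down_intercept_2 = 0.05, down_intercept_3 = 0.02)
  s1 <- step_distribution(p, 1)   # no contraction possible
  expect_equal(unname(s1[c("-1", "-2", "-3")]), c(0, 0, 0))
  expect_equal(sum(s1), 1, tolerance = 1e-12)
  s2 <- step_distribution(p, 2)   # -2/-3 fold into -1
  expect_equal(unname(s2["-1"]), 0.17, tolerance = 1e-12)
  expect_equal(unname(s2[c("-2", "-3")]), c(0, 0))
  s3 <- step_distribution(p, 3)   # -3 folds into -2
  expect_equal(unname(s3["-2"]), 0.07, tolerance = 1e-12)
  expect_equal(unname(s3["-3"]), 0)
})

test_that("kernel rows are stochastic and match the step distribution", {
  expect_equal(build_kernel(stutter_params("AC"), 5, 30)$matrix,
               diag(26), ignore_attr = TRUE)

  p <- ac_params()
  K <- build_kernel(p, 1, 60)
  expect_true(all(abs(rowSums(K$matrix) - 1) < 1e-9))
  expect_true(all(K$matrix >= 0))
  # interior row equals the step distribution mapped to absolute lengths
  s <- step_distribution(p, 20)
  row <- K$matrix["20", ]
  expect_equal(unname(row[as.character(c(21, 20, 19, 18, 17))]), unname(s))
  expect_equal(sum(row[setdiff(colnames(K$matrix),
                               as.character(17:21))]), 0)
  # off-diagonal support restricted to offsets {+1,-1,-2,-3}
  M <- K$matrix
  for (i in seq_len(nrow(M))) {
    nz <- which(M[i, ] > 0) - i
    expect_true(all(nz %in% c(-3, -2, -1, 0, 1)))
  }
  expect_error(build_kernel(p, 10, 10), "n_min < n_max")
})

test_that("DTMC prediction starts as a delta and composes over cycles", {
  p <- ac_params()
  h0 <- predict_histogram(p, 20, 0)
  expect_equal(h0$repeats, 20L)
  expect_equal(h0$counts, 1)

  # Chapman-Kolmogorov: predicting a+b cycles equals pushing the a-cycle
  # distribution b further cycles through the kernel
  a <- 7L; b <- 5L
  h_ab <- predict_histogram(p, 20, a + b)
  K <- build_kernel(p, 1, 40)$matrix
  v <- numeric(40); v[20] <- 1
  for (i in seq_len(a + b)) v <- as.numeric(v %*% K)
  ha <- predict_histogram(p, 20, a)
  va <- numeric(40); va[ha$repeats] <- ha$counts
  for (i in seq_len(b)) va <- as.numeric(va %*% K)
  expect_equal(va[h_ab$repeats], h_ab$counts, tolerance = 1e-12)
  expect_equal(v[h_ab$repeats], h_ab$counts, tolerance = 1e-12)

  expect_error(predict_histogram(p, 20, -1), "nonnegative")
})

test_that("contraction bias pulls the predicted mean down monotonically", {
  p <- ac_params()
  means <- sapply(0:25, function(t) {
    h <- predict_histogram(p, 25, t)
    sum(h$repeats * h$counts)
  })
  expect_true(all(diff(means) < 0))
  for (t in c(1, 5, 15, 25)) {
    h <- predict_histogram(p, 25, t)
    below <- sum(h$counts[h$repeats < 25])
    above <- sum(h$counts[h$repeats > 25])
    expect_gt(below, above)
  }
})

test_that("mixture predictions are convex combinations of allele patterns", {
  p <- ac_params()
  m1 <- predict_mixture(p, 17, 27, 1, 12)
  h1 <- predict_histogram(p, 17, 12)
  expect_equal(m1$repeats, h1$repeats)
  expect_equal(m1$counts, h1$counts, tolerance = 1e-12)

  m2 <- predict_mixture(p, 20, 20, 0.5, 12)
  h2 <- predict_histogram(p, 20, 12)
  expect_equal(m2$counts, h2$counts, tolerance = 1e-12)

  m3 <- predict_mixture(p, 17, 27, 0.3, 0)
  expect_equal(m3$repeats, c(17L, 27L))
  expect_equal(m3$counts, c(0.3, 0.7))
  expect_error(predict_mixture(p, 27, 17, 0.5, 5), "l1")
})

test_that("model families are pluggable through the registry", {
  expect_true("Linear1up3dw" %in% stutter_families())
  # a constant-probability competitor family via the same interface
  register_stutter_family("ConstTest", function(params, n) {
    m <- matrix(rep(c(0.01, 0.97, 0.02, 0, 0), each = length(n)),
                nrow = length(n))
    colnames(m) <- c("+1", "0", "-1", "-2", "-3")
    m
  })
  p <- stutter_params("AC", model_family = "ConstTest")
  s <- step_distribution(p, 30)
  expect_equal(unname(s["-1"]), 0.02)
  h <- predict_histogram(p, 20, 1)
  expect_equal(h$repeats, c(19L, 20L, 21L))
  expect_error(step_distribution(stutter_params("AC", model_family = "nope"), 5),
               "unknown model family")
})

test_that("parameter JSON round-trips with format versioning", {
  p1 <- ac_params()
  p2 <- default_stutter_params("A")
  tmp <- tempfile(fileext = ".json")
  write_stutter_params(list(p1, p2), tmp)
  back <- read_stutter_params(tmp)
  expect_named(back, c("AC", "A"))
  expect_equal(back$AC$down_slope_1, p1$down_slope_1)
  expect_equal(back$A$up_slope, p2$up_slope)
  expect_equal(back$AC$model_family, "Linear1up3dw")

  bad <- tempfile(fileext = ".json")
  jsonlite::write_json(list(classes = list()), bad, auto_unbox = TRUE)
  expect_error(read_stutter_params(bad), "format_version")
})
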