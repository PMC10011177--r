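test_that("fixation sets validate coordinates and round-trip CSV", {
  fix <- fixation_set(cbind(c(3, 10), c(4, 20)), c(12, 24))
  expect_s3_class(fix, "fixation_set")
  expect_error(fixation_set(cbind(13, 4), c(12, 24)),
               class = "wavsal_input_error")
  path <- tempfile(fileext = ".csv")
  write_fixations_csv(fix, path)
  back <- read_fixations_csv(path, c(12, 24))
  expect_equal(back$points, fix$points)
  # binary map reader
  m <- matrix(0, 6, 6); m[2, 3] <- 1; m[5, 5] <- 1
  fm <- fixations_from_map(m)
  expect_equal(nrow(fm$points), 2)
})

test_that("threshold-sweep ROC area equals the pair-counting oracle", {
  for (seed in 1:8) {
    pos <- withr::with_seed(seed, sample(seq(0, 1, by = 0.1), 6, TRUE))
    neg <- withr::with_seed(seed + 100, sample(seq(0, 1, by = 0.1), 9, TRUE))
    expect_equal(wavsal:::roc_area(pos, neg), brute_auc(pos, neg),
                 tolerance = 1e-12)
  }
})

test_that("AUC-Borji rewards perfect maps and scores chance on flat ones", {
  sal <- matrix(0, 40, 60)
  pts <- cbind(c(5, 20, 35), c(10, 30, 50))
  sal[pts] <- 1
  fix <- fixation_set(pts, c(40, 60))
  res <- auc_borji(sal, fix, n_splits = 100, seed = 3)
  expect_gte(res$score, 0.99)   # negatives rarely land on the 3 hot pixels
  expect_equal(auc_borji(matrix(0.5, 40, 60), fix, 50, seed = 4)$score, 0.5)
})

test_that("AUC is invariant under monotone transforms and flips on negation", {
  sal <- matrix(withr::with_seed(8, stats::runif(30 * 30)), 30, 30)
  fix <- fixation_set(cbind(c(4, 9, 22, 17), c(6, 25, 13, 28)), c(30, 30))
  a <- auc_borji(sal, fix, 40, seed = 11)$score
  b <- auc_borji(sal^3, fix, 40, seed = 11)$score
  expect_equal(a, b, tolerance = 1e-12)
  d <- auc_borji(1 - sal, fix, 40, seed = 11)$score
  expect_equal(a + d, 1, tolerance = 1e-12)   # ties are absent in runif maps
})

test_that("AUC runs are reproducible given a seed", {
  sal <- matrix(withr::with_seed(9, stats::runif(400)), 20, 20)
  fix <- fixation_set(cbind(c(3, 7, 15), c(3, 12, 18)), c(20, 20))
  expect_identical(auc_borji(sal, fix, 30, seed = 5)$score,
                   auc_borji(sal, fix, 30, seed = 5)$score)
  other <- list(fixation_set(cbind(c(2, 9, 13, 18), c(11, 4, 17, 6)),
                             c(20, 20)))
  expect_identical(sauc(sal, fix, other, 30, seed = 6)$score,
                   sauc(sal, fix, other, 30, seed = 6)$score)
})

test_that("sAUC with identical positive and negative sets is exactly 0.5", {
  sal <- matrix(withr::with_seed(10, stats::runif(400)), 20, 20)
  pts <- cbind(c(2, 8, 14, 19), c(5, 9, 2, 16))
  fix <- fixation_set(pts, c(20, 20))
  # the pool has exactly as many points as the positive set, so sampling
  # without replacement returns the same coordinates every split
  res <- sauc(sal, fix, fix, n_splits = 10, seed = 2)
  expect_equal(res$score, 0.5, tolerance = 1e-12)
})

test_that("sAUC penalizes center bias when negatives share it", {
  H <- 60; W <- 60
  center_map <- gauss_center <- exp(-(outer((1:H - H / 2)^2,
                                            (1:W - W / 2)^2, `+`)) / (2 * 12^2))
  draw_center_biased <- function(n, seed) {
    withr::with_seed(seed, {
      p <- as.vector(gauss_center) / sum(gauss_center)
      idx <- sample.int(H * W, n, replace = TRUE, prob = p)
      fixation_set(cbind(((idx - 1) %% H) + 1, ((idx - 1) %/% H) + 1),
                   c(H, W))
    })
  }
  fix <- draw_center_biased(80, 21)
  pool <- lapply(1:5, function(i) draw_center_biased(80, 30 + i))
  res <- sauc(center_map, fix, pool, n_splits = 100, seed = 7)
  # three binomial sigmas of a 80-vs-80 AUC at chance
  expect_lt(abs(res$score - 0.5), 0.1)
  # while the plain AUC of the same center-biased map is well above chance
  res_auc <- auc_borji(center_map, fix, 100, seed = 8)
  expect_gt(res_auc$score, 0.7)
})

test_that("empty fixations and empty pools are rejected", {
  sal <- matrix(0.5, 10, 10)
  empty <- fixation_set(matrix(0L, 0, 2), c(10, 10))
  expect_error(auc_borji(sal, empty), class = "wavsal_input_error")
  fix <- fixation_set(cbind(5, 5), c(10, 10))
  expect_error(sauc(sal, fix, list()), class = "wavsal_input_error")
})
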