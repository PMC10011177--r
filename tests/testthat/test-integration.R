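test_that("local maxima detection matches an exhaustive window scan", {
  expect_length(find_local_maxima(matrix(1, 5, 5))$values, 0)
  single <- matrix(0, 5, 5); single[3, 4] <- 1
  got <- find_local_maxima(single)
  expect_equal(unname(got$locations), rbind(c(3L, 4L)))
  two <- matrix(0, 5, 5); two[2, 2] <- 0.9; two[4, 5] <- 0.4
  got <- find_local_maxima(two)
  expect_equal(unname(got$locations), rbind(c(2L, 2L), c(4L, 5L)))
  expect_equal(got$values, c(0.9, 0.4))
  expect_equal(unname(got$locations), brute_local_maxima(two))
  # random matrices: same maxima as the brute-force scan (no plateaus in
  # continuous noise)
  for (seed in 1:5) {
    m <- matrix(withr::with_seed(seed, stats::rnorm(56)), 7, 8)
    expect_equal(unname(find_local_maxima(m)$locations),
                 brute_local_maxima(m))
  }
  expect_error(find_local_maxima(two, neighborhood = 4),
               class = "wavsal_config_error")
})

test_that("plateaus collapse to their first row-major pixel", {
  m <- matrix(0, 6, 6)
  m[3:4, 3:4] <- 1          # 2x2 plateau
  got <- find_local_maxima(m)
  expect_equal(unname(got$locations), rbind(c(3L, 3L)))
  m[1, 6] <- 2              # distinct higher peak in a corner
  got <- find_local_maxima(m)
  expect_equal(unname(got$locations), rbind(c(1L, 6L), c(3L, 3L)))
})

test_that("nearest-maximum assignment picks a closest seed everywhere", {
  for (seed in 1:4) {
    H <- 9; W <- 11
    locs <- unique(cbind(withr::with_seed(seed, sample.int(H, 6, TRUE)),
                         withr::with_seed(seed + 50, sample.int(W, 6, TRUE))))
    vals <- seq_len(nrow(locs)) / nrow(locs)
    got <- wavsal:::nearest_max_matrix(locs, vals, c(H, W))
    for (i in seq_len(H)) for (j in seq_len(W)) {
      d2 <- (locs[, 1] - i)^2 + (locs[, 2] - j)^2
      expect_true(got[i, j] %in% vals[d2 == min(d2)])
    }
  }
})

test_that("max integration takes the per-pixel maximum of grouped maps", {
  z <- matrix(0, 4, 4)
  a <- matrix(withr::with_seed(11, stats::runif(16)), 4)
  out <- integrate_max(list(I = a, RG = z, BY = z))
  expect_equal(out$values, normalize01(a))
  # dominance: pre-normalization max >= each grouped map; verified on a
  # hand-built case per pixel
  m1 <- matrix(c(0.1, 0.9, 0.4, 0.2), 2)
  m2 <- matrix(c(0.5, 0.3, 0.6, 0.1), 2)
  got <- integrate_max(list(I = m1, RG = m2))
  want <- matrix(0, 2, 2)
  for (i in 1:2) for (j in 1:2) want[i, j] <- max(m1[i, j], m2[i, j])
  expect_equal(got$values, normalize01(want))
})

test_that("orientation channels are pooled before max integration", {
  z <- matrix(0, 4, 4)
  os <- lapply(1:8, function(i) matrix(0.1 * i, 4, 4) + diag(4) * 0.01 * i)
  names(os) <- sprintf("O%d.I", 0:7)
  cmaps <- c(list(I = z, RG = z, BY = z), os)
  got <- integrate_max(cmaps)
  pooled <- normalize01(Reduce(`+`, os))
  expect_equal(got$values, normalize01(pmax(z, pooled)))
})

test_that("global weighting follows |Max - mean(other maxima)|", {
  # map with global max 1.0 and all other local maxima 0.2 -> weight 0.8
  m <- matrix(0, 7, 7)
  m[2, 2] <- 1; m[5, 5] <- 0.2; m[2, 6] <- 0.2
  out <- integrate_weighted_global(list(A = m, B = m))
  expect_equal(out$provenance$weights, c(0.8, 0.8))
  expect_equal(out$values, normalize01(m))   # identical maps pass through
  # two maps: a single dominant peak vs many equal peaks; direct formula
  many <- matrix(0, 7, 7)
  many[c(2, 5), 2] <- 0.6; many[c(2, 5), 5] <- 0.6
  out2 <- integrate_weighted_global(list(A = m, B = many))
  w_m <- 0.8
  w_many <- abs(0.6 - 0.6)
  want <- normalize01((w_m * normalize01(m) + w_many * normalize01(many)) /
                        (w_m + w_many))
  expect_equal(out2$values, want, tolerance = 1e-12)
  expect_gt(stats::cor(as.vector(out2$values), as.vector(m)), 0.99)
})

test_that("a lone peak gets weight Max and zero weights fall back", {
  lone <- matrix(0, 5, 5); lone[3, 3] <- 0.7
  out <- integrate_weighted_global(list(A = lone))
  expect_equal(out$provenance$weights, 1)   # normalized map peak = 1
  expect_warning(out0 <- integrate_weighted_global(
    list(A = matrix(0, 4, 4), B = matrix(0, 4, 4))), "zero")
  expect_equal(out0$values, matrix(0, 4, 4))
})

test_that("local weighting follows |Max - nearest local maximum|", {
  # two maxima 1.0 and 0.5: pixels closer to the 0.5 peak weigh 0.5,
  # pixels closer to the 1.0 peak weigh 0
  m <- matrix(0, 5, 9); m[3, 2] <- 1; m[3, 8] <- 0.5
  st <- wavsal:::map_stats(list(m))
  W <- abs(1 - wavsal:::nearest_max_matrix(st[[1]]$maxima$locations,
                                           st[[1]]$maxima$values, c(5, 9)))
  expect_equal(W[3, 2], 0)
  expect_equal(W[3, 8], 0.5)
  expect_true(all(W[, 1:4] == 0))
  expect_true(all(W[, 6:9] == 0.5))
  # two-map 4x4 case against the direct element-wise formula
  a <- matrix(0, 4, 4); a[1, 1] <- 1; a[4, 4] <- 0.25
  b <- matrix(0, 4, 4); b[2, 3] <- 0.9; b[4, 1] <- 0.6
  sta <- wavsal:::map_stats(list(a, b))
  Wa <- abs(max(normalize01(a)) -
            wavsal:::nearest_max_matrix(sta[[1]]$maxima$locations,
                                        sta[[1]]$maxima$values, c(4, 4)))
  Wb <- abs(max(normalize01(b)) -
            wavsal:::nearest_max_matrix(sta[[2]]$maxima$locations,
                                        sta[[2]]$maxima$values, c(4, 4)))
  num <- Wa * normalize01(a) + Wb * normalize01(b)
  den <- Wa + Wb
  want <- matrix(0, 4, 4); nz <- den > 0
  want[nz] <- num[nz] / den[nz]
  got <- integrate_weighted_local(list(a, b))
  expect_equal(got$values, normalize01(want), tolerance = 1e-12)
})

test_that("degenerate local weights trigger the documented fallback", {
  lone <- matrix(0, 5, 5); lone[3, 3] <- 1   # single max = global max
  expect_warning(out <- integrate_weighted_local(list(A = lone)),
                 "method 2")
  expect_equal(out$provenance$fallback, "weighted_global")
  expect_equal(out$values, normalize01(lone))
})

test_that("combined integration is the rescaled sum of methods 2 and 3", {
  a <- matrix(0, 6, 6); a[2, 2] <- 1; a[5, 5] <- 0.3
  b <- matrix(0, 6, 6); b[3, 4] <- 0.8; b[6, 1] <- 0.5
  maps <- list(A = a, B = b)
  m2 <- integrate_weighted_global(maps)
  m3 <- integrate_weighted_local(maps)
  got <- integrate_combined(maps)
  expect_equal(got$values, normalize01(m2$values + m3$values),
               tolerance = 1e-12)
  # when method 3 falls back to method 2 (lone peak), the sum equals it
  lone <- matrix(0, 6, 6); lone[2, 5] <- 1
  m2s <- integrate_weighted_global(list(A = lone))
  got2 <- suppressWarnings(integrate_combined(list(A = lone)))
  expect_equal(got2$values, m2s$values, tolerance = 1e-12)
})

test_that("integration is permutation invariant and bounded in [0,1]", {
  maps <- lapply(1:4, function(i)
    matrix(withr::with_seed(20 + i, stats::runif(36)), 6))
  names(maps) <- c("I", "RG", "BY", "O0.I")
  perm <- maps[c(3, 1, 4, 2)]
  for (method in 1:4) {
    m_a <- integrate_features(maps, method)
    m_b <- integrate_features(perm, method)
    expect_equal(m_a$values, m_b$values, tolerance = 1e-12)
    expect_gte(min(m_a$values), 0)
    expect_lte(max(m_a$values), 1)
  }
})
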