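mat2 <- function(...) {
  m <- rbind(...)
  rownames(m) <- paste0("P", seq_len(nrow(m)))
  colnames(m) <- paste0("ch", seq_len(ncol(m)))
  m
}

test_that("loading normalization equalizes channel sums and is idempotent", {
  # hand example: sums 100 and 300 -> factors 0.5 / 1.5, both sums 200
  m <- mat2(c(40, 120), c(60, 180))
  nm <- loading_normalize(m)
  expect_equal(unname(nm$loading_factors), c(0.5, 1.5))
  expect_equal(unname(colSums(nm$intensities)), c(200, 200))
  # identical channels: factors 1, unchanged
  m1 <- mat2(c(10, 10), c(5, 5))
  nm1 <- loading_normalize(m1)
  expect_equal(unname(nm1$loading_factors), c(1, 1))
  expect_equal(nm1$intensities, m1)
  # random matrices: equal sums, factors average 1, idempotent
  withr::with_seed(81, {
    for (i in 1:20) {
      m <- matrix(rlnorm(60, 10, 1), 10, 6)
      nm <- loading_normalize(m)
      s <- colSums(nm$intensities)
      expect_lt(max(abs(s - mean(s))), 1e-9 * mean(s))
      expect_equal(mean(nm$loading_factors), 1)
      twice <- loading_normalize(nm$intensities)
      expect_equal(twice$intensities, nm$intensities, tolerance = 1e-12)
      expect_equal(unname(twice$loading_factors), rep(1, 6))
    }
  })
  expect_error(loading_normalize(mat2(c(0, 0), c(0, 1))), "zero channel sum")
})

test_that("log2 centering zeroes row means and ignores row scaling", {
  m <- mat2(c(2, 8))
  cen <- log2_center(m)
  expect_equal(unname(cen$intensities[1, ]), c(-1, 1))
  # constant row -> all zeros
  expect_equal(unname(log2_center(mat2(c(4, 4, 4)))$intensities[1, ]),
               rep(0, 3))
  # doubling every sample of a row cancels in the centering
  withr::with_seed(82, {
    m <- matrix(rlnorm(24, 8, 1), 4, 6)
    expect_equal(log2_center(2 * m)$intensities,
                 log2_center(m)$intensities, tolerance = 1e-12)
  })
  expect_error(log2_center(mat2(c(0, 1))), "non-positive")
})

test_that("differential abundance matches per-protein t-tests and BH", {
  withr::with_seed(83, {
    m <- matrix(rnorm(50 * 6, 0, 0.3), 50, 6)
    m[1:5, 4:6] <- m[1:5, 4:6] + 2
    rownames(m) <- paste0("P", 1:50)
    groups <- rep(c("control", "CKD"), each = 3)
    da <- differential_abundance(m, groups)
    # spot-check protein rows against the scalar oracle
    for (i in c(1, 17, 50)) {
      expect_equal(da$t[i], -oracle_pooled_t(m[i, 1:3], m[i, 4:6]),
                   tolerance = 1e-12)
      expect_equal(da$log2fc[i], mean(m[i, 4:6]) - mean(m[i, 1:3]))
    }
    expect_equal(da$p_adj, oracle_bh(da$p), tolerance = 1e-12)
    expect_true(all(da$p_adj >= da$p))
    # identical groups -> zero fold change
    eq <- differential_abundance(cbind(m[, 1:3], m[, 1:3]), groups)
    expect_equal(eq$log2fc, rep(0, 50))
  })
})

test_that("BH adjustment equals the brute-force step-up oracle", {
  expect_equal(p.adjust(c(0.01, 0.02, 0.03, 0.04, 0.05), "BH"),
               rep(0.05, 5))
  withr::with_seed(84, {
    for (i in 1:200) {
      p <- runif(sample(3:40, 1))
      expect_equal(p.adjust(p, "BH"), oracle_bh(p), tolerance = 1e-12)
    }
  })
})

test_that("degenerate proteins are flagged with p = 1", {
  m <- mat2(c(1, 1, 1, 1, 1, 1), c(1, 2, 3, 4, 5, 6))
  m <- log2_center(m)$intensities
  da <- differential_abundance(m, rep(c("control", "CKD"), each = 3))
  expect_true(da$degenerate[1])
  expect_equal(da$p[1], 1)
  expect_false(da$degenerate[2])
})

test_that("count_significant splits by fold-change sign", {
  da <- data.frame(protein = paste0("P", 1:10),
                   log2fc = c(rep(1, 5), rep(-1, 5)),
                   p = c(0.001, 0.002, 0.2, 0.3, 0.4,
                         0.003, 0.5, 0.6, 0.7, 0.8),
                   p_adj = c(0.01, 0.02, 0.5, 0.6, 0.7,
                             0.03, 0.8, 0.9, 0.95, 1))
  cs <- count_significant(da, alpha = 0.05, adjusted = TRUE)
  expect_equal(cs$total, 3)
  expect_equal(cs$up, 2)
  expect_equal(cs$down, 1)
  expect_equal(cs$up + cs$down, cs$total)
  expect_equal(count_significant(da, alpha = 0)$total, 0)
})

test_that("overlap sets enumerate Venn intersections", {
  s <- list(skeletal = c("A", "B", "C"), cardiac = c("B", "C", "D"),
            renal = c("C"))
  ov <- overlap_sets(s)
  expect_equal(unname(ov$sizes), c(3, 3, 1))
  expect_equal(unname(ov$pairwise["skeletal:cardiac"]), 2)
  expect_equal(ov$threeway, 1)
  expect_equal(ov$common, "C")
  # disjoint and identical cases
  expect_equal(overlap_sets(list(a = "X", b = "Y"))$pairwise[["a:b"]], 0)
  expect_equal(overlap_sets(list(a = c("X", "Y"), b = c("X", "Y")))$pairwise[["a:b"]], 2)
})

test_that("conductance correlations match the covariance oracle", {
  withr::with_seed(85, {
    cond <- c(10, 9, 8, 3, 2.5, 2)
    m <- matrix(rnorm(30 * 6), 30, 6)
    m[1, ] <- 0.5 * cond          # proportional -> r = 1
    m[2, ] <- -2 * cond + 3       # anti-proportional -> r = -1
    rownames(m) <- paste0("P", 1:30)
    cr <- correlate_conductance(m, cond)
    expect_equal(cr$r[1], 1)
    expect_equal(cr$r[2], -1)
    for (i in 3:10) {
      or <- cov(m[i, ], cond) / (sd(m[i, ]) * sd(cond))
      expect_equal(cr$r[i], or, tolerance = 1e-12)
      tt <- or * sqrt(4 / (1 - or^2))
      expect_equal(cr$p[i], 2 * pt(abs(tt), 4, lower.tail = FALSE),
                   tolerance = 1e-12)
    }
    # zero-variance protein flagged
    m[3, ] <- 5
    cr2 <- correlate_conductance(m, cond)
    expect_true(cr2$degenerate[3])
    expect_true(is.na(cr2$r[3]))
  })
  expect_error(correlate_conductance(matrix(1:9, 3), c(1, 2, 3)), ">= 4")
})

test_that("reporter matrix reader pairs channels with the sample sheet", {
  mf <- withr::local_tempfile(fileext = ".csv")
  sf <- withr::local_tempfile(fileext = ".csv")
  d <- data.frame(protein = c("P1", "P2"),
                  c1 = c(10, 20), c2 = c(11, 21),
                  c3 = c(30, 40), c4 = c(31, 41))
  write.csv(d, mf, row.names = FALSE)
  write.csv(data.frame(channel = c("c1", "c2", "c3", "c4"),
                       tissue = "cardiac",
                       group = c("control", "control", "CKD", "CKD")),
            sf, row.names = FALSE)
  rm <- read_reporter_matrix(mf, sf)
  expect_s3_class(rm, "reporter_matrix")
  expect_equal(rm$tissue, "cardiac")
  expect_equal(rm$groups, c("control", "control", "CKD", "CKD"))
  expect_equal(unname(rm$intensities["P2", "c3"]), 40)
})
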