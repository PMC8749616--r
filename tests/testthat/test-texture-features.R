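test_that("ROI histogram matches a brute-force tally and handles edge cases", {
  pl <- matrix(100L, 10, 5)
  mask <- matrix(FALSE, 10, 5); mask[1:10, 1:5] <- TRUE
  h <- roi_histogram(pl, mask)
  expect_equal(h$H[101], 1)
  expect_equal(sum(h$H), 1)
  expect_equal(h$n_pixels, 50)

  pl2 <- matrix(c(rep(0L, 32), rep(255L, 32)), 8, 8)
  h2 <- roi_histogram(pl2, matrix(TRUE, 8, 8))
  expect_equal(h2$H[c(1, 256)], c(0.5, 0.5))

  rm <- random_masked_plane(11)
  h3 <- roi_histogram(rm$plane, rm$mask)
  tally <- numeric(256)
  for (x in rm$plane[rm$mask]) tally[x + 1] <- tally[x + 1] + 1
  expect_equal(h3$H, tally / sum(tally))

  expect_error(roi_histogram(pl, matrix(FALSE, 10, 5)), "empty")
  expect_error(roi_histogram(pl, matrix(TRUE, 5, 10)), "shape")
})

test_that("HS features reproduce degenerate and hand-computed histograms", {
  h <- roi_histogram(matrix(100L, 5, 10), matrix(TRUE, 5, 10))
  f <- hs_features(h)
  expect_equal(unname(f[c("Mean", "Variance", "Skewness", "Kurtosis")]),
               c(100, 0, 0, 0))
  expect_true(all(f[c("Perc01", "Perc10", "Perc50", "Perc90", "Perc99")] == 100))
  expect_equal(unname(f["Domn01"]), 100)
  expect_equal(unname(f["Maxm01"]), 1)

  h2 <- roi_histogram(matrix(c(rep(0L, 32), rep(255L, 32)), 8, 8),
                      matrix(TRUE, 8, 8))
  f2 <- hs_features(h2)
  expect_equal(unname(f2["Mean"]), 127.5)
  expect_equal(unname(f2["Variance"]), 16256.25)
  expect_equal(unname(f2["Skewness"]), 0)
  # cumulative histogram reaches 0.5 already at level 0
  expect_equal(unname(f2["Perc50"]), 0)
})

test_that("HS features agree with the independent loop oracle on random ROIs", {
  for (seed in 1:25) {
    rm <- random_masked_plane(seed, K = 256, shape = c(10, 10))
    f <- hs_features(roi_histogram(rm$plane, rm$mask))
    expect_equal(f, oracle_hs(rm$plane[rm$mask]), tolerance = 1e-12,
                 info = seed)
  }
})

test_that("co-occurrence counting matches enumeration of ordered pairs", {
  pl <- rbind(c(0L, 1L), c(0L, 1L))
  mask <- matrix(TRUE, 2, 2)
  a <- build_cooccurrence(pl, mask, c(0, 1), symmetric = FALSE, gray_levels = 2)
  expect_equal(a$counts[1, 2], 2)
  expect_equal(a$p[1, 2], 1)
  s <- build_cooccurrence(pl, mask, c(0, 1), symmetric = TRUE, gray_levels = 2)
  expect_equal(s$p[1, 2], 0.5)
  expect_equal(s$p[2, 1], 0.5)
  expect_true(isSymmetric(s$p))

  cst <- build_cooccurrence(matrix(7L, 4, 4), matrix(TRUE, 4, 4),
                            gray_levels = 256)
  expect_equal(cst$p[8, 8], 1)

  # both endpoints must lie inside the ROI
  mask2 <- matrix(TRUE, 2, 2); mask2[1, 2] <- FALSE
  b <- build_cooccurrence(pl, mask2, c(0, 1), symmetric = FALSE, gray_levels = 2)
  expect_equal(b$n_pairs, 1)     # only the (2,1)-(2,2) pair survives
  expect_error(build_cooccurrence(pl, diag(c(TRUE, TRUE)), c(0, 1),
                                  symmetric = FALSE, gray_levels = 2),
               "pairs")
})

test_that("co-occurrence agrees with the brute-force pair loop on random ROIs", {
  for (seed in 1:10) {
    for (off in list(c(0, 1), c(1, 0), c(1, 1), c(-1, 1))) {
      rm <- random_masked_plane(seed + 100, K = 4)
      got <- build_cooccurrence(rm$plane, rm$mask, off, symmetric = (seed %% 2 == 0),
                                gray_levels = 4)
      exp <- oracle_cooccurrence(rm$plane, rm$mask, off,
                                 symmetric = (seed %% 2 == 0), K = 4)
      expect_equal(got$p, exp, tolerance = 1e-12,
                   info = paste(seed, paste(off, collapse = ",")))
    }
  }
})

test_that("Haralick features reproduce hand-evaluated small matrices", {
  cst <- build_cooccurrence(matrix(7L, 4, 4), matrix(TRUE, 4, 4),
                            gray_levels = 256)
  f <- glcm_features(cst)
  expect_equal(unname(f[c("AngScMom", "Contrast", "InvDefMom", "Entropy",
                          "SumEntrp", "DifEntrp")]),
               c(1, 0, 1, 0, 0, 0))
  expect_equal(unname(f["SumAverg"]), 14)   # k + l = 7 + 7
  expect_equal(unname(f["Correlat"]), 0)    # zero marginal SD convention

  pl <- rbind(c(0L, 1L), c(0L, 1L))
  s <- build_cooccurrence(pl, matrix(TRUE, 2, 2), c(0, 1), TRUE, gray_levels = 2)
  f2 <- glcm_features(s)
  expect_equal(unname(f2["AngScMom"]), 0.5)
  expect_equal(unname(f2["Contrast"]), 1)
  expect_equal(unname(f2["InvDefMom"]), 0.5)
  expect_equal(unname(f2["Entropy"]), log(2))
  expect_equal(unname(f2["SumAverg"]), 1)   # all mass at k + l = 1
  expect_equal(unname(f2["SumVarnc"]), 0)
  expect_equal(unname(f2["SumEntrp"]), 0)
  expect_equal(unname(f2["DifEntrp"]), 0)   # all mass at |k - l| = 1
  expect_equal(unname(f2["Correlat"]), -1)  # perfect anti-correlation
})

test_that("Haralick features agree with the naive loop oracle", {
  for (seed in 1:15) {
    rm <- random_masked_plane(seed + 200, K = 4)
    com <- build_cooccurrence(rm$plane, rm$mask, c(0, 1),
                              symmetric = (seed %% 2 == 0), gray_levels = 4)
    expect_equal(glcm_features(com), oracle_glcm(com$p), tolerance = 1e-9,
                 info = seed)
  }
})

test_that("contrast via difference decomposition equals the direct double sum", {
  for (seed in 1:10) {
    rm <- random_masked_plane(seed + 300, K = 8)
    com <- build_cooccurrence(rm$plane, rm$mask, gray_levels = 8)
    direct <- 0
    for (k in 1:8) for (l in 1:8) direct <- direct + com$p[k, l] * (k - l)^2
    expect_equal(unname(glcm_features(com)["Contrast"]), direct,
                 tolerance = 1e-12)
  }
})

test_that("symmetric functionals agree between GLCM and GLCH", {
  sym_feats <- c("Contrast", "InvDefMom", "SumAverg", "SumVarnc",
                 "SumEntrp", "DifVarnc", "DifEntrp")
  for (seed in 1:8) {
    rm <- random_masked_plane(seed + 400, K = 16)
    glcm <- glcm_features(build_cooccurrence(rm$plane, rm$mask,
                                             symmetric = TRUE, gray_levels = 16))
    glch <- glcm_features(build_cooccurrence(rm$plane, rm$mask,
                                             symmetric = FALSE, gray_levels = 16))
    expect_equal(glcm[sym_feats], glch[sym_feats], tolerance = 1e-12,
                 info = seed)
  }
})

test_that("gray-level shift moves location features and leaves texture ones", {
  rm <- random_masked_plane(7, K = 64, shape = c(12, 12))
  shift <- 100L
  h1 <- hs_features(roi_histogram(rm$plane, rm$mask))
  h2 <- hs_features(roi_histogram(rm$plane + shift, rm$mask))
  expect_equal(h2[["Mean"]], h1[["Mean"]] + shift)
  for (p in c("Perc01", "Perc10", "Perc50", "Perc90", "Perc99", "Domn01")) {
    expect_equal(h2[[p]], h1[[p]] + shift, info = p)
  }
  for (inv in c("Variance", "Skewness", "Kurtosis", "Maxm01", "Maxm10")) {
    expect_equal(h2[[inv]], h1[[inv]], info = inv)
  }
  g1 <- glcm_features(build_cooccurrence(rm$plane, rm$mask))
  g2 <- glcm_features(build_cooccurrence(rm$plane + shift, rm$mask))
  for (inv in c("AngScMom", "Contrast", "Entropy", "InvDefMom", "DifEntrp",
                "DifVarnc", "SumVarnc", "SumEntrp", "SumOfSqs")) {
    expect_equal(g2[[inv]], g1[[inv]], tolerance = 1e-12, info = inv)
  }
  expect_equal(g2[["SumAverg"]], g1[["SumAverg"]] + 2 * shift, tolerance = 1e-12)
})

test_that("per-frame extraction yields 350 tidy records with the expected split", {
  img <- withr::with_seed(5, array(sample(0:255, 64 * 64 * 3, TRUE),
                                   dim = c(64, 64, 3)))
  frame <- list(image = img, mask = matrix(TRUE, 64, 64), meta = list())
  ft <- extract_frame_features(frame)
  expect_equal(nrow(ft), 350)
  expect_equal(as.vector(table(ft$approach)[c("HS", "GLCM", "GLCH")]),
               c(10 * 13, 10 * 11, 10 * 11))
  expect_equal(length(unique(ft$component)), 10)
  expect_equal(nrow(unique(ft[, c("component", "approach", "feature")])), 350)

  # gray-constant frame: symmetric and asymmetric matrices coincide
  cimg <- array(77, dim = c(64, 64, 3))
  cft <- extract_frame_features(list(image = cimg, mask = matrix(TRUE, 64, 64)))
  glcm <- cft[cft$approach == "GLCM", c("component", "feature", "value")]
  glch <- cft[cft$approach == "GLCH", c("component", "feature", "value")]
  expect_equal(glcm$value, glch$value)
})

test_that("explicit gray-level reduction rescales planes as documented", {
  pl <- matrix(c(0L, 63L, 64L, 255L), 2, 2)
  co <- build_cooccurrence(floor(pl * 4 / 256), matrix(TRUE, 2, 2),
                           c(1, 0), gray_levels = 4)
  expect_equal(sum(co$p), 1)
  expect_equal(dim(co$p), c(4, 4))
})
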