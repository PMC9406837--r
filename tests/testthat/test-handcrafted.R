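test_that("wavelet statistics: constant image has no detail energy", {
  g <- matrix(60, 8, 8)
  f <- dwt_features(g)
  expect_length(f, 12)
  expect_equal(unname(f[1]), 120)            # LL mean = 2c, orthonormal Haar
  expect_equal(unname(f[4:12]), rep(0, 9))   # LH/HL/HH mean, var, sd all 0
  expect_error(dwt_features(matrix(1, 1, 1)), "2x2")
})

test_that("wavelet subbands match the block-transform oracle", {
  set.seed(31)
  for (i in 1:10) {
    g <- rand_gray(8, 8)
    sb <- histofusion:::haar_subbands(g)
    ob <- oracle_haar(g)
    for (nm in c("LL", "LH", "HL", "HH")) {
      expect_equal(sb[[nm]], ob[[nm]], tolerance = 1e-12)
    }
  }
  # odd sizes are padded, not rejected
  expect_length(dwt_features(rand_gray(7, 9)), 12)
})

test_that("orthonormal subbands conserve energy (Parseval)", {
  set.seed(32)
  for (i in 1:10) {
    g <- rand_gray(2 * sample(2:8, 1), 2 * sample(2:8, 1))
    sb <- histofusion:::haar_subbands(g)
    expect_equal(sum(sapply(sb, function(s) sum(s^2))), sum(g^2),
                 tolerance = 1e-6)
  }
})

test_that("LBP codes follow the >= tie rule and the 24-term oracle", {
  flat <- matrix(5, 7, 7)
  expect_equal(lbp_code(flat, 4, 4), 2^24 - 1)   # ties count as 1

  g <- matrix(0, 7, 7); g[4, 4] <- 10            # all neighbours below centre
  expect_equal(lbp_code(g, 4, 4), 0)

  expect_error(lbp_code(flat, 2, 4), "border")

  set.seed(33)
  for (i in 1:20) {
    g <- rand_gray(5, 5)
    expect_equal(lbp_code(g, 3, 3), oracle_lbp_code(g, 3, 3))
  }
})

test_that("LBP histogram has 203 bins, sums to 1, one-hot on constants", {
  f <- lbp_features(matrix(9, 10, 10))
  expect_length(f, 203)
  expect_equal(sum(f), 1)
  expect_equal(unname(f[203]), 1)  # code 2^24 - 1 falls in the last bin
  expect_error(lbp_features(matrix(1, 4, 4)), "5x5")
})

test_that("LBP features are invariant to a constant gray offset", {
  set.seed(34)
  g <- rand_gray(12, 12)
  expect_equal(lbp_features(g), lbp_features(g + 10))
  # vectorised codes agree with the per-pixel definition
  codes <- histofusion:::lbp_code_matrix(g)
  expect_equal(codes[1, 1], lbp_code(g, 3, 3))
  expect_equal(codes[3, 5], lbp_code(g, 5, 7))
})

test_that("fuzzy colour histogram puts mass where the hue dictates", {
  # hue exactly on the centre of bin 5 (90 degrees)
  img <- array(0, dim = c(6, 6, 3))
  img[, , 1] <- 127.5; img[, , 2] <- 255; img[, , 3] <- 0
  f <- fch_features(img)
  expect_length(f, 16)
  expect_equal(sum(f), 1)
  expect_equal(unname(f[5]), 1)

  # hue midway between centres 1 (0 deg) and 2 (22.5 deg): 11.25 degrees
  img2 <- array(0, dim = c(4, 4, 3))
  img2[, , 1] <- 255; img2[, , 2] <- 0.1875 * 255; img2[, , 3] <- 0
  f2 <- fch_features(img2)
  expect_equal(unname(f2[1]), 0.5, tolerance = 1e-9)
  expect_equal(unname(f2[2]), 0.5, tolerance = 1e-9)

  # achromatic image: all mass in bin 1 by convention
  f3 <- fch_features(array(120, dim = c(4, 4, 3)))
  expect_equal(unname(f3[1]), 1)
})

test_that("fuzzy colour histogram ignores pixel order", {
  set.seed(35)
  img <- rand_rgb(8, 8)
  perm <- sample(64)
  shuffled <- img
  for (ch in 1:3) {
    m <- img[, , ch]
    shuffled[, , ch] <- matrix(as.numeric(m)[perm], 8, 8)
  }
  expect_equal(fch_features(img), fch_features(shuffled), tolerance = 1e-12)
})

test_that("co-occurrence matrix matches the hand-enumerated binary case", {
  img <- matrix(c(0, 0, 1, 1), 2, 2)  # columns (0,0) and (1,1)
  M <- glcm_matrix(img, theta = 0, d = 1, levels = 2, pre_quantized = TRUE)
  expect_equal(unclass(M)[1, 2], 0.5, ignore_attr = TRUE)
  expect_equal(unclass(M)[2, 1], 0.5, ignore_attr = TRUE)
  expect_equal(unclass(M)[1, 1] + unclass(M)[2, 2], 0)
  st <- histofusion:::haralick13(M)
  expect_equal(unname(st["contrast"]), 1.0)
  expect_equal(unname(st["asm"]), 0.5)
})

test_that("constant image collapses the co-occurrence statistics", {
  g <- matrix(100, 6, 6)
  for (th in c(0, 45, 90, 135)) {
    M <- glcm_matrix(g, theta = th, d = 1)
    st <- histofusion:::haralick13(M)
    expect_equal(unname(st["contrast"]), 0)
    expect_equal(unname(st["asm"]), 1)
    expect_equal(unname(st["entropy"]), 0)
  }
  expect_length(glcm_features(g), 13)
})

test_that("GLCM matrices are symmetric, normalised, and match the oracle", {
  set.seed(36)
  for (i in 1:10) {
    q <- matrix(sample(0:3, 64, replace = TRUE), 8, 8)
    for (th in c(0, 45, 90, 135)) {
      M <- glcm_matrix(q, theta = th, d = 1, levels = 4, pre_quantized = TRUE)
      expect_equal(sum(M), 1, tolerance = 1e-12)
      expect_equal(unclass(M), t(unclass(M)), ignore_attr = TRUE)
      off <- histofusion:::glcm_offset(th, 1L)
      expect_equal(unclass(M), oracle_glcm(q, 4, off), ignore_attr = TRUE,
                   tolerance = 1e-12)
    }
    expect_equal(unname(glcm_features(q, levels = 4, pre_quantized = TRUE)),
                 unname(oracle_glcm13(q, 4)), tolerance = 1e-9)
  }
})

test_that("the 244-feature descriptor has the fixed block layout", {
  set.seed(37)
  img <- rand_rgb(12, 12)
  f <- handcrafted_features(img)
  expect_length(f, 244)
  expect_equal(attr(f, "blocks"),
               c(dwt = 12L, lbp = 203L, fch = 16L, glcm = 13L))
  expect_equal(names(f)[1], "dwt_1")
  expect_equal(names(f)[13], "lbp_1")
  expect_equal(names(f)[216], "fch_1")
  expect_equal(names(f)[232], "glcm_asm")
  expect_identical(f, handcrafted_features(img))  # determinism

  flat <- array(90, dim = c(8, 8, 3))
  ff <- handcrafted_features(flat)
  lbp_block <- ff[13:215]
  expect_equal(sum(lbp_block == 0), 202)           # one-hot histogram
  expect_equal(sum(ff[216:231]), 1)                # FCH sums to 1
  expect_equal(unname(ff["glcm_contrast"]), 0)
})
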