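two_pop_field <- function(noise_sd = 0, seed = 60, n_pos = 20, n_neg = 180) {
  synth_image(list(
    "IBA1+MAC2+" = list(n = n_pos, channels = c(IBA1 = 200, MAC2 = 180)),
    "IBA1+MAC2-" = list(n = n_neg, channels = c(IBA1 = 200))),
    width = 600, height = 500, radius = 5, noise_sd = noise_sd, seed = seed)
}

seg_all <- function(stack, window = 51, offset = 60, min_size = 20) {
  lapply(stack$channels, function(ch) {
    segment_mask(adaptive_threshold(ch, window, offset), min_size)
  })
}

test_that("synthetic fields carry exact ground truth", {
  st <- two_pop_field()
  expect_equal(nrow(st$truth), 200)
  expect_equal(sum(st$truth$phenotype == "IBA1+MAC2+"), 20)
  # noiseless render: configured intensity inside masks, zero outside
  expect_setequal(unique(as.vector(st$channels$IBA1)), c(0, 200))
  expect_setequal(unique(as.vector(st$channels$MAC2)), c(0, 180))

  empty <- synth_image(list(none = list(n = 0, channels = c(A = 1))),
                       width = 50, height = 40, seed = 1)
  expect_equal(nrow(empty$truth), 0)
  expect_true(all(empty$channels$A == 0))

  expect_error(synth_image(list(x = list(n = 500,
                                         channels = c(A = 10))),
                           width = 60, height = 60, radius = 8, seed = 1),
               "dense")
})

test_that("adaptive thresholding matches a sliding-window oracle", {
  img <- matrix(0, 24, 30)
  img[10:13, 12:15] <- 100 # square smaller than the window
  got <- adaptive_threshold(img, window = 11, offset = 2)
  oracle <- matrix(FALSE, 24, 30)
  for (i in 1:24) for (j in 1:30) {
    ri <- pmin(pmax((i - 5):(i + 5), 1), 24)
    ci <- pmin(pmax((j - 5):(j + 5), 1), 30)
    oracle[i, j] <- img[i, j] > mean(img[ri, ci]) + 2
  }
  expect_identical(got, oracle)
  expect_true(all(got[10:13, 12:15])) # the square itself is foreground

  flat <- matrix(7, 20, 20)
  expect_false(any(adaptive_threshold(flat, 5, offset = 1)))
  expect_true(all(adaptive_threshold(flat, 5, offset = -10)))
  expect_error(adaptive_threshold(flat, 4), "odd")
  expect_error(adaptive_threshold(flat, 21), "larger")
})

test_that("segmentation labels 8-connected components with a size gate", {
  mask <- matrix(FALSE, 30, 30)
  mask[2:7, 2:7] <- TRUE        # 36 px
  mask[20:23, 20:24] <- TRUE    # 20 px
  mask[15, 15] <- TRUE          # 1 px speck
  li <- segment_mask(mask, min_size = 5)
  expect_equal(nrow(li$objects), 2)
  expect_setequal(li$objects$area, c(36, 20))
  # diagonal touch merges under 8-connectivity
  d <- matrix(FALSE, 10, 10)
  d[2:3, 2:3] <- TRUE; d[4:5, 4:5] <- TRUE
  expect_equal(nrow(segment_mask(d, min_size = 1)$objects), 1)
  expect_equal(nrow(segment_mask(matrix(FALSE, 5, 5))$objects), 0)
})

test_that("segmentation commutes with translation away from borders", {
  set.seed(61)
  mask <- matrix(FALSE, 60, 60)
  mask[10:14, 10:15] <- TRUE
  mask[30:37, 40:44] <- TRUE
  shift <- function(m, dr, dc) {
    out <- matrix(FALSE, nrow(m), ncol(m))
    out[(1 + dr):nrow(m), (1 + dc):ncol(m)] <-
      m[1:(nrow(m) - dr), 1:(ncol(m) - dc)]
    out
  }
  a <- segment_mask(mask, min_size = 5)$objects
  b <- segment_mask(shift(mask, 3, 4), min_size = 5)$objects
  expect_equal(b$area, a$area)
  expect_equal(b$cx, a$cx + 4)
  expect_equal(b$cy, a$cy + 3)
})

test_that("colocalization applies the strict >10% min-area rule", {
  lab <- function(m) segment_mask(m, min_size = 1)
  base <- matrix(FALSE, 40, 40)
  a <- base; a[1:10, 1:10] <- TRUE            # 100 px
  b <- base; b[1:10, 21:30] <- TRUE           # disjoint
  expect_equal(nrow(colocalize(lab(a), lab(b))), 0)

  # overlap of exactly 10% of the smaller mask: NOT paired
  b2 <- base; b2[1:10, 10:19] <- TRUE         # 100 px, overlap col 10 = 10 px
  expect_equal(nrow(colocalize(lab(a), lab(b2), min_overlap = 0.10)), 0)
  # one more column of overlap crosses the threshold
  b3 <- base; b3[1:10, 9:18] <- TRUE          # overlap 20 px = 20%
  got <- colocalize(lab(a), lab(b3), min_overlap = 0.10)
  expect_equal(nrow(got), 1)

  # nested masks pair with fraction 1 under the min denominator
  small <- base; small[4:6, 4:6] <- TRUE
  nest <- colocalize(lab(a), lab(small))
  expect_equal(nest$overlap_frac, 1)

  # symmetry of the pairing rule
  s1 <- colocalize(lab(a), lab(b3))
  s2 <- colocalize(lab(b3), lab(a))
  expect_equal(s1$overlap_px, s2$overlap_px)
  expect_error(colocalize(lab(a), lab(matrix(FALSE, 10, 10))), "mismatch")
})

test_that("each object pairs at most once, preferring the larger overlap", {
  base <- matrix(FALSE, 30, 60)
  a <- base; a[5:14, 5:24] <- TRUE               # one wide object
  b <- base
  b[5:14, 20:29] <- TRUE                          # overlaps 5 columns
  b[5:14, 31:40] <- TRUE                          # disjoint twin
  got <- colocalize(segment_mask(a, 1), segment_mask(b, 1))
  expect_equal(nrow(got), 1)
  expect_equal(got$overlap_px, 50)
})

test_that("phenotype counting recovers the planted truth exactly", {
  st <- two_pop_field()
  pc <- count_phenotypes(seg_all(st), anchor = "IBA1")
  expect_equal(unname(pc$counts["IBA1+MAC2+"]), 20)
  expect_equal(unname(pc$counts["IBA1+MAC2-"]), 180)
  expect_equal(sum(pc$counts), pc$n_anchor) # partition
  expect_equal(unname(pc$fractions["MAC2"]), 10)

  # no marker objects at all -> zero percent positive
  st0 <- synth_image(list(only = list(n = 30, channels = c(IBA1 = 150,
                                                           MAC2 = 0))),
                     width = 400, height = 300, radius = 5, seed = 3)
  pc0 <- count_phenotypes(seg_all(st0, offset = 40), anchor = "IBA1")
  expect_equal(unname(pc0$fractions["MAC2"]), 0)
  expect_error(count_phenotypes(seg_all(st)["MAC2"], anchor = "IBA1"),
               "anchor")
})

test_that("per-object intensity means are exact on noiseless renders", {
  ph <- list(dim_cells = list(n = 10, channels = c(IBA1 = 150, P2RY12 = 10)),
             bright_cells = list(n = 10, channels = c(IBA1 = 150,
                                                      P2RY12 = 50)))
  st <- synth_image(ph, width = 500, height = 400, radius = 5, seed = 4)
  labs <- seg_all(st, offset = 40)
  mi <- mean_intensity_per_object(st$channels$P2RY12, labs$IBA1)
  expect_equal(nrow(mi), 20)
  expect_setequal(round(unique(mi$mean_intensity), 6), c(10, 50))
  expect_equal(attr(mi, "image_mean"), 30)

  uni <- mean_intensity_per_object(matrix(7, 400, 500), labs$IBA1)
  expect_true(all(uni$mean_intensity == 7))
  empty <- segment_mask(matrix(FALSE, 400, 500))
  expect_equal(nrow(mean_intensity_per_object(st$channels$P2RY12, empty)),
               0)
})

test_that("intensity images survive the TIFF round trip", {
  st <- two_pop_field(seed = 62, n_pos = 5, n_neg = 10)
  path <- withr::local_tempfile(fileext = ".tif")
  write_image_tiff(st$channels$IBA1, path)
  back <- read_image_tiff(path)
  expect_equal(dim(back), dim(st$channels$IBA1))
  expect_equal(max(abs(back - st$channels$IBA1)), 0, tolerance = 0.51)
})
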