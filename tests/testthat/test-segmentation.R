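# Edge-based foreground segmentation and seeded instance splitting.

test_that("denoising is a mean-preserving smoother with an identity limit", {
  const <- matrix(7, 60, 60)
  expect_equal(denoise(const, 2), const, tolerance = 1e-12)
  img <- matrix(100, 80, 80)
  expect_identical(denoise(img, 0), img)
  set.seed(1)
  noisy <- img + matrix(rnorm(6400, 0, 5), 80, 80)
  sm <- denoise(noisy, 1.5)
  expect_lt(sd(sm - img), sd(noisy - img))
  expect_lt(abs(mean(sm) - mean(noisy)) / mean(noisy), 0.001)
})

test_that("Scharr magnitude localises steps at any orientation", {
  expect_equal(edge_magnitude(matrix(3, 50, 50)), matrix(0, 50, 50))
  # vertical step: maximal response in the two columns flanking the step
  step <- matrix(0, 50, 50); step[, 26:50] <- 10
  mag <- edge_magnitude(step)
  expect_true(all(mag[, c(25, 26)] == max(mag)))
  expect_true(all(mag[, c(1:23, 28:50)] == 0))
  # 45-degree edge with the same cross-sectional profile: peak response
  # within 5% of the axis-aligned peak, against a convolution oracle
  nr <- 60
  sigmoid <- function(d) 10 / (1 + exp(-d / 1.5))
  axis_edge <- outer(1:nr, 1:nr, function(r, c) sigmoid(c - nr / 2))
  diag_edge <- outer(1:nr, 1:nr,
                     function(r, c) sigmoid((r + c - nr) / sqrt(2)))
  mag_axis <- edge_magnitude(axis_edge)
  mag_diag <- edge_magnitude(diag_edge)
  expect_lt(abs(max(mag_diag) - max(mag_axis)) / max(mag_axis), 0.05)
  scharr_at <- function(img, r, c) {
    gx <- sum(img[(r - 1):(r + 1), c + 1] * c(3, 10, 3) -
                img[(r - 1):(r + 1), c - 1] * c(3, 10, 3)) / 16
    gy <- sum(img[r + 1, (c - 1):(c + 1)] * c(3, 10, 3) -
                img[r - 1, (c - 1):(c + 1)] * c(3, 10, 3)) / 16
    sqrt(gx^2 + gy^2)
  }
  expect_equal(mag_diag[30, 31], scharr_at(diag_edge, 30, 31),
               tolerance = 1e-12)
})

test_that("log-normal threshold recovers a dark disk and handles edge cases", {
  # constant image: no edges anywhere, empty foreground
  mag0 <- edge_magnitude(matrix(5, 200, 200))
  expect_equal(sum(threshold_foreground(mag0, seg_params())), 0)
  # dark disk on bright background, 50% contrast
  img <- matrix(100, 200, 200)
  rr <- outer((1:200 - 100)^2, (1:200 - 100)^2, "+")
  disk <- rr <= 20^2
  img[disk] <- 50
  p <- seg_params()
  fg <- threshold_foreground(edge_magnitude(denoise(img, 1)), p)
  truthd <- dilate01(disk, p$footprint_dilation_radius)
  iou <- sum(fg & truthd) / sum(fg | truthd)
  expect_gte(iou, 0.90)
  # a frame that is almost all foreground cannot seed the flood fill:
  # one large dark region whose filled interior exceeds 80% of the frame
  set.seed(2)
  big <- matrix(100, 200, 200) + matrix(rnorm(40000), 200, 200)
  big[8:192, 8:192] <- big[8:192, 8:192] - 50
  expect_error(
    threshold_foreground(edge_magnitude(denoise(big, 0.5)), seg_params()),
    "flood-fill seed")
  # degenerate distributions are refused
  mag2 <- matrix(0, 200, 200); mag2[1:50] <- 1
  expect_error(threshold_foreground(mag2, seg_params()), "degenerate")
})

test_that("increasing the threshold never grows the foreground", {
  ds <- small_dataset()
  img <- denoise(ds$fxm[[10]], 1)
  mag <- edge_magnitude(img)
  areas <- vapply(c(0.5, 1, 1.5, 2), function(k)
    sum(threshold_foreground(mag, seg_params(threshold_k = k),
                             ds$pillar_mask)), numeric(1))
  expect_true(all(diff(areas) <= 0))
})

test_that("nuclear seed detection finds isolated spots at their centres", {
  p <- seg_params()
  expect_identical(nrow(detect_seeds(matrix(5, 100, 100), p)), 0L)
  img <- matrix(10, 120, 120)
  put_spot <- function(img, r0, c0, amp = 200, sd = 3) {
    rr <- outer((1:120 - r0)^2, (1:120 - c0)^2, "+")
    img + amp * exp(-rr / (2 * sd^2))
  }
  img <- put_spot(img, 40, 40)
  img <- put_spot(img, 40, 80)
  s <- detect_seeds(img, p)
  expect_identical(nrow(s), 2L)
  s <- s[order(s$col), ]
  expect_lt(abs(s$row[1] - 40), 1)
  expect_lt(abs(s$col[1] - 40), 1)
  expect_lt(abs(s$col[2] - 80), 1)
  # spots below the minimum area are rejected by the area gate
  tiny <- put_spot(matrix(10, 120, 120), 60, 60, amp = 200, sd = 0.8)
  found <- detect_seeds(tiny, seg_params(seed_min_area = 1))
  expect_identical(nrow(found), 1L)
  expect_identical(
    nrow(detect_seeds(tiny, seg_params(seed_min_area = found$area + 1L))),
    0L)
})

test_that("instance splitting honours seeds and flags unseeded components", {
  # one component, one interior seed: whole component takes the label
  mask <- matrix(FALSE, 60, 60); mask[20:40, 20:40] <- TRUE
  res <- split_instances(mask, data.frame(row = 30, col = 30, label = 4L))
  expect_true(all(res$labels[mask] == 4L))
  expect_true(all(res$labels[!mask] == 0L))
  # two touching disks, one seed each: boundary on the equidistant line
  rr1 <- outer((1:100 - 50)^2, (1:100 - 35)^2, "+")
  rr2 <- outer((1:100 - 50)^2, (1:100 - 65)^2, "+")
  mask2 <- rr1 <= 16^2 | rr2 <= 16^2
  res2 <- split_instances(mask2, data.frame(row = c(50, 50), col = c(35, 65),
                                            label = c(1L, 2L)))
  lab <- res2$labels
  idx <- which(mask2, arr.ind = TRUE)
  d1 <- sqrt((idx[, 1] - 50)^2 + (idx[, 2] - 35)^2)
  d2 <- sqrt((idx[, 1] - 50)^2 + (idx[, 2] - 65)^2)
  got <- lab[idx]
  want <- ifelse(d1 < d2, 1L, 2L)
  # pixels further than 1 px from the equidistant line must match the
  # distance-to-seed oracle
  off_line <- abs(d1 - d2) > 2
  expect_true(all(got[off_line] == want[off_line]))
  # labels partition the mask
  expect_true(all(lab[!mask2] == 0L))
  expect_identical(sum(res2$unseeded), 0L)
  # component without a seed stays foreground but unlabelled, flagged
  mask3 <- mask2
  mask3[5:10, 5:10] <- TRUE
  res3 <- split_instances(mask3, data.frame(row = c(50, 50), col = c(35, 65)))
  expect_true(all(res3$labels[5:10, 5:10] == 0L))
  expect_true(all(res3$unseeded[5:10, 5:10]))
  # seeds off the mask are dropped with a warning
  expect_warning(split_instances(mask, data.frame(row = 5, col = 5)),
                 "outside")
})

test_that("every synthetic cell is captured by exactly one label", {
  ds <- small_dataset()
  p <- seg_params()
  for (f in c(5, 15)) {
    fg <- threshold_foreground(edge_magnitude(denoise(ds$fxm[[f]],
                                                      p$denoise_sigma)),
                               p, ds$pillar_mask)
    seeds <- detect_seeds(ds$nuclear[[f]], p)
    res <- split_instances(fg, seeds)
    lab <- res$labels
    # label partition: labelled pixels lie inside the foreground, and
    # labels are disjoint positive integers by construction
    expect_true(all(fg[lab > 0]))
    hit <- integer(0)
    for (i in seq_len(ds$config$n_cells)) {
      tm <- dilate01(truth_footprint_mask(ds, i, f - 1),
                     p$footprint_dilation_radius)
      ids <- lab[tm]
      ids <- ids[ids > 0]
      id <- as.integer(names(which.max(table(ids))))
      # the winning label covers essentially the whole footprint
      expect_gte(sum(ids == id) / sum(tm), 0.95)
      hit <- c(hit, id)
    }
    # one distinct label per cell: no merges
    expect_identical(length(unique(hit)), ds$config$n_cells)
  }
})

test_that("segmentation recovers default-experiment footprints", {
  ds <- default_dataset()
  p <- seg_params()
  ious <- c()
  for (f in c(20, 100)) {
    fg <- threshold_foreground(edge_magnitude(denoise(ds$fxm[[f]],
                                                      p$denoise_sigma)),
                               p, ds$pillar_mask)
    seeds <- detect_seeds(ds$nuclear[[f]], p)
    lab <- split_instances(fg, seeds)$labels
    for (i in seq_len(ds$config$n_cells)) {
      # deliberate over-segmentation: compare against the truth dilated by
      # the same footprint dilation the masks carry
      tm <- dilate01(truth_footprint_mask(ds, i, f - 1),
                     p$footprint_dilation_radius)
      ids <- lab[tm]
      ids <- ids[ids > 0]
      if (!length(ids)) { ious <- c(ious, 0); next }
      id <- as.integer(names(which.max(table(ids))))
      pred <- lab == id
      ious <- c(ious, sum(pred & tm) / sum(pred | tm))
    }
  }
  expect_gte(mean(ious >= 0.85), 0.95)
})
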