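test_that("8-bit conversion maps endpoints linearly and is idempotent", {
  hi <- channel_image(matrix(65535, 4, 4), 65535, "x")
  expect_true(all(to_8bit(hi)$pixels == 255))
  mid <- channel_image(matrix(32768, 2, 2), 65535, "x")
  expect_true(all(to_8bit(mid)$pixels == 128))  # round(32768/65535*255)
  set.seed(3)
  m <- matrix(sample(0:255, 64, TRUE), 8, 8)
  expect_equal(to_8bit(img8(m))$pixels, m)      # identity on 8-bit
  expect_equal(to_8bit(to_8bit(channel_image(m * 257, 65535)))$pixels,
               to_8bit(channel_image(m * 257, 65535))$pixels)
})

test_that("inversion is an involution on 8-bit images", {
  z <- img8(matrix(0, 5, 5))
  expect_true(all(invert_image(z)$pixels == 255))
  expect_equal(invert_image(img8(matrix(13, 1, 1)))$pixels[1, 1], 242)
  set.seed(4)
  m <- img8(matrix(sample(0:255, 100, TRUE), 10, 10))
  expect_equal(invert_image(invert_image(m))$pixels, m$pixels)
  expect_error(invert_image(channel_image(matrix(5, 2, 2), 65535)), "8-bit")
})

test_that("rolling-ball subtraction removes flat background, keeps small objects,
           and never exceeds the input", {
  flat <- img8(matrix(40, 80, 80))
  expect_true(all(subtract_background_rolling(flat, 30)$pixels == 0))

  sq <- matrix(0, 101, 101)
  sq[50:52, 50:52] <- 200   # 3x3 square, far smaller than the r=30 element
  out <- subtract_background_rolling(img8(sq), 30)$pixels
  expect_equal(out[50:52, 50:52], matrix(200, 3, 3))
  expect_true(all(out[sq == 0] == 0))

  set.seed(5)
  r <- matrix(sample(0:255, 60 * 60, TRUE), 60, 60)
  expect_true(all(subtract_background_rolling(img8(r), 10)$pixels <= r))
})

test_that("median filter matches the brute-force disk-neighborhood oracle", {
  expect_equal(px(median_filter(img8(matrix(7, 9, 9)), 1)), matrix(7, 9, 9))
  hot <- matrix(0, 9, 9); hot[5, 5] <- 255
  expect_true(all(px(median_filter(img8(hot), 1)) == 0))

  # exhaustive oracle with edge replication, disk offsets dr^2+dc^2 <= r^2
  brute <- function(m, r) {
    n <- nrow(m); k <- ncol(m)
    out <- m
    for (i in seq_len(n)) for (j in seq_len(k)) {
      vals <- c()
      for (dr in -r:r) for (dc in -r:r) if (dr^2 + dc^2 <= r^2)
        vals <- c(vals, m[min(max(i + dr, 1), n), min(max(j + dc, 1), k)])
      out[i, j] <- median(vals)
    }
    out
  }
  set.seed(6)
  for (r in 1:2) {
    m <- matrix(sample(0:255, 25, TRUE), 5, 5)
    expect_equal(px(median_filter(img8(m), r)), brute(m, r), info = paste("r =", r))
  }
})

test_that("threshold windows are inclusive and partition the intensity range", {
  m <- img8(matrix(c(0, 13, 14, 255), 2, 2))
  w <- threshold_window(m, 0, 13)
  expect_equal(as.vector(w), c(TRUE, TRUE, FALSE, FALSE))
  expect_true(all(threshold_window(m, 0, 255)))
  expect_true(threshold_window(img8(matrix(50, 1, 1)), 50, 50)[1, 1])
  expect_error(threshold_window(m, 20, 10), "lo must not exceed")

  set.seed(8)
  r <- img8(matrix(sample(0:255, 400, TRUE), 20, 20))
  parts <- list(c(0, 50), c(51, 200), c(201, 255))
  masks <- lapply(parts, function(p) threshold_window(r, p[1], p[2]))
  expect_false(any(masks[[1]] & masks[[2]]) || any(masks[[2]] & masks[[3]]))
  expect_true(all(masks[[1]] | masks[[2]] | masks[[3]]))
})

test_that("morphological clean fills sub-element holes and removes specks", {
  d <- disk_mask(160, 160, 80, 80, 60)
  holey <- d; holey[78:82, 78:82] <- FALSE   # 5-px hole
  cleaned <- morphological_clean(holey, 25)
  expect_true(all(cleaned[78:82, 78:82]))
  speck <- matrix(FALSE, 160, 160); speck[10:12, 10:12] <- TRUE
  expect_false(any(morphological_clean(speck, 25)))
  # large disk survives with area within 2%
  expect_lt(abs(sum(morphological_clean(d, 25)) - sum(d)) / sum(d), 0.02)
})

test_that("watershed splits touching disks and degrades to component labeling", {
  two <- disk_mask(100, 100, 50, 28, 15) | disk_mask(100, 100, 50, 72, 15)
  expect_false(any(disk_mask(100, 100, 50, 28, 15) & disk_mask(100, 100, 50, 72, 15)))
  lab <- watershed_split(two, 5)
  expect_equal(max(lab), 2L)

  # overlapping disks, centers 30 px apart: split near the waist
  ov <- disk_mask(100, 100, 35, 50, 20) | disk_mask(100, 100, 65, 50, 20)
  labo <- watershed_split(ov, 5)
  expect_equal(max(labo), 2L)
  expect_true(labo[35, 50] > 0 && labo[65, 50] > 0)
  expect_false(labo[35, 50] == labo[65, 50])
  expect_true(all((labo > 0) == ov))   # every foreground pixel labeled once

  expect_true(all(watershed_split(matrix(FALSE, 10, 10), 5) == 0L))
  expect_identical(watershed_split(ov, 5), labo)  # deterministic
})
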