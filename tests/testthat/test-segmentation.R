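test_that("particle gates are inclusive at both area bounds", {
  gate <- particle_gate(1000, 50000, 0.5, 1.0)
  lab <- matrix(0L, 60, 80)
  lab[10:34, 10:49] <- 1L          # 25 x 40 = exactly 1,000 px^2
  expect_length(find_particles(lab, gate), 1)
  lab2 <- matrix(0L, 60, 80)
  lab2[10:36, 10:46] <- 1L         # 27 x 37 = 999 px^2
  expect_length(find_particles(lab2, gate), 0)

  ngate <- particle_gate(10, 1000, 0.3, 1.0)
  lab3 <- matrix(0L, 20, 20)
  lab3[5:7, 5:7] <- 1L             # 9 px^2 < 10
  expect_length(find_particles(lab3, ngate), 0)
  lab3[5:7, 5:8] <- 1L             # 12 px^2
  expect_length(find_particles(lab3, ngate), 1)
})

test_that("circularity separates disks from lines under the contour estimator", {
  for (r in c(10, 25, 50)) {
    lab <- ifelse(disk_mask(2 * r + 21, 2 * r + 21, r + 11, r + 11, r), 1L, 0L)
    roi <- find_particles(lab, particle_gate(1, 1e9))[[1]]
    expect_gte(roi$circularity, 0.90)
    expect_lte(roi$circularity, 1.00)
  }
  line <- matrix(0L, 3, 2010); line[2, 6:2005] <- 1L
  roi <- find_particles(line, particle_gate(1, 1e9))[[1]]
  expect_lt(roi$circularity, 0.1)
  # and the neurosphere gate rejects it on circularity despite its area
  expect_length(find_particles(line, particle_gate(1000, 50000, 0.5, 1.0)), 0)
})

test_that("gating is monotone: wider gates never drop retained particles", {
  set.seed(12)
  noise <- matrix(runif(64 * 64) > 0.6, 64, 64)
  lab <- label_components(noise)
  narrow <- find_particles(lab, particle_gate(3, 20, 0.4, 0.9))
  wide <- find_particles(lab, particle_gate(1, 50, 0.2, 1.0))
  expect_true(all(vapply(narrow, `[[`, 0L, "roi_id") %in%
                  vapply(wide, `[[`, 0L, "roi_id")))
})

test_that("component labeling matches the flood-fill oracle on random masks", {
  set.seed(13)
  for (i in 1:20) {
    mask <- matrix(runif(64 * 64) > 0.7, 64, 64)
    expect_identical(canonical_labels(label_components(mask)),
                     canonical_labels(flood_fill_labels(mask)))
  }
})

test_that("neurosphere segmentation recovers planted blobs and gates small ones", {
  # three spheroid blobs of gateable size
  gen <- generate_stack(synthesis_params(
    seed = 1, image_shape = c(700, 700), n_spheroids = 3,
    spheroid_radius_range = c(60, 90), n_nuclei_per_spheroid = 20))
  rois <- segment_neurospheres(get_channel(gen$stack, "HU"))
  expect_length(rois, 3)
  expect_true(all(vapply(rois, `[[`, "", "source") == "auto"))
  # each planted center lands inside one detected ROI
  for (s in seq_len(3)) {
    ctr <- unlist(gen$truth$spheroids[s, c("row", "col")])
    hits <- vapply(rois, function(r)
      spherequant:::roi_contains(r, ctr), TRUE)
    expect_equal(sum(hits), 1L)
  }

  blank <- img8(matrix(5, 300, 300), "HU")
  expect_length(segment_neurospheres(blank), 0)

  # radius-10 blob (~314 px^2) falls below the 1,000 px^2 area gate
  small <- matrix(5, 300, 300)
  small[disk_mask(300, 300, 150, 150, 10)] <- 200
  expect_length(segment_neurospheres(img8(small, "HU")), 0)
})

test_that("nucleus segmentation within an ROI respects gate and membership", {
  gen <- generate_stack(synthesis_params(
    seed = 2, image_shape = c(360, 360), n_spheroids = 1,
    n_nuclei_per_spheroid = 20, min_separation = 15))
  rois <- segment_neurospheres(get_channel(gen$stack, "HU"))
  expect_length(rois, 1)
  nuc <- segment_nuclei_in_roi(get_channel(gen$stack, "DAPI"), rois[[1]])
  expect_length(nuc, 20)
  # all centroids inside the parent ROI; nucleus areas sum below ROI area
  expect_true(all(vapply(nuc, function(n)
    spherequant:::roi_contains(rois[[1]], n$centroid), TRUE)))
  expect_lt(sum(vapply(nuc, `[[`, 0L, "area")), rois[[1]]$area)

  blank_roi <- roi_from_mask(disk_mask(200, 200, 100, 100, 60), 1L)
  expect_length(
    segment_nuclei_in_roi(img8(matrix(5, 200, 200), "DAPI"), blank_roi), 0)

  # an 8 px^2 particle is rejected by the 10-1,000 px^2 gate
  tiny <- matrix(5, 200, 200)
  tiny[96:99, 100:101] <- 250
  expect_length(
    segment_nuclei_in_roi(img8(tiny, "DAPI"), blank_roi), 0)
  expect_error(
    segment_nuclei_in_roi(img8(tiny, "DAPI"),
                          roi_from_mask(disk_mask(300, 300, 250, 250, 40), 1L)),
    "outside")
})
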