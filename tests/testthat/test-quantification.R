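mk_records <- function(hu, sox, phox = NULL, roi_id = 1L) {
  df <- data.frame(roi_id = roi_id, pos_HU = hu, pos_SOX10 = sox)
  if (!is.null(phox)) df$pos_PHOX2B <- phox
  df
}

test_that("per-neurosphere summaries count conjunctions and negations", {
  rec <- data.frame(roi_id = 1L, pos_HU = c(rep(TRUE, 4), rep(FALSE, 6)))
  s <- summarize_roi(rec, 1L, c("HU+", "HU-"))
  expect_equal(s$n_nuclei, 10L)
  expect_equal(s$n_positive[["HU+"]], 4L)
  expect_equal(s$proportion[["HU+"]], 0.4)
  expect_true(s$proportions_defined)

  rec2 <- mk_records(hu = rep(TRUE, 5),
                     sox = c(TRUE, TRUE, TRUE, TRUE, FALSE),
                     phox = c(TRUE, TRUE, TRUE, FALSE, TRUE))
  s2 <- summarize_roi(rec2, 1L, c("SOX10+PHOX2B+", "SOX10+PHOX2B+HU-"))
  expect_equal(s2$n_positive[["SOX10+PHOX2B+"]], 3L)
  # all nuclei are HU+ so the HU- progenitor combination is empty
  expect_equal(s2$n_positive[["SOX10+PHOX2B+HU-"]], 0L)

  empty <- summarize_roi(rec[0, ], 1L, "HU+")
  expect_equal(empty$n_nuclei, 0L)
  expect_false(empty$proportions_defined)
  expect_true(is.na(empty$proportion[["HU+"]]))
})

test_that("combination counts are monotone and sign combinations partition", {
  set.seed(31)
  rec <- mk_records(hu = runif(40) > 0.5, sox = runif(40) > 0.5,
                    phox = runif(40) > 0.5)
  s <- summarize_roi(rec, 1L, c("SOX10+", "SOX10+PHOX2B+", "SOX10+PHOX2B+HU+"))
  expect_gte(s$n_positive[["SOX10+"]], s$n_positive[["SOX10+PHOX2B+"]])
  expect_gte(s$n_positive[["SOX10+PHOX2B+"]],
             s$n_positive[["SOX10+PHOX2B+HU+"]])
  quad <- summarize_roi(rec, 1L, c("HU+SOX10+", "HU+SOX10-", "HU-SOX10+", "HU-SOX10-"))
  expect_equal(sum(unlist(quad$n_positive)), quad$n_nuclei)
})

test_that("border distances agree with geometry and brute force", {
  sph <- roi_from_mask(disk_mask(220, 220, 101, 101, 50), 1L)  # center (100,100) 0-based
  pts <- rbind(c(100, 180), c(20, 100), c(100, 195), c(180, 100), c(10, 100),
               c(100, 15))
  mm <- measure_border_distances(sph, pts, shape = c(220, 220))
  expect_length(mm$distances, 5)
  expect_false(is.unsorted(rev(mm$distances)))
  # analytic: center distance minus radius, up to discretization
  # planted distances: 30, 30, 45, 30, 40, 35 -> top 5 = 45, 40, 35, 30, 30
  expect_true(all(abs(mm$distances - c(45, 40, 35, 30, 30)) < 0.5))

  # top-5 selection from 7 points at known distances
  offs <- c(1:7)
  pts7 <- cbind(100, 150 + offs)   # boundary col near 150
  mm7 <- measure_border_distances(sph, pts7, shape = c(220, 220))
  expect_equal(round(mm7$distances), c(7, 6, 5, 4, 3, 2, 1)[1:5])

  # a point on the boundary measures exactly 0
  bnd <- which(spherequant:::mask_boundary(roi_full_mask(sph, c(220, 220))),
               arr.ind = TRUE)[1, ] - 1
  mm0 <- measure_border_distances(sph, rbind(pts[1:4, ], unname(bnd)),
                                  shape = c(220, 220))
  expect_equal(min(mm0$distances), 0)

  expect_error(measure_border_distances(sph, pts[1:4, ], shape = c(220, 220)),
               "got 4")
})

test_that("emigrated-point detection finds distal pixels outside the spheroid", {
  fld <- generate_migration_field(50, c(10, 20, 30, 40, 50, 60, 70, 80, 90,
                                        100, 110, 120), seed = 4)
  pts <- detect_emigrated_points(get_channel(fld$stack, "TUJ1"), fld$spheroid)
  expect_equal(nrow(pts), 12)
  mm <- measure_border_distances(fld$spheroid, pts, shape = fld$stack$shape)
  top5 <- sort(fld$planted_distances, decreasing = TRUE)[1:5]
  expect_true(all(abs(mm$distances - top5) <= 1))

  # nothing outside -> no points; a particle fully inside is ignored
  blank <- generate_migration_field(40, numeric(0), seed = 5)
  expect_equal(nrow(detect_emigrated_points(get_channel(blank$stack, "TUJ1"),
                                            blank$spheroid)), 0)
  inside <- matrix(5, 201, 201)
  inside[disk_mask(201, 201, 101, 101, 40)] <- 250   # spheroid
  inside[disk_mask(201, 201, 101, 101, 3)] <- 255    # particle inside it
  sph <- roi_from_mask(disk_mask(201, 201, 101, 101, 40), 1L)
  expect_equal(nrow(detect_emigrated_points(img8(inside, "TUJ1"), sph)), 0)
})
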