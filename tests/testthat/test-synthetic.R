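small_params <- function(seed = 1, ...) {
  synthesis_params(seed = seed, image_shape = c(360, 360), n_spheroids = 1,
                   n_nuclei_per_spheroid = 40, ...)
}

test_that("generation is deterministic per seed and exact in counts", {
  g1 <- generate_stack(small_params(seed = 1))
  g2 <- generate_stack(small_params(seed = 1))
  expect_identical(lapply(g1$stack$channels, `[[`, "pixels"),
                   lapply(g2$stack$channels, `[[`, "pixels"))
  expect_identical(g1$truth$nuclei, g2$truth$nuclei)
  g3 <- generate_stack(small_params(seed = 2))
  expect_false(identical(g1$truth$nuclei, g3$truth$nuclei))

  expect_equal(nrow(g1$truth$nuclei), 40)  # requested count is exact
  # nuclei inside their spheroid, pairwise separation >= min_separation
  tr <- g1$truth
  d_ctr <- sqrt((tr$nuclei$row - tr$spheroids$row)^2 +
                (tr$nuclei$col - tr$spheroids$col)^2)
  expect_true(all(d_ctr + tr$nuclei$radius <= tr$spheroids$radius))
  dm <- as.matrix(dist(tr$nuclei[, c("row", "col")]))
  diag(dm) <- Inf
  expect_gte(min(dm), tr$params$min_separation)
})

test_that("marker fractions and co-expression follow the model", {
  g0 <- generate_stack(small_params(
    seed = 3, marker_model = list(green = c(fraction = 0, mu_pos = 60, mu_neg = 2))))
  expect_false(any(g0$truth$nuclei$green))

  # law of large numbers on the sign draws (rendering-free check via a
  # many-nuclei, many-spheroid layout)
  gbig <- generate_stack(synthesis_params(
    seed = 4, image_shape = c(1000, 1000), n_spheroids = 6,
    n_nuclei_per_spheroid = 170, min_separation = 8,
    marker_model = list(green = c(fraction = 0.37, mu_pos = 60, mu_neg = 2))))
  n <- nrow(gbig$truth$nuclei)
  expect_gte(n, 1000)
  expect_lt(abs(mean(gbig$truth$nuclei$green) - 0.37), 0.05)

  # the sign-draw machinery itself converges at n = 10,000 to within 1%
  signs <- spherequant:::with_local_seed(11, spherequant:::draw_marker_signs(
    10000, list(green = c(fraction = 0.37, mu_pos = 60, mu_neg = 2)), NULL))
  expect_lt(abs(mean(signs[, "green"]) - 0.37), 0.01)
  co <- c("++" = 0.3, "+-" = 0.35, "-+" = 0.2, "--" = 0.15)
  signs2 <- spherequant:::with_local_seed(12, spherequant:::draw_marker_signs(
    10000, list(green = c(fraction = NA, mu_pos = 60, mu_neg = 2),
                red = c(fraction = NA, mu_pos = 60, mu_neg = 2)), co))
  expect_lt(abs(mean(signs2[, "green"] & signs2[, "red"]) - 0.3), 0.01)
})

test_that("noise-free rendering reproduces mu exactly over nucleus disks", {
  g <- generate_stack(small_params(
    seed = 5, noise_sigma = 0, min_separation = 15,
    marker_model = list(green = c(fraction = 0.5, mu_pos = 60, mu_neg = 2))))
  tr <- g$truth$nuclei
  green <- g$stack$channels$green$pixels
  for (i in seq_len(nrow(tr))) {
    mask <- disk_mask(360, 360, round(tr$row[i]) + 1, round(tr$col[i]) + 1, 1)
    mu <- if (tr$green[i]) 60 else 2
    expect_true(all(green[mask] == mu))
  }
})

test_that("migration fields plant recoverable distal-edge distances", {
  fld <- generate_migration_field(45, c(10, 25, 40, 55, 70, 85, 100), seed = 6)
  expect_equal(fld$planted_distances, c(10, 25, 40, 55, 70, 85, 100) + 2)
  expect_equal(fld$spheroid$source, "manual")
  only <- generate_migration_field(45, numeric(0), seed = 6)
  expect_equal(length(only$stack$channels), 1)
  # spheroid-only image: nothing bright outside the spheroid mask
  m <- only$stack$channels$TUJ1$pixels
  outside <- !roi_full_mask(only$spheroid, dim(m))
  expect_lt(max(m[outside]), 50)
})

test_that("group datasets are reproducible and respect their specs", {
  specs <- list(CTRL = list(n = 8, dist = "normal", mean = 10, sd = 2),
                GDNF = list(n = 12, dist = "normal", mean = 14, sd = 2),
                GWEN = list(n = 10, dist = "lognormal", mean = 1, sd = 0.3))
  a <- generate_group_dataset(specs, seed = 7)
  b <- generate_group_dataset(specs, seed = 7)
  expect_identical(a, b)
  expect_equal(vapply(a, function(s) length(s$values), 0L), c(8L, 12L, 10L),
               ignore_attr = TRUE)
  expect_equal(vapply(a, `[[`, "", "group_label"), c("CTRL", "GDNF", "GWEN"),
               ignore_attr = TRUE)
  expect_error(generate_group_dataset(
    list(x = list(n = 1, dist = "normal", mean = 0, sd = 1)), 1), "n >= 2")

  # a 3-sigma shift at n = 8 is detected with high power by Kruskal-Wallis
  set.seed(8)
  hits <- 0
  for (r in 1:60) {
    d <- generate_group_dataset(
      list(a = list(n = 8, dist = "normal", mean = 0, sd = 1),
           b = list(n = 8, dist = "normal", mean = 3, sd = 1)),
      seed = 1000 + r)
    if (omnibus_compare(d, "kruskal")$p_raw < 0.05) hits <- hits + 1
  }
  expect_gt(hits / 60, 0.9)
})

test_that("presets encode a declining bipotent co-expression fraction", {
  fr <- vapply(c("e8", "e12", "d0"), function(p)
    unname(synthesis_preset(p)$co_expression["++"]), 0)
  expect_true(all(diff(fr) < 0))
  g <- generate_stack(synthesis_preset("e12", seed = 9,
                                       image_shape = c(360, 360),
                                       n_spheroids = 1,
                                       n_nuclei_per_spheroid = 60))
  expect_true(all(c("green", "red", "far-red") %in% names(g$stack$channels)))
})
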