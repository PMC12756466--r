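# run code under a local, restored RNG state so generators are
# bit-reproducible without disturbing the caller's stream
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  set.seed(as.integer(seed))
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  force(code)
}

#' Parameters of the synthetic confocal image generator
#'
#' The generator emulates a 2-D confocal plane of spheroids bearing surface
#' neurospheres: bright disk-shaped nuclei on a dark background, a
#' neurosphere (HU) channel rendering each spheroid as a bright region, and
#' marker channels in which each nucleus carries `mu_pos` or `mu_neg`
#' according to its planted sign. Intensities are 8-bit a.u.; additive
#' Gaussian noise is clipped to `[0, 255]` and rounded.
#'
#' Defaults encode the conditions the pipeline is designed for: DAPI nuclei
#' near saturation (250 a.u.) over a 5 a.u. background with sigma = 2 noise
#' (so the 0-13 a.u. inverted window is the operating point), neurosphere
#' disks at 200 a.u. whose area stays inside the 1,000-50,000 px^2 gate,
#' nucleus radii 3-7 px with centroids >= 11 px apart (touching but
#' watershed-separable).
#'
#' @param image_shape `c(rows, cols)` (default 640 x 640).
#' @param n_spheroids Number of spheroids (default 2).
#' @param spheroid_radius_range Radius range, px (default 90-115).
#' @param n_nuclei_per_spheroid Count or range (default `c(50, 150)`).
#' @param nucleus_radius_range Nucleus radius range, px (default 3-7).
#' @param min_separation Minimum centroid separation of nuclei within a
#'   spheroid, px (default 11).
#' @param marker_model Named list `marker -> c(fraction, mu_pos, mu_neg)`.
#' @param co_expression Optional named probability vector over sign
#'   combinations of the first two markers, e.g.
#'   `c("++" = .3, "+-" = .35, "-+" = .2, "--" = .15)` (must sum to 1);
#'   remaining markers stay independent.
#' @param background_level Background of the DAPI / HU channels, a.u.
#'   (default 5); marker channels are dark (0) outside nuclei.
#' @param dapi_intensity Nucleus intensity on DAPI, a.u. (default 250).
#' @param spheroid_intensity Spheroid intensity on HU, a.u. (default 200).
#' @param noise_sigma Gaussian noise sigma, a.u. (default 2).
#' @param seed Integer seed; identical seed gives identical output.
#' @return An object of class `synthesis_params`.
#' @export
synthesis_params <- function(image_shape = c(640, 640), n_spheroids = 2,
                             spheroid_radius_range = c(90, 115),
                             n_nuclei_per_spheroid = c(50, 150),
                             nucleus_radius_range = c(3, 7),
                             min_separation = 11,
                             marker_model = list(
                               green = c(fraction = 0.5, mu_pos = 60, mu_neg = 2),
                               red = c(fraction = 0.5, mu_pos = 60, mu_neg = 2),
                               "far-red" = c(fraction = 0.3, mu_pos = 60, mu_neg = 2)),
                             co_expression = NULL,
                             background_level = 5, dapi_intensity = 250,
                             spheroid_intensity = 200, noise_sigma = 2,
                             seed = 1L) {
  for (m in names(marker_model)) {
    mm <- marker_model[[m]]
    if (!is.na(mm["fraction"]) && (mm["fraction"] < 0 || mm["fraction"] > 1))
      stop("synthesis_params: marker fractions must lie in [0, 1]")
    if (!(mm["mu_pos"] > mm["mu_neg"]) || mm["mu_neg"] < 0)
      stop("synthesis_params: need mu_pos > mu_neg >= 0")
  }
  if (!is.null(co_expression) && abs(sum(co_expression) - 1) > 1e-9)
    stop("synthesis_params: co_expression probabilities must sum to 1")
  structure(as.list(environment()), class = "synthesis_params")
}

# internal: set disk pixels to max(current, value)
paint_disk <- function(img, row, col, radius, value) {
  r0 <- max(1L, floor(row + 1 - radius)); r1 <- min(nrow(img), ceiling(row + 1 + radius))
  c0 <- max(1L, floor(col + 1 - radius)); c1 <- min(ncol(img), ceiling(col + 1 + radius))
  rs <- r0:r1; cs <- c0:c1
  sub <- img[rs, cs, drop = FALSE]
  dm <- outer((rs - 1 - row)^2, (cs - 1 - col)^2, "+")
  sub[dm <= radius^2] <- pmax(sub[dm <= radius^2], value)
  img[rs, cs] <- sub
  img
}

# internal: rejection-sample n points inside a disk with min pairwise distance
sample_packed_points <- function(center, radius, n, min_dist, max_tries = 5000L) {
  pts <- matrix(numeric(0), ncol = 2L)
  tries <- 0L
  while (nrow(pts) < n) {
    tries <- tries + 1L
    if (tries > max_tries * n)
      stop("generation error: infeasible nucleus packing (raise radius or lower n)")
    ang <- runif(1, 0, 2 * pi)
    rr <- radius * sqrt(runif(1))
    p <- center + rr * c(cos(ang), sin(ang))
    if (nrow(pts) == 0 ||
        min((pts[, 1L] - p[1L])^2 + (pts[, 2L] - p[2L])^2) >= min_dist^2)
      pts <- rbind(pts, p)
  }
  pts
}

# internal: draw marker signs for n nuclei
draw_marker_signs <- function(n, marker_model, co_expression) {
  markers <- names(marker_model)
  signs <- matrix(FALSE, n, length(markers), dimnames = list(NULL, markers))
  if (!is.null(co_expression) && length(markers) >= 2L) {
    combos <- names(co_expression)
    pick <- sample(combos, n, replace = TRUE, prob = co_expression)
    signs[, 1L] <- substr(pick, 1L, 1L) == "+"
    signs[, 2L] <- substr(pick, 2L, 2L) == "+"
    rest <- markers[-(1:2)]
  } else {
    rest <- markers
  }
  for (m in rest)
    signs[, m] <- runif(n) < marker_model[[m]]["fraction"]
  signs
}

#' Generate a ground-truth-annotated multichannel stack
#'
#' Channels, in order: `"DAPI"`, `"HU"`, then one channel per marker in
#' `params$marker_model`. Every nucleus lies fully inside its spheroid with
#' pairwise centroid separation >= `min_separation`; with
#' `noise_sigma = 0` the rendered mean intensity of a (non-overlapping)
#' nucleus disk on its marker channel equals `mu_pos` / `mu_neg` exactly.
#'
#' @param params A [synthesis_params].
#' @return List with elements `stack` (an [image_stack]) and `truth`
#'   (class `synthetic_ground_truth`: `nuclei` data.frame with
#'   `spheroid_id`, `row`, `col`, `radius` and one logical column per
#'   marker; `spheroids` data.frame; `params`).
#' @export
generate_stack <- function(params = synthesis_params()) {
  stopifnot(inherits(params, "synthesis_params"))
  with_local_seed(params$seed, {
    shape <- params$image_shape
    markers <- names(params$marker_model)
    nsp <- params$n_spheroids
    rrng <- params$spheroid_radius_range
    nrng <- params$n_nuclei_per_spheroid
    nuc_r <- params$nucleus_radius_range
    # per-spheroid nucleus counts
    ns <- if (length(nrng) == 1L) rep(nrng, nsp)
          else sample(seq(nrng[1L], nrng[2L]), nsp, replace = TRUE)
    # spheroid radii: raise to the packing-feasibility minimum
    # (pi * r_eff^2 >= 1.5 * n * d^2 keeps rejection sampling bounded)
    radii <- vapply(ns, function(n) {
      r <- runif(1, rrng[1L], rrng[2L])
      rmin <- sqrt(1.5 * n * params$min_separation^2 / pi) + nuc_r[2L]
      max(r, rmin)
    }, 0)
    # spheroid centers on a grid of non-overlapping slots
    centers <- matrix(0, nsp, 2L)
    margin <- max(radii) + 5
    slots <- expand.grid(
      row = seq(margin, shape[1L] - margin, length.out = max(2L, ceiling(sqrt(nsp)))),
      col = seq(margin, shape[2L] - margin, length.out = max(2L, ceiling(sqrt(nsp)))))
    if (nrow(slots) < nsp)
      stop("generation error: too many spheroids for the image shape")
    idx <- sample(nrow(slots), nsp)
    centers[, 1L] <- slots$row[idx]; centers[, 2L] <- slots$col[idx]
    # nuclei
    nuclei <- list()
    for (s in seq_len(nsp)) {
      rmax_nuc <- nuc_r[2L]
      pts <- sample_packed_points(centers[s, ], radii[s] - rmax_nuc - 1,
                                  ns[s], params$min_separation)
      rad <- runif(ns[s], nuc_r[1L], nuc_r[2L])
      nuclei[[s]] <- data.frame(spheroid_id = s, row = pts[, 1L],
                                col = pts[, 2L], radius = rad)
    }
    nuclei <- do.call(rbind, nuclei)
    signs <- draw_marker_signs(nrow(nuclei), params$marker_model,
                               params$co_expression)
    for (m in markers) nuclei[[m]] <- signs[, m]
    # render
    dapi <- matrix(params$background_level, shape[1L], shape[2L])
    hu <- matrix(params$background_level, shape[1L], shape[2L])
    marker_imgs <- lapply(markers, function(m) matrix(0, shape[1L], shape[2L]))
    names(marker_imgs) <- markers
    for (s in seq_len(nsp))
      hu <- paint_disk(hu, centers[s, 1L], centers[s, 2L], radii[s],
                       params$spheroid_intensity)
    for (i in seq_len(nrow(nuclei))) {
      dapi <- paint_disk(dapi, nuclei$row[i], nuclei$col[i], nuclei$radius[i],
                         params$dapi_intensity)
      for (m in markers) {
        mm <- params$marker_model[[m]]
        mu <- if (nuclei[[m]][i]) mm["mu_pos"] else mm["mu_neg"]
        marker_imgs[[m]] <- paint_disk(marker_imgs[[m]], nuclei$row[i],
                                       nuclei$col[i], nuclei$radius[i], mu)
      }
    }
    noisy <- function(img) {
      if (params$noise_sigma > 0) {
        img <- img + matrix(rnorm(length(img), 0, params$noise_sigma),
                            nrow(img), ncol(img))
        img <- round(pmin(pmax(img, 0), 255))
      }
      img
    }
    chans <- c(list(channel_image(noisy(dapi), 255, "DAPI"),
                    channel_image(noisy(hu), 255, "HU")),
               lapply(markers, function(m)
                 channel_image(noisy(marker_imgs[[m]]), 255, m)))
    truth <- structure(list(
      nuclei = nuclei,
      spheroids = data.frame(spheroid_id = seq_len(nsp),
                             row = centers[, 1L], col = centers[, 2L],
                             radius = radii),
      params = params), class = "synthetic_ground_truth")
    list(stack = image_stack(chans), truth = truth)
  })
}

#' Generate a migration-assay field with planted border distances
#'
#' Renders a central spheroid and marker-positive cells at the given radial
#' offsets from the spheroid border, at random angles. The planted distance
#' of a cell is `offset + cell_radius` - the distance of its distal edge
#' from the border, matching the farthest-pixel measurement rule.
#'
#' @param spheroid_radius Spheroid radius, px.
#' @param cell_offsets Radial offsets of cell centers from the border, px
#'   (all >= 0).
#' @param seed Integer seed.
#' @param cell_radius Cell radius, px (default 2).
#' @param background_level,intensity,noise_sigma Rendering parameters.
#' @return List with `stack` (one `"TUJ1"` channel), `spheroid`
#'   (a `region_of_interest` of the planted spheroid), and
#'   `planted_distances` (distal-edge distances, same order as
#'   `cell_offsets`).
#' @export
generate_migration_field <- function(spheroid_radius, cell_offsets, seed = 1L,
                                     cell_radius = 2, background_level = 5,
                                     intensity = 250, noise_sigma = 2) {
  if (any(cell_offsets < 0)) stop("cell offsets must be >= 0")
  with_local_seed(seed, {
    pad <- 20 + cell_radius
    half <- ceiling(spheroid_radius +
                      (if (length(cell_offsets)) max(cell_offsets) else 0) + pad)
    n <- 2L * half + 1L
    ctr <- c(half, half)  # 0-based center
    img <- matrix(background_level, n, n)
    img <- paint_disk(img, ctr[1L], ctr[2L], spheroid_radius, intensity)
    placed <- matrix(numeric(0), ncol = 2L)
    for (off in cell_offsets) {
      repeat {
        ang <- runif(1, 0, 2 * pi)
        p <- ctr + (spheroid_radius + off) * c(cos(ang), sin(ang))
        if (nrow(placed) == 0 ||
            min((placed[, 1L] - p[1L])^2 + (placed[, 2L] - p[2L])^2) >
              (4 * cell_radius + 2)^2) break
      }
      placed <- rbind(placed, p)
      img <- paint_disk(img, p[1L], p[2L], cell_radius, intensity)
    }
    if (noise_sigma > 0) {
      img <- img + matrix(rnorm(length(img), 0, noise_sigma), n, n)
      img <- round(pmin(pmax(img, 0), 255))
    }
    sph_mask <- matrix(FALSE, n, n)
    sph_mask <- paint_disk(sph_mask * 1, ctr[1L], ctr[2L], spheroid_radius, 1) > 0
    list(stack = image_stack(list(channel_image(img, 255, "TUJ1"))),
         spheroid = roi_from_mask(sph_mask, 1L, source = "manual"),
         planted_distances = cell_offsets + cell_radius)
  })
}

#' Draw per-group samples for the statistics layer
#'
#' @param group_specs Named list `label -> list(n, dist, mean, sd)` with
#'   `dist` either `"normal"` or `"lognormal"` (meanlog/sdlog).
#' @param seed Integer seed.
#' @return List of [group_sample], deterministic per seed.
#' @export
generate_group_dataset <- function(group_specs, seed = 1L) {
  with_local_seed(seed, {
    lapply(names(group_specs), function(lab) {
      sp <- group_specs[[lab]]
      if (sp$n < 2L) stop("generate_group_dataset: need n >= 2 per group")
      vals <- switch(match.arg(sp$dist, c("normal", "lognormal")),
                     normal = rnorm(sp$n, sp$mean, sp$sd),
                     lognormal = rlnorm(sp$n, sp$mean, sp$sd))
      group_sample(lab, vals)
    })
  })
}

#' Stage presets for the synthetic generator
#'
#' Illustrative co-expression structures for three developmental stages,
#' encoding a decline of the green+/red+ (bipotent progenitor) fraction and
#' of the far-red (EdU) labeling fraction from `"e8"` to `"d0"`. The values
#' are generator defaults, not measured data.
#'
#' @param preset `"e8"`, `"e12"` or `"d0"`.
#' @param seed Integer seed.
#' @param ... Overrides passed to [synthesis_params].
#' @return A [synthesis_params].
#' @export
synthesis_preset <- function(preset = c("e8", "e12", "d0"), seed = 1L, ...) {
  preset <- match.arg(preset)
  co <- switch(preset,
    e8 = c("++" = 0.60, "+-" = 0.20, "-+" = 0.15, "--" = 0.05),
    e12 = c("++" = 0.30, "+-" = 0.35, "-+" = 0.20, "--" = 0.15),
    d0 = c("++" = 0.05, "+-" = 0.55, "-+" = 0.25, "--" = 0.15))
  edu <- switch(preset, e8 = 0.5, e12 = 0.3, d0 = 0.1)
  synthesis_params(
    marker_model = list(
      green = c(fraction = NA, mu_pos = 60, mu_neg = 2),
      red = c(fraction = NA, mu_pos = 60, mu_neg = 2),
      "far-red" = c(fraction = edu, mu_pos = 60, mu_neg = 2)),
    co_expression = co, seed = seed, ...)
}
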