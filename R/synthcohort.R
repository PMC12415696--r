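# Synthetic H&E-like cohort generator. Tiles are composed in optical-density
# (OD) space under the Beer-Lambert law: each pixel's OD is
# c_H * S_H + c_E * S_E, where S_H / S_E are the patient's (jittered)
# hematoxylin / eosin RGB OD vectors and c_H / c_E the stain concentrations.
# Nuclei are high-hematoxylin ellipses on a uniform eosin background; overlaps
# add OD. Intensity = 255 * 10^(-OD), scaled by a per-patient brightness
# factor, plus additive Gaussian pixel noise.

#' Canonical H&E stain OD matrix
#'
#' The widely used reference hematoxylin/eosin RGB optical-density vectors
#' (unit-normalised), as columns of a 3x2 matrix with hematoxylin first. These
#' are both the canonical vectors from which the synthetic generator jitters
#' per-patient stains, and the fixed matrix used by the Ruifrok normaliser.
#'
#' @return A 3x2 numeric matrix with unit-norm columns `H` and `E`.
#' @export
ruifrok_stain_matrix <- function() {
  h <- c(0.650, 0.704, 0.286)
  e <- c(0.072, 0.990, 0.105)
  m <- cbind(H = h / sqrt(sum(h^2)), E = e / sqrt(sum(e^2)))
  rownames(m) <- c("R", "G", "B")
  m
}

#' Nuclear morphology parameters for one synthetic tissue class
#'
#' @param nucleus_radius_mean Mean nucleus semi-major axis, pixels (> 0).
#' @param nucleus_radius_sd SD of the nucleus radius, pixels.
#' @param nucleus_density Poisson mean nucleus count per 512x512 tile.
#' @param hematoxylin_od_peak Hematoxylin concentration added inside a
#'   nucleus, optical-density units.
#' @param eosin_od_background Uniform eosin background concentration, OD units.
#' @return An object of class `morphology_params`.
#' @export
morphology_params <- function(nucleus_radius_mean,
                              nucleus_radius_sd = nucleus_radius_mean / 5,
                              nucleus_density = 100,
                              hematoxylin_od_peak = 0.9,
                              eosin_od_background = 0.25) {
  if (nucleus_radius_mean <= 0) abort("nucleus_radius_mean must be > 0")
  if (nucleus_radius_sd < 0) abort("nucleus_radius_sd must be >= 0")
  if (nucleus_density < 0) abort("nucleus_density must be >= 0")
  if (hematoxylin_od_peak < 0 || eosin_od_background < 0)
    abort("OD values must be >= 0")
  structure(
    list(
      nucleus_radius_mean = nucleus_radius_mean,
      nucleus_radius_sd = nucleus_radius_sd,
      nucleus_density = nucleus_density,
      hematoxylin_od_peak = hematoxylin_od_peak,
      eosin_od_background = eosin_od_background
    ),
    class = "morphology_params"
  )
}

#' Default class morphologies: small dense nuclei vs large sparse nuclei
#'
#' The RLH-like class (label 0) mimics small, densely packed lymphocytes; the
#' cDLBCL-like class (label 1) mimics large monomorphic cells.
#'
#' @return Named list with elements `rlh` and `dlbcl`.
#' @export
default_class_params <- function() {
  list(
    rlh = morphology_params(4, 0.8, 180),
    dlbcl = morphology_params(9, 1.5, 60)
  )
}

#' Per-patient stain variation parameters
#'
#' Emulates inter-case staining variability (reagents, staining intensity,
#' slide age): each patient's stain vectors are rotated in the H--E OD plane
#' by angles drawn from a truncated normal, concentrations scaled, and overall
#' brightness scaled.
#'
#' @param vector_rotation_sd SD (radians) of the stain-vector rotation;
#'   draws are truncated at +/- 3 SD.
#' @param concentration_scale_range Uniform range for the per-patient
#'   concentration scale.
#' @param brightness_scale_range Uniform range for the per-patient brightness
#'   scale.
#' @return An object of class `stain_jitter`.
#' @export
stain_jitter <- function(vector_rotation_sd = 0.05,
                         concentration_scale_range = c(0.9, 1.1),
                         brightness_scale_range = c(0.9, 1.1)) {
  if (vector_rotation_sd < 0) abort("vector_rotation_sd must be >= 0")
  for (r in list(concentration_scale_range, brightness_scale_range))
    if (length(r) != 2L || r[1] > r[2]) abort("scale ranges must be length-2 increasing")
  structure(
    list(
      vector_rotation_sd = vector_rotation_sd,
      concentration_scale_range = concentration_scale_range,
      brightness_scale_range = brightness_scale_range
    ),
    class = "stain_jitter"
  )
}

# rotate `v` within the plane span(v, other) by angle theta, keeping unit norm
# and non-negative entries
rotate_stain_vector <- function(v, other, theta) {
  orth <- other - sum(other * v) * v
  orth <- orth / sqrt(sum(orth^2))
  w <- cos(theta) * v + sin(theta) * orth
  w <- pmax(w, 0)
  w / sqrt(sum(w^2))
}

draw_patient_stain <- function(jitter) {
  canon <- ruifrok_stain_matrix()
  sd <- jitter$vector_rotation_sd
  th <- if (sd > 0) pmin(pmax(rnorm(2, 0, sd), -3 * sd), 3 * sd) else c(0, 0)
  h <- rotate_stain_vector(canon[, 1], canon[, 2], th[1])
  e <- rotate_stain_vector(canon[, 2], canon[, 1], th[2])
  list(
    h = h, e = e,
    conc_scale = runif(1, jitter$concentration_scale_range[1], jitter$concentration_scale_range[2]),
    brightness = runif(1, jitter$brightness_scale_range[1], jitter$brightness_scale_range[2])
  )
}

resolve_tile_counts <- function(spec, n) {
  counts <- if (is.function(spec)) spec(n)
  else if (length(spec) == 1L) rep(as.integer(spec), n)
  else if (length(spec) == 2L) sample(seq.int(spec[1], spec[2]), n, replace = TRUE)
  else abort("tiles_per_patient must be a count, a length-2 range, or a function(n)")
  counts <- as.integer(counts)
  if (length(counts) != n || any(counts < 1L))
    abort("tiles_per_patient spec must yield one positive count per patient")
  counts
}

#' Generate a seeded synthetic H&E cohort
#'
#' Creates a two-class cohort of patients, each with one slide and a number of
#' 512x512 RGB tiles. All tiles of one patient share that patient's jittered
#' stain vectors, concentration scale and brightness. Tiles are rendered
#' lazily ([render_tile()]) and deterministically: the same arguments and seed
#' always yield byte-identical pixels, independent of rendering order.
#'
#' @param n_patients_per_class Number of patients in each class (>= 1).
#' @param tiles_per_patient A single count, a length-2 integer range sampled
#'   uniformly per patient, or a `function(n)` returning `n` positive counts.
#' @param class_params List with `morphology_params` elements `rlh` and
#'   `dlbcl` (see [default_class_params()]).
#' @param jitter A [stain_jitter()] object.
#' @param seed Integer seed.
#' @param noise_sd SD of additive Gaussian pixel noise on the 0--255 scale
#'   (0 disables noise).
#' @param tile_size Tile edge length in pixels.
#' @return An object of class `synthetic_cohort` with a `patients` data frame
#'   (ids, labels, per-patient stain parameters, tile counts) and the
#'   generation parameters.
#' @export
generate_cohort <- function(n_patients_per_class,
                            tiles_per_patient = 20L,
                            class_params = default_class_params(),
                            jitter = stain_jitter(),
                            seed = 1L,
                            noise_sd = 3,
                            tile_size = 512L) {
  if (n_patients_per_class < 1L) abort("n_patients_per_class must be >= 1")
  if (!all(c("rlh", "dlbcl") %in% names(class_params)))
    abort("class_params must have elements 'rlh' and 'dlbcl'")
  n <- 2L * as.integer(n_patients_per_class)
  patients <- with_seed(seed, {
    counts <- resolve_tile_counts(tiles_per_patient, n)
    rows <- lapply(seq_len(n), function(i) {
      cls <- if (i <= n_patients_per_class) "rlh" else "dlbcl"
      st <- draw_patient_stain(jitter)
      data.frame(
        patient_id = sprintf("%s_p%03d", cls, ifelse(cls == "rlh", i, i - n_patients_per_class)),
        slide_id = sprintf("%s_p%03d_s1", cls, ifelse(cls == "rlh", i, i - n_patients_per_class)),
        class = cls,
        label = if (cls == "rlh") 0L else 1L,
        n_tiles = counts[i],
        h_r = st$h[1], h_g = st$h[2], h_b = st$h[3],
        e_r = st$e[1], e_g = st$e[2], e_b = st$e[3],
        conc_scale = st$conc_scale,
        brightness = st$brightness,
        stringsAsFactors = FALSE
      )
    })
    do.call(rbind, rows)
  })
  structure(
    list(
      patients = patients,
      class_params = class_params,
      jitter = jitter,
      seed = as.integer(seed),
      noise_sd = noise_sd,
      tile_size = as.integer(tile_size)
    ),
    class = "synthetic_cohort"
  )
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(
    "Synthetic H&E cohort: %d patients (%d RLH-like, %d cDLBCL-like), %d tiles, seed %d\n",
    nrow(x$patients), sum(x$patients$label == 0L), sum(x$patients$label == 1L),
    sum(x$patients$n_tiles), x$seed
  ))
  invisible(x)
}

patient_row <- function(cohort, patient_id) {
  i <- match(patient_id, cohort$patients$patient_id)
  if (is.na(i)) abort("unknown patient_id: ", patient_id)
  cohort$patients[i, ]
}

# draw the nucleus table for one tile; shared by render_tile()/tile_nuclei()
# so counting and rendering consume the identical random stream
draw_nuclei <- function(params, size) {
  n <- rpois(1, params$nucleus_density)
  if (n == 0L)
    return(data.frame(cx = numeric(0), cy = numeric(0), r = numeric(0),
                      ratio = numeric(0), theta = numeric(0)))
  data.frame(
    cx = runif(n, 0, size),
    cy = runif(n, 0, size),
    r = pmax(rnorm(n, params$nucleus_radius_mean, params$nucleus_radius_sd), 0.5),
    ratio = runif(n, 0.7, 1.0),
    theta = runif(n, 0, pi)
  )
}

# additive hematoxylin concentration map from a nucleus table; ellipses have
# a ~1 px soft rim (coverage ramps from 1 inside to 0 at the boundary) so
# partial-coverage pixels carry intermediate concentrations, as real nuclear
# borders do
nuclei_concentration <- function(nuclei, od_peak, h, w) {
  ch <- matrix(0, h, w)
  for (k in seq_len(nrow(nuclei))) {
    cx <- nuclei$cx[k]; cy <- nuclei$cy[k]
    a <- nuclei$r[k]; b <- a * nuclei$ratio[k]; th <- nuclei$theta[k]
    x0 <- max(0L, floor(cx - a - 1)); x1 <- min(w - 1L, ceiling(cx + a + 1))
    y0 <- max(0L, floor(cy - a - 1)); y1 <- min(h - 1L, ceiling(cy + a + 1))
    if (x0 > x1 || y0 > y1) next
    xs <- x0:x1; ys <- y0:y1
    dx <- outer(rep(1, length(ys)), xs + 0.5 - cx)
    dy <- outer(ys + 0.5 - cy, rep(1, length(xs)))
    u <- dx * cos(th) + dy * sin(th)
    v <- -dx * sin(th) + dy * cos(th)
    q <- (u / a)^2 + (v / b)^2
    cov <- pmin(pmax((1 - q) * max(a / 2, 1), 0), 1)
    block <- ch[ys + 1L, xs + 1L, drop = FALSE]
    ch[ys + 1L, xs + 1L] <- block + od_peak * cov
  }
  ch
}

compose_beer_lambert <- function(c_h, c_e, h_vec, e_vec, brightness, noise_sd) {
  hh <- nrow(c_h); ww <- ncol(c_h)
  img <- array(0, dim = c(hh, ww, 3L))
  for (ch in 1:3) {
    od <- c_h * h_vec[ch] + c_e * e_vec[ch]
    img[, , ch] <- 255 * 10^(-od) * brightness
  }
  if (noise_sd > 0) img <- img + array(rnorm(length(img), 0, noise_sd), dim = dim(img))
  round_half_up(clip8(img))
}

#' Render one tile of a synthetic cohort
#'
#' @param cohort A `synthetic_cohort`.
#' @param patient_id Patient identifier.
#' @param tile_index Tile number within the patient, 1-based.
#' @return A `(tile_size, tile_size, 3)` array of 0--255 values.
#' @export
render_tile <- function(cohort, patient_id, tile_index) {
  p <- patient_row(cohort, patient_id)
  if (tile_index < 1L || tile_index > p$n_tiles)
    abort("tile_index out of range for patient ", patient_id)
  params <- cohort$class_params[[p$class]]
  size <- cohort$tile_size
  pi_ <- match(patient_id, cohort$patients$patient_id)
  with_seed(derive_seed(cohort$seed, pi_, tile_index), {
    nuc <- draw_nuclei(params, size)
    c_h <- nuclei_concentration(nuc, params$hematoxylin_od_peak, size, size) * p$conc_scale
    c_e <- matrix(params$eosin_od_background * p$conc_scale, size, size)
    compose_beer_lambert(c_h, c_e, c(p$h_r, p$h_g, p$h_b), c(p$e_r, p$e_g, p$e_b),
                         p$brightness, cohort$noise_sd)
  })
}

#' Nucleus table underlying one rendered tile
#'
#' Returns the centres, radii, axis ratios and orientations of the nuclei that
#' [render_tile()] draws for the same tile, for verification of the generator's
#' statistical properties.
#'
#' @inheritParams render_tile
#' @return Data frame with columns `cx, cy, r, ratio, theta`.
#' @export
tile_nuclei <- function(cohort, patient_id, tile_index) {
  p <- patient_row(cohort, patient_id)
  params <- cohort$class_params[[p$class]]
  pi_ <- match(patient_id, cohort$patients$patient_id)
  with_seed(derive_seed(cohort$seed, pi_, tile_index), draw_nuclei(params, cohort$tile_size))
}

#' Closed-form expected mean OD of a tissue class
#'
#' Analytic expectation of the per-pixel optical density under the generator's
#' composition model: mean hematoxylin concentration is
#' `density * E[ellipse area] * mean_rim_coverage * od_peak / tile_area`
#' (overlaps add), eosin is the uniform background. The soft nuclear rim
#' ramps coverage linearly over the outer `1/k` of the ellipse's area
#' parameter (`k = max(radius/2, 1)`), giving mean coverage `1 - 1/(2k)`.
#' Ignores edge truncation of nuclei whose centres lie near the canvas
#' border.
#'
#' @param params A `morphology_params` object.
#' @param tile_size Canvas edge length used for the density normalisation.
#' @return Length-3 numeric: expected OD per RGB channel (canonical stains,
#'   unit concentration scale).
#' @export
expected_mean_od <- function(params, tile_size = 512L) {
  canon <- ruifrok_stain_matrix()
  e_r2 <- params$nucleus_radius_mean^2 + params$nucleus_radius_sd^2
  e_area <- pi * e_r2 * mean(c(0.7, 1.0))
  k <- max(params$nucleus_radius_mean / 2, 1)
  coverage <- 1 - 1 / (2 * k)
  c_h <- params$nucleus_density * e_area * coverage *
    params$hematoxylin_od_peak / tile_size^2
  as.numeric(c_h * canon[, 1] + params$eosin_od_background * canon[, 2])
}

#' Render a slide-scale image and ROI mask for one patient
#'
#' The slide is rendered with the same stain parameters and nuclear morphology
#' as the patient's tiles, with nucleus count scaled to the canvas area.
#' Tissue appears inside the ROI; pixels outside the ROI are background white.
#'
#' @param cohort A `synthetic_cohort`.
#' @param patient_id Patient identifier.
#' @param size Canvas `(height, width)` in pixels.
#' @param roi ROI specification: `NULL` for the full canvas,
#'   `list(shape = "rect", x, y, w, h)` (0-based pixel origin),
#'   `list(shape = "ellipse", cx, cy, rx, ry)`, or a 0/1 matrix of canvas size.
#' @param seed Integer seed (defaults to a value derived from the cohort seed).
#' @return List with elements `image` (`(h, w, 3)` array) and `mask`
#'   (0/1 matrix).
#' @export
generate_slide <- function(cohort, patient_id, size = c(1024L, 1024L),
                           roi = NULL, seed = NULL) {
  p <- patient_row(cohort, patient_id)
  params <- cohort$class_params[[p$class]]
  h <- as.integer(size[1]); w <- as.integer(size[2])
  mask <- roi_mask(roi, h, w)
  pi_ <- match(patient_id, cohort$patients$patient_id)
  seed <- seed %||% derive_seed(cohort$seed, pi_, 999983L)
  img <- with_seed(seed, {
    scaled <- params
    scaled$nucleus_density <- params$nucleus_density * (h * w) / cohort$tile_size^2
    nuc <- draw_nuclei(scaled, max(h, w))
    nuc <- nuc[nuc$cx < w & nuc$cy < h, , drop = FALSE]
    c_h <- nuclei_concentration(nuc, params$hematoxylin_od_peak, h, w) * p$conc_scale
    c_e <- matrix(params$eosin_od_background * p$conc_scale, h, w)
    compose_beer_lambert(c_h, c_e, c(p$h_r, p$h_g, p$h_b), c(p$e_r, p$e_g, p$e_b),
                         p$brightness, cohort$noise_sd)
  })
  for (ch in 1:3) {
    plane <- img[, , ch]
    plane[mask == 0] <- 255
    img[, , ch] <- plane
  }
  list(image = img, mask = mask)
}

roi_mask <- function(roi, h, w) {
  if (is.null(roi)) return(matrix(1, h, w))
  if (is.matrix(roi)) {
    if (!all(dim(roi) == c(h, w))) abort("ROI mask does not fit the slide canvas")
    return((roi != 0) * 1)
  }
  if (!is.list(roi) || is.null(roi$shape)) abort("unrecognised ROI specification")
  m <- matrix(0, h, w)
  if (roi$shape == "rect") {
    if (roi$x < 0 || roi$y < 0 || roi$x + roi$w > w || roi$y + roi$h > h)
      abort("ROI larger than canvas")
    m[(roi$y + 1):(roi$y + roi$h), (roi$x + 1):(roi$x + roi$w)] <- 1
  } else if (roi$shape == "ellipse") {
    if (roi$cx - roi$rx < 0 || roi$cx + roi$rx > w || roi$cy - roi$ry < 0 || roi$cy + roi$ry > h)
      abort("ROI larger than canvas")
    xs <- (seq_len(w) - 0.5 - roi$cx) / roi$rx
    ys <- (seq_len(h) - 0.5 - roi$cy) / roi$ry
    m <- (outer(ys^2, xs^2, "+") <= 1) * 1
  } else abort("unrecognised ROI shape: ", roi$shape)
  m
}

# synthetic per-patient grid origins so direct cohort tiles carry coordinates
cohort_tile_origin <- function(tile_index, n_tiles, tile_size) {
  k <- max(1L, ceiling(sqrt(n_tiles)))
  i <- tile_index - 1L
  c(x = (i %% k) * tile_size, y = (i %/% k) * tile_size)
}

#' Tile-level manifest of a synthetic cohort
#'
#' One row per tile with identity, label, and synthetic slide-grid origin.
#'
#' @param cohort A `synthetic_cohort`.
#' @return Data frame with columns `tile_id, patient_id, slide_id, tile_index,
#'   x_origin, y_origin, label`.
#' @export
cohort_manifest <- function(cohort) {
  rows <- lapply(seq_len(nrow(cohort$patients)), function(i) {
    p <- cohort$patients[i, ]
    idx <- seq_len(p$n_tiles)
    org <- t(vapply(idx, cohort_tile_origin, numeric(2),
                    n_tiles = p$n_tiles, tile_size = cohort$tile_size))
    data.frame(
      tile_id = sprintf("%s_x%d_y%d", p$slide_id, org[, 1], org[, 2]),
      patient_id = p$patient_id,
      slide_id = p$slide_id,
      tile_index = idx,
      x_origin = org[, 1],
      y_origin = org[, 2],
      label = p$label,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Write a synthetic cohort to disk as PNG tiles plus a CSV manifest
#'
#' Tiles are named `{slide_id}_x{X}_y{Y}.png`; the manifest has columns
#' `tile_path, patient_id, slide_id, x_origin, y_origin, label`.
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if needed).
#' @return Path to the manifest CSV, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  man <- cohort_manifest(cohort)
  paths <- character(nrow(man))
  for (i in seq_len(nrow(man))) {
    img <- render_tile(cohort, man$patient_id[i], man$tile_index[i])
    fn <- tile_filename(man$slide_id[i], man$x_origin[i], man$y_origin[i])
    write_image_png(img, file.path(dir, fn))
    paths[i] <- fn
  }
  out <- data.frame(
    tile_path = paths,
    patient_id = man$patient_id,
    slide_id = man$slide_id,
    x_origin = man$x_origin,
    y_origin = man$y_origin,
    label = man$label,
    stringsAsFactors = FALSE
  )
  manifest_path <- file.path(dir, "manifest.csv")
  write.csv(out, manifest_path, row.names = FALSE)
  invisible(manifest_path)
}
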