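test_that("cohort generation is deterministic given a seed, byte for byte", {
  co1 <- generate_cohort(2, 4, seed = 11)
  co2 <- generate_cohort(2, 4, seed = 11)
  expect_identical(co1$patients, co2$patients)
  for (p in co1$patients$patient_id[c(1, 3)]) {
    expect_identical(render_tile(co1, p, 1L), render_tile(co2, p, 1L))
  }
  co3 <- generate_cohort(2, 4, seed = 12)
  expect_false(identical(render_tile(co1, co1$patients$patient_id[1], 1L),
                         render_tile(co3, co3$patients$patient_id[1], 1L)))
  # rendering order must not matter
  t2 <- render_tile(co1, co1$patients$patient_id[2], 3L)
  t1 <- render_tile(co1, co1$patients$patient_id[1], 1L)
  expect_identical(t1, render_tile(co2, co2$patients$patient_id[1], 1L))
  expect_identical(t2, render_tile(co2, co2$patients$patient_id[2], 3L))
})

test_that("zero nucleus density with noise disabled yields the flat eosin background", {
  params <- list(rlh = morphology_params(4, 0.8, 0),
                 dlbcl = morphology_params(9, 1.5, 0))
  co <- generate_cohort(1, 2, class_params = params, seed = 3, noise_sd = 0,
                        jitter = stain_jitter(0, c(1, 1), c(1, 1)))
  img <- render_tile(co, co$patients$patient_id[1], 1L)
  for (ch in 1:3) expect_equal(var(as.numeric(img[, , ch])), 0)
  expected <- od_to_rgb(0.25 * ruifrok_stain_matrix()[, 2])
  # rendering uses 255*10^-OD, the read-back convention 256*10^-OD - 1;
  # the two agree within one grey level
  expect_true(all(abs(img[1, 1, ] - expected) <= 1))
})

test_that("nucleus counts are Poisson with the configured density", {
  co <- generate_cohort(1, 200, seed = 5)
  pid <- co$patients$patient_id[1]
  density <- co$class_params$rlh$nucleus_density
  counts <- vapply(1:200, function(i) nrow(tile_nuclei(co, pid, i)), numeric(1))
  expect_lt(abs(mean(counts) - density), 3 * sqrt(density / 200))
})

test_that("invalid generation arguments are rejected", {
  expect_error(generate_cohort(0, 5), "n_patients_per_class")
  expect_error(generate_cohort(2, 0), "positive")
  expect_error(morphology_params(-1), "radius")
  expect_error(morphology_params(4, nucleus_density = -5), "density")
})

test_that("per-patient stain vectors stay within the truncated rotation bound", {
  sd <- 0.08
  co <- generate_cohort(30, 1, jitter = stain_jitter(sd), seed = 9)
  canon <- ruifrok_stain_matrix()
  for (i in seq_len(nrow(co$patients))) {
    p <- co$patients[i, ]
    ang_h <- acos(min(1, sum(c(p$h_r, p$h_g, p$h_b) * canon[, 1])))
    ang_e <- acos(min(1, sum(c(p$e_r, p$e_g, p$e_b) * canon[, 2])))
    expect_lte(ang_h, 3 * sd + 1e-6)
    expect_lte(ang_e, 3 * sd + 1e-6)
  }
})

test_that("classes are separable by measured nucleus size in rendered tiles", {
  skip_if_not_installed("EBImage")
  co <- generate_cohort(2, 6, seed = 21, noise_sd = 0)
  measure_radius <- function(pid) {
    radii <- c()
    for (i in 1:6) {
      img <- render_tile(co, pid, i)
      # hematoxylin channel via colour deconvolution, thresholded at half peak
      od <- hawkshead:::rgb_to_od(hawkshead:::image_to_pixmat(img))
      conc <- hawkshead:::stain_concentrations(od, ruifrok_stain_matrix())
      hmap <- matrix(conc[1, ] > 0.45, 512, 512)
      lab <- EBImage::bwlabel(EBImage::Image(t(hmap)))
      areas <- table(as.integer(lab))
      areas <- areas[names(areas) != "0"]
      radii <- c(radii, sqrt(as.numeric(areas) / pi))
    }
    mean(radii)
  }
  r_rlh <- measure_radius(co$patients$patient_id[1])
  r_dlbcl <- measure_radius(co$patients$patient_id[3])
  expect_gte(r_dlbcl - r_rlh, 2)
})

test_that("slides render with the patient's stains and honour ROI shapes", {
  co <- tiny_cohort(seed = 31)
  pid <- co$patients$patient_id[1]
  s1 <- generate_slide(co, pid, size = c(1024, 1024))
  expect_true(all(s1$mask == 1))
  expect_identical(dim(s1$image), c(1024L, 1024L, 3L))
  s2 <- generate_slide(co, pid, size = c(1024, 1024))
  expect_identical(s1$image, s2$image)
  r <- generate_slide(co, pid, size = c(600, 800),
                      roi = list(shape = "rect", x = 100, y = 50, w = 400, h = 300))
  expect_equal(sum(r$mask), 400 * 300)
  expect_true(all(r$image[1, 1, ] == 255))  # outside ROI is background white
  expect_error(generate_slide(co, pid, size = c(200, 200),
                              roi = list(shape = "rect", x = 0, y = 0, w = 300, h = 100)),
               "ROI larger than canvas")
})

test_that("mean OD inside the ROI matches the closed-form class expectation", {
  co <- generate_cohort(1, 1, seed = 41, noise_sd = 0,
                        jitter = stain_jitter(0, c(1, 1), c(1, 1)))
  pid <- co$patients$patient_id[1]
  sl <- generate_slide(co, pid, size = c(1024, 1024))
  od <- hawkshead:::rgb_to_od(sl$image)
  measured <- apply(od, 3, mean)
  expected <- expected_mean_od(co$class_params$rlh)
  for (ch in 1:3)
    expect_lt(abs(measured[ch] - expected[ch]) / expected[ch], 0.10)
})

test_that("written cohorts round-trip through the manifest", {
  dir <- withr::local_tempdir()
  co <- tiny_cohort(n = 1, tiles = 2, seed = 13, noise_sd = 2)
  manifest <- write_cohort(co, dir)
  tiles <- read_tiles(manifest)
  expect_equal(length(tiles$pixels), 4L)  # 1 patient/class x 2 tiles
  expect_identical(tiles$pixels[[1]],
                   render_tile(co, co$patients$patient_id[1], 1L))
  expect_identical(sort(unique(tiles$info$label)), c(0L, 1L))
})
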