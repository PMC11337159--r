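guide_seg <- build_color_guide(t_range = c(10, 200), step = 1)

test_that("three flat-colour regions are recovered exactly by k-means", {
  img <- synth_film_image(c(17, 96, 151), guide_seg, dim = c(30, 60),
                          sigma = 0, seed = 1)
  seg <- segment_kmeans(img, k = 3, seed = 2)
  truth <- attr(img, "ground_truth")$labels
  expect_equal(label_accuracy(truth, seg$labels), 1)
  # flat regions: zero within-cluster variance means centroids equal region colours
  expect_equal(sort(seg$pixel_counts), sort(as.vector(table(truth))))
  expect_equal(seg$iterations <= 3, TRUE)
})

test_that("noisy synthetic micrographs are segmented with >= 99% accuracy", {
  img <- synth_film_image(c(17, 96, 151), guide_seg, dim = c(60, 90),
                          sigma = 0.02, seed = 7)
  seg <- segment_kmeans(img, k = 3, seed = 11)
  truth <- attr(img, "ground_truth")$labels
  expect_gte(label_accuracy(truth, seg$labels), 0.99)
})

test_that("segmentation is deterministic given a seed and stable across seeds up to relabelling", {
  img <- synth_film_image(c(17, 96, 151), guide_seg, dim = c(40, 60),
                          sigma = 0.02, seed = 3)
  a <- segment_kmeans(img, k = 3, seed = 5)
  b <- segment_kmeans(img, k = 3, seed = 5)
  expect_identical(a$labels, b$labels)
  # a different seed may permute labels but partitions the same pixels
  c <- segment_kmeans(img, k = 3, seed = 99)
  expect_gte(label_accuracy(a$labels, c$labels), 0.99)
})

test_that("masked pixels are excluded and labelled -1", {
  img0 <- synth_film_image(c(17, 96), guide_seg, dim = c(20, 40),
                           sigma = 0.01, seed = 2)
  mask <- matrix(TRUE, 20, 40)
  mask[, 1:10] <- FALSE
  img <- film_image(img0$pixels, img0$scale_mm_per_px, mask = mask)
  seg <- segment_kmeans(img, k = 2, seed = 1)
  expect_true(all(seg$labels[, 1:10] == -1L))
  expect_true(all(seg$labels[, 11:40] %in% 1:2))
  expect_equal(sum(seg$pixel_counts), sum(mask))
})

test_that("degenerate clustering (k above distinct colours) errors informatively", {
  img <- synth_film_image(c(17, 96, 151), guide_seg, dim = c(12, 12),
                          sigma = 0, seed = 1)
  expect_error(segment_kmeans(img, k = 5, seed = 1), "3 distinct colours")
})

test_that("region areas scale with the pixel size and sum to the image area", {
  img <- synth_film_image(c(17, 96, 151), guide_seg, dim = c(60, 90),
                          sigma = 0.02, seed = 7, scale_mm_per_px = 0.01)
  seg <- segment_kmeans(img, k = 3, seed = 1)
  areas <- region_areas(seg)
  expect_equal(sum(areas), 60 * 90 * 0.01^2)
  # rescaling the pixel size rescales areas quadratically
  expect_equal(region_areas(seg, scale_mm_per_px = 0.02), areas * 4)
  # direct arithmetic: 100x100 px at 0.01 mm/px in one cluster -> 1 mm^2
  expect_equal(100 * 100 * 0.01^2, 1.0)
})

test_that("film volume is area x thickness in 10^3 um^3, and is linear in thickness", {
  v <- estimate_film_volume(2.0, 17)
  expect_identical(v$per_region, 34)
  expect_identical(v$total, 34)
  # exact products for the three-region scenario
  v3 <- estimate_film_volume(c(2.0, 0.9, 0.5), c(17, 96, 151))
  expect_equal(v3$per_region, c(34, 86.4, 75.5))
  expect_equal(v3$total, 195.9)
  # zero area contributes zero volume
  expect_equal(estimate_film_volume(0, 100)$total, 0)
  # doubling thickness doubles volume
  v2 <- estimate_film_volume(c(2.0, 0.9, 0.5), 2 * c(17, 96, 151))
  expect_equal(v2$per_region, 2 * v3$per_region)
  # mismatched regions rejected
  expect_error(estimate_film_volume(c(a = 1, b = 2), c(b = 10, a = 20)),
               "do not match")
  expect_error(estimate_film_volume(c(1, 2), c(10)), "different region sets")
})

test_that("image I/O round-trips through PNG and segmentation summaries are written", {
  img <- synth_film_image(c(17, 96, 151), guide_seg, dim = c(20, 30),
                          sigma = 0.02, seed = 4)
  f <- withr::local_tempfile(fileext = ".png")
  write_synth(img, f)
  expect_true(file.exists(paste0(f, ".truth.json")))
  back <- read_film_image(f, scale_mm_per_px = 0.01)
  expect_equal(dim(back$pixels), dim(img$pixels))
  # PNG is 8-bit: agreement to 1/255
  expect_lt(max(abs(back$pixels - img$pixels)), 1 / 255)

  seg <- segment_kmeans(back, k = 3, seed = 1)
  csv <- withr::local_tempfile(fileext = ".csv")
  lab <- withr::local_tempfile(fileext = ".png")
  write_segmentation(seg, png_path = lab, csv_path = csv,
                     thicknesses_nm = c(17, 96, 151))
  summ <- read.csv(csv)
  expect_equal(summ$volume_1e3_um3, summ$area_mm2 * summ$thickness_nm)
  expect_true(file.exists(lab))
})
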