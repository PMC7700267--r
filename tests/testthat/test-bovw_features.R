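test_that("the Gabor envelope spread follows the bandwidth closed form", {
  expect_equal(gabor_sigma(0.25, 1.5),
               (1 / (pi * 0.25)) * sqrt(log(2) / 2) * (2^1.5 + 1) / (2^1.5 - 1),
               tolerance = 1e-15)
  expect_equal(gabor_sigma(0.25, 1.5), 1.5695, tolerance = 1e-4)
  # inverse-frequency scaling law
  expect_equal(gabor_sigma(0.5, 1.5), gabor_sigma(0.25, 1.5) / 2)
  # B = 1 substitution: factor (2+1)/(2-1) = 3
  expect_equal(gabor_sigma(0.2, 1), 3 * sqrt(log(2) / 2) / (pi * 0.2))
  expect_error(gabor_sigma(-0.1, 1))
  expect_error(gabor_sigma(0.25, 0))
})

test_that("Gabor kernels have the expected symmetries and orientations", {
  bank <- build_gabor_bank(0.25, 1.5, 4)
  expect_equal(bank$thetas, c(0, pi / 4, pi / 2, 3 * pi / 4))
  expect_equal(length(bank$kernels), 4)
  k0 <- bank$kernels[[1]]
  expect_true(nrow(k0) %% 2 == 1)
  # theta = 0: real part even in the column direction, imaginary part odd
  expect_equal(Re(k0), Re(k0[, ncol(k0):1]))
  expect_equal(Im(k0), -Im(k0[, ncol(k0):1]))
  # kernel at theta + pi/2 is the 90-degree rotation of the theta kernel
  k90 <- bank$kernels[[3]]
  rot90 <- function(m) t(m)[, nrow(m):1]
  expect_equal(Re(k90), rot90(Re(k0)), tolerance = 1e-12)
})

test_that("texture responses have the documented shape and null imaginaries", {
  img <- microscopy_image(array(137, dim = c(24, 24, 3)), 1.5)
  bank <- build_gabor_bank(0.25, 1.5, 4)
  resp <- texture_responses(img, bank)
  expect_equal(dim(resp), c(24, 24, 8))
  # constant input: odd (imaginary) filters integrate to ~0
  for (i in 1:4) expect_lt(max(abs(resp[, , 2 * i])), 1e-8)
})

test_that("a sinusoid at the central frequency maximises its own orientation", {
  H <- W <- 48
  x <- matrix(seq_len(W) - 1, H, W, byrow = TRUE)
  px <- array(rep(127 + 100 * sin(2 * pi * 0.25 * x), 3), dim = c(H, W, 3))
  img <- microscopy_image(pmin(pmax(px, 0), 255), 1.5)
  bank <- build_gabor_bank(0.25, 1.5, 4)
  resp <- texture_responses(img, bank)
  mid <- 20:28
  mag <- vapply(1:4, function(i)
    mean(sqrt(resp[mid, mid, 2 * i - 1]^2 + resp[mid, mid, 2 * i]^2)),
    numeric(1))
  # the sinusoid varies along columns (x'), i.e. the theta = 0 filter
  expect_equal(which.max(mag), 1)
})

test_that("whole-image responses equal per-crop responses in the interior", {
  sc <- generate_scene(quick_spec(seed = 5), "crop5")
  img <- sc$image
  bank <- build_gabor_bank(0.25, 1.5, 4)
  whole <- texture_responses(img, bank)
  r <- (nrow(bank$kernels[[1]]) - 1) / 2
  rows <- 60:120; cols <- 60:140
  crop <- microscopy_image(img$pixels[rows, cols, , drop = FALSE], 1.5)
  cropped <- texture_responses(crop, bank)
  inner_r <- (r + 1):(length(rows) - r)
  inner_c <- (r + 1):(length(cols) - r)
  expect_equal(cropped[inner_r, inner_c, ],
               whole[rows[inner_r], cols[inner_c], ], tolerance = 1e-10)
})

test_that("dictionaries are deterministic and reject degenerate input", {
  set.seed(31)
  cloud1 <- matrix(rnorm(60, mean = 0, sd = 0.5), ncol = 3)
  cloud2 <- matrix(rnorm(60, mean = 10, sd = 0.5), ncol = 3)
  rows <- rbind(cloud1, cloud2)
  d1 <- build_dictionary(rows, 2, seed = 4)
  d2 <- build_dictionary(rows, 2, seed = 4)
  expect_identical(d1$centroids, d2$centroids)
  # one centroid inside each cloud
  mins <- apply(d1$centroids, 1, min)
  expect_equal(sort(rowMeans(d1$centroids) > 5), c(FALSE, TRUE))
  expect_error(build_dictionary(rows[1:1, , drop = FALSE], 2), "fewer")
  expect_error(build_dictionary(rows[c(1, 1, 1), ], 2), "distinct")
  expect_error(build_dictionary(rows, 1), "at least 2")
})

test_that("histograms are normalized, tie-stable and match enumeration", {
  dict <- structure(list(mode = "colour", k = 2L, d = 1L,
                         centroids = matrix(c(0, 10), 2, 1),
                         feature_scaling = "none", seed = 1L),
                    class = "bovw_dictionary")
  h <- bovw_histogram(matrix(c(1, 1, 2, 8, 9, 9, 9), ncol = 1), dict)
  expect_equal(h, c(3 / 7, 4 / 7))
  expect_equal(sum(h), 1, tolerance = 1e-9)

  # all rows at one centroid: one-hot
  h2 <- bovw_histogram(matrix(rep(10, 5), ncol = 1), dict)
  expect_equal(h2, c(0, 1))
  # exact tie (5 is equidistant): lowest centroid index wins
  h3 <- bovw_histogram(matrix(5, ncol = 1), dict)
  expect_equal(h3, c(1, 0))
  expect_error(bovw_histogram(matrix(numeric(0), ncol = 1), dict), "empty")

  # permutation invariance on a real dictionary
  set.seed(8)
  rows <- matrix(runif(300, 0, 255), ncol = 3)
  d <- build_dictionary(rows, 4, seed = 2)
  r2 <- rows[sample(nrow(rows)), ]
  expect_equal(bovw_histogram(rows, d), bovw_histogram(r2, d))
})

test_that("descriptors grow the bbox, clamp at borders and concatenate modes", {
  px <- array(200, dim = c(60, 60, 3))
  px[20:29, 20:29, ] <- 60
  img <- microscopy_image(px, 1.5)
  cfg <- pipeline_config()
  cd <- make_candidate(1, 19, 19, size = 11)
  expect_equal(grow_bbox(cd$bbox, 0.10, c(60, 60)), bbox(18, 18, 31, 31))

  set.seed(9)
  rows <- matrix(runif(120, 0, 255), ncol = 3)
  dcol <- build_dictionary(rows, 3, seed = 5)
  bank <- build_gabor_bank(0.25, 1.5, 4)
  trows <- matrix(rnorm(160), ncol = 8)
  dtex <- build_dictionary(trows, 5, seed = 5, mode = "texture")
  desc <- extract_descriptor(img, cd, "both",
                             list(colour = dcol, texture = dtex), cfg, bank)
  expect_length(desc, 8)            # kc = 3 + kt = 5
  expect_equal(sum(desc), 2)        # two normalized histograms

  # same foreground on a different background changes the colour histogram
  px2 <- px; px2[px2 == 200] <- 120
  img2 <- microscopy_image(px2, 1.5)
  h1 <- extract_descriptor(img, cd, "colour", list(colour = dcol), cfg)
  h2 <- extract_descriptor(img2, cd, "colour", list(colour = dcol), cfg)
  expect_false(isTRUE(all.equal(h1, h2)))
})

test_that("dictionaries round-trip through JSON", {
  set.seed(3)
  d <- build_dictionary(matrix(runif(90, 0, 255), ncol = 3), 4, seed = 7,
                        mode = "colour")
  path <- withr::local_tempfile(fileext = ".json")
  write_dictionary(d, path)
  back <- read_dictionary(path)
  expect_equal(back$centroids, d$centroids)
  expect_equal(back$k, d$k)
  expect_equal(back$mode, d$mode)
})
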