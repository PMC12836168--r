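test_that("8-bit conversion min-max scales and collapses constants", {
  img <- matrix(c(100, 300, 500, 900), 2)
  out <- to_8bit(img)
  expect_equal(range(out), c(0, 255))
  expect_equal(to_8bit(matrix(7, 4, 4)), matrix(0, 4, 4))
})

test_that("rolling ball flattens constants and preserves small dark objects", {
  expect_equal(rolling_ball_subtract(matrix(40, 32, 32), 6, TRUE),
               matrix(0, 32, 32))
  # bright flat field with one dark disk of radius 2 < ball radius 6
  img <- matrix(200, 64, 64)
  cc <- outer((1:64 - 32)^2, (1:64 - 32)^2, "+") <= 4
  img[cc] <- 120
  out <- rolling_ball_subtract(img, 6, TRUE)
  expect_true(all(out[cc] >= 79))          # disk contrast preserved
  far <- outer((1:64 - 32)^2, (1:64 - 32)^2, "+") > 400
  expect_true(all(out[far] == 0))          # field flattened
  # output deviations never exceed the deviation from the brightest level
  expect_true(all(out <= max(img) - img + 1e-9))
})

test_that("rolling ball agrees with a direct morphology oracle", {
  set.seed(5)
  img <- matrix(runif(64 * 64, 0, 255), 64)
  radius <- 4
  # independent oracle: brute-force non-flat dilation then erosion
  d <- -radius:radius
  offs <- expand.grid(di = d, dj = d)
  offs <- offs[offs$di^2 + offs$dj^2 <= radius^2, ]
  offs$h <- sqrt(radius^2 - offs$di^2 - offs$dj^2) - radius
  morph <- function(m, op) {
    out <- matrix(if (op == "max") -Inf else Inf, 64, 64)
    for (i in 1:64) for (j in 1:64) {
      for (k in seq_len(nrow(offs))) {
        ii <- i - offs$di[k]; jj <- j - offs$dj[k]
        if (ii >= 1 && ii <= 64 && jj >= 1 && jj <= 64) {
          v <- if (op == "max") m[ii, jj] + offs$h[k] else m[ii, jj] - offs$h[k]
          out[i, j] <- if (op == "max") max(out[i, j], v) else min(out[i, j], v)
        }
      }
    }
    out
  }
  oracle <- pmax(morph(morph(img, "max"), "min") - img, 0)
  expect_equal(rolling_ball_subtract(img, radius, TRUE), oracle)
})

test_that("rolling ball validates its radius", {
  expect_error(rolling_ball_subtract(matrix(0, 32, 32), 0.5), ">= 1")
  expect_error(rolling_ball_subtract(matrix(0, 8, 8), 10), "smaller")
})

test_that("contrast enhancement hits the endpoints and clips the exact pixel count", {
  two <- matrix(c(10, 200), 2, 8)
  out <- enhance_contrast(two, saturation = 0)
  expect_setequal(unique(as.vector(out)), c(0, 255))
  # identity when the image already spans the full range at zero saturation
  ramp8 <- matrix(seq(0, 255, length.out = 64), 8)
  expect_equal(enhance_contrast(ramp8, saturation = 0), ramp8)
  # linear ramp of 1e4 distinct pixels: ceiling(0.00175 * 1e4) = 18 pixels
  # saturate at each end
  ramp <- matrix(seq_len(1e4), 100)
  out <- enhance_contrast(ramp, saturation = 0.35)
  expect_equal(sum(out == 0), 18)
  expect_equal(sum(out == 255), 18)
  # rank order preserved between the tails
  mid <- out > 0 & out < 255
  expect_true(all(diff(out[mid][order(ramp[mid])]) > 0))
})

test_that("constant images cannot be contrast stretched", {
  expect_warning(out <- enhance_contrast(matrix(5, 4, 4)), "constant")
  expect_equal(out, matrix(5, 4, 4))
})

test_that("Yen threshold separates a two-level histogram", {
  # ties along the flat inter-mode plateau break to the lowest level, so the
  # threshold sits at the lower mode and foreground (> threshold) is exactly
  # the upper class
  img <- matrix(c(rep(10, 500), rep(200, 500)), 25)
  thr <- yen_threshold(img)
  expect_gte(thr, 10); expect_lt(thr, 200)
  expect_identical(img > thr, img == 200)
  expect_error(yen_threshold(matrix(3, 4, 4)), "constant")
})

test_that("Yen equals brute-force criterion maximization on 50 seeded images", {
  for (s in 1:50) {
    img <- withr::with_seed(s, {
      base <- sample(0:255, 16, replace = TRUE)
      matrix(sample(base, 32 * 32, replace = TRUE) +
               sample(0:20, 32 * 32, replace = TRUE), 32)
    })
    img <- pmin(img, 255)
    expect_identical(yen_threshold(img), as.double(yen_bruteforce(as.vector(img))),
                     label = sprintf("seed %d", s))
  }
})

test_that("Yen thresholds of an image and its bit-inverse are complementary", {
  for (s in 1:10) {
    img <- withr::with_seed(100 + s, matrix(sample(0:255, 32 * 32, TRUE), 32))
    t1 <- yen_threshold(img)
    t2 <- yen_threshold(255 - img)
    expect_lte(abs((255 - t2) - t1), 1)
  }
})

test_that("binarization uses >= and is monotone in the threshold", {
  m <- matrix(0.5, 4, 4)
  expect_true(all(binarize(m, 0.5)))
  expect_true(all(binarize(m, 0)))
  prob <- matrix(runif(256, 0, 1), 16)
  fracs <- vapply(seq(0, 1, by = 0.1), function(th) mean(binarize(prob, th)),
                  numeric(1))
  expect_true(all(diff(fracs) <= 0))
  # mask at a higher threshold is a subset of the mask at a lower one
  expect_true(all(binarize(prob, 0.7) <= binarize(prob, 0.3)))
})
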