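test_that("CIE76 distance is a metric with the canonical Lab endpoints", {
  expect_equal(cie76_delta_e("#FF0000", "#FF0000"), 0)
  expect_equal(cie76_delta_e("#000000", "#FFFFFF"), 100, tolerance = 1e-6)
  expect_error(cie76_delta_e("#GG0000", "#FFFFFF"), "malformed")
  expect_error(cie76_delta_e("red", "#FFFFFF"), "malformed")

  set.seed(3)
  hexes <- sprintf("#%06X", sample.int(16777216, 60) - 1)
  a <- hexes[1:20]; b <- hexes[21:40]; c <- hexes[41:60]
  expect_equal(cie76_delta_e(a, b), cie76_delta_e(b, a))
  # identity of indiscernibles on identical codes, triangle inequality
  expect_true(all(cie76_delta_e(a, a) == 0))
  expect_true(all(cie76_delta_e(a, c) <=
                    cie76_delta_e(a, b) + cie76_delta_e(b, c) + 1e-9))
})

test_that("sRGB to Lab conversion matches the reference converter", {
  hexes <- c("#FFFF00", "#E08000", "#A6CAF0", "#123456", "#808000")
  ours <- srgb_to_lab(hexes)
  rgb <- t(sapply(hexes, function(h) {
    strtoi(c(substr(h, 2, 3), substr(h, 4, 5), substr(h, 6, 7)), 16L)
  })) / 255
  ref <- grDevices::convertColor(rgb, from = "sRGB", to = "Lab")
  expect_equal(unname(ours), unname(ref), tolerance = 0.01)
  # hence the pairwise distance agrees with the oracle Lab pipeline
  d_ref <- sqrt(sum((ref[1, ] - ref[2, ])^2))
  expect_equal(cie76_delta_e("#FFFF00", "#E08000"), d_ref, tolerance = 0.01)
})

test_that("the standard region is blacked out and leaves the counting domain", {
  img <- random_color_image(40, 50, c("#FF0000", "#404040"))
  full <- cbind(c(0, 51, 51, 0), c(0, 0, 41, 41))
  blacked <- mask_standard_region(img, full)
  expect_true(all(blacked == 0))
  counts <- count_color_pixels(blacked, c(S3 = "#FF0000"))
  expect_equal(counts$count, 0)

  set.seed(8)
  for (i in 1:5) {
    x0 <- sample(1:20, 1); x1 <- x0 + sample(5:25, 1)
    y0 <- sample(1:15, 1); y1 <- y0 + sample(5:20, 1)
    rect <- cbind(c(x0, x1, x1, x0) - 0.5, c(y0, y0, y1, y1) - 0.5)
    img <- random_color_image(40, 50, c("#FF0000"))
    masked <- mask_standard_region(img, rect)
    domain <- sum(masked[, , 1] != 0 | masked[, , 2] != 0 | masked[, , 3] != 0)
    area <- (min(x1 - 1, 50) - x0 + 1) * (min(y1 - 1, 40) - y0 + 1)
    expect_equal(domain, 40 * 50 - area)
  }

  expect_error(mask_standard_region(img, cbind(1, 1)), "polygon")
  expect_error(mask_standard_region(img, cbind(c(0, 500, 500), c(0, 0, 500))),
               "outside")
})

test_that("color-pixel counting matches a brute-force nearest-deltaE scan", {
  pal <- step_palette()
  img <- random_color_image(32, 32, pal)
  counts <- count_color_pixels(img, pal, tolerance = 0)
  # pure palette image: exact histogram at any tolerance
  hex_img <- sprintf("#%02X%02X%02X", img[, , 1], img[, , 2], img[, , 3])
  expect_equal(counts$count, unname(as.vector(table(factor(hex_img, levels = pal)))))
  counts10 <- count_color_pixels(img, pal, tolerance = 10)
  expect_equal(counts10$count, counts$count)

  # perturbed colors with zero tolerance are uncounted
  perturbed <- img
  perturbed[, , 1] <- ifelse(perturbed[, , 1] < 255,
                             perturbed[, , 1] + 1, perturbed[, , 1] - 1)
  expect_true(all(count_color_pixels(perturbed, pal, tolerance = 0)$count == 0))

  # random off-palette images against a per-pixel oracle
  set.seed(14)
  for (i in 1:20) {
    colors <- sprintf("#%06X", sample.int(16777216, 6) - 1)
    img <- random_color_image(16, 16, colors)
    tol <- runif(1, 5, 60)
    got <- count_color_pixels(img, pal, tolerance = tol)
    truth <- numeric(length(pal))
    for (r in 1:16) for (c in 1:16) {
      hx <- sprintf("#%02X%02X%02X", img[r, c, 1], img[r, c, 2], img[r, c, 3])
      if (hx == "#000000") next
      d <- cie76_delta_e(rep(hx, length(pal)), pal)
      if (min(d) <= tol + 1e-9) {
        truth[which.min(d)] <- truth[which.min(d)] + 1
      }
    }
    expect_equal(got$count, truth)
  }

  # ties break toward the lowest step index
  dup <- c(A = "#FF0000", B = "#FF0000")
  img_red <- random_color_image(8, 8, "#FF0000")
  cd <- count_color_pixels(img_red, dup, tolerance = 5)
  expect_equal(cd$count, c(64, 0))

  expect_error(count_color_pixels(img_red, character(0)), "empty palette")
  expect_error(count_color_pixels(img_red, pal, tolerance = -1), ">= 0")
})

test_that("percent color pixels normalizes by the white reference", {
  counts <- data.frame(color = step_palette(), name = names(step_palette()),
                       count = c(0, 200, 50, rep(10, 7)))
  pct <- percent_color(counts, white_count = 200)
  expect_equal(pct$percent[1], 0)
  expect_equal(pct$percent[2], 100)
  expect_equal(pct$percent[3], 25)
  expect_error(percent_color(counts, 0), "positive")
})

test_that("artifact detection counts colored pixels outside the limb", {
  # clutter-free scene: severity none at the low-kV preset
  rad <- render_radiograph(wedge_spec(), knee_tissue_spec(),
                           exposure_setting(50, 1.2), seed = 41)
  res <- cda_pipeline(rad)
  expect_equal(attr(res$artifacts, "severity"), "none")
  expect_true(all(res$artifacts$fraction <= 0.005))

  # closed loop: severe clutter at 80 kV flags only the low steps, severely
  rad80 <- render_radiograph(wedge_spec(), knee_tissue_spec(),
                             exposure_setting(80, 1.2), seed = 42)
  rad80 <- add_background_clutter(rad80, "severe", seed = 2)
  res80 <- cda_pipeline(rad80)
  expect_equal(attr(res80$artifacts, "severity"), "severe")
  expect_true(all(which(res80$artifacts$flagged) %in% 1:3))
  expect_gt(sum(res80$artifacts$flagged), 0)
  # artifact inflation makes the low-step percentages exceed the clean run
  clean80 <- cda_pipeline(render_radiograph(wedge_spec(), knee_tissue_spec(),
                                            exposure_setting(80, 1.2),
                                            seed = 42))
  expect_gt(res80$percent$percent[1], clean80$percent$percent[1])

  # brute-force oracle on a small constructed set
  set.seed(5)
  cmap <- cda_colormap()
  tab <- disjoint_table(0, 1000)
  px <- matrix(runif(64 * 64, -200, 1200), 64, 64)
  limb <- matrix(FALSE, 64, 64); limb[16:48, 16:48] <- TRUE
  rad_s <- as_rad(px, limb_mask = limb)
  set <- decompose(rad_s, tab, cmap, limb, size = c(64, 64))
  rep_ <- detect_artifacts(set)
  for (k in c(1, 4, 9)) {
    truth <- sum(px >= tab$min_hu[k] & px <= tab$max_hu[k] & !limb)
    expect_equal(rep_$artifact_pixels[k], truth)
  }
  expect_error(detect_artifacts(set, matrix(TRUE, 10, 10)), "misaligned")
})
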