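test_that("measuring lines sample nearest pixels and average across the band", {
  px <- matrix(7, 64, 64)
  rad <- as_rad(px)
  line <- measuring_line(1, rbind(c(5, 10), c(60, 10)))
  expect_true(all(sample_measuring_line(rad, line) == 7))

  # vertical gradient: row r has value r; a width-3 horizontal band averages
  # the three adjacent rows
  grad <- matrix(rep(1:64, 64), 64, 64)
  line3 <- measuring_line(1, rbind(c(5, 20), c(60, 20)), width = 3)
  expect_true(all(sample_measuring_line(as_rad(grad), line3) == 20))

  out <- measuring_line(1, rbind(c(-3, 10), c(60, 10)))
  expect_error(sample_measuring_line(rad, out), "outside")
})

test_that("line samples over a noise-free wedge equal the generator value", {
  w <- small_wedge()
  exp <- exposure_setting(60, 1.2)
  rad <- render_radiograph(w, NULL, exp, seed = 1, size = c(64, 64),
                           noise = FALSE)
  truth <- wedge_step_hu(w, exp)
  for (s in c(1, 5, 10)) {
    fp <- w$footprints[w$footprints$step == s, ]
    y <- round((fp$y0 + fp$y1) / 2)
    line <- measuring_line(s, rbind(c(fp$x0, y), c(fp$x1, y)))
    expect_true(all(abs(sample_measuring_line(rad, line) - truth[s]) < 1e-9))
  }
})

test_that("step_range is the raw min/max with no outlier handling", {
  expect_equal(unname(step_range(c(5, 3, 9))), c(3, 9))
  expect_equal(unname(step_range(rep(4.2, 10))), c(4.2, 4.2))
  expect_error(step_range(numeric(0)), "zero samples")
  set.seed(42)
  for (i in 1:25) {
    x <- rnorm(sample(2:100, 1), sd = 500)
    expect_equal(unname(step_range(x)), c(min(x), max(x)))
  }
})

test_that("calibration tables carry 10 per-step ranges read from the image", {
  w <- small_wedge()
  exp <- exposure_setting(70, 1.2)
  rad <- render_radiograph(w, NULL, exp, seed = 3, size = c(64, 64))
  tab <- build_calibration_table(rad)
  expect_equal(nrow(tab), 10)
  expect_equal(tab$step, 1:10)
  expect_true(all(tab$min_hu <= tab$max_hu))

  # brute-force oracle: min/max over the center row of each footprint
  for (s in 1:10) {
    fp <- w$footprints[w$footprints$step == s, ]
    y <- round((fp$y0 + fp$y1) / 2)
    row <- rad$pixels[y, fp$x0:fp$x1]
    expect_equal(tab$min_hu[s], min(row))
    expect_equal(tab$max_hu[s], max(row))
  }

  missing <- w
  missing$footprints <- missing$footprints[-4, ]
  expect_error(build_calibration_table(rad, missing), "S4")

  # replicate renders differ only within noise
  tab2 <- build_calibration_table(
    render_radiograph(w, NULL, exp, seed = 4, size = c(64, 64)))
  expect_lt(max(abs(tab2$min_hu - tab$min_hu)), 12 * noise_sd_at(exp))
})

test_that("replicate summaries use mean and sample SD", {
  t1 <- make_table(seq(100, 1000, by = 100), seq(150, 1050, by = 100))
  s1 <- summarize_replicates(list(t1))
  expect_true(all(s1$sd == 0))
  expect_true(all(s1$n == 1))
  expect_equal(s1$mean[s1$bound == "Min"], t1$min_hu)

  mins2 <- seq(100, 1000, by = 100); mins2[1] <- 200
  t2 <- make_table(mins2, seq(150, 1050, by = 100))
  s12 <- summarize_replicates(list(t1, t2))
  expect_equal(s12$mean[s12$bound == "Min" & s12$step == 1], 150)
  expect_equal(s12$sd[s12$bound == "Min" & s12$step == 1],
               sd(c(100, 200)), tolerance = 1e-12)
  expect_equal(round(s12$sd[s12$bound == "Min" & s12$step == 1], 2), 70.71)

  t3 <- make_table(t1$min_hu, t1$max_hu, exposure = exposure_setting(80, 1.2))
  expect_error(summarize_replicates(list(t1, t3)), "mixed exposures")

  # nine replicates against a brute-force two-pass mean/SD
  set.seed(9)
  tabs <- lapply(1:9, function(i) {
    make_table(sort(rnorm(10, 1000, 200)), sort(rnorm(10, 1400, 200)))
  })
  sm <- summarize_replicates(tabs)
  mins <- sapply(tabs, `[[`, "min_hu")
  for (s in 1:10) {
    v <- mins[s, ]
    m <- sum(v) / 9
    expect_equal(sm$mean[sm$bound == "Min" & sm$step == s], m,
                 tolerance = 1e-9)
    expect_equal(sm$sd[sm$bound == "Min" & sm$step == s],
                 sqrt(sum((v - m)^2) / 8), tolerance = 1e-9)
  }
})

test_that("coverage intervals match the published endpoints", {
  cov50 <- coverage_interval(reference_ranges("50 kV; 1.2 mAs"))
  expect_equal(unname(cov50), c(880.6, 2798.9))
  cov60 <- coverage_interval(reference_ranges("60 kV; 1.2 mAs"))
  expect_equal(unname(cov60), c(672.8, 2539.4))
  degen <- make_table(rep(42, 10), rep(42, 10))
  expect_equal(unname(coverage_interval(degen)), c(42, 42))
  # bounds dominate every step range
  tab <- disjoint_table(100, 900)
  cv <- coverage_interval(tab)
  expect_true(all(cv["low"] <= tab$min_hu))
  expect_true(all(cv["high"] >= tab$max_hu))
})

test_that("range gaps quantify coverage scattering", {
  gaps_hi_mas <- range_gaps(reference_ranges("60 kV; 12 mAs"))
  expect_equal(gaps_hi_mas[1], 63.3 - (-148.6))
  gaps50 <- range_gaps(reference_ranges("50 kV; 1.2 mAs"))
  expect_equal(gaps50[1], max(0, 1173.9 - 1130.6))
  adj <- make_table(seq(0, 900, by = 100), seq(100, 1000, by = 100))
  expect_true(all(range_gaps(adj) == 0))
  expect_length(range_gaps(adj), 9)
})

test_that("calibration results round-trip through CSV and JSON", {
  tab <- make_table(seq(100, 1000, by = 100), seq(180, 1080, by = 100),
                    exposure = exposure_setting(60, 1.2))
  for (ext in c("csv", "json")) {
    path <- tempfile(fileext = paste0(".", ext))
    write_calibration(tab, path)
    back <- read_calibration(path)
    expect_equal(back$min_hu, tab$min_hu)
    expect_equal(back$max_hu, tab$max_hu)
    expect_equal(attr(back, "exposure")$kv, 60)
  }
  sm <- summarize_replicates(list(tab))
  path <- tempfile(fileext = ".csv")
  write_calibration(sm, path)
  back <- read_calibration(path)
  expect_s3_class(back, "calibration_summary")
  expect_equal(back$mean, sm$mean)
  expect_error(write_calibration(tab, tempfile(fileext = ".xlsx")),
               "unsupported")
})
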