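# Spearman correlation, line-scan profiles and per-side root statistics.

test_that("Spearman matches hand arithmetic and rank invariance", {
  set.seed(1)
  x <- sort(runif(20)); y <- x^3 + 1  # strictly monotone
  expect_equal(spearman_correlation(x, y)$estimate, 1)
  # worked example: d^2 = (1,1,1,1) -> 1 - 6*4/(4*15) = 0.6
  r <- spearman_correlation(c(1, 2, 3, 4), c(2, 1, 4, 3))
  expect_equal(r$estimate, 0.6)
  # invariance under strictly monotone transforms
  a <- rnorm(30); b <- rnorm(30)
  expect_equal(spearman_correlation(exp(a), b)$estimate,
               spearman_correlation(a, b)$estimate)
  expect_equal(spearman_correlation(a, 3 * b + 5)$estimate,
               spearman_correlation(a, b)$estimate)
})

test_that("Spearman equals the brute-force implementation on 1000 vectors", {
  set.seed(2)
  for (i in 1:1000) {
    n <- sample(11:30, 1)
    x <- sample(1:12, n, replace = TRUE)  # ties included
    y <- sample(1:12, n, replace = TRUE)
    if (length(unique(x)) == 1L || length(unique(y)) == 1L) next
    got <- spearman_correlation(x, y)$estimate
    expect_equal(got, brute_spearman(x, y), tolerance = 1e-12)
    expect_equal(got, suppressWarnings(cor(x, y, method = "spearman")),
                 tolerance = 1e-12)
  }
})

test_that("exact permutation p matches in-test enumeration for small n", {
  perms <- function(v) {
    if (length(v) == 1L) return(matrix(v, 1, 1))
    do.call(rbind, lapply(seq_along(v), function(i)
      cbind(v[i], perms(v[-i]))))
  }
  set.seed(3)
  for (i in 1:5) {
    n <- sample(4:6, 1)
    x <- rnorm(n); y <- rnorm(n)
    got <- spearman_correlation(x, y)
    expect_identical(got$method, "exact permutation")
    rx <- rank(x); ry <- rank(y)
    r_obs <- abs(cor(rx, ry))
    pm <- perms(seq_len(n))
    r_all <- apply(pm, 1, function(idx) abs(cor(rx[idx], ry)))
    expect_equal(got$p_value, mean(r_all >= r_obs - 1e-9), tolerance = 1e-12)
  }
})

test_that("degenerate Spearman input is flagged, not crashed", {
  expect_warning(r <- spearman_correlation(rep(1, 5), 1:5), "constant")
  expect_true(r$degenerate)
  expect_true(is.na(r$estimate))
  expect_error(spearman_correlation(1:2, 2:3), "at least 3")
})

test_that("line scans bin pixels as specified", {
  m <- matrix(5, 20, 20)
  pr <- line_scan_profile(m, rbind(c(2, 2), c(2, 15)), bin_px = 3,
                          pixel_size_um = 0.5)
  expect_true(all(pr$value == 5))  # constant map -> constant profile
  # 9-pixel straight line, bin 3 -> exactly 3 data points at the bin means
  m2 <- matrix(0, 10, 10)
  m2[4, 1:9] <- c(1, 2, 3, 10, 20, 30, 7, 8, 9)
  pr2 <- line_scan_profile(m2, rbind(c(4, 1), c(4, 9)), bin_px = 3)
  expect_identical(nrow(pr2), 3L)
  expect_equal(pr2$value, c(2, 20, 8))
  expect_equal(pr2$n, rep(3L, 3))
  # distances in um via the pixel size
  pr3 <- line_scan_profile(m2, rbind(c(4, 1), c(4, 9)), bin_px = 3,
                           pixel_size_um = 70 / 512)
  expect_equal(diff(pr3$distance_um), rep(3 * 70 / 512, 2))
})

test_that("a linear ramp profiles to bin-centre values", {
  ramp <- matrix(rep(1:40, each = 40), 40, 40)  # value = column index
  pr <- line_scan_profile(ramp, rbind(c(10, 1), c(10, 36)), bin_px = 3)
  centres <- tapply(1:36, (0:35) %/% 3, mean)
  expect_equal(pr$value, as.numeric(centres))
})

test_that("paired maps share bins and polylines are validated", {
  m13 <- matrix(1, 10, 10); m15 <- matrix(2, 10, 10)
  pr <- line_scan_profile(list(at13c = m13, at15n = m15),
                          rbind(c(1, 1), c(10, 10)), bin_px = 3)
  expect_true(all(c("value_at13c", "value_at15n", "se_at13c", "se_at15n")
                  %in% names(pr)))
  expect_true(all(pr$value_at13c == 1 & pr$value_at15n == 2))
  expect_error(line_scan_profile(m13, rbind(c(1, 1), c(1, 30))),
               "exits the image")
})

test_that("root-side analysis computes weighted means and per-side fits", {
  rec <- data.frame(side = c("a", "a", "b", "b", "b"),
                    ape13c = c(1, 2, 0.5, 1, 1.5),
                    ape15n = c(0.4, 0.0, 0.1, 0.2, 0.3),
                    mass_mg = c(1, 3, 2, 2, 2))
  out <- suppressWarnings(root_side_analysis(rec))  # side b is an exact line
  a <- out$summary[out$summary$side == "a", ]
  expect_equal(a$wmean_ape15n, 0.1)  # masses (1, 3) with APE (0.4, 0)
  b <- out$summary[out$summary$side == "b", ]
  expect_equal(b$wmean_ape15n, 0.2)  # equal masses -> arithmetic mean
  expect_equal(b$slope, 0.2, tolerance = 1e-12)
  # single-segment side: means only, regression flagged unavailable
  one <- root_side_analysis(data.frame(side = "solo", ape13c = 1,
                                       ape15n = 0.2, mass_mg = 5))
  expect_false(one$summary$regression)
  expect_true(is.na(one$summary$slope))
  expect_error(root_side_analysis(transform(rec, mass_mg = 0)), "> 0")
})

test_that("root-system generator recovers configured models", {
  # noiseless draw: OLS refit returns the configured slope exactly
  cfg <- root_system_config(
    sides = list(amended = list(n = 35L, slope = 0.25, intercept = -0.06,
                                r_squared = NULL, noise_sd = 0,
                                x_meanlog = -0.213, x_sdlog = 0.28)),
    seed = 7)
  tab <- generate_root_system_table(cfg)
  fit <- lm(ape15n ~ ape13c, tab$segments)
  expect_equal(unname(coef(fit)), c(-0.06, 0.25), tolerance = 1e-12)

  # zero-effect side: mean APE15N ~ 0 within Monte-Carlo error
  cfg0 <- root_system_config(
    sides = list(unamended = list(n = 500L, slope = 0, intercept = 0,
                                  r_squared = NULL, noise_sd = 0.01,
                                  x_meanlog = -0.3, x_sdlog = 0.3)),
    seed = 8)
  tab0 <- generate_root_system_table(cfg0)
  expect_lt(abs(mean(tab0$segments$ape15n)), 3 * 0.01 / sqrt(500))
})

test_that("amended-side calibration reproduces the published segment mean", {
  # 200 replicate draws of n = 35: grand mean APE15N within 2 SE of 0.15
  ys <- unlist(lapply(1:200, function(i) {
    tab <- generate_root_system_table(root_system_config(seed = i))
    tab$segments$ape15n[tab$segments$side == "amended"]
  }))
  se <- sd(ys) / sqrt(length(ys))
  expect_lt(abs(mean(ys) - 0.15), 2 * se)
  # and the dispersion is of the published magnitude (SD ~ 0.16)
  expect_equal(sd(ys), 0.16, tolerance = 0.2)
})

test_that("root tips are heavy-tailed: most near zero, few large", {
  tab <- generate_root_system_table(root_system_config(seed = 10))
  tips <- tab$tips$ape15n[tab$tips$side == "amended"]
  expect_lt(median(tips), 0.05)
  expect_gt(max(tips), 10 * median(tips))
  # determinism
  tab2 <- generate_root_system_table(root_system_config(seed = 10))
  expect_identical(tab, tab2)
})
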