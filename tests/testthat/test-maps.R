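# Per-pixel isotope-fraction maps: worked arithmetic, Poisson uncertainty,
# masking, and the pairing-model and plane-accumulation identities.

test_that("carbon atom fraction follows the pairing formula", {
  s <- make_stack(`13C12C` = matrix(c(0, 198, 5, 1), 2, 2),
                  `12C12C` = matrix(c(500, 9801, 2, 0), 2, 2))
  cf <- carbon_atom_fraction(s, min_counts = 10)
  expect_equal(cf$at[1, 1], 0)                      # zero numerator
  expect_equal(cf$at[2, 1], 100 * 198 / 19800)      # exactly 1.00 at%
  expect_false(cf$valid[1, 2])                       # denominator 9 < 10
  expect_true(is.na(cf$at[1, 2]))
  expect_false(cf$valid[2, 2])                       # denominator 1 < 10
})

test_that("nitrogen atom fraction follows the CN- formula", {
  s <- make_stack(`12C15N` = matrix(c(0, 37), 1, 2),
                  `12C14N` = matrix(c(1000, 9963), 1, 2))
  nf <- nitrogen_atom_fraction(s)
  expect_equal(nf$at[1, 1], 0)
  expect_equal(nf$at[1, 2], 0.37)  # the control-magnitude worked example
})

test_that("at%15N is strictly monotone in 12C15N at fixed 12C14N", {
  at <- vapply(0:50, function(b) {
    s <- make_stack(`12C15N` = matrix(b, 1, 1), `12C14N` = matrix(500, 1, 1))
    nitrogen_atom_fraction(s)$at[1, 1]
  }, numeric(1))
  expect_true(all(diff(at) > 0))
})

test_that("total CN- signal applies the dual-label correction", {
  s <- make_stack(`12C14N` = 1000, `12C15N` = 50, `13C12C` = 200,
                  `12C12C` = 10000)
  expect_equal(total_cn_signal(s)$signal[1, 1], 1050 * 1.01)
  s0 <- make_stack(`12C14N` = 800, `12C15N` = 30, `13C12C` = 0, `12C12C` = 500)
  expect_equal(total_cn_signal(s0)$signal[1, 1], 830)  # R = 0, correction vanishes
  s_mask <- make_stack(`12C14N` = 800, `12C15N` = 30, `13C12C` = 5, `12C12C` = 0)
  expect_true(is.na(total_cn_signal(s_mask)$signal[1, 1]))
})

test_that("factored and expanded total-CN forms agree on random stacks", {
  for (seed in 1:5) {
    s <- random_stack(seed = seed)
    got <- total_cn_signal(s)$signal
    r <- s$counts[["13C12C"]] / (2 * s$counts[["12C12C"]])
    expanded <- s$counts[["12C14N"]] * (1 + r) + s$counts[["12C15N"]] * (1 + r)
    expect_equal(got, expanded, tolerance = 1e-12)
  }
})

test_that("APE reproduces the published worked examples and is signed", {
  ctrl <- control_reference(1.07, 0.37)
  expect_equal(ape(6.68, ctrl, "13C"), 5.61)            # Table-1 max 13C
  expect_equal(signif(ape(21.30, ctrl, "15N"), 3), 20.9) # Table-1 max 15N
  expect_equal(ape(1.07, ctrl, "13C"), 0)               # control on itself
  expect_lt(ape(1.00, ctrl, "13C"), 0)                  # unclamped
  m <- matrix(c(1.07, 2.07), 1, 2)
  expect_equal(ape(m, ctrl, "13C"), matrix(c(0, 1), 1, 2))
})

test_that("simulated pixels at p13C = 0.011 recover 1.10 at% within 3 SE", {
  # independent Monte-Carlo oracle: binomial pairing + Poisson, built here
  set.seed(7)
  n <- 1e4; lam <- 500; p <- 0.011
  s <- make_stack(`12C12C` = matrix(rpois(n, lam * (1 - p)^2), 100, 100),
                  `13C12C` = matrix(rpois(n, lam * 2 * p * (1 - p)), 100, 100),
                  nrow = 100, ncol = 100)
  cf <- carbon_atom_fraction(s)
  m <- mean(cf$at[cf$valid])
  se <- sd(cf$at[cf$valid]) / sqrt(sum(cf$valid))
  expect_lt(abs(m - 1.10), 3 * se)
})

test_that("simulated pixels at p15N = 0.20 recover 20 at% within 3 SE", {
  set.seed(8)
  n <- 1e4; lam <- 300; p <- 0.20
  s <- make_stack(`12C14N` = matrix(rpois(n, lam * (1 - p)), 100, 100),
                  `12C15N` = matrix(rpois(n, lam * p), 100, 100),
                  nrow = 100, ncol = 100)
  nf <- nitrogen_atom_fraction(s)
  m <- mean(nf$at[nf$valid])
  se <- sd(nf$at[nf$valid]) / sqrt(sum(nf$valid))
  expect_lt(abs(m - 20), 3 * se)
})

test_that("delta-method SE follows the Poisson scaling law", {
  s1 <- make_stack(`12C15N` = 40, `12C14N` = 960,
                   `12C12C` = 800, `13C12C` = 16)
  s100 <- make_stack(`12C15N` = 4000, `12C14N` = 96000,
                     `12C12C` = 80000, `13C12C` = 1600)
  for (ch in c("13C", "15N")) {
    r <- ratio_uncertainty(s1, ch)[1, 1] / ratio_uncertainty(s100, ch)[1, 1]
    expect_equal(r, 10, tolerance = 0.01)
  }
})

test_that("delta-method SE matches Monte-Carlo SD within 10% at moderate counts", {
  set.seed(9)
  n <- 1e4; lam14 <- 190; lam15 <- 10
  a <- rpois(n, lam14); b <- rpois(n, lam15)
  at <- 100 * b / (a + b)
  mc_sd <- sd(at[(a + b) >= 10])
  s <- make_stack(`12C14N` = lam14, `12C15N` = lam15)
  expect_equal(ratio_uncertainty(s, "15N")[1, 1], mc_sd, tolerance = 0.1)
})

test_that("noiseless expected counts invert to the generating p13C exactly", {
  # pairing-model identity: E[13C12C] / (2 E[12C12C] + E[13C12C]) = p
  for (p in c(0.01, 0.11, 0.25, 0.5, 0.9)) {
    lam <- 1e6  # integer expected counts for 2-decimal p
    s <- make_stack(`12C12C` = round(lam * (1 - p)^2), `13C12C` = round(lam * 2 * p * (1 - p)))
    expect_equal(carbon_atom_fraction(s)$at[1, 1], 100 * p, tolerance = 1e-12)
  }
})

test_that("ratios from accumulated planes equal ratios from a pre-summed stack", {
  set.seed(10)
  planes <- lapply(1:3, function(i) random_stack(seed = i))
  summed <- accumulate_planes(planes)
  expect_identical(summed$planes, 3L)
  manual <- make_stack(
    `12C12C` = Reduce(`+`, lapply(planes, function(s) s$counts[["12C12C"]])),
    `13C12C` = Reduce(`+`, lapply(planes, function(s) s$counts[["13C12C"]])),
    nrow = 8, ncol = 8)
  expect_equal(carbon_atom_fraction(summed)$at, carbon_atom_fraction(manual)$at)
})

test_that("valid at% pixels are bounded in [0, 100] and APE(control) = 0", {
  s <- random_stack(seed = 11)
  pm <- isotope_pair_map(s, control_reference(1.07, 0.37))
  for (ch in c("at13c", "at15n")) {
    v <- pm[[ch]][!is.na(pm[[ch]])]
    expect_true(all(v >= 0 & v <= 100))
  }
  expect_true(all(pm$total_cn >= s$counts[["12C14N"]] + s$counts[["12C15N"]],
                  na.rm = TRUE))
})

test_that("missing species raise errors", {
  s <- random_stack()
  s$counts[["13C12C"]] <- NULL
  expect_error(carbon_atom_fraction(s), "species missing: 13C12C")
  expect_error(total_cn_signal(s), "species missing: 13C12C")
})
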