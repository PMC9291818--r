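# Segmented regression: exact recovery on noiseless kinks, grid-oracle
# equivalence, linear fallback, RSS dominance, bootstrap reproducibility and
# the model-selection procedure.

test_that("noiseless two-segment data is recovered exactly", {
  set.seed(1)
  x <- runif(50, 0, 3)
  y <- 1 + 2 * x + (0.5 - 2) * pmax(0, x - 1.5)
  fit <- fit_segmented(x, y, bootstrap = 0)
  expect_true(fit$kink)
  expect_equal(fit$breakpoint, 1.5, tolerance = 1e-6)
  expect_equal(unname(coef(fit)[c("slope_low", "slope_high", "intercept")]),
               c(2, 0.5, 1), tolerance = 1e-6)
  expect_equal(fit$r_squared$total, 1, tolerance = 1e-9)
})

test_that("iterative fit matches the exhaustive grid-search oracle", {
  for (seed in 1:4) {
    set.seed(seed)
    n <- 120
    bp_true <- runif(1, 0.5, 2.5)
    x <- runif(n, 0, 3.5)
    y <- 0.3 + 5 * x + (runif(1, -4, -1) - 5) * pmax(0, x - bp_true) +
      rnorm(n, 0, 0.4)
    fit <- fit_segmented(x, y, bootstrap = 0)
    oracle <- grid_segfit_oracle(x, y)
    expect_equal(fit$breakpoint, oracle$bp, tolerance = 2e-3)
    expect_lte(fit$rss, oracle$rss + 1e-8)  # refinement at least as good
    expect_equal(coef(fit)[["slope_low"]], oracle$a_low, tolerance = 1e-2)
  }
})

test_that("an exact straight line falls back to the linear fit", {
  x <- seq(0, 5, length.out = 40)
  y <- x
  fit <- fit_segmented(x, y, bootstrap = 0)
  expect_false(fit$kink)
  expect_true(is.na(fit$breakpoint))
  expect_equal(coef(fit)[["slope_low"]], 1, tolerance = 1e-10)
  # noisy straight line: still no kink claimed
  set.seed(2)
  fit2 <- fit_segmented(x, x + rnorm(40, 0, 0.3), bootstrap = 0)
  expect_false(fit2$kink)
})

test_that("the segmented fit never increases RSS over the linear fit", {
  for (seed in 1:10) {
    set.seed(seed)
    x <- rlnorm(60, 0, 0.8)
    y <- 0.5 + 0.7 * x + rnorm(60, 0, 1)
    fit <- fit_segmented(x, y, bootstrap = 0, test = FALSE)
    rss_lin <- sum(resid(lm(y ~ x))^2)
    expect_lte(fit$rss, rss_lin + 1e-10)
  }
})

test_that("bootstrap SE(BP) is reproducible under a fixed seed", {
  d <- simulate_coupling_rois(n = 200, seed = 5)
  f1 <- fit_segmented(d$ape13c, d$ape15n, bootstrap = 59L, seed = 42)
  f2 <- fit_segmented(d$ape13c, d$ape15n, bootstrap = 59L, seed = 42)
  expect_identical(f1$se_bp, f2$se_bp)
  expect_identical(f1$bootstrap_breakpoints, f2$bootstrap_breakpoints)
  expect_true(is.finite(f1$se_bp) && f1$se_bp > 0)
})

test_that("preconditions are enforced", {
  expect_error(fit_segmented(1:5, 1:5), "at least 8")
  expect_error(fit_segmented(rep(c(1, 2), 5), rnorm(10)), "5 distinct")
})

test_that("methods behave coherently", {
  d <- simulate_coupling_rois(n = 300, seed = 9)
  fit <- fit_segmented(d$ape13c, d$ape15n, bootstrap = 0)
  expect_equal(predict(fit), fitted(fit))
  expect_equal(fitted(fit) + residuals(fit), d$ape15n[order(seq_along(d$ape15n))],
               ignore_attr = TRUE)
  expect_named(coef(fit), c("intercept", "slope_low", "slope_high", "breakpoint"))
  # prediction is continuous at the breakpoint
  eps <- 1e-9
  expect_equal(predict(fit, fit$breakpoint - eps),
               predict(fit, fit$breakpoint + eps), tolerance = 1e-6)
  sims <- simulate(fit, nsim = 3, seed = 1)
  expect_identical(dim(sims), c(fit$n, 3L))
  expect_s3_class(summary(fit), "summary.segfit")
  expect_output(print(fit), "breakpoint")
  ll <- logLik(fit)
  expect_identical(attr(ll, "df"), 5)
})

test_that("model selection identifies the generating model family", {
  set.seed(11)
  # straight line, n = 500 -> linear wins
  x <- runif(500, 0.5, 4)
  y <- 1 + 2 * x + rnorm(500, 0, 0.5)
  expect_identical(select_model(x, y, "BIC")$selected, "linear")
  # pronounced kink -> segmented wins
  d <- simulate_coupling_rois(n = 500, seed = 12)
  ms <- select_model(d$ape13c, d$ape15n)
  expect_identical(ms$selected, "segmented")
  # the selected model attains the minimum of the criterion
  expect_equal(min(ms$table$AIC, na.rm = TRUE),
               ms$table$AIC[ms$table$model == ms$selected])
})

test_that("log-x saturation data selects log-x in >= 95% of seeded draws", {
  hits <- vapply(1:100, function(seed) {
    set.seed(seed)
    x <- runif(200, 0.2, 5)
    y <- 1 + 2 * log(x) + rnorm(200, 0, 0.35)
    select_model(x, y)$selected == "log-x"
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("log candidates are excluded with a note when data forbid them", {
  set.seed(13)
  x <- c(-1, runif(40, 0, 2))
  y <- 1 + x + rnorm(41, 0, 0.2)
  ms <- select_model(x, y)
  tab <- ms$table
  expect_match(tab$note[tab$model == "log-x"], "excluded")
  expect_true(is.na(tab$AIC[tab$model == "log-x"]))
  # y has negatives too after noise? force it
  y2 <- y - 5
  ms2 <- select_model(x, y2)
  expect_match(ms2$table$note[ms2$table$model == "log-y"], "excluded")
})

test_that("Jacobian correction changes comparability, not the transformed fit", {
  d <- simulate_coupling_rois(n = 300, seed = 14)
  x <- d$ape13c; y <- d$ape15n - min(d$ape15n) + 0.1
  with_j <- select_model(x, y, jacobian = TRUE)$table
  no_j <- select_model(x, y, jacobian = FALSE)$table
  # uncorrected columns agree between the two runs
  expect_equal(with_j$AIC_uncorrected, no_j$AIC_uncorrected)
  # corrected and uncorrected differ for the log-response candidates
  ly <- with_j$model == "log-y"
  expect_false(isTRUE(all.equal(with_j$AIC[ly], with_j$AIC_uncorrected[ly])))
})

test_that("a single large fit recovers the published fungal cell-wall model", {
  d <- simulate_coupling_rois(seed = 77)  # n = 1118, Table-2 operating point
  fit <- fit_segmented(d$ape13c, d$ape15n, bootstrap = 0)
  expect_true(fit$kink)
  expect_lt(abs(fit$breakpoint - 1.93), 0.4)
  expect_lt(abs(coef(fit)[["slope_low"]] - 7.77), 1)
  expect_equal(fit$r_squared$total, 0.65, tolerance = 0.1)
})
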