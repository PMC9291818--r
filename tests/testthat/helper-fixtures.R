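# In-code fixtures and independent oracles used across the suite.

# full ion stack with all-zero species images except the given overrides
make_stack <- function(..., nrow = 2, ncol = 2, pixel_size_um = 70 / 512,
                       dwell_ms = 13.5, planes = 1L) {
  over <- list(...)
  mats <- Filter(is.matrix, over)
  if (length(mats) > 0L) {  # infer canvas shape from the first matrix override
    nrow <- base::nrow(mats[[1L]])
    ncol <- base::ncol(mats[[1L]])
  }
  counts <- stats::setNames(lapply(ion_species(), function(sp) {
    if (!is.null(over[[sp]])) {
      m <- over[[sp]]
      if (!is.matrix(m)) m <- matrix(m, nrow, ncol)
      m
    } else matrix(0, nrow, ncol)
  }), ion_species())
  ion_count_stack(counts, pixel_size_um = pixel_size_um, dwell_ms = dwell_ms,
                  planes = planes)
}

# random stack of Poisson counts (for algebraic identity checks)
random_stack <- function(n = 8, lambda = 200, seed = 1) {
  set.seed(seed)
  counts <- stats::setNames(lapply(ion_species(), function(sp)
    matrix(rpois(n * n, lambda), n, n)), ion_species())
  ion_count_stack(counts, pixel_size_um = 70 / 512)
}

# brute-force Spearman rank correlation: mid-ranks by counting, then the
# explicit product-moment formula on the ranks (independent of rank()/cor())
brute_spearman <- function(x, y) {
  midrank <- function(v) {
    vapply(v, function(vi) sum(v < vi) + (sum(v == vi) + 1) / 2, numeric(1))
  }
  rx <- midrank(x); ry <- midrank(y)
  mx <- sum(rx) / length(rx); my <- sum(ry) / length(ry)
  sum((rx - mx) * (ry - my)) /
    sqrt(sum((rx - mx)^2) * sum((ry - my)^2))
}

# exhaustive-grid segmented-fit oracle: profile RSS minimised over a fine
# breakpoint grid using lm(), independent of the package's fitting path
grid_segfit_oracle <- function(x, y, grid_n = 4000,
                               quantiles = c(0.05, 0.95)) {
  lo <- quantile(x, quantiles[1], names = FALSE)
  hi <- quantile(x, quantiles[2], names = FALSE)
  grid <- seq(lo, hi, length.out = grid_n)
  rss <- vapply(grid, function(bp) {
    sum(resid(lm(y ~ x + pmax(0, x - bp)))^2)
  }, numeric(1))
  bp <- grid[which.min(rss)]
  fit <- lm(y ~ x + pmax(0, x - bp))
  list(bp = bp, intercept = unname(coef(fit)[1]),
       a_low = unname(coef(fit)[2]),
       a_high = unname(coef(fit)[2] + coef(fit)[3]),
       rss = min(rss))
}

# small structured scene + mosaic used by several tests
small_pipeline_inputs <- function(seed = 3, artifact = FALSE, canvas = 168,
                                  tile_px = 96, overlap_px = 24) {
  cfg <- scene_config(canvas_px = canvas, seed = seed,
                      adsorption = list(enabled = artifact, depth = 3 / 7,
                                        natural_at15n = 0.366))
  truth <- generate_root_tip_scene(cfg)
  layout <- mosaic_layout(2, 2, tile_px = tile_px, overlap_px = overlap_px,
                          pixel_size_um = 70 / 512)
  tiles <- simulate_counts(truth, layout, seed = seed + 5000)
  mosaic <- assemble_mosaic(tiles, layout)
  list(truth = truth, layout = layout, tiles = tiles, mosaic = mosaic,
       control = control_reference(1.07, 0.37))
}
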