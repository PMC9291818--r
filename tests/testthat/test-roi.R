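# ROI quantification: ratio-of-sums estimator, merge additivity, tissue
# summaries and the bulk arithmetic (mixing, molarity, excess mass).

test_that("ROI over a uniform field equals the per-pixel at%", {
  s <- make_stack(`12C14N` = matrix(900, 4, 4), `12C15N` = matrix(100, 4, 4),
                  `12C12C` = matrix(800, 4, 4), `13C12C` = matrix(16, 4, 4),
                  nrow = 4, ncol = 4)
  lab <- matrix(1, 4, 4)
  rs <- roi_set(lab, data.frame(id = 1, tissue = "PC", compartment = "L"))
  tab <- roi_composition(s, rs, control_reference(1.07, 0.37))
  expect_equal(tab$at15n, 10)
  expect_equal(tab$at13c, 100 * 16 / (2 * 800 + 16))
  expect_equal(tab$ape15n, 10 - 0.37)
})

test_that("ratio-of-sums and mean-of-ratios differ exactly as hand-computed", {
  # pixels (15N, 14N): symmetric case agrees at 50 at%
  s1 <- make_stack(`12C15N` = matrix(c(0, 100), 1, 2),
                   `12C14N` = matrix(c(100, 0), 1, 2),
                   `12C12C` = matrix(100, 1, 2), nrow = 1, ncol = 2)
  lab <- matrix(1, 1, 2)
  rs <- roi_set(lab, data.frame(id = 1, tissue = "HE", compartment = "CW"))
  ctrl <- control_reference(1.07, 0.37)
  expect_equal(roi_composition(s1, rs, ctrl)$at15n, 50)
  expect_equal(roi_composition(s1, rs, ctrl, "mean_of_ratios")$at15n, 50)
  # asymmetric case distinguishes the estimators: (10,90) & (90,110)
  s2 <- make_stack(`12C15N` = matrix(c(10, 90), 1, 2),
                   `12C14N` = matrix(c(90, 110), 1, 2),
                   `12C12C` = matrix(100, 1, 2), nrow = 1, ncol = 2)
  expect_equal(roi_composition(s2, rs, ctrl)$at15n, 100 * 100 / 300,
               tolerance = 1e-12)                              # 33.33 at%
  expect_equal(roi_composition(s2, rs, ctrl, "mean_of_ratios")$at15n,
               mean(c(10 / 100, 90 / 200)) * 100)               # 27.5 at%
})

test_that("merging two ROIs equals pooling their summed intensities", {
  inp <- small_pipeline_inputs(seed = 23, canvas = 70, tile_px = 40,
                               overlap_px = 10)
  rois <- labels_to_roi_set(inp$truth)
  # merge the two largest ROIs of the same class into one
  tab0 <- roi_composition(inp$mosaic$canvas, rois, inp$control)
  cls <- paste(tab0$tissue, tab0$compartment)
  big <- names(sort(table(cls[duplicated(cls) | duplicated(cls, fromLast = TRUE)]),
                    decreasing = TRUE))[1]
  ids <- tab0$id[cls == big][1:2]
  merged_lab <- rois$labels
  merged_lab[merged_lab == ids[2]] <- ids[1]
  ann <- rois$annotations[rois$annotations$id != ids[2], ]
  merged <- roi_set(merged_lab, ann)
  tabm <- roi_composition(inp$mosaic$canvas, merged, inp$control)
  a <- tab0[tab0$id %in% ids, ]
  m <- tabm[tabm$id == ids[1], ]
  expect_equal(m$n_px, sum(a$n_px))
  s15 <- sum(a$mean_12c15n * a$n_px); s14 <- sum(a$mean_12c14n * a$n_px)
  expect_equal(m$at15n, 100 * s15 / (s15 + s14), tolerance = 1e-12)
  s13 <- sum(a$mean_13c12c * a$n_px); s12 <- sum(a$mean_12c12c * a$n_px)
  expect_equal(m$at13c, 100 * s13 / (2 * s12 + s13), tolerance = 1e-12)
})

test_that("an ROI over a uniform simulated field recovers p15N within 3 SE", {
  tr <- uniform_scene_truth(canvas_px = 60, p_n = 0.05)
  lay <- mosaic_layout(1, 1, tile_px = 60, overlap_px = 0,
                       pixel_size_um = 70 / 512)
  tile <- simulate_counts(tr, lay, seed = 6)[[1]]
  lab <- matrix(1, 60, 60)
  rs <- roi_set(lab, data.frame(id = 1, tissue = "HE", compartment = "CW"))
  tab <- roi_composition(tile, rs, control_reference(1.07, 0.37))
  # Poisson SE of the pooled ratio
  s15 <- tab$mean_12c15n * tab$n_px; s14 <- tab$mean_12c14n * tab$n_px
  se <- 100 * sqrt(s14 * s15 / (s14 + s15)^3)
  expect_lt(abs(tab$at15n - 5), 3 * se)
})

test_that("tissue summary reproduces hand-computed statistics", {
  tab <- data.frame(id = 1:4,
                    tissue = c("HE", "HE", "HE", "PC"),
                    compartment = c("CW", "CW", "CW", "L"),
                    at13c = c(1, 2, 3, 1.5), at15n = c(2, 4, 6, 1),
                    stringsAsFactors = FALSE)
  class(tab) <- c("roi_table", "data.frame")
  ts <- tissue_summary(tab)
  he <- ts[ts$tissue == "HE", ]
  expect_equal(he$n, 3L)
  expect_equal(he$mean_at13c, 2)
  expect_equal(he$rsd_at13c, 0.5)   # sample SD 1 over mean 2
  expect_equal(he$min_at13c, 1)
  expect_equal(he$max_at13c, 3)
  pc <- ts[ts$tissue == "PC", ]     # degenerate single-ROI group
  expect_equal(pc$rsd_at13c, 0)
  expect_true(pc$rsd_degenerate)
  expect_equal(pc$min_at13c, pc$max_at13c)
  # min <= mean <= max everywhere
  expect_true(all(ts$min_at15n <= ts$mean_at15n & ts$mean_at15n <= ts$max_at15n))
})

test_that("summary of a simulated scene covers the configured 6 x 2 classes", {
  inp <- small_pipeline_inputs(seed = 3)
  tab <- roi_composition(inp$mosaic$canvas, labels_to_roi_set(inp$truth),
                         inp$control)
  ts <- tissue_summary(tab)
  expect_identical(nrow(ts), 12L)
  expect_setequal(unique(ts$tissue), tissue_classes())
  expect_setequal(unique(ts$compartment), compartment_classes())
})

test_that("mixing fraction reproduces the one-fifth replacement arithmetic", {
  f <- mixing_fraction(20, 99, 0.37)
  expect_equal(f, (20 - 0.37) / (99 - 0.37))
  expect_equal(f, 0.199, tolerance = 0.001)
  expect_equal(mixing_fraction(0.37, 99, 0.37), 0)
  expect_equal(mixing_fraction(99, 99, 0.37), 1)
  expect_error(mixing_fraction(5, 1, 1), "undefined")
  expect_warning(out <- mixing_fraction(100, 99, 0.37), "clamped")
  expect_equal(out, 1)
  # strictly increasing in the observed value
  obs <- seq(0.5, 98, length.out = 50)
  expect_true(all(diff(mixing_fraction(obs, 99, 0.37)) > 0))
})

test_that("solution molarity matches the labelling-solution arithmetic", {
  # 98 at% 15NH4Cl at 54.5 mg/l -> ~1 mM N (isotope-weighted M ~ 54.47 g/mol)
  m <- solution_molarity(54.5, "NH4Cl", label_at = 98)
  expect_equal(m, 1, tolerance = 0.01)
  # amino-acid mix: 140 mg/l at an assumed 140 g/mol with 1 N per molecule
  expect_equal(solution_molarity(140, molar_mass = 140, n_nitrogen = 1), 1)
  expect_equal(solution_molarity(0, "NH4Cl", label_at = 98), 0)
  # isotope weighting matters: unlabelled NH4Cl gives a lower molarity
  expect_lt(m, solution_molarity(54.5, "NH4Cl", label_at = 0.366))
  expect_error(solution_molarity(10, "XqZ2"), "unknown element")
  expect_error(solution_molarity(10, "C6H12O6"), "no nitrogen")
})

test_that("excess 15N mass is linear and conventions differ by 15/M_N", {
  expect_equal(as.numeric(excess_15n_mass(0, 100)), 0)
  one <- excess_15n_mass(2, 100)
  expect_equal(as.numeric(excess_15n_mass(2, 200)), 2 * as.numeric(one))
  atom <- as.numeric(excess_15n_mass(3, 50, "atom"))
  mass <- as.numeric(excess_15n_mass(3, 50, "mass"))
  expect_equal(atom / mass, 15.0001089 / 14.0067, tolerance = 1e-9)
  expect_error(excess_15n_mass(-1, 10), ">= 0")
})
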