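# Synthetic ground-truth scenes: a stylised mycorrhizal root-tip cross-section
# (concentric tissue rings around a vascular core, a cell lattice separating
# cell walls from lumina, and external hyphae scattered outside the mantle)
# with per-cell 13C/15N enrichment drawn from a biphasically coupled model,
# plus Poisson simulation of the secondary-ion count tiles acquired over it.

TISSUE_LEVELS <- c("VT", "E", "PC", "HN", "HM", "HE")  # label codes 1..6
COMPARTMENT_LEVELS <- c("CW", "L")                     # compartment codes 1..2

with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit(if (is.null(old)) rm(".Random.seed", envir = globalenv())
            else assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
  }
  expr
}

#' Default per-tissue enrichment model
#'
#' @return Data frame with one row per tissue class; see [scene_config()].
#' @export
default_enrichment <- function() {
  # Per-tissue biphasic coupling of APE15N on APE13C (breakpoint, low/high
  # slopes, intercept, cell-to-cell noise SD) and the lognormal APE13C driving
  # distribution. Magnitudes follow the published cell-wall coupling of each
  # tissue class; the driving distributions are right-skewed with most cells
  # only slightly enriched.
  data.frame(
    tissue    = c("HE", "HM", "HN", "PC", "E", "VT"),
    x_meanlog = log(c(0.15, 0.07, 0.12, 0.05, 0.06, 0.25)),
    x_sdlog   = c(1.30, 0.80, 0.90, 0.80, 0.90, 1.00),
    bp        = c(1.49, 0.111, 0.13, 0.311, 0.33, 1.283),
    a_low     = c(8.86, 21.42, 12.13, 13.54, 21.95, 1.12),
    a_high    = c(0.0, 0.0, 2.54, 0.0, 0.0, 0.0),
    intercept = c(0.3, 0.3, 0.3, 0.2, 0.2, 0.3),
    noise_sd  = c(1.0, 0.8, 0.8, 0.5, 0.5, 0.4),
    stringsAsFactors = FALSE)
}

#' Configuration of a synthetic root-tip scene
#'
#' Describes the stylised cross-section geometry (concentric rings: vascular
#' core, endodermis, cortex, Hartig net, mantle; external hyphae outside the
#' mantle), the per-tissue biphasic enrichment model, the acquisition
#' constants and the optional N2-adsorption artifact.
#'
#' @param canvas_px Canvas side length in pixels (square canvas).
#' @param pixel_size_um Micrometres per pixel; default 70/512 (a 70 um field
#'   imaged at 512 x 512 px).
#' @param radii Named numeric, strictly increasing fractions of the half-canvas
#'   giving the outer radius of `vt`, `e`, `pc`, `hn`, `hm`. Must not exceed 1.
#' @param wall_frac Fraction of a cell's half-size occupied by cell wall.
#' @param cell_px Named integer, lattice cell size (px) per ring tissue.
#' @param hyphae List: `n` (count), `radius_px`, `radius_sd` (hyphal
#'   cross-section radius distribution), `max_dist_frac` (outer placement
#'   limit as fraction of the half-canvas).
#' @param enrichment Data frame as [default_enrichment()]: per-tissue
#'   `x_meanlog`, `x_sdlog` (lognormal APE13C draw), `bp`, `a_low`, `a_high`,
#'   `intercept` (biphasic APE15N response) and `noise_sd`.
#' @param hotspot List: `fraction` of external hyphae that are enrichment
#'   hot-spots and the lognormal multiplier (`meanlog`, `sdlog`) applied to
#'   their APE13C draw.
#' @param pattern_mix Fraction of external hyphae carrying the
#'   "wall-co-located" high-enrichment radial pattern; the remainder carry the
#'   "centre-15N" pattern (15N peaked in the lumen, little 13C).
#' @param acquisition List of species yields in counts/pixel/ms (`c_rate`,
#'   `c2_rate`, `cn_rate`, `p_rate_plant`, `p_rate_fungus`, `se_rate`), the
#'   lumen density factor `lumen_factor`, `dwell_ms` and `planes`.
#' @param adsorption List: `enabled`, `depth` (adsorbed-CN rate as a fraction
#'   of the native CN rate in re-measured areas) and `natural_at15n`.
#' @param natural Named numeric: baseline (natural-abundance) at%13C and
#'   at%15N of unlabelled tissue.
#' @param seed RNG seed.
#' @return Object of class `scene_config`.
#' @export
scene_config <- function(canvas_px = 512,
                         pixel_size_um = 70 / 512,
                         radii = c(vt = 0.17, e = 0.22, pc = 0.40, hn = 0.46, hm = 0.55),
                         wall_frac = 0.35,
                         cell_px = c(vt = 10, e = 8, pc = 16, hn = 5, hm = 6),
                         hyphae = list(n = 60, radius_px = 5, radius_sd = 1.5,
                                       max_dist_frac = 0.98),
                         enrichment = default_enrichment(),
                         hotspot = list(fraction = 0.05, meanlog = log(8), sdlog = 0.5),
                         pattern_mix = 0.25,
                         acquisition = list(c_rate = 2, c2_rate = 4, cn_rate = 20,
                                            p_rate_plant = 0.6, p_rate_fungus = 0.1,
                                            se_rate = 2, lumen_factor = 0.5,
                                            dwell_ms = 13.5, planes = 1L),
                         adsorption = list(enabled = FALSE, depth = 3 / 7,
                                           natural_at15n = 0.366),
                         natural = c(at13c = 1.07, at15n = 0.37),
                         seed = 1L) {
  cfg <- structure(as.list(environment()), class = "scene_config")
  validate_scene_config(cfg)
  cfg
}

validate_scene_config <- function(cfg) {
  need_r <- c("vt", "e", "pc", "hn", "hm")
  if (!all(need_r %in% names(cfg$radii)))
    stop("radii must name ", paste(need_r, collapse = ", "))
  r <- cfg$radii[need_r]
  if (any(diff(r) <= 0)) {
    bad <- need_r[which(diff(r) <= 0)[1L] + 1L]
    stop("tissue radii must be strictly increasing; radius '", bad,
         "' does not exceed the ring inside it")
  }
  if (any(r > 1)) {
    bad <- need_r[which(r > 1)[1L]]
    stop("radius '", bad, "' does not fit the canvas (fraction > 1)")
  }
  if (cfg$canvas_px < 16) stop("canvas_px too small")
  if (cfg$pattern_mix < 0 || cfg$pattern_mix > 1)
    stop("pattern_mix must lie in [0, 1]")
  if (cfg$hotspot$fraction < 0 || cfg$hotspot$fraction > 1)
    stop("hotspot fraction must lie in [0, 1]")
  acq <- cfg$acquisition
  if (any(unlist(acq[c("c_rate", "c2_rate", "cn_rate", "se_rate",
                       "dwell_ms")]) < 0))
    stop("acquisition yields and dwell must be >= 0")
  if (cfg$adsorption$depth < 0) stop("adsorption depth must be >= 0")
  invisible(cfg)
}

biphasic <- function(x, bp, a_low, a_high, intercept) {
  intercept + a_low * x + (a_high - a_low) * pmax(0, x - bp)
}

#' Generate a ground-truth root-tip scene
#'
#' Builds the tissue label image, the cell-wall/lumen compartment image, a
#' per-cell id map, and the true per-pixel atom-fraction fields p13C and p15N
#' together with the elemental (C2 and CN) emission-rate fields. Deterministic
#' for a fixed `config$seed`.
#'
#' @param config A [scene_config()].
#' @return Object of class `scene_truth` with elements `label` (0 =
#'   background, codes per `TISSUE_LEVELS`), `compartment` (0/1/2 =
#'   none/CW/L), `cell` (per-cell integer ids), `p_c`, `p_n` (atom fractions
#'   in `[0, 1]`), `ape13c`, `ape15n` (the generating APE fields, at%),
#'   `c2_rate`, `cn_rate` (counts/px/ms), `structure_factor`, `hyphae`
#'   (placement and pattern table) and `config`.
#' @export
generate_root_tip_scene <- function(config = scene_config()) {
  validate_scene_config(config)
  with_seed(config$seed, {
    n <- config$canvas_px
    half <- n / 2
    centre <- (n + 1) / 2
    ri <- matrix(seq_len(n), n, n)
    ci <- matrix(seq_len(n), n, n, byrow = TRUE)
    dist <- sqrt((ri - centre)^2 + (ci - centre)^2)

    r_px <- config$radii * half
    label <- matrix(0L, n, n)
    label[dist <= r_px["hm"]] <- 5L  # HM
    label[dist <= r_px["hn"]] <- 4L  # HN
    label[dist <= r_px["pc"]] <- 3L  # PC
    label[dist <= r_px["e"]]  <- 2L  # E
    label[dist <= r_px["vt"]] <- 1L  # VT

    compartment <- matrix(0L, n, n)
    cell <- matrix(0, n, n)
    ring_cells <- c(vt = 1L, e = 2L, pc = 3L, hn = 4L, hm = 5L)
    for (t_idx in seq_along(ring_cells)) {
      sel <- label == t_idx
      if (!any(sel)) next
      cs <- config$cell_px[[names(ring_cells)[t_idx]]]
      w <- max(1L, as.integer(round(config$wall_frac * cs / 2)))
      off <- 3L * t_idx  # decorrelate lattices across rings
      is_wall <- ((ri + off) %% cs) < w | ((ci + off) %% cs) < w
      compartment[sel] <- ifelse(is_wall[sel], 1L, 2L)
      cell_id <- t_idx * 1e6 + ((ri + off) %/% cs) * 1e3 + ((ci + off) %/% cs) + 1
      cell[sel] <- cell_id[sel]
    }

    # external hyphae: annular wall + disc lumen, outside the mantle
    n_hy <- config$hyphae$n
    hy <- data.frame(id = integer(0), row = numeric(0), col = numeric(0),
                     radius = numeric(0), pattern = character(0),
                     hotspot = logical(0), stringsAsFactors = FALSE)
    if (n_hy > 0) {
      placed <- 0L
      max_r <- config$hyphae$max_dist_frac * half
      rows <- cols <- rads <- numeric(n_hy)
      for (k in seq_len(n_hy)) {
        hr <- max(2, round(stats::rnorm(1, config$hyphae$radius_px,
                                        config$hyphae$radius_sd)))
        ok <- FALSE
        if (r_px[["hm"]] + hr + 1 >= max_r - hr) next  # cannot fit this radius
        for (try in 1:40) {
          ang <- stats::runif(1, 0, 2 * pi)
          dd <- stats::runif(1, r_px["hm"] + hr + 1, max_r - hr)
          if (dd <= r_px["hm"] + hr) next
          y <- centre + dd * sin(ang); x <- centre + dd * cos(ang)
          if (y - hr < 1 || y + hr > n || x - hr < 1 || x + hr > n) next
          if (placed > 0L &&
              any(sqrt((rows[seq_len(placed)] - y)^2 +
                       (cols[seq_len(placed)] - x)^2) <
                  (rads[seq_len(placed)] + hr + 1))) next
          ok <- TRUE
          break
        }
        if (!ok) next
        placed <- placed + 1L
        rows[placed] <- y; cols[placed] <- x; rads[placed] <- hr
      }
      if (placed > 0L) {
        pattern <- ifelse(stats::runif(placed) < config$pattern_mix,
                          "wall", "centre")
        hot <- stats::runif(placed) < config$hotspot$fraction
        hy <- data.frame(id = seq_len(placed), row = rows[seq_len(placed)],
                         col = cols[seq_len(placed)], radius = rads[seq_len(placed)],
                         pattern = pattern, hotspot = hot, stringsAsFactors = FALSE)
        for (k in seq_len(placed)) {
          d_k <- sqrt((ri - hy$row[k])^2 + (ci - hy$col[k])^2)
          sel <- d_k <= hy$radius[k] & label == 0L
          label[sel] <- 6L  # HE
          wall_r <- hy$radius[k] * (1 - config$wall_frac)
          compartment[sel] <- ifelse(d_k[sel] > wall_r, 1L, 2L)
          cell[sel] <- 1e7 + k
        }
      }
    }

    # per-cell enrichment draws under the tissue's biphasic coupling
    x_img <- matrix(0, n, n)  # APE13C
    y_img <- matrix(0, n, n)  # APE15N
    enr <- config$enrichment
    for (t_idx in 1:5) {
      sel <- label == t_idx
      if (!any(sel)) next
      pars <- enr[enr$tissue == TISSUE_LEVELS[t_idx], ]
      ids <- sort(unique(cell[sel]))
      x_cell <- stats::rlnorm(length(ids), pars$x_meanlog, pars$x_sdlog)
      y_cell <- biphasic(x_cell, pars$bp, pars$a_low, pars$a_high, pars$intercept) +
        stats::rnorm(length(ids), 0, pars$noise_sd)
      idx <- match(cell[sel], ids)
      x_img[sel] <- x_cell[idx]
      y_img[sel] <- y_cell[idx]
    }
    if (nrow(hy) > 0L) {
      pars <- enr[enr$tissue == "HE", ]
      for (k in seq_len(nrow(hy))) {
        sel <- cell == (1e7 + k)
        if (!any(sel)) next
        x_k <- stats::rlnorm(1, pars$x_meanlog, pars$x_sdlog)
        if (hy$hotspot[k])
          x_k <- x_k * stats::rlnorm(1, config$hotspot$meanlog, config$hotspot$sdlog)
        cw <- sel & compartment == 1L
        lu <- sel & compartment == 2L
        if (hy$pattern[k] == "wall") {
          # high enrichment, 13C and 15N co-located in the outer ring
          y_k <- biphasic(x_k, pars$bp, pars$a_low, pars$a_high, pars$intercept) +
            stats::rnorm(1, 0, pars$noise_sd)
          x_img[cw] <- x_k;        y_img[cw] <- y_k
          x_img[lu] <- 0.35 * x_k; y_img[lu] <- 0.35 * y_k
        } else {
          # low enrichment, 15N peaked in the hyphal centre, almost no 13C
          x_c <- 0.2 * x_k
          y_k <- biphasic(x_c, pars$bp, pars$a_low, pars$a_high, pars$intercept) +
            stats::rnorm(1, 0, pars$noise_sd)
          x_img[cw] <- 0.3 * x_c; y_img[cw] <- 0.3 * y_k
          x_img[lu] <- 0.1 * x_c; y_img[lu] <- y_k
        }
      }
    }
    x_img[label == 0L] <- 0
    y_img[label == 0L] <- 0
    y_img <- pmax(y_img, -config$natural["at15n"])  # atom fraction floor at 0

    p_c <- pmin(pmax((config$natural[["at13c"]] + x_img) / 100, 0), 1)
    p_n <- pmin(pmax((config$natural[["at15n"]] + y_img) / 100, 0), 1)
    p_c[label == 0L] <- 0
    p_n[label == 0L] <- 0

    factor <- matrix(0, n, n)
    factor[compartment == 1L] <- 1
    factor[compartment == 2L] <- config$acquisition$lumen_factor

    structure(list(label = label, compartment = compartment, cell = cell,
                   p_c = p_c, p_n = p_n, ape13c = x_img, ape15n = y_img,
                   c2_rate = config$acquisition$c2_rate * factor,
                   cn_rate = config$acquisition$cn_rate * factor,
                   structure_factor = factor, hyphae = hy, config = config),
              class = "scene_truth")
  })
}

#' @export
print.scene_truth <- function(x, ...) {
  n <- nrow(x$label)
  cat(sprintf("<scene_truth> %d x %d px, %.4g um/px, seed %d\n",
              n, n, x$config$pixel_size_um, x$config$seed))
  tab <- table(factor(x$label, levels = 0:6,
                      labels = c("background", TISSUE_LEVELS)))
  print(round(tab / n^2, 3))
  invisible(x)
}

#' Simulate secondary-ion count tiles from a ground-truth scene
#'
#' Draws per-pixel, per-species counts independently: the C2- species by
#' binomial atom pairing from p13C (12C12C ~ (1-p)^2, 13C12C ~ 2p(1-p)) scaled
#' by the C2 emission rate x dwell x planes; the CN- species by the p15N split
#' of the CN rate; monatomic carbon, 31P and secondary electrons from their
#' configured yields; Poisson sampling throughout. If the adsorption artifact
#' is enabled in the scene config, pixels of a tile already covered by an
#' earlier-acquired tile receive additional CN- counts at natural-abundance
#' p15N (depressing the measured at%15N there) unless the tile is flagged
#' pre-sputtered in the layout.
#'
#' @param truth A [generate_root_tip_scene()] result.
#' @param layout A [mosaic_layout()] whose canvas matches the scene canvas.
#' @param seed RNG seed; default derives from the scene seed.
#' @return List of [ion_count_stack()] tiles in row-major grid order.
#' @export
simulate_counts <- function(truth, layout, seed = truth$config$seed + 1000L) {
  stopifnot(inherits(truth, "scene_truth"), inherits(layout, "mosaic_layout"))
  cd <- canvas_dim(layout)
  if (!identical(cd, dim(truth$label)))
    stop(sprintf("truth/grid dimension mismatch: canvas %d x %d vs layout %d x %d",
                 nrow(truth$label), ncol(truth$label), cd[1L], cd[2L]))
  acq <- truth$config$acquisition
  ads <- truth$config$adsorption
  exposure <- acq$dwell_ms * acq$planes
  p_nat <- ads$natural_at15n / 100
  with_seed(seed, {
    lapply(seq_len(layout$nrow * layout$ncol), function(k) {
      fp <- tile_footprint(layout, k)
      rows <- fp[1L]:fp[2L]; cols <- fp[3L]:fp[4L]
      p <- truth$p_c[rows, cols]
      q <- truth$p_n[rows, cols]
      lam_c2 <- truth$c2_rate[rows, cols] * exposure
      lam_cn <- truth$cn_rate[rows, cols] * exposure
      fac <- truth$structure_factor[rows, cols]
      lam_c <- acq$c_rate * fac * exposure
      lab <- truth$label[rows, cols]
      p_yield <- ifelse(lab %in% 1:3, acq$p_rate_plant,
                        ifelse(lab %in% 4:6, acq$p_rate_fungus, 0))
      lam_p <- p_yield * fac * exposure
      lam_se <- acq$se_rate * exposure * pmax(fac, 0.05)
      d <- dim(p)
      draw <- function(lam) matrix(stats::rpois(length(lam), lam), d[1L], d[2L])
      n14 <- draw(lam_cn * (1 - q))
      n15 <- draw(lam_cn * q)
      if (isTRUE(ads$enabled) && !layout$pre_sputtered[k]) {
        prev <- covered_by_earlier(layout, k)[rows - fp[1L] + 1L, cols - fp[3L] + 1L,
                                              drop = FALSE]
        lam_ads <- ads$depth * lam_cn * prev
        n14 <- n14 + draw(lam_ads * (1 - p_nat))
        n15 <- n15 + draw(lam_ads * p_nat)
      }
      counts <- list(
        "12C" = draw(lam_c * (1 - p)),
        "13C" = draw(lam_c * p),
        "12C12C" = draw(lam_c2 * (1 - p)^2),
        "13C12C" = draw(lam_c2 * 2 * p * (1 - p)),
        "12C14N" = n14,
        "12C15N" = n15,
        "31P" = draw(lam_p),
        "SE" = draw(lam_se))
      ion_count_stack(counts,
                      pixel_size_um = layout$pixel_size_um,
                      dwell_ms = acq$dwell_ms, planes = acq$planes,
                      stage_offset_um = c((fp[3L] - 1L), (fp[1L] - 1L)) *
                        layout$pixel_size_um,
                      pre_sputtered = layout$pre_sputtered[k],
                      order = layout$order[k],
                      id = sprintf("tile_%02d", k))
    })
  })
}

#' Homogeneous calibration phantom
#'
#' A spatially uniform ground-truth scene: constant atom fractions and
#' emission rates over the whole canvas (one tissue class, all "cell wall").
#' Used to characterise the counting model and the adsorption-QC detector
#' free of biological structure, like a flat-field phantom.
#'
#' @param canvas_px Canvas side length (px).
#' @param p_c,p_n True 13C and 15N atom fractions (scalars in `[0, 1]`).
#' @param tissue Tissue class code assigned to every pixel.
#' @param config A [scene_config()] supplying acquisition and adsorption
#'   settings (its geometry fields are ignored).
#' @return A `scene_truth` with constant fields.
#' @export
uniform_scene_truth <- function(canvas_px = 128, p_c = 0.011, p_n = 0.05,
                                tissue = "HE", config = scene_config()) {
  n <- canvas_px
  code <- match(tissue, TISSUE_LEVELS)
  if (is.na(code)) stop("unknown tissue code: ", tissue)
  ones <- matrix(1, n, n)
  structure(list(label = matrix(code, n, n),
                 compartment = matrix(1L, n, n),
                 cell = ones,
                 p_c = ones * p_c, p_n = ones * p_n,
                 ape13c = ones * (100 * p_c - config$natural[["at13c"]]),
                 ape15n = ones * (100 * p_n - config$natural[["at15n"]]),
                 c2_rate = ones * config$acquisition$c2_rate,
                 cn_rate = ones * config$acquisition$cn_rate,
                 structure_factor = ones,
                 hyphae = data.frame(), config = config),
            class = "scene_truth")
}

#' Convert a ground-truth scene into a region-of-interest set
#'
#' Stands in for the manual ROI drawing of the original workflow: every
#' cell x compartment unit of the generator becomes one ROI, annotated with
#' its tissue class and compartment.
#'
#' @param truth A `scene_truth`.
#' @param min_px Drop ROIs smaller than this pixel count.
#' @return An [roi_set()] on the scene canvas.
#' @export
labels_to_roi_set <- function(truth, min_px = 3L) {
  sel <- truth$label > 0L & truth$compartment > 0L
  key <- paste(truth$cell[sel], truth$compartment[sel], sep = "/")
  ids <- match(key, sort(unique(key)))
  keep_tab <- tabulate(ids)
  keep <- keep_tab[ids] >= min_px
  labels <- matrix(0, nrow(truth$label), ncol(truth$label))
  dense <- match(ids[keep], sort(unique(ids[keep])))
  labels[which(sel)[keep]] <- dense
  first <- which(sel)[keep][!duplicated(dense)]
  ord <- order(dense[!duplicated(dense)])
  first <- first[ord]
  ann <- data.frame(id = seq_along(first),
                    tissue = TISSUE_LEVELS[truth$label[first]],
                    compartment = COMPARTMENT_LEVELS[truth$compartment[first]],
                    stringsAsFactors = FALSE)
  roi_set(labels, ann)
}
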