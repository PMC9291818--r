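# Mosaic geometry, tile stitching and the N2-adsorption QC screen.
#
# Overlapping acquisitions of the same area are not independent Poisson
# replicates once sputtering has altered the surface, so overlap pixels are
# resolved by the nearest-tile-centre rule (ties broken by acquisition order)
# rather than averaged or summed; non-overlap pixels are copied verbatim.

round_half_up <- function(x) floor(x + 0.5)

#' Mosaic layout of tile acquisitions
#'
#' Regular grid of square tiles with a fixed overlap. The overlap in pixels is
#' round-half-up of overlap_um / pixel size (recorded in the layout). The
#' published acquisition used 4 x 4 tiles of 512 px (70 um) with a 20 um
#' overlap, giving 146 overlap px and a 1610 px canvas; the total quoted there
#' as "200 x 200 um" is kept as metadata, not reconciled with the arithmetic.
#'
#' @param nrow,ncol Grid shape.
#' @param tile_px Tile side length in pixels.
#' @param overlap_um Overlap between adjacent tiles in micrometres.
#' @param pixel_size_um Micrometres per pixel.
#' @param overlap_px Overlap in pixels; default round-half-up of
#'   `overlap_um / pixel_size_um`.
#' @param order Integer permutation of `1:(nrow*ncol)` giving the acquisition
#'   rank of each row-major tile index; default row-major order.
#' @param pre_sputtered Logical vector (recycled) flagging tiles that were
#'   pre-sputtered before acquisition.
#' @return Object of class `mosaic_layout`.
#' @export
mosaic_layout <- function(nrow, ncol, tile_px = 512L, overlap_um = 20,
                          pixel_size_um = 70 / 512, overlap_px = NULL,
                          order = NULL, pre_sputtered = FALSE) {
  if (is.null(overlap_px)) overlap_px <- round_half_up(overlap_um / pixel_size_um)
  overlap_px <- as.integer(overlap_px)
  tile_px <- as.integer(tile_px)
  n <- nrow * ncol
  if (overlap_px < 0 || overlap_px >= tile_px)
    stop("overlap_px must lie in [0, tile_px)")
  if (is.null(order)) order <- seq_len(n)
  if (!identical(sort(order), seq_len(n)))
    stop("order must be a permutation of 1:(nrow*ncol)")
  structure(list(nrow = as.integer(nrow), ncol = as.integer(ncol),
                 tile_px = tile_px, overlap_px = overlap_px,
                 overlap_um = overlap_px * pixel_size_um,
                 pixel_size_um = pixel_size_um,
                 order = as.integer(order),
                 pre_sputtered = rep_len(pre_sputtered, n)),
            class = "mosaic_layout")
}

#' @export
print.mosaic_layout <- function(x, ...) {
  cd <- canvas_dim(x)
  cat(sprintf("<mosaic_layout> %d x %d tiles of %d px, overlap %d px (%.3g um); canvas %d x %d px (%.3g um)\n",
              x$nrow, x$ncol, x$tile_px, x$overlap_px, x$overlap_um,
              cd[1L], cd[2L], cd[1L] * x$pixel_size_um))
  invisible(x)
}

#' Canvas dimensions implied by a layout
#'
#' @param layout A [mosaic_layout()].
#' @return Integer length-2 (rows, cols).
#' @export
canvas_dim <- function(layout) {
  step <- layout$tile_px - layout$overlap_px
  c(layout$nrow * layout$tile_px - (layout$nrow - 1L) * layout$overlap_px,
    layout$ncol * layout$tile_px - (layout$ncol - 1L) * layout$overlap_px)
}

# canvas-pixel footprint (r0, r1, c0, c1) of row-major tile index k
tile_footprint <- function(layout, k) {
  step <- layout$tile_px - layout$overlap_px
  gr <- (k - 1L) %/% layout$ncol
  gc <- (k - 1L) %% layout$ncol
  r0 <- gr * step + 1L
  c0 <- gc * step + 1L
  c(r0, r0 + layout$tile_px - 1L, c0, c0 + layout$tile_px - 1L)
}

# logical tile-shaped mask of pixels already covered by earlier-acquired tiles
covered_by_earlier <- function(layout, k) {
  fp <- tile_footprint(layout, k)
  mask <- matrix(FALSE, layout$tile_px, layout$tile_px)
  for (u in seq_len(layout$nrow * layout$ncol)) {
    if (u == k || layout$order[u] >= layout$order[k]) next
    fu <- tile_footprint(layout, u)
    r0 <- max(fp[1L], fu[1L]); r1 <- min(fp[2L], fu[2L])
    c0 <- max(fp[3L], fu[3L]); c1 <- min(fp[4L], fu[4L])
    if (r0 <= r1 && c0 <= c1)
      mask[(r0:r1) - fp[1L] + 1L, (c0:c1) - fp[3L] + 1L] <- TRUE
  }
  mask
}

# per-axis nearest-band assignment with tie information
axis_bands <- function(n_bands, tile_px, overlap_px, n_px) {
  step <- tile_px - overlap_px
  centres <- (seq_len(n_bands) - 1L) * step + (tile_px + 1) / 2
  if (n_bands == 1L)
    return(list(band = rep(1L, n_px), tie = rep(FALSE, n_px)))
  mids <- (centres[-n_bands] + centres[-1L]) / 2
  i <- seq_len(n_px)
  band <- findInterval(i, mids, left.open = TRUE) + 1L  # tie -> lower band
  tie <- i %in% mids
  list(band = band, tie = tie)
}

#' Assemble tile stacks into a mosaic canvas
#'
#' Each canvas pixel takes its counts from exactly one source tile, the one
#' whose centre is nearest (ties broken toward the earlier-acquired tile); a
#' contribution map records the source tile per pixel. Counts outside overlap
#' regions are copied verbatim, so per-tile count sums are conserved.
#'
#' @param tiles List of [ion_count_stack()] in row-major grid order.
#' @param layout The [mosaic_layout()] the tiles were acquired under.
#' @return List with `canvas` (an [ion_count_stack()]), `contribution`
#'   (integer matrix of source-tile indices) and `layout`.
#' @export
assemble_mosaic <- function(tiles, layout) {
  n <- layout$nrow * layout$ncol
  if (length(tiles) != n) stop("expected ", n, " tiles, got ", length(tiles))
  px <- vapply(tiles, function(t) t$pixel_size_um, numeric(1))
  if (length(unique(px)) != 1L) stop("inconsistent pixel sizes across tiles")
  if (any(vapply(tiles, function(t) !identical(sort(names(t$counts)),
                                               sort(ion_species())), logical(1))))
    stop("inconsistent species sets across tiles")
  for (t in tiles)
    if (!identical(dim(t), c(layout$tile_px, layout$tile_px)))
      stop("tile dimensions do not match layout tile_px")
  cd <- canvas_dim(layout)

  rb <- axis_bands(layout$nrow, layout$tile_px, layout$overlap_px, cd[1L])
  cb <- axis_bands(layout$ncol, layout$tile_px, layout$overlap_px, cd[2L])
  contribution <- matrix(rb$band, cd[1L], cd[2L]) * 0L +
    (matrix(rb$band, cd[1L], cd[2L], byrow = FALSE) - 1L) * layout$ncol +
    matrix(cb$band, cd[1L], cd[2L], byrow = TRUE)
  # resolve ties (pixels exactly midway between tile centres) by acq. order
  tie_r <- which(rb$tie); tie_c <- which(cb$tie)
  tie_px <- rbind(
    if (length(tie_r)) cbind(rep(tie_r, cd[2L]), rep(seq_len(cd[2L]), each = length(tie_r))),
    if (length(tie_c)) cbind(rep(seq_len(cd[1L]), each = length(tie_c)), rep(tie_c, cd[1L])))
  if (!is.null(tie_px) && nrow(tie_px) > 0L) {
    tie_px <- unique(tie_px)
    for (m in seq_len(nrow(tie_px))) {
      i <- tie_px[m, 1L]; j <- tie_px[m, 2L]
      rcand <- if (rb$tie[i]) c(rb$band[i], rb$band[i] + 1L) else rb$band[i]
      ccand <- if (cb$tie[j]) c(cb$band[j], cb$band[j] + 1L) else cb$band[j]
      cand <- as.vector(outer(rcand - 1L, ccand, function(a, b) a * layout$ncol + b))
      contribution[i, j] <- cand[which.min(layout$order[cand])]
    }
  }

  counts <- stats::setNames(lapply(ion_species(), function(sp)
    matrix(0, cd[1L], cd[2L])), ion_species())
  for (k in seq_len(n)) {
    fp <- tile_footprint(layout, k)
    sel <- which(contribution == k, arr.ind = TRUE)
    if (nrow(sel) == 0L) next
    loc <- cbind(sel[, 1L] - fp[1L] + 1L, sel[, 2L] - fp[3L] + 1L)
    for (sp in ion_species())
      counts[[sp]][sel] <- tiles[[k]]$counts[[sp]][loc]
  }
  canvas <- ion_count_stack(counts, pixel_size_um = layout$pixel_size_um,
                            dwell_ms = tiles[[1L]]$dwell_ms,
                            planes = tiles[[1L]]$planes, id = "mosaic")
  list(canvas = canvas, contribution = contribution, layout = layout)
}

#' Screen a mosaic for the N2-adsorption bias
#'
#' Re-measuring an area that an earlier tile already sputtered can deposit
#' adsorbed N2 of natural isotopic composition, depressing the measured
#' at%15N there. For every tile acquired after an overlapping neighbour, the
#' mean at%15N of its re-measured strip (the overlap pixels it contributed to
#' the canvas) is compared against a matched interior band of equal width
#' shifted inward, by a one-sided Wilcoxon rank-sum test. A strip is flagged
#' when the depression is significant at `alpha` AND exceeds `min_effect`
#' relative depression (the practical threshold keeps structured tissue
#' variation from triggering flags on artifact-free mosaics). Pre-sputtered
#' tiles are exempt.
#'
#' @param at15n at%15N canvas (matrix, NA = masked), e.g. from
#'   [nitrogen_atom_fraction()] of the assembled canvas.
#' @param layout The [mosaic_layout()].
#' @param contribution Contribution map from [assemble_mosaic()].
#' @param alpha Significance level (default 0.01).
#' @param min_effect Minimum relative depression (default 0.05).
#' @param min_n Minimum pixels per group for a comparison to be made.
#' @return Data frame of class `adsorption_qc`: one row per
#'   tile x earlier-neighbour comparison with group sizes, means, relative
#'   depression, p-value and flag. Zero rows when the layout has no overlaps.
#' @export
adsorption_qc <- function(at15n, layout, contribution, alpha = 0.01,
                          min_effect = 0.05, min_n = 10L) {
  n <- layout$nrow * layout$ncol
  out <- list()
  for (k in seq_len(n)) {
    if (layout$pre_sputtered[k]) next
    fp <- tile_footprint(layout, k)
    for (u in seq_len(n)) {
      if (u == k || layout$order[u] >= layout$order[k]) next
      fu <- tile_footprint(layout, u)
      r0 <- max(fp[1L], fu[1L]); r1 <- min(fp[2L], fu[2L])
      c0 <- max(fp[3L], fu[3L]); c1 <- min(fp[4L], fu[4L])
      if (r0 > r1 || c0 > c1) next
      gr_k <- (k - 1L) %/% layout$ncol; gc_k <- (k - 1L) %% layout$ncol
      gr_u <- (u - 1L) %/% layout$ncol; gc_u <- (u - 1L) %% layout$ncol
      if (abs(gr_k - gr_u) + abs(gc_k - gc_u) != 1L) next  # 4-adjacent pairs
      strip_rows <- r0:r1; strip_cols <- c0:c1
      w_r <- 0L; w_c <- 0L
      if (gr_u < gr_k) w_r <- (r1 - r0 + 1L)        # neighbour above: shift down
      else if (gr_u > gr_k) w_r <- -(r1 - r0 + 1L)  # below: shift up
      if (gc_u < gc_k) w_c <- (c1 - c0 + 1L)
      else if (gc_u > gc_k) w_c <- -(c1 - c0 + 1L)
      band_rows <- strip_rows + w_r
      band_cols <- strip_cols + w_c
      band_rows <- band_rows[band_rows >= fp[1L] & band_rows <= fp[2L]]
      band_cols <- band_cols[band_cols >= fp[3L] & band_cols <= fp[4L]]
      if (length(band_rows) == 0L || length(band_cols) == 0L) next
      strip_m <- contribution[strip_rows, strip_cols, drop = FALSE] == k
      strip_v <- at15n[strip_rows, strip_cols, drop = FALSE][strip_m]
      band_m <- contribution[band_rows, band_cols, drop = FALSE] == k &
        !covered_by_earlier(layout, k)[band_rows - fp[1L] + 1L,
                                       band_cols - fp[3L] + 1L, drop = FALSE]
      band_v <- at15n[band_rows, band_cols, drop = FALSE][band_m]
      strip_v <- strip_v[is.finite(strip_v)]
      band_v <- band_v[is.finite(band_v)]
      if (length(strip_v) < min_n || length(band_v) < min_n) next
      p <- suppressWarnings(
        stats::wilcox.test(strip_v, band_v, alternative = "less")$p.value)
      eff <- 1 - mean(strip_v) / mean(band_v)
      out[[length(out) + 1L]] <- data.frame(
        tile = k, neighbour = u, n_strip = length(strip_v),
        n_band = length(band_v), mean_strip = mean(strip_v),
        mean_band = mean(band_v), rel_depression = eff, p_value = p,
        flagged = is.finite(p) && p < alpha && eff > min_effect)
    }
  }
  res <- if (length(out) > 0L) do.call(rbind, out) else
    data.frame(tile = integer(0), neighbour = integer(0), n_strip = integer(0),
               n_band = integer(0), mean_strip = numeric(0),
               mean_band = numeric(0), rel_depression = numeric(0),
               p_value = numeric(0), flagged = logical(0))
  attr(res, "alpha") <- alpha
  attr(res, "min_effect") <- min_effect
  class(res) <- c("adsorption_qc", "data.frame")
  res
}

#' @export
print.adsorption_qc <- function(x, ...) {
  cat(sprintf("<adsorption_qc> %d strip comparison(s), %d flagged (alpha = %g, min effect = %g)\n",
              nrow(x), sum(x$flagged), attr(x, "alpha"), attr(x, "min_effect")))
  if (nrow(x) > 0L) print.data.frame(x, digits = 4, row.names = FALSE)
  invisible(x)
}
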