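# Spearman rank correlation (with exact small-sample permutation p), line-scan
# profiles along polylines, and root-system-scale per-side statistics.

#' Spearman rank correlation
#'
#' Computes the rank correlation with average (mid) ranks for ties. The
#' p-value is exact (full permutation enumeration, done in C) for n <= 10 and
#' uses the t approximation otherwise.
#'
#' @param x,y Numeric vectors of equal length (n >= 3).
#' @return List with `estimate` (r_s), `p_value`, `n` and `method`. A constant
#'   input yields `NA` with a warning and `degenerate = TRUE`.
#' @export
spearman_correlation <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need at least 3 paired observations")
  rx <- rank(x); ry <- rank(y)
  sx <- rx - mean(rx); sy <- ry - mean(ry)
  den <- sqrt(sum(sx^2) * sum(sy^2))
  if (den == 0) {
    warning("Spearman correlation undefined for constant input")
    return(list(estimate = NA_real_, p_value = NA_real_, n = n,
                method = "undefined", degenerate = TRUE))
  }
  rs <- sum(sx * sy) / den
  if (n <= 10L) {
    thr <- abs(sum(rx * ry) - n * mean(rx) * mean(ry)) - 1e-9
    hits <- spearman_perm_count(rx, ry, thr)
    p <- hits / factorial(n)
    method <- "exact permutation"
  } else {
    tval <- rs * sqrt((n - 2) / (1 - rs^2))
    p <- if (is.finite(tval)) 2 * stats::pt(-abs(tval), n - 2) else 0
    method <- "t approximation"
  }
  list(estimate = rs, p_value = min(1, p), n = n, method = method,
       degenerate = FALSE)
}

bresenham <- function(r0, c0, r1, c1) {
  dr <- abs(r1 - r0); dc <- abs(c1 - c0)
  sr <- sign(r1 - r0); sc <- sign(c1 - c0)
  err <- dc - dr
  out <- matrix(NA_integer_, dr + dc + 1L, 2L)
  i <- 0L
  repeat {
    i <- i + 1L
    out[i, ] <- c(r0, c0)
    if (r0 == r1 && c0 == c1) break
    e2 <- 2L * err
    if (e2 > -dr) { err <- err - dr; c0 <- c0 + sc }
    if (e2 < dc) { err <- err + dc; r0 <- r0 + sr }
  }
  out[seq_len(i), , drop = FALSE]
}

#' Line-scan profile along a polyline
#'
#' Samples map pixels along a polyline (Bresenham rasterisation of each
#' segment) and aggregates consecutive runs of `bin_px` pixels into one data
#' point (the published line scans use 3 pixels per data point). Several maps
#' can be profiled over shared bins, e.g. paired 13C/15N profiles.
#'
#' @param map Numeric matrix, or a named list of same-sized matrices.
#' @param polyline Numeric matrix with columns (row, col) of vertices, in
#'   pixel coordinates (1-based).
#' @param bin_px Pixels per data point (>= 1).
#' @param pixel_size_um Micrometres per pixel for the distance axis.
#' @param se_map Optional SE matrix (or named list matching `map`); bin SEs
#'   are then propagated as sqrt(sum(se^2))/n instead of the sample SEM.
#' @return Data frame: `distance_um` (bin centre along the path), `n`, and per
#'   map a `value_<name>` and `se_<name>` column (`value`/`se` for a single
#'   matrix).
#' @export
line_scan_profile <- function(map, polyline, bin_px = 3L, pixel_size_um = 1,
                              se_map = NULL) {
  if (bin_px < 1L) stop("bin_px must be >= 1")
  maps <- if (is.matrix(map)) list(value = map) else map
  if (is.null(names(maps)) || any(names(maps) == ""))
    stop("map list must be named")
  dims <- dim(maps[[1L]])
  polyline <- as.matrix(polyline)
  if (ncol(polyline) != 2L || nrow(polyline) < 2L)
    stop("polyline must be a matrix of >= 2 (row, col) vertices")
  if (any(polyline[, 1L] < 1 | polyline[, 1L] > dims[1L] |
          polyline[, 2L] < 1 | polyline[, 2L] > dims[2L]))
    stop("polyline exits the image")
  path <- NULL
  for (s in seq_len(nrow(polyline) - 1L)) {
    seg <- bresenham(round(polyline[s, 1L]), round(polyline[s, 2L]),
                     round(polyline[s + 1L, 1L]), round(polyline[s + 1L, 2L]))
    if (!is.null(path)) seg <- seg[-1L, , drop = FALSE]  # drop shared vertex
    path <- rbind(path, seg)
  }
  np <- nrow(path)
  step <- c(0, sqrt(rowSums(diff(path)^2))) * pixel_size_um
  dist <- cumsum(step)
  bin <- (seq_len(np) - 1L) %/% bin_px + 1L
  idx <- cbind(path[, 1L], path[, 2L])
  out <- data.frame(distance_um = as.numeric(tapply(dist, bin, mean)),
                    n = as.integer(tabulate(bin)))
  for (nm in names(maps)) {
    v <- maps[[nm]][idx]
    out[[paste0("value_", nm)]] <- as.numeric(tapply(v, bin, mean, na.rm = TRUE))
    if (!is.null(se_map)) {
      sm <- if (is.matrix(se_map)) se_map else se_map[[nm]]
      s <- sm[idx]
      out[[paste0("se_", nm)]] <- as.numeric(
        tapply(s, bin, function(z) sqrt(sum(z^2, na.rm = TRUE)) / sum(is.finite(z))))
    } else {
      out[[paste0("se_", nm)]] <- as.numeric(
        tapply(v, bin, function(z) {
          z <- z[is.finite(z)]
          if (length(z) > 1L) stats::sd(z) / sqrt(length(z)) else 0
        }))
    }
  }
  if (is.matrix(map)) names(out) <- sub("_value$", "", names(out))
  out
}

#' Per-side root-system analysis
#'
#' For each root-system half (N-amended / unamended), computes the dry-mass
#' weighted mean APE13C and APE15N over segments and the ordinary
#' least-squares regression of APE15N on APE13C (slope, intercept, R-squared,
#' p-value of the slope).
#'
#' @param records Data frame with columns `side`, `ape13c`, `ape15n` and
#'   `mass_mg` (weights).
#' @return Object of class `root_side_analysis`: a per-side summary data frame
#'   and the per-side `lm` fits (regression flagged unavailable for sides with
#'   fewer than 2 segments).
#' @export
root_side_analysis <- function(records) {
  need <- c("side", "ape13c", "ape15n", "mass_mg")
  if (!all(need %in% names(records)))
    stop("records must have columns ", paste(need, collapse = ", "))
  if (any(records$mass_mg <= 0)) stop("segment masses must be > 0")
  sides <- unique(records$side)
  rows <- list(); fits <- list()
  for (s in sides) {
    d <- records[records$side == s, ]
    wm13 <- stats::weighted.mean(d$ape13c, d$mass_mg)
    wm15 <- stats::weighted.mean(d$ape15n, d$mass_mg)
    if (nrow(d) >= 2L && length(unique(d$ape13c)) >= 2L) {
      fit <- stats::lm(ape15n ~ ape13c, data = d)
      sm <- summary(fit)
      rows[[s]] <- data.frame(side = s, n = nrow(d),
                              wmean_ape13c = wm13, wmean_ape15n = wm15,
                              slope = unname(stats::coef(fit)[2L]),
                              intercept = unname(stats::coef(fit)[1L]),
                              r_squared = sm$r.squared,
                              p_value = sm$coefficients[2L, 4L],
                              regression = TRUE, stringsAsFactors = FALSE)
      fits[[s]] <- fit
    } else {
      rows[[s]] <- data.frame(side = s, n = nrow(d),
                              wmean_ape13c = wm13, wmean_ape15n = wm15,
                              slope = NA_real_, intercept = NA_real_,
                              r_squared = NA_real_, p_value = NA_real_,
                              regression = FALSE, stringsAsFactors = FALSE)
      fits[s] <- list(NULL)
    }
  }
  structure(list(summary = do.call(rbind, rows), fits = fits),
            class = "root_side_analysis")
}

#' @export
print.root_side_analysis <- function(x, ...) {
  cat("<root_side_analysis>\n")
  print.data.frame(x$summary, digits = 4, row.names = FALSE)
  invisible(x)
}
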