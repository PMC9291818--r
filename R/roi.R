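# ROI-level quantification and bulk enrichment arithmetic.
#
# ROI isotope compositions use the ratio-of-sums estimator: species
# intensities are averaged over the ROI's pixels first and the at% formulas
# applied to the averages (equivalently, ratios of summed counts). The
# mean-of-per-pixel-ratios estimator differs on heterogeneous ROIs and is
# exposed only for cross-checking.

#' Per-ROI isotope composition
#'
#' For every ROI, species counts are summed over its pixels and the at%
#' formulas applied to the sums, then APE computed against the control
#' (per-tissue override when available).
#'
#' @param canvas An [ion_count_stack()] (typically the assembled mosaic).
#' @param rois An [roi_set()] on the same canvas.
#' @param control A [control_reference()].
#' @param estimator `"ratio_of_sums"` (default, the reference estimator) or
#'   `"mean_of_ratios"` (mean of valid per-pixel ratios; for cross-checks).
#' @param min_counts Per-pixel validity threshold used by the
#'   mean-of-ratios estimator only.
#' @return Data frame of class `roi_table`: id, tissue, compartment, n_px,
#'   mean per-pixel intensities of the four ratio species, at13c, at15n,
#'   ape13c, ape15n, mean_total_cn.
#' @export
roi_composition <- function(canvas, rois, control,
                            estimator = c("ratio_of_sums", "mean_of_ratios"),
                            min_counts = 10) {
  estimator <- match.arg(estimator)
  validate_roi_set(rois)
  if (!identical(dim(rois$labels), dim(canvas)))
    stop("ROI label image does not match canvas dimensions")
  sel <- rois$labels > 0
  if (!any(sel)) stop("empty ROI set")
  f <- factor(rois$labels[sel])
  ids <- as.numeric(levels(f))
  npx <- as.vector(table(f))
  sums <- function(sp) as.vector(rowsum(canvas$counts[[sp]][sel], f))
  s12 <- sums("12C12C"); s13 <- sums("13C12C")
  s14 <- sums("12C14N"); s15 <- sums("12C15N")
  if (estimator == "ratio_of_sums") {
    at13c <- 100 * s13 / (2 * s12 + s13)
    at15n <- 100 * s15 / (s15 + s14)
  } else {
    cf <- carbon_atom_fraction(canvas, min_counts)$at
    nf <- nitrogen_atom_fraction(canvas, min_counts)$at
    at13c <- as.vector(rowsum(cf[sel], f, na.rm = TRUE)) /
      as.vector(rowsum(as.numeric(is.finite(cf[sel])), f))
    at15n <- as.vector(rowsum(nf[sel], f, na.rm = TRUE)) /
      as.vector(rowsum(as.numeric(is.finite(nf[sel])), f))
  }
  r <- ifelse(s12 > 0, s13 / (2 * s12), NA_real_)
  total_cn <- (s14 + s15) * (1 + r) / npx
  ann <- rois$annotations[match(ids, rois$annotations$id), ]
  ape13c <- mapply(function(a, t, cmp) ape(a, control, "13C", t, cmp),
                   at13c, ann$tissue, ann$compartment)
  ape15n <- mapply(function(a, t, cmp) ape(a, control, "15N", t, cmp),
                   at15n, ann$tissue, ann$compartment)
  out <- data.frame(id = ids, tissue = ann$tissue, compartment = ann$compartment,
                    n_px = npx,
                    mean_12c12c = s12 / npx, mean_13c12c = s13 / npx,
                    mean_12c14n = s14 / npx, mean_12c15n = s15 / npx,
                    at13c = at13c, at15n = at15n,
                    ape13c = ape13c, ape15n = ape15n,
                    mean_total_cn = total_cn,
                    stringsAsFactors = FALSE)
  class(out) <- c("roi_table", "data.frame")
  out
}

#' Tissue-class summary of an ROI table
#'
#' Groups ROIs by tissue x compartment and reports n, mean, RSD (sample
#' SD/mean; 0 by convention for single-ROI groups, flagged in
#' `rsd_degenerate`), min and max for both at% channels — the layout of the
#' published per-tissue summary table.
#'
#' @param table An [roi_composition()] result.
#' @return Data frame of class `tissue_summary`.
#' @export
tissue_summary <- function(table) {
  if (nrow(table) == 0L) stop("empty ROI table")
  key <- interaction(table$tissue, table$compartment, drop = TRUE)
  one <- function(v, f) {
    m <- tapply(v, f, mean)
    s <- tapply(v, f, function(z) if (length(z) > 1L) stats::sd(z) else 0)
    list(n = tapply(v, f, length), mean = m,
         rsd = ifelse(m != 0, s / m, 0),
         min = tapply(v, f, min), max = tapply(v, f, max))
  }
  c13 <- one(table$at13c, key)
  n15 <- one(table$at15n, key)
  parts <- do.call(rbind, strsplit(levels(key), ".", fixed = TRUE))
  out <- data.frame(tissue = parts[, 1L], compartment = parts[, 2L],
                    n = as.integer(c13$n),
                    mean_at13c = as.numeric(c13$mean), rsd_at13c = as.numeric(c13$rsd),
                    min_at13c = as.numeric(c13$min), max_at13c = as.numeric(c13$max),
                    mean_at15n = as.numeric(n15$mean), rsd_at15n = as.numeric(n15$rsd),
                    min_at15n = as.numeric(n15$min), max_at15n = as.numeric(n15$max),
                    rsd_degenerate = as.integer(c13$n) == 1L,
                    stringsAsFactors = FALSE)
  ord <- order(match(out$compartment, compartment_classes()),
               match(out$tissue, tissue_classes()))
  out <- out[ord, ]
  rownames(out) <- NULL
  class(out) <- c("tissue_summary", "data.frame")
  out
}

#' Two-pool mixing fraction
#'
#' Fraction of a pool replaced by a labelled source:
#' f = (observed - natural) / (source - natural). An observed at%15N of 20
#' against a 99 at% source and 0.37 at% natural abundance gives f close to
#' one fifth.
#'
#' @param observed_at Observed at% of the mixture.
#' @param source_at At% of the labelled source (must differ from natural).
#' @param natural_at Natural-abundance at%.
#' @return Mixing fraction in `[0, 1]` (clamped with a warning outside).
#' @export
mixing_fraction <- function(observed_at, source_at, natural_at) {
  if (source_at == natural_at)
    stop("mixing fraction undefined: source equals natural abundance")
  f <- (observed_at - natural_at) / (source_at - natural_at)
  if (any(f < 0) || any(f > 1)) {
    warning("observed at% outside [natural, source]; fraction clamped to [0, 1]")
    f <- pmin(pmax(f, 0), 1)
  }
  f
}

ATOMIC_MASS <- c(H = 1.00794, C = 12.011, N = 14.0067, O = 15.9994,
                 P = 30.973762, S = 32.065, Cl = 35.453, Na = 22.98977,
                 K = 39.0983)
MASS_14N <- 14.0030740
MASS_15N <- 15.0001089

parse_formula <- function(formula) {
  tokens <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)[[1L]]
  parts <- regmatches(formula, gregexpr("([A-Z][a-z]?)([0-9]*)", formula))[[1L]]
  if (sum(nchar(parts)) != nchar(formula))
    stop("cannot parse chemical formula: ", formula)
  el <- sub("[0-9]*$", "", parts)
  cnt <- as.numeric(ifelse(grepl("[0-9]+$", parts),
                           sub("^[A-Za-z]+", "", parts), "1"))
  unknown <- setdiff(el, names(ATOMIC_MASS))
  if (length(unknown) > 0L)
    stop("unknown element(s) in formula: ", paste(unknown, collapse = ", "))
  tapply(cnt, el, sum)
}

#' Nitrogen molarity of a labelled solution
#'
#' Converts a mass concentration to mM of N using an isotope-weighted molar
#' mass: the N mass is `(1-f)*m(14N) + f*m(15N)` with f the label fraction.
#' 98 at% 15NH4Cl at 54.5 mg/l gives close to 1 mM N; a 140 mg/l amino-acid
#' mix at an assumed 140 g/mol with one N per molecule gives 1 mM N exactly
#' (use `molar_mass`/`n_nitrogen` for mixtures without a single formula).
#'
#' @param mass_conc_mg_l Mass concentration in mg/l.
#' @param formula Chemical formula, e.g. `"NH4Cl"`; ignored when `molar_mass`
#'   is supplied.
#' @param label_at 15N label content in at% (0-100).
#' @param molar_mass Optional molar mass in g/mol overriding the formula.
#' @param n_nitrogen N atoms per molecule; required with `molar_mass`,
#'   otherwise taken from the formula.
#' @return Millimolar concentration of N.
#' @export
solution_molarity <- function(mass_conc_mg_l, formula = NULL, label_at = 0.366,
                              molar_mass = NULL, n_nitrogen = NULL) {
  if (label_at < 0 || label_at > 100) stop("label_at must lie in [0, 100]")
  if (is.null(molar_mass)) {
    if (is.null(formula)) stop("supply a formula or a molar_mass")
    comp <- parse_formula(formula)
    if (!"N" %in% names(comp)) stop("formula contains no nitrogen: ", formula)
    n_nitrogen <- comp[["N"]]
    f <- label_at / 100
    m_n <- (1 - f) * MASS_14N + f * MASS_15N
    molar_mass <- sum(ATOMIC_MASS[names(comp)] * comp) -
      comp[["N"]] * ATOMIC_MASS[["N"]] + n_nitrogen * m_n
  } else if (is.null(n_nitrogen)) {
    stop("n_nitrogen must be given with molar_mass")
  }
  mass_conc_mg_l / molar_mass * n_nitrogen
}

#' Excess 15N mass from an APE value
#'
#' Mass of excess 15N implied by an atom-percent-excess and a total N mass.
#' Two conventions: `"atom"` converts total N mass to moles at the natural
#' mean N atomic mass and weighs the excess atoms at m(15N)
#' (`total/14.0067 * APE/100 * 15.0001`); `"mass"` applies the APE fraction
#' to the N mass directly. The convention used is recorded on the result.
#'
#' @param ape15n At% excess 15N (>= 0).
#' @param total_n_ug Total N mass in ug (>= 0).
#' @param convention `"atom"` or `"mass"`.
#' @return Excess 15N mass in ug, with the convention as an attribute.
#' @export
excess_15n_mass <- function(ape15n, total_n_ug,
                            convention = c("atom", "mass")) {
  convention <- match.arg(convention)
  if (any(ape15n < 0) || any(total_n_ug < 0)) stop("inputs must be >= 0")
  out <- if (convention == "atom")
    total_n_ug / ATOMIC_MASS[["N"]] * (ape15n / 100) * MASS_15N
  else total_n_ug * ape15n / 100
  attr(out, "convention") <- convention
  out
}
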