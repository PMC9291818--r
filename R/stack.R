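# Ion-count stack container and species vocabulary.

#' Secondary-ion species detected in one acquisition
#'
#' The seven secondary ion species recorded in parallel by the instrument
#' (monatomic and diatomic carbon, the two CN- isotopologues, phosphorus)
#' plus the secondary-electron channel.
#'
#' @return Character vector of species keys, in canonical page order.
#' @export
ion_species <- function() {
  c("12C", "13C", "12C12C", "13C12C", "12C14N", "12C15N", "31P", "SE")
}

#' Tissue and compartment vocabularies
#'
#' Tissue classes from the outside to the inside of a mycorrhizal root tip:
#' external hyphae (HE), hyphal mantle (HM), Hartig net (HN), plant cortex
#' (PC), endodermis (E) and vascular tissue (VT). Every region of interest is
#' further classified as cell wall (CW) or lumen (L).
#'
#' @return Character vector of allowed codes.
#' @export
tissue_classes <- function() c("HE", "HM", "HN", "PC", "E", "VT")

#' @rdname tissue_classes
#' @export
compartment_classes <- function() c("CW", "L")

#' Create an ion-count stack for one acquisition tile
#'
#' Bundles the per-species count images of a single field of view with its
#' acquisition metadata. Counts must be non-negative integers and all species
#' images must share dimensions.
#'
#' @param counts Named list of integer matrices, one per [ion_species()].
#' @param pixel_size_um Pixel size in micrometres per pixel (> 0).
#' @param dwell_ms Per-pixel dwell time in milliseconds.
#' @param planes Number of accumulated scan planes the counts sum over.
#' @param stage_offset_um Numeric length-2, stage offset (x, y) in um.
#' @param pre_sputtered Logical; was the field pre-sputtered before
#'   acquisition (remedy for the N2-adsorption bias)?
#' @param order Acquisition order index within a mosaic (1-based).
#' @param id Character identifier.
#' @return An object of class `ion_count_stack`.
#' @export
ion_count_stack <- function(counts, pixel_size_um, dwell_ms = 13.5, planes = 1L,
                            stage_offset_um = c(0, 0), pre_sputtered = FALSE,
                            order = 1L, id = "tile") {
  stack <- structure(
    list(counts = counts, pixel_size_um = pixel_size_um, dwell_ms = dwell_ms,
         planes = as.integer(planes), stage_offset_um = as.numeric(stage_offset_um),
         pre_sputtered = isTRUE(pre_sputtered), order = as.integer(order),
         id = as.character(id)),
    class = "ion_count_stack")
  validate_ion_stack(stack)
  stack
}

#' Validate an ion-count stack
#'
#' @param stack An `ion_count_stack`.
#' @return The stack, invisibly, or an error naming the violated field.
#' @export
validate_ion_stack <- function(stack) {
  if (!is.list(stack$counts)) stop("counts must be a named list of matrices")
  missing <- setdiff(ion_species(), names(stack$counts))
  if (length(missing) > 0L)
    stop("species missing: ", paste(missing, collapse = ", "))
  dims <- lapply(stack$counts[ion_species()], dim)
  if (length(unique(lapply(dims, paste, collapse = "x"))) != 1L)
    stop("dimension mismatch across species images")
  for (sp in ion_species()) {
    m <- stack$counts[[sp]]
    if (!is.matrix(m) || !is.numeric(m))
      stop("species ", sp, ": count image must be a numeric matrix")
    if (anyNA(m) || any(m < 0))
      stop("species ", sp, ": counts must be non-negative")
    if (any(m != floor(m)))
      stop("species ", sp, ": counts must be integers")
  }
  if (!is.numeric(stack$pixel_size_um) || stack$pixel_size_um <= 0)
    stop("pixel_size_um must be > 0")
  if (stack$dwell_ms < 0) stop("dwell_ms must be >= 0")
  invisible(stack)
}

#' @export
print.ion_count_stack <- function(x, ...) {
  d <- dim(x$counts[[1L]])
  cat(sprintf("<ion_count_stack '%s'> %d x %d px, %.4g um/px, dwell %.3g ms, %d plane(s)\n",
              x$id, d[1L], d[2L], x$pixel_size_um, x$dwell_ms, x$planes))
  tot <- vapply(x$counts, sum, numeric(1))
  cat("  total counts:", paste(sprintf("%s=%g", names(tot), tot), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.ion_count_stack <- function(x) dim(x$counts[[1L]])

#' Sum accumulated planes of several co-located stacks
#'
#' Adds per-species counts of stacks acquired over the same field (e.g.
#' individual scan planes); metadata is taken from the first stack and the
#' `planes` counter is summed. Isotope ratios computed from the summed stack
#' equal ratios computed from pre-summed counts by construction.
#'
#' @param stacks List of `ion_count_stack` objects with identical geometry.
#' @return A single `ion_count_stack`.
#' @export
accumulate_planes <- function(stacks) {
  stopifnot(length(stacks) >= 1L)
  out <- stacks[[1L]]
  if (length(stacks) > 1L) {
    for (s in stacks[-1L]) {
      if (!identical(dim(s), dim(out)))
        stop("dimension mismatch across accumulated stacks")
      for (sp in ion_species()) out$counts[[sp]] <- out$counts[[sp]] + s$counts[[sp]]
    }
    out$planes <- sum(vapply(stacks, function(s) s$planes, integer(1)))
  }
  validate_ion_stack(out)
  out
}
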