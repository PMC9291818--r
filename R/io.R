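# File formats: multi-page TIFF + JSON sidecar for count stacks, 16-bit label
# TIFF + CSV for ROI sets, CSV for the unlabelled-control reference.
#
# Counts are stored as 32-bit samples (values scaled by 1/(2^32-1) for the
# tiff writer and recovered exactly with readTIFF(as.is = TRUE)); label images
# as 16-bit. All JSON is written with a fixed key order so identical inputs
# produce byte-identical files.

TIFF_MAX32 <- 2^32 - 1
TIFF_MAX16 <- 2^16 - 1

sidecar_path <- function(path) paste0(sub("\\.tiff?$", "", path), ".json")

#' Write an ion-count stack to disk
#'
#' Writes a multi-page 32-bit TIFF (one page per species, in [ion_species()]
#' order) plus a JSON sidecar carrying the page-to-species map and all
#' acquisition metadata. The stack is validated before writing; a write -> read
#' round trip reproduces counts bit-exactly and metadata field-for-field.
#'
#' @param stack An [ion_count_stack()].
#' @param path Output TIFF path; the sidecar is written next to it with a
#'   `.json` extension.
#' @return `path`, invisibly.
#' @export
write_ion_stack <- function(stack, path) {
  validate_ion_stack(stack)
  if (any(vapply(stack$counts, max, numeric(1)) > TIFF_MAX32))
    stop("counts exceed 32-bit storage range")
  pages <- lapply(stack$counts[ion_species()], function(m) m / TIFF_MAX32)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, compression = "none")
  d <- dim(stack$counts[[1L]])
  meta <- list(
    format = "isopixel-ion-stack",
    version = 1L,
    species = as.list(ion_species()),
    dim_px = as.integer(d),
    pixel_size_um = stack$pixel_size_um,
    dwell_ms = stack$dwell_ms,
    planes = stack$planes,
    stage_offset_um = as.numeric(stack$stage_offset_um),
    pre_sputtered = stack$pre_sputtered,
    order = stack$order,
    id = stack$id)
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an ion-count stack from disk
#'
#' Counterpart of [write_ion_stack()]. Validates that every species page is
#' present and that pixel values are non-negative integers; errors name the
#' offending field.
#'
#' @param path TIFF path written by [write_ion_stack()].
#' @return An [ion_count_stack()].
#' @export
read_ion_stack <- function(path) {
  sc <- sidecar_path(path)
  if (!file.exists(sc)) stop("missing JSON sidecar: ", sc)
  meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
  if (!identical(meta$format, "isopixel-ion-stack"))
    stop("not an isopixel ion-stack sidecar: ", sc)
  missing <- setdiff(ion_species(), meta$species)
  if (length(missing) > 0L)
    stop("species missing: ", paste(missing, collapse = ", "))
  pages <- tiff::readTIFF(path, as.is = TRUE, all = TRUE)
  if (length(pages) != length(meta$species))
    stop("page count does not match sidecar species list")
  counts <- stats::setNames(lapply(pages, function(p) {
    storage.mode(p) <- "double"
    p
  }), meta$species)
  stack <- structure(
    list(counts = counts[ion_species()],
         pixel_size_um = meta$pixel_size_um,
         dwell_ms = meta$dwell_ms,
         planes = as.integer(meta$planes),
         stage_offset_um = as.numeric(meta$stage_offset_um),
         pre_sputtered = isTRUE(meta$pre_sputtered),
         order = as.integer(meta$order),
         id = meta$id),
    class = "ion_count_stack")
  validate_ion_stack(stack)
  stack
}

#' Create a region-of-interest set
#'
#' An ROI set is a positive-integer label image on the (mosaic) canvas plus an
#' annotation table mapping each ROI id to a tissue class and compartment.
#' Every labelled pixel's id must appear in the table and vice versa.
#'
#' @param labels Integer matrix; 0 = unlabelled, positive values are ROI ids.
#' @param annotations Data frame with columns `id`, `tissue`, `compartment`.
#' @return An object of class `roi_set`.
#' @export
roi_set <- function(labels, annotations) {
  rs <- structure(list(labels = labels, annotations = annotations), class = "roi_set")
  validate_roi_set(rs)
  rs
}

#' @rdname roi_set
#' @param x An `roi_set` to validate.
#' @export
validate_roi_set <- function(x) {
  lab <- x$labels
  ann <- x$annotations
  if (!is.matrix(lab) || anyNA(lab) || any(lab < 0) || any(lab != floor(lab)))
    stop("labels must be a non-negative integer matrix")
  need <- c("id", "tissue", "compartment")
  if (!all(need %in% names(ann)))
    stop("annotation table must have columns id, tissue, compartment")
  if (anyDuplicated(ann$id)) stop("duplicate ROI ids in annotation table")
  bad_t <- setdiff(unique(ann$tissue), tissue_classes())
  if (length(bad_t) > 0L)
    stop("unknown tissue code(s): ", paste(bad_t, collapse = ", "),
         " (allowed: ", paste(tissue_classes(), collapse = ", "), ")")
  bad_c <- setdiff(unique(ann$compartment), compartment_classes())
  if (length(bad_c) > 0L)
    stop("unknown compartment code(s): ", paste(bad_c, collapse = ", "),
         " (allowed: ", paste(compartment_classes(), collapse = ", "), ")")
  img_ids <- sort(unique(lab[lab > 0]))
  only_img <- setdiff(img_ids, ann$id)
  if (length(only_img) > 0L)
    stop("ROI id(s) present in label image but absent from annotations: ",
         paste(only_img, collapse = ", "))
  only_ann <- setdiff(ann$id, img_ids)
  if (length(only_ann) > 0L)
    stop("ROI id(s) annotated but empty in label image: ",
         paste(only_ann, collapse = ", "))
  invisible(x)
}

#' @export
print.roi_set <- function(x, ...) {
  cat(sprintf("<roi_set> %d ROIs on a %d x %d px canvas\n",
              nrow(x$annotations), nrow(x$labels), ncol(x$labels)))
  print(table(tissue = x$annotations$tissue, compartment = x$annotations$compartment))
  invisible(x)
}

#' Write / read an ROI set
#'
#' The label image is stored as a 16-bit TIFF and the annotations as a UTF-8
#' CSV with columns `id,tissue,compartment`. Round trips are exact.
#'
#' @param rois An [roi_set()].
#' @param label_path TIFF path for the label image.
#' @param annotation_path CSV path for the annotation table.
#' @return `label_path`, invisibly.
#' @export
write_roi_set <- function(rois, label_path, annotation_path) {
  validate_roi_set(rois)
  if (max(rois$labels) > TIFF_MAX16)
    stop("ROI ids exceed 16-bit storage range")
  tiff::writeTIFF(rois$labels / TIFF_MAX16, label_path,
                  bits.per.sample = 16L, compression = "none")
  ann <- rois$annotations[order(rois$annotations$id),
                          c("id", "tissue", "compartment")]
  utils::write.csv(ann, annotation_path, row.names = FALSE, quote = FALSE)
  invisible(label_path)
}

#' @rdname write_roi_set
#' @export
read_roi_set <- function(label_path, annotation_path) {
  lab <- tiff::readTIFF(label_path, as.is = TRUE)
  storage.mode(lab) <- "double"
  ann <- utils::read.csv(annotation_path, stringsAsFactors = FALSE)
  roi_set(lab, ann)
}

#' Create an unlabelled-control reference
#'
#' Holds the mean at%13C and at%15N measured on an unlabelled control sample;
#' APE values are computed relative to these. Optionally carries per
#' tissue x compartment overrides; lookups fall back to the global means.
#'
#' @param at13c,at15n Global control means in at% (each in (0, 100)).
#' @param n Number of control ROIs behind the global means.
#' @param rsd13c,rsd15n Relative standard deviations (SD/mean) of the control.
#' @param per_tissue Optional data frame with columns `tissue`, `compartment`,
#'   `at13c`, `at15n` overriding the global means for specific classes.
#' @return An object of class `control_reference`.
#' @export
control_reference <- function(at13c, at15n, n = 1L, rsd13c = NA_real_,
                              rsd15n = NA_real_, per_tissue = NULL) {
  check_at <- function(v, what) {
    if (anyNA(v) || any(v <= 0) || any(v >= 100))
      stop(what, " must lie in (0, 100) at%")
  }
  check_at(at13c, "control at%13C")
  check_at(at15n, "control at%15N")
  if (n < 1L) stop("control ROI count n must be >= 1")
  if (!is.null(per_tissue)) {
    need <- c("tissue", "compartment", "at13c", "at15n")
    if (!all(need %in% names(per_tissue)))
      stop("per_tissue must have columns ", paste(need, collapse = ", "))
    check_at(per_tissue$at13c, "per-tissue control at%13C")
    check_at(per_tissue$at15n, "per-tissue control at%15N")
  }
  structure(list(at13c = at13c, at15n = at15n, n = as.integer(n),
                 rsd13c = rsd13c, rsd15n = rsd15n, per_tissue = per_tissue),
            class = "control_reference")
}

#' @export
print.control_reference <- function(x, ...) {
  cat(sprintf("<control_reference> at%%13C = %.3f, at%%15N = %.3f (n = %d)\n",
              x$at13c, x$at15n, x$n))
  if (!is.null(x$per_tissue))
    cat("  per-tissue overrides:", nrow(x$per_tissue), "rows\n")
  invisible(x)
}

#' Look up the control at% for a channel (with per-tissue fallback)
#'
#' @param control A [control_reference()].
#' @param channel `"13C"` or `"15N"`.
#' @param tissue,compartment Optional codes; if a matching per-tissue override
#'   exists it is used, otherwise the global mean.
#' @return Control at% (scalar).
#' @export
control_at <- function(control, channel = c("13C", "15N"),
                       tissue = NULL, compartment = NULL) {
  channel <- match.arg(channel)
  col <- if (channel == "13C") "at13c" else "at15n"
  pt <- control$per_tissue
  if (!is.null(pt) && !is.null(tissue)) {
    hit <- pt$tissue == tissue &
      (if (is.null(compartment)) TRUE else pt$compartment == compartment)
    if (any(hit)) return(pt[[col]][which(hit)[1L]])
  }
  control[[col]]
}

#' Load a control reference from CSV or JSON
#'
#' CSV schema: columns `tissue,compartment,at13c,at15n,n`; the global means
#' are the row with `tissue == "global"` (required), any other rows become
#' per-tissue overrides. A JSON file must carry the fields of
#' [control_reference()].
#'
#' @param path CSV or JSON file path.
#' @return A [control_reference()].
#' @export
load_control_reference <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    j <- jsonlite::read_json(path, simplifyVector = TRUE)
    pt <- j$per_tissue
    if (!is.null(pt) && nrow(as.data.frame(pt)) == 0L) pt <- NULL
    return(control_reference(j$at13c, j$at15n, n = j$n %||% 1L,
                             rsd13c = j$rsd13c %||% NA_real_,
                             rsd15n = j$rsd15n %||% NA_real_,
                             per_tissue = if (is.null(pt)) NULL else as.data.frame(pt)))
  }
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("tissue", "compartment", "at13c", "at15n")
  if (!all(need %in% names(tab)))
    stop("control CSV must have columns ", paste(need, collapse = ", "))
  gl <- tab[tab$tissue == "global", , drop = FALSE]
  if (nrow(gl) != 1L) stop("control CSV must contain exactly one 'global' row")
  pt <- tab[tab$tissue != "global", , drop = FALSE]
  control_reference(gl$at13c, gl$at15n,
                    n = if ("n" %in% names(gl) && !is.na(gl$n)) gl$n else 1L,
                    per_tissue = if (nrow(pt) > 0L) pt else NULL)
}

#' Write a control reference as CSV
#'
#' @param control A [control_reference()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_control_reference <- function(control, path) {
  rows <- data.frame(tissue = "global", compartment = "",
                     at13c = control$at13c, at15n = control$at15n,
                     n = control$n, stringsAsFactors = FALSE)
  if (!is.null(control$per_tissue)) {
    pt <- control$per_tissue
    pt$n <- if ("n" %in% names(pt)) pt$n else NA_integer_
    rows <- rbind(rows, pt[, c("tissue", "compartment", "at13c", "at15n", "n")])
  }
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write / read a floating-point map image
#'
#' Isotope-fraction and uncertainty maps are written as 32-bit TIFF with an
#' affine encoding recorded in a JSON sidecar: finite values are stored as
#' `offset + slope * value/scale` (keeping raw samples below 2^31, where
#' integer TIFF readers stay exact), masked (`NA`) pixels as 0. The
#' quantisation step is scale/(0.4 * 2^32), i.e. ~6e-8 at% for at% maps.
#'
#' @param map Numeric matrix (may contain `NA` for masked pixels).
#' @param path Output TIFF path.
#' @param scale Full-scale value of the encoding (values must lie in
#'   `[0, scale]`).
#' @param meta Optional named list of extra provenance fields for the sidecar.
#' @return `path`, invisibly.
#' @export
write_float_map <- function(map, path, scale = 100, meta = list()) {
  stopifnot(is.matrix(map))
  finite <- map[is.finite(map)]
  if (length(finite) > 0L && (min(finite) < 0 || max(finite) > scale))
    stop("map values outside [0, scale]; increase scale")
  offset <- 0.05; slope <- 0.4
  img <- offset + slope * map / scale
  img[!is.finite(map)] <- 0  # NA sentinel well below the value band
  tiff::writeTIFF(img, path, bits.per.sample = 32L, compression = "none")
  side <- c(list(format = "isopixel-float-map", version = 1L, scale = scale,
                 offset = offset, slope = slope,
                 dim_px = as.integer(dim(map))), meta)
  jsonlite::write_json(side, sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_float_map
#' @export
read_float_map <- function(path) {
  meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  if (!identical(meta$format, "isopixel-float-map"))
    stop("not an isopixel float-map sidecar")
  raw <- tiff::readTIFF(path, as.is = TRUE)
  img <- raw / TIFF_MAX32
  out <- (img - meta$offset) / meta$slope * meta$scale
  out[img < meta$offset / 2] <- NA_real_
  attr(out, "meta") <- meta
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
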