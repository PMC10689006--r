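#' Scalar image volume
#'
#' A `volume` is a 3D numeric lattice with physical voxel dimensions and a
#' common-space tag. All analysis operations require their inputs to share
#' dimensions and space tag; mismatches are errors, never silent resampling.
#'
#' @param data Numeric 3D array (a 2D matrix is promoted to a single-slice
#'   volume with third dimension 1). Non-finite values are permitted and are
#'   treated as out-of-mask background.
#' @param voxel_mm Positive numeric triple, voxel edge lengths in mm.
#' @param space_tag Non-empty string identifying the common space the volume
#'   has been registered to.
#' @return An object of class `volume`.
#' @export
volume <- function(data, voxel_mm = c(1, 1, 1), space_tag = "common") {
  if (is.matrix(data)) dim(data) <- c(dim(data), 1L)
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("volume data must be a 3D array")
  storage.mode(data) <- "double"
  voxel_mm <- as.numeric(voxel_mm)
  if (length(voxel_mm) != 3L || any(!is.finite(voxel_mm)) || any(voxel_mm <= 0))
    stop("voxel_mm must be a positive numeric triple")
  if (!is.character(space_tag) || length(space_tag) != 1L || !nzchar(space_tag))
    stop("space_tag must be a non-empty string")
  structure(list(data = data, voxel_mm = voxel_mm, space_tag = space_tag),
            class = "volume")
}

#' @export
print.volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<volume> %d x %d x %d voxels, %.3g x %.3g x %.3g mm, space '%s'\n",
              d[1], d[2], d[3], x$voxel_mm[1], x$voxel_mm[2], x$voxel_mm[3],
              x$space_tag))
  invisible(x)
}

#' @export
dim.volume <- function(x) dim(x$data)

#' Integer-labelled parcellation volume
#'
#' Couples a non-negative integer label lattice (0 = background) with a parcel
#' table giving, for each label, a name, a hemisphere (`ipsi` or `contra`) and
#' a tissue class (`cortex` or `subcortical`).
#'
#' @param labels Integer 3D array; 0 marks background.
#' @param parcel_table Data frame with columns `label_id`, `name`,
#'   `hemisphere`, `tissue`.
#' @param voxel_mm,space_tag As for [volume()].
#' @return An object of class `label_volume`.
#' @export
label_volume <- function(labels, parcel_table, voxel_mm = c(1, 1, 1),
                         space_tag = "common") {
  if (is.matrix(labels)) dim(labels) <- c(dim(labels), 1L)
  if (!is.array(labels) || length(dim(labels)) != 3L)
    stop("labels must be a 3D array")
  storage.mode(labels) <- "integer"
  if (any(labels < 0, na.rm = TRUE)) stop("labels must be non-negative")
  req <- c("label_id", "name", "hemisphere", "tissue")
  if (!is.data.frame(parcel_table) || !all(req %in% names(parcel_table)))
    stop("parcel_table must have columns ", paste(req, collapse = ", "))
  if (anyDuplicated(parcel_table$label_id))
    stop("parcel_table label_id values must be unique")
  if (!all(parcel_table$hemisphere %in% c("ipsi", "contra")))
    stop("hemisphere must be 'ipsi' or 'contra'")
  if (!all(parcel_table$tissue %in% c("cortex", "subcortical")))
    stop("tissue must be 'cortex' or 'subcortical'")
  present <- sort(unique(labels[labels > 0L]))
  missing <- setdiff(present, parcel_table$label_id)
  if (length(missing))
    stop("labels present in lattice but absent from parcel_table: ",
         paste(missing, collapse = ", "))
  voxel_mm <- as.numeric(voxel_mm)
  structure(list(labels = labels, parcel_table = parcel_table,
                 voxel_mm = voxel_mm, space_tag = space_tag),
            class = "label_volume")
}

#' @export
print.label_volume <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("<label_volume> %d x %d x %d voxels, %d parcels, space '%s'\n",
              d[1], d[2], d[3], nrow(x$parcel_table), x$space_tag))
  invisible(x)
}

#' Boolean deficit mask with provenance
#'
#' @param mask Logical 3D array.
#' @param modality `"cbf"` or `"md"`.
#' @param threshold_descriptor String recording the exact rule applied.
#' @param subject,timepoint Optional provenance strings.
#' @param voxel_mm,space_tag As for [volume()].
#' @return An object of class `deficit_mask`.
#' @export
deficit_mask <- function(mask, modality, threshold_descriptor,
                         subject = NA_character_, timepoint = NA_character_,
                         voxel_mm = c(1, 1, 1), space_tag = "common") {
  if (is.matrix(mask)) dim(mask) <- c(dim(mask), 1L)
  if (!is.array(mask) || length(dim(mask)) != 3L)
    stop("mask must be a 3D array")
  storage.mode(mask) <- "logical"
  mask[is.na(mask)] <- FALSE
  modality <- match.arg(modality, c("cbf", "md"))
  structure(list(mask = mask, modality = modality,
                 threshold_descriptor = threshold_descriptor,
                 subject = subject, timepoint = timepoint,
                 voxel_mm = as.numeric(voxel_mm), space_tag = space_tag),
            class = "deficit_mask")
}

#' @export
print.deficit_mask <- function(x, ...) {
  cat(sprintf("<deficit_mask> modality=%s, %d voxels set, rule: %s\n",
              x$modality, sum(x$mask), x$threshold_descriptor))
  invisible(x)
}

# Enforce the one-common-space contract between lattice-bearing objects.
# Accepts volume / label_volume / deficit_mask / zmap, or bare arrays
# (arrays are dimension-checked only).
check_same_space <- function(...) {
  objs <- list(...)
  lat <- function(o) {
    if (is.array(o)) return(list(dim = dim(o), tag = NULL))
    if (inherits(o, "label_volume")) return(list(dim = dim(o$labels), tag = o$space_tag))
    if (inherits(o, c("volume", "deficit_mask", "zmap")))
      return(list(dim = dim(o$data %||% o$mask), tag = o$space_tag))
    stop("unsupported object in check_same_space")
  }
  infos <- lapply(objs, lat)
  d0 <- infos[[1]]$dim
  for (inf in infos[-1]) {
    if (!identical(as.integer(inf$dim), as.integer(d0)))
      stop(sprintf("image dimension mismatch: %s vs %s (inputs must be co-registered; resampling is out of scope)",
                   paste(d0, collapse = "x"), paste(inf$dim, collapse = "x")))
  }
  tags <- unique(unlist(lapply(infos, `[[`, "tag")))
  if (length(tags) > 1L)
    stop(sprintf("common-space mismatch: '%s' vs '%s'", tags[1], tags[2]))
  invisible(TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Voxel volume in cubic millimetres
#' @param x A `volume`, `label_volume` or `deficit_mask`.
#' @return Scalar voxel volume in mm^3.
#' @export
voxel_volume_mm3 <- function(x) prod(x$voxel_mm)
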