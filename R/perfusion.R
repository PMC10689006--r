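#' Relative CBF normalization
#'
#' Divides every in-brain voxel of a single-slice CBF map by the mean CBF
#' over contralateral cortical grey matter within the slice, yielding
#' relative CBF (rCBF). The normalizer region is all parcels with
#' `hemisphere == "contra"` and `tissue == "cortex"` intersected with the
#' slice footprint.
#'
#' @param cbf A single-slice CBF [volume()] (second dimension 1, or carrying
#'   a `slice_y` attribute locating the slice within the label volume grid).
#' @param labels A [label_volume()] on the session's common grid.
#' @return An object of class `rcbf_map`: the ratio lattice plus the
#'   normalizer value and a description of the normalizer region.
#' @export
normalize_cbf <- function(cbf, labels) {
  if (!inherits(cbf, "volume")) stop("cbf must be a volume")
  slice_y <- attr(cbf, "slice_y")
  ld <- dim(labels$labels)
  cd <- dim(cbf$data)
  if (!identical(cbf$space_tag, labels$space_tag))
    stop(sprintf("common-space mismatch: '%s' vs '%s'", cbf$space_tag,
                 labels$space_tag))
  if (is.null(slice_y)) {
    # full-grid CBF: must match label dims exactly
    check_same_space(cbf$data, labels$labels)
    lab_slice <- labels$labels
  } else {
    if (!identical(cd[c(1, 3)], ld[c(1, 3)]) || cd[2] != 1L)
      stop(sprintf("CBF slice dims %s do not match label grid %s",
                   paste(cd, collapse = "x"), paste(ld, collapse = "x")))
    lab_slice <- labels$labels[, slice_y, , drop = FALSE]
  }
  pt <- labels$parcel_table
  contra_cortex <- pt$label_id[pt$hemisphere == "contra" & pt$tissue == "cortex"]
  norm_vox <- array(lab_slice %in% contra_cortex, dim = cd) & is.finite(cbf$data)
  if (!any(norm_vox))
    stop("no contralateral cortical grey-matter voxels within the CBF slice")
  normalizer <- mean(cbf$data[norm_vox])
  if (!is.finite(normalizer) || normalizer <= 0)
    stop("contralateral cortical normalizer is non-positive")
  ratio <- cbf$data / normalizer
  structure(list(data = ratio, normalizer_value = normalizer,
                 normalizer_region = "contralateral cortex (hemisphere=contra, tissue=cortex) within slice",
                 voxel_mm = cbf$voxel_mm, space_tag = cbf$space_tag,
                 slice_y = slice_y),
            class = "rcbf_map")
}

#' @export
print.rcbf_map <- function(x, ...) {
  cat(sprintf("<rcbf_map> %s voxels, normalizer %.4g (%s)\n",
              paste(dim(x$data), collapse = "x"), x$normalizer_value,
              x$normalizer_region))
  invisible(x)
}

#' Perfusion-deficit mask
#'
#' Marks voxels whose relative CBF falls strictly below `threshold`
#' (default 0.5, i.e. less than 50% of contralateral cortical grey matter).
#' Voxels exactly at the threshold are not deficits.
#'
#' @param rcbf An `rcbf_map` from [normalize_cbf()].
#' @param threshold Deficit threshold in (0, 1]; default 0.5.
#' @param domain Optional logical array (same dims as the slice) restricting
#'   the mask; defaults to all finite voxels.
#' @param subject,timepoint Optional provenance.
#' @return A [deficit_mask()] with `modality = "cbf"`.
#' @export
cbf_deficit_mask <- function(rcbf, threshold = 0.5, domain = NULL,
                             subject = NA_character_, timepoint = NA_character_) {
  if (!inherits(rcbf, "rcbf_map")) stop("rcbf must be an rcbf_map")
  if (!is.numeric(threshold) || threshold <= 0 || threshold > 1)
    stop("threshold must lie in (0, 1]")
  m <- is.finite(rcbf$data) & rcbf$data < threshold
  if (!is.null(domain)) {
    if (!identical(dim(domain), dim(rcbf$data)))
      stop("domain dims do not match the rCBF slice")
    m <- m & domain
  }
  dm <- deficit_mask(m, "cbf",
                     sprintf("rCBF < %g of contralateral cortical mean (strict)", threshold),
                     subject = subject, timepoint = timepoint,
                     voxel_mm = rcbf$voxel_mm, space_tag = rcbf$space_tag)
  dm$slice_y <- rcbf$slice_y
  dm
}

#' Regional rCBF summary
#'
#' Mean relative CBF and count of deficit voxels inside a region of the
#' slice, selected either by an explicit logical array or by parcel
#' attributes (hemisphere/tissue) of a label volume.
#'
#' @param rcbf An `rcbf_map`.
#' @param labels A [label_volume()] (needed for attribute-based selection).
#' @param hemisphere,tissue Parcel selectors (e.g. `"ipsi"`, `"cortex"`);
#'   ignored when `region` is given.
#' @param region Optional logical array (slice dims) selecting voxels
#'   directly.
#' @param threshold Deficit threshold, as in [cbf_deficit_mask()].
#' @return A list with `mean_ratio`, `n_deficit_voxels` and `n_voxels`.
#' @export
region_summary <- function(rcbf, labels = NULL, hemisphere = "ipsi",
                           tissue = "cortex", region = NULL, threshold = 0.5) {
  if (is.null(region)) {
    if (is.null(labels)) stop("either region or labels must be supplied")
    pt <- labels$parcel_table
    ids <- pt$label_id[pt$hemisphere %in% hemisphere & pt$tissue %in% tissue]
    lab_slice <- if (!is.null(rcbf$slice_y))
      labels$labels[, rcbf$slice_y, , drop = FALSE] else labels$labels
    region <- array(lab_slice %in% ids, dim = dim(rcbf$data))
  }
  region <- region & is.finite(rcbf$data)
  if (!any(region)) stop("selected region contains no voxels")
  vals <- rcbf$data[region]
  list(mean_ratio = mean(vals),
       n_deficit_voxels = sum(vals < threshold),
       n_voxels = length(vals))
}
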