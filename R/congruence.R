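#' Perfusion-diffusion overlap fraction
#'
#' Fraction of perfusion-deficit voxels that also show low MD, within an
#' analysis domain (by default the CBF slice footprint intersected with the
#' ipsilateral hemisphere). The fraction conditions on the CBF mask: it is
#' the share of low-CBF voxels associated with low MD. When no CBF-deficit
#' voxel lies in the domain the fraction is undefined (0/0) and is reported
#' as 1.0 with a warning, so lesion-free subjects do not read as discordant.
#'
#' @param cbf_mask A [deficit_mask()] with `modality = "cbf"`. May live on
#'   the single-slice lattice (with a `slice_y` field) or the full grid.
#' @param md_mask A [deficit_mask()] with `modality = "md"` on the full grid
#'   (or the slice lattice).
#' @param domain Logical array restricting the count; on the slice lattice
#'   or the full grid. Required (use [slice_ipsi_domain()] for the standard
#'   choice).
#' @param subject_id Optional provenance.
#' @return A list of class `congruence_result`: `subject_id`,
#'   `n_cbf_deficit`, `n_overlap`, `fraction`, `domain_descriptor`.
#' @export
overlap_fraction <- function(cbf_mask, md_mask, domain,
                             subject_id = NA_character_) {
  if (cbf_mask$modality != "cbf" || md_mask$modality != "md")
    stop("expected cbf_mask with modality 'cbf' and md_mask with modality 'md'")
  slice_y <- cbf_mask$slice_y
  cbf <- cbf_mask$mask
  md <- md_mask$mask
  to_slice <- function(a) {
    if (identical(dim(a), dim(cbf))) return(a)
    if (!is.null(slice_y) && identical(dim(a)[c(1, 3)], dim(cbf)[c(1, 3)]))
      return(a[, slice_y, , drop = FALSE])
    stop("mask/domain dims are incompatible with the CBF slice lattice")
  }
  md <- to_slice(md)
  dom <- to_slice(domain)
  n_cbf <- sum(cbf & dom)
  n_overlap <- sum(cbf & md & dom)
  if (n_cbf == 0L) {
    warning("no CBF-deficit voxels in domain: overlap fraction undefined, reported as 1.0 by convention")
    fraction <- 1.0
  } else {
    fraction <- n_overlap / n_cbf
  }
  structure(list(subject_id = subject_id, n_cbf_deficit = n_cbf,
                 n_overlap = n_overlap, fraction = fraction,
                 domain_descriptor = "CBF slice footprint intersect supplied domain"),
            class = "congruence_result")
}

#' Standard congruence domain: CBF slice x ipsilateral hemisphere
#'
#' @param labels A [label_volume()].
#' @param slice_y Slice index (second grid dimension) of the CBF slice.
#' @param tissue Optional tissue restriction (`"cortex"`, `"subcortical"`
#'   or both, the default).
#' @return Logical 3D array, TRUE only on the slice plane.
#' @export
slice_ipsi_domain <- function(labels, slice_y,
                              tissue = c("cortex", "subcortical")) {
  pt <- labels$parcel_table
  ids <- pt$label_id[pt$hemisphere == "ipsi" & pt$tissue %in% tissue]
  dom <- array(FALSE, dim(labels$labels))
  sl <- labels$labels[, slice_y, , drop = FALSE]
  dom[, slice_y, ] <- array(sl %in% ids, dim(sl)[c(1, 3)])
  dom
}

#' Deficit incidence map
#'
#' Voxelwise count of subjects whose deficit mask covers each voxel
#' (the pseudo-color overlap maps of group lesion topography).
#'
#' @param masks Non-empty list of [deficit_mask()]s with shared dims.
#' @return A [volume()] of integer counts.
#' @export
incidence_map <- function(masks) {
  if (!length(masks)) stop("need >= 1 mask")
  do.call(check_same_space, masks)
  counts <- Reduce(`+`, lapply(masks, function(m) m$mask + 0L))
  volume(array(as.double(counts), dim(counts)),
         voxel_mm = masks[[1]]$voxel_mm, space_tag = masks[[1]]$space_tag)
}
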