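#' Parcel time-series container
#'
#' @param mat Numeric matrix, time by parcels.
#' @param repetition_time_s Frame interval (s).
#' @param parcel_ids Character vector naming the columns (aligned with the
#'   label volume's `label_id`s).
#' @return A `parcel_ts` matrix with metadata attributes. Constant columns
#'   are dropped with a warning (they carry no correlation information).
#' @export
parcel_timeseries <- function(mat, repetition_time_s, parcel_ids = NULL) {
  mat <- as.matrix(mat)
  if (nrow(mat) < 2L) stop("need >= 2 timepoints")
  if (is.null(parcel_ids)) parcel_ids <- colnames(mat) %||% as.character(seq_len(ncol(mat)))
  parcel_ids <- as.character(parcel_ids)
  const <- apply(mat, 2, function(col) max(col) == min(col))
  if (any(const)) {
    warning("dropping constant parcel column(s): ",
            paste(parcel_ids[const], collapse = ", "))
    mat <- mat[, !const, drop = FALSE]
    parcel_ids <- parcel_ids[!const]
  }
  colnames(mat) <- parcel_ids
  structure(mat, class = c("parcel_ts", "matrix"),
            repetition_time_s = repetition_time_s, parcel_ids = parcel_ids)
}

#' @export
print.parcel_ts <- function(x, ...) {
  cat(sprintf("<parcel_ts> %d frames x %d parcels, TR = %g s\n",
              nrow(x), ncol(x), attr(x, "repetition_time_s")))
  invisible(x)
}

#' Zero-phase band-pass filter
#'
#' Frequency-domain (FFT) band-pass applied independently per parcel column:
#' the mean is removed and Fourier components with frequency outside
#' `[low_hz, high_hz]` are zeroed. Being a multiplication in the frequency
#' domain the filter is exactly zero-phase, so temporal alignment across
#' parcels is untouched.
#'
#' @param ts A `parcel_ts`.
#' @param low_hz,high_hz Pass band in Hz; defaults 0.01-0.2. `high_hz` must
#'   be below the Nyquist frequency `1 / (2 TR)`.
#' @return Filtered `parcel_ts`.
#' @export
bandpass_filter <- function(ts, low_hz = 0.01, high_hz = 0.2) {
  tr <- attr(ts, "repetition_time_s")
  nyq <- 1 / (2 * tr)
  if (low_hz < 0 || high_hz <= low_hz) stop("need 0 <= low_hz < high_hz")
  if (high_hz >= nyq)
    stop(sprintf("high_hz (%g) must be below Nyquist (%g Hz at TR = %g s)",
                 high_hz, nyq, tr))
  n <- nrow(ts)
  freqs <- (seq_len(n) - 1) / (n * tr)
  freqs <- pmin(freqs, 1 / tr - freqs)   # two-sided spectrum
  keep <- freqs >= low_hz & freqs <= high_hz
  X <- sweep(unclass(ts), 2, colMeans(ts))
  F <- stats::mvfft(X)
  F[!keep, ] <- 0
  Y <- Re(stats::mvfft(F, inverse = TRUE)) / n
  parcel_timeseries_keep(Y, tr, attr(ts, "parcel_ids"))
}

# internal constructor that skips the constant-column check (a filtered
# constant series legitimately becomes all-zero)
parcel_timeseries_keep <- function(mat, tr, parcel_ids) {
  mat <- as.matrix(mat)
  parcel_ids <- as.character(parcel_ids)
  colnames(mat) <- parcel_ids
  structure(mat, class = c("parcel_ts", "matrix"),
            repetition_time_s = tr, parcel_ids = parcel_ids)
}

#' Extract parcel-mean time series from 4D data
#'
#' @param frames List of [volume()]s (one per timepoint) or a 4D array.
#' @param labels A [label_volume()] matching the spatial dims.
#' @param repetition_time_s Frame interval (s).
#' @return A `parcel_ts` (time by parcels). Parcels with zero voxels are
#'   dropped and recorded in the `dropped_parcels` attribute.
#' @export
extract_parcel_series <- function(frames, labels, repetition_time_s = 2) {
  if (is.array(frames) && length(dim(frames)) == 4L)
    frames <- lapply(seq_len(dim(frames)[4]),
                     function(t) volume(frames[, , , t],
                                        voxel_mm = labels$voxel_mm,
                                        space_tag = labels$space_tag))
  check_same_space(frames[[1]], labels$labels)
  lab <- as.vector(labels$labels)
  ids <- labels$parcel_table$label_id
  groups <- factor(lab, levels = ids)
  counts <- table(groups)
  present <- ids[counts > 0]
  dropped <- ids[counts == 0]
  rows <- lapply(frames, function(f) {
    v <- as.vector(f$data)
    tapply(v, groups, mean)[as.character(present)]
  })
  mat <- do.call(rbind, rows)
  # constant columns are legitimate here (e.g. piecewise-constant phantoms);
  # they are rejected only when a correlation is actually requested
  out <- parcel_timeseries_keep(mat, repetition_time_s,
                                parcel_ids = as.character(present))
  attr(out, "dropped_parcels") <- dropped
  out
}

#' Parcels common to all subjects
#'
#' @param coverage Named list (per subject) of character/integer vectors of
#'   covered parcel ids (e.g. the `parcel_ids` of each subject's series).
#' @return Character vector: the intersection over subjects.
#' @export
common_parcels <- function(coverage) {
  if (!length(coverage)) stop("need >= 1 subject")
  sets <- lapply(coverage, as.character)
  common <- Reduce(intersect, sets)
  if (!length(common)) stop("no parcel is common to all subjects")
  common
}

#' Fisher-z functional connectivity matrix
#'
#' Pairwise Pearson correlation between parcel time series, Fisher
#' z-transformed (`z = atanh(r)`), with r clipped to +/-(1 - 1e-12) before
#' the transform so perfectly correlated pairs yield a large finite z (such
#' pairs are flagged in the `clipped` attribute). The diagonal is NA.
#'
#' @param ts A `parcel_ts`.
#' @return An `fc_matrix`: symmetric parcels-by-parcels matrix with
#'   `parcel_ids` attribute.
#' @export
fc_matrix <- function(ts) {
  X <- unclass(ts)
  if (any(apply(X, 2, function(c) max(c) == min(c))))
    stop("constant parcel column reached fc_matrix; drop it upstream")
  r <- stats::cor(X)
  clip <- 1 - 1e-12
  clipped <- abs(r) >= clip & row(r) != col(r)
  r <- pmin(pmax(r, -clip), clip)
  z <- atanh(r)
  diag(z) <- NA_real_
  ids <- attr(ts, "parcel_ids")
  dimnames(z) <- list(ids, ids)
  structure(z, class = c("fc_matrix", "matrix"), parcel_ids = ids,
            clipped = any(clipped))
}

#' @export
print.fc_matrix <- function(x, ...) {
  cat(sprintf("<fc_matrix> %d x %d parcels, mean |z| = %.3f\n",
              nrow(x), ncol(x), mean(abs(x), na.rm = TRUE)))
  invisible(x)
}

#' All unordered parcel pairs
#'
#' @param parcel_ids Character vector of parcel ids.
#' @return Data frame with character columns `i`, `j` (i precedes j in
#'   `parcel_ids` order), one row per edge.
#' @export
all_edges <- function(parcel_ids) {
  p <- length(parcel_ids)
  idx <- which(upper.tri(matrix(0, p, p)), arr.ind = TRUE)
  data.frame(i = parcel_ids[idx[, 1]], j = parcel_ids[idx[, 2]],
             stringsAsFactors = FALSE)
}

#' Partition edges by low-MD membership
#'
#' Splits all edges over the common parcels into a low-MD edge set and a
#' normal-MD edge set. Under the default `rule = "any"` an edge is low-MD
#' when at least one endpoint is a low-MD region (maximally sensitive to
#' connections from damaged tissue); under `rule = "both"` both endpoints
#' must be low-MD. The two sets always partition the full edge list.
#'
#' @param low_md_regions Character/integer vector of low-MD parcel ids.
#' @param all_parcels Character vector of common parcel ids.
#' @param rule `"any"` (default) or `"both"`.
#' @return List of class `edge_sets` with data frames `low_md_edges`,
#'   `normal_md_edges` and a `definition_descriptor`.
#' @export
build_edge_sets <- function(low_md_regions, all_parcels, rule = c("any", "both")) {
  rule <- match.arg(rule)
  low <- as.character(low_md_regions)
  if (length(setdiff(low, all_parcels)))
    stop("low-MD regions must be a subset of the common parcels")
  ed <- all_edges(as.character(all_parcels))
  in_low <- if (rule == "any") ed$i %in% low | ed$j %in% low
            else ed$i %in% low & ed$j %in% low
  structure(list(low_md_edges = ed[in_low, , drop = FALSE],
                 normal_md_edges = ed[!in_low, , drop = FALSE],
                 definition_descriptor = sprintf(
                   "low-MD edge: %s endpoint(s) in low-MD region set",
                   if (rule == "any") ">=1" else "both")),
            class = "edge_sets")
}

#' Group-level low-MD parcel classification
#'
#' A parcel is classified low-MD when at least `fraction_threshold` of its
#' voxels are low-MD (z below the threshold) in at least `subject_fraction`
#' of the injured subjects. Both cutoffs are analysis choices exposed as
#' parameters (defaults: 10% of voxels, half the subjects).
#'
#' @param md_masks List (per injured subject) of MD [deficit_mask()]s on the
#'   label grid.
#' @param labels A [label_volume()].
#' @param fraction_threshold Voxel-fraction cutoff per parcel (default 0.10).
#' @param subject_fraction Subject-fraction cutoff (default 0.5).
#' @return Character vector of low-MD parcel ids (possibly empty, with a
#'   warning).
#' @export
classify_lowmd_regions <- function(md_masks, labels, fraction_threshold = 0.10,
                                   subject_fraction = 0.5) {
  if (!length(md_masks)) stop("need >= 1 injured subject")
  ids <- labels$parcel_table$label_id
  lab <- as.vector(labels$labels)
  groups <- factor(lab, levels = ids)
  sizes <- as.integer(table(groups))
  hit <- matrix(0L, length(md_masks), length(ids))
  for (s in seq_along(md_masks)) {
    check_same_space(md_masks[[s]], labels$labels)
    cnt <- tapply(as.vector(md_masks[[s]]$mask), groups, sum)
    cnt[is.na(cnt)] <- 0
    frac <- as.numeric(cnt) / pmax(sizes, 1L)
    hit[s, ] <- as.integer(frac >= fraction_threshold)
  }
  n_needed <- ceiling(subject_fraction * length(md_masks))
  sel <- ids[colSums(hit) >= n_needed & sizes > 0]
  if (!length(sel)) warning("no parcel meets the low-MD classification rule")
  as.character(sel)
}
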