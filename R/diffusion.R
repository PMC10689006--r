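#' Diffusion gradient scheme
#'
#' @param b_values Numeric vector of b-values in s/mm^2 (must contain at
#'   least one 0 and at least 6 non-zero entries).
#' @param b_vectors Matrix (n x 3) of unit gradient directions (rows for
#'   b = 0 may be zero vectors).
#' @return Validated list of class `dwi_scheme`.
#' @export
dwi_scheme <- function(b_values, b_vectors) {
  b_values <- as.numeric(b_values)
  b_vectors <- as.matrix(b_vectors)
  if (nrow(b_vectors) != length(b_values) || ncol(b_vectors) != 3L)
    stop("b_vectors must be an n x 3 matrix aligned with b_values")
  nz <- b_values > 0
  if (sum(!nz) < 1L || sum(nz) < 6L)
    stop("scheme needs >= 1 b=0 and >= 6 diffusion-weighted directions")
  nrm <- sqrt(rowSums(b_vectors^2))
  if (any(abs(nrm[nz] - 1) > 1e-6))
    stop("non-zero-b gradient vectors must be unit norm (tol 1e-6)")
  structure(list(b_values = b_values, b_vectors = b_vectors),
            class = "dwi_scheme")
}

#' Evenly spread gradient directions (Fibonacci sphere)
#'
#' Deterministic quasi-uniform unit vectors, used to synthesize acquisition
#' schemes such as 42 directions at b = 2800 s/mm^2 plus b = 0.
#'
#' @param n Number of directions.
#' @return n x 3 matrix of unit vectors.
#' @export
fibonacci_directions <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- pi * (3 - sqrt(5)) * (seq_len(n) - 1)
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

# design matrix for the log-linear tensor model:
# log S = log S0 - b (g' D g); columns: [1, Dxx, Dyy, Dzz, Dxy, Dxz, Dyz]
tensor_design <- function(scheme) {
  b <- scheme$b_values
  g <- scheme$b_vectors
  cbind(1,
        -b * g[, 1]^2, -b * g[, 2]^2, -b * g[, 3]^2,
        -2 * b * g[, 1] * g[, 2], -2 * b * g[, 1] * g[, 3],
        -2 * b * g[, 2] * g[, 3])
}

#' Log-linear diffusion tensor fit
#'
#' Fits the diffusion tensor per voxel by unweighted least squares on the
#' log signal, then derives mean diffusivity (MD = trace/3) and fractional
#' anisotropy (FA) from the tensor eigenvalues. Negative eigenvalues are
#' clamped to zero before computing FA and the voxel is flagged.
#'
#' @param signals Matrix (voxels x measurements) of diffusion-weighted
#'   signals, columns aligned with the scheme. Voxels with fewer than 7
#'   usable (positive, finite) measurements are masked out (`NA`).
#' @param scheme A [dwi_scheme()].
#' @return A list with vectors `md`, `fa` (NA where masked) and logical
#'   `clamped` marking voxels with negative eigenvalues clamped.
#' @export
fit_tensor <- function(signals, scheme) {
  signals <- as.matrix(signals)
  if (ncol(signals) != length(scheme$b_values))
    stop("signals columns must match the scheme length")
  X <- tensor_design(scheme)
  nv <- nrow(signals)
  md <- fa <- rep(NA_real_, nv)
  clamped <- rep(FALSE, nv)
  usable <- is.finite(signals) & signals > 0
  n_ok <- rowSums(usable)
  full <- n_ok == ncol(signals)
  if (any(full)) {
    # shared design: one solve for all complete voxels
    beta <- t(qr.coef(qr(X), t(log(signals[full, , drop = FALSE]))))
    res <- tensor_indices(beta[, 2:7, drop = FALSE])
    md[full] <- res$md; fa[full] <- res$fa; clamped[full] <- res$clamped
  }
  partial <- which(!full & n_ok >= 7L)
  for (v in partial) {
    ok <- usable[v, ]
    beta <- qr.coef(qr(X[ok, , drop = FALSE]), log(signals[v, ok]))
    res <- tensor_indices(matrix(beta[2:7], 1))
    md[v] <- res$md; fa[v] <- res$fa; clamped[v] <- res$clamped
  }
  list(md = md, fa = fa, clamped = clamped, n_masked = sum(n_ok < 7L))
}

# eigen-derived MD / FA from rows of (Dxx,Dyy,Dzz,Dxy,Dxz,Dyz)
tensor_indices <- function(D6) {
  n <- nrow(D6)
  md <- fa <- numeric(n)
  clamped <- logical(n)
  for (i in seq_len(n)) {
    d <- D6[i, ]
    if (any(!is.finite(d))) { md[i] <- fa[i] <- NA_real_; next }
    Dm <- matrix(c(d[1], d[4], d[5],
                   d[4], d[2], d[6],
                   d[5], d[6], d[3]), 3, 3)
    ev <- eigen(Dm, symmetric = TRUE, only.values = TRUE)$values
    md[i] <- mean(ev)
    if (any(ev < 0)) { clamped[i] <- TRUE; ev <- pmax(ev, 0) }
    mbar <- mean(ev)
    denom <- sum(ev^2)
    fa[i] <- if (denom == 0) 0 else
      sqrt(1.5 * sum((ev - mbar)^2) / denom)
  }
  list(md = md, fa = fa, clamped = clamped)
}

#' Sham reference maps
#'
#' Voxelwise mean and (n-1)-denominator standard deviation over a set of
#' co-registered sham MD volumes. Voxels with zero or undefined SD (or any
#' non-finite input) are excluded from the analysis domain, with a count.
#'
#' @param md_volumes List of >= 2 [volume()]s with matching dims/space.
#' @return An object of class `sham_reference` with `mean_map`, `sd_map`
#'   (both `volume`s), logical `domain`, `n_sham` and `n_excluded`.
#' @export
build_sham_reference <- function(md_volumes) {
  if (length(md_volumes) < 2L) stop("need >= 2 sham volumes")
  do.call(check_same_space, md_volumes)
  arrs <- lapply(md_volumes, `[[`, "data")
  n <- length(arrs)
  d3 <- dim(arrs[[1]])
  stack <- matrix(unlist(arrs), nrow = prod(d3), ncol = n)
  mu <- rowMeans(stack)
  sdv <- sqrt(rowSums((stack - mu)^2) / (n - 1))
  dim(mu) <- d3
  dim(sdv) <- d3
  domain <- is.finite(mu) & is.finite(sdv) & sdv > 0
  n_excluded <- sum(!domain & is.finite(mu))
  if (!any(domain))
    warning("sham SD map is zero or undefined everywhere: empty analysis domain")
  v1 <- md_volumes[[1]]
  structure(list(mean_map = volume(mu, v1$voxel_mm, v1$space_tag),
                 sd_map = volume(sdv, v1$voxel_mm, v1$space_tag),
                 domain = domain, n_sham = n, n_excluded = n_excluded),
            class = "sham_reference")
}

#' Sham-referenced MD z-map
#'
#' `z_v = (MD_v - mean_v) / sd_v` on the sham-reference analysis domain;
#' out-of-domain voxels are NA.
#'
#' @param md A subject MD [volume()].
#' @param ref A [build_sham_reference()] result.
#' @param subject,timepoint Optional provenance.
#' @return An object of class `zmap`.
#' @export
md_zmap <- function(md, ref, subject = NA_character_, timepoint = NA_character_) {
  check_same_space(md, ref$mean_map)
  z <- (md$data - ref$mean_map$data) / ref$sd_map$data
  z[!ref$domain | !is.finite(md$data)] <- NA_real_
  structure(list(data = z, subject = subject, timepoint = timepoint,
                 n_sham = ref$n_sham, voxel_mm = md$voxel_mm,
                 space_tag = md$space_tag),
            class = "zmap")
}

#' Low-MD deficit mask
#'
#' Voxels with z strictly below `-z_threshold` (one-sided: only reduced MD is
#' masked; elevated MD is not).
#'
#' @param z A [md_zmap()] result.
#' @param z_threshold Positive threshold in sham-SD units; default 1.7.
#' @return A [deficit_mask()] with `modality = "md"`.
#' @export
low_md_mask <- function(z, z_threshold = 1.7) {
  if (!inherits(z, "zmap")) stop("z must be a zmap")
  if (!is.numeric(z_threshold) || z_threshold <= 0)
    stop("z_threshold must be > 0")
  m <- !is.na(z$data) & z$data < -z_threshold
  deficit_mask(m, "md",
               sprintf("MD z < -%g vs sham reference (strict)", z_threshold),
               subject = z$subject, timepoint = z$timepoint,
               voxel_mm = z$voxel_mm, space_tag = z$space_tag)
}

#' Persistent low-MD tissue
#'
#' Voxelwise AND of the day-1 and day-7 low-MD masks of one subject, with
#' the persisting tissue volume in mm^3.
#'
#' @param mask_d1,mask_d7 [deficit_mask()]s with `modality = "md"` of the
#'   same subject at the two timepoints.
#' @return A list with `mask` (a `deficit_mask`) and `volume_mm3`.
#' @export
persistent_low_md <- function(mask_d1, mask_d7) {
  if (mask_d1$modality != "md" || mask_d7$modality != "md")
    stop("persistent_low_md expects MD deficit masks")
  check_same_space(mask_d1, mask_d7)
  if (!is.na(mask_d1$subject) && !is.na(mask_d7$subject) &&
      mask_d1$subject != mask_d7$subject)
    stop("masks belong to different subjects")
  if (identical(mask_d1$timepoint, mask_d7$timepoint) &&
      !is.na(mask_d1$timepoint))
    stop("masks are from the same timepoint")
  both <- mask_d1$mask & mask_d7$mask
  out <- deficit_mask(both, "md", "low MD at d1 AND d7 (persistent)",
                      subject = mask_d1$subject, timepoint = "d1&d7",
                      voxel_mm = mask_d1$voxel_mm, space_tag = mask_d1$space_tag)
  list(mask = out, volume_mm3 = sum(both) * prod(mask_d1$voxel_mm))
}

#' Synthesize noiseless tensor-model signals
#'
#' Forward model `S = S0 * exp(-b g' D g)` for a given tensor, used as an
#' independent oracle for [fit_tensor()].
#'
#' @param D 3x3 symmetric diffusion tensor (mm^2/s).
#' @param scheme A [dwi_scheme()].
#' @param s0 Signal at b = 0.
#' @return Numeric vector of signals, one per scheme row.
#' @export
tensor_signal <- function(D, scheme, s0 = 1000) {
  g <- scheme$b_vectors
  adc <- rowSums((g %*% D) * g)
  s0 * exp(-scheme$b_values * adc)
}
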