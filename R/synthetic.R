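#' Simulation configuration for synthetic multimodal cohorts
#'
#' Builds and validates the configuration of the synthetic-cohort generator.
#' Defaults encode the study design the pipeline is meant for: a sham group
#' (n = 10), an injured vehicle-treated group (n = 10) and an injured
#' treated group (n = 8), imaged at post-injury days 1 and 7, with an
#' ipsilateral lesion carrying a co-localized perfusion deficit (CBF reduced
#' to 40% of baseline, i.e. well below the 50%-of-contralateral deficit
#' criterion) and a mean-diffusivity reduction of several sham standard
#' deviations, post-impact apnea averaging 8.1 s over a 5-14 s range coupled
#' to lesion severity, and block-covariance parcel time series (450 frames at
#' TR = 2 s) with injury-induced homotopic hypoconnectivity, contralateral
#' hyperconnectivity, and treatment-induced potentiation at day 7.
#'
#' @param ... Named overrides of the defaults, nested lists merged by name
#'   (e.g. `lesion = list(cbf_factor = 0.45)` overrides one lesion field).
#' @return A validated object of class `sim_config`.
#' @export
simulation_config <- function(...) {
  cfg <- list(
    grid_dims = c(32L, 32L, 16L),
    voxel_mm = c(0.25, 0.25, 0.25),
    n_parcels = 20L,
    group_sizes = c(sham = 10L, injury_vehicle = 10L, injury_treated = 8L),
    lesion = list(
      center = NULL,              # default: dorsal ipsilateral cortex
      radii = c(5, 5, 3),         # voxels; ~314-voxel ellipsoid
      cbf_factor = 0.4,           # d1 CBF multiplier inside lesion
      cbf_factor_d7 = 0.85,       # perfusion largely resolved by d7
      md_z_depth = 4,             # lesion MD reduction in sham-SD units
      md_fraction = 0.70,         # share of lesion voxels with the MD deficit
      persist_fraction_treated = 0.8,
      persist_fraction_vehicle = 0.15,
      bilateral_md = TRUE),       # MD deficit extends to the homotopic mirror
    md = list(baseline = 0.7,     # nominal MD, 1e-3 mm^2/s units
              noise_sd = 0.02),
    cbf = list(baseline = 100,    # arbitrary perfusion units
               noise_sd = 5),
    timeseries = list(
      n_timepoints = 450L,
      repetition_time_s = 2,
      base_corr = 0.1,
      homotopic_corr = 0.6,
      injury_homotopic_delta = -0.3,
      contra_hyper_delta = 0.15,
      treatment_delta = 0.2,
      noise_sd = 1),
    apnea = list(mean_s = 8.1, range_s = c(5, 14), severity_coupling = 0.5),
    severity_sd = 0.1,            # subject-level lesion-severity spread
    space_tag = "synthetic-common",
    seed = 42L)
  overrides <- list(...)
  cfg <- merge_config(cfg, overrides)
  validate_sim_config(cfg)
}

merge_config <- function(base, over) {
  for (nm in names(over)) {
    if (is.list(base[[nm]]) && is.list(over[[nm]]))
      base[[nm]] <- merge_config(base[[nm]], over[[nm]])
    else base[[nm]] <- over[[nm]]
  }
  base
}

validate_sim_config <- function(cfg) {
  d <- cfg$grid_dims <- as.integer(cfg$grid_dims)
  if (length(d) != 3L || any(d < 4L)) stop("grid_dims must be 3 integers >= 4")
  if (any(cfg$voxel_mm <= 0)) stop("voxel_mm must be positive")
  cfg$n_parcels <- as.integer(cfg$n_parcels)
  if (cfg$n_parcels < 8L || cfg$n_parcels %% 2L != 0L)
    stop("n_parcels must be an even integer >= 8 (mirrored hemispheres)")
  if (any(cfg$group_sizes < 2L)) stop("all group sizes must be >= 2")
  les <- cfg$lesion
  if (is.null(les$center))
    cfg$lesion$center <- les$center <- c(round(d[1] * 0.3), round(d[2] / 2),
                                         round(d[3] * 0.65))
  if (any(les$radii < 0)) stop("lesion radii must be non-negative")
  if (any(les$center - les$radii < 1) || any(les$center + les$radii > d))
    stop("lesion ellipsoid must lie inside the grid")
  if (les$cbf_factor <= 0 || les$cbf_factor >= 1)
    stop("cbf_factor must lie in (0,1)")
  if (les$md_z_depth <= 0) stop("md_z_depth must be > 0")
  if (les$md_fraction < 0 || les$md_fraction > 1)
    stop("md_fraction must lie in [0,1]")
  for (f in c("persist_fraction_treated", "persist_fraction_vehicle"))
    if (les[[f]] < 0 || les[[f]] > 1) stop(f, " must lie in [0,1]")
  ts <- cfg$timeseries
  if (abs(ts$base_corr) >= 1) stop("base_corr must lie in (-1,1)")
  ap <- cfg$apnea
  if (ap$severity_coupling < 0 || ap$severity_coupling > 1)
    stop("severity_coupling must lie in [0,1]")
  if (length(ap$range_s) != 2L || ap$range_s[1] > ap$range_s[2])
    stop("apnea range_s must be an increasing pair")
  cfg$seed <- as.integer(cfg$seed)
  # the target covariances must be buildable (positive definite)
  geom <- build_geometry(cfg)
  build_target_covariances(cfg, geom$lesion_parcels, geom$n_parcels / 2L)
  structure(cfg, class = "sim_config")
}

# Brain geometry: ellipsoidal brain mask, mirrored slab parcellation,
# lesion masks. Deterministic (no RNG).
build_geometry <- function(cfg) {
  d <- cfg$grid_dims
  idx <- as.matrix(expand.grid(x = seq_len(d[1]), y = seq_len(d[2]),
                               z = seq_len(d[3])))
  ctr <- (d + 1) / 2
  brad <- 0.45 * d
  brain <- ((idx[, 1] - ctr[1]) / brad[1])^2 + ((idx[, 2] - ctr[2]) / brad[2])^2 +
    ((idx[, 3] - ctr[3]) / brad[3])^2 <= 1
  brain_mask <- array(brain, dim = d)
  nh <- cfg$n_parcels / 2L
  half <- floor(d[1] / 2)
  labels <- array(0L, dim = d)
  ipsi_vox <- which(brain_mask & slice.index(brain_mask, 1) <= half)
  ai <- arrayInd(ipsi_vox, d)
  ord <- order(ai[, 3], ai[, 2], ai[, 1])
  chunks <- as.integer(cut(seq_along(ord), breaks = nh, labels = FALSE))
  labels[ipsi_vox[ord]] <- chunks
  # mirror: contra voxel (nx+1-x, y, z) gets label + nh
  mir <- cbind(d[1] + 1L - ai[, 1], ai[, 2], ai[, 3])
  mir_lin <- mir[, 1] + (mir[, 2] - 1L) * d[1] + (mir[, 3] - 1L) * d[1] * d[2]
  labels[mir_lin[ord]] <- chunks + nh
  # dorsal half of the slabs (higher z -> higher chunk index) is cortex
  tissue_h <- ifelse(seq_len(nh) > nh / 2, "cortex", "subcortical")
  parcel_table <- data.frame(
    label_id = seq_len(cfg$n_parcels),
    name = sprintf("P%02d_%s", c(seq_len(nh), seq_len(nh)),
                   rep(c("ipsi", "contra"), each = nh)),
    hemisphere = rep(c("ipsi", "contra"), each = nh),
    tissue = rep(tissue_h, 2),
    stringsAsFactors = FALSE)
  les <- cfg$lesion
  if (all(les$radii > 0)) {
    lesion <- ((idx[, 1] - les$center[1]) / les$radii[1])^2 +
      ((idx[, 2] - les$center[2]) / les$radii[2])^2 +
      ((idx[, 3] - les$center[3]) / les$radii[3])^2 <= 1
    lesion_mask <- array(lesion, dim = d) & brain_mask
  } else {
    lesion_mask <- array(FALSE, dim = d)
  }
  # parcels carrying the lesion: >= 10% of parcel voxels inside the lesion
  lesion_parcels <- integer(0)
  if (any(lesion_mask)) {
    tab_all <- tabulate(labels[labels > 0L], nbins = cfg$n_parcels)
    tab_les <- tabulate(labels[lesion_mask & labels > 0L], nbins = cfg$n_parcels)
    lesion_parcels <- which(tab_les / pmax(tab_all, 1L) >= 0.10)
  }
  list(brain_mask = brain_mask, labels = labels, parcel_table = parcel_table,
       lesion_mask = lesion_mask, lesion_parcels = lesion_parcels,
       slice_y = les$center[2], n_parcels = cfg$n_parcels)
}

# Correlation targets per (group, timepoint). Injury reduces homotopic
# coupling of lesion parcels and raises coupling within the contralateral
# hemisphere (from the mirror of the lesion); treatment potentiates the
# depressed edges at d7. Returns covariances plus the signed effect table.
build_target_covariances <- function(cfg, lesion_parcels, nh) {
  p <- cfg$n_parcels
  ts <- cfg$timeseries
  base <- matrix(ts$base_corr, p, p)
  diag(base) <- 1
  for (l in seq_len(nh)) {
    base[l, l + nh] <- base[l + nh, l] <- ts$homotopic_corr
  }
  contra_ids <- seq_len(nh) + nh
  effects <- list()
  add_eff <- function(i, j, delta, phase) {
    effects[[length(effects) + 1L]] <<- data.frame(
      i = min(i, j), j = max(i, j), effect = delta, phase = phase,
      stringsAsFactors = FALSE)
  }
  mats <- list()
  for (g in c("sham", "injury_vehicle", "injury_treated")) {
    for (tp in c("d1", "d7")) {
      R <- base
      if (g != "sham" && length(lesion_parcels)) {
        for (l in lesion_parcels) {
          m <- l + nh  # homotopic mirror
          inj <- ts$injury_homotopic_delta
          if (tp == "d7" && g == "injury_treated") inj <- inj + ts$treatment_delta
          R[l, m] <- R[m, l] <- R[l, m] + inj
          if (g == "injury_vehicle" && tp == "d1")
            add_eff(l, m, ts$injury_homotopic_delta, "injury_d1")
          if (tp == "d7" && g == "injury_treated" && ts$treatment_delta != 0)
            add_eff(l, m, ts$treatment_delta, "treatment_d7")
          for (j in setdiff(contra_ids, m)) {
            R[m, j] <- R[j, m] <- R[m, j] + ts$contra_hyper_delta
            if (g == "injury_vehicle" && tp == "d1")
              add_eff(m, j, ts$contra_hyper_delta, "injury_d1")
          }
        }
      }
      ev_ok <- tryCatch({ chol(R); TRUE }, error = function(e) FALSE)
      if (!ev_ok)
        stop(sprintf("target covariance for block (%s, %s) is not positive definite; reduce |deltas| or |correlations|", g, tp))
      mats[[paste(g, tp, sep = ".")]] <- R * ts$noise_sd^2
    }
  }
  eff <- if (length(effects)) unique(do.call(rbind, effects)) else
    data.frame(i = integer(), j = integer(), effect = numeric(),
               phase = character())
  list(cov = mats, effects = eff)
}

#' Sample multivariate-normal parcel time series
#'
#' Draws `n_timepoints` i.i.d. multivariate normal frames with the given
#' target covariance (Cholesky factorization). The sample covariance
#' converges to the target as `n_timepoints` grows.
#'
#' @param target_covariance Symmetric positive-definite parcel-by-parcel
#'   covariance matrix.
#' @param n_timepoints Number of frames (>= 2).
#' @param seed Integer seed; the draw is bit-reproducible for a fixed seed.
#' @param repetition_time_s Frame interval in seconds (metadata).
#' @return A `parcel_ts`: numeric matrix (time by parcels) with attributes
#'   `repetition_time_s` and `parcel_ids`.
#' @export
simulate_timeseries <- function(target_covariance, n_timepoints, seed,
                                repetition_time_s = 2) {
  S <- as.matrix(target_covariance)
  if (!isSymmetric(S, tol = 1e-10)) stop("target covariance must be symmetric")
  L <- tryCatch(chol(S), error = function(e)
    stop("target covariance is not positive definite"))
  p <- ncol(S)
  n_timepoints <- as.integer(n_timepoints)
  if (n_timepoints < 2L) stop("n_timepoints must be >= 2")
  if (n_timepoints < max(3L, p))
    warning(sprintf("only %d timepoints for %d parcels: downstream correlations will be unstable", n_timepoints, p))
  old <- preserve_rng()
  on.exit(restore_rng(old))
  set.seed(seed)
  Z <- matrix(stats::rnorm(n_timepoints * p), n_timepoints, p)
  X <- Z %*% L
  parcel_timeseries(X, repetition_time_s,
                    parcel_ids = colnames(S) %||% as.character(seq_len(p)))
}

preserve_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Generate a synthetic multimodal cohort with known ground truth
#'
#' Produces, for every subject: a single coronal CBF slice through the lesion
#' center per timepoint, a 3D MD volume per timepoint, and parcel time series
#' per timepoint; plus the shared label volume, the subject manifest (group,
#' apnea seconds, timepoints) and a `ground_truth` record holding the true
#' deficit masks, the true altered edges with signed effects, the true
#' perfusion-diffusion congruence and per-subject apnea.
#'
#' Injured subjects receive a lesion in which CBF is multiplied by
#' `cbf_factor` (day 1) and MD is reduced by `md_z_depth` sham standard
#' deviations in a fixed `md_fraction` subset of lesion voxels (the subset is
#' balanced within the CBF slice so the true congruence equals `md_fraction`
#' up to rounding). At day 7 the MD deficit reverts toward baseline except in
#' a group-dependent persisting subset (`persist_fraction_*`). Per-subject
#' lesion severity scales the MD depth and couples to the apnea covariate.
#'
#' @param config A [simulation_config()].
#' @return An object of class `tbi_cohort`.
#' @export
simulate_cohort <- function(config) {
  cfg <- if (inherits(config, "sim_config")) config else
    do.call(simulation_config, config)
  d <- cfg$grid_dims
  geom <- build_geometry(cfg)
  tgt <- build_target_covariances(cfg, geom$lesion_parcels, cfg$n_parcels / 2L)
  old <- preserve_rng()
  on.exit(restore_rng(old))
  set.seed(cfg$seed)

  lesion_idx <- which(geom$lesion_mask)
  slice_y <- geom$slice_y
  in_slice <- arrayInd(lesion_idx, d)[, 2] == slice_y
  # MD-deficit subset of the lesion, balanced within the CBF slice so that
  # the slice-domain congruence matches md_fraction up to rounding
  pick <- function(v, frac) {
    k <- round(frac * length(v))
    if (k <= 0) integer(0) else v[sample.int(length(v), k)]
  }
  md_idx <- c(pick(lesion_idx[in_slice], cfg$lesion$md_fraction),
              pick(lesion_idx[!in_slice], cfg$lesion$md_fraction))
  if (isTRUE(cfg$lesion$bilateral_md) && length(md_idx)) {
    # diffuse MD reduction extends to the homotopic mirror of the deficit
    ai_md <- arrayInd(md_idx, d)
    mir_md <- (d[1] + 1L - ai_md[, 1]) + (ai_md[, 2] - 1L) * d[1] +
      (ai_md[, 3] - 1L) * d[1] * d[2]
    md_idx <- c(md_idx, mir_md)
  }
  md_set <- array(FALSE, d); md_set[md_idx] <- TRUE
  persist_subset <- function(frac) {
    keep <- pick(md_idx, frac)
    m <- array(FALSE, d); m[keep] <- TRUE
    m
  }
  persist <- list(injury_vehicle = persist_subset(cfg$lesion$persist_fraction_vehicle),
                  injury_treated = persist_subset(cfg$lesion$persist_fraction_treated))

  # smooth sham baselines (identical across subjects) + per-subject iid noise
  ax <- seq_len(d[1]); ay <- seq_len(d[2]); az <- seq_len(d[3])
  smooth <- outer(outer(sin(2 * pi * ax / d[1]), sin(2 * pi * ay / d[2])),
                  cos(2 * pi * az / d[3]))
  md_base <- cfg$md$baseline * (1 + 0.05 * smooth)
  cbf_base <- cfg$cbf$baseline * (1 + 0.05 * smooth[, slice_y, , drop = FALSE])
  nanify <- function(arr3, mask) { arr3[!mask] <- NA_real_; arr3 }
  slice_mask <- geom$brain_mask[, slice_y, , drop = FALSE]

  manifest <- do.call(rbind, lapply(names(cfg$group_sizes), function(g) {
    n <- cfg$group_sizes[[g]]
    data.frame(subject_id = sprintf("%s_%02d", g, seq_len(n)), group = g,
               stringsAsFactors = FALSE)
  }))
  ns <- nrow(manifest)
  severity <- ifelse(manifest$group == "sham", NA_real_,
                     pmin(pmax(stats::rnorm(ns, 1, cfg$severity_sd), 0.7), 1.3))
  ap <- cfg$apnea
  jitter <- stats::runif(ns, -2.5, 2.5)
  apnea <- ifelse(manifest$group == "sham", NA_real_,
                  pmin(pmax(ap$mean_s + ap$severity_coupling * 10 * (severity - 1) +
                              jitter, ap$range_s[1]), ap$range_s[2]))
  manifest$apnea_s <- apnea
  manifest$timepoints <- I(rep(list(c("d1", "d7")), ns))

  vol <- function(arr) volume(arr, cfg$voxel_mm, cfg$space_tag)
  subjects <- vector("list", ns)
  names(subjects) <- manifest$subject_id
  for (s in seq_len(ns)) {
    g <- manifest$group[s]
    injured <- g != "sham"
    sev <- if (injured) severity[s] else 1
    sub <- list()
    for (tp in c("d1", "d7")) {
      md <- md_base + stats::rnorm(prod(d), 0, cfg$md$noise_sd)
      dim(md) <- d
      if (injured) {
        drop_mask <- if (tp == "d1") md_set else persist[[g]]
        md[drop_mask] <- md[drop_mask] - cfg$lesion$md_z_depth * sev * cfg$md$noise_sd
      }
      cbf <- cbf_base + stats::rnorm(length(cbf_base), 0, cfg$cbf$noise_sd)
      dim(cbf) <- dim(cbf_base)
      if (injured && any(geom$lesion_mask)) {
        fac <- if (tp == "d1") cfg$lesion$cbf_factor else cfg$lesion$cbf_factor_d7
        les_slice <- geom$lesion_mask[, slice_y, , drop = FALSE]
        cbf[les_slice] <- cbf[les_slice] * fac
      }
      ts_seed <- cfg$seed + 1000L * s + ifelse(tp == "d1", 1L, 2L)
      X <- simulate_timeseries(tgt$cov[[paste(g, tp, sep = ".")]],
                               cfg$timeseries$n_timepoints, seed = ts_seed,
                               repetition_time_s = cfg$timeseries$repetition_time_s)
      sub[[tp]] <- list(
        md = vol(nanify(md, geom$brain_mask)),
        cbf = structure(vol(nanify(cbf, slice_mask)), slice_y = slice_y),
        ts = X)
    }
    subjects[[s]] <- sub
  }

  lab <- label_volume(geom$labels, geom$parcel_table, cfg$voxel_mm, cfg$space_tag)
  mk_mask <- function(m, modality, rule)
    deficit_mask(m, modality, rule, voxel_mm = cfg$voxel_mm,
                 space_tag = cfg$space_tag)
  true_cbf <- mk_mask(geom$lesion_mask, "cbf", "true lesion (generator)")
  true_md <- list(
    d1 = mk_mask(md_set, "md", "true MD-deficit subset (generator)"),
    d7 = list(
      injury_vehicle = mk_mask(persist$injury_vehicle, "md", "true persisting MD deficit (vehicle)"),
      injury_treated = mk_mask(persist$injury_treated, "md", "true persisting MD deficit (treated)")))
  gt_domain <- slice_and_ipsi_domain(lab, slice_y)
  true_congruence <- if (!any(geom$lesion_mask)) {
    1.0  # no-lesion convention, matches overlap_fraction()
  } else {
    cbf_sl <- geom$lesion_mask & gt_domain   # gt_domain is TRUE only on slice_y
    sum(md_set & cbf_sl) / sum(cbf_sl)
  }
  gt <- list(
    true_cbf_deficit_mask = true_cbf,
    true_low_md_mask = true_md,
    true_altered_edges = tgt$effects,
    true_congruence = true_congruence,
    apnea_by_subject = stats::setNames(manifest$apnea_s, manifest$subject_id),
    lesion_parcels = geom$lesion_parcels,
    lowmd_parcels = if (isTRUE(cfg$lesion$bilateral_md))
      sort(c(geom$lesion_parcels, geom$lesion_parcels + cfg$n_parcels / 2L))
      else geom$lesion_parcels,
    severity_by_subject = stats::setNames(severity, manifest$subject_id),
    slice_y = slice_y)
  structure(list(config = cfg, manifest = manifest, labels = lab,
                 brain_mask = geom$brain_mask, slice_y = slice_y,
                 subjects = subjects, target_cov = tgt$cov,
                 ground_truth = gt),
            class = "tbi_cohort")
}

#' @export
print.tbi_cohort <- function(x, ...) {
  cat(sprintf("<tbi_cohort> %d subjects (%s), grid %s, %d parcels, seed %d\n",
              nrow(x$manifest),
              paste(sprintf("%s=%d", names(x$config$group_sizes),
                            x$config$group_sizes), collapse = ", "),
              paste(x$config$grid_dims, collapse = "x"),
              x$config$n_parcels, x$config$seed))
  invisible(x)
}

# ipsilateral footprint of the CBF slice (3D logical, TRUE only on slice_y)
slice_and_ipsi_domain <- function(labels, slice_y) {
  lv <- labels$labels
  ipsi_ids <- labels$parcel_table$label_id[labels$parcel_table$hemisphere == "ipsi"]
  dom <- array(FALSE, dim(lv))
  dom[, slice_y, ] <- array(lv[, slice_y, ] %in% ipsi_ids,
                            dim(lv)[c(1, 3)])
  dom
}

#' Write a synthetic cohort to disk
#'
#' Writes per-subject NIfTI volumes (MD per timepoint, CBF as a single-slice
#' NIfTI), the label volume, the parcel table and subject manifest as TSV,
#' parcel time series as TSV, and the ground truth as JSON.
#'
#' @param cohort A `tbi_cohort`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_volume(cohort$labels, file.path(dir, "labels.nii"), datatype = "int32")
  write_parcel_table(cohort$labels$parcel_table, file.path(dir, "parcels.tsv"))
  write_manifest(cohort$manifest, file.path(dir, "manifest.tsv"))
  for (sid in names(cohort$subjects)) {
    sdir <- file.path(dir, sid)
    dir.create(sdir, showWarnings = FALSE)
    for (tp in names(cohort$subjects[[sid]])) {
      rec <- cohort$subjects[[sid]][[tp]]
      write_volume(rec$md, file.path(sdir, sprintf("md_%s.nii", tp)))
      write_volume(rec$cbf, file.path(sdir, sprintf("cbf_%s.nii", tp)))
      ts <- as.data.frame(unclass(rec$ts))
      names(ts) <- attr(rec$ts, "parcel_ids")
      utils::write.table(ts, file.path(sdir, sprintf("ts_%s.tsv", tp)),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  jsonlite::write_json(list(slice_y = cohort$slice_y,
                            space_tag = cohort$config$space_tag,
                            seed = cohort$config$seed,
                            repetition_time_s = cohort$config$timeseries$repetition_time_s),
                       file.path(dir, "cohort_meta.json"), auto_unbox = TRUE)
  gt <- cohort$ground_truth
  gt_json <- list(
    true_congruence = gt$true_congruence,
    lesion_parcels = gt$lesion_parcels,
    apnea_by_subject = as.list(gt$apnea_by_subject),
    true_altered_edges = gt$true_altered_edges,
    n_true_cbf_deficit = sum(gt$true_cbf_deficit_mask$mask),
    n_true_low_md_d1 = sum(gt$true_low_md_mask$d1$mask))
  jsonlite::write_json(gt_json, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_volume(gt$true_cbf_deficit_mask, file.path(dir, "true_cbf_deficit.nii"))
  write_volume(gt$true_low_md_mask$d1, file.path(dir, "true_low_md_d1.nii"))
  invisible(dir)
}
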