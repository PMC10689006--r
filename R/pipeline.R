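#' Per-parcel median MD
#'
#' @param md An MD [volume()].
#' @param labels A [label_volume()].
#' @return Named numeric vector, median MD per parcel (NA for empty parcels).
#' @export
parcel_median_md <- function(md, labels) {
  check_same_space(md, labels$labels)
  ids <- labels$parcel_table$label_id
  groups <- factor(as.vector(labels$labels), levels = ids)
  out <- tapply(as.vector(md$data), groups, stats::median, na.rm = TRUE)
  stats::setNames(as.numeric(out), as.character(ids))
}

#' Read a cohort previously written by [write_cohort()]
#'
#' @param dir Cohort directory.
#' @return A list shaped like a `tbi_cohort` (without generator ground
#'   truth beyond what was serialized).
#' @export
read_cohort <- function(dir) {
  meta_path <- file.path(dir, "cohort_meta.json")
  meta <- if (file.exists(meta_path))
    jsonlite::read_json(meta_path, simplifyVector = TRUE) else list()
  manifest <- load_manifest(file.path(dir, "manifest.tsv"))
  pt <- read_parcel_table(file.path(dir, "parcels.tsv"))
  labv <- read_volume(file.path(dir, "labels.nii"))
  labels <- label_volume(array(as.integer(labv$data), dim(labv$data)), pt,
                         voxel_mm = labv$voxel_mm, space_tag = labv$space_tag)
  subjects <- list()
  for (sid in manifest$subject_id) {
    sub <- list()
    for (tp in manifest$timepoints[[match(sid, manifest$subject_id)]]) {
      md <- read_volume(file.path(dir, sid, sprintf("md_%s.nii", tp)))
      cbf <- read_volume(file.path(dir, sid, sprintf("cbf_%s.nii", tp)))
      if (!is.null(meta$slice_y)) attr(cbf, "slice_y") <- as.integer(meta$slice_y)
      tst <- utils::read.delim(file.path(dir, sid, sprintf("ts_%s.tsv", tp)),
                               check.names = FALSE)
      sub[[tp]] <- list(md = md, cbf = cbf,
                        ts = parcel_timeseries(as.matrix(tst),
                                               meta$repetition_time_s %||% 2,
                                               parcel_ids = names(tst)))
    }
    subjects[[sid]] <- sub
  }
  gt_path <- file.path(dir, "ground_truth.json")
  gt <- if (file.exists(gt_path)) jsonlite::read_json(gt_path, simplifyVector = TRUE) else NULL
  list(manifest = manifest, labels = labels, subjects = subjects,
       slice_y = if (!is.null(meta$slice_y)) as.integer(meta$slice_y) else NULL,
       ground_truth = gt)
}

#' Pipeline run configuration
#'
#' @param simulate A [simulation_config()] (or list of overrides) to
#'   generate the cohort, or `NULL` when `input_dir` is given.
#' @param input_dir Directory with a cohort written by [write_cohort()].
#' @param cbf_threshold rCBF deficit threshold (default 0.5).
#' @param md_z_threshold MD z threshold (default 1.7).
#' @param sparsity [sparsity_grid()] levels.
#' @param alpha FDR threshold (default 0.01).
#' @param n_perm Permutation count (default 5000).
#' @param edge_rule Low-MD edge membership rule, `"any"` or `"both"`.
#' @param lowmd_fraction_threshold,lowmd_subject_fraction Parcel
#'   classification cutoffs (defaults 0.10, 0.5).
#' @param sham_reference Which sham timepoint anchors the d7 z-maps:
#'   `"match"` (sham d7, default) or `"d1"`.
#' @param seed Integer seed stamped into every output.
#' @return A validated `run_config`.
#' @export
run_config <- function(simulate = list(), input_dir = NULL,
                       cbf_threshold = 0.5, md_z_threshold = 1.7,
                       sparsity = sparsity_grid(), alpha = 0.01,
                       n_perm = 5000, edge_rule = "any",
                       lowmd_fraction_threshold = 0.10,
                       lowmd_subject_fraction = 0.5,
                       sham_reference = c("match", "d1"), seed = 1) {
  if (cbf_threshold <= 0 || cbf_threshold > 1) stop("cbf_threshold in (0,1]")
  if (md_z_threshold <= 0) stop("md_z_threshold must be > 0")
  structure(list(simulate = simulate, input_dir = input_dir,
                 cbf_threshold = cbf_threshold,
                 md_z_threshold = md_z_threshold,
                 sparsity = sparsity_grid(as.numeric(sparsity)), alpha = alpha,
                 n_perm = n_perm, edge_rule = match.arg(edge_rule, c("any", "both")),
                 lowmd_fraction_threshold = lowmd_fraction_threshold,
                 lowmd_subject_fraction = lowmd_subject_fraction,
                 sham_reference = match.arg(sham_reference),
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full pipeline
#'
#' Orchestrates simulate (or load) -> perfusion -> diffusion -> congruence
#' -> FC -> graph metrics -> statistics as one configured run. All stage
#' outputs are written under `out_dir` and a machine-readable JSON report is
#' produced. The run is deterministic for a fixed seed.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created).
#' @return The report, invisibly (also written to `out_dir/report.json`).
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "run.log")
  logf <- function(stage, msg) {
    line <- sprintf("%s\t%s\t%s", format(Sys.time(), "%H:%M:%OS2"), stage, msg)
    cat(line, "\n", file = log_path, append = TRUE)
  }
  stage <- function(name, expr) {
    t0 <- proc.time()[3]
    r <- tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
    logf(name, sprintf("done in %.2fs", proc.time()[3] - t0))
    r
  }
  report <- list(software = list(package = "tbiconn",
                                 version = as.character(utils::packageVersion("tbiconn"))),
                 seed = config$seed,
                 config = config[setdiff(names(config), "simulate")])

  cohort <- stage("cohort", {
    if (!is.null(config$input_dir)) read_cohort(config$input_dir)
    else {
      sim <- config$simulate
      if (!inherits(sim, "sim_config")) {
        sim$seed <- sim$seed %||% config$seed
        sim <- do.call(simulation_config, sim)
      }
      simulate_cohort(sim)
    }
  })
  man <- cohort$manifest
  labels <- cohort$labels
  injured_ids <- man$subject_id[man$group != "sham"]
  sham_ids <- man$subject_id[man$group == "sham"]
  if (length(sham_ids) < 2) stop("pipeline requires >= 2 sham subjects for the MD reference")

  # sham references per timepoint
  refs <- stage("sham_reference", {
    mk <- function(tp) build_sham_reference(
      lapply(sham_ids, function(s) cohort$subjects[[s]][[tp]]$md))
    list(d1 = mk("d1"),
         d7 = if (config$sham_reference == "match") mk("d7") else mk("d1"))
  })

  # diffusion: z-maps, low-MD masks, persistence
  diff_res <- stage("diffusion", {
    out <- list()
    for (sid in man$subject_id) {
      zs <- lapply(c(d1 = "d1", d7 = "d7"), function(tp)
        md_zmap(cohort$subjects[[sid]][[tp]]$md, refs[[tp]],
                subject = sid, timepoint = tp))
      masks <- lapply(zs, low_md_mask, z_threshold = config$md_z_threshold)
      pers <- persistent_low_md(masks$d1, masks$d7)
      out[[sid]] <- list(zmaps = zs, masks = masks,
                         persistent_volume_mm3 = pers$volume_mm3)
    }
    out
  })

  # perfusion + congruence (injured subjects; skipped when none)
  perf_res <- NULL
  if (length(injured_ids)) {
    perf_res <- stage("perfusion_congruence", {
      dom <- slice_ipsi_domain(labels, cohort$slice_y %||%
                                 attr(cohort$subjects[[1]]$d1$cbf, "slice_y"))
      out <- list()
      for (sid in man$subject_id) {
        rcbf <- normalize_cbf(cohort$subjects[[sid]]$d1$cbf, labels)
        cmask <- cbf_deficit_mask(rcbf, config$cbf_threshold, subject = sid,
                                  timepoint = "d1")
        summ <- region_summary(rcbf, labels, hemisphere = "ipsi",
                               tissue = "cortex", threshold = config$cbf_threshold)
        cong <- if (sid %in% injured_ids)
          suppressWarnings(overlap_fraction(cmask, diff_res[[sid]]$masks$d1,
                                            dom, subject_id = sid)) else NULL
        out[[sid]] <- list(mean_rcbf_ipsi_cortex = summ$mean_ratio,
                           n_deficit_voxels = summ$n_deficit_voxels,
                           congruence = if (!is.null(cong)) cong$fraction else NA_real_)
      }
      out
    })
  } else {
    logf("perfusion_congruence", "skipped: no injured subjects in cohort")
  }

  # low-MD regions and edge sets
  lowmd_parcels <- stage("lowmd_regions", {
    if (!length(injured_ids)) character(0) else
      suppressWarnings(classify_lowmd_regions(
        lapply(injured_ids, function(s) diff_res[[s]]$masks$d1), labels,
        config$lowmd_fraction_threshold, config$lowmd_subject_fraction))
  })
  fcs <- stage("fc", cohort_fc(cohort))
  common <- common_parcels(lapply(fcs, function(f) attr(f$d1, "parcel_ids")))
  esets <- build_edge_sets(intersect(lowmd_parcels, common), common,
                           rule = config$edge_rule)

  # nodal graph metrics per subject/timepoint
  metrics <- stage("graph_metrics", {
    do.call(rbind, lapply(man$subject_id, function(sid) {
      do.call(rbind, lapply(names(fcs[[sid]]), function(tp) {
        t1 <- sparsity_summed_metrics(fcs[[sid]][[tp]], config$sparsity)
        cbind(subject = sid, timepoint = tp, t1, stringsAsFactors = FALSE)
      }))
    }))
  })

  # MD-metric association at d1 over injured subjects
  md_corr <- NULL
  if (length(injured_ids)) {
    md_corr <- stage("md_metric_correlation", {
      pooled <- do.call(rbind, lapply(injured_ids, function(sid) {
        med <- parcel_median_md(cohort$subjects[[sid]]$d1$md, labels)
        mt <- metrics[metrics$subject == sid & metrics$timepoint == "d1", ]
        data.frame(md = med[mt$node], cc = mt$cc_sum, le = mt$le_sum)
      }))
      pooled <- pooled[is.finite(pooled$md), ]
      list(cc = nodal_md_correlation(pooled$md, pooled$cc, n_perm = config$n_perm,
                                     seed = config$seed),
           le = nodal_md_correlation(pooled$md, pooled$le, n_perm = config$n_perm,
                                     seed = config$seed))
    })
  }

  # contrasts + persistent-volume group test
  contrasts <- NULL
  vol_test <- NULL
  if (all(c("sham", "injury_vehicle", "injury_treated") %in% man$group)) {
    contrasts <- stage("contrasts",
      contrast_runner(cohort, esets, n_perm = config$n_perm,
                      alpha = config$alpha, seed = config$seed, fcs = fcs))
    vol_test <- stage("volume_test", {
      v <- vapply(man$subject_id, function(s) diff_res[[s]]$persistent_volume_mm3,
                  numeric(1))
      volume_group_test(v, man$group, n_perm = config$n_perm, seed = config$seed)
    })
  } else {
    logf("contrasts", "skipped: cohort lacks the three-group design")
  }

  # assemble + write
  subj_tab <- data.frame(
    subject_id = man$subject_id, group = man$group,
    apnea_s = man$apnea_s,
    mean_rcbf_ipsi_cortex = vapply(man$subject_id, function(s)
      if (!is.null(perf_res)) perf_res[[s]]$mean_rcbf_ipsi_cortex else NA_real_, numeric(1)),
    n_cbf_deficit_voxels = vapply(man$subject_id, function(s)
      if (!is.null(perf_res)) perf_res[[s]]$n_deficit_voxels else NA_real_, numeric(1)),
    congruence_d1 = vapply(man$subject_id, function(s)
      if (!is.null(perf_res)) perf_res[[s]]$congruence else NA_real_, numeric(1)),
    persistent_low_md_mm3 = vapply(man$subject_id, function(s)
      diff_res[[s]]$persistent_volume_mm3, numeric(1)),
    stringsAsFactors = FALSE)
  utils::write.table(subj_tab, file.path(out_dir, "subjects.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(metrics, file.path(out_dir, "nodal_metrics.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(contrasts))
    for (nm in names(contrasts))
      utils::write.table(contrasts[[nm]],
                         file.path(out_dir, sprintf("edges_%s.tsv", nm)),
                         sep = "\t", quote = FALSE, row.names = FALSE)

  report$subjects <- subj_tab
  report$low_md_parcels <- as.character(lowmd_parcels)
  report$edge_set_rule <- esets$definition_descriptor
  report$group_mean_congruence <- if (length(injured_ids) && !is.null(perf_res))
    mean(subj_tab$congruence_d1[subj_tab$group != "sham"]) else NULL
  report$md_metric_correlation <- md_corr
  report$contrast_summary <- if (!is.null(contrasts)) lapply(contrasts, function(cr)
    list(n_edges = nrow(cr), n_significant = sum(cr$significant),
         n_hyper = sum(cr$significant & cr$direction == "hyper"),
         n_hypo = sum(cr$significant & cr$direction == "hypo"))) else NULL
  report$persistent_volume_test <- vol_test
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(report)
}

#' Validate a pipeline report
#'
#' Checks a parsed `report.json` against the required schema (see
#' `inst/schema/report-schema.json`): required top-level fields and
#' per-subject columns.
#'
#' @param report Parsed report list (e.g. `jsonlite::read_json(...,
#'   simplifyVector = TRUE)`) or the value of [run_pipeline()].
#' @return `TRUE` invisibly; errors describe the first violation.
#' @export
validate_report <- function(report) {
  req <- c("software", "seed", "config", "subjects")
  miss <- setdiff(req, names(report))
  if (length(miss)) stop("report missing fields: ", paste(miss, collapse = ", "))
  sub_req <- c("subject_id", "group", "persistent_low_md_mm3")
  if (!all(sub_req %in% names(report$subjects)))
    stop("report$subjects missing columns")
  invisible(TRUE)
}
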