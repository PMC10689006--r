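#' FC change map
#'
#' Elementwise Fisher-z difference `z_d7 - z_d1` for one subject.
#'
#' @param fc_d1,fc_d7 `fc_matrix` objects of the same subject over the same
#'   parcels.
#' @return An `fc_matrix` of changes.
#' @export
delta_fc <- function(fc_d1, fc_d7) {
  if (!identical(attr(fc_d1, "parcel_ids"), attr(fc_d7, "parcel_ids")))
    stop("parcel mismatch between the two FC matrices")
  out <- unclass(fc_d7) - unclass(fc_d1)
  structure(out, class = c("fc_matrix", "matrix"),
            parcel_ids = attr(fc_d1, "parcel_ids"))
}

#' Benjamini-Hochberg step-up FDR
#'
#' @param p_values Numeric vector of p-values in (0, 1].
#' @param alpha Significance level on the q scale (default 0.01).
#' @return List with `q_values` (monotone BH-adjusted p, input order) and
#'   logical `significant` (`q < alpha`, strict).
#' @export
fdr_bh <- function(p_values, alpha = 0.01) {
  p <- as.numeric(p_values)
  if (!length(p)) stop("empty p-value vector")
  if (any(!is.finite(p) | p <= 0 | p > 1)) stop("p-values must lie in (0, 1]")
  m <- length(p)
  o <- order(p)
  q_sorted <- rev(cummin(rev(p[o] * m / seq_len(m))))
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  list(q_values = q, significant = q < alpha)
}

# permutation weight matrix: each row is the group-contrast weight vector
# under one permutation of subjects (shared across edges)
perm_weight_rows <- function(w, n_perm) {
  n <- length(w)
  t(vapply(seq_len(n_perm), function(i) w[sample.int(n)], numeric(n)))
}

#' Covariate-adjusted edgewise permutation test
#'
#' Two-tailed, two-group permutation test applied jointly to many edges.
#' When a nuisance covariate is supplied, values are first regressed on the
#' covariate (intercept + slope, pooled across subjects) and the test is run
#' on the residuals, with the null built by permuting residuals across
#' subjects (Freedman-Lane-style). One shared subject permutation per
#' iteration is used for all edges, preserving the dependence structure
#' between edges. `p = (1 + #\{|T_perm| >= |T_obs|\}) / (n_perm + 1)`.
#'
#' With `exact = TRUE` (or `exact = "auto"` and a small enough design) the
#' null is the complete enumeration of group assignments and
#' `p = #\{|T| >= |T_obs|\} / n_assignments` (the identity assignment
#' included, so p is never 0).
#'
#' @param values Numeric matrix, subjects by edges (column names are edge
#'   keys).
#' @param groups Two-level factor/character vector per subject; the observed
#'   statistic is `mean(first level) - mean(second level)` per edge.
#' @param covariate Optional numeric per subject (e.g. apnea seconds).
#'   A constant covariate is dropped with a warning.
#' @param n_perm Number of permutations (default 5000, >= 100).
#' @param alpha FDR threshold (default 0.01).
#' @param seed Integer seed for the permutation stream.
#' @param exact `TRUE`, `FALSE` or `"auto"` (enumerate when the number of
#'   assignments is at most `max_enum`).
#' @param max_enum Enumeration cap for `exact = "auto"` (default 20000).
#' @return An `edge_stats` data frame: `edge`, `observed_stat`, `p_perm`,
#'   `q_fdr`, `significant`, `direction` (`hyper` when the first group
#'   exceeds the second).
#' @export
permutation_edge_test <- function(values, groups, covariate = NULL,
                                  n_perm = 5000, alpha = 0.01, seed = 1,
                                  exact = "auto", max_enum = 20000) {
  Y <- as.matrix(values)
  n <- nrow(Y)
  lev <- if (is.factor(groups)) levels(droplevels(groups)) else unique(as.character(groups))
  groups <- as.character(groups)
  if (length(lev) != 2L) stop("groups must have exactly two levels")
  n1 <- sum(groups == lev[1]); n2 <- sum(groups == lev[2])
  if (min(n1, n2) < 2L) stop("each group needs >= 2 subjects")
  if (n_perm < 100) stop("n_perm must be >= 100")
  if (!is.null(covariate)) {
    if (length(covariate) != n) stop("covariate length must match subjects")
    if (any(!is.finite(covariate)))
      stop("covariate missing for some subjects; omit the covariate for sham-involving contrasts")
    if (stats::sd(covariate) == 0) {
      warning("constant covariate dropped")
      covariate <- NULL
    }
  }
  # Freedman-Lane: residualize the data on the nuisance model, and project
  # the contrast weights onto the same residual space. Permuting plain
  # residuals with unprojected weights is conservative when the covariate
  # correlates with the group factor; with a = (I - H) w the permuted
  # statistic a' R[perm, ] has the correct null scale, and a' R = w' R
  # because R is already orthogonal to the nuisance columns.
  w <- ifelse(groups == lev[1], 1 / n1, -1 / n2)
  if (!is.null(covariate)) {
    X <- cbind(1, covariate)
    XtXi <- solve(crossprod(X))
    R <- Y - X %*% (XtXi %*% crossprod(X, Y))
    a <- drop(w - X %*% (XtXi %*% crossprod(X, w)))
  } else {
    R <- sweep(Y, 2, colMeans(Y))
    a <- w
  }
  T_obs <- drop(a %*% R)
  eps <- 1e-12
  n_comb <- choose(n, n1)
  do_exact <- isTRUE(exact) || (identical(exact, "auto") && n_comb <= max_enum)
  if (do_exact) {
    combos <- utils::combn(n, n1)
    W <- matrix(-1 / n2, ncol(combos), n)
    for (i in seq_len(ncol(combos))) W[i, combos[, i]] <- 1 / n1
    if (!is.null(covariate))
      W <- W - (W %*% X) %*% (XtXi %*% t(X))   # project each assignment's weights
    T_perm <- W %*% R
    p <- colSums(abs(T_perm) >= abs(rep(1, nrow(T_perm)) %o% T_obs) - eps) /
      nrow(T_perm)
    n_used <- nrow(T_perm)
  } else {
    old <- preserve_rng(); on.exit(restore_rng(old))
    set.seed(seed)
    W <- perm_weight_rows(a, n_perm)
    T_perm <- W %*% R
    exceed <- colSums(abs(T_perm) >= abs(rep(1, n_perm) %o% T_obs) - eps)
    p <- (1 + exceed) / (n_perm + 1)
    n_used <- n_perm
  }
  bh <- fdr_bh(p, alpha)
  out <- data.frame(
    edge = colnames(Y) %||% as.character(seq_along(T_obs)),
    observed_stat = unname(T_obs),
    p_perm = unname(p),
    q_fdr = bh$q_values,
    significant = bh$significant,
    direction = ifelse(T_obs > 0, "hyper", "hypo"),
    stringsAsFactors = FALSE)
  attr(out, "contrast") <- sprintf("%s vs %s", lev[1], lev[2])
  attr(out, "n_perm") <- n_used
  attr(out, "exact") <- do_exact
  attr(out, "alpha") <- alpha
  attr(out, "covariate_adjusted") <- !is.null(covariate)
  class(out) <- c("edge_stats", "data.frame")
  out
}

#' Pooled MD-metric correlation
#'
#' Pearson correlation between per-(subject, region) median MD and a nodal
#' graph metric, pooled across subjects and regions, with a two-tailed
#' permutation p-value obtained by shuffling the pairing.
#'
#' @param median_md,metric Numeric vectors of paired observations (>= 3).
#' @param n_perm Number of pairing permutations (default 5000).
#' @param seed Integer seed.
#' @return List with `r`, `p` and `n`.
#' @export
nodal_md_correlation <- function(median_md, metric, n_perm = 5000, seed = 1) {
  x <- as.numeric(median_md); y <- as.numeric(metric)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("need >= 3 paired observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in one of the variables")
  r <- stats::cor(x, y)
  old <- preserve_rng(); on.exit(restore_rng(old))
  set.seed(seed)
  r_null <- vapply(seq_len(n_perm),
                   function(i) stats::cor(x, y[sample.int(length(y))]),
                   numeric(1))
  p <- (1 + sum(abs(r_null) >= abs(r) - 1e-12)) / (n_perm + 1)
  list(r = r, p = p, n = length(x))
}

#' Group comparison of persistent-low-MD volumes
#'
#' Two-tailed permutation test on the group mean difference, for every
#' pairwise contrast among the supplied groups. Small designs are
#' enumerated exactly.
#'
#' @param volumes Numeric vector of per-subject volumes (mm^3).
#' @param groups Group label per subject.
#' @param n_perm Number of permutations when enumeration is infeasible.
#' @param seed Integer seed.
#' @return Named list of contrasts, each with `p`, `mean_diff` and `groups`.
#' @export
volume_group_test <- function(volumes, groups, n_perm = 5000, seed = 1) {
  groups <- as.character(groups)
  gl <- unique(groups)
  if (length(gl) < 2L) stop("need >= 2 groups")
  out <- list()
  for (a in seq_along(gl)) for (b in seq_along(gl)) if (a < b) {
    sel <- groups %in% c(gl[a], gl[b])
    res <- permutation_edge_test(
      matrix(volumes[sel], ncol = 1, dimnames = list(NULL, "volume")),
      groups[sel], n_perm = max(n_perm, 100), seed = seed, alpha = 0.05)
    key <- paste(gl[a], gl[b], sep = "_vs_")
    out[[key]] <- list(p = res$p_perm, mean_diff = res$observed_stat,
                       groups = c(gl[a], gl[b]))
  }
  out
}

#' Contrast specification
#'
#' @param kind `"cross_sectional"` or `"temporal_change"`.
#' @param groups Character pair of group names (first minus second).
#' @param timepoint Timepoint (`"d1"`/`"d7"`) for cross-sectional contrasts;
#'   temporal contrasts use the d7 - d1 change.
#' @param edge_set `"low_md"`, `"normal_md"` or `"all"`.
#' @param covariates Character vector of nuisance covariates (only
#'   `"apnea"` is defined); ignored (with a notice) for sham-involving
#'   contrasts where apnea is undefined.
#' @param n_perm,alpha,seed Permutation count (default 5000), FDR threshold
#'   (default 0.01) and RNG seed.
#' @return A `contrast_spec` list.
#' @export
contrast_spec <- function(kind = c("cross_sectional", "temporal_change"),
                          groups, timepoint = "d1", edge_set = "low_md",
                          covariates = character(), n_perm = 5000,
                          alpha = 0.01, seed = 1) {
  kind <- match.arg(kind)
  if (length(groups) != 2L || groups[1] == groups[2])
    stop("groups must be two distinct group names")
  if (n_perm < 100) stop("n_perm must be >= 100")
  structure(list(kind = kind, groups = groups, timepoint = timepoint,
                 edge_set = edge_set, covariates = covariates,
                 n_perm = n_perm, alpha = alpha, seed = seed),
            class = "contrast_spec")
}

# per-subject FC matrices for a cohort (optionally band-pass filtered)
cohort_fc <- function(cohort, bandpass = TRUE, low_hz = 0.01, high_hz = 0.2) {
  lapply(cohort$subjects, function(sub) {
    lapply(sub, function(rec) {
      ts <- rec$ts
      if (bandpass) ts <- bandpass_filter(ts, low_hz, high_hz)
      fc_matrix(ts)
    })
  })
}

# subjects x edges matrix of Fisher z (or Dz for temporal contrasts)
edge_value_matrix <- function(fcs, subject_ids, edges, timepoint = NULL) {
  ids <- attr(fcs[[subject_ids[1]]][[if (is.null(timepoint)) "d1" else timepoint]],
              "parcel_ids")
  idx <- cbind(match(edges$i, ids), match(edges$j, ids))
  if (any(is.na(idx))) stop("edge endpoints missing from FC parcel ids")
  keys <- paste(edges$i, edges$j, sep = "--")
  vals <- t(vapply(subject_ids, function(s) {
    m <- if (is.null(timepoint))
      unclass(delta_fc(fcs[[s]]$d1, fcs[[s]]$d7)) else
      unclass(fcs[[s]][[timepoint]])
    m[idx]
  }, numeric(nrow(edges))))
  dimnames(vals) <- list(subject_ids, keys)
  vals
}

#' Run one contrast on a cohort
#'
#' @param cohort A `tbi_cohort` (or a list with `manifest` and precomputed
#'   FC matrices via the `fcs` argument).
#' @param spec A [contrast_spec()].
#' @param edge_sets An `edge_sets` object from [build_edge_sets()].
#' @param fcs Optional precomputed per-subject FC (from repeated calls);
#'   computed from the cohort time series when NULL.
#' @return An `edge_stats` data frame.
#' @export
run_contrast <- function(cohort, spec, edge_sets, fcs = NULL) {
  if (is.null(fcs)) fcs <- cohort_fc(cohort)
  man <- cohort$manifest
  sel <- man$group %in% spec$groups
  if (!any(man$group == spec$groups[1]) || !any(man$group == spec$groups[2]))
    stop("cohort lacks a requested group: ",
         paste(spec$groups, collapse = ", "))
  subj <- man$subject_id[sel]
  grp <- factor(man$group[sel], levels = spec$groups)
  edges <- switch(spec$edge_set,
                  low_md = edge_sets$low_md_edges,
                  normal_md = edge_sets$normal_md_edges,
                  all = rbind(edge_sets$low_md_edges, edge_sets$normal_md_edges),
                  stop("unknown edge_set: ", spec$edge_set))
  if (!nrow(edges)) stop("selected edge set is empty")
  tp <- if (spec$kind == "temporal_change") NULL else spec$timepoint
  vals <- edge_value_matrix(fcs, subj, edges, timepoint = tp)
  covariate <- NULL
  if ("apnea" %in% spec$covariates) {
    if ("sham" %in% spec$groups) {
      message("apnea covariate omitted: undefined for sham subjects")
    } else {
      covariate <- man$apnea_s[sel]
    }
  }
  res <- permutation_edge_test(vals, grp, covariate = covariate,
                               n_perm = spec$n_perm, alpha = spec$alpha,
                               seed = spec$seed, exact = FALSE)
  attr(res, "spec") <- spec
  res
}

#' Run the standard contrast families on a cohort
#'
#' Executes the four contrast families of the analysis design:
#' 1. injured (pooled) vs sham at d1, separately within the low-MD and
#'    normal-MD edge sets;
#' 2. treated vs vehicle on the d1-to-d7 FC change (apnea-adjusted);
#' 3. treated vs vehicle cross-sectionally at d7 (apnea-adjusted);
#' 4. each injured group vs sham at d7.
#' Sham-involving contrasts pool the two injured groups where stated and
#' never use the apnea covariate (undefined for shams).
#'
#' @param cohort A `tbi_cohort`.
#' @param edge_sets An `edge_sets` object ([build_edge_sets()]).
#' @param n_perm,alpha,seed As in [contrast_spec()].
#' @param fcs Optional precomputed per-subject FC matrices.
#' @return Named list of `edge_stats` data frames.
#' @export
contrast_runner <- function(cohort, edge_sets, n_perm = 5000, alpha = 0.01,
                            seed = 1, fcs = NULL) {
  if (is.null(fcs)) fcs <- cohort_fc(cohort)
  man <- cohort$manifest
  res <- list()
  es_empty <- function(es) {
    n <- nrow(switch(es, low_md = edge_sets$low_md_edges,
                     normal_md = edge_sets$normal_md_edges, all = edge_sets$low_md_edges))
    if (es == "all") n <- nrow(edge_sets$low_md_edges) + nrow(edge_sets$normal_md_edges)
    n == 0L
  }
  add <- function(nm, co, spec) {
    if (es_empty(spec$edge_set)) {
      message(sprintf("contrast '%s' skipped: %s edge set is empty", nm,
                      spec$edge_set))
      return(invisible(NULL))
    }
    res[[nm]] <<- run_contrast(co, spec, edge_sets, fcs = fcs)
  }
  # family 1: injured (pooled) vs sham at d1, both edge sets
  pooled <- cohort
  pooled$manifest$group <- ifelse(man$group == "sham", "sham", "injured")
  for (es in c("low_md", "normal_md"))
    add(paste0("injured_vs_sham_d1_", es), pooled,
        contrast_spec("cross_sectional", c("injured", "sham"), timepoint = "d1",
                      edge_set = es, n_perm = n_perm, alpha = alpha, seed = seed))
  # family 2: treated vs vehicle on D(1->7d), apnea-adjusted
  add("treated_vs_vehicle_delta", cohort,
      contrast_spec("temporal_change", c("injury_treated", "injury_vehicle"),
                    edge_set = "low_md", covariates = "apnea",
                    n_perm = n_perm, alpha = alpha, seed = seed))
  # family 3: treated vs vehicle at d7, apnea-adjusted
  add("treated_vs_vehicle_d7", cohort,
      contrast_spec("cross_sectional", c("injury_treated", "injury_vehicle"),
                    timepoint = "d7", edge_set = "low_md", covariates = "apnea",
                    n_perm = n_perm, alpha = alpha, seed = seed))
  # family 4: each injured group vs sham at d7
  for (g in c("injury_vehicle", "injury_treated"))
    add(paste0(g, "_vs_sham_d7"), cohort,
        contrast_spec("cross_sectional", c(g, "sham"), timepoint = "d7",
                      edge_set = "low_md", n_perm = n_perm, alpha = alpha,
                      seed = seed))
  res
}
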