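test_that("band-pass preserves in-band and kills out-of-band components", {
  n <- 200
  t2 <- (0:(n - 1)) * 2                       # TR = 2 s
  sin05 <- sin(2 * pi * 0.05 * t2)            # 0.05 Hz: in band, 20 cycles
  ts <- parcel_timeseries(cbind(a = sin05, b = rnorm(n)), 2)
  f <- bandpass_filter(ts)
  expect_lt(abs(sd(f[, 1]) / sd(sin05) - 1), 0.05)

  t1 <- 0:(n - 1)                             # TR = 1 s, Nyquist 0.5
  sin04 <- sin(2 * pi * 0.4 * t1)             # 0.4 Hz: out of band
  ts1 <- parcel_timeseries(cbind(a = sin04, b = rnorm(n)), 1)
  f1 <- bandpass_filter(ts1)
  expect_lt(sd(f1[, 1]), 0.1 * sd(sin04))     # attenuated >= 90%
})

test_that("band-pass removes the mean and validates the band", {
  n <- 128
  x <- 5 + sin(2 * pi * 0.05 * (0:(n - 1)) * 2)
  ts <- parcel_timeseries(cbind(a = x, b = rnorm(n)), 2)
  f <- bandpass_filter(ts)
  expect_lt(abs(mean(f[, 1])), 1e-10)
  expect_error(bandpass_filter(ts, 0.01, 0.3), "Nyquist")  # 0.3 >= 0.25
  expect_error(bandpass_filter(ts, 0.2, 0.1), "low_hz")
})

test_that("constant columns are dropped at construction with a warning", {
  expect_warning(ts <- parcel_timeseries(cbind(a = rnorm(10), b = rep(2, 10)), 2),
                 "constant")
  expect_equal(ncol(ts), 1L)
  expect_identical(attr(ts, "parcel_ids"), "a")
  expect_error(parcel_timeseries(matrix(1, 1, 3), 2), ">= 2")
})

test_that("parcel series extraction averages voxels per parcel", {
  lab <- tiny_labels()
  d <- dim(lab$labels)
  # identity check: every voxel's value equals its label id
  frames <- lapply(1:3, function(t)
    volume(array(as.double(lab$labels), d), voxel_mm = lab$voxel_mm,
           space_tag = "toy"))
  ts <- extract_parcel_series(frames, lab, repetition_time_s = 2)
  for (p in 1:4) expect_true(all(ts[, as.character(p)] == p))

  # two-voxel parcel: column is the hand mean, single-voxel: the voxel itself
  lab2 <- label_volume(array(c(1L, 1L, 2L, 0L), c(4, 1, 1)),
                       data.frame(label_id = 1:2, name = c("a", "b"),
                                  hemisphere = c("ipsi", "contra"),
                                  tissue = "cortex"),
                       space_tag = "toy2")
  fr <- lapply(c(0, 1), function(t)
    volume(array(c(1, 3, 7, 9) + t, c(4, 1, 1)), space_tag = "toy2"))
  ts2 <- extract_parcel_series(fr, lab2)
  expect_equal(as.numeric(ts2[, "1"]), c(2, 3))     # mean(1,3), mean(2,4)
  expect_equal(as.numeric(ts2[, "2"]), c(7, 8))
})

test_that("parcels with zero voxels are dropped and recorded", {
  lab3 <- label_volume(array(c(1L, 1L, 1L, 0L), c(4, 1, 1)),
                       data.frame(label_id = 1:2, name = c("a", "ghost"),
                                  hemisphere = c("ipsi", "contra"),
                                  tissue = "cortex"),
                       space_tag = "t")
  fr <- lapply(1:3, function(t) volume(array(rnorm(4), c(4, 1, 1)),
                                       space_tag = "t"))
  ts <- extract_parcel_series(fr, lab3)
  expect_identical(attr(ts, "parcel_ids"), "1")
  expect_equal(as.integer(attr(ts, "dropped_parcels")), 2L)
})

test_that("common parcels are the intersection over subjects", {
  expect_setequal(common_parcels(list(s1 = c("A", "B", "C"),
                                      s2 = c("B", "C", "D"),
                                      s3 = c("B", "C"))), c("B", "C"))
  expect_setequal(common_parcels(list(s1 = 1:4, s2 = 1:4)), as.character(1:4))
  expect_setequal(common_parcels(list(s1 = c("A", "B"), s2 = c("A", "B", "C"),
                                      s3 = setdiff(c("A", "B"), "A"))), "B")
  expect_error(common_parcels(list(s1 = "A", s2 = "B")), "common")
  expect_error(common_parcels(list()), ">= 1")
})

test_that("fc_matrix matches the closed-form Fisher transform", {
  # construct a pair with sample correlation exactly 0.5
  n <- 400
  tt <- seq_len(n)
  u <- sin(2 * pi * 4 * tt / n)
  v <- cos(2 * pi * 4 * tt / n)                 # orthogonal, equal norm
  y <- 0.5 * u + sqrt(1 - 0.25) * v
  ts <- parcel_timeseries(cbind(x = u, y = y, w = rnorm(n)), 2)
  z <- fc_matrix(ts)
  expect_equal(cor(u, y), 0.5, tolerance = 1e-12)
  expect_equal(round(z["x", "y"], 4), 0.5493)
  expect_true(is.na(z["x", "x"]))
  expect_identical(unclass(z), t(unclass(z)))
})

test_that("fc_matrix handles degeneracy and affine invariance", {
  n <- 100
  x <- rnorm(n)
  ts <- parcel_timeseries(cbind(a = x, b = x, c = rnorm(n)), 2)
  z <- fc_matrix(ts)
  expect_true(is.finite(z["a", "b"]))
  expect_gt(z["a", "b"], 10)                    # clipped-large
  expect_true(attr(z, "clipped"))
  # affine rescaling of columns leaves z unchanged
  ts2 <- parcel_timeseries(cbind(a = 3 * x + 7, b = x, c = ts[, "c"] / 2), 2)
  expect_equal(unclass(fc_matrix(ts2)), unclass(z), tolerance = 1e-10)
  # long independent series: z near 0
  set.seed(23)
  ts3 <- parcel_timeseries(matrix(rnorm(5000 * 2), ncol = 2), 2)
  expect_lt(abs(fc_matrix(ts3)[1, 2]), 0.05)
})

test_that("edge sets partition all edges under both rules", {
  parcels <- c("A", "B", "C", "D")
  es <- build_edge_sets("A", parcels)
  expect_equal(nrow(es$low_md_edges), 3L)
  expect_setequal(paste(es$low_md_edges$i, es$low_md_edges$j),
                  c("A B", "A C", "A D"))
  expect_setequal(paste(es$normal_md_edges$i, es$normal_md_edges$j),
                  c("B C", "B D", "C D"))
  # empty and full low-MD sets
  e0 <- build_edge_sets(character(0), parcels)
  expect_equal(nrow(e0$low_md_edges), 0L)
  expect_equal(nrow(e0$normal_md_edges), 6L)
  eF <- build_edge_sets(parcels, parcels)
  expect_equal(nrow(eF$normal_md_edges), 0L)
  # property: partition holds for random subsets under both rules
  set.seed(4)
  ps <- as.character(1:9)
  for (i in 1:10) for (rule in c("any", "both")) {
    low <- sample(ps, sample(0:9, 1))
    es <- build_edge_sets(low, ps, rule = rule)
    keys <- function(df) paste(df$i, df$j)
    expect_setequal(c(keys(es$low_md_edges), keys(es$normal_md_edges)),
                    keys(all_edges(ps)))
    expect_length(intersect(keys(es$low_md_edges), keys(es$normal_md_edges)), 0L)
  }
  expect_error(build_edge_sets("Z", parcels), "subset")
})

test_that("low-MD parcel classification applies both cutoffs", {
  lab <- tiny_labels()                       # 4 parcels of 9 voxels each... (6x3x4/4=18)
  d <- dim(lab$labels)
  sizes <- table(lab$labels[lab$labels > 0])
  mask_with_fraction <- function(parcel, frac) {
    m <- array(FALSE, d)
    vox <- which(lab$labels == parcel)
    m[vox[seq_len(ceiling(frac * length(vox)))]] <- TRUE
    deficit_mask(m, "md", "t", voxel_mm = lab$voxel_mm, space_tag = "toy")
  }
  # parcel 1 at 12% of voxels in 6 of 10 subjects -> selected at defaults
  masks <- c(rep(list(mask_with_fraction(1, 0.12)), 6),
             rep(list(mask_with_fraction(1, 0.0)), 4))
  expect_identical(classify_lowmd_regions(masks, lab), "1")
  # below the subject fraction -> not selected
  masks2 <- c(rep(list(mask_with_fraction(1, 0.12)), 4),
              rep(list(mask_with_fraction(1, 0.0)), 6))
  expect_warning(sel2 <- classify_lowmd_regions(masks2, lab), "no parcel")
  expect_length(sel2, 0L)
  # lesion everywhere in parcel 2 for every subject -> selected
  masks3 <- rep(list(mask_with_fraction(2, 1)), 3)
  expect_true("2" %in% classify_lowmd_regions(masks3, lab))
})
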