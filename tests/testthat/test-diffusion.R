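scheme42 <- dwi_scheme(c(0, rep(2800, 42)),
                       rbind(c(0, 0, 0), fibonacci_directions(42)))

random_pd_tensor <- function() {
  ev <- sort(runif(3, 0.2e-3, 2.2e-3), decreasing = TRUE)
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  q %*% diag(ev) %*% t(q)
}

test_that("isotropic signal recovers MD analytically with FA = 0", {
  D <- diag(rep(0.7e-3, 3))
  s <- tensor_signal(D, scheme42, s0 = 1500)
  fit <- fit_tensor(matrix(s, 1), scheme42)
  expect_equal(fit$md, 0.7e-3, tolerance = 1e-9)
  expect_equal(fit$fa, 0, tolerance = 1e-7)
})

test_that("noiseless prolate tensor is recovered to 1e-6 relative", {
  ev <- c(1.7e-3, 0.3e-3, 0.3e-3)
  set.seed(31)
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  D <- q %*% diag(ev) %*% t(q)
  fit <- fit_tensor(matrix(tensor_signal(D, scheme42), 1), scheme42)
  expect_equal(fit$md, mean(ev), tolerance = 1e-6)
  fa_true <- sqrt(1.5 * sum((ev - mean(ev))^2) / sum(ev^2))
  expect_equal(fit$fa, fa_true, tolerance = 1e-6)
})

test_that("degenerate voxels are masked, not fatal", {
  sig <- rbind(rep(0, 43),                       # all-zero signal
               tensor_signal(diag(rep(1e-3, 3)), scheme42))
  fit <- fit_tensor(sig, scheme42)
  expect_true(is.na(fit$md[1]))
  expect_equal(fit$md[2], 1e-3, tolerance = 1e-9)
  expect_equal(fit$n_masked, 1L)
  # exactly 7 usable measurements still fit; 6 are masked
  sig2 <- tensor_signal(diag(rep(1e-3, 3)), scheme42)
  sig2[8:43] <- NA
  expect_equal(fit_tensor(matrix(sig2, 1), scheme42)$md, 1e-3,
               tolerance = 1e-8)
  sig3 <- sig2; sig3[7] <- NA
  expect_true(is.na(fit_tensor(matrix(sig3, 1), scheme42)$md))
})

test_that("scheme validation enforces b=0, direction count and unit norms", {
  expect_error(dwi_scheme(rep(2800, 42), fibonacci_directions(42)), "b=0")
  expect_error(dwi_scheme(c(0, rep(2800, 5)),
                          rbind(0, fibonacci_directions(5))), ">= 6")
  bad <- rbind(c(0, 0, 0), fibonacci_directions(42) * 1.01)
  expect_error(dwi_scheme(c(0, rep(2800, 42)), bad), "unit norm")
})

test_that("sham reference mean and SD follow closed forms", {
  base <- array(0.7, c(4, 4, 2))
  eps <- 0.01
  v1 <- volume(base, space_tag = "s")
  v2 <- volume(base + 2 * eps, space_tag = "s")
  ref <- build_sham_reference(list(v1, v2))
  expect_equal(ref$mean_map$data, base + eps)
  expect_true(all(abs(ref$sd_map$data - sqrt(2) * eps) < 1e-12))
  expect_equal(ref$n_sham, 2L)
  # identical volumes: SD zero everywhere -> empty-domain warning
  expect_warning(build_sham_reference(list(v1, v1)), "empty analysis domain")
  expect_error(build_sham_reference(list(v1)), ">= 2")
})

test_that("sham mean approaches the generator baseline at rate sd/sqrt(n)", {
  set.seed(8)
  base <- array(0.7, c(6, 6, 3))
  vols <- lapply(1:10, function(i)
    volume(base + array(rnorm(length(base), 0, 0.02), dim(base)),
           space_tag = "s"))
  ref <- build_sham_reference(vols)
  expect_lt(max(abs(ref$mean_map$data - base)), 0.02 / sqrt(10) * 4)
})

test_that("z-maps are exact at the boundary and zero at the sham mean", {
  set.seed(9)
  base <- array(0.7, c(5, 5, 2))
  vols <- lapply(1:6, function(i)
    volume(base + array(rnorm(50, 0, 0.02), dim(base)), space_tag = "s"))
  ref <- build_sham_reference(vols)
  z0 <- md_zmap(volume(ref$mean_map$data, space_tag = "s"), ref)
  expect_true(all(abs(z0$data) < 1e-12))
  z17 <- md_zmap(volume(ref$mean_map$data - 1.7 * ref$sd_map$data,
                        space_tag = "s"), ref)
  expect_true(all(abs(z17$data + 1.7) < 1e-10))
  # strict threshold: {-1.69, -1.70, -1.71} -> exactly one voxel
  zm <- z0
  zm$data[1:3] <- c(-1.69, -1.70, -1.71)
  m <- low_md_mask(zm, 1.7)
  expect_equal(sum(m$mask), 1L)
  expect_true(m$mask[3])
  expect_error(low_md_mask(zm, -1), "> 0")
})

test_that("persistent low-MD volume is the voxel-counted AND", {
  d <- c(10, 10, 4)
  m1 <- array(FALSE, d); m1[1:100] <- TRUE
  mk <- function(m, tp) deficit_mask(m, "md", "test", subject = "s1",
                                     timepoint = tp,
                                     voxel_mm = c(0.25, 0.25, 0.25),
                                     space_tag = "s")
  res <- persistent_low_md(mk(m1, "d1"), mk(m1, "d7"))
  expect_equal(res$volume_mm3, 100 * 0.25^3)   # 1.5625 mm^3
  expect_equal(res$volume_mm3, 1.5625)
  # disjoint masks
  m2 <- array(FALSE, d); m2[101:150] <- TRUE
  expect_equal(persistent_low_md(mk(m1, "d1"), mk(m2, "d7"))$volume_mm3, 0)
  # subset identity
  m3 <- array(FALSE, d); m3[1:40] <- TRUE
  res3 <- persistent_low_md(mk(m1, "d1"), mk(m3, "d7"))
  expect_identical(res3$mask$mask, m3)
  expect_error(persistent_low_md(mk(m1, "d1"), mk(m1, "d1")), "same timepoint")
})

test_that("persistent volume never exceeds either timepoint's volume", {
  set.seed(14)
  d <- c(8, 8, 4)
  for (i in 1:20) {
    a <- array(runif(prod(d)) < 0.3, d)
    b <- array(runif(prod(d)) < 0.3, d)
    mk <- function(m, tp) deficit_mask(m, "md", "t", timepoint = tp,
                                       voxel_mm = c(1, 1, 1), space_tag = "s")
    v <- persistent_low_md(mk(a, "d1"), mk(b, "d7"))$volume_mm3
    expect_lte(v, min(sum(a), sum(b)))
  }
})
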