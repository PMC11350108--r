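test_that("dispersion95 follows the linear-interpolation percentile definition", {
  expect_equal(dispersion95(rep(7, 25)), 0)
  expect_equal(dispersion95(seq(0, 100, length.out = 1001)), 95)
  # sort-and-interpolate oracle on random data
  set.seed(42)
  x <- rnorm(137, 50, 12)
  s <- sort(x)
  h <- function(p) {
    k <- (length(s) - 1) * p + 1
    s[floor(k)] + (k - floor(k)) * (s[floor(k) + 1] - s[floor(k)])
  }
  expect_equal(dispersion95(x), h(0.975) - h(0.025), tolerance = 1e-12)
  expect_error(dispersion95(1:5), "at least 10")
  # permutation invariance and shift equivariance
  expect_equal(dispersion95(sample(x)), dispersion95(x))
  expect_equal(dispersion95(x + 13.7), dispersion95(x))
})

test_that("plane-fit gradient is exact on linear fields and zero on constants", {
  m <- planar_mesh(6, 6, spacing = 2)
  vals <- 0.5 * m$vertices[, 1]  # 0.5 ms/mm along x
  expect_equal(mean_spatial_gradient(m, vals, radius = 5), 0.5,
               tolerance = 1e-10)
  expect_equal(mean_spatial_gradient(m, rep(3, nrow(m$vertices)), 5), 0)
})

test_that("mean gradient matches a brute-force per-node plane-fit oracle", {
  m <- cloud_mesh(n = 50, scale = 12, seed = 11)
  set.seed(2)
  vals <- rnorm(50, 100, 10)
  d <- as.matrix(dist(m$vertices))
  oracle <- vapply(1:50, function(i) {
    pts <- c(i, setdiff(which(d[i, ] <= 5), i))
    if (length(pts) < 3) return(NA_real_)
    A <- sweep(m$vertices[pts, , drop = FALSE], 2,
               colMeans(m$vertices[pts, , drop = FALSE]))
    b <- vals[pts] - mean(vals[pts])
    sv <- svd(A)
    keep <- sv$d >= 0.1 * sv$d[1]
    g <- sv$v[, keep, drop = FALSE] %*%
      ((t(sv$u[, keep, drop = FALSE]) %*% b) / sv$d[keep])
    sqrt(sum(g^2))
  }, numeric(1))
  expect_equal(mean_spatial_gradient(m, vals, 5), mean(oracle, na.rm = TRUE),
               tolerance = 1e-9)
  per_node <- mean_spatial_gradient(m, vals, 5, per_node = TRUE)
  expect_equal(per_node, oracle, tolerance = 1e-9)
})

test_that("gradient metric is invariant to field offsets and rigid mesh motion", {
  m <- cloud_mesh(n = 40, scale = 10, seed = 5)
  set.seed(9)
  vals <- rnorm(40, 60, 8)
  g0 <- mean_spatial_gradient(m, vals, 5)
  expect_equal(mean_spatial_gradient(m, vals + 25, 5), g0, tolerance = 1e-10)
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  m2 <- epi_mesh(m$vertices %*% R + 5, m$faces)
  expect_equal(mean_spatial_gradient(m2, vals, 5), g0, tolerance = 1e-8)
})

test_that("marker extraction equals brute-force derivative-scan oracles", {
  egm <- average_one(canonical_egm(at = 40, rt = 290)$trace)
  d <- delineate_egm(egm)
  t0 <- d$qrs_on
  lat <- local_activation_time(egm, d, t0)
  lrt <- local_repolarization_time(egm, d, t0)
  # oracle: exhaustive scan over the smoothed finite-difference derivative
  sd <- epimapr:::smoothed_derivative(egm$voltage, egm$fs)
  qi <- d$qrs_on:d$qrs_off
  expect_equal(lat, (qi[which.min(sd[qi])] - t0) * 1000 / egm$fs,
               tolerance = 2)  # sub-sample refinement stays within the bin
  ti <- d$t_on:d$t_off
  expect_equal(lrt, (ti[which.max(sd[ti])] - t0) * 1000 / egm$fs,
               tolerance = 2)
  # configured events recovered within one sample
  expect_equal(lat, 40, tolerance = 1)
  expect_equal(lrt, 290, tolerance = 1)
})

test_that("LAT is translation-equivariant with the time reference held fixed", {
  egm <- average_one(canonical_egm(at = 40, rt = 290)$trace)
  d <- delineate_egm(egm)
  t0 <- d$qrs_on
  lat0 <- local_activation_time(egm, d, t0)
  shift <- 10
  egm2 <- egm
  egm2$voltage <- c(rep(egm$voltage[1], shift), utils::head(egm$voltage, -shift))
  d2 <- d
  d2$qrs_on <- d$qrs_on + shift; d2$qrs_off <- d$qrs_off + shift
  expect_equal(local_activation_time(egm2, d2, t0), lat0 + shift,
               tolerance = 0.5)
})

test_that("Wyatt timing works identically for inverted T waves", {
  egm <- average_one(canonical_egm(at = 40, rt = 310, pol = -1)$trace)
  d <- delineate_egm(egm)
  expect_equal(local_repolarization_time(egm, d, d$qrs_on), 310,
               tolerance = 1)
})

test_that("ARI is the LRT-LAT difference and non-positive values flag the node", {
  a <- activation_recovery_interval(40, 290)
  expect_equal(as.numeric(a), 250)
  expect_true(attr(a, "valid"))
  b <- activation_recovery_interval(40, 40)
  expect_equal(as.numeric(b), 0)
  expect_false(attr(b, "valid"))
})

test_that("global QRS start is the exhaustive minimum over accepted nodes", {
  delins <- lapply(c(120, 115, 130), function(on)
    list(qrs_on = on, quality = "accepted"))
  delins[[4]] <- list(qrs_on = 90, quality = "rejected_no_t")
  expect_equal(global_qrs_start(delins), 115)
  set.seed(1)
  ons <- sample(80:200, 25)
  delins <- lapply(ons, function(on) list(qrs_on = on, quality = "accepted"))
  expect_equal(global_qrs_start(delins), min(ons))
  expect_error(global_qrs_start(list(list(qrs_on = 5, quality = "rejected_no_t"))),
               "empty map")
})

test_that("heart metrics are internally consistent (linearity, bookkeeping)", {
  m <- small_spheroid()
  n <- nrow(m$vertices)
  set.seed(8)
  lat <- rnorm(n, 55, 10)
  ari <- rnorm(n, 230, 20)
  mk <- data.frame(node_id = 1:n, lat_ms = lat, lrt_ms = lat + ari,
                   ari_ms = ari, accepted = TRUE, reason = "accepted")
  hm <- heart_metrics(mk, m)
  expect_equal(hm$mean_ari, mean(lat + ari) - mean(lat), tolerance = 1e-10)
  expect_equal(hm$nodes_used, n)
  # excluding k nodes changes the bookkeeping by exactly k
  mk2 <- mk
  drop <- sample(n, 7)
  mk2$accepted[drop] <- FALSE
  hm2 <- heart_metrics(mk2, m)
  expect_equal(hm2$nodes_used, n - 7)
  expect_equal(hm2$nodes_rejected, 7)
  # identical markers: zero dispersion and zero gradient
  mk3 <- data.frame(node_id = 1:n, lat_ms = 50, lrt_ms = 280, ari_ms = 230,
                    accepted = TRUE, reason = "accepted")
  hm3 <- heart_metrics(mk3, m)
  expect_equal(hm3$disp_at, 0)
  expect_equal(hm3$grad_at, 0)
})

test_that("Bazett correction has the declared fixed points and monotonicity", {
  expect_equal(rate_correct(400, 1), 400)
  expect_equal(rate_correct(400, 0.64), 500)
  rr <- seq(1.2, 0.5, by = -0.1)
  expect_true(all(diff(rate_correct(380, rr)) > 0))
  expect_error(rate_correct(400, 0), "positive")
})
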