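unit_rows <- function(m) m / sqrt(rowSums(m^2))

test_that("unit-sphere mapping normalizes sites by vesicle radius", {
  r <- 27.5
  ves <- vrow("v1", z = r, radius = r)
  pole <- c(0, 0, 2 * r)               # center + (0, 0, r)
  eq <- c(r, 0, r)                     # center + (r, 0, 0)
  set.seed(31)
  u_rand <- unit(rnorm(3))
  rand_site <- c(0, 0, r) + r * u_rand
  fils <- rbind(
    frow("f1", "rib", rbind(c(0, 0, r + 5), pole), av = "v1"),
    frow("f2", "rib", rbind(c(2 * r, 0, r), eq), av = "v1"),
    frow("f3", "boom", rbind(rand_site + 10 * u_rand, rand_site), av = "v1")
  )
  s <- scene_of(ves, fils)
  m <- mapToUnitSphere(s, "v1")
  expect_equal(m$u[1, ], c(0, 0, 1), tolerance = 1e-9)
  expect_equal(m$u[2, ], c(1, 0, 0), tolerance = 1e-9)
  expect_lt(abs(sqrt(sum(m$u[3, ]^2)) - 1), 1e-9)
  # rescaling returns the original site exactly
  expect_equal(c(0, 0, r) + r * m$u[3, ], rand_site, tolerance = 1e-9)

  off <- s
  off@filaments$path[[3]][2, ] <- rand_site + 4 * u_rand
  expect_error(mapToUnitSphere(off, "v1"), class = "azm_surface_error")
  expect_error(mapToUnitSphere(s, "ghost"), class = "azm_reference_error")
})

test_that("rough alignment carries the mean site direction onto +x", {
  mk_map <- function(u) {
    methods::new("SphereMap", vesicle_ids = "a",
                 sites = list(list(class = rep("rib", nrow(u)), u = u)),
                 rotations = list(diag(3)))
  }
  set.seed(32)
  near_x <- unit_rows(cbind(1, matrix(rnorm(6, 0, 0.05), 3, 2)))
  m <- roughAlign(mk_map(near_x))
  # sites already centered on +x: rotation stays (near) identity
  expect_lt(azmetrics:::rotation_angle(m@rotations[[1]]), 0.1)

  near_negx <- -near_x
  m2 <- roughAlign(mk_map(near_negx))
  mean_dir <- unit(colMeans(m2@sites[[1]]$u))
  expect_equal(mean_dir, c(1, 0, 0), tolerance = 1e-9)

  antipodal <- rbind(c(0, 0, 1), c(0, 0, -1))
  expect_warning(m3 <- roughAlign(mk_map(antipodal)), "zero mean")
  expect_equal(m3@rotations[[1]], diag(3))

  s <- generateRestingScene(defaultSceneConfig(band_length = 250), seed = 33)
  sm <- roughAlign(sphereMap(s))
  for (i in seq_along(sm@vesicle_ids))
    expect_equal(unit(colMeans(sm@sites[[i]]$u)), c(1, 0, 0), tolerance = 1e-9)
})

test_that("rib overlap matches closed forms and its invariances", {
  mk_map <- function(us, classes = NULL) {
    methods::new("SphereMap", vesicle_ids = letters[seq_along(us)],
                 sites = lapply(us, function(u)
                   list(class = if (is.null(classes)) rep("rib", nrow(u))
                        else classes, u = u)),
                 rotations = rep(list(diag(3)), length(us)))
  }
  coincident <- mk_map(list(matrix(c(1, 0, 0), 1), matrix(c(1, 0, 0), 1)))
  expect_equal(ribOverlap(coincident, 0.3), 1)

  antip <- mk_map(list(matrix(c(0, 0, 1), 1), matrix(c(0, 0, -1), 1)))
  expect_equal(ribOverlap(antip, 0.3), exp(-pi^2 / (2 * 0.09)), tolerance = 1e-12)

  set.seed(34)
  us <- lapply(1:3, function(i) unit_rows(matrix(rnorm(12), 4, 3)))
  m <- mk_map(us)
  o <- ribOverlap(m, 0.3)
  # invariant under one common rotation of all vesicles
  R <- random_rotation()
  mr <- mk_map(lapply(us, function(u) u %*% t(R)))
  expect_lt(abs(ribOverlap(mr, 0.3) - o), 1e-9)
  # symmetric under relabeling vesicles
  mp <- mk_map(us[c(3, 1, 2)])
  expect_lt(abs(ribOverlap(mp, 0.3) - o), 1e-12)

  none <- mk_map(list(matrix(c(0, 0, 1), 1)), classes = "boom")
  expect_warning(expect_equal(ribOverlap(none, 0.3), 0), "no rib sites")
  expect_error(ribOverlap(m, 0), class = "azm_argument_error")
})

test_that("fine alignment recovers a known rotation within 5 degrees", {
  set.seed(35)
  u0 <- unit_rows(matrix(rnorm(12), 4, 3))
  for (bw in c(0.2, 0.3, 0.4)) {
    Rt <- random_rotation()
    m <- methods::new("SphereMap", vesicle_ids = c("a", "b"),
                      sites = list(list(class = rep("rib", 4), u = u0),
                                   list(class = rep("rib", 4), u = u0 %*% t(Rt))),
                      rotations = list(diag(3), diag(3)))
    res <- fineAlign(m, bandwidth = bw, grid_deg = 10)
    # after alignment the two site sets coincide: the recovered relative
    # rotation is within 5 degrees (geodesic) of the true inverse
    Rrel <- t(res@map@rotations[[2]]) %*% res@map@rotations[[1]]
    expect_lt(azmetrics:::rotation_distance(Rrel, Rt) * 180 / pi, 5)
  }
})

test_that("fine alignment is a fixed point for pre-aligned identical vesicles", {
  set.seed(36)
  u0 <- unit_rows(matrix(rnorm(9), 3, 3))
  m <- methods::new("SphereMap", vesicle_ids = c("a", "b", "c"),
                    sites = rep(list(list(class = rep("rib", 3), u = u0)), 3),
                    rotations = rep(list(diag(3)), 3))
  o0 <- ribOverlap(m, 0.3)
  res <- fineAlign(m, bandwidth = 0.3, grid_deg = 20)
  expect_equal(res@objective, o0, tolerance = 1e-9)
  for (R in res@map@rotations)
    expect_lt(azmetrics:::rotation_angle(R), 1e-6)
  expect_true(res@converged)
})

test_that("fine alignment reaches the exhaustive 5-degree grid oracle", {
  set.seed(37)
  u1 <- unit_rows(matrix(rnorm(9), 3, 3))
  u2 <- unit_rows(matrix(rnorm(9), 3, 3))
  m <- methods::new("SphereMap", vesicle_ids = c("a", "b"),
                    sites = list(list(class = rep("rib", 3), u = u1),
                                 list(class = rep("rib", 3), u = u2)),
                    rotations = list(diag(3), diag(3)))
  res <- fineAlign(m, bandwidth = 0.3, grid_deg = 10)
  oracle <- grid_align_oracle(u1, u2, bandwidth = 0.3, step_deg = 5)
  expect_gte(res@objective, oracle - 1e-6)
})

test_that("alignment objective increases monotonically and beats rough alignment", {
  s <- generateRestingScene(defaultSceneConfig(band_length = 250), seed = 38)
  sm <- roughAlign(sphereMap(s))
  o_rough <- ribOverlap(sm)
  res <- fineAlign(sm, grid_deg = 20)
  expect_true(all(diff(res@trace) >= -1e-9))
  expect_gt(res@objective, o_rough)
  expect_output(show(res), "objective")
})

test_that("class centroid depths normalize to the rib centroid per vesicle", {
  r <- 27.5
  mk <- function(id, class, z, phi) {
    site <- sphere_point(0, 0, r, r, z, phi)
    frow(id, class, rbind(site + c(-12, 2, -1), site), av = "v1")
  }
  s <- scene_of(vrow("v1", z = r, radius = r),
                rbind(mk("r1", "rib", 6, 160), mk("r2", "rib", 10, 200),
                      mk("s1", "spar", 18, 180)))
  out <- classCentroidDepths(s)
  expect_equal(out$depth_mean[out$class == "rib"], 8)
  expect_equal(out$offset_mean[out$class == "spar"], 10)
  expect_identical(out$n[out$class == "boom"], 0L)

  ribs_only <- scene_of(vrow("v1", z = r, radius = r),
                        rbind(mk("r1", "rib", 6, 160), mk("r2", "rib", 10, 200)))
  out2 <- classCentroidDepths(ribs_only)
  expect_true(all(is.na(out2$offset_mean[out2$class %in% c("spar", "boom")])))
})

test_that("one-way ANOVA separates class depth distributions", {
  same <- data.frame(class = rep(c("a", "b", "c"), each = 3), depth = 5)
  res <- classSeparationAnova(same)
  expect_equal(res$F, 0)
  expect_equal(res$p, 1)

  two <- data.frame(class = rep(c("a", "b"), each = 3),
                    depth = c(1, 2, 3, 11, 12, 13))
  res2 <- classSeparationAnova(two)
  # hand computation: SSB = 3*(2-7)^2 + 3*(12-7)^2 = 150 on 1 df;
  # SSW = 2 + 2 = 4 on 4 df, so F = 150 / 1 = 150
  expect_equal(res2$F, 150)
  expect_equal(res2$p, anova(lm(depth ~ class, two))$`Pr(>F)`[1])

  expect_error(classSeparationAnova(data.frame(class = "a", depth = 1)),
               class = "azm_argument_error")
})
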