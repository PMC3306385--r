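test_that("arc length measures polylines along the midline", {
  expect_equal(arcLength(rbind(c(0, 0, 0), c(0, 0, 9))), 9)
  expect_equal(arcLength(rbind(c(0, 0, 0), c(3, 4, 0), c(3, 4, 12))), 17)
  expect_error(arcLength(matrix(c(0, 0, 0), 1, 3)), class = "azm_argument_error")
})

test_that("filament length is invariant under rigid motions", {
  s <- generateRestingScene(defaultSceneConfig(band_length = 200), seed = 21)
  len0 <- filamentLengths(s)$length
  set.seed(99)
  for (i in 1:100) {
    R <- random_rotation()
    t <- rnorm(3, 0, 50)
    moved <- s
    moved@filaments$path <- rigid_transform_paths(s@filaments$path, R, t)
    expect_lt(max(abs(filamentLengths(moved)$length - len0)), 1e-9)
  }
})

test_that("compression ratio estimation is exact by construction", {
  s <- generateRestingScene(defaultSceneConfig(band_length = 250), seed = 22)
  est <- estimateCompressionRatio(s)
  expect_equal(est$ratio, 1)
  expect_equal(est$sd, 0)
  expect_lt(abs(estimateCompressionRatio(applyZCompression(s, 0.805))$ratio - 0.805),
            1e-6)
  expect_equal(estimateCompressionRatio(applyZCompression(s, 0.5))$ratio, 0.5)
  expect_error(estimateCompressionRatio(scene_of()), class = "azm_argument_error")
})

test_that("stretch correction follows the compression protocol", {
  s <- generateRestingScene(defaultSceneConfig(band_length = 250), seed = 23)
  expect_equal(vesicles(zStretchCorrect(s, 1)), vesicles(s))
  sc <- applyZCompression(s, 0.805)
  corrected <- zStretchCorrect(sc, 1.2)
  expect_equal(estimateCompressionRatio(corrected)$ratio, 0.966)
  # protocol: stretch by 1.2 only when the estimated ratio is below 0.9
  auto <- zStretchProtocol(sc)
  expect_equal(sceneMetadata(auto)$stretch_applied, 1.2)
  expect_equal(estimateCompressionRatio(auto)$ratio, 0.966)
  noop <- zStretchProtocol(s)
  expect_equal(sceneMetadata(noop)$stretch_applied, 1)
  expect_error(zStretchCorrect(s, 0), class = "azm_argument_error")
})

test_that("compression round trip restores a unit ratio to 1e-9", {
  s <- generateRestingScene(defaultSceneConfig(band_length = 200), seed = 24)
  for (r in c(0.805, 0.5, 0.93)) {
    rt <- zStretchCorrect(applyZCompression(s, r), 1 / r)
    expect_lt(abs(estimateCompressionRatio(rt)$ratio - 1), 1e-9)
  }
})

test_that("step spacing lists consecutive centroid distances along the band", {
  mk_step <- function(id, y) frow(id, "step", rbind(c(0, y - 14, 21), c(0, y + 14, 21)),
                                  diameter = 21.8, dv = 13.9)
  s <- scene_of(fils = rbind(mk_step("s1", 0), mk_step("s2", 50)))
  expect_equal(stepCenterSpacing(s), 50)
  s3 <- scene_of(fils = rbind(mk_step("s1", 0), mk_step("s3", 100), mk_step("s2", 48)))
  expect_equal(stepCenterSpacing(s3), c(48, 52))
  expect_identical(stepCenterSpacing(scene_of(fils = mk_step("s1", 0))), numeric())
})

test_that("angle of approach implements the unsigned projection protocol", {
  r <- 27.5
  mk <- function(id, dir, class = "rib") {
    site <- sphere_point(0, 0, r, r, 8, 180)
    frow(id, class, rbind(site - 20 * dir / sqrt(sum(dir^2)), site), av = "v1")
  }
  s <- scene_of(vrow("v1", z = r, radius = r),
                rbind(mk("f1", c(1, 0, 0.3)), mk("f2", c(1, 1, 0)),
                      mk("f3", c(-1, 1, 0))))
  a <- angleOfApproach(s)
  expect_equal(a$angle, c(0, 45, 45), tolerance = 1e-9)

  vert <- scene_of(vrow("v1", z = r, radius = r), mk("f1", c(0, 0, 1)))
  expect_error(angleOfApproach(vert), class = "azm_undefined_angle_error")
})

test_that("angle of approach is invariant under band translation and x reflection", {
  s <- generateRestingScene(defaultSceneConfig(band_length = 200), seed = 25)
  a0 <- angleOfApproach(s)$angle
  shifted <- s
  shifted@filaments$path <- lapply(s@filaments$path, function(p) {
    p[, 2] <- p[, 2] + 123.4; p
  })
  expect_equal(angleOfApproach(shifted)$angle, a0, tolerance = 1e-9)
  mirrored <- s
  mirrored@filaments$path <- lapply(s@filaments$path, function(p) {
    p[, 1] <- -p[, 1]; p
  })
  expect_equal(angleOfApproach(mirrored)$angle, a0, tolerance = 1e-9)
})

test_that("connection counts tabulate per-vesicle class bindings", {
  r <- 27.5
  empty <- scene_of(vrow("v1", z = r, radius = r))
  cc <- connectionCounts(empty)
  expect_true(all(cc[, c("rib", "spar", "boom", "pin", "main_body")] == 0))

  mk <- function(id, class, z, phi) {
    site <- sphere_point(0, 0, r, r, z, phi)
    frow(id, class, rbind(site + c(-15, 3, -2), site), av = "v1")
  }
  fils <- do.call(rbind, c(
    lapply(1:4, function(i) mk(paste0("r", i), "rib", 8, 130 + 20 * i)),
    lapply(1:2, function(i) mk(paste0("s", i), "spar", 18, 150 + 30 * i)),
    lapply(1:5, function(i) mk(paste0("b", i), "boom", 32, 130 + 18 * i)),
    lapply(1:4, function(i) {
      site <- sphere_point(0, 0, r, r, 8, -40 + 25 * i)
      frow(paste0("p", i), "pin", rbind(c(site[1], site[2], 0), site),
           av = "v1", am = TRUE)
    })
  ))
  s <- scene_of(vrow("v1", z = r, radius = r), fils)
  cc <- connectionCounts(s)
  expect_identical(unname(unlist(cc[1, c("rib", "spar", "boom", "pin")])),
                   c(4, 2, 5, 4))
  expect_identical(cc$main_body, 11)
})

test_that("pin lengths group by vesicle docking state", {
  none <- pinLengthByState(scene_of(vrow("v1")))
  expect_identical(nrow(none), 0L)

  r <- 27.5
  mkpin <- function(id, vid, cx, z) {
    site <- sphere_point(cx, 0, vesz(vid), r, z, 20)
    frow(id, "pin", rbind(c(site[1], site[2], 0), site), av = vid, am = TRUE)
  }
  vesz <- function(vid) if (vid == "d1") r else r + 12
  ves <- rbind(vrow("d1", z = r, radius = r),
               vrow("u1", x = 100, z = r + 12, radius = r, state = "undocked"))
  fils <- rbind(mkpin("p1", "d1", 0, 8), mkpin("p2", "d1", 0, 10),
                mkpin("p3", "u1", 100, 20), mkpin("p4", "u1", 100, 24))
  s <- scene_of(ves, fils)
  out <- pinLengthByState(s)
  expect_setequal(out$state, c("docked", "undocked"))
  expect_equal(out$mean[out$state == "docked"], 9)     # vertical pins: length = site z
  expect_equal(out$mean[out$state == "undocked"], 22)
  expect_identical(out$n, c(2L, 2L))
})

test_that("morphometry summary mirrors the dimensions-table layout", {
  s <- generateRestingScene(seed = 26)
  ms <- morphometrySummary(s)
  expect_identical(ms@dimensions$class,
                   c("beam", "step", "mast", "rib", "pin", "spar", "boom", "topmast"))
  expect_true(all(ms@dimensions$length_n == table(filaments(s)$class)[ms@dimensions$class]))
  # sample SDs use the n-1 denominator
  rib_len <- filamentLengths(s, "rib")$length
  expect_equal(ms@dimensions$length_sd[ms@dimensions$class == "rib"], sd(rib_len))
  expect_output(show(ms), "step spacing")
})
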