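test_that("default resting scenes are valid with the expected band layout", {
  s <- generateRestingScene(seed = 1)
  expect_identical(nrow(validateScene(s)), 0L)
  n_steps <- sum(filaments(s)$class == "step")
  expect_gte(n_steps, 6)   # 500 nm band at ~50 nm spacing
  expect_lte(n_steps, 14)
  vs <- vesicles(s)
  expect_true(all(table(vs$row_side[vs$state == "docked"]) >= 2))
  # docked vesicle diameters inside the configured uniform range
  dk <- vs[vs$state == "docked", ]
  expect_true(all(dk$radius >= 25 & dk$radius <= 30))
})

test_that("generation is deterministic given (config, seed)", {
  cfg <- defaultSceneConfig(band_length = 300)
  f1 <- tempfile(); f2 <- tempfile(); f3 <- tempfile()
  writeScene(generateRestingScene(cfg, seed = 7), f1)
  writeScene(generateRestingScene(cfg, seed = 7), f2)
  writeScene(generateRestingScene(cfg, seed = 8), f3)
  expect_identical(readLines(f1), readLines(f2))
  expect_false(identical(readLines(f1), readLines(f3)))
})

test_that("degenerate config (all SDs zero) fixes counts at rounded means", {
  cfg <- degenerate_config()
  s <- generateRestingScene(cfg, seed = 3)
  expect_identical(nrow(validateScene(s)), 0L)
  sp <- stepCenterSpacing(s)
  expect_equal(sp, rep(48.8, length(sp)), tolerance = 1e-9)
  cc <- connectionCounts(s)
  dk <- cc[cc$state == "docked", ]
  expect_true(all(dk$rib == 4))    # round(3.9)
  expect_true(all(dk$spar == 2))   # round(2.2)
  expect_true(all(dk$pin == 4))    # round(4.1), range 3-5
  # round(10.6) = 11 booms per mast shared over 4 tetrad slots: each
  # vesicle receives 2-3 from each of its two flanking masts
  expect_true(all(dk$boom >= 4 & dk$boom <= 6))
  fs <- filaments(s)
  boom_by_mast <- table(fs$attach_filament[fs$class == "boom"])
  expect_true(all(boom_by_mast <= 11))
  # fixed class dimensions are reproduced exactly by measurement
  fl <- filamentLengths(s)
  expect_equal(fl$length[fl$class == "rib"],
               rep(27.9, sum(fl$class == "rib")), tolerance = 1e-9)
  ang <- angleOfApproach(s)
  expect_equal(ang$angle[ang$class == "spar"],
               rep(23.3, sum(ang$class == "spar")), tolerance = 1e-9)
})

test_that("generator statistics converge to the configured means", {
  ang <- list(); len <- list(); cnt <- list(); sp <- c()
  for (seed in 1:10) {
    s <- generateRestingScene(seed = seed)
    ang[[seed]] <- angleOfApproach(s)
    len[[seed]] <- filamentLengths(s)
    sp <- c(sp, stepCenterSpacing(s))
    cc <- connectionCounts(s)
    cnt[[seed]] <- cc[cc$state == "docked", ]
  }
  a <- do.call(rbind, ang); l <- do.call(rbind, len); k <- do.call(rbind, cnt)
  # 3 SE of the empirical mean, plus a small allowance for the documented
  # truncation/folding/rounding biases of the draws
  expect_lt(abs(mean(l$length[l$class == "rib"]) - 27.9),
            3 * sd(l$length[l$class == "rib"]) / sqrt(sum(l$class == "rib")) + 0.1)
  expect_lt(abs(mean(sp) - 48.8), 3 * sd(sp) / sqrt(length(sp)) + 0.5)
  expect_lt(abs(mean(k$rib) - 3.9), 3 * sd(k$rib) / sqrt(nrow(k)) + 0.05)
  expect_lt(abs(mean(k$pin) - 4.1), 3 * sd(k$pin) / sqrt(nrow(k)) + 0.05)
  expect_lt(abs(mean(a$angle[a$class == "boom"]) - 30.0),
            3 * sd(a$angle[a$class == "boom"]) / sqrt(sum(a$class == "boom")) + 0.3)
})

test_that("rib and pin sites ring the fusion domain below the spar sites", {
  s <- generateRestingScene(seed = 4)
  cs <- connectionSites(s)
  vs <- vesicles(s)
  above <- 0L; ring_total <- 0L
  for (v in vs$id[vs$state == "docked"]) {
    sub <- cs[cs$vesicle_id == v, ]
    ring <- sub[sub$class %in% c("rib", "pin"), ]
    spar_z <- mean(sub$z[sub$class == "spar"])
    if (!nrow(ring) || !is.finite(spar_z)) next
    # ring sites stay in the superficial layer, with their centroid
    # superficial to the spar centroid (the depth bands themselves overlap
    # slightly, as in the published site maps)
    expect_true(all(ring$z <= 15 + 1e-9))
    expect_lt(mean(ring$z), spar_z)
    above <- above + sum(ring$z >= spar_z)
    ring_total <- ring_total + nrow(ring)
    # azimuthal span around the contact point exceeds 180 degrees
    ctr <- vs[vs$id == v, ]
    az <- sort(atan2(ring$y - ctr$y, ring$x - ctr$x) * 180 / pi)
    gaps <- diff(c(az, az[1] + 360))
    expect_gt(360 - max(gaps), 180)
  }
  expect_gt(ring_total, 0L)
  expect_lt(above / ring_total, 0.2)
})

test_that("activated scenes wire undocked vesicles by distance bin", {
  s <- generateActivatedScene(seed = 2)
  expect_identical(nrow(validateScene(s)), 0L)
  vs <- vesicles(s)
  expect_true(any(vs$state == "vacated_marker"))
  expect_true(any(vs$state == "undocked"))
  expect_identical(sum(vs$state == "fused_omega"), 1L)
  # the fused vesicle keeps a full main-body complement but no pins
  cc <- connectionCounts(s)
  fo <- cc[cc$state == "fused_omega", ]
  expect_gte(fo$main_body, 5)
  expect_identical(fo$pin, 0)
  # undocked vesicles at vacated sites only get pins within 15 nm
  und <- sceneMetadata(s)$undocked_at_vacated
  d <- shortestDistanceToMembrane(s, und)
  haspin <- cc$pin[match(und, cc$vesicle_id)] > 0
  expect_true(all(d[haspin] <= 15))
})

test_that("mean main-body connections fall from near to far bins", {
  counts <- list()
  for (seed in 1:8) {
    s <- generateActivatedScene(seed = seed)
    g <- binUndocked(s)
    cc <- connectionCounts(s)
    for (b in setdiff(names(g), "unbinned")) {
      sub <- cc[cc$vesicle_id %in% g[[b]], ]
      if (nrow(sub)) { sub$bin <- b; counts[[length(counts) + 1L]] <- sub }
    }
  }
  k <- do.call(rbind, counts)
  m <- sapply(split(k$main_body, k$bin), mean)
  expect_lt(m[["29-42"]], m[["17-24"]])
  expect_lt(m[["17-24"]], m[["4-16"]])
  expect_true(all(k$rib[k$bin == "29-42"] == 0))
})

test_that("zeroed bin rules leave undocked vesicles unconnected; fixed rules give exact counts", {
  cfg <- defaultSceneConfig()
  cfg$bin_rules$boom_mean[] <- 0; cfg$bin_rules$boom_sd[] <- 0
  cfg$bin_rules$spar_mean[] <- 0; cfg$bin_rules$spar_sd[] <- 0
  cfg$bin_rules$rib_mean[] <- 0; cfg$bin_rules$rib_sd[] <- 0
  cfg$bin_rules$pins[] <- FALSE
  s <- generateActivatedScene(cfg, seed = 5)
  cc <- connectionCounts(s)
  und <- sceneMetadata(s)$undocked_at_vacated
  expect_true(all(cc$main_body[match(und, cc$vesicle_id)] == 0))

  cfg2 <- defaultSceneConfig()
  cfg2$bin_rules$boom_sd[] <- 0
  cfg2$bin_rules$spar_sd[] <- 0
  cfg2$bin_rules$rib_sd[] <- 0
  s2 <- generateActivatedScene(cfg2, seed = 6)
  cc2 <- connectionCounts(s2)
  g <- binUndocked(s2)
  near <- cc2[cc2$vesicle_id %in% g[["4-16"]], ]
  # near rule with SDs 0: round(3.6) + round(1.9) + round(5.6) = 4 + 2 + 6
  expect_true(all(near$rib == 4))
  expect_true(all(near$spar == 2))
  expect_true(all(near$boom == 6))
  expect_true(all(near$main_body == 12))
})

test_that("z compression scales geometry exactly and round-trips", {
  s0 <- scene_of(vrow("v1", z = 27.5, radius = 27.5))
  expect_identical(applyZCompression(s0, 1)@vesicles, s0@vesicles)

  v55 <- scene_of(vrow("v1", z = 27.5, radius = 27.5))
  sc <- applyZCompression(v55, 0.805)
  expect_equal(2 * vesicles(sc)$z_semi_axis, 44.275)

  s <- generateRestingScene(defaultSceneConfig(band_length = 250), seed = 9)
  rt <- zStretchCorrect(applyZCompression(s, 0.805), 1 / 0.805)
  expect_lt(max(abs(vesicles(rt)$z - vesicles(s)$z)), 1e-9)
  pmax_err <- max(mapply(function(a, b) max(abs(a - b)),
                         filaments(rt)$path, filaments(s)$path))
  expect_lt(pmax_err, 1e-9)
  expect_equal(sceneMetadata(rt)$compression, 1)

  expect_error(applyZCompression(s, 0), class = "azm_argument_error")
  expect_error(applyZCompression(s, 1.2), class = "azm_argument_error")
})

test_that("config validation rejects malformed inputs", {
  cfg <- defaultSceneConfig()
  cfg$counts$ribs_per_vesicle <- c(3.9, -1)
  expect_error(validateConfig(cfg), class = "azm_config_error")
  cfg <- defaultSceneConfig()
  cfg$bin_rules$lo[1] <- 10   # overlaps the 4-16 bin
  expect_error(validateConfig(cfg), class = "azm_config_error")
  cfg <- defaultSceneConfig()
  cfg$compression_ratio <- 1.5
  expect_error(validateConfig(cfg), class = "azm_config_error")
})
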