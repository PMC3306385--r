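# Seeded generators of resting and activated active-zone scenes.
#
# The generator lays out a straight band along +y: beams end-to-end next to
# the membrane, steps at stochastic intervals with one mast each, and two
# mirrored rows of docked vesicles so that each step sits centered between a
# tetrad (the two flanking vesicles in each row). Docked vesicles are wired
# to ribs (from beams), spars (from the two flanking steps), booms (from the
# two flanking masts, shared over the tetrad), pins (from the membrane, on
# the hemisphere facing away from the band) and unorganized non-AZM
# filaments; each mast also carries 1-2 topmasts to deep undocked vesicles.
#
# Filament construction works backwards from the measurement protocols: the
# vesicle-bound endpoint (the connection site) is placed at a drawn class
# depth, the filament length and in-plane approach angle are drawn from the
# class distributions, and the origin endpoint is then computed so that arc
# length and projected angle are exactly the drawn values. The configured
# distributions are therefore recovered by the measurement operators without
# projection-bias corrections.

# --- internal scene builder ------------------------------------------------

new_builder <- function() {
  env <- new.env(parent = emptyenv())
  env$ves <- list(); env$fil <- list(); env$warn <- character()
  env$nv <- 0L; env$nf <- 0L
  env
}

add_vesicle <- function(b, x, y, z, radius, z_semi = radius, state, row_side) {
  b$nv <- b$nv + 1L
  id <- sprintf("v%04d", b$nv)
  b$ves[[b$nv]] <- data.frame(id = id, x = x, y = y, z = z, radius = radius,
                              z_semi_axis = z_semi, state = state,
                              row_side = row_side, stringsAsFactors = FALSE)
  id
}

add_filament <- function(b, class, diameter, path, diameter_vertical = NA_real_,
                         strands = NA_integer_, attach_vesicle = NA_character_,
                         attach_filament = NA_character_, attach_membrane = FALSE) {
  b$nf <- b$nf + 1L
  id <- sprintf("f%05d", b$nf)
  path <- unname(path); dimnames(path) <- NULL
  row <- data.frame(id = id, class = class, diameter = diameter,
                    diameter_vertical = diameter_vertical, strands = strands,
                    attach_vesicle = attach_vesicle,
                    attach_filament = attach_filament,
                    attach_membrane = attach_membrane, stringsAsFactors = FALSE)
  row$path <- list(path)
  b$fil[[b$nf]] <- row
  id
}

builder_scene <- function(b, config, seed, mode, extra_meta = list()) {
  ves <- if (b$nv) do.call(rbind, b$ves) else emptyVesicles()
  fil <- if (b$nf) do.call(rbind, b$fil) else emptyFilaments()
  meta <- c(list(seed = as.integer(seed), config_hash = configHash(config),
                 compression = 1, mode = mode, warnings = b$warn), extra_meta)
  Scene(membrane = Membrane(extent = c(-150, 150, 0, config$band_length)),
        vesicles = ves, filaments = fil, azmAxis = c(0, 1, 0), metadata = meta)
}

# --- site and filament geometry --------------------------------------------

# Place sites on a vesicle surface at given membrane depths, with azimuths
# stratified about a facing direction (base_deg) so the sites disperse over
# the facing hemisphere (and, for ribs + pins jointly, surround the fusion
# domain). Clips depths to the sphere and records a warning on clipping.
place_sites <- function(b, cx, cy, cz, r, depths, base_deg, halfwidth) {
  n <- length(depths)
  zmin <- cz - r + 0.5; zmax <- cz + r - 0.5
  if (any(depths < zmin | depths > zmax))
    b$warn <- c(b$warn, sprintf("%d site depth(s) clipped to vesicle surface",
                                sum(depths < zmin | depths > zmax)))
  z <- pmin(pmax(depths, zmin), zmax)
  uz <- (z - cz) / r
  uh <- sqrt(pmax(1 - uz^2, 0))
  # stratified azimuths with jitter inside each stratum
  k <- seq_len(n)
  off <- halfwidth * (2 * (k - 0.5) / n - 1) +
    stats::runif(n, -halfwidth / n, halfwidth / n)
  phi <- (base_deg + off) * pi / 180
  cbind(x = cx + r * uh * cos(phi), y = cy + r * uh * sin(phi), z = z)
}

# Build a 2-point filament path ending at `site`, with exact arc length
# `len`, whose horizontal projection makes `angle_deg` with the x axis
# (the perpendicular to the band axis), pointing from the band midline
# toward side `sx` (+1/-1), and whose origin z approximates `origin_z`.
filament_path_to_site <- function(site, len, angle_deg, sx, origin_z,
                                  sy = sample(c(-1, 1), 1)) {
  uz <- (site[3] - origin_z) / len
  uz <- pmin(pmax(uz, -0.95), 0.95)
  uh <- sqrt(1 - uz^2)
  a <- angle_deg * pi / 180
  u <- c(sx * cos(a) * uh, sy * sin(a) * uh, uz)
  origin <- site - len * u
  rbind(origin, unname(site))
}

draw2 <- function(ms, n = 1, lower = -Inf, upper = Inf)
  rtrunc_norm(n, ms[1], ms[2], lower, upper)

# --- band skeleton ----------------------------------------------------------

# Step center y positions along the band.
draw_step_centers <- function(config) {
  L <- config$band_length
  y <- 25
  out <- numeric()
  repeat {
    if (y > L - 25) break
    out <- c(out, y)
    y <- y + draw2(config$step_spacing, lower = config$step_spacing_min)
  }
  out
}

# Beams laid end-to-end covering the band; returns data.frame(id, y0, y1, z).
lay_beams <- function(b, config) {
  L <- config$band_length
  y0 <- 0; rows <- list()
  while (y0 < L) {
    len <- min(draw2(config$length$beam, lower = 20), L - y0)
    dia <- draw2(config$diameter$beam, lower = 0.5)
    z <- dia / 2
    id <- add_filament(b, "beam", dia,
                       rbind(c(0, y0, z), c(0, y0 + len, z)))
    rows[[length(rows) + 1L]] <- data.frame(id = id, y0 = y0, y1 = y0 + len,
                                            z = z, stringsAsFactors = FALSE)
    y0 <- y0 + len
  }
  do.call(rbind, rows)
}

beam_at <- function(beams, y) {
  i <- findInterval(y, beams$y0)
  i <- min(max(i, 1L), nrow(beams))
  beams[i, ]
}

# Steps and masts at the given centers; returns data.frame(step_id, mast_id,
# y, step_z, mast_bottom, mast_top).
lay_steps_masts <- function(b, config, centers, beams) {
  rows <- list()
  for (y in centers) {
    slen <- draw2(config$length$step, lower = 8)
    dh <- draw2(config$diameter$step, lower = 2)
    dv <- draw2(config$step_diameter_vertical, lower = 2)
    step_z <- 15 + dv / 2          # intermediate layer, above the beams
    bid <- beam_at(beams, y)$id
    sid <- add_filament(b, "step", dh,
                        rbind(c(0, y - slen / 2, step_z),
                              c(0, y + slen / 2, step_z)),
                        diameter_vertical = dv, attach_filament = bid)
    mlen <- draw2(config$length$mast, lower = 10)
    mdia <- draw2(config$diameter$mast, lower = 5)
    mb <- step_z + dv / 2
    strands <- sample(seq(config$mast_strands[1], config$mast_strands[2]), 1)
    mid <- add_filament(b, "mast", mdia,
                        rbind(c(0, y, mb), c(0, y, mb + mlen)),
                        strands = as.integer(strands), attach_filament = sid)
    rows[[length(rows) + 1L]] <- data.frame(step_id = sid, mast_id = mid,
                                            y = y, step_z = step_z,
                                            mast_bottom = mb,
                                            mast_top = mb + mlen,
                                            stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

# --- per-vesicle wiring -----------------------------------------------------

# Wire ribs, pins and non-AZM filaments of one (docked-style) vesicle and
# return the vesicle's rib-centroid depth. `d` is the vesicle-membrane
# distance (0 for docked); rib counts may be overridden (activated bins).
wire_ribs_pins <- function(b, config, vid, cx, cy, cz, r, sx, beams,
                           d = 0, n_ribs = NULL, with_pins = TRUE,
                           n_pins = NULL, pin_len = NULL) {
  inward <- if (sx > 0) 180 else 0
  outward <- if (sx > 0) 0 else 180
  hw <- config$azimuth_halfwidth
  if (is.null(n_ribs))
    n_ribs <- rcount(1, config$counts$ribs_per_vesicle[1],
                     config$counts$ribs_per_vesicle[2], 0)
  rib_centroid <- d + config$depth$rib_site[1]
  if (n_ribs > 0) {
    depths <- d + draw2(config$depth$rib_site, n_ribs, lower = 0.5,
                        upper = config$depth$rib_site_max)
    rib_centroid <- mean(depths)
    sites <- place_sites(b, cx, cy, cz, r, depths, inward, hw)
    for (i in seq_len(n_ribs)) {
      bm <- beam_at(beams, cy)
      path <- filament_path_to_site(sites[i, ], draw2(config$length$rib, lower = 2),
                                    rangle(1, config$angle$rib[1], config$angle$rib[2]),
                                    sx, bm$z)
      add_filament(b, "rib", draw2(config$diameter$rib, lower = 0.5), path,
                   attach_vesicle = vid, attach_filament = bm$id)
    }
  }
  if (with_pins) {
    if (is.null(n_pins))
      n_pins <- rcount(1, config$counts$pins_per_vesicle[1],
                       config$counts$pins_per_vesicle[2],
                       config$counts$pins_range[1], config$counts$pins_range[2])
    if (n_pins > 0) {
      if (is.null(pin_len))
        pin_len <- draw2(config$length$pin, n_pins, lower = 2,
                         upper = d + config$depth$pin_site_max)
      # vertical pins: membrane endpoint directly beneath the surface site,
      # so arc length equals the drawn value exactly
      sites <- place_sites(b, cx, cy, cz, r, pin_len, outward, hw)
      for (i in seq_len(n_pins)) {
        path <- rbind(c(sites[i, 1], sites[i, 2], 0), sites[i, , drop = TRUE])
        add_filament(b, "pin", draw2(config$diameter$pin, lower = 0.5), path,
                     attach_vesicle = vid, attach_membrane = TRUE)
      }
    }
  }
  n_free <- stats::rpois(1, config$counts$non_azm_per_vesicle)
  if (n_free > 0) {
    depths <- stats::runif(n_free, cz - 0.8 * r, cz + 0.8 * r)
    sites <- place_sites(b, cx, cy, cz, r, depths, outward, 85)
    for (i in seq_len(n_free)) {
      u <- unit(c(sites[i, 1] - cx, sites[i, 2] - cy, sites[i, 3] - cz))
      far <- sites[i, ] + stats::runif(1, 10, 40) * u
      if (far[3] < 0.5) far[3] <- 0.5
      add_filament(b, "non_azm", draw2(config$diameter$non_azm, lower = 0.5),
                   rbind(unname(far), sites[i, , drop = TRUE]),
                   attach_vesicle = vid)
    }
  }
  rib_centroid
}

# Spars of one vesicle, split between its flanking steps.
wire_spars <- function(b, config, vid, cx, cy, cz, r, sx, steps_of_v,
                       rib_centroid, n_spars = NULL) {
  inward <- if (sx > 0) 180 else 0
  if (is.null(n_spars))
    n_spars <- rcount(1, config$counts$spars_per_vesicle[1],
                      config$counts$spars_per_vesicle[2], 0)
  if (n_spars == 0) return(invisible(NULL))
  depths <- rib_centroid + stats::rnorm(n_spars, config$depth$spar_offset[1],
                                        config$depth$spar_offset[2])
  sites <- place_sites(b, cx, cy, cz, r, depths, inward,
                       config$azimuth_halfwidth * 0.85)
  for (i in seq_len(n_spars)) {
    st <- steps_of_v[((i - 1) %% nrow(steps_of_v)) + 1, ]
    sy <- sign(st$y - cy); if (sy == 0) sy <- sample(c(-1, 1), 1)
    path <- filament_path_to_site(sites[i, ], draw2(config$length$spar, lower = 2),
                                  rangle(1, config$angle$spar[1], config$angle$spar[2]),
                                  sx, st$step_z, sy = sy)
    add_filament(b, "spar", draw2(config$diameter$spar, lower = 0.5), path,
                 attach_vesicle = vid, attach_filament = st$step_id)
  }
  invisible(NULL)
}

# Booms to one vesicle from one mast (count decided by the caller's per-mast
# allocation), or directly by count for activated bin wiring.
wire_booms <- function(b, config, vid, cx, cy, cz, r, sx, mast, n_booms,
                       rib_centroid) {
  if (n_booms == 0) return(invisible(NULL))
  inward <- if (sx > 0) 180 else 0
  depths <- rib_centroid + stats::rnorm(n_booms, config$depth$boom_offset[1],
                                        config$depth$boom_offset[2])
  sites <- place_sites(b, cx, cy, cz, r, depths, inward,
                       config$azimuth_halfwidth * 0.85)
  for (i in seq_len(n_booms)) {
    o_z <- draw2(config$depth$boom_origin)
    sy <- sign(mast$y - cy); if (sy == 0) sy <- sample(c(-1, 1), 1)
    path <- filament_path_to_site(sites[i, ], draw2(config$length$boom, lower = 2),
                                  rangle(1, config$angle$boom[1], config$angle$boom[2]),
                                  sx, o_z, sy = sy)
    add_filament(b, "boom", draw2(config$diameter$boom, lower = 0.5), path,
                 attach_vesicle = vid, attach_filament = mast$mast_id)
  }
  invisible(NULL)
}

wire_topmasts <- function(b, config, mast) {
  n_t <- sample(seq(config$counts$topmasts_per_mast[1],
                    config$counts$topmasts_per_mast[2]), 1)
  for (i in seq_len(n_t)) {
    len <- draw2(config$length$topmast, lower = 8)
    theta <- stats::runif(1, 0, 50) * pi / 180     # polar angle from +z
    phi <- stats::runif(1, 0, 2 * pi)
    u <- c(sin(theta) * cos(phi), sin(theta) * sin(phi), cos(theta))
    top <- c(0, mast$y, mast$mast_top)
    site <- top + len * u
    r_u <- stats::runif(1, config$vesicle_diameter[1] / 2,
                        config$vesicle_diameter[2] / 2)
    ctr <- site + r_u * u
    vid <- add_vesicle(b, ctr[1], ctr[2], ctr[3], r_u, state = "undocked",
                       row_side = "none")
    add_filament(b, "topmast", draw2(config$diameter$topmast, lower = 0.5),
                 rbind(top, site), attach_vesicle = vid,
                 attach_filament = mast$mast_id)
  }
  invisible(NULL)
}

# --- docked-row layout ------------------------------------------------------

# Docked vesicle slots at the midpoints between consecutive steps, two rows
# mirrored in x. Returns data.frame(slot, side, sx, y, step_lo, step_hi).
docked_slots <- function(config, centers) {
  if (length(centers) < 2) return(NULL)
  mids <- (centers[-1] + centers[-length(centers)]) / 2
  out <- expand.grid(gap = seq_along(mids), sx = c(-1, 1))
  data.frame(slot = seq_len(nrow(out)), side = ifelse(out$sx < 0, "left", "right"),
             sx = out$sx, y = mids[out$gap], step_lo = out$gap,
             step_hi = out$gap + 1L, stringsAsFactors = FALSE)
}

# Per-mast boom allocation: total drawn once per mast, split as evenly as
# possible over its four nominal tetrad slots, remainders assigned at random.
# Returns a matrix [n_steps x 4] of boom counts; slot columns are
# (lo-left, lo-right, hi-left, hi-right) relative to the step's two gaps.
allocate_booms <- function(config, n_steps) {
  out <- matrix(0L, n_steps, 4)
  for (i in seq_len(n_steps)) {
    total <- rcount(1, config$counts$booms_per_mast[1],
                    config$counts$booms_per_mast[2], 0)
    base <- total %/% 4L
    extra <- total %% 4L
    cnt <- rep(base, 4)
    if (extra > 0) cnt[sample(4, extra)] <- base + 1L
    out[i, ] <- cnt
  }
  out
}

#' Generate a resting active-zone scene
#'
#' Deterministic given (config, seed): the same inputs produce a
#' byte-identical scene (and byte-identical JSON via [writeScene()]).
#'
#' @param config a \code{SceneConfig}, see [defaultSceneConfig()].
#' @param seed integer master seed (default: \code{config$seed}). Child
#'   seeds for the layout and wiring stages are derived deterministically.
#' @return a [Scene-class] passing [validateScene()] with zero violations.
#' @export
generateRestingScene <- function(config = defaultSceneConfig(),
                                 seed = config$seed) {
  validateConfig(config)
  b <- new_builder()
  set.seed(child_seed(seed, 1L))
  beams <- lay_beams(b, config)
  centers <- draw_step_centers(config)
  sm <- lay_steps_masts(b, config, centers, beams)
  slots <- docked_slots(config, centers)

  set.seed(child_seed(seed, 2L))
  booms_alloc <- allocate_booms(config, nrow(sm))
  if (!is.null(slots)) {
    for (i in seq_len(nrow(slots))) {
      s <- slots[i, ]
      r <- stats::runif(1, config$vesicle_diameter[1] / 2,
                        config$vesicle_diameter[2] / 2)
      cx <- s$sx * config$row_offset + stats::rnorm(1, 0, config$row_jitter)
      cy <- s$y + stats::rnorm(1, 0, config$row_jitter)
      vid <- add_vesicle(b, cx, cy, r, r, state = "docked",
                         row_side = s$side)
      rc <- wire_ribs_pins(b, config, vid, cx, cy, r, r, s$sx, beams)
      steps_of_v <- sm[c(s$step_lo, s$step_hi), ]
      wire_spars(b, config, vid, cx, cy, r, r, s$sx, steps_of_v, rc)
      # booms from the two flanking masts: slot column 3/4 of the lower
      # step (its "hi" gap), column 1/2 of the upper step (its "lo" gap)
      col_lo <- if (s$sx < 0) 3L else 4L
      col_hi <- if (s$sx < 0) 1L else 2L
      wire_booms(b, config, vid, cx, cy, r, r, s$sx, sm[s$step_lo, ],
                 booms_alloc[s$step_lo, col_lo], rc)
      wire_booms(b, config, vid, cx, cy, r, r, s$sx, sm[s$step_hi, ],
                 booms_alloc[s$step_hi, col_hi], rc)
    }
  }
  set.seed(child_seed(seed, 3L))
  for (i in seq_len(nrow(sm))) wire_topmasts(b, config, sm[i, ])
  builder_scene(b, config, seed, "resting")
}

# Wiring of one undocked vesicle at a vacated docking site, per the matching
# distance-bin rule. Vesicles whose distance falls in an inter-bin gap are
# wired by the nearest rule (binning operators still report them unbinned).
wire_undocked <- function(b, config, vid, cx, cy, cz, r, sx, d, beams,
                          steps_of_v) {
  br <- config$bin_rules
  j <- which(d >= br$lo & d <= br$hi)
  if (!length(j)) j <- which.min(pmax(br$lo - d, d - br$hi, 0))
  rule <- br[j[1], ]
  n_ribs <- if (rule$rib_mean == 0 && rule$rib_sd == 0) 0L else
    rcount(1, rule$rib_mean, rule$rib_sd, 0)
  with_pins <- isTRUE(rule$pins) && d <= config$activated$pins_within
  n_pins <- NULL; pin_len <- NULL
  if (with_pins) {
    n_pins <- rcount(1, config$activated$undocked_pins_per_vesicle[1],
                     config$activated$undocked_pins_per_vesicle[2],
                     config$counts$pins_range[1], config$counts$pins_range[2])
    # pin length grows with vesicle distance: length = distance + slack.
    # Slack is gamma-distributed (positive support, exact mean) with
    # moments chosen so that, under the default uniform distance sampler,
    # pooled pin length recovers the configured mean/SD.
    dr <- c(config$activated$distance_range[1], config$activated$pins_within)
    mu_d <- mean(dr); var_d <- diff(dr)^2 / 12
    tgt <- config$activated$undocked_pin_length
    mu_s <- max(tgt[1] - mu_d, 1)
    var_s <- max(tgt[2]^2 - var_d, 1)
    slack <- stats::rgamma(n_pins, shape = mu_s^2 / var_s,
                           scale = var_s / mu_s)
    pin_len <- d + pmax(slack, 0.5)
  }
  rc <- wire_ribs_pins(b, config, vid, cx, cy, cz, r, sx, beams, d = d,
                       n_ribs = n_ribs, with_pins = with_pins,
                       n_pins = n_pins, pin_len = pin_len)
  n_spars <- if (rule$spar_mean == 0 && rule$spar_sd == 0) 0L else
    rcount(1, rule$spar_mean, rule$spar_sd, 0)
  wire_spars(b, config, vid, cx, cy, cz, r, sx, steps_of_v, rc,
             n_spars = n_spars)
  n_booms <- rcount(1, rule$boom_mean, rule$boom_sd, 0)
  n1 <- n_booms %/% 2L; n2 <- n_booms - n1
  if (stats::runif(1) < 0.5) { tmp <- n1; n1 <- n2; n2 <- tmp }
  wire_booms(b, config, vid, cx, cy, cz, r, sx, steps_of_v[1, ], n1, rc)
  wire_booms(b, config, vid, cx, cy, cz, r, sx, steps_of_v[2, ], n2, rc)
  invisible(NULL)
}

#' Generate an activated active-zone scene
#'
#' As [generateRestingScene()], but a configured fraction of docking sites
#' are vacated: the former docked vesicle is replaced by a
#' \code{vacated_marker} flattened into the membrane, and an undocked
#' vesicle is placed above the site at a membrane distance drawn from the
#' configured sampler (default uniform on 4-42 nm) and wired according to
#' the matching distance-bin rule: booms always, spars and ribs gated by
#' bin, and pins only within 15 nm of the membrane with lengths growing
#' with vesicle distance. Optionally one docked slot instead carries a
#' \code{fused_omega} vesicle retaining the full docked complement of
#' ribs, spars and booms.
#'
#' @inheritParams generateRestingScene
#' @return a [Scene-class].
#' @export
generateActivatedScene <- function(config = defaultSceneConfig(),
                                   seed = config$seed) {
  validateConfig(config)
  b <- new_builder()
  set.seed(child_seed(seed, 11L))
  beams <- lay_beams(b, config)
  centers <- draw_step_centers(config)
  sm <- lay_steps_masts(b, config, centers, beams)
  slots <- docked_slots(config, centers)

  set.seed(child_seed(seed, 12L))
  n_slots <- if (is.null(slots)) 0L else nrow(slots)
  n_vac <- round(config$activated$vacated_fraction * n_slots)
  vac <- if (n_vac > 0) sort(sample(n_slots, n_vac)) else integer()
  fused_slot <- integer()
  if (isTRUE(config$activated$fused_omega) && length(setdiff(seq_len(n_slots), vac)))
    fused_slot <- sample(setdiff(seq_len(n_slots), vac), 1)

  booms_alloc <- allocate_booms(config, nrow(sm))
  undocked_ids <- character()
  if (n_slots > 0) {
    for (i in seq_len(n_slots)) {
      s <- slots[i, ]
      r <- stats::runif(1, config$vesicle_diameter[1] / 2,
                        config$vesicle_diameter[2] / 2)
      cx <- s$sx * config$row_offset + stats::rnorm(1, 0, config$row_jitter)
      cy <- s$y + stats::rnorm(1, 0, config$row_jitter)
      steps_of_v <- sm[c(s$step_lo, s$step_hi), ]
      if (i %in% vac) {
        add_vesicle(b, cx, cy, 0, r, state = "vacated_marker",
                    row_side = s$side)
        d <- stats::runif(1, config$activated$distance_range[1],
                          config$activated$distance_range[2])
        cz <- r + d
        vid <- add_vesicle(b, cx, cy, cz, r, state = "undocked",
                           row_side = s$side)
        undocked_ids <- c(undocked_ids, vid)
        wire_undocked(b, config, vid, cx, cy, cz, r, s$sx, d, beams, steps_of_v)
      } else {
        fused <- i %in% fused_slot
        cz <- if (fused) 0.6 * r else r
        vid <- add_vesicle(b, cx, cy, cz, r,
                           state = if (fused) "fused_omega" else "docked",
                           row_side = s$side)
        rc <- wire_ribs_pins(b, config, vid, cx, cy, cz, r, s$sx, beams,
                             with_pins = !fused)
        wire_spars(b, config, vid, cx, cy, cz, r, s$sx, steps_of_v, rc)
        col_lo <- if (s$sx < 0) 3L else 4L
        col_hi <- if (s$sx < 0) 1L else 2L
        wire_booms(b, config, vid, cx, cy, cz, r, s$sx, sm[s$step_lo, ],
                   booms_alloc[s$step_lo, col_lo], rc)
        wire_booms(b, config, vid, cx, cy, cz, r, s$sx, sm[s$step_hi, ],
                   booms_alloc[s$step_hi, col_hi], rc)
      }
    }
  }
  set.seed(child_seed(seed, 13L))
  for (i in seq_len(nrow(sm))) wire_topmasts(b, config, sm[i, ])
  builder_scene(b, config, seed, "activated",
                extra_meta = list(undocked_at_vacated = undocked_ids))
}

#' Inject artificial z-axis compression
#'
#' Multiplies every z coordinate (vesicle centers and filament path points)
#' by \code{ratio} and stores the compressed z semi-axis of each vesicle
#' (\code{radius * ratio}): vesicles become oblate, exactly as in
#' beam-induced thinning of plastic sections. The cumulative compression
#' state is recorded in the scene metadata. The inverse operation is
#' [zStretchCorrect()] with factor \code{1/ratio}.
#'
#' @param scene a [Scene-class].
#' @param ratio compression ratio in (0, 1]; 1 is the identity.
#' @return the compressed [Scene-class].
#' @export
applyZCompression <- function(scene, ratio) {
  if (!is.numeric(ratio) || length(ratio) != 1 || ratio <= 0 || ratio > 1)
    azm_error("compression ratio must be a scalar in (0, 1]", "azm_argument_error")
  scale_scene_z(scene, ratio)
}

#' @noRd
scale_scene_z <- function(scene, factor) {
  vs <- scene@vesicles
  vs$z <- vs$z * factor
  vs$z_semi_axis <- vs$z_semi_axis * factor
  fs <- scene@filaments
  fs$path <- lapply(fs$path, function(p) { p[, 3] <- p[, 3] * factor; p })
  md <- scene@metadata
  md$compression <- (md$compression %||% 1) * factor
  Scene(membrane = scene@membrane, vesicles = vs, filaments = fs,
        azmAxis = scene@azmAxis, metadata = md)
}
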