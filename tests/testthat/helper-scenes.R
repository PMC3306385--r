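# Small scene constructors and independent oracles used across the suite.

vrow <- function(id, x = 0, y = 0, z = 27.5, radius = 27.5, zs = radius,
                 state = "docked", row_side = "left") {
  data.frame(id = id, x = x, y = y, z = z, radius = radius, z_semi_axis = zs,
             state = state, row_side = row_side, stringsAsFactors = FALSE)
}

frow <- function(id, class, path, diameter = 8, dv = NA_real_,
                 strands = NA_integer_, av = NA_character_,
                 af = NA_character_, am = FALSE) {
  out <- data.frame(id = id, class = class, diameter = diameter,
                    diameter_vertical = dv, strands = strands,
                    attach_vesicle = av, attach_filament = af,
                    attach_membrane = am, stringsAsFactors = FALSE)
  out$path <- list(path)
  out
}

scene_of <- function(ves = emptyVesicles(), fils = emptyFilaments(),
                     extent = c(-150, 150, 0, 200)) {
  Scene(membrane = Membrane(extent = extent), vesicles = ves, filaments = fils)
}

# A point on a sphere surface at a given z and azimuth (degrees).
sphere_point <- function(cx, cy, cz, r, z, phi_deg) {
  uz <- (z - cz) / r
  uh <- sqrt(1 - uz^2)
  phi <- phi_deg * pi / 180
  c(cx + r * uh * cos(phi), cy + r * uh * sin(phi), z)
}

# Degenerate configuration: every SD zero, counts fixed at their means.
degenerate_config <- function(band_length = 500) {
  cfg <- defaultSceneConfig(band_length = band_length)
  zap <- function(x) c(x[1], 0)
  cfg$step_spacing <- zap(cfg$step_spacing)
  cfg$row_jitter <- 0
  for (nm in names(cfg$length)) cfg$length[[nm]] <- zap(cfg$length[[nm]])
  for (nm in names(cfg$diameter)) cfg$diameter[[nm]] <- zap(cfg$diameter[[nm]])
  cfg$step_diameter_vertical <- zap(cfg$step_diameter_vertical)
  for (nm in c("ribs_per_vesicle", "spars_per_vesicle", "booms_per_mast",
               "pins_per_vesicle"))
    cfg$counts[[nm]] <- zap(cfg$counts[[nm]])
  for (nm in c("rib_site", "spar_offset", "boom_offset", "boom_origin"))
    cfg$depth[[nm]] <- zap(cfg$depth[[nm]])
  for (nm in names(cfg$angle)) cfg$angle[[nm]] <- zap(cfg$angle[[nm]])
  cfg
}

# Brute-force oracle for the vesicle-membrane distance: minimum |z| over
# surface points enumerated on a uniform grid of polar heights (azimuth is
# irrelevant for a distance to the plane z = 0).
surface_min_dist_oracle <- function(cz, r, n = 1e4) {
  uz <- seq(-1, 1, length.out = n)
  min(abs(cz + r * uz))
}

# Rigid motion of a scene: rotate all coordinates by R and translate by t.
# Only paths and vesicle centers matter for length invariance checks.
rigid_transform_paths <- function(paths, R, t) {
  lapply(paths, function(p) sweep(p %*% t(R), 2, t, `+`))
}

random_rotation <- function() {
  # QR of a Gaussian matrix, sign-fixed to a proper rotation
  Q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

# Independent exhaustive grid oracle for two-vesicle rib alignment: holds
# vesicle 1 fixed and scans vesicle 2's z-y-z Euler angles on a uniform
# grid, computing the overlap by direct double summation.
grid_align_oracle <- function(u1, u2, bandwidth, step_deg = 5) {
  rz <- function(a) matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
  ry <- function(a) matrix(c(cos(a), 0, -sin(a), 0, 1, 0, sin(a), 0, cos(a)), 3, 3)
  overlap <- function(v2) {
    D <- u1 %*% t(v2)
    sum(exp(-acos(pmin(pmax(D, -1), 1))^2 / (2 * bandwidth^2)))
  }
  step <- step_deg * pi / 180
  best <- -Inf
  for (a in seq(0, 2 * pi - step / 2, by = step))
    for (b in seq(0, pi, by = step)) {
      Rab <- rz(a) %*% ry(b)
      for (g in seq(0, 2 * pi - step / 2, by = step)) {
        v2 <- u2 %*% t(Rab %*% rz(g))
        val <- overlap(v2)
        if (val > best) best <- val
      }
    }
  best
}

# Memoized scene pools shared by the acceptance suite (regenerating ~40
# scenes per block would dominate the suite's runtime).
.azm_pool <- new.env(parent = emptyenv())

pooled_resting <- function(n = 30) {
  key <- paste0("resting", n)
  if (is.null(.azm_pool[[key]]))
    .azm_pool[[key]] <- lapply(seq_len(n), function(i)
      generateRestingScene(seed = i))
  .azm_pool[[key]]
}

pooled_activated <- function(seeds = 201:207) {
  key <- paste0("act", paste(range(seeds), collapse = "_"))
  if (is.null(.azm_pool[[key]]))
    .azm_pool[[key]] <- lapply(seeds, function(i)
      generateActivatedScene(seed = i))
  .azm_pool[[key]]
}

# Per-vesicle counts of binned undocked vesicles across activated scenes,
# with bin, membrane distance and source seed attached.
binned_counts <- function(scenes, seeds) {
  out <- list()
  for (i in seq_along(scenes)) {
    g <- binUndocked(scenes[[i]])
    cc <- connectionCounts(scenes[[i]])
    d <- attr(g, "distance")
    for (b in names(g)) {
      sub <- cc[cc$vesicle_id %in% g[[b]], ]
      if (nrow(sub)) {
        sub$bin <- b
        sub$d <- d[match(sub$vesicle_id, names(d))]
        sub$seed <- seeds[i]
        out[[length(out) + 1L]] <- sub
      }
    }
  }
  do.call(rbind, out)
}

# Docked reference cohort: 20 vesicles drawn from three scenes (at most 7
# per scene), mirroring a multi-data-set sample.
docked_cohort <- function(scenes) {
  rest <- do.call(rbind, lapply(scenes[1:3], function(s) {
    cc <- connectionCounts(s)
    head(cc[cc$state == "docked", ], 7)
  }))
  head(rest, 20)
}
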