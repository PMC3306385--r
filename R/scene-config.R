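# Scene configuration: every distribution the synthetic generator draws from.
#
# Defaults are the published class dimensions and connection statistics for
# resting and activated frog neuromuscular-junction active zones (mean/SD in
# nm, degrees, or counts). The configuration is a validated nested list; it
# round-trips to/from JSON for the command-line interface.

#' Default scene configuration
#'
#' Returns the full configuration used by [generateRestingScene()] and
#' [generateActivatedScene()]. All lengths are nm, angles degrees. Each
#' continuous quantity is parameterized as \code{c(mean, sd)} and drawn from
#' a normal distribution (truncated at physical bounds); integer counts are
#' drawn normal, rounded, and clipped to their stated range; in-plane
#' approach angles are drawn as folded normals so the unsigned projection
#' protocol recovers the configured mean.
#'
#' Key defaults: step spacing 48.8 +/- 14.9 nm; vesicle diameter uniform on
#' 50-60 nm; class lengths/diameters (beam 75.1/10.7, step 28.4/21.8 horiz +
#' 13.9 vert, mast 31.5/22, rib 27.9/9.4, pin 8.6/5.0, spar 17.6/7.1, boom
#' 16.0/6.5, topmast 24.6/6.9); per-vesicle counts (ribs 3.9 +/- 0.6, spars
#' 2.2 +/- 0.5, pins 4.1 +/- 0.7 clipped to 3-5); booms 10.6 +/- 1.8 per
#' mast shared over its tetrad; connection-site depths (rib 7.7 +/- 3.3 nm,
#' spar offset 10.3 +/- 4.4, boom offset 24.2 +/- 6.6, boom origin on mast
#' 39.0 +/- 7.7); approach angles (rib 10.6 +/- 6.2, spar 23.3 +/- 13.1,
#' boom 30.0 +/- 14.7 degrees); and the activated distance-bin wiring rules
#' (see [defaultBinRules()]).
#'
#' @param band_length band length in nm along +y (default 500).
#' @param seed default master seed recorded in the config.
#' @return a list of class \code{SceneConfig}.
#' @export
defaultSceneConfig <- function(band_length = 500, seed = 1L) {
  cfg <- list(
    seed = as.integer(seed),
    band_length = band_length,
    step_spacing = c(48.8, 14.9),
    step_spacing_min = 15,
    vesicle_diameter = c(50, 60),
    row_offset = 40,            # |x| of the docked-vesicle rows
    row_jitter = 2,             # SD of lateral jitter on vesicle centers
    length = list(beam = c(75.1, 13.1), step = c(28.4, 7.6),
                  mast = c(31.5, 4.5), rib = c(27.9, 7.7),
                  pin = c(8.6, 3.5), spar = c(17.6, 6.5),
                  boom = c(16.0, 4.8), topmast = c(24.6, 9.4)),
    diameter = list(beam = c(10.7, 0.7), step = c(21.8, 5.8),
                    mast = c(22, 3), rib = c(9.4, 1.4),
                    pin = c(5.0, 1.0), spar = c(7.1, 1.2),
                    boom = c(6.5, 1.3), topmast = c(6.9, 2.1),
                    non_azm = c(7.0, 1.5)),
    step_diameter_vertical = c(13.9, 2.7),
    mast_strands = c(4L, 9L),
    counts = list(ribs_per_vesicle = c(3.9, 0.6),
                  spars_per_vesicle = c(2.2, 0.5),
                  booms_per_mast = c(10.6, 1.8),
                  pins_per_vesicle = c(4.1, 0.7),
                  pins_range = c(3L, 5L),
                  topmasts_per_mast = c(1L, 2L),
                  non_azm_per_vesicle = 10),
    depth = list(rib_site = c(7.7, 3.3),
                 rib_site_max = 15,          # superficial-layer thickness
                 spar_offset = c(10.3, 4.4),
                 boom_offset = c(24.2, 6.6),
                 boom_origin = c(39.0, 7.7),
                 pin_site_max = 15),
    angle = list(rib = c(10.6, 6.2), spar = c(23.3, 13.1), boom = c(30.0, 14.7)),
    azimuth_halfwidth = 80,     # degrees; dispersal of sites about the facing direction
    activated = list(vacated_fraction = 0.5,
                     distance_range = c(4, 42),
                     pins_within = 15,
                     undocked_pins_per_vesicle = c(3.8, 0.5),
                     undocked_pin_length = c(16.5, 6.5),
                     fused_omega = TRUE),
    bin_rules = defaultBinRules(),
    compression_ratio = 0.805,
    schema_version = 1L
  )
  class(cfg) <- "SceneConfig"
  validateConfig(cfg)
  cfg
}

#' Default distance-bin wiring rules for undocked vesicles
#'
#' One rule per distance bin (closed nm interval of shortest vesicle-membrane
#' distance): expected boom, spar and rib connection counts (mean/SD) and
#' whether pins are present. The bins keep the published gaps (16-17 and
#' 24-29 nm): vesicles falling in a gap are reported separately, never
#' silently assigned.
#'
#' @return data.frame with columns lo, hi, boom_mean, boom_sd, spar_mean,
#'   spar_sd, rib_mean, rib_sd, pins.
#' @export
defaultBinRules <- function() {
  data.frame(
    lo = c(29, 17, 4), hi = c(42, 24, 16),
    boom_mean = c(4.8, 5.6, 5.6), boom_sd = c(0.8, 1.0, 1.0),
    spar_mean = c(0.3, 1.7, 1.9), spar_sd = c(0.5, 0.6, 0.4),
    rib_mean = c(0, 1.3, 3.6), rib_sd = c(0, 0.6, 0.5),
    pins = c(FALSE, FALSE, TRUE),
    stringsAsFactors = FALSE
  )
}

#' Validate a scene configuration
#'
#' Checks that all SDs are non-negative, counts non-negative, distance bins
#' ordered and non-overlapping, and the compression ratio in (0, 1].
#'
#' @param config a \code{SceneConfig} list.
#' @return the config, invisibly; errors on violation.
#' @export
validateConfig <- function(config) {
  stopifnot(is.list(config))
  chk_ms <- function(x, what) {
    if (length(x) != 2 || x[2] < 0)
      azm_error(paste0(what, " must be c(mean, sd) with sd >= 0"),
                "azm_config_error")
  }
  chk_ms(config$step_spacing, "step_spacing")
  for (nm in names(config$length)) chk_ms(config$length[[nm]], paste("length$", nm))
  for (nm in names(config$diameter)) chk_ms(config$diameter[[nm]], paste("diameter$", nm))
  for (nm in c("ribs_per_vesicle", "spars_per_vesicle", "booms_per_mast",
               "pins_per_vesicle"))
    chk_ms(config$counts[[nm]], paste("counts$", nm))
  for (nm in c("rib_site", "spar_offset", "boom_offset", "boom_origin"))
    chk_ms(config$depth[[nm]], paste("depth$", nm))
  for (nm in names(config$angle)) chk_ms(config$angle[[nm]], paste("angle$", nm))
  if (diff(config$vesicle_diameter) < 0)
    azm_error("vesicle_diameter must be c(min, max)", "azm_config_error")
  br <- config$bin_rules
  if (any(br$hi < br$lo))
    azm_error("bin_rules intervals must have lo <= hi", "azm_config_error")
  o <- order(br$lo)
  if (nrow(br) > 1 && any(br$lo[o][-1] <= br$hi[o][-nrow(br)]))
    azm_error("bin_rules intervals must be disjoint", "azm_config_error")
  if (any(c(br$boom_mean, br$spar_mean, br$rib_mean) < 0) ||
      any(c(br$boom_sd, br$spar_sd, br$rib_sd) < 0))
    azm_error("bin_rules expectations must be non-negative", "azm_config_error")
  cr <- config$compression_ratio
  if (!is.numeric(cr) || cr <= 0 || cr > 1)
    azm_error("compression_ratio must be in (0, 1]", "azm_config_error")
  invisible(config)
}

#' Read / write a SceneConfig as JSON
#'
#' The JSON document mirrors the configuration list; partial documents are
#' merged over [defaultSceneConfig()], so a config file needs to list only
#' the fields it changes.
#'
#' @param path file path.
#' @param config a \code{SceneConfig}.
#' @return \code{readSceneConfig()} returns a validated \code{SceneConfig}.
#' @export
readSceneConfig <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  cfg <- defaultSceneConfig()
  merge_into <- function(base, upd) {
    for (nm in names(upd)) {
      if (is.list(base[[nm]]) && is.list(upd[[nm]]) &&
          !is.data.frame(base[[nm]])) {
        base[[nm]] <- merge_into(base[[nm]], upd[[nm]])
      } else if (is.data.frame(base[[nm]])) {
        base[[nm]] <- as.data.frame(upd[[nm]], stringsAsFactors = FALSE)
      } else {
        base[[nm]] <- upd[[nm]]
      }
    }
    base
  }
  cfg <- merge_into(unclass(cfg), raw)
  class(cfg) <- "SceneConfig"
  validateConfig(cfg)
  cfg
}

#' @rdname readSceneConfig
#' @export
writeSceneConfig <- function(config, path) {
  validateConfig(config)
  json <- jsonlite::toJSON(unclass(config), auto_unbox = FALSE, digits = 6,
                           pretty = TRUE, dataframe = "columns")
  writeLines(json, path)
  invisible(path)
}

# Stable hash of a configuration (md5 of its canonical JSON serialization).
#' @noRd
configHash <- function(config) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  writeLines(jsonlite::toJSON(unclass(config), auto_unbox = FALSE, digits = 10,
                              dataframe = "columns"), tf)
  unname(tools::md5sum(tf))
}
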