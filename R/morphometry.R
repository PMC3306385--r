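# Measurement operators applied to any Scene (synthetic or imported).

#' Arc length of a polyline path
#'
#' @param path n-by-3 matrix of nm coordinates, n >= 2.
#' @return arc length in nm (sum of segment lengths along the midline).
#' @export
arcLength <- function(path) {
  if (!is.matrix(path) || ncol(path) != 3 || nrow(path) < 2)
    azm_error("path must be an n-by-3 matrix with n >= 2", "azm_argument_error")
  d <- path[-1, , drop = FALSE] - path[-nrow(path), , drop = FALSE]
  sum(sqrt(rowSums(d^2)))
}

#' Filament lengths of a scene
#'
#' @param scene a [Scene-class].
#' @param classes optional filament classes to keep (default all).
#' @return data.frame with columns id, class, length (nm).
#' @export
filamentLengths <- function(scene, classes = NULL) {
  fs <- scene@filaments
  if (!is.null(classes)) fs <- fs[fs$class %in% classes, , drop = FALSE]
  data.frame(id = fs$id, class = fs$class,
             length = vapply(fs$path, arcLength, numeric(1)),
             stringsAsFactors = FALSE)
}

#' Estimate the z-axis compression ratio from vesicle shape
#'
#' The ratio of each vesicle's z diameter to its mean x-y diameter
#' (\code{z_semi_axis / radius} under the stored-ellipsoid representation),
#' averaged over vesicles. 1.0 for uncompressed scenes.
#'
#' @param scene a [Scene-class] with at least one vesicle.
#' @return list with elements \code{ratio} (mean), \code{sd} and \code{n}.
#' @export
estimateCompressionRatio <- function(scene) {
  vs <- scene@vesicles
  vs <- vs[vs$state != "vacated_marker", , drop = FALSE]
  if (!nrow(vs))
    azm_error("scene has no vesicles to estimate compression from",
              "azm_argument_error")
  r <- vs$z_semi_axis / vs$radius
  list(ratio = mean(r), sd = if (length(r) > 1) stats::sd(r) else 0,
       n = length(r))
}

#' Stretch-correct the z axis of a scene
#'
#' Multiplies all z coordinates and vesicle z semi-axes by \code{factor},
#' the correction applied to reconstructions whose vesicles show z-axis
#' compression (a factor of 1.2 for an estimated ratio around 0.8; the
#' conventional protocol applies it when the estimated ratio falls below
#' 0.9). [zStretchProtocol()] applies that rule automatically.
#'
#' @param scene a [Scene-class].
#' @param factor positive stretch factor; \code{1/ratio} inverts
#'   [applyZCompression()] exactly.
#' @return the stretched [Scene-class] (metadata compression state updated).
#' @export
zStretchCorrect <- function(scene, factor) {
  if (!is.numeric(factor) || length(factor) != 1 || factor <= 0)
    azm_error("stretch factor must be a positive scalar", "azm_argument_error")
  scale_scene_z(scene, factor)
}

#' @rdname zStretchCorrect
#' @param threshold apply the stretch only when the estimated compression
#'   ratio is below this value (default 0.9).
#' @export
zStretchProtocol <- function(scene, factor = 1.2, threshold = 0.9) {
  est <- estimateCompressionRatio(scene)
  if (est$ratio < threshold) {
    scene <- zStretchCorrect(scene, factor)
    scene@metadata$stretch_applied <- factor
  } else {
    scene@metadata$stretch_applied <- 1
  }
  scene
}

#' Center-to-center spacing of steps along the band
#'
#' @param scene a [Scene-class].
#' @return numeric vector of consecutive centroid distances (nm), ordered
#'   along the band axis; empty if fewer than two steps.
#' @export
stepCenterSpacing <- function(scene) {
  fs <- scene@filaments
  st <- fs[fs$class == "step", , drop = FALSE]
  if (nrow(st) < 2) return(numeric())
  cent <- t(vapply(st$path, colMeans, numeric(3)))
  ax <- scene@azmAxis
  pos <- cent %*% ax
  o <- order(pos)
  d <- cent[o, , drop = FALSE]
  sqrt(rowSums((d[-1, , drop = FALSE] - d[-nrow(d), , drop = FALSE])^2))
}

#' In-plane angle of approach of filaments to vesicles
#'
#' Implements the projection protocol: the filament's long-axis direction
#' (from its non-vesicle endpoint to its vesicle-bound endpoint) is
#' projected onto the horizontal (x-y) plane, and the unsigned angle in
#' degrees between that projection and the perpendicular to the band axis
#' (the x axis under the fixed convention) is returned, in [0, 90].
#'
#' @param scene a [Scene-class].
#' @param classes filament classes to measure (default rib, spar, boom).
#' @return data.frame with columns id, class, angle (degrees).
#' @export
angleOfApproach <- function(scene, classes = c("rib", "spar", "boom")) {
  fs <- scene@filaments
  fs <- fs[fs$class %in% classes & !is.na(fs$attach_vesicle), , drop = FALSE]
  ang <- vapply(fs$path, function(p) {
    d <- p[nrow(p), ] - p[1, ]
    h <- sqrt(d[1]^2 + d[2]^2)
    if (h < 1e-12)
      azm_error("vertical filament: projected direction has zero length",
                "azm_undefined_angle_error")
    atan2(abs(d[2]), abs(d[1])) * 180 / pi
  }, numeric(1))
  data.frame(id = fs$id, class = fs$class, angle = ang,
             stringsAsFactors = FALSE)
}

#' Per-vesicle connection counts by filament class
#'
#' One row per vesicle with counts of rib, spar, boom, pin, topmast and
#' non-AZM connections, plus \code{main_body = rib + spar + boom} (the
#' total used for distance-binned connectivity profiles).
#'
#' @param scene a [Scene-class].
#' @return data.frame with columns vesicle_id, state, rib, spar, boom, pin,
#'   topmast, non_azm, main_body.
#' @export
connectionCounts <- function(scene) {
  vs <- scene@vesicles
  cs <- connectionSites(scene)
  cls <- c("rib", "spar", "boom", "pin", "topmast", "non_azm")
  out <- data.frame(vesicle_id = vs$id, state = vs$state,
                    stringsAsFactors = FALSE)
  for (cl in cls)
    out[[cl]] <- vapply(vs$id, function(v)
      sum(cs$vesicle_id == v & cs$class == cl), numeric(1))
  out$main_body <- out$rib + out$spar + out$boom
  rownames(out) <- NULL
  out
}

#' Pin lengths grouped by the bound vesicle's docking state
#'
#' @param scene a [Scene-class].
#' @return data.frame with columns state, mean, sd, n (sample SD, n-1
#'   denominator); states with no pins are absent. The raw lengths are
#'   attached as attribute \code{"lengths"} (a data.frame state/length).
#' @export
pinLengthByState <- function(scene) {
  fs <- scene@filaments
  pins <- fs[fs$class == "pin" & !is.na(fs$attach_vesicle), , drop = FALSE]
  vs <- scene@vesicles
  if (!nrow(pins)) {
    out <- data.frame(state = character(), mean = double(), sd = double(),
                      n = integer(), stringsAsFactors = FALSE)
    attr(out, "lengths") <- data.frame(state = character(), length = double())
    return(out)
  }
  len <- vapply(pins$path, arcLength, numeric(1))
  st <- vs$state[match(pins$attach_vesicle, vs$id)]
  raw <- data.frame(state = st, length = len, stringsAsFactors = FALSE)
  agg <- do.call(rbind, lapply(split(raw$length, raw$state), function(x)
    data.frame(mean = mean(x), sd = if (length(x) > 1) stats::sd(x) else NA_real_,
               n = length(x))))
  out <- data.frame(state = rownames(agg), agg, row.names = NULL,
                    stringsAsFactors = FALSE)
  attr(out, "lengths") <- raw
  out
}

#' Morphometry summary of a scene
#'
#' Aggregates the measurement operators into one object mirroring a
#' dimensions table: per-class length and diameter mean/SD/n, step spacing,
#' per-vesicle connection counts, pin lengths by state, and per-class
#' approach angles. All SDs are sample SDs (n-1 denominator); every n is
#' the number of contributing entities.
#'
#' @param scene a [Scene-class].
#' @return a \code{MorphometrySummary} object (S4) with data.frame slots
#'   \code{dimensions}, \code{spacing}, \code{counts}, \code{pins},
#'   \code{angles}.
#' @export
morphometrySummary <- function(scene) {
  fs <- scene@filaments
  msd <- function(x) c(mean = if (length(x)) mean(x) else NA_real_,
                       sd = if (length(x) > 1) stats::sd(x) else NA_real_,
                       n = length(x))
  cls <- c("beam", "step", "mast", "rib", "pin", "spar", "boom", "topmast")
  dims <- do.call(rbind, lapply(cls, function(cl) {
    sub <- fs[fs$class == cl, , drop = FALSE]
    ln <- msd(vapply(sub$path, arcLength, numeric(1)))
    dm <- msd(sub$diameter)
    dv <- msd(sub$diameter_vertical[!is.na(sub$diameter_vertical)])
    data.frame(class = cl, length_mean = ln[1], length_sd = ln[2],
               length_n = ln[3], diameter_mean = dm[1], diameter_sd = dm[2],
               diameter_n = dm[3], diameter_vertical_mean = dv[1],
               stringsAsFactors = FALSE)
  }))
  rownames(dims) <- NULL
  sp <- stepCenterSpacing(scene)
  spacing <- data.frame(mean = if (length(sp)) mean(sp) else NA_real_,
                        sd = if (length(sp) > 1) stats::sd(sp) else NA_real_,
                        n = length(sp))
  ang <- angleOfApproach(scene)
  angles <- do.call(rbind, lapply(split(ang$angle, ang$class), function(x) {
    m <- msd(x); data.frame(mean = m[1], sd = m[2], n = m[3])
  }))
  angles <- data.frame(class = rownames(angles), angles, row.names = NULL,
                       stringsAsFactors = FALSE)
  methods::new("MorphometrySummary", dimensions = dims, spacing = spacing,
               counts = connectionCounts(scene), pins = pinLengthByState(scene),
               angles = angles)
}

#' @rdname morphometrySummary
#' @export
setClass("MorphometrySummary",
  representation(dimensions = "data.frame", spacing = "data.frame",
                 counts = "data.frame", pins = "data.frame",
                 angles = "data.frame"))

setMethod("show", "MorphometrySummary", function(object) {
  cat("MorphometrySummary\n")
  cat("  class dimensions (nm):\n")
  print(object@dimensions[, c("class", "length_mean", "length_sd", "length_n",
                              "diameter_mean", "diameter_sd", "diameter_n")],
        digits = 3, row.names = FALSE)
  cat(sprintf("  step spacing: %.1f +/- %.1f nm (n = %d)\n",
              object@spacing$mean, object@spacing$sd, object@spacing$n))
  if (nrow(object@angles)) {
    cat("  approach angles (degrees):\n")
    print(object@angles, digits = 3, row.names = FALSE)
  }
  dk <- object@counts[object@counts$state == "docked", , drop = FALSE]
  if (nrow(dk))
    cat(sprintf("  docked vesicles: %d; mean connections rib %.1f, spar %.1f, boom %.1f, pin %.1f\n",
                nrow(dk), mean(dk$rib), mean(dk$spar), mean(dk$boom), mean(dk$pin)))
  invisible(object)
})
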