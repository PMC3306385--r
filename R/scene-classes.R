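# S4 containers for three-dimensional active-zone scenes.
#
# Coordinate convention (used throughout the package): the presynaptic
# membrane is the plane z = 0 with the cytoplasm at z > 0; the long axis of
# the active-zone band is +y and the transverse axis is x. All lengths are
# nanometers, double precision.

SURFACE_TOL <- 0.5   # nm; filament endpoint-on-vesicle-surface tolerance
CONTACT_TOL <- 0.5   # nm; docked-vesicle membrane-contact tolerance

#' Presynaptic membrane
#'
#' The membrane is modeled as the flat plane z = 0 with a rectangular lateral
#' extent in x-y and unit normal pointing into the cytoplasm (+z). The
#' active-zone ridge (curvature into the synaptic cleft) is deliberately not
#' modeled: every statistic computed by the package is defined relative to
#' the flat portion of the membrane.
#'
#' @slot extent numeric(4), \code{c(xmin, xmax, ymin, ymax)} in nm.
#' @slot normal numeric(3), unit normal (fixed at \code{c(0, 0, 1)}).
#' @export
setClass("Membrane",
  representation(extent = "numeric", normal = "numeric"),
  prototype(extent = c(-150, 150, 0, 500), normal = c(0, 0, 1)),
  validity = function(object) {
    msgs <- character()
    if (length(object@extent) != 4 ||
        object@extent[2] <= object@extent[1] ||
        object@extent[4] <= object@extent[3])
      msgs <- c(msgs, "extent must be c(xmin, xmax, ymin, ymax) with positive span")
    if (length(object@normal) != 3 ||
        abs(sqrt(sum(object@normal^2)) - 1) > 1e-9)
      msgs <- c(msgs, "normal must have unit length")
    if (length(msgs)) msgs else TRUE
  }
)

#' @describeIn Membrane constructor
#' @param extent numeric(4) lateral extent in nm.
#' @export
Membrane <- function(extent = c(-150, 150, 0, 500)) {
  methods::new("Membrane", extent = extent, normal = c(0, 0, 1))
}

.vesicle_cols <- c("id", "x", "y", "z", "radius", "z_semi_axis", "state", "row_side")
.filament_cols <- c("id", "class", "diameter", "diameter_vertical", "strands",
                    "attach_vesicle", "attach_filament", "attach_membrane", "path")

VESICLE_STATES <- c("docked", "undocked", "fused_omega", "vacated_marker")
FILAMENT_CLASSES <- c("beam", "step", "mast", "rib", "spar", "boom",
                      "topmast", "pin", "non_azm")
MAIN_BODY_CLASSES <- c("rib", "spar", "boom")

#' Active-zone scene
#'
#' A complete 3D active zone: the presynaptic membrane, synaptic vesicles,
#' classed filaments, and (derived) connection sites, all in nm coordinates.
#' Vesicles and filaments are stored as data frames; filament polyline paths
#' are a list column of n-by-3 matrices. A filament endpoint bound to a
#' vesicle is always the last path point; an endpoint bound to the membrane
#' or to another filament is the first path point.
#'
#' Structural integrity (column layout, reference resolution) is enforced by
#' the S4 validity method; geometric invariants (surface binding, docked
#' contact, path sanity) are reported as data by [validateScene()] so that
#' defective scenes can be represented and diagnosed.
#'
#' @slot membrane a [Membrane-class] object.
#' @slot vesicles data.frame with columns id, x, y, z, radius, z_semi_axis,
#'   state (docked/undocked/fused_omega/vacated_marker), row_side.
#' @slot filaments data.frame with columns id, class, diameter,
#'   diameter_vertical, strands, attach_vesicle, attach_filament,
#'   attach_membrane, path (list of n-by-3 matrices).
#' @slot azmAxis numeric(3), unit vector along the band (convention +y).
#' @slot metadata list: seed, config hash, compression state, warnings.
#' @export
setClass("Scene",
  representation(membrane = "Membrane", vesicles = "data.frame",
                 filaments = "data.frame", azmAxis = "numeric",
                 metadata = "list"),
  validity = function(object) {
    msgs <- character()
    if (!all(.vesicle_cols %in% names(object@vesicles)))
      msgs <- c(msgs, paste("vesicles must have columns:",
                            paste(.vesicle_cols, collapse = ", ")))
    if (!all(.filament_cols %in% names(object@filaments)))
      msgs <- c(msgs, paste("filaments must have columns:",
                            paste(.filament_cols, collapse = ", ")))
    if (anyDuplicated(object@vesicles$id))
      msgs <- c(msgs, "vesicle ids must be unique")
    if (anyDuplicated(object@filaments$id))
      msgs <- c(msgs, "filament ids must be unique")
    if (length(object@azmAxis) != 3 ||
        abs(sqrt(sum(object@azmAxis^2)) - 1) > 1e-9)
      msgs <- c(msgs, "azmAxis must be a unit 3-vector")
    if (length(msgs)) msgs else TRUE
  }
)

#' @describeIn Scene constructor
#' @param membrane a [Membrane-class] object.
#' @param vesicles,filaments data frames (see slots).
#' @param azmAxis unit 3-vector along the band.
#' @param metadata named list.
#' @export
Scene <- function(membrane = Membrane(), vesicles = emptyVesicles(),
                  filaments = emptyFilaments(), azmAxis = c(0, 1, 0),
                  metadata = list()) {
  if (is.null(metadata$compression)) metadata$compression <- 1
  methods::new("Scene", membrane = membrane, vesicles = vesicles,
               filaments = filaments, azmAxis = azmAxis, metadata = metadata)
}

#' @rdname Scene
#' @export
emptyVesicles <- function() {
  data.frame(id = character(), x = double(), y = double(), z = double(),
             radius = double(), z_semi_axis = double(), state = character(),
             row_side = character(), stringsAsFactors = FALSE)
}

#' @rdname Scene
#' @export
emptyFilaments <- function() {
  out <- data.frame(id = character(), class = character(), diameter = double(),
                    diameter_vertical = double(), strands = integer(),
                    attach_vesicle = character(), attach_filament = character(),
                    attach_membrane = logical(), stringsAsFactors = FALSE)
  out$path <- list()
  out
}

setMethod("show", "Scene", function(object) {
  vs <- object@vesicles; fs <- object@filaments
  cat("Scene (active zone, nm coordinates)\n")
  cat(sprintf("  membrane extent: x [%g, %g], y [%g, %g]\n",
              object@membrane@extent[1], object@membrane@extent[2],
              object@membrane@extent[3], object@membrane@extent[4]))
  cat(sprintf("  vesicles: %d (%s)\n", nrow(vs),
              paste(sprintf("%s: %d", names(table(vs$state)),
                            as.integer(table(vs$state))), collapse = ", ")))
  cat(sprintf("  filaments: %d (%s)\n", nrow(fs),
              paste(sprintf("%s: %d", names(table(fs$class)),
                            as.integer(table(fs$class))), collapse = ", ")))
  cat(sprintf("  connection sites: %d\n", nrow(connectionSites(object))))
  cm <- object@metadata$compression %||% 1
  if (!identical(cm, 1)) cat(sprintf("  z-compression state: %g\n", cm))
  invisible(object)
})

#' Scene accessors
#'
#' @param scene a [Scene-class] object.
#' @return \code{vesicles()} and \code{filaments()} return the respective
#'   data frames; \code{membrane()} the [Membrane-class]; \code{azmAxis()}
#'   the band axis; \code{sceneMetadata()} the metadata list.
#' @name scene-accessors
NULL

#' @rdname scene-accessors
#' @export
vesicles <- function(scene) scene@vesicles

#' @rdname scene-accessors
#' @export
filaments <- function(scene) scene@filaments

#' @rdname scene-accessors
#' @export
membrane <- function(scene) scene@membrane

#' @rdname scene-accessors
#' @export
azmAxis <- function(scene) scene@azmAxis

#' @rdname scene-accessors
#' @export
sceneMetadata <- function(scene) scene@metadata

#' Derive connection sites from vesicle-bound filament endpoints
#'
#' Connection sites are not stored: they are, bijectively, the vesicle-bound
#' filament endpoints (the last path point of every filament whose
#' \code{attach_vesicle} is set). This guarantees the conservation invariant
#' that sites and (filament endpoint, vesicle) bindings are in one-to-one
#' correspondence.
#'
#' @param scene a [Scene-class] object.
#' @return data.frame with columns vesicle_id, filament_id, class, x, y, z.
#' @export
connectionSites <- function(scene) {
  fs <- scene@filaments
  sel <- which(!is.na(fs$attach_vesicle))
  if (!length(sel)) {
    return(data.frame(vesicle_id = character(), filament_id = character(),
                      class = character(), x = double(), y = double(),
                      z = double(), stringsAsFactors = FALSE))
  }
  pos <- t(vapply(fs$path[sel], function(p) p[nrow(p), ], numeric(3)))
  data.frame(vesicle_id = fs$attach_vesicle[sel], filament_id = fs$id[sel],
             class = fs$class[sel], x = pos[, 1], y = pos[, 2], z = pos[, 3],
             stringsAsFactors = FALSE)
}

#' Shortest distance from vesicle surface to the presynaptic membrane
#'
#' Under the flat-membrane convention the shortest distance from a vesicle's
#' surface to the membrane plane is \code{max(center_z - z_semi_axis, 0)};
#' the z semi-axis equals the radius for uncompressed (spherical) vesicles.
#' Zero means the vesicle touches or interpenetrates the membrane.
#'
#' @param scene a [Scene-class] object.
#' @param ids optional character vector of vesicle ids (default all).
#' @return named numeric vector of distances in nm.
#' @export
shortestDistanceToMembrane <- function(scene, ids = NULL) {
  vs <- scene@vesicles
  if (!is.null(ids)) {
    miss <- setdiff(ids, vs$id)
    if (length(miss))
      azm_error(paste("unknown vesicle id(s):", paste(miss, collapse = ", ")),
                "azm_reference_error")
    vs <- vs[match(ids, vs$id), , drop = FALSE]
  }
  if (any(vs$z < 0))
    azm_error("vesicle center z < 0: coordinate-convention error (cytoplasm is +z)",
              "azm_convention_error")
  stats::setNames(pmax(vs$z - vs$z_semi_axis, 0), vs$id)
}

# Scaled residual of a point against a vesicle's (possibly oblate) surface,
# in nm: |ellipsoidal norm - 1| * smallest semi-axis.
#' @noRd
surface_residual <- function(point, vx, vy, vz, r, zs) {
  nrm <- sqrt(((point[1] - vx) / r)^2 + ((point[2] - vy) / r)^2 +
              ((point[3] - vz) / zs)^2)
  abs(nrm - 1) * min(r, zs)
}

#' Check every scene invariant and report violations as data
#'
#' Violations are returned as rows of a data frame (entity id, the invariant
#' violated, and a human-readable message), never raised as errors, so
#' defective scenes can be constructed and inspected. An empty data frame
#' means the scene satisfies all invariants. The check is side-effect free
#' and idempotent.
#'
#' Invariants checked: positive vesicle radii; docked vesicles contact the
#' membrane (center z equals the z semi-axis within 0.5 nm); undocked
#' vesicles clear the membrane; vesicle centers in the cytoplasm (z >= 0);
#' known state and class labels; filament paths with >= 2 distinct
#' consecutive points and positive diameter; attachment references resolve;
#' vesicle-bound endpoints on the vesicle surface within 0.5 nm;
#' membrane-bound endpoints at z = 0 within 0.5 nm.
#'
#' @param scene a [Scene-class] object.
#' @return data.frame with columns entity, invariant, message (zero rows if
#'   the scene is valid).
#' @export
validateScene <- function(scene) {
  out <- list()
  bad <- function(entity, invariant, message) {
    out[[length(out) + 1L]] <<- data.frame(entity = entity,
                                           invariant = invariant,
                                           message = message,
                                           stringsAsFactors = FALSE)
  }
  vs <- scene@vesicles
  fs <- scene@filaments

  for (i in seq_len(nrow(vs))) {
    v <- vs[i, ]
    if (!(v$radius > 0) || !(v$z_semi_axis > 0))
      bad(v$id, "vesicle_radius_positive", "radius and z semi-axis must be > 0")
    if (!(v$state %in% VESICLE_STATES))
      bad(v$id, "vesicle_state_known", paste("unknown state:", v$state))
    if (v$z < 0)
      bad(v$id, "vesicle_in_cytoplasm", "center z < 0")
    if (identical(v$state, "docked") && abs(v$z - v$z_semi_axis) > CONTACT_TOL)
      bad(v$id, "docked_contact",
          sprintf("docked vesicle center z = %.3f but z semi-axis = %.3f (gap %.3f nm)",
                  v$z, v$z_semi_axis, v$z - v$z_semi_axis))
    if (identical(v$state, "undocked") && v$z <= v$z_semi_axis)
      bad(v$id, "undocked_clearance", "undocked vesicle touches or crosses the membrane")
  }

  for (i in seq_len(nrow(fs))) {
    f <- fs[i, ]
    p <- f$path[[1]]
    if (!is.matrix(p) || ncol(p) != 3 || nrow(p) < 2) {
      bad(f$id, "path_shape", "path must be an n-by-3 matrix with n >= 2")
      next
    }
    seglen <- sqrt(rowSums((p[-1, , drop = FALSE] - p[-nrow(p), , drop = FALSE])^2))
    if (any(seglen == 0))
      bad(f$id, "path_points_distinct", "consecutive path points must be distinct")
    if (!(f$class %in% FILAMENT_CLASSES))
      bad(f$id, "class_known", paste("unknown class:", f$class))
    if (!(f$diameter > 0))
      bad(f$id, "diameter_positive", "diameter must be > 0")
    if (!is.na(f$attach_vesicle)) {
      j <- match(f$attach_vesicle, vs$id)
      if (is.na(j)) {
        bad(f$id, "vesicle_reference",
            paste("attached vesicle does not exist:", f$attach_vesicle))
      } else {
        res <- surface_residual(p[nrow(p), ], vs$x[j], vs$y[j], vs$z[j],
                                vs$radius[j], vs$z_semi_axis[j])
        if (res > SURFACE_TOL)
          bad(f$id, "endpoint_on_surface",
              sprintf("vesicle-bound endpoint is %.3f nm off the surface of %s",
                      res, f$attach_vesicle))
      }
    }
    if (!is.na(f$attach_filament) && !(f$attach_filament %in% fs$id))
      bad(f$id, "filament_reference",
          paste("attached filament does not exist:", f$attach_filament))
    if (isTRUE(f$attach_membrane) && abs(p[1, 3]) > SURFACE_TOL)
      bad(f$id, "endpoint_on_membrane",
          sprintf("membrane-bound endpoint has z = %.3f nm", p[1, 3]))
  }

  if (length(out)) do.call(rbind, out)
  else data.frame(entity = character(), invariant = character(),
                  message = character(), stringsAsFactors = FALSE)
}
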