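# Scene JSON serialization (versioned schema), CSV report bundle, run
# manifest. Floats are serialized with 6 decimal places (well below every
# geometric tolerance) and canonical key ordering, so identical scenes
# serialize byte-identically.

SCENE_SCHEMA <- "azm-scene"
SCENE_SCHEMA_VERSION <- 1L

.scene_json_fields <- c("schema", "version", "metadata", "azm_axis",
                        "membrane", "vesicles", "filaments")
.vesicle_json_fields <- c("id", "center", "radius", "z_semi_axis", "state",
                          "row_side")
.filament_json_fields <- c("id", "class_label", "diameter",
                           "diameter_vertical", "strands", "attachments",
                           "path")

#' @noRd
azm_log <- function(stage, fmt, ...) {
  message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

#' Write a scene to its JSON schema
#'
#' Refuses to write scenes with validation violations. Serialization is
#' canonical (fixed key order, 6 decimal places), so the same scene always
#' produces the same bytes.
#'
#' @param scene a [Scene-class] passing [validateScene()].
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeScene <- function(scene, path) {
  viol <- validateScene(scene)
  if (nrow(viol))
    azm_error(paste0("refusing to write invalid scene:\n",
                     paste(sprintf("  %s [%s]: %s", viol$entity,
                                   viol$invariant, viol$message),
                           collapse = "\n")),
              "azm_schema_error")
  vs <- scene@vesicles
  ves <- lapply(seq_len(nrow(vs)), function(i) list(
    id = vs$id[i], center = c(vs$x[i], vs$y[i], vs$z[i]),
    radius = vs$radius[i], z_semi_axis = vs$z_semi_axis[i],
    state = vs$state[i], row_side = vs$row_side[i]))
  fs <- scene@filaments
  fil <- lapply(seq_len(nrow(fs)), function(i) {
    at <- list()
    if (isTRUE(fs$attach_membrane[i]))
      at[[length(at) + 1L]] <- list(kind = "membrane", target = NA,
                                    endpoint = "first")
    if (!is.na(fs$attach_filament[i]))
      at[[length(at) + 1L]] <- list(kind = "filament",
                                    target = fs$attach_filament[i],
                                    endpoint = "first")
    if (!is.na(fs$attach_vesicle[i]))
      at[[length(at) + 1L]] <- list(kind = "vesicle",
                                    target = fs$attach_vesicle[i],
                                    endpoint = "last")
    list(id = fs$id[i], class_label = fs$class[i], diameter = fs$diameter[i],
         diameter_vertical = fs$diameter_vertical[i],
         strands = fs$strands[i], attachments = at,
         path = unname(lapply(seq_len(nrow(fs$path[[i]])),
                              function(r) fs$path[[i]][r, ])))
  })
  doc <- list(schema = SCENE_SCHEMA, version = SCENE_SCHEMA_VERSION,
              metadata = scene@metadata, azm_axis = scene@azmAxis,
              membrane = list(extent = scene@membrane@extent,
                              normal = scene@membrane@normal),
              vesicles = ves, filaments = fil)
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = 6, null = "null",
                           na = "null", pretty = FALSE)
  writeLines(json, path)
  invisible(path)
}

#' @noRd
schema_check <- function(ok, msg) {
  if (!ok) azm_error(msg, "azm_schema_error")
}

#' Read a scene from its JSON schema
#'
#' Parses, checks the schema name and version, rejects unknown fields, and
#' verifies that all attachment references resolve. Errors carry distinct
#' condition classes: \code{azm_parse_error} for malformed JSON,
#' \code{azm_version_error} for a version mismatch,
#' \code{azm_schema_error} for structural violations and
#' \code{azm_reference_error} for dangling references.
#'
#' @param path JSON file written by [writeScene()].
#' @return a [Scene-class].
#' @export
readScene <- function(path) {
  if (!file.exists(path))
    azm_error(paste("no such file:", path), "azm_parse_error")
  doc <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e)
                    azm_error(paste("malformed scene JSON:",
                                    conditionMessage(e)), "azm_parse_error"))
  if (!is.list(doc) || is.null(doc$schema))
    azm_error("not a scene document (no schema field)", "azm_schema_error")
  schema_check(identical(doc$schema, SCENE_SCHEMA),
               paste("unknown schema:", doc$schema))
  if (!identical(as.integer(doc$version), SCENE_SCHEMA_VERSION))
    azm_error(sprintf("schema version mismatch: file %s, supported %d",
                      doc$version, SCENE_SCHEMA_VERSION), "azm_version_error")
  unknown <- setdiff(names(doc), .scene_json_fields)
  schema_check(!length(unknown),
               paste("unknown top-level field(s):", paste(unknown, collapse = ", ")))
  num3 <- function(x) vapply(x, as.numeric, numeric(1))

  ves <- lapply(doc$vesicles, function(v) {
    unknown <- setdiff(names(v), .vesicle_json_fields)
    schema_check(!length(unknown),
                 paste("unknown vesicle field(s):", paste(unknown, collapse = ", ")))
    schema_check(all(c("id", "center", "radius", "state") %in% names(v)),
                 "vesicle missing required fields")
    ctr <- num3(v$center)
    data.frame(id = v$id, x = ctr[1], y = ctr[2], z = ctr[3],
               radius = as.numeric(v$radius),
               z_semi_axis = as.numeric(v$z_semi_axis %||% v$radius),
               state = v$state, row_side = v$row_side %||% "none",
               stringsAsFactors = FALSE)
  })
  ves <- if (length(ves)) do.call(rbind, ves) else emptyVesicles()

  fil <- lapply(doc$filaments, function(f) {
    unknown <- setdiff(names(f), .filament_json_fields)
    schema_check(!length(unknown),
                 paste("unknown filament field(s):", paste(unknown, collapse = ", ")))
    schema_check(all(c("id", "class_label", "diameter", "path") %in% names(f)),
                 "filament missing required fields")
    av <- NA_character_; af <- NA_character_; am <- FALSE
    for (at in f$attachments %||% list()) {
      if (identical(at$kind, "vesicle")) av <- at$target
      else if (identical(at$kind, "filament")) af <- at$target
      else if (identical(at$kind, "membrane")) am <- TRUE
      else azm_error(paste("unknown attachment kind:", at$kind),
                     "azm_schema_error")
    }
    row <- data.frame(id = f$id, class = f$class_label,
                      diameter = as.numeric(f$diameter),
                      diameter_vertical = as.numeric(f$diameter_vertical %||% NA),
                      strands = as.integer(f$strands %||% NA),
                      attach_vesicle = av, attach_filament = af,
                      attach_membrane = am, stringsAsFactors = FALSE)
    row$path <- list(do.call(rbind, lapply(f$path, num3)))
    row
  })
  fil <- if (length(fil)) do.call(rbind, fil) else emptyFilaments()

  bad_v <- setdiff(stats::na.omit(fil$attach_vesicle), ves$id)
  if (length(bad_v))
    azm_error(paste("filament(s) reference missing vesicle id(s):",
                    paste(unique(bad_v), collapse = ", ")),
              "azm_reference_error")
  bad_f <- setdiff(stats::na.omit(fil$attach_filament), fil$id)
  if (length(bad_f))
    azm_error(paste("filament(s) reference missing filament id(s):",
                    paste(unique(bad_f), collapse = ", ")),
              "azm_reference_error")

  md <- doc$metadata %||% list()
  md <- lapply(md, function(x) {
    if (!is.list(x)) return(x)
    unlist(x, use.names = FALSE) %||% character(0)
  })
  Scene(membrane = Membrane(extent = num3(doc$membrane$extent)),
        vesicles = ves, filaments = fil, azmAxis = num3(doc$azm_axis),
        metadata = md)
}

#' Run the full report bundle on a scene
#'
#' Emits the morphometry summary (a dimensions-table-shaped CSV with one
#' row per filament class), the per-class connection-site depth CSV, the
#' distance-bin profile CSV (for scenes with undocked vesicles), and a run
#' manifest (JSON) recording tool version, config hash, seed, and md5
#' digests of every output. Identical scenes produce identical CSV
#' digests.
#'
#' @param scene a [Scene-class].
#' @param dir output directory (created if needed).
#' @param bins distance bins for the profile CSV.
#' @return named character vector of written file paths, invisibly.
#' @export
runReport <- function(scene, dir, bins = defaultBins()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c()
  ms <- morphometrySummary(scene)
  p <- file.path(dir, "morphometry.csv")
  utils::write.csv(ms@dimensions, p, row.names = FALSE)
  paths["morphometry"] <- p
  azm_log("measure", "wrote %s", p)

  p <- file.path(dir, "counts.csv")
  utils::write.csv(ms@counts, p, row.names = FALSE)
  paths["counts"] <- p

  dep <- classCentroidDepths(scene)
  p <- file.path(dir, "depths.csv")
  utils::write.csv(dep, p, row.names = FALSE)
  paths["depths"] <- p
  azm_log("align", "wrote %s", p)

  if (any(scene@vesicles$state == "undocked")) {
    prof <- binnedProfile(scene, binUndocked(scene, bins))
    p <- file.path(dir, "profile.csv")
    utils::write.csv(prof, p, row.names = FALSE)
    paths["profile"] <- p
    azm_log("profile", "wrote %s", p)
  }

  manifest <- list(
    tool = "azmetrics",
    version = as.character(utils::packageVersion("azmetrics")),
    seed = scene@metadata$seed %||% NA,
    config_hash = scene@metadata$config_hash %||% NA,
    mode = scene@metadata$mode %||% NA,
    compression = scene@metadata$compression %||% 1,
    outputs = as.list(stats::setNames(unname(tools::md5sum(paths)),
                                      names(paths))),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  p <- file.path(dir, "manifest.json")
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE,
                              digits = 10), p)
  paths["manifest"] <- p
  invisible(paths)
}
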