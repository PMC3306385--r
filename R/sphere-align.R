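# Unit-sphere mapping of vesicle connection sites and co-alignment of
# vesicles by maximizing rib-connection overlap over rotations.

#' Per-vesicle connection sites on the unit sphere
#'
#' Sites are mapped as (site - center) / radius to normalize the
#' variability of vesicle diameters; each vesicle carries the rotation so
#' far applied to its mapped sites (identity at construction).
#'
#' @slot vesicle_ids character vector.
#' @slot sites list, one element per vesicle: a list with \code{class}
#'   (character) and \code{u} (n-by-3 matrix of unit vectors).
#' @slot rotations list of 3-by-3 proper orthonormal matrices.
#' @export
setClass("SphereMap",
  representation(vesicle_ids = "character", sites = "list", rotations = "list"),
  validity = function(object) {
    msgs <- character()
    for (i in seq_along(object@sites)) {
      u <- object@sites[[i]]$u
      if (any(abs(sqrt(rowSums(u^2)) - 1) > 1e-9))
        msgs <- c(msgs, sprintf("vesicle %s: site vectors must have unit norm",
                                object@vesicle_ids[i]))
      R <- object@rotations[[i]]
      if (max(abs(t(R) %*% R - diag(3))) > 1e-9 || abs(det(R) - 1) > 1e-9)
        msgs <- c(msgs, sprintf("vesicle %s: rotation must be proper orthonormal",
                                object@vesicle_ids[i]))
    }
    if (length(msgs)) msgs else TRUE
  }
)

setMethod("show", "SphereMap", function(object) {
  n <- vapply(object@sites, function(s) nrow(s$u), integer(1))
  cat(sprintf("SphereMap: %d vesicles, %d sites (%d rib)\n",
              length(object@vesicle_ids), sum(n),
              sum(vapply(object@sites, function(s) sum(s$class == "rib"),
                         integer(1)))))
  invisible(object)
})

#' Map one vesicle's connection sites to the unit sphere
#'
#' @param scene a [Scene-class]; vesicles must be uncompressed (spherical).
#' @param vesicleId a vesicle id.
#' @param classes connection classes to map.
#' @return list with \code{class} and \code{u} (n-by-3 unit vectors).
#' @export
mapToUnitSphere <- function(scene, vesicleId,
                            classes = c("rib", "spar", "boom", "pin")) {
  vs <- scene@vesicles
  j <- match(vesicleId, vs$id)
  if (is.na(j))
    azm_error(paste("unknown vesicle id:", vesicleId), "azm_reference_error")
  if (abs(vs$z_semi_axis[j] - vs$radius[j]) > 1e-9)
    azm_error("vesicle is compressed (oblate); stretch-correct the scene first",
              "azm_argument_error")
  cs <- connectionSites(scene)
  cs <- cs[cs$vesicle_id == vesicleId & cs$class %in% classes, , drop = FALSE]
  u <- cbind(cs$x - vs$x[j], cs$y - vs$y[j], cs$z - vs$z[j]) / vs$radius[j]
  nrm <- sqrt(rowSums(u^2))
  off <- which(abs(nrm - 1) * vs$radius[j] > SURFACE_TOL)
  if (length(off))
    azm_error(sprintf("site(s) of filament(s) %s lie off the surface of %s",
                      paste(cs$filament_id[off], collapse = ", "), vesicleId),
              "azm_surface_error")
  list(class = cs$class, u = u / nrm)
}

#' Build a SphereMap for a scene
#'
#' @param scene a [Scene-class].
#' @param states vesicle states to include (default docked).
#' @param classes connection classes to map.
#' @param minSites keep vesicles with at least this many mapped sites.
#' @return a [SphereMap-class] with identity rotations.
#' @export
sphereMap <- function(scene, states = "docked",
                      classes = c("rib", "spar", "boom", "pin"),
                      minSites = 1L) {
  vs <- scene@vesicles
  ids <- vs$id[vs$state %in% states]
  sites <- lapply(ids, mapToUnitSphere, scene = scene, classes = classes)
  keep <- vapply(sites, function(s) nrow(s$u) >= minSites, logical(1))
  methods::new("SphereMap", vesicle_ids = ids[keep], sites = sites[keep],
               rotations = rep(list(diag(3)), sum(keep)))
}

# Apply an extra rotation to one vesicle of a map.
#' @noRd
rotate_vesicle <- function(map, i, R) {
  map@sites[[i]]$u <- map@sites[[i]]$u %*% t(R)
  map@rotations[[i]] <- R %*% map@rotations[[i]]
  map
}

#' Rough alignment: face all connection sites the same direction
#'
#' Rotates each vesicle by the minimal-angle rotation carrying the
#' normalized mean direction of its sites onto +x (the AZM-facing
#' direction). Vesicles whose sites are perfectly antipodal (zero mean)
#' are left at identity with a warning.
#'
#' @param map a [SphereMap-class].
#' @return the rotated [SphereMap-class].
#' @export
roughAlign <- function(map) {
  target <- c(1, 0, 0)
  for (i in seq_along(map@vesicle_ids)) {
    m <- colMeans(map@sites[[i]]$u)
    if (sqrt(sum(m^2)) < 1e-9) {
      warning(sprintf("vesicle %s: zero mean site direction; left unrotated",
                      map@vesicle_ids[i]))
      next
    }
    map <- rotate_vesicle(map, i, rotation_between(m, target))
  }
  map
}

#' Rib-connection overlap of a SphereMap
#'
#' A Gaussian kernel on the great-circle distance, summed over all
#' unordered pairs of rib sites from different vesicles:
#' \deqn{O = \sum_{pairs} \exp(-d_{gc}^2 / (2 w^2))}
#' with bandwidth \eqn{w} in radians. Symmetric under vesicle relabeling
#' and invariant under a common rotation of all vesicles.
#'
#' @param map a [SphereMap-class].
#' @param bandwidth kernel bandwidth in radians (default 0.3).
#' @return scalar overlap; 0 with a warning if there are no rib sites.
#' @export
ribOverlap <- function(map, bandwidth = 0.3) {
  if (bandwidth <= 0)
    azm_error("bandwidth must be > 0", "azm_argument_error")
  rib <- rib_sites(map)
  if (!nrow(rib$u)) {
    warning("no rib sites in map; overlap is 0")
    return(0)
  }
  D <- rib$u %*% t(rib$u)
  d <- acos(pmin(pmax(D, -1), 1))
  k <- exp(-d^2 / (2 * bandwidth^2))
  diff_ves <- outer(rib$ves, rib$ves, `!=`)
  sum(k[upper.tri(k) & diff_ves])
}

#' @noRd
rib_sites <- function(map, exclude = 0L) {
  us <- list(); ves <- integer()
  for (i in seq_along(map@vesicle_ids)) {
    if (i == exclude) next
    sel <- map@sites[[i]]$class == "rib"
    if (any(sel)) {
      us[[length(us) + 1L]] <- map@sites[[i]]$u[sel, , drop = FALSE]
      ves <- c(ves, rep(i, sum(sel)))
    }
  }
  list(u = if (length(us)) do.call(rbind, us) else matrix(0, 0, 3), ves = ves)
}

# Overlap contribution of vesicle i's rib sites (rotated by R) against all
# other vesicles' rib sites O (fixed).
#' @noRd
overlap_contribution <- function(S, R, O, bw) {
  D <- (S %*% t(R)) %*% t(O)
  d <- acos(pmin(pmax(D, -1), 1))
  sum(exp(-d^2 / (2 * bw^2)))
}

# Vectorized contribution over a list of candidate rotations.
#' @noRd
overlap_contribution_grid <- function(S, TRmat, K, O, bw) {
  n <- nrow(S)
  X <- S %*% TRmat                       # n x 3K, blocks of t(R_k)
  A <- array(X, c(n, 3, K))
  A <- aperm(A, c(1, 3, 2))
  dim(A) <- c(n * K, 3)
  D <- A %*% t(O)
  d <- acos(pmin(pmax(D, -1), 1))
  rs <- rowSums(exp(-d^2 / (2 * bw^2)))
  colSums(matrix(rs, n, K))
}

#' Alignment result
#'
#' @slot map the aligned [SphereMap-class].
#' @slot objective final rib-overlap value.
#' @slot trace objective after every accepted per-vesicle update (monotone
#'   non-decreasing).
#' @slot converged logical; FALSE if the iteration cap was reached.
#' @slot sites aggregated common-sphere site table (vesicle_id, class,
#'   x, y, z).
#' @slot classCentroids per-class normalized centroid directions.
#' @export
setClass("AlignmentResult",
  representation(map = "SphereMap", objective = "numeric", trace = "numeric",
                 converged = "logical", sites = "data.frame",
                 classCentroids = "data.frame"))

setMethod("show", "AlignmentResult", function(object) {
  cat(sprintf("AlignmentResult: %d vesicles, objective %.4f (%s, %d updates)\n",
              length(object@map@vesicle_ids), object@objective,
              if (object@converged) "converged" else "iteration cap reached",
              length(object@trace)))
  invisible(object)
})

#' Fine alignment by rib-overlap maximization
#'
#' Coordinate ascent over vesicles: for each vesicle in turn, its rotation
#' (z-y-z Euler parameterization) is optimized against the other vesicles'
#' rib sites by a coarse Euler-angle grid search followed by local
#' Nelder-Mead refinement; sweeps repeat until the objective improves by
#' less than \code{tol}. The current rotation always competes with the
#' candidates, so the objective never decreases. Scan order is by vesicle
#' position in the map; grid ties are broken toward the smaller rotation
#' angle. On small instances the result matches an exhaustive grid-search
#' oracle at the grid resolution.
#'
#' @param map a [SphereMap-class], typically after [roughAlign()]; needs at
#'   least 2 vesicles with at least 1 rib site each.
#' @param bandwidth kernel bandwidth in radians.
#' @param grid_deg coarse Euler grid resolution in degrees (default 10).
#' @param tol convergence tolerance on the objective.
#' @param max_sweeps sweep cap; if reached, the best-so-far result is
#'   returned with \code{converged = FALSE}.
#' @param refine logical; run Nelder-Mead refinement after the grid.
#' @return an [AlignmentResult-class].
#' @export
fineAlign <- function(map, bandwidth = 0.3, grid_deg = 10, tol = 1e-6,
                      max_sweeps = 8, refine = TRUE) {
  nv <- length(map@vesicle_ids)
  has_rib <- vapply(map@sites, function(s) any(s$class == "rib"), logical(1))
  if (nv < 2 || sum(has_rib) < 2)
    azm_error("fine alignment needs >= 2 vesicles with >= 1 rib site each",
              "azm_argument_error")
  step <- grid_deg * pi / 180
  alphas <- seq(0, 2 * pi - step / 2, by = step)
  betas <- seq(0, pi, by = step)
  gammas <- alphas
  grid <- expand.grid(alpha = alphas, beta = betas, gamma = gammas)
  Rs <- mapply(rotation_euler_zyz, grid$alpha, grid$beta, grid$gamma,
               SIMPLIFY = FALSE)
  grid_angle <- vapply(Rs, rotation_angle, numeric(1))
  TRmat <- matrix(unlist(lapply(Rs, t)), nrow = 3)
  K <- length(Rs)

  obj <- ribOverlap(map, bandwidth)
  trace <- obj
  converged <- FALSE
  for (sweep in seq_len(max_sweeps)) {
    improved <- obj
    for (i in seq_len(nv)) {
      if (!has_rib[i]) next
      others <- rib_sites(map, exclude = i)
      if (!nrow(others$u)) next
      sel <- map@sites[[i]]$class == "rib"
      S <- map@sites[[i]]$u[sel, , drop = FALSE]
      cur <- overlap_contribution(S, diag(3), others$u, bandwidth)
      vals <- overlap_contribution_grid(S, TRmat, K, others$u, bandwidth)
      best <- max(vals)
      cand <- which(vals > best - 1e-12)
      k <- cand[which.min(grid_angle[cand])]
      best_par <- as.numeric(grid[k, ])
      best_val <- vals[k]
      if (refine) {
        op <- stats::optim(best_par, function(p)
          -overlap_contribution(S, rotation_euler_zyz(p[1], p[2], p[3]),
                                others$u, bandwidth),
          method = "Nelder-Mead",
          control = list(reltol = 1e-10, maxit = 400))
        if (-op$value > best_val) { best_val <- -op$value; best_par <- op$par }
      }
      if (best_val > cur + 1e-12) {
        map <- rotate_vesicle(map, i, rotation_euler_zyz(best_par[1],
                                                         best_par[2],
                                                         best_par[3]))
        obj <- obj + (best_val - cur)
        trace <- c(trace, obj)
      }
    }
    if (obj - improved < tol) { converged <- TRUE; break }
  }
  obj <- ribOverlap(map, bandwidth)   # recompute exactly
  sites <- do.call(rbind, lapply(seq_len(nv), function(i)
    data.frame(vesicle_id = map@vesicle_ids[i], class = map@sites[[i]]$class,
               x = map@sites[[i]]$u[, 1], y = map@sites[[i]]$u[, 2],
               z = map@sites[[i]]$u[, 3], stringsAsFactors = FALSE)))
  cents <- do.call(rbind, lapply(split(sites[, c("x", "y", "z")], sites$class),
                                 function(m) {
    v <- unit(colMeans(as.matrix(m)))
    data.frame(x = v[1], y = v[2], z = v[3])
  }))
  cents <- data.frame(class = rownames(cents), cents, row.names = NULL,
                      stringsAsFactors = FALSE)
  methods::new("AlignmentResult", map = map, objective = obj, trace = trace,
               converged = converged, sites = sites, classCentroids = cents)
}

#' Per-vesicle class-centroid depths from the membrane
#'
#' For each vesicle the centroid of each connection class is summarized by
#' its membrane distance (mean z of the class's sites, exact under the
#' flat-membrane convention); offsets normalize each class centroid to the
#' vesicle's own rib centroid. Vesicles without rib sites contribute no
#' offsets.
#'
#' @param scene a [Scene-class].
#' @param states vesicle states to include (default docked).
#' @param classes connection classes to summarize.
#' @return data.frame (class, depth_mean, depth_sd, offset_mean, offset_sd,
#'   n) pooled over vesicles; the per-vesicle table is attached as
#'   attribute \code{"per_vesicle"} (vesicle_id, class, depth, offset).
#' @export
classCentroidDepths <- function(scene, states = "docked",
                                classes = c("rib", "spar", "boom")) {
  vs <- scene@vesicles
  cs <- connectionSites(scene)
  cs <- cs[cs$class %in% classes &
           cs$vesicle_id %in% vs$id[vs$state %in% states], , drop = FALSE]
  pv <- list()
  for (v in unique(cs$vesicle_id)) {
    sub <- cs[cs$vesicle_id == v, , drop = FALSE]
    if (!any(sub$class == "rib")) next
    ribz <- mean(sub$z[sub$class == "rib"])
    for (cl in unique(sub$class)) {
      depth <- mean(sub$z[sub$class == cl])
      pv[[length(pv) + 1L]] <- data.frame(vesicle_id = v, class = cl,
                                          depth = depth,
                                          offset = depth - ribz,
                                          stringsAsFactors = FALSE)
    }
  }
  pv <- if (length(pv)) do.call(rbind, pv) else
    data.frame(vesicle_id = character(), class = character(),
               depth = double(), offset = double(), stringsAsFactors = FALSE)
  out <- do.call(rbind, lapply(classes, function(cl) {
    sub <- pv[pv$class == cl, , drop = FALSE]
    data.frame(class = cl,
               depth_mean = if (nrow(sub)) mean(sub$depth) else NA_real_,
               depth_sd = if (nrow(sub) > 1) stats::sd(sub$depth) else NA_real_,
               offset_mean = if (nrow(sub)) mean(sub$offset) else NA_real_,
               offset_sd = if (nrow(sub) > 1) stats::sd(sub$offset) else NA_real_,
               n = nrow(sub), stringsAsFactors = FALSE)
  }))
  attr(out, "per_vesicle") <- pv
  out
}

#' One-way ANOVA across connection-class depth distributions
#'
#' @param depths data.frame with columns \code{class} and \code{depth}
#'   (e.g. the \code{"per_vesicle"} attribute of [classCentroidDepths()]).
#' @return list with F, p, df1, df2.
#' @export
classSeparationAnova <- function(depths) {
  depths <- depths[!is.na(depths$depth), , drop = FALSE]
  tab <- table(depths$class)
  if (length(tab) < 2 || any(tab < 2))
    azm_error("ANOVA needs >= 2 classes with >= 2 observations each",
              "azm_argument_error")
  fit <- stats::aov(depth ~ factor(class), data = depths)
  s <- summary(fit)[[1]]
  if (s[["Sum Sq"]][1] < 1e-12)   # no between-class variation at all
    return(list(F = 0, p = 1, df1 = s[["Df"]][1], df2 = s[["Df"]][2]))
  list(F = s[["F value"]][1], p = s[["Pr(>F)"]][1],
       df1 = s[["Df"]][1], df2 = s[["Df"]][2])
}
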