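# Distance-binned connectivity of undocked vesicles at vacated docking
# sites, and comparison against the docked-vesicle connection profile.

#' Default membrane-distance bins for undocked vesicles
#'
#' The published closed intervals, far to near: 29-42, 17-24 and 4-16 nm.
#' The gaps between them (16-17 and 24-29 nm) are preserved: a vesicle in a
#' gap is reported in the \code{unbinned} group, never silently assigned.
#'
#' @return data.frame with columns lo, hi (nm).
#' @export
defaultBins <- function() {
  data.frame(lo = c(29, 17, 4), hi = c(42, 24, 16))
}

#' Assign undocked vesicles to membrane-distance bins
#'
#' Undocked vesicles are assigned by [shortestDistanceToMembrane()] to the
#' closed bin containing their distance; vesicles in inter-bin gaps (or
#' beyond all bins) go to the \code{unbinned} group. Together the groups
#' partition the undocked vesicles.
#'
#' @param scene a [Scene-class].
#' @param bins data.frame with columns lo, hi (disjoint closed intervals).
#' @return named list of character vectors of vesicle ids: one element per
#'   bin (named \code{"lo-hi"}) plus \code{unbinned}; the distances used
#'   are attached as attribute \code{"distance"}.
#' @export
binUndocked <- function(scene, bins = defaultBins()) {
  if (any(bins$hi < bins$lo))
    azm_error("bins must have lo <= hi", "azm_config_error")
  o <- order(bins$lo)
  if (nrow(bins) > 1 && any(bins$lo[o][-1] <= bins$hi[o][-nrow(bins)]))
    azm_error("bins must be disjoint", "azm_config_error")
  vs <- scene@vesicles
  ids <- vs$id[vs$state == "undocked"]
  d <- shortestDistanceToMembrane(scene, ids)
  groups <- stats::setNames(
    lapply(seq_len(nrow(bins)), function(i)
      ids[d >= bins$lo[i] & d <= bins$hi[i]]),
    sprintf("%g-%g", bins$lo, bins$hi))
  groups$unbinned <- setdiff(ids, unlist(groups))
  attr(groups, "distance") <- d
  groups
}

#' Per-bin connection profiles
#'
#' For each bin group: per-class connection count mean/SD and the
#' main-body total (rib + spar + boom, summed per vesicle before
#' averaging).
#'
#' @param scene a [Scene-class].
#' @param groups groups from [binUndocked()] (default: recomputed with the
#'   default bins).
#' @return data.frame, one row per bin, with columns bin, n, and for rib,
#'   spar, boom, pin and main_body their mean and sd; empty bins have
#'   n = 0 and NA statistics. The raw per-vesicle counts are attached as
#'   attribute \code{"counts"}.
#' @export
binnedProfile <- function(scene, groups = binUndocked(scene)) {
  cc <- connectionCounts(scene)
  cls <- c("rib", "spar", "boom", "pin", "main_body")
  rows <- lapply(names(groups), function(g) {
    sub <- cc[cc$vesicle_id %in% groups[[g]], , drop = FALSE]
    row <- data.frame(bin = g, n = nrow(sub), stringsAsFactors = FALSE)
    for (cl in cls) {
      row[[paste0(cl, "_mean")]] <- if (nrow(sub)) mean(sub[[cl]]) else NA_real_
      row[[paste0(cl, "_sd")]] <- if (nrow(sub) > 1) stats::sd(sub[[cl]]) else NA_real_
    }
    row
  })
  out <- do.call(rbind, rows)
  attr(out, "counts") <- cc[cc$vesicle_id %in% unlist(groups), , drop = FALSE]
  out
}

#' Summarize per-vesicle counts into a class profile
#'
#' @param counts data.frame of per-vesicle counts as returned by
#'   [connectionCounts()] (possibly subset to a bin group).
#' @param classes classes to summarize.
#' @return data.frame with columns class, mean, sd, n.
#' @export
profileStats <- function(counts,
                         classes = c("rib", "spar", "boom", "pin",
                                     "main_body")) {
  do.call(rbind, lapply(classes, function(cl) {
    x <- counts[[cl]]
    data.frame(class = cl, mean = if (length(x)) mean(x) else NA_real_,
               sd = if (length(x) > 1) stats::sd(x) else NA_real_,
               n = length(x), stringsAsFactors = FALSE)
  }))
}

#' Compare two connection profiles per class
#'
#' Welch's two-sample t-test (unequal variances) computed from the profile
#' summaries (per-class mean, SD, n), with a flag for significance at
#' \code{alpha}. Classes with fewer than 2 observations on either side are
#' reported as not testable. Raw per-vesicle count tables (from
#' [connectionCounts()]) are accepted and summarized on the fly.
#'
#' @param profileA,profileB class profiles as returned by [profileStats()]
#'   (columns class, mean, sd, n), or raw count data.frames.
#' @param classes classes to compare (default: all classes shared by both
#'   profiles).
#' @param alpha significance level for the flag.
#' @return data.frame with columns class, mean_a, mean_b, t, df, p,
#'   significant, testable.
#' @export
compareProfiles <- function(profileA, profileB, classes = NULL,
                            alpha = 0.05) {
  as_profile <- function(x) {
    if (all(c("mean", "sd", "n") %in% names(x))) return(x)
    profileStats(x, classes = classes %||%
                   c("rib", "spar", "boom", "pin", "main_body"))
  }
  pa <- as_profile(profileA); pb <- as_profile(profileB)
  if (is.null(classes)) classes <- intersect(pa$class, pb$class)
  rows <- lapply(classes, function(cl) {
    a <- pa[pa$class == cl, ]; b <- pb[pb$class == cl, ]
    out <- data.frame(class = cl, mean_a = a$mean, mean_b = b$mean,
                      t = NA_real_, df = NA_real_, p = NA_real_,
                      significant = NA, testable = FALSE,
                      stringsAsFactors = FALSE)
    if (a$n < 2 || b$n < 2) return(out)
    out$testable <- TRUE
    v1 <- a$sd^2 / a$n; v2 <- b$sd^2 / b$n
    if (v1 + v2 == 0) {
      # zero variance on both sides: equal constants are identically
      # distributed, different constants trivially differ
      eq <- isTRUE(all.equal(a$mean, b$mean))
      out$t <- if (eq) 0 else Inf
      out$p <- if (eq) 1 else 0
      out$significant <- !eq
      return(out)
    }
    out$t <- (a$mean - b$mean) / sqrt(v1 + v2)
    out$df <- (v1 + v2)^2 / (v1^2 / (a$n - 1) + v2^2 / (b$n - 1))
    out$p <- 2 * stats::pt(-abs(out$t), out$df)
    out$significant <- out$p < alpha
    out
  })
  do.call(rbind, rows)
}
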