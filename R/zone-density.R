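# Positional density along the screen axis, the NCF/DFM proportion-of-
# density curve, decision-zone detection, and the region of behavioral
# uncertainty (block-wise divergence of the proportion curve).

#' Cue-conditional positional density
#'
#' Gaussian kernel density of distance-from-screen, estimated separately per
#' cue on a common grid and normalized so each cue's curve integrates to 1
#' over the analyzed range.
#'
#' @param distances Numeric vector of distances from the screen, mm.
#' @param cues Character vector of cue labels (`"NCF"`/`"DFM"`), same length.
#' @param range Analyzed range `c(lower, upper)` mm.
#' @param bandwidth Gaussian kernel SD, mm.
#' @param bin_width Grid spacing, mm.
#' @return An object of class `density_curve`: a data.frame with
#'   `bin_center` and one density column per cue; frame counts are kept in
#'   the `"n_frames"` attribute.
#' @export
location_density <- function(distances, cues, range = c(20, 240),
                             bandwidth = 10, bin_width = 2) {
  stopifnot(length(distances) == length(cues), range[1] < range[2],
            bandwidth > 0, bin_width > 0)
  if (!length(distances)) stop("no frames supplied")
  grid <- seq(range[1], range[2], by = bin_width)
  levs <- unique(cues)
  n_frames <- integer(0)
  out <- data.frame(bin_center = grid)
  for (cu in levs) {
    x <- distances[cues == cu]
    if (!length(x)) stop("no frames for cue ", cu)
    d <- stats::density(x, bw = bandwidth, from = range[1], to = range[2],
                        n = length(grid))
    y <- d$y
    y <- y / (sum(y) * bin_width)   # renormalize over the analyzed range
    out[[cu]] <- y
    n_frames[cu] <- length(x)
  }
  attr(out, "n_frames") <- n_frames
  attr(out, "bin_width") <- bin_width
  class(out) <- c("density_curve", "data.frame")
  out
}

#' NCF proportion-of-density curve
#'
#' Pointwise occupancy share of the NCF cue,
#' `p = w * density_NCF / (w * density_NCF + (1 - w) * density_DFM)` with
#' `w` the NCF share of frames — each per-cue density integrates to 1, so
#' the frame counts re-weight them into occupancy proportions (with equal
#' counts this is the plain density ratio). Bins whose joint density falls
#' below a floor (default 1% of the uniform level over the analyzed range)
#' are flagged undefined (`NA`).
#'
#' @param curve A [location_density()] result containing both cues.
#' @param floor_frac Undefined-bin floor as a fraction of the uniform
#'   density level.
#' @return An object of class `proportion_curve`: data.frame with
#'   `bin_center` and `p_ncf` (`NA` where undefined).
#' @export
proportion_curve <- function(curve, floor_frac = 0.01) {
  stopifnot(all(c("NCF", "DFM") %in% names(curve)))
  nf <- attr(curve, "n_frames")
  if (!is.null(nf) && all(c("NCF", "DFM") %in% names(nf))) {
    w <- nf[["NCF"]] / (nf[["NCF"]] + nf[["DFM"]])
  } else w <- 0.5
  curve$NCF <- w * curve$NCF
  curve$DFM <- (1 - w) * curve$DFM
  joint <- curve$NCF + curve$DFM
  rng <- range(curve$bin_center)
  uniform <- 1 / (rng[2] - rng[1])
  p <- curve$NCF / joint
  p[joint < floor_frac * uniform] <- NA_real_
  out <- data.frame(bin_center = curve$bin_center, p_ncf = p)
  class(out) <- c("proportion_curve", "data.frame")
  out
}

#' Detect the decision zone
#'
#' The decision zone is the band of distances where the cue-conditional
#' occupancy proportion changes steeply: the maximal contiguous interval in
#' which the absolute gradient `|dp/dx|` exceeds the `gradient_quantile`
#' quantile of its own distribution (over defined bins), required to contain
#' the global maximum-gradient bin.
#'
#' @param p A [proportion_curve()] with >= 10 defined bins.
#' @param gradient_quantile Quantile defining "steep", in `(0, 1)`.
#' @param flat_tol Curves whose maximum gradient is below this (per mm) are
#'   declared flat (no zone).
#' @return A list of class `decision_zone` with `lower`, `upper` (mm),
#'   `max_gradient` (per mm) and `found` (FALSE for flat curves, in which
#'   case bounds are `NA`).
#' @export
detect_decision_zone <- function(p, gradient_quantile = 0.75,
                                 flat_tol = 1e-6) {
  ok <- !is.na(p$p_ncf)
  if (sum(ok) < 10L) stop("proportion curve has fewer than 10 defined bins")
  x <- p$bin_center[ok]
  y <- p$p_ncf[ok]
  grad <- abs(diff(y) / diff(x))       # gradient on bin midpoints
  if (max(grad) < flat_tol)
    return(structure(list(lower = NA_real_, upper = NA_real_,
                          max_gradient = max(grad), found = FALSE),
                     class = "decision_zone"))
  thr <- stats::quantile(grad, gradient_quantile, names = FALSE)
  steep <- grad > thr
  imax <- which.max(grad)
  if (!steep[imax]) steep[imax] <- TRUE
  r <- rle(steep)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  seg <- which(r$values & starts <= imax & ends >= imax)
  i0 <- starts[seg]; i1 <- ends[seg]
  structure(list(lower = x[i0], upper = x[i1 + 1L],
                 max_gradient = max(grad), found = TRUE),
            class = "decision_zone")
}

#' @export
print.decision_zone <- function(x, ...) {
  if (x$found)
    cat(sprintf("<decision_zone: [%.1f, %.1f] mm, max |dp/dx| = %.4g /mm>\n",
                x$lower, x$upper, x$max_gradient))
  else cat("<decision_zone: none (flat proportion curve)>\n")
  invisible(x)
}

#' Region of behavioral uncertainty
#'
#' Compares the proportion curves of two trial blocks and returns the
#' distance intervals where they diverge by more than `tolerance`, plus the
#' integrated absolute divergence over those intervals. In the assay this
#' divergence is attributed to hysteresis from preceding aversive trials.
#'
#' @param p_a,p_b Two [proportion_curve()] results on identical bins.
#' @param tolerance Divergence threshold on the proportion scale.
#' @return A list of class `uncertainty_region` with `intervals` (data.frame
#'   `lower`/`upper`, mm) and `magnitude` (integral of `|p_a - p_b|` over
#'   the intervals, mm).
#' @export
uncertainty_region <- function(p_a, p_b, tolerance = 0.05) {
  if (nrow(p_a) != nrow(p_b) ||
      any(abs(p_a$bin_center - p_b$bin_center) > 1e-9))
    stop("proportion curves are on different bins")
  d <- abs(p_a$p_ncf - p_b$p_ncf)
  ok <- !is.na(d)
  over <- ok & d > tolerance
  if (!any(over))
    return(structure(list(intervals = data.frame(lower = numeric(0),
                                                 upper = numeric(0)),
                          magnitude = 0),
                     class = "uncertainty_region"))
  r <- rle(over)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  sel <- which(r$values)
  bw <- diff(p_a$bin_center[1:2])
  intervals <- data.frame(lower = p_a$bin_center[starts[sel]] - bw / 2,
                          upper = p_a$bin_center[ends[sel]] + bw / 2)
  magnitude <- sum(d[over]) * bw
  structure(list(intervals = intervals, magnitude = magnitude),
            class = "uncertainty_region")
}

#' Plot density / proportion curves
#'
#' @param x A `density_curve` or `proportion_curve`.
#' @param ... Passed to [graphics::matplot()] / [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.density_curve <- function(x, ...) {
  cues <- setdiff(names(x), "bin_center")
  graphics::matplot(x$bin_center, as.matrix(x[cues]), type = "l", lty = 1,
                    col = c("firebrick", "steelblue")[seq_along(cues)],
                    xlab = "distance from screen (mm)", ylab = "density (/mm)",
                    ...)
  graphics::legend("topright", legend = cues, lty = 1,
                   col = c("firebrick", "steelblue")[seq_along(cues)])
  invisible(x)
}

#' @rdname plot.density_curve
#' @export
plot.proportion_curve <- function(x, ...) {
  graphics::plot(x$bin_center, x$p_ncf, type = "l", ylim = c(0, 1),
                 xlab = "distance from screen (mm)",
                 ylab = "proportion NCF", ...)
  graphics::abline(h = 0.5, lty = 3)
  invisible(x)
}
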