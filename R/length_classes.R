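# The 3-component length-distribution model: the empirical inverse CDF of
# transcript lengths is fitted in double-log coordinates by piecewise
# quadratics ("extended power laws"; a pure power law is the linear case),
# the segmentation chosen by exhaustive grid search minimizing total squared
# residual, and the nt cutoffs separating the lncRNA classes taken from the
# intersections of adjacent fitted components.

#' Construct a mixture component
#'
#' A quadratic `y = a0 + a1 x + a2 x^2` in `x = log10(length_nt)`,
#' `y = log10(fraction of transcripts >= length)`, valid on `fit_range`.
#' Since an iCDF is non-increasing, the fitted slope should be <= 0 on the
#' fit range; a violation (possible on noisy near-flat segments) is a
#' warning, not an error.
#'
#' @param a0,a1,a2 polynomial coefficients.
#' @param fit_range optional `c(x_lo, x_hi)` in log10 nt.
#' @return a list of class `"MixtureComponent"`.
#' @export
mixture_component <- function(a0, a1, a2, fit_range = NULL) {
  if (!is.null(fit_range)) {
    if (fit_range[1] >= fit_range[2]) stop("fit_range must be increasing")
    slope <- a1 + 2 * a2 * fit_range
    if (any(slope > 1e-6))
      warning("component slope positive inside fit_range")
  }
  structure(list(a0 = a0, a1 = a1, a2 = a2, fit_range = fit_range),
            class = "MixtureComponent")
}

predict_component <- function(comp, x) comp$a0 + comp$a1 * x + comp$a2 * x^2

#' Empirical inverse cumulative distribution of lengths
#'
#' For each distinct observed length `L`, the fraction of transcripts with
#' length >= `L`. The fraction at the minimum length is exactly 1 and the
#' sequence is non-increasing; no binning is applied.
#'
#' @param lengths numeric vector of transcript lengths in nt (all >= 1).
#' @return data.frame with columns `length` (distinct, ascending) and
#'   `fraction`.
#' @export
empirical_icdf <- function(lengths) {
  if (length(lengths) == 0L) stop("empty length vector")
  if (any(lengths < 1)) stop("lengths must be >= 1 nt")
  x <- sort(unique(lengths))
  n <- length(lengths)
  # fraction >= x[i]: count of observations at or above x[i]
  counts <- tabulate(match(lengths, x), nbins = length(x))
  frac <- rev(cumsum(rev(counts))) / n
  data.frame(length = x, fraction = frac)
}

# Quadratic OLS on (x, y) restricted to index range l..r, using prefix sums
# over a centered abscissa for conditioning. Returns coefficients in the
# ORIGINAL x basis plus the segment SSE.
make_segment_fitter <- function(x, y) {
  ctr <- mean(x)
  xc <- x - ctr
  P <- sapply(0:4, function(p) cumsum(xc^p))       # moments of xc
  Q <- sapply(0:2, function(p) cumsum(xc^p * y))   # cross moments
  Syy <- cumsum(y^2)
  seg <- function(l, r) {
    at <- function(M, p) M[r, p + 1L] - if (l > 1L) M[l - 1L, p + 1L] else 0
    m <- matrix(c(at(P, 0), at(P, 1), at(P, 2),
                  at(P, 1), at(P, 2), at(P, 3),
                  at(P, 2), at(P, 3), at(P, 4)), 3, 3)
    v <- c(at(Q, 0), at(Q, 1), at(Q, 2))
    b <- tryCatch(solve(m, v), error = function(e) NULL)
    if (is.null(b)) return(NULL)
    syy <- Syy[r] - if (l > 1L) Syy[l - 1L] else 0
    sse <- max(0, syy - sum(b * v))
    # expand centered polynomial back to the original x basis
    a2 <- b[3]
    a1 <- b[2] - 2 * b[3] * ctr
    a0 <- b[1] - b[2] * ctr + b[3] * ctr^2
    # iCDF monotonicity: the fitted slope a1 + 2 a2 x must be <= 0 across
    # the segment (linear in x, so the endpoints suffice)
    slope_ok <- all(a1 + 2 * a2 * x[c(l, r)] <= 1e-6)
    list(coef = c(a0, a1, a2), sse = sse, valid = slope_ok)
  }
  seg
}

#' Fit the length-mixture model in double-log iCDF space
#'
#' The distinct-length iCDF points are split into `n_components` contiguous
#' segments; every candidate segmentation on the (possibly thinned)
#' distinct-length grid is scored by the total squared residual of
#' per-segment quadratic least-squares fits, and the global minimizer is
#' returned. Cutoffs in nt come from [component_intersection()] of adjacent
#' components; the fit is fully deterministic given the input.
#'
#' @param lengths numeric vector of lengths in nt (>= 30 distinct values).
#' @param n_components 1, 2 or 3.
#' @param min_points minimum iCDF points per segment (default 8).
#' @param max_candidates maximum number of candidate breakpoint positions;
#'   when the distinct-length grid is larger it is thinned evenly (the fit
#'   itself always uses every point).
#' @return a list of class `"MixtureFit"`: `components` (list of
#'   [mixture_component()]), `breakpoints_x` (log10 intersection abscissae),
#'   `cutoffs_nt`, `sse`, `class_proportions` (fraction of the input lengths
#'   per class), `lognormal_body` (`mu`, `sigma` of the natural-log fit to
#'   the shortest class), and `n`.
#' @export
fit_mixture <- function(lengths, n_components = 3, min_points = 8,
                        max_candidates = 60) {
  if (!n_components %in% 1:3) stop("n_components must be 1, 2 or 3")
  icdf <- empirical_icdf(lengths)
  if (nrow(icdf) < 30L) stop("need at least 30 distinct lengths")
  x <- log10(icdf$length)
  y <- log10(icdf$fraction)
  npts <- length(x)
  fit_seg <- make_segment_fitter(x, y)

  # candidate segment boundaries: segment 1 ends at index b (points 1..b)
  cand <- seq_len(npts)
  if (npts > max_candidates)
    cand <- unique(round(seq(1, npts, length.out = max_candidates)))

  # Enumerate all candidate segmentations with their total SSE. Ones whose
  # fitted component has positive slope anywhere on its range violate the
  # iCDF monotonicity invariant and are deferred behind all valid ones;
  # within each group, smaller SSE is preferred. The best segmentation
  # whose adjacent components actually intersect at strictly increasing
  # cutoffs is returned, so the fit minimizes SSE among segmentations that
  # yield a usable set of cutoffs.
  segmentations <- list()
  consider <- function(bounds) {
    fits <- list()
    lo <- c(1L, bounds + 1L)
    hi <- c(bounds, npts)
    for (k in seq_along(lo)) {
      f <- fit_seg(lo[k], hi[k])
      if (is.null(f)) return(invisible(NULL))
      fits[[k]] <- f
    }
    segmentations[[length(segmentations) + 1L]] <<- list(
      bounds = bounds, fits = fits,
      sse = sum(vapply(fits, `[[`, numeric(1), "sse")),
      valid = all(vapply(fits, `[[`, logical(1), "valid")))
    invisible(NULL)
  }
  if (n_components == 1L) {
    consider(integer(0))
  } else if (n_components == 2L) {
    for (b1 in cand[cand >= min_points & cand <= npts - min_points])
      consider(b1)
  } else {
    b1s <- cand[cand >= min_points & cand <= npts - 2L * min_points]
    for (b1 in b1s) {
      b2s <- cand[cand >= b1 + min_points & cand <= npts - min_points]
      for (b2 in b2s) consider(c(b1, b2))
    }
  }
  if (length(segmentations) == 0L)
    stop("no segmentation with at least ", min_points,
         " points per segment; try fewer components")
  ord <- order(!vapply(segmentations, `[[`, logical(1), "valid"),
               vapply(segmentations, `[[`, numeric(1), "sse"))

  best <- NULL
  components <- NULL
  cutoffs_nt <- numeric(0)
  last_err <- NULL
  for (si in ord) {
    s <- segmentations[[si]]
    seg_lo <- c(1L, s$bounds + 1L)
    seg_hi <- c(s$bounds, npts)
    comps <- lapply(seq_len(n_components), function(k)
      suppressWarnings(mixture_component(
        s$fits[[k]]$coef[1], s$fits[[k]]$coef[2], s$fits[[k]]$coef[3],
        fit_range = c(x[seg_lo[k]], x[seg_hi[k]])
      )))
    cuts <- tryCatch({
      if (n_components == 1L) numeric(0)
      else {
        cc <- vapply(seq_len(n_components - 1L), function(k)
          component_intersection(comps[[k]], comps[[k + 1L]],
                                 search = c(x[seg_lo[k]],
                                            x[seg_hi[k + 1L]])),
          numeric(1))
        if (is.unsorted(cc, strictly = TRUE))
          stop("fitted cutoffs are not strictly increasing")
        cc
      }
    }, error = function(e) e)
    if (!inherits(cuts, "error")) {
      best <- s
      components <- comps
      cutoffs_nt <- cuts
      break
    }
    last_err <- cuts
  }
  if (is.null(best))
    stop("no segmentation yields intersecting components: ",
         conditionMessage(last_err))

  edges <- c(-Inf, cutoffs_nt, Inf)
  class_proportions <- vapply(seq_len(n_components), function(k)
    mean(lengths > edges[k] & lengths <= edges[k + 1L]), numeric(1))
  body <- lengths[lengths <= edges[2]]
  lognormal_body <- if (length(body) >= 2L)
    c(mu = mean(log(body)), sigma = stats::sd(log(body)))
  else c(mu = NA_real_, sigma = NA_real_)

  structure(list(components = components,
                 breakpoints_x = log10(cutoffs_nt),
                 cutoffs_nt = cutoffs_nt,
                 sse = best$sse,
                 class_proportions = class_proportions,
                 lognormal_body = lognormal_body,
                 n = length(lengths)),
            class = "MixtureFit")
}

#' @export
print.MixtureFit <- function(x, ...) {
  cat(sprintf("MixtureFit: %d component(s), n = %d, SSE = %.4g\n",
              length(x$components), x$n, x$sse))
  if (length(x$cutoffs_nt))
    cat("cutoffs (nt):", paste(sprintf("%.0f", x$cutoffs_nt),
                               collapse = ", "), "\n")
  cat("class proportions:",
      paste(sprintf("%.3f", x$class_proportions), collapse = ", "), "\n")
  invisible(x)
}

#' Intersection of two mixture components
#'
#' Solves `(a0_1 - a0_2) + (a1_1 - a1_2) x + (a2_1 - a2_2) x^2 = 0` and
#' returns `10^x` for the real root inside `search`. When both roots fall
#' inside, the one closer to the components' shared segment boundary (or to
#' the middle of `search` if fit ranges are unknown) is taken.
#'
#' @param c1,c2 [mixture_component()] objects.
#' @param search `c(x_lo, x_hi)` interval in log10 nt to search.
#' @return cutoff in nt.
#' @export
component_intersection <- function(c1, c2, search) {
  d0 <- c1$a0 - c2$a0; d1 <- c1$a1 - c2$a1; d2 <- c1$a2 - c2$a2
  eps <- 1e-12
  if (abs(d2) < eps && abs(d1) < eps)
    stop(if (abs(d0) < eps) "components are identical"
         else "components are parallel (no intersection)")
  roots <- if (abs(d2) < eps) {
    -d0 / d1
  } else {
    disc <- d1^2 - 4 * d2 * d0
    if (disc < 0) stop("components do not intersect (no real root)")
    (-d1 + c(-1, 1) * sqrt(disc)) / (2 * d2)
  }
  inside <- roots[roots >= search[1] - 1e-9 & roots <= search[2] + 1e-9]
  if (length(inside) == 0L)
    stop("no intersection inside the search interval")
  if (length(inside) > 1L) {
    boundary <- if (!is.null(c1$fit_range) && !is.null(c2$fit_range))
      (c1$fit_range[2] + c2$fit_range[1]) / 2
    else mean(search)
    inside <- inside[which.min(abs(inside - boundary))]
  }
  10^inside
}

#' Classify lengths into the three lncRNA classes
#'
#' Class 1 is `[min_nt, c1]`, class 2 `(c1, c2]`, class 3 `(c2, Inf)`;
#' anything below `min_nt` is `below_min`. Ties at a cutoff go to the lower
#' class; the partition is total.
#'
#' @param lengths numeric lengths in nt.
#' @param cutoffs_nt `c(c1, c2)` with `min_nt < c1 < c2`.
#' @param min_nt lncRNA length floor (default 200).
#' @return factor with levels `below_min`, `class1`, `class2`, `class3`.
#' @export
classify_lengths <- function(lengths, cutoffs_nt, min_nt = 200) {
  if (length(cutoffs_nt) != 2L || !(min_nt < cutoffs_nt[1]) ||
      !(cutoffs_nt[1] < cutoffs_nt[2]))
    stop("need min_nt < cutoffs_nt[1] < cutoffs_nt[2]")
  lab <- ifelse(lengths < min_nt, "below_min",
                ifelse(lengths <= cutoffs_nt[1], "class1",
                       ifelse(lengths <= cutoffs_nt[2], "class2", "class3")))
  factor(lab, levels = c("below_min", "class1", "class2", "class3"))
}
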