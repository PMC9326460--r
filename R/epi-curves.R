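#' @include AllClasses.R AllGenerics.R
NULL

# Raw (unclamped) relative risk: log-linear interpolation between knots,
# constant extrapolation beyond the outermost knots.
.rawRR <- function(curve, x) {
  k <- curve@intake
  lr <- log(curve@rr)
  if (length(k) == 1L) return(rep(curve@rr, length(x)))
  exp(stats::approx(k, lr, xout = x, rule = 2)$y)
}

.insideTMREL <- function(tmrel, x) x >= tmrel@low & x <= tmrel@high

#' Evaluate a relative-risk curve at an intake
#'
#' Relative risk is 1 inside the theoretical minimum-risk exposure level
#' (TMREL) range — marginal changes there carry no benefit or harm. Outside
#' it, the curve is log-linear between knots and constant beyond the
#' outermost knots.
#'
#' @param curve an [RRCurve-class].
#' @param intake intake, g/day (vectorized, must be >= 0).
#' @return relative risk(s) at the given intake(s).
#' @examples
#' cv <- RRCurve("sodium", intake = c(2, 3), rr = c(1, exp(1)),
#'               tmrel = TMRELRange(-Inf, 2))
#' rrEvaluate(cv, 3)  # e
#' rrEvaluate(cv, 1)  # 1 (inside TMREL)
#' @export
rrEvaluate <- function(curve, intake) {
  stopifnot(is(curve, "RRCurve"))
  validObject(curve)
  if (anyNA(intake) || any(intake < 0)) stop("intake must be non-negative")
  out <- .rawRR(curve, intake)
  out[.insideTMREL(curve@tmrel, intake)] <- 1
  out
}

# Exact integral of the clamped RR over [l, u]. The clamped curve is
# piecewise: 1 inside the TMREL, exp(a + b x) between knots, constant beyond
# the knot range — so the integral has a closed form on each piece. Exact
# integration (rather than midpoint quadrature) is what makes PAF invariant
# under histogram-bin refinement.
.integrateRR <- function(curve, l, u) {
  if (u <= l) return(0)
  k <- curve@intake
  cuts <- sort(unique(c(l, u,
                        k[k > l & k < u],
                        curve@tmrel@low[curve@tmrel@low > l & curve@tmrel@low < u],
                        curve@tmrel@high[curve@tmrel@high > l & curve@tmrel@high < u])))
  total <- 0
  lr <- log(curve@rr)
  for (i in seq_len(length(cuts) - 1L)) {
    p <- cuts[i]; q <- cuts[i + 1L]; m <- (p + q) / 2
    if (.insideTMREL(curve@tmrel, m)) {
      total <- total + (q - p)
    } else if (length(k) == 1L || m <= k[1L]) {
      total <- total + curve@rr[1L] * (q - p)
    } else if (m >= k[length(k)]) {
      total <- total + curve@rr[length(k)] * (q - p)
    } else {
      j <- findInterval(m, k)
      b <- (lr[j + 1L] - lr[j]) / (k[j + 1L] - k[j])
      a <- lr[j] - b * k[j]
      total <- total +
        if (b == 0) exp(a) * (q - p)
        else (exp(a + b * q) - exp(a + b * p)) / b
    }
  }
  total
}

# Shifted-histogram pieces after clamping at zero intake: returns a list of
# (lower, upper, prob) pieces, where lower == upper encodes a point mass.
.histogramPieces <- function(dist) {
  b <- dist@bins
  s <- dist@shift
  pieces <- vector("list", 0L)
  for (i in seq_len(nrow(b))) {
    l <- b$lower[i] + s; u <- b$upper[i] + s; p <- b$prob[i]
    if (p == 0) next
    if (u <= 0) {
      pieces[[length(pieces) + 1L]] <- c(0, 0, p)
    } else if (l < 0) {
      w <- u - l
      pieces[[length(pieces) + 1L]] <- c(0, 0, p * (-l) / w)
      pieces[[length(pieces) + 1L]] <- c(0, u, p * u / w)
    } else {
      pieces[[length(pieces) + 1L]] <- c(l, u, p)
    }
  }
  pieces
}

#' Expected relative risk over an intake distribution
#'
#' Integrates the TMREL-clamped relative-risk curve over the population
#' intake distribution. Histogram bins are integrated in closed form
#' (the clamped curve is piecewise exponential); the lognormal case uses
#' adaptive quadrature.
#'
#' @param curve an [RRCurve-class].
#' @param dist an [IntakeDistribution-class].
#' @return E[RR], a single number >= min(RR).
#' @export
expectedRR <- function(curve, dist) {
  stopifnot(is(curve, "RRCurve"), is(dist, "IntakeDistribution"))
  validObject(curve); validObject(dist)
  switch(dist@type,
    point = unname(rrEvaluate(curve, max(0, dist@value + dist@shift))),
    histogram = {
      tot <- 0
      for (pc in .histogramPieces(dist)) {
        l <- pc[1L]; u <- pc[2L]; p <- pc[3L]
        tot <- tot + if (u > l) p * .integrateRR(curve, l, u) / (u - l)
                     else p * rrEvaluate(curve, l)
      }
      tot
    },
    lognormal = {
      s <- dist@shift
      atZero <- if (s < 0) stats::plnorm(-s, dist@meanlog, dist@sdlog) else 0
      f <- function(t) rrEvaluate(curve, t + s) * stats::dlnorm(t, dist@meanlog, dist@sdlog)
      lower <- max(0, -s)
      int <- stats::integrate(f, lower, Inf, rel.tol = 1e-10,
                              subdivisions = 500L)$value
      atZero * rrEvaluate(curve, 0) + int
    })
}

#' Population attributable fraction with a TMREL counterfactual
#'
#' The comparative-risk-assessment PAF: `(E[RR] - 1) / E[RR]`, where the
#' expectation integrates the TMREL-clamped relative risk over the observed
#' intake distribution and the counterfactual population at the TMREL has
#' RR = 1. The PAF lies in (-Inf, 1); it is 0 when RR is identically 1, and
#' negative when current intakes are protective relative to the TMREL.
#'
#' @param curve an [RRCurve-class].
#' @param dist an [IntakeDistribution-class].
#' @return the population attributable fraction.
#' @examples
#' cv <- RRCurve("red_meat", intake = c(0, 50), rr = c(1, 2),
#'               tmrel = TMRELRange(0, 0))
#' paf(cv, intakePoint(50))  # (2-1)/2 = 0.5
#' @export
paf <- function(curve, dist) {
  err <- expectedRR(curve, dist)
  (err - 1) / err
}

#' Rigidly shift an intake distribution
#'
#' Translates the whole distribution by `delta` g/day (a change in mean
#' intake, keeping the shape). Mass that a negative shift would push below
#' zero intake is lumped at zero and the distribution's `clamped` flag is
#' raised.
#'
#' @param dist an [IntakeDistribution-class].
#' @param delta signed shift, g/day.
#' @return the shifted [IntakeDistribution-class].
#' @export
shiftIntake <- function(dist, delta) {
  stopifnot(is(dist, "IntakeDistribution"))
  if (!is.finite(delta)) stop("shift must be finite")
  out <- dist
  out@shift <- dist@shift + delta
  if (dist@type == "point") {
    v <- dist@value + out@shift
    if (v < 0) out@clamped <- TRUE
  } else if (dist@type == "histogram") {
    if (any(dist@bins$lower + out@shift < 0) && any(dist@bins$prob > 0))
      out@clamped <- TRUE
  } else {
    if (out@shift < 0) out@clamped <- TRUE
  }
  out
}

#' @rdname meanIntake
#' @export
setMethod("meanIntake", "IntakeDistribution", function(x) {
  s <- x@shift
  switch(x@type,
    point = max(0, x@value + s),
    histogram = {
      m <- 0
      for (pc in .histogramPieces(x)) m <- m + pc[3L] * (pc[1L] + pc[2L]) / 2
      m
    },
    lognormal = {
      mu <- x@meanlog; sg <- x@sdlog
      ex <- exp(mu + sg^2 / 2)
      if (s >= 0) s + ex
      else {
        tail <- ex * (1 - stats::pnorm((log(-s) - mu - sg^2) / sg))
        s * (1 - stats::plnorm(-s, mu, sg)) + tail
      }
    })
})

#' Fraction of the population outside the TMREL (active range)
#'
#' Marginal characterization is meaningful only for the share of the
#' population in the active range of consumption — outside the TMREL, where
#' marginal intake changes alter risk. This reports that probability mass so
#' users can see when a marginal score is inapplicable.
#'
#' @param dist an [IntakeDistribution-class].
#' @param tmrel a [TMRELRange-class].
#' @return probability mass outside `[low, high]`.
#' @examples
#' activeRangeFraction(intakeHistogram(0, 10, 1), TMRELRange(5, Inf))  # 0.5
#' @export
activeRangeFraction <- function(dist, tmrel) {
  stopifnot(is(dist, "IntakeDistribution"), is(tmrel, "TMRELRange"))
  validObject(dist); validObject(tmrel)
  inside <- function(v) v >= tmrel@low & v <= tmrel@high
  switch(dist@type,
    point = as.numeric(!inside(max(0, dist@value + dist@shift))),
    histogram = {
      outside <- 0
      for (pc in .histogramPieces(dist)) {
        l <- pc[1L]; u <- pc[2L]; p <- pc[3L]
        if (u > l) {
          ov <- max(0, min(u, tmrel@high) - max(l, tmrel@low))
          outside <- outside + p * (1 - ov / (u - l))
        } else outside <- outside + p * (!inside(l))
      }
      outside
    },
    lognormal = {
      s <- dist@shift
      mu <- dist@meanlog; sg <- dist@sdlog
      pBelow <- function(q) {  # P(clamp(s + L, 0) < q)
        if (q <= 0) 0 else stats::plnorm(q - s, mu, sg)
      }
      below <- if (is.finite(tmrel@low)) pBelow(tmrel@low)
               else if (tmrel@low == -Inf) 0 else 0
      above <- if (is.finite(tmrel@high)) 1 - pBelow(tmrel@high) else 0
      # point mass at zero (from clamping) counts as inside iff 0 is in range
      below + above
    })
}
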