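# Optically weighted oxygen-drop metrics derived from a solved 3D field.
# The detector sits below the window plane, so PO2 values deeper in the
# channel are attenuated exponentially: the depth weight is e^{-mu (y-y0)}.
# The weighting is normalized so a uniform field maps to itself and every
# weighted quantity keeps units of mmHg.

weighted_profile_internal <- function(f, mu, centreline = FALSE,
                                      normalize = TRUE) {
  m <- f$mesh
  g <- m$geometry
  if (is.null(mu)) mu <- f$cfg$physics$mu_attenuation
  if (is.na(mu))
    stop("mu (optical attenuation, 1/mm) must be set in the physics ",
         "or passed explicitly; pass mu = 0 for unweighted averaging")
  if (mu < 0) stop("mu must be >= 0")
  pf <- po2_array(f)
  rbc <- m$tag == TAG_RBC
  xi <- which(apply(rbc, 1, any))
  jk <- which(rbc[xi[1], , ], arr.ind = TRUE)
  if (centreline) {
    zb <- abs(m$zc[jk[, 2]])
    jk <- jk[zb <= min(zb) + 1e-12, , drop = FALSE]
  }
  w <- exp(-mu * (m$yc[jk[, 1]] - g$y0)) * m$dy[jk[, 1]] * m$dz[jk[, 2]]
  den <- if (normalize) sum(w) else sum(m$dz[unique(jk[, 2])])
  po2 <- vapply(xi, function(i) {
    sum(pf[cbind(i, jk)] * w)
  }, numeric(1)) / den
  data.frame(x = m$xc[xi], po2 = po2)
}

#' Weighted oxygen drop of a solved field
#'
#' The detector-visible oxygen drop: at every streamwise station the PO2
#' deficit \eqn{P_0 - PO_2} is integrated over the RBC-channel cross-section
#' with the depth weight \eqn{e^{-\mu (y - y_0)}} (the detector sits below
#' the channel), averaged across the width, and the weighted drop is the
#' maximum along the flow.
#'
#' Two conventions are provided. With `normalize = TRUE` (default) the depth
#' weight is normalized so a uniform deficit maps to itself and the result
#' is in mmHg: the right convention for profiles and for comparisons at
#' fixed channel height. With `normalize = FALSE` the depth integral is left
#' unnormalized (divided by the channel width only, units mmHg mm), so a
#' deeper channel contributes more signal volume: the convention in which
#' channel geometries of different height are compared as detector signals.
#' With `mu = 0` the normalized form reduces to the plain cross-sectional
#' average deficit.
#'
#' @param f A `po2_field` from [solve_transport()].
#' @param mu Optical attenuation of the RBC suspension (1/mm); defaults to
#'   the configured `mu_attenuation`. Must be supplied one way or the other.
#' @param normalize Normalize the depth weighting (see Details).
#' @return The weighted drop (mmHg, or mmHg mm when `normalize = FALSE`).
#' @export
weighted_drop <- function(f, mu = NULL, normalize = TRUE) {
  stopifnot(inherits(f, "po2_field"))
  prof <- weighted_profile_internal(f, mu, centreline = FALSE,
                                    normalize = normalize)
  if (normalize) return(max(f$cfg$physics$P0 - prof$po2))
  # prof$po2 already holds the width-averaged depth integral of PO2;
  # subtract it from the same integral of the uniform baseline
  g <- f$mesh$geometry
  m <- f$mesh
  rbc <- m$tag == TAG_RBC
  xi1 <- which(apply(rbc, 1, any))[1]
  jk <- which(rbc[xi1, , ], arr.ind = TRUE)
  if (is.null(mu)) mu <- f$cfg$physics$mu_attenuation
  w <- exp(-mu * (m$yc[jk[, 1]] - g$y0)) * m$dy[jk[, 1]] * m$dz[jk[, 2]]
  base <- f$cfg$physics$P0 * sum(w) / sum(m$dz[unique(jk[, 2])])
  max(base - prof$po2)
}

#' Weighted centreline profile
#'
#' Same depth weighting as [weighted_drop()], but evaluated on the channel
#' centreline (the cell column(s) nearest z = 0) instead of averaging over
#' the width: the streamwise profile used for the drop-kinetics criterion
#' and the saturation curves.
#'
#' @inheritParams weighted_drop
#' @return An object of class `weighted_profile`: data.frame with columns
#'   `x` (mm) and `po2` (mmHg), with the device parameters attached.
#' @export
weighted_centreline <- function(f, mu = NULL) {
  stopifnot(inherits(f, "po2_field"))
  prof <- weighted_profile_internal(f, mu, centreline = TRUE)
  structure(prof, class = c("weighted_profile", "data.frame"),
            P0 = f$cfg$physics$P0, Pl = f$cfg$physics$Pl,
            window_length = f$mesh$geometry$window_length,
            phys = f$cfg$physics)
}

#' Drop kinetics of a weighted profile
#'
#' Applies the same deviation criterion as the 1D drop distance to a
#' discrete streamwise profile: the drop distance runs from where the drop
#' first exceeds `frac` of its maximum to where it first reaches within
#' `frac` of the maximum, with linear interpolation between stations. The
#' drop time is the distance divided by the mean velocity, and the rate is
#' the maximum drop divided by the drop time.
#'
#' @param p A [weighted_centreline()] profile (or any data.frame with `x`
#'   and `po2`).
#' @param c Mean RBC channel velocity (mm/s).
#' @param P0 Baseline PO2 (mmHg); defaults to the attached value.
#' @param frac Deviation fraction; default 0.01.
#' @return List with `drop_max` (mmHg), `drop_distance` (mm), `drop_time`
#'   (s), `drop_rate` (mmHg/s) and `truncated` (TRUE when the profile never
#'   rises above the onset level before its minimum, so the distance is
#'   measured from the profile start).
#' @export
drop_kinetics_3d <- function(p, c, P0 = attr(p, "P0"), frac = 0.01) {
  stopifnot(is.data.frame(p), all(c("x", "po2") %in% names(p)), c > 0)
  if (is.null(P0)) stop("P0 must be given")
  drop <- P0 - p$po2
  imax <- which.max(drop)
  dmax <- drop[imax]
  if (dmax <= 0) stop("profile has no oxygen drop")
  lev1 <- frac * dmax
  lev2 <- (1 - frac) * dmax
  cross_before <- function(lev) {
    below <- which(drop[seq_len(imax)] < lev)
    if (!length(below)) return(structure(p$x[1], truncated = TRUE))
    i0 <- max(below)
    if (i0 == imax) return(structure(p$x[imax], truncated = FALSE))
    x0 <- p$x[i0]; x1 <- p$x[i0 + 1]
    d0 <- drop[i0]; d1 <- drop[i0 + 1]
    structure(x0 + (lev - d0) / (d1 - d0) * (x1 - x0), truncated = FALSE)
  }
  x1 <- cross_before(lev1)
  x2 <- cross_before(lev2)
  dx <- as.numeric(x2) - as.numeric(x1)
  dt <- dx / c
  list(drop_max = dmax, drop_distance = dx, drop_time = dt,
       drop_rate = if (dt > 0) dmax / dt else Inf,
       truncated = isTRUE(attr(x1, "truncated")))
}

#' Attach the hemoglobin saturation to a weighted profile
#'
#' Transforms the weighted PO2 profile through the Hill equation,
#' SO2(x) = SO2(weighted PO2(x)). This is a profile transform: the weighted
#' mean of the saturation field is not in general the saturation of the
#' weighted mean.
#'
#' @param p A [weighted_centreline()] profile.
#' @param phys A [physical_parameters()]; defaults to the attached physics.
#' @return The profile with an added `so2` column (fraction).
#' @export
so2_profile <- function(p, phys = attr(p, "phys")) {
  stopifnot(is.data.frame(p), "po2" %in% names(p))
  if (is.null(phys)) phys <- physical_parameters()
  p$so2 <- hill_saturation(p$po2, phys$P50, phys$N_hill)
  p
}
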