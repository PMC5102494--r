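# Closed-form 1D advection-diffusion-permeation model of the exchange
# window, its finite-difference oracle, and the design criteria built on it.
#
# In dimensionless form (xi = x/Lw + 1/2, u = 1 - v, v = (PO2-Pl)/(P0-Pl))
# the drop u satisfies
#   u'' - Pe u' - S1 u = 0            on (-inf, 0) and (1, inf)
#   u'' - Pe u' - S1 u = S2 (u - 1)   on [0, 1]   (the window)
# with u -> 0 far upstream/downstream. The window forcing is written
# S2 (u - 1): substituting u = 1 - v into the dimensional balance yields this
# sign, and it is the form whose interior equilibrium u_p = S2/(S1+S2)
# reproduces the published behaviour of the solution.

#' Parameters of the 1D window-exchange model
#'
#' @param D Oxygen diffusivity in the channel fluid (mm^2/s).
#' @param c Mean flow velocity (mm/s), non-negative.
#' @param k1 Wall permeation rate toward ambient oxygen (1/s), >= 0.
#' @param k2 Window permeation rate toward the gas channel (1/s), > 0.
#' @param Lw Exchange window length (mm).
#' @param P0 Ambient oxygen partial pressure (mmHg).
#' @param Pl Gas-channel oxygen partial pressure (mmHg), < P0.
#' @return An object of class `model1d_parameters`.
#' @export
model1d_parameters <- function(D, c, k1, k2, Lw, P0 = 160, Pl = 0) {
  stopifnot(D > 0, c >= 0, k1 >= 0, k2 > 0, Lw > 0, Pl < P0)
  p <- list(D = D, c = c, k1 = k1, k2 = k2, Lw = Lw, P0 = P0, Pl = Pl)
  class(p) <- "model1d_parameters"
  p
}

#' Dimensionless groups of the 1D model
#'
#' Computes the Peclet number and the two dimensionless permeation rates,
#' \deqn{Pe = c L_w / D,\quad S_1 = k_1 L_w^2 / D,\quad S_2 = k_2 L_w^2 / D.}
#'
#' @param p A [model1d_parameters()] object.
#' @return An object of class `dimensionless1d` with fields `Pe`, `S1`, `S2`.
#' @export
nondimensionalize <- function(p) {
  stopifnot(inherits(p, "model1d_parameters"))
  dimensionless1d(Pe = p$c * p$Lw / p$D,
                  S1 = p$k1 * p$Lw^2 / p$D,
                  S2 = p$k2 * p$Lw^2 / p$D)
}

#' @rdname nondimensionalize
#' @param Pe,S1,S2 Dimensionless groups given directly.
#' @export
dimensionless1d <- function(Pe, S1, S2) {
  stopifnot(Pe >= 0, S1 >= 0, S2 > 0)
  d <- list(Pe = Pe, S1 = S1, S2 = S2)
  class(d) <- "dimensionless1d"
  d
}

#' Closed-form solution of the dimensionless 1D model
#'
#' Solves the piecewise-linear ODE exactly: decaying exponentials
#' \eqn{A e^{\lambda^+ \xi}} upstream and \eqn{B e^{\lambda^- (\xi-1)}}
#' downstream with \eqn{\lambda^\pm = (Pe \pm \sqrt{Pe^2+4S_1})/2}, and
#' \eqn{u_p + C_1 e^{\mu^+ \xi} + C_2 e^{\mu^- \xi}} inside the window with
#' \eqn{\mu^\pm = (Pe \pm \sqrt{Pe^2+4(S_1+S_2)})/2} and equilibrium drop
#' \eqn{u_p = S_2/(S_1+S_2)}. The four coefficients follow from continuity of
#' u and u' at \eqn{\xi = 0} and \eqn{\xi = 1} (a 4x4 linear system).
#'
#' When S1 = 0 and Pe > 0 the downstream branch is the bounded constant
#' solution (the drop is never recharged downstream).
#'
#' @param d A [dimensionless1d()] object.
#' @return An object of class `piecewise1d`: exponents, coefficients,
#'   equilibrium value `u_p`, and evaluators `u(xi)` and `v(xi) = 1 - u(xi)`.
#' @export
solve_closed_form <- function(d) {
  stopifnot(inherits(d, "dimensionless1d"))
  Pe <- d$Pe; S1 <- d$S1; S2 <- d$S2
  r1 <- sqrt(Pe^2 + 4 * S1)
  lam_p <- (Pe + r1) / 2
  lam_m <- (Pe - r1) / 2
  r2 <- sqrt(Pe^2 + 4 * (S1 + S2))
  mu_p <- (Pe + r2) / 2
  mu_m <- (Pe - r2) / 2
  u_p <- S2 / (S1 + S2)
  if (lam_p <= 0)
    stop("degenerate upstream decay (Pe = 0 and S1 = 0): no bounded solution")
  # unknowns (A, C1, C2, B) with the window written as
  #   u = u_p + C1 e^{mu+ (xi-1)} + C2 e^{mu- xi},
  # anchoring each exponential at the end where it is largest, so every
  # matrix entry is bounded even for very large S2.
  e_p <- exp(-mu_p)            # e^{mu+ (0-1)}
  e_m <- exp(mu_m)             # e^{mu- * 1}
  M <- rbind(c(1,     -e_p,         -1,           0),
             c(lam_p, -mu_p * e_p,  -mu_m,        0),
             c(0,      1,            e_m,        -1),
             c(0,      mu_p,         mu_m * e_m, -lam_m))
  rhs <- c(u_p, 0, -u_p, 0)
  co <- tryCatch(solve(M, rhs),
                 error = function(e) stop("singular matching system: ",
                                          conditionMessage(e)))
  A <- co[1]; C1 <- co[2]; C2 <- co[3]; B <- co[4]
  sol <- list(Pe = Pe, S1 = S1, S2 = S2,
              lambda_plus = lam_p, lambda_minus = lam_m,
              mu_plus = mu_p, mu_minus = mu_m,
              A = A, B = B, C1 = C1, C2 = C2, u_p = u_p)
  sol$u <- function(xi) {
    out <- numeric(length(xi))
    lo <- xi < 0
    hi <- xi > 1
    mid <- !lo & !hi
    out[lo] <- A * exp(lam_p * xi[lo])
    out[mid] <- u_p + C1 * exp(mu_p * (xi[mid] - 1)) +
      C2 * exp(mu_m * xi[mid])
    out[hi] <- B * exp(lam_m * (xi[hi] - 1))
    out
  }
  sol$v <- function(xi) 1 - sol$u(xi)
  class(sol) <- "piecewise1d"
  sol
}

#' @export
print.piecewise1d <- function(x, ...) {
  cat(sprintf("piecewise1d: Pe = %g, S1 = %g, S2 = %g\n", x$Pe, x$S1, x$S2))
  cat(sprintf("  u_p = %.6g, u_max = %.6g at xi = %.4g\n",
              x$u_p, u_max(x), attr(u_max(x), "xi")))
  invisible(x)
}

# Location and value of the global maximum of u. The outer pieces are
# monotone, so the only interior candidate is the stationary point of the
# window piece; endpoints xi = 0, 1 complete the candidate set.
u_argmax <- function(sol) {
  cand <- c(0, 1)
  C1 <- sol$C1; C2 <- sol$C2; mp <- sol$mu_plus; mm <- sol$mu_minus
  # stationary point of u_p + C1 e^{mu+ (xi-1)} + C2 e^{mu- xi}
  ratio <- -(C2 * mm) / (C1 * mp)
  if (is.finite(ratio) && ratio > 0 && C1 != 0) {
    xs <- (log(ratio) + mp) / (mp - mm)
    if (xs > 0 && xs < 1) cand <- c(cand, xs)
  }
  vals <- sol$u(cand)
  cand[which.max(vals)]
}

#' Maximum dimensionless drop
#'
#' Global maximum of u over the line, located from the closed-form
#' stationary point of the window piece and the interval endpoints (the
#' outer pieces are monotone exponentials).
#'
#' @param sol A [solve_closed_form()] solution.
#' @return The maximum of u, with the maximizing `xi` attached as an
#'   attribute.
#' @export
u_max <- function(sol) {
  stopifnot(inherits(sol, "piecewise1d"))
  xs <- u_argmax(sol)
  structure(sol$u(xs), xi = xs)
}

#' Dimensionless drop distance
#'
#' Width of the oxygen-drop transition: the distance in xi between the onset
#' of the drop, where u first rises through `frac` of its maximum, and its
#' completion, where u first reaches within `frac` of the maximum. Both
#' crossings are located by root finding on the exact closed-form pieces
#' (absolute xi tolerance 1e-10).
#'
#' `method = "endpoint-relative"` is the documented alternative reading of
#' the 1% criterion: the onset level is `frac` of the full scale (P0) and the
#' completion level is within `frac` of the minimum PO2 relative to that
#' minimum, i.e. u between `frac` and `u_max - frac (1 - u_max)`.
#'
#' @param sol A [solve_closed_form()] solution.
#' @param frac Deviation fraction defining the two crossings; default 0.01
#'   (the 1% criterion). Must lie in (0, 0.5).
#' @param method Level convention, `"drop-relative"` (default) or
#'   `"endpoint-relative"`; see Details.
#' @return The drop distance in units of window length.
#' @export
delta_xi <- function(sol, frac = 0.01,
                     method = c("drop-relative", "endpoint-relative")) {
  stopifnot(inherits(sol, "piecewise1d"))
  method <- match.arg(method)
  if (!(frac > 0 && frac < 0.5)) stop("frac must lie in (0, 0.5)")
  um <- as.numeric(u_max(sol))
  if (um <= 0) stop("u_max must be positive to define a drop distance")
  lev <- switch(method,
                "drop-relative" = c(frac * um, (1 - frac) * um),
                "endpoint-relative" = c(frac, um - frac * (1 - um)))
  xs <- attr(u_max(sol), "xi")
  c(rising_crossing(sol, lev[2], xs) - rising_crossing(sol, lev[1], xs))
}

# Last xi before the argmax where u crosses `level` from below.
rising_crossing <- function(sol, level, xs) {
  u <- sol$u
  if (u(xs) < level) stop("level above the maximum of u")
  # bracket: march upstream from the argmax until u < level
  lo <- xs - max(1, 2 / sol$lambda_plus)
  while (u(lo) >= level) lo <- lo - max(1, 2 / sol$lambda_plus)
  stats::uniroot(function(x) u(x) - level, c(lo, xs), tol = 1e-10)$root
}

#' Finite-difference oracle for the 1D model
#'
#' Independent second-order central-difference solution of the dimensionless
#' window model on a truncated domain `[-halfwidth, 1 + halfwidth]`, used to
#' verify the closed form. Truncation is closed either with homogeneous
#' Dirichlet ends (`bc = "zero"`) or with one-sided exponential-decay
#' conditions matching the far-field decay rates (`bc = "decay"`, useful when
#' a decay length approaches the truncation width).
#'
#' @param d A [dimensionless1d()] object.
#' @param halfwidth Distance from the window to each truncated end (window
#'   lengths).
#' @param n_nodes Number of grid nodes (>= 1001).
#' @param bc Truncation closure, `"zero"` or `"decay"`.
#' @return A data.frame with columns `xi` and `u`.
#' @export
fd_oracle_1d <- function(d, halfwidth = 20, n_nodes = 20001,
                         bc = c("zero", "decay")) {
  stopifnot(inherits(d, "dimensionless1d"), halfwidth > 1, n_nodes >= 1001)
  bc <- match.arg(bc)
  Pe <- d$Pe; S1 <- d$S1; S2 <- d$S2
  # snap the grid so the window edges xi = 0, 1 fall exactly on nodes
  # (otherwise the forcing region is misplaced by O(h))
  m_per <- max(10L, round((n_nodes - 1) / (2 * halfwidth + 1)))
  hw <- ceiling(halfwidth * m_per) / m_per
  h <- 1 / m_per
  xi <- seq(-hw, 1 + hw, by = h)
  n <- length(xi)
  # window indicator with half weights on the edge nodes (keeps the
  # scheme second order across the forcing discontinuity)
  inwin <- as.numeric(xi > -h / 2 & xi < 1 + h / 2)
  edge <- abs(xi) < h / 2 | abs(xi - 1) < h / 2
  inwin[edge] <- 0.5
  # interior rows: u'' - Pe u' - (S1 + S2 I_win) u = -S2 I_win
  diag_main <- -2 / h^2 - S1 - S2 * inwin
  diag_up <- rep(1 / h^2 - Pe / (2 * h), n)
  diag_dn <- rep(1 / h^2 + Pe / (2 * h), n)
  rhs <- -S2 * inwin
  # truncation rows
  lam_p <- (Pe + sqrt(Pe^2 + 4 * S1)) / 2
  lam_m <- (Pe - sqrt(Pe^2 + 4 * S1)) / 2
  if (bc == "zero") {
    first <- c(1, 0); last <- c(0, 1)     # u = 0 at both ends
  } else {
    first <- c(1, -exp(-lam_p * h))       # u_1 = u_2 e^{-lam+ h}
    last <- c(-exp(lam_m * h), 1)         # u_n = u_{n-1} e^{lam- h}
  }
  A <- Matrix::bandSparse(n, n, k = c(-1, 0, 1),
                          diagonals = list(diag_dn[-1], diag_main,
                                           diag_up[-n]))
  A[1, 1] <- first[1]; A[1, 2] <- first[2]; rhs[1] <- 0
  A[n, n - 1] <- last[1]; A[n, n] <- last[2]; rhs[n] <- 0
  u <- tryCatch(as.numeric(Matrix::solve(A, rhs)),
                error = function(e) stop("oracle linear solve failed: ",
                                         conditionMessage(e)))
  data.frame(xi = xi, u = u)
}

#' Performance criteria of the 1D design
#'
#' Re-dimensionalizes the closed-form solution into the three device
#' performance criteria: the maximum drop in PO2
#' \eqn{\Delta PO_{2,max} = (P_0 - P_l) u_{max}}, the drop rate
#' \eqn{c (P_0-P_l) u_{max} / (L_w \Delta\xi)}, and the temporal resolution
#' \eqn{\tau = \epsilon / c} set by the detector's spatial resolution.
#'
#' @param p A [model1d_parameters()] object with `c > 0`.
#' @param epsilon Detector spatial resolution (mm), > 0.
#' @param frac Deviation fraction for the drop distance (see [delta_xi()]).
#' @return An object of class `criteria1d`: `u_max`, `delta_xi`, `max_drop`
#'   (mmHg), `drop_rate` (mmHg/s) and `temporal_resolution` (s).
#' @export
criteria <- function(p, epsilon, frac = 0.01) {
  stopifnot(inherits(p, "model1d_parameters"), epsilon > 0)
  if (p$c == 0) stop("temporal resolution is undefined for c = 0")
  sol <- solve_closed_form(nondimensionalize(p))
  um <- as.numeric(u_max(sol))
  dx <- delta_xi(sol, frac = frac)
  out <- list(u_max = um, delta_xi = dx,
              max_drop = (p$P0 - p$Pl) * um,
              drop_rate = p$c * (p$P0 - p$Pl) * um / (p$Lw * dx),
              temporal_resolution = epsilon / p$c)
  class(out) <- "criteria1d"
  out
}

#' Design curves over the dimensionless parameter space
#'
#' Tabulates `u_max` and the dimensionless drop rate `u_max / delta_xi` over
#' a grid of Peclet numbers for each combination of wall and window
#' permeation numbers, in the layout used for the published design charts.
#'
#' @param pe_grid Numeric vector of Peclet numbers.
#' @param s1_set,s2_set Numeric vectors of S1 and S2 values.
#' @param frac Deviation fraction for the drop distance.
#' @return A data.frame with columns `Pe`, `S1`, `S2`, `u_max`, `delta_xi`,
#'   `drop_rate_dimless`.
#' @export
design_curves <- function(pe_grid, s1_set = c(1, 5, 10),
                          s2_set = c(5, 20, 80), frac = 0.01) {
  stopifnot(length(pe_grid) > 0, length(s1_set) > 0, length(s2_set) > 0)
  grid <- expand.grid(Pe = pe_grid, S1 = s1_set, S2 = s2_set,
                      KEEP.OUT.ATTRS = FALSE)
  res <- t(vapply(seq_len(nrow(grid)), function(i) {
    sol <- solve_closed_form(dimensionless1d(grid$Pe[i], grid$S1[i],
                                             grid$S2[i]))
    um <- as.numeric(u_max(sol))
    dx <- delta_xi(sol, frac = frac)
    c(um, dx, um / dx)
  }, numeric(3)))
  cbind(grid, data.frame(u_max = res[, 1], delta_xi = res[, 2],
                         drop_rate_dimless = res[, 3]))
}

#' Map PDMS membrane thicknesses to 1D permeation rates
#'
#' Series-resistance closure for the effective wall and window permeation
#' rates of the 1D model: a PDMS membrane of thickness t has conductance
#' `D_pdms k_pdms / t` per unit area, and dividing by the channel's oxygen
#' capacity per unit exchange area, `k_plasma Hr`, gives a first-order rate,
#' \deqn{k = D_{pdms} k_{pdms} / (k_p\, t\, H_r)\ \ (1/s).}
#'
#' @param phys A [physical_parameters()] object.
#' @param t_wall PDMS thickness between the channel and ambient air (mm).
#' @param t_spincoat Spin coat thickness between channel and window (mm).
#' @param Hr RBC channel height (mm).
#' @return List with rates `k1` (wall) and `k2` (window), 1/s.
#' @export
wall_conductances <- function(phys, t_wall, t_spincoat, Hr) {
  stopifnot(t_wall > 0, t_spincoat > 0, Hr > 0)
  perm <- phys$D_pdms * phys$k_pdms
  list(k1 = perm / (phys$k_plasma * t_wall * Hr),
       k2 = perm / (phys$k_plasma * t_spincoat * Hr))
}

#' 1D predictions of geometry effects
#'
#' Sweeps window length and spin-coat thickness through the 1D model with
#' the membrane-conductance mapping of [wall_conductances()], and
#' re-dimensionalizes the result into a predicted weighted oxygen drop
#' (mmHg). The predictions are qualitative: the 1D idealization (infinitely
#' wide, vanishingly shallow channel; infinitely fast gas flow) makes it an
#' upper envelope for the 3D drop at matched parameters.
#'
#' @param cfg A [simulation_config()] providing physics and base geometry
#'   (requires `mean_velocity_rbc`).
#' @param window_lengths Window lengths to sweep (mm), or `NULL` to skip.
#' @param spincoat_thicknesses Spin coat thicknesses to sweep (mm), or
#'   `NULL` to skip.
#' @return A data.frame with columns `sweep`, `value`, `drop_mmHg`,
#'   `drop_rate_mmHg_per_s`.
#' @export
predict_geometry_effects_1d <- function(cfg, window_lengths = NULL,
                                        spincoat_thicknesses = NULL) {
  stopifnot(inherits(cfg, "simulation_config"))
  phys <- cfg$physics
  g <- cfg$geometry
  if (is.na(phys$mean_velocity_rbc))
    stop("mean_velocity_rbc must be set in the configuration")
  one <- function(Lw, t_sc) {
    k <- wall_conductances(phys, t_wall = g$pdms_pad_y, t_spincoat = t_sc,
                           Hr = g$rbc_height)
    p <- model1d_parameters(D = phys$D_plasma, c = phys$mean_velocity_rbc,
                            k1 = k$k1, k2 = k$k2, Lw = Lw,
                            P0 = phys$P0, Pl = phys$Pl)
    sol <- solve_closed_form(nondimensionalize(p))
    um <- as.numeric(u_max(sol))
    dx <- delta_xi(sol)
    c(drop = (phys$P0 - phys$Pl) * um,
      rate = phys$mean_velocity_rbc * (phys$P0 - phys$Pl) * um / (Lw * dx))
  }
  rows <- list()
  for (Lw in window_lengths) {
    v <- one(Lw, g$spincoat_thickness)
    rows[[length(rows) + 1]] <- data.frame(sweep = "window_length",
                                           value = Lw, drop_mmHg = v["drop"],
                                           drop_rate_mmHg_per_s = v["rate"])
  }
  for (t_sc in spincoat_thicknesses) {
    v <- one(g$window_length, t_sc)
    rows[[length(rows) + 1]] <- data.frame(sweep = "spincoat",
                                           value = t_sc, drop_mmHg = v["drop"],
                                           drop_rate_mmHg_per_s = v["rate"])
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
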