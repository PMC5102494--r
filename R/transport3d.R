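# Steady conjugate oxygen transport over the composite device domain.
#
# Region-wise balance, with PO2 as the continuous unknown:
#   PDMS : 0                = div(D_pdms k_pdms grad PO2)
#   gas  : k_g  v.grad PO2  = div(D_g k_g grad PO2)
#   blood: beta(PO2) v.grad PO2 = div(D_p k_p grad PO2)
# where beta is the effective capacity including the hemoglobin reservoir
# (see effective_capacity). Solubility-weighted diffusion coefficients make
# the interfacial flux continuity automatic in the conservative
# finite-volume form. The discretization is a cell-centred finite-volume
# scheme on the structured hex mesh: harmonic-mean interface diffusion plus
# first-order upwinding of the advection in the convective regions (an
# M-matrix, so the discrete maximum principle holds by construction). The
# hemoglobin nonlinearity is resolved by relaxed Picard iteration with the
# capacity frozen at the previous iterate; each linearized system is solved
# by a sparse direct factorization, which is deterministic and robust to the
# strong coefficient contrasts between gas, PDMS and blood.

#' Solver options for the 3D transport solve
#'
#' @param picard_tol Relative Picard tolerance: iteration stops when the
#'   maximum nodal change drops below `picard_tol * P0` (mmHg). Default 1e-6.
#' @param max_picard Maximum Picard iterations. Default 50.
#' @param lin_tol Relative residual guard for the linearized solve; the
#'   sparse direct solve is checked a posteriori against it. Default 1e-8.
#' @param relaxation Picard under-relaxation factor in (0, 1]. Default 0.7.
#' @param upwind Apply upwind stabilization of the advection term in the
#'   convective regions (default `TRUE`); `FALSE` selects the unstabilized
#'   central scheme (useful only at low cell Peclet numbers).
#' @return An object of class `solver_options`.
#' @export
solver_options <- function(picard_tol = 1e-6, max_picard = 50,
                           lin_tol = 1e-8, relaxation = 0.7, upwind = TRUE) {
  stopifnot(picard_tol > 0, picard_tol < 1, max_picard >= 1,
            lin_tol > 0, lin_tol < 1, relaxation > 0, relaxation <= 1)
  o <- list(picard_tol = picard_tol, max_picard = as.integer(max_picard),
            lin_tol = lin_tol, relaxation = relaxation,
            upwind = isTRUE(upwind))
  class(o) <- "solver_options"
  o
}

cell_diffusivity <- function(m, phys) {
  dk <- c(NA_real_, phys$D_pdms * phys$k_pdms, phys$D_gas * phys$k_gas,
          phys$D_plasma * phys$k_plasma)
  array(dk[m$tag + 1L], dim(m$tag))
}

cell_capacity <- function(m, phys, po2) {
  cap <- array(0, dim(m$tag))
  gas <- m$tag == TAG_GAS
  if (any(gas)) cap[gas] <- phys$k_gas
  rbc <- m$tag == TAG_RBC
  if (any(rbc)) cap[rbc] <- effective_capacity(pmax(po2[rbc], 0), phys)
  cap
}

# advected oxygen content per unit volume (uM): free dissolved oxygen plus
# the hemoglobin-bound reservoir in the blood, k_gas * PO2 in the gas
oxygen_content <- function(po2, phys) {
  ((1 - phys$Ht) * phys$k_plasma + phys$Ht * phys$k_rbc) * po2 +
    phys$HbT * hill_saturation(pmax(po2, 0), phys$P50, phys$N_hill)
}

cell_content <- function(m, phys, po2) {
  cont <- array(0, dim(m$tag))
  gas <- m$tag == TAG_GAS
  if (any(gas)) cont[gas] <- phys$k_gas * po2[gas]
  rbc <- m$tag == TAG_RBC
  if (any(rbc)) cont[rbc] <- oxygen_content(po2[rbc], phys)
  cont
}

# Assemble the linearized FV system A p = b for the active cells, with the
# capacity frozen at `po2_prev` (full-grid array). Returns the sparse matrix,
# rhs, and the active-cell index map.
assemble_transport <- function(m, vel, phys, po2_prev, gas_mode,
                               upwind = TRUE) {
  dims <- dim(m$tag)
  act <- m$tag != TAG_VOID
  if (!any(act)) stop("mesh has no active cells")
  id <- array(NA_integer_, dims)
  id[act] <- seq_len(sum(act))
  n <- sum(act)
  dk <- cell_diffusivity(m, phys)
  cap <- cell_capacity(m, phys, po2_prev)
  # conservative content advection, linearized about the previous iterate:
  # the upwind advective flux is q * [cont_up + cap_up (P_up - P_up^k)],
  # so r = cont - cap * P^k is the known affine part per cell
  radv <- cell_content(m, phys, po2_prev) - cap * po2_prev
  g <- m$geometry

  ti <- ti_j <- ti_x <- list()
  rhs <- numeric(n)
  push <- function(i, j, x) {
    k <- length(ti) + 1L
    ti[[k]] <<- i; ti_j[[k]] <<- j; ti_x[[k]] <<- x
  }

  half <- list(x = m$dx / 2, y = m$dy / 2, z = m$dz / 2)
  centers <- list(x = m$xc, y = m$yc, z = m$zc)
  nxyz <- c(m$nx, m$ny, m$nz)

  # --- interior faces, one axis at a time ------------------------------
  for (ax in 1:3) {
    nax <- nxyz[ax]
    if (nax < 2) next
    # index arrays of "left" cells (1..nax-1 along ax)
    take <- function(a, rng, axis) {
      ix <- list(seq_len(dims[1]), seq_len(dims[2]), seq_len(dims[3]))
      ix[[axis]] <- rng
      a[ix[[1]], ix[[2]], ix[[3]], drop = FALSE]
    }
    rngL <- seq_len(nax - 1L); rngR <- rngL + 1L
    c1 <- take(id, rngL, ax); c2 <- take(id, rngR, ax)
    dk1 <- take(dk, rngL, ax); dk2 <- take(dk, rngR, ax)
    cap1 <- take(cap, rngL, ax); cap2 <- take(cap, rngR, ax)
    tag1 <- take(m$tag, rngL, ax); tag2 <- take(m$tag, rngR, ax)
    both <- !is.na(c1) & !is.na(c2)

    # face open? only the y = 0 plane has a glass lid outside the window
    open <- both
    if (ax == 2 && gas_mode == "full-gas") {
      j0 <- which(abs(m$ys - 0) < 1e-12) - 1L    # cell layer below y=0
      if (length(j0) == 1 && j0 >= 1 && j0 <= m$ny - 1) {
        fdim <- dim(c1)
        X <- array(m$xc, fdim)
        Z <- array(rep(m$zc, each = fdim[1] * fdim[2]), fdim)
        blocked <- !(abs(X) <= g$window_length / 2 + 1e-12 &
                       abs(Z) <= g$window_width / 2 + 1e-12)
        sel <- array(FALSE, fdim); sel[, j0, ] <- TRUE
        open <- open & !(sel & blocked)
      }
    }

    # geometric factors
    hL <- half[[ax]][rngL]; hR <- half[[ax]][rngR]
    oth <- setdiff(1:3, ax)
    area_ax <- switch(ax,
                      outer(rep(1, nax - 1),
                            outer(m$dy, m$dz)),
                      aperm(outer(rep(1, nax - 1),
                                  outer(m$dx, m$dz)), c(2, 1, 3)),
                      aperm(outer(rep(1, nax - 1),
                                  outer(m$dx, m$dy)), c(2, 3, 1)))
    hfac <- switch(ax,
                   array(hL, dim(c1)),
                   aperm(array(hL, dim(c1)[c(2, 1, 3)]), c(2, 1, 3)),
                   aperm(array(hL, dim(c1)[c(3, 1, 2)]), c(2, 3, 1)))
    hfac2 <- switch(ax,
                    array(hR, dim(c1)),
                    aperm(array(hR, dim(c1)[c(2, 1, 3)]), c(2, 1, 3)),
                    aperm(array(hR, dim(c1)[c(3, 1, 2)]), c(2, 3, 1)))

    w <- which(open)
    if (!length(w)) next
    G <- area_ax[w] / (hfac[w] / dk1[w] + hfac2[w] / dk2[w])
    i1 <- c1[w]; i2 <- c2[w]
    push(i1, i1, G);  push(i1, i2, -G)
    push(i2, i2, G);  push(i2, i1, -G)

    # advection on axial faces of the channels: conservative upwind flux
    # of the linearized content, q * [cont_up + cap_up (P_up - P_up^k)]
    vface <- NULL
    if (ax == 1 && !is.null(vel)) {
      vv <- vel$vx
      v1 <- take(vv, rngL, ax); v2 <- take(vv, rngR, ax)
      vface <- ifelse(tag1 == TAG_RBC & tag2 == TAG_RBC, (v1 + v2) / 2, 0)
    } else if (ax == 3 && !is.null(vel)) {
      vv <- vel$vz
      v1 <- take(vv, rngL, ax); v2 <- take(vv, rngR, ax)
      vface <- ifelse(tag1 == TAG_GAS & tag2 == TAG_GAS, (v1 + v2) / 2, 0)
    }
    if (!is.null(vface)) {
      q <- vface[w] * area_ax[w]
      adv <- which(q != 0)
      if (length(adv)) {
        qa <- q[adv]; a1 <- i1[adv]; a2 <- i2[adv]
        capL <- cap1[w][adv]; capR <- cap2[w][adv]
        rL <- take(radv, rngL, ax)[w][adv]
        rR <- take(radv, rngR, ax)[w][adv]
        if (upwind) {
          up_is_1 <- qa > 0
          au <- ifelse(up_is_1, a1, a2)
          bu <- ifelse(up_is_1, capL, capR)
          ru <- ifelse(up_is_1, rL, rR)
          # row c1 sees +q * flux_up, row c2 sees -q * flux_up
          push(a1, au, qa * bu)
          rhs[a1] <- rhs[a1] - qa * ru
          push(a2, au, -qa * bu)
          rhs[a2] <- rhs[a2] + qa * ru
        } else {
          # central: face content is the average of the two linearizations
          push(a1, a1, qa * capL / 2);  push(a1, a2, qa * capR / 2)
          push(a2, a1, -qa * capL / 2); push(a2, a2, -qa * capR / 2)
          rhs[a1] <- rhs[a1] - qa * (rL + rR) / 2
          rhs[a2] <- rhs[a2] + qa * (rL + rR) / 2
        }
      }
    }
  }

  # --- boundary faces ---------------------------------------------------
  shift_missing <- function(axis, side) {
    # active cells whose neighbour on `side` of `axis` is absent or void
    ix <- which(act, arr.ind = TRUE)
    nb <- ix
    nb[, axis] <- nb[, axis] + side
    out_of_range <- nb[, axis] < 1 | nb[, axis] > dims[axis]
    nb_void <- rep(FALSE, nrow(ix))
    inr <- !out_of_range
    if (any(inr))
      nb_void[inr] <- m$tag[nb[inr, , drop = FALSE]] == TAG_VOID
    ix[out_of_range | nb_void, , drop = FALSE]
  }
  P0 <- phys$P0; Pl <- phys$Pl
  for (axis in 1:3) for (side in c(-1L, 1L)) {
    bc <- shift_missing(axis, side)
    if (!nrow(bc)) next
    i <- bc[, 1]; j <- bc[, 2]; k <- bc[, 3]
    lin <- id[bc]
    tagb <- m$tag[bc]
    area <- switch(axis, m$dy[j] * m$dz[k], m$dx[i] * m$dz[k],
                   m$dx[i] * m$dy[j])
    dist <- switch(axis, half$x[i], half$y[j], half$z[k])
    dkb <- dk[bc]
    capb <- cap[bc]

    # classify
    kind <- rep("wall", length(lin))
    if (axis == 1) {
      kind[tagb == TAG_RBC] <- if (side == -1L) "rbc_inlet" else "rbc_outlet"
      kind[tagb == TAG_PDMS] <- "ambient"
    } else if (axis == 3) {
      kind[tagb == TAG_GAS] <- if (side == -1L) "gas_inlet" else "gas_outlet"
      kind[tagb == TAG_PDMS] <- "ambient"
    } else {
      if (side == 1L) {
        kind[tagb == TAG_PDMS] <- "ambient"
      } else {
        # bottom faces: glass everywhere on y = 0 except the window
        on0 <- abs(m$ys[j] - 0) < 1e-12
        kind[tagb == TAG_PDMS & !on0] <- "ambient"   # pad bottom elsewhere
        if (gas_mode == "ideal-window") {
          inwin <- abs(m$xc[i]) <= g$window_length / 2 + 1e-12 &
            abs(m$zc[k]) <= g$window_width / 2 + 1e-12
          kind[tagb == TAG_PDMS & on0 & inwin] <- "window"
        }
      }
    }

    dir_val <- c(ambient = P0, window = Pl, rbc_inlet = P0, gas_inlet = Pl)
    for (kn in intersect(names(dir_val), unique(kind))) {
      s <- kind == kn
      G <- area[s] * dkb[s] / dist[s]
      push(lin[s], lin[s], G)
      rhs[lin[s]] <- rhs[lin[s]] + G * dir_val[[kn]]
    }
    # advective content flux across inlet (known boundary content) and
    # outlet (upwinded from the cell) faces
    if (!is.null(vel)) {
      if (axis == 1) {
        s <- kind == (if (side == -1L) "rbc_inlet" else "rbc_outlet")
        if (any(s)) {
          qf <- vel$vx[bc[s, , drop = FALSE]] * area[s]
          if (side == -1L) {
            rhs[lin[s]] <- rhs[lin[s]] + qf * oxygen_content(P0, phys)
          } else {
            push(lin[s], lin[s], qf * capb[s])
            rhs[lin[s]] <- rhs[lin[s]] - qf * radv[bc[s, , drop = FALSE]]
          }
        }
      }
      if (axis == 3) {
        s <- kind == (if (side == -1L) "gas_inlet" else "gas_outlet")
        if (any(s)) {
          qf <- vel$vz[bc[s, , drop = FALSE]] * area[s]
          if (side == -1L) {
            rhs[lin[s]] <- rhs[lin[s]] + qf * phys$k_gas * Pl
          } else {
            push(lin[s], lin[s], qf * capb[s])
            rhs[lin[s]] <- rhs[lin[s]] - qf * radv[bc[s, , drop = FALSE]]
          }
        }
      }
    }
  }

  ii <- unlist(ti); jj <- unlist(ti_j); xx <- unlist(ti_x)
  A <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n))
  # matrix diagonal straight from the triplets (cheaper than extracting
  # it from the assembled sparse matrix)
  w <- ii == jj
  dv <- numeric(n)
  dtab <- rowsum(xx[w], ii[w])
  dv[as.integer(rownames(dtab))] <- dtab[, 1]
  list(A = A, b = rhs, id = id, act = act, diagonal = dv)
}

# Preconditioned BiCGSTAB for the nonsymmetric linearized systems. The
# preconditioner is a Cholesky factorization of the symmetric positive
# definite diffusion part of the operator (computed once per solve and
# reused across Picard iterations); warm starts come from the previous
# iterate. Falls back to a sparse direct solve if the Krylov iteration
# stalls (e.g. advection-dominated full-gas runs on coarse meshes).
solve_krylov <- function(A, b, precond, x0, tol, maxit = 250) {
  x <- x0
  r <- b - as.numeric(A %*% x)
  nb <- sqrt(sum(b^2))
  if (nb == 0) nb <- 1
  best <- list(x = x, res = sqrt(sum(r^2)) / nb)
  if (best$res < tol) return(list(x = x, iterations = 0L, relres = best$res))
  rhat <- r; rho <- 1; alpha <- 1; omega <- 1
  v <- p <- numeric(length(b))
  for (it in seq_len(maxit)) {
    rho1 <- sum(rhat * r)
    if (!is.finite(rho1) || rho1 == 0 || omega == 0) break
    beta <- (rho1 / rho) * (alpha / omega)
    p <- r + beta * (p - omega * v)
    phat <- as.numeric(Matrix::solve(precond, p))
    v <- as.numeric(A %*% phat)
    alpha <- rho1 / sum(rhat * v)
    s <- r - alpha * v
    rs <- sqrt(sum(s^2)) / nb
    if (rs < tol) {
      return(list(x = x + alpha * phat, iterations = it, relres = rs))
    }
    shat <- as.numeric(Matrix::solve(precond, s))
    tv <- as.numeric(A %*% shat)
    omega <- sum(tv * s) / sum(tv * tv)
    x <- x + alpha * phat + omega * shat
    r <- s - omega * tv
    rr <- sqrt(sum(r^2)) / nb
    if (is.finite(rr) && rr < best$res) best <- list(x = x, res = rr)
    if (rr < tol) return(list(x = x, iterations = it, relres = rr))
    rho <- rho1
  }
  list(x = best$x, iterations = maxit, relres = best$res, failed = TRUE)
}

#' Solve the steady 3D oxygen transport problem
#'
#' Builds (or reuses) the mesh and velocity field, then runs the relaxed
#' Picard loop: the hemoglobin capacity is frozen at the previous iterate,
#' the linearized finite-volume system is solved by preconditioned BiCGSTAB
#' (Cholesky of the diffusion operator as preconditioner, direct sparse
#' fallback), and the update is under-relaxed until the maximum change
#' falls below the Picard tolerance. With zero hematocrit the problem is
#' linear and a single solve is returned. The initial iterate is PO2 = P0
#' everywhere; the solver is fully deterministic.
#'
#' @param cfg A [simulation_config()].
#' @param m Optional pre-built [build_mesh()] mesh (built from `cfg` if
#'   `NULL`).
#' @param vel Optional pre-built [assign_velocity()] field.
#' @param opts Optional [solver_options()] overriding `cfg$solver`.
#' @return An object of class `po2_field`: cell values `values` (mmHg, per
#'   active cell), the mesh, the configuration, and a `convergence` report
#'   (iterations, change history, linear-solve residuals, cell count).
#' @export
solve_transport <- function(cfg, m = NULL, vel = NULL, opts = NULL) {
  stopifnot(inherits(cfg, "simulation_config"))
  phys <- cfg$physics
  if (is.null(m)) m <- build_mesh(cfg$geometry, cfg$resolution, cfg$gas_mode)
  if (is.null(vel)) vel <- assign_velocity(m, cfg$geometry, phys)
  if (is.null(opts)) opts <- cfg$solver
  act <- m$tag != TAG_VOID
  n <- sum(act)
  P0 <- phys$P0
  pfull <- array(P0, dim(m$tag))
  linear <- phys$HbT == 0    # the Hill reservoir is the only nonlinearity
  tol <- opts$picard_tol * P0
  history <- numeric(0)
  resid <- numeric(0)
  krylov_its <- integer(0)
  iterations <- 0L
  p <- rep(P0, n)
  # SPD part of the operator for preconditioning: the diffusion operator
  # with the same boundary conditions (assembled once, without velocity),
  # augmented below with the current advective diagonal
  sys0 <- assemble_transport(m, NULL, phys, pfull, cfg$gas_mode,
                             upwind = opts$upwind)
  diff_sym <- Matrix::forceSymmetric(sys0$A)
  diag0 <- sys0$diagonal
  precond <- NULL
  refresh <- TRUE
  for (it in seq_len(if (linear) 1L else opts$max_picard)) {
    iterations <- it
    sys <- assemble_transport(m, vel, phys, pfull, cfg$gas_mode,
                              upwind = opts$upwind)
    if (refresh) {
      dsum <- diff_sym + Matrix::Diagonal(x = sys$diagonal - diag0)
      precond <- tryCatch(
        if (is.null(precond)) {
          Matrix::Cholesky(dsum, LDL = FALSE, perm = TRUE)
        } else {
          # numeric re-factorization on the cached symbolic analysis
          Matrix::update(precond, dsum)
        },
        error = function(e) stop("preconditioner factorization failed: ",
                                 conditionMessage(e)))
    }
    # inexact Picard: early linearized solves only need to out-resolve the
    # current nonlinear error; the tolerance tightens as the iteration
    # converges and bottoms out at lin_tol
    tol_it <- if (linear || it == 1) opts$lin_tol else
      max(opts$lin_tol, min(1e-5, 1e-3 * history[length(history)] / P0))
    ks <- solve_krylov(sys$A, sys$b, precond, p, tol = tol_it)
    if (isTRUE(ks$failed) && !(ks$relres < 1e-3 && !linear)) {
      # robust fallback for strongly advection-dominated systems
      ks <- tryCatch(
        list(x = as.numeric(Matrix::solve(sys$A, sys$b)), iterations = NA),
        error = function(e) stop("linear solver breakdown: ",
                                 conditionMessage(e),
                                 " (consider coarser mesh or more relaxation)"))
    }
    pnew <- ks$x
    krylov_its <- c(krylov_its, ks$iterations)
    # refresh the preconditioner only when the Krylov solver is straining
    refresh <- is.na(ks$iterations) || ks$iterations > 40 ||
      isTRUE(ks$failed)
    r <- sqrt(sum((sys$b - as.numeric(sys$A %*% pnew))^2)) /
      max(sqrt(sum(sys$b^2)), .Machine$double.eps)
    resid <- c(resid, r)
    if (linear) {
      p <- pnew
      history <- max(abs(pnew - rep(P0, n)))
      pfull[act] <- p
      break
    }
    pupd <- p + opts$relaxation * (pnew - p)
    change <- max(abs(pupd - p))
    history <- c(history, change)
    p <- pupd
    pfull[act] <- p
    if (change < tol) break
  }
  if (!linear && history[length(history)] >= tol &&
      iterations == opts$max_picard) {
    cond <- structure(
      class = c("oxywindow_nonconvergence", "error", "condition"),
      list(message = sprintf(
        "Picard iteration did not converge in %d iterations (last change %.3g mmHg)",
        opts$max_picard, history[length(history)]),
        call = sys.call(), history = history))
    stop(cond)
  }
  out <- list(values = p, mesh = m, velocity = vel, cfg = cfg,
              convergence = list(iterations = iterations,
                                 change_history = history,
                                 linear = linear,
                                 lin_residuals = resid,
                                 krylov_iterations = krylov_its,
                                 n_cells = n,
                                 gas_mode = cfg$gas_mode))
  class(out) <- "po2_field"
  out
}

#' @export
print.po2_field <- function(x, ...) {
  cat(sprintf("po2_field: %d cells, PO2 in [%.4g, %.4g] mmHg\n",
              length(x$values), min(x$values), max(x$values)))
  cat(sprintf("  %s, %d Picard iteration(s)%s\n", x$convergence$gas_mode,
              x$convergence$iterations,
              if (x$convergence$linear) " (linear)" else ""))
  invisible(x)
}

#' Full-grid PO2 array
#' @param f A `po2_field`.
#' @return 3D array over the mesh grid, `NA` in void cells.
#' @export
po2_array <- function(f) {
  stopifnot(inherits(f, "po2_field"))
  a <- array(NA_real_, dim(f$mesh$tag))
  a[f$mesh$tag != TAG_VOID] <- f$values
  a
}

#' Boundary flux audit of a solved field
#'
#' Integrates the oxygen fluxes over every boundary class: diffusive
#' (solubility-weighted) fluxes through the window and the ambient PDMS
#' surfaces, and advective content fluxes through the channel inlets and
#' outlets (free dissolved oxygen plus, in the blood, the hemoglobin-bound
#' reservoir). The relative imbalance is reported against the window influx
#' magnitude; on a converged solution it reflects only the first-order
#' upwind discretization of the nonlinear content advection (and round-off
#' when the capacity is constant).
#'
#' @param f A `po2_field`.
#' @return List of named fluxes (uM mm^3/s), the total `imbalance`, the
#'   `window_influx`, and `rel_imbalance`.
#' @export
flux_report <- function(f) {
  stopifnot(inherits(f, "po2_field"))
  m <- f$mesh; phys <- f$cfg$physics; g <- m$geometry
  gas_mode <- f$cfg$gas_mode
  pf <- po2_array(f)
  dk <- cell_diffusivity(m, phys)
  content_blood <- function(p) oxygen_content(p, phys)
  fluxes <- c(window_in = 0, ambient_in = 0, rbc_adv_in = 0,
              rbc_adv_out = 0, gas_adv_in = 0, gas_adv_out = 0,
              gas_diff_window = 0)
  dims <- dim(m$tag)
  act <- m$tag != TAG_VOID

  # boundary Dirichlet faces (reuse classification logic via assembly run
  # would be circular; recompute directly)
  for (axis in 1:3) for (side in c(-1L, 1L)) {
    ix <- which(act, arr.ind = TRUE)
    nb <- ix; nb[, axis] <- nb[, axis] + side
    oor <- nb[, axis] < 1 | nb[, axis] > dims[axis]
    nbv <- rep(FALSE, nrow(ix))
    nbv[!oor] <- m$tag[nb[!oor, , drop = FALSE]] == TAG_VOID
    bc <- ix[oor | nbv, , drop = FALSE]
    if (!nrow(bc)) next
    i <- bc[, 1]; j <- bc[, 2]; k <- bc[, 3]
    tagb <- m$tag[bc]
    area <- switch(axis, m$dy[j] * m$dz[k], m$dx[i] * m$dz[k],
                   m$dx[i] * m$dy[j])
    dist <- switch(axis, m$dx[i] / 2, m$dy[j] / 2, m$dz[k] / 2)
    pcell <- pf[bc]
    Gb <- area * dk[bc] / dist
    if (axis == 1) {
      rbcb <- tagb == TAG_RBC
      qa <- f$velocity$vx[bc] * area
      if (side == -1L) {
        s <- rbcb
        fluxes["rbc_adv_in"] <- fluxes["rbc_adv_in"] +
          sum(qa[s] * content_blood(phys$P0)) +
          sum(Gb[s] * (phys$P0 - pcell[s]))
        amb <- tagb == TAG_PDMS
        fluxes["ambient_in"] <- fluxes["ambient_in"] +
          sum(Gb[amb] * (phys$P0 - pcell[amb]))
      } else {
        s <- rbcb
        fluxes["rbc_adv_out"] <- fluxes["rbc_adv_out"] +
          sum(qa[s] * content_blood(pcell[s]))
        amb <- tagb == TAG_PDMS
        fluxes["ambient_in"] <- fluxes["ambient_in"] +
          sum(Gb[amb] * (phys$P0 - pcell[amb]))
      }
    } else if (axis == 3) {
      gasb <- tagb == TAG_GAS
      qa <- f$velocity$vz[bc] * area
      if (side == -1L) {
        fluxes["gas_adv_in"] <- fluxes["gas_adv_in"] +
          sum(qa[gasb] * phys$k_gas * phys$Pl) +
          sum(Gb[gasb] * (phys$Pl - pcell[gasb]))
      } else {
        fluxes["gas_adv_out"] <- fluxes["gas_adv_out"] +
          sum(qa[gasb] * phys$k_gas * pcell[gasb])
      }
      amb <- tagb == TAG_PDMS
      fluxes["ambient_in"] <- fluxes["ambient_in"] +
        sum(Gb[amb] * (phys$P0 - pcell[amb]))
    } else {
      if (side == 1L) {
        amb <- tagb == TAG_PDMS
        fluxes["ambient_in"] <- fluxes["ambient_in"] +
          sum(Gb[amb] * (phys$P0 - pcell[amb]))
      } else {
        on0 <- abs(m$ys[j] - 0) < 1e-12
        amb <- tagb == TAG_PDMS & !on0
        fluxes["ambient_in"] <- fluxes["ambient_in"] +
          sum(Gb[amb] * (phys$P0 - pcell[amb]))
        if (gas_mode == "ideal-window") {
          inwin <- abs(m$xc[i]) <= g$window_length / 2 + 1e-12 &
            abs(m$zc[k]) <= g$window_width / 2 + 1e-12
          s <- tagb == TAG_PDMS & on0 & inwin
          fluxes["window_in"] <- fluxes["window_in"] +
            sum(Gb[s] * (phys$Pl - pcell[s]))
        }
      }
    }
  }

  if (gas_mode == "full-gas") {
    # open y = 0 faces between gas (below) and pdms (above)
    j0 <- which(abs(m$ys - 0) < 1e-12) - 1L
    if (length(j0) == 1 && j0 >= 1 && j0 < m$ny) {
      for (i in seq_len(m$nx)) for (k in seq_len(m$nz)) {
        if (m$tag[i, j0, k] != TAG_GAS || m$tag[i, j0 + 1L, k] != TAG_PDMS)
          next
        if (abs(m$xc[i]) > g$window_length / 2 + 1e-12 ||
            abs(m$zc[k]) > g$window_width / 2 + 1e-12) next
        A <- m$dx[i] * m$dz[k]
        G <- A / (m$dy[j0] / 2 / dk[i, j0, k] +
                    m$dy[j0 + 1L] / 2 / dk[i, j0 + 1L, k])
        fluxes["window_in"] <- fluxes["window_in"] +
          G * (pf[i, j0, k] - pf[i, j0 + 1L, k])
      }
    }
  }

  total_in <- fluxes["window_in"] + fluxes["ambient_in"] +
    fluxes["rbc_adv_in"] + fluxes["gas_adv_in"]
  total_out <- fluxes["rbc_adv_out"] + fluxes["gas_adv_out"]
  imb <- as.numeric(total_in - total_out)
  win <- abs(as.numeric(fluxes["window_in"]))
  out <- as.list(fluxes)
  out$imbalance <- imb
  out$window_influx <- win
  out$rel_imbalance <- abs(imb) / max(win, .Machine$double.eps)
  out
}

#' Mesh convergence study
#'
#' Re-solves the transport problem on successively refined meshes and
#' reports the weighted drop and its level-to-level relative change.
#'
#' @param cfg A [simulation_config()].
#' @param levels Number of mesh levels (>= 2); level L uses the base mesh
#'   refined L-1 times by factor 2.
#' @param mu Optical attenuation for the weighted drop; defaults to the
#'   configured `mu_attenuation`.
#' @return Data.frame with columns `level`, `n_cells`, `weighted_drop`,
#'   `rel_change`.
#' @export
convergence_study <- function(cfg, levels = 2, mu = NULL) {
  stopifnot(levels >= 2)
  m <- build_mesh(cfg$geometry, cfg$resolution, cfg$gas_mode)
  rows <- list()
  wd_prev <- NA_real_
  for (L in seq_len(levels)) {
    if (L > 1) m <- refine(m, 2)
    f <- solve_transport(cfg, m = m)
    wd <- weighted_drop(f, mu = mu)
    rows[[L]] <- data.frame(level = L, n_cells = f$convergence$n_cells,
                            weighted_drop = wd,
                            rel_change = if (L == 1) NA_real_ else
                              abs(wd - wd_prev) / abs(wd_prev))
    wd_prev <- wd
  }
  do.call(rbind, rows)
}
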