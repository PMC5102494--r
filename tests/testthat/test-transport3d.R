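# Steady conjugate transport solver: exact degenerate cases, maximum
# principle, symmetry, conservation, nonlinearity handling, and the
# cross-model comparison against the 1D closed form.

test_that("a pure-diffusion slab recovers the exact linear profile", {
  # white-box: single-column PDMS slab, window plane (Pl) below, ambient
  # (P0) above; huge lateral cells make the side influence negligible
  ny <- 8
  fake_g <- structure(list(rbc_width = 1, rbc_height = 1, rbc_length = 4e5,
                           window_length = 4e5, window_width = 4e5,
                           spincoat_thickness = 0.01, pdms_pad_x = 1,
                           pdms_pad_y = 1, pdms_pad_z = 1, y0 = 10,
                           gas_width = 4e5, gas_height = 1,
                           gas_length = 4e5), class = "device_geometry")
  m <- oxywindow:::mesh_from_axes(c(-2e5, 2e5), seq(0, 1, length.out = ny + 1),
                                  c(-2e5, 2e5), fake_g, "ideal-window",
                                  mesh_resolution())
  expect_true(all(m$tag == 1L))   # classified pdms (channel is off-grid)
  phys <- test_physics()
  sys <- oxywindow:::assemble_transport(m, NULL, phys,
                                        array(160, dim(m$tag)),
                                        "ideal-window")
  p <- as.numeric(Matrix::solve(sys$A, sys$b))
  exact <- phys$Pl + (phys$P0 - phys$Pl) * m$yc   # linear in y
  expect_equal(p, exact, tolerance = 1e-8)
})

test_that("uniform Dirichlet data yields the constant solution", {
  m <- build_mesh(test_geometry(), test_resolution())
  phys <- test_physics()
  phys$Pl <- phys$P0   # every boundary then carries the same value
  sys <- oxywindow:::assemble_transport(m, NULL, phys,
                                        array(160, dim(m$tag)),
                                        "ideal-window")
  p <- as.numeric(Matrix::solve(sys$A, sys$b))
  expect_equal(p, rep(phys$P0, length(p)), tolerance = 1e-9)
})

test_that("hemoglobin-free blood solves in a single Picard iteration", {
  cfg <- test_config(physics = test_physics(HbT = 0, Ht = 0))
  f <- solve_transport(cfg)
  expect_true(f$convergence$linear)
  expect_equal(f$convergence$iterations, 1L)
  # and the nonlinear problem takes several
  f2 <- cached_test_field()
  expect_gt(f2$convergence$iterations, 3L)
  expect_false(f2$convergence$linear)
})

test_that("converged fields respect the discrete maximum principle", {
  f <- cached_test_field()
  expect_gte(min(f$values), f$cfg$physics$Pl)
  expect_lte(max(f$values), f$cfg$physics$P0)
  # also on a deliberately coarse mesh
  cfg <- test_config(resolution = mesh_resolution(h_channel = 0.1,
                                                  h_axial = 0.25,
                                                  h_coarse = 0.5,
                                                  n_spincoat = 1))
  fc <- solve_transport(cfg)
  expect_gte(min(fc$values), 0)
  expect_lte(max(fc$values), 160)
})

test_that("solutions are mirror-symmetric across the gas-flow midplane", {
  f <- cached_test_field()
  a <- po2_array(f)
  m <- f$mesh
  # the z grid is symmetric by construction
  expect_equal(m$zc, -rev(m$zc), tolerance = 1e-12)
  flipped <- a[, , m$nz:1]
  expect_equal(a, flipped, tolerance = 1e-4)
})

test_that("global oxygen balance closes on converged solutions", {
  # constant capacity: the upwind advection telescopes and the audit is
  # exact to round-off
  cfg <- test_config(physics = test_physics(HbT = 0, Ht = 0))
  f <- solve_transport(cfg)
  fx <- flux_report(f)
  expect_gt(fx$window_influx, 0)
  # exact telescoping, limited only by the linear-solver tolerance
  expect_lt(fx$rel_imbalance, 1e-6)
  # nonlinear content advection: first-order audit, within 1% of the
  # window influx
  fx2 <- flux_report(cached_test_field())
  expect_lt(fx2$rel_imbalance, 0.01)
})

test_that("the full gas domain approaches the ideal window at high flow", {
  geom <- test_geometry()
  base_phys <- test_physics(mean_velocity_gas = 500)
  res <- test_resolution()
  f_ideal <- solve_transport(simulation_config(geometry = geom,
                                               physics = base_phys,
                                               resolution = res,
                                               gas_mode = "ideal-window"))
  f_full <- solve_transport(simulation_config(geometry = geom,
                                              physics = base_phys,
                                              resolution = res,
                                              gas_mode = "full-gas"))
  wd_i <- weighted_drop(f_ideal)
  wd_f <- weighted_drop(f_full)
  expect_lt(abs(wd_f - wd_i) / wd_i, 0.15)
  # the finite gas supply can only weaken the exchange
  expect_lte(wd_f, wd_i * 1.02)
  # gas-side maximum principle still holds with both inlets active
  expect_gte(min(f_full$values), 0)
  expect_lte(max(f_full$values), 160)
})

test_that("quasi-1D device agrees with the 1D closed form", {
  # wide, very shallow channel over a thick membrane: the centreline is
  # locally one-dimensional and the membrane dominates the series
  # resistance, which is the regime in which the conductance mapping of
  # the 1D model is meaningful
  ph <- physical_parameters(Ht = 0, HbT = 0, mu_attenuation = 0,
                            mean_velocity_rbc = 0.011,
                            mean_velocity_gas = 100)
  g <- suppressWarnings(device_geometry(
    rbc_width = 1, rbc_height = 0.005, window_length = 2, window_width = 2,
    spincoat_thickness = 0.3, pdms_pad_x = 1, pdms_pad_y = 0.6,
    pdms_pad_z = 0.5, gas_width = 3, gas_length = 3))
  cfg <- simulation_config(geometry = g, physics = ph,
                           resolution = mesh_resolution(h_channel = 0.05,
                                                        h_axial = 0.25,
                                                        h_coarse = 0.4,
                                                        n_spincoat = 2))
  f <- solve_transport(cfg)
  prof <- weighted_centreline(f, mu = 0)
  wd3 <- max(ph$P0 - prof$po2)
  k <- wall_conductances(ph, t_wall = g$pdms_pad_y,
                         t_spincoat = g$spincoat_thickness,
                         Hr = g$rbc_height)
  d <- nondimensionalize(model1d_parameters(
    D = ph$D_plasma, c = ph$mean_velocity_rbc, k1 = k$k1, k2 = k$k2,
    Lw = g$window_length))
  wd1 <- (ph$P0 - ph$Pl) * as.numeric(u_max(solve_closed_form(d)))
  expect_lte(wd3, wd1)                      # the 1D model overestimates
  expect_lt((wd1 - wd3) / wd1, 0.10)        # but by less than 10% here
})

test_that("solver failure modes raise informative errors", {
  cfg <- test_config(solver = solver_options(max_picard = 2,
                                             relaxation = 0.3))
  err <- tryCatch(solve_transport(cfg), error = function(e) e)
  expect_s3_class(err, "oxywindow_nonconvergence")
  expect_match(conditionMessage(err), "did not converge")
  expect_true(length(err$history) == 2)
})
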