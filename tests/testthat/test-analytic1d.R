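# Closed-form 1D window-exchange model against its finite-difference
# oracle, the published design-chart behaviour, and the re-dimensionalized
# criteria.

test_that("nondimensionalization produces the three governing groups", {
  p <- model1d_parameters(D = 0.00275, c = 0.0275, k1 = 0,
                          k2 = 20 * 0.00275, Lw = 1)
  d <- nondimensionalize(p)
  expect_equal(d$Pe, 10)
  expect_equal(d$S1, 0)
  expect_equal(d$S2, 20)
  p2 <- model1d_parameters(D = 0.002, c = 0.01, k1 = 0.5, k2 = 1, Lw = 0.4)
  d2 <- nondimensionalize(p2)
  expect_equal(d2$Pe, 0.01 * 0.4 / 0.002)
  expect_equal(d2$S1, 0.5 * 0.16 / 0.002)
  expect_equal(d2$S2, 1 * 0.16 / 0.002)
})

test_that("closed form reproduces the published example solution", {
  sol <- solve_closed_form(dimensionless1d(10, 5, 20))
  um <- u_max(sol)
  # published maximum drop 0.68 at the printed 2-decimal precision
  expect_equal(as.numeric(um), 0.68, tolerance = 0.01)
  # frozen regression value (verified against the fd oracle below)
  expect_equal(as.numeric(um), 0.6850264, tolerance = 1e-6)
  # drop begins just before the window and peaks near its end
  expect_gt(attr(um, "xi"), 0.8)
  expect_lt(attr(um, "xi"), 1)
  # interior equilibrium bounds the drop
  expect_lt(as.numeric(um), sol$u_p)
  expect_equal(sol$u_p, 0.8)
})

test_that("matching conditions are satisfied to round-off", {
  for (d in list(dimensionless1d(10, 5, 20), dimensionless1d(0.5, 2, 80),
                 dimensionless1d(100, 10, 5))) {
    s <- solve_closed_form(d)
    # value and slope of each piece at the window edges, analytically
    e_p <- exp(-s$mu_plus); e_m <- exp(s$mu_minus)
    res <- c(
      s$A - (s$u_p + s$C1 * e_p + s$C2),
      s$A * s$lambda_plus - (s$mu_plus * s$C1 * e_p + s$mu_minus * s$C2),
      (s$u_p + s$C1 + s$C2 * e_m) - s$B,
      (s$mu_plus * s$C1 + s$mu_minus * s$C2 * e_m) - s$lambda_minus * s$B)
    expect_lt(max(abs(res)), 1e-10)
  }
})

test_that("finite-difference oracle converges to the closed form", {
  d <- dimensionless1d(10, 5, 20)
  sol <- solve_closed_form(d)
  o <- fd_oracle_1d(d, halfwidth = 20, n_nodes = 400001)
  expect_lt(max(abs(o$u - sol$u(o$xi))), 1e-4)
  # oracle self-consistency on the maximum
  expect_equal(max(o$u), as.numeric(u_max(sol)), tolerance = 1e-3)
  # second-order convergence: halving h reduces the error ~4x (decay
  # closures keep the truncation error out of the comparison)
  e1 <- max(abs(fd_oracle_1d(d, 20, 25001, bc = "decay")$u -
                  sol$u(fd_oracle_1d(d, 20, 25001, bc = "decay")$xi)))
  e2 <- max(abs(fd_oracle_1d(d, 20, 50001, bc = "decay")$u -
                  sol$u(fd_oracle_1d(d, 20, 50001, bc = "decay")$xi)))
  expect_gt(e1 / e2, 3.3)
  expect_lt(e1 / e2, 4.7)
  # vanishing window forcing leaves no drop
  o0 <- fd_oracle_1d(dimensionless1d(10, 5, 1e-10), 20, 25001)
  expect_lt(max(abs(o0$u)), 1e-10)
})

test_that("closed form agrees with the oracle over a parameter sample", {
  set.seed(421)
  for (rep in 1:10) {
    Pe <- 10^stats::runif(1, -1, 2)
    S1 <- stats::runif(1, 0.5, 20)
    S2 <- stats::runif(1, 1, 100)
    d <- dimensionless1d(Pe, S1, S2)
    sol <- solve_closed_form(d)
    # decay closures are exact for the far-field modes, so a moderate
    # truncation width suffices; h is set by the upstream layer ~ 1/Pe
    hw <- 15
    n <- ceiling((2 * hw + 1) / min(3e-4, 0.02 / Pe))
    o <- fd_oracle_1d(d, hw, n, bc = "decay")
    expect_lt(max(abs(o$u - sol$u(o$xi))), 1e-4)
    # solution bounds: 0 <= u <= u_p <= 1 everywhere
    expect_gte(min(o$u), -1e-8)
    expect_lte(max(sol$u(seq(-2, 3, by = 1e-3))), sol$u_p + 1e-12)
    # maximum sits in or just downstream of the window
    expect_gte(attr(u_max(sol), "xi"), 0)
    expect_lte(attr(u_max(sol), "xi"), 1)
  }
})

test_that("complete exchange is approached for huge window permeation", {
  # S2 -> infinity with weak walls and vanishing advection: u_max -> 1
  expect_gt(as.numeric(u_max(solve_closed_form(
    dimensionless1d(1e-6, 1e-8, 1e5)))), 0.99)
  # and the S1 = 0 particular solution equals 1 inside a long window
  s <- solve_closed_form(dimensionless1d(0.1, 1e-12, 50))
  expect_equal(s$u_p, 1, tolerance = 1e-10)
})

test_that("drop distance follows the 1% transition criterion", {
  sol <- solve_closed_form(dimensionless1d(10, 5, 20))
  dx <- delta_xi(sol)
  # frozen from the closed form; the drop spans slightly more than the
  # window itself, consistent with onset just upstream of the window
  expect_equal(dx, 1.130968, tolerance = 1e-5)
  expect_gt(dx, 1)
  # the documented alternative level convention gives a nearby value
  expect_equal(delta_xi(sol, method = "endpoint-relative"), 1.1217,
               tolerance = 1e-4)
  # tightening the band widens the distance, loosening shrinks it
  expect_lt(delta_xi(sol, frac = 0.02), dx)
  expect_gt(delta_xi(sol, frac = 0.005), dx)
  expect_error(delta_xi(sol, frac = 0.7), "frac")
})

test_that("re-dimensionalized criteria scale as the design formulas", {
  p <- model1d_parameters(D = 0.00275, c = 0.0275, k1 = 5 * 0.00275,
                          k2 = 20 * 0.00275, Lw = 1)
  cr <- criteria(p, epsilon = 0.005)
  expect_equal(cr$max_drop, 160 * cr$u_max)
  expect_equal(cr$max_drop, 108.8, tolerance = 0.9)  # (P0-Pl) * 0.68
  expect_equal(cr$drop_rate,
               p$c * 160 * cr$u_max / (p$Lw * cr$delta_xi))
  expect_equal(cr$temporal_resolution, 0.005 / 0.0275)
  # doubling c at fixed dimensionless solution doubles the rate and
  # halves the temporal resolution
  expect_equal(2 * p$c * 160 * cr$u_max / (p$Lw * cr$delta_xi),
               2 * cr$drop_rate)
  expect_error(criteria(model1d_parameters(D = 1, c = 0, k1 = 0, k2 = 1,
                                           Lw = 1), epsilon = 1), "c = 0")
})

test_that("design curves reproduce the published chart trends", {
  pe <- c(0.5, 1, 2, 5, 10, 20, 50, 100)
  tab <- design_curves(pe, s1_set = c(1, 5, 10), s2_set = c(5, 20, 80))
  expect_equal(nrow(tab), length(pe) * 9)
  ok <- logical(0)
  for (s1 in c(1, 5, 10)) for (s2 in c(5, 20, 80)) {
    sub <- tab[tab$S1 == s1 & tab$S2 == s2, ]
    sub <- sub[order(sub$Pe), ]
    ok <- c(ok, all(diff(sub$u_max) < 0))              # drop falls with Pe
  }
  expect_true(all(ok))
  # the dimensionless rate grows with Pe through the design window
  # (Pe up to ~5; beyond, the shrinking drop overtakes the narrowing
  # transition and the rate turns over)
  tabr <- design_curves(c(0.25, 0.5, 1, 2, 3, 5), s1_set = c(1, 5, 10),
                        s2_set = c(5, 20, 80))
  ok <- logical(0)
  for (s1 in c(1, 5, 10)) for (s2 in c(5, 20, 80)) {
    sub <- tabr[tabr$S1 == s1 & tabr$S2 == s2, ]
    sub <- sub[order(sub$Pe), ]
    ok <- c(ok, all(diff(sub$drop_rate_dimless) > 0))
  }
  expect_true(all(ok))
  # u_max grows with S2 at fixed Pe, S1
  ok <- logical(0)
  for (pe1 in pe) for (s1 in c(1, 5, 10)) {
    sub <- tab[tab$Pe == pe1 & tab$S1 == s1, ]
    sub <- sub[order(sub$S2), ]
    ok <- c(ok, all(diff(sub$u_max) > 0))
  }
  expect_true(all(ok))
  # the relative wall sensitivity of u_max shrinks as the window
  # strengthens
  spread <- function(s2, pe1) {
    sub <- tab[tab$S2 == s2 & tab$Pe == pe1, ]
    diff(range(sub$u_max)) / mean(sub$u_max)
  }
  for (pe1 in c(1, 10, 100))
    expect_lt(spread(80, pe1), spread(5, pe1))
})

test_that("1D geometry predictions level off and vanish as expected", {
  cfg <- test_config()
  tab <- predict_geometry_effects_1d(
    cfg, window_lengths = c(0.1, 0.25, 0.5, 1, 2, 5, 10, 20),
    spincoat_thicknesses = c(0.02, 0.05, 0.1, 0.5, 1, 2))
  win <- tab[tab$sweep == "window_length", ]
  # drop grows toward a plateau: non-decreasing (to round-off on the
  # plateau), clearly increasing early, and the last doubling of the
  # window changes the drop by under 2%
  inc <- diff(win$drop_mmHg)
  expect_true(all(inc > -1e-9))
  expect_gt(win$drop_mmHg[4], win$drop_mmHg[1])
  n <- nrow(win)
  expect_lt((win$drop_mmHg[n] - win$drop_mmHg[n - 1]) / win$drop_mmHg[n],
            0.02)
  sc <- tab[tab$sweep == "spincoat", ]
  expect_true(all(diff(sc$drop_mmHg) < 0))
  expect_lt(sc$drop_mmHg[nrow(sc)], 0.25 * sc$drop_mmHg[1])
})
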