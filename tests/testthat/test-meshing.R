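# Graded structured hex meshing: tags, volumes, conformity, refinement.

test_that("region volumes are exact for the structured mesh", {
  g <- test_geometry()
  m <- build_mesh(g, test_resolution())
  vol <- mesh_region_volumes(m)
  expect_equal(vol[["rbc"]], g$rbc_width * g$rbc_height * g$rbc_length,
               tolerance = 1e-12)
  ytop <- g$y0 + g$rbc_height + g$pdms_pad_y
  block <- g$rbc_length * ytop * (g$rbc_width + 2 * g$pdms_pad_z)
  expect_equal(vol[["pdms"]] + vol[["rbc"]], block, tolerance = 1e-12)
  expect_equal(vol[["void"]], 0)
  # bounding box is fully partitioned
  bb <- diff(range(m$xs)) * diff(range(m$ys)) * diff(range(m$zs))
  expect_equal(sum(vol), bb, tolerance = 1e-12)
})

test_that("cell tags agree with centroid point-in-box classification", {
  g <- test_geometry()
  m <- build_mesh(g, test_resolution(), gas_mode = "full-gas")
  ijk <- which(m$tag == 3L, arr.ind = TRUE)
  expect_true(all(abs(m$zc[ijk[, 3]]) < g$rbc_width / 2))
  expect_true(all(m$yc[ijk[, 2]] > g$y0 &
                    m$yc[ijk[, 2]] < g$y0 + g$rbc_height))
  ijk <- which(m$tag == 2L, arr.ind = TRUE)
  expect_true(all(m$yc[ijk[, 2]] < 0))
  expect_true(all(abs(m$xc[ijk[, 1]]) < g$gas_width / 2))
  # void cells lie outside both the PDMS block and the gas channel
  ijk <- which(m$tag == 0L, arr.ind = TRUE)
  if (nrow(ijk)) {
    in_pdms <- m$yc[ijk[, 2]] > 0 &
      m$yc[ijk[, 2]] < g$y0 + g$rbc_height + g$pdms_pad_y &
      abs(m$zc[ijk[, 3]]) < g$rbc_width / 2 + g$pdms_pad_z &
      abs(m$xc[ijk[, 1]]) < g$rbc_length / 2
    in_gas <- m$yc[ijk[, 2]] < 0 & m$yc[ijk[, 2]] > -g$gas_height &
      abs(m$xc[ijk[, 1]]) < g$gas_width / 2 &
      abs(m$zc[ijk[, 3]]) < g$gas_length / 2
    expect_true(!any(in_pdms | in_gas))
  }
})

test_that("channels are resolved fine and the PDMS is graded coarse", {
  g <- device_geometry(rbc_width = 0.1, rbc_height = 0.1)
  m <- build_mesh(g, mesh_resolution(h_channel = 0.01, h_axial = 0.05,
                                     h_coarse = 0.5, n_spincoat = 2))
  expect_equal(min(m$dx, m$dy, m$dz), 0.01, tolerance = 0.01)
  expect_gt(max(m$dx, m$dy, m$dz), 0.2)
  # the window footprint is resolved by at least 4 cells in-plane even at
  # coarse settings
  g2 <- test_geometry()
  m2 <- build_mesh(g2, mesh_resolution(h_channel = 0.08, h_axial = 0.4,
                                       h_coarse = 0.6))
  inwin_x <- sum(abs(m2$xc) < g2$window_length / 2)
  inwin_z <- sum(abs(m2$zc) < g2$window_width / 2)
  expect_gte(inwin_x, 4)
  expect_gte(inwin_z, 4)
  expect_error(build_mesh(g, mesh_resolution(h_channel = 0.2)),
               "h_channel")
})

test_that("refinement preserves regions and multiplies cells 8-fold", {
  m <- build_mesh(test_geometry(), test_resolution())
  m2 <- refine(m, 2)
  expect_equal(m2$nx * m2$ny * m2$nz, 8 * m$nx * m$ny * m$nz)
  expect_gt(nrow(mesh_nodes(m2)), nrow(mesh_nodes(m)))
  expect_equal(mesh_region_volumes(m2), mesh_region_volumes(m),
               tolerance = 1e-12)
  m3 <- refine(m, 3)
  expect_equal(m3$nx, 3 * m$nx)
  expect_error(refine(m, 5), "factor")
})

test_that("every interior face is shared by exactly two hexahedra", {
  m <- build_mesh(device_geometry(rbc_width = 0.3, rbc_height = 0.3,
                                  window_length = 0.4, window_width = 0.4,
                                  pdms_pad_x = 0.3, pdms_pad_y = 0.3,
                                  pdms_pad_z = 0.3),
                  mesh_resolution(h_channel = 0.1, h_axial = 0.2,
                                  h_coarse = 0.3, n_spincoat = 1))
  cl <- mesh_cells(m)
  # hex faces in VTK node ordering
  faceix <- list(c(1, 2, 3, 4), c(5, 6, 7, 8), c(1, 2, 6, 5),
                 c(4, 3, 7, 8), c(1, 4, 8, 5), c(2, 3, 7, 6))
  keys <- character(0)
  for (fi in faceix) {
    quad <- cl$conn[, fi, drop = FALSE]
    keys <- c(keys, apply(quad, 1, function(r)
      paste(sort(r), collapse = "-")))
  }
  counts <- table(keys)
  expect_true(all(counts <= 2))
  n_interior <- sum(counts == 2)
  # tensor-grid interior face count
  expected <- (m$nx - 1) * m$ny * m$nz + m$nx * (m$ny - 1) * m$nz +
    m$nx * m$ny * (m$nz - 1)
  expect_equal(n_interior, expected)
  # axes strictly increasing: every hex has positive volume
  expect_true(all(diff(m$xs) > 0) && all(diff(m$ys) > 0) &&
                all(diff(m$zs) > 0))
})

test_that("VTK export writes a readable unstructured grid", {
  m <- build_mesh(test_geometry(), mesh_resolution(h_channel = 0.1,
                                                   h_axial = 0.25,
                                                   h_coarse = 0.5,
                                                   n_spincoat = 1))
  path <- withr::local_tempfile(fileext = ".vtk")
  write_vtk(m, path, cell_fields = list(dummy = rep(1, sum(m$tag != 0L))))
  txt <- readLines(path)
  expect_equal(txt[1], "# vtk DataFile Version 3.0")
  expect_true(any(grepl("^CELLS", txt)))
  expect_true(any(grepl("SCALARS dummy", txt)))
  np <- as.integer(sub("POINTS (\\d+) double", "\\1",
                       grep("^POINTS", txt, value = TRUE)))
  expect_equal(np, nrow(mesh_nodes(m)))
})
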