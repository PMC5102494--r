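# Graded structured hexahedral meshing of the composite device domain.
# The mesh is a tensor grid whose axis breakpoints include every material
# interface, so cells never straddle regions and conformity is automatic;
# channels are resolved at fine size and the PDMS bulk is graded to coarse.

TAG_VOID <- 0L
TAG_PDMS <- 1L
TAG_GAS <- 2L
TAG_RBC <- 3L
TAG_LEVELS <- c("void", "pdms", "gas", "rbc")

# uniform subdivision of [a, b] at target size h
seg_uniform <- function(a, b, h) {
  n <- max(1L, ceiling((b - a) / h - 1e-9))
  seq(a, b, length.out = n + 1)
}

# geometric grading of [a, b] from size h_fine at one end toward h_coarse,
# rescaled to fit the interval exactly
seg_graded <- function(a, b, h_fine, h_coarse, ratio, fine_at = "left") {
  L <- b - a
  if (L <= h_fine * 1.5) return(c(a, b))
  w <- h_fine
  widths <- c()
  while (sum(widths) < L) {
    widths <- c(widths, w)
    w <- min(w * ratio, h_coarse)
  }
  widths <- widths * (L / sum(widths))
  if (fine_at == "right") widths <- rev(widths)
  a + cumsum(c(0, widths))
}

# merge consecutive segment node vectors into one strictly increasing axis;
# zero-length segments (coincident features) are dropped
join_segs <- function(...) {
  segs <- Filter(function(s) !is.null(s) && diff(range(s)) > 1e-12, list(...))
  out <- segs[[1]]
  for (s in segs[-1]) out <- c(out, s[-1])
  stopifnot(all(diff(out) > 0))
  out
}

classify_cells <- function(xc, yc, zc, g, gas_mode) {
  nx <- length(xc); ny <- length(yc); nz <- length(zc)
  tag <- array(TAG_VOID, c(nx, ny, nz))
  ytop <- g$y0 + g$rbc_height + g$pdms_pad_y
  zpd <- g$rbc_width / 2 + g$pdms_pad_z
  X <- array(rep(xc, ny * nz), c(nx, ny, nz))
  Y <- array(rep(rep(yc, each = nx), nz), c(nx, ny, nz))
  Z <- array(rep(zc, each = nx * ny), c(nx, ny, nz))
  pdms <- abs(X) <= g$rbc_length / 2 & Y >= 0 & Y <= ytop & abs(Z) <= zpd
  tag[pdms] <- TAG_PDMS
  rbc <- pdms & Y >= g$y0 & Y <= g$y0 + g$rbc_height & abs(Z) <= g$rbc_width / 2
  tag[rbc] <- TAG_RBC
  if (gas_mode == "full-gas") {
    gas <- abs(X) <= g$gas_width / 2 & Y <= 0 & Y >= -g$gas_height &
      abs(Z) <= g$gas_length / 2
    tag[gas] <- TAG_GAS
  }
  tag
}

mesh_from_axes <- function(xs, ys, zs, g, gas_mode, resolution) {
  xc <- (xs[-1] + xs[-length(xs)]) / 2
  yc <- (ys[-1] + ys[-length(ys)]) / 2
  zc <- (zs[-1] + zs[-length(zs)]) / 2
  m <- list(xs = xs, ys = ys, zs = zs,
            xc = xc, yc = yc, zc = zc,
            dx = diff(xs), dy = diff(ys), dz = diff(zs),
            nx = length(xc), ny = length(yc), nz = length(zc),
            tag = classify_cells(xc, yc, zc, g, gas_mode),
            geometry = g, gas_mode = gas_mode, resolution = resolution)
  class(m) <- "device_mesh"
  m
}

#' Build a graded hexahedral mesh of the device
#'
#' Tensor-product hexahedral mesh of the PDMS block with embedded RBC
#' channel and spin coat, plus (in full-gas mode) the gas channel below the
#' window plane. Channel cross-sections and the window footprint are meshed
#' at the fine sizes in `res` (the window is always resolved by at least 4
#' cells in each in-plane direction); the PDMS bulk is geometrically graded
#' to `h_coarse`. Every material interface coincides with a grid plane, so
#' each cell carries exactly one region tag and interfaces are conforming.
#'
#' @param g A [device_geometry()].
#' @param res A [mesh_resolution()].
#' @param gas_mode `"ideal-window"` (no gas domain; the window face is a
#'   boundary) or `"full-gas"`.
#' @return An object of class `device_mesh`: axis node coordinates
#'   `xs, ys, zs`, cell sizes, and the cell region tag array (`void`,
#'   `pdms`, `gas`, `rbc`).
#' @export
build_mesh <- function(g, res = mesh_resolution(),
                       gas_mode = c("ideal-window", "full-gas")) {
  stopifnot(inherits(g, "device_geometry"), inherits(res, "mesh_resolution"))
  gas_mode <- match.arg(gas_mode)
  if (res$h_channel > max(g$rbc_width, g$rbc_height))
    stop(sprintf(paste("mesh resolution too coarse for the channel",
                       "cross-section; use h_channel <= %.4g mm"),
                 max(g$rbc_width, g$rbc_height) / 3))
  if (gas_mode == "full-gas" && g$gas_width > g$rbc_length)
    stop("full-gas meshing requires gas_width <= rbc_length")

  ratio <- res$grading
  hx <- min(res$h_axial, g$window_length / 4)
  hy <- min(res$h_channel, g$rbc_height / 4)
  hz <- min(res$h_channel, g$rbc_width / 4, g$window_width / 4)

  # x axis: fine across the window, graded outward to the block ends
  xr <- g$rbc_length / 2
  xw <- g$window_length / 2
  xsegs <- list(seg_graded(-xr, -xw, hx, res$h_coarse, ratio, "right"),
                seg_uniform(-xw, xw, hx),
                seg_graded(xw, xr, hx, res$h_coarse, ratio, "left"))
  if (gas_mode == "full-gas" && g$gas_width / 2 > xw &&
      g$gas_width / 2 < xr) {
    xg <- g$gas_width / 2
    xsegs <- list(seg_graded(-xr, -xg, hx, res$h_coarse, ratio, "right"),
                  seg_graded(-xg, -xw, hx, res$h_coarse, ratio, "right"),
                  seg_uniform(-xw, xw, hx),
                  seg_graded(xw, xg, hx, res$h_coarse, ratio, "left"),
                  seg_graded(xg, xr, hx, res$h_coarse, ratio, "left"))
  }
  xs <- do.call(join_segs, xsegs)

  # y axis: gas channel (optional), spin coat, RBC channel, PDMS pad above.
  # The channel interval is graded fine at its bottom face, where the
  # oxygen boundary layer against the window forms.
  ytop <- g$y0 + g$rbc_height + g$pdms_pad_y
  ysegs <- list(seq(0, g$y0, length.out = res$n_spincoat + 1),
                seg_graded(g$y0, g$y0 + g$rbc_height, hy / 16, hy,
                           ratio, "left"),
                seg_graded(g$y0 + g$rbc_height, ytop, hy, res$h_coarse,
                           ratio, "left"))
  if (gas_mode == "full-gas")
    ysegs <- c(list(seg_graded(-g$gas_height, 0, hy, res$h_coarse, ratio,
                               "right")), ysegs)
  ys <- do.call(join_segs, ysegs)

  # z axis: fine across channel and window footprint, graded outward
  zch <- g$rbc_width / 2
  zwin <- g$window_width / 2
  zpd <- zch + g$pdms_pad_z
  zmax <- if (gas_mode == "full-gas") max(zpd, g$gas_length / 2) else zpd
  zfine <- max(zch, zwin)
  # fine cells between consecutive features (channel walls, window edges),
  # graded toward the channel side walls inside the channel where the
  # lateral oxygen boundary layer forms; no sliver cells appear at
  # material interfaces
  feats <- sort(unique(c(-zfine, -zch, zch, -zwin, zwin, zfine, 0)))
  inner <- feats[1]
  for (q in seq_len(length(feats) - 1)) {
    a <- feats[q]; b <- feats[q + 1]
    seg <- if (abs(a + zch) < 1e-12 && b <= 0) {
      seg_graded(a, b, hz / 16, hz, ratio, "left")    # left wall inward
    } else if (abs(b - zch) < 1e-12 && a >= 0) {
      seg_graded(a, b, hz / 16, hz, ratio, "right")   # right wall inward
    } else {
      seg_uniform(a, b, hz)
    }
    inner <- c(inner, seg[-1])
  }
  zsegs <- list(seg_graded(-zmax, -zfine, hz, res$h_coarse, ratio, "right"),
                inner,
                seg_graded(zfine, zmax, hz, res$h_coarse, ratio, "left"))
  if (gas_mode == "full-gas" && g$gas_length / 2 > zfine &&
      g$gas_length / 2 < zmax) {
    zg <- g$gas_length / 2
    zsegs <- list(seg_graded(-zmax, -zg, hz, res$h_coarse, ratio, "right"),
                  seg_graded(-zg, -zfine, hz, res$h_coarse, ratio, "right"),
                  inner,
                  seg_graded(zfine, zg, hz, res$h_coarse, ratio, "left"),
                  seg_graded(zg, zmax, hz, res$h_coarse, ratio, "left"))
  }
  zs <- do.call(join_segs, zsegs)

  mesh_from_axes(xs, ys, zs, g, gas_mode, res)
}

#' Uniformly refine a device mesh
#'
#' Splits every cell into `factor^3` children by subdividing each axis
#' interval; region tags are re-derived from cell centroids, which leaves
#' region volumes and interface conformity unchanged (material interfaces
#' lie on grid planes).
#'
#' @param m A `device_mesh`.
#' @param factor Subdivision factor, 2 or 3.
#' @return The refined `device_mesh`.
#' @export
refine <- function(m, factor = 2) {
  stopifnot(inherits(m, "device_mesh"), factor %in% c(2, 3))
  split_axis <- function(xs) {
    out <- xs[1]
    for (i in seq_len(length(xs) - 1))
      out <- c(out, xs[i] + diff(xs[i:(i + 1)]) * seq_len(factor) / factor)
    out
  }
  mesh_from_axes(split_axis(m$xs), split_axis(m$ys), split_axis(m$zs),
                 m$geometry, m$gas_mode, m$resolution)
}

#' @export
print.device_mesh <- function(x, ...) {
  counts <- table(factor(TAG_LEVELS[x$tag + 1L], levels = TAG_LEVELS))
  cat(sprintf("device_mesh: %d x %d x %d cells (%d active)\n",
              x$nx, x$ny, x$nz, sum(x$tag != TAG_VOID)))
  cat("  regions:", paste(sprintf("%s=%d", names(counts), counts),
                          collapse = ", "), "\n")
  cat(sprintf("  edge lengths: %.4g - %.4g mm\n",
              min(x$dx, x$dy, x$dz), max(x$dx, x$dy, x$dz)))
  invisible(x)
}

#' Mesh node coordinates
#' @param m A `device_mesh`.
#' @return Matrix (n_nodes x 3) of node coordinates (mm), x fastest.
#' @export
mesh_nodes <- function(m) {
  as.matrix(expand.grid(x = m$xs, y = m$ys, z = m$zs,
                        KEEP.OUT.ATTRS = FALSE))
}

#' Hexahedral cell connectivity of the active cells
#' @param m A `device_mesh`.
#' @return List with `conn` (n_cells x 8 node indices, VTK hexahedron
#'   ordering), `tag` (region name per cell) and `cell_index` (linear index
#'   into the tag array).
#' @export
mesh_cells <- function(m) {
  act <- which(m$tag != TAG_VOID)
  ijk <- arrayInd(act, dim(m$tag))
  nxp <- m$nx + 1L; nyp <- m$ny + 1L
  nid <- function(i, j, k) i + nxp * ((j - 1L) + nyp * (k - 1L))
  i <- ijk[, 1]; j <- ijk[, 2]; k <- ijk[, 3]
  conn <- cbind(nid(i, j, k), nid(i + 1L, j, k),
                nid(i + 1L, j + 1L, k), nid(i, j + 1L, k),
                nid(i, j, k + 1L), nid(i + 1L, j, k + 1L),
                nid(i + 1L, j + 1L, k + 1L), nid(i, j + 1L, k + 1L))
  list(conn = conn, tag = TAG_LEVELS[m$tag[act] + 1L], cell_index = act)
}

#' Region volumes of a device mesh
#' @param m A `device_mesh`.
#' @return Named numeric vector of region volumes (mm^3).
#' @export
mesh_region_volumes <- function(m) {
  vol <- outer(m$dx, outer(m$dy, m$dz))
  vapply(setNames(seq_along(TAG_LEVELS) - 1L, TAG_LEVELS),
         function(t) sum(vol[m$tag == t]), numeric(1))
}

#' Write a mesh (and optional fields) as legacy VTK
#'
#' Plain-text VTK unstructured-grid export for inspection in ParaView.
#'
#' @param m A `device_mesh`.
#' @param file Output path (`.vtk`).
#' @param cell_fields Named list of per-active-cell scalar vectors.
#' @param point_fields Named list of per-node vectors (length n_nodes) or
#'   3-column matrices (written as vectors).
#' @return `file`, invisibly.
#' @export
write_vtk <- function(m, file, cell_fields = list(), point_fields = list()) {
  nod <- mesh_nodes(m)
  cl <- mesh_cells(m)
  nc <- nrow(cl$conn)
  con <- file(file, "w")
  on.exit(close(con))
  wr <- function(...) writeLines(c(...), con)
  wr("# vtk DataFile Version 3.0", "oxywindow device mesh", "ASCII",
     "DATASET UNSTRUCTURED_GRID")
  wr(sprintf("POINTS %d double", nrow(nod)))
  writeLines(apply(nod, 1, function(r) paste(format(r, digits = 10),
                                             collapse = " ")), con)
  wr(sprintf("CELLS %d %d", nc, nc * 9))
  writeLines(apply(cl$conn - 1L, 1, function(r) paste(c(8L, r),
                                                      collapse = " ")), con)
  wr(sprintf("CELL_TYPES %d", nc))
  writeLines(rep("12", nc), con)
  cell_fields <- c(list(region = match(cl$tag, TAG_LEVELS) - 1L), cell_fields)
  wr(sprintf("CELL_DATA %d", nc))
  for (nm in names(cell_fields)) {
    wr(sprintf("SCALARS %s double 1", nm), "LOOKUP_TABLE default")
    writeLines(format(cell_fields[[nm]], digits = 10), con)
  }
  if (length(point_fields)) {
    wr(sprintf("POINT_DATA %d", nrow(nod)))
    for (nm in names(point_fields)) {
      v <- point_fields[[nm]]
      if (is.matrix(v)) {
        wr(sprintf("VECTORS %s double", nm))
        writeLines(apply(v, 1, function(r) paste(format(r, digits = 10),
                                                 collapse = " ")), con)
      } else {
        wr(sprintf("SCALARS %s double 1", nm), "LOOKUP_TABLE default")
        writeLines(format(v, digits = 10), con)
      }
    }
  }
  invisible(file)
}
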