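#' Read a triangulated surface from an STL file
#'
#' Supports both ASCII and binary STL. The format is auto-detected: a file
#' whose size matches the binary layout (80-byte header, 4-byte triangle
#' count, 50 bytes per facet) is read as binary, otherwise as ASCII.
#'
#' @param path file path.
#' @return object of class `stl_mesh`: list with `v1`, `v2`, `v3` (n x 3
#'   vertex matrices, one row per facet) and `normal` (n x 3).
#' @export
read_stl <- function(path) {
  sz <- file.info(path)$size
  if (is.na(sz) || sz < 15) stop("not a readable STL file: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  header <- readBin(con, "raw", 80)
  is_binary <- FALSE
  if (sz >= 84) {
    ntri <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (!is.na(ntri) && ntri >= 0 && sz == 84 + 50 * as.numeric(ntri))
      is_binary <- TRUE
  }
  if (is_binary) {
    n <- ntri
    if (n == 0) stop("degenerate STL: zero facets")
    vals <- matrix(NA_real_, n, 12)
    for (k in seq_len(n)) {
      vals[k, ] <- readBin(con, "numeric", 12, size = 4, endian = "little")
      readBin(con, "raw", 2)
    }
    mesh <- list(normal = vals[, 1:3, drop = FALSE],
                 v1 = vals[, 4:6, drop = FALSE],
                 v2 = vals[, 7:9, drop = FALSE],
                 v3 = vals[, 10:12, drop = FALSE])
  } else {
    txt <- readLines(path, warn = FALSE)
    vl <- grep("^\\s*vertex", txt, value = TRUE)
    nl <- grep("^\\s*facet\\s+normal", txt, value = TRUE)
    if (length(vl) == 0 || length(vl) %% 3 != 0)
      stop("degenerate STL: vertex count not a multiple of 3")
    num <- function(lines, skip) {
      t(vapply(strsplit(trimws(lines), "\\s+"), function(p)
        as.numeric(p[(skip + 1):(skip + 3)]), numeric(3)))
    }
    v <- num(vl, 1)
    nm <- if (length(nl)) num(nl, 2) else matrix(0, length(vl) / 3, 3)
    i <- seq(1, nrow(v), by = 3)
    mesh <- list(normal = nm, v1 = v[i, , drop = FALSE],
                 v2 = v[i + 1, , drop = FALSE], v3 = v[i + 2, , drop = FALSE])
  }
  structure(mesh, class = "stl_mesh")
}

#' Write a triangle soup as ASCII STL
#'
#' @param mesh an `stl_mesh` (or list with `v1`, `v2`, `v3` matrices).
#' @param path output path.
#' @param name solid name written to the file.
#' @export
write_stl <- function(mesh, path, name = "hemolbm") {
  v1 <- mesh$v1; v2 <- mesh$v2; v3 <- mesh$v3
  n <- nrow(v1)
  nm <- mesh$normal
  if (is.null(nm)) {
    a <- v2 - v1; b <- v3 - v1
    nm <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
                a[, 3] * b[, 1] - a[, 1] * b[, 3],
                a[, 1] * b[, 2] - a[, 2] * b[, 1])
    len <- sqrt(rowSums(nm^2)); len[len == 0] <- 1
    nm <- nm / len
  }
  fmt <- function(m) sprintf("%.9g %.9g %.9g", m[, 1], m[, 2], m[, 3])
  lines <- c(paste("solid", name),
             as.vector(rbind(paste("  facet normal", fmt(nm)),
                             "    outer loop",
                             paste("      vertex", fmt(v1)),
                             paste("      vertex", fmt(v2)),
                             paste("      vertex", fmt(v3)),
                             "    endloop",
                             "  endfacet")),
             paste("endsolid", name))
  writeLines(lines, path)
  invisible(path)
}

.stl_bounds <- function(mesh) {
  v <- rbind(mesh$v1, mesh$v2, mesh$v3)
  rbind(apply(v, 2, min), apply(v, 2, max))
}

# Even-odd (ray parity) inside test: rays along +x through each query point.
# A tiny deterministic offset on y/z avoids rays grazing facet edges.
.stl_inside_fun <- function(mesh) {
  v1 <- mesh$v1; v2 <- mesh$v2; v3 <- mesh$v3
  function(p) {
    if (is.null(dim(p))) p <- matrix(p, ncol = 3)
    eps <- 1e-7 * max(1, max(abs(p)))
    py <- p[, 2] + eps * 0.618; pz <- p[, 3] + eps * 1.414
    inside <- logical(nrow(p))
    for (k in seq_len(nrow(v1))) {
      a <- v1[k, ]; b <- v2[k, ]; c3 <- v3[k, ]
      # 2D barycentric test in the yz projection
      d00 <- c(b[2] - a[2], b[3] - a[3])
      d01 <- c(c3[2] - a[2], c3[3] - a[3])
      det <- d00[1] * d01[2] - d00[2] * d01[1]
      if (abs(det) < 1e-30) next
      wy <- py - a[2]; wz <- pz - a[3]
      l1 <- (wy * d01[2] - wz * d01[1]) / det
      l2 <- (wz * d00[1] - wy * d00[2]) / det
      hit <- l1 >= 0 & l2 >= 0 & (l1 + l2) <= 1
      if (!any(hit)) next
      xs <- a[1] + l1[hit] * (b[1] - a[1]) + l2[hit] * (c3[1] - a[1])
      cross <- xs > p[hit, 1]
      inside[hit] <- xor(inside[hit], cross)
    }
    inside
  }
}

#' Extract the voxel boundary surface of a geometry
#'
#' Triangulates every exposed face between a non-solid node and a solid (or
#' hull) neighbor, producing a watertight staircase surface suitable for
#' [write_stl()] and quick visual checks.
#'
#' @param geom an `lbm_geometry`.
#' @return an `stl_mesh` in physical coordinates (m).
#' @export
geometry_surface <- function(geom) {
  fl <- geom$flags
  n <- dim(fl)
  dx <- geom$dx
  org <- geom$origin
  solid <- fl == FLAG_SOLID
  tri1 <- list(); tri2 <- list(); tri3 <- list()
  add_face <- function(centers, axis, sgn) {
    if (nrow(centers) == 0) return()
    # face center offset half a node toward the neighbour
    fc <- sweep((centers - 1) * dx, 2, org, "+")
    fc[, axis] <- fc[, axis] + sgn * dx / 2
    ax <- setdiff(1:3, axis)
    h <- dx / 2
    c1 <- fc; c1[, ax[1]] <- c1[, ax[1]] - h; c1[, ax[2]] <- c1[, ax[2]] - h
    c2 <- fc; c2[, ax[1]] <- c2[, ax[1]] + h; c2[, ax[2]] <- c2[, ax[2]] - h
    c3 <- fc; c3[, ax[1]] <- c3[, ax[1]] + h; c3[, ax[2]] <- c3[, ax[2]] + h
    c4 <- fc; c4[, ax[1]] <- c4[, ax[1]] - h; c4[, ax[2]] <- c4[, ax[2]] + h
    tri1[[length(tri1) + 1]] <<- rbind(c1, c1)
    tri2[[length(tri2) + 1]] <<- rbind(c2, c3)
    tri3[[length(tri3) + 1]] <<- rbind(c3, c4)
  }
  open_idx <- which(fl != FLAG_SOLID, arr.ind = TRUE)
  for (axis in 1:3) for (sgn in c(-1L, 1L)) {
    nb <- open_idx
    nb[, axis] <- nb[, axis] + sgn
    outside <- nb[, axis] < 1L | nb[, axis] > n[axis]
    inb <- !outside
    is_solid <- outside
    if (any(inb)) is_solid[inb] <- solid[nb[inb, , drop = FALSE]]
    add_face(open_idx[is_solid, , drop = FALSE], axis, sgn)
  }
  structure(list(v1 = do.call(rbind, tri1), v2 = do.call(rbind, tri2),
                 v3 = do.call(rbind, tri3), normal = NULL),
            class = "stl_mesh")
}
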