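# Watertight 3D triangle meshes for the cell catalogue, built as surfaces of
# revolution of the 2D half-profile about the cell axis (which yields
# spherical caps for capsules naturally); bent rods bend the straight capsule
# mesh about its neutral axis. Exported as binary STL for CFD pipelines.

# revolve a half-profile (x_i >= ordered along axis, r_i >= 0 with
# r_1 = r_m = 0 at the poles) around the x axis with n_theta sectors.
# Returns list(vertices = V x 3, faces = F x 3, 1-based indices).
revolve_profile <- function(px, pr, n_theta = 32L) {
  m <- length(px)
  stopifnot(m >= 3L, abs(pr[1L]) < 1e-9, abs(pr[m]) < 1e-9, all(pr >= -1e-9))
  pr[c(1L, m)] <- 0
  th <- seq(0, 2 * pi, length.out = n_theta + 1L)[-(n_theta + 1L)]
  verts <- rbind(c(px[1L], 0, 0))
  ring_start <- integer(m)  # vertex index of first ring vertex per profile row
  for (i in 2:(m - 1L)) {
    ring_start[i] <- nrow(verts) + 1L
    verts <- rbind(verts, cbind(px[i], pr[i] * cos(th), pr[i] * sin(th)))
  }
  apex2 <- nrow(verts) + 1L
  verts <- rbind(verts, c(px[m], 0, 0))
  faces <- matrix(integer(0), 0L, 3L)
  nxt <- c(2:n_theta, 1L)
  # first cap fan
  r1 <- ring_start[2L]
  faces <- rbind(faces, cbind(1L, r1 + seq_len(n_theta) - 1L,
                              r1 + nxt - 1L))
  # side quads
  if (m > 3L) for (i in 2:(m - 2L)) {
    a <- ring_start[i] + seq_len(n_theta) - 1L
    b <- ring_start[i] + nxt - 1L
    c2 <- ring_start[i + 1L] + seq_len(n_theta) - 1L
    d <- ring_start[i + 1L] + nxt - 1L
    faces <- rbind(faces, cbind(a, c2, d), cbind(a, d, b))
  }
  # last cap fan
  rl <- ring_start[m - 1L]
  faces <- rbind(faces, cbind(apex2, rl + nxt - 1L, rl + seq_len(n_theta) - 1L))
  list(vertices = verts, faces = faces)
}

# axial half-profile of a catalogue shape at given angular resolution
shape_profile <- function(kind, length, width, resolution = 16L) {
  r <- width / 2
  if (kind == "coccoid") {
    th <- seq(0, pi, length.out = 2L * resolution + 1L)
    rr <- length / 2
    return(list(px = -rr * cos(th), pr = rr * sin(th)))
  }
  if (kind == "ellipsoid") {
    th <- seq(0, pi, length.out = 2L * resolution + 1L)
    return(list(px = -(length / 2) * cos(th), pr = r * sin(th)))
  }
  # rod / bent_rod: straight capsule profile; bending applied afterwards
  h <- (length - width) / 2
  th <- seq(0, pi / 2, length.out = resolution + 1L)
  # left hemisphere pole->junction, sampled cylinder, right hemisphere;
  # intermediate rings let the bend transform follow the arc faithfully
  px_l <- -h - r * cos(th)          # -h - r ... -h
  pr_l <- r * sin(th)               # 0 ... r
  px_r <- h + r * sin(th)           # h ... h + r
  pr_r <- r * cos(th)               # r ... 0
  if (h > 0) {
    mid <- seq(-h, h, length.out = 2L * resolution + 2L)
    mid <- mid[-c(1L, length(mid))]
    px <- c(px_l, mid, px_r)
    pr <- c(pr_l, rep(r, length(mid)), pr_r)
  } else {
    px <- c(px_l, px_r)
    pr <- c(pr_l, pr_r)
  }
  list(px = px, pr = pr)
}

# bend a straight-axis mesh about the z axis: axial coordinate x becomes arc
# position along a circle of radius R = L / bend (neutral axis y = 0)
bend_mesh <- function(verts, bend, arc_length) {
  if (bend == 0) return(verts)
  R <- arc_length / abs(bend)
  sgn <- sign(bend)
  phi <- verts[, 1L] / R
  x <- (R - sgn * verts[, 2L]) * sin(phi)
  y <- sgn * (R - sgn * verts[, 2L]) * cos(phi) - sgn * R
  cbind(x, y, verts[, 3L])
}

#' Triangle mesh of a cell agent
#'
#' Builds a watertight closed surface for the agent's shape: rods become 3D
#' capsules, coccoids spheres, ellipsoids revolved ellipses and bent rods
#' swept tubes with spherical caps. Coordinates in µm, in the agent's body
#' frame (axis along x).
#'
#' @param agent single-row agent table (or list with `kind`, `length`,
#'   `width`, `bend`).
#' @param resolution angular resolution: profile points per quarter turn;
#'   each ring has `4 * resolution` sectors.
#' @return List with `vertices` (V x 3 matrix, µm) and `faces` (F x 3
#'   1-based vertex indices, outward orientation).
#' @export
agent_mesh <- function(agent, resolution = 16L) {
  kind <- agent$kind
  prof <- shape_profile(kind, agent$length, agent$width, resolution)
  mesh <- revolve_profile(prof$px, prof$pr, n_theta = 4L * resolution)
  if (kind == "bent_rod" && agent$bend != 0)
    mesh$vertices <- bend_mesh(mesh$vertices, agent$bend,
                               agent$length - agent$width)
  # normalize to outward orientation (positive divergence-theorem volume)
  if (mesh_volume(mesh) < 0) mesh$faces <- mesh$faces[, c(1L, 3L, 2L)]
  mesh
}

#' Mesh volume via the divergence theorem
#'
#' `V = sum det(v1, v2, v3) / 6` over triangles; exact for watertight,
#' consistently oriented meshes.
#'
#' @param mesh list with `vertices` and `faces` as from [agent_mesh()].
#' @return Signed volume in µm³ (positive for outward orientation).
#' @export
mesh_volume <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 1L], , drop = FALSE]
  b <- v[f[, 2L], , drop = FALSE]
  c3 <- v[f[, 3L], , drop = FALSE]
  sum(a[, 1L] * (b[, 2L] * c3[, 3L] - b[, 3L] * c3[, 2L]) -
      a[, 2L] * (b[, 1L] * c3[, 3L] - b[, 3L] * c3[, 1L]) +
      a[, 3L] * (b[, 1L] * c3[, 2L] - b[, 2L] * c3[, 1L])) / 6
}

#' Check mesh watertightness
#'
#' A closed orientable surface has every undirected edge shared by exactly
#' two triangles (and in opposite directions).
#'
#' @param mesh list with `vertices` and `faces`.
#' @return `TRUE` if watertight.
#' @export
mesh_is_watertight <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1L, 2L)], f[, c(2L, 3L)], f[, c(3L, 1L)])
  key <- paste(pmin(e[, 1L], e[, 2L]), pmax(e[, 1L], e[, 2L]))
  all(table(key) == 2L)
}

#' Export a cell agent as binary STL
#'
#' Writes the agent's watertight surface mesh (see [agent_mesh()]) as a
#' binary STL file, the de-facto exchange format for CFD meshing pipelines.
#'
#' @inheritParams agent_mesh
#' @param path output `.stl` path.
#' @return `path`, invisibly.
#' @export
export_mesh <- function(agent, path, resolution = 16L) {
  mesh <- agent_mesh(agent, resolution)
  v <- mesh$vertices; f <- mesh$faces
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(80L), con)
  writeBin(as.integer(nrow(f)), con, size = 4L, endian = "little")
  for (i in seq_len(nrow(f))) {
    a <- v[f[i, 1L], ]; b <- v[f[i, 2L], ]; c3 <- v[f[i, 3L], ]
    nrm <- c((b[2L] - a[2L]) * (c3[3L] - a[3L]) - (b[3L] - a[3L]) * (c3[2L] - a[2L]),
             (b[3L] - a[3L]) * (c3[1L] - a[1L]) - (b[1L] - a[1L]) * (c3[3L] - a[3L]),
             (b[1L] - a[1L]) * (c3[2L] - a[2L]) - (b[2L] - a[2L]) * (c3[1L] - a[1L]))
    nl <- sqrt(sum(nrm^2))
    if (nl > 0) nrm <- nrm / nl
    writeBin(as.numeric(c(nrm, a, b, c3)), con, size = 4L, endian = "little")
    writeBin(raw(2L), con)
  }
  invisible(path)
}
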