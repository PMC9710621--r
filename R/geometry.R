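#' @useDynLib colonysim, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Cell outlines are closed polygonal chains: an n x 2 matrix of (x, y)
# vertices in micrometres, implicitly closed (last vertex connects to the
# first), stored counterclockwise. Class "polygon_chain".

#' Construct a polygon chain
#'
#' Wraps an n x 2 vertex matrix as a validated, counterclockwise-normalized
#' closed polygonal chain, the universal cell-outline representation.
#'
#' @param vertices numeric matrix with n >= 8 rows and columns (x, y), in µm.
#' @return A `polygon_chain` object (the matrix, CCW-normalized).
#' @export
polygon_chain <- function(vertices) {
  vertices <- as.matrix(vertices)
  if (!is.numeric(vertices) || ncol(vertices) != 2L)
    stop("invalid shape: vertices must be a numeric n x 2 matrix", call. = FALSE)
  if (nrow(vertices) < 8L)
    stop("invalid shape: a polygon chain needs >= 8 vertices", call. = FALSE)
  if (any(!is.finite(vertices)))
    stop("invalid shape: non-finite vertex coordinates", call. = FALSE)
  a <- signed_area(vertices)
  if (a == 0)
    stop("invalid shape: degenerate polygon (zero area)", call. = FALSE)
  if (a < 0) vertices <- vertices[rev(seq_len(nrow(vertices))), , drop = FALSE]
  dimnames(vertices) <- NULL
  structure(vertices, class = "polygon_chain")
}

signed_area <- function(v) {
  x <- v[, 1L]; y <- v[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  sum(x * yn - xn * y) / 2
}

#' Polygon area (shoelace formula)
#'
#' @param chain a `polygon_chain` (or plain n x 2 vertex matrix).
#' @return Absolute enclosed area in µm², independent of vertex orientation.
#' @export
polygon_area <- function(chain) {
  abs(signed_area(as.matrix(chain)))
}

#' Polygon centroid
#'
#' Area-weighted centroid of the enclosed region.
#'
#' @inheritParams polygon_area
#' @return Numeric length-2 vector (x, y) in µm.
#' @export
polygon_centroid <- function(chain) {
  v <- as.matrix(chain)
  x <- v[, 1L]; y <- v[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  cr <- x * yn - xn * y
  a <- sum(cr) / 2
  c(sum((x + xn) * cr), sum((y + yn) * cr)) / (6 * a)
}

#' Straight rod (capsule) outline
#'
#' A spherocylinder contour: a rectangle of length `length - width` capped by
#' two semicircles of radius `width / 2`. `length` is tip-to-tip, as cell
#' length is read in micrographs. Centroid at the origin, major axis along +x.
#'
#' @param length tip-to-tip length in µm; must satisfy `length >= width`.
#' @param width cell width (cap diameter) in µm; must be > 0.
#' @param n_vertices number of contour vertices (>= 8; default 32).
#' @return A `polygon_chain`.
#' @export
make_rod <- function(length, width, n_vertices = 32L) {
  check_rod_params(length, width, n_vertices)
  r <- width / 2
  h <- (length - width) / 2  # half-length of the straight mid-section
  # split vertices between the two cap arcs; endpoints of each arc are the
  # junctions with the straight sides, so no duplicated vertices
  m <- max(4L, floor(n_vertices / 2))
  th_r <- seq(-pi / 2, pi / 2, length.out = m)        # right cap, CCW
  th_l <- seq(pi / 2, 3 * pi / 2, length.out = m)     # left cap, CCW
  v <- rbind(
    cbind(h + r * cos(th_r), r * sin(th_r)),
    cbind(-h + r * cos(th_l), r * sin(th_l))
  )
  polygon_chain(v)
}

check_rod_params <- function(length, width, n_vertices) {
  if (!is.finite(length) || !is.finite(width) || width <= 0 || length < width)
    stop("invalid shape: need length >= width > 0", call. = FALSE)
  if (n_vertices < 8L)
    stop("invalid shape: n_vertices must be >= 8", call. = FALSE)
  invisible(TRUE)
}

#' Bent rod outline
#'
#' A capsule whose centerline is a circular arc of arc length
#' `length - width` subtending a total angle `bend` (radians). `bend = 0`
#' reduces exactly to [make_rod()]. The outline is the arc offset by
#' `width/2` on both sides, closed with semicircular caps. Centroid at the
#' origin, chord of the centerline along +x, bulge towards -y for positive
#' `bend`.
#'
#' @inheritParams make_rod
#' @param bend total centerline arc angle in radians; `|bend| < pi`.
#' @return A `polygon_chain`.
#' @export
make_bent_rod <- function(length, width, bend, n_vertices = 32L) {
  check_rod_params(length, width, n_vertices)
  if (!is.finite(bend) || abs(bend) >= pi)
    stop("invalid shape: |bend| must be < pi", call. = FALSE)
  if (bend == 0) return(make_rod(length, width, n_vertices))
  ch <- polygon_chain(bent_rod_raw(length, width, bend, n_vertices))
  # recentre on the area centroid so pose = centroid, as for other shapes
  ctr <- polygon_centroid(ch)
  polygon_chain(sweep(unclass(ch), 2L, ctr))
}

# centerline arc of a bent rod in the raw frame: chord on the x axis,
# bulge towards +y for positive bend. Shared by the outline construction and
# the placement capsule so both live in the same body frame.
bent_centerline <- function(length, width, bend, k) {
  L <- length - width
  R <- L / abs(bend)
  sgn <- sign(bend)
  phi <- seq(-abs(bend) / 2, abs(bend) / 2, length.out = k)
  cbind(R * sin(phi), sgn * (R * cos(phi) - R * cos(abs(bend) / 2)))
}

# un-centred bent rod outline vertices (raw frame of bent_centerline)
bent_rod_raw <- function(length, width, bend, n_vertices) {
  r <- width / 2
  L <- length - width              # centerline arc length
  R <- L / abs(bend)               # radius of curvature
  sgn <- sign(bend)
  m <- max(4L, floor(n_vertices / 2))
  k <- max(8L, m)                  # centerline sampling for the offset sides
  cl <- bent_centerline(length, width, bend, k)
  cx <- cl[, 1L]; cy <- cl[, 2L]
  phi <- seq(-abs(bend) / 2, abs(bend) / 2, length.out = k)
  # unit tangent (cos phi, -sgn sin phi); unit normal = tangent rotated +90deg
  tx <- cos(phi); ty <- -sgn * sin(phi)
  nx <- -ty; ny <- tx
  upper <- cbind(cx + r * nx, cy + r * ny)           # +normal side
  lower <- cbind(cx - r * nx, cy - r * ny)           # -normal side
  # caps: semicircles about the centerline endpoints, joining the two sides
  end_th <- atan2(ny[k], nx[k])                       # normal direction at end
  th_r <- end_th - seq(0, pi, length.out = m)[-c(1L, m)]
  cap_r <- cbind(cx[k] + r * cos(th_r), cy[k] + r * sin(th_r))
  start_th <- atan2(-ny[1L], -nx[1L])
  th_l <- start_th - seq(0, pi, length.out = m)[-c(1L, m)]
  cap_l <- cbind(cx[1L] + r * cos(th_l), cy[1L] + r * sin(th_l))
  rbind(upper, cap_r, lower[rev(seq_len(k)), , drop = FALSE], cap_l)
}

#' Ellipse / coccoid outline
#'
#' Ellipse contour with semi-axes `major/2` and `minor/2`; `major == minor`
#' yields the coccoid (circular) shape.
#'
#' @param major major axis (tip-to-tip) in µm; `major >= minor`.
#' @param minor minor axis in µm; must be > 0.
#' @param n_vertices number of contour vertices (>= 8; default 32).
#' @return A `polygon_chain`.
#' @export
make_ellipsoid <- function(major, minor, n_vertices = 32L) {
  if (!is.finite(major) || !is.finite(minor) || minor <= 0 || major < minor)
    stop("invalid shape: need major >= minor > 0", call. = FALSE)
  if (n_vertices < 8L)
    stop("invalid shape: n_vertices must be >= 8", call. = FALSE)
  th <- seq(0, 2 * pi, length.out = n_vertices + 1L)[-(n_vertices + 1L)]
  polygon_chain(cbind(major / 2 * cos(th), minor / 2 * sin(th)))
}

#' Coccoid outline
#'
#' Circle of diameter `width`; equivalent to `make_ellipsoid(width, width)`.
#'
#' @param width cell diameter in µm.
#' @param n_vertices number of contour vertices (>= 8; default 32).
#' @return A `polygon_chain`.
#' @export
make_coccoid <- function(width, n_vertices = 32L) {
  make_ellipsoid(width, width, n_vertices)
}

#' Outline for a shape-parameter set
#'
#' Dispatches on the catalogue kind (`"rod"`, `"bent_rod"`, `"coccoid"`,
#' `"ellipsoid"`) used throughout the simulator.
#'
#' @param kind one of `"rod"`, `"bent_rod"`, `"coccoid"`, `"ellipsoid"`.
#' @param length tip-to-tip length in µm.
#' @param width width (minor axis / diameter) in µm.
#' @param bend centerline arc angle in radians (bent rod only).
#' @param n_vertices contour vertex count.
#' @return A `polygon_chain` centered at the origin, axis along +x.
#' @export
shape_outline <- function(kind, length, width, bend = 0, n_vertices = 32L) {
  switch(kind,
    rod       = make_rod(length, width, n_vertices),
    bent_rod  = make_bent_rod(length, width, bend, n_vertices),
    coccoid   = make_coccoid(length, n_vertices),
    ellipsoid = make_ellipsoid(length, width, n_vertices),
    stop("unknown shape kind: ", kind, call. = FALSE)
  )
}

#' Rigidly place a polygon chain
#'
#' Rotates by `angle` about the origin, then translates by `position`.
#' Rigid, hence exactly area-preserving.
#'
#' @param chain a `polygon_chain`.
#' @param position numeric (x, y) translation in µm.
#' @param angle rotation in radians (counterclockwise).
#' @return The transformed `polygon_chain`.
#' @export
place <- function(chain, position = c(0, 0), angle = 0) {
  v <- as.matrix(chain)
  ca <- cos(angle); sa <- sin(angle)
  out <- cbind(v[, 1L] * ca - v[, 2L] * sa + position[1L],
               v[, 1L] * sa + v[, 2L] * ca + position[2L])
  structure(out, class = "polygon_chain")
}

# ---- polygon intersection ---------------------------------------------------
# Exact area of intersection of two simple polygons, used as the independent
# oracle for the placement contract. Convex clip polygons use
# Sutherland-Hodgman directly; a non-convex operand is ear-clipped into
# triangles first.

is_convex <- function(v) {
  n <- nrow(v)
  ip <- c(2:n, 1L); ipp <- c(3:n, 1L, 2L)
  e1x <- v[ip, 1L] - v[, 1L];  e1y <- v[ip, 2L] - v[, 2L]
  e2x <- v[ipp, 1L] - v[ip, 1L]; e2y <- v[ipp, 2L] - v[ip, 2L]
  cr <- e1x * e2y - e1y * e2x
  all(cr >= -1e-12 * max(abs(cr), 1))
}

# clip arbitrary simple subject polygon against a convex clip polygon (CCW)
sutherland_hodgman <- function(subject, clip) {
  out <- subject
  nc <- nrow(clip)
  for (i in seq_len(nc)) {
    if (nrow(out) == 0L) return(out)
    a <- clip[i, ]; b <- clip[if (i == nc) 1L else i + 1L, ]
    ex <- b[1L] - a[1L]; ey <- b[2L] - a[2L]
    inp <- out
    n <- nrow(inp)
    # signed side of each subject vertex wrt clip edge (>=0 is inside, CCW)
    side <- ex * (inp[, 2L] - a[2L]) - ey * (inp[, 1L] - a[1L])
    keep <- side >= 0
    nxt <- c(2:n, 1L)
    res <- matrix(numeric(0), 0L, 2L)
    for (j in seq_len(n)) {
      k <- nxt[j]
      if (keep[j]) {
        res <- rbind(res, inp[j, ])
        if (!keep[k]) {
          t <- side[j] / (side[j] - side[k])
          res <- rbind(res, inp[j, ] + t * (inp[k, ] - inp[j, ]))
        }
      } else if (keep[k]) {
        t <- side[j] / (side[j] - side[k])
        res <- rbind(res, inp[j, ] + t * (inp[k, ] - inp[j, ]))
      }
    }
    out <- res
  }
  out
}

# ear-clipping triangulation of a simple polygon (CCW); list of 3x2 matrices
triangulate_polygon <- function(v) {
  if (signed_area(v) < 0) v <- v[rev(seq_len(nrow(v))), , drop = FALSE]
  idx <- seq_len(nrow(v))
  tris <- vector("list", nrow(v) - 2L)
  nt <- 0L
  guard <- 0L
  while (length(idx) > 3L && guard < 10000L) {
    guard <- guard + 1L
    n <- length(idx)
    clipped <- FALSE
    for (j in seq_len(n)) {
      i0 <- idx[if (j == 1L) n else j - 1L]
      i1 <- idx[j]
      i2 <- idx[if (j == n) 1L else j + 1L]
      a <- v[i0, ]; b <- v[i1, ]; c <- v[i2, ]
      cr <- (b[1L] - a[1L]) * (c[2L] - a[2L]) - (b[2L] - a[2L]) * (c[1L] - a[1L])
      if (cr <= 1e-14) next  # reflex or degenerate corner
      # no other polygon vertex may lie inside the candidate ear
      others <- setdiff(idx, c(i0, i1, i2))
      if (length(others)) {
        px <- v[others, 1L]; py <- v[others, 2L]
        s1 <- (b[1L] - a[1L]) * (py - a[2L]) - (b[2L] - a[2L]) * (px - a[1L])
        s2 <- (c[1L] - b[1L]) * (py - b[2L]) - (c[2L] - b[2L]) * (px - b[1L])
        s3 <- (a[1L] - c[1L]) * (py - c[2L]) - (a[2L] - c[2L]) * (px - c[1L])
        if (any(s1 > 0 & s2 > 0 & s3 > 0)) next
      }
      nt <- nt + 1L
      tris[[nt]] <- rbind(a, b, c)
      idx <- idx[-j]
      clipped <- TRUE
      break
    }
    if (!clipped) break  # numerically stuck; remaining region has ~zero area
  }
  if (length(idx) == 3L) {
    nt <- nt + 1L
    tris[[nt]] <- v[idx, , drop = FALSE]
  }
  tris[seq_len(nt)]
}

#' Area of intersection of two polygon chains
#'
#' Exact polygon clipping: if either polygon is convex it is used as the
#' Sutherland-Hodgman clip region; otherwise one operand is triangulated and
#' the pieces clipped individually. Serves as the independent overlap oracle
#' for the placement contract.
#'
#' @param a,b `polygon_chain` objects (or n x 2 vertex matrices).
#' @return Intersection area in µm² (0 when disjoint).
#' @export
polygon_overlap_area <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  # cheap reject on bounding boxes
  if (max(a[, 1L]) <= min(b[, 1L]) || max(b[, 1L]) <= min(a[, 1L]) ||
      max(a[, 2L]) <= min(b[, 2L]) || max(b[, 2L]) <= min(a[, 2L])) return(0)
  if (signed_area(a) < 0) a <- a[rev(seq_len(nrow(a))), , drop = FALSE]
  if (signed_area(b) < 0) b <- b[rev(seq_len(nrow(b))), , drop = FALSE]
  if (is_convex(b)) {
    out <- sutherland_hodgman(a, b)
    if (nrow(out) < 3L) return(0)
    return(abs(signed_area(out)))
  }
  if (is_convex(a)) return(polygon_overlap_area(b, a))
  tris <- triangulate_polygon(a)
  tot <- 0
  for (tr in tris) {
    out <- sutherland_hodgman(b, tr)
    if (nrow(out) >= 3L) tot <- tot + abs(signed_area(out))
  }
  tot
}

#' Test points for polygon membership
#'
#' Vectorized even-odd (crossing number) test; boundary points are assigned
#' by the half-open crossing rule.
#'
#' @param px,py point coordinates.
#' @param chain a `polygon_chain` or n x 2 matrix.
#' @return Logical vector.
#' @export
points_in_polygon <- function(px, py, chain) {
  v <- as.matrix(chain)
  n <- nrow(v)
  inside <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- v[i, 1L]; yi <- v[i, 2L]
    xj <- v[j, 1L]; yj <- v[j, 2L]
    cross <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, cross)
    j <- i
  }
  inside
}
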