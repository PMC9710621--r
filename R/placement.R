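# Overlap resolution: cells are approximated by capsules around short
# centerline polylines (which contain the exact polygon outlines), and a
# deterministic damped position-based solver separates them until the
# residual capsule penetration bounds the polygon overlap below tolerance.

#' Placement configuration
#'
#' @param overlap_tolerance maximum allowed pairwise overlap, as a fraction
#'   of the smaller cell's area (default 0.01, sub-pixel at 0.09 µm/pixel).
#' @param max_iterations iteration cap for the separation solver.
#' @param damping step-size factor in (0, 1]; the solver additionally halves
#'   its step whenever total penetration would increase, so convergence is
#'   monotone.
#' @param rot_strength scale of the angular correction applied at contacts
#'   (0 freezes orientations; the default lets rods rotate and align).
#' @param boundary optional rectangular arena `c(xmin, ymin, xmax, ymax)` in
#'   µm, or `NULL` for an unbounded plane.
#' @return A `placement_config` list.
#' @export
placement_config <- function(overlap_tolerance = 0.01, max_iterations = 1000L,
                             damping = 0.7, rot_strength = 0.3,
                             boundary = NULL) {
  if (overlap_tolerance < 0) stop("overlap_tolerance must be >= 0", call. = FALSE)
  if (max_iterations < 1) stop("max_iterations must be >= 1", call. = FALSE)
  if (damping <= 0 || damping > 1) stop("damping must be in (0, 1]", call. = FALSE)
  if (!is.null(boundary) && length(boundary) != 4L)
    stop("boundary must be c(xmin, ymin, xmax, ymax) or NULL", call. = FALSE)
  structure(list(overlap_tolerance = overlap_tolerance,
                 max_iterations = as.integer(max_iterations),
                 damping = damping, rot_strength = rot_strength,
                 boundary = boundary),
            class = "placement_config")
}

# body-frame centerline polyline + contact radius for one agent.
# The polyline's capsule hull contains the rendered polygon outline:
# rods/ellipsoids use the axis segment, coccoids a point, bent rods a sampled
# arc with the radius inflated by the sampling sagitta so the discretization
# never under-covers the outline.
agent_capsule <- function(kind, length, width, bend) {
  if (kind == "coccoid") {
    return(list(pts = matrix(0, 1L, 2L), radius = length / 2))
  }
  r <- width / 2
  h <- max(0, (length - width) / 2)
  if (kind != "bent_rod" || bend == 0) {
    return(list(pts = cbind(c(-h, h), c(0, 0)), radius = r))
  }
  k <- 9L
  R <- (length - width) / abs(bend)
  pts <- bent_centerline(length, width, bend, k)
  # shift into the recentred body frame of make_bent_rod: subtract the raw
  # outline's centroid
  ctr <- polygon_centroid(polygon_chain(bent_rod_raw(length, width, bend, 32L)))
  pts <- sweep(pts, 2L, ctr)
  sagitta <- R * (1 - cos(abs(bend) / (2 * (k - 1))))
  list(pts = pts, radius = r + sagitta)
}

#' Resolve physical overlaps in a colony
#'
#' Iteratively separates overlapping cells by rigid translations and small
#' rotations until, for every pair, the polygon overlap area is at most
#' `overlap_tolerance` times the smaller cell's area, or `max_iterations` is
#' reached. Cell shape parameters are never modified; the solver is
#' deterministic for identical inputs.
#'
#' @param agents agent table (see [cell_agent()]).
#' @param config a [placement_config()].
#' @return The agent table with updated `x`, `y`, `angle`, carrying
#'   attributes `iterations`, `converged` and `penetration_log` (total
#'   contact penetration depth after each accepted solver iteration,
#'   non-increasing).
#' @export
resolve_overlaps <- function(agents, config = placement_config()) {
  validate_agents(agents)
  n <- nrow(agents)
  if (n == 0L) return(agents)
  if (any(!is.finite(agents$x)) || any(!is.finite(agents$y)) ||
      any(!is.finite(agents$angle)))
    stop("invalid state: non-finite agent positions", call. = FALSE)
  if (n == 1L && is.null(config$boundary)) {
    attr(agents, "iterations") <- 0L
    attr(agents, "converged") <- TRUE
    attr(agents, "penetration_log") <- 0
    return(agents)
  }
  caps <- lapply(seq_len(n), function(i)
    agent_capsule(agents$kind[i], agents$length[i], agents$width[i],
                  agents$bend[i]))
  pts <- do.call(rbind, lapply(caps, `[[`, "pts"))
  counts <- vapply(caps, function(cp) nrow(cp$pts), integer(1))
  offsets <- c(0L, cumsum(counts))
  radius <- vapply(caps, `[[`, numeric(1), "radius")
  areas <- vapply(seq_len(n), function(i)
    polygon_area(shape_outline(agents$kind[i], agents$length[i],
                               agents$width[i], agents$bend[i])), numeric(1))
  res <- resolve_overlaps_cpp(
    pts, as.integer(offsets), radius, areas, agents$length,
    agents$x, agents$y, agents$angle,
    config$overlap_tolerance, config$max_iterations, config$damping,
    config$rot_strength,
    if (is.null(config$boundary)) numeric(0) else as.numeric(config$boundary))
  agents$x <- res$x
  agents$y <- res$y
  agents$angle <- res$angle
  attr(agents, "iterations") <- res$iterations
  attr(agents, "converged") <- res$converged
  attr(agents, "penetration_log") <- res$penetration_log
  agents
}

#' Axis-aligned bounding box of a colony
#'
#' Tight box over all outline vertices of all agents.
#'
#' @param agents agent table with at least one row.
#' @param n_vertices contour vertex count used for the outlines.
#' @return Named numeric vector `(min_x, min_y, max_x, max_y)` in µm.
#' @export
colony_bounding_box <- function(agents, n_vertices = 32L) {
  if (nrow(agents) == 0L) stop("empty colony has no bounding box", call. = FALSE)
  vs <- lapply(seq_len(nrow(agents)), function(i)
    as.matrix(agent_outline(agents[i, ], n_vertices)))
  v <- do.call(rbind, vs)
  c(min_x = min(v[, 1L]), min_y = min(v[, 2L]),
    max_x = max(v[, 1L]), max_y = max(v[, 2L]))
}
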