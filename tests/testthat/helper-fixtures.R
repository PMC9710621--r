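# shared fixtures: all inputs are generated in code at test time

# Monte-Carlo point-in-polygon estimate of the intersection area of two
# polygons; independent oracle for polygon_overlap_area
mc_overlap_area <- function(a, b, n = 1e5, seed = 1) {
  a <- as.matrix(a); b <- as.matrix(b)
  lo <- pmin(apply(a, 2, min), apply(b, 2, min))
  hi <- pmax(apply(a, 2, max), apply(b, 2, max))
  set.seed(seed)
  px <- runif(n, lo[1], hi[1])
  py <- runif(n, lo[2], hi[2])
  hits <- points_in_polygon(px, py, a) & points_in_polygon(px, py, b)
  mean(hits) * prod(hi - lo)
}

# deterministic colony grown to >= n cells under the given model
grow_colony <- function(n, seed = 1, model = homeostasis_model(),
                        dt = 1 / 12, ...) {
  cfg <- simulation_config(seed = seed, dt = dt, duration = 0, model = model,
                           ...)
  res <- step_until_count(init_world(cfg), cfg, n)
  res$world
}

# exact worst pairwise overlap fraction over a colony, via the polygon oracle
worst_overlap_fraction <- function(agents) {
  n <- nrow(agents)
  if (n < 2) return(0)
  polys <- lapply(seq_len(n), function(i) agent_outline(agents[i, ]))
  areas <- vapply(polys, polygon_area, numeric(1))
  worst <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    ov <- polygon_overlap_area(polys[[i]], polys[[j]])
    worst <- max(worst, ov / min(areas[i], areas[j]))
  }
  worst
}

# small render config for fast tests
small_render <- function(px = 128L, ...) {
  render_config(image_size = c(px, px), ...)
}
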