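# Cell agents are rows of a data frame: vectorized state is the natural R
# idiom for an agent population, and keeps grow() a one-line closed form.

agent_columns <- c("id", "parent_id", "birth_time", "x", "y", "angle",
                   "kind", "length", "width", "bend", "growth_rate",
                   "division_trigger", "birth_length", "fluorescence")

#' Create cell agents
#'
#' Builds one or more cell agents as rows of an agent table. All lengths in
#' µm, times in hours, rates in 1/h.
#'
#' @param id unique integer id(s).
#' @param parent_id integer id of the mother cell, or `NA` for founders.
#' @param birth_time time of birth in h.
#' @param x,y position of the outline centroid in µm.
#' @param angle orientation of the major axis in radians.
#' @param kind shape kind: `"rod"`, `"bent_rod"`, `"coccoid"`, `"ellipsoid"`.
#' @param length tip-to-tip length in µm.
#' @param width cell width in µm.
#' @param bend centerline arc angle in radians (bent rods).
#' @param growth_rate exponential elongation constant in 1/h (> 0).
#' @param division_trigger division threshold: an age in h under the timer
#'   model, a length in µm under the sizer model (> 0).
#' @param birth_length length at birth in µm.
#' @param fluorescence total fluorescence emission of the cell (arbitrary
#'   units, >= 0).
#' @return A `data.frame` with one row per agent.
#' @export
cell_agent <- function(id, parent_id = NA_integer_, birth_time = 0,
                       x = 0, y = 0, angle = 0,
                       kind = "rod", length = 2, width = 0.9, bend = 0,
                       growth_rate = log(2), division_trigger = 1,
                       birth_length = length, fluorescence = 0) {
  ag <- data.frame(id = as.integer(id), parent_id = as.integer(parent_id),
                   birth_time = birth_time, x = x, y = y, angle = angle,
                   kind = kind, length = length, width = width, bend = bend,
                   growth_rate = growth_rate,
                   division_trigger = division_trigger,
                   birth_length = birth_length, fluorescence = fluorescence,
                   stringsAsFactors = FALSE)
  validate_agents(ag)
  ag
}

#' Empty agent table
#'
#' Zero-row agent table with the standard columns (e.g. for empty frames).
#'
#' @return A `data.frame` with 0 rows.
#' @export
empty_agents <- function() {
  cell_agent(1L)[0L, , drop = FALSE]
}

validate_agents <- function(agents) {
  stopifnot(is.data.frame(agents), all(agent_columns %in% names(agents)))
  if (nrow(agents)) {
    if (anyDuplicated(agents$id)) stop("agent ids must be unique", call. = FALSE)
    if (any(agents$growth_rate <= 0)) stop("growth_rate must be > 0", call. = FALSE)
    if (any(agents$division_trigger <= 0)) stop("division_trigger must be > 0", call. = FALSE)
    bad <- agents$width <= 0 |
      (agents$kind %in% c("rod", "bent_rod", "ellipsoid") & agents$length < agents$width)
    if (any(bad)) stop("invalid shape: need length >= width > 0", call. = FALSE)
  }
  invisible(agents)
}

#' Size-homeostasis model
#'
#' Phenomenological division rules: under `"timer"` a cell divides once its
#' age reaches its trigger (hours); under `"sizer"` once its length reaches
#' its trigger (µm). Per-cell triggers and elongation rates are drawn from
#' lognormal distributions with the given arithmetic means and coefficients
#' of variation, giving cell-to-cell heterogeneity with positive support.
#'
#' @param kind `"timer"` or `"sizer"`.
#' @param trigger_mean mean division trigger (h for timer, µm for sizer).
#' @param trigger_cv coefficient of variation of the trigger (>= 0).
#' @param rate_mean mean exponential elongation rate in 1/h.
#' @param rate_cv coefficient of variation of the rate (>= 0).
#' @return A `homeostasis_model` list.
#' @export
homeostasis_model <- function(kind = c("sizer", "timer"),
                              trigger_mean = if (match.arg(kind) == "timer") 1 else 3.6,
                              trigger_cv = 0.1,
                              rate_mean = log(2), rate_cv = 0.1) {
  kind <- match.arg(kind)
  if (!is.finite(trigger_mean) || trigger_mean <= 0)
    stop("trigger_mean must be > 0", call. = FALSE)
  if (!is.finite(rate_mean) || rate_mean <= 0)
    stop("rate_mean must be > 0", call. = FALSE)
  if (trigger_cv < 0 || rate_cv < 0) stop("cv must be >= 0", call. = FALSE)
  structure(list(kind = kind, trigger_mean = trigger_mean,
                 trigger_cv = trigger_cv, rate_mean = rate_mean,
                 rate_cv = rate_cv),
            class = "homeostasis_model")
}

#' Grow agents for one time step
#'
#' Exponential elongation: `length' = length * exp(growth_rate * dt)`.
#' Width and all other state are unchanged. Vectorized over the agent table.
#'
#' @param agents agent table (see [cell_agent()]).
#' @param dt time step in h (>= 0).
#' @return The grown agent table.
#' @export
grow <- function(agents, dt) {
  if (!is.finite(dt) || dt < 0) stop("invalid step: dt must be >= 0", call. = FALSE)
  agents$length <- agents$length * exp(agents$growth_rate * dt)
  agents
}

#' Division eligibility
#'
#' Timer: `now - birth_time >= division_trigger`; sizer:
#' `length >= division_trigger`. Comparisons are inclusive so a cell exactly
#' at its trigger divides.
#'
#' @param agents agent table.
#' @param model a [homeostasis_model()].
#' @param now current simulation time in h.
#' @return Logical vector, one element per agent.
#' @export
should_divide <- function(agents, model, now) {
  # tiny relative slack so a trigger hit exactly at a step boundary is not
  # missed to accumulated floating-point drift of the simulation clock
  eps <- 1e-9
  switch(model$kind,
    timer = (now - agents$birth_time) >= agents$division_trigger * (1 - eps),
    sizer = agents$length >= agents$division_trigger * (1 - eps),
    stop("unknown homeostasis model kind: ", model$kind, call. = FALSE)
  )
}

#' Lognormal draw parametrized by arithmetic mean and CV
#'
#' Draws from a lognormal with the requested arithmetic mean and coefficient
#' of variation; `cv = 0` returns `mean` exactly. Uses the current RNG state.
#'
#' @param n number of draws.
#' @param mean arithmetic mean (> 0).
#' @param cv coefficient of variation (>= 0).
#' @return Numeric vector of length `n`.
#' @export
sample_lognormal <- function(n, mean, cv) {
  if (!is.finite(mean) || mean <= 0) stop("mean must be > 0", call. = FALSE)
  if (cv < 0) stop("cv must be >= 0", call. = FALSE)
  if (cv == 0) return(rep(mean, n))
  sdlog <- sqrt(log(1 + cv^2))
  meanlog <- log(mean) - sdlog^2 / 2
  stats::rlnorm(n, meanlog, sdlog)
}

# evaluate expr under a derived RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# deterministic per-agent seed derivation (order-independent divisions)
derive_seed <- function(seed, id) {
  as.integer((as.double(seed) * 48271 + as.double(id) * 16807) %% 2147483647)
}

#' Divide eligible agents
#'
#' Symmetric fission: each mother is replaced by two daughters placed
#' end-to-end along the mother's axis at `+/- L/4` from her centroid, each of
#' length `L/2` (an optional Gaussian perturbation of the split fraction
#' redistributes length between daughters but total length is conserved
#' exactly). Daughters inherit width, bend and shape kind; their orientation
#' is the mother's plus a small Gaussian perturbation; fresh elongation rates
#' and division triggers are sampled from the model distributions; each
#' daughter keeps the mother's fluorescence *per unit length* (total emission
#' is split in proportion to daughter length). New parameter draws use a seed
#' derived from `(seed, daughter id)`, so results do not depend on the order
#' in which mothers are processed.
#'
#' @param agents agent table.
#' @param which_divide logical vector marking mothers (from [should_divide()]).
#' @param model a [homeostasis_model()].
#' @param now current simulation time in h; daughters get `birth_time = now`.
#' @param next_id first free integer id for daughters.
#' @param seed integer base seed of the simulation RNG stream.
#' @param angle_sd std. dev. of the daughter angle perturbation in radians.
#' @param split_sd std. dev. of the split-fraction perturbation (0 gives the
#'   exact symmetric split).
#' @return List with the updated agent table (`agents`) and the new `next_id`.
#' @export
divide_agents <- function(agents, which_divide, model, now, next_id,
                          seed = 0L, angle_sd = 0.05, split_sd = 0) {
  if (!any(which_divide)) return(list(agents = agents, next_id = next_id))
  mothers <- agents[which_divide, , drop = FALSE]
  mothers <- mothers[order(mothers$id), , drop = FALSE]
  keep <- agents[!which_divide, , drop = FALSE]
  daughters <- vector("list", nrow(mothers))
  for (m in seq_len(nrow(mothers))) {
    mo <- mothers[m, ]
    id1 <- next_id; id2 <- next_id + 1L
    next_id <- next_id + 2L
    pars <- with_seed(derive_seed(seed, id1), {
      list(rate = sample_lognormal(2L, model$rate_mean, model$rate_cv),
           trig = sample_lognormal(2L, model$trigger_mean, model$trigger_cv),
           dang = if (angle_sd > 0) stats::rnorm(2L, 0, angle_sd) else c(0, 0),
           frac = if (split_sd > 0)
             min(max(stats::rnorm(1L, 0.5, split_sd), 0.1), 0.9) else 0.5)
    })
    L <- mo$length
    l1 <- pars$frac * L; l2 <- L - l1
    ux <- cos(mo$angle); uy <- sin(mo$angle)
    # daughters sit head-to-tail: centers at -L/4 and +L/4 for the even split,
    # generally at the midpoints of the two length shares
    c1 <- -L / 2 + l1 / 2; c2 <- L / 2 - l2 / 2
    fl <- mo$fluorescence
    d <- mo[c(1L, 1L), ]
    d$id <- c(id1, id2)
    d$parent_id <- mo$id
    d$birth_time <- now
    d$x <- mo$x + c(c1, c2) * ux
    d$y <- mo$y + c(c1, c2) * uy
    d$angle <- mo$angle + pars$dang
    d$length <- c(l1, l2)
    d$birth_length <- c(l1, l2)
    d$growth_rate <- pars$rate
    d$division_trigger <- pars$trig
    d$fluorescence <- fl * c(l1, l2) / L
    daughters[[m]] <- d
  }
  out <- rbind(keep, do.call(rbind, daughters))
  rownames(out) <- NULL
  out <- out[order(out$id), , drop = FALSE]
  rownames(out) <- NULL
  list(agents = out, next_id = next_id)
}

#' Agent outline in the world frame
#'
#' @param agent single-row agent table (or list with the same fields).
#' @param n_vertices contour vertex count.
#' @return A `polygon_chain` in world coordinates (µm).
#' @export
agent_outline <- function(agent, n_vertices = 32L) {
  ch <- shape_outline(agent$kind, agent$length, agent$width, agent$bend,
                      n_vertices)
  place(ch, c(agent$x, agent$y), agent$angle)
}
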