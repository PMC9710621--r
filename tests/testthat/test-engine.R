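# simulation loop: founding, stepping, closed-form colony growth, determinism

test_that("init_world seeds founders reproducibly", {
  cfg <- simulation_config(seed = 7, n_founders = 4,
                           model = homeostasis_model())
  w1 <- init_world(cfg)
  w2 <- init_world(cfg)
  expect_equal(nrow(w1$agents), 4L)
  expect_true(all(is.na(w1$agents$parent_id)))
  expect_identical(w1$agents, w2$agents)
  expect_equal(w1$time, 0)
  expect_error(simulation_config(n_founders = 0), "n_founders")
})

test_that("a step divides exactly the cells at their trigger", {
  cfg <- simulation_config(seed = 1, dt = 0.1, duration = 1,
                           model = homeostasis_model("sizer",
                                                     trigger_mean = 4,
                                                     trigger_cv = 0,
                                                     rate_cv = 0),
                           founder_length = 2)
  w <- init_world(cfg)
  w1 <- step_world(w, cfg)
  expect_equal(nrow(w1$agents), 1L)  # far from trigger
  w$agents$length <- 4  # at the trigger
  w2 <- step_world(w, cfg)
  expect_equal(nrow(w2$agents), 2L)
  expect_equal(w2$time, w$time + cfg$dt)
})

test_that("timer colony doubles synchronously: 2^n cells after n periods", {
  cfg <- simulation_config(seed = 1, dt = 1 / 20, duration = 5,
                           model = homeostasis_model("timer",
                                                     trigger_mean = 1,
                                                     trigger_cv = 0,
                                                     rate_mean = log(2),
                                                     rate_cv = 0))
  tr <- run_simulation(cfg)
  counts <- vapply(tr, function(w) nrow(w$agents), integer(1))
  expect_equal(counts[length(counts)], 32L)
  expect_true(all(diff(counts) >= 0))
  # length at division equals birth_length * exp(k * tau) (cv = 0)
  final <- tr[[length(tr)]]$agents
  expect_equal(final$birth_length,
               rep(final$birth_length[1], nrow(final)), tolerance = 1e-9)
})

test_that("sizer colony at cv=0 has all birth lengths at half the trigger", {
  cfg <- simulation_config(seed = 2, dt = 1 / 8, duration = 8,
                           model = homeostasis_model("sizer",
                                                     trigger_mean = 3.6,
                                                     trigger_cv = 0,
                                                     rate_mean = log(2),
                                                     rate_cv = 0))
  tr <- run_simulation(cfg)
  ag <- tr[[length(tr)]]$agents
  expect_equal(nrow(ag), 256L)  # 8 synchronous generations
  expect_true(all(abs(ag$birth_length - 1.8) < 1e-9))
})

test_that("duration zero yields only the initial world", {
  cfg <- simulation_config(seed = 3, duration = 0)
  tr <- run_simulation(cfg)
  expect_length(tr, 1L)
  expect_equal(tr[[1]]$time, 0)
})

test_that("division step conserves total cell length when angles are frozen", {
  cfg <- simulation_config(seed = 4, dt = 1 / 10, duration = 0, angle_sd = 0,
                           model = homeostasis_model("sizer",
                                                     trigger_mean = 3.6,
                                                     trigger_cv = 0.1,
                                                     rate_cv = 0.1))
  w <- init_world(cfg)
  for (s in 1:40) {
    grown <- grow(w$agents, cfg$dt)
    div <- should_divide(grown, cfg$model, w$time + cfg$dt)
    after <- divide_agents(grown, div, cfg$model, w$time + cfg$dt,
                           w$next_id, seed = cfg$seed, angle_sd = 0)
    expect_equal(sum(after$agents$length), sum(grown$length),
                 tolerance = 1e-9)
    w <- step_world(w, cfg)
  }
})

test_that("colony growth rate matches the mean doubling time", {
  model <- homeostasis_model("sizer", trigger_mean = 3.6, trigger_cv = 0.1,
                             rate_mean = log(2), rate_cv = 0.1)
  cfg <- simulation_config(seed = 5, dt = 1 / 12, duration = 9,
                           model = model, emit_every = 12L, max_cells = 400)
  tr <- run_simulation(cfg)
  counts <- vapply(tr, function(w) nrow(w$agents), numeric(1))
  times <- vapply(tr, function(w) w$time, numeric(1))
  keep <- counts >= 4 & counts <= 400
  expect_gte(sum(keep), 4)
  fit <- stats::lm(log2(counts[keep]) ~ times[keep])
  # mean doubling time is 1 h (rate ln 2): slope should be ~1 /h
  expect_lt(abs(unname(stats::coef(fit)[2]) - 1), 0.15)
})

test_that("identical config and seed reproduce the trajectory bit-exactly", {
  cfg <- simulation_config(seed = 10, dt = 1 / 10, duration = 3,
                           model = homeostasis_model())
  t1 <- run_simulation(cfg)
  t2 <- run_simulation(cfg)
  expect_identical(t1, t2)
  cfg2 <- cfg
  cfg2$seed <- 11L
  t3 <- run_simulation(cfg2)
  expect_false(identical(t1[[length(t1)]]$agents, t3[[length(t3)]]$agents))
})

test_that("emitters receive every emitted frame in order", {
  seen <- list()
  em <- function(world, frame) seen[[length(seen) + 1L]] <<- frame
  cfg <- simulation_config(seed = 1, dt = 0.1, duration = 1, emit_every = 5L)
  tr <- run_simulation(cfg, emitters = list(em))
  expect_equal(unlist(seen), seq_along(tr) - 1L)
})
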