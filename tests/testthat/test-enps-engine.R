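test_that("enzyme applicability follows the gating semantics", {
  cfg <- c(e = 256, x = 255, E = -0.1, ed1 = 0, ed2 = 1, ed3 = -256)

  p <- enps_program("x", c(x = 1), "m", enzyme = "e")
  expect_true(enps_applicable(p, cfg))  # 256 >= 255

  p32 <- enps_program("ed1 + 2 * ed2", c(x = 1), "m", enzyme = "E")
  expect_false(enps_applicable(p32, cfg))  # -0.1 < min(0, 1)

  p33 <- enps_program("0 * ed1 + 0 * ed3", c(x = 1), "m", enzyme = "E")
  expect_true(enps_applicable(p33, cfg))  # -0.1 >= min(0, -256)

  free <- enps_program("x + ed3", c(x = 1), "m")
  expect_true(enps_applicable(free, cfg))  # no enzyme: unconditional

  # boundary: enzyme equal to operand minimum separates ge from gt
  cfg2 <- c(e = 1, a = 1, b = 3, t = 0)
  pe <- enps_program("a + b", c(t = 1), "m", enzyme = "e",
                     comparison = "ge")
  pg <- enps_program("a + b", c(t = 1), "m", enzyme = "e",
                     comparison = "gt")
  expect_true(enps_applicable(pe, cfg2))
  expect_false(enps_applicable(pg, cfg2))

  # operand-free production: the operand minimum is taken to be 0
  k <- enps_program("0", c(x = 1), "m", enzyme = "e")
  expect_true(enps_applicable(k, c(e = 256, x = 0)))
  expect_false(enps_applicable(k, c(e = -1, x = 0)))

  expect_error(enps_applicable(p, c(x = 255)), "unresolved")
})

test_that("production evaluation is pure and matches hand values", {
  cfg <- c(ed1 = 0, ed2 = 1, gx = 3, gy = 4, t = 0)
  p <- enps_program("ed1 + 2 * ed2", c(t = 1), "m")
  expect_identical(enps_production_value(p, cfg), 2)

  q <- enps_program("sqrt(gx^2 + gy^2)", c(t = 1), "m")
  expect_identical(enps_production_value(q, cfg), 5)

  # zero-sum mask coefficients on a constant window evaluate to 0
  cc <- c(a = 7, b = 7, c = 7, d = 7, e = 7, f = 7, t = 0)
  z <- enps_program("a + 2 * b + c - d - 2 * e - f", c(t = 1), "m")
  expect_identical(enps_production_value(z, cc), 0)

  expect_error(
    enps_production_value(enps_program("sqrt(a)", c(t = 1), "m", name = "s"),
                          c(a = -1, t = 0)),
    "non-finite")
})

test_that("repartition distributes proportionally and conserves the amount", {
  expect_identical(enps_distribute(2, c(edg = 1, ED = 1)),
                   c(edg = 1, ED = 1))
  expect_identical(enps_distribute(0.6, c(g = 1, E = 1)),
                   c(g = 0.3, E = 0.3))
  expect_identical(enps_distribute(0, c(gx = 1)), c(gx = 0))
  # zero coefficient sum: legal only for zero amounts
  expect_identical(enps_distribute(0, c(gx = 0)), c(gx = 0))
  expect_error(enps_distribute(1, c(gx = 0)), "repartition error")
  expect_error(enps_distribute(1, numeric(0)), "at least one term")
  expect_error(enps_program("1", numeric(0), "m"), "at least one term")

  # conservation property on randomized protocols
  set.seed(42)
  for (k in 1:200) {
    nt <- sample(1:6, 1)
    coefs <- stats::setNames(stats::runif(nt, 0, 5), paste0("t", 1:nt))
    amount <- stats::runif(1, -100, 100)
    inc <- enps_distribute(amount, coefs)
    expect_lt(abs(sum(inc) - amount), 1e-9 * max(1, abs(amount)))
  }
})

test_that("a step applies all applicable rules against the pre-step state", {
  mk <- function(consumption) {
    sys <- enps_system(
      list(list(label = "m", parent = NA, variables = c(a = 3, b = 0))),
      list(enps_program("2 * a", c(b = 1), "m", name = "r")))
    enps_step(sys, enps_init(sys), enps_policy(consumption = consumption))
  }
  st <- mk("non-consuming")
  expect_identical(st$config$values, c(a = 3, b = 6))
  expect_identical(st$fired, 1L)
  st2 <- mk("consuming")
  expect_identical(st2$config$values, c(a = 0, b = 6))

  # targets are reset before increments (assignment semantics), and two
  # rules hitting one target sum their shares
  sys <- enps_system(
    list(list(label = "m", parent = NA, variables = c(a = 2, t = 99))),
    list(enps_program("a", c(t = 1), "m"),
         enps_program("3 * a", c(t = 1), "m")))
  st3 <- enps_step(sys, enps_init(sys), enps_policy())
  expect_identical(st3$config$values[["t"]], 8)

  # no applicable rule: unchanged values, fired 0
  sys0 <- enps_system(
    list(list(label = "m", parent = NA, variables = c(a = 1, e = -10),
              enzymes = "e")),
    list(enps_program("a", c(a = 1), "m", enzyme = "e")))
  st0 <- enps_step(sys0, enps_init(sys0), enps_policy())
  expect_identical(st0$fired, 0L)
  expect_identical(st0$config$values, c(a = 1, e = -10))
  expect_identical(st0$config$step_index, 1L)
})

test_that("membrane and group selection narrow the firing set", {
  sys <- enps_system(
    list(list(label = "skin", parent = NA, variables = c(a = 1, b = 0)),
         list(label = "in", parent = "skin", variables = c(c = 0))),
    list(enps_program("a", c(b = 1), "skin", name = "s", group = "g1"),
         enps_program("a", c(c = 1), "in", name = "i", group = "g2")))
  st <- enps_step(sys, enps_init(sys), enps_policy(), membranes = "in")
  expect_identical(st$fired_programs, "i")
  st2 <- enps_step(sys, enps_init(sys), enps_policy(), groups = "g1")
  expect_identical(st2$fired_programs, "s")
  expect_error(enps_step(sys, enps_init(sys), enps_policy(),
                         membranes = "nope"), "unknown membrane")
})

test_that("runs halt on the halt variable, on silence, or at a fixed point", {
  # zero-program system: nothing ever fires
  sys0 <- enps_system(list(list(label = "m", parent = NA,
                                variables = c(a = 1))))
  r0 <- enps_run(sys0, enps_policy(mode = "parallel"))
  expect_true(r0$halted)
  expect_identical(sum(r0$fired), 0L)

  # identity rule a -> a: values never change; without fixed-point halting
  # this is non-halting, with it the run stops after two identical states
  mkid <- function(...) {
    sys <- enps_system(
      list(list(label = "m", parent = NA, variables = c(a = 5))),
      list(enps_program("a", c(a = 1), "m", name = "id")))
    enps_run(sys, enps_policy(mode = "parallel", ...))
  }
  expect_error(mkid(max_steps = 10), class = "enps_nonhalting_error")
  rfix <- mkid(max_steps = 10, halt_on_fixpoint = TRUE)
  expect_true(rfix$halted)
  expect_identical(rfix$config$values[["a"]], 5)

  # halt variable threshold
  sys <- enps_system(
    list(list(label = "m", parent = NA, variables = c(a = 0, stop = 0))),
    list(enps_program("a + 1", c(a = 1), "m"),
         enps_program("1", c(stop = 1), "m")))
  r <- enps_run(sys, enps_policy(mode = "parallel", halt_variable = "stop"))
  expect_true(r$halted)
  expect_identical(r$steps, 1L)
  expect_error(
    enps_run(sys, enps_policy(mode = "parallel", halt_variable = "gone")),
    "not declared")

  # staged mode requires a schedule
  expect_error(enps_run(sys, enps_policy(mode = "staged")), "schedule")
})

test_that("traces are recorded and runs are deterministic", {
  sys <- random_system(7)
  pol <- enps_policy(mode = "parallel", max_steps = 4,
                     halt_on_fixpoint = TRUE)
  run_once <- function() tryCatch(
    enps_run(sys, pol, trace = TRUE),
    enps_nonhalting_error = function(e) NULL)
  a <- run_once(); b <- run_once()
  if (!is.null(a)) {
    expect_identical(a$trace, b$trace)
    expect_identical(names(a$trace), c("step", "variable", "value"))
    expect_identical(unique(a$trace$step), 0:a$steps)
  } else {
    expect_null(b)
  }
})

test_that("one engine step equals the brute-force reference on random systems", {
  for (seed in 1:40) {
    sys <- random_system(seed)
    for (consumption in c("non-consuming", "consuming")) {
      got <- enps_step(sys, enps_init(sys),
                       enps_policy(consumption = consumption))
      want <- brute_step(sys, sys$initial_values, consumption)
      expect_equal(got$config$values, want$values, tolerance = 1e-12,
                   label = sprintf("seed %d, %s values", seed, consumption))
      expect_identical(got$fired, want$fired)
    }
  }
})

test_that("a gated-out rule never contributes to any variable", {
  # enzyme e = -10 sits below min(a, b) = 1 forever, so target t must keep
  # receiving only the unconditional rule's contribution across the trace
  sys <- enps_system(
    list(list(label = "m", parent = NA,
              variables = c(a = 1, b = 2, e = -10, t = 0),
              enzymes = "e")),
    list(enps_program("100 * a", c(t = 1), "m", enzyme = "e",
                      name = "gated"),
         enps_program("a + b", c(t = 1), "m", name = "open")))
  r <- enps_run(sys, enps_policy(mode = "parallel", max_steps = 3,
                                 halt_on_fixpoint = TRUE), trace = TRUE)
  tvals <- r$trace$value[r$trace$variable == "t" & r$trace$step > 0]
  expect_true(all(tvals == 3))  # never 103 or 100
})
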