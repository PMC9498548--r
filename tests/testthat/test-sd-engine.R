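# Generic stock-and-flow engine: validation, auxiliary ordering, Euler
# stepping with non-negativity limiting, simulation and mass balance.

test_that("validation accepts a well-formed model and reports each broken invariant", {
  expect_equal(nrow(validate_sd_model(chain_model())), 0L)

  dangling <- sd_model(
    stocks = list(sd_stock("A", 10)),
    flows = list(sd_flow("f", "A", "Ghost", rate = "r1")),
    auxiliaries = list(sd_aux("r1", "A * 0.1")))
  rep <- validate_sd_model(dangling)
  expect_equal(rep$code, "dangling_endpoint")
  expect_match(rep$message, "Ghost")

  cyclic <- sd_model(
    stocks = list(sd_stock("A", 10)),
    flows = list(),
    auxiliaries = list(sd_aux("a", "b + 1"), sd_aux("b", "a + 1")))
  rep <- validate_sd_model(cyclic)
  expect_true("aux_cycle" %in% rep$code)

  messy <- sd_model(
    stocks = list(sd_stock("A", -5), sd_stock("A", 1)),
    flows = list(sd_flow("f", "A", BOUNDARY, rate = "nope")),
    auxiliaries = list(sd_aux("x", "unknown_name * 2")))
  rep <- validate_sd_model(messy)
  expect_setequal(rep$code, c("duplicate_name", "negative_initial",
                              "unresolved_rate", "unknown_symbol"))
})

test_that("auxiliaries are ordered after their dependencies", {
  indep <- sd_model(list(), list(),
                    list(sd_aux("x", "1"), sd_aux("y", "2")))
  expect_setequal(order_auxiliaries(indep), c("x", "y"))

  dep <- sd_model(list(), list(),
                  list(sd_aux("b", "a * 2"), sd_aux("a", "3")))
  ord <- order_auxiliaries(dep)
  expect_true(which(ord == "a") < which(ord == "b"))

  expect_error(order_auxiliaries(sd_model(list(), list(),
    list(sd_aux("a", "b"), sd_aux("b", "a")))), "cyclic")
})

test_that("a 5-auxiliary chain declared in reverse evaluates as sequential substitution", {
  # oracle by hand substitution at p = 2: a1=3, a2=6, a3=9, a4=27, a5=21
  spec <- sd_model(
    stocks = list(), flows = list(),
    auxiliaries = list(sd_aux("a5", "a4 - a2"), sd_aux("a4", "a3 * a1"),
                       sd_aux("a3", "a2 + a1"), sd_aux("a2", "a1 * 2"),
                       sd_aux("a1", "p + 1")),
    parameters = c(p = 2))
  ord <- order_auxiliaries(spec)
  deps <- list(a1 = character(), a2 = "a1", a3 = c("a1", "a2"),
               a4 = c("a1", "a3"), a5 = c("a2", "a4"))
  for (nm in names(deps)) {
    expect_true(all(match(deps[[nm]], ord) < match(nm, ord)), info = nm)
  }
  env <- new.env(parent = baseenv())
  assign("p", 2, envir = env)
  exprs <- setNames(lapply(spec$auxiliaries, `[[`, "parsed"),
                    vapply(spec$auxiliaries, `[[`, "", "name"))
  for (nm in ord) assign(nm, eval(exprs[[nm]], env), envir = env)
  expect_equal(get("a5", env), 21)
  expect_equal(get("a4", env), 27)
})

test_that("one Euler step applies dt * (inflows - outflows) and floors at zero", {
  m <- decay_model(s0 = 1000, r = 10)
  res <- sd_step(m, c(S = 1000), t = 0, dt = 1)
  expect_equal(res$state[["S"]], 900)

  res0 <- sd_step(m, c(S = 1000), t = 0, dt = 1, parameters = c(r = 0))
  expect_equal(res0$state[["S"]], 1000)

  # outflow demand 20/yr on a stock of 10: proportionally limited to 10
  res_floor <- sd_step(decay_model(s0 = 10, r = 200), c(S = 10), t = 0, dt = 1)
  expect_equal(res_floor$state[["S"]], 0)
  expect_equal(res_floor$flows[["decay"]], 10)

  bad <- sd_model(
    stocks = list(sd_stock("A", 1)),
    flows = list(sd_flow("boom", "A", BOUNDARY, rate = "r1")),
    auxiliaries = list(sd_aux("r1", "1 / 0 - 1 / 0")))
  expect_error(sd_step(bad, c(A = 1), 0, 1), "boom")
})

test_that("linear decay matches the closed form within 1% at dt = 1/64", {
  traj <- simulate(decay_model(1000, 10), config = sim_config(0, 12, 1 / 64))
  expect_lt(abs(endpoint(traj, "S", 12) - 1000 * exp(-1.2)) /
              (1000 * exp(-1.2)), 0.01)
  # deSolve integration of the same ODE as an independent numeric oracle
  ode <- deSolve::lsoda(c(S = 1000), times = c(0, 12),
                        func = function(t, y, p) list(-0.10 * y),
                        parms = NULL, rtol = 1e-10, atol = 1e-10)
  expect_equal(endpoint(traj, "S", 12), unname(ode[2, "S"]), tolerance = 0.01)
})

test_that("Euler endpoint error shrinks linearly as dt is halved", {
  exact <- 1000 * exp(-1.2)
  errs <- vapply(c(1 / 16, 1 / 32, 1 / 64), function(dt) {
    abs(endpoint(simulate(decay_model(1000, 10),
                          config = sim_config(0, 12, dt)), "S", 12) - exact)
  }, numeric(1L))
  expect_true(all(diff(errs) < 0))
  ratios <- errs[-1] / errs[-length(errs)]
  expect_true(all(abs(ratios - 0.5) < 0.1))
})

test_that("closed models conserve total mass and runs are bitwise deterministic", {
  m <- chain_model()
  cfg <- sim_config(0, 10, 1 / 8)
  traj <- simulate(m, config = cfg)
  total <- rowSums(traj$stocks)
  expect_lt(max(abs(total - total[1]) / total[1]), 1e-9)
  expect_identical(traj, simulate(m, config = cfg))
})

test_that("mass balance accounts for boundary flows step by step", {
  m <- chain_model()
  traj <- simulate(m, config = sim_config(0, 5, 0.5))
  expect_lt(max(abs(attr(mass_balance(traj), "relative"))), 1e-9)

  inflow <- sd_model(
    stocks = list(sd_stock("A", 0)),
    flows = list(sd_flow("fill", BOUNDARY, "A", rate = "fill_rate")),
    auxiliaries = list(sd_aux("fill_rate", "5")))
  tr <- simulate(inflow, config = sim_config(0, 4, 1))
  expect_equal(diff(rowSums(tr$stocks)), rep(5, 4))
  expect_lt(max(abs(mass_balance(tr))), 1e-9)

  expect_error(mass_balance(traj, decay_model()), "does not match")
})
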