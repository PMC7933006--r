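test_that("one-species toy model matches the closed-form steady state", {
  # source k0 = 1 into S, MM consumption Vmax = 2, Km = 1: S* = Km*k0/(Vmax-k0)
  m <- toy_source_sink(k0 = 1, vmax = 2, km = 1)
  for (meth in c("relaxation", "hybrid")) {
    ss <- steady_state(m, method = meth)
    expect_true(ss$converged)
    expect_equal(ss$concentrations[["S"]], 1, tolerance = 1e-8)
    expect_equal(ss$fluxes[["R_out"]], 1, tolerance = 1e-8)
  }
})

test_that("consumption capacity below inflow yields no steady state", {
  m <- toy_source_sink(k0 = 1, vmax = 0.5, km = 1)
  ss <- steady_state(m, method = "relaxation", t_max = 100)
  expect_false(ss$converged)
  # S keeps growing at the horizon: net production stays ~ k0 - vmax = 0.5
  expect_gt(ss$residual_norm, 0.4)
  expect_gt(ss$concentrations[["S"]], 10)
})

test_that("the default model's steady state is independent of the initial state", {
  m <- build_trp_model()
  tol <- 1e-9
  ref <- steady_state(m, tol = tol)
  expect_true(ref$converged)
  set.seed(42)
  dyn <- dynamic_species(m)
  rand_init <- stats::setNames(runif(length(dyn), 0.01, 3), dyn)
  alt <- steady_state(m, init = rand_init, tol = tol)
  expect_true(alt$converged)
  expect_equal(alt$concentrations, ref$concentrations, tolerance = 10 * tol)
})

test_that("Newton refinement converges on and fixes the relaxation root", {
  m <- toy_source_sink()
  relax <- steady_state(m, method = "relaxation")
  nw <- refine_newton(m, guess = relax$concentrations)
  expect_true(nw$converged)
  expect_lte(nw$diagnostics$iterations, 3)
  expect_equal(nw$concentrations, relax$concentrations, tolerance = 1e-8)

  exact <- stats::setNames(1, "S")
  at_root <- refine_newton(m, guess = exact)
  expect_true(at_root$converged)
  expect_equal(at_root$diagnostics$iterations, 0)
  expect_lte(at_root$residual_norm, 1e-9)
})

test_that("a clearance-only network has the all-zero root", {
  species <- data.frame(id = c("X", "A", "B"),
                        display_name = c("anchor", "A", "B"),
                        compartment = "intracellular",
                        is_boundary = c(TRUE, FALSE, FALSE),
                        initial_concentration = c(1, 0, 0),
                        stringsAsFactors = FALSE)
  reactions <- list(
    RA = list(id = "RA", substrates = c(A = 1), products = numeric(0),
              rate_law = "first_order_clearance"),
    RB = list(id = "RB", substrates = c(B = 1), products = numeric(0),
              rate_law = "first_order_clearance"))
  m <- trp_model(species, reactions,
                 trp_params(list(RA = list(kclear = 1),
                                 RB = list(kclear = 2))))
  nw <- refine_newton(m, guess = c(A = 5, B = 3))
  expect_true(nw$converged)
  expect_equal(unname(nw$concentrations), c(0, 0), tolerance = 1e-9)
})

test_that("fluxes at steady state satisfy the stoichiometric balances", {
  tc <- toy_chain()
  ss <- steady_state(tc)
  expect_true(ss$converged)
  # series conservation along the chain
  expect_equal(ss$fluxes[["R1"]], ss$fluxes[["R2"]], tolerance = 1e-9)
  expect_equal(ss$fluxes[["R2"]], ss$fluxes[["R3"]], tolerance = 1e-9)

  m <- build_trp_model()
  ss <- steady_state(m)
  v <- compute_fluxes(m, steady = ss)
  expect_lt(attr(v, "conservation_residual"), 1e-9)
  # Kyn node balance: TDO2 influx = KAT + KMO + KYNU_a + antiport export
  kyn_coupling <- m$reactions$R_LAT1$substrates[["Kyn"]]
  export <- kyn_coupling * (v[["R_LAT1"]] + v[["R_LAT2"]])
  expect_equal(v[["R_TDO2"]],
               v[["R_KAT"]] + v[["R_KMO"]] + v[["R_KYNU_a"]] + export,
               tolerance = 1e-9)
})

test_that("relaxation and Newton agree on randomized parameterizations", {
  m <- build_trp_model()
  set.seed(11)
  for (i in 1:3) {
    p <- m$params
    for (id in names(p$reactions)) {
      r <- p$reactions[[id]]
      if (!is.null(r$vmax)) r$vmax <- r$vmax * exp(rnorm(1, 0, 0.2))
      if (!is.null(r$km)) r$km <- r$km * exp(rnorm(length(r$km), 0, 0.2))
      p$reactions[[id]] <- r
    }
    relax <- steady_state(m, p, method = "relaxation")
    expect_true(relax$converged)
    guess <- relax$concentrations * exp(rnorm(length(relax$concentrations),
                                              0, 0.1))
    nw <- refine_newton(m, p, guess)
    expect_true(nw$converged)
    expect_equal(nw$concentrations, relax$concentrations, tolerance = 1e-6)
  }
})

test_that("steady-state flux through TDO2 is monotone in its capacity", {
  m <- build_trp_model()
  vm <- m$params$reactions$R_TDO2$vmax
  sweep <- vm * 10^seq(-1, 1, length.out = 7)  # 100-fold range
  flux <- vapply(sweep, function(v) {
    p <- m$params
    p$reactions$R_TDO2$vmax <- v
    ss <- steady_state(m, p)
    expect_true(ss$converged)
    ss$fluxes[["R_TDO2"]]
  }, numeric(1))
  expect_true(all(diff(flux) >= -1e-9))
})

test_that("global capacity scaling moves fluxes but not concentrations", {
  m <- build_trp_model()
  ref <- steady_state(m)
  for (lam in c(0.5, 2)) {
    p <- m$params
    for (id in names(p$reactions)) {
      if (!is.null(p$reactions[[id]]$vmax))
        p$reactions[[id]]$vmax <- p$reactions[[id]]$vmax * lam
      if (!is.null(p$reactions[[id]]$kclear))
        p$reactions[[id]]$kclear <- p$reactions[[id]]$kclear * lam
    }
    ss <- steady_state(m, p)
    expect_true(ss$converged)
    expect_equal(ss$concentrations, ref$concentrations, tolerance = 1e-6)
    expect_equal(ss$fluxes, lam * ref$fluxes, tolerance = 1e-6)
  }
})

test_that("steady-state results serialize to TSV and JSON", {
  ss <- steady_state(toy_source_sink())
  f <- tempfile(fileext = ".tsv")
  write_steady_state(ss, f)
  back <- read_steady_state(f)
  expect_setequal(back$kind, c("concentration", "flux"))
  expect_equal(back$value[back$id == "S"], ss$concentrations[["S"]],
               tolerance = 1e-11)
  fj <- tempfile(fileext = ".json")
  write_steady_state(ss, fj, format = "json")
  parsed <- jsonlite::read_json(fj, simplifyVector = TRUE)
  expect_true(parsed$converged)
  expect_equal(parsed$method, ss$method)
})
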