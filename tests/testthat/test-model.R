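test_that("default hepatocyte model has the expected network structure", {
  m <- build_trp_model()
  non_clear <- Filter(function(r) r$rate_law != "first_order_clearance",
                      m$reactions)
  expect_length(non_clear, 15L)  # 9 enzymes + 2 transporters + branch steps
  genes <- unique(na.omit(vapply(m$reactions, `[[`, "", "gene")))
  expect_setequal(genes, c("Slc7a5", "Slc7a8", "Tdo2", "Kyat1", "Kmo",
                           "Kynu", "Haao", "Qprt", "Ddc", "Tph1", "Inmt",
                           "Il4i1"))
  expect_true(m$species["Trp_ext", "is_boundary"])
  expect_equal(m$species["Trp_ext", "initial_concentration"], 10)
  expect_false(anyDuplicated(m$species$id) > 0)
})

test_that("branch toggles remove their species and reactions cleanly", {
  m <- build_trp_model(branches = c(il4i1 = FALSE))
  expect_false("I3P" %in% m$species$id)
  expect_false("R_IL4I1" %in% names(m$reactions))
  expect_false("R_clr_I3P" %in% names(m$reactions))
  full <- build_trp_model()
  kept <- setdiff(names(full$reactions), c("R_IL4I1", "R_clr_I3P"))
  expect_identical(names(m$reactions), kept)
  expect_error(build_trp_model(branches = c(nadir = FALSE)),
               "unknown branch")
})

test_that("model validation catches structural violations", {
  m <- build_trp_model()
  bad <- m
  bad$reactions$R_TDO2$substrates <- c(Nonexistent = 1)
  expect_error(validate_trp_model(bad), "R_TDO2.*Nonexistent")
  bad2 <- m
  bad2$reactions$R_LAT1$substrates <- c(Trp_ext = 1)
  expect_error(validate_trp_model(bad2), "2 substrates")
  bad3 <- m
  bad3$species <- rbind(bad3$species, bad3$species["Trp", ])
  expect_error(validate_trp_model(bad3), "duplicate")
})

test_that("stoichiometric matrix excludes boundary species and encodes the antiport coupling", {
  tc <- toy_chain()
  N <- stoichiometric_matrix(tc)
  expect_identical(rownames(N), c("A", "B", "C"))
  expect_equal(unname(N), rbind(c(-1, 0, 0), c(1, -1, 0), c(0, 1, -1)))

  m <- build_trp_model(kyn_coupling = 0.5)
  N <- stoichiometric_matrix(m)
  expect_false(any(c("Trp_ext", "Kyn_ext") %in% rownames(N)))
  expect_equal(N["Trp", "R_LAT1"], 1)
  expect_equal(N["Kyn", "R_LAT1"], -0.5)
  clear_cols <- grep("^R_clr_", colnames(N), value = TRUE)
  for (j in clear_cols) {
    expect_equal(sum(N[, j] != 0), 1)
    expect_equal(sum(N[, j]), -1)
  }
})

test_that("rate laws obey their defining identities", {
  m <- build_trp_model()
  conc <- full_concs(m, Trp = 2)  # Km of TDO2
  v <- evaluate_rates(m, conc)
  expect_equal(v[["R_TDO2"]], m$params$reactions$R_TDO2$vmax / 2)

  zero <- full_concs(m)
  zero[c("Trp_ext", "Kyn_ext", "Trp")] <- 0
  expect_true(all(evaluate_rates(m, zero) == 0))

  # antiport exchange symmetry: S_out*C_in = S_in*C_out with keq_bias 1
  conc2 <- full_concs(m, Trp = 5, Kyn = 0.005)
  # Trp_ext=10, Kyn_ext=0.01: 10*0.005 == 5*0.01
  v2 <- evaluate_rates(m, conc2)
  expect_equal(v2[["R_LAT1"]], 0)
  expect_equal(v2[["R_LAT2"]], 0)

  expect_error(evaluate_rates(m, full_concs(m, Trp = -1)), "negative")
})

test_that("rates are homogeneous in Vmax and non-negative for irreversible laws", {
  m <- build_trp_model()
  set.seed(7)
  for (i in 1:5) {
    conc <- full_concs(m)
    dyn <- dynamic_species(m)
    conc[dyn] <- runif(length(dyn), 0, 3)
    v1 <- evaluate_rates(m, conc)
    p2 <- m$params
    for (id in names(p2$reactions))
      if (!is.null(p2$reactions[[id]]$vmax))
        p2$reactions[[id]]$vmax <- 2 * p2$reactions[[id]]$vmax
    v2 <- evaluate_rates(m, conc, p2)
    has_vmax <- !vapply(m$reactions, function(r)
      r$rate_law == "first_order_clearance", logical(1))
    expect_equal(v2[has_vmax], 2 * v1[has_vmax])
    irrev <- vapply(m$reactions, function(r)
      r$rate_law != "antiport_exchange", logical(1))
    expect_true(all(v1[irrev] >= 0))
    # derivative is exactly N %*% v
    expect_equal(state_derivative(m, conc),
                 drop(stoichiometric_matrix(m) %*% v1))
  }
})

test_that("oxygen term reduces to the plain rates in the Km_O2 -> 0 limit", {
  m_off <- build_trp_model(oxygen_term = FALSE)
  m_on <- build_trp_model(oxygen_term = TRUE, oxygen_level = 1)
  for (id in names(m_on$params$reactions))
    if (!is.null(m_on$params$reactions[[id]]$km_oxygen))
      m_on$params$reactions[[id]]$km_oxygen <- 1e-14
  conc <- full_concs(m_off, Trp = 1.5, Kyn = 0.4, HAA3 = 0.7)
  expect_equal(evaluate_rates(m_on, conc, m_on$params),
               evaluate_rates(m_off, conc, m_off$params),
               tolerance = 1e-12)
  # at finite Km_O2 oxygen-dependent reactions are attenuated, others not
  m_on2 <- build_trp_model(oxygen_term = TRUE, oxygen_level = 0.5)
  v_on <- evaluate_rates(m_on2, conc, m_on2$params)
  v_off <- evaluate_rates(m_off, conc, m_off$params)
  expect_lt(v_on[["R_TDO2"]], v_off[["R_TDO2"]])
  expect_equal(v_on[["R_KAT"]], v_off[["R_KAT"]])
})

test_that("parameter validation rejects non-positive constants and bad oxygen levels", {
  expect_error(trp_params(list(R1 = list(vmax = -1, km = c(A = 1)))), "vmax")
  expect_error(trp_params(list(R1 = list(vmax = 1, km = c(A = 0)))), "km")
  expect_error(trp_params(list(), oxygen_level = 1.5), "oxygen_level")
  p <- trp_params(list(R1 = list(vmax = 1, km = c(A = 1))))
  expect_s3_class(p, "trp_params")
})

test_that("parameter YAML round-trips", {
  m <- build_trp_model()
  f <- tempfile(fileext = ".yaml")
  write_parameters(m$params, f)
  p2 <- read_parameters(f)
  expect_equal(p2$reactions, m$params$reactions)
  expect_equal(p2$oxygen_level, m$params$oxygen_level)
})
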