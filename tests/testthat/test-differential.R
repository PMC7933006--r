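# Minimal stand-in replicates: steady-state-like objects with prescribed
# flux/concentration values, so the statistics can be tested in isolation.
fake_rep <- function(flux, conc = c(M = 1), converged = TRUE) {
  structure(list(concentrations = conc, fluxes = flux,
                 converged = converged, residual_norm = 0,
                 method = "newton", diagnostics = list()),
            class = "trp_steady_state")
}
reps <- function(values, conc_values = NULL) {
  lapply(seq_along(values), function(i)
    fake_rep(c(J = values[i]),
             c(M = if (is.null(conc_values)) 1 else conc_values[i])))
}

test_that("the worked t-test example matches an independent t-distribution oracle", {
  A <- reps(c(1, 2, 3)); B <- reps(c(4, 5, 6))
  tab <- compare_conditions(A, B)
  row <- tab[tab$quantity == "J", ]
  expect_equal(row$mean_A, 2)
  expect_equal(row$mean_B, 5)
  expect_equal(row$fold_change, 2.5)
  expect_equal(row$sem_A, 1 / sqrt(3))

  # independent oracle: Welch statistic + t CDF by hand
  se <- sqrt(1 / 3 + 1 / 3)           # both sample variances are 1, n = 3
  tstat <- (5 - 2) / se               # 3.674 on 4 df (Welch df = 4 here)
  df <- (1 / 3 + 1 / 3)^2 / ((1 / 3)^2 / 2 + (1 / 3)^2 / 2)
  p_oracle <- 2 * stats::pt(-abs(tstat), df)
  expect_equal(tstat, 3.674, tolerance = 1e-3)
  expect_equal(df, 4)
  expect_equal(p_oracle, 0.0213, tolerance = 2e-3)
  expect_equal(row$p_welch, p_oracle, tolerance = 1e-6)
  expect_equal(row$p_student, p_oracle, tolerance = 1e-6)  # equal variances
  expect_identical(row$significance_code, "*")
  expect_identical(row$direction, "up")
})

test_that("identical conditions give fold 1 and ns", {
  A <- reps(c(1.2, 1.5, 1.8))
  tab <- compare_conditions(A, A)
  expect_equal(tab$fold_change, rep(1, nrow(tab)))
  expect_true(all(tab$significance_code == "ns"))
  expect_true(all(tab$direction == "flat"))
})

test_that("significance codes follow the star thresholds", {
  expect_identical(significance_code(c(0.2, 0.05, 0.04, 0.01, 0.0007,
                                       0.0001, 0.00005, NA)),
                   c("ns", "*", "*", "**", "***", "****", "****",
                     NA_character_))
})

test_that("swapping conditions inverts fold changes and preserves p-values", {
  set.seed(5)
  A <- reps(rlnorm(4), rlnorm(4)); B <- reps(rlnorm(4, 0.5), rlnorm(4, 1))
  ab <- compare_conditions(A, B)
  ba <- compare_conditions(B, A)
  expect_equal(ba$fold_change, 1 / ab$fold_change)
  expect_equal(ba$p_welch, ab$p_welch)
  expect_equal(ba$p_student, ab$p_student)
})

test_that("p-values are invariant under common rescaling of both conditions", {
  A <- reps(c(1, 2, 3)); B <- reps(c(2, 4, 5))
  A2 <- reps(c(1, 2, 3) * 100); B2 <- reps(c(2, 4, 5) * 100)
  expect_equal(compare_conditions(A2, B2)$p_welch,
               compare_conditions(A, B)$p_welch)
})

test_that("non-converged replicates are excluded; too few make quantities untestable", {
  A <- reps(c(1, 2, 3)); B <- reps(c(4, 5, 6))
  B[[3]]$converged <- FALSE
  expect_warning(tab <- compare_conditions(A, B), "non-converged")
  expect_equal(tab$mean_B[tab$quantity == "J"], 4.5)

  B[[2]]$converged <- FALSE
  expect_warning(expect_warning(tab2 <- compare_conditions(A, B),
                                "non-converged"),
                 "untestable")
  expect_true(all(is.na(tab2$p_value)))
  expect_true(all(tab2$direction == "flat"))
})

test_that("replicate-identical (noise-free) data get the degenerate-limit p-values", {
  A <- reps(c(2, 2, 2)); B <- reps(c(3, 3, 3))
  tab <- compare_conditions(A, B)
  expect_equal(tab$p_welch[tab$quantity == "J"], 0)
  same <- compare_conditions(A, A)
  expect_equal(same$p_welch[same$quantity == "J"], 1)
})

test_that("sign_pattern reports mismatches and passes vacuously on empty tables", {
  A <- reps(c(1, 2, 3), c(5, 6, 7)); B <- reps(c(4, 5, 6), c(1, 2, 3))
  tab <- compare_conditions(A, B)
  rep_ok <- sign_pattern(tab, c(J = "up", M = "down"))
  expect_true(attr(rep_ok, "overall_pass"))
  rep_bad <- sign_pattern(tab, c(J = "up", M = "up"))
  expect_false(attr(rep_bad, "overall_pass"))
  expect_identical(rep_bad$quantity[!rep_bad$pass], "M")

  empty <- tab[0, ]
  class(empty) <- class(tab)
  expect_warning(rep_vac <- sign_pattern(empty, c(J = "up")), "vacuously")
  expect_true(attr(rep_vac, "overall_pass"))

  expect_error(sign_pattern(tab, c(Nope = "up")), "unknown quantities")
})

test_that("the BH column adjusts monotonically without touching the codes", {
  A <- reps(c(1, 2, 3), c(5, 6, 7)); B <- reps(c(4, 5, 6), c(1, 2, 3))
  tab <- compare_conditions(A, B)
  expect_true(all(tab$p_adj_BH >= tab$p_value))
  expect_identical(tab$significance_code, significance_code(tab$p_value))
})
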