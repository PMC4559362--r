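p_default <- kinetic_params()

zero_input <- c(IFNg = 0, IL12 = 0, IL6 = 0, TGFb = 0)
tgfb_only <- c(IFNg = 0, IL12 = 0, IL6 = 0, TGFb = 1)
ifng_only <- c(IFNg = 1, IL12 = 0, IL6 = 0, TGFb = 0)
th17_input <- c(IFNg = 0, IL12 = 0, IL6 = 1, TGFb = 1)

zero_state <- c(Tbet = 0, RORgt = 0, FOXP3 = 0, IL17 = 0, IFNg_out = 0)

test_that("the origin is an absorbing fixed point without stimulation", {
  rates <- diff_rates(zero_state, zero_input, p_default)
  expect_equal(unname(rates), rep(0, 5))
})

test_that("TGFb alone drives only the Treg regulator from rest", {
  rates <- diff_rates(zero_state, tgfb_only, p_default)
  expect_equal(rates[["FOXP3"]], 16 / 17, tolerance = 1e-12)
  expect_equal(unname(rates[c("Tbet", "RORgt", "IL17", "IFNg_out")]),
               rep(0, 4))
})

test_that("closed-form equilibria are stationary points of the rates", {
  treg_eq <- zero_state
  treg_eq[["FOXP3"]] <- 16 / 17
  expect_lt(max(abs(diff_rates(treg_eq, tgfb_only, p_default))), 1e-12)

  th1_eq <- zero_state
  th1_eq[["Tbet"]] <- 16 / 17
  th1_eq[["IFNg_out"]] <- hill_activation(16 / 17, K = 0.3, n = 2)
  expect_lt(max(abs(diff_rates(th1_eq, ifng_only, p_default))), 1e-12)
})

test_that("diff_rates rejects invalid states", {
  bad <- zero_state
  bad[["Tbet"]] <- -0.1
  expect_error(diff_rates(bad, zero_input, p_default), "nonnegative")
  expect_error(
    diff_rates(zero_state, c(IFNg = 1.5, IL12 = 0, IL6 = 0, TGFb = 0),
               p_default),
    "\\[0, 1\\]"
  )
})

test_that("steady states match closed forms for decoupled stimulations", {
  ss <- steady_state(tibble::tibble(
    IFNg = c(0, 0, 1), IL12 = 0, IL6 = 0, TGFb = c(0, 1, 0)
  ))
  # no stimulation: all zero
  expect_equal(unname(unlist(ss[1, ])), rep(0, 5))
  # TGFb only: FOXP3 = 16/17, everything else stays at zero
  expect_equal(ss$FOXP3[2], 16 / 17, tolerance = 1e-7)
  expect_equal(ss$IL17[2] + ss$RORgt[2] + ss$Tbet[2] + ss$IFNg_out[2], 0,
               tolerance = 1e-7)
  # IFNg only: Tbet = 16/17 and the secreted IFNg follows its Hill curve
  expect_equal(ss$Tbet[3], 16 / 17, tolerance = 1e-7)
  expect_equal(ss$IFNg_out[3], hill_activation(16 / 17, K = 0.3, n = 2),
               tolerance = 1e-6)
})

test_that("TGFb + IL-6 flips the outcome from Treg to Th17", {
  ss <- steady_state(tibble::as_tibble(as.list(th17_input)))
  expect_gt(ss$IL17[1], 0.8)
  expect_lt(ss$FOXP3[1], 0.06)
  oracle <- fixed_point_oracle(th17_input)
  expect_equal(unlist(ss[1, ]), oracle, tolerance = 1e-6)
})

test_that("steady_state is deterministic", {
  inp <- tibble::tibble(IFNg = 0.5, IL12 = 0.25, IL6 = 0.75, TGFb = 0.5)
  expect_identical(steady_state(inp), steady_state(inp))
})

test_that("non-convergence is reported with the residual", {
  p_short <- kinetic_params(t_max = 0.01)
  expect_error(
    steady_state(tibble::as_tibble(as.list(tgfb_only)), p_short),
    "residual"
  )
})

test_that("steady states are bounded and phenotype dominance holds", {
  d <- grid_dataset_raw()
  Y <- as.matrix(tibble::as_tibble(d)[c("IL17", "RORgt", "IFNg_out",
                                        "Tbet", "FOXP3")])
  expect_true(all(Y >= 0 & Y <= 1 + 1e-9)) # v/delta = 1
  row_of <- function(IFNg, IL12, IL6, TGFb) {
    which(d$IFNg == IFNg & d$IL12 == IL12 & d$IL6 == IL6 & d$TGFb == TGFb)
  }
  treg <- Y[row_of(0, 0, 0, 1), ]
  expect_true(all(treg[["FOXP3"]] > treg[setdiff(names(treg), "FOXP3")]))
  th17 <- Y[row_of(0, 0, 1, 1), ]
  expect_gt(th17[["IL17"]], th17[["FOXP3"]])
  for (r in list(row_of(1, 0, 0, 0), row_of(0, 1, 0, 0))) {
    expect_true(Y[r, "Tbet"] > Y[r, "RORgt"] &&
                  Y[r, "Tbet"] > Y[r, "FOXP3"])
  }
})

test_that("steady-state FOXP3 is non-increasing in IL-6 everywhere", {
  d <- tibble::as_tibble(grid_dataset_raw())
  worst <- d |>
    dplyr::arrange(.data$IFNg, .data$IL12, .data$TGFb, .data$IL6) |>
    dplyr::group_by(.data$IFNg, .data$IL12, .data$TGFb) |>
    dplyr::summarise(max_rise = max(diff(.data$FOXP3)), .groups = "drop")
  expect_equal(nrow(worst), 125)
  expect_true(all(worst$max_rise <= 1e-7))
})

test_that("ODE steady states agree with the fixed-point oracle on the grid", {
  d <- grid_dataset_raw()
  Y <- as.matrix(tibble::as_tibble(d)[c("IL17", "RORgt", "IFNg_out",
                                        "Tbet", "FOXP3")])
  X <- as.matrix(tibble::as_tibble(d)[c("IFNg", "IL12", "IL6", "TGFb")])
  worst <- 0
  for (i in seq_len(nrow(d))) {
    oracle <- fixed_point_oracle(X[i, ])
    worst <- max(worst, max(abs(Y[i, ] - oracle)))
  }
  expect_lt(worst, 1e-6)
})

test_that("time courses are consistent with the steady state", {
  tc <- simulate_timecourse(tgfb_only, t_grid = c(0))
  expect_equal(nrow(tc), 1)
  expect_equal(unname(unlist(tc[1, -1])), rep(0, 5))

  tc <- simulate_timecourse(tgfb_only, t_grid = seq(0, 60, by = 0.5))
  expect_equal(tc$FOXP3[nrow(tc)], 16 / 17, tolerance = 1e-6)
  # scalar logistic-type dynamics: FOXP3 rises monotonically from rest
  expect_true(all(diff(tc$FOXP3) >= -1e-10))
  expect_error(simulate_timecourse(tgfb_only, t_grid = c(1, 0.5)),
               "increasing")
})
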