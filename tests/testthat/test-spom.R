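sp_mid <- species_params(alpha = 0.004, y = 10, A0 = 0.05, preference = "mid")

test_that("connectivity evaluates the dispersal kernel sum", {
  # an empty network contributes nothing
  L3 <- triangle_landscape()
  expect_equal(unname(connectivity(L3, c(FALSE, FALSE, FALSE), sp_mid)),
               c(0, 0, 0))

  # two coincident unit-area patches: S_i = 1 * exp(0) * 1
  L0 <- as_landscape(data.frame(id = 1:2, x = c(5, 5), y = c(5, 5),
                                area = c(1, 1), age = c(0, 0)), side = 10)
  S <- connectivity(L0, c(FALSE, TRUE), sp_mid)
  expect_equal(unname(S[1]), 1)

  # one occupied unit-area neighbour at distance 1/alpha: S = exp(-1)
  L1 <- as_landscape(data.frame(id = 1:2, x = c(0, 1 / sp_mid$alpha),
                                y = c(0, 0), area = c(1, 1), age = c(0, 0)),
                     side = 1000)
  S <- connectivity(L1, c(FALSE, TRUE), sp_mid)
  expect_equal(unname(S[1]), exp(-1))

  # area exponents scale source (b) and focal (c) contributions
  spb <- species_params(alpha = 0.004, y = 10, A0 = 0.05, preference = "mid",
                        b = 0.5)
  L2 <- as_landscape(data.frame(id = 1:2, x = c(5, 5), y = c(5, 5),
                                area = c(2, 4), age = c(0, 0)), side = 10)
  S <- connectivity(L2, c(FALSE, TRUE), spb)
  expect_equal(unname(S[1]), 2^1 * 4^0.5)

  # misaligned state errors out
  expect_error(connectivity(L3, c(TRUE, FALSE), sp_mid), "aligned")
})

test_that("Allee colonization follows S^2 / (S^2 + y^2)", {
  expect_equal(colonization_spatial(0, 5), 0)
  expect_equal(colonization_spatial(5, 5), 0.5)
  expect_equal(colonization_spatial(2, 5), 4 / 29)
  S <- seq(0, 50, by = 0.5)
  expect_true(all(diff(colonization_spatial(S, 10)) > 0))
  expect_true(all(colonization_spatial(S, 10) < 1))
})

test_that("area-dependent extinction caps at 1 below the critical area", {
  expect_equal(extinction_spatial(0.5, 0.05, 1), 0.1)
  expect_equal(extinction_spatial(1, 0.1, 1), 0.1) # unit-area definition of e
  expect_equal(extinction_spatial(0.04, 0.05, 1), 1) # A <= e^(1/x)
  expect_equal(extinction_spatial(0.05, 0.05, 1), 1) # boundary inclusive
  expect_equal(extinction_spatial(0.2, 0.04, 2), 1)  # x != 1 threshold
})

test_that("rate combination is product for C and configurable for E", {
  cr <- combine_rates(0.8, 0, 0.1, 0.9)
  expect_equal(cr$C, 0) # successionally unsuitable: no colonization
  expect_equal(cr$E, 0.09)
  expect_equal(combine_rates(0.5, 0.5, 0.1, 0.1)$C, 0.25)
  expect_equal(combine_rates(0.5, 1, 0.1, 0.1, "or")$E, 0.19)
  expect_equal(combine_rates(0.5, 0.5, 0.3, 1, "or")$E, 1)
  expect_error(combine_rates(1.2, 0.5, 0.1, 0.1), "probabilities")
  expect_error(combine_rates(0.5, 0.5, -0.1, 0.1), "probabilities")
})

test_that("step_rates yields aligned probabilities with the area threshold", {
  L <- small_landscape(seed = 21)
  set.seed(22)
  occ <- runif(n_patches(L)) < 0.5
  r <- step_rates(L, occ, sp_mid)
  expect_equal(r$id, L$patches$id)
  for (col in c("C_is", "E_is", "C_it", "E_it", "C", "E")) {
    expect_true(all(r[[col]] >= 0 & r[[col]] <= 1))
  }
  expect_true(all(r$S >= 0))
  tiny <- L$patches$area <= sp_mid$e^(1 / sp_mid$x)
  expect_true(all(r$E_is[tiny] == 1))
})

test_that("extinction shows no rescue effect: E ignores connectivity", {
  L <- small_landscape(seed = 23)
  n <- n_patches(L)
  r_empty <- step_rates(L, rep(FALSE, n), sp_mid)
  r_full <- step_rates(L, rep(TRUE, n), sp_mid)
  expect_equal(r_empty$E, r_full$E)
  expect_false(isTRUE(all.equal(r_empty$C, r_full$C)))
})

test_that("better dispersers are never less colonizable, all else equal", {
  L <- small_landscape(seed = 24)
  set.seed(25)
  occ <- runif(n_patches(L)) < 0.5
  sp_lo <- species_params(alpha = 0.02, y = 10, A0 = 0.05, preference = "mid")
  sp_hi <- species_params(alpha = 0.001, y = 10, A0 = 0.05, preference = "mid")
  expect_true(all(step_rates(L, occ, sp_hi)$C_is >=
                    step_rates(L, occ, sp_lo)$C_is))
})

test_that("deterministic limits of the update behave as absorbing states", {
  L3 <- triangle_landscape()
  # all empty + Allee colonization: S = 0 so the empty state is absorbing
  occ <- c(FALSE, FALSE, FALSE)
  set.seed(26)
  for (i in 1:20) occ <- step_occupancy(L3, occ, sp_mid)
  expect_equal(unname(occ), c(FALSE, FALSE, FALSE))
  # forced E = 0 keeps occupied patches occupied
  forced <- data.frame(C = rep(0, 3), E = rep(0, 3))
  occ <- step_occupancy(L3, c(TRUE, TRUE, FALSE), sp_mid, rates = forced)
  expect_equal(unname(occ[1:2]), c(TRUE, TRUE))
})

test_that("single-patch occupancy converges to the stationary law C/(C+E)", {
  L1 <- as_landscape(data.frame(id = 1, x = 5, y = 5, area = 1, age = 0),
                     side = 10)
  Cc <- 0.3
  Ee <- 0.1
  forced <- data.frame(C = Cc, E = Ee)
  n_steps <- 2e4
  occ_trace <- logical(n_steps)
  occ <- c(`1` = FALSE)
  set.seed(27)
  for (t in seq_len(n_steps)) {
    occ <- step_occupancy(L1, occ, sp_mid, rates = forced)
    occ_trace[t] <- occ
  }
  J <- Cc / (Cc + Ee)
  # Markov-chain CLT standard error with lag-1 correlation 1 - C - E
  rho <- 1 - Cc - Ee
  se <- sqrt(J * (1 - J) / n_steps * (1 + rho) / (1 - rho))
  expect_lt(abs(mean(occ_trace) - J), 3 * se)
})
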