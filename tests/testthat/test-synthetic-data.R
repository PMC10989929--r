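test_that("steady-state abundances follow Int = alpha/lambda with read-through splitting", {
  # no termination, identical decay: identical levels
  p0 <- simulation_params(alpha = 1, f_term = 0, lambda_utr = 0.1,
                          lambda_orf = 0.1)
  ss0 <- steady_state_abundance(p0)
  expect_equal(ss0$intensity, c(10, 10))

  # study-condition parameters; expected ratio computed by hand as
  # (1 / (1 - f)) * (lambda_orf / lambda_utr) = 24.390244 * (3.1 / 7.2)
  p <- simulation_params(alpha = 1, f_term = 0.959,
                         lambda_utr = log(2) / 3.1,
                         lambda_orf = log(2) / 7.2)
  ss <- steady_state_abundance(p)
  ratio <- ss$intensity[ss$compartment == "UTR"] /
    ss$intensity[ss$compartment == "ORF"]
  expect_equal(ratio, 10.501355, tolerance = 1e-6)

  # termination fraction approaching 1 starves the ORF
  p1 <- simulation_params(f_term = 1 - 1e-9)
  ss1 <- steady_state_abundance(p1)
  expect_lt(ss1$intensity[ss1$compartment == "ORF"], 1e-7)
  expect_gt(ss1$intensity[ss1$compartment == "UTR"], 1)

  # steady-state identity holds to machine precision for random params
  for (s in 1:20) {
    par <- withr::with_seed(s, list(
      alpha = runif(1, 0.1, 10), f = runif(1, 0, 0.99),
      lu = runif(1, 0.01, 1), lo = runif(1, 0.01, 1)
    ))
    pp <- simulation_params(alpha = par$alpha, f_term = par$f,
                            lambda_utr = par$lu, lambda_orf = par$lo)
    ssp <- steady_state_abundance(pp)
    expect_equal(ssp$intensity[1] * ssp$lambda[1], par$alpha)
    expect_equal(ssp$intensity[2] * ssp$lambda[2],
                 (1 - par$f) * par$alpha)
  }
})

test_that("parameter validation rejects out-of-domain values", {
  expect_error(simulation_params(alpha = 0), "alpha")
  expect_error(simulation_params(f_term = 1), "f_term")
  expect_error(simulation_params(f_term = -0.1), "f_term")
  expect_error(simulation_params(lambda_utr = -1), "lambda_utr")
  expect_error(simulation_params(timepoints = c(5, 10)), "start at 0")
  expect_error(simulation_params(timepoints = c(0, 10, 5)), "increasing")
  expect_error(simulation_params(ct_noise_sd = -0.1), "ct_noise_sd")
  expect_error(simulation_params(n_bio_reps = 0), "n_bio_reps")
})

test_that("noiseless chase Ct rises exactly one cycle per half-life", {
  t_half <- 10
  p <- simulation_params(lambda_utr = log(2) / t_half, ct_noise_sd = 0,
                         timepoints = c(0, 10, 20, 30))
  ct <- simulate_chase(p)
  utr <- ct[ct$compartment == "UTR" & ct$region == "5UTR-1" &
              ct$bio_rep == 1 & ct$tech_rep == 1, ]
  ct_by_time <- utr$ct[order(utr$time_min)]
  expect_equal(diff(ct_by_time), c(1, 1, 1))

  # reference gene is flat
  ref <- ct[ct$compartment == "reference", ]
  expect_equal(unique(ref$ct), p$ref_ct_mean)
})

test_that("chase simulation is deterministic given the seed", {
  p <- simulation_params(seed = 99)
  expect_identical(simulate_chase(p), simulate_chase(p))
  # and different seeds perturb the noise
  p2 <- simulation_params(seed = 100)
  expect_false(identical(simulate_chase(p), simulate_chase(p2)))
})

test_that("noiseless chase round-trips the half-life through the full fit", {
  p <- simulation_params(lambda_utr = log(2) / 3.1, ct_noise_sd = 0)
  rq <- delta_delta_ct(simulate_chase(p))
  fit <- fit_exponential_decay(rq[rq$compartment == "UTR", ])
  expect_equal(fit$half_life, 3.1, tolerance = 1e-6)
})

test_that("intensity fold changes reduce to the steady-state algebra", {
  p <- study_params("mock", seed = 1)
  # identical params: both between-condition fold changes are exactly
  # 1 and the two within-condition UTR/ORF ratios coincide
  fc_same <- simulate_intensity_fc(p, p, labels = c("a", "b"))
  expect_equal(fc_same$fc[3:4], c(1, 1))
  expect_equal(fc_same$fc[1], fc_same$fc[2])

  # noiseless single condition: FC(UTR/ORF) = (1/(1-f)) (lambda_orf/lambda_utr)
  fc <- simulate_intensity_fc(p, study_params("uv", seed = 1))
  expected_mock <- (1 / (1 - p$f_term)) * (p$lambda_orf / p$lambda_utr)
  expect_equal(fc$fc[fc$comparison == "mock UTR/ORF"], expected_mock)

  # with noise: deterministic given seed, centred on the exact value
  fc_n1 <- simulate_intensity_fc(p, p, log_noise_sd = 0.1, seed = 3)
  fc_n2 <- simulate_intensity_fc(p, p, log_noise_sd = 0.1, seed = 3)
  expect_identical(fc_n1, fc_n2)
  expect_false(all(fc_n1$fc == 1))
})

test_that("planted sequences contain exactly the requested signatures", {
  sim <- simulate_sequence_with_sites(50, site_positions = 20, seed = 1)
  expect_equal(nchar(sim$seq), 50)
  hits <- scan_cleavage_sites(sim$seq)
  expect_true(20 %in% hits$bond[hits$both])
  # background is A/U free except the plants, so bond 20 is the only
  # both-rule call
  expect_equal(hits$bond[hits$both], 20)

  sim2 <- simulate_sequence_with_sites(40, u_tract = c(10, 15), seed = 2)
  tracts <- find_u_tracts(sim2$seq, min_len = 6)
  expect_equal(tracts$start, 10)
  expect_equal(tracts$end, 15)

  # reproducible
  expect_identical(simulate_sequence_with_sites(60, c(10, 30), seed = 7),
                   simulate_sequence_with_sites(60, c(10, 30), seed = 7))

  # contradictory plants error: bond b demands U at b+2; bond b+4
  # demands A at (b+4)-2 = b+2
  expect_error(
    simulate_sequence_with_sites(50, site_positions = c(20, 24), seed = 1),
    "contradictory"
  )
})

test_that("end-to-end recovery of the termination fraction is accurate for the control design", {
  # Study conditions: sigma_Ct = 0.15, 2 regions x 3 biological
  # replicates per compartment. For the strong-termination condition
  # (f = 0.959) the recovered fraction stays within 0.02 of truth
  # essentially always.
  errs <- vapply(1:60, function(s) {
    recover_termination(study_params("mock", seed = s)) - 0.959
  }, numeric(1))
  expect_gte(mean(abs(errs) <= 0.02), 0.95)

  # For the weak-termination condition (f = 0.653) the single-run
  # estimate is noisier (the 30-min window carries little information
  # on a 17.1-min half-life), but the estimator is unbiased: the
  # central recovery over seeds is well within 0.02.
  errs_uv <- vapply(1:60, function(s) {
    recover_termination(study_params("uv", seed = s)) - 0.653
  }, numeric(1))
  expect_lt(abs(median(errs_uv)), 0.02)
})
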