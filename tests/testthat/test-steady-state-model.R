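test_that("synthesis ratio is the product of intensity and decay fold changes", {
  r <- synthesis_ratio(11, 2.2)
  expect_equal(r$fc_synthesis, 24.2)
  expect_equal(synthesis_ratio(1, 1)$fc_synthesis, 1)

  r_uv <- synthesis_ratio(6.5, 7.5 / 17.1)
  expect_equal(round_half_up(r_uv$fc_synthesis, 1), 2.9)

  expect_error(synthesis_ratio(-1, 2), "positive")
  expect_error(synthesis_ratio(2, 0), "positive")

  # invariance under common intensity rescaling: both compartments
  # scaled by c leaves the UTR/ORF intensity FC, hence everything,
  # unchanged
  expect_equal(synthesis_ratio((11 * 7) / 7, 2.2), synthesis_ratio(11, 2.2))
})

test_that("termination fraction follows 1 - 1/FCsynt with a floor at no evidence", {
  expect_equal(termination_fraction(24.2), 1 - 1 / 24.2)
  expect_equal(round_half_up(100 * termination_fraction(24.2), 1), 95.9)
  expect_equal(termination_fraction(1), 0)
  # 1 - 1/2.851 = 0.64925...: reported 64.9%
  expect_equal(round_half_up(100 * termination_fraction(2.851), 1), 64.9)
  # below 1: no evidence of termination, clamped to 0 and flagged
  expect_equal(termination_fraction(0.5), 0)
  expect_true(synthesis_ratio(0.5, 1)$no_evidence)
  expect_error(termination_fraction(0), "positive")

  # monotone in FCsynt and bounded in [0, 1)
  grid <- seq(1, 100, length.out = 200)
  tf <- termination_fraction(grid)
  expect_true(all(diff(tf) > 0))
  expect_true(all(tf >= 0 & tf < 1))
})

test_that("decay-constant fold changes invert the half-life ratio", {
  expect_equal(decay_fc_from_half_lives(17.1, 7.5), 7.5 / 17.1)
  expect_equal(round_half_up(decay_fc_from_half_lives(17.1, 7.5), 1), 0.4)
  expect_equal(round_half_up(decay_fc_from_half_lives(17.1, 3.1), 2), 0.18)
  expect_equal(decay_fc_from_half_lives(4.2, 4.2), 1)
  expect_error(decay_fc_from_half_lives(0, 1), "positive")
})

test_that("round trip with the generative model recovers f exactly", {
  for (f in c(0, 0.1, 0.5, 0.653, 0.959, 0.99)) {
    p <- simulation_params(f_term = f, lambda_utr = log(2) / 3.1,
                           lambda_orf = log(2) / 7.2)
    ss <- steady_state_abundance(p)
    fc_int <- ss$intensity[ss$compartment == "UTR"] /
      ss$intensity[ss$compartment == "ORF"]
    fc_dec <- p$lambda_utr / p$lambda_orf
    f_hat <- termination_fraction(fc_int * fc_dec)
    expect_equal(f_hat, f, tolerance = 1e-12)
  }
})

test_that("the full report reproduces the published synthesis-rate row", {
  rep <- table1_report(
    fc_int_mock = 11, fc_decay_mock = 2.2,
    fc_int_uv = 6.5, t12_uv_utr = 17.1, t12_uv_orf = 7.5,
    fc_int_utr_uvmock = 2.52, t12_mock_utr = 3.1
  )
  expect_equal(rep$fc_synthesis_label, c("24.2", "2.9", "0.46"))
  expect_equal(rep$termination_label[1], "95.9%")
  # transcription-rate interpretation of the UV/mock synthesis FC
  expect_equal(round_half_up(rep$transcription_rate_factor[3], 1), 2.2)
  # termination is not defined for the between-condition comparison
  expect_true(is.na(rep$termination_fraction[3]))

  # all-equal inputs: unit fold changes, no termination
  flat <- table1_report(
    fc_int_mock = 1, fc_decay_mock = 1, fc_int_uv = 1, fc_decay_uv = 1,
    fc_int_utr_uvmock = 1, fc_decay_utr_uvmock = 1
  )
  expect_equal(flat$fc_synthesis, c(1, 1, 1))
  expect_equal(flat$termination_fraction[1:2], c(0, 0))

  # incomplete input lists the missing cells by name
  expect_error(table1_report(fc_int_mock = 11), "missing cells.*UV")

  tab <- format_table1(rep)
  expect_equal(tab$quantity[3], "FC of synthesis rate")
  expect_equal(tab[["mock UTR/ORF"]][3], "24.2")
  expect_equal(tab[["mock UTR/ORF"]][4], "95.9%")
})

test_that("measurement-based entry reproduces the fold-change entry", {
  meas <- tibble::tibble(
    condition = rep(c("mock", "uv"), each = 2),
    compartment = rep(c("UTR", "ORF"), 2),
    intensity = c(11, 1, 2.52 * 11, 6.5 * 2.52 * 11 / 6.5),
    half_life = c(3.1, 7.2, 17.1, 7.5)
  )
  rep <- table1_from_measurements(meas)
  expect_equal(rep$fc_intensity[1], 11)
  expect_equal(rep$fc_intensity[3], 2.52)
  expect_equal(rep$fc_decay[2], 7.5 / 17.1)
  # absolute synthesis rates alpha = Int * lambda are attached
  a <- attr(rep, "alpha_hat")
  expect_equal(a$alpha_hat, meas$intensity * log(2) / meas$half_life)

  expect_error(table1_from_measurements(meas[1:3, ]), "missing cells.*uv")
})

test_that("reported stability statements derive from the half-life arithmetic", {
  # UV stabilizes the 5' UTR 5.5-fold
  expect_equal(round_half_up(17.1 / 3.1, 1), 5.5)
  # equivalently the decay constant drops to 0.18 of the mock value
  expect_equal(round_half_up(decay_fc_from_half_lives(17.1, 3.1), 2), 0.18)
})

test_that("reporting precision follows the fold-change/percentage conventions", {
  # ties (exactly representable ones) go away from zero
  expect_equal(round_half_up(c(0.25, -0.25), 1), c(0.3, -0.3))
  expect_equal(round_half_up(c(2.5, -2.5)), c(3, -3))
  expect_equal(format_fold(c(24.24, 2.8509, 0.4568, 0.1813)),
               c("24.2", "2.9", "0.46", "0.18"))
  expect_equal(format_pct(0.9586777), "95.9%")
})
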