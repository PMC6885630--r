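test_that("positional_composition counts per-position base fractions", {
  cm <- positional_composition(c("GUAG", "GUAA"))
  expect_equal(cm$fractions["N1", "G"], 1.0)
  expect_equal(cm$fractions["N4", "G"], 0.5)
  expect_equal(cm$fractions["N4", "A"], 0.5)
  expect_equal(unname(rowSums(cm$counts)), rep(2L, 4))
  expect_equal(unname(rowSums(cm$fractions)), rep(1, 4), tolerance = 1e-12)

  cm2 <- positional_composition(rep("AAAA", 5))
  expect_true(all(cm2$fractions[, "A"] == 1))

  expect_error(positional_composition(character(0)), "no called reads")
  expect_error(positional_composition(c("GUAG", "GA")), "same length")
})

test_that("normalize_composition removes baseline bias (ratio-of-fractions)", {
  obs <- positional_composition(c(rep("AAAA", 2), rep("CCCC", 2)))
  unif <- positional_composition(c("AAAA", "CCCC", "GGGG", "UUUU"))

  # identity under a uniform baseline
  norm <- normalize_composition(obs, unif)
  expect_equal(norm$fractions, obs$fractions, tolerance = 1e-12)

  # self-normalization is uniform
  self <- normalize_composition(obs, obs)
  # positions where obs has zero bases keep 0 there; restrict to nonzero
  expect_equal(unname(self$fractions[, "A"]), rep(0.5, 4), tolerance = 1e-12)
  expect_equal(unname(self$fractions[, "C"]), rep(0.5, 4), tolerance = 1e-12)

  # worked ratio example: obs (.5,.5,0,0) / baseline (.5,.25,.125,.125)
  obs2 <- positional_composition(c(rep("A", 2), rep("C", 2)))
  base2 <- positional_composition(c(rep("A", 4), rep("C", 2), "G", "U"))
  out <- normalize_composition(obs2, base2)
  expect_equal(unname(out$fractions[1, ]), c(1 / 3, 2 / 3, 0, 0),
               tolerance = 1e-12)
})

test_that("normalize_composition flags zero-baseline bases and renormalizes", {
  obs <- positional_composition(c("A", "C", "G"))
  base <- positional_composition(c("A", "C"))  # G absent from baseline
  expect_warning(out <- normalize_composition(obs, base), "zero baseline")
  expect_true(is.na(out$fractions[1, "G"]))
  expect_equal(sum(out$fractions[1, ], na.rm = TRUE), 1, tolerance = 1e-12)
})

test_that("nta_profile reports string and length laws with display pooling", {
  payloads <- c(rep("CAA", 60), rep("CA", 30), rep("C", 6), rep("A", 4))
  prof <- nta_profile(payloads)
  s <- prof$strata$ALL
  expect_equal(unname(s$string_freq["CAA"]), 0.60)
  expect_equal(unname(s$string_freq["CA"]), 0.30)
  expect_equal(unname(s$string_freq["C"]), 0.06)
  expect_equal(unname(s$string_freq["other"]), 0.04)  # A pooled at 4% < 5%
  expect_false("A" %in% names(s$string_freq))
  expect_equal(unname(s$string_freq_raw["A"]), 0.04)  # raw kept alongside
  expect_equal(unname(s$length_freq[c("3", "2", "1")]), c(0.6, 0.3, 0.1))
  expect_equal(sum(s$string_freq), 1, tolerance = 1e-12)  # pooling conserves mass
  expect_equal(sum(s$length_freq), 1, tolerance = 1e-12)

  empty <- nta_profile(rep("", 10))
  expect_equal(unname(empty$strata$ALL$string_freq["-"]), 1.0)
  expect_equal(unname(empty$strata$ALL$length_freq["0"]), 1.0)

  expect_error(nta_profile(character(0)), "no payloads")
})

test_that("stratified profiles aggregate to the ALL stratum", {
  set.seed(60)
  payloads <- sample(c("", "C", "CA", "CAA", "A"), 500, TRUE)
  first <- sample(c("A", "C", "G", "U"), 500, TRUE)
  prof <- nta_profile(payloads, first_base = first, min_frac = 0)
  all_freq <- prof$strata$ALL$string_freq_raw
  agg <- Reduce(`+`, lapply(c("A", "C", "G", "U"), function(b) {
    s <- prof$strata[[b]]
    out <- stats::setNames(numeric(length(all_freq)), names(all_freq))
    out[names(s$string_freq_raw)] <- s$string_freq_raw * s$n
    out
  })) / 500
  expect_equal(agg, all_freq, tolerance = 1e-12)
})

test_that("junction_profile adds the single-base identity distribution", {
  prof <- junction_profile(c(rep("", 9), "C"))
  expect_equal(unname(prof$strata$ALL$length_freq[c("0", "1")]), c(0.9, 0.1))
  expect_equal(unname(prof$single_base_identity["C"]), 1.0)

  prof2 <- junction_profile(rep("C", 5))
  expect_equal(unname(prof2$strata$ALL$length_freq["1"]), 1.0)
  expect_equal(unname(prof2$single_base_identity["C"]), 1.0)
})

test_that("estimate_step_propensities is the per-step categorical MLE", {
  est <- estimate_step_propensities(c("A", "", "CA"))
  expect_equal(unname(est$q["A"]), 2 / 6)
  expect_equal(unname(est$q["C"]), 1 / 6)
  expect_equal(est$p_stop, 3 / 6)
  expect_equal(est$total_steps, 6)

  est0 <- estimate_step_propensities(rep("", 7))
  expect_equal(est0$p_stop, 1)
  expect_true(all(est0$q == 0))

  expect_error(estimate_step_propensities(character(0)), "no molecules")
})

test_that("propensity estimates are consistent against the generating law", {
  eta <- c(A = 0.8, C = 0.5, G = 0.3, T = 0.1)
  sigma <- 1
  params <- sim_params(eta = eta, sigma = sigma, max_nta = Inf)
  lib <- simulate_library("NTA", 50000, tpl4("HYDROXYL"), NULL, params,
                          seed = 61)
  est <- estimate_step_propensities(lib$truth$nta_string)
  q_true <- eta / (sum(eta) + sigma)
  p_true <- sigma / (sum(eta) + sigma)
  for (b in names(q_true))
    expect_lt(abs(est$q[[b]] - q_true[[b]]), 3 * est$se_q[[b]] + 1e-12)
  expect_lt(abs(est$p_stop - p_true), 3 * est$se_p_stop)
})

test_that("nta_closed_form matches direct per-string arithmetic", {
  params <- sim_params(eta = c(A = 0.5, C = 1, G = 0.25, T = 0.25), sigma = 2)
  law <- nta_closed_form(params, max_len = 3)
  A <- 2; stop_p <- 2 / 4
  expect_equal(unname(law["-"]), 0.5)
  expect_equal(unname(law["C"]), (1 / 4) * 0.5)
  expect_equal(unname(law["CA"]), (1 / 4) * (0.5 / 4) * 0.5)
  expect_equal(sum(law) + (1 - sum(law)), 1)  # law is a (truncated) pmf
  expect_error(nta_closed_form(sim_preset("capped")), "constant")
})
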