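test_that("sim_params rejects invalid parameterizations", {
  expect_error(sim_params(eta = c(A = -1, C = 0, G = 0, T = 0)), "eta")
  expect_error(sim_params(sigma = 0, max_nta = Inf), "sigma")
  expect_error(sim_params(cap_c_prob = 1.5), "cap_c_prob")
  expect_error(sim_params(dntp_conc = c(A = 0, C = 1, G = 1, T = 1)),
               "dntp_conc")
  expect_error(sim_params(seq_error_rate = 1), "seq_error_rate")
  # sigma = 0 is fine when max_nta bounds the segment
  expect_s3_class(sim_params(sigma = 0, max_nta = 5), "sim_params")
})

test_that("switch_score scores terminal overlaps with mismatch disqualification", {
  p <- sim_params(w_gc = 3, w_at = 1, kappa_blunt = 0)
  # the +CAA / rUrUrG pairing: C:G + A:U + A:U
  expect_equal(switch_score("CAA", tso("UUG"), p), 5)
  expect_equal(switch_score("A", tso("GGG"), p), 0)
  expect_equal(switch_score("C", tso("GGG"), p), 3)
  # a mismatch anywhere in the considered overlap voids that overlap:
  # "CA" vs rGrGrG has no valid L >= 1 (terminal A:G mismatches)
  expect_equal(switch_score("CA", tso("GGG"), p), 0)
  expect_equal(switch_score("CC", tso("GGG"), p), 6)   # two C:G pairs
  expect_equal(switch_score("ACCC", tso("GGG"), p), 9) # overlap capped at 3
  # empty overhang scores the blunt propensity
  p2 <- sim_params(kappa_blunt = 1.5)
  expect_equal(switch_score("", tso("GGG"), p2), 1.5)
  expect_equal(switch_score("A", tso("GGG"), p2), 1.5) # blunt beats mismatch
})

test_that("zero addition propensity yields the bare template complement", {
  set.seed(1)
  rec <- simulate_molecule(tpl4("HYDROXYL", "GUAG"), NULL,
                           sim_params(eta = c(A = 0, C = 0, G = 0, T = 0),
                                      sigma = 1))
  expect_identical(rec$cdna, "TTGAGCGTACTCGACGAAGTTCTAC")
  expect_identical(rec$nta_string, "")
  expect_identical(rec$n_switches, 0L)
  expect_identical(rec$junction_extras, "")
  expect_identical(rec$terminated_by, "NTA_STOP")
})

test_that("cap-templated C followed by immediate switch reproduces the +C junction", {
  params <- sim_params(eta = c(A = 0, C = 0, G = 0, T = 0), sigma = 1,
                       cap_c_prob = 1, kappa_ts = 1e9, kappa_blunt = 0,
                       max_switches = 1)
  g3 <- tso_g3()
  set.seed(2)
  for (i in 1:5) {
    rec <- simulate_molecule(tpl4("M7G_CAP", "GUAG"), g3, params)
    expect_identical(rec$junction_extras, "C")
    expect_identical(rec$nta_string, "C")
    expect_true(rec$cap_templated_c)
    expect_identical(rec$n_switches, 1L)
    expect_identical(rec$terminated_by, "SWITCH_LIMIT")
    expect_identical(rec$cdna,
                     paste0("TTGAGCGTACTCGACGAAGTTCTAC", "C",
                            cdna_of_tso(g3)))
  }
})

test_that("constant switch propensity lambda = sigma gives switch probability 1/2", {
  # overhang-independent switching: w_gc = w_at = 0 so only kappa_blunt acts
  n <- 20000
  params <- sim_params(eta = c(A = 0.3, C = 0.3, G = 0.3, T = 0.3), sigma = 1,
                       kappa_ts = 1, kappa_blunt = 1, w_gc = 0, w_at = 0,
                       max_switches = 1, max_nta = Inf)
  lib <- simulate_library("JUNCTION", n, tpl4("HYDROXYL"), tso_g3(), params,
                          seed = 101)
  frac <- mean(lib$truth$n_switches > 0)
  se <- sqrt(0.25 / n)
  expect_lt(abs(frac - 0.5), 3 * se)
})

test_that("every molecule halts and satisfies the structural invariants", {
  set.seed(33)
  cases <- list(
    sim_params(eta = c(A = 5, C = 5, G = 5, T = 5), sigma = 0.01, max_nta = 10),
    sim_params(eta = c(A = 2, C = 2, G = 2, T = 2), sigma = 0, max_nta = 6),
    sim_preset("capped"), sim_preset("oh"))
  g3 <- tso_g3()
  for (params in cases) {
    for (i in 1:40) {
      rec <- simulate_molecule(tpl4("M7G_CAP", "ACGU"), g3, params)
      expect_true(startsWith(rec$cdna, "TTGAGCGTACTCGACGAAGTTACGT"))
      expect_lte(rec$n_switches, params$max_switches)
      expect_true(rec$terminated_by %in% c("NTA_STOP", "SWITCH_LIMIT", "MAX_NTA"))
      if (rec$n_switches == 0L) expect_identical(rec$junction_extras, "")
      else expect_identical(rec$junction_extras, rec$nta_string)
    }
  }
})

test_that("biotinylated TSO caps switching at one event", {
  params <- sim_params(eta = c(A = 0, C = 5, G = 0, T = 0), sigma = 0.2,
                       kappa_ts = 50, kappa_blunt = 1, max_switches = 3)
  bio <- tso("GGG", biotin5 = TRUE)
  set.seed(9)
  recs <- replicate(50, simulate_molecule(tpl4("HYDROXYL", "AAAA"), bio,
                                          params),
                    simplify = FALSE)
  expect_true(all(vapply(recs, `[[`, integer(1), "n_switches") <= 1L))
})

test_that("apply_seq_errors is a per-base binomial substitution process", {
  expect_identical(apply_seq_errors(c("ACGT", ""), 0), c("ACGT", ""))
  expect_identical(apply_seq_errors("", 0.5), "")
  expect_error(apply_seq_errors("ACGT", 1), "rate")
  set.seed(5)
  s <- strrep("A", 10000)
  out <- apply_seq_errors(s, 0.1)
  expect_identical(nchar(out), 10000L)
  d <- sum(strsplit(out, "")[[1]] != "A")
  expect_lt(abs(d / 10000 - 0.1), 3 * sqrt(0.1 * 0.9 / 10000))
  # substituted bases are never the original base
  expect_false(any(strsplit(out, "")[[1]] == "A" &
                     strsplit(s, "")[[1]] != "A"))
})

test_that("emit_ce_peaks turns molecule lengths into count-proportional peaks", {
  truth <- data.frame(cdna_length = c(rep(25, 100), rep(67, 100)))
  pk <- emit_ce_peaks(truth)
  expect_identical(nrow(pk), 2L)
  expect_equal(pk$size_nt, c(25, 67))
  expect_equal(pk$area, c(100, 100))
  expect_true(is_calibrated(pk))

  pk1 <- emit_ce_peaks(data.frame(cdna_length = rep(28, 10)))
  expect_identical(nrow(pk1), 1L)

  # two switches add 2 x 42 nt
  pk2 <- emit_ce_peaks(data.frame(cdna_length = 25 + 84))
  expect_gte(pk2$size_nt, 109)

  pk3 <- emit_ce_peaks(truth, primer_len = 20, primer_area = 50)
  expect_equal(pk3$size_nt[1], 20)
  expect_equal(pk3$area[1], 50)
  expect_error(emit_ce_peaks(data.frame(cdna_length = numeric(0))), "no molecules")
})

test_that("emit_masses is additive in added residues", {
  m <- emit_masses(c("ACGT", "ACGTC", "ACGTCAA"))
  tab <- default_mass_table()
  expect_equal(m[2] - m[1], tab$residue_mass[["C"]])
  expect_equal(m[3] - m[2], 2 * tab$residue_mass[["A"]])
  expect_equal(m[3] - m[1],
               tab$residue_mass[["C"]] + 2 * tab$residue_mass[["A"]])
  expect_identical(emit_masses(c("AAA", "AAA"))[1], emit_masses("AAA"))
})

test_that("simulate_library emits the documented read structures", {
  quiet <- sim_params(eta = c(A = 0, C = 0, G = 0, T = 0), sigma = 1)
  lib <- simulate_library("NTA", 1, tpl4("HYDROXYL", "GUAG"), NULL, quiet,
                          seed = 3)
  expect_identical(lib$reads$seq,
                   paste0("TTGAGCGTACTCGACGAAGTT", "CTAC", DEFAULT_APP_ADAPTER))

  g3 <- tso_g3()
  sw <- sim_params(eta = c(A = 0, C = 0, G = 0, T = 0), sigma = 1,
                   cap_c_prob = 1, kappa_ts = 1e9, kappa_blunt = 0,
                   max_switches = 1)
  jlib <- simulate_library("JUNCTION", 1, tpl4("M7G_CAP", "GUAG"), g3, sw,
                           seed = 4)
  expect_identical(jlib$reads$seq,
                   paste0("TTGAGCGTACTCGACGAAGTT", "CTAC", "C", "CCC",
                          substr(cdna_of_tso(g3), 4, 42)))

  clib <- simulate_library("COMPOSITION", 1, tpl4("HYDROXYL", "AAAA"), NULL,
                           quiet, seed = 5, tail_mean = 8)
  expect_true(startsWith(clib$reads$seq,
                         paste0("TTGAGCGTACTCGACGAAGTT", "TTTT")))
  expect_true(grepl("^TTGAGCGTACTCGACGAAGTTTTTTG*$", clib$reads$seq))
  expect_error(simulate_library("NTA", 0, tpl4(), NULL, quiet), "n must be > 0")
})

test_that("library simulation is reproducible from (config, seed)", {
  a <- simulate_library("NTA", 200, tpl4(), NULL, sim_preset("capped"), seed = 77)
  b <- simulate_library("NTA", 200, tpl4(), NULL, sim_preset("capped"), seed = 77)
  expect_identical(a$reads, b$reads)
  expect_identical(a$truth, b$truth)
})
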