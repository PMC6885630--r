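anchor <- ANCHOR21_DEFAULT

test_that("match_anchor finds the smallest offset under a mismatch budget", {
  read <- paste0(anchor, "ACGTACGT")
  expect_identical(match_anchor(read, anchor, 0), 0L)

  # one substitution, embedded at offset 5
  mut <- anchor
  substr(mut, 10, 10) <- if (substr(mut, 10, 10) == "A") "C" else "A"
  read2 <- paste0("GGGGG", mut, "AA")
  expect_identical(match_anchor(read2, anchor, 2), 5L)
  expect_identical(match_anchor(read2, anchor, 0), NA_integer_)

  # a read sharing < 19/21 positions in every window has no match at mm = 2;
  # verified against a brute-force positionwise scan
  set.seed(8)
  repeat {
    rnd <- random_dna(60)
    brute <- sapply(0:(60 - 21), function(off) {
      w <- substr(rnd, off + 1, off + 21)
      sum(strsplit(w, "")[[1]] != strsplit(anchor, "")[[1]])
    })
    if (all(brute > 2)) break
  }
  expect_identical(match_anchor(rnd, anchor, 2), NA_integer_)

  # anchor longer than read is an absence, not an error
  expect_identical(match_anchor("ACGT", anchor, 2), NA_integer_)
})

test_that("canonicalize orients reads by the anchor", {
  cfg <- parser_config("NTA")
  read <- paste0(anchor, "CTAC", "CAA", DEFAULT_APP_ADAPTER)
  cz <- canonicalize(read, cfg)
  expect_identical(cz$read, read)
  expect_false(cz$flipped)

  rc <- revcomp(read, "DNA")
  cz2 <- canonicalize(rc, cfg)
  expect_identical(cz2$read, read)
  expect_true(cz2$flipped)

  expect_identical(canonicalize(strrep("T", 60), cfg)$status, "NO_ANCHOR")
})

test_that("composition reads recover template-sense randomized bases", {
  cfg <- parser_config("COMPOSITION")
  p <- parse_composition_read(paste0(anchor, "CTAC", strrep("G", 12)), cfg)
  expect_identical(p$status, "OK")
  expect_identical(p$n_bases, "GUAG")
  expect_identical(p$payload, "")

  p2 <- parse_composition_read(paste0(anchor, "TTTT", strrep("G", 5)), cfg)
  expect_identical(p2$n_bases, "AAAA")

  expect_identical(parse_composition_read(strrep("A", 40), cfg)$status,
                   "NO_ANCHOR")
  # anchor present but read truncated inside the variable region
  expect_identical(parse_composition_read(paste0(anchor, "CT"), cfg)$status,
                   "NO_ADAPTER")
})

test_that("NTA reads extract the payload between variable region and adapter", {
  cfg <- parser_config("NTA")
  p <- parse_nta_read(paste0(anchor, "CTAC", "CAA", DEFAULT_APP_ADAPTER), cfg)
  expect_identical(p$status, "OK")
  expect_identical(p$n_bases, "GUAG")
  expect_identical(p$payload, "CAA")  # synthesis order, literally

  # the "-" category: ligation directly after the template complement
  p0 <- parse_nta_read(paste0(anchor, "CTAC", DEFAULT_APP_ADAPTER), cfg)
  expect_identical(p0$status, "OK")
  expect_identical(p0$payload, "")

  p3 <- parse_nta_read(paste0(anchor, "CTAC", "CAA"), cfg)
  expect_identical(p3$status, "NO_ADAPTER")
})

test_that("junction reads apply the maximal-assignment triplet convention", {
  g3 <- tso_g3()
  ct <- cdna_of_tso(g3)
  body <- substr(ct, 4, 42)
  cfg <- parser_config("JUNCTION", ctso = ct)

  p <- parse_junction_read(paste0(anchor, "CTAC", "CCCC", body), cfg)
  expect_identical(p$status, "OK")
  expect_identical(p$payload, "C")  # CCCC parses as extras "C" + TSO "CCC"

  p0 <- parse_junction_read(paste0(anchor, "CTAC", "CCC", body), cfg)
  expect_identical(p0$payload, "")

  pm <- parse_junction_read(paste0(anchor, "CTAC", "CAC", body), cfg)
  expect_identical(pm$status, "TRIPLET_MISMATCH")

  pn <- parse_junction_read(paste0(anchor, "CTAC", "CCC"), cfg)
  expect_identical(pn$status, "NO_ADAPTER")
})

test_that("parsing round-trips simulator output exactly at zero error rate", {
  g3 <- tso_g3()
  for (preset in c("capped", "oh")) {
    chem <- preset_end_chem(preset)
    params <- sim_preset(preset)

    nl <- simulate_library("NTA", 400, tpl4(chem), NULL, params, seed = 21)
    np <- parse_reads(nl$reads$seq, parser_config("NTA"), nl$reads$read_id)
    expect_true(all(np$status == "OK"))
    expect_identical(np$n_bases, nl$truth$n_bases)
    expect_identical(np$payload, nl$truth$nta_string)

    jl <- simulate_library("JUNCTION", 400, tpl4(chem), g3, params, seed = 22)
    jp <- parse_reads(jl$reads$seq, parser_config("JUNCTION",
                                                  ctso = cdna_of_tso(g3)),
                      jl$reads$read_id)
    sw <- jl$truth$n_switches > 0
    expect_identical(jp$status == "OK", sw)  # dropout of non-switched reads
    expect_identical(jp$payload[sw], jl$truth$junction_extras[sw])
    expect_identical(jp$n_bases[sw], jl$truth$n_bases[sw])

    cl <- simulate_library("COMPOSITION", 400, tpl4(chem), NULL, params,
                           seed = 23)
    cp <- parse_reads(cl$reads$seq, parser_config("COMPOSITION"),
                      cl$reads$read_id)
    expect_true(all(cp$status == "OK"))
    expect_identical(cp$n_bases, cl$truth$n_bases)
  }
})

test_that("status conservation: every read gets exactly one status", {
  params <- sim_preset("oh", seq_error_rate = 0.05)
  lib <- simulate_library("NTA", 500, tpl4("HYDROXYL"), NULL, params, seed = 31)
  parsed <- parse_reads(lib$reads$seq, parser_config("NTA"))
  s <- parse_summary(parsed)
  expect_identical(s$total, 500L)
  expect_identical(sum(unlist(s[PARSE_STATUSES])), 500L)
  expect_identical(sum(parsed$status == "OK"), s$OK)
})

test_that("reverse-complemented input yields identical fields with flipped flag", {
  lib <- simulate_library("NTA", 200, tpl4("M7G_CAP"), NULL,
                          sim_preset("capped"), seed = 41)
  cfg <- parser_config("NTA")
  fwd <- parse_reads(lib$reads$seq, cfg)
  rc <- vapply(lib$reads$seq, revcomp, "", out_alphabet = "DNA",
               USE.NAMES = FALSE)
  rev <- parse_reads(rc, cfg)
  expect_identical(rev$status, fwd$status)
  expect_identical(rev$n_bases, fwd$n_bases)
  expect_identical(rev$payload, fwd$payload)
  ok <- fwd$status == "OK"
  expect_true(all(fwd$orientation_flipped[ok] == FALSE))
  expect_true(all(rev$orientation_flipped[ok] == TRUE))
})

test_that("FASTQ round-trips through Biostrings I/O", {
  lib <- simulate_library("NTA", 50, tpl4(), NULL, sim_preset("capped"),
                          seed = 51)
  fp <- tempfile(fileext = ".fastq")
  write_fastq(lib$reads$read_id, lib$reads$seq, fp)
  fq <- read_fastq(fp)
  expect_identical(fq$read_id, lib$reads$read_id)
  expect_identical(fq$seq, lib$reads$seq)
  parsed <- parse_fastq(fp, parser_config("NTA"))
  expect_identical(parsed$payload, lib$truth$nta_string)
  unlink(fp)
})
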