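# Stochastic generative model of first-strand synthesis: at every
# post-template opportunity the reverse transcriptase draws one event from a
# categorical distribution over propensities -- add a nontemplated base,
# switch onto the TSO, or terminate. Only event order/identity matter for the
# observables modeled here, so the competition is an embedded discrete chain,
# not continuous time.

#' Simulation parameters for the competition model
#'
#' @param eta Addition propensities. Either a named vector `c(A=,C=,G=,T=)`
#'   (constant propensities) or a matrix with columns A/C/G/T whose row `i`
#'   applies when the current post-template overhang has length `i - 1`
#'   (last row recycled beyond the schedule). All values must be >= 0.
#' @param sigma Termination propensity per opportunity (> 0 unless `max_nta`
#'   is finite).
#' @param kappa_ts Scale on the annealing score for the switching propensity.
#' @param w_gc,w_at Annealing weights for G:C and A:T/A:U terminal pairs.
#' @param kappa_blunt Zero-overlap ("blunt") switching score; lets the model
#'   express switching that does not require base pairing at all.
#' @param cap_c_prob Probability that an m7G-capped template templates a +C as
#'   the first post-template base (applies to `M7G_CAP` templates only). The
#'   cap-templated C precedes the competition loop and is flagged separately
#'   in the event log.
#' @param dntp_conc Relative dNTP concentrations, named `c(A=,C=,G=,T=)`;
#'   multiplies `eta` as `conc^alpha`. Default balanced `1,1,1,1`.
#' @param alpha Concentration exponent.
#' @param max_switches Maximum template switches per molecule (concatemer
#'   bound). A 5'-biotinylated TSO should be run with `max_switches = 1`.
#' @param max_nta Hard cap on additions within one segment; `Inf` allowed when
#'   `sigma > 0`.
#' @param delay_steps Number of initial post-template opportunities during
#'   which switching is disabled (termination still applies); models delayed
#'   TSO addition.
#' @param seq_error_rate Per-base substitution probability applied to emitted
#'   reads.
#' @param seed Optional integer; used by [simulate_library()] when its own
#'   `seed` argument is missing.
#' @return Object of class `sim_params`.
#' @export
sim_params <- function(eta = c(A = 1, C = 1, G = 1, T = 1),
                       sigma = 1,
                       kappa_ts = 1,
                       w_gc = 3, w_at = 1,
                       kappa_blunt = 0,
                       cap_c_prob = 0,
                       dntp_conc = c(A = 1, C = 1, G = 1, T = 1),
                       alpha = 1,
                       max_switches = 3L,
                       max_nta = 10,
                       delay_steps = 0L,
                       seq_error_rate = 0,
                       seed = NULL) {
  if (is.null(dim(eta))) {
    eta <- matrix(as.numeric(eta[DNA_BASES]), nrow = 1,
                  dimnames = list(NULL, DNA_BASES))
  } else {
    eta <- as.matrix(eta)
    if (is.null(colnames(eta))) colnames(eta) <- DNA_BASES
    eta <- eta[, DNA_BASES, drop = FALSE]
  }
  if (anyNA(eta) || any(eta < 0)) stop("invalid `eta`: propensities must be >= 0")
  if (!is.numeric(sigma) || sigma < 0) stop("invalid `sigma`: must be >= 0")
  if (sigma == 0 && !is.finite(max_nta))
    stop("invalid `sigma`/`max_nta`: need sigma > 0 or finite max_nta so synthesis terminates")
  if (kappa_ts < 0) stop("invalid `kappa_ts`: must be >= 0")
  if (w_gc < 0 || w_at < 0) stop("invalid `w_gc`/`w_at`: must be >= 0")
  if (kappa_blunt < 0) stop("invalid `kappa_blunt`: must be >= 0")
  if (cap_c_prob < 0 || cap_c_prob > 1) stop("invalid `cap_c_prob`: must lie in [0, 1]")
  dntp_conc <- dntp_conc[DNA_BASES]
  if (anyNA(dntp_conc) || any(dntp_conc <= 0))
    stop("invalid `dntp_conc`: needs positive values for A, C, G, T")
  if (max_switches < 0) stop("invalid `max_switches`: must be >= 0")
  if (is.finite(max_nta) && max_nta < 0) stop("invalid `max_nta`: must be >= 0")
  if (delay_steps < 0) stop("invalid `delay_steps`: must be >= 0")
  if (seq_error_rate < 0 || seq_error_rate >= 1)
    stop("invalid `seq_error_rate`: must lie in [0, 1)")
  structure(
    list(eta = eta, sigma = as.numeric(sigma), kappa_ts = as.numeric(kappa_ts),
         w_gc = as.numeric(w_gc), w_at = as.numeric(w_at),
         kappa_blunt = as.numeric(kappa_blunt),
         cap_c_prob = as.numeric(cap_c_prob),
         dntp_conc = as.numeric(dntp_conc), alpha = as.numeric(alpha),
         max_switches = as.integer(max_switches), max_nta = max_nta,
         delay_steps = as.integer(delay_steps),
         seq_error_rate = as.numeric(seq_error_rate), seed = seed),
    class = "sim_params")
}

#' Shipped parameter presets
#'
#' Parameter tables calibrated so that the model reproduces the qualitative
#' patterns observed for each 5'-end chemistry: under `"capped"` the modal
#' nontemplated addition is three bases with +CAA the most frequent string and
#' junction extras modally a single +C; under `"oh"` and `"p"` (uncapped) the
#' modal addition is a single base and junction extras are modally absent.
#' The numbers are calibration choices of this package, not measured
#' constants.
#'
#' @param name `"capped"`, `"oh"`, or `"p"`.
#' @param ... Overrides passed on to [sim_params()] (e.g. `dntp_conc`,
#'   `delay_steps`, `seq_error_rate`, `seed`).
#' @return A `sim_params` object.
#' @export
sim_preset <- function(name = c("capped", "oh", "p"), ...) {
  name <- match.arg(name)
  base <- switch(name,
    capped = list(
      eta = rbind(c(A = 0.40, C = 5.00, G = 0.50, T = 0.20),
                  c(A = 6.00, C = 1.00, G = 0.40, T = 0.20),
                  c(A = 5.00, C = 0.80, G = 0.40, T = 0.20),
                  c(A = 0.25, C = 0.15, G = 0.10, T = 0.05)),
      sigma = 1, kappa_ts = 4.0, kappa_blunt = 0.2,
      w_gc = 3, w_at = 1, cap_c_prob = 0.9),
    oh = list(
      eta = rbind(c(A = 1.20, C = 1.00, G = 0.90, T = 0.35),
                  c(A = 0.35, C = 0.25, G = 0.20, T = 0.10)),
      sigma = 1, kappa_ts = 0.5, kappa_blunt = 5.0,
      w_gc = 3, w_at = 1, cap_c_prob = 0),
    p = list(
      eta = rbind(c(A = 1.40, C = 1.20, G = 1.00, T = 0.40),
                  c(A = 0.40, C = 0.30, G = 0.25, T = 0.12)),
      sigma = 1, kappa_ts = 0.5, kappa_blunt = 5.0,
      w_gc = 3, w_at = 1, cap_c_prob = 0))
  do.call(sim_params, utils::modifyList(base, list(...)))
}

#' End chemistry matching a preset name
#' @param name Preset name as in [sim_preset()].
#' @return One of `"M7G_CAP"`, `"HYDROXYL"`, `"MONOPHOSPHATE"`.
#' @export
preset_end_chem <- function(name = c("capped", "oh", "p")) {
  switch(match.arg(name), capped = "M7G_CAP", oh = "HYDROXYL",
         p = "MONOPHOSPHATE")
}

# Derived quantities used by the inner loop; computed once per run.
.prep_params <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  eff <- sweep(params$eta, 2, params$dntp_conc^params$alpha, `*`)
  params$eff_eta <- eff
  params$n_eta_rows <- nrow(eff)
  params$row_cum <- lapply(seq_len(nrow(eff)), function(i) cumsum(eff[i, ]))
  params$row_tot <- vapply(params$row_cum, function(x) x[4L], numeric(1))
  params
}

.pair_weight <- function(b_cdna, b_ribo, w_gc, w_at) {
  if ((b_cdna == "C" && b_ribo == "G") || (b_cdna == "G" && b_ribo == "C"))
    return(w_gc)
  if ((b_cdna == "A" && (b_ribo == "U" || b_ribo == "T")) ||
      ((b_cdna == "T") && b_ribo == "A"))
    return(w_at)
  0
}

# overhang: character vector (cDNA 5'->3'); ribo: character vector length 3
# (TSO ribonucleotides 5'->3').
.switch_score_vec <- function(overhang, ribo, w_gc, w_at, kappa_blunt) {
  best <- kappa_blunt
  n <- length(overhang)
  for (L in seq_len(min(n, 3L))) {
    s <- 0
    for (i in seq_len(L)) {
      w <- .pair_weight(overhang[n - L + i], ribo[4L - i], w_gc, w_at)
      if (w == 0) { s <- 0; break }
      s <- s + w
    }
    if (s > best) best <- s
  }
  best
}

#' Annealing score between the cDNA overhang and a TSO 3' end
#'
#' Scores every terminal overlap length L in 0..3 between the 3' end of the
#' post-template overhang and the 3'-terminal ribonucleotides of the TSO
#' (antiparallel pairing). An overlap scores the sum of `w_gc` (G:C pairs) and
#' `w_at` (A:T / A:U pairs) over its L pairs; any mismatched pair voids that
#' overlap. L = 0 scores `kappa_blunt`. The returned score is the maximum over
#' overlaps, and the switching propensity is `kappa_ts * switch_score(...)`.
#'
#' @param overhang DNA string: the post-template 3' suffix of the nascent
#'   cDNA (may be empty).
#' @param tso A [tso()].
#' @param params A [sim_params()] (supplies `w_gc`, `w_at`, `kappa_blunt`).
#' @return Nonnegative score.
#' @examples
#' p <- sim_params(w_gc = 3, w_at = 1, kappa_blunt = 0)
#' switch_score("CAA", tso("UUG"), p)  # C:G + A:U + A:U = 5
#' @export
switch_score <- function(overhang, tso, params) {
  stopifnot(inherits(tso, "tso"))
  ov <- if (nzchar(overhang)) strsplit(toupper(overhang), "", fixed = TRUE)[[1]]
        else character(0)
  ribo <- strsplit(tso$ribo3, "", fixed = TRUE)[[1]]
  .switch_score_vec(ov, ribo, params$w_gc, params$w_at, params$kappa_blunt)
}

# Core event loop. base_cdna: full template complement (DNA, 5'->3').
# tso_info: NULL or list(ctso = 42-nt string, ribo = char vector length 3).
.sim_core <- function(base_cdna, end_chem, tso_info, pp) {
  overhang <- character(0)
  segs <- base_cdna
  capc <- FALSE
  if (end_chem == "M7G_CAP" && pp$cap_c_prob > 0 &&
      stats::runif(1) < pp$cap_c_prob) {
    overhang <- "C"
    capc <- TRUE
  }
  nsw <- 0L; opp <- 0L; seg_adds <- 0L
  nta <- NULL; junction <- ""
  has_tso <- !is.null(tso_info) && pp$max_switches > 0L
  term <- NULL
  repeat {
    opp <- opp + 1L
    ri <- min(length(overhang) + 1L, pp$n_eta_rows)
    tot_add <- pp$row_tot[ri]
    sw <- 0
    if (has_tso && opp > pp$delay_steps)
      sw <- pp$kappa_ts *
        .switch_score_vec(overhang, tso_info$ribo, pp$w_gc, pp$w_at,
                          pp$kappa_blunt)
    tot <- tot_add + sw + pp$sigma
    u <- stats::runif(1) * tot
    if (u < tot_add) {
      b <- DNA_BASES[findInterval(u, pp$row_cum[[ri]]) + 1L]
      overhang <- c(overhang, b)
      seg_adds <- seg_adds + 1L
      if (is.finite(pp$max_nta) && seg_adds >= pp$max_nta) {
        term <- "MAX_NTA"
        break
      }
    } else if (u < tot_add + sw) {
      if (nsw == 0L) {
        nta <- overhang
        junction <- paste(overhang, collapse = "")
      }
      segs <- c(segs, paste(overhang, collapse = ""), tso_info$ctso)
      nsw <- nsw + 1L
      overhang <- character(0)
      seg_adds <- 0L
      if (nsw >= pp$max_switches) {
        term <- "SWITCH_LIMIT"
        break
      }
    } else {
      term <- "NTA_STOP"
      break
    }
  }
  if (nsw == 0L) nta <- overhang
  list(cdna = paste0(paste(segs, collapse = ""),
                     paste(overhang, collapse = "")),
       nta_string = paste(nta, collapse = ""),
       cap_templated_c = capc,
       junction_extras = junction,
       n_switches = nsw,
       terminated_by = term)
}

#' Simulate one first-strand synthesis event
#'
#' Synthesizes the full complement of `template`, optionally adds a
#' cap-templated +C (m7G-capped templates), then iterates the
#' addition/switch/termination competition until the molecule terminates.
#' A switch appends [cdna_of_tso()] to the cDNA; the additions made before the
#' first switch are logged as `junction_extras`. A switch that reaches
#' `max_switches` ends the molecule (`terminated_by = "SWITCH_LIMIT"`).
#'
#' `nta_string` logs the post-template additions of the first segment (equal
#' to `junction_extras` for switched molecules, and to all additions for
#' non-switched ones); the cap-templated C, when present, is its first base
#' and is additionally flagged by `cap_templated_c`.
#'
#' @param template An [build_template()] object with concrete (non-N) bases.
#' @param tso A [tso()] or `NULL` (no-TSO reaction).
#' @param params A [sim_params()].
#' @return Object of class `cdna_record`: fields `cdna`, `template_bases`,
#'   `nta_string`, `cap_templated_c`, `junction_extras`, `n_switches`,
#'   `terminated_by`.
#' @export
simulate_molecule <- function(template, tso = NULL, params = sim_params()) {
  stopifnot(inherits(template, "rna_template"))
  if (grepl("N", template$seq, fixed = TRUE))
    stop("simulate_molecule(): template has undrawn N positions; realize them first")
  pp <- .prep_params(params)
  tso_info <- NULL
  if (!is.null(tso)) {
    stopifnot(inherits(tso, "tso"))
    if (tso$biotin5) pp$max_switches <- min(pp$max_switches, 1L)
    tso_info <- list(ctso = cdna_of_tso(tso),
                     ribo = strsplit(tso$ribo3, "", fixed = TRUE)[[1]])
  }
  base_cdna <- revcomp(template$seq, "DNA")
  rec <- .sim_core(base_cdna, template$end_chem, tso_info, pp)
  nvar <- length(template$variable_positions)
  rec$template_bases <- substr(template$seq, 1L, nvar)
  structure(rec, class = "cdna_record")
}

#' @export
print.cdna_record <- function(x, ...) {
  cat("cDNA record: ", nchar(x$cdna), " nt, ", x$n_switches, " switch(es), ",
      "NTA '", if (nzchar(x$nta_string)) x$nta_string else "-", "', ",
      "terminated by ", x$terminated_by, "\n", sep = "")
  invisible(x)
}

.draw_variable_bases <- function(n, nvar, fixed_bases, baseline_comp) {
  fixed <- strsplit(fixed_bases, "", fixed = TRUE)[[1]]
  out <- matrix("", nrow = n, ncol = nvar)
  for (j in seq_len(nvar)) {
    if (fixed[j] != "N") {
      out[, j] <- fixed[j]
    } else {
      probs <- rep(0.25, 4)
      if (!is.null(baseline_comp)) {
        probs <- if (is.matrix(baseline_comp)) baseline_comp[j, RNA_BASES]
                 else baseline_comp[RNA_BASES]
        probs <- probs / sum(probs)
      }
      out[, j] <- sample(RNA_BASES, n, replace = TRUE, prob = probs)
    }
  }
  apply(out, 1, paste, collapse = "")
}

#' Simulate a sequencing library with ground truth
#'
#' Draws the template's randomized positions (uniformly, or from
#' `baseline_comp` to emulate synthesis bias), simulates each molecule with
#' [simulate_molecule()]'s event loop, and assembles the design-specific read:
#' \describe{
#'   \item{NTA}{cDNA + App-DNA adapter (3' ssDNA ligation readout).}
#'   \item{JUNCTION}{the cDNA itself; non-switched molecules are emitted but
#'     carry no cTSO segment, so they fail junction parsing -- mimicking
#'     library dropout.}
#'   \item{COMPOSITION}{cDNA + a geometric-length G run (terminal-transferase
#'     dG tailing readout).}
#' }
#' Substitution errors are applied at `params$seq_error_rate`.
#'
#' @param design `"NTA"`, `"JUNCTION"` or `"COMPOSITION"`.
#' @param n Number of reads (> 0).
#' @param template A [build_template()]; positions given as `N` are drawn per
#'   read.
#' @param tso A [tso()] or `NULL`.
#' @param params A [sim_params()].
#' @param seed Integer seed (defaults to `params$seed`); seeds R's RNG.
#' @param baseline_comp Optional baseline base composition for the randomized
#'   positions: named vector over A/C/G/U or a (positions x 4) matrix.
#' @param tail_mean Mean of the geometric G-tail length (COMPOSITION design).
#' @param adapter App-DNA adapter sequence appended in the NTA design.
#' @param id_prefix Read-id prefix.
#' @return Object of class `sim_library`: list with `reads` (data.frame:
#'   read_id, seq) and `truth` (one row per read: all event-log fields).
#' @export
simulate_library <- function(design = c("NTA", "JUNCTION", "COMPOSITION"),
                             n, template, tso = NULL,
                             params = sim_params(), seed = NULL,
                             baseline_comp = NULL, tail_mean = 12,
                             adapter = DEFAULT_APP_ADAPTER,
                             id_prefix = NULL) {
  design <- match.arg(design)
  if (!is.numeric(n) || n <= 0) stop("simulate_library(): n must be > 0")
  n <- as.integer(n)
  stopifnot(inherits(template, "rna_template"))
  seed <- seed %||% params$seed
  if (!is.null(seed)) set.seed(as.integer(seed))
  pp <- .prep_params(params)
  tso_info <- NULL
  if (!is.null(tso)) {
    stopifnot(inherits(tso, "tso"))
    if (tso$biotin5) pp$max_switches <- min(pp$max_switches, 1L)
    tso_info <- list(ctso = cdna_of_tso(tso),
                     ribo = strsplit(tso$ribo3, "", fixed = TRUE)[[1]])
  }

  nvar <- length(template$variable_positions)
  fixed_bases <- substr(template$seq, 1L, nvar)
  constant <- substr(template$seq, nvar + 1L, 25L)
  anchor <- .revcomp_chr(constant, "DNA")  # constant-region complement
  var_bases <- .draw_variable_bases(n, nvar, fixed_bases, baseline_comp)
  var_cdna <- .revcomp_chr(var_bases, "DNA")

  recs <- vector("list", n)
  for (i in seq_len(n)) {
    recs[[i]] <- .sim_core(paste0(anchor, var_cdna[i]), template$end_chem,
                           tso_info, pp)
  }
  cdna <- vapply(recs, `[[`, character(1), "cdna")

  reads <- switch(design,
    NTA = paste0(cdna, adapter),
    JUNCTION = cdna,
    COMPOSITION = {
      tails <- stats::rgeom(n, prob = 1 / (1 + tail_mean))
      paste0(cdna, strrep("G", tails))
    })
  if (params$seq_error_rate > 0)
    reads <- apply_seq_errors(reads, params$seq_error_rate)

  id_prefix <- id_prefix %||% tolower(design)
  ids <- sprintf("%s_%06d", id_prefix, seq_len(n))
  nmat <- do.call(rbind, strsplit(var_bases, "", fixed = TRUE))
  truth <- data.frame(
    read_id = ids,
    design = design,
    end_chem = template$end_chem,
    n1 = nmat[, 1],
    n2 = if (nvar >= 2) nmat[, 2] else NA_character_,
    n3 = if (nvar >= 3) nmat[, 3] else NA_character_,
    n4 = if (nvar >= 4) nmat[, 4] else NA_character_,
    n_bases = var_bases,
    nta_string = vapply(recs, `[[`, character(1), "nta_string"),
    cap_templated_c = vapply(recs, `[[`, logical(1), "cap_templated_c"),
    junction_extras = vapply(recs, `[[`, character(1), "junction_extras"),
    n_switches = vapply(recs, `[[`, integer(1), "n_switches"),
    terminated_by = vapply(recs, `[[`, character(1), "terminated_by"),
    cdna_length = nchar(cdna),
    stringsAsFactors = FALSE)

  structure(list(reads = data.frame(read_id = ids, seq = reads,
                                    stringsAsFactors = FALSE),
                 truth = truth, design = design,
                 end_chem = template$end_chem),
            class = "sim_library")
}

#' @export
print.sim_library <- function(x, ...) {
  cat("Simulated ", x$design, " library: ", nrow(x$reads), " reads (",
      x$end_chem, "); switch fraction ",
      signif(mean(x$truth$n_switches > 0), 3), "\n", sep = "")
  invisible(x)
}

#' Apply uniform substitution errors to reads
#'
#' Each base is independently substituted with probability `rate` to a
#' uniformly chosen different base; lengths are preserved.
#'
#' @param seqs Character vector of DNA sequences.
#' @param rate Substitution probability in `[0, 1)`.
#' @return Character vector, same shape.
#' @export
apply_seq_errors <- function(seqs, rate) {
  if (!is.numeric(rate) || rate < 0 || rate >= 1)
    stop("apply_seq_errors(): rate must lie in [0, 1)")
  if (rate == 0) return(seqs)
  vapply(seqs, function(s) {
    nc <- nchar(s)
    if (nc == 0L) return(s)
    k <- stats::rbinom(1, nc, rate)
    if (k == 0L) return(s)
    pos <- sample.int(nc, k)
    ch <- strsplit(s, "", fixed = TRUE)[[1]]
    ch[pos] <- vapply(ch[pos],
                      function(b) sample(setdiff(DNA_BASES, b), 1L),
                      character(1))
    paste(ch, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Emit a synthetic CE peak table from simulated molecules
#'
#' Bins molecules by total cDNA length and returns one product peak per
#' distinct length with area (and height) proportional to the molecule count,
#' plus an optional unextended-primer peak. With zero jitter, areas are exact
#' counts, so downstream [ts_efficiency()] equals the molecule-level switch
#' fraction exactly.
#'
#' @param records A `sim_library`, its `truth` data.frame, or a list of
#'   `cdna_record`s.
#' @param primer_len Unextended primer size (nt).
#' @param primer_area Area of the unextended-primer peak (0 = omit).
#' @param size_jitter_sd Gaussian jitter SD on peak sizes (nt).
#' @param area_cv Multiplicative coefficient of variation on areas.
#' @return A calibrated [peak_table()].
#' @export
emit_ce_peaks <- function(records, primer_len = 20, primer_area = 0,
                          size_jitter_sd = 0, area_cv = 0) {
  lens <- .record_lengths(records)
  if (length(lens) == 0L) stop("emit_ce_peaks(): no molecules supplied")
  tab <- table(lens)
  sizes <- as.numeric(names(tab))
  areas <- as.numeric(tab)
  if (primer_area > 0) {
    sizes <- c(primer_len, sizes)
    areas <- c(primer_area, areas)
  }
  if (size_jitter_sd > 0) sizes <- sizes + stats::rnorm(length(sizes), 0, size_jitter_sd)
  if (area_cv > 0) areas <- areas * pmax(0, 1 + stats::rnorm(length(areas), 0, area_cv))
  peak_table(size_nt = sizes, height = areas, area = areas, calibrated = TRUE)
}

.record_lengths <- function(records) {
  if (inherits(records, "sim_library")) return(records$truth$cdna_length)
  if (is.data.frame(records)) return(records$cdna_length)
  if (is.list(records))
    return(vapply(records, function(r) nchar(r$cdna), numeric(1)))
  stop("unsupported records input")
}

.record_cdna <- function(records) {
  if (inherits(records, "sim_library"))
    stop("emit_masses(): pass cdna_record objects or cDNA strings, not a library; ",
         "library reads carry adapters/tails")
  if (is.character(records)) return(records)
  if (is.list(records))
    return(vapply(records, `[[`, character(1), "cdna"))
  stop("unsupported records input")
}

#' Emit deconvoluted intact masses for simulated cDNA products
#'
#' Computes the theoretical [oligo_mass()] of each molecule's cDNA, optionally
#' Gaussian-perturbed by an instrument SD.
#'
#' @param records List of `cdna_record`s or character vector of cDNA strings.
#' @param table A [default_mass_table()]-style mass table.
#' @param five_prime 5' end state of the cDNA (`"PHOSPHATE"` or `"OH"`).
#' @param end_mods Character vector of end-modification names looked up in
#'   `table$end_mod_mass`.
#' @param sd Gaussian mass error SD (Da).
#' @return Numeric vector of masses (Da).
#' @export
emit_masses <- function(records, table = default_mass_table(),
                        five_prime = "PHOSPHATE", end_mods = character(),
                        sd = 0) {
  cd <- .record_cdna(records)
  if (length(cd) == 0L) stop("emit_masses(): no molecules supplied")
  m <- vapply(cd, oligo_mass, numeric(1), five_prime = five_prime,
              mods = end_mods, table = table, USE.NAMES = FALSE)
  if (sd > 0) m <- m + stats::rnorm(length(m), 0, sd)
  m
}
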