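# Turns parsed reads into the reported statistics: positional composition
# with template-baseline normalization, NTA and junction profiles with a
# display-abundance filter, and closed-form per-step propensity estimation.

#' Positional base composition of the randomized template positions
#'
#' @param n_bases Character vector of template-sense RNA strings (all the
#'   same length, typically the 4 called N1..N4 bases of OK reads).
#' @return Object of class `composition_matrix`: `counts` and `fractions`
#'   (positions x A/C/G/U) and `n_reads`.
#' @export
positional_composition <- function(n_bases) {
  n_bases <- n_bases[!is.na(n_bases)]
  if (length(n_bases) == 0L)
    stop("positional_composition(): no called reads supplied")
  w <- unique(nchar(n_bases))
  if (length(w) != 1L)
    stop("positional_composition(): inputs must all have the same length")
  mat <- do.call(rbind, strsplit(n_bases, "", fixed = TRUE))
  counts <- t(apply(mat, 2, function(col)
    table(factor(col, levels = RNA_BASES))))
  counts <- matrix(as.integer(counts), ncol = 4,
                   dimnames = list(paste0("N", seq_len(w)), RNA_BASES))
  structure(list(counts = counts,
                 fractions = counts / rowSums(counts),
                 n_reads = length(n_bases)),
            class = "composition_matrix")
}

#' @export
print.composition_matrix <- function(x, ...) {
  cat("Positional composition over", x$n_reads, "reads\n")
  print(round(x$fractions, 4))
  invisible(x)
}

#' Normalize an observed composition by a template baseline
#'
#' Per position, `normalized_b = (obs_b / base_b) / sum_b'(obs_b' / base_b')`.
#' This removes the composition bias introduced during template synthesis
#' ("hand-mix" misrepresentation) so that the displayed fractions reflect the
#' enzymatic bias alone. A base with zero baseline but nonzero observed
#' fraction is flagged `NA` (with a warning) and the position renormalized
#' over the remaining bases.
#'
#' @param observed,baseline `composition_matrix` objects over the same
#'   positions.
#' @return A `composition_matrix` whose `fractions` are the normalized
#'   fractions (`counts` carried over from `observed`).
#' @export
normalize_composition <- function(observed, baseline) {
  stopifnot(inherits(observed, "composition_matrix"),
            inherits(baseline, "composition_matrix"))
  fo <- observed$fractions
  fb <- baseline$fractions
  if (!identical(dim(fo), dim(fb)))
    stop("normalize_composition(): matrices must cover the same positions")
  ratio <- fo / fb
  bad <- fb == 0 & fo > 0
  if (any(bad)) {
    warning("normalize_composition(): zero baseline with nonzero observed ",
            "fraction; affected entries set NA and positions renormalized")
    ratio[bad] <- NA_real_
  }
  ratio[fb == 0 & fo == 0] <- 0
  norm <- ratio / rowSums(ratio, na.rm = TRUE)
  structure(list(counts = observed$counts, fractions = norm,
                 n_reads = observed$n_reads),
            class = "composition_matrix")
}

.freq_table <- function(x) {
  tab <- table(x)
  stats::setNames(as.numeric(tab) / length(x), names(tab))
}

.profile_stratum <- function(payloads, min_frac) {
  lab <- ifelse(nzchar(payloads), payloads, "-")
  string_raw <- sort(.freq_table(lab), decreasing = TRUE)
  pooled <- string_raw
  small <- pooled < min_frac
  if (any(small)) {
    pooled <- c(pooled[!small], other = sum(pooled[small]))
  }
  len_freq <- .freq_table(nchar(payloads))
  list(string_freq = pooled, string_freq_raw = string_raw,
       length_freq = len_freq, n = length(payloads))
}

#' Nontemplated-addition profile
#'
#' Computes, overall and stratified by the first template base, the
#' distribution of NTA strings (empty payloads reported as the `"-"`
#' category) and of NTA lengths. Strings below `min_frac` relative abundance
#' are pooled into `"other"` for display -- fractions are computed before
#' pooling and the unpooled distribution is returned alongside
#' (`string_freq_raw`).
#'
#' @param payloads Character vector of NTA strings (possibly empty) from OK
#'   reads.
#' @param first_base Optional vector of first template bases (RNA) used for
#'   stratification; `NULL` gives the ALL stratum only.
#' @param min_frac Display-abundance filter (default 0.05).
#' @return Object of class `nta_profile`: list `strata` mapping stratum name
#'   (`"A"`, `"C"`, `"G"`, `"U"`, `"ALL"`) to `string_freq`,
#'   `string_freq_raw`, `length_freq`, `n`.
#' @export
nta_profile <- function(payloads, first_base = NULL, min_frac = 0.05) {
  if (length(payloads) == 0L) stop("nta_profile(): no payloads supplied")
  if (anyNA(payloads)) stop("nta_profile(): payloads must be non-NA (OK reads)")
  strata <- list(ALL = .profile_stratum(payloads, min_frac))
  if (!is.null(first_base)) {
    stopifnot(length(first_base) == length(payloads))
    for (b in intersect(RNA_BASES, unique(first_base))) {
      strata[[b]] <- .profile_stratum(payloads[first_base == b], min_frac)
    }
  }
  structure(list(strata = strata, min_frac = min_frac), class = "nta_profile")
}

#' @export
print.nta_profile <- function(x, ...) {
  s <- x$strata$ALL
  cat("NTA profile (ALL stratum, n = ", s$n, ")\n", sep = "")
  cat("  lengths: ", paste(sprintf("%s:%.3f", names(s$length_freq),
                                   s$length_freq), collapse = "  "), "\n")
  top <- utils::head(s$string_freq, 6)
  cat("  strings: ", paste(sprintf("%s:%.3f", names(top), top),
                           collapse = "  "), "\n")
  invisible(x)
}

#' Profile of cDNA-cTSO junction extras
#'
#' Same shape as [nta_profile()] but computed over junction payloads, with an
#' additional identity distribution over single-base extras.
#'
#' @inheritParams nta_profile
#' @return An `nta_profile` with an extra `single_base_identity` element.
#' @export
junction_profile <- function(payloads, first_base = NULL, min_frac = 0.05) {
  prof <- nta_profile(payloads, first_base, min_frac)
  singles <- payloads[nchar(payloads) == 1L]
  prof$single_base_identity <-
    if (length(singles)) .freq_table(singles) else numeric(0)
  class(prof) <- c("junction_profile", "nta_profile")
  prof
}

#' Maximum-likelihood per-step propensity estimates
#'
#' Under the constant-propensity competition model with no TSO, every
#' post-template opportunity is an i.i.d. categorical draw over {add A, add
#' C, add G, add T, stop}. The MLE is the observed per-step frequency:
#' `q_b = additions of b / total steps`, `p_stop = molecules / total steps`,
#' with `total steps = sum of NTA lengths + number of molecules`. Binomial
#' standard errors are attached.
#'
#' @param nta_strings Character vector of NTA strings (empty = no addition).
#' @return List with `q` (named per-base step probabilities), `p_stop`,
#'   `se_q`, `se_p_stop`, `total_steps`, `n_molecules`.
#' @export
estimate_step_propensities <- function(nta_strings) {
  if (length(nta_strings) == 0L)
    stop("estimate_step_propensities(): no molecules supplied")
  if (anyNA(nta_strings))
    stop("estimate_step_propensities(): NA strings not allowed")
  n_mol <- length(nta_strings)
  bases <- unlist(strsplit(nta_strings[nzchar(nta_strings)], "", fixed = TRUE))
  counts <- table(factor(bases, levels = DNA_BASES))
  total <- sum(counts) + n_mol
  q <- as.numeric(counts) / total
  names(q) <- DNA_BASES
  p_stop <- n_mol / total
  list(q = q,
       p_stop = p_stop,
       se_q = sqrt(q * (1 - q) / total),
       se_p_stop = sqrt(p_stop * (1 - p_stop) / total),
       total_steps = total,
       n_molecules = n_mol)
}

#' Closed-form NTA string law under constant propensities
#'
#' With no TSO and constant per-step propensities, the probability of an NTA
#' string b1..bk is `prod(q_{b_i}) * p_stop` with
#' `q_b = eta_b * conc_b^alpha / (A + sigma)`, `p_stop = sigma / (A + sigma)`,
#' `A = sum_b eta_b * conc_b^alpha`. Exposed so tests and analyses can
#' compare empirical distributions against the analytic law.
#'
#' @param params A [sim_params()] with a 1-row `eta` schedule.
#' @param max_len Truncation length for enumeration of the support.
#' @return Named numeric vector of probabilities over strings (`"-"` for the
#'   empty string), covering all strings up to `max_len` (tail mass left
#'   unassigned).
#' @export
nta_closed_form <- function(params, max_len = 8L) {
  if (nrow(params$eta) != 1L)
    stop("nta_closed_form(): requires a constant (1-row) eta schedule")
  e <- params$eta[1, ] * params$dntp_conc^params$alpha
  A <- sum(e)
  q <- e / (A + params$sigma)
  p_stop <- params$sigma / (A + params$sigma)
  out <- c("-" = p_stop)
  strings <- ""
  probs <- 1
  for (len in seq_len(max_len)) {
    strings <- as.vector(outer(strings, DNA_BASES, paste0))
    probs <- as.vector(outer(probs, q))
    out <- c(out, stats::setNames(probs * p_stop, strings))
  }
  out
}
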