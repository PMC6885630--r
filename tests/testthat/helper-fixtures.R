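# Shared fixtures and independent oracles used across the suite.

tpl4 <- function(chem = "M7G_CAP", bases = "NNNN")
  build_template("FOUR_RN", bases, chem)

tso_g3 <- function(...) tso("GGG", ...)

# Independent reverse-complement oracle: per-base complement lookup then
# reversal, written without reusing package internals.
oracle_revcomp <- function(s, out = "DNA") {
  comp <- list(A = c(DNA = "T", RNA = "U"), C = c(DNA = "G", RNA = "G"),
               G = c(DNA = "C", RNA = "C"), T = c(DNA = "A", RNA = "A"),
               U = c(DNA = "A", RNA = "A"), N = c(DNA = "N", RNA = "N"))
  ch <- strsplit(s, "")[[1]]
  paste(rev(vapply(ch, function(b) comp[[b]][[out]], "")), collapse = "")
}

# Independent brute-force composition enumeration: recursive descent over
# counts, no matrix algebra shared with the implementation.
oracle_enumerate <- function(delta, tol, max_n, residue = c(A = 313.21,
                                                            C = 289.18,
                                                            G = 329.21,
                                                            T = 304.20)) {
  hits <- list()
  for (a in 0:max_n) for (c in 0:(max_n - a)) for (g in 0:(max_n - a - c))
    for (t in 0:(max_n - a - c - g)) {
      m <- a * residue["A"] + c * residue["C"] + g * residue["G"] +
        t * residue["T"]
      if (abs(m - delta) <= tol)
        hits[[length(hits) + 1L]] <- c(A = a, C = c, G = g, T = t)
    }
  hits
}

comp_key <- function(df) {
  if (nrow(df) == 0) return(character(0))
  sort(apply(df[, c("A", "C", "G", "T"), drop = FALSE], 1, paste,
             collapse = ":"))
}

tv_distance <- function(p, q) {
  keys <- union(names(p), names(q))
  pv <- ifelse(keys %in% names(p), p[keys], 0)
  qv <- ifelse(keys %in% names(q), q[keys], 0)
  sum(abs(pv - qv)) / 2
}

empirical_string_freq <- function(strings) {
  lab <- ifelse(nzchar(strings), strings, "-")
  tab <- table(lab)
  stats::setNames(as.numeric(tab) / length(strings), names(tab))
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                                collapse = "")
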