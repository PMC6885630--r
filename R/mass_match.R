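# Theoretical oligonucleotide masses and inversion of deconvoluted intact
# masses into candidate added-nucleotide compositions. Average (not
# monoisotopic) masses are the default, matching ion-trap intact-mass
# deconvolution practice.

#' Default (average) DNA mass table
#'
#' Standard chemistry constants: average internal-residue masses of the four
#' deoxynucleotide monophosphates, the mass of water (terminal H/OH), and the
#' HPO3 mass subtracted for a 5'-OH end. End-modification masses (FAM,
#' biotin, ...) are user-supplied configuration, not shipped constants.
#'
#' @param end_mod_mass Optional named numeric vector of end-modification
#'   masses (Da).
#' @return Object of class `mass_table`.
#' @export
default_mass_table <- function(end_mod_mass = numeric(0)) {
  structure(
    list(residue_mass = c(A = 313.21, C = 289.18, G = 329.21, T = 304.20),
         water_mass = 18.02,
         hpo3_mass = 79.98,
         end_mod_mass = end_mod_mass),
    class = "mass_table")
}

#' Monoisotopic DNA mass table
#' @inheritParams default_mass_table
#' @return Object of class `mass_table`.
#' @export
monoisotopic_mass_table <- function(end_mod_mass = numeric(0)) {
  structure(
    list(residue_mass = c(A = 313.05758, C = 289.04637, G = 329.05249,
                          T = 304.04604),
         water_mass = 18.01056,
         hpo3_mass = 79.96633,
         end_mod_mass = end_mod_mass),
    class = "mass_table")
}

.check_mass_table <- function(table) {
  stopifnot(inherits(table, "mass_table"))
  if (!identical(sort(names(table$residue_mass)), c("A", "C", "G", "T")))
    stop("mass table must have residue masses for exactly A, C, G, T")
  if (any(unlist(table[c("residue_mass", "water_mass", "hpo3_mass")]) <= 0))
    stop("mass table entries must be strictly positive")
  invisible(table)
}

#' Theoretical mass of a DNA oligonucleotide
#'
#' Sum of internal residue masses plus water, minus HPO3 when the 5' end is a
#' hydroxyl (the residue masses carry one phosphate each), plus any end
#' modifications.
#'
#' @param seq Nonempty DNA string.
#' @param five_prime `"PHOSPHATE"` or `"OH"`.
#' @param mods Character vector of modification names present in
#'   `table$end_mod_mass`.
#' @param table A mass table.
#' @return Mass in Da.
#' @examples
#' oligo_mass("A")               # 331.23
#' @export
oligo_mass <- function(seq, five_prime = c("PHOSPHATE", "OH"),
                       mods = character(), table = default_mass_table()) {
  five_prime <- match.arg(five_prime)
  .check_mass_table(table)
  if (!is.character(seq) || length(seq) != 1L || !nzchar(seq))
    stop("oligo_mass(): seq must be a nonempty DNA string")
  seq <- toupper(seq)
  .check_bases(seq, DNA_BASES, "seq")
  counts <- table(factor(strsplit(seq, "", fixed = TRUE)[[1]],
                         levels = DNA_BASES))
  m <- sum(as.numeric(counts) * table$residue_mass[DNA_BASES]) +
    table$water_mass
  if (five_prime == "OH") m <- m - table$hpo3_mass
  if (length(mods)) {
    unknown <- setdiff(mods, names(table$end_mod_mass))
    if (length(unknown))
      stop("oligo_mass(): unknown end modification(s): ",
           paste(unknown, collapse = ", "))
    m <- m + sum(table$end_mod_mass[mods])
  }
  m
}

#' Summed residue mass of a base-count composition
#'
#' @param counts Named integer vector over A/C/G/T (missing entries = 0).
#' @param table A mass table.
#' @return Mass shift in Da (no terminal water: this is an *added-residue*
#'   mass, the observable difference between an extended and a bare product).
#' @export
composition_mass <- function(counts, table = default_mass_table()) {
  full <- stats::setNames(numeric(4), DNA_BASES)
  full[names(counts)] <- counts
  sum(full * table$residue_mass[DNA_BASES])
}

#' Enumerate base compositions consistent with a mass shift
#'
#' Exhaustively enumerates all compositions `{A, C, G, T}` with total count
#' `<= max_n` whose summed residue mass lies within `tol` of `delta_mass`.
#' Near-isobaric ambiguity is surfaced, never silently resolved: every
#' composition within tolerance is returned, sorted by absolute mass error.
#'
#' @param delta_mass Observed mass shift (Da), e.g. product minus bare
#'   complement.
#' @param tol Mass tolerance (Da), > 0. Default 0.5 Da, a typical intact-mass
#'   deconvolution tolerance.
#' @param max_n Maximum total nucleotides in a composition.
#' @param table A mass table.
#' @return data.frame with columns `A`, `C`, `G`, `T`, `total`, `mass`,
#'   `error`, sorted by `abs(error)`; zero rows if nothing matches.
#' @export
enumerate_compositions <- function(delta_mass, tol = 0.5, max_n = 6L,
                                   table = default_mass_table()) {
  if (tol <= 0) stop("enumerate_compositions(): tol must be > 0")
  if (max_n < 0) stop("enumerate_compositions(): max_n must be >= 0")
  .check_mass_table(table)
  grid <- expand.grid(A = 0:max_n, C = 0:max_n, G = 0:max_n, T = 0:max_n)
  grid <- grid[rowSums(grid) <= max_n, , drop = FALSE]
  rm <- table$residue_mass[DNA_BASES]
  mass <- as.matrix(grid) %*% rm
  err <- mass - delta_mass
  keep <- abs(err) <= tol
  out <- grid[keep, , drop = FALSE]
  out$total <- rowSums(out[, DNA_BASES])
  out$mass <- mass[keep]
  out$error <- err[keep]
  out <- out[order(abs(out$error)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

.string_composition <- function(s) {
  if (!nzchar(s)) return(stats::setNames(integer(4), DNA_BASES))
  tab <- table(factor(strsplit(s, "", fixed = TRUE)[[1]], levels = DNA_BASES))
  stats::setNames(as.integer(tab), DNA_BASES)
}

#' Rank mass-consistent compositions by sequencing-observed priors
#'
#' For each composition, lists the sequencing-observed NTA strings with a
#' matching base multiset, ordered by their sequencing frequency; this is how
#' a base-order-blind MS observation is resolved into concrete species.
#' Strings unexplained by any composition and compositions unmatched by any
#' string are reported separately.
#'
#' @param compositions Result of [enumerate_compositions()] (or a data.frame
#'   with columns A/C/G/T).
#' @param string_freq Named numeric vector: NTA string -> fraction (`"-"` and
#'   `"other"` entries are ignored for matching).
#' @return List with `matches` (data.frame: string, A, C, G, T, prior),
#'   `unexplained_strings`, `unmatched_compositions` (row indices).
#' @export
rank_species <- function(compositions, string_freq) {
  strings <- setdiff(names(string_freq), c("-", "other"))
  comp_keys <- if (nrow(compositions))
    apply(compositions[, DNA_BASES, drop = FALSE], 1, paste, collapse = ":")
  else character(0)
  string_keys <- vapply(strings,
                        function(s) paste(.string_composition(s), collapse = ":"),
                        character(1))
  matched <- string_keys %in% comp_keys
  rows <- match(string_keys[matched], comp_keys)
  matches <- data.frame(string = strings[matched],
                        compositions[rows, DNA_BASES, drop = FALSE],
                        prior = as.numeric(string_freq[strings[matched]]),
                        stringsAsFactors = FALSE)
  matches <- matches[order(-matches$prior), , drop = FALSE]
  rownames(matches) <- NULL
  list(matches = matches,
       unexplained_strings = strings[!matched],
       unmatched_compositions = which(!comp_keys %in% string_keys))
}
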