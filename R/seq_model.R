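# Domain types and deterministic sequence arithmetic shared by the simulator
# and the parsers. Conventions used package-wide:
#   * all cDNA-side sequences are DNA-alphabet strings written 5'->3' on the
#     cDNA strand ("cDNA orientation");
#   * all templates are RNA-alphabet strings written 5'->3';
#   * indices are 0-based and intervals half-open.

DNA_BASES <- c("A", "C", "G", "T")
RNA_BASES <- c("A", "C", "G", "U")

#' Constant region of the 25-mer RNA template
#'
#' The study template is a 25-mer whose 5'-terminal positions are randomized
#' (either position 0 alone or positions 0-3) and whose remainder is constant.
#' `TEMPLATE_CONSTANT_21` is the constant suffix shared by the four-randomized
#' design (positions 4-24); `TEMPLATE_CONSTANT_24` is the constant suffix of
#' the single-N design (positions 1-24).
#'
#' @format Character scalars (RNA alphabet, 5'->3').
#' @name template_constants
NULL

#' @rdname template_constants
#' @export
TEMPLATE_CONSTANT_21 <- "AACUUCGUCGAGUACGCUCAA"

#' @rdname template_constants
#' @export
TEMPLATE_CONSTANT_24 <- "UAGAACUUCGUCGAGUACGCUCAA"

#' Default cDNA-side anchor: reverse complement of the constant 21-mer
#'
#' Every first-strand product starts (5'->3', cDNA orientation) with this
#' 21-nt constant-region complement; the parsers anchor on it.
#' @export
ANCHOR21_DEFAULT <- "TTGAGCGTACTCGACGAAGTT"

#' Placeholder 39-nt TSO body and App-DNA adapter
#'
#' The study's TSOs share a 39-nt DNA body 5' of the three terminal
#' ribonucleotides, and the nontemplated-addition library ligates a
#' 5'-adenylated ssDNA adapter to the cDNA 3' end. The concrete oligo
#' sequences are vendor/config values, not fixed by the method, so the package
#' ships documented placeholders of the correct lengths; override them in the
#' run config when modeling a specific protocol.
#' @name oligo_defaults
NULL

#' @rdname oligo_defaults
#' @export
DEFAULT_TSO_BODY <- "AAGCAGTGGTATCAACGCAGAGTACATGGGAGTGGTACC"

#' @rdname oligo_defaults
#' @export
DEFAULT_APP_ADAPTER <- "AGATCGGAAGAGCACACGTCT"

.COMPLEMENT_DNA <- c(A = "T", C = "G", G = "C", T = "A", U = "A", N = "N")
.COMPLEMENT_RNA <- c(A = "U", C = "G", G = "C", T = "A", U = "A", N = "N")

# Vectorized reverse complement without validation; internal fast path.
.revcomp_chr <- function(x, out_alphabet = "DNA") {
  to <- if (out_alphabet == "DNA") "TGCAAN" else "UGCAAN"
  y <- chartr("ACGTUN", to, x)
  vapply(strsplit(y, "", fixed = TRUE),
         function(s) paste(rev(s), collapse = ""), character(1))
}

#' Reverse complement of a nucleotide string
#'
#' @param seq Single nucleotide string (A/C/G/T/U/N, case-insensitive).
#' @param out_alphabet `"DNA"` or `"RNA"`; controls whether complements of A
#'   are written T or U.
#' @return The reverse complement, same length; `N` maps to `N`.
#' @examples
#' revcomp("GUAGAACUUCGUCGAGUACGCUCAA", "DNA")
#' @export
revcomp <- function(seq, out_alphabet = c("DNA", "RNA")) {
  out_alphabet <- match.arg(out_alphabet)
  if (!is.character(seq) || length(seq) != 1L || is.na(seq))
    stop("revcomp(): `seq` must be a single character string")
  seq <- toupper(seq)
  if (!nzchar(seq)) return(seq)
  bad <- setdiff(strsplit(seq, "", fixed = TRUE)[[1]],
                 c("A", "C", "G", "T", "U", "N"))
  if (length(bad))
    stop("revcomp(): non-nucleotide character(s): ",
         paste(unique(bad), collapse = ", "))
  .revcomp_chr(seq, out_alphabet)
}

.check_bases <- function(x, allowed, what) {
  bad <- setdiff(strsplit(x, "", fixed = TRUE)[[1]], allowed)
  if (length(bad))
    stop(what, " contains invalid character(s): ",
         paste(unique(bad), collapse = ", "))
  invisible(x)
}

END_CHEMISTRIES <- c("HYDROXYL", "MONOPHOSPHATE", "M7G_CAP")

#' Construct a 25-mer RNA template
#'
#' Builds the study's 25-mer template in one of two randomization designs:
#' `"SINGLE_N"` (only the first position varies; constant remainder
#' [TEMPLATE_CONSTANT_24]) or `"FOUR_RN"` (positions 0-3 randomized; constant
#' suffix [TEMPLATE_CONSTANT_21]). `first_bases` may contain `N` to denote a
#' position to be drawn at simulation time.
#'
#' @param design `"SINGLE_N"` or `"FOUR_RN"`.
#' @param first_bases RNA string of length 1 (`SINGLE_N`) or 4 (`FOUR_RN`);
#'   bases in A/C/G/U/N.
#' @param end_chem 5'-end chemistry: `"HYDROXYL"`, `"MONOPHOSPHATE"`, or
#'   `"M7G_CAP"`.
#' @param name Optional label.
#' @return An object of class `rna_template` with fields `name`, `seq`,
#'   `end_chem`, `variable_positions` (0-based), `design`.
#' @examples
#' build_template("SINGLE_N", "G", "M7G_CAP")
#' @export
build_template <- function(design = c("FOUR_RN", "SINGLE_N"), first_bases,
                           end_chem = END_CHEMISTRIES, name = NULL) {
  design <- match.arg(design)
  end_chem <- match.arg(end_chem)
  first_bases <- toupper(first_bases)
  want <- if (design == "SINGLE_N") 1L else 4L
  if (!is.character(first_bases) || length(first_bases) != 1L ||
      nchar(first_bases) != want)
    stop("build_template(): design ", design, " requires first_bases of length ",
         want, ", got ", nchar(first_bases))
  .check_bases(first_bases, c(RNA_BASES, "N"), "first_bases")
  constant <- if (design == "SINGLE_N") TEMPLATE_CONSTANT_24 else TEMPLATE_CONSTANT_21
  seq <- paste0(first_bases, constant)
  stopifnot(nchar(seq) == 25L)
  structure(
    list(name = name %||% paste0(design, "_", first_bases, "_", end_chem),
         seq = seq,
         end_chem = end_chem,
         variable_positions = seq_len(want) - 1L,
         design = design),
    class = "rna_template")
}

#' @export
print.rna_template <- function(x, ...) {
  cat("RNA template <", x$name, ">\n", sep = "")
  cat("  5'-", x$seq, "-3'  (", x$end_chem, ")\n", sep = "")
  cat("  variable positions (0-based): ",
      paste(x$variable_positions, collapse = ","), "\n", sep = "")
  invisible(x)
}

#' Construct a template-switching oligo (TSO)
#'
#' A TSO is a 39-nt DNA body followed by exactly three 3'-terminal
#' ribonucleotides (e.g. rGrGrG). A 5'-biotin modifier, used experimentally to
#' limit concatemer formation, is carried as a flag; the simulator maps it to
#' `max_switches = 1`.
#'
#' @param ribo3 RNA string of length 3 (the 3'-terminal ribonucleotides).
#' @param body_dna DNA string of length 39.
#' @param biotin5 Logical; 5'-biotin modifier present.
#' @param name Optional label.
#' @return An object of class `tso`.
#' @examples
#' tso("GGG")
#' tso("UUG", biotin5 = TRUE)
#' @export
tso <- function(ribo3, body_dna = DEFAULT_TSO_BODY, biotin5 = FALSE, name = NULL) {
  ribo3 <- toupper(ribo3); body_dna <- toupper(body_dna)
  if (nchar(ribo3) != 3L)
    stop("tso(): ribo3 must be exactly 3 ribonucleotides, got ", nchar(ribo3))
  if (nchar(body_dna) != 39L)
    stop("tso(): body_dna must be exactly 39 nt, got ", nchar(body_dna))
  .check_bases(ribo3, RNA_BASES, "ribo3")
  .check_bases(body_dna, DNA_BASES, "body_dna")
  structure(
    list(name = name %||% paste0("r", paste(strsplit(ribo3, "")[[1]],
                                            collapse = "r"), "_TSO"),
         body_dna = body_dna, ribo3 = ribo3, biotin5 = isTRUE(biotin5)),
    class = "tso")
}

#' @export
print.tso <- function(x, ...) {
  cat("TSO <", x$name, ">: 5'-", if (x$biotin5) "[biotin]" else "",
      x$body_dna, tolower(x$ribo3), "-3'\n", sep = "")
  invisible(x)
}

#' cDNA-orientation segment contributed by a template switch
#'
#' When the reverse transcriptase switches onto a TSO it copies the TSO
#' 3'->5', so the cDNA gains `revcomp(body + ribo3)` written in DNA alphabet.
#' The first three bases of the returned 42-mer are the complement of the
#' ribonucleotide 3' end, i.e. the junction-adjacent triplet the parser
#' expects (`"CCC"` for rGrGrG, `"CAA"` for rUrUrG).
#'
#' @param x A [tso()].
#' @return DNA string of length 42.
#' @export
cdna_of_tso <- function(x) {
  stopifnot(inherits(x, "tso"))
  revcomp(paste0(x$body_dna, x$ribo3), "DNA")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
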