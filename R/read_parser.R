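# Anchored parsing of the three amplicon library designs. All matching is
# substitution-only (no indels): the inserts are short single-insert
# amplicons, and indel-bearing reads fall into counted rejection categories
# rather than being silently dropped.

PARSE_STATUSES <- c("OK", "NO_ANCHOR", "NO_ADAPTER", "TRIPLET_MISMATCH",
                    "AMBIGUOUS")

#' Parser configuration
#'
#' @param design `"COMPOSITION"`, `"NTA"` or `"JUNCTION"`.
#' @param anchor21 Constant-region complement the parser anchors on (21 nt).
#' @param adapter App-DNA adapter sequence as it appears in the read (NTA
#'   design); matched on its first `adapter_match_len` bases. The default of
#'   15 keeps the chance of a spurious in-payload match below 1e-6 per
#'   candidate offset at two tolerated mismatches.
#' @param ctso cDNA-orientation TSO segment ([cdna_of_tso()] of the run's
#'   TSO); required for the JUNCTION design.
#' @param max_anchor_mismatches Substitutions tolerated in anchor/adapter/body
#'   matches (default 2, ~10% of the 21-mer anchor).
#' @param adapter_match_len Adapter prefix length used for matching.
#' @param n_var Number of randomized template positions (4 or 1).
#' @return Object of class `parser_config`.
#' @export
parser_config <- function(design = c("NTA", "JUNCTION", "COMPOSITION"),
                          anchor21 = ANCHOR21_DEFAULT,
                          adapter = DEFAULT_APP_ADAPTER,
                          ctso = NULL,
                          max_anchor_mismatches = 2L,
                          adapter_match_len = 15L,
                          n_var = 4L) {
  design <- match.arg(design)
  if (nchar(anchor21) != 21L)
    stop("parser_config(): anchor21 must be 21 nt")
  if (max_anchor_mismatches < 0)
    stop("parser_config(): max_anchor_mismatches must be >= 0")
  if (design == "JUNCTION") {
    if (is.null(ctso)) stop("parser_config(): JUNCTION design requires ctso")
    if (nchar(ctso) != 42L)
      stop("parser_config(): ctso must be 42 nt (3-nt triplet + 39-nt body complement)")
  }
  if (!n_var %in% c(1L, 4L))
    stop("parser_config(): n_var must be 1 or 4")
  structure(list(design = design, anchor21 = toupper(anchor21),
                 adapter = toupper(adapter), ctso = ctso,
                 max_anchor_mismatches = as.integer(max_anchor_mismatches),
                 adapter_match_len = as.integer(adapter_match_len),
                 n_var = as.integer(n_var)),
            class = "parser_config")
}

#' Find an anchor within a read (substitution-only)
#'
#' Returns the smallest 0-based offset at which `anchor` matches `read` with
#' at most `max_mm` substitutions (no indels), or `NA` if absent (including
#' when the anchor is longer than the read).
#'
#' @param read,anchor DNA strings.
#' @param max_mm Maximum substitutions.
#' @return Integer 0-based offset or `NA_integer_`.
#' @export
match_anchor <- function(read, anchor, max_mm = 0L) {
  rr <- charToRaw(read)
  ar <- charToRaw(anchor)
  la <- length(ar)
  lr <- length(rr)
  if (la > lr || la == 0L) return(NA_integer_)
  for (off in 0:(lr - la)) {
    if (sum(rr[(off + 1L):(off + la)] != ar) <= max_mm) return(off)
  }
  NA_integer_
}

#' Canonicalize read orientation against the anchor
#'
#' Returns the read as-is if the anchor matches in forward orientation, the
#' reverse complement if only that matches, `NO_ANCHOR` if neither does, and
#' `AMBIGUOUS` if both do (palindromic artifact).
#'
#' @param read DNA string.
#' @param config A [parser_config()].
#' @return List with `read` (oriented, or `NA`), `flipped`, `status`.
#' @export
canonicalize <- function(read, config) {
  mm <- config$max_anchor_mismatches
  fwd <- match_anchor(read, config$anchor21, mm)
  rc <- .revcomp_chr(read, "DNA")
  rev <- match_anchor(rc, config$anchor21, mm)
  if (!is.na(fwd) && !is.na(rev))
    return(list(read = NA_character_, flipped = NA, status = "AMBIGUOUS"))
  if (!is.na(fwd)) return(list(read = read, flipped = FALSE, status = "OK"))
  if (!is.na(rev)) return(list(read = rc, flipped = TRUE, status = "OK"))
  list(read = NA_character_, flipped = NA, status = "NO_ANCHOR")
}

.parsed <- function(status, n_bases = NA_character_, payload = NA_character_) {
  list(status = status, n_bases = n_bases, payload = payload)
}

# Locate anchor and return 0-based end of the variable region, or NULL.
.anchor_var <- function(read, config) {
  off <- match_anchor(read, config$anchor21, config$max_anchor_mismatches)
  if (is.na(off)) return(NULL)
  var_start <- off + 21L
  var_end <- var_start + config$n_var
  if (nchar(read) < var_end) return(NULL)
  list(var_start = var_start, var_end = var_end,
       var_cdna = substr(read, var_start + 1L, var_end))
}

#' Parse a composition-design read
#'
#' Takes the `n_var` bases following the anchor as the complement of the
#' randomized positions (cDNA order) and converts them to template-sense RNA
#' N1..N4 by reverse complement.
#'
#' @param read Canonicalized read (see [canonicalize()]).
#' @param config A [parser_config()].
#' @return List with `status`, `n_bases` (template-sense RNA), `payload` (empty).
#' @export
parse_composition_read <- function(read, config) {
  av <- .anchor_var(read, config)
  if (is.null(av)) {
    if (is.na(match_anchor(read, config$anchor21, config$max_anchor_mismatches)))
      return(.parsed("NO_ANCHOR"))
    return(.parsed("NO_ADAPTER"))  # too short after the anchor
  }
  .parsed("OK", n_bases = .revcomp_chr(av$var_cdna, "RNA"), payload = "")
}

#' Parse an NTA-design read
#'
#' Extracts the template-sense randomized bases and the nontemplated-addition
#' string: the bases strictly between the variable region and the adapter
#' match, reported in cDNA synthesis order (so +CAA appears literally as
#' `"CAA"`). An empty payload is the valid "-" (no addition) category.
#'
#' @inheritParams parse_composition_read
#' @return List with `status`, `n_bases`, `payload` (NTA string).
#' @export
parse_nta_read <- function(read, config) {
  av <- .anchor_var(read, config)
  if (is.null(av)) {
    if (is.na(match_anchor(read, config$anchor21, config$max_anchor_mismatches)))
      return(.parsed("NO_ANCHOR"))
    return(.parsed("NO_ADAPTER"))
  }
  prefix <- substr(config$adapter, 1L, config$adapter_match_len)
  tail <- substr(read, av$var_end + 1L, nchar(read))
  off <- match_anchor(tail, prefix, config$max_anchor_mismatches)
  if (is.na(off)) return(.parsed("NO_ADAPTER"))
  .parsed("OK", n_bases = .revcomp_chr(av$var_cdna, "RNA"),
          payload = substr(tail, 1L, off))
}

#' Parse a junction-design read
#'
#' Locates the 39-nt body-complement portion of the cTSO downstream of the
#' variable region. The segment S between the variable region and the body
#' must end with the expected junction triplet (the first 3 bases of the
#' cTSO, e.g. `"CCC"` for rGrGrG); the payload is S minus that triplet, in
#' synthesis order. This is the maximal-assignment convention: the 3 bases
#' adjacent to the body are always assigned to the TSO, so with rGrGrG a run
#' `"CCCC"` parses as extras `"C"`. For concatemers the first (template-side)
#' junction is reported.
#'
#' @inheritParams parse_composition_read
#' @return List with `status`, `n_bases`, `payload` (junction extras).
#' @export
parse_junction_read <- function(read, config) {
  av <- .anchor_var(read, config)
  if (is.null(av)) {
    if (is.na(match_anchor(read, config$anchor21, config$max_anchor_mismatches)))
      return(.parsed("NO_ANCHOR"))
    return(.parsed("NO_ADAPTER"))
  }
  body <- substr(config$ctso, 4L, 42L)
  triplet <- substr(config$ctso, 1L, 3L)
  tail <- substr(read, av$var_end + 1L, nchar(read))
  off <- match_anchor(tail, body, config$max_anchor_mismatches)
  if (is.na(off)) return(.parsed("NO_ADAPTER"))
  if (off < 3L) return(.parsed("TRIPLET_MISMATCH"))
  s <- substr(tail, 1L, off)
  if (substr(s, off - 2L, off) != triplet)
    return(.parsed("TRIPLET_MISMATCH"))
  .parsed("OK", n_bases = .revcomp_chr(av$var_cdna, "RNA"),
          payload = substr(s, 1L, off - 3L))
}

#' Parse a vector of reads
#'
#' Canonicalizes each read and applies the design-specific extractor from
#' `config`. Conservation holds by construction: every read receives exactly
#' one status.
#'
#' @param seqs Character vector of read sequences.
#' @param config A [parser_config()].
#' @param ids Optional read ids (defaults to `read_<i>`).
#' @return `data.frame` with columns `read_id`, `status`, `n_bases`,
#'   `payload`, `orientation_flipped`, plus a `"status_counts"` attribute.
#' @export
parse_reads <- function(seqs, config, ids = NULL) {
  ids <- ids %||% sprintf("read_%06d", seq_along(seqs))
  fun <- switch(config$design,
                COMPOSITION = parse_composition_read,
                NTA = parse_nta_read,
                JUNCTION = parse_junction_read)
  n <- length(seqs)
  status <- character(n)
  n_bases <- character(n)
  payload <- character(n)
  flipped <- logical(n)
  for (i in seq_len(n)) {
    cz <- canonicalize(seqs[i], config)
    if (cz$status != "OK") {
      status[i] <- cz$status
      n_bases[i] <- NA_character_
      payload[i] <- NA_character_
      flipped[i] <- NA
      next
    }
    p <- fun(cz$read, config)
    status[i] <- p$status
    n_bases[i] <- p$n_bases
    payload[i] <- p$payload
    flipped[i] <- cz$flipped
  }
  out <- data.frame(read_id = ids, status = status, n_bases = n_bases,
                    payload = payload, orientation_flipped = flipped,
                    stringsAsFactors = FALSE)
  counts <- table(factor(status, levels = PARSE_STATUSES))
  attr(out, "status_counts") <- as.list(as.integer(counts) |>
                                          stats::setNames(PARSE_STATUSES))
  out
}

#' Parse a FASTQ file
#'
#' @param path FASTQ file (plain or gzip).
#' @param config A [parser_config()].
#' @return As [parse_reads()].
#' @export
parse_fastq <- function(path, config) {
  fq <- read_fastq(path)
  parse_reads(fq$seq, config, ids = fq$read_id)
}

#' Status-count summary of a parsed table
#' @param parsed Result of [parse_reads()]/[parse_fastq()].
#' @return Named list of counts over all statuses plus `total`.
#' @export
parse_summary <- function(parsed) {
  counts <- attr(parsed, "status_counts")
  if (is.null(counts)) {
    tab <- table(factor(parsed$status, levels = PARSE_STATUSES))
    counts <- as.list(as.integer(tab) |> stats::setNames(PARSE_STATUSES))
  }
  c(counts, list(total = nrow(parsed)))
}

#' Write reads to FASTQ with constant quality
#'
#' @param ids,seqs Read ids and sequences.
#' @param path Output path; `.gz` suffix enables compression.
#' @param qual_char Constant Phred character (default `"?"` = Q30).
#' @return `path`, invisibly.
#' @export
write_fastq <- function(ids, seqs, path, qual_char = "?") {
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- ids
  quals <- Biostrings::BStringSet(strrep(qual_char, nchar(seqs)))
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = quals,
                              compress = endsWith(path, ".gz"))
  invisible(path)
}

#' Read a FASTQ file (sequences and ids)
#' @param path FASTQ file (plain or gzip).
#' @return List with `read_id` and `seq` character vectors.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  list(read_id = sub("\\s.*$", "", names(x)),
       seq = unname(as.character(x)))
}
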