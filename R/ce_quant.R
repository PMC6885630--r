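# Capillary-electrophoresis quantification: ladder-based sizing, peak
# classification into primer / extension / template-switched / concatemer
# classes, and the template-switching efficiency statistic.

#' Construct a CE peak table
#'
#' @param size_nt Peak sizes in nucleotides (may be `NA` before calibration).
#' @param migration Migration positions in arbitrary units (may be `NA` when
#'   sizes are supplied directly, e.g. exported peak-scanner tables).
#' @param height,area Peak heights and areas (>= 0).
#' @param calibrated Logical: do all peaks carry a size?
#' @return Object of class `peak_table` (a data.frame).
#' @export
peak_table <- function(size_nt = NULL, migration = NULL, height = NULL,
                       area, calibrated = !is.null(size_nt)) {
  n <- length(area)
  size_nt <- size_nt %||% rep(NA_real_, n)
  migration <- migration %||% rep(NA_real_, n)
  height <- height %||% area
  if (any(area < 0) || any(height < 0))
    stop("peak_table(): heights and areas must be >= 0")
  if (calibrated && anyNA(size_nt))
    stop("peak_table(): calibrated table requires a size for every peak")
  out <- data.frame(migration = migration, size_nt = size_nt,
                    height = height, area = area)
  class(out) <- c("peak_table", "data.frame")
  attr(out, "calibrated") <- isTRUE(calibrated)
  out
}

#' Is a peak table calibrated?
#' @param peaks A [peak_table()].
#' @return Logical.
#' @export
is_calibrated <- function(peaks) isTRUE(attr(peaks, "calibrated"))

#' The nine GeneScan 120 LIZ ladder fragment sizes (nt)
#'
#' Vendor constant for the size standard commonly co-electrophoresed with
#' short cDNA products; used as the default set of ladder knot sizes.
#' @export
LIZ120_SIZES <- c(15, 20, 25, 35, 50, 62, 80, 110, 120)

# Piecewise-linear interpolation with linear extrapolation beyond the end
# knots (stats::approx clamps instead of extrapolating).
.pwl <- function(x, y, xout) {
  n <- length(x)
  lo <- xout < x[1]
  hi <- xout > x[n]
  mid <- !lo & !hi
  out <- numeric(length(xout))
  if (any(mid)) out[mid] <- stats::approx(x, y, xout = xout[mid])$y
  if (any(lo)) out[lo] <- y[1] + (xout[lo] - x[1]) * (y[2] - y[1]) / (x[2] - x[1])
  if (any(hi)) out[hi] <- y[n] + (xout[hi] - x[n]) * (y[n] - y[n - 1]) / (x[n] - x[n - 1])
  out
}

#' Calibrate peak sizes against a co-run ladder
#'
#' Maps migration to size by piecewise-linear interpolation through the
#' ladder knots, extrapolating linearly beyond the terminal segments.
#'
#' @param ladder Two-column data.frame (or matrix) of `migration` and
#'   `size_nt` for the ladder fragments; at least two points, strictly
#'   increasing in both coordinates.
#' @param peaks A [peak_table()] with migration values.
#' @return The peak table with `size_nt` filled in and `calibrated = TRUE`.
#' @export
calibrate_sizes <- function(ladder, peaks) {
  ladder <- as.data.frame(ladder)
  names(ladder)[1:2] <- c("migration", "size_nt")
  if (nrow(ladder) < 2L)
    stop("calibrate_sizes(): ladder needs at least 2 points")
  if (any(diff(ladder$migration) <= 0) || any(diff(ladder$size_nt) <= 0))
    stop("calibrate_sizes(): ladder must be strictly increasing in migration and size")
  if (anyNA(peaks$migration))
    stop("calibrate_sizes(): peaks carry no migration values")
  peaks$size_nt <- .pwl(ladder$migration, ladder$size_nt, peaks$migration)
  attr(peaks, "calibrated") <- TRUE
  peaks
}

#' Classify calibrated CE peaks
#'
#' Windows, all `+/- tol_nt`:
#' \describe{
#'   \item{PRIMER}{`primer_len`}
#'   \item{EXTENSION}{`[template_len, template_len + max_nta_window]`
#'     (non-switched products, including nontemplated additions)}
#'   \item{TS_PRODUCT}{the extension window shifted by `+tso_len`}
#'   \item{CONCATEMER(k)}{shifted by `+k * tso_len`, `k = 2..concat_max`}
#' }
#' Peaks matching no window are `UNASSIGNED`. PRIMER is tested first.
#'
#' @param peaks Calibrated [peak_table()].
#' @param primer_len,template_len Unextended primer and template lengths (nt).
#' @param tso_len Length added per switch (42 for a 39+3 TSO).
#' @param max_nta_window Width allowed for nontemplated additions (nt).
#' @param concat_max Highest concatemer order considered.
#' @param tol_nt Sizing tolerance (nt).
#' @return Object of class `peak_classification`: the peak table plus
#'   `label` and `k` (number of switches; NA for PRIMER/UNASSIGNED) columns.
#' @export
classify_peaks <- function(peaks, primer_len = 20, template_len = 25,
                           tso_len = 42, max_nta_window = 10,
                           concat_max = 4, tol_nt = 1) {
  if (!is_calibrated(peaks))
    stop("classify_peaks(): peak table is not calibrated")
  label <- rep("UNASSIGNED", nrow(peaks))
  kvec <- rep(NA_integer_, nrow(peaks))
  for (i in seq_len(nrow(peaks))) {
    s <- peaks$size_nt[i]
    if (abs(s - primer_len) <= tol_nt) {
      label[i] <- "PRIMER"
      next
    }
    for (k in 0:concat_max) {
      lo <- template_len + k * tso_len - tol_nt
      hi <- template_len + max_nta_window + k * tso_len + tol_nt
      if (s >= lo && s <= hi) {
        label[i] <- if (k == 0) "EXTENSION"
                    else if (k == 1) "TS_PRODUCT"
                    else sprintf("CONCATEMER(%d)", k)
        kvec[i] <- k
        break
      }
    }
  }
  out <- cbind(as.data.frame(peaks), label = label, k = kvec)
  class(out) <- c("peak_classification", "data.frame")
  out
}

#' Template-switching efficiency from classified peaks
#'
#' Area of all switched products (TS_PRODUCT plus concatemers, each molecule
#' counted once regardless of its switch count) over the area of all
#' elongation products. The unextended primer is excluded from the
#' denominator by default -- the efficiency contrasts switched against
#' elongated products; set `include_primer = TRUE` for the primer-inclusive
#' variant.
#'
#' @param classification A [classify_peaks()] result.
#' @param include_primer Include the PRIMER area in the denominator.
#' @return Efficiency in `[0, 1]`.
#' @export
ts_efficiency <- function(classification, include_primer = FALSE) {
  stopifnot(inherits(classification, "peak_classification"))
  a <- function(lab) sum(classification$area[classification$label %in% lab])
  switched <- sum(classification$area[!is.na(classification$k) &
                                        classification$k >= 1])
  ext <- a("EXTENSION")
  denom <- switched + ext + if (include_primer) a("PRIMER") else 0
  if (length(classification$label) == 0 || (switched + ext) == 0)
    stop("ts_efficiency(): no product peaks (EXTENSION/TS/CONCATEMER) present")
  if (denom == 0) stop("ts_efficiency(): zero denominator")
  switched / denom
}
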