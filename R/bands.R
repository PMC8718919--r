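#' Canonical frequency bands
#'
#' Returns the band definitions used throughout the package. The classical
#' bands are delta (1--4 Hz), theta (4--8 Hz), alpha (8--12 Hz) and beta
#' (12--30 Hz). The high-beta sub-band commonly called "beta3" is taken as
#' 25--30 Hz and gamma as 30--45 Hz. So that the band set forms a disjoint
#' partition of 1--45 Hz (required both for band-power additivity and for
#' the independent per-band components of the synthetic generator), the
#' "beta" feature here covers 12--25 Hz and beta3 the remaining 25--30 Hz;
#' their union is the classical 12--30 Hz beta range.
#'
#' Intervals are half-open \code{[low, high)} in the sense that adjacent
#' bands share an edge frequency without double counting (trapezoidal
#' integration splits shared edges evenly).
#'
#' @return A data frame with columns \code{band}, \code{low}, \code{high}
#'   (Hz), one row per band, ordered by \code{low}.
#' @export
#' @examples
#' band_definitions()
band_definitions <- function() {
  data.frame(
    band = c("delta", "theta", "alpha", "beta", "beta3", "gamma"),
    low  = c(1, 4, 8, 12, 25, 30),
    high = c(4, 8, 12, 25, 30, 45),
    stringsAsFactors = FALSE
  )
}

#' Standard 19-channel 10-20 montage
#'
#' Channel labels of the international 10-20 system in the conventional
#' 19-electrode layout.
#'
#' @return Character vector of 19 channel labels.
#' @export
montage_1020 <- function() {
  c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8",
    "T3", "C3", "Cz", "C4", "T4",
    "T5", "P3", "Pz", "P4", "T6", "O1", "O2")
}

#' Normalize a channel label to its montage form
#'
#' Matches labels case-insensitively against [montage_1020()] and repairs
#' the mojibake variant "\enc{Ñ}{N}4" occasionally seen for "C4" in
#' transcribed channel lists.
#'
#' @param labels character vector of channel labels.
#' @return Character vector of canonical labels.
#' @export
normalize_channel_label <- function(labels) {
  labels <- as.character(labels)
  labels[labels %in% c("Ñ4", "ñ4", "N4")] <- "C4"
  canon <- montage_1020()
  idx <- match(toupper(labels), toupper(canon))
  if (anyNA(idx)) {
    stop("unknown channel label(s): ",
         paste(unique(labels[is.na(idx)]), collapse = ", "))
  }
  canon[idx]
}

band_names <- function() band_definitions()$band

check_band <- function(band) {
  if (!all(band %in% band_names())) {
    stop("unknown band(s): ",
         paste(setdiff(band, band_names()), collapse = ", "),
         " (known: ", paste(band_names(), collapse = ", "), ")")
  }
  invisible(band)
}

# log of positive values; non-positive entries become NA without warnings
safe_log <- function(x) {
  out <- rep(NA_real_, length(x))
  ok <- !is.na(x) & x > 0
  out[ok] <- log(x[ok])
  out
}
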