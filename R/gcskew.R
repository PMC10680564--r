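#' GC-skew track of a genome
#'
#' Watson-strand GC skew, `(G - C) / (G + C)`, counted in a centered
#' sliding window and assigned to the window's center position.  Windows
#' with no G or C give 0; windows containing any non-ACGT base, and
#' positions whose window would cross a chromosome end, give `NA`.
#'
#' At a site used as a replication origin over evolutionary time, skew is
#' negative upstream and positive downstream of the initiation point on
#' either strand read 5' to 3' (cytosines on the lagging-strand template
#' deaminate preferentially), so the composite over origin midpoints
#' crosses zero there.
#'
#' @param genome Named `DNAStringSet` or named character vector.
#' @param window Odd window width in bp (default 51).
#' @return An `"external"` [signal_track()] with values in `[-1, 1]`.
#' @export
skew_track <- function(genome, window = 51) {
  window <- as.integer(window)
  stopifnot(window >= 3L, window %% 2L == 1L)
  h <- (window - 1L) %/% 2L
  seqs <- if (is.character(genome)) genome else
    stats::setNames(as.character(genome), names(genome))
  if (is.null(names(seqs))) stop("genome sequences must be named")
  data <- lapply(seqs, function(s) {
    chars <- strsplit(toupper(s), "")[[1]]
    n <- length(chars)
    out <- rep(NA_real_, n)
    if (n < window) return(out)
    csG <- c(0L, cumsum(chars == "G"))
    csC <- c(0L, cumsum(chars == "C"))
    csN <- c(0L, cumsum(!chars %in% BASES))
    ctr <- (h + 1L):(n - h)
    G <- csG[ctr + h + 1L] - csG[ctr - h]
    C <- csC[ctr + h + 1L] - csC[ctr - h]
    N <- csN[ctr + h + 1L] - csN[ctr - h]
    v <- ifelse(G + C == 0L, 0, (G - C) / (G + C))
    v[N > 0L] <- NA_real_
    out[ctr] <- v
    out
  })
  signal_track(data, mode = "external")
}

#' Cohort composites of GC skew around CMBS midpoints
#'
#' Per cohort of consecutive ranks, the mean Watson-strand skew at each
#' offset from the CMBS midpoint (missing values excluded).  A zero
#' crossing at offset 0 in the top cohorts is the evolutionary footprint
#' of replication initiation; the mirrored (reverse-complement) profile
#' follows by antisymmetry and is not computed separately.
#'
#' @param track A [skew_track()] result.
#' @param cmbs A `cmbs_list`.
#' @param cohort_size Sites per cohort (default 1100).
#' @param halfwidth Profile half-width in bp (default 200).
#' @param max_rank Highest rank included (default all).
#' @return Offsets x cohorts matrix of mean skew.
#' @export
skew_composite <- function(track, cmbs, cohort_size = 1100, halfwidth = 200,
                           max_rank = nrow(cmbs)) {
  cohort_composite(track, cmbs, cohort_size, halfwidth, max_rank)
}

#' Offset at which a profile crosses zero
#'
#' Linear interpolation between the last non-positive and first positive
#' profile value around the sign change nearest offset 0; `NA` when the
#' profile does not change sign.
#'
#' @param profile Named numeric vector (names = offsets), e.g. one column
#'   of [skew_composite()].
#' @return Interpolated crossing offset in bp, or `NA`.
#' @export
zero_crossing_offset <- function(profile) {
  off <- as.numeric(names(profile))
  v <- as.numeric(profile)
  ok <- !is.na(v)
  off <- off[ok]
  v <- v[ok]
  sgn <- sign(v)
  flips <- which(sgn[-length(sgn)] <= 0 & sgn[-1] > 0)
  if (!length(flips)) return(NA_real_)
  i <- flips[which.min(abs(off[flips]))]
  # interpolate between (off[i], v[i]) and (off[i+1], v[i+1])
  if (v[i + 1L] == v[i]) return(off[i])
  off[i] + (0 - v[i]) * (off[i + 1L] - off[i]) / (v[i + 1L] - v[i])
}
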