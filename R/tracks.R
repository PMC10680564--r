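#' Per-base signal tracks
#'
#' A `signal_track` holds one numeric value per base pair for each
#' chromosome, together with a mode tag recording how it was produced:
#' `"full_extent"` (each retained fragment adds 1 to every covered base),
#' `"midpoint"` (each retained fragment adds 1 at its midpoint), or
#' `"external"` (an imported processed signal such as an ssDNA S/G1 ratio,
#' a PWM score track, or a GC-skew track; may contain `NA` for positions
#' with no data).  Depth-mode tracks must be non-negative and `NA`-free.
#'
#' @param data Named list of numeric vectors, one per chromosome; vector
#'   length equals chromosome length (positions are 1-based).
#' @param mode One of `"full_extent"`, `"midpoint"`, `"external"`.
#' @param size_range Optional integer pair recording the fragment size
#'   selection (bp) that produced a depth track.
#' @return An object of class `signal_track`.
#' @export
signal_track <- function(data, mode = c("full_extent", "midpoint", "external"),
                         size_range = NULL) {
  mode <- match.arg(mode)
  if (!is.list(data) || is.null(names(data)) || any(!nzchar(names(data))))
    stop("'data' must be a named list of per-chromosome numeric vectors")
  data <- lapply(data, as.numeric)
  if (mode != "external") {
    bad <- vapply(data, function(v) anyNA(v) || any(v < 0), logical(1))
    if (any(bad))
      stop("depth-mode tracks must be non-negative and NA-free; offending: ",
           paste(names(data)[bad], collapse = ", "))
  }
  if (!is.null(size_range)) {
    size_range <- as.integer(size_range)
    stopifnot(length(size_range) == 2L, size_range[1] <= size_range[2])
  }
  structure(list(data = data, mode = mode, size_range = size_range),
            class = "signal_track")
}

#' @export
print.signal_track <- function(x, ...) {
  cat(sprintf("<signal_track> mode=%s, %d chromosome(s), %s bp total\n",
              x$mode, length(x$data),
              format(sum(track_lengths(x)), big.mark = ",")))
  invisible(x)
}

#' Chromosome lengths of a track
#' @param track A `signal_track`.
#' @return Named integer vector of per-chromosome lengths.
#' @export
track_lengths <- function(track) {
  vapply(track$data, length, integer(1))
}

same_genome <- function(a, b) {
  identical(names(a$data), names(b$data)) &&
    identical(unname(track_lengths(a)), unname(track_lengths(b)))
}

#' Build a size-selected per-base depth track from fragments
#'
#' Only fragments whose length lies within `size_range` contribute.  In
#' `full_extent` mode each retained fragment adds 1 to every base it covers;
#' in `midpoint` mode it adds 1 at `start + floor(length/2)` only, so the
#' total track mass equals the number of retained fragments exactly.
#'
#' @param frags A `GRanges` of fragment intervals (1-based, inclusive),
#'   e.g. from [read_fragments()].
#' @param size_range Integer pair: inclusive fragment-length selection in bp.
#'   The default 51--100 bp selects Mcm double-hexamer footprint fragments;
#'   use `c(46, 56)` for nucleosome-dyad chemical-cleavage fragments.
#' @param mode `"full_extent"` or `"midpoint"`.
#' @param seqlens Named integer vector of chromosome lengths; taken from
#'   `seqlengths(frags)` when `NULL`.
#' @return A `signal_track`.
#' @export
depth_track <- function(frags, size_range = c(51, 100),
                        mode = c("full_extent", "midpoint"), seqlens = NULL) {
  mode <- match.arg(mode)
  size_range <- as.integer(size_range)
  stopifnot(length(size_range) == 2L, size_range[1] >= 1L,
            size_range[1] <= size_range[2])
  if (is.null(seqlens)) {
    seqlens <- GenomeInfoDb::seqlengths(frags)
    if (anyNA(seqlens))
      stop("fragment set carries no chromosome lengths; supply 'seqlens'")
  }
  chroms <- as.character(GenomicRanges::seqnames(frags))
  unknown <- setdiff(unique(chroms), names(seqlens))
  if (length(unknown))
    stop("fragments on chromosome(s) absent from the genome: ",
         paste(unknown, collapse = ", "))
  if (length(frags) &&
      (any(GenomicRanges::start(frags) < 1L) ||
       any(GenomicRanges::end(frags) > seqlens[chroms])))
    stop("fragment extends past chromosome end")

  keep <- GenomicRanges::width(frags) >= size_range[1] &
    GenomicRanges::width(frags) <= size_range[2]
  fr <- frags[keep]
  kchrom <- as.character(GenomicRanges::seqnames(fr))
  data <- vector("list", length(seqlens))
  names(data) <- names(seqlens)
  for (ch in names(seqlens)) {
    n <- seqlens[[ch]]
    sel <- kchrom == ch
    if (!any(sel)) {
      data[[ch]] <- numeric(n)
      next
    }
    s <- GenomicRanges::start(fr)[sel]
    e <- GenomicRanges::end(fr)[sel]
    if (mode == "midpoint") {
      mid <- s + (e - s + 1L) %/% 2L   # start + floor(length/2), 1-based
      data[[ch]] <- as.numeric(tabulate(mid, nbins = n))
    } else {
      # difference-array coverage: +1 at starts, -1 past ends, then cumsum
      d <- numeric(n + 1L)
      add <- tabulate(s, nbins = n)
      sub <- tabulate(e + 1L, nbins = n + 1L)
      d[seq_len(n)] <- add
      d <- d - sub
      data[[ch]] <- cumsum(d)[seq_len(n)]
    }
  }
  signal_track(data, mode = mode, size_range = size_range)
}

#' Smooth a track with a centered sliding window
#'
#' Each output value is the mean of input values in a centered window of
#' `2 * floor(width/2) + 1` positions.  At chromosome ends the window is
#' truncated and the mean is taken over the available positions only (no
#' padding), so a constant track stays constant.
#'
#' @param track A `signal_track`.
#' @param width Window width in bp (approximate full width; the effective
#'   window is the centered odd window of half-width `floor(width/2)`).
#'   The peak caller uses 10 bp; 200 bp suits display-scale profiles.
#' @return A smoothed `signal_track` with the same mode and size range.
#' @export
smooth_track <- function(track, width = 10) {
  if (!inherits(track, "signal_track")) stop("'track' must be a signal_track")
  if (!is.numeric(width) || length(width) != 1L || width < 1)
    stop("'width' must be a positive number of base pairs")
  h <- as.integer(width) %/% 2L
  data <- lapply(track$data, function(x) {
    n <- length(x)
    if (h == 0L || n == 0L) return(x)
    cs <- c(0, cumsum(x))
    i <- seq_len(n)
    lo <- pmax(i - h, 1L)
    hi <- pmin(i + h, n)
    (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  })
  signal_track(data, mode = track$mode, size_range = track$size_range)
}

#' Read a two-column chrom.sizes file
#' @param path Path to a TSV with columns chromosome name and length.
#' @return Named integer vector of chromosome lengths.
#' @export
read_chrom_sizes <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE,
                          col.names = c("chrom", "length"))
  stats::setNames(as.integer(df$length), df$chrom)
}

#' Write a track as bedGraph
#'
#' Runs of equal value are collapsed to single 0-based half-open intervals.
#' Zero-valued and `NA` (no data) runs are omitted, so sparse tracks stay
#' small; [read_bedgraph()] restores omitted positions with its `fill`
#' value.  Values are printed with 17 significant digits so that a
#' write/read round trip reproduces every double bitwise.
#'
#' @param track A `signal_track`.
#' @param path Output file path.
#' @return Invisibly, the path.
#' @export
write_bedgraph <- function(track, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (ch in names(track$data)) {
    x <- track$data[[ch]]
    x0 <- ifelse(is.na(x), 0, x)
    r <- rle(x0)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values != 0
    if (!any(keep)) next
    writeLines(sprintf("%s\t%d\t%d\t%.17g",
                       ch, starts[keep] - 1L, ends[keep], r$values[keep]),
               con)
  }
  invisible(path)
}

#' Read a bedGraph file into a track
#'
#' @param path bedGraph file (0-based half-open intervals).
#' @param seqlens Named integer vector of chromosome lengths.
#' @param mode Mode tag for the resulting track (default `"external"`).
#' @param fill Value for positions not covered by any interval (default 0;
#'   use `NA` for sparse processed signals such as microarray ssDNA ratios).
#' @return A `signal_track`.
#' @export
read_bedgraph <- function(path, seqlens, mode = "external", fill = 0) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  if (length(gr) && any(GenomicRanges::countOverlaps(gr, gr) > 1L))
    stop("bedGraph contains overlapping intervals: ", path)
  chroms <- as.character(GenomicRanges::seqnames(gr))
  unknown <- setdiff(unique(chroms), names(seqlens))
  if (length(unknown))
    stop("bedGraph covers chromosome(s) absent from the genome: ",
         paste(unknown, collapse = ", "))
  data <- lapply(seqlens, function(n) rep(as.numeric(fill), n))
  sc <- as.numeric(S4Vectors::mcols(gr)$score)
  for (i in seq_along(gr)) {
    s <- GenomicRanges::start(gr)[i]
    e <- GenomicRanges::end(gr)[i]
    if (e > seqlens[[chroms[i]]])
      stop("bedGraph interval extends past end of ", chroms[i])
    data[[chroms[i]]][s:e] <- sc[i]
  }
  signal_track(data, mode = mode)
}
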