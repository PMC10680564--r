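#' Read paired-end fragment intervals
#'
#' Reads aligned insert intervals from BED3 (one interval per fragment),
#' BEDPE (both mates; the fragment spans min(start) to max(end)), or
#' SAM/BAM (properly paired alignments; the insert is inferred from POS and
#' a positive TLEN).  Coordinates are returned 1-based inclusive in a
#' `GRanges`; BED input is converted from its 0-based half-open convention.
#'
#' @param path Input file.
#' @param format `"auto"` (by extension), `"bed3"`, `"bedpe"`, `"sam"` or
#'   `"bam"`.
#' @param seqlens Optional named integer vector of chromosome lengths; when
#'   supplied, fragments on unlisted chromosomes or beyond chromosome ends
#'   are rejected and the lengths are attached to the result.
#' @return A `GRanges` of fragments; the number of records is reported via
#'   `message()`.
#' @export
read_fragments <- function(path,
                           format = c("auto", "bed3", "bedpe", "sam", "bam"),
                           seqlens = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext,
                     bed = "bed3", bedpe = "bedpe", sam = "sam", bam = "bam",
                     stop("cannot infer fragment format from extension '.",
                          ext, "'; pass 'format' explicitly"))
  }
  gr <- switch(format,
               bed3 = read_fragments_bed3(path),
               bedpe = read_fragments_bedpe(path),
               sam = ,
               bam = read_fragments_bam(path, format))
  if (!is.null(seqlens)) {
    chroms <- as.character(GenomicRanges::seqnames(gr))
    unknown <- setdiff(unique(chroms), names(seqlens))
    if (length(unknown))
      stop("fragments on unknown chromosome(s): ",
           paste(unknown, collapse = ", "))
    if (length(gr) && any(GenomicRanges::end(gr) > seqlens[chroms]))
      stop("fragment extends past chromosome end")
    gr <- GenomicRanges::GRanges(
      chroms, IRanges::IRanges(GenomicRanges::start(gr),
                               GenomicRanges::end(gr)),
      seqlengths = seqlens)
  }
  message(sprintf("read %d fragment(s) from %s", length(gr), basename(path)))
  gr
}

split_data_lines <- function(path) {
  lns <- readLines(path)
  idx <- which(nzchar(trimws(lns)) &
                 !grepl("^(#|track\\b|browser\\b)", lns))
  list(fields = strsplit(trimws(lns[idx]), "[ \t]+"), lineno = idx)
}

read_fragments_bed3 <- function(path) {
  d <- split_data_lines(path)
  if (!length(d$fields))
    return(GenomicRanges::GRanges())
  chrom <- character(length(d$fields))
  start0 <- integer(length(d$fields))
  end0 <- integer(length(d$fields))
  for (i in seq_along(d$fields)) {
    f <- d$fields[[i]]
    s <- suppressWarnings(as.numeric(f[2]))
    e <- suppressWarnings(as.numeric(f[3]))
    if (length(f) < 3L || is.na(s) || is.na(e) || s < 0 || e <= s)
      stop(sprintf("malformed BED3 record at line %d of %s",
                   d$lineno[i], path))
    chrom[i] <- f[1]
    start0[i] <- as.integer(s)
    end0[i] <- as.integer(e)
  }
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start0 + 1L, end0))
}

read_fragments_bedpe <- function(path) {
  d <- split_data_lines(path)
  if (!length(d$fields))
    return(GenomicRanges::GRanges())
  chrom <- character(length(d$fields))
  start0 <- integer(length(d$fields))
  end0 <- integer(length(d$fields))
  for (i in seq_along(d$fields)) {
    f <- d$fields[[i]]
    v <- suppressWarnings(as.numeric(f[c(2, 3, 5, 6)]))
    if (length(f) < 6L || anyNA(v) || f[1] != f[4] ||
        v[2] <= v[1] || v[4] <= v[3])
      stop(sprintf("malformed BEDPE record at line %d of %s",
                   d$lineno[i], path))
    chrom[i] <- f[1]
    start0[i] <- as.integer(min(v[1], v[3]))
    end0[i] <- as.integer(max(v[2], v[4]))
  }
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start0 + 1L, end0))
}

read_fragments_bam <- function(path, format) {
  bam <- if (format == "sam") {
    Rsamtools::asBam(path, destination = tempfile(), overwrite = TRUE,
                     indexDestination = FALSE)
  } else path
  param <- Rsamtools::ScanBamParam(
    flag = Rsamtools::scanBamFlag(isProperPair = TRUE),
    what = c("rname", "pos", "isize"))
  res <- Rsamtools::scanBam(bam, param = param)[[1]]
  keep <- !is.na(res$isize) & res$isize > 0L & !is.na(res$pos)
  if (!any(keep))
    return(GenomicRanges::GRanges())
  GenomicRanges::GRanges(
    as.character(res$rname[keep]),
    IRanges::IRanges(res$pos[keep],
                     res$pos[keep] + res$isize[keep] - 1L))
}

#' Fragment midpoints
#'
#' Deterministic midpoint convention: `start + floor(length/2)` (1-based),
#' identical to the position incremented by midpoint-mode [depth_track()].
#'
#' @param frags A `GRanges` of fragments.
#' @return Integer vector of midpoint coordinates.
#' @export
fragment_midpoints <- function(frags) {
  GenomicRanges::start(frags) + GenomicRanges::width(frags) %/% 2L
}
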