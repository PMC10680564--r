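#' @keywords internal
#' Normalize anchors to a data.frame(chrom, pos, strand)
as_anchors <- function(anchors) {
  if (inherits(anchors, "cmbs_list")) {
    return(data.frame(chrom = anchors$chrom, pos = anchors$midpoint,
                      strand = "+", stringsAsFactors = FALSE))
  }
  if (methods::is(anchors, "GRanges")) {
    st <- as.character(GenomicRanges::strand(anchors))
    st[st == "*"] <- "+"
    return(data.frame(
      chrom = as.character(GenomicRanges::seqnames(anchors)),
      pos = GenomicRanges::start(anchors) +
        GenomicRanges::width(anchors) %/% 2L,
      strand = st, stringsAsFactors = FALSE))
  }
  stopifnot(is.data.frame(anchors), all(c("chrom", "pos") %in%
                                          colnames(anchors)))
  if (is.null(anchors$strand)) anchors$strand <- "+"
  data.frame(chrom = as.character(anchors$chrom),
             pos = as.integer(anchors$pos),
             strand = as.character(anchors$strand),
             stringsAsFactors = FALSE)
}

#' Extract an anchor-aligned matrix from a track
#'
#' Row `i` holds the track values at `anchor_i + offset` for offsets
#' `-halfwidth..+halfwidth`.  Rows anchored on the "-" strand are reversed
#' so that the offset axis always runs 5' to 3' of the anchor.  Anchors
#' whose window would cross a chromosome end are dropped; the count of
#' dropped rows is attached as attribute `"dropped"` and the surviving
#' anchor indices as `"kept"`.
#'
#' @param track A `signal_track`.
#' @param anchors A `cmbs_list`, a `GRanges`, or a data.frame with columns
#'   `chrom`, `pos` and optionally `strand`.
#' @param halfwidth Window half-width in bp.
#' @return A numeric matrix of class `aligned_matrix` with offset column
#'   names.
#' @export
extract_matrix <- function(track, anchors, halfwidth) {
  stopifnot(inherits(track, "signal_track"), halfwidth >= 1)
  a <- as_anchors(anchors)
  halfwidth <- as.integer(halfwidth)
  lens <- track_lengths(track)
  unknown <- setdiff(unique(a$chrom), names(lens))
  if (length(unknown))
    stop("anchor on unknown chromosome(s): ", paste(unknown, collapse = ", "))
  inb <- unname(a$pos - halfwidth >= 1L & a$pos + halfwidth <= lens[a$chrom])
  kept <- which(inb)
  m <- matrix(NA_real_, nrow = length(kept), ncol = 2L * halfwidth + 1L,
              dimnames = list(NULL, as.character(seq(-halfwidth, halfwidth))))
  for (j in seq_along(kept)) {
    i <- kept[j]
    row <- track$data[[a$chrom[i]]][(a$pos[i] - halfwidth):
                                      (a$pos[i] + halfwidth)]
    if (a$strand[i] == "-") row <- rev(row)
    m[j, ] <- row
  }
  structure(m, dropped = sum(!inb), kept = kept,
            strand = a$strand[kept],
            class = c("aligned_matrix", class(m)))
}

matrix_offsets <- function(m) as.integer(colnames(m))

#' Composite profile of an aligned matrix
#'
#' * `"none"`: per-offset column means (missing values excluded, so sparse
#'   external signals are averaged only over rows with data at an offset).
#' * `"per_row_sum_100"`: each row is scaled so its total is 100, then rows
#'   are **summed** into a cumulative profile (all-zero rows are dropped
#'   with a warning, since their scaling is undefined).
#' * `"cohort_median_100"`: rows are grouped by `cohorts`; one mean profile
#'   per cohort is returned as a matrix (offsets x cohorts).  When
#'   `abundance` is supplied, per-cohort median abundances rescaled so that
#'   cohort 1 is 100 are attached as attribute `"cohort_medians"`.
#'
#' @param m An [extract_matrix()] result.
#' @param normalization One of the modes above.
#' @param cohorts Integer cohort id per row (required for
#'   `"cohort_median_100"`); rows with `NA` cohort are ignored.
#' @param abundance Optional per-row abundance for the cohort-median table.
#' @return Named numeric vector (offsets), or an offsets x cohorts matrix.
#' @export
composite_profile <- function(m,
                              normalization = c("none", "per_row_sum_100",
                                                "cohort_median_100"),
                              cohorts = NULL, abundance = NULL) {
  normalization <- match.arg(normalization)
  if (!nrow(m)) stop("aligned matrix has no rows")
  if (normalization == "none") {
    return(colMeans(m, na.rm = TRUE))
  }
  if (normalization == "per_row_sum_100") {
    s <- rowSums(m, na.rm = TRUE)
    if (any(s == 0)) {
      warning(sum(s == 0), " all-zero row(s) dropped (undefined scaling)")
      m <- m[s != 0, , drop = FALSE]
      s <- s[s != 0]
    }
    if (!nrow(m)) stop("no rows left after dropping all-zero rows")
    return(colSums(m * (100 / s), na.rm = TRUE))
  }
  # cohort_median_100
  if (is.null(cohorts) || length(cohorts) != nrow(m))
    stop("'cohorts' must give one cohort id per matrix row")
  sel <- !is.na(cohorts)
  ks <- sort(unique(cohorts[sel]))
  prof <- vapply(ks, function(k) {
    colMeans(m[sel & cohorts == k, , drop = FALSE], na.rm = TRUE)
  }, numeric(ncol(m)))
  colnames(prof) <- as.character(ks)
  if (!is.null(abundance)) {
    meds <- vapply(ks, function(k) {
      stats::median(abundance[sel & cohorts == k])
    }, numeric(1))
    attr(prof, "cohort_medians") <- 100 * meds / meds[1L]
  }
  prof
}

#' Cohort composite of any track around CMBS midpoints
#'
#' Aligns a track to CMBS midpoints, groups rows into cohorts of
#' `cohort_size` consecutive ranks, and returns one mean profile per
#' cohort.  This is the shared machinery behind [acs_composite()] and
#' [skew_composite()] and is equally suited to ssDNA S/G1 ratio or
#' nucleosome-dyad depth tracks.
#'
#' @param track A `signal_track`.
#' @param cmbs A `cmbs_list`.
#' @param cohort_size Sites per cohort.
#' @param halfwidth Profile half-width in bp.
#' @param max_rank Highest rank included (default all).
#' @return Offsets x cohorts matrix with attribute `"cohort_medians"`
#'   (per-cohort median abundance, cohort 1 = 100).
#' @export
cohort_composite <- function(track, cmbs, cohort_size, halfwidth,
                             max_rank = nrow(cmbs)) {
  m <- extract_matrix(track, cmbs, halfwidth)
  kept <- attr(m, "kept")
  ranks <- cmbs$rank[kept]
  cohorts <- ifelse(ranks <= max_rank,
                    (ranks - 1L) %/% as.integer(cohort_size) + 1L,
                    NA_integer_)
  empty <- setdiff(seq_len(max(cohorts, na.rm = TRUE)),
                   unique(cohorts[!is.na(cohorts)]))
  if (length(empty))
    warning("empty cohort(s) skipped: ", paste(empty, collapse = ", "))
  composite_profile(m, "cohort_median_100", cohorts = cohorts,
                    abundance = cmbs$abundance[kept])
}

#' NFR vs nucleosomal occupancy score at a site
#'
#' Ratio of the mean nucleosome-dyad signal in `midpoint +/- 50` bp to the
#' mean in the flanks (`[-150,-51]` and `[+51,+150]`).  Values near 0 mark
#' a nucleosome-free region with positioned flanking nucleosomes; values
#' near or above 1 mark nucleosomal signal at the site itself.  A zero
#' flank with a nonzero center returns `Inf`; 0/0 returns 0.
#'
#' @param dyad_track `signal_track` built from 46--56 bp chemical-cleavage
#'   (or MNase) fragments.
#' @param chrom,midpoint Parallel vectors of site coordinates, or pass a
#'   `cmbs_list` as `chrom` and leave `midpoint` missing.
#' @return Numeric vector of occupancy ratios.
#' @export
nfr_occupancy_score <- function(dyad_track, chrom, midpoint) {
  if (inherits(chrom, "cmbs_list") && missing(midpoint)) {
    midpoint <- chrom$midpoint
    chrom <- chrom$chrom
  }
  lens <- track_lengths(dyad_track)
  vapply(seq_along(midpoint), function(i) {
    p <- midpoint[i]
    x <- dyad_track$data[[chrom[i]]]
    if (is.null(x)) stop("unknown chromosome: ", chrom[i])
    if (p - 150L < 1L || p + 150L > length(x))
      stop("occupancy window exceeds chromosome at ", chrom[i], ":", p)
    center <- mean(x[(p - 50L):(p + 50L)])
    flank <- mean(x[c((p - 150L):(p - 51L), (p + 51L):(p + 150L))])
    if (flank == 0) {
      if (center == 0) 0 else Inf
    } else {
      center / flank
    }
  }, numeric(1))
}
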