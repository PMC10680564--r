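#' Peak-calling parameters
#'
#' Bundles the tunable parameters of the iterative CMBS caller.  Defaults
#' reproduce the standard analysis: 51--100 bp insert selection, 10 bp
#' smoothing, a 60 bp refinement radius for the midpoint-track coordinate,
#' a 500 bp exclusion zone around each called site, and removal of sites
#' within 100 bp of Ty elements.
#'
#' The stop rule: calling stops when the genome-wide maximum of the (zeroed)
#' full-extent track drops to `min_signal` or below, or after `max_peaks`
#' sites, whichever comes first.  At least one of the two must be effective.
#'
#' @param size_range Inclusive fragment-length selection in bp.
#' @param smooth_width Sliding-window width for both tracks, bp.
#' @param refine_radius Half-width of the midpoint-track refinement window.
#' @param exclusion_radius Half-width of the zeroed exclusion zone.
#' @param ty_distance Maximum distance to a Ty element for removal, bp.
#' @param min_signal Stop when the global full-track maximum is `<=` this.
#' @param max_peaks Optional hard cap on the number of called sites.
#' @return An object of class `peak_params`.
#' @export
peak_params <- function(size_range = c(51, 100), smooth_width = 10,
                        refine_radius = 60, exclusion_radius = 500,
                        ty_distance = 100, min_signal = 0, max_peaks = Inf) {
  size_range <- as.integer(size_range)
  stopifnot(length(size_range) == 2L, size_range[1] <= size_range[2],
            smooth_width >= 1, refine_radius > 0, exclusion_radius > 0,
            ty_distance > 0)
  if (is.null(min_signal) && !is.finite(max_peaks))
    stop("no stop rule: supply 'min_signal' and/or a finite 'max_peaks'")
  if (is.null(min_signal)) min_signal <- -Inf
  structure(list(size_range = size_range,
                 smooth_width = smooth_width,
                 refine_radius = as.integer(refine_radius),
                 exclusion_radius = as.integer(exclusion_radius),
                 ty_distance = as.integer(ty_distance),
                 min_signal = min_signal,
                 max_peaks = max_peaks),
            class = "peak_params")
}

new_cmbs_list <- function(df, params = NULL) {
  rownames(df) <- NULL
  structure(df, params = params, class = c("cmbs_list", "data.frame"))
}

#' @export
print.cmbs_list <- function(x, ...) {
  cat(sprintf("<cmbs_list> %d candidate Mcm binding site(s)\n", nrow(x)))
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 10L), ...)
  if (nrow(x) > 10L) cat("...\n")
  invisible(x)
}

# half-width of the abundance readout window: the Mcm double hexamer
# protects 61 bp, so abundance = raw midpoint counts in midpoint +/- 30 bp
ABUNDANCE_HALFWIDTH <- 30L

#' Call candidate Mcm binding sites (CMBSs)
#'
#' Iterative dual-track peak identification.  Each round: (a) find the
#' genome-wide argmax of the smoothed full-extent track (the wide, robust
#' signal); (b) refine the coordinate to the argmax of the smoothed
#' midpoint track within `refine_radius` of it (the sharp signal);
#' (c) record the site with the full-track height at selection and an
#' abundance equal to the unsmoothed midpoint-track sum over the refined
#' coordinate +/- 30 bp; (d) zero both smoothed tracks within
#' `exclusion_radius` of the refined coordinate.  Rounds continue until the
#' stop rule fires.  Argmax ties are broken by chromosome order as declared
#' in the tracks, then by lowest coordinate, so identical inputs give
#' bitwise-identical output.
#'
#' @param full_track Smoothed full-extent `signal_track`.
#' @param mid_track Smoothed midpoint `signal_track` on the same genome.
#' @param params A [peak_params()] object.
#' @param raw_mid_track Optional unsmoothed midpoint track used for the
#'   abundance readout (never zeroed).  Defaults to `mid_track`.
#' @return A `cmbs_list` data.frame with columns `rank`, `chrom`,
#'   `midpoint`, `peak_height`, `abundance`, `cohort` (initially `NA`).
#' @export
call_cmbs <- function(full_track, mid_track, params = peak_params(),
                      raw_mid_track = NULL) {
  stopifnot(inherits(full_track, "signal_track"),
            inherits(mid_track, "signal_track"),
            inherits(params, "peak_params"))
  if (!same_genome(full_track, mid_track))
    stop("full and midpoint tracks must cover the same genome")
  if (is.null(raw_mid_track)) {
    raw_mid_track <- mid_track
  } else if (!same_genome(full_track, raw_mid_track)) {
    stop("raw midpoint track must cover the same genome")
  }
  chroms <- names(full_track$data)
  full <- full_track$data
  mid <- mid_track$data
  raw <- raw_mid_track$data
  lens <- track_lengths(full_track)

  # block maxima over fixed-size blocks: each exclusion zeroing touches only
  # a handful of blocks, so the global argmax never needs a full rescan
  B <- 4096L
  bmax <- lapply(full, function(x) {
    nb <- max(1L, as.integer(ceiling(length(x) / B)))
    vapply(seq_len(nb), function(k) {
      max(x[(((k - 1L) * B) + 1L):min(k * B, length(x))])
    }, numeric(1))
  })

  cap <- if (is.finite(params$max_peaks)) as.integer(params$max_peaks) else
    as.integer(sum(lens) %/% (2L * params$exclusion_radius) + length(lens) + 1L)
  res_chrom <- character(cap)
  res_mid <- integer(cap)
  res_height <- numeric(cap)
  res_abund <- numeric(cap)
  npk <- 0L

  repeat {
    if (npk >= params$max_peaks) break
    best_val <- -Inf
    best_ci <- 0L
    for (ci in seq_along(chroms)) {
      v <- max(bmax[[ci]])
      if (v > best_val) {
        best_val <- v
        best_ci <- ci
      }
    }
    if (!(best_val > params$min_signal)) break
    n <- lens[[best_ci]]
    x <- full[[best_ci]]
    blk <- which(bmax[[best_ci]] == best_val)[1L]
    off <- (blk - 1L) * B
    seg <- x[(off + 1L):min(off + B, n)]
    c_pos <- off + which.max(seg)
    # refine to the sharp midpoint-track coordinate near c_pos
    lo <- max(1L, c_pos - params$refine_radius)
    hi <- min(n, c_pos + params$refine_radius)
    m <- lo + which.max(mid[[best_ci]][lo:hi]) - 1L
    alo <- max(1L, m - ABUNDANCE_HALFWIDTH)
    ahi <- min(n, m + ABUNDANCE_HALFWIDTH)
    npk <- npk + 1L
    res_chrom[npk] <- chroms[best_ci]
    res_mid[npk] <- m
    res_height[npk] <- best_val
    res_abund[npk] <- sum(raw[[best_ci]][alo:ahi])
    # exclusion: zero both smoothed tracks around the refined coordinate
    zlo <- max(1L, m - params$exclusion_radius)
    zhi <- min(n, m + params$exclusion_radius)
    full[[best_ci]][zlo:zhi] <- 0
    mid[[best_ci]][zlo:zhi] <- 0
    x <- full[[best_ci]]
    for (k in (((zlo - 1L) %/% B) + 1L):(((zhi - 1L) %/% B) + 1L)) {
      bmax[[best_ci]][k] <- max(x[(((k - 1L) * B) + 1L):min(k * B, n)])
    }
  }

  idx <- seq_len(npk)
  new_cmbs_list(data.frame(rank = idx,
                           chrom = res_chrom[idx],
                           midpoint = res_mid[idx],
                           peak_height = res_height[idx],
                           abundance = res_abund[idx],
                           cohort = rep(NA_integer_, npk),
                           stringsAsFactors = FALSE),
                params = params)
}

# arithmetic bp distance from point positions to the nearest interval of a
# GRanges (0 if inside); Inf when the chromosome carries no interval
point_feature_distance <- function(chrom, pos, features) {
  fchrom <- as.character(GenomicRanges::seqnames(features))
  fs <- GenomicRanges::start(features)
  fe <- GenomicRanges::end(features)
  vapply(seq_along(pos), function(i) {
    sel <- fchrom == chrom[i]
    if (!any(sel)) return(Inf)
    d <- pmax(0L, fs[sel] - pos[i], pos[i] - fe[sel])
    min(d)
  }, numeric(1))
}

#' Filter CMBSs on rDNA and Ty annotations
#'
#' Within the rDNA locus, only the best-ranked site is kept (the repeat
#' array otherwise yields a pile of redundant calls around its one true
#' origin); sites whose midpoint lies within `ty_distance` of a Ty element
#' (arithmetic distance to the nearest interval edge, 0 inside) are
#' removed.  Survivors are re-ranked consecutively, preserving order.
#'
#' @param cmbs A `cmbs_list`.
#' @param ann A [genome_annotation()] supplying `rdna` and `ty` intervals
#'   (either may be empty, in which case that rule is a no-op).
#' @param ty_distance Distance threshold in bp (default 100).
#' @return The filtered, re-ranked `cmbs_list`.
#' @export
apply_filters <- function(cmbs, ann, ty_distance = 100) {
  keep <- rep(TRUE, nrow(cmbs))
  if (!is.null(ann$rdna) && length(ann$rdna)) {
    d <- point_feature_distance(cmbs$chrom, cmbs$midpoint, ann$rdna)
    inside <- d == 0
    if (any(inside)) {
      best <- which(inside)[which.min(cmbs$rank[inside])]
      keep[inside] <- FALSE
      keep[best] <- TRUE
    }
  }
  if (!is.null(ann$ty) && length(ann$ty)) {
    d <- point_feature_distance(cmbs$chrom, cmbs$midpoint, ann$ty)
    keep[d <= ty_distance] <- FALSE
  }
  out <- as.data.frame(cmbs)[keep, , drop = FALSE]
  out <- out[order(out$rank), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  new_cmbs_list(out, params = attr(cmbs, "params"))
}

#' Assign abundance cohorts
#'
#' Cohort `k` holds ranks `(k-1)*cohort_size + 1` to `k*cohort_size`, for
#' ranks up to `max_rank`; remaining sites get `NA`.  A per-cohort median
#' abundance table, normalized so that cohort 1's median is 100, is
#' attached as attribute `"cohort_table"` (see [cohort_table()]).  A final
#' partial cohort (when `max_rank` is not a multiple of `cohort_size`) is
#' flagged in the table.
#'
#' @param cmbs A `cmbs_list`.
#' @param cohort_size Sites per cohort (e.g. 200 for ssDNA composites, 500
#'   for nucleosome profiles, 1100 for PWM/GC-skew profiles).
#' @param max_rank Highest rank assigned to a cohort; defaults to all.
#' @return The `cmbs_list` with its `cohort` column filled.
#' @export
assign_cohorts <- function(cmbs, cohort_size, max_rank = nrow(cmbs)) {
  stopifnot(cohort_size >= 1, max_rank <= nrow(cmbs))
  cohort_size <- as.integer(cohort_size)
  out <- as.data.frame(cmbs)
  out$cohort <- ifelse(out$rank <= max_rank,
                       (out$rank - 1L) %/% cohort_size + 1L,
                       NA_integer_)
  assigned <- out[!is.na(out$cohort), , drop = FALSE]
  meds <- tapply(assigned$abundance, assigned$cohort, stats::median)
  sizes <- tapply(assigned$abundance, assigned$cohort, length)
  ks <- as.integer(names(meds))
  tbl <- data.frame(cohort = ks,
                    n = as.integer(sizes),
                    median_abundance = as.numeric(meds),
                    normalized_median = 100 * as.numeric(meds) /
                      as.numeric(meds[1L]),
                    partial = as.integer(sizes) < cohort_size)
  res <- new_cmbs_list(out, params = attr(cmbs, "params"))
  attr(res, "cohort_table") <- tbl
  res
}

#' Per-cohort median abundance table
#' @param cmbs A `cmbs_list` processed by [assign_cohorts()].
#' @return The cohort table data.frame.
#' @export
cohort_table <- function(cmbs) {
  tbl <- attr(cmbs, "cohort_table")
  if (is.null(tbl)) stop("no cohorts assigned; run assign_cohorts() first")
  tbl
}

#' Write CMBSs as a BED6+2 table
#'
#' Columns: chrom, midpoint-30 (0-based), midpoint+31, name `CMBS_<rank>`,
#' score = abundance, strand ".", peak_height, cohort.
#'
#' @param cmbs A `cmbs_list`.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_cmbs_bed <- function(cmbs, path) {
  df <- data.frame(chrom = cmbs$chrom,
                   start = cmbs$midpoint - 1L - ABUNDANCE_HALFWIDTH,
                   end = cmbs$midpoint + ABUNDANCE_HALFWIDTH,
                   name = sprintf("CMBS_%d", cmbs$rank),
                   score = cmbs$abundance,
                   strand = ".",
                   peak_height = cmbs$peak_height,
                   cohort = cmbs$cohort)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
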