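# Independent oracle for the iterative peak caller: re-scans every
# chromosome from scratch on every iteration, with the same declared
# tie-breaking (chromosome order, then lowest coordinate).  Deliberately
# shares no code with call_cmbs().
naive_call_cmbs <- function(full_track, mid_track, params,
                            raw_mid_track = NULL) {
  full <- full_track$data
  mid <- mid_track$data
  raw <- if (is.null(raw_mid_track)) mid_track$data else raw_mid_track$data
  chroms <- names(full)
  rows <- list()
  repeat {
    if (length(rows) >= params$max_peaks) break
    best_val <- -Inf
    best_ci <- 0L
    best_pos <- 0L
    for (ci in seq_along(chroms)) {
      v <- max(full[[ci]])
      if (v > best_val) {
        best_val <- v
        best_ci <- ci
        best_pos <- which.max(full[[ci]])
      }
    }
    if (!(best_val > params$min_signal)) break
    n <- length(full[[best_ci]])
    lo <- max(1L, best_pos - params$refine_radius)
    hi <- min(n, best_pos + params$refine_radius)
    m <- lo + which.max(mid[[best_ci]][lo:hi]) - 1L
    alo <- max(1L, m - 30L)
    ahi <- min(n, m + 30L)
    rows[[length(rows) + 1L]] <-
      data.frame(chrom = chroms[best_ci], midpoint = m,
                 peak_height = best_val,
                 abundance = sum(raw[[best_ci]][alo:ahi]),
                 stringsAsFactors = FALSE)
    zlo <- max(1L, m - params$exclusion_radius)
    zhi <- min(n, m + params$exclusion_radius)
    full[[best_ci]][zlo:zhi] <- 0
    mid[[best_ci]][zlo:zhi] <- 0
  }
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(chrom = character(), midpoint = integer(),
               peak_height = numeric(), abundance = numeric(),
               stringsAsFactors = FALSE)
  df <- cbind(rank = seq_len(nrow(df)), df)
  df$cohort <- NA_integer_
  rownames(df) <- NULL
  df
}

# a random smoothed track pair on one small chromosome
random_track_pair <- function(n, seed, chrom = "chrT") {
  set.seed(seed)
  full <- signal_track(setNames(list(runif(n)), chrom), "external")
  mid <- signal_track(setNames(list(runif(n)), chrom), "external")
  list(full = smooth_track(full, 10), mid = smooth_track(mid, 10))
}

# triangular bump of given peak height and half-width on a numeric vector
add_bump <- function(x, center, height, halfwidth = 50) {
  idx <- (center - halfwidth):(center + halfwidth)
  x[idx] <- x[idx] + height * (1 - abs(idx - center) / (halfwidth + 1))
  x
}

# strip cmbs_list attributes/class down to a plain data.frame for
# comparison against the oracle
plain_cmbs <- function(x) {
  df <- as.data.frame(x)
  attr(df, "params") <- NULL
  attr(df, "cohort_table") <- NULL
  class(df) <- "data.frame"
  rownames(df) <- NULL
  df
}
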