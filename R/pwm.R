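BASES <- c("A", "C", "G", "T")

#' Construct a position-weight matrix object
#'
#' @param f 17 x 4 matrix of per-position base probabilities, columns
#'   A, C, G, T; each row must sum to 1 within `row_tol` (printed tables
#'   carry rounding).
#' @param background Base composition the odds are taken against (must sum
#'   to 1); uniform by default.
#' @param pseudocount Added to both matrix and background entries before
#'   taking odds, so zero-probability bases score finitely.
#' @param log_base Base of the logarithm (2 by default, i.e. bits).
#' @param row_tol Allowed deviation of row sums from 1.
#' @return An object of class `pwm`.
#' @export
pwm <- function(f, background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
                pseudocount = 0.001, log_base = 2, row_tol = 0.002) {
  f <- as.matrix(f)
  stopifnot(ncol(f) == 4L, pseudocount >= 0, log_base > 0)
  colnames(f) <- BASES
  if (any(abs(rowSums(f) - 1) > row_tol))
    stop("PWM rows must sum to 1 (tolerance ", row_tol, ")")
  background <- stats::setNames(as.numeric(background), BASES)
  if (abs(sum(background) - 1) > 1e-6)
    stop("background frequencies must sum to 1")
  structure(list(f = f, background = background,
                 pseudocount = pseudocount, log_base = log_base),
            class = "pwm")
}

#' The extended ACS (EACS) position-weight matrix
#'
#' The 17-position probability matrix describing the extended ARS
#' consensus sequence recognized by Orc, shipped as package data
#' (`inst/extdata/eacs_pwm.tsv`).  Scores are log-odds:
#' `S = sum_i log_b((f[i, base_i] + eps) / (bg[base_i] + eps))`.
#'
#' @inheritParams pwm
#' @return A `pwm` object.
#' @export
eacs_pwm <- function(background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
                     pseudocount = 0.001, log_base = 2) {
  path <- system.file("extdata", "eacs_pwm.tsv", package = "checOrigins",
                      mustWork = TRUE)
  tab <- utils::read.table(path, header = TRUE, sep = "\t")
  pwm(as.matrix(tab[, BASES]), background = background,
      pseudocount = pseudocount, log_base = log_base)
}

# per-position log-odds lookup table (17 x 4)
pwm_logodds <- function(p) {
  num <- p$f + p$pseudocount
  den <- p$background + p$pseudocount
  log(sweep(num, 2L, den, "/"), base = p$log_base)
}

#' Consensus sequence of a PWM (per-position most probable base)
#' @param p A `pwm`.
#' @return A character scalar.
#' @export
pwm_consensus <- function(p) {
  paste(BASES[apply(p$f, 1L, which.max)], collapse = "")
}

#' Score one sequence against a PWM
#'
#' @param seq Character scalar (or `DNAString`) whose length equals the
#'   number of PWM positions; only A/C/G/T are allowed.
#' @param p A `pwm`.
#' @return The log-odds score.
#' @export
pwm_score <- function(seq, p) {
  s <- toupper(as.character(seq))
  chars <- strsplit(s, "")[[1]]
  if (length(chars) != nrow(p$f))
    stop("sequence length must be ", nrow(p$f))
  idx <- match(chars, BASES)
  if (anyNA(idx)) stop("sequence contains non-ACGT characters")
  L <- pwm_logodds(p)
  sum(L[cbind(seq_len(nrow(L)), idx)])
}

#' Scan a genome with a PWM on both strands
#'
#' `watson[i]` scores the forward 17-mer starting at `i`; `crick[i]`
#' scores the reverse complement of that same window, so both tracks are
#' indexed by the window's leftmost coordinate and are directly comparable
#' per offset.  The last 16 positions of each chromosome, and windows
#' containing any non-ACGT base, carry `NA`.
#'
#' @param genome A named `DNAStringSet`, or a named character vector of
#'   chromosome sequences.
#' @param p A `pwm` (default [eacs_pwm()]).
#' @return List of two `"external"` [signal_track()]s, `watson` and
#'   `crick`.
#' @export
scan_strands <- function(genome, p = eacs_pwm()) {
  seqs <- if (is.character(genome)) genome else
    stats::setNames(as.character(genome), names(genome))
  if (is.null(names(seqs))) stop("genome sequences must be named")
  w <- nrow(p$f)
  L <- pwm_logodds(p)
  Lc <- L[w:1, 4:1, drop = FALSE]  # Lc[j, b] = L[w+1-j, complement(b)]
  res_w <- list()
  res_c <- list()
  for (ch in names(seqs)) {
    b <- match(strsplit(toupper(seqs[[ch]]), "")[[1]], BASES)
    n <- length(b)
    if (n < w) {
      res_w[[ch]] <- rep(NA_real_, n)
      res_c[[ch]] <- rep(NA_real_, n)
      next
    }
    nw <- n - w + 1L
    sW <- numeric(nw)
    sC <- numeric(nw)
    for (j in seq_len(w)) {
      bj <- b[j:(j + nw - 1L)]
      sW <- sW + L[j, ][bj]   # NA base propagates NA through the sum
      sC <- sC + Lc[j, ][bj]
    }
    res_w[[ch]] <- c(sW, rep(NA_real_, w - 1L))
    res_c[[ch]] <- c(sC, rep(NA_real_, w - 1L))
  }
  list(watson = signal_track(res_w, mode = "external"),
       crick = signal_track(res_c, mode = "external"))
}

#' PWM scanning parameters
#'
#' @param strong_threshold Minimum Watson-strand score defining a
#'   "particularly strong" ACS (default 10.8).
#' @param proximity ACS-to-CMBS pairing distance in bp (default 100).
#' @param max_score_window Half-width (bp) of the window around a CMBS
#'   midpoint over which its per-site maximum score is taken (default 100).
#' @return An object of class `scan_params`.
#' @export
scan_params <- function(strong_threshold = 10.8, proximity = 100,
                        max_score_window = 100) {
  stopifnot(proximity > 0, max_score_window > 0)
  structure(list(strong_threshold = strong_threshold,
                 proximity = as.integer(proximity),
                 max_score_window = as.integer(max_score_window)),
            class = "scan_params")
}

#' Cohort composites of PWM scores around CMBS midpoints
#'
#' Per cohort of consecutive ranks, the mean Watson and Crick score at
#' each offset from the CMBS midpoint (missing scores excluded).
#'
#' @param tracks Result of [scan_strands()].
#' @param cmbs A `cmbs_list`.
#' @param cohort_size Sites per cohort (default 1100).
#' @param halfwidth Profile half-width in bp (default 200).
#' @param max_rank Highest rank included (default all).
#' @return List with `watson` and `crick`, each an offsets x cohorts
#'   matrix.
#' @export
acs_composite <- function(tracks, cmbs, cohort_size = 1100, halfwidth = 200,
                          max_rank = nrow(cmbs)) {
  list(watson = cohort_composite(tracks$watson, cmbs, cohort_size, halfwidth,
                                max_rank),
       crick = cohort_composite(tracks$crick, cmbs, cohort_size, halfwidth,
                               max_rank))
}

# per-CMBS maximum strand score within midpoint +/- window
cmbs_max_score <- function(track, cmbs, window) {
  lens <- track_lengths(track)
  vapply(seq_len(nrow(cmbs)), function(i) {
    x <- track$data[[cmbs$chrom[i]]]
    lo <- max(1L, cmbs$midpoint[i] - window)
    hi <- min(lens[[cmbs$chrom[i]]], cmbs$midpoint[i] + window)
    v <- x[lo:hi]
    if (all(is.na(v))) -Inf else max(v, na.rm = TRUE)
  }, numeric(1))
}

#' Two-sided Orc-site analysis: strong-Watson subset vs all
#'
#' Extracts the CMBSs whose maximum Watson-strand score within
#' `max_score_window` of the midpoint reaches `strong_threshold`, then
#' compares the Crick-strand composite of that subset with the composite
#' over all sites.  A subset Crick enrichment comparable to the full set
#' argues that sites carry Orc binding sites on both flanks.
#'
#' @param tracks Result of [scan_strands()].
#' @param cmbs A `cmbs_list`.
#' @param params A [scan_params()].
#' @param halfwidth Composite half-width in bp.
#' @return List: `subset` (`cmbs_list`), `watson_max` (per-site scores),
#'   `crick_subset` and `crick_all` (offset profiles; `NULL` when the
#'   subset is empty).
#' @export
strong_watson_subset <- function(tracks, cmbs, params = scan_params(),
                                 halfwidth = 200) {
  wmax <- cmbs_max_score(tracks$watson, cmbs, params$max_score_window)
  sel <- wmax >= params$strong_threshold
  subset <- new_cmbs_list(as.data.frame(cmbs)[sel, , drop = FALSE],
                          params = attr(cmbs, "params"))
  if (!nrow(subset)) {
    message("no CMBS reaches the strong-ACS threshold; composites omitted")
    return(list(subset = subset, watson_max = wmax,
                crick_subset = NULL, crick_all = NULL))
  }
  list(subset = subset,
       watson_max = wmax,
       crick_subset = composite_profile(
         extract_matrix(tracks$crick, subset, halfwidth), "none"),
       crick_all = composite_profile(
         extract_matrix(tracks$crick, cmbs, halfwidth), "none"))
}

#' ACS-anchored cumulative Mcm signal profile
#'
#' Windows of the fragment-midpoint track centered on each ACS are
#' oriented by ACS strand (offset axis 5' to 3' of the motif), scaled so
#' each window totals 100, and summed into a cumulative vector.  Mass at
#' positive offsets therefore measures Mcm loading downstream of the ACS.
#' All-zero windows are dropped and counted.
#'
#' @param mid_track Midpoint-mode `signal_track` from 51--100 bp inserts.
#' @param acs Oriented ACS positions (data.frame `chrom`, `pos`, `strand`
#'   or stranded `GRanges`).
#' @param halfwidth Window half-width in bp (default 500, i.e. 1 kb).
#' @return Named numeric profile over offsets, with attributes `n_used`,
#'   `n_zero` and `n_oob`.
#' @export
acs_anchored_mcm_profile <- function(mid_track, acs, halfwidth = 500) {
  m <- extract_matrix(mid_track, acs, halfwidth)
  s <- rowSums(m, na.rm = TRUE)
  nz <- s != 0
  prof <- if (any(nz)) {
    colSums(m[nz, , drop = FALSE] * (100 / s[nz]), na.rm = TRUE)
  } else {
    stats::setNames(numeric(ncol(m)), colnames(m))
  }
  structure(prof, n_used = sum(nz), n_zero = sum(!nz),
            n_oob = attr(m, "dropped"))
}

#' Downstream-of-ACS loading bias
#'
#' Pairs each ACS with the nearest CMBS midpoint within `proximity` bp
#' (ties broken toward the lower coordinate) and counts how often the
#' site lies downstream of the oriented motif (midpoint > pos on "+",
#' midpoint < pos on "-").  A midpoint exactly at the ACS position counts
#' as neither and is reported separately.
#'
#' @param cmbs A `cmbs_list`.
#' @param acs Oriented ACS positions.
#' @param proximity Pairing distance in bp (default 100).
#' @return List: `n_paired`, `n_downstream`, `n_upstream`, `n_at_acs`,
#'   `fraction` (= downstream/paired) and the per-pair data.frame `pairs`.
#' @export
downstream_bias <- function(cmbs, acs, proximity = 100) {
  a <- as_anchors(acs)
  n <- nrow(a)
  paired_mid <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    sel <- cmbs$chrom == a$chrom[i]
    if (!any(sel)) next
    mids <- cmbs$midpoint[sel]
    d <- abs(mids - a$pos[i])
    within <- d <= proximity
    if (!any(within)) next
    cand <- mids[within]
    dmin <- min(d[within])
    paired_mid[i] <- min(cand[d[within] == dmin])  # tie -> lower coordinate
  }
  ok <- !is.na(paired_mid)
  downstream <- ok & ((a$strand == "+" & paired_mid > a$pos) |
                        (a$strand == "-" & paired_mid < a$pos))
  at_acs <- ok & paired_mid == a$pos
  upstream <- ok & !downstream & !at_acs
  list(n_paired = sum(ok),
       n_downstream = sum(downstream),
       n_upstream = sum(upstream),
       n_at_acs = sum(at_acs),
       fraction = if (any(ok)) sum(downstream) / sum(ok) else NA_real_,
       pairs = data.frame(a, cmbs_midpoint = paired_mid,
                          downstream = downstream))
}
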