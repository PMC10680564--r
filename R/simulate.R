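#' Configuration for the synthetic genome generator
#'
#' Defaults emulate the structure of the real assay at continuous-
#' integration scale: one 500 kb chromosome carrying 100 origins whose
#' planted abundances span three orders of magnitude, each origin sitting
#' in a ~150 bp nucleosome-free region flanked by a 165 bp-spaced
#' nucleosome array, with an oriented ACS motif 35 bp upstream of the Mcm
#' double-hexamer midpoint and divergently transcribed flanking genes.
#'
#' @param chrom_lengths Named integer vector of chromosome lengths.
#' @param n_origins Total origins planted (distributed over chromosomes in
#'   proportion to length).
#' @param abundance_range Min and max planted abundance (expected relative
#'   fragment yield); abundances follow a geometric series over this range
#'   assigned to origins in random order, so the configured dynamic range
#'   is realized exactly.
#' @param acs_offset Distance (bp) from the ACS window start to the Mcm
#'   midpoint on the oriented strand (default 35).
#' @param nfr_width Nucleosome-free region width in bp (default 150).
#' @param nucleosome_spacing Dyad-to-dyad spacing in bp (default 165).
#' @param first_dyad_offset Distance from origin midpoint to the first
#'   flanking dyad (default 115 bp: half NFR plus half nucleosome).
#' @param downstream_fraction Fraction of origins whose Mcm midpoint lies
#'   downstream of the oriented ACS (default 0.77, the rate observed at
#'   annotated origins; set to 1 for strictly directional loading).
#' @param background_fraction Fraction of MCM-ChEC fragments drawn from
#'   nucleosomes rather than planted footprints (default 0.2).
#' @param midpoint_jitter Half-range (bp) of uniform jitter applied to
#'   fragment centers around the planted midpoint (default 3).
#' @param expression_meanlog,expression_sdlog Log-normal parameters of
#'   simulated gene expression (arbitrary units).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(chrom_lengths = c(chrS = 500000L),
                       n_origins = 100,
                       abundance_range = c(1, 1000),
                       acs_offset = 35,
                       nfr_width = 150,
                       nucleosome_spacing = 165,
                       first_dyad_offset = 115,
                       downstream_fraction = 0.77,
                       background_fraction = 0.2,
                       midpoint_jitter = 3,
                       expression_meanlog = 2,
                       expression_sdlog = 1) {
  stopifnot(all(chrom_lengths > 0), n_origins >= 0,
            length(abundance_range) == 2L,
            abundance_range[1] > 0,
            abundance_range[1] <= abundance_range[2],
            acs_offset > 0, nfr_width > 0, nucleosome_spacing > 0,
            downstream_fraction >= 0, downstream_fraction <= 1,
            background_fraction >= 0, background_fraction < 1,
            midpoint_jitter >= 0)
  structure(list(chrom_lengths = chrom_lengths,
                 n_origins = as.integer(n_origins),
                 abundance_range = abundance_range,
                 acs_offset = as.integer(acs_offset),
                 nfr_width = as.integer(nfr_width),
                 nucleosome_spacing = as.integer(nucleosome_spacing),
                 first_dyad_offset = as.integer(first_dyad_offset),
                 downstream_fraction = downstream_fraction,
                 background_fraction = background_fraction,
                 midpoint_jitter = as.integer(midpoint_jitter),
                 expression_meanlog = expression_meanlog,
                 expression_sdlog = expression_sdlog),
            class = "sim_config")
}

# sample n values from the discretized truncated normal on lo:hi
sample_trunc_norm <- function(n, mean, sd, lo, hi) {
  vals <- lo:hi
  p <- stats::dnorm(vals, mean, sd)
  sample(vals, n, replace = TRUE, prob = p)
}

# MCM-ChEC insert length law: with probability 0.15 a clean 61 bp
# double-hexamer footprint cut, otherwise cut-position dispersion as a
# discretized Gaussian (mean 61, sd 8) truncated to 51..100 bp
sample_mcm_lengths <- function(n) {
  vals <- 51:100
  p <- stats::dnorm(vals, 61, 8)
  p <- p / sum(p) * 0.85
  p[vals == 61] <- p[vals == 61] + 0.15
  sample(vals, n, replace = TRUE, prob = p)
}

#' Simulate a toy genome with planted replication origins
#'
#' Generates a random A/C/G/T genome, plants PWM-sampled oriented ACS
#' 17-mers with Mcm midpoints offset downstream (or upstream) of them,
#' tiles the non-NFR sequence with genes whose strands give every origin
#' divergently transcribed flanks, and lays down flanking nucleosome dyad
#' arrays.  Identical seeds give bitwise-identical output.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed; recorded in the truth attributes.
#' @return List: `genome` (named `DNAStringSet`), `annotation`
#'   ([genome_annotation()]), `truth` (data.frame, one row per origin:
#'   `chrom`, `mcm_midpoint`, `abundance`, `acs_pos`, `acs_strand`,
#'   `downstream`, `activity`; attributes `dyads`, `nfr`, `seqlens`,
#'   `config`, `seed`).
#' @export
simulate_genome <- function(config = sim_config(), seed = 1) {
  set.seed(seed)
  pw <- eacs_pwm()
  lens <- config$chrom_lengths
  chars <- lapply(lens, function(n) sample(BASES, n, replace = TRUE))

  # origins per chromosome, proportional to length
  n_or <- config$n_origins
  alloc <- if (n_or > 0) {
    a <- floor(n_or * lens / sum(lens))
    rem <- n_or - sum(a)
    if (rem > 0) a[seq_len(rem)] <- a[seq_len(rem)] + 1L
    a
  } else stats::setNames(rep(0L, length(lens)), names(lens))

  margin <- 1500L
  rows <- list()
  for (ch in names(lens)) {
    k <- alloc[[ch]]
    if (k == 0) next
    slot <- (lens[[ch]] - 2L * margin) / k
    if (slot < 2500)
      stop("cannot place ", k, " origins on ", ch,
           " without overlap: need >= 2.5 kb per origin")
    mids <- as.integer(round(margin + (seq_len(k) - 0.5) * slot +
                               stats::runif(k, -slot / 5, slot / 5)))
    rows[[ch]] <- data.frame(chrom = ch, mcm_midpoint = mids,
                             stringsAsFactors = FALSE)
  }
  truth <- if (length(rows)) do.call(rbind, rows) else
    data.frame(chrom = character(), mcm_midpoint = integer(),
               stringsAsFactors = FALSE)
  n <- nrow(truth)

  if (n > 0) {
    ab <- exp(seq(log(config$abundance_range[1]),
                  log(config$abundance_range[2]), length.out = max(n, 2L)))
    truth$abundance <- if (n == 1) config$abundance_range[2] else
      ab[sample.int(n)]
    truth$acs_strand <- sample(c("+", "-"), n, replace = TRUE)
    truth$downstream <- stats::runif(n) < config$downstream_fraction
    # ACS window start relative to the Mcm midpoint: downstream loading on
    # "+" puts the motif acs_offset bp to the left; signs flip with strand
    # and with upstream loading
    side <- ifelse(truth$acs_strand == "+", -1L, 1L) *
      ifelse(truth$downstream, 1L, -1L)
    truth$acs_pos <- truth$mcm_midpoint + side * config$acs_offset
    truth$activity <- truth$abundance / max(truth$abundance)

    # plant PWM-sampled 17-mers (reverse complemented for "-" motifs)
    for (i in seq_len(n)) {
      motif <- vapply(seq_len(nrow(pw$f)), function(j) {
        sample(BASES, 1L, prob = pw$f[j, ])
      }, character(1))
      if (truth$acs_strand[i] == "-") {
        motif <- rev(c(A = "T", C = "G", G = "C", T = "A")[motif])
      }
      at <- truth$acs_pos[i]:(truth$acs_pos[i] + nrow(pw$f) - 1L)
      chars[[truth$chrom[i]]][at] <- motif
    }
  } else {
    truth$abundance <- numeric(0)
    truth$acs_strand <- character(0)
    truth$downstream <- logical(0)
    truth$acs_pos <- integer(0)
    truth$activity <- numeric(0)
  }

  nfr_h <- config$nfr_width %/% 2L

  # nucleosome dyad arrays: first dyad at +/- first_dyad_offset from each
  # origin midpoint, then every nucleosome_spacing bp out to the midpoint
  # of the gap to the neighboring origin (or the chromosome end margin)
  dyads <- list()
  for (ch in names(lens)) {
    sel <- truth$chrom == ch
    if (!any(sel)) next
    mids <- sort(truth$mcm_midpoint[sel])
    bounds_lo <- c(60L, as.integer((mids[-length(mids)] + mids[-1]) / 2))
    bounds_hi <- c(as.integer((mids[-length(mids)] + mids[-1]) / 2),
                   lens[[ch]] - 60L)
    pos <- integer(0)
    for (i in seq_along(mids)) {
      left <- seq(mids[i] - config$first_dyad_offset, bounds_lo[i],
                  by = -config$nucleosome_spacing)
      right <- seq(mids[i] + config$first_dyad_offset, bounds_hi[i],
                   by = config$nucleosome_spacing)
      pos <- c(pos, left, right)
    }
    pos <- sort(unique(as.integer(pos)))
    pos <- pos[pos > 60L & pos < lens[[ch]] - 60L]
    dyads[[ch]] <- data.frame(chrom = ch, pos = pos,
                              stringsAsFactors = FALSE)
  }
  dyads <- if (length(dyads)) do.call(rbind, dyads) else
    data.frame(chrom = character(), pos = integer(),
               stringsAsFactors = FALSE)
  rownames(dyads) <- NULL

  # genes tile the sequence between NFRs; the gene left of each origin is
  # on "-" and the gene right of it on "+", i.e. divergent flanks
  gene_rows <- list()
  for (ch in names(lens)) {
    sel <- truth$chrom == ch
    mids <- sort(truth$mcm_midpoint[sel])
    starts <- c(1L, mids + nfr_h + 1L)
    ends <- c(mids - nfr_h - 1L, lens[[ch]])
    for (i in seq_along(starts)) {
      if (ends[i] - starts[i] + 1L < 400L) next
      cut <- as.integer((starts[i] + ends[i]) / 2)
      gene_rows[[length(gene_rows) + 1L]] <-
        data.frame(chrom = ch,
                   start = c(starts[i], cut + 1L),
                   end = c(cut - 1L, ends[i]),
                   strand = c("+", "-"),
                   stringsAsFactors = FALSE)
    }
  }
  genes <- if (length(gene_rows)) do.call(rbind, gene_rows) else
    data.frame(chrom = character(), start = integer(), end = integer(),
               strand = character(), stringsAsFactors = FALSE)
  genes_gr <- GenomicRanges::GRanges(
    genes$chrom, IRanges::IRanges(genes$start, genes$end),
    strand = genes$strand, seqlengths = lens)
  if (length(genes_gr)) {
    S4Vectors::mcols(genes_gr)$gene_id <-
      sprintf("g%04d", seq_along(genes_gr))
    S4Vectors::mcols(genes_gr)$expression <-
      stats::rlnorm(length(genes_gr), config$expression_meanlog,
                    config$expression_sdlog)
  }

  nfr_gr <- GenomicRanges::GRanges(
    truth$chrom,
    IRanges::IRanges(truth$mcm_midpoint - nfr_h, truth$mcm_midpoint + nfr_h),
    seqlengths = lens)
  origin_gr <- GenomicRanges::GRanges(
    truth$chrom,
    IRanges::IRanges(truth$mcm_midpoint - 30L, truth$mcm_midpoint + 30L),
    seqlengths = lens)

  genome <- Biostrings::DNAStringSet(
    vapply(chars, paste, character(1), collapse = ""))
  names(genome) <- names(lens)

  ann <- genome_annotation(
    genes = genes_gr, origins = origin_gr,
    acs = if (n > 0) data.frame(chrom = truth$chrom, pos = truth$acs_pos,
                                strand = truth$acs_strand) else NULL)

  attr(truth, "dyads") <- dyads
  attr(truth, "nfr") <- nfr_gr
  attr(truth, "seqlens") <- lens
  attr(truth, "config") <- config
  attr(truth, "seed") <- seed
  list(genome = genome, annotation = ann, truth = truth)
}

#' Simulate paired-end fragment sets
#'
#' * `mcm_chec`: fragment centers at planted Mcm midpoints (uniform jitter
#'   within `midpoint_jitter`), per-origin counts multinomial in planted
#'   abundance, insert lengths sharply peaked at 61 bp within 51--100 bp;
#'   plus `background_fraction` of nucleosome-length fragments centered at
#'   dyads.
#' * `dyad`: chemical-cleavage fragments at dyads, lengths peaked at 51 bp
#'   within 46--56 bp.
#' * `mnase`: mononucleosome fragments at dyads, lengths around 147 bp.
#'
#' @param truth Truth table from [simulate_genome()].
#' @param assay One of `"mcm_chec"`, `"dyad"`, `"mnase"`.
#' @param n Number of fragments to draw (fragments falling off a
#'   chromosome end are discarded).
#' @param seed Integer seed.
#' @return A `GRanges` fragment set with chromosome lengths attached.
#' @export
simulate_fragments <- function(truth, assay = c("mcm_chec", "dyad", "mnase"),
                               n, seed = 1) {
  assay <- match.arg(assay)
  stopifnot(n >= 0)
  set.seed(seed)
  config <- attr(truth, "config")
  dyads <- attr(truth, "dyads")
  lens <- attr(truth, "seqlens")
  empty <- GenomicRanges::GRanges(seqlengths = lens)
  if (n == 0) return(empty)

  if (assay == "mcm_chec") {
    nb <- if (nrow(dyads)) round(n * config$background_fraction) else 0L
    no <- n - nb
    if (nrow(truth) == 0) {
      no <- 0L
      nb <- n
      if (!nrow(dyads)) stop("nothing to simulate: no origins and no dyads")
    }
    parts <- list()
    if (no > 0) {
      counts <- as.vector(stats::rmultinom(1L, no, truth$abundance))
      jit <- if (config$midpoint_jitter > 0) {
        sample(seq(-config$midpoint_jitter, config$midpoint_jitter),
               no, replace = TRUE)
      } else integer(no)
      centers <- rep(truth$mcm_midpoint, counts) + jit
      parts$fg <- data.frame(chrom = rep(truth$chrom, counts),
                             center = centers,
                             len = sample_mcm_lengths(no))
    }
    if (nb > 0) {
      di <- sample.int(nrow(dyads), nb, replace = TRUE)
      parts$bg <- data.frame(chrom = dyads$chrom[di],
                             center = dyads$pos[di] +
                               sample(-10:10, nb, replace = TRUE),
                             len = sample_trunc_norm(nb, 165, 30, 100, 250))
    }
    df <- do.call(rbind, parts)
  } else if (assay == "dyad") {
    if (!nrow(dyads)) return(empty)
    di <- sample.int(nrow(dyads), n, replace = TRUE)
    df <- data.frame(chrom = dyads$chrom[di],
                     center = dyads$pos[di] +
                       sample(-1:1, n, replace = TRUE),
                     len = sample_trunc_norm(n, 51, 2, 46, 56))
  } else {
    if (!nrow(dyads)) return(empty)
    di <- sample.int(nrow(dyads), n, replace = TRUE)
    df <- data.frame(chrom = dyads$chrom[di],
                     center = dyads$pos[di] +
                       sample(-5:5, n, replace = TRUE),
                     len = sample_trunc_norm(n, 147, 10, 120, 180))
  }
  # choose start so that start + floor(len/2) reproduces the drawn center
  start <- df$center - df$len %/% 2L
  end <- start + df$len - 1L
  ok <- start >= 1L & end <= lens[df$chrom]
  GenomicRanges::GRanges(df$chrom[ok],
                         IRanges::IRanges(start[ok], end[ok]),
                         seqlengths = lens)
}

#' Simulate a processed ssDNA (S/G1 ratio) track
#'
#' Gaussian-shaped replication-initiation bumps at origin midpoints with
#' height proportional to planted activity over a baseline of 1.0, plus
#' Gaussian noise; optionally subsampled to probe-like spacing (positions
#' between probes set to `NA`).
#'
#' @param truth Truth table from [simulate_genome()].
#' @param peak_width Gaussian sd of each bump in bp (default 800).
#' @param max_height Bump height for the most active origin (default 4).
#' @param noise_sd Per-base Gaussian noise sd (default 0.05).
#' @param probe_spacing Keep one value every this many bp (default 1 =
#'   dense).
#' @param seed Integer seed.
#' @return An `"external"` [signal_track()].
#' @export
simulate_ssdna <- function(truth, peak_width = 800, max_height = 4,
                           noise_sd = 0.05, probe_spacing = 1, seed = 1) {
  set.seed(seed)
  lens <- attr(truth, "seqlens")
  data <- lapply(names(lens), function(ch) {
    nl <- lens[[ch]]
    x <- rep(1, nl)
    if (noise_sd > 0) x <- x + stats::rnorm(nl, 0, noise_sd)
    sel <- which(truth$chrom == ch)
    for (i in sel) {
      m <- truth$mcm_midpoint[i]
      lo <- max(1L, m - 4L * as.integer(peak_width))
      hi <- min(nl, m + 4L * as.integer(peak_width))
      d <- (lo:hi) - m
      x[lo:hi] <- x[lo:hi] + truth$activity[i] * max_height *
        exp(-d^2 / (2 * peak_width^2))
    }
    if (probe_spacing > 1) {
      keep <- seq(1L, nl, by = as.integer(probe_spacing))
      y <- rep(NA_real_, nl)
      y[keep] <- x[keep]
      x <- y
    }
    x
  })
  names(data) <- names(lens)
  signal_track(data, mode = "external")
}

#' Plant a replication GC-skew footprint around origins
#'
#' Within 200 bp of each origin midpoint, cytosines on the strand
#' replicated as the lagging-strand template are deaminated (C to T): on
#' the Watson strand downstream of the midpoint, and on the Crick strand
#' (i.e. Watson G to A) upstream.  The substitution rate `q = 2s/(1+s)`
#' yields an expected Watson-strand skew of `-s` upstream and `+s`
#' downstream for a base-balanced genome.  Planted ACS 17-mers are never
#' mutated.  `s = 0` returns the genome unchanged.
#'
#' @param genome Named `DNAStringSet` from [simulate_genome()].
#' @param truth Matching truth table.
#' @param s Target skew magnitude in [0, 1].
#' @param seed Integer seed.
#' @param halfwidth Footprint half-width in bp (default 200).
#' @return The modified `DNAStringSet`.
#' @export
plant_gc_skew <- function(genome, truth, s, seed = 1, halfwidth = 200) {
  stopifnot(s >= 0, s <= 1)
  if (s == 0 || nrow(truth) == 0) return(genome)
  set.seed(seed)
  q <- 2 * s / (1 + s)
  lens <- attr(truth, "seqlens")
  protected <- lapply(lens, function(nl) logical(nl))
  for (i in seq_len(nrow(truth))) {
    at <- truth$acs_pos[i]:(truth$acs_pos[i] + 16L)
    protected[[truth$chrom[i]]][at] <- TRUE
  }
  out <- as.character(genome)
  for (ch in names(lens)) {
    sel <- which(truth$chrom == ch)
    if (!length(sel)) next
    chars <- strsplit(out[[ch]], "")[[1]]
    for (i in sel) {
      m <- truth$mcm_midpoint[i]
      up <- max(1L, m - as.integer(halfwidth)):(m - 1L)
      down <- (m + 1L):min(lens[[ch]], m + as.integer(halfwidth))
      # upstream: lagging template is Crick; C->T there is G->A on Watson
      g <- up[chars[up] == "G" & !protected[[ch]][up]]
      g <- g[stats::runif(length(g)) < q]
      chars[g] <- "A"
      cc <- down[chars[down] == "C" & !protected[[ch]][down]]
      cc <- cc[stats::runif(length(cc)) < q]
      chars[cc] <- "T"
    }
    out[[ch]] <- paste(chars, collapse = "")
  }
  res <- Biostrings::DNAStringSet(out)
  names(res) <- names(genome)
  res
}

#' Chromosome lengths of a simulated genome
#' @param genome A named `DNAStringSet`.
#' @return Named integer vector.
#' @export
genome_seqlens <- function(genome) {
  stats::setNames(Biostrings::width(genome), names(genome))
}
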