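#' Bundle genome annotations
#'
#' Collects the annotation tracks the pipeline consumes: gene bodies with
#' strand and expression level, Ty elements, the rDNA locus, known origin
#' intervals, and oriented ACS motif positions.  Genes are sorted by
#' chromosome and start so that overlap lookups are deterministic.
#'
#' @param genes `GRanges` with strand; metadata columns `gene_id`
#'   (created as `gene_1..n` if missing) and optionally `expression`.
#' @param expression Optional data.frame (`gene_id`, `expression`) merged
#'   onto the genes by id; values are in arbitrary units.
#' @param ty,rdna,origins Optional `GRanges` (empty by default).
#' @param acs Optional oriented ACS positions: data.frame with `chrom`,
#'   `pos`, `strand` (in `{+,-}`) or a width-1 stranded `GRanges`.
#' @return An object of class `genome_annotation`.
#' @export
genome_annotation <- function(genes = GenomicRanges::GRanges(),
                              expression = NULL,
                              ty = GenomicRanges::GRanges(),
                              rdna = GenomicRanges::GRanges(),
                              origins = GenomicRanges::GRanges(),
                              acs = NULL) {
  if (length(genes)) {
    if (is.null(S4Vectors::mcols(genes)$gene_id))
      S4Vectors::mcols(genes)$gene_id <- sprintf("gene_%d", seq_along(genes))
    if (!is.null(expression)) {
      stopifnot(all(c("gene_id", "expression") %in% colnames(expression)))
      S4Vectors::mcols(genes)$expression <-
        expression$expression[match(S4Vectors::mcols(genes)$gene_id,
                                    expression$gene_id)]
    } else if (is.null(S4Vectors::mcols(genes)$expression)) {
      S4Vectors::mcols(genes)$expression <- NA_real_
    }
    genes <- genes[order(as.character(GenomicRanges::seqnames(genes)),
                         GenomicRanges::start(genes))]
  }
  if (!is.null(acs)) {
    acs <- as_anchors(acs)
    stopifnot(all(acs$strand %in% c("+", "-")))
  } else {
    acs <- data.frame(chrom = character(), pos = integer(),
                      strand = character(), stringsAsFactors = FALSE)
  }
  structure(list(genes = genes, ty = ty, rdna = rdna,
                 origins = origins, acs = acs),
            class = "genome_annotation")
}

#' Read gene bodies from GFF3 or BED6
#'
#' GFF3 records of type `gene` (all features if none are typed `gene`) or
#' BED6 intervals; coordinates are converted to the internal 1-based
#' convention by `rtracklayer`.
#'
#' @param path GFF3 (`.gff`/`.gff3`) or BED (`.bed`) file.
#' @return A stranded `GRanges` with a `gene_id` metadata column.
#' @export
read_genes <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("gff", "gff3")) {
    gr <- rtracklayer::import(path, format = "gff3")
    if (any(S4Vectors::mcols(gr)$type == "gene"))
      gr <- gr[S4Vectors::mcols(gr)$type == "gene"]
    id <- S4Vectors::mcols(gr)$ID
    if (is.null(id)) id <- S4Vectors::mcols(gr)$Name
    gr2 <- GenomicRanges::granges(gr)
    S4Vectors::mcols(gr2)$gene_id <-
      if (is.null(id)) sprintf("gene_%d", seq_along(gr)) else as.character(id)
    gr2
  } else {
    gr <- rtracklayer::import(path, format = "bed")
    gr2 <- GenomicRanges::granges(gr)
    nm <- S4Vectors::mcols(gr)$name
    S4Vectors::mcols(gr2)$gene_id <-
      if (is.null(nm)) sprintf("gene_%d", seq_along(gr)) else as.character(nm)
    gr2
  }
}

#' Classify CMBS midpoints as genic or intergenic
#'
#' A site is genic iff its midpoint falls inside a gene body (1-based
#' inclusive interval; a midpoint at a gene's first base is genic, one base
#' before it is intergenic).  Genic calls carry the id and expression of
#' the first (leftmost) containing gene.
#'
#' @param cmbs A `cmbs_list`.
#' @param ann A [genome_annotation()].
#' @return data.frame with `rank`, `chrom`, `midpoint`, `class`
#'   (`"genic"`/`"intergenic"`), `gene_id`, `expression`.
#' @export
classify_genic <- function(cmbs, ann) {
  out <- data.frame(rank = cmbs$rank, chrom = cmbs$chrom,
                    midpoint = cmbs$midpoint,
                    class = "intergenic",
                    gene_id = NA_character_,
                    expression = NA_real_,
                    stringsAsFactors = FALSE)
  if (length(ann$genes) && nrow(cmbs)) {
    pts <- GenomicRanges::GRanges(cmbs$chrom,
                                  IRanges::IRanges(cmbs$midpoint,
                                                   cmbs$midpoint))
    hit <- GenomicRanges::findOverlaps(pts, ann$genes, select = "first",
                                       ignore.strand = TRUE)
    genic <- !is.na(hit)
    out$class[genic] <- "genic"
    out$gene_id[genic] <- S4Vectors::mcols(ann$genes)$gene_id[hit[genic]]
    out$expression[genic] <- S4Vectors::mcols(ann$genes)$expression[hit[genic]]
  }
  out
}

#' Sliding-window count of genic sites along the rank axis
#'
#' For each window of `window` consecutive ranks, the number of genic
#' calls, reported at the window's center rank.
#'
#' @param calls Output of [classify_genic()], ordered by rank.
#' @param window Window size in sites (default 50).
#' @return data.frame with `center_rank` and `n_genic`.
#' @export
genic_sliding_count <- function(calls, window = 50) {
  window <- as.integer(window)
  n <- nrow(calls)
  if (window > n) stop("'window' exceeds the number of sites")
  stopifnot(!is.unsorted(calls$rank))
  g <- as.integer(calls$class == "genic")
  cs <- c(0L, cumsum(g))
  counts <- cs[(window + 1L):(n + 1L)] - cs[1L:(n - window + 1L)]
  centers <- calls$rank[seq_len(n - window + 1L) + (window - 1L) %/% 2L]
  data.frame(center_rank = centers, n_genic = counts)
}

#' Orientation of the genes flanking an intergenic site
#'
#' Let L be the nearest gene ending at or left of the midpoint and R the
#' nearest gene starting right of it.  Transcription pointing toward the
#' site from both sides (L on "+", R on "-") is `"convergent"`; pointing
#' away from both sides is `"divergent"`; equal strands are `"tandem"`;
#' a missing flank gives `"undefined"`.  Calling this on a genic site is
#' an error.
#'
#' @param cmbs A `cmbs_list` (all sites must be intergenic).
#' @param ann A [genome_annotation()].
#' @return Character vector in
#'   `{"convergent","divergent","tandem","undefined"}`.
#' @export
flanking_orientation <- function(cmbs, ann) {
  cls <- classify_genic(cmbs, ann)
  if (any(cls$class == "genic"))
    stop("flanking orientation is defined only for intergenic sites")
  gchrom <- as.character(GenomicRanges::seqnames(ann$genes))
  gstart <- GenomicRanges::start(ann$genes)
  gend <- GenomicRanges::end(ann$genes)
  gstrand <- as.character(GenomicRanges::strand(ann$genes))
  vapply(seq_len(nrow(cmbs)), function(i) {
    sel <- gchrom == cmbs$chrom[i]
    le <- sel & gend <= cmbs$midpoint[i]
    ri <- sel & gstart > cmbs$midpoint[i]
    if (!any(le) || !any(ri)) return("undefined")
    L <- gstrand[which(le)[which.max(gend[le])]]
    R <- gstrand[which(ri)[which.min(gstart[ri])]]
    if (!L %in% c("+", "-") || !R %in% c("+", "-")) return("undefined")
    if (L == R) "tandem"
    else if (L == "+") "convergent"
    else "divergent"
  }, character(1))
}

#' Match features against CMBS midpoints within a distance
#'
#' For each feature (interval or point), reports whether any CMBS midpoint
#' lies within `dist` bp (arithmetic distance to the nearest feature edge,
#' 0 inside) and the best (lowest) rank among the matches; with
#' `per = "cmbs"`, the symmetric per-site query against the features.
#'
#' @param cmbs A `cmbs_list`.
#' @param features A `GRanges` of intervals or points.
#' @param dist Distance threshold in bp (>= 0).
#' @param per `"feature"` (default) or `"cmbs"`.
#' @return data.frame of matches; for `per = "feature"`: `feature`,
#'   `chrom`, `matched`, `best_rank`, `distance`.
#' @export
nearest_within <- function(cmbs, features, dist = 100, per = c("feature",
                                                               "cmbs")) {
  per <- match.arg(per)
  stopifnot(dist >= 0)
  fchrom <- as.character(GenomicRanges::seqnames(features))
  fs <- GenomicRanges::start(features)
  fe <- GenomicRanges::end(features)
  if (per == "feature") {
    res <- data.frame(feature = seq_along(features), chrom = fchrom,
                      matched = FALSE, best_rank = NA_integer_,
                      distance = NA_real_, stringsAsFactors = FALSE)
    for (i in seq_along(features)) {
      sel <- cmbs$chrom == fchrom[i]
      if (!any(sel)) next
      d <- pmax(0L, fs[i] - cmbs$midpoint[sel], cmbs$midpoint[sel] - fe[i])
      within <- d <= dist
      if (any(within)) {
        ranks <- cmbs$rank[sel][within]
        best <- which.min(ranks)
        res$matched[i] <- TRUE
        res$best_rank[i] <- ranks[best]
        res$distance[i] <- d[within][best]
      }
    }
    res
  } else {
    res <- data.frame(rank = cmbs$rank, chrom = cmbs$chrom,
                      matched = FALSE, feature = NA_integer_,
                      distance = NA_real_, stringsAsFactors = FALSE)
    for (i in seq_len(nrow(cmbs))) {
      sel <- fchrom == cmbs$chrom[i]
      if (!any(sel)) next
      d <- pmax(0L, fs[sel] - cmbs$midpoint[i], cmbs$midpoint[i] - fe[sel])
      j <- which.min(d)
      if (d[j] <= dist) {
        res$matched[i] <- TRUE
        res$feature[i] <- which(sel)[j]
        res$distance[i] <- d[j]
      }
    }
    res
  }
}
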