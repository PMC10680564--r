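test_that("genome simulation is seed-deterministic and echoes its config", {
  cfg <- sim_config(chrom_lengths = c(chrZ = 200000L), n_origins = 50)
  a <- simulate_genome(cfg, seed = 7)
  b <- simulate_genome(cfg, seed = 7)
  expect_identical(as.character(a$genome), as.character(b$genome))
  expect_identical(a$truth$mcm_midpoint, b$truth$mcm_midpoint)
  expect_identical(a$truth$abundance, b$truth$abundance)

  # abundance dynamic range realized exactly
  expect_equal(max(a$truth$abundance) / min(a$truth$abundance), 1000)

  # every ACS within 50 bp of its Mcm midpoint; every origin inside an NFR
  expect_true(all(abs(a$truth$acs_pos - a$truth$mcm_midpoint) <= 50))
  nfr <- attr(a$truth, "nfr")
  pts <- GenomicRanges::GRanges(a$truth$chrom,
                                IRanges::IRanges(a$truth$mcm_midpoint,
                                                 a$truth$mcm_midpoint))
  expect_true(all(GenomicRanges::countOverlaps(pts, nfr) >= 1))

  # planted motifs really sit in the sequence where truth says
  pw <- eacs_pwm(pseudocount = 0)
  sc <- scan_strands(a$genome, pw)
  w_at_acs <- vapply(seq_len(nrow(a$truth)), function(i) {
    tr <- if (a$truth$acs_strand[i] == "+") sc$watson else sc$crick
    tr$data[[a$truth$chrom[i]]][a$truth$acs_pos[i]]
  }, numeric(1))
  set.seed(1)
  null_scores <- sc$watson$data$chrZ[sample(150000, 500)]
  expect_gt(stats::median(w_at_acs), stats::quantile(null_scores, 0.99,
                                                     na.rm = TRUE))

  # origin count 0: genes only, empty truth
  z <- simulate_genome(sim_config(chrom_lengths = c(chrZ = 50000L),
                                  n_origins = 0), seed = 7)
  expect_equal(nrow(z$truth), 0L)
  expect_gt(length(z$annotation$genes), 0L)
})

test_that("fragment simulation reproduces the configured length laws", {
  fx <- small_sim_fixture()

  expect_equal(length(simulate_fragments(fx$sim$truth, "mcm_chec", 0)), 0L)

  fr <- simulate_fragments(fx$sim$truth, "mcm_chec", 10000, seed = 5)
  w <- GenomicRanges::width(fr)
  mcm_w <- w[w <= 100]
  expect_equal(as.integer(names(which.max(table(mcm_w)))), 61L)

  dy <- simulate_fragments(fx$sim$truth, "dyad", 10000, seed = 6)
  wd <- GenomicRanges::width(dy)
  expect_true(all(wd >= 46 & wd <= 56))
  expect_equal(as.integer(names(which.max(table(wd)))), 51L)

  expect_error(simulate_fragments(fx$sim$truth, "chipseq", 10), "arg")

  # identical seeds give identical fragment sets
  expect_identical(fr, simulate_fragments(fx$sim$truth, "mcm_chec", 10000,
                                          seed = 5))
})

test_that("fragment counts are multinomial in planted abundance", {
  cfg <- sim_config(chrom_lengths = c(chrM = 60000L), n_origins = 2,
                    abundance_range = c(1, 100), background_fraction = 0)
  sim <- simulate_genome(cfg, seed = 13)
  fr <- simulate_fragments(sim$truth, "mcm_chec", 50000, seed = 14)
  mids <- fragment_midpoints(fr)
  hi <- sim$truth$mcm_midpoint[which.max(sim$truth$abundance)]
  lo <- sim$truth$mcm_midpoint[which.min(sim$truth$abundance)]
  n_hi <- sum(abs(mids - hi) <= 10)
  n_lo <- sum(abs(mids - lo) <= 10)
  # expected ratio 100:1; binomial sd of the low count ~ sqrt(n/101)
  expect_lt(abs(n_lo - 50000 / 101), 3 * sqrt(50000 / 101))
  expect_gt(n_hi / n_lo, 50)
})

test_that("ssDNA tracks have activity-proportional peaks over baseline 1", {
  cfg <- sim_config(chrom_lengths = c(chrS = 50000L), n_origins = 2,
                    abundance_range = c(1, 2))
  sim <- simulate_genome(cfg, seed = 23)
  tr <- simulate_ssdna(sim$truth, peak_width = 300, noise_sd = 0,
                       max_height = 4, seed = 24)
  x <- tr$data$chrS
  i_hi <- which.max(sim$truth$abundance)
  i_lo <- which.min(sim$truth$abundance)
  expect_equal(which.max(x),
               sim$truth$mcm_midpoint[i_hi])
  h_hi <- x[sim$truth$mcm_midpoint[i_hi]] - 1
  h_lo <- x[sim$truth$mcm_midpoint[i_lo]] - 1
  expect_equal(h_hi / h_lo, 2, tolerance = 0.01)

  # null genome: flat at baseline
  z <- simulate_genome(sim_config(chrom_lengths = c(chrS = 20000L),
                                  n_origins = 0), seed = 25)
  tz <- simulate_ssdna(z$truth, noise_sd = 0.05, seed = 26)
  expect_lt(abs(mean(tz$data$chrS) - 1), 3 * 0.05 / sqrt(20000))

  # probe-like sparse sampling leaves NA between probes
  sp <- simulate_ssdna(sim$truth, probe_spacing = 50, noise_sd = 0,
                       seed = 27)
  expect_equal(mean(is.na(sp$data$chrS)), 1 - 1 / 50, tolerance = 1e-3)
})

test_that("skew planting hits the target contrast and spares ACS motifs", {
  fx <- small_sim_fixture()
  s <- 0.3
  mut <- plant_gc_skew(fx$sim$genome, fx$sim$truth, s, seed = 91)

  # every planted ACS 17-mer survives verbatim
  seqs <- as.character(mut)
  orig <- as.character(fx$sim$genome)
  for (i in seq_len(nrow(fx$sim$truth))) {
    at <- fx$sim$truth$acs_pos[i]
    expect_identical(substr(seqs[[fx$sim$truth$chrom[i]]], at, at + 16),
                     substr(orig[[fx$sim$truth$chrom[i]]], at, at + 16))
  }

  # mean Watson skew contrast across midpoints exceeds s
  tr <- skew_track(mut, 51)
  up <- down <- numeric(0)
  for (i in seq_len(nrow(fx$sim$truth))) {
    x <- tr$data[[fx$sim$truth$chrom[i]]]
    m <- fx$sim$truth$mcm_midpoint[i]
    up <- c(up, x[(m - 150):(m - 50)])
    down <- c(down, x[(m + 50):(m + 150)])
  }
  expect_gt(mean(down, na.rm = TRUE) - mean(up, na.rm = TRUE), s)

  # only the +/- 200 bp neighborhoods are touched
  changed <- which(strsplit(seqs[[1]], "")[[1]] !=
                     strsplit(orig[[1]], "")[[1]])
  d <- vapply(changed, function(p) {
    min(abs(p - fx$sim$truth$mcm_midpoint))
  }, numeric(1))
  expect_true(all(d <= 200))
})
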