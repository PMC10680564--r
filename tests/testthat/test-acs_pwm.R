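test_that("packaged EACS matrix is a valid PWM and scores as frozen", {
  pw <- eacs_pwm()
  expect_equal(dim(pw$f), c(17L, 4L))
  expect_true(all(abs(rowSums(pw$f) - 1) <= 0.002))

  # uniform matrix, eps = 0: every sequence scores 0
  uni <- pwm(matrix(0.25, 8, 4), pseudocount = 0)
  expect_equal(pwm_score("ACGTACGT", uni), 0)

  # per-position-max consensus under log2 / uniform / eps = 0:
  # frozen from independent per-position summation over the printed table
  pw0 <- eacs_pwm(pseudocount = 0)
  expect_equal(pwm_consensus(pw0), "TTTTTTTATGTTTAGTT")
  expect_equal(pwm_score(pwm_consensus(pw0), pw0), 26.229, tolerance = 1e-4)

  # a zero-probability base (A at position 12) is penalized by the
  # pseudocount-dominated odds log2(0.001/0.251) ~ -8 at that position
  seq_badA <- sub("^(.{11}).", "\\1A", pwm_consensus(pw0))
  expect_lt(pwm_score(seq_badA, eacs_pwm()) -
              pwm_score(pwm_consensus(pw0), eacs_pwm()), -5)

  expect_error(pwm_score("NNNNNNNNNNNNNNNNN", pw0), "non-ACGT")
  expect_error(pwm_score("ACGT", pw0), "length")
})

test_that("raising a matched base's probability never lowers the score", {
  pw <- eacs_pwm()
  s <- pwm_consensus(pw)
  base_score <- pwm_score(s, pw)
  f2 <- pw$f
  i <- 1L
  b <- substr(s, 1, 1)
  bump <- 0.1
  f2[i, ] <- f2[i, ] * (1 - bump) / sum(f2[i, ])
  f2[i, b] <- f2[i, b] + bump
  expect_gte(pwm_score(s, pwm(f2, pseudocount = pw$pseudocount)), base_score)
})

test_that("strand scanning finds planted motifs and respects involution", {
  pw <- eacs_pwm()
  cons <- pwm_consensus(pw)
  set.seed(21)
  bg <- paste(sample(c("A", "C", "G", "T"), 500, replace = TRUE),
              collapse = "")
  k <- 201L
  seqW <- paste0(substr(bg, 1, k - 1), cons, substr(bg, k + 17, 500))
  st <- scan_strands(c(chr = seqW), pw)
  expect_equal(unname(which.max(st$watson$data$chr)), k)
  # trailing 16 positions carry NA
  expect_true(all(is.na(st$watson$data$chr[485:500])))

  rc <- function(s) as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(s)))
  seqC <- paste0(substr(bg, 1, k - 1), rc(cons), substr(bg, k + 17, 500))
  stc <- scan_strands(c(chr = seqC), pw)
  expect_equal(unname(which.max(stc$crick$data$chr)), k)

  # involution: crick scores of a sequence equal the position-mapped watson
  # scores of its reverse complement
  strc <- scan_strands(c(chr = rc(seqW)), pw)
  n <- nchar(seqW)
  i <- 1:(n - 16)
  expect_equal(st$crick$data$chr[i], rev(strc$watson$data$chr[i]))

  # windows containing N are missing
  seqN <- paste0(substr(seqW, 1, 99), "N", substr(seqW, 101, 500))
  stn <- scan_strands(c(chr = seqN), pw)
  expect_true(all(is.na(stn$watson$data$chr[84:100])))
  expect_false(is.na(stn$watson$data$chr[101]))
})

test_that("strong-Watson subset logic covers the threshold extremes", {
  fx <- small_sim_fixture()
  st <- scan_strands(fx$sim$genome)
  cmbs <- fx$res$cmbs

  none <- strong_watson_subset(st, cmbs, scan_params(strong_threshold = 1e6))
  expect_equal(nrow(none$subset), 0L)
  expect_null(none$crick_subset)

  all_in <- strong_watson_subset(st, cmbs,
                                 scan_params(strong_threshold = -Inf))
  expect_equal(nrow(all_in$subset), nrow(cmbs))
  expect_identical(all_in$crick_subset, all_in$crick_all)

  some <- strong_watson_subset(st, cmbs, scan_params())
  expect_true(nrow(some$subset) >= 1)
  expect_true(all(some$watson_max[some$subset$rank] >= 10.8))
})

test_that("ACS-anchored cumulative profiles fold both strands downstream", {
  x <- numeric(2000)
  x[1040] <- 3   # 40 bp right of a "+" ACS at 1000
  tr <- signal_track(list(c1 = x), "midpoint")
  acs1 <- data.frame(chrom = "c1", pos = 1000, strand = "+")
  p1 <- acs_anchored_mcm_profile(tr, acs1, halfwidth = 500)
  expect_equal(unname(p1["40"]), 100)
  expect_equal(sum(p1), 100)

  y <- numeric(2000)
  y[1040] <- 3
  y[1460] <- 5   # 40 bp left of a "-" ACS at 1500
  tr2 <- signal_track(list(c1 = y), "midpoint")
  acs2 <- data.frame(chrom = "c1", pos = c(1000, 1500),
                     strand = c("+", "-"))
  p2 <- acs_anchored_mcm_profile(tr2, acs2, halfwidth = 300)
  expect_equal(unname(p2["40"]), 200)

  # all-zero windows are dropped and counted
  acs3 <- rbind(acs2, data.frame(chrom = "c1", pos = 600, strand = "+"))
  p3 <- acs_anchored_mcm_profile(tr2, acs3, halfwidth = 300)
  expect_equal(attr(p3, "n_zero"), 1L)
  expect_equal(attr(p3, "n_used"), 2L)
})

test_that("downstream bias counts oriented ACS-CMBS pairs correctly", {
  cm <- new_test_cmbs("c1", c(1040L, 960L, 2000L, 3000L))
  acs <- data.frame(chrom = "c1",
                    pos = c(1010, 1000, 2150, 3000),
                    strand = c("+", "-", "+", "+"))
  db <- downstream_bias(cm, acs, proximity = 100)
  # +ACS at 1010 pairs with 1040 (downstream); -ACS at 1000 ties between
  # 960 and 1040, resolved to the lower coordinate 960 (downstream for -);
  # ACS at 2150 is unpaired (nearest site 150 bp away); ACS at 3000
  # coincides exactly with a midpoint (neither side)
  expect_equal(db$n_paired, 3L)
  expect_equal(db$n_downstream, 2L)
  expect_equal(db$n_at_acs, 1L)
  expect_equal(db$fraction, 2 / 3)
})
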