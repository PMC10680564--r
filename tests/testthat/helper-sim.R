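# Small shared study fixture: a 120 kb genome with 24 planted origins,
# strictly downstream Mcm loading, and matched MCM-ChEC / dyad fragment
# sets.  Built once per test run and memoised (generation is seeded, so
# every test sees the same objects).
small_sim_fixture <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    cfg <- sim_config(chrom_lengths = c(chrA = 120000L),
                      n_origins = 24, downstream_fraction = 1.0)
    sim <- simulate_genome(cfg, seed = 101)
    frags <- simulate_fragments(sim$truth, "mcm_chec", 60000, seed = 102)
    dyad_frags <- simulate_fragments(sim$truth, "dyad", 40000, seed = 103)
    res <- identify_cmbs(frags)
    cache <<- list(cfg = cfg, sim = sim, frags = frags,
                   dyad_frags = dyad_frags, res = res)
    cache
  }
})

# hand-built ranked site list for unit tests (heights/abundances default to
# a strictly decreasing series so rank invariants hold)
new_test_cmbs <- function(chrom, midpoint,
                          abundance = rev(seq_along(midpoint)),
                          peak_height = rev(seq_along(midpoint)),
                          cohort = NA_integer_) {
  df <- data.frame(rank = seq_along(midpoint), chrom = chrom,
                   midpoint = as.integer(midpoint),
                   peak_height = peak_height, abundance = abundance,
                   cohort = cohort, stringsAsFactors = FALSE)
  structure(df, class = c("cmbs_list", "data.frame"))
}
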