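# Shared driver: the read-level analysis chain on a scenario, returning the
# detected star report (the same sequence of calls run_pipeline() performs,
# exposed piecewise so tests can inspect intermediates).
analyze_scenario <- function(scn, seed, depth_mean = 6, error_rate = 1e-3) {
  p <- seq_params(depth_mean = depth_mean, error_rate = error_rate, seed = seed)
  sim <- simulate_mutations(scn, p)
  counts <- simulate_reads(sim, p)
  calls <- apply_private_filter(call_genotypes(counts), counts)
  filt <- filter_sites(calls)
  m0 <- calls_matrix(filt)
  m0[m0 %in% c("?", "-")] <- "0"
  guide <- build_tree(m0)
  imp <- impute_missing(filt, guide, seed = seed)
  gen <- build_tree(dplyr::select(imp, -imputed))
  list(sim = sim, counts = counts, calls = filt, genealogy = gen,
       stars = detect_stars(gen))
}

# Match detected stars to the planted stars of multi_star_scenario() by tip
# prefix: planted star i owns tips "S<i>_..". Returns, per planted star, the
# matched detected age (NA if no detected node of >= min_k tips all from
# that star).
match_planted_stars <- function(stars, n_planted, min_k = 5) {
  gen <- attr(stars, "genealogy")
  phy <- gen$tree
  ages <- rep(NA_real_, n_planted)
  if (!nrow(stars)) return(ages)
  for (r in seq_len(nrow(stars))) {
    tips <- phy$tip.label[unlist(tips_under_node(phy, stars$node[r]))]
    pre <- unique(sub("_.*$", "", tips))
    if (length(pre) == 1L && grepl("^S[0-9]+$", pre)) {
      i <- as.integer(sub("^S", "", pre))
      if (i <= n_planted && stars$k[r] >= min_k &&
          (is.na(ages[i]) || stars$n_tips[r] > 0)) {
        ages[i] <- stars$age_years[r]
      }
    }
  }
  ages
}
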