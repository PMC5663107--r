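# Shared in-code fixtures: everything is generated at test time.

toy_build <- function(lengths = c(chr1 = 1000, chr2 = 600)) {
  genome_build("toy", lengths)
}

toy_partition <- function(lengths = c(chr1 = 1000, chr2 = 600),
                          window_size = 200) {
  partition_genome(toy_build(lengths), window_size)
}

# small world reused by several module tests; cached per session
small_world <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- simulate_world(sim_config(
        genome = c(chr1 = 2e5, chr2 = 2e5), n_tss = 40, n_risk = 40,
        n_benign_pool = 1500, n_features = 20, n_informative = 3,
        seed = 101))
    cache
  }
})

# a tiny trained model + matrix for scoretrack/query tests; cached
small_fit <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      w <- small_world()
      am <- assemble_matrix(w$tracks, w$partition)
      pos <- risk_set(w$risk_catalog, "traitA")
      cand <- benign_candidates(w$benign_catalog, 0.05, w$risk_catalog)
      ms <- match_negatives_tss(pos, cand, w$tss, ratio = 10, seed = 7)
      pm <- annotate_variants(ms$positives, am)
      nm <- annotate_variants(ms$negatives, am)
      model <- train_ensemble(pm, nm,
                              selected_features = w$ground_truth$traitA,
                              seed = 7)
      track <- score_genome(model, am, "traitA")
      cache <<- list(world = w, am = am, ms = ms, model = model,
                     track = track, dist = build_distribution(track))
    }
    cache
  }
})

write_tsv_catalog <- function(lines, path = tempfile(fileext = ".tsv")) {
  writeLines(lines, path)
  path
}
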