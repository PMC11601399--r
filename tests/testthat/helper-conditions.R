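## Trained-network conditions shared across acceptance tests. Training is
## the expensive step, so each condition is trained once per test run and
## memoized; every condition uses the full 500 x 100 schedule at a
## scaled-down seed count.
.cond_cache <- new.env(parent = emptyenv())

trainedCondition <- function(set_size, n_stripes, chunk, seeds = 1:10,
                             n_eval = 250) {
  key <- paste(set_size, n_stripes, chunk, length(seeds), sep = "_")
  if (!is.null(.cond_cache[[key]])) return(.cond_cache[[key]])
  cfg <- experimentConfig(set_size = set_size, n_stripes = n_stripes,
                          chunk_enabled = chunk, seeds = seeds,
                          n_eval_episodes = n_eval)
  ex <- runExperiment(cfg)
  occ <- do.call(rbind, lapply(ex$runs, function(r) r$eval$occupancy))
  out <- list(ex = ex, recall = ex$recall, usage = stripeUsage(occ))
  .cond_cache[[key]] <- out
  out
}
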