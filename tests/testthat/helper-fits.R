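# Shared small fits, built once per test run.  Sizes are kept modest so the
# whole suite stays quick; the scaled study conditions live in
# test-acceptance.R.

small_sim <- function(family, N = 200, J = 8, seed = 42) {
  design <- sim_design(N, J, family = family, base_seed = seed)
  truth <- draw_true_parameters(design, seed = seed)
  list(truth = truth, X = simulate_responses(truth), design = design)
}

# memoized tiny Rasch fit reused across method/criteria tests
tiny_rasch_fit <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      s <- small_sim("rasch", N = 120, J = 6, seed = 11)
      cache <<- girt(s$X, "rasch", chains = 2, iter = 600, burnin = 300,
                     seed = 11)
      attr(cache, "truth") <- s$truth
    }
    cache
  }
})
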