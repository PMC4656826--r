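# standard error of a proportion estimated from n trials
prop_se <- function(p, n) sqrt(p * (1 - p) / n)

# quick parameter sets for small, fast simulations
tiny_params <- function(...) {
  args <- modifyList(list(N = 20, n_generations = 10, n_replicates = 5,
                          seed = 42), list(...))
  do.call(model_params, args)
}
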