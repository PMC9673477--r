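# shared fixtures, all built in code

# small random genotype matrix with possibly heterozygous calls
toy_genotypes <- function(n = 20, m = 10, seed = 1, states = 0:2) {
  set.seed(seed)
  V <- matrix(sample(states, n * m, replace = TRUE), n, m)
  gs_genotypes(V)
}

# a mid-sized panel + simulated trait reused by model tests
toy_simulation <- function(n = 150, m = 300, n_background = 100,
                           c_frac = 0.3, h = 0.95, seed = 2) {
  G <- generate_genotypes(n, m, seed = 5)
  cfg <- sim_config("toy", n, 1, c_frac, heritability = h,
                    n_background = n_background)
  sp <- simulate_phenotype(cfg, G, seed = seed)
  list(G = G, sp = sp,
       X012 = encode_genotypes(G, "additive012")$values,
       Xc = encode_genotypes(G, "additive_centered")$values)
}
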