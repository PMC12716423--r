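# Shared fixtures: tiny spaces, generators and trees built in code.

# single region, three biome states
space_1region <- function() build_state_space(region_set("X"), 1)

# three regions in a chain X - Y - Z
space_chain3 <- function(max_range = 2L) {
  build_state_space(region_set(c("X", "Y", "Z"), cbind(c("X", "Y"), c("Y", "Z"))),
                    max_range)
}

# one-state generator: pure birth-death with rates lambda, mu
gen_bd <- function(lambda = 1, mu = 0) {
  generator_set(matrix(0, 1, 1),
                data.frame(parent = 1L, left = 1L, right = 1L, rate = lambda),
                mu)
}

# S-state generator with symmetric anagenetic rate q, diagonal-only
# cladogenesis at rate lambda and constant extinction mu (state-independent)
gen_state_independent <- function(S = 3, q = 0.3, lambda = 0.5, mu = 0.15) {
  Q <- matrix(q, S, S); diag(Q) <- 0
  generator_set(Q, data.frame(parent = seq_len(S), left = seq_len(S),
                              right = seq_len(S), rate = lambda), rep(mu, S))
}

tree_4tip <- function() ape::read.tree(text = "((a:0.7,b:0.7):0.8,(c:1.0,d:1.0):0.5);")
tree_2tip <- function(len = 1) ape::read.tree(text = sprintf("(a:%g,b:%g);", len, len))

# recovery-study conditions: 3 chain regions, known rates
recovery_params <- function() {
  classe_parameters(lambda_within = c(0.4, 0.25, 0.3), lambda_between = 0.03,
                    dispersal = 0.08, biome_rate = 0.08, extirpation = 0.05)
}

# simulate under recovery_params until the clade size lands in [min, max] tips
simulate_recovery_clade <- function(seed, min_tips = 300, max_tips = 1200,
                                    max_age = 18) {
  sp <- space_chain3()
  gen <- build_generators(recovery_params(), sp)
  root <- state_index(sp, "Y", "BOTH")
  s <- seed
  repeat {
    res <- tryCatch(
      simulate_clade(gen, root, max_age, seed = s, min_survivors = min_tips),
      alpassembly_extinct = function(e) NULL)
    if (!is.null(res) && res$n_extant <= max_tips) return(res)
    s <- s + 1
  }
}
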