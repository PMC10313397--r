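# build a posterior_draws object directly from an array, for diagnostic
# and summary tests that need controlled draw values
make_draws <- function(values, names = NULL) {
  if (is.null(names)) names <- paste0("x", seq_len(dim(values)[3]))
  dimnames(values) <- list(NULL, NULL, names)
  structure(list(values = values, param_names = names,
                 config = NULL),
            class = "posterior_draws")
}

# a small but well-conditioned true_params set for generator tests
toy_params <- function(taste = "sweetness", rho = 0.4,
                       mu = c(40, 30, 45, 32), sigma = rep(15, 4)) {
  corr <- matrix(rho, 4, 4); diag(corr) <- 1
  true_params(mu, sigma, corr, taste)
}

# reduced chain configuration for pipeline tests where sampler quality is
# not the property under test
quick_chains <- function(seed = 1) {
  chain_config(n_chains = 2, n_iterations = 1000, burn_in = 250,
               seed = seed)
}
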