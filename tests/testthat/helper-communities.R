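# shared fixtures: small deterministic networks and communities used across
# test files; everything is generated in code under fixed seeds

small_net <- function(seed = 9, S_P = 10, S_A = 12, kappa = 0.3) {
  random_bipartite(S_P, S_A, kappa, seed = seed)
}

det_meta <- function(...) {
  # deterministic coefficient draws: all distribution widths zero
  meta_parameters(delta_b = 0, delta_c = 0, delta_N = 0, ...)
}

small_comm <- function(seed = 7, S_P = 10, S_A = 12, kappa = 0.3,
                       net = NULL, ...) {
  if (is.null(net)) net <- small_net(seed = 9, S_P = S_P, S_A = S_A,
                                     kappa = kappa)
  build_community(net, meta_parameters(...), seed = seed)
}

# brute-force nestedness oracle: explicit loop over same-guild pairs
nestedness_oracle <- function(inc, guild = c("plants", "animals")) {
  m <- if (match.arg(guild) == "plants") inc else t(inc)
  S <- nrow(m)
  vals <- c()
  for (i in seq_len(S - 1)) for (j in (i + 1):S) {
    shared <- sum(m[i, ] == 1 & m[j, ] == 1)
    lo <- min(sum(m[i, ]), sum(m[j, ]))
    if (lo > 0) vals <- c(vals, shared / lo)
  }
  mean(vals)
}
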