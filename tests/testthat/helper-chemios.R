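# Shared fixtures for the chemios test suite. Everything is generated in
# code; nothing is read from disk.

.env310 <- thermo_env()

# random admissible carrier states with fixed pool totals
random_states <- function(n, D_tot = 100, A_tot = 100, seed = 1) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    fd <- stats::runif(1, 1e-6, 1 - 1e-6)
    fa <- stats::runif(1, 1e-6, 1 - 1e-6)
    carrier_state(Dred = fd * D_tot, Dox = (1 - fd) * D_tot,
                  Aox = fa * A_tot, Ared = (1 - fa) * A_tot)
  })
}

# carrier state with a prescribed total force for a given spec
state_at_force <- function(spec, TF_over_RT, env = .env310,
                           D_tot = 100, A_tot = 100) {
  # choose r_D = r_A = r so that log(r^2) = TF/RT - n_e F dE0 / RT
  lr2 <- TF_over_RT - spec$n_e * env$F * spec$dE0 / 1000 / rt_energy(env)
  r <- exp(lr2 / 2)
  fd <- r / (1 + r)
  carrier_state(Dred = fd * D_tot, Dox = (1 - fd) * D_tot,
                Aox = fd * A_tot, Ared = (1 - fd) * A_tot)
}

ci_params <- function(...) {
  args <- utils::modifyList(
    list(Vmf = 0.4, Km_D = 5, Km_A = 20, k_D = 0.03, k_A = 0.3),
    list(...))
  do.call(kinetic_params, args)
}

# cached noiseless CI assay pair + two-stage fit (built once per test file
# that needs it)
.fixture_cache <- new.env(parent = emptyenv())

noiseless_ci_sets <- function() {
  if (is.null(.fixture_cache$ci_sets)) {
    dgs <- reference_designs(seed = 11, noise_sd_rel = 0, pip_sd_rel = 0)
    .fixture_cache$ci_sets <- list(
      donor = generate_assay_set(dgs$CI_donor, reference_truth()$CI,
                                 etc_complex("CI"), .env310),
      acceptor = generate_assay_set(dgs$CI_acceptor, reference_truth()$CI,
                                    etc_complex("CI"), .env310))
  }
  .fixture_cache$ci_sets
}

# exact stationary solution of the rapid-equilibrium binding schemes,
# solved by linear algebra on the scheme's states (independent oracle for
# the saturation function)
binding_scheme_oracle <- function(mechanism, D, A, Ki_D, Ki_A, K_D, K_A,
                                  kon = 1e3) {
  if (mechanism == "ordered") {
    # states: E, ED, EDA
    Q <- matrix(0, 3, 3)
    Q[1, 2] <- kon * D;      Q[2, 1] <- kon * Ki_D
    Q[2, 3] <- kon * A;      Q[3, 2] <- kon * K_A
  } else {
    # states: E, ED, EA, EDA
    Q <- matrix(0, 4, 4)
    Q[1, 2] <- kon * D;      Q[2, 1] <- kon * Ki_D
    Q[1, 3] <- kon * A;      Q[3, 1] <- kon * Ki_A
    Q[2, 4] <- kon * A;      Q[4, 2] <- kon * K_A
    Q[3, 4] <- kon * D;      Q[4, 3] <- kon * K_D
  }
  G <- t(Q); diag(G) <- -rowSums(Q)
  p <- qr.solve(rbind(G, rep(1, nrow(Q))), c(numeric(nrow(Q)), 1))
  p[length(p)]
}
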