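# Shared fixtures: small simulated communities and fits, built once per run.

small_sim <- local({
  val <- NULL
  function() {
    if (is.null(val)) {
      cfg <- community_config(n_species = 8, n_sites = 25, n_visits = 3, seed = 3)
      val <<- list(cfg = cfg, sim = simulate_community(cfg))
    }
    val
  }
})

small_bundle <- function(sim = small_sim()$sim, cfg = small_sim()$cfg,
                         spec = NULL) {
  if (is.null(spec)) {
    spec <- model_spec(
      occupancy = c(elev_m = "random", dist_range = "random"),
      detection = c(time = "fixed"), variant = "bmsom")
  }
  build_covariate_bundle(sim$ranges, sim$sites, spec,
                         n_visits = cfg$n_visits, visits = sim$visits)
}

# one small fitted model, cached (several tests inspect it)
small_fit <- local({
  val <- NULL
  function() {
    if (is.null(val)) {
      s <- small_sim()
      spec <- model_spec(occupancy = c(elev_m = "random", dist_range = "random"),
                         detection = c(time = "fixed"), variant = "bmsom")
      bundle <- small_bundle(spec = spec)
      val <<- list(
        spec = spec, bundle = bundle, sim = s$sim, cfg = s$cfg,
        fit = fit_occupancy(spec, bundle, s$sim$detections, chains = 2,
                            warmup = 200, draws = 200, seed = 42)
      )
    }
    val
  }
})

# brute-force oracle: joint probability of Y summed over all latent Z
# configurations, for arbitrary fixed psi (S x J), theta (S x J x K), y
enumeration_loglik <- function(psi, theta, y, keep = NULL, vis = NULL) {
  S <- nrow(psi); J <- ncol(psi); K <- dim(theta)[3]
  if (is.null(keep)) keep <- matrix(TRUE, S, J)
  if (is.null(vis)) vis <- array(TRUE, c(S, J, K))
  cells <- which(keep, arr.ind = TRUE)
  n <- nrow(cells)
  total <- 0
  for (zidx in 0:(2^n - 1)) {
    zbits <- as.integer(intToBits(zidx))[seq_len(n)]
    p <- 1
    for (r in seq_len(n)) {
      i <- cells[r, 1]; j <- cells[r, 2]
      z <- zbits[r]
      p <- p * (if (z == 1) psi[i, j] else 1 - psi[i, j])
      for (k in seq_len(K)) {
        if (!vis[i, j, k]) next
        th <- z * theta[i, j, k]
        p <- p * (if (y[i, j, k] == 1) th else 1 - th)
      }
      if (p == 0) break
    }
    total <- total + p
  }
  log(total)
}

# random tiny model instance for oracle tests
random_instance <- function(S, J, K, seed) {
  set.seed(seed)
  psi <- matrix(runif(S * J, 0.05, 0.95), S, J)
  theta <- array(runif(S * J * K, 0.05, 0.95), c(S, J, K))
  Z <- matrix(rbinom(S * J, 1, psi), S, J)
  y <- array(rbinom(S * J * K, 1, as.numeric(theta)), c(S, J, K)) *
    as.numeric(Z)
  list(psi = psi, theta = theta, y = y)
}
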