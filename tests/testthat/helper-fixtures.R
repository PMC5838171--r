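# Shared toy builders. Everything is constructed in code; no stored fixtures.

toy_domain <- function(n = 3, masks = TRUE) {
  msp_domain(data.frame(
    site_id = paste0("s", seq_len(n)),
    x = seq_len(n), y = 0,
    dev_mussel = rep_len(masks, n),
    dev_finfish = rep_len(masks, n),
    dev_kelp = rep_len(masks, n)
  ))
}

# complete seven-sector response bundle with controllable surfaces
toy_responses <- function(domain, seed = 1) {
  set.seed(seed)
  n <- nrow(domain)
  C <- matrix(runif(n * n), n)
  diag(C) <- 0
  response_tensor(domain, list(
    mussel = aquaculture_response(domain, runif(n, 1, 10), "MUSSEL"),
    finfish = aquaculture_response(domain, runif(n, 1, 10), "FINFISH"),
    kelp = aquaculture_response(domain, runif(n, 1, 10), "KELP"),
    halibut = halibut_response(domain, runif(n, 0, 5)),
    viewshed = viewshed_response(domain, runif(n, 0, 3), runif(n, 3, 6)),
    benthic = benthic_response(domain, runif(n, 0, 2)),
    disease = disease_response(domain, C)
  ))
}

toy_scaled <- function(n = 3, seed = 1, masks = TRUE) {
  domain <- toy_domain(n, masks)
  scale_values(build_values(toy_responses(domain, seed)))
}

# random small domain with random masks (NONE always allowed), for
# exhaustive-search oracles
random_small_scaled <- function(n_sites, seed) {
  set.seed(seed)
  repeat {
    d <- data.frame(
      site_id = paste0("s", seq_len(n_sites)),
      x = seq_len(n_sites), y = 0,
      dev_mussel = runif(n_sites) > 0.3,
      dev_finfish = runif(n_sites) > 0.3,
      dev_kelp = runif(n_sites) > 0.3
    )
    # scaling needs every sector to retain positive domain-wide value
    if (any(d$dev_mussel) && any(d$dev_finfish) && any(d$dev_kelp)) break
  }
  domain <- msp_domain(d)
  scale_values(build_values(toy_responses(domain, seed + 1000)))
}

# exhaustive whole-domain optimum over all 4^S feasible plans
exhaustive_best <- function(scaled, alpha) {
  domain <- attr(scaled, "domain")
  sectors <- attr(scaled, "sectors")
  X <- mspfrontier:::scaled_array(scaled)
  mask <- mspfrontier:::dev_mask(domain)
  S <- nrow(domain)
  V <- sapply(1:4, function(p) {
    as.numeric(alpha[sectors$sector] %*% matrix(X[, , p], nrow = nrow(sectors)))
  })  # S x 4
  grid <- as.matrix(expand.grid(rep(list(1:4), S)))
  feasible <- rowSums(matrix(mask[cbind(rep(seq_len(S), each = nrow(grid)),
                                        as.vector(grid))],
                             nrow(grid))) == S
  objs <- rowSums(matrix(V[cbind(rep(seq_len(S), each = nrow(grid)),
                                 as.vector(grid))],
                         nrow(grid)))
  objs[!feasible] <- -Inf
  list(obj = max(objs), choice = grid[which.max(objs), ])
}

# plans-by-sites code matrix with planted cluster structure; the last member
# of each cluster is a clear outlier (more flipped sites) so the
# farthest-from-centroid representative is unambiguous
planted_plans <- function(n_per = 4, n_sites = 30, seed = 7) {
  set.seed(seed)
  centers <- lapply(1:3, function(i) sample(1:4, n_sites, replace = TRUE))
  do.call(rbind, lapply(1:3, function(g) {
    t(sapply(seq_len(n_per), function(j) {
      p <- centers[[g]]
      # distinct flip sets guarantee all-distinct plans
      flip <- if (j < n_per) j else n_per:(n_per + 5)
      p[flip] <- p[flip] %% 4 + 1
      p
    }))
  }))
}
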