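test_that("suitability is annuity over worst-case scaled impact, with the
          zero-impact tie rule", {
  sc <- toy_scaled(4, seed = 3)
  suit <- suitability_index(sc)
  X <- mspfrontier:::scaled_array(sc)
  sectors <- attr(sc, "sectors")
  denom <- attr(sc, "denom")
  existing <- which(is.na(sectors$option))

  # independent per-row recomputation
  for (r in seq_len(nrow(suit))) {
    j <- match(suit$sector[r], sectors$sector)
    i <- match(suit$site_id[r], attr(sc, "domain")$site_id)
    p <- match(suit$option[r], msp_options())
    ann <- unname(X[j, i, p] * denom[j])
    imp <- max(pmax(X[existing, i, 1] - X[existing, i, p], 0))
    expect_equal(suit$annuity[r], ann)
    expect_equal(suit$impact[r], imp)
    expect_equal(suit$suitability[r],
                 if (imp <= 1e-15) Inf else ann / imp)
  }
  # ordering: descending suitability
  expect_true(!is.unsorted(rev(suit$suitability)))
})

test_that("zero-impact sites rank by annuity among themselves", {
  sc <- toy_scaled(5, seed = 19)
  # force every pair through the zero-impact branch: all suitabilities are
  # infinite and the ordering must fall back to annuity (then site order)
  suit <- suitability_index(sc, zero_impact = Inf)
  expect_true(all(is.infinite(suit$suitability)))
  for (nm in c("mussel", "finfish", "kelp")) {
    ann <- suit$annuity[suit$sector == nm]
    expect_equal(ann, sort(ann, decreasing = TRUE))
  }
})

test_that("unconstrained planning is greedy with site exclusivity", {
  sc <- toy_scaled(6, seed = 12)
  suit <- suitability_index(sc)
  traj <- conventional_plan(sc, "unconstrained")

  # oracle: walk the ranked table, skipping taken sites
  taken <- character(0)
  steps <- list()
  for (r in seq_len(nrow(suit))) {
    if (!suit$site_id[r] %in% taken) {
      taken <- c(taken, suit$site_id[r])
      steps[[length(steps) + 1]] <- suit[r, c("site_id", "option")]
    }
  }
  oracle <- do.call(rbind, steps)
  expect_equal(traj$site_id, oracle$site_id)
  expect_equal(traj$option, oracle$option)
  # suitability sequence is non-increasing
  expect_true(!is.unsorted(rev(traj$suitability)))
})

test_that("constrained planning keeps farm-type footprints balanced and
          continues when a type exhausts its sites", {
  sc <- toy_scaled(6, seed = 13)
  traj <- conventional_plan(sc, "constrained")
  counts <- as.matrix(traj[, c("n_mussel", "n_finfish", "n_kelp")])
  # while all types have candidates, footprints differ by at most one
  spread <- apply(counts, 1, function(v) max(v) - min(v))
  full_rotation <- which(apply(counts, 1, min) > 0)
  expect_true(all(spread[seq_len(min(full_rotation))] <= 1))

  # kelp restricted to one site: rotation continues among the others
  d <- msp_domain(data.frame(site_id = paste0("s", 1:6), x = 1:6, y = 0,
                             dev_mussel = TRUE, dev_finfish = TRUE,
                             dev_kelp = c(TRUE, rep(FALSE, 5))))
  sc2 <- scale_values(build_values(toy_responses(d, seed = 14)))
  traj2 <- conventional_plan(sc2, "constrained")
  expect_equal(max(traj2$n_kelp), 1)
  expect_equal(nrow(traj2), 6)
  after_kelp <- traj2$sector[traj2$n_kelp == 1 & traj2$sector != "kelp"]
  expect_true(all(after_kelp %in% c("mussel", "finfish")))
})

test_that("trajectory outcomes match independent per-step recomputation", {
  sc <- toy_scaled(5, seed = 15)
  traj <- conventional_plan(sc, "unconstrained")
  domain <- attr(sc, "domain")
  choice <- setNames(rep("NONE", nrow(domain)), domain$site_id)
  for (k in seq_len(nrow(traj))) {
    choice[traj$site_id[k]] <- traj$option[k]
    out <- plan_outcomes(sc, msp_plan(domain, choice))
    for (nm in out$sector) {
      expect_equal(traj[[paste0("o_", nm)]][k],
                   out$outcome[out$sector == nm], tolerance = 1e-9)
    }
  }
})

test_that("the 2-D frontier interpolates linearly between its points", {
  h <- mspfrontier:::upper_hull(c(0, 100, 30), c(100, 90, 60))
  # the dominated interior point drops; query midway gives the chord value
  expect_equal(approx(h$x, h$y, xout = 50)$y, 95)
})

test_that("coordinated planning dominates both conventional variants on a
          conflicted seascape", {
  sea <- make_fixture("conflict", seed = 1)
  sc <- scale_values(build_values(sea$responses))
  fr <- enumerate_frontier(sc, weights = c(0, 0.5, 1))
  for (mode in c("unconstrained", "constrained")) {
    traj <- conventional_plan(sc, mode = mode)
    vom <- value_of_msp(fr, traj)
    expect_gte(min(vom$value_of_msp, na.rm = TRUE), -1e-9)
    # a conventional point lying on the frontier scores zero, and gaps are
    # NA rather than failures
    expect_true(any(is.na(vom$value_of_msp)))
  }
})
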