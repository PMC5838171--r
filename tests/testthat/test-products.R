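make_small_frontier <- function(n = 4, seed = 21, weights = c(0, 0.5, 1)) {
  sc <- toy_scaled(n, seed = seed)
  enumerate_frontier(sc, weights = weights)
}

test_that("policy filtering keeps exactly the qualifying entries", {
  fr <- make_small_frontier()
  all_in <- filter_plans(fr, min_aqua = 0, max_impact = 100)
  # min_aqua = 0 is a strict bound: only entries with positive aqua outcomes
  e <- fr$entries
  qual <- e$o_mussel > 0 & e$o_finfish > 0 & e$o_kelp > 0
  expect_equal(nrow(all_in$entries), sum(qual))
  expect_equal(nrow(filter_plans(fr, 100, 0)$entries), 0)

  # membership equals an independent per-entry check
  ps <- filter_plans(fr, min_aqua = 5, max_impact = 40)
  keep <- logical(nrow(e))
  for (i in seq_len(nrow(e))) {
    keep[i] <- e$o_mussel[i] > 5 && e$o_finfish[i] > 5 && e$o_kelp[i] > 5 &&
      (100 - e$o_halibut[i]) <= 40 && (100 - e$o_viewshed[i]) <= 40 &&
      (100 - e$o_benthic[i]) <= 40 && (100 - e$o_disease[i]) <= 40
  }
  expect_equal(ps$entries$entry, e$entry[keep])

  # monotone: a stricter policy yields a subset
  strict <- filter_plans(fr, min_aqua = 10, max_impact = 20)
  expect_true(all(strict$entries$entry %in% ps$entries$entry))
  expect_error(filter_plans(fr, -1, 5), "\\[0, 100\\]")
})

test_that("filtered plans match re-solved weights and respect dedup", {
  fr <- make_small_frontier(seed = 22)
  frk <- enumerate_frontier(fr$scaled, weights = c(0, 0.5, 1),
                            keep_plans = TRUE)
  ps <- filter_plans(fr, 5, 50)       # re-solves plans
  psk <- filter_plans(frk, 5, 50)     # slices stored plans
  expect_equal(ps$plans, psk$plans)
  dd <- filter_plans(fr, 5, 50, dedup = TRUE)
  expect_equal(sum(!duplicated(ps$plans)), nrow(dd$entries))
})

test_that("hotspot frequencies equal a counting oracle", {
  set.seed(31)
  d <- toy_domain(6)
  M <- matrix(sample(1:4, 20 * 6, replace = TRUE), 20, 6)
  hs <- hotspot_map(M, domain = d)
  for (i in 1:6) {
    expect_equal(hs$freq_any[i], 100 * mean(M[, i] != 1))
    expect_equal(hs$freq_mussel[i], 100 * mean(M[, i] == 2))
    expect_equal(hs$freq_finfish[i], 100 * mean(M[, i] == 3))
    expect_equal(hs$freq_kelp[i], 100 * mean(M[, i] == 4))
  }
  expect_true(all(hs$freq_any >=
                    pmax(hs$freq_mussel, hs$freq_finfish, hs$freq_kelp)))
  expect_true(all(hs$freq_any <=
                    hs$freq_mussel + hs$freq_finfish + hs$freq_kelp + 1e-12))

  # frontier-accumulated counts equal recounting the stored plans
  fr <- enumerate_frontier(toy_scaled(4, seed = 23),
                           weights = c(0, 1), keep_plans = TRUE)
  expect_equal(hotspot_map(fr),
               hotspot_map(fr$plans, domain = attr(fr$scaled, "domain")))
})

test_that("one-hot Bray-Curtis equals the Hamming fraction of differing sites", {
  set.seed(33)
  M <- matrix(sample(1:4, 8 * 12, replace = TRUE), 8, 12)
  D <- bray_curtis(M)
  for (i in 1:8) for (j in 1:8) {
    expect_equal(D[i, j], mean(M[i, ] != M[j, ]))
  }
  expect_equal(diag(D), rep(0, 8))
  expect_equal(D, t(D))
  expect_equal(bray_curtis(M[c(1, 1), ])[1, 2], 0)
  expect_error(bray_curtis(M[1, , drop = FALSE]), "at least two")

  # cross-check against vegan's Bray-Curtis on the one-hot encoding
  B <- do.call(cbind, lapply(1:4, function(p) (M == p) * 1))
  expect_equal(unname(D), unname(as.matrix(vegan::vegdist(B, "bray"))),
               tolerance = 1e-12)
})

test_that("integer-encoded Bray-Curtis follows the literal formula", {
  M <- rbind(c(1, 2, 3), c(1, 4, 1), c(2, 2, 2))
  D <- bray_curtis(M, encoding = "integer")
  codes <- M - 1
  for (i in 1:3) for (j in 1:3) {
    num <- sum(abs(codes[i, ] - codes[j, ]))
    den <- sum(codes[i, ] + codes[j, ])
    expect_equal(D[i, j], if (den > 0) num / den else 0)
  }
})

test_that("seed-plan clustering recovers planted structure and matches a
          reference single-linkage agglomeration", {
  M <- planted_plans(n_per = 4, n_sites = 30, seed = 7)
  ps <- structure(list(entries = tibble::tibble(entry = 1:12), plans = M,
                       scaled = NULL), class = "msp_plan_set")
  sp <- seed_plans(ps, k = 3, seed = 5)
  truth <- rep(1:3, each = 4)
  # memberships equal the planted groups up to label permutation
  expect_equal(length(unique(paste(sp$clusters$cluster, truth))), 3)
  # and equal an independent hclust single-linkage cut
  ref <- cutree(hclust(as.dist(bray_curtis(M)), "single"), 3)
  expect_equal(length(unique(paste(sp$clusters$cluster, ref))), 3)
  expect_equal(nrow(sp$representatives), 3)
  expect_true(all(sp$representatives$plan %in% sp$clusters$plan))
  expect_lt(sp$stress, 0.2)

  # representatives are the members farthest from the global centroid
  emb <- as.matrix(sp$embedding[, c("dim1", "dim2")])
  cen <- colMeans(emb)
  dc <- sqrt(rowSums(sweep(emb, 2, cen)^2))
  for (r in seq_len(3)) {
    g <- sp$representatives$cluster[r]
    members <- which(sp$clusters$cluster == g)
    expect_equal(sp$representatives$plan[r],
                 members[which.max(dc[members])])
  }

  # representative choice is stable across nMDS seeds
  reps <- sapply(1:5, function(s) seed_plans(ps, k = 3, seed = s)$representatives$plan)
  expect_true(all(apply(reps, 1, function(v) length(unique(v)) == 1)))
})

test_that("degenerate cluster counts behave: k equal to the number of plans", {
  M <- planted_plans(n_per = 2, n_sites = 25, seed = 9)
  ps <- structure(list(entries = tibble::tibble(entry = 1:6), plans = M,
                       scaled = NULL), class = "msp_plan_set")
  sp <- seed_plans(ps, k = 6, seed = 2)
  expect_equal(sort(unique(sp$clusters$cluster)), 1:6)
  expect_equal(sort(sp$representatives$plan), 1:6)
  expect_error(seed_plans(ps, k = 40), "between 1 and")
})
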