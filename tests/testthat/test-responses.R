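test_that("sector response rules follow the stated per-option structure", {
  d <- toy_domain(2)

  h <- halibut_response(d, c(10, 20))
  expect_equal(h$value_none, c(10, 20))
  expect_equal(unlist(h[1, c("value_mussel", "value_finfish", "value_kelp")],
                      use.names = FALSE), c(0, 0, 0))
  expect_error(halibut_response(d, c(-1, 2)), "non-negative")

  v <- viewshed_response(d, c(5, 0), c(8, 0))
  expect_equal(v$value_none, c(0, 0))
  expect_equal(v$value_mussel, c(5, 0))
  expect_equal(v$value_kelp, c(5, 0))
  expect_equal(v$value_finfish, c(8, 0))
  expect_error(viewshed_response(d, c(8, 0), c(5, 0)), "must not exceed")

  b <- benthic_response(d, c(2.5, 0))
  expect_equal(b$value_finfish, c(2.5, 0))
  expect_equal(b$value_mussel + b$value_kelp + b$value_none, c(0, 0))
  expect_error(benthic_response(d, c(-0.1, 0)), "non-negative")

  a <- aquaculture_response(d, c(2, 3), "MUSSEL")
  expect_equal(a$value_mussel, c(2, 3))
  expect_equal(a$value_finfish + a$value_kelp + a$value_none, c(0, 0))
})

test_that("eigenvector centrality agrees with a dense eigendecomposition", {
  expect_equal(eigen_centrality(matrix(c(0, 1, 1, 0), 2)), c(0.5, 0.5))

  # 3-site chain: middle node most central, ends symmetric
  C <- matrix(0, 3, 3)
  C[1, 2] <- C[2, 1] <- C[2, 3] <- C[3, 2] <- 1
  cen <- eigen_centrality(C)
  expect_gt(cen[2], cen[1])
  expect_equal(cen[1], cen[3])

  set.seed(11)
  for (n in c(5, 12, 30, 50)) {
    M <- matrix(runif(n * n), n)
    got <- eigen_centrality(M)
    ref <- eigen(M)$vectors[, 1]
    ref <- abs(Re(ref))
    ref <- ref / sum(ref)
    expect_equal(got, ref, tolerance = 1e-8)
    expect_equal(sum(got), 1, tolerance = 1e-12)
    # invariant under positive rescaling of the matrix
    expect_equal(eigen_centrality(1234.5 * M), got, tolerance = 1e-9)
  }
  expect_error(eigen_centrality(matrix(0, 3, 3)), "no nonzero")
  expect_error(eigen_centrality(matrix(-1, 2, 2)), "non-negative")
})

test_that("tensor assembly masks undevelopable options and negative annuities", {
  d <- toy_domain(3)
  ann <- c(-2, 5, 7)  # negative mussel annuity at s1 => undevelopable there
  resp <- response_tensor(d, list(
    mussel = aquaculture_response(d, ann, "MUSSEL"),
    finfish = aquaculture_response(d, c(1, 1, 1), "FINFISH"),
    kelp = aquaculture_response(d, c(1, 1, 1), "KELP"),
    halibut = halibut_response(d, c(4, 4, 4)),
    viewshed = viewshed_response(d, rep(1, 3), rep(2, 3)),
    benthic = benthic_response(d, rep(1, 3)),
    disease = disease_response(d, matrix(c(0, 1, 0, 1, 0, 1, 0, 1, 0), 3))
  ))
  dom2 <- attr(resp, "domain")
  expect_false(dom2$dev_mussel[1])
  expect_true(all(dom2$dev_mussel[2:3]))
  # masked option carries the no-development response
  R <- mspfrontier:::tensor_array(resp)
  expect_equal(R["mussel", "s1", "MUSSEL"], R["mussel", "s1", "NONE"])
  expect_equal(R["halibut", "s1", "MUSSEL"], R["halibut", "s1", "NONE"])
  # impact sectors have zero response without development
  expect_true(all(R[c("viewshed", "benthic", "disease"), , "NONE"] == 0))
  expect_true(all(R >= 0))
})

test_that("rbar is the exhaustive max over sites and options", {
  resp <- toy_responses(toy_domain(4), seed = 5)
  R <- mspfrontier:::tensor_array(resp)
  for (nm in attr(resp, "sectors")$sector) {
    brute <- -Inf
    for (i in seq_len(dim(R)[2])) for (p in 1:4) {
      brute <- max(brute, R[nm, i, p])
    }
    expect_equal(rbar(resp, nm), brute)
  }
  expect_error(rbar(resp, "shrimp"), "unknown sector")
})

test_that("response and connectivity files round-trip through the readers", {
  d <- toy_domain(3)
  resp <- toy_responses(d, seed = 9)
  dir <- withr::local_tempdir()
  sea <- list(domain = attr(resp, "domain"), responses = resp,
              sectors = attr(resp, "sectors"),
              surfaces = list(connectivity = {
                set.seed(1)
                M <- matrix(runif(9), 3)
                diag(M) <- 0
                dimnames(M) <- list(d$site_id, d$site_id)
                M
              }))
  class(sea) <- "msp_seascape"
  write_seascape(sea, dir)

  d2 <- read_domain(file.path(dir, "sites.csv"))
  files <- setNames(as.list(file.path(dir, paste0("response_",
                                                  sea$sectors$sector, ".csv"))),
                    sea$sectors$sector)
  resp2 <- read_responses(d2, files)
  expect_equal(as.data.frame(resp2), as.data.frame(resp))

  C2 <- read_connectivity(file.path(dir, "connectivity.csv"), d2)
  expect_equal(C2, sea$surfaces$connectivity)

  # misaligned site set fails loudly
  d3 <- toy_domain(4)
  expect_error(read_responses(d3, files), "missing site")
  expect_error(read_connectivity(file.path(dir, "connectivity.csv"), d3),
               "missing site")
})
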