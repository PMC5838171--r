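# Planning products distilled from the frontier: filtered plan sets,
# development hotspot maps, Bray-Curtis plan dissimilarity, and
# cluster-derived seed plans.

# solve many weight vectors at once; returns an entries x sites integer
# choice matrix (codes into msp_options())
solve_many <- function(scaled, Wmat, tol = 1e-12, chunk_size = 2048) {
  sectors <- attr(scaled, "sectors")
  domain <- attr(scaled, "domain")
  X <- scaled_array(scaled)
  mask <- dev_mask(domain)
  n_sec <- nrow(sectors)
  S <- nrow(domain)
  Xp <- lapply(1:4, function(p) matrix(X[, , p], nrow = n_sec))
  n <- nrow(Wmat)
  out <- matrix(1L, n, S)
  for (st in seq(1L, n, by = chunk_size)) {
    rows <- st:min(st + chunk_size - 1L, n)
    Wc <- Wmat[rows, , drop = FALSE]
    best <- Wc %*% Xp[[1]]
    choice <- matrix(1L, length(rows), S)
    for (p in 2:4) {
      objp <- Wc %*% Xp[[p]]
      off <- !mask[, p]
      if (any(off)) objp[, off] <- -Inf
      upd <- objp > best + tol
      if (any(upd)) {
        choice[upd] <- p
        best[upd] <- objp[upd]
      }
    }
    out[rows, ] <- choice
  }
  colnames(out) <- domain$site_id
  out
}

#' Filter frontier plans by a policy
#'
#' Keeps frontier entries in which every aquaculture sector achieves more
#' than `min_aqua` percent of its maximum possible value while no existing
#' sector is impacted by more than `max_impact` percent (impact of an
#' existing sector is `100 - outcome`). The kept entries' plans are
#' materialized (re-derived from their weight vectors when the frontier did
#' not store plans).
#'
#' @param frontier An `msp_frontier`.
#' @param min_aqua Minimum outcome (%) each aquaculture sector must exceed
#'   (strict; default 5).
#' @param max_impact Maximum tolerated impact (%) on each existing sector
#'   (inclusive; default 5).
#' @param dedup If `TRUE`, drop duplicate plans, keeping the first entry of
#'   each; default `FALSE` (duplicates across weight points are retained).
#' @return An object of class `msp_plan_set`: list with `entries` (the kept
#'   frontier rows), `plans` (entries-by-sites integer option codes), and
#'   the `scaled` tensor. An empty result is allowed.
#' @export
filter_plans <- function(frontier, min_aqua = 5, max_impact = 5,
                         dedup = FALSE) {
  if (any(c(min_aqua, max_impact) < 0) || any(c(min_aqua, max_impact) > 100)) {
    abort("policy thresholds must lie in [0, 100]")
  }
  sectors <- attr(frontier$scaled, "sectors")
  e <- frontier$entries
  keep <- rep(TRUE, nrow(e))
  for (nm in sectors$sector[!is.na(sectors$option)]) {
    keep <- keep & e[[paste0("o_", nm)]] > min_aqua
  }
  for (nm in sectors$sector[is.na(sectors$option)]) {
    keep <- keep & (100 - e[[paste0("o_", nm)]]) <= max_impact
  }
  entries <- e[keep, , drop = FALSE]
  plans <- if (!is.null(frontier$plans)) {
    frontier$plans[keep, , drop = FALSE]
  } else if (nrow(entries)) {
    W <- as.matrix(entries[paste0("w_", sectors$sector)])
    colnames(W) <- sectors$sector
    solve_many(frontier$scaled, W, tol = frontier$tol)
  } else {
    matrix(1L, 0, nrow(attr(frontier$scaled, "domain")))
  }
  if (dedup && nrow(entries)) {
    first <- !duplicated(plans)
    entries <- entries[first, , drop = FALSE]
    plans <- plans[first, , drop = FALSE]
  }
  structure(list(entries = entries, plans = plans, scaled = frontier$scaled),
            class = "msp_plan_set")
}

#' @export
print.msp_plan_set <- function(x, ...) {
  cat(sprintf("<msp_plan_set> %d plans over %d sites\n",
              nrow(x$entries), ncol(x$plans)))
  invisible(x)
}

#' Extract one plan from a plan set
#'
#' @param plan_set An `msp_plan_set`.
#' @param row Row index into `plan_set$entries`.
#' @return An `msp_plan`.
#' @export
plan_set_plan <- function(plan_set, row) {
  msp_plan(attr(plan_set$scaled, "domain"),
           msp_options()[plan_set$plans[row, ]])
}

#' Development hotspot map
#'
#' Per-site frequency (percent of plans) of development in any form and for
#' each specific farm type, across all plans of a frontier (accumulated
#' during enumeration) or of a filtered plan set.
#'
#' @param x An `msp_frontier`, an `msp_plan_set`, or an integer plans-by-
#'   sites option-code matrix.
#' @param ... Unused.
#' @return A tibble of class `msp_hotspots`: `site_id`, `x`, `y`,
#'   `freq_any`, `freq_mussel`, `freq_finfish`, `freq_kelp` (percent).
#' @export
hotspot_map <- function(x, ...) UseMethod("hotspot_map")

#' @export
hotspot_map.msp_frontier <- function(x, ...) {
  hotspot_tbl(x$hotspot_counts, nrow(x$entries), attr(x$scaled, "domain"))
}

#' @export
hotspot_map.msp_plan_set <- function(x, ...) {
  hotspot_map(x$plans, domain = attr(x$scaled, "domain"))
}

#' @param domain The `msp_domain` the plan matrix refers to (matrix method
#'   only).
#' @rdname hotspot_map
#' @export
hotspot_map.matrix <- function(x, domain, ...) {
  if (nrow(x) == 0) abort("hotspot map needs at least one plan")
  counts <- vapply(1:4, function(p) colSums(x == p), numeric(ncol(x)))
  hotspot_tbl(counts, nrow(x), domain)
}

hotspot_tbl <- function(counts, n_plans, domain) {
  if (n_plans == 0) abort("hotspot map needs at least one plan")
  freq <- 100 * counts / n_plans
  dimnames(freq) <- NULL
  out <- tibble::tibble(
    site_id = domain$site_id,
    x = domain$x,
    y = domain$y,
    freq_any = 100 - freq[, 1],
    freq_mussel = freq[, 2],
    freq_finfish = freq[, 3],
    freq_kelp = freq[, 4]
  )
  class(out) <- c("msp_hotspots", class(out))
  out
}

plans_matrix <- function(plans) {
  if (inherits(plans, "msp_plan_set")) return(plans$plans)
  if (is.matrix(plans)) return(plans)
  if (is.list(plans) && all(vapply(plans, inherits, TRUE, "msp_plan"))) {
    return(do.call(rbind, lapply(plans, plan_codes)))
  }
  abort("`plans` must be an msp_plan_set, a code matrix, or a list of msp_plan")
}

#' Bray-Curtis dissimilarity between plans
#'
#' Pairwise Bray-Curtis dissimilarity over a set of plans. With the default
#' `one_hot` encoding each plan is a binary site-by-option indicator vector,
#' for which Bray-Curtis reduces exactly to the fraction of sites with
#' differing choices (Hamming fraction) - invariant to how option codes are
#' assigned. The `integer` encoding applies Bray-Curtis literally to the
#' per-site option codes (0 = none, 1 = mussel, 2 = finfish, 3 = kelp),
#' which depends on that code assignment and is retained for comparability.
#'
#' @param plans An `msp_plan_set`, plans-by-sites integer code matrix, or
#'   list of `msp_plan`s; at least two plans.
#' @param encoding `"one_hot"` (default) or `"integer"`.
#' @return A symmetric dissimilarity matrix with zero diagonal, entries in
#'   `[0, 1]`.
#' @export
bray_curtis <- function(plans, encoding = c("one_hot", "integer")) {
  encoding <- match.arg(encoding)
  M <- plans_matrix(plans)
  if (nrow(M) < 2) abort("Bray-Curtis needs at least two plans")
  S <- ncol(M)
  if (encoding == "one_hot") {
    B <- do.call(cbind, lapply(1:4, function(p) (M == p) * 1))
    D <- 1 - tcrossprod(B) / S
  } else {
    codes <- M - 1L  # none = 0
    num <- as.matrix(stats::dist(codes, method = "manhattan"))
    den <- outer(rowSums(codes), rowSums(codes), "+")
    D <- ifelse(den > 0, num / den, 0)
  }
  D[D < 0] <- 0
  diag(D) <- 0
  dimnames(D) <- list(rownames(M), rownames(M))
  D
}

#' Cluster filtered plans and select seed plans
#'
#' Deduplicates the plan set, computes Bray-Curtis dissimilarities, builds a
#' single-linkage dendrogram cut into `k` clusters, embeds the dissimilarity
#' matrix in two dimensions by non-metric multidimensional scaling (Kruskal
#' stress-1, seeded restarts), and selects one seed plan per cluster: the
#' member farthest (Euclidean, in the embedding) from the global embedding
#' centroid, so the seeds span the variation in spatial design.
#'
#' @param plan_set An `msp_plan_set` (e.g. from [filter_plans()]).
#' @param k Number of clusters; default: the largest `k <= 8` whose clusters
#'   all have at least two members (falling back to 2).
#' @param encoding Plan encoding for [bray_curtis()].
#' @param linkage_space `"dissimilarity"` (default: single linkage applied
#'   directly to the Bray-Curtis matrix) or `"embedding"` (single linkage on
#'   Euclidean distances in the 2-D ordination).
#' @param seed RNG seed governing the nMDS restarts (default 42).
#' @param trymax Maximum nMDS random restarts (default 30).
#' @return An object of class `msp_seed_plans`: list with `clusters`
#'   (tibble: unique plan index, frontier entry, cluster), `representatives`
#'   (one row per cluster with its seed plan's entry and embedding
#'   distance), `embedding`, `stress`, `tree` (the `hclust`), `k`, `plans`
#'   (unique plan code matrix), and `dissimilarity`.
#' @export
seed_plans <- function(plan_set, k = NULL, encoding = c("one_hot", "integer"),
                       linkage_space = c("dissimilarity", "embedding"),
                       seed = 42, trymax = 30) {
  encoding <- match.arg(encoding)
  linkage_space <- match.arg(linkage_space)
  M <- plans_matrix(plan_set)
  entry_ids <- if (inherits(plan_set, "msp_plan_set")) {
    plan_set$entries$entry
  } else {
    seq_len(nrow(M))
  }
  first <- !duplicated(M)
  Mu <- M[first, , drop = FALSE]
  ids <- entry_ids[first]
  n <- nrow(Mu)
  if (n < 2) abort("seed-plan selection needs at least two distinct plans")
  rownames(Mu) <- as.character(ids)
  D <- bray_curtis(Mu, encoding)

  # ordination first (it may define the linkage space)
  set.seed(seed)
  ord <- withCallingHandlers(
    vegan::metaMDS(as.dist(D), k = 2, trymax = trymax, trace = 0,
                   autotransform = FALSE, wascores = FALSE),
    warning = function(w) {
      # near-zero stress is a perfect fit, not a failure, on small plan sets
      if (grepl("stress is (nearly) zero", conditionMessage(w), fixed = TRUE)) {
        invokeRestart("muffleWarning")
      }
    })
  if (!isTRUE(ord$converged) && !is.numeric(ord$converged)) {
    abort(sprintf("nMDS did not converge in %d restarts (stress %.4f)",
                  trymax, ord$stress))
  }
  emb <- ord$points

  link_d <- if (linkage_space == "dissimilarity") as.dist(D) else stats::dist(emb)
  tree <- hclust(link_d, method = "single")

  if (is.null(k)) {
    k <- 2L
    for (kk in seq(min(8L, n), 2L)) {
      if (min(table(cutree(tree, kk))) >= 2) {
        k <- kk
        break
      }
    }
  }
  if (k < 1 || k > n) abort("`k` must lie between 1 and the number of distinct plans")
  cl <- cutree(tree, k)

  centroid <- colMeans(emb)
  d_cen <- unname(sqrt(rowSums(sweep(emb, 2, centroid)^2)))
  cl <- unname(cl)
  reps <- purrr::map_dfr(sort(unique(cl)), function(g) {
    members <- which(cl == g)
    r <- members[which.max(d_cen[members])]
    tibble::tibble(cluster = g, plan = r, entry = ids[r],
                   dist_centroid = d_cen[r])
  })

  structure(list(
    clusters = tibble::tibble(plan = seq_len(n), entry = ids, cluster = cl),
    representatives = reps,
    embedding = tibble::tibble(plan = seq_len(n), entry = ids,
                               dim1 = emb[, 1], dim2 = emb[, 2],
                               cluster = cl),
    stress = ord$stress,
    tree = tree,
    k = k,
    plans = Mu,
    dissimilarity = D,
    domain = if (inherits(plan_set, "msp_plan_set")) {
      attr(plan_set$scaled, "domain")
    } else NULL
  ), class = "msp_seed_plans")
}

#' @export
print.msp_seed_plans <- function(x, ...) {
  cat(sprintf("<msp_seed_plans> %d distinct plans in %d clusters (stress-1 %.3f)\n",
              nrow(x$clusters), x$k, x$stress))
  invisible(x)
}
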