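# Conventional-planning counterfactuals: suitability index, greedy
# development trajectories (unconstrained and constrained), and the value of
# coordinated planning measured against them.

#' Suitability index for conventional planning
#'
#' For every developable (aquaculture sector, site) pair: the sector's
#' annuity at the site divided by the scaled-value loss of the most impacted
#' existing (non-aquaculture) sector if that farm type were developed there.
#' Impacts are measured on the common scaled-value currency so they are
#' commensurable across sectors. Sites with no measurable impact get
#' infinite suitability and rank among themselves by annuity (then site
#' order); development that would benefit an existing sector counts as zero
#' impact.
#'
#' @param scaled An `msp_scaled` tensor.
#' @param zero_impact Threshold below which an impact counts as zero
#'   (default 1e-15).
#' @return A tibble of class `msp_suitability`: `sector`, `option`,
#'   `site_id`, `annuity`, `impact`, `suitability`, ordered by descending
#'   suitability with deterministic ties.
#' @export
suitability_index <- function(scaled, zero_impact = 1e-15) {
  sectors <- attr(scaled, "sectors")
  domain <- attr(scaled, "domain")
  X <- scaled_array(scaled)
  mask <- dev_mask(domain)
  denom <- attr(scaled, "denom")
  existing <- which(is.na(sectors$option))
  aqua <- which(!is.na(sectors$option))
  if (!length(aqua)) abort("no aquaculture sectors in the sector table")

  rows <- purrr::map_dfr(aqua, function(j) {
    p <- match(sectors$option[j], msp_options())
    dev <- mask[, p]
    if (!any(dev)) return(tibble::tibble())
    loss <- matrix(X[existing, dev, 1], nrow = length(existing)) -
      matrix(X[existing, dev, p], nrow = length(existing))
    impact <- if (length(existing)) apply(loss, 2, max) else rep(0, sum(dev))
    impact <- pmax(impact, 0)
    tibble::tibble(
      sector = sectors$sector[j],
      option = sectors$option[j],
      site_id = domain$site_id[dev],
      site_idx = which(dev),
      sector_idx = j,
      annuity = unname(X[j, dev, p] * denom[j]),
      impact = unname(impact)
    )
  })
  rows$suitability <- ifelse(rows$impact <= zero_impact, Inf,
                             rows$annuity / rows$impact)
  ord <- order(-rows$suitability,
               ifelse(is.infinite(rows$suitability), -rows$annuity, 0),
               rows$sector_idx, rows$site_idx)
  out <- rows[ord, c("sector", "option", "site_id", "annuity", "impact",
                     "suitability")]
  attr(out, "site_idx") <- rows$site_idx[ord]
  attr(out, "sector_idx") <- rows$sector_idx[ord]
  class(out) <- c("msp_suitability", class(out))
  out
}

#' Simulate a conventional-planning development trajectory
#'
#' Develops sites one at a time in rank order of suitability.
#' `"unconstrained"` planning lets the three aquaculture types compete
#' freely: the globally highest-suitability remaining (sector, site) pair is
#' developed next, and a site taken by one sector is unavailable to the
#' others. `"constrained"` planning regulates an equal footprint across farm
#' types: the farm type with the fewest developed sites picks its most
#' suitable remaining site; once a type exhausts its developable sites the
#' rotation continues among the types still having candidates.
#'
#' @param scaled An `msp_scaled` tensor.
#' @param mode `"unconstrained"` or `"constrained"`.
#' @param levels Maximum number of development steps (default: until no
#'   candidate pairs remain).
#' @param suit Optional precomputed [suitability_index()].
#' @return A tibble of class `msp_trajectory`, one row per step: the site
#'   and farm type developed, its suitability, cumulative per-type
#'   footprints, and the outcome percentage of every sector after the step.
#'   The no-development outcomes are attached as attribute `baseline`.
#' @export
conventional_plan <- function(scaled, mode = c("unconstrained", "constrained"),
                              levels = NULL, suit = NULL) {
  mode <- match.arg(mode)
  sectors <- attr(scaled, "sectors")
  domain <- attr(scaled, "domain")
  suit <- suit %||% suitability_index(scaled)
  site_idx <- attr(suit, "site_idx")
  sector_idx <- attr(suit, "sector_idx")
  X <- scaled_array(scaled)
  n_sec <- nrow(sectors)

  aqua <- unique(sector_idx)
  aqua <- aqua[order(aqua)]
  taken <- rep(FALSE, nrow(domain))
  used <- rep(FALSE, nrow(suit))
  steps_max <- levels %||% nrow(domain)

  pick <- integer(0)
  counts <- setNames(rep(0L, length(aqua)), sectors$sector[aqua])
  if (mode == "unconstrained") {
    for (r in seq_len(nrow(suit))) {
      if (length(pick) >= steps_max) break
      if (!taken[site_idx[r]]) {
        pick <- c(pick, r)
        taken[site_idx[r]] <- TRUE
      }
    }
  } else {
    repeat {
      if (length(pick) >= steps_max) break
      # candidate availability per type
      avail <- vapply(aqua, function(j) {
        any(!used & sector_idx == j & !taken[site_idx])
      }, TRUE)
      if (!any(avail)) break
      active <- aqua[avail]
      j <- active[which.min(counts[match(active, aqua)])]
      r <- which(!used & sector_idx == j & !taken[site_idx])[1]
      pick <- c(pick, r)
      used[r] <- TRUE
      taken[site_idx[r]] <- TRUE
      counts[match(j, aqua)] <- counts[match(j, aqua)] + 1L
    }
  }

  # incremental outcomes along the trajectory
  extra <- scaled_extra(scaled)
  smin <- attr(scaled, "sum_min")
  smax <- attr(scaled, "sum_max")
  den <- smax - smin + extra
  ach <- rowSums(matrix(X[, , 1], nrow = n_sec))
  baseline <- clamp_outcomes(100 * (ach - smin + extra) / den)

  n_steps <- length(pick)
  O <- matrix(0, n_steps, n_sec, dimnames = list(NULL, sectors$sector))
  cum <- matrix(0L, n_steps, length(aqua),
                dimnames = list(NULL, sectors$sector[aqua]))
  cnt <- setNames(rep(0L, length(aqua)), sectors$sector[aqua])
  for (k in seq_len(n_steps)) {
    r <- pick[k]
    i <- site_idx[r]
    p <- match(suit$option[r], msp_options())
    ach <- ach + X[, i, p] - X[, i, 1]
    O[k, ] <- clamp_outcomes(100 * (ach - smin + extra) / den)
    nm <- suit$sector[r]
    cnt[nm] <- cnt[nm] + 1L
    cum[k, ] <- cnt
  }

  out <- tibble::tibble(
    step = seq_len(n_steps),
    site_id = suit$site_id[pick],
    sector = suit$sector[pick],
    option = suit$option[pick],
    suitability = suit$suitability[pick]
  )
  for (nm in colnames(cum)) out[[paste0("n_", nm)]] <- cum[, nm]
  for (nm in sectors$sector) out[[paste0("o_", nm)]] <- O[, nm]
  structure(out, class = c("msp_trajectory", class(out)),
            mode = mode, baseline = baseline, sectors = sectors)
}

# concave majorant (upper convex hull) of a 2-D point cloud, left to right
upper_hull <- function(x, y) {
  o <- order(x, -y)
  x <- x[o]
  y <- y[o]
  keep <- !duplicated(x)
  x <- x[keep]
  y <- y[keep]
  n <- length(x)
  if (n <= 2) return(list(x = x, y = y))
  hx <- hy <- numeric(0)
  for (i in seq_len(n)) {
    while (length(hx) >= 2) {
      m <- length(hx)
      cross <- (hx[m] - hx[m - 1]) * (y[i] - hy[m - 1]) -
        (x[i] - hx[m - 1]) * (hy[m] - hy[m - 1])
      if (cross >= 0) {
        hx <- hx[-m]
        hy <- hy[-m]
      } else break
    }
    hx <- c(hx, x[i])
    hy <- c(hy, y[i])
  }
  list(x = hx, y = hy)
}

#' Value of coordinated planning over a conventional trajectory
#'
#' For each farm type and each sector, the 7-D frontier is projected to a
#' continuous 2-D efficiency frontier: the sector's best outcome as a
#' function of that farm type's development level (its outcome percentage,
#' the framework's currency for "level of development"), linearly
#' interpolated along its concave upper boundary. For each point on that
#' 2-D frontier, the value of coordinated planning to the sector is the
#' frontier outcome minus the conventional outcome at the same development
#' level, the conventional trajectory being interpolated linearly between
#' its site-by-site steps (and anchored at the no-development baseline).
#' Frontier levels the conventional trajectory never reaches (and vice
#' versa) yield `NA` - a gap, not a failure, since no like-for-like
#' comparison exists there.
#'
#' @param frontier An `msp_frontier`.
#' @param trajectory An `msp_trajectory` from [conventional_plan()].
#' @param level Matching currency: `"outcome"` (the farm type's outcome
#'   percentage, the default) or `"footprint"` (number of sites developed
#'   of that farm type).
#' @return A tibble: `mode`, `level_sector` (the farm type fixing the
#'   development level), `sector`, `point` (index along the 2-D frontier),
#'   `level`, `o_msp` (frontier outcome), `o_conventional` (trajectory
#'   outcome at the same level), `value_of_msp` (percentage points).
#' @export
value_of_msp <- function(frontier, trajectory,
                         level = c("outcome", "footprint")) {
  level <- match.arg(level)
  sectors <- attr(frontier$scaled, "sectors")
  e <- frontier$entries
  aqua <- sectors$sector[!is.na(sectors$option)]
  mode <- attr(trajectory, "mode")
  baseline <- attr(trajectory, "baseline")

  purrr::map_dfr(aqua, function(a) {
    lev_conv <- c(0, if (level == "footprint") {
      trajectory[[paste0("n_", a)]]
    } else {
      trajectory[[paste0("o_", a)]]
    })
    purrr::map_dfr(sectors$sector, function(nm) {
      # the pairwise 2-D frontier for (development level of a, value to n):
      # entries whose weights fall only on the two sectors concerned, i.e.
      # the exact scalarization optima of the (a, n) bi-objective problem
      # at the grid's weight ratios
      pair <- rep(TRUE, nrow(e))
      for (other in setdiff(sectors$sector, c(a, nm))) {
        pair <- pair & e[[paste0("w_", other)]] == 0
      }
      ep <- e[pair, , drop = FALSE]
      lev_frontier <- if (level == "footprint") {
        ep[[paste0("n_", a)]]
      } else {
        ep[[paste0("o_", a)]]
      }
      h <- upper_hull(lev_frontier, ep[[paste0("o_", nm)]])
      # conventional outcome as a function of level: first attainment
      # (max over coincident levels), linearly interpolated between steps
      conv_o <- c(baseline[nm], trajectory[[paste0("o_", nm)]])
      cv <- tapply(conv_o, lev_conv, max)
      cl <- as.numeric(names(cv))
      ord <- order(cl)
      cl <- cl[ord]
      cv <- as.numeric(cv)[ord]
      o_conv <- if (length(cl) >= 2) {
        approx(cl, cv, xout = h$x, rule = 1)$y
      } else {
        ifelse(h$x == cl[1], cv[1], NA_real_)
      }
      tibble::tibble(
        mode = mode,
        level_sector = a,
        sector = nm,
        point = seq_along(h$x),
        level = h$x,
        o_msp = h$y,
        o_conventional = o_conv,
        value_of_msp = h$y - o_conv
      )
    })
  })
}
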