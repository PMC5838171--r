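# The tradeoff engine: sector values from responses, domain-wide scaling,
# per-site weighted argmax, frontier enumeration over a weight grid, and
# plan outcomes.

#' Sector values from responses
#'
#' Converts the response tensor to the value tensor: gain sectors (the
#' aquaculture sectors and the fishery) take their response as value;
#' impact sectors take the distance of their response below the sector's
#' domain-wide maximum response, so a higher response (more impact) means a
#' lower value.
#'
#' @param responses An `msp_responses` tensor from [response_tensor()].
#' @return A long tibble of class `msp_values` with columns `sector`,
#'   `site_id`, `option`, `value`, carrying domain/sector attributes and the
#'   per-sector maximum response as `rbar`.
#' @export
build_values <- function(responses) {
  sectors <- attr(responses, "sectors")
  domain <- attr(responses, "domain")
  R <- tensor_array(responses, "response")
  rbar_n <- apply(R, 1, max)
  V <- R
  for (j in which(sectors$klass == "impact")) {
    V[j, , ] <- rbar_n[j] - R[j, , ]
  }
  out <- tensor_tibble(V, "value")
  structure(out, class = c("msp_values", class(out)),
            domain = domain, sectors = sectors, rbar = rbar_n)
}

tensor_tibble <- function(arr, value_col) {
  d <- dim(arr)
  out <- tibble::tibble(
    sector = rep(dimnames(arr)[[1]], times = d[2] * d[3]),
    site_id = rep(rep(dimnames(arr)[[2]], each = d[1]), times = d[3]),
    option = rep(dimnames(arr)[[3]], each = d[1] * d[2])
  )
  out[[value_col]] <- as.vector(arr)
  out
}

#' Scale sector values to a common currency
#'
#' Divides each sector's values by the domain-wide value the sector would
#' attain if its ideal option were selected at every site, yielding unitless
#' scaled values in `[0, 1]` whose sitewise-best total is exactly 1 per
#' sector. These scaled values are the optimization currency: a site-option
#' entry is the proportional contribution to the sector's total potential
#' value.
#'
#' @param values An `msp_values` tensor from [build_values()].
#' @return A long tibble of class `msp_scaled` with column `x`, carrying the
#'   per-sector native denominators and outcome bounds as attributes.
#' @export
scale_values <- function(values) {
  sectors <- attr(values, "sectors")
  domain <- attr(values, "domain")
  V <- tensor_array(values, "value")
  # denominator: sum over sites of the best value across options
  denom <- apply(V, 1, function(m) sum(apply(m, 1, max)))
  if (any(denom <= 0)) {
    abort(paste0("degenerate sector(s) with zero domain-wide value: ",
                 paste(sectors$sector[denom <= 0], collapse = ", ")))
  }
  X <- V / denom
  out <- tensor_tibble(X, "x")
  structure(out, class = c("msp_scaled", class(out)),
            domain = domain, sectors = sectors,
            denom = denom,
            sum_min = apply(X, 1, function(m) sum(apply(m, 1, min))),
            sum_max = apply(X, 1, function(m) sum(apply(m, 1, max))),
            array = X)
}

scaled_array <- function(scaled) {
  attr(scaled, "array") %||% tensor_array(scaled, "x")
}

# outcomes are mathematically confined to [0, 100]; snap summation noise
clamp_outcomes <- function(O, tol = 1e-6) {
  O[O < 0 & O > -tol] <- 0
  O[O > 100 & O < 100 + tol] <- 100
  O
}

# extra (out-of-domain) sector value expressed in scaled units
scaled_extra <- function(scaled) {
  sectors <- attr(scaled, "sectors")
  sectors$extra_value / attr(scaled, "denom")
}

check_weights <- function(alpha, sectors) {
  if (length(alpha) != nrow(sectors)) {
    abort(sprintf("expected %d weights, got %d", nrow(sectors), length(alpha)))
  }
  if (is.null(names(alpha))) {
    names(alpha) <- sectors$sector
  }
  if (!setequal(names(alpha), sectors$sector)) {
    abort("weight names must match the sector set")
  }
  alpha <- alpha[sectors$sector]
  if (anyNA(alpha) || any(alpha < 0) || any(alpha > 1)) {
    abort("weights must lie in [0, 1]")
  }
  alpha
}

#' Solve the optimal plan for one weight vector
#'
#' The per-site objective is the weighted sum of scaled sector values of the
#' chosen option; because the objective is separable across sites, choosing
#' the best permitted option at each site is globally optimal. Ties within
#' `tol` break to no development, then mussel, finfish, kelp.
#'
#' @param scaled An `msp_scaled` tensor.
#' @param alpha Sector weights in `[0, 1]`, named by sector (or unnamed in
#'   sector-table order). An all-zero vector is degenerate and yields the
#'   all-`NONE` plan with a warning.
#' @param tol Absolute tie tolerance (default 1e-12).
#' @return An `msp_plan` tibble with an extra `obj` column (the attained
#'   per-site objective) and the weights attached as an attribute.
#' @export
solve_plan <- function(scaled, alpha, tol = 1e-12) {
  sectors <- attr(scaled, "sectors")
  domain <- attr(scaled, "domain")
  alpha <- check_weights(alpha, sectors)
  if (all(alpha == 0)) {
    warn("all-zero weight vector: objective is identically 0; returning the no-development plan")
  }
  X <- scaled_array(scaled)
  mask <- dev_mask(domain)
  S <- nrow(domain)
  best <- as.numeric(alpha %*% matrix(X[, , 1], nrow = nrow(sectors)))
  choice <- rep(1L, S)
  for (p in 2:4) {
    objp <- as.numeric(alpha %*% matrix(X[, , p], nrow = nrow(sectors)))
    objp[!mask[, p]] <- -Inf
    upd <- objp > best + tol
    choice[upd] <- p
    best[upd] <- objp[upd]
  }
  plan <- msp_plan(domain, msp_options()[choice])
  plan$obj <- best
  attr(plan, "weights") <- alpha
  plan
}

#' Outcomes of a plan
#'
#' For each sector, the plan's cumulative scaled value across sites is
#' expressed as a percentage of the sector's range between its minimum
#' possible cumulative value (full development for gain aquaculture; maximal
#' impact for existing sectors) and its maximum (ideal development for the
#' sector). Sectors holding value outside the planning domain (`extra_value`
#' in the sector table) have that constant added to the achieved sum and to
#' the range, which bounds their minimum outcome above zero.
#'
#' @param scaled An `msp_scaled` tensor.
#' @param plan An `msp_plan` over the same domain.
#' @return A tibble with one row per sector: `sector`, `klass`, `achieved_x`
#'   (cumulative scaled value), `value_native` (same, in native units),
#'   `outcome` (percent, 0-100).
#' @export
plan_outcomes <- function(scaled, plan) {
  sectors <- attr(scaled, "sectors")
  domain <- attr(scaled, "domain")
  if (!identical(plan$site_id, domain$site_id)) {
    idx <- match(domain$site_id, plan$site_id)
    if (anyNA(idx)) abort("plan does not cover the scaled tensor's domain")
    plan <- plan[idx, ]
  }
  X <- scaled_array(scaled)
  code <- plan_codes(plan)
  S <- nrow(domain)
  n_sec <- nrow(sectors)
  ach <- numeric(n_sec)
  for (p in 1:4) {
    sel <- code == p
    if (any(sel)) {
      ach <- ach + rowSums(matrix(X[, sel, p], nrow = n_sec))
    }
  }
  extra <- scaled_extra(scaled)
  smin <- attr(scaled, "sum_min")
  smax <- attr(scaled, "sum_max")
  den <- smax - smin + extra
  if (any(den <= 0)) {
    abort(paste0("zero outcome denominator for sector(s): ",
                 paste(sectors$sector[den <= 0], collapse = ", ")))
  }
  tibble::tibble(
    sector = sectors$sector,
    klass = sectors$klass,
    achieved_x = unname(ach),
    value_native = unname(ach * attr(scaled, "denom")),
    outcome = unname(clamp_outcomes(100 * (ach - smin + extra) / den))
  )
}

#' Enumerate the efficiency frontier over a weight grid
#'
#' Solves the per-site argmax for every combination of per-sector weights
#' (the Cartesian product of the per-sector grids) and records each entry's
#' weights, attained cumulative scaled values, outcome percentages, and
#' per-option development footprints. With the default six-point grid
#' `{0, 0.2, ..., 1}` over seven sectors this enumerates 6^7 = 279,936
#' exact optimal plans.
#'
#' Plans are not stored by default (they are re-derivable from any entry's
#' weights via [solve_plan()] / [frontier_plan()]); per-site development
#' frequencies over all entries are accumulated during the sweep and
#' retrieved with [hotspot_map()].
#'
#' @param scaled An `msp_scaled` tensor.
#' @param weights Either a numeric vector of grid values shared by all
#'   sectors (default `seq(0, 1, 0.2)`), or a named list of per-sector grids.
#' @param max_entries Refusal guard on the grid-product size (default
#'   3e5, admitting the full 6^7 grid).
#' @param chunk_size Weight vectors per matrix-algebra chunk (default 2048).
#' @param keep_plans If `TRUE`, store every entry's plan as an
#'   entries-by-sites integer matrix (memory permitting); default stores
#'   plans only when `entries * sites <= 2e6`.
#' @param tol Tie tolerance passed to the argmax.
#' @return An object of class `msp_frontier`: a list with `entries` (one row
#'   per weight-grid point), `hotspot_counts`, the `scaled` tensor, and
#'   optionally `plans`.
#' @export
enumerate_frontier <- function(scaled, weights = seq(0, 1, 0.2),
                               max_entries = 3e5, chunk_size = 2048,
                               keep_plans = NULL, tol = 1e-12) {
  sectors <- attr(scaled, "sectors")
  domain <- attr(scaled, "domain")
  n_sec <- nrow(sectors)
  grids <- weight_grids(weights, sectors)
  n_entries <- prod(vapply(grids, length, 1L))
  if (n_entries > max_entries) {
    abort(sprintf(
      "weight grid has %d combinations, above the cap of %d; raise `max_entries` if intended",
      n_entries, max_entries))
  }
  Wmat <- as.matrix(do.call(expand.grid, c(grids, KEEP.OUT.ATTRS = FALSE)))
  colnames(Wmat) <- sectors$sector

  X <- scaled_array(scaled)
  mask <- dev_mask(domain)
  S <- nrow(domain)
  Xp <- lapply(1:4, function(p) matrix(X[, , p], nrow = n_sec))
  keep_plans <- keep_plans %||% (as.double(n_entries) * S <= 2e6)

  ach <- matrix(0, n_entries, n_sec)
  counts <- matrix(0L, n_entries, 4)
  hot <- matrix(0, S, 4, dimnames = list(domain$site_id, msp_options()))
  objective <- numeric(n_entries)
  plans <- if (keep_plans) matrix(1L, n_entries, S) else NULL

  starts <- seq(1L, n_entries, by = chunk_size)
  for (st in starts) {
    en <- min(st + chunk_size - 1L, n_entries)
    rows <- st:en
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
    for (p in 1:4) {
      ind <- choice == p
      counts[rows, p] <- as.integer(rowSums(ind))
      hot[, p] <- hot[, p] + colSums(ind)
      ach[rows, ] <- ach[rows, , drop = FALSE] + tcrossprod(ind, Xp[[p]])
    }
    objective[rows] <- rowSums(best)
    if (keep_plans) plans[rows, ] <- choice
  }

  extra <- scaled_extra(scaled)
  smin <- attr(scaled, "sum_min")
  smax <- attr(scaled, "sum_max")
  den <- smax - smin + extra
  O <- clamp_outcomes(100 * sweep(sweep(ach, 2, smin - extra, "-"), 2, den, "/"))

  entries <- tibble::tibble(entry = seq_len(n_entries))
  for (j in seq_len(n_sec)) entries[[paste0("w_", sectors$sector[j])]] <- Wmat[, j]
  for (j in seq_len(n_sec)) entries[[paste0("x_", sectors$sector[j])]] <- ach[, j]
  for (j in seq_len(n_sec)) entries[[paste0("o_", sectors$sector[j])]] <- O[, j]
  entries$n_mussel <- counts[, 2]
  entries$n_finfish <- counts[, 3]
  entries$n_kelp <- counts[, 4]
  entries$n_developed <- counts[, 2] + counts[, 3] + counts[, 4]
  entries$objective <- objective

  structure(list(entries = entries,
                 hotspot_counts = hot,
                 scaled = scaled,
                 plans = plans,
                 grids = grids,
                 tol = tol),
            class = "msp_frontier")
}

weight_grids <- function(weights, sectors) {
  if (is.numeric(weights)) {
    grids <- rep(list(sort(weights)), nrow(sectors))
    names(grids) <- sectors$sector
  } else if (is.list(weights)) {
    if (!setequal(names(weights), sectors$sector)) {
      abort("per-sector weight grids must be named by the sector set")
    }
    grids <- lapply(weights[sectors$sector], sort)
  } else {
    abort("`weights` must be a numeric grid or a named list of grids")
  }
  if (any(vapply(grids, length, 1L) == 0)) abort("empty weight grid")
  rng <- range(unlist(grids))
  if (rng[1] < 0 || rng[2] > 1) abort("weight grid values must lie in [0, 1]")
  grids
}

#' Re-derive the plan of a frontier entry
#'
#' Plans are exact deterministic functions of an entry's weight vector, so
#' frontiers that do not store plans can reproduce any entry's plan on
#' demand.
#'
#' @param frontier An `msp_frontier`.
#' @param entry Entry id (row of `frontier$entries`).
#' @return An `msp_plan`.
#' @export
frontier_plan <- function(frontier, entry) {
  e <- frontier$entries[frontier$entries$entry == entry, ]
  if (nrow(e) != 1) abort("unknown frontier entry")
  sectors <- attr(frontier$scaled, "sectors")
  alpha <- as.numeric(e[paste0("w_", sectors$sector)])
  names(alpha) <- sectors$sector
  suppressWarnings(solve_plan(frontier$scaled, alpha, tol = frontier$tol))
}

#' @export
print.msp_frontier <- function(x, ...) {
  sectors <- attr(x$scaled, "sectors")
  cat(sprintf("<msp_frontier> %d optimal plans over %d sites, %d sectors\n",
              nrow(x$entries), nrow(attr(x$scaled, "domain")), nrow(sectors)))
  cat("  weight grid sizes: ",
      paste(vapply(x$grids, length, 1L), collapse = " x "), "\n", sep = "")
  invisible(x)
}

#' Check the scalarization weight-monotonicity property
#'
#' Along any line of the weight grid where only one sector's weight
#' increases, that sector's attained cumulative scaled value must not
#' decrease. Returns the per-sector minimum forward difference (negative
#' values beyond tolerance indicate violations).
#'
#' @param frontier An `msp_frontier`.
#' @param tol Tolerance below which a negative difference counts as a
#'   violation (default 1e-12).
#' @return A tibble with `sector`, `min_diff`, `violations`.
#' @export
check_weight_monotonicity <- function(frontier, tol = 1e-12) {
  sectors <- attr(frontier$scaled, "sectors")
  e <- frontier$entries
  res <- purrr::map_dfr(sectors$sector, function(nm) {
    others <- setdiff(sectors$sector, nm)
    ord <- do.call(order, c(unname(as.list(e[paste0("w_", others)])),
                            list(e[[paste0("w_", nm)]])))
    g <- length(frontier$grids[[nm]])
    xs <- e[[paste0("x_", nm)]][ord]
    d <- diff(xs)
    # drop differences that straddle group boundaries
    keep <- rep(c(rep(TRUE, g - 1), FALSE), length.out = length(d))
    d <- d[keep]
    tibble::tibble(sector = nm,
                   min_diff = if (length(d)) min(d) else NA_real_,
                   violations = sum(d < -tol))
  })
  res
}
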