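# Synthetic seascape generator: spatially structured domains, constraint
# masks, sector value surfaces, profit streams and connectivity matrices,
# so the whole engine runs with no external data.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (!is.null(old)) {
      assign(".Random.seed", old, globalenv())
    } else if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# Gaussian-kernel-smoothed standard-normal field on an ny x nx grid,
# standardized to mean 0, sd 1; corr_len = 0 gives i.i.d. noise.
smooth_field <- function(nx, ny, corr_len = 0) {
  z <- matrix(rnorm(nx * ny), nrow = ny, ncol = nx)
  if (corr_len > 0) {
    kmat <- function(n) {
      d <- abs(outer(seq_len(n), seq_len(n), "-"))
      k <- exp(-d^2 / (2 * corr_len^2))
      k / rowSums(k)
    }
    z <- kmat(ny) %*% z %*% t(kmat(nx))
    z <- (z - mean(z)) / stats::sd(as.vector(z))
  }
  as.vector(t(z))  # row-major: x varies fastest, matching site order
}

gaussian_bump <- function(x, y, center, radius, nx, ny) {
  cx <- 1 + center[1] * (nx - 1)
  cy <- 1 + center[2] * (ny - 1)
  r <- radius * max(nx, ny)
  exp(-((x - cx)^2 + (y - cy)^2) / (2 * r^2))
}

#' Synthetic seascape configuration
#'
#' Parameters of the synthetic planning domain and its sector surfaces: a
#' rectangular 1-km site grid with a smooth monotone offshore depth
#' gradient, depth-window and random-exclusion developability constraints,
#' spatially autocorrelated (Gaussian-kernel-smoothed) value surfaces with
#' sector-specific hotspot centers so inter-sector conflict intensity is
#' tunable, per-site aquaculture profit streams (start-up cost at year 0,
#' level operating profit thereafter) amortized to annuities, and a sparse
#' non-negative distance-decay connectivity matrix with optional directional
#' advection bias.
#'
#' @param nx,ny Grid dimensions (sites are 1 km apart; `y` increases
#'   offshore).
#' @param seed Master RNG seed for the seascape.
#' @param depth Depth field: `near`/`far` endpoints (m) of the offshore
#'   gradient, plus `noise_sd` (m) and `corr_len` (sites) of its smoothed
#'   noise.
#' @param exclusion_frac Fraction of sites inside randomly placed exclusion
#'   zones (marine protected areas, shipping lanes, military zones), in
#'   `[0, 1)`; `exclusion_len` sets their spatial coherence.
#' @param exclusion_len Correlation length (sites) of the exclusion field.
#' @param delta,horizon Discount rate and amortization horizon for the
#'   profit streams.
#' @param aqua Per-farm-type surface parameters: hotspot `center` (fractions
#'   of the domain), `radius` (fraction of extent), annual `profit` scale
#'   ($/yr), start-up `capex` ($), annual operating `cost` ($/yr),
#'   `corr_len` and `noise_sd` of the multiplicative noise.
#' @param halibut,viewshed,benthic Existing-sector surface parameters. The
#'   viewshed surface combines an offshore exponential `decay` with an
#'   alongshore population profile (`pop_base` plus Gaussian `cities`, each
#'   `list(x, width, weight)` in domain fractions), mirroring how
#'   person-views concentrate near population centres; `finfish_factor >= 1`
#'   scales partial (longline) to full (pen) visibility.
#' @param connectivity Distance-decay scale `rho` (km), `advection` drift
#'   vector (km), and `sparsity` (quantile of entries zeroed).
#' @param halibut_extra_multiple Fishery value held outside the domain, as a
#'   multiple of the in-domain maximum cumulative fishery value (enters the
#'   outcome denominators only).
#' @return A list of class `seascape_config`.
#' @export
seascape_config <- function(
    nx = 15, ny = 15, seed = 1,
    depth = list(near = 10, far = 120, noise_sd = 5, corr_len = 3),
    exclusion_frac = 0.1, exclusion_len = 2,
    delta = 0.05, horizon = 10,
    aqua = list(
      mussel = list(center = c(0.35, 0.5), radius = 0.8, profit = 3e5,
                    capex = 4e5, cost = 5e4, corr_len = 2, noise_sd = 0.3),
      finfish = list(center = c(0.7, 0.65), radius = 0.6, profit = 8e5,
                     capex = 1.6e6, cost = 2.5e5, corr_len = 2,
                     noise_sd = 0.35),
      kelp = list(center = c(0.55, 0.45), radius = 0.6, profit = 2e5,
                  capex = 2.5e5, cost = 4e4, corr_len = 2, noise_sd = 0.3)
    ),
    halibut = list(center = c(0.35, 0.4), radius = 0.35, amp = 5e4,
                   corr_len = 2, noise_sd = 0.4, base = 0.5),
    viewshed = list(shore_views = 5e4, decay = 0.3, finfish_factor = 1.8,
                    corr_len = 2, noise_sd = 0.4, pop_base = 0.1,
                    cities = list(list(x = 0.12, width = 0.08, weight = 1),
                                  list(x = 0.85, width = 0.06,
                                       weight = 0.7))),
    benthic = list(amp = 2, corr_len = 2, noise_sd = 0.12),
    connectivity = list(rho = 3, advection = c(1.5, 0), sparsity = 0.8),
    halibut_extra_multiple = 0) {
  cfg <- list(nx = nx, ny = ny, seed = seed, depth = depth,
              exclusion_frac = exclusion_frac, exclusion_len = exclusion_len,
              delta = delta, horizon = horizon, aqua = aqua,
              halibut = halibut, viewshed = viewshed, benthic = benthic,
              connectivity = connectivity,
              halibut_extra_multiple = halibut_extra_multiple)
  stopifnot(nx >= 1, ny >= 1, exclusion_frac >= 0, exclusion_frac < 1)
  class(cfg) <- "seascape_config"
  cfg
}

#' Generate a synthetic planning domain
#'
#' Builds the site grid and its developability masks: mussel and kelp
#' longlines permitted at 20-80 m depth, finfish pens at 30-100 m, with
#' randomly placed coherent exclusion zones removing a configured fraction
#' of sites from all aquaculture. Economic (negative-annuity) masking is
#' applied later, during response-tensor assembly.
#'
#' @param cfg A [seascape_config()].
#' @return An `msp_domain` with attribute `depth`.
#' @export
generate_domain <- function(cfg) {
  with_seed(cfg$seed, {
    nx <- cfg$nx
    ny <- cfg$ny
    x <- rep(seq_len(nx), times = ny)
    y <- rep(seq_len(ny), each = nx)
    grad <- if (ny > 1) (y - 1) / (ny - 1) else rep(0.5, length(y))
    depth <- cfg$depth$near + (cfg$depth$far - cfg$depth$near) * grad +
      cfg$depth$noise_sd * smooth_field(nx, ny, cfg$depth$corr_len)
    shellfish_ok <- depth >= 20 & depth <= 80
    finfish_ok <- depth >= 30 & depth <= 100
    excluded <- rep(FALSE, nx * ny)
    if (cfg$exclusion_frac > 0) {
      e <- smooth_field(nx, ny, cfg$exclusion_len)
      excluded <- e > stats::quantile(e, 1 - cfg$exclusion_frac)
    }
    dom <- msp_domain(tibble::tibble(
      site_id = sprintf("s%04d", seq_len(nx * ny)),
      x = x, y = y,
      dev_mussel = shellfish_ok & !excluded,
      dev_finfish = finfish_ok & !excluded,
      dev_kelp = shellfish_ok & !excluded
    ))
    attr(dom, "depth") <- depth
    dom
  })
}

sector_surface <- function(domain, cfg, params, nx, ny) {
  bump <- gaussian_bump(domain$x, domain$y, params$center, params$radius,
                        nx, ny)
  base <- params$base %||% 0
  noise <- exp(params$noise_sd * smooth_field(nx, ny, params$corr_len))
  list(bump = base + (1 - base) * bump, noise = noise)
}

#' Generate synthetic sector value surfaces and connectivity
#'
#' Produces every input the response builders need: per-farm-type annuity
#' surfaces (from year-0 capital outlay plus level annual operating profit,
#' amortized via [profit_annuity()]; sites far from a sector's hotspot run
#' negative and become economically undevelopable), a non-negative fishery
#' annuity surface, viewshed surfaces with partial <= full, a benthic flux
#' surface, and a sparse non-negative connectivity matrix with
#' distance-decay kernel and advection bias.
#'
#' @param cfg A [seascape_config()].
#' @param domain The domain from [generate_domain()].
#' @return A list: `annuity` (named list per farm type), `halibut`,
#'   `views_partial`, `views_full`, `toc_flux`, `connectivity`, `profits`
#'   (named list of per-site annual profit matrices).
#' @export
generate_values <- function(cfg, domain) {
  with_seed(cfg$seed + 1L, {
    nx <- cfg$nx
    ny <- cfg$ny
    S <- nrow(domain)

    annuity_list <- list()
    profit_list <- list()
    for (nm in names(cfg$aqua)) {
      ps <- cfg$aqua[[nm]]
      sf <- sector_surface(domain, cfg, ps, nx, ny)
      annual <- ps$profit * sf$bump * sf$noise - ps$cost
      profits <- cbind(-ps$capex, matrix(rep(annual, cfg$horizon), nrow = S))
      annuity_list[[nm]] <- apply(profits, 1, profit_annuity,
                                  delta = cfg$delta)
      profit_list[[nm]] <- profits
    }

    hs <- sector_surface(domain, cfg, cfg$halibut, nx, ny)
    halibut <- cfg$halibut$amp * hs$bump * hs$noise

    vn <- exp(cfg$viewshed$noise_sd *
                smooth_field(nx, ny, cfg$viewshed$corr_len))
    vw <- cfg$viewshed
    pop <- vw$pop_base %||% 1
    if (!is.null(vw$cities)) {
      for (ct in vw$cities) {
        pop <- pop + ct$weight *
          exp(-(domain$x - (1 + ct$x * (nx - 1)))^2 /
                (2 * (ct$width * nx)^2))
      }
    }
    views_partial <- vw$shore_views * pop *
      exp(-vw$decay * domain$y) * vn
    views_full <- views_partial * vw$finfish_factor

    toc_flux <- cfg$benthic$amp *
      exp(cfg$benthic$noise_sd * smooth_field(nx, ny, cfg$benthic$corr_len))

    cc <- cfg$connectivity
    dx <- outer(domain$x, domain$x, function(a, b) b - a) - cc$advection[1]
    dy <- outer(domain$y, domain$y, function(a, b) b - a) - cc$advection[2]
    C <- exp(-sqrt(dx^2 + dy^2) / cc$rho)
    diag(C) <- 0
    if (cc$sparsity > 0) {
      thr <- stats::quantile(C[C > 0], cc$sparsity)
      C[C < thr] <- 0
    }
    if (all(C == 0)) C[which.max(dx^2)] <- 1
    dimnames(C) <- list(domain$site_id, domain$site_id)

    list(annuity = annuity_list, halibut = halibut,
         views_partial = views_partial, views_full = views_full,
         toc_flux = toc_flux, connectivity = C, profits = profit_list)
  })
}

#' Generate a complete synthetic seascape
#'
#' Runs [generate_domain()] and [generate_values()] and assembles the
#' response tensor (applying economic masking), yielding everything the
#' tradeoff engine consumes.
#'
#' @param cfg A [seascape_config()].
#' @return A list of class `msp_seascape`: `domain` (after economic
#'   masking), `responses`, `sectors`, `surfaces`, `config`.
#' @export
sim_seascape <- function(cfg) {
  domain <- generate_domain(cfg)
  vals <- generate_values(cfg, domain)
  extra <- if (cfg$halibut_extra_multiple > 0) {
    cfg$halibut_extra_multiple * sum(vals$halibut)
  } else 0
  sectors <- default_sectors(halibut_extra_value = extra)
  slices <- list(
    mussel = aquaculture_response(domain, vals$annuity$mussel, "MUSSEL"),
    finfish = aquaculture_response(domain, vals$annuity$finfish, "FINFISH"),
    kelp = aquaculture_response(domain, vals$annuity$kelp, "KELP"),
    halibut = halibut_response(domain, vals$halibut),
    viewshed = viewshed_response(domain, vals$views_partial, vals$views_full),
    benthic = benthic_response(domain, vals$toc_flux),
    disease = disease_response(domain, vals$connectivity)
  )
  responses <- response_tensor(domain, slices, sectors)
  structure(list(domain = attr(responses, "domain"),
                 responses = responses,
                 sectors = sectors,
                 surfaces = vals,
                 config = cfg),
            class = "msp_seascape")
}

#' Named fixture seascapes
#'
#' Ready-made synthetic seascapes exercising distinct planning regimes:
#' * `tiny` - 5 sites, everything developable; small enough for exhaustive
#'   whole-domain enumeration.
#' * `conflict` - 15 x 15 grid with the fishery hotspot sitting on the
#'   mussel hotspot, forcing a strict mussel-fishery tradeoff.
#' * `segregated` - 15 x 15 grid with disjoint sector hotspots and tight
#'   economic footprints, so all aquaculture sectors can be developed nearly
#'   fully at once.
#' * `scb-like` - 33 x 33 grid (1089 sites) with depth windows, exclusion
#'   zones, seven sectors, moderate hotspot overlap, and out-of-domain
#'   fishery value, qualitatively mimicking a realistic bight-scale domain.
#'
#' @param name Preset name.
#' @param seed Master seed (default 1).
#' @return An `msp_seascape`.
#' @export
make_fixture <- function(name = c("tiny", "conflict", "segregated",
                                  "scb-like"),
                         seed = 1) {
  name <- match.arg(name)
  cfg <- switch(
    name,
    tiny = seascape_config(
      nx = 5, ny = 1, seed = seed,
      depth = list(near = 50, far = 50, noise_sd = 0, corr_len = 0),
      exclusion_frac = 0,
      aqua = list(
        mussel = list(center = c(0.4, 0.5), radius = 1.5, profit = 6e5,
                      capex = 5e5, cost = 1e5, corr_len = 1, noise_sd = 0.4),
        finfish = list(center = c(0.6, 0.5), radius = 1.5, profit = 9e5,
                       capex = 1e6, cost = 2e5, corr_len = 1, noise_sd = 0.4),
        kelp = list(center = c(0.5, 0.5), radius = 1.5, profit = 4e5,
                    capex = 3e5, cost = 8e4, corr_len = 1, noise_sd = 0.4)
      ),
      halibut = list(center = c(0.5, 0.5), radius = 1.5, amp = 4e4,
                     corr_len = 1, noise_sd = 0.4),
      connectivity = list(rho = 2, advection = c(0.5, 0), sparsity = 0.3)
    ),
    conflict = seascape_config(
      nx = 15, ny = 15, seed = seed,
      exclusion_frac = 0.05,
      halibut = list(center = c(0.35, 0.5), radius = 0.25, amp = 5e4,
                     corr_len = 2, noise_sd = 0.4, base = 0.65),
      viewshed = list(shore_views = 5e4, decay = 0.3, finfish_factor = 1.8,
                      corr_len = 2, noise_sd = 0.4, pop_base = 0.2,
                      cities = list(list(x = 0.12, width = 0.08, weight = 1),
                                    list(x = 0.85, width = 0.06,
                                         weight = 0.7)))
    ),
    segregated = seascape_config(
      nx = 15, ny = 15, seed = seed,
      exclusion_frac = 0,
      depth = list(near = 40, far = 60, noise_sd = 3, corr_len = 3),
      aqua = list(
        mussel = list(center = c(0.15, 0.2), radius = 0.16, profit = 8e5,
                      capex = 8e5, cost = 3e5, corr_len = 2, noise_sd = 0.15),
        finfish = list(center = c(0.85, 0.2), radius = 0.16, profit = 1.6e6,
                       capex = 2.5e6, cost = 6e5, corr_len = 2,
                       noise_sd = 0.15),
        kelp = list(center = c(0.5, 0.85), radius = 0.16, profit = 5e5,
                    capex = 4e5, cost = 2e5, corr_len = 2, noise_sd = 0.15)
      ),
      halibut = list(center = c(0.15, 0.85), radius = 0.16, amp = 5e4,
                     corr_len = 2, noise_sd = 0.15)
    ),
    `scb-like` = seascape_config(
      nx = 33, ny = 33, seed = seed,
      exclusion_frac = 0.12, exclusion_len = 3,
      depth = list(near = 10, far = 130, noise_sd = 8, corr_len = 4),
      aqua = list(
        mussel = list(center = c(0.35, 0.5), radius = 0.8, profit = 3e5,
                      capex = 4e5, cost = 5e4, corr_len = 3, noise_sd = 0.3),
        finfish = list(center = c(0.7, 0.65), radius = 0.6, profit = 8e5,
                       capex = 1.6e6, cost = 2.5e5, corr_len = 3,
                       noise_sd = 0.35),
        kelp = list(center = c(0.55, 0.45), radius = 0.6, profit = 2e5,
                    capex = 2.5e5, cost = 4e4, corr_len = 3, noise_sd = 0.3)
      ),
      halibut = list(center = c(0.35, 0.4), radius = 0.35, amp = 5e4,
                     corr_len = 3, noise_sd = 0.4),
      viewshed = list(shore_views = 5e4, decay = 0.3, finfish_factor = 1.8,
                      corr_len = 3, noise_sd = 0.4, pop_base = 0.1,
                      cities = list(list(x = 0.12, width = 0.08, weight = 1),
                                    list(x = 0.85, width = 0.06,
                                         weight = 0.7))),
      benthic = list(amp = 2, corr_len = 3, noise_sd = 0.12),
      connectivity = list(rho = 4, advection = c(2, 0.5), sparsity = 0.9),
      halibut_extra_multiple = 13.3
    )
  )
  sim_seascape(cfg)
}

#' Write a seascape's inputs to files
#'
#' Writes the exact file formats the readers consume: a site-table CSV, one
#' response CSV per sector, and a dense connectivity CSV.
#'
#' @param seascape An `msp_seascape`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_seascape <- function(seascape, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_domain(seascape$domain, file.path(dir, "sites.csv"))
  resp <- seascape$responses
  for (nm in seascape$sectors$sector) {
    sl <- resp[resp$sector == nm, ]
    wide <- tidyr::pivot_wider(sl[c("site_id", "option", "response")],
                               names_from = "option",
                               values_from = "response")
    names(wide) <- c("site_id", paste0("value_", tolower(msp_options())))
    readr::write_csv(wide, file.path(dir, paste0("response_", nm, ".csv")))
  }
  write_connectivity(seascape$surfaces$connectivity,
                     file.path(dir, "connectivity.csv"))
  invisible(dir)
}
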