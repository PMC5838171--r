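# broom-style tidiers for the fitted/derived objects.

#' Tidy a frontier into long outcome form
#'
#' One row per (entry, sector) with the entry's weight and outcome for that
#' sector plus its development footprints.
#'
#' @param x An `msp_frontier`.
#' @param ... Unused.
#' @return A tibble: `entry`, `sector`, `weight`, `achieved_x`, `outcome`,
#'   `n_mussel`, `n_finfish`, `n_kelp`, `n_developed`.
#' @export
tidy.msp_frontier <- function(x, ...) {
  sectors <- attr(x$scaled, "sectors")
  e <- x$entries
  purrr::map_dfr(sectors$sector, function(nm) {
    tibble::tibble(
      entry = e$entry,
      sector = nm,
      weight = e[[paste0("w_", nm)]],
      achieved_x = e[[paste0("x_", nm)]],
      outcome = e[[paste0("o_", nm)]],
      n_mussel = e$n_mussel,
      n_finfish = e$n_finfish,
      n_kelp = e$n_kelp,
      n_developed = e$n_developed
    )
  })
}

#' @rdname tidy.msp_frontier
#' @export
glance.msp_frontier <- function(x, ...) {
  sectors <- attr(x$scaled, "sectors")
  domain <- attr(x$scaled, "domain")
  tibble::tibble(
    n_entries = nrow(x$entries),
    n_sectors = nrow(sectors),
    n_sites = nrow(domain),
    grid_sizes = paste(vapply(x$grids, length, 1L), collapse = "x"),
    max_developed = max(x$entries$n_developed)
  )
}

#' Tidy a conventional-planning trajectory
#'
#' One row per (step, sector) with the outcome after the step.
#'
#' @param x An `msp_trajectory`.
#' @param ... Unused.
#' @return A tibble: `step`, `site_id`, `developed_sector`, `option`,
#'   `sector`, `outcome`.
#' @export
tidy.msp_trajectory <- function(x, ...) {
  sectors <- attr(x, "sectors")
  purrr::map_dfr(sectors$sector, function(nm) {
    tibble::tibble(
      step = x$step,
      site_id = x$site_id,
      developed_sector = x$sector,
      option = x$option,
      sector = nm,
      outcome = x[[paste0("o_", nm)]]
    )
  })
}

#' @rdname tidy.msp_trajectory
#' @export
glance.msp_trajectory <- function(x, ...) {
  tibble::tibble(
    mode = attr(x, "mode"),
    n_steps = nrow(x),
    min_suitability = min(x$suitability),
    max_suitability = max(x$suitability)
  )
}

#' Tidy seed-plan clusters
#'
#' One row per distinct plan with its cluster, ordination coordinates and
#' whether it is the cluster's seed (representative) plan.
#'
#' @param x An `msp_seed_plans`.
#' @param ... Unused.
#' @return A tibble: `plan`, `entry`, `cluster`, `dim1`, `dim2`,
#'   `is_representative`.
#' @export
tidy.msp_seed_plans <- function(x, ...) {
  emb <- x$embedding
  emb$is_representative <- emb$plan %in% x$representatives$plan
  emb
}

#' @rdname tidy.msp_seed_plans
#' @export
glance.msp_seed_plans <- function(x, ...) {
  tibble::tibble(
    n_plans = nrow(x$clusters),
    k = x$k,
    stress = x$stress,
    min_cluster_size = min(table(x$clusters$cluster))
  )
}
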