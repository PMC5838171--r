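# Core domain types: development options, sector specifications, planning
# domains and plans, plus their file readers/writers.

#' Development options
#'
#' The four per-site development options: no development, mussel longlines,
#' finfish pens, kelp longlines. `"NONE"` is permitted at every site; the
#' three aquaculture options are subject to the domain's developability masks.
#'
#' @return Character vector of the four option codes, in canonical
#'   (tie-breaking) order: `NONE`, `MUSSEL`, `FINFISH`, `KELP`.
#' @export
#' @examples
#' msp_options()
msp_options <- function() {
  c("NONE", "MUSSEL", "FINFISH", "KELP")
}

# columns of the developability mask matching msp_options()[-1]
dev_columns <- function() c("dev_mussel", "dev_finfish", "dev_kelp")

#' Sector specification table
#'
#' Describes the sectors entering the tradeoff analysis. Each sector is either
#' a gain sector (its response raises its value: the three aquaculture sectors
#' and the wild-capture fishery) or an impact sector (its response lowers its
#' value: viewshed, benthic health, disease risk). Aquaculture sectors carry
#' the development option whose adoption generates their value; `extra_value`
#' is value held outside the planning domain, entering only the outcome
#' denominators (the fishery adjustment that bounds its minimum outcome
#' above zero).
#'
#' @param sector Character vector of sector names.
#' @param klass `"gain"` or `"impact"` per sector.
#' @param option For aquaculture gain sectors, the matching development option
#'   code; `NA` otherwise.
#' @param units Free-text units per sector (metadata only; the engine never
#'   converts units).
#' @param extra_value Non-negative value held outside the domain, in the
#'   sector's native units. Default 0.
#'
#' @return A tibble of class `msp_sectors` with one row per sector.
#' @export
#' @examples
#' sector_spec(c("mussel", "halibut"), c("gain", "gain"),
#'             option = c("MUSSEL", NA), units = c("$/yr", "$/yr"))
sector_spec <- function(sector, klass, option = NA_character_, units = "",
                        extra_value = 0) {
  stopifnot(is.character(sector), length(sector) >= 1)
  if (anyDuplicated(sector)) {
    abort("duplicate sector names in sector specification")
  }
  klass <- match.arg(klass, c("gain", "impact"), several.ok = TRUE)
  out <- tibble::tibble(
    sector = sector,
    klass = vctrs_recycle(klass, length(sector), "klass"),
    option = vctrs_recycle(as.character(option), length(sector), "option"),
    units = vctrs_recycle(units, length(sector), "units"),
    extra_value = vctrs_recycle(extra_value, length(sector), "extra_value")
  )
  bad <- !is.na(out$option) & !out$option %in% msp_options()[-1]
  if (any(bad)) {
    abort(paste0("unknown development option for sector(s): ",
                 paste(out$sector[bad], collapse = ", ")))
  }
  if (any(!is.na(out$option) & out$klass != "gain")) {
    abort("only gain sectors may carry a development option")
  }
  if (any(out$extra_value < 0)) abort("extra_value must be non-negative")
  class(out) <- c("msp_sectors", class(out))
  out
}

vctrs_recycle <- function(x, n, what) {
  if (length(x) == n) return(x)
  if (length(x) == 1) return(rep(x, n))
  abort(sprintf("`%s` must have length 1 or %d", what, n))
}

#' Default seven-sector specification
#'
#' Three aquaculture gain sectors (mussel, finfish, kelp), the halibut
#' fishery gain sector, and three impact sectors (viewshed, benthic health,
#' disease risk).
#'
#' @param halibut_extra_value Fishery value held outside the developable
#'   domain, as a multiple of nothing by default (0 = no adjustment); supply
#'   a native-unit amount to bound the fishery's minimum outcome above zero.
#' @return An `msp_sectors` tibble with seven rows.
#' @export
default_sectors <- function(halibut_extra_value = 0) {
  sector_spec(
    sector = c("mussel", "finfish", "kelp", "halibut",
               "viewshed", "benthic", "disease"),
    klass = c("gain", "gain", "gain", "gain",
              "impact", "impact", "impact"),
    option = c("MUSSEL", "FINFISH", "KELP", NA, NA, NA, NA),
    units = c("$/yr", "$/yr", "$/yr", "$/yr",
              "person-views", "kg-C/m2/d", "centrality"),
    extra_value = c(0, 0, 0, halibut_extra_value, 0, 0, 0)
  )
}

#' Construct a planning domain
#'
#' A planning domain is the ordered universe of discrete planning units
#' (sites), each with planar coordinates and a developability flag per
#' aquaculture option. Row order defines the canonical site order used by
#' every tensor and plan; all outputs carry `site_id`, so order is advisory,
#' not semantic.
#'
#' @param sites A data frame with columns `site_id`, `x`, `y`,
#'   `dev_mussel`, `dev_finfish`, `dev_kelp`.
#' @return A validated tibble of class `msp_domain`.
#' @export
#' @examples
#' msp_domain(data.frame(site_id = c("s1", "s2"), x = c(0, 1), y = 0,
#'                       dev_mussel = TRUE, dev_finfish = c(TRUE, FALSE),
#'                       dev_kelp = TRUE))
msp_domain <- function(sites) {
  needed <- c("site_id", "x", "y", dev_columns())
  missing <- setdiff(needed, names(sites))
  if (length(missing)) {
    abort(paste0("site table is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  out <- tibble::as_tibble(sites)[needed]
  out$site_id <- as.character(out$site_id)
  if (anyDuplicated(out$site_id)) {
    dups <- unique(out$site_id[duplicated(out$site_id)])
    abort(paste0("duplicated site_id: ", paste(head(dups, 5), collapse = ", ")))
  }
  for (col in dev_columns()) {
    v <- out[[col]]
    if (is.numeric(v) && all(v %in% c(0, 1))) v <- as.logical(v)
    if (!is.logical(v) || anyNA(v)) {
      abort(paste0("column ", col, " must be boolean with no missing values"))
    }
    out[[col]] <- v
  }
  if (!is.numeric(out$x) || !is.numeric(out$y) || anyNA(out$x) || anyNA(out$y)) {
    abort("site coordinates x, y must be numeric and complete")
  }
  class(out) <- c("msp_domain", setdiff(class(out), "msp_domain"))
  out
}

# developability mask: sites x 4 options, NONE always permitted
dev_mask <- function(domain) {
  m <- cbind(TRUE, domain$dev_mussel, domain$dev_finfish, domain$dev_kelp)
  dimnames(m) <- list(domain$site_id, msp_options())
  m
}

#' Read a planning domain from CSV or GeoJSON
#'
#' CSV files must carry columns `site_id`, `x`, `y`, `dev_mussel`,
#' `dev_finfish`, `dev_kelp`; GeoJSON FeatureCollections must carry the same
#' fields as feature properties (except `x`, `y`, taken from Point geometry
#' coordinates when absent).
#'
#' @param path Path to a `.csv`, `.json` or `.geojson` file.
#' @return An `msp_domain` tibble in file row order.
#' @export
read_domain <- function(path) {
  if (grepl("\\.(geojson|json)$", path, ignore.case = TRUE)) {
    gj <- jsonlite::read_json(path, simplifyVector = FALSE)
    if (!identical(gj$type, "FeatureCollection")) {
      abort("GeoJSON domain must be a FeatureCollection")
    }
    rows <- purrr::map_dfr(gj$features, function(f) {
      props <- tibble::as_tibble(f$properties)
      if (!all(c("x", "y") %in% names(props)) &&
          identical(f$geometry$type, "Point")) {
        props$x <- f$geometry$coordinates[[1]]
        props$y <- f$geometry$coordinates[[2]]
      }
      props
    })
    return(msp_domain(rows))
  }
  msp_domain(readr::read_csv(path, show_col_types = FALSE))
}

#' Write a planning domain to CSV
#'
#' @param domain An `msp_domain`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_domain <- function(domain, path) {
  readr::write_csv(tibble::as_tibble(unclass_tbl(domain)), path)
  invisible(path)
}

unclass_tbl <- function(x) {
  class(x) <- c("tbl_df", "tbl", "data.frame")
  x
}

#' Construct a plan
#'
#' A plan assigns one development option to every site of a domain. The
#' chosen option must be developable at its site.
#'
#' @param domain An `msp_domain`.
#' @param option Character vector of option codes (recycled if length 1), or
#'   a named vector keyed by `site_id`.
#' @return A tibble of class `msp_plan` with columns `site_id`, `option`.
#' @export
msp_plan <- function(domain, option = "NONE") {
  if (!is.null(names(option))) {
    opt <- rep("NONE", nrow(domain))
    idx <- match(names(option), domain$site_id)
    if (anyNA(idx)) abort("plan names unknown site_id(s)")
    opt[idx] <- unname(option)
    option <- opt
  }
  option <- vctrs_recycle(as.character(option), nrow(domain), "option")
  bad <- !option %in% msp_options()
  if (any(bad)) {
    abort(paste0("unknown development option(s): ",
                 paste(unique(option[bad]), collapse = ", ")))
  }
  plan <- tibble::tibble(site_id = domain$site_id, option = option)
  mask <- dev_mask(domain)
  code <- match(option, msp_options())
  ok <- mask[cbind(seq_len(nrow(plan)), code)]
  if (!all(ok)) {
    abort(paste0("option not developable at site(s): ",
                 paste(head(plan$site_id[!ok], 5), collapse = ", ")))
  }
  class(plan) <- c("msp_plan", class(plan))
  attr(plan, "domain") <- domain
  plan
}

# integer codes 1..4 in canonical site order
plan_codes <- function(plan) {
  match(plan$option, msp_options())
}

#' Write / read a plan as CSV
#'
#' Round-trip safe: `read_plan(write_plan(p, f), domain)` equals `p`.
#'
#' @param plan An `msp_plan`.
#' @param path CSV path with columns `site_id`, `option`.
#' @return `write_plan` returns `path` invisibly; `read_plan` an `msp_plan`.
#' @export
write_plan <- function(plan, path) {
  readr::write_csv(tibble::tibble(site_id = plan$site_id, option = plan$option),
                   path)
  invisible(path)
}

#' @param domain The `msp_domain` the plan refers to; sites are realigned to
#'   its canonical order and validated against its developability masks.
#' @rdname write_plan
#' @export
read_plan <- function(path, domain) {
  tab <- readr::read_csv(path, col_types = readr::cols(
    site_id = readr::col_character(), option = readr::col_character()))
  if (nrow(tab) == 0 && nrow(domain) == 0) return(msp_plan(domain, character(0)))
  idx <- match(domain$site_id, tab$site_id)
  if (anyNA(idx)) {
    abort(paste0("plan file is missing site(s): ",
                 paste(head(domain$site_id[is.na(idx)], 5), collapse = ", ")))
  }
  msp_plan(domain, tab$option[idx])
}
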