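# Per-sector response construction: each sector's response R[n, i, p] to the
# four development options at every site, assembled into a response tensor.
#
# Response slices are tibbles with columns
#   site_id, value_none, value_mussel, value_finfish, value_kelp
# in the sector's native units.

slice_cols <- function() {
  c("value_none", "value_mussel", "value_finfish", "value_kelp")
}

check_surface <- function(x, domain, what, allow_negative = FALSE) {
  if (length(x) != nrow(domain) || !is.numeric(x) || any(!is.finite(x))) {
    abort(sprintf("`%s` must be a finite numeric vector with one value per site",
                  what))
  }
  if (!allow_negative && any(x < 0)) {
    abort(sprintf("`%s` must be non-negative", what))
  }
  x
}

new_slice <- function(domain, none = 0, mussel = 0, finfish = 0, kelp = 0) {
  tibble::tibble(
    site_id = domain$site_id,
    value_none = rep_len(none, nrow(domain)),
    value_mussel = rep_len(mussel, nrow(domain)),
    value_finfish = rep_len(finfish, nrow(domain)),
    value_kelp = rep_len(kelp, nrow(domain))
  )
}

#' Aquaculture sector response
#'
#' An aquaculture sector earns its annuity only when its own farm type is
#' developed at a site; any other option (including no development) yields
#' zero. Negative annuities are retained here and flag the (site, option)
#' pair economically undevelopable during tensor assembly.
#'
#' @param domain An `msp_domain`.
#' @param annuity Numeric annuity per site ($/yr), in domain order.
#' @param option The sector's farm type: `"MUSSEL"`, `"FINFISH"` or `"KELP"`.
#' @return A response slice tibble.
#' @export
aquaculture_response <- function(domain, annuity, option) {
  option <- match.arg(option, msp_options()[-1])
  check_surface(annuity, domain, "annuity", allow_negative = TRUE)
  args <- list(domain = domain)
  args[[tolower(option)]] <- annuity
  do.call(new_slice, args)
}

#' Wild-capture fishery response
#'
#' The fishery keeps its per-site annuity only where no aquaculture is
#' developed; any development excludes the fishery from the site, zeroing
#' its response there.
#'
#' @param domain An `msp_domain`.
#' @param annuity Non-negative fishery annuity per site, in domain order.
#' @return A response slice tibble.
#' @export
halibut_response <- function(domain, annuity) {
  check_surface(annuity, domain, "annuity")
  new_slice(domain, none = annuity)
}

#' Viewshed impact response
#'
#' No impact without development; partial impact (surface structures visible
#' within a short radius) for mussel or kelp longlines; full impact for
#' finfish pens, whose structures are visible from farther away and hence by
#' at least as many people.
#'
#' @param domain An `msp_domain`.
#' @param views_partial Person-views impacted by mussel/kelp structures.
#' @param views_full Person-views impacted by finfish structures; must be
#'   at least `views_partial` sitewise.
#' @return A response slice tibble.
#' @export
viewshed_response <- function(domain, views_partial, views_full) {
  check_surface(views_partial, domain, "views_partial")
  check_surface(views_full, domain, "views_full")
  if (any(views_partial > views_full)) {
    abort("views_partial must not exceed views_full at any site")
  }
  new_slice(domain, mussel = views_partial, kelp = views_partial,
            finfish = views_full)
}

#' Benthic organic-loading response
#'
#' Total organic carbon flux to the seafloor occurs only under finfish pens;
#' mussel and kelp culture are assumed to have no benthic impact.
#'
#' @param domain An `msp_domain`.
#' @param toc_flux Non-negative TOC flux per site (e.g. kg-C/m2/d).
#' @return A response slice tibble.
#' @export
benthic_response <- function(domain, toc_flux) {
  check_surface(toc_flux, domain, "toc_flux")
  new_slice(domain, finfish = toc_flux)
}

#' Eigenvector centrality of a connectivity matrix
#'
#' Leading right eigenvector of a non-negative site-to-site connectivity
#' matrix, computed by power iteration and normalized to unit sum. Centrality
#' is invariant to any positive rescaling of the matrix.
#'
#' @param C Square non-negative numeric matrix aligned to the domain (need
#'   not be symmetric: directional transport is respected).
#' @param row_standardize If `TRUE`, rows are scaled to unit sum before the
#'   iteration (treats connectivity as a transition matrix). Default `FALSE`.
#' @param tol Convergence tolerance on the iterate (default 1e-10).
#' @param max_iter Iteration cap (default 10000).
#' @return Numeric centrality per site, non-negative, summing to 1.
#' @export
#' @examples
#' eigen_centrality(matrix(c(0, 1, 1, 0), 2))   # 0.5, 0.5 by symmetry
eigen_centrality <- function(C, row_standardize = FALSE, tol = 1e-10,
                             max_iter = 10000) {
  if (!is.matrix(C) || nrow(C) != ncol(C)) abort("`C` must be a square matrix")
  if (anyNA(C) || any(!is.finite(C))) abort("`C` must be finite with no NA")
  if (any(C < 0)) abort("`C` must be non-negative")
  if (all(C == 0)) abort("`C` has no nonzero entries; centrality is undefined")
  if (row_standardize) {
    rs <- rowSums(C)
    C[rs > 0, ] <- C[rs > 0, , drop = FALSE] / rs[rs > 0]
  }
  n <- nrow(C)
  # spectral shift: C + cI has the same eigenvectors but strictly dominant
  # leading eigenvalue, so the iteration converges even on bipartite graphs
  shift <- 0.5 * max(rowSums(C))
  v <- rep(1 / n, n)
  for (k in seq_len(max_iter)) {
    w <- as.numeric(C %*% v) + shift * v
    s <- sum(w)
    if (s <= 0) abort("power iteration collapsed to the zero vector")
    w <- w / s
    if (max(abs(w - v)) < tol) {
      return(w)
    }
    v <- w
  }
  abort(sprintf("power iteration did not converge in %d iterations", max_iter))
}

#' Disease-connectivity response
#'
#' Relative risk of viral spread among finfish farms, taken as the
#' eigenvector centrality of the hydrodynamic connectivity matrix at each
#' site. The response is nonzero only for the finfish option: mussel and
#' kelp farms are assumed to pose no disease risk. A plan's total disease
#' response is then the sum of the centralities of its developed finfish
#' sites.
#'
#' @param domain An `msp_domain`.
#' @param C Site-to-site connectivity matrix aligned to the domain (rows =
#'   source, columns = destination).
#' @inheritParams eigen_centrality
#' @return A response slice tibble with `value_finfish` = centrality.
#' @export
disease_response <- function(domain, C, row_standardize = FALSE,
                             tol = 1e-10, max_iter = 10000) {
  if (nrow(C) != nrow(domain)) {
    abort("connectivity matrix is not aligned to the domain")
  }
  cen <- eigen_centrality(C, row_standardize, tol, max_iter)
  new_slice(domain, finfish = cen)
}

#' Assemble a response tensor
#'
#' Combines per-sector response slices into the dense response tensor
#' `R[n, i, p]` used by the tradeoff engine. Assembly (i) realigns every
#' slice to canonical site order, (ii) marks aquaculture (site, option) pairs
#' with negative annuity as undevelopable, (iii) overwrites responses at
#' undevelopable options with the site's no-development response (so masked
#' entries never influence maxima or plans), and (iv) validates the sector
#' invariants: finite values, zero no-development response for impact
#' sectors, non-negativity after masking.
#'
#' @param domain An `msp_domain`.
#' @param slices Named list of response slice tibbles, one per sector, names
#'   matching `sectors$sector`.
#' @param sectors An `msp_sectors` specification (default [default_sectors()]).
#' @return A long tibble of class `msp_responses` with columns `sector`,
#'   `site_id`, `option`, `response`, carrying the (possibly mask-updated)
#'   domain and sector table as attributes.
#' @export
response_tensor <- function(domain, slices, sectors = default_sectors()) {
  if (!setequal(names(slices), sectors$sector)) {
    abort(paste0("slices must be named exactly by the sectors: ",
                 paste(sectors$sector, collapse = ", ")))
  }
  S <- nrow(domain)
  mats <- lapply(sectors$sector, function(nm) {
    sl <- tibble::as_tibble(slices[[nm]])
    missing_cols <- setdiff(c("site_id", slice_cols()), names(sl))
    if (length(missing_cols)) {
      abort(sprintf("slice '%s' is missing column(s): %s", nm,
                    paste(missing_cols, collapse = ", ")))
    }
    idx <- match(domain$site_id, as.character(sl$site_id))
    if (anyNA(idx)) {
      abort(sprintf("slice '%s' is missing site(s): %s", nm,
                    paste(head(domain$site_id[is.na(idx)], 5), collapse = ", ")))
    }
    m <- as.matrix(sl[idx, slice_cols()])
    if (anyNA(m) || any(!is.finite(m))) {
      abort(sprintf("slice '%s' contains non-finite responses", nm))
    }
    dimnames(m) <- list(domain$site_id, msp_options())
    m
  })
  names(mats) <- sectors$sector

  # negative annuity at a sector's own option => economically undevelopable
  for (j in which(!is.na(sectors$option))) {
    nm <- sectors$sector[j]
    opt <- sectors$option[j]
    neg <- mats[[nm]][, opt] < 0
    if (any(neg)) {
      domain[[paste0("dev_", tolower(opt))]][neg] <- FALSE
    }
  }
  mask <- dev_mask(domain)

  # masked options carry the no-development response
  for (nm in sectors$sector) {
    m <- mats[[nm]]
    for (p in 2:4) {
      off <- !mask[, p]
      if (any(off)) m[off, p] <- m[off, 1]
    }
    mats[[nm]] <- m
  }

  for (j in seq_len(nrow(sectors))) {
    nm <- sectors$sector[j]
    if (sectors$klass[j] == "impact" && any(mats[[nm]][, 1] != 0)) {
      abort(sprintf("impact sector '%s' must have zero response without development",
                    nm))
    }
    if (any(mats[[nm]] < 0)) {
      abort(sprintf("sector '%s' has negative responses after masking", nm))
    }
  }

  long <- purrr::map_dfr(sectors$sector, function(nm) {
    tibble::tibble(
      sector = nm,
      site_id = rep(domain$site_id, times = 4),
      option = rep(msp_options(), each = S),
      response = as.vector(mats[[nm]])
    )
  })
  structure(long,
            class = c("msp_responses", class(long)),
            domain = domain, sectors = sectors)
}

# sectors x sites x options array from a long tensor tibble
tensor_array <- function(x, value_col = "response") {
  domain <- attr(x, "domain")
  sectors <- attr(x, "sectors")
  arr <- array(NA_real_,
               dim = c(nrow(sectors), nrow(domain), 4),
               dimnames = list(sectors$sector, domain$site_id, msp_options()))
  arr[cbind(match(x$sector, sectors$sector),
            match(x$site_id, domain$site_id),
            match(x$option, msp_options()))] <- x[[value_col]]
  if (anyNA(arr)) abort("tensor is incomplete: missing (sector, site, option) entries")
  arr
}

#' Maximum response of a sector
#'
#' The domain-wide maximum response of a sector over all sites and options,
#' the reference from which impact-sector values are reflected.
#'
#' @param responses An `msp_responses` tensor.
#' @param sector Sector name.
#' @return A single number.
#' @export
rbar <- function(responses, sector) {
  if (!sector %in% attr(responses, "sectors")$sector) {
    abort(paste0("unknown sector: ", sector))
  }
  max(responses$response[responses$sector == sector])
}

#' Read per-sector response files into a tensor
#'
#' Each sector is supplied as a CSV with columns `site_id`, `value_none`,
#' `value_mussel`, `value_finfish`, `value_kelp`; the disease sector may
#' instead be derived from a dense connectivity CSV (see
#' [read_connectivity()]), in which case pass its path via `connectivity`
#' and omit it from `files`.
#'
#' @param domain An `msp_domain`.
#' @param files Named list of CSV paths keyed by sector name.
#' @param sectors An `msp_sectors` specification.
#' @param connectivity Optional connectivity CSV path for the `disease`
#'   sector.
#' @return An `msp_responses` tensor.
#' @export
read_responses <- function(domain, files, sectors = default_sectors(),
                           connectivity = NULL) {
  slices <- lapply(files, function(p) readr::read_csv(p, show_col_types = FALSE))
  if (!is.null(connectivity)) {
    C <- read_connectivity(connectivity, domain)
    slices$disease <- disease_response(domain, C)
  }
  response_tensor(domain, slices, sectors)
}

#' Read / write a dense connectivity matrix CSV
#'
#' Format: a header row of destination `site_id`s preceded by a `site_id`
#' column of sources; entries are non-negative relative transport strengths.
#'
#' @param path CSV path.
#' @param domain An `msp_domain` to align against.
#' @return A sites-by-sites numeric matrix in canonical site order.
#' @export
read_connectivity <- function(path, domain) {
  tab <- readr::read_csv(path, show_col_types = FALSE)
  ids <- as.character(tab[[1]])
  M <- as.matrix(tab[, -1])
  colnames(M) <- names(tab)[-1]
  ri <- match(domain$site_id, ids)
  ci <- match(domain$site_id, colnames(M))
  if (anyNA(ri) || anyNA(ci)) {
    miss <- domain$site_id[is.na(ri) | is.na(ci)]
    abort(paste0("connectivity matrix is missing site(s): ",
                 paste(head(miss, 5), collapse = ", ")))
  }
  M <- M[ri, ci, drop = FALSE]
  storage.mode(M) <- "double"
  dimnames(M) <- list(domain$site_id, domain$site_id)
  M
}

#' @param C Matrix to write (sources in rows, destinations in columns).
#' @rdname read_connectivity
#' @export
write_connectivity <- function(C, path) {
  out <- tibble::as_tibble(C, .name_repair = "minimal")
  names(out) <- colnames(C)
  out <- tibble::add_column(out, site_id = rownames(C), .before = 1)
  readr::write_csv(out, path)
  invisible(path)
}
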