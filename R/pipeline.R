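# Config-driven pipeline: one entry point wiring the stages together, with
# a reproducibility manifest.

run_config_keys <- function() {
  c("seed", "preset", "inputs", "weights", "max_entries", "filter",
    "cluster", "conventional", "stages", "out_dir")
}

read_run_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) abort(paste0("config file not found: ", config))
    config <- if (grepl("\\.json$", config, ignore.case = TRUE)) {
      jsonlite::read_json(config, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(config)
    }
  }
  if (!is.list(config)) abort("config must be a file path or a list")
  unknown <- setdiff(names(config), run_config_keys())
  if (length(unknown)) {
    abort(paste0("unknown config key(s): ", paste(unknown, collapse = ", ")))
  }
  defaults <- list(
    seed = 1L,
    preset = "conflict",
    inputs = NULL,
    weights = seq(0, 1, 0.2),
    max_entries = 3e5,
    filter = list(min_aqua = 5, max_impact = 5),
    cluster = list(k = NULL, encoding = "one_hot", trymax = 30),
    conventional = list(modes = c("unconstrained", "constrained"),
                        level = "footprint"),
    stages = c("simulate", "frontier", "conventional", "filter",
               "hotspots", "seeds"),
    out_dir = "msp-run"
  )
  for (nm in names(defaults)) {
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  }
  config
}

stage <- function(name, code) {
  tryCatch(force(code), error = function(e) {
    abort(sprintf("stage '%s' failed: %s", name, conditionMessage(e)))
  })
}

#' Run the full planning pipeline from a config
#'
#' Executes the requested stages - synthesize or load inputs, enumerate the
#' efficiency frontier, simulate conventional planning and the value of
#' coordinated planning, filter plans, map hotspots, select seed plans -
#' writing plain CSV outputs and a JSON manifest recording the config hash,
#' seed, package version and output checksums. Identical config and seed
#' give byte-identical outputs.
#'
#' @param config Path to a YAML/JSON config file, or an equivalent named
#'   list. Recognised keys: `seed`, `preset` (fixture name), `inputs`
#'   (paths: `sites`, `responses` named per sector, `connectivity`,
#'   optional `halibut_extra_value`), `weights`, `max_entries`, `filter`
#'   (`min_aqua`, `max_impact`), `cluster` (`k`, `encoding`, `trymax`),
#'   `conventional` (`modes`, `level`), `stages`, `out_dir`. Unknown keys
#'   are rejected before any computation.
#' @param out_dir Overrides the config's output directory.
#' @return The manifest, invisibly (also written to `manifest.json`).
#' @export
msp_run <- function(config, out_dir = NULL) {
  cfg <- read_run_config(config)
  if (!is.null(out_dir)) cfg$out_dir <- out_dir
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  outputs <- character(0)
  emit <- function(tbl, name) {
    path <- file.path(cfg$out_dir, name)
    readr::write_csv(tibble::as_tibble(tbl), path)
    outputs <<- c(outputs, path)
    path
  }

  if (!is.null(cfg$inputs)) {
    scaled <- stage("load", {
      inp <- cfg$inputs
      if (!file.exists(inp$sites %||% "")) {
        abort(paste0("input file not found: ", inp$sites %||% "<missing sites>"))
      }
      for (f in unlist(inp$responses)) {
        if (!file.exists(f)) abort(paste0("input file not found: ", f))
      }
      domain <- read_domain(inp$sites)
      sectors <- default_sectors(inp$halibut_extra_value %||% 0)
      responses <- read_responses(domain, inp$responses, sectors,
                                  connectivity = inp$connectivity)
      scale_values(build_values(responses))
    })
  } else {
    scaled <- stage("simulate", {
      sea <- make_fixture(cfg$preset, seed = cfg$seed)
      if ("simulate" %in% cfg$stages) write_seascape(sea, cfg$out_dir)
      scale_values(build_values(sea$responses))
    })
  }

  frontier <- NULL
  if (any(c("frontier", "conventional", "filter", "hotspots", "seeds") %in%
          cfg$stages)) {
    frontier <- stage("frontier", {
      fr <- enumerate_frontier(scaled, weights = cfg$weights,
                               max_entries = cfg$max_entries)
      if ("frontier" %in% cfg$stages) emit(fr$entries, "frontier_entries.csv")
      fr
    })
  }

  if ("conventional" %in% cfg$stages) {
    stage("conventional", {
      for (mode in cfg$conventional$modes) {
        traj <- conventional_plan(scaled, mode = mode)
        emit(unclass_tbl(traj), paste0("conventional_", mode, ".csv"))
        vom <- value_of_msp(frontier, traj, level = cfg$conventional$level)
        emit(vom, paste0("value_of_msp_", mode, ".csv"))
      }
    })
  }

  plan_set <- NULL
  if (any(c("filter", "seeds") %in% cfg$stages)) {
    plan_set <- stage("filter", {
      ps <- filter_plans(frontier, min_aqua = cfg$filter$min_aqua,
                         max_impact = cfg$filter$max_impact)
      if ("filter" %in% cfg$stages) {
        emit(ps$entries, "filtered_entries.csv")
        if (nrow(ps$entries)) {
          emit(hotspot_map(ps), "filtered_hotspots.csv")
        }
      }
      ps
    })
  }

  if ("hotspots" %in% cfg$stages) {
    stage("hotspots", emit(hotspot_map(frontier), "hotspots.csv"))
  }

  if ("seeds" %in% cfg$stages) {
    stage("seeds", {
      sp <- seed_plans(plan_set, k = cfg$cluster$k,
                       encoding = cfg$cluster$encoding,
                       seed = cfg$seed, trymax = cfg$cluster$trymax)
      emit(sp$clusters, "seed_clusters.csv")
      emit(sp$representatives, "seed_representatives.csv")
      domain <- attr(scaled, "domain")
      for (r in seq_len(nrow(sp$representatives))) {
        plan <- msp_plan(domain,
                         msp_options()[sp$plans[sp$representatives$plan[r], ]])
        emit(tibble::tibble(site_id = plan$site_id, option = plan$option),
             sprintf("seed_plan_%02d.csv", sp$representatives$cluster[r]))
      }
    })
  }

  manifest <- list(
    package = "mspfrontier",
    version = as.character(utils::packageVersion("mspfrontier")),
    seed = cfg$seed,
    config = cfg[setdiff(names(cfg), "out_dir")],
    config_hash = config_hash(cfg[setdiff(names(cfg), "out_dir")]),
    outputs = as.list(setNames(unname(tools::md5sum(outputs)),
                               basename(outputs)))
  )
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  invisible(manifest)
}

config_hash <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA,
                              null = "null"), tmp)
  unname(tools::md5sum(tmp))
}
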