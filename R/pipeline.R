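#' Pipeline run configuration
#'
#' A single flat, human-editable configuration for an end-to-end run.
#' Stages: obtain a cohort (simulate, or load from CSVs), optionally expand
#' it to streamline bundles and rebuild the connectomes from them (the
#' tractography-equivalence path), form the group edge-presence mask, run
#' the network-based statistic against apathy, compute sub-network metrics,
#' and produce the marginal/partial correlation specificity table.
#'
#' One master seed deterministically spawns per-stage child seeds (cohort
#' simulation, NBS permutations) via [spawn_seeds()], so any stage can be
#' re-run in isolation with the stream it had inside the full run.
#'
#' @param seed master seed.
#' @param out_dir output directory for all artifacts.
#' @param cohort list of arguments for [cohort_spec()] (its `rng_seed` is
#'   overridden by the spawned child seed), or `NULL` when loading.
#' @param cohort_dir directory of a saved cohort to load instead of
#'   simulating (see [load_cohort()]).
#' @param rebuild_from_streamlines logical: if `TRUE`, connectomes are
#'   re-derived by expanding each subject's connectome to streamline
#'   bundles and rebuilding with [build_connectome()] (exercises the
#'   edge-weight formula end-to-end).
#' @param edge_presence_min minimum subjects for the group mask
#'   (default 30).
#' @param nbs list of arguments for [nbs_config()] (its `rng_seed` is
#'   overridden by the spawned child seed).
#' @param subnetworks named list of [subnetwork()] definitions or a path to
#'   a YAML file for [read_subnetworks()]; default the built-in three.
#' @param save_cohort_csv logical: also write the cohort CSVs under
#'   `out_dir/cohort/`.
#' @return object of class `run_config`.
#' @export
run_config <- function(seed = 1L, out_dir = tempfile("apathynet_run_"),
                       cohort = list(), cohort_dir = NULL,
                       rebuild_from_streamlines = FALSE,
                       edge_presence_min = 30L, nbs = list(),
                       subnetworks = NULL, save_cohort_csv = FALSE) {
  structure(list(seed = as.integer(seed), out_dir = out_dir,
                 cohort = cohort, cohort_dir = cohort_dir,
                 rebuild_from_streamlines = isTRUE(rebuild_from_streamlines),
                 edge_presence_min = as.integer(edge_presence_min),
                 nbs = nbs, subnetworks = subnetworks,
                 save_cohort_csv = isTRUE(save_cohort_csv)),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Keys mirror the arguments of [run_config()]; nested `cohort:` and `nbs:`
#' mappings mirror [cohort_spec()] and [nbs_config()] arguments.
#'
#' @param path YAML file.
#' @param overrides named list applied over the file's values (e.g. from
#'   command-line flags).
#' @return a `run_config`.
#' @export
read_run_config <- function(path, overrides = list()) {
  vals <- yaml::read_yaml(path)
  for (nm in names(overrides)) vals[[nm]] <- overrides[[nm]]
  do.call(run_config, vals)
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass(config)[setdiff(names(config), "out_dir")],
                       tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

#' Run the full pipeline
#'
#' Executes cohort acquisition, optional streamline round-trip, group edge
#' mask, NBS, sub-network metrics and the specificity table, writing every
#' intermediate artifact plus a machine-readable `report.json` (components,
#' specificity table, config echo, config hash, seed, package version) and
#' a `MANIFEST.json` listing each artifact with its md5 and the config hash
#' that produced it. Any stage failure aborts with the stage name and
#' cause. Given the same configuration and seed, outputs are
#' byte-reproducible.
#'
#' @param config a [run_config()].
#' @return invisibly, the report as a list.
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  seeds <- spawn_seeds(config$seed, 2)
  hash <- config_hash(config)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop_stage(name, conditionMessage(e))
    })
  }

  cohort <- stage("cohort", {
    if (!is.null(config$cohort_dir)) {
      load_cohort(config$cohort_dir)
    } else {
      args <- config$cohort
      args$rng_seed <- seeds[1]
      simulate_cohort(do.call(cohort_spec, args))
    }
  })

  if (config$rebuild_from_streamlines) {
    cohort <- stage("streamline-roundtrip", {
      sls <- cohort_to_streamlines(cohort)
      n <- dim(cohort$weights)[1]
      for (s in seq_along(sls)) {
        cohort$weights[, , s] <- build_connectome(sls[[s]], n_nodes = n,
                                                  node_names = cohort$node_labels)
      }
      cohort
    })
  }

  if (config$save_cohort_csv) {
    stage("cohort-io", save_cohort(cohort, file.path(config$out_dir, "cohort")))
  }

  mask <- stage("edge-mask",
                group_edge_mask(cohort, config$edge_presence_min))

  nbs_res <- stage("nbs", {
    args <- config$nbs
    args$rng_seed <- seeds[2]
    nbs(cohort, mask, cohort$table$apathy, do.call(nbs_config, args))
  })

  subnets <- stage("subnetworks", {
    if (is.null(config$subnetworks)) builtin_subnetworks()
    else if (is.character(config$subnetworks)) read_subnetworks(config$subnetworks)
    else config$subnetworks
  })

  metrics <- stage("metrics", network_metrics(cohort, subnets))

  covars <- intersect(c("age", "hypertension", "hypercholesterolemia",
                        "diabetes", "smoking"), colnames(cohort$table))
  # a covariate constant across the cohort carries no information and would
  # make the control design singular; drop it
  covars <- covars[vapply(covars, function(v) {
    stats::sd(cohort$table[[v]]) > 0
  }, logical(1))]
  spec_tab <- stage("statistics", {
    specificity_table(metrics, cohort$table$apathy,
                      covariates = cohort$table[, covars, drop = FALSE])
  })

  out <- function(f) file.path(config$out_dir, f)
  stage("write-artifacts", {
    write_metrics_csv(metrics, out("metrics.csv"))
    utils::write.csv(spec_tab, out("specificity.csv"), row.names = FALSE)
    write_nbs_report(nbs_res, out("nbs_report.json"), out("t_matrix.csv"),
                     node_names = cohort$node_labels)
  })

  report <- list(
    config = unclass(config)[setdiff(names(config), "out_dir")],
    config_hash = hash, seed = config$seed,
    package_version = as.character(utils::packageVersion("apathynet")),
    n_subjects = nrow(cohort$table),
    apathy_mean = mean(cohort$table$apathy),
    apathy_sd = stats::sd(cohort$table$apathy),
    components = lapply(names(nbs_res$components), function(tl) {
      lapply(nbs_res$components[[tl]], function(cc) {
        list(tail = tl, extent = cc$extent, nodes_count = length(cc$nodes),
             nodes = cohort$node_labels[cc$nodes], p_fwer = cc$p_fwer,
             significant = cc$significant)
      })
    }),
    specificity = spec_tab)
  jsonlite::write_json(report, out("report.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  artifacts <- setdiff(list.files(config$out_dir, recursive = TRUE),
                       "MANIFEST.json")
  manifest <- list(config_hash = hash,
                   files = lapply(artifacts, function(f) {
                     list(path = f,
                          md5 = unname(tools::md5sum(file.path(config$out_dir, f))))
                   }))
  jsonlite::write_json(manifest, out("MANIFEST.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(report)
}
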