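#' Specification of a synthetic SVD cohort
#'
#' Describes the statistical structure of a simulated small-vessel-disease
#' cohort: 90-node symmetric non-negative connectomes with
#' distance-dependent baseline weights shared across subjects, per-subject
#' multiplicative log-normal noise, an integer apathy score in `[0, 6]`
#' from a discretized truncated normal, demographic covariates, and an
#' optional planted effect: every edge inside `target_subnetwork` is scaled
#' by `max(0, 1 - effect_beta * apathy)`, so higher apathy means weaker
#' reward-circuit connectivity.
#'
#' The noise has three multiplicative log-normal components, all unit-mean:
#' a global per-subject factor (`subject_cv`), a per-subject factor for
#' each anatomical system in `systems` applied to edges lying wholly
#' inside that system (`system_cv`), and independent per-edge noise
#' (`noise_cv`). The system factors model per-subject variation in the
#' integrity of the fiber systems supporting each circuit (e.g. cingulum
#' and uncinate fasciculus for the reward network): such variation does not
#' average out in sub-network efficiency, yet differs between circuits, so
#' sub-network metrics are realistically variable without all being slaved
#' to one global factor.
#'
#' Defaults follow the cohort the pipeline is designed around: n = 114
#' subjects, apathy mean 2.9 and SD 1.7, age 70.0 (9.6), and vascular risk
#' factor prevalences of 88.6% (hypertension), 91.2%
#' (hypercholesterolemia), 19.3% (diabetes) and 52.6% (smoking).
#'
#' @param n_subjects number of subjects (default 114).
#' @param n_nodes connectome dimension (default 90, the AAL cerebrum).
#' @param apathy_mean,apathy_sd target moments of the integer apathy score
#'   (defaults 2.9 and 1.7). The latent normal is moment-matched so the
#'   discretized, truncated score attains these moments.
#' @param effect_beta fractional weight reduction per apathy point on
#'   target-sub-network edges (>= 0; 0 plants no effect). See
#'   [calibrated_effect_beta()] for the value calibrated to give a
#'   population reward-efficiency/apathy correlation near -0.35.
#' @param noise_cv coefficient of variation of the per-edge multiplicative
#'   log-normal noise (default 0.05).
#' @param subject_cv coefficient of variation of the per-subject global
#'   log-normal factor (default 0.02).
#' @param system_cv coefficient of variation of the per-subject, per-system
#'   log-normal factors (default 0.15).
#' @param systems list of integer node-id vectors defining the anatomical
#'   systems that receive shared factors; default the node sets of the
#'   three built-in sub-networks.
#' @param edge_density expected fraction of nonzero edges (default 0.25).
#' @param target_subnetwork integer node ids (1-based) of the sub-network
#'   carrying the planted effect; default the built-in reward network.
#' @param age_mean,age_sd age distribution (defaults 70.0, 9.6).
#' @param risk_prevalence named numeric vector of Bernoulli prevalences for
#'   the four binary vascular risk factors.
#' @param age_apathy_r optional confounding knob: correlation between age
#'   and the apathy score (default 0, covariates independent of apathy so
#'   covariate adjustment is testable under a known null).
#' @param rng_seed integer seed; the whole cohort is deterministic given it.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 114L, n_nodes = 90L,
                        apathy_mean = 2.9, apathy_sd = 1.7,
                        effect_beta = 0, noise_cv = 0.05, subject_cv = 0.02,
                        system_cv = 0.15,
                        systems = lapply(builtin_subnetworks(), `[[`, "node_ids"),
                        edge_density = 0.25,
                        target_subnetwork = builtin_subnetworks()$reward$node_ids,
                        age_mean = 70.0, age_sd = 9.6,
                        risk_prevalence = c(hypertension = 0.886,
                                            hypercholesterolemia = 0.912,
                                            diabetes = 0.193,
                                            smoking = 0.526),
                        age_apathy_r = 0, rng_seed = 1L) {
  stopifnot(n_subjects >= 1, n_nodes >= 2, apathy_sd > 0,
            effect_beta >= 0, noise_cv >= 0, subject_cv >= 0,
            system_cv >= 0, is.list(systems),
            edge_density > 0, edge_density <= 1,
            abs(age_apathy_r) < 1)
  target_subnetwork <- as.integer(target_subnetwork)
  if (any(target_subnetwork < 1) || any(target_subnetwork > n_nodes)) {
    stop("target_subnetwork ids outside 1..", n_nodes)
  }
  systems <- lapply(systems, as.integer)
  if (any(unlist(systems) < 1) || any(unlist(systems) > n_nodes)) {
    stop("system node ids outside 1..", n_nodes)
  }
  structure(list(n_subjects = as.integer(n_subjects),
                 n_nodes = as.integer(n_nodes),
                 apathy_mean = apathy_mean, apathy_sd = apathy_sd,
                 effect_beta = effect_beta, noise_cv = noise_cv,
                 subject_cv = subject_cv, system_cv = system_cv,
                 systems = systems, edge_density = edge_density,
                 target_subnetwork = target_subnetwork,
                 age_mean = age_mean, age_sd = age_sd,
                 risk_prevalence = risk_prevalence,
                 age_apathy_r = age_apathy_r,
                 rng_seed = as.integer(rng_seed)),
            class = "cohort_spec")
}

#' Calibrated planted-effect slope
#'
#' The `effect_beta` at which, under all other [cohort_spec()] defaults, the
#' population correlation between reward-network efficiency and the apathy
#' score is approximately -0.35. Determined once by a pilot sweep over beta
#' at large n (see the methods vignette); fixed thereafter.
#'
#' @return a single number.
#' @export
calibrated_effect_beta <- function() 0.030

# probabilities of scores 0..6 under a discretized normal truncated to [0,6],
# with the latent (mu, sigma) moment-matched to the requested mean/sd
apathy_score_probs <- function(mean, sd) {
  k <- 0:6
  moments <- function(th) {
    p <- stats::pnorm(k + 0.5, th[1], th[2]) - stats::pnorm(k - 0.5, th[1], th[2])
    p <- p / sum(p)
    m <- sum(k * p)
    c(m, sqrt(sum((k - m)^2 * p)), p)
  }
  fit <- stats::optim(c(mean, sd), function(th) {
    if (th[2] <= 0) return(1e6)
    sum((moments(th)[1:2] - c(mean, sd))^2)
  })
  moments(fit$par)[-(1:2)]
}

#' Simulate a synthetic cohort of connectomes with apathy scores
#'
#' Generates `n_subjects` symmetric non-negative connectomes sharing a base
#' network (exponential distance decay on uniformly random node coordinates
#' in a 120 mm cube, sparsified to `edge_density` by keeping the strongest
#' pairs), perturbed per subject by multiplicative log-normal noise, plus an
#' integer apathy score, age and four binary vascular risk factors. If
#' `effect_beta > 0`, every edge whose two endpoints both lie in
#' `target_subnetwork` is additionally scaled by
#' `max(0, 1 - effect_beta * apathy)`.
#'
#' @param spec a [cohort_spec()].
#' @return object of class `svd_cohort`: list with `weights` (an
#'   `n_nodes x n_nodes x n_subjects` array), `table` (data.frame of
#'   subject_id, apathy, age and risk factors), `node_coords` (mm),
#'   `base_weights`, and the originating `spec`.
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_nodes
  S <- spec$n_subjects
  labels <- if (n == 90L) aal90_labels() else sprintf("Node_%02d", seq_len(n))

  with_seed(spec$rng_seed, {
    # base connectome: distance decay, sparsified to the strongest pairs
    coords <- matrix(stats::runif(n * 3, 0, 120), n, 3)
    ut <- upper_pairs(n)
    d <- sqrt(rowSums((coords[ut[, 1], ] - coords[ut[, 2], ])^2))
    w0 <- exp(-d / 30)
    n_keep <- max(1L, round(spec$edge_density * nrow(ut)))
    kept <- order(w0, decreasing = TRUE)[seq_len(n_keep)]
    w0_kept <- w0[kept] / stats::median(w0[kept])  # median kept weight = 1

    # apathy: discretized truncated normal, moment-matched
    probs <- apathy_score_probs(spec$apathy_mean, spec$apathy_sd)
    apathy <- sample(0:6, S, replace = TRUE, prob = probs)

    # noise components (log-normal, unit mean): global per-subject factor,
    # per-subject per-system factors on within-system edges, per-edge noise
    sdlog_s <- sqrt(log(1 + spec$subject_cv^2))
    sdlog_g <- sqrt(log(1 + spec$system_cv^2))
    sdlog_e <- sqrt(log(1 + spec$noise_cv^2))
    n_sys <- length(spec$systems)
    eta <- stats::rnorm(S, -sdlog_s^2 / 2, sdlog_s)
    psi <- matrix(stats::rnorm(n_sys * S, -sdlog_g^2 / 2, sdlog_g), n_sys, S)
    eps <- matrix(stats::rnorm(n_keep * S, -sdlog_e^2 / 2, sdlog_e), n_keep, S)

    kept_pairs <- ut[kept, , drop = FALSE]
    in_system <- vapply(spec$systems, function(ids) {
      kept_pairs[, 1] %in% ids & kept_pairs[, 2] %in% ids
    }, logical(n_keep))
    in_target <- kept_pairs[, 1] %in% spec$target_subnetwork &
      kept_pairs[, 2] %in% spec$target_subnetwork

    weights <- array(0, c(n, n, S), dimnames = list(labels, labels, NULL))
    for (s in seq_len(S)) {
      lognoise <- eta[s] + eps[, s]
      if (n_sys > 0) {
        lognoise <- lognoise +
          as.numeric(in_system %*% psi[, s, drop = FALSE])
      }
      w_s <- w0_kept * exp(lognoise)
      if (spec$effect_beta > 0) {
        w_s[in_target] <- w_s[in_target] *
          max(0, 1 - spec$effect_beta * apathy[s])
      }
      weights[, , s] <- sym_from_upper_kept(w_s, kept_pairs, n)
    }

    # covariates; age optionally coupled to apathy via a Gaussian copula
    z_age <- stats::rnorm(S)
    if (spec$age_apathy_r != 0) {
      z_ap <- as.numeric(scale(apathy))
      z_age <- spec$age_apathy_r * z_ap +
        sqrt(1 - spec$age_apathy_r^2) * z_age
    }
    age <- spec$age_mean + spec$age_sd * z_age
    risks <- vapply(spec$risk_prevalence,
                    function(p) as.integer(stats::runif(S) < p),
                    integer(S))

    tab <- data.frame(subject_id = sprintf("S%03d", seq_len(S)),
                      apathy = apathy, age = age, risks,
                      stringsAsFactors = FALSE)
    structure(list(weights = weights, table = tab, node_labels = labels,
                   node_coords = coords, base_weights =
                     sym_from_upper_kept(w0_kept, ut[kept, , drop = FALSE], n),
                   spec = spec),
              class = "svd_cohort")
  })
}

# symmetric matrix from values on an explicit list of (i < j) pairs
sym_from_upper_kept <- function(values, pairs, n) {
  m <- matrix(0, n, n)
  m[pairs] <- values
  m[pairs[, c(2, 1), drop = FALSE]] <- values
  m
}

#' @export
print.svd_cohort <- function(x, ...) {
  cat(sprintf(paste0("svd_cohort: %d subjects, %d nodes, %.0f%% edge density",
                     ", apathy %.2f (%.2f), effect_beta = %g\n"),
              dim(x$weights)[3], dim(x$weights)[1],
              100 * mean(x$weights[, , 1][upper.tri(x$weights[, , 1])] > 0),
              mean(x$table$apathy), stats::sd(x$table$apathy),
              x$spec$effect_beta))
  invisible(x)
}

#' Expand a cohort's connectomes into per-subject streamline bundles
#'
#' Inverse of the edge-weight formula `w = 1/2 sum(1/l_m)`: for every
#' nonzero edge, emits a bundle of equal-length straight streamlines whose
#' count and lengths reproduce the stored weight. With
#' `length_model = "distance"` lengths approximate the inter-node distance;
#' with `"constant"` they approximate `nominal_length_mm`. The bundle count
#' is `max(1, round(streamlines_per_unit_weight * w))` and lengths are set
#' to `N / (2 w)`, so the round trip through [build_connectome()] recovers
#' the weight up to floating-point error (well within the 5% tolerance that
#' count rounding alone would allow).
#'
#' @param cohort a `svd_cohort`.
#' @param streamlines_per_unit_weight bundle count per unit edge weight
#'   (> 0, default 20).
#' @param length_model `"distance"` (default) or `"constant"`.
#' @param nominal_length_mm length scale for `length_model = "constant"`.
#' @return list of edge-labelled [streamline_set()], one per subject.
#' @export
cohort_to_streamlines <- function(cohort, streamlines_per_unit_weight = 20,
                                  length_model = c("distance", "constant"),
                                  nominal_length_mm = 10) {
  stopifnot(inherits(cohort, "svd_cohort"), streamlines_per_unit_weight > 0)
  length_model <- match.arg(length_model)
  n <- dim(cohort$weights)[1]
  ut <- upper_pairs(n)
  lapply(seq_len(dim(cohort$weights)[3]), function(s) {
    w <- cohort$weights[, , s][ut]
    nz <- which(w > 0)
    pts <- list(); edges <- vector("list", 0)
    for (k in nz) {
      i <- ut[k, 1]; j <- ut[k, 2]
      N <- max(1L, as.integer(round(streamlines_per_unit_weight * w[k])))
      l <- N / (2 * w[k])
      a <- cohort$node_coords[i, ]
      u <- cohort$node_coords[j, ] - a
      u <- u / sqrt(sum(u^2))
      seg <- rbind(a, a + u * l)
      pts <- c(pts, rep(list(seg), N))
      edges <- c(edges, rep(list(c(i, j)), N))
    }
    if (length(pts) == 0) {
      structure(list(points = list(), lengths = numeric(0),
                     edges = matrix(integer(0), 0, 2)),
                class = "streamline_set")
    } else {
      streamline_set(pts, do.call(rbind, edges))
    }
  })
}

#' Save / load a cohort as CSV files
#'
#' Writes `cohort.csv` (subject_id, apathy, age, hypertension,
#' hypercholesterolemia, diabetes, smoking) plus one `connectome_<id>.csv`
#' per subject (symmetric matrix with node-name headers) into `dir`.
#' `load_cohort()` reads them back; if `cohort.csv` lacks an `apathy`
#' column but carries the six GDS item columns (`gds_stay_home`,
#' `gds_avoid_gatherings`, `gds_dropped_activities`, `gds_life_exciting`,
#' `gds_hard_new_projects`, `gds_full_of_energy`, values "yes"/"no"), the
#' score is computed with [apathy_score()].
#'
#' @param cohort a `svd_cohort`.
#' @param dir directory (created if needed).
#' @return `save_cohort` invisibly returns `dir`; `load_cohort` returns a
#'   `svd_cohort` (without generator-only fields such as `base_weights`).
#' @export
save_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(cohort$table, file.path(dir, "cohort.csv"),
                   row.names = FALSE)
  for (s in seq_len(dim(cohort$weights)[3])) {
    write_connectome_csv(cohort$weights[, , s],
                         file.path(dir, sprintf("connectome_%s.csv",
                                                cohort$table$subject_id[s])))
  }
  invisible(dir)
}

#' @rdname save_cohort
#' @export
load_cohort <- function(dir) {
  tab_path <- file.path(dir, "cohort.csv")
  if (!file.exists(tab_path)) stop("missing ", tab_path)
  tab <- utils::read.csv(tab_path, stringsAsFactors = FALSE)
  if (!"subject_id" %in% colnames(tab)) {
    stop("cohort.csv: missing required column 'subject_id'")
  }
  if (!"apathy" %in% colnames(tab)) {
    item_cols <- paste0("gds_", names(gds_item_polarity()))
    if (!all(item_cols %in% colnames(tab))) {
      stop("cohort.csv needs either an 'apathy' column or the six GDS item ",
           "columns: ", paste(item_cols, collapse = ", "))
    }
    tab$apathy <- vapply(seq_len(nrow(tab)), function(r) {
      items <- as.list(stats::setNames(unlist(tab[r, item_cols]),
                                       names(gds_item_polarity())))
      apathy_score(items)
    }, integer(1))
  }
  mats <- lapply(tab$subject_id, function(id) {
    read_connectome_csv(file.path(dir, sprintf("connectome_%s.csv", id)))
  })
  n <- nrow(mats[[1]])
  weights <- array(unlist(mats), c(n, n, length(mats)),
                   dimnames = list(rownames(mats[[1]]), rownames(mats[[1]]),
                                   NULL))
  structure(list(weights = weights, table = tab,
                 node_labels = rownames(mats[[1]]), node_coords = NULL,
                 base_weights = NULL, spec = NULL),
            class = "svd_cohort")
}
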