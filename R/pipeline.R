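# Full-analysis orchestration: simulate (or ingest) cycle matrices, run
# per-participant/gravity NMF with cross-validated model selection,
# cluster modules within and across gravity levels, fit the nonnegative
# CP tensor model, and report similarities against the 1 g condition with
# bootstrap chance levels. All stage seeds derive deterministically from
# one master seed.

#' Default analysis configuration
#'
#' Returns the package defaults mirroring the published protocol: 20 NMF
#' restarts, 5-fold x 20-rep cross-validation with the > 90% VAF rule,
#' silhouette-based k over 2..10 with cannot-link constraints across
#' gravity levels, 20 CP restarts and 10,000 bootstrap rounds. Any field
#' may be overridden via `...`.
#'
#' @param ... Named overrides.
#' @return Named list of settings.
#' @export
default_config <- function(...) {
  cfg <- list(
    gravity_labels = c("1g", "0.6g", "0.38g", "0.16g", "0.07g"),
    n_participants = 9,
    n_modules_true = 4,
    profile_kinds = c("constant", "linear_decreasing",
                      "threshold_decreasing", "u_shaped"),
    noise_sd = 0.02,
    n_bins = 200,
    nmf = list(n_restarts = 20, n_folds = 5, n_reps = 20, threshold = 90,
               n_range = 1:8, cv_restarts = 1),
    clustering = list(k_range = 2:10, n_init = 50),
    tensor = list(n_restarts = 10),
    bootstrap = list(n_boot = 10000, alpha = 0.05),
    seed = 1
  )
  modifyList(cfg, list(...))
}

#' Read an analysis configuration from JSON
#' @param path JSON file of overrides applied on top of [default_config()].
#' @return Configuration list.
#' @export
read_config <- function(path) {
  if (!is.character(path) || length(path) != 1 || !file.exists(path)) {
    stop_invalid("config file not found: '", paste(path, collapse = ""), "'")
  }
  do.call(default_config, jsonlite::read_json(path, simplifyVector = TRUE))
}

simulate_cycle_matrices <- function(cfg) {
  gt <- make_ground_truth(n_modules = cfg$n_modules_true,
                          condition_labels = cfg$gravity_labels,
                          profile_kinds = cfg$profile_kinds,
                          seed = derive_seed(cfg$seed, 1),
                          n_participants = cfg$n_participants,
                          n_bins = cfg$n_bins,
                          noise_sd = cfg$noise_sd)
  mats <- list()
  for (p in seq_len(cfg$n_participants)) {
    per_cond <- lapply(cfg$gravity_labels, function(g) {
      generate_cycle_matrix(gt, p, g, seed = derive_seed(cfg$seed, 2))
    })
    mats[[p]] <- normalize_amplitude(per_cond)
    names(mats[[p]]) <- cfg$gravity_labels
  }
  list(ground_truth = gt, matrices = mats)
}

#' Per-condition NMF and clustering analysis
#'
#' For every participant x gravity level: unit-variance scaling,
#' cross-validated VAF curve, module-number selection (> threshold rule)
#' and final NMF extraction. Per gravity level the spatial (and temporal)
#' modules are pooled across participants, clustered by cosine k-means at
#' the modal module number, de-duplicated within participant, and reduced
#' to cluster representatives (SPc / TEc). Representatives are then
#' clustered across gravity levels under cannot-link constraints with
#' silhouette-selected k, and each cluster's modules are compared with the
#' first (1 g) gravity level with bootstrap chance levels.
#'
#' @param config From [default_config()] / [read_config()].
#' @param matrices Optional pre-built list (participants) of lists
#'   (gravity labels) of `cycle_matrix`; simulated when omitted.
#' @return A `condition_analysis` report list.
#' @export
run_condition_analysis <- function(config = default_config(),
                                   matrices = NULL) {
  cfg <- config
  gt <- NULL
  if (is.null(matrices)) {
    sim <- simulate_cycle_matrices(cfg)
    gt <- sim$ground_truth
    matrices <- sim$matrices
  }
  gl <- cfg$gravity_labels
  n_part <- length(matrices)

  per_participant <- vector("list", n_part)
  for (p in seq_len(n_part)) {
    per_participant[[p]] <- lapply(gl, function(g) {
      m <- matrices[[p]][[g]]
      if (is.null(m)) stop_invalid("missing matrix for participant ", p,
                                   ", gravity ", g)
      sc <- scale_unit_variance(m)
      curve <- cross_validated_vaf_curve(
        sc$values, n_range = cfg$nmf$n_range, n_folds = cfg$nmf$n_folds,
        n_reps = cfg$nmf$n_reps, n_restarts = cfg$nmf$cv_restarts,
        seed = derive_seed(cfg$seed, 100 + p * 10 + match(g, gl)))
      sel <- select_module_number(curve, cfg$nmf$threshold)
      n_mod <- if (sel$reached) sel$n_selected else sel$n_max
      ms <- nmf_extract(sc$values, n_mod, n_restarts = cfg$nmf$n_restarts,
                        seed = derive_seed(cfg$seed, 200 + p * 10 + match(g, gl)))
      ms$W_unscaled <- unitize_cols(unscale_unit_variance(ms$W, sc$scales))
      list(curve = curve, selection = sel, modules = ms)
    })
    names(per_participant[[p]]) <- gl
  }

  per_gravity <- lapply(gl, function(g) {
    ns <- vapply(per_participant, function(pp) {
      s <- pp[[g]]$selection
      # fall back to the best available N when the threshold is not reached
      if (s$reached) s$n_selected else as.integer(s$n_max)
    }, integer(1))
    k <- modal_module_number(ns)
    sp_pool <- bind_pools(lapply(seq_len(n_part), function(p) {
      W <- per_participant[[p]][[g]]$modules$W_unscaled
      module_pool(t(W), participant = p, gravity = g, kind = "spatial")
    }))
    te_pool <- bind_pools(lapply(seq_len(n_part), function(p) {
      C <- per_participant[[p]][[g]]$modules$C
      module_pool(C, participant = p, gravity = g, kind = "temporal")
    }))
    cl_sp <- spherical_kmeans(sp_pool, k, n_init = cfg$clustering$n_init,
                              seed = derive_seed(cfg$seed, 300 + match(g, gl)))
    cl_sp <- dedupe_within_participant(cl_sp, sp_pool)
    spc <- representative_modules(cl_sp, sp_pool)
    # temporal clusters follow the spatial assignment structure: cluster
    # temporal vectors independently with the same k
    cl_te <- spherical_kmeans(te_pool, k, n_init = cfg$clustering$n_init,
                              seed = derive_seed(cfg$seed, 400 + match(g, gl)))
    cl_te <- dedupe_within_participant(cl_te, te_pool)
    tec <- representative_modules(cl_te, te_pool)
    list(gravity = g, n_selected = ns, k = k,
         spatial_clusters = cl_sp, temporal_clusters = cl_te,
         spc = spc, tec = tec)
  })
  names(per_gravity) <- gl

  # cross-gravity constrained clustering of representatives
  spc_pool <- bind_pools(lapply(per_gravity, function(pg) {
    module_pool(pg$spc, gravity = pg$gravity, kind = "spatial")
  }))
  tec_pool <- bind_pools(lapply(per_gravity, function(pg) {
    module_pool(pg$tec, gravity = pg$gravity, kind = "temporal")
  }))
  sel_sp <- select_k_by_silhouette(spc_pool, k_range = cfg$clustering$k_range,
                                   constrained = TRUE,
                                   n_init = cfg$clustering$n_init,
                                   seed = derive_seed(cfg$seed, 500))
  sel_te <- select_k_by_silhouette(tec_pool, k_range = cfg$clustering$k_range,
                                   constrained = TRUE,
                                   n_init = cfg$clustering$n_init,
                                   seed = derive_seed(cfg$seed, 501))

  # similarity of each gravity level's representatives to 1 g
  ref <- gl[1]
  similarity <- lapply(gl[-1], function(g) {
    mr <- match_modules(t(per_gravity[[ref]]$spc), t(per_gravity[[g]]$spc),
                        metric = "cosine")
    pool <- t(rbind(per_gravity[[ref]]$spc, per_gravity[[g]]$spc))
    ch <- bootstrap_chance_level(pool, metric = "cosine",
                                 n_boot = cfg$bootstrap$n_boot,
                                 alpha = cfg$bootstrap$alpha,
                                 seed = derive_seed(cfg$seed, 600 + match(g, gl)))
    list(gravity = g, match = mr, chance = ch$lower_bound,
         above_chance = mr$pairs$similarity > ch$lower_bound)
  })
  names(similarity) <- gl[-1]

  structure(list(config = cfg, ground_truth = gt,
                 per_participant = per_participant,
                 per_gravity = per_gravity,
                 cross_gravity = list(spatial = sel_sp, temporal = sel_te),
                 similarity = similarity),
            class = "condition_analysis")
}

#' Tensor-decomposition analysis of a slice set
#'
#' Builds the muscles x bins x slices tensor from all
#' participant x gravity cycle matrices, fits the nonnegative CP model
#' with `n_components` (defaulting to the cross-gravity cluster count),
#' summarizes the task gains per gravity level, and reconstructs the
#' SPc/TEc representatives from the CP components by NNLS.
#'
#' @param config Configuration list.
#' @param condition_report Optional result of [run_condition_analysis()];
#'   computed when omitted.
#' @param matrices Optional slice source as in [run_condition_analysis()].
#' @param n_components Number of CP components; default: spatial
#'   silhouette-selected k from the condition analysis.
#' @return A `tensor_analysis` report list.
#' @export
run_tensor_analysis <- function(config = default_config(),
                                condition_report = NULL, matrices = NULL,
                                n_components = NULL) {
  cfg <- config
  if (is.null(condition_report)) {
    condition_report <- run_condition_analysis(cfg, matrices)
  }
  gl <- cfg$gravity_labels
  if (is.null(matrices)) {
    # re-simulate the identical matrices (same derived seed)
    sim <- simulate_cycle_matrices(cfg)
    matrices <- sim$matrices
  }
  slices <- list(); labels <- NULL
  for (p in seq_along(matrices)) {
    for (g in gl) {
      if (is.null(matrices[[p]][[g]])) {
        stop_invalid("missing slice: participant ", p, ", gravity ", g)
      }
      slices[[length(slices) + 1]] <- matrices[[p]][[g]]
      labels <- rbind(labels, data.frame(participant = p, gravity = g))
    }
  }
  tensor <- build_tensor(slices, slice_labels = labels)
  if (is.null(n_components)) {
    n_components <- condition_report$cross_gravity$spatial$k_best
  }
  model <- ncp_decompose(tensor, n_components,
                         n_restarts = cfg$tensor$n_restarts,
                         seed = derive_seed(cfg$seed, 700))
  gains <- gain_by_condition(model, by = "gravity", levels = gl)

  ref_g <- gl[1]
  spc <- condition_report$per_gravity[[ref_g]]$spc
  tec <- condition_report$per_gravity[[ref_g]]$tec
  fit_sp <- nnls_reconstruct(t(spc), model$W_st)
  fit_te <- nnls_reconstruct(t(tec), model$C_st)

  structure(list(config = cfg, tensor_dim = dim(tensor$values),
                 model = model, gains_by_gravity = gains,
                 nnls_spatial = fit_sp, nnls_temporal = fit_te),
            class = "tensor_analysis")
}

#' Write an analysis report to JSON
#'
#' Serializes the numeric content of a condition or tensor report
#' (settings, selections, silhouettes, gains, similarities) to a
#' reviewable JSON file; factors and matrices are embedded as arrays.
#'
#' @param report A `condition_analysis` or `tensor_analysis`.
#' @param path Output JSON path.
#' @export
write_report_json <- function(report, path) {
  strip <- function(x) {
    if (inherits(x, c("cluster_result", "match_result", "module_set",
                      "cp_model", "chance_level", "cross_model_fit"))) {
      x <- unclass(x)
      x$samples <- NULL
    }
    if (is.list(x)) return(lapply(x, strip))
    x
  }
  obj <- strip(unclass(report))
  obj$ground_truth <- NULL
  jsonlite::write_json(obj, path, digits = 10, auto_unbox = TRUE,
                       force = TRUE, matrix = "rowmajor")
  invisible(path)
}
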