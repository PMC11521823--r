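# End-to-end orchestration: one validated config, a hierarchical seed
# policy (the master seed deterministically derives one seed per stage, so
# skipping a stage never shifts another stage's randomness), structured
# logging, and a run manifest with checksums.

.default_config <- function() {
  list(
    synth = list(),            # synth_config() overrides; NULL disables
    inputs = NULL,             # list(blocks=<named tsv paths>, sheet=, participants=)
    nmar_threshold = 0.75,
    nmar_percentile = 0.01,
    mar_sd = 0.5,
    alpha = 0.05,
    vip_threshold = 1.0,
    n_components = 2,
    snf_K = NULL,              # default max(2, floor(n/3)) at run time
    snf_mu = 0.5,
    snf_t = 20,
    cor_threshold = 0.7,
    trend_tol = 0.25,
    level = 0.95,
    max_missing = 10,
    min_paired = 9,
    seed = 1,
    out_dir = NULL)
}

#' Validate a run configuration
#'
#' Reads a YAML/JSON file (or takes a list), fills defaults (the printed
#' analysis values: NMAR threshold 0.75, low-intensity percentile 0.01, MAR
#' SD 0.5, alpha 0.05, VIP gate 1.0, correlation threshold 0.7, confidence
#' level 0.95) and rejects unknown keys and out-of-range values.
#'
#' @param config path to a YAML/JSON file, a list, or `NULL` (all
#'   defaults).
#' @return A validated config list of class `run_config`.
#' @export
validate_config <- function(config = NULL) {
  if (is.character(config)) {
    config <- if (grepl("\\.json$", config)) {
      jsonlite::read_json(config, simplifyVector = TRUE)
    } else yaml::read_yaml(config)
    if (is.null(config)) config <- list()
  }
  config <- config %||% list()
  .assert(is.list(config), "config must be a list or a YAML/JSON path")
  def <- .default_config()
  unknown <- setdiff(names(config), names(def))
  .assert(length(unknown) == 0,
          paste("unknown config key(s):", paste(unknown, collapse = ", ")))
  cfg <- utils::modifyList(def, config, keep.null = TRUE)
  in01 <- function(x) is.numeric(x) && length(x) == 1 && x > 0 && x < 1
  .assert(in01(cfg$alpha), "alpha must lie in (0, 1)")
  .assert(in01(cfg$nmar_threshold), "nmar_threshold must lie in (0, 1)")
  .assert(in01(cfg$nmar_percentile), "nmar_percentile must lie in (0, 1)")
  .assert(in01(cfg$level), "level must lie in (0, 1)")
  .assert(is.numeric(cfg$cor_threshold) && cfg$cor_threshold >= 0 &&
            cfg$cor_threshold <= 1, "cor_threshold must lie in [0, 1]")
  .assert(cfg$mar_sd > 0, "mar_sd must be positive")
  .assert(cfg$trend_tol > 0, "trend_tol must be positive")
  if (!is.null(cfg$inputs)) {
    paths <- c(unlist(cfg$inputs$blocks), cfg$inputs$sheet, cfg$inputs$participants)
    absent <- paths[!file.exists(paths)]
    .assert(length(absent) == 0,
            paste("missing input file(s):", paste(absent, collapse = ", ")))
  }
  structure(cfg, class = c("run_config", "list"))
}

# participant_timepoint-labelled sample profile matrix for paired samples
.paired_profiles <- function(block, design, type) {
  pr <- design_pairs(design, type, block)
  cols <- c(pr$bt, pr$at)
  m <- t(block$values[, cols, drop = FALSE])
  rownames(m) <- paste(rep(pr$participant_id, 2),
                       rep(c("BT", "AT"), each = nrow(pr)), sep = "_")
  m
}

# BT (or AT) profile matrix rowed by participant, restricted to `pids`
.timepoint_profiles <- function(block, sheet, type, timepoint, pids) {
  sheet <- as.data.frame(sheet)
  s <- sheet[sheet$sample_type == type & sheet$timepoint == timepoint &
               sheet$participant_id %in% pids, , drop = FALSE]
  s <- s[s$sample_id %in% block$sample_ids, , drop = FALSE]
  m <- t(block$values[, s$sample_id, drop = FALSE])
  rownames(m) <- s$participant_id
  m
}

#' Run the full analysis pipeline
#'
#' Stages: `synth` (optional) -> `preprocess` -> `markers` -> `integrate`
#' -> `response` -> `health`. Any stage failure aborts with a stage-named
#' error; the manifest records stage wall-clocks, consumed seeds, the
#' config hash and checksums of everything written.
#'
#' @param config a [validate_config()] result (or anything it accepts).
#' @param stages character subset of stages to execute (earlier stage
#'   results must then be supplied via `state`).
#' @param state optional list of prior-stage results (as returned by this
#'   function under `$state`) for partial runs.
#' @return list with `state` (all intermediate results), `manifest`.
#' @export
run_pipeline <- function(config = NULL,
                         stages = c("synth", "preprocess", "markers",
                                    "integrate", "response", "health"),
                         state = list()) {
  cfg <- validate_config(if (inherits(config, "run_config")) unclass(config) else config)
  manifest <- list(package_version = as.character(utils::packageVersion("pairomics")),
                   config_hash = .hash_obj(unclass(cfg)),
                   seeds = list(), timings = list(), outputs = list())
  run_stage <- function(name, fun) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(fun(), error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
    manifest$timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    res
  }

  if ("synth" %in% stages && is.null(state$cohort)) {
    manifest$seeds$synth <- derive_seed(cfg$seed, "synth")
    state$cohort <- run_stage("synth", function() {
      args <- utils::modifyList(list(seed = manifest$seeds$synth),
                                cfg$synth %||% list())
      generate_cohort(do.call(synth_config, args))
    })
  } else if (is.null(state$cohort) && !is.null(cfg$inputs)) {
    state$cohort <- run_stage("load", function() {
      sheet <- read_sample_sheet(cfg$inputs$sheet)
      blocks <- lapply(cfg$inputs$blocks, read_block, sheet = sheet)
      list(blocks = blocks, sheet = sheet,
           participants = read_participant_sheet(cfg$inputs$participants),
           truth = NULL)
    })
  }
  .assert(!is.null(state$cohort), "no cohort: enable synth or provide inputs")
  cohort <- state$cohort
  design <- build_paired_design(cohort$sheet)
  state$design <- design

  if ("preprocess" %in% stages) {
    manifest$seeds$preprocess <- derive_seed(cfg$seed, "preprocess")
    state$preprocessed <- run_stage("preprocess", function() {
      params <- imputation_params(cfg$nmar_threshold, cfg$nmar_percentile,
                                  cfg$mar_sd, seed = manifest$seeds$preprocess)
      out <- list()
      for (ty in names(cohort$blocks)) {
        out[[ty]] <- preprocess_block(cohort$blocks[[ty]], cohort$sheet,
                                      design, ty, params = params,
                                      max_missing = cfg$max_missing,
                                      min_paired = cfg$min_paired)
      }
      out
    })
  }
  pp <- state$preprocessed
  .assert(!is.null(pp) || !any(c("markers", "integrate", "response", "health")
                               %in% stages),
          "preprocess results required for later stages")

  if ("markers" %in% stages) {
    state$markers <- run_stage("markers", function() {
      lapply(stats::setNames(names(pp), names(pp)), function(ty) {
        discover_markers(pp[[ty]]$block, design, ty, alpha = cfg$alpha,
                         vip_threshold = cfg$vip_threshold,
                         n_components = cfg$n_components)
      })
    })
  }

  if ("integrate" %in% stages) {
    manifest$seeds$integrate <- derive_seed(cfg$seed, "integrate")
    state$integration <- run_stage("integrate", function() {
      marker_ids <- lapply(state$markers, function(m) m$feature_id[m$selected])
      # fall back to the full profile when a block yields too few markers
      feats <- lapply(names(pp), function(ty) {
        ids <- marker_ids[[ty]]
        if (length(ids) >= 3) ids else rownames(pp[[ty]]$block$values)
      })
      names(feats) <- names(pp)
      changes <- lapply(names(pp), function(ty) {
        participant_change_matrix(pp[[ty]]$block, design, ty, feats[[ty]])
      })
      names(changes) <- names(pp)
      epi <- c("buccal", "pbmc")
      common <- Reduce(intersect, lapply(changes[epi], rownames))
      K <- cfg$snf_K %||% max(2, floor(length(common) / 3))
      affs <- lapply(changes[epi], function(ch) {
        build_affinity(ch[common, , drop = FALSE], K = K, mu = cfg$snf_mu)
      })
      fused <- snf_fuse(affs, K = K, t = cfg$snf_t)
      clust <- spectral_cluster(fused, k = "auto",
                                seed = manifest$seeds$integrate)
      ptm_changes <- do.call(cbind, lapply(epi, function(ty) {
        changes[[ty]][common, , drop = FALSE]
      }))
      net <- change_correlation_network(ptm_changes,
                                        changes$plasma[intersect(common, rownames(changes$plasma)), ,
                                                       drop = FALSE],
                                        threshold = cfg$cor_threshold)
      hubs <- high_degree_nodes(net, min_degree = 1)
      ptm_prof <- do.call(cbind, lapply(epi, function(ty) {
        m <- .paired_profiles(pp[[ty]]$block, design, ty)
        m[, feats[[ty]], drop = FALSE]
      }))
      pl_prof <- .paired_profiles(pp$plasma$block, design, "plasma")[, feats$plasma,
                                                                     drop = FALSE]
      coph <- cophenetic_compare(ptm_prof, pl_prof)
      list(affinities = affs, fused = fused, clusters = clust,
           network = net, hubs = hubs, cophenetic = coph,
           changes = changes, marker_features = feats)
    })
  }

  if ("response" %in% stages) {
    manifest$seeds$response <- derive_seed(cfg$seed, "response")
    state$response <- run_stage("response", function() {
      adj <- baseline_adjust(cohort$participants)
      gmm <- gmm_categories(adj, seed = manifest$seeds$response)
      trends <- lapply(names(pp), function(ty) {
        ids <- state$markers[[ty]]$feature_id[state$markers[[ty]]$selected]
        if (length(ids) == 0) return(NULL)
        eff <- participant_change_matrix(pp[[ty]]$block, design, ty, ids)
        common <- intersect(rownames(eff), names(gmm$labels))
        prof <- category_effect_profile(eff[common, , drop = FALSE],
                                        gmm$labels[common])
        if (ncol(prof) != 3) return(NULL)
        data.frame(feature_id = rownames(prof),
                   trend = trend_classify(prof, tol = cfg$trend_tol),
                   prof, check.names = FALSE, row.names = NULL)
      })
      names(trends) <- names(pp)
      list(adjusted = adj, gmm = gmm, trends = trends)
    })
  }

  if ("health" %in% stages) {
    state$health <- run_stage("health", function() {
      parts <- as.data.frame(cohort$participants)
      lifestyles <- list(
        exercise = stats::setNames(parts$exercise_class, parts$participant_id),
        diet = stats::setNames(parts$diet_class, parts$participant_id),
        bmi = stats::setNames(parts$bmi_class, parts$participant_id))
      healthy <- c(exercise = "sportive", diet = "balanced", bmi = "normal")
      maps <- list(); dvec <- list(); score_rows <- list(); regress <- list()
      for (ty in names(pp)) {
        for (lf in names(lifestyles)) {
          pbt <- .timepoint_profiles(pp[[ty]]$block, cohort$sheet, ty, "BT",
                                     parts$participant_id)
          pat <- .timepoint_profiles(pp[[ty]]$block, cohort$sheet, ty, "AT",
                                     parts$participant_id)
          map <- suppressWarnings(
            fit_health_map(pbt, lifestyles[[lf]], healthy[[lf]],
                           n_components = cfg$n_components))
          at_scores <- project_at(map, pat)
          d <- therapy_effect_distance(map, at_scores)
          key <- paste(ty, lf, sep = ".")
          maps[[key]] <- map
          dvec[[key]] <- d
          rng <- tryCatch(healthy_range(map, pbt, pat, level = cfg$level,
                                        vip_threshold = cfg$vip_threshold),
                          error = function(e) NULL)
          if (!is.null(rng)) {
            common <- intersect(rownames(pbt), rownames(pat))
            rows <- lapply(common, function(p) {
              sb <- similarity_score(pbt[p, rng$feature_id], rng)
              sa <- similarity_score(pat[p, rng$feature_id], rng)
              data.frame(cell = key, participant_id = p,
                         bt_score = sb$weighted_score,
                         at_score = sa$weighted_score,
                         bt_n_in = sb$n_in_range, at_n_in = sa$n_in_range,
                         stringsAsFactors = FALSE)
            })
            score_rows[[key]] <- do.call(rbind, rows)
          }
          bt_d <- sqrt(colSums((t(map$bt_scores[names(d), , drop = FALSE]) -
                                  map$healthy_centroid)^2))
          regress[[key]] <- tryCatch(robust_regress(unname(d), unname(bt_d)),
                                     error = function(e) NULL)
        }
      }
      # Kendall's W across sample types per lifestyle component
      concordance <- lapply(names(lifestyles), function(lf) {
        keys <- paste(names(pp), lf, sep = ".")
        common <- Reduce(intersect, lapply(dvec[keys], names))
        if (length(common) < 3) return(NULL)
        mat <- sapply(keys, function(k) dvec[[k]][common])
        kendalls_w(as.matrix(mat))
      })
      names(concordance) <- names(lifestyles)
      scores <- do.call(rbind, score_rows)
      tests <- if (!is.null(scores)) compare_bt_at(scores) else NULL
      list(maps = maps, distances = dvec, concordance = concordance,
           scores = scores, tests = tests, regression = regress)
    })
  }

  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    manifest$outputs <- run_stage("write", function() .write_artifacts(state, cfg))
  }
  manifest$seed <- cfg$seed
  list(state = state, manifest = manifest)
}

.hash_obj <- function(obj) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA,
                              null = "null", force = TRUE), tmp)
  unname(tools::md5sum(tmp))
}

.write_artifacts <- function(state, cfg) {
  out <- character(0)
  w <- function(obj, name) {
    path <- file.path(cfg$out_dir, name)
    write_results(obj, path)
    out[[name]] <<- unname(tools::md5sum(path))
  }
  if (!is.null(state$markers)) {
    for (ty in names(state$markers)) w(state$markers[[ty]], paste0("markers_", ty, ".json"))
  }
  if (!is.null(state$integration)) {
    w(unclass(state$integration$fused), "fused_affinity.tsv")
    w(as.list(state$integration$clusters$labels), "clusters.json")
    if (nrow(state$integration$network) > 0) {
      w(state$integration$network, "network.graphml")
    }
    w(list(cophenetic = state$integration$cophenetic), "cophenetic.json")
  }
  if (!is.null(state$response)) {
    w(list(k = state$response$gmm$k,
           labels = as.list(as.character(state$response$gmm$labels))),
      "response.json")
  }
  if (!is.null(state$health)) {
    if (!is.null(state$health$scores)) w(state$health$scores, "health_scores.json")
    if (!is.null(state$health$tests)) w(state$health$tests, "health_tests.json")
  }
  as.list(out)
}
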