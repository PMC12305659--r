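#' Default pipeline configuration
#'
#' Returns the bundled defaults for the end-to-end synthetic run, a
#' desk-scale version of the screening campaign this package models
#' (384-well layout with ~94 populated wells, 200 raw cell features, 300
#' cells/well, 18 extract treatments in 4-point 2-fold dilution of which 6
#' carry a real phenotype, 120 aligned MS features of which 30 are planted
#' bioactive markers). Any element can be overridden via `...` or by an
#' entry in a JSON config file.
#'
#' @param ... named overrides.
#' @return a validated config list.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    seed = 1L,
    # synthetic plate
    n_features = 200L, n_cells = 300L,
    n_treatments = 18L, n_active = 8L, n_moa_classes = 2L,
    top_conc = 200, ec50 = 300, n_affected = 20L, effect_size = 3,
    heavy_tails = TRUE, n_vehicle_wells = 16L, n_pos_wells = 3L,
    # synthetic MS
    n_ms_features = 120L, features_per_class = 8L,
    background_cardinality = 4L, background_rate = 0.01,
    # histdiff
    n_bins = 32L, smooth = 1, cp_sqrt = TRUE, vehicle_stat = "max",
    # feature selection ("auto" = permutation-null threshold); FCBF under a
    # binary activity label collapses mutually redundant responsive
    # features aggressively, so the retained set is padded back to
    # min_fingerprint_features with the next most relevant features
    su_threshold = "auto", fcbf_bins = 5L, min_fingerprint_features = 20L,
    # networking
    min_activity = 0.03, min_cluster = 0.5, min_intensity = 0,
    activity_aggregate = "mean", singleton_score = 1,
    # annotation
    compound_db = NULL, tol_ppm = 10, electron_correction = FALSE,
    adducts = c("[M+H]+", "[M+Na]+"),
    # outputs
    write_cell_tables = FALSE, heatmap = TRUE
  )
  over <- list(...)
  if (length(over) == 1L && is.list(over[[1L]]) && is.null(names(over)))
    over <- over[[1L]]
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown) > 0L)
    stop(sprintf("unknown config field(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  cfg[names(over)] <- over
  validate_config(cfg)
}

#' @rdname pipeline_config
#' @param path JSON config file.
#' @export
read_config <- function(path) {
  over <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipeline_config, over)
}

validate_config <- function(cfg) {
  chk <- function(ok, msg) if (!ok) stop("config: ", msg, call. = FALSE)
  chk(cfg$min_cluster >= -1 && cfg$min_cluster <= 1,
      "min_cluster must be in [-1, 1]")
  chk(cfg$min_activity >= 0 && cfg$min_activity <= 1,
      "min_activity must be in [0, 1]")
  chk(identical(cfg$su_threshold, "auto") ||
        (is.numeric(cfg$su_threshold) && cfg$su_threshold >= 0 &&
           cfg$su_threshold < 1),
      "su_threshold must be 'auto' or in [0, 1)")
  chk(cfg$n_bins >= 8, "n_bins must be >= 8")
  chk(cfg$n_features >= 2 && cfg$n_cells >= 10,
      "need n_features >= 2 and n_cells >= 10")
  chk(cfg$background_rate >= 0 && cfg$background_rate <= 1,
      "background_rate must be in [0, 1]")
  chk(cfg$tol_ppm > 0, "tol_ppm must be > 0")
  chk(cfg$vehicle_stat %in% c("max", "median", "quantile"),
      "vehicle_stat must be max, median or quantile")
  cfg
}

# wells populated in the default desk-scale run: a vehicle pool, the top
# doses of both positive-control dilution columns, and every sample well
populated_wells <- function(plate_map, cfg) {
  veh <- plate_map$well[plate_map$kind == "vehicle"]
  veh <- veh[seq_len(min(cfg$n_vehicle_wells, length(veh)))]
  pos <- plate_map[plate_map$kind == "positive_control", ]
  pos <- do.call(rbind, lapply(split(pos, pos$treatment_id), function(d)
    d[order(-d$concentration), ][seq_len(min(cfg$n_pos_wells, nrow(d))), ]))
  smp <- plate_map$well[plate_map$kind == "sample" &
                          !is.na(plate_map$treatment_id)]
  c(veh, pos$well, smp)
}

sample_id_of <- function(plate_row) {
  paste0(plate_row$treatment_id, "_",
         formatC(plate_row$concentration, format = "fg"))
}

#' Run the full synthetic-to-network pipeline
#'
#' Executes the stages in order: synthetic data generation, HistDiff
#' profiling + CP scores + vehicle activity filter, FCBF feature selection,
#' Spearman/Ward clustering gated by the positive controls, optional
#' formula/adduct annotation, and the thresholded bipartite bioactivity
#' network with Louvain communities. All stage outputs land in `out_dir`
#' together with a provenance manifest; re-running with the same config
#' reproduces every CSV byte for byte.
#'
#' @param config a config list from [pipeline_config()] / [read_config()],
#'   or a path to a JSON config file.
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with the main in-memory results and the
#'   manifest.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir) {
  if (is.character(config)) config <- read_config(config)
  cfg <- validate_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }
  out <- function(f) file.path(out_dir, f)

  ## --- synth -------------------------------------------------------------
  synth <- stage("synth", {
    treatments <- sprintf("T%02d", seq_len(cfg$n_treatments))
    pm <- synth_plate_map(treatments, top_conc = cfg$top_conc)
    gt <- synth_ground_truth(
      cfg$n_features, treatments,
      active = treatments[seq_len(cfg$n_active)],
      n_classes = cfg$n_moa_classes,
      n_affected = cfg$n_affected, effect_size = cfg$effect_size,
      ec50 = cfg$ec50, seed = cfg$seed)
    wells <- populated_wells(pm, cfg)
    ct <- synth_cell_tables(pm, gt, n_features = cfg$n_features,
                            n_cells = cfg$n_cells, seed = cfg$seed,
                            wells = wells, heavy_tails = cfg$heavy_tails)
    # MS samples are extracts (one per treatment): the planted markers of a
    # MOA class occur in every extract of that class
    ms_samples <- treatments
    active_sets <- list()
    for (k in sort(unique(stats::na.omit(gt$class_of)))) {
      sset <- names(gt$class_of)[!is.na(gt$class_of) & gt$class_of == k]
      for (m in seq_len(cfg$features_per_class))
        active_sets[[paste0(k, "_m", m)]] <- sset
    }
    ms <- synth_ms_features(
      ms_samples, n_features = cfg$n_ms_features,
      active_samples = active_sets,
      background_cardinality = cfg$background_cardinality,
      background_rate = cfg$background_rate, seed = cfg$seed)
    write_plate_map(pm, out("plate_map.csv"))
    write_ms_features(ms$table, out("ms_features.csv"))
    jsonlite::write_json(
      list(active_treatments = gt$active_treatments,
           ec50 = gt$ec50, effects = gt$effects,
           active_ms_features = as.list(ms$active_ids)),
      out("ground_truth.json"), auto_unbox = TRUE, digits = NA)
    if (isTRUE(cfg$write_cell_tables))
      write_cell_tables(ct$cells, out("cell_tables.csv"))
    list(pm = pm, gt = gt, ct = ct, ms = ms, ms_samples = ms_samples)
  })

  ## --- profile -----------------------------------------------------------
  prof <- stage("profile", {
    profiles_w <- profile_wells(synth$ct$cells, synth$pm,
                                n_bins = cfg$n_bins, smooth = cfg$smooth,
                                vehicle_loo = TRUE)
    pm <- synth$pm
    idx <- match(rownames(profiles_w), pm$well)
    is_veh <- pm$kind[idx] == "vehicle"
    ids <- ifelse(is_veh, paste0("vehicle_", rownames(profiles_w)),
                  sample_id_of(pm[idx, ]))
    rownames(profiles_w) <- ids
    scores <- cp_score(profiles_w, sqrt = cfg$cp_sqrt)
    retained <- activity_filter(scores[!is_veh], scores[is_veh],
                                stat = cfg$vehicle_stat)
    conc <- stats::setNames(pm$concentration[idx], ids)
    # extract-level view: one profile per treatment, taken at the top
    # tested concentration (the most informative dose); an extract counts
    # as retained when any of its doses survives the activity filter
    trt_of <- stats::setNames(pm$treatment_id[idx], ids)
    smp <- which(pm$kind[idx] == "sample")
    extracts <- unique(trt_of[smp])
    top_well <- vapply(extracts, function(t) {
      cand <- names(trt_of)[which(trt_of == t & seq_along(ids) %in% smp)]
      cand[which.max(conc[cand])]
    }, "")
    extract_profiles <- profiles_w[top_well, , drop = FALSE]
    rownames(extract_profiles) <- extracts
    extract_retained <- extracts[vapply(extracts, function(t)
      any(names(trt_of)[trt_of == t] %in% retained, na.rm = TRUE),
      logical(1))]
    write_fingerprints(profiles_w, scores, out("histdiff_profiles.csv"),
                       concentration = conc)
    write.csv(data.frame(sample = names(scores), score = scores,
                         vehicle = is_veh,
                         retained = names(scores) %in% retained,
                         row.names = NULL),
              out("cp_scores.csv"), row.names = FALSE)
    list(profiles = profiles_w, scores = scores, retained = retained,
         is_veh = is_veh, ids = ids,
         extract_profiles = extract_profiles,
         extract_retained = extract_retained)
  })

  ## --- select ------------------------------------------------------------
  sel <- stage("select", {
    nonveh <- prof$profiles[!prof$is_veh, , drop = FALSE]
    labels <- ifelse(rownames(nonveh) %in% prof$retained,
                     "active", "inactive")
    fs <- if (length(unique(labels)) < 2L) {
      notice("select: activity filter produced a single class; keeping all features")
      list(selected = colnames(nonveh),
           su_with_class = stats::setNames(rep(NA_real_, ncol(nonveh)),
                                           colnames(nonveh)))
    } else {
      thr <- if (identical(cfg$su_threshold, "auto"))
        fcbf_auto_threshold(nonveh, labels, bins = cfg$fcbf_bins,
                            seed = cfg$seed)
      else cfg$su_threshold
      fcbf(nonveh, labels, su_threshold = thr, bins = cfg$fcbf_bins)
    }
    fs$selected_fcbf <- fs$selected
    want <- min(cfg$min_fingerprint_features, ncol(nonveh))
    if (length(fs$selected) < want && !all(is.na(fs$su_with_class))) {
      ranking <- names(sort(fs$su_with_class, decreasing = TRUE))
      ranking <- ranking[order(-fs$su_with_class[ranking], ranking)]
      pad <- setdiff(ranking, fs$selected)
      fs$selected <- c(fs$selected,
                       pad[seq_len(want - length(fs$selected))])
    }
    write.csv(data.frame(feature = names(fs$su_with_class),
                         su_with_class = fs$su_with_class,
                         selected_fcbf = names(fs$su_with_class) %in%
                           fs$selected_fcbf,
                         selected = names(fs$su_with_class) %in% fs$selected,
                         rank = match(names(fs$su_with_class), fs$selected),
                         row.names = NULL),
              out("feature_selection.csv"), row.names = FALSE)
    fs
  })

  ## --- cluster -----------------------------------------------------------
  clus <- stage("cluster", {
    pm <- synth$pm
    pos_rows <- pm[pm$kind == "positive_control" & !is.na(pm$treatment_id), ]
    pos_ids <- intersect(sample_id_of(pos_rows), rownames(prof$profiles))
    members <- union(prof$retained, pos_ids)
    fp <- prof$profiles[members, sel$selected, drop = FALSE]
    d <- spearman_distance(fp)
    tree <- ward_cluster(d)
    gating <- gate_clusters(tree, pos_ids)
    write.csv(data.frame(id = names(gating$assignment),
                         cluster = gating$assignment,
                         is_positive_control =
                           names(gating$assignment) %in% pos_ids,
                         row.names = NULL),
              out("cluster_assignments.csv"), row.names = FALSE)
    dendrogram_newick(tree, out("dendrogram.nwk"))
    if (isTRUE(cfg$heatmap))
      heatmap_export(fp, tree, gating, out("heatmap"))
    list(tree = tree, gating = gating, pos_ids = pos_ids)
  })

  ## --- annotate ----------------------------------------------------------
  annot <- stage("annotate", {
    if (is.null(cfg$compound_db)) NULL else {
      db <- read_compound_db(cfg$compound_db)
      ann <- annotate_features(synth$ms$table, db, rules = cfg$adducts,
                               tol_ppm = cfg$tol_ppm,
                               electron_correction = cfg$electron_correction)
      ann$ppm <- round(ann$ppm, 1L) # exports mirror the 1-decimal convention
      write.csv(ann, out("annotations.csv"), row.names = FALSE)
      ann
    }
  })

  ## --- network -----------------------------------------------------------
  net <- stage("network", {
    ep <- prof$extract_profiles[intersect(rownames(prof$extract_profiles),
                                          synth$ms_samples), ,
                                drop = FALSE]
    fp01 <- fingerprint_normalize(ep[, sel$selected, drop = FALSE])
    write_fingerprints(fp01, cp_score(ep, sqrt = cfg$cp_sqrt),
                       out("bioactivity_fingerprints.csv"))
    scores <- feature_scores(synth$ms$table, fp01,
                             min_intensity = cfg$min_intensity,
                             aggregate = cfg$activity_aggregate,
                             singleton_score = cfg$singleton_score)
    write.csv(scores, out("feature_scores.csv"), row.names = FALSE)
    presence <- detect_presence(synth$ms$table, cfg$min_intensity)
    g <- build_network(scores, presence, min_activity = cfg$min_activity,
                       min_cluster = cfg$min_cluster,
                       samples = rownames(fp01))
    comm <- if (igraph::vcount(g) > 0L)
      detect_communities(g, seed = derive_seed(cfg$seed, 7L)) else NULL
    export_network(g, out("network"), communities = comm)
    list(graph = g, scores = scores, communities = comm)
  })

  ## --- manifest ----------------------------------------------------------
  manifest <- stage("manifest", {
    files <- sort(list.files(out_dir, full.names = FALSE))
    files <- setdiff(files, "manifest.json")
    sums <- tools::md5sum(file.path(out_dir, files))
    names(sums) <- files
    cfg_json <- jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA,
                                 null = "null")
    man <- list(package = "cpbionet",
                version = as.character(utils::packageVersion("cpbionet")),
                seed = cfg$seed,
                config = cfg,
                config_md5 = md5_of_string(as.character(cfg_json)),
                files = as.list(sums))
    jsonlite::write_json(man, out("manifest.json"), auto_unbox = TRUE,
                         digits = NA, null = "null", pretty = TRUE)
    man
  })

  invisible(list(config = cfg, synth = synth, profile = prof, select = sel,
                 cluster = clus, annotate = annot, network = net,
                 manifest = manifest))
}

md5_of_string <- function(s) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(s, tf)
  unname(tools::md5sum(tf))
}
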