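#' Assemble a full pipeline configuration
#'
#' @param phantom a [phantom_config()].
#' @param tracking a [tracking_params()].
#' @param k clusters per side.
#' @param cutoff silhouette cutoff.
#' @param bin profile down-binning factor.
#' @param n_restarts k-means restarts.
#' @param groupmap_threshold population-fraction cutoff for group maps.
#' @param n_subjects cohort size.
#' @param rng_seed global seed; per-stage, per-subject seeds derive from it
#'   via [derive_seed()].
#' @return a config list of class `pag_pipeline_config`.
#' @export
pipeline_config <- function(phantom = phantom_config(),
                            tracking = tracking_params(),
                            k = 4L, cutoff = 0.25, bin = 3L,
                            n_restarts = 50L,
                            groupmap_threshold = 0.30,
                            n_subjects = 19L, rng_seed = 1L) {
  structure(list(phantom = phantom, tracking = tracking, k = as.integer(k),
                 cutoff = cutoff, bin = as.integer(bin),
                 n_restarts = as.integer(n_restarts),
                 groupmap_threshold = groupmap_threshold,
                 n_subjects = as.integer(n_subjects),
                 rng_seed = as.integer(rng_seed)),
            class = "pag_pipeline_config")
}

#' Segment one subject end-to-end
#'
#' Track, cluster, filter and identify columns on both sides of one phantom
#' subject. Stage seeds derive from `rng_seed` and the subject index so any
#' subject reruns identically in isolation.
#'
#' @param ph a `pag_phantom`.
#' @param cfg a [pipeline_config()].
#' @param subject subject index used in seed derivation.
#' @return list with per-side elements `cm` (`pag_connectivity`) and
#'   `clusters` (`pag_clusters` with identities), plus `subject`.
#' @export
segment_subject <- function(ph, cfg, subject = 1L) {
  track_seed <- derive_seed(cfg$rng_seed, "track", subject)
  clust_seed <- derive_seed(cfg$rng_seed, "cluster", subject)
  tp <- cfg$tracking
  tp$rng_seed <- track_seed
  sides <- list()
  for (side in c("left", "right")) {
    cm <- track_seed_mask(ph, tp, side)
    cl <- cluster_side(cm, k = cfg$k, cutoff = cfg$cutoff,
                       prob_threshold = tp$prob_threshold, bin = cfg$bin,
                       n_restarts = cfg$n_restarts, rng_seed = clust_seed)
    cl <- assign_column_identities(cl, ph)
    sides[[side]] <- list(cm = cm, clusters = cl)
  }
  c(sides, list(subject = subject))
}

#' Run the full pipeline over a synthetic cohort
#'
#' simulate -> track -> cluster -> profiles -> backproject -> groupmap.
#' Writes label maps, profile tables, test tables, and group maps under
#' `out_dir` and returns a run manifest (config hash, per-stage seeds, output
#' paths, file checksums). Rerunning with the same config reproduces every
#' output bit-identically.
#'
#' @param cfg a [pipeline_config()].
#' @param out_dir output directory (created). `NULL` keeps results in memory
#'   only.
#' @param verbose print stage progress.
#' @return list: `manifest`, `cohort` (phantoms), `subjects` (per-subject
#'   segmentations), `profiles` (cohort long table), `tests` (pairwise and
#'   multivariate tables), `success` (per-column fractions), `group_maps`
#'   (per column identity), `backprojections`.
#' @export
run_pipeline <- function(cfg = pipeline_config(), out_dir = NULL,
                         verbose = FALSE) {
  say <- function(...) if (verbose) message(...)
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  say("simulate: ", cfg$n_subjects, " subjects")
  cohort <- generate_cohort(cfg$phantom, cfg$n_subjects)
  template <- template_phantom(cfg$phantom)
  gd <- cfg$phantom$grid_shape

  subjects <- vector("list", cfg$n_subjects)
  profile_list <- vector("list", cfg$n_subjects)
  backprojections <- vector("list", cfg$n_subjects)
  cluster_results <- list()
  template_maps <- list()   # per column identity: list of binary template maps

  for (i in seq_len(cfg$n_subjects)) {
    say("subject ", i, ": track + cluster")
    ph <- cohort[[i]]
    seg <- segment_subject(ph, cfg, i)
    subjects[[i]] <- seg

    side_profiles <- list()
    bp_side <- list()
    for (side in c("left", "right")) {
      cm <- seg[[side]]$cm
      cl <- seg[[side]]$clusters
      cluster_results[[paste0("s", i, "_", side)]] <- cl

      tot <- total_seed_connectivity(cm, cfg$tracking$prob_threshold)
      kept <- tot$target[!tot$removed]
      prof <- tryCatch(column_profiles(cl, cm, kept), error = function(e) NULL)
      if (!is.null(prof)) side_profiles[[side]] <- prof

      bp <- tryCatch(backproject(cl, cm, cfg$tracking$prob_threshold),
                     error = function(e) NULL)
      bp_side[[side]] <- bp

      lab_t <- to_template(
        cluster_label_volume(cl, gd, by_identity = TRUE),
        ph$subject_affine, gd)
      bp_side[[paste0(side, "_template_labels")]] <- lab_t
    }
    # one binary template map per subject per column (both sides pooled)
    lab_l <- bp_side$left_template_labels
    lab_r <- bp_side$right_template_labels
    for (ci in seq_along(ph$columns)) {
      cn <- ph$columns[ci]
      template_maps[[cn]] <- c(template_maps[[cn]] %||% list(),
                               list(lab_l == ci | lab_r == ci))
    }
    profile_list[[i]] <- side_profiles
    backprojections[[i]] <- bp_side
  }

  say("profiles + tests")
  have_prof <- vapply(profile_list, function(p) length(p) > 0, logical(1))
  profiles <- cohort_profiles(profile_list[have_prof])
  tests <- if (length(unique(profiles$subject)) >= 3)
    tryCatch(
      pairwise_column_tests(profiles,
                            rng_seed = derive_seed(cfg$rng_seed, "profiles")),
      error = function(e) {
        warning("pairwise column tests skipped: ", conditionMessage(e))
        NULL
      })
  else NULL

  success <- evaluate_success(cluster_results,
                              columns = column_names(cfg$k))

  say("group maps")
  group_maps <- lapply(template_maps, group_probability_map,
                       threshold = cfg$groupmap_threshold)

  manifest <- list(package_version = as.character(utils::packageVersion("pagseg")),
                   rng_seed = cfg$rng_seed,
                   n_subjects = cfg$n_subjects,
                   stage_seeds = list(
                     phantom = vapply(seq_len(cfg$n_subjects), function(i)
                       derive_seed(cfg$rng_seed, "phantom", i), integer(1)),
                     track = vapply(seq_len(cfg$n_subjects), function(i)
                       derive_seed(cfg$rng_seed, "track", i), integer(1)),
                     cluster = vapply(seq_len(cfg$n_subjects), function(i)
                       derive_seed(cfg$rng_seed, "cluster", i), integer(1)),
                     profiles = derive_seed(cfg$rng_seed, "profiles")),
                   outputs = list())

  if (!is.null(out_dir)) {
    cfg_file <- file.path(out_dir, "config.json")
    jsonlite::write_json(strip_config(cfg), cfg_file, auto_unbox = TRUE,
                         digits = NA)
    manifest$config_hash <- unname(tools::md5sum(cfg_file))

    write.table(profiles, file.path(out_dir, "column_profiles.tsv"),
                sep = "\t", row.names = FALSE, quote = FALSE)
    if (!is.null(tests)) {
      write.table(tests$pairwise, file.path(out_dir, "pairwise_tests.tsv"),
                  sep = "\t", row.names = FALSE, quote = FALSE)
      write.table(tests$multivariate,
                  file.path(out_dir, "multivariate_tests.tsv"),
                  sep = "\t", row.names = FALSE, quote = FALSE)
    }
    write.table(data.frame(column = names(success), success = success),
                file.path(out_dir, "success_rates.tsv"),
                sep = "\t", row.names = FALSE, quote = FALSE)
    for (cn in names(group_maps))
      write_volume(group_maps[[cn]]$values,
                   file.path(out_dir, paste0("groupmap_", cn, ".nii.gz")),
                   diag(4), cfg$phantom$voxel_size_mm)
    outs <- list.files(out_dir, full.names = TRUE)
    manifest$outputs <- as.list(setNames(unname(tools::md5sum(outs)),
                                         basename(outs)))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  list(manifest = manifest, cohort = cohort, template = template,
       subjects = subjects, profiles = profiles, tests = tests,
       success = success, group_maps = group_maps,
       backprojections = backprojections)
}

# config as plain JSON-serializable nested list
strip_config <- function(cfg) {
  cfg <- unclass(cfg)
  lapply(cfg, function(e) if (is.list(e)) strip_config(e) else e)
}
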