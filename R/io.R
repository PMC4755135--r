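#' Write a volume as NIfTI-1
#'
#' The world affine is the voxel-size scaling of the subject's
#' voxel-to-template transform, so template-space volumes and subject-space
#' volumes carry consistent headers.
#'
#' @param vol 3D array.
#' @param file output path (`.nii` or `.nii.gz`).
#' @param affine 4x4 voxel-to-template-voxel affine (default identity).
#' @param voxel_size_mm isotropic voxel size recorded in the header.
#' @return `file`, invisibly.
#' @export
write_volume <- function(vol, file, affine = diag(4), voxel_size_mm = 1.5) {
  world <- diag(c(rep(voxel_size_mm, 3), 1)) %*% affine
  im <- RNifti::asNifti(vol)
  im <- RNifti::`sform<-`(im, structure(world, code = 2L))
  RNifti::writeNifti(im, file)
  invisible(file)
}

#' Read a NIfTI volume as a plain array
#'
#' @param file path to a NIfTI file.
#' @return list: `data` (array), `affine` (4x4 world transform from the
#'   header).
#' @export
read_volume <- function(file) {
  im <- RNifti::readNifti(file)
  list(data = array(as.numeric(im), dim = dim(im)),
       affine = unclass(RNifti::xform(im))[1:4, 1:4])
}

#' Persist a connectivity matrix as text
#'
#' Sparse seed-by-brain-voxel counts go to MatrixMarket (`counts.mtx`), the
#' seed index and per-target sample counts to TSV, scalars to JSON.
#'
#' @param cm a `pag_connectivity`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_connectivity <- function(cm, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(cm$counts, file.path(dir, "counts.mtx"))
  si <- as.data.frame(cm$seed_coords)
  names(si) <- c("x", "y", "z")
  write.table(si, file.path(dir, "seed_index.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  tc <- as.data.frame(cm$target_counts)
  write.table(tc, file.path(dir, "target_counts.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  meta <- list(n_samples = cm$n_samples, grid_dim = cm$grid_dim,
               side = cm$side, prob_threshold = cm$prob_threshold,
               target_names = cm$target_names)
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' Load a connectivity matrix written by [write_connectivity()]
#'
#' @param dir directory containing `counts.mtx`, `seed_index.tsv`,
#'   `target_counts.tsv`, `meta.json`.
#' @return a `pag_connectivity`.
#' @export
read_connectivity <- function(dir) {
  if (!dir.exists(dir)) stop("connectivity directory not found: ", dir)
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  counts <- as(Matrix::readMM(file.path(dir, "counts.mtx")), "CsparseMatrix")
  si <- as.matrix(read.table(file.path(dir, "seed_index.tsv"), header = TRUE,
                             sep = "\t"))
  tc <- as.matrix(read.table(file.path(dir, "target_counts.tsv"), header = TRUE,
                             sep = "\t", check.names = FALSE))
  structure(list(seed_coords = si, counts = counts, target_counts = tc,
                 target_names = meta$target_names,
                 n_samples = meta$n_samples,
                 grid_dim = meta$grid_dim, side = meta$side,
                 prob_threshold = meta$prob_threshold),
            class = "pag_connectivity")
}

#' Write a phantom subject to a directory of NIfTI volumes
#'
#' Masks and truth labels as integer NIfTI volumes with the subject affine in
#' the header; a `subject.json` manifest with the shift, affine and seed.
#'
#' @param ph a `pag_phantom`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_phantom <- function(ph, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  vox <- ph$config$voxel_size_mm
  wv <- function(v, name)
    write_volume(array(as.integer(v), dim = dim(v)),
                 file.path(dir, paste0(name, ".nii.gz")),
                 ph$subject_affine, vox)
  wv(ph$brain_mask, "brain_mask")
  wv(ph$aqueduct_mask, "aqueduct_mask")
  wv(ph$seed_mask_left, "seed_mask_left")
  wv(ph$seed_mask_right, "seed_mask_right")
  wv(ph$truth_labels, "truth_labels")
  for (tn in names(ph$target_masks)) wv(ph$target_masks[[tn]], tn)
  jsonlite::write_json(
    list(rng_seed = ph$config$rng_seed, shift = ph$shift,
         subject_affine = ph$subject_affine, columns = ph$columns,
         seed_z = ph$seed_z, center = ph$center),
    file.path(dir, "subject.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a pipeline configuration from YAML
#'
#' Recognized sections: `phantom` (arguments of [phantom_config()]),
#' `tracking` ([tracking_params()]), `segmentation` (`k`, `cutoff`, `bin`,
#' `n_restarts`), `groupmap` (`threshold`), `n_subjects`, `rng_seed`.
#' Missing entries fall back to the package defaults.
#'
#' @param file YAML path.
#' @return a config list as produced by [pipeline_config()].
#' @export
read_pipeline_config <- function(file) {
  y <- yaml::read_yaml(file)
  pipeline_config(
    phantom = do.call(phantom_config, c(y$phantom, list())),
    tracking = do.call(tracking_params, c(y$tracking, list())),
    k = y$segmentation$k %||% 4L,
    cutoff = y$segmentation$cutoff %||% 0.25,
    bin = y$segmentation$bin %||% 3L,
    n_restarts = y$segmentation$n_restarts %||% 50L,
    groupmap_threshold = y$groupmap$threshold %||% 0.30,
    n_subjects = y$n_subjects %||% 19L,
    rng_seed = y$rng_seed %||% 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
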