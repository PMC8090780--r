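#' Write / read a cohort table as TSV
#'
#' Tab-separated, `NA` markers for missing clinical scores; lossless
#' round-trip of the columns produced by [generate_cohort()].
#'
#' @param cohort cohort data.frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.table(cohort, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, na.strings = "NA")
  if ("group" %in% names(df))
    df$group <- factor(df$group, levels = intersect(c("HC", "BP", "SZ"),
                                                    unique(df$group)))
  df
}

#' Write a binary mask as NIfTI
#' @param vs a [voxel_space()].
#' @param path output `.nii`/`.nii.gz` file.
#' @return `path`, invisibly.
#' @export
write_mask_nifti <- function(vs, path) {
  img <- RNifti::asNifti(array(as.integer(vs$mask), dim = vs$dims),
                         pixdim = vs$voxel_size)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a binary mask from NIfTI into a voxel space
#' @param path mask file.
#' @return A [voxel_space()].
#' @export
read_mask_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  vox <- RNifti::pixdim(img)[1:3]
  voxel_space(array(as.array(img) != 0, dim = dim(img)[1:3]), voxel_size = vox)
}

#' Write a subjects-by-voxels matrix as a 4D NIfTI stack
#'
#' In-mask values are embedded into the grid (background 0) and stored
#' as 32-bit float, the conventional precision for smoothed
#' gray-matter maps.
#'
#' @param mat subjects x voxels matrix (also accepts a single map as a
#'   vector).
#' @param vs a [voxel_space()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_maps_nifti <- function(mat, vs, path) {
  if (is.vector(mat)) mat <- matrix(mat, nrow = 1)
  stopifnot(ncol(mat) == n_voxels(vs))
  arr <- array(0, dim = c(vs$dims, nrow(mat)))
  stride <- prod(vs$dims)
  for (i in seq_len(nrow(mat)))
    arr[(i - 1L) * stride + vs$lin_index] <- mat[i, ]
  img <- RNifti::asNifti(arr, pixdim = vs$voxel_size, datatype = "float")
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a 4D NIfTI stack back into a subjects-by-voxels matrix
#'
#' @param path 3D or 4D NIfTI file.
#' @param vs the [voxel_space()] defining the mask; grid dimensions must
#'   match.
#' @return subjects x voxels matrix of in-mask values.
#' @export
read_maps_nifti <- function(path, vs) {
  arr <- as.array(RNifti::readNifti(path))
  d <- dim(arr)
  if (!identical(as.integer(d[1:3]), as.integer(vs$dims)))
    stop("volume dimensions do not match the mask")
  nsub <- if (length(d) == 3L) 1L else d[4]
  out <- matrix(NA_real_, nsub, n_voxels(vs))
  stride <- prod(vs$dims)
  for (i in seq_len(nsub))
    out[i, ] <- arr[(i - 1L) * stride + vs$lin_index]
  out
}

#' Pipeline run configuration
#'
#' All stage parameters and per-stage seeds in one round-trippable list.
#'
#' @param generator a [generator_config()] (or a list of overrides for
#'   one).
#' @param thresholds Z thresholds for extreme deviations.
#' @param fdr_q FDR level for the FDR-thresholded maps.
#' @param k_folds cross-validation folds for healthy subjects.
#' @param n_perm GLM permutations.
#' @param hyperparams GP hyperparameter mode, see [fit_normative()].
#' @param seeds named list of per-stage seeds (`simulate`, `fit`,
#'   `glm`).
#' @param out_dir output directory for [run_pipeline()].
#' @return A list of class `run_config`.
#' @export
run_config <- function(generator = generator_config(),
                       thresholds = c(1.96, 2.6, 3.1),
                       fdr_q = 0.05,
                       k_folds = 10L,
                       n_perm = 1000L,
                       hyperparams = "tied",
                       seeds = list(simulate = 1L, fit = 2L, glm = 3L),
                       out_dir = tempfile("normdev_run_")) {
  if (!inherits(generator, "generator_config"))
    generator <- do.call(generator_config, generator)
  stopifnot(all(thresholds > 0), k_folds >= 2, n_perm >= 100)
  structure(list(generator = generator, thresholds = thresholds,
                 fdr_q = fdr_q, k_folds = as.integer(k_folds),
                 n_perm = as.integer(n_perm), hyperparams = hyperparams,
                 seeds = seeds, out_dir = out_dir),
            class = "run_config")
}

#' Write / read a run configuration as YAML
#' @param config a [run_config()].
#' @param path YAML file path.
#' @return `path` / the re-read `run_config`.
#' @export
write_run_config <- function(config, path) {
  lst <- unclass(config)
  lst$generator <- unclass(lst$generator)
  lst$generator$lesion_rate <- as.list(lst$generator$lesion_rate)
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  lst <- yaml::read_yaml(path)
  gen <- lst$generator
  gen$age_ref <- NULL
  gen$lesion_rate <- unlist(gen$lesion_rate)
  lst$generator <- do.call(generator_config, gen)
  do.call(run_config, lst[c("generator", "thresholds", "fdr_q", "k_folds",
                            "n_perm", "hyperparams", "seeds", "out_dir")])
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  path
}

#' Run the full normative-deviation pipeline
#'
#' Executes simulate -> normative fit (10-fold CV for healthy subjects,
#' transfer of the all-healthy model to patients) -> deviation scoring ->
#' group statistics -> permutation GLM -> overlap mapping, writing every
#' artifact under `config$out_dir` and returning a manifest with MD5
#' checksums. Fully reproducible given the configuration.
#'
#' @param config a [run_config()].
#' @return A list with `manifest` (data.frame of files + checksums),
#'   `results` (in-memory stage outputs) — invisibly.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(...) file.path(config$out_dir, ...)
  files <- character(0)
  stage <- "simulate"
  res <- list()
  run_stage <- function(name, expr) {
    stage <<- name
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }

  run_stage("simulate", {
    gen <- config$generator
    gen$seed <- as.integer(config$seeds$simulate)
    class(gen) <- "generator_config"
    res$cohort <- generate_cohort(gen)
    vd <- generate_voxel_data(res$cohort, gen)
    res$voxel_space <- vd$voxel_space
    res$gm <- vd$gm
    res$truth <- vd$truth
    files <- c(files, write_cohort(res$cohort, out("cohort.tsv")),
                write_mask_nifti(vd$voxel_space, out("mask.nii.gz")),
                write_maps_nifti(vd$gm, vd$voxel_space, out("gm_4d.nii.gz")))
  })

  run_stage("fit", {
    hc <- res$cohort$group == "HC"
    cov_all <- res$cohort[, c("age", "sex")]
    cv <- crossvalidated_z(res$gm[hc, , drop = FALSE], cov_all[hc, ],
                           k = config$k_folds, seed = config$seeds$fit,
                           hyperparams = config$hyperparams)
    fit <- fit_normative(res$gm[hc, , drop = FALSE], cov_all[hc, ],
                         seed = config$seeds$fit,
                         hyperparams = config$hyperparams)
    pred_pat <- predict(fit, cov_all[!hc, , drop = FALSE])
    zp <- compute_z(res$gm[!hc, , drop = FALSE], pred_pat)
    Z <- matrix(NA_real_, nrow(res$gm), ncol(res$gm),
                dimnames = list(res$cohort$subject_id, NULL))
    Z[hc, ] <- cv$Z; Z[!hc, ] <- zp$Z
    res$fit <- fit
    res$dev <- structure(list(
      Z = Z,
      provenance = ifelse(hc, "cv", "transfer"),
      folds = cv$folds), class = "deviation_maps")
    res$slopes <- forward_model_slopes(fit)
    files <- c(files,
                write_maps_nifti(Z, res$voxel_space, out("zmaps_4d.nii.gz")),
                .write_tsv(data.frame(subject = res$cohort$subject_id,
                                      provenance = res$dev$provenance),
                           out("z_provenance.tsv")))
  })

  run_stage("deviate", {
    res$scores <- deviation_scores(res$dev, thresholds = config$thresholds,
                                    fdr_q = config$fdr_q)
    res$scores$group <- res$cohort$group[match(res$scores$subject,
                                                res$cohort$subject_id)]
    files <- c(files, .write_tsv(res$scores, out("deviation_scores.tsv")))
  })

  thr_main <- if (length(config$thresholds) >= 2) config$thresholds[2] else config$thresholds[1]

  run_stage("groupstats", {
    key <- sprintf("z%.2f", thr_main)
    sc <- res$scores[res$scores$threshold == key, ]
    cmp <- rbind(compare_groups(sc, "pct_negative"),
                 compare_groups(sc, "pct_positive"),
                 compare_groups(sc, "evs_stat"))
    panss <- res$cohort$panss_total[match(sc$subject, res$cohort$subject_id)]
    corr <- correlate_scores(sc$pct_negative, panss, sc$group)
    ratio <- prevalence_ratio(mean(sc$pct_negative[sc$group == "SZ"]),
                              mean(sc$pct_negative[sc$group == "HC"]))
    res$group_stats <- list(comparisons = cmp, panss_correlation = corr,
                             prevalence_ratio_sz_hc = ratio,
                             threshold = key)
    files <- c(files, .write_tsv(cmp, out("group_comparisons.tsv")),
                .write_tsv(corr, out("panss_correlations.tsv")))
  })

  run_stage("glm", {
    design <- group_design(res$cohort$group)
    res$glm <- permutation_inference(res$dev$Z, design,
                                      n_perm = config$n_perm,
                                      seed = config$seeds$glm)
    sig <- colSums(res$glm$p_fwer < 0.05)
    summ <- data.frame(contrast = colnames(res$glm$t),
                       max_t = apply(res$glm$t, 2, max),
                       n_fwer_sig = sig)
    files <- c(files, .write_tsv(summ, out("glm_summary.tsv")))
    for (gl in colnames(res$glm$group_mean_z))
      files <- c(files, write_maps_nifti(res$glm$group_mean_z[, gl],
                                          res$voxel_space,
                                          out(sprintf("mean_z_%s.nii.gz", gl))))
  })

  run_stage("overlap", {
    thr <- thr_main
    neg <- res$dev$Z < -thr
    pos <- res$dev$Z > thr
    om_neg <- overlap_map(neg, res$cohort$group, res$voxel_space)
    om_pos <- overlap_map(pos, res$cohort$group, res$voxel_space)
    strat <- stratified_overlap(neg, res$cohort$group, res$cohort$sex,
                                res$voxel_space)
    res$overlap <- list(negative = om_neg, positive = om_pos,
                         stratified = strat, threshold = thr)
    pk <- do.call(rbind, lapply(om_neg, function(m)
      data.frame(group = m$group, tail = "negative", n = m$n_subjects,
                 peak_pct = 100 * m$peak_value,
                 peak_i = m$peak_coords[1, 1], peak_j = m$peak_coords[1, 2],
                 peak_k = m$peak_coords[1, 3])))
    files <- c(files, .write_tsv(pk, out("overlap_peaks.tsv")))
    for (gl in names(om_neg))
      files <- c(files, write_maps_nifti(om_neg[[gl]]$proportion,
                                          res$voxel_space,
                                          out(sprintf("overlap_neg_%s.nii.gz", gl))))
  })

  cfg_path <- write_run_config(config, out("config.yaml"))
  files <- c(files, cfg_path)
  manifest <- data.frame(file = basename(unlist(files)),
                         md5 = unname(tools::md5sum(unlist(files))))
  jsonlite::write_json(list(seeds = config$seeds, files = manifest),
                       out("manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(list(manifest = manifest, results = res))
}
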