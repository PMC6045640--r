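# End-to-end pipeline: segment -> sub-volumes -> measurements -> planning
# volumes -> (optional) dose evaluation, with a reproducible run manifest.

#' Run the full delineation and quantification pipeline
#'
#' Loads a PET SUV volume, segments the tumor from the seed, partitions it
#' into metabolic sub-volumes (with the minimum-size merge rule), measures
#' them, expands planning margins, optionally evaluates a dose grid, and
#' writes all results plus a manifest sufficient to reproduce the run.
#'
#' @param pet_path path to the PET SUV NIfTI volume.
#' @param seed integer length-3 voxel index (1-based).
#' @param out_dir output directory (created if needed).
#' @param config_path optional YAML file of [mtv_control()] keys.
#' @param dose_path optional dose-grid NIfTI for plan evaluation.
#' @param dp prescribed dose in Gy (required when `dose_path` is given).
#' @param vx_thresholds Vx thresholds in Gy for the dose report.
#' @param control optional [mtv_control()] overriding `config_path`.
#' @return Invisibly, a list with the segmentation, partition, report, PTVs,
#'   metrics and manifest.
#' @export
run_pipeline <- function(pet_path, seed, out_dir, config_path = NULL,
                         dose_path = NULL, dp = 60,
                         vx_thresholds = c(60), control = NULL) {
  if (is.null(control))
    control <- read_control(config_path)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- proc.time()[["elapsed"]]
  vol <- load_volume(pet_path)
  seg <- segment_tumor(vol, seed, control)
  part <- partition_subvolumes(vol, seg$tumor)
  part <- merge_small_components(part, control$merge_min_voxels)
  report <- measure_subvolumes(part)
  ptvs <- subvolume_ptvs(part, control$margin_mm)

  save_volume(seg$tumor, file.path(out_dir, "tumor.nii.gz"))
  save_volume(seg$ms, file.path(out_dir, "masking_surface.nii.gz"))
  save_volume(part$class_map, file.path(out_dir, "subvolumes.nii.gz"))
  save_volume(ptvs$exclusive, file.path(out_dir, "ptv_classes.nii.gz"))
  jsonlite::write_json(list(labels = list(`0` = "outside", `1` = "low",
                                          `2` = "mod", `3` = "high")),
                       file.path(out_dir, "subvolumes_legend.json"),
                       auto_unbox = TRUE)
  rep_df <- data.frame(class = report$class,
                       ml = sprintf("%.2f", report$ml),
                       percent = sprintf("%.2f", report$percent))
  utils::write.csv(rep_df, file.path(out_dir, "subvolume_report.csv"),
                   row.names = FALSE)

  metrics <- list(suv_max = seg$suv_max,
                  tumor_ml = sum(seg$tumor$labels != 0L) *
                    prod(vol$spacing) / 1000,
                  boundary_suv_pct_of_max =
                    unname(stats::quantile(seg$boundary_suv / seg$suv_max,
                                           c(0.05, 0.5, 0.95)) * 100))
  if (!is.null(dose_path)) {
    dose <- load_volume(dose_path)
    pm <- dose_metrics(dose, seg$tumor, dp = dp,
                       vx_thresholds = vx_thresholds,
                       bin_width_gy = control$dvh_bin_gy)
    utils::write.csv(data.frame(dose_gy = pm$dvh$dose_gy,
                                volume_fraction = pm$dvh$volume_fraction),
                     file.path(out_dir, "dvh.csv"), row.names = FALSE)
    metrics$plan <- list(d2 = pm$d2, d98 = pm$d98, dmean = pm$dmean,
                         hi_rtog = pm$hi_rtog, hi_d2d98 = pm$hi_d2d98,
                         vx = as.list(pm$vx), compliant = pm$compliant)
  }
  jsonlite::write_json(metrics, file.path(out_dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA)

  manifest <- list(
    package_version = as.character(utils::packageVersion("mtvseg")),
    r_version = R.version.string,
    inputs = list(pet = unname(tools::md5sum(pet_path)),
                  dose = if (is.null(dose_path)) NULL
                         else unname(tools::md5sum(dose_path)),
                  seed = as.integer(seed)),
    control = unclass(control),
    timings = list(total_s = proc.time()[["elapsed"]] - t0,
                   stage1_s = unname(seg$timings["stage1"]),
                   stage2_s = unname(seg$timings["stage2"])),
    outputs = as.list(tools::md5sum(list.files(out_dir, full.names = TRUE,
                                               pattern = "\\.(nii|gz|csv|json)$")))
  )
  manifest$outputs[[file.path(out_dir, "manifest.json")]] <- NULL
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(list(segmentation = seg, partition = part, report = report,
                 ptvs = ptvs, metrics = metrics, manifest = manifest))
}

#' Write a phantom scene to disk
#'
#' Convenience used by the command-line interface: generates a phantom and
#' writes `pet.nii.gz`, `truth_tumor.nii.gz`, `truth_organ.nii.gz` and
#' `seed.json` under an output prefix.
#'
#' @param spec a [phantom_spec()].
#' @param out_prefix output path prefix.
#' @return Invisibly, the generated scene.
#' @export
write_phantom <- function(spec, out_prefix) {
  ph <- generate_phantom(spec)
  dir.create(dirname(out_prefix), showWarnings = FALSE, recursive = TRUE)
  save_volume(ph$vol, paste0(out_prefix, "_pet.nii.gz"))
  save_volume(ph$truth_tumor, paste0(out_prefix, "_truth_tumor.nii.gz"))
  save_volume(ph$truth_organ, paste0(out_prefix, "_truth_organ.nii.gz"))
  jsonlite::write_json(list(seed = as.integer(ph$seed)),
                       paste0(out_prefix, "_seed.json"), auto_unbox = TRUE)
  invisible(ph)
}
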