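#' Desk-scale experiment profile
#'
#' A scaled-down counterpart of the reference training setup, sized for a
#' single CPU: a cohort of 20 phantoms (64^3 voxels at 0.3 mm isotropic,
#' two vessels of radius 0.5-1.2 mm, one aneurysm per case drawn from the
#' clinical size mixture and capped at 8 mm so every bulge fits a 32^3
#' patch), 32^3 patches, a depth-2 residual attention U-Net with 8 base
#' channels, two positive patches per aneurysm, flips as augmentation, and
#' 4 epochs of Adam at learning rate 2e-3 with batch size 2 and
#' best-validation checkpointing. The full-scale profile (64^3 patches,
#' depth 4, 16 base channels, batch 16, 500 epochs, learning rate 1e-3)
#' remains available through the individual configuration objects.
#'
#' @param master_seed integer seed for the whole experiment.
#' @param ratios ratio sweep (normals per aneurysm patch).
#' @param aux auxiliary-classifier sweep.
#' @param n_cases cohort size.
#' @param epochs training epochs.
#' @param out_dir optional persistence directory.
#' @return an [experiment_config()].
#' @export
desk_experiment_config <- function(master_seed = 1L, ratios = 2L,
                                   aux = c(TRUE, FALSE), n_cases = 20L,
                                   epochs = 4L, out_dir = NULL) {
  experiment_config(
    n_cases = n_cases,
    phantom = list(volume_shape = c(64, 64, 64),
                   spacing_mm = c(0.3, 0.3, 0.3),
                   n_vessels = 2,
                   vessel_radius_range_mm = c(0.5, 1.2),
                   n_aneurysms = 1,
                   aneurysm_diameter_range_mm = c(1.8, 8),
                   rician_sigma = 15,
                   bias_amplitude = 0.2),
    preprocess = preprocess_config(target_spacing_mm = c(0.3, 0.3, 0.3)),
    skeleton = skeleton_config(threshold_strategy = "auto",
                               min_component_voxels = 300,
                               closing_radius_vox = 1),
    plan = sampling_plan(patch_size = c(32, 32, 32), ratio = 2L,
                         n_positive_per_aneurysm = 2L,
                         min_negative_distance_mm = 5),
    network = network_spec(depth = 2L, base_channels = 8L,
                           block_style = "residual", attention = TRUE),
    train = train_config(batch_size = 2L, epochs = epochs, lr = 2e-3,
                         augment = augmentation_policy(
                           transforms = c("flip_h", "flip_v"))),
    loss = loss_config(),
    ratios = ratios, aux = aux,
    master_seed = master_seed, out_dir = out_dir)
}

#' Auxiliary-loss ablation study at desk scale
#'
#' Repeats the (ratio 1:2) auxiliary-loss comparison over several master
#' seeds — each seed generates its own phantom cohort, splits and model
#' initialization — and pools held-out test-case Dice coefficients per arm.
#' This mirrors, at phantom scale, the reference comparison between the
#' plain 3D U-Net and the multi-task variant with auxiliary classifiers.
#'
#' @param seeds integer vector of master seeds.
#' @param ratio normal : aneurysm patch ratio used in both arms.
#' @param n_cases phantom cohort size per seed.
#' @param epochs training epochs.
#' @return list with `per_seed` (data.frame: seed, aux, case, dsc,
#'   accuracy), `median_dsc_aux`, `median_dsc_noaux`, `max_dsc_aux`,
#'   `max_dsc_noaux` and `accuracy` (mean patch-level accuracy per arm).
#' @export
aux_ablation_study <- function(seeds = c(101L, 102L, 103L), ratio = 2L,
                               n_cases = 20L, epochs = 4L) {
  rows <- list()
  for (s in seeds) {
    cfg <- desk_experiment_config(master_seed = s, ratios = ratio,
                                  aux = c(TRUE, FALSE), n_cases = n_cases,
                                  epochs = epochs)
    res <- run_experiment(cfg)
    for (id in names(res$cells)) {
      cell <- res$cells[[id]]
      rows[[paste(s, id)]] <- data.frame(
        seed = s, aux = cell$aux,
        case = cell$scores$case_id, dsc = cell$scores$dsc,
        panel_accuracy = cell$panel[["accuracy"]],
        stringsAsFactors = FALSE)
    }
  }
  per_seed <- do.call(rbind, rows)
  rownames(per_seed) <- NULL
  dsc_aux <- per_seed$dsc[per_seed$aux]
  dsc_noaux <- per_seed$dsc[!per_seed$aux]
  list(per_seed = per_seed,
       median_dsc_aux = median(dsc_aux, na.rm = TRUE),
       median_dsc_noaux = median(dsc_noaux, na.rm = TRUE),
       max_dsc_aux = max(dsc_aux, na.rm = TRUE),
       max_dsc_noaux = max(dsc_noaux, na.rm = TRUE),
       accuracy = c(
         aux = mean(per_seed$panel_accuracy[per_seed$aux], na.rm = TRUE),
         noaux = mean(per_seed$panel_accuracy[!per_seed$aux], na.rm = TRUE)))
}
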