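#' Experiment configuration
#'
#' Bundles every stage of a seeded end-to-end experiment on synthetic
#' phantoms: phantom generation, preprocessing, skeletonization, patch
#' sampling, network architecture, training, and the ratio / auxiliary-loss
#' ablation grid. Cases are split by case (never by patch) into
#' train/validation/test using the 120 : 19 : 15 proportions with
#' largest-remainder rounding; all sweep cells share the same cohort and
#' splits so ratio and auxiliary-loss effects are paired.
#'
#' @param n_cases number of phantom cases in the cohort.
#' @param phantom named list of [phantom_spec()] argument overrides applied
#'   to every case (per-case seeds are derived from `master_seed`).
#' @param preprocess a [preprocess_config()].
#' @param skeleton a [skeleton_config()].
#' @param plan a [sampling_plan()]; its `ratio` is overridden by the sweep.
#' @param network a [network_spec()]; its `aux_tap_levels` is overridden by
#'   the sweep.
#' @param train a [train_config()].
#' @param loss a [loss_config()].
#' @param ratios integer vector of normal-per-aneurysm ratios to sweep
#'   (1..5).
#' @param aux logical vector of auxiliary-classifier settings to sweep.
#' @param split_fractions relative train/validation/test sizes.
#' @param master_seed one seed fans out to phantoms, sampling, model
#'   initialization and training.
#' @param out_dir optional directory for persisted results (report CSV/JSON
#'   and per-cell artifacts); cells found on disk are reused (resume).
#' @return an object of class `experiment_config`.
#' @export
experiment_config <- function(n_cases = 20L,
                              phantom = list(),
                              preprocess = preprocess_config(),
                              skeleton = skeleton_config(threshold_strategy = "auto"),
                              plan = sampling_plan(),
                              network = network_spec(),
                              train = train_config(),
                              loss = loss_config(),
                              ratios = 2L,
                              aux = TRUE,
                              split_fractions = c(120, 19, 15),
                              master_seed = 1L,
                              out_dir = NULL) {
  stopifnot(n_cases >= 3, length(ratios) >= 1, length(aux) >= 1,
            all(ratios >= 1), all(ratios <= 5),
            length(split_fractions) == 3, all(split_fractions > 0))
  structure(list(n_cases = as.integer(n_cases), phantom = phantom,
                 preprocess = preprocess, skeleton = skeleton, plan = plan,
                 network = network, train = train, loss = loss,
                 ratios = as.integer(ratios), aux = as.logical(aux),
                 split_fractions = split_fractions,
                 master_seed = as.integer(master_seed), out_dir = out_dir),
            class = "experiment_config")
}

#' Split case counts by largest-remainder rounding
#'
#' Counts are `floor(n * f / sum(f))` with the remaining cases assigned in
#' order of largest fractional remainder. When `n >= length(fractions)`,
#' every split is additionally guaranteed at least one case (taken from the
#' largest split), so small cohorts always retain a validation and test
#' case.
#'
#' @param n number of cases.
#' @param fractions relative split sizes (e.g. `c(120, 19, 15)`).
#' @return integer vector of counts summing to `n`.
#' @export
split_counts <- function(n, fractions = c(120, 19, 15)) {
  raw <- n * fractions / sum(fractions)
  base <- floor(raw)
  extra <- n - sum(base)
  if (extra > 0) {
    ord <- order(raw - base, decreasing = TRUE)
    base[ord[seq_len(extra)]] <- base[ord[seq_len(extra)]] + 1
  }
  while (n >= length(fractions) && any(base == 0)) {
    i <- which(base == 0)[1]
    j <- which.max(base)
    base[i] <- base[i] + 1
    base[j] <- base[j] - 1
  }
  as.integer(base)
}

#' Prepare one case for sampling and evaluation
#'
#' Runs preprocessing on the image, resamples the ground-truth aneurysm
#' mask to the target grid, and extracts the vessel skeleton.
#'
#' @param case a `phantom_case` (or a list with `image`, `aneurysm_mask`).
#' @param cfg an [experiment_config()] (its preprocess/skeleton configs are
#'   used).
#' @param case_id identifier.
#' @return list with `case_id`, `image`, `aneurysm_mask`, `skeleton`,
#'   `vessel_mask` and `diameter_mm` (max aneurysm diameter, NA if none).
#' @export
prepare_case <- function(case, cfg, case_id = "case") {
  img <- preprocess_volume(case$image, cfg$preprocess)
  amask <- resample_isotropic(case$aneurysm_mask,
                              cfg$preprocess$target_spacing_mm)
  sk <- vessel_skeleton(img, cfg$skeleton)
  diam <- if (length(case$aneurysm_centers %||% list()) > 0)
    max(vapply(case$aneurysm_centers, function(a) a$diameter_mm, 0))
  else NA_real_
  list(case_id = case_id, image = img, aneurysm_mask = amask,
       skeleton = sk$skeleton, vessel_mask = sk$mask, diameter_mm = diam)
}

cell_id <- function(ratio, aux) sprintf("ratio%d_aux%s", ratio,
                                        if (aux) "on" else "off")

# Train and evaluate one sweep cell on prepared splits.
run_cell <- function(prep, splits, cfg, ratio, aux_on) {
  cseed <- derive_seed(cfg$master_seed, 101L * ratio + as.integer(aux_on))
  plan <- cfg$plan
  plan$ratio <- as.integer(ratio)
  plan$seed <- cseed
  net_spec <- cfg$network
  net_spec$aux_tap_levels <- if (aux_on) c("bridge", "mid") else character(0)
  loss_cfg <- cfg$loss
  if (!aux_on) loss_cfg$aux_weight <- 0
  train_set <- build_dataset(prep[splits$train], plan)
  val_plan <- plan
  val_plan$seed <- derive_seed(cseed, 5L)
  val_set <- suppressWarnings(
    build_dataset(prep[splits$val], val_plan, strict_ratio = FALSE))
  model <- build_model(net_spec, seed = derive_seed(cseed, 9L))
  tcfg <- cfg$train
  tcfg$seed <- derive_seed(cseed, 13L)
  fit <- train_network(model, train_set, val_set, tcfg, loss_cfg)
  # case-level segmentation on held-out test cases
  ps <- plan$patch_size
  test_prep <- prep[splits$test]
  gt <- lapply(test_prep, function(p) p$aneurysm_mask)
  pred <- lapply(test_prep, function(p)
    predict_volume(fit$model, p$image, p$skeleton, patch_size = ps,
                   stride = ps %/% 2L)$mask)
  scores <- seg_scores(gt, pred,
                       vapply(test_prep, function(p) p$case_id, ""))
  # patch-level classification panel on test patches
  test_plan <- plan
  test_plan$seed <- derive_seed(cseed, 17L)
  test_set <- suppressWarnings(
    build_dataset(test_prep, test_plan, require_positives = FALSE,
                  strict_ratio = FALSE))
  cls <- classify_patches(fit$model, test_set)
  panel <- metric_panel(confusion_from_patches(cls$prob, cls$label))
  case_acc <- vapply(test_prep, function(p) {
    sel <- test_set$manifest$case_id == p$case_id
    if (!any(sel)) return(NA_real_)
    mean(cls$pred[sel] == cls$label[sel])
  }, 0)
  list(ratio = ratio, aux = aux_on, panel = panel, scores = scores,
       case_accuracy = case_acc,
       diameters = vapply(test_prep, function(p) p$diameter_mm, 0),
       history = fit$history, model = fit$model)
}

#' Run a full seeded experiment
#'
#' Generates the phantom cohort, preprocesses and skeletonizes every case,
#' splits by case, then trains and evaluates one model per (ratio,
#' auxiliary-loss) sweep cell. Emits a report grid with one row per cell:
#' accuracy, specificity, PPV, NPV, sensitivity (patch level) and DSC mean
#' +- sd (case level, over aneurysm-bearing test cases). Deterministic
#' given `master_seed`; a failing cell is marked failed and the sweep
#' continues.
#'
#' @param cfg an [experiment_config()].
#' @return an object of class `experiment_result`: list with `report`
#'   (data.frame), `cells` (per-cell details), `splits` and `case_info`.
#' @export
run_experiment <- function(cfg) {
  stopifnot(inherits(cfg, "experiment_config"))
  t0 <- Sys.time()
  stage <- function(what)
    message(sprintf("[skelpatch] %-10s seed %d  +%.1fs", what,
                    cfg$master_seed,
                    as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  stage("phantoms")
  cases <- lapply(seq_len(cfg$n_cases), function(i) {
    args <- cfg$phantom
    args$seed <- derive_seed(cfg$master_seed, i)
    generate_phantom(do.call(phantom_spec, args))
  })
  stage("prepare")
  prep <- lapply(seq_along(cases), function(i)
    prepare_case(cases[[i]], cfg, case_id = sprintf("case%03d", i)))
  counts <- split_counts(cfg$n_cases, cfg$split_fractions)
  ord <- with_seed(derive_seed(cfg$master_seed, 999L),
                   sample.int(cfg$n_cases))
  splits <- list(train = sort(ord[seq_len(counts[1])]),
                 val = sort(ord[counts[1] + seq_len(counts[2])]),
                 test = sort(ord[counts[1] + counts[2] + seq_len(counts[3])]))
  if (!is.null(cfg$out_dir))
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  cells <- list()
  rows <- list()
  for (ratio in cfg$ratios) {
    for (aux_on in cfg$aux) {
      id <- cell_id(ratio, aux_on)
      cell_file <- if (!is.null(cfg$out_dir))
        file.path(cfg$out_dir, paste0(id, ".json")) else NULL
      cell <- NULL
      if (!is.null(cell_file) && file.exists(cell_file)) {
        saved <- jsonlite::read_json(cell_file, simplifyVector = TRUE)
        rows[[id]] <- as.data.frame(saved$row, stringsAsFactors = FALSE)
        cells[[id]] <- saved
        next
      }
      stage(id)
      cell <- tryCatch(run_cell(prep, splits, cfg, ratio, aux_on),
                       error = function(e) e)
      if (inherits(cell, "error")) {
        warning(sprintf("cell %s failed: %s", id, conditionMessage(cell)))
        rows[[id]] <- data.frame(
          ratio = ratio, aux = aux_on, status = "failed",
          accuracy = NA_real_, specificity = NA_real_, ppv = NA_real_,
          npv = NA_real_, sensitivity = NA_real_,
          dsc_mean = NA_real_, dsc_sd = NA_real_)
        next
      }
      row <- data.frame(
        ratio = ratio, aux = aux_on, status = "ok",
        accuracy = cell$panel[["accuracy"]],
        specificity = cell$panel[["specificity"]],
        ppv = cell$panel[["ppv"]],
        npv = cell$panel[["npv"]],
        sensitivity = cell$panel[["sensitivity"]],
        dsc_mean = attr(cell$scores, "mean_dsc"),
        dsc_sd = attr(cell$scores, "std_dsc"))
      rows[[id]] <- row
      cells[[id]] <- cell
      if (!is.null(cell_file)) {
        jsonlite::write_json(
          list(row = as.list(row),
               per_case_dsc = cell$scores$dsc,
               case_accuracy = cell$case_accuracy),
          cell_file, auto_unbox = TRUE, digits = NA)
        save_model(cell$model,
                   file.path(cfg$out_dir, paste0(id, "_model.rds")))
        write.csv(cell$history,
                  file.path(cfg$out_dir, paste0(id, "_history.csv")),
                  row.names = FALSE)
      }
    }
  }
  report <- do.call(rbind, rows)
  rownames(report) <- NULL
  if (!is.null(cfg$out_dir)) {
    write.csv(report, file.path(cfg$out_dir, "report.csv"),
              row.names = FALSE)
    jsonlite::write_json(report, file.path(cfg$out_dir, "report.json"),
                         dataframe = "rows", auto_unbox = TRUE, digits = NA)
  }
  structure(list(report = report, cells = cells, splits = splits,
                 case_info = data.frame(
                   case_id = vapply(prep, function(p) p$case_id, ""),
                   diameter_mm = vapply(prep, function(p) p$diameter_mm, 0),
                   skeleton_voxels = vapply(prep, function(p)
                     nrow(p$skeleton$coords), 0L))),
            class = "experiment_result")
}

#' @export
print.experiment_result <- function(x, ...) {
  cat("Experiment report (one row per sweep cell):\n")
  print(x$report)
  invisible(x)
}
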