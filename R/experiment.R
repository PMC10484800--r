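#' Build the four-class and reference mu-maps for a phantom
#'
#' Convenience wrapper for the mu-map stage of the workflow: segments the
#' Dixon pair into the four-class map (body contour from the in-phase
#' image), scales the CT to LAC, and inserts CT bone above the LAC threshold
#' within the pelvic mask to form the reference map.
#'
#' @param phantom A `phantom`.
#' @param transform A [hu_lac_transform()].
#' @param threshold_lac Bone-definition LAC threshold (cm^-1).
#' @return List with `mu4c`, `muref` (`mu_map`s) and `ct_lac`.
#' @export
phantom_mumaps <- function(phantom, transform = hu_lac_transform(),
                           threshold_lac = 0.1) {
  body <- body_contour_mask(phantom$dixon_ip)
  mu4c <- four_class_mumap(phantom$dixon_ip, phantom$dixon_op, body)
  ct_lac <- hu_to_lac(phantom$ct, transform)
  muref <- insert_bone(mu4c, ct_lac, phantom$pelvic_mask, threshold_lac)
  list(mu4c = mu4c, muref = muref, ct_lac = ct_lac)
}

#' Configuration of an end-to-end correction study
#'
#' Bundles every stage's settings. Train, validation and test phantoms are
#' generated from disjoint seed ranges so the splits differ anatomically.
#'
#' @param phantom Template [phantom_spec()] (its seed is overridden per
#'   phantom).
#' @param recon A [recon_config()].
#' @param net A [net_config()].
#' @param n_train,n_val,n_test Phantom counts per split.
#' @param seed Base seed; split seeds are derived from it disjointly.
#' @param act_floor_bqml Activity floor for correction maps and evaluation.
#' @param clamp_range Clamp interval for predicted maps.
#' @return A list of class `experiment_config`.
#' @export
experiment_config <- function(phantom = phantom_spec(),
                              recon = recon_config(),
                              net = net_config(),
                              n_train = 8, n_val = 2, n_test = 4,
                              seed = 1, act_floor_bqml = 300,
                              clamp_range = c(-2, 1)) {
  cfg <- list(phantom = phantom, recon = recon, net = net,
              n_train = as.integer(n_train), n_val = as.integer(n_val),
              n_test = as.integer(n_test), seed = as.integer(seed),
              act_floor_bqml = act_floor_bqml, clamp_range = clamp_range)
  class(cfg) <- "experiment_config"
  if (cfg$n_train < 1 || cfg$n_test < 1) stop("need train and test phantoms")
  cfg
}

split_seeds <- function(cfg) {
  base <- cfg$seed * 10000L
  list(train = base + seq_len(cfg$n_train),
       val = base + 1000L + seq_len(cfg$n_val),
       test = base + 2000L + seq_len(cfg$n_test))
}

phantom_with_seed <- function(template, seed) {
  template$seed <- as.integer(seed)
  generate_phantom(template)
}

# run every per-phantom stage: mu-maps, PET pair, exact correction map
process_phantom <- function(ph, cfg) {
  mm <- phantom_mumaps(ph)
  pets <- simulate_pet_pair(ph, mm$mu4c, mm$muref, cfg$recon)
  cmap <- compute_correction_map(pets$pet_4c, pets$pet_ctmr, ph$pelvic_mask,
                                 cfg$act_floor_bqml)
  list(phantom = ph, mu4c = mm$mu4c, muref = mm$muref,
       pet_4c = pets$pet_4c, pet_ctmr = pets$pet_ctmr, cmap = cmap)
}

evaluate_test_case <- function(case, net, cfg) {
  pred <- predict_correction_map(net, case$phantom, case$mu4c,
                                 clamp_range = cfg$clamp_range)
  pet_cor <- apply_correction_map(case$pet_4c, pred)
  m <- lapply(list(pet_4c = case$pet_4c, pet_cor = pet_cor),
              function(img) {
                re <- relative_error_image(img, case$pet_ctmr,
                                           case$phantom$pelvic_mask,
                                           cfg$act_floor_bqml)
                compute_metrics(re)
              })
  lesions <- lesion_metrics(case$phantom$lesions,
                            list(pet_4c = case$pet_4c, pet_cor = pet_cor,
                                 pet_ctmr = case$pet_ctmr))
  list(pet_cor = pet_cor, pred_cmap = pred, metrics = m, lesions = lesions)
}

#' Run the full correction study in memory
#'
#' Generates the phantom splits, simulates the PET pairs, trains the
#' network on the exact correction maps of the training split, predicts and
#' applies correction maps on the held-out split, and evaluates voxel- and
#' lesion-level errors.
#'
#' @param cfg An [experiment_config()].
#' @param verbose Log stage progress?
#' @return A list: `voxel_metrics` (data.frame, one row per test phantom and
#'   method), `lesion_metrics` (data.frame), `comparison` (paired test, when
#'   enough test subjects), `net` (trained network), `test_cases`.
#' @export
run_correction_study <- function(cfg, verbose = FALSE) {
  seeds <- split_seeds(cfg)
  say <- function(fmt, ...) if (verbose) message(sprintf(fmt, ...))
  stage <- function(what, code) {
    t0 <- Sys.time()
    r <- code
    say("%-28s %6.1f s", what, as.numeric(difftime(Sys.time(), t0, "secs")))
    r
  }
  prep_split <- function(sds, label) stage(
    sprintf("simulate %s (%d phantoms)", label, length(sds)),
    lapply(sds, function(s) process_phantom(phantom_with_seed(cfg$phantom, s),
                                            cfg)))
  train_cases <- prep_split(seeds$train, "train")
  val_cases <- if (cfg$n_val > 0) prep_split(seeds$val, "val") else list()
  test_cases <- prep_split(seeds$test, "test")

  flatten_samples <- function(cases)
    do.call(c, lapply(cases, function(cs)
      make_training_samples(cs$phantom, cs$mu4c, cs$cmap)))
  tr_samples <- flatten_samples(train_cases)
  va_samples <- if (length(val_cases)) flatten_samples(val_cases) else NULL
  say("training on %d slices, validating on %d", length(tr_samples),
      length(va_samples))
  net <- build_network(cfg$net)
  net <- stage("train network", train_network(net, tr_samples, va_samples,
                                              verbose = verbose))

  evals <- stage("evaluate test split",
                 lapply(test_cases, evaluate_test_case, net = net, cfg = cfg))
  vox <- do.call(rbind, lapply(seq_along(evals), function(i) {
    do.call(rbind, lapply(names(evals[[i]]$metrics), function(nm) {
      m <- evals[[i]]$metrics[[nm]]
      data.frame(phantom = i, image = nm, mape = m$mape, rmspe = m$rmspe,
                 mu_re = m$mu_re, sigma_re = m$sigma_re, n_mask = m$n_mask)
    }))
  }))
  les <- do.call(rbind, lapply(seq_along(evals), function(i) {
    df <- evals[[i]]$lesions
    if (is.null(df) || !nrow(df)) return(NULL)
    df$phantom <- i
    df
  }))
  comparison <- NULL
  r4 <- vox$rmspe[vox$image == "pet_4c"]
  rc <- vox$rmspe[vox$image == "pet_cor"]
  if (length(r4) >= 5) comparison <- paired_compare(rc, list(pet_4c = r4))
  list(voxel_metrics = vox, lesion_metrics = les, comparison = comparison,
       net = net, test_cases = test_cases, evals = evals, config = cfg)
}

#' Run a correction study and persist every artifact to disk
#'
#' Wraps [run_correction_study()]: writes the test-split volumes (PET pairs,
#' corrected PET, exact and predicted correction maps) as NIfTI, the metric
#' tables as CSV, the training history as CSV, and a machine-readable
#' summary JSON into `out_dir`.
#'
#' @param cfg An [experiment_config()].
#' @param out_dir Output directory.
#' @param verbose Log stage progress?
#' @return The study result list, invisibly; `summary` element added.
#' @export
run_experiment <- function(cfg, out_dir, verbose = TRUE) {
  stopifnot(inherits(cfg, "experiment_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  res <- run_correction_study(cfg, verbose = verbose)
  for (i in seq_along(res$test_cases)) {
    cs <- res$test_cases[[i]]
    ev <- res$evals[[i]]
    pdir <- file.path(out_dir, sprintf("test_phantom_%02d", i))
    write_phantom(cs$phantom, pdir)
    write_mumap(cs$mu4c, file.path(pdir, "mu_4c.nii.gz"))
    write_mumap(cs$muref, file.path(pdir, "mu_ref.nii.gz"))
    write_volume(cs$pet_4c, file.path(pdir, "pet_4c.nii.gz"))
    write_volume(cs$pet_ctmr, file.path(pdir, "pet_ctmr.nii.gz"))
    write_volume(ev$pet_cor, file.path(pdir, "pet_cor.nii.gz"))
    write_correction_map(cs$cmap, file.path(pdir, "cmap_exact.nii.gz"))
    write_correction_map(ev$pred_cmap, file.path(pdir, "cmap_pred.nii.gz"))
  }
  utils::write.csv(res$voxel_metrics, file.path(out_dir, "voxel_metrics.csv"),
                   row.names = FALSE)
  if (!is.null(res$lesion_metrics))
    utils::write.csv(res$lesion_metrics,
                     file.path(out_dir, "lesion_metrics.csv"),
                     row.names = FALSE)
  utils::write.csv(res$net$history, file.path(out_dir, "loss_history.csv"),
                   row.names = FALSE)
  save_network(res$net, file.path(out_dir, "model.rds"))
  summ <- summarize_study(res)
  jsonlite::write_json(summ, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  res$summary <- summ
  invisible(res)
}

#' Summarize a study as median [min, max] per method
#' @param res Result of [run_correction_study()].
#' @return A list suitable for JSON serialization.
#' @export
summarize_study <- function(res) {
  vox <- res$voxel_metrics
  by_img <- split(vox, vox$image)
  vox_summary <- lapply(by_img, function(df)
    list(rmspe_median = stats::median(df$rmspe),
         rmspe_range = range(df$rmspe),
         mape_median = stats::median(df$mape),
         mape_range = range(df$mape),
         rmspe = median_range(df$rmspe),
         mape = median_range(df$mape)))
  les_summary <- NULL
  if (!is.null(res$lesion_metrics) && nrow(res$lesion_metrics)) {
    les <- res$lesion_metrics
    grp <- split(les, list(les$image, les$tissue_class), drop = TRUE)
    les_summary <- lapply(grp, function(df)
      list(n = nrow(df),
           abs_pct_error_median = stats::median(df$abs_pct_error),
           rel_error_median = stats::median(df$rel_error),
           abs_pct_error = median_range(df$abs_pct_error),
           rel_error = median_range(df$rel_error)))
  }
  list(voxel = vox_summary, lesion = les_summary,
       comparison = res$comparison,
       n_test = length(res$test_cases))
}
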