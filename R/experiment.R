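#' Reconstruct a sinogram with a trained network
#'
#' @param net A `hier_net` or the path of a [save_checkpoint()] directory.
#' @param sino A [sinogram()], a value matrix, or the path of a
#'   [write_ct_bundle()] directory containing a sinogram. The geometry must
#'   match the checkpoint's schedule.
#' @param intermediates Also return each stage's partial images.
#' @return As [net_forward()].
#' @export
reconstruct <- function(net, sino, intermediates = FALSE) {
  if (is.character(net)) net <- load_checkpoint(net)
  if (is.character(sino)) sino <- read_ct_bundle(sino)$sino
  if (inherits(sino, "sinogram")) {
    sc <- net$schedule
    g <- sino$geom
    if (g$n_angles != sc$n_angles || g$n_channels != sc$n_radial ||
        abs(g$fov - sc$fov) > 1e-9 * sc$fov) {
      stop("reconstruct: sinogram geometry does not match the checkpoint")
    }
  }
  net_forward(net, sino, intermediates = intermediates)
}

.require_fields <- function(config, fields) {
  miss <- setdiff(fields, names(config))
  if (length(miss) > 0) {
    stop("run_experiment: missing config field(s): ",
         paste(miss, collapse = ", "),
         " (required: ", paste(fields, collapse = ", "), ")")
  }
}

#' Run a complete scaled experiment from a configuration
#'
#' Executes the full workflow: plan the stage schedule, build the network,
#' generate the noise training set and its intermediate labels, pretrain
#' stage-wise, train end-to-end on noise (linear mode), optionally refine
#' with noisy reprojected phantoms (nonlinear mode), and evaluate on held-out
#' ellipse phantoms against the ground truth and the FBP reference. All
#' randomness derives from the single `seed` field. Artifacts (checkpoint,
#' loss history, metrics, manifest) are written under `out_dir`.
#'
#' @param config A YAML file path or a named list with fields `image_size`,
#'   `n_angles`, `n_radial`, `n_stages`, `n_noise`, `n_test`, `seed`, and
#'   optionally `epochs`, `epochs_pretrain`, `batch_size`, `lr`, `lr_filter`,
#'   `refine` (logical), `n_refine`, `noise_level`, `out_dir`.
#' @return A list with the trained `net`, `metrics` (per-image data frame),
#'   `fbp_metrics`, `history`, and the `manifest`; artifacts on disk when
#'   `out_dir` is set.
#' @export
run_experiment <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  .require_fields(config, c("image_size", "n_angles", "n_radial", "n_stages",
                            "n_noise", "n_test", "seed"))
  cfg <- utils::modifyList(
    list(epochs = 40L, epochs_pretrain = 60L, batch_size = 20L,
         lr = NULL, lr_filter = NULL, refine = FALSE, n_refine = 50L,
         noise_level = 0.01, out_dir = NULL), config)
  run <- function(stage_name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("run_experiment: stage '%s' failed: %s", stage_name,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  tc_args <- list(batch_size = cfg$batch_size, epochs = cfg$epochs,
                  epochs_pretrain = cfg$epochs_pretrain, seed = cfg$seed)
  if (!is.null(cfg$lr)) tc_args$lr <- cfg$lr
  if (!is.null(cfg$lr_filter)) tc_args$lr_filter <- cfg$lr_filter
  tc <- do.call(training_config, tc_args)

  schedule <- run("plan", plan_schedule(cfg$n_radial, cfg$n_angles,
                                        cfg$image_size, cfg$n_stages))
  grid <- image_grid(cfg$image_size, fov = schedule$fov)
  geom <- projection_geometry(cfg$n_radial, cfg$n_angles, fov = schedule$fov)
  net <- run("build", build_network(schedule, mode = "linear",
                                    seed = cfg$seed))
  pairs <- run("gen-noise", gen_noise_dataset(cfg$n_noise, grid, geom,
                                              seed = cfg$seed))
  labels <- run("make-labels", make_intermediate_labels(pairs, schedule))
  net <- run("pretrain", pretrain_stagewise(net, pairs, labels, tc))

  # validation phantoms: structured images, unlike the noise training set
  val <- lapply(seq_len(5L), function(i) {
    list(image = random_ellipses(grid, seed = cfg$seed + 9000L + i)$image$values,
         sino = NULL)
  })
  for (i in seq_along(val)) {
    img <- image_grid(grid$n_x, grid$n_y, grid$fov, values = val[[i]]$image)
    val[[i]]$sino <- radon_forward(img, geom)$values
  }
  trained <- run("train", train_end_to_end(net, pairs, tc, val_pairs = val))
  net <- trained$net

  refine_hist <- NULL
  if (isTRUE(cfg$refine)) {
    imgs <- lapply(seq_len(cfg$n_refine), function(i) {
      random_ellipses(grid, seed = cfg$seed + 5000L + i)$image$values
    })
    ref <- run("refine", refine_nonlinear(net, imgs,
                                          noise_level = cfg$noise_level,
                                          config = tc,
                                          val_images = lapply(val, `[[`,
                                                              "image")))
    net <- ref$net
    refine_hist <- ref$val_history
  }

  # held-out evaluation against ground truth and the FBP reference
  reports <- list(); fbp_reports <- list()
  for (i in seq_len(cfg$n_test)) {
    truth <- random_ellipses(grid, seed = cfg$seed + 7000L + i)$image
    sino <- radon_forward(truth, geom)
    rec <- net_forward(net, sino)
    fbp <- fbp_reconstruct(sino, grid)
    reports[[i]] <- metrics(truth, rec)
    fbp_reports[[i]] <- metrics(truth, fbp)
  }
  mt <- metrics_table(reports)
  ft <- metrics_table(fbp_reports)

  manifest <- list(seed = cfg$seed,
                   config_hash = .text_hash(yaml::as.yaml(cfg)),
                   package_version = as.character(
                     utils::packageVersion("hierct")),
                   image_size = cfg$image_size, n_stages = schedule$n_stages)
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    save_checkpoint(net, file.path(cfg$out_dir, "checkpoint"))
    utils::write.csv(trained$history,
                     file.path(cfg$out_dir, "loss_history.csv"),
                     row.names = FALSE)
    utils::write.csv(mt, file.path(cfg$out_dir, "metrics.csv"))
    utils::write.csv(ft, file.path(cfg$out_dir, "metrics_fbp.csv"))
    yaml::write_yaml(manifest, file.path(cfg$out_dir, "manifest.yaml"))
  }
  list(net = net, metrics = mt, fbp_metrics = ft, history = trained$history,
       val_history = trained$val_history, refine_history = refine_hist,
       manifest = manifest, schedule = schedule)
}
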