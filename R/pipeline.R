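## Pipeline orchestration: a YAML run configuration drives subcommands that
## write their artifacts (PNG images and masks, CSV tables, JSON logs) under
## one output directory, so the whole analysis is reproducible end to end.

default_run_config <- function() {
  list(
    dataset = list(n_per_class = 40L, image_size = 32L,
                   disc_radius_range = c(10, 13),
                   healthy_cdr_range = c(0.25, 0.45),
                   glaucoma_cdr_range = c(0.60, 0.80),
                   rim_loss_sector = NULL, rim_loss_strength = 0,
                   texture_noise_sd = 0.03, vessel_count = 4L,
                   laterality_probability = 0.5, seed = 1L,
                   manifest = NULL),
    split = list(test_fraction = 0.2, k = 5L, seed = 11L),
    model = list(filters = c(8L, 8L), lr = 3e-3, epochs = 30L,
                 batch_size = 16L, seed = 21L, fold = 1L),
    saliency = list(methods = saliency_methods(), score_view = "logit",
                    channel_reduction = "max_abs", sg_samples = 25L,
                    sg_noise_sd = 0.15, ig_baseline = "black",
                    ig_steps = 50L, occl_patch = NULL, occl_stride = NULL,
                    occl_fill = NULL, cam_upsampling = "bilinear",
                    seed = 31L),
    sectors = list(style = "garway_heath", temporal_side_od = "left",
                   rim_only = FALSE, tau = 0.75),
    analysis = list(discard_threshold = 0.5, replicates = 3L,
                    label_flip_fraction = 0.5, seed = 41L,
                    agreement_methods = setdiff(saliency_methods(),
                                                c("GBack", "SCam"))),
    output_dir = "sectorsal-run")
}

#' Load and validate a run configuration
#'
#' Unknown keys are rejected; omitted keys take the package defaults. The
#' configuration round-trips losslessly through its YAML representation.
#'
#' @param config A YAML file path, or a list of configuration blocks.
#' @return An object of class `run_config`.
#' @export
run_config <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  def <- default_run_config()
  bad <- setdiff(names(config), names(def))
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  for (blk in setdiff(names(def), "output_dir")) {
    if (!is.null(config[[blk]])) {
      bad <- setdiff(names(config[[blk]]), names(def[[blk]]))
      if (length(bad)) stop("unknown keys in block '", blk, "': ",
                            paste(bad, collapse = ", "), call. = FALSE)
      def[[blk]] <- utils::modifyList(def[[blk]], config[[blk]],
                                      keep.null = TRUE)
    }
  }
  if (!is.null(config$output_dir)) def$output_dir <- config$output_dir
  structure(def, class = "run_config")
}

# Small deterministic string hash (FNV-1a, 32-bit) used to stamp artifacts
# with the configuration that produced them.
config_hash <- function(config) {
  s <- yaml::as.yaml(unclass(config))
  bytes <- utf8ToInt(s)
  h <- 2166136261
  for (b in bytes) {
    low <- bitwXor(h %% 256, b)      # bytes only touch the low 8 bits
    h <- h - (h %% 256) + low
    h <- (h * 16777619) %% 4294967296
  }
  paste0(format(as.hexmode(h %/% 65536), width = 4),
         format(as.hexmode(h %% 65536), width = 4))
}

write_runlog <- function(config, step, outdir, seeds, extra = list()) {
  dir.create(file.path(outdir, "logs"), showWarnings = FALSE,
             recursive = TRUE)
  log <- c(list(step = step, config_hash = config_hash(config),
                seeds = seeds,
                package_version =
                  as.character(utils::packageVersion("sectorsal")),
                timestamp = format(Sys.time(), tz = "UTC")),
           extra)
  jsonlite::write_json(log, file.path(outdir, "logs",
                                      paste0(step, ".json")),
                       auto_unbox = TRUE, pretty = TRUE)
}

require_artifact <- function(path, produced_by) {
  if (!file.exists(path)) {
    stop("missing artifact '", basename(path), "': run subcommand '",
         produced_by, "' first", call. = FALSE)
  }
  path
}

dataset_config <- function(cfg) {
  d <- cfg$dataset
  generator_config(image_size = d$image_size,
                   disc_radius_range = d$disc_radius_range,
                   healthy_cdr_range = d$healthy_cdr_range,
                   glaucoma_cdr_range = d$glaucoma_cdr_range,
                   rim_loss_sector = d$rim_loss_sector,
                   rim_loss_strength = d$rim_loss_strength,
                   texture_noise_sd = d$texture_noise_sd,
                   vessel_count = d$vessel_count,
                   laterality_probability = d$laterality_probability,
                   seed = d$seed)
}

saliency_config_from <- function(cfg) {
  s <- cfg$saliency
  saliency_config(score_view = s$score_view,
                  channel_reduction = s$channel_reduction,
                  sg_samples = s$sg_samples, sg_noise_sd = s$sg_noise_sd,
                  ig_baseline = s$ig_baseline, ig_steps = s$ig_steps,
                  occl_patch = s$occl_patch, occl_stride = s$occl_stride,
                  occl_fill = s$occl_fill,
                  cam_upsampling = s$cam_upsampling, seed = s$seed)
}

scheme_from <- function(cfg) {
  sector_scheme(style = cfg$sectors$style,
                temporal_side_od = cfg$sectors$temporal_side_od,
                rim_only = cfg$sectors$rim_only)
}

#' Write a dataset to disk (PNG images, PNG masks, CSV manifest, JSON
#' annotations)
#'
#' @param ds Result of [generate_dataset()].
#' @param outdir Output directory.
#' @return The manifest data frame (with file-path columns), invisibly.
#' @export
write_dataset <- function(ds, outdir) {
  img_dir <- file.path(outdir, "images")
  mask_dir <- file.path(outdir, "masks")
  dir.create(img_dir, showWarnings = FALSE, recursive = TRUE)
  dir.create(mask_dir, showWarnings = FALSE, recursive = TRUE)
  man <- ds$manifest
  man$image_path <- file.path("images", paste0(man$sample_id, ".png"))
  man$disc_mask_path <- file.path("masks",
                                  paste0(man$sample_id, "_disc.png"))
  man$cup_mask_path <- file.path("masks", paste0(man$sample_id, "_cup.png"))
  shape <- dim(ds$samples[[1]]$image)[1:2]
  ann_json <- list()
  for (i in seq_len(nrow(man))) {
    png::writePNG(ds$samples[[i]]$image, file.path(outdir, man$image_path[i]))
    a <- ds$annotations[[i]]
    png::writePNG(annotation_mask(a, shape, "disc") * 1,
                  file.path(outdir, man$disc_mask_path[i]))
    png::writePNG(annotation_mask(a, shape, "cup") * 1,
                  file.path(outdir, man$cup_mask_path[i]))
    ell <- function(e) if (is.list(e))
      list(center = e$center, semi_axes = e$semi_axes,
           rotation = e$rotation %||% 0) else NULL
    ann_json[[man$sample_id[i]]] <- list(disc = ell(a$disc),
                                         cup = ell(a$cup),
                                         laterality = a$laterality)
  }
  jsonlite::write_json(ann_json, file.path(outdir, "annotations.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  utils::write.csv(man, file.path(outdir, "manifest.csv"),
                   row.names = FALSE)
  invisible(man)
}

#' Load a dataset written by [write_dataset()]
#'
#' @param dir Directory containing `manifest.csv`.
#' @return List with `samples`, `annotations`, `manifest` as in
#'   [generate_dataset()].
#' @export
load_dataset <- function(dir) {
  man <- utils::read.csv(require_artifact(file.path(dir, "manifest.csv"),
                                          "generate"),
                         stringsAsFactors = FALSE)
  ann_json <- jsonlite::read_json(file.path(dir, "annotations.json"))
  samples <- vector("list", nrow(man))
  annotations <- vector("list", nrow(man))
  for (i in seq_len(nrow(man))) {
    img <- png::readPNG(file.path(dir, man$image_path[i]))
    aj <- ann_json[[man$sample_id[i]]]
    e <- function(x) list(center = unlist(x$center),
                          semi_axes = unlist(x$semi_axes),
                          rotation = x$rotation)
    annotations[[i]] <- disc_cup_annotation(e(aj$disc), e(aj$cup),
                                            aj$laterality)
    samples[[i]] <- structure(list(image = img,
                                   laterality = man$laterality[i],
                                   label = man$label[i],
                                   sample_id = man$sample_id[i]),
                              class = "fundus_sample")
  }
  list(samples = samples, annotations = annotations, manifest = man)
}

split_to_json <- function(sp, path) {
  jsonlite::write_json(list(test_ids = sp$test_ids,
                            folds = lapply(sp$folds, function(f)
                              list(train_ids = f$train_ids,
                                   validation_ids = f$validation_ids)),
                            seed = sp$seed),
                       path, auto_unbox = FALSE, pretty = TRUE)
}

split_from_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  folds <- if (is.data.frame(j$folds)) {
    lapply(seq_len(nrow(j$folds)), function(i)
      list(train_ids = unlist(j$folds$train_ids[i]),
           validation_ids = unlist(j$folds$validation_ids[i])))
  } else {
    lapply(j$folds, function(f) list(train_ids = unlist(f$train_ids),
                                     validation_ids =
                                       unlist(f$validation_ids)))
  }
  structure(list(test_ids = unlist(j$test_ids), folds = folds,
                 seed = j$seed), class = "split_spec")
}

# Shared context loaded by the downstream subcommands.
pipeline_context <- function(cfg, need = c("dataset")) {
  out <- list(outdir = cfg$output_dir)
  if ("dataset" %in% need) out$ds <- load_dataset(cfg$output_dir)
  if ("splits" %in% need) {
    out$splits <- split_from_json(require_artifact(
      file.path(cfg$output_dir, "splits.json"), "split"))
  }
  if ("model" %in% need) {
    out$model <- readRDS(require_artifact(
      file.path(cfg$output_dir, "model.rds"), "train"))
  }
  out
}

test_set_of <- function(ds, splits) {
  idx <- match(splits$test_ids, ds$manifest$sample_id)
  list(samples = ds$samples[idx], annotations = ds$annotations[idx],
       ids = ds$manifest$sample_id[idx])
}

cmd_generate <- function(cfg) {
  ds <- generate_dataset(dataset_config(cfg), cfg$dataset$n_per_class)
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  write_dataset(ds, cfg$output_dir)
  write_runlog(cfg, "generate", cfg$output_dir,
               seeds = list(dataset = cfg$dataset$seed),
               extra = list(n_images = length(ds$samples)))
  invisible(ds)
}

cmd_split <- function(cfg) {
  ctx <- pipeline_context(cfg, "dataset")
  sp <- make_splits(ctx$ds$manifest, cfg$split$test_fraction, cfg$split$k,
                    cfg$split$seed)
  split_to_json(sp, file.path(cfg$output_dir, "splits.json"))
  write_runlog(cfg, "split", cfg$output_dir,
               seeds = list(split = cfg$split$seed),
               extra = list(n_test = length(sp$test_ids), k = cfg$split$k))
  invisible(sp)
}

cmd_train <- function(cfg) {
  ctx <- pipeline_context(cfg, c("dataset", "splits"))
  fold <- ctx$splits$folds[[cfg$model$fold]]
  idx <- match(fold$train_ids, ctx$ds$manifest$sample_id)
  model <- train_toy_model(ctx$ds$samples[idx],
                           ctx$ds$manifest$label[idx],
                           hyperparams = list(filters = cfg$model$filters,
                                              lr = cfg$model$lr,
                                              epochs = cfg$model$epochs,
                                              batch_size =
                                                cfg$model$batch_size),
                           seed = cfg$model$seed)
  saveRDS(model, file.path(cfg$output_dir, "model.rds"))
  utils::write.csv(model$log, file.path(cfg$output_dir,
                                        "training_log.csv"),
                   row.names = FALSE)
  vidx <- match(fold$validation_ids, ctx$ds$manifest$sample_id)
  ba <- balanced_accuracy(predicted_classes(model, ctx$ds$samples[vidx]),
                          ctx$ds$manifest$label[vidx])
  write_runlog(cfg, "train", cfg$output_dir,
               seeds = list(model = cfg$model$seed),
               extra = list(fold = cfg$model$fold,
                            validation_balanced_accuracy = ba))
  invisible(model)
}

cmd_saliency <- function(cfg) {
  ctx <- pipeline_context(cfg, c("dataset", "splits", "model"))
  ts <- test_set_of(ctx$ds, ctx$splits)
  sconf <- saliency_config_from(cfg)
  sal_dir <- file.path(cfg$output_dir, "saliency")
  dir.create(sal_dir, showWarnings = FALSE, recursive = TRUE)
  for (m in cfg$saliency$methods) {
    maps <- lapply(ts$samples, function(s)
      compute_saliency(ctx$model, s, m, sconf))
    names(maps) <- ts$ids
    saveRDS(maps, file.path(sal_dir, paste0(m, ".rds")))
  }
  write_runlog(cfg, "saliency", cfg$output_dir,
               seeds = list(saliency = cfg$saliency$seed),
               extra = list(methods = cfg$saliency$methods,
                            n_images = length(ts$samples)))
  invisible(NULL)
}

cmd_discretize <- function(cfg) {
  ctx <- pipeline_context(cfg, c("dataset", "splits", "model"))
  ts <- test_set_of(ctx$ds, ctx$splits)
  scheme <- scheme_from(cfg)
  shape <- dim(ts$samples[[1]]$image)[1:2]
  pred <- predicted_classes(ctx$model, ts$samples)
  rows <- list()
  for (m in cfg$saliency$methods) {
    maps <- readRDS(require_artifact(
      file.path(cfg$output_dir, "saliency", paste0(m, ".rds")), "saliency"))
    for (i in seq_along(ts$samples)) {
      masks <- build_sector_masks(ts$annotations[[i]], shape, scheme)
      d <- discretize_saliency(maps[[ts$ids[i]]], masks, cfg$sectors$tau)
      rows[[length(rows) + 1]] <-
        data.frame(sample_id = ts$ids[i], method = m, model_id = "model",
                   t(unclass(d)[sector_ids()]), predicted_class = pred[i],
                   stringsAsFactors = FALSE)
    }
  }
  disc <- do.call(rbind, rows)
  utils::write.csv(disc, file.path(cfg$output_dir, "discrete.csv"),
                   row.names = FALSE)
  write_runlog(cfg, "discretize", cfg$output_dir,
               seeds = list(), extra = list(tau = cfg$sectors$tau))
  invisible(disc)
}

discrete_from_csv <- function(disc, method) {
  sub <- disc[disc$method == method, ]
  maps <- lapply(seq_len(nrow(sub)), function(i) {
    structure(stats::setNames(as.numeric(sub[i, sector_ids()]),
                              sector_ids()),
              class = "discrete_saliency", method = method,
              sample_id = sub$sample_id[i], tau = NA_real_)
  })
  discrete_collection(maps, sub$sample_id, model_id = sub$model_id[1],
                      method = method)
}

cmd_relevance <- function(cfg) {
  path <- require_artifact(file.path(cfg$output_dir, "discrete.csv"),
                           "discretize")
  disc <- utils::read.csv(path, stringsAsFactors = FALSE)
  rows <- lapply(unique(disc$method), function(m) {
    coll <- discrete_from_csv(disc, m)
    pred <- disc$predicted_class[disc$method == m]
    tab <- relevance_as_percent(global_relevance(coll$maps, pred))
    data.frame(method = m, tab, stringsAsFactors = FALSE)
  })
  rel <- do.call(rbind, rows)
  utils::write.csv(rel, file.path(cfg$output_dir, "relevance.csv"),
                   row.names = FALSE)
  write_runlog(cfg, "relevance", cfg$output_dir, seeds = list())
  invisible(rel)
}

cmd_agreement <- function(cfg) {
  path <- require_artifact(file.path(cfg$output_dir, "discrete.csv"),
                           "discretize")
  disc <- utils::read.csv(path, stringsAsFactors = FALSE)
  methods <- intersect(cfg$analysis$agreement_methods,
                       unique(disc$method))
  colls <- stats::setNames(lapply(methods, discrete_from_csv,
                                  disc = disc), methods)
  agr <- pairwise_agreement(colls)
  utils::write.csv(agr, file.path(cfg$output_dir, "agreement.csv"),
                   row.names = FALSE)
  utils::write.csv(agreement_summary(agr),
                   file.path(cfg$output_dir, "agreement_summary.csv"),
                   row.names = FALSE)
  write_runlog(cfg, "agreement", cfg$output_dir, seeds = list(),
               extra = list(methods = methods, n_pairs = nrow(agr)))
  invisible(agr)
}

cmd_sanity <- function(cfg) {
  ctx <- pipeline_context(cfg, c("dataset", "splits", "model"))
  ts <- test_set_of(ctx$ds, ctx$splits)
  scheme <- scheme_from(cfg)
  shape <- dim(ts$samples[[1]]$image)[1:2]
  mask_sets <- lapply(ts$annotations, build_sector_masks,
                      image_shape = shape, scheme = scheme)
  sconf <- saliency_config_from(cfg)
  methods <- cfg$saliency$methods
  par_fr <- parameter_randomization_test(ctx$model, ts$samples, mask_sets,
                                         methods, sconf,
                                         n_replicates =
                                           cfg$analysis$replicates,
                                         seed = cfg$analysis$seed,
                                         tau = cfg$sectors$tau)
  fold <- ctx$splits$folds[[cfg$model$fold]]
  idx <- match(fold$train_ids, ctx$ds$manifest$sample_id)
  lab_fr <- label_randomization_test(ctx$model, ctx$ds$samples[idx],
                                     ctx$ds$manifest$label[idx],
                                     ts$samples, mask_sets, methods, sconf,
                                     fraction =
                                       cfg$analysis$label_flip_fraction,
                                     seed = cfg$analysis$seed,
                                     tau = cfg$sectors$tau)
  rep <- sanity_report(par_fr, lab_fr, cfg$analysis$discard_threshold)
  utils::write.csv(par_fr, file.path(cfg$output_dir,
                                     "sanity_parameter.csv"),
                   row.names = FALSE)
  utils::write.csv(lab_fr, file.path(cfg$output_dir, "sanity_label.csv"),
                   row.names = FALSE)
  utils::write.csv(rep$flags, file.path(cfg$output_dir,
                                        "sanity_flags.csv"),
                   row.names = FALSE)
  write_runlog(cfg, "sanity", cfg$output_dir,
               seeds = list(analysis = cfg$analysis$seed))
  invisible(rep)
}

cmd_report <- function(cfg) {
  rep_dir <- file.path(cfg$output_dir, "report")
  dir.create(rep_dir, showWarnings = FALSE, recursive = TRUE)
  wanted <- c("relevance.csv", "agreement.csv", "agreement_summary.csv",
              "sanity_parameter.csv", "sanity_label.csv",
              "sanity_flags.csv")
  found <- character(0)
  for (f in wanted) {
    src <- file.path(cfg$output_dir, f)
    if (file.exists(src)) {
      file.copy(src, file.path(rep_dir, f), overwrite = TRUE)
      found <- c(found, f)
    }
  }
  if (!length(found)) {
    stop("nothing to report: run 'relevance', 'agreement' or 'sanity' first",
         call. = FALSE)
  }
  write_runlog(cfg, "report", cfg$output_dir, seeds = list(),
               extra = list(collated = found))
  invisible(found)
}

#' Run one pipeline subcommand
#'
#' Subcommands, in dependency order: `generate` (synthesize and write the
#' dataset), `split`, `train`, `saliency`, `discretize`, `relevance`,
#' `agreement`, `sanity`, `report` (collate result tables). Each writes its
#' artifacts plus a JSON run log under the configured output directory; a
#' missing prerequisite raises an error naming the subcommand to run first.
#'
#' @param name Subcommand name.
#' @param config A [run_config()], a YAML path, or a config list.
#' @return The subcommand's main result, invisibly.
#' @export
run_subcommand <- function(name = c("generate", "split", "train",
                                    "saliency", "discretize", "relevance",
                                    "agreement", "sanity", "report"),
                           config = list()) {
  name <- match.arg(name)
  cfg <- if (inherits(config, "run_config")) config else run_config(config)
  switch(name,
         generate = cmd_generate(cfg), split = cmd_split(cfg),
         train = cmd_train(cfg), saliency = cmd_saliency(cfg),
         discretize = cmd_discretize(cfg), relevance = cmd_relevance(cfg),
         agreement = cmd_agreement(cfg), sanity = cmd_sanity(cfg),
         report = cmd_report(cfg))
}

#' Run the full pipeline from generation to report
#'
#' @param config A [run_config()], YAML path, or config list.
#' @param steps Subcommands to run, in order.
#' @return The output directory, invisibly.
#' @export
run_pipeline <- function(config = list(),
                         steps = c("generate", "split", "train", "saliency",
                                   "discretize", "relevance", "agreement",
                                   "sanity", "report")) {
  cfg <- if (inherits(config, "run_config")) config else run_config(config)
  for (s in steps) run_subcommand(s, cfg)
  invisible(cfg$output_dir)
}
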