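#' Default pipeline configuration
#'
#' Returns the fully resolved configuration for [run_pipeline()]; any subset
#' of fields can be overridden via a flat key-value YAML file or the
#' `overrides` list (flags beat file values beat defaults).
#'
#' @param config_file optional path to a flat YAML document.
#' @param overrides named list of fields overriding the file and defaults.
#' @return Named list of class `run_config`.
#' @export
pipeline_config <- function(config_file = NULL, overrides = list()) {
  cfg <- list(
    n_images = 4L,          # synthetic content images when no content_dir
    image_size = 64L,       # synthetic image side, px
    artifact_density = 0.1,
    content_dir = NULL,     # directory of PNG/TIFF CLE images (optional)
    style_path = NULL,      # style image path; NULL generates a pseudo-H&E
    crop_fraction = 0.5,    # center-crop applied to content images
    backbone = "test",      # "test" or "pretrained"
    backbone_seed = 0L,
    weights_path = NULL,    # required when backbone = "pretrained"
    iterations = 1600L,     # production L-BFGS budget
    alpha = 100,
    scores_path = NULL,     # rating CSV; NULL generates a planted table
    run_seed = 0L,
    out_dir = NULL          # NULL creates a timestamped directory
  )
  if (!is.null(config_file)) {
    if (!file.exists(config_file)) {
      abort(sprintf("config file '%s' not found", config_file),
            class = "hestain_io_error")
    }
    file_cfg <- yaml::read_yaml(config_file)
    cfg[names(file_cfg)] <- file_cfg
  }
  cfg[names(overrides)] <- overrides
  cfg$n_images <- as.integer(cfg$n_images)
  cfg$image_size <- as.integer(cfg$image_size)
  cfg$iterations <- as.integer(cfg$iterations)
  cfg$run_seed <- as.integer(cfg$run_seed)
  cfg$backbone_seed <- as.integer(cfg$backbone_seed)
  structure(cfg, class = "run_config")
}

pipeline_log <- function(log_path, ...) {
  msg <- sprintf(...)
  cat(msg, "\n", sep = "", file = log_path, append = TRUE)
  message(msg)
}

load_content_images <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.(png|tif|tiff)$",
                           ignore.case = TRUE, full.names = TRUE))
  if (length(files) == 0L) {
    abort(sprintf("no PNG/TIFF images found in '%s'", dir),
          class = "hestain_io_error")
  }
  lapply(files, load_image)
}

#' Run the full stylization and evaluation pipeline
#'
#' End to end: obtain content images (from `content_dir` or the pseudo-CLE
#' generator) and a style image (from `style_path` or the pseudo-H&E
#' generator), center-crop, stylize each content image, post-process into the
#' four color presentation groups, and compute the rater-score report from
#' `scores_path` (or a planted synthetic rating table). All outputs — the
#' stylized and color-coded PNGs, loss traces, score statistics, the resolved
#' configuration, and a log — are written under one output directory.
#'
#' @param config a `run_config` from [pipeline_config()] (or a named list of
#'   overrides applied to the defaults).
#' @return Invisibly, a list with `status` (0 on success), `out_dir`, and the
#'   paths of the main outputs.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (!inherits(config, "run_config")) {
    config <- pipeline_config(overrides = config)
  }
  out_dir <- config$out_dir %||%
    file.path(tempdir(), format(Sys.time(), "hestain_run_%Y%m%d_%H%M%S"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (sub in c("stylized", "colorized", "report")) {
    dir.create(file.path(out_dir, sub), showWarnings = FALSE)
  }
  cfg_to_write <- config
  cfg_to_write$out_dir <- out_dir
  yaml::write_yaml(lapply(unclass(cfg_to_write), function(x) x %||% ""),
                   file.path(out_dir, "config.yaml"))
  log_path <- file.path(out_dir, "run.log")
  cat("", file = log_path)

  # ---- inputs --------------------------------------------------------------
  if (!is.null(config$content_dir)) {
    contents <- load_content_images(config$content_dir)
  } else {
    pipeline_log(log_path, "generating %d pseudo-CLE content images (%d px)",
                 config$n_images, config$image_size)
    contents <- lapply(seq_len(config$n_images), function(i) {
      make_cle_image(size = config$image_size,
                     n_cells = max(5L, config$image_size %/% 8L),
                     artifact_density = config$artifact_density,
                     seed = config$run_seed * 1000L + i)
    })
  }
  style <- if (!is.null(config$style_path)) {
    load_image(config$style_path)
  } else {
    make_he_style_image(size = config$image_size, seed = config$run_seed + 99L)
  }

  contents <- lapply(contents, center_crop, fraction = config$crop_fraction)
  image_ids <- vapply(contents, function(x) attr(x, "source_id"), character(1))
  if (anyDuplicated(image_ids)) {
    image_ids <- sprintf("img%03d", seq_along(contents))
  }

  backbone <- switch(config$backbone,
    test = build_test_backbone(config$backbone_seed),
    pretrained = load_pretrained_backbone(config$weights_path),
    abort(sprintf("unknown backbone kind '%s'", config$backbone),
          class = "hestain_config_error"))

  tcfg <- transfer_config(weights = loss_weights(alpha = config$alpha),
                          n_iterations = config$iterations)

  # ---- stylization ---------------------------------------------------------
  stylized <- vector("list", length(contents))
  stylized_paths <- character(length(contents))
  for (i in seq_along(contents)) {
    pipeline_log(log_path, "stylizing %s (%d iterations)", image_ids[i],
                 config$iterations)
    res <- stylize(contents[[i]], style, backbone, tcfg)
    stylized[[i]] <- res
    stylized_paths[i] <- file.path(out_dir, "stylized",
                                   paste0(image_ids[i], ".png"))
    save_image(res$image, stylized_paths[i])
    utils::write.csv(res$trace,
                     file.path(out_dir, "stylized",
                               paste0(image_ids[i], "_trace.csv")),
                     row.names = FALSE)
    pipeline_log(log_path, "  loss %.4g -> %.4g", res$initial$total,
                 res$final$total)
  }

  # ---- color coding --------------------------------------------------------
  groups <- assign_color_groups(image_ids, seed = config$run_seed)
  utils::write.csv(groups, file.path(out_dir, "colorized", "groups.csv"),
                   row.names = FALSE)
  for (i in seq_along(stylized)) {
    grp <- as.character(groups$group[groups$image_id == image_ids[i]])
    save_image(apply_color_group(stylized[[i]]$image, grp),
               file.path(out_dir, "colorized",
                         paste0(image_ids[i], "_", grp, ".png")))
  }

  # ---- rater-score report --------------------------------------------------
  scores <- if (!is.null(config$scores_path)) {
    read_scores(config$scores_path)
  } else {
    make_rating_table(n_images = length(contents), seed = config$run_seed)
  }
  report_dir <- file.path(out_dir, "report")
  utils::write.csv(score_histogram(scores, "added"),
                   file.path(report_dir, "histogram_added.csv"),
                   row.names = FALSE)
  utils::write.csv(score_histogram(scores, "removed"),
                   file.path(report_dir, "histogram_removed.csv"),
                   row.names = FALSE)
  imap <- intensity_map(scores)
  utils::write.csv(tidy(imap), file.path(report_dir, "intensity_map.csv"),
                   row.names = FALSE)
  cats <- categorize_images(scores)
  utils::write.csv(cats$counts, file.path(report_dir, "categories.csv"),
                   row.names = FALSE)
  tests <- list(
    modal = as.list(modal_combination(imap)),
    chi_square_added = as.list(chi_square_uniform(
      improvement_counts(scores, "added"))),
    chi_square_removed = as.list(chi_square_uniform(
      improvement_counts(scores, "removed"))),
    paired_t = tryCatch(
      as.list(paired_t_test(scores$added_score, scores$removed_score)),
      error = function(e) list(error = conditionMessage(e)))
  )
  jsonlite::write_json(tests, file.path(report_dir, "tests.json"),
                       auto_unbox = TRUE, digits = NA)
  pipeline_log(log_path, "report written to %s", report_dir)

  invisible(list(status = 0L, out_dir = out_dir,
                 stylized = stylized_paths,
                 groups = file.path(out_dir, "colorized", "groups.csv"),
                 report = report_dir,
                 results = stylized))
}
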