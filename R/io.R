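## Disk interfaces: PNG frame directories for videos, YAML configs, and the
## model bundle (an archive directory of the per-component serialisations).

#' Write a video stack as a directory of PNG frames
#'
#' 8-bit grayscale PNGs `frame_0001.png, ...` plus a `video.yaml` metadata
#' record (label, subject, fps).
#'
#' @param video a `video_stack`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_video_stack <- function(video, dir) {
  if (!inherits(video, "video_stack")) stopf("`video` must be a video_stack")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Tn <- dim(video$frames)[1]
  for (t in seq_len(Tn))
    png::writePNG(video$frames[t, , ],
                  file.path(dir, sprintf("frame_%04d.png", t)))
  yaml::write_yaml(list(label = video$label, subject_id = video$subject_id,
                        fps = video$fps, n_frames = Tn),
                   file.path(dir, "video.yaml"))
  invisible(dir)
}

#' @rdname write_video_stack
#' @export
read_video_stack <- function(dir) {
  meta_path <- file.path(dir, "video.yaml")
  meta <- if (file.exists(meta_path)) yaml::read_yaml(meta_path)
          else list(label = NA_character_, subject_id = 1L, fps = 25)
  files <- sort(list.files(dir, pattern = "^frame_\\d+\\.png$",
                           full.names = TRUE))
  if (length(files) == 0L) stopf("no frame_*.png files in %s", dir)
  first <- png::readPNG(files[1])
  if (length(dim(first)) == 3L) first <- first[, , 1]
  frames <- array(0, c(length(files), nrow(first), ncol(first)))
  frames[1, , ] <- first
  for (t in seq_along(files)[-1]) {
    f <- png::readPNG(files[t])
    if (length(dim(f)) == 3L) f <- f[, , 1]
    frames[t, , ] <- f
  }
  structure(list(frames = frames, label = meta$label,
                 subject_id = as.integer(meta$subject_id), fps = meta$fps,
                 joints = NULL, spec = NULL),
            class = "video_stack")
}

#' Write / read a pipeline configuration as YAML
#'
#' @param config an [action_config()].
#' @param path file path.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  do.call(action_config, yaml::read_yaml(path))
}

#' Save a fitted action model as an archive directory
#'
#' The bundle holds the per-component text serialisations: the config
#' (YAML), one active-basis-template archive per class, the prototype bank
#' and the ELM. Numeric content round-trips bit-exactly.
#'
#' @param model an [action_model()].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
save_action_model <- function(model, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_config(model$config, file.path(dir, "config.yaml"))
  yaml::write_yaml(list(classes = model$classes,
                        train_subjects = model$train_subjects,
                        n_train_frames = model$n_train_frames),
                   file.path(dir, "model.yaml"))
  for (cl in model$classes)
    write_template(model$templates[[cl]],
                   file.path(dir, sprintf("template_%s.txt", cl)))
  write_prototypes(model$prototypes, file.path(dir, "prototypes.txt"))
  write_elm(model$elm, file.path(dir, "elm.txt"))
  invisible(dir)
}

#' @rdname save_action_model
#' @export
load_action_model <- function(dir) {
  config <- read_config(file.path(dir, "config.yaml"))
  meta <- yaml::read_yaml(file.path(dir, "model.yaml"))
  classes <- as.character(meta$classes)
  templates <- stats::setNames(lapply(classes, function(cl)
    read_template(file.path(dir, sprintf("template_%s.txt", cl)))), classes)
  structure(list(classes = classes,
                 dictionary = gabor_dictionary(config$n_orientations,
                                               config$n_scales,
                                               config$base_size),
                 templates = templates,
                 prototypes = read_prototypes(file.path(dir, "prototypes.txt")),
                 elm = read_elm(file.path(dir, "elm.txt")),
                 config = config,
                 train_subjects = as.integer(meta$train_subjects),
                 n_train_frames = as.integer(meta$n_train_frames)),
            class = "action_model")
}
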