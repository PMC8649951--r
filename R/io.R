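# Fixture container, stack readers, model checkpoints, and provenance.
#
# The canonical single-file container is a versioned RDS archive (images,
# TIs, labels, ground truth, DVFs, seeds). A plain-text directory layout
# (frame_k.csv per frame + tis.csv sidecar) is supported as a
# no-dependency stand-in for a DICOM series; DICOM/NIfTI proper are out of
# scope in this build (no reader installed in the target R environment).

FIXTURE_FORMAT <- "t1moco-fixture-v1"
CHECKPOINT_FORMAT <- "t1moco-checkpoint-v1"

#' Write an object to the fixture container
#' @param object Any serializable object (typically an [irw_stack],
#'   [dvf_set] or list of them).
#' @param path Output file path (conventionally `.rds`).
#' @return `path`, invisibly.
#' @export
write_fixture <- function(object, path) {
  saveRDS(list(format = FIXTURE_FORMAT, version = .t1moco_version(),
               payload = object), path)
  invisible(path)
}

#' Read an object from the fixture container
#' @param path Path written by [write_fixture()].
#' @return The stored payload.
#' @export
read_fixture <- function(path) {
  if (!file.exists(path))
    t1moco_stop("t1moco_format_error", "no such fixture: %s", path)
  x <- readRDS(path)
  if (!identical(x$format, FIXTURE_FORMAT))
    t1moco_stop("t1moco_format_error", "%s is not a fixture container", path)
  x$payload
}

#' Read an IRW stack from disk
#'
#' Accepts either a fixture container file holding an [irw_stack], or a
#' directory of 7 plain-text frames (`frame_1.csv` .. `frame_7.csv`,
#' headerless comma-separated matrices) with a `tis.csv` sidecar (7
#' inversion times in ms, one per line, matching frame order). Frames are
#' sorted by ascending TI on read.
#'
#' @param path Fixture file or frame directory.
#' @return A validated [irw_stack].
#' @export
read_irw_stack <- function(path) {
  if (dir.exists(path)) {
    frames <- sort(list.files(path, pattern = "^frame_[0-9]+\\.csv$",
                              full.names = TRUE))
    if (length(frames) != 7)
      t1moco_stop("t1moco_format_error",
                  "expected 7 frames in %s, found %d of 7",
                  path, length(frames))
    ti_path <- file.path(path, "tis.csv")
    if (!file.exists(ti_path))
      t1moco_stop("t1moco_format_error", "missing TI sidecar %s", ti_path)
    tis <- scan(ti_path, quiet = TRUE)
    if (length(tis) != 7)
      t1moco_stop("t1moco_format_error", "TI sidecar must list 7 values")
    # honour the numeric order in the file names
    ord <- order(as.integer(sub("^frame_([0-9]+)\\.csv$", "\\1",
                                basename(frames))))
    frames <- frames[ord]
    mats <- lapply(frames, function(f)
      as.matrix(utils::read.csv(f, header = FALSE)))
    images <- array(0, c(dim(mats[[1]]), 7))
    for (k in 1:7) images[, , k] <- mats[[k]]
    return(irw_stack(images, tis))   # irw_stack() sorts by TI
  }
  obj <- read_fixture(path)
  if (!inherits(obj, "irw_stack"))
    t1moco_stop("t1moco_format_error", "%s does not hold an IRW stack", path)
  irw_stack(obj$images, obj$tis, obj$pixel_spacing, obj$meta)
}

#' Write an IRW stack as a plain-text frame directory
#' @param stack An [irw_stack].
#' @param path Directory to create.
#' @return `path`, invisibly.
#' @export
write_irw_dir <- function(stack, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  for (k in 1:7)
    utils::write.table(stack$images[, , k],
                       file.path(path, sprintf("frame_%d.csv", k)),
                       sep = ",", row.names = FALSE, col.names = FALSE)
  writeLines(format(stack$tis, scientific = FALSE),
             file.path(path, "tis.csv"))
  invisible(path)
}

#' Save a model checkpoint
#' @param model A `registration_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  saveRDS(list(format = CHECKPOINT_FORMAT, version = .t1moco_version(),
               config = model$config, params = model$params,
               buffers = model$buffers), path)
  invisible(path)
}

#' Load a model checkpoint
#' @param path Path written by [save_model()].
#' @return A `registration_model`.
#' @export
load_model <- function(path) {
  if (!file.exists(path))
    t1moco_stop("t1moco_format_error",
                "checkpoint not found: %s (train a model or pass --checkpoint)",
                path)
  x <- readRDS(path)
  if (!identical(x$format, CHECKPOINT_FORMAT))
    t1moco_stop("t1moco_format_error", "%s is not a model checkpoint", path)
  structure(list(config = x$config, params = x$params, buffers = x$buffers),
            class = "registration_model")
}

# Write run provenance (effective config, seed, version, input checksums)
# next to a run's outputs.
write_provenance <- function(out_dir, config, seed, inputs = character()) {
  sums <- if (length(inputs)) as.list(tools::md5sum(inputs)) else list()
  jsonlite::write_json(
    list(package_version = .t1moco_version(), seed = seed, config = config,
         input_md5 = sums, timestamp = format(Sys.time(), tz = "UTC")),
    file.path(out_dir, "run_config.json"),
    auto_unbox = TRUE, pretty = TRUE, force = TRUE, digits = NA)
}

#' Motion-correct a stored stack and write all artifacts
#'
#' Reads the stack and checkpoint, predicts the 7 inverse DVFs, writes the
#' corrected frames, the predicted fields, and T1 + R-squared maps before
#' and after correction, with full provenance. Wall time for the single
#' stack is logged, never asserted.
#'
#' @param stack_path Fixture file or frame directory.
#' @param checkpoint_path Model checkpoint.
#' @param out_dir Output directory (created).
#' @param seed Seed recorded in provenance (the operation itself is
#'   deterministic).
#' @return Invisible list with `corrected`, `dvfs`, `maps_pre`,
#'   `maps_post` and output paths.
#' @export
run_correct <- function(stack_path, checkpoint_path, out_dir, seed = 1) {
  stack <- read_irw_stack(stack_path)
  model <- load_model(checkpoint_path)
  t0 <- proc.time()[["elapsed"]]
  res <- correct_stack(stack, model)
  elapsed <- proc.time()[["elapsed"]] - t0
  maps_pre <- reconstruct_maps(stack)
  maps_post <- reconstruct_maps(res$corrected)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_fixture(res$corrected, file.path(out_dir, "corrected_stack.rds"))
  write_fixture(res$dvfs, file.path(out_dir, "predicted_dvfs.rds"))
  write_fixture(list(pre = maps_pre, post = maps_post),
                file.path(out_dir, "maps.rds"))
  utils::write.csv(data.frame(
    quantity = c("median_t1_pre", "median_t1_post",
                 "mean_r2_pre", "mean_r2_post", "seconds"),
    value = c(stats::median(maps_pre$t1_ms[maps_pre$valid]),
              stats::median(maps_post$t1_ms[maps_post$valid]),
              mean(maps_pre$r2[maps_pre$valid]),
              mean(maps_post$r2[maps_post$valid]), elapsed)),
    file.path(out_dir, "summary.csv"), row.names = FALSE)
  inputs <- c(checkpoint_path, if (!dir.exists(stack_path)) stack_path)
  write_provenance(out_dir, list(stack = stack_path,
                                 checkpoint = checkpoint_path),
                   seed, inputs)
  message(sprintf("corrected 1 stack in %.2f s", elapsed))
  invisible(c(res, list(maps_pre = maps_pre, maps_post = maps_post,
                        out_dir = out_dir)))
}
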