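# Reading and writing echo loops as numbered PNG frames or multi-frame
# TIFF, mask/flow-frame export, and cohort manifests. Frames are grayscale
# float matrices in [0, 1]; PNG export quantises to 8 bit.

#' Write an echo sequence as numbered PNG frames
#'
#' Files are named `frame_0001.png`, ... in frame order (8-bit grayscale).
#'
#' @param sequence An `echo_sequence`.
#' @param dir Output directory (created if needed).
#' @return Character vector of written paths, invisibly.
#' @export
write_frames <- function(sequence, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(length(sequence$frames))
  for (t in seq_along(sequence$frames)) {
    paths[t] <- file.path(dir, sprintf("frame_%04d.png", t))
    png::writePNG(pmin(pmax(sequence$frames[[t]], 0), 1), paths[t])
  }
  invisible(paths)
}

# numbered-image ordering: extract the numeric part of each filename,
# reject ties and gaps (silent reordering would corrupt the flow stage)
ordered_frame_files <- function(files) {
  nums <- suppressWarnings(as.integer(gsub("\\D", "", basename(files))))
  if (anyNA(nums)) stop("frame filenames must contain a frame number")
  if (anyDuplicated(nums)) stop("duplicate frame numbers in directory")
  o <- order(nums)
  if (!all(diff(nums[o]) == 1L)) stop("frame numbering has gaps")
  files[o]
}

# pad to square with zeros, then resize
conform_frame <- function(m, input_size = NULL) {
  if (is.null(input_size)) return(m)
  h <- nrow(m)
  w <- ncol(m)
  if (h != w) {
    s <- max(h, w)
    sq <- matrix(0, s, s)
    r0 <- (s - h) %/% 2
    c0 <- (s - w) %/% 2
    sq[r0 + seq_len(h), c0 + seq_len(w)] <- m
    m <- sq
  }
  if (nrow(m) != input_size) {
    m <- as.matrix(EBImage::resize(EBImage::Image(m), w = input_size, h = input_size))
  }
  pmin(pmax(m, 0), 1)
}

#' Read an echo loop from disk
#'
#' Accepts a directory of numbered PNG frames or a (multi-frame) TIFF
#' file. Frames become grayscale matrices in `[0, 1]`; color inputs are
#' averaged over channels. Non-square frames are zero-padded to a square
#' before resizing to `input_size`.
#'
#' @param path Directory of numbered images, or a TIFF file.
#' @param input_size Optional target side length.
#' @param view,subject_id,label Metadata stored on the sequence.
#' @return An `echo_sequence`.
#' @export
read_echo <- function(path, input_size = NULL, view = "A4C",
                      subject_id = basename(path), label = NA_character_) {
  to_gray <- function(a) {
    if (length(dim(a)) == 3L) a <- apply(a[, , seq_len(min(3, dim(a)[3])), drop = FALSE], c(1, 2), mean)
    as.matrix(a)
  }
  if (dir.exists(path)) {
    files <- list.files(path, pattern = "\\.(png|tif|tiff)$", ignore.case = TRUE,
                        full.names = TRUE)
    if (length(files) == 0L) stop(sprintf("no frames found in '%s'", path))
    files <- ordered_frame_files(files)
    frames <- lapply(files, function(f) {
      a <- if (grepl("\\.png$", f, ignore.case = TRUE)) png::readPNG(f) else tiff::readTIFF(f)
      conform_frame(to_gray(a), input_size)
    })
  } else if (file.exists(path) && grepl("\\.(tif|tiff)$", path, ignore.case = TRUE)) {
    imgs <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(imgs)) imgs <- list(imgs)
    if (length(imgs) == 0L) stop(sprintf("no frames in '%s'", path))
    frames <- lapply(imgs, function(a) conform_frame(to_gray(a), input_size))
  } else {
    stop(sprintf("cannot read echo input '%s': not a frame directory or TIFF", path))
  }
  structure(list(frames = frames, view = view, subject_id = subject_id,
                 label = label),
            class = "echo_sequence")
}

#' Write a phantom cohort to disk
#'
#' Materialises each subject, writing per-view frame directories, optional
#' ground-truth mask directories, a cohort manifest CSV (subject_id, view,
#' label, path) and the template configuration as YAML.
#'
#' @param cohort A `phantom_cohort`.
#' @param dir Output directory.
#' @param masks Also write ground-truth wall masks.
#' @return The manifest data.frame, invisibly.
#' @export
write_cohort <- function(cohort, dir, masks = TRUE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  for (subj in cohort$subjects) {
    views <- phantom_realize(subj)
    for (v in names(views)) {
      vdir <- file.path(dir, subj$subject_id, v)
      write_frames(views[[v]]$sequence, vdir)
      if (masks) {
        mdir <- file.path(dir, subj$subject_id, paste0(v, "_masks"))
        dir.create(mdir, recursive = TRUE, showWarnings = FALSE)
        wm <- views[[v]]$truth$wall_masks
        for (t in seq_along(wm)) {
          png::writePNG(wm[[t]], file.path(mdir, sprintf("mask_%04d.png", t)))
        }
      }
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = subj$subject_id, view = v, label = subj$label,
        path = vdir, stringsAsFactors = FALSE
      )
    }
  }
  manifest <- do.call(rbind, rows)
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  tmpl <- cohort$template
  tmpl_list <- unclass(tmpl)
  tmpl_list$hypokinetic_segments <- as.list(tmpl_list$hypokinetic_segments)
  yaml::write_yaml(tmpl_list, file.path(dir, "phantom_config.yaml"))
  invisible(manifest)
}

#' Write encoded flow frames as paired PNGs
#'
#' @param encodings List of `ef_flow_encoding`s.
#' @param dir Output directory; files are `flow_%04d_x.png` / `_y.png`.
#' @return Invisibly, the directory.
#' @export
write_flow_frames <- function(encodings, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (e in encodings) {
    png::writePNG(e$x_frame / 255, file.path(dir, sprintf("flow_%04d_x.png", e$t)))
    png::writePNG(e$y_frame / 255, file.path(dir, sprintf("flow_%04d_y.png", e$t)))
  }
  invisible(dir)
}
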