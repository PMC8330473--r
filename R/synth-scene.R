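# Synthetic patchy scenes with ground-truth microhabitat labels.
#
# Patchiness comes from smoothed Gaussian noise fields (one per microhabitat,
# smoothing length = patch_scale_px / 2) combined by argmax after adding
# per-field offsets calibrated so that expected areal fractions match the
# requested weights. Pixel colours are then drawn independently as
# per-channel Gaussians around the label's mean Lab.

#' Define a microhabitat
#'
#' @param name label, e.g. `"grass"`.
#' @param mean_lab length-3 Lab mean colour.
#' @param sd_lab length-3 non-negative per-channel SDs.
#' @param weight expected areal fraction in `[0, 1]`.
#' @param patch_scale_px characteristic patch diameter in pixels.
#' @return an object of class `microhabitat`.
#' @export
microhabitat <- function(name, mean_lab, sd_lab = c(0, 0, 0), weight = 1,
                         patch_scale_px = 8) {
  stopifnot(is.character(name), length(name) == 1L)
  mean_lab <- as.numeric(mean_lab); sd_lab <- as.numeric(sd_lab)
  if (length(mean_lab) != 3L || any(!is.finite(mean_lab)))
    stop("'mean_lab' must be 3 finite values", call. = FALSE)
  if (length(sd_lab) != 3L || any(sd_lab < 0))
    stop("'sd_lab' must be 3 non-negative values", call. = FALSE)
  if (!is.numeric(weight) || weight < 0)
    stop("'weight' must be >= 0", call. = FALSE)
  .check_scalar(patch_scale_px, "patch_scale_px", positive = TRUE)
  structure(list(name = name, mean_lab = mean_lab, sd_lab = sd_lab,
                 weight = weight, patch_scale_px = patch_scale_px),
            class = "microhabitat")
}

#' Define a synthetic scene specification
#'
#' @param width_px,height_px scene dimensions in pixels.
#' @param px_per_mm spatial scale (image pixels per mm on the ground); the
#'   analyses here use 0.8 (10 m photographs) and 0.3 (30 m photographs).
#' @param microhabitats list of [microhabitat()] objects; weights must sum
#'   to 1.
#' @param seed integer seed; the scene is bitwise reproducible from it.
#' @return an object of class `scene_spec`.
#' @export
scene_spec <- function(width_px, height_px, px_per_mm, microhabitats,
                       seed = 1L) {
  .check_scalar(width_px, "width_px", positive = TRUE, integer = TRUE)
  .check_scalar(height_px, "height_px", positive = TRUE, integer = TRUE)
  .check_scalar(px_per_mm, "px_per_mm", positive = TRUE)
  if (inherits(microhabitats, "microhabitat")) microhabitats <- list(microhabitats)
  if (length(microhabitats) < 1L ||
      !all(vapply(microhabitats, inherits, TRUE, "microhabitat")))
    stop("'microhabitats' must be a non-empty list of microhabitat objects",
         call. = FALSE)
  w <- vapply(microhabitats, `[[`, 1.0, "weight")
  if (abs(sum(w) - 1) > 1e-8)
    stop("microhabitat weights must sum to 1", call. = FALSE)
  structure(list(width_px = as.integer(width_px),
                 height_px = as.integer(height_px),
                 px_per_mm = px_per_mm,
                 microhabitats = microhabitats,
                 seed = as.integer(seed)),
            class = "scene_spec")
}

#' Read a scene specification from YAML
#'
#' Expects top-level keys `width_px`, `height_px`, `px_per_mm`, `seed` and a
#' `microhabitats` list with `name`, `mean_lab`, `sd_lab`, `weight`,
#' `patch_scale_px` per entry.
#'
#' @param path YAML file.
#' @return a [scene_spec()].
#' @export
read_scene_spec <- function(path) {
  y <- yaml::read_yaml(path)
  mh <- lapply(y$microhabitats, function(m)
    microhabitat(m$name, m$mean_lab, m$sd_lab %||% c(0, 0, 0),
                 m$weight, m$patch_scale_px %||% 8))
  scene_spec(y$width_px, y$height_px, y$px_per_mm, mh, y$seed %||% 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Habitat names of a scene specification
#' @param spec a [scene_spec()].
#' @return character vector of microhabitat names.
#' @export
habitat_names <- function(spec) vapply(spec$microhabitats, `[[`, "", "name")

# calibrate per-field offsets so argmax fractions match the weights;
# large scenes use a strided pixel subsample (deterministic, no RNG use)
.calibrate_offsets <- function(fields, weights) {
  k <- length(fields)
  off <- rep(0, k)
  npix <- length(fields[[1]])
  stride <- max(1L, floor(npix / 65536))
  idx <- seq(1L, npix, by = stride)
  sub <- lapply(fields, function(f) f[idx])
  for (iter in seq_len(200)) {
    best <- sub[[1]] + off[1]
    lab <- rep(1L, length(idx))
    for (j in seq_len(k)[-1]) {
      fj <- sub[[j]] + off[j]
      sel <- fj > best
      lab[sel] <- j
      best[sel] <- fj[sel]
    }
    frac <- tabulate(lab, k) / length(idx)
    err <- weights - frac
    if (max(abs(err)) < 0.002) break
    off <- off + 1.5 * err
    off <- off - mean(off)
  }
  off
}

.field_argmax <- function(fields, off) {
  k <- length(fields)
  best <- fields[[1]] + off[1]
  lab <- matrix(1L, nrow(best), ncol(best))
  if (k > 1) for (j in 2:k) {
    fj <- fields[[j]] + off[j]
    sel <- fj > best
    lab[sel] <- j
    best[sel] <- fj[sel]
  }
  lab
}

#' Generate a synthetic patchy scene
#'
#' Builds the ground-truth label map by thresholding independent smoothed
#' Gaussian noise fields (argmax with offsets calibrated to the weights),
#' then draws pixel colours as independent per-channel Gaussians around each
#' label's mean Lab. Fully reproducible from `spec$seed`.
#'
#' @param spec a [scene_spec()].
#' @return an object of class `synthetic_scene`: list with `lab`
#'   (height x width x 3 array), `labels` (integer matrix, `NA` under the
#'   target), `target_mask` (logical matrix) and `spec`.
#' @export
generate_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  h <- spec$height_px; w <- spec$width_px
  k <- length(spec$microhabitats)
  weights <- vapply(spec$microhabitats, `[[`, 1.0, "weight")

  labels <- withr::with_seed(substream_seed(spec$seed, "scene-labels"), {
    if (k == 1L) {
      matrix(1L, h, w)
    } else {
      fields <- lapply(spec$microhabitats, function(m) {
        f <- gaussian_blur_cpp(matrix(rnorm(h * w), h, w), m$patch_scale_px / 2)
        (f - mean(f)) / sd(f)
      })
      .field_argmax(fields, .calibrate_offsets(fields, weights))
    }
  })

  lab <- withr::with_seed(substream_seed(spec$seed, "scene-colors"), {
    means <- t(vapply(spec$microhabitats, `[[`, numeric(3), "mean_lab"))
    sds <- t(vapply(spec$microhabitats, `[[`, numeric(3), "sd_lab"))
    arr <- array(0, dim = c(h, w, 3))
    idx <- as.vector(labels)
    for (ch in 1:3)
      arr[, , ch] <- means[idx, ch] + sds[idx, ch] * rnorm(h * w)
    arr
  })

  structure(list(lab = lab, labels = labels,
                 target_mask = matrix(FALSE, h, w), spec = spec),
            class = "synthetic_scene")
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cat(sprintf("synthetic_scene: %d x %d px, %.2f px/mm, %d microhabitat(s) [%s]\n",
              x$spec$height_px, x$spec$width_px, x$spec$px_per_mm,
              length(x$spec$microhabitats),
              paste(habitat_names(x$spec), collapse = ", ")))
  if (any(x$target_mask))
    cat(sprintf("  target: %d px (bounding box %d x %d)\n", sum(x$target_mask),
                diff(range(which(rowSums(x$target_mask) > 0))) + 1L,
                diff(range(which(colSums(x$target_mask) > 0))) + 1L))
  invisible(x)
}

#' Stylised hare silhouette
#'
#' A synthetic stand-in for the hare-shaped target: ellipse body, round head
#' and two ears, facing right (use `flip = TRUE` for left-facing).
#'
#' @param height_px silhouette height in pixels.
#' @param width_px silhouette width; default preserves the 40 cm tall x
#'   26 cm wide aspect ratio (0.65).
#' @param flip mirror horizontally.
#' @return logical matrix `height_px` x `width_px`.
#' @export
hare_silhouette <- function(height_px, width_px = round(height_px * 0.65),
                            flip = FALSE) {
  .check_scalar(height_px, "height_px", positive = TRUE, integer = TRUE)
  .check_scalar(width_px, "width_px", positive = TRUE, integer = TRUE)
  r <- (row(matrix(0, height_px, width_px)) - 0.5) / height_px
  c <- (col(matrix(0, height_px, width_px)) - 0.5) / width_px
  ell <- function(rc, cc, rr, cr)
    ((r - rc) / rr)^2 + ((c - cc) / cr)^2 <= 1
  m <- ell(0.695, 0.45, 0.31, 0.48) |     # body (reaches the bottom edge)
       ell(0.38, 0.75, 0.16, 0.25) |      # head
       ell(0.155, 0.82, 0.165, 0.07) |    # ear (reaches the top edge)
       ell(0.155, 0.64, 0.165, 0.07)      # ear
  if (flip) m <- m[, rev(seq_len(ncol(m))), drop = FALSE]
  m
}

# nearest-neighbour rescale of a logical mask to a target height
.rescale_mask <- function(mask, height_px) {
  h0 <- nrow(mask); w0 <- ncol(mask)
  w1 <- max(1L, round(w0 * height_px / h0))
  ri <- pmin(h0, pmax(1L, ceiling(seq_len(height_px) * h0 / height_px)))
  ci <- pmin(w0, pmax(1L, ceiling(seq_len(w1) * w0 / w1)))
  mask[ri, ci, drop = FALSE]
}

#' Place a target silhouette in a scene
#'
#' Scales the silhouette to `height_mm * px_per_mm` pixels tall (rounded),
#' stamps it into the scene's target mask (centred unless `offset` is given)
#' and removes microhabitat labels under the target.
#'
#' @param scene a `synthetic_scene`.
#' @param silhouette logical matrix defining the shape at any resolution;
#'   default [hare_silhouette()] at the scaled height.
#' @param height_mm real-world target height (default 400 mm).
#' @param offset integer `(row, col)` displacement of the target centre from
#'   the scene centre.
#' @return the scene with `target_mask` set and covered labels set to `NA`.
#' @export
place_target <- function(scene, silhouette = NULL, height_mm = 400,
                         offset = c(0L, 0L)) {
  stopifnot(inherits(scene, "synthetic_scene"))
  hpx <- as.integer(round(height_mm * scene$spec$px_per_mm))
  sil <- if (is.null(silhouette)) hare_silhouette(hpx) else {
    stopifnot(is.logical(silhouette), is.matrix(silhouette))
    if (!any(silhouette)) return(scene)  # empty silhouette: unchanged
    .rescale_mask(silhouette, hpx)
  }
  h <- nrow(scene$labels); w <- ncol(scene$labels)
  sh <- nrow(sil); sw <- ncol(sil)
  if (sh > h || sw > w)
    stop(sprintf("silhouette (%d x %d) does not fit in scene (%d x %d)",
                 sh, sw, h, w), call. = FALSE)
  r0 <- floor((h - sh) / 2) + 1L + offset[1]
  c0 <- floor((w - sw) / 2) + 1L + offset[2]
  if (r0 < 1L || c0 < 1L || r0 + sh - 1L > h || c0 + sw - 1L > w)
    stop("offset pushes the target outside the scene", call. = FALSE)
  scene$target_mask[r0:(r0 + sh - 1L), c0:(c0 + sw - 1L)] <-
    scene$target_mask[r0:(r0 + sh - 1L), c0:(c0 + sw - 1L)] | sil
  scene$labels[scene$target_mask] <- NA_integer_
  scene
}

#' Render a scene to 8-bit RGB
#'
#' Lab -> XYZ -> linear RGB -> power-law presentation encoding, with linear
#' values clipped to gamut.
#'
#' @param scene a `synthetic_scene`.
#' @param power presentation exponent.
#' @return integer array height x width x 3 in `0:255`.
#' @export
render_scene <- function(scene, power = 0.42) {
  stopifnot(inherits(scene, "synthetic_scene"))
  lab_to_rgb(scene$lab, power = power)
}

#' Write a scene to disk
#'
#' Writes `<name>.png` (rendered sRGB-like image), `<name>_labels.png`
#' (indexed grey levels) and `<name>_mask.png` to `dir`.
#'
#' @param scene a `synthetic_scene`.
#' @param dir output directory (created if needed).
#' @param name file stem.
#' @return invisibly, the three file paths.
#' @export
write_scene <- function(scene, dir, name = "scene") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  img <- render_scene(scene) / 255
  p1 <- file.path(dir, paste0(name, ".png"))
  png::writePNG(img, p1)
  lab <- scene$labels
  lab[is.na(lab)] <- 0L
  p2 <- file.path(dir, paste0(name, "_labels.png"))
  png::writePNG(lab / max(1L, max(lab)), p2)
  p3 <- file.path(dir, paste0(name, "_mask.png"))
  png::writePNG(scene$target_mask * 1, p3)
  invisible(c(p1, p2, p3))
}
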