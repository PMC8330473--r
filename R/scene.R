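# Scene analysis: ranked smoothing, naive Bayes microhabitat segmentation,
# patch (particle) statistics, near-zone construction and target-background
# colour contrast predictors.

#' Ranked-filter parameters
#'
#' Parameters of the edge-preserving smoothing filter applied before
#' clustering. Discriminability gates derive from receptor-noise-style Weber
#' fractions: a neighbour contributes to the channelwise median only if its
#' luminance (L) difference and chromatic (a, b plane) distance from the
#' centre pixel fall below `threshold_mult * weber * 100`, scaled by the
#' distance weight `(1 - r/kernel_radius)^falloff`.
#'
#' @param weber_chrom chromatic Weber fraction (default 0.05).
#' @param weber_lum luminance Weber fraction (default 0.1).
#' @param kernel_radius neighbourhood radius in pixels (default 3).
#' @param falloff distance-weight exponent (default 2).
#' @param iterations filter passes (default 3).
#' @param threshold_mult multiplier scaling Weber fractions to Lab channel
#'   range (default 2, i.e. gates of 20 L units and 10 chroma units at the
#'   centre of the kernel).
#' @return object of class `filter_params`.
#' @export
filter_params <- function(weber_chrom = 0.05, weber_lum = 0.1,
                          kernel_radius = 3, falloff = 2, iterations = 3,
                          threshold_mult = 2) {
  for (nm in c("weber_chrom", "weber_lum", "kernel_radius", "falloff",
               "threshold_mult"))
    .check_scalar(get(nm), nm, positive = TRUE)
  .check_scalar(iterations, "iterations", positive = TRUE, integer = TRUE)
  structure(list(weber_chrom = weber_chrom, weber_lum = weber_lum,
                 kernel_radius = as.integer(kernel_radius), falloff = falloff,
                 iterations = as.integer(iterations),
                 threshold_mult = threshold_mult),
            class = "filter_params")
}

#' Edge-preserving ranked smoothing of a Lab image
#'
#' Iterated threshold-gated, distance-weighted channelwise median filter (see
#' [filter_params()]). Within-patch noise is smoothed away while boundaries
#' between patches whose colour difference exceeds the gates are preserved; a
#' uniform image is a fixed point.
#'
#' @param lab Lab image (height x width x 3 array).
#' @param params a [filter_params()].
#' @return smoothed Lab image, same dimensions.
#' @export
ranked_smooth <- function(lab, params = filter_params()) {
  stopifnot(inherits(params, "filter_params"),
            length(dim(lab)) == 3L, dim(lab)[3] == 3L)
  thr_lum <- params$threshold_mult * params$weber_lum * 100
  thr_chrom <- params$threshold_mult * params$weber_chrom * 100
  res <- ranked_filter_cpp(lab[, , 1], lab[, , 2], lab[, , 3],
                           params$kernel_radius, params$falloff,
                           thr_lum, thr_chrom, params$iterations)
  out <- array(0, dim = dim(lab))
  out[, , 1] <- res$L; out[, , 2] <- res$a; out[, , 3] <- res$b
  out
}

#' Fit a naive Bayes microhabitat classifier
#'
#' Diagonal-covariance Gaussian class-conditional model in Lab, one class per
#' microhabitat, summarised by per-channel means and SDs (floored at 1e-6).
#'
#' @param groups list of [color_group()] objects (>= 2), or a list of
#'   [microhabitat()] objects (their `mean_lab` / `sd_lab` are used).
#' @param priors class priors; default uniform. Must sum to 1.
#' @return object of class `habitat_classifier`.
#' @export
fit_classifier <- function(groups, priors = NULL) {
  if (length(groups) < 2L)
    stop("need at least two groups to classify", call. = FALSE)
  if (all(vapply(groups, inherits, TRUE, "microhabitat"))) {
    means <- t(vapply(groups, `[[`, numeric(3), "mean_lab"))
    sds <- t(vapply(groups, `[[`, numeric(3), "sd_lab"))
    nms <- vapply(groups, `[[`, "", "name")
  } else if (all(vapply(groups, inherits, TRUE, "color_group"))) {
    means <- t(vapply(groups, `[[`, numeric(3), "mean"))
    sds <- t(vapply(groups, `[[`, numeric(3), "sd"))
    nms <- vapply(groups, `[[`, "", "name")
  } else stop("'groups' must all be color_group or microhabitat objects",
              call. = FALSE)
  sds <- pmax(sds, 1e-6)
  k <- nrow(means)
  if (is.null(priors)) priors <- rep(1 / k, k)
  if (length(priors) != k || any(priors < 0) || abs(sum(priors) - 1) > 1e-8)
    stop("'priors' must be non-negative and sum to 1", call. = FALSE)
  structure(list(habitats = nms, means = means, sds = sds, priors = priors),
            class = "habitat_classifier")
}

#' @export
print.habitat_classifier <- function(x, ...) {
  cat(sprintf("habitat_classifier: %d classes (%s)\n",
              length(x$habitats), paste(x$habitats, collapse = ", ")))
  invisible(x)
}

#' Per-pixel class posteriors
#'
#' @param clf a [fit_classifier()] object.
#' @param lab Lab colours (n x 3 matrix or h x w x 3 array).
#' @return n x k matrix of posterior probabilities (rows sum to 1).
#' @export
posterior_probs <- function(clf, lab) {
  m <- if (length(dim(lab)) == 3L) .flatten_lab(lab) else .as_color_matrix(lab)
  ll <- .loglik_matrix(clf, m)
  ll <- ll - apply(ll, 1, max)
  p <- exp(ll)
  p / rowSums(p)
}

.loglik_matrix <- function(clf, m) {
  k <- length(clf$habitats)
  ll <- matrix(0, nrow(m), k)
  for (j in seq_len(k)) {
    s <- 0
    for (ch in 1:3)
      s <- s - (m[, ch] - clf$means[j, ch])^2 / (2 * clf$sds[j, ch]^2) -
        log(clf$sds[j, ch])
    ll[, j] <- s + log(clf$priors[j])
  }
  colnames(ll) <- clf$habitats
  ll
}

#' Classify pixels into microhabitats
#'
#' Per-pixel argmax of log prior plus summed per-channel Gaussian
#' log-likelihoods. Exact posterior ties go to the lowest habitat index.
#' Excluded pixels (target, exclusion zone, scene exclusions) get `NA`.
#'
#' @param clf a [fit_classifier()] object.
#' @param lab Lab image (height x width x 3 array).
#' @param exclude optional logical matrix, `TRUE` = exclude.
#' @return integer label matrix with attribute `habitats` (class names).
#' @export
classify_pixels <- function(clf, lab, exclude = NULL) {
  stopifnot(inherits(clf, "habitat_classifier"),
            length(dim(lab)) == 3L, dim(lab)[3] == 3L)
  d <- dim(lab)[1:2]
  if (!is.null(exclude))
    stopifnot(is.logical(exclude), all(dim(exclude) == d))
  ll <- .loglik_matrix(clf, .flatten_lab(lab))
  lab_idx <- max.col(ll, ties.method = "first")
  out <- matrix(as.integer(lab_idx), d[1], d[2])
  if (!is.null(exclude)) out[exclude] <- NA_integer_
  attr(out, "habitats") <- clf$habitats
  out
}

#' Particle analysis of a label map
#'
#' Connected-component ("cluster particle") analysis: one row per contiguous
#' patch of same-labelled pixels, with its pixel area. `NA` ("none") pixels
#' are excluded.
#'
#' @param labels integer label matrix (optionally with a `habitats` name
#'   attribute, as returned by [classify_pixels()]).
#' @param connectivity 4 or 8 (default 8).
#' @return data frame `(habitat, patch_id, area_px)` of class `patch_table`;
#'   `patch_id` is sequential within habitat.
#' @export
particle_analysis <- function(labels, connectivity = 8) {
  stopifnot(is.matrix(labels), connectivity %in% c(4, 8))
  hab <- attr(labels, "habitats")
  lm <- labels
  storage.mode(lm) <- "integer"
  comp <- label_components_cpp(lm, as.integer(connectivity))
  np <- max(comp)
  if (np == 0L)
    return(structure(data.frame(habitat = character(), patch_id = integer(),
                                area_px = integer()),
                     class = c("patch_table", "data.frame")))
  areas <- tabulate(comp, np)
  first <- match(seq_len(np), comp)
  lab_of <- lm[first]
  hab_of <- if (is.null(hab)) as.character(lab_of) else hab[lab_of]
  ord <- order(lab_of, seq_len(np))
  df <- data.frame(habitat = hab_of[ord],
                   patch_id = unlist(lapply(table(lab_of), seq_len),
                                     use.names = FALSE),
                   area_px = areas[ord])
  structure(df, class = c("patch_table", "data.frame"))
}

#' Per-habitat patch summaries
#'
#' @param patches a [particle_analysis()] table.
#' @return data frame with per-habitat patch count, median and total area.
#' @export
patch_summary <- function(patches) {
  stopifnot(inherits(patches, "patch_table"))
  habs <- unique(patches$habitat)
  do.call(rbind, lapply(habs, function(h) {
    a <- patches$area_px[patches$habitat == h]
    data.frame(habitat = h, n_patches = length(a),
               median_area_px = median(a), total_area_px = sum(a))
  }))
}

# binary Chebyshev (square structuring element) dilation, separable
.cheb_dilate <- function(mask, k) {
  if (k <= 0) return(mask)
  h <- nrow(mask); w <- ncol(mask)
  out <- matrix(FALSE, h, w)
  for (d in -k:k) {
    src <- max(1, 1 - d):min(h, h - d)
    out[src + d, ] <- out[src + d, ] | mask[src, ]
  }
  res <- matrix(FALSE, h, w)
  for (d in -k:k) {
    src <- max(1, 1 - d):min(w, w - d)
    res[, src + d] <- res[, src + d] | out[, src]
  }
  res
}

#' Near-zone mask around a target
#'
#' The "immediate surrounds": a band of width `band_width_px` around the
#' target, starting beyond an exclusion ring of width `exclusion_px` (which
#' guards against target pixels contaminating background measurements).
#' Dilations use a square (Chebyshev) structuring element and are clipped at
#' image borders.
#'
#' @param target_mask logical matrix of target pixels.
#' @param band_width_px band width in pixels (>= 0; 0 gives an empty mask).
#' @param exclusion_px exclusion-ring width in pixels (>= 0).
#' @return logical mask, disjoint from the target and the exclusion ring.
#' @export
near_zone_mask <- function(target_mask, band_width_px, exclusion_px = 0) {
  stopifnot(is.logical(target_mask), is.matrix(target_mask))
  if (band_width_px < 0 || exclusion_px < 0)
    stop("band and exclusion widths must be >= 0", call. = FALSE)
  if (band_width_px == 0) return(target_mask & FALSE)
  outer <- .cheb_dilate(target_mask, as.integer(exclusion_px + band_width_px))
  inner <- .cheb_dilate(target_mask, as.integer(exclusion_px))
  outer & !inner
}

#' Target-background colour contrast predictors
#'
#' Computes the two CIEDE2000 predictors of detection risk: contrast between
#' the target colour and the mean Lab of (i) the near zone and (ii) the whole
#' scene (excluding target, exclusion ring and any scene exclusions).
#'
#' @param target_lab length-3 Lab colour of the (uniform) target.
#' @param lab Lab image (height x width x 3 array).
#' @param target_mask logical target mask.
#' @param band_width_px near-zone band width in pixels (conventionally the
#'   target height).
#' @param exclusion_px exclusion-ring width in pixels.
#' @param scene_exclude optional logical mask of scene-level exclusions
#'   (skyline, man-made structures).
#' @return named list `delta_e_near`, `delta_e_whole`.
#' @export
contrast_predictors <- function(target_lab, lab, target_mask, band_width_px,
                                exclusion_px = 0, scene_exclude = NULL) {
  stopifnot(length(dim(lab)) == 3L,
            all(dim(target_mask) == dim(lab)[1:2]))
  keep <- if (is.null(scene_exclude)) TRUE else !scene_exclude
  near <- near_zone_mask(target_mask, band_width_px, exclusion_px) & keep
  whole <- !.cheb_dilate(target_mask, as.integer(exclusion_px)) & keep
  if (!any(near)) stop("near zone is empty", call. = FALSE)
  if (!any(whole)) stop("whole-scene background is empty", call. = FALSE)
  list(delta_e_near = delta_e_ciede2000(target_lab, region_mean_lab(lab, near)),
       delta_e_whole = delta_e_ciede2000(target_lab, region_mean_lab(lab, whole)))
}

#' Habitat proportions within a region
#'
#' Proportion of labelled pixels in a region belonging to each habitat
#' (`NA`/"none" pixels excluded). Proportions sum to 1.
#'
#' @param labels integer label matrix (with optional `habitats` attribute).
#' @param region optional logical matrix restricting the region (default:
#'   whole image).
#' @return named numeric vector of proportions, one entry per habitat level.
#' @export
habitat_proportions <- function(labels, region = NULL) {
  stopifnot(is.matrix(labels))
  hab <- attr(labels, "habitats")
  k <- if (is.null(hab)) max(labels, na.rm = TRUE) else length(hab)
  v <- if (is.null(region)) as.vector(labels) else {
    stopifnot(is.logical(region), all(dim(region) == dim(labels)))
    labels[region]
  }
  v <- v[!is.na(v)]
  if (length(v) == 0L)
    stop("region contains no labelled pixels", call. = FALSE)
  p <- tabulate(v, k) / length(v)
  names(p) <- if (is.null(hab)) as.character(seq_len(k)) else hab
  p
}
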