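# Target-colour design: specialist / generalist colour summaries and the
# paint-matching selection rule.

#' Group of colour samples
#'
#' A named set of Lab samples (one per selection or image) with per-channel
#' min, max and median, as used both for target-colour design and as the
#' training summary of the pixel classifier.
#'
#' @param name group label (e.g. `"grass"`, `"whole_image"`).
#' @param samples Lab samples: length-3 vector or n x 3 matrix.
#' @return object of class `color_group` with `samples`, `min`, `max`,
#'   `median`, `mean`, `sd` (per channel).
#' @export
color_group <- function(name, samples) {
  stopifnot(is.character(name), length(name) == 1L)
  m <- .as_color_matrix(samples, "samples")
  if (nrow(m) < 1L) stop("a colour group needs at least one sample", call. = FALSE)
  structure(list(name = name, samples = m,
                 min = apply(m, 2, min), max = apply(m, 2, max),
                 median = apply(m, 2, median), mean = colMeans(m),
                 sd = if (nrow(m) > 1) apply(m, 2, sd) else rep(0, 3)),
            class = "color_group")
}

#' @export
print.color_group <- function(x, ...) {
  cat(sprintf("color_group '%s': %d sample(s); median Lab = (%.2f, %.2f, %.2f)\n",
              x$name, nrow(x$samples), x$median[1], x$median[2], x$median[3]))
  invisible(x)
}

#' Mean Lab colour of a masked region
#'
#' @param lab Lab image (height x width x 3 array).
#' @param mask logical matrix of the same height/width; must select at least
#'   one pixel.
#' @return length-3 named Lab vector.
#' @export
region_mean_lab <- function(lab, mask) {
  stopifnot(length(dim(lab)) == 3L, dim(lab)[3] == 3L)
  stopifnot(is.logical(mask), all(dim(mask) == dim(lab)[1:2]))
  if (!any(mask)) stop("mask selects no pixels", call. = FALSE)
  out <- vapply(1:3, function(ch) mean(lab[, , ch][mask]), 0.0)
  names(out) <- c("L", "a", "b")
  out
}

#' Whole-scene "generalist" colour
#'
#' The unweighted mean over scenes of each scene's whole-image mean Lab,
#' with per-scene exclusions (sky, colour standards, man-made objects)
#' removed first.
#'
#' @param scenes list; each element a list with `lab` (h x w x 3 array) and
#'   optional logical `exclude` mask (`TRUE` = drop pixel).
#' @return length-3 named Lab vector.
#' @export
generalist_color <- function(scenes) {
  if (length(scenes) < 1L) stop("need at least one scene", call. = FALSE)
  per_scene <- vapply(scenes, function(s) {
    keep <- if (is.null(s$exclude)) {
      matrix(TRUE, dim(s$lab)[1], dim(s$lab)[2])
    } else !s$exclude
    if (!any(keep)) stop("a scene is fully excluded", call. = FALSE)
    region_mean_lab(s$lab, keep)
  }, numeric(3))
  out <- rowMeans(per_scene)
  names(out) <- c("L", "a", "b")
  out
}

# is a Lab colour inside a group's per-channel [min, max] box?
.in_box <- function(lab, group) {
  all(lab >= group$min) && all(lab <= group$max)
}

#' Match paints to target colour groups
#'
#' Selection rule for real paints approximating the designed target colours:
#' a paint is eligible for a group iff its Lab value lies inside that group's
#' per-channel min-max box and inside no other group's box; eligible paints
#' are ranked by CIEDE2000 distance to the group's per-channel median colour
#' (ascending; ties broken by paint name), after removing any paint whose
#' distance to another group's median is less than or equal to its distance
#' to this group's median. The top `n_per_group` survivors are returned; a
#' shortfall is reported, never silently padded.
#'
#' @param palette data frame with columns `name`, `L`, `a`, `b`.
#' @param groups list of [color_group()] objects.
#' @param n_per_group paints requested per group (default 2).
#' @return object of class `paint_match`: named list (one entry per group) of
#'   data frames `(name, delta_e)`, with attribute `shortfall` (named integer
#'   vector of missing counts).
#' @export
match_paints <- function(palette, groups, n_per_group = 2) {
  stopifnot(is.data.frame(palette),
            all(c("name", "L", "a", "b") %in% names(palette)))
  if (nrow(palette) < 1L) stop("palette is empty", call. = FALSE)
  if (inherits(groups, "color_group")) groups <- list(groups)
  stopifnot(all(vapply(groups, inherits, TRUE, "color_group")))
  gnames <- vapply(groups, `[[`, "", "name")
  labm <- as.matrix(palette[, c("L", "a", "b")])
  medians <- t(vapply(groups, `[[`, numeric(3), "median"))

  # membership matrix: paint i inside group j's box
  inside <- vapply(groups, function(g)
    apply(labm, 1, .in_box, group = g), logical(nrow(palette)))
  inside <- matrix(inside, nrow = nrow(palette))
  # delta E to every group median
  de <- vapply(seq_along(groups), function(j)
    delta_e_ciede2000(labm, medians[j, ]), numeric(nrow(palette)))
  de <- matrix(de, nrow = nrow(palette))

  shortfall <- integer(length(groups))
  names(shortfall) <- gnames
  out <- vector("list", length(groups))
  names(out) <- gnames
  for (j in seq_along(groups)) {
    elig <- inside[, j] & rowSums(inside) == 1L
    if (length(groups) > 1L) {
      other_min <- apply(de[, -j, drop = FALSE], 1, min)
      elig <- elig & de[, j] < other_min   # "just as closely" excludes ties
    }
    idx <- which(elig)
    idx <- idx[order(de[idx, j], palette$name[idx])]
    take <- head(idx, n_per_group)
    shortfall[j] <- max(0L, n_per_group - length(take))
    out[[j]] <- data.frame(name = palette$name[take],
                           delta_e = de[take, j], row.names = NULL)
  }
  structure(out, shortfall = shortfall, class = c("paint_match", "list"))
}

#' @export
print.paint_match <- function(x, ...) {
  sf <- attr(x, "shortfall")
  for (g in names(x)) {
    cat(sprintf("%s:", g))
    if (nrow(x[[g]]) == 0) cat(" (no eligible paints)")
    else cat(sprintf(" %s (dE %.3f)", x[[g]]$name, x[[g]]$delta_e))
    if (sf[[g]] > 0) cat(sprintf("  [shortfall: %d]", sf[[g]]))
    cat("\n")
  }
  invisible(x)
}
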