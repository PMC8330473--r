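# Online-experiment stimulus generation: treatment colours, cropping,
# target recolouring, database construction and constrained slide sets.

SMALL_CROP <- c(height = 1080L, width = 1920L)
LARGE_CROP <- c(height = 2160L, width = 3840L)

#' Treatment colours
#'
#' The five 8-bit RGB treatment colours applied to targets in the online
#' search task: four microhabitat specialists and the whole-image generalist.
#' These are fixed constants (re-derivation from new scenes will differ; see
#' [region_mean_lab()] / [generalist_color()] for the derivation route).
#'
#' @return data frame `(name, r, g, b, strategy)`.
#' @export
treatment_colors <- function() {
  data.frame(
    name = c("bracken", "bramble", "leaf_litter", "grass", "whole_image"),
    r = c(143L, 112L, 165L, 132L, 123L),
    g = c(125L, 121L, 139L, 148L, 122L),
    b = c(92L, 85L, 113L, 78L, 81L),
    strategy = c(rep("specialist", 4), "generalist")
  )
}

#' Seeded crop frames around a target
#'
#' Draws three small-crop (1920 x 1080) and three large-crop (3840 x 2160)
#' frames from the feasible offset set (frames fully containing the target
#' box, inside the source). Offsets are sampled without replacement when the
#' feasible set allows, so the three crops per class are pairwise distinct
#' whenever possible; identical seeds give identical crops.
#'
#' @param source_dim integer `(height, width)` of the source image; must be
#'   at least the large-crop size.
#' @param target_box integer `(row0, col0, height, width)` (1-based) of the
#'   target bounding box (including any exclusion zone); must fit inside the
#'   small-crop frame.
#' @param seed integer seed.
#' @param n_per_class crops per class (default 3).
#' @return data frame `(crop_class, row0, col0, height, width)`.
#' @export
make_crops <- function(source_dim, target_box, seed = 1L, n_per_class = 3L) {
  source_dim <- as.integer(source_dim)
  tb <- as.integer(target_box)
  if (length(source_dim) != 2L || length(tb) != 4L)
    stop("'source_dim' must be (h, w) and 'target_box' (row0, col0, h, w)",
         call. = FALSE)
  if (any(source_dim < LARGE_CROP))
    stop("source image smaller than the large-crop frame", call. = FALSE)
  if (tb[3] >= SMALL_CROP["height"] || tb[4] >= SMALL_CROP["width"])
    stop("target box must be smaller than the small-crop frame", call. = FALSE)
  if (tb[1] < 1L || tb[2] < 1L || tb[1] + tb[3] - 1L > source_dim[1] ||
      tb[2] + tb[4] - 1L > source_dim[2])
    stop("target box outside the source image", call. = FALSE)

  one_class <- function(frame, cls, sub) {
    # feasible top-left corners keeping the target box inside the frame
    r_lo <- max(1L, tb[1] + tb[3] - frame[1]); r_hi <- min(tb[1], source_dim[1] - frame[1] + 1L)
    c_lo <- max(1L, tb[2] + tb[4] - frame[2]); c_hi <- min(tb[2], source_dim[2] - frame[2] + 1L)
    nr <- r_hi - r_lo + 1L; nc <- c_hi - c_lo + 1L
    nfeas <- as.numeric(nr) * nc
    pick <- withr::with_seed(substream_seed(seed, sub), {
      if (nfeas >= n_per_class) sample(nfeas, n_per_class)
      else sample(nfeas, n_per_class, replace = TRUE)
    })
    data.frame(crop_class = cls,
               row0 = r_lo + as.integer((pick - 1) %% nr),
               col0 = c_lo + as.integer((pick - 1) %/% nr),
               height = frame[1], width = frame[2])
  }
  rbind(one_class(unname(SMALL_CROP), "small", "crops-small"),
        one_class(unname(LARGE_CROP), "large", "crops-large"))
}

#' Extract crop pixels
#'
#' @param image array (height x width x channels) or matrix.
#' @param crop one row of a [make_crops()] frame table.
#' @return the cropped sub-image.
#' @export
extract_crop <- function(image, crop) {
  r <- crop$row0:(crop$row0 + crop$height - 1L)
  c <- crop$col0:(crop$col0 + crop$width - 1L)
  if (length(dim(image)) == 3L) image[r, c, , drop = FALSE] else image[r, c, drop = FALSE]
}

#' Recolour the target region of a stimulus image
#'
#' Sets every masked pixel (target plus surrounding exclusion zone) to the
#' treatment RGB exactly; all other pixels are untouched. Idempotent.
#'
#' @param image integer 8-bit RGB array (height x width x 3).
#' @param mask logical matrix of target-plus-exclusion pixels; must be
#'   non-empty and within the image.
#' @param treatment a row of [treatment_colors()] (or any list with `r`,
#'   `g`, `b`).
#' @return the recoloured image.
#' @export
recolor_target <- function(image, mask, treatment) {
  stopifnot(length(dim(image)) == 3L, dim(image)[3] == 3L,
            is.logical(mask), all(dim(mask) == dim(image)[1:2]))
  if (!any(mask)) stop("target mask is empty", call. = FALSE)
  rgb <- as.integer(c(treatment$r, treatment$g, treatment$b))
  for (ch in 1:3) {
    plane <- image[, , ch]
    plane[mask] <- rgb[ch]
    image[, , ch] <- plane
  }
  image
}

#' Build the stimulus database (metadata)
#'
#' Expands locations x orientations x crops x treatments into the full
#' stimulus table: `n_locations * 2 * 6 * 5` rows for a complete input (e.g.
#' 40 locations -> 2400 stimuli). Pixel materialisation is separate (crop
#' with [extract_crop()], then [recolor_target()]).
#'
#' @param sources data frame with one row per (location, orientation):
#'   columns `location`, `habitat` (`"wood"`/`"farm"`) and `orientation`
#'   (`"left"`/`"right"`). Unless `permissive`, every location must supply
#'   both orientations.
#' @param treatments treatment table (default [treatment_colors()]).
#' @param n_crops_per_class crops per size class (default 3).
#' @param permissive allow locations with a single orientation.
#' @return data frame of stimulus metadata with columns `id`, `location`,
#'   `habitat`, `orientation`, `crop_class`, `crop_index`, `treatment`,
#'   `strategy`.
#' @export
build_database <- function(sources, treatments = treatment_colors(),
                           n_crops_per_class = 3L, permissive = FALSE) {
  stopifnot(is.data.frame(sources),
            all(c("location", "habitat", "orientation") %in% names(sources)))
  if (!all(sources$orientation %in% c("left", "right")))
    stop("orientation must be 'left' or 'right'", call. = FALSE)
  if (!permissive) {
    tab <- table(sources$location)
    bad <- names(tab)[tab != 2L]
    bad2 <- unique(sources$location[!sources$location %in% names(tab)[tab == 2L]])
    if (length(bad))
      stop(sprintf("location(s) missing an orientation: %s",
                   paste(union(bad, bad2), collapse = ", ")), call. = FALSE)
  }
  crops <- data.frame(
    crop_class = rep(c("small", "large"), each = n_crops_per_class),
    crop_index = rep(seq_len(n_crops_per_class), 2L))
  out <- merge(merge(sources, crops, by = NULL),
               data.frame(treatment = treatments$name,
                          strategy = treatments$strategy), by = NULL)
  out$id <- sprintf("%s_%s_%s%d_%s", out$location, out$orientation,
                    out$crop_class, out$crop_index, out$treatment)
  out[, c("id", "location", "habitat", "orientation", "crop_class",
          "crop_index", "treatment", "strategy")]
}

#' Validate a slide set
#'
#' Checks the full invariant battery: 20 slides; 10 wood + 10 farm; no
#' repeated location; 10 left + 10 right; exactly 4 of each of the 5
#' treatments; exactly 8 small crops.
#'
#' @param set data frame as returned by [sample_slide_set()].
#' @param treatments treatment table defining the expected colour names.
#' @return `TRUE` invisibly, or an error naming the violated constraint.
#' @export
validate_slide_set <- function(set, treatments = treatment_colors()) {
  if (nrow(set) != 20L) stop("slide set must have 20 slides", call. = FALSE)
  if (!all(table(set$habitat)[c("wood", "farm")] == 10L))
    stop("habitat balance violated (need 10 wood + 10 farm)", call. = FALSE)
  if (anyDuplicated(set$location))
    stop("repeated background location", call. = FALSE)
  if (!all(table(set$orientation)[c("left", "right")] == 10L))
    stop("orientation balance violated (need 10 left + 10 right)", call. = FALSE)
  tt <- table(factor(set$treatment, levels = treatments$name))
  if (!all(tt == 4L))
    stop("treatment balance violated (need 4 of each colour)", call. = FALSE)
  if (sum(set$crop_class == "small") != 8L)
    stop("crop balance violated (need exactly 8 small crops)", call. = FALSE)
  invisible(TRUE)
}

#' Sample a constrained slide set
#'
#' Draws 20 stimuli satisfying the slide-set constraints (see
#' [validate_slide_set()]) in a randomised order: balanced marginals are
#' shuffled independently, locations are drawn without replacement within
#' habitat, and a matching database row is chosen at random for each slide
#' (with restarts if an incomplete database makes a draw infeasible).
#'
#' @param database stimulus table from [build_database()].
#' @param seed integer seed.
#' @param max_tries restarts before giving up on a sparse database.
#' @return data frame of 20 stimulus rows, in presentation order, with a
#'   `slide` column; attribute `seed`.
#' @export
sample_slide_set <- function(database, seed = 1L, max_tries = 50L) {
  need <- treatment_colors()$name
  missing_tr <- setdiff(need, unique(database$treatment))
  if (length(missing_tr))
    stop(sprintf("database is missing treatment(s): %s",
                 paste(missing_tr, collapse = ", ")), call. = FALSE)
  locs <- unique(database[, c("location", "habitat")])
  for (h in c("wood", "farm"))
    if (sum(locs$habitat == h) < 10L)
      stop(sprintf("database has fewer than 10 locations in habitat '%s'", h),
           call. = FALSE)

  withr::with_seed(substream_seed(seed, "slide-set"), {
    for (try in seq_len(max_tries)) {
      habitat <- sample(rep(c("wood", "farm"), each = 10L))
      orientation <- sample(rep(c("left", "right"), each = 10L))
      treatment <- sample(rep(need, each = 4L))
      crop_class <- sample(rep(c("small", "large"), c(8L, 12L)))
      loc_pool <- list(wood = sample(locs$location[locs$habitat == "wood"]),
                       farm = sample(locs$location[locs$habitat == "farm"]))
      used <- c(wood = 0L, farm = 0L)
      rows <- integer(20L)
      ok <- TRUE
      for (i in 1:20) {
        used[habitat[i]] <- used[habitat[i]] + 1L
        loc <- loc_pool[[habitat[i]]][used[habitat[i]]]
        cand <- which(database$location == loc &
                      database$orientation == orientation[i] &
                      database$treatment == treatment[i] &
                      database$crop_class == crop_class[i])
        if (length(cand) == 0L) { ok <- FALSE; break }
        rows[i] <- if (length(cand) == 1L) cand else sample(cand, 1L)
      }
      if (ok) {
        out <- database[rows, , drop = FALSE]
        out$slide <- 1:20
        rownames(out) <- NULL
        attr(out, "seed") <- seed
        return(out)
      }
    }
    stop("could not satisfy slide-set constraints: no stimulus available for a required (location, orientation, treatment, crop) combination",
         call. = FALSE)
  })
}
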