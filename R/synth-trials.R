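# Simulated detection trials with known hazard structure.
#
# Detection "times" live on the transformed relative-distance scale
# u = 1 - d/d_max in [0, 1 - d_min/d_max]: a proportional-hazards law is
# imposed directly on u (the scale on which the analysis models are fitted),
# with an exponential baseline and normal random effects (log-frailties) for
# subject and position.

#' Define a detection-trial simulation design
#'
#' Defaults mirror the field study being emulated: 39 observer trials over 20
#' transect positions (780 presentations), maximum viewing distances between
#' 30 and 200 m averaging about 57 m, and a baseline event rate giving
#' roughly a 10% miss fraction.
#'
#' @param n_subjects,n_positions design size; each subject sees each position
#'   once.
#' @param strategy_log_hr true log hazard ratio of the generalist level of a
#'   binary strategy covariate.
#' @param delta_e_log_hr true per-unit log hazard slope on a `delta_e_near`
#'   covariate (used when the presentation table carries one).
#' @param subject_sd,position_sd SDs of normal random effects on the
#'   log-hazard scale.
#' @param d_max_min,d_max_mean,d_max_cap maximum viewing distance per
#'   position is `d_max_min + Exp(mean = d_max_mean - d_max_min)` truncated
#'   at `d_max_cap` (metres).
#' @param d_min_range range of the uniform minimum-approach distance
#'   (metres).
#' @param baseline_hazard exponential event rate on the u scale.
#' @param timeout_s censoring horizon for online-style trials (seconds).
#' @param seed integer seed.
#' @return an object of class `trial_design`.
#' @export
trial_design <- function(n_subjects = 39, n_positions = 20,
                         strategy_log_hr = 0, delta_e_log_hr = 0,
                         subject_sd = 0.2, position_sd = 0.2,
                         d_max_min = 30, d_max_mean = 57, d_max_cap = 200,
                         d_min_range = c(1, 15),
                         baseline_hazard = 2.5, timeout_s = 10, seed = 1L) {
  .check_scalar(n_subjects, "n_subjects", positive = TRUE, integer = TRUE)
  .check_scalar(n_positions, "n_positions", positive = TRUE, integer = TRUE)
  if (subject_sd < 0 || position_sd < 0)
    stop("random-effect SDs must be >= 0", call. = FALSE)
  if (baseline_hazard < 0) stop("'baseline_hazard' must be >= 0", call. = FALSE)
  if (d_min_range[2] >= d_max_min)
    stop("minimum distances must stay below the smallest maximum distance",
         call. = FALSE)
  structure(list(n_subjects = as.integer(n_subjects),
                 n_positions = as.integer(n_positions),
                 strategy_log_hr = strategy_log_hr,
                 delta_e_log_hr = delta_e_log_hr,
                 subject_sd = subject_sd, position_sd = position_sd,
                 d_max_min = d_max_min, d_max_mean = d_max_mean,
                 d_max_cap = d_max_cap, d_min_range = d_min_range,
                 baseline_hazard = baseline_hazard,
                 timeout_s = timeout_s, seed = as.integer(seed)),
            class = "trial_design")
}

# default presentation table: each subject sees each position once, with
# strategy balanced within subject
.default_presentations <- function(design) {
  ns <- design$n_subjects; np <- design$n_positions
  df <- expand.grid(position = seq_len(np), subject = seq_len(ns))[, 2:1]
  strat <- withr::with_seed(substream_seed(design$seed, "presentations"), {
    unlist(lapply(seq_len(ns), function(s)
      sample(rep_len(c("specialist", "generalist"), np))))
  })
  # specialist as reference level: coefficients report generalist log-HRs
  df$strategy <- factor(strat, levels = c("specialist", "generalist"))
  df
}

#' Simulate detection trials
#'
#' For each presentation an event "time" on the transformed scale
#' `u in [0, 1 - d_min/d_max]` is drawn from an exponential baseline scaled
#' by `exp(X beta + b_subject + b_position)`; draws beyond the position's
#' maximum u are censored (missed targets). Detection distance is
#' back-computed as `d = d_max * (1 - u)`.
#'
#' @param design a [trial_design()].
#' @param presentations optional data frame with columns `subject`,
#'   `position`, `strategy` and optionally `delta_e_near` (plus any
#'   bookkeeping columns, carried through). Default: every subject x
#'   position, strategy balanced within subject.
#' @return data frame of detection records: the presentation columns plus
#'   `d_max`, `d_min`, `detected` (logical) and `d_detect` (`NA` when
#'   missed).
#' @export
generate_detection_trials <- function(design, presentations = NULL) {
  stopifnot(inherits(design, "trial_design"))
  if (is.null(presentations)) presentations <- .default_presentations(design)
  stopifnot(all(c("subject", "position") %in% names(presentations)))
  np <- design$n_positions
  if (max(presentations$position) > np)
    stop("presentation table refers to unknown positions", call. = FALSE)

  geom <- withr::with_seed(substream_seed(design$seed, "positions"), {
    d_max <- pmin(design$d_max_cap,
                  design$d_max_min + rexp(np, 1 / (design$d_max_mean - design$d_max_min)))
    d_min <- runif(np, design$d_min_range[1], design$d_min_range[2])
    list(d_max = d_max, d_min = d_min)
  })
  fr <- withr::with_seed(substream_seed(design$seed, "frailty"), {
    list(subj = rnorm(max(presentations$subject), 0, design$subject_sd),
         pos = rnorm(np, 0, design$position_sd))
  })

  lp <- fr$subj[presentations$subject] + fr$pos[presentations$position]
  if (!is.null(presentations$strategy))
    lp <- lp + design$strategy_log_hr * (presentations$strategy == "generalist")
  if (!is.null(presentations$delta_e_near))
    lp <- lp + design$delta_e_log_hr * presentations$delta_e_near

  n <- nrow(presentations)
  u <- withr::with_seed(substream_seed(design$seed, "events"), {
    rate <- design$baseline_hazard * exp(lp)
    ifelse(rate > 0, rexp(n) / rate, Inf)
  })
  d_max <- geom$d_max[presentations$position]
  d_min <- geom$d_min[presentations$position]
  u_max <- 1 - d_min / d_max
  detected <- u <= u_max
  out <- presentations
  out$d_max <- d_max
  out$d_min <- d_min
  out$detected <- detected
  out$d_detect <- ifelse(detected, d_max * (1 - u), NA_real_)
  out
}

#' Default microhabitat palette for synthetic scenes
#'
#' Realistic temperate-vegetation Lab means and SDs for the four
#' microhabitats (grass, bracken, bramble, leaf litter), equal weights.
#'
#' @param patch_scale_px characteristic patch diameter in pixels.
#' @param sd_scale multiplier on the per-channel SDs.
#' @return list of four [microhabitat()] objects.
#' @export
default_microhabitats <- function(patch_scale_px = 8, sd_scale = 1) {
  list(
    microhabitat("grass",       c(52, -16, 30), c(5, 3, 5) * sd_scale, 0.25, patch_scale_px),
    microhabitat("bracken",     c(56,  10, 36), c(5, 3, 5) * sd_scale, 0.25, patch_scale_px),
    microhabitat("bramble",     c(30,  -8, 14), c(5, 3, 5) * sd_scale, 0.25, patch_scale_px),
    microhabitat("leaf_litter", c(44,   8, 24), c(5, 3, 5) * sd_scale, 0.25, patch_scale_px)
  )
}

#' Simulate a colour-contrast detection study end to end
#'
#' Generates one synthetic scene per transect position, places a target,
#' computes target-background colour contrast predictors (near zone and
#' whole image) for every treatment colour (the four microhabitat
#' "specialists" plus the areal-average "generalist"), then simulates
#' detection trials whose hazard is driven by the near-zone contrast.
#'
#' @param design a [trial_design()]; its `delta_e_log_hr` drives the hazard.
#' @param scene_px scene side length in pixels.
#' @param px_per_mm spatial scale of the scenes.
#' @param target_height_mm target height.
#' @param exclusion_px exclusion-band width around the target outline.
#' @param microhabitats list of [microhabitat()]s for the scenes.
#' @return list with `predictors` (one row per position x treatment:
#'   `position`, `treatment`, `strategy`, `delta_e_near`, `delta_e_whole`)
#'   and `trials` (detection records with predictors merged in).
#' @export
simulate_contrast_study <- function(design = trial_design(),
                                    scene_px = 512, px_per_mm = 0.15,
                                    target_height_mm = 400, exclusion_px = 2,
                                    microhabitats = default_microhabitats(patch_scale_px = 48)) {
  stopifnot(inherits(design, "trial_design"))
  np <- design$n_positions
  means <- t(vapply(microhabitats, `[[`, numeric(3), "mean_lab"))
  weights <- vapply(microhabitats, `[[`, 1.0, "weight")
  hnames <- vapply(microhabitats, `[[`, "", "name")
  treatments <- rbind(means, colSums(means * weights))
  rownames(treatments) <- c(hnames, "whole_image")
  strategy <- c(rep("specialist", length(hnames)), "generalist")

  band_px <- as.integer(round(target_height_mm * px_per_mm))
  pred <- do.call(rbind, lapply(seq_len(np), function(p) {
    sc <- generate_scene(scene_spec(scene_px, scene_px, px_per_mm,
                                    microhabitats,
                                    seed = substream_seed(design$seed, paste0("scene-", p))))
    sc <- place_target(sc, height_mm = target_height_mm)
    # background means are shared across treatments: compute masks once
    near <- near_zone_mask(sc$target_mask, band_px, exclusion_px)
    whole <- !.cheb_dilate(sc$target_mask, exclusion_px)
    mean_near <- region_mean_lab(sc$lab, near)
    mean_whole <- region_mean_lab(sc$lab, whole)
    data.frame(position = p, treatment = rownames(treatments),
               strategy = factor(strategy, levels = c("specialist", "generalist")),
               delta_e_near = delta_e_ciede2000(treatments, mean_near),
               delta_e_whole = delta_e_ciede2000(treatments, mean_whole),
               row.names = NULL)
  }))

  pres <- .default_presentations(design)
  treat <- withr::with_seed(substream_seed(design$seed, "treatments"), {
    unlist(lapply(seq_len(design$n_subjects), function(s)
      sample(rep_len(rownames(treatments), design$n_positions))))
  })
  pres$treatment <- treat
  pres$strategy <- factor(strategy[match(treat, rownames(treatments))],
                          levels = c("specialist", "generalist"))
  pres <- merge(pres, pred, by = c("position", "treatment", "strategy"),
                sort = FALSE)
  trials <- generate_detection_trials(design, pres)
  list(predictors = pred, trials = trials)
}
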