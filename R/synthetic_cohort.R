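#' Toy brain-like region atlas
#'
#' Builds an ellipsoidal "brain" foreground on the grid and partitions it
#' into left/right lateral region pairs plus midline regions, with a lower
#' z-slab flagged infratentorial — a schematic stand-in for the 18-region
#' parcellation (8 left/right pairs of lobes plus cerebellar vermis and
#' brainstem as midline structures). Lateral pairs are allocated to the
#' tentorial compartments proportionally to compartment size (at least one
#' infratentorial pair when the cut is positive, the cerebellum analogue);
#' midline regions sit in the infratentorial zone when it exists.
#'
#' @param shape grid shape (integer triple).
#' @param n_lateral_pairs number of left/right region pairs (default 8).
#' @param n_midline number of midline regions (default 2).
#' @param infratentorial_fraction fraction of the z-extent below which
#'   voxels are infratentorial; 0 disables the compartment split.
#' @param voxel_volume voxel volume in mm^3 for region-volume arithmetic.
#' @return A [region_atlas()] with `n_lateral_pairs * 2 + n_midline` regions.
#' @examples
#' atlas <- build_toy_atlas(c(24, 24, 24))  # 18 regions
#' nrow(atlas$regions)
#' @export
build_toy_atlas <- function(shape, n_lateral_pairs = 8, n_midline = 2,
                            infratentorial_fraction = 0.25,
                            voxel_volume = 0.08) {
  shape <- as.integer(shape)
  grid <- grid_spec(shape, voxel_volume = voxel_volume)
  if (n_lateral_pairs < 1L) stop("need at least one lateral pair")
  if (n_midline < 0L) stop("n_midline must be >= 0")
  if (infratentorial_fraction < 0 || infratentorial_fraction >= 1)
    stop("infratentorial_fraction must lie in [0, 1)")

  ctr <- (shape - 1) / 2
  semi <- pmax((shape - 1) / 2, 0.5)
  xi <- (seq_len(shape[1]) - 1 - ctr[1]) / semi[1]
  yi <- (seq_len(shape[2]) - 1 - ctr[2]) / semi[2]
  zi <- (seq_len(shape[3]) - 1 - ctr[3]) / semi[3]
  fg <- outer(outer(xi^2, yi^2, `+`), zi^2, `+`) <= 1
  idx <- which(fg)
  coords <- arrayInd(idx, shape) - 1L
  if (length(idx) < 2L * n_lateral_pairs + n_midline)
    stop("infeasible partition: foreground too small for requested regions")

  zcut <- floor(infratentorial_fraction * shape[3])
  infra <- coords[, 3] < zcut
  mid_hw <- max(1, shape[1] / 12)
  in_mid_slab <- abs(coords[, 1] - ctr[1]) < mid_hw

  labels <- array(0L, dim = shape)
  regions <- list()
  rid <- 0L
  add_region <- function(vox, name, lat, comp) {
    if (length(vox) == 0L)
      stop("infeasible partition: region '", name, "' would be empty")
    rid <<- rid + 1L
    labels[idx[vox]] <<- rid
    regions[[rid]] <<- data.frame(region_id = rid, name = name,
                                  laterality = lat, compartment = comp,
                                  stringsAsFactors = FALSE)
  }
  z_bands <- function(sel, nb) {
    z <- coords[sel, 3]
    if (nb == 1L) return(rep(1L, length(z)))
    br <- unique(stats::quantile(z, probs = seq(0, 1, length.out = nb + 1),
                                 type = 1))
    if (length(br) < nb + 1)
      stop("infeasible partition: not enough z levels for ", nb, " bands")
    as.integer(cut(z, breaks = br, include.lowest = TRUE))
  }

  # midline regions (vermis/brainstem analogues when an infra zone exists)
  mid_sel <- logical(length(idx))
  if (n_midline > 0L) {
    mid_sel <- in_mid_slab & (if (zcut > 0L) infra else TRUE)
    if (!any(mid_sel))
      stop("infeasible partition: no voxels available for midline regions")
    bands <- z_bands(mid_sel, n_midline)
    comp <- if (zcut > 0L) "infratentorial" else "supratentorial"
    wh <- which(mid_sel)
    for (b in seq_len(n_midline))
      add_region(wh[bands == b], sprintf("midline_%d", b), "midline", comp)
  }

  # lateral pairs, allocated across compartments by voxel share
  lat_sel <- !mid_sel
  n_inf_vox <- sum(lat_sel & infra)
  n_pairs_inf <- if (zcut > 0L && n_inf_vox > 0L)
    min(n_lateral_pairs - (n_inf_vox < sum(lat_sel)),
        max(1L, round(n_lateral_pairs * n_inf_vox / sum(lat_sel))))
  else 0L
  n_pairs_sup <- n_lateral_pairs - n_pairs_inf
  left <- coords[, 1] <= ctr[1]

  add_pairs <- function(sel, npairs, comp, tag) {
    if (npairs == 0L) return(invisible())
    bands <- z_bands(sel, npairs)
    wh <- which(sel)
    for (b in seq_len(npairs)) {
      add_region(wh[bands == b & left[wh]],
                 sprintf("%s_%d_left", tag, b), "left", comp)
      add_region(wh[bands == b & !left[wh]],
                 sprintf("%s_%d_right", tag, b), "right", comp)
    }
  }
  add_pairs(lat_sel & infra, n_pairs_inf, "infratentorial", "inf")
  sup_sel <- lat_sel & (if (n_pairs_inf > 0L) !infra else TRUE)
  add_pairs(sup_sel, n_pairs_sup, "supratentorial", "sup")

  region_atlas(labels, grid, do.call(rbind, regions))
}

#' Rasterize a sphere onto the grid
#'
#' A voxel belongs to the sphere iff the Euclidean distance from its center
#' to `center` is at most `radius` (0-based index space); radius 0 yields
#' exactly the center voxel. Spheres are clipped at the grid boundary.
#'
#' @param center length-3 coordinate, must lie within the grid.
#' @param radius sphere radius in voxels (>= 0).
#' @param grid `grid_spec`.
#' @param patient_id identifier for the returned mask.
#' @return A [lesion_mask()].
#' @export
rasterize_sphere <- function(center, radius, grid, patient_id = NA) {
  stopifnot(inherits(grid, "grid_spec"))
  if (radius < 0) stop("radius must be >= 0")
  shape <- grid$shape
  if (length(center) != 3L || any(center < -0.5) || any(center > shape - 0.5))
    stop("center outside grid")
  data <- array(0L, dim = shape)
  lo <- pmax(ceiling(center - radius), 0)
  hi <- pmin(floor(center + radius), shape - 1)
  if (all(lo <= hi)) {
    xs <- lo[1]:hi[1]; ys <- lo[2]:hi[2]; zs <- lo[3]:hi[3]
    d2 <- outer(outer((xs - center[1])^2, (ys - center[2])^2, `+`),
                (zs - center[3])^2, `+`)
    data[xs + 1, ys + 1, zs + 1] <- as.integer(d2 <= radius^2 + 1e-12)
  }
  lesion_mask(data, grid, patient_id)
}

#' Cohort generation parameters
#'
#' Bundles the generating model of the synthetic cohort. Defaults mirror a
#' large surgical brain-metastasis series: lesion-count split 49.4 / 17.0 /
#' 33.6 percent across 1 / 2 / >= 3 lesions with a shifted-geometric tail
#' (mean about 4 lesions per patient overall), 60.5 percent male, mean age
#' 59.8 years, lung-dominated primaries, Ki-67 distributions with medians
#' near 35 percent (primary) and 45 percent (metastasis), exponential
#' baseline hazard with reference median survival of 12 months, an
#' infratentorial hazard ratio of 1.473, lesion-number hazard ratios of
#' 1.142 (two lesions) and 2.132 (three or more), and independent uniform
#' censoring over a 60-month follow-up horizon.
#'
#' @param n_patients cohort size (>= 0).
#' @param lesion_count_probs probabilities of 1 / 2 / >= 3 lesions; must sum
#'   to 1.
#' @param tail_geom_p geometric parameter of the >= 3 tail: counts are
#'   3 + Geometric(tail_geom_p).
#' @param region_weights per-region placement weights, named by region_id or
#'   in atlas region order; NULL = uniform per unit volume. All >= 0, at
#'   least one positive.
#' @param radius_range lesion radius range in voxels; radii drawn uniformly.
#' @param age_mean,age_sd,age_range normal age model, truncated to range.
#' @param p_male probability of male sex.
#' @param primary_probs named probabilities over primary tumor classes.
#' @param lung_subtype_probs named probabilities over lung subtypes.
#' @param ki67_primary_shape,ki67_bm_shape Beta shape pairs; Ki-67 percent is
#'   100 x Beta(shape1, shape2).
#' @param p_treatment_known probability a patient has treatment data.
#' @param treatment_probs named probabilities over treatment categories.
#' @param baseline_hazard exponential baseline hazard per month.
#' @param log_hr_infratentorial log hazard ratio of infratentorial
#'   involvement.
#' @param log_hr_n2,log_hr_n3 log hazard ratios of the 2 and >= 3 lesion
#'   groups versus a single lesion.
#' @param censor_horizon uniform censoring horizon in months.
#' @param seed integer RNG seed.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients = 200,
                        lesion_count_probs = c(0.494, 0.170, 0.336),
                        tail_geom_p = 0.137,
                        region_weights = NULL,
                        radius_range = c(2, 4),
                        age_mean = 59.8, age_sd = 12, age_range = c(16, 89),
                        p_male = 0.605,
                        primary_probs = c(lung = 0.861, breast = 0.042,
                                          colorectal = 0.025,
                                          `head-and-neck` = 0.013,
                                          kidney = 0.011, melanoma = 0.006,
                                          other = 0.042),
                        lung_subtype_probs = c(adenocarcinoma = 0.664,
                                               squamous = 0.112,
                                               `small-cell` = 0.178,
                                               other = 0.046),
                        ki67_primary_shape = c(2, 3.5),
                        ki67_bm_shape = c(2.5, 3),
                        p_treatment_known = 0.365,
                        treatment_probs = c(surgery = 0.363, WBRT = 0.483,
                                            SRS = 0.025,
                                            `surgery+WBRT` = 0.092,
                                            `surgery+SRS` = 0.037),
                        baseline_hazard = log(2) / 12,
                        log_hr_infratentorial = log(1.473),
                        log_hr_n2 = log(1.142),
                        log_hr_n3 = log(2.132),
                        censor_horizon = 60,
                        seed = 1L) {
  if (n_patients < 0) stop("n_patients must be >= 0")
  check_probs <- function(p, what) {
    if (any(p < 0) || abs(sum(p) - 1) > 1e-6)
      stop(what, " must be nonnegative and sum to 1")
  }
  check_probs(lesion_count_probs, "lesion_count_probs")
  check_probs(primary_probs, "primary_probs")
  check_probs(lung_subtype_probs, "lung_subtype_probs")
  check_probs(treatment_probs, "treatment_probs")
  if (tail_geom_p <= 0 || tail_geom_p > 1)
    stop("tail_geom_p must lie in (0, 1]")
  if (!is.null(region_weights)) {
    if (any(region_weights < 0) || all(region_weights == 0))
      stop("region weights must be >= 0 with at least one positive")
  }
  if (length(radius_range) != 2L || any(radius_range < 0) ||
      radius_range[1] > radius_range[2])
    stop("radius_range must be an increasing nonnegative pair")
  if (baseline_hazard <= 0) stop("baseline_hazard must be positive")
  if (censor_horizon <= 0) stop("censor_horizon must be positive")
  structure(list(
    n_patients = as.integer(n_patients),
    lesion_count_probs = lesion_count_probs, tail_geom_p = tail_geom_p,
    region_weights = region_weights, radius_range = radius_range,
    age_mean = age_mean, age_sd = age_sd, age_range = age_range,
    p_male = p_male, primary_probs = primary_probs,
    lung_subtype_probs = lung_subtype_probs,
    ki67_primary_shape = ki67_primary_shape, ki67_bm_shape = ki67_bm_shape,
    p_treatment_known = p_treatment_known, treatment_probs = treatment_probs,
    baseline_hazard = baseline_hazard,
    log_hr_infratentorial = log_hr_infratentorial,
    log_hr_n2 = log_hr_n2, log_hr_n3 = log_hr_n3,
    censor_horizon = censor_horizon, seed = as.integer(seed)),
    class = "cohort_spec")
}

#' Draw per-patient lesion counts
#'
#' Categorical over {1, 2} with a shifted geometric tail for the >= 3 group:
#' counts there are 3 + Geometric(tail_geom_p). This is the count model
#' [simulate_cohort()] uses.
#'
#' @param n number of patients.
#' @param probs probabilities of the 1 / 2 / >= 3 groups.
#' @param tail_geom_p geometric parameter of the tail.
#' @return integer vector of lesion counts (>= 1).
#' @export
draw_lesion_counts <- function(n, probs = c(0.494, 0.170, 0.336),
                               tail_geom_p = 0.137) {
  grp <- sample.int(3L, n, replace = TRUE, prob = probs)
  counts <- grp
  tail <- grp == 3L
  counts[tail] <- 3L + stats::rgeom(sum(tail), tail_geom_p)
  counts
}

#' Simulate a synthetic cohort of lesion masks and patient records
#'
#' Draws per-patient lesion counts, places lesion centers on labeled atlas
#' voxels with probability proportional to the voxel's region weight,
#' rasterizes spheres of random radius clipped to the placeable foreground
#' (the positively weighted regions; overlapping spheres merge), and derives the
#' measured lesion summary (labeling, centroids, region assignment) from the
#' resulting mask. Survival times are exponential with log-linear effects of
#' the measured infratentorial involvement and lesion-number group, censored
#' uniformly. Reproducible under the spec's seed.
#'
#' @param spec [cohort_spec()].
#' @param atlas [region_atlas()].
#' @param connectivity connectivity used for the measured lesion summary.
#' @return list with `records` (patient covariates + survival), `summaries`
#'   (per-patient lesion summary), `lesions` (cohort lesion table), `masks`
#'   (list of [lesion_mask()]), and `placements` (the generator's drawn
#'   lesion centers, radii and seeding regions, before spheres merge).
#' @export
simulate_cohort <- function(spec, atlas, connectivity = 26) {
  stopifnot(inherits(spec, "cohort_spec"), inherits(atlas, "region_atlas"))
  set.seed(spec$seed)
  n <- spec$n_patients
  empty <- list(
    records = data.frame(patient_id = character(), age = numeric(),
                         sex = character(), primary_class = character(),
                         lung_subtype = character(),
                         ki67_primary = numeric(), ki67_bm = numeric(),
                         treatments = character(), os_time = numeric(),
                         event = logical()),
    summaries = data.frame(), lesions = data.frame(), masks = list(),
    placements = data.frame())
  if (n == 0L) return(empty)

  fg_idx <- which(atlas$labels > 0L)
  fg_coords <- arrayInd(fg_idx, atlas$grid$shape) - 1L
  w <- region_weight_per_voxel(spec$region_weights, atlas, fg_idx)
  # lesions live in the placeable foreground: regions with positive weight
  placeable <- array(FALSE, dim = atlas$grid$shape)
  placeable[fg_idx[w > 0]] <- TRUE
  ids <- sprintf("P%04d", seq_len(n))

  counts <- draw_lesion_counts(n, spec$lesion_count_probs, spec$tail_geom_p)
  masks <- vector("list", n)
  lesions <- vector("list", n)
  placements <- vector("list", n)
  for (i in seq_len(n)) {
    pick <- sample(length(fg_idx), counts[i], replace = TRUE, prob = w)
    radii <- stats::runif(counts[i], spec$radius_range[1],
                          spec$radius_range[2])
    placements[[i]] <- data.frame(
      patient_id = ids[i],
      center_x = fg_coords[pick, 1], center_y = fg_coords[pick, 2],
      center_z = fg_coords[pick, 3], radius = radii,
      region_id = atlas$labels[fg_idx[pick]], stringsAsFactors = FALSE)
    data <- array(0L, dim = atlas$grid$shape)
    for (j in seq_len(counts[i])) {
      sph <- rasterize_sphere(fg_coords[pick[j], ], radii[j], atlas$grid)
      data <- data | sph$data
    }
    data <- array(as.integer(data & placeable), dim = atlas$grid$shape)
    masks[[i]] <- lesion_mask(data, atlas$grid, ids[i])
    lesions[[i]] <- lesion_table(label_components(masks[[i]], connectivity),
                                 atlas)
  }
  lesion_df <- do.call(rbind, lesions)
  summaries <- summarize_cohort(lesion_df)
  summaries <- summaries[match(ids, summaries$patient_id), ]
  rownames(summaries) <- NULL

  records <- draw_covariates(spec, ids)
  lp <- spec$log_hr_infratentorial * summaries$infratentorial_involvement +
    spec$log_hr_n2 * (summaries$number_group == "2") +
    spec$log_hr_n3 * (summaries$number_group == "3+")
  t_event <- stats::rexp(n, rate = spec$baseline_hazard * exp(lp))
  t_cens <- stats::runif(n, 0, spec$censor_horizon)
  records$os_time <- pmin(t_event, t_cens)
  records$event <- t_event <= t_cens

  list(records = records, summaries = summaries, lesions = lesion_df,
       masks = masks, placements = do.call(rbind, placements))
}

# per-foreground-voxel sampling weight from per-region weights
region_weight_per_voxel <- function(region_weights, atlas, fg_idx) {
  rid <- atlas$regions$region_id
  if (is.null(region_weights)) {
    wr <- stats::setNames(rep(1, length(rid)), rid)
  } else if (!is.null(names(region_weights))) {
    if (!all(as.character(rid) %in% names(region_weights)))
      stop("region_weights must name every atlas region")
    wr <- region_weights[as.character(rid)]
  } else {
    if (length(region_weights) != length(rid))
      stop("region_weights length must equal the number of regions")
    wr <- stats::setNames(region_weights, rid)
  }
  if (all(wr == 0)) stop("zero total region weight")
  lab <- atlas$labels[fg_idx]
  as.numeric(wr[as.character(lab)])
}

draw_covariates <- function(spec, ids) {
  n <- length(ids)
  age <- pmin(pmax(stats::rnorm(n, spec$age_mean, spec$age_sd),
                   spec$age_range[1]), spec$age_range[2])
  sex <- ifelse(stats::runif(n) < spec$p_male, "male", "female")
  primary <- sample(names(spec$primary_probs), n, replace = TRUE,
                    prob = spec$primary_probs)
  lung_subtype <- rep(NA_character_, n)
  is_lung <- primary == "lung"
  if (any(is_lung))
    lung_subtype[is_lung] <- sample(names(spec$lung_subtype_probs),
                                    sum(is_lung), replace = TRUE,
                                    prob = spec$lung_subtype_probs)
  ki67_primary <- 100 * stats::rbeta(n, spec$ki67_primary_shape[1],
                                     spec$ki67_primary_shape[2])
  ki67_bm <- 100 * stats::rbeta(n, spec$ki67_bm_shape[1],
                                spec$ki67_bm_shape[2])
  treatments <- rep(NA_character_, n)
  known <- stats::runif(n) < spec$p_treatment_known
  if (any(known))
    treatments[known] <- sample(names(spec$treatment_probs), sum(known),
                                replace = TRUE, prob = spec$treatment_probs)
  data.frame(patient_id = ids, age = age, sex = sex, primary_class = primary,
             lung_subtype = lung_subtype, ki67_primary = ki67_primary,
             ki67_bm = ki67_bm, treatments = treatments,
             stringsAsFactors = FALSE)
}
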