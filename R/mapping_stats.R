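#' Tumor-frequency heatmap
#'
#' Voxel-wise count of patients with a lesion at each voxel, the overlap map
#' obtained by summing the cohort's binary masks. Each patient contributes
#' at most 1 per voxel.
#'
#' @param masks list of [lesion_mask()] objects sharing one grid.
#' @return An object of class `frequency_map`: list with `counts` (3-D
#'   integer array), `n_patients`, `grid`.
#' @export
frequency_map <- function(masks) {
  if (length(masks) == 0L) stop("empty mask list")
  grid <- masks[[1]]$grid
  counts <- array(0L, dim = grid$shape)
  for (m in masks) {
    stopifnot(inherits(m, "lesion_mask"))
    if (!same_grid(m$grid, grid))
      stop_grid_mismatch(m$grid$shape, grid$shape)
    counts <- counts + m$data
  }
  structure(list(grid = grid, counts = counts, n_patients = length(masks)),
            class = "frequency_map")
}

#' @export
print.frequency_map <- function(x, ...) {
  cat(sprintf("frequency_map: %d patients, max overlap %d\n",
              x$n_patients, max(x$counts)))
  invisible(x)
}

#' Two-sided Fisher exact test of a 2x2 contingency table
#'
#' Exact test on the table (a = lesioned patients of phenotype A, b =
#' lesioned of B, c = lesion-free of A, d = lesion-free of B). The point
#' probability of a table with fixed margins is hypergeometric,
#' \deqn{p = \frac{(a+b)!\,(c+d)!\,(a+c)!\,(b+d)!}{a!\,b!\,c!\,d!\,n!},}
#' and the two-sided p-value sums the point probabilities of all tables with
#' the observed margins that are no more probable than the observed one
#' (ties included). Degenerate margins give p = 1.
#'
#' @param a,b,c,d nonnegative integer cell counts (vectorized).
#' @return p-value(s) in (0, 1].
#' @export
fisher_exact_two_sided <- function(a, b, c, d) {
  if (any(c(a, b, c, d) < 0) || any(c(a, b, c, d) != round(c(a, b, c, d))))
    stop("cell counts must be nonnegative integers")
  mapply(function(a, b, c, d) {
    if (a + b + c + d < 1) stop("table must contain at least one subject")
    m <- a + b           # lesioned margin
    mf <- c + d          # lesion-free margin
    k <- a + c           # phenotype-A margin
    support <- max(0, k - mf):min(k, m)
    dens <- stats::dhyper(support, m, mf, k)
    obs <- stats::dhyper(a, m, mf, k)
    min(1, sum(dens[dens <= obs * (1 + 1e-7)]))
  }, a, b, c, d)
}

#' ADIFFI: voxel-wise two-sided Fisher exact-test map
#'
#' Analysis of differential involvement between two patient phenotypes. At
#' every voxel a 2x2 table is formed from patient-level lesion presence
#' (a = phenotype-A patients with a lesion at the voxel, b = phenotype-B
#' patients with one, c/d the lesion-free remainders) and tested with the
#' two-sided Fisher exact test. The direction map records which phenotype
#' has the higher lesion proportion (+1 = A, -1 = B, 0 = equal). Voxels
#' lesioned in nobody (or everybody) are degenerate and get p = 1,
#' direction 0.
#'
#' @param masks_A,masks_B lists of [lesion_mask()] on one common grid.
#' @param fdr also compute Benjamini-Hochberg adjusted p-values across
#'   non-degenerate voxels (off by default; the per-voxel threshold is the
#'   method's native convention).
#' @return An object of class `pvalue_map`: `p` (3-D array in [0,1]),
#'   `direction` (3-D integer array in {-1,0,1}), `n_A`, `n_B`, `grid`, and
#'   `p_fdr` when requested.
#' @export
adiffi_map <- function(masks_A, masks_B, fdr = FALSE) {
  if (length(masks_A) == 0L || length(masks_B) == 0L)
    stop("both phenotype groups must be nonempty")
  fa <- frequency_map(masks_A)
  fb <- frequency_map(masks_B)
  if (!same_grid(fa$grid, fb$grid))
    stop_grid_mismatch(fb$grid$shape, fa$grid$shape)
  nA <- fa$n_patients; nB <- fb$n_patients
  a <- as.integer(fa$counts); b <- as.integer(fb$counts)
  key <- a * (nB + 1L) + b
  uk <- unique(key)
  ua <- uk %/% (nB + 1L); ub <- uk %% (nB + 1L)
  up <- fisher_exact_two_sided(ua, ub, nA - ua, nB - ub)
  p <- array(up[match(key, uk)], dim = fa$grid$shape)
  propdiff <- a / nA - b / nB
  direction <- array(as.integer(sign(propdiff)), dim = fa$grid$shape)
  out <- structure(list(grid = fa$grid, p = p, direction = direction,
                        n_A = nA, n_B = nB),
                   class = "pvalue_map")
  if (fdr) {
    testable <- (a + b) > 0L & (a + b) < (nA + nB)
    p_fdr <- array(NA_real_, dim = fa$grid$shape)
    p_fdr[testable] <- stats::p.adjust(p[testable], method = "BH")
    out$p_fdr <- p_fdr
  }
  out
}

#' @export
print.pvalue_map <- function(x, ...) {
  cat(sprintf("pvalue_map (ADIFFI): nA = %d, nB = %d, min p = %.4g\n",
              x$n_A, x$n_B, min(x$p)))
  invisible(x)
}

#' Extract significant clusters from a p-value map
#'
#' Thresholds the map at `alpha`, labels connected components separately for
#' each direction (same connectivity rule as lesion labeling), drops
#' clusters below `min_size`, and annotates each cluster with its peak
#' (minimum-p) voxel, per-compartment voxel fractions against the atlas, and
#' the dominant (modal) region.
#'
#' @param pmap `pvalue_map`.
#' @param alpha significance threshold in (0,1); the method's convention is
#'   0.05 per voxel.
#' @param min_size minimum cluster size in voxels.
#' @param atlas optional `region_atlas` for compartment fractions and
#'   dominant region.
#' @param connectivity 6, 18 or 26 (default 26).
#' @param use_fdr threshold `p_fdr` instead of `p` (requires `adiffi_map(...,
#'   fdr = TRUE)`).
#' @return data.frame ordered by decreasing size: cluster_id, direction
#'   ("A"/"B"), size, peak_x/y/z (0-based), peak_p, and with an atlas:
#'   frac_infratentorial, frac_supratentorial, frac_background,
#'   dominant_region_id.
#' @export
extract_clusters <- function(pmap, alpha = 0.05, min_size = 1, atlas = NULL,
                             connectivity = 26, use_fdr = FALSE) {
  stopifnot(inherits(pmap, "pvalue_map"))
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stop("alpha must lie in (0, 1)")
  pvals <- if (use_fdr) {
    if (is.null(pmap$p_fdr)) stop("pvalue_map has no FDR-adjusted values")
    ifelse(is.na(pmap$p_fdr), 1, pmap$p_fdr)
  } else pmap$p
  rows <- list()
  for (dir in c(1L, -1L)) {
    sel <- array(as.integer(pvals < alpha & pmap$direction == dir),
                 dim = pmap$grid$shape)
    if (!any(sel == 1L)) next
    labs <- .label_components_cpp(sel, pmap$grid$shape,
                                  as.integer(connectivity))
    k <- attr(labs, "n_components")
    for (i in seq_len(k)) {
      vox <- which(labs == i)
      if (length(vox) < min_size) next
      pv <- pvals[vox]
      peak <- vox[order(pv, vox)[1]]
      peak_xyz <- arrayInd(peak, pmap$grid$shape) - 1L
      row <- data.frame(direction = if (dir == 1L) "A" else "B",
                        size = length(vox),
                        peak_x = peak_xyz[1], peak_y = peak_xyz[2],
                        peak_z = peak_xyz[3], peak_p = min(pv),
                        stringsAsFactors = FALSE)
      if (!is.null(atlas)) {
        stopifnot(inherits(atlas, "region_atlas"))
        vlab <- atlas$labels[vox]
        comp <- rep("background", length(vlab))
        nz <- vlab > 0L
        comp[nz] <- atlas$regions$compartment[
          match(vlab[nz], atlas$regions$region_id)]
        row$frac_infratentorial <- mean(comp == "infratentorial")
        row$frac_supratentorial <- mean(comp == "supratentorial")
        row$frac_background <- mean(comp == "background")
        row$dominant_region_id <- if (any(nz)) {
          tab <- table(vlab[nz])
          as.integer(names(tab)[which.max(tab)])
        } else NA_integer_
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  if (length(rows) == 0L) {
    out <- data.frame(cluster_id = integer(), direction = character(),
                      size = integer(), peak_x = integer(),
                      peak_y = integer(), peak_z = integer(),
                      peak_p = numeric())
    if (!is.null(atlas)) {
      out$frac_infratentorial <- numeric()
      out$frac_supratentorial <- numeric()
      out$frac_background <- numeric()
      out$dominant_region_id <- integer()
    }
    return(out)
  }
  out <- do.call(rbind, rows)
  out <- out[order(-out$size, out$peak_p), , drop = FALSE]
  out <- cbind(cluster_id = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  out
}

#' Relative metastatic risk per brain region
#'
#' Volume-normalized, cohort-normalized regional risk:
#' \deqn{RMR_x = \frac{N_x / N_p / V_x}{\sum_{i=1}^{N_R} (N_i / N_p / V_i) / N_R}}
#' where N_x is the number of patients with at least one centroid-assigned
#' lesion in region x, N_p the cohort size, V_x the region volume and N_R
#' the number of regions. By construction the mean RMR across regions is 1;
#' RMR > 1 marks a susceptible region.
#'
#' @param lesion_df cohort lesion table ([lesion_table()] rows).
#' @param atlas `region_atlas`.
#' @param n_patients cohort size N_p (>= 1); patients without lesions still
#'   count in the denominator.
#' @return data.frame per region: region_id, name, laterality, compartment,
#'   n_patients_region (N_x), volume_mm3 (V_x), risk_per_mm3, rmr; with
#'   attributes `n_patients` and `n_regions`.
#' @export
relative_metastatic_risk <- function(lesion_df, atlas, n_patients) {
  stopifnot(inherits(atlas, "region_atlas"))
  if (n_patients < 1L) stop("n_patients must be >= 1")
  if (nrow(lesion_df) &&
      !all(lesion_df$region_id %in% atlas$regions$region_id))
    stop("lesion table contains regions absent from the atlas")
  out <- atlas$regions[, c("region_id", "name", "laterality", "compartment",
                           "volume_mm3")]
  if (any(out$volume_mm3 <= 0)) stop("region with zero volume")
  nx <- integer(nrow(out))
  if (nrow(lesion_df)) {
    per <- tapply(lesion_df$patient_id, lesion_df$region_id,
                  function(x) length(unique(x)))
    i <- match(as.integer(names(per)), out$region_id)
    nx[i] <- as.integer(per)
  }
  if (all(nx == 0L)) stop("no lesions assigned to any region")
  out$n_patients_region <- nx
  out$risk_per_mm3 <- nx / n_patients / out$volume_mm3
  out$rmr <- out$risk_per_mm3 / mean(out$risk_per_mm3)
  attr(out, "n_patients") <- as.integer(n_patients)
  attr(out, "n_regions") <- nrow(out)
  out
}
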