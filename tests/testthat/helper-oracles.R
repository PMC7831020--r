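# Independent oracles and fixture builders used across the suite.

# Brute-force flood fill over a 3-D binary array; stack-based, pure R.
flood_fill_oracle <- function(arr, connectivity) {
  d <- dim(arr)
  offsets <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  nz <- rowSums(abs(offsets))
  offsets <- offsets[nz > 0 & nz <= switch(as.character(connectivity),
                                           "6" = 1, "18" = 2, "26" = 3), ,
                     drop = FALSE]
  labels <- array(0L, dim = d)
  k <- 0L
  for (start in which(arr > 0)) {
    if (labels[start] != 0L) next
    k <- k + 1L
    stack <- start
    labels[start] <- k
    while (length(stack)) {
      cur <- stack[length(stack)]
      stack <- stack[-length(stack)]
      cc <- arrayInd(cur, d)
      nb <- sweep(offsets, 2, as.integer(cc), `+`)
      ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
        nb[, 3] >= 1 & nb[, 3] <= d[3]
      nb <- nb[ok, , drop = FALSE]
      lin <- nb[, 1] + d[1] * (nb[, 2] - 1L + d[2] * (nb[, 3] - 1L))
      lin <- lin[arr[lin] > 0 & labels[lin] == 0L]
      labels[lin] <- k
      stack <- c(stack, lin)
    }
  }
  attr(labels, "k") <- k
  labels
}

# Two labelings agree when they induce the same partition of the foreground.
same_partition <- function(l1, l2) {
  fg <- which(l1 > 0L)
  if (!identical(fg, which(l2 > 0L))) return(FALSE)
  key <- paste(l1[fg], l2[fg])
  length(unique(key)) == length(unique(l1[fg])) &&
    length(unique(key)) == length(unique(l2[fg]))
}

# Exact two-sided Fisher p by direct factorial enumeration of all tables
# with the observed margins (valid for small n).
fisher_enum_oracle <- function(a, b, c, d) {
  m <- a + b; mf <- c + d; k <- a + c; l <- b + d; n <- m + mf
  point <- function(x) {
    factorial(m) * factorial(mf) * factorial(k) * factorial(l) /
      (factorial(x) * factorial(m - x) * factorial(k - x) *
         factorial(mf - k + x) * factorial(n))
  }
  support <- max(0, k - mf):min(k, m)
  probs <- vapply(support, point, numeric(1))
  obs <- point(a)
  min(1, sum(probs[probs <= obs + 1e-12]))
}

# Random binary mask on a toy grid.
random_mask <- function(shape = c(8, 8, 8), p = 0.3, grid = NULL) {
  if (is.null(grid)) grid <- grid_spec(shape, voxel_volume = 1)
  lesion_mask(array(stats::rbinom(prod(grid$shape), 1, p),
                    dim = grid$shape), grid)
}

# Two-region atlas with chosen voxel counts (used for RMR hand examples).
two_region_atlas <- function(n1 = 10, n2 = 40, voxel_volume = 0.1) {
  shape <- c(10, 10, 2)
  labels <- array(0L, dim = shape)
  labels[seq_len(n1)] <- 1L
  labels[n1 + seq_len(n2)] <- 2L
  region_atlas(labels, grid_spec(shape, voxel_volume = voxel_volume),
               data.frame(region_id = 1:2, name = c("r1", "r2"),
                          laterality = c("left", "right"),
                          compartment = "supratentorial"))
}

# Minimal lesion-table rows for constructed examples.
make_lesions <- function(patient_id, region_id, compartment = "supratentorial",
                         volume = 1, laterality = "left") {
  n <- length(patient_id)
  data.frame(patient_id = patient_id, lesion_id = seq_len(n),
             voxel_count = rep(1L, n), volume_mm3 = rep(volume, length.out = n),
             cx = 0, cy = 0, cz = 0,
             region_id = rep(region_id, length.out = n),
             laterality = rep(laterality, length.out = n),
             compartment = rep(compartment, length.out = n),
             stringsAsFactors = FALSE)
}
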