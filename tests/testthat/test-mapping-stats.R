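test_that("frequency maps sum patient-level presence per voxel", {
  g <- grid_spec(c(6, 6, 6), voxel_volume = 1)
  a <- array(0L, g$shape); a[1:5] <- 1L
  b <- array(0L, g$shape); b[4:8] <- 1L
  ma <- lesion_mask(a, g, "a"); mb <- lesion_mask(b, g, "b")

  fm1 <- frequency_map(list(ma))
  expect_identical(fm1$counts, ma$data)

  fm2 <- frequency_map(list(ma, mb))
  expect_equal(max(fm2$counts), 2)
  expect_equal(sum(fm2$counts), 10)

  fmN <- frequency_map(rep(list(ma), 7))
  expect_equal(unique(fmN$counts[a == 1L]), 7L)
  expect_equal(sum(fmN$counts[a == 0L]), 0)
  expect_true(all(fmN$counts <= fmN$n_patients))

  expect_error(frequency_map(list()), "empty")
  expect_error(frequency_map(list(ma, lesion_mask(array(0, c(5, 5, 5)),
                                                  grid_spec(c(5, 5, 5), 1)))),
               "grid mismatch")
})

test_that("two-sided Fisher exact test matches its worked examples", {
  expect_equal(fisher_exact_two_sided(0, 0, 5, 5), 1)
  expect_equal(fisher_exact_two_sided(3, 0, 0, 3), 0.1)
  expect_equal(fisher_exact_two_sided(1, 1, 1, 1), 1)
  expect_error(fisher_exact_two_sided(-1, 0, 2, 2), "nonnegative")
})

test_that("Fisher p-values agree with enumeration and fisher.test", {
  # exhaustive sweep over all small tables
  for (n in 1:6) {
    combos <- expand.grid(a = 0:n, b = 0:n, c = 0:n, d = 0:n)
    combos <- combos[rowSums(combos) == n, ]
    p_pkg <- with(combos, fisher_exact_two_sided(a, b, c, d))
    p_ora <- mapply(fisher_enum_oracle, combos$a, combos$b, combos$c,
                    combos$d)
    expect_lt(max(abs(p_pkg - p_ora)), 1e-12)
  }
  # independent cross-check against stats::fisher.test at larger counts
  set.seed(99)
  for (i in 1:50) {
    cells <- rpois(4, 8)
    if (sum(cells) == 0) cells[1] <- 1
    p_pkg <- fisher_exact_two_sided(cells[1], cells[2], cells[3], cells[4])
    p_ref <- stats::fisher.test(matrix(cells, 2, byrow = TRUE))$p.value
    expect_equal(p_pkg, p_ref, tolerance = 1e-9)
  }
})

test_that("ADIFFI maps handle identical, separated and empty voxels", {
  g <- grid_spec(c(6, 6, 6), voxel_volume = 1)
  a <- array(0L, g$shape); a[10:20] <- 1L
  masks <- lapply(1:3, function(i) lesion_mask(a, g, paste0("p", i)))

  ident <- adiffi_map(masks, masks)
  expect_true(all(ident$p == 1))
  expect_true(all(ident$direction == 0L))

  # a voxel lesioned in all of A (nA = 3) and none of B (nB = 3)
  empty <- lapply(1:3, function(i)
    lesion_mask(array(0L, g$shape), g, paste0("q", i)))
  sep <- adiffi_map(masks, empty)
  expect_equal(unique(sep$p[a == 1L]), 0.1)
  expect_true(all(sep$direction[a == 1L] == 1L))
  # voxels lesioned in nobody are degenerate
  expect_true(all(sep$p[a == 0L] == 1))
  expect_true(all(sep$direction[a == 0L] == 0L))

  expect_error(adiffi_map(masks, list()), "nonempty")
})

test_that("swapping ADIFFI groups preserves p and flips direction", {
  set.seed(21)
  g <- grid_spec(c(8, 8, 8), voxel_volume = 1)
  A <- lapply(1:6, function(i) random_mask(grid = g, p = 0.3))
  B <- lapply(1:8, function(i) random_mask(grid = g, p = 0.15))
  ab <- adiffi_map(A, B)
  ba <- adiffi_map(B, A)
  expect_equal(ab$p, ba$p)
  expect_identical(ab$direction, -ba$direction)
  expect_true(all(ab$p >= 0 & ab$p <= 1))
  # FDR-adjusted values are defined exactly on non-degenerate voxels
  fdr <- adiffi_map(A, B, fdr = TRUE)
  counts <- frequency_map(A)$counts + frequency_map(B)$counts
  expect_true(all(is.na(fdr$p_fdr[counts == 0])))
  expect_true(all(!is.na(fdr$p_fdr[counts > 0 & counts < 14])))
  expect_true(all(fdr$p_fdr >= fdr$p, na.rm = TRUE))
})

test_that("cluster extraction thresholds, labels and annotates", {
  g <- grid_spec(c(8, 8, 8), voxel_volume = 1)
  pm <- structure(list(grid = g, p = array(1, g$shape),
                       direction = array(0L, g$shape), n_A = 5, n_B = 5),
                  class = "pvalue_map")
  expect_equal(nrow(extract_clusters(pm, 0.05)), 0)

  pm$p[2, 2, 2] <- 0.01; pm$direction[2, 2, 2] <- 1L
  one <- extract_clusters(pm, 0.05, min_size = 1)
  expect_equal(nrow(one), 1)
  expect_equal(one$size, 1)
  expect_equal(c(one$peak_x, one$peak_y, one$peak_z), c(1, 1, 1))

  # two face-adjacent significant voxels of one direction form one cluster
  pm$p[3, 2, 2] <- 0.02; pm$direction[3, 2, 2] <- 1L
  two <- extract_clusters(pm, 0.05, min_size = 1)
  expect_equal(nrow(two), 1)
  expect_equal(two$size, 2)
  expect_equal(two$peak_p, 0.01)
  # opposite-direction voxels never join a cluster
  pm$p[4, 2, 2] <- 0.02; pm$direction[4, 2, 2] <- -1L
  split2 <- extract_clusters(pm, 0.05, min_size = 1)
  expect_equal(sort(split2$size), c(1, 2))
  expect_setequal(split2$direction, c("A", "B"))
  # min_size filter
  expect_equal(nrow(extract_clusters(pm, 0.05, min_size = 2)), 1)
  expect_error(extract_clusters(pm, 1.5), "alpha")
})

test_that("tightening alpha yields voxel-subsets of looser clusters", {
  set.seed(31)
  g <- grid_spec(c(10, 10, 10), voxel_volume = 1)
  A <- lapply(1:12, function(i) random_mask(grid = g, p = 0.35))
  B <- lapply(1:12, function(i) random_mask(grid = g, p = 0.10))
  pm <- adiffi_map(A, B)
  vox_at <- function(alpha) {
    cl <- pm$p < alpha & pm$direction != 0L
    which(cl)
  }
  expect_true(all(vox_at(0.01) %in% vox_at(0.05)))
  expect_true(all(vox_at(0.005) %in% vox_at(0.01)))
})

test_that("relative metastatic risk reproduces Eq.-style hand examples", {
  # two regions, N = (10, 10), V = (1, 4), N_p = 100 -> RMR (1.6, 0.4)
  at <- two_region_atlas(10, 40, voxel_volume = 0.1)
  lesions <- rbind(
    make_lesions(sprintf("p%02d", 1:10), 1),
    make_lesions(sprintf("p%02d", 11:20), 2))
  rmr <- relative_metastatic_risk(lesions, at, 100)
  expect_equal(rmr$rmr, c(1.6, 0.4))
  expect_equal(rmr$n_patients_region, c(10L, 10L))
  expect_equal(mean(rmr$rmr), 1)

  # identical per-volume risk in every region -> RMR = 1 everywhere
  at_eq <- two_region_atlas(20, 20, voxel_volume = 1)
  les_eq <- rbind(make_lesions(c("a", "b"), 1), make_lesions(c("c", "d"), 2))
  expect_equal(relative_metastatic_risk(les_eq, at_eq, 50)$rmr, c(1, 1))

  # an untouched region has RMR 0 and duplicated patients count once
  les_dup <- rbind(make_lesions(c("a", "a", "b"), 1))
  r0 <- relative_metastatic_risk(les_dup, at_eq, 50)
  expect_equal(r0$n_patients_region, c(2L, 0L))
  expect_equal(r0$rmr[2], 0)
  expect_equal(mean(r0$rmr), 1)

  expect_error(relative_metastatic_risk(les_eq[0, ], at_eq, 50),
               "no lesions")
})

test_that("mean RMR equals one for random synthetic cohorts", {
  at <- build_toy_atlas(c(14, 14, 14), 3, 1, 0.25, voxel_volume = 1)
  for (s in 1:10) {
    co <- simulate_cohort(cohort_spec(n_patients = 15, seed = 500 + s,
                                      radius_range = c(1, 2)), at)
    rmr <- relative_metastatic_risk(co$lesions, at, 15)
    expect_lt(abs(mean(rmr$rmr) - 1), 1e-9)
    expect_true(all(rmr$rmr >= 0))
  }
})
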