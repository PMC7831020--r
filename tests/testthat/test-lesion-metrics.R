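test_that("component labeling matches the connectivity definitions", {
  g <- grid_spec(c(6, 6, 6), voxel_volume = 1)
  one <- array(0L, g$shape); one[3, 3, 3] <- 1L
  expect_equal(label_components(lesion_mask(one, g))$n_components, 1)

  face <- array(0L, g$shape); face[3, 3, 3] <- 1L; face[4, 3, 3] <- 1L
  for (cn in c(6, 18, 26))
    expect_equal(label_components(lesion_mask(face, g), cn)$n_components, 1)

  # voxels sharing only an edge: one lesion at 18/26, two at 6
  edge <- array(0L, g$shape); edge[3, 3, 3] <- 1L; edge[4, 4, 3] <- 1L
  expect_equal(label_components(lesion_mask(edge, g), 6)$n_components, 2)
  expect_equal(label_components(lesion_mask(edge, g), 18)$n_components, 1)
  expect_equal(label_components(lesion_mask(edge, g), 26)$n_components, 1)

  # voxels touching only at a cube corner: one lesion only at 26
  corner <- array(0L, g$shape); corner[3, 3, 3] <- 1L; corner[4, 4, 4] <- 1L
  expect_equal(label_components(lesion_mask(corner, g), 6)$n_components, 2)
  expect_equal(label_components(lesion_mask(corner, g), 18)$n_components, 2)
  expect_equal(label_components(lesion_mask(corner, g), 26)$n_components, 1)

  expect_error(label_components(lesion_mask(one, g), 12), "connectivity")
})

test_that("labeling agrees with a flood-fill oracle on random masks", {
  set.seed(11)
  for (i in 1:40) {
    m <- random_mask(c(8, 8, 8), p = runif(1, 0.1, 0.6))
    for (cn in c(6, 18, 26)) {
      lab <- label_components(m, cn)
      oracle <- flood_fill_oracle(m$data, cn)
      expect_equal(lab$n_components, attr(oracle, "k"))
      expect_true(same_partition(lab$labels, oracle))
      # partition invariant: component sizes sum to the foreground size
      expect_equal(sum(tabulate(lab$labels[lab$labels > 0])), sum(m$data))
    }
  }
})

test_that("centroids are unweighted means of member voxel coordinates", {
  g <- grid_spec(c(8, 8, 8), voxel_volume = 1)
  a <- array(0L, g$shape)
  a[4, 5, 6] <- 1L                        # 0-based (3, 4, 5)
  lab <- label_components(lesion_mask(a, g))
  expect_equal(lesion_centroid(lab, 1), c(3, 4, 5))

  b <- array(0L, g$shape); b[1, 1, 1] <- 1L; b[3, 1, 1] <- 1L; b[2, 1, 1] <- 1L
  labb <- label_components(lesion_mask(b, g))
  expect_equal(lesion_centroid(labb, 1), c(1, 0, 0))

  cc <- array(0L, g$shape); cc[1, 1, 1] <- 1L; cc[2, 1, 1] <- 1L; cc[2, 2, 1] <- 1L
  labc <- label_components(lesion_mask(cc, g))
  expect_equal(lesion_centroid(labc, 1), c(2 / 3, 1 / 3, 0))

  expect_error(lesion_centroid(labc, 2), "unknown lesion_id")
})

test_that("centroids map to regions with the documented tie-breaks", {
  shape <- c(9, 3, 3)
  labels <- array(0L, shape)
  labels[2, 2, 2] <- 3L                   # 0-based x = 1
  at3 <- region_atlas(labels, grid_spec(shape, voxel_volume = 1),
                      data.frame(region_id = 3, name = "r3",
                                 laterality = "left",
                                 compartment = "supratentorial"))
  hit <- assign_region(c(1, 1, 1), at3)
  expect_equal(hit$region_id, 3)

  # background centroid equidistant from regions 2 and 5: lowest id wins
  labels2 <- array(0L, shape)
  labels2[2, 2, 2] <- 5L; labels2[6, 2, 2] <- 2L   # x = 1 and x = 5
  at25 <- region_atlas(labels2, grid_spec(shape, voxel_volume = 1),
                       data.frame(region_id = c(2, 5), name = c("r2", "r5"),
                                  laterality = "left",
                                  compartment = "supratentorial"))
  mid <- assign_region(c(3, 1, 1), at25)   # background; both at distance 2
  expect_equal(mid$region_id, 2)

  # nearest labeled voxel wins outright when distances differ
  labels3 <- array(0L, shape)
  labels3[3, 2, 2] <- 7L; labels3[6, 2, 2] <- 1L   # x = 2 and x = 5
  at17 <- region_atlas(labels3, grid_spec(shape, voxel_volume = 1),
                       data.frame(region_id = c(1, 7), name = c("r1", "r7"),
                                  laterality = "left",
                                  compartment = "supratentorial"))
  near <- assign_region(c(3, 1, 1), at17)  # 1 step from region 7, 2 from 1
  expect_equal(near$region_id, 7)

  expect_error(assign_region(c(50, 1, 1), at17), "outside")
})

test_that("patient summaries aggregate number, TV, VSL and compartments", {
  one <- make_lesions("p1", 1, volume = 0.8)
  s1 <- summarize_patient(one)
  expect_equal(s1$n_lesions, 1)
  expect_equal(s1$tv_mm3, 0.8)
  expect_equal(s1$vsl_mm3, 0.8)
  expect_equal(as.character(s1$number_group), "1")

  three <- make_lesions(rep("p2", 3), 1, volume = c(1, 2, 3))
  s3 <- summarize_patient(three)
  expect_equal(s3$n_lesions, 3)
  expect_equal(s3$tv_mm3, 6)
  expect_equal(s3$vsl_mm3, 2)
  expect_equal(as.character(s3$number_group), "3+")

  sup2 <- make_lesions(rep("p3", 2), 1, compartment = "supratentorial")
  expect_false(summarize_patient(sup2)$infratentorial_involvement)
  mix <- make_lesions(rep("p4", 2), 1,
                      compartment = c("supratentorial", "infratentorial"))
  expect_true(summarize_patient(mix)$infratentorial_involvement)

  expect_error(summarize_patient(one[0, ]), "no lesion records")
  expect_error(summarize_patient(rbind(one, three)), "one patient")
})

test_that("volumes scale linearly with the voxel volume", {
  set.seed(5)
  arr <- array(rbinom(6^3, 1, 0.4), dim = c(6, 6, 6))
  for (cvv in c(1, 2.5)) {
    at <- build_toy_atlas(c(6, 6, 6), 1, 0, 0, voxel_volume = cvv)
    g <- grid_spec(c(6, 6, 6), voxel_volume = cvv)
    lab <- label_components(lesion_mask(arr * (at$labels > 0), g, "p"))
    tab <- lesion_table(lab, at)
    expect_equal(tab$volume_mm3, tab$voxel_count * cvv)
    s <- summarize_patient(tab)
    expect_equal(s$tv_mm3, sum(tab$voxel_count) * cvv)
  }
})

test_that("group comparisons use exact ranks and Dunn post-hocs", {
  # rank-identical groups cannot differ
  same <- compare_groups(list(a = 1:3, b = 1:3))
  expect_equal(same$p.value, 1)
  # complete separation at n = 3 vs 3: smallest achievable exact p
  apart <- compare_groups(list(a = c(1, 2, 3), b = c(100, 101, 102)))
  expect_equal(apart$p.value, 0.1)

  set.seed(8)
  shifted <- list(a = rnorm(60), b = rnorm(60), c = rnorm(60, mean = 2))
  kw <- compare_groups(shifted)
  expect_equal(kw$method, "kruskal-wallis")
  expect_lt(kw$p.value, 0.05)
  ph <- kw$posthoc
  expect_equal(nrow(ph), 3)
  expect_gt(ph$p_adjusted[ph$group1 == "a" & ph$group2 == "b"], 0.05)
  expect_lt(ph$p_adjusted[ph$group1 == "a" & ph$group2 == "c"], 0.05)
  expect_true(all(ph$p_adjusted >= ph$p_unadjusted - 1e-12))

  expect_error(compare_groups(list(a = 1:3)), "two groups")
  expect_error(compare_groups(list(a = 1:3, b = numeric())), "at least one")
})
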