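test_that("generated atlases label every parcel non-empty and deterministically", {
  cc <- shrinking_config(seed = 7)
  atlas <- generate_atlas(cc)
  labs <- as.vector(atlas$labels)
  expect_true(all(labs %in% 0:cc$n_parcels))
  expect_setequal(unique(labs[labs > 0]), seq_len(cc$n_parcels))
  expect_length(atlas$network_of, cc$n_parcels)
  expect_equal(length(unique(atlas$network_of)), cc$n_networks)
  atlas2 <- generate_atlas(cc)
  expect_identical(atlas$labels, atlas2$labels)
  expect_identical(atlas$network_of, atlas2$network_of)
})

test_that("a full-resolution atlas hosts 1035 parcels over 21 networks", {
  cc <- cohort_config(grid_shape = c(48, 48, 48), n_parcels = 1035,
                      n_networks = 21, n_streamlines = 10,
                      lesion_specs = list(list(center = c(24, 24, 24), radius = 4),
                                          list(center = c(24, 24, 24), radius = 2)),
                      seed = 11)
  atlas <- generate_atlas(cc)
  counts <- tabulate(atlas$labels, nbins = 1035)
  expect_true(all(counts >= 1L))
  expect_equal(length(unique(atlas$network_of)), 21L)
})

test_that("infeasible parcel counts are rejected as configuration errors", {
  cc <- cohort_config(grid_shape = c(2, 2, 2), n_parcels = 2, n_networks = 1,
                      n_streamlines = 5,
                      lesion_specs = list(list(center = c(1, 1, 1), radius = 1),
                                          list(center = c(1, 1, 1), radius = 0)),
                      seed = 1)
  cc$n_parcels <- 9L  # more parcels than the 8 voxels
  expect_error(generate_atlas(cc), class = "disconnectome_config_error")
})

test_that("streamline endpoints land in their declared parcels and counts are conserved", {
  cc <- shrinking_config(seed = 3)
  atlas <- generate_atlas(cc)
  sl <- generate_streamlines(atlas, cc)
  dims <- dim(atlas$labels)
  for (s in sl$streamlines$streamlines) {
    first <- floor(s$points[1, ]) + 1
    last <- floor(s$points[nrow(s$points), ]) + 1
    got <- sort(c(atlas$labels[first[1], first[2], first[3]],
                  atlas$labels[last[1], last[2], last[3]]))
    expect_identical(got, s$endpoints)
    gaps <- sqrt(rowSums(diff(s$points)^2))
    expect_true(all(gaps <= 1))
  }
  expect_identical(dim(sl$healthy), c(12L, 12L))
  expect_equal(sum(sl$healthy[upper.tri(sl$healthy)]), cc$n_streamlines)
  expect_equal(sl$healthy, t(sl$healthy))
  expect_true(all(diag(sl$healthy) == 0))
  expect_gte(min(sl$healthy[sl$healthy > 0]), 1)
})

test_that("lesion trajectories produce nesting, emptiness and regrowth on demand", {
  base <- shrinking_config(seed = 5)
  les <- generate_lesions(base)
  g <- lapply(les$masks, `[[`, "grid")
  expect_true(all(g[[2]][g[[3]] == 1L] == 1L))  # S3 inside S2
  expect_true(all(g[[1]][g[[2]] == 1L] == 1L))  # S2 inside S1
  vols <- les$ground_truth$lesion_volume_true
  expect_true(all(diff(vols) < 0))
  expect_equal(unname(vols[1]), sum(g[[1]]) * base$voxel_size^3)

  zero <- base
  zero$lesion_specs[[3]]$radius <- 0
  expect_equal(sum(generate_lesions(zero)$masks[[3]]$grid), 0)

  regrow <- cohort_config(grid_shape = base$grid_shape,
                          n_parcels = base$n_parcels,
                          n_networks = base$n_networks,
                          n_streamlines = base$n_streamlines,
                          lesion_specs = list(
                            list(center = c(8, 8, 8), radius = 3),
                            list(center = c(8, 8, 8), radius = 2),
                            list(center = c(8, 8, 8), radius = 3)),
                          seed = base$seed)
  v <- generate_lesions(regrow)$ground_truth$lesion_volume_true
  expect_lt(v[2], v[1])
  expect_gt(v[3], v[2])

  outside <- base
  outside$lesion_specs[[1]]$center <- c(100, 100, 100)
  expect_error(generate_lesions(outside),
               class = "disconnectome_config_error")
})

test_that("identical config and seed regenerate a bit-identical cohort", {
  a <- generate_cohort(shrinking_config(seed = 99, jitter = 0.5))
  b <- generate_cohort(shrinking_config(seed = 99, jitter = 0.5))
  expect_identical(a$atlas$labels, b$atlas$labels)
  expect_identical(a$healthy, b$healthy)
  expect_identical(lapply(a$masks, `[[`, "grid"),
                   lapply(b$masks, `[[`, "grid"))
  expect_identical(a$ground_truth, b$ground_truth)
  c_ <- generate_cohort(shrinking_config(seed = 100, jitter = 0.5))
  expect_false(identical(a$healthy, c_$healthy))
})

test_that("nested masks give elementwise non-increasing ground-truth disconnection", {
  co <- generate_cohort(shrinking_config(seed = 21))
  d <- co$ground_truth$disconnection_fraction_true
  expect_true(all(d[[2]] <= d[[1]] + 1e-12))
  expect_true(all(d[[3]] <= d[[2]] + 1e-12))
  for (m in d) {
    expect_equal(m, t(m))
    expect_true(all(diag(m) == 0))
    expect_true(all(m >= 0 & m <= 1))
  }
})
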