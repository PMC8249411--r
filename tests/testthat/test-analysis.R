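test_that("linear value binning conserves area and handles edge cases", {
  # constant field: one occupied bin, fraction 1
  bm <- bin_curvature(rep(2.5, 7), rep(0.1, 7), n_bins = 10)
  expect_identical(nrow(bm), 1L)
  expect_equal(bm$area_fraction, 1)
  # uniform integers with equal areas: each of 10 bins holds 0.1
  bm2 <- bin_curvature(0:9, rep(1, 10), n_bins = 10)
  expect_equal(bm2$area_fraction, rep(0.1, 10))
  expect_true(all(diff(attr(bm2, "breaks")) > 0))
  # real curvature map: fractions sum to 1 exactly
  fld <- per_triangle_curvature(rbc_mesh(12000), rbc_surface())
  bm3 <- bin_curvature(fld$KG_um_2, fld$area_um2)
  expect_equal(sum(bm3$area_fraction), 1, tolerance = 1e-12)
  expect_equal(sum(bm3$area_um2), sum(fld$area_um2))
  expect_identical(length(attr(bm3, "bin_index")), nrow(fld))
  expect_error(bin_curvature(numeric(0), numeric(0)), "empty")
})

test_that("curvature profile of the relaxed cell matches direct binning", {
  prof <- curvature_profile(rbc_geometry(), theta = 0, xi = 1, target_edges = 12000)
  expect_setequal(unique(prof$curvature), c("KG", "KM", "k1", "k2"))
  fld <- per_triangle_curvature(rbc_mesh(12000), rbc_surface())
  direct <- bin_curvature(fld$KG_um_2, fld$area_um2)
  got <- prof[prof$curvature == "KG", ]
  expect_equal(got$area_fraction, direct$area_fraction, tolerance = 1e-12)
  expect_equal(got$mean_value, direct$mean_value, tolerance = 1e-12)
})

test_that("profiles are rotation-invariant but shift under strain", {
  p0 <- curvature_profile(rbc_geometry(), 0, 1, target_edges = 12000)
  p90 <- curvature_profile(rbc_geometry(), 90, 1, target_edges = 12000)
  # intrinsic: rotation alone moves nothing beyond re-mesh noise
  expect_lt(max(abs(p90$area_fraction - p0$area_fraction)), 0.02)
  # area-weighted mean of each curvature type is theta-independent
  for (cv in unique(p0$curvature)) {
    s0 <- p0[p0$curvature == cv, ]
    s90 <- p90[p90$curvature == cv, ]
    w0 <- sum(s0$mean_value * s0$area_fraction, na.rm = TRUE)
    w90 <- sum(s90$mean_value * s90$area_fraction, na.rm = TRUE)
    expect_lt(abs(w90 - w0) / max(abs(w0), 0.1), 0.02)
  }
  # strain changes the area-weighted distribution
  p_str <- curvature_profile(rbc_geometry(), 45, 1.75, target_edges = 12000)
  p_rot <- curvature_profile(rbc_geometry(), 45, 1, target_edges = 12000)
  shift <- max(abs(p_str$area_fraction - p_rot$area_fraction))
  expect_gt(shift, 0.05)
})

test_that("strain sweep reproduces the orientation-dependent area response", {
  sw <- sweep_12k()
  expect_identical(nrow(sw), 12L)
  expect_true(all(is.na(sw$error)))
  relaxed <- sw$area_um2[sw$xi == 1]
  # xi = 1 rows agree across theta (re-mesh tolerance)
  expect_lt(diff(range(relaxed)) / mean(relaxed), 0.005)
  # monotone trends along xi
  a90 <- sw$area_um2[sw$theta_deg == 90][order(sw$xi[sw$theta_deg == 90])]
  expect_true(all(diff(a90) > 0))
  a0 <- sw$area_um2[sw$theta_deg == 0][order(sw$xi[sw$theta_deg == 0])]
  expect_true(all(diff(a0) < 0))
  # volume is conserved across the whole grid
  expect_lt(max(abs(sw$volume_um3 - 86) / 86), 0.01)
})

test_that("edge-length histograms conserve counts and scale linearly", {
  m <- rbc_mesh(12000)
  h <- edge_length_histogram(m, n_bins = 20)
  expect_identical(sum(h$histogram$count), nrow(mesh_edges(m)))
  expect_equal(h$modal_bin_fraction, max(h$histogram$count) / sum(h$histogram$count))
  expect_gte(h$top_k_fraction, h$modal_bin_fraction)
  h200 <- edge_length_histogram(m, n_bins = 200)
  expect_identical(nrow(h200$histogram), 200L)
  doubled <- trimesh(2 * m$vertices, m$faces)
  expect_equal(edge_length_histogram(doubled)$mean_nm, 2 * h$mean_nm)
})

test_that("triangle-area histograms partition the total area", {
  m <- rbc_mesh(12000)
  h <- triangle_area_histogram(m, n_bins = 10)
  expect_equal(sum(h$histogram$area_share), 1, tolerance = 1e-12)
  expect_identical(sum(h$histogram$count), nrow(m$faces))
  expect_equal(h$mean_area_nm2, mesh_area(m) / nrow(m$faces) * 1e6)
  # degenerate: all faces identical area -> single occupied bin
  flat <- trimesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(1, 1, 0)),
                  rbind(c(1, 2, 3), c(2, 4, 3)))
  hf <- triangle_area_histogram(flat)
  expect_identical(nrow(hf$histogram), 1L)
  expect_equal(hf$histogram$area_share, 1)
})

test_that("area-change partition classifies every triangle exactly once", {
  # identity strain: nothing changes
  p1 <- area_change_partition(rbc_geometry(), theta = 0, xi = 1, target_edges = 12000)
  expect_identical(length(p1$unchanged), nrow(p1$relaxed$faces))
  expect_identical(length(p1$expanded), 0L)
  # real strain: both classes occupied, classes partition the face set
  p2 <- area_change_partition(rbc_geometry(), theta = 0, xi = 1.75, target_edges = 12000)
  expect_gt(length(p2$expanded), 0)
  expect_gt(length(p2$diminished), 0)
  idx <- sort(c(p2$expanded, p2$diminished, p2$unchanged))
  expect_identical(idx, seq_len(nrow(p2$relaxed$faces)))
  expect_gte(p2$n_components_expanded, 1L)
  expect_gte(p2$n_components_diminished, 1L)
  # volume preserved exactly under the det-1 push-forward
  expect_lt(abs(mesh_volume(p2$pushed) - mesh_volume(p2$relaxed)) /
              mesh_volume(p2$relaxed), 1e-10)
  expect_output(print(p2), "expanded")
})

test_that("curvature difference maps vanish at identity and balance under strain", {
  d0 <- curvature_difference_map(rbc_geometry(), theta = 0, xi = 1, target_edges = 12000)
  expect_true(all(d0$dKG_um_2 == 0))
  expect_true(all(d0$dk1_um_1 == 0))
  d1 <- curvature_difference_map(rbc_geometry(), theta = 45, xi = 1.75,
                                 target_edges = 12000)
  expect_gt(sum(d1$dKG_um_2 > 0), 0)
  expect_gt(sum(d1$dKG_um_2 < 0), 0)
  # Gauss-Bonnet holds in both states, so the net total-curvature change ~ 0
  fld <- per_triangle_curvature(rbc_mesh(12000), rbc_surface())
  tot_before <- sum(fld$KG_um_2 * d1$area_before_um2)
  tot_after <- sum((fld$KG_um_2 + d1$dKG_um_2) * d1$area_after_um2)
  expect_lt(abs(tot_after - tot_before) / (4 * pi), 0.02)
})

test_that("cytoskeleton arithmetic reproduces the closed-form tessellation numbers", {
  rep1 <- cytoskeleton_report(n_edges = 121000, extended_strut_nm = 200,
                              total_area_um2 = 128, patch_area_um2 = 0.79)
  expect_identical(rep1$triangle_count, 80667L)
  expect_equal(rep1$extended_triangle_area_um2, 0.2^2 * sqrt(3) / 4)
  expect_equal(rep1$implied_total_area_um2, 1397.1, tolerance = 1e-3)
  expect_equal(rep1$area_ratio, 10.9, tolerance = 1e-2)
  expect_equal(rep1$mean_triangle_area_rounded_um2, 0.0016)
  expect_equal(rep1$implied_side_nm, 60.8, tolerance = 1e-3)
  expect_equal(round(rep1$triangles_per_patch, -2), 500)
  expect_output(print(rep1), "triangles")
})
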