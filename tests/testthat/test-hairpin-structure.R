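# Superposition, average-unit construction, RMSD filtering and interface
# mapping on Calpha hairpins.

test_that("kabsch superposition recovers rigid motions exactly", {
  h <- ideal_hairpin_coords()
  sup0 <- kabsch_superpose(h, h)
  expect_equal(sup0$rmsd, 0, tolerance = 1e-9)
  expect_equal(sup0$rotation, diag(3), tolerance = 1e-9)
  set.seed(41)
  for (i in 1:5) {
    moved <- rigid_copy(h$coords)
    sup <- kabsch_superpose(moved, h$coords)
    expect_equal(sup$rmsd, 0, tolerance = 1e-9)
    expect_equal(det(sup$rotation), 1, tolerance = 1e-9)
    expect_equal(apply_superposition(sup, moved), h$coords,
                 tolerance = 1e-8, ignore_attr = TRUE)
  }
})

test_that("kabsch rmsd agrees with the quaternion oracle", {
  set.seed(42)
  for (i in 1:10) {
    a <- matrix(rnorm(34 * 3, sd = 8), ncol = 3)
    b <- rigid_copy(a + matrix(rnorm(34 * 3, sd = 1.5), ncol = 3))
    expect_equal(kabsch_superpose(a, b)$rmsd, quaternion_rmsd(a, b),
                 tolerance = 1e-9)
    # symmetry
    expect_equal(kabsch_superpose(a, b)$rmsd, kabsch_superpose(b, a)$rmsd,
                 tolerance = 1e-9)
  }
})

test_that("kabsch rejects malformed input", {
  a <- matrix(rnorm(12), ncol = 3)
  expect_error(kabsch_superpose(a, a[1:3, ]), class = "tpr_shape_error")
  expect_error(kabsch_superpose(a[1:2, ], a[1:2, ]),
               class = "tpr_value_error")
})

test_that("hairpin validator enforces shape and warns on distorted helices", {
  expect_error(hairpin_structure(matrix(0, 10, 3)),
               class = "tpr_shape_error")
  good <- ideal_hairpin_coords()
  expect_silent(hairpin_structure(good$coords))
  squashed <- good$coords
  squashed[2, ] <- squashed[1, ]   # zero-length helical step
  expect_warning(hairpin_structure(squashed), "2.9-4.1")
})

test_that("average_unit recovers a common structure from rotated copies", {
  truth <- ideal_hairpin_coords()
  set.seed(43)
  copies <- lapply(1:6, function(i) {
    hairpin_structure(rigid_copy(truth$coords), label = sprintf("c%d", i))
  })
  avg <- average_unit(copies)
  expect_equal(superposed_rmsd(avg, truth), 0, tolerance = 1e-6)
  expect_true(all(attr(avg, "member_rmsd") < 1e-6))
})

test_that("two-member average is the superposed midpoint", {
  truth <- ideal_hairpin_coords()
  set.seed(44)
  a <- truth$coords + matrix(rnorm(102, sd = 0.4), ncol = 3)
  b <- rigid_copy(truth$coords + matrix(rnorm(102, sd = 0.4), ncol = 3))
  avg <- average_unit(list(a, b), tol = 1e-9, max_iter = 500)
  r_a <- superposed_rmsd(avg, a)
  r_b <- superposed_rmsd(avg, b)
  expect_equal(r_a, r_b, tolerance = 1e-6)
  # closed form: superpose b onto a, midpoint of the pair
  bt <- apply_superposition(kabsch_superpose(b, a), b)
  mid <- (a + bt) / 2
  expect_equal(superposed_rmsd(avg, mid), 0, tolerance = 1e-5)
})

test_that("average_unit is invariant to input order and pre-rotation", {
  truth <- ideal_hairpin_coords()
  set.seed(45)
  members <- lapply(1:8, function(i) {
    truth$coords + matrix(rnorm(102, sd = 0.5), ncol = 3)
  })
  avg1 <- average_unit(members)
  avg2 <- average_unit(rev(lapply(members, rigid_copy)))
  expect_lt(superposed_rmsd(avg1, avg2), 1e-3)
})

test_that("average_unit input checks and convergence error carry data", {
  expect_error(average_unit(list(ideal_hairpin_coords())),
               class = "tpr_value_error")
  truth <- ideal_hairpin_coords()
  set.seed(46)
  members <- lapply(1:4, function(i) {
    truth$coords + matrix(rnorm(102, sd = 0.5), ncol = 3)
  })
  err <- tryCatch(average_unit(members, tol = 0, max_iter = 2),
                  tpr_convergence_error = function(e) e)
  expect_s3_class(err, "tpr_convergence_error")
  expect_true(is.matrix(err$data))
})

test_that("rmsd_filter separates near-native from distorted hairpins", {
  truth <- ideal_hairpin_coords()
  set.seed(47)
  near <- lapply(1:10, function(i) {
    suppressWarnings(hairpin_structure(
      truth$coords + matrix(rnorm(102, sd = 0.5), ncol = 3),
      label = sprintf("near%02d", i)))
  })
  avg <- average_unit(near)
  part <- rmsd_filter(c(list(avg), near), avg, cutoff = 2.0)
  expect_identical(length(part$fail), 0L)
  expect_equal(part$report$rmsd[1], 0, tolerance = 1e-9)
  far <- lapply(1:10, function(i) {
    suppressWarnings(hairpin_structure(
      truth$coords + matrix(rnorm(102, sd = 3), ncol = 3),
      label = sprintf("far%02d", i)))
  })
  part2 <- rmsd_filter(far, avg, cutoff = 2.0)
  expect_identical(length(part2$pass), 0L)
  expect_error(rmsd_filter(near, avg, cutoff = 0),
               class = "tpr_value_error")
})

test_that("interface positions transfer across hairpin variants", {
  tpr_unit <- ideal_hairpin_coords(helixB_len = 14L)
  # query identical to reference: identity mapping
  expect_identical(map_interface_positions(tpr_unit, tpr_unit),
                   c(3L, 7L, 10L, 21L, 28L))
  # RPS20-like hairpin (longer helix B) keeps the canonical positions
  rps20_hh <- ideal_hairpin_coords(helixB_len = 18L)
  expect_identical(map_interface_positions(rps20_hh, tpr_unit),
                   c(3L, 7L, 10L, 21L, 28L))
  # mapping is invariant to rigid motion of the query
  set.seed(48)
  moved <- hairpin_structure(rigid_copy(tpr_unit$coords))
  expect_identical(map_interface_positions(moved, tpr_unit),
                   c(3L, 7L, 10L, 21L, 28L))
  # and robust to moderate coordinate noise
  noisy <- ideal_hairpin_coords(noise_sd = 0.3, seed = 9)
  expect_identical(map_interface_positions(noisy, tpr_unit),
                   c(3L, 7L, 10L, 21L, 28L))
  # a grossly displaced position triggers the mapping-quality warning
  broken <- tpr_unit$coords
  broken[3, ] <- broken[3, ] + c(50, 0, 0)
  expect_warning(
    map_interface_positions(tpr_unit,
                            suppressWarnings(hairpin_structure(broken))),
    "low-confidence")
})
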