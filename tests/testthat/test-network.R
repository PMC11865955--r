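test_that("allometric scaling follows the power law and its defaults", {
  # equal weights: no change
  expect_equal(allometric_scale(10, 60, 60), 10)
  # direct evaluation: 10 * 2^0.35
  expect_equal(allometric_scale(10, 70, 35), 10 * 2^0.35, tolerance = 1e-12)
  expect_equal(allometric_scale(10, 70, 35), 12.746, tolerance = 1e-4)
  # the default exponent is 0.35
  expect_identical(formals(allometric_scale)$exponent, 0.35)
  # monotone decreasing in patient weight
  w2 <- seq(30, 90, by = 5)
  vals <- allometric_scale(10, 60, w2)
  expect_true(all(diff(vals) < 0))
  # errors name the offending field
  expect_error(allometric_scale(-1, 60, 60), "L1")
  expect_error(allometric_scale(10, 0, 60), "W1")
  expect_error(allometric_scale(10, 60, -3), "W2")
})

test_that("build_network validates tree structure", {
  v1 <- data.frame(id = 1, length_cm = 5, r_in_cm = 0.5, r_out_cm = 0.4)
  net <- build_network(v1)
  expect_s3_class(net, "pt_network")
  expect_true(net$vessels$terminal[1])
  expect_equal(net$root_id, 1)

  v2 <- data.frame(id = 1:2, length_cm = 5, r_in_cm = 0.5, r_out_cm = 0.4)
  expect_error(build_network(v2, data.frame(parent = c(2, 1),
                                            child = c(1, 2))),
               "root|cycle")
  expect_error(
    build_network(rbind(v2, v2[2, ]), data.frame(parent = 1, child = 2)),
    "duplicate")
  v3 <- data.frame(id = 1:3, length_cm = 5, r_in_cm = 0.5, r_out_cm = 0.4)
  expect_error(build_network(v3, data.frame(parent = c(1, 1),
                                            child = c(2, 2))),
               "multiple parents")
  expect_error(build_network(v3, data.frame(parent = 1, child = 2)),
               "root")
  # vessels in a detached cycle are unreachable from the root
  expect_error(build_network(v3, data.frame(parent = c(2, 3),
                                            child = c(3, 2))),
               "orphan")
  v4 <- data.frame(id = 1:5, length_cm = 5, r_in_cm = 0.5, r_out_cm = 0.4)
  expect_error(build_network(v4, data.frame(parent = c(1, 1, 1, 1),
                                            child = 2:5)),
               "two children")
})

test_that("canonical network has 17 vessels and the right terminals", {
  for (cohort in c("DORV", "HLHS")) {
    net <- canonical_network(cohort)
    expect_equal(nrow(net$vessels), 17)
    expect_equal(sum(net$vessels$terminal), 9)
    expect_setequal(net$vessels$id[net$vessels$terminal],
                    c(7, 8, 9, 12, 13, 14, 15, 16, 17))
    expect_equal(net$root_id, 1)
    # r_min: arteriolar 0.001 everywhere except the descending aorta
    expect_equal(net$vessels$r_min_cm[net$vessels$id == 7], 0.01)
    expect_true(all(net$vessels$r_min_cm[net$vessels$terminal &
                                           net$vessels$id != 7] == 0.001))
  }
  d <- canonical_network("DORV")$vessels
  expect_equal(unlist(d[d$id == 1, c("length_cm", "r_in_cm", "r_out_cm")],
                      use.names = FALSE), c(3.8, 1.18, 1.04))
  h <- canonical_network("HLHS")$vessels
  expect_equal(unlist(h[h$id == 7, c("length_cm", "r_in_cm", "r_out_cm")],
                      use.names = FALSE), c(35.1, 0.74, 0.55))
})

test_that("stiffness group labels match the grouping scheme", {
  v <- canonical_network("DORV")$vessels
  gl <- split(v$id, v$group_large)
  expect_setequal(gl[["1"]], c(1, 2, 3, 4, 7))
  expect_setequal(gl[["2"]], c(10, 11, 14, 15))
  expect_setequal(gl[["3"]], c(5, 12, 13))
  expect_setequal(gl[["4"]], c(6, 8, 9, 16, 17))
  gs <- split(v$id, v$group_small)
  expect_setequal(gs[["1"]], 7)
  expect_setequal(gs[["2"]], c(10, 14, 15))
  expect_setequal(gs[["3"]], c(12, 13))
  expect_setequal(gs[["4"]], c(8, 9, 16, 17))
})

test_that("network serialisation round-trips", {
  net <- canonical_network("HLHS")
  dir <- withr::local_tempdir()
  write_network(net, dir)
  net2 <- read_network(dir)
  expect_equal(net2$vessels$id, net$vessels$id)
  expect_equal(net2$vessels$r_in_cm, net$vessels$r_in_cm)
  expect_equal(net2$vessels$terminal, net$vessels$terminal)
  expect_equal(as.data.frame(net2$edges), as.data.frame(net$edges))
  expect_equal(net2$root_id, net$root_id)
})

test_that("subnetwork re-derives terminal flags and r_min", {
  net <- canonical_network("DORV")
  sub <- subnetwork(net, c(4, 6, 7), r_min_new = 0.001)
  expect_equal(nrow(sub$vessels), 3)
  expect_equal(sub$root_id, 4)
  expect_setequal(sub$vessels$id[sub$vessels$terminal], c(6, 7))
  # vessel 7 keeps its original termination radius, vessel 6 gets the new one
  expect_equal(sub$vessels$r_min_cm[sub$vessels$id == 7], 0.01)
  expect_equal(sub$vessels$r_min_cm[sub$vessels$id == 6], 0.001)
})

test_that("radius taper matches both measured ends", {
  v <- list(length_cm = 10, r_in_cm = 1.2, r_out_cm = 0.8)
  for (tp in c("exponential", "linear")) {
    expect_equal(vessel_radius(v, 0, tp), 1.2)
    expect_equal(vessel_radius(v, 10, tp), 0.8)
    r <- vessel_radius(v, seq(0, 10, 0.5), tp)
    expect_true(all(r > 0) && all(diff(r) < 0))
  }
})

test_that("tidy returns the vessel table with parents", {
  td <- tidy(canonical_network("DORV"))
  expect_true(all(c("id", "parent", "terminal") %in% names(td)))
  expect_equal(td$parent[td$id == 7], 4)
  expect_true(is.na(td$parent[td$id == 1]))
})
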