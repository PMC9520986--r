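test_that("knot fixtures have their textbook determinants", {
  expect_equal(as.numeric(classify_knot(make_knot_fixture("unknot", 50))$determinant), 1)
  tre <- classify_knot(make_knot_fixture("trefoil", 60))
  expect_equal(as.numeric(tre$determinant), 3)
  expect_false(tre$is_trivial)
  f8 <- classify_knot(make_knot_fixture("figure_eight", 80))
  expect_equal(as.numeric(f8$determinant), 5)
  expect_false(f8$is_trivial)

  expect_error(make_knot_fixture("granny", 60), "unknown knot")
  expect_error(make_knot_fixture("trefoil", 20), "at least 30")
})

test_that("KMT simplification preserves knot type and reaches fixed points", {
  # planar convex polygon collapses to the 3-bead floor
  circ <- make_knot_fixture("unknot", 64)
  expect_equal(simplify_chain(circ)$N, 3L)

  # idempotence
  tre <- make_knot_fixture("trefoil", 60)
  s1 <- simplify_chain(tre)
  s2 <- simplify_chain(s1)
  expect_identical(s1$positions, s2$positions)
  expect_lte(s1$N, tre$N)

  # knot call identical before and after simplification
  expect_equal(classify_knot(tre, simplify = FALSE)$determinant,
               classify_knot(s1)$determinant)

  # random rings: with/without simplification agree (fast subset; the
  # full-scale safety suite runs with the acceptance properties)
  sp <- build_spectrum(100, 3, 3)
  R <- ringknots:::sample_ring_matrix(sp, 100, seed = 8)
  raw <- ringknots:::classify_stack(R, 100, simplify = FALSE, seed = 21)
  sim <- ringknots:::classify_stack(R, 100, simplify = TRUE, seed = 22)
  expect_identical(raw$trivial, sim$trivial)
})

test_that("projection diagrams behave and degenerate directions are reported", {
  circ <- make_knot_fixture("unknot", 40)
  dg <- build_diagram(circ, c(0, 0, 1))      # normal to the circle's plane
  expect_equal(nrow(dg$crossings), 0L)
  expect_equal(as.numeric(alexander_determinant(dg)), 1)

  tre <- make_knot_fixture("trefoil", 60)
  dg3 <- build_diagram(tre, c(0.23, -0.51, 0.83))
  expect_gte(nrow(dg3$crossings), 3L)
  expect_equal(dg3$n_arcs, nrow(dg3$crossings))
  expect_equal(as.numeric(alexander_determinant(dg3)), 3)

  # crossing with coincident depths: a flat bowtie projected along z
  flat <- ring_conformation(cbind(c(0, 1, 1, 0), c(0, 1, 0, 1), c(0, 0, 0, 0)))
  expect_error(build_diagram(flat, c(0, 0, 1)),
               class = "ringknots_degenerate_projection")
})

test_that("the determinant is a projection and rigid-motion invariant", {
  tre <- make_knot_fixture("trefoil", 60)
  f8 <- make_knot_fixture("figure_eight", 80)
  for (fix in list(tre, f8)) {
    ref <- classify_knot(fix, seed = 1)
    for (s in 1:10) {
      rot <- transform_conformation(fix, rot = random_rotation(s))
      call_s <- classify_knot(rot, seed = 100 + s)
      expect_identical(call_s$determinant, ref$determinant)
      expect_identical(call_s$is_trivial, ref$is_trivial)
    }
    # scale and translation invariance
    moved <- transform_conformation(fix, scale = 0.037, shift = c(5, -3, 11))
    expect_identical(classify_knot(moved, seed = 77)$determinant,
                     ref$determinant)
  }
  # two classifications with different direction streams agree
  sp <- build_spectrum(80, 3, 3)
  r <- sample_ring(sp, seed = 5)
  expect_identical(classify_knot(r, seed = 1)[c("determinant", "is_trivial")],
                   classify_knot(r, seed = 999)[c("determinant", "is_trivial")])
})

test_that("abstract Alexander evaluation matches hand-computed diagrams", {
  # standard 3-crossing trefoil (arcs 1,2,3): delete row/col 3 leaves
  # [[-1,-1],[2,-1]], |det| = 3
  tre_tab <- matrix(as.integer(c(3, 1, 2, 1,
                                 1, 2, 3, 1,
                                 2, 3, 1, 1)), ncol = 4, byrow = TRUE)
  res <- ringknots:::cpp_alexander(tre_tab, 3L)
  expect_equal(res$det, 3)
  expect_false(res$trivial)

  # its mirror gives the same determinant
  mir <- tre_tab; mir[, 4] <- -1L
  expect_equal(ringknots:::cpp_alexander(mir, 3L)$det, 3)

  # empty diagram is the unknot
  empty <- matrix(integer(0), ncol = 4)
  expect_equal(ringknots:::cpp_alexander(empty, 0L)$det, 1)

  # inconsistent bookkeeping is rejected
  bad <- matrix(as.integer(c(4, 1, 2, 1,
                             1, 2, 3, 1,
                             2, 3, 1, 1)), ncol = 4, byrow = TRUE)
  expect_error(ringknots:::cpp_alexander(bad, 3L), "inconsistent")
})

test_that("knot calls on noisy and random rings are sane", {
  # unknotted circle with small radial noise stays trivial
  th <- 2 * pi * (0:49) / 50
  set.seed(4)
  noisy <- ring_conformation(cbind((1 + rnorm(50, 0, 0.05)) * cos(th),
                                   (1 + rnorm(50, 0, 0.05)) * sin(th),
                                   rnorm(50, 0, 0.05)))
  expect_true(classify_knot(noisy, seed = 2)$is_trivial)

  # every reported determinant is odd
  sp <- build_spectrum(120, 3.5, 3)
  R <- ringknots:::sample_ring_matrix(sp, 300, seed = 13)
  res <- ringknots:::classify_stack(R, 300, seed = 14)
  dets <- res$det[!is.na(res$det)]
  expect_true(all(dets %% 2 == 1))
  expect_true(all(dets >= 1))
  # trivial <=> determinant 1 wherever the value is representable
  expect_identical(res$trivial[!is.na(res$det)], dets == 1)
})
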