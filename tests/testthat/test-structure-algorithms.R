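test_that("superimposing a structure onto itself is the identity", {
  set.seed(1)
  P <- matrix(rnorm(30), 10, 3)
  fit <- superimpose(P, P)
  expect_equal(fit$transform$rotation, diag(3), tolerance = 1e-9)
  expect_lt(rmsd(P, fit$fitted), 1e-12)
})

test_that("a known rigid motion is recovered exactly", {
  set.seed(2)
  for (rep in 1:20) {
    P <- matrix(rnorm(36), 12, 3)
    R <- random_rotation()
    t <- rnorm(3, sd = 5)
    Q <- P %*% t(R) + matrix(t, 12, 3, byrow = TRUE)
    fit <- superimpose(P, Q)
    expect_lt(rmsd(P, fit$fitted), 1e-9)
    # recovered rotation is the inverse of the applied one
    expect_lt(max(abs(fit$transform$rotation %*% R - diag(3))), 1e-9)
    expect_equal(det(fit$transform$rotation), 1, tolerance = 1e-9)
    expect_lt(max(abs(crossprod(fit$transform$rotation) - diag(3))), 1e-9)
  }
})

test_that("minimal RMSD on noisy pairs matches the quaternion oracle", {
  set.seed(3)
  for (rep in 1:25) {
    n <- sample(4:30, 1)
    P <- matrix(rnorm(3 * n), n, 3)
    Q <- P + matrix(rnorm(3 * n, sd = 0.6), n, 3)
    R <- random_rotation()
    Q <- Q %*% t(R) + matrix(rnorm(3, sd = 4), n, 3, byrow = TRUE)
    fit <- superimpose(P, Q)
    expect_equal(rmsd(P, fit$fitted), oracle_min_rmsd(P, Q),
                 tolerance = 1e-9)
  }
})

test_that("superimposition beats random rigid transforms", {
  set.seed(4)
  P <- matrix(rnorm(45), 15, 3)
  Q <- P + matrix(rnorm(45, sd = 0.4), 15, 3)
  best <- rmsd(P, superimpose(P, Q)$fitted)
  for (rep in 1:100) {
    R <- random_rotation()
    t <- rnorm(3, sd = 3)
    moved <- Q %*% t(R) + matrix(t, 15, 3, byrow = TRUE)
    expect_lte(best, rmsd(P, moved) + 1e-12)
  }
})

test_that("superimposition input validation", {
  expect_error(superimpose(matrix(0, 4, 3), matrix(0, 5, 3)), "differ")
  expect_error(superimpose(matrix(0, 2, 3), matrix(0, 2, 3)), "at least 3")
})

test_that("rmsd closed forms and stack behaviour", {
  P <- matrix(0, 4, 3)
  expect_equal(rmsd(P, P), 0)
  Q <- P; Q[2, 1] <- 2
  expect_equal(rmsd(P, Q), 2 / sqrt(4))
  st <- random_stack(6, 4, seed = 5)
  ref <- st[1, ]
  vals <- rmsd(ref, st)
  expect_length(vals, 4L)
  for (k in 1:4) expect_equal(vals[k], rmsd(ref, st[k, ]))
})

test_that("rmsf matches its closed form and a brute-force oracle", {
  cs <- array(0, c(2, 3, 3))
  cs[1, 1, 1] <- 1.5; cs[2, 1, 1] <- -1.5
  st <- atom_array_stack(cs)
  expect_equal(rmsf(st), c(1.5, 0, 0))
  st2 <- random_stack(7, 5, seed = 6)
  got <- rmsf(st2)
  mean_coord <- apply(st2$coord, c(2, 3), mean)
  want <- numeric(7)
  for (i in 1:7) {
    acc <- 0
    for (k in 1:5) acc <- acc + sum((st2$coord[k, i, ] - mean_coord[i, ])^2)
    want[i] <- sqrt(acc / 5)
  }
  expect_equal(got, want, tolerance = 1e-12)
  expect_error(rmsf(st2[1, ]), "at least 2")
  # identical models fluctuate by zero
  arr <- random_structure(5, seed = 1)
  expect_equal(rmsf(stack_atom_arrays(list(arr, arr))), rep(0, 5))
})

test_that("isolated-atom SASA matches the analytic sphere", {
  arr <- atom_array(matrix(0, 1, 3), element = "O")  # r = 1.52
  v <- sasa(arr, probe_radius = 1.4, point_count = 1000L,
            radius_set = "single")
  expect_equal(v, 4 * pi * 2.92^2, tolerance = 0.01)
  # every point is exposed, so the value is exact at sampling resolution
  expect_equal(v, 4 * pi * 2.92^2, tolerance = 1e-12)
})

test_that("a fully enclosed atom has zero SASA", {
  shell <- rbind(c(2, 0, 0), c(-2, 0, 0), c(0, 2, 0), c(0, -2, 0),
                 c(0, 0, 2), c(0, 0, -2))
  arr <- atom_array(rbind(c(0, 0, 0), shell), element = "O")
  v <- sasa(arr, radius_set = "single")
  expect_equal(v[1], 0)
})

test_that("two-sphere SASA matches the cap-integral oracle within 2%", {
  for (d in c(1.0, 2.5, 4.0, 5.5)) {
    arr <- atom_array(rbind(c(0, 0, 0), c(d, 0, 0)), element = "O")
    v <- sasa(arr, probe_radius = 1.4, point_count = 5000L,
              radius_set = "single")
    want <- oracle_two_sphere_area(2.92, 2.92, d)
    # closed form and lat-long integration agree
    expect_equal(numeric_two_sphere_area(2.92, 2.92, d), want,
                 tolerance = 2e-3)
    if (want > 0) {
      expect_equal(v[1], want, tolerance = 0.02)
      expect_equal(v[2], want, tolerance = 0.02)
    }
  }
})

test_that("sampling error decreases with the point count", {
  seps <- c(1.5, 2.4, 3.3, 4.2, 5.1)
  errs <- vapply(c(100L, 1000L, 10000L), function(np) {
    mean(vapply(seps, function(d) {
      arr <- atom_array(rbind(c(0, 0, 0), c(d, 0, 0)), element = "O")
      abs(sasa(arr, point_count = np, radius_set = "single")[1] -
            oracle_two_sphere_area(2.92, 2.92, d))
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
})

test_that("SASA radius handling: masks, protor set, unknown atoms", {
  arr <- atom_array(rbind(c(0, 0, 0), c(2, 0, 0)),
                    res_name = c("ALA", "HOH"),
                    atom_name = c("CA", "O"), element = c("C", "O"))
  # masked-out atoms neither get a value nor occlude
  v <- sasa(arr, atom_mask = c(TRUE, FALSE), radius_set = "single")
  expect_true(is.na(v[2]))
  expect_equal(v[1], 4 * pi * (1.70 + 1.4)^2, tolerance = 1e-12)
  # protor radii: backbone carbonyl C is smaller than CA
  pep <- atom_array(matrix(rnorm(9), 3, 3), res_name = "ALA",
                    atom_name = c("N", "CA", "C"),
                    element = c("N", "C", "C"))
  r <- atomseq:::atom_radii(pep, "protor")
  expect_equal(r, c(1.64, 1.88, 1.61))
  bad <- atom_array(matrix(0, 1, 3), element = "ZZ")
  expect_error(sasa(bad, radius_set = "single"), "no single radius")
})

test_that("total SASA does not increase when atoms are added", {
  set.seed(8)
  base <- atom_array(matrix(rnorm(15, sd = 2), 5, 3), element = "C")
  more <- atom_array(rbind(matrix(rnorm(15, sd = 2), 5, 3),
                           matrix(rnorm(6, sd = 2), 2, 3)),
                     element = "C")
  more$coord[1:5, ] <- base$coord
  s_base <- sum(sasa(base, radius_set = "single"))
  s_more <- sum(sasa(more, radius_set = "single")[1:5])
  expect_lte(s_more, s_base + 1e-9)
  expect_gte(s_base, 0)
})

test_that("ideal helix and strand traces get their P-SEA labels", {
  helix <- ideal_helix_ca(30)
  labels <- annotate_sse(helix)
  interior <- labels[3:28]
  expect_gte(mean(interior == "a"), 0.9)
  strand <- ideal_strand_ca(14)
  slab <- annotate_sse(strand)
  expect_true(all(slab[3:10] == "b"))
  # short chains are entirely coil
  expect_equal(annotate_sse(ideal_helix_ca(4)), rep("c", 4))
  expect_equal(annotate_sse(ideal_helix_ca(2)), rep("c", 2))
})

test_that("P-SEA uses CA geometry only", {
  helix <- ideal_helix_ca(20)
  # add side-chain atoms with arbitrary coordinates
  side <- atom_array(matrix(rnorm(60, sd = 20), 20, 3),
                     chain_id = "A", res_id = 1:20, res_name = "ALA",
                     atom_name = "CB", element = "C", hetero = FALSE)
  merged <- concat_atom_arrays(helix, side)
  expect_identical(annotate_sse(merged), annotate_sse(helix))
})

test_that("random coil is not annotated as regular structure", {
  coil <- random_structure(40, seed = 12, spread = 20)
  coil$atom_name <- rep("CA", 40)
  coil$res_id <- 1:40
  labels <- annotate_sse(coil)
  expect_equal(length(labels), 40L)
  # a uniformly random walk essentially never satisfies 4-5 consecutive
  # strict helix/strand windows
  expect_gte(mean(labels == "c"), 0.8)
})
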