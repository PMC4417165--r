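test_that("fiber groove profile equals a brute-force P-P scan", {
  s <- sequence_for("f1", "A", "T")
  st <- build_duplex(s, parameter_table(13))
  g <- groove_width_profile(st)
  # brute-force oracle: exhaustive cross-strand distances, same window
  topo <- st$topology
  n <- 13
  Pw <- st$coords[topo$chain == "A" & topo$atom == "P", ]
  Pc <- st$coords[topo$chain == "B" & topo$atom == "P", ][n:1, ]
  for (i in seq_len(n)) {
    js <- i - (2:3)
    if (all(js >= 1)) {
      d <- min(apply(Pc[js, , drop = FALSE], 1,
                     function(p) sqrt(sum((p - Pw[i, ])^2))))
      expect_equal(g$minor[i], max(d - 5.8, 0), tolerance = 1e-12)
    } else {
      expect_true(is.na(g$minor[i]))
    }
  }
  # flat interior profile on a straight build
  interior <- g$minor[!is.na(g$minor)]
  expect_lt(diff(range(interior)), 1e-9)
  expect_equal(mean(interior), 5.894, tolerance = 1e-2)
})

test_that("displacing the minimal P pair moves the width one-for-one", {
  s <- sequence_for("f1", "A", "T")
  st <- build_duplex(s, parameter_table(13))
  topo <- st$topology
  n <- 13; i <- 7
  g0 <- groove_width_profile(st)
  iw <- which(topo$chain == "A" & topo$atom == "P" & topo$resno == i)
  # the minimising Crick partner for the minor window at pair 7 is pair 5
  jc <- which(topo$chain == "B" & topo$atom == "P" & topo$resno == n + 1 - 5)
  u <- st$coords[iw, ] - st$coords[jc, ]
  u <- u / sqrt(sum(u^2))
  st1 <- st
  st1$coords[iw, ] <- st1$coords[iw, ] + 0.5 * u
  st1$coords[jc, ] <- st1$coords[jc, ] - 0.5 * u
  g1 <- groove_width_profile(st1)
  expect_equal(g1$minor[i] - g0$minor[i], 1, tolerance = 1e-9)
})

test_that("short duplexes flag the whole profile as undefined", {
  s <- duplex_sequence("ATG")
  g <- groove_width_profile(build_duplex(s, parameter_table(3)))
  expect_true(all(is.na(g$minor)))
  expect_true(all(is.na(g$major)))
})

test_that("groove widths are invariant under rigid motion", {
  set.seed(81)
  s <- sequence_for("f2", "C", "A")
  st <- build_duplex(s, rand_table(13, t_max = 1, r_max = 20, rise_min = 2.8))
  g0 <- groove_width_profile(st)
  for (k in 1:5) {
    R <- rand_rotation(); t <- rnorm(3, sd = 20)
    st2 <- st
    st2$coords <- sweep(tcrossprod(st$coords, R), 2, t, "+")
    g2 <- groove_width_profile(st2)
    expect_equal(g2$minor, g0$minor, tolerance = 1e-9)
    expect_equal(g2$major, g0$major, tolerance = 1e-9)
  }
})

test_that("widening the backbone strictly widens the mean minor groove", {
  s <- sequence_for("f1", "A", "T")
  st <- build_duplex(s, parameter_table(13))
  g0 <- mean(groove_width_profile(st)$minor, na.rm = TRUE)
  # push Watson P atoms outward along their separation from the axis
  st2 <- st
  sel <- st2$topology$chain == "A" & st2$topology$atom == "P"
  p <- st2$coords[sel, ]
  radial <- p; radial[, 3] <- 0
  st2$coords[sel, ] <- p + 0.4 * radial / sqrt(rowSums(radial^2))
  g2 <- mean(groove_width_profile(st2)$minor, na.rm = TRUE)
  expect_gt(g2, g0)
})

test_that("empty and single-occupancy ion maps convert exactly", {
  s <- sequence_for("f2", "A", "T")
  st <- build_duplex(s, parameter_table(13))
  mk_traj <- function(ions, n_fr) {
    structure(list(topology = st$topology,
                   xyz = matrix(rep(as.vector(t(st$coords)), n_fr), n_fr,
                                byrow = TRUE),
                   ions = ions, seq = s), class = "dna_trajectory")
  }
  none <- mk_traj(replicate(20, matrix(numeric(0), 0, 3), simplify = FALSE), 20)
  m0 <- ion_density_map(none)
  expect_true(all(m0$molarity == 0))
  expect_equal(map_mean_count(m0), 0)
  # one ion pinned in a single bin of volume 1660.6 A^3 -> 1.00 M there
  an <- analyze_structure(st)
  pf <- an$pair_frames[[7]]
  z_half <- 1660.6 / (pi * 10^2) / 2
  pos <- pf$origin + drop(pf$rotation %*% c(3, 0, 0))
  pinned <- mk_traj(replicate(50, matrix(pos, 1, 3, byrow = TRUE),
                              simplify = FALSE), 50)
  m1 <- ion_density_map(pinned, r_max = 10, dr = 10, dtheta = 360,
                        z_half = z_half)
  expect_equal(dim(m1$molarity), c(1L, 1L))
  expect_equal(m1$molarity[1, 1], 1 / (1660.6 * 6.022e-4), tolerance = 1e-9)
  expect_equal(m1$molarity[1, 1], 1.00, tolerance = 1e-2)
  expect_equal(map_mean_count(m1), 1, tolerance = 1e-12)
  expect_error(ion_density_map(pinned, dr = 0), "zero-volume")
})

test_that("map counts and molarities satisfy the conversion identity", {
  s <- sequence_for("f2", "G", "G")
  spec <- ensemble_spec(s, n_frames = 200, seed = 17,
                        ion_spec = list(type = "uniform", molarity = 2,
                                        r_min = 2, r_max = 14, z_half = 1.7))
  traj <- sample_trajectory(spec)
  map <- ion_density_map(traj, z_half = 1.7)
  in_slab <- mean(vapply(seq_len(200), function(f) {
    nrow(traj$ions[[f]])
  }, 0))
  # every sampled ion lies inside the mapped slab for this frozen ensemble
  expect_equal(map_mean_count(map), in_slab, tolerance = 1e-12)
})
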