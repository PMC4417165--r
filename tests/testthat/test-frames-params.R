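test_that("frame fitting tolerates coordinate noise", {
  set.seed(21)
  ref <- standard_base("A")
  planted <- rand_rotation(); t <- c(1, 2, 3)
  obs <- sweep(tcrossprod(ref, planted), 2, t, "+")
  rownames(obs) <- rownames(ref)
  angs <- vapply(1:25, function(k) {
    noisy <- obs + matrix(rnorm(length(obs), sd = 0.01), nrow(obs))
    f <- fit_base_frame(noisy, "A")
    tr <- sum(diag(crossprod(planted, f$rotation)))
    acos(pmin(1, (tr - 1) / 2)) * 180 / pi
  }, 0)
  # 0.01 A isotropic noise on ~10 atoms with ~2 A lever arms perturbs the
  # fitted frame by of order 0.15 degree
  expect_lt(mean(angs), 0.3)
  expect_lt(max(angs), 0.8)
  noisy <- obs + matrix(rnorm(length(obs), sd = 0.01), nrow(obs))
  f <- fit_base_frame(noisy, "A")
  expect_lt(f$rms_fit, 0.05)
  expect_gt(f$rms_fit, 0)
  expect_error(fit_base_frame(obs[1:2, ], "A"), "at least 3")
})

test_that("identity pairs and planted single parameters decompose exactly", {
  # Crick frame = flipped Watson frame, no displacement -> all zeros
  R <- rand_rotation(); o <- c(3, 1, -2)
  fw <- mmduplex:::new_base_frame(o, R)
  fc <- mmduplex:::new_base_frame(o, R %*% mmduplex:::.flip_x)
  p <- intra_bp_params(fw, fc)$params
  expect_lt(max(abs(p)), 1e-9)
  # identical pair frames -> zero step
  pf <- mmduplex:::new_base_frame(o, R)
  expect_lt(max(abs(inter_bp_params(pf, pf)$params)), 1e-9)
  # single planted parameters round-trip through the builder
  s <- duplex_sequence("GAC")
  for (spec1 in list(c(opening = 10), c(shear = 1))) {
    intra <- matrix(0, 3, 6,
                    dimnames = list(NULL, mmduplex:::.intra_names))
    intra[2, names(spec1)] <- spec1
    an <- analyze_structure(build_duplex(s, parameter_table(3, intra = intra)))
    expect_equal(unname(an$intra[2, names(spec1)]), unname(spec1),
                 tolerance = 1e-9)
    expect_lt(max(abs(an$intra[2, setdiff(colnames(an$intra), names(spec1))])),
              1e-9)
  }
})

test_that("decomposition inverts the builder over random draws", {
  set.seed(31)
  s <- sequence_for("f1", "T", "T")
  worst <- 0
  for (k in 1:100) {
    tb <- rand_table(13)
    an <- analyze_structure(build_duplex(s, tb))
    worst <- max(worst,
                 max(abs(an$intra - tb$intra)),
                 max(abs(an$inter - tb$inter)),
                 max(abs(wrap_angle(an$chi - tb$chi))))
  }
  expect_lt(worst, 1e-6)
})

test_that("emitted rotations stay orthonormal and bend stays in range", {
  set.seed(41)
  s <- sequence_for("r", "C", "C")
  for (k in 1:10) {
    an <- analyze_structure(build_duplex(s, rand_table(13, r_max = 40)))
    for (pf in an$pair_frames) {
      R <- pf$rotation
      expect_lt(abs(det(R) - 1), 1e-8)
      expect_lt(max(abs(crossprod(R) - diag(3))), 1e-8)
    }
    g <- global_descriptors(an$pair_frames)
    expect_gte(g$helical_bend, 0)
    expect_lte(g$helical_bend, 180)
  }
})

test_that("strand relabelling negates the odd parameters only", {
  set.seed(51)
  s <- sequence_for("f2", "G", "A")
  tb <- rand_table(13, t_max = 1.2, r_max = 25, rise_min = 2.6)
  st <- build_duplex(s, tb)
  an <- analyze_structure(st)
  flipped <- st
  flipped$topology$chain <- ifelse(st$topology$chain == "A", "B", "A")
  flipped$seq <- duplex_sequence(s$crick, s$watson)
  an2 <- analyze_structure(flipped)
  n <- 13
  ri <- an$intra[n:1, ]
  expect_lt(max(abs(an2$intra[, c("shear", "buckle")] +
                      ri[, c("shear", "buckle")])), 1e-8)
  expect_lt(max(abs(an2$intra[, c("stretch", "stagger", "propeller", "opening")] -
                      ri[, c("stretch", "stagger", "propeller", "opening")])), 1e-8)
  rs <- an$inter[(n - 1):1, ]
  expect_lt(max(abs(an2$inter[, c("shift", "tilt")] + rs[, c("shift", "tilt")])),
            1e-8)
  expect_lt(max(abs(an2$inter[, c("slide", "rise", "roll", "twist")] -
                      rs[, c("slide", "rise", "roll", "twist")])), 1e-8)
})

test_that("chi conformer bins are as declared", {
  expect_equal(chi_conformer(c(-117, 150, 180)), rep("anti", 3))
  expect_equal(chi_conformer(c(-75, -90.0001, -30)),
               c("high-anti", "anti", "high-anti"))
  expect_equal(chi_conformer(c(60, -29.9, 90)), rep("syn", 3))
  expect_equal(chi_conformer(c(100, 120)), c("other", "other"))
  # through the builder
  s <- duplex_sequence("AGC")
  tb <- parameter_table(3, chi = matrix(c(-117, 60, -75, -117, -117, -117), 3))
  an <- analyze_structure(build_duplex(s, tb))
  expect_equal(an$chi[, "W"], c(-117, 60, -75), tolerance = 1e-9)
  expect_equal(chi_conformer(an$chi[, "W"]), c("anti", "syn", "high-anti"))
})

test_that("global descriptors follow straight and bent builds", {
  s <- sequence_for("f1", "A", "T")
  an0 <- analyze_structure(build_duplex(s, parameter_table(13)))
  g0 <- global_descriptors(an0$pair_frames)
  expect_equal(g0$helical_bend, 0, tolerance = 1e-9)
  expect_equal(g0$total_twist, 432, tolerance = 1e-9)
  inter <- matrix(rep(c(0, 0, 3.38, 0, 0, 36), each = 12), 12)
  inter[6, 5] <- 20
  an1 <- analyze_structure(build_duplex(s, parameter_table(13, inter = inter)))
  g1 <- global_descriptors(an1$pair_frames)
  expect_equal(g1$helical_bend, 20, tolerance = 0.5)
  expect_error(global_descriptors(an0$pair_frames[1:5]),
               "too few steps")
  expect_error(global_descriptors(an0$pair_frames[1:3]), "at least 4")
})

test_that("trajectory driver reports constant series with zero SD", {
  s <- sequence_for("f1", "A", "C")
  spec <- ensemble_spec(s, n_frames = 5, seed = 3)
  an <- analyze_trajectory(sample_trajectory(spec))
  expect_true(all(an$summary$intra$sd < 1e-9))
  expect_true(all(an$summary$inter$sd < 1e-9))
  # degenerate ensemble means equal the planted table
  expect_lt(max(abs(an$summary$inter$mean[an$summary$inter$parameter == "twist"] - 36)),
            1e-9)
  expect_lt(max(abs(an$summary$inter$mean[an$summary$inter$parameter == "rise"] - 3.38)),
            1e-9)
})

test_that("ensemble means land within 3 SE of the planted mean", {
  s <- duplex_sequence("ATG")
  spec <- ensemble_spec(s, sds = list(inter = c(0, 0, 0, 0, 3, 0)),
                        n_frames = 400, seed = 13)
  an <- analyze_trajectory(sample_trajectory(spec))
  roll <- an$inter$value[an$inter$parameter == "roll" & an$inter$position == 0]
  expect_lt(abs(mean(roll) - 0), 3 * 3 / sqrt(400))
})
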