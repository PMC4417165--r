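test_that("hydrogen-bond criteria gate on distance and angle", {
  s <- sequence_for("f1", "A", "T")
  st <- build_duplex(s, parameter_table(13))
  hb <- detect_hbonds(st)
  at <- hb[hb$donor_resno == 7 & hb$acceptor_resno == 7 &
             hb$donor_chain != hb$acceptor_chain, ]
  key <- paste(at$donor_chain, at$donor_atom, at$acceptor_chain, at$acceptor_atom)
  expect_true("A N6 B O4" %in% key)    # A(N6)-H...T(O4)
  expect_true("B N3 A N1" %in% key)    # T(N3)-H...A(N1)
  expect_true(all(at$distance <= 3.5))
  expect_true(all(at$angle >= 135))
  # pulling the pair apart breaks the bonds on distance
  apart <- build_with_mm_intra(s, c(0, 2.5, 0, 0, 0, 0))
  hb2 <- detect_hbonds(apart)
  expect_false(any(hb2$donor_resno == 7 & hb2$acceptor_resno == 7 &
                     hb2$donor_chain != hb2$acceptor_chain))
  # tightening the angle cutoff to an unreachable level empties the list
  hb3 <- detect_hbonds(st, theta_min = 179.9)
  expect_equal(nrow(hb3), 0L)
  # shrinking d_max below the shortest bond removes everything too
  hb4 <- detect_hbonds(st, d_max = 2.0)
  expect_equal(nrow(hb4), 0L)
})

test_that("planted scheme mixtures are recovered with exact fractions", {
  s <- sequence_for("f1", "G", "T")
  wob <- build_with_mm_intra(s, c(-2, 0, 0, 0, 0, 0))
  opn <- build_with_mm_intra(s, c(-2, 0, 0, 0, 0, 70))
  traj <- structures_as_traj(c(replicate(70, wob, simplify = FALSE),
                               replicate(30, opn, simplify = FALSE)), s)
  occ <- scheme_occupancies(traj, catalog = read_scheme_catalog("GT"))
  expect_equal(unname(occ$fractions["GT_wobble"]), 0.70)
  expect_equal(unname(occ$fractions["unassigned"]), 0.30)
  expect_equal(sum(occ$fractions), 1, tolerance = 1e-12)
  expect_equal(occ$promiscuity, 1L)
})

test_that("canonical ensembles sit in the WC scheme full time", {
  s <- sequence_for("f1", "A", "T")
  st <- build_duplex(s, parameter_table(13))
  traj <- structures_as_traj(replicate(5, st, simplify = FALSE), s)
  occ <- scheme_occupancies(traj, catalog = read_scheme_catalog("AT"))
  expect_equal(unname(occ$fractions["AT_wc"]), 1)
})

test_that("mirrored G.G schemes recover a planted binomial mixture", {
  s <- sequence_for("f1", "G", "G")
  ga <- build_with_mm_intra(s, c(-1, 0, 0, 0, 0, 10))
  gb <- build_with_mm_intra(s, c(1, 0, 0, 0, 0, 10))
  set.seed(61)
  n <- 300
  pick <- rbinom(n, 1, 0.5)
  traj <- structures_as_traj(lapply(pick, function(p) if (p) ga else gb), s)
  occ <- scheme_occupancies(traj, catalog = read_scheme_catalog("GG"))
  se <- sqrt(0.25 / n)
  expect_lt(abs(occ$fractions[["GG_sym_a"]] - mean(pick)), 1e-12)
  expect_lt(abs(occ$fractions[["GG_sym_a"]] - 0.5), 3 * se)
  expect_lt(abs(occ$fractions[["GG_sym_b"]] - (1 - mean(pick))), 1e-12)
  expect_equal(sum(occ$fractions), 1, tolerance = 1e-12)
})

test_that("breathing summary matches hand-counted run lengths", {
  op <- c(rep(0, 5), rep(80, 3), rep(0, 2), rep(80, 2), rep(0, 8))
  br <- breathing_analysis(op, frame_dt = 1, threshold = 45, min_frames = 2,
                           reference = 0)
  expect_equal(br$summary$occupancy_pct, 25)
  expect_equal(br$summary$n_transitions, 2L)
  expect_equal(br$summary$mean_residence_frames, 2.5)
  expect_equal(br$summary$mean_residence_time, 2.5)
  expect_equal(br$summary$minor$n_events, 0L)
  expect_equal(br$summary$major$occupancy_pct, 25)
  # direction: negative excursions open toward the minor groove
  br2 <- breathing_analysis(-op, threshold = 45, min_frames = 2, reference = 0)
  expect_equal(br2$summary$minor$occupancy_pct, 25)
  expect_equal(br2$summary$major$n_events, 0L)
})

test_that("constant and too-short series behave at the edges", {
  br <- breathing_analysis(rep(3, 50), threshold = 45, min_frames = 2)
  expect_equal(br$summary$occupancy_pct, 0)
  expect_equal(br$summary$n_transitions, 0L)
  expect_error(breathing_analysis(c(1), min_frames = 2), "shorter")
  expect_error(breathing_analysis(c(1, 2, Inf)), "finite")
  expect_error(breathing_analysis(1:10, frame_dt = 0), "positive")
})

test_that("run-length bookkeeping equals a brute-force scan", {
  set.seed(71)
  for (k in 1:200) {
    n <- sample(10:80, 1)
    op <- rnorm(n, sd = 30)
    br <- breathing_analysis(op, threshold = 25, min_frames = 2, reference = 0)
    bf <- brute_breathing(op, threshold = 25, min_frames = 2, reference = 0)
    expect_identical(br$summary$occupancy_pct, bf$occupancy_pct)
    expect_identical(br$summary$n_transitions, bf$n_transitions)
    expect_identical(br$summary$mean_residence_frames, bf$mean_residence)
    expect_identical(br$summary$max_residence_frames, bf$max_residence)
  }
})

test_that("catalog parsing validates bond syntax", {
  expect_error(mmduplex:::.parse_bond("N1 > O2"), "malformed")
  b <- mmduplex:::.parse_bond("W:N1 > C:O2")
  expect_equal(b$donor_strand, "W")
  expect_equal(b$acceptor_atom, "O2")
  expect_error(read_scheme_catalog("nope_no_such"), "no such catalog")
})
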