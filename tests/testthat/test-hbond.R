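test_that("the donor-hydrogen-acceptor angle has exact special cases", {
  expect_equal(dha_angle(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)), 180)
  expect_equal(dha_angle(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0)), 90)
  expect_error(dha_angle(c(0, 0, 0), c(0, 0, 0), c(1, 1, 0)), "coincident")

  # rigid-motion invariance
  set.seed(2)
  for (i in 1:10) {
    d <- rnorm(3); h <- rnorm(3); a <- rnorm(3)
    rot <- rotation_about(rnorm(3), runif(1, 0, 2 * pi))
    shift <- runif(3, -20, 20)
    a0 <- dha_angle(d, h, a)
    a1 <- dha_angle(rot %*% d + shift, rot %*% h + shift, rot %*% a + shift)
    expect_equal(a0, a1, tolerance = 1e-9)
  }
})

test_that("detection applies strict thresholds on distance and angle", {
  spec <- ser_gly_spec()
  ev <- detect_hbonds(fixed_pair_frame(2.8, 165), spec)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$distance, 2.8, tolerance = 1e-9)
  expect_equal(ev$angle, 165, tolerance = 1e-9)
  expect_equal(ev$donor_moiety, "sidechain")
  expect_equal(ev$acceptor_moiety, "backbone")

  # boundaries excluded by strict inequality: set each threshold to the
  # exact measured geometry of the frame, so equality is hit bit-for-bit
  f <- fixed_pair_frame(2.8, 150)
  a <- f$atoms
  d_real <- sqrt(sum((as.numeric(a[a$elety == "OG", c("x", "y", "z")]) -
                      as.numeric(a[a$elety == "O", c("x", "y", "z")]))^2))
  ang_real <- dha_angle(as.numeric(a[a$elety == "OG", c("x", "y", "z")]),
                        as.numeric(a[a$elety == "HG", c("x", "y", "z")]),
                        as.numeric(a[a$elety == "O", c("x", "y", "z")]))
  expect_equal(nrow(detect_hbonds(f, spec, d_max = d_real)), 0L)
  expect_equal(nrow(detect_hbonds(f, spec, d_max = d_real * (1 + 1e-12))),
               1L)
  expect_equal(nrow(detect_hbonds(f, spec, angle_min = ang_real)), 0L)
  expect_equal(nrow(detect_hbonds(f, spec,
                                  angle_min = ang_real - 1e-9)), 1L)
})

test_that("a donor present without its hydrogen is an error naming the atom", {
  f <- fixed_pair_frame(2.8, 165)
  f2 <- cof_structure(f$atoms[f$atoms$elety != "HG", ])
  expect_error(detect_hbonds(f2, ser_gly_spec()), "OG.*HG")
})

test_that("intra-residue pairs are never reported", {
  # put a glycine O inside the serine residue itself: must be ignored
  f <- fixed_pair_frame(2.8, 165)
  a <- f$atoms
  a$resno[a$elety == "O"] <- 1L
  a$resid[a$elety == "O"] <- "SER"
  spec <- hbond_spec(
    donors = data.frame(resid = "SER", heavy = "OG", hydrogen = "HG"),
    acceptors = data.frame(resid = "SER", heavy = "O"))
  expect_equal(nrow(detect_hbonds(cof_structure(a), spec)), 0L)
})

test_that("detection matches exhaustive enumeration on random frames", {
  spec <- ser_gly_spec()
  set.seed(404)
  for (i in 1:8) {
    f <- random_hbond_frame(n_ser = 12, n_gly = 20, box = 14)
    got <- detect_hbonds(f, spec)
    ref <- brute_force_hbonds(f, spec)
    expect_equal(nrow(got), nrow(ref))
    if (nrow(ref)) {
      got_key <- sort(paste(paste0(got$donor_chain, ":", got$donor_resno),
                            got$donor_atom,
                            paste0(got$acceptor_chain, ":", got$acceptor_resno),
                            got$acceptor_atom))
      ref_key <- sort(paste(ref$donor_key, ref$donor_atom,
                            ref$acceptor_key, ref$acceptor_atom))
      expect_equal(got_key, ref_key)
      expect_equal(sort(got$distance), sort(ref$distance), tolerance = 1e-9)
    }
  }
})

test_that("detection is invariant under a global rigid motion", {
  spec <- ser_gly_spec()
  set.seed(9)
  f <- random_hbond_frame(n_ser = 10, n_gly = 15, box = 12)
  rot <- rotation_about(rnorm(3), runif(1, 0, 2 * pi))
  f2 <- apply_rigid_motion(f, rot, runif(3, -30, 30))
  e1 <- detect_hbonds(f, spec)
  e2 <- detect_hbonds(f2, spec)
  expect_equal(nrow(e1), nrow(e2))
  expect_equal(e1$distance, e2$distance, tolerance = 1e-9)
  expect_equal(e1$angle, e2$angle, tolerance = 1e-9)
})

test_that("occupancy is the mean of per-frame bond indicators", {
  sched <- data.frame(distance = c(rep(2.8, 5), rep(3.8, 5)),
                      angle = 170)
  tr <- make_hbond_frames(sched, seed = 3)
  occ <- occupancy(tr, ser_gly_spec())
  expect_equal(nrow(occ), 1L)
  expect_equal(occ$occupancy, 0.5)
  expect_equal(occ$moiety, "sidechain")
  counts <- attr(occ, "counts")
  expect_equal(dim(counts), c(1L, 10L))
  expect_equal(occ$occupancy, mean(counts[1, ] > 0))

  # all frames identical -> occupancy is 0 or 1
  occ_on <- occupancy(make_hbond_frames(
    data.frame(distance = rep(2.8, 4), angle = 170), seed = 1),
    ser_gly_spec())
  expect_equal(occ_on$occupancy, 1)
  occ_off <- occupancy(make_hbond_frames(
    data.frame(distance = rep(3.9, 4), angle = 170), seed = 1),
    ser_gly_spec())
  expect_equal(nrow(occ_off), 0L)
})

test_that("ligand atoms are grouped into named halves for occupancy", {
  # NAP carboxamide N7N donates to a glycine O placed 2.9 A away
  nap <- nap_template()$atoms
  n7n <- as.numeric(nap[nap$elety == "N7N", c("x", "y", "z")])
  extra <- data.frame(
    type = c("HETATM", "HETATM", "ATOM", "ATOM"),
    eleno = max(nap$eleno) + 1:4,
    elety = c("H71", "H72", "O", "CA"),
    resid = c("NAP", "NAP", "GLY", "GLY"),
    chain = c("A", "A", "B", "B"), resno = c(500L, 500L, 1L, 1L),
    x = c(n7n[1] - 1, n7n[1] + 0.3, n7n[1] - 2.7, n7n[1] - 3.4),
    y = c(n7n[2], n7n[2] + 0.9, n7n[2], n7n[2] + 1),
    z = c(n7n[3], n7n[3], n7n[3], n7n[3]),
    o = 1, b = 0, elesy = c("H", "H", "O", "C"))
  fr <- cof_structure(rbind(nap, extra))
  tr <- cof_trajectory(list(fr, fr))
  spec <- hbond_spec(
    donors = data.frame(resid = "NAP", heavy = "N7N",
                        hydrogen = c("H71", "H72")),
    acceptors = data.frame(resid = "GLY", heavy = "O"))
  occ <- occupancy(tr, spec,
                   group_map = list(`nicotinamide` = c("N7N", "O7N", "N1N"),
                                    `2'-phosphate` = c("P2B", "O1X", "O2X",
                                                       "O3X")))
  expect_equal(nrow(occ), 1L)
  expect_equal(occ$group, "nicotinamide")
  expect_equal(occ$resid, "GLY")
  expect_equal(occ$occupancy, 1)
})

test_that("the shipped donor/acceptor dictionary drives detection", {
  spec <- default_hbond_spec()
  expect_true(all(c("resid", "heavy", "hydrogen") %in% names(spec$donors)))
  nap_acc <- spec$acceptors$heavy[spec$acceptors$resid == "NAP"]
  expect_true(all(c("O1X", "O2X", "O3X", "N7A", "O7N") %in% nap_acc))
  # the synthetic serine/glycine frames are covered by the default dictionary
  tr <- make_hbond_frames(data.frame(distance = c(2.8, 3.6), angle = 170),
                          seed = 12)
  occ <- occupancy(tr)
  expect_equal(occ$occupancy, 0.5)
})

test_that("empty trajectories are rejected", {
  expect_error(cof_trajectory(list()), "at least one frame")
})
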