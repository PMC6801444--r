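test_that("ambient filter honors the cutoff boundary and the brute-force oracle", {
  p <- build_peptide(C6_SEQUENCE, "L")
  # CB of residue 1 is the outermost atom along +y at the N-terminus; build
  # lipids whose nearest atom sits just inside / outside the 0.3 nm cutoff
  cb1 <- as.numeric(p$atoms[p$atoms$res_id == 1 & p$atoms$atom == "CB",
                            c("x", "y", "z")])
  pol <- contact_policy()
  near <- frame_of(lipid_at(1, head = cb1 + c(0, 0.29, 0),
                            c2 = cb1 + c(0, 0.6, 0),
                            tail = cb1 + c(0, 0.9, 0)),
                   lipid_at(2, head = cb1 + c(0, 0.31, 0.8),
                            c2 = cb1 + c(0, 0.6, 0.8),
                            tail = cb1 + c(0, 0.9, 0.8)))
  near$lipids <- near$lipids[near$lipids$atom != "N", ]  # single head atom
  amb <- ambient_lipids(p, near, pol)
  expect_equal(amb, 1L)
  # empty lipid set is an empty result, not an error
  empty <- frame_of(lipid_at(1, head = cb1 + c(0, 0, 50)))
  empty$lipids <- empty$lipids[0, ]
  expect_identical(ambient_lipids(p, empty, pol), integer(0))
  # graded-distance fixture equals the all-pairs minimum-distance scan
  for (seed in 1:30) {
    fr <- random_frame(seed + 100, p, n_lipids = 5, spread = 1.0)
    expect_equal(ambient_lipids(p, fr, pol),
                 oracle_ambient(p, fr, pol$ambient_cutoff))
  }
})

test_that("single-contact construction produces exactly one classified count", {
  p <- build_peptide(C6_SEQUENCE, "L")
  arg1 <- p$atoms[p$atoms$res_id == 1 & p$atoms$atom == "CB",
                  c("x", "y", "z")]
  # head 0.4 nm radially outward from the Arg1 side chain, so residue 1 is
  # the only residue within the 0.5 nm contact cutoff
  fr <- frame_of(lipid_at(1, head = as.numeric(arg1) + c(0, 0.4, 0),
                          c2 = as.numeric(arg1) + c(0, 5, 0),
                          tail = as.numeric(arg1) + c(0, 6, 0)))
  hf <- helix_axis(peptide_coords(p, "CA"))
  sides <- classify_sides(fr, hf, "L")
  sides$side <- "descending"          # place the pair on the descending side
  pol <- contact_policy()
  cb <- count_contacts(p, fr, sides, pol)
  expect_equal(c(cb$N_dp, cb$N_dh, cb$N_ah, cb$N_ap), c(1, 0, 0, 0))
  expect_equal(cb$S_rot, unname(pol$weights["w_dp"]))
  # nothing within cutoff: all zero
  far <- frame_of(lipid_at(1, head = as.numeric(arg1) + c(10, 0, 0)))
  sides_far <- data.frame(lipid_id = 1L, side = "descending", tie = FALSE)
  cb0 <- count_contacts(p, far, sides_far, pol)
  expect_equal(cb0$S_rot, 0)
  expect_equal(cb0$N_dp + cb0$N_dh + cb0$N_ah + cb0$N_ap, 0)
})

test_that("classified counts equal the exhaustive pair-enumeration oracle", {
  p <- build_peptide(C6_SEQUENCE, "L")
  hf <- helix_axis(peptide_coords(p, "CA"))
  for (seed in 1:60) {
    fr <- random_frame(seed + 200, p, n_lipids = sample(2:5, 1),
                       spread = 0.9)
    for (scheme in c("lipid_atom", "strict")) {
      pol <- contact_policy(scheme = scheme)
      sides <- classify_sides(fr, hf, "L", basis = "c2")
      got <- count_contacts(p, fr, sides, pol)
      want <- oracle_contacts(p, fr, sides, pol)
      expect_equal(c(got$N_dp, got$N_dh, got$N_ah, got$N_ap),
                   unname(want), info = paste("seed", seed, scheme))
    }
  }
})

test_that("the rotation score is linear in the weights", {
  p <- build_peptide(C6_SEQUENCE, "L")
  mem <- build_bilayer(seed = 2)
  posed <- pose_peptide(p, mem, 1.3, 250)
  pol1 <- contact_policy()
  pol2 <- contact_policy(weights = 2 * pol1$weights)
  cb1 <- contact_breakdown(posed, mem, pol1)
  cb2 <- contact_breakdown(posed, mem, pol2)
  expect_equal(cb2$S_rot, 2 * cb1$S_rot)
  expect_equal(cb1$S_rot, sum(pol1$weights *
                                c(cb1$N_dp, cb1$N_dh, cb1$N_ah, cb1$N_ap)))
})

test_that("contact counts are monotone non-decreasing in the cutoff", {
  p <- build_peptide(C6_SEQUENCE, "L")
  hf <- helix_axis(peptide_coords(p, "CA"))
  fr <- random_frame(42, p, 5, spread = 1.0)
  sides <- classify_sides(fr, hf, "L")
  prev <- c(0, 0, 0, 0)
  for (cut in c(0.3, 0.5, 0.7, 1.0)) {
    cb <- count_contacts(p, fr, sides, contact_policy(contact_cutoff = cut))
    cur <- c(cb$N_dp, cb$N_dh, cb$N_ah, cb$N_ap)
    expect_true(all(cur >= prev))
    prev <- cur
  }
})

test_that("contact breakdown is mirror symmetric", {
  p <- build_peptide(C6_SEQUENCE, "L")
  mem <- build_bilayer(seed = 9)
  posed <- pose_peptide(p, mem, 1.3, 200)
  cbL <- contact_breakdown(posed, mem)
  cbD <- contact_breakdown(mirror_peptide(posed), mirror_bilayer(mem))
  expect_equal(c(cbD$N_dp, cbD$N_dh, cbD$N_ah, cbD$N_ap),
               c(cbL$N_dp, cbL$N_dh, cbL$N_ah, cbL$N_ap))
  expect_equal(cbD$delta_n, cbL$delta_n)
  expect_equal(cbD$trp_head_contacts, cbL$trp_head_contacts)
})

test_that("Trp-head contacts cap at one per lipid", {
  p <- build_peptide(C6_SEQUENCE, "L")
  trp_cg <- as.numeric(p$atoms[p$atoms$atom == "CG", c("x", "y", "z")])
  # one lipid, both head atoms within cutoff -> a single contact
  fr <- frame_of(lipid_at(1, head = trp_cg + c(0.3, 0, 0),
                          c2 = trp_cg + c(5, 0, 0),
                          tail = trp_cg + c(6, 0, 0)))
  expect_equal(trp_head_contacts(p, fr), 1L)
  # heads beyond the cutoff -> zero
  fr0 <- frame_of(lipid_at(1, head = trp_cg + c(2, 0, 0)))
  expect_equal(trp_head_contacts(p, fr0), 0L)
})

test_that("Poisson placement fixture reproduces its requested means", {
  p <- build_peptide(C6_SEQUENCE, "D")
  fr0 <- place_contact_fixture(p, 0, 50, seed = 1)
  cnt0 <- vapply(fr0, function(f) trp_head_contacts(p, f), integer(1))
  expect_true(all(cnt0 == 0))
  fr <- place_contact_fixture(p, 0.96, 1500, seed = 2)
  cnt <- vapply(fr, function(f) trp_head_contacts(p, f), integer(1))
  se <- sd(cnt) / sqrt(length(cnt))
  expect_lt(abs(mean(cnt) - 0.96), 3 * se)
  expect_error(place_contact_fixture(p, -1, 10), ">= 0")
})

test_that("side census and its sign conventions", {
  sides <- data.frame(lipid_id = 1:8,
                      side = c(rep("descending", 3), rep("ascending", 5)),
                      tie = FALSE)
  cen <- side_census(sides)
  expect_equal(cen$n_des, 3)
  expect_equal(cen$n_asc, 5)
  expect_equal(cen$delta_n, -2)
  balanced <- data.frame(lipid_id = 1:4,
                         side = rep(c("descending", "ascending"), 2),
                         tie = FALSE)
  expect_equal(side_census(balanced)$delta_n, 0)
})

test_that("switch events debounce flicker and count persistent changes", {
  s1 <- list(l1 = c("descending", "descending", "ascending", "ascending",
                    "ascending"))
  expect_equal(switch_events(s1, debounce = 2)$per_lipid$n_switches, 1L)
  flicker <- list(l1 = rep(c("descending", "ascending"), 50))
  expect_equal(switch_events(flicker, debounce = 5)$per_lipid$n_switches,
               0L)
  expect_error(switch_events(list(a = c("descending", "ascending"),
                                  b = "descending")), "mismatched")
  # planted hop rates: the faster-hopping system shows more switching lipids
  mk <- function(rate, seed) {
    set.seed(seed)
    lapply(1:30, function(l) {
      lab <- character(400)
      lab[1] <- "descending"
      for (f in 2:400)
        lab[f] <- if (runif(1) < rate)
          setdiff(c("descending", "ascending"), lab[f - 1]) else lab[f - 1]
      lab
    })
  }
  fast <- switch_events(mk(0.03, 1), debounce = 5)
  slow <- switch_events(mk(0.002, 2), debounce = 5)
  expect_gt(switch_diff(fast, slow), 0)
})
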