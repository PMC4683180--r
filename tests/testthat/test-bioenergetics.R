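couples <- default_redox_couples()
cpl <- function(name) get_couple(couples, name)

test_that("the shipped couple table carries the reconstruction's potentials", {
  expect_equal(cpl("NO3-/NO2-")$e0_prime_mv, 433)
  expect_equal(cpl("CO2/CH4")$e0_prime_mv, -244)
  expect_equal(cpl("F420")$e0_prime_mv, -360)
  expect_equal(cpl("ferredoxin")$e0_prime_mv, -500)
  expect_error(get_couple(couples, "nope"), "unknown")
})

test_that("delta_g is antisymmetric, linear in n, and classified by sign", {
  set.seed(29)
  for (i in 1:200) {
    a <- redox_couple("a", runif(1, -600, 500))
    b <- redox_couple("b", runif(1, -600, 500))
    n <- sample(1:8, 1)
    ab <- delta_g(n, a, b); ba <- delta_g(n, b, a)
    expect_equal(ab$delta_g0_kj, -ba$delta_g0_kj)
    expect_equal(delta_g(2 * n, a, b)$delta_g0_kj, 2 * ab$delta_g0_kj)
    if (ab$delta_e_mv > 1e-9) {
      expect_lt(ab$delta_g0_kj, 0)
      expect_equal(ab$classification, "EXERGONIC")
    } else if (ab$delta_e_mv < -1e-9) {
      expect_equal(ab$classification, "ENDERGONIC")
    }
  }
  x <- redox_couple("x", -143)
  expect_equal(delta_g(2, x, x)$classification, "ISOERGONIC")
  expect_equal(delta_g(2, x, x)$delta_g0_kj, 0)
})

test_that("membrane electron-acceptor feasibility matches the quinone choice", {
  thiols <- cpl("CoM-S-S-CoB/CoM-SH+CoB-SH")
  expect_equal(classify_transfer(thiols, cpl("menaquinone")), "EXERGONIC")
  expect_equal(classify_transfer(thiols, cpl("methanophenazine")),
               "ENDERGONIC")
})

test_that("coupled reactions sum branch free energies", {
  thiols <- cpl("CoM-S-S-CoB/CoM-SH+CoB-SH")
  f420 <- cpl("F420"); fd <- cpl("ferredoxin")
  cc <- coupled_reaction_dg(list(list(2, thiols, f420), list(2, fd, f420)))
  expect_equal(cc$branches$delta_g0_kj[1], -2 * 96.485 * (-0.217))
  expect_equal(cc$branches$delta_g0_kj[2], -2 * 96.485 * 0.140)
  expect_equal(cc$total_dg0_kj, 14.85869, tolerance = 1e-6)
  # at standard potentials the confurcation is (slightly) endergonic
  expect_equal(cc$classification, "ENDERGONIC")

  single <- coupled_reaction_dg(list(list(2, fd, f420)))
  expect_equal(single$total_dg0_kj, delta_g(2, fd, f420)$delta_g0_kj)

  mirror <- coupled_reaction_dg(list(list(2, fd, f420), list(2, f420, fd)))
  expect_equal(mirror$total_dg0_kj, 0)
  expect_equal(mirror$classification, "ISOERGONIC")
})

test_that("the reverse-methanogenesis ledger conserves 8 electrons per CH4", {
  led <- reverse_methanogenesis_ledger()
  expect_equal(led$flows$electrons_per_ch4[led$flows$carrier == "F420H2"], 4L)
  expect_equal(led$total_donated, 8L)
  expect_equal(led$total_accepted, 8L)
  expect_error(reverse_methanogenesis_ledger(list(f420h2 = 3)),
               "not conserved")
  # a rebalanced custom stoichiometry is accepted
  led2 <- reverse_methanogenesis_ledger(list(f420h2 = 3, nitrate = 5))
  expect_equal(led2$total_donated, 10L)
})

test_that("pmf bookkeeping sums pump terms against the fixed Mtr cost", {
  led <- reverse_methanogenesis_ledger()
  pmf <- pmf_balance(led)
  expect_equal(pmf$mtr_charges, -2)
  expect_equal(pmf$steps$charges[pmf$steps$step == "Fqo"], 6)
  expect_equal(pmf$steps$charges[pmf$steps$step == "Rieske"], 12)
  expect_equal(pmf$net_charges, 16)
  expect_gt(pmf$net_charges, 0)  # pumping overcompensates the Na+ import

  # no pumps: only the Mtr cost remains
  off <- default_pumps(); off$enabled <- FALSE
  pmf0 <- pmf_balance(led, pumps = off,
                      routing = list(F420H2 = character(0),
                                     `CoM-SH/CoB-SH` = character(0),
                                     Fdred = character(0)))
  expect_equal(pmf0$net_charges, -2)

  # doubling routed electrons doubles pump terms but not Mtr
  led2 <- reverse_methanogenesis_ledger(list(f420h2 = 4, fd_red = 2,
                                             thiol_pairs = 2, nitrate = 8))
  pmf2 <- pmf_balance(led2)
  expect_equal(pmf2$steps$charges, 2 * pmf$steps$charges)
  expect_equal(pmf2$mtr_charges, pmf$mtr_charges)

  # routing through a disabled pump is an error
  expect_error(pmf_balance(led, routing = list(Fdred = "Nar")), "disabled")
})
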