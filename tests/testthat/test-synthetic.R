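test_that("generated pedigree follows the breeding design", {
  spec <- design_spec()
  ped <- generate_pedigree(spec, seed = 1)
  off <- ped[ped$generation == "offspring", ]
  expect_equal(nrow(off), 29 * 10)
  # each family shares exactly one dam and one sire, 5 + 5 composition
  fam <- split(off, off$dam)
  expect_equal(length(fam), 29)
  for (f in fam) {
    expect_equal(length(unique(f$sire)), 1)
    expect_equal(sum(f$sex == "female"), 5)
    expect_equal(sum(f$sex == "male"), 5)
  }

  # minimal design: two founders, two full-sib offspring with A = 0.5
  small <- design_spec(n_dams = 1, n_sires = 1, n_families = 1,
                       daughters_per_family = 1, sons_per_family = 1)
  ped2 <- generate_pedigree(small, seed = 1)
  expect_equal(nrow(ped2), 4)
  A <- additive_relationship(ped2)$A
  expect_equal(A["F1O1", "F1O2"], 0.5)

  # determinism contract
  expect_identical(as.data.frame(generate_pedigree(spec, seed = 5)),
                   as.data.frame(generate_pedigree(spec, seed = 5)))
  expect_false(identical(as.data.frame(generate_pedigree(spec, seed = 5)),
                         as.data.frame(generate_pedigree(spec, seed = 6))))
})

test_that("assortative pairing rank-matches scores", {
  pr <- assortative_pairing(c(d1 = 3, d2 = 1, d3 = 2),
                            c(s1 = 10, s2 = 30, s3 = 20))
  expect_equal(pr$pairs$dam, c("d1", "d3", "d2"))
  expect_equal(pr$pairs$sire, c("s2", "s3", "s1"))
  expect_length(pr$unpaired, 0)

  # ties broken by id order
  pr <- assortative_pairing(c(a = 1, b = 1), c(x = 1, y = 1))
  expect_equal(pr$pairs$dam, c("a", "b"))
  expect_equal(pr$pairs$sire, c("x", "y"))

  # unequal counts: pair the minimum, report the rest
  pr <- assortative_pairing(c(a = 2, b = 1), c(x = 9, y = 8, z = 7))
  expect_equal(nrow(pr$pairs), 2)
  expect_equal(pr$unpaired, "z")

  # rank matching on noiseless scores gives perfect rank correlation
  set.seed(1)
  ds <- stats::setNames(runif(20), paste0("d", 1:20))
  ss <- stats::setNames(runif(20), paste0("s", 1:20))
  pr <- assortative_pairing(ds, ss)
  expect_equal(cor(ds[pr$pairs$dam], ss[pr$pairs$sire], method = "spearman"), 1)
})

test_that("phenotype simulation honours degenerate and pure-noise truths", {
  ped <- generate_pedigree(design_spec(n_dams = 4, n_sires = 4, n_families = 3,
                                       daughters_per_family = 2,
                                       sons_per_family = 2), seed = 1)
  # all variances zero -> records equal the sex means exactly
  t0 <- sim_truth(mu_f = 2, mu_m = 5, V_A_f = 0, V_A_m = 0, V_R_f = 0,
                  V_R_m = 0)
  tab <- simulate_phenotypes(ped, t0, design_spec(), seed = 1)
  expect_true(all(tab$value[tab$sex == "female"] == 2))
  expect_true(all(tab$value[tab$sex == "male"] == 5))

  # residual only: sample variance within 3% of V_R at n = 10,000
  n <- 5000
  big <- founder_pedigree(n)
  t1 <- sim_truth(mu_f = 0, mu_m = 0, V_A_f = 0, V_A_m = 0, V_R_f = 4,
                  V_R_m = 4)
  spec1 <- design_spec(n_dams = n, n_sires = 1, n_families = 1,
                       daughters_per_family = 0, sons_per_family = 0,
                       parent_replicates = 2)
  tab <- simulate_phenotypes(big, t1, spec1, seed = 2)
  expect_equal(length(tab$value), 10000)
  expect_lt(abs(var(tab$value) / 4 - 1), 0.03)

  # determinism
  tab_a <- simulate_phenotypes(ped, t0, design_spec(), seed = 9)
  tab_b <- simulate_phenotypes(ped, t0, design_spec(), seed = 9)
  expect_identical(tab_a, tab_b)
})

test_that("breeding-value pairs follow G kron A", {
  # unrelated founders, V_Af = V_Am = COV = V: empirical covariance ~ [[V,V],[V,V]]
  n <- 1000
  ped <- founder_pedigree(n)
  G <- matrix(3, 2, 2)
  set.seed(3)
  a <- sexqg:::draw_breeding_values(diag(n), G)
  emp <- cov(a)
  expect_lt(max(abs(emp - G)), 0.3)
  expect_lt(max(abs(a[, 1] - a[, 2])), 1e-8) # perfectly correlated components

  # zero cross-sex covariance: brother-sister additive correlation ~ 0
  spec <- design_spec(n_dams = 200, n_sires = 200, n_families = 200,
                      daughters_per_family = 1, sons_per_family = 1)
  ped2 <- generate_pedigree(spec, seed = 4)
  t2 <- sim_truth(mu_f = 0, mu_m = 0, V_A_f = 1, V_A_m = 1, COV_A_mf = 0,
                  V_R_f = 1e-6, V_R_m = 1e-6)
  tab <- simulate_phenotypes(ped2, t2, spec, seed = 5)
  off <- tab[tab$generation == "offspring", ]
  fam <- split(off, list(sub("O.*", "", off$id)))
  sis <- sapply(fam, function(f) f$value[f$sex == "female"][1])
  bro <- sapply(fam, function(f) f$value[f$sex == "male"][1])
  expect_lt(abs(cor(sis, bro)), 0.2)
})

test_that("family covariance structure matches theory", {
  # same-sex full-sib phenotypic covariance = 0.5 V_A + V_CE; parent repeat
  # covariance = V_A + V_PE (founders carry no CE level)
  spec <- design_spec(n_dams = 600, n_sires = 600, n_families = 600,
                      daughters_per_family = 2, sons_per_family = 0,
                      parent_replicates = 2)
  truth <- sim_truth(mu_f = 0, mu_m = 0, V_A_f = 2, V_A_m = 2, COV_A_mf = 0,
                     V_CE_f = 1, V_CE_m = 1, V_PE_f = 0.5, V_PE_m = 0.5,
                     V_R_f = 1, V_R_m = 1)
  ped <- generate_pedigree(spec, seed = 6)
  tab <- simulate_phenotypes(ped, truth, spec, seed = 7)
  off <- tab[tab$generation == "offspring", ]
  o1 <- off$value[grepl("O1$", off$id)]
  o2 <- off$value[grepl("O2$", off$id)]
  # expected 0.5 * 2 + 1 = 2
  expect_lt(abs(cov(o1, o2) - 2), 0.45)
  par <- tab[tab$generation == "parental" & tab$sex == "female", ]
  r1 <- par$value[par$replicate == 1][order(par$id[par$replicate == 1])]
  r2 <- par$value[par$replicate == 2][order(par$id[par$replicate == 2])]
  # expected V_A + V_PE = 2.5
  expect_lt(abs(cov(r1, r2) - 2.5), 0.45)
})

test_that("censoring clips at the limit and log traits stay positive", {
  n <- 500
  ped <- founder_pedigree(n)
  truth <- sim_truth(mu_f = 5.5, mu_m = 5.5, V_A_f = 0, V_A_m = 0,
                     V_R_f = 1, V_R_m = 1, censor_limit = 300,
                     transform = "log")
  spec <- design_spec(n_dams = n, n_sires = 1, n_families = 1,
                      daughters_per_family = 0, sons_per_family = 0)
  tab <- simulate_phenotypes(ped, truth, spec, seed = 8)
  expect_true(all(tab$value <= 300))
  expect_true(all(tab$value >= 1))
  expect_gt(sum(tab$value == 300), 0) # the limit is actually hit

  # no censoring: unbounded on the latent scale (values exceed the limit)
  truth2 <- sim_truth(mu_f = 5.5, mu_m = 5.5, V_A_f = 0, V_A_m = 0,
                      V_R_f = 1, V_R_m = 1, transform = "log")
  tab2 <- simulate_phenotypes(ped, truth2, spec, seed = 8)
  expect_gt(max(tab2$value), 300)
})

test_that("simulated studies are deterministic and well-formed", {
  spec <- design_spec(n_dams = 8, n_sires = 8, n_families = 6,
                      daughters_per_family = 2, sons_per_family = 2)
  sim1 <- simulate_study(spec, seed = 11)
  sim2 <- simulate_study(spec, seed = 11)
  expect_identical(sim1$phenotypes, sim2$phenotypes)
  expect_identical(as.data.frame(sim1$pedigree), as.data.frame(sim2$pedigree))
  sim3 <- simulate_study(spec, seed = 12)
  expect_false(identical(sim1$phenotypes, sim3$phenotypes))

  # aggression contests: every contest has exactly two same-sex members
  agg <- sim1$phenotypes[sim1$phenotypes$trait == "aggression", ]
  expect_true(all(table(agg$contest_id) == 2))
  expect_true(all(tapply(agg$sex, agg$contest_id,
                         function(s) length(unique(s))) == 1))

  # assortative mating induces positive mate correlation in aggression
  big <- simulate_study(design_spec(), seed = 13)
  agg <- big$phenotypes[big$phenotypes$trait == "aggression", ]
  sc <- tapply(agg$value, agg$id, mean)
  off <- big$pedigree[big$pedigree$generation == "offspring", ]
  pairs <- unique(data.frame(dam = off$dam, sire = off$sire))
  expect_gt(cor(sc[pairs$dam], sc[pairs$sire], method = "spearman"), 0.5)
})
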