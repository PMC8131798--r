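test_that("model build links records to the right latent structures", {
  # 2 founders, one record each: 4 latent breeding values (2 ind x 2 sexes)
  ped <- pedigree(c("a", "b"), c(NA, NA), c(NA, NA), c("f", "m"))
  phen <- data.frame(id = c("a", "b"), sex = c("female", "male"),
                     generation = "parental", trait = "t", replicate = 1,
                     contest_id = NA, value = c(1, 2))
  fr <- build_animal_model(phen, ped, "t", random = c("animal"))
  expect_equal(fr$n_bv, 4L)
  expect_false(fr$has_ce) # founders carry no common-environment level

  # log transform stores ln(300)
  fr <- build_animal_model(transform = "log",
                           phen = within(phen, value <- c(300, 300)),
                           ped = ped, trait = "t", random = "animal")
  expect_equal(fr$y[1], log(300), tolerance = 1e-12)
  expect_equal(round(fr$y[1], 4), 5.7038)

  # 10 dyads -> 10 contest levels touching exactly 2 records each
  n <- 20
  ped2 <- founder_pedigree(n)
  phen2 <- founder_phenotypes(n, value = rnorm(n))
  phen2$contest_id <- rep(paste0("C", 1:10), each = 2)
  fr2 <- build_animal_model(phen2, ped2, "t")
  expect_equal(length(fr2$contest_lev), 10)
  expect_true(all(table(fr2$contest_idx) == 2))
})

test_that("model build rejects malformed inputs", {
  ped <- founder_pedigree(3)
  phen <- founder_phenotypes(4, value = 1:4) # F4 not in pedigree
  expect_error(build_animal_model(phen, ped, "t"), "absent from pedigree")

  phen <- founder_phenotypes(3, value = 1:3)
  phen$contest_id <- c("C1", "C1", "C1")
  expect_error(build_animal_model(phen, ped, "t"), "!= 2 members")

  ped2 <- pedigree(c("a", "b"), c(NA, NA), c(NA, NA), c("f", "m"))
  phen2 <- data.frame(id = c("a", "b"), sex = c("female", "male"),
                      generation = "parental", trait = "t", replicate = 1,
                      contest_id = "C1", value = c(1, 2))
  expect_error(build_animal_model(phen2, ped2, "t"), "mixed-sex contest")

  expect_error(build_animal_model(founder_phenotypes(3, value = c(-1, 1, 2)),
                                  ped, "t", transform = "log"),
               "positive")
})

test_that("residual-only sampler reproduces the closed-form posterior", {
  set.seed(42)
  n <- 80
  ped <- founder_pedigree(n)
  phen <- founder_phenotypes(n, value = rnorm(n, 5, 2))
  fit <- animal_model(phen, ped, "t", random = character(0),
                      prior = prior_spec(r_V = 2, r_nu = 1),
                      chain = chain_config(n_iterations = 52000,
                                           burn_in = 2000, thin = 50,
                                           seed = 9))
  vr <- fit$draws[, "V_R_f"]
  # closed form (flat mean prior is indistinguishable from N(0, 1e8)):
  # sigma^2 | y ~ IG((nu0 + n - 1)/2, (nu0 V0 + sum (y - ybar)^2)/2)
  SS <- sum((phen$value - mean(phen$value))^2)
  set.seed(1)
  direct <- (1 * 2 + SS) / 2 / rgamma(1e4, (1 + n - 1) / 2)
  expect_gt(stats::ks.test(vr, direct)$p.value, 0.01)
})

test_that("chains are deterministic given the seed", {
  sim <- simulate_study(design_spec(n_dams = 6, n_sires = 6, n_families = 4,
                                    daughters_per_family = 2,
                                    sons_per_family = 2),
                        truths = list(activity = trait_preset("activity")),
                        seed = 3)
  cc <- chain_config("test", seed = 5)
  f1 <- animal_model(sim$phenotypes, sim$pedigree, "activity",
                     transform = "log", chain = cc)
  f2 <- animal_model(sim$phenotypes, sim$pedigree, "activity",
                     transform = "log", chain = cc)
  expect_identical(f1$draws, f2$draws)
  f3 <- animal_model(sim$phenotypes, sim$pedigree, "activity",
                     transform = "log", chain = chain_config("test", seed = 6))
  expect_false(identical(f1$draws, f3$draws))
  # different seeds, overlapping posterior summaries
  expect_lt(abs(mean(f1$draws[, "V_R_f"]) - mean(f3$draws[, "V_R_f"])),
            4 * sd(f1$draws[, "V_R_f"]))
})

test_that("every retained draw satisfies the posterior invariants", {
  sim <- simulate_study(design_spec(n_dams = 8, n_sires = 8, n_families = 6,
                                    daughters_per_family = 3,
                                    sons_per_family = 3), seed = 5)
  fit <- animal_model(sim$phenotypes, sim$pedigree, "aggression",
                      chain = chain_config("test", seed = 2))
  d <- fit$draws
  vars <- setdiff(colnames(d), c("mu_f", "mu_m", "COV_A_mf"))
  expect_true(all(d[, vars] >= 0))
  # G positive semi-definite draw by draw
  expect_true(all(d[, "COV_A_mf"]^2 <= d[, "V_A_f"] * d[, "V_A_m"] + 1e-12))
  expect_equal(fit$n_retained, 1000)
})

test_that("animal term with identity A matches an independent individual effect", {
  # founders only (A = I): the animal-only and permanent-environment-only
  # models are the same model, so matched-seed posterior summaries agree
  # within Monte-Carlo error
  set.seed(7)
  n <- 200; reps <- 3
  ped <- founder_pedigree(n)
  a <- rnorm(n, 0, 1)
  phen <- data.frame(id = rep(ped$id, each = reps), sex = "female",
                     generation = "parental", trait = "t",
                     replicate = sequence(rep(reps, n)), contest_id = NA,
                     value = rep(a, each = reps) + rnorm(n * reps, 0, 1))
  fa <- animal_model(phen, ped, "t", random = "animal",
                     prior = prior_spec(px = FALSE),
                     chain = chain_config("test", seed = 1))
  fp <- animal_model(phen, ped, "t", random = "pe",
                     chain = chain_config("test", seed = 1))
  expect_lt(abs(mean(fa$draws[, "V_A_f"]) - mean(fp$draws[, "V_PE_f"])), 0.1)
  expect_lt(abs(mean(fa$draws[, "V_R_f"]) - mean(fp$draws[, "V_R_f"])), 0.05)
})

test_that("fixed sex difference is recovered within its credible interval", {
  truth <- sim_truth(mu_f = 10, mu_m = 14, V_A_f = 0.5, V_A_m = 0.5,
                     V_CE_f = 0.3, V_CE_m = 0.3, V_PE_f = 0.3, V_PE_m = 0.3,
                     V_R_f = 1, V_R_m = 1)
  sim <- simulate_study(design_spec(), truths = list(trait = truth), seed = 8)
  fit <- animal_model(sim$phenotypes, sim$pedigree, "trait",
                      chain = chain_config("test", seed = 3))
  diff <- fit$draws[, "mu_m"] - fit$draws[, "mu_f"]
  ci <- quantile(diff, c(0.025, 0.975))
  expect_gt(4, ci[1])
  expect_lt(4, ci[2])
})

test_that("fit methods expose coefficients, fitted values and predictions", {
  sim <- simulate_study(design_spec(n_dams = 6, n_sires = 6, n_families = 4,
                                    daughters_per_family = 2,
                                    sons_per_family = 2),
                        truths = list(boldness = trait_preset("boldness")),
                        seed = 9)
  fit <- animal_model(sim$phenotypes, sim$pedigree, "boldness",
                      chain = chain_config("test", seed = 4))
  expect_named(coef(fit), c("mu_f", "mu_m"))
  expect_equal(length(fitted(fit)), length(fit$frame$y))
  expect_equal(residuals(fit), fit$frame$y - fitted(fit))
  bv <- predict(fit)
  expect_equal(dim(bv), c(nrow(sim$pedigree), 2))
  # fitted values track the data far better than the raw sex means
  mu <- coef(fit)[fit$frame$sex_rec + 1]
  expect_lt(sd(residuals(fit)), sd(fit$frame$y - mu))
  sims <- simulate(fit, nsim = 2, seed = 1)
  expect_equal(dim(sims), c(length(fit$frame$y), 2))
  s <- summary(fit)
  expect_s3_class(s, "summary.animal_model")
  expect_true(all(c("V_A_f", "h2_m") %in% s$parameters$quantity))
})
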