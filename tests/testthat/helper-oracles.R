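# Gene-dropping Monte-Carlo oracle for additive relationships: founder
# alleles are dropped down the pedigree and A is estimated as twice the
# probability that random alleles from two individuals are identical by
# descent. Independent of the tabular method it is used to check.
gene_drop_A <- function(ped, n_drops = 1e5) {
  n <- nrow(ped)
  di <- attr(ped, "dam_idx"); si <- attr(ped, "sire_idx")
  next_allele <- 0L
  al1 <- matrix(0L, n_drops, n) # allele inherited from dam side
  al2 <- matrix(0L, n_drops, n) # from sire side
  for (i in seq_len(n)) {
    if (is.na(di[i])) {
      al1[, i] <- next_allele + 1L
      next_allele <- next_allele + 1L
    } else {
      pick <- stats::runif(n_drops) < 0.5
      al1[, i] <- ifelse(pick, al1[, di[i]], al2[, di[i]])
    }
    if (is.na(si[i])) {
      al2[, i] <- next_allele + 1L
      next_allele <- next_allele + 1L
    } else {
      pick <- stats::runif(n_drops) < 0.5
      al2[, i] <- ifelse(pick, al1[, si[i]], al2[, si[i]])
    }
  }
  A_hat <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  se <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in i:n) {
      if (i == j) {
        p <- as.numeric(al1[, i] == al2[, i])
        A_hat[i, i] <- 1 + mean(p)
      } else {
        p <- (as.numeric(al1[, i] == al1[, j]) + as.numeric(al1[, i] == al2[, j]) +
              as.numeric(al2[, i] == al1[, j]) + as.numeric(al2[, i] == al2[, j])) / 2
        A_hat[i, j] <- A_hat[j, i] <- mean(p)
      }
      se[i, j] <- se[j, i] <- stats::sd(p) / sqrt(n_drops)
    }
  }
  list(A = A_hat, se = se)
}

# random valid pedigree: founders plus generations of offspring with
# randomly chosen earlier parents of the right sex
random_pedigree <- function(n_founders = 40, n_offspring = 260, seed = 1) {
  set.seed(seed)
  n <- n_founders + n_offspring
  id <- paste0("I", seq_len(n))
  sex <- sample(c("female", "male"), n, replace = TRUE)
  sex[1:2] <- c("female", "male") # guarantee both sexes among founders
  dam <- rep(NA_character_, n); sire <- rep(NA_character_, n)
  for (i in (n_founders + 1):n) {
    prev_f <- which(sex[seq_len(i - 1)] == "female")
    prev_m <- which(sex[seq_len(i - 1)] == "male")
    dam[i] <- id[sample(prev_f, 1)]
    sire[i] <- id[sample(prev_m, 1)]
  }
  pedigree(id, dam, sire, sex)
}

# small phenotype table for founders-only designs used in several tests
founder_phenotypes <- function(n, sex = "female", value, trait = "t") {
  data.frame(id = paste0("F", seq_len(n)), sex = sex, generation = "parental",
             trait = trait, replicate = 1L, contest_id = NA_character_,
             value = value, stringsAsFactors = FALSE)
}

founder_pedigree <- function(n, sex = "female") {
  pedigree(paste0("F", seq_len(n)), rep(NA, n), rep(NA, n), rep(sex, n))
}

published_estimates <- function() {
  path <- system.file("extdata", "published_qg_estimates.tsv", package = "sexqg")
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

# draw vector with an exactly specified mean (for worked-example contrasts)
centered_draws <- function(n, target_mean, sd = 1, seed = 1) {
  set.seed(seed)
  x <- stats::rnorm(n, 0, sd)
  x - mean(x) + target_mean
}
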