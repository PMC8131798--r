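#' Breeding-design specification
#'
#' Describes the paired full-sib design the generator emulates: a parental
#' generation of field-collected founder dams and sires, monogamous pairs, a
#' target number of full-sib families each aiming at a fixed number of
#' daughters and sons, repeated measurements of parents, single measurements
#' of offspring, and optional assortative pairing by aggressiveness.
#'
#' Defaults mirror the study design the package emulates: 30 dams, 31 sires,
#' 29 families of 5 daughters + 5 sons, parents tested twice, offspring once,
#' assortative pairing on.
#'
#' @param n_dams,n_sires founder counts.
#' @param n_families number of full-sib families (`<= min(n_dams, n_sires)`).
#' @param daughters_per_family,sons_per_family target offspring per family.
#' @param parent_replicates,offspring_replicates measurements per individual.
#' @param assortative logical; rank-match pairs by parental aggressiveness.
#' @param sex_ratio_jitter logical; if `TRUE` each family's sex split is
#'   binomially resampled around the target total (off by default).
#' @return A list of class `"design_spec"`.
#' @export
design_spec <- function(n_dams = 30, n_sires = 31, n_families = 29,
                        daughters_per_family = 5, sons_per_family = 5,
                        parent_replicates = 2, offspring_replicates = 1,
                        assortative = TRUE, sex_ratio_jitter = FALSE) {
  stopifnot(n_families <= min(n_dams, n_sires),
            parent_replicates >= 1, offspring_replicates >= 1,
            daughters_per_family >= 0, sons_per_family >= 0)
  structure(list(n_dams = n_dams, n_sires = n_sires, n_families = n_families,
                 daughters_per_family = daughters_per_family,
                 sons_per_family = sons_per_family,
                 parent_replicates = parent_replicates,
                 offspring_replicates = offspring_replicates,
                 assortative = assortative,
                 sex_ratio_jitter = sex_ratio_jitter),
            class = "design_spec")
}

#' Generating values for a simulated trait
#'
#' Holds the variance components and means used to simulate one trait:
#' sex-specific means on the analysis scale, the 2x2 cross-sex additive
#' genetic matrix G = [[V_Af, COV_Amf], [COV_Amf, V_Am]], sex-specific common
#' environment/maternal, permanent environment and residual variances, an
#' optional contest variance (dyadic traits), an optional right-censoring
#' limit on the observation scale, and the transform linking the analysis
#' scale to the observation scale.
#'
#' @param mu_f,mu_m sex-specific means on the analysis scale.
#' @param V_A_f,V_A_m,COV_A_mf additive genetic (co)variances; the implied G
#'   must be positive semi-definite.
#' @param V_CE_f,V_CE_m common environment/maternal variances.
#' @param V_PE_f,V_PE_m permanent environment variances.
#' @param V_R_f,V_R_m residual variances.
#' @param V_C contest variance (`NA` for non-dyadic traits).
#' @param censor_limit right-censoring limit in observation-scale units
#'   (seconds for latencies), or `NA` for none.
#' @param transform `"none"` or `"log"`; with `"log"` the model operates on
#'   the natural-log scale and observations are `exp(latent)` clipped to
#'   `[1, censor_limit]`.
#' @return A list of class `"sim_truth"`.
#' @export
sim_truth <- function(mu_f, mu_m, V_A_f, V_A_m, COV_A_mf = 0,
                      V_CE_f = 0, V_CE_m = 0, V_PE_f = 0, V_PE_m = 0,
                      V_R_f = 1, V_R_m = 1, V_C = NA, censor_limit = NA,
                      transform = c("none", "log")) {
  transform <- match.arg(transform)
  vars <- c(V_A_f, V_A_m, V_CE_f, V_CE_m, V_PE_f, V_PE_m, V_R_f, V_R_m)
  if (any(vars < 0)) stop("variances must be >= 0")
  if (COV_A_mf^2 > V_A_f * V_A_m + 1e-12) {
    stop("G not positive semi-definite: COV_A_mf^2 > V_A_f * V_A_m")
  }
  if (!is.na(V_C) && V_C < 0) stop("V_C must be >= 0")
  if (!is.na(censor_limit) && censor_limit <= 0) stop("censor_limit must be > 0")
  structure(list(mu_f = mu_f, mu_m = mu_m,
                 G = matrix(c(V_A_f, COV_A_mf, COV_A_mf, V_A_m), 2, 2,
                            dimnames = list(c("f", "m"), c("f", "m"))),
                 V_CE_f = V_CE_f, V_CE_m = V_CE_m,
                 V_PE_f = V_PE_f, V_PE_m = V_PE_m,
                 V_R_f = V_R_f, V_R_m = V_R_m, V_C = V_C,
                 censor_limit = censor_limit, transform = transform),
            class = "sim_truth")
}

#' Trait presets with realistic generating values
#'
#' Named presets for the four behaviours the package's worked examples use:
#' aggression (raw-scale dyadic contest scores), activity and exploration
#' (novel-environment latencies, natural-log analysis scale, right-censored
#' at 300 s) and boldness (death-feigning latency, raw scale, censored at
#' 300 s). Variance components are the by-sex posterior means of the
#' published study the package's design emulates (see
#' `system.file("extdata", "published_qg_estimates.tsv", package = "sexqg")`),
#' so that recovery experiments run at empirically realistic magnitudes.
#' Means are chosen to be consistent with the published mean-standardized
#' coefficients and sex contrasts; the aggression contest variance, which the
#' published tables do not print, is set to 5.
#'
#' @param trait one of `"aggression"`, `"activity"`, `"exploration"`,
#'   `"boldness"`.
#' @return A [sim_truth()] object.
#' @export
trait_preset <- function(trait = c("aggression", "activity", "exploration",
                                   "boldness")) {
  trait <- match.arg(trait)
  switch(trait,
    aggression = sim_truth(mu_f = 4.9, mu_m = 17.0,
                           V_A_f = 3.330, V_A_m = 59.367, COV_A_mf = 3.109,
                           V_CE_f = 1.663, V_CE_m = 31.016,
                           V_PE_f = 13.471, V_PE_m = 41.030,
                           V_R_f = 0.723, V_R_m = 110.382,
                           V_C = 5, transform = "none"),
    activity = sim_truth(mu_f = 4.007, mu_m = 4.230,
                         V_A_f = 0.006, V_A_m = 0.071, COV_A_mf = 0,
                         V_CE_f = 0.012, V_CE_m = 0.038,
                         V_PE_f = 0.027, V_PE_m = 0.170,
                         V_R_f = 0.116, V_R_m = 0.035,
                         censor_limit = 300, transform = "log"),
    exploration = sim_truth(mu_f = 4.382, mu_m = 4.290,
                            V_A_f = 0.015, V_A_m = 0.051, COV_A_mf = 0,
                            V_CE_f = 0.053, V_CE_m = 0.042,
                            V_PE_f = 0.144, V_PE_m = 0.203,
                            V_R_f = 0.168, V_R_m = 0.146,
                            censor_limit = 300, transform = "log"),
    boldness = sim_truth(mu_f = 64.6, mu_m = 58.9,
                         V_A_f = 327.139, V_A_m = 173.983, COV_A_mf = 23.220,
                         V_CE_f = 379.028, V_CE_m = 208.236,
                         V_PE_f = 1326.757, V_PE_m = 1431.35,
                         V_R_f = 2852.365, V_R_m = 1100.852,
                         censor_limit = 300, transform = "none"))
}

#' Generate a breeding-design pedigree
#'
#' Builds founder dams (`D1..`) and sires (`S1..`), forms `n_families`
#' monogamous pairs (in id order; phenotype-based assortative pairing is done
#' by [simulate_study()], which pairs after simulating parental aggression),
#' and attaches the requested full-sib offspring to each pair. Deterministic
#' given `seed`.
#'
#' @param spec a [design_spec()].
#' @param seed integer RNG seed (used for sex-ratio jitter and family
#'   subsampling).
#' @param pairing optional integer vector: for family `k`, the index of the
#'   sire paired with dam `k`'s family; defaults to id order.
#' @return A [pedigree()] object.
#' @export
generate_pedigree <- function(spec = design_spec(), seed = 1, pairing = NULL) {
  stopifnot(inherits(spec, "design_spec"))
  set.seed(seed)
  dams <- paste0("D", seq_len(spec$n_dams))
  sires <- paste0("S", seq_len(spec$n_sires))
  if (is.null(pairing)) {
    fam_dams <- sample(seq_len(spec$n_dams), spec$n_families)
    fam_sires <- sample(seq_len(spec$n_sires), spec$n_families)
  } else {
    stopifnot(length(pairing$dam) == length(pairing$sire))
    fam_dams <- pairing$dam[seq_len(min(spec$n_families, length(pairing$dam)))]
    fam_sires <- pairing$sire[seq_len(min(spec$n_families, length(pairing$sire)))]
  }
  id <- c(dams, sires); dam <- rep(NA_character_, length(id))
  sire <- rep(NA_character_, length(id))
  sex <- c(rep("female", spec$n_dams), rep("male", spec$n_sires))
  for (k in seq_along(fam_dams)) {
    nd <- spec$daughters_per_family; ns <- spec$sons_per_family
    if (spec$sex_ratio_jitter) {
      tot <- nd + ns
      nd <- stats::rbinom(1, tot, nd / tot)
      ns <- tot - nd
    }
    n_off <- nd + ns
    if (n_off == 0) next
    oid <- paste0("F", k, "O", seq_len(n_off))
    id <- c(id, oid)
    dam <- c(dam, rep(dams[fam_dams[k]], n_off))
    sire <- c(sire, rep(sires[fam_sires[k]], n_off))
    sex <- c(sex, rep(c("female", "male"), c(nd, ns)))
  }
  pedigree(id, dam, sire, sex)
}

#' Rank-matched assortative pairing
#'
#' Pairs dams with sires by matching phenotype ranks (highest score with
#' highest score), the mating scheme used for aggressive spiders in the
#' emulated design. Ties are broken by id order. When the usable counts
#' differ only the first `min(n_dams, n_sires)` ranks are paired and the
#' remainder reported unpaired.
#'
#' @param dam_scores,sire_scores named numeric vectors of per-individual
#'   scores (names are ids).
#' @return A list with `pairs` (data frame `dam`, `sire`, in descending score
#'   rank) and `unpaired` (character vector of ids left out).
#' @export
assortative_pairing <- function(dam_scores, sire_scores) {
  rank_ids <- function(x) names(x)[order(-x, seq_along(x))]
  dr <- rank_ids(dam_scores); sr <- rank_ids(sire_scores)
  k <- min(length(dr), length(sr))
  list(pairs = data.frame(dam = dr[seq_len(k)], sire = sr[seq_len(k)],
                          stringsAsFactors = FALSE),
       unpaired = c(dr[-seq_len(k)], sr[-seq_len(k)]))
}

# Joint draw of breeding-value pairs over a pedigree: a (n x 2) with
# cov(a[i, s], a[j, t]) = A[i, j] * G[s, t], via chol(A) %*% Z %*% chol(G)'.
draw_breeding_values <- function(A, G) {
  n <- nrow(A)
  eg <- eigen(G, symmetric = TRUE)
  LG <- eg$vectors %*% diag(sqrt(pmax(eg$values, 0)), 2) # G may be singular
  ea <- eigen(A, symmetric = TRUE)
  LA <- ea$vectors %*% diag(sqrt(pmax(ea$values, 0)), n)
  Z <- matrix(stats::rnorm(2 * n), n, 2)
  a <- LA %*% Z %*% t(LG)
  dimnames(a) <- list(rownames(A), c("f", "m"))
  a
}

#' Simulate phenotypes over a pedigree
#'
#' Draws records from the generative model the animal model assumes. For each
#' record of individual `i`: `y = mu_sex + a[i, sex] + ce_family + pe_i +
#' c_contest + e`, where the stacked breeding-value pairs `(a_f, a_m)` follow
#' a zero-mean multivariate normal with covariance `G` Kronecker the additive
#' relationship matrix (only the component matching the individual's sex
#' enters its records), `ce` is shared by same-sex members of a full-sib
#' family (individuals with an unknown dam carry no `ce`), `pe` is a
#' per-individual permanent effect, `c` is shared by exactly the two same-sex
#' contestants of a dyad (dyadic traits only, paired at random within sex and
#' replicate), and `e` is residual. With a log transform the latent scale is
#' natural log; observed values are back-transformed, clipped to
#' `[1, censor_limit]`, and the analysis value re-transformed, so censored
#' latencies enter as plain clipped values. Deterministic given `seed`.
#'
#' @param ped a [pedigree()].
#' @param truth a [sim_truth()].
#' @param spec a [design_spec()] (replicate counts; family structure is taken
#'   from the pedigree itself).
#' @param trait trait label written to the table.
#' @param seed integer seed.
#' @param dyadic logical; simulate shared contest effects (defaults to
#'   `TRUE` when `truth$V_C` is set).
#' @param breeding_values optional precomputed `n x 2` matrix (rows in pedigree
#'   order) to condition on; drawn fresh when `NULL`.
#' @return A data frame of class `"phenotype_table"` with columns `id`, `sex`,
#'   `generation`, `trait`, `replicate`, `contest_id` and `value`
#'   (observation scale).
#' @export
simulate_phenotypes <- function(ped, truth, spec = design_spec(),
                                trait = "trait", seed = 1,
                                dyadic = !is.na(truth$V_C),
                                breeding_values = NULL) {
  stopifnot(inherits(ped, "pedigree"), inherits(truth, "sim_truth"))
  set.seed(seed)
  n <- nrow(ped)
  A <- additive_relationship(ped)$A
  a <- if (is.null(breeding_values)) draw_breeding_values(A, truth$G) else breeding_values
  stopifnot(nrow(a) == n)

  sex_num <- ifelse(ped$sex == "female", 1L, 2L)
  mu <- c(truth$mu_f, truth$mu_m)
  v_ce <- c(truth$V_CE_f, truth$V_CE_m)
  v_pe <- c(truth$V_PE_f, truth$V_PE_m)
  v_r <- c(truth$V_R_f, truth$V_R_m)

  # family (clutch) effects: one level per dam x sex; founders carry none
  fam <- ifelse(is.na(ped$dam), NA, ped$dam)
  fam_lev <- unique(stats::na.omit(fam))
  ce_f <- stats::rnorm(length(fam_lev), 0, sqrt(truth$V_CE_f))
  ce_m <- stats::rnorm(length(fam_lev), 0, sqrt(truth$V_CE_m))
  names(ce_f) <- names(ce_m) <- fam_lev

  pe <- stats::rnorm(n, 0, sqrt(v_pe[sex_num]))

  reps <- ifelse(ped$generation == "parental", spec$parent_replicates,
                 spec$offspring_replicates)
  rows <- rep(seq_len(n), reps)
  replicate <- sequence(reps)

  contest_id <- rep(NA_character_, length(rows))
  c_eff <- numeric(length(rows))
  if (dyadic) {
    v_c <- if (is.na(truth$V_C)) 0 else truth$V_C
    for (r in unique(replicate)) {
      for (s in 1:2) {
        idx <- which(replicate == r & sex_num[rows] == s)
        idx <- idx[sample.int(length(idx))]
        npair <- floor(length(idx) / 2)
        if (npair == 0) next
        for (p in seq_len(npair)) {
          members <- idx[c(2 * p - 1, 2 * p)]
          cid <- paste0("C", r, "_", c("f", "m")[s], p)
          contest_id[members] <- cid
          c_eff[members] <- stats::rnorm(1, 0, sqrt(v_c))
        }
      }
    }
    # an odd individual out has no opponent that round: drop its record
    keep <- !is.na(contest_id)
    rows <- rows[keep]; replicate <- replicate[keep]
    contest_id <- contest_id[keep]; c_eff <- c_eff[keep]
  }

  e <- stats::rnorm(length(rows), 0, sqrt(v_r[sex_num[rows]]))
  ce_term <- ifelse(is.na(fam[rows]), 0,
                    ifelse(sex_num[rows] == 1L, ce_f[fam[rows]], ce_m[fam[rows]]))
  latent <- mu[sex_num[rows]] + a[cbind(rows, sex_num[rows])] +
    ce_term + pe[rows] + c_eff + e

  # value is on the observation scale: back-transform, clip to the censoring
  # limit (and to >= 1 s for log-scale latencies), and leave any re-transform
  # to the analysis stage
  if (truth$transform == "log") {
    raw <- exp(latent)
    if (!is.na(truth$censor_limit)) raw <- pmin(raw, truth$censor_limit)
    raw <- pmax(raw, 1) # latencies are at least 1 s by construction
  } else {
    raw <- latent
    if (!is.na(truth$censor_limit)) raw <- pmin(raw, truth$censor_limit)
  }

  out <- data.frame(id = ped$id[rows], sex = ped$sex[rows],
                    generation = ped$generation[rows], trait = trait,
                    replicate = replicate, contest_id = contest_id,
                    value = raw, stringsAsFactors = FALSE)
  attr(out, "breeding_values") <- a
  class(out) <- c("phenotype_table", "data.frame")
  out
}

#' Simulate a complete study (pedigree + phenotypes for all traits)
#'
#' End-to-end emulation of the breeding design: founders are generated and
#' their phenotypes simulated first; dams and sires are then paired
#' assortatively by their mean observed aggression score (rank matching) when
#' `spec$assortative` is set, full-sib families are attached to the first
#' `n_families` pairs, and offspring phenotypes are simulated conditional on
#' the parental breeding values (offspring pair = parental average plus a
#' Mendelian-sampling deviate with covariance `G/2`).
#'
#' @param spec a [design_spec()].
#' @param truths named list of [sim_truth()] objects (default: the four trait
#'   presets).
#' @param seed integer seed; the run is deterministic given it.
#' @return A list with `pedigree`, `phenotypes` (one long
#'   `"phenotype_table"`), `truths`, `spec`, `seed`.
#' @export
simulate_study <- function(spec = design_spec(),
                           truths = list(aggression = trait_preset("aggression"),
                                         activity = trait_preset("activity"),
                                         exploration = trait_preset("exploration"),
                                         boldness = trait_preset("boldness")),
                           seed = 1) {
  stopifnot(length(names(truths)) == length(truths))
  set.seed(seed)
  dams <- paste0("D", seq_len(spec$n_dams))
  sires <- paste0("S", seq_len(spec$n_sires))
  founders <- pedigree(c(dams, sires), rep(NA, spec$n_dams + spec$n_sires),
                       rep(NA, spec$n_dams + spec$n_sires),
                       c(rep("female", spec$n_dams), rep("male", spec$n_sires)))

  # founder breeding values per trait (A = I among founders)
  seeds <- sample.int(2^30, 2 * length(truths) + 2)
  founder_bv <- lapply(seq_along(truths), function(k) {
    set.seed(seeds[k])
    draw_breeding_values(diag(nrow(founders)), truths[[k]]$G)
  })
  names(founder_bv) <- names(truths)

  parent_spec <- spec
  parent_tabs <- lapply(seq_along(truths), function(k) {
    simulate_phenotypes(founders, truths[[k]], parent_spec,
                        trait = names(truths)[k],
                        seed = seeds[length(truths) + k],
                        breeding_values = founder_bv[[k]])
  })
  names(parent_tabs) <- names(truths)

  # assortative pairing by observed mean aggression (falls back to id order)
  if (spec$assortative && "aggression" %in% names(truths)) {
    agg <- parent_tabs$aggression
    sc <- tapply(agg$value, agg$id, mean)
    pr <- assortative_pairing(sc[dams], sc[sires])
    pairing <- list(dam = match(pr$pairs$dam, dams),
                    sire = match(pr$pairs$sire, sires))
  } else {
    pairing <- list(dam = seq_len(spec$n_dams), sire = seq_len(spec$n_sires))
  }
  if (length(pairing$dam) > spec$n_families) {
    set.seed(seeds[2 * length(truths) + 1])
    keep <- sort(sample(seq_along(pairing$dam), spec$n_families))
    pairing <- list(dam = pairing$dam[keep], sire = pairing$sire[keep])
  }
  ped <- generate_pedigree(spec, seed = seeds[2 * length(truths) + 2],
                           pairing = pairing)

  # offspring phenotypes conditional on the founder draws
  tabs <- lapply(seq_along(truths), function(k) {
    truth <- truths[[k]]
    bv <- matrix(0, nrow(ped), 2, dimnames = list(ped$id, c("f", "m")))
    bv[rownames(founder_bv[[k]]), ] <- founder_bv[[k]]
    di <- attr(ped, "dam_idx"); si <- attr(ped, "sire_idx")
    set.seed(seeds[length(truths) + k] + 1)
    for (i in which(!is.na(di) & !is.na(si))) {
      mend <- draw_breeding_values(diag(1), truth$G / 2)
      bv[i, ] <- 0.5 * (bv[di[i], ] + bv[si[i], ]) + mend
    }
    # offspring-only records (parents keep their pre-pairing tables, so the
    # pairing was based on the very records analysed; contests stay within
    # the offspring round)
    spec_off <- spec
    spec_off$parent_replicates <- 0L
    tab <- simulate_phenotypes(ped, truth, spec_off, trait = names(truths)[k],
                               seed = seeds[length(truths) + k] + 2,
                               breeding_values = bv)
    ptab <- parent_tabs[[k]]
    # contest ids are simulated per table; disambiguate the two rounds
    ptab$contest_id <- ifelse(is.na(ptab$contest_id), NA,
                              paste0("P.", ptab$contest_id))
    tab$contest_id <- ifelse(is.na(tab$contest_id), NA,
                             paste0("O.", tab$contest_id))
    rbind(ptab, tab)
  })
  phen <- do.call(rbind, tabs)
  rownames(phen) <- NULL
  class(phen) <- c("phenotype_table", "data.frame")
  list(pedigree = ped, phenotypes = phen, truths = truths, spec = spec,
       seed = seed)
}

#' Read/write long-format phenotype tables
#'
#' Tab- or comma-delimited with header `id, sex, generation, trait, replicate,
#' contest_id, value` (and optionally `value_raw`); `contest_id` is `NA` for
#' non-dyadic records.
#' @param path file path.
#' @return `read_phenotypes`: a `"phenotype_table"` data frame.
#' @export
read_phenotypes <- function(path) {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  tab <- utils::read.table(path, header = TRUE, sep = sep, na.strings = c("NA", ""),
                           stringsAsFactors = FALSE, comment.char = "")
  need <- c("id", "sex", "trait", "value")
  if (!all(need %in% names(tab))) {
    stop("phenotype file must have at least columns id, sex, trait, value")
  }
  tab$id <- as.character(tab$id)
  tab$sex <- normalize_sex(tab$sex)
  if (is.null(tab$replicate)) tab$replicate <- 1L
  if (is.null(tab$contest_id)) tab$contest_id <- NA_character_
  class(tab) <- c("phenotype_table", "data.frame")
  tab
}

#' @rdname read_phenotypes
#' @param phen a phenotype table.
#' @export
write_phenotypes <- function(phen, path) {
  utils::write.table(as.data.frame(phen), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}
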