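#' Prior specification for the animal model
#'
#' Weakly-informative conjugate priors, the conventional default for this
#' model family. The cross-sex additive genetic matrix G gets an
#' inverse-Wishart prior with scale matrix `diag(V_P / 2)` (per-sex phenotypic
#' variance halves) and belief parameter `2.002` (dimension minus one plus
#' `1.002`); each sex-diagonal variance (common environment/maternal,
#' permanent environment, contest, residual) gets a scaled-inverse-chi-square
#' prior with scale `V_P / 2` and belief `0.002`; fixed effects are
#' `N(0, 1e8)`. Scales left `NULL` are filled in from the data's phenotypic
#' variance when the model is built, so the prior is proper but carries
#' essentially no information at the data's scale.
#'
#' By default (`px = TRUE`) the additive block is sampled with parameter
#' expansion: working breeding values carry an inverse-Wishart
#' `IW(psi_V, psi_nu)` working matrix Psi and per-sex scale parameters
#' `alpha_s ~ N(0, V_P,s / 2)`, so the reported
#' `G = diag(alpha) Psi diag(alpha)`. The induced marginal prior on each
#' additive variance is a scaled-F-type distribution with positive density
#' at zero; unlike the plain inverse-Wishart (whose `exp(-Psi_ss / 2V)`
#' factor repels the sampler from variances far below the prior scale) it
#' lets additive variances collapse towards zero when the data say so, which
#' matters here because behavioural additive variances can be a tiny share
#' of phenotypic variance. Set `px = FALSE` for the plain conjugate
#' inverse-Wishart update at `G_V`, `G_nu`.
#'
#' @param G_V optional 2x2 scale matrix for G (female first).
#' @param G_nu inverse-Wishart belief (degrees of freedom) for G.
#' @param ce_V,pe_V,c_V,r_V optional scalar scales (`r_V` may be length 2,
#'   female and male).
#' @param ce_nu,pe_nu,c_nu,r_nu belief parameters of the diagonal blocks.
#' @param fixed_var prior variance of fixed effects.
#' @param px logical; parameter-expanded sampling of the additive block.
#' @param psi_V,psi_nu working-matrix prior for the expanded sampler.
#' @param alpha_var optional length-2 prior variance of the expansion scale
#'   parameters (default `V_P / 2` per sex, filled from the data).
#' @return A list of class `"prior_spec"`.
#' @export
prior_spec <- function(G_V = NULL, G_nu = 2.002,
                       ce_V = NULL, ce_nu = 0.002,
                       pe_V = NULL, pe_nu = 0.002,
                       c_V = NULL, c_nu = 0.002,
                       r_V = NULL, r_nu = 0.002,
                       fixed_var = 1e8,
                       px = TRUE, psi_V = diag(2), psi_nu = 2,
                       alpha_var = NULL) {
  structure(list(G_V = G_V, G_nu = G_nu, ce_V = ce_V, ce_nu = ce_nu,
                 pe_V = pe_V, pe_nu = pe_nu, c_V = c_V, c_nu = c_nu,
                 r_V = r_V, r_nu = r_nu, fixed_var = fixed_var,
                 px = isTRUE(px), psi_V = psi_V, psi_nu = psi_nu,
                 alpha_var = alpha_var),
            class = "prior_spec")
}

#' MCMC chain configuration
#'
#' The `"full"` profile (130,000 iterations, 30,000 burn-in, thinning 100;
#' 1,000 retained draws) is the default for reported analyses; the `"test"`
#' profile (13,000 / 3,000 / 10) retains the same number of draws from a
#' tenfold shorter chain and is intended for quick runs.
#'
#' @param profile `"full"` or `"test"`; ignored when the counts are given.
#' @param n_iterations,burn_in,thin chain controls; retained draws =
#'   `floor((n_iterations - burn_in) / thin)` and must be at least 100 for
#'   posterior summaries.
#' @param seed integer RNG seed.
#' @return A list of class `"chain_config"`.
#' @export
chain_config <- function(profile = c("full", "test"), n_iterations = NULL,
                         burn_in = NULL, thin = NULL, seed = 1) {
  profile <- match.arg(profile)
  def <- if (profile == "full") c(130000, 30000, 100) else c(13000, 3000, 10)
  n_iterations <- if (is.null(n_iterations)) def[1] else n_iterations
  burn_in <- if (is.null(burn_in)) def[2] else burn_in
  thin <- if (is.null(thin)) def[3] else thin
  stopifnot(burn_in < n_iterations, thin >= 1)
  structure(list(n_iterations = as.integer(n_iterations),
                 burn_in = as.integer(burn_in), thin = as.integer(thin),
                 seed = as.integer(seed), profile = profile),
            class = "chain_config")
}

#' Assemble the design structures of a sex-specific animal model
#'
#' Links each phenotype record to the levels of the random terms: the
#' breeding-value pair of its individual (own-sex component observed, other
#' sex latent), the family x sex common-environment/maternal level (only for
#' individuals with a known dam), the per-individual permanent-environment
#' level, and, for dyadic traits, the shared contest level. The trait's
#' transform (natural log for latency scores analysed on the log scale) is
#' applied here, and the sparse inverse relationship matrix is attached.
#'
#' @param phenotypes a phenotype table (see [read_phenotypes()]); rows for
#'   other traits are dropped.
#' @param ped a [pedigree()] containing every measured individual.
#' @param trait trait name to select from `phenotypes`.
#' @param transform `"none"` or `"log"`.
#' @param random character subset of `c("animal", "ce", "pe", "contest")`;
#'   `"contest"` requires contest ids on every record of the trait.
#' @return A list of class `"animal_model_frame"` with the design vectors,
#'   the transformed response, level counts (`n_bv` = 2 x individuals is the
#'   number of latent breeding values) and the attached `A_inv`.
#' @export
build_animal_model <- function(phenotypes, ped, trait = NULL,
                               transform = c("none", "log"),
                               random = c("animal", "ce", "pe", "contest")) {
  transform <- match.arg(transform)
  stopifnot(inherits(ped, "pedigree"))
  allowed <- c("animal", "ce", "pe", "contest")
  if (length(random) && !all(random %in% allowed)) {
    stop("unknown random term: ", paste(setdiff(random, allowed), collapse = ", "))
  }
  if (identical(sort(random), sort(allowed))) random <- allowed # default
  # an empty `random` fits means + sex-specific residuals only
  phen <- as.data.frame(phenotypes)
  if (!is.null(trait)) phen <- phen[phen$trait == trait, , drop = FALSE]
  if (nrow(phen) == 0) stop("no records for trait ", trait)
  missing_id <- setdiff(unique(phen$id), ped$id)
  if (length(missing_id)) {
    stop("phenotype records for individuals absent from pedigree: ",
         paste(utils::head(missing_id, 5), collapse = ", "))
  }
  phen$sex <- normalize_sex(phen$sex)
  idx <- match(phen$id, ped$id)
  if (any(phen$sex != ped$sex[idx])) {
    stop("record sex disagrees with pedigree sex for: ",
         paste(unique(phen$id[phen$sex != ped$sex[idx]]), collapse = ", "))
  }

  y <- phen$value
  if (transform == "log") {
    if (any(y <= 0)) stop("log transform requires positive values")
    y <- log(y)
  }

  dyadic <- "contest" %in% random && any(!is.na(phen$contest_id))
  contest_lev <- NULL
  contest_idx <- rep(-1L, nrow(phen))
  if (dyadic) {
    if (anyNA(phen$contest_id)) {
      stop("dyadic trait has records without a contest id")
    }
    tab <- table(phen$contest_id)
    if (any(tab != 2)) {
      stop("contest with != 2 members: ",
           paste(names(tab)[tab != 2], collapse = ", "))
    }
    mixed <- tapply(phen$sex, phen$contest_id, function(s) length(unique(s)) > 1)
    if (any(mixed)) {
      stop("mixed-sex contest: ", paste(names(mixed)[mixed], collapse = ", "))
    }
    contest_lev <- sort(unique(phen$contest_id))
    contest_idx <- match(phen$contest_id, contest_lev) - 1L
  }

  has_ce <- "ce" %in% random
  ce_lev <- character(0); ce_sex <- integer(0)
  ce_idx <- rep(-1L, nrow(phen))
  if (has_ce) {
    fam <- ped$dam[idx] # clutch = dam identity; founders carry no level
    key <- ifelse(is.na(fam), NA, paste0(fam, ".", phen$sex))
    ce_lev <- sort(unique(stats::na.omit(key)))
    if (length(ce_lev) == 0) {
      has_ce <- FALSE
    } else {
      ce_idx <- ifelse(is.na(key), -1L, match(key, ce_lev) - 1L)
      ce_sex <- ifelse(grepl("\\.female$", ce_lev), 0L, 1L)
    }
  }

  structure(list(
    trait = if (is.null(trait)) unique(phen$trait)[1] else trait,
    transform = transform, dyadic = dyadic,
    y = y, value_raw = if ("value_raw" %in% names(phen)) phen$value_raw else phen$value,
    sex_rec = ifelse(phen$sex == "female", 0L, 1L),
    ind = idx - 1L,
    ce_idx = as.integer(ce_idx), ce_lev = ce_lev, ce_sex = as.integer(ce_sex),
    contest_idx = as.integer(contest_idx), contest_lev = contest_lev,
    record_id = phen$id, record_sex = phen$sex,
    generation = if ("generation" %in% names(phen)) phen$generation else
      ped$generation[idx],
    has_animal = "animal" %in% random, has_ce = has_ce,
    has_pe = "pe" %in% random, has_contest = dyadic,
    n_ind = nrow(ped), n_bv = 2L * nrow(ped),
    sex_ind = ifelse(ped$sex == "female", 0L, 1L),
    ids = ped$id, A_inv = inverse_relationship(ped)),
    class = "animal_model_frame")
}

fill_priors <- function(prior, frame) {
  y <- frame$y
  vp <- sapply(0:1, function(s) {
    ys <- y[frame$sex_rec == s]
    if (length(ys) > 1) stats::var(ys) else 1
  })
  if (any(vp < 1e-10)) {
    warning("near-degenerate phenotypes (phenotypic variance ~ 0); ",
            "conditionals are barely proper and results are not meaningful")
    vp <- pmax(vp, 1e-8)
  }
  if (is.null(prior$G_V)) prior$G_V <- diag(vp / 2)
  gv <- prior$G_V
  prior$G_V <- c(gv[1, 1], gv[1, 2], gv[2, 2])
  vp_pool <- mean(vp)
  for (nm in c("ce_V", "pe_V", "c_V")) {
    if (is.null(prior[[nm]])) prior[[nm]] <- vp_pool / 2
  }
  if (is.null(prior$r_V)) prior$r_V <- vp / 2
  if (length(prior$r_V) == 1) prior$r_V <- rep(prior$r_V, 2)
  pv <- prior$psi_V
  prior$psi_V <- c(pv[1, 1], pv[1, 2], pv[2, 2])
  if (is.null(prior$alpha_var)) prior$alpha_var <- vp / 2
  if (length(prior$alpha_var) == 1) prior$alpha_var <- rep(prior$alpha_var, 2)
  prior
}

#' Fit a Bayesian sex-specific animal model by Gibbs sampling
#'
#' The central model of the package. Phenotypic variance of one trait is
#' partitioned into sex-specific additive genetic variance with a cross-sex
#' covariance (`V_A_f`, `V_A_m`, `COV_A_mf`; an unstructured 2x2 G over the
#' pedigree's additive relationship matrix), common environment/maternal
#' (`V_CE_f`, `V_CE_m`), permanent environment (`V_PE_f`, `V_PE_m`), optional
#' contest (`V_C`, dyadic traits) and residual (`V_R_f`, `V_R_m`) components,
#' with per-sex means (`mu_f`, `mu_m`) as fixed effects. Sampling is a
#' systematic-scan Gibbs sampler: Gaussian full conditionals for fixed
#' effects and all random-effect levels (breeding values are updated jointly
#' as each individual's female/male pair, the unobserved other-sex component
#' kept latent), an inverse-Wishart conditional for G driven by the
#' `A^-1`-weighted cross-products of the pairs, and scaled-inverse-chi-square
#' conditionals for every diagonal variance. Draws are deterministic given
#' `chain$seed`.
#'
#' @param phenotypes phenotype table, or an `"animal_model_frame"` from
#'   [build_animal_model()].
#' @param ped pedigree (ignored when a frame is supplied).
#' @param trait,transform,random passed to [build_animal_model()].
#' @param prior a [prior_spec()].
#' @param chain a [chain_config()].
#' @return An object of class `"animal_model"`: list with `draws` (retained
#'   draws x parameters matrix), `frame`, `prior`, `chain`, posterior-mean
#'   random effects (`bv_mean` etc.) and per-record `fitted` values.
#' @seealso [summary.animal_model()], [heritability()],
#'   [cross_sex_correlation()], [evolvability_coefficients()], [diagnose()]
#' @examples
#' sim <- simulate_study(design_spec(n_dams = 6, n_sires = 6, n_families = 4,
#'                                   daughters_per_family = 2,
#'                                   sons_per_family = 2),
#'                       truths = list(activity = trait_preset("activity")),
#'                       seed = 7)
#' fit <- animal_model(sim$phenotypes, sim$pedigree, trait = "activity",
#'                     transform = "log",
#'                     chain = chain_config("test", seed = 7))
#' fit
#' @export
animal_model <- function(phenotypes, ped = NULL, trait = NULL,
                         transform = c("none", "log"),
                         random = c("animal", "ce", "pe", "contest"),
                         prior = prior_spec(), chain = chain_config()) {
  frame <- if (inherits(phenotypes, "animal_model_frame")) phenotypes else
    build_animal_model(phenotypes, ped, trait, transform, random)
  stopifnot(inherits(prior, "prior_spec"), inherits(chain, "chain_config"))
  n_keep <- (chain$n_iterations - chain$burn_in) %/% chain$thin
  if (n_keep < 100) {
    stop("chain would retain ", n_keep, " draws; at least 100 are needed")
  }
  prior_filled <- fill_priors(prior, frame)

  Ainv <- methods::as(methods::as(frame$A_inv, "generalMatrix"), "RsparseMatrix")
  set.seed(chain$seed)
  res <- .gibbs_animal(frame$y, frame$sex_rec, frame$ind, frame$ce_idx,
                       frame$contest_idx, frame$n_ind, frame$sex_ind,
                       Ainv@p, Ainv@j, Ainv@x,
                       length(frame$ce_lev), frame$ce_sex,
                       length(frame$contest_lev),
                       frame$has_animal, frame$has_ce, frame$has_pe,
                       frame$has_contest, prior_filled$px,
                       prior_filled[c("G_V", "G_nu", "ce_V", "ce_nu", "pe_V",
                                      "pe_nu", "c_V", "c_nu", "r_V", "r_nu",
                                      "fixed_var", "psi_V", "psi_nu",
                                      "alpha_var")],
                       chain$n_iterations, chain$burn_in, chain$thin)

  draws <- res$draws
  colnames(draws) <- c("mu_f", "mu_m", "V_A_f", "V_A_m", "COV_A_mf",
                       "V_CE_f", "V_CE_m", "V_PE_f", "V_PE_m",
                       "V_R_f", "V_R_m", "V_C")
  keep_cols <- c("mu_f", "mu_m",
                 if (frame$has_animal) c("V_A_f", "V_A_m", "COV_A_mf"),
                 if (frame$has_ce) c("V_CE_f", "V_CE_m"),
                 if (frame$has_pe) c("V_PE_f", "V_PE_m"),
                 "V_R_f", "V_R_m",
                 if (frame$has_contest) "V_C")
  draws <- draws[, keep_cols, drop = FALSE]

  bv <- res$bv_mean
  dimnames(bv) <- list(frame$ids, c("f", "m"))
  out <- list(draws = draws, frame = frame, prior = prior, chain = chain,
              bv_mean = bv,
              ce_mean = if (frame$has_ce)
                stats::setNames(as.numeric(res$ce_mean), frame$ce_lev),
              pe_mean = stats::setNames(as.numeric(res$pe_mean), frame$ids),
              contest_mean = if (frame$has_contest)
                stats::setNames(as.numeric(res$contest_mean), frame$contest_lev),
              fitted = as.numeric(res$fitted),
              n_retained = res$n_retained)
  class(out) <- "animal_model"
  out
}

#' @method print animal_model
#' @export
print.animal_model <- function(x, ...) {
  cat("Sex-specific animal model fit: trait '", x$frame$trait, "'",
      if (x$frame$transform == "log") " (log scale)", "\n", sep = "")
  cat(" ", length(x$frame$y), "records,", x$frame$n_ind, "individuals,",
      x$n_retained, "retained draws\n")
  cat("  posterior means:\n")
  print(round(colMeans(x$draws), 4))
  invisible(x)
}

#' Posterior summary of an animal model fit
#'
#' Posterior mean and 95% interval for every parameter, the sex-specific
#' heritabilities, and the female-minus-male contrasts of each sex-specific
#' component (with pMCMC).
#'
#' @param object an `"animal_model"` fit.
#' @param interval `"hpd"` (default) or `"quantile"`.
#' @param prob interval mass.
#' @param ... unused.
#' @return A list of class `"summary.animal_model"` with data frames
#'   `parameters` and `contrasts`.
#' @method summary animal_model
#' @export
summary.animal_model <- function(object, interval = c("hpd", "quantile"),
                                 prob = 0.95, ...) {
  interval <- match.arg(interval)
  draws <- object$draws
  h2f <- heritability(object, "female")
  h2m <- heritability(object, "male")
  all_draws <- cbind(draws, h2_f = h2f, h2_m = h2m)
  pars <- do.call(rbind, lapply(colnames(all_draws), function(p) {
    summarize_draws(all_draws[, p], interval = interval, prob = prob,
                    name = p)
  }))
  comp <- c("V_A", "V_CE", "V_PE", "V_R", "h2")
  contrasts <- do.call(rbind, lapply(comp, function(q) {
    f <- paste0(q, "_f"); m <- paste0(q, "_m")
    if (!all(c(f, m) %in% colnames(all_draws))) return(NULL)
    sex_contrast(all_draws[, f], all_draws[, m], interval = interval,
                 prob = prob, name = paste0(q, "_f_minus_m"))$summary
  }))
  out <- list(trait = object$frame$trait, parameters = pars,
              contrasts = contrasts, n_draws = nrow(draws),
              interval = interval)
  class(out) <- "summary.animal_model"
  out
}

#' @method print summary.animal_model
#' @export
print.summary.animal_model <- function(x, ...) {
  cat("Trait '", x$trait, "': ", x$n_draws, " retained draws, 95% ",
      x$interval, " intervals\n\nParameters:\n", sep = "")
  print(format_summary_table(x$parameters), row.names = FALSE)
  cat("\nFemale minus male contrasts:\n")
  print(format_summary_table(x$contrasts), row.names = FALSE)
  invisible(x)
}

#' @export
coef.animal_model <- function(object, ...) {
  colMeans(object$draws[, c("mu_f", "mu_m"), drop = FALSE])
}

#' Fitted values and residuals on the analysis scale
#'
#' Fitted values are posterior means of each record's linear predictor
#' (fixed effects plus all random-effect levels); residuals are observed
#' (transformed) values minus fitted.
#' @param object an `"animal_model"` fit.
#' @param ... unused.
#' @export
fitted.animal_model <- function(object, ...) object$fitted

#' @rdname fitted.animal_model
#' @export
residuals.animal_model <- function(object, ...) object$frame$y - object$fitted

#' Predicted genetic merit or record means
#'
#' With `type = "breeding_value"` (default) returns the posterior-mean
#' breeding-value pair (female- and male-expression components) of every
#' pedigree member, including the latent other-sex component; with
#' `type = "record"` returns the per-record fitted values.
#' @param object an `"animal_model"` fit.
#' @param type see above.
#' @param ... unused.
#' @export
predict.animal_model <- function(object, type = c("breeding_value", "record"),
                                 ...) {
  type <- match.arg(type)
  if (type == "breeding_value") object$bv_mean else object$fitted
}

#' Trace and density plots of retained draws
#' @param x an `"animal_model"` fit.
#' @param pars parameter names (default: variance components).
#' @param ... unused.
#' @export
plot.animal_model <- function(x, pars = NULL, ...) {
  if (is.null(pars)) {
    pars <- setdiff(colnames(x$draws), c("mu_f", "mu_m"))
  }
  pars <- intersect(pars, colnames(x$draws))
  old <- graphics::par(mfrow = c(length(pars), 2), mar = c(2.5, 4, 1, 1))
  on.exit(graphics::par(old))
  for (p in pars) {
    v <- x$draws[, p]
    graphics::plot(v, type = "l", ylab = p, xlab = "")
    graphics::plot(stats::density(v), main = "", xlab = "")
  }
  invisible(x)
}

#' Posterior-predictive simulation of phenotype records
#'
#' For each simulation, one retained draw of the variance components and
#' means is picked at random and a fresh data set with the fit's design
#' (same individuals, replicates and contest structure sizes) is generated
#' from the model at those parameter values.
#'
#' @param object an `"animal_model"` fit.
#' @param nsim number of simulated record vectors.
#' @param seed optional seed.
#' @param ... unused.
#' @return A matrix (records x nsim) of simulated analysis-scale values.
#' @export
simulate.animal_model <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  fr <- object$frame
  n <- length(fr$y)
  A <- solve(as.matrix(fr$A_inv))
  out <- matrix(NA_real_, n, nsim)
  for (k in seq_len(nsim)) {
    d <- object$draws[sample.int(nrow(object$draws), 1), ]
    gv <- function(p) if (p %in% names(d)) d[[p]] else 0
    G <- matrix(c(gv("V_A_f"), gv("COV_A_mf"), gv("COV_A_mf"), gv("V_A_m")), 2)
    a <- if (fr$has_animal) draw_breeding_values(A, G) else
      matrix(0, fr$n_ind, 2)
    ce <- if (fr$has_ce)
      stats::rnorm(length(fr$ce_lev), 0,
                   sqrt(ifelse(fr$ce_sex == 0, gv("V_CE_f"), gv("V_CE_m"))))
    pe <- stats::rnorm(fr$n_ind, 0,
                       sqrt(ifelse(fr$sex_ind == 0, gv("V_PE_f"), gv("V_PE_m"))))
    if (!fr$has_pe) pe[] <- 0
    cc <- if (fr$has_contest)
      stats::rnorm(length(fr$contest_lev), 0, sqrt(gv("V_C")))
    mu <- c(d[["mu_f"]], d[["mu_m"]])
    s <- fr$sex_rec + 1L
    yk <- mu[s] + a[cbind(fr$ind + 1L, s)] + pe[fr$ind + 1L] +
      stats::rnorm(n, 0, sqrt(ifelse(s == 1, gv("V_R_f"), gv("V_R_m"))))
    if (fr$has_ce) yk <- yk + ifelse(fr$ce_idx >= 0, ce[fr$ce_idx + 1L], 0)
    if (fr$has_contest) yk <- yk + cc[fr$contest_idx + 1L]
    out[, k] <- yk
  }
  out
}
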