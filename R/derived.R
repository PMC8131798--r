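draws_of <- function(x) {
  if (inherits(x, "animal_model")) x$draws else as.matrix(x)
}

#' Per-draw narrow-sense heritability
#'
#' `h2 = V_A / (V_A + V_CE/M + V_PE + V_R)` for the requested sex, computed
#' draw by draw (never as a ratio of posterior means). For dyadic traits the
#' contest variance joins the denominator:
#' `h2 = V_A / (V_A + V_CE/M + V_PE + V_R + V_C)`. Components absent from the
#' fitted model contribute zero. Draws with an all-zero denominator are
#' returned as `NA` with their count in the `"n_undefined"` attribute.
#'
#' @param draws an `"animal_model"` fit or a draws matrix with the package's
#'   column names.
#' @param sex `"female"` or `"male"`.
#' @param dyadic include `V_C` in the denominator; defaults to its presence
#'   in the draws.
#' @return Numeric vector of per-draw heritabilities in `[0, 1]`.
#' @export
heritability <- function(draws, sex = c("female", "male"),
                         dyadic = NULL) {
  sex <- match.arg(sex)
  d <- draws_of(draws)
  s <- if (sex == "female") "f" else "m"
  if (is.null(dyadic)) dyadic <- "V_C" %in% colnames(d)
  if (dyadic && !"V_C" %in% colnames(d)) {
    stop("dyadic heritability requested but draws contain no V_C")
  }
  col <- function(p) if (p %in% colnames(d)) d[, p] else 0
  va <- col(paste0("V_A_", s))
  denom <- va + col(paste0("V_CE_", s)) + col(paste0("V_PE_", s)) +
    col(paste0("V_R_", s)) + if (dyadic) d[, "V_C"] else 0
  h2 <- ifelse(denom > 0, va / denom, NA_real_)
  attr(h2, "n_undefined") <- sum(denom <= 0)
  h2
}

#' Per-draw cross-sex genetic correlation with refusal rule
#'
#' `r_mf = COV_Amf / sqrt(V_Af * V_Am)` per draw. When the additive genetic
#' variance of one or both sexes tends to zero the correlation is not
#' estimable; draws with `V_Af * V_Am` below `floor` are flagged undefined
#' (`NA`), and the summary withholds a point estimate when the defined
#' fraction falls below `min_defined`. The default absolute floor (1e-12 in
#' trait-scale units^4) only catches numerically degenerate draws; pipelines
#' use a relative floor via [cross_sex_summary()].
#'
#' @param draws fit or draws matrix (needs `V_A_f`, `V_A_m`, `COV_A_mf`).
#' @param floor undefined-draw threshold on `V_Af * V_Am`.
#' @param min_defined minimum defined fraction for a reported summary.
#' @return List: `r_mf` (per-draw, `NA` where undefined), `defined_fraction`,
#'   `withheld` (logical).
#' @export
cross_sex_correlation <- function(draws, floor = 1e-12, min_defined = 0.5) {
  d <- draws_of(draws)
  need <- c("V_A_f", "V_A_m", "COV_A_mf")
  if (!all(need %in% colnames(d))) {
    stop("draws lack the cross-sex additive components")
  }
  prod_va <- d[, "V_A_f"] * d[, "V_A_m"]
  r <- ifelse(prod_va >= floor, d[, "COV_A_mf"] / sqrt(prod_va), NA_real_)
  frac <- mean(!is.na(r))
  list(r_mf = r, defined_fraction = frac, withheld = frac < min_defined)
}

#' Cross-sex genetic correlation summary with a relative refusal floor
#'
#' The operational version of the refusal rule used by [run_study()]: a draw
#' counts as defined only when each sex's `V_A` draw exceeds `rel_floor`
#' times that sex's phenotypic variance (estimated from the fit's data), so
#' fits whose additive variances concentrate near zero withhold the estimate
#' and report the defined-draw fraction instead. The default floor, 5% of
#' phenotypic variance, operationalizes "additive variance close to zero"
#' at the conventional negligible-heritability scale.
#'
#' @param fit an `"animal_model"` fit.
#' @param rel_floor per-sex relative threshold on `V_A / V_P`.
#' @param interval,prob summary interval settings.
#' @return List with `summary` (a one-row summary data frame, or `NULL` when
#'   withheld), `defined_fraction`, `withheld`.
#' @export
cross_sex_summary <- function(fit, rel_floor = 0.05,
                              interval = c("hpd", "quantile"), prob = 0.95) {
  stopifnot(inherits(fit, "animal_model"))
  interval <- match.arg(interval)
  vp <- sapply(0:1, function(s) stats::var(fit$frame$y[fit$frame$sex_rec == s]))
  vp[is.na(vp)] <- Inf
  d <- fit$draws
  ok <- d[, "V_A_f"] > rel_floor * vp[1] & d[, "V_A_m"] > rel_floor * vp[2]
  r <- ifelse(ok, d[, "COV_A_mf"] / sqrt(d[, "V_A_f"] * d[, "V_A_m"]), NA_real_)
  frac <- mean(ok)
  withheld <- frac < 0.5
  list(summary = if (!withheld)
         summarize_draws(r[ok], interval = interval, prob = prob, name = "r_mf"),
       defined_fraction = frac, withheld = withheld)
}

#' Per-draw mean-standardized evolvability coefficients
#'
#' Computes, per draw and sex, `CV_A = sqrt(V_A)/mean` and its square
#' `I_A = V_A/mean^2`, plus `CV_CE/M = sqrt(V_CE/M)/mean`,
#' `CV_PE = sqrt(V_PE)/mean` and `CV_R = sqrt(V_R)/mean`. Means must be
#' phenotypic means of the untransformed (raw) data pooled across the
#' parental and offspring generations, and sex-specific by default (the
#' female mean standardizes female components).
#'
#' @param draws fit or draws matrix of raw-scale variance components.
#' @param mean_f,mean_m raw-scale phenotypic means; must be non-zero, and a
#'   negative mean is rejected (the coefficients are meaningless there).
#' @return A list with per-draw matrices `female` and `male`, columns
#'   `CV_A`, `I_A`, `CV_CE`, `CV_PE`, `CV_R`.
#' @export
evolvability_coefficients <- function(draws, mean_f, mean_m) {
  d <- draws_of(draws)
  if (!is.finite(mean_f) || !is.finite(mean_m) || mean_f <= 0 || mean_m <= 0) {
    stop("evolvability coefficients need positive phenotypic means")
  }
  one_sex <- function(s, m) {
    col <- function(p) if (p %in% colnames(d)) d[, p] else 0
    cbind(CV_A = sqrt(col(paste0("V_A_", s))) / m,
          I_A = col(paste0("V_A_", s)) / m^2,
          CV_CE = sqrt(col(paste0("V_CE_", s))) / m,
          CV_PE = sqrt(col(paste0("V_PE_", s))) / m,
          CV_R = sqrt(col(paste0("V_R_", s))) / m)
  }
  list(female = one_sex("f", mean_f), male = one_sex("m", mean_m))
}

#' Female-minus-male posterior contrast
#'
#' Per-draw difference of two aligned draw vectors and its posterior summary.
#' By linearity the summary mean equals `mean(female) - mean(male)` exactly.
#' `pMCMC` is the two-tailed sign fraction `2 * min(P(d > 0), P(d < 0))`,
#' floored at `1/n` and capped at 1 (a contrast that is identically zero has
#' `pMCMC = 1`).
#'
#' @param female_draws,male_draws equal-length aligned per-draw vectors.
#' @param interval,prob summary interval settings.
#' @param name quantity label for the summary row.
#' @return List with `draws` (per-draw contrast) and `summary` (one-row data
#'   frame with mean, interval and pMCMC).
#' @export
sex_contrast <- function(female_draws, male_draws,
                         interval = c("hpd", "quantile"), prob = 0.95,
                         name = "contrast") {
  if (length(female_draws) != length(male_draws)) {
    stop("female and male draw vectors differ in length")
  }
  interval <- match.arg(interval)
  d <- female_draws - male_draws
  s <- summarize_draws(d, interval = interval, prob = prob, name = name,
                       contrast = TRUE)
  list(draws = d, summary = s)
}

# empirical highest-posterior-density interval: shortest window containing
# ceil(prob * n) order statistics
hpd_interval <- function(x, prob = 0.95) {
  x <- sort(x)
  n <- length(x)
  m <- ceiling(prob * n)
  if (m >= n) return(c(x[1], x[n]))
  w <- x[(m):n] - x[seq_len(n - m + 1)]
  i <- which.min(w)
  c(x[i], x[i + m - 1])
}

#' Posterior summary of a draw vector
#'
#' Posterior mean with a 95% (by default) interval, highest-posterior-density
#' by default or equal-tailed quantile on request, and pMCMC when the
#' quantity is a contrast. At least 100 draws are required; if more than half
#' of the draws are undefined (`NA`) the summary is withheld.
#'
#' @param x per-draw numeric vector (`NA` = undefined draw).
#' @param interval `"hpd"` or `"quantile"`.
#' @param prob interval mass.
#' @param name quantity label.
#' @param contrast logical; add a pMCMC column.
#' @return One-row data frame: `quantity`, `mean`, `lower`, `upper`,
#'   `n_draws`, `n_undefined` and optionally `pMCMC`.
#' @export
summarize_draws <- function(x, interval = c("hpd", "quantile"), prob = 0.95,
                            name = "quantity", contrast = FALSE) {
  interval <- match.arg(interval)
  n_all <- length(x)
  if (n_all < 100) stop("at least 100 draws are required for a summary")
  n_und <- sum(is.na(x))
  if (n_und > n_all / 2) {
    stop("more than half of the draws are undefined; summary withheld")
  }
  x <- x[!is.na(x)]
  ci <- if (interval == "hpd") hpd_interval(x, prob) else
    unname(stats::quantile(x, c((1 - prob) / 2, 1 - (1 - prob) / 2)))
  out <- data.frame(quantity = name, mean = mean(x), lower = ci[1],
                    upper = ci[2], n_draws = n_all, n_undefined = n_und,
                    stringsAsFactors = FALSE)
  if (contrast) {
    p <- 2 * min(mean(x >= 0), mean(x <= 0))
    out$pMCMC <- min(max(p, 1 / length(x)), 1)
  }
  out
}

# Table-style formatting: 3 decimals, tiny positive values printed "<0.001"
format_estimate <- function(x) {
  ifelse(is.na(x), "NA",
         ifelse(x > 0 & x < 0.001, "<0.001", sprintf("%.3f", x)))
}

format_summary_table <- function(tab) {
  if (is.null(tab)) return(NULL)
  out <- data.frame(quantity = tab$quantity,
                    estimate = paste0(format_estimate(tab$mean), " [",
                                      format_estimate(tab$lower), ", ",
                                      format_estimate(tab$upper), "]"),
                    stringsAsFactors = FALSE)
  if (!is.null(tab$pMCMC)) {
    out$pMCMC <- ifelse(tab$pMCMC < 0.001, "<0.001", sprintf("%.3f", tab$pMCMC))
  }
  out
}
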