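# Spectral density at zero of a chain segment, from a low-order
# autoregressive approximation chosen by AIC: S(0) = var_pred / (1 - sum(phi))^2.
spectrum0_ar <- function(x, max_order = NULL) {
  x <- as.numeric(x)
  if (stats::var(x) == 0) return(0)
  if (is.null(max_order)) {
    max_order <- min(length(x) - 1L, floor(10 * log10(length(x))))
  }
  fit <- stats::ar(x, aic = TRUE, order.max = max_order, method = "yule-walker")
  if (fit$order == 0) return(fit$var.pred)
  fit$var.pred / (1 - sum(fit$ar))^2
}

# Asymptotic CDF of the Cramer-von Mises statistic (Anderson-Darling series
# with Bessel-K terms), used for the stationarity p-value.
pcramer <- function(q, eps = 1e-5) {
  q <- pmax(q, 1e-10)
  total <- rep(0, length(q))
  for (k in 0:3) {
    z <- gamma(k + 0.5) * sqrt(4 * k + 1) / (gamma(k + 1) * pi^1.5 * sqrt(q))
    u <- (4 * k + 1)^2 / (16 * q)
    term <- ifelse(u > -log(eps), 0, z * exp(-u) * besselK(u, 0.25))
    total <- total + term
  }
  pmin(pmax(total, 0), 1)
}

#' Heidelberger-Welch convergence diagnostic
#'
#' Stationarity: starting from the full retained chain, leading 10%
#' increments are dropped (up to 50%) until the Cramer-von Mises statistic of
#' the Brownian-bridge functional of the standardized cumulative sums,
#' `I = sum_t B_t^2 / (n^2 S(0))` with `B_t = cumsum(x)_t - t * mean(x)` and
#' `S(0)` the spectral density at zero estimated from the second half of the
#' chain, is non-significant at `alpha`. Halfwidth: on the retained segment,
#' the test passes iff `z_{1-alpha/2} * sqrt(S(0)/n_kept) / |mean|` is at
#' most `eps`. A constant chain passes trivially and is flagged. The decision
#' is invariant to affine rescaling of the chain.
#'
#' @param chain numeric vector of retained draws (length >= 100).
#' @param alpha significance level for both tests.
#' @param eps target relative halfwidth accuracy.
#' @return A one-row data frame: `stationarity_passed`, `start_iteration`
#'   (first kept index), `cvm_statistic`, `cvm_p`, `halfwidth_passed`,
#'   `mean`, `halfwidth`, `relative_halfwidth`, `flag_constant`.
#' @export
heidelberger_welch <- function(chain, alpha = 0.05, eps = 0.1) {
  chain <- as.numeric(chain)
  n1 <- length(chain)
  if (n1 < 100) stop("chain too short for Heidelberger-Welch (need >= 100)")
  if (stats::var(chain) == 0) {
    return(data.frame(stationarity_passed = TRUE, start_iteration = 1,
                      cvm_statistic = 0, cvm_p = 1, halfwidth_passed = TRUE,
                      mean = chain[1], halfwidth = 0,
                      relative_halfwidth = 0, flag_constant = TRUE))
  }
  S0 <- spectrum0_ar(chain[floor(n1 / 2):n1])
  passed <- FALSE; start <- 1L; I <- NA_real_; pval <- NA_real_
  for (frac in seq(0, 0.5, by = 0.1)) {
    start <- floor(frac * n1) + 1L
    xs <- chain[start:n1]
    n <- length(xs)
    B <- cumsum(xs) - mean(xs) * seq_len(n)
    I <- sum(B^2) / (n^2 * S0)
    pval <- 1 - pcramer(I)
    if (!is.na(I) && pval > alpha) { passed <- TRUE; break }
  }
  xs <- chain[start:n1]
  n <- length(xs)
  S0k <- spectrum0_ar(xs)
  hw <- stats::qnorm(1 - alpha / 2) * sqrt(S0k / n)
  m <- mean(xs)
  rel <- abs(hw / m)
  data.frame(stationarity_passed = passed, start_iteration = start,
             cvm_statistic = I, cvm_p = pval,
             halfwidth_passed = passed && is.finite(rel) && rel <= eps,
             mean = m, halfwidth = hw, relative_halfwidth = rel,
             flag_constant = FALSE)
}

#' Chain autocorrelation
#'
#' Autocorrelation at lags `0..max_lag` with the standard biased
#' autocovariance normalization (lag 0 is exactly 1).
#' @param chain numeric vector.
#' @param max_lag largest lag (must be below `length(chain)/2`).
#' @return Named numeric vector, names `lag0..`.
#' @export
autocorrelation <- function(chain, max_lag = min(50, length(chain) %/% 2 - 1)) {
  if (max_lag >= length(chain) / 2) stop("max_lag must be < length/2")
  ac <- stats::acf(chain, lag.max = max_lag, plot = FALSE,
                   demean = TRUE)$acf[, 1, 1]
  stats::setNames(ac, paste0("lag", 0:max_lag))
}

#' Effective sample size (initial monotone sequence estimator)
#'
#' `ESS = n / (1 + 2 * sum(rho_k))` where the sum runs over the initial
#' sequence of lags whose adjacent-pair autocorrelation sums remain positive
#' and monotonically non-increasing (Geyer's initial monotone sequence). A
#' constant chain is reported as `ESS = 0` with a flag attribute.
#'
#' @param chain numeric vector of length >= 100.
#' @return Effective sample size (numeric; attribute `"flag"` set to
#'   `"constant chain"` when degenerate).
#' @export
effective_sample_size <- function(chain) {
  n <- length(chain)
  if (n < 100) stop("chain too short (need >= 100)")
  if (stats::var(chain) == 0) {
    return(structure(0, flag = "constant chain"))
  }
  max_lag <- min(n %/% 2L - 1L, 2000L)
  rho <- autocorrelation(chain, max_lag)[-1]
  npair <- length(rho) %/% 2
  tau <- 1
  prev <- Inf
  for (m in seq_len(npair)) {
    g <- rho[2 * m - 1] + rho[2 * m]
    if (g <= 0) break
    g <- min(g, prev)
    tau <- tau + 2 * g
    prev <- g
  }
  min(n, n / tau)
}

#' Convergence report for a fitted animal model
#'
#' Applies the Heidelberger-Welch stationarity and halfwidth tests, lag-1 and
#' lag-10 autocorrelation and the effective sample size to every retained
#' parameter chain of a fit.
#'
#' @param fit an `"animal_model"` fit (or a draws matrix).
#' @param alpha,eps passed to [heidelberger_welch()].
#' @return A data frame of class `"diagnostic_report"`, one row per
#'   parameter.
#' @export
diagnose <- function(fit, alpha = 0.05, eps = 0.1) {
  d <- draws_of(fit)
  rows <- lapply(colnames(d), function(p) {
    hw <- heidelberger_welch(d[, p], alpha = alpha, eps = eps)
    ac <- autocorrelation(d[, p], max_lag = min(10, nrow(d) %/% 2 - 1))
    cbind(data.frame(parameter = p, stringsAsFactors = FALSE), hw,
          data.frame(acf_lag1 = unname(ac["lag1"]),
                     acf_lag10 = unname(ac[length(ac)]),
                     ess = as.numeric(effective_sample_size(d[, p]))))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("diagnostic_report", "data.frame")
  out
}

#' @method print diagnostic_report
#' @export
print.diagnostic_report <- function(x, ...) {
  cat("MCMC diagnostics (", nrow(x), " parameters):\n", sep = "")
  show <- data.frame(parameter = x$parameter,
                     stationarity = ifelse(x$stationarity_passed, "passed", "FAILED"),
                     halfwidth = ifelse(x$halfwidth_passed, "passed", "FAILED"),
                     rel_halfwidth = sprintf("%.3f", x$relative_halfwidth),
                     acf_lag1 = sprintf("%.3f", x$acf_lag1),
                     ess = round(x$ess))
  print(show, row.names = FALSE)
  invisible(x)
}
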