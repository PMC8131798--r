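default_trait_specs <- function() {
  list(aggression = list(transform = "none", dyadic = TRUE),
       activity = list(transform = "log", dyadic = FALSE),
       exploration = list(transform = "log", dyadic = FALSE),
       boldness = list(transform = "none", dyadic = FALSE))
}

#' Run the full sex-specific quantitative-genetic study
#'
#' Orchestrates the whole analysis for a set of traits: builds and fits the
#' sex-specific animal model per trait (log scale for latency traits flagged
#' so, contest random effect for dyadic traits), computes variance-component
#' and heritability summaries with female-minus-male contrasts (the
#' "component table"), mean-standardized evolvability coefficients on the raw
#' scale with their contrasts (the "evolvability table"; traits analysed on
#' the log scale are refitted untransformed for this, since mean-standardized
#' coefficients only make sense for raw-scale variances), the cross-sex
#' genetic correlation summary with the defined-fraction refusal rule, and
#' Heidelberger-Welch/autocorrelation/ESS diagnostics. A failing trait is
#' reported and the remaining traits still run.
#'
#' @param phenotypes phenotype table or path readable by [read_phenotypes()].
#' @param pedigree a [pedigree()] or path readable by [read_pedigree()].
#' @param traits named list of per-trait settings (`transform`, `dyadic`);
#'   default covers aggression/activity/exploration/boldness. Traits absent
#'   from the data are skipped.
#' @param prior a [prior_spec()].
#' @param chain a [chain_config()]; per-trait seeds are derived from
#'   `chain$seed`.
#' @param interval `"hpd"` or `"quantile"`.
#' @param out_dir optional directory: draws, summary tables (raw and
#'   3-decimal formatted with `<0.001` substitution), diagnostics and a YAML
#'   run manifest are written there.
#' @return A list of class `"qg_study"`: per-trait list with `fit`,
#'   `component_table`, `evolvability_table`, `r_mf`, `diagnostics`,
#'   `status`; plus `manifest`.
#' @export
run_study <- function(phenotypes, pedigree, traits = NULL,
                      prior = prior_spec(), chain = chain_config(),
                      interval = c("hpd", "quantile"), out_dir = NULL) {
  interval <- match.arg(interval)
  if (is.character(phenotypes)) phenotypes <- read_phenotypes(phenotypes)
  if (is.character(pedigree)) pedigree <- read_pedigree(pedigree)
  if (is.null(traits)) {
    traits <- default_trait_specs()
    traits <- traits[names(traits) %in% unique(phenotypes$trait)]
  }
  if (length(traits) == 0) stop("no requested trait present in the data")

  results <- list()
  for (k in seq_along(traits)) {
    tname <- names(traits)[k]
    tspec <- traits[[k]]
    tchain <- chain
    tchain$seed <- chain$seed + 1000L * k
    res <- tryCatch(
      run_one_trait(phenotypes, pedigree, tname, tspec, prior, tchain,
                    interval),
      error = function(e) list(status = conditionMessage(e)))
    if (is.null(res$status)) res$status <- "ok"
    results[[tname]] <- res
  }

  manifest <- list(
    package = "sexqg",
    version = as.character(utils::packageVersion("sexqg")),
    date = format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
    seed = chain$seed, profile = chain$profile,
    chain = list(n_iterations = chain$n_iterations, burn_in = chain$burn_in,
                 thin = chain$thin),
    interval = interval,
    traits = lapply(results, function(r) r$status))
  out <- list(traits = results, manifest = manifest)
  class(out) <- "qg_study"
  if (!is.null(out_dir)) write_study(out, out_dir)
  failed <- vapply(results, function(r) !identical(r$status, "ok"), logical(1))
  if (any(failed)) {
    warning("traits failed: ", paste(names(results)[failed], collapse = ", "))
  }
  out
}

run_one_trait <- function(phenotypes, ped, tname, tspec, prior, chain,
                          interval) {
  transform <- if (isTRUE(tspec$transform == "log")) "log" else "none"
  random <- c("animal", "ce", "pe", if (isTRUE(tspec$dyadic)) "contest")
  fit <- animal_model(phenotypes, ped, trait = tname, transform = transform,
                      random = random, prior = prior, chain = chain)
  smy <- summary(fit, interval = interval)
  component_table <- component_rows(fit, interval)

  # evolvability coefficients live on the raw scale: refit untransformed
  # when the component model used a log scale
  raw_fit <- fit
  if (transform == "log") {
    rchain <- chain
    rchain$seed <- chain$seed + 1L
    raw_fit <- animal_model(phenotypes, ped, trait = tname,
                            transform = "none", random = random,
                            prior = prior, chain = rchain)
  }
  phen <- as.data.frame(phenotypes)
  phen <- phen[phen$trait == tname, ]
  raw_col <- if ("value_raw" %in% names(phen)) phen$value_raw else phen$value
  mean_f <- mean(raw_col[phen$sex == "female"])
  mean_m <- mean(raw_col[phen$sex == "male"])
  evolvability_table <- evolvability_rows(raw_fit, mean_f, mean_m, interval)

  list(fit = fit, raw_fit = if (transform == "log") raw_fit,
       component_table = component_table,
       evolvability_table = evolvability_table,
       r_mf = cross_sex_summary(fit, interval = interval),
       diagnostics = diagnose(fit),
       phenotypic_means = c(female = mean_f, male = mean_m),
       summary = smy)
}

# by-sex rows plus the female-minus-male contrast row for each component
component_rows <- function(fit, interval) {
  h2f <- heritability(fit, "female")
  h2m <- heritability(fit, "male")
  d <- cbind(fit$draws, h2_f = h2f, h2_m = h2m)
  quantities <- c("V_A", "V_CE", "V_PE", "V_R", "h2")
  build_sex_rows(d, quantities, interval,
                 extra = fit$draws[, "COV_A_mf", drop = TRUE])
}

evolvability_rows <- function(fit, mean_f, mean_m, interval) {
  ev <- evolvability_coefficients(fit, mean_f, mean_m)
  d <- cbind(`colnames<-`(ev$female, paste0(colnames(ev$female), "_f")),
             `colnames<-`(ev$male, paste0(colnames(ev$male), "_m")))
  build_sex_rows(d, c("CV_A", "CV_CE", "CV_PE", "CV_R", "I_A"), interval)
}

build_sex_rows <- function(d, quantities, interval, extra = NULL) {
  rows <- list()
  for (q in quantities) {
    f <- paste0(q, "_f"); m <- paste0(q, "_m")
    if (!all(c(f, m) %in% colnames(d))) next
    rf <- summarize_draws(d[, f], interval = interval, name = q)
    rf$sex <- "female"
    rm_ <- summarize_draws(d[, m], interval = interval, name = q)
    rm_$sex <- "male"
    ct <- sex_contrast(d[, f], d[, m], interval = interval, name = q)$summary
    ct$sex <- "f_minus_m"
    rf$pMCMC <- NA_real_; rm_$pMCMC <- NA_real_
    rows <- c(rows, list(rf, rm_, ct))
  }
  if (!is.null(extra)) {
    cv <- summarize_draws(extra, interval = interval, name = "COV_A_mf")
    cv$sex <- "both"; cv$pMCMC <- NA_real_
    rows <- c(rows, list(cv))
  }
  out <- do.call(rbind, rows)
  out[, c("quantity", "sex", "mean", "lower", "upper", "pMCMC",
          "n_draws", "n_undefined")]
}

#' @method print qg_study
#' @export
print.qg_study <- function(x, ...) {
  cat("Quantitative-genetic study:", length(x$traits), "trait(s), profile '",
      x$manifest$profile, "', seed ", x$manifest$seed, "\n", sep = "")
  for (tname in names(x$traits)) {
    r <- x$traits[[tname]]
    cat("\n==", tname, "(", r$status, ")\n")
    if (!identical(r$status, "ok")) next
    print(format_component_table(r$component_table), row.names = FALSE)
    if (r$r_mf$withheld) {
      cat(sprintf("r_mf withheld: only %.1f%% of draws defined\n",
                  100 * r$r_mf$defined_fraction))
    } else {
      cat(sprintf("r_mf = %.3f [%.3f, %.3f]\n", r$r_mf$summary$mean,
                  r$r_mf$summary$lower, r$r_mf$summary$upper))
    }
  }
  invisible(x)
}

format_component_table <- function(tab) {
  data.frame(quantity = tab$quantity, sex = tab$sex,
             estimate = paste0(format_estimate(tab$mean), " [",
                               format_estimate(tab$lower), ", ",
                               format_estimate(tab$upper), "]"),
             pMCMC = ifelse(is.na(tab$pMCMC), "",
                            ifelse(tab$pMCMC < 0.001, "<0.001",
                                   sprintf("%.3f", tab$pMCMC))),
             stringsAsFactors = FALSE)
}

write_study <- function(study, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (tname in names(study$traits)) {
    r <- study$traits[[tname]]
    if (!identical(r$status, "ok")) next
    base <- file.path(out_dir, tname)
    utils::write.csv(as.data.frame(r$fit$draws),
                     paste0(base, "_draws.csv"), row.names = FALSE)
    utils::write.table(r$component_table, paste0(base, "_components.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(format_component_table(r$component_table),
                       paste0(base, "_components_formatted.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(r$evolvability_table, paste0(base, "_evolvability.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(format_component_table(r$evolvability_table),
                       paste0(base, "_evolvability_formatted.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(as.data.frame(r$diagnostics),
                       paste0(base, "_diagnostics.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  yaml::write_yaml(study$manifest, file.path(out_dir, "manifest.yaml"))
  invisible(out_dir)
}

#' Simulate a study and write its input files
#'
#' One-command wrapper around [simulate_study()] that writes the pedigree and
#' phenotype tables, plus a YAML sidecar with the design and generating
#' values, so the files round-trip through [read_pedigree()] /
#' [read_phenotypes()] / [run_study()].
#'
#' @param out_dir output directory.
#' @param spec a [design_spec()].
#' @param truths named list of [sim_truth()] presets.
#' @param seed integer seed.
#' @return Invisibly, the list from [simulate_study()] with the file paths
#'   attached.
#' @export
simulate_command <- function(out_dir, spec = design_spec(),
                             truths = list(aggression = trait_preset("aggression"),
                                           activity = trait_preset("activity"),
                                           exploration = trait_preset("exploration"),
                                           boldness = trait_preset("boldness")),
                             seed = 1) {
  sim <- simulate_study(spec, truths, seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ped_path <- file.path(out_dir, "pedigree.tsv")
  phen_path <- file.path(out_dir, "phenotypes.tsv")
  write_pedigree(sim$pedigree, ped_path)
  write_phenotypes(sim$phenotypes, phen_path)
  cfg <- list(seed = seed, design = unclass(sim$spec),
              truths = lapply(sim$truths, function(t) {
                t$G <- as.numeric(t$G)
                unclass(t)
              }))
  yaml::write_yaml(cfg, file.path(out_dir, "simulation.yaml"))
  sim$paths <- list(pedigree = ped_path, phenotypes = phen_path)
  invisible(sim)
}
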