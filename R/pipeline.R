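#' Run the full exposure-by-outcome MR workflow
#'
#' Orchestrates, for every configured exposure/outcome pair: instrument
#' selection (significance filter, optional LD clumping), harmonization
#' with optional proxy substitution, the univariable estimator panel,
#' MR-PRESSO with outlier-corrected IVW, instrument-strength F statistics,
#' optional analytic power, and Bonferroni classification of the primary
#' (IVW) p-values across the whole family. When mediators are configured,
#' each is adjusted for one at a time by multivariable MR and a
#' difference-method mediation decomposition is reported. A failure in one
#' pair is recorded and the pipeline continues over the remaining pairs.
#'
#' @param config A named list, or the path of a YAML/JSON file holding one.
#'   Recognized entries: `exposures` (named list: path or table),
#'   `outcomes` (named list: path/table, or list with `path`/`table` and
#'   logical `binary`), optional `ld` and `proxies` (path or LD table),
#'   optional `mediators` (named list like `exposures`), `p_threshold`
#'   (default 5e-8), `clump` (`r2` 0.01, `window_kb` 10000),
#'   `maf_threshold` (0.42), `methods`, `n_boot` (default 5000),
#'   `presso` (`enabled`, `n_sim`), `power` (`beta_alt` or `or_alt`,
#'   `alpha`), `bonferroni` (`alpha`, optional `n_exposures`/`n_outcomes`
#'   overrides), `seed`.
#' @param out_dir Optional directory; when given, writes
#'   `results_primary.tsv` (one row per pair: IVW estimate with
#'   heterogeneity/pleiotropy/PRESSO diagnostics and classification),
#'   `results_methods.tsv` (one row per pair and estimator),
#'   `forest.tsv` (per-SNP Wald ratios), `mediation.tsv` (mediator, ES,
#'   ci_low, ci_high), and `manifest.json`. Output bytes are deterministic
#'   for a fixed config and seed.
#' @return A list of class `mr_report`: `primary`, `methods`, `forest`,
#'   `mediation` data.frames, per-pair `details`, and the `manifest`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- config
  p_threshold <- cfg$p_threshold %||% 5e-8
  clump_r2 <- cfg$clump$r2 %||% 0.01
  window_kb <- cfg$clump$window_kb %||% 10000
  maf_threshold <- cfg$maf_threshold %||% 0.42
  methods <- cfg$methods %||% c("ivw", "egger", "wmedian", "ml")
  n_boot <- cfg$n_boot %||% 5000L
  presso_on <- cfg$presso$enabled %||% TRUE
  presso_nsim <- cfg$presso$n_sim %||% 1000L
  seed <- cfg$seed %||% 1L
  exposures <- load_tables(cfg$exposures)
  outcomes <- load_outcomes(cfg$outcomes)
  mediators <- if (!is.null(cfg$mediators)) load_tables(cfg$mediators)
  ld <- load_ld(cfg$ld)
  proxies <- load_ld(cfg$proxies)

  details <- list()
  primary <- methods_rows <- forest <- med_rows <- NULL
  for (ex in names(exposures)) {
    for (oc in names(outcomes)) {
      pair <- paste(ex, oc, sep = ":")
      res <- tryCatch(
        run_pair(exposures[[ex]], outcomes[[oc]]$table,
                 binary = outcomes[[oc]]$binary, ld = ld, proxies = proxies,
                 p_threshold = p_threshold, clump_r2 = clump_r2,
                 window_kb = window_kb, maf_threshold = maf_threshold,
                 methods = methods, n_boot = n_boot,
                 presso_on = presso_on, presso_nsim = presso_nsim,
                 seed = seed),
        error = function(e) list(error = conditionMessage(e)))
      details[[pair]] <- res
      if (!is.null(res$error)) {
        primary <- rbind(primary, data.frame(
          exposure = ex, outcome = oc, n_snp = NA_integer_,
          estimate = NA_real_, or = NA_real_, ci_low = NA_real_,
          ci_high = NA_real_, pval = NA_real_, i2 = NA_real_,
          q_pval = NA_real_, intercept_pval = NA_real_,
          presso_global_pval = NA_real_, n_outliers = NA_integer_,
          corrected_estimate = NA_real_, corrected_pval = NA_real_,
          f_stat = NA_real_, power = NA_real_,
          error = res$error, stringsAsFactors = FALSE))
        next
      }
      ivw <- res$results$ivw
      egg <- res$results$egger
      pw <- pair_power(cfg$power, outcomes[[oc]], res)
      primary <- rbind(primary, data.frame(
        exposure = ex, outcome = oc, n_snp = ivw$n_snp,
        estimate = ivw$estimate,
        or = if (outcomes[[oc]]$binary) exp(ivw$estimate) else NA_real_,
        ci_low = ivw$ci_low, ci_high = ivw$ci_high, pval = ivw$pval,
        i2 = ivw$i2 %||% NA_real_, q_pval = ivw$q_pval %||% NA_real_,
        intercept_pval = if (!is.null(egg)) egg$intercept_pval else NA_real_,
        presso_global_pval =
          if (!is.null(res$presso)) res$presso$global_pval else NA_real_,
        n_outliers =
          if (!is.null(res$presso)) length(res$presso$outlier_ids)
          else NA_integer_,
        corrected_estimate =
          if (!is.null(res$presso)) res$presso$corrected_estimate$estimate
          else NA_real_,
        corrected_pval =
          if (!is.null(res$presso)) res$presso$corrected_estimate$pval
          else NA_real_,
        f_stat = res$f_stat, power = pw, error = NA_character_,
        stringsAsFactors = FALSE))
      for (m in names(res$results)) {
        r <- res$results[[m]]
        mrow <- as.data.frame(r)
        mrow$exposure <- ex; mrow$outcome <- oc
        mrow$or <- if (outcomes[[oc]]$binary) exp(r$estimate) else NA_real_
        methods_rows <- rbind(methods_rows, mrow)
      }
      wr <- wald_ratio(res$set$beta_x, res$set$se_x,
                       res$set$beta_y, res$set$se_y)
      forest <- rbind(forest, data.frame(
        exposure = ex, outcome = oc, snp = res$set$snp,
        estimate = wr$estimate, se = wr$se,
        ci_low = wr$estimate - stats::qnorm(0.975) * wr$se,
        ci_high = wr$estimate + stats::qnorm(0.975) * wr$se,
        stringsAsFactors = FALSE))
      if (!is.null(mediators)) {
        for (md in names(mediators)) {
          mrow <- tryCatch(
            run_mediation(exposures[[ex]], mediators[[md]],
                          outcomes[[oc]]$table, res, ld = ld,
                          p_threshold = p_threshold, clump_r2 = clump_r2,
                          window_kb = window_kb,
                          maf_threshold = maf_threshold,
                          exposure = ex, outcome = oc, mediator = md),
            error = function(e) data.frame(
              exposure = ex, outcome = oc, mediator = md,
              direct = NA_real_, direct_se = NA_real_, direct_pval = NA_real_,
              indirect = NA_real_, es = NA_real_, ci_low = NA_real_,
              ci_high = NA_real_, error = conditionMessage(e),
              stringsAsFactors = FALSE))
          med_rows <- rbind(med_rows, mrow)
        }
      }
    }
  }
  bon <- cfg$bonferroni %||% list()
  n_e <- bon$n_exposures %||% length(exposures)
  n_o <- bon$n_outcomes %||% length(outcomes)
  ok <- !is.na(primary$pval)
  primary$class <- NA_character_
  if (any(ok)) {
    cl <- bonferroni_classify(primary[ok, c("exposure", "outcome", "pval")] |>
                                stats::setNames(c("exposure", "outcome", "p")),
                              n_exposures = n_e, n_outcomes = n_o,
                              alpha = bon$alpha %||% 0.05)
    primary$class[ok] <- as.character(cl$class)
  }
  manifest <- list(
    package = "mrpipe",
    version = as.character(utils::packageVersion("mrpipe")),
    seed = seed,
    settings = list(p_threshold = p_threshold, clump_r2 = clump_r2,
                    window_kb = window_kb, maf_threshold = maf_threshold,
                    methods = methods, n_boot = n_boot,
                    presso = list(enabled = presso_on, n_sim = presso_nsim),
                    bonferroni = list(alpha = bon$alpha %||% 0.05,
                                      n_exposures = n_e, n_outcomes = n_o)),
    pairs = names(details),
    audits = lapply(details, function(d) {
      if (!is.null(d$error)) list(error = d$error)
      else list(n_selected = nrow(d$set),
                exclusions = as.list(table(d$audit$reason)))
    }))
  report <- structure(list(primary = primary, methods = methods_rows,
                           forest = forest, mediation = med_rows,
                           details = details, manifest = manifest),
                      class = "mr_report")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

load_tables <- function(x) {
  stopifnot(!is.null(names(x)))
  lapply(x, function(e) {
    if (inherits(e, "sumstats")) e else read_sumstats(e)
  })
}

load_outcomes <- function(x) {
  stopifnot(!is.null(names(x)))
  lapply(x, function(e) {
    if (inherits(e, "sumstats")) return(list(table = e, binary = FALSE))
    if (is.character(e)) return(list(table = read_sumstats(e),
                                     binary = FALSE))
    tab <- if (!is.null(e$table)) e$table else read_sumstats(e$path)
    if (!inherits(tab, "sumstats")) tab <- sumstats(tab)
    list(table = tab, binary = isTRUE(e$binary))
  })
}

load_ld <- function(x) {
  if (is.null(x)) return(NULL)
  if (is.character(x)) read_ld_table(x) else ld_table(x)
}

# One exposure-outcome pair: selection, harmonization, estimation, PRESSO.
run_pair <- function(exposure, outcome, binary, ld, proxies, p_threshold,
                     clump_r2, window_kb, maf_threshold, methods, n_boot,
                     presso_on, presso_nsim, seed) {
  iset <- filter_significant(exposure, p_threshold)
  if (!is.null(ld)) {
    iset <- ld_clump(iset, ld, r2_threshold = clump_r2,
                     window_kb = window_kb)
  }
  if (nrow(iset$selected) == 0L) stop("no instruments pass selection")
  sel <- iset$selected
  out_tab <- outcome
  proxy_log <- NULL
  missing <- setdiff(sel$snp, out_tab$snp)
  if (length(missing) && !is.null(proxies)) {
    sub <- substitute_proxies(missing, proxies)
    sub <- sub[!is.na(sub$proxy) & sub$proxy %in% out_tab$snp, , drop = FALSE]
    if (nrow(sub)) {
      # proxy rows stand in for the instrument; proxy-search output is
      # assumed allele-matched to the instrument's effect/other coding
      rows <- out_tab[match(sub$proxy, out_tab$snp), , drop = FALSE]
      rows$snp <- sub$snp
      sel_idx <- match(sub$snp, sel$snp)
      rows$effect_allele <- sel$effect_allele[sel_idx]
      rows$other_allele <- sel$other_allele[sel_idx]
      out_tab <- sumstats(rbind(as.data.frame(out_tab), rows))
      proxy_log <- data.frame(snp = sub$snp,
                              reason = paste0("proxy-substituted:",
                                              sub$proxy),
                              stringsAsFactors = FALSE)
    }
  }
  h <- harmonize(sel, out_tab, maf_threshold)
  if (nrow(h) == 0L) stop("no SNPs survive harmonization")
  haud <- harmonize_audit(h)
  names(haud)[names(haud) == "action"] <- "reason"
  audit <- rbind(iset$audit, haud, proxy_log)
  results <- list()
  results$ivw <- mr_ivw(h)
  if (nrow(h) >= 3L) {
    if ("egger" %in% methods) results$egger <- mr_egger(h)
    if ("wmedian" %in% methods) {
      results$wmedian <- mr_weighted_median(h, n_boot = n_boot, seed = seed)
    }
  }
  if ("ml" %in% methods) results$ml <- mr_max_likelihood(h)
  pres <- NULL
  if (presso_on && nrow(h) >= 4L) {
    pres <- presso(h, n_sim = presso_nsim, seed = seed)
  }
  loo <- if (nrow(h) >= 3L) leave_one_out(h)
  r2_tot <- variance_explained(sel)
  f_stat <- if (r2_tot > 0 && r2_tot < 1 &&
                sel$n[1] > nrow(sel) + 1) {
    instrument_strength(r2_tot, sel$n[1], nrow(sel))$f
  } else NA_real_
  list(set = h, audit = audit, results = results, presso = pres, loo = loo,
       r2 = r2_tot, f_stat = f_stat, binary = binary)
}

pair_power <- function(power_cfg, outcome, res) {
  if (is.null(power_cfg) || !is.finite(res$r2) || res$r2 <= 0 ||
      res$r2 >= 1) {
    return(NA_real_)
  }
  alpha <- power_cfg$alpha %||% 0.05
  n <- outcome$table$n[1]
  if (outcome$binary && !is.null(power_cfg$or_alt)) {
    mr_power(n, res$r2, alpha, or_alt = power_cfg$or_alt,
             k_cases = power_cfg$k_cases %||% 0.5)
  } else if (!outcome$binary && !is.null(power_cfg$beta_alt)) {
    mr_power(n, res$r2, alpha, beta_alt = power_cfg$beta_alt)
  } else {
    NA_real_
  }
}

# One-mediator-at-a-time MVMR adjustment and difference-method mediation.
run_mediation <- function(exposure_tab, mediator_tab, outcome_tab, pair_res,
                          ld, p_threshold, clump_r2, window_kb, maf_threshold,
                          exposure, outcome, mediator) {
  med_set <- filter_significant(mediator_tab, p_threshold)
  if (!is.null(ld)) {
    med_set <- ld_clump(med_set, ld, r2_threshold = clump_r2,
                        window_kb = window_kb)
  }
  ids <- union(pair_res$set$snp, med_set$selected$snp)
  if (!is.null(ld)) {
    # clump the instrument union jointly, preferring the exposure's rows
    pool <- rbind(
      as.data.frame(exposure_tab)[exposure_tab$snp %in% ids, ],
      as.data.frame(mediator_tab)[
        mediator_tab$snp %in% setdiff(ids, exposure_tab$snp), ])
    pool <- sumstats(pool)
    ids <- ld_clump(pool, ld, r2_threshold = clump_r2,
                    window_kb = window_kb)$selected$snp
  }
  mv_in <- build_mvmr_input(
    stats::setNames(list(exposure_tab, mediator_tab), c(exposure, mediator)),
    outcome_tab, ids, maf_threshold)
  direct <- mvmr(mv_in)[[exposure]]
  total <- pair_res$results$ivw
  med <- withCallingHandlers(
    mediate(total, direct, mediator_names = mediator),
    warning = function(w) invokeRestart("muffleWarning"))
  data.frame(exposure = exposure, outcome = outcome, mediator = mediator,
             direct = direct$estimate, direct_se = direct$se,
             direct_pval = direct$pval,
             indirect = med$indirect$estimate,
             es = med$proportion_mediated,
             ci_low = med$pm_ci_low, ci_high = med$pm_ci_high,
             error = NA_character_, stringsAsFactors = FALSE)
}

#' @export
print.mr_report <- function(x, ...) {
  cat(sprintf("<mr_report> %d exposure x outcome pairs\n", nrow(x$primary)))
  print(x$primary[, c("exposure", "outcome", "n_snp", "estimate", "pval",
                      "class")])
  invisible(x)
}

#' @rdname run_pipeline
#' @param report An `mr_report`.
#' @param dir Output directory (created if absent).
#' @export
write_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  wt <- function(df, name) {
    if (is.null(df)) return(invisible(NULL))
    utils::write.table(df, file.path(dir, name), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  wt(report$primary, "results_primary.tsv")
  wt(report$methods, "results_methods.tsv")
  wt(report$forest, "forest.tsv")
  if (!is.null(report$mediation)) {
    wt(report$mediation, "mediation.tsv")
    mv <- report$mediation[, intersect(c("exposure", "outcome", "mediator",
                                         "direct", "direct_se",
                                         "direct_pval"),
                                       names(report$mediation))]
    wt(mv, "results_mvmr.tsv")
  }
  jsonlite::write_json(report$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
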