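#' Experiment presets
#'
#' Named presets that orchestrate replicate simulations, virtual sequencing
#' and the summary statistics into the package's standard simulation
#' experiments:
#'
#' * `fig1_growth` - growth-rate comparison of NS and NFDS tumors at equal
#'   selection intensity (one-sided Wilcoxon, NFDS > NS).
#' * `fig1_load_vs_s` - antigenic mutation load across a grid of selection
#'   coefficients under NS and NFDS (Kruskal-Wallis per scenario).
#' * `fig2_correlations` - per-tumor average antigenic CCF versus subclonal
#'   antigenic load, with the per-scenario Spearman test (the
#'   frequency-dependent-selection signature: negative under NFDS, positive
#'   under NS).
#' * `fig3_icb_survival` - treated versus untreated virtual patients under
#'   NS_IE and NFDS_IE with Kaplan-Meier curves and log-rank tests.
#' * `fig3_neutrality` - pre-therapy neutrality R-squared of NS_IE versus
#'   NFDS_IE tumors (one-sided Wilcoxon, NFDS_IE more neutral-like).
#'
#' @param name Preset name.
#' @param replicates Established replicates per arm (defaults per preset).
#' @param seed Root seed; every output is fully determined by it.
#' @param scale Ceiling divisor for desk runs: the population ceiling is
#'   `100000 / scale` (default 1: full scale).
#' @param out_dir Optional directory; when set, per-arm tables, the summary,
#'   the test results and a JSON manifest are written as tab-separated text.
#' @param config_overrides Named list overriding any [sim_config()] field in
#'   every arm.
#' @return A list with `name`, `arms` (per-arm data frames), `tests`
#'   (statistics), and `manifest`.
#' @export
run_preset <- function(name = c("fig1_growth", "fig1_load_vs_s",
                                "fig2_correlations", "fig3_icb_survival",
                                "fig3_neutrality"),
                       replicates = NULL, seed = 1, scale = 1,
                       out_dir = NULL, config_overrides = list()) {
  name <- match.arg(name)
  ceiling_n <- round(1e5 / scale)
  base_cfg <- function(sc, ...) {
    args <- utils::modifyList(
      list(scenario = sc, max_population = ceiling_n, max_time = 1000, ...),
      config_overrides
    )
    do.call(sim_config, args)
  }
  out <- if (!is.null(replicates) && replicates == 0) {
    list(arms = list(), tests = list())
  } else switch(
    name,
    fig1_growth = preset_growth(base_cfg, replicates %||% 20, seed),
    fig1_load_vs_s = preset_load_vs_s(base_cfg, replicates %||% 15, seed),
    fig2_correlations = preset_correlations(base_cfg, replicates %||% 50,
                                            seed),
    fig3_icb_survival = preset_icb_survival(base_cfg, replicates %||% 20,
                                            seed),
    fig3_neutrality = preset_neutrality(base_cfg, replicates %||% 30, seed)
  )
  out$name <- name
  out$manifest <- list(
    preset = name, seed = seed, scale = scale,
    population_ceiling = ceiling_n,
    replicates = replicates,
    config_overrides = config_overrides,
    package_version = as.character(utils::packageVersion("nfdsim")),
    timestamp = format(Sys.time(), tz = "UTC")
  )
  if (!is.null(out_dir)) write_preset(out, out_dir)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

preset_growth <- function(base_cfg, n, seed) {
  arms <- lapply(c(NS = "NS", NFDS = "NFDS"), function(sc) {
    rr <- run_replicates(base_cfg(sc), n = n, seed = seed + match(sc,
                           c("NS", "NFDS")), record_mutations = FALSE,
                         summarize = function(r) data.frame(
                           scenario = sc, seed = r$seed,
                           outcome = r$outcome,
                           outcome_time = r$outcome_time,
                           growth_rate = growth_rate_fit(r)))
    do.call(rbind, rr$results)
  })
  test <- compare_groups(arms$NFDS$growth_rate, arms$NS$growth_rate,
                         alternative = "greater")
  list(arms = arms, tests = list(nfds_faster_than_ns = test))
}

preset_load_vs_s <- function(base_cfg, n, seed) {
  grid <- expand.grid(scenario = c("NS", "NFDS"),
                      s = c(0, -0.4, -0.8), stringsAsFactors = FALSE)
  arms <- list()
  for (i in seq_len(nrow(grid))) {
    sc <- grid$scenario[i]; sv <- grid$s[i]
    rr <- run_replicates(base_cfg(sc, selection_s = sv), n = n,
                         seed = seed + i,
                         summarize = function(r) {
                           if (r$outcome == "extinct") return(NULL)
                           tab <- true_ccf_table(r, min_ccf = 0.01)
                           data.frame(
                             scenario = sc, s = sv, seed = r$seed,
                             load_001 = antigenic_load(tab, 0.01),
                             load_004 = antigenic_load(tab, 0.04),
                             load_01 = antigenic_load(tab, 0.1))
                         })
    arms[[sprintf("%s_s%g", sc, sv)]] <-
      do.call(rbind, Filter(Negate(is.null), rr$results))
  }
  flat <- do.call(rbind, arms)
  tests <- lapply(split(flat, flat$scenario), function(d) {
    stats::kruskal.test(d$load_001, factor(d$s))$p.value
  })
  list(arms = arms, tests = list(kruskal_p_by_scenario = tests))
}

preset_correlations <- function(base_cfg, n, seed) {
  arms <- lapply(c(NS = "NS", NFDS = "NFDS"), function(sc) {
    rr <- run_replicates(base_cfg(sc), n = n, seed = seed + match(sc,
                           c("NS", "NFDS")),
                         summarize = function(r) {
                           if (r$outcome == "extinct") return(NULL)
                           tab <- true_ccf_table(r, min_ccf = 0.01)
                           data.frame(
                             scenario = sc, seed = r$seed,
                             avg_ccf = average_ccf(tab, antigenic_only = TRUE,
                                                   ccf_threshold = 0.1),
                             subclonal_load = antigenic_load(tab, 0.1,
                               subclonal_only = TRUE),
                             r_squared = neutrality_r2(tab$true_ccf)$r_squared,
                             shannon = shannon_diversity(r$clones$cell_count))
                         })
    do.call(rbind, Filter(Negate(is.null), rr$results))
  })
  tests <- lapply(arms, function(d) {
    ok <- stats::complete.cases(d[, c("avg_ccf", "subclonal_load")])
    if (sum(ok) < 3L) return(list(rho = NA_real_, p_value = NA_real_))
    spearman_correlation(d$avg_ccf[ok], d$subclonal_load[ok])
  })
  list(arms = arms, tests = list(spearman = tests))
}

preset_icb_survival <- function(base_cfg, n, seed) {
  arms <- list()
  for (sc in c("NS_IE", "NFDS_IE")) {
    for (treated in c(TRUE, FALSE)) {
      cfg <- if (treated) base_cfg(sc, icb_population_fraction = 0.5)
             else base_cfg(sc)
      rr <- run_replicates(cfg, n = n,
                           seed = seed + 10 * match(sc,
                             c("NS_IE", "NFDS_IE")) + treated,
                           record_mutations = FALSE,
                           summarize = function(r) data.frame(
                             scenario = sc, treated = treated, seed = r$seed,
                             event_time = r$outcome_time,
                             event = as.integer(r$outcome ==
                                                  "reached_ceiling"),
                             outcome = r$outcome))
      arms[[paste0(sc, if (treated) "_treated" else "_untreated")]] <-
        do.call(rbind, rr$results)
    }
  }
  tests <- list(
    logrank_ns = logrank_test(arms$NS_IE_treated, arms$NS_IE_untreated),
    logrank_nfds = logrank_test(arms$NFDS_IE_treated, arms$NFDS_IE_untreated)
  )
  km <- lapply(arms, km_curve)
  list(arms = arms, tests = tests, km = km)
}

preset_neutrality <- function(base_cfg, n, seed) {
  arms <- lapply(c(NS_IE = "NS_IE", NFDS_IE = "NFDS_IE"), function(sc) {
    rr <- run_replicates(base_cfg(sc), n = n, seed = seed + match(sc,
                           c("NS_IE", "NFDS_IE")),
                         summarize = function(r) {
                           if (r$outcome == "extinct") return(NULL)
                           tab <- true_ccf_table(r, min_ccf = 0.01)
                           data.frame(
                             scenario = sc, seed = r$seed,
                             r_squared = neutrality_r2(tab$true_ccf)$r_squared)
                         })
    do.call(rbind, Filter(Negate(is.null), rr$results))
  })
  test <- compare_groups(
    stats::na.omit(arms$NFDS_IE$r_squared),
    stats::na.omit(arms$NS_IE$r_squared),
    alternative = "greater"
  )
  list(arms = arms, tests = list(nfds_ie_more_neutral = test))
}

write_preset <- function(out, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (arm in names(out$arms)) {
    utils::write.table(
      out$arms[[arm]],
      file.path(out_dir, paste0(out$name, "_", arm, ".tsv")),
      sep = "\t", quote = FALSE, row.names = FALSE
    )
  }
  jsonlite::write_json(
    out$manifest, file.path(out_dir, paste0(out$name, "_manifest.json")),
    auto_unbox = TRUE, pretty = TRUE
  )
  jsonlite::write_json(
    out$tests, file.path(out_dir, paste0(out$name, "_tests.json")),
    auto_unbox = TRUE, pretty = TRUE, digits = NA, force = TRUE
  )
  invisible(out_dir)
}

#' Write simulation outputs as tab-separated tables
#'
#' Writes the trajectory, mutation registry and a machine-readable run
#' manifest for one simulation.
#'
#' @param result An `nfds_result`.
#' @param out_dir Output directory (created if needed).
#' @param prefix File-name prefix (default `"tumor"`).
#' @return The output directory, invisibly.
#' @export
write_simulation <- function(result, out_dir, prefix = "tumor") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(result$trajectory,
                     file.path(out_dir, paste0(prefix, "_trajectory.tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(result$mutations)) {
    utils::write.table(result$mutations,
                       file.path(out_dir, paste0(prefix, "_mutations.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  manifest <- list(
    outcome = result$outcome, outcome_time = result$outcome_time,
    max_population_attained = result$max_population_attained,
    seed = result$seed,
    config = result$config[setdiff(names(result$config), "rng_seed")]
  )
  jsonlite::write_json(manifest,
                       file.path(out_dir, paste0(prefix, "_manifest.json")),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}
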