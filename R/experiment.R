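stand_factor_cols <- function() {
  c("rcp", "disturbance_response", "forest_age", "forest_type",
    "harvest_intensity", "salvage")
}

post_factor_cols <- function() c("material_usage", "cascade", "decarb_2050")

factor_cols <- function() c(stand_factor_cols(), post_factor_cols())

#' Run the factorial mitigation experiment
#'
#' Simulates every scenario of the design and returns the headline metrics
#' per scenario and horizon. Stand dynamics depend only on the first six
#' factors, so each distinct stand configuration is simulated once (per
#' site) and shared across the wood-usage / cascade / decarbonization
#' variants; all scenarios share their stochastic draws through the
#' common-random-numbers seed policy, making pairwise contrasts exact.
#' Patch means are taken first, then site means.
#'
#' @param levels factor levels, as [scenario_factor_levels()]; subsets of
#'   the default levels give reduced designs.
#' @param n_patches replicate patches per stand (default 100; reduce for
#'   fast ensembles).
#' @param n_sites number of (exchangeable) climate-replicate sites.
#' @param seed integer base seed for all stochastic draws.
#' @param horizons horizon years for the metrics.
#' @param years simulation years.
#' @param check_balance if `TRUE`, add per-scenario maximum relative
#'   closure residuals (`stand_residual`, `system_residual`) to the output.
#' @param params_args named list of extra arguments to [stand_params()]
#'   (e.g. emulator constants) applied to every stand.
#' @param verbose log progress to stderr.
#' @return `data.frame` of class `mitigation_results`: one row per
#'   (scenario, horizon) with all factor levels, `combined_sink`,
#'   `cumulative_avoided`, `total_mitigation` (kgC/m2).
#' @export
run_experiment <- function(levels = scenario_factor_levels(),
                           n_patches = 100L, n_sites = 1L, seed = 1L,
                           horizons = c(2050, 2100),
                           years = 1920:2100,
                           check_balance = FALSE,
                           params_args = list(),
                           verbose = FALSE) {
  design <- enumerate_scenarios(levels)
  sites <- paste0("site", seq_len(n_sites))
  rcps <- unique(design$rcp)

  climates <- list()
  for (s in sites) for (r in rcps)
    climates[[paste(s, r)]] <- generate_climate(r, s, seed, years = years)

  scols <- stand_factor_cols()
  key <- do.call(paste, c(design[scols], list(sep = "|")))
  ukeys <- unique(key)
  if (verbose)
    message(sprintf("running %d scenarios (%d stand configurations, %d site(s), %d patches)",
                    nrow(design), length(ukeys), n_sites, n_patches))

  stand_cache <- vector("list", length(ukeys))
  names(stand_cache) <- ukeys
  for (k in ukeys) {
    scen <- as.list(design[match(k, key), scols])
    params <- do.call(stand_params, c(list(forest_type = scen$forest_type,
                                           n_patches = n_patches),
                                      params_args))
    per_site <- lapply(sites, function(s)
      simulate_stand(scen, climates[[paste(s, scen$rcp)]], params, seed, s))
    avg <- per_site[[1]]
    if (n_sites > 1) {
      num <- setdiff(names(avg), "year")
      for (col in num)
        avg[[col]] <- rowMeans(vapply(per_site, `[[`, numeric(nrow(avg)), col))
    }
    stand_cache[[k]] <- avg
    if (verbose) message("  stand done: ", k)
  }

  n_out <- nrow(design) * length(horizons)
  rows <- vector("list", nrow(design))
  for (i in seq_len(nrow(design))) {
    st <- stand_cache[[key[i]]]
    pr <- product_dynamics(st$removed_stem, st$firewood, st$year,
                           forest_type = design$forest_type[i],
                           material_usage = design$material_usage[i],
                           cascade = design$cascade[i],
                           decarb_2050 = design$decarb_2050[i])
    traj <- mitigation_trajectory(st, pr)
    res <- lapply(horizons, function(h) total_mitigation(traj, h))
    row <- data.frame(scenario_id = design$scenario_id[i],
                      design[i, factor_cols(), drop = FALSE],
                      horizon = horizons,
                      combined_sink = vapply(res, `[[`, 0, "combined_sink"),
                      cumulative_avoided = vapply(res, `[[`, 0,
                                                  "cumulative_avoided"),
                      total_mitigation = vapply(res, `[[`, 0,
                                                "total_mitigation"),
                      row.names = NULL)
    if (check_balance) {
      row$system_residual <- closure_residual(traj)
      row$stand_residual <- stand_closure_residual(st)
    }
    rows[[i]] <- row
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  stopifnot(nrow(out) == n_out)
  class(out) <- c("mitigation_results", "data.frame")
  out
}

#' Maximum relative stand-side closure residual
#'
#' Checks, for every simulated year, that the change of the forest stock
#' (vegetation + deadwood + soil) equals NPP minus removed stems, firewood
#' and heterotrophic respiration.
#'
#' @param stand a [simulate_stand()] series.
#' @return maximum annual residual relative to the stock scale.
#' @export
stand_closure_residual <- function(stand) {
  stock <- stand$veg_c + stand$deadwood_c + stand$soil_c
  net <- (stand$npp - stand$removed_stem - stand$firewood -
            stand$deadwood_resp - stand$soil_resp)[-1]
  scale <- max(abs(stock), stand$npp, 1e-12)
  max(abs(diff(stock) - net)) / scale
}

#' Pairwise differences between partner simulations
#'
#' Attributes the effect of one factor by subtracting, within the analysis
#' subset, the metric of each simulation at `level_b` from its partner
#' simulation at `level_a` where all other factors are identical (an exact
#' join on the remaining factor columns). By design arithmetic, a two-level
#' factor in the exponential subset yields 576 pairs, one harvest-intensity
#' contrast 288, and one decarbonization contrast 384.
#'
#' @param results a [run_experiment()] table.
#' @param factor factor column to contrast.
#' @param level_a,level_b factor levels; differences are `a - b`.
#' @param metric `"total_mitigation"` or `"combined_sink"`.
#' @param horizon horizon year to analyse.
#' @param subset disturbance-response subset the analysis is restricted to
#'   (default `"exponential"`); ignored when contrasting
#'   `disturbance_response` itself, and `NULL` disables the filter.
#' @return list of class `forestmit_comparison`: `n_pairs`, `differences`,
#'   and a `summary` (median, min, max, share_positive).
#' @export
pairwise_differences <- function(results, factor, level_a, level_b,
                                 metric = c("total_mitigation",
                                            "combined_sink"),
                                 horizon = 2100,
                                 subset = "exponential") {
  metric <- match.arg(metric)
  if (!factor %in% factor_cols()) stop_config("unknown factor: ", factor)
  if (identical(level_a, level_b)) stop_config("levels must differ")
  r <- results[results$horizon == horizon, , drop = FALSE]
  if (!nrow(r)) stop("results do not contain horizon ", horizon)
  if (!is.null(subset) && factor != "disturbance_response")
    r <- r[r$disturbance_response == subset, , drop = FALSE]
  lv <- r[[factor]]
  if (!any(lv == level_a) || !any(lv == level_b))
    stop_config("level not present in design for factor ", factor)
  by_cols <- setdiff(factor_cols(), factor)
  a <- r[lv == level_a, c(by_cols, metric), drop = FALSE]
  b <- r[lv == level_b, c(by_cols, metric), drop = FALSE]
  m <- merge(a, b, by = by_cols, suffixes = c(".a", ".b"))
  if (nrow(m) != nrow(a) || nrow(a) != nrow(b))
    stop("design incomplete: unmatched partner simulations for ", factor)
  diffs <- m[[paste0(metric, ".a")]] - m[[paste0(metric, ".b")]]
  structure(list(factor = factor, level_a = level_a, level_b = level_b,
                 metric = metric, horizon = horizon, subset = subset,
                 n_pairs = length(diffs), differences = diffs,
                 summary = c(median = stats::median(diffs),
                             min = min(diffs), max = max(diffs),
                             share_positive = mean(diffs > 0))),
            class = "forestmit_comparison")
}

#' @export
print.forestmit_comparison <- function(x, ...) {
  cat(sprintf("<comparison %s: %s vs %s | %s @ %d | subset %s>\n",
              x$factor, x$level_a, x$level_b, x$metric, x$horizon,
              if (is.null(x$subset)) "none" else x$subset))
  cat(sprintf("  n_pairs=%d median=%.4f min=%.4f max=%.4f share_positive=%.3f\n",
              x$n_pairs, x$summary[["median"]], x$summary[["min"]],
              x$summary[["max"]], x$summary[["share_positive"]]))
  invisible(x)
}

#' Standard per-factor effect summary of an experiment
#'
#' Computes the standard contrasts (each two-level factor, the harvest
#' decrease/stop/increase contrasts against 100%, and the climate and
#' decarbonization contrasts against their middle level) for one metric and
#' horizon and tabulates median, range and share of positive differences.
#'
#' @param results a [run_experiment()] table.
#' @param metric metric column to summarize.
#' @param horizon horizon year.
#' @param subset analysis subset, as in [pairwise_differences()].
#' @return `data.frame`, one row per contrast.
#' @export
summarize_experiment <- function(results,
                                 metric = c("total_mitigation",
                                            "combined_sink"),
                                 horizon = 2100,
                                 subset = "exponential") {
  metric <- match.arg(metric)
  contrasts <- list(
    list("rcp", "RCP8.5", "RCP4.5"),
    list("rcp", "RCP2.6", "RCP4.5"),
    list("forest_age", "young", "mature"),
    list("forest_type", "NE", "BD"),
    list("harvest_intensity", 0, 1),
    list("harvest_intensity", 0.5, 1),
    list("harvest_intensity", 1.5, 1),
    list("salvage", TRUE, FALSE),
    list("material_usage", 1.5, 1),
    list("cascade", 1.5, 1),
    list("decarb_2050", 0.25, 0.5),
    list("decarb_2050", 0.75, 0.5)
  )
  rows <- list()
  for (ct in contrasts) {
    lv <- results[[ct[[1]]]]
    if (!any(lv == ct[[2]]) || !any(lv == ct[[3]])) next
    cmp <- pairwise_differences(results, ct[[1]], ct[[2]], ct[[3]],
                                metric, horizon, subset)
    rows[[length(rows) + 1L]] <- data.frame(
      factor = ct[[1]], level_a = as.character(ct[[2]]),
      level_b = as.character(ct[[3]]), metric = metric, horizon = horizon,
      n_pairs = cmp$n_pairs,
      median = cmp$summary[["median"]], min = cmp$summary[["min"]],
      max = cmp$summary[["max"]],
      share_positive = cmp$summary[["share_positive"]])
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
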