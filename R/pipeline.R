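# End-to-end pipeline: build/load models, sample the polytopes, compute
# ENA indices and the Lindeman spine, and compare the seasons.

#' Run the full seasonal food-web analysis
#'
#' Executes, per season: model construction (or parsing), feasibility
#' validation, mirror-MCMC sampling, per-sample ENA indices, mean-flow
#' network indices (including cycle analysis), the Lindeman spine and
#' derived flow aggregates; then a season-by-season rank-sum comparison.
#' All artifacts are written as plain text (CSV/JSON) plus a JSON run
#' manifest.
#'
#' @param out_dir output directory (created if missing).
#' @param seasons character vector; each entry is either a bundled season
#'   name (`"winter"`, `"summer"`) or a path to a `.lim` declaration.
#' @param iterations,jump,seed sampler settings (seed is offset by one
#'   per season so the chains differ).
#' @param burn_in,thin passed to [sampler_config()].
#' @param alpha significance level of the seasonal comparison.
#' @param indices index columns compared across seasons.
#' @param write_samples write the full sample matrices (`samples_*.csv`;
#'   large) in addition to the summaries.
#' @param quiet suppress progress messages.
#' @return invisibly, a list with per-season results and the comparison
#'   table; side effect: files under `out_dir`.
#' @export
run_pipeline <- function(out_dir, seasons = c("winter", "summer"),
                         iterations = 50000L, jump = 1, seed = 42L,
                         burn_in = 0L, thin = 1L, alpha = 0.01,
                         indices = c("TST", "AMI", "A_rel", "A_i_rel",
                                     "FCI", "APL"),
                         write_samples = FALSE, quiet = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(...)
  t_start <- Sys.time()
  manifest <- list(
    package = "tideweb",
    version = as.character(utils::packageVersion("tideweb")),
    started = format(t_start, "%Y-%m-%d %H:%M:%S"),
    seasons = seasons, iterations = iterations, jump = jump,
    seed = seed, burn_in = burn_in, thin = thin, alpha = alpha)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  results <- list()
  for (i in seq_along(seasons)) {
    sn <- seasons[i]
    tag <- if (file.exists(sn))
      sub("\\.lim$", "", basename(sn)) else sn
    say("[", tag, "] building model")
    p <- if (file.exists(sn)) read_lim(sn) else brouage_model(sn)
    diag <- validate_problem(p)
    if (!diag$feasible) stop("model '", tag, "' is infeasible")
    say("[", tag, "] sampling: ", iterations, " iterations")
    cfg <- sampler_config(iterations = iterations, jump = jump,
                          seed = seed + i - 1L, burn_in = burn_in,
                          thin = thin)
    smp <- mirror_sample(p, cfg)
    summ <- summarize_samples(smp)
    write.csv(summ, file.path(out_dir, paste0("means_", tag, ".csv")),
              row.names = FALSE)
    if (write_samples)
      write.csv(as.data.frame(smp$samples),
                file.path(out_dir, paste0("samples_", tag, ".csv")),
                row.names = FALSE)
    say("[", tag, "] ENA over ", iterations, " samples")
    idx <- ena_over_samples(smp)
    write.csv(idx, file.path(out_dir, paste0("indices_", tag, ".csv")),
              row.names = FALSE)
    mean_net <- network_from_solution(p, summ$mean, check = FALSE)
    mean_ena <- ena(mean_net)
    write.csv(mean_ena,
              file.path(out_dir, paste0("mean_ena_", tag, ".csv")),
              row.names = FALSE)
    spine <- lindeman_spine(mean_net)
    spine_json <- list(
      levels = spine$levels, det = spine$det,
      efficiencies_pct = 100 * spine$efficiencies, L = spine$L,
      system_trophic_efficiency_pct = system_trophic_efficiency(spine))
    jsonlite::write_json(spine_json,
                         file.path(out_dir, paste0("spine_", tag, ".json")),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    results[[tag]] <- list(
      problem = p, diagnostics = diag, summary = summ, indices = idx,
      mean_network = mean_net, mean_ena = mean_ena, spine = spine,
      aggregates = c(
        detritivory = detritivory(mean_net)$detritivory,
        herb_bact_ratio_pct = herbivory_bacterivory(mean_net)$ratio_pct))
  }

  comparison <- NULL
  if (length(results) >= 2L) {
    say("[compare] rank-sum tests")
    comparison <- compare_seasons(results[[1]]$indices,
                                  results[[2]]$indices,
                                  indices = indices, alpha = alpha)
    write.csv(comparison, file.path(out_dir, "comparison.csv"),
              row.names = FALSE)
    quant <- do.call(rbind, lapply(names(results), function(tag)
      do.call(rbind, lapply(indices, function(ix)
        cbind(season = tag, index = ix,
              index_quantiles(stats::na.omit(results[[tag]]$indices[[ix]])))))))
    write.csv(quant, file.path(out_dir, "index_quantiles.csv"),
              row.names = FALSE)
  }
  manifest$finished <- format(Sys.time(), "%Y-%m-%d %H:%M:%S")
  manifest$elapsed_s <- as.numeric(difftime(Sys.time(), t_start, units = "secs"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(seasons = results, comparison = comparison,
                 manifest = manifest))
}
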