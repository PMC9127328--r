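#' End-to-end analysis recipes
#'
#' Each recipe reproduces one figure-level analysis on synthetic or
#' user-supplied data and returns a report of tables plus a JSON-ready
#' summary, together with a log of every threshold used. Recipes are
#' deterministic given `config$rng_seed`.
#'
#' Available recipes:
#' * `cleavage_on_sheets` — per-sheet background-corrected two-channel
#'   intensity ratio, summarized per condition.
#' * `inhibitor_intensity` — one-channel corrected intensity per condition,
#'   normalized to a reference condition.
#' * `maxima_association` — maxima densities, shortest-distance histogram
#'   against the flipped null, close-association fraction and density.
#' * `crosslink_coaggregation` — PCC and rSDM per sheet for fixed /
#'   control / cross-linked (CoP) conditions, normalized to `fixed`.
#' * `frap` — normalization, drift QC, replicate averaging and hyperbolic
#'   recovery fit.
#' * `wb_cleavage` — cleavage ratios per construct and percent of
#'   wildtype.
#'
#' @param name recipe name (see above).
#' @param config an [analysis_config()]; `rng_seed` drives every
#'   stochastic step.
#' @param params recipe-specific inputs; when omitted, a synthetic dataset
#'   matching the assay's imaging conditions is generated (see each
#'   `recipe_*` function).
#' @param out_dir optional directory; when given, tables are written as
#'   CSV, the summary as `summary.json` and the log as `log.txt`.
#' @return An object of class `sheetquant_report`: list with `recipe`,
#'   `tables` (named data frames), `summary` (named list of scalars),
#'   `log` (character) and `config`.
#' @export
run_recipe <- function(name, config = analysis_config(), params = list(),
                       out_dir = NULL) {
  name <- match.arg(name, c("cleavage_on_sheets", "inhibitor_intensity",
                            "maxima_association", "crosslink_coaggregation",
                            "frap", "wb_cleavage"))
  report <- switch(name,
    cleavage_on_sheets = recipe_cleavage_on_sheets(config, params),
    inhibitor_intensity = recipe_inhibitor_intensity(config, params),
    maxima_association = recipe_maxima_association(config, params),
    crosslink_coaggregation = recipe_crosslink_coaggregation(config, params),
    frap = recipe_frap(config, params),
    wb_cleavage = recipe_wb_cleavage(config, params))
  report$recipe <- name
  report$config <- unclass(config)
  class(report) <- "sheetquant_report"
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' Write a recipe report to disk
#'
#' @param report a `sheetquant_report`.
#' @param dir output directory (created if missing).
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "sheetquant_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(report$tables))
    utils::write.csv(report$tables[[nm]],
                     file.path(dir, paste0(nm, ".csv")), row.names = FALSE)
  jsonlite::write_json(
    list(recipe = report$recipe, summary = report$summary,
         config = report$config),
    file.path(dir, "summary.json"), auto_unbox = TRUE, digits = NA)
  writeLines(report$log, file.path(dir, "log.txt"))
  invisible(dir)
}

#' @export
print.sheetquant_report <- function(x, ...) {
  cat(sprintf("<sheetquant_report> recipe: %s\n", x$recipe))
  for (nm in names(x$summary))
    cat(sprintf("  %s: %s\n", nm,
                paste(format(x$summary[[nm]], digits = 4), collapse = ", ")))
  invisible(x)
}

log_line <- function(...) sprintf(...)

# default membrane ROI: the emitter placement region of a simulated sheet
interior_roi <- function(sim) {
  m <- ceiling(sim$truth$margin_px)
  d <- dim(sim$img_a$pixels)
  roi_rect(m, m, d[1] - 2 * m, d[2] - 2 * m, "membrane")
}

#' @rdname run_recipe
#' @export
recipe_maxima_association <- function(config = analysis_config(),
                                      params = list()) {
  if (is.null(params$sheets)) {
    spec0 <- if (is.null(params$sim_spec)) sheet_sim_spec() else params$sim_spec
    n_sheets <- if (is.null(params$n_sheets)) 3L else params$n_sheets
    params$sheets <- lapply(seq_len(n_sheets), function(i) {
      spec <- spec0; spec$rng_seed <- config$rng_seed + i
      sim <- simulate_sheet(spec)
      list(img_query = sim$img_b, img_target = sim$img_a,
           roi = interior_roi(sim))
    })
  }
  log <- c(log_line("threshold_au=%g blur_sigma_px=%g cutoff_nm=%g",
                    config$maxima_threshold_au, config$blur_sigma_px,
                    config$close_cutoff_nm))
  results <- lapply(params$sheets, function(s)
    associate_channels(s$img_query, s$img_target, s$roi, config))
  per <- do.call(rbind, lapply(seq_along(results), function(i) {
    res <- results[[i]]
    data.frame(sheet = i,
               density_query = maxima_density(res$query),
               density_target = maxima_density(res$target),
               close_fraction = res$close_fraction,
               flipped_close_fraction = res$flipped_close_fraction,
               excess_close_fraction = res$excess_close_fraction,
               close_density_per_um2 = res$close_density_per_um2)
  }))
  # per-sheet histograms pooled by summing counts
  pool <- NULL
  for (res in results) {
    h <- res$histogram
    if (is.null(pool)) pool <- h
    else {
      pool$observed <- pool$observed + h$observed
      pool$flipped <- pool$flipped + h$flipped
      pool$observed_overflow <- pool$observed_overflow + h$observed_overflow
      pool$flipped_overflow <- pool$flipped_overflow + h$flipped_overflow
    }
  }
  hist_tbl <- data.frame(bin_lo_nm = pool$breaks_nm[-length(pool$breaks_nm)],
                         bin_hi_nm = pool$breaks_nm[-1],
                         observed = pool$observed, flipped = pool$flipped)
  list(tables = list(per_sheet = per, distance_histogram = hist_tbl),
       summary = list(
         mean_density_query_per_um2 = mean(per$density_query),
         mean_density_target_per_um2 = mean(per$density_target),
         mean_close_fraction = mean(per$close_fraction),
         mean_flipped_close_fraction = mean(per$flipped_close_fraction),
         mean_excess_close_fraction = mean(per$excess_close_fraction),
         mean_close_density_per_um2 = mean(per$close_density_per_um2)),
       log = log)
}

#' @rdname run_recipe
#' @export
recipe_crosslink_coaggregation <- function(config = analysis_config(),
                                           params = list()) {
  if (is.null(params$sheets)) {
    spec0 <- if (is.null(params$sim_spec))
      sheet_sim_spec(aggregation = list(n_aggregates = 12,
                                        co_drag_fraction = 0.5))
    else params$sim_spec
    n_sheets <- if (is.null(params$n_sheets)) 3L else params$n_sheets
    sheets <- list()
    for (i in seq_len(n_sheets)) {
      for (cond in c("fixed", "control")) {
        spec <- spec0
        spec$rng_seed <- config$rng_seed + 101L * i +
          (if (cond == "fixed") 0L else 50L)
        sim <- simulate_sheet(spec)
        sim$img_a$condition <- cond; sim$img_b$condition <- cond
        sheets[[length(sheets) + 1L]] <-
          list(img_a = sim$img_a, img_b = sim$img_b,
               roi = interior_roi(sim), condition = cond)
      }
      spec <- spec0; spec$rng_seed <- config$rng_seed + 101L * i + 77L
      base <- simulate_sheet(spec)
      cop <- simulate_crosslink(spec, base)
      sheets[[length(sheets) + 1L]] <-
        list(img_a = cop$img_a, img_b = cop$img_b,
             roi = interior_roi(base), condition = "CoP")
    }
    params$sheets <- sheets
  }
  ref <- if (is.null(params$reference_condition)) "fixed"
         else params$reference_condition
  log <- log_line("reference_condition=%s", ref)
  per <- do.call(rbind, lapply(seq_along(params$sheets), function(i) {
    s <- params$sheets[[i]]
    st <- sheet_stats(s$img_a, s$img_b, s$roi)
    st$condition <- s$condition
    st$sheet <- i
    st
  }))
  norm_pcc <- normalize_to_reference(
    data.frame(condition = per$condition, value = per$pcc), ref)
  norm_rsdm <- normalize_to_reference(
    data.frame(condition = per$condition, value = per$rsdm_a), ref)
  list(tables = list(per_sheet = per,
                     pcc_percent_of_reference = norm_pcc$summary,
                     rsdm_percent_of_reference = norm_rsdm$summary),
       summary = as.list(stats::setNames(
         c(norm_pcc$summary$mean_percent, norm_rsdm$summary$mean_percent),
         c(paste0("pcc_percent_", norm_pcc$summary$condition),
           paste0("rsdm_a_percent_", norm_rsdm$summary$condition)))),
       log = log)
}

#' @rdname run_recipe
#' @export
recipe_frap <- function(config = analysis_config(), params = list()) {
  if (is.null(params$traces)) {
    n_traces <- if (is.null(params$n_traces)) 10L else params$n_traces
    t_half <- if (is.null(params$t_half_s)) 10 else params$t_half_s
    params$traces <- lapply(seq_len(n_traces), function(i)
      simulate_frap(t_half_s = t_half, seed = config$rng_seed + i))
  }
  traces <- lapply(params$traces, function(t) qc_exclude(normalize_trace(t)))
  n_excl <- sum(vapply(traces, function(t) t$excluded, logical(1)))
  avg <- average_traces(traces)
  fit <- fit_recovery(avg)
  log <- c(log_line("n_traces=%d n_excluded=%d qc_max_variation=0.15",
                    length(traces), n_excl),
           log_line("fit bounds: offset,R in [0,1.5]; t_half multistart"))
  tbl <- data.frame(time_s = avg$times_s, normalized = avg$normalized)
  list(tables = list(mean_trace = tbl),
       summary = list(n_traces = length(traces), n_excluded = n_excl,
                      offset = fit$offset,
                      maximal_recovery = fit$maximal_recovery,
                      t_half_s = fit$t_half_s, fit_r2 = fit$r2),
       log = log)
}

#' @rdname run_recipe
#' @export
recipe_wb_cleavage <- function(config = analysis_config(), params = list()) {
  if (is.null(params$bands)) {
    # synthetic three-replicate assay: variant cleaved at 40% of wildtype
    truth <- expand.grid(construct = c("APP", "APP-TMS"),
                         replicate = 1:3, stringsAsFactors = FALSE)
    bands <- do.call(rbind, lapply(seq_len(nrow(truth)), function(i) {
      ratio <- if (truth$construct[i] == "APP") 1.0 else 0.4
      tb <- data.frame(
        lane = c("Ly", "Sn", "Ly", "Ly"),
        band = c("sAPPalpha", "sAPPalpha", "APP_mature", "APP_immature"),
        true_au = c(600 * ratio, 400 * ratio, 600, 400))
      out <- simulate_lanes(tb, background_au = 100, noise_sd = 0.05,
                            seed = config$rng_seed + i * 13L +
                              match(truth$construct[i], c("APP", "APP-TMS")))
      out$construct <- truth$construct[i]
      out$replicate <- truth$replicate[i]
      out
    }))
    params$bands <- bands
  }
  wt <- if (is.null(params$wt_label)) "APP" else params$wt_label
  bands <- band_measurements(params$bands)
  key <- interaction(bands$construct, bands$replicate, drop = TRUE)
  ratios <- do.call(rbind, lapply(split(bands, key), function(g)
    data.frame(construct = g$construct[1], replicate = g$replicate[1],
               ratio = as.numeric(cleavage_ratio(g)))))
  rownames(ratios) <- NULL
  pw <- percent_of_wildtype(ratios, wt)
  summ <- as.list(stats::setNames(pw$summary$mean_percent,
                                  paste0("percent_of_wt_",
                                         pw$summary$construct)))
  list(tables = list(ratios = pw$per_replicate, summary = pw$summary),
       summary = summ,
       log = log_line("wt_label=%s", wt))
}

#' @rdname run_recipe
#' @export
recipe_cleavage_on_sheets <- function(config = analysis_config(),
                                      params = list()) {
  if (is.null(params$sheets)) {
    n_sheets <- if (is.null(params$n_sheets)) 3L else params$n_sheets
    conds <- list(control = 50, cleaved = 20)  # channel-B brightness drops
    sheets <- list()
    for (cond in names(conds)) for (i in seq_len(n_sheets)) {
      spec <- sheet_sim_spec(b_amp_au = conds[[cond]],
                             rng_seed = config$rng_seed + 31L * i +
                               match(cond, names(conds)))
      sim <- simulate_sheet(spec)
      sim$img_a$condition <- cond; sim$img_b$condition <- cond
      d <- dim(sim$img_a$pixels); m <- ceiling(sim$truth$margin_px)
      sheets[[length(sheets) + 1L]] <- list(
        img_a = sim$img_a, img_b = sim$img_b, condition = cond,
        membrane_roi = interior_roi(sim),
        background_roi = roi_rect(0, 0, m - 1, d[2], "background"))
    }
    params$sheets <- sheets
  }
  per <- do.call(rbind, lapply(seq_along(params$sheets), function(i) {
    s <- params$sheets[[i]]
    ma <- corrected_mean(s$img_a, s$membrane_roi, s$background_roi)
    mb <- corrected_mean(s$img_b, s$membrane_roi, s$background_roi)
    data.frame(sheet = i, condition = s$condition, mean_a = ma,
               mean_b = mb, ratio_b_over_a = mb / ma)
  }))
  agg <- do.call(rbind, lapply(split(per, per$condition), function(g)
    data.frame(condition = g$condition[1], n = nrow(g),
               mean_ratio = mean(g$ratio_b_over_a),
               sd_ratio = stats::sd(g$ratio_b_over_a))))
  rownames(agg) <- NULL
  list(tables = list(per_sheet = per, summary = agg),
       summary = as.list(stats::setNames(agg$mean_ratio,
                                         paste0("ratio_", agg$condition))),
       log = log_line("ratio = corrected mean(B) / corrected mean(A)"))
}

#' @rdname run_recipe
#' @export
recipe_inhibitor_intensity <- function(config = analysis_config(),
                                       params = list()) {
  if (is.null(params$sheets)) {
    n_sheets <- if (is.null(params$n_sheets)) 3L else params$n_sheets
    conds <- list(control = 50, inhibitor = 80)  # cleavage block retains signal
    sheets <- list()
    for (cond in names(conds)) for (i in seq_len(n_sheets)) {
      spec <- sheet_sim_spec(b_amp_au = conds[[cond]],
                             rng_seed = config$rng_seed + 17L * i +
                               match(cond, names(conds)))
      sim <- simulate_sheet(spec)
      d <- dim(sim$img_b$pixels); m <- ceiling(sim$truth$margin_px)
      sheets[[length(sheets) + 1L]] <- list(
        img = sim$img_b, condition = cond,
        membrane_roi = interior_roi(sim),
        background_roi = roi_rect(0, 0, m - 1, d[2], "background"))
    }
    params$sheets <- sheets
  }
  ref <- if (is.null(params$reference_condition)) "control"
         else params$reference_condition
  per <- do.call(rbind, lapply(seq_along(params$sheets), function(i) {
    s <- params$sheets[[i]]
    data.frame(sheet = i, condition = s$condition,
               value = corrected_mean(s$img, s$membrane_roi,
                                      s$background_roi))
  }))
  norm <- normalize_to_reference(per[, c("condition", "value")], ref)
  list(tables = list(per_sheet = per, summary = norm$summary),
       summary = as.list(stats::setNames(
         norm$summary$mean_percent,
         paste0("percent_", norm$summary$condition))),
       log = log_line("reference_condition=%s", ref))
}
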