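#' End-to-end pipeline reports
#'
#' The two headline products: a per-occupation climate report (mid-age and
#' range extrema for every variable, regional comparison tests, coefficients
#' of variation, dating-uncertainty sensitivity summaries) and a
#' predictability report (occupation- and site-level CVD percentages with
#' regional comparisons of the variability percentage).
#'
#' @name pipeline
NULL

default_variables <- function() c("bio01", "bio04", "bio12", "bio15", "npp")
cvd_variables <- function() c("bio01", "bio12", "npp")

#' Per-occupation climate report
#'
#' @param cube a `climate_cube`.
#' @param occs deduplicated occupation data.frame.
#' @param variables variables to report (default all five).
#' @param tests tests for the regional comparisons.
#' @param n_iter sensitivity permutation iterations (0 disables the stage).
#' @param seed root seed for the sensitivity permutations.
#' @param alpha significance level.
#' @return list with `values` (per-occupation mid/min/max per variable),
#'   `comparisons` (per variable x test), `cv` (per region x variable), and
#'   `sensitivity` (per variable x test summaries), plus collected warnings.
#' @export
run_occupation_report <- function(cube, occs, variables = default_variables(),
                                  tests = c("MANN_WHITNEY", "ANSARI_BRADLEY"),
                                  n_iter = 1000, seed = 1, alpha = 0.05) {
  if (is.null(occs$occ_id))
    occs$occ_id <- paste(occs$site_id, occs$layer_id, sep = ":")
  warn <- character()
  vals <- list()
  for (v in variables) {
    for (i in seq_len(nrow(occs))) {
      occ <- occs[i, ]
      s <- extract_occupation_series(cube, v, occ)
      vals[[length(vals) + 1L]] <- data.frame(
        occ_id = occ$occ_id, site_id = occ$site_id, region = occ$region,
        variable = v, age_mid = occ$age_mid,
        value_mid = extract_mid_value(cube, v, occ),
        value_min = min(s$values), value_max = max(s$values),
        stringsAsFactors = FALSE)
    }
  }
  values <- do.call(rbind, vals)
  comparisons <- list(); cv <- list(); sensitivity <- list()
  for (v in variables) {
    g <- values[values$variable == v, ]
    by_region <- split(g$value_mid, g$region)
    for (te in tests) {
      res <- compare_regions(by_region, te, alpha)
      comparisons[[length(comparisons) + 1L]] <- data.frame(
        variable = v, test = te, statistic = res$statistic,
        p_value = res$p_value, n_east = res$n_a, n_northwest = res$n_b,
        significant = res$significant, stringsAsFactors = FALSE)
    }
    for (reg in names(by_region)) {
      cv_val <- tryCatch(coef_variation(by_region[[reg]]), error = function(e) NA_real_)
      if (is.finite(cv_val) && abs(mean(by_region[[reg]])) <
            stats::sd(by_region[[reg]]) / 10)
        warn <- c(warn, paste0("near-zero-mean CV for ", v, " in ", reg))
      cv[[length(cv) + 1L]] <- data.frame(variable = v, region = reg,
                                          cv_percent = cv_val,
                                          stringsAsFactors = FALSE)
    }
    if (n_iter > 0) for (te in tests) {
      sr <- sensitivity_permutation(occs, cube, v, te, n_iter = n_iter,
                                    seed = seed, alpha = alpha)
      sensitivity[[length(sensitivity) + 1L]] <- data.frame(
        variable = v, test = te, n_iter = sr$n_iter,
        n_significant = sr$n_significant,
        mid_age_statistic = sr$mid_age_statistic, mid_age_p = sr$mid_age_p,
        percentile_of_mid_statistic = sr$percentile_of_mid_statistic,
        stringsAsFactors = FALSE)
    }
  }
  list(values = values,
       comparisons = do.call(rbind, comparisons),
       cv = do.call(rbind, cv),
       sensitivity = if (length(sensitivity)) do.call(rbind, sensitivity) else NULL,
       warnings = warn)
}

cvd_rows <- function(cube, tab, variables, M, alpha, level,
                     id_col, lo_col, hi_col) {
  out <- list()
  for (i in seq_len(nrow(tab))) {
    row <- tab[i, ]
    occ <- list(site_id = row[[id_col]], lon = row$lon, lat = row$lat,
                age_min = row[[lo_col]], age_max = row[[hi_col]])
    for (v in variables) {
      s <- extract_occupation_series(cube, v, occ)
      res <- suppressWarnings(cvd_decompose(s$values, M = M, alpha = alpha,
                                            quiet = TRUE))
      out[[length(out) + 1L]] <- data.frame(
        level = level, id = as.character(row[[id_col]]), region = row$region,
        variable = v, n = res$N, w = res$w,
        pct_change = res$pct_change, pct_variability = res$pct_variability,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Climate predictability report
#'
#' Occupation-level CVD for occupations whose own date range covers at
#' least one precession cycle (`age_max - age_min >= cycle_ka`), site-level
#' CVD for sites whose combined span does, and regional comparisons
#' (Mann-Whitney and Ansari-Bradley) of the variability percentage at each
#' level for each variable.
#'
#' @param cube a `climate_cube`.
#' @param occs deduplicated occupation data.frame.
#' @param sites site table from [site_spans()] (computed from `occs` when
#'   omitted).
#' @param variables CVD variables (default bio01, bio12, npp).
#' @param M,alpha CVD parameters.
#' @param cycle_ka eligibility span (default 23).
#' @return list with `occupation_cvd`, `site_cvd`, `comparisons`.
#' @export
run_predictability_report <- function(cube, occs, sites = NULL,
                                      variables = cvd_variables(),
                                      M = 23, alpha = 0.05, cycle_ka = 23) {
  if (is.null(sites)) sites <- site_spans(occs, cycle_ka)
  if (is.null(occs$occ_id))
    occs$occ_id <- paste(occs$site_id, occs$layer_id, sep = ":")
  occ_elig <- occs[(occs$age_max - occs$age_min) >= cycle_ka, , drop = FALSE]
  site_elig <- sites[sites$covers_precession, , drop = FALSE]
  occ_cvd <- if (nrow(occ_elig))
    cvd_rows(cube, occ_elig, variables, M, alpha, "occupation",
             "occ_id", "age_min", "age_max") else NULL
  site_cvd <- if (nrow(site_elig))
    cvd_rows(cube, site_elig, variables, M, alpha, "site",
             "site_id", "span_min", "span_max") else NULL
  comparisons <- list()
  for (tab_name in c("occupation", "site")) {
    tab <- if (tab_name == "occupation") occ_cvd else site_cvd
    if (is.null(tab)) next
    for (v in variables) {
      g <- tab[tab$variable == v, ]
      by_region <- split(g$pct_variability, g$region)
      if (!all(c("EAST", "NORTHWEST") %in% names(by_region))) next
      if (any(lengths(by_region) < 2)) next
      for (te in c("MANN_WHITNEY", "ANSARI_BRADLEY")) {
        res <- compare_regions(by_region, te, alpha)
        comparisons[[length(comparisons) + 1L]] <- data.frame(
          level = tab_name, variable = v, test = te,
          statistic = res$statistic, p_value = res$p_value,
          mean_pct_variability_east = mean(by_region$EAST),
          mean_pct_variability_northwest = mean(by_region$NORTHWEST),
          significant = res$significant, stringsAsFactors = FALSE)
      }
    }
  }
  list(occupation_cvd = occ_cvd, site_cvd = site_cvd,
       comparisons = if (length(comparisons)) do.call(rbind, comparisons) else NULL)
}

#' Run the full pipeline on synthetic data
#'
#' `simulate -> normalize/dedupe -> occupation report -> predictability
#' report`, writing CSV outputs and a run manifest (config hash, seed,
#' package version, stage timings, collected warnings) when `out_dir` is
#' given. Fully reproducible under a fixed seed.
#'
#' @param config a [generator_config()].
#' @param out_dir optional output directory.
#' @param n_iter sensitivity iterations (default 200 to keep desk runs
#'   quick; the study-scale value is 1000).
#' @param M,alpha CVD parameters.
#' @param seed root seed (overrides `config$seed`).
#' @return list with `cube`, `truth`, `occupations`, `sites`,
#'   `occupation_report`, `predictability_report`, `manifest`.
#' @export
run_all <- function(config = generator_config(), out_dir = NULL,
                    n_iter = 200, M = 23, alpha = 0.05, seed = NULL) {
  if (is.null(seed)) seed <- config$seed
  timings <- c()
  tic <- function() proc.time()[["elapsed"]]
  t0 <- tic()
  sim <- make_climate_cube(config, seed = seed)
  occs_raw <- make_occupations(config, sim$cube, seed = seed)
  timings["simulate"] <- tic() - t0; t0 <- tic()
  occs <- dedupe_occupations(normalize_occupations(occs_raw))
  sites <- site_spans(occs)
  timings["occupations"] <- tic() - t0; t0 <- tic()
  occ_rep <- run_occupation_report(sim$cube, occs, n_iter = n_iter,
                                   seed = seed, alpha = alpha)
  timings["occupation_report"] <- tic() - t0; t0 <- tic()
  pred_rep <- run_predictability_report(sim$cube, occs, sites, M = M,
                                        alpha = alpha)
  timings["predictability_report"] <- tic() - t0
  cfg_json <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA)
  tmp <- tempfile(); writeLines(cfg_json, tmp)
  manifest <- list(package_version = as.character(utils::packageVersion("paleocvd")),
                   r_version = R.version.string,
                   seed = seed, config_hash = unname(tools::md5sum(tmp)),
                   n_iter = n_iter, M = M, alpha = alpha,
                   timings_s = as.list(round(timings, 3)),
                   warnings = occ_rep$warnings)
  unlink(tmp)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(occs, file.path(out_dir, "occupations.csv"), row.names = FALSE)
    utils::write.csv(sites, file.path(out_dir, "sites.csv"), row.names = FALSE)
    utils::write.csv(occ_rep$values, file.path(out_dir, "occupation_values.csv"),
                     row.names = FALSE)
    utils::write.csv(occ_rep$comparisons, file.path(out_dir, "comparisons.csv"),
                     row.names = FALSE)
    utils::write.csv(occ_rep$cv, file.path(out_dir, "cv.csv"), row.names = FALSE)
    if (!is.null(occ_rep$sensitivity))
      utils::write.csv(occ_rep$sensitivity, file.path(out_dir, "sensitivity.csv"),
                       row.names = FALSE)
    if (!is.null(pred_rep$occupation_cvd))
      utils::write.csv(pred_rep$occupation_cvd,
                       file.path(out_dir, "occupation_cvd.csv"), row.names = FALSE)
    if (!is.null(pred_rep$site_cvd))
      utils::write.csv(pred_rep$site_cvd, file.path(out_dir, "site_cvd.csv"),
                       row.names = FALSE)
    if (!is.null(pred_rep$comparisons))
      utils::write.csv(pred_rep$comparisons,
                       file.path(out_dir, "cvd_comparisons.csv"), row.names = FALSE)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(cube = sim$cube, truth = sim$truth, occupations = occs, sites = sites,
       occupation_report = occ_rep, predictability_report = pred_rep,
       manifest = manifest)
}
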