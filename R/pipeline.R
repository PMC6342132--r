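# End-to-end orchestration: simulate -> mask -> SECR -> RSF -> compare.

#' Configure an end-to-end pipeline run
#'
#' @param sim A [sim_config()] describing the synthetic world and survey.
#' @param truth Named list of [true_params()] per sex to analyze (any subset
#'   of `"F"`, `"M"`).
#' @param mask_spacing SECR mask spacing in km (field convention 2.5).
#' @param buffer Mask buffer in km, or `NULL` for 3 x RPSV per sex.
#' @param step1,step2 Candidate sets for [run_two_step()].
#' @param distribution `"poisson"` or `"binomial"` SECR likelihood.
#' @param rsf_formulas Candidate RSF formulas for [select_rsf()].
#' @param global_rsf_formula Formula for the global placement-bias RSF.
#' @param mcp_buffer_km Buffer around the detector MCP (field default 2.4).
#' @param available_ratio Available:used ratio for the placement RSF.
#' @param drop_lowest Lowest global-RSF bins excluded from the area of
#'   inference.
#' @param reference Named list per sex of arguments to
#'   [reference_estimate()] *without* `area` (density, lo, hi per 1,000
#'   km^2), or `NULL` to skip the RSF extrapolation.
#' @param reference_region Tenure class serving as the reference area.
#' @param seed Master seed; every stage seed derives from it.
#' @return A `run_config` list.
#' @export
run_config <- function(sim = sim_config(),
                       truth = list(F = true_params(sex = "F")),
                       mask_spacing = 2.5,
                       buffer = NULL,
                       step1 = list(secr_model(~traptype, ~1), secr_model(~1, ~1)),
                       step2 = list(~tenure),
                       distribution = "poisson",
                       rsf_formulas = rsf_candidates()[c(1, 5, 7)],
                       global_rsf_formula = ~ ndvi + canopy + water + tertiary_rd + rddens,
                       mcp_buffer_km = 2.4,
                       available_ratio = 20,
                       drop_lowest = 3,
                       reference = list(F = list(density = 72.3, lo = 60.3, hi = 87.5),
                                        M = list(density = 48.3, lo = 40.2, hi = 57.3)),
                       reference_region = "protected",
                       seed = 1L) {
  structure(as.list(environment()), class = "run_config")
}

#' Run the full dual-estimation pipeline
#'
#' Simulates the world, builds per-sex SECR masks (3 x RPSV buffer), runs
#' two-step SECR selection and region abundance by tenure, fits the global
#' placement-bias RSF to define the area of inference, fits per-sex RSFs,
#' extrapolates the reference-area abundance over habitat bins, and writes
#' every artifact plus a side-by-side SECR-vs-RSF comparison to `out_dir`.
#' The run is a pure function of (config, seed): identical configs give
#' byte-identical outputs.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the comparison `report` tibble, per-sex
#'   fits, tables and the run log. A stage failure aborts with the stage
#'   name; artifacts written so far are kept.
#' @export
run_pipeline <- function(config, out_dir = tempfile("ursadens_run_")) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log <- list(package = "ursadens",
              version = as.character(utils::packageVersion("ursadens")),
              seed = config$seed, stages = list())
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }
  wt <- function(x, f) readr::write_tsv(x, file.path(out_dir, f))

  landscape <- stage("simulate-landscape", sim_landscape(config$sim))
  detectors <- stage("simulate-detectors", sim_detectors(landscape, config$sim))
  wt(tibble::as_tibble(landscape), "landscape.tsv")
  wt(detectors, "detectors.tsv")

  sexes <- names(config$truth)
  caps <- list()
  for (sx in sexes) {
    pop <- stage(paste0("simulate-population-", sx),
                 sim_population(landscape, config$truth[[sx]],
                                seed = config$seed * 10L + match(sx, c("F", "M"))))
    caps[[sx]] <- stage(paste0("simulate-captures-", sx),
                        sim_captures(pop, detectors, config$truth[[sx]],
                                     seed = config$seed * 10L + 4L + match(sx, c("F", "M"))))
    wt(caps[[sx]], paste0("captures_", sx, ".tsv"))
    log$stages[[paste0("sim_", sx)]] <- list(
      n_true = attr(pop, "N_true"), n_detected = attr(caps[[sx]], "n_detected"))
  }

  covariate_names <- setdiff(names(landscape), c("x", "y"))
  secr_rows <- list(); secr_fits <- list(); masks <- list()
  for (sx in sexes) {
    buf <- config$buffer %||% (3 * rpsv(caps[[sx]], detectors))
    mask <- stage(paste0("mask-", sx), {
      m <- build_mask(detectors, buf, config$mask_spacing)
      m <- clip_mask(m, c(0, config$sim$extent[1]), c(0, config$sim$extent[2]))
      attach_covariates(m, setNames(
        lapply(covariate_names, function(v) landscape[c("x", "y", v)]),
        covariate_names))
    })
    masks[[sx]] <- mask
    wt(tibble::as_tibble(mask), paste0("mask_", sx, ".tsv"))
    two <- stage(paste0("secr-", sx),
                 run_two_step(caps[[sx]], detectors, mask,
                              step1 = config$step1, step2 = config$step2,
                              distribution = config$distribution))
    secr_fits[[sx]] <- two
    readr::write_csv(two$step1_table, file.path(out_dir, paste0("secr_step1_", sx, ".csv")))
    readr::write_csv(two$step2_table, file.path(out_dir, paste0("secr_step2_", sx, ".csv")))
    write_fit_json(two$best_fit, file.path(out_dir, paste0("secr_fit_", sx, ".json")))
    surf <- predict_density(two$best_fit, mask, per_1000 = TRUE)
    wt(surf, paste0("secr_surface_", sx, ".tsv"))
    ra <- region_abundance(two$best_fit, mask, region = "tenure",
                           seed = config$seed * 10L + 8L)
    secr_rows[[sx]] <- dplyr::mutate(
      ra, method = "SECR", sex = sx,
      density = 1000 * N_hat / area,
      lo_density = 1000 * lo / area, hi_density = 1000 * hi / area)
  }

  # Global placement-bias RSF over the detector array.
  rub_pts <- detectors[detectors$type != "opp", c("x", "y")]
  report_rows <- dplyr::bind_rows(secr_rows)
  rsf_out <- NULL
  if (!is.null(config[["reference"]])) {
    rsf_out <- stage("rsf", {
      dom <- mcp_buffer(rub_pts, config$mcp_buffer_km)
      write_geojson(dom, file.path(out_dir, "mcp.geojson"),
                    properties = list(buffer_km = config$mcp_buffer_km))
      avail <- sample_available(dom, nrow(rub_pts), config$available_ratio,
                                seed = config$seed * 10L + 3L)
      # keep random points on the mapped landscape
      ext <- config$sim$extent
      avail <- avail[avail$x >= 0 & avail$x <= ext[1] &
                       avail$y >= 0 & avail$y <= ext[2], ]
      lc_cov <- function(pts) attach_covariates(
        new_mask_grid(pts, mask_spacing(landscape)),
        setNames(lapply(covariate_names, function(v) landscape[c("x", "y", v)]),
                 covariate_names))
      used_g <- lc_cov(rub_pts)
      avail_g <- lc_cov(avail)
      global <- fit_rsf(used_g, avail_g, config$global_rsf_formula)
      inside <- in_mcp(dom, landscape$x, landscape$y)
      cells <- tibble::as_tibble(landscape)[inside, ]
      gbins <- bin_scores(predict_rsf(global, cells), cell_area(landscape))
      keep <- area_of_inference(gbins, config$drop_lowest)
      aoi <- cells[keep, ]
      wt(aoi[c("x", "y")], "area_of_inference.tsv")

      per_sex <- list()
      for (sx in sexes) {
        used_det <- detectors[detectors$detector %in% caps[[sx]]$detector &
                                detectors$type != "opp", c("x", "y")]
        if (nrow(used_det) == 0) next
        sel <- select_rsf(config$rsf_formulas, lc_cov(used_det), used_g)
        readr::write_csv(sel$table, file.path(out_dir, paste0("rsf_aic_", sx, ".csv")))
        sc_aoi <- predict_rsf(sel$model, aoi)
        ref_cells <- cells[cells$tenure == config$reference_region, ]
        if (nrow(ref_cells) == 0) abort("reference region has no cells in the availability domain")
        ref <- reference_estimate(
          density = config[["reference"]][[sx]]$density,
          lo = config[["reference"]][[sx]]$lo, hi = config[["reference"]][[sx]]$hi,
          area = nrow(ref_cells) * cell_area(landscape), sex = sx)
        mx <- max(predict_rsf(sel$model, ref_cells))
        rbins <- bin_scores(predict_rsf(sel$model, ref_cells),
                            cell_area(landscape))
        # Target cells binned on the reference scaling so bins correspond.
        tbin <- pmax(1L, pmin(10L, as.integer(ceiling(sc_aoi / mx * 10))))
        ex <- extrapolate_density(ref, rbins, tbin)
        readr::write_csv(ex$bins, file.path(out_dir, paste0("rsf_bins_", sx, ".csv")))
        cells_sx <- dplyr::bind_cols(aoi[c("x", "y", "tenure")], ex$cells)
        wt(cells_sx, paste0("rsf_surface_", sx, ".tsv"))
        a <- cell_area(landscape)
        per_sex[[sx]] <- cells_sx |>
          dplyr::group_by(region = tenure) |>
          dplyr::summarise(
            area = dplyr::n() * a,
            N_hat = sum(density) * a / 1000,
            lo = sum(lo) * a / 1000, hi = sum(hi) * a / 1000,
            density = 1000 * N_hat / area,
            lo_density = 1000 * lo / area, hi_density = 1000 * hi / area,
            .groups = "drop") |>
          dplyr::mutate(method = "RSF", sex = sx)
      }
      dplyr::bind_rows(per_sex)
    })
    report_rows <- dplyr::bind_rows(report_rows, rsf_out)
  } else {
    inform("no reference estimate configured; RSF extrapolation skipped")
  }

  report <- report_rows |>
    dplyr::mutate(region = as.character(region)) |>
    dplyr::select(method, sex, region, area, N_hat, lo, hi,
                  density, lo_density, hi_density) |>
    dplyr::arrange(method, sex, region)
  ratios <- tryCatch(
    report |> dplyr::group_by(method) |>
      dplyr::group_modify(~ sex_ratio(.x)) |> dplyr::ungroup(),
    error = function(e) NULL
  )
  readr::write_csv(report, file.path(out_dir, "comparison_report.csv"))
  if (!is.null(ratios)) readr::write_csv(ratios, file.path(out_dir, "sex_ratios.csv"))
  log$stages$report <- list(rows = nrow(report))
  jsonlite::write_json(log, file.path(out_dir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(report = report, sex_ratios = ratios, secr = secr_fits,
                 masks = masks, captures = caps, out_dir = out_dir, log = log))
}

write_fit_json <- function(fit, path) {
  jsonlite::write_json(
    list(model = model_label(fit$model),
         distribution = fit$distribution,
         coefficients = as.list(fit$coefficients),
         vcov = fit$vcov, logLik = fit$logLik, K = fit$K, n = fit$n,
         AICc = fit$AICc, Lambda = fit$Lambda, rse = fit$rse,
         converged = fit$converged),
    path, auto_unbox = TRUE, digits = 10)
  invisible(path)
}

#' Female-to-male abundance ratio per region
#'
#' @param report Tibble with columns `sex` (`"F"`/`"M"`), `region` and
#'   `N_hat` (abundance point estimates).
#' @param digits Rounding of the reported ratio (default 1 decimal).
#' @return Tibble `region`, `ratio` (F/M).
#' @export
sex_ratio <- function(report, digits = 1) {
  need <- c("sex", "region", "N_hat")
  stopifnot(all(need %in% names(report)))
  wide <- report |>
    dplyr::select(sex, region, N_hat) |>
    tidyr::pivot_wider(names_from = sex, values_from = N_hat)
  if (!all(c("F", "M") %in% names(wide))) {
    abort("both sexes must be present to compute F/M ratios")
  }
  if (any(is.na(wide$F)) || any(is.na(wide$M))) {
    abort("both sexes must be present in every region")
  }
  if (any(wide$M == 0)) abort("male abundance is zero in at least one region")
  tibble::tibble(region = as.character(wide$region),
                 ratio = round(wide$F / wide$M, digits))
}
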