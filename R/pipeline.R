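#' Run the full analysis pipeline from a config
#'
#' Orchestrates simulate -> SEC-SAXS reduction -> Guinier -> P(r) ->
#' envelope -> dual-space validation on one configuration, writing every
#' stage product plus a consolidated JSON report into a report directory.
#' The config is a named list (or a path to a YAML/JSON file) with
#' optional stage blocks:
#'
#' * `simulate`: `preset` (`"sphere"`, `"dumbbell"`, `"nsd3"`),
#'   `noise_a`, `noise_b`, `secsaxs = TRUE` to go through a simulated
#'   elution (frame selection + buffer subtraction) instead of a single
#'   curve.
#' * `curve`: path to a measured `.dat` file (alternative to `simulate`).
#' * `pr`: `dmax` (number or `"auto"`).
#' * `envelope`: `n_runs`, `refine` (logical).
#' * `validate`: `model` = path to a PDB file, or `"truth"` for the
#'   simulated generator model (requires `simulate`).
#' * `seed`: base seed for every stochastic stage.
#'
#' @param config named list or path to a YAML/JSON config file.
#' @param out_dir report directory (created); default `tempfile()`.
#' @return the report list, invisibly; the same content is written to
#'   `out_dir/report.json`.
#' @export
run_pipeline <- function(config, out_dir = tempfile("saxstruct_report_")) {
  if (is.character(config)) {
    config <- if (grepl("[.]json$", config)) jsonlite::read_json(config, simplifyVector = TRUE)
    else yaml::read_yaml(config)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed %||% 1
  report <- list(schema_version = "1.0", seed = seed, stages = list())
  truth_model <- NULL

  # --- input stage: simulate or load ------------------------------------
  if (!is.null(config$simulate)) {
    sm <- config$simulate
    truth_model <- toy_preset(sm$preset %||% "sphere", seed = seed)
    if (isTRUE(sm$secsaxs)) {
      series <- simulate_secsaxs(
        list(list(model = truth_model, center = sm$center %||% 60,
                  width = sm$width %||% 8, amplitude = sm$amplitude %||% 100)),
        n_frames = sm$n_frames %||% 100, buffer_level = sm$buffer_level %||% 1,
        noise_a = sm$noise_a %||% 0.01, noise_b = sm$noise_b %||% 4,
        seed = seed)
      chr <- chromatogram(series)
      buf <- auto_buffer_frames(series)
      bpos <- match(buf, series$frame_index)
      bcurve <- saxs_curve(series$q,
                           colMeans(series_matrix(series)[bpos, , drop = FALSE]))
      rgv <- frame_rg(series, bcurve)
      peak <- which(chr > stats::median(chr) + 0.5 * (max(chr) - stats::median(chr)))
      win <- select_window(series, rgv, peak)
      curve <- average_and_subtract(series, win, buf)
      report$stages$secsaxs <- list(
        window = list(first_frame = win$first_frame, last_frame = win$last_frame,
                      n_frames = win$n_frames, mean_rg = win$mean_rg,
                      sigma_rg = win$sigma_rg, fallback = win$fallback),
        n_buffer_frames = length(buf))
    } else {
      curve <- simulate_curve(truth_model, i0_scale = sm$i0 %||% 100,
                              noise_a = sm$noise_a %||% 0.01,
                              noise_b = sm$noise_b %||% 4, seed = seed)
    }
    report$stages$simulate <- list(preset = sm$preset %||% "sphere",
                                   truth = attr(truth_model, "truth")[c("rg", "dmax")],
                                   seed = seed)
  } else if (!is.null(config$curve)) {
    curve <- read_dat(config$curve)
  } else stop("config must name an input: 'simulate' or 'curve'")
  write_dat(curve, file.path(out_dir, "curve.dat"))

  # --- reciprocal- and real-space size analysis -------------------------
  g <- guinier_fit(curve)
  report$stages$guinier <- list(rg = g$rg, rg_se = g$rg_se, i0 = g$i0,
                                q_range = g$q_range_used, n_points = g$n_points)
  pr_cfg <- config$pr %||% list()
  if (is.null(pr_cfg$dmax) || identical(pr_cfg$dmax, "auto")) {
    fd <- find_dmax(curve)
    dd <- fd$dd
  } else {
    dd <- ift(curve, pr_cfg$dmax)
  }
  qual <- pr_quality(dd)
  mw <- tryCatch(estimate_mw(curve, dd), error = function(e) list(mw_kda = NA))
  report$stages$pr <- list(dmax = dd$dmax, rg_real = dd$rg_real,
                           i0_real = dd$i0_real, fit_chi2 = dd$fit_chi2,
                           alpha = dd$alpha, quality = qual$score,
                           mw_kda = mw$mw_kda)
  jsonlite::write_json(list(r = dd$r, p = dd$p, dmax = dd$dmax,
                            rg_real = dd$rg_real, quality = qual$score),
                       file.path(out_dir, "pr.json"),
                       auto_unbox = TRUE, digits = NA)

  # --- envelope reconstruction ------------------------------------------
  env <- NULL
  if (!is.null(config$envelope)) {
    ec <- config$envelope
    runs <- anneal_beads(curve, dd, n_runs = ec$n_runs %||% 20, seed = seed)
    avg <- average_models(runs)
    env <- if (isTRUE(ec$refine)) refine_beads(avg$model, curve, seed = seed)
    else avg$model
    write_model(env, file.path(out_dir, "envelope.pdb"))
    report$stages$envelope <- list(
      n_runs = ec$n_runs %||% 20, mean_pairwise_nsd = avg$mean_nsd,
      excluded = avg$excluded, n_beads = nrow(env$centers),
      chi2 = attr(runs[[1]], "fit")$chi2, seed = seed)
  }

  # --- dual-space validation --------------------------------------------
  if (!is.null(config$validate)) {
    vc <- config$validate
    vmodel <- if (identical(vc$model %||% "truth", "truth")) {
      if (is.null(truth_model)) stop("validate stage: no model (no simulate stage and no model path)")
      truth_model
    } else read_model(vc$model)
    if (is.null(env)) stop("validate stage: missing envelope stage input")
    fr <- validate_dual(vmodel, curve, env)
    report$stages$validate <- list(chi2 = fr$chi2, nsd = fr$nsd,
                                   n_points = fr$n_points)
  }

  report$consistency <- list(
    rg_reciprocal = g$rg, rg_direct = dd$rg_real,
    rg_rel_diff = abs(g$rg - dd$rg_real) / g$rg)
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}
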