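#' Configuration for the end-to-end pipeline
#'
#' Collects the knobs of every stage: simulation sizes, basis grids,
#' thresholds and the master seed. All stage seeds are derived
#' deterministically from `seed`, so identical configurations give
#' identical reports.
#'
#' @param n_subjects Subjects to simulate.
#' @param n_runs Runs per subject.
#' @param n_volumes,tr_seconds Run geometry.
#' @param grid_shape Phantom voxel grid.
#' @param alpha_grid,tau_grid Basis search grids (seconds).
#' @param L Basis order.
#' @param memory_s Basis memory (seconds).
#' @param cdt_z Cluster defining threshold preset (4.5, 3.1 or 2.3).
#' @param alpha FWER level.
#' @param fdr_q FDR level.
#' @param n_permutations Sign-flip permutations.
#' @param visit_times Cohort visit schedule (years).
#' @param cohort_betas Planted coefficients, [eq_betas()] overrides.
#' @param seed Master seed.
#' @param output_dir Optional directory; when given, stage outputs are
#'   written there (NIfTI maps, TSV tables, YAML config echo, JSON report).
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(n_subjects = 8, n_runs = 6, n_volumes = 127,
                            tr_seconds = 2, grid_shape = c(12, 12, 8),
                            alpha_grid = c(0.5, 1, 1.5), tau_grid = c(0, 1, 2),
                            L = 2, memory_s = 24,
                            cdt_z = 3.1, alpha = 0.05, fdr_q = 0.05,
                            n_permutations = 200,
                            visit_times = 0:4,
                            cohort_betas = c(beta_a_time = 0.1,
                                             beta_ab_time = 0.2),
                            seed = 1, output_dir = NULL) {
  stopifnot(n_subjects >= 2, n_runs >= 2, n_volumes > 0, tr_seconds > 0,
            length(alpha_grid) >= 1, length(tau_grid) >= 1, L >= 1,
            cdt_z > 0, alpha > 0, alpha < 1, fdr_q > 0, fdr_q < 1)
  if (!is.null(output_dir) && !dir.exists(output_dir))
    dir.create(output_dir, recursive = TRUE)
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full analysis chain on synthetic data
#'
#' Executes simulate -> preprocess -> HRF estimation -> activation GLM +
#' gPPI -> longitudinal group model, entirely from the configuration:
#' \enumerate{
#'   \item simulate per-subject multi-run BOLD phantoms with planted
#'     condition amplitudes and gPPI coupling;
#'   \item scrub high-DVARS volumes, regress out the 30-column confound
#'     set, and report the seed-ventricle diagnostic;
#'   \item estimate each subject's basis parameters and condition HRFs by
#'     the two-step grid-search scheme, plus the group HRF shape (PC1);
#'   \item compute per-subject activation and gPPI contrasts;
#'   \item simulate a longitudinal cohort whose imaging predictor is the
#'     subjects' activation contrast, fit the three-way moderation model,
#'     and run simple slopes + floodlight over the amyloid range.
#' }
#'
#' @param config A [pipeline_config()].
#' @return A `pipeline_report` list (also written as JSON when
#'   `output_dir` is set).
#' @export
run_pipeline <- function(config) {
  cfg <- config
  designs <- make_task_design(cfg$tr_seconds, cfg$n_runs,
                              n_volumes = cfg$n_volumes)
  dt <- cfg$tr_seconds
  hrf_true <- make_ground_truth_hrf("double-gamma", list(amplitude = 1),
                                    dt = dt, memory_s = cfg$memory_s)
  hrf_rep_true <- make_ground_truth_hrf("double-gamma",
                                        list(amplitude = 0.6),
                                        dt = dt, memory_s = cfg$memory_s)
  masks <- make_phantom_masks(cfg$grid_shape)

  subj_contrast <- numeric(cfg$n_subjects)
  subj_fc <- numeric(cfg$n_subjects)
  subj_alpha <- numeric(cfg$n_subjects)
  subj_tau <- numeric(cfg$n_subjects)
  seed_vent_r <- numeric(cfg$n_subjects)
  hrf_curves <- vector("list", cfg$n_subjects)

  for (s in seq_len(cfg$n_subjects)) {
    gt <- make_ground_truth(hrf_true, hrf_rep_true, beta_nov = 1,
                            beta_rep = 0.6, coupling_nov = 0.6,
                            coupling_rep = 0.2, white_sd = 0.3, ar1 = 0.3)
    runs <- lapply(seq_len(cfg$n_runs), function(r)
      simulate_bold_run(designs[[r]], gt, masks,
                        seed = child_seed(cfg$seed, s * 100 + r)))
    # fixed preprocessing order: scrub -> nuisance regression -> smoothing
    prepped <- lapply(runs, function(run) {
      scrub <- dvars_scrub(run$bold, mask = run$masks$brain)
      conf <- build_confounds(run$confounds[, c("vent4", "latvent", "wm")],
                              run$confounds[, paste0("mot", 1:6)])
      clean <- nuisance_regress(run$bold, conf)
      smoothed <- ellipsoid_smooth(clean, c(2, 2, 4), c(1, 1, 1))
      list(bold = smoothed, scrub = scrub)
    })
    seed_ts <- lapply(prepped, function(p) roi_mean_series(p$bold, masks$seed))
    vent_ts <- lapply(prepped, function(p) roi_mean_series(p$bold, masks$vent4))
    seed_vent_r[s] <- mean(mapply(seed_ventricle_correlation, seed_ts, vent_ts))

    est <- estimate_hrf_twostep(seed_ts, seed_ts, designs, L = cfg$L,
                                alpha_grid = cfg$alpha_grid,
                                tau_grid = cfg$tau_grid,
                                memory_s = cfg$memory_s)
    subj_alpha[s] <- est$alpha
    subj_tau[s] <- est$tau
    hn <- est$estimates[[1]]$hrf_nov
    hr <- est$estimates[[1]]$hrf_rep
    hrf_curves[[s]] <- hn$h
    act <- fit_condition_glm(seed_ts, designs, hn$h, hr$h)
    subj_contrast[s] <- act$contrast

    target_ts <- lapply(prepped, function(p) roi_mean_series(p$bold, masks$target))
    fc <- mapply(function(st, tt, d) {
      gp <- build_gppi_design(st, d, hn$h)
      fit_gppi(tt, gp)$fc_contrast
    }, seed_ts, target_ts, designs)
    subj_fc[s] <- mean(fc)
  }

  group_shape <- group_hrf_shape(hrf_curves)
  # imaging predictor: the measured activation contrast per subject
  cohort <- simulate_cohort(n_subjects = cfg$n_subjects,
                            betas = eq_betas(cfg$cohort_betas),
                            predA_values = subj_contrast,
                            visit_times = cfg$visit_times,
                            seed = child_seed(cfg$seed, 7))
  lfit <- fit_lme_cohort(cohort, lme_spec("ii"))
  fl <- floodlight(lfit, "predA:time", "predA:predB:time",
                   grid = seq(min(cohort$predB), max(cohort$predB),
                              length.out = 25),
                   alpha = cfg$fdr_q)
  report <- list(
    config = cfg[c("n_subjects", "n_runs", "n_volumes", "tr_seconds", "L",
                   "cdt_z", "alpha", "fdr_q", "seed")],
    basis = list(alpha = subj_alpha, tau = subj_tau),
    hrf = list(group_shape_explained_variance = group_shape$explained_variance),
    activation = list(contrast = subj_contrast,
                      mean_contrast = mean(subj_contrast)),
    gppi = list(fc_contrast = subj_fc, mean_fc_contrast = mean(subj_fc)),
    diagnostics = list(seed_ventricle_r = seed_vent_r),
    lme = list(table = lfit$table, random = lfit$random),
    floodlight = list(lower_bound = fl$lower_bound,
                      n_significant = sum(fl$significant)))
  if (!is.null(cfg$output_dir)) {
    jsonlite::write_json(report, file.path(cfg$output_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "columns")
    write_params_yaml(report$config, file.path(cfg$output_dir, "config.yaml"))
    write_cohort(cohort, file.path(cfg$output_dir, "cohort.csv"))
  }
  structure(report, class = "pipeline_report")
}
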