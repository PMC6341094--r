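#' Available experiment presets
#' @return Character vector of preset names.
#' @export
list_presets <- function() {
  c("fig2_shortblock", "fig3_coupling", "fig4_restraint", "fig5_fluoxetine")
}

config_defaults <- function() {
  list(
    preset        = "fig2_shortblock",
    protocol      = "short",
    seed          = 1L,
    n_subjects    = 10L,
    n_perm        = 1000L,
    poly_order    = 2,
    d_merge       = 2.5,
    refractory_ms = 2,
    min_spikes    = 50,
    forming_p     = 0.01,
    hrf_shape     = 6,
    hrf_scale     = 0.6,
    band_delta    = c(1, 4),
    band_gamma    = c(30, 90),
    transition_s  = 5,
    out_dir       = NA_character_,
    log_level     = "info")
}

#' Validate an experiment configuration
#'
#' Fills in every documented default, rejects unknown keys, and aggregates
#' all type/range violations into one error. The returned config is the
#' full manifest written alongside every result bundle, so any table can
#' be regenerated from its manifest alone.
#'
#' @param config Named list of overrides (may be empty).
#' @return Validated config list with all defaults materialised.
#' @export
validate_config <- function(config = list()) {
  defaults <- config_defaults()
  unknown <- setdiff(names(config), names(defaults))
  errs <- character(0)
  if (length(unknown))
    errs <- c(errs, paste0("unknown key(s): ", paste(unknown, collapse = ", ")))
  cfg <- utils::modifyList(defaults, config[setdiff(names(config), unknown)])
  chk <- function(ok, msg) if (!isTRUE(ok)) errs <<- c(errs, msg)
  chk(cfg$preset %in% list_presets(),
      paste0("preset must be one of: ", paste(list_presets(), collapse = ", ")))
  chk(cfg$protocol %in% c("short", "long"), "protocol must be 'short' or 'long'")
  chk(is.numeric(cfg$seed) && length(cfg$seed) == 1, "seed must be a single integer")
  chk(is.numeric(cfg$n_subjects) && cfg$n_subjects >= 2, "n_subjects must be >= 2")
  chk(is.numeric(cfg$n_perm) && cfg$n_perm >= 100, "n_perm must be >= 100")
  chk(is.numeric(cfg$d_merge) && cfg$d_merge > 0, "d_merge must be positive")
  chk(is.numeric(cfg$refractory_ms) && cfg$refractory_ms > 0,
      "refractory_ms must be positive")
  chk(is.numeric(cfg$min_spikes) && cfg$min_spikes >= 0, "min_spikes must be >= 0")
  chk(is.numeric(cfg$forming_p) && cfg$forming_p > 0 && cfg$forming_p < 1,
      "forming_p must lie in (0, 1)")
  chk(is.numeric(cfg$hrf_shape) && cfg$hrf_shape > 1, "hrf_shape must be > 1")
  chk(is.numeric(cfg$hrf_scale) && cfg$hrf_scale > 0, "hrf_scale must be > 0")
  chk(is.numeric(cfg$transition_s) && cfg$transition_s >= 0,
      "transition_s must be >= 0")
  if (length(errs))
    stop_config("invalid configuration:\n  - ", paste(errs, collapse = "\n  - "))
  cfg
}

#' Run an end-to-end synthetic experiment
#'
#' Generates a cohort for the preset's condition, runs first-level GLMs on
#' every scan, applies the session contrast and the group-level analysis
#' the preset calls for, and returns (optionally writes) the result tables
#' plus a manifest capturing every parameter and seed.
#'
#' Presets:
#' \describe{
#'   \item{`fig2_shortblock`}{Adaptation experiment: block-wise amplitudes
#'     on the declining-schedule cohort, plus pooled COPEs and
#'     DRN-normalised connectivity.}
#'   \item{`fig3_coupling`}{Site-paired coupling (delta band) and the
#'     regional fractional-metric vs COPE correlations.}
#'   \item{`fig4_restraint`}{Restraint (amplitude x0.5) vs control group
#'     permutation test, plus DRN-normalised connectivity of both arms.}
#'   \item{`fig5_fluoxetine`}{Fluoxetine session contrasts vs control
#'     session contrasts, permutation test + FDR across ROIs.}
#' }
#'
#' @param config Config list (see [validate_config()]).
#' @return List of class `raphemap_run`: `tables` (named list of data
#'   frames), `manifest` (the validated config plus derived seeds).
#' @export
run_experiment <- function(config = list()) {
  cfg <- validate_config(config)
  protocol <- make_protocol(cfg$protocol)
  hrf <- gamma_hrf(shape = cfg$hrf_shape, scale = cfg$hrf_scale)
  seed <- as.integer(cfg$seed)
  tables <- list()

  first_level <- function(cohort, scan = 1) {
    design <- build_design(cohort$protocol, hrf, poly_order = cfg$poly_order)
    t(vapply(seq_len(nrow(cohort$subjects)), function(s) {
      pp <- preprocess_cbv(cohort$scans[[s]][[scan]], cohort$protocol, "cbv")
      fit_glm(pp, design)$copes$cope
    }, numeric(length(cohort$truth$roi_labels))))
  }
  session_level <- function(cohort, mode) {
    design <- build_design(cohort$protocol, hrf, poly_order = cfg$poly_order)
    t(vapply(seq_len(nrow(cohort$subjects)), function(s) {
      scans <- t(vapply(1:3, function(k) {
        pp <- preprocess_cbv(cohort$scans[[s]][[k]], cohort$protocol, "cbv")
        fit_glm(pp, design)$copes$cope
      }, numeric(length(cohort$truth$roi_labels))))
      session_contrast(scans, mode)
    }, numeric(length(cohort$truth$roi_labels))))
  }

  if (cfg$preset == "fig2_shortblock") {
    truth <- synth_truth("adaptation_short", hrf = hrf)
    cohort <- simulate_cbv_cohort(protocol, truth, cfg$n_subjects, seed,
                                  n_scans = 1)
    amps <- lapply(seq_len(cfg$n_subjects), function(s) {
      pp <- preprocess_cbv(cohort$scans[[s]][[1]], protocol, "cbv")
      blockwise_amplitudes(pp, protocol, hrf, poly_order = cfg$poly_order)
    })
    mean_amp <- Reduce(`+`, amps) / length(amps)
    tables$blockwise <- data.frame(block = seq_len(nrow(mean_amp)),
                                   mean_amp, check.names = FALSE)
    copes <- first_level(cohort)
    colnames(copes) <- truth$roi_labels
    fit_mean <- data.frame(roi = truth$roi_labels, cope = colMeans(copes))
    tables$copes <- fit_mean
    drn_fit <- fit_glm(preprocess_cbv(cohort$scans[[1]][[1]], protocol, "cbv"),
                       build_design(protocol, hrf, poly_order = cfg$poly_order))
    tables$connectivity <- normalize_to_drn(drn_fit)
  } else if (cfg$preset == "fig3_coupling") {
    truth <- synth_truth("control", hrf = hrf)
    cs <- simulate_coupled_sites(protocol, truth, n_sites = 8,
                                 target_r = truth$coupling_targets[["delta"]],
                                 seed = seed)
    tables$site_coupling <- couple_sites(cs, hrf, kind = "delta")
    md <- simulate_matched_sites(15, truth$regional_targets[["delta_power"]],
                                 seed = seed + 1)
    mb <- simulate_matched_sites(15, truth$regional_targets[["burst_frequency"]],
                                 seed = seed + 2, metric_mean = -0.35,
                                 metric_name = "burst_frequency")
    rc <- function(df) {
      r <- regional_coupling(df[, c("animal", "roi", "metric")],
                             data.frame(animal = df$animal, roi = df$roi,
                                        cope = df$cope))
      data.frame(metric = attr(df, "metric_name"), r = r$r, p = r$p, n = r$n)
    }
    tables$regional_coupling <- rbind(rc(md), rc(mb))
  } else if (cfg$preset == "fig4_restraint") {
    truth_c <- synth_truth("control", hrf = hrf)
    truth_r <- synth_truth("restraint", hrf = hrf)
    ctrl <- simulate_cbv_cohort(protocol, truth_c, cfg$n_subjects, seed)
    rstr <- simulate_cbv_cohort(protocol, truth_r, cfg$n_subjects, seed + 1)
    copes <- rbind(session_level(ctrl, "restraint"),
                   session_level(rstr, "restraint"))
    colnames(copes) <- truth_c$roi_labels
    groups <- factor(rep(c("control", "restraint"), each = cfg$n_subjects))
    sex <- c(ctrl$subjects$sex, rstr$subjects$sex)
    pr <- permutation_test(copes, groups, covariates = data.frame(sex = sex),
                           n_perm = cfg$n_perm, seed = seed + 2,
                           adjacency = default_atlas()$adjacency,
                           forming_p = cfg$forming_p)
    tables$group_test <- pr$table
    tables$group_test$q <- fdr_correct(pr$table$p_uncorrected)
    conn <- function(copes_arm) {
      mean_cope <- data.frame(roi = colnames(copes_arm),
                              cope = colMeans(copes_arm))
      normalize_to_drn(mean_cope)
    }
    tables$connectivity <- merge(
      stats::setNames(conn(copes[groups == "control", ]),
                      c("roi", "control")),
      stats::setNames(conn(copes[groups == "restraint", ]),
                      c("roi", "restraint")), by = "roi")
  } else if (cfg$preset == "fig5_fluoxetine") {
    truth_c <- synth_truth("control", hrf = hrf)
    truth_f <- synth_truth("fluoxetine", hrf = hrf)
    ctrl <- simulate_cbv_cohort(protocol, truth_c, cfg$n_subjects, seed)
    flx <- simulate_cbv_cohort(protocol, truth_f, cfg$n_subjects, seed + 1)
    copes <- rbind(session_level(ctrl, "fluoxetine"),
                   session_level(flx, "fluoxetine"))
    colnames(copes) <- truth_c$roi_labels
    groups <- factor(rep(c("control", "fluoxetine"), each = cfg$n_subjects))
    sex <- c(ctrl$subjects$sex, flx$subjects$sex)
    pr <- permutation_test(copes, groups, covariates = data.frame(sex = sex),
                           n_perm = cfg$n_perm, seed = seed + 2)
    tab <- pr$table
    tab$q <- fdr_correct(tab$p_uncorrected)
    tab$significant <- tab$q < 0.05
    tables$session_test <- tab
  }

  manifest <- cfg
  manifest$derived_seeds <- seed + 0:2
  manifest$hrf <- list(shape = cfg$hrf_shape, scale = cfg$hrf_scale)
  out <- structure(list(tables = tables, manifest = manifest),
                   class = "raphemap_run")
  if (!is.na(cfg$out_dir)) write_run(out, cfg$out_dir)
  out
}

#' @export
print.raphemap_run <- function(x, ...) {
  cat(sprintf("<raphemap_run '%s'> tables: %s\n", x$manifest$preset,
              paste(names(x$tables), collapse = ", ")))
  invisible(x)
}

write_run <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(run$tables)) {
    df <- run$tables[[nm]]
    df$members <- NULL
    utils::write.table(format(df, digits = 10),
                       file.path(dir, paste0(nm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  jsonlite::write_json(run$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
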