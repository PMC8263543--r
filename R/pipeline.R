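# End-to-end orchestration: synthetic subject -> input function -> all
# estimators -> comparison/stability report, deterministic given the seed.

#' Build a validated run configuration
#'
#' Defaults mirror the package's emulated study protocol: fixed 5% blood
#' volume, t* = 20 min, duration weighting, the four late SUVR windows,
#' and truncation from 90 down to 40 min in 10-min steps.
#'
#' @param seed Master integer seed.
#' @param noise_scale TAC noise magnitude for the synthetic subject.
#' @param Vb Fixed fractional blood volume.
#' @param t_star Equilibrium time (s) for graphical and reference models.
#' @param weights Frame-weight scheme for NLS fits.
#' @param parent_model Parent-fraction model kind.
#' @param models Plasma-input models to run.
#' @param suvr_windows List of `c(start_s, end_s)` windows.
#' @param truncation_grid Durations (s) for the stability analysis.
#' @param stability_regions Regions refit under truncation.
#' @param reference Reference region name.
#' @param with_blood If `FALSE`, the arterial pathway is skipped and only
#'   blood-free estimators (MRTMo, SUVR) are run.
#' @param n_restarts NLS multi-start count.
#' @return A list of class `run_config`.
#' @export
run_config <- function(seed = 1L, noise_scale = 0.1, Vb = 0.05,
                       t_star = 1200, weights = "duration",
                       parent_model = "hill",
                       models = c("1tcm", "2tcm", "logan", "ma1"),
                       suvr_windows = default_suvr_windows(),
                       truncation_grid = seq(5400, 2400, by = -600),
                       stability_regions = c("pallidum", "putamen",
                                             "cerebellar_cortex"),
                       reference = "cerebellar_cortex",
                       with_blood = TRUE, n_restarts = 5L) {
  cfg <- list(seed = as.integer(seed), noise_scale = noise_scale, Vb = Vb,
              t_star = t_star, weights = weights, parent_model = parent_model,
              models = models, suvr_windows = suvr_windows,
              truncation_grid = truncation_grid,
              stability_regions = stability_regions, reference = reference,
              with_blood = isTRUE(with_blood),
              n_restarts = as.integer(n_restarts))
  validate_run_config(cfg)
  class(cfg) <- "run_config"
  cfg
}

validate_run_config <- function(cfg) {
  stopifnot(
    is.numeric(cfg$seed), length(cfg$seed) == 1L,
    cfg$noise_scale >= 0, cfg$Vb >= 0, cfg$Vb < 1, cfg$t_star > 0,
    cfg$weights %in% c("uniform", "duration", "duration_decay"),
    cfg$parent_model %in% c("hill", "power", "linear_interp"),
    all(cfg$models %in% c("1tcm", "2tcm", "logan", "ma1")),
    length(cfg$suvr_windows) >= 1L, all(cfg$truncation_grid > 0),
    cfg$n_restarts >= 1L
  )
  invisible(cfg)
}

#' Read a run configuration from JSON or YAML
#'
#' Fields missing from the file fall back to the [run_config()] defaults.
#'
#' @param path A `.json`, `.yaml` or `.yml` file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  if (!is.null(raw$suvr_windows) && is.matrix(raw$suvr_windows)) {
    raw$suvr_windows <- lapply(seq_len(nrow(raw$suvr_windows)),
                               function(i) raw$suvr_windows[i, ])
  }
  defaults <- run_config()
  for (nm in names(raw)) defaults[[nm]] <- raw[[nm]]
  validate_run_config(defaults)
  class(defaults) <- "run_config"
  defaults
}

#' Run the full quantification pipeline on a synthetic subject
#'
#' Generates a seeded synthetic subject, reconstructs the
#' metabolite-corrected input function from its blood and HPLC tables,
#' runs every configured estimator on every region, and assembles a study
#' report: per-region VT by model, BPND by the indirect method, MRTMo and
#' SUVR windows, model-selection statistics, method-comparison regressions
#' and time-stability tables. With `with_blood = FALSE` only blood-free
#' stages run. Deterministic given the configuration (seed included).
#'
#' @param config A `run_config`.
#' @param outdir Optional directory; when given, report tables are written
#'   as CSV and the report as JSON.
#' @return A list of class `study_report`.
#' @export
run_full_pipeline <- function(config = run_config(), outdir = NULL) {
  validate_run_config(config)
  subj <- simulate_subject(noise_scale = config$noise_scale,
                           seed = config$seed)
  sched <- subj$tacs[[1]]$schedule
  w <- frame_weights(sched, config$weights)
  ref_name <- config$reference
  regions <- names(subj$tacs)

  inf <- NULL
  vt_tab <- NULL
  model_sel <- NULL
  stability <- list()
  if (config$with_blood) {
    pf <- fit_parent_fraction(subj$hplc, config$parent_model)
    blood_corr <- metabolite_correct(subj$blood, pf)
    inf <- build_input_function(blood_corr)
    rows <- list()
    sel_rows <- list()
    for (nm in regions) {
      tc <- subj$tacs[[nm]]
      row <- data.frame(region = nm, vt_true = subj$truth[[nm]]$vt)
      fits <- list()
      if (any(c("1tcm", "2tcm") %in% config$models)) {
        for (kind in intersect(c("1tcm", "2tcm"), config$models)) {
          fit <- fit_compartment(tc, inf, kind = kind, weights = w,
                                 Vb = config$Vb,
                                 n_restarts = config$n_restarts,
                                 seed = derive_seed(config$seed, paste0(nm, kind)))
          fits[[kind]] <- fit
          row[[paste0("vt_", kind)]] <- fit$vt
          row[[paste0("vt_se_percent_", kind)]] <- unname(fit$se_percent[["VT"]])
        }
      }
      if ("logan" %in% config$models) {
        row$vt_logan <- logan_vt(tc, inf, config$t_star, vb = config$Vb)$vt
      }
      if ("ma1" %in% config$models) {
        row$vt_ma1 <- ma1_vt(tc, inf, config$t_star, vb = config$Vb)$vt
      }
      if (all(c("1tcm", "2tcm") %in% names(fits))) {
        a1 <- aic_ls(fits$`1tcm`$ssr, fits$`1tcm`$n_frames, fits$`1tcm`$n_params)
        a2 <- aic_ls(fits$`2tcm`$ssr, fits$`2tcm`$n_frames, fits$`2tcm`$n_params)
        m1 <- msc(w, tc$activity, fits$`1tcm`$fitted$activity, 2)
        m2 <- msc(w, tc$activity, fits$`2tcm`$fitted$activity, 4)
        ft <- f_test(fits$`1tcm`, fits$`2tcm`)
        sel_rows[[nm]] <- data.frame(
          region = nm, aic_1tcm = a1, aic_2tcm = a2, msc_1tcm = m1,
          msc_2tcm = m2, f = ft$F, p = ft$p,
          preferred = if (a2 < a1 && m2 > m1 && ft$p < 0.05) "2tcm" else "mixed"
        )
      }
      rows[[nm]] <- row
    }
    vt_tab <- do.call(rbind, rows)
    rownames(vt_tab) <- NULL
    if (length(sel_rows)) {
      model_sel <- do.call(rbind, sel_rows)
      rownames(model_sel) <- NULL
    }
    if ("2tcm" %in% config$models) {
      for (nm in intersect(config$stability_regions, regions)) {
        stability[[nm]] <- truncate_and_refit(
          subj$tacs[[nm]], inf, durations = config$truncation_grid,
          kind = "2tcm", weights = NULL, Vb = config$Vb,
          n_restarts = config$n_restarts,
          seed = derive_seed(config$seed, paste0("stab", nm)))
      }
    }
  }

  # blood-free estimators
  ref_tac <- subj$tacs[[ref_name]]
  bp_rows <- lapply(setdiff(regions, ref_name), function(nm) {
    mf <- mrtmo_fit(subj$tacs[[nm]], ref_tac, config$t_star)
    data.frame(region = nm,
               bpnd_true = true_bpnd(subj$truth[[nm]], subj$truth[[ref_name]]),
               bpnd_mrtmo = mf$bpnd)
  })
  bp_tab <- do.call(rbind, bp_rows)
  rownames(bp_tab) <- NULL
  if (!is.null(vt_tab) && "vt_2tcm" %in% names(vt_tab)) {
    ref_vt <- vt_tab$vt_2tcm[vt_tab$region == ref_name]
    bp_tab$bpnd_indirect <- indirect_bpnd(
      vt_tab$vt_2tcm[match(bp_tab$region, vt_tab$region)], ref_vt)
  }
  suvr_tab <- suvr_minus_one(subj$tacs, config$suvr_windows, ref_name)

  comparisons <- list()
  if (!is.null(vt_tab)) {
    if (all(c("vt_2tcm", "vt_logan") %in% names(vt_tab))) {
      comparisons$logan_vs_2tcm <- compare_methods(vt_tab$vt_2tcm, vt_tab$vt_logan)
    }
    if (all(c("vt_2tcm", "vt_ma1") %in% names(vt_tab))) {
      comparisons$ma1_vs_2tcm <- compare_methods(vt_tab$vt_2tcm, vt_tab$vt_ma1)
    }
    if ("bpnd_indirect" %in% names(bp_tab)) {
      comparisons$mrtmo_vs_indirect <-
        compare_methods(bp_tab$bpnd_indirect, bp_tab$bpnd_mrtmo)
      bp_ref <- bp_tab$bpnd_indirect
      suvr_slopes <- vapply(config$suvr_windows, function(wdw) {
        s <- suvr_tab[suvr_tab$window_start_s == wdw[1] &
                        suvr_tab$region != ref_name, ]
        compare_methods(bp_ref[match(s$region, bp_tab$region)],
                        s$suvr_minus_one)$slope
      }, numeric(1))
      comparisons$suvr_slope_by_window <- data.frame(
        window_start_s = vapply(config$suvr_windows, `[`, numeric(1), 1),
        window_end_s = vapply(config$suvr_windows, `[`, numeric(1), 2),
        slope_vs_bpnd = suvr_slopes
      )
    }
  }

  report <- structure(list(
    config = unclass(config),
    package_version = as.character(utils::packageVersion("petkin")),
    vt_table = vt_tab, bpnd_table = bp_tab, suvr_table = suvr_tab,
    model_selection = model_sel, stability = stability,
    comparisons = comparisons,
    free_fraction = subj$free_fraction
  ), class = "study_report")

  if (!is.null(outdir)) write_study_report(report, outdir)
  report
}

#' @export
print.study_report <- function(x, ...) {
  cat("Study report (seed", x$config$seed, ")\n")
  if (!is.null(x$vt_table)) {
    cat("VT table:\n"); print.data.frame(x$vt_table, row.names = FALSE, digits = 4)
  }
  cat("BPND table:\n"); print.data.frame(x$bpnd_table, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Write a study report to disk
#'
#' CSV tables plus a single JSON report; output is byte-stable for a fixed
#' configuration (no timestamps).
#'
#' @param report A `study_report`.
#' @param outdir Output directory (created if needed).
#' @export
write_study_report <- function(report, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(df, name) {
    if (!is.null(df)) {
      utils::write.csv(df, file.path(outdir, name), row.names = FALSE,
                       quote = FALSE)
    }
  }
  wr(report$vt_table, "vt_by_model.csv")
  wr(report$bpnd_table, "bpnd_by_method.csv")
  wr(report$suvr_table, "suvr_windows.csv")
  wr(report$model_selection, "model_selection.csv")
  for (nm in names(report$stability)) {
    wr(as.data.frame(report$stability[[nm]]), paste0("stability_", nm, ".csv"))
  }
  json <- report
  json$stability <- lapply(report$stability, as.data.frame)
  json$comparisons <- lapply(report$comparisons, function(cs) {
    if (inherits(cs, "comparison_stats")) unclass(cs) else cs
  })
  jsonlite::write_json(json, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)
  invisible(outdir)
}
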