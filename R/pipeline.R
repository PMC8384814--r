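#' Study configuration
#'
#' Assembles (and validates) the configuration driving [run_study()]. Any
#' subset of the defaults can be overridden; the object round-trips through
#' YAML via [write_study_config()] / [read_study_config()]. All stage seeds
#' derive deterministically from the single master `seed`.
#'
#' @param input_dir directory of epoch files plus `ground_truth.json`
#'   sidecar (as written by [write_cohort()]); `NULL` runs the bundled
#'   simulation scenario instead.
#' @param simulation named list overriding [synthetic_truth()] arguments for
#'   the built-in scenario (ignored when `input_dir` is given); entries
#'   `duration_mean_as_ms` / `duration_mean_qs_ms` set the two states'
#'   duration laws.
#' @param preprocess list: `low_hz`, `high_hz`, `order`, `target_fs`.
#' @param clustering list: `k` (`"auto"` or integer), `k_min`, `k_max`,
#'   `rule`, `n_restarts`, `min_separation_ms`.
#' @param syntax list: `n_reps`.
#' @param tanova list: `n_permutations`, `alpha` (pooling gate).
#' @param bands logical: run the narrow-band arm.
#' @param seed master integer seed.
#' @return A `study_config` list.
#' @export
study_config <- function(input_dir = NULL,
                         simulation = list(),
                         preprocess = list(),
                         clustering = list(),
                         syntax = list(),
                         tanova = list(),
                         bands = FALSE,
                         seed = 1) {
  cfg <- list(
    input_dir = input_dir,
    simulation = utils::modifyList(list(
      n_templates = 7, n_channels = 19, min_gd = 0.8,
      n_subjects = 10, n_epochs = 1, epoch_length_s = 60,
      snr = 5, fs = 100,
      duration_mean_as_ms = 110, duration_mean_qs_ms = 150,
      duration_sd_ms = 40
    ), simulation),
    preprocess = utils::modifyList(list(
      low_hz = 0.15, high_hz = 45, order = 7, target_fs = 100
    ), preprocess),
    clustering = utils::modifyList(list(
      k = "auto", k_min = 3, k_max = 15, rule = "second_max",
      n_restarts = 20, min_separation_ms = 10
    ), clustering),
    syntax = utils::modifyList(list(n_reps = 5000), syntax),
    tanova = utils::modifyList(list(n_permutations = 5000, alpha = 0.05),
                               tanova),
    bands = isTRUE(bands),
    seed = as.integer(seed)
  )
  structure(cfg, class = "study_config")
}

#' @rdname study_config
#' @param config a `study_config`.
#' @param path YAML file path.
#' @export
write_study_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname study_config
#' @export
read_study_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(study_config, raw[intersect(names(raw), names(formals(study_config)))])
}

# deterministic per-stage seeds below 2^31 from one master seed
derive_seed <- function(master, stage) {
  (as.integer(master) * 1103L + stage * 7919L) %% 2147483629L
}

load_cohort_dir <- function(dir) {
  sidecar <- file.path(dir, "ground_truth.json")
  if (!file.exists(sidecar)) stop("no ground_truth.json in ", dir, call. = FALSE)
  gt <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  epochs <- lapply(seq_along(gt$files), function(i) {
    read_epoch(file.path(dir, gt$files[i]),
               subject_id = gt$subject[i], state = gt$state[i])
  })
  list(epochs = epochs, ground_truth = gt)
}

#' Run the full microstate study pipeline
#'
#' Executes the complete analysis on either a cohort directory or the
#' built-in simulation scenario: preprocessing, per-state two-step
#' clustering (with optional KL selection of k), TANOVA comparison of the
#' two states' templates (gating the pooled-template branch: when no
#' template differs between states at the configured alpha, clustering is
#' redone on the pooled epochs and all subsequent analyses use the pooled
#' templates), backfitting with metrics and GEV, syntax statistics per
#' state, repeated-measures ANOVA per metric with post-hoc tests, and
#' optionally the narrow-band arm with log-log scaling fits.
#'
#' @param config a [study_config()].
#' @param verbose print stage progress.
#' @return An `ms_study` list with elements `config`, `k`, `kl`,
#'   `templates` (pooled or per-state), `template_tanova`, `pooled`,
#'   `metrics`, `gev`, `anova`, `posthoc`, `syntax`, `predominance`,
#'   `bands`, `scaling`.
#' @export
run_study <- function(config = study_config(), verbose = interactive()) {
  say <- function(...) if (verbose) message(...)
  seed0 <- config$seed

  # --- input ------------------------------------------------------------
  if (!is.null(config$input_dir)) {
    say("loading cohort from ", config$input_dir)
    cohort <- load_cohort_dir(config$input_dir)
    epochs <- cohort$epochs
  } else {
    say("simulating cohort")
    sim <- config$simulation
    templates <- make_templates(sim$n_templates, sim$n_channels,
                                geometry = if (sim$n_channels == 19) "10-20" else "random",
                                min_pairwise_dissimilarity = sim$min_gd,
                                seed = derive_seed(seed0, 1L))
    mk_truth <- function(mean_ms) synthetic_truth(
      templates,
      duration_law = list(name = "lognormal", mean_ms = mean_ms,
                          sd_ms = sim$duration_sd_ms, min_ms = 30),
      snr = sim$snr, fs = sim$fs, n_subjects = sim$n_subjects,
      n_epochs = sim$n_epochs, epoch_length_s = sim$epoch_length_s,
      seed = derive_seed(seed0, 2L))
    cohort <- simulate_cohort(mk_truth(sim$duration_mean_as_ms),
                              mk_truth(sim$duration_mean_qs_ms))
    epochs <- cohort$epochs
  }

  # --- preprocessing ----------------------------------------------------
  say("preprocessing ", length(epochs), " epochs")
  pp <- config$preprocess
  spec <- filter_spec(pp$low_hz, pp$high_hz, pp$order)
  epochs <- lapply(epochs, preprocess, spec = spec, target_fs = pp$target_fs)

  # --- clustering per state --------------------------------------------
  cl <- config$clustering
  states <- unique(vapply(epochs, function(e) e$state, ""))
  kl_curve <- NULL
  if (identical(cl$k, "auto")) {
    say("selecting k with the KL criterion")
    pool_maps <- do.call(rbind, lapply(epochs, function(e) {
      peak_maps(e, min_separation_ms = cl$min_separation_ms)$maps
    }))
    kl_curve <- kl_select(pool_maps, k_min = cl$k_min, k_max = cl$k_max,
                          rule = cl$rule, n_restarts = cl$n_restarts,
                          seed = derive_seed(seed0, 3L))
    k <- attr(kl_curve, "chosen_k")
    say("  chosen k = ", k)
  } else {
    k <- as.integer(cl$k)
  }

  say("two-step clustering per state")
  per_state <- lapply(states, function(st) {
    two_step_cluster(epochs, k, states = st,
                     min_separation_ms = cl$min_separation_ms,
                     n_restarts = cl$n_restarts,
                     seed = derive_seed(seed0, 4L))
  })
  names(per_state) <- states

  # --- TANOVA gate for pooling -----------------------------------------
  pooled <- TRUE
  template_tanova <- NULL
  if (length(states) == 2L) {
    say("TANOVA between state templates")
    mt <- match_templates(per_state[[1L]]$group, per_state[[2L]]$group)
    maps1 <- subject_template_maps(per_state[[1L]]$individual, per_state[[1L]]$group)
    maps2 <- subject_template_maps(per_state[[2L]]$individual, per_state[[2L]]$group)
    paired_ok <- length(per_state[[1L]]$individual) == length(per_state[[2L]]$individual)
    rows <- lapply(seq_len(nrow(mt)), function(i) {
      tv <- tanova(maps1[[mt$index1[i]]], maps2[[mt$index2[i]]],
                   n_permutations = config$tanova$n_permutations,
                   paired = paired_ok, seed = derive_seed(seed0, 5L + i))
      tibble::tibble(template = per_state[[1L]]$group$labels[mt$index1[i]],
                     effect = tv$effect, p_value = tv$p_value)
    })
    template_tanova <- dplyr::bind_rows(rows)
    pooled <- all(template_tanova$p_value > config$tanova$alpha)
  }

  if (pooled) {
    say("states indistinguishable; clustering pooled epochs")
    fit <- two_step_cluster(epochs, k,
                            min_separation_ms = cl$min_separation_ms,
                            n_restarts = cl$n_restarts,
                            seed = derive_seed(seed0, 20L))
    templates <- fit$group
  } else {
    say("states differ; keeping per-state templates (reporting on state 1)")
    templates <- per_state[[1L]]$group
  }

  # --- backfit + metrics ------------------------------------------------
  say("backfitting")
  res <- lapply(epochs, backfit_epoch, templates = templates,
                min_separation_ms = cl$min_separation_ms)
  metrics <- dplyr::bind_rows(lapply(res, `[[`, "metrics"))
  gev_tbl <- tibble::tibble(
    subject_id = vapply(epochs, function(e) as.character(e$subject_id), ""),
    state = vapply(epochs, function(e) e$state, ""),
    gev = vapply(res, `[[`, 0, "gev")
  )

  # --- syntax per state -------------------------------------------------
  say("syntax statistics")
  syntax <- list(); predominance <- list()
  for (st in states) {
    sel <- vapply(epochs, function(e) identical(e$state, st), TRUE)
    ts_list <- lapply(res[sel], function(r) transition_stats(r$labels))
    syntax[[st]] <- syntax_randomization_test(
      ts_list, n_reps = config$syntax$n_reps,
      seed = derive_seed(seed0, 30L + match(st, states)))
    predominance[[st]] <- directional_predominance(ts_list)
  }

  # --- group statistics -------------------------------------------------
  say("repeated-measures ANOVA")
  anova <- list(); posthoc <- list()
  if (length(states) == 2L) {
    subj_metrics <- metrics |>
      dplyr::group_by(.data$subject_id, .data$state, .data$template) |>
      dplyr::summarise(duration_ms = mean(.data$duration_ms, na.rm = TRUE),
                       occurrence_hz = mean(.data$occurrence_hz),
                       coverage_pct = mean(.data$coverage_pct),
                       .groups = "drop")
    complete <- !anyNA(subj_metrics$duration_ms)
    for (m in c("duration_ms", "occurrence_hz", "coverage_pct")) {
      if (m == "duration_ms" && !complete) next
      a <- rm_anova_2way(subj_metrics, value = m, subject = "subject_id",
                         factor_a = "state", factor_b = "template")
      if (m == "coverage_pct") {
        # total coverage is 100% in every cell, so a state main effect
        # cannot exist; reported as not applicable
        a[a$effect == "state",
          c("statistic", "p_value", "epsilon", "df1_gg", "df2_gg")] <- NA
      }
      anova[[m]] <- a
      posthoc[[m]] <- paired_posthoc(subj_metrics, value = m,
                                     subject = "subject_id",
                                     condition = "state", by = "template",
                                     method = "bonferroni")
    }
  }

  # --- narrow-band arm --------------------------------------------------
  bands_res <- NULL; scaling <- NULL
  if (isTRUE(config$bands)) {
    say("narrow-band pipeline")
    bands_res <- band_pipeline(epochs, k, min_separation_ms = cl$min_separation_ms,
                               n_restarts = cl$n_restarts,
                               seed = derive_seed(seed0, 40L))
    band_means <- bands_res$metrics |>
      dplyr::group_by(.data$band) |>
      dplyr::summarise(duration_ms = mean(.data$duration_ms, na.rm = TRUE),
                       occurrence_hz = mean(.data$occurrence_hz),
                       .groups = "drop")
    scaling <- list(
      duration = loglog_fit(stats::setNames(band_means$duration_ms, band_means$band),
                            metric_name = "duration_ms"),
      occurrence = loglog_fit(stats::setNames(band_means$occurrence_hz, band_means$band),
                              metric_name = "occurrence_hz")
    )
  }

  structure(list(config = config, k = k, kl = kl_curve,
                 templates = templates, per_state = per_state,
                 template_tanova = template_tanova, pooled = pooled,
                 metrics = metrics, gev = gev_tbl, anova = anova,
                 posthoc = posthoc, syntax = syntax,
                 predominance = predominance, bands = bands_res,
                 scaling = scaling),
            class = "ms_study")
}

#' @export
print.ms_study <- function(x, ...) {
  cat(sprintf("<ms_study> k = %d templates (%s), mean GEV %.2f%%\n",
              x$k, if (x$pooled) "pooled states" else "per-state",
              mean(x$gev$gev)))
  for (st in names(x$syntax)) {
    cat(sprintf("  syntax %s: D = %.4g, p = %.4g\n", st,
                x$syntax[[st]]$distance, x$syntax[[st]]$p_value))
  }
  for (m in names(x$anova)) {
    a <- x$anova[[m]]
    cat(sprintf("  ANOVA %s: state F = %.4g (p = %.3g)\n", m,
                a$statistic[a$effect == "state"], a$p_value[a$effect == "state"]))
  }
  invisible(x)
}
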