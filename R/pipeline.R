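#' Full pipeline configuration
#'
#' Collects every stage's parameters: phantom and scanner, acquisition
#' (duration, accepted count rate, CT phase), respiratory-signal extraction
#' (bin width, rROI dilation, baseline window), gating, reconstruction,
#' registration and evaluation. The seed drives all randomness and is
#' recorded in the run report.
#'
#' @param seed integer master seed.
#' @param phantom a [phantom_config()].
#' @param scanner a [scanner_geometry()].
#' @param duration_s scan duration, s.
#' @param mean_rate_cps accepted coincidence rate, counts/s.
#' @param ct_phase respiratory phase of the CT snapshot in `[0,1]` (near 1 =
#'   deep inspiration, mismatching the PET gates).
#' @param signal list: `bin_ms`, `dilation_mm`, `baseline_window_s`,
#'   `lowpass_hz`, `rind_mm`, `min_duration_s`.
#' @param gating list: `n_gates`.
#' @param recon list: `n_iter`, `n_subsets`, `step_mm`, `n_sens_lors`,
#'   `post_filter_mm`.
#' @param registration a [register_config()] for the gate-to-reference
#'   registrations.
#' @param alignment a [register_config()] for the mu-to-CT alignment; the
#'   expected field is smooth and small, so it defaults to a coarser, more
#'   heavily regularised setting.
#' @param evaluation list: `decay_correct`.
#' @param signal_source `"cod"` (data-driven) or `"device"` (the phantom's
#'   programmed waveform, emulating a hardware respiration monitor).
#' @param mu_estimator `"surrogate"`, `"oracle"`, or a callable
#'   `function(lambda_nac, gate_phase) -> rmc_volume`.
#' @param cavity_fn optional replacement for [segment_body_cavity()].
#' @param out_dir optional output directory for volumes/tables/report.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1L, phantom = phantom_config(),
                            scanner = scanner_geometry(), duration_s = 60,
                            mean_rate_cps = 1e4, ct_phase = 1.0,
                            signal = list(), gating = list(), recon = list(),
                            registration = register_config(),
                            alignment = register_config(levels = 2,
                                                        iterations = c(150, 80),
                                                        sigma_field_vox = 4),
                            evaluation = list(),
                            signal_source = c("cod", "device"),
                            mu_estimator = "surrogate", cavity_fn = NULL,
                            out_dir = NULL) {
  structure(list(
    seed = as.integer(seed), phantom = phantom, scanner = scanner,
    duration_s = duration_s, mean_rate_cps = mean_rate_cps,
    ct_phase = ct_phase,
    signal = modifyList(list(bin_ms = 100, dilation_mm = 50,
                             baseline_window_s = 30, lowpass_s = 0.5,
                             rind_mm = 15, min_duration_s = 30,
                             lowpass_hz = 0.6), signal),
    gating = modifyList(list(n_gates = 4L), gating),
    recon = modifyList(list(n_iter = 3L, n_subsets = 8L, step_mm = 2,
                            n_sens_lors = 1e5, post_filter_mm = 2.5), recon),
    registration = registration, alignment = alignment,
    evaluation = modifyList(list(decay_correct = TRUE), evaluation),
    signal_source = match.arg(signal_source), mu_estimator = mu_estimator,
    cavity_fn = cavity_fn, out_dir = out_dir), class = "pipeline_config")
}

pipeline_stages <- c("simulate", "signal", "gate", "recon", "urmc", "evaluate")

#' Run the unified respiratory motion correction pipeline
#'
#' Orchestrates simulate -> respiratory signal -> equal-count gating ->
#' gated NAC reconstruction -> per-gate attenuation maps -> reference-gate
#' selection (mutual information with the CT) -> gated AC reconstruction ->
#' non-rigid gate-to-reference registration and consolidation (the
#' motion-corrected image) -> single-modal PET-CT alignment (the final image
#' in CT space) -> evaluation (SUV per lesion for the uncorrected and
#' corrected images, per-organ motion amplitudes). The ungated all-counts AC
#' reconstruction with the CT mu map serves as the no-motion-correction
#' (NMC) baseline, attenuation-mismatch artifacts intact. With a single gate
#' the consolidation degenerates to the one AC image and no gate
#' registration is performed. Fully deterministic under a fixed seed.
#'
#' @param config a [pipeline_config()].
#' @param through run only up to this stage (one of `r
#'   paste(pipeline_stages, collapse = ", ")`).
#' @param verbose emit INFO messages per stage.
#' @return an `urmc_run` object (volumes, tables, report).
#' @export
run_pipeline <- function(config = pipeline_config(), through = "evaluate",
                         verbose = FALSE) {
  stopifnot(inherits(config, "pipeline_config"), through %in% pipeline_stages)
  last <- match(through, pipeline_stages)
  info <- function(...) if (verbose) message(sprintf(...))
  timings <- c()
  clock <- function(stage, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(force(expr), error = function(e)
      stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
           call. = FALSE))
    timings[[stage]] <<- proc.time()[["elapsed"]] - t0
    out
  }
  run <- list(config = config)
  class(run) <- "urmc_run"

  # -- simulate ---------------------------------------------------------
  info("stage simulate: phantom + list-mode")
  sim <- clock("simulate", {
    phantom <- build_phantom(config$phantom)
    mu_ct <- render_ct(phantom, config$ct_phase)
    lm <- simulate_listmode(phantom, config$scanner, config$duration_s,
                            config$mean_rate_cps, seed = config$seed)
    list(phantom = phantom, mu_ct = mu_ct, lm = lm)
  })
  run$phantom <- sim$phantom
  run$mu_ct <- sim$mu_ct
  run$listmode <- sim$lm
  run$n_events <- nrow(sim$lm$events)
  if (last < 2) return(finish_run(run, timings))

  # -- respiratory signal ----------------------------------------------
  info("stage signal: %s respiratory signal", config$signal_source)
  sg <- config$signal
  run <- clock("signal", {
    n_bins <- as.integer(ceiling(config$duration_s * 1000 / sg$bin_ms))
    bin_t <- (seq_len(n_bins) - 0.5) * sg$bin_ms / 1000
    if (config$signal_source == "cod") {
      seg <- if (is.null(config$cavity_fn)) {
        function(mu) segment_body_cavity(mu, rind_mm = sg$rind_mm)
      } else config$cavity_fn
      run$cavity <- seg(run$mu_ct)
      run$rroi <- build_rroi(run$cavity, dilation_mm = sg$dilation_mm)
      run$cod_trace <- extract_cod(run$listmode, run$rroi, bin_ms = sg$bin_ms)
      run$signal <- condition_signal(run$cod_trace,
                                     baseline_window_s = sg$baseline_window_s,
                                     lowpass_hz = sg$lowpass_hz,
                                     min_duration_s = sg$min_duration_s)
    } else {
      counts <- tabulate(pmin(n_bins, run$listmode$events$t_ms %/% sg$bin_ms + 1L),
                         nbins = n_bins)
      run$signal <- tibble::tibble(
        time_s = bin_t,
        amplitude = run$phantom$waveform$phase_fn(bin_t),
        counts = counts, valid = TRUE)
      attr(run$signal, "bin_s") <- sg$bin_ms / 1000
    }
    run$bin_phase <- run$phantom$waveform$phase_fn(bin_t)
    run
  })
  if (last < 3) return(finish_run(run, timings))

  # -- gating -----------------------------------------------------------
  info("stage gate: %d equal-count amplitude gates", config$gating$n_gates)
  run <- clock("gate", {
    # equal-count gating balances the full event stream, not only the
    # rROI events that formed the COD signal
    all_counts <- tabulate(pmin(length(run$bin_phase),
                                run$listmode$events$t_ms %/% sg$bin_ms + 1L),
                           nbins = length(run$bin_phase))
    run$gates <- equal_count_gates(run$signal, counts_per_bin = all_counts,
                                   n_gates = config$gating$n_gates)
    run$gate_listmodes <- split_listmode(run$listmode, run$gates,
                                         bin_ms = sg$bin_ms)
    # mean programmed phase per gate (phantom truth; used by the oracle
    # mu estimator and reported for diagnostics)
    asg <- run$gates$assignment
    run$gate_mean_phase <- vapply(0:(run$gates$n_gates - 1), function(g) {
      sel <- asg$gate == g & asg$counts > 0
      sum(run$bin_phase[sel] * asg$counts[sel]) / sum(asg$counts[sel])
    }, 0)
    run
  })
  if (last < 4) return(finish_run(run, timings))

  # -- gated NAC recon + mu maps + reference gate -----------------------
  info("stage recon: gated NAC, mu maps, gated AC")
  rc <- config$recon
  run <- clock("recon", {
    grid <- listmode_grid(run$listmode)
    sens_nac <- sensitivity_image(run$config$scanner, grid, mu = NULL,
                                  n_lors = rc$n_sens_lors,
                                  seed = config$seed + 101L,
                                  step_mm = rc$step_mm)
    run$lambda_nac <- lapply(run$gate_listmodes, function(glm)
      mlem_reconstruct(glm, grid, n_iter = rc$n_iter,
                       n_subsets = rc$n_subsets, sensitivity = sens_nac,
                       step_mm = rc$step_mm, calibrate = FALSE,
                       post_filter_mm = rc$post_filter_mm))
    est <- config$mu_estimator
    run$mu_gates <- lapply(seq_along(run$lambda_nac), function(i) {
      if (is.function(est)) est(run$lambda_nac[[i]], run$gate_mean_phase[i])
      else if (identical(est, "oracle"))
        oracle_mu(run$phantom, run$gate_mean_phase[i])
      else estimate_mu_surrogate(run$lambda_nac[[i]])
    })
    ref <- select_reference_gate(run$mu_gates, run$mu_ct)
    run$reference_gate <- as.integer(ref)
    run$gate_mi <- attr(ref, "mi")
    run$lambda_ac <- lapply(seq_along(run$gate_listmodes), function(i) {
      sens <- sensitivity_image(run$config$scanner, grid,
                                mu = run$mu_gates[[i]],
                                n_lors = rc$n_sens_lors,
                                seed = config$seed + 200L + i,
                                step_mm = rc$step_mm)
      mlem_reconstruct(run$gate_listmodes[[i]], grid, n_iter = rc$n_iter,
                       n_subsets = rc$n_subsets, mu = run$mu_gates[[i]],
                       sensitivity = sens, step_mm = rc$step_mm,
                       post_filter_mm = 0)
    })
    sens_ct <- sensitivity_image(run$config$scanner, grid, mu = run$mu_ct,
                                 n_lors = rc$n_sens_lors,
                                 seed = config$seed + 300L,
                                 step_mm = rc$step_mm)
    run$nmc <- mlem_reconstruct(run$listmode, grid, n_iter = rc$n_iter,
                                n_subsets = rc$n_subsets, mu = run$mu_ct,
                                sensitivity = sens_ct, step_mm = rc$step_mm,
                                post_filter_mm = rc$post_filter_mm)
    run$nmc$tags$method <- "NMC"
    run
  })
  if (last < 5) return(finish_run(run, timings))

  # -- motion correction + alignment ------------------------------------
  info("stage urmc: gate registration, consolidation, PET-CT alignment")
  run <- clock("urmc", {
    G <- run$gates$n_gates
    ref1 <- run$reference_gate + 1L
    run$gate_fields <- vector("list", G)
    warped <- vector("list", G)
    # fields are estimated on lightly filtered copies and applied to the
    # raw gate images (the usual estimate-on-smoothed, apply-on-raw split)
    pf <- config$recon$post_filter_mm
    ac_f <- lapply(run$lambda_ac, function(v)
      if (pf > 0) smooth_volume(v, pf) else v)
    for (i in seq_len(G)) {
      if (i == ref1) {
        warped[[i]] <- run$lambda_ac[[i]]
      } else {
        run$gate_fields[[i]] <- register_nonrigid(ac_f[[ref1]], ac_f[[i]],
                                                  config$registration)
        warped[[i]] <- warp_image(run$lambda_ac[[i]], run$gate_fields[[i]])
      }
    }
    rmc_raw <- consolidate(warped, run$gates$gate_counts,
                           reference_gate = run$reference_gate)
    al <- align_pet_ct(rmc_raw, run$mu_gates[[ref1]], run$mu_ct,
                       config$alignment)
    # single clinical post-filter at the end of the chain, matching the
    # NMC and motion-free reconstructions
    pf <- rc$post_filter_mm
    run$lambda_rmc <- if (pf > 0) smooth_volume(rmc_raw, pf) else rmc_raw
    run$lambda_rmc$tags <- rmc_raw$tags
    run$lambda_urmc <- if (pf > 0) smooth_volume(al$lambda_urmc, pf)
                       else al$lambda_urmc
    run$lambda_urmc$tags <- al$lambda_urmc$tags
    run$alignment_field <- al$field
    run$mi_alignment <- c(before = al$mi_before, after = al$mi_after)
    # inspiration <-> expiration field for the motion-amplitude statistic,
    # anchored on whichever extreme gate is nearer the reference gate so the
    # field lives in (essentially) the reference-gate frame that the organ
    # masks are resliced into
    run$extreme_field <- if (G > 1) {
      fixed_i <- if (run$reference_gate >= (G - 1) / 2) G else 1L
      moving_i <- if (fixed_i == G) 1L else G
      register_nonrigid(ac_f[[fixed_i]], ac_f[[moving_i]],
                        config$registration)
    } else {
      z <- array(0, dim(run$lambda_rmc$data))
      new_field(z, z, z, run$lambda_rmc)
    }
    run
  })
  if (last < 6) return(finish_run(run, timings))

  # -- evaluation --------------------------------------------------------
  info("stage evaluate: SUV and organ amplitudes")
  run <- clock("evaluate", {
    meta <- run$phantom$meta
    dc <- config$evaluation$decay_correct
    run$suv <- list(NMC = suv_image(run$nmc, meta, dc),
                    uRMC = suv_image(run$lambda_urmc, meta, dc))
    ct_frame <- frame_at_phase(run$phantom, config$ct_phase)
    run$ct_labels <- ct_frame$labels
    lesions <- run$config$phantom$lesions
    run$suv_table <- purrr::map_dfr(seq_along(lesions), function(i) {
      roi <- organ_mask(run$ct_labels, paste0("lesion_", i))
      purrr::map_dfr(names(run$suv), function(mth) {
        st <- lesion_stats(run$suv[[mth]], roi)
        dplyr::mutate(st, lesion = i, method = mth, .before = 1)
      })
    })
    organs <- c("liver", "spleen", "stomach", "kidney_l", "kidney_r",
                "lung_l", "lung_r", "chest_wall", "abdominal_wall")
    masks <- lapply(organs, function(o) organ_mask(run$ct_labels, o))
    names(masks) <- organs
    run$amplitude_table <- organ_motion_amplitude(masks, run$alignment_field,
                                                  run$extreme_field,
                                                  subject = config$seed)
    run
  })
  finish_run(run, timings)
}

#' Organ motion-amplitude study (lean pipeline path)
#'
#' Runs only the stages needed for the per-organ motion-amplitude statistic:
#' simulation, respiratory signal, gating, gated NAC reconstruction and mu
#' maps, reference-gate selection, AC reconstruction of the two extreme
#' gates, the mu-to-CT alignment field and the extreme-gate registration
#' field, then [organ_motion_amplitude()]. Much cheaper than a full
#' [run_pipeline()] when only amplitudes are needed (e.g. cohort studies).
#'
#' @param config a [pipeline_config()].
#' @param organs organ names to report.
#' @return tibble of per-organ amplitudes (mm) for this subject.
#' @export
estimate_organ_amplitudes <- function(config = pipeline_config(),
                                      organs = c("liver", "spleen", "stomach",
                                                 "kidney_l", "kidney_r",
                                                 "lung_l", "lung_r",
                                                 "chest_wall",
                                                 "abdominal_wall")) {
  run <- run_pipeline(config, through = "gate")
  rc <- config$recon
  grid <- listmode_grid(run$listmode)
  G <- run$gates$n_gates
  sens_nac <- sensitivity_image(config$scanner, grid, mu = NULL,
                                n_lors = rc$n_sens_lors,
                                seed = config$seed + 101L,
                                step_mm = rc$step_mm)
  est <- config$mu_estimator
  mu_gates <- lapply(seq_len(G), function(i) {
    nac <- mlem_reconstruct(run$gate_listmodes[[i]], grid, n_iter = rc$n_iter,
                            n_subsets = rc$n_subsets, sensitivity = sens_nac,
                            step_mm = rc$step_mm, calibrate = FALSE,
                            post_filter_mm = rc$post_filter_mm)
    if (is.function(est)) est(nac, run$gate_mean_phase[i])
    else if (identical(est, "oracle"))
      oracle_mu(run$phantom, run$gate_mean_phase[i])
    else estimate_mu_surrogate(nac)
  })
  ref <- as.integer(select_reference_gate(mu_gates, run$mu_ct))
  ac_of <- function(i) {
    sens <- sensitivity_image(config$scanner, grid, mu = mu_gates[[i]],
                              n_lors = rc$n_sens_lors,
                              seed = config$seed + 200L + i,
                              step_mm = rc$step_mm)
    v <- mlem_reconstruct(run$gate_listmodes[[i]], grid, n_iter = rc$n_iter,
                          n_subsets = rc$n_subsets, mu = mu_gates[[i]],
                          sensitivity = sens, step_mm = rc$step_mm,
                          post_filter_mm = 0)
    if (rc$post_filter_mm > 0) smooth_volume(v, rc$post_filter_mm) else v
  }
  fixed_i <- if (ref >= (G - 1) / 2) G else 1L
  moving_i <- if (fixed_i == G) 1L else G
  extreme_field <- register_nonrigid(ac_of(fixed_i), ac_of(moving_i),
                                     config$registration)
  align_field <- register_nonrigid(fixed = run$mu_ct,
                                   moving = mu_gates[[ref + 1L]],
                                   config$alignment)
  ct_labels <- frame_at_phase(run$phantom, config$ct_phase)$labels
  masks <- lapply(organs, function(o) organ_mask(ct_labels, o))
  names(masks) <- organs
  organ_motion_amplitude(masks, align_field, extreme_field,
                         subject = config$seed)
}

finish_run <- function(run, timings) {
  cfg <- run$config
  run$report <- list(
    package_version = as.character(utils::packageVersion("urmc")),
    seed = cfg$seed,
    config_hash = rlang::hash(unclass(cfg)),
    timings_s = lapply(as.list(timings), round, 2),
    n_events = run$n_events,
    gate_counts = if (!is.null(run$gates)) run$gates$gate_counts,
    reference_gate = run$reference_gate,
    gate_mi = run$gate_mi,
    gate_mean_phase = run$gate_mean_phase,
    mi_alignment = run$mi_alignment)
  if (!is.null(cfg$out_dir)) write_run_outputs(run, cfg$out_dir)
  run
}

write_run_outputs <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wv <- function(v, name) if (!is.null(v))
    write_volume(v, file.path(dir, paste0(name, ".nii.gz")))
  wv(run$mu_ct, "mu_ct")
  for (i in seq_along(run$lambda_nac)) {
    wv(run$lambda_nac[[i]], sprintf("lambda_nac_g%d", i - 1))
    wv(run$mu_gates[[i]], sprintf("mu_g%d", i - 1))
    wv(run$lambda_ac[[i]], sprintf("lambda_ac_g%d", i - 1))
  }
  wv(run$lambda_rmc, "lambda_rmc")
  wv(run$lambda_urmc, "lambda_urmc")
  wv(run$nmc, "nmc")
  if (!is.null(run$suv_table))
    utils::write.csv(run$suv_table, file.path(dir, "suv_table.csv"),
                     row.names = FALSE)
  if (!is.null(run$amplitude_table))
    utils::write.csv(run$amplitude_table,
                     file.path(dir, "organ_amplitudes.csv"),
                     row.names = FALSE)
  jsonlite::write_json(run$report, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' @export
print.urmc_run <- function(x, ...) {
  cat("<urmc_run>\n")
  cat(sprintf("  events: %s; gates: %s\n", x$n_events %||% "?",
              if (!is.null(x$gates)) paste(x$gates$gate_counts, collapse = ", ")
              else "-"))
  if (!is.null(x$reference_gate))
    cat(sprintf("  reference gate: %d (MI %s)\n", x$reference_gate,
                paste(signif(x$gate_mi, 3), collapse = ", ")))
  if (!is.null(x$mi_alignment))
    cat(sprintf("  PET-CT alignment MI: %.3f -> %.3f\n",
                x$mi_alignment[["before"]], x$mi_alignment[["after"]]))
  if (!is.null(x$suv_table)) {
    cat("  lesion SUV:\n")
    print(x$suv_table)
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy per-lesion results of a pipeline run
#'
#' @param x an `urmc_run`.
#' @param ... unused.
#' @return tibble of per-lesion, per-method SUV statistics.
#' @export
tidy.urmc_run <- function(x, ...) {
  if (is.null(x$suv_table)) stop("run has no evaluation stage")
  x$suv_table
}

#' One-row summary of a pipeline run
#'
#' @param x an `urmc_run`.
#' @param ... unused.
#' @return one-row tibble: event count, gate balance, reference gate, MI
#'   improvement, SUV gain of the corrected over the uncorrected image.
#' @export
glance.urmc_run <- function(x, ...) {
  suv_gain <- NA_real_
  if (!is.null(x$suv_table)) {
    wide <- tidyr::pivot_wider(x$suv_table[, c("lesion", "method", "suv_mean")],
                               names_from = "method", values_from = "suv_mean")
    suv_gain <- mean(wide$uRMC / wide$NMC - 1)
  }
  tibble::tibble(
    n_events = x$n_events,
    n_gates = x$gates$n_gates %||% NA_integer_,
    gate_imbalance = if (!is.null(x$gates))
      max(x$gates$gate_counts) - min(x$gates$gate_counts) else NA_integer_,
    reference_gate = x$reference_gate %||% NA_integer_,
    mi_gain = if (!is.null(x$mi_alignment))
      unname(x$mi_alignment["after"] - x$mi_alignment["before"]) else NA_real_,
    suv_mean_gain = suv_gain)
}

#' Compare methods over a shared lesion set
#'
#' Builds the per-category summary (mean and SD of SUV_max and SUV_mean per
#' method, plus an all-lesions block) and paired t-tests between every
#' method pair.
#'
#' @param suv_tables named list of per-lesion SUV tibbles (columns `lesion`,
#'   `suv_max`, `suv_mean`, `category`), one per method, over the same
#'   lesion set; or a single tibble with a `method` column.
#' @return an `urmc_comparison`: list of `summary` and `tests` tibbles.
#' @export
compare_methods <- function(suv_tables) {
  tab <- if (is.data.frame(suv_tables)) suv_tables
         else dplyr::bind_rows(lapply(suv_tables, function(t)
           t[setdiff(names(t), "method")]), .id = "method")
  methods <- unique(tab$method)
  lesset <- lapply(methods, function(m) sort(tab$lesion[tab$method == m]))
  if (length(unique(lesset)) != 1)
    stop("methods were evaluated on mismatched lesion sets")
  long <- tidyr::pivot_longer(tab, cols = c("suv_max", "suv_mean"),
                              names_to = "metric", values_to = "suv")
  blocks <- dplyr::bind_rows(long,
                             dplyr::mutate(long, category = "all"))
  summary <- blocks |>
    dplyr::group_by(.data$category, .data$metric, .data$method) |>
    dplyr::summarise(mean = mean(.data$suv), sd = ifelse(dplyr::n() > 1,
                                                         sd(.data$suv), 0),
                     n = dplyr::n(), .groups = "drop")
  pairs <- utils::combn(methods, 2, simplify = FALSE)
  tests <- purrr::map_dfr(pairs, function(pr) {
    purrr::map_dfr(unique(blocks$category), function(cat) {
      purrr::map_dfr(c("suv_max", "suv_mean"), function(met) {
        sel <- blocks$category == cat & blocks$metric == met
        x <- blocks$suv[sel & blocks$method == pr[1]][
          order(blocks$lesion[sel & blocks$method == pr[1]])]
        y <- blocks$suv[sel & blocks$method == pr[2]][
          order(blocks$lesion[sel & blocks$method == pr[2]])]
        if (length(x) < 2) {
          return(tibble::tibble(category = cat, metric = met,
                                method_a = pr[1], method_b = pr[2],
                                t = NA_real_, p = NA_real_))
        }
        tt <- paired_t_test(x, y)
        tibble::tibble(category = cat, metric = met, method_a = pr[1],
                       method_b = pr[2], t = tt$t, p = tt$p)
      })
    })
  })
  structure(list(summary = summary, tests = tests),
            class = "urmc_comparison")
}

#' @export
print.urmc_comparison <- function(x, ...) {
  cat("<urmc_comparison>\nsummary:\n")
  print(x$summary)
  cat("paired tests:\n")
  print(x$tests)
  invisible(x)
}

#' Side-by-side coronal view of the corrected and uncorrected images
#'
#' @param object an `urmc_run` that reached the `urmc` stage.
#' @param index coronal slice index (default: through the first lesion).
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.urmc_run <- function(object, index = NULL, ...) {
  stopifnot(!is.null(object$lambda_urmc), !is.null(object$nmc))
  if (is.null(index)) {
    ctr <- object$config$phantom$lesions[[1]]$center
    index <- round((ctr[2] - object$nmc$origin[2]) / object$nmc$spacing[2]) + 1
  }
  grab <- function(v, lab) {
    sl <- v$data[, index, ]
    tibble::tibble(x = rep(seq_len(nrow(sl)), ncol(sl)),
                   z = rep(seq_len(ncol(sl)), each = nrow(sl)),
                   value = as.numeric(sl), method = lab)
  }
  df <- dplyr::bind_rows(grab(object$nmc, "NMC"),
                         grab(object$lambda_urmc, "uRMC"))
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$z, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::facet_wrap(~method) +
    ggplot2::scale_fill_viridis_c(option = "magma") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL, fill = "Bq/mL",
                  title = sprintf("coronal slice %d", index)) +
    ggplot2::theme_minimal()
}
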