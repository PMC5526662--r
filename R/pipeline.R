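#' Analysis configuration for the end-to-end pipeline
#'
#' @param sim a [sim_config()] describing the dataset to generate (or
#'   the conditions a loaded dataset was recorded under).
#' @param contrasts subset of `"stop_vs_prev_tap"`, `"success_vs_fail"`,
#'   `"prestop_window"`, `"band_timecourses"`, `"peak_latency"`,
#'   `"corr_extent_gamma"`, `"behavior_correlations"`, `"ispc_change"`.
#' @param band_set `"gamma"` (filterbank bands with centers inside
#'   `gamma_band`; fast) or `"all"` (full 3-40 / 50-120 Hz filterbank).
#' @param gamma_band analysis gamma band, Hz.
#' @param epoch_window peri-cue epoch, s.
#' @param baseline_window regular-tap baseline epoch, s.
#' @param peak_window peak-latency search window, s (wider than the
#'   stopping window so late failed-stop peaks are measurable).
#' @param n_perm permutations for cluster tests.
#' @param threshold_p pre-cluster threshold.
#' @param alpha cluster significance level.
#' @param n_boot bootstrap resamples for correlation CIs.
#' @param seed master analysis seed (permutations, bootstraps).
#' @param preproc a [preproc_config()].
#' @param behavior a [behavior_config()].
#' @param ispc an [ispc_spec()].
#' @param channel_subset optional character vector of channel names to
#'   retain before preprocessing (e.g. only the STN and behavior
#'   channels when no EEG contrast is requested); `NULL` keeps all.
#' @param cache_dir optional directory for content-addressed stage
#'   caching (`NULL` = off).
#' @return list of class `analysis_config`.
#' @export
analysis_config <- function(sim = sim_config(),
                            contrasts = c("stop_vs_prev_tap",
                                          "success_vs_fail",
                                          "band_timecourses",
                                          "peak_latency",
                                          "corr_extent_gamma",
                                          "behavior_correlations"),
                            band_set = c("gamma", "all"),
                            gamma_band = c(60, 90),
                            epoch_window = c(-0.35, 0.35),
                            baseline_window = c(-0.45, 0.45),
                            peak_window = c(0, 0.3),
                            n_perm = 2000, threshold_p = 0.05,
                            alpha = 0.05, n_boot = 2000, seed = 1,
                            preproc = preproc_config(),
                            behavior = behavior_config(),
                            ispc = ispc_spec(), channel_subset = NULL,
                            cache_dir = NULL) {
  known <- c("stop_vs_prev_tap", "success_vs_fail", "prestop_window",
             "band_timecourses", "peak_latency", "corr_extent_gamma",
             "behavior_correlations", "ispc_change")
  bad <- setdiff(contrasts, known)
  if (length(bad)) stop("unknown contrast(s): ",
                        paste(bad, collapse = ", "), call. = FALSE)
  structure(list(sim = sim, contrasts = contrasts,
                 band_set = match.arg(band_set), gamma_band = gamma_band,
                 epoch_window = epoch_window,
                 baseline_window = baseline_window,
                 peak_window = peak_window, n_perm = n_perm,
                 threshold_p = threshold_p, alpha = alpha,
                 n_boot = n_boot, seed = seed, preproc = preproc,
                 behavior = behavior, ispc = ispc,
                 channel_subset = channel_subset,
                 cache_dir = cache_dir),
            class = "analysis_config")
}

analysis_bands <- function(cfg) {
  fb <- filterbank_spec()
  if (cfg$band_set == "gamma") {
    fb$bands <- fb$bands[fb$bands$center >= cfg$gamma_band[1] &
                           fb$bands$center <= cfg$gamma_band[2], ]
    rownames(fb$bands) <- NULL
  }
  fb
}

# tap times per trial with their indices, from the event table
trial_taps <- function(events, tr) {
  sub <- events[events$trial_idx == tr & events$event_type == "tap_onset" &
                  !is.na(events$tap_idx), , drop = FALSE]
  sub[order(sub$tap_idx), c("tap_idx", "time")]
}

# content-addressed stage cache: key = md5 of the serialized inputs
cached_stage <- function(cache_dir, key_obj, fun) {
  if (is.null(cache_dir)) return(fun())
  dir.create(cache_dir, showWarnings = FALSE, recursive = TRUE)
  tmp <- tempfile()
  saveRDS(key_obj, tmp)
  key <- unname(tools::md5sum(tmp))
  unlink(tmp)
  path <- file.path(cache_dir, paste0(key, ".rds"))
  if (file.exists(path)) return(readRDS(path))
  val <- fun()
  saveRDS(val, path)
  val
}

# Per-subject stage: preprocess, behavioral scoring, normalized
# time-frequency epochs and class means on the contralateral STN.
analyze_subject <- function(sub, cfg) {
  rec_in <- sub$recording
  if (!is.null(cfg$channel_subset)) {
    keep_ch <- rec_in$channels$name %in% cfg$channel_subset
    rec_in$channels <- rec_in$channels[keep_ch, , drop = FALSE]
    rec_in$data <- rec_in$data[keep_ch, , drop = FALSE]
  }
  pp <- preprocess_recording(rec_in, cfg$preproc)
  rec <- pp$rec
  events <- sub$events
  trials <- build_trial_table(rec, events, cfg$behavior,
                              interval = cfg$sim$metronome_interval / 1000)
  keep <- !trials$excluded
  lat <- lateralize_channels(rec)
  fb <- analysis_bands(cfg)
  stn <- channel_data(rec, lat$stn_contra)
  tf <- tf_power(stn, rec$sample_rate, fb,
                 subject_id = rec$subject_id)

  # alignment times
  stop_t <- trials$stop_time[keep]
  delay_s <- trials$stop_delay[keep] / 1000
  virt_t <- rep(NA_real_, sum(keep))
  base_taps <- c()
  k <- 0
  for (tr in trials$trial_idx[keep]) {
    k <- k + 1
    taps <- trial_taps(events, tr)
    n_reg <- sum(taps$time < trials$stop_time[trials$trial_idx == tr])
    if (n_reg >= 2) virt_t[k] <- taps$time[n_reg - 1] + delay_s[k]
    if (n_reg >= 3)
      base_taps <- c(base_taps, taps$time[2:(n_reg - 1)])
  }
  edge <- pp$flagged_edge_s
  base_ep <- epoch_tf(tf, base_taps, cfg$baseline_window, edge)
  stop_ep <- epoch_tf(tf, stop_t, cfg$epoch_window, edge)
  virt_ok <- !is.na(virt_t)
  virt_ep <- epoch_tf(tf, virt_t[virt_ok], cfg$epoch_window, edge)

  stop_n <- normalize_to_regular_taps(stop_ep, base_ep)
  virt_n <- normalize_to_regular_taps(virt_ep, base_ep)

  kept_stop <- attr(stop_ep, "kept")
  tr_info <- trials[keep, ][kept_stop, ]
  success <- tr_info$outcome %in% c("full", "intermediate")

  mean_map <- function(arr, rows) {
    if (!sum(rows)) return(NULL)
    apply(arr[rows, , , drop = FALSE], c(2, 3), mean)
  }
  list(rec = rec, events = events, trials = trials, pp = pp, lat = lat,
       fb = fb, tf_times = attr(stop_ep, "times"),
       tf_freqs = attr(stop_ep, "freqs"),
       stop_epochs = stop_n, virt_epochs = virt_n,
       success = success, extents = tr_info$movement_extent,
       map_all = mean_map(stop_n, rep(TRUE, dim(stop_n)[1])),
       map_success = mean_map(stop_n, success),
       map_fail = mean_map(stop_n, !success),
       map_virtual = mean_map(virt_n, rep(TRUE, dim(virt_n)[1])),
       stop_win = stop_window_end(trials, events))
}

#' Run the full analysis pipeline on a (synthetic) dataset
#'
#' Stages: dataset generation (or `dataset` supplied), preprocessing,
#' behavioral scoring, time-frequency power on the contralateral STN with
#' regular-tap normalization, the requested group contrasts with
#' cluster-based permutation correction, gamma peak latencies,
#' extent-power correlations and, when requested, ISPC connectivity.
#'
#' @param cfg an [analysis_config()].
#' @param dataset optional list of subjects as produced by
#'   [simulate_dataset()]; generated from `cfg$sim` when `NULL`.
#' @return a report bundle: list with `summary` (plain named list,
#'   JSON-serializable), `results` (full R objects per contrast),
#'   `subjects` (per-subject stage outputs) and `config`.
#' @export
run_pipeline <- function(cfg = analysis_config(), dataset = NULL) {
  if (is.null(dataset))
    dataset <- cached_stage(cfg$cache_dir, list("dataset", cfg$sim),
                            function() simulate_dataset(cfg$sim))
  subjects <- lapply(dataset, function(sub)
    cached_stage(cfg$cache_dir,
                 list("subject", sub$recording$subject_id, cfg$sim,
                      cfg$preproc, cfg$behavior, cfg$band_set,
                      cfg$gamma_band, cfg$epoch_window,
                      cfg$baseline_window, cfg$channel_subset),
                 function() analyze_subject(sub, cfg)))
  ns <- length(subjects)
  res <- list()
  summary <- list(n_subjects = ns, seed = cfg$seed, n_perm = cfg$n_perm,
                  alpha = cfg$alpha, band_set = cfg$band_set,
                  contrasts = cfg$contrasts)

  freqs <- subjects[[1]]$tf_freqs
  times <- subjects[[1]]$tf_times
  # subjects missing one outcome class (no failed or no successful stop
  # epochs) cannot contribute to a paired contrast and are dropped
  stack_maps <- function(field_a, field_b = NULL) {
    mats <- list()
    for (j in seq_len(ns)) {
      a <- subjects[[j]][[field_a]]
      if (is.null(a)) next
      if (!is.null(field_b)) {
        b <- subjects[[j]][[field_b]]
        if (is.null(b)) next
        a <- a - b
      }
      if (anyNA(a)) next
      mats[[length(mats) + 1]] <- a
    }
    if (length(mats) < 2)
      stop("fewer than two subjects with complete maps", call. = FALSE)
    arr <- array(NA_real_, c(length(mats), length(freqs), length(times)))
    for (j in seq_along(mats)) arr[j, , ] <- mats[[j]]
    arr
  }
  stop_win <- mean(vapply(subjects, `[[`, numeric(1), "stop_win"))
  summary$stop_window_ms <- stop_win * 1000
  beh <- do.call(rbind, lapply(subjects, function(s)
    cbind(subject = s$rec$subject_id, as.data.frame(s$trials))))
  summary$success_rate_pct <- 100 * mean(
    beh$outcome[!beh$excluded] != "failed")
  summary$mean_stop_delay_ms <- mean(vapply(subjects, function(s)
    mean(s$trials$stop_delay), numeric(1)))

  if ("success_vs_fail" %in% cfg$contrasts) {
    d <- stack_maps("map_success", "map_fail")
    res$success_vs_fail <- cluster_permutation(
      d, cfg$n_perm, cfg$threshold_p, cfg$alpha, seed = cfg$seed + 11L)
    summary$success_vs_fail <- cluster_summary(res$success_vs_fail,
                                               freqs, times)
  }
  if ("stop_vs_prev_tap" %in% cfg$contrasts) {
    d <- stack_maps("map_all", "map_virtual")
    res$stop_vs_prev_tap <- cluster_permutation(
      d, cfg$n_perm, cfg$threshold_p, cfg$alpha, seed = cfg$seed + 12L)
    summary$stop_vs_prev_tap <- cluster_summary(res$stop_vs_prev_tap,
                                                freqs, times)
  }
  if ("prestop_window" %in% cfg$contrasts) {
    pre <- which(times < 0)
    d <- stack_maps("map_success", "map_fail")[, , pre, drop = FALSE]
    res$prestop_window <- cluster_permutation(
      d, cfg$n_perm, cfg$threshold_p, cfg$alpha, seed = cfg$seed + 13L)
    summary$prestop_window <- cluster_summary(res$prestop_window, freqs,
                                              times[pre])
  }
  if (any(c("band_timecourses", "peak_latency") %in% cfg$contrasts)) {
    tc_s <- t(vapply(subjects, function(s)
      colMeans(band_timecourse(s$stop_epochs,
                               cfg$gamma_band)[s$success, , drop = FALSE]),
      numeric(length(times))))
    tc_f <- t(vapply(subjects, function(s)
      colMeans(band_timecourse(s$stop_epochs,
                               cfg$gamma_band)[!s$success, , drop = FALSE]),
      numeric(length(times))))
    if ("band_timecourses" %in% cfg$contrasts) {
      d_tc <- tc_s - tc_f
      d_tc <- d_tc[rowSums(!is.finite(d_tc)) == 0, , drop = FALSE]
      res$band_timecourses <- cluster_permutation_1d(
        d_tc, cfg$n_perm, cfg$threshold_p, cfg$alpha,
        seed = cfg$seed + 14L)
      summary$band_timecourses <- cluster_summary(res$band_timecourses,
                                                  cfg$gamma_band, times)
    }
    if ("peak_latency" %in% cfg$contrasts) {
      lat_s <- apply(tc_s, 1, peak_latency, times = times,
                     window = cfg$peak_window)
      lat_f <- apply(tc_f, 1, peak_latency, times = times,
                     window = cfg$peak_window)
      pt <- if (length(lat_s) >= 5 && !anyNA(lat_s) && !anyNA(lat_f))
        paired_test(lat_s, lat_f)
      else list(statistic = NA_real_, p = NA_real_,
                test_used = "none", normality_p = NA_real_)
      res$peak_latency <- list(success_ms = lat_s, fail_ms = lat_f,
                               test = pt)
      summary$peak_latency <- list(
        mean_success_ms = mean(lat_s, na.rm = TRUE),
        mean_fail_ms = mean(lat_f, na.rm = TRUE),
        p = pt$p, test_used = pt$test_used)
    }
  }
  if ("corr_extent_gamma" %in% cfg$contrasts) {
    per_sub <- lapply(seq_len(ns), function(j) {
      s <- subjects[[j]]
      max_corr_search(s$stop_epochs, s$extents, band = cfg$gamma_band,
                      window = c(0, stop_win), n_boot = cfg$n_boot,
                      seed = cfg$seed + 20L + j)
    })
    rhos <- vapply(per_sub, `[[`, numeric(1), "rho")
    res$corr_extent_gamma <- list(per_subject = per_sub, rhos = rhos,
                                  group = fisherz_group_test(rhos))
    summary$corr_extent_gamma <- list(
      mean_rho = mean(rhos, na.rm = TRUE),
      group_t = res$corr_extent_gamma$group$t,
      group_p = res$corr_extent_gamma$group$p)
  }
  if ("behavior_correlations" %in% cfg$contrasts) {
    res$behavior_correlations <- behavior_correlation_table(
      subjects, cfg)
    summary$behavior_correlations <-
      res$behavior_correlations[, c("variable", "mean_rho", "p",
                                    "p_fdr")]
  }
  if ("ispc_change" %in% cfg$contrasts) {
    isres <- ispc_contrast(subjects, cfg)
    res$ispc_change <- isres
    summary$ispc_change <- isres$summary
  }
  structure(list(summary = summary, results = res, subjects = subjects,
                 config = cfg, trials = beh),
            class = "report_bundle")
}

cluster_summary <- function(cr, freqs, times) {
  sig <- which(vapply(cr$clusters, function(cl) cl$p_perm <= cr$alpha,
                      logical(1)))
  inv <- lapply(seq_along(cr$clusters), function(i) {
    cl <- cr$clusters[[i]]
    mask <- cl$mask
    if (is.matrix(mask)) {
      fr <- range(freqs[rowSums(mask) > 0])
      tr <- range(times[colSums(mask) > 0])
    } else {
      fr <- range(freqs); tr <- range(times[mask])
    }
    list(sign = cl$sign, mass = cl$mass, p = cl$p_perm,
         freq_lo = fr[1], freq_hi = fr[2],
         t_lo_ms = tr[1] * 1000, t_hi_ms = tr[2] * 1000)
  })
  list(n_clusters = length(cr$clusters), n_significant = length(sig),
       clusters = inv)
}

# Table-1-style analysis: per-subject Spearman correlations between the
# last regular tap's covariates and movement extent, Fisher-z group
# t-tests, BH-FDR over the covariate family.
behavior_correlation_table <- function(subjects, cfg) {
  vars <- c("soundOffset", "downTime", "maxPres", "tapNr", "peakVelDown",
            "upMvmt", "peakVelUp")
  per_sub <- lapply(subjects, function(s) {
    tm <- tap_metrics(s$events, s$rec, cfg$behavior)
    tm <- tm[match(s$trials$trial_idx, tm$trial_idx), ]
    ok <- !s$trials$excluded
    cbind(tm[ok, ], extent = s$trials$movement_extent[ok])
  })
  rows <- lapply(vars, function(v) {
    rhos <- vapply(per_sub, function(df) {
      x <- df[[v]]; y <- df$extent
      keep <- is.finite(x) & is.finite(y)
      if (sum(keep) < 5 || sd(x[keep]) == 0) return(NA_real_)
      cor(x[keep], y[keep], method = "spearman")
    }, numeric(1))
    gt <- tryCatch(fisherz_group_test(rhos),
                   error = function(e) list(t = NA, p = NA))
    data.frame(variable = v, mean_rho = mean(rhos, na.rm = TRUE),
               sd_rho = sd(rhos, na.rm = TRUE), t = gt$t, p = gt$p)
  })
  tab <- do.call(rbind, rows)
  tab$p_fdr <- bh_fdr(ifelse(is.na(tab$p), 1, tab$p))
  tab
}

ispc_contrast <- function(subjects, cfg) {
  ns <- length(subjects)
  maps <- vector("list", ns)
  for (j in seq_len(ns)) {
    s <- subjects[[j]]
    if (is.na(s$lat$m1_contra)) next  # subject without EEG: skip
    seed_sig <- channel_data(s$rec, s$lat$stn_contra)
    targ <- list(m1 = channel_data(s$rec, s$lat$m1_contra))
    keep_t <- s$trials$stop_time[!s$trials$excluded]
    m <- ispc_map(seed_sig, targ, s$rec$sample_rate, keep_t,
                  spec = cfg$ispc, fb = analysis_bands(cfg),
                  subject_id = s$rec$subject_id)$m1
    maps[[j]] <- normalize_ispc(m, cfg$ispc$baseline)
  }
  have <- !vapply(maps, is.null, logical(1))
  maps <- maps[have]
  if (length(maps) < 2)
    return(list(summary = list(note = "insufficient EEG subjects")))
  freqs <- maps[[1]]$freqs; times <- maps[[1]]$times
  arr <- array(NA_real_, c(length(maps), length(freqs), length(times)))
  for (j in seq_along(maps)) arr[j, , ] <- maps[[j]]$values
  cr <- cluster_permutation(arr, cfg$n_perm, cfg$threshold_p, cfg$alpha,
                            seed = cfg$seed + 15L)
  post <- times > 0
  gsel <- freqs >= cfg$gamma_band[1] & freqs <= cfg$gamma_band[2]
  list(maps = maps, cluster = cr,
       summary = list(
         mean_postcue_gamma_change =
           mean(arr[, gsel, post, drop = FALSE]),
         cluster = cluster_summary(cr, freqs, times)))
}

#' Write a report bundle to disk
#'
#' Emits `summary.json` (machine-readable summary including all seeds
#' and permutation counts), `trials.tsv` (pooled trial table) and, per
#' cluster contrast, a `clusters_<name>.tsv` inventory. Output is
#' byte-deterministic for identical bundles.
#'
#' @param bundle a `report_bundle` from [run_pipeline()].
#' @param path output directory (created if needed).
#' @return `path`, invisibly.
#' @export
report <- function(bundle, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  json <- jsonlite::toJSON(bundle$summary, auto_unbox = TRUE,
                           digits = NA, pretty = TRUE, na = "null")
  con <- file(file.path(path, "summary.json"), open = "wb")
  writeBin(charToRaw(paste0(as.character(json), "\n")), con)
  close(con)
  write.table(bundle$trials, file.path(path, "trials.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  for (nm in names(bundle$results)) {
    r <- bundle$results[[nm]]
    if (!inherits(r, "cluster_result")) next
    inv <- do.call(rbind, lapply(r$clusters, function(cl)
      data.frame(sign = cl$sign, mass = cl$mass, p = cl$p_perm)))
    if (is.null(inv)) inv <- data.frame(sign = integer(), mass = numeric(),
                                        p = numeric())
    write.table(inv, file.path(path, paste0("clusters_", nm, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
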