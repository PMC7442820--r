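#' Response and noise windows for evoked-trial metrics
#'
#' Defaults follow the acute-stimulation analysis: the compound response is
#' quantified 0.75-4 ms after stimulation onset (consistent with conduction
#' latencies of small myelinated axons over the recording distance) and
#' compared against a 10.75-14 ms "noise" window well after the response;
#' both lie outside the 0-0.5 ms stimulation-artifact span.
#'
#' @param signal ms pair, response window (default c(0.75, 4))
#' @param noise ms pair, noise window (default c(10.75, 14))
#' @return a `response_windows`
#' @export
response_windows <- function(signal = c(0.75, 4), noise = c(10.75, 14)) {
  stopifnot(signal[1] < signal[2], noise[1] < noise[2])
  if (max(signal[1], noise[1]) < 0.5)
    stop("windows must start after the 0-0.5 ms artifact span")
  if (signal[2] > noise[1] && noise[2] > signal[1])
    stop("signal and noise windows must be disjoint")
  structure(list(signal = signal, noise = noise), class = "response_windows")
}

# Detect the stimulation-artifact onset in one trial: first sample in the
# [-1, +1] ms neighborhood of nominal zero whose absolute amplitude
# exceeds `k` times the MAD-based SD of the pre-stimulus baseline.
find_artifact_onset <- function(trial, k = 8) {
  t <- trial$times
  base <- trial$trace[t < -1e-3]
  s <- stats::mad(base)
  if (s == 0) s <- stats::sd(base)
  if (s == 0) s <- 1e-9
  cand <- which(t >= -1e-3 & t <= 1e-3 & abs(trial$trace) > k * s)
  if (length(cand) == 0) return(NA_integer_)
  cand[1]
}

#' Align evoked trials on the stimulation-artifact onset
#'
#' Sets t = 0 at the detected artifact onset of every trial by shifting the
#' trace an integer number of samples. Trials with no detectable artifact
#' are flagged and excluded.
#'
#' @param trials list of `evoked_trial`s
#' @return list: `trials` (aligned), `excluded` (indices with no artifact)
#' @export
align_trials <- function(trials) {
  zero_idx <- which.min(abs(trials[[1]]$times))
  excluded <- integer(0)
  out <- list()
  for (i in seq_along(trials)) {
    tr <- trials[[i]]
    on <- find_artifact_onset(tr)
    if (is.na(on)) {
      excluded <- c(excluded, i)
      next
    }
    shift <- on - zero_idx
    v <- tr$trace
    n <- length(v)
    if (shift > 0) v <- c(v[(shift + 1):n], rep(v[n], shift))
    else if (shift < 0) v <- c(rep(v[1], -shift), v[1:(n + shift)])
    tr$trace <- v
    out[[length(out) + 1]] <- tr
  }
  list(trials = out, excluded = excluded)
}

# Extract a window (ms pair, relative to stimulation onset) from a trial.
window_samples <- function(trial, win_ms) {
  idx <- trial$times >= win_ms[1] / 1000 & trial$times <= win_ms[2] / 1000
  if (!any(idx)) stop("window outside the trial's time span")
  trial$trace[idx]
}

#' Response amplitude and SNR of evoked trials
#'
#' Vpp is max - min within the signal window; SNR is
#' `10 * log10(RMS_signal / RMS_noise)` over the two windows. By default
#' the metrics are taken on the mean trace over trials (the trial-mean
#' aggregation used for recruitment curves, nominally over 20 trials);
#' `aggregate = FALSE` returns per-trial metrics.
#'
#' @param trials a single `evoked_trial` or a list of them
#' @param windows a `response_windows`
#' @param aggregate average traces across trials before computing metrics
#' @return list (aggregate) or data.frame (per-trial) with `vpp` (uV) and
#'   `snr_db`
#' @export
response_metrics <- function(trials, windows = response_windows(),
                             aggregate = TRUE) {
  if (inherits(trials, "evoked_trial")) trials <- list(trials)
  if (aggregate) {
    m <- rowMeans(vapply(trials, function(tr) tr$trace,
                         numeric(length(trials[[1]]$trace))))
    mt <- trials[[1]]
    mt$trace <- m
    s <- window_samples(mt, windows$signal)
    nz <- window_samples(mt, windows$noise)
    list(vpp = diff(range(s)), snr_db = 10 * log10(rms(s) / rms(nz)),
         n_trials = length(trials))
  } else {
    do.call(rbind, lapply(trials, function(tr) {
      s <- window_samples(tr, windows$signal)
      nz <- window_samples(tr, windows$noise)
      data.frame(current = tr$current, vpp = diff(range(s)),
                 snr_db = 10 * log10(rms(s) / rms(nz)))
    }))
  }
}

#' Bootstrap detection of an evoked response
#'
#' The observed statistic is the SNR of the trial-mean trace (RMS of the
#' signal window over RMS of the noise window, in dB). The null
#' distribution is built by resampling with replacement both a
#' signal-window-sized and a noise-window-sized sample from the pooled
#' noise-window samples and recomputing the statistic, `n_boot` times. A
#' response is detected when the observed SNR exceeds the upper limit of
#' the two-sided `level` CI of that null (one-sided exceedance of a 90%
#' CI, hence a nominal 5% false-positive rate). `convention =
#' "ci_of_observed"` instead bootstraps the observed windows and detects
#' when the lower CI limit of the observed SNR exceeds 0 dB.
#'
#' @param trials list of `evoked_trial`s (>= 8)
#' @param windows a `response_windows`
#' @param n_boot bootstrap resamples (default 10000)
#' @param level CI level (default 0.90)
#' @param convention `"null_ci"` (default) or `"ci_of_observed"`
#' @param seed integer seed
#' @return list: `detected`, `observed_snr_db`, `ci` (the relevant
#'   bootstrap CI), `convention`
#' @export
detect_response <- function(trials, windows = response_windows(),
                            n_boot = 10000, level = 0.90,
                            convention = c("null_ci", "ci_of_observed"),
                            seed = 1) {
  convention <- match.arg(convention)
  if (length(trials) < 8) stop("need >= 8 trials for bootstrap detection")
  m <- rowMeans(vapply(trials, function(tr) tr$trace,
                       numeric(length(trials[[1]]$trace))))
  mt <- trials[[1]]
  mt$trace <- m
  s <- window_samples(mt, windows$signal)
  nz <- window_samples(mt, windows$noise)
  if (stats::sd(nz) == 0) stop("degenerate noise window (zero variance)")
  obs <- 10 * log10(rms(s) / rms(nz))
  alpha <- (1 - level) / 2
  with_seed(child_seed(seed, 9), {
    if (convention == "null_ci") {
      boot <- vapply(seq_len(n_boot), function(b) {
        bs <- sample(nz, length(s), replace = TRUE)
        bn <- sample(nz, length(nz), replace = TRUE)
        10 * log10(rms(bs) / rms(bn))
      }, numeric(1))
      ci <- stats::quantile(boot, c(alpha, 1 - alpha), names = FALSE)
      detected <- obs > ci[2]
    } else {
      boot <- vapply(seq_len(n_boot), function(b) {
        bs <- sample(s, length(s), replace = TRUE)
        bn <- sample(nz, length(nz), replace = TRUE)
        10 * log10(rms(bs) / rms(bn))
      }, numeric(1))
      ci <- stats::quantile(boot, c(alpha, 1 - alpha), names = FALSE)
      detected <- ci[1] > 0
    }
    list(detected = detected, observed_snr_db = obs, ci = ci,
         convention = convention)
  })
}

#' Fit a sigmoidal recruitment curve over stimulation currents
#'
#' Least-squares fit of `Vpp(I) = baseline + vmax / (1 + exp(-(I - i50) /
#' slope))` to trial-mean Vpp per current. The threshold current is
#' operational: the smallest tested current at which bootstrap detection
#' fires; if none fires it is reported as censored above the maximum
#' tested current.
#'
#' @param trials list of `evoked_trial`s spanning >= 4 distinct currents
#' @param windows a `response_windows`
#' @param n_boot resamples for the per-current detection calls
#' @param seed integer seed
#' @return a `recruitment_fit`: vmax, i50, slope, baseline (uV),
#'   threshold_current (uA, possibly `Inf` = censored), `censored`,
#'   per-current table, fit covariance, convergence info
#' @export
recruitment_curve <- function(trials, windows = response_windows(),
                              n_boot = 2000, seed = 1) {
  currents <- vapply(trials, function(tr) tr$current, numeric(1))
  u <- sort(unique(currents))
  if (length(u) < 4) stop("need >= 4 distinct currents")
  tab <- do.call(rbind, lapply(u, function(cur) {
    sub <- trials[currents == cur]
    rm <- response_metrics(sub, windows)
    det <- tryCatch(detect_response(sub, windows, n_boot = n_boot,
                                    seed = child_seed(seed, round(cur * 16))),
                    error = function(e) list(detected = NA))
    data.frame(current = cur, vpp = rm$vpp, snr_db = rm$snr_db,
               n = length(sub), detected = det$detected)
  }))
  start <- list(baseline = min(tab$vpp),
                vmax = max(diff(range(tab$vpp)), 1e-6),
                i50 = stats::approx(tab$vpp, tab$current,
                                    xout = min(tab$vpp) + diff(range(tab$vpp)) / 2,
                                    ties = mean, rule = 2)$y,
                slope = max(diff(range(u)) / 10, 1e-3))
  det_cur <- tab$current[which(tab$detected %in% TRUE)]
  threshold <- if (length(det_cur)) min(det_cur) else Inf
  base <- list(threshold_current = threshold,
               censored = !is.finite(threshold),
               max_tested = max(u), table = tab)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      vpp ~ baseline + vmax / (1 + exp(-(current - i50) / slope)),
      data = tab, start = start,
      lower = c(baseline = 0, vmax = 0, i50 = min(u) - diff(range(u)),
                slope = 1e-4),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) e)
  if (inherits(fit, "error")) {
    return(structure(c(list(converged = FALSE,
                            error = conditionMessage(fit)), base),
                     class = "recruitment_fit"))
  }
  cf <- stats::coef(fit)
  structure(c(list(vmax = unname(cf["vmax"]), i50 = unname(cf["i50"]),
                   slope = unname(cf["slope"]),
                   baseline = unname(cf["baseline"]),
                   covariance = stats::vcov(fit),
                   converged = TRUE), base),
            class = "recruitment_fit")
}

#' Compare evoked amplitudes across paired pharmacological conditions
#'
#' Per-subject amplitudes are normalized to the subject's baseline mean;
#' the condition effect is tested with a repeated-measures ANOVA on
#' subject-by-condition means (sphericity checked by Mauchly's test where
#' the covariance permits; the Huynh-Feldt degree-of-freedom correction is
#' applied when sphericity is violated or untestable), followed by Dunnett
#' contrasts of every condition against the control.
#'
#' @param data data.frame: `subject`, `condition`, `amplitude` (uV), with
#'   every subject measured in every condition
#' @param control control condition for normalization-free Dunnett
#'   contrasts (default `"saline"` falling back to `"baseline"`)
#' @param baseline condition used to normalize amplitudes (default
#'   `"baseline"`)
#' @return list: `normalized` (per-subject condition means / baseline
#'   mean), `anova` (F, df, p, epsilon, sphericity p), `dunnett`
#'   (contrast estimates + p-values vs control)
#' @export
condition_compare <- function(data, control = NULL, baseline = "baseline") {
  stopifnot(all(c("subject", "condition", "amplitude") %in% names(data)))
  conds <- unique(data$condition)
  if (length(conds) < 2) stop("need >= 2 conditions")
  subs <- unique(data$subject)
  full <- table(data$subject, data$condition)
  if (any(full == 0)) stop("conditions must be paired within every subject")
  if (is.null(control))
    control <- if ("saline" %in% conds) "saline" else baseline
  # subject x condition mean matrix
  agg <- stats::aggregate(amplitude ~ subject + condition, data, mean)
  M <- stats::xtabs(amplitude ~ subject + condition, agg)
  M <- matrix(as.numeric(M[, conds, drop = FALSE]), nrow = nrow(M),
              dimnames = list(rownames(M), conds))
  base_mean <- M[, baseline]
  Mn <- sweep(M, 1, base_mean, "/")
  # repeated-measures ANOVA with Huynh-Feldt correction on the raw means
  k <- ncol(M); n <- nrow(M)
  sub_means <- rowMeans(M); cond_means <- colMeans(M); gm <- mean(M)
  ss_cond <- n * sum((cond_means - gm)^2)
  resid <- M - outer(sub_means, rep(1, k)) - outer(rep(1, n), cond_means) + gm
  ss_err <- sum(resid^2)
  df1 <- k - 1; df2 <- (k - 1) * (n - 1)
  f_stat <- (ss_cond / df1) / (ss_err / df2)
  # Greenhouse-Geisser epsilon from orthonormal contrasts of the
  # condition covariance, then the Huynh-Feldt adjustment
  S <- stats::cov(M)
  C <- t(stats::contr.helmert(k))
  C <- C / sqrt(rowSums(C^2))
  V <- C %*% S %*% t(C)
  trV <- sum(diag(V))
  eps_gg <- if (trV > 0 && sum(V^2) > 0)
    min(1, trV^2 / ((k - 1) * sum(V^2))) else 1 / (k - 1)
  eps_hf <- min(1, (n * (k - 1) * eps_gg - 2) /
                  ((k - 1) * (n - 1 - (k - 1) * eps_gg)))
  eps_hf <- max(eps_hf, 1 / (k - 1))
  # with very few subjects the condition covariance is singular (the
  # sphericity statistic degenerates to W = 0); treat as untestable
  mauchly_p <- tryCatch(suppressWarnings({
    fitlm <- stats::lm(M ~ 1)
    stats::mauchly.test(fitlm, X = ~1)$p.value
  }), error = function(e) NA_real_)
  use_eps <- if (is.na(mauchly_p) || mauchly_p < 0.05) eps_hf else 1
  p <- stats::pf(f_stat, df1 * use_eps, df2 * use_eps, lower.tail = FALSE)
  anova_res <- list(F = f_stat, df1 = df1 * use_eps, df2 = df2 * use_eps,
                    p = p, epsilon = use_eps, mauchly_p = mauchly_p)
  # Dunnett contrasts vs control on normalized per-subject means
  long <- data.frame(
    subject = factor(rep(rownames(Mn), k)),
    condition = factor(rep(colnames(Mn), each = n)),
    value = as.numeric(Mn))
  long$condition <- stats::relevel(long$condition, ref = control)
  dun <- tryCatch({
    # subject as a blocking factor, Dunnett on the condition effect
    fit2 <- stats::lm(value ~ subject + condition, data = long)
    gl <- multcomp::glht(fit2, linfct = multcomp::mcp(condition = "Dunnett"))
    sm <- summary(gl)
    data.frame(contrast = names(sm$test$coefficients),
               estimate = as.numeric(sm$test$coefficients),
               p_value = as.numeric(sm$test$pvalues))
  }, error = function(e) data.frame(contrast = character(0),
                                    estimate = numeric(0),
                                    p_value = numeric(0)))
  list(normalized = Mn, anova = anova_res, dunnett = dun,
       control = control)
}

#' Compression force corresponding to a pressure over a contact area
#'
#' Converts an interface pressure (mmHg) applied over a nerve-contact area
#' (mm^2) to force in micronewtons: `F = P x 133.322 Pa/mmHg x A`. At the
#' 30 mmHg compression-damage limit over a 0.03 mm^2 contact area this
#' gives the ~120 uN upper force bound used to assess implant safety.
#'
#' @param pressure_mmHg pressure, mmHg (> 0 for a physical bound)
#' @param area_mm2 contact area, mm^2
#' @return force in microNewtons
#' @export
compression_force_limit <- function(pressure_mmHg, area_mm2) {
  stopifnot(pressure_mmHg >= 0, area_mm2 > 0)
  pa <- pressure_mmHg * 133.322        # N/m^2
  area_m2 <- area_mm2 * 1e-6
  pa * area_m2 * 1e6                   # uN
}
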