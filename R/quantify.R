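#' Fit a Gaussian to a binned velocity histogram
#'
#' Velocities are binned at a fixed width anchored at 0 and the resulting
#' histogram is fitted to a Gaussian by unweighted nonlinear least squares
#' with free amplitude, mean and standard deviation. The model value for a
#' bin is the integrated Gaussian mass over the bin (scaled by the
#' amplitude), which is exact where a bin-centre evaluation is only
#' approximate. When a `detection_floor` is given (velocities below it are
#' unobservable), the mass below the floor is excluded from every bin's
#' prediction, so the fitted mean and sd refer to the underlying untruncated
#' Gaussian. The reported `+/-` on a velocity is this fitted sd, not a
#' standard error.
#'
#' @param velocities Numeric vector of velocities (nt/s), or a data frame
#'   with a `velocity_nt_s` column.
#' @param bin_width Histogram bin width in nt/s.
#' @param detection_floor Velocity below which events cannot be observed
#'   (0 = none).
#' @return A `gaussian_fit` object: fields `mean_nt_s`, `sd_nt_s`,
#'   `amplitude`, `bin_width_nt_s`, `n`, `histogram` (tibble of bins),
#'   `converged`.
#' @examples
#' set.seed(1)
#' fit <- fit_velocity_gaussian(rnorm(5000, 30, 10))
#' fit$mean_nt_s
#' @export
fit_velocity_gaussian <- function(velocities, bin_width = 10,
                                  detection_floor = 0) {
  if (is.data.frame(velocities)) velocities <- velocities$velocity_nt_s
  v <- velocities[is.finite(velocities)]
  if (length(v) < 10) {
    abort(sprintf(
      "need at least 10 velocities to fit a histogram (got %d); fall back to raw moments: mean %.3g, sd %.3g.",
      length(v), mean(v), sd(v)))
  }
  # bin edges anchored at multiples of the bin width (0 is always an edge);
  # extended below zero only if the sample demands it
  breaks <- seq(bin_width * floor(min(v, 0) / bin_width),
                max(v) + bin_width, by = bin_width)
  h <- graphics::hist(v, breaks = breaks, plot = FALSE)
  bins <- tibble::tibble(lo = head(breaks, -1), hi = breaks[-1],
                         mid = h$mids, count = h$counts)
  floor_v <- detection_floor
  n <- length(v)
  m0 <- min(max(mean(v), bin_width), max(v))
  s0 <- max(sd(v), bin_width / 2)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      count ~ A * (pnorm((hi - mu) / sg) - pnorm((pmax(lo, floor_v) - mu) / sg)),
      data = bins,
      start = list(A = n, mu = m0, sg = s0),
      lower = c(1e-9, 0, bin_width / 10),
      upper = c(Inf, 2 * max(v), 2 * max(v)),
      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) e)
  if (inherits(fit, "error")) {
    abort(sprintf(
      "Gaussian histogram fit did not converge (%s); raw sample mean %.4g, sd %.4g.",
      conditionMessage(fit), mean(v), sd(v)))
  }
  cf <- coef(fit)
  # a mean collapsed onto its lower bound (with inflated sd) means the
  # histogram does not constrain a peak: treat as non-convergence
  if (cf["mu"] <= 1e-6 || cf["sg"] >= 2 * max(v) - 1e-6) {
    abort(sprintf(
      "Gaussian histogram fit is degenerate (no resolvable peak); raw sample mean %.4g, sd %.4g.",
      mean(v), sd(v)))
  }
  structure(list(
    mean_nt_s = unname(cf["mu"]),
    sd_nt_s = unname(cf["sg"]),
    amplitude = unname(cf["A"]),
    bin_width_nt_s = bin_width,
    detection_floor = detection_floor,
    n = n,
    histogram = bins,
    method = "histogram",
    converged = TRUE
  ), class = "gaussian_fit")
}

#' Empirical survival curve of run lengths
#'
#' Fraction of runs at least as long as each observed distance:
#' `S(d) = mean(run_lengths >= d)`, evaluated at every observed distance
#' (right-continuous step convention; `S` at the smallest observation is 1
#' when it is unique, and `S(0) = 1` always).
#'
#' @param run_lengths_nt Numeric vector of run lengths (nt), or a data frame
#'   with a `run_length_nt` column.
#' @return A tibble with columns `distance_nt` (sorted) and `surviving`
#'   (nonincreasing).
#' @examples
#' survival_curve(c(1, 2, 3)) # S = 1, 2/3, 1/3
#' @export
survival_curve <- function(run_lengths_nt) {
  if (is.data.frame(run_lengths_nt)) run_lengths_nt <- run_lengths_nt$run_length_nt
  d <- run_lengths_nt[is.finite(run_lengths_nt)]
  if (length(d) == 0) abort("no run lengths supplied.")
  d <- sort(d)
  tibble::tibble(
    distance_nt = d,
    surviving = vapply(d, function(x) mean(d >= x), numeric(1))
  )
}

#' Fit a single-exponential decay to a survival curve
#'
#' Least-squares fit of `S(d) = exp(-d * log(2) / halflife)` to the
#' empirical survival curve, amplitude fixed at 1 (the curve starts at 1 by
#' construction). The half-life is the distance at which survival reaches
#' 0.5 under the fitted model, reported in kilonucleotides. The confidence
#' interval is a percentile bootstrap over run lengths.
#'
#' @param curve Tibble from [survival_curve()], or a numeric vector of run
#'   lengths (the curve is then built internally).
#' @param ci Whether to bootstrap a confidence interval.
#' @param n_boot Bootstrap replicates.
#' @param level Confidence level.
#' @param seed Optional integer seed for the bootstrap.
#' @return A `survival_fit` object: `halflife_knt`, `decay_rate_per_knt`,
#'   `ci_low`, `ci_high`, `n`, `curve`.
#' @examples
#' set.seed(1)
#' fit_survival_halflife(rexp(500, log(2) / 4100), ci = FALSE)
#' @export
fit_survival_halflife <- function(curve, ci = TRUE, n_boot = 1000,
                                  level = 0.95, seed = NULL) {
  if (is.numeric(curve)) curve <- survival_curve(curve)
  if (nrow(curve) < 10) abort("survival fit needs at least 10 observations.")
  if (diff(range(curve$distance_nt)) == 0) {
    abort("degenerate survival curve: all run lengths identical.")
  }
  hl_nt <- fit_halflife_ls(curve$distance_nt, curve$surviving)
  ci_low <- ci_high <- NA_real_
  if (ci) {
    d <- curve$distance_nt
    bounds <- bootstrap_ci(d, function(x) {
      cv <- survival_curve(x)
      tryCatch(fit_halflife_ls(cv$distance_nt, cv$surviving),
               error = function(e) NA_real_)
    }, n_boot = n_boot, level = level, seed = seed)
    ci_low <- bounds[[1]] / 1000
    ci_high <- bounds[[2]] / 1000
  }
  structure(list(
    halflife_knt = hl_nt / 1000,
    decay_rate_per_knt = log(2) / (hl_nt / 1000),
    ci_low = ci_low,
    ci_high = ci_high,
    n = nrow(curve),
    curve = curve
  ), class = "survival_fit")
}

fit_halflife_ls <- function(d, S) {
  # start at the distance where the curve crosses 0.5 (the half-life under
  # the model); fall back to a median-based guess for short curves
  start <- d[which.min(abs(S - 0.5))]
  if (!is.finite(start) || start <= 0) start <- max(median(d), 1e-6) * 1.44
  fit <- minpack.lm::nlsLM(
    S ~ exp(-d * log(2) / hl),
    data = data.frame(d = d, S = S),
    start = list(hl = start), lower = 1e-9,
    control = minpack.lm::nls.lm.control(maxiter = 500))
  unname(coef(fit)["hl"])
}

#' Percentile bootstrap confidence interval
#'
#' Resamples the input with replacement `n_boot` times, applies `statistic`,
#' and returns the percentile interval of the replicates. Deterministic for
#' a fixed seed.
#'
#' @param sample A vector (or data frame resampled by row).
#' @param statistic Function of a resample returning a single number.
#' @param n_boot Number of bootstrap replicates.
#' @param level Confidence level.
#' @param seed Optional integer seed.
#' @return A tibble with columns `low` and `high`.
#' @examples
#' bootstrap_ci(rnorm(100), mean, n_boot = 200, seed = 1)
#' @export
bootstrap_ci <- function(sample, statistic, n_boot = 1000, level = 0.95,
                         seed = NULL) {
  n <- if (is.data.frame(sample)) nrow(sample) else length(sample)
  if (n == 0) abort("empty sample.")
  alpha <- (1 - level) / 2
  reps <- with_seed_if(seed, {
    vapply(seq_len(n_boot), function(i) {
      idx <- sample.int(n, n, replace = TRUE)
      s <- if (is.data.frame(sample)) sample[idx, , drop = FALSE] else sample[idx]
      as.numeric(statistic(s))
    }, numeric(1))
  })
  qs <- quantile(reps, c(alpha, 1 - alpha), na.rm = TRUE, names = FALSE)
  tibble::tibble(low = qs[1], high = qs[2])
}

#' Colocalization fraction of binding events
#'
#' Fraction of binding events whose position coincides with a cluster
#' (`colocalized` flag), with a percentile-bootstrap confidence interval
#' over events.
#'
#' @param events Tibble with a logical `colocalized` column (see
#'   [classify_events()]), or a logical vector.
#' @param n_boot,level,seed Bootstrap settings.
#' @return A `coloc_result`: `n_coloc`, `n_total`, `fraction`, `percent`
#'   (rounded to integer percent), `ci_low`, `ci_high`.
#' @examples
#' coloc_fraction(c(rep(TRUE, 270), rep(FALSE, 72)), seed = 1)
#' @export
coloc_fraction <- function(events, n_boot = 1000, level = 0.95, seed = NULL) {
  flags <- if (is.data.frame(events)) events$colocalized else events
  if (length(flags) == 0) abort("no events supplied.")
  frac <- mean(flags)
  ci <- bootstrap_ci(flags, mean, n_boot = n_boot, level = level, seed = seed)
  structure(list(
    n_coloc = sum(flags),
    n_total = length(flags),
    fraction = frac,
    percent = round(100 * frac),
    ci_low = ci$low,
    ci_high = ci$high
  ), class = "coloc_result")
}

#' Binding-position distribution along the molecule
#'
#' Positions are normalised to `[0, 1]` by the molecule length and counted
#' in fixed-width bins; densities (bin probabilities) sum to 1. Per-bin
#' uncertainties are percentile-bootstrap intervals over events.
#'
#' @param events Tibble with `position_nt` (see [classify_events()]), or a
#'   numeric vector of positions.
#' @param molecule_length_nt Molecule length (nt).
#' @param n_bins Number of bins.
#' @param n_boot,level,seed Bootstrap settings.
#' @return A tibble: `bin`, `mid` (normalised position), `count`, `density`,
#'   `ci_low`, `ci_high`.
#' @export
binding_distribution <- function(events, molecule_length_nt, n_bins = 10,
                                 n_boot = 1000, level = 0.95, seed = NULL) {
  pos <- if (is.data.frame(events)) events$position_nt else events
  if (any(pos < 0 | pos > molecule_length_nt)) {
    abort("event positions must lie within the molecule.")
  }
  u <- pos / molecule_length_nt
  breaks <- seq(0, 1, length.out = n_bins + 1)
  bin_of <- function(x) pmin(findInterval(x, breaks, rightmost.closed = TRUE),
                             n_bins)
  counts <- tabulate(bin_of(u), nbins = n_bins)
  n <- length(u)
  alpha <- (1 - level) / 2
  reps <- with_seed_if(seed, {
    vapply(seq_len(n_boot), function(i) {
      tabulate(bin_of(sample(u, n, replace = TRUE)), nbins = n_bins) / n
    }, numeric(n_bins))
  })
  tibble::tibble(
    bin = seq_len(n_bins),
    mid = (head(breaks, -1) + breaks[-1]) / 2,
    count = counts,
    density = counts / n,
    ci_low = apply(reps, 1, quantile, probs = alpha, names = FALSE),
    ci_high = apply(reps, 1, quantile, probs = 1 - alpha, names = FALSE)
  )
}

#' Two-sample comparison of velocity distributions
#'
#' Two-sided two-sample t test. The default is Welch's form (unequal
#' variances); `pooled = TRUE` gives the classical Student test. Two
#' degenerate groups with equal means return `p = 1`.
#'
#' @param velocities_a,velocities_b Numeric vectors (each length >= 2).
#' @param pooled Use the pooled-variance Student form.
#' @return A tibble: `statistic`, `p_value`, `df`, `mean_a`, `mean_b`,
#'   `method`.
#' @examples
#' compare_groups(rnorm(50), rnorm(50, 5))
#' @export
compare_groups <- function(velocities_a, velocities_b, pooled = FALSE) {
  if (length(velocities_a) < 2 || length(velocities_b) < 2) {
    abort("each group needs at least 2 observations.")
  }
  if (sd(velocities_a) == 0 && sd(velocities_b) == 0) {
    same <- isTRUE(all.equal(mean(velocities_a), mean(velocities_b)))
    return(tibble::tibble(
      statistic = if (same) 0 else Inf, p_value = if (same) 1 else 0,
      df = NA_real_, mean_a = mean(velocities_a), mean_b = mean(velocities_b),
      method = "degenerate"))
  }
  tt <- t.test(velocities_a, velocities_b, var.equal = pooled)
  tibble::tibble(
    statistic = unname(tt$statistic),
    p_value = tt$p.value,
    df = unname(tt$parameter),
    mean_a = mean(velocities_a),
    mean_b = mean(velocities_b),
    method = if (pooled) "student" else "welch"
  )
}

#' Binding events per molecule
#'
#' Counts events per molecule, including molecules with zero events, and
#' returns the mean and standard deviation of the per-molecule counts.
#'
#' @param events Tibble with a `molecule_id` column, or a vector of
#'   molecule ids (one entry per event).
#' @param n_molecules_observed Total molecules observed (>= number of
#'   molecules with events).
#' @return A tibble: `n_molecules`, `n_events`, `mean_per_molecule`,
#'   `sd_per_molecule`.
#' @examples
#' events_per_molecule(c(1, 1, 2), n_molecules_observed = 5)
#' @export
events_per_molecule <- function(events, n_molecules_observed) {
  stopifnot_scalar_number(n_molecules_observed, "n_molecules_observed",
                          min = 0, strict = TRUE)
  ids <- if (is.data.frame(events)) events$molecule_id else events
  counts <- table(factor(ids))
  if (length(counts) > n_molecules_observed) {
    abort("more molecules with events than molecules observed.")
  }
  per_mol <- c(as.numeric(counts),
               rep(0, n_molecules_observed - length(counts)))
  tibble::tibble(
    n_molecules = as.integer(n_molecules_observed),
    n_events = length(ids),
    mean_per_molecule = mean(per_mol),
    sd_per_molecule = if (length(per_mol) > 1) sd(per_mol) else 0
  )
}

#' Initial-rate fit of an ATP-hydrolysis time course
#'
#' Ordinary least-squares slope of the hydrolysed fraction against time over
#' the early linear regime (points with `frac_hydrolyzed` below
#' `linear_fraction`), converted to a catalytic turnover number
#' `kcat = slope * atp_conc / enzyme_conc`.
#'
#' @param tc Time course from [simulate_atpase()], or any tibble with
#'   `time_s` and `frac_hydrolyzed`.
#' @param linear_fraction Upper limit of the linear regime.
#' @param enzyme_conc,atp_conc Concentrations (molar); default to the time
#'   course attributes.
#' @return A `rate_fit`: `rate_frac_per_s`, `kcat_s`, `se_kcat_s`,
#'   `n_points`.
#' @examples
#' tc <- simulate_atpase(256, 1e-9, 2e-3, times_s = seq(10, 2000, by = 10))
#' fit_initial_rate(tc)$kcat_s
#' @export
fit_initial_rate <- function(tc, linear_fraction = 0.15,
                             enzyme_conc = attr(tc, "enzyme_conc"),
                             atp_conc = attr(tc, "atp_conc")) {
  if (is.null(enzyme_conc) || is.null(atp_conc)) {
    abort("`enzyme_conc` and `atp_conc` are required.")
  }
  early <- dplyr::filter(tc, .data$frac_hydrolyzed < linear_fraction)
  if (nrow(early) < 3) {
    abort(sprintf("need >= 3 points below frac = %g (got %d).",
                  linear_fraction, nrow(early)))
  }
  fit <- lm(frac_hydrolyzed ~ time_s, data = early)
  slope <- unname(coef(fit)["time_s"])
  se <- suppressWarnings(
    summary(fit)$coefficients["time_s", "Std. Error"])
  structure(list(
    rate_frac_per_s = slope,
    kcat_s = slope * atp_conc / enzyme_conc,
    se_kcat_s = se * atp_conc / enzyme_conc,
    n_points = nrow(early)
  ), class = "rate_fit")
}

#' Ratio of catalytic rates
#'
#' @param kcat_a,kcat_b Turnover numbers; `kcat_b` must be positive.
#' @return A tibble: `ratio`, `ratio_1sf` (rounded to one significant
#'   figure), `label` (e.g. `"2 x 10^4"`).
#' @examples
#' rate_ratio(256, 0.012)
#' @export
rate_ratio <- function(kcat_a, kcat_b) {
  stopifnot_scalar_number(kcat_a, "kcat_a", min = 0)
  if (!is.numeric(kcat_b) || kcat_b <= 0) abort("`kcat_b` must be > 0.")
  r <- kcat_a / kcat_b
  r1 <- signif(r, 1)
  expo <- floor(log10(r1))
  mant <- r1 / 10^expo
  tibble::tibble(
    ratio = r,
    ratio_1sf = r1,
    label = sprintf("%g x 10^%d", mant, expo)
  )
}
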