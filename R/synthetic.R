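# Synthetic phase-coupled oscillator studies with known ground truth.
#
# The generator exists so that every downstream stage (PLI, spanning trees,
# group statistics) can be validated against planted structure. Coupled
# channel pairs share a narrowband Gaussian carrier; the target channel
# carries a phase-shifted copy of the source mixed with independent
# narrowband noise, so the mixing weight maps monotonically onto the
# expected phase lag index. A zero-lag common source emulates the
# volume-conduction confound PLI is designed to reject.

#' Construct a ground-truth coupling graph
#'
#' @param n_channels number of channels (network nodes).
#' @param pairs data frame with columns `i`, `j` (1-based channel indices,
#'   `i < j`), `strength` (mixing weight in `[0, 1]`), `lag` (phase lag in
#'   radians, nonzero modulo pi) and optionally `modulated` (logical; which
#'   edges carry condition effects in group simulations, default all).
#' @param common_source_gain gain (>= 0) of a zero-lag narrowband source
#'   added to every channel; a volume-conduction surrogate.
#' @return a `ground_truth_graph` object.
#' @export
truth_graph <- function(n_channels, pairs, common_source_gain = 0) {
  stopifnot(is.numeric(n_channels), n_channels >= 2)
  n_channels <- as.integer(n_channels)
  if (is.null(pairs) || nrow(pairs) == 0L) {
    pairs <- data.frame(i = integer(), j = integer(),
                        strength = numeric(), lag = numeric(),
                        modulated = logical())
  }
  stopifnot(all(c("i", "j", "strength", "lag") %in% names(pairs)))
  if (is.null(pairs$modulated)) pairs$modulated <- rep(TRUE, nrow(pairs))
  if (nrow(pairs) > 0L) {
    if (any(pairs$i == pairs$j)) stop("self-pairs are not allowed")
    if (any(pairs$i < 1L | pairs$j < 1L |
            pairs$i > n_channels | pairs$j > n_channels))
      stop("pair indices outside 1..n_channels")
    swap <- pairs$i > pairs$j
    tmp <- pairs$i[swap]; pairs$i[swap] <- pairs$j[swap]; pairs$j[swap] <- tmp
    if (anyDuplicated(pairs[, c("i", "j")]))
      stop("duplicate coupled pairs")
    if (any(pairs$strength < 0 | pairs$strength > 1))
      stop("coupling strengths must lie in [0, 1]")
    # a lag of 0 or pi gives a symmetric sign distribution: PLI-invisible
    if (any(abs(sin(pairs$lag)) < 1e-6))
      stop("phase lags must be nonzero modulo pi (PLI is blind otherwise)")
  }
  if (!is.numeric(common_source_gain) || common_source_gain < 0)
    stop("common_source_gain must be >= 0")
  structure(list(n_channels = n_channels, pairs = pairs,
                 common_source_gain = common_source_gain),
            class = "ground_truth_graph")
}

#' Line-backbone plus star-overlay ground truth
#'
#' Default planted structure for group simulations. A chain through all
#' channels (constant coupling `line_strength`, not condition-modulated)
#' coexists with a star overlay from a hub channel to every non-adjacent
#' channel (`star_strength`, condition-modulated). When the star coupling
#' exceeds the line coupling the strongest backbone of the network is
#' star-like; below it, line-like — the axis the tree metrics measure.
#'
#' @param n_channels number of channels.
#' @param star_strength coupling of the hub-to-channel overlay edges.
#' @param line_strength coupling of the chain edges.
#' @param hub hub channel index.
#' @param common_source_gain zero-lag confound gain.
#' @param seed RNG seed for the per-edge phase lags.
#' @return a `ground_truth_graph`.
#' @export
line_star_truth <- function(n_channels = 32L, star_strength = 0.3,
                            line_strength = 0.45, hub = 1L,
                            common_source_gain = 0, seed = NULL) {
  stopifnot(n_channels >= 3L, hub >= 1L, hub <= n_channels)
  line <- data.frame(i = seq_len(n_channels - 1L),
                     j = seq_len(n_channels - 1L) + 1L,
                     strength = line_strength, modulated = FALSE)
  others <- setdiff(seq_len(n_channels), c(hub - 1L, hub, hub + 1L))
  star <- data.frame(i = pmin(hub, others), j = pmax(hub, others),
                     strength = star_strength, modulated = TRUE)
  pairs <- rbind(line, star)
  # lags uniform on +/-[pi/6, 5pi/6]: bounded away from 0 and pi
  pairs$lag <- with_seed(seed, {
    sample(c(-1, 1), nrow(pairs), replace = TRUE) *
      runif(nrow(pairs), pi / 6, 5 * pi / 6)
  })
  truth_graph(n_channels, pairs, common_source_gain)
}

#' @export
print.ground_truth_graph <- function(x, ...) {
  cat(sprintf("<ground_truth_graph> %d channels, %d coupled pairs, common-source gain %g\n",
              x$n_channels, nrow(x$pairs), x$common_source_gain))
  invisible(x)
}

# Analytic narrowband Gaussian noise, k independent columns: complex
# series with spectral support on [lo, hi] Hz only; Re() is the real
# carrier (unit SD), Arg() its phase.
narrowband_analytic <- function(n, fs, lo, hi, k = 1L) {
  f <- (seq_len(n) - 1L) * fs / n
  keep <- f >= lo & f <= hi & f <= fs / 2
  if (!any(keep)) stop("band contains no Fourier bins at this length")
  spec <- matrix(complex(real = rnorm(n * k), imaginary = rnorm(n * k)),
                 nrow = n)
  spec[!keep, ] <- 0
  z <- stats::mvfft(spec, inverse = TRUE) / n
  s <- apply(z, 2L, function(col) sd(Re(col)))
  if (any(s == 0)) stop("degenerate narrowband draw")
  sweep(z, 2L, s, `/`)
}

# Slowly varying phase jitter, one column per requested SD: lowpass
# Gaussian process rescaled to the target SD. f_hi controls how fast the
# lag wanders (default 1 Hz).
smooth_jitter <- function(n, fs, sd_target, f_hi = 1) {
  k <- length(sd_target)
  f <- (seq_len(n) - 1L) * fs / n
  keep <- f > 0 & f <= f_hi
  if (!any(keep)) keep[2L] <- TRUE
  spec <- matrix(complex(real = rnorm(n * k), imaginary = rnorm(n * k)),
                 nrow = n)
  spec[!keep, ] <- 0
  x <- Re(stats::mvfft(spec, inverse = TRUE) / n)
  s <- apply(x, 2L, sd)
  scale <- ifelse(s > 0, sd_target / pmax(s, 1e-300), 0)
  out <- sweep(x, 2L, scale, `*`)
  out[, sd_target <= 0] <- 0
  out
}

#' Generate one multichannel trial from a ground-truth graph
#'
#' Every channel has an independent narrowband Gaussian base oscillation in
#' `band`. For each coupled pair `(i, j)` the higher-index channel receives
#' `strength` times a phase-shifted copy of the lower-index channel's base
#' signal (shift = `lag` plus slowly wandering wrapped-Gaussian jitter with
#' SD `(1 - strength) * pi / 2`), mixed with its own base at weight
#' `1 - strength`. A zero-lag common source scaled by the graph's
#' `common_source_gain` and white noise at `noise_sd` are then added to all
#' channels.
#'
#' The returned recording carries attribute `truth_dphi`: for each coupled
#' pair, the wrapped phase-difference series of the noise-free narrowband
#' composite signals, the generator's own bookkeeping that downstream PLI
#' estimates can be checked against.
#'
#' @param truth a [truth_graph()].
#' @param band band name or [band_definition()]; must lie within 4--45 Hz.
#' @param fs sampling rate in Hz (default 128).
#' @param duration trial length in seconds; `fs * duration >= 512` samples.
#' @param noise_sd SD of additive white noise (signal bases have unit SD).
#' @param seed RNG seed for reproducibility.
#' @param channel_names optional channel labels.
#' @param bookkeeping store the `truth_dphi` attribute (default TRUE);
#'   bulk group simulation turns it off. Disabling it does not change the
#'   generated signals or the random stream they consume.
#' @return a [trial_recording()].
#' @export
generate_trial <- function(truth, band = "gamma", fs = 128, duration = 60,
                           noise_sd = 0.5, seed = NULL,
                           channel_names = NULL, bookkeeping = TRUE) {
  stopifnot(inherits(truth, "ground_truth_graph"))
  band <- as_band(band)
  if (band$lo < 4 || band$hi > 45)
    stop("generator bands must lie within 4-45 Hz")
  if (band$hi >= fs / 2) stop("band upper edge at or above Nyquist")
  n <- round(fs * duration)
  if (n < 512) stop("fs * duration must be at least 512 samples")
  nc <- truth$n_channels

  with_seed(seed, {
    base <- narrowband_analytic(n, fs, band$lo, band$hi, k = nc)
    x <- matrix(0, nrow = nc, ncol = n)
    mixed_in <- numeric(nc)  # total coupled weight received per channel
    np <- nrow(truth$pairs)
    if (np > 0L) {
      jit <- smooth_jitter(n, fs, (1 - truth$pairs$strength) * pi / 2)
      for (p in seq_len(np)) {
        i <- truth$pairs$i[p]; j <- truth$pairs$j[p]
        s <- truth$pairs$strength[p]; lag <- truth$pairs$lag[p]
        shifted <- Re(base[, i] * exp(-1i * (lag + jit[, p])))
        x[j, ] <- x[j, ] + s * shifted
        mixed_in[j] <- mixed_in[j] + s
      }
    }
    own <- pmax(0, 1 - pmin(1, mixed_in))
    x <- x + own * Re(t(base))
    # bookkeeping before confound/noise: phase differences of the clean
    # narrowband composites, the quantity downstream PLI estimates
    truth_dphi <- NULL
    if (np > 0L && bookkeeping) {
      involved <- sort(unique(c(truth$pairs$i, truth$pairs$j)))
      ok <- involved[apply(x[involved, , drop = FALSE], 1L,
                           function(r) sd(r) > 0)]
      ph <- matrix(NA_real_, nc, n)
      if (length(ok) > 0L) {
        zz <- apply(t(x[ok, , drop = FALSE]), 2L, analytic_signal)
        ph[ok, ] <- t(Arg(zz))
      }
      truth_dphi <- lapply(seq_len(np), function(p) {
        i <- truth$pairs$i[p]; j <- truth$pairs$j[p]
        if (!(i %in% ok) || !(j %in% ok)) return(NULL)
        wrap_phase(ph[i, ] - ph[j, ])
      })
    }
    if (truth$common_source_gain > 0) {
      src <- Re(narrowband_analytic(n, fs, band$lo, band$hi)[, 1L])
      x <- x + rep(truth$common_source_gain, nc) %o% src
    }
    if (noise_sd > 0)
      x <- x + matrix(rnorm(nc * n, sd = noise_sd), nrow = nc)

    tr <- trial_recording(x, fs = fs,
                          channel_names = channel_names %||%
                            default_channel_names(nc))
    attr(tr, "truth_dphi") <- truth_dphi
    attr(tr, "truth") <- truth
    tr
  })
}

#' Configuration for a simulated group study
#'
#' Defines the 2 (arousal: high/low) x 2 (valence: high/low) within-subject
#' design. Condition effects act additively on the coupling strength of the
#' modulated (star-overlay) edges of each subject's ground-truth graph:
#'
#' `coupling = baseline + arousal_effect * [high arousal] +
#'  valence_effect * [low valence] + interaction_effect * [both]`
#'
#' so high arousal and low valence raise coupling, matching the direction
#' in which star-like reorganisation is expected.
#'
#' @param n_subjects number of subjects (>= 2).
#' @param trials_per_condition trials per emotion condition (>= 1).
#' @param band_of_effect band in which coupling is planted.
#' @param baseline_coupling star-overlay coupling in the LAHV reference
#'   condition, in `[0, 1]`.
#' @param arousal_effect,valence_effect,interaction_effect additive
#'   coupling deltas; all four resulting condition couplings must stay in
#'   `[0, 1]`.
#' @param noise_sd white-noise SD per trial.
#' @param fs sampling rate (Hz).
#' @param duration trial length (s).
#' @param n_channels channels per trial (32 for the standard montage).
#' @param subject_sd SD of the per-subject Gaussian random intercept on
#'   baseline coupling.
#' @param line_strength coupling of the unmodulated line backbone.
#' @param common_source_gain zero-lag confound gain.
#' @param seed RNG seed; the whole study is reproducible given the seed.
#' @return a `group_sim_config` object.
#' @export
group_sim_config <- function(n_subjects = 32L, trials_per_condition = 10L,
                             band_of_effect = "gamma",
                             baseline_coupling = 0.30,
                             arousal_effect = 0.20, valence_effect = 0.10,
                             interaction_effect = 0.05, noise_sd = 0.5,
                             fs = 128, duration = 60, n_channels = 32L,
                             subject_sd = 0.05, line_strength = 0.45,
                             common_source_gain = 0, seed = NULL) {
  stopifnot(n_subjects >= 2L, trials_per_condition >= 1L,
            fs > 0, duration > 0, n_channels >= 3L)
  band <- as_band(band_of_effect)
  cond <- condition_couplings(baseline_coupling, arousal_effect,
                              valence_effect, interaction_effect)
  if (any(cond < 0 | cond > 1))
    stop("configuration error: condition couplings leave [0, 1]: ",
         paste(sprintf("%s=%.3f", names(cond), cond), collapse = ", "))
  structure(list(n_subjects = as.integer(n_subjects),
                 trials_per_condition = as.integer(trials_per_condition),
                 band_of_effect = band,
                 baseline_coupling = baseline_coupling,
                 arousal_effect = arousal_effect,
                 valence_effect = valence_effect,
                 interaction_effect = interaction_effect,
                 noise_sd = noise_sd, fs = fs, duration = duration,
                 n_channels = as.integer(n_channels),
                 subject_sd = subject_sd, line_strength = line_strength,
                 common_source_gain = common_source_gain, seed = seed),
            class = "group_sim_config")
}

#' Emotion conditions of the 2x2 design
#' @return character vector `c("HAHV", "HALV", "LAHV", "LALV")`.
#' @export
emotion_conditions <- function() c("HAHV", "HALV", "LAHV", "LALV")

condition_couplings <- function(baseline, arousal, valence, interaction) {
  c(HAHV = baseline + arousal,
    HALV = baseline + arousal + valence + interaction,
    LAHV = baseline,
    LALV = baseline + valence)
}

#' Simulate a whole group study
#'
#' Generates `n_subjects` subjects, each with `trials_per_condition` trials
#' in all four emotion conditions (HAHV, HALV, LAHV, LALV). Each subject
#' has a Gaussian random intercept on baseline coupling and a private set
#' of planted phase lags; the star-overlay coupling in each condition
#' follows the additive-effect model of [group_sim_config()]. Self-reported
#' valence/arousal ratings consistent with each trial's condition are drawn
#' from U(6, 9) (high) or U(1, 4) (low), so trial classification can be
#' exercised end to end.
#'
#' @param config a [group_sim_config()].
#' @return an `eeg_study`: list with `subjects` (each holding `subject_id`,
#'   `trials`, `labels` data frame and per-condition `truth` graphs) and
#'   the `config`.
#' @export
generate_group <- function(config) {
  stopifnot(inherits(config, "group_sim_config"))
  cond_base <- condition_couplings(config$baseline_coupling,
                                   config$arousal_effect,
                                   config$valence_effect,
                                   config$interaction_effect)
  seeds <- derive_seeds(config$seed, config$n_subjects + 1L)
  subjects <- lapply(seq_len(config$n_subjects), function(s) {
    sseed <- seeds[s]
    sub <- with_seed(sseed, {
      intercept <- rnorm(1, 0, config$subject_sd)
      lag_seed <- sample.int(.Machine$integer.max - 1L, 1L)
      trial_seeds <- sample.int(.Machine$integer.max - 1L,
                                4L * config$trials_per_condition)
      list(intercept = intercept, lag_seed = lag_seed,
           trial_seeds = trial_seeds)
    })
    truths <- lapply(cond_base, function(b) {
      s_star <- min(1, max(0, b + sub$intercept))
      line_star_truth(config$n_channels, star_strength = s_star,
                      line_strength = config$line_strength,
                      common_source_gain = config$common_source_gain,
                      seed = sub$lag_seed)
    })
    conds <- rep(emotion_conditions(), each = config$trials_per_condition)
    trials <- vector("list", length(conds))
    labels <- data.frame(trial_id = seq_along(conds),
                         valence = NA_real_, arousal = NA_real_,
                         condition = conds, stringsAsFactors = FALSE)
    for (t in seq_along(conds)) {
      tr <- generate_trial(truths[[conds[t]]],
                           band = config$band_of_effect,
                           fs = config$fs, duration = config$duration,
                           noise_sd = config$noise_sd,
                           seed = sub$trial_seeds[t], bookkeeping = FALSE)
      tr$subject_id <- s
      tr$trial_id <- t
      trials[[t]] <- tr
      rating <- with_seed(sub$trial_seeds[t] %% 1000000L + t, {
        hi_a <- substr(conds[t], 1, 1) == "H"
        hi_v <- substr(conds[t], 3, 3) == "H"
        c(valence = if (hi_v) runif(1, 6, 9) else runif(1, 1, 4),
          arousal = if (hi_a) runif(1, 6, 9) else runif(1, 1, 4))
      })
      labels$valence[t] <- rating["valence"]
      labels$arousal[t] <- rating["arousal"]
    }
    list(subject_id = s, trials = trials, labels = labels, truth = truths)
  })
  structure(list(subjects = subjects, config = config), class = "eeg_study")
}

#' @export
print.eeg_study <- function(x, ...) {
  ns <- length(x$subjects)
  nt <- if (ns > 0) length(x$subjects[[1]]$trials) else 0
  cat(sprintf("<eeg_study> %d subjects x %d trials (%d channels, %g s at %g Hz)\n",
              ns, nt, x$config$n_channels, x$config$duration, x$config$fs))
  invisible(x)
}

#' PLI implied by the generator's own phase bookkeeping
#'
#' Computes `|mean(sign(dphi))|` directly from the wrapped phase-difference
#' series the generator stored for each coupled pair (attribute
#' `truth_dphi`), independent of the filtering/Hilbert estimation path.
#'
#' @param trial a trial produced by [generate_trial()].
#' @return data frame with columns `i`, `j`, `pli_truth`.
#' @export
truth_pair_pli <- function(trial) {
  dphi <- attr(trial, "truth_dphi")
  truth <- attr(trial, "truth")
  if (is.null(dphi) || is.null(truth))
    stop("trial carries no generator bookkeeping")
  data.frame(i = truth$pairs$i, j = truth$pairs$j,
             pli_truth = vapply(dphi, function(d) {
               if (is.null(d)) return(NA_real_)
               pli_from_phase_diff(d)
             }, numeric(1)))
}
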