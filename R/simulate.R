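#' Specify one planted functional state
#'
#' @param duration_epochs State length in 1-s epochs (>= 1).
#' @param power_gain Per-band amplitude gain of the band-limited signal
#'   component, relative to the background: a named numeric vector
#'   (`delta`, `theta`, ...), or a band x region matrix (dimnames
#'   required) for region-specific gains. Unlisted bands default to 1.
#' @param synchrony Per-band synchrony level in \[0, 1\]: the share of a
#'   common band-limited driver mixed into every channel's band
#'   component. Named numeric vector; unlisted bands default to 0.
#' @return A list of class `state_spec`.
#' @export
state_spec <- function(duration_epochs, power_gain = NULL,
                       synchrony = NULL) {
  if (duration_epochs < 1) abort("duration_epochs must be >= 1")
  if (!is.null(power_gain) && any(power_gain <= 0)) {
    abort("power gains must be positive")
  }
  if (!is.null(synchrony) && any(synchrony < 0 | synchrony > 1)) {
    abort("synchrony levels must lie in [0, 1]")
  }
  structure(list(duration_epochs = as.integer(duration_epochs),
                 power_gain = power_gain, synchrony = synchrony),
            class = "state_spec")
}

#' Recipe for a piecewise-stationary synthetic recording
#'
#' @param states Ordered list of [state_spec()]s.
#' @param channels Channel names; defaults to the standard 38-channel
#'   montage so [roi_map_15()] applies.
#' @param sfreq Sampling rate (Hz).
#' @param noise_sd SD of the white measurement noise added per channel.
#' @param background_scale Amplitude of the 1/f background.
#' @param bands A [band_scheme()] shared with the feature recipe.
#' @param rois A [roi_map()] used to resolve region-specific gains.
#' @param fir_order FIR band-pass order for the band-limited components.
#' @param base_synchrony Synchrony floor applied to every band in every
#'   state via the band drivers; state synchrony levels add on top of it.
#' @param conduction Named vector `c(region = r, global = g)` with
#'   `r + g < 1`: instantaneous spatial mixing weights emulating volume
#'   conduction — each channel is blended with its region mean (weight
#'   `r`) and the all-channel mean (weight `g`). Neighbouring electrodes
#'   then cohere strongly and distant ones weakly, flat across
#'   frequencies. `c(0, 0)` disables it.
#' @param epoch_modulation_sd SD (log scale) of a slow common amplitude
#'   modulation shared by all channels — the vigilance/arousal-like
#'   fluctuation that makes artifact epochs deviate in many power columns
#'   at once. 0 disables it.
#' @param epoch_modulation_ar AR(1) coefficient of that modulation across
#'   epochs.
#' @return A list of class `sim_recipe`.
#' @export
sim_recipe <- function(states, channels = standard_channels(), sfreq = 500,
                       noise_sd = 0.5, background_scale = 1,
                       bands = band_scheme(), rois = roi_map_15(),
                       fir_order = 512, base_synchrony = 0,
                       conduction = c(region = 0, global = 0),
                       epoch_modulation_sd = 0,
                       epoch_modulation_ar = 0.8) {
  if (length(states) < 1) abort("need at least one state")
  ok <- vapply(states, inherits, logical(1), "state_spec")
  if (!all(ok)) abort("states must be state_spec objects")
  if (base_synchrony < 0 || base_synchrony >= 1) {
    abort("base_synchrony must lie in [0, 1)")
  }
  if (any(conduction < 0) || sum(conduction) >= 1) {
    abort("conduction weights must be nonnegative and sum below 1")
  }
  structure(list(states = states, channels = channels, sfreq = sfreq,
                 noise_sd = noise_sd, background_scale = background_scale,
                 bands = bands, rois = rois, fir_order = fir_order,
                 base_synchrony = base_synchrony, conduction = conduction,
                 epoch_modulation_sd = epoch_modulation_sd,
                 epoch_modulation_ar = epoch_modulation_ar),
            class = "sim_recipe")
}

# pink (1/f) noise via spectral shaping of white noise
pink_noise <- function(n) {
  w <- rnorm(n)
  sp <- fft(w)
  f <- c(1, seq_len(n - 1))
  f <- pmin(f, n - f + 1)                 # symmetric frequency index
  sp <- sp / sqrt(f)
  x <- Re(fft(sp, inverse = TRUE)) / n
  x / sd(x)
}

#' Generate a synthetic recording with planted states
#'
#' Each channel is the sum of a 1/f background, five FIR band-passed noise
#' components whose amplitudes follow the active state's per-band (and
#' optionally per-region) gains, shared band-limited drivers mixed in
#' proportion to the state's synchrony levels, and white measurement
#' noise. Output is bitwise-reproducible for a fixed seed.
#'
#' @param recipe A [sim_recipe()].
#' @param seed Integer seed.
#' @return List with `recording` (a [continuous_recording()]), `truth`
#'   (the planted [segment_partition()]) and `recipe`.
#' @export
generate_recording <- function(recipe, seed = 1L) {
  stopifnot(inherits(recipe, "sim_recipe"))
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)
  nch <- length(recipe$channels)
  durations <- vapply(recipe$states, `[[`, integer(1), "duration_epochs")
  n_epochs <- sum(durations)
  spe <- as.integer(recipe$sfreq)         # 1-s epochs
  n <- n_epochs * spe
  bands <- recipe$bands
  nyq <- recipe$sfreq / 2
  if (max(bands$high) >= nyq) {
    abort("sampling rate must exceed twice the top band edge")
  }
  reg_of <- setNames(recipe$rois$region[match(recipe$channels,
                                              recipe$rois$channel)],
                     recipe$channels)
  if (anyNA(reg_of)) abort("every channel must belong to a region")

  # FIR band-pass bank applied to white noise, one component per channel
  # and band plus one shared driver per band. The zero-phase FIR response
  # (|H|^2, the filtfilt response) is applied in the frequency domain,
  # which is exact up to circular wrap-around and fast at recording scale.
  band_filter <- function(w, lo, hi) {
    ord <- min(recipe$fir_order, 2L * (length(w) %/% 2L) - 2L)
    h <- signal::fir1(ord, c(lo, hi) / nyq, type = "pass")
    hf <- Mod(fft(c(h, rep(0, length(w) - length(h)))))^2
    Re(fft(fft(w) * hf, inverse = TRUE)) / length(w)
  }
  comp <- vector("list", nrow(bands))
  driver <- vector("list", nrow(bands))
  for (b in seq_len(nrow(bands))) {
    m <- matrix(rnorm(nch * n), nch, n)
    filt <- t(apply(m, 1, band_filter, lo = bands$low[b],
                    hi = bands$high[b]))
    comp[[b]] <- filt / apply(filt, 1, sd)
    dr <- band_filter(rnorm(n), bands$low[b], bands$high[b])
    driver[[b]] <- dr / sd(dr)
  }
  background <- t(vapply(seq_len(nch), function(ch) pink_noise(n),
                         numeric(n))) * recipe$background_scale

  gain_of <- function(st, band, region) {
    g <- st$power_gain
    if (is.null(g)) return(1)
    if (is.matrix(g)) {
      if (!band %in% rownames(g)) return(1)
      if (!region %in% colnames(g)) return(1)
      return(g[band, region])
    }
    if (band %in% names(g)) g[[band]] else 1
  }
  base_s <- recipe$base_synchrony %||% 0
  sync_of <- function(st, band) {
    s <- st$synchrony
    own <- if (is.null(s) || !band %in% names(s)) 0 else s[[band]]
    base_s + (1 - base_s) * own
  }

  x <- background
  edges <- c(0L, cumsum(durations)) * spe
  for (si in seq_along(recipe$states)) {
    st <- recipe$states[[si]]
    cols <- (edges[si] + 1):edges[si + 1]
    for (b in seq_len(nrow(bands))) {
      s <- sync_of(st, bands$band[b])
      shared <- driver[[b]][cols]
      for (ch in seq_len(nch)) {
        g <- gain_of(st, bands$band[b], reg_of[[ch]])
        own <- comp[[b]][ch, cols]
        x[ch, cols] <- x[ch, cols] +
          g * (sqrt(1 - s) * own + sqrt(s) * shared)
      }
    }
  }
  cond <- recipe$conduction %||% c(region = 0, global = 0)
  cr <- unname(cond["region"]); cg <- unname(cond["global"])
  if (cr + cg > 0) {
    # volume conduction as instantaneous spatial mixing: every channel is
    # blended with its region mean and the global mean, so neighbouring
    # electrodes share signal at every frequency (flat-spectrum
    # coherence), strong within a region and weaker across regions
    g_mean <- colMeans(x)
    regions <- unique(reg_of)
    r_mean <- lapply(setNames(regions, regions), function(r) {
      colMeans(x[which(reg_of == r), , drop = FALSE])
    })
    x_new <- x
    for (ch in seq_len(nch)) {
      x_new[ch, ] <- (1 - cr - cg) * x[ch, ] +
        cr * r_mean[[reg_of[[ch]]]] + cg * g_mean
    }
    x <- x_new
  }
  mod_sd <- recipe$epoch_modulation_sd %||% 0
  if (mod_sd > 0) {
    # slow common amplitude modulation, constant within an epoch
    ar <- recipe$epoch_modulation_ar %||% 0.8
    m <- if (ar == 0) {
      rnorm(n_epochs, sd = mod_sd)
    } else {
      as.numeric(stats::arima.sim(list(ar = ar), n_epochs,
                                  sd = mod_sd * sqrt(1 - ar^2)))
    }
    x <- sweep(x, 2, rep(exp(m), each = spe), "*")
  }
  x <- x + matrix(rnorm(nch * n, sd = recipe$noise_sd), nch, n)
  rec <- continuous_recording(x, recipe$sfreq, recipe$channels)
  truth <- segment_partition(cumsum(durations)[-length(durations)],
                             n_epochs)
  list(recording = rec, truth = truth, recipe = recipe)
}

#' Default eight-state test recipe
#'
#' Eight states of 60--180 epochs on the standard 38-channel montage at
#' 500 Hz, with state-specific band gains and synchrony levels — the
#' regime of a staged, tens-of-minutes recording. `n_channels` and
#' `epoch_range` let tests scale the same structure down.
#'
#' @param n_states Number of planted states.
#' @param epoch_range Min/max state duration in epochs.
#' @param strength Contrast multiplier (>= 1 strengthens the planted
#'   effects).
#' @param channels Channel subset (default full montage).
#' @param sfreq Sampling rate.
#' @param rois Region map matching `channels`.
#' @param seed Seed used for drawing the per-state gain pattern.
#' @return A [sim_recipe()].
#' @export
default_sim_recipe <- function(n_states = 8, epoch_range = c(60, 180),
                               strength = 1, channels = standard_channels(),
                               sfreq = 500, rois = roi_map_15(),
                               seed = 100L) {
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)
  bands <- band_scheme()
  states <- lapply(seq_len(n_states), function(s) {
    dur <- sample(seq(epoch_range[1], epoch_range[2]), 1)
    gains <- setNames(exp(runif(nrow(bands), log(1 / (1 + strength)),
                                log(1 + strength))), bands$band)
    sync <- setNames(runif(nrow(bands), 0, min(1, 0.4 * strength)),
                     bands$band)
    state_spec(dur, power_gain = gains, synchrony = sync)
  })
  sim_recipe(states, channels = channels, sfreq = sfreq, rois = rois)
}

#' Eight-state validation recipe with strong, deterministic contrasts
#'
#' The canonical recipe for validating state recovery: each state carries a
#' distinct hand-picked combination of band-power gains (3x up, 3x down)
#' and band synchrony levels, so every pair of states — in any order — is
#' strongly separated in the feature space the pipeline measures. Patterns
#' cycle when `n_states > 8`.
#'
#' @param durations Integer vector of state lengths in epochs (its length
#'   sets the number of states); the default is eight states of 85--120
#'   epochs, the regime of a staged recording of tens of minutes.
#' @param channels,sfreq,rois,noise_sd Passed to [sim_recipe()].
#' @return A [sim_recipe()].
#' @export
contrast_recipe <- function(durations = c(95, 110, 85, 120, 90, 105, 115, 100),
                            channels = standard_channels(), sfreq = 500,
                            rois = roi_map_15(), noise_sd = 0.5) {
  # per-epoch band power carries multiplicative (chi-square-like) noise,
  # so the usable contrast scale is the within-state SD: gains of ~1.25x
  # amplitude (~1.6x power) shift a column by roughly one within-state SD,
  # the regime real functional states show; much stronger gains would park
  # whole states in the 3-SD artifact-rejection tail. Every pattern pair —
  # not just consecutive ones, since rearrangement can make any pair
  # adjacent — differs in at least two band cues. Synchrony is a secondary
  # cue only: at 1-s epochs the taper bandwidth dilutes narrowband
  # coherence well below the connectivity-index thresholds, so a state
  # must never rely on synchrony alone for its identity
  # State signatures form a balanced two-level design: 8 cells (four
  # estimator-resolvable band groups x two scalp halves; on 1-s epochs the
  # taper bandwidth blurs delta into theta, so the two low bands move as
  # one group) take gain "up" or "down" following the rows of an 8 x 8
  # Hadamard matrix. Any two states then differ in exactly four cells, so
  # every pairwise contrast — hence every possible adjacent Ward distance
  # after rearrangement — is the same size, and the relative-distance
  # merge rule (D_min <= W * D_avg) cannot starve a weak pair. Gains of
  # 1.25x/0.8x amplitude shift a power column by about one within-state
  # SD, the few-fold contrast regime real functional states show; much
  # stronger gains would park whole states in the 3-SD rejection tail.
  # Synchrony stays at 0.5: visible in raw coherence/PLV, but — after the
  # taper bandwidth dilutes narrowband coherence — safely below the 0.6
  # index threshold, where estimator noise would toggle the thresholded
  # counts and masquerade as internal state structure.
  up <- 1.25
  dn <- 0.8
  band_groups <- list(low = c("delta", "theta"), alpha = "alpha",
                      beta = "beta", gamma = "gamma")
  region_names <- unique(rois$region)
  anterior <- grep("frontal|temporal", region_names, value = TRUE)
  halves <- list(anterior = anterior,
                 posterior = setdiff(region_names, anterior))
  h2 <- matrix(c(1, 1, 1, -1), 2, 2, byrow = TRUE)
  h8 <- h2 %x% h2 %x% h2
  cells <- expand.grid(group = names(band_groups), half = names(halves),
                       stringsAsFactors = FALSE)
  all_bands <- c("delta", "theta", "alpha", "beta", "gamma")
  gain_for_state <- function(s) {
    g <- matrix(1, length(all_bands), length(region_names),
                dimnames = list(all_bands, region_names))
    for (j in seq_len(nrow(cells))) {
      val <- if (h8[s, j] > 0) up else dn
      g[band_groups[[cells$group[j]]], halves[[cells$half[j]]]] <- val
    }
    g
  }
  syncs <- list(NULL, NULL, NULL, NULL, NULL, c(beta = 0.5), NULL,
                c(alpha = 0.5))
  states <- lapply(seq_along(durations), function(s) {
    i <- (s - 1) %% 8 + 1
    state_spec(durations[s], power_gain = gain_for_state(i),
               synchrony = syncs[[i]])
  })
  # iid per-epoch modulation (ar = 0): common-factor power outliers
  # without temporal drift, keeping states internally stationary
  sim_recipe(states, channels = channels, sfreq = sfreq, rois = rois,
             noise_sd = noise_sd, base_synchrony = 0.25,
             epoch_modulation_sd = 0.15, epoch_modulation_ar = 0)
}

#' Epoch-shuffled surrogate of a recording or feature table
#'
#' One random permutation applied identically to epochs (and to per-epoch
#' feature rows when given a table): the marginal distribution of rows is
#' preserved while all temporal structure is destroyed.
#'
#' @param x An `epoched_recording`, [feature_table()], matrix or data
#'   frame (rows = epochs).
#' @param seed Integer seed; the same seed yields the same permutation.
#' @return Object of the same type with rows/epochs permuted; the
#'   permutation is attached as attribute `permutation`.
#' @export
make_surrogate <- function(x, seed = 1L) {
  n <- if (inherits(x, "epoched_recording")) n_epochs(x) else nrow(x)
  if (n < 2) abort("need at least two epochs")
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)
  perm <- sample(n)
  out <- permute_rows(x, perm)
  attr(out, "permutation") <- perm
  out
}

permute_rows <- function(x, perm) {
  if (inherits(x, "epoched_recording")) {
    x$data <- x$data[perm, , , drop = FALSE]
    x$epoch_index <- x$epoch_index[perm]
    x
  } else if (inherits(x, "feature_table")) {
    feature_table(ft_values(x)[perm, , drop = FALSE], feature_meta(x))
  } else {
    x[perm, , drop = FALSE]
  }
}

#' Rearrange the states of a recording as contiguous blocks
#'
#' The state blocks of `p` are permuted as whole units (feature rows or
#' epochs move with their block); the expected boundaries of the
#' rearranged recording follow from the permuted durations.
#'
#' @param x An `epoched_recording`, [feature_table()] or matrix.
#' @param p A [segment_partition()] over the same epochs.
#' @param seed Integer seed for the block permutation.
#' @return List with `data` (rearranged object), `expected` (the permuted
#'   ground-truth [segment_partition()]) and `state_order` (new order of
#'   original state ids).
#' @export
rearrange_states <- function(x, p, seed = 1L) {
  n <- if (inherits(x, "epoched_recording")) n_epochs(x) else nrow(x)
  if (n != p$n_epochs) abort("partition does not match the data")
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)
  ns <- n_states(p)
  ord <- sample(ns)
  b <- p$boundaries
  blocks <- lapply(seq_len(ns), function(s) (b[s] + 1):b[s + 1])
  perm <- unlist(blocks[ord])
  durations <- diff(b)[ord]
  expected <- segment_partition(cumsum(durations)[-ns], n)
  list(data = permute_rows(x, perm), expected = expected,
       state_order = ord)
}
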