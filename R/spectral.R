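#' Morlet wavelet time-frequency decomposition of one trace
#'
#' Convolves a signal with complex Morlet wavelets. The wavelet at
#' frequency f has Gaussian-envelope width `sigma_t = c / (2 * pi * f)`
#' (c cycles), support truncated at `+/- m * sigma_t`, and amplitude
#' normalisation `A = sigma_t^(-1/2) * pi^(-1/4)` (unit energy). Samples
#' whose wavelet support extends beyond the epoch are returned as `NA`
#' rather than zero-padded, so edge artefacts are flagged, not hidden.
#'
#' @param x Numeric signal (one trial, one recording site).
#' @param fs Sampling rate in Hz (2000 at the default 0.5-ms step).
#' @param freqs Analysis frequencies in Hz (default 4-100 in 1-Hz steps).
#' @param n_cycles Wavelet cycles `c`.
#' @param m Support truncation in units of `sigma_t`.
#' @return A complex matrix `[length(freqs) x length(x)]` of wavelet
#'   coefficients, `NA` where the support is incomplete, with the
#'   frequency vector attached as attribute `"freqs"`.
#' @export
morlet_tfr <- function(x, fs, freqs = 4:100, n_cycles = 6, m = 3) {
  n <- length(x)
  kern <- morlet_kernels(fs, freqs, n_cycles, m, n)
  if (2L * max(kern$half) + 1L > n) {
    stop("epoch too short for the ", min(freqs), " Hz wavelet: needs at least ",
         2L * max(kern$half) + 1L, " samples, got ", n)
  }
  X <- stats::fft(c(x, numeric(kern$nfft - n)))
  out <- matrix(NA_complex_, length(freqs), n)
  for (k in seq_along(freqs)) {
    conv <- stats::fft(X * kern$K[[k]], inverse = TRUE) / kern$nfft
    h <- kern$half[k]
    valid <- (h + 1L):(n - h)
    # convolution index t + h carries the coefficient centred on sample t
    out[k, valid] <- conv[valid + h]
  }
  attr(out, "freqs") <- freqs
  out
}

# Precompute FFTs of the Morlet kernels (cached per geometry within a call
# chain via the caller; cheap enough to rebuild otherwise).
morlet_kernels <- function(fs, freqs, n_cycles, m, n_sig) {
  sigma_t <- n_cycles / (2 * pi * freqs)
  half <- pmin(floor(m * sigma_t * fs), n_sig)
  nfft <- stats::nextn(n_sig + 2L * max(half), c(2, 3, 5))
  K <- vector("list", length(freqs))
  for (k in seq_along(freqs)) {
    tt <- (-half[k]:half[k]) / fs
    A <- sigma_t[k]^(-0.5) * pi^(-0.25)
    psi <- A * exp(-tt^2 / (2 * sigma_t[k]^2)) *
      exp(2i * pi * freqs[k] * tt) / fs
    # zero-phase placement: centre tap at position 1, tail wrapped
    buf <- complex(nfft)
    buf[seq_along(psi)] <- psi
    K[[k]] <- stats::fft(buf)
  }
  list(K = K, half = half, nfft = nfft)
}

# Average columns of a [freq x steps] map into fixed-width time bins.
bin_columns <- function(mat, bin_len) {
  n <- ncol(mat)
  nb <- n %/% bin_len
  idx <- rep(seq_len(nb), each = bin_len)
  out <- matrix(NA_real_, nrow(mat), nb)
  for (b in seq_len(nb)) {
    cols <- which(idx == b)
    out[, b] <- rowMeans(mat[, cols, drop = FALSE])
  }
  out
}

#' Total, evoked and induced spectral power of recorded trials
#'
#' The full time-frequency pipeline applied to S-ERP recordings of one
#' condition: single-trial Morlet power averaged across trials (total),
#' power of the across-trial average S-ERP (evoked, the phase-locked
#' part), and their difference (induced, time- but not phase-locked).
#' Coefficients are computed at the native sampling rate and averaged
#' into time bins (10 ms by default); before baseline correction the maps
#' satisfy `total = evoked + induced` exactly. Baseline correction
#' subtracts, per area and frequency, the mean over the baseline window.
#'
#' @param recordings A `spikelex_recordings`.
#' @param trials Trial indices to include (e.g. all word trials);
#'   default all.
#' @param freqs Analysis frequencies (Hz).
#' @param bin_ms Output time-bin width (ms).
#' @param baseline Baseline window in seconds relative to stimulus onset
#'   (`NULL` to skip correction).
#' @param n_cycles,m Wavelet parameters, see [morlet_tfr()].
#' @return An object of class `spikelex_tfr`: arrays `total`, `evoked`,
#'   `induced` of shape `[areas x freqs x bins]`, the bin-centre `times`
#'   (s, relative to onset), `freqs`, `baseline`, and `n_trials`.
#' @export
induced_power <- function(recordings, trials = NULL, freqs = 4:100,
                          bin_ms = 10, baseline = c(-0.5, -0.1),
                          n_cycles = 6, m = 3) {
  serp <- recordings$serp
  if (is.null(trials)) trials <- seq_len(dim(serp)[3])
  if (length(trials) < 2) {
    stop("induced power needs at least 2 trials (got ", length(trials), ")")
  }
  fs <- 1000 / recordings$dt
  n_steps <- dim(serp)[2]
  bin_len <- round(bin_ms * fs / 1000)
  nb <- n_steps %/% bin_len
  n_areas <- dim(serp)[1]
  areas <- dimnames(serp)[[1]]

  total <- evoked <- array(NA_real_, c(n_areas, length(freqs), nb))
  for (a in seq_len(n_areas)) {
    acc <- matrix(0, length(freqs), n_steps)
    for (tr in trials) {
      co <- morlet_tfr(serp[a, , tr], fs, freqs, n_cycles, m)
      acc <- acc + Mod(co)^2
    }
    total[a, , ] <- bin_columns(acc / length(trials), bin_len)
    avg <- rowMeans(serp[a, , trials, drop = FALSE][, , , drop = TRUE])
    co <- morlet_tfr(avg, fs, freqs, n_cycles, m)
    evoked[a, , ] <- bin_columns(Mod(co)^2, bin_len)
  }
  induced <- total - evoked

  t_step <- ((seq_len(n_steps) - 1) - recordings$baseline_steps) / fs
  times <- vapply(seq_len(nb), function(b)
    mean(t_step[((b - 1) * bin_len + 1):(b * bin_len)]), numeric(1))

  out <- list(total = total, evoked = evoked, induced = induced,
              times = times, freqs = freqs, areas = areas,
              baseline = baseline, n_trials = length(trials))
  if (!is.null(baseline)) {
    bsel <- times >= baseline[1] & times <= baseline[2]
    if (!any(bsel)) stop("baseline window contains no time bins")
    for (nm in c("total", "evoked", "induced")) {
      x <- out[[nm]]
      # wavelet-support edge bins are NA; the baseline uses the valid ones
      bl <- apply(x[, , bsel, drop = FALSE], c(1, 2), mean, na.rm = TRUE)
      out[[nm]] <- x - as.vector(bl)   # recycles over the time dimension
    }
  }
  class(out) <- "spikelex_tfr"
  out
}

#' @exportS3Method base::print
print.spikelex_tfr <- function(x, ...) {
  cat(sprintf("<spikelex_tfr> %d areas x %d freqs (%g-%g Hz) x %d bins, %d trials\n",
              dim(x$total)[1], dim(x$total)[2], min(x$freqs), max(x$freqs),
              dim(x$total)[3], x$n_trials))
  invisible(x)
}

#' Average a time-frequency map over a frequency band
#'
#' @param tfr A `spikelex_tfr`.
#' @param band Frequency band `c(lo, hi)` in Hz (inclusive).
#' @param kind Which map: `"induced"`, `"total"` or `"evoked"`.
#' @return A matrix `[areas x bins]` with the band-averaged power; bin
#'   times as attribute `"times"`.
#' @export
band_average <- function(tfr, band = c(20, 40), kind = "induced") {
  sel <- tfr$freqs >= band[1] & tfr$freqs <= band[2]
  if (!any(sel)) stop("band contains no analysis frequencies")
  out <- apply(tfr[[kind]][, sel, , drop = FALSE], c(1, 3), mean)
  attr(out, "times") <- tfr$times
  out
}

#' Frequency of maximal induced power in a time window
#'
#' @param tfr A `spikelex_tfr`.
#' @param window Time window in seconds relative to onset.
#' @param kind Which map to scan.
#' @return The analysis frequency (Hz) whose power, averaged over areas
#'   and the window's bins, is largest.
#' @export
peak_frequency <- function(tfr, window = c(0, 0.5), kind = "induced") {
  tsel <- tfr$times >= window[1] & tfr$times <= window[2]
  prof <- apply(tfr[[kind]][, , tsel, drop = FALSE], 2, mean, na.rm = TRUE)
  tfr$freqs[which.max(prof)]
}

#' Across-trial wavelet coherence between two areas
#'
#' Magnitude-squared coherence of the single-trial complex wavelet
#' coefficients of a seed and a target area:
#' `|<X_seed * conj(X_target)>|^2 / (<|X_seed|^2> <|X_target|^2>)`,
#' where `< >` averages across trials at each native time sample. The
#' resulting coherence map (values in `[0, 1]`) is then averaged into
#' time bins.
#'
#' @param recordings A `spikelex_recordings`.
#' @param seed_area,target_area Area names (e.g. `"M1_i"` and `"V1"`).
#' @param trials Trial indices to include (one condition).
#' @param freqs,bin_ms,n_cycles,m As in [induced_power()].
#' @return An object of class `spikelex_coherence`: `coherence`
#'   `[freqs x bins]`, `times`, `freqs`, `seed_area`, `target_area`,
#'   `n_trials`.
#' @export
wavelet_coherence <- function(recordings, seed_area, target_area,
                              trials = NULL, freqs = 4:100, bin_ms = 10,
                              n_cycles = 6, m = 3) {
  serp <- recordings$serp
  areas <- dimnames(serp)[[1]]
  si <- match(seed_area, areas)
  ti <- match(target_area, areas)
  if (is.na(si) || is.na(ti)) stop("unknown seed or target area")
  if (is.null(trials)) trials <- seq_len(dim(serp)[3])
  if (length(trials) < 2) stop("coherence needs at least 2 trials")
  fs <- 1000 / recordings$dt
  n_steps <- dim(serp)[2]
  Sxy <- matrix(0 + 0i, length(freqs), n_steps)
  Sxx <- Syy <- matrix(0, length(freqs), n_steps)
  for (tr in trials) {
    X <- morlet_tfr(serp[si, , tr], fs, freqs, n_cycles, m)
    Y <- morlet_tfr(serp[ti, , tr], fs, freqs, n_cycles, m)
    Sxy <- Sxy + X * Conj(Y)
    Sxx <- Sxx + Mod(X)^2
    Syy <- Syy + Mod(Y)^2
  }
  coh <- Mod(Sxy)^2 / (Sxx * Syy)
  bin_len <- round(bin_ms * fs / 1000)
  nb <- n_steps %/% bin_len
  cohb <- bin_columns(coh, bin_len)
  t_step <- ((seq_len(n_steps) - 1) - recordings$baseline_steps) / fs
  times <- vapply(seq_len(nb), function(b)
    mean(t_step[((b - 1) * bin_len + 1):(b * bin_len)]), numeric(1))
  structure(list(coherence = cohb, times = times, freqs = freqs,
                 seed_area = seed_area, target_area = target_area,
                 n_trials = length(trials)),
            class = "spikelex_coherence")
}

#' @exportS3Method base::print
print.spikelex_coherence <- function(x, ...) {
  cat(sprintf("<spikelex_coherence> %s <-> %s, %d freqs x %d bins, %d trials\n",
              x$seed_area, x$target_area, length(x$freqs),
              ncol(x$coherence), x$n_trials))
  invisible(x)
}

#' Cluster-based permutation test for paired condition differences
#'
#' Nonparametric control of the family-wise error over a (site x time)
#' grid of paired observations, in the spirit of the standard
#' cluster-permutation procedure for neurophysiological data: a
#' dependent-samples t statistic is computed per bin; bins exceeding the
#' two-tailed threshold at `alpha` are clustered by temporal adjacency
#' within each site; each cluster's mass is the sum of its t values; the
#' null distribution of the maximum absolute cluster mass is built by
#' randomly swapping the two conditions within pairs (sign flips).
#' Monte-Carlo p values use the (1 + exceedances) / (1 + draws)
#' convention. With `n_perm = NULL` all `2^n` sign flips are enumerated
#' exactly.
#'
#' @param cond_a,cond_b Arrays `[pairs x sites x bins]` (or matrices
#'   `[pairs x bins]` for a single site) of paired observations, e.g.
#'   20-40 Hz band-averaged induced power per network instance.
#' @param n_perm Number of random permutations (or `NULL` for exhaustive
#'   enumeration).
#' @param alpha Two-tailed threshold level for bin inclusion.
#' @return A list with `clusters` (data frame: site, first and last bin,
#'   sign, mass, p), `t_map` (sites x bins), `t_crit`, and `min_p` (1 when
#'   no cluster is suprathreshold).
#' @export
cluster_permutation_test <- function(cond_a, cond_b, n_perm = 1000,
                                     alpha = 0.05) {
  if (length(dim(cond_a)) == 2) {
    dim(cond_a) <- c(dim(cond_a), 1)
    cond_a <- aperm(cond_a, c(1, 3, 2))
    dim(cond_b) <- c(dim(cond_b), 1)
    cond_b <- aperm(cond_b, c(1, 3, 2))
  }
  stopifnot(identical(dim(cond_a), dim(cond_b)))
  d <- cond_a - cond_b
  n <- dim(d)[1]
  if (n < 2) stop("need at least 2 pairs")
  t_crit <- stats::qt(1 - alpha / 2, df = n - 1)

  tmap_of <- function(dd) {
    mu <- apply(dd, c(2, 3), mean)
    s <- apply(dd, c(2, 3), stats::sd)
    t <- mu / (s / sqrt(n))
    t[!is.na(s) & s == 0 & mu == 0] <- 0
    t
  }
  clusters_of <- function(tm) {
    res <- NULL
    for (s in seq_len(nrow(tm))) {
      for (sgn in c(1, -1)) {
        above <- !is.na(tm[s, ]) & sgn * tm[s, ] > t_crit
        r <- rle(above)
        ends <- cumsum(r$lengths)
        starts <- ends - r$lengths + 1
        for (k in which(r$values)) {
          res <- rbind(res, data.frame(
            site = s, from = starts[k], to = ends[k], sign = sgn,
            mass = sum(tm[s, starts[k]:ends[k]])))
        }
      }
    }
    res
  }
  max_mass_of <- function(tm) {
    cl <- clusters_of(tm)
    if (is.null(cl)) 0 else max(abs(cl$mass))
  }

  t_obs <- tmap_of(d)
  cl <- clusters_of(t_obs)

  if (is.null(n_perm)) {
    signs <- as.matrix(expand.grid(rep(list(c(1, -1)), n)))
    null <- apply(signs, 1, function(sg) max_mass_of(tmap_of(d * sg)))
    denom <- nrow(signs)
    exceed <- function(m) sum(null >= m)
    p_of <- function(m) exceed(m) / denom
  } else {
    null <- numeric(n_perm)
    for (i in seq_len(n_perm)) {
      sg <- sample(c(1, -1), n, replace = TRUE)
      null[i] <- max_mass_of(tmap_of(d * sg))
    }
    p_of <- function(m) (1 + sum(null >= m)) / (1 + n_perm)
  }
  if (!is.null(cl)) {
    cl$p <- vapply(abs(cl$mass), p_of, numeric(1))
    cl <- cl[order(cl$p, -abs(cl$mass)), ]
    rownames(cl) <- NULL
  }
  list(clusters = cl, t_map = t_obs, t_crit = t_crit,
       min_p = if (is.null(cl)) 1 else min(cl$p),
       null_max_mass = null)
}

#' Peak S-ERP amplitude per trial
#'
#' The peak membrane-potential response within an area during a
#' post-onset window (50-500 ms by default), averaged across areas, one
#' value per trial.
#'
#' @param recordings A `spikelex_recordings`.
#' @param window Window in seconds relative to stimulus onset.
#' @return A data frame with `trial`, `condition` and `peak`.
#' @export
peak_serp_amplitude <- function(recordings, window = c(0.05, 0.5)) {
  tt <- trial_times(recordings)
  sel <- tt >= window[1] & tt <= window[2]
  peaks <- apply(recordings$serp[, sel, , drop = FALSE], 3,
                 function(m) mean(apply(m, 1, max)))
  data.frame(trial = seq_along(peaks),
             condition = recordings$meta$condition, peak = peaks)
}

#' Paired t test on per-instance peak amplitudes
#'
#' Compares, across network instances, the mean peak S-ERP response to
#' words against pseudowords. With zero variance of the paired
#' differences the statistic is degenerate and reported as such (infinite
#' t, with a warning) rather than failing.
#'
#' @param word,pseudoword Numeric vectors: per-instance mean peak
#'   amplitudes for the two conditions (same instance order).
#' @return A list with `t`, `df`, `p`, `mean_diff` and `degenerate`.
#' @export
peak_amplitude_test <- function(word, pseudoword) {
  if (length(word) != length(pseudoword)) {
    stop("conditions have different instance counts")
  }
  d <- word - pseudoword
  n <- length(d)
  if (n < 2) stop("need at least 2 instances")
  s <- stats::sd(d)
  if (s == 0) {
    if (mean(d) == 0) {
      return(list(t = 0, df = n - 1, p = 1, mean_diff = 0, degenerate = TRUE))
    }
    warning("zero variance of paired differences: degenerate t statistic")
    return(list(t = sign(mean(d)) * Inf, df = n - 1, p = 0,
                mean_diff = mean(d), degenerate = TRUE))
  }
  t <- mean(d) / (s / sqrt(n))
  list(t = t, df = n - 1, p = 2 * stats::pt(-abs(t), n - 1),
       mean_diff = mean(d), degenerate = FALSE)
}
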