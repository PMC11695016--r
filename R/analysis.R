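# Whole-curve statistics for gait cycles: nonparametric (permutation) 1D
# statistical parametric mapping (SPM) paired tests, banded dynamic time
# warping (DTW) similarity scores, gait-cycle normalization and scalar peak
# metrics.

#' Gait curve set
#'
#' A set of repeated trials of one gait variable, each resampled to 101
#' points spanning 0-100% of the gait cycle.
#'
#' @param trials An n_trials x 101 numeric matrix (rows = trials), or a
#'   vector for a single trial.
#' @param label Variable/condition label.
#' @param units Unit string ("deg", "N m", "normalized", ...).
#' @export
gait_curve_set <- function(trials, label = "", units = "") {
  if (is.vector(trials)) trials <- matrix(trials, nrow = 1)
  if (ncol(trials) != 101L)
    stop("gait curves must have 101 samples (0-100% of the cycle)")
  if (nrow(trials) < 1L) stop("at least one trial is required")
  structure(list(trials = trials, label = label, units = units),
            class = "gait_curve_set")
}

#' @export
print.gait_curve_set <- function(x, ...) {
  cat(sprintf("<gait_curve_set> '%s' [%s]: %d trials x 101 samples\n",
              x$label, x$units, nrow(x$trials)))
  invisible(x)
}

as_trial_matrix <- function(x) {
  if (inherits(x, "gait_curve_set")) x$trials
  else if (is.matrix(x)) x
  else matrix(x, nrow = 1)
}

#' Normalize time series to gait cycles
#'
#' Detects ipsilateral heel strikes as upward crossings of the vertical
#' ground reaction force through a threshold, cuts the signals into cycles
#' and resamples each cycle to 101 points (0-100% of the gait cycle) by
#' cubic spline interpolation.
#'
#' @param time Time vector (s), strictly increasing.
#' @param signals Named list (or data.frame) of numeric signals sampled at
#'   `time`.
#' @param grf Vertical GRF signal used for event detection (N); may also be
#'   the name of an entry of `signals`.
#' @param threshold Heel-strike threshold in N (default 20).
#' @return A named list of [gait_curve_set] objects (one per signal, one
#'   trial row per detected cycle) plus an attribute `events` with the
#'   heel-strike times.
#' @export
normalize_gait_cycle <- function(time, signals, grf, threshold = 20) {
  stopifnot_scalar(threshold, "threshold", positive = TRUE)
  if (is.character(grf)) {
    if (is.null(signals[[grf]])) stop("GRF channel '", grf, "' not found")
    grf <- signals[[grf]]
  }
  below <- grf[-length(grf)] < threshold & grf[-1] >= threshold
  idx <- which(below)
  if (length(idx) < 2)
    stop("fewer than two upward GRF crossings of ", threshold,
         " N: cannot segment gait cycles (vertical GRF channel)")
  # linear interpolation of the crossing time
  ev <- time[idx] + (threshold - grf[idx]) / (grf[idx + 1] - grf[idx]) *
    (time[idx + 1] - time[idx])
  pct <- seq(0, 100, length.out = 101)
  out <- lapply(names(signals), function(nm) {
    sig <- signals[[nm]]
    sf <- stats::splinefun(time, sig, method = "natural")
    tr <- t(vapply(seq_len(length(ev) - 1), function(k) {
      tq <- seq(ev[k], ev[k + 1], length.out = 101)
      sf(tq)
    }, numeric(101)))
    gait_curve_set(tr, label = nm)
  })
  names(out) <- names(signals)
  attr(out, "events") <- ev
  out
}

# --- SPM ------------------------------------------------------------------

#' Nonparametric 1D SPM paired t-test
#'
#' Computes the pointwise paired t statistic over the 101 cycle nodes and
#' builds the null distribution of the supremum of |t| from sign-flip
#' permutations of the trial differences (exhaustive when `2^n` does not
#' exceed `perm_cap`, otherwise a seeded random subsample).  The critical
#' threshold is the (1 - alpha) quantile of the permutation distribution;
#' suprathreshold clusters are the maximal intervals with |t| above it.
#'
#' @param setA,setB Paired [gait_curve_set]s (equal trial counts).
#' @param alpha Family-wise significance level (default 0.05).
#' @param perm_cap Maximum number of permutations (default 10000).
#' @param seed Seed for the permutation subsample (only used when
#'   `2^n > perm_cap`).
#' @return An `spm_result`: `t_curve` (101 values), `t_crit`, `clusters`
#'   (matrix of [start%, end%] intervals), `alpha`, `n_perm`, and
#'   `reject` (TRUE if any suprathreshold cluster exists).
#' @export
spm_paired_nonparametric <- function(setA, setB, alpha = 0.05,
                                     perm_cap = 10000, seed = 1L) {
  A <- as_trial_matrix(setA); B <- as_trial_matrix(setB)
  if (nrow(A) != nrow(B))
    stop("paired test requires equal trial counts (", nrow(A), " vs ",
         nrow(B), ")")
  n <- nrow(A)
  if (n < 2) stop("at least two paired trials are required")
  if (2^n * alpha < 1)
    warning("2^n_trials * alpha < 1: the permutation test cannot reject ",
            "at this resolution")
  D <- A - B
  # sign-flip matrix
  if (2^n <= perm_cap) {
    signs <- as.matrix(expand.grid(rep(list(c(1, -1)), n)))
    n_perm <- 2^n
  } else {
    # local RNG: do not disturb the caller's random stream
    old_seed <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    set.seed(seed)
    signs <- matrix(sample(c(1, -1), perm_cap * n, replace = TRUE),
                    perm_cap, n)
    signs[1, ] <- 1  # include the identity labelling
    n_perm <- perm_cap
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  }
  # paired t over all permutations at once: the sum of squares per node is
  # invariant under sign flips, only the mean changes
  SS <- colSums(D^2)
  MU <- (signs %*% D) / n
  VAR <- sweep(-n * MU^2, 2, SS, "+") / (n - 1)
  SE <- sqrt(pmax(VAR, 0) / n)
  Tm <- ifelse(SE > 1e-300, MU / SE, 0)
  t_obs <- Tm[1, ]  # identity labelling is the first row
  maxstat <- apply(abs(Tm), 1, max)
  t_crit <- as.numeric(stats::quantile(maxstat, 1 - alpha, type = 1))
  supra <- abs(t_obs) > t_crit
  clusters <- run_intervals(supra)
  structure(list(t_curve = t_obs, t_crit = t_crit, clusters = clusters,
                 alpha = alpha, n_perm = n_perm,
                 reject = nrow(clusters) > 0),
            class = "spm_result")
}

# maximal TRUE runs of a logical vector, as [start%, end%] over 0..100
run_intervals <- function(supra) {
  r <- rle(supra)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- which(r$values)
  out <- cbind(start = (starts[keep] - 1), end = (ends[keep] - 1))
  out
}

#' @export
print.spm_result <- function(x, ...) {
  cat(sprintf("<spm_result> alpha=%.3g t_crit=%.3f n_perm=%d\n",
              x$alpha, x$t_crit, x$n_perm))
  if (nrow(x$clusters) == 0) cat("  no suprathreshold clusters\n")
  else for (i in seq_len(nrow(x$clusters)))
    cat(sprintf("  cluster: %g%% - %g%% of the gait cycle\n",
                x$clusters[i, 1], x$clusters[i, 2]))
  invisible(x)
}

# --- DTW ------------------------------------------------------------------

#' Normalize curves for DTW comparison
#'
#' Divides every curve by the single maximum absolute value over the whole
#' collection, mapping all values into [-1, 1].  The normalization constant
#' is taken per comparison set, not globally.
#'
#' @param curves A list of numeric vectors, a matrix (rows = curves) or a
#'   [gait_curve_set].
#' @return The same structure, normalized, with attribute `constant`.
#' @export
normalize_curves_for_dtw <- function(curves) {
  vals <- if (is.list(curves) && !inherits(curves, "gait_curve_set"))
    unlist(curves) else as_trial_matrix(curves)
  cmax <- max(abs(vals), na.rm = TRUE)
  if (!is.finite(cmax) || cmax == 0) {
    warning("all-zero curve set: returned unchanged")
    return(curves)
  }
  out <- if (is.list(curves) && !inherits(curves, "gait_curve_set"))
    lapply(curves, function(x) x / cmax)
  else if (inherits(curves, "gait_curve_set")) {
    curves$trials <- curves$trials / cmax; curves
  } else curves / cmax
  attr(out, "constant") <- cmax
  out
}

#' Banded DTW score of two gait curves
#'
#' Dynamic-programming alignment with a Sakoe-Chiba band restricting the
#' temporal shift (default 5% of the series length), endpoints pinned to
#' (1,1) and (N,N).  The score is the total accumulated Euclidean distance
#' of the aligned samples; 0 means the curves are identical.
#'
#' @param x,y Numeric vectors of equal length.
#' @param window_frac Band half-width as a fraction of the length
#'   (default 0.05).
#' @return A `dtw_result`: `score`, `window_frac`, `band`.
#' @export
dtw_score <- function(x, y, window_frac = 0.05) {
  if (length(x) != length(y)) stop("dtw_score requires equal lengths")
  if (window_frac <= 0 || window_frac > 1)
    stop("window_frac must be in (0, 1]")
  N <- length(x)
  w <- ceiling(window_frac * N)
  D <- matrix(Inf, N, N)
  local_d <- function(i, j) abs(x[i] - y[j])
  D[1, 1] <- local_d(1, 1)
  for (i in seq_len(N)) {
    jmin <- max(1, i - w); jmax <- min(N, i + w)
    for (j in jmin:jmax) {
      if (i == 1 && j == 1) next
      best <- Inf
      if (i > 1) best <- min(best, D[i - 1, j])
      if (j > 1) best <- min(best, D[i, j - 1])
      if (i > 1 && j > 1) best <- min(best, D[i - 1, j - 1])
      D[i, j] <- local_d(i, j) + best
    }
  }
  structure(list(score = D[N, N], window_frac = window_frac, band = w),
            class = "dtw_result")
}

#' DTW score matrix across muscles and comparisons
#'
#' Scores the similarity of activation curves between two models or sides,
#' muscle by muscle.  Curves are normalized jointly (per comparison) to
#' [-1, 1]; muscles missing on one side get NaN.  Grouped muscles may be
#' supplied as the pointwise maximum of their components (use
#' [group_curves_max()]).
#'
#' @param set_a,set_b Named lists mapping muscle name to a numeric curve
#'   (101 samples) or NULL/missing for non-existent muscles.
#' @param window_frac DTW band fraction.
#' @param normalize If TRUE (default) apply the joint [-1, 1] normalization.
#' @return A data.frame with columns `muscle` and `score`.
#' @export
dtw_matrix <- function(set_a, set_b, window_frac = 0.05, normalize = TRUE) {
  muscles <- union(names(set_a), names(set_b))
  if (length(muscles) == 0) stop("empty curve sets")
  if (normalize) {
    vals <- c(unlist(set_a), unlist(set_b))
    cmax <- max(abs(vals), na.rm = TRUE)
    if (is.finite(cmax) && cmax > 0) {
      set_a <- lapply(set_a, function(x) if (is.null(x)) NULL else x / cmax)
      set_b <- lapply(set_b, function(x) if (is.null(x)) NULL else x / cmax)
    }
  }
  score <- vapply(muscles, function(m) {
    a <- set_a[[m]]; b <- set_b[[m]]
    if (is.null(a) || is.null(b) || anyNA(a) || anyNA(b)) return(NaN)
    dtw_score(a, b, window_frac)$score
  }, 0)
  data.frame(muscle = muscles, score = unname(score),
             stringsAsFactors = FALSE)
}

#' Pointwise maximum of component muscle curves
#'
#' Builds the activation curve of a muscle group as the pointwise maximum
#' of its components (e.g. biceps femoris = max of long and short head).
#'
#' @param ... Numeric curves of equal length (or a single list).
#' @export
group_curves_max <- function(...) {
  args <- list(...)
  if (length(args) == 1 && is.list(args[[1]])) args <- args[[1]]
  do.call(pmax, args)
}

# --- peak metrics ---------------------------------------------------------

#' Peak value and timing within a phase window
#'
#' Maximum of a gait curve over a [start%, end%] window with parabolic
#' sub-sample refinement of the peak location (ties broken toward the
#' earlier sample; no refinement at window edges).
#'
#' @param curve Numeric vector of 101 samples (0-100% cycle).
#' @param window Phase window in percent, e.g. `c(60, 100)` for swing.
#' @return List with `peak` and `timing_pct`.
#' @export
peak_metrics <- function(curve, window = c(0, 100)) {
  if (length(curve) != 101) stop("curve must have 101 samples")
  if (window[1] > window[2] || window[1] < 0 || window[2] > 100)
    stop("invalid phase window")
  pct <- 0:100
  sel <- which(pct >= window[1] & pct <= window[2])
  if (length(sel) == 0) stop("empty phase window")
  vals <- curve[sel]
  k <- sel[which.max(vals)]  # which.max breaks ties toward the earlier sample
  peak <- curve[k]; timing <- pct[k]
  if (k > sel[1] && k < sel[length(sel)]) {
    y1 <- curve[k - 1]; y2 <- curve[k]; y3 <- curve[k + 1]
    denom <- y1 - 2 * y2 + y3
    if (denom < 0) {
      off <- 0.5 * (y1 - y3) / denom
      if (abs(off) <= 0.5) {
        timing <- pct[k] + off
        peak <- y2 - 0.25 * (y1 - y3) * off
      }
    }
  }
  list(peak = peak, timing_pct = timing)
}
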