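# Reduction: omega-scan maps -> 1D diffractograms -> fitted Bragg peaks.

#' Reduce a reciprocal-space map to a 1D diffractogram
#'
#' Sums intensity across the Omega rows inside the region of interest,
#' yielding the I versus 2-theta curve; the counting error per 2-theta bin
#' is the square root of the summed counts. Total counts inside the ROI are
#' conserved exactly.
#'
#' @param map A [reciprocal_map()].
#' @param roi_omega Length-2 numeric range of Omega (degrees) to integrate,
#'   or `NULL` (default) for the full scanned range.
#' @return A [diffractogram()]; the ROI is recorded in the metadata.
#' @export
integrate_roi <- function(map, roi_omega = NULL) {
  stopifnot(inherits(map, "reciprocal_map"))
  om <- map$omega_axis
  if (is.null(roi_omega)) roi_omega <- range(om)
  if (length(roi_omega) != 2L || roi_omega[1L] > roi_omega[2L]) {
    stop("roi_omega must be an increasing length-2 range")
  }
  rows <- om >= roi_omega[1L] & om <= roi_omega[2L]
  if (!any(rows)) {
    stop(sprintf("ROI [%g, %g] lies outside the scanned Omega range [%g, %g]",
                 roi_omega[1L], roi_omega[2L], min(om), max(om)))
  }
  counts <- colSums(map$intensity[rows, , drop = FALSE])
  diffractogram(map$two_theta_axis, counts, sqrt(pmax(counts, 1)),
                metadata = c(map$metadata,
                             list(roi_omega = as.numeric(roi_omega))))
}

# Internal: prominence of local maxima of a signal (classic definition:
# height above the higher of the two key saddles toward higher terrain).
peak_prominence <- function(sig, idx) {
  vapply(idx, function(i) {
    h <- sig[i]
    left <- sig[seq_len(i - 1L)]
    right <- sig[seq(i + 1L, length(sig))]
    base_left <- if (any(left > h)) {
      j <- max(which(left > h)); min(sig[j:i])
    } else min(c(left, h))
    base_right <- if (any(right > h)) {
      j <- i + min(which(right > h)); min(sig[i:j])
    } else min(c(right, h))
    h - max(base_left, base_right)
  }, numeric(1))
}

#' Detect candidate Bragg peak positions
#'
#' Finds local maxima of the background-subtracted, lightly smoothed signal
#' whose prominence exceeds `min_prominence` times the strongest peak (and
#' a counting-noise floor). The background is a running median wide enough
#' to pass under the Bragg peaks.
#'
#' @param diff A [diffractogram()] with at least 16 bins.
#' @param min_prominence Fractional prominence threshold relative to the
#'   strongest background-subtracted feature (default 2e-4; the weakest
#'   lamellar orders can carry well under 0.1% of the first-order
#'   intensity, and the counting-noise floor already suppresses spurious
#'   bumps).
#' @param max_orders Keep at most this many candidates (the most prominent
#'   ones), default 8.
#' @return Numeric vector of candidate 2-theta positions, sorted ascending;
#'   empty when nothing exceeds the threshold.
#' @export
detect_peaks <- function(diff, min_prominence = 2e-4, max_orders = 8L) {
  stopifnot(inherits(diff, "diffractogram"))
  y <- diff$counts
  n <- length(y)
  if (n < 16L) stop("need at least 16 bins")
  k <- min(max(31L, 2L * (n %/% 16L) + 1L), if (n %% 2L) n else n - 1L)
  bg <- stats::runmed(y, k, endrule = "median")
  sig <- y - bg
  if (n >= 7L) {
    sm <- stats::filter(sig, rep(1 / 5, 5), sides = 2)
    sig <- ifelse(is.na(sm), sig, as.numeric(sm))
  }
  interior <- 2:(n - 1L)
  # plateau-tolerant: smoothed integer counts can tie at the crest
  is_max <- sig[interior] > sig[interior - 1L] &
    sig[interior] >= sig[interior + 1L]
  idx <- interior[is_max & sig[interior] > 0]
  if (!length(idx)) return(numeric())
  prom <- peak_prominence(sig, idx)
  floor_abs <- 5 * stats::median(diff$sigma)
  thr <- max(min_prominence * max(prom), floor_abs)
  keep <- prom >= thr
  idx <- idx[keep]; prom <- prom[keep]
  if (!length(idx)) return(numeric())
  if (length(idx) > max_orders) {
    ord <- order(prom, decreasing = TRUE)[seq_len(max_orders)]
    idx <- idx[ord]
  }
  sort(diff$two_theta[idx])
}

# Internal: evaluate the multipeak model (Gaussians + shared linear
# background) at the given parameter vector.
multipeak_model <- function(par, x, npk) {
  y <- par[1L] + par[2L] * x
  for (k in seq_len(npk)) {
    a <- par[2L + 3L * (k - 1L) + 1L]
    mu <- par[2L + 3L * (k - 1L) + 2L]
    s <- exp(par[2L + 3L * (k - 1L) + 3L])
    y <- y + a * stats::dnorm(x, mu, s)
  }
  y
}

#' Fit Gaussian Bragg peaks with a shared linear background
#'
#' Simultaneous weighted least-squares fit (weights 1/sigma^2) of one
#' Gaussian per candidate position plus a single shared linear background.
#' Candidates closer than one estimated width are merged before fitting.
#' Peaks are indexed by ascending position (h = 1, 2, ...) and validated
#' against the arithmetic progression in q expected of a lamellar stack: a
#' peak whose q deviates by more than 10% of the median order spacing from
#' the progression implied by its neighbours is flagged `lamellar = FALSE`
#' and excluded from the d-spacing fit. A peak whose fitted area comes out
#' negative is dropped with a warning.
#'
#' @param diff A [diffractogram()].
#' @param candidates Numeric vector of candidate 2-theta positions (e.g.
#'   from [detect_peaks()]).
#' @param wavelength Wavelength used only for the lamellar-progression
#'   check, Angstrom.
#' @return A `bragg_peak_set`: a data frame with one row per fitted peak
#'   (`order`, `position`, `position_se`, `area`, `area_se`, `width`,
#'   `lamellar`) and attributes `chi2_reduced` and `background`. Areas are
#'   integrated intensities in total counts under the peak.
#' @export
fit_peaks <- function(diff, candidates, wavelength = 4.487) {
  stopifnot(inherits(diff, "diffractogram"))
  candidates <- sort(as.numeric(candidates))
  if (!length(candidates)) stop("need at least one candidate position")
  x <- diff$two_theta
  y <- diff$counts
  sdev <- pmax(diff$sigma, 1e-6)
  step <- stats::median(diff(x))
  bg0 <- stats::median(y)
  # Initial width: half-maximum span around each candidate.
  est_width <- function(p) {
    i <- which.min(abs(x - p))
    h <- y[i] - bg0
    if (h <= 0) return(5 * step)
    above <- which(y - bg0 > h / 2)
    runs <- split(above, cumsum(c(1, diff(above) != 1)))
    run <- runs[[which(vapply(runs, function(r) i %in% r, logical(1)))[1L]]]
    max(length(run) * step / 2.355, 2 * step)
  }
  widths0 <- vapply(candidates, est_width, numeric(1))
  # Merge candidates closer than one width.
  repeat {
    if (length(candidates) < 2L) break
    gaps <- diff(candidates)
    wmax <- pmax(widths0[-1L], widths0[-length(widths0)])
    j <- which(gaps < wmax)
    if (!length(j)) break
    j <- j[1L]
    candidates[j] <- mean(candidates[j + 0:1])
    candidates <- candidates[-(j + 1L)]
    widths0[j] <- max(widths0[j + 0:1])
    widths0 <- widths0[-(j + 1L)]
  }
  npk <- length(candidates)
  par0 <- c(bg0, 0)
  for (k in seq_len(npk)) {
    i <- which.min(abs(x - candidates[k]))
    height <- max(y[i] - bg0, stats::median(sdev))
    par0 <- c(par0, height * widths0[k] * sqrt(2 * pi), candidates[k],
              log(widths0[k]))
  }
  objective <- function(par) {
    r <- (multipeak_model(par, x, npk) - y) / sdev
    sum(r * r)
  }
  opt <- stats::optim(par0, objective, method = "BFGS",
                      control = list(maxit = 1000, reltol = 1e-14))
  if (opt$convergence != 0) {
    # One Nelder-Mead polish before giving up.
    opt <- stats::optim(opt$par, objective,
                        control = list(maxit = 5000, reltol = 1e-14))
    if (opt$convergence != 0) {
      stop(sprintf(paste0("peak fit did not converge (code %d); residual ",
                          "chi2 = %.4g over %d bins"),
                   opt$convergence, opt$value, length(x)))
    }
  }
  par <- opt$par
  # Covariance from the Gauss-Newton approximation J' J with weighted J.
  np <- length(par)
  eps <- pmax(abs(par), 1) * 1e-6
  f0 <- multipeak_model(par, x, npk) / sdev
  J <- matrix(0, length(x), np)
  for (j in seq_len(np)) {
    pj <- par; pj[j] <- pj[j] + eps[j]
    J[, j] <- (multipeak_model(pj, x, npk) / sdev - f0) / eps[j]
  }
  cov <- tryCatch(solve(crossprod(J)), error = function(e) {
    matrix(NA_real_, np, np)
  })
  se <- sqrt(pmax(diag(cov), 0))
  dof <- max(length(x) - np, 1L)
  chi2_red <- opt$value / dof
  # The model's area parameter is in counts x degrees; report integrated
  # intensities as total counts under the peak (area / bin width).
  area <- par[2 + 3 * (seq_len(npk) - 1) + 1] / step
  pos <- par[2 + 3 * (seq_len(npk) - 1) + 2]
  wid <- exp(par[2 + 3 * (seq_len(npk) - 1) + 3])
  area_se <- se[2 + 3 * (seq_len(npk) - 1) + 1] / step
  pos_se <- se[2 + 3 * (seq_len(npk) - 1) + 2]
  drop <- area <= 0
  if (any(drop)) {
    warning(sprintf("dropping %d peak(s) with non-positive fitted area",
                    sum(drop)))
  }
  keep <- which(!drop)[order(pos[!drop])]
  pk <- data.frame(order = seq_along(keep), position = pos[keep],
                   position_se = pos_se[keep], area = area[keep],
                   area_se = area_se[keep], width = wid[keep],
                   lamellar = TRUE)
  # Lamellar-progression validation: index peaks on the arithmetic grid
  # q_h = h * dq. Candidate spacings are taken from every q_i / m; the
  # spacing indexing the most peaks within 10% wins, and peaks off the
  # progression are flagged non-lamellar (they still appear in the set).
  if (nrow(pk) >= 3L) {
    q <- q_from_theta(pk$position, wavelength)
    cands <- unique(as.vector(outer(q, seq_len(nrow(pk) + 2L), "/")))
    cands <- cands[cands >= max(q) / 8 & cands <= max(q)]
    best <- NULL
    for (dq in sort(cands, decreasing = TRUE)) {  # prefer fundamental spacing
      h <- round(q / dq)
      res <- abs(q - h * dq)
      ok <- h >= 1 & res <= 0.10 * dq
      # a shared index keeps only the best-fitting peak
      for (hh in unique(h[ok])) {
        tied <- which(ok & h == hh)
        if (length(tied) > 1L) ok[setdiff(tied, tied[which.min(res[tied])])] <- FALSE
      }
      score <- sum(ok)
      if (is.null(best) || score > best$score) {
        best <- list(score = score, h = h, ok = ok)
      }
    }
    pk$lamellar <- best$ok
    pk$order[best$ok] <- as.integer(best$h[best$ok])
  }
  structure(pk, class = c("bragg_peak_set", "data.frame"),
            chi2_reduced = chi2_red,
            background = c(intercept = par[1L], slope = par[2L]))
}

#' @export
print.bragg_peak_set <- function(x, ...) {
  cat(sprintf("<bragg_peak_set> %d peaks, reduced chi2 = %.3g\n",
              nrow(x), attr(x, "chi2_reduced")))
  print.data.frame(x, digits = 5)
  invisible(x)
}
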