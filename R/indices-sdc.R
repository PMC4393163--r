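# Sway density curve (SDC) indices 23-28.  The SDC at radius R gives, for
# each sampling instant, how long the CoP trajectory stays locally and
# time-continuously inside a circle of radius R (mm) centred at the current
# point.  Peaks of the SDC are episodes in which the CoP is trapped locally
# (high density); valleys are migrations between such episodes.

moving_average_zero_phase <- function(x, width) {
  if (width <= 1L) return(x)
  if (width %% 2L == 0L) width <- width + 1L
  half <- (width - 1L) %/% 2L
  n <- length(x)
  xp <- c(rep(x[1], half), x, rep(x[n], half))
  as.numeric(stats::filter(xp, rep(1 / width, width), sides = 2))[
    (half + 1L):(half + n)]
}

# Alternating extremum detection on a smoothed series: peaks where the
# forward difference changes from positive to negative (plateaus collapse to
# their last sample), valleys conversely.  Alternation is automatic.
sdc_peaks <- function(s, min_prom_frac = 0.05) {
  d <- diff(s)
  # floating-point ripple on plateaus must not register as extrema
  d[abs(d) < 1e-9 * max(abs(s), 1e-300)] <- 0
  sg <- sign(d)
  nz <- which(sg != 0)
  if (length(nz) == 0L) return(which.max(s))
  # carry last non-zero sign across plateaus (vectorized LOCF)
  pos <- findInterval(seq_along(sg), nz)
  sg_f <- sg[nz][pmax(pos, 1L)]
  turns <- which(sg_f[-1] != sg_f[-length(sg_f)]) + 1L
  kind <- ifelse(sg_f[turns - 1L] > 0, 1L, -1L)  # 1 = peak, -1 = valley
  # prune low-prominence peak/valley pairs (least prominent first), keeping
  # the alternation intact
  thr <- min_prom_frac * (max(s) - min(s))
  ext <- turns; typ <- kind
  while (length(ext) >= 2L) {
    dh <- abs(diff(s[ext]))
    j <- which.min(dh)
    if (dh[j] >= thr) break
    keep <- setdiff(seq_along(ext), c(j, j + 1L))
    ext <- ext[keep]; typ <- typ[keep]
  }
  peaks <- ext[typ > 0L]
  if (length(peaks) == 0L) peaks <- which.max(s)
  peaks
}

#' Sway-density profile at one radius
#'
#' @param pt A \code{processed_trial}.
#' @param radius Circle radius (mm).
#' @param config A \code{\link{sway_config}}.
#' @return List with \code{sdc} (raw residence times, s), \code{smooth}
#'   (zero-phase moving-average smoothed SDC), \code{peaks} (sample indices)
#'   and the per-radius summaries \code{mt} (mean inter-peak interval, s),
#'   \code{mp} (mean peak value, s), \code{md} (mean planar distance between
#'   successive peak locations, mm).
#' @export
sdc_profile <- function(pt, radius, config = sway_config()) {
  sdc <- .sdc_residence(pt$ml_f, pt$ap_f, radius, pt$fs)
  width <- as.integer(round(config$sdc_smooth_s * pt$fs))
  sm <- moving_average_zero_phase(sdc, width)
  pk <- sdc_peaks(sm, config$sdc_min_prominence)
  mt <- if (length(pk) >= 2L) mean(diff(pk)) / pt$fs else NA_real_
  mp <- if (length(pk) >= 1L) mean(sm[pk]) else NA_real_
  md <- if (length(pk) >= 2L) {
    mean(sqrt(diff(pt$ml_f[pk])^2 + diff(pt$ap_f[pk])^2))
  } else NA_real_
  list(sdc = sdc, smooth = sm, peaks = pk, radius = radius,
       mt = mt, mp = mp, md = md)
}

#' Sway-density indices (23-28)
#'
#' MT3/MP3/MD3 at the reporting radius (default R = 3 mm); Mean-MT and
#' Mean-MD averaged over the radius grid (default 2-5 mm); the raw MP-vs-R
#' regression slope (log10-transformed later as log-Slope-MP).
#'
#' @param pt A \code{processed_trial}.
#' @param config A \code{\link{sway_config}}.
#' @return List with \code{values} and \code{flags}.
#' @export
sway_density_indices <- function(pt, config = sway_config()) {
  radii <- sort(config$sdc_radii)
  sdc_all <- .sdc_residence_multi(pt$ml_f, pt$ap_f, radii, pt$fs)
  width <- as.integer(round(config$sdc_smooth_s * pt$fs))
  profs <- lapply(seq_along(radii), function(j) {
    sm <- moving_average_zero_phase(sdc_all[, j], width)
    pk <- sdc_peaks(sm, config$sdc_min_prominence)
    list(mt = if (length(pk) >= 2L) mean(diff(pk)) / pt$fs else NA_real_,
         mp = if (length(pk) >= 1L) mean(sm[pk]) else NA_real_,
         md = if (length(pk) >= 2L) {
           mean(sqrt(diff(pt$ml_f[pk])^2 + diff(pt$ap_f[pk])^2))
         } else NA_real_)
  })
  names(profs) <- as.character(radii)
  at <- profs[[as.character(config$sdc_peak_radius)]]
  mts <- vapply(profs, `[[`, numeric(1), "mt")
  mps <- vapply(profs, `[[`, numeric(1), "mp")
  mds <- vapply(profs, `[[`, numeric(1), "md")
  vals <- c(`23` = at$mt, `24` = at$mp, `25` = at$md,
            `26` = if (all(is.finite(mts))) mean(mts) else NA_real_,
            `27` = NA_real_,
            `28` = if (all(is.finite(mds))) mean(mds) else NA_real_)
  flags <- stats::setNames(ifelse(is.na(vals), "degenerate", "ok"),
                           names(vals))
  if (all(is.finite(mps)) && length(radii) >= 2L) {
    sl <- unname(stats::coef(stats::lm(mps ~ radii))[2])
    if (is.finite(sl) && sl > 0) {
      vals[["27"]] <- sl
      flags[["27"]] <- "ok"
    }
  }
  list(values = vals, flags = flags)
}
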