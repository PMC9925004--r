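# Scalar biomarkers from activation maps and pseudo-ECG traces, sex and
# geometry difference markers, and the Welch comparison.

#' Activation markers from a simulation
#'
#' Total activation time (TAT, last local activation), the times to
#' activate 10% and 90% of the excitable tissue volume (TAT10, TAT90,
#' volume-weighted), and the electrical dyssynchrony index (EDI, the
#' volume-weighted standard deviation of the local activation time).
#'
#' @param result a `simulation_result`.
#' @param weighted volume-weight TAT10/90 and EDI (default) or treat nodes
#'   equally.
#' @return list with `TAT`, `TAT10`, `TAT90`, `EDI` (ms) and `complete`
#'   (logical). Markers are `NA` when activation is incomplete.
#' @export
activation_markers <- function(result, weighted = TRUE) {
  lat <- result$lat[result$excitable]
  w <- if (weighted) result$mass[result$excitable] else
    rep(1, sum(result$excitable))
  if (anyNA(lat))
    return(list(TAT = NA_real_, TAT10 = NA_real_, TAT90 = NA_real_,
                EDI = NA_real_, complete = FALSE))
  o <- order(lat)
  cw <- cumsum(w[o]) / sum(w)
  tat10 <- lat[o][which(cw >= 0.1)[1]]
  tat90 <- lat[o][which(cw >= 0.9)[1]]
  mu <- sum(w * lat) / sum(w)
  edi <- sqrt(sum(w * (lat - mu)^2) / sum(w))
  list(TAT = max(lat), TAT10 = tat10, TAT90 = tat90, EDI = edi,
       complete = TRUE)
}

#' Apparent conduction velocity on a surface
#'
#' Per-face conduction speed `1 / ||grad_surface LAT||` on a triangulated
#' surface; the marker is the mode of the face-area-weighted speed
#' histogram (ties broken toward the lower bin).
#'
#' @param result a `simulation_result` (or any list with `lat` and `mesh`).
#' @param faces r x 3 matrix of surface triangles; defaults to the
#'   epicardial surface stored in the mesh.
#' @param bin_width_cm_s histogram bin width (cm/s).
#' @param cv_max_cm_s speeds above this cap (near-flat activation) are
#'   excluded from the histogram.
#' @return modal conduction velocity (cm/s), the midpoint of the modal bin.
#' @export
apparent_cv <- function(result, faces = NULL, bin_width_cm_s = 2,
                        cv_max_cm_s = 150) {
  mesh <- result$mesh
  if (is.null(faces)) {
    if (is.null(mesh$surfaces))
      stop("mesh carries no surface triangulation; supply `faces`")
    faces <- mesh$surfaces$epi$faces
  }
  lat <- result$lat
  p1 <- mesh$nodes[faces[, 1], , drop = FALSE]
  p2 <- mesh$nodes[faces[, 2], , drop = FALSE]
  p3 <- mesh$nodes[faces[, 3], , drop = FALSE]
  t1 <- lat[faces[, 1]]; t2 <- lat[faces[, 2]]; t3 <- lat[faces[, 3]]
  e1 <- p2 - p1; e2 <- p3 - p1
  a11 <- rowSums(e1 * e1); a12 <- rowSums(e1 * e2); a22 <- rowSums(e2 * e2)
  det <- a11 * a22 - a12^2
  b1 <- t2 - t1; b2 <- t3 - t1
  al <- (a22 * b1 - a12 * b2) / det
  be <- (a11 * b2 - a12 * b1) / det
  g <- cbind(al * e1[, 1] + be * e2[, 1], al * e1[, 2] + be * e2[, 2],
             al * e1[, 3] + be * e2[, 3])
  gmag <- sqrt(rowSums(g^2)) # ms/cm
  cr <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  area <- sqrt(rowSums(cr^2)) / 2
  cv <- 1000 / gmag # cm/s
  ok <- is.finite(cv) & cv <= cv_max_cm_s
  if (mean(!ok) > 0.5)
    stop("more than half of the surface faces have unusable activation",
         " gradients")
  cv <- cv[ok]; area <- area[ok]
  breaks <- seq(0, max(cv) + bin_width_cm_s, by = bin_width_cm_s)
  bin <- findInterval(cv, breaks, rightmost.closed = TRUE)
  wsum <- tapply(area, bin, sum)
  modal <- as.integer(names(wsum)[which.max(wsum)]) # which.max: lowest tie
  breaks[modal] + bin_width_cm_s / 2
}

# per-lead baseline and out-of-band mask; the tolerance is a fraction of
# the lead's peak-to-peak amplitude measured over [amp_lo, amp_hi]
.ecg_bands <- function(ecg, stim_onset_ms, baseline_tol_frac,
                       amp_lo = -Inf, amp_hi = Inf,
                       base_from = c("pre", "tail"), tail_ms = 30,
                       leads = c("LI", "LII", "LIII")) {
  base_from <- match.arg(base_from)
  pre <- ecg$t_ms < stim_onset_ms
  seg <- ecg$t_ms >= amp_lo & ecg$t_ms <= amp_hi
  tailseg <- seg & ecg$t_ms > amp_hi - tail_ms
  out <- lapply(leads, function(ld) {
    v <- ecg[[ld]]
    base <- if (base_from == "tail" && any(tailseg)) mean(v[tailseg])
      else if (any(pre)) mean(v[pre]) else v[1]
    pp <- if (any(seg)) diff(range(v[seg])) else 0
    tol <- baseline_tol_frac * pp
    list(base = base, tol = tol, pp = pp, off = abs(v - base) > tol)
  })
  names(out) <- leads
  out
}

#' QRS complex duration from a pseudo-ECG
#'
#' Time from the onset of the complex (the stimulus onset) to the point at
#' which all three limb leads have returned to - and stay within for at
#' least `hold_ms` - a tolerance band around the pre-stimulus baseline,
#' searched inside the depolarization window.
#'
#' @param ecg an `ecg_trace`.
#' @param stim_onset_ms stimulus onset (ms).
#' @param window_ms depolarization window after onset (default 200 ms).
#' @param baseline_tol_frac tolerance band as a fraction of each lead's
#'   peak-to-peak amplitude (default 0.02).
#' @param hold_ms dwell time required inside the band to call the complex
#'   ended (suppresses the brief baseline touches of fractionated
#'   complexes).
#' @return QRS duration (ms); `NA` (flagged undefined) for flat leads or if
#'   the leads never settle at baseline within the window.
#' @export
qrs_duration <- function(ecg, stim_onset_ms = 0, window_ms = 200,
                         baseline_tol_frac = 0.02, hold_ms = 12) {
  bands <- .ecg_bands(ecg, stim_onset_ms, baseline_tol_frac)
  any_off <- Reduce(`|`, lapply(bands, `[[`, "off"))
  t <- ecg$t_ms
  win <- which(t >= stim_onset_ms & t <= stim_onset_ms + window_ms)
  if (!any(any_off[win])) return(NA_real_) # flat leads
  first_off <- win[which(any_off[win])[1]]
  for (k in win[win > first_off]) {
    if (any_off[k]) next
    dwell <- which(t >= t[k] & t <= t[k] + hold_ms)
    if (all(!any_off[dwell])) return(t[k] - stim_onset_ms)
  }
  NA_real_
}

#' QT interval duration from a pseudo-ECG
#'
#' Time from the onset of the complex to the last point at which the three
#' limb leads reach the baseline after the T wave. The T-wave tolerance
#' band is scaled by the repolarization-segment amplitude so that the end
#' of a low-amplitude T wave is still resolved against a large QRS.
#'
#' @inheritParams qrs_duration
#' @param window_ms analysis window; defaults to the full trace.
#' @param t_gap_ms gap after the QRS end before the T-wave segment starts.
#' @return QT interval (ms), or `NA` when undefined (no QRS or no
#'   detectable T wave).
#' @export
qt_interval <- function(ecg, stim_onset_ms = 0,
                        window_ms = max(ecg$t_ms) - stim_onset_ms,
                        baseline_tol_frac = 0.02, hold_ms = 12,
                        t_gap_ms = 20) {
  qrs <- qrs_duration(ecg, stim_onset_ms, min(200, window_ms),
                      baseline_tol_frac, hold_ms)
  if (is.na(qrs)) return(NA_real_)
  t_lo <- stim_onset_ms + qrs + t_gap_ms
  t_hi <- stim_onset_ms + window_ms
  # the post-T quiescent level anchors the band: slow late drifts of the
  # resting potential must not mask the T-wave end
  bands <- .ecg_bands(ecg, stim_onset_ms, baseline_tol_frac, t_lo, t_hi,
                      base_from = "tail")
  if (all(vapply(bands, function(b) b$pp <= 0, TRUE))) return(NA_real_)
  any_off <- Reduce(`|`, lapply(bands, `[[`, "off"))
  t <- ecg$t_ms
  seg <- which(t >= t_lo & t <= t_hi)
  if (!any(any_off[seg])) return(NA_real_) # no T wave resolved
  last_off <- seg[max(which(any_off[seg]))]
  nxt <- which(seq_along(t) > last_off & !any_off)
  end <- if (length(nxt)) t[nxt[1]] else t[last_off]
  end - stim_onset_ms
}

#' Count baseline crossings inside the QRS window (fractionation index)
#'
#' Number of sign alternations of the out-of-band lead excursions within
#' the depolarization window, summed over the three leads. Extra
#' zero-crossings relative to a smoothed counterpart indicate QRS
#' fractionation caused by sub-structure propagation short-cuts.
#'
#' @inheritParams qrs_duration
#' @return integer crossing count.
#' @export
qrs_crossings <- function(ecg, stim_onset_ms = 0, window_ms = 200,
                          baseline_tol_frac = 0.02) {
  bands <- .ecg_bands(ecg, stim_onset_ms, baseline_tol_frac)
  win <- ecg$t_ms >= stim_onset_ms & ecg$t_ms <= stim_onset_ms + window_ms
  total <- 0L
  for (ld in names(bands)) {
    v <- ecg[[ld]][win] - bands[[ld]]$base
    s <- sign(v)
    s[abs(v) <= bands[[ld]]$tol] <- 0
    s <- s[s != 0]
    if (length(s) > 1) total <- total + sum(diff(s) != 0)
  }
  total
}

#' Count deflection notches within the QRS complex
#'
#' Number of sign alternations of the lead derivative inside the QRS
#' window, summed over the three limb leads: extra notches relative to a
#' smoothed counterpart indicate QRS fractionation caused by sub-structure
#' propagation short-cuts.
#'
#' @inheritParams qrs_duration
#' @param qrs_ms QRS duration; computed via [qrs_duration()] when `NULL`.
#' @return integer notch count (`NA` if the QRS is undefined).
#' @export
qrs_notches <- function(ecg, stim_onset_ms = 0, qrs_ms = NULL,
                        baseline_tol_frac = 0.02) {
  if (is.null(qrs_ms))
    qrs_ms <- qrs_duration(ecg, stim_onset_ms,
                           baseline_tol_frac = baseline_tol_frac)
  if (is.na(qrs_ms)) return(NA_integer_)
  win <- ecg$t_ms >= stim_onset_ms & ecg$t_ms <= stim_onset_ms + qrs_ms
  tot <- 0L
  for (ld in c("LI", "LII", "LIII")) {
    dv <- diff(ecg[[ld]][win])
    s <- sign(dv)
    s <- s[s != 0]
    if (length(s) > 1) tot <- tot + sum(diff(s) != 0)
  }
  tot
}

#' High-frequency fractionation index of the QRS complex
#'
#' Ratio of the second-difference (curvature) energy to the total signal
#' energy of the three limb leads inside the QRS window. Fractionated
#' complexes — extra notching and slurring produced by sub-structure
#' propagation short-cuts — concentrate energy at high frequencies, so the
#' detailed member of a geometry pair scores higher than its smoothed
#' counterpart regardless of complex duration.
#'
#' @inheritParams qrs_notches
#' @return dimensionless ratio (`NA` if the QRS is undefined).
#' @export
qrs_hf_ratio <- function(ecg, stim_onset_ms = 0, qrs_ms = NULL,
                         baseline_tol_frac = 0.02) {
  if (is.null(qrs_ms))
    qrs_ms <- qrs_duration(ecg, stim_onset_ms,
                           baseline_tol_frac = baseline_tol_frac)
  if (is.na(qrs_ms)) return(NA_real_)
  win <- ecg$t_ms >= stim_onset_ms & ecg$t_ms <= stim_onset_ms + qrs_ms
  hf <- 0; sig <- 0
  for (ld in c("LI", "LII", "LIII")) {
    v <- ecg[[ld]][win]
    hf <- hf + sum(diff(diff(v))^2)
    sig <- sig + sum((v - mean(v))^2)
  }
  if (sig == 0) return(NA_real_)
  hf / sig
}

#' Sex and geometry difference markers
#'
#' Per-heart sex differences (female minus male on the same geometry) and
#' per-sex geometry differences (detailed minus smoothed for the same sex),
#' with group means, mirroring the comparison logic of the reference study
#' tables.
#'
#' @param records data.frame with columns `heart`, `geometry`
#'   (`"detailed"`/`"smoothed"`), `sex` (`"M"`/`"F"`) and marker columns
#'   (`QRS`, `QT`, `TAT`, `TAT10`, `TAT90`, `EDI`, `CV` as available).
#' @return list with `sex_diff` (QT_diff, QRS_diff per heart x geometry),
#'   `geometry_diff` (G-diff markers per heart x sex) and `means`.
#' @export
difference_markers <- function(records) {
  stopifnot(all(c("heart", "geometry", "sex") %in% names(records)))
  markers <- intersect(c("QRS", "QT", "TAT", "TAT10", "TAT90", "EDI", "CV"),
                       names(records))
  sex_rows <- list()
  for (h in unique(records$heart)) for (g in unique(records$geometry)) {
    f <- records[records$heart == h & records$geometry == g &
                   records$sex == "F", ]
    m <- records[records$heart == h & records$geometry == g &
                   records$sex == "M", ]
    if (nrow(f) != 1 || nrow(m) != 1) {
      message("difference_markers: unmatched sex pair for ", h, "/", g,
              " - excluded")
      next
    }
    row <- data.frame(heart = h, geometry = g)
    if ("QT" %in% markers) row$QT_diff <- f$QT - m$QT
    if ("QRS" %in% markers) row$QRS_diff <- f$QRS - m$QRS
    sex_rows[[length(sex_rows) + 1]] <- row
  }
  geo_rows <- list()
  for (h in unique(records$heart)) for (sx in unique(records$sex)) {
    d <- records[records$heart == h & records$sex == sx &
                   records$geometry == "detailed", ]
    s <- records[records$heart == h & records$sex == sx &
                   records$geometry == "smoothed", ]
    if (nrow(d) != 1 || nrow(s) != 1) {
      message("difference_markers: unmatched geometry pair for ", h, "/", sx,
              " - excluded")
      next
    }
    row <- data.frame(heart = h, sex = sx)
    for (mk in markers) row[[paste0(mk, "_Gdiff")]] <- d[[mk]] - s[[mk]]
    geo_rows[[length(geo_rows) + 1]] <- row
  }
  sex_diff <- do.call(rbind, sex_rows)
  geometry_diff <- do.call(rbind, geo_rows)
  means <- list()
  if (!is.null(sex_diff) && "QT_diff" %in% names(sex_diff))
    means$QT_diff_by_geometry <- tapply(sex_diff$QT_diff, sex_diff$geometry,
                                        mean)
  if (!is.null(geometry_diff))
    for (mk in grep("_Gdiff$", names(geometry_diff), value = TRUE))
      means[[mk]] <- mean(geometry_diff[[mk]])
  list(sex_diff = sex_diff, geometry_diff = geometry_diff, means = means)
}

#' Welch two-sample t-test
#'
#' Two-tailed unequal-variance comparison (Welch-Satterthwaite degrees of
#' freedom), as used for the sex and geometry marker comparisons. Delegates
#' to [stats::t.test()]; the degenerate zero-variance case with equal means
#' returns `p = 1` by convention.
#'
#' @param group_a,group_b numeric vectors (n >= 2 each).
#' @return list with `t`, `df`, `p`.
#' @export
welch_ttest <- function(group_a, group_b) {
  stopifnot(length(group_a) >= 2, length(group_b) >= 2)
  if (sd(group_a) == 0 && sd(group_b) == 0) {
    eq <- isTRUE(all.equal(mean(group_a), mean(group_b)))
    return(list(t = if (eq) 0 else Inf * sign(mean(group_a) - mean(group_b)),
                df = length(group_a) + length(group_b) - 2,
                p = if (eq) 1 else 0))
  }
  ht <- t.test(group_a, group_b, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value))
}
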