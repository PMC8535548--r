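#' @title Q/S fiducial detection by gamma-oriented slope predicates
#'
#' @description
#' Q and S are the notches flanking the R-peak: gamma-oriented local minima
#' of the normalized signal (true minima for upright beats, maxima for
#' inverted ones). Q-onset and S-offset are the shoulders where the notch
#' walls meet the baseline; their predicates relax the slope comparison to
#' admit zero slopes and confirm with a two-point look-ahead (look-back),
#' so a flat baseline point fires immediately. Every operation scans sample
#' by sample away from its anchor and returns the first index whose
#' predicate holds; if none does, the far end of the scan range is returned
#' with `mapped = TRUE`.
#'
#' All predicates are evaluated on the backward slope sign
#' `sign(I(t) - I(t+1))`.
#'
#' @param I Normalized window (list with `samples`, see [normalize_window()]).
#' @param from Anchor index: the leftmost accepted R (for Q), the detected Q
#'   (for Q-onset), the rightmost accepted R (for S), or the detected S (for
#'   S-offset). Scanning starts one sample beyond it.
#' @param gamma R-peak polarity, +1 or -1.
#' @param config [detector_config()]; supplies the search ranges.
#' @param limit Optional hard bound on the scan (sample index) in the scan
#'   direction, e.g. the previous beat's territory.
#' @return List with `index` and logical `mapped`.
#' @name qs_detection
NULL

scan_slope <- function(x, from, range_len, direction, cond, limit = NULL) {
  n <- length(x)
  s <- slope_sign(x)
  if (direction == "left") {
    lo <- max(from - range_len, 2L)
    if (!is.null(limit)) lo <- max(lo, limit)
    seqx <- if (from - 1L >= lo) seq.int(from - 1L, lo) else integer(0)
  } else {
    hi <- min(from + range_len, n - 1L)
    if (!is.null(limit)) hi <- min(hi, limit)
    seqx <- if (from + 1L <= hi) seq.int(from + 1L, hi) else integer(0)
  }
  for (x0 in seqx) {
    if (x0 < 2L || x0 > n - 1L) next
    if (cond(s, x0)) return(list(index = x0, mapped = FALSE))
  }
  fallback <- if (length(seqx)) seqx[length(seqx)] else from
  list(index = as.integer(fallback), mapped = TRUE)
}

# relaxed sign test helper: out-of-range slope positions count as satisfied
relaxed <- function(s, pos, gamma, cmp) {
  pos <- pos[pos >= 1 & pos <= length(s)]
  if (!length(pos)) return(TRUE)
  if (cmp == "le") all(gamma * s[pos] <= 0) else all(gamma * s[pos] >= 0)
}

#' @rdname qs_detection
#' @export
detect_q <- function(I, from, gamma, config = detector_config(), limit = NULL) {
  scan_slope(I$samples, from, config$alpha_q, "left",
             function(s, x) gamma * s[x - 1L] > 0 && gamma * s[x] < 0,
             limit = limit)
}

#' @rdname qs_detection
#' @export
detect_q_onset <- function(I, from, gamma, config = detector_config(),
                           limit = NULL) {
  scan_slope(I$samples, from, config$alpha_ql, "left",
             function(s, x) {
               relaxed(s, x - 1L, gamma, "le") &&
                 relaxed(s, c(x, x + 1L), gamma, "ge")
             },
             limit = limit)
}

#' @rdname qs_detection
#' @export
detect_s <- function(I, from, gamma, config = detector_config(), limit = NULL) {
  scan_slope(I$samples, from, config$alpha_s, "right",
             function(s, x) gamma * s[x - 1L] > 0 && gamma * s[x] < 0,
             limit = limit)
}

#' @rdname qs_detection
#' @export
detect_s_offset <- function(I, from, gamma, config = detector_config(),
                            limit = NULL) {
  scan_slope(I$samples, from, config$alpha_sr, "right",
             function(s, x) {
               relaxed(s, c(x - 2L, x - 1L), gamma, "le") &&
                 relaxed(s, x, gamma, "ge")
             },
             limit = limit)
}

# --- symmetric point filter (P/T peaks) -----------------------------------

# wing test at candidate x: left wings x-(v+1)..x-(v+lw) must be
# omega-rising (omega*sign B' <= 0), right wings x+(v+1)-1..x+(v+rw)-1 must
# be omega-falling (omega*sign B' >= 0). sign(0) satisfies both (plateaus
# pass), but each side must contribute at least one strictly-signed
# satisfying slope so perfectly flat segments never fire. Returns the
# number of satisfied wing points, or -Inf when inadmissible.
peak_filter_count <- function(s, x, omega, v, lw, rw) {
  n <- length(s)
  li <- x - ((v + 1L):(v + lw))
  ri <- x + ((v + 1L):(v + rw)) - 1L
  if (any(li < 1L) || any(ri > n)) return(-Inf)
  sl <- omega * s[li]
  sr <- omega * s[ri]
  ok_l <- sl <= 0
  ok_r <- sr >= 0
  if (!any(ok_l & sl != 0) || !any(ok_r & sr != 0)) return(-Inf)
  sum(ok_l) + sum(ok_r)
}

peak_filter_fires <- function(s, x, omega, v, lw, rw, rho) {
  peak_filter_count(s, x, omega, v, lw, rw) >= rho * (lw + rw)
}

#' Detect a P- or T-peak with the symmetric point filter
#'
#' Scans the predicted background signal over a search range (leftward from
#' Q-onset - 1 for P, rightward from S-offset + 1 for T) and accepts the
#' first sample whose surrounding slope signs look like a wave apex of
#' polarity `omega`: the left wing rising, the right wing falling (both
#' orientation-flipped for `omega = -1`), with at least a fraction `rho` of
#' the `2 * (wing - v)` wing points satisfying their condition. The
#' deformation width `v` starts at 0 and grows until acceptance, skipping
#' `v` samples next to the apex so plateaued or locally deformed peaks can
#' still fire; the value at which acceptance first occurs is returned as
#' `v_true`.
#'
#' @param B Numeric predicted background signal.
#' @param from Anchor index; scanning starts one sample beyond it.
#' @param direction `"left"` (P) or `"right"` (T).
#' @param range_len Search range in samples (`alpha_p` or `alpha_t`).
#' @param omega Wave polarity to search, +1 (convex) or -1 (inverted).
#' @param wing Base wing length (10 for P, 20 for T at 360 Hz).
#' @param v_max Maximum deformation width tried.
#' @param rho Acceptance ratio in (0, 1].
#' @param limit Optional hard bound on the scan in the scan direction.
#' @return List with `index`, `omega`, `v_true`, or `NULL` when no
#'   (v, x) combination fires (a legal outcome consumed by mapping).
#' @export
detect_wave_peak <- function(B, from, direction, range_len, omega,
                             wing, v_max, rho, limit = NULL) {
  n <- length(B)
  s <- slope_sign(B)
  if (direction == "left") {
    lo <- max(from - range_len, 1L)
    if (!is.null(limit)) lo <- max(lo, limit)
    seqx <- if (from - 1L >= lo) seq.int(from - 1L, lo) else integer(0)
  } else {
    hi <- min(from + range_len, n)
    if (!is.null(limit)) hi <- min(hi, limit)
    seqx <- if (from + 1L <= hi) seq.int(from + 1L, hi) else integer(0)
  }
  if (!length(seqx)) return(NULL)
  for (v in 0:v_max) {
    lw <- wing - v
    if (lw < 1L) break
    thr <- rho * 2 * lw
    for (k in seq_along(seqx)) {
      cnt <- peak_filter_count(s, seqx[k], omega, v, lw, lw)
      if (cnt >= thr) {
        # refine within the contiguous cluster of accepting candidates: the
        # clean apex has the maximal wing count, while rho < 1 lets the scan
        # fire a sample or two early on its shoulder
        best_x <- seqx[k]
        best_cnt <- cnt
        j <- k + 1L
        while (j <= length(seqx)) {
          cj <- peak_filter_count(s, seqx[j], omega, v, lw, lw)
          if (cj < thr) break
          if (cj > best_cnt) {
            best_cnt <- cj
            best_x <- seqx[j]
          }
          j <- j + 1L
        }
        return(list(index = as.integer(best_x), omega = as.integer(omega),
                    v_true = as.integer(v)))
      }
    }
  }
  NULL
}

# asymmetric bound filter: toes are the mirror pattern of the apex. All
# (rho = 1) wing points must satisfy omega*sign B'(x-l) >= 0 (left) and
# omega*sign B'(x+r-1) <= 0 (right); sign(0) passes, out-of-range fails.
bound_filter_fires <- function(s, x, omega, lw, rw) {
  n <- length(s)
  li <- x - seq_len(lw)
  ri <- x + seq_len(rw) - 1L
  if (any(li < 1L) || any(ri > n)) return(FALSE)
  all(omega * s[li] >= 0) && all(omega * s[ri] <= 0)
}

#' Detect a P/T onset or offset with the asymmetric point filter
#'
#' Starting next to the detected wave apex (shifted by the deformation width
#' `v_true`) and moving outward, accepts the first sample where all wing
#' slope signs match the toe pattern of a wave of polarity `omega`: the side
#' toward the apex still sloping, the outer side flat or reversed. Onsets
#' use 2 outer / 4 inner wing points, offsets 4 inner / 2 outer. Because the
#' scan moves outward from the apex, the first acceptance is the toe closest
#' to the wave.
#'
#' @param B Numeric predicted background signal.
#' @param peak_index,omega,v_true Apex triple from [detect_wave_peak()].
#' @param side `"onset"` (scan left) or `"offset"` (scan right).
#' @param lower,upper Scan bounds (sample indices, inclusive).
#' @return Integer index, or `NULL` when no sample qualifies (the bound is
#'   then mapped).
#' @export
detect_wave_bounds <- function(B, peak_index, omega, v_true, side,
                               lower, upper) {
  n <- length(B)
  s <- slope_sign(B)
  if (side == "onset") {
    start <- min(peak_index - 1L + v_true, n - 1L)
    seqx <- if (start >= lower) seq.int(start, max(lower, 1L)) else integer(0)
    lw <- 2L; rw <- 4L
  } else {
    start <- max(peak_index + 1L + v_true, 2L)
    seqx <- if (start <= upper) seq.int(start, min(upper, n)) else integer(0)
    lw <- 4L; rw <- 2L
  }
  for (x0 in seqx) {
    if (bound_filter_fires(s, x0, omega, lw, rw)) {
      idx <- if (side == "onset") min(x0, peak_index) else max(x0, peak_index)
      return(as.integer(idx))
    }
  }
  NULL
}

#' Choose between the normal and inverted wave candidate
#'
#' When both polarities of a P- or T-wave were detected, the inverted
#' (concave) candidate wins only if it is both wider (onset-to-offset) and
#' has the larger triangle area spanned by its three fiducials on the
#' background signal; otherwise the normal (convex) candidate is kept. With
#' a single candidate, that candidate is returned.
#'
#' @param normal,inverted Candidate lists with `onset`, `peak`, `offset`,
#'   `omega`, `v_true` (either may be `NULL`).
#' @param B Numeric background signal (for the triangle areas).
#' @return The chosen candidate list, or `NULL` when neither exists.
#' @export
select_wave_polarity <- function(normal, inverted, B) {
  complete <- function(cand) {
    !is.null(cand) && !is.null(cand$onset) && !is.null(cand$offset)
  }
  tri_area <- function(cand) {
    xs <- c(cand$onset, cand$peak, cand$offset)
    ys <- B[xs]
    abs(xs[1] * (ys[2] - ys[3]) + xs[2] * (ys[3] - ys[1]) +
          xs[3] * (ys[1] - ys[2])) / 2
  }
  if (is.null(normal) && is.null(inverted)) return(NULL)
  if (is.null(inverted)) return(normal)
  if (is.null(normal)) return(inverted)
  if (complete(inverted) && complete(normal)) {
    wider <- (inverted$offset - inverted$onset) > (normal$offset - normal$onset)
    bigger <- tri_area(inverted) > tri_area(normal)
    if (wider && bigger) return(inverted)
  }
  normal
}

#' Map undetected P/T fiducials
#'
#' Guarantees that every beat carries all 11 fiducials. A missing P-peak
#' collapses all three P fiducials onto the Q-onset; a present P-peak with a
#' missing onset maps the onset onto the peak, and a missing offset onto the
#' Q-onset. Symmetrically, a missing T-peak collapses the T fiducials onto
#' the S-offset, a missing T-onset maps onto the S-offset and a missing
#' T-offset onto the T-peak. Every mapped name is recorded.
#'
#' @param beat Named list of fiducials; P/T entries may be `NULL` or `NA`.
#'   Must contain `q_onset` and `s_offset`.
#' @return The beat with all 11 fiducials populated and a character vector
#'   `mapped` naming the substituted ones. The fiducial ordering invariant
#'   holds afterwards.
#' @export
map_missing_fps <- function(beat) {
  missing_fp <- function(v) is.null(v) || (length(v) == 1 && is.na(v))
  mapped <- character(0)
  if (missing_fp(beat$p_peak)) {
    beat$p_onset <- beat$p_peak <- beat$p_offset <- beat$q_onset
    mapped <- c(mapped, "p_onset", "p_peak", "p_offset")
  } else {
    if (missing_fp(beat$p_onset)) {
      beat$p_onset <- beat$p_peak
      mapped <- c(mapped, "p_onset")
    }
    if (missing_fp(beat$p_offset)) {
      beat$p_offset <- beat$q_onset
      mapped <- c(mapped, "p_offset")
    }
  }
  if (missing_fp(beat$t_peak)) {
    beat$t_onset <- beat$t_peak <- beat$t_offset <- beat$s_offset
    mapped <- c(mapped, "t_onset", "t_peak", "t_offset")
  } else {
    if (missing_fp(beat$t_onset)) {
      beat$t_onset <- beat$s_offset
      mapped <- c(mapped, "t_onset")
    }
    if (missing_fp(beat$t_offset)) {
      beat$t_offset <- beat$t_peak
      mapped <- c(mapped, "t_offset")
    }
  }
  beat$mapped <- unique(c(beat$mapped, mapped))
  beat
}
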