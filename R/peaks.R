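#' Score deviations of observed counts from the fitted background
#'
#' For every (pair, direction, separation) in the scan range, compares the
#' observed first-passage count with the background expectation
#' `exp(intercept - lambda * L)` and reports the log-amplitude
#' `q = ln(observed / expected)` — the logarithm of a signal-to-noise
#' ratio — and the z-score `q / resid_sd`. Separations below the fit window
#' are scored against the extrapolated fitted line. `q` is invariant under
#' rescaling all counts by a constant, so raw counts and normalized
#' probabilities give the same amplitudes.
#'
#' Bins with zero observed count have no defined `q`; they are returned with
#' `defined = FALSE` and are never significant-over (under-representation
#' calls require a positive observed count).
#'
#' @param fp First-passage counts from [count_all_pairs()].
#' @param fits Background fits from [fit_backgrounds()]; invalid fits are
#'   skipped.
#' @param l_scan Integer range `c(l_lo, l_hi)` of separations to score.
#' @param z_thresh Significance threshold on `|z|` (the classic rule is 3
#'   standard deviations from the background).
#' @param sd_mode `"resid"` uses the fit's residual SD of log-counts as the
#'   noise scale (default); `"poisson"` uses the Poisson-approximate SD of a
#'   log-count, `1 / sqrt(observed)`.
#' @return A tibble with one row per scored bin: `x`, `y`, `direction`, `L`,
#'   `observed`, `expected`, `q`, `z`, `defined`, `significant`,
#'   `sign` (`"over"`/`"under"`).
#' @export
score_deviations <- function(fp, fits, l_scan = c(1L, 49L), z_thresh = 3,
                             sd_mode = c("resid", "poisson")) {
  sd_mode <- match.arg(sd_mode)
  stopifnot(length(l_scan) == 2L, l_scan[1] >= 1L, l_scan[2] <= 63L,
            l_scan[1] <= l_scan[2])
  ok <- dplyr::filter(fits, .data$valid, !is.na(.data$resid_sd))
  l_grid <- seq.int(l_scan[1], l_scan[2])
  n_l <- length(l_grid)
  g <- rep(fp_group_key(ok$x, ok$y, ok$direction), each = n_l)
  L <- rep.int(l_grid, nrow(ok))
  lambda <- rep(ok$lambda, each = n_l)
  intercept <- rep(ok$intercept, each = n_l)
  resid_sd <- rep(ok$resid_sd, each = n_l)
  # match observed counts by (pair, direction, L) key; L_scan capped at 63
  # so the key g * 64 + L is injective
  in_scan <- fp$L >= l_scan[1] & fp$L <= l_scan[2]
  obs_key <- fp_group_key(fp$x[in_scan], fp$y[in_scan],
                          fp$direction[in_scan]) * 64L + fp$L[in_scan]
  hit <- match(g * 64L + L, obs_key)
  observed <- fp$count[in_scan][hit]
  observed[is.na(observed)] <- 0L
  expected <- exp(intercept - lambda * L)
  defined <- observed > 0L
  q <- ifelse(defined, log(observed / expected), NA_real_)
  noise_sd <- if (sd_mode == "resid") resid_sd else 1 / sqrt(pmax(observed, 1L))
  z <- ifelse(noise_sd > 0, q / noise_sd, NA_real_)
  dec <- fp_group_decode(g)
  tibble::tibble(
    x = dec$x, y = dec$y, direction = dec$direction, L = L,
    observed = observed, expected = expected, q = q, z = z,
    defined = defined,
    significant = defined & !is.na(z) & abs(z) >= z_thresh,
    sign = ifelse(is.na(q), NA_character_, ifelse(q > 0, "over", "under"))
  )
}

#' Score a single (pair, separation) deviation
#'
#' @param table First-passage counts for one pair (e.g. from
#'   [count_first_passages()]).
#' @param fit One-row fit tibble for that pair.
#' @param L Separation to score.
#' @inheritParams score_deviations
#' @return A one-row tibble; see [score_deviations()].
#' @export
score_deviation <- function(table, fit, L, z_thresh = 3,
                            sd_mode = c("resid", "poisson")) {
  score_deviations(table, fit, l_scan = c(L, L), z_thresh = z_thresh,
                   sd_mode = sd_mode)
}

#' Call significant first-passage peaks for one organism
#'
#' Scores every (pair, direction, separation) in the scan range against the
#' fitted exponential background and returns the significant calls, sorted
#' by decreasing `|z|`. Pairs whose background fit failed are skipped (and
#' reported in the `skipped` attribute).
#'
#' @inheritParams score_deviations
#' @return Significant peak calls (rows of [score_deviations()] output with
#'   `significant == TRUE`), sorted by `|z|` descending, with the skipped
#'   pairs as an attribute.
#' @export
call_peaks <- function(fp, fits, l_scan = c(1L, 49L), z_thresh = 3,
                       sd_mode = c("resid", "poisson")) {
  scored <- score_deviations(fp, fits, l_scan = l_scan, z_thresh = z_thresh,
                             sd_mode = sd_mode)
  peaks <- scored |>
    dplyr::filter(.data$significant) |>
    dplyr::arrange(dplyr::desc(abs(.data$z)))
  # skipped = every (pair, direction) in the scanned directions without a
  # valid fit, including pairs that produced no counts at all
  dirs <- unique(c(fp$direction, fits$direction))
  full <- tidyr::expand_grid(x = AA20, y = AA20, direction = dirs)
  attr(peaks, "skipped") <- dplyr::anti_join(
    full,
    dplyr::filter(fits, .data$valid)[, c("x", "y", "direction")],
    by = c("x", "y", "direction"))
  peaks
}
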