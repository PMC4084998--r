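# Closed-form OLS of log(count) on L per (x, y, direction) group, computed
# with rowsum() on an integer group key; lm() (or even grouped dplyr) per
# pair would dominate the pipeline at 400 pairs x directions x organisms.
ols_groups <- function(g, L, lc) {
  if (length(g) == 0L) {
    return(list(g = integer(), n = integer(), slope = double(),
                intercept = double(), resid_sd = double(), r = double(),
                valid = logical()))
  }
  m <- rowsum(cbind(1, L, lc, L * L, L * lc, lc * lc), g)
  n <- m[, 1L]
  sxx <- m[, 4L] - m[, 2L]^2 / n
  sxy <- m[, 5L] - m[, 2L] * m[, 3L] / n
  syy <- m[, 6L] - m[, 3L]^2 / n
  valid <- n >= 3 & sxx > 0
  slope <- ifelse(valid, sxy / sxx, NA_real_)
  intercept <- (m[, 3L] - slope * m[, 2L]) / n
  sse <- pmax(syy - slope * sxy, 0)
  resid_sd <- sqrt(sse / pmax(n - 2, 1))
  r <- ifelse(valid & syy > 0, sxy / sqrt(sxx * syy), NA_real_)
  list(g = as.integer(rownames(m)), n = as.integer(n), slope = slope,
       intercept = intercept, resid_sd = resid_sd, r = r, valid = valid)
}

# group key <-> (x, y, direction); key = ((xi-1)*20 + (yi-1))*2 + di
fp_group_key <- function(x, y, direction) {
  ((match(x, AA20) - 1L) * 20L + (match(y, AA20) - 1L)) * 2L +
    match(direction, c("C", "N"))
}

fp_group_decode <- function(g) {
  di <- (g - 1L) %% 2L + 1L
  rest <- (g - di) %/% 2L
  list(x = AA20[rest %/% 20L + 1L],
       y = AA20[rest %% 20L + 1L],
       direction = c("C", "N")[di])
}

finish_fit <- function(o, l_min, l_max, clip_sigma) {
  dec <- fp_group_decode(o$g)
  r2 <- pmin(o$r^2, 1)
  tstat <- abs(o$r) * sqrt(pmax(o$n - 2L, 0L) / pmax(1 - r2, 1e-300))
  p_lin <- ifelse(is.na(o$r), NA_real_,
                  ifelse(r2 >= 1, 0, 2 * stats::pt(-tstat, o$n - 2L)))
  tibble::tibble(
    x = dec$x, y = dec$y, direction = dec$direction,
    lambda = -o$slope,
    intercept = o$intercept,
    resid_sd = o$resid_sd,
    n_points = o$n,
    r = o$r,
    p_linearity = p_lin,
    l_min = l_min, l_max = l_max,
    clip_sigma = clip_sigma,
    valid = o$valid
  )
}

#' Fit the exponential background to first-passage distributions
#'
#' For every (anchor, target, direction) series, fits ordinary least squares
#' of `ln(count)` on `L` over bins with nonzero counts inside the fit window,
#' then applies one sigma-clipping pass (bins with absolute residual above
#' `clip_sigma` times the residual SD are removed, protecting the background
#' slope from genuine peaks) and refits. The decay constant is
#' `lambda = -slope`. Fitting raw log-counts rather than normalized
#' probabilities only shifts the intercept, never `lambda` or the residuals.
#'
#' The window defaults to separations 2 through 49: the exponential regime
#' sets in after a couple of residues, and larger separations are noisy
#' because genes are finite.
#'
#' @param fp First-passage counts from [count_all_pairs()] (columns `x`,
#'   `y`, `direction`, `L`, `count`).
#' @param l_min,l_max Inclusive fit window in residue separations
#'   (`l_min >= 1`, `l_max <= 49`).
#' @param clip_sigma Residual threshold, in units of the residual SD, for the
#'   single clipping pass.
#' @return A tibble with one row per (x, y, direction): `lambda` (decay per
#'   residue), `intercept` (log-count at L = 0), `resid_sd` (SD of log-count
#'   residuals on retained bins, n - 2 denominator), `n_points` (retained
#'   bins), `r` and `p_linearity` (Pearson correlation of log-count with L
#'   and its two-sided t-test p-value), the window, and `valid` (FALSE when
#'   fewer than 3 usable bins; such pairs are skipped downstream rather than
#'   raising an error).
#' @export
fit_backgrounds <- function(fp, l_min = 2L, l_max = 49L, clip_sigma = 3) {
  stopifnot(l_min >= 1L, l_max <= 49L, l_min < l_max, clip_sigma > 0)
  sel <- fp$L >= l_min & fp$L <= l_max & fp$count > 0
  L <- as.numeric(fp$L[sel])
  lc <- log(as.numeric(fp$count[sel]))
  g <- fp_group_key(fp$x[sel], fp$y[sel], fp$direction[sel])
  p1 <- ols_groups(g, L, lc)
  gi <- match(g, p1$g)
  pred <- p1$intercept[gi] + p1$slope[gi] * L
  keep <- p1$valid[gi] &
    abs(lc - pred) <= clip_sigma * p1$resid_sd[gi] + 1e-12
  keep[is.na(keep)] <- FALSE
  p2 <- ols_groups(g[keep], L[keep], lc[keep])
  # pairs invalid already in pass 1 are reported from pass 1 (still invalid)
  only1 <- !(p1$g %in% p2$g)
  o1 <- lapply(p1, `[`, only1)
  out <- dplyr::bind_rows(finish_fit(p2, l_min, l_max, clip_sigma),
                          finish_fit(o1, l_min, l_max, clip_sigma))
  dplyr::arrange(out, .data$x, .data$y, .data$direction)
}

#' Fit the exponential background for a single series
#'
#' Convenience wrapper around [fit_backgrounds()] for one first-passage
#' series (e.g. the output of [count_first_passages()], or any tibble with
#' `L` and `count` columns).
#'
#' @param counts A tibble with columns `L` and `count` (and optionally `x`,
#'   `y`, `direction`).
#' @inheritParams fit_backgrounds
#' @return A one-row fit tibble; see [fit_backgrounds()].
#' @export
#' @examples
#' exact <- tibble::tibble(L = 1:40, count = round(1e9 * 0.5^(1:40)))
#' fit_background(exact)$lambda # ~ log(2)
fit_background <- function(counts, l_min = 2L, l_max = 49L, clip_sigma = 3) {
  if (!all(c("x", "y", "direction") %in% names(counts))) {
    counts <- dplyr::mutate(counts, x = "A", y = "A", direction = "C")
  }
  fit_backgrounds(counts, l_min = l_min, l_max = l_max, clip_sigma = clip_sigma)
}

#' Amino-acid frequency table of a proteome
#'
#' @param chains Character vector of chains or a data frame with a
#'   `sequence` column.
#' @return A tibble with one row per amino acid in [aa_alphabet()]:
#'   `aa`, `count`, `freq` (frequencies sum to 1).
#' @export
#' @examples
#' frequency_table("AAC")
frequency_table <- function(chains) {
  chains <- as_chains(chains)
  code <- aa_encode(unlist(strsplit(chains, "", fixed = TRUE), use.names = FALSE))
  counts <- tabulate(code, nbins = 20L)
  tibble::tibble(aa = AA20, count = counts, freq = counts / sum(counts))
}

#' Geometric decay constant implied by a residue frequency
#'
#' If residues were independent, the first passage to an amino acid with
#' frequency `f` would be geometric with decay constant `-ln(1 - f)` per
#' residue.
#'
#' @param f Frequency (or vector of frequencies) strictly inside (0, 1).
#' @return `-log(1 - f)`.
#' @export
#' @examples
#' lambda_geometric(0.5) # log(2)
lambda_geometric <- function(f) {
  if (any(!is.finite(f) | f <= 0 | f >= 1)) {
    stop("frequencies must lie strictly inside (0, 1)", call. = FALSE)
  }
  -log(1 - f)
}

#' Compare fitted decay constants with the geometric (iid) null
#'
#' Joins each background fit with the genome-wide frequency of its target
#' amino acid and reports the decay constant `-ln(1 - f_y)` a fully
#' independent sequence would give, the corresponding decay length, and the
#' ratio `lam_geo / lambda`. A ratio near 1 indicates the target amino acid
#' is essentially uncorrelated with its surroundings; above 1 the observed
#' distribution decays more slowly than independence predicts.
#'
#' @param fits Fit tibble from [fit_backgrounds()].
#' @param freqs Frequency tibble from [frequency_table()] (columns `aa`,
#'   `freq`).
#' @return `fits` with added columns `f_y`, `lam_geo`, `decay_length_geo`
#'   and `ratio` (`NA` where the fitted `lambda` is not positive or `f_y`
#'   is degenerate).
#' @export
geometric_null <- function(fits, freqs) {
  fr <- dplyr::select(freqs, y = "aa", f_y = "freq")
  fits |>
    dplyr::left_join(fr, by = "y") |>
    dplyr::mutate(
      lam_geo = dplyr::if_else(.data$f_y > 0 & .data$f_y < 1,
                               -log(1 - .data$f_y), NA_real_),
      decay_length_geo = 1 / .data$lam_geo,
      ratio = dplyr::if_else(!is.na(.data$lambda) & .data$lambda > 0,
                             .data$lam_geo / .data$lambda, NA_real_)
    )
}

#' Mean first-passage length from a background fit
#'
#' The fitted background is the exponential `exp(intercept - lambda * L)`
#' on integer separations, i.e. a geometric law with per-step success
#' probability `p = 1 - exp(-lambda)`; its mean is `1 / p`, in residues.
#' The discrete form is used, not the continuous `1 / lambda`, because
#' separations are integer-valued.
#'
#' @param fits Fit tibble from [fit_backgrounds()] (or [geometric_null()]).
#' @return `fits` with an added `mean_L` column (`NA` where `lambda <= 0`).
#' @export
#' @examples
#' mean_first_passage(tibble::tibble(lambda = log(2)))$mean_L # 2
mean_first_passage <- function(fits) {
  dplyr::mutate(fits, mean_L = dplyr::if_else(
    !is.na(.data$lambda) & .data$lambda > 0,
    1 / (1 - exp(-.data$lambda)), NA_real_))
}
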