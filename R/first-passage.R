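# Core single-pass scan. Chains are concatenated into one coded vector with a
# per-position chain id; for each target amino acid y the next occurrence
# after every position is located with one findInterval() over the whole
# proteome, and passages that would cross a chain boundary are censored.
# Total work is O(total residues x targets), independent of chain count.
fp_scan_engine <- function(code, chain_id, max_l, y_codes) {
  n <- length(code)
  pos <- seq_len(n)
  n_anchors_x <- tabulate(code, nbins = 20L)

  res <- vector("list", length(y_codes))
  censored <- matrix(0L, nrow = 20L, ncol = length(y_codes))
  for (j in seq_along(y_codes)) {
    yc <- y_codes[j]
    py <- which(code == yc)
    if (length(py) == 0L) {
      censored[, j] <- n_anchors_x
      res[j] <- list(NULL)
      next
    }
    k <- findInterval(pos, py) + 1L
    has <- k <= length(py)
    nxt <- py[k[has]]
    anchor <- which(has)
    same_chain <- chain_id[nxt] == chain_id[anchor]
    anchor <- anchor[same_chain]
    lag <- nxt[same_chain] - anchor
    acode <- code[anchor]
    key <- (acode - 1L) * max_l + lag
    tab <- tabulate(key, nbins = 20L * max_l)
    nz <- which(tab > 0L)
    censored[, j] <- n_anchors_x - tabulate(acode, nbins = 20L)
    res[[j]] <- list(
      xcode = (nz - 1L) %/% max_l + 1L,
      L = (nz - 1L) %% max_l + 1L,
      count = tab[nz]
    )
  }
  list(res = res, censored = censored, n_anchors_x = n_anchors_x)
}

fp_encode_chains <- function(chains) {
  lens <- nchar(chains)
  code <- aa_encode(unlist(strsplit(chains, "", fixed = TRUE),
                           use.names = FALSE))
  list(code = code,
       chain_id = rep.int(seq_along(chains), lens),
       max_l = max(lens))
}

fp_assemble <- function(scan, direction, y_codes) {
  parts <- vector("list", length(y_codes))
  for (j in seq_along(y_codes)) {
    r <- scan$res[[j]]
    if (is.null(r)) next
    parts[[j]] <- tibble::tibble(
      x = AA20[r$xcode],
      y = AA20[y_codes[j]],
      direction = direction,
      L = r$L,
      count = r$count,
      n_anchors = scan$n_anchors_x[r$xcode],
      n_censored = scan$censored[cbind(r$xcode, j)]
    )
  }
  counts <- dplyr::bind_rows(parts)
  if (nrow(counts) == 0L) {
    counts <- tibble::tibble(x = character(), y = character(),
                             direction = character(), L = integer(),
                             count = integer(), n_anchors = integer(),
                             n_censored = integer())
  }
  dplyr::arrange(counts, .data$x, .data$y, .data$L)
}

fp_scan_direction <- function(chains, direction, y_codes) {
  direction <- check_direction(direction)
  enc <- fp_encode_chains(chains)
  if (direction == "N") {
    # N-terminal scan == C-terminal scan on reversed chains; reversing the
    # whole concatenation reverses every chain while keeping ids intact.
    enc$code <- rev(enc$code)
    enc$chain_id <- rev(enc$chain_id)
  }
  fp_scan_engine(enc$code, enc$chain_id, enc$max_l, y_codes)
}

#' Count first-passage events for one amino-acid pair
#'
#' For each occurrence of `x` (the anchor) in each chain, records the
#' separation `L` (in residues; adjacent residues have `L = 1`) to the first
#' occurrence of `y` in the chosen scan direction within the same chain.
#' Anchors with no `y` before the chain end are censored, not dropped, so
#' per-anchor probabilities can be formed. Intervening non-`y` residues never
#' block a passage, and for `x == y` the anchor itself does not count as the
#' target. Passages never cross protein boundaries.
#'
#' @param chains Character vector of normalized chains (20-letter alphabet
#'   only; see [normalize_chains()]), or a data frame with a `sequence`
#'   column.
#' @param x,y Single one-letter amino-acid codes (anchor and target).
#' @param direction `"C"` to scan toward the carboxyl terminus (increasing
#'   index) or `"N"` toward the amino terminus (decreasing index).
#' @return A tibble with columns `x`, `y`, `direction`, `L`, `count`,
#'   `n_anchors`, `n_censored`, one row per observed separation. The total
#'   of `count` plus `n_censored` equals `n_anchors`. `n_anchors` and
#'   `n_censored` are also attached as attributes for the zero-row case.
#' @export
#' @examples
#' count_first_passages("ACACA", "A", "C", "C")
count_first_passages <- function(chains, x, y, direction = "C") {
  chains <- as_chains(chains)
  check_aa(x); check_aa(y)
  y_code <- match(y, AA20)
  scan <- fp_scan_direction(chains, direction, y_code)
  tab <- fp_assemble(scan, direction, y_code) |>
    dplyr::filter(.data$x == !!x)
  x_code <- match(x, AA20)
  attr(tab, "n_anchors") <- scan$n_anchors_x[x_code]
  attr(tab, "n_censored") <- scan$censored[x_code, 1L]
  tab
}

#' Count first-passage events for all 400 ordered pairs
#'
#' Computes the full first-passage table for every ordered amino-acid pair
#' in one pass per direction over the proteome (a per-position
#' next-occurrence scan), rather than 400 independent scans.
#'
#' @inheritParams count_first_passages
#' @param direction Character vector of directions to scan, any subset of
#'   `c("C", "N")`.
#' @return A tibble with columns `x`, `y`, `direction`, `L`, `count`,
#'   `n_anchors`, `n_censored`; one row per (pair, direction, separation)
#'   with a nonzero count. Pairs whose anchor is absent simply contribute no
#'   rows (their `n_anchors` is 0).
#' @export
#' @examples
#' fp <- count_all_pairs(c("MKVLAK", "ACDEAC"), direction = "C")
#' dplyr::filter(fp, x == "A", y == "C")
count_all_pairs <- function(chains, direction = c("C", "N")) {
  chains <- as_chains(chains)
  direction <- unique(match.arg(direction, c("C", "N"), several.ok = TRUE))
  y_codes <- seq_len(20L)
  out <- purrr::map(direction, function(d) {
    fp_assemble(fp_scan_direction(chains, d, y_codes), d, y_codes)
  })
  dplyr::bind_rows(out)
}

#' Per-anchor first-passage probabilities
#'
#' Divides first-passage counts by the number of anchors scanned, giving the
#' empirical probability that the first `y` lies exactly `L` residues from an
#' `x`. For independent residues this converges to the geometric law
#' `f_y * (1 - f_y)^(L - 1)`.
#'
#' @param fp A first-passage tibble from [count_all_pairs()] or
#'   [count_first_passages()].
#' @return The input with an added `prob` column (`count / n_anchors`).
#' @export
fp_probabilities <- function(fp) {
  dplyr::mutate(fp, prob = .data$count / .data$n_anchors)
}
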