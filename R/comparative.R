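#' Summarize peaks across a study set of organisms
#'
#' Counts, for every (pair, direction, separation, sign), the number of
#' organisms in which the peak is significant, retains combinations seen in
#' at least `min_genomes` organisms, and reports the mean log-amplitude
#' `q_bar`. Within each (pair, direction, sign) the modal separation — the
#' one significant in most organisms, ties broken toward smaller `L` — is
#' flagged, matching the convention of reporting a single `L` per pair.
#'
#' @param scores Combined [score_deviations()] output across organisms, with
#'   an `organism_id` column.
#' @param min_genomes Minimum number of organisms with a significant call
#'   for a (pair, L) to be retained.
#' @param qbar_scope `"all"` averages `q` over every organism where `q` is
#'   defined at that (pair, L); `"significant"` averages only over organisms
#'   where the call is significant.
#' @return A tibble with columns `x`, `y`, `direction`, `sign`, `L`,
#'   `n_genomes`, `q_bar`, `is_modal`, sorted by `|q_bar|` within sign.
#' @export
summarize_pairs <- function(scores, min_genomes = 25L,
                            qbar_scope = c("all", "significant")) {
  qbar_scope <- match.arg(qbar_scope)
  if (!"organism_id" %in% names(scores)) {
    stop("`scores` must have an `organism_id` column", call. = FALSE)
  }
  sig <- scores |>
    dplyr::filter(.data$significant) |>
    dplyr::count(.data$x, .data$y, .data$direction, .data$sign, .data$L,
                 name = "n_genomes") |>
    dplyr::filter(.data$n_genomes >= min_genomes)
  if (nrow(sig) == 0L) {
    return(tibble::tibble(x = character(), y = character(),
                          direction = character(), sign = character(),
                          L = integer(), n_genomes = integer(),
                          q_bar = double(), is_modal = logical()))
  }
  qsrc <- if (qbar_scope == "significant") {
    dplyr::filter(scores, .data$significant)
  } else {
    dplyr::filter(scores, .data$defined)
  }
  qbar <- qsrc |>
    dplyr::semi_join(sig, by = c("x", "y", "direction", "L")) |>
    dplyr::group_by(.data$x, .data$y, .data$direction, .data$L) |>
    dplyr::summarise(q_bar = mean(.data$q, na.rm = TRUE), .groups = "drop")
  sig |>
    dplyr::left_join(qbar, by = c("x", "y", "direction", "L")) |>
    dplyr::group_by(.data$x, .data$y, .data$direction, .data$sign) |>
    dplyr::arrange(dplyr::desc(.data$n_genomes), .data$L, .by_group = TRUE) |>
    dplyr::mutate(is_modal = dplyr::row_number() == 1L) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$sign, dplyr::desc(abs(.data$q_bar)))
}

#' Pearson correlation with a Student-t p-value
#'
#' Sample Pearson correlation with the classic two-sided p-value from
#' `t = r * sqrt((n - 2) / (1 - r^2))` against Student's t with `n - 2`
#' degrees of freedom.
#'
#' @param a,b Numeric vectors of equal length (`n >= 3`); pairs with a
#'   missing value are dropped.
#' @return A one-row tibble: `statistic` (`"pearson_r"`), `value`,
#'   `p_value`, `n`, `method_p` (`"t_transform"`). `value` is `NA` (with
#'   `p_value` `NA`) when either vector has zero variance or fewer than 3
#'   complete pairs remain.
#' @export
#' @examples
#' pearson_with_p(1:10, 2 * (1:10) + 1)
pearson_with_p <- function(a, b) {
  stopifnot(length(a) == length(b))
  keep <- stats::complete.cases(a, b)
  a <- as.numeric(a[keep]); b <- as.numeric(b[keep])
  n <- length(a)
  out <- tibble::tibble(statistic = "pearson_r", value = NA_real_,
                        p_value = NA_real_, n = n, method_p = "t_transform")
  if (n < 3L || stats::sd(a) == 0 || stats::sd(b) == 0) return(out)
  r <- stats::cor(a, b)
  r2 <- min(r^2, 1)
  p <- if (r2 >= 1) 0 else 2 * stats::pt(-abs(r) * sqrt((n - 2) / (1 - r2)), n - 2)
  out$value <- r
  out$p_value <- p
  out
}

# all permutations of 1..n as an n! x n matrix (n <= 8 in practice)
all_perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_perms(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  for (k in seq_len(n)) {
    rows <- (k - 1L) * nrow(sub) + seq_len(nrow(sub))
    out[rows, ] <- cbind(rep.int(k, nrow(sub)), sub + (sub >= k))
  }
  out
}

#' Spearman correlation with a permutation p-value
#'
#' Spearman's rho computed as the Pearson correlation of mid-ranks (average
#' ranks on ties), with a two-sided permutation p-value: the fraction of
#' permutations of one vector whose `|rho|` is at least the observed
#' `|rho|`. For `n <= 8` all `n!` permutations are enumerated and the
#' p-value is exact; otherwise `n_perm` random permutations are drawn under
#' the given seed and the add-one estimator
#' `(1 + #extreme) / (1 + n_perm)` is used.
#'
#' @inheritParams pearson_with_p
#' @param n_perm Number of random permutations when exact enumeration is not
#'   used.
#' @param seed Integer seed for the permutation draw (ignored when exact).
#' @return A one-row tibble: `statistic` (`"spearman_rho"`), `value`,
#'   `p_value`, `n`, `method_p` (`"exact"` or `"permutation"`).
#' @export
#' @examples
#' spearman_with_p(c(1, 2, 3), c(3, 2, 1))
spearman_with_p <- function(a, b, n_perm = 1e5, seed = 1L) {
  stopifnot(length(a) == length(b))
  keep <- stats::complete.cases(a, b)
  a <- as.numeric(a[keep]); b <- as.numeric(b[keep])
  n <- length(a)
  out <- tibble::tibble(statistic = "spearman_rho", value = NA_real_,
                        p_value = NA_real_, n = n, method_p = NA_character_)
  if (n < 3L || stats::sd(a) == 0 || stats::sd(b) == 0) return(out)
  ra <- rank(a, ties.method = "average")
  rb <- rank(b, ties.method = "average")
  rho <- stats::cor(ra, rb)
  ca <- ra - mean(ra)
  cb <- rb - mean(rb)
  denom <- sqrt(sum(ca^2) * sum(cb^2))
  if (n <= 8L) {
    perms <- all_perms(n)
    # cor(ra[perm], rb) = sum(ca[perm] * cb) / denom
    rho_star <- (matrix(ca[perms], nrow(perms)) %*% cb) / denom
    p <- mean(abs(rho_star) >= abs(rho) - 1e-12)
    method <- "exact"
  } else {
    set.seed(as.integer(seed))
    perm_mat <- vapply(seq_len(n_perm), function(i) ca[sample.int(n)],
                       numeric(n))
    rho_star <- as.vector(crossprod(perm_mat, cb)) / denom
    p <- (1 + sum(abs(rho_star) >= abs(rho) - 1e-12)) / (1 + n_perm)
    method <- "permutation"
  }
  out$value <- rho
  out$p_value <- p
  out$method_p <- method
  out
}

#' OGT dependence of peak amplitudes
#'
#' Correlates the per-organism log-amplitude `q` at a fixed (pair, L) with
#' optimal growth temperature across a study set, reporting both the Pearson
#' correlation (Student-t p-value) and the Spearman correlation
#' (permutation p-value).
#'
#' @param data A data frame with one row per organism.
#' @param q_col,ogt_col Names of the amplitude and OGT columns.
#' @inheritParams spearman_with_p
#' @return A two-row tibble (Pearson, Spearman) as in [pearson_with_p()] /
#'   [spearman_with_p()]; all-`NA` values when fewer than 3 organisms have a
#'   defined amplitude.
#' @export
ogt_dependence <- function(data, q_col = "q", ogt_col = "ogt_celsius",
                           n_perm = 1e5, seed = 1L) {
  q <- data[[q_col]]
  ogt <- data[[ogt_col]]
  dplyr::bind_rows(
    pearson_with_p(q, ogt),
    spearman_with_p(q, ogt, n_perm = n_perm, seed = seed)
  )
}

#' OGT dependence of mean first-passage lengths
#'
#' Spearman correlation (permutation p-value) between the mean first-passage
#' length toward a fixed target amino acid and OGT across organisms. A
#' target that becomes more abundant at high OGT is reached faster, giving a
#' negative correlation.
#'
#' @param data A data frame with one row per organism.
#' @param mean_col,ogt_col Names of the mean-length and OGT columns.
#' @inheritParams spearman_with_p
#' @return A one-row tibble as in [spearman_with_p()].
#' @export
mean_length_ogt <- function(data, mean_col = "mean_L", ogt_col = "ogt_celsius",
                            n_perm = 1e5, seed = 1L) {
  spearman_with_p(data[[mean_col]], data[[ogt_col]], n_perm = n_perm, seed = seed)
}

#' Kruskal-Wallis grouping of mean first-passage lengths
#'
#' Tests, within one organism, whether the 400 mean first-passage lengths
#' depend on the target amino acid (grouped by `y`) and, separately, on the
#' anchor (grouped by `x`). Under near-independence of residues the mean
#' length is set by the target's frequency alone, so grouping by target is
#' highly significant while grouping by anchor is not.
#'
#' @param mean_lengths A data frame with columns `x`, `y` and `mean_L`
#'   (e.g. from [mean_first_passage()]); rows with missing `mean_L` are
#'   dropped, and groups with fewer than 2 values are dropped from their
#'   test.
#' @return A tibble with one row per grouping (`"y"`, `"x"`): `statistic`
#'   (Kruskal-Wallis H), `df`, `p_value`, `n_groups`, `n`.
#' @export
kruskal_grouping <- function(mean_lengths) {
  d <- dplyr::filter(mean_lengths, is.finite(.data$mean_L))
  one <- function(group_col) {
    g <- d |>
      dplyr::group_by(.data[[group_col]]) |>
      dplyr::filter(dplyr::n() >= 2L) |>
      dplyr::ungroup()
    if (nrow(g) == 0L || dplyr::n_distinct(g[[group_col]]) < 2L) {
      return(tibble::tibble(grouping = group_col, statistic = NA_real_,
                            df = NA_real_, p_value = NA_real_,
                            n_groups = dplyr::n_distinct(g[[group_col]]),
                            n = nrow(g)))
    }
    if (stats::sd(g$mean_L) == 0) {
      # all values identical: no group effect by definition
      return(tibble::tibble(grouping = group_col, statistic = 0,
                            df = dplyr::n_distinct(g[[group_col]]) - 1,
                            p_value = 1,
                            n_groups = dplyr::n_distinct(g[[group_col]]),
                            n = nrow(g)))
    }
    kt <- stats::kruskal.test(g$mean_L, factor(g[[group_col]]))
    tibble::tibble(grouping = group_col,
                   statistic = unname(kt$statistic),
                   df = unname(kt$parameter),
                   p_value = kt$p.value,
                   n_groups = dplyr::n_distinct(g[[group_col]]),
                   n = nrow(g))
  }
  dplyr::bind_rows(one("y"), one("x"))
}

#' Bonferroni significance cutoff on the -ln(p) scale
#'
#' For a family of `n_tests` hypotheses at family-wise level `alpha`, a test
#' is significant when its `-ln(p)` exceeds `-ln(alpha / n_tests)`. With
#' `alpha = 0.05` and a study design of 76 organisms times 400 ordered
#' pairs (30400 tests) the cutoff is 13.318.
#'
#' @param alpha Family-wise error level in (0, 1).
#' @param n_tests Number of hypotheses (>= 1).
#' @return `-log(alpha / n_tests)` (natural log).
#' @export
#' @examples
#' bonferroni_cutoff(0.05, 30400)
bonferroni_cutoff <- function(alpha, n_tests) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha > 1) {
    stop("`alpha` must be a single value in (0, 1]", call. = FALSE)
  }
  if (!is.numeric(n_tests) || length(n_tests) != 1L || n_tests < 1) {
    stop("`n_tests` must be a single value >= 1", call. = FALSE)
  }
  -log(alpha / n_tests)
}
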