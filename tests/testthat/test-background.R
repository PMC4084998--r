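test_that("exact log-linear input recovers the generating decay exactly", {
  counts <- tibble::tibble(L = 1:40, count = 1000 * exp(-log(2) * (1:40)) * 1e6)
  fit <- fit_background(counts)
  expect_equal(fit$lambda, log(2), tolerance = 1e-9)
  expect_lt(fit$resid_sd, 1e-9)
  expect_equal(fit$r, -1, tolerance = 1e-9)
  expect_equal(fit$p_linearity, 0)
  expect_true(fit$valid)
})

test_that("flat input gives zero decay", {
  flat <- tibble::tibble(L = 1:40, count = rep(500, 40))
  fit <- fit_background(flat)
  expect_equal(fit$lambda, 0)
  expect_true(fit$valid)
})

test_that("fits fail gracefully below 3 usable bins", {
  fit <- fit_background(tibble::tibble(L = c(5L, 9L), count = c(10, 4)))
  expect_false(fit$valid)
  expect_true(is.na(fit$lambda))
})

test_that("sigma clipping removes a planted outlier bin from the fit", {
  set.seed(5)
  base <- exp(8 - 0.05 * (2:49)) * exp(rnorm(48, 0, 0.02))
  counts <- tibble::tibble(L = 2:49, count = base)
  counts$count[counts$L == 3] <- counts$count[counts$L == 3] * 20
  fit_clip <- fit_background(counts)
  fit_noclip <- fit_background(counts, clip_sigma = 1e6)
  expect_equal(fit_clip$n_points, 47L)
  expect_lt(abs(fit_clip$lambda - 0.05), 0.005)
  # without clipping the outlier drags the slope
  expect_gt(abs(fit_noclip$lambda - 0.05), abs(fit_clip$lambda - 0.05))
})

test_that("fit window bounds are honored and validated", {
  counts <- tibble::tibble(L = 1:60, count = exp(10 - 0.1 * (1:60)))
  fit <- fit_background(counts, l_min = 5, l_max = 30)
  expect_equal(fit$n_points, 26L)
  expect_error(fit_background(counts, l_min = 0), "l_min")
  expect_error(fit_background(counts, l_max = 50), "l_max")
})

test_that("frequency_table counts residues and sums to one", {
  ft <- frequency_table("AAC")
  expect_equal(ft$freq[ft$aa == "A"], 2 / 3)
  expect_equal(ft$freq[ft$aa == "C"], 1 / 3)
  expect_equal(sum(ft$freq), 1)
  set.seed(8)
  ft2 <- frequency_table(random_chains(20, 50, 200))
  expect_equal(sum(ft2$freq), 1)
  expect_true(all(abs(ft2$freq - 0.05) < 4 * sqrt(0.05 * 0.95 / sum(ft2$count))))
})

test_that("geometric null closed forms hold", {
  expect_equal(lambda_geometric(0.5), log(2))
  expect_error(lambda_geometric(0), "inside")
  expect_error(lambda_geometric(1), "inside")
  fits <- tibble::tibble(x = "A", y = "C", direction = "C",
                         lambda = log(2), valid = TRUE)
  freqs <- tibble::tibble(aa = "C", freq = 0.5)
  g <- geometric_null(fits, freqs)
  expect_equal(g$lam_geo, log(2))
  expect_equal(g$ratio, 1)
  expect_equal(g$decay_length_geo, 1 / log(2))
  # non-positive fitted decay flags the ratio undefined
  g2 <- geometric_null(dplyr::mutate(fits, lambda = -0.01), freqs)
  expect_true(is.na(g2$ratio))
})

test_that("mean first passage uses the discrete geometric closed form", {
  expect_equal(mean_first_passage(tibble::tibble(lambda = log(2)))$mean_L, 2)
  expect_lt(mean_first_passage(tibble::tibble(lambda = 10))$mean_L, 1.0001)
  expect_true(is.na(mean_first_passage(tibble::tibble(lambda = 0))$mean_L))
})

test_that("iid proteome recovers the geometric decay and unit ratio", {
  # moderate scale here; the full closed-form check runs at 1e6 residues in
  # the acceptance suite
  set.seed(21)
  sp <- synthetic_spec(n_proteins = 60,
                       length_distribution = list(type = "fixed", length = 5000),
                       seed = 210)
  pr <- generate_proteome(sp)
  fp <- count_all_pairs(pr$sequence, direction = "C")
  fits <- fit_backgrounds(fp)
  freqs <- frequency_table(pr$sequence)
  g <- geometric_null(fits, freqs)
  chk <- g |>
    dplyr::filter(f_y >= 0.04, valid) |>
    dplyr::group_by(y) |>
    dplyr::summarise(med_lambda = stats::median(lambda), f_y = f_y[1])
  expect_gt(nrow(chk), 5)
  expect_true(all(abs(chk$med_lambda / lambda_geometric(chk$f_y) - 1) < 0.1))

  # lambda depends on the target, not the anchor: spread across anchors for
  # a fixed target is small relative to spread across targets
  lam <- dplyr::filter(g, valid, f_y >= 0.02)
  by_y <- stats::kruskal.test(lam$lambda, factor(lam$y))
  by_x <- stats::kruskal.test(lam$lambda, factor(lam$x))
  expect_lt(by_y$p.value, 1e-10)
  expect_gt(by_x$p.value, 0.05)

  # log-linearity is extreme on iid data for abundant targets
  expect_gt(stats::median(-log(pmax(lam$p_linearity, 1e-300))),
            bonferroni_cutoff(0.05, 30400))
})

test_that("N and C fits agree on the same iid proteome", {
  set.seed(77)
  sp <- synthetic_spec(n_proteins = 40,
                       length_distribution = list(type = "fixed", length = 4000),
                       seed = 770)
  pr <- generate_proteome(sp)
  fp <- count_all_pairs(pr$sequence)
  fits <- geometric_null(fit_backgrounds(fp), frequency_table(pr$sequence))
  wide <- fits |>
    dplyr::filter(valid, f_y >= 0.04) |>
    dplyr::group_by(y, direction) |>
    dplyr::summarise(lam = stats::median(lambda), .groups = "drop") |>
    tidyr::pivot_wider(names_from = direction, values_from = lam)
  expect_true(all(abs(wide$N / wide$C - 1) < 0.05))
})
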