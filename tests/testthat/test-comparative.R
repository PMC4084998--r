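fake_scores <- function(n_org, x = "C", y = "C", L = 3L, q = 1.5,
                        significant = TRUE, direction = "N") {
  tibble::tibble(
    organism_id = sprintf("org%03d", seq_len(n_org)),
    x = x, y = y, direction = direction, L = L,
    observed = 100L, expected = 30, q = q, z = ifelse(significant, 5, 1),
    defined = TRUE, significant = significant,
    sign = ifelse(q > 0, "over", "under"))
}

test_that("summarize_pairs retains by genome count with a sharp threshold", {
  sc <- fake_scores(30)
  out <- summarize_pairs(sc, min_genomes = 25)
  expect_equal(nrow(out), 1L)
  expect_equal(out$n_genomes, 30L)
  expect_equal(out$q_bar, 1.5)
  expect_true(out$is_modal)
  expect_equal(nrow(summarize_pairs(sc, min_genomes = 31)), 0L)
})

test_that("summarize_pairs separates signs and picks the modal L", {
  over <- fake_scores(30, q = 1.2)
  under <- dplyr::mutate(fake_scores(28, q = -0.4), x = "G", y = "D", L = 2L)
  minor <- dplyr::mutate(fake_scores(26, q = 1.0), L = 5L)
  out <- summarize_pairs(dplyr::bind_rows(over, under, minor), min_genomes = 25)
  expect_setequal(out$sign, c("over", "under"))
  cc <- dplyr::filter(out, x == "C", sign == "over")
  expect_equal(nrow(cc), 2L)
  expect_equal(cc$L[cc$is_modal], 3L) # 30 genomes beats 26
  gd <- dplyr::filter(out, x == "G")
  expect_equal(gd$sign, "under")
  # ties in genome count break toward smaller L
  tie <- dplyr::bind_rows(fake_scores(26, L = 4L), fake_scores(26, L = 2L))
  out2 <- summarize_pairs(tie, min_genomes = 25)
  expect_equal(out2$L[out2$is_modal], 2L)
})

test_that("summarize_pairs is invariant to organism order and qbar_scope works", {
  sig <- fake_scores(26, q = 2)
  nonsig <- dplyr::mutate(fake_scores(10, q = 0.5, significant = FALSE),
                          organism_id = sprintf("extra%02d", 1:10))
  sc <- dplyr::bind_rows(sig, nonsig)
  shuffled <- sc[sample(nrow(sc)), ]
  expect_equal(summarize_pairs(sc), summarize_pairs(shuffled))
  all_scope <- summarize_pairs(sc, qbar_scope = "all")
  sig_scope <- summarize_pairs(sc, qbar_scope = "significant")
  expect_equal(all_scope$q_bar, (26 * 2 + 10 * 0.5) / 36)
  expect_equal(sig_scope$q_bar, 2)
})

test_that("pearson correlation and t-transform p-value are correct", {
  r <- pearson_with_p(1:10, 2 * (1:10) + 1)
  expect_equal(r$value, 1)
  expect_equal(r$p_value, 0)

  r2 <- pearson_with_p(c(1, 2, 3), c(1, 3, 2))
  expect_equal(r2$value, 0.5)

  # matches the classical test
  set.seed(12)
  a <- rnorm(25); b <- 0.3 * a + rnorm(25)
  ours <- pearson_with_p(a, b)
  ref <- stats::cor.test(a, b)
  expect_equal(ours$value, unname(ref$estimate))
  expect_equal(ours$p_value, ref$p.value, tolerance = 1e-12)

  expect_true(is.na(pearson_with_p(rep(1, 5), 1:5)$value))
})

test_that("pearson p-values are uniform under the null", {
  set.seed(22)
  ps <- replicate(200, pearson_with_p(rnorm(200), rnorm(200))$p_value)
  ks <- stats::ks.test(ps, "punif")
  expect_gt(ks$p.value, 0.01)
})

test_that("spearman handles monotone, reversed and tied inputs", {
  up <- spearman_with_p(1:10, exp(1:10), n_perm = 200, seed = 1)
  expect_equal(up$value, 1)
  down <- spearman_with_p(c(1, 2, 3), c(3, 2, 1))
  expect_equal(down$value, -1)
  expect_equal(down$method_p, "exact")
  # mid-ranks on ties agree with the classical estimator
  a <- c(1, 2, 2, 3, 5, 5, 7, 8, 9, 10)
  b <- c(2, 1, 4, 4, 4, 6, 8, 7, 10, 9)
  ours <- spearman_with_p(a, b, n_perm = 100, seed = 2)
  expect_equal(ours$value,
               unname(stats::cor.test(a, b, method = "spearman",
                                      exact = FALSE)$estimate))
})

test_that("permutation p converges to the exhaustive enumeration", {
  a <- c(0.3, 1.2, 0.7, 2.5, 1.9, 0.1)
  b <- c(10, 30, 25, 60, 55, 5)
  exact <- spearman_with_p(a, b) # n = 6 -> all 720 permutations
  expect_equal(exact$method_p, "exact")
  # independent enumeration oracle over all 720 permutations
  perms <- rbind(expand.grid(rep(list(1:6), 6)))
  perms <- as.matrix(perms[apply(perms, 1, function(p) length(unique(p)) == 6), ])
  ra <- rank(a); rb <- rank(b)
  rho_obs <- stats::cor(ra, rb)
  rho_star <- apply(perms, 1, function(p) stats::cor(ra[p], rb))
  expect_equal(nrow(perms), factorial(6))
  expect_equal(exact$p_value, mean(abs(rho_star) >= abs(rho_obs) - 1e-12))

  # sampling route at n = 9: two independent draws agree within Monte Carlo
  # error, and a fixed seed reproduces exactly
  a9 <- c(a, 4, 0.05, 1.4); b9 <- c(b, 70, 2, 40)
  big1 <- spearman_with_p(a9, b9, n_perm = 20000, seed = 3)
  big2 <- spearman_with_p(a9, b9, n_perm = 20000, seed = 4)
  expect_equal(big1$method_p, "permutation")
  expect_lt(abs(big1$p_value - big2$p_value),
            4 * sqrt(0.5 * 0.5 / 20000) + 1e-4)
  r1 <- spearman_with_p(a9, b9, n_perm = 500, seed = 9)
  set.seed(123) # an interfering global seed must not matter
  r2 <- spearman_with_p(a9, b9, n_perm = 500, seed = 9)
  expect_identical(r1, r2)
})

test_that("ogt_dependence recovers a planted monotone trend", {
  set.seed(91)
  ogt <- seq(5, 100, length.out = 40)
  q <- 0.02 * ogt + rnorm(40, 0, 0.15)
  res <- ogt_dependence(tibble::tibble(q = q, ogt_celsius = ogt),
                        n_perm = 2000, seed = 4)
  expect_gt(res$value[res$statistic == "pearson_r"], 0.9)
  expect_gt(res$value[res$statistic == "spearman_rho"], 0.9)
  expect_lt(res$p_value[res$statistic == "spearman_rho"], 0.01)
  # constant amplitude: no dependence
  null_res <- ogt_dependence(tibble::tibble(q = rnorm(40, 1, 0.1),
                                            ogt_celsius = ogt),
                             n_perm = 500, seed = 5)
  expect_lt(abs(null_res$value[1]), 0.5)
  # too few organisms: undefined
  tiny <- ogt_dependence(tibble::tibble(q = c(1, 2), ogt_celsius = c(10, 50)))
  expect_true(all(is.na(tiny$value)))
})

test_that("mean_length_ogt has the documented sign convention", {
  set.seed(14)
  ogt <- seq(5, 100, length.out = 30)
  # target more abundant at high OGT -> shorter mean passage -> negative rho
  mean_up <- 20 - 0.1 * ogt + rnorm(30, 0, 0.5)
  res <- mean_length_ogt(tibble::tibble(mean_L = mean_up, ogt_celsius = ogt),
                         n_perm = 500, seed = 6)
  expect_lt(res$value, -0.5)
  mean_down <- 10 + 0.1 * ogt + rnorm(30, 0, 0.5)
  res2 <- mean_length_ogt(tibble::tibble(mean_L = mean_down, ogt_celsius = ogt),
                          n_perm = 500, seed = 7)
  expect_gt(res2$value, 0.5)
})

test_that("kruskal grouping matches the hand formula and flags group effects", {
  # small printed integers, 3 groups: H against the textbook formula
  vals <- c(27, 2, 4, 18, 7, 9, 1, 5, 11, 12, 16, 15, 19, 3, 17)
  grp <- rep(c("a", "b", "c"), each = 5)
  kt <- stats::kruskal.test(vals, factor(grp))
  expect_equal(unname(kt$statistic), oracle_kruskal_h(vals, grp))

  # all values equal: no effect either way
  flat <- tidyr::expand_grid(x = aa_alphabet(), y = aa_alphabet())
  flat$mean_L <- 10
  res_flat <- kruskal_grouping(flat)
  expect_true(all(res_flat$p_value > 0.99))

  # values driven by the target amino acid only
  set.seed(33)
  eff <- tidyr::expand_grid(x = aa_alphabet(), y = aa_alphabet())
  g_y <- stats::setNames(seq(5, 43, by = 2), aa_alphabet())
  eff$mean_L <- g_y[eff$y] + rnorm(400, 0, 0.05)
  res <- kruskal_grouping(eff)
  expect_lt(res$p_value[res$grouping == "y"], 1e-10)
  expect_gt(res$p_value[res$grouping == "x"], 0.05)
})

test_that("bonferroni cutoff reproduces the study-design threshold", {
  expect_equal(round(bonferroni_cutoff(0.05, 30400), 3), 13.318)
  expect_equal(bonferroni_cutoff(0.05, 1), -log(0.05))
  expect_equal(bonferroni_cutoff(1, 1), 0)
  expect_error(bonferroni_cutoff(0, 10), "alpha")
  expect_error(bonferroni_cutoff(0.05, 0), "n_tests")
})
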