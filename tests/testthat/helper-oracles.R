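# Brute-force first-passage oracle: for one chain, walk every anchor and
# scan residue by residue until the target is found. Independent of the
# package's vectorized scan.
oracle_first_passage <- function(chain, x, y, direction = "C") {
  chars <- strsplit(chain, "", fixed = TRUE)[[1]]
  if (direction == "N") chars <- rev(chars)
  n <- length(chars)
  anchors <- which(chars == x)
  lags <- integer(0)
  censored <- 0L
  for (i in anchors) {
    if (i < n) {
      hit <- match(y, chars[(i + 1L):n])
      if (!is.na(hit)) lags <- c(lags, hit) else censored <- censored + 1L
    } else {
      censored <- censored + 1L
    }
  }
  list(lags = lags, n_anchors = length(anchors), n_censored = censored)
}

# Oracle over several chains, as a tidy counts table.
oracle_fp_table <- function(chains, x, y, direction = "C") {
  per <- lapply(chains, oracle_first_passage, x = x, y = y,
                direction = direction)
  lags <- unlist(lapply(per, `[[`, "lags"))
  counts <- table(lags)
  tibble::tibble(
    L = as.integer(names(counts)),
    count = as.integer(counts),
    n_anchors = sum(vapply(per, `[[`, integer(1), "n_anchors")),
    n_censored = sum(vapply(per, `[[`, integer(1), "n_censored"))
  )
}

# Brute-force planted-peak amplitude: the recounted first-passage count at
# the planted lag over its local geometric background, estimated as the
# geometric mean of the counts at the two flanking lags. Entirely
# independent of the package's counting and fitting code.
oracle_peak_q <- function(chains, x, y, lag, direction = "C") {
  o <- oracle_fp_table(chains, x, y, direction)
  c0 <- o$count[o$L == lag]
  c_lo <- o$count[o$L == lag - 1L]
  c_hi <- o$count[o$L == lag + 1L]
  log(c0 / sqrt(c_lo * c_hi))
}

random_chains <- function(n_chains, min_len = 5L, max_len = 200L,
                          alphabet = aa_alphabet(), prob = NULL) {
  lens <- sample(min_len:max_len, n_chains, replace = TRUE)
  vapply(lens, function(l) {
    paste(sample(alphabet, l, replace = TRUE, prob = prob), collapse = "")
  }, character(1))
}

# Kruskal-Wallis H by the textbook formula (no tie correction):
# H = 12 / (N (N + 1)) * sum_g n_g (rbar_g - (N + 1) / 2)^2
oracle_kruskal_h <- function(values, groups) {
  r <- rank(values)
  n <- length(values)
  h <- 0
  for (g in unique(groups)) {
    rg <- r[groups == g]
    h <- h + length(rg) * (mean(rg) - (n + 1) / 2)^2
  }
  12 / (n * (n + 1)) * h
}
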