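# Typical proteome amino-acid composition (fractions, renormalized on use);
# used as the default background for synthetic proteomes.
TYPICAL_AA_FREQS <- c(
  A = 0.0826, C = 0.0137, D = 0.0546, E = 0.0674, F = 0.0386,
  G = 0.0708, H = 0.0227, I = 0.0593, K = 0.0582, L = 0.0965,
  M = 0.0241, N = 0.0406, P = 0.0472, Q = 0.0393, R = 0.0553,
  S = 0.0660, T = 0.0535, W = 0.0110, Y = 0.0292, V = 0.0687
)

#' Default amino-acid composition for synthetic proteomes
#'
#' A typical proteome-wide amino-acid composition (fractions summing to 1),
#' used as the default `base_frequencies` of [synthetic_spec()].
#'
#' @return A named numeric vector over [aa_alphabet()].
#' @export
typical_aa_frequencies <- function() {
  f <- TYPICAL_AA_FREQS[AA20]
  f / sum(f)
}

#' Specification of a synthetic proteome
#'
#' Describes one organism's synthetic proteome: number of proteins, chain
#' length distribution, background amino-acid composition, a pseudo optimal
#' growth temperature, optional linear OGT trends on the composition, and
#' optional planted lag correlations.
#'
#' A planted effect `(x, y, lag, strength)` means: scanning each chain left
#' to right, every occurrence of `x` overwrites, with probability
#' `strength`, the residue `lag` positions downstream with `y` (when inside
#' the chain; later overwrites win). This localizes the correlation at
#' exactly that lag, giving a clean single-peak ground truth.
#'
#' Composition trends are anchored at a 37 degC mesophile reference: the
#' frequency of amino acid `a` becomes proportional to
#' `max(base_a + slope_a * (ogt - 37), 1e-6)`, renormalized.
#'
#' @param n_proteins Number of protein chains.
#' @param length_distribution Either `list(type = "fixed", length = L0)` or
#'   `list(type = "geometric", mean = m, min = lo)` (chain length is
#'   `lo` plus a geometric draw with mean `m - lo`).
#' @param base_frequencies Named 20-vector of positive frequencies
#'   (renormalized to sum to 1).
#' @param ogt Pseudo optimal growth temperature in degrees Celsius.
#' @param frequency_trend Optional named numeric vector of per-degC slopes
#'   for a subset of amino acids.
#' @param planted_effects Optional list of `list(x =, y =, lag =,
#'   strength =)` entries with `1 <= lag <= 49` and `0 <= strength <= 1`.
#' @param seed Integer seed; generation is deterministic given the spec.
#' @return An object of class `synthetic_spec`.
#' @export
#' @examples
#' spec <- synthetic_spec(n_proteins = 20, seed = 7,
#'                        planted_effects = list(list(x = "C", y = "C",
#'                                                    lag = 3, strength = 0.3)))
synthetic_spec <- function(n_proteins = 150L,
                           length_distribution = list(type = "geometric",
                                                      mean = 350, min = 30),
                           base_frequencies = typical_aa_frequencies(),
                           ogt = 37,
                           frequency_trend = NULL,
                           planted_effects = list(),
                           seed = 1L) {
  if (!is.numeric(n_proteins) || n_proteins < 1) {
    stop("invalid spec: `n_proteins` must be >= 1", call. = FALSE)
  }
  ld <- length_distribution
  if (!is.list(ld) || !ld$type %in% c("fixed", "geometric")) {
    stop('invalid spec: length_distribution$type must be "fixed" or "geometric"',
         call. = FALSE)
  }
  if (ld$type == "fixed" && (is.null(ld$length) || ld$length < 1)) {
    stop("invalid spec: fixed length_distribution needs `length` >= 1",
         call. = FALSE)
  }
  if (ld$type == "geometric" &&
      (is.null(ld$mean) || is.null(ld$min) || ld$mean <= ld$min || ld$min < 1)) {
    stop("invalid spec: geometric length_distribution needs mean > min >= 1",
         call. = FALSE)
  }
  f <- base_frequencies
  if (length(f) != 20L || is.null(names(f)) || !setequal(names(f), AA20) ||
      any(!is.finite(f) | f <= 0)) {
    stop("invalid spec: base_frequencies must be a positive named 20-vector",
         call. = FALSE)
  }
  f <- f[AA20] / sum(f[AA20])
  if (!is.null(frequency_trend)) {
    if (is.null(names(frequency_trend)) ||
        !all(names(frequency_trend) %in% AA20)) {
      stop("invalid spec: frequency_trend must be named by amino acid",
           call. = FALSE)
    }
  }
  for (e in planted_effects) {
    if (!all(c("x", "y", "lag", "strength") %in% names(e))) {
      stop("invalid spec: planted effect needs x, y, lag, strength",
           call. = FALSE)
    }
    check_aa(e$x, "planted x"); check_aa(e$y, "planted y")
    if (e$lag < 1 || e$lag > 49) {
      stop("invalid spec: planted lag must be in [1, 49]", call. = FALSE)
    }
    if (e$strength < 0 || e$strength > 1) {
      stop("invalid spec: planted strength must be in [0, 1]", call. = FALSE)
    }
  }
  structure(
    list(n_proteins = as.integer(n_proteins),
         length_distribution = ld,
         base_frequencies = f,
         ogt = ogt,
         frequency_trend = frequency_trend,
         planted_effects = planted_effects,
         seed = as.integer(seed)),
    class = "synthetic_spec"
  )
}

trend_adjust <- function(base, trend, ogt, ref = 37) {
  f <- base
  if (!is.null(trend) && length(trend) > 0L) {
    f[names(trend)] <- f[names(trend)] + trend * (ogt - ref)
    f <- pmax(f, 1e-6)
  }
  f / sum(f)
}

# Overwrite-based planting on one chain (character vector of residues).
# Anchors are processed left to right on the evolving chain: an overwrite
# that creates a new x downstream (y == x) adds an anchor; one that
# destroys an x removes it.
plant_effect <- function(chars, x, y, lag, strength) {
  if (strength <= 0) return(chars)
  n <- length(chars)
  anchors <- which(chars == x)
  i <- 1L
  while (i <= length(anchors)) {
    p <- anchors[i]
    if (chars[p] == x && stats::runif(1L) < strength) {
      tgt <- p + lag
      if (tgt <= n) {
        creates <- (y == x && chars[tgt] != x)
        chars[tgt] <- y
        if (creates) {
          anchors <- append(anchors, tgt, after = findInterval(tgt, anchors))
        }
      }
    }
    i <- i + 1L
  }
  chars
}

#' Generate a synthetic proteome
#'
#' Draws chains independently from the (trend-adjusted) composition of the
#' spec, then applies each planted lag effect chain by chain. Deterministic
#' under the spec's seed.
#'
#' @param spec A [synthetic_spec()].
#' @return A tibble with columns `id` and `sequence`.
#' @export
generate_proteome <- function(spec) {
  if (!inherits(spec, "synthetic_spec")) {
    stop("`spec` must be a synthetic_spec object", call. = FALSE)
  }
  set.seed(spec$seed)
  ld <- spec$length_distribution
  lens <- if (ld$type == "fixed") {
    rep.int(as.integer(ld$length), spec$n_proteins)
  } else {
    ld$min + stats::rgeom(spec$n_proteins, prob = 1 / (ld$mean - ld$min + 1))
  }
  freqs <- trend_adjust(spec$base_frequencies, spec$frequency_trend, spec$ogt)
  residues <- sample(AA20, sum(lens), replace = TRUE, prob = freqs)
  chain_idx <- rep.int(seq_along(lens), lens)
  chains <- split(residues, chain_idx)
  if (length(spec$planted_effects) > 0L) {
    chains <- lapply(chains, function(ch) {
      for (e in spec$planted_effects) {
        ch <- plant_effect(ch, e$x, e$y, e$lag, e$strength)
      }
      ch
    })
  }
  tibble::tibble(
    id = sprintf("prot%05d", seq_along(chains)),
    sequence = unname(vapply(chains, paste, character(1), collapse = ""))
  )
}

#' Generate a synthetic study set of organisms
#'
#' Builds `n_organisms` synthetic proteomes with pseudo-OGTs evenly spaced
#' across `ogt_range`, a shared composition with optional OGT trends, and
#' planted effects whose strength may depend on OGT (pass a function of
#' OGT). Optionally writes one FASTA per organism plus the metadata TSV
#' consumed by [read_metadata()].
#'
#' @param n_organisms Number of organisms (>= 2).
#' @param ogt_range Two-vector `c(lo, hi)` of pseudo-OGTs in degrees
#'   Celsius.
#' @param n_proteins,length_distribution,base_frequencies,frequency_trend
#'   Passed to [synthetic_spec()] for every organism.
#' @param planted_effects List of `list(x =, y =, lag =, strength =)`;
#'   `strength` may be a single number or a `function(ogt)`.
#' @param seed Integer master seed; per-organism seeds are drawn from it.
#' @param out_dir If non-`NULL`, directory (created if needed) where
#'   `<organism_id>.fasta` files and `metadata.tsv` are written.
#' @return A list with `metadata` (tibble: `organism_id`, `name`,
#'   `ogt_celsius`, `fasta_path`) and `proteomes` (named list of proteome
#'   tibbles).
#' @export
generate_study <- function(n_organisms = 40L,
                           ogt_range = c(5, 100),
                           n_proteins = 150L,
                           length_distribution = list(type = "geometric",
                                                      mean = 350, min = 30),
                           base_frequencies = typical_aa_frequencies(),
                           frequency_trend = NULL,
                           planted_effects = list(),
                           seed = 1L,
                           out_dir = NULL) {
  if (n_organisms < 2L) stop("`n_organisms` must be >= 2", call. = FALSE)
  set.seed(as.integer(seed))
  org_seeds <- sample.int(.Machine$integer.max - 1L, n_organisms)
  ogts <- seq(ogt_range[1], ogt_range[2], length.out = n_organisms)
  ids <- sprintf("org%03d", seq_len(n_organisms))

  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok || !dir.exists(out_dir)) {
      stop("cannot create output directory: ", out_dir, call. = FALSE)
    }
  }

  proteomes <- vector("list", n_organisms)
  names(proteomes) <- ids
  paths <- rep(NA_character_, n_organisms)
  for (i in seq_len(n_organisms)) {
    effects_i <- lapply(planted_effects, function(e) {
      if (is.function(e$strength)) e$strength <- e$strength(ogts[i])
      e$strength <- min(max(e$strength, 0), 1)
      e
    })
    spec_i <- synthetic_spec(
      n_proteins = n_proteins,
      length_distribution = length_distribution,
      base_frequencies = base_frequencies,
      ogt = ogts[i],
      frequency_trend = frequency_trend,
      planted_effects = effects_i,
      seed = org_seeds[i]
    )
    proteomes[[i]] <- generate_proteome(spec_i)
    if (!is.null(out_dir)) {
      paths[i] <- file.path(out_dir, paste0(ids[i], ".fasta"))
      write_fasta(proteomes[[i]], paths[i])
    }
  }
  metadata <- tibble::tibble(
    organism_id = ids,
    name = paste0("synthetic organism ", seq_len(n_organisms)),
    ogt_celsius = ogts,
    fasta_path = paths
  )
  if (!is.null(out_dir)) {
    write_metadata(metadata, file.path(out_dir, "metadata.tsv"))
  }
  list(metadata = metadata, proteomes = proteomes)
}
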