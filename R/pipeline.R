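#' Configuration for a first-passage scan
#'
#' Collects every tunable of the pipeline in one validated list.
#'
#' @param l_min,l_max Background fit window (residue separations, within
#'   \[1, 49\]).
#' @param clip_sigma Sigma-clipping threshold of the background fit.
#' @param z_thresh Peak significance threshold in background SDs.
#' @param min_genomes Minimum organisms sharing a significant (pair, L) for
#'   retention in the cross-organism summary.
#' @param directions Directions to scan, subset of `c("N", "C")`.
#' @param l_scan Range of separations scored for peaks.
#' @param policy Nonstandard-residue policy for [normalize_chains()].
#' @param n_perm Permutations for Spearman p-values.
#' @param seed Seed for permutation tests.
#' @param qbar_scope `"all"` or `"significant"`; see [summarize_pairs()].
#' @param sd_mode Noise scale for peak z-scores; see [score_deviations()].
#' @return A list of class `fp_config`.
#' @export
run_config <- function(l_min = 2L, l_max = 49L, clip_sigma = 3, z_thresh = 3,
                       min_genomes = 25L, directions = c("N", "C"),
                       l_scan = c(1L, 49L), policy = c("split", "drop_chain"),
                       n_perm = 1e5, seed = 1L,
                       qbar_scope = c("all", "significant"),
                       sd_mode = c("resid", "poisson")) {
  policy <- match.arg(policy)
  qbar_scope <- match.arg(qbar_scope)
  sd_mode <- match.arg(sd_mode)
  directions <- unique(match.arg(directions, c("N", "C"), several.ok = TRUE))
  stopifnot(l_min >= 1L, l_max <= 49L, l_min < l_max, clip_sigma > 0,
            z_thresh > 0, min_genomes >= 1L,
            length(l_scan) == 2L, l_scan[1] >= 1L, l_scan[1] <= l_scan[2],
            n_perm >= 1)
  structure(list(l_min = as.integer(l_min), l_max = as.integer(l_max),
                 clip_sigma = clip_sigma, z_thresh = z_thresh,
                 min_genomes = as.integer(min_genomes),
                 directions = directions,
                 l_scan = as.integer(l_scan), policy = policy,
                 n_perm = n_perm, seed = as.integer(seed),
                 qbar_scope = qbar_scope, sd_mode = sd_mode),
            class = "fp_config")
}

# Analyze one organism's chains: counts, fits (with geometric null and mean
# lengths), scored deviations.
analyze_organism <- function(chains, config) {
  fp <- count_all_pairs(chains, direction = config$directions)
  fits <- fit_backgrounds(fp, l_min = config$l_min, l_max = config$l_max,
                          clip_sigma = config$clip_sigma)
  freqs <- frequency_table(chains)
  fits <- mean_first_passage(geometric_null(fits, freqs))
  scores <- score_deviations(fp, fits, l_scan = config$l_scan,
                             z_thresh = config$z_thresh,
                             sd_mode = config$sd_mode)
  list(fp = fp, fits = fits, freqs = freqs, scores = scores,
       n_residues = sum(freqs$count))
}

#' Run the full first-passage pipeline over a study set
#'
#' For each organism: reads (or receives) the proteome, normalizes chains,
#' counts first passages for all 400 ordered pairs in the configured
#' directions, fits the exponential backgrounds, scores deviations and calls
#' peaks. Then aggregates across organisms: pairs significant in at least
#' `min_genomes` organisms are retained, and for each retained modal
#' (pair, L) the Pearson and Spearman correlations of the log-amplitude `q`
#' with OGT are computed.
#'
#' A failing organism (e.g. missing FASTA) is recorded in `failures` and the
#' run continues; the returned `status` is nonzero when any organism failed.
#'
#' @param metadata A metadata tibble (see [read_metadata()]) or the path to
#'   a metadata TSV.
#' @param out_dir If non-`NULL`, per-organism and summary TSVs plus a run
#'   log are written there.
#' @param config A [run_config()].
#' @param proteomes Optional named list (by `organism_id`) of in-memory
#'   proteomes (tibbles with a `sequence` column, e.g. from
#'   [generate_study()]); organisms present here are not read from disk.
#' @return An object of class `fp_scan_result`: a list with `metadata`,
#'   `config`, `fits`, `scores` (both with `organism_id`), `pair_summary`,
#'   `ogt_correlations`, `organism_stats`, `failures`, `status`.
#' @export
run_scan <- function(metadata, out_dir = NULL, config = run_config(),
                     proteomes = NULL) {
  if (is.character(metadata) && length(metadata) == 1L) {
    metadata <- read_metadata(metadata)
  }
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  log_lines <- c(
    paste0("fpscan run ", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
    paste0("R ", getRversion(), ", fpscan ",
           tryCatch(as.character(utils::packageVersion("fpscan")),
                    error = function(e) "dev")),
    paste0("config: ", paste(names(unclass(config)),
                             vapply(unclass(config), function(v)
                               paste(format(v), collapse = ","), character(1)),
                             sep = "=", collapse = " "))
  )

  fits_all <- list(); scores_all <- list()
  stats_rows <- list(); failures <- list()
  for (i in seq_len(nrow(metadata))) {
    oid <- metadata$organism_id[i]
    res <- tryCatch({
      chains <- if (!is.null(proteomes) && oid %in% names(proteomes)) {
        normalize_chains(proteomes[[oid]], policy = config$policy)
      } else {
        normalize_chains(read_fasta(metadata$fasta_path[i]),
                         policy = config$policy)
      }
      analyze_organism(chains$sequence, config)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures[[oid]] <- conditionMessage(res)
      log_lines <- c(log_lines,
                     paste0("FAIL ", oid, ": ", conditionMessage(res)))
      next
    }
    fits_all[[oid]] <- dplyr::mutate(res$fits, organism_id = oid,
                                     .before = 1L)
    scores_all[[oid]] <- dplyr::mutate(res$scores, organism_id = oid,
                                       .before = 1L)
    stats_rows[[oid]] <- tibble::tibble(
      organism_id = oid, n_chains = NA_integer_,
      n_residues = res$n_residues,
      n_valid_fits = sum(res$fits$valid),
      n_significant = sum(res$scores$significant)
    )
    log_lines <- c(log_lines, paste0("OK ", oid, ": ", res$n_residues,
                                     " residues, ", sum(res$scores$significant),
                                     " significant bins"))
    if (!is.null(out_dir)) {
      readr::write_tsv(dplyr::mutate(res$fp, organism_id = oid, .before = 1L),
                       file.path(out_dir, paste0(oid, "_first_passage.tsv")))
      readr::write_tsv(fits_all[[oid]],
                       file.path(out_dir, paste0(oid, "_background.tsv")))
      readr::write_tsv(dplyr::filter(scores_all[[oid]], .data$significant),
                       file.path(out_dir, paste0(oid, "_peaks.tsv")))
    }
  }

  fits <- dplyr::bind_rows(fits_all)
  scores <- dplyr::bind_rows(scores_all)
  pair_summary <- if (nrow(scores) > 0L) {
    summarize_pairs(scores, min_genomes = config$min_genomes,
                    qbar_scope = config$qbar_scope)
  } else {
    summarize_pairs(dplyr::mutate(scores, organism_id = character(0)),
                    min_genomes = config$min_genomes)
  }

  modal <- dplyr::filter(pair_summary, .data$is_modal)
  ogt_correlations <- purrr::pmap_dfr(
    dplyr::select(modal, "x", "y", "direction", "L"),
    function(x, y, direction, L) {
      d <- scores |>
        dplyr::filter(.data$x == !!x, .data$y == !!y,
                      .data$direction == !!direction, .data$L == !!L,
                      .data$defined) |>
        dplyr::inner_join(
          dplyr::select(metadata, "organism_id", "ogt_celsius"),
          by = "organism_id")
      cor_res <- ogt_dependence(d, n_perm = config$n_perm, seed = config$seed)
      tibble::tibble(
        x = x, y = y, direction = direction, L = L,
        n = cor_res$n[1],
        pearson_r = cor_res$value[cor_res$statistic == "pearson_r"],
        pearson_p = cor_res$p_value[cor_res$statistic == "pearson_r"],
        spearman_rho = cor_res$value[cor_res$statistic == "spearman_rho"],
        spearman_p = cor_res$p_value[cor_res$statistic == "spearman_rho"]
      )
    })
  if (nrow(modal) == 0L) {
    ogt_correlations <- tibble::tibble(
      x = character(), y = character(), direction = character(),
      L = integer(), n = integer(), pearson_r = double(),
      pearson_p = double(), spearman_rho = double(), spearman_p = double())
  }

  if (!is.null(out_dir)) {
    readr::write_tsv(pair_summary, file.path(out_dir, "pair_summary.tsv"))
    readr::write_tsv(ogt_correlations,
                     file.path(out_dir, "ogt_correlations.tsv"))
    writeLines(log_lines, file.path(out_dir, "run.log"))
  }

  structure(list(
    metadata = metadata, config = config,
    fits = fits, scores = scores,
    pair_summary = pair_summary,
    ogt_correlations = ogt_correlations,
    organism_stats = dplyr::bind_rows(stats_rows),
    failures = failures,
    status = if (length(failures) > 0L) 1L else 0L
  ), class = "fp_scan_result")
}

#' @export
print.fp_scan_result <- function(x, ...) {
  cat("First-passage scan of", nrow(x$metadata), "organism(s)\n")
  cat("  directions:", paste(x$config$directions, collapse = ", "),
      " fit window: [", x$config$l_min, ",", x$config$l_max, "]",
      " z threshold:", x$config$z_thresh, "\n")
  cat("  organisms analyzed:", nrow(x$organism_stats),
      " failed:", length(x$failures), "\n")
  cat("  retained (pair, L) combinations (>=", x$config$min_genomes,
      "genomes):", nrow(x$pair_summary), "\n")
  if (nrow(x$pair_summary) > 0L) {
    print(utils::head(dplyr::filter(x$pair_summary, .data$is_modal), 10L))
  }
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a first-passage scan result
#'
#' Returns the cross-organism pair summary (one row per retained
#' (pair, direction, sign, L)), joined with the OGT correlations for the
#' modal rows.
#'
#' @param x An `fp_scan_result` from [run_scan()].
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.fp_scan_result <- function(x, ...) {
  dplyr::left_join(
    x$pair_summary,
    dplyr::select(x$ogt_correlations, -"n"),
    by = c("x", "y", "direction", "L")
  )
}

#' Glance at a first-passage scan result
#'
#' @param x An `fp_scan_result` from [run_scan()].
#' @param ... Unused.
#' @return A one-row tibble with study-level counts.
#' @export
glance.fp_scan_result <- function(x, ...) {
  tibble::tibble(
    n_organisms = nrow(x$metadata),
    n_analyzed = nrow(x$organism_stats),
    n_failed = length(x$failures),
    total_residues = sum(x$organism_stats$n_residues),
    n_valid_fits = sum(x$fits$valid),
    n_retained = nrow(x$pair_summary),
    status = x$status
  )
}
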