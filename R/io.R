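#' Read sequences from a FASTA file
#'
#' @param path Path to a (multi-)FASTA file.
#' @return An `element_set` tibble with columns `id` and `sequence`
#'   (upper-cased); record identifiers are preserved.
#' @examples
#' f <- tempfile(fileext = ".fa")
#' writeLines(c(">a", "acgt", ">b", "GGCC"), f)
#' read_fasta(f)
#' @export
read_fasta <- function(path) {
  stop_input_if(!file.exists(path), sprintf("file not found: %s", path))
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) {
      stop_input(paste0("malformed FASTA (", path, "): ",
                        conditionMessage(e)))
    }
  )
  element_set(toupper(as.character(set)), ids = names(set))
}

#' Write an element set to FASTA
#'
#' @param elements An `element_set` (or any data frame with `id` and
#'   `sequence` columns), or a named character vector.
#' @param path Output path.
#' @param header Optional comment line (written as a `;` FASTA comment is
#'   non-portable, so it goes into the first record description instead of
#'   the file; pass NULL to skip). Identifiers encode the leaf index.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(elements, path, header = NULL) {
  if (is.character(elements)) {
    elements <- element_set(elements,
                            ids = names(elements) %||%
                              paste0("L", seq_along(elements)))
  }
  set <- Biostrings::DNAStringSet(elements$sequence)
  names(set) <- elements$id
  Biostrings::writeXStringSet(set, filepath = path)
  invisible(path)
}

#' Write an abundance spectrum (raw or binned) as TSV
#'
#' Emits the columns `k`, `s_or_bin_center`, `n` and `density` with fixed
#' decimal formatting so repeated runs diff cleanly. Provenance (producing
#' command, config checksum, seed) goes into `#`-prefixed header comments.
#'
#' @param spectrum An [spectrum_from_counts()] or [log_bin()] tibble.
#' @param path Output path.
#' @param producer Name of the producing command (for the header).
#' @param config_hash,seed Optional provenance fields for the header.
#' @return `path`, invisibly.
#' @export
write_spectrum_tsv <- function(spectrum, path, producer = "spectrum",
                               config_hash = NULL, seed = NULL) {
  if (inherits(spectrum, "binned_spectrum")) {
    df <- tibble::tibble(
      k = spectrum$k,
      s_or_bin_center = sprintf("%.4f", spectrum$center),
      n = sprintf("%.4f", spectrum$mass),
      density = sprintf("%.6f", spectrum$density)
    )
  } else {
    df <- tibble::tibble(
      k = spectrum$k,
      s_or_bin_center = sprintf("%.4f", as.numeric(spectrum$s)),
      n = sprintf("%.4f", as.numeric(spectrum$n)),
      density = sprintf("%.6f", as.numeric(spectrum$n))
    )
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(output_header(producer, config_hash, seed), con)
  writeLines(paste(names(df), collapse = "\t"), con)
  writeLines(do.call(paste, c(unname(as.list(df)), sep = "\t")), con)
  invisible(path)
}

#' Read back a spectrum TSV
#'
#' @param path A file written by [write_spectrum_tsv()].
#' @return A tibble with numeric columns `k`, `s_or_bin_center`, `n`,
#'   `density`.
#' @export
read_spectrum_tsv <- function(path) {
  stop_input_if(!file.exists(path), sprintf("file not found: %s", path))
  df <- utils::read.delim(path, comment.char = "#", sep = "\t",
                          stringsAsFactors = FALSE)
  tibble::as_tibble(df)
}

output_header <- function(producer, config_hash = NULL, seed = NULL) {
  sprintf("# repeatburst %s config=%s seed=%s", producer,
          config_hash %||% "-",
          if (is.null(seed)) "-" else format(seed))
}

# small polynomial checksum (not cryptographic) used to stamp outputs with
# the configuration they came from
config_checksum <- function(x) {
  strip <- function(v) {
    if (is.list(v)) {
      v <- lapply(v, strip)
      attributes(v) <- list(names = names(v))
    }
    v
  }
  s <- jsonlite::toJSON(strip(x), auto_unbox = TRUE, digits = NA,
                        null = "null")
  b <- utf8ToInt(as.character(s))
  h <- 0
  for (byte in b) h <- (h * 31 + byte) %% 2147483647
  sprintf("%08x", h)
}

#' Pipeline configuration
#'
#' Bundles everything the end-to-end pipeline needs, pre-filled with the
#' Alu-calibrated defaults: k grid 5..90 in steps of 5, Hill tail cutoff
#' `s_min = 3`, exponent-fit window 35..75, log binning above 7 with edge
#' ratio 1.1885.
#'
#' @param params A [burst_params()] object.
#' @param target_n Elements to simulate.
#' @param k_grid K-mer lengths for the spectra.
#' @param s_min Hill tail cutoff.
#' @param k_fit Exponent-curve fit window `c(lo, hi)`.
#' @param bin_threshold,bin_ratio Log-binning settings.
#' @param seed Integer seed for the whole run.
#' @param t2_grid Optional grid for the silent-phase fit stage.
#' @param gc_content GC fraction of the generated ancestor.
#' @return A `pipeline_config` list.
#' @examples
#' cfg <- pipeline_config(target_n = 500, seed = 1)
#' @export
pipeline_config <- function(params = alu_params(), target_n = 10000,
                            k_grid = seq(5, 90, by = 5), s_min = 3,
                            k_fit = c(35, 75), bin_threshold = 7,
                            bin_ratio = 1.1885, seed = 1, t2_grid = NULL,
                            gc_content = 0.5) {
  structure(list(
    params = params, target_n = as.integer(target_n), k_grid = k_grid,
    s_min = s_min, k_fit = k_fit, bin_threshold = bin_threshold,
    bin_ratio = bin_ratio, seed = as.integer(seed), t2_grid = t2_grid,
    gc_content = gc_content
  ), class = "pipeline_config")
}

#' Serialise / restore a pipeline configuration
#'
#' JSON round trip is lossless.
#'
#' @param config A [pipeline_config()].
#' @param path JSON file path.
#' @return `write_config`: `path` invisibly; `read_config`: the config.
#' @export
write_config <- function(config, path) {
  x <- unclass(config)
  x$params <- unclass(x$params)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  stop_input_if(!file.exists(path), sprintf("file not found: %s", path))
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  p <- x$params
  params <- burst_params(gamma = p$gamma, delta = p$delta, mu0 = p$mu0,
                         cpg_factor = p$cpg_factor, T1 = p$T1, T2 = p$T2,
                         L = p$L, n_cpg = p$n_cpg)
  pipeline_config(params = params, target_n = x$target_n, k_grid = x$k_grid,
                  s_min = x$s_min, k_fit = x$k_fit,
                  bin_threshold = x$bin_threshold, bin_ratio = x$bin_ratio,
                  seed = x$seed, t2_grid = x$t2_grid,
                  gc_content = x$gc_content)
}

#' Run the full simulate-count-fit pipeline
#'
#' Executes the whole workflow: generate (or load) an ancestor, simulate the
#' duplication burst, evolve sequences, count k-mers and build binned
#' spectra over the k grid, estimate the element count, profile the Hill
#' exponent curve, fit the analytic exponent to recover the rate ratio,
#' invert the growth curve for `T1`, and (when a `t2_grid` is configured)
#' fit `T2` by spectrum matching. All artefacts (FASTA, Newick, TSV spectra
#' and curve, JSON fit report, log) are written under `out_dir`; outputs are
#' byte-reproducible for a fixed config and seed.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @param ancestor Optional ancestral sequence (A/C/G/T string); by default
#'   a CpG-matched synthetic ancestor is generated from the config.
#' @param elements Optional pre-existing `element_set` (e.g. from
#'   [read_fasta()]); when given, the simulation stages are skipped and only
#'   the inference stages run.
#' @param quiet Suppress progress messages.
#' @return The fit report (a list), invisibly; also written as `fit.json`.
#' @export
run_pipeline <- function(config, out_dir, ancestor = NULL, elements = NULL,
                         quiet = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_checksum(within(unclass(config), rm(seed)))
  log_path <- file.path(out_dir, "pipeline.log")
  log_con <- file(log_path, "w")
  on.exit(close(log_con))
  t0 <- proc.time()[["elapsed"]]
  say <- function(fmt, ...) {
    msg <- sprintf(fmt, ...)
    writeLines(sprintf("[%8.2fs] %s", proc.time()[["elapsed"]] - t0, msg),
               log_con)
    if (!quiet) message(msg)
  }
  params <- config$params
  rates <- effective_rates(params)
  say("config checksum %s, seed %d", hash, config$seed)
  say("effective rates: mu = %g, delta*gamma = %g, ratio = %g",
      rates$mu, rates$delta_gamma, rates$ratio)

  fit_window <- config$k_grid[config$k_grid >= config$k_fit[1] &
                                config$k_grid <= config$k_fit[2]]
  if (all(config$k_grid * rates$ratio >= 1)) {
    stop_no_tail("no power-law tail exists for any k in the configured grid.")
  }

  if (is.null(elements)) {
    if (is.null(ancestor)) {
      ancestor <- make_ancestral(params$L, params$n_cpg,
                                 gc_content = config$gc_content,
                                 seed = config$seed)
      say("generated ancestor: L = %d, CpG = %d", params$L, params$n_cpg)
    }
    write_fasta(element_set(ancestor, ids = "ancestor"),
                file.path(out_dir, "ancestor.fasta"))
    say("simulating burst to %d elements (seed %d)",
        config$target_n, config$seed)
    tree <- simulate_burst(params, config$target_n, seed = config$seed)
    write_newick(tree, file.path(out_dir, "tree.nwk"))
    say("evolving sequences along %d edges", nrow(tree$edge))
    elements <- evolve_sequences(tree, ancestor, params,
                                 seed = config$seed + 1L)
    write_fasta(elements, file.path(out_dir, "elements.fasta"))
  }

  say("counting k-mers over %d values of k", length(config$k_grid))
  spectra <- kmer_spectra(elements, config$k_grid)
  write_spectrum_tsv(spectra, file.path(out_dir, "spectrum_raw.tsv"),
                     producer = "spectrum", config_hash = hash,
                     seed = config$seed)
  binned <- log_bin(spectra, threshold = config$bin_threshold,
                    ratio = config$bin_ratio)
  write_spectrum_tsv(binned, file.path(out_dir, "spectrum_binned.tsv"),
                     producer = "spectrum --binned", config_hash = hash,
                     seed = config$seed)

  N_hat <- estimate_N(elements,
                      k_values = config$k_grid[config$k_grid < params$L],
                      L = params$L)
  say("estimated element count N = %.1f", N_hat)

  curve <- exponent_curve(elements, k_values = fit_window,
                          s_min = config$s_min)
  curve_path <- file.path(out_dir, "exponent_curve.tsv")
  con <- file(curve_path, "w")
  writeLines(output_header("hill", hash, config$seed), con)
  writeLines("k\talpha_hat\tn_tail\tse", con)
  writeLines(sprintf("%d\t%.6f\t%d\t%.6f", curve$k, curve$alpha_hat,
                     curve$n_tail, curve$se), con)
  close(con)

  fit <- fit_ratio(curve, k_lo = config$k_fit[1], k_hi = config$k_fit[2])
  say("fitted ratio mu/(delta*gamma) = %.6g (se %.2g)", fit$ratio_hat, fit$se)

  mu_hat <- rates$mu # CpG geometry of the ancestor is known
  dg_hat <- mu_hat / fit$ratio_hat
  T1_hat <- estimate_T1(N_hat, burst_params(gamma = dg_hat / params$delta,
                                            delta = params$delta))
  say("implied delta*gamma = %.4g, T1 = %.4g", dg_hat, T1_hat)

  report <- list(
    config_checksum = hash,
    seed = config$seed,
    n_elements = length(elements$sequence),
    N_hat = N_hat,
    ratio_hat = fit$ratio_hat,
    ratio_se = fit$se,
    residual_norm = fit$residual_norm,
    mu_assumed = mu_hat,
    delta_gamma_hat = dg_hat,
    T1_hat = T1_hat,
    alpha_curve = as.data.frame(curve[, c("k", "alpha_hat", "n_tail", "se")])
  )

  if (!is.null(config$t2_grid) && length(config$t2_grid) > 0) {
    say("fitting T2 over a grid of %d values", length(config$t2_grid))
    p_sim <- params
    p_sim$delta <- 1
    p_sim$gamma <- dg_hat
    p_sim$T1 <- T1_hat
    t2 <- fit_T2(binned, p_sim, config$t2_grid,
                 target_n = min(config$target_n,
                                length(elements$sequence)),
                 ancestor = ancestor %||% make_ancestral(
                   params$L, params$n_cpg, config$gc_content,
                   seed = config$seed),
                 k_values = fit_window, seed = config$seed + 2L)
    report$T2_hat <- t2$best_T2
    report$T2_profile <- as.data.frame(t2$profile)
    say("best T2 = %g", t2$best_T2)
  }

  jsonlite::write_json(report, file.path(out_dir, "fit.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  say("report written to %s", file.path(out_dir, "fit.json"))
  invisible(report)
}
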