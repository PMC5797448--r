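#' Default acrophases for the clock signature
#'
#' Peak times (hours, zeitgeber time) encoding the two-arm architecture of
#' the mammalian clock: positive-arm genes (Arntl, Npas2, Clock) peak
#' shortly before ZT0 (default 22 h), negative-arm genes near ZT10, and the
#' intermediate Cry1 near ZT18.
#'
#' @param signature Gene panel with arm annotations; default
#'   [clock_signature()].
#' @return Named numeric vector of phases in \[0, 24).
#' @export
default_phases <- function(signature = clock_signature()) {
  signature <- as_signature(signature)
  if (anyNA(signature$arm)) {
    stop("Signature lacks arm annotations; supply phases explicitly.")
  }
  ph <- c(positive = 22, intermediate = 18, negative = 10)[signature$arm]
  names(ph) <- signature$gene
  ph
}

#' Configuration for the circadian transcriptome simulator
#'
#' Bundles and validates everything [simulate_clock()] needs. Defaults
#' emulate a bulk time-course of a peripheral mouse organ on the log2
#' expression scale: sinusoids of amplitude 3 (about 64-fold peak-to-trough,
#' the regime of strongly rhythmic core clock genes) for the 12 clock genes
#' around a baseline of 8, Gaussian noise with SD 0.5, 200 non-rhythmic
#' background genes, and sample times drawn uniformly over the full
#' circadian cycle (the unlabeled-samples scenario the CCD targets).
#'
#' @param n_samples Number of samples.
#' @param sample_times `"uniform"` (times drawn uniformly over
#'   `time_range`) or an explicit numeric vector of hours, length
#'   `n_samples`.
#' @param time_range Two hours in \[0, 24\] delimiting the sampling window;
#'   e.g. `c(0, 8)` for day-only collection.
#' @param phases Named per-gene acrophase in hours; default
#'   [default_phases()].
#' @param amplitudes Per-gene nonnegative amplitudes (recycled scalar ok).
#' @param baselines Per-gene baseline expression (recycled scalar ok).
#' @param noise_sd Gaussian noise SD (>= 0), shared by clock and background
#'   genes.
#' @param phase_jitter_sd Per-sample desynchronization SD in hours: each
#'   sample's effective time is jittered by N(0, phase_jitter_sd^2),
#'   emulating inter-individual variation in human data. Default 0.
#' @param n_background Number of non-rhythmic background genes (pure noise
#'   around gene-specific baselines).
#' @param background_blocks Number of correlated background blocks; genes in
#'   a block share a latent factor so that the random-gene null can be
#'   stressed with module structure. Default 0 (independent background).
#' @param block_size,block_cor Genes per block and within-block correlation
#'   of the latent-factor model (only used when `background_blocks > 0`).
#' @param condition `"normal"`, `"arrhythmic"` (all signature amplitudes set
#'   to 0), `"phase_scrambled"` (each signature gene's phase redrawn
#'   uniformly on \[0, 24)), or `"knockout"` (amplitude 0 plus a baseline
#'   shift for `knockout_genes`).
#' @param knockout_genes Genes zeroed under `condition = "knockout"`.
#' @param knockout_shift Baseline shift applied to knocked-out genes.
#' @param signature Gene panel; default [clock_signature()].
#' @param seed Integer seed making the dataset reproducible.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_samples = 48L, sample_times = "uniform",
                       time_range = c(0, 24), phases = NULL,
                       amplitudes = 3, baselines = 8, noise_sd = 0.5,
                       phase_jitter_sd = 0, n_background = 200L,
                       background_blocks = 0L, block_size = 10L,
                       block_cor = 0.7,
                       condition = c("normal", "arrhythmic",
                                     "phase_scrambled", "knockout"),
                       knockout_genes = NULL, knockout_shift = -2,
                       signature = clock_signature(), seed = 1L) {
  condition <- match.arg(condition)
  signature <- as_signature(signature)
  genes <- signature$gene
  k <- length(genes)
  if (is.null(phases)) phases <- default_phases(signature)
  phases <- rep_len(phases, k)
  amplitudes <- rep_len(amplitudes, k)
  baselines <- rep_len(baselines, k)
  names(phases) <- names(amplitudes) <- names(baselines) <- genes

  if (n_samples < 1L) stop("`n_samples` must be positive.")
  if (any(phases < 0 | phases >= 24)) stop("Phases must lie in [0, 24).")
  if (any(amplitudes < 0)) stop("Amplitudes must be nonnegative.")
  if (noise_sd < 0 || phase_jitter_sd < 0) stop("Noise SDs must be >= 0.")
  if (length(time_range) != 2L || time_range[1L] >= time_range[2L] ||
      time_range[1L] < 0 || time_range[2L] > 24) {
    stop("`time_range` must be an increasing pair within [0, 24].")
  }
  if (is.numeric(sample_times) && length(sample_times) != n_samples) {
    stop("Explicit `sample_times` must have length n_samples.")
  }
  if (condition == "knockout") {
    if (is.null(knockout_genes) || !all(knockout_genes %in% genes)) {
      stop("`knockout_genes` must name signature genes.")
    }
  }
  structure(list(n_samples = as.integer(n_samples),
                 sample_times = sample_times, time_range = time_range,
                 phases = phases, amplitudes = amplitudes,
                 baselines = baselines, noise_sd = noise_sd,
                 phase_jitter_sd = phase_jitter_sd,
                 n_background = as.integer(n_background),
                 background_blocks = as.integer(background_blocks),
                 block_size = as.integer(block_size), block_cor = block_cor,
                 condition = condition, knockout_genes = knockout_genes,
                 knockout_shift = knockout_shift, signature = signature,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a circadian transcriptome dataset
#'
#' Expression of signature gene g in sample s is
#' `baseline_g + A_g * cos(2*pi*(t_s - phi_g)/24) + eps`, with eps iid
#' Gaussian(0, noise_sd^2); background genes are noise around random
#' baselines (optionally in correlated blocks). Disruption modes zero
#' amplitudes (arrhythmic, knockout) or redraw phases (phase-scrambled).
#' The same config (including seed) regenerates the dataset bit-exactly.
#'
#' @param config A [sim_config()].
#' @return Object of class `sim_dataset`: list with `expr` (gene-by-sample
#'   matrix: signature genes first, then background genes `Bkg0001`, ...),
#'   `times` (per-sample hours actually used, before jitter), and `truth`
#'   (per-gene phases, amplitudes, baselines actually used, plus the
#'   per-sample jittered times), and `config`.
#' @examples
#' sim <- simulate_clock(sim_config(n_samples = 24, seed = 42))
#' dim(sim$expr)
#' @export
simulate_clock <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, simulate_clock_impl(config))
}

simulate_clock_impl <- function(cfg) {
  genes <- cfg$signature$gene
  k <- length(genes)
  n <- cfg$n_samples

  times <- if (is.numeric(cfg$sample_times)) {
    cfg$sample_times
  } else {
    stats::runif(n, cfg$time_range[1L], cfg$time_range[2L])
  }

  phases <- cfg$phases
  amplitudes <- cfg$amplitudes
  baselines <- cfg$baselines
  if (cfg$condition == "arrhythmic") {
    amplitudes[] <- 0
  } else if (cfg$condition == "phase_scrambled") {
    phases[] <- stats::runif(k, 0, 24)
  } else if (cfg$condition == "knockout") {
    ko <- genes %in% cfg$knockout_genes
    amplitudes[ko] <- 0
    baselines[ko] <- baselines[ko] + cfg$knockout_shift
  }

  eff_times <- times
  if (cfg$phase_jitter_sd > 0) {
    eff_times <- times + stats::rnorm(n, 0, cfg$phase_jitter_sd)
  }

  signal <- outer(seq_len(k), seq_len(n), function(g, s) {
    baselines[g] + amplitudes[g] * cos(2 * pi * (eff_times[s] - phases[g]) / 24)
  })
  if (cfg$noise_sd > 0) {
    signal <- signal + matrix(stats::rnorm(k * n, 0, cfg$noise_sd), k, n)
  }
  rownames(signal) <- genes

  expr <- signal
  if (cfg$n_background > 0L) {
    nb <- cfg$n_background
    bg_base <- stats::runif(nb, 4, 12)
    bg <- matrix(stats::rnorm(nb * n, 0, cfg$noise_sd), nb, n) + bg_base
    if (cfg$background_blocks > 0L) {
      r <- cfg$block_cor
      for (b in seq_len(cfg$background_blocks)) {
        rows <- ((b - 1L) * cfg$block_size + 1L):(b * cfg$block_size)
        rows <- rows[rows <= nb]
        if (length(rows) == 0L) break
        latent <- stats::rnorm(n)
        shared <- matrix(latent, length(rows), n, byrow = TRUE)
        noise <- matrix(stats::rnorm(length(rows) * n), length(rows), n)
        bg[rows, ] <- bg_base[rows] +
          cfg$noise_sd * (sqrt(r) * shared + sqrt(1 - r) * noise)
      }
    }
    rownames(bg) <- sprintf("Bkg%04d", seq_len(nb))
    expr <- rbind(expr, bg)
  }
  colnames(expr) <- sprintf("S%03d", seq_len(n))

  structure(list(expr = expr, times = times,
                 truth = list(times = eff_times, phases = phases,
                              amplitudes = amplitudes,
                              baselines = baselines),
                 config = cfg),
            class = "sim_dataset")
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat("Simulated circadian dataset: ", nrow(x$expr), " genes x ",
      ncol(x$expr), " samples, condition = ", x$config$condition,
      ", noise_sd = ", x$config$noise_sd, ", seed = ", x$config$seed,
      "\n", sep = "")
  invisible(x)
}

#' Simulate a panel of independent reference datasets
#'
#' Generates `k_datasets` datasets from one underlying truth (shared phase
#' architecture) with dataset-specific seeds, mirroring the construction of
#' a co-expression reference from multiple independent organ time courses;
#' feed their correlation vectors to [meta_reference()].
#'
#' @param k_datasets Number of datasets, at least 2.
#' @param n_samples Samples per dataset (recycled vector ok).
#' @param noise_sd Noise SD per dataset (recycled vector ok).
#' @param seed Master seed from which per-dataset seeds are derived.
#' @param ... Further arguments passed to [sim_config()].
#' @return List of `sim_dataset` objects.
#' @examples
#' panel <- simulate_reference_panel(3, n_samples = 24, seed = 5)
#' length(panel)
#' @export
simulate_reference_panel <- function(k_datasets, n_samples = 48L,
                                     noise_sd = 0.5, seed = 1L, ...) {
  if (k_datasets < 2L) stop("A reference panel needs at least 2 datasets.")
  n_samples <- rep_len(n_samples, k_datasets)
  noise_sd <- rep_len(noise_sd, k_datasets)
  seeds <- child_seeds(seed, k_datasets)
  lapply(seq_len(k_datasets), function(i) {
    simulate_clock(sim_config(n_samples = n_samples[i],
                              noise_sd = noise_sd[i], seed = seeds[i], ...))
  })
}

#' Population (noiseless) correlation vector of a phase architecture
#'
#' Correlation vector of exact sinusoids at the given phases sampled densely
#' and evenly over one full cycle with no noise — the truth that simulated
#' datasets estimate and that the meta-analyzed reference should recover.
#'
#' @inheritParams sim_config
#' @param n_grid Number of evenly spaced time points over \[0, 24).
#' @return A `cor_vector`.
#' @export
noiseless_cor_vector <- function(signature = clock_signature(),
                                 phases = NULL, n_grid = 480L) {
  cfg <- sim_config(n_samples = n_grid,
                    sample_times = seq(0, 24, length.out = n_grid + 1L)[-(n_grid + 1L)],
                    phases = phases, noise_sd = 0, n_background = 0L,
                    signature = signature, seed = 0L)
  correlation_vector(simulate_clock(cfg)$expr, signature)
}
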