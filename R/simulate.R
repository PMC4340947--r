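# Seeded synthetic-data generators. The network generator plants
# phase-coherent modules as metabolite-chained reaction paths (so intra-module
# hop distance is at most module_size - 1), optionally joined by bridge
# reactions whose genes carry no phase; gene phases are module centre plus
# wrapped-normal noise, the circular analogue of Gaussian noise. Metabolite
# tokens are synthetic and disjoint from the default currency list.

#' Simulate a reaction network with planted phase-coherent modules
#'
#' Each module is a chain of `module_size` reactions in which consecutive
#' reactions share a metabolite; each reaction carries one gene whose phase is
#' drawn as the module centre plus wrapped-normal noise with circular standard
#' deviation `phase_spread_h`. `n_bridges` bridge reactions chain the end of
#' one module to the start of the next (cyclically); bridge genes are omitted
#' from the phase table, so bridges shape connectivity but are not clustered.
#' Background reactions draw random substrate/product pairs from a separate
#' metabolite pool and carry uniformly phased genes.
#'
#' @param n_modules Number of planted modules.
#' @param module_size Reactions (and genes) per module.
#' @param module_phase_centers Module peak times in hours; length
#'   `n_modules`.
#' @param phase_spread_h Circular standard deviation of the phase noise in
#'   hours; must be `< 12`. `0` gives phases exactly at the centres.
#' @param n_background Number of background reactions.
#' @param n_bridges Number of inter-module bridge reactions.
#' @param seed Integer seed; identical seeds give identical output.
#' @return A list: `reactions` (reaction tibble in the
#'   [read_reaction_table()] schema), `phases` (`gene`, `phase_h`), and
#'   `truth` (`gene`, `reaction_id`, `module`, with `NA` for background).
#' @export
simulate_reaction_network <- function(n_modules = 2, module_size = 5,
                                      module_phase_centers = c(2, 14),
                                      phase_spread_h = 0.5,
                                      n_background = 10, n_bridges = 1,
                                      seed = 1L) {
  if (length(module_phase_centers) != n_modules) {
    stop("module_phase_centers must have length n_modules", call. = FALSE)
  }
  if (phase_spread_h < 0 || phase_spread_h >= 12) {
    stop("phase_spread_h must lie in [0, 12)", call. = FALSE)
  }
  if (n_modules < 1 || module_size < 2) {
    stop("need >= 1 module with >= 2 reactions each", call. = FALSE)
  }
  withr::local_seed(seed)

  rows <- list()
  phases <- list()
  truth <- list()
  for (m in seq_len(n_modules)) {
    ids <- sprintf("M%d_R%02d", m, seq_len(module_size))
    genes <- sprintf("gm%d_%02d", m, seq_len(module_size))
    rows[[length(rows) + 1]] <- tibble::tibble(
      reaction_id = ids,
      genes = as.list(genes),
      substrates = as.list(sprintf("m%d_met%02d", m, seq_len(module_size))),
      products = as.list(sprintf("m%d_met%02d", m, seq_len(module_size) + 1)),
      reversible = FALSE,
      pathways = rep(list(sprintf("PWY_M%d", m)), module_size)
    )
    phases[[m]] <- tibble::tibble(
      gene = genes,
      phase_h = (module_phase_centers[m] +
                   stats::rnorm(module_size, 0, phase_spread_h)) %% 24
    )
    truth[[length(truth) + 1]] <- tibble::tibble(
      gene = genes, reaction_id = ids, module = m
    )
  }

  if (n_bridges > 0 && n_modules > 1) {
    for (j in seq_len(n_bridges)) {
      a <- ((j - 1) %% n_modules) + 1
      b <- (a %% n_modules) + 1
      rows[[length(rows) + 1]] <- tibble::tibble(
        reaction_id = sprintf("BRG%02d", j),
        genes = list(sprintf("gbridge_%02d", j)),
        substrates = list(sprintf("m%d_met%02d", a, module_size + 1)),
        products = list(sprintf("m%d_met%02d", b, 1L)),
        reversible = TRUE,
        pathways = list(character(0))
      )
    }
  }

  if (n_background > 0) {
    pool <- sprintf("bg_met%02d", seq_len(max(4, n_background)))
    bg_genes <- sprintf("gb%02d", seq_len(n_background))
    bg <- tibble::tibble(
      reaction_id = sprintf("B%02d", seq_len(n_background)),
      genes = as.list(bg_genes),
      substrates = purrr::map(seq_len(n_background),
                              function(i) sample(pool, 1)),
      products = purrr::map(seq_len(n_background),
                            function(i) sample(pool, 1)),
      reversible = FALSE,
      pathways = rep(list("PWY_BG"), n_background)
    )
    rows[[length(rows) + 1]] <- bg
    phases[[length(phases) + 1]] <- tibble::tibble(
      gene = bg_genes, phase_h = stats::runif(n_background, 0, 24)
    )
    truth[[length(truth) + 1]] <- tibble::tibble(
      gene = bg_genes, reaction_id = bg$reaction_id, module = NA_integer_
    )
  }

  list(
    reactions = dplyr::bind_rows(rows),
    phases = dplyr::bind_rows(phases),
    truth = dplyr::bind_rows(truth)
  )
}

#' Simulate cosine-plus-noise time series
#'
#' Rhythmic features follow
#' `mesor + amplitude * cos(2*pi*(t - acrophase)/period_h)` plus Gaussian
#' noise; non-rhythmic features are mesor plus noise. Acrophases are drawn
#' uniformly per feature and shared across conditions and replicates.
#'
#' @param n_features Number of features.
#' @param fraction_rhythmic Fraction (first features) that carry a rhythm.
#' @param period_h True oscillation period in hours.
#' @param amplitude,mesor,noise_sd Waveform parameters; `noise_sd >= 0`.
#' @param timepoints Sampling times in hours (default 4 h steps over 48 h).
#' @param replicates Biological replicates per timepoint.
#' @param conditions Condition labels (default LD and DD).
#' @param seed Integer seed.
#' @return A list: `expr` (feature-by-sample tibble), `samples` (sample
#'   sheet), `truth` (`feature`, `is_rhythmic`, `acrophase`, `amplitude`,
#'   `mesor`).
#' @export
simulate_timeseries <- function(n_features = 200, fraction_rhythmic = 0.5,
                                period_h = 24, amplitude = 2, mesor = 10,
                                noise_sd = 1,
                                timepoints = seq(0, 44, by = 4),
                                replicates = 1,
                                conditions = c("LD", "DD"), seed = 1L) {
  if (fraction_rhythmic < 0 || fraction_rhythmic > 1) {
    stop("fraction_rhythmic must lie in [0, 1]", call. = FALSE)
  }
  if (noise_sd < 0) {
    stop("noise_sd must be nonnegative", call. = FALSE)
  }
  if (n_features < 1 || replicates < 1 || length(timepoints) < 2) {
    stop("need >= 1 feature, >= 1 replicate and >= 2 timepoints",
         call. = FALSE)
  }
  withr::local_seed(seed)

  n_rhythmic <- round(fraction_rhythmic * n_features)
  features <- sprintf("f%05d", seq_len(n_features))
  is_rhythmic <- seq_len(n_features) <= n_rhythmic
  acrophase <- ifelse(is_rhythmic, stats::runif(n_features, 0, 24), NA_real_)

  samples <- tidyr::expand_grid(
    condition = conditions,
    timepoint_h = timepoints,
    replicate = seq_len(replicates)
  ) |>
    dplyr::mutate(sample = paste0(.data$condition, "_T", .data$timepoint_h,
                                  "_r", .data$replicate)) |>
    dplyr::select("sample", "timepoint_h", "condition", "replicate")

  signal <- matrix(mesor, nrow = n_features, ncol = nrow(samples))
  if (n_rhythmic > 0) {
    phase_term <- outer(
      acrophase[is_rhythmic], samples$timepoint_h,
      function(a, t) cos(2 * pi * (t - a) / period_h)
    )
    signal[is_rhythmic, ] <- mesor + amplitude * phase_term
  }
  noise <- matrix(stats::rnorm(length(signal), 0, noise_sd),
                  nrow = n_features)
  values <- signal + noise
  colnames(values) <- samples$sample

  expr <- dplyr::bind_cols(
    tibble::tibble(feature = features),
    tibble::as_tibble(values)
  )
  truth <- tibble::tibble(
    feature = features,
    is_rhythmic = is_rhythmic,
    acrophase = acrophase,
    amplitude = ifelse(is_rhythmic, amplitude, 0),
    mesor = mesor
  )
  list(expr = expr, samples = samples, truth = truth)
}
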