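# Synthetic lifespan datasets with known ground-truth epistasis structure.
#
# Each simulated experiment emulates what the classifier expects from a
# curated study: a wild-type control cohort, all single mutants, a sampled
# fraction of intermediary mutants, and the full n-mutant, with
# multiplicative log-normal noise on lifespans (noise on a positive scale,
# parameterised by a coefficient of variation).

#' Configuration for the synthetic-data generator
#'
#' Defaults emulate a C. elegans lifespan assay at 20 degrees: wild-type
#' mean lifespan 18.8 days and a between-cohort coefficient of variation of
#' 0.18, the magnitude reported for wild-type worms across studies.
#'
#' @param genes Named numeric vector: single-mutant percent effects keyed
#'   by gene symbol (each > -100).
#' @param organism Organism label.
#' @param wt_lifespan_days Wild-type mean lifespan (days).
#' @param interaction_model How multi-gene effects derive from single
#'   effects: `"additive_deltas"` (percent effects add),
#'   `"multiplicative_lifespans"` (lifespan ratios multiply),
#'   `"masking"` (the single effect of largest magnitude masks the rest),
#'   or `"custom_table"` (taken from `interaction_overrides`, additive
#'   where unspecified).
#' @param interaction_overrides Named numeric vector of percent effects
#'   keyed by canonical subset name; overrides the model for those subsets
#'   under any `interaction_model`.
#' @param noise_cv Coefficient of variation of the multiplicative
#'   log-normal lifespan noise (>= 0; 0 = deterministic).
#' @param completeness Fraction of intermediary mutants (sizes 2..n-1)
#'   assayed per experiment, in (0, 1]; WT, all singles and the full
#'   n-mutant are always assayed.
#' @param n_experiments Number of independent experiments (distinct study
#'   ids).
#' @param seed Integer seed; identical config + seed gives an identical
#'   dataset.
#' @param temperature_c,diet Recorded assay conditions.
#' @param intervention_type Intervention type recorded for every gene.
#' @return A `generator_config` list.
#' @export
generator_config <- function(genes,
                             organism = "C. elegans",
                             wt_lifespan_days = 18.8,
                             interaction_model = c("additive_deltas",
                                                   "multiplicative_lifespans",
                                                   "masking", "custom_table"),
                             interaction_overrides = NULL,
                             noise_cv = 0.18,
                             completeness = 1,
                             n_experiments = 1,
                             seed = 1L,
                             temperature_c = 20,
                             diet = "standard",
                             intervention_type = "loss-of-function mutation") {
  interaction_model <- arg_match(interaction_model)
  if (is.null(names(genes)) || any(!nzchar(names(genes)))) {
    abort("`genes` must be a named numeric vector (names = gene symbols).")
  }
  if (any(genes <= -100)) {
    abort("Single effects must exceed -100% (lifespans are positive).")
  }
  if (!organism %in% ORGANISMS) {
    abort(paste0("Unknown organism: ", organism))
  }
  if (wt_lifespan_days <= 0) abort("`wt_lifespan_days` must be positive.")
  if (noise_cv < 0) abort("`noise_cv` must be >= 0.")
  if (completeness <= 0 || completeness > 1) {
    abort("`completeness` must be in (0, 1].")
  }
  if (n_experiments < 1) abort("`n_experiments` must be >= 1.")
  if (!intervention_type %in% names(INTERVENTION_DIRECTIONS)) {
    abort(paste0("Unknown intervention type: ", intervention_type))
  }
  structure(
    list(
      genes = genes, organism = organism,
      wt_lifespan_days = wt_lifespan_days,
      interaction_model = interaction_model,
      interaction_overrides = interaction_overrides,
      noise_cv = noise_cv, completeness = completeness,
      n_experiments = as.integer(n_experiments), seed = as.integer(seed),
      temperature_c = temperature_c, diet = diet,
      intervention_type = intervention_type
    ),
    class = "generator_config"
  )
}

# Noise-free percent effect of a gene subset under the configured
# interaction model.
expected_delta <- function(config, genes_subset) {
  nm <- canonical_name(genes_subset)
  ov <- config$interaction_overrides
  if (!is.null(ov) && nm %in% names(ov)) {
    return(unname(ov[[nm]]))
  }
  d <- config$genes[genes_subset]
  switch(config$interaction_model,
    additive_deltas = sum(d),
    custom_table = sum(d),
    multiplicative_lifespans = (prod(1 + d / 100) - 1) * 100,
    masking = unname(d[which.max(abs(d))])
  )
}

all_subsets <- function(genes, min_size = 1, max_size = length(genes)) {
  unlist(lapply(seq(min_size, max_size), function(k) {
    combn(genes, k, simplify = FALSE)
  }), recursive = FALSE)
}

#' Generate a synthetic lifespan dataset with analytic ground truth
#'
#' Emits, per experiment, cohorts for the wild type, every single mutant, a
#' completeness-sampled subset of the intermediary mutants and the full
#' n-mutant. Expected lifespans follow the configured interaction model;
#' observed lifespans multiply them by mean-one log-normal noise with the
#' configured CV. Ground-truth categories are computed analytically from
#' the noise-free effects: the five-way pair rule for 2-gene subsets and
#' the full-synergism bipartition rule (synergistic / not-synergistic) for
#' larger subsets.
#'
#' @param config A [generator_config()].
#' @return List with `dataset` (a `lifespan_dataset`) and `ground_truth`
#'   (tibble: combination, n, expected_category).
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  genes <- names(config$genes)
  n <- length(genes)
  subsets <- all_subsets(genes)
  subset_names <- vapply(subsets, canonical_name, character(1))
  exp_delta <- setNames(
    vapply(subsets, function(s) expected_delta(config, s), numeric(1)),
    subset_names
  )
  sizes <- vapply(subsets, length, integer(1))

  sigma <- sqrt(log(1 + config$noise_cv^2))
  noisy <- function(mu, m) {
    if (config$noise_cv == 0) {
      return(rep(mu, m))
    }
    mu * rlnorm(m, meanlog = -sigma^2 / 2, sdlog = sigma)
  }

  rows <- withr::with_seed(config$seed, {
    bind_rows(lapply(seq_len(config$n_experiments), function(e) {
      study <- sprintf("SYN%04d", e)
      mids <- which(sizes >= 2 & sizes <= n - 1)
      keep_mid <- if (length(mids) > 0 && config$completeness < 1) {
        n_keep <- round(config$completeness * length(mids))
        sort(sample(mids, n_keep))
      } else {
        mids
      }
      idx <- c(which(sizes == 1), keep_mid, if (n >= 2) which(sizes == n))
      strain_genes <- c(list(character(0)), subsets[idx])
      mu <- c(config$wt_lifespan_days,
              config$wt_lifespan_days * (1 + exp_delta[subset_names[idx]] / 100))
      tibble(
        organism = config$organism,
        genes = vapply(strain_genes, function(s) paste(sort_genes(s), collapse = ";"),
                       character(1)),
        alleles = "",
        intervention_types = vapply(strain_genes, function(s) {
          paste(rep(config$intervention_type, length(s)), collapse = ";")
        }, character(1)),
        lifespan_days = noisy(1, length(mu)) * mu,
        lifespan_metric = "mean",
        temperature_c = config$temperature_c,
        diet = config$diet,
        study_id = study
      )
    }))
  })

  truth_idx <- which(sizes >= 2)
  truth <- tibble(
    combination = subset_names[truth_idx],
    n = sizes[truth_idx],
    expected_category = vapply(truth_idx, function(i) {
      s <- subsets[[i]]
      if (length(s) == 2) {
        classify_pair(exp_delta[[s[1]]], exp_delta[[s[2]]],
                      exp_delta[[subset_names[i]]])$category
      } else {
        ground_truth_full(exp_delta, s)
      }
    }, character(1))
  )

  list(dataset = as_lifespan_dataset(rows), ground_truth = truth)
}

# Full-synergism ground truth for n > 2 from noise-free effects.
ground_truth_full <- function(exp_delta, genes_subset) {
  subs <- proper_subsets(sort(genes_subset))
  dcomb <- exp_delta[[canonical_name(genes_subset)]]
  dsubs <- exp_delta[subs]
  signs <- unique(sign(dsubs))
  if (length(signs) != 1 || signs == 0) {
    return("not_assessable_mixed_directions")
  }
  if (dcomb != 0 && sign(dcomb) != signs) {
    return("antagonistic")
  }
  parts <- bipartitions(sort(genes_subset))
  ok <- all(vapply(parts, function(p) {
    abs(dcomb) > abs(exp_delta[[p$left]]) + abs(exp_delta[[p$right]])
  }, logical(1)))
  if (ok) "synergistic" else "not_synergistic"
}

#' Category-recovery experiment over noise levels
#'
#' For each noise level, generates `n_replicates` datasets from `config`,
#' classifies every multi-gene combination with [classify_dataset()] in
#' full mode, and reports the fraction of calls matching the analytic
#' ground truth. Deterministic given `seed` (replicate seeds are drawn once
#' from it).
#'
#' @param config A [generator_config()]; its `noise_cv` and `seed` are
#'   overridden per cell.
#' @param noise_cvs Numeric vector of coefficients of variation.
#' @param n_replicates Replicates per noise level.
#' @param seed Master seed.
#' @return Tibble with noise_cv, recovery (fraction in \[0, 1\]), n_calls.
#' @export
recovery_experiment <- function(config, noise_cvs, n_replicates = 100,
                                seed = 1L) {
  stopifnot(inherits(config, "generator_config"))
  rep_seeds <- withr::with_seed(seed, {
    matrix(sample.int(.Machine$integer.max - 1, length(noise_cvs) * n_replicates),
           nrow = length(noise_cvs))
  })
  rows <- lapply(seq_along(noise_cvs), function(ci) {
    cv <- noise_cvs[ci]
    hits <- 0L
    total <- 0L
    for (r in seq_len(n_replicates)) {
      cfg <- config
      cfg$noise_cv <- cv
      cfg$seed <- rep_seeds[ci, r]
      sim <- generate_dataset(cfg)
      calls <- classify_dataset(sim$dataset, mode = "full")
      merged <- dplyr::inner_join(
        calls |> select(combination, category),
        sim$ground_truth,
        by = "combination"
      )
      assessable <- merged[!merged$category %in% "insufficient_data", , drop = FALSE]
      hits <- hits + sum(assessable$category == assessable$expected_category)
      total <- total + nrow(assessable)
    }
    tibble(noise_cv = cv, recovery = hits / total, n_calls = total)
  })
  bind_rows(rows)
}
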