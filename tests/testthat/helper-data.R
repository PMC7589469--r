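# Builders for small in-code fixtures, plus independent brute-force oracles
# for path enumeration and monotony (written against permutations, not the
# package's lattice walk).

obs_row <- function(genes, lifespan_days, study_id = "S1",
                    organism = "C. elegans", temperature_c = 20,
                    diet = "standard", lifespan_metric = "mean") {
  gs <- if (identical(genes, "WT") || !nzchar(genes)) character(0) else
    strsplit(genes, ";", fixed = TRUE)[[1]]
  tibble::tibble(
    organism = organism,
    genes = paste(gs, collapse = ";"),
    alleles = "",
    intervention_types = paste(rep("loss-of-function mutation", length(gs)),
                               collapse = ";"),
    lifespan_days = lifespan_days,
    lifespan_metric = lifespan_metric,
    temperature_c = temperature_c,
    diet = diet,
    study_id = study_id
  )
}

# `models`: named numeric vector of lifespans in days; name "WT" is the
# wild type, other names are ";"-joined gene lists.
make_dataset <- function(models, study_id = "S1", ...) {
  rows <- dplyr::bind_rows(lapply(seq_along(models), function(i) {
    obs_row(names(models)[i], unname(models[i]), study_id = study_id, ...)
  }))
  as_lifespan_dataset(rows)
}

# Same strains expressed as percent effects relative to a WT lifespan.
make_delta_dataset <- function(wt, deltas, study_id = "S1", ...) {
  models <- c(WT = wt, wt * (1 + deltas / 100))
  names(models) <- c("WT", names(deltas))
  make_dataset(models, study_id = study_id, ...)
}

first_group <- function(ds) {
  experiment_groups(ds)[[1]]
}

# Many independent single-pair experiments in one dataset: one row of
# `triples` (d1, d2, d12) per experiment, genes gA/gB, WT = 100 days.
# Built columnwise so large grids stay fast.
pair_experiments_dataset <- function(triples) {
  n <- nrow(triples)
  lof <- "loss-of-function mutation"
  rows <- tibble::tibble(
    organism = "C. elegans",
    genes = rep(c("", "gA", "gB", "gA;gB"), n),
    alleles = "",
    intervention_types = rep(c("", lof, lof, paste(lof, lof, sep = ";")), n),
    lifespan_days = as.vector(rbind(
      100,
      100 * (1 + triples$d1 / 100),
      100 * (1 + triples$d2 / 100),
      100 * (1 + triples$d12 / 100)
    )),
    lifespan_metric = "mean",
    temperature_c = 20,
    diet = "standard",
    study_id = rep(sprintf("S%06d", seq_len(n)), each = 4)
  )
  as_lifespan_dataset(rows)
}

# --- independent oracles -------------------------------------------------

permutations <- function(v) {
  if (length(v) <= 1) {
    return(list(v))
  }
  out <- list()
  for (i in seq_along(v)) {
    for (p in permutations(v[-i])) {
      out[[length(out) + 1]] <- c(v[i], p)
    }
  }
  out
}

# Count WT -> n-mutant construction paths whose every prefix strain is in
# `present`, by checking all n! gene orderings.
oracle_path_count <- function(genes, present) {
  if (!wt_name() %in% present) {
    return(0L)
  }
  sum(vapply(permutations(genes), function(p) {
    all(vapply(seq_along(p), function(k) {
      canonical_name(p[seq_len(k)]) %in% present
    }, logical(1)))
  }, logical(1)))
}

# Monotony verdict by brute force over all orderings, given named lifespans
# (must include "WT").
oracle_monotony <- function(genes, lifespans, tie_tolerance = 0) {
  target <- canonical_name(genes)
  if (!target %in% names(lifespans)) {
    return("no_known_path")
  }
  signs <- c()
  for (p in permutations(genes)) {
    nodes <- c(wt_name(), vapply(seq_along(p), function(k) {
      canonical_name(p[seq_len(k)])
    }, character(1)))
    if (!all(nodes %in% names(lifespans))) next
    steps <- diff(unname(lifespans[nodes]))
    signs <- c(signs, if (all(steps > tie_tolerance)) 1
               else if (all(steps < -tie_tolerance)) -1 else 0)
  }
  if (length(signs) == 0) {
    "no_known_path"
  } else if (any(signs == 0)) {
    "contains_dependency"
  } else if (all(signs == 1)) {
    "monotonic_positive"
  } else if (all(signs == -1)) {
    "monotonic_negative"
  } else {
    "contains_dependency"
  }
}

masked_triple_path <- function() {
  system.file("extdata", "synthetic_masked_triple.csv", package = "epilifespan")
}
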