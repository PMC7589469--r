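# Epistasis mathematics: percent lifespan effects, the five-way pair
# classifier, full/simple synergism for n-mutants, and path monotony.

#' Percent lifespan change versus wild type
#'
#' The effect of an intervention set is
#' \eqn{\Delta = (LS_{mutant} - LS_{WT}) \times 100 / LS_{WT}}, in percent.
#'
#' @param ls_mutant Mutant lifespan in days (> 0); vectorised.
#' @param ls_wt Wild-type lifespan in days (> 0).
#' @return Percent change; `delta_percent(40, 20)` is `100`.
#' @export
delta_percent <- function(ls_mutant, ls_wt) {
  if (any(ls_mutant <= 0) || any(ls_wt <= 0)) {
    abort("Lifespans must be positive (days).")
  }
  (ls_mutant - ls_wt) * 100 / ls_wt
}

#' Classify the epistasis of a double mutant from its three effects
#'
#' Given the percent effects of the two single mutants and the double
#' mutant (all relative to the same wild type), assigns exactly one
#' category. Only combinations whose single interventions act in the same
#' direction are assessable; a zero single effect has no direction. With
#' shared sign `s` and magnitudes `a1 = |d1|`, `a2 = |d2|`, `a12 = |d12|`:
#'
#' * double flipped against `s` -> `antagonistic` (direction `"opposite"`)
#' * `a12 = a1 + a2` (within `additive_epsilon`, relative) -> `additive`
#' * `a12 > a1 + a2` -> `synergistic`
#' * `max(a1, a2) < a12 < a1 + a2` -> `almost_additive`
#' * `min(a1, a2) <= a12 <= max(a1, a2)` -> `dependent`
#' * `a12 < min(a1, a2)` -> `antagonistic`
#'
#' The exactly-additive case is a knife edge ("mostly theoretical"), hence
#' the configurable tolerance.
#'
#' @param d1,d2 Percent effects of the single mutants.
#' @param d12 Percent effect of the double mutant.
#' @param additive_epsilon Relative half-width of the additive band around
#'   `a1 + a2`; default `1e-9`.
#' @return List with `category` and `phenotype_direction` (`"long-lived"`,
#'   `"short-lived"`, `"opposite"`, or `NA` when not assessable).
#' @examples
#' classify_pair(30, 20, 60)  # synergistic, long-lived
#' classify_pair(30, 20, -5)  # antagonistic, opposite
#' classify_pair(-30, -20, -60) # synergistic, short-lived
#' @export
classify_pair <- function(d1, d2, d12, additive_epsilon = 1e-9) {
  if (anyNA(c(d1, d2, d12))) {
    return(list(category = "insufficient_data", phenotype_direction = NA_character_))
  }
  if (d1 == 0 || d2 == 0 || sign(d1) != sign(d2)) {
    return(list(
      category = "not_assessable_mixed_directions",
      phenotype_direction = NA_character_
    ))
  }
  s <- sign(d1)
  if (d12 != 0 && sign(d12) != s) {
    return(list(category = "antagonistic", phenotype_direction = "opposite"))
  }
  direction <- if (s > 0) "long-lived" else "short-lived"
  a1 <- abs(d1)
  a2 <- abs(d2)
  a12 <- abs(d12)
  total <- a1 + a2
  category <- if (abs(a12 - total) <= additive_epsilon * total) {
    "additive"
  } else if (a12 > total) {
    "synergistic"
  } else if (a12 > max(a1, a2)) {
    "almost_additive"
  } else if (a12 >= min(a1, a2)) {
    "dependent"
  } else {
    "antagonistic"
  }
  list(category = category, phenotype_direction = direction)
}

# Percent effects of every strain in one experiment group, relative to the
# group's own wild type (cohorts of one strain averaged first). Returns a
# named numeric vector keyed by canonical name, or NULL without a WT.
group_delta_table <- function(group) {
  ml <- model_lifespans(group)
  wt <- ml$lifespan_days[ml$n == 0]
  if (length(wt) == 0) {
    return(NULL)
  }
  muts <- ml[ml$n >= 1, , drop = FALSE]
  setNames(delta_percent(muts$lifespan_days, wt), muts$canonical_name)
}

new_epistasis_call <- function(group, combination, mode, category,
                               phenotype_direction = NA_character_,
                               evidence = list(), violated_bipartition = NA_character_,
                               detail_category = NA_character_) {
  tibble::new_tibble(list(
    organism = group$organism[1],
    combination = combination,
    n = length(gene_set(combination)),
    mode = mode,
    category = category,
    phenotype_direction = phenotype_direction,
    experiment_key = group$experiment_key[1],
    evidence = list(evidence),
    violated_bipartition = violated_bipartition,
    detail_category = detail_category
  ), nrow = 1L)
}

# All unordered bipartitions of a gene set into two non-empty disjoint
# parts, as a list of list(left, right) of canonical names. Deduplicated by
# anchoring the first gene on the left.
bipartitions <- function(genes) {
  genes <- sort(genes)
  n <- length(genes)
  rest <- genes[-1]
  out <- list()
  for (k in 0:(length(rest) - 1)) {
    picks <- if (k == 0) list(character(0)) else
      combn(rest, k, simplify = FALSE)
    for (p in picks) {
      left <- c(genes[1], p)
      right <- setdiff(genes, left)
      out[[length(out) + 1]] <- list(
        left = canonical_name(left),
        right = canonical_name(right)
      )
    }
  }
  out
}

proper_subsets <- function(genes) {
  genes <- sort(genes)
  unlist(lapply(seq_len(length(genes) - 1), function(k) {
    vapply(combn(genes, k, simplify = FALSE), canonical_name, character(1))
  }))
}

#' Evaluate full synergism of an n-mutant within one experiment
#'
#' Full synergism requires the lifespan of every intermediary mutant to
#' have been reported in the same experiment: the n-mutant is fully
#' synergistic iff for every bipartition of its gene set into two non-empty
#' disjoint parts S and S', `|d(comb)| > |d(S)| + |d(S')|`, with all
#' effects sharing one direction. For `n = 2` this reduces exactly to
#' [classify_pair()] and the detailed five-way category is reported. For
#' `n > 2` only the synergistic / not-synergistic outcome is reported,
#' together with the most violated bipartition and the pair-style category
#' of the combination against that bipartition.
#'
#' `strict = TRUE` additionally requires every sub-combination of 2+ genes
#' to be fully synergistic itself (the stricter reading; the flexible
#' bipartition-only rule is the default because it keeps combinations that
#' are only synergistic at the top level).
#'
#' @param group Tibble of observations sharing one experiment key.
#' @param combination Canonical name (or character vector of gene symbols)
#'   of the n-mutant, `n >= 2`.
#' @param strict Require all sub-levels synergistic too.
#' @param additive_epsilon Passed to [classify_pair()].
#' @return One-row tibble (an epistasis call): organism, combination, n,
#'   mode, category, phenotype_direction, experiment_key, evidence (named
#'   deltas used), violated_bipartition, detail_category.
#' @export
full_synergy <- function(group, combination, strict = FALSE,
                         additive_epsilon = 1e-9) {
  combination <- canonical_name(if (length(combination) == 1)
    gene_set(combination) else combination)
  genes <- gene_set(combination)
  if (length(genes) < 2) {
    abort("`combination` must contain at least two genes.")
  }
  deltas <- group_delta_table(group)
  call0 <- function(...) new_epistasis_call(group, combination, "full", ...)
  if (is.null(deltas) || !combination %in% names(deltas)) {
    return(call0("insufficient_data"))
  }
  needed <- c(proper_subsets(genes), combination)
  missing <- setdiff(needed, names(deltas))
  if (length(missing) > 0) {
    return(call0("insufficient_data"))
  }
  ev <- as.list(deltas[needed])

  if (length(genes) == 2) {
    res <- classify_pair(deltas[[genes[1]]], deltas[[genes[2]]],
                         deltas[[combination]], additive_epsilon)
    return(call0(res$category, res$phenotype_direction, evidence = ev))
  }

  sub_deltas <- deltas[setdiff(needed, combination)]
  signs <- unique(sign(sub_deltas))
  if (length(signs) != 1 || signs == 0) {
    return(call0("not_assessable_mixed_directions", evidence = ev))
  }
  dcomb <- deltas[[combination]]
  if (dcomb != 0 && sign(dcomb) != signs) {
    return(call0("antagonistic", "opposite", evidence = ev))
  }
  direction <- if (signs > 0) "long-lived" else "short-lived"

  parts <- bipartitions(genes)
  sums <- vapply(parts, function(p) abs(deltas[[p$left]]) + abs(deltas[[p$right]]),
                 numeric(1))
  violated <- abs(dcomb) <= sums
  if (strict) {
    sub_multi <- setdiff(needed, combination)
    sub_multi <- sub_multi[vapply(sub_multi, function(nm)
      length(gene_set(nm)) >= 2, logical(1))]
    sub_ok <- vapply(sub_multi, function(nm) {
      identical(full_synergy(group, nm, strict = TRUE,
                             additive_epsilon = additive_epsilon)$category,
                "synergistic")
    }, logical(1))
    if (!all(sub_ok)) {
      bad <- sub_multi[!sub_ok][1]
      return(call0("not_synergistic", direction, evidence = ev,
                   violated_bipartition = paste0("subset:", bad)))
    }
  }
  if (!any(violated)) {
    return(call0("synergistic", direction, evidence = ev))
  }
  worst <- which.max(sums)
  wp <- parts[[worst]]
  detail <- classify_pair(deltas[[wp$left]], deltas[[wp$right]], dcomb,
                          additive_epsilon)
  call0("not_synergistic", direction, evidence = ev,
        violated_bipartition = paste0(wp$left, "|", wp$right),
        detail_category = detail$category)
}

#' Approximate simple synergism of an n-mutant within one experiment
#'
#' The popular approximation: the combination's effect exceeds the sum of
#' the n single-gene effects. Only the single mutants and the final
#' n-mutant need to have been assayed, so a strong sub-group can mask a
#' dependency that only the intermediary mutants would reveal — compare
#' with [full_synergy()] on completed data.
#'
#' @inheritParams full_synergy
#' @return One-row epistasis-call tibble with category `synergistic`,
#'   `not_synergistic`, `not_assessable_mixed_directions` or
#'   `insufficient_data`.
#' @export
simple_synergy <- function(group, combination) {
  combination <- canonical_name(if (length(combination) == 1)
    gene_set(combination) else combination)
  genes <- gene_set(combination)
  if (length(genes) < 2) {
    abort("`combination` must contain at least two genes.")
  }
  deltas <- group_delta_table(group)
  call0 <- function(...) new_epistasis_call(group, combination, "simple", ...)
  needed <- c(genes, combination)
  if (is.null(deltas) || !all(needed %in% names(deltas))) {
    return(call0("insufficient_data"))
  }
  ev <- as.list(deltas[needed])
  singles <- deltas[genes]
  signs <- unique(sign(singles))
  if (length(signs) != 1 || signs == 0) {
    return(call0("not_assessable_mixed_directions", evidence = ev))
  }
  dcomb <- deltas[[combination]]
  if (dcomb != 0 && sign(dcomb) != signs) {
    return(call0("antagonistic", "opposite", evidence = ev))
  }
  direction <- if (signs > 0) "long-lived" else "short-lived"
  category <- if (abs(dcomb) > sum(abs(singles))) "synergistic" else "not_synergistic"
  call0(category, direction, evidence = ev)
}

# Orderings of `genes` whose every prefix (as a canonical name, or WT for
# the empty prefix) is in `present`; each complete ordering is one assayed
# construction path WT -> n-mutant. Deterministic: genes are added in
# canonical-name order at each step.
assayed_paths <- function(genes, present) {
  walk <- function(have, remaining) {
    if (length(remaining) == 0) {
      return(list(character(0)))
    }
    out <- list()
    for (g in remaining) {
      nxt <- canonical_name(c(have, g))
      if (nxt %in% present) {
        for (tail in walk(c(have, g), setdiff(remaining, g))) {
          out[[length(out) + 1]] <- c(g, tail)
        }
      }
    }
    out
  }
  if (!wt_name() %in% present) {
    return(list())
  }
  walk(character(0), sort_genes(genes))
}

sort_genes <- function(genes) {
  genes[order(tolower(genes), genes, method = "radix")]
}

#' Partially known monotonic epistasis along assayed paths
#'
#' An n-mutant can be built along `n!` orders of single interventions; only
#' the orders whose every intermediate strain was assayed in the same
#' experiment are checked. A path is monotonic-positive when every added
#' intervention strictly increases the lifespan of the previously
#' constructed mutant (monotonic-negative: strictly decreases; a tie within
#' `tie_tolerance` days counts as non-monotonic). One non-monotonic known
#' path means the combination contains dependency relationships.
#'
#' @inheritParams full_synergy
#' @param tie_tolerance Absolute lifespan difference (days) under which a
#'   step counts as a tie; default 0 (strict).
#' @return List with `combination`, `paths_known`, `paths_total` (`n!`) and
#'   `verdict` in `monotonic_positive`, `monotonic_negative`,
#'   `contains_dependency`, `no_known_path`.
#' @export
monotony <- function(group, combination, tie_tolerance = 0) {
  combination <- canonical_name(if (length(combination) == 1)
    gene_set(combination) else combination)
  genes <- gene_set(combination)
  n <- length(genes)
  if (n < 1) {
    abort("`combination` must contain at least one gene.")
  }
  ml <- model_lifespans(group)
  ls <- setNames(ml$lifespan_days, ml$canonical_name)
  res <- list(combination = combination, paths_known = 0L,
              paths_total = factorial(n), verdict = "no_known_path")
  if (!combination %in% names(ls)) {
    return(res)
  }
  paths <- assayed_paths(genes, names(ls))
  if (length(paths) == 0) {
    return(res)
  }
  res$paths_known <- length(paths)
  path_sign <- vapply(paths, function(p) {
    nodes <- c(wt_name(), vapply(seq_along(p), function(k)
      canonical_name(p[seq_len(k)]), character(1)))
    steps <- diff(unname(ls[nodes]))
    if (all(steps > tie_tolerance)) 1 else if (all(steps < -tie_tolerance)) -1 else 0
  }, numeric(1))
  res$verdict <- if (any(path_sign == 0)) {
    "contains_dependency"
  } else if (all(path_sign == 1)) {
    "monotonic_positive"
  } else if (all(path_sign == -1)) {
    "monotonic_negative"
  } else {
    # paths of both monotone signs cannot reach the same endpoint, but be
    # explicit rather than unreachable-by-assumption
    "contains_dependency"
  }
  res
}

#' Classify every multi-gene combination in a dataset
#'
#' Runs [full_synergy()], [simple_synergy()] or [monotony()] for each
#' (experiment, n-mutant) with `n >= 2`, per experiment group. Epistasis is
#' never inferred across experiments: lifespans vary too much between labs
#' and conditions, so each call uses a single group's data.
#'
#' @param x A `lifespan_dataset`.
#' @param mode `"full"`, `"simple"` or `"monotony"`.
#' @param min_n Smallest combination size to classify (default 2; monotony
#'   accepts 1).
#' @inheritParams full_synergy
#' @inheritParams monotony
#' @return Tibble of epistasis calls, one row per (combination, experiment).
#' @export
classify_dataset <- function(x, mode = c("full", "simple", "monotony"),
                             strict = FALSE, additive_epsilon = 1e-9,
                             tie_tolerance = 0, min_n = 2) {
  mode <- arg_match(mode)
  groups <- experiment_groups(x)
  calls <- lapply(groups, function(group) {
    combos <- unique(group$canonical_name[group$n >= min_n])
    if (length(combos) == 0) {
      return(NULL)
    }
    combos <- sort_genes(combos)
    rows <- lapply(combos, function(comb) {
      switch(mode,
        full = full_synergy(group, comb, strict = strict,
                            additive_epsilon = additive_epsilon),
        simple = simple_synergy(group, comb),
        monotony = {
          m <- monotony(group, comb, tie_tolerance = tie_tolerance)
          new_epistasis_call(
            group, comb, "monotony",
            category = m$verdict,
            phenotype_direction = NA_character_,
            evidence = list(paths_known = m$paths_known,
                            paths_total = m$paths_total)
          )
        }
      )
    })
    bind_rows(rows)
  })
  bind_rows(calls)
}

#' Aggregate epistasis calls across experiments
#'
#' A gene combination may be annotated with more than one epistatic
#' relationship when different studies report different results; the
#' summary is the union of informative categories with supporting
#' experiment counts, never a collapse to one. Combinations with only
#' insufficient-data calls are summarised as
#' `"Not enough data to assess"`.
#'
#' @param calls Tibble of epistasis calls (see [classify_dataset()]).
#' @return Tibble with organism, combination, category, n_experiments.
#' @export
aggregate_calls <- function(calls) {
  if (nrow(calls) == 0) {
    return(tibble(organism = character(0), combination = character(0),
                  category = character(0), n_experiments = integer(0)))
  }
  calls |>
    group_by(organism, combination) |>
    dplyr::group_modify(function(df, key) {
      informative <- df[!df$category %in% "insufficient_data", , drop = FALSE]
      if (nrow(informative) == 0) {
        return(tibble(category = "Not enough data to assess",
                      n_experiments = 0L))
      }
      informative |>
        count(category, name = "n_experiments") |>
        mutate(n_experiments = as.integer(n_experiments))
    }) |>
    ungroup()
}
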