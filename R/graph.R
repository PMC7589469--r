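# The intervention graph: strains as nodes, one added gene intervention per
# edge, plus display effect-intervals, path enumeration, network export and
# database summary tables.

#' Effect interval of a combination across all experiments
#'
#' Per experiment with an in-group wild type, the combination's percent
#' effect against that control. For experiments without their own wild
#' type, two bracketing effects are produced against the minimum and
#' maximum wild-type lifespan recorded for the species — restricted to the
#' mutant's temperature stratum when its temperature is recorded and WT
#' data exist there (`temperature_stratified = FALSE` always pools). The
#' interval is the min/max over all produced effects.
#'
#' @param x A `lifespan_dataset`.
#' @param combination Canonical name or gene vector.
#' @param organism Organism to restrict to; default: the single organism
#'   observed for the combination.
#' @param temperature_stratified Stratify the WT fallback by temperature.
#' @return List with `combination`, `min_percent`, `max_percent`,
#'   `n_experiments`, and `deltas` (all produced effects).
#' @export
effect_interval <- function(x, combination, organism = NULL,
                            temperature_stratified = TRUE) {
  combination <- canonical_name(if (length(combination) == 1)
    gene_set(combination) else combination)
  df <- as_tibble(x)
  rows <- df[df$canonical_name == combination, , drop = FALSE]
  if (!is.null(organism)) {
    rows <- rows[rows$organism == organism, , drop = FALSE]
  } else if (nrow(rows) > 0) {
    organism <- rows$organism[1]
    rows <- rows[rows$organism == organism, , drop = FALSE]
  }
  if (nrow(rows) == 0) {
    abort(paste0("No observations for combination: ", combination))
  }
  wt_pool <- df[df$organism == organism & df$n == 0, , drop = FALSE]
  keys <- unique(rows$experiment_key)
  deltas <- unlist(lapply(keys, function(key) {
    group <- df[df$experiment_key == key & df$organism == organism, , drop = FALSE]
    ml <- model_lifespans(group)
    m <- ml$lifespan_days[ml$canonical_name == combination]
    wt_in <- ml$lifespan_days[ml$n == 0]
    if (length(wt_in) == 1) {
      return(delta_percent(m, wt_in))
    }
    if (nrow(wt_pool) == 0) {
      return(numeric(0))
    }
    pool <- wt_pool
    temp <- rows$temperature_c[rows$experiment_key == key][1]
    if (temperature_stratified && !is.na(temp)) {
      strat <- pool[!is.na(pool$temperature_c) & pool$temperature_c == temp, ,
                    drop = FALSE]
      if (nrow(strat) > 0) pool <- strat
    }
    c(delta_percent(m, max(pool$lifespan_days)),
      delta_percent(m, min(pool$lifespan_days)))
  }))
  if (length(deltas) == 0) {
    abort(paste0("No wild-type reference available for: ", combination))
  }
  list(
    combination = combination,
    min_percent = min(deltas),
    max_percent = max(deltas),
    n_experiments = length(keys),
    deltas = deltas
  )
}

#' Build the wild-type-to-n-mutant intervention graph
#'
#' One node per distinct strain of the organism; a directed edge links a
#' k-mutant to a (k+1)-mutant whose gene set adds exactly one gene, when
#' both strains are observed anywhere in the dataset (the network
#' aggregates studies; per-experiment subsets are used for monotony, not
#' here). Nodes carry the record count, mean percent effect, effect
#' interval and a colour hint (green = long-lived, red = short-lived,
#' intensity proportional to the mean effect magnitude).
#'
#' @param x A `lifespan_dataset`.
#' @param organism One of `"C. elegans"`, `"D. melanogaster"`,
#'   `"M. musculus"`.
#' @inheritParams effect_interval
#' @return An `igraph` directed acyclic graph; vertex names are canonical
#'   strain names.
#' @export
build_graph <- function(x, organism, temperature_stratified = TRUE) {
  if (!organism %in% ORGANISMS) {
    abort(paste0("Unknown organism: ", organism))
  }
  df <- as_tibble(x)
  df <- df[df$organism == organism, , drop = FALSE]
  if (nrow(df) == 0) {
    abort(paste0("No observations for organism: ", organism))
  }
  nodes <- df |>
    group_by(canonical_name, n) |>
    summarise(n_records = dplyr::n(), .groups = "drop") |>
    arrange(n, canonical_name)

  intervals <- lapply(nodes$canonical_name, function(nm) {
    if (nm == wt_name()) {
      return(list(mean_delta = 0, min_percent = 0, max_percent = 0))
    }
    iv <- tryCatch(
      effect_interval(df, nm, organism = organism,
                      temperature_stratified = temperature_stratified),
      error = function(e) NULL
    )
    if (is.null(iv)) {
      return(list(mean_delta = NA_real_, min_percent = NA_real_,
                  max_percent = NA_real_))
    }
    list(mean_delta = mean(iv$deltas), min_percent = iv$min_percent,
         max_percent = iv$max_percent)
  })
  nodes$mean_delta_percent <- vapply(intervals, function(i) i$mean_delta, numeric(1))
  nodes$min_percent <- vapply(intervals, function(i) i$min_percent, numeric(1))
  nodes$max_percent <- vapply(intervals, function(i) i$max_percent, numeric(1))
  nodes$color_hint <- ifelse(
    is.na(nodes$mean_delta_percent) | nodes$mean_delta_percent == 0, "neutral",
    ifelse(nodes$mean_delta_percent > 0, "green", "red")
  )
  max_abs <- max(abs(nodes$mean_delta_percent), na.rm = TRUE)
  nodes$color_intensity <- if (is.finite(max_abs) && max_abs > 0) {
    ifelse(is.na(nodes$mean_delta_percent), 0,
           abs(nodes$mean_delta_percent) / max_abs)
  } else {
    0
  }

  present <- nodes$canonical_name
  edges <- bind_rows(lapply(present, function(nm) {
    gs <- gene_set(nm)
    if (length(gs) == 0) {
      return(NULL)
    }
    parents <- vapply(gs, function(g) canonical_name(setdiff(gs, g)), character(1))
    added <- gs[parents %in% present]
    parents <- parents[parents %in% present]
    if (length(parents) == 0) {
      return(NULL)
    }
    tibble(from = parents, to = nm, added_gene = added)
  }))
  if (is.null(edges) || nrow(edges) == 0) {
    edges <- tibble(from = character(0), to = character(0),
                    added_gene = character(0))
  }
  g <- igraph::graph_from_data_frame(
    edges,
    directed = TRUE,
    vertices = nodes |>
      rename(name = canonical_name) |>
      select(name, n, n_records, mean_delta_percent, min_percent,
             max_percent, color_hint, color_intensity)
  )
  igraph::graph_attr(g, "organism") <- organism
  g
}

#' Enumerate construction paths between two strains
#'
#' All directed paths from `source` to `target` in the intervention graph;
#' on a complete Boolean lattice from wild type to an n-mutant there are
#' `n!` of them. Ordering is deterministic (the gene added at each step, in
#' canonical order). `source == target` yields the single empty path.
#'
#' @param graph An intervention graph from [build_graph()].
#' @param source,target Canonical strain names; `source`'s gene set must be
#'   a subset of `target`'s.
#' @return List of paths, each a character vector of node names from
#'   `source` to `target` inclusive; empty list when unreachable.
#' @export
enumerate_paths <- function(graph, source = wt_name(), target) {
  nodes <- igraph::V(graph)$name
  if (!source %in% nodes || !target %in% nodes) {
    return(list())
  }
  sg <- gene_set(source)
  tg <- gene_set(target)
  if (!all(sg %in% tg)) {
    abort("`source` gene set must be a subset of `target`'s.")
  }
  walk <- function(have, name_have) {
    if (setequal(have, tg)) {
      return(list(name_have))
    }
    out <- list()
    for (g in sort_genes(setdiff(tg, have))) {
      nxt <- canonical_name(c(have, g))
      if (nxt %in% nodes &&
          igraph::are_adjacent(graph, name_have[length(name_have)], nxt)) {
        for (p in walk(c(have, g), c(name_have, nxt))) {
          out[[length(out) + 1]] <- p
        }
      }
    }
    out
  }
  walk(sg, source)
}

#' Export an intervention graph
#'
#' Writes either a Cytoscape.js elements JSON document or GraphML (typed
#' attribute keys, via igraph's writer). Nodes carry label, intervention
#' count, mean percent effect, record count, colour hint/intensity and a
#' display size proportional to the record count; edges carry the added
#' gene.
#'
#' @param graph An intervention graph from [build_graph()].
#' @param path Output file.
#' @param format `"cytoscape-json"` or `"graphml"`.
#' @return `path`, invisibly.
#' @export
export_network <- function(graph, path, format = c("cytoscape-json", "graphml")) {
  format <- arg_match(format)
  v <- igraph::as_data_frame(graph, what = "vertices")
  e <- igraph::as_data_frame(graph, what = "edges")
  max_rec <- max(v$n_records)
  v$size <- 10 + 30 * v$n_records / max_rec
  if (format == "graphml") {
    igraph::V(graph)$size <- v$size
    igraph::write_graph(graph, path, format = "graphml")
    return(invisible(path))
  }
  nodes <- lapply(seq_len(nrow(v)), function(i) {
    list(data = list(
      id = v$name[i],
      label = v$name[i],
      n = v$n[i],
      mean_delta_percent = v$mean_delta_percent[i],
      n_records = v$n_records[i],
      color_hint = v$color_hint[i],
      color_intensity = v$color_intensity[i],
      size = v$size[i]
    ))
  })
  edges <- lapply(seq_len(nrow(e)), function(i) {
    list(data = list(
      id = paste0("e", i),
      source = e$from[i],
      target = e$to[i],
      added_gene = e$added_gene[i]
    ))
  })
  doc <- list(elements = list(nodes = nodes, edges = edges))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  invisible(path)
}

# TRUE when some experiment group contains every strain named in `needed`.
evaluable_in_some_group <- function(groups_models, needed) {
  any(vapply(groups_models, function(present) all(needed %in% present),
             logical(1)))
}

#' Summary tables of a lifespan-records database
#'
#' Computes (i) record counts per organism — lifespan values, multi-gene
#' combinations, distinct genes in multi-gene combinations and articles —
#' with row-sum totals; (ii) the cross-tabulation of five-way epistasis
#' calls (full evaluation of 2-mutants, one call per combination and
#' experiment) by phenotype direction and category; (iii) evaluability
#' counts: for how many distinct 2-mutants full synergism and monotony can
#' be computed in at least one experiment, the same for `n >= 3` mutants
#' under full, simple and monotony modes, and the opposite-direction
#' statistics (doubles with complete data whose single effects disagree in
#' sign).
#'
#' @param x A `lifespan_dataset`.
#' @inheritParams full_synergy
#' @return List with tibbles `table1`, `table2`, `higher_order`, and
#'   `opposite_direction`.
#' @export
summarize_database <- function(x, additive_epsilon = 1e-9) {
  df <- as_tibble(x)
  orgs <- intersect(ORGANISMS, unique(df$organism))

  per_org <- lapply(orgs, function(org) {
    d <- df[df$organism == org, , drop = FALSE]
    multi <- d[d$n >= 2, , drop = FALSE]
    genes_multi <- unique(unlist(lapply(unique(multi$canonical_name), gene_set)))
    tibble(
      organism = org,
      lifespan_values = nrow(d),
      gene_combinations = n_distinct(multi$canonical_name),
      genes = length(genes_multi),
      articles = n_distinct(d$study_id)
    )
  })
  table1 <- bind_rows(per_org)
  table1 <- bind_rows(table1, tibble(
    organism = "Total",
    lifespan_values = sum(table1$lifespan_values),
    gene_combinations = sum(table1$gene_combinations),
    genes = sum(table1$genes),
    articles = sum(table1$articles)
  ))

  calls2 <- classify_dataset(df, mode = "full",
                             additive_epsilon = additive_epsilon, min_n = 2)
  calls2 <- calls2[calls2$n == 2, , drop = FALSE]
  informative <- calls2[calls2$category %in%
    c("synergistic", "additive", "almost_additive", "dependent",
      "antagonistic"), , drop = FALSE]
  table2 <- informative |>
    count(organism, phenotype_direction, category, name = "n_calls") |>
    arrange(organism, phenotype_direction, category)

  complete2 <- calls2[calls2$category != "insufficient_data", , drop = FALSE]
  mixed <- complete2[complete2$category == "not_assessable_mixed_directions", ,
                     drop = FALSE]
  mixed_dir <- vapply(seq_len(nrow(mixed)), function(i) {
    ev <- mixed$evidence[[i]]
    d12 <- ev[[mixed$combination[i]]]
    if (is.null(d12) || d12 == 0) "neutral" else if (d12 > 0) "long-lived" else "short-lived"
  }, character(1))
  opposite_direction <- tibble(
    long_lived = sum(mixed_dir == "long-lived"),
    short_lived = sum(mixed_dir == "short-lived"),
    complete_2mutant_calls = nrow(complete2),
    percent_of_complete = if (nrow(complete2) > 0) {
      100 * nrow(mixed) / nrow(complete2)
    } else {
      NA_real_
    }
  )

  groups <- experiment_groups(df)
  groups_models <- lapply(groups, function(g) unique(g$canonical_name))
  groups_org <- vapply(groups, function(g) g$organism[1], character(1))
  combos <- df[df$n >= 2, , drop = FALSE] |>
    distinct(organism, canonical_name, n)
  eval_row <- function(nm, org) {
    genes <- gene_set(nm)
    keys_with <- groups_models[groups_org == org &
                                 vapply(groups_models, function(p) nm %in% p,
                                        logical(1))]
    full_ok <- evaluable_in_some_group(
      keys_with, c(wt_name(), proper_subsets(genes), nm))
    simple_ok <- evaluable_in_some_group(keys_with, c(wt_name(), genes, nm))
    mono_ok <- any(vapply(keys_with, function(present) {
      length(assayed_paths(genes, present)) > 0
    }, logical(1)))
    c(full = full_ok, simple = simple_ok, monotony = mono_ok)
  }
  if (nrow(combos) > 0) {
    evals <- mapply(eval_row, combos$canonical_name, combos$organism)
    combos$full_evaluable <- evals["full", ]
    combos$simple_evaluable <- evals["simple", ]
    combos$monotony_evaluable <- evals["monotony", ]
  } else {
    combos$full_evaluable <- logical(0)
    combos$simple_evaluable <- logical(0)
    combos$monotony_evaluable <- logical(0)
  }
  higher_order <- combos |>
    mutate(degree = ifelse(n == 2, "2", "3+")) |>
    group_by(degree) |>
    summarise(
      combinations = dplyr::n(),
      full_evaluable = sum(full_evaluable),
      simple_evaluable = sum(simple_evaluable),
      monotony_evaluable = sum(monotony_evaluable),
      .groups = "drop"
    )

  list(
    table1 = table1,
    table2 = table2,
    higher_order = higher_order,
    opposite_direction = opposite_direction
  )
}
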