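test_that("percent lifespan effects follow the delta formula", {
  expect_identical(delta_percent(40, 20), 100)
  expect_identical(delta_percent(20, 20), 0)
  expect_identical(delta_percent(15, 20), -25)
  expect_error(delta_percent(-1, 20), "positive")
  expect_error(delta_percent(20, 0), "positive")
})

test_that("the pair classifier reproduces the five-way rules", {
  cat_of <- function(...) classify_pair(...)$category
  expect_identical(cat_of(30, 20, 60), "synergistic")
  expect_identical(classify_pair(30, 20, 60)$phenotype_direction, "long-lived")
  expect_identical(cat_of(30, 20, 50), "additive")
  expect_identical(cat_of(30, 20, 40), "almost_additive")
  expect_identical(cat_of(30, 20, 25), "dependent")
  expect_identical(cat_of(30, 20, 10), "antagonistic")
  # boundary equalities: the dependent band is closed
  expect_identical(cat_of(30, 20, 30), "dependent")
  expect_identical(cat_of(30, 20, 20), "dependent")
  # double flipped against the shared direction
  flipped <- classify_pair(30, 20, -5)
  expect_identical(flipped$category, "antagonistic")
  expect_identical(flipped$phenotype_direction, "opposite")
  # mixed or zero single directions are not assessable
  expect_identical(cat_of(30, -20, 10), "not_assessable_mixed_directions")
  expect_identical(cat_of(0, 20, 10), "not_assessable_mixed_directions")
  # magnitude rules for short-lived phenotypes
  short <- classify_pair(-30, -20, -60)
  expect_identical(short$category, "synergistic")
  expect_identical(short$phenotype_direction, "short-lived")
  expect_identical(cat_of(-30, -20, -25), "dependent")
  expect_identical(classify_pair(NA, 20, 10)$category, "insufficient_data")
})

test_that("the pair classifier is symmetric and assigns exactly one category", {
  withr::with_seed(21, {
    for (i in 1:200) {
      d1 <- runif(1, -90, 150)
      d2 <- runif(1, -90, 150)
      d12 <- runif(1, -90, 250)
      expect_identical(classify_pair(d1, d2, d12), classify_pair(d2, d1, d12))
    }
  })
  five <- c("synergistic", "additive", "almost_additive", "dependent",
            "antagonistic")
  sweep <- vapply(seq(0.5, 200, by = 0.5), function(d12) {
    classify_pair(30, 20, d12)$category
  }, character(1))
  expect_true(all(sweep %in% five))
})

test_that("epistasis calls are invariant to rescaling all lifespans", {
  withr::with_seed(31, {
    for (i in 1:10) {
      deltas <- c(g1 = runif(1, 5, 60), g2 = runif(1, 5, 60),
                  g3 = runif(1, 5, 60))
      deltas[["g1;g2"]] <- runif(1, 5, 150)
      deltas[["g1;g3"]] <- runif(1, 5, 150)
      deltas[["g2;g3"]] <- runif(1, 5, 150)
      deltas[["g1;g2;g3"]] <- runif(1, 5, 200)
      scale <- runif(1, 0.1, 10)
      g_base <- first_group(make_delta_dataset(20, deltas))
      g_scaled <- g_base
      g_scaled$lifespan_days <- g_scaled$lifespan_days * scale
      for (comb in c("g1;g2", "g1;g2;g3")) {
        expect_identical(full_synergy(g_base, comb)$category,
                         full_synergy(g_scaled, comb)$category)
        expect_identical(simple_synergy(g_base, comb)$category,
                         simple_synergy(g_scaled, comb)$category)
        expect_identical(monotony(g_base, comb)$verdict,
                         monotony(g_scaled, comb)$verdict)
      }
    }
  })
})

test_that("full synergism for a triple matches brute-force bipartition enumeration", {
  deltas <- c(g1 = 10, g2 = 20, g3 = 30,
              `g1;g2` = 35, `g1;g3` = 45, `g2;g3` = 55)

  # independent oracle: enumerate the three bipartitions directly
  oracle_full <- function(d123) {
    sums <- c(deltas["g1"] + deltas["g2;g3"],
              deltas["g2"] + deltas["g1;g3"],
              deltas["g3"] + deltas["g1;g2"])
    all(abs(d123) > sums)
  }
  expect_true(oracle_full(90))  # all three bipartition sums are 65
  expect_false(oracle_full(64)) # violates {g1},{g2;g3}: 10 + 55 = 65 > 64

  g90 <- first_group(make_delta_dataset(20, c(deltas, `g1;g2;g3` = 90)))
  expect_identical(full_synergy(g90, "g1;g2;g3")$category, "synergistic")

  g64 <- first_group(make_delta_dataset(20, c(deltas, `g1;g2;g3` = 64)))
  call64 <- full_synergy(g64, "g1;g2;g3")
  expect_identical(call64$category, "not_synergistic")
  expect_match(call64$violated_bipartition, "\\|")

  # completeness requirement: a missing pair voids the evaluation
  gmiss <- first_group(make_delta_dataset(
    20, c(deltas[setdiff(names(deltas), "g2;g3")], `g1;g2;g3` = 90)
  ))
  expect_identical(full_synergy(gmiss, "g1;g2;g3")$category, "insufficient_data")
  expect_identical(full_synergy(gmiss, "g4;g5")$category, "insufficient_data")
})

test_that("full synergism on pairs reduces to the pair classifier", {
  withr::with_seed(41, {
    for (i in 1:50) {
      d1 <- runif(1, -80, 120)
      d2 <- runif(1, -80, 120)
      d12 <- runif(1, -80, 250)
      g <- first_group(make_delta_dataset(20, c(gA = d1, gB = d2, `gA;gB` = d12)))
      call <- full_synergy(g, "gA;gB")
      ref <- classify_pair(d1, d2, d12)
      expect_identical(call$category, ref$category)
      expect_identical(call$phenotype_direction, ref$phenotype_direction)
    }
  })
})

test_that("simple synergism needs only singles and the combination", {
  singles <- c(g1 = 10, g2 = 20, g3 = 30)
  g_yes <- first_group(make_delta_dataset(20, c(singles, `g1;g2;g3` = 90)))
  expect_identical(simple_synergy(g_yes, "g1;g2;g3")$category, "synergistic")
  # even though every pair is missing, full synergism is not evaluable
  expect_identical(full_synergy(g_yes, "g1;g2;g3")$category, "insufficient_data")

  g_no <- first_group(make_delta_dataset(20, c(singles, `g1;g2;g3` = 55)))
  expect_identical(simple_synergy(g_no, "g1;g2;g3")$category, "not_synergistic")

  g_missing <- first_group(make_delta_dataset(20, c(singles[-1], `g1;g2;g3` = 90)))
  expect_identical(simple_synergy(g_missing, "g1;g2;g3")$category,
                   "insufficient_data")
})

test_that("flexible full synergism can hold without simple synergism; strict cannot", {
  # All pairs dependent (5 < each single sum of 20), yet 16 beats every
  # bipartition sum of 15 -- synergy only at the top level.
  deltas <- c(g1 = 10, g2 = 10, g3 = 10,
              `g1;g2` = 5, `g1;g3` = 5, `g2;g3` = 5, `g1;g2;g3` = 16)
  g <- first_group(make_delta_dataset(20, deltas))
  expect_identical(full_synergy(g, "g1;g2;g3")$category, "synergistic")
  expect_identical(simple_synergy(g, "g1;g2;g3")$category, "not_synergistic")
  strict <- full_synergy(g, "g1;g2;g3", strict = TRUE)
  expect_identical(strict$category, "not_synergistic")
  expect_match(strict$violated_bipartition, "^subset:")
})

test_that("monotony follows assayed paths and flags dependencies", {
  # only the path through g1 is assayed; it strictly increases
  g <- first_group(make_dataset(c(WT = 20, g1 = 25, `g1;g2` = 30)))
  m <- monotony(g, "g1;g2")
  expect_identical(m$verdict, "monotonic_positive")
  expect_identical(m$paths_known, 1L)
  expect_identical(m$paths_total, 2)

  # the path through g2 dips below its predecessor: dependency
  g2 <- first_group(make_dataset(c(WT = 20, g1 = 25, g2 = 22, `g1;g2` = 24)))
  expect_identical(monotony(g2, "g1;g2")$verdict, "contains_dependency")

  gdown <- first_group(make_dataset(c(WT = 20, g1 = 15, `g1;g2` = 12)))
  expect_identical(monotony(gdown, "g1;g2")$verdict, "monotonic_negative")

  gnone <- first_group(make_dataset(c(WT = 20, `g1;g2` = 30)))
  expect_identical(monotony(gnone, "g1;g2")$verdict, "no_known_path")

  # an exact tie is non-monotonic at the default tolerance
  gtie <- first_group(make_dataset(c(WT = 20, g1 = 25, `g1;g2` = 25)))
  expect_identical(monotony(gtie, "g1;g2")$verdict, "contains_dependency")

  # a single fully-assayed increasing chain on a 4-mutant, siblings unassayed
  chain <- make_dataset(c(WT = 20, g1 = 24, `g1;g2` = 28, `g1;g2;g3` = 33,
                          `g1;g2;g3;g4` = 40))
  m4 <- monotony(first_group(chain), "g1;g2;g3;g4")
  expect_identical(m4$verdict, "monotonic_positive")
  expect_identical(m4$paths_known, 1L)
  expect_identical(m4$paths_total, 24)
})

test_that("monotony agrees with a brute-force permutation oracle", {
  withr::with_seed(53, {
    genes <- c("a", "b", "c", "d")
    for (i in 1:25) {
      subsets <- unlist(lapply(1:4, function(k) {
        combn(genes, k, FUN = canonical_name, simplify = FALSE)
      }))
      present <- c("WT", unlist(subsets)[runif(15) < 0.6], "a;b;c;d")
      ls <- setNames(round(runif(length(present), 10, 40), 1), present)
      ls <- ls[!duplicated(names(ls))]
      ds <- make_dataset(ls)
      m <- monotony(first_group(ds), "a;b;c;d")
      ml <- setNames(
        tibble::as_tibble(ds)$lifespan_days, tibble::as_tibble(ds)$canonical_name
      )
      expect_identical(m$verdict, oracle_monotony(genes, ml))
      expect_identical(m$paths_known,
                       oracle_path_count(genes, names(ml)))
    }
  })
})

test_that("same-direction pair categories align with monotony verdicts", {
  withr::with_seed(61, {
    for (i in 1:60) {
      d1 <- runif(1, 1, 80)
      d2 <- runif(1, 1, 80)
      d12 <- runif(1, 1, 200)
      g <- first_group(make_delta_dataset(20, c(gA = d1, gB = d2, `gA;gB` = d12)))
      cat <- full_synergy(g, "gA;gB")$category
      verdict <- monotony(g, "gA;gB")$verdict
      if (cat %in% c("synergistic", "additive", "almost_additive")) {
        expect_identical(verdict, "monotonic_positive")
      }
      if (cat == "antagonistic") {
        expect_identical(verdict, "contains_dependency")
      }
    }
  })
})

test_that("calls aggregate as a union of categories across experiments", {
  ds <- as_lifespan_dataset(dplyr::bind_rows(
    obs_row("WT", 20, "S1"), obs_row("g1", 26, "S1"), obs_row("g2", 24, "S1"),
    obs_row("g1;g2", 25, "S1"),   # dependent
    obs_row("WT", 20, "S2"), obs_row("g1", 26, "S2"), obs_row("g2", 24, "S2"),
    obs_row("g1;g2", 25.5, "S2"), # dependent again
    obs_row("WT", 20, "S3"), obs_row("g1", 26, "S3"), obs_row("g2", 24, "S3"),
    obs_row("g1;g2", 35, "S3"),   # synergistic
    obs_row("WT", 20, "S4"), obs_row("g1;g3", 30, "S4") # no data to assess
  ))
  agg <- aggregate_calls(classify_dataset(ds, mode = "full"))
  pair <- agg[agg$combination == "g1;g2", ]
  expect_setequal(pair$category, c("dependent", "synergistic"))
  expect_identical(pair$n_experiments[pair$category == "dependent"], 2L)
  expect_identical(pair$n_experiments[pair$category == "synergistic"], 1L)
  other <- agg[agg$combination == "g1;g3", ]
  expect_identical(other$category, "Not enough data to assess")
})
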