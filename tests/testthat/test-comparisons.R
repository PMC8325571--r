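# Reciprocal-monophyly extraction, polarization, pathogen filtering and
# MAG species-bin comparisons.

test_that("anchor rule finds exactly the forced comparisons", {
  at <- make_at("((g1:1,g2:1):1,(o1:1,o2:1):1);",
                c("gut", "gut", "oral", "oral"))
  comps <- find_independent_comparisons(at)
  expect_equal(nrow(comps), 1)
  expect_setequal(comps$gut_tips[[1]], c("g1", "g2"))
  expect_setequal(comps$nongut_tips[[1]], c("o1", "o2"))
  expect_equal(comps$stratum, "oral")

  # relabel g2 as oral: the root sees a mixed child, only the cherry
  # (g1, g2) anchors
  at2 <- make_at("((g1:1,g2:1):1,(o1:1,o2:1):1);",
                 c("gut", "oral", "oral", "oral"))
  comps2 <- find_independent_comparisons(at2)
  expect_equal(nrow(comps2), 1)
  expect_equal(comps2$gut_tips[[1]], "g1")
  expect_equal(comps2$nongut_tips[[1]], "g2")

  # two qualifying cherries in different genera: two tip-disjoint
  # comparisons
  at3 <- make_at("((g1:1,o1:1):1,(g2:1,o2:1):1);",
                 c("gut", "oral", "gut", "oral"),
                 genus = c("A", "A", "B", "B"))
  comps3 <- find_independent_comparisons(at3)
  expect_equal(nrow(comps3), 2)
  expect_length(unique(unlist(c(comps3$gut_tips, comps3$nongut_tips))), 4)
  # ... but the shared root cannot anchor when genus is required and
  # genera differ, and can when the requirement is dropped
  expect_equal(comps3$genus, c("A", "B"))

  # conspecific level needs a shared species label
  at4 <- make_at("((g1:1,o1:1):1,x:1);", c("gut", "oral", "skin"),
                 species = c("s1", "s1", "s2"))
  expect_equal(nrow(find_independent_comparisons(at4, "conspecific")), 1)
  at5 <- make_at("((g1:1,o1:1):1,x:1);", c("gut", "oral", "skin"),
                 species = c("s1", "s2", "s3"))
  expect_equal(nrow(find_independent_comparisons(at5, "conspecific")), 0)
})

test_that("multifurcations pool pure children and reject mixed ones", {
  # all children pure: gut children pooled against non-gut children
  at <- make_at("(g1:1,g2:1,o1:1,o2:1);", c("gut", "gut", "oral", "skin"))
  comps <- find_independent_comparisons(at)
  expect_equal(nrow(comps), 1)
  expect_setequal(comps$gut_tips[[1]], c("g1", "g2"))
  expect_setequal(comps$nongut_tips[[1]], c("o1", "o2"))
  expect_equal(comps$stratum, "mixed")

  # a mixed child disqualifies the node even if other children are pure
  at2 <- make_at("((g1:1,o1:1):1,g2:1,o2:1);",
                 c("gut", "oral", "gut", "oral"))
  comps2 <- find_independent_comparisons(at2)
  expect_equal(nrow(comps2), 1)  # only the (g1, o1) cherry
  expect_equal(comps2$gut_tips[[1]], "g1")
})

test_that("polarization reads the anchor's sister context", {
  at <- make_at("(((g1:1,o1:1):1,o2:1):1,o3:1);",
                c("gut", "oral", "oral", "oral"))
  comps <- polarize_comparisons(at, find_independent_comparisons(at))
  expect_equal(comps$polarity, "gut_derived")

  at2 <- make_at("(((g1:1,o1:1):1,g2:1):1,g3:1);",
                 c("gut", "oral", "gut", "gut"))
  comps2 <- polarize_comparisons(at2, find_independent_comparisons(at2))
  expect_equal(comps2$polarity, "nongut_derived")

  # mixed sister clade leaves the comparison unpolarized
  at3 <- make_at("((g1:1,o1:1):1,(g2:1,o2:1):1);",
                 c("gut", "oral", "gut", "oral"),
                 genus = c("A", "A", "B", "B"))
  comps3 <- polarize_comparisons(at3, find_independent_comparisons(at3))
  expect_equal(comps3$polarity, c("unpolarized", "unpolarized"))

  # root anchor has no outgroup
  at4 <- make_at("((g1:1,g2:1):1,(o1:1,o2:1):1);",
                 c("gut", "gut", "oral", "oral"))
  comps4 <- polarize_comparisons(at4, find_independent_comparisons(at4))
  expect_equal(comps4$polarity, "unpolarized")
})

test_that("pathogen filter excludes whole comparisons by member flags", {
  # 21 cherry comparisons in 21 genera, flags on tips of 2 of them
  nw <- paste0("(", paste(sprintf("(g%d:1,o%d:1):1", 1:21, 1:21),
                          collapse = ","), ");")
  hab <- stats::setNames(rep(c("gut", "oral"), 21),
                         c(sprintf("g%d", 1:21), sprintf("o%d", 1:21)))
  tree <- ape::read.tree(text = nw)
  rec <- make_records(tree$tip.label, hab[tree$tip.label],
                      genus = paste0("G", gsub("\\D", "", tree$tip.label)))
  rec$pathogen_flag <- rec$tip_id %in% c("g3", "o17")
  at <- join_tree_metadata(tree, rec)
  comps <- find_independent_comparisons(at)
  expect_equal(nrow(comps), 21)
  part <- filter_pathogen_comparisons(comps, at$tips)
  expect_equal(nrow(part$retained), 19)
  expect_equal(nrow(part$excluded), 2)

  rec$pathogen_flag <- FALSE
  part2 <- filter_pathogen_comparisons(comps,
                                       validate_tip_metadata(rec))
  expect_equal(nrow(part2$excluded), 0)
  rec$pathogen_flag <- TRUE
  part3 <- filter_pathogen_comparisons(comps,
                                       validate_tip_metadata(rec))
  expect_equal(nrow(part3$retained), 0)
})

test_that("MAG species-bin comparisons apply strict quality filters", {
  mags <- data.frame(
    bin_id = sprintf("b%d", 1:6),
    species_bin = c("S1", "S1", "S1", "S2", "S2", "S1"),
    habitat = c("gut", "gut", "oral", "gut", "gut", "skin"),
    completeness = c(95, 97, 93, 96, 99, 90),
    genome_size = rep(2e6, 6), stringsAsFactors = FALSE)
  comps <- mag_species_comparisons(mags, min_completeness = 90)
  # S2 is gut-only; b6 at exactly 90 is excluded by the strict filter
  expect_equal(nrow(comps), 1)
  expect_equal(comps$comparison_id, "S1")
  expect_setequal(comps$gut_tips[[1]], c("b1", "b2"))
  expect_setequal(comps$nongut_tips[[1]], "b3")
  expect_false("b6" %in% unlist(comps$nongut_tips))
  expect_equal(comps$level, "mag_species")

  # contamination ceiling is strict too
  mags$contamination <- c(1, 1, 5, 1, 1, 1)
  comps2 <- mag_species_comparisons(mags, 90, max_contamination = 5)
  expect_equal(nrow(comps2), 0)

  expect_equal(nrow(mag_species_comparisons(mags[0, , drop = FALSE])), 0)
})

test_that("extraction matches a brute-force node predicate and stays tip-disjoint", {
  set.seed(41)
  for (rep in 1:200) {
    at <- random_at(n_tips = sample(4:10, 1))
    comps <- find_independent_comparisons(at)
    # tip-disjointness
    all_tips <- unlist(c(comps$gut_tips, comps$nongut_tips))
    expect_equal(anyDuplicated(all_tips), 0)
    # brute-force oracle: same anchors and the same tip sets
    oracle <- brute_force_comparisons(at)
    expect_equal(nrow(comps), length(oracle))
    if (nrow(comps)) {
      o <- oracle[order(vapply(oracle, `[[`, numeric(1), "anchor"))]
      c2 <- comps[order(comps$anchor_node), , drop = FALSE]
      for (i in seq_along(o)) {
        expect_equal(sort(c2$gut_tips[[i]]), o[[i]]$gut)
        expect_equal(sort(c2$nongut_tips[[i]]), o[[i]]$nongut)
      }
    }
    # anchor minimality: no descendant of an anchor can itself anchor,
    # because anchors require both habitats below (children are pure)
    expect_true(all(comps$n_gut >= 1 & comps$n_nongut >= 1))
  }
})

test_that("extraction is equivariant under tip relabeling", {
  set.seed(42)
  at <- random_at(12)
  comps <- find_independent_comparisons(at)
  perm <- stats::setNames(sprintf("z%02d", sample(12)), at$tree$tip.label)
  tree2 <- at$tree
  tree2$tip.label <- unname(perm[tree2$tip.label])
  rec2 <- at$tips
  rec2$tip_id <- unname(perm[rec2$tip_id])
  comps2 <- find_independent_comparisons(join_tree_metadata(tree2, rec2))
  expect_equal(nrow(comps2), nrow(comps))
  expect_equal(comps2$anchor_node, comps$anchor_node)
  for (i in seq_len(nrow(comps))) {
    expect_setequal(comps2$gut_tips[[i]], unname(perm[comps$gut_tips[[i]]]))
    expect_setequal(comps2$nongut_tips[[i]],
                    unname(perm[comps$nongut_tips[[i]]]))
  }
})

test_that("tip-disjointness holds across simulated cohorts", {
  for (s in 1:25) {
    co <- simulate_cohort(simulation_config(n_tips = 40, seed = s))
    comps <- find_independent_comparisons(co$tree)
    all_tips <- unlist(c(comps$gut_tips, comps$nongut_tips))
    expect_equal(anyDuplicated(all_tips), 0)
  }
})
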