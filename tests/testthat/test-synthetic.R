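# The synthetic-cohort generator: trees, habitat histories, trend-BM
# sizes, observation model, and full-cohort determinism.

test_that("Yule trees are ultrametric and seed-deterministic", {
  t2 <- simulate_tree(2, 1, seed = 1)
  expect_equal(length(t2$tip.label), 2)
  expect_true(ape::is.ultrametric(t2, tol = 1e-8))

  ta <- simulate_tree(100, 1, seed = 42)
  tb <- simulate_tree(100, 1, seed = 42)
  expect_identical(ape::write.tree(ta), ape::write.tree(tb))
  expect_true(ape::is.ultrametric(ta, tol = 1e-8))
  expect_error(simulate_tree(1), "n_tips")
})

test_that("habitat histories follow the CTMC rates", {
  tree <- simulate_tree(8, 1, seed = 2)

  # zero rates: everything inherits the root state
  states <- c("gut", "oral")
  Q0 <- matrix(0, 2, 2, dimnames = list(states, states))
  h0 <- simulate_habitats(tree, Q0, "oral", seed = 3)
  expect_true(all(h0$tip_habitat == "oral"))
  expect_equal(h0$n_transitions, 0)

  # determinism
  Q <- matrix(c(-1, 1, 1, -1), 2, byrow = TRUE,
              dimnames = list(states, states))
  ha <- simulate_habitats(tree, Q, "gut", seed = 4)
  hb <- simulate_habitats(tree, Q, "gut", seed = 4)
  expect_identical(ha$tip_habitat, hb$tip_habitat)
  expect_identical(ha$paths, hb$paths)

  # per-branch dwell segments add up to the branch length
  lens <- vapply(ha$paths, sum, numeric(1))
  expect_equal(unname(lens), unname(tree$edge.length), tolerance = 1e-9)

  # expected transition count on a branch ~ rate * length
  cherry <- ape::read.tree(text = "(A:4,B:4);")
  rate <- 1.5
  Qr <- matrix(c(-rate, rate, rate, -rate), 2, byrow = TRUE,
               dimnames = list(states, states))
  n_tr <- vapply(1:400, function(s)
    simulate_habitats(cherry, Qr, "gut", seed = 9000 + s)$n_transitions,
    numeric(1))
  expected <- rate * sum(cherry$edge.length)
  se <- stats::sd(n_tr) / sqrt(length(n_tr))
  expect_lt(abs(mean(n_tr) - expected), 3 * se + 1e-9)

  # long-branch symmetric chain forgets its root state
  long <- ape::read.tree(text = "(A:12,B:12);")
  ends <- vapply(1:800, function(s)
    simulate_habitats(long, Qr, "gut", seed = 20000 + s)$tip_habitat[["A"]],
    character(1))
  chi <- stats::chisq.test(table(factor(ends, levels = states)),
                           p = c(0.5, 0.5))
  expect_gt(chi$p.value, 0.001)
})

test_that("trend-BM sizes obey their deterministic and diffusive limits", {
  tree <- simulate_tree(12, 1, seed = 5)
  states <- c("gut", "oral")
  Q0 <- matrix(0, 2, 2, dimnames = list(states, states))
  hab_gut <- simulate_habitats(tree, Q0, "gut", seed = 1)
  depth <- max(ape::node.depth.edgelength(tree))

  # sigma2 = 0, delta = 0: every tip at exactly the root size
  s0 <- simulate_genome_sizes(tree, hab_gut, 0, 0, log(3e6), seed = 6)
  expect_true(all(abs(s0$tip_log_size - log(3e6)) < 1e-12))

  # sigma2 = 0, delta > 0: log size = root + delta * gut dwell, exactly
  s1 <- simulate_genome_sizes(tree, hab_gut, 0, 0.3, log(3e6), seed = 6)
  expect_equal(unname(s1$tip_log_size),
               unname(log(3e6) + 0.3 * s1$gut_dwell), tolerance = 1e-12)
  expect_equal(unname(s1$gut_dwell), rep(depth, 12), tolerance = 1e-9)

  # point-shift mode with zero shifts is pure BM; nongut trend applies
  # when the lineage is out of the gut
  hab_oral <- simulate_habitats(tree, Q0, "oral", seed = 1)
  s2 <- simulate_genome_sizes(tree, hab_oral, 0, 0.3, log(3e6), seed = 6,
                              nongut_trend_delta = -0.1)
  expect_equal(unname(s2$tip_log_size),
               rep(log(3e6) - 0.1 * depth, 12), tolerance = 1e-9)

  # BM variance law on a star tree: var(log size) ~ sigma2 * T
  star <- ape::stree(2000, "star")
  star$edge.length <- rep(2, 2000)
  hs <- simulate_habitats(star, Q0, "oral", seed = 2)
  s3 <- simulate_genome_sizes(star, hs, 0.5, 0, log(3e6), seed = 7)
  v <- stats::var(s3$tip_log_size)
  se_v <- 1 * sqrt(2 / (2000 - 1))  # var of sample variance of N(.,1)
  expect_lt(abs(v - 1), 3 * se_v)

  # integer bp sizes
  expect_true(all(s3$tip_size == round(s3$tip_size)))
})

test_that("observation model is invertible and seeded", {
  sizes <- stats::setNames(round(stats::runif(50, 1e6, 6e6)),
                           sprintf("t%02d", 1:50))
  obs <- apply_observation_model(sizes, c(90, 100), seed = 8)
  expect_true(all(obs$completeness >= 90 & obs$completeness <= 100))
  recovered <- corrected_size(obs$assembly_size, obs$completeness)
  expect_true(all(abs(recovered - obs$true_size) <= 1))

  full <- apply_observation_model(sizes, c(100, 100), seed = 8)
  expect_equal(full$assembly_size, unname(sizes))

  o2 <- apply_observation_model(sizes, c(90, 100), seed = 8)
  expect_identical(obs, o2)
  expect_error(apply_observation_model(sizes, c(0, 100)), "range")
})

test_that("cohorts are internally consistent and bit-reproducible", {
  cfg <- simulation_config(n_tips = 48, seed = 77)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$tips, b$tips)
  expect_identical(a$abundance, b$abundance)
  expect_identical(a$mags, b$mags)
  expect_identical(a$enrichment, b$enrichment)
  expect_identical(ape::write.tree(a$tree$tree), ape::write.tree(b$tree$tree))

  # tree and metadata are joined; truth and observation agree
  expect_s3_class(a$tree, "annotated_tree")
  expect_equal(a$tips$tip_id, a$tree$tree$tip.label)
  rec <- corrected_size(a$tips$assembly_size, a$tips$completeness)
  expect_true(all(abs(rec - a$truth$true_size) <= 1))
  expect_true(all(a$tips$completeness > 89.99 &
                    a$tips$completeness <= 100))

  # genus cut is shallower than the species cut, so species nest in
  # genera
  nest <- tapply(a$tips$genus, a$tips$species,
                 function(g) length(unique(g)))
  expect_true(all(nest == 1))

  # different seeds give different cohorts
  c2 <- simulate_cohort(simulation_config(n_tips = 48, seed = 78))
  expect_false(identical(a$tips$habitat, c2$tips$habitat))

  expect_error(simulation_config(n_tips = 1), "n_tips")
  expect_error(simulation_config(completeness_range = c(50, 200)),
               "completeness_range")
  expect_error(simulation_config(genus_depth_frac = 1.5), "genus_depth")
})

test_that("cohort files round-trip through the pipeline readers", {
  co <- simulate_cohort(simulation_config(n_tips = 32, seed = 99))
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  tree <- read_newick(file.path(dir, "tree.nwk"))
  meta <- read_tip_metadata(file.path(dir, "metadata.tsv"))
  at <- join_tree_metadata(tree, meta)
  expect_equal(sort(at$tips$tip_id), sort(co$tips$tip_id))
  ab <- read_abundance_table(file.path(dir, "abundance.tsv"))
  expect_equal(nrow(ab), nrow(co$abundance))
  mg <- read_mag_table(file.path(dir, "mags.tsv"))
  expect_equal(nrow(mg), nrow(co$mags))
  en <- read_enrichment_table(file.path(dir, "enrichment.tsv"))
  expect_equal(nrow(en), nrow(co$enrichment))
})
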