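# Synthetic study-cohort generator: Yule trees, continuous-time Markov
# habitat histories with full per-branch state paths, trend
# Brownian-motion log genome sizes, an assembly-completeness observation
# model, and abundance / MAG / enrichment tables with known ground
# truth. Every stage draws from its own seeded substream so stage-level
# reruns reproduce exactly.

#' Build a habitat transition-rate matrix
#'
#' Continuous-time Markov rates over the five body-site states
#' (`"other"` is reserved for unannotated metadata and is not
#' simulated). Off-diagonal entries are transition rates per unit branch
#' length; rows sum to zero.
#'
#' @param to_gut Rate from each non-gut site into the gut.
#' @param from_gut Total rate out of the gut (split equally across the
#'   four non-gut sites).
#' @param between Rate between each ordered pair of non-gut sites.
#' @return 5x5 rate matrix with dimnames.
#' @export
habitat_rate_matrix <- function(to_gut = 0.25, from_gut = 0.25,
                                between = 0.02) {
  states <- c("gut", "oral", "urogenital", "skin", "airways")
  Q <- matrix(0, 5, 5, dimnames = list(states, states))
  Q["gut", states != "gut"] <- from_gut / 4
  Q[states != "gut", "gut"] <- to_gut
  for (a in states[-1]) for (b in states[-1]) if (a != b) Q[a, b] <- between
  diag(Q) <- -rowSums(Q)
  Q
}

validate_rate_matrix <- function(Q) {
  if (!is.matrix(Q) || nrow(Q) != ncol(Q) || is.null(rownames(Q)) ||
        !identical(rownames(Q), colnames(Q)))
    stop("rate matrix must be square with matching state dimnames")
  off <- Q; diag(off) <- 0
  if (any(off < 0)) stop("off-diagonal rates must be nonnegative")
  if (any(abs(rowSums(Q)) > 1e-8)) stop("rate-matrix rows must sum to zero")
  Q
}

#' Simulation configuration
#'
#' Collects and validates every generative parameter of the synthetic
#' cohort. The defaults describe the study conditions the generator
#' emulates: a desk-scale isolate phylogeny (512 tips), habitat
#' switching frequent enough that a default cohort yields independent
#' gut / non-gut comparison counts on the order of the real HMP
#' phylogeny's 59, log genome
#' sizes evolving by Brownian motion (rate `bm_sigma2` per unit branch
#' length) with a deterministic expansion trend `gut_trend_delta` (ln bp
#' per unit time spent in the gut state), assembly completeness uniform
#' on 90-100%, and per-habitat linear abundance-size relationships with
#' a positive slope in the gut and negative slopes elsewhere.
#'
#' @param n_tips Number of tips of the Yule tree.
#' @param birth_rate Yule speciation rate.
#' @param rate_matrix Habitat CTMC rates (see [habitat_rate_matrix()]).
#' @param root_habitat Habitat state at the root.
#' @param root_log_size Root log genome size, ln(bp).
#' @param bm_sigma2 Brownian-motion variance of log size per unit branch
#'   length.
#' @param gut_trend_delta Drift in ln(bp) per unit branch length while a
#'   lineage is in the gut state.
#' @param nongut_trend_delta Drift while in any non-gut state (default
#'   0).
#' @param shift_at_transition If TRUE, replace the continuous trend by a
#'   point shift: log size jumps by `shift_size` on entering the gut and
#'   by `-shift_size` on leaving it.
#' @param shift_size Point-shift magnitude in ln(bp).
#' @param completeness_range Assembly completeness range in percent.
#' @param abundance_params Named list (one entry per habitat) of
#'   `c(intercept, slope, sd)`: log10 relative abundance of a species in
#'   a host = intercept + slope * genome size (Mb) + a species-level
#'   effect Normal(0, `abundance_species_sd`) + host-level noise
#'   Normal(0, sd).
#' @param abundance_species_sd Standard deviation of the species-level
#'   abundance effect (log10 units); this, not host noise, dominates the
#'   residual scatter of the species-mean regression.
#' @param n_hosts Hosts sampled per habitat for the abundance table.
#' @param genus_depth_frac Depth (fraction of root-to-tip distance) at
#'   which the tree is cut into genus clades.
#' @param species_depth_frac Depth fraction for species clades (deeper
#'   than the genus cut).
#' @param pathogen_rate Probability a genus is flagged as being under
#'   pathogen surveillance.
#' @param mag_completeness_range,mag_contamination_range Ranges of MAG
#'   completeness and contamination (percent).
#' @param mags_per_tip_mean Mean MAGs sampled per strain.
#' @param n_annotations,enrichment_zero_frac,enrichment_gut_bias
#'   Enrichment-score table parameters: table size, fraction of exact
#'   zeros, and mean of nonzero scores (positive = gut-enriched).
#' @param crispr_rate_zero,crispr_rate_nonzero Probability an annotation
#'   carries the CRISPR flag, for zero-score and nonzero-score rows.
#' @param seed Master seed; each stage derives its own substream from
#'   it.
#' @return Validated list of class `simulation_config`.
#' @export
simulation_config <- function(n_tips = 512,
                              birth_rate = 1,
                              rate_matrix = habitat_rate_matrix(),
                              root_habitat = "oral",
                              root_log_size = log(3e6),
                              bm_sigma2 = 0.02,
                              gut_trend_delta = 0.25,
                              nongut_trend_delta = 0,
                              shift_at_transition = FALSE,
                              shift_size = 0,
                              completeness_range = c(90, 100),
                              abundance_params = list(
                                gut = c(intercept = -4, slope = 0.5, sd = 0.5),
                                oral = c(intercept = -4, slope = -0.5, sd = 0.5),
                                urogenital = c(intercept = -4, slope = -0.5, sd = 0.5),
                                skin = c(intercept = -4, slope = -0.5, sd = 0.5),
                                airways = c(intercept = -4, slope = -0.5, sd = 0.5)),
                              abundance_species_sd = 1,
                              n_hosts = 30,
                              genus_depth_frac = 0.6,
                              species_depth_frac = 0.88,
                              pathogen_rate = 0.05,
                              mag_completeness_range = c(80, 100),
                              mag_contamination_range = c(0, 8),
                              mags_per_tip_mean = 2,
                              n_annotations = 600,
                              enrichment_zero_frac = 0.4,
                              enrichment_gut_bias = 0.4,
                              crispr_rate_zero = 0.005,
                              crispr_rate_nonzero = 0.02,
                              seed = 1) {
  cfg <- as.list(environment())
  bad <- character(0)
  if (cfg$n_tips < 2 || cfg$n_tips != round(cfg$n_tips)) bad <- c(bad, "n_tips")
  if (cfg$birth_rate <= 0) bad <- c(bad, "birth_rate")
  ok_q <- tryCatch({validate_rate_matrix(cfg$rate_matrix); TRUE},
                   error = function(e) FALSE)
  if (!ok_q) bad <- c(bad, "rate_matrix")
  if (!cfg$root_habitat %in% rownames(cfg$rate_matrix))
    bad <- c(bad, "root_habitat")
  if (cfg$bm_sigma2 < 0) bad <- c(bad, "bm_sigma2")
  cr <- cfg$completeness_range
  if (length(cr) != 2 || cr[1] > cr[2] || cr[1] <= 0 || cr[2] > 100)
    bad <- c(bad, "completeness_range")
  if (cfg$genus_depth_frac <= 0 || cfg$genus_depth_frac >= 1)
    bad <- c(bad, "genus_depth_frac")
  if (cfg$species_depth_frac <= cfg$genus_depth_frac ||
        cfg$species_depth_frac >= 1)
    bad <- c(bad, "species_depth_frac")
  if (cfg$pathogen_rate < 0 || cfg$pathogen_rate > 1)
    bad <- c(bad, "pathogen_rate")
  if (cfg$enrichment_zero_frac < 0 || cfg$enrichment_zero_frac > 1)
    bad <- c(bad, "enrichment_zero_frac")
  if (length(bad))
    stop("invalid simulation config field(s): ", paste(bad, collapse = ", "))
  structure(cfg, class = "simulation_config")
}

#' Simulate an ultrametric Yule tree
#'
#' Pure-birth tree via [ape::rphylo()]; deterministic under `seed`.
#'
#' @param n_tips Number of tips (>= 2).
#' @param birth_rate Speciation rate per unit time.
#' @param seed Seed for the tree substream.
#' @return A rooted ultrametric `phylo`.
#' @export
simulate_tree <- function(n_tips, birth_rate = 1, seed = NULL) {
  if (n_tips < 2) stop("n_tips must be >= 2")
  with_seed(seed, ape::rphylo(n_tips, birth = birth_rate, death = 0))
}

#' Simulate habitat histories along a tree
#'
#' Continuous-time Markov simulation of the habitat character along
#' every branch, recording the full state path (dwell segments) per
#' branch - required downstream because the genome-size drift depends on
#' the time spent in the gut state, not only on the end states.
#'
#' @param tree A `phylo`.
#' @param rate_matrix CTMC rate matrix (rows sum to zero).
#' @param root_habitat State at the root.
#' @param seed Seed for the habitat substream.
#' @return List of class `habitat_history`: `tip_habitat` (named),
#'   `node_state` (all nodes), `paths` (per edge, a numeric vector of
#'   dwell durations named by state, in order along the branch),
#'   `n_transitions`.
#' @export
simulate_habitats <- function(tree, rate_matrix, root_habitat,
                              seed = NULL) {
  Q <- validate_rate_matrix(rate_matrix)
  states <- rownames(Q)
  if (!root_habitat %in% states) stop("root_habitat not a state of the matrix")
  n <- length(tree$tip.label)
  nn <- n + tree$Nnode
  with_seed(seed, {
    node_state <- character(nn)
    node_state[n + 1L] <- root_habitat
    paths <- vector("list", nrow(tree$edge))
    n_trans <- 0L
    ord <- reorder(tree, "cladewise")
    edge_index <- match(paste(ord$edge[, 1], ord$edge[, 2]),
                        paste(tree$edge[, 1], tree$edge[, 2]))
    for (i in seq_len(nrow(ord$edge))) {
      p <- ord$edge[i, 1L]; ch <- ord$edge[i, 2L]
      len <- ord$edge.length[i]
      s <- node_state[p]
      dwell <- numeric(0); labs <- character(0)
      t <- 0
      repeat {
        rate <- -Q[s, s]
        wait <- if (rate > 0) stats::rexp(1, rate) else Inf
        if (t + wait >= len) {
          dwell <- c(dwell, len - t); labs <- c(labs, s)
          break
        }
        dwell <- c(dwell, wait); labs <- c(labs, s)
        t <- t + wait
        probs <- Q[s, ]; probs[s] <- 0
        s <- sample(states, 1, prob = probs / sum(probs))
        n_trans <- n_trans + 1L
      }
      paths[[edge_index[i]]] <- stats::setNames(dwell, labs)
      node_state[ch] <- s
    }
    structure(list(
      tip_habitat = stats::setNames(node_state[seq_len(n)], tree$tip.label),
      node_state = node_state, paths = paths,
      n_transitions = n_trans, states = states),
      class = "habitat_history")
  })
}

#' Simulate genome sizes under trend Brownian motion
#'
#' Log genome size evolves along each branch as Brownian motion with
#' variance `bm_sigma2 * dt` plus a deterministic drift of
#' `gut_trend_delta` per unit time spent in the gut state (and
#' `nongut_trend_delta` elsewhere). Alternatively
#' (`shift_at_transition`), the trend is replaced by a point shift of
#' `shift_size` ln(bp) applied at each transition into the gut (and its
#' negative on leaving). Tip size is `exp(log size)` rounded to integer
#' bp.
#'
#' @param tree A `phylo`.
#' @param habitats A `habitat_history` for the same tree.
#' @param bm_sigma2 BM variance per unit branch length (>= 0).
#' @param gut_trend_delta Drift in ln(bp) per unit gut dwell time.
#' @param root_log_size Root log size, ln(bp).
#' @param seed Seed for the size substream.
#' @param nongut_trend_delta Drift while not in the gut (default 0).
#' @param shift_at_transition Use the point-shift model instead of the
#'   continuous trend.
#' @param shift_size Point-shift magnitude in ln(bp).
#' @return List with `tip_log_size`, `tip_size` (integer bp),
#'   `gut_dwell` (per-tip total time spent in the gut on the root path),
#'   all named by tip label.
#' @export
simulate_genome_sizes <- function(tree, habitats, bm_sigma2,
                                  gut_trend_delta, root_log_size,
                                  seed = NULL, nongut_trend_delta = 0,
                                  shift_at_transition = FALSE,
                                  shift_size = 0) {
  stopifnot(inherits(habitats, "habitat_history"))
  if (bm_sigma2 < 0) stop("bm_sigma2 must be >= 0")
  n <- length(tree$tip.label)
  nn <- n + tree$Nnode
  with_seed(seed, {
    logsize <- numeric(nn)
    dwell_to <- numeric(nn)
    logsize[n + 1L] <- root_log_size
    ord <- reorder(tree, "cladewise")
    edge_index <- match(paste(ord$edge[, 1], ord$edge[, 2]),
                        paste(tree$edge[, 1], tree$edge[, 2]))
    for (i in seq_len(nrow(ord$edge))) {
      p <- ord$edge[i, 1L]; ch <- ord$edge[i, 2L]
      len <- ord$edge.length[i]
      path <- habitats$paths[[edge_index[i]]]
      gut_dt <- sum(path[names(path) == "gut"])
      drift <- if (shift_at_transition) {
        sts <- names(path)
        into <- sum(sts[-1] == "gut" & sts[-length(sts)] != "gut")
        outof <- sum(sts[-1] != "gut" & sts[-length(sts)] == "gut")
        shift_size * (into - outof)
      } else {
        gut_trend_delta * gut_dt + nongut_trend_delta * (len - gut_dt)
      }
      logsize[ch] <- logsize[p] + drift +
        stats::rnorm(1, 0, sqrt(bm_sigma2 * len))
      dwell_to[ch] <- dwell_to[p] + gut_dt
    }
    tipnames <- tree$tip.label
    list(tip_log_size = stats::setNames(logsize[seq_len(n)], tipnames),
         tip_size = stats::setNames(round(exp(logsize[seq_len(n)])), tipnames),
         gut_dwell = stats::setNames(dwell_to[seq_len(n)], tipnames))
  })
}

#' Observation model: assembly size and completeness
#'
#' Draws a completeness per genome uniform on `completeness_range` and
#' returns the observed assembly size `round(true_size * completeness /
#' 100)`. [corrected_size()] inverts this to within 1 bp.
#'
#' @param true_sizes Named integer vector of true genome sizes (bp).
#' @param completeness_range Range `c(lo, hi)` in percent, within
#'   (0, 100].
#' @param seed Seed for the observation substream.
#' @return Data.frame with `tip_id`, `true_size`, `completeness`,
#'   `assembly_size`.
#' @export
apply_observation_model <- function(true_sizes,
                                    completeness_range = c(90, 100),
                                    seed = NULL) {
  cr <- completeness_range
  if (length(cr) != 2 || cr[1] > cr[2] || cr[1] <= 0 || cr[2] > 100)
    stop("completeness_range must be within (0, 100]")
  with_seed(seed, {
    comp <- stats::runif(length(true_sizes), cr[1], cr[2])
    data.frame(tip_id = names(true_sizes),
               true_size = as.numeric(true_sizes),
               completeness = comp,
               assembly_size = round(as.numeric(true_sizes) * comp / 100),
               stringsAsFactors = FALSE)
  })
}

# Cut the tree at a fixed fraction of the root-to-tip depth; each edge
# crossing the cut founds one clade, labelled in preorder.
assign_depth_clades <- function(tree, depth_frac, prefix) {
  n <- length(tree$tip.label)
  depth <- node_depths(tree)
  cut <- depth_frac * max(depth[seq_len(n)])
  ord <- reorder(tree, "cladewise")
  clade <- character(n + tree$Nnode)
  clade[n + 1L] <- NA_character_
  counter <- 0L
  for (i in seq_len(nrow(ord$edge))) {
    p <- ord$edge[i, 1L]; ch <- ord$edge[i, 2L]
    dp <- depth[p]; dc <- depth[ch]
    if (dp < cut && dc >= cut) {
      counter <- counter + 1L
      clade[ch] <- sprintf("%s%03d", prefix, counter)
    } else {
      clade[ch] <- clade[p]
    }
  }
  stats::setNames(clade[seq_len(n)], tree$tip.label)
}

#' Simulate a complete synthetic cohort
#'
#' End-to-end generation of every pipeline input from a
#' [simulation_config()]: tree, habitat history, true and observed
#' genome sizes, genus/species labels (tree cut at the configured
#' depths), pathogen flags (per genus), a per-host abundance table, a
#' MAG table (several bins per strain, species-level bins shared across
#' habitats through the species clades), an enrichment-score table, and
#' a ground-truth table for recovery tests.
#'
#' @param config A `simulation_config`.
#' @return List of class `cohort` with elements `tree`
#'   (`annotated_tree`), `tips`, `abundance`, `mags`, `enrichment`,
#'   `truth`, `habitats`, `config`.
#' @export
simulate_cohort <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  cfg <- config
  tree <- simulate_tree(cfg$n_tips, cfg$birth_rate,
                        stage_seed(cfg$seed, "tree"))
  hab <- simulate_habitats(tree, cfg$rate_matrix, cfg$root_habitat,
                           stage_seed(cfg$seed, "habitat"))
  sizes <- simulate_genome_sizes(tree, hab, cfg$bm_sigma2,
                                 cfg$gut_trend_delta, cfg$root_log_size,
                                 stage_seed(cfg$seed, "size"),
                                 nongut_trend_delta = cfg$nongut_trend_delta,
                                 shift_at_transition = cfg$shift_at_transition,
                                 shift_size = cfg$shift_size)
  obs <- apply_observation_model(sizes$tip_size, cfg$completeness_range,
                                 stage_seed(cfg$seed, "obs"))
  genus <- assign_depth_clades(tree, cfg$genus_depth_frac, "G")
  species <- assign_depth_clades(tree, cfg$species_depth_frac, "S")
  pathogen <- with_seed(stage_seed(cfg$seed, "pathogen"), {
    gl <- sort(unique(genus))
    flagged <- gl[stats::runif(length(gl)) < cfg$pathogen_rate]
    genus %in% flagged
  })
  tips <- data.frame(tip_id = tree$tip.label,
                     genus = unname(genus[tree$tip.label]),
                     species = unname(species[tree$tip.label]),
                     habitat = unname(hab$tip_habitat[tree$tip.label]),
                     assembly_size = obs$assembly_size[match(tree$tip.label,
                                                             obs$tip_id)],
                     completeness = obs$completeness[match(tree$tip.label,
                                                           obs$tip_id)],
                     pathogen_flag = unname(pathogen),
                     stringsAsFactors = FALSE)
  at <- join_tree_metadata(tree, tips)

  size_mb <- sizes$tip_size / 1e6
  abundance <- with_seed(stage_seed(cfg$seed, "abundance"), {
    rows <- list()
    for (h in names(cfg$abundance_params)) {
      sp <- tips$tip_id[tips$habitat == h]
      if (!length(sp)) next
      par <- cfg$abundance_params[[h]]
      mu <- par[["intercept"]] + par[["slope"]] * size_mb[sp] +
        stats::rnorm(length(sp), 0, cfg$abundance_species_sd)
      host <- rep(seq_len(cfg$n_hosts), each = length(sp))
      la <- stats::rnorm(length(sp) * cfg$n_hosts, rep(mu, cfg$n_hosts),
                         par[["sd"]])
      ra <- 10^la
      # compositional closure: a sample's abundances cannot exceed 1 in
      # total; the per-host renormalization shifts log abundances by a
      # host constant only, leaving the size slope untouched
      tot <- tapply(ra, host, sum)
      ra <- ra / pmax(1, tot[as.character(host)])
      rows[[h]] <- data.frame(
        species = rep(sp, cfg$n_hosts), habitat = h,
        host_id = sprintf("%s_h%03d", h, host),
        rel_abundance = unname(ra), stringsAsFactors = FALSE)
    }
    do.call(rbind, rows)
  })

  mags <- with_seed(stage_seed(cfg$seed, "mag"), {
    nm <- 1L + stats::rpois(nrow(tips), max(cfg$mags_per_tip_mean - 1, 0))
    idx <- rep(seq_len(nrow(tips)), nm)
    total <- length(idx)
    comp <- stats::runif(total, cfg$mag_completeness_range[1],
                         cfg$mag_completeness_range[2])
    cont <- stats::runif(total, cfg$mag_contamination_range[1],
                         cfg$mag_contamination_range[2])
    rep_no <- sequence(nm)
    data.frame(
      bin_id = sprintf("%s_%s_m%02d", tips$species[idx], tips$tip_id[idx],
                       rep_no),
      species_bin = tips$species[idx], habitat = tips$habitat[idx],
      completeness = comp, contamination = cont,
      genome_size = round(sizes$tip_size[tips$tip_id[idx]] * comp / 100),
      stringsAsFactors = FALSE)
  })

  enrichment <- with_seed(stage_seed(cfg$seed, "enrichment"), {
    sources <- c("prodigal_cluster", "COG", "Pfam", "TIGRFAM",
                 "KEGG_module", "KEGG_class")
    src <- sample(sources, cfg$n_annotations, replace = TRUE)
    zero <- stats::runif(cfg$n_annotations) < cfg$enrichment_zero_frac
    score <- ifelse(zero, 0,
                    stats::rnorm(cfg$n_annotations,
                                 cfg$enrichment_gut_bias, 1))
    crispr <- stats::runif(cfg$n_annotations) <
      ifelse(score == 0, cfg$crispr_rate_zero, cfg$crispr_rate_nonzero)
    data.frame(annotation_id = sprintf("ann%05d",
                                       seq_len(cfg$n_annotations)),
               source = src, score = score,
               category_flags = ifelse(crispr, "CRISPR", ""),
               stringsAsFactors = FALSE)
  })

  truth <- data.frame(tip_id = tree$tip.label,
                      habitat = tips$habitat, genus = tips$genus,
                      species = tips$species,
                      true_size = unname(sizes$tip_size[tree$tip.label]),
                      log_size = unname(sizes$tip_log_size[tree$tip.label]),
                      gut_dwell = unname(sizes$gut_dwell[tree$tip.label]),
                      pathogen_flag = tips$pathogen_flag,
                      stringsAsFactors = FALSE)

  structure(list(tree = at, tips = tips, abundance = abundance, mags = mags,
                 enrichment = enrichment, truth = truth, habitats = hab,
                 config = cfg),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat("Synthetic cohort:", nrow(x$tips), "tips;",
      x$habitats$n_transitions, "habitat transitions;",
      nrow(x$mags), "MAGs;", nrow(x$enrichment), "annotations\n")
  invisible(x)
}

#' Write a cohort to disk in the pipeline's input formats
#'
#' Emits the Newick tree, the tip-metadata/abundance/MAG/enrichment
#' TSVs, a `truth.tsv` ground-truth table, and a manifest recording the
#' full configuration.
#'
#' @param cohort A `cohort` from [simulate_cohort()].
#' @param out_dir Output directory.
#' @return Paths written, invisibly.
#' @export
write_cohort <- function(cohort, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tp <- file.path(out_dir, "tree.nwk")
  write_newick(cohort$tree$tree, tp)
  cfg <- cohort$config
  cfg$rate_matrix <- as.vector(cfg$rate_matrix)
  man <- list(stage = "simulate", seed = cohort$config$seed,
              config = lapply(unclass(cfg), function(v)
                if (is.numeric(v) || is.character(v) || is.logical(v))
                  as.vector(v) else unclass(v)))
  paths <- write_results(list(metadata = cohort$tips,
                              abundance = cohort$abundance,
                              mags = cohort$mags,
                              enrichment = cohort$enrichment,
                              truth = cohort$truth),
                         out_dir, manifest = man)
  invisible(c(tp, paths))
}
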