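# Shared fixture builders: all synthetic, generated in code.

# Tip-record data.frame with sensible defaults.
make_records <- function(tip_id, habitat, genus = "X", species = NA,
                         assembly_size = 2e6, completeness = 100,
                         pathogen_flag = FALSE) {
  data.frame(tip_id = tip_id, genus = genus, species = species,
             habitat = habitat, assembly_size = assembly_size,
             completeness = completeness, pathogen_flag = pathogen_flag,
             stringsAsFactors = FALSE)
}

# Annotated tree from a newick string plus per-tip habitats (named or in
# tip order).
make_at <- function(newick, habitat, ...) {
  tree <- ape::read.tree(text = newick)
  if (!is.null(names(habitat))) habitat <- habitat[tree$tip.label]
  join_tree_metadata(tree, make_records(tree$tip.label, habitat, ...))
}

# Random annotated tree for property tests: random topology, branch
# lengths, habitats and genera.
random_at <- function(n_tips, n_genera = 2, p_gut = 0.4) {
  tree <- ape::rtree(n_tips)
  hab <- ifelse(stats::runif(n_tips) < p_gut, "gut",
                sample(c("oral", "skin", "urogenital"), n_tips,
                       replace = TRUE))
  # guarantee both sides are represented so extraction has a contrast
  hab[1] <- "gut"
  hab[2] <- "oral"
  hab <- sample(hab)
  gen <- sample(paste0("G", seq_len(n_genera)), n_tips, replace = TRUE)
  join_tree_metadata(tree, make_records(tree$tip.label, hab, genus = gen,
                                        assembly_size = round(stats::runif(
                                          n_tips, 1e6, 5e6))))
}

# Brute-force oracle for comparison extraction: test the
# reciprocal-monophyly anchor predicate at every internal node directly
# on tip sets, independent of the package's postorder fold.
brute_force_comparisons <- function(at, genus_required = TRUE) {
  tree <- at$tree
  tips <- at$tips
  n <- length(tree$tip.label)
  anchors <- list()
  for (node in (n + 1L):(n + tree$Nnode)) {
    kids <- tree$edge[tree$edge[, 1] == node, 2]
    sets <- lapply(kids, function(k) {
      if (k <= n) k else {
        sub <- ape::extract.clade(tree, k)
        match(sub$tip.label, tree$tip.label)
      }
    })
    purity <- vapply(sets, function(s) {
      h <- tips$habitat[s] == "gut"
      if (all(h)) "gut" else if (all(!h)) "nongut" else "mixed"
    }, character(1))
    if (any(purity == "mixed")) next
    if (!any(purity == "gut") || !any(purity == "nongut")) next
    all_under <- unlist(sets)
    if (genus_required && length(unique(tips$genus[all_under])) != 1) next
    anchors[[length(anchors) + 1L]] <- list(
      anchor = node,
      gut = sort(tips$tip_id[unlist(sets[purity == "gut"])]),
      nongut = sort(tips$tip_id[unlist(sets[purity == "nongut"])]))
  }
  anchors
}

# Exhaustive sign-test oracle: enumerate all 2^n equally likely outcome
# vectors and count those with at least k successes.
enumerate_sign_p <- function(k, n) {
  counts <- vapply(0:(2^n - 1), function(m)
    sum(as.integer(intToBits(m))[seq_len(n)]), numeric(1))
  mean(counts >= k)
}

# Exhaustive two-sided Fisher oracle with the minimum-likelihood
# convention, enumerating every table with the observed margins.
enumerate_fisher_p <- function(tab) {
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); tot <- sum(tab)
  lo <- max(0, r1 + c1 - tot); hi <- min(r1, c1)
  probs <- vapply(lo:hi, function(a)
    stats::dhyper(a, c1, tot - c1, r1), numeric(1))
  p_obs <- stats::dhyper(tab[1, 1], c1, tot - c1, r1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Step-up FDR oracle written independently of stats::p.adjust.
step_up_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  sorted <- p[o]
  adj <- sorted * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}
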