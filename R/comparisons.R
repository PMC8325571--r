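# Extraction of phylogenetically independent gut / non-gut comparisons:
# reciprocal-monophyly anchors, polarization by outgroup context,
# pathogen exclusion, and species-bin comparisons from MAG tables.

#' Find phylogenetically independent gut vs non-gut comparisons
#'
#' Scans the internal nodes of an annotated tree for anchors of
#' reciprocally monophyletic habitat comparisons: a node anchors a
#' comparison iff every one of its child subtrees is habitat-pure (all
#' gut, or all non-gut), with at least one pure-gut and one pure-non-gut
#' child. Pure-gut children are pooled into the gut side and
#' pure-non-gut children into the other side (so multifurcations need no
#' random resolution). Because an anchor's subtree is habitat-mixed, no
#' ancestor of an anchor can itself anchor, which makes the emitted
#' comparisons tip-disjoint - each contributes one phylogenetically
#' independent observation.
#'
#' At `level = "congeneric"` all tips under the anchor must share one
#' genus (when `genus_required`); at `level = "conspecific"` they must
#' also share one species. `level = "mag_species"` comparisons are built
#' from MAG tables by [mag_species_comparisons()], not here.
#'
#' Each comparison is assigned a habitat stratum: the common habitat of
#' its non-gut tips, or `"mixed"` when they span several sites.
#'
#' @param at An `annotated_tree` from [join_tree_metadata()].
#' @param level `"congeneric"` or `"conspecific"`.
#' @param genus_required Require all tips under the anchor to share a
#'   genus (default TRUE).
#' @return A data.frame of class `comparison_set`, ordered by preorder
#'   index of the anchor node, with list columns `gut_tips`,
#'   `nongut_tips`, `nongut_habitats`.
#' @export
find_independent_comparisons <- function(at,
                                         level = c("congeneric",
                                                   "conspecific"),
                                         genus_required = TRUE) {
  level <- match.arg(level)
  stopifnot(inherits(at, "annotated_tree"))
  tree <- at$tree
  tips <- at$tips
  n <- length(tree$tip.label)
  nn <- n + tree$Nnode

  is_gut <- tips$habitat == "gut"
  if (!any(is_gut) || all(is_gut))
    warning("tree has no gut/non-gut contrast; returning no comparisons")

  # Per-node habitat purity ("gut", "nongut", "mixed") and the single
  # genus/species under the node (NA when heterogeneous), by postorder.
  purity <- character(nn)
  genus <- character(nn)
  species <- character(nn)
  purity[seq_len(n)] <- ifelse(is_gut, "gut", "nongut")
  genus[seq_len(n)] <- tips$genus
  species[seq_len(n)] <- tips$species
  # fold a shared label up the tree; "" = unset, NA = heterogeneous/unknown
  fold_label <- function(acc, v) {
    if (!is.na(acc) && acc == "") return(if (is.na(v)) NA_character_ else v)
    if (is.na(acc) || is.na(v) || acc != v) NA_character_ else acc
  }
  post <- reorder(tree, "postorder")
  for (i in seq_len(nrow(post$edge))) {
    p <- post$edge[i, 1L]; ch <- post$edge[i, 2L]
    purity[p] <- if (purity[p] == "") purity[ch]
                 else if (purity[p] == purity[ch]) purity[p] else "mixed"
    genus[p] <- fold_label(genus[p], genus[ch])
    species[p] <- fold_label(species[p], species[ch])
  }

  kids <- node_children(tree)
  under <- tips_under(tree)
  rank <- preorder_rank(tree)

  anchors <- integer(0)
  for (node in (n + 1L):nn) {
    ch <- kids[[node]]
    pur <- purity[ch]
    if (any(pur == "mixed")) next
    if (!any(pur == "gut") || !any(pur == "nongut")) next
    if (genus_required && is.na(genus[node])) next
    if (level == "conspecific" && is.na(species[node])) next
    anchors <- c(anchors, node)
  }
  anchors <- anchors[order(rank[anchors])]

  rows <- lapply(seq_along(anchors), function(i) {
    node <- anchors[i]
    ch <- kids[[node]]
    gut_idx <- unlist(under[ch[purity[ch] == "gut"]])
    non_idx <- unlist(under[ch[purity[ch] == "nongut"]])
    non_hab <- sort(unique(tips$habitat[non_idx]))
    data.frame(
      comparison_id = sprintf("cmp_%04d", i),
      genus = if (genus_required) genus[node] else NA_character_,
      species = if (level == "conspecific") species[node] else NA_character_,
      level = level,
      anchor_node = node,
      n_gut = length(gut_idx),
      n_nongut = length(non_idx),
      stratum = if (length(non_hab) == 1L) non_hab else "mixed",
      polarity = "unpolarized",
      gut_tips = I(list(tree$tip.label[gut_idx])),
      nongut_tips = I(list(tree$tip.label[non_idx])),
      nongut_habitats = I(list(non_hab)),
      stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else empty_comparison_set()
  class(out) <- c("comparison_set", class(out))
  out
}

empty_comparison_set <- function() {
  data.frame(comparison_id = character(0), genus = character(0),
             species = character(0), level = character(0),
             anchor_node = integer(0), n_gut = integer(0),
             n_nongut = integer(0), stratum = character(0),
             polarity = character(0),
             gut_tips = I(list()), nongut_tips = I(list()),
             nongut_habitats = I(list()), stringsAsFactors = FALSE)
}

#' Polarize comparisons by outgroup context
#'
#' A comparison is polarized by the habitats of the sister clade(s) of
#' its anchor node (all other children of the anchor's parent): if every
#' sister tip is non-gut, the gut lineages are nested within non-gut
#' context and the gut state is derived (`"gut_derived"`); if every
#' sister tip is gut, the non-gut state is derived (`"nongut_derived"`);
#' a mixed sister context, or an anchor at the root, leaves the
#' comparison `"unpolarized"`. Unanimity of the immediate sister clade is
#' required - a deliberately conservative parsimony criterion; ambiguous
#' comparisons are retained but excluded from polarity-conditioned tests.
#'
#' @param at The `annotated_tree` the comparisons came from.
#' @param comps A `comparison_set`.
#' @return The comparison set with the `polarity` column filled in.
#' @export
polarize_comparisons <- function(at, comps) {
  stopifnot(inherits(at, "annotated_tree"))
  tree <- at$tree
  n <- length(tree$tip.label)
  root <- n + 1L
  if (!nrow(comps)) return(comps)
  if (any(comps$anchor_node > n + tree$Nnode))
    stop("anchor node not in tree")
  kids <- node_children(tree)
  under <- tips_under(tree)
  parent_of <- integer(n + tree$Nnode)
  parent_of[tree$edge[, 2L]] <- tree$edge[, 1L]
  is_gut <- at$tips$habitat == "gut"

  comps$polarity <- vapply(comps$anchor_node, function(node) {
    if (node == root) return("unpolarized")
    par <- parent_of[node]
    sibs <- setdiff(kids[[par]], node)
    sib_tips <- unlist(under[sibs])
    if (!length(sib_tips)) return("unpolarized")
    g <- is_gut[sib_tips]
    if (all(!g)) "gut_derived" else if (all(g)) "nongut_derived"
    else "unpolarized"
  }, character(1))
  comps
}

#' Exclude comparisons containing pathogen-surveillance lineages
#'
#' A comparison is excluded iff any member tip carries
#' `pathogen_flag = TRUE` (lineages under active foodborne-pathogen
#' surveillance, e.g. FoodNet/FDOSS listings). Both partitions are
#' returned so the excluded set can be examined.
#'
#' @param comps A `comparison_set`.
#' @param tip_records Tip-record data.frame with `pathogen_flag`.
#' @return List with elements `retained` and `excluded`.
#' @export
filter_pathogen_comparisons <- function(comps, tip_records) {
  if (!"pathogen_flag" %in% names(tip_records))
    stop("tip records carry no pathogen_flag column")
  flagged <- tip_records$tip_id[tip_records$pathogen_flag]
  has_flag <- vapply(seq_len(nrow(comps)), function(i) {
    any(c(comps$gut_tips[[i]], comps$nongut_tips[[i]]) %in% flagged)
  }, logical(1))
  if (!nrow(comps)) has_flag <- logical(0)
  list(retained = comps[!has_flag, , drop = FALSE],
       excluded = comps[has_flag, , drop = FALSE])
}

#' Build intraspecific comparisons from a MAG table
#'
#' Filters MAGs to high quality (completeness strictly greater than
#' `min_completeness`; contamination strictly less than
#' `max_contamination` when given), groups them by species-level genome
#' bin, and emits one comparison per bin detected in the gut and at
#' least one other body site. Phylogenetic independence across bins is
#' assumed (no within-species tree is used).
#'
#' @param mags MAG-record data.frame (see [read_mag_table()]).
#' @param min_completeness Completeness threshold in percent; MAGs must
#'   exceed it strictly (default 90, i.e. ">90% complete").
#' @param max_contamination Optional contamination ceiling in percent
#'   (strict); `NULL` disables the filter.
#' @return A `comparison_set` with `level = "mag_species"`; `gut_tips`
#'   and `nongut_tips` hold bin member ids.
#' @export
mag_species_comparisons <- function(mags, min_completeness = 90,
                                    max_contamination = NULL) {
  mags <- validate_mags(mags)
  keep <- mags$completeness > min_completeness
  if (!is.null(max_contamination))
    keep <- keep & !is.na(mags$contamination) &
      mags$contamination < max_contamination
  mags <- mags[keep, , drop = FALSE]
  bins <- split(mags, mags$species_bin)
  rows <- list()
  for (bin in sort(names(bins))) {
    b <- bins[[bin]]
    gut <- b$bin_id[b$habitat == "gut"]
    non <- b$bin_id[b$habitat != "gut"]
    if (!length(gut) || !length(non)) next
    non_hab <- sort(unique(b$habitat[b$habitat != "gut"]))
    rows[[length(rows) + 1L]] <- data.frame(
      comparison_id = bin, genus = NA_character_, species = bin,
      level = "mag_species", anchor_node = NA_integer_,
      n_gut = length(gut), n_nongut = length(non),
      stratum = if (length(non_hab) == 1L) non_hab else "mixed",
      polarity = "unpolarized",
      gut_tips = I(list(sort(gut))), nongut_tips = I(list(sort(non))),
      nongut_habitats = I(list(non_hab)), stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else empty_comparison_set()
  class(out) <- c("comparison_set", class(out))
  out
}

#' @export
print.comparison_set <- function(x, ...) {
  cat("Independent habitat comparisons:", nrow(x), "\n")
  if (nrow(x)) {
    cat("  levels: ", paste(sprintf("%s=%d", names(table(x$level)),
                                    table(x$level)), collapse = ", "), "\n")
    cat("  strata: ", paste(sprintf("%s=%d", names(table(x$stratum)),
                                    table(x$stratum)), collapse = ", "), "\n")
    cat("  polarity:", paste(sprintf("%s=%d", names(table(x$polarity)),
                                     table(x$polarity)), collapse = ", "), "\n")
  }
  invisible(x)
}
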