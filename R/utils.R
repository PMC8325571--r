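# Internal helpers shared across modules.

#' Closed habitat vocabulary
#'
#' The six recognized body-site labels. `"other"` is the sink for
#' unrecognized sites in metadata normalization.
#'
#' @return Character vector of the six habitat levels.
#' @export
habitat_levels <- function() {
  c("gut", "oral", "urogenital", "skin", "airways", "other")
}

# Evaluate `code` under a temporary RNG state seeded with `seed`; the
# caller's stream is untouched. A NULL seed uses the ambient stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Deterministic per-stage substream: each generator stage draws from its
# own seed derived from the master seed, so stage-level reruns reproduce.
stage_seed <- function(seed, stage) {
  if (is.null(seed)) return(NULL)
  offsets <- c(tree = 101L, habitat = 211L, size = 307L, obs = 401L,
               abundance = 503L, mag = 601L, enrichment = 701L,
               pathogen = 811L, anova = 907L)
  off <- offsets[[stage]]
  as.integer((as.numeric(seed) + off * 97) %% (.Machine$integer.max - 1))
}

# Depth (distance from root) of every node of a phylo object.
node_depths <- function(tree) {
  n <- length(tree$tip.label)
  nn <- n + tree$Nnode
  depth <- numeric(nn)
  root <- n + 1L
  ord <- reorder(tree, "cladewise")  # parent before child
  for (i in seq_len(nrow(ord$edge))) {
    p <- ord$edge[i, 1L]; ch <- ord$edge[i, 2L]
    depth[ch] <- depth[p] + ord$edge.length[i]
  }
  depth
}

# Tip indices descending from each node, as a list indexed by node id.
tips_under <- function(tree) {
  n <- length(tree$tip.label)
  nn <- n + tree$Nnode
  out <- vector("list", nn)
  for (i in seq_len(n)) out[[i]] <- i
  post <- reorder(tree, "postorder")
  for (i in seq_len(nrow(post$edge))) {
    p <- post$edge[i, 1L]; ch <- post$edge[i, 2L]
    out[[p]] <- c(out[[p]], out[[ch]])
  }
  out
}

# Children of every node.
node_children <- function(tree) {
  n <- length(tree$tip.label)
  nn <- n + tree$Nnode
  kids <- vector("list", nn)
  for (i in seq_len(nrow(tree$edge))) {
    p <- tree$edge[i, 1L]
    kids[[p]] <- c(kids[[p]], tree$edge[i, 2L])
  }
  kids
}

# Preorder rank of every node (root = 1); used for deterministic ordering
# of emitted comparisons.
preorder_rank <- function(tree) {
  n <- length(tree$tip.label)
  nn <- n + tree$Nnode
  ord <- reorder(tree, "cladewise")
  rank <- integer(nn)
  rank[n + 1L] <- 1L
  r <- 1L
  for (i in seq_len(nrow(ord$edge))) {
    r <- r + 1L
    rank[ord$edge[i, 2L]] <- r
  }
  rank
}

`%||%` <- function(a, b) if (is.null(a)) b else a
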