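# Phylogenetically independent contrasts (Felsenstein pruning), contrast
# regression with its GLS oracle, and tip-level abundance-size
# regressions.

#' Phylogenetically independent contrasts
#'
#' Computes standardized contrasts by the pruning algorithm: at each
#' internal node joining subtrees with values `x1`, `x2` and adjusted
#' branch lengths `v1`, `v2`, the contrast is `(x1 - x2) / sqrt(v1 +
#' v2)`, the nodal value is the weighted average `(x1/v1 + x2/v2) /
#' (1/v1 + 1/v2)`, and the branch above is lengthened by `v1 * v2 / (v1
#' + v2)`. Polytomies are resolved deterministically with zero-length
#' internal branches, folding children in tip-label order; the sign
#' convention is first child minus second child in tip-label order, so
#' results are reproducible without any random resolution. A node whose
#' two adjusted lengths are both zero is uninformative and raises an
#' error.
#'
#' This is implemented in-package (rather than delegating to
#' [ape::pic()]) to guarantee the deterministic polytomy and sign
#' conventions; on fully bifurcating trees the absolute contrast values
#' agree with `ape::pic`.
#'
#' @param tree Rooted `phylo` with nonnegative branch lengths.
#' @param trait Numeric vector of tip values, named by tip label (an
#'   unnamed vector is taken in tip order).
#' @return Data.frame (class `contrast_set`) with columns `node`,
#'   `contrast`, `expected_variance`; one row per pruning step (n - 1
#'   rows for n tips).
#' @export
pic_contrasts <- function(tree, trait) {
  n <- length(tree$tip.label)
  if (n < 2) stop("need at least 2 tips")
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (any(tree$edge.length < 0)) stop("negative branch lengths")
  x <- align_trait(tree, trait)

  nn <- n + tree$Nnode
  kids <- node_children(tree)
  # smallest tip label under each node, for the deterministic fold order
  min_lab <- character(nn)
  min_lab[seq_len(n)] <- tree$tip.label
  post <- reorder(tree, "postorder")
  for (i in seq_len(nrow(post$edge))) {
    p <- post$edge[i, 1L]; ch <- post$edge[i, 2L]
    min_lab[p] <- if (min_lab[p] == "") min_lab[ch]
                  else min(min_lab[p], min_lab[ch])
  }
  edge_len <- numeric(nn)
  edge_len[tree$edge[, 2L]] <- tree$edge.length

  val <- numeric(nn); val[seq_len(n)] <- x
  extra <- numeric(nn)  # pruning-induced lengthening of the branch above
  res_node <- integer(0); res_con <- numeric(0); res_var <- numeric(0)

  post_nodes <- unique(post$edge[, 1L])  # postorder over internal nodes
  for (node in post_nodes) {
    ch <- kids[[node]]
    ch <- ch[order(min_lab[ch])]
    v1 <- edge_len[ch[1]] + extra[ch[1]]
    x1 <- val[ch[1]]
    for (j in 2:length(ch)) {
      v2 <- edge_len[ch[j]] + extra[ch[j]]
      x2 <- val[ch[j]]
      vv <- v1 + v2
      if (vv == 0)
        stop("uninformative contrast: both adjusted branch lengths zero at node ",
             node)
      res_node <- c(res_node, node)
      res_con <- c(res_con, (x1 - x2) / sqrt(vv))
      res_var <- c(res_var, vv)
      x1 <- (x1 / v1 + x2 / v2) / (1 / v1 + 1 / v2)
      v1 <- v1 * v2 / vv  # zero-length resolving branch adds nothing
    }
    val[node] <- x1
    extra[node] <- v1
  }
  structure(data.frame(node = res_node, contrast = res_con,
                       expected_variance = res_var),
            class = c("contrast_set", "data.frame"))
}

align_trait <- function(tree, trait) {
  n <- length(tree$tip.label)
  if (!is.null(names(trait))) {
    missing <- setdiff(tree$tip.label, names(trait))
    if (length(missing))
      stop("trait missing for tip(s): ", paste(missing, collapse = ", "))
    trait <- trait[tree$tip.label]
  } else if (length(trait) != n) {
    stop("unnamed trait vector must have one value per tip")
  }
  if (anyNA(trait)) stop("trait values must not be NA")
  unname(trait)
}

#' Through-origin regression of contrasts on contrasts
#'
#' Least-squares regression with no intercept, the standard model for
#' independent contrasts (a contrast's sign is arbitrary, so the fit
#' must pass through the origin). Reports the slope, uncentered R
#' squared, and the t-test p-value on the slope (NA when fewer than 3
#' contrasts, where the residual t test is degenerate).
#'
#' @param contrasts_x,contrasts_y Numeric contrast vectors of equal
#'   length (or `contrast_set` data.frames).
#' @return Object of class `regression_result`.
#' @export
pic_regression <- function(contrasts_x, contrasts_y) {
  cx <- if (inherits(contrasts_x, "data.frame")) contrasts_x$contrast
        else contrasts_x
  cy <- if (inherits(contrasts_y, "data.frame")) contrasts_y$contrast
        else contrasts_y
  if (length(cx) != length(cy)) stop("contrast vectors differ in length")
  n <- length(cx)
  if (n < 2) stop("need at least 2 contrasts")
  fit <- stats::lm(cy ~ cx + 0)
  sm <- summary(fit)
  p <- if (n >= 3) sm$coefficients["cx", "Pr(>|t|)"] else NA_real_
  structure(list(coefficients = c(slope = unname(stats::coef(fit)["cx"])),
                 r_squared = sm$r.squared, p_linear = p, n = n, degree = 1L,
                 through_origin = TRUE),
            class = "regression_result")
}

#' GLS oracle for the contrast-regression slope
#'
#' Independent test oracle: fits trait y on trait x at the tips by
#' generalized least squares under the Brownian-motion covariance
#' `C[i, j] = shared path length from the root`, with an intercept. The
#' intercept absorbs the root state, so the GLS slope is algebraically
#' identical to the through-origin slope of the contrast regression;
#' the equality (to 1e-8) is a cross-check of the pruning
#' implementation. Intended for small trees.
#'
#' @param tree Rooted `phylo` with branch lengths.
#' @param trait_x,trait_y Tip-value vectors named by tip label.
#' @return The GLS slope (numeric scalar).
#' @export
pic_regression_oracle_gls <- function(tree, trait_x, trait_y) {
  x <- align_trait(tree, trait_x)
  y <- align_trait(tree, trait_y)
  C <- ape::vcv(tree)
  X <- cbind(1, x)
  CiX <- tryCatch(solve(C, X), error = function(e)
    stop("singular Brownian-motion covariance: ", conditionMessage(e)))
  Ciy <- solve(C, y)
  beta <- solve(crossprod(X, CiX), crossprod(X, Ciy))
  unname(beta[2, 1])
}

#' Per-species mean log relative abundance
#'
#' For one habitat, averages `log10(rel_abundance)` over hosts for each
#' species. Zero abundances are dropped by default (`"drop"`), or
#' imputed at half the smallest nonzero abundance (`"half_min"`).
#'
#' @param records Abundance data.frame (see [read_abundance_table()]).
#' @param habitat Habitat to subset to.
#' @param zero_handling `"drop"` or `"half_min"`.
#' @return Named numeric vector of per-species mean log10 abundances.
#' @export
species_mean_log_abundance <- function(records, habitat,
                                       zero_handling = c("drop", "half_min")) {
  zero_handling <- match.arg(zero_handling)
  r <- records[records$habitat == habitat, , drop = FALSE]
  if (!nrow(r)) stop("no abundance records for habitat '", habitat, "'")
  if (zero_handling == "drop") {
    r <- r[r$rel_abundance > 0, , drop = FALSE]
  } else {
    floor_val <- min(r$rel_abundance[r$rel_abundance > 0]) / 2
    r$rel_abundance[r$rel_abundance == 0] <- floor_val
  }
  agg <- stats::aggregate(list(y = log10(r$rel_abundance)),
                          by = list(species = r$species), FUN = mean)
  stats::setNames(agg$y, agg$species)
}

#' Polynomial regression of abundance on genome size within a habitat
#'
#' Ordinary least squares of per-species mean log10 relative abundance
#' on genome size in Mb, with polynomial terms up to `degree` (default 2
#' - abundance-size relationships are typically curved, and significance
#' is reported for the linear coefficient). Regression is at the tip
#' (species) level and keeps its intercept.
#'
#' @param records Abundance data.frame.
#' @param sizes_mb Named numeric vector of per-species genome sizes in
#'   Mb.
#' @param habitat Habitat to analyse.
#' @param degree Polynomial degree, 1 or 2.
#' @param zero_handling Zero-abundance handling (see
#'   [species_mean_log_abundance()]).
#' @return Object of class `regression_result`; `coefficients` holds
#'   intercept and polynomial terms, `p_linear` the p-value of the
#'   linear coefficient.
#' @export
abundance_size_regression <- function(records, sizes_mb, habitat,
                                      degree = 2,
                                      zero_handling = c("drop", "half_min")) {
  if (!degree %in% c(1, 2)) stop("degree must be 1 or 2")
  y <- species_mean_log_abundance(records, habitat, zero_handling)
  common <- intersect(names(y), names(sizes_mb))
  if (length(common) < degree + 2)
    stop("need at least ", degree + 2, " species with both abundance and size")
  y <- y[common]; x <- sizes_mb[common]
  fit <- stats::lm(y ~ stats::poly(x, degree, raw = TRUE))
  sm <- summary(fit)
  cf <- stats::coef(fit)
  names(cf) <- c("intercept", paste0("x", seq_len(degree)))
  structure(list(coefficients = cf, r_squared = sm$r.squared,
                 p_linear = sm$coefficients[2, "Pr(>|t|)"],
                 linear_sign = sign(cf[["x1"]]),
                 n = length(common), degree = as.integer(degree),
                 through_origin = FALSE),
            class = "regression_result")
}

#' Within-genus abundance-size regression
#'
#' Removes between-genus variation by centering both genome size and
#' mean log abundance on their genus means, then pools the centered
#' values across genera in one ordinary regression. Genera with fewer
#' than 2 species are dropped (they carry no within-genus information).
#'
#' @param records Abundance data.frame.
#' @param sizes_mb Named per-species genome sizes in Mb.
#' @param genus Named character vector mapping species to genus.
#' @param habitat Habitat to analyse.
#' @param zero_handling Zero-abundance handling.
#' @return Object of class `regression_result` (degree 1, centered).
#' @export
within_genus_regression <- function(records, sizes_mb, genus,
                                    habitat = "gut",
                                    zero_handling = c("drop", "half_min")) {
  y <- species_mean_log_abundance(records, habitat, zero_handling)
  common <- intersect(intersect(names(y), names(sizes_mb)), names(genus))
  y <- y[common]; x <- sizes_mb[common]; g <- genus[common]
  counts <- table(g)
  keep <- g %in% names(counts)[counts >= 2]
  if (!any(keep)) stop("no genus with at least 2 species")
  y <- y[keep]; x <- x[keep]; g <- g[keep]
  yc <- y - stats::ave(y, g)
  xc <- x - stats::ave(x, g)
  fit <- stats::lm(yc ~ xc)
  sm <- summary(fit)
  structure(list(coefficients = c(intercept = unname(stats::coef(fit)[1]),
                                  x1 = unname(stats::coef(fit)[2])),
                 r_squared = sm$r.squared,
                 p_linear = sm$coefficients["xc", "Pr(>|t|)"],
                 linear_sign = sign(unname(stats::coef(fit)[2])),
                 n = length(yc), degree = 1L, through_origin = FALSE,
                 n_genera = length(unique(g))),
            class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("Regression (degree %d%s), n = %d\n", x$degree,
              if (isTRUE(x$through_origin)) ", through origin" else "", x$n))
  cat("  coefficients:",
      paste(sprintf("%s = %.6g", names(x$coefficients), x$coefficients),
            collapse = ", "), "\n")
  cat(sprintf("  R^2 = %.4g, linear-coefficient P = %.4g\n",
              x$r_squared, x$p_linear))
  invisible(x)
}
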