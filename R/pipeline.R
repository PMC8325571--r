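# End-to-end analysis: extraction -> summaries -> tests (overall,
# per-habitat, per-polarity, pathogen-excluded) -> regressions ->
# enrichment, with a TSV + Markdown report bundle.

input_error <- function(...) {
  stop(errorCondition(paste0(...), class = c("gexpand_input_error",
                                             "error", "condition")))
}

#' Run the full comparative analysis
#'
#' Orchestrates every stage on a set of inputs: extracts and polarizes
#' phylogenetically independent gut / non-gut comparisons, summarizes
#' size divergences (raw and completeness-corrected), runs the overall,
#' per-habitat, per-polarity and pathogen-excluded sign tests with t
#' confidence intervals, the unanimous-minority pattern probability for
#' the excluded pathogen comparisons, abundance-size regressions
#' (per-habitat polynomial, within-genus, and independent-contrast) when
#' an abundance table is supplied, MAG species-bin comparisons when a
#' MAG table is supplied, and enrichment statistics when a score table
#' is supplied.
#'
#' @param tree A `phylo`, a path to a Newick file, or a `cohort` (whose
#'   bundled tables are then used as defaults for the other inputs).
#' @param metadata Tip-record data.frame or TSV path (ignored when
#'   `tree` is a cohort).
#' @param abundance Optional abundance data.frame or TSV path.
#' @param mags Optional MAG data.frame or TSV path.
#' @param enrichment Optional enrichment data.frame or TSV path.
#' @param level Comparison level, `"congeneric"` or `"conspecific"`.
#' @param ci_method `"t"` or `"bootstrap"` for the mean-difference CIs.
#' @param n_boot Bootstrap resamples when `ci_method = "bootstrap"`.
#' @param seed Seed for stochastic steps (bootstrap).
#' @param min_completeness,max_contamination MAG quality filters.
#' @param out_dir Optional directory for the TSV + report bundle.
#' @return List of class `gexpand_report`.
#' @export
run_full_pipeline <- function(tree, metadata = NULL, abundance = NULL,
                              mags = NULL, enrichment = NULL,
                              level = "congeneric", ci_method = "t",
                              n_boot = 10000, seed = NULL,
                              min_completeness = 90,
                              max_contamination = NULL,
                              out_dir = NULL) {
  hashes <- list()
  if (inherits(tree, "cohort")) {
    cohort <- tree
    at <- cohort$tree
    abundance <- abundance %||% cohort$abundance
    mags <- mags %||% cohort$mags
    enrichment <- enrichment %||% cohort$enrichment
  } else {
    if (is.character(tree)) {
      if (!file.exists(tree)) input_error("tree file not found: ", tree)
      hashes$tree <- unname(tools::md5sum(tree))
      tree <- read_newick(tree)
    }
    if (is.null(metadata)) input_error("metadata is required")
    if (is.character(metadata)) {
      if (!file.exists(metadata))
        input_error("metadata file not found: ", metadata)
      hashes$metadata <- unname(tools::md5sum(metadata))
      metadata <- read_tip_metadata(metadata)
    }
    at <- join_tree_metadata(tree, metadata)
  }
  for (nm in c("abundance", "mags", "enrichment")) {
    v <- get(nm)
    if (is.character(v)) {
      if (!file.exists(v)) input_error(nm, " file not found: ", v)
      hashes[[nm]] <- unname(tools::md5sum(v))
      assign(nm, switch(nm, abundance = read_abundance_table(v),
                        mags = read_mag_table(v),
                        enrichment = read_enrichment_table(v)))
    }
  }

  comps <- find_independent_comparisons(at, level = level)
  comps <- polarize_comparisons(at, comps)
  summaries <- summarize_comparisons(comps, at$tips)

  tests <- list()
  tests$overall <- direction_test(comps, summaries, "all", ci_method,
                                  n_boot, seed)
  tests$gut_derived <- direction_test(comps, summaries, "gut_derived",
                                      ci_method, n_boot, seed)
  tests$nongut_derived <- direction_test(comps, summaries, "nongut_derived",
                                         ci_method, n_boot, seed,
                                         direction = "gut_smaller")
  part <- filter_pathogen_comparisons(comps, at$tips)
  sum_ret <- summaries[summaries$comparison_id %in%
                         part$retained$comparison_id, , drop = FALSE]
  tests$pathogen_excluded <- direction_test(part$retained, sum_ret, "all",
                                            ci_method, n_boot, seed)
  tests$pathogen_excluded_gut_derived <-
    direction_test(part$retained, sum_ret, "gut_derived", ci_method,
                   n_boot, seed)
  pattern <- pathogen_pattern(part, summaries)
  strata <- if (nrow(comps)) stratify_by_habitat(comps, summaries) else NULL

  regressions <- NULL
  if (!is.null(abundance))
    regressions <- abundance_analyses(at, abundance)

  mag_res <- NULL
  if (!is.null(mags)) {
    mc <- mag_species_comparisons(mags, min_completeness, max_contamination)
    mag_tips <- data.frame(tip_id = mags$bin_id,
                           assembly_size = mags$genome_size,
                           completeness = mags$completeness,
                           stringsAsFactors = FALSE)
    ms <- summarize_comparisons(mc, mag_tips)
    mag_res <- list(comparisons = mc, summaries = ms,
                    test = direction_test(mc, ms, "all", ci_method,
                                          n_boot, seed))
  }

  enr_res <- NULL
  if (!is.null(enrichment)) {
    per_source <- lapply(split(enrichment, enrichment$source),
                         enrichment_sign_test)
    per_source <- per_source[!vapply(per_source, function(x)
      identical(x, NA), logical(1))]
    praw <- vapply(per_source, function(s) s$p_one_sided, numeric(1))
    enr_res <- list(overall = enrichment_sign_test(enrichment),
                    per_source = per_source,
                    per_source_bh = bh_adjust(praw),
                    crispr = category_overrepresentation(enrichment,
                                                         "CRISPR", "zero"))
  }

  report <- structure(list(
    n_tips = nrow(at$tips), level = level, comparisons = comps,
    summaries = summaries, tests = tests, strata = strata,
    pathogen = list(n_retained = nrow(part$retained),
                    n_excluded = nrow(part$excluded),
                    pattern_probability = pattern),
    regressions = regressions, mag = mag_res, enrichment = enr_res,
    seed = seed, input_hashes = hashes), class = "gexpand_report")

  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

# Sign test + CI over (a polarity subset of) the summaries.
direction_test <- function(comps, summaries, polarity, ci_method = "t",
                           n_boot = 10000, seed = NULL,
                           direction = "gut_larger") {
  ids <- if (polarity == "all") comps$comparison_id
         else comps$comparison_id[comps$polarity == polarity]
  s <- summaries[summaries$comparison_id %in% ids & !summaries$tie, ,
                 drop = FALSE]
  n <- nrow(s)
  if (n == 0)
    return(list(n = 0, k = NA, sign_test = NA, ci = NA, ci_corrected = NA,
                polarity = polarity))
  k <- if (direction == "gut_larger") sum(s$gut_larger)
       else sum(!s$gut_larger)
  ci <- if (n >= 2) mean_percent_diff_ci(s$percent_diff, ci_method,
                                         n_boot = n_boot, seed = seed)
        else NA
  cic <- if (n >= 2) mean_percent_diff_ci(s$percent_diff_corrected,
                                          ci_method, n_boot = n_boot,
                                          seed = seed)
         else NA
  list(n = n, k = k, sign_test = sign_test(k, n, direction = direction),
       ci = ci, ci_corrected = cic, polarity = polarity)
}

# Chance probability that every pathogen-flagged comparison falls in the
# minority direction of the whole comparison set.
pathogen_pattern <- function(part, summaries) {
  exc <- summaries[summaries$comparison_id %in%
                     part$excluded$comparison_id & !summaries$tie, ,
                   drop = FALSE]
  all_s <- summaries[!summaries$tie, , drop = FALSE]
  if (!nrow(exc) || !nrow(all_s)) return(NA_real_)
  q_larger <- mean(all_s$gut_larger)
  majority_larger <- q_larger >= 0.5
  minority_unanimous <- if (majority_larger) all(!exc$gut_larger)
                        else all(exc$gut_larger)
  if (!minority_unanimous) return(NA_real_)
  pattern_probability(max(q_larger, 1 - q_larger), nrow(exc))
}

# Abundance-size regressions: per-habitat polynomial fits, within-genus
# centered fit (gut), and the independent-contrast regression on the
# gut-species subtree.
abundance_analyses <- function(at, abundance) {
  sizes_mb <- stats::setNames(
    corrected_size(at$tips$assembly_size, at$tips$completeness) / 1e6,
    at$tips$tip_id)
  genus <- stats::setNames(at$tips$genus, at$tips$tip_id)
  out <- list(per_habitat = list())
  for (h in intersect(unique(abundance$habitat), habitat_levels())) {
    fit <- tryCatch(abundance_size_regression(abundance, sizes_mb, h),
                    error = function(e) NULL)
    if (!is.null(fit)) out$per_habitat[[h]] <- fit
  }
  out$within_genus <- tryCatch(
    within_genus_regression(abundance, sizes_mb, genus, habitat = "gut"),
    error = function(e) NULL)
  out$pic <- tryCatch({
    y <- species_mean_log_abundance(abundance, "gut")
    sp <- intersect(names(y), at$tree$tip.label)
    if (length(sp) < 4) stop("too few gut species for contrasts")
    sub <- ape::keep.tip(at$tree, sp)
    cx <- pic_contrasts(sub, sizes_mb[sp])
    cy <- pic_contrasts(sub, y[sp])
    pic_regression(cx, cy)
  }, error = function(e) NULL)
  out
}

#' @export
print.gexpand_report <- function(x, ...) {
  cat("Habitat genome-size divergence report\n")
  cat(sprintf("  %d tips, %d independent %s comparisons\n", x$n_tips,
              nrow(x$comparisons), x$level))
  ov <- x$tests$overall
  if (ov$n > 0) {
    cat(sprintf("  overall: %d/%d gut larger, P = %.3g\n", ov$k, ov$n,
                ov$sign_test$p_one_sided))
    if (inherits(ov$ci, "interval_estimate"))
      cat(sprintf("  mean %% difference %.2f (%.2f, %.2f)\n", ov$ci$mean,
                  ov$ci$ci_low, ov$ci$ci_high))
  }
  invisible(x)
}

# Write the TSV tables plus a human-readable Markdown report.
write_report <- function(report, out_dir) {
  tables <- list(comparisons = report$comparisons,
                 summaries = report$summaries)
  if (!is.null(report$strata)) tables$strata <- report$strata
  tables$tests <- tests_table(report)
  if (!is.null(report$mag)) {
    tables$mag_comparisons <- report$mag$comparisons
    tables$mag_summaries <- report$mag$summaries
  }
  man <- list(stage = "run", level = report$level,
              seed = report$seed %||% NA,
              input_hashes = report$input_hashes)
  paths <- write_results(tables, out_dir, manifest = man)
  md <- file.path(out_dir, "report.md")
  writeLines(report_markdown(report), md)
  invisible(c(paths, md))
}

tests_table <- function(report) {
  row <- function(name, t) {
    if (!is.list(t) || t$n == 0)
      return(data.frame(test = name, n = 0, k = NA, direction = NA,
                        p_one_sided = NA, mean_percent_diff = NA,
                        ci_low = NA, ci_high = NA, stringsAsFactors = FALSE))
    data.frame(test = name, n = t$n, k = t$k,
               direction = t$sign_test$direction,
               p_one_sided = t$sign_test$p_one_sided,
               mean_percent_diff = if (inherits(t$ci, "interval_estimate"))
                 t$ci$mean else NA,
               ci_low = if (inherits(t$ci, "interval_estimate"))
                 t$ci$ci_low else NA,
               ci_high = if (inherits(t$ci, "interval_estimate"))
                 t$ci$ci_high else NA,
               stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, lapply(names(report$tests), function(nm)
    row(nm, report$tests[[nm]])))
  if (!is.null(report$mag)) out <- rbind(out, row("mag", report$mag$test))
  out
}

report_markdown <- function(report) {
  lines <- c("# Habitat genome-size divergence report", "",
             sprintf("Tips: %d; level: %s; comparisons: %d", report$n_tips,
                     report$level, nrow(report$comparisons)), "")
  tt <- tests_table(report)
  lines <- c(lines, "## Sign tests", "",
             paste(utils::capture.output(print(tt, row.names = FALSE)),
                   collapse = "\n"), "")
  if (!is.null(report$strata)) {
    lines <- c(lines, "## Habitat strata", "",
               paste(utils::capture.output(
                 print(report$strata, row.names = FALSE)), collapse = "\n"),
               "")
  }
  lines <- c(lines, "## Pathogen exclusion", "",
             sprintf("Retained %d, excluded %d; unanimous-minority pattern probability: %s",
                     report$pathogen$n_retained, report$pathogen$n_excluded,
                     format(report$pathogen$pattern_probability)), "")
  if (!is.null(report$regressions)) {
    lines <- c(lines, "## Abundance-size regressions", "")
    for (h in names(report$regressions$per_habitat)) {
      r <- report$regressions$per_habitat[[h]]
      lines <- c(lines, sprintf(
        "- %s: linear coefficient %.4g (P = %.3g), R^2 = %.3g, n = %d",
        h, r$coefficients[["x1"]], r$p_linear, r$r_squared, r$n))
    }
    if (!is.null(report$regressions$within_genus)) {
      r <- report$regressions$within_genus
      lines <- c(lines, sprintf(
        "- within-genus (gut): slope %.4g (P = %.3g), R^2 = %.3g",
        r$coefficients[["x1"]], r$p_linear, r$r_squared))
    }
    if (!is.null(report$regressions$pic)) {
      r <- report$regressions$pic
      lines <- c(lines, sprintf(
        "- independent contrasts (gut): slope %.4g (P = %.3g), R^2 = %.3g",
        r$coefficients[["slope"]], r$p_linear, r$r_squared))
    }
    lines <- c(lines, "")
  }
  if (!is.null(report$enrichment)) {
    ov <- report$enrichment$overall
    lines <- c(lines, "## Enrichment", "",
               if (inherits(ov, "sign_test"))
                 sprintf("Overall direction: %d/%d positive, P = %.3g",
                         ov$k, ov$n, ov$p_one_sided)
               else "Overall direction: NA (all scores zero)",
               sprintf("CRISPR overrepresentation (vs zero-score): P = %.3g",
                       report$enrichment$crispr$p_value), "")
  }
  lines
}
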