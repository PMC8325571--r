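# Reading, validating and writing the external representations: Newick
# trees, tab-separated metadata/abundance/MAG/enrichment tables, and the
# TSV + manifest result bundle.

#' Read a rooted Newick tree
#'
#' Thin, validating wrapper around [ape::read.tree()]. The tree must be
#' rooted, have unique tip labels, and carry a branch length on every
#' edge unless `default_branch_length` supplies one. Negative branch
#' lengths are rejected (zero is allowed: downstream contrast and
#' Brownian-motion machinery requires nonnegative lengths only).
#'
#' @param path Path to a Newick file.
#' @param default_branch_length Optional length substituted for missing
#'   branch lengths; by default missing lengths are an error.
#' @return An object of class `phylo`.
#' @export
read_newick <- function(path, default_branch_length = NULL) {
  if (!file.exists(path)) stop("tree file does not exist: ", path)
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  check_newick_syntax(txt)
  tree <- tryCatch(ape::read.tree(text = txt),
                   error = function(e) NULL, warning = function(w) NULL)
  if (is.null(tree) || !inherits(tree, "phylo"))
    stop("malformed Newick in ", path)
  validate_tree(tree, default_branch_length)
}

# Cheap syntax pre-check so parse failures report a character offset,
# which ape's parser does not.
check_newick_syntax <- function(txt) {
  chars <- strsplit(txt, "")[[1]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L)
        stop("malformed Newick: unmatched ')' at character offset ", i)
    }
  }
  if (depth != 0L)
    stop("malformed Newick: ", depth,
         " unclosed '(' by character offset ", length(chars))
  if (!grepl(";", txt))
    stop("malformed Newick: missing terminating ';' at character offset ",
         length(chars))
  invisible(TRUE)
}

validate_tree <- function(tree, default_branch_length = NULL) {
  if (anyDuplicated(tree$tip.label))
    stop("duplicate tip labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "))
  if (is.null(tree$edge.length)) {
    if (is.null(default_branch_length))
      stop("tree has no branch lengths; supply default_branch_length to proceed")
    tree$edge.length <- rep(default_branch_length, nrow(tree$edge))
  }
  if (anyNA(tree$edge.length)) {
    if (is.null(default_branch_length))
      stop("tree has missing branch lengths; supply default_branch_length")
    tree$edge.length[is.na(tree$edge.length)] <- default_branch_length
  }
  if (any(tree$edge.length < 0))
    stop("negative branch lengths are not allowed")
  tree
}

#' Write a tree in Newick format
#'
#' Branch lengths are printed to at least 12 significant digits so that
#' read/write round-trips preserve them.
#'
#' @param tree A `phylo` object.
#' @param path Output file path.
#' @param digits Significant digits for branch lengths (default 12).
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path, digits = 12) {
  ape::write.tree(tree, file = path, digits = digits)
  invisible(path)
}

#' Read a tip-metadata table
#'
#' Reads a tab-separated table (UTF-8, `#` comment lines ignored; CSV via
#' `sep = ","`) of per-genome records. Required columns: `tip_id`,
#' `genus`, `habitat`, `assembly_size`, `completeness`; optional:
#' `species`, `pathogen_flag`. Habitat strings are normalized
#' case-insensitively onto the closed vocabulary of [habitat_levels()];
#' unknown values map to `"other"` with a warning. `aliases` supplies
#' custom site-to-habitat mappings (e.g. `c(stool = "gut")`).
#'
#' @param path Path to the table.
#' @param sep Field separator; tab by default.
#' @param aliases Optional named character vector mapping custom site
#'   labels (lower-cased) to habitat levels.
#' @return A data.frame of validated tip records.
#' @export
read_tip_metadata <- function(path, sep = "\t", aliases = NULL) {
  if (!file.exists(path)) stop("metadata file does not exist: ", path)
  df <- utils::read.table(path, header = TRUE, sep = sep, comment.char = "#",
                          stringsAsFactors = FALSE, quote = "",
                          check.names = FALSE)
  validate_tip_metadata(df, aliases = aliases)
}

#' Validate a data.frame of tip records
#'
#' @param df Data.frame with the columns described in
#'   [read_tip_metadata()].
#' @param aliases Optional site-label aliases, as in
#'   [read_tip_metadata()].
#' @return The validated, normalized data.frame.
#' @export
validate_tip_metadata <- function(df, aliases = NULL) {
  required <- c("tip_id", "genus", "habitat", "assembly_size", "completeness")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("metadata is missing required column(s): ",
         paste(missing, collapse = ", "))
  df$tip_id <- as.character(df$tip_id)
  if (anyDuplicated(df$tip_id))
    stop("duplicate tip_id values: ",
         paste(unique(df$tip_id[duplicated(df$tip_id)]), collapse = ", "))
  df$genus <- as.character(df$genus)
  if (!"species" %in% names(df)) df$species <- NA_character_
  df$species <- as.character(df$species)
  df$habitat <- normalize_habitat(df$habitat, aliases = aliases)

  for (col in c("assembly_size", "completeness")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]))
    if (length(bad))
      stop("non-numeric ", col, " in row(s): ", paste(bad, collapse = ", "))
    df[[col]] <- v
  }
  bad_size <- which(is.na(df$assembly_size) | df$assembly_size <= 0)
  if (length(bad_size))
    stop("assembly_size must be > 0; offending row(s): ",
         paste(bad_size, collapse = ", "))
  bad_comp <- which(is.na(df$completeness) | df$completeness <= 0 |
                      df$completeness > 100)
  if (length(bad_comp))
    stop("completeness must lie in (0, 100]; offending row(s): ",
         paste(bad_comp, collapse = ", "))
  if (!"pathogen_flag" %in% names(df)) df$pathogen_flag <- FALSE
  df$pathogen_flag <- parse_flag(df$pathogen_flag)
  df[, c("tip_id", "genus", "species", "habitat", "assembly_size",
         "completeness", "pathogen_flag")]
}

normalize_habitat <- function(x, aliases = NULL) {
  lev <- habitat_levels()
  x <- tolower(trimws(as.character(x)))
  if (!is.null(aliases)) {
    names(aliases) <- tolower(names(aliases))
    hit <- x %in% names(aliases)
    x[hit] <- unname(aliases[x[hit]])
  }
  unknown <- !(x %in% lev)
  if (any(unknown)) {
    warning("unknown habitat value(s) mapped to 'other': ",
            paste(unique(x[unknown]), collapse = ", "))
    x[unknown] <- "other"
  }
  x
}

parse_flag <- function(x) {
  if (is.logical(x)) return(ifelse(is.na(x), FALSE, x))
  x <- tolower(trimws(as.character(x)))
  out <- x %in% c("true", "t", "1", "yes", "y")
  bad <- !(x %in% c("true", "t", "1", "yes", "y",
                    "false", "f", "0", "no", "n", "na", ""))
  if (any(bad))
    stop("unparseable pathogen_flag value(s): ",
         paste(unique(x[bad]), collapse = ", "))
  out
}

#' Join a tree with its tip metadata
#'
#' Verifies that the tip set of the tree and the `tip_id` set of the
#' records are in bijection, and returns an annotated tree. Downstream
#' analyses refuse partial joins: any orphan tip or orphan record is an
#' error naming both sets.
#'
#' @param tree A `phylo` object.
#' @param records Tip-record data.frame (see [read_tip_metadata()]).
#' @return An object of class `annotated_tree`: a list with elements
#'   `tree` (`phylo`) and `tips` (records, reordered to match the tree's
#'   tip order).
#' @export
join_tree_metadata <- function(tree, records) {
  records <- validate_tip_metadata(records)
  tips <- tree$tip.label
  orphan_tips <- setdiff(tips, records$tip_id)
  orphan_recs <- setdiff(records$tip_id, tips)
  if (length(orphan_tips) || length(orphan_recs))
    stop("tree/metadata join is not a bijection; tips without records: {",
         paste(orphan_tips, collapse = ", "), "}; records without tips: {",
         paste(orphan_recs, collapse = ", "), "}")
  records <- records[match(tips, records$tip_id), , drop = FALSE]
  rownames(records) <- NULL
  structure(list(tree = tree, tips = records), class = "annotated_tree")
}

#' @export
print.annotated_tree <- function(x, ...) {
  cat("Annotated phylogeny:", length(x$tree$tip.label), "tips,",
      x$tree$Nnode, "internal nodes\n")
  cat("Habitats:", paste(sprintf("%s=%d", names(table(x$tips$habitat)),
                                 table(x$tips$habitat)), collapse = ", "), "\n")
  invisible(x)
}

#' Read a relative-abundance table
#'
#' Columns: `species`, `habitat`, `host_id`, `rel_abundance`.
#' Abundances must lie in \[0, 1\] and sum to at most 1 within each
#' (host, habitat) sample.
#'
#' @param path Path to the TSV.
#' @param sep Field separator.
#' @return Validated data.frame of abundance records.
#' @export
read_abundance_table <- function(path, sep = "\t") {
  df <- utils::read.table(path, header = TRUE, sep = sep, comment.char = "#",
                          stringsAsFactors = FALSE, quote = "")
  validate_abundance(df)
}

validate_abundance <- function(df) {
  required <- c("species", "habitat", "host_id", "rel_abundance")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("abundance table missing column(s): ", paste(missing, collapse = ", "))
  df$rel_abundance <- as.numeric(df$rel_abundance)
  if (any(is.na(df$rel_abundance) | df$rel_abundance < 0 |
            df$rel_abundance > 1))
    stop("rel_abundance must lie in [0, 1]")
  df$habitat <- normalize_habitat(df$habitat)
  tot <- stats::aggregate(rel_abundance ~ host_id + habitat, df, sum)
  if (any(tot$rel_abundance > 1 + 1e-9))
    stop("relative abundances exceed 1 within a (host, habitat) sample")
  df
}

#' Read a MAG metadata table
#'
#' Columns: `bin_id`, `species_bin`, `habitat`, `completeness`,
#' `genome_size`; optional `contamination`.
#'
#' @param path Path to the TSV.
#' @param sep Field separator.
#' @return Validated data.frame of MAG records.
#' @export
read_mag_table <- function(path, sep = "\t") {
  df <- utils::read.table(path, header = TRUE, sep = sep, comment.char = "#",
                          stringsAsFactors = FALSE, quote = "")
  validate_mags(df)
}

validate_mags <- function(df) {
  required <- c("bin_id", "species_bin", "habitat", "completeness",
                "genome_size")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("MAG table missing column(s): ", paste(missing, collapse = ", "))
  df$completeness <- as.numeric(df$completeness)
  df$genome_size <- as.numeric(df$genome_size)
  if (any(is.na(df$completeness) | df$completeness <= 0 |
            df$completeness > 100))
    stop("MAG completeness must lie in (0, 100]")
  if (any(is.na(df$genome_size) | df$genome_size <= 0))
    stop("MAG genome_size must be > 0")
  if (!"contamination" %in% names(df)) df$contamination <- NA_real_
  df$habitat <- normalize_habitat(df$habitat)
  df
}

#' Read a functional-enrichment score table
#'
#' Columns: `annotation_id`, `source`, `score`; optional
#' `category_flags` (comma-separated strings, e.g. `"CRISPR"`). Positive
#' scores mean gut-enriched, negative mean enriched at other body sites,
#' zero means no enrichment.
#'
#' @param path Path to the TSV.
#' @param sep Field separator.
#' @return Validated data.frame with `category_flags` as a list column.
#' @export
read_enrichment_table <- function(path, sep = "\t") {
  df <- utils::read.table(path, header = TRUE, sep = sep, comment.char = "#",
                          stringsAsFactors = FALSE, quote = "")
  required <- c("annotation_id", "source", "score")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("enrichment table missing column(s): ",
         paste(missing, collapse = ", "))
  df$score <- as.numeric(df$score)
  if (any(!is.finite(df$score))) stop("enrichment scores must be finite")
  if (!"category_flags" %in% names(df)) df$category_flags <- ""
  df$category_flags <- as.character(df$category_flags)
  df
}

#' Write a result bundle to a directory
#'
#' Each table is written as a TSV with a fixed column order; list columns
#' (tip-id sets) are flattened to comma-separated strings. A
#' `manifest.yaml` records the configuration, seeds and package version
#' so a run can be reproduced; the timestamp is the only
#' non-deterministic field.
#'
#' @param tables Named list of data.frames.
#' @param out_dir Output directory (created if needed).
#' @param manifest Named list of run metadata merged into the manifest.
#' @return Character vector of file paths written, invisibly.
#' @export
write_results <- function(tables, out_dir, manifest = list()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  paths <- character(0)
  for (nm in names(tables)) {
    df <- flatten_list_columns(tables[[nm]])
    p <- file.path(out_dir, paste0(nm, ".tsv"))
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE,
                       na = "NA")
    paths <- c(paths, p)
  }
  man <- c(manifest,
           list(package_version = as.character(utils::packageVersion("gexpand")),
                timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")))
  mp <- file.path(out_dir, "manifest.yaml")
  yaml::write_yaml(man, mp)
  invisible(c(paths, mp))
}

flatten_list_columns <- function(df) {
  for (nm in names(df)) {
    if (is.list(df[[nm]]))
      df[[nm]] <- vapply(df[[nm]], function(v) paste(v, collapse = ","), "")
  }
  df
}
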