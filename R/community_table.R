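# Core domain objects: the OTU-by-sample count table with metadata, and the
# paired rooted phylogeny. All matrices are OTUs-as-rows, samples-as-columns;
# relative abundances are stored as fractions (0.01% == 1e-4).

#' Construct a community table
#'
#' The central observational object: a non-negative integer OTU-by-sample
#' count matrix plus a group label per sample (e.g. "monsoon" /
#' "intermonsoon") and optional named environmental variables per sample
#' (temperature, nutrients, chlorophyll a, ...).
#'
#' @param counts integer matrix, OTUs in rows, samples in columns. Row and
#'   column names are the OTU and sample identifiers.
#' @param sample_groups named character vector mapping every sample id to a
#'   group label.
#' @param env optional data.frame of per-sample environmental variables,
#'   rows named by sample id.
#' @return an object of class `community_table` with elements `counts`,
#'   `otu_ids`, `sample_ids`, `sample_groups`, `env`.
#' @export
#' @examples
#' m <- matrix(1:6, nrow = 3, dimnames = list(paste0("OTU", 1:3), c("s1", "s2")))
#' ct <- community_table(m, c(s1 = "monsoon", s2 = "intermonsoon"))
community_table <- function(counts, sample_groups, env = NULL) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("`counts` must have OTU row names and sample column names")
  }
  bad <- which(counts < 0 | counts != round(counts), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf(
      "non-integer or negative count at OTU '%s', sample '%s'",
      rownames(counts)[bad[1, 1]], colnames(counts)[bad[1, 2]]
    ))
  }
  if (anyDuplicated(rownames(counts))) stop("duplicate OTU ids")
  if (anyDuplicated(colnames(counts))) stop("duplicate sample ids")
  sample_groups <- sample_groups[colnames(counts)]
  if (any(is.na(sample_groups)) || any(!nzchar(sample_groups))) {
    missing <- colnames(counts)[is.na(sample_groups) | !nzchar(sample_groups)]
    stop("samples missing a group label: ", paste(missing, collapse = ", "))
  }
  names(sample_groups) <- colnames(counts)
  if (!is.null(env)) {
    env <- as.data.frame(env)
    if (!all(colnames(counts) %in% rownames(env))) {
      stop("environmental table missing samples: ",
           paste(setdiff(colnames(counts), rownames(env)), collapse = ", "))
    }
    env <- env[colnames(counts), , drop = FALSE]
  }
  structure(
    list(
      counts = counts,
      otu_ids = rownames(counts),
      sample_ids = colnames(counts),
      sample_groups = sample_groups,
      env = env
    ),
    class = "community_table"
  )
}

#' @export
print.community_table <- function(x, ...) {
  cat(sprintf(
    "community_table: %d OTUs x %d samples (%s)\n",
    nrow(x$counts), ncol(x$counts),
    paste(sprintf("%s: %d", names(table(x$sample_groups)),
                  as.integer(table(x$sample_groups))), collapse = ", ")
  ))
  invisible(x)
}

#' Read a community table from TSV files
#'
#' The counts file has a header row of sample ids with first column
#' `#OTU ID`; the metadata file has columns `sample_id`, `group`, then any
#' number of environmental columns. Metadata rows for unknown samples are
#' ignored with a warning.
#'
#' @param path path to the tab-separated counts file.
#' @param metadata_path path to the tab-separated metadata file.
#' @return a [community_table()].
#' @export
read_community_table <- function(path, metadata_path) {
  tab <- utils::read.delim(path, check.names = FALSE, comment.char = "",
                           stringsAsFactors = FALSE)
  otus <- as.character(tab[[1]])
  counts <- as.matrix(tab[, -1, drop = FALSE])
  rownames(counts) <- otus
  meta <- utils::read.delim(metadata_path, check.names = FALSE,
                            stringsAsFactors = FALSE)
  if (!all(c("sample_id", "group") %in% colnames(meta))) {
    stop("metadata must have columns 'sample_id' and 'group'")
  }
  extra <- setdiff(meta$sample_id, colnames(counts))
  if (length(extra) > 0) {
    warning("metadata rows for unknown samples ignored: ",
            paste(extra, collapse = ", "))
    meta <- meta[meta$sample_id %in% colnames(counts), , drop = FALSE]
  }
  missing <- setdiff(colnames(counts), meta$sample_id)
  if (length(missing) > 0) {
    stop("samples missing a group label: ", paste(missing, collapse = ", "))
  }
  groups <- stats::setNames(as.character(meta$group), meta$sample_id)
  env_cols <- setdiff(colnames(meta), c("sample_id", "group"))
  env <- NULL
  if (length(env_cols) > 0) {
    env <- meta[, env_cols, drop = FALSE]
    rownames(env) <- meta$sample_id
  }
  community_table(counts, groups, env)
}

#' Write a community table to TSV files
#'
#' Emits the same dialect [read_community_table()] reads, so write/read
#' round-trips are identity.
#'
#' @param table a [community_table()].
#' @param path counts TSV destination.
#' @param metadata_path metadata TSV destination.
#' @return invisibly, the paths written.
#' @export
write_community_table <- function(table, path, metadata_path) {
  df <- data.frame(`#OTU ID` = table$otu_ids, table$counts,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- data.frame(sample_id = table$sample_ids,
                     group = unname(table$sample_groups))
  if (!is.null(table$env)) meta <- cbind(meta, table$env)
  utils::write.table(meta, metadata_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(path, metadata_path))
}

#' Read a rooted phylogeny from a Newick file
#'
#' Thin wrapper over [ape::read.tree()] adding the validation the null
#' models require: unique tip labels and non-negative branch lengths.
#' Missing branch lengths are set to 0 with a warning.
#'
#' @param path path to a Newick file.
#' @return an [ape::phylo] tree.
#' @export
read_newick <- function(path) {
  tree <- tryCatch(ape::read.tree(path),
                   error = function(e) stop("Newick parse error: ",
                                            conditionMessage(e)))
  if (is.null(tree)) stop("Newick parse error: could not read ", path)
  validate_tree(tree)
}

#' @rdname read_newick
#' @param tree an [ape::phylo] tree to validate.
#' @export
validate_tree <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a phylo object")
  if (anyDuplicated(tree$tip.label)) {
    stop("duplicate tip labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "))
  }
  if (is.null(tree$edge.length)) {
    warning("tree has no branch lengths; assigning 0")
    tree$edge.length <- rep(0, nrow(tree$edge))
  }
  if (anyNA(tree$edge.length)) {
    warning("tips without branch lengths assigned 0")
    tree$edge.length[is.na(tree$edge.length)] <- 0
  }
  if (any(tree$edge.length < 0)) stop("negative branch lengths")
  tree
}

#' Write a phylogeny to a Newick file
#'
#' @param tree an [ape::phylo] tree.
#' @param path destination path.
#' @return invisibly, `path`.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Align a community table and a phylogeny
#'
#' Tree tips absent from the table are pruned with a warning; table OTUs
#' missing from the tree are a hard error, because the phylogenetic null
#' models are undefined for them.
#'
#' @param table a [community_table()].
#' @param tree an [ape::phylo] tree.
#' @return list with elements `table` and `tree`, tip set equal to OTU set.
#' @export
align_tree_table <- function(table, tree) {
  missing <- setdiff(table$otu_ids, tree$tip.label)
  if (length(missing) > 0) {
    stop("OTUs missing from the tree (null models undefined): ",
         paste(utils::head(missing, 5), collapse = ", "),
         if (length(missing) > 5) sprintf(" ... (%d total)", length(missing)))
  }
  extra <- setdiff(tree$tip.label, table$otu_ids)
  if (length(extra) > 0) {
    warning(sprintf("pruning %d tree tips absent from the table", length(extra)))
    tree <- ape::drop.tip(tree, extra)
  }
  list(table = table, tree = tree)
}

#' Rarefy a count table to equal depth
#'
#' Subsamples every sample without replacement (multivariate
#' hypergeometric) to exactly `depth` reads, the normalization applied to
#' survey data before all downstream analyses.
#'
#' @param table a [community_table()].
#' @param depth target reads per sample; every sample total must be at
#'   least `depth` (undersized samples are an error, never dropped
#'   silently).
#' @param seed integer seed; the same seed reproduces the same subsample.
#' @return a rarefied [community_table()] whose columns each sum to `depth`.
#' @export
rarefy_counts <- function(table, depth, seed) {
  stopifnot(depth > 0, depth == round(depth))
  totals <- colSums(table$counts)
  small <- totals < depth
  if (any(small)) {
    stop("samples with fewer than `depth` reads: ",
         paste(sprintf("%s (%d)", names(totals)[small],
                       as.integer(totals[small])), collapse = ", "))
  }
  rare <- with_seed(seed, {
    # vegan warns whenever the smallest nonzero count exceeds 1, which is
    # routine for valid integer tables; silence only that message
    withCallingHandlers(
      t(vegan::rrarefy(t(table$counts), depth)),
      warning = function(w) {
        if (grepl("observed counts", conditionMessage(w))) {
          invokeRestart("muffleWarning")
        }
      }
    )
  })
  dimnames(rare) <- dimnames(table$counts)
  community_table(rare, table$sample_groups, table$env)
}

#' Per-sample relative abundance
#'
#' Divides each sample column by its total. All-zero samples stay all-zero
#' with a warning. Values are fractions in \[0, 1\] (0.01% == 1e-4).
#'
#' @param table a [community_table()].
#' @return object of class `rel_abundance`: list with `values` (matrix of
#'   fractions, same axes as the counts) plus the table's ids and groups.
#' @export
relative_abundance <- function(table) {
  totals <- colSums(table$counts)
  if (any(totals == 0)) {
    warning("all-zero samples left all-zero: ",
            paste(names(totals)[totals == 0], collapse = ", "))
  }
  scale <- ifelse(totals > 0, totals, 1)
  values <- sweep(table$counts, 2, scale, "/")
  structure(
    list(values = values, otu_ids = table$otu_ids,
         sample_ids = table$sample_ids, sample_groups = table$sample_groups,
         env = table$env),
    class = "rel_abundance"
  )
}

#' Cophenetic (patristic) distance matrix of a phylogeny
#'
#' d(i, j) is the sum of branch lengths on the path between tips i and j;
#' symmetric with zero diagonal.
#'
#' @param tree an [ape::phylo] tree.
#' @return numeric matrix labelled by tip.
#' @export
cophenetic_matrix <- function(tree) {
  D <- ape::cophenetic.phylo(validate_tree(tree))
  D[tree$tip.label, tree$tip.label]
}
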