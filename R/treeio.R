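## Tree input, validation and branching-time extraction.
##
## Time convention: 0 = present, ages increase into the past (Myr).  Node
## ages are always recomputed from the branch lengths (summed from the
## tips), never read from annotations.

#' Node ages of a dated tree
#'
#' @param tree a rooted `phylo` object with branch lengths.
#' @return numeric vector of ages (root age minus root-to-node distance) for
#'   all nodes, tips first, in `phylo` node numbering.
#' @keywords internal
.node_ages <- function(tree) {
  depth <- ape::node.depth.edgelength(tree)
  max(depth[seq_len(ape::Ntip(tree))]) - depth
}

# validate a single tree; idx only used for error messages
.validate_tree <- function(tree, ultra_tol = 1e-4, idx = NA) {
  where <- if (is.na(idx)) "" else paste0(" (tree ", idx, ")")
  if (!inherits(tree, "phylo")) .verr("not a phylo object", where)
  if (is.null(tree$edge.length)) .verr("tree has no branch lengths", where)
  if (!ape::is.rooted(tree)) .verr("tree is not rooted", where)
  if (!ape::is.binary(tree)) .verr("tree contains polytomies", where)
  ages <- .node_ages(tree)
  ntip <- ape::Ntip(tree)
  root_age <- max(ages)
  if (!(root_age > 0)) .verr("tree has zero depth", where)
  tip_ages <- abs(ages[seq_len(ntip)])
  if (max(tip_ages) > ultra_tol * root_age)
    .verr("tree is not ultrametric within tolerance: max tip age ",
          format(max(tip_ages)), " vs root age ", format(root_age), where)
  invisible(tree)
}

#' Read a posterior sample of dated trees
#'
#' Reads all trees from a NEXUS trees block (translate tables honoured,
#' BEAST-style square-bracket annotations stripped) or a plain newick file
#' (one tree per line), validates that every tree is rooted, binary and
#' ultrametric, and optionally keeps a uniform random subsample.
#'
#' @param path path to the tree file.
#' @param format `"auto"` (sniff for `#NEXUS`), `"nexus"` or `"newick"`.
#' @param subsample number of trees to keep (uniform without replacement),
#'   or `NULL` for all.
#' @param seed RNG seed for the subsample; the caller's RNG state is
#'   restored afterwards.
#' @param ultra_tol ultrametricity tolerance as a fraction of the root age.
#' @return a `tree_sample` object: a list of `phylo` trees with provenance
#'   attributes.
#' @export
read_trees <- function(path, format = c("auto", "nexus", "newick"),
                       subsample = NULL, seed = NULL, ultra_tol = 1e-4) {
  format <- match.arg(format)
  if (!file.exists(path)) .verr("tree file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (format == "auto") {
    first <- lines[nzchar(trimws(lines))][1]
    format <- if (!is.na(first) && grepl("^#NEXUS", trimws(first),
                                         ignore.case = TRUE))
      "nexus" else "newick"
  }
  if (format == "nexus") {
    txt <- paste(lines, collapse = "\n")
    # strip (possibly nested) square-bracket comments/annotations
    repeat {
      new <- gsub("\\[[^][]*\\]", "", txt)
      if (identical(new, txt)) break
      txt <- new
    }
    tf <- tempfile(fileext = ".nex")
    on.exit(unlink(tf), add = TRUE)
    writeLines(txt, tf)
    trees <- ape::read.nexus(tf)
  } else {
    trees <- ape::read.tree(text = paste(lines, collapse = "\n"))
  }
  if (inherits(trees, "phylo")) trees <- list(trees)
  trees <- unclass(trees)
  if (length(trees) == 0) .verr("no trees found in ", path)
  if (!is.null(subsample)) {
    if (subsample < 1 || subsample > length(trees))
      .verr("subsample must be between 1 and the number of trees")
    keep <- .with_seed(seed, sort(sample.int(length(trees), subsample)))
    trees <- trees[keep]
  }
  tree_sample(trees, ultra_tol = ultra_tol,
              provenance = list(source = path, subsample = subsample,
                                seed = seed))
}

#' Construct a validated tree sample
#'
#' @param trees a `phylo` or list of `phylo` objects with identical tip
#'   label sets.
#' @param ultra_tol ultrametricity tolerance (fraction of root age).
#' @param provenance optional metadata list.
#' @return object of class `tree_sample`.
#' @export
tree_sample <- function(trees, ultra_tol = 1e-4, provenance = list()) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  if (!length(trees)) .verr("tree sample is empty")
  ref <- sort(trees[[1]]$tip.label)
  for (i in seq_along(trees)) {
    .validate_tree(trees[[i]], ultra_tol = ultra_tol, idx = i)
    if (!identical(sort(trees[[i]]$tip.label), ref))
      .verr("tree ", i, " has tips missing or extra relative to tree 1")
  }
  structure(trees, class = "tree_sample", provenance = provenance)
}

#' @export
print.tree_sample <- function(x, ...) {
  cat("tree_sample:", length(x), "trees,", ape::Ntip(x[[1]]), "tips\n")
  invisible(x)
}

#' Branching times of an ultrametric tree
#'
#' Extracts the ages of the internal nodes (Myr before present), sorted in
#' non-increasing order.  These are the sufficient statistic for all
#' diversification likelihoods in the package.
#'
#' @param tree a `phylo` object, or a numeric vector of node ages (which is
#'   sorted and wrapped as-is).
#' @return object of class `branching_times`: list with elements `x` (ages,
#'   non-increasing, length `s - 1`), `s` (number of tips) and `root_age`.
#' @export
branching_times <- function(tree) {
  if (inherits(tree, "branching_times")) return(tree)
  if (is.numeric(tree)) {
    x <- sort(as.numeric(tree), decreasing = TRUE)
    if (length(x) < 1 || any(x <= 0)) .verr("node ages must be positive")
    return(structure(list(x = x, s = length(x) + 1L, root_age = x[1]),
                     class = "branching_times"))
  }
  if (!inherits(tree, "phylo")) .verr("need a phylo object or numeric ages")
  ntip <- ape::Ntip(tree)
  if (ntip < 2) .verr("tree must have at least 2 tips")
  ages <- .node_ages(tree)
  x <- sort(ages[(ntip + 1):(ntip + tree$Nnode)], decreasing = TRUE)
  structure(list(x = x, s = ntip, root_age = x[1]),
            class = "branching_times")
}

#' @export
print.branching_times <- function(x, ...) {
  cat("branching_times: s =", x$s, " root age =", format(x$root_age), "\n")
  invisible(x)
}

#' Define a clade partition
#'
#' @param labels character vector of clade labels.
#' @param taxa list of character vectors (pairwise disjoint taxon sets, each
#'   of size >= 2).
#' @param rho per-clade sampling fractions in (0, 1]; recycled if scalar.
#' @return object of class `clade_partition`.
#' @export
clade_partition <- function(labels, taxa, rho = 1) {
  if (length(labels) != length(taxa)) .verr("labels and taxa differ in length")
  if (anyDuplicated(labels)) .verr("duplicated clade labels")
  rho <- rep_len(rho, length(labels))
  if (any(rho <= 0 | rho > 1)) .verr("sampling fractions must be in (0, 1]")
  all_taxa <- unlist(taxa)
  if (anyDuplicated(all_taxa)) .verr("taxon sets are not pairwise disjoint")
  if (any(lengths(taxa) < 2)) .verr("each clade needs at least 2 taxa")
  structure(list(labels = labels, taxa = taxa, rho = rho),
            class = "clade_partition")
}

#' Read a clade partition from a plain-text file
#'
#' One clade per line: `label rho taxon1,taxon2,...`.  Blank lines and lines
#' starting with `#` are ignored.
#'
#' @param path file path.
#' @return a [clade_partition()] object.
#' @export
read_clade_partition <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) .verr("no clades found in ", path)
  parts <- strsplit(lines, "[[:space:]]+")
  bad <- which(lengths(parts) != 3)
  if (length(bad)) .verr("malformed clade line ", bad[1], " in ", path)
  clade_partition(labels = vapply(parts, `[[`, "", 1),
                  taxa = lapply(parts, function(p)
                    strsplit(p[3], ",", fixed = TRUE)[[1]]),
                  rho = as.numeric(vapply(parts, `[[`, "", 2)))
}

#' Per-clade crown branching times
#'
#' Checks that each taxon set is monophyletic in the tree and returns the
#' crown-group branching times of each clade (the clade's own root age is
#' its oldest branching time).
#'
#' @param tree a `phylo` object.
#' @param partition a [clade_partition()].
#' @param tree_index index used in error messages when iterating a sample.
#' @return list with one element per clade: `list(label, bt, rho)`.
#' @export
clade_branching_times <- function(tree, partition, tree_index = NA) {
  if (!inherits(partition, "clade_partition")) .verr("need a clade_partition")
  missing <- setdiff(unlist(partition$taxa), tree$tip.label)
  if (length(missing))
    .verr("taxa not in tree: ", paste(missing, collapse = ", "))
  out <- vector("list", length(partition$labels))
  for (i in seq_along(out)) {
    taxa <- partition$taxa[[i]]
    mrca <- ape::getMRCA(tree, taxa)
    sub <- ape::extract.clade(tree, mrca)
    if (!setequal(sub$tip.label, taxa))
      .verr("clade '", partition$labels[i], "' is not monophyletic",
            if (is.na(tree_index)) "" else paste0(" in tree ", tree_index))
    out[[i]] <- list(label = partition$labels[i],
                     bt = branching_times(sub),
                     rho = partition$rho[i])
  }
  out
}
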