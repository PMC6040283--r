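# Neighbor-joining phylogeny with bootstrap support.
#
# Distance stage (p-distance, optional Poisson correction, pairwise or
# complete gap deletion), Saitou-Nei agglomeration, and column-resampling
# bootstrap. Trees are unrooted; the internal representation is rooted at
# the final trifurcating join purely for traversal.

#' Uncorrected p-distance between two aligned sequences
#'
#' Proportion of mismatching columns among columns where neither sequence
#' has a gap (pairwise deletion).
#'
#' @param aln_a,aln_b Equal-length aligned strings (gap `-`).
#' @return Mismatch proportion in \[0, 1\].
#' @export
p_distance <- function(aln_a, aln_b) {
  a <- strsplit(aln_a, "")[[1]]
  b <- strsplit(aln_b, "")[[1]]
  if (length(a) != length(b)) stop("aligned strings differ in length")
  keep <- a != "-" & b != "-"
  if (!any(keep)) stop("no gap-free columns shared by the pair")
  mean(a[keep] != b[keep])
}

#' Poisson correction of a p-distance
#'
#' Multiple-hit correction `-ln(1 - p)` (substitutions per site under a
#' Poisson model of change).
#'
#' @param p Mismatch proportion, `0 <= p < 1`.
#' @return Corrected distance.
#' @export
poisson_correct <- function(p) {
  if (any(p < 0)) stop("p must be >= 0")
  if (any(p >= 1)) stop("saturated distance: p >= 1 cannot be corrected")
  -log(1 - p)
}

#' Pairwise distance matrix from an alignment
#'
#' @param aln Character vector of equal-length aligned sequences.
#' @param labels Taxon labels (default: names of `aln`).
#' @param model `"p"` (uncorrected, the 16S default) or `"poisson"`
#'   (protein default).
#' @param gaps `"pairwise"` (per-pair column exclusion, the default) or
#'   `"complete"` (drop any column with a gap in any row).
#' @return A list of class `dist_matrix` with `labels` and the symmetric
#'   matrix `d`.
#' @export
dist_matrix <- function(aln, labels = names(aln),
                        model = c("p", "poisson"),
                        gaps = c("pairwise", "complete")) {
  model <- match.arg(model)
  gaps <- match.arg(gaps)
  n <- length(aln)
  stopifnot(n >= 2L, length(labels) == n)
  if (length(unique(nchar(aln))) != 1L) stop("rows differ in length")
  if (gaps == "complete") {
    m <- do.call(rbind, strsplit(aln, ""))
    keep <- colSums(m == "-") == 0L
    if (!any(keep)) stop("no gap-free columns under complete deletion")
    aln <- apply(m[, keep, drop = FALSE], 1, paste, collapse = "")
  }
  d <- matrix(0, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      p <- p_distance(aln[i], aln[j])
      d[i, j] <- d[j, i] <- if (model == "poisson") poisson_correct(p) else p
    }
  }
  structure(list(labels = labels, d = d), class = "dist_matrix")
}

tip_node <- function(label) list(tip = label)
join_node <- function(children, lengths) {
  list(children = children, lengths = lengths, support = NA_real_)
}
is_tip <- function(node) !is.null(node$tip)

node_tips <- function(node) {
  if (is_tip(node)) return(node$tip)
  unlist(lapply(node$children, node_tips), use.names = FALSE)
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration: repeated Q-matrix minimization (ties broken
#' by the smallest index pair), branch-length assignment, and matrix
#' reduction, with the final three-taxon star resolved by the closed form
#' `L_A = (d_AB + d_AC - d_BC) / 2`. Negative branch-length estimates are
#' clamped to zero and counted in `n_clamped`.
#'
#' @param dm A [dist_matrix()] (or a plain symmetric matrix with
#'   dimnames).
#' @return An object of class `phylo_tree`: `root` (the trifurcating
#'   center node), `labels`, `n_clamped`.
#' @export
nj_tree <- function(dm) {
  if (is.matrix(dm)) dm <- structure(list(labels = rownames(dm), d = dm),
                                     class = "dist_matrix")
  d <- dm$d
  labels <- dm$labels
  n <- length(labels)
  if (n < 3L) stop("neighbor joining needs at least 3 taxa")
  if (any(!is.finite(d))) stop("distance matrix has non-finite entries")
  nodes <- lapply(labels, tip_node)
  n_clamped <- 0L
  clamp <- function(x) {
    if (x < 0) { n_clamped <<- n_clamped + 1L; 0 } else x
  }
  while (length(nodes) > 3L) {
    r <- length(nodes)
    R <- rowSums(d)
    # Q matrix; scan upper triangle row-major so ties fall to smallest (i,j)
    best <- c(NA_integer_, NA_integer_); best_q <- Inf
    for (i in seq_len(r - 1L)) {
      for (j in (i + 1L):r) {
        q <- (r - 2) * d[i, j] - R[i] - R[j]
        if (q < best_q - 1e-12) { best_q <- q; best <- c(i, j) }
      }
    }
    i <- best[1]; j <- best[2]
    li <- clamp(d[i, j] / 2 + (R[i] - R[j]) / (2 * (r - 2)))
    lj <- clamp(d[i, j] - (d[i, j] / 2 + (R[i] - R[j]) / (2 * (r - 2))))
    new_node <- join_node(list(nodes[[i]], nodes[[j]]), c(li, lj))
    du <- (d[i, ] + d[j, ] - d[i, j]) / 2
    keep <- setdiff(seq_len(r), c(i, j))
    d <- rbind(cbind(d[keep, keep, drop = FALSE], du[keep]),
               c(du[keep], 0))
    nodes <- c(nodes[keep], list(new_node))
  }
  # resolve the final three-taxon star by the three-point closed form
  la <- clamp((d[1, 2] + d[1, 3] - d[2, 3]) / 2)
  lb <- clamp((d[1, 2] + d[2, 3] - d[1, 3]) / 2)
  lc <- clamp((d[1, 3] + d[2, 3] - d[1, 2]) / 2)
  root <- join_node(nodes, c(la, lb, lc))
  structure(list(root = root, labels = labels, n_clamped = n_clamped),
            class = "phylo_tree")
}

# Canonical key of the bipartition induced by a subtree's tip set:
# always the side NOT containing the reference (first) label.
bipart_key <- function(tips, all_labels) {
  side <- sort(tips)
  if (all_labels[1] %in% side) side <- sort(setdiff(all_labels, side))
  if (length(side) < 2L || length(side) > length(all_labels) - 2L) {
    return(NA_character_)  # trivial split (single tip): not an internal edge
  }
  paste(side, collapse = "|")
}

# All internal-edge bipartition keys of a tree (center node excluded).
tree_biparts <- function(tree) {
  keys <- character()
  walk <- function(node, at_root) {
    if (is_tip(node)) return()
    if (!at_root) {
      k <- bipart_key(node_tips(node), tree$labels)
      if (!is.na(k)) keys[[length(keys) + 1L]] <<- k
    }
    for (ch in node$children) walk(ch, FALSE)
  }
  walk(tree$root, TRUE)
  unlist(keys)
}

#' Bootstrap supports for a neighbor-joining tree
#'
#' Resamples alignment columns with replacement, rebuilds the NJ tree per
#' replicate, and scores each internal bipartition of the full-data tree
#' by the percentage of replicates containing it. Replicate `r` is seeded
#' with `seed + r`, so any replicate is independently reproducible.
#'
#' @param aln Character vector of equal-length aligned sequences.
#' @param labels Taxon labels.
#' @param n_reps Number of replicates (the classical figure is 1000).
#' @param seed Base RNG seed.
#' @inheritParams dist_matrix
#' @return The full-data `phylo_tree` with `support` (percent, 0-100) set
#'   on every internal non-center node.
#' @export
bootstrap_support <- function(aln, labels = names(aln), n_reps = 1000L,
                              seed = 1L, model = c("p", "poisson"),
                              gaps = c("pairwise", "complete")) {
  stopifnot(n_reps >= 1L)
  model <- match.arg(model)
  gaps <- match.arg(gaps)
  full <- nj_tree(dist_matrix(aln, labels, model = model, gaps = gaps))
  keys <- tree_biparts(full)
  counts <- stats::setNames(rep(0L, length(keys)), keys)
  m <- do.call(rbind, strsplit(aln, ""))
  ncol_aln <- ncol(m)
  for (r in seq_len(n_reps)) {
    cols <- with_seed(seed + r,
                      sample.int(ncol_aln, ncol_aln, replace = TRUE))
    rep_aln <- apply(m[, cols, drop = FALSE], 1, paste, collapse = "")
    rep_tree <- try(nj_tree(dist_matrix(rep_aln, labels, model = model,
                                        gaps = gaps)), silent = TRUE)
    if (inherits(rep_tree, "try-error")) next
    hit <- keys %in% tree_biparts(rep_tree)
    counts[hit] <- counts[hit] + 1L
  }
  pct <- 100 * counts / n_reps
  annotate <- function(node, at_root) {
    if (is_tip(node)) return(node)
    node$children <- lapply(node$children, annotate, at_root = FALSE)
    if (!at_root) {
      k <- bipart_key(node_tips(node), full$labels)
      if (!is.na(k)) node$support <- unname(pct[k])
    }
    node
  }
  full$root <- annotate(full$root, TRUE)
  full$n_reps <- n_reps
  full
}

#' Serialize a tree to Newick
#'
#' Branch lengths on every edge; bootstrap supports (when present) as
#' integer internal-node labels in 0-100.
#'
#' @param tree A `phylo_tree`.
#' @param digits Significant digits for branch lengths.
#' @return A single Newick string terminated by `;`.
#' @export
write_newick <- function(tree, digits = 10L) {
  fmt_len <- function(x) sprintf("%.*g", digits, x)
  render <- function(node) {
    if (is_tip(node)) return(node$tip)
    inner <- vapply(seq_along(node$children), function(i) {
      paste0(render(node$children[[i]]), ":", fmt_len(node$lengths[i]))
    }, "")
    lab <- if (!is.na(node$support)) sprintf("%d", as.integer(round(node$support)))
           else ""
    paste0("(", paste(inner, collapse = ","), ")", lab)
  }
  paste0(render(tree$root), ";")
}

#' Count the internal edges of a tree
#'
#' For a binary unrooted tree this is `n_taxa - 3`.
#'
#' @param tree A `phylo_tree`.
#' @return Integer count.
#' @export
n_internal_edges <- function(tree) length(tree_biparts(tree))
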