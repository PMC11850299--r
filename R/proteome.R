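# Proteome composition analysis: pairwise similarity of loci by shared
# protein groups, average-linkage (UPGMA) clustering for row order and
# sequence clusters, and per-cluster conserved/intermediate/variable
# classification of protein groups (analogous to pangenome
# core/shell/cloud).

#' Pairwise proteome composition similarity
#'
#' For loci i, j with group sets Gi, Gj the default score is the symmetric
#' mean of the two directional shared fractions,
#' S = (|Gi n Gj|/|Gi| + |Gi n Gj|/|Gj|) / 2, so a locus fully contained in
#' a larger one still scores high (a phage and its deletion variant group
#' together). `method = "jaccard"` uses |Gi n Gj| / |Gi u Gj| instead.
#' Empty sets give S = 0 off-diagonal; the diagonal is always 1. The
#' distance matrix is D = 1 - S.
#'
#' @param group_sets named list of per-locus character vectors of group ids
#' @param method "mean_directional" (default) or "jaccard"
#' @return an `lv_proteome` with components `locus_ids`, `S`, `D`
#' @export
proteome_similarity <- function(group_sets,
                                method = c("mean_directional", "jaccard")) {
  method <- match.arg(method)
  ids <- names(group_sets)
  if (is.null(ids)) stop2("group_sets must be a named list")
  n <- length(group_sets)
  S <- diag(1, n)
  if (n > 1) for (i in seq_len(n - 1)) for (j in seq.int(i + 1, n)) {
    gi <- group_sets[[i]]; gj <- group_sets[[j]]
    if (!length(gi) || !length(gj)) { S[i, j] <- S[j, i] <- 0; next }
    inter <- length(intersect(gi, gj))
    s <- if (method == "jaccard") inter / length(union(gi, gj))
         else 0.5 * (inter / length(gi) + inter / length(gj))
    S[i, j] <- S[j, i] <- s
  }
  dimnames(S) <- list(ids, ids)
  structure(list(locus_ids = ids, S = S, D = 1 - S,
                 tree = NULL, leaf_order = NULL, clusters = NULL,
                 method = method),
            class = "lv_proteome")
}

#' @export
print.lv_proteome <- function(x, ...) {
  cat(sprintf("<lv_proteome> %d loci (similarity: %s)%s\n",
              length(x$locus_ids), x$method,
              if (!is.null(x$clusters))
                sprintf(", %d clusters", length(unique(x$clusters))) else ""))
  invisible(x)
}

#' Average-linkage (UPGMA) hierarchical clustering
#'
#' Unweighted average linkage on a dissimilarity matrix. Merge heights are
#' ultrametric node heights, i.e. half the average inter-cluster distance at
#' the merge (so the cophenetic distance between two leaves is twice the
#' height of their join). Ties are broken by the smallest (i, j) index pair
#' in cluster-creation order. A 1x1 matrix yields a single-leaf tree.
#'
#' @param D symmetric non-negative matrix with zero diagonal; dimnames give
#'   the leaf labels.
#' @return an `lv_dendro`: list(merge, height, labels, n) in hclust-style
#'   encoding (negative entries are leaves), heights are node heights.
#' @export
upgma <- function(D) {
  D <- as.matrix(D)
  n <- nrow(D)
  if (n != ncol(D)) stop2("D must be square")
  if (any(is.na(D))) stop2("D contains missing values")
  if (max(abs(D - t(D))) > 1e-9) stop2("D must be symmetric")
  if (any(D < -1e-12)) stop2("D must be non-negative")
  if (any(abs(diag(D)) > 1e-12)) stop2("D must have a zero diagonal")
  labels <- rownames(D) %||% paste0("L", seq_len(n))
  if (n == 1)
    return(structure(list(merge = matrix(integer(0), 0, 2), height = numeric(0),
                          labels = labels, n = 1L), class = "lv_dendro"))
  # active cluster bookkeeping; id <= n are leaves, > n are merge nodes
  active <- seq_len(n)           # cluster ids in creation order
  size <- rep(1L, n)
  node_of <- c(seq_len(n))       # id -> merge-matrix code (leaves negative)
  code <- -seq_len(n)
  d <- D
  rownames(d) <- colnames(d) <- as.character(active)
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  next_id <- n
  for (step in seq_len(n - 1L)) {
    m <- length(active)
    # smallest distance; ties -> smallest (i, j) in creation order
    best <- c(NA_integer_, NA_integer_); bestd <- Inf
    for (i in seq_len(m - 1L)) for (j in seq.int(i + 1L, m)) {
      if (d[i, j] < bestd - 1e-15) { bestd <- d[i, j]; best <- c(i, j) }
    }
    i <- best[1]; j <- best[2]
    id_i <- active[i]; id_j <- active[j]
    next_id <- next_id + 1L
    merge[step, ] <- c(code[id_i], code[id_j])
    height[step] <- bestd / 2
    # unweighted average update
    newrow <- (size[id_i] * d[i, ] + size[id_j] * d[j, ]) /
      (size[id_i] + size[id_j])
    keep <- setdiff(seq_len(m), c(i, j))
    d <- rbind(cbind(d[keep, keep, drop = FALSE], newrow[keep]),
               c(newrow[keep], 0))
    active <- c(active[keep], next_id)
    size[next_id] <- size[id_i] + size[id_j]
    code[next_id] <- step
  }
  structure(list(merge = merge, height = height, labels = labels, n = n),
            class = "lv_dendro")
}

#' @export
print.lv_dendro <- function(x, ...) {
  cat(sprintf("<lv_dendro> %d leaves, root height %s\n", x$n,
              if (x$n > 1) format(max(x$height)) else "0"))
  invisible(x)
}

# leaf indices (1..n) under each merge node; list indexed by merge step
merge_members <- function(tree) {
  members <- vector("list", nrow(tree$merge))
  for (s in seq_len(nrow(tree$merge))) {
    kids <- tree$merge[s, ]
    members[[s]] <- unlist(lapply(kids, function(k)
      if (k < 0) -k else members[[k]]))
  }
  members
}

#' Cophenetic distance matrix of a UPGMA tree
#'
#' Distance between two leaves = twice the height of their lowest common
#' merge node (the average-linkage distance at which they join).
#' @param tree an `lv_dendro`
#' @return symmetric matrix with the tree's labels
#' @export
cophenetic_matrix <- function(tree) {
  n <- tree$n
  M <- matrix(0, n, n, dimnames = list(tree$labels, tree$labels))
  if (n == 1) return(M)
  members <- merge_members(tree)
  for (s in seq_len(nrow(tree$merge))) {
    kids <- tree$merge[s, ]
    left <- if (kids[1] < 0) -kids[1] else members[[kids[1]]]
    right <- if (kids[2] < 0) -kids[2] else members[[kids[2]]]
    for (a in left) {
      M[a, right] <- 2 * tree$height[s]
      M[right, a] <- 2 * tree$height[s]
    }
  }
  M
}

#' Left-to-right leaf order of a dendrogram
#'
#' Deterministic orientation: at every internal node the child subtree
#' containing the lexicographically smallest leaf label is traversed first.
#' @param tree an `lv_dendro`
#' @return character vector of leaf labels in display order
#' @export
leaf_order <- function(tree) {
  if (tree$n == 1) return(tree$labels)
  walk <- function(k) {
    if (k < 0) return(tree$labels[-k])
    l <- walk(tree$merge[k, 1])
    r <- walk(tree$merge[k, 2])
    if (min(l) <= min(r)) c(l, r) else c(r, l)
  }
  walk(nrow(tree$merge))
}

#' Cut a UPGMA tree into flat sequence clusters
#'
#' Clusters are the maximal subtrees whose node heights are at most
#' `max_distance / 2`, i.e. whose members are within cophenetic distance
#' `max_distance` of each other. Labels ("C1", "C2", ...) are assigned by
#' first appearance along the leaf order.
#' @param tree an `lv_dendro`
#' @param max_distance cophenetic distance threshold (default 0.75)
#' @return named character vector locus_id -> cluster label
#' @export
cut_tree_clusters <- function(tree, max_distance = 0.75) {
  stopifnot(max_distance >= 0)
  n <- tree$n
  comp <- seq_len(n)
  if (n > 1) {
    members <- merge_members(tree)
    for (s in seq_len(nrow(tree$merge))) {
      if (tree$height[s] <= max_distance / 2 + 1e-12) {
        ms <- members[[s]]
        comp[ms] <- min(comp[ms])
      }
    }
  }
  lab_order <- leaf_order(tree)
  cluster_of <- stats::setNames(comp, tree$labels)
  first_seen <- unique(unname(cluster_of[lab_order]))
  names_map <- stats::setNames(paste0("C", seq_along(first_seen)), first_seen)
  out <- names_map[as.character(cluster_of)]
  names(out) <- tree$labels
  out
}

#' Classify protein groups as conserved / intermediate / variable
#'
#' Within each sequence cluster, a group's presence fraction f is the number
#' of member loci carrying at least one feature of the group divided by the
#' cluster size (paralogues count once). Class: conserved if
#' f >= `conserved_cutoff`, variable if f <= `variable_cutoff`, otherwise
#' intermediate. Size-1 clusters carry no variability evidence, so all their
#' groups are conserved.
#'
#' @param clusters named cluster labels per locus id (from
#'   [cut_tree_clusters()] or a locus table)
#' @param group_sets named list of per-locus group-id sets
#' @param conserved_cutoff,variable_cutoff presence-fraction cutoffs
#'   (defaults 0.75 and 0.25; must satisfy variable < conserved)
#' @return data.frame(cluster, group_id, presence_fraction, class)
#' @export
classify_protein_groups <- function(clusters, group_sets,
                                    conserved_cutoff = 0.75,
                                    variable_cutoff = 0.25) {
  stopifnot(variable_cutoff >= 0, conserved_cutoff <= 1,
            variable_cutoff < conserved_cutoff)
  out <- list()
  for (cl in unique(clusters[names(group_sets)])) {
    members <- names(clusters)[clusters == cl]
    members <- intersect(members, names(group_sets))
    sz <- length(members)
    groups <- sort(unique(unlist(group_sets[members])))
    if (!length(groups)) next
    f <- vnumeric(groups, function(g)
      sum(vlogical(members, function(m) g %in% group_sets[[m]])) / sz)
    class <- if (sz == 1) rep("conserved", length(groups)) else
      ifelse(f >= conserved_cutoff, "conserved",
             ifelse(f <= variable_cutoff, "variable", "intermediate"))
    out[[length(out) + 1L]] <- data.frame(
      cluster = cl, group_id = groups, presence_fraction = unname(f),
      class = class, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out) %||%
    data.frame(cluster = character(0), group_id = character(0),
               presence_fraction = numeric(0), class = character(0))
  rownames(res) <- NULL
  res
}

#' Run similarity, UPGMA, ordering and clustering in one step
#' @param group_sets named list of per-locus group-id sets
#' @param method similarity method
#' @param max_distance cluster cut threshold on cophenetic distance
#' @return a completed `lv_proteome` (tree, leaf_order, clusters filled)
#' @export
proteome_analysis <- function(group_sets, method = "mean_directional",
                              max_distance = 0.75) {
  pm <- proteome_similarity(group_sets, method = method)
  pm$tree <- upgma(pm$D)
  pm$leaf_order <- leaf_order(pm$tree)
  pm$clusters <- cut_tree_clusters(pm$tree, max_distance)
  pm
}

#' Newick string of a UPGMA tree
#'
#' Branch lengths are differences of node heights (leaves at height 0), so
#' root-to-leaf path lengths equal the node heights.
#' @param tree an `lv_dendro`
#' @return Newick string terminated by ";"
#' @export
as_newick <- function(tree) {
  if (tree$n == 1) return(paste0(tree$labels, ";"))
  h_of <- function(k) if (k < 0) 0 else tree$height[k]
  min_leaf <- function(k) if (k < 0) tree$labels[-k] else
    min(vcharacter(tree$merge[k, ], min_leaf))
  walk <- function(k) {
    if (k < 0) return(tree$labels[-k])
    kids <- tree$merge[k, ]
    if (min_leaf(kids[2]) < min_leaf(kids[1])) kids <- rev(kids)  # same
    # orientation rule as leaf_order(): smallest leaf label first
    parts <- vcharacter(kids, function(kk)
      paste0(walk(kk), ":", format(tree$height[k] - h_of(kk))))
    paste0("(", paste(parts, collapse = ","), ")")
  }
  paste0(walk(nrow(tree$merge)), ";")
}

#' Write the similarity matrix as TSV and the dendrogram as Newick
#' @param pm an `lv_proteome`
#' @param tsv_path output TSV (header row + row names)
#' @param newick_path optional Newick output (requires tree)
#' @return invisible list of paths
#' @export
write_similarity_tsv <- function(pm, tsv_path, newick_path = NULL) {
  df <- as.data.frame(pm$S)
  df <- cbind(locus_id = pm$locus_ids, df)
  utils::write.table(df, tsv_path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(newick_path)) {
    if (is.null(pm$tree)) stop2("no tree in proteome object; run proteome_analysis()")
    writeLines(as_newick(pm$tree), newick_path)
  }
  invisible(list(tsv = tsv_path, newick = newick_path))
}

#' Write the group-class table as TSV
#' @param classes data.frame from [classify_protein_groups()]
#' @param path output TSV
#' @export
write_class_tsv <- function(classes, path) {
  utils::write.table(classes, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
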