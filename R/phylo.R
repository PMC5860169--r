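# Distance-tree inference, midpoint rooting, branch support from replicate
# trees, monophyly classification and the taxon-support statistic.

#' Neighbour-joining tree from a distance matrix
#'
#' Standard NJ (Saitou-Nei with the Studier-Keppler Q criterion, as
#' implemented in [ape::nj()]); negative branch-length estimates are clamped
#' to 0. With fewer than three taxa a trivial two-leaf tree is built with the
#' single distance split evenly.
#'
#' @param m A `gbdp_dist`, symmetric labelled matrix, or [stats::dist].
#' @return An unrooted [ape::phylo] tree.
#' @export
nj_tree <- function(m) {
  if (inherits(m, "gbdp_dist")) m <- as.matrix(m)
  if (inherits(m, "dist")) m <- as.matrix(m)
  stopifnot(is.matrix(m), nrow(m) == ncol(m))
  labels <- rownames(m)
  if (is.null(labels)) labels <- paste0("t", seq_len(nrow(m)))
  n <- nrow(m)
  if (n < 2L) stop("need at least 2 taxa", call. = FALSE)
  if (n == 2L) {
    tr <- list(edge = matrix(c(3L, 1L, 3L, 2L), 2L, 2L, byrow = TRUE),
               edge.length = rep(m[1, 2] / 2, 2L),
               tip.label = labels, Nnode = 1L)
    class(tr) <- "phylo"
    return(tr)
  }
  tr <- ape::nj(stats::as.dist(m))
  tr$edge.length <- pmax(tr$edge.length, 0)
  tr
}

# adjacency list of an (un)rooted phylo: per node, matrix of (neighbour, edge length)
tree_adjacency <- function(tree) {
  n_nodes <- ape::Ntip(tree) + tree$Nnode
  adj <- vector("list", n_nodes)
  for (k in seq_len(nrow(tree$edge))) {
    a <- tree$edge[k, 1]; b <- tree$edge[k, 2]; w <- tree$edge.length[k]
    adj[[a]] <- rbind(adj[[a]], c(b, w))
    adj[[b]] <- rbind(adj[[b]], c(a, w))
  }
  adj
}

# Re-root an unrooted tree at a point on the edge between neighbouring nodes
# a and b, at distance `dist_from_a` from a. Returns a rooted binary-rooted
# phylo (one degree-2 root).
root_on_edge <- function(tree, a, b, dist_from_a) {
  ntip <- ape::Ntip(tree)
  adj <- tree_adjacency(tree)
  len_ab <- NA_real_
  for (k in seq_len(nrow(adj[[a]]))) {
    if (adj[[a]][k, 1] == b) { len_ab <- adj[[a]][k, 2]; break }
  }
  if (is.na(len_ab)) stop("nodes are not adjacent", call. = FALSE)
  dist_from_a <- min(max(dist_from_a, 0), len_ab)

  edges <- list()
  lengths <- numeric(0)
  counter <- new.env()
  counter$next_internal <- ntip + 1L  # root gets ntip+1, assigned first
  new_id <- function() {
    id <- counter$next_internal
    counter$next_internal <- id + 1L
    id
  }
  # first pass: count internal nodes of the new tree to number tips/internals
  # consistently; tips keep their original indices 1..ntip
  root_new <- new_id()
  # recursive descent away from `from_old`, returning the new id of old node
  descend <- function(old, from_old, parent_new, elen) {
    my_new <- if (old <= ntip) old else new_id()
    edges[[length(edges) + 1L]] <<- c(parent_new, my_new)
    lengths[length(lengths) + 1L] <<- elen
    nb <- adj[[old]]
    for (k in seq_len(nrow(nb))) {
      if (nb[k, 1] != from_old)
        descend(nb[k, 1], old, my_new, nb[k, 2])
    }
    my_new
  }
  descend(a, b, root_new, dist_from_a)
  descend(b, a, root_new, len_ab - dist_from_a)

  edge <- do.call(rbind, edges)
  tr <- list(edge = edge, edge.length = lengths, tip.label = tree$tip.label,
             Nnode = counter$next_internal - 1L - ntip)
  class(tr) <- "phylo"
  ape::reorder.phylo(tr, "cladewise")
}

#' Midpoint rooting
#'
#' Inserts the root at the midpoint of the longest leaf-to-leaf path; ties
#' are broken by the lexicographically smallest leaf pair. If every branch
#' length is zero the root is placed on the pendant edge of the
#' lexicographically smallest leaf. Any branch-support node labels are
#' dropped (support is assigned on the rooted tree by [branch_support()]).
#'
#' @param tree An unrooted [ape::phylo] tree with branch lengths (a rooted
#'   input is unrooted first).
#' @return A rooted [ape::phylo] tree whose two most distant leaves are
#'   equidistant from the root.
#' @export
midpoint_root <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length))
    stop("tree has no branch lengths", call. = FALSE)
  ntip <- ape::Ntip(tree)
  if (ntip == 2L) {
    total <- sum(tree$edge.length)
    ord <- order(tree$tip.label)
    tr <- list(edge = matrix(c(3L, ord[1L], 3L, ord[2L]), 2L, 2L, byrow = TRUE),
               edge.length = rep(total / 2, 2L),
               tip.label = tree$tip.label, Nnode = 1L)
    class(tr) <- "phylo"
    return(tr)
  }
  tree <- ape::unroot(tree)
  tree$node.label <- NULL
  D <- stats::cophenetic(tree)
  labs <- rownames(D)
  maxd <- max(D)
  if (maxd <= 0) {
    leaf <- which(tree$tip.label == sort(tree$tip.label)[1L])
    k <- which(tree$edge[, 2] == leaf)
    return(root_on_edge(tree, tree$edge[k, 1], leaf,
                        tree$edge.length[k] / 2))
  }
  idx <- which(D >= maxd - 1e-12, arr.ind = TRUE)
  pairs <- t(apply(idx, 1, function(r) sort(labs[r])))
  pairs <- unique(pairs)
  best <- pairs[order(pairs[, 1], pairs[, 2])[1L], ]
  i <- which(tree$tip.label == best[1L])
  j <- which(tree$tip.label == best[2L])
  path <- ape::nodepath(tree, i, j)
  half <- D[best[1L], best[2L]] / 2
  elen <- function(a, b) {
    k <- which((tree$edge[, 1] == a & tree$edge[, 2] == b) |
               (tree$edge[, 1] == b & tree$edge[, 2] == a))
    tree$edge.length[k[1L]]
  }
  cum <- 0
  for (k in seq_len(length(path) - 1L)) {
    w <- elen(path[k], path[k + 1L])
    if (cum + w >= half - 1e-12) {
      return(root_on_edge(tree, path[k], path[k + 1L], half - cum))
    }
    cum <- cum + w
  }
  root_on_edge(tree, path[length(path) - 1L], path[length(path)],
               elen(path[length(path) - 1L], path[length(path)]))
}

# Canonical key of the (unrooted) bipartition induced by a clade tip set:
# the side not containing the alphabetically first leaf, as a string.
bipartition_key <- function(tips, all_labels) {
  ref <- sort(all_labels)[1L]
  side <- if (ref %in% tips) setdiff(all_labels, tips) else tips
  paste(sort(side), collapse = "\x1f")
}

# tip-index sets of each internal node, in internal-node-number order
# (names = node numbers; entry i corresponds to node Ntip + i)
clade_tip_sets <- function(tree) {
  ntip <- ape::Ntip(tree)
  nn <- tree$Nnode
  sets <- vector("list", ntip + nn)
  for (t in seq_len(ntip)) sets[[t]] <- t
  po <- ape::reorder.phylo(tree, "postorder")$edge
  for (k in seq_len(nrow(po))) {
    u <- po[k, 1]; v <- po[k, 2]
    sets[[u]] <- c(sets[[u]], sets[[v]])
  }
  out <- sets[(ntip + 1L):(ntip + nn)]
  names(out) <- as.character((ntip + 1L):(ntip + nn))
  out
}

# keys of the non-trivial bipartitions of a tree (any rooting)
tree_bipartitions <- function(tree) {
  labs <- tree$tip.label
  n <- length(labs)
  keys <- character(0)
  for (tips_idx in clade_tip_sets(tree)) {
    if (length(tips_idx) <= 1L || length(tips_idx) >= n - 1L) next
    keys <- c(keys, bipartition_key(labs[tips_idx], labs))
  }
  unique(keys)
}

#' Branch support from replicate trees
#'
#' For each internal branch of the reference tree, support is the rounded
#' percentage of replicate trees whose unrooted bipartition set contains
#' that branch's bipartition. Trivial bipartitions (pendant edges, and hence
#' the root of a rooted reference) are present in every tree and get 100.
#'
#' @param tree Reference [ape::phylo] tree (typically midpoint-rooted).
#' @param replicates List of replicate trees on the identical leaf set.
#' @return The reference tree with integer percent supports as internal node
#'   labels.
#' @export
branch_support <- function(tree, replicates) {
  stopifnot(inherits(tree, "phylo"), length(replicates) > 0)
  labs <- tree$tip.label
  for (rep in replicates) {
    if (!setequal(rep$tip.label, labs)) {
      diffs <- c(setdiff(labs, rep$tip.label), setdiff(rep$tip.label, labs))
      stop("replicate tree leaf set differs from reference: ",
           paste(diffs, collapse = ", "), call. = FALSE)
    }
  }
  rep_keys <- as.character(unlist(lapply(replicates, tree_bipartitions)))
  counts <- table(rep_keys)
  n <- length(labs)
  pp <- clade_tip_sets(tree)
  support <- integer(length(pp))
  for (i in seq_along(pp)) {
    tips_idx <- pp[[i]]
    if (length(tips_idx) <= 1L || length(tips_idx) >= n - 1L) {
      support[i] <- 100L
      next
    }
    key <- bipartition_key(labs[tips_idx], labs)
    cnt <- if (key %in% names(counts)) counts[[key]] else 0L
    support[i] <- as.integer(round(100 * cnt / length(replicates)))
  }
  tree$node.label <- as.character(support)
  tree
}

# Minimum-change (Fitch-style, via Sankoff up-down passes) feasibility of a
# binary membership character: is "member" an MP state at node `node`?
mp_member_feasible <- function(tree, member_tips, node) {
  ntip <- ape::Ntip(tree)
  n_nodes <- ntip + tree$Nnode
  INF <- 1e9
  down <- matrix(INF, n_nodes, 2L)  # columns: state 0 (non-member), 1 (member)
  for (t in seq_len(ntip)) {
    s <- if (t %in% member_tips) 2L else 1L
    down[t, s] <- 0
  }
  po <- ape::reorder.phylo(tree, "postorder")$edge
  children <- split(po[, 2], po[, 1])
  for (u in unique(po[, 1])) down[u, ] <- 0
  for (k in seq_len(nrow(po))) {
    u <- po[k, 1]; v <- po[k, 2]
    down[u, 1] <- down[u, 1] + min(down[v, 1], down[v, 2] + 1)
    down[u, 2] <- down[u, 2] + min(down[v, 2], down[v, 1] + 1)
  }
  root <- ntip + 1L
  up <- matrix(INF, n_nodes, 2L)
  up[root, ] <- 0
  pre <- po[rev(seq_len(nrow(po))), , drop = FALSE]
  for (k in seq_len(nrow(pre))) {
    u <- pre[k, 1]; v <- pre[k, 2]
    # cost above v for each state of v: min over parent state of
    # up[u] + transition + siblings' best-given-parent-state
    for (sv in 1:2) {
      best <- INF
      for (su in 1:2) {
        sib <- 0
        for (w in children[[as.character(u)]]) {
          if (w == v) next
          sib <- sib + min(down[w, su], down[w, 3L - su] + 1)
        }
        cand <- up[u, su] + (if (su == sv) 0 else 1) + sib
        if (cand < best) best <- cand
      }
      up[v, sv] <- best
    }
  }
  total_min <- min(down[root, 1], down[root, 2])
  down[node, 2] + up[node, 2] <= total_min + 1e-9
}

#' Classify a taxon on a rooted tree
#'
#' A single-leaf taxon is `"trivial"`; a taxon whose members exactly form a
#' clade is `"monophyletic"`. Otherwise a minimum-change reconstruction of
#' the binary membership character decides: if some most-parsimonious
#' reconstruction assigns "member" to the most recent common ancestor of the
#' taxon it is `"paraphyletic"`, else `"polyphyletic"`.
#'
#' @param tree A rooted [ape::phylo] tree.
#' @param members Character vector of member leaf labels.
#' @return One of `"trivial"`, `"monophyletic"`, `"paraphyletic"`,
#'   `"polyphyletic"`.
#' @export
classify_taxon <- function(tree, members) {
  stopifnot(inherits(tree, "phylo"))
  unknown <- setdiff(members, tree$tip.label)
  if (length(unknown))
    stop("unknown leaves: ", paste(unknown, collapse = ", "), call. = FALSE)
  if (length(members) == 0L) stop("empty member set", call. = FALSE)
  if (length(members) == 1L) return("trivial")
  tips <- match(members, tree$tip.label)
  if (length(members) == ape::Ntip(tree)) return("monophyletic")
  mrca <- ape::getMRCA(tree, tips)
  clade <- clade_tip_sets(tree)[[as.character(mrca)]]
  if (setequal(clade, tips)) return("monophyletic")
  if (mp_member_feasible(tree, tips, mrca)) "paraphyletic" else "polyphyletic"
}

node_supports <- function(tree) {
  if (is.null(tree$node.label))
    stop("tree has no branch-support node labels; run branch_support() first",
         call. = FALSE)
  sup <- suppressWarnings(as.numeric(tree$node.label))
  sup[is.na(sup)] <- 100  # root / unlabeled nodes: support by convention
  sup
}

#' Taxon support of a tree against a reference taxonomy
#'
#' For every non-trivial taxon at the requested rank: if the taxon is
#' monophyletic its signed support is the bootstrap support of the branch
#' subtending its clade (100 by convention for the root clade); otherwise it
#' is minus the maximum support among all clades of the rooted tree that
#' cross the taxon (a clade K crosses taxon G when K∩G, K\\G and G\\K are all
#' non-empty). The overall taxon support is the sum of the signed values over
#' the sum of their absolute values (0 when that denominator is 0); it lies
#' in [-1, 1] and measures the phylogenetic fit of the tree (and hence of
#' the distance matrix behind it) to the classification at that rank.
#'
#' @param tree A rooted tree with branch-support node labels
#'   (see [branch_support()]).
#' @param taxonomy Tibble with column `genome_id` and one column per rank.
#' @param rank Rank column to score; leaves with an empty value at the rank
#'   are excluded.
#' @return An object of class `taxon_support`: list with `report` (tibble:
#'   `taxon`, `rank`, `n_leaves`, `status`, `signed_support`), `overall`,
#'   `rank`.
#' @export
taxon_support <- function(tree, taxonomy, rank = "species") {
  stopifnot(inherits(tree, "phylo"))
  if (!rank %in% names(taxonomy))
    stop("taxonomy has no rank column '", rank, "'", call. = FALSE)
  missing <- setdiff(tree$tip.label, taxonomy$genome_id)
  if (length(missing))
    stop("leaves absent from taxonomy: ", paste(missing, collapse = ", "),
         call. = FALSE)
  sup <- node_supports(tree)
  ntip <- ape::Ntip(tree)
  clades <- clade_tip_sets(tree)
  labs <- tree$tip.label

  tax <- taxonomy[match(labs, taxonomy$genome_id), ]
  values <- tax[[rank]]
  values[is.na(values)] <- ""
  taxa <- sort(unique(values[nzchar(values)]))

  rows <- lapply(taxa, function(tx) {
    g <- which(values == tx)
    status <- classify_taxon(tree, labs[g])
    signed <- NA_real_
    if (status != "trivial") {
      if (status == "monophyletic") {
        if (length(g) == ntip) {
          signed <- 100
        } else {
          mrca <- ape::getMRCA(tree, g)
          signed <- sup[mrca - ntip]
        }
      } else {
        conflict <- 0
        for (k in seq_along(clades)) {
          K <- clades[[k]]
          n_in <- length(intersect(K, g))
          if (n_in > 0 && length(K) > n_in && length(g) > n_in)
            conflict <- max(conflict, sup[k])
        }
        signed <- -conflict
      }
    }
    tibble(taxon = tx, rank = rank, n_leaves = length(g), status = status,
           signed_support = signed)
  })
  report <- bind_rows(rows)
  nt <- report[report$status != "trivial", ]
  denom <- sum(abs(nt$signed_support))
  overall <- if (denom > 0) sum(nt$signed_support) / denom else 0
  structure(list(report = report, overall = overall, rank = rank),
            class = "taxon_support")
}

#' @export
print.taxon_support <- function(x, ...) {
  cat("<taxon_support> rank ", x$rank, ": ", nrow(x$report), " taxa, overall ",
      round(x$overall, 4), "\n", sep = "")
  print(x$report, n = 10)
  invisible(x)
}

#' @method tidy taxon_support
#' @export
tidy.taxon_support <- function(x, ...) x$report

#' @method glance taxon_support
#' @export
glance.taxon_support <- function(x, ...) {
  tibble(rank = x$rank,
         n_taxa = nrow(x$report),
         n_nontrivial = sum(x$report$status != "trivial"),
         n_monophyletic = sum(x$report$status == "monophyletic"),
         overall = x$overall)
}
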