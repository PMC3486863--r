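#' Read a rooted species tree
#'
#' Loads a newick tree and (optionally) the tip-to-taxon map used to connect
#' tree tips to taxonomy ids. Unrooted trees are rejected unless an outgroup
#' is named: rooting changes every most-recent-common-ancestor computation
#' and is never guessed.
#'
#' @param path Newick file path.
#' @param tip_taxa_file Optional TSV with columns `tip`, `taxon_id`.
#' @param outgroup Optional tip label (or vector of labels) to root on when
#'   the input tree is unrooted.
#' @return List with `tree` (an `ape::phylo`) and `tip_taxa` (named integer
#'   vector tip -> taxon id, or `NULL`).
#' @export
read_species_tree <- function(path, tip_taxa_file = NULL, outgroup = NULL) {
  tree <- ape::read.tree(path)
  if (!ape::is.rooted(tree)) {
    if (is.null(outgroup)) {
      stop("usage error: tree is unrooted; supply an outgroup to root on")
    }
    tree <- ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
  }
  tip_taxa <- NULL
  if (!is.null(tip_taxa_file)) {
    tt <- utils::read.delim(tip_taxa_file, stringsAsFactors = FALSE)
    tip_taxa <- stats::setNames(as.integer(tt$taxon_id), tt$tip)
    missing <- setdiff(names(tip_taxa), tree$tip.label)
    if (length(missing)) {
      stop("usage error: tip map names absent from tree: ",
           paste(utils::head(missing, 5), collapse = ", "))
    }
  }
  list(tree = tree, tip_taxa = tip_taxa)
}

# Precomputed traversal structures for one rooted tree. Node numbering is
# ape's: tips 1..N, internal N+1..M, root N+1.
.tree_index <- function(tree) {
  N <- length(tree$tip.label)
  M <- N + tree$Nnode
  root <- N + 1L
  parent <- integer(M)
  parent[tree$edge[, 2L]] <- tree$edge[, 1L]
  parent[root] <- root
  po <- ape::reorder.phylo(tree, "postorder")$edge  # children before parents
  # D[v, t]: tip t lies in the subtree of node v
  D <- matrix(FALSE, M, N)
  D[cbind(seq_len(N), seq_len(N))] <- TRUE
  for (i in seq_len(nrow(po))) {
    D[po[i, 1L], ] <- D[po[i, 1L], ] | D[po[i, 2L], ]
  }
  # A[g, v]: g is ancestor-or-self of v
  A <- matrix(FALSE, M, M)
  diag(A) <- TRUE
  for (i in rev(seq_len(nrow(po)))) {          # preorder: parents first
    A[, po[i, 2L]] <- A[, po[i, 1L]]
    A[po[i, 2L], po[i, 2L]] <- TRUE
  }
  children <- split(po[, 2L], factor(po[, 1L], levels = seq_len(M)))
  list(tree = tree, N = N, M = M, root = root, parent = parent,
       postorder = po, D = D, A = A, tipcount = rowSums(D),
       children = children)
}

# Dollo core: presence counts per subtree, gain = minimal clade covering all
# presence tips, losses = maximal absent subtrees strictly below the gain.
.dollo_core <- function(ti, pres) {
  cnt <- as.integer(ti$D %*% pres)
  k <- sum(pres)
  cand <- which(cnt == k)
  gain <- cand[which.min(ti$tipcount[cand])]
  under <- ti$A[gain, ]
  losses <- sum(under & cnt == 0L & cnt[ti$parent] > 0L &
                seq_len(ti$M) != gain)
  list(gain = gain, losses = losses, cnt = cnt, under = under)
}

#' Dollo-parsimony reconstruction of one binary character on a tree
#'
#' Treats an RNA family as a binary presence/absence character evolving under
#' Dollo parsimony: a single gain followed by any number of independent
#' losses. The gain node is the most recent common ancestor of the presence
#' tips; the loss count is the minimal number of loss events explaining the
#' absences below it, i.e. the number of maximal subtrees under the gain node
#' containing no presence tip. Polytomies are allowed; each maximal absent
#' subtree hanging off a polytomy counts one loss.
#'
#' @param tree A rooted `ape::phylo`.
#' @param presence Character vector of tip labels where the character is
#'   present (non-empty, all must be tips of `tree`).
#' @param unit_id Optional accession recorded in the result.
#' @return Object of class `dollo_reconstruction`: list with `unit_id`,
#'   `gain_node` (ape node number), `gain_label` (tip/node label when
#'   available), `loss_count`, and `node_states` (named character vector over
#'   all nodes, `"present"`/`"absent"`).
#' @export
dollo_reconstruct <- function(tree, presence, unit_id = NA_character_) {
  ti <- if (inherits(tree, "phylo")) .tree_index(tree) else tree
  stopifnot(is.list(ti), !is.null(ti$D))
  if (length(presence) == 0L) {
    stop("usage error: presence set is empty")
  }
  tipidx <- match(presence, ti$tree$tip.label)
  if (anyNA(tipidx)) {
    stop("usage error: unknown tip(s): ",
         paste(presence[is.na(tipidx)], collapse = ", "))
  }
  pres <- rep(FALSE, ti$N)
  pres[tipidx] <- TRUE
  core <- .dollo_core(ti, pres)
  states <- ifelse(core$under & core$cnt > 0L, "present", "absent")
  names(states) <- .node_labels(ti)
  structure(list(unit_id = unit_id, gain_node = core$gain,
                 gain_label = .node_labels(ti)[core$gain],
                 loss_count = core$losses, node_states = states),
            class = "dollo_reconstruction")
}

.node_labels <- function(ti) {
  labs <- c(ti$tree$tip.label,
            if (!is.null(ti$tree$node.label) &&
                length(ti$tree$node.label) == ti$M - ti$N) {
              ti$tree$node.label
            } else {
              paste0("node", (ti$N + 1L):ti$M)
            })
  labs[labs == "" | is.na(labs)] <-
    paste0("node", seq_len(ti$M))[labs == "" | is.na(labs)]
  labs
}

#' @export
print.dollo_reconstruction <- function(x, ...) {
  cat("dollo_reconstruction", if (!is.na(x$unit_id)) paste0("[", x$unit_id, "]"),
      ": gain at", x$gain_label, "with", x$loss_count, "loss(es)\n")
  invisible(x)
}

#' Nominate families consistent with vertical inheritance from a deep ancestor
#'
#' Maps each unit's presence pattern onto the species tree under Dollo
#' parsimony and nominates units whose inferred gain sits at the domain root,
#' or whose gain clade contains at least `clade_coverage` of the domain
#' root's immediate descendant clades that carry a presence tip (mirroring
#' the division-level broad-distribution rule on the tree: a unit confined
#' to a clade deeper than a root child covers none of them). An optional cap
#' on the loss count filters patterns that would require implausibly many
#' independent losses.
#'
#' @param tree A rooted `ape::phylo` whose tips all belong to one domain.
#' @param presence Named list: unit accession -> character vector of presence
#'   tip labels. Units with empty presence are skipped.
#' @param domain_root Node (ape number or node label) acting as the domain's
#'   ancestor; defaults to the tree root.
#' @param max_losses Optional integer cap on the Dollo loss count.
#' @param clade_coverage Fraction in (0, 1] of the domain root's child clades
#'   that must contain a presence tip (default 0.5).
#' @return data.frame ordered by accession: `unit_id`, `gain_label`,
#'   `loss_count`, `clades_covered` (presence-bearing root child clades
#'   inside the gain clade), `clades_bearing`, `nominated`.
#' @export
nominate_candidates <- function(tree, presence, domain_root = NULL,
                                max_losses = NULL, clade_coverage = 0.5) {
  ti <- .tree_index(tree)
  if (is.null(domain_root)) {
    root_node <- ti$root
  } else if (is.numeric(domain_root)) {
    root_node <- as.integer(domain_root)
    if (root_node < 1L || root_node > ti$M) {
      stop("usage error: domain_root node number out of range")
    }
  } else {
    labs <- .node_labels(ti)
    root_node <- match(domain_root, labs)
    if (is.na(root_node)) {
      stop("usage error: domain_root '", domain_root, "' not in tree")
    }
  }
  kids <- ti$children[[root_node]]
  if (length(presence)) presence <- presence[order(names(presence))]
  rows <- lapply(names(presence), function(u) {
    tips <- presence[[u]]
    if (length(tips) == 0L) return(NULL)
    rec <- dollo_reconstruct(ti, tips, unit_id = u)
    tipidx <- match(tips, ti$tree$tip.label)
    bearing <- kids[vapply(kids, function(k) any(ti$D[k, tipidx]),
                           logical(1))]
    covered <- sum(ti$A[rec$gain_node, bearing])
    nom <- (rec$gain_node == root_node) ||
      (length(bearing) > 0L && covered / length(bearing) >= clade_coverage)
    if (!is.null(max_losses)) nom <- nom && rec$loss_count <= max_losses
    data.frame(unit_id = u, gain_label = rec$gain_label,
               loss_count = rec$loss_count,
               clades_covered = as.integer(covered),
               clades_bearing = length(bearing),
               nominated = nom, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(unit_id = character(0), gain_label = character(0),
                      loss_count = integer(0), clades_covered = integer(0),
                      clades_bearing = integer(0), nominated = logical(0))
  }
  out
}

#' Fitch parsimony score for comparison with the Dollo reconstruction
#'
#' Convenience wrapper around `phangorn::fitch` scoring the same binary
#' character without the single-gain constraint. Provided for comparison
#' only; candidate nomination always uses the Dollo model, since family
#' membership implies homology and hence a single origin.
#'
#' @param tree A rooted `ape::phylo`.
#' @param presence Character vector of presence tip labels.
#' @return Integer parsimony score (minimum number of state changes).
#' @export
fitch_changes <- function(tree, presence) {
  if (!requireNamespace("phangorn", quietly = TRUE)) {
    stop("fitch_changes requires the 'phangorn' package")
  }
  states <- ifelse(tree$tip.label %in% presence, "1", "0")
  dat <- phangorn::phyDat(matrix(states, ncol = 1,
                                 dimnames = list(tree$tip.label, NULL)),
                          type = "USER", levels = c("0", "1"))
  as.integer(phangorn::fitch(tree, dat))
}

#' Write per-unit Dollo reconstructions to TSV
#'
#' @param nominations data.frame from [nominate_candidates()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_reconstructions <- function(nominations, path) {
  utils::write.table(nominations, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
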