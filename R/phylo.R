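# Balance indices on rooted trees, extreme-shape constructors, and
# normalization by the closed-form extreme values.  Trees are ape "phylo"
# objects (Newick I/O is delegated to ape); index computations walk the edge
# matrix directly, treating child order as irrelevant.  Branch lengths and
# internal node labels are ignored throughout.

# basic traversal statistics: depths, leaf counts, children lists
.tree_stats <- function(phy) {
  n <- length(phy$tip.label)
  if (n == 1L || is.null(phy$edge) || nrow(phy$edge) == 0L) {
    return(list(n = 1L, root = 1L, depth = 0L, kappa = 1L,
                kids = list(), order = 1L, parent = 0L))
  }
  N <- n + phy$Nnode
  root <- n + 1L
  kids <- vector("list", N)
  sp <- split(phy$edge[, 2L], phy$edge[, 1L])
  kids[as.integer(names(sp))] <- sp
  parent <- integer(N)
  parent[phy$edge[, 2L]] <- phy$edge[, 1L]
  depth <- integer(N)
  ord <- integer(N)
  ord[1L] <- root
  qi <- 1L; cnt <- 1L
  while (qi <= cnt) {
    v <- ord[qi]
    for (ch in kids[[v]]) {
      depth[ch] <- depth[v] + 1L
      cnt <- cnt + 1L
      ord[cnt] <- ch
    }
    qi <- qi + 1L
  }
  if (cnt != N) stop("tree is not connected from the root")
  kappa <- integer(N)
  kappa[seq_len(n)] <- 1L
  for (v in rev(ord)) {
    if (!is.null(kids[[v]])) kappa[v] <- sum(kappa[kids[[v]]])
  }
  list(n = n, root = root, depth = depth, kappa = kappa, kids = kids,
       order = ord, parent = parent)
}

.check_tree <- function(phy) {
  if (!inherits(phy, "phylo")) stop("expected a \"phylo\" tree")
  if (anyDuplicated(phy$tip.label)) stop("duplicate leaf labels")
  st <- .tree_stats(phy)
  if (st$n > 1L) {
    n_children <- lengths(st$kids[(st$n + 1L):(st$n + phy$Nnode)])
    if (any(n_children < 2L))
      stop("every internal node must have at least two children")
  }
  st
}

.is_bifurcating <- function(st) {
  st$n == 1L || all(lengths(st$kids[(st$n + 1L):length(st$kids)]) == 2L)
}

.check_bifurcating <- function(st, what) {
  internal <- st$kids[(st$n + 1L):length(st$kids)]
  if (st$n > 1L && any(lengths(internal) != 2L))
    stop(what, " is defined for bifurcating trees only")
}

#' Parse and write rooted trees in Newick format
#'
#' Thin validating wrappers around [ape::read.tree()] / [ape::write.tree()].
#' Branch lengths and internal labels are accepted and ignored by all index
#' computations; the terminating semicolon is required; duplicate leaf labels
#' and internal nodes with fewer than two children are rejected.
#'
#' @param text a Newick string (one tree).
#' @return `parse_newick`: an [ape::read.tree()] `"phylo"` object;
#'   `write_newick`: a Newick string.
#' @examples
#' tr <- parse_newick("((a,b),(c,d));")
#' write_newick(tr)
#' @export
parse_newick <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  bal <- 0L
  chars <- strsplit(text, "")[[1L]]
  for (i in seq_along(chars)) {
    if (chars[i] == "(") bal <- bal + 1L
    if (chars[i] == ")") bal <- bal - 1L
    if (bal < 0L) stop("unbalanced ')' at position ", i)
  }
  if (bal != 0L) stop("unbalanced '(' in Newick string (depth ", bal, " at end)")
  if (!grepl(";\\s*$", text)) stop("Newick string must end with ';'")
  phy <- tryCatch(ape::read.tree(text = text), error = function(e) NULL,
                  warning = function(w) NULL)
  if (is.null(phy)) stop("malformed Newick string")
  .check_tree(phy)
  phy
}

#' @rdname parse_newick
#' @param tree a `"phylo"` tree.
#' @export
write_newick <- function(tree) {
  .check_tree(tree)
  ape::write.tree(tree)
}

# single-leaf degenerate tree (a bare labeled leaf; all indices are 0)
.leaf_tree <- function(label = "L1") {
  structure(list(edge = matrix(integer(), 0L, 2L), tip.label = label,
                 Nnode = 0L), class = "phylo")
}

#' Rooted caterpillar with n leaves
#'
#' The maximally unbalanced bifurcating shape: every internal node has a leaf
#' child.  Leaves are labeled `L1..Ln` with `L1` the depth-1 leaf.
#'
#' @param n number of leaves, `n >= 2`.
#' @return a `"phylo"` tree.
#' @export
caterpillar_tree <- function(n) {
  stopifnot(n >= 2, n == floor(n))
  n <- as.integer(n)
  if (n == 2L)
    return(structure(list(edge = matrix(c(3L, 3L, 1L, 2L), 2L, 2L),
                          tip.label = c("L1", "L2"), Nnode = 1L),
                     class = "phylo"))
  edge <- matrix(0L, 2L * (n - 1L), 2L)
  row <- 0L
  for (k in seq_len(n - 2L)) {          # internal node n+k: leaf k + next internal
    edge[row + 1L, ] <- c(n + k, k)
    edge[row + 2L, ] <- c(n + k, n + k + 1L)
    row <- row + 2L
  }
  edge[row + 1L, ] <- c(2L * n - 1L, n - 1L)
  edge[row + 2L, ] <- c(2L * n - 1L, n)
  structure(list(edge = edge, tip.label = paste0("L", seq_len(n)),
                 Nnode = n - 1L), class = "phylo")
}

#' Maximally balanced tree with n leaves
#'
#' The recursive most-balanced bifurcating shape: the root splits its `n`
#' leaves into `ceiling(n/2)` and `floor(n/2)`, and each part is itself
#' maximally balanced, so every internal node's children differ by at most one
#' descendant leaf (asserted after construction).
#'
#' @param n number of leaves, `n >= 1` (for `n = 1` a bare labeled leaf).
#' @return a `"phylo"` tree.
#' @export
max_balanced_tree <- function(n) {
  stopifnot(n >= 1, n == floor(n))
  n <- as.integer(n)
  if (n == 1L) return(.leaf_tree())
  edge <- matrix(0L, 2L * (n - 1L), 2L)
  env <- new.env()
  env$tip <- 0L; env$int <- 0L; env$row <- 0L
  build <- function(k) {
    if (k == 1L) {
      env$tip <- env$tip + 1L
      return(env$tip)
    }
    env$int <- env$int + 1L
    id <- n + env$int
    left <- build(as.integer(ceiling(k / 2)))
    right <- build(as.integer(k %/% 2))
    edge[env$row + 1L, ] <<- c(id, left)
    edge[env$row + 2L, ] <<- c(id, right)
    env$row <- env$row + 2L
    id
  }
  build(n)
  phy <- structure(list(edge = edge, tip.label = paste0("L", seq_len(n)),
                        Nnode = n - 1L), class = "phylo")
  st <- .tree_stats(phy)
  for (v in (n + 1L):(2L * n - 1L)) {
    kk <- st$kappa[st$kids[[v]]]
    if (abs(kk[1L] - kk[2L]) > 1L)
      stop("internal error: constructed tree is not maximally balanced")
  }
  phy
}

#' Sackin index
#'
#' Sum of the leaves' depths (edge counts from the root).  Defined for any
#' rooted tree, bifurcating or not.
#'
#' @param tree a `"phylo"` tree (see [parse_newick()]).
#' @return a numeric (integer-valued) scalar.
#' @examples
#' sackin_index(caterpillar_tree(4))   # 1 + 2 + 3 + 3 = 9
#' @export
sackin_index <- function(tree) {
  st <- .check_tree(tree)
  if (st$n == 1L) return(0)
  sum(st$depth[seq_len(st$n)])
}

#' Colless index
#'
#' Sum over the internal nodes of the absolute difference between the leaf
#' counts of their two children; bifurcating trees only.
#'
#' @inheritParams sackin_index
#' @export
colless_index <- function(tree) {
  st <- .check_tree(tree)
  if (st$n == 1L) return(0)
  .check_bifurcating(st, "the Colless index")
  acc <- 0
  for (v in (st$n + 1L):length(st$kids)) {
    kk <- st$kappa[st$kids[[v]]]
    acc <- acc + abs(kk[1L] - kk[2L])
  }
  acc
}

#' Total Cophenetic index
#'
#' Sum over all unordered pairs of leaves of the depth of their lowest common
#' ancestor.  `method = "subtree"` uses the equivalent node sum
#' `sum_{v != root} choose(kappa_v, 2)` (each non-root node contributes one
#' unit of depth to every leaf pair below it); `method = "pairs"` evaluates
#' the pairwise LCA definition literally and is the cross-check.
#'
#' @inheritParams sackin_index
#' @param method `"subtree"` or `"pairs"`.
#' @export
cophenetic_index <- function(tree, method = c("subtree", "pairs")) {
  method <- match.arg(method)
  st <- .check_tree(tree)
  if (st$n == 1L) return(0)
  if (method == "subtree") {
    internal <- (st$n + 1L):length(st$kids)
    internal <- setdiff(internal, st$root)
    return(sum(choose(st$kappa[internal], 2)))
  }
  paths <- .leaf_paths(st)
  acc <- 0
  for (i in seq_len(st$n - 1L)) {
    for (j in (i + 1L):st$n) {
      acc <- acc + .lca_depth(paths[[i]], paths[[j]])
    }
  }
  acc
}

# root-to-leaf node paths (including the leaf)
.leaf_paths <- function(st) {
  lapply(seq_len(st$n), function(tip) {
    p <- tip
    v <- tip
    while (v != st$root) {
      v <- st$parent[v]
      p <- c(v, p)
    }
    p
  })
}

.lca_depth <- function(p1, p2) {
  m <- min(length(p1), length(p2))
  k <- 0L
  while (k < m && p1[k + 1L] == p2[k + 1L]) k <- k + 1L
  k - 1L                                   # depth of last common node
}

#' Rooted Quartet index
#'
#' Number of 4-leaf induced subtrees that are fully symmetric (two cherries);
#' bifurcating trees only.  `method = "subtree"` counts, at each internal node
#' with children leaf counts `k1, k2`, the `choose(k1,2) * choose(k2,2)`
#' quartets whose root split is 2-2 there; `method = "bruteforce"` enumerates
#' all `choose(n, 4)` leaf quadruples and tests each induced topology, and is
#' the cross-check for small trees.
#'
#' @inheritParams sackin_index
#' @param method `"subtree"` or `"bruteforce"`.
#' @export
quartet_index <- function(tree, method = c("subtree", "bruteforce")) {
  method <- match.arg(method)
  st <- .check_tree(tree)
  if (st$n == 1L) return(0)
  .check_bifurcating(st, "the rooted Quartet index")
  if (method == "subtree") {
    acc <- 0
    for (v in (st$n + 1L):length(st$kids)) {
      kk <- st$kappa[st$kids[[v]]]
      acc <- acc + choose(kk[1L], 2) * choose(kk[2L], 2)
    }
    return(acc)
  }
  if (st$n < 4L) return(0)
  paths <- .leaf_paths(st)
  quads <- utils::combn(st$n, 4L)
  acc <- 0
  for (c_i in seq_len(ncol(quads))) {
    quad <- quads[, c_i]
    pp <- paths[quad]
    k <- 0L
    repeat {
      nxt <- vapply(pp, function(p) if (length(p) > k + 1L) p[k + 2L] else NA_integer_, 0L)
      if (anyNA(nxt) || length(unique(nxt)) > 1L) break
      k <- k + 1L
    }
    branch <- vapply(pp, function(p) p[k + 2L], 0L)   # child of the LCA per leaf
    if (max(table(branch)) == 2L && length(unique(branch)) == 2L)
      acc <- acc + 1
  }
  acc
}

#' All balance indices of a tree
#'
#' @inheritParams sackin_index
#' @return a list of class `balance_indices` with `n`, `sackin`, `colless`,
#'   `cophenetic`, `quartet`; the Colless and Quartet entries are `NA` for
#'   non-bifurcating trees (their definitions need bifurcation).
#' @export
balance_indices <- function(tree) {
  st <- .check_tree(tree)
  bif <- .is_bifurcating(st)
  structure(list(
    n = st$n,
    sackin = sackin_index(tree),
    colless = if (bif) colless_index(tree) else NA_real_,
    cophenetic = cophenetic_index(tree),
    quartet = if (bif) quartet_index(tree) else NA_real_
  ), class = "balance_indices")
}

#' @export
print.balance_indices <- function(x, ...) {
  cat(sprintf("balance indices (n = %d): sackin = %s, colless = %s, cophenetic = %s, quartet = %s\n",
              x$n, format(x$sackin), format(x$colless), format(x$cophenetic),
              format(x$quartet)))
  invisible(x)
}

#' Extreme index values over bifurcating trees with n leaves
#'
#' The minimum and maximum of an index over the bifurcating shapes with `n`
#' leaves: the maximally balanced tree side comes from the closed formulas
#' ([sackin_min()], [colless_min()], [cophenetic_min()], [quartet_max()]);
#' the caterpillar side is computed directly on [caterpillar_tree()].  The
#' Sackin, Colless and Total Cophenetic indices are minimized by the balanced
#' tree and maximized by the caterpillar; the rooted Quartet index is the
#' reverse (the caterpillar has no symmetric quartets at all).
#'
#' @param index one of `"sackin"`, `"colless"`, `"cophenetic"`, `"quartet"`.
#' @param n number of leaves, `n >= 2`.
#' @return a list with numeric `min` and `max`.
#' @examples
#' extreme_values("colless", 8)   # min 0, max 21
#' @export
extreme_values <- function(index = c("sackin", "colless", "cophenetic", "quartet"), n) {
  index <- match.arg(index)
  stopifnot(n >= 2, n == floor(n))
  cat_tree <- caterpillar_tree(n)
  switch(index,
    sackin = list(min = as.numeric(sackin_min(n)), max = sackin_index(cat_tree)),
    colless = list(min = as.numeric(colless_min(n)), max = colless_index(cat_tree)),
    cophenetic = list(min = as.numeric(cophenetic_min(n)), max = cophenetic_index(cat_tree)),
    quartet = list(min = quartet_index(cat_tree), max = as.numeric(quartet_max(n)))
  )
}

#' Normalized balance index in [0, 1]
#'
#' Rescales an index affinely by its extreme values for the tree's number of
#' leaves.  The package convention orients every normalized index so that 0
#' is the most balanced shape and 1 the caterpillar: for the Sackin, Colless
#' and Total Cophenetic indices this is `(I - min) / (max - min)`; for the
#' rooted Quartet index (which is *maximized* by the balanced tree) the value
#' is inverted to `(max - I) / (max - min)`.
#'
#' @inheritParams extreme_values
#' @param tree a `"phylo"` tree.
#' @return a [rational()] scalar in `[0, 1]`.
#' @examples
#' normalize_index("colless", caterpillar_tree(16))   # 1
#' @export
normalize_index <- function(index = c("sackin", "colless", "cophenetic", "quartet"), tree) {
  index <- match.arg(index)
  st <- .check_tree(tree)
  n <- st$n
  ex <- extreme_values(index, n)
  if (ex$min == ex$max)
    stop(sprintf("the %s index has a degenerate range at n = %d (min = max = %s)",
                 index, n, format(ex$min)))
  value <- switch(index,
    sackin = sackin_index(tree), colless = colless_index(tree),
    cophenetic = cophenetic_index(tree), quartet = quartet_index(tree))
  num <- if (index == "quartet") ex$max - value else value - ex$min
  rational(num, ex$max - ex$min)
}
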