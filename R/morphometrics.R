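# Morphometric analyses: canonical ordered labelled trees from bodies,
# tree-edit distance (Zhang-Shasha, unit costs), eight normalized body traits,
# population diversity, parent-child similarity and the learning delta.

#' Canonical ordered labelled tree of a robot body
#'
#' Nodes are labelled by module kind (and, by default, rotation); children are
#' ordered by the parent's socket index, so structurally identical bodies map
#' to identical trees.
#' @param b a `robot_body`
#' @param include_rotation include the 0/90 rotation in node labels
#'   (default TRUE)
#' @return nested list of class `morph_tree` with fields `label`, `children`
#' @export
morph_tree <- function(b, include_rotation = TRUE) {
  m <- b$modules
  build <- function(id) {
    row <- m[m$id == id, ]
    lab <- if (include_rotation && row$kind != "core")
      paste0(row$kind, "/", row$rotation) else row$kind
    kid_rows <- m[!is.na(m$parent) & m$parent == id, , drop = FALSE]
    kid_rows <- kid_rows[order(kid_rows$socket), , drop = FALSE]
    structure(list(label = lab,
                   children = lapply(kid_rows$id, build)),
              class = "morph_tree")
  }
  build(m$id[m$kind == "core"])
}

#' Number of nodes of a `morph_tree`
#' @param tree a `morph_tree`
#' @return integer
#' @export
tree_size <- function(tree) {
  1L + sum(vapply(tree$children, tree_size, integer(1)))
}

# postorder traversal helpers for Zhang-Shasha
.postorder <- function(tree) {
  labels <- character(0)
  lml <- integer(0)     # leftmost leaf descendant (postorder index)
  walk <- function(node) {
    if (length(node$children) == 0) {
      labels <<- c(labels, node$label)
      lml <<- c(lml, length(labels))
      return(length(labels))
    }
    first <- NA_integer_
    for (ch in node$children) {
      f <- walk(ch)
      if (is.na(first)) first <- lml[f]
    }
    labels <<- c(labels, node$label)
    lml <<- c(lml, first)
    length(labels)
  }
  walk(tree)
  list(labels = labels, lml = lml)
}

.keyroots <- function(lml) {
  n <- length(lml)
  kr <- integer(0)
  seen <- logical(n + 1)
  for (i in n:1) {
    if (!seen[lml[i]]) {
      kr <- c(kr, i)
      seen[lml[i]] <- TRUE
    }
  }
  sort(kr)
}

#' Tree-edit distance between two canonical trees
#'
#' Minimal number of node insertions, deletions and relabelings (unit costs)
#' transforming one ordered labelled tree into the other; computed with the
#' Zhang-Shasha dynamic programme. Accepts `morph_tree`s or `robot_body`s.
#' @param a,b `morph_tree` or `robot_body` objects
#' @return non-negative integer-valued distance
#' @export
tree_edit_distance <- function(a, b) {
  if (inherits(a, "robot_body")) a <- morph_tree(a)
  if (inherits(b, "robot_body")) b <- morph_tree(b)
  A <- .postorder(a); B <- .postorder(b)
  n <- length(A$labels); m <- length(B$labels)
  td <- matrix(0, n, m)
  for (i in .keyroots(A$lml)) for (j in .keyroots(B$lml)) {
    li <- A$lml[i]; lj <- B$lml[j]
    fd <- matrix(0, i - li + 2, j - lj + 2)
    fd[, 1] <- 0:(i - li + 1)
    fd[1, ] <- 0:(j - lj + 1)
    for (x in li:i) for (y in lj:j) {
      xi <- x - li + 2; yj <- y - lj + 2
      if (A$lml[x] == li && B$lml[y] == lj) {
        cost <- if (A$labels[x] == B$labels[y]) 0 else 1
        fd[xi, yj] <- min(fd[xi - 1, yj] + 1, fd[xi, yj - 1] + 1,
                          fd[xi - 1, yj - 1] + cost)
        td[x, y] <- fd[xi, yj]
      } else {
        fd[xi, yj] <- min(fd[xi - 1, yj] + 1, fd[xi, yj - 1] + 1,
                          fd[A$lml[x] - li + 1, B$lml[y] - lj + 1] + td[x, y])
      }
    }
  }
  td[n, m]
}

#' Eight normalized morphological traits of a body
#'
#' All traits lie in `[0, 1]` and are invariant under mirror reflection. The
#' formulas are documented reconstructions of standard modular-robot
#' descriptors (with m = number of non-core modules):
#' \describe{
#'   \item{branching}{modules with >= 3 children / max(1, floor(m / 3))}
#'   \item{limbs}{leaf modules / m}
#'   \item{length_of_limbs}{deepest module depth / m}
#'   \item{coverage}{modules / cells of the 3D bounding box}
#'   \item{joints}{active hinges / m}
#'   \item{proportion}{short / long side of the 2D (x, y) bounding box}
#'   \item{symmetry}{largest matched-cell fraction under x- or y-mirror of the
#'     2D projection}
#'   \item{size}{m / 10}
#' }
#' @param b a `robot_body`
#' @param max_modules normalizer for size (default 10)
#' @return named numeric vector of length 8
#' @export
traits <- function(b, max_modules = 10) {
  m <- b$modules
  nc <- m[m$kind != "core", , drop = FALSE]
  mm <- nrow(nc)
  n_children <- table(factor(nc$parent, levels = m$id))
  branch_nodes <- sum(n_children >= 3)
  leaves <- if (mm == 0) 0L else sum(!(nc$id %in% nc$parent))
  bbox3 <- prod(apply(m[, c("x", "y", "z")], 2, function(v) diff(range(v)) + 1))
  ext2 <- c(diff(range(m$x)) + 1, diff(range(m$y)) + 1)
  cells <- unique(m[, c("x", "y")])
  sym_frac <- function(mirror) {
    mirrored <- cells
    mirrored[[mirror]] <- -mirrored[[mirror]]
    keys <- paste(cells$x, cells$y)
    mkeys <- paste(mirrored$x, mirrored$y)
    mean(mkeys %in% keys)
  }
  c(branching = if (mm == 0) 0 else branch_nodes / max(1, floor(mm / 3)),
    limbs = if (mm == 0) 0 else leaves / mm,
    length_of_limbs = if (mm == 0) 0 else max(m$depth) / mm,
    coverage = nrow(m) / bbox3,
    joints = if (mm == 0) 0 else sum(nc$kind == "active_hinge") / mm,
    proportion = min(ext2) / max(ext2),
    symmetry = max(sym_frac("x"), sym_frac("y")),
    size = min(1, mm / max_modules))
}

#' Morphological diversity of a population
#'
#' Mean tree-edit distance over all unordered pairs of individuals' bodies.
#' @param pop list of individuals (each with a `$body`) or of `robot_body`s
#' @return mean pairwise distance
#' @export
diversity <- function(pop) {
  bodies <- lapply(pop, function(p) if (inherits(p, "robot_body")) p else p$body)
  n <- length(bodies)
  if (n < 2) stop("diversity requires at least two individuals")
  trees <- lapply(bodies, morph_tree)
  total <- 0; count <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    total <- total + tree_edit_distance(trees[[i]], trees[[j]])
    count <- count + 1
  }
  total / count
}

#' Parent-child morphological distance
#'
#' Tree-edit distance between a child's body and its fittest parent's body.
#' @param child,parent `robot_body` (or `morph_tree`) objects
#' @return non-negative distance
#' @export
parent_child_distance <- function(child, parent) {
  if (is.null(child) || is.null(parent)) stop("lineage not resolvable")
  tree_edit_distance(child, parent)
}

#' Learning delta of an individual
#'
#' Task performance after lifetime learning minus performance before: the
#' proxy for how much the body facilitates learning ("morphological
#' intelligence"). May be negative; no clamping.
#' @param ind an individual with recorded `fitness_before` and `fitness_after`
#' @return numeric
#' @export
learning_delta <- function(ind) {
  if (is.null(ind$fitness_before) || is.na(ind$fitness_before))
    stop("pre-learning fitness not recorded")
  if (is.null(ind$fitness_after) || is.na(ind$fitness_after))
    stop("post-learning fitness not recorded")
  ind$fitness_after - ind$fitness_before
}

#' Generate a random body
#'
#' Decodes a fresh random CPPN; used by the morphological-intelligence control
#' experiment, where a newborn's inherited body is replaced by a random one
#' while the inherited brain genome is kept (unused genome rows tolerate the
#' change by construction).
#' @param max_modules non-core module cap (default 10)
#' @return a `robot_body`
#' @export
random_body <- function(max_modules = 10L) {
  decode_body(random_cppn(), max_modules)
}
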