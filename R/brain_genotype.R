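# The brain genotype is a fixed 440 x 14 real table. Rows index the 440 cells
# of the 21 x 21 body grid (centre excluded) a joint can occupy after the z
# dimension is dropped; columns hold, per cell, 12 weights for couplings to
# CPGs in the distance-2 neighbourhood, 1 weight for couplings to CPGs at the
# same 2D coordinate (joints stacked in z), and 1 internal CPG weight. Only
# the entries addressed by a concrete body are expressed; the rest ride along
# silently and can be expressed in offspring with different bodies. The
# develop/encode pair below is exactly invertible on the expressed entries,
# which is what makes Lamarckian write-back possible.

.GRID_HALF <- 10L      # grid spans -10..10 in x and y
.GRID_SIDE <- 21L
.N_ROWS    <- 440L     # 21*21 - 1 (centre excluded)
.N_SLOTS   <- 14L

#' Construct a brain genome table
#' @param weights 440 x 14 numeric matrix, or a single number used as fill
#'   (default 0)
#' @return object of class `brain_genome` (a 440 x 14 matrix)
#' @export
brain_genome <- function(weights = 0) {
  if (length(weights) == 1) weights <- matrix(weights, .N_ROWS, .N_SLOTS)
  weights <- as.matrix(weights)
  if (!all(dim(weights) == c(.N_ROWS, .N_SLOTS)))
    stop("brain genome must be a 440 x 14 matrix")
  if (!all(is.finite(weights))) stop("brain genome entries must be finite")
  structure(weights, class = c("brain_genome", "matrix", "array"))
}

#' Random brain genome with i.i.d. Gaussian entries
#' @param sd standard deviation of the entries (default 0.5)
#' @return a `brain_genome`
#' @export
random_brain_genome <- function(sd = 0.5) {
  brain_genome(matrix(stats::rnorm(.N_ROWS * .N_SLOTS, 0, sd), .N_ROWS, .N_SLOTS))
}

#' Map a 2D grid position to its genome row
#'
#' Row-major bijection from the 440 valid cells of the 21 x 21 grid (x fastest,
#' centre (0,0) skipped) onto 0..439.
#' @param x,y integer grid coordinates in -10..10, not both zero
#' @return 0-based row index in `[0, 440)`
#' @export
grid_row <- function(x, y) {
  if (any(abs(c(x, y)) > .GRID_HALF)) stop("grid coordinate out of range")
  if (x == 0 && y == 0) stop("the grid centre cannot hold a joint")
  lin <- (y + .GRID_HALF) * .GRID_SIDE + (x + .GRID_HALF)
  centre <- .GRID_HALF * .GRID_SIDE + .GRID_HALF
  as.integer(if (lin > centre) lin - 1L else lin)
}

#' Inverse of [grid_row()]
#' @param row 0-based row index in `[0, 440)`
#' @return integer vector `c(x, y)`
#' @export
grid_row_inverse <- function(row) {
  if (row < 0 || row >= .N_ROWS) stop("row index out of range")
  centre <- .GRID_HALF * .GRID_SIDE + .GRID_HALF
  lin <- if (row >= centre) row + 1L else row
  c(lin %% .GRID_SIDE - .GRID_HALF, lin %/% .GRID_SIDE - .GRID_HALF)
}

# the 12 neighbour offsets {(dx,dy): 1 <= |dx|+|dy| <= 2}, lexicographic
.neighbour_offsets <- local({
  g <- expand.grid(dy = -2:2, dx = -2:2)   # dx major, dy minor -> lexicographic
  g <- g[abs(g$dx) + abs(g$dy) >= 1 & abs(g$dx) + abs(g$dy) <= 2, c("dx", "dy")]
  g <- g[order(g$dx, g$dy), ]
  rownames(g) <- NULL
  g
})

#' The 12 distance-2 neighbourhood offsets, in slot order
#' @return data.frame with columns `dx`, `dy` and 12 rows (lexicographic order)
#' @export
neighbour_offsets <- function() .neighbour_offsets

#' Map a relative joint offset to its genome column
#'
#' Columns 0..11 are the 12 offsets with Manhattan distance 1 or 2 (in
#' lexicographic (dx, dy) order), column 12 is the same-2D-coordinate slot and
#' column 13 the CPG's internal weight.
#' @param dx,dy integer offset of the neighbouring joint
#' @param same_coord if `TRUE`, return the same-coordinate slot (12)
#' @return 0-based column index
#' @export
slot_for_offset <- function(dx, dy, same_coord = FALSE) {
  if (same_coord) return(12L)
  md <- abs(dx) + abs(dy)
  if (md < 1 || md > 2) stop("offset outside the distance-2 neighbourhood")
  hit <- which(.neighbour_offsets$dx == dx & .neighbour_offsets$dy == dy)
  hit - 1L
}

.SLOT_SAME     <- 12L
.SLOT_INTERNAL <- 13L

# -- expressed entries of a body ---------------------------------------------

# Pairwise tree distances between modules (edges of the module tree).
.module_tree_dist <- function(b) {
  m <- b$modules
  n <- nrow(m)
  adj <- vector("list", n)
  for (i in seq_len(n)) {
    if (!is.na(m$parent[i])) {
      p <- match(m$parent[i], m$id)
      adj[[i]] <- c(adj[[i]], p)
      adj[[p]] <- c(adj[[p]], i)
    }
  }
  d <- matrix(Inf, n, n)
  for (s in seq_len(n)) {
    d[s, s] <- 0
    frontier <- s
    while (length(frontier)) {
      nxt <- integer(0)
      for (v in frontier) for (w in adj[[v]]) {
        if (d[s, w] > d[s, v] + 1) { d[s, w] <- d[s, v] + 1; nxt <- c(nxt, w) }
      }
      frontier <- nxt
    }
  }
  d
}

# The genome entries a body expresses. For each joint (decode order) one
# internal entry; for each unordered neighbour pair (tree distance <= 2) one
# coupling entry, stored in the row of the earlier joint in decode order (the
# reverse coupling is its negation). Returns a data.frame with one row per
# expressed entry.
.used_entries <- function(b) {
  j <- body_joints(b)
  n <- length(j)
  if (n == 0)
    return(data.frame(kind = character(), i = integer(), jj = integer(),
                      row = integer(), col = integer()))
  m <- b$modules
  rows <- vapply(j, function(k) grid_row(m$x[k], m$y[k]), integer(1))
  out <- data.frame(kind = "internal", i = seq_len(n), jj = NA_integer_,
                    row = rows, col = .SLOT_INTERNAL, stringsAsFactors = FALSE)
  if (n > 1) {
    td <- .module_tree_dist(b)[j, j, drop = FALSE]
    for (a in 1:(n - 1)) for (bb in (a + 1):n) {
      if (td[a, bb] > 2) next
      dx <- m$x[j[bb]] - m$x[j[a]]
      dy <- m$y[j[bb]] - m$y[j[a]]
      col <- if (dx == 0 && dy == 0) .SLOT_SAME else slot_for_offset(dx, dy)
      out <- rbind(out, data.frame(kind = "coupling", i = a, jj = bb,
                                   row = rows[a], col = col,
                                   stringsAsFactors = FALSE))
    }
  }
  out
}

#' Develop a brain genome into a CPG network for a given body
#'
#' One CPG per active hinge (in decode order). The internal weight of joint i
#' at 2D grid position p is read from `g[grid_row(p), internal slot]`; the
#' coupling between neighbouring joints (tree distance <= 2) is read from the
#' row of the earlier joint in decode order, at the column of the relative 2D
#' offset (the same-coordinate slot when the two joints stack in z). The
#' reverse coupling is the negation (antisymmetry). Entries not addressed by
#' the body are ignored.
#'
#' @param g a `brain_genome`
#' @param b a `robot_body`
#' @return a `cpg_network` (see [cpg_network()]) with states initialized to
#'   sqrt(2)/2
#' @export
develop_brain <- function(g, b) {
  ue <- .used_entries(b)
  j <- body_joints(b)
  n <- length(j)
  w_internal <- numeric(n)
  coupling <- matrix(0, n, n)
  gm <- unclass(g)
  for (r in seq_len(nrow(ue))) {
    val <- gm[ue$row[r] + 1L, ue$col[r] + 1L]
    if (ue$kind[r] == "internal") {
      w_internal[ue$i[r]] <- val
    } else {
      coupling[ue$i[r], ue$jj[r]] <- val
      coupling[ue$jj[r], ue$i[r]] <- -val
    }
  }
  cpg_network(b, w_internal, coupling)
}

#' Write a CPG network's weights back into a brain genome
#'
#' The exact inverse of [develop_brain()]: the entries of `g` that the body
#' expresses are overwritten with the network's weights; all other entries are
#' left untouched (they may be expressed by offspring with different bodies).
#'
#' @param n a `cpg_network` developed from `b`
#' @param b the `robot_body` the network was developed from
#' @param g the `brain_genome` to copy and overwrite
#' @return a new `brain_genome`
#' @export
encode_brain <- function(n, b, g) {
  j <- body_joints(b)
  if (n$n != length(j)) stop("network topology does not match body")
  ue <- .used_entries(b)
  gm <- unclass(g)
  for (r in seq_len(nrow(ue))) {
    val <- if (ue$kind[r] == "internal") n$w_internal[ue$i[r]]
           else n$coupling[ue$i[r], ue$jj[r]]
    gm[ue$row[r] + 1L, ue$col[r] + 1L] <- val
  }
  brain_genome(gm)
}

#' Uniform crossover of two brain genomes
#'
#' Every one of the 440 x 14 entries is taken from either parent independently
#' with equal probability.
#' @param g1,g2 parent `brain_genome`s
#' @return child `brain_genome`
#' @export
uniform_crossover_brain <- function(g1, g2) {
  mask <- matrix(stats::runif(.N_ROWS * .N_SLOTS) < 0.5, .N_ROWS, .N_SLOTS)
  out <- unclass(g1)
  out[!mask] <- unclass(g2)[!mask]
  brain_genome(out)
}

#' Gaussian mutation of a brain genome
#'
#' Each entry is independently perturbed with probability `p` by additive
#' Gaussian noise with mean 0 and standard deviation `sd`.
#' @param g a `brain_genome`
#' @param p per-entry mutation probability (default 0.8)
#' @param sd noise standard deviation (default 0.5)
#' @return mutated `brain_genome`
#' @export
gaussian_mutate_brain <- function(g, p = 0.8, sd = 0.5) {
  if (p <= 0) return(g)
  out <- unclass(g)
  hit <- matrix(stats::runif(.N_ROWS * .N_SLOTS) < p, .N_ROWS, .N_SLOTS)
  out[hit] <- out[hit] + stats::rnorm(sum(hit), 0, sd)
  brain_genome(out)
}

#' @export
print.brain_genome <- function(x, ...) {
  cat(sprintf("<brain_genome: 440 x 14 weight table, mean %.3f, sd %.3f>\n",
              mean(x), stats::sd(x)))
  invisible(x)
}

#' Read/write a brain genome as flat CSV
#' @param g a `brain_genome`
#' @param path file path
#' @return `read_brain_csv` returns a `brain_genome`
#' @export
write_brain_csv <- function(g, path) {
  # 17 significant digits round-trip IEEE doubles exactly
  txt <- apply(unclass(g), 1, function(r)
    paste(sprintf("%.17g", r), collapse = ","))
  writeLines(txt, path)
  invisible(path)
}

#' @rdname write_brain_csv
#' @export
read_brain_csv <- function(path) {
  brain_genome(as.matrix(utils::read.table(path, sep = ",", header = FALSE)))
}

#' Serialize / deserialize a brain genome as JSON (bit-exact)
#' @param g a `brain_genome`
#' @return `brain_to_json`: JSON string; `brain_from_json`: a `brain_genome`
#' @export
brain_to_json <- function(g) {
  # 17 significant digits round-trip IEEE doubles exactly
  jsonlite::toJSON(unclass(g), digits = I(17))
}

#' @rdname brain_to_json
#' @param json JSON string produced by [brain_to_json()]
#' @export
brain_from_json <- function(json) {
  brain_genome(jsonlite::fromJSON(json))
}
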