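# -- module frames ------------------------------------------------------------
# Each module carries an orthonormal integer frame (3x3 matrix, columns = the
# module's local x/y/z axes in world coordinates). Local +y is "front", the
# direction the module grows in. A child's frame is
#   parent_frame %*% R_socket %*% (Ry90 if rotated 90 degrees)
# so a 90-degree rotation rolls the whole subtree about the attachment axis.

.rot_z <- function(q) switch(as.character(q %% 4),
  "0" = diag(3),
  "1" = matrix(c(0, 1, 0, -1, 0, 0, 0, 0, 1), 3, 3),
  "2" = matrix(c(-1, 0, 0, 0, -1, 0, 0, 0, 1), 3, 3),
  "3" = matrix(c(0, -1, 0, 1, 0, 0, 0, 0, 1), 3, 3))
.rot_x <- function(q) switch(as.character(q %% 4),
  "0" = diag(3),
  "1" = matrix(c(1, 0, 0, 0, 0, 1, 0, -1, 0), 3, 3),
  "2" = matrix(c(1, 0, 0, 0, -1, 0, 0, 0, -1), 3, 3),
  "3" = matrix(c(1, 0, 0, 0, 0, -1, 0, 1, 0), 3, 3))
.rot_y90 <- matrix(c(0, 0, -1, 0, 1, 0, 1, 0, 0), 3, 3)

# Fixed socket tables: name, local direction, frame rotation taking local
# forward (0,1,0) onto the socket direction. Socket order is the documented
# BFS expansion order.
.socket_defs <- list(
  core = list(
    front  = list(dir = c(0, 1, 0),  R = .rot_z(0)),
    back   = list(dir = c(0, -1, 0), R = .rot_z(2)),
    left   = list(dir = c(-1, 0, 0), R = .rot_z(1)),
    right  = list(dir = c(1, 0, 0),  R = .rot_z(3)),
    top    = list(dir = c(0, 0, 1),  R = .rot_x(1)),
    bottom = list(dir = c(0, 0, -1), R = .rot_x(3))
  ),
  brick = list(
    front = list(dir = c(0, 1, 0),  R = .rot_z(0)),
    left  = list(dir = c(-1, 0, 0), R = .rot_z(1)),
    right = list(dir = c(1, 0, 0),  R = .rot_z(3))
  ),
  active_hinge = list(
    front = list(dir = c(0, 1, 0), R = .rot_z(0))
  )
)

#' Socket names of a module kind, in fixed expansion order
#' @param kind one of "core", "brick", "active_hinge"
#' @return character vector of socket names
#' @export
module_sockets <- function(kind) names(.socket_defs[[kind]])

.new_body <- function(modules) {
  structure(list(modules = modules), class = "robot_body")
}

#' Decode a CPPN genome into a robot body
#'
#' The core module is placed at the origin and expansion proceeds breadth-first
#' over open sockets in fixed socket order (core: front, back, left, right,
#' top, bottom; brick: front, left, right; hinge: front). For every open slot
#' the CPPN is queried at the slot's integer coordinates with the tree distance
#' to the core as fourth input; the argmax of the three type outputs decides
#' brick / active hinge / empty (ties by that fixed order), the argmax of the
#' two rotation outputs decides 0 or 90 degrees. "Empty" closes the branch; an
#' already-occupied target position also closes the branch (the module is not
#' placed); expansion stops once `max_modules` non-core modules exist.
#'
#' @param g a `cppn_genome`
#' @param max_modules cap on non-core modules (default 10)
#' @return a `robot_body`: a tree of modules with integer 3D grid positions
#' @export
decode_body <- function(g, max_modules = 10L) {
  modules <- data.frame(
    id = 1L, kind = "core", x = 0L, y = 0L, z = 0L, rotation = 0L,
    parent = NA_integer_, socket = NA_integer_, depth = 0L,
    stringsAsFactors = FALSE
  )
  frames <- list(diag(3))
  occupied <- new.env(parent = emptyenv())
  assign("0,0,0", TRUE, envir = occupied)
  # BFS queue of open slots: (parent row index, socket index)
  queue <- lapply(seq_along(module_sockets("core")),
                  function(s) list(parent = 1L, socket = s))
  n_noncore <- 0L
  while (length(queue) > 0 && n_noncore < max_modules) {
    slot <- queue[[1]]; queue <- queue[-1]
    p <- slot$parent
    pk <- modules$kind[p]
    sdef <- .socket_defs[[pk]][[slot$socket]]
    dir <- as.integer(round(frames[[p]] %*% sdef$dir))
    pos <- c(modules$x[p], modules$y[p], modules$z[p]) + dir
    key <- paste(pos, collapse = ",")
    if (exists(key, envir = occupied, inherits = FALSE)) next  # branch ends
    d <- modules$depth[p] + 1L
    q <- query_cppn(g, pos[1], pos[2], pos[3], d)
    ti <- .argmax_first(q$type)
    if (ti == 3L) next  # empty: branch closed
    kind <- c("brick", "active_hinge")[ti]
    # the brain genotype cannot address a joint at the 2D grid centre, so a
    # hinge stacked in the core's z-column is never placed (branch ends)
    if (kind == "active_hinge" && pos[1] == 0L && pos[2] == 0L) next
    rot <- c(0L, 90L)[.argmax_first(q$rot)]
    id <- nrow(modules) + 1L
    modules <- rbind(modules, data.frame(
      id = id, kind = kind, x = pos[1], y = pos[2], z = pos[3],
      rotation = rot, parent = modules$id[p], socket = slot$socket, depth = d,
      stringsAsFactors = FALSE))
    fr <- frames[[p]] %*% sdef$R
    if (rot == 90L) fr <- fr %*% .rot_y90
    frames[[id]] <- fr
    assign(key, TRUE, envir = occupied)
    n_noncore <- n_noncore + 1L
    for (s in seq_along(module_sockets(kind)))
      queue <- c(queue, list(list(parent = id, socket = s)))
  }
  .new_body(modules)
}

#' Validate a robot body's structural invariants
#'
#' One core at the origin, unique integer positions, tree structure, every
#' non-core module one orthogonal grid step from its parent, and at most
#' `max_modules` non-core modules.
#' @param b a `robot_body`
#' @param max_modules non-core module cap (default 10)
#' @return `b` invisibly; stops on violation
#' @export
validate_body <- function(b, max_modules = 10L) {
  m <- b$modules
  core <- m[m$kind == "core", ]
  if (nrow(core) != 1 || any(c(core$x, core$y, core$z) != 0))
    stop("body must have exactly one core module at the origin")
  if (anyDuplicated(m[, c("x", "y", "z")])) stop("duplicate module positions")
  if (nrow(m) - 1 > max_modules) stop("too many non-core modules")
  nc <- m[m$kind != "core", , drop = FALSE]
  if (nrow(nc)) {
    if (any(is.na(nc$parent))) stop("non-core module without parent")
    pidx <- match(nc$parent, m$id)
    step <- abs(nc$x - m$x[pidx]) + abs(nc$y - m$y[pidx]) + abs(nc$z - m$z[pidx])
    if (any(step != 1)) stop("module not one orthogonal step from its parent")
  }
  if (any(abs(m[, c("x", "y", "z")]) > 10)) stop("module outside the 21-cell grid")
  invisible(b)
}

#' Number of non-core modules of a body
#' @param b a `robot_body`
#' @return integer
#' @export
module_count <- function(b) nrow(b$modules) - 1L

#' Row indices (decode order) of the active hinges of a body
#' @param b a `robot_body`
#' @return integer vector
#' @export
body_joints <- function(b) which(b$modules$kind == "active_hinge")

#' Project a body's joints to the 2D grid
#'
#' Drops the z dimension. Joints that collapse onto the same (x, y) cell are
#' preserved as ordered lists (decode order).
#' @param b a `robot_body`
#' @return named list: names are `"x,y"` keys, values integer vectors of joint
#'   module ids in decode order
#' @export
project_2d <- function(b) {
  j <- body_joints(b)
  out <- list()
  for (i in j) {
    key <- paste(b$modules$x[i], b$modules$y[i], sep = ",")
    out[[key]] <- c(out[[key]], b$modules$id[i])
  }
  out
}

#' @export
print.robot_body <- function(x, ...) {
  m <- x$modules
  cat(sprintf("<robot_body: %d modules (%d bricks, %d hinges)>\n",
              nrow(m), sum(m$kind == "brick"), sum(m$kind == "active_hinge")))
  invisible(x)
}

#' Render the z = 0 layer of a body as an ASCII grid
#'
#' `O` core, `B` brick, `H` active hinge, `.` empty. Debug aid only.
#' @param b a `robot_body`
#' @return character vector of grid rows (printed top to bottom, +y up)
#' @export
body_ascii <- function(b) {
  m <- b$modules[b$modules$z == 0, , drop = FALSE]
  xs <- range(m$x); ys <- range(m$y)
  grid <- matrix(".", nrow = diff(ys) + 1, ncol = diff(xs) + 1)
  sym <- c(core = "O", brick = "B", active_hinge = "H")
  for (i in seq_len(nrow(m)))
    grid[ys[2] - m$y[i] + 1, m$x[i] - xs[1] + 1] <- sym[[m$kind[i]]]
  apply(grid, 1, paste, collapse = "")
}

# -- serialization ------------------------------------------------------------

.body_subtree <- function(m, id) {
  row <- m[m$id == id, ]
  kids <- m$id[!is.na(m$parent) & m$parent == id]
  node <- list(kind = row$kind, position = c(row$x, row$y, row$z),
               rotation = row$rotation)
  if (length(kids)) node$children <- lapply(kids, .body_subtree, m = m)
  node
}

#' Serialize a robot body as a JSON tree
#' @param b a `robot_body`
#' @return JSON string (kind, position, rotation, children), round-trip stable
#' @export
body_to_json <- function(b) {
  root_id <- b$modules$id[b$modules$kind == "core"]
  jsonlite::toJSON(.body_subtree(b$modules, root_id),
                   auto_unbox = TRUE, digits = NA)
}

#' @rdname body_to_json
#' @param json JSON string produced by [body_to_json()]
#' @export
body_from_json <- function(json) {
  tree <- jsonlite::fromJSON(json, simplifyDataFrame = FALSE)
  rows <- list()
  walk <- function(node, parent, depth) {
    id <- length(rows) + 1L
    rows[[id]] <<- data.frame(
      id = id, kind = node$kind, x = node$position[1], y = node$position[2],
      z = node$position[3], rotation = node$rotation,
      parent = if (is.null(parent)) NA_integer_ else parent,
      socket = NA_integer_, depth = depth, stringsAsFactors = FALSE)
    for (ch in node$children) walk(ch, id, depth + 1L)
  }
  walk(tree, NULL, 0L)
  m <- do.call(rbind, rows)
  # restore socket indices from geometry so the canonical child order is stable
  for (i in seq_len(nrow(m))) {
    if (is.na(m$parent[i])) next
    p <- match(m$parent[i], m$id)
    m$socket[i] <- .infer_socket(m, i, p)
  }
  b <- .new_body(m)
  validate_body(b)
  b
}

# Infer the parent's socket index from relative geometry: rebuild parent frames
# top-down. Used only on deserialization.
.infer_socket <- function(m, i, p) {
  # recompute the parent's frame by walking from the root
  frame_of <- function(idx) {
    if (is.na(m$parent[idx])) return(diag(3))
    pp <- match(m$parent[idx], m$id)
    fr <- frame_of(pp)
    sdef <- .socket_defs[[m$kind[pp]]][[m$socket[idx]]]
    fr <- fr %*% sdef$R
    if (m$rotation[idx] == 90) fr <- fr %*% .rot_y90
    fr
  }
  pf <- frame_of(p)
  dir <- c(m$x[i] - m$x[p], m$y[i] - m$y[p], m$z[i] - m$z[p])
  socks <- .socket_defs[[m$kind[p]]]
  for (s in seq_along(socks)) {
    if (all(as.integer(round(pf %*% socks[[s]]$dir)) == dir)) return(s)
  }
  stop("cannot infer socket from geometry")
}

# -- shipped deterministic fixtures ------------------------------------------

#' Deterministic fixture CPPN genomes
#'
#' Three hand-built genomes with known decodings, used throughout the test
#' suite and available for experimentation:
#' \describe{
#'   \item{`"core_only"`}{the empty-space output has a large bias, so every
#'     query returns "empty" and the body is a bare core (F1).}
#'   \item{`"plus"`}{decodes to the "+"-shaped robot: four active hinges at
#'     (1,0,0), (-1,0,0), (0,1,0), (0,-1,0) in the z = 0 plane (F2).}
#'   \item{`"chain10"`}{decodes to a straight chain of ten active hinges along
#'     +y (F3).}
#' }
#' @param which one of `"core_only"`, `"plus"`, `"chain10"`
#' @return a `cppn_genome`
#' @export
fixture_cppn <- function(which = c("core_only", "plus", "chain10")) {
  which <- match.arg(which)
  base_nodes <- data.frame(
    id   = c(1:4, 5:9),
    type = c(rep("input", 4), rep("output", 5)),
    act  = "linear",
    bias = 0,
    stringsAsFactors = FALSE
  )
  no_conns <- data.frame(src = integer(), dst = integer(), weight = numeric(),
                         enabled = logical(), innov = numeric())
  if (which == "core_only") {
    nodes <- base_nodes
    nodes$bias[nodes$id == 7] <- 10   # empty always wins
    nodes$bias[nodes$id == 8] <- 1    # rotation 0
    return(cppn_genome(nodes, no_conns))
  }
  if (which == "plus") {
    # hidden gaussian node on z keeps the body planar; joint beats empty only
    # at tree distance 1 in the z = 0 plane
    nodes <- rbind(base_nodes,
                   data.frame(id = 100, type = "hidden", act = "gauss",
                              bias = 0, stringsAsFactors = FALSE))
    nodes$bias[nodes$id == 8] <- 1    # rotation 0
    conns <- data.frame(
      src    = c(3,   100, 4),
      dst    = c(100, 6,   7),
      weight = c(1,   1.5, 1),
      enabled = TRUE,
      innov  = .innovation_id(c(3, 100, 4), c(100, 6, 7)))
    return(cppn_genome(nodes, conns))
  }
  # chain10: joint score = y, empty score = 0.5 -> a chain along +y
  nodes <- base_nodes
  nodes$bias[nodes$id == 7] <- 0.5
  nodes$bias[nodes$id == 8] <- 1      # rotation 0
  conns <- data.frame(src = 2, dst = 6, weight = 1, enabled = TRUE,
                      innov = .innovation_id(2, 6))
  cppn_genome(nodes, conns)
}
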