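# -- activation functions available to CPPN nodes -----------------------------

.cppn_activations <- list(
  sigmoid = function(x) 1 / (1 + exp(-x)),
  tanh    = function(x) tanh(x),
  gauss   = function(x) exp(-x^2),
  sine    = function(x) sin(x),
  linear  = function(x) x
)

#' Names of the activation functions a CPPN node may use
#' @return character vector
#' @export
cppn_activation_set <- function() names(.cppn_activations)

# Deterministic innovation numbering: the structural gene connecting node `src`
# to node `dst` always receives the same innovation id, in every lineage, via
# Cantor pairing. This keeps crossover alignment reproducible without any
# global mutable registry.
.innovation_id <- function(src, dst) (src + dst) * (src + dst + 1) / 2 + dst

# Hidden node created by splitting connection src->dst gets a deterministic id
# offset well above the fixed input/output ids.
.split_node_id <- function(src, dst) 1000 + .innovation_id(src, dst)

.CPPN_INPUTS  <- 1:4   # x, y, z, tree distance to core
.CPPN_OUTPUTS <- 5:9   # brick, joint, empty, rot0, rot90

#' Construct a CPPN genome from node and connection tables
#'
#' A CPPN (compositional pattern-producing network) is a small feed-forward
#' network queried at the grid coordinates of a candidate body module; its five
#' outputs score the module type (brick, active hinge, empty) and rotation
#' (0 or 90 degrees). Inputs are the module's x, y, z grid coordinates and its
#' tree distance to the core.
#'
#' @param nodes data.frame with columns `id`, `type` ("input"/"output"/"hidden"),
#'   `act` (activation name, see [cppn_activation_set()]), `bias` (numeric).
#' @param conns data.frame with columns `src`, `dst`, `weight`, `enabled`,
#'   `innov`. May have zero rows.
#' @return an object of class `cppn_genome`
#' @export
cppn_genome <- function(nodes, conns) {
  nodes <- as.data.frame(nodes, stringsAsFactors = FALSE)
  conns <- as.data.frame(conns, stringsAsFactors = FALSE)
  if (nrow(conns) == 0) {
    conns <- data.frame(src = integer(), dst = integer(), weight = numeric(),
                        enabled = logical(), innov = numeric())
  }
  g <- structure(list(nodes = nodes, conns = conns), class = "cppn_genome")
  validate_cppn(g)
  g
}

#' Validate a CPPN genome's structural invariants
#'
#' Checks arity (4 inputs, 5 outputs), uniqueness of node and innovation ids,
#' known activation names, and acyclicity of the enabled connection graph.
#'
#' @param g a `cppn_genome`
#' @return `g`, invisibly; stops with an error on violation
#' @export
validate_cppn <- function(g) {
  nodes <- g$nodes
  conns <- g$conns
  if (anyDuplicated(nodes$id)) stop("duplicate node ids in CPPN genome")
  if (sum(nodes$type == "input") != 4L) stop("CPPN must have exactly 4 input nodes")
  if (sum(nodes$type == "output") != 5L) stop("CPPN must have exactly 5 output nodes")
  if (!all(nodes$act %in% names(.cppn_activations)))
    stop("unknown activation function in CPPN genome")
  if (nrow(conns) > 0) {
    if (anyDuplicated(conns$innov)) stop("duplicate innovation ids")
    if (!all(conns$src %in% nodes$id) || !all(conns$dst %in% nodes$id))
      stop("connection endpoint references unknown node")
    if (anyDuplicated(conns[, c("src", "dst")])) stop("duplicate connection")
  }
  if (is.null(.topo_order(g))) stop("enabled connections of CPPN contain a cycle")
  invisible(g)
}

# Kahn topological sort over enabled connections; NULL if cyclic.
.topo_order <- function(g) {
  ids <- g$nodes$id
  cc <- g$conns[g$conns$enabled, , drop = FALSE]
  indeg <- stats::setNames(integer(length(ids)), ids)
  for (d in cc$dst) indeg[as.character(d)] <- indeg[as.character(d)] + 1L
  queue <- ids[indeg[as.character(ids)] == 0L]
  out <- integer(0)
  while (length(queue)) {
    n <- queue[1]; queue <- queue[-1]
    out <- c(out, n)
    outgoing <- cc$dst[cc$src == n]
    for (d in outgoing) {
      key <- as.character(d)
      indeg[key] <- indeg[key] - 1L
      if (indeg[key] == 0L) queue <- c(queue, d)
    }
  }
  if (length(out) != length(ids)) NULL else out
}

#' Create a random minimal CPPN genome
#'
#' Inputs are connected straight to outputs (fully or sparsely, per
#' `init_config`) with independent standard-normal weights; there are no hidden
#' nodes. Deterministic for a fixed RNG state.
#'
#' @param seed optional integer; when given, `set.seed(seed)` is called first
#' @param init_config `"fully-connected"` (default, 4 x 5 = 20 connections) or
#'   `"sparse"` (each output wired to one random input)
#' @param output_act activation used by output nodes (default `"linear"`)
#' @return a `cppn_genome`
#' @export
random_cppn <- function(seed = NULL, init_config = c("fully-connected", "sparse"),
                        output_act = "linear") {
  init_config <- match.arg(init_config)
  if (!is.null(seed)) set.seed(seed)
  nodes <- data.frame(
    id   = c(.CPPN_INPUTS, .CPPN_OUTPUTS),
    type = c(rep("input", 4), rep("output", 5)),
    act  = c(rep("linear", 4), rep(output_act, 5)),
    bias = c(rep(0, 4), stats::rnorm(5)),
    stringsAsFactors = FALSE
  )
  if (init_config == "fully-connected") {
    src <- rep(.CPPN_INPUTS, times = 5)
    dst <- rep(.CPPN_OUTPUTS, each = 4)
  } else {
    dst <- .CPPN_OUTPUTS
    src <- sample(.CPPN_INPUTS, 5, replace = TRUE)
  }
  conns <- data.frame(
    src = src, dst = dst,
    weight = stats::rnorm(length(src)),
    enabled = TRUE,
    innov = .innovation_id(src, dst)
  )
  cppn_genome(nodes, conns)
}

#' Query a CPPN at one grid position
#'
#' Evaluates the network at coordinates (x, y, z) with tree distance `d` to the
#' core and returns the raw output scores. Module-type and rotation decisions
#' are the argmax of these scores; no randomness is involved.
#'
#' @param g a `cppn_genome`
#' @param x,y,z integer grid coordinates of the candidate module
#' @param d integer tree distance from the candidate module to the core
#' @return list with `type` (named numeric: brick, joint, empty) and
#'   `rot` (named numeric: deg0, deg90)
#' @export
query_cppn <- function(g, x, y, z, d) {
  ord <- .topo_order(g)
  if (is.null(ord)) stop("malformed CPPN genome: cyclic")
  vals <- stats::setNames(numeric(nrow(g$nodes)), g$nodes$id)
  inputs <- c(x, y, z, d)
  cc <- g$conns[g$conns$enabled, , drop = FALSE]
  node_act  <- stats::setNames(g$nodes$act, g$nodes$id)
  node_bias <- stats::setNames(g$nodes$bias, g$nodes$id)
  node_type <- stats::setNames(g$nodes$type, g$nodes$id)
  for (n in ord) {
    key <- as.character(n)
    if (node_type[key] == "input") {
      vals[key] <- inputs[match(n, .CPPN_INPUTS)]
    } else {
      inc <- cc[cc$dst == n, , drop = FALSE]
      s <- node_bias[key]
      if (nrow(inc)) s <- s + sum(inc$weight * vals[as.character(inc$src)])
      vals[key] <- .cppn_activations[[node_act[key]]](s)
    }
  }
  out <- vals[as.character(.CPPN_OUTPUTS)]
  list(type = stats::setNames(out[1:3], c("brick", "joint", "empty")),
       rot  = stats::setNames(out[4:5], c("deg0", "deg90")))
}

# argmax with ties broken by the fixed output order (first wins)
.argmax_first <- function(v) which(v == max(v))[1]

#' Mutate a CPPN body genome (NEAT-style)
#'
#' With overall probability `rates$p_mutate` the genome undergoes one round of
#' mutation: every connection weight is perturbed with probability
#' `rates$p_weight` by additive Gaussian noise (sd `rates$weight_sd`), a new
#' connection is added with probability `rates$p_add_conn` (feed-forwardness
#' preserved), and an existing connection is split by a new hidden node with
#' probability `rates$p_add_node`. Innovation ids of new genes are derived
#' deterministically from their endpoints.
#'
#' @param g a `cppn_genome`
#' @param rates list of rates; see [body_mutation_rates()]
#' @return mutated `cppn_genome`
#' @export
mutate_body <- function(g, rates = body_mutation_rates()) {
  if (stats::runif(1) >= rates$p_mutate) return(g)
  conns <- g$conns
  nodes <- g$nodes
  # weight perturbation
  if (nrow(conns) > 0 && rates$p_weight > 0) {
    hit <- stats::runif(nrow(conns)) < rates$p_weight
    conns$weight[hit] <- conns$weight[hit] + stats::rnorm(sum(hit), 0, rates$weight_sd)
  }
  g2 <- structure(list(nodes = nodes, conns = conns), class = "cppn_genome")
  # add connection
  if (stats::runif(1) < rates$p_add_conn) g2 <- .add_connection(g2)
  # add node (split a connection)
  if (stats::runif(1) < rates$p_add_node) g2 <- .add_node(g2)
  validate_cppn(g2)
  g2
}

#' Default mutation rates for the body genome
#'
#' `p_mutate` is the overall per-individual mutation probability (default 0.8);
#' the inner rates control what a mutation round does.
#' @param p_mutate,p_weight,weight_sd,p_add_conn,p_add_node numeric rates
#' @return named list
#' @export
body_mutation_rates <- function(p_mutate = 0.8, p_weight = 0.9, weight_sd = 0.5,
                                p_add_conn = 0.15, p_add_node = 0.1) {
  list(p_mutate = p_mutate, p_weight = p_weight, weight_sd = weight_sd,
       p_add_conn = p_add_conn, p_add_node = p_add_node)
}

# candidate feed-forward connections absent from the genome
.missing_connections <- function(g) {
  ord <- .topo_order(g)
  pos <- match(g$nodes$id, ord)
  names(pos) <- g$nodes$id
  srcs <- g$nodes$id[g$nodes$type != "output"]
  dsts <- g$nodes$id[g$nodes$type != "input"]
  cand <- expand.grid(src = srcs, dst = dsts)
  cand <- cand[cand$src != cand$dst, , drop = FALSE]
  # keep only pairs respecting the current topological order (guarantees
  # acyclicity) and not already present
  cand <- cand[pos[as.character(cand$src)] < pos[as.character(cand$dst)], , drop = FALSE]
  have <- paste(g$conns$src, g$conns$dst)
  cand[!(paste(cand$src, cand$dst) %in% have), , drop = FALSE]
}

.add_connection <- function(g) {
  cand <- .missing_connections(g)
  if (nrow(cand) == 0) return(g)  # saturated: genome unchanged
  pick <- cand[sample.int(nrow(cand), 1), ]
  newc <- data.frame(src = pick$src, dst = pick$dst,
                     weight = stats::rnorm(1), enabled = TRUE,
                     innov = .innovation_id(pick$src, pick$dst))
  if (newc$innov %in% g$conns$innov) return(g)
  g$conns <- rbind(g$conns, newc)
  g
}

.add_node <- function(g) {
  en <- which(g$conns$enabled)
  if (!length(en)) return(g)
  idx <- en[sample.int(length(en), 1)]
  src <- g$conns$src[idx]; dst <- g$conns$dst[idx]
  nid <- .split_node_id(src, dst)
  if (nid %in% g$nodes$id) return(g)  # this connection was split before
  g$conns$enabled[idx] <- FALSE
  act <- sample(names(.cppn_activations), 1)
  g$nodes <- rbind(g$nodes, data.frame(id = nid, type = "hidden", act = act,
                                       bias = 0, stringsAsFactors = FALSE))
  add <- data.frame(src = c(src, nid), dst = c(nid, dst),
                    weight = c(1, g$conns$weight[idx]), enabled = TRUE,
                    innov = .innovation_id(c(src, nid), c(nid, dst)))
  add <- add[!(add$innov %in% g$conns$innov), , drop = FALSE]
  g$conns <- rbind(g$conns, add)
  g
}

#' Recombine two CPPN body genomes (NEAT-style crossover)
#'
#' With probability `p_cross` the parents' connection genes are aligned on
#' innovation ids: matching genes are taken from either parent with equal
#' probability, disjoint and excess genes from the fitter parent. Otherwise the
#' child is a clone of the fitter parent. Ties in fitness favour `g1`.
#'
#' @param g1,g2 parent `cppn_genome`s
#' @param f1,f2 parental fitness values used to pick the gene donor
#' @param p_cross probability of performing crossover (default 0.8)
#' @return child `cppn_genome`
#' @export
crossover_body <- function(g1, g2, f1 = 0, f2 = 0, p_cross = 0.8) {
  fitter <- if (f2 > f1) g2 else g1
  if (stats::runif(1) >= p_cross) return(fitter)
  other <- if (f2 > f1) g1 else g2
  fi <- fitter$conns$innov
  oi <- other$conns$innov
  child_conns <- fitter$conns
  common <- intersect(fi, oi)
  if (length(common)) {
    take_other <- common[stats::runif(length(common)) < 0.5]
    if (length(take_other)) {
      rows_f <- match(take_other, fi)
      rows_o <- match(take_other, oi)
      child_conns[rows_f, c("weight", "enabled")] <-
        other$conns[rows_o, c("weight", "enabled")]
    }
  }
  # node set: fitter parent's nodes already cover all referenced nodes
  g <- structure(list(nodes = fitter$nodes, conns = child_conns),
                 class = "cppn_genome")
  validate_cppn(g)
  g
}

#' @export
print.cppn_genome <- function(x, ...) {
  cat(sprintf("<cppn_genome: %d nodes (%d hidden), %d connections (%d enabled)>\n",
              nrow(x$nodes), sum(x$nodes$type == "hidden"),
              nrow(x$conns), sum(x$conns$enabled)))
  invisible(x)
}

#' Serialize / deserialize a CPPN genome as JSON
#' @param g a `cppn_genome`
#' @return `cppn_to_json`: a JSON string; `cppn_from_json`: a `cppn_genome`
#' @export
cppn_to_json <- function(g) {
  jsonlite::toJSON(list(nodes = g$nodes, conns = g$conns), digits = I(17))
}

#' @rdname cppn_to_json
#' @param json JSON string produced by [cppn_to_json()]
#' @export
cppn_from_json <- function(json) {
  obj <- jsonlite::fromJSON(json)
  cppn_genome(obj$nodes, obj$conns)
}
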