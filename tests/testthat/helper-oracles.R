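# Independent oracles and hand-built fixtures used across the suite.

# --- naive recursive forest edit distance (independent of the package's
# Zhang-Shasha implementation): operates on forests of morph_tree-like nodes,
# memoised on serialized forest keys. Exponential but fine for <= 7 nodes.
naive_ted <- function(t1, t2) {
  memo <- new.env(parent = emptyenv())
  ser <- function(f) paste(vapply(f, function(n)
    paste0(n$label, "(", ser(n$children), ")"), character(1)), collapse = ",")
  fsize <- function(f) sum(vapply(f, function(n) 1L + fsize(n$children), integer(1)))
  fd <- function(f1, f2) {
    if (length(f1) == 0) return(fsize(f2))
    if (length(f2) == 0) return(fsize(f1))
    key <- paste(ser(f1), "|", ser(f2))
    if (!is.null(memo[[key]])) return(memo[[key]])
    # rightmost trees
    t1 <- f1[[length(f1)]]; r1 <- f1[-length(f1)]
    t2 <- f2[[length(f2)]]; r2 <- f2[-length(f2)]
    del <- fd(c(r1, t1$children), f2) + 1
    ins <- fd(f1, c(r2, t2$children)) + 1
    rel <- fd(r1, r2) + fd(t1$children, t2$children) +
      (if (t1$label == t2$label) 0 else 1)
    res <- min(del, ins, rel)
    memo[[key]] <- res
    res
  }
  fd(list(t1), list(t2))
}

# random ordered labelled tree with n nodes (labels from a small alphabet)
random_tree <- function(n, labels = c("a", "b", "c")) {
  make <- function(size) {
    lab <- sample(labels, 1)
    if (size == 1) return(list(label = lab, children = list()))
    left <- size - 1
    kids <- list()
    while (left > 0) {
      k <- sample.int(left, 1)
      kids <- c(kids, list(make(k)))
      left <- left - k
    }
    list(label = lab, children = kids)
  }
  make(n)
}

# hand-built body: core plus a single hinge in front
single_hinge_body <- function() {
  m <- data.frame(
    id = 1:2, kind = c("core", "active_hinge"),
    x = c(0L, 0L), y = c(0L, 1L), z = c(0L, 0L), rotation = 0L,
    parent = c(NA_integer_, 1L), socket = c(NA_integer_, 1L),
    depth = c(0L, 1L), stringsAsFactors = FALSE)
  structure(list(modules = m), class = "robot_body")
}

# hand-built body with two hinges stacked in z at the same 2D cell (0, 1)
stacked_z_body <- function() {
  m <- data.frame(
    id = 1:4,
    kind = c("core", "brick", "active_hinge", "active_hinge"),
    x = c(0L, 0L, 0L, 0L), y = c(0L, 1L, 1L, 1L), z = c(0L, 0L, 1L, -1L),
    rotation = 0L,
    parent = c(NA_integer_, 1L, 2L, 2L), socket = c(NA_integer_, 1L, 1L, 2L),
    depth = c(0L, 1L, 2L, 2L), stringsAsFactors = FALSE)
  structure(list(modules = m), class = "robot_body")
}

# mirror a body about the x = 0 plane (positions only; labels unchanged)
mirror_body_x <- function(b) {
  b$modules$x <- -b$modules$x
  b
}

# straight-segment trajectory through the default two targets over 40 s,
# sampled at 5 Hz with a sample landing exactly on each target
shortest_path_trajectory <- function() {
  seg1 <- cbind(seq(0, 1, length.out = 101), seq(0, -1, length.out = 101))
  seg2 <- cbind(seq(1, 0, length.out = 101), seq(-1, -2, length.out = 101))
  trajectory(rbind(seg1, seg2[-1, ]), duration = 40, sample_hz = 5)
}

# small, fast configuration used by unit tests (not the study conditions)
tiny_cfg <- function(mode = "lamarckian", generations = 2, ...) {
  evo_config(mu = 4, lambda = 2, generations = generations, mode = mode,
             learner = learner_config(K = 4, iterations = 2), ...)
}
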