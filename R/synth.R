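# Seed sub-streams: topology and attributes are drawn under different
# derived seeds, so changing attribute noise never perturbs the topology
# of the same model.
split_seed <- function(seed, stream) {
  (as.integer(seed) + 999983L * stream) %% .Machine$integer.max
}

#' Seeded Erdős–Rényi random graph
#'
#' Every unordered vertex pair is an edge independently with probability
#' `density`.  Identical seeds yield identical graphs.
#'
#' @param n vertex count.
#' @param density edge probability in `[0, 1]`.
#' @param seed integer seed.
#' @return A [cis_graph()] with labels `"1" .. "n"`.
#' @export
er_graph <- function(n, density, seed) {
  n <- as.integer(n)
  if (!is.finite(density) || density < 0 || density > 1)
    stop("density must be in [0, 1]")
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  edges <- withr::with_seed(as.integer(seed), {
    pairs[stats::runif(nrow(pairs)) < density, , drop = FALSE]
  })
  cis_graph(matrix(as.character(edges[, c(1, 2)]), ncol = 2),
            vertices = as.character(seq_len(n)))
}

#' Standard graph families
#'
#' Deterministic constructors matching [closed_form_count()]: `"path"` and
#' `"cycle"` on `size` vertices, `"complete"` on `size` vertices, `"star"`
#' with a center plus `size` leaves.
#'
#' @inheritParams closed_form_count
#' @return A [cis_graph()].
#' @export
family_graph <- function(family = c("path", "complete", "star", "cycle"),
                         size) {
  family <- match.arg(family)
  size <- as.integer(size)
  if (is.na(size) || size < 1) stop("size must be a positive integer")
  if (family == "cycle" && size < 3) stop("a cycle needs at least 3 vertices")
  edges <- switch(family,
    path = if (size == 1) NULL else cbind(seq_len(size - 1), seq_len(size - 1) + 1),
    complete = if (size == 1) NULL else t(utils::combn(size, 2)),
    star = cbind(1L, seq_len(size) + 1L),
    cycle = rbind(cbind(seq_len(size - 1), seq_len(size - 1) + 1), c(size, 1L)))
  if (is.null(edges))
    return(cis_graph(matrix(character(), ncol = 2), vertices = "1"))
  cis_graph(matrix(as.character(edges), ncol = 2))
}

#' Planted-module model for attributed graphs
#'
#' Parameters of the synthetic generator: an Erdős–Rényi background of
#' `n` vertices at the given edge `density`, `d` binary attribute
#' dimensions whose bits are 1 with probability `background_rate`, and a
#' list of planted modules.  Each module is a random connected vertex set
#' of the requested size whose members all carry the same randomly chosen
#' `shared` attribute dimensions, so it is cohesive at
#' `s_min = shared` by construction.
#'
#' @param n vertex count.
#' @param density background edge probability.
#' @param d attribute dimension count.
#' @param modules list of `c(size, shared)` pairs.
#' @param background_rate probability a background bit is 1.
#' @param seed integer seed.
#' @return A list of class `planted_model`.
#' @export
planted_model <- function(n, density, d, modules = list(),
                          background_rate = 0.1, seed = 1) {
  n <- as.integer(n)
  d <- as.integer(d)
  if (!is.finite(density) || density < 0 || density > 1)
    stop("density must be in [0, 1]")
  if (!is.finite(background_rate) || background_rate < 0 ||
      background_rate > 1)
    stop("background_rate must be in [0, 1]")
  if (d < 1) stop("d must be >= 1")
  modules <- lapply(modules, function(m) {
    m <- as.integer(m)
    if (length(m) != 2) stop("each module is a (size, shared) pair")
    if (m[[2]] > d) stop("module shared-feature count exceeds d")
    if (m[[1]] > n) stop("module size exceeds n")
    if (m[[1]] < 1 || m[[2]] < 0) stop("invalid module")
    m
  })
  if (sum(vapply(modules, `[[`, integer(1), 1)) > n)
    stop("modules need more vertices than the graph has")
  structure(list(n = n, density = density, d = d, modules = modules,
                 background_rate = background_rate,
                 seed = as.integer(seed)),
            class = "planted_model")
}

#' Generate an attributed graph with planted cohesive modules
#'
#' Topology: Erdős–Rényi background plus, per module, a uniform random
#' spanning tree over the (disjointly sampled) module members, so every
#' module induces a connected subgraph.  Attributes: i.i.d. background
#' bits at `background_rate`, overwritten with 1 on each module's shared
#' dimensions.  The same model yields byte-identical output.
#'
#' @param model a [planted_model()].
#' @return A list of class `planted_graph`: `agraph` (a
#'   [cis_attributed_graph()]), `modules` (integer id vectors) and
#'   `module_dims` (the shared dimension indices per module).
#' @export
planted_attributed_graph <- function(model) {
  stopifnot(inherits(model, "planted_model"))
  n <- model$n
  sizes <- vapply(model$modules, `[[`, integer(1), 1)

  topo <- withr::with_seed(split_seed(model$seed, 1L), {
    pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    edges <- pairs[stats::runif(nrow(pairs)) < model$density, , drop = FALSE]
    pool <- sample.int(n)
    members <- list()
    for (s in sizes) {
      members[[length(members) + 1]] <- sort(pool[seq_len(s)])
      pool <- pool[-seq_len(s)]
    }
    for (mem in members) {
      if (length(mem) > 1) {
        ord <- sample(mem)
        for (i in 2:length(ord)) {
          j <- ord[[sample.int(i - 1, 1)]]
          edges <- rbind(edges, c(ord[[i]], j))
        }
      }
    }
    list(edges = edges, members = members)
  })

  attrs <- withr::with_seed(split_seed(model$seed, 2L), {
    feat <- matrix(stats::rbinom(n * model$d, 1, model$background_rate),
                   n, model$d)
    dims <- list()
    # modules draw disjoint shared dimensions while the budget lasts, so
    # two modules cannot merge into one cohesive superset through their
    # planted dimensions alone
    avail <- seq_len(model$d)
    for (k in seq_along(model$modules)) {
      shared <- model$modules[[k]][[2]]
      dsel <- if (length(avail) >= shared) {
        picked <- avail[sample.int(length(avail), shared)]
        avail <- setdiff(avail, picked)
        sort(picked)
      } else {
        sort(sample.int(model$d, shared))
      }
      dims[[k]] <- dsel
      feat[topo$members[[k]], dsel] <- 1L
    }
    list(feat = feat, dims = dims)
  })

  # spanning-tree edges may repeat background edges; dedupe quietly
  lo <- pmin(topo$edges[, 1], topo$edges[, 2])
  hi <- pmax(topo$edges[, 1], topo$edges[, 2])
  keep <- !duplicated(lo * (n + 1) + hi)
  g <- cis_graph(cbind(as.character(lo[keep]), as.character(hi[keep])),
                 vertices = as.character(seq_len(n)))
  feat <- attrs$feat
  colnames(feat) <- as.character(seq_len(model$d))
  rownames(feat) <- as.character(seq_len(n))
  ag <- cis_attributed_graph(g, feat)
  relabel <- function(v) sort(match(as.character(v), g$labels))
  structure(list(agraph = ag,
                 modules = lapply(topo$members, relabel),
                 module_dims = attrs$dims,
                 model = model),
            class = "planted_graph")
}
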