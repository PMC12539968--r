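# Multilayer PageRank versatility: a random walker moves within monthly
# layers along (possibly directed) edge weights and across layers between
# replicas of the same node; its stationary mass, summed over a node's layer
# replicas and normalized over alters, measures the ego's proportional
# investment in each partner (quality) and whether a tie exists at all
# (connectivity).

#' Build the supra-transition matrix of a multilayer ego network
#'
#' Rows and columns index (node, layer) pairs. Within-layer moves are
#' proportional to edge weights out of each node replica (following edge
#' direction for directed behaviours; undirected edges contribute both
#' ways). Between-layer moves connect replicas of the same node with weight
#' `interlayer_weight`; `coupling = "categorical"` couples every pair of
#' layers (the common default for multiplex PageRank), `"ordinal"` couples
#' consecutive layers only, respecting the temporal ordering. Rows with no
#' outgoing mass redistribute uniformly over all pairs. Teleportation mixes
#' the walk with the uniform distribution at rate `1 - damping`.
#'
#' @param multinet a `multilayer_ego_network`.
#' @param damping restart/teleportation parameter in (0,1), default 0.85.
#' @param interlayer_weight nonnegative coupling strength, default 1.
#' @param coupling `"categorical"` (all layer pairs) or `"ordinal"`
#'   (consecutive layers).
#' @return object of class `supra_transition` with fields `node_layer_index`
#'   (data.frame `node`, `layer`), `transition` (row-stochastic matrix),
#'   `damping`, `interlayer_weight`.
#' @export
build_supra_transition <- function(multinet, damping = 0.85,
                                   interlayer_weight = 1,
                                   coupling = c("categorical", "ordinal")) {
  coupling <- match.arg(coupling)
  if (!is.numeric(damping) || damping <= 0 || damping >= 1) {
    stop("damping must be in (0, 1)", call. = FALSE)
  }
  stopifnot(interlayer_weight >= 0, length(multinet$layers) >= 1)
  nodes <- multinet$node_set
  n <- length(nodes)
  L <- length(multinet$layers)
  NL <- n * L
  ego <- multinet$ego_id

  # weighted supra-adjacency (rows = from, cols = to)
  W <- matrix(0, NL, NL)
  idx <- function(node_i, layer_l) (layer_l - 1L) * n + node_i
  ego_i <- match(ego, nodes)
  for (l in seq_len(L)) {
    ed <- multinet$layers[[l]]$edges
    if (nrow(ed)) {
      ai <- match(ed$alter_id, nodes)
      for (k in seq_len(nrow(ed))) {
        w <- ed$weight[k]
        if (ed$direction[k] == "given") {
          W[idx(ego_i, l), idx(ai[k], l)] <- W[idx(ego_i, l), idx(ai[k], l)] + w
        } else if (ed$direction[k] == "received") {
          W[idx(ai[k], l), idx(ego_i, l)] <- W[idx(ai[k], l), idx(ego_i, l)] + w
        } else { # undirected: both directions
          W[idx(ego_i, l), idx(ai[k], l)] <- W[idx(ego_i, l), idx(ai[k], l)] + w
          W[idx(ai[k], l), idx(ego_i, l)] <- W[idx(ai[k], l), idx(ego_i, l)] + w
        }
      }
    }
  }
  if (L > 1 && interlayer_weight > 0) {
    for (i in seq_len(n)) {
      for (l1 in seq_len(L)) {
        targets <- if (coupling == "categorical") setdiff(seq_len(L), l1)
                   else intersect(c(l1 - 1L, l1 + 1L), seq_len(L))
        for (l2 in targets) {
          W[idx(i, l1), idx(i, l2)] <- W[idx(i, l1), idx(i, l2)] +
            interlayer_weight
        }
      }
    }
  }

  rs <- rowSums(W)
  P <- matrix(1 / NL, NL, NL)           # dangling rows: uniform
  nz <- rs > 0
  P[nz, ] <- W[nz, , drop = FALSE] / rs[nz]
  Tm <- damping * P + (1 - damping) / NL

  structure(list(
    node_layer_index = data.frame(node = rep(nodes, L),
                                  layer = rep(seq_len(L), each = n)),
    transition = Tm, damping = damping,
    interlayer_weight = interlayer_weight),
    class = "supra_transition")
}

#' Stationary distribution of a supra-transition matrix
#'
#' Power iteration `v <- v T` from the uniform vector until the L1 residual
#' drops below `tol`.
#'
#' @param supra a `supra_transition`.
#' @param tol L1 convergence tolerance (default 1e-10).
#' @param max_iter iteration cap (default 10000).
#' @return nonnegative probability vector over (node, layer) pairs.
#' @export
pagerank_stationary <- function(supra, tol = 1e-10, max_iter = 10000) {
  Tm <- supra$transition
  NL <- nrow(Tm)
  v <- rep(1 / NL, NL)
  for (i in seq_len(max_iter)) {
    v_new <- as.vector(v %*% Tm)
    v_new <- v_new / sum(v_new)
    res <- sum(abs(v_new - v))
    v <- v_new
    if (res < tol) return(v)
  }
  stop(sprintf("power iteration did not converge in %d iterations (final L1 residual %.3g)",
               max_iter, res), call. = FALSE)
}

#' Versatility per node
#'
#' Sums stationary mass over each node's layer replicas.
#' @param stationary probability vector from [pagerank_stationary()].
#' @param node_layer_index data.frame with a `node` column, aligned with
#'   `stationary`.
#' @return named numeric vector (sums to 1).
#' @export
node_versatility <- function(stationary, node_layer_index) {
  tapply(stationary, node_layer_index$node, sum)[unique(node_layer_index$node)]
}

#' Normalize versatility to proportional investment
#'
#' Removes the ego's own mass and rescales the alters' versatilities to sum
#' to one, which neutralises differences in degree across egos and in layer
#' counts across partitions. If every alter has zero versatility all values
#' stay zero.
#'
#' @param versatility named vector from [node_versatility()].
#' @param ego_id the ego's id (must be present).
#' @return named vector over alters.
#' @export
normalize_versatility <- function(versatility, ego_id) {
  stopifnot(ego_id %in% names(versatility))
  alters <- versatility[setdiff(names(versatility), ego_id)]
  s <- sum(alters)
  if (length(alters) == 0) return(alters)
  if (s > 0) alters / s else alters * 0
}

#' Normalized versatility of one multilayer ego network
#'
#' @param multinet a `multilayer_ego_network`.
#' @inheritParams build_supra_transition
#' @param tol,max_iter convergence controls for [pagerank_stationary()].
#' @return data.frame rows (`ego_id`, `behaviour`, `partition_index`,
#'   `alter_id`, `versatility`, `zero_populated = FALSE`).
#' @export
multilayer_versatility <- function(multinet, damping = 0.85,
                                   interlayer_weight = 1,
                                   coupling = "categorical",
                                   tol = 1e-10, max_iter = 10000) {
  if (length(multinet$node_set) <= 1) {
    return(data.frame(ego_id = character(), behaviour = character(),
                      partition_index = integer(), alter_id = character(),
                      versatility = numeric(), zero_populated = logical()))
  }
  st <- build_supra_transition(multinet, damping, interlayer_weight, coupling)
  v <- pagerank_stationary(st, tol, max_iter)
  nv <- node_versatility(v, st$node_layer_index)
  av <- normalize_versatility(nv, multinet$ego_id)
  data.frame(ego_id = multinet$ego_id, behaviour = multinet$behaviour,
             partition_index = multinet$partition_index,
             alter_id = names(av), versatility = as.numeric(av),
             zero_populated = FALSE, row.names = NULL)
}

#' Versatility table over many multilayer networks
#'
#' @param multinets list of `multilayer_ego_network`.
#' @inheritParams multilayer_versatility
#' @return data.frame stacking [multilayer_versatility()] rows.
#' @export
versatility_table <- function(multinets, damping = 0.85,
                              interlayer_weight = 1,
                              coupling = "categorical",
                              tol = 1e-10, max_iter = 10000) {
  out <- do.call(rbind, lapply(multinets, multilayer_versatility,
                               damping = damping,
                               interlayer_weight = interlayer_weight,
                               coupling = coupling, tol = tol,
                               max_iter = max_iter))
  if (is.null(out)) {
    out <- data.frame(ego_id = character(), behaviour = character(),
                      partition_index = integer(), alter_id = character(),
                      versatility = numeric(), zero_populated = logical())
  }
  out
}

#' Zero-populate feasible but unobserved dyads
#'
#' Every (ego, alter) pair realised in any behaviour or partition gains
#' explicit zero-versatility rows in all behaviours and partitions where it
#' is absent -- all animals share one enclosure, so absence of a tie is
#' informative (putative connectivity) rather than missing data. Partitions
#' entirely before the alter's birth or after its removal are excluded, as
#' are partitions in which the ego itself was never observed. Existing rows
#' are never modified, so the operation is idempotent.
#'
#' @param table versatility table ([versatility_table()]).
#' @param demography validated demography.
#' @param scheme the `partition_scheme` used to build the networks.
#' @return the augmented table with `zero_populated = TRUE` on added rows.
#' @export
zero_populate <- function(table, demography, scheme) {
  if (!nrow(table)) return(table)
  out <- list(table)
  dem_i <- function(id) match(id, demography$animal_id)
  for (ego in unique(table$ego_id)) {
    te <- table[table$ego_id == ego, , drop = FALSE]
    ego_birth <- demography$birth_date[dem_i(ego)]
    observed_parts <- sort(unique(te$partition_index))
    alters <- unique(te$alter_id)
    a_idx <- dem_i(alters)
    a_birth <- demography$birth_date[a_idx]
    a_removal <- demography$removal_date[a_idx]
    have <- paste(te$behaviour, te$partition_index, te$alter_id)
    add <- list()
    for (p in observed_parts) {
      win <- partition_window(scheme, p, ego_birth)
      feasible <- a_birth <= win[2] &
        (is.na(a_removal) | a_removal >= win[1])
      for (b in BEHAVIOURS) {
        miss <- alters[feasible &
                         !(paste(b, p, alters) %in% have)]
        if (length(miss)) {
          add[[length(add) + 1L]] <- data.frame(
            ego_id = ego, behaviour = b, partition_index = p,
            alter_id = miss, versatility = 0, zero_populated = TRUE)
        }
      }
    }
    if (length(add)) out[[length(out) + 1L]] <- do.call(rbind, add)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
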