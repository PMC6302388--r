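# Core-attachment complex detection: maximal cliques as candidate cores,
# density-ranked greedy pruning into disjoint seed cores, then attachment of
# neighboring proteins by correlation score.

#' Detection configuration
#'
#' @param theta attachment threshold (default 0.3): a neighbor joins a core
#'   when its mean edge weight to the core exceeds this value (strict `>`).
#' @param min_clique_size minimum core size (default 3).
#' @param clamp_weights floor negative edge weights at 0 when building the
#'   weighted adjacency upstream (recorded here for pipeline use).
#' @return An object of class `detection_config`.
#' @export
detection_config <- function(theta = 0.3, min_clique_size = 3L,
                             clamp_weights = FALSE) {
  stopifnot(theta >= 0, theta <= 1, min_clique_size >= 1L)
  structure(list(theta = theta, min_clique_size = as.integer(min_clique_size),
                 clamp_weights = isTRUE(clamp_weights)),
            class = "detection_config")
}

# Canonical key for a member set; used for dedup and tie-breaking.
.clique_key <- function(members) paste(members, collapse = " ")

#' Enumerate maximal cliques
#'
#' All maximal cliques of the network with at least `min_size` members,
#' via pivoting Bron-Kerbosch. Output is normalized: member lists sorted,
#' cliques ordered lexicographically by member list.
#'
#' @param net a [ppi_network].
#' @param min_size minimum clique size (default 3).
#' @return List of character vectors (sorted member IDs).
#' @export
enumerate_maximal_cliques <- function(net, min_size = 3L) {
  stopifnot(inherits(net, "ppi_network"), min_size >= 1L)
  if (length(net$proteins) == 0L) return(list())
  g <- as_igraph(net)
  cl <- igraph::max_cliques(g, min = min_size)
  cl <- lapply(cl, function(v) sort(names(v), method = "radix"))
  keys <- vapply(cl, .clique_key, character(1L))
  cl[order(keys, method = "radix")]
}

#' Density score of a candidate core
#'
#' Sum of embedding-derived edge weights over the unordered distinct member
#' pairs of a clique; captures both internal connectivity and biological
#' (attribute) coherence, since weights are embedding cosines.
#'
#' @param clique character vector of member IDs.
#' @param W weighted adjacency from [build_weighted_adjacency()].
#' @return The scalar density score.
#' @export
density_score <- function(clique, W) {
  sum(W[clique, clique, drop = FALSE]) / 2
}

#' Greedy seed-core selection
#'
#' Iteratively: sort the remaining candidate cliques by density score
#' (descending; ties broken by larger size, then lexicographically smallest
#' member list), promote the top clique to a seed core, subtract its members
#' from every overlapping candidate, drop candidates that fall below
#' `min_size`, collapse duplicates, and repeat until no candidates remain.
#' Subtraction preserves clique-ness (an induced subset of a clique is a
#' clique), and scores are recomputed after every update, so ranking always
#' reflects the current candidate sets. The returned seed cores are pairwise
#' disjoint.
#'
#' @param cliques candidate cliques from [enumerate_maximal_cliques()].
#' @param W weighted adjacency.
#' @param min_size minimum surviving candidate size (default 3).
#' @return List of seed cores (character vectors), in order of promotion.
#' @export
select_seed_cores <- function(cliques, W, min_size = 3L) {
  cands <- cliques[!duplicated(vapply(cliques, .clique_key, character(1L)))]
  seeds <- list()
  while (length(cands) > 0L) {
    scores <- vapply(cands, density_score, numeric(1L), W = W)
    sizes <- lengths(cands)
    keys <- vapply(cands, .clique_key, character(1L))
    ord <- order(-scores, -sizes, keys, method = "radix")
    top <- cands[[ord[1L]]]
    seeds[[length(seeds) + 1L]] <- top
    rest <- cands[ord[-1L]]
    rest <- lapply(rest, setdiff, y = top)
    rest <- rest[lengths(rest) >= min_size]
    cands <- rest[!duplicated(vapply(rest, .clique_key, character(1L)))]
  }
  seeds
}

#' Correlation score of a candidate attachment
#'
#' Mean edge weight from protein `p` to the members of a seed core:
#' \deqn{\mathrm{corr}(p, C) = \frac{\sum_{k \in C} w_{pk}}{|C|},}
#' with \eqn{w_{pk} = 0} for non-edges.
#'
#' @param protein candidate attachment ID (must not belong to the core).
#' @param clique the seed core, a character vector of member IDs.
#' @param W weighted adjacency.
#' @return The scalar correlation score.
#' @export
correlation_score <- function(protein, clique, W) {
  if (protein %in% clique) stop("protein is already a member of the core")
  sum(W[protein, clique]) / length(clique)
}

#' Attach proteins to seed cores and assemble complexes
#'
#' For each seed core, the candidate attachments are the proteins outside
#' the core adjacent (in the unweighted network) to at least one core
#' member; those with correlation score strictly greater than `theta` are
#' attached. Each complex is the union of its core and attachments; a
#' protein may attach to several cores, and exact-duplicate complexes
#' (identical member sets) collapse to the first occurrence.
#'
#' @param seeds list of disjoint seed cores from [select_seed_cores()].
#' @param net the [ppi_network].
#' @param W weighted adjacency.
#' @param theta attachment threshold (strict `>`).
#' @return A [complex_set] with core/attachment annotation and seed-core
#'   density scores.
#' @export
attach_and_assemble <- function(seeds, net, W, theta = 0.3) {
  nb <- neighbor_list(net)
  complexes <- vector("list", length(seeds))
  atts <- vector("list", length(seeds))
  dens <- numeric(length(seeds))
  for (k in seq_along(seeds)) {
    core <- seeds[[k]]
    cand <- setdiff(unique(unlist(nb[core], use.names = FALSE)), core)
    if (length(cand) > 0L) {
      sc <- vapply(cand, correlation_score, numeric(1L),
                   clique = core, W = W)
      att <- cand[sc > theta]
    } else {
      att <- character()
    }
    atts[[k]] <- att
    complexes[[k]] <- c(core, att)
    dens[k] <- density_score(core, W)
  }
  keys <- vapply(lapply(complexes, sort_ids), .clique_key, character(1L))
  keep <- !duplicated(keys)
  complex_set(complexes[keep], cores = seeds[keep],
              attachments = atts[keep], density = dens[keep])
}

#' Detect protein complexes
#'
#' Full detection stage on a weighted network: enumerate maximal cliques of
#' at least `config$min_clique_size` members, prune them into disjoint seed
#' cores by density ranking, and expand each core with attachments scoring
#' above `config$theta`.
#'
#' @param net a [ppi_network].
#' @param W weighted adjacency from [build_weighted_adjacency()].
#' @param config a [detection_config()].
#' @return A [complex_set] of predicted complexes with core/attachment
#'   annotation; empty (with a warning) if the network has no clique of the
#'   minimum size.
#' @export
detect_complexes <- function(net, W, config = detection_config()) {
  stopifnot(inherits(config, "detection_config"))
  cliques <- enumerate_maximal_cliques(net, config$min_clique_size)
  if (length(cliques) == 0L) {
    warning("no maximal clique of the minimum size; no complexes detected")
    return(complex_set(list()))
  }
  seeds <- select_seed_cores(cliques, W, config$min_clique_size)
  attach_and_assemble(seeds, net, W, config$theta)
}
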