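# Synthetic attributed PPI networks with planted core-attachment complexes.
# Each planted complex is a fully connected core plus loosely wired
# attachments; background nodes, Erdos-Renyi edges and spurious annotations
# emulate the noise present in real interaction screens.

#' Specification of a synthetic attributed network
#'
#' Defaults describe a moderately noisy screen: 10 planted complexes with
#' cores of 4-6 proteins and 1-2 attachments each, 30 unrelated background
#' proteins, a 2% background interaction rate, and GO-slim-like annotations
#' in which complex members share 3 coherent terms (each carried with
#' probability 0.8) over a 50-term vocabulary with a 2% spurious annotation
#' rate. Attachments are wired to each core member with probability 0.8,
#' with at least one interaction guaranteed.
#'
#' @param n_complexes number of planted complexes K.
#' @param core_size inclusive range `c(min, max)` of core sizes (min >= 3).
#' @param n_attachments inclusive range of attachments per complex.
#' @param background_nodes number of proteins outside every complex.
#' @param background_p Erdos-Renyi probability of a spurious interaction
#'   between any protein pair.
#' @param attach_p probability an attachment interacts with each individual
#'   core member (one interaction is always forced).
#' @param vocab_size number of GO-slim-like terms in the vocabulary.
#' @param coherent_terms number of coherent terms drawn per complex.
#' @param coherent_p probability a complex member carries each of its
#'   complex's coherent terms.
#' @param background_term_p probability any protein carries any term
#'   spuriously.
#' @param seed RNG seed; fixed seed gives fully reproducible output.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_complexes = 10L, core_size = c(4L, 6L),
                           n_attachments = c(1L, 2L), background_nodes = 30L,
                           background_p = 0.02, attach_p = 0.8,
                           vocab_size = 50L, coherent_terms = 3L,
                           coherent_p = 0.8, background_term_p = 0.02,
                           seed = 1L) {
  stopifnot(n_complexes >= 1L, length(core_size) == 2L, core_size[1L] >= 3L,
            core_size[1L] <= core_size[2L], length(n_attachments) == 2L,
            n_attachments[1L] >= 0L, n_attachments[1L] <= n_attachments[2L],
            background_nodes >= 0L,
            background_p >= 0, background_p <= 1,
            attach_p >= 0, attach_p <= 1,
            vocab_size >= 1L, coherent_terms >= 0L,
            coherent_terms <= vocab_size,
            coherent_p >= 0, coherent_p <= 1,
            background_term_p >= 0, background_term_p <= 1)
  structure(list(n_complexes = as.integer(n_complexes),
                 core_size = as.integer(core_size),
                 n_attachments = as.integer(n_attachments),
                 background_nodes = as.integer(background_nodes),
                 background_p = background_p, attach_p = attach_p,
                 vocab_size = as.integer(vocab_size),
                 coherent_terms = as.integer(coherent_terms),
                 coherent_p = coherent_p,
                 background_term_p = background_term_p,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

# sample() that also works for a single-element range.
.sample_range <- function(range, k) {
  if (range[1L] == range[2L]) rep(range[1L], k)
  else sample(seq(range[1L], range[2L]), k, replace = TRUE)
}

#' Generate a synthetic attributed network
#'
#' Builds a PPI network, a GO-slim-style annotation table and the
#' ground-truth complex set from a [synthetic_spec()]. Cores are pairwise
#' disjoint cliques; attachments are fresh proteins wired to each core
#' member with probability `attach_p` (at least one edge forced);
#' background edges are overlaid Erdos-Renyi over all protein pairs. Each
#' complex draws distinct coherent terms from the vocabulary (falling back
#' to reuse only when the vocabulary is exhausted); members carry each
#' coherent term with probability `coherent_p`, and every protein carries
#' every term spuriously with probability `background_term_p`. The
#' ground-truth complex is the core plus its attachments.
#'
#' @param spec a [synthetic_spec()].
#' @return A list with elements `network` ([ppi_network]), `annotation`
#'   (data frame: protein, term, aspect), `truth` ([complex_set] with
#'   core/attachment split), and `spec`.
#' @export
generate_synthetic <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  old_seed <- snapshot_seed()
  on.exit(restore_seed(old_seed), add = TRUE)
  set.seed(spec$seed)
  K <- spec$n_complexes
  core_sizes <- .sample_range(spec$core_size, K)
  att_counts <- .sample_range(spec$n_attachments, K)
  n <- sum(core_sizes) + sum(att_counts) + spec$background_nodes
  ids <- sprintf("P%04d", seq_len(n))
  next_id <- 1L
  take <- function(k) {
    out <- ids[seq.int(next_id, length.out = k)]
    next_id <<- next_id + k
    out
  }
  cores <- vector("list", K)
  atts <- vector("list", K)
  edges <- list()
  for (k in seq_len(K)) {
    core <- take(core_sizes[k])
    cores[[k]] <- core
    if (length(core) >= 2L) {
      pr <- utils::combn(core, 2L)
      edges[[length(edges) + 1L]] <- t(pr)
    }
    att <- if (att_counts[k] > 0L) take(att_counts[k]) else character()
    atts[[k]] <- att
    for (a in att) {
      wired <- core[stats::runif(length(core)) < spec$attach_p]
      if (length(wired) == 0L) wired <- sample(core, 1L)
      edges[[length(edges) + 1L]] <- cbind(a, wired)
    }
  }
  if (spec$background_nodes > 0L) take(spec$background_nodes)
  if (spec$background_p > 0 && n >= 2L) {
    pr <- utils::combn(ids, 2L)
    hit <- stats::runif(ncol(pr)) < spec$background_p
    if (any(hit)) edges[[length(edges) + 1L]] <- t(pr[, hit, drop = FALSE])
  }
  edges <- if (length(edges) > 0L) do.call(rbind, edges) else NULL
  network <- ppi_network(edges, proteins = ids)

  terms <- sprintf("T%03d", seq_len(spec$vocab_size))
  term_aspect <- sample(c("Bp", "Mf"), spec$vocab_size, replace = TRUE)
  names(term_aspect) <- terms
  pool <- sample(terms)  # shuffled; complexes consume disjoint blocks
  ann_protein <- character()
  ann_term <- character()
  if (spec$coherent_terms > 0L) {
    for (k in seq_len(K)) {
      if (length(pool) >= spec$coherent_terms) {
        coh <- pool[seq_len(spec$coherent_terms)]
        pool <- pool[-seq_len(spec$coherent_terms)]
      } else {
        coh <- sample(terms, spec$coherent_terms)
      }
      members <- c(cores[[k]], atts[[k]])
      for (tm in coh) {
        carry <- members[stats::runif(length(members)) < spec$coherent_p]
        ann_protein <- c(ann_protein, carry)
        ann_term <- c(ann_term, rep(tm, length(carry)))
      }
    }
  }
  if (spec$background_term_p > 0) {
    hit <- which(stats::runif(n * spec$vocab_size) < spec$background_term_p)
    if (length(hit) > 0L) {
      ann_protein <- c(ann_protein, ids[((hit - 1L) %% n) + 1L])
      ann_term <- c(ann_term, terms[((hit - 1L) %/% n) + 1L])
    }
  }
  annotation <- data.frame(protein = ann_protein, term = ann_term,
                           aspect = unname(term_aspect[ann_term]),
                           stringsAsFactors = FALSE)
  annotation <- annotation[!duplicated(paste(annotation$protein,
                                             annotation$term, sep = "\t")), ,
                           drop = FALSE]
  rownames(annotation) <- NULL
  truth <- complex_set(mapply(c, cores, atts, SIMPLIFY = FALSE),
                       cores = cores, attachments = atts)
  list(network = network, annotation = annotation, truth = truth,
       spec = spec)
}

#' Write a synthetic instance to disk
#'
#' Writes the three input files the pipeline consumes: `<prefix>_edges.tsv`
#' (edge list), `<prefix>_go_slim.tsv` (go_slim_mapping dialect: protein,
#' gene, ID, aspect letter, term, term ID, feature type) and
#' `<prefix>_truth.txt` (annotated complex dialect).
#'
#' @param sim output of [generate_synthetic()].
#' @param prefix output path prefix.
#' @return Character vector of the three paths, invisibly.
#' @export
write_synthetic <- function(sim, prefix) {
  edge_path <- paste0(prefix, "_edges.tsv")
  go_path <- paste0(prefix, "_go_slim.tsv")
  truth_path <- paste0(prefix, "_truth.txt")
  writeLines(paste(sim$network$edges[, 1L], sim$network$edges[, 2L],
                   sep = "\t"), edge_path)
  letter <- c(Bp = "P", Mf = "F", Cc = "C")[sim$annotation$aspect]
  writeLines(paste(sim$annotation$protein, sim$annotation$protein, "SYN",
                   letter, sim$annotation$term, sim$annotation$term, "ORF",
                   sep = "\t"), go_path)
  write_complexes(sim$truth, truth_path)
  invisible(c(edge_path, go_path, truth_path))
}

#' Planted-complex recovery experiment
#'
#' Runs the full pipeline (affinity, embedding, reweighting, detection) on
#' independently generated replicates of a synthetic spec and evaluates
#' each prediction against its ground truth. Replicate r uses generator
#' seed `spec$seed + r - 1` and embedding seed `embed_config$seed + r - 1`.
#'
#' @param spec a [synthetic_spec()].
#' @param embed_config an [embedding_config()].
#' @param detect_config a [detection_config()].
#' @param replicates number of replicates (>= 1).
#' @param omega matching threshold for the evaluation.
#' @return A data frame with one row per replicate and columns `replicate`,
#'   `n_pred`, `precision`, `recall`, `fscore`, `sn`, `ppv`, `acc`,
#'   `composite`.
#' @export
recovery_experiment <- function(spec,
                                embed_config = embedding_config(d = 32L),
                                detect_config = detection_config(),
                                replicates = 5L, omega = 0.25) {
  stopifnot(replicates >= 1L)
  rows <- vector("list", replicates)
  for (r in seq_len(replicates)) {
    sp <- spec
    sp$seed <- spec$seed + r - 1L
    sim <- generate_synthetic(sp)
    ec <- embed_config
    ec$seed <- embed_config$seed + r - 1L
    res <- gane_pipeline(sim$network, sim$annotation, ec, detect_config)
    ev <- evaluate_complexes(res$complexes, sim$truth, omega = omega)
    rows[[r]] <- data.frame(replicate = r, n_pred = ev$n_pred,
                            precision = ev$precision, recall = ev$recall,
                            fscore = ev$fscore, sn = ev$sn, ppv = ev$ppv,
                            acc = ev$acc, composite = ev$composite)
  }
  do.call(rbind, rows)
}
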