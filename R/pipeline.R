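# End-to-end pipeline and parameter sweeps.

#' Run the full detection pipeline
#'
#' Chains the stages: attribute matrix and affinity, joint embedding,
#' cosine-reweighted adjacency, and core-attachment detection.
#'
#' @param network a [ppi_network].
#' @param annotation annotation data frame (protein, term, aspect), already
#'   aspect-filtered (see [read_go_slim()]).
#' @param embed_config an [embedding_config()].
#' @param detect_config a [detection_config()].
#' @return A list with `attributes`, `embedding`, `W` (weighted adjacency)
#'   and `complexes` (a [complex_set]).
#' @export
gane_pipeline <- function(network, annotation,
                          embed_config = embedding_config(),
                          detect_config = detection_config()) {
  attr <- build_affinity(build_attribute_matrix(network, annotation))
  emb <- fit_embedding(network, attr, embed_config)
  W <- build_weighted_adjacency(emb, network,
                                clamp = detect_config$clamp_weights)
  cx <- detect_complexes(network, W, detect_config)
  list(attributes = attr, embedding = emb, W = W, complexes = cx)
}

#' Sweep one pipeline parameter
#'
#' Re-runs the pipeline on fixed data for each value of one parameter and
#' evaluates against a reference, reporting the composite score alongside
#' the individual metrics. Sensible grids are `d` in 32-224 (step 32),
#' `lambda` over decades from 1e-5 to 1e3, and `theta` in 0.1-0.9.
#'
#' @param param one of `"d"`, `"lambda"`, `"theta"`.
#' @param values numeric vector of parameter values.
#' @param network a [ppi_network].
#' @param annotation aspect-filtered annotation data frame.
#' @param reference a [complex_set] to evaluate against.
#' @param embed_config,detect_config baseline configurations; the swept
#'   parameter overrides the corresponding field.
#' @param omega matching threshold for the evaluation.
#' @return A data frame with one row per value: `param`, `value`,
#'   `precision`, `recall`, `fscore`, `sn`, `ppv`, `acc`, `composite`.
#' @export
sweep_parameter <- function(param, values, network, annotation, reference,
                            embed_config = embedding_config(d = 32L),
                            detect_config = detection_config(),
                            omega = 0.25) {
  param <- match.arg(param, c("d", "lambda", "theta"))
  rows <- vector("list", length(values))
  for (k in seq_along(values)) {
    ec <- embed_config
    dc <- detect_config
    if (param == "d") ec$d <- as.integer(values[k])
    if (param == "lambda") ec$lambda <- values[k]
    if (param == "theta") dc$theta <- values[k]
    res <- gane_pipeline(network, annotation, ec, dc)
    ev <- evaluate_complexes(res$complexes, reference, omega = omega)
    rows[[k]] <- data.frame(param = param, value = values[k],
                            precision = ev$precision, recall = ev$recall,
                            fscore = ev$fscore, sn = ev$sn, ppv = ev$ppv,
                            acc = ev$acc, composite = ev$composite)
  }
  do.call(rbind, rows)
}
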