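#' Serialise a generative model to a list / YAML / JSON
#'
#' Captures factors (levels, d counts, learnability), modalities (outcomes,
#' a counts, learnability), transitions, preferences, policies and horizon
#' in plain lists so a model specification round-trips losslessly through
#' YAML or JSON.
#'
#' @param model a [generative_model()].
#' @return a plain list.
#' @export
model_to_list <- function(model) {
  list(
    factors = lapply(model$factors, function(f)
      list(levels = f$levels, d = as.numeric(f$d),
           learnable = is_learnable(f$d))),
    modalities = lapply(model$modalities, function(m)
      list(outcomes = m$outcomes,
           a = lapply(seq_len(ncol(m$a)), function(j) unname(unclass(m$a)[, j])),
           learnable = is_learnable(m$a))),
    transitions = lapply(model$transitions, function(Bs)
      lapply(Bs, function(B)
        lapply(seq_len(ncol(B)), function(j) unname(B[, j])))),
    preferences = lapply(model$preferences, as.numeric),
    policies = lapply(model$policies, as.integer),
    horizon = model$horizon,
    policy_precision = model$policy_precision)
}

#' Rebuild a generative model from its list form
#' @param x a list produced by [model_to_list()] (possibly via YAML/JSON).
#' @return a [generative_model()].
#' @export
model_from_list <- function(x) {
  generative_model(
    factors = lapply(x$factors, function(f)
      list(levels = unlist(f$levels),
           d = dirichlet_counts(unlist(f$d), learnable = isTRUE(f$learnable)))),
    modalities = lapply(x$modalities, function(m)
      list(outcomes = unlist(m$outcomes),
           a = dirichlet_counts(do.call(cbind, lapply(m$a, unlist)),
                                learnable = isTRUE(m$learnable)))),
    transitions = lapply(x$transitions, function(Bs)
      lapply(Bs, function(B) do.call(cbind, lapply(B, unlist)))),
    preferences = lapply(x$preferences, unlist),
    policies = lapply(x$policies, unlist),
    horizon = x$horizon %||% 1L,
    policy_precision = x$policy_precision %||% 1)
}

#' Write / read a model specification file
#'
#' @param model a `gen_model`.
#' @param path `.yaml`/`.yml` or `.json` destination.
#' @return `path` (write) or the rebuilt `gen_model` (read).
#' @export
write_model <- function(model, path) {
  x <- model_to_list(model)
  if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  else yaml::write_yaml(x, path, precision = 15L)
  invisible(path)
}

#' @rdname write_model
#' @param path path to a model file written by [write_model()].
#' @export
read_model <- function(path) {
  x <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = FALSE)
  else yaml::read_yaml(path)
  model_from_list(x)
}

#' Belief trajectory as a data.frame
#'
#' One row per (timestep, joint state) with the posterior probability --
#' the CSV-friendly view of an inference result.
#'
#' @param x a `belief_state`.
#' @param row.names,optional,... ignored (S3 signature).
#' @return data.frame with columns `timestep`, `state`, `probability`.
#' @export
as.data.frame.belief_state <- function(x, row.names = NULL, optional = FALSE, ...) {
  Tn <- ncol(x$s); n <- nrow(x$s)
  data.frame(timestep = rep(seq_len(Tn), each = n),
             state = rep(seq_len(n), times = Tn),
             probability = as.numeric(x$s))
}

#' Policy evaluation as a data.frame
#'
#' @param x a `policy_eval`.
#' @param row.names,optional,... ignored (S3 signature).
#' @return data.frame with one row per scored timestep: `policy`,
#'   `timestep`, `risk`, `ambiguity`, `novelty`, `G` (total).
#' @export
as.data.frame.policy_eval <- function(x, row.names = NULL, optional = FALSE, ...) {
  data.frame(policy = x$policy, timestep = x$timesteps,
             risk = x$risk, ambiguity = x$ambiguity, novelty = x$novelty,
             G = x$G)
}
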