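CONFIG_SCHEMAS <- list(
  exp1 = c("experiment", "seed", "n_agents", "obs_level_trials",
           "state_level_trials", "p_negative", "p_high_arousal", "p_couple",
           "valence_precision", "lock_factor", "arousal_count0", "d_mass",
           "optimism_prior", "a1_precision"),
  exp2 = c("experiment", "seed", "levels", "n_runs", "n_trials", "precisions",
           "sweep", "sweep_runs", "sweep_trials"),
  exp3 = c("experiment", "seed", "levels", "n_seeds", "optimism_level",
           "n_trials", "p_large_win", "p_small_win", "q_optimistic",
           "q_pessimistic", "preferences", "initial_mass", "support_floor",
           "policy_precision", "action_mode")
)

#' Load and validate an experiment configuration file
#'
#' Reads a YAML or JSON configuration, checks it against the schema of the
#' named experiment (`experiment: exp1 | exp2 | exp3`), rejects unknown
#' keys, and fills defaults for everything not specified. A seed is always
#' present in the result (default 1).
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return named list: the validated configuration with defaults applied
#'   and attribute `config_hash`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) abort("config file not found: ", path)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  if (!is.list(raw)) abort("config must parse to a mapping")
  exp_name <- raw$experiment %||% abort("config must name an 'experiment' (exp1/exp2/exp3)")
  schema <- CONFIG_SCHEMAS[[exp_name]]
  if (is.null(schema)) abort("unknown experiment '", exp_name, "'")
  unknown <- setdiff(names(raw), schema)
  if (length(unknown))
    abort("unknown config keys for ", exp_name, ": ", paste(unknown, collapse = ", "))
  counts <- raw[intersect(names(raw), c("n_agents", "obs_level_trials",
                                        "state_level_trials", "n_runs",
                                        "n_trials", "n_seeds"))]
  bad <- names(counts)[vapply(counts, function(x) any(x < 1), logical(1))]
  if (length(bad)) abort("config keys must be >= 1: ", paste(bad, collapse = ", "))
  raw$seed <- as.integer(raw$seed %||% 1L)
  defaults <- switch(exp_name,
    exp1 = unclass(development_config()),
    exp2 = list(levels = seq(0.1, 0.9, by = 0.1), n_runs = 70L, n_trials = 70L,
                precisions = NULL, sweep = TRUE, sweep_runs = 10L,
                sweep_trials = 30L, seed = 1L),
    exp3 = c(list(levels = seq(0.1, 0.9, by = 0.1), n_seeds = 25L),
             unclass(bandit_config())))
  cfg <- utils::modifyList(defaults, raw[setdiff(names(raw), "experiment")])
  cfg$experiment <- exp_name
  attr(cfg, "config_hash") <- config_hash(cfg)
  cfg
}

#' Save an experiment configuration
#'
#' Writes a configuration list as YAML or JSON; [load_config()] of the
#' written file returns an equivalent configuration (round trip).
#'
#' @param config named list as returned by [load_config()].
#' @param path destination (`.yaml`/`.yml` or `.json`).
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  config <- config[!vapply(config, is.null, logical(1))]
  attr(config, "config_hash") <- NULL
  if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  else yaml::write_yaml(config, path)
  invisible(path)
}

# stable short hash of a configuration (order-independent)
config_hash <- function(config) {
  config <- config[order(names(config))]
  rlang::hash(lapply(config, unname))
}

#' Write a result table with a reproducibility header
#'
#' Serialises a data.frame (or a `bandit_trajectory`'s trial table) to CSV
#' or JSON. CSV output carries comment-prefixed metadata lines (seed,
#' package version, config hash) followed by the table with a fixed column
#' order and numerics rounded to 10 significant digits, so identical
#' results produce byte-identical files.
#'
#' @param x data.frame or `bandit_trajectory`.
#' @param path output path.
#' @param format `"csv"` (default) or `"json"`.
#' @param seed the master seed used to produce `x` (recorded in the
#'   header).
#' @param config optional configuration list; its hash is recorded.
#' @return `path`, invisibly.
#' @export
write_results <- function(x, path, format = c("csv", "json"), seed = NA,
                          config = NULL) {
  format <- match.arg(format)
  if (inherits(x, "bandit_trajectory")) x <- x$trials
  if (!is.data.frame(x)) abort("write_results expects a data.frame")
  num <- vapply(x, is.numeric, logical(1))
  x[num] <- lapply(x[num], function(v) signif(v, 10))
  meta <- c(seed = as.character(seed),
            version = as.character(utils::packageVersion("optibias")),
            config_hash = if (is.null(config)) "none" else config_hash(config))
  if (format == "csv") {
    con <- file(path, open = "wb")
    on.exit(close(con))
    writeLines(paste0("# ", names(meta), ": ", meta), con)
    utils::write.table(x, con, sep = ",", row.names = FALSE, qmethod = "double",
                       eol = "\n")
  } else {
    jsonlite::write_json(list(meta = as.list(meta), results = x), path,
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' Read a result table written by [write_results()]
#' @param path CSV path.
#' @return data.frame with attribute `meta`.
#' @export
read_results <- function(path) {
  header <- readLines(path, n = 10L)
  meta_lines <- grep("^# ", header, value = TRUE)
  out <- utils::read.csv(path, comment.char = "#")
  attr(out, "meta") <- meta_lines
  out
}

#' Small seeded fixtures for tests and documentation
#'
#' @param name one of `"tiny-model"`, `"exp1-mini"`, `"exp2-mini"`,
#'   `"exp3-mini"`.
#' @param seed seed (default 42).
#' @return a list; `tiny-model` bundles a 2-state model, a one-hot
#'   observation and the closed-form Bayes posterior for it; the `-mini`
#'   fixtures are small configurations plus the data they generate.
#' @export
make_fixture <- function(name, seed = 42L) {
  switch(name,
    "tiny-model" = {
      A <- matrix(c(0.8, 0.2, 0.3, 0.7), 2L, 2L)
      D <- c(0.5, 0.5)
      model <- generative_model(
        factors = list(state = list(levels = c("s1", "s2"), d = D)),
        modalities = list(obs = list(outcomes = c("o1", "o2"),
                                     a = dirichlet_counts(A, learnable = FALSE))))
      o <- c(1, 0)
      bayes <- (D * A[1L, ]) / sum(D * A[1L, ])
      list(model = model, observation = o, bayes_posterior = bayes)
    },
    "exp1-mini" = {
      cfg <- development_config(n_agents = 2L, obs_level_trials = 8L,
                                state_level_trials = 2L, p_negative = 1,
                                seed = seed)
      list(config = cfg, events = generate_environment(cfg),
           expect_optimism_below_prior = TRUE)
    },
    "exp2-mini" = {
      list(levels = c(0.1, 0.5, 0.9), n_runs = 2L, n_trials = 10L,
           precisions = c(0.6, 0.9), seed = seed)
    },
    "exp3-mini" = {
      cfg <- bandit_config(optimism_level = 0.7, n_trials = 5L, seed = seed)
      list(config = cfg, trajectory = run_bandit(cfg))
    },
    abort("unknown fixture name '", name, "'"))
}
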