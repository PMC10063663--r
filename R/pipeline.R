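#' Read a pipeline configuration file
#'
#' JSON and YAML dialects are both accepted (chosen by file extension).
#' Values given in \code{overrides} take precedence over file keys, which
#' take precedence over built-in defaults.
#'
#' @param path config file path (\code{.json}, \code{.yaml} or \code{.yml});
#'   \code{NULL} uses defaults only.
#' @param overrides named list of config keys to override.
#' @return named list of configuration values.
#' @export
read_config <- function(path = NULL, overrides = list()) {
  defaults <- list(
    mode = "exp2",
    out = "simdims_out",
    seed = 1L,
    # simulate
    n_items = 65L, k_true = 4L, sparseness = 0.5,
    n_participants = 53L, subset_size = 30L,
    rating_noise_sd = 0.05, participant_bias_sd = 0,
    # select
    k_cap = Inf, k_range = NULL,
    grid = default_sparsity_grid(), reps = 5L, n_holdout_units = 5L,
    max_iter = 500L, tol = 1e-5,
    # robustness / validation
    selectors = NULL, shuffle_iter = 1000L, sign_iter = 5000L,
    # inputs
    ratings = NULL, features = NULL, embeddings = NULL,
    responses = NULL, trials = NULL, labels = NULL)
  cfg <- defaults
  if (!is.null(path)) {
    if (!file.exists(path)) stop_input("config file not found: ", path)
    ext <- tolower(tools::file_ext(path))
    file_cfg <- switch(ext,
      json = jsonlite::read_json(path, simplifyVector = TRUE),
      yaml = ,
      yml = yaml::read_yaml(path),
      stop_input("config must be .json, .yaml or .yml (got .", ext, ")"))
    unknown <- setdiff(names(file_cfg), names(defaults))
    if (length(unknown))
      stop_input("unknown config key(s): ", paste(unknown, collapse = ", "))
    cfg <- modifyList(cfg, file_cfg)
  }
  if (length(overrides)) cfg <- modifyList(cfg, overrides)
  cfg
}

pipeline_log <- function(dir, msg) {
  line <- paste0(format(Sys.time(), "%Y-%m-%d %H:%M:%S"), " | ", msg)
  cat(line, "\n", sep = "")
  cat(line, "\n", sep = "", file = file.path(dir, "pipeline.log"), append = TRUE)
}

write_manifest <- function(dir, command, cfg) {
  inputs <- Filter(function(p) is.character(p) && length(p) == 1 && file.exists(p),
                   cfg[c("ratings", "features", "embeddings", "responses",
                         "trials", "labels")])
  jsonlite::write_json(
    list(command = command,
         config = cfg[!vapply(cfg, is.null, logical(1))],
         input_checksums = as.list(vapply(inputs, function(p)
           unname(tools::md5sum(p)), character(1))),
         package_version = as.character(utils::packageVersion("simdims")),
         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
    file.path(dir, paste0("manifest_", command, ".json")),
    auto_unbox = TRUE, digits = NA, null = "null", force = TRUE)
}

load_pipeline_dataset <- function(cfg) {
  mode <- if (identical(cfg$mode, "exp1")) "rating_sampled" else "participant_complete"
  if (is.null(cfg$ratings)) stop_input("config key 'ratings' is required")
  read_ratings(cfg$ratings, mode = mode)
}

#' Run a pipeline stage
#'
#' Orchestrates the package's analyses as named commands writing a
#' deterministic artifact layout (plus a manifest and log) under the
#' configured output directory:
#' \describe{
#'   \item{simulate}{plant a model, simulate ratings, write
#'     \code{ratings.csv} and \code{ground_truth/}.}
#'   \item{fit}{fit one sparse NMF to the aggregated ratings; writes a model
#'     directory.}
#'   \item{select}{full nested cross-validated selection; writes
#'     \code{selection_report.json} and \code{curve.tsv}.}
#'   \item{robustness}{category-removal robustness; writes
#'     \code{robustness_report.tsv} (needs a prior \code{select} in the
#'     same output directory).}
#'   \item{validate}{score odd-one-out responses and test them; writes
#'     \code{validation_report.json}.}
#'   \item{report}{aggregate prior stage outputs into \code{report.txt}.}
#' }
#'
#' @param command one of \code{simulate}, \code{fit}, \code{select},
#'   \code{robustness}, \code{validate}, \code{report}.
#' @param config a config list from [read_config()], or a path to a
#'   JSON/YAML config file.
#' @param overrides named list overriding config keys (CLI flags map here).
#' @return invisibly, the stage's primary result object.
#' @export
run_pipeline <- function(command = c("simulate", "fit", "select",
                                     "robustness", "validate", "report"),
                         config = NULL, overrides = list()) {
  command <- match.arg(command)
  cfg <- if (is.list(config)) modifyList(read_config(NULL), config)
         else read_config(config)
  if (length(overrides)) cfg <- modifyList(cfg, overrides)
  # ratings simulated into the same output directory are picked up by later
  # stages without repeating the path in the config
  if (is.null(cfg$ratings) &&
      file.exists(file.path(cfg$out, "ratings.csv")))
    cfg$ratings <- file.path(cfg$out, "ratings.csv")
  dir.create(cfg$out, recursive = TRUE, showWarnings = FALSE)
  pipeline_log(cfg$out, paste("stage", command, "started (seed", cfg$seed, ")"))
  seeds <- derive_seeds(cfg$seed, 4)

  result <- switch(command,
    simulate = {
      model <- make_planted_model(cfg$n_items, cfg$k_true, cfg$sparseness,
                                  seed = seeds[[1]])
      ds <- simulate_dataset(model, cfg$n_participants,
                             mode = if (identical(cfg$mode, "exp1"))
                               "exp1_subsets" else "exp2_complete",
                             subset_size = cfg$subset_size,
                             rating_noise_sd = cfg$rating_noise_sd,
                             participant_bias_sd = cfg$participant_bias_sd,
                             seed = seeds[[2]])
      write_simulation(ds, model, cfg$out)
      cfg$ratings <- file.path(cfg$out, "ratings.csv")
      ds
    },
    fit = {
      ds <- load_pipeline_dataset(cfg)
      V <- fold_matrix(ds)
      k <- if (is.null(cfg$k_range)) cfg$k_true else max(cfg$k_range)
      model <- nmf_fit(V, k, max_iter = cfg$max_iter, tol = cfg$tol)
      model$items <- V$items
      write_nmf_model(model, file.path(cfg$out, "model"))
      model
    },
    select = {
      ds <- load_pipeline_dataset(cfg)
      res <- select_dimensions(ds, k_range = cfg$k_range, grid = cfg$grid,
                               reps = cfg$reps, seed = seeds[[3]],
                               n_holdout_units = cfg$n_holdout_units,
                               k_cap = cfg$k_cap, max_iter = cfg$max_iter,
                               tol = cfg$tol)
      write_selection_report(res, cfg$out)
      write_nmf_model(res$model, file.path(cfg$out, "model"))
      saveRDS(res, file.path(cfg$out, "selection_result.rds"))
      res
    },
    robustness = {
      res_path <- file.path(cfg$out, "selection_result.rds")
      if (!file.exists(res_path))
        stop_input("run the 'select' stage first (missing selection_result.rds)")
      ds <- load_pipeline_dataset(cfg)
      original <- readRDS(res_path)
      selectors <- cfg$selectors
      if (is.null(selectors))
        selectors <- unique(ds$stimuli$categories)[1]
      rb <- run_robustness(ds, original, selectors,
                           n_iter = cfg$shuffle_iter, seed = seeds[[4]],
                           k_range = cfg$k_range, grid = cfg$grid,
                           reps = cfg$reps, k_cap = cfg$k_cap,
                           n_holdout_units = cfg$n_holdout_units)
      write_robustness_report(rb, file.path(cfg$out, "robustness_report.tsv"))
      rb
    },
    validate = {
      if (is.null(cfg$trials) || is.null(cfg$responses))
        stop_input("config keys 'trials' and 'responses' are required")
      trials <- read.csv(cfg$trials, stringsAsFactors = FALSE)
      responses <- read_responses(cfg$responses)
      scores <- score_responses(trials, responses)
      p <- sign_permutation_test(scores$accuracy_matrix,
                                 n_iter = cfg$sign_iter, seed = seeds[[4]])
      out <- list(accuracy_per_dimension = as.list(scores$accuracy_per_dimension),
                  excluded_participants = scores$excluded_participants,
                  p_per_dimension = as.list(p))
      jsonlite::write_json(out, file.path(cfg$out, "validation_report.json"),
                           auto_unbox = TRUE, digits = NA, null = "null")
      out
    },
    report = {
      lines <- c("simdims pipeline report", strrep("=", 23))
      sel <- file.path(cfg$out, "selection_report.json")
      if (file.exists(sel)) {
        s <- jsonlite::read_json(sel, simplifyVector = TRUE)
        lines <- c(lines, "",
                   sprintf("Selected k = %s, s = (%s, %s)", s$k_selected,
                           s$s_selected$s_w, s$s_selected$s_h),
                   sprintf("tau_train = %.3f, tau_holdout = %.3f, tau_true = %.3f",
                           s$tau_train, s$tau_holdout, s$tau_true))
      }
      rob <- file.path(cfg$out, "robustness_report.tsv")
      if (file.exists(rob)) {
        tb <- utils::read.table(rob, sep = "\t", header = TRUE)
        lines <- c(lines, "", "Robustness (removed category: k, mean match r):",
                   vapply(split(tb, tb$removed_category), function(g)
                     sprintf("  %s: k = %d, mean r = %.2f",
                             g$removed_category[1], g$k_new[1],
                             mean(g$match_r, na.rm = TRUE)), character(1)))
      }
      val <- file.path(cfg$out, "validation_report.json")
      if (file.exists(val)) {
        v <- jsonlite::read_json(val, simplifyVector = TRUE)
        lines <- c(lines, "", "Validation p-values (omnibus-corrected):",
                   paste0("  ", names(v$p_per_dimension), ": ",
                          vapply(v$p_per_dimension, function(x)
                            format(x, digits = 3), character(1))))
      }
      writeLines(lines, file.path(cfg$out, "report.txt"))
      lines
    })

  write_manifest(cfg$out, command, cfg)
  pipeline_log(cfg$out, paste("stage", command, "finished"))
  invisible(result)
}
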