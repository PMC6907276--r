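#' Pipeline run configuration
#'
#' Bundles every tunable of the end-to-end reproduction run. All randomness in
#' a run flows from the single `seed`, fanned out deterministically to
#' per-stage child seeds so stages rerun standalone reproduce the same
#' artifacts.
#'
#' @param seed Master integer seed.
#' @param n_records Cohort size (default 2453, the study size).
#' @param cmi_threshold Structure-learning CMI pruning threshold (nats).
#' @param smoothing CPT additive smoothing (default 0: plain ML frequencies).
#' @param alpha Screening significance level.
#' @param minute_value USD per specialist minute in the utility aggregation.
#' @param out_dir Directory for run artifacts.
#' @return A list of class `vdt_run_config`.
#' @export
run_config <- function(seed = 1, n_records = 2453, cmi_threshold = 0.01,
                       smoothing = 0, alpha = 0.05, minute_value = 1,
                       out_dir = tempfile("vdt-run-")) {
  cfg <- structure(list(seed = as.integer(seed), n_records = n_records,
                        cmi_threshold = cmi_threshold, smoothing = smoothing,
                        alpha = alpha, minute_value = minute_value,
                        out_dir = out_dir),
                   class = "vdt_run_config")
  validate_run_config(cfg)
  cfg
}

validate_run_config <- function(cfg) {
  if (cfg$n_records < 1) abort("field `n_records`: must be >= 1")
  if (cfg$cmi_threshold < 0) abort("field `cmi_threshold`: must be >= 0")
  if (cfg$smoothing < 0) abort("field `smoothing`: must be >= 0")
  if (cfg$alpha <= 0 || cfg$alpha >= 1) abort("field `alpha`: must be in (0, 1)")
  if (cfg$minute_value < 0) abort("field `minute_value`: must be >= 0")
  invisible(cfg)
}

#' @rdname run_config
#' @param path JSON file path.
#' @export
write_run_config <- function(cfg, path) {
  validate_run_config(cfg)
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname run_config
#' @param cfg A `vdt_run_config`.
#' @export
read_run_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(run_config, x)
}

# Deterministic per-stage child seed, kept below 2^31.
child_seed <- function(seed, stage) {
  stages <- c(cohort = 1, learn = 2, profile = 3, screen = 4, evaluate = 5)
  (as.integer(seed) %% 1000000L) * 1000L + stages[[stage]] * 7L
}

#' Write an exam-record cohort to CSV
#'
#' @param records Cohort tibble.
#' @param path Output CSV path; header is
#'   `sex,age_ge39,bmi,sleep,activity,smoker,alcohol,disorder`.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(records, path) {
  check_cohort(records)
  cols <- c(names(exam_attribute_states()), "disorder")
  readr::write_csv(records[cols], path)
  invisible(path)
}

#' Read an exam-record cohort from CSV
#'
#' Validates the header and every state token; a malformed value is rejected
#' with its row and column. A header-only file yields an empty cohort.
#'
#' @param path CSV path written by [write_cohort()].
#' @return Cohort tibble.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  cols <- c(names(exam_attribute_states()), "disorder")
  records <- readr::read_csv(path, col_types = readr::cols(
    .default = readr::col_character()))
  attr(records, "spec") <- NULL
  attr(records, "problems") <- NULL
  if (!identical(names(records), cols)) {
    abort(paste0("bad cohort header: expected '", paste(cols, collapse = ","),
                 "' got '", paste(names(records), collapse = ","), "'"))
  }
  states <- c(exam_attribute_states(), list(disorder = disorder_classes()))
  for (col in cols) {
    bad <- which(!records[[col]] %in% states[[col]])
    if (length(bad) > 0) {
      abort(paste0("invalid state token '", records[[col]][bad[[1]]],
                   "' in row ", bad[[1]], ", column '", col, "'"))
    }
  }
  records
}

#' Run the full reproduction pipeline
#'
#' Executes every stage with the configured seed: generates the synthetic
#' cohort, learns the augmented-naive-Bayes structure and fits its CPTs,
#' computes the diagnostic risk-factor profile of every disorder class,
#' screens risk factors against the no-disorder reference, and evaluates the
#' six protocol strategies. Artifacts are written under `cfg$out_dir`
#' (`cohort.csv`, `network.json`, `profile.csv`, `screening.csv`,
#' `strategy_costs.csv`, `summary.log`); identical configs produce identical
#' artifacts.
#'
#' @param cfg A [run_config()].
#' @return Invisibly, a list with the in-memory results (`cohort`, `network`,
#'   `profile`, `screening`, `strategy_report`) and `paths` to the artifacts.
#' @export
run_reproduction <- function(cfg = run_config()) {
  validate_run_config(cfg)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- purrr::map(
    list(cohort = "cohort.csv", network = "network.json",
         profile = "profile.csv", screening = "screening.csv",
         strategy = "strategy_costs.csv", log = "summary.log"),
    ~ file.path(cfg$out_dir, .x))
  log_lines <- character(0)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("stage '", name, "' failed: ", conditionMessage(e)))
    })
  }
  note <- function(...) {
    log_lines <<- c(log_lines, paste0(...))
  }

  spec <- default_population_spec(n_records = cfg$n_records)
  cohort <- stage("generate", generate_cohort(spec, n = cfg$n_records,
                                              seed = child_seed(cfg$seed, "cohort")))
  write_cohort(cohort, paths$cohort)
  note("generate: n=", cfg$n_records, " seed=", child_seed(cfg$seed, "cohort"),
       " -> ", paths$cohort)

  g <- stage("learn", learn_abn_structure(cohort, target = "disorder",
                                          cmi_threshold = cfg$cmi_threshold))
  bn <- stage("fit", fit_mle(g, cohort, smoothing = cfg$smoothing))
  write_network(bn, paths$network)
  note("learn+fit: cmi_threshold=", cfg$cmi_threshold, " smoothing=",
       cfg$smoothing, " arcs=", nrow(g$arcs), " -> ", paths$network)

  present <- intersect(disorder_classes(), unique(cohort$disorder))
  profile <- stage("profile", purrr::map(present, function(cl) {
    mutate(diagnostic_profile(bn, cl), class = cl, .before = 1)
  }) %>% bind_rows())
  readr::write_csv(profile, paths$profile)
  note("profile: classes=", paste(present, collapse = "|"), " -> ",
       paths$profile)

  screen_classes <- setdiff(present, "none")
  screening <- stage("screen", purrr::map(screen_classes, function(cl) {
    screen_risk_factors(cohort, cl, reference_label = "none",
                        alpha = cfg$alpha)
  }) %>% bind_rows())
  readr::write_csv(screening, paths$screening)
  note("screen: alpha=", cfg$alpha, " reference=none -> ", paths$screening)

  report <- stage("evaluate", reduction_report(canonical_tests(),
                                               canonical_strategies(),
                                               reference = "A",
                                               minute_value = cfg$minute_value))
  readr::write_csv(strategy_cost_table(minute_value = cfg$minute_value),
                   paths$strategy)
  note("evaluate: minute_value=", cfg$minute_value, " reference=A -> ",
       paths$strategy)

  writeLines(log_lines, paths$log)
  invisible(list(cohort = cohort, network = bn, profile = profile,
                 screening = screening, strategy_report = report,
                 paths = paths))
}
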