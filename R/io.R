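#' @importFrom utils read.csv write.csv
NULL

#' Read a transect profile table
#'
#' Reads the long CSV schema (`transect_id`, `reef_id`, `distance_m`,
#' `depth_m`) and validates it: missing depths, duplicated
#' `(transect_id, distance_m)` records and non-monotone distances within a
#' transect are rejected, or — with `clean = TRUE` — duplicates and missing
#' values are removed and counted in the attached report.
#'
#' @param path CSV path.
#' @param clean Remove (rather than reject) duplicates and missing values.
#' @return data.frame of profiles with attribute `clean_report`
#'   (list: n_duplicates, n_missing).
#' @export
read_profiles <- function(path, clean = FALSE) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  req <- c("transect_id", "reef_id", "distance_m", "depth_m")
  miss <- setdiff(req, names(df))
  if (length(miss) > 0) {
    stop("profile file ", path, " missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  dup <- duplicated(df[, c("transect_id", "distance_m")])
  na_row <- is.na(df$depth_m) | is.na(df$distance_m)
  report <- list(n_duplicates = sum(dup), n_missing = sum(na_row))
  if (any(dup) || any(na_row)) {
    if (!clean) {
      stop("profile file ", path, " has ", sum(dup), " duplicated and ",
           sum(na_row), " missing records; re-read with clean = TRUE ",
           "to remove them", call. = FALSE)
    }
    df <- df[!dup & !na_row, , drop = FALSE]
  }
  mono <- vapply(split(df$distance_m, df$transect_id),
                 function(d) all(diff(d) > 0), logical(1))
  if (!all(mono)) {
    stop("non-monotone distance_m in transect(s): ",
         paste(names(mono)[!mono], collapse = ", "), call. = FALSE)
  }
  attr(df, "clean_report") <- report
  df
}

#' Write a transect profile table
#'
#' @param profiles Profile data.frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_profiles <- function(profiles, path) {
  write.csv(profiles, path, row.names = FALSE)
  invisible(path)
}

#' Build the regression observation table
#'
#' One observation per transect x depth section with a defined cover:
#' the shallow-section and deep-section potential rubble covers of each
#' transect become proportions in `[0, 1]`, tagged with the depth class and
#' the transect's aspect class. Transects without a defined aspect are
#' excluded from aspect analyses.
#'
#' @param summary Per-transect summary from [evaluate_profiles()].
#' @param transects Transect metadata with `transect_id` and `aspect_class`
#'   (from [extract_profiles()]).
#' @return data.frame: `transect_id`, `proportion`, `depth_class`,
#'   `aspect_class`.
#' @export
build_observations <- function(summary, transects) {
  aspect <- transects$aspect_class[match(summary$transect_id,
                                         transects$transect_id)]
  rows <- list()
  for (i in seq_len(nrow(summary))) {
    if (is.na(aspect[i])) next
    for (dc in c("shallow", "deep")) {
      cov <- summary[[paste0("cover_pct_", dc)]][i]
      if (is.na(cov)) next
      rows[[length(rows) + 1]] <- data.frame(
        transect_id = summary$transect_id[i], proportion = cov / 100,
        depth_class = dc, aspect_class = aspect[i]
      )
    }
  }
  if (length(rows) == 0) {
    stop("no observations with defined cover and aspect", call. = FALSE)
  }
  do.call(rbind, rows)
}

#' Pipeline configuration
#'
#' Collects every tunable quantity of the pipeline with defaults equal to
#' the study design: Table-2 base-case algorithm parameters, thresholds
#' 10-90% (critical 30/40/50), 500-m transect spacing, 10-m sample spacing,
#' 2-m end truncation, 10-m shallow/deep split and a 1000-m reef search
#' radius.
#'
#' @param params A [rubble_params()].
#' @param thresholds Cover thresholds (percent).
#' @param critical_thresholds Thresholds used for rankings.
#' @param transect_spacing_m,sample_spacing_m,truncate_limit_m,
#'   shallow_limit_m,reef_search_radius_m Scalars as documented above.
#' @param zero_base_thresholds `"exclude"` or `"include"` for
#'   [count_sensitivity()].
#' @param seed Integer seed for stochastic stages.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(params = rubble_params(),
                            thresholds = seq(10, 90, by = 10),
                            critical_thresholds = c(30, 40, 50),
                            transect_spacing_m = 500,
                            sample_spacing_m = 10,
                            truncate_limit_m = 2,
                            shallow_limit_m = 10,
                            reef_search_radius_m = 1000,
                            zero_base_thresholds = c("exclude", "include"),
                            seed = 1L) {
  zero_base_thresholds <- match.arg(zero_base_thresholds)
  stopifnot(inherits(params, "rubble_params"),
            all(thresholds > 0 & thresholds < 100),
            all(critical_thresholds %in% thresholds),
            transect_spacing_m > 0, sample_spacing_m > 0,
            truncate_limit_m > 0, shallow_limit_m > 0,
            reef_search_radius_m > 0)
  structure(
    list(params = params, thresholds = thresholds,
         critical_thresholds = critical_thresholds,
         transect_spacing_m = transect_spacing_m,
         sample_spacing_m = sample_spacing_m,
         truncate_limit_m = truncate_limit_m,
         shallow_limit_m = shallow_limit_m,
         reef_search_radius_m = reef_search_radius_m,
         zero_base_thresholds = zero_base_thresholds,
         seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' Unknown keys are rejected; `params` may override any of the four
#' algorithm parameters. Overrides of the defaults are reported via message.
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- c("params", "thresholds", "critical_thresholds",
             "transect_spacing_m", "sample_spacing_m", "truncate_limit_m",
             "shallow_limit_m", "reef_search_radius_m",
             "zero_base_thresholds", "seed")
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0) {
    stop("unknown config key(s) in ", path, ": ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  args <- raw
  if (!is.null(raw$params)) args$params <- do.call(rubble_params, raw$params)
  if (length(args) > 0) {
    message("config overrides from ", path, ": ",
            paste(names(raw), collapse = ", "))
  }
  do.call(pipeline_config, args)
}

# Small rolling hash of a config's serialised text, for the manifest.
.config_hash <- function(config) {
  txt <- paste(deparse(unclass(config)), collapse = "")
  bytes <- utf8ToInt(txt)
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Run the full rubble-susceptibility pipeline on a profile table
#'
#' Orchestrates every stage downstream of profile extraction: per-point
#' rubble evaluation, per-transect summaries, reef susceptibility,
#' region-wide summary, top-decile rankings at the critical thresholds,
#' one-at-a-time sensitivity, and (when transect aspect metadata is given)
#' the two-component beta-mixture regression of cover on depth and aspect.
#' All tables are written as CSV beside a JSON manifest recording the
#' configuration, its hash and the row counts of every output; reruns with
#' the same inputs are byte-identical.
#'
#' @param profiles Profile table (or CSV path, read with `clean = TRUE`).
#' @param out_dir Output directory (created if needed).
#' @param config A [pipeline_config()].
#' @param transects Optional transect metadata (for the regression stage).
#' @param run_sensitivity,run_regression Toggle the expensive stages.
#' @return Invisibly, a list with every computed object and `manifest`.
#' @export
run_pipeline <- function(profiles, out_dir, config = pipeline_config(),
                         transects = NULL, run_sensitivity = TRUE,
                         run_regression = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.character(profiles)) profiles <- read_profiles(profiles, clean = TRUE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  outputs <- list()
  emit <- function(df, name) {
    path <- file.path(out_dir, paste0(name, ".csv"))
    write.csv(df, path, row.names = FALSE)
    outputs[[name]] <<- nrow(df)
    path
  }

  ev <- evaluate_profiles(profiles, config$params, config$shallow_limit_m)
  emit(ev$points, "point_flags")
  emit(ev$summary, "transect_summary")

  susc <- reef_susceptibility(ev$summary, config$thresholds,
                              config$transect_spacing_m)
  emit(susc, "reef_susceptibility")
  gbr <- gbr_summary(susc, ev$summary)
  emit(gbr$by_threshold, "gbr_summary")

  ranks <- do.call(rbind, lapply(config$critical_thresholds, function(t) {
    cbind(threshold = t, suppressWarnings(rank_top_decile(susc, t)))
  }))
  emit(ranks, "top_decile_rank")

  oat <- NULL
  if (run_sensitivity) {
    oat <- run_oat(profiles, config$params, config$thresholds,
                   spacing_m = config$transect_spacing_m)
    par_rank <- rank_parameters(oat, config$zero_base_thresholds)
    emit(par_rank, "parameter_sensitivity")
  }

  mix <- NULL
  if (run_regression) {
    if (is.null(transects)) {
      stop("run_regression requires transect aspect metadata", call. = FALSE)
    }
    obs <- build_observations(ev$summary, transects)
    mix <- fit_beta_mixture(obs, seed = config$seed)
    co <- do.call(rbind, lapply(1:2, function(k) {
      data.frame(component = k,
                 variable = rownames(mix$coefficients[[k]]),
                 mix$coefficients[[k]], row.names = NULL)
    }))
    emit(co, "mixture_coefficients")
    jsonlite::write_json(
      list(pi1 = mix$pi1, phi = mix$phi, loglik = mix$loglik,
           n_iter = mix$n_iter, converged = mix$converged),
      file.path(out_dir, "mixture_fit.json"), auto_unbox = TRUE, digits = NA)
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("reefrubble")),
    config = list(
      params = unclass(config$params),
      thresholds = config$thresholds,
      critical_thresholds = config$critical_thresholds,
      transect_spacing_m = config$transect_spacing_m,
      sample_spacing_m = config$sample_spacing_m,
      truncate_limit_m = config$truncate_limit_m,
      shallow_limit_m = config$shallow_limit_m,
      reef_search_radius_m = config$reef_search_radius_m,
      zero_base_thresholds = config$zero_base_thresholds,
      seed = config$seed
    ),
    config_hash = .config_hash(config),
    n_transects = nrow(ev$summary),
    outputs = outputs,
    excluded_reefs = gbr$excluded
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(evaluation = ev, susceptibility = susc, gbr = gbr,
                 rankings = ranks, oat = oat, mixture = mix,
                 manifest = manifest))
}
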