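.cohort_cols <- c("lesion_id", "true_type", "true_malignant", "cirrhotic",
                  "pattern", "area_lesion", "area_parenchyma")
.tic_cols <- c("lesion_id", "roi", "t_seconds", "intensity_db")

## numbers written with 12 significant digits so write -> read round-trips
.fmt_num <- function(x) ifelse(is.na(x), "", sprintf("%.12g", x))

#' Write / read a cohort lesion table (CSV)
#'
#' Plain UTF-8 CSV with "." as decimal separator, one row per lesion:
#' `lesion_id`, `true_type`, `true_malignant` (0/1), `cirrhotic` (0/1),
#' `pattern` (one of the seven arterial pattern labels, or empty),
#' `area_lesion`, `area_parenchyma` (dB, 12 significant digits). Reading
#' validates the schema and fails naming the first missing column, a
#' duplicated `lesion_id`, or an unknown pattern label.
#'
#' @param lesions cohort lesion data frame (as in [sample_cohort()]).
#' @param path file path.
#' @return `write_cohort` returns `path` invisibly; `read_cohort` the
#'   validated data frame.
#' @export
write_cohort <- function(lesions, path) {
  out <- data.frame(
    lesion_id = lesions$lesion_id,
    true_type = lesions$true_type,
    true_malignant = as.integer(lesions$true_malignant),
    cirrhotic = as.integer(lesions$cirrhotic),
    pattern = ifelse(is.na(lesions$pattern), "", lesions$pattern),
    area_lesion = .fmt_num(lesions$area_lesion),
    area_parenchyma = .fmt_num(lesions$area_parenchyma),
    stringsAsFactors = FALSE)
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(.cohort_cols, names(d))
  if (length(missing))
    stop("cohort file is missing required column(s): ",
         paste(missing, collapse = ", "))
  d$lesion_id <- as.character(d$lesion_id)
  d$pattern <- as.character(d$pattern)
  if (anyDuplicated(d$lesion_id))
    stop("duplicate lesion_id: ",
         d$lesion_id[duplicated(d$lesion_id)][1])
  d$pattern[is.na(d$pattern) | d$pattern == ""] <- NA_character_
  known <- enhancement_patterns()$pattern
  bad <- setdiff(stats::na.omit(unique(d$pattern)), known)
  if (length(bad))
    stop("unknown pattern label(s): ", paste(bad, collapse = ", "))
  d$true_malignant <- as.logical(d$true_malignant)
  d$cirrhotic <- as.logical(d$cirrhotic)
  d[.cohort_cols]
}

#' Write / read a long-format TIC table (CSV)
#'
#' One row per sample: `lesion_id`, `roi` (`lesion`/`parenchyma`),
#' `t_seconds`, `intensity_db`. The long format admits irregular sampling
#' grids. `(lesion_id, roi, t_seconds)` must be unique.
#'
#' @param tic TIC long data frame.
#' @param path file path.
#' @return `write_tic` returns `path` invisibly; `read_tic` the validated
#'   data frame.
#' @export
write_tic <- function(tic, path) {
  out <- data.frame(lesion_id = tic$lesion_id, roi = tic$roi,
                    t_seconds = .fmt_num(tic$t_seconds),
                    intensity_db = .fmt_num(tic$intensity_db),
                    stringsAsFactors = FALSE)
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_tic
#' @export
read_tic <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(.tic_cols, names(d))
  if (length(missing))
    stop("TIC file is missing required column(s): ",
         paste(missing, collapse = ", "))
  if (!all(d$roi %in% c("lesion", "parenchyma")))
    stop("'roi' must be 'lesion' or 'parenchyma'")
  if (any(d$t_seconds < 0)) stop("negative time in TIC file")
  if (anyDuplicated(d[c("lesion_id", "roi", "t_seconds")]))
    stop("duplicate (lesion_id, roi, t_seconds) in TIC file")
  d$lesion_id <- as.character(d$lesion_id)
  d[.tic_cols]
}

.rule_key <- function(cirrhotic, washout, pattern) {
  paste(ifelse(cirrhotic, "cirrhotic", "noncirrhotic"),
        ifelse(washout, "washout", "nowashout"), pattern, sep = "|")
}

#' Serialize a decision-tree rule table to / from JSON
#'
#' The rule table is stored as a flat JSON object whose keys are
#' `"cirrhotic|washout|pattern"` triplets (e.g.
#' `"cirrhotic|nowashout|iso-enhancement"`) and whose values are lesion
#' types, so alternative tree readings are plain data files.
#'
#' @param rule_table data frame as from [default_rule_table()].
#' @param path JSON file path.
#' @return `write_rule_table` returns `path` invisibly; `read_rule_table`
#'   the rule table data frame.
#' @export
write_rule_table <- function(rule_table, path) {
  keys <- .rule_key(rule_table$cirrhotic, rule_table$washout,
                    rule_table$pattern)
  obj <- as.list(stats::setNames(rule_table$type, keys))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_rule_table
#' @export
read_rule_table <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  parts <- strsplit(names(obj), "|", fixed = TRUE)
  if (any(lengths(parts) != 3))
    stop("malformed rule key; expected 'cirrhotic|washout|pattern'")
  out <- data.frame(
    cirrhotic = vapply(parts, function(p) p[1] == "cirrhotic", logical(1)),
    washout = vapply(parts, function(p) p[2] == "washout", logical(1)),
    pattern = vapply(parts, `[`, character(1), 3),
    type = unname(unlist(obj)), stringsAsFactors = FALSE)
  bad <- setdiff(out$pattern, enhancement_patterns()$pattern)
  if (length(bad))
    stop("unknown pattern label(s) in rule table: ",
         paste(bad, collapse = ", "))
  out
}

#' Write / read a cohort-generator configuration (JSON)
#'
#' @param cfg a [cohort_config()].
#' @param path JSON file path.
#' @return `write_config` returns `path` invisibly; `read_config` a
#'   validated `cohort_config`.
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "cohort_config"))
  keep <- setdiff(names(cfg), "count_mode")
  obj <- cfg[keep]
  obj$composition <- as.list(obj$composition)
  obj <- obj[!vapply(obj, is.null, logical(1))]
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$composition <- unlist(obj$composition)
  if (!is.null(obj$area_max))       # jsonlite writes Inf as the string "Inf"
    obj$area_max <- as.numeric(obj$area_max)
  if (!is.null(obj$malignant_override))
    obj$malignant_override <- unlist(obj$malignant_override)
  args <- obj[intersect(names(obj), names(formals(cohort_config)))]
  do.call(cohort_config, args)
}

## run one pipeline stage, prefixing any error with the stage name
.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE))
}

#' Run the full simulate-quantify-classify-evaluate pipeline
#'
#' Orchestrates the whole decision pipeline: draw (or load) a cohort, fit
#' the washout model to every TIC, run the three-step decision tree, and
#' score the result against the reference diagnoses. All artifacts are
#' written to `out_dir`: `cohort.csv`, `tic.csv`, `tic_params.csv`,
#' `results.csv`, `report.json` and `run_log.json` (seed, cutoff,
#' config/rule-table MD5 hashes, AREA mode, package and R versions). The
#' report JSON stores each proportion both as an exact fraction and as a
#' conventionally rounded percentage string, so downstream checks are
#' rounding-unambiguous. Identical seeds give byte-identical reports.
#'
#' @param config a [cohort_config()], or path to a config JSON.
#' @param out_dir output directory (created if needed).
#' @param seed integer seed overriding the config's.
#' @param cutoff washout cutoff, dB.
#' @param rule_table decision-tree rule table.
#' @param cohort optionally, a precomputed `mpus_cohort` to use instead of
#'   simulating (the config is then ignored for generation).
#' @param area_mode passed to the washout fits.
#' @return the [evaluate_results()] report, invisibly; the written file
#'   paths are attached as attribute `"paths"`.
#' @export
#' @examples
#' \donttest{
#' out <- run_pipeline(cohort_config(n = 20,
#'                                   composition = c(HCC = 10,
#'                                                   haemangioma = 10)),
#'                     out_dir = tempfile(), seed = 1)
#' }
run_pipeline <- function(config, out_dir, seed = NULL, cutoff = -19.3,
                         rule_table = default_rule_table(),
                         cohort = NULL,
                         area_mode = c("fitted", "raw")) {
  area_mode <- match.arg(area_mode)
  if (is.character(config)) config <- .stage("config", read_config(config))
  if (!is.null(seed)) config$seed <- seed
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  if (is.null(cohort))
    cohort <- .stage("simulate", sample_cohort(config))
  params <- .stage("quantify",
                   quantify_cohort(cohort, roi = "both",
                                   area_mode = area_mode))
  results <- .stage("classify", {
    les <- cohort$lesions
    areas <- params$area[params$roi == "lesion"]
    ids <- params$lesion_id[params$roi == "lesion"]
    rows <- lapply(seq_len(nrow(les)), function(i) {
      a <- areas[match(les$lesion_id[i], ids)]
      r <- bdtc_classify(les$cirrhotic[i], a,
                         pattern = if (is.na(les$pattern[i])) NA
                                   else les$pattern[i],
                         cutoff = cutoff, rule_table = rule_table)
      data.frame(lesion_id = les$lesion_id[i], area_lesion = a,
                 washout = r$washout,
                 predicted_malignant = r$predicted_malignant,
                 predicted_type = r$predicted_type,
                 path = paste(r$path, collapse = " -> "),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
  report <- .stage("evaluate", evaluate_results(results, cohort$lesions))

  paths <- c(cohort = file.path(out_dir, "cohort.csv"),
             tic = file.path(out_dir, "tic.csv"),
             params = file.path(out_dir, "tic_params.csv"),
             results = file.path(out_dir, "results.csv"),
             report = file.path(out_dir, "report.json"),
             log = file.path(out_dir, "run_log.json"))
  write_cohort(cohort$lesions, paths[["cohort"]])
  write_tic(cohort$tic, paths[["tic"]])
  utils::write.csv(params, paths[["params"]], row.names = FALSE)
  utils::write.csv(results, paths[["results"]], row.names = FALSE)

  conf <- report$confusion
  rep_obj <- list(
    n = report$n,
    confusion = list(tp = conf$tp, fp = conf$fp, tn = conf$tn, fn = conf$fn),
    metrics = list(
      sensitivity = conf$sensitivity, specificity = conf$specificity,
      ppv = conf$ppv, npv = conf$npv, accuracy = conf$accuracy,
      f1 = conf$f1, auroc_area = report$auroc_area,
      detection_rate = report$detection$rate),
    printed = list(
      sensitivity = format_pct(conf$sensitivity),
      specificity = format_pct(conf$specificity),
      ppv = format_pct(conf$ppv), npv = format_pct(conf$npv),
      accuracy = format_pct(conf$accuracy), f1 = format_pct(conf$f1),
      detection_rate = sprintf("%d%%", report$detection$percent)))
  jsonlite::write_json(rep_obj, paths[["report"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  cfg_tmp <- tempfile(fileext = ".json"); write_config(config, cfg_tmp)
  rt_tmp <- tempfile(fileext = ".json"); write_rule_table(rule_table, rt_tmp)
  log_obj <- list(seed = if (is.null(config$seed)) NA else config$seed,
                  cutoff = cutoff,
                  area_mode = area_mode,
                  config_md5 = unname(tools::md5sum(cfg_tmp)),
                  rule_table_md5 = unname(tools::md5sum(rt_tmp)),
                  package_version = as.character(
                    utils::packageVersion("mpus")),
                  r_version = paste(R.version$major, R.version$minor,
                                    sep = "."))
  unlink(c(cfg_tmp, rt_tmp))
  jsonlite::write_json(log_obj, paths[["log"]], auto_unbox = TRUE,
                       pretty = TRUE)

  attr(report, "paths") <- paths
  invisible(report)
}
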